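#' 2-D affine transform
#'
#' @param linear 2x2 invertible matrix
#' @param translation length-2 numeric vector (micrometres)
#' @return object of class `affine_transform`
#' @export
affine_transform <- function(linear = diag(2), translation = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (abs(det(linear)) < .Machine$double.eps * 100) {
    stop("invalid transform: linear part is singular", call. = FALSE)
  }
  structure(list(linear = linear, translation = as.numeric(translation)),
            class = "affine_transform")
}

apply_affine <- function(tr, coords) {
  out <- t(tr$linear %*% t(coords) + tr$translation)
  colnames(out) <- colnames(coords)
  rownames(out) <- rownames(coords)
  out
}

#' Per-unit normalized axis coordinate
#'
#' A lightweight container for the rostrocaudal axis value of each unit:
#' `value` lies in \[0,1\] (NA for out-of-mask units), with 0 at the
#' rostral landmark and 1 at the caudal landmark.
#'
#' @param unit_ids character identifiers
#' @param value numeric in \[0,1\] or NA
#' @param method axis construction method used
#' @param rostral_landmark,caudal_landmark landmark labels
#' @return object of class `axis_assignment`
#' @export
axis_assignment <- function(unit_ids, value, method = "relative_distance",
                            rostral_landmark = NA_character_,
                            caudal_landmark = NA_character_) {
  value <- as.numeric(value)
  if (length(value) != length(unit_ids)) {
    stop("value and unit_ids lengths differ", call. = FALSE)
  }
  ok <- !is.na(value)
  if (any(value[ok] < 0 | value[ok] > 1)) {
    stop("axis values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(unit_ids = as.character(unit_ids), value = value,
                 method = method, rostral_landmark = rostral_landmark,
                 caudal_landmark = caudal_landmark),
            class = "axis_assignment")
}

#' @export
print.axis_assignment <- function(x, ...) {
  cat(sprintf("<axis_assignment> %d units (%d with values), method %s\n",
              length(x$unit_ids), sum(!is.na(x$value)), x$method))
  invisible(x)
}

#' Assign a normalized rostrocaudal axis from landmark annotations
#'
#' For each in-mask unit u, the distance d_R(u) to the nearest
#' rostral-landmark unit and d_C(u) to the nearest caudal-landmark unit
#' are computed, and the axis value is the normalized relative distance
#' d_R / (d_R + d_C), so annotated rostral units sit at 0 and caudal
#' units at 1. With `method = "geodesic"` (the default) distances are
#' shortest paths along a spatial adjacency graph (symmetric kNN graph,
#' edges longer than 3x the median nearest-neighbour spacing removed),
#' which tracks arc-length in curved organs where straight-line distance
#' does not; if the graph is disconnected the method falls back to
#' Euclidean distance with a warning.
#'
#' @param spatial a [spatial_dataset()] with landmark annotations, all
#'   units in one coordinate frame (stitch first if multi-section)
#' @param rostral_label,caudal_label landmark labels defining the two axis
#'   ends
#' @param mask_label optional anatomical label; units outside the mask
#'   receive NA
#' @param method `"geodesic"` or `"euclidean"`
#' @param graph_k neighbours per unit for the geodesic adjacency graph
#' @return an [axis_assignment()]
#' @export
assign_axis <- function(spatial, rostral_label = "rostral_tip",
                        caudal_label = "caudal_tip", mask_label = NULL,
                        method = c("geodesic", "euclidean"), graph_k = 10L) {
  method <- match.arg(method)
  lm <- spatial$landmark_label
  r_idx <- which(!is.na(lm) & lm == rostral_label)
  c_idx <- which(!is.na(lm) & lm == caudal_label)
  if (!length(r_idx)) {
    stop("landmark not found: ", rostral_label, call. = FALSE)
  }
  if (!length(c_idx)) {
    stop("landmark not found: ", caudal_label, call. = FALSE)
  }
  coords <- spatial$coords
  if (method == "geodesic") {
    d <- geodesic_landmark_distances(coords, r_idx, c_idx, graph_k)
    if (is.null(d)) {
      warning("adjacency graph disconnected; falling back to euclidean",
              call. = FALSE)
      method <- "euclidean"
    }
  }
  if (method == "euclidean") {
    d <- list(rostral = min_euclidean(coords, r_idx),
              caudal = min_euclidean(coords, c_idx))
  }
  denom <- d$rostral + d$caudal
  if (any(denom == 0)) {
    stop("ambiguous landmarks: unit(s) at distance 0 from both ends: ",
         paste(unit_ids(spatial)[denom == 0], collapse = ", "), call. = FALSE)
  }
  value <- d$rostral / denom
  if (!is.null(mask_label)) {
    value[is.na(spatial$anatomical_label) |
            spatial$anatomical_label != mask_label] <- NA_real_
  }
  axis_assignment(unit_ids(spatial), value, method = method,
                  rostral_landmark = rostral_label,
                  caudal_landmark = caudal_label)
}

min_euclidean <- function(coords, idx) {
  d2 <- outer(rowSums(coords^2), rowSums(coords[idx, , drop = FALSE]^2), `+`) -
    2 * coords %*% t(coords[idx, , drop = FALSE])
  sqrt(pmax(apply(d2, 1, min), 0))
}

geodesic_landmark_distances <- function(coords, r_idx, c_idx, graph_k) {
  n <- nrow(coords)
  k <- min(graph_k, n - 1L)
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), `+`) -
    2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  dm <- sqrt(d2)
  nn1 <- apply(dm + diag(Inf, n), 1, min)
  cutoff <- 3 * stats::median(nn1)
  ord <- apply(dm, 1, order)  # column i: units sorted by distance to i
  from <- rep(seq_len(n), each = k)
  to <- as.vector(ord[2:(k + 1L), ])
  keep <- dm[cbind(from, to)] <= cutoff | dm[cbind(from, to)] <= nn1[from]
  from <- from[keep]
  to <- to[keep]
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g <- igraph::simplify(g)
  igraph::E(g)$weight <- dm[igraph::as_edgelist(g, names = FALSE)]
  # bridge stray components (sparse outlying units) with their shortest
  # connecting edge so the geodesic remains defined on the whole tissue
  comp <- igraph::components(g)
  guard <- 0L
  while (comp$no > 1L && guard < n) {
    main <- which(comp$membership == which.max(comp$csize))
    rest <- setdiff(seq_len(n), main)
    sub <- dm[rest, main, drop = FALSE]
    hit <- arrayInd(which.min(sub), dim(sub))
    u <- rest[hit[1]]
    v <- main[hit[2]]
    g <- igraph::add_edges(g, c(u, v), weight = dm[u, v])
    comp <- igraph::components(g)
    guard <- guard + 1L
  }
  if (comp$no > 1L) return(NULL)
  dr <- igraph::distances(g, v = seq_len(n), to = r_idx)
  dc <- igraph::distances(g, v = seq_len(n), to = c_idx)
  list(rostral = apply(dr, 1, min), caudal = apply(dc, 1, min))
}

#' Stitch consecutive sections into one coordinate frame
#'
#' Applies a per-section affine transform (typically estimated from image
#' alignment elsewhere) to each section's coordinates and concatenates the
#' sections into a single dataset. Gene universes are unified by union
#' with zero-fill; a message reports genes not shared by all sections.
#' Unit identifiers duplicated across sections are prefixed by section.
#'
#' @param sections list of [spatial_dataset()]
#' @param transforms list of [affine_transform()], one per section,
#'   mapping each section's local frame to the common global frame
#' @return a single [spatial_dataset()]
#' @export
stitch_sections <- function(sections, transforms) {
  if (length(sections) != length(transforms)) {
    stop("need one transform per section", call. = FALSE)
  }
  transforms <- lapply(transforms, function(tr) {
    if (!inherits(tr, "affine_transform")) {
      tr <- affine_transform(tr[, 1:2], tr[, 3])
    }
    tr
  })
  all_genes <- unique(unlist(lapply(sections, gene_ids)))
  shared <- Reduce(intersect, lapply(sections, gene_ids))
  if (length(shared) < length(all_genes)) {
    message(sprintf("stitch_sections: %d/%d genes not shared by all sections; zero-filled",
                    length(all_genes) - length(shared), length(all_genes)))
  }
  ids <- unlist(lapply(sections, unit_ids))
  prefix <- anyDuplicated(ids) > 0L
  parts <- vector("list", length(sections))
  coords <- vector("list", length(sections))
  meta <- list(section_id = NULL, anatomical_label = NULL,
               landmark_label = NULL)
  for (i in seq_along(sections)) {
    sec <- sections[[i]]
    m <- Matrix::Matrix(0, n_units(sec), length(all_genes), sparse = TRUE,
                        dimnames = list(unit_ids(sec), all_genes))
    m[, gene_ids(sec)] <- sec$counts
    if (prefix) rownames(m) <- paste(sec$section_id, rownames(m), sep = ":")
    parts[[i]] <- m
    co <- apply_affine(transforms[[i]], sec$coords)
    rownames(co) <- rownames(m)
    coords[[i]] <- co
    meta$section_id <- c(meta$section_id, sec$section_id)
    meta$anatomical_label <- c(meta$anatomical_label, sec$anatomical_label)
    meta$landmark_label <- c(meta$landmark_label, sec$landmark_label)
  }
  spatial_dataset(do.call(rbind, parts), do.call(rbind, coords),
                  section_id = meta$section_id,
                  anatomical_label = meta$anatomical_label,
                  landmark_label = meta$landmark_label)
}

#' Rescale an axis with a piecewise-linear monotone map
#'
#' Anchors (raw -> target) let different samples of the same organ be put
#' on a consistent axis; (0,0) and (1,1) are implicit, so an empty anchor
#' list is the identity map.
#'
#' @param assignment an [axis_assignment()]
#' @param anchors numeric matrix / data.frame with two columns (raw,
#'   target) or an empty list; both columns must be strictly increasing
#'   within (0,1)
#' @return a rescaled [axis_assignment()]
#' @export
rescale_axis <- function(assignment, anchors = NULL) {
  if (is.null(anchors) || (is.list(anchors) && !length(anchors)) ||
      (is.data.frame(anchors) && !nrow(anchors))) {
    anchors <- matrix(numeric(), 0, 2)
  }
  anchors <- matrix(as.numeric(as.matrix(anchors)), ncol = 2)
  raw <- c(0, anchors[, 1], 1)
  target <- c(0, anchors[, 2], 1)
  if (is.unsorted(raw, strictly = TRUE) || is.unsorted(target, strictly = TRUE)) {
    stop("invalid anchors: must be strictly increasing in both coordinates",
         call. = FALSE)
  }
  ok <- !is.na(assignment$value)
  out <- assignment
  out$value[ok] <- stats::approx(raw, target, xout = assignment$value[ok])$y
  out
}

#' Bin axis values into equal-width intervals
#'
#' @param assignment an [axis_assignment()] (or a bare numeric vector of
#'   values in \[0,1\])
#' @param n_bins number of bins (>= 2)
#' @return integer bin index in 0..n_bins-1 per unit (NA preserved);
#'   value 1 falls in the last bin
#' @export
bin_axis <- function(assignment, n_bins = 20L) {
  if (n_bins < 2) stop("n_bins must be at least 2", call. = FALSE)
  value <- if (inherits(assignment, "axis_assignment")) {
    assignment$value
  } else {
    as.numeric(assignment)
  }
  bin <- floor(value * n_bins)
  bin[!is.na(bin) & bin >= n_bins] <- n_bins - 1L
  as.integer(bin)
}
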
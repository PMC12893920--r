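# Shared-gene PCA space for reference->query kNN transfer.
#
# Both datasets are restricted to shared genes, log[CPM/100+1]
# normalized, scaled per gene with the REFERENCE mean/sd (so the query is
# projected into the reference's space rather than a batch-dominated
# joint embedding), and projected onto the reference's top principal
# components.
transfer_space <- function(reference, query, n_pcs) {
  shared <- intersect(gene_ids(reference), gene_ids(query))
  if (length(shared) < 10) {
    stop(sprintf("insufficient panel: only %d shared genes (need >= 10)",
                 length(shared)), call. = FALSE)
  }
  ref <- as.matrix(normalize_log_cpm100(reference)[, shared, drop = FALSE])
  qry <- as.matrix(normalize_log_cpm100(query)[, shared, drop = FALSE])
  mu <- colMeans(ref)
  sd <- apply(ref, 2, stats::sd)
  sd[sd == 0] <- 1
  ref <- sweep(sweep(ref, 2, mu), 2, sd, `/`)
  qry <- sweep(sweep(qry, 2, mu), 2, sd, `/`)
  n_pcs <- min(n_pcs, ncol(ref), nrow(ref) - 1L)
  pca <- stats::prcomp(ref, center = FALSE, scale. = FALSE, rank. = n_pcs)
  list(ref = pca$x,
       qry = qry %*% pca$rotation,
       n_shared_genes = length(shared))
}

# k nearest reference rows for each query row (Euclidean), ties broken by
# reference index for reproducibility. Returns k x n_query index matrix.
knn_index <- function(ref_pc, qry_pc, k) {
  d2 <- outer(rowSums(qry_pc^2), rowSums(ref_pc^2), `+`) -
    2 * tcrossprod(qry_pc, ref_pc)
  d2[d2 < 0] <- 0
  idx <- apply(d2, 1, function(d) order(d)[seq_len(k)])
  matrix(idx, nrow = k)
}

#' Impute an axis coordinate onto dissociated cells by kNN transfer
#'
#' Each query cell receives the mean (optionally inverse-distance
#' weighted) axis value of its k nearest reference units in the shared
#' reference-fit PC space. Reference units with a missing axis value are
#' excluded before the neighbour search. Confidence is
#' 1 - sd(neighbour values) / (reference axis range / 2), clamped to
#' \[0,1\]: 1 when all neighbours agree, low when they span the organ.
#'
#' @param reference a [spatial_dataset()] (ISS-like, panel-limited)
#' @param ref_axis an [axis_assignment()] on the reference units
#' @param query an [expression_dataset()] of dissociated cells
#' @param k number of nearest neighbours
#' @param n_pcs number of reference principal components
#' @param weighted inverse-distance weighting of neighbour values
#' @return a data.frame of class `transfer_result`: unit_id, value,
#'   confidence, low_confidence; attributes `k`, `n_shared_genes`
#' @export
impute_axis_knn <- function(reference, ref_axis, query, k = 50L,
                            n_pcs = 30L, weighted = FALSE) {
  axis_vals <- ref_axis$value[match(unit_ids(reference), ref_axis$unit_ids)]
  usable <- which(!is.na(axis_vals))
  if (k > length(usable)) {
    stop(sprintf("invalid k: %d exceeds the %d usable reference units",
                 k, length(usable)), call. = FALSE)
  }
  if (k < 1) stop("invalid k: must be >= 1", call. = FALSE)
  reference <- subset_units(reference, usable)
  axis_vals <- axis_vals[usable]
  sp <- transfer_space(reference, query, n_pcs)
  nn <- knn_index(sp$ref, sp$qry, k)
  vals <- matrix(axis_vals[nn], nrow = k)
  if (weighted && k > 1) {
    imputed <- numeric(ncol(nn))
    for (i in seq_len(ncol(nn))) {
      d <- sqrt(colSums((t(sp$ref[nn[, i], , drop = FALSE]) - sp$qry[i, ])^2))
      w <- 1 / pmax(d, 1e-12)
      imputed[i] <- sum(w * vals[, i]) / sum(w)
    }
  } else {
    imputed <- colMeans(vals)
  }
  half_range <- max(diff(range(axis_vals)) / 2, .Machine$double.eps)
  disp <- if (k > 1) apply(vals, 2, stats::sd) else rep(0, ncol(nn))
  confidence <- pmin(pmax(1 - disp / half_range, 0), 1)
  res <- data.frame(unit_id = unit_ids(query), value = imputed,
                    confidence = confidence,
                    low_confidence = confidence < 0.5,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("transfer_result", "data.frame"),
            k = k, n_shared_genes = sp$n_shared_genes)
}

#' Transfer categorical labels from a spatial reference by kNN majority vote
#'
#' The query label is the majority label among the k nearest reference
#' units; confidence is the majority fraction. Units whose majority
#' fraction falls below `min_fraction` are flagged low-confidence but
#' retained, matching the convention of keeping only transfers with a
#' label fraction above 0.8 for downstream enrichment summaries.
#'
#' @inheritParams impute_axis_knn
#' @param labels per-reference-unit labels; defaults to
#'   `reference$unit_meta$cell_type`
#' @param min_fraction majority fraction below which a transfer is
#'   flagged low-confidence
#' @return a data.frame of class `transfer_result`: unit_id, label,
#'   confidence, low_confidence
#' @export
transfer_labels_knn <- function(reference, query, labels = NULL, k = 50L,
                                min_fraction = 0.8, n_pcs = 30L) {
  if (is.null(labels)) labels <- reference$unit_meta$cell_type
  labels <- as.character(labels)
  if (length(labels) != n_units(reference) || anyNA(labels)) {
    stop("reference labels must be non-missing, one per unit", call. = FALSE)
  }
  if (k < 1 || k > n_units(reference)) {
    stop("invalid k for the reference size", call. = FALSE)
  }
  sp <- transfer_space(reference, query, n_pcs)
  nn <- knn_index(sp$ref, sp$qry, k)
  vote <- apply(nn, 2, function(idx) {
    tab <- table(labels[idx])
    top <- tab[order(-tab, names(tab))][1]  # lexicographic tie-break
    c(names(top), unname(top) / length(idx))
  })
  confidence <- as.numeric(vote[2, ])
  res <- data.frame(unit_id = unit_ids(query), label = vote[1, ],
                    confidence = confidence,
                    low_confidence = confidence < min_fraction,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("transfer_result", "data.frame"),
            k = k, n_shared_genes = sp$n_shared_genes)
}
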
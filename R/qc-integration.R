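#' Shannon entropy of label composition per cluster
#'
#' H(cluster) = -sum_l f_l log_base(f_l) over the labels present in the
#' cluster. With donor labels, clusters with entropy 0 (donor-specific
#' clusters) are flagged for removal.
#'
#' @param clusters per-unit cluster assignment
#' @param labels per-unit categorical labels (cell type, donor, sex, ...)
#' @param base logarithm base (2 = bits)
#' @param flag_zero_entropy set the removal flag for zero-entropy
#'   clusters (the donor-specific-cluster rule)
#' @return data.frame: cluster_id, n_units, entropy, majority_label,
#'   majority_fraction, remove_flag; per-cluster label fractions in
#'   attribute `label_fractions`
#' @export
cluster_label_entropy <- function(clusters, labels, base = 2,
                                  flag_zero_entropy = FALSE) {
  if (length(clusters) != length(labels)) {
    stop("invalid input: clusters and labels lengths differ", call. = FALSE)
  }
  if (anyNA(clusters) || anyNA(labels)) {
    stop("invalid input: missing values", call. = FALSE)
  }
  clusters <- as.character(clusters)
  labels <- as.character(labels)
  ids <- sort(unique(clusters))
  fractions <- lapply(ids, function(cl) {
    tab <- table(labels[clusters == cl])
    tab / sum(tab)
  })
  names(fractions) <- ids
  rows <- lapply(ids, function(cl) {
    f <- fractions[[cl]]
    h <- -sum(f * log(f) / log(base))
    top <- f[order(-f, names(f))][1]
    data.frame(cluster_id = cl, n_units = sum(clusters == cl),
               entropy = h, majority_label = names(top),
               majority_fraction = unname(top),
               remove_flag = flag_zero_entropy && h == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "label_fractions") <- fractions
  attr(out, "base") <- base
  out
}

#' Annotate clusters by thresholded majority vote
#'
#' Assigns each cluster its modal label when the modal fraction is at
#' least `threshold` (inclusive); otherwise "unresolved". Modal ties at
#' or above the threshold are also "unresolved", with the tie flagged.
#'
#' @inheritParams cluster_label_entropy
#' @param threshold minimum modal fraction for assignment
#' @return data.frame: cluster_id, label, majority_fraction, tie
#' @export
majority_vote_annotation <- function(clusters, labels, threshold = 0.40) {
  if (length(clusters) != length(labels)) {
    stop("invalid input: clusters and labels lengths differ", call. = FALSE)
  }
  clusters <- as.character(clusters)
  labels <- as.character(labels)
  ids <- sort(unique(clusters))
  rows <- lapply(ids, function(cl) {
    tab <- table(labels[clusters == cl])
    f <- tab / sum(tab)
    f <- f[order(-f, names(f))]
    tie <- length(f) > 1 && f[2] == f[1]
    assigned <- f[1] >= threshold && !tie
    data.frame(cluster_id = cl,
               label = if (assigned) names(f)[1] else "unresolved",
               majority_fraction = unname(f[1]), tie = tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' TF-IDF cluster marker genes
#'
#' Term frequency = fraction of the cluster's units detecting the gene
#' (count > 0); inverse document frequency = ln(total units / units
#' detecting the gene dataset-wide); score = tf * idf. Genes never
#' expressed are dropped. The top `top_n` genes per cluster are
#' returned, ties broken by higher tf then gene identifier.
#'
#' @param ds an [expression_dataset()]
#' @param clusters per-unit cluster assignment (>= 2 clusters)
#' @param top_n markers reported per cluster
#' @return data.frame: cluster_id, gene_id, tf, idf, score, rank
#' @export
tfidf_markers <- function(ds, clusters, top_n = 20L) {
  clusters <- as.character(clusters)
  if (length(clusters) != n_units(ds)) {
    stop("invalid input: one cluster per unit required", call. = FALSE)
  }
  if (length(unique(clusters)) < 2) {
    stop("invalid input: need at least 2 clusters", call. = FALSE)
  }
  detected <- ds$counts > 0
  n_total <- n_units(ds)
  n_expr <- Matrix::colSums(detected)
  keep <- n_expr >= 1
  detected <- detected[, keep, drop = FALSE]
  idf <- log(n_total / n_expr[keep])
  rows <- lapply(sort(unique(clusters)), function(cl) {
    in_cl <- clusters == cl
    tf <- Matrix::colMeans(detected[in_cl, , drop = FALSE])
    score <- tf * idf
    ord <- order(-score, -tf, colnames(detected))[seq_len(min(top_n, length(score)))]
    data.frame(cluster_id = cl, gene_id = colnames(detected)[ord],
               tf = tf[ord], idf = idf[ord], score = score[ord],
               rank = seq_along(ord), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cell-type by region z-score enrichment
#'
#' Per cell type and region, mean abundance over the region's units; the
#' z-score standardizes each cell type's regional means across regions
#' (sample sd, `ddof = 1`). Cell types with zero sd across regions get
#' an all-zero row.
#'
#' @param abundance units x cell-type non-negative matrix (e.g. deconvolved
#'   abundances, or a one-hot cell-type indicator for single-cell data)
#' @param regions per-unit region labels
#' @param ddof degrees-of-freedom correction for the sd (1 = sample sd)
#' @return cell-type x region z-score matrix
#' @export
celltype_region_enrichment <- function(abundance, regions, ddof = 1) {
  abundance <- as.matrix(abundance)
  regions <- as.character(regions)
  if (length(regions) != nrow(abundance)) {
    stop("one region per unit required", call. = FALSE)
  }
  if (anyNA(regions)) stop("every unit needs a region", call. = FALSE)
  region_ids <- sort(unique(regions))
  if (length(region_ids) < 2) stop("need at least 2 regions", call. = FALSE)
  m <- vapply(region_ids, function(r) {
    idx <- which(regions == r)
    if (!length(idx)) stop("empty region: ", r, call. = FALSE)
    colMeans(abundance[idx, , drop = FALSE])
  }, numeric(ncol(abundance)))
  m <- matrix(m, nrow = ncol(abundance))  # guard the single-cell-type case
  mu <- rowMeans(m)
  n_r <- length(region_ids)
  sd <- sqrt(rowSums((m - mu)^2) / (n_r - ddof))
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  dimnames(z) <- list(colnames(abundance), region_ids)
  z
}
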
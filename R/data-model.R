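#' Expression dataset: sparse counts plus unit and gene metadata
#'
#' The basic container used throughout the package: a sparse non-negative
#' integer count matrix with units (cells or spots) as rows and genes as
#' columns, a per-unit metadata table (donor, sex, stage, cluster, cell
#' type, ...) and optional per-gene metadata.
#'
#' @param counts matrix or sparse Matrix, units x genes, non-negative
#'   integers. Dimnames supply unit and gene identifiers; defaults are
#'   generated when absent.
#' @param unit_meta optional data.frame of per-unit metadata, one row per
#'   unit in matrix order (a `unit_id` column, if present, must match).
#' @param gene_meta optional data.frame of per-gene metadata (e.g. a
#'   mitochondrial flag), one row per gene.
#' @return an object of class `expression_dataset`: a list with elements
#'   `counts` (dgCMatrix), `unit_meta`, `gene_meta`.
#' @export
expression_dataset <- function(counts, unit_meta = NULL, gene_meta = NULL) {
  counts <- as_count_matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("unit_%d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("gene_%d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("unit identifiers must be unique", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("gene identifiers must be unique", call. = FALSE)
  }
  unit_meta <- check_meta(unit_meta, rownames(counts), "unit")
  gene_meta <- check_meta(gene_meta, colnames(counts), "gene")
  structure(
    list(counts = counts, unit_meta = unit_meta, gene_meta = gene_meta),
    class = "expression_dataset"
  )
}

#' Spatial dataset: an expression dataset whose units carry coordinates
#'
#' @inheritParams expression_dataset
#' @param coords two-column numeric matrix (x, y) in micrometres, one row
#'   per unit; must be finite.
#' @param section_id per-unit section identifier (recycled if length 1).
#' @param anatomical_label optional per-unit anatomical annotation.
#' @param landmark_label optional per-unit landmark annotation (NA for
#'   units that are not landmarks).
#' @return an object of class `spatial_dataset` (inherits
#'   `expression_dataset`) with additional elements `coords`,
#'   `section_id`, `anatomical_label`, `landmark_label`.
#' @export
spatial_dataset <- function(counts, coords, section_id = "section_1",
                            anatomical_label = NULL, landmark_label = NULL,
                            unit_meta = NULL, gene_meta = NULL) {
  ds <- expression_dataset(counts, unit_meta, gene_meta)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) != nrow(ds$counts)) {
    stop("coords must be a 2-column matrix with one row per unit", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("coords must be finite", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x_um", "y_um")
  rownames(coords) <- rownames(ds$counts)
  n <- nrow(coords)
  section_id <- rep_len(as.character(section_id), n)
  anatomical_label <- if (is.null(anatomical_label)) {
    rep(NA_character_, n)
  } else {
    rep_len(as.character(anatomical_label), n)
  }
  landmark_label <- if (is.null(landmark_label)) {
    rep(NA_character_, n)
  } else {
    rep_len(as.character(landmark_label), n)
  }
  ds$coords <- coords
  ds$section_id <- section_id
  ds$anatomical_label <- anatomical_label
  ds$landmark_label <- landmark_label
  class(ds) <- c("spatial_dataset", "expression_dataset")
  ds
}

as_count_matrix <- function(counts) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts@x != round(counts@x))) {
    stop("counts must be integers", call. = FALSE)
  }
  counts
}

check_meta <- function(meta, ids, what) {
  if (is.null(meta)) {
    meta <- data.frame(row.names = ids)
  } else {
    meta <- as.data.frame(meta)
    if (nrow(meta) != length(ids)) {
      stop(sprintf("%s_meta has %d rows for %d %ss", what, nrow(meta),
                   length(ids), what), call. = FALSE)
    }
    id_col <- paste0(what, "_id")
    if (id_col %in% names(meta) && !identical(as.character(meta[[id_col]]), ids)) {
      stop(sprintf("%s column does not match matrix dimnames", id_col),
           call. = FALSE)
    }
    rownames(meta) <- ids
  }
  meta
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<%s> %d units x %d genes\n", class(x)[1L],
              nrow(x$counts), ncol(x$counts)))
  if (ncol(x$unit_meta)) {
    cat("  unit_meta:", paste(names(x$unit_meta), collapse = ", "), "\n")
  }
  if (inherits(x, "spatial_dataset")) {
    cat(sprintf("  sections: %s\n", paste(unique(x$section_id), collapse = ", ")))
    n_lm <- sum(!is.na(x$landmark_label))
    if (n_lm) cat(sprintf("  landmark units: %d\n", n_lm))
  }
  invisible(x)
}

#' Number of units / genes and their identifiers
#' @param ds an `expression_dataset`
#' @return integer count or character vector of identifiers.
#' @export
n_units <- function(ds) nrow(ds$counts)

#' @rdname n_units
#' @export
n_genes <- function(ds) ncol(ds$counts)

#' @rdname n_units
#' @export
unit_ids <- function(ds) rownames(ds$counts)

#' @rdname n_units
#' @export
gene_ids <- function(ds) colnames(ds$counts)

#' Subset a dataset by units or genes
#'
#' Retains order of the supplied index; all parallel slots (metadata,
#' coordinates, labels) are subset consistently.
#'
#' @param ds an `expression_dataset` or `spatial_dataset`
#' @param idx integer, logical or character index into units (or genes)
#' @return a dataset of the same class.
#' @export
subset_units <- function(ds, idx) {
  if (is.character(idx)) idx <- match(idx, unit_ids(ds))
  if (is.logical(idx)) idx <- which(idx)
  if (anyNA(idx)) stop("unknown unit identifiers in subset", call. = FALSE)
  ds$counts <- ds$counts[idx, , drop = FALSE]
  ds$unit_meta <- ds$unit_meta[idx, , drop = FALSE]
  if (inherits(ds, "spatial_dataset")) {
    ds$coords <- ds$coords[idx, , drop = FALSE]
    ds$section_id <- ds$section_id[idx]
    ds$anatomical_label <- ds$anatomical_label[idx]
    ds$landmark_label <- ds$landmark_label[idx]
  }
  ds
}

#' @rdname subset_units
#' @export
subset_genes <- function(ds, idx) {
  if (is.character(idx)) {
    pos <- match(idx, gene_ids(ds))
    if (anyNA(pos)) {
      stop("genes absent from dataset: ",
           paste(idx[is.na(pos)], collapse = ", "), call. = FALSE)
    }
    idx <- pos
  }
  if (is.logical(idx)) idx <- which(idx)
  ds$counts <- ds$counts[, idx, drop = FALSE]
  ds$gene_meta <- ds$gene_meta[idx, , drop = FALSE]
  ds
}
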
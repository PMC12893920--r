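#' Read a 10x-style expression matrix triplet
#'
#' Reads a MatrixMarket coordinate file with its features and barcodes
#' TSVs (Cell Ranger dialect: genes as MTX rows, no TSV headers; the
#' first features column is the identifier, further columns are kept as
#' gene metadata). Gzipped files are read transparently. The returned
#' counts are units x genes. Duplicated gene identifiers are
#' disambiguated with a numeric suffix and a warning.
#'
#' @param matrix_path path to matrix.mtx(.gz)
#' @param features_path path to features.tsv(.gz)
#' @param barcodes_path path to barcodes.tsv(.gz)
#' @param truncate_non_integer truncate non-integer entries instead of
#'   raising a format error
#' @return an [expression_dataset()]
#' @export
read_expression_matrix <- function(matrix_path, features_path, barcodes_path,
                                   truncate_non_integer = FALSE) {
  for (p in c(matrix_path, features_path, barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  m <- Matrix::readMM(matrix_path)
  features <- utils::read.delim(features_path, header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                stringsAsFactors = FALSE)
  if (nrow(features) != nrow(m) || nrow(barcodes) != ncol(m)) {
    stop(sprintf(
      "format error: MTX is %d x %d but features has %d rows and barcodes %d",
      nrow(m), ncol(m), nrow(features), nrow(barcodes)), call. = FALSE)
  }
  m <- methods::as(m, "CsparseMatrix")
  if (any(m@x != round(m@x))) {
    if (truncate_non_integer) {
      m@x <- trunc(m@x)
    } else {
      stop("format error: non-integer values in count matrix", call. = FALSE)
    }
  }
  ids <- as.character(features[[1]])
  if (anyDuplicated(ids)) {
    warning("duplicated gene identifiers disambiguated with numeric suffixes",
            call. = FALSE)
    ids <- make.unique(ids, sep = "-")
  }
  counts <- Matrix::t(m)
  dimnames(counts) <- list(as.character(barcodes[[1]]), ids)
  gene_meta <- if (ncol(features) > 1) {
    stats::setNames(features[-1], paste0("feature_col", seq_len(ncol(features) - 1)))
  } else {
    NULL
  }
  expression_dataset(counts, gene_meta = gene_meta)
}

#' Write / read a dataset bundle directory
#'
#' `write_bundle` emits the on-disk exchange format: `matrix.mtx`
#' (1-based MatrixMarket coordinate, genes x units per the Cell Ranger
#' convention), `features.tsv`, `barcodes.tsv`, plus — for spatial data —
#' `coords.csv` (unit_id, x_um, y_um, section_id) and `landmarks.csv`
#' (unit_id, landmark_label), and `truth.json` when a synthetic truth is
#' supplied. `read_bundle` reads the directory back.
#'
#' @param ds an [expression_dataset()] or [spatial_dataset()]
#' @param dir output directory (created if needed)
#' @param truth optional synthetic truth list to serialize as truth.json
#' @return `write_bundle`: the directory, invisibly. `read_bundle`: a
#'   dataset of the appropriate class.
#' @export
write_bundle <- function(ds, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(ds$counts), file.path(dir, "matrix.mtx"))
  writeLines(gene_ids(ds), file.path(dir, "features.tsv"))
  writeLines(unit_ids(ds), file.path(dir, "barcodes.tsv"))
  if (inherits(ds, "spatial_dataset")) {
    utils::write.csv(
      data.frame(unit_id = unit_ids(ds), x_um = ds$coords[, 1],
                 y_um = ds$coords[, 2], section_id = ds$section_id),
      file.path(dir, "coords.csv"), row.names = FALSE)
    lm <- !is.na(ds$landmark_label)
    utils::write.csv(
      data.frame(unit_id = unit_ids(ds)[lm],
                 landmark_label = ds$landmark_label[lm]),
      file.path(dir, "landmarks.csv"), row.names = FALSE)
  }
  if (ncol(ds$unit_meta)) {
    utils::write.csv(cbind(unit_id = unit_ids(ds), ds$unit_meta),
                     file.path(dir, "unit_meta.csv"), row.names = FALSE)
  }
  if (!is.null(truth)) {
    tr <- truth
    if (!is.null(tr$gradient_table)) {
      tr$gradient_table <- as.data.frame(tr$gradient_table)
    }
    if (!is.null(tr$section_transforms)) {
      tr$section_transforms <- lapply(tr$section_transforms, function(t) {
        list(linear = t$linear, translation = t$translation)
      })
    }
    # named atomic vectors serialize as JSON objects (names survive the
    # round-trip), not as bare arrays
    tr <- lapply(tr, function(x) {
      if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
    })
    jsonlite::write_json(tr, file.path(dir, "truth.json"), digits = NA)
  }
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  ds <- read_expression_matrix(file.path(dir, "matrix.mtx"),
                               file.path(dir, "features.tsv"),
                               file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "unit_meta.csv")
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    ds$unit_meta <- check_meta(meta[setdiff(names(meta), "unit_id")],
                               unit_ids(ds), "unit")
  }
  coords_path <- file.path(dir, "coords.csv")
  if (!file.exists(coords_path)) return(ds)
  co <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  idx <- match(unit_ids(ds), co$unit_id)
  if (anyNA(idx)) stop("coords.csv missing units", call. = FALSE)
  landmark <- rep(NA_character_, n_units(ds))
  lm_path <- file.path(dir, "landmarks.csv")
  if (file.exists(lm_path)) {
    lm <- utils::read.csv(lm_path, stringsAsFactors = FALSE)
    landmark[match(lm$unit_id, unit_ids(ds))] <- lm$landmark_label
  }
  spatial_dataset(ds$counts, as.matrix(co[idx, c("x_um", "y_um")]),
                  section_id = co$section_id[idx],
                  landmark_label = landmark,
                  unit_meta = ds$unit_meta, gene_meta = ds$gene_meta)
}

#' log[CPM/100 + 1] normalization
#'
#' Converts counts to the normalized expression space
#' `ln(count / total * 1e6 / 100 + 1)` (counts per million over 100,
#' i.e. counts per 10,000, natural log). Counts are left untouched; the
#' normalized matrix is returned separately (sparse).
#'
#' @param ds an [expression_dataset()] (or a bare counts matrix,
#'   units x genes)
#' @return sparse matrix of normalized expression, units x genes
#' @export
normalize_log_cpm100 <- function(ds) {
  counts <- if (inherits(ds, "expression_dataset")) ds$counts else
    as_count_matrix(ds)
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) {
    stop("zero-library unit(s): ",
         paste(rownames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  }
  norm <- Matrix::Diagonal(x = 1e4 / totals) %*% counts
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  methods::as(norm, "CsparseMatrix")
}

#' Quality-control filter for cells
#'
#' Retains units detecting at least `min_genes` genes and with a
#' mitochondrial count fraction at most `max_mito_frac`; never reorders
#' retained units. The report reserves a `doublet_score` column so
#' externally computed doublet scores can be filtered with the same
#' machinery (doublet calling itself is out of scope).
#'
#' @param ds an [expression_dataset()]
#' @param min_genes minimum number of detected (count > 0) genes
#' @param max_mito_frac maximum mitochondrial count fraction
#' @param mito_prefix gene-identifier prefix marking mitochondrial genes
#' @return list with `dataset` (filtered) and `report` (per-unit
#'   data.frame: unit_id, n_genes, mito_frac, doublet_score, kept, reason)
#' @export
qc_filter_cells <- function(ds, min_genes = 1500L, max_mito_frac = 0.20,
                            mito_prefix = "MT-") {
  detected <- Matrix::rowSums(ds$counts > 0)
  mito <- startsWith(gene_ids(ds), mito_prefix)
  totals <- Matrix::rowSums(ds$counts)
  mito_frac <- ifelse(totals > 0,
                      Matrix::rowSums(ds$counts[, mito, drop = FALSE]) /
                        pmax(totals, 1), 0)
  keep_genes <- detected >= min_genes
  keep_mito <- mito_frac <= max_mito_frac
  kept <- keep_genes & keep_mito
  reason <- rep("", n_units(ds))
  reason[!keep_genes] <- "low_n_genes"
  reason[!keep_mito] <- ifelse(reason[!keep_mito] == "", "high_mito",
                               "low_n_genes;high_mito")
  report <- data.frame(unit_id = unit_ids(ds), n_genes = detected,
                       mito_frac = mito_frac,
                       doublet_score = NA_real_,
                       kept = kept, reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  if (!any(kept)) warning("qc_filter_cells removed every unit", call. = FALSE)
  list(dataset = subset_units(ds, which(kept)), report = report)
}
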
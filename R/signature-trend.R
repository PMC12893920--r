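#' Score units for a gene signature against expression-matched controls
#'
#' The average normalized expression of the signature genes minus the
#' average over an expression-matched control pool: genes are ranked by
#' dataset-mean normalized expression and cut into `n_ctrl_bins`
#' equal-size bins, and for each signature gene `ctrl_size` control
#' genes are sampled (without replacement, excluding signature genes)
#' from its bin. Scores are deterministic given the seed.
#'
#' @param ds an [expression_dataset()] (counts; normalized internally to
#'   log\[CPM/100 + 1\])
#' @param gene_set character vector of signature genes; absent genes are
#'   dropped with a warning
#' @param n_ctrl_bins number of expression bins for control matching
#' @param ctrl_size control genes sampled per signature gene
#' @param seed integer seed for control sampling
#' @return data.frame of class `signature_score`: unit_id, score;
#'   attributes `gene_set`, `control_pool`, `n_ctrl_bins`, `ctrl_size`,
#'   `seed`
#' @export
score_signature <- function(ds, gene_set, n_ctrl_bins = 25L, ctrl_size = 50L,
                            seed = 1L) {
  gene_set <- unique(as.character(gene_set))
  present <- intersect(gene_set, gene_ids(ds))
  if (!length(present)) {
    stop("empty signature: none of the genes are in the dataset", call. = FALSE)
  }
  if (length(present) < length(gene_set)) {
    warning(sprintf("%d signature gene(s) absent from dataset; dropped",
                    length(gene_set) - length(present)), call. = FALSE)
  }
  norm <- normalize_log_cpm100(ds)
  gmeans <- Matrix::colMeans(norm)
  # equal-size bins on the mean-expression ranking (random tie order is
  # avoided by ranking with ties.method = "first" on the sorted means)
  rk <- rank(gmeans, ties.method = "first")
  bins <- ceiling(rk / (length(gmeans) / n_ctrl_bins))
  names(bins) <- names(gmeans)
  pool <- withr_seed(seed, {
    unique(unlist(lapply(present, function(g) {
      # sorted so the sampled pool is invariant to gene order in the input
      cand <- sort(setdiff(names(bins)[bins == bins[g]], gene_set))
      if (!length(cand)) return(character())
      sample(cand, min(ctrl_size, length(cand)))
    })))
  })
  sig_mean <- Matrix::rowMeans(norm[, present, drop = FALSE])
  ctrl_mean <- if (length(pool)) {
    Matrix::rowMeans(norm[, pool, drop = FALSE])
  } else {
    rep(0, n_units(ds))
  }
  res <- data.frame(unit_id = unit_ids(ds), score = sig_mean - ctrl_mean,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("signature_score", "data.frame"),
            gene_set = present, control_pool = pool,
            n_ctrl_bins = n_ctrl_bins, ctrl_size = ctrl_size, seed = seed)
}

# Jonckheere-Terpstra statistic: sum over ordered group pairs i < j of
# Mann-Whitney counts #(a < b) + 0.5 #(a = b), a in group i, b in group j.
jt_statistic <- function(values, group_idx) {
  k <- length(group_idx)
  stat <- 0
  for (i in seq_len(k - 1)) {
    vi <- values[group_idx[[i]]]
    for (j in (i + 1):k) {
      vj <- values[group_idx[[j]]]
      cmp <- outer(vi, vj, `<`)
      ties <- outer(vi, vj, `==`)
      stat <- stat + sum(cmp) + 0.5 * sum(ties)
    }
  }
  stat
}

check_groups <- function(values, groups) {
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups[!is.na(groups)])
  if (nlevels(groups) < 2) stop("need at least 2 ordered groups", call. = FALSE)
  idx <- split(seq_along(groups), groups)
  if (any(lengths(idx) == 0)) stop("invalid groups: empty group", call. = FALSE)
  if (length(values) != length(groups)) {
    stop("values and groups lengths differ", call. = FALSE)
  }
  idx
}

#' Permutation Jonckheere-Terpstra trend test across ordered groups
#'
#' Tests a monotone trend of `values` across the stated order of
#' `groups` (e.g. signature scores across fimbria, ampulla, isthmus).
#' The null distribution is built by shuffling group labels `n_perm`
#' times; the p-value uses the add-one estimator
#' `(1 + #as-or-more-extreme) / (n_perm + 1)`, so it is never exactly 0.
#'
#' @param values numeric vector
#' @param groups factor (level order = hypothesized order) or character
#'   vector in order of first appearance
#' @param alternative `"decreasing"`, `"increasing"` or `"two_sided"`
#' @param n_perm number of label permutations
#' @param seed integer seed
#' @return list of class `trend_test`: `jt_stat`, `p_value`,
#'   `alternative`, `n_perm`, `seed`, `group_sizes`
#' @export
jonckheere_test <- function(values, groups,
                            alternative = c("decreasing", "increasing",
                                            "two_sided"),
                            n_perm = 2000L, seed = 1L) {
  alternative <- match.arg(alternative)
  idx <- check_groups(values, groups)
  obs <- jt_statistic(values, idx)
  sizes <- lengths(idx)
  perm <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      jt_statistic(sample(values), idx)
    }, 0)
  })
  p_inc <- (1 + sum(perm >= obs)) / (n_perm + 1)
  p_dec <- (1 + sum(perm <= obs)) / (n_perm + 1)
  p <- switch(alternative,
              increasing = p_inc,
              decreasing = p_dec,
              two_sided = min(1, 2 * min(p_inc, p_dec)))
  structure(list(jt_stat = obs, p_value = p, alternative = alternative,
                 n_perm = n_perm, seed = seed,
                 group_sizes = unname(sizes)),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("<trend_test> JT = %g, p = %.4g (%s, %d permutations)\n",
              x$jt_stat, x$p_value, x$alternative, x$n_perm))
  invisible(x)
}

#' Exact Jonckheere-Terpstra p-value by complete enumeration
#'
#' Enumerates every distinct assignment of the observed values to the
#' observed group sizes (the permutation null) and returns the exact
#' tail probability. Serves as the independent oracle for
#' [jonckheere_test()] on small instances.
#'
#' @inheritParams jonckheere_test
#' @param max_enum refuse instances with more than this many distinct
#'   assignments
#' @return list: `jt_stat`, `p_value`, `n_assignments`
#' @export
exact_jonckheere_p <- function(values, groups,
                               alternative = c("decreasing", "increasing",
                                               "two_sided"),
                               max_enum = 1e5) {
  alternative <- match.arg(alternative)
  idx <- check_groups(values, groups)
  sizes <- lengths(idx)
  n_assign <- factorial(sum(sizes)) / prod(factorial(sizes))
  if (n_assign > max_enum) {
    stop(sprintf("too large for enumeration: %.3g assignments (max %g)",
                 n_assign, max_enum), call. = FALSE)
  }
  obs <- jt_statistic(values, idx)
  # enumerate multiset partitions: choose indices for each group in turn
  stats_all <- numeric(0)
  recurse <- function(remaining, chosen) {
    g <- length(chosen) + 1L
    if (g > length(sizes)) {
      stats_all[length(stats_all) + 1L] <<- jt_statistic(values, chosen)
      return(invisible())
    }
    if (g == length(sizes)) {
      recurse(integer(0), c(chosen, list(remaining)))
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes[g], simplify = FALSE)
    for (p in picks) {
      recurse(setdiff(remaining, p), c(chosen, list(p)))
    }
  }
  recurse(seq_along(values), list())
  p_inc <- mean(stats_all >= obs)
  p_dec <- mean(stats_all <= obs)
  p <- switch(alternative,
              increasing = p_inc,
              decreasing = p_dec,
              two_sided = min(1, 2 * min(p_inc, p_dec)))
  list(jt_stat = obs, p_value = p, n_assignments = length(stats_all))
}

#' Per-cell target-set scoring with rank-sum enrichment filtering
#'
#' For each target set (drug), the per-cell score is the mean normalized
#' expression of its target genes. Scores of the focus cell type are
#' compared with all other cells by a Wilcoxon rank-sum test; drugs pass
#' when the BH-adjusted p-value is below `p_adj_max`, the log2 fold
#' change of mean scores exceeds `min_log2fc`, and at least
#' `min_expr_frac` of focus cells express at least one target. The table
#' is ordered by the standardized rank-sum statistic (the "rank score").
#'
#' @param ds an [expression_dataset()] with a `cell_type` column in
#'   `unit_meta` (or supply `cell_types`)
#' @param target_sets named list: drug -> character vector of target genes
#' @param focus_label the cell-type label tested for enrichment
#' @param cell_types optional per-unit cell-type labels
#' @param p_adj_max adjusted p-value threshold
#' @param min_log2fc log2 fold-change threshold on mean scores
#' @param min_expr_frac minimum fraction of focus cells expressing >= 1
#'   target
#' @return data.frame: drug, n_targets, mean_focus, mean_other,
#'   log2_fc, rank_score, p_value, p_adj, expr_frac, pass — ordered by
#'   decreasing rank_score
#' @export
target_set_enrichment <- function(ds, target_sets, focus_label,
                                  cell_types = NULL, p_adj_max = 0.01,
                                  min_log2fc = 2, min_expr_frac = 0.10) {
  if (is.null(cell_types)) cell_types <- ds$unit_meta$cell_type
  cell_types <- as.character(cell_types)
  if (length(cell_types) != n_units(ds)) {
    stop("need one cell-type label per unit", call. = FALSE)
  }
  focus <- cell_types == focus_label
  if (!any(focus)) {
    stop("label not found: ", focus_label, call. = FALSE)
  }
  norm <- normalize_log_cpm100(ds)
  eps <- 1e-9
  rows <- lapply(names(target_sets), function(drug) {
    targets <- intersect(target_sets[[drug]], gene_ids(ds))
    if (!length(targets)) return(NULL)
    score <- Matrix::rowMeans(norm[, targets, drop = FALSE])
    w <- stats::wilcox.test(score[focus], score[!focus], exact = FALSE)
    n1 <- sum(focus); n2 <- sum(!focus)
    r <- rank(score)
    rank_sum <- sum(r[focus])
    z <- (rank_sum - n1 * (n1 + n2 + 1) / 2) /
      sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    expr_frac <- mean(Matrix::rowSums(
      ds$counts[focus, targets, drop = FALSE] > 0) > 0)
    data.frame(drug = drug, n_targets = length(targets),
               mean_focus = mean(score[focus]),
               mean_other = mean(score[!focus]),
               log2_fc = log2((mean(score[focus]) + eps) /
                                (mean(score[!focus]) + eps)),
               rank_score = z, p_value = w$p.value,
               expr_frac = expr_frac, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    stop("no target set has genes in the dataset", call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p_value, method = "BH")
  tab$pass <- tab$p_adj < p_adj_max & tab$log2_fc > min_log2fc &
    tab$expr_frac >= min_expr_frac
  tab <- tab[order(-tab$rank_score), ]
  rownames(tab) <- NULL
  tab
}

#' Read gene sets from a GMT or two-column TSV file
#'
#' GMT: tab-separated `set_id`, `description`, then member genes.
#' TSV: two columns `set_id`, `gene` (no header required; a header row
#' named set_id/gene is skipped).
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"gmt"` or `"tsv"`
#' @return named list of character vectors
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt(\\.gz)?$", path, ignore.case = TRUE)) {
      "gmt"
    } else {
      "tsv"
    }
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (format == "gmt") {
    sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
    names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  } else {
    parts <- strsplit(lines, "\t")
    if (identical(tolower(parts[[1]][1]), "set_id")) parts <- parts[-1]
    ids <- vapply(parts, `[`, "", 1)
    genes <- vapply(parts, `[`, "", 2)
    sets <- split(genes, ids)
  }
  sets
}
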
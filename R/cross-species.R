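#' Shared orthologue HVG feature space for two species
#'
#' Candidate features are one-to-one orthologue pairs expressed (count >
#' 0) in at least `min_cells` cells in BOTH datasets. Within each
#' dataset, candidates are ranked by normalized dispersion of
#' log-normalized expression (dispersion = variance/mean, z-scored
#' within 20 mean-expression bins) and the top `n_hvg` taken; the
#' returned feature list is the intersection of the two top sets.
#'
#' @param ds_a,ds_b the two [expression_dataset()]s
#' @param orth_map data.frame with columns `gene_a`, `gene_b` (one-to-one)
#' @param min_cells expression floor, in cells, applied in both species
#' @param n_hvg number of highly variable genes ranked per species
#' @return data.frame of class `shared_features` with columns `gene_a`,
#'   `gene_b`
#' @export
shared_hvg_space <- function(ds_a, ds_b, orth_map, min_cells = 10L,
                             n_hvg = 4000L) {
  orth_map <- as.data.frame(orth_map)
  if (!all(c("gene_a", "gene_b") %in% names(orth_map))) {
    stop("orth_map needs columns gene_a and gene_b", call. = FALSE)
  }
  if (anyDuplicated(orth_map$gene_a) || anyDuplicated(orth_map$gene_b)) {
    stop("orth_map must be one-to-one", call. = FALSE)
  }
  orth_map <- orth_map[orth_map$gene_a %in% gene_ids(ds_a) &
                         orth_map$gene_b %in% gene_ids(ds_b), , drop = FALSE]
  n_expr_a <- Matrix::colSums(ds_a$counts[, orth_map$gene_a, drop = FALSE] > 0)
  n_expr_b <- Matrix::colSums(ds_b$counts[, orth_map$gene_b, drop = FALSE] > 0)
  cand <- orth_map[n_expr_a >= min_cells & n_expr_b >= min_cells, , drop = FALSE]
  if (!nrow(cand)) {
    stop("no shared features pass the expression floor", call. = FALSE)
  }
  top_a <- hvg_rank(ds_a, cand$gene_a)
  top_b <- hvg_rank(ds_b, cand$gene_b)
  keep <- top_a <= min(n_hvg, nrow(cand)) & top_b <= min(n_hvg, nrow(cand))
  if (!any(keep)) stop("no shared features: empty HVG intersection", call. = FALSE)
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("shared_features", "data.frame"))
}

# Rank genes by normalized dispersion (1 = most variable).
hvg_rank <- function(ds, genes, n_bins = 20L) {
  norm <- normalize_log_cpm100(ds)[, genes, drop = FALSE]
  mu <- Matrix::colMeans(norm)
  ex2 <- Matrix::colMeans(norm^2)
  v <- pmax(ex2 - mu^2, 0) * nrow(norm) / max(nrow(norm) - 1, 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  qs <- stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1))
  bins <- cut(mu, breaks = unique(qs), include.lowest = TRUE)
  z <- disp
  for (b in levels(bins)) {
    i <- which(bins == b)
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  rank(-z, ties.method = "first")
}

#' Build kNN-graph neighbourhoods on an embedding
#'
#' Index cells are sampled uniformly without replacement
#' (`ceiling(sample_prop * n)` of them); each neighbourhood is its index
#' cell plus that cell's `k_graph` nearest neighbours in the embedding.
#' Neighbourhood expression profiles are mean log-normalized expression
#' of the member cells over the shared feature list, and each
#' neighbourhood carries the majority label of its members (with its
#' fraction) when labels are available.
#'
#' @param ds an [expression_dataset()]
#' @param features character vector of feature genes for the profiles
#' @param embedding optional numeric matrix (units x dims); default: the
#'   dataset's top 30 principal components on the scaled log-normalized
#'   feature expression
#' @param labels optional per-unit labels (default
#'   `ds$unit_meta$population`, then `$cell_type`)
#' @param k_graph neighbours per index cell
#' @param sample_prop fraction of units sampled as index cells
#' @param seed integer seed for index-cell sampling
#' @return object of class `neighbourhoods`: `index_units`, `membership`
#'   (list), `profile` (matrix nbhd x features), `majority_label`,
#'   `majority_fraction`
#' @export
build_neighbourhoods <- function(ds, features, embedding = NULL,
                                 labels = NULL, k_graph = 30L,
                                 sample_prop = 0.1, seed = 1L) {
  n <- n_units(ds)
  if (k_graph >= n) stop("k_graph must be below the number of units", call. = FALSE)
  n_index <- ceiling(sample_prop * n)
  if (n_index < 1) stop("invalid proportion: no index cells", call. = FALSE)
  if (is.null(labels)) {
    labels <- ds$unit_meta$population
    if (is.null(labels)) labels <- ds$unit_meta$cell_type
  }
  norm <- as.matrix(normalize_log_cpm100(ds)[, features, drop = FALSE])
  if (is.null(embedding)) {
    sc <- scale(norm)
    sc[, attr(sc, "scaled:scale") == 0] <- 0
    embedding <- stats::prcomp(sc, center = FALSE,
                               rank. = min(30L, ncol(sc), n - 1L))$x
  }
  embedding <- as.matrix(embedding)
  if (nrow(embedding) != n) {
    stop("embedding rows must align with dataset units", call. = FALSE)
  }
  index <- withr_seed(seed, sort(sample.int(n, n_index)))
  d2 <- outer(rowSums(embedding[index, , drop = FALSE]^2),
              rowSums(embedding^2), `+`) -
    2 * tcrossprod(embedding[index, , drop = FALSE], embedding)
  membership <- lapply(seq_along(index), function(i) {
    d <- d2[i, ]
    d[index[i]] <- -Inf                     # index cell always first
    ord <- order(d)[seq_len(k_graph + 1L)]
    sort(ord)
  })
  profile <- t(vapply(membership, function(m) {
    colMeans(norm[m, , drop = FALSE])
  }, numeric(ncol(norm))))
  colnames(profile) <- features
  maj_label <- maj_frac <- NULL
  if (!is.null(labels)) {
    labels <- as.character(labels)
    maj <- vapply(membership, function(m) {
      tab <- table(labels[m])
      top <- tab[order(-tab, names(tab))][1]
      c(names(top), unname(top) / length(m))
    }, character(2))
    maj_label <- maj[1, ]
    maj_frac <- as.numeric(maj[2, ])
  }
  structure(list(index_units = unit_ids(ds)[index], membership = membership,
                 unit_ids = unit_ids(ds), profile = profile,
                 majority_label = maj_label, majority_fraction = maj_frac,
                 k_graph = k_graph, seed = seed),
            class = "neighbourhoods")
}

#' @export
print.neighbourhoods <- function(x, ...) {
  cat(sprintf("<neighbourhoods> %d neighbourhoods of size %d on %d features\n",
              length(x$membership), x$k_graph + 1L, ncol(x$profile)))
  invisible(x)
}

#' Match neighbourhoods across two datasets by mutual nearest pairs
#'
#' Profiles are standardized per feature (statistics pooled across both
#' datasets) and compared by Euclidean distance. Each neighbourhood is
#' matched to its `k_match` closest neighbourhoods in the other dataset,
#' in both directions; the retained pairs are those appearing in both
#' directions (mutual nearest pairs).
#'
#' @param nb_a,nb_b [build_neighbourhoods()] objects on the identical
#'   shared feature list
#' @param k_match neighbours considered per direction
#' @return object of class `neighbourhood_match`: `pairs` (data.frame
#'   nbhd_a, nbhd_b, distance, mutual — all candidate edges with the
#'   mutual flag), `mutual_pairs` (the mutual subset)
#' @export
match_neighbourhoods <- function(nb_a, nb_b, k_match = 30L) {
  if (!identical(colnames(nb_a$profile), colnames(nb_b$profile))) {
    stop("invalid profiles: feature lists differ", call. = FALSE)
  }
  pooled <- rbind(nb_a$profile, nb_b$profile)
  mu <- colMeans(pooled)
  sd <- apply(pooled, 2, stats::sd)
  sd[sd == 0] <- 1
  pa <- sweep(sweep(nb_a$profile, 2, mu), 2, sd, `/`)
  pb <- sweep(sweep(nb_b$profile, 2, mu), 2, sd, `/`)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * tcrossprod(pa, pb)
  d2[d2 < 0] <- 0
  ka <- min(k_match, ncol(d2))
  kb <- min(k_match, nrow(d2))
  near_ab <- apply(d2, 1, function(d) order(d)[seq_len(ka)])  # ka x nA
  near_ba <- apply(d2, 2, function(d) order(d)[seq_len(kb)])  # kb x nB
  edges_ab <- cbind(rep(seq_len(nrow(d2)), each = ka), as.vector(near_ab))
  in_ba <- matrix(FALSE, nrow(d2), ncol(d2))
  in_ba[cbind(as.vector(near_ba), rep(seq_len(ncol(d2)), each = kb))] <- TRUE
  mutual <- in_ba[edges_ab]
  # exact distances for the reported edges (the expansion above is only
  # used for neighbour ranking and carries float cancellation error)
  edge_dist <- sqrt(rowSums((pa[edges_ab[, 1], , drop = FALSE] -
                               pb[edges_ab[, 2], , drop = FALSE])^2))
  pairs <- data.frame(nbhd_a = edges_ab[, 1], nbhd_b = edges_ab[, 2],
                      distance = edge_dist, mutual = mutual)
  pairs <- pairs[order(pairs$nbhd_a, pairs$distance), ]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 mutual_pairs = pairs[pairs$mutual, , drop = FALSE],
                 k_match = k_match),
            class = "neighbourhood_match")
}

#' @export
print.neighbourhood_match <- function(x, ...) {
  cat(sprintf("<neighbourhood_match> %d candidate edges, %d mutual pairs\n",
              nrow(x$pairs), nrow(x$mutual_pairs)))
  invisible(x)
}

#' Harmonize annotations over mutual neighbourhood pairs
#'
#' For each mutual pair, the majority label of the member cells on each
#' side is computed (ties broken by lexicographic label order and
#' flagged), and pair counts are aggregated per unique (label_a,
#' label_b) combination — the harmonized cross-species annotations.
#'
#' @param match a [match_neighbourhoods()] result
#' @param nb_a,nb_b the neighbourhood objects that were matched
#' @param labels_a,labels_b per-unit labels, named by unit id or aligned
#'   with each dataset's units
#' @return list with `pair_labels` (per mutual pair: label_a, label_b,
#'   tie_a, tie_b) and `combinations` (label_a, label_b, n_pairs, sorted
#'   by decreasing n_pairs)
#' @export
harmonize_annotations <- function(match, nb_a, nb_b, labels_a, labels_b) {
  get_labels <- function(labels, nb) {
    labels <- if (!is.null(names(labels))) {
      unname(labels[nb$unit_ids])
    } else {
      as.character(labels)
    }
    if (length(labels) != length(nb$unit_ids) || anyNA(labels)) {
      stop("missing labels for some member units", call. = FALSE)
    }
    labels
  }
  la <- get_labels(labels_a, nb_a)
  lb <- get_labels(labels_b, nb_b)
  vote <- function(members, labels) {
    tab <- table(labels[members])
    tab <- tab[order(-tab, names(tab))]
    list(label = names(tab)[1],
         tie = length(tab) > 1 && tab[2] == tab[1])
  }
  mp <- match$mutual_pairs
  res <- lapply(seq_len(nrow(mp)), function(i) {
    va <- vote(nb_a$membership[[mp$nbhd_a[i]]], la)
    vb <- vote(nb_b$membership[[mp$nbhd_b[i]]], lb)
    data.frame(nbhd_a = mp$nbhd_a[i], nbhd_b = mp$nbhd_b[i],
               label_a = va$label, label_b = vb$label,
               tie_a = va$tie, tie_b = vb$tie, stringsAsFactors = FALSE)
  })
  pair_labels <- do.call(rbind, res)
  combos <- stats::aggregate(list(n_pairs = seq_len(nrow(pair_labels))),
                             by = pair_labels[c("label_a", "label_b")],
                             FUN = length)
  combos <- combos[order(-combos$n_pairs), ]
  rownames(combos) <- NULL
  list(pair_labels = pair_labels, combinations = combos)
}
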
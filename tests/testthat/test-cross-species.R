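test_that("an identical renamed copy recovers the top HVGs symmetrically", {
  pair <- generate_species_pair(150, n_populations = 3, n_genes = 120,
                                orth_frac = 1, species_shift = 0, seed = 2)
  a <- pair$a
  # species B: literally A with renamed genes and units
  b <- a
  colnames(b$counts) <- paste0("B_", gene_ids(a))
  rownames(b$counts) <- paste0("B_", unit_ids(a))
  rownames(b$unit_meta) <- rownames(b$counts)
  orth <- data.frame(gene_a = gene_ids(a), gene_b = gene_ids(b))
  feats <- shared_hvg_space(a, b, orth, n_hvg = 40)
  expect_identical(feats$gene_b, paste0("B_", feats$gene_a))
  expect_lte(nrow(feats), 40)
  # symmetric: swapping the datasets returns the mirrored pairs
  orth_rev <- data.frame(gene_a = orth$gene_b, gene_b = orth$gene_a)
  feats_rev <- shared_hvg_space(b, a, orth_rev, n_hvg = 40)
  expect_setequal(feats_rev$gene_b, feats$gene_a)
})

test_that("a gene expressed in only 9 cells of one species is excluded", {
  pair <- generate_species_pair(200, n_populations = 2, n_genes = 60,
                                orth_frac = 1, seed = 5)
  a <- pair$a
  b <- pair$b
  g_b <- pair$orthologues$gene_b[1]
  col <- rep(0L, n_units(b))
  col[1:9] <- 5L
  b$counts[, g_b] <- col
  feats <- shared_hvg_space(a, b, pair$orthologues, n_hvg = 60)
  expect_false(pair$orthologues$gene_a[1] %in% feats$gene_a)
  # brute-force recount: every returned feature passes both floors and is mapped
  expect_true(all(feats$gene_a %in% pair$orthologues$gene_a))
  na <- Matrix::colSums(a$counts[, feats$gene_a, drop = FALSE] > 0)
  nb <- Matrix::colSums(b$counts[, feats$gene_b, drop = FALSE] > 0)
  expect_true(all(na >= 10) && all(nb >= 10))
})

test_that("orthologue maps must be one-to-one", {
  pair <- generate_species_pair(100, n_populations = 2, n_genes = 40,
                                orth_frac = 1, seed = 1)
  dup <- rbind(pair$orthologues, pair$orthologues[1, ])
  expect_error(shared_hvg_space(pair$a, pair$b, dup), "one-to-one")
})

test_that("neighbourhoods have fixed size, are seeded, and saturate at full k", {
  pair <- generate_species_pair(120, n_populations = 3, n_genes = 80,
                                orth_frac = 1, seed = 3)
  feats <- shared_hvg_space(pair$a, pair$b, pair$orthologues, n_hvg = 50)
  nb <- build_neighbourhoods(pair$a, feats$gene_a, k_graph = 15,
                             sample_prop = 0.2, seed = 7)
  expect_true(all(lengths(nb$membership) == 16))
  expect_length(nb$index_units, ceiling(0.2 * 120))
  nb2 <- build_neighbourhoods(pair$a, feats$gene_a, k_graph = 15,
                              sample_prop = 0.2, seed = 7)
  expect_identical(nb$index_units, nb2$index_units)
  expect_identical(nb$membership, nb2$membership)

  full <- build_neighbourhoods(pair$a, feats$gene_a, k_graph = 119,
                               sample_prop = 0.05, seed = 1)
  expect_true(all(lengths(full$membership) == 120))
  expect_lt(max(apply(full$profile, 2, sd)), 1e-12)

  expect_error(build_neighbourhoods(pair$a, feats$gene_a, k_graph = 120),
               "below the number of units")
  expect_error(build_neighbourhoods(pair$a, feats$gene_a, k_graph = 10,
                                    sample_prop = 0), "invalid proportion")
})

test_that("matching an object against itself recovers the identity at distance 0", {
  pair <- generate_species_pair(200, n_populations = 3, n_genes = 100,
                                orth_frac = 1, seed = 11)
  feats <- shared_hvg_space(pair$a, pair$b, pair$orthologues, n_hvg = 60)
  nb <- build_neighbourhoods(pair$a, feats$gene_a, seed = 4)
  m <- match_neighbourhoods(nb, nb, k_match = 5)
  self <- m$mutual_pairs[m$mutual_pairs$nbhd_a == m$mutual_pairs$nbhd_b, ]
  expect_identical(nrow(self), length(nb$membership))
  expect_identical(max(self$distance), 0)
})

test_that("mutuality is symmetric under swapping the two datasets", {
  pair <- generate_species_pair(300, n_populations = 3, n_genes = 120,
                                orth_frac = 1, seed = 13)
  feats <- shared_hvg_space(pair$a, pair$b, pair$orthologues, n_hvg = 80)
  nba <- build_neighbourhoods(pair$a, feats$gene_a, seed = 1)
  nbb <- build_neighbourhoods(pair$b, feats$gene_b, seed = 2)
  nbb$profile <- nbb$profile[, feats$gene_b, drop = FALSE]
  colnames(nbb$profile) <- feats$gene_a
  m_ab <- match_neighbourhoods(nba, nbb, k_match = 10)
  m_ba <- match_neighbourhoods(nbb, nba, k_match = 10)
  ab <- with(m_ab$mutual_pairs, paste(nbhd_a, nbhd_b))
  ba <- with(m_ba$mutual_pairs, paste(nbhd_b, nbhd_a))
  expect_setequal(ab, ba)
  expect_error(match_neighbourhoods(nba, build_neighbourhoods(
    pair$b, feats$gene_b, seed = 2)), "feature lists differ")
})

test_that("mutual pairs join the same planted population", {
  pair <- generate_species_pair(1500, n_populations = 5, n_genes = 400,
                                seed = 17)
  feats <- shared_hvg_space(pair$a, pair$b, pair$orthologues)
  nba <- build_neighbourhoods(pair$a, feats$gene_a, seed = 1)
  nbb <- build_neighbourhoods(pair$b, feats$gene_b, seed = 2)
  nbb$profile <- nbb$profile[, feats$gene_b, drop = FALSE]
  colnames(nbb$profile) <- feats$gene_a
  m <- match_neighbourhoods(nba, nbb)
  mp <- m$mutual_pairs
  expect_gt(nrow(mp), 0)
  same <- nba$majority_label[mp$nbhd_a] == nbb$majority_label[mp$nbhd_b]
  expect_gte(mean(same), 0.95)
  # harmonized combination table is diagonal-dominant
  harm <- harmonize_annotations(m, nba, nbb, pair$truth$population_a,
                                pair$truth$population_b)
  combos <- harm$combinations
  diag_n <- sum(combos$n_pairs[combos$label_a == combos$label_b])
  expect_gte(diag_n / sum(combos$n_pairs), 0.95)
})

test_that("harmonize votes per side and flags 50/50 ties lexicographically", {
  mk_nb <- function(ids, membership, profile) {
    structure(list(index_units = ids, membership = membership,
                   unit_ids = ids, profile = profile,
                   k_graph = length(membership[[1]]) - 1L, seed = 1),
              class = "neighbourhoods")
  }
  prof <- matrix(0, 1, 2, dimnames = list(NULL, c("g1", "g2")))
  nb_a <- mk_nb(c("a1", "a2", "a3", "a4"), list(1:4), prof)
  nb_b <- mk_nb(c("b1", "b2", "b3", "b4"), list(1:4), prof)
  match <- list(mutual_pairs = data.frame(nbhd_a = 1, nbhd_b = 1,
                                          distance = 0, mutual = TRUE))
  pure <- harmonize_annotations(match, nb_a, nb_b,
                                rep("epithelium", 4), rep("mesenchyme", 4))
  expect_identical(pure$pair_labels$label_a, "epithelium")
  expect_identical(pure$pair_labels$label_b, "mesenchyme")
  expect_false(pure$pair_labels$tie_a)

  split <- harmonize_annotations(match, nb_a, nb_b,
                                 c("zeta", "zeta", "alpha", "alpha"),
                                 rep("m", 4))
  expect_identical(split$pair_labels$label_a, "alpha")
  expect_true(split$pair_labels$tie_a)
  expect_error(harmonize_annotations(match, nb_a, nb_b,
                                     c("x", NA, "x", "x"), rep("m", 4)),
               "missing labels")
})
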
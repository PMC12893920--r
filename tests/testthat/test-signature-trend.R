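test_that("the worked Jonckheere instance is enumerated exactly", {
  v <- c(1, 2, 3, 4)
  g <- c("a", "a", "b", "b")
  e <- exact_jonckheere_p(v, g, "increasing")
  expect_identical(e$jt_stat, 4)
  expect_equal(e$p_value, 1 / 6, tolerance = 1e-12)
  expect_identical(e$n_assignments, 6L)
  # reversed alternative: JT = 4 is the maximum, every assignment is <= it
  expect_equal(exact_jonckheere_p(v, g, "decreasing")$p_value, 1)
  # permutation p agrees within Monte-Carlo error
  j <- jonckheere_test(v, g, "increasing", n_perm = 2000, seed = 5)
  expect_identical(j$jt_stat, 4)
  expect_lte(abs(j$p_value - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / 2000))
})

test_that("singleton groups with strictly increasing values give p = 1/k!", {
  e <- exact_jonckheere_p(c(1, 2, 3), c("a", "b", "c"), "increasing")
  expect_equal(e$p_value, 1 / 6, tolerance = 1e-12)
  e4 <- exact_jonckheere_p(c(1, 2, 3, 4), c("a", "b", "c", "d"), "increasing")
  expect_equal(e4$p_value, 1 / 24, tolerance = 1e-12)
})

test_that("complete ties give JT = half the cross-group pairs and p = 1", {
  j <- jonckheere_test(rep(1, 6), rep(c("a", "b", "c"), each = 2),
                       "increasing", seed = 2)
  expect_identical(j$jt_stat, 6)  # 12 cross-group pairs, all tied
  expect_identical(j$p_value, 1)
})

test_that("defaults follow the fetal-signature convention", {
  f <- formals(jonckheere_test)
  expect_identical(eval(f$n_perm), 2000L)
  expect_identical(eval(f$alternative)[1], "decreasing")
  expect_gte(jonckheere_test(rnorm(9), rep(1:3, 3), seed = 1)$p_value,
             1 / 2001)  # add-one estimator floor
})

test_that("the JT statistic is invariant under strictly monotone transforms", {
  set.seed(8)
  v <- rnorm(24)
  g <- rep(c("a", "b", "c"), each = 8)
  j1 <- jonckheere_test(v, g, "increasing", n_perm = 50, seed = 3)
  j2 <- jonckheere_test(exp(v), g, "increasing", n_perm = 50, seed = 3)
  expect_identical(j1$jt_stat, j2$jt_stat)
  expect_identical(j1$p_value, j2$p_value)
})

test_that("permutation p converges to the exact enumeration p", {
  set.seed(13)
  agree <- 0L
  for (i in 1:20) {
    sizes <- sample(2:4, sample(2:3, 1), replace = TRUE)
    v <- round(rnorm(sum(sizes)), 1)  # rounding induces occasional ties
    g <- rep(seq_along(sizes), sizes)
    alt <- sample(c("increasing", "decreasing"), 1)
    pe <- exact_jonckheere_p(v, g, alt)$p_value
    pp <- jonckheere_test(v, g, alt, n_perm = 2000, seed = i)$p_value
    tol <- 3 * sqrt(pe * (1 - pe) / 2000) + 1e-9
    if (abs(pp - pe) <= tol) agree <- agree + 1L
  }
  expect_gte(agree, 19L)
})

test_that("null p-values are super-uniform at nominal levels", {
  set.seed(21)
  p <- replicate(200, {
    jonckheere_test(rnorm(15), rep(1:3, each = 5), "increasing",
                    n_perm = 200, seed = sample.int(1e6, 1))$p_value
  })
  for (alpha in c(0.05, 0.2)) {
    expect_lte(mean(p <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 200))
  }
})

test_that("enumeration refuses oversized instances", {
  expect_error(exact_jonckheere_p(rnorm(40), rep(1:4, each = 10)),
               "too large")
})

test_that("signature scores are zero under exchangeable expression", {
  counts <- matrix(4L, 10, 30,
                   dimnames = list(sprintf("u%d", 1:10),
                                   sprintf("g%d", 1:30)))
  ds <- tiny_dataset(counts)
  sc <- score_signature(ds, c("g1", "g5", "g9"), n_ctrl_bins = 3,
                        ctrl_size = 5, seed = 1)
  expect_equal(sc$score, rep(0, 10), tolerance = 1e-12)
})

test_that("identical units get identical scores and gene order does not matter", {
  b <- generate_tube_organ(80, 60, frac_gradient = 0.4, seed = 15)
  ds <- b$spatial
  ds$counts[2, ] <- ds$counts[1, ]
  sig <- b$truth$gradient_table$gene_id[1:8]
  sc <- score_signature(ds, sig, seed = 4)
  expect_equal(sc$score[1], sc$score[2], tolerance = 1e-12)
  perm <- sample(n_genes(ds))
  sc2 <- score_signature(subset_genes(ds, perm), sig, seed = 4)
  expect_equal(sc2$score, sc$score, tolerance = 1e-12)
  expect_warning(score_signature(ds, c(sig, "absent_gene"), seed = 1),
                 "absent")
  expect_error(score_signature(ds, "absent_gene"), "empty signature")
})

test_that("a planted rostral signature scores higher in the rostral tertile", {
  wins <- vapply(1:10, function(s) {
    b <- generate_tube_organ(300, 150, frac_gradient = 0.3, seed = 100 + s)
    spec <- b$truth$gradient_table
    sig <- utils::head(spec$gene_id[spec$pattern == "rostral_decreasing"], 15)
    sc <- score_signature(b$spatial, sig, seed = s)
    ax <- b$truth$true_axis[sc$unit_id]
    mean(sc$score[ax < 1 / 3]) > mean(sc$score[ax > 2 / 3])
  }, TRUE)
  expect_identical(sum(wins), 10L)
})

test_that("target-set enrichment passes planted drugs and rejects uniform ones", {
  set.seed(19)
  n <- 300
  cell_type <- rep(c("focus_epi", "other"), c(100, 200))
  counts <- matrix(rpois(n * 50, 5), n, 50,
                   dimnames = list(sprintf("c%03d", 1:n),
                                   sprintf("g%d", 1:50)))
  # drug A targets g1..g3, strongly and exclusively expressed in focus cells
  counts[, 1:3] <- 0L
  counts[1:100, 1:3] <- matrix(rpois(300, 60), 100, 3)
  ds <- expression_dataset(Matrix::Matrix(counts, sparse = TRUE),
                           unit_meta = data.frame(cell_type = cell_type))
  tab <- target_set_enrichment(
    ds, list(drugA = c("g1", "g2", "g3"), drugB = c("g10", "g11")),
    focus_label = "focus_epi")
  expect_true(tab$pass[tab$drug == "drugA"])
  expect_false(tab$pass[tab$drug == "drugB"])
  expect_lt(abs(tab$log2_fc[tab$drug == "drugB"]), 0.5)
  # ordered by the rank score
  expect_true(all(diff(tab$rank_score) <= 0))
  expect_error(target_set_enrichment(ds, list(d = "g1"), "missing_label"),
               "label not found")
  # filter defaults match the stringent contract
  f <- formals(target_set_enrichment)
  expect_identical(f$p_adj_max, 0.01)
  expect_identical(f$min_log2fc, 2)
  expect_identical(f$min_expr_frac, 0.10)
})

test_that("gene sets read from GMT and TSV files", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), gmt)
  sets <- read_gene_sets(gmt)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("set_id\tgene", "s1\tg1", "s1\tg2", "s2\tg9"), tsv)
  sets2 <- read_gene_sets(tsv)
  expect_identical(unname(sets2$s1), c("g1", "g2"))
})
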
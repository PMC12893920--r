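test_that("the df = 1 likelihood ratio matches an independent NB-GLM fit", {
  skip_if_not_installed("MASS")
  set.seed(2)
  n <- 400
  ax <- runif(n)
  sf <- rlnorm(n, 0, 0.3)
  y <- rnbinom(n, mu = 10 * sf * exp(ax), size = 2)
  m <- fit_gene_axis_model(y, ax, sf, spline_df = 1)
  phi <- m$dispersion
  B <- splines::ns(ax, df = 1, Boundary.knots = c(0, 1))
  gf <- stats::glm(y ~ B + offset(log(sf)),
                   family = MASS::negative.binomial(theta = 1 / phi))
  gn <- stats::glm(y ~ 1 + offset(log(sf)),
                   family = MASS::negative.binomial(theta = 1 / phi))
  ll <- function(fit) sum(dnbinom(y, size = 1 / phi, mu = fitted(fit),
                                  log = TRUE))
  expect_equal(m$lrt_stat, 2 * (ll(gf) - ll(gn)), tolerance = 1e-6)
})

test_that("an all-zero gene returns the stated flat contract", {
  set.seed(1)
  m <- fit_gene_axis_model(rep(0L, 200), runif(200))
  expect_identical(m$lrt_stat, 0)
  expect_identical(m$p_value, 1)
  expect_identical(m$log2_amplitude, 0)
  expect_identical(classify_pattern(m), "flat")
})

test_that("a constant-mean Poisson gene fits a nearly flat profile", {
  set.seed(6)
  spread <- replicate(50, {
    ax <- runif(500)
    m <- fit_gene_axis_model(rpois(500, 10), ax)
    diff(range(m$fitted_log_mean))
  })
  expect_lt(mean(spread), 0.2)
})

test_that("a planted log-linear gradient's amplitude is recovered without bias", {
  set.seed(3)
  amps <- replicate(50, {
    ax <- runif(500)
    sf <- rlnorm(500, 0, 0.3)
    y <- rnbinom(500, mu = 10 * sf * 2^ax, size = 2)
    fit_gene_axis_model(y, ax, sf)$log2_amplitude
  })
  expect_gte(mean(amps), 0.8)
  expect_lte(mean(amps), 1.2)
})

test_that("a strong gradient is detected at p below 1e-6", {
  set.seed(9)
  hits <- replicate(20, {
    ax <- runif(500)
    sf <- rlnorm(500, 0, 0.3)
    y <- rnbinom(500, mu = 20 * sf * 2^(2 * ax), size = 2)
    fit_gene_axis_model(y, ax, sf)$p_value < 1e-6
  })
  expect_gte(sum(hits), 19)
})

test_that("association_test validates unit identity and degenerates to p = 1", {
  set.seed(4)
  ax <- runif(300)
  y <- rpois(300, 5)
  m <- fit_gene_axis_model(y, ax)
  expect_identical(association_test(m, m)$lrt_stat, 0)
  expect_identical(association_test(m, m)$p_value, 1)
  other <- fit_gene_axis_model(rpois(250, 5), runif(250))
  expect_error(association_test(m, other), "invalid comparison")
})

test_that("the LRT is invariant to rescaling all size factors", {
  set.seed(5)
  ax <- runif(300)
  sf <- rlnorm(300, 0, 0.3)
  y <- rnbinom(300, mu = 8 * sf * 2^ax, size = 2)
  m1 <- fit_gene_axis_model(y, ax, sf)
  m2 <- fit_gene_axis_model(y, ax, sf * 5)
  expect_equal(m1$lrt_stat, m2$lrt_stat, tolerance = 1e-6)
})

test_that("planted gradient genes are recovered and classified among flat ones", {
  b <- generate_tube_organ(500, 200, frac_gradient = 0.15, seed = 23)
  truth <- b$truth$gradient_table
  tab <- detect_spatially_variable_genes(
    b$spatial, b$truth$true_axis[unit_ids(b$spatial)],
    size_factors = b$truth$size_factors)
  planted <- truth$gene_id[truth$pattern != "flat"]
  expect_gte(mean(planted %in% tab$gene_id[tab$pass]), 0.9)
  # pattern classes agree with the planted patterns
  map <- c(rostral_decreasing = "rostral", caudal_increasing = "caudal",
           middle_peak = "middle")
  got <- tab$pattern[match(planted, tab$gene_id)]
  expect_gte(mean(got == map[truth$pattern[match(planted, truth$gene_id)]]),
             0.9)
  # q-values are BH over tested genes
  ok <- tab$converged
  expect_equal(tab$q_value[ok],
               p.adjust(tab$p_value[ok], "BH"), tolerance = 1e-12)
  # table is sorted by decreasing statistic
  expect_true(all(diff(tab$lrt_stat) <= 0))
})

test_that("an all-flat dataset yields at most the nominal false positives", {
  b <- generate_tube_organ(400, 300, frac_gradient = 0, seed = 29)
  tab <- detect_spatially_variable_genes(
    b$spatial, b$truth$true_axis[unit_ids(b$spatial)],
    size_factors = b$truth$size_factors)
  # binomial(300, 0.001) leaves essentially no room above 3
  expect_lte(sum(tab$pass), 3)
})

test_that("the stringent criteria default to p < 0.001 and log2 amplitude > 0.5", {
  f <- formals(detect_spatially_variable_genes)
  expect_identical(f$p_max, 0.001)
  expect_identical(f$min_log2fc, 0.5)
})

test_that("detection output is invariant to unit permutation", {
  b <- generate_tube_organ(200, 40, frac_gradient = 0.3, seed = 33)
  ax <- b$truth$true_axis[unit_ids(b$spatial)]
  sf <- b$truth$size_factors[unit_ids(b$spatial)]
  t1 <- detect_spatially_variable_genes(b$spatial, ax, size_factors = sf)
  set.seed(1)
  perm <- sample(n_units(b$spatial))
  t2 <- detect_spatially_variable_genes(subset_units(b$spatial, perm),
                                        ax[perm], size_factors = sf[perm])
  expect_equal(t1$lrt_stat[match(t2$gene_id, t1$gene_id)], t2$lrt_stat,
               tolerance = 1e-8)
})

test_that("binned min-max profiles scale rows to [0,1] and track monotone genes", {
  b <- generate_tube_organ(1500, 60, frac_gradient = 0.5,
                           amplitude_range = c(2, 2), seed = 41)
  truth <- b$truth$gradient_table
  ax <- b$truth$true_axis[unit_ids(b$spatial)]
  dec <- truth$gene_id[truth$pattern == "rostral_decreasing"][1:3]
  prof <- binned_minmax_profiles(b$spatial, ax, dec)
  expect_true(all(apply(prof, 1, min) == 0))
  expect_true(all(apply(prof, 1, max) == 1))
  for (g in dec) {
    expect_lte(cor(prof[g, ], seq_len(ncol(prof)), method = "spearman"),
               -0.9)
  }
  # constant gene -> all-zero row by convention
  const <- tiny_dataset(matrix(5L, 1500, 2,
                               dimnames = list(paste0("u", 1:1500),
                                               c("c1", "c2"))))
  p0 <- binned_minmax_profiles(const, seq(0, 1, length.out = 1500), "c1",
                               n_bins = 5)
  expect_true(all(p0 == 0))
  # empty bins are NA-backed unless fitted values are requested
  skew <- binned_minmax_profiles(b$spatial, ax / 2, dec, n_bins = 20)
  expect_true(all(is.na(skew[, 12:20]) | skew[, 12:20] == 0))
  m <- fit_gene_axis_model(b$spatial$counts[, dec[1]], ax)
  pf <- binned_minmax_profiles(b$spatial, ax / 2, dec[1], n_bins = 20,
                               use_fitted = TRUE,
                               models = setNames(list(m), dec[1]))
  expect_false(anyNA(pf))
})

test_that("classify_pattern places the fitted peak into thirds", {
  grid <- seq(0, 1, length.out = 100)
  mk <- function(profile) {
    structure(list(grid = grid, fitted_log_mean = profile,
                   log2_amplitude = diff(range(profile)) / log(2)),
              class = "gene_axis_model")
  }
  expect_identical(classify_pattern(mk(2 - 2 * grid)), "rostral")
  expect_identical(classify_pattern(mk(2 * grid)), "caudal")
  expect_identical(classify_pattern(mk(exp(-(grid - 0.5)^2 / 0.02))), "middle")
  expect_identical(classify_pattern(mk(rep(1, 100))), "flat")
})
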
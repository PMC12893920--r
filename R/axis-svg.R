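# ---- negative-binomial IRLS with log link and fixed dispersion ----
#
# The axis-variable-gene model: counts_g ~ NB(mu, phi) with
# log mu = X beta + log(size_factor), X an intercept plus a cubic
# B-spline basis in the axis coordinate. Written as a small dedicated
# IRLS rather than via a generic GLM routine so the dispersion handling
# (moment estimate on the full fit, then held fixed for full and null)
# is explicit; a generic GLM serves as an independent oracle in tests.

nb_loglik <- function(y, mu, phi) {
  if (phi <= 1e-8) {
    sum(stats::dpois(y, lambda = mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
}

# IRLS for Poisson (phi = 0) or fixed-dispersion NB, log link + offset.
nb_irls <- function(y, X, offset, phi = 0, maxit = 100L, tol = 1e-10) {
  beta <- c(log(mean(y) + 1e-8) - mean(offset), rep(0, ncol(X) - 1L))
  eta <- drop(X %*% beta) + offset
  mu <- exp(eta)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu / (1 + phi * mu)           # NB working weights, log link
    z <- eta - offset + (y - mu) / mu  # working response
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) {             # rank deficiency: pin aliased terms
      beta_new[is.na(beta_new)] <- 0
    }
    eta <- drop(X %*% beta_new) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    ll <- nb_loglik(y, mu, phi)
    if (abs(ll - dev_old) < tol * (abs(ll) + 0.1)) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    dev_old <- ll
    beta <- beta_new
  }
  list(beta = beta, mu = mu, eta = eta, loglik = nb_loglik(y, mu, phi),
       converged = converged, iterations = it)
}

# Method-of-moments dispersion: phi solving
# sum (y-mu)^2 / (mu + phi mu^2) = n - p  (Pearson chi-square matching),
# given the fitted means of an initial fit; floored at 1e-8.
moment_dispersion <- function(y, mu, n_params, floor = 1e-8) {
  df <- length(y) - n_params
  if (df <= 0) return(floor)
  pearson <- function(phi) sum((y - mu)^2 / (mu + phi * mu^2)) - df
  if (pearson(0) <= 0) return(floor)   # under-dispersed: Poisson limit
  upper <- 10
  while (pearson(upper) > 0 && upper < 1e6) upper <- upper * 10
  if (pearson(upper) > 0) return(upper)
  stats::uniroot(pearson, c(0, upper), tol = 1e-10)$root
}

# Natural cubic spline basis: spline_df basis functions, internal knots
# at axis quantiles, linear beyond the boundary knots. The natural
# boundary constraint keeps the fitted curve's edge variance low, which
# matters because the amplitude statistic is the max-min of the fitted
# profile; spline_df = 1 reduces to a linear basis.
spline_basis <- function(axis, spline_df, boundary = c(0, 1)) {
  if (spline_df < 1) stop("spline_df must be >= 1", call. = FALSE)
  splines::ns(axis, df = spline_df, Boundary.knots = boundary)
}

#' Fit a negative-binomial spline model of expression along the axis
#'
#' Regresses a gene's counts on a natural cubic spline basis
#' (`spline_df` basis functions, internal knots at axis quantiles,
#' linear beyond the boundary) in the axis coordinate,
#' with `log(size_factor)` as offset and a log link. Dispersion is
#' estimated once by method of moments (Pearson chi-square matching) on
#' the full fit, then held fixed for both the full and the intercept-only
#' null fit, whose likelihood ratio provides the association test. The
#' fitted log-mean profile is evaluated on a 100-point grid at size
#' factor 1.
#'
#' @param counts_g integer count vector, one per unit
#' @param axis per-unit axis values in \[0,1\] (NA units dropped)
#' @param size_factors per-unit positive size factors (default: library
#'   size over mean library size of the supplied vector)
#' @param spline_df number of spline basis functions (>= 1; 1 gives a
#'   linear basis)
#' @param grid_size number of grid points for the fitted profile
#' @return object of class `gene_axis_model`: coefficients, dispersion,
#'   `fitted_log_mean` (on `grid`), `lrt_stat`, `p_value`,
#'   `log2_amplitude`, `loglik_full`, `loglik_null`, `converged`
#' @export
fit_gene_axis_model <- function(counts_g, axis, size_factors = NULL,
                                spline_df = 5L, grid_size = 100L) {
  keep <- !is.na(axis)
  y <- as.numeric(counts_g)[keep]
  ax <- axis[keep]
  n <- length(y)
  if (n < 10 * spline_df) {
    stop(sprintf("need at least %d units with non-missing axis (got %d)",
                 10 * spline_df, n), call. = FALSE)
  }
  if (is.null(size_factors)) size_factors <- rep(1, length(axis))
  sf <- size_factors[keep]
  if (any(sf <= 0)) stop("size_factors must be positive", call. = FALSE)
  offset <- log(sf)
  grid <- seq(0, 1, length.out = grid_size)

  if (all(y == 0)) {
    return(structure(list(
      spline_df = spline_df, coefficients = rep(0, spline_df + 1L),
      dispersion = 1e-8, grid = grid,
      fitted_log_mean = rep(-Inf, grid_size),
      lrt_stat = 0, p_value = 1, log2_amplitude = 0,
      loglik_full = 0, loglik_null = 0, converged = TRUE,
      n = n, offset_sum = sum(offset), y_sum = 0, all_zero = TRUE
    ), class = "gene_axis_model"))
  }

  B <- spline_basis(ax, spline_df)
  X <- cbind(1, B)
  pois <- nb_irls(y, X, offset, phi = 0)
  phi <- moment_dispersion(y, pois$mu, ncol(X))
  full <- nb_irls(y, X, offset, phi = phi)
  null <- nb_irls(y, matrix(1, n, 1), offset, phi = phi)

  Bg <- stats::predict(B, grid)
  fitted <- drop(cbind(1, Bg) %*% full$beta)
  lrt <- max(0, 2 * (full$loglik - null$loglik))
  structure(list(
    spline_df = spline_df, coefficients = full$beta, dispersion = phi,
    grid = grid, fitted_log_mean = fitted,
    lrt_stat = lrt,
    p_value = if (lrt == 0) 1 else
      stats::pchisq(lrt, df = spline_df, lower.tail = FALSE),
    log2_amplitude = (max(fitted) - min(fitted)) / log(2),
    loglik_full = full$loglik, loglik_null = null$loglik,
    converged = full$converged && null$converged,
    n = n, offset_sum = sum(offset), y_sum = sum(y), all_zero = FALSE
  ), class = "gene_axis_model")
}

#' @export
print.gene_axis_model <- function(x, ...) {
  cat(sprintf(
    "<gene_axis_model> df %d  LRT %.3f  p %.3g  log2 amplitude %.3f  dispersion %.3g\n",
    x$spline_df, x$lrt_stat, x$p_value, x$log2_amplitude, x$dispersion))
  invisible(x)
}

#' Likelihood-ratio association test between a spline fit and its null
#'
#' Compares a fitted [fit_gene_axis_model()] against an intercept-only
#' null fitted on identical units and offsets; the statistic
#' `2 (loglik_full - loglik_null)` (clipped at 0) is referred to a
#' chi-square with the spline degrees of freedom.
#'
#' @param model a `gene_axis_model`
#' @param null_model an intercept-only `gene_axis_model` on the same
#'   units (default: the null fit stored inside `model`)
#' @return list with `lrt_stat` and `p_value`
#' @export
association_test <- function(model, null_model = NULL) {
  if (is.null(null_model)) {
    return(list(lrt_stat = model$lrt_stat, p_value = model$p_value))
  }
  same <- isTRUE(all.equal(model$n, null_model$n)) &&
    isTRUE(all.equal(model$offset_sum, null_model$offset_sum)) &&
    isTRUE(all.equal(model$y_sum, null_model$y_sum))
  if (!same) {
    stop("invalid comparison: fits are not on identical units and offsets",
         call. = FALSE)
  }
  lrt <- max(0, 2 * (model$loglik_full - null_model$loglik_full))
  df <- model$spline_df
  list(lrt_stat = lrt,
       p_value = if (lrt == 0) 1 else
         stats::pchisq(lrt, df = df, lower.tail = FALSE))
}

#' Detect axis-variable (spatially variable) genes
#'
#' Fits the NB spline model for every gene detected in at least
#' `min_expr_frac` of units and flags genes passing the stringent
#' criteria p < `p_max` and fitted log2 amplitude > `min_log2fc`.
#' Benjamini-Hochberg q-values over all converged tested genes are
#' reported for transparency, though the pass flag uses the raw p-value.
#'
#' @param ds an [expression_dataset()]
#' @param axis an [axis_assignment()] (or numeric vector) aligned on the
#'   dataset's units
#' @param p_max raw p-value threshold
#' @param min_log2fc log2 fitted-amplitude threshold
#' @param spline_df spline basis size
#' @param min_expr_frac minimum detection fraction for a gene to be tested
#' @param cell_mask optional logical/index vector restricting the units
#'   used (e.g. one compartment)
#' @param size_factors optional per-unit size factors (default: library
#'   size over its mean)
#' @return data.frame of class `svg_table`, sorted by decreasing LRT:
#'   gene_id, lrt_stat, p_value, q_value, log2_amplitude, pattern,
#'   converged, pass
#' @export
detect_spatially_variable_genes <- function(ds, axis, p_max = 0.001,
                                            min_log2fc = 0.5, spline_df = 5L,
                                            min_expr_frac = 0.01,
                                            cell_mask = NULL,
                                            size_factors = NULL) {
  value <- if (inherits(axis, "axis_assignment")) {
    axis$value[match(unit_ids(ds), axis$unit_ids)]
  } else {
    as.numeric(axis)
  }
  if (!is.null(cell_mask)) {
    ds <- subset_units(ds, cell_mask)
    value <- value[if (is.logical(cell_mask)) which(cell_mask) else cell_mask]
  }
  keep <- !is.na(value)
  ds <- subset_units(ds, which(keep))
  value <- value[keep]
  if (is.null(size_factors)) {
    lib <- Matrix::rowSums(ds$counts)
    size_factors <- lib / mean(lib)
  }
  detected <- Matrix::colMeans(ds$counts > 0)
  test_genes <- gene_ids(ds)[detected >= min_expr_frac]
  if (!length(test_genes)) {
    warning("no genes pass the expression floor", call. = FALSE)
    return(structure(data.frame(gene_id = character(), lrt_stat = numeric(),
                                p_value = numeric(), q_value = numeric(),
                                log2_amplitude = numeric(),
                                pattern = character(), converged = logical(),
                                pass = logical()),
                     class = c("svg_table", "data.frame")))
  }
  counts <- ds$counts[, test_genes, drop = FALSE]
  rows <- lapply(seq_along(test_genes), function(j) {
    m <- fit_gene_axis_model(counts[, j], value, size_factors, spline_df)
    data.frame(gene_id = test_genes[j], lrt_stat = m$lrt_stat,
               p_value = m$p_value, log2_amplitude = m$log2_amplitude,
               pattern = classify_pattern(m, min_log2fc),
               converged = m$converged, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q_value <- NA_real_
  tab$q_value[tab$converged] <- stats::p.adjust(tab$p_value[tab$converged],
                                                method = "BH")
  tab$pass <- tab$converged & tab$p_value < p_max & tab$log2_amplitude > min_log2fc
  tab <- tab[order(-tab$lrt_stat), c("gene_id", "lrt_stat", "p_value",
                                     "q_value", "log2_amplitude", "pattern",
                                     "converged", "pass")]
  rownames(tab) <- NULL
  structure(tab, class = c("svg_table", "data.frame"))
}

#' Classify the axis pattern of a fitted gene model
#'
#' `flat` when the fitted log2 amplitude is at most `min_log2fc`;
#' otherwise `rostral`, `middle` or `caudal` according to where the
#' fitted profile attains its maximum (first, middle or last third of
#' the axis).
#'
#' @param model a `gene_axis_model`
#' @param min_log2fc amplitude below which a gene is called flat
#' @return one of "rostral", "middle", "caudal", "flat"
#' @export
classify_pattern <- function(model, min_log2fc = 0.5) {
  if (model$log2_amplitude <= min_log2fc) return("flat")
  peak <- model$grid[which.max(model$fitted_log_mean)]
  if (peak < 1 / 3) "rostral" else if (peak <= 2 / 3) "middle" else "caudal"
}

#' Binned min-max expression profiles along the axis
#'
#' Mean normalized expression per axis bin for the given genes, each row
#' min-max scaled to \[0,1\] (constant rows are all zeros by convention).
#' With `use_fitted`, fitted model values at bin centres are used
#' instead, which also fills otherwise-empty bins.
#'
#' @param ds an [expression_dataset()]
#' @param axis an [axis_assignment()] or numeric vector on the units
#' @param gene_list genes to profile (subset of the dataset's genes)
#' @param n_bins number of axis bins
#' @param use_fitted use fitted spline values at bin centres
#' @param models named list of `gene_axis_model` (required when
#'   `use_fitted`; names = gene ids)
#' @return numeric matrix, genes x bins, in \[0,1\]
#' @export
binned_minmax_profiles <- function(ds, axis, gene_list, n_bins = 20L,
                                   use_fitted = FALSE, models = NULL) {
  missing <- setdiff(gene_list, gene_ids(ds))
  if (length(missing)) {
    stop("genes absent from dataset: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  value <- if (inherits(axis, "axis_assignment")) {
    axis$value[match(unit_ids(ds), axis$unit_ids)]
  } else {
    as.numeric(axis)
  }
  bins <- bin_axis(value, n_bins)
  centres <- (seq_len(n_bins) - 0.5) / n_bins
  out <- matrix(NA_real_, length(gene_list), n_bins,
                dimnames = list(gene_list, sprintf("bin_%02d", seq_len(n_bins) - 1L)))
  if (use_fitted) {
    if (is.null(models)) stop("use_fitted requires fitted models", call. = FALSE)
    for (g in gene_list) {
      m <- models[[g]]
      if (is.null(m)) stop("no fitted model for gene ", g, call. = FALSE)
      out[g, ] <- stats::approx(m$grid, m$fitted_log_mean, xout = centres,
                                rule = 2)$y
    }
  } else {
    norm <- normalize_log_cpm100(ds)[, gene_list, drop = FALSE]
    ok <- !is.na(bins)
    for (b in seq_len(n_bins) - 1L) {
      idx <- which(ok & bins == b)
      if (length(idx)) {
        out[, b + 1L] <- Matrix::colMeans(norm[idx, , drop = FALSE])
      }
    }
  }
  t(apply(out, 1, function(row) {
    rng <- range(row, na.rm = TRUE)
    if (!is.finite(rng[1]) || rng[1] == rng[2]) {
      rep(0, length(row))
    } else {
      (row - rng[1]) / (rng[2] - rng[1])
    }
  }))
}
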
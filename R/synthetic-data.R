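#' Axis-dependent expression patterns
#'
#' The generator plants four pattern classes along the normalized axis
#' coordinate `s` in \[0,1\]: `flat` (no axis dependence),
#' `rostral_decreasing` (profile 1 - s), `caudal_increasing` (profile s)
#' and `middle_peak` (Gaussian bump centred at s = 0.5, sd 0.15). The
#' log2 mean of gene g at axis position s is
#' `log2(base_mean) + amplitude * f_pattern(s)`.
#'
#' @param pattern character vector of pattern names
#' @param s numeric vector of axis positions in \[0,1\]
#' @return matrix of f values, length(s) x length(pattern)
#' @export
pattern_profile <- function(pattern, s) {
  f <- vapply(pattern, function(p) {
    switch(p,
      flat = rep(0, length(s)),
      rostral_decreasing = 1 - s,
      caudal_increasing = s,
      middle_peak = exp(-(s - 0.5)^2 / (2 * 0.15^2)),
      stop("unknown pattern: ", p, call. = FALSE)
    )
  }, numeric(length(s)))
  matrix(f, nrow = length(s), dimnames = list(NULL, pattern))
}

#' Build a gradient specification table
#'
#' @param gene_id gene identifiers
#' @param pattern per-gene pattern (see [pattern_profile()])
#' @param base_mean per-gene expected counts at unit scale (> 0)
#' @param amplitude per-gene max-min of the log2 mean along the axis
#'   (>= 0; must be 0 exactly when pattern is `flat`)
#' @param dispersion per-gene negative-binomial dispersion
#'   (variance = mu + mu^2 * dispersion; > 0)
#' @return data.frame of class `gradient_spec`
#' @export
gradient_spec <- function(gene_id, pattern, base_mean, amplitude, dispersion) {
  tab <- data.frame(gene_id = as.character(gene_id),
                    pattern = as.character(pattern),
                    base_mean = base_mean, amplitude = amplitude,
                    dispersion = dispersion, stringsAsFactors = FALSE)
  if (any(tab$base_mean <= 0)) stop("base_mean must be positive", call. = FALSE)
  if (any(tab$dispersion <= 0)) stop("dispersion must be positive", call. = FALSE)
  if (any(tab$amplitude < 0)) stop("amplitude must be non-negative", call. = FALSE)
  flat <- tab$pattern == "flat"
  if (any(xor(flat, tab$amplitude == 0))) {
    stop("amplitude must be 0 exactly for flat genes", call. = FALSE)
  }
  class(tab) <- c("gradient_spec", "data.frame")
  tab
}

# Quadratic Bezier centerline with arc-length lookup tables.
tube_centerline <- function(p0 = c(0, 0), p1 = c(600, 900), p2 = c(1400, 0),
                            n_grid = 2000L) {
  t <- seq(0, 1, length.out = n_grid)
  bx <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  by <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  seg <- sqrt(diff(bx)^2 + diff(by)^2)
  arc <- c(0, cumsum(seg))
  list(t = t, x = bx, y = by, s = arc / arc[length(arc)], length = arc[length(arc)])
}

nb_mean_at <- function(spec, s) {
  f <- pattern_profile(spec$pattern, s)
  sweep(2^(f * rep(spec$amplitude, each = length(s))), 2, spec$base_mean, `*`)
}

draw_nb_counts <- function(mu, dispersion, size_factors) {
  mu <- mu * size_factors
  n <- length(mu)
  counts <- matrix(
    stats::rnbinom(n, mu = as.vector(mu),
                   size = 1 / rep(dispersion, each = nrow(mu))),
    nrow = nrow(mu)
  )
  counts
}

#' Generate a synthetic curved tubular organ with axis-dependent expression
#'
#' Units are placed along a quadratic Bezier centerline (so Euclidean
#' distance between units differs from arc-length) with Gaussian lateral
#' jitter (sd = 5% of tube length). The 2% of units nearest each
#' endpoint are annotated `rostral_tip` / `caudal_tip`, mimicking
#' annotated landmark regions rather than single points. A fraction
#' `frac_gradient` of genes receive a non-flat pattern (cycling through
#' rostral_decreasing, caudal_increasing, middle_peak); counts are drawn
#' negative-binomial with per-unit log-normal(0, 0.3) size factors.
#'
#' @param n_units number of spatial units (>= 50)
#' @param n_genes number of genes
#' @param frac_gradient fraction of genes carrying a non-flat pattern
#' @param base_mean_range genes draw base_mean log-uniformly in this range
#' @param amplitude_range gradient genes draw log2 amplitude uniformly here
#' @param dispersion NB dispersion shared by all genes
#' @param lib_sdlog sdlog of the per-unit log-normal size factor
#' @param seed integer seed; the generator is a pure function of its
#'   arguments
#' @return list with `spatial` (a [spatial_dataset()]) and `truth`
#'   (list: `true_axis` named per unit, `gradient_table`,
#'   `population_labels`, `size_factors`, `section_transforms`)
#' @export
generate_tube_organ <- function(n_units, n_genes, frac_gradient = 0.1,
                                base_mean_range = c(1, 50),
                                amplitude_range = c(1, 2),
                                dispersion = 0.5, lib_sdlog = 0.3,
                                seed = 1L) {
  if (n_units < 50) stop("n_units must be at least 50", call. = FALSE)
  if (n_genes < 1) stop("n_genes must be positive", call. = FALSE)
  if (frac_gradient < 0 || frac_gradient > 1) {
    stop("frac_gradient must lie in [0, 1]", call. = FALSE)
  }
  withr_seed(seed, {
    cl <- tube_centerline()
    s <- sort(stats::runif(n_units))
    t_at <- stats::approx(cl$s, cl$t, xout = s, rule = 2)$y
    px <- stats::approx(cl$t, cl$x, xout = t_at, rule = 2)$y
    py <- stats::approx(cl$t, cl$y, xout = t_at, rule = 2)$y
    # lateral jitter perpendicular to the local tangent
    dx <- stats::approx(cl$t, c(diff(cl$x), 0), xout = t_at, rule = 2)$y
    dy <- stats::approx(cl$t, c(diff(cl$y), 0), xout = t_at, rule = 2)$y
    nrm <- sqrt(dx^2 + dy^2)
    nrm[nrm == 0] <- 1
    off <- stats::rnorm(n_units, 0, 0.05 * cl$length)
    coords <- cbind(px - dy / nrm * off, py + dx / nrm * off)

    n_lm <- max(1L, round(0.02 * n_units))
    d_r <- sqrt((coords[, 1] - cl$x[1])^2 + (coords[, 2] - cl$y[1])^2)
    d_c <- sqrt((coords[, 1] - cl$x[length(cl$x)])^2 +
                  (coords[, 2] - cl$y[length(cl$y)])^2)
    landmark <- rep(NA_character_, n_units)
    landmark[order(d_r)[seq_len(n_lm)]] <- "rostral_tip"
    landmark[order(d_c)[seq_len(n_lm)]] <- "caudal_tip"

    n_grad <- round(frac_gradient * n_genes)
    patterns <- rep("flat", n_genes)
    if (n_grad > 0) {
      patterns[seq_len(n_grad)] <-
        rep_len(c("rostral_decreasing", "caudal_increasing", "middle_peak"),
                n_grad)
    }
    base_mean <- exp(stats::runif(n_genes, log(base_mean_range[1]),
                                  log(base_mean_range[2])))
    amplitude <- ifelse(patterns == "flat", 0,
                        stats::runif(n_genes, amplitude_range[1],
                                     amplitude_range[2]))
    spec <- gradient_spec(sprintf("gene_%04d", seq_len(n_genes)),
                          patterns, base_mean, amplitude,
                          rep(dispersion, n_genes))
    sf <- stats::rlnorm(n_units, 0, lib_sdlog)
    mu <- nb_mean_at(spec, s)
    counts <- draw_nb_counts(mu, spec$dispersion, sf)
    dimnames(counts) <- list(sprintf("spot_%04d", seq_len(n_units)), spec$gene_id)
    rownames(coords) <- rownames(counts)

    spatial <- spatial_dataset(counts, coords, section_id = "section_1",
                               landmark_label = landmark)
    truth <- list(
      true_axis = stats::setNames(s, rownames(counts)),
      gradient_table = spec,
      population_labels = stats::setNames(rep("tube", n_units), rownames(counts)),
      size_factors = stats::setNames(sf, rownames(counts)),
      section_transforms = NULL
    )
    list(spatial = spatial, truth = truth)
  })
}

#' Generate dissociated cells from a tube-organ bundle
#'
#' Cells are sampled at uniform-random true-axis positions (or at pinned
#' positions via `axis_positions`) and draw counts from the same
#' negative-binomial gradient model as the spatial organ; coordinates are
#' absent. With `panel`, the returned dataset is restricted to the given
#' gene subset, emulating a panel-limited ISS-like reference.
#'
#' @param bundle output of [generate_tube_organ()]
#' @param n_cells number of cells to generate
#' @param panel optional character vector of genes to retain
#' @param axis_positions optional numeric vector (recycled to `n_cells`)
#'   of pinned axis positions in \[0,1\]
#' @param seed integer seed
#' @inheritParams generate_tube_organ
#' @return list with `dataset` (an [expression_dataset()]) and
#'   `true_axis` (named numeric per cell)
#' @export
generate_dissociated <- function(bundle, n_cells, panel = NULL,
                                 axis_positions = NULL, lib_sdlog = 0.3,
                                 seed = 1L) {
  if (n_cells < 1) stop("n_cells must be positive", call. = FALSE)
  spec <- bundle$truth$gradient_table
  if (!is.null(panel)) {
    missing <- setdiff(panel, spec$gene_id)
    if (length(missing)) {
      stop("panel genes absent from bundle: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  withr_seed(seed, {
    s <- if (is.null(axis_positions)) {
      stats::runif(n_cells)
    } else {
      rep_len(axis_positions, n_cells)
    }
    sf <- stats::rlnorm(n_cells, 0, lib_sdlog)
    mu <- nb_mean_at(spec, s)
    counts <- draw_nb_counts(mu, spec$dispersion, sf)
    dimnames(counts) <- list(sprintf("cell_%05d", seq_len(n_cells)), spec$gene_id)
    ds <- expression_dataset(counts)
    if (!is.null(panel)) ds <- subset_genes(ds, panel)
    list(dataset = ds, true_axis = stats::setNames(s, rownames(counts)))
  })
}

#' Split a spatial dataset into sections with random rigid transforms
#'
#' Cuts the organ at the given true-axis positions and re-expresses each
#' section's coordinates in a section-local frame via a random rigid
#' transform (rotation + translation; the first section keeps the
#' identity). The transforms mapping each local frame back to the global
#' frame are returned and recorded in the truth, so stitching with them
#' reproduces the original coordinates; this manufactures the un-stitched
#' multi-section state that [stitch_sections()] repairs.
#'
#' @param bundle output of [generate_tube_organ()]
#' @param cut_positions strictly increasing axis positions in (0,1)
#' @param seed integer seed for the random transforms
#' @return list with `sections` (list of [spatial_dataset()]),
#'   `transforms` (list of [affine_transform()] local->global, one per
#'   section) and `truth` (the input truth with `section_transforms` set)
#' @export
split_into_sections <- function(bundle, cut_positions = numeric(), seed = 1L) {
  if (is.unsorted(cut_positions, strictly = TRUE)) {
    stop("cut_positions must be strictly increasing", call. = FALSE)
  }
  if (length(cut_positions) && (min(cut_positions) <= 0 || max(cut_positions) >= 1)) {
    stop("cut_positions must lie in (0, 1)", call. = FALSE)
  }
  spatial <- bundle$spatial
  s <- bundle$truth$true_axis[unit_ids(spatial)]
  breaks <- c(-Inf, cut_positions, Inf)
  sect <- findInterval(s, breaks, left.open = TRUE)
  n_sections <- length(cut_positions) + 1L
  empty <- setdiff(seq_len(n_sections), unique(sect))
  if (length(empty)) {
    stop("degenerate section(s) with no units: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  withr_seed(seed, {
    sections <- vector("list", n_sections)
    transforms <- vector("list", n_sections)
    for (i in seq_len(n_sections)) {
      idx <- which(sect == i)
      sec <- subset_units(spatial, idx)
      sec$section_id <- rep(sprintf("section_%d", i), length(idx))
      if (i == 1L) {
        tr <- affine_transform(diag(2), c(0, 0))
      } else {
        theta <- stats::runif(1, -pi, pi)
        tr <- affine_transform(
          matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2),
          stats::runif(2, -500, 500)
        )
      }
      # store local coords; tr maps local -> global
      inv <- solve(tr$linear)
      sec$coords <- t(inv %*% (t(sec$coords) - tr$translation))
      colnames(sec$coords) <- c("x_um", "y_um")
      sections[[i]] <- sec
      transforms[[i]] <- tr
    }
    truth <- bundle$truth
    truth$section_transforms <- transforms
    list(sections = sections, transforms = transforms, truth = truth)
  })
}

#' Generate a two-species pair sharing cell populations
#'
#' Both datasets draw from the same population-specific log-mean profiles
#' on orthologous genes (distinct identifiers per species, one-to-one
#' orthologue map covering a fraction `orth_frac` of genes);
#' `species_shift` adds a species-wide log2 offset to a random 20% gene
#' subset of species B, emulating species-specific expression divergence.
#'
#' @param n_cells_per_species cells per species
#' @param n_populations number of shared populations (>= 2, and at most
#'   n_cells_per_species / 20)
#' @param n_genes genes per species
#' @param orth_frac fraction of genes present in the orthologue map, in (0,1]
#' @param species_shift log2 offset applied to a random gene subset of B
#' @param marker_frac fraction of genes upregulated per population
#' @param dispersion NB dispersion
#' @param seed integer seed
#' @return list with `a`, `b` (datasets; population in `unit_meta$population`),
#'   `orthologues` (data.frame gene_a, gene_b) and `truth` (population
#'   labels per cell and the population log2-mean profiles)
#' @export
generate_species_pair <- function(n_cells_per_species, n_populations = 5L,
                                  n_genes = 500L, orth_frac = 0.8,
                                  species_shift = 0.5, marker_frac = 0.1,
                                  dispersion = 0.5, seed = 1L) {
  if (orth_frac <= 0) {
    stop("no shared features: orth_frac must be positive", call. = FALSE)
  }
  if (orth_frac > 1) stop("orth_frac must be at most 1", call. = FALSE)
  if (n_populations < 2) stop("need at least 2 populations", call. = FALSE)
  if (n_populations > n_cells_per_species / 20) {
    stop("n_populations must be at most n_cells_per_species / 20", call. = FALSE)
  }
  withr_seed(seed, {
    base_l2 <- stats::runif(n_genes, 0, log2(20))
    prof <- matrix(rep(base_l2, n_populations), ncol = n_populations)
    for (p in seq_len(n_populations)) {
      up <- sample.int(n_genes, max(1L, round(marker_frac * n_genes)))
      prof[up, p] <- prof[up, p] + stats::runif(length(up), 1, 2.5)
    }
    colnames(prof) <- sprintf("pop_%d", seq_len(n_populations))
    shift_genes <- sample.int(n_genes, round(0.2 * n_genes))
    prof_b <- prof
    prof_b[shift_genes, ] <- prof_b[shift_genes, ] + species_shift

    gen <- function(profiles, prefix, cell_prefix) {
      pop <- sort(rep_len(seq_len(n_populations), n_cells_per_species))
      sf <- stats::rlnorm(n_cells_per_species, 0, 0.3)
      mu <- t(2^profiles[, pop, drop = FALSE]) * sf
      counts <- matrix(
        stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
        nrow = n_cells_per_species
      )
      dimnames(counts) <- list(
        sprintf("%s_%05d", cell_prefix, seq_len(n_cells_per_species)),
        sprintf("%s_%04d", prefix, seq_len(n_genes))
      )
      meta <- data.frame(population = colnames(profiles)[pop],
                         row.names = rownames(counts))
      expression_dataset(counts, unit_meta = meta)
    }
    a <- gen(prof, "gA", "cellA")
    b <- gen(prof_b, "gB", "cellB")
    n_orth <- max(1L, round(orth_frac * n_genes))
    orth_idx <- sort(sample.int(n_genes, n_orth))
    orthologues <- data.frame(gene_a = gene_ids(a)[orth_idx],
                              gene_b = gene_ids(b)[orth_idx],
                              stringsAsFactors = FALSE)
    truth <- list(
      population_a = stats::setNames(a$unit_meta$population, unit_ids(a)),
      population_b = stats::setNames(b$unit_meta$population, unit_ids(b)),
      profiles_a = prof, profiles_b = prof_b,
      shifted_genes = sprintf("gB_%04d", shift_genes)
    )
    list(a = a, b = b, orthologues = orthologues, truth = truth)
  })
}

# Evaluate a block with a private RNG state so generators are pure
# functions of their seed and leave the caller's stream untouched.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
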
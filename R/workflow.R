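# Allowed configuration keys per workflow, with defaults. The synthetic
# generator's sizes default to desk-scale versions of the study
# conditions so the demo configs run in seconds.
workflow_schema <- list(
  common = list(workflow = NULL, seed = 1L, out_dir = NULL),
  axis_svg = list(n_units = 1000L, n_genes = 400L, frac_gradient = 0.1,
                  panel_size = 150L, n_query_cells = 1000L, k = 50L,
                  n_pcs = 30L, spline_df = 5L, p_max = 0.001,
                  min_log2fc = 0.5, n_bins = 20L, method = "geodesic"),
  trend = list(n_units = 600L, n_genes = 300L, frac_gradient = 0.15,
               signature_size = 15L, n_groups = 3L, n_perm = 2000L,
               alternative = "decreasing", n_ctrl_bins = 25L,
               ctrl_size = 50L),
  match = list(n_cells_per_species = 1500L, n_populations = 5L,
               n_genes = 400L, orth_frac = 0.8, species_shift = 0.5,
               min_cells = 10L, n_hvg = 4000L, k_graph = 30L,
               k_match = 30L, sample_prop = 0.1),
  qc = list(n_units = 800L, n_genes = 300L, frac_gradient = 0.2,
            n_clusters = 4L, top_n_markers = 20L)
)

resolve_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    path <- config
    config <- yaml::read_yaml(config)
    config$.config_path <- path
  }
  wf <- config$workflow
  if (is.null(wf) || !wf %in% names(workflow_schema)[-1]) {
    stop("config error: workflow must be one of ",
         paste(names(workflow_schema)[-1], collapse = ", "), call. = FALSE)
  }
  if (is.null(config$out_dir)) {
    stop("config error: out_dir is required", call. = FALSE)
  }
  allowed <- c(names(workflow_schema$common), names(workflow_schema[[wf]]),
               ".config_path")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- c(workflow_schema$common, workflow_schema[[wf]])
  for (key in names(defaults)) {
    if (is.null(config[[key]])) config[[key]] <- defaults[[key]]
  }
  config
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run an end-to-end workflow from a configuration
#'
#' Orchestrates the synthetic-data workflows (`axis_svg`: simulate ->
#' axis -> impute -> axis-variable genes; `trend`: simulate -> signature
#' score -> trend test; `match`: simulate species pair -> shared HVG
#' space -> neighbourhoods -> mutual matching; `qc`: simulate -> cluster
#' -> entropy / majority vote / TF-IDF markers / region enrichment) from
#' a single keyed configuration (a YAML file path or a named list).
#' Unknown keys are rejected before any computation. Every run writes a
#' `manifest.json` recording the resolved parameters, package version
#' and input checksums; outputs are plain TSVs, byte-identical across
#' reruns with the same config and seed. The single seed is fanned out
#' to per-stage seeds by fixed offsets so stages are reproducible in
#' isolation.
#'
#' @param config path to a YAML config or a named list
#' @return invisibly, a list with `out_dir` and the output `files`
#' @export
run_workflow <- function(config) {
  cfg <- resolve_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- switch(cfg$workflow,
                  axis_svg = run_axis_svg(cfg),
                  trend = run_trend(cfg),
                  match = run_match(cfg),
                  qc = run_qc(cfg))
  manifest <- list(
    workflow = cfg$workflow,
    package_version = as.character(utils::packageVersion("organaxis")),
    parameters = cfg[setdiff(names(cfg), c(".config_path", "out_dir"))],
    config_checksum = if (!is.null(cfg$.config_path)) {
      unname(tools::md5sum(cfg$.config_path))
    } else {
      NA
    },
    outputs = lapply(stats::setNames(nm = basename(files)), function(f) {
      unname(tools::md5sum(file.path(cfg$out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(out_dir = cfg$out_dir, files = files))
}

run_axis_svg <- function(cfg) {
  seed <- cfg$seed
  stage_log("simulate", "tube organ: %d units, %d genes", cfg$n_units, cfg$n_genes)
  bundle <- generate_tube_organ(cfg$n_units, cfg$n_genes,
                                frac_gradient = cfg$frac_gradient,
                                seed = seed)
  stage_log("axis", "assigning %s axis", cfg$method)
  ax <- assign_axis(bundle$spatial, method = cfg$method)
  axis_tab <- data.frame(unit_id = ax$unit_ids, axis_value = ax$value,
                         bin = bin_axis(ax, cfg$n_bins))
  write_tsv(axis_tab, file.path(cfg$out_dir, "axis.tsv"))

  stage_log("impute", "reference panel %d genes, %d query cells",
            cfg$panel_size, cfg$n_query_cells)
  spec <- bundle$truth$gradient_table
  panel <- utils::head(c(spec$gene_id[spec$pattern != "flat"],
                  spec$gene_id[spec$pattern == "flat"]), cfg$panel_size)
  ref <- subset_genes(bundle$spatial, panel)
  query <- generate_dissociated(bundle, cfg$n_query_cells, seed = seed + 1L)
  imp <- impute_axis_knn(ref, ax, query$dataset, k = cfg$k, n_pcs = cfg$n_pcs)
  write_tsv(imp, file.path(cfg$out_dir, "imputed_axis.tsv"))

  stage_log("svg", "testing genes along the imputed axis")
  svg <- detect_spatially_variable_genes(
    query$dataset, imp$value, p_max = cfg$p_max,
    min_log2fc = cfg$min_log2fc, spline_df = cfg$spline_df)
  write_tsv(svg, file.path(cfg$out_dir, "svg_results.tsv"))
  top <- utils::head(svg$gene_id[svg$pass], 25)
  if (length(top)) {
    prof <- binned_minmax_profiles(query$dataset, imp$value, top,
                                   n_bins = cfg$n_bins)
    write_tsv(cbind(gene_id = rownames(prof), as.data.frame(prof)),
              file.path(cfg$out_dir, "profiles.tsv"))
  }
  stage_log("svg", "%d genes pass (p < %g, log2 amplitude > %g)",
            sum(svg$pass), cfg$p_max, cfg$min_log2fc)
  c("axis.tsv", "imputed_axis.tsv", "svg_results.tsv",
    if (length(top)) "profiles.tsv")
}

run_trend <- function(cfg) {
  seed <- cfg$seed
  stage_log("simulate", "tube organ: %d units, %d genes", cfg$n_units, cfg$n_genes)
  bundle <- generate_tube_organ(cfg$n_units, cfg$n_genes,
                                frac_gradient = cfg$frac_gradient,
                                seed = seed)
  spec <- bundle$truth$gradient_table
  signature <- utils::head(spec$gene_id[spec$pattern == "rostral_decreasing"],
                    cfg$signature_size)
  stage_log("score", "signature of %d rostral-decreasing genes",
            length(signature))
  sc <- score_signature(bundle$spatial, signature,
                        n_ctrl_bins = cfg$n_ctrl_bins,
                        ctrl_size = cfg$ctrl_size, seed = seed + 1L)
  ax <- assign_axis(bundle$spatial)
  groups <- cut(ax$value, breaks = seq(0, 1, length.out = cfg$n_groups + 1),
                include.lowest = TRUE,
                labels = sprintf("region_%d", seq_len(cfg$n_groups)))
  jt <- jonckheere_test(sc$score, groups, alternative = cfg$alternative,
                        n_perm = cfg$n_perm, seed = seed + 2L)
  stage_log("trend", "JT = %g, p = %g (%s)", jt$jt_stat, jt$p_value,
            jt$alternative)
  write_tsv(cbind(sc, group = as.character(groups)),
            file.path(cfg$out_dir, "signature_scores.tsv"))
  write_tsv(data.frame(jt_stat = jt$jt_stat, p_value = jt$p_value,
                       alternative = jt$alternative, n_perm = jt$n_perm,
                       group_sizes = paste(jt$group_sizes, collapse = ",")),
            file.path(cfg$out_dir, "trend_test.tsv"))
  c("signature_scores.tsv", "trend_test.tsv")
}

run_match <- function(cfg) {
  seed <- cfg$seed
  stage_log("simulate", "species pair: %d cells/side, %d populations",
            cfg$n_cells_per_species, cfg$n_populations)
  pair <- generate_species_pair(cfg$n_cells_per_species,
                                n_populations = cfg$n_populations,
                                n_genes = cfg$n_genes,
                                orth_frac = cfg$orth_frac,
                                species_shift = cfg$species_shift,
                                seed = seed)
  feats <- shared_hvg_space(pair$a, pair$b, pair$orthologues,
                            min_cells = cfg$min_cells, n_hvg = cfg$n_hvg)
  stage_log("hvg", "%d shared orthologue HVGs", nrow(feats))
  nb_a <- build_neighbourhoods(pair$a, feats$gene_a, k_graph = cfg$k_graph,
                               sample_prop = cfg$sample_prop, seed = seed + 1L)
  nb_b <- build_neighbourhoods(pair$b, feats$gene_b, k_graph = cfg$k_graph,
                               sample_prop = cfg$sample_prop, seed = seed + 2L)
  nb_b$profile <- nb_b$profile[, feats$gene_b, drop = FALSE]
  colnames(nb_b$profile) <- feats$gene_a   # align on the orthologue pairing
  m <- match_neighbourhoods(nb_a, nb_b, k_match = cfg$k_match)
  stage_log("match", "%d mutual pairs", nrow(m$mutual_pairs))
  harm <- harmonize_annotations(m, nb_a, nb_b,
                                pair$truth$population_a,
                                pair$truth$population_b)
  write_tsv(m$mutual_pairs, file.path(cfg$out_dir, "matches.tsv"))
  write_tsv(harm$combinations, file.path(cfg$out_dir, "combinations.tsv"))
  c("matches.tsv", "combinations.tsv")
}

run_qc <- function(cfg) {
  seed <- cfg$seed
  stage_log("simulate", "tube organ: %d units, %d genes", cfg$n_units, cfg$n_genes)
  bundle <- generate_tube_organ(cfg$n_units, cfg$n_genes,
                                frac_gradient = cfg$frac_gradient,
                                seed = seed)
  norm <- as.matrix(normalize_log_cpm100(bundle$spatial))
  sc <- scale(norm)
  sc[, attr(sc, "scaled:scale") == 0] <- 0
  pcs <- stats::prcomp(sc, center = FALSE, rank. = 20L)$x
  clusters <- withr_seed(seed + 1L, {
    sprintf("cluster_%d", stats::kmeans(pcs, cfg$n_clusters, nstart = 5)$cluster)
  })
  ax <- assign_axis(bundle$spatial)
  region <- cut(ax$value, breaks = c(0, 1 / 3, 2 / 3, 1),
                include.lowest = TRUE,
                labels = c("rostral", "middle", "caudal"))
  stage_log("qc", "entropy over %d clusters", cfg$n_clusters)
  ent <- cluster_label_entropy(clusters, as.character(region))
  vote <- majority_vote_annotation(clusters, as.character(region))
  markers <- tfidf_markers(bundle$spatial, clusters,
                           top_n = cfg$top_n_markers)
  onehot <- stats::model.matrix(~ cluster - 1,
                                data.frame(cluster = factor(clusters)))
  colnames(onehot) <- levels(factor(clusters))
  z <- celltype_region_enrichment(onehot, as.character(region))
  write_tsv(ent, file.path(cfg$out_dir, "cluster_stats.tsv"))
  write_tsv(vote, file.path(cfg$out_dir, "cluster_annotation.tsv"))
  write_tsv(markers, file.path(cfg$out_dir, "markers.tsv"))
  write_tsv(cbind(cluster = rownames(z), as.data.frame(z)),
            file.path(cfg$out_dir, "enrichment_z.tsv"))
  c("cluster_stats.tsv", "cluster_annotation.tsv", "markers.tsv",
    "enrichment_z.tsv")
}
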
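#!/usr/bin/env Rscript
# Simulate the study's data modalities with known ground truth:
# a landmark-annotated curved tubular organ (Visium-like spots), a
# panel-limited ISS-like spatial reference, dissociated single cells
# without coordinates, a multi-section split of the organ, and a
# two-species pair sharing cell populations through an orthologue map.
# Everything downstream (02-07) reads from results/data/.

suppressPackageStartupMessages(library(organaxis))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026L

message("-- tubular organ: 2,000 spots x 500 genes, 30% gradient genes")
bundle <- generate_tube_organ(2000, 500, frac_gradient = 0.3, seed = seed)
write_bundle(bundle$spatial, file.path(out, "tube"), truth = bundle$truth)
tab <- table(bundle$truth$gradient_table$pattern)
message("   planted patterns: ",
        paste(names(tab), tab, sep = "=", collapse = ", "))

message("-- multi-section split at axis positions 0.4 and 0.75")
sections <- split_into_sections(bundle, c(0.4, 0.75), seed = seed + 1L)
for (i in seq_along(sections$sections)) {
  write_bundle(sections$sections[[i]], file.path(out, sprintf("section_%d", i)))
}
transforms <- lapply(seq_along(sections$transforms), function(i) {
  tr <- sections$transforms[[i]]
  list(section_id = sprintf("section_%d", i),
       matrix = cbind(tr$linear, tr$translation))
})
jsonlite::write_json(transforms, file.path(out, "transforms.json"),
                     digits = NA)

message("-- dissociated cells: 2,000 cells from the same gradient model")
cells <- generate_dissociated(bundle, 2000, seed = seed + 2L)
write_bundle(cells$dataset, file.path(out, "dissociated"))
write.csv(data.frame(unit_id = names(cells$true_axis),
                     true_axis = cells$true_axis),
          file.path(out, "dissociated_true_axis.csv"), row.names = FALSE)

message("-- species pair: 3,000 cells/side, 5 shared populations")
pair <- generate_species_pair(3000, n_populations = 5, n_genes = 500,
                              orth_frac = 0.8, species_shift = 0.5,
                              seed = seed + 3L)
write_bundle(pair$a, file.path(out, "species_a"))
write_bundle(pair$b, file.path(out, "species_b"))
write.table(pair$orthologues, file.path(out, "orthologues.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("done: fixtures under ", out)
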
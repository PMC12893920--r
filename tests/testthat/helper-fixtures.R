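# Small fixtures built in code, shared across test files.

# A tiny dense dataset with named units/genes.
tiny_dataset <- function(counts, ...) {
  expression_dataset(Matrix::Matrix(counts, sparse = TRUE), ...)
}

# Collinear three-unit spatial dataset with landmark labels at both ends.
collinear_spatial <- function() {
  counts <- matrix(1L, 4, 3,
                   dimnames = list(paste0("u", 1:4), paste0("g", 1:3)))
  coords <- cbind(c(0, 1, 3, 4), c(0, 0, 0, 0))
  spatial_dataset(counts, coords,
                  landmark_label = c("rostral_tip", NA, NA, "caudal_tip"))
}

# Write a hand-rolled 10x-style triplet; returns the directory.
write_mtx_fixture <- function(dir, header = "3 2 2",
                              entries = c("1 1 5", "3 2 7"),
                              type = "integer",
                              features = c("GENE1", "GENE2", "GENE3"),
                              barcodes = c("CELL1", "CELL2")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(sprintf("%%%%MatrixMarket matrix coordinate %s general", type),
               header, entries),
             file.path(dir, "matrix.mtx"))
  writeLines(features, file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  dir
}

# Two well-separated populations sharing one gene universe: a labelled
# "spatial" reference and a query drawn from the same profiles, with the
# query's true population recorded. Populations are interleaved so both
# splits are balanced, and marker_frac is raised so the populations are
# well separated (the regime the label-transfer contract targets).
two_population_sets <- function(n_ref = 300, n_query = 200, n_genes = 120,
                                seed = 42) {
  n <- n_ref + n_query
  pair <- generate_species_pair(n, n_populations = 2L,
                                n_genes = n_genes, orth_frac = 1,
                                species_shift = 0, marker_frac = 0.3,
                                seed = seed)
  ds <- pair$a
  half <- n %/% 2
  idx_ref <- c(seq_len(n_ref %/% 2), half + seq_len(n_ref - n_ref %/% 2))
  idx_query <- setdiff(seq_len(n), idx_ref)
  ref <- subset_units(ds, idx_ref)
  reference <- spatial_dataset(ref$counts, matrix(0, n_ref, 2),
                               unit_meta = ref$unit_meta)
  query <- subset_units(ds, idx_query)
  list(reference = reference, query = query,
       ref_labels = ref$unit_meta$population,
       query_labels = query$unit_meta$population)
}
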
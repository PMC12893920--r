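#!/usr/bin/env Rscript
# Integration-style QC statistics on the simulated organ: cluster the
# spots by expression, then summarize how axis regions distribute over
# clusters — Shannon entropy per cluster, thresholded (>= 40%) majority
# voting, TF-IDF marker genes, and the cluster-by-region z-score
# enrichment map.

suppressPackageStartupMessages(library(organaxis))

dat <- "results/data"
tube <- read_bundle(file.path(dat, "tube"))
axis_tab <- read.csv("results/axis.csv")
value <- axis_tab$axis_value[match(unit_ids(tube), axis_tab$unit_id)]
region <- as.character(cut(value, breaks = c(0, 1 / 3, 2 / 3, 1),
                           include.lowest = TRUE,
                           labels = c("rostral", "middle", "caudal")))

norm <- as.matrix(normalize_log_cpm100(tube))
sc <- scale(norm)
sc[, attr(sc, "scaled:scale") == 0] <- 0
pcs <- prcomp(sc, center = FALSE, rank. = 20)$x
set.seed(17)
clusters <- sprintf("cluster_%d", kmeans(pcs, 4, nstart = 5)$cluster)

ent <- cluster_label_entropy(clusters, region)
message("-- entropy of region labels per expression cluster (bits):")
print(ent[c("cluster_id", "n_units", "entropy", "majority_label",
            "majority_fraction")])

vote <- majority_vote_annotation(clusters, region)
message(sprintf("-- majority-vote (>=40%%) annotations: %s",
                paste(vote$cluster_id, vote$label, sep = "->",
                      collapse = ", ")))

markers <- tfidf_markers(tube, clusters, top_n = 10)
z <- celltype_region_enrichment(
  model.matrix(~ cl - 1, data.frame(cl = factor(clusters))), region)
rownames(z) <- sub("^cl", "", rownames(z))
message("-- cluster-by-region z enrichment:")
print(round(z, 2))

write.table(ent, "results/cluster_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(markers, "results/markers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cbind(cluster = rownames(z), as.data.frame(z)),
            "results/enrichment_z.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/cluster_stats.tsv, markers.tsv, enrichment_z.tsv")
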
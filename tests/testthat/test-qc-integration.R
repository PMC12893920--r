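test_that("cluster label entropy matches closed forms", {
  clusters <- rep(c("c1", "c2", "c3"), c(4, 4, 4))
  labels <- c(rep("x", 4),                 # single label -> 0 bits
              rep(c("x", "y"), 2),         # 50/50 -> 1 bit
              c("a", "b", "c", "d"))       # 4-way uniform -> 2 bits
  st <- cluster_label_entropy(clusters, labels)
  expect_equal(st$entropy, c(0, 1, 2), tolerance = 1e-12)
  fr <- attr(st, "label_fractions")
  expect_equal(sum(fr$c2), 1, tolerance = 1e-9)
  # natural-log base scales entropies by ln 2
  st_e <- cluster_label_entropy(clusters, labels, base = exp(1))
  expect_equal(st_e$entropy, c(0, 1, 2) * log(2), tolerance = 1e-12)
  # donor mode: zero-entropy (donor-specific) clusters flagged for removal
  stf <- cluster_label_entropy(clusters, labels, flag_zero_entropy = TRUE)
  expect_identical(stf$remove_flag, c(TRUE, FALSE, FALSE))
  expect_error(cluster_label_entropy(clusters, labels[-1]), "invalid input")
})

test_that("entropy is maximal exactly at uniform label fractions", {
  set.seed(2)
  labels <- sample(letters[1:4], 400, replace = TRUE)
  st <- cluster_label_entropy(rep("c1", 400), labels)
  expect_lt(st$entropy, 2)
  st_u <- cluster_label_entropy(rep("c1", 400), rep(letters[1:4], 100))
  expect_equal(st_u$entropy, 2, tolerance = 1e-12)
})

test_that("majority vote annotation respects the inclusive 40% boundary", {
  clusters <- rep("c1", 100)
  at_40 <- c(rep("winner", 40), rep(letters[1:6], 10))
  expect_identical(majority_vote_annotation(clusters, at_40)$label, "winner")
  at_39 <- c(rep("winner", 39), rep(letters[1:6], 10), "g")
  expect_identical(majority_vote_annotation(clusters, at_39)$label,
                   "unresolved")
  single <- majority_vote_annotation(rep("c9", 5), rep("only", 5))
  expect_identical(single$label, "only")
  expect_identical(single$majority_fraction, 1)
  # modal ties are unresolved and flagged
  tie <- majority_vote_annotation(rep("c1", 4), c("x", "x", "y", "y"))
  expect_identical(tie$label, "unresolved")
  expect_true(tie$tie)
  # threshold 0 assigns everything except ties
  lo <- majority_vote_annotation(rep("c1", 5), c("x", "x", "y", "z", "w"),
                                 threshold = 0)
  expect_identical(lo$label, "x")
})

test_that("TF-IDF markers match the closed form and a brute-force recount", {
  # 100 units, cluster of 10, gene expressed in exactly those 10:
  # tf = 1, idf = ln(10), score = ln(10)
  counts <- matrix(0L, 100, 3,
                   dimnames = list(sprintf("u%03d", 1:100),
                                   c("marker", "ubiq", "noise")))
  counts[1:10, "marker"] <- 3L
  counts[, "ubiq"] <- 1L
  counts[seq(1, 99, 2), "noise"] <- 2L
  clusters <- rep(c("small", "big"), c(10, 90))
  tab <- tfidf_markers(tiny_dataset(counts), clusters, top_n = 3)
  row <- tab[tab$cluster_id == "small" & tab$gene_id == "marker", ]
  expect_equal(row$tf, 1)
  expect_equal(row$idf, log(10), tolerance = 1e-12)
  expect_equal(row$score, log(10), tolerance = 1e-12)
  # ubiquitous gene: idf = 0 -> score 0
  ub <- tab[tab$gene_id == "ubiq", ]
  expect_true(all(ub$score == 0))

  # brute-force recount on a random fixture
  set.seed(31)
  m <- matrix(rbinom(50 * 30, 1, 0.3) * rpois(50 * 30, 4), 50, 30,
              dimnames = list(sprintf("u%02d", 1:50), sprintf("g%02d", 1:30)))
  cl <- rep(c("A", "B"), 25)
  got <- tfidf_markers(tiny_dataset(m), cl, top_n = 30)
  det <- m > 0
  expressed <- colSums(det) >= 1
  for (i in sample(nrow(got), 10)) {
    g <- got$gene_id[i]
    in_cl <- cl == got$cluster_id[i]
    expect_equal(got$tf[i], mean(det[in_cl, g]), tolerance = 1e-12)
    expect_equal(got$idf[i], log(50 / sum(det[, g])), tolerance = 1e-12)
    expect_equal(got$score[i], got$tf[i] * got$idf[i], tolerance = 1e-12)
  }
  # ranks are a permutation within cluster; never-expressed genes dropped
  for (c0 in c("A", "B")) {
    expect_identical(sort(got$rank[got$cluster_id == c0]),
                     seq_len(sum(got$cluster_id == c0)))
  }
  expect_true(all(got$gene_id %in% names(which(expressed))))
  expect_error(tfidf_markers(tiny_dataset(m), rep("A", 50)), "2 clusters")
})

test_that("TF-IDF depends only on the detection pattern, not count magnitude", {
  set.seed(5)
  m <- matrix(rbinom(40 * 10, 1, 0.4), 40, 10,
              dimnames = list(sprintf("u%d", 1:40), sprintf("g%d", 1:10)))
  cl <- rep(c("A", "B"), 20)
  t1 <- tfidf_markers(tiny_dataset(m), cl, top_n = 10)
  t2 <- tfidf_markers(tiny_dataset(m * 97L), cl, top_n = 10)
  expect_identical(t1, t2)
})

test_that("region enrichment z-scores match the closed form", {
  # cell type present only in region 1 of 3: z = (2/3) * m / (m / sqrt(3))
  abundance <- cbind(ct = c(5, 5, 0, 0, 0, 0))
  regions <- rep(c("r1", "r2", "r3"), each = 2)
  z <- celltype_region_enrichment(abundance, regions)
  expect_equal(unname(z["ct", ]), c(2 * sqrt(3) / 3, -sqrt(3) / 3,
                                    -sqrt(3) / 3), tolerance = 1e-12)
  # independent of the magnitude m
  z2 <- celltype_region_enrichment(abundance * 13, regions)
  expect_equal(z, z2, tolerance = 1e-12)

  # uniform abundance -> all zeros
  zu <- celltype_region_enrichment(cbind(ct = rep(2, 6)), regions)
  expect_true(all(zu == 0))

  # rows standardized: mean 0, sample sd 1 for non-degenerate rows
  set.seed(9)
  ab <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  zz <- celltype_region_enrichment(ab, rep(c("r1", "r2", "r3", "r4"), 5))
  expect_lt(max(abs(rowMeans(zz))), 1e-9)
  expect_equal(apply(zz, 1, sd), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)

  # permuting region order permutes columns identically
  ord <- c(5:6, 1:4)
  zp <- celltype_region_enrichment(abundance[ord, , drop = FALSE],
                                   regions[ord])
  expect_equal(zp, z[, colnames(zp), drop = FALSE], tolerance = 1e-12)

  expect_error(celltype_region_enrichment(abundance, rep("r1", 6)),
               "2 regions")
  expect_error(celltype_region_enrichment(abundance, c(regions[-1], NA)),
               "region")
})
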
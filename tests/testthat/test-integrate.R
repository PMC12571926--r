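test_that("RNA counting collapses exact-match UMI triples", {
  recs <- data.frame(read_id = sprintf("r%d", 1:7),
                     pixel = c(rep("A1B1", 6L), NA),
                     umi = c("AAAA", "AAAA", "AAAA", "CCCC", "GGGG", "TTTT", "AAAA"),
                     status = c(rep("assigned", 6L), "no_match"),
                     stringsAsFactors = FALSE)
  asg <- data.frame(read_id = sprintf("r%d", 1:7),
                    gene = c("g1", "g1", "g1", "g2", "g2", "g2", "g1"),
                    stringsAsFactors = FALSE)
  cnt <- count_rna(recs, asg)
  expect_equal(as.numeric(cnt["g1", "A1B1"]), 1)   # 3 reads, same UMI
  expect_equal(as.numeric(cnt["g2", "A1B1"]), 3)   # 3 distinct UMIs
  expect_equal(attr(cnt, "n_unassigned"), 1L)
})

test_that("simulated counts equal the provenance distinct-triple tally", {
  rd <- emit_reads(make_truth(tiny_config(reads_per_pixel_rna = 40L)))
  pr <- rd$provenance[rd$provenance$library == "rna", ]
  recs <- data.frame(read_id = pr$read_id, pixel = pr$pixel, umi = pr$umi,
                     status = "assigned", stringsAsFactors = FALSE)
  cnt <- count_rna(recs, data.frame(read_id = pr$read_id, gene = pr$gene))
  oracle <- table(unique(pr[, c("pixel", "gene", "umi")])[, c("gene", "pixel")])
  expect_equal(sum(cnt), sum(oracle))
  for (g in rownames(oracle)) {
    expect_equal(as.numeric(cnt[g, colnames(oracle)]),
                 as.numeric(oracle[g, ]))
  }
})

test_that("median-ratio log-normalisation is scale invariant per pixel", {
  # column totals 4, 6, 10, 14, 20: median 10, stable when p1 doubles
  counts <- matrix(c(1, 1, 2, 2, 2, 2, 3, 3, 4, 4, 5, 5, 6, 7, 7), 3L,
                   dimnames = list(paste0("g", 1:3), paste0("p", 1:5)))
  nm <- normalize_rna(counts)
  # equal totals: scaling is the identity before log
  eq <- matrix(c(1, 2, 3, 3, 2, 1, 2, 2, 2), 3L,
               dimnames = list(paste0("g", 1:3), paste0("q", 1:3)))
  expect_equal(as.matrix(normalize_rna(eq)), log1p(eq), tolerance = 1e-12)
  # doubling every count of one (non-median) pixel leaves its profile fixed
  doubled <- counts
  doubled[, "p1"] <- 2 * counts[, "p1"]
  expect_equal(as.matrix(normalize_rna(doubled))[, "p1"],
               as.matrix(nm)[, "p1"], tolerance = 1e-12)
  # hand-computed oracle for one entry: scale to median total, then log1p
  tot <- colSums(counts)
  expect_equal(as.matrix(nm)["g2", "p2"],
               log1p(counts["g2", "p2"] * median(tot) / tot["p2"]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # zero-total pixels are dropped with a report
  z <- cbind(counts, p0 = c(0, 0, 0))
  nz <- normalize_rna(z)
  expect_false("p0" %in% colnames(nz))
  expect_equal(attr(nz, "dropped_pixels"), "p0")
})

test_that("PCA embedding matches a full SVD oracle up to fixed signs", {
  set.seed(41)
  x <- matrix(rnorm(50 * 20), 50L, dimnames = list(paste0("s", 1:50), NULL))
  emb <- embed_pca(x, n_components = 5L)
  xc <- scale(x, center = TRUE, scale = FALSE)
  s <- svd(xc)
  oracle <- s$u[, 1:5] %*% diag(s$d[1:5])
  for (j in 1:5) {
    expect_equal(abs(emb$scores[, j]), abs(oracle[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # variance shares are monotone non-increasing
  expect_true(all(diff(emb$var_share) <= 1e-12))
  # deterministic sign convention across runs
  expect_identical(emb$scores, embed_pca(x, n_components = 5L)$scores)
  # 2-dimensional data is reconstructed exactly from 2 components
  y <- matrix(rnorm(30 * 2), 30L) %*% matrix(rnorm(2 * 6), 2L)
  e2 <- embed_pca(y, n_components = 2L)
  recon <- e2$scores %*% t(e2$loadings)
  yc <- scale(y, center = TRUE, scale = FALSE)
  expect_equal(recon, yc, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(embed_pca(cbind(c(1, NA, 3))), "missing")
})

test_that("WNN weights are normalised and symmetric for identical inputs", {
  set.seed(8)
  x <- matrix(rnorm(60 * 4), 60L, dimnames = list(paste0("p", 1:60), NULL))
  emb <- structure(list(scores = x, modality = "rna"),
                   class = "sdmt_embedding")
  wg <- wnn_fuse(emb, emb, k = 10L)
  expect_true(all(abs(wg$weights$w_rna - 0.5) < 1e-9))
  expect_true(all(abs(wg$weights$w_rna + wg$weights$w_meth - 1) < 1e-12))
  # weights stay in [0, 1] for arbitrary pairs
  y <- matrix(rnorm(60 * 4), 60L, dimnames = list(paste0("p", 1:60), NULL))
  emb_y <- structure(list(scores = y, modality = "meth"),
                     class = "sdmt_embedding")
  wg2 <- wnn_fuse(emb, emb_y, k = 10L)
  expect_true(all(wg2$weights$w_rna >= 0 & wg2$weights$w_rna <= 1))
  expect_true(all(abs(wg2$weights$w_rna + wg2$weights$w_meth - 1) < 1e-12))
  expect_error(wnn_fuse(emb, emb_y, k = 60L), "smaller")
})

test_that("the informative modality receives the larger weight", {
  medians <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 80L
    blobs <- rbind(matrix(rnorm(n / 2 * 3), n / 2),
                   matrix(rnorm(n / 2 * 3, mean = 8), n / 2))
    rownames(blobs) <- paste0("p", 1:n)
    noise <- matrix(rnorm(n * 3), n, dimnames = list(paste0("p", 1:n), NULL))
    wg <- wnn_fuse(structure(list(scores = blobs, modality = "rna"),
                             class = "sdmt_embedding"),
                   structure(list(scores = noise, modality = "meth"),
                             class = "sdmt_embedding"), k = 10L)
    median(wg$weights$w_rna)
  }, numeric(1))
  expect_true(all(medians > 0.5))
})

test_that("graph clustering separates disconnected cliques deterministically", {
  g <- igraph::make_full_graph(10L) + igraph::make_full_graph(10L)
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- as.character(1:20)
  cl <- cluster_graph(g, resolution = 0.8, seed = 1L)
  expect_equal(nlevels(cl), 2L)
  expect_equal(length(unique(cl[1:10])), 1L)
  expect_equal(length(unique(cl[11:20])), 1L)
  # same seed, permuted vertices: identical partition up to renaming
  perm <- sample(20L)
  gp <- igraph::permute(g, perm)
  clp <- cluster_graph(gp, resolution = 0.8, seed = 1L)
  expect_equal(adjusted_rand_index(cl, clp[perm]), 1)
})

test_that("well-separated blobs cluster perfectly through the WNN graph", {
  set.seed(12)
  n <- 200L
  blobs <- rbind(matrix(rnorm(n / 2 * 2, sd = 1), n / 2),
                 matrix(rnorm(n / 2 * 2, mean = 10, sd = 1), n / 2))
  rownames(blobs) <- paste0("p", 1:n)
  emb <- structure(list(scores = blobs, modality = "rna"),
                   class = "sdmt_embedding")
  wg <- wnn_fuse(emb, emb, k = 15L)
  cl <- cluster_graph(wg, resolution = 0.5, seed = 2L)
  truth <- rep(1:2, each = n / 2)
  expect_equal(adjusted_rand_index(cl, truth), 1)
})

test_that("cluster comparison equals nested-loop pair counting", {
  set.seed(13)
  a <- sample(letters[1:3], 50L, TRUE)
  b <- sample(LETTERS[1:4], 50L, TRUE)
  cc <- compare_clusterings(a, b)
  for (i in letters[1:3]) for (j in LETTERS[1:4]) {
    expect_equal(unname(cc$table[i, j]), sum(a == i & b == j))
  }
  expect_true(all(abs(rowSums(cc$confusion) - 1) < 1e-12))
  expect_equal(sum(cc$flow$n), 50L)
  # identical labelings give a diagonal table, ARI 1
  ci <- compare_clusterings(a, a)
  expect_true(all(ci$table[upper.tri(ci$table) | lower.tri(ci$table)] == 0L))
  expect_equal(ci$ari, 1)
  # one constant labeling: a single row holding the other's sizes
  cst <- compare_clusterings(rep("x", 50L), b)
  expect_equal(as.numeric(cst$table), as.numeric(table(b)))
  expect_error(compare_clusterings(a, b[-1]), "length")
  # ARI agrees with the mclust reference implementation
  expect_equal(cc$ari, mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
})

test_that("joint WNN clustering recovers the four tissue regions (5 seeds)", {
  aris <- vapply(1:5, function(s) run_joint_recovery(s)$ari, numeric(1))
  expect_true(all(aris >= 0.8))
})
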
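test_that("rank-sum differential tests match exact enumeration", {
  # identical groups: p = 1
  x <- cbind(f1 = c(1, 2, 3, 1, 2, 3))
  lab <- rep(c("a", "b"), each = 3L)
  expect_equal(diff_features(x, lab, pseudo = 1)$p, 1)

  # complete separation, n = m = 5: two-sided exact p = 2 / choose(10, 5)
  y <- cbind(f1 = c(1:5, 101:105))
  lab5 <- rep(c("a", "b"), each = 5L)
  expect_equal(diff_features(y, lab5, pseudo = 1)$p, 2 / 252)

  # exact p equals full permutation enumeration for n + m <= 12
  set.seed(19)
  for (nm in list(c(3L, 4L), c(5L, 5L), c(6L, 6L))) {
    va <- rnorm(nm[1]); vb <- rnorm(nm[2])
    got <- diff_features(cbind(f = c(va, vb)),
                         rep(c("a", "b"), nm), pseudo = 1)$p
    pooled <- c(va, vb)
    w_obs <- sum(rank(pooled)[seq_len(nm[1])]) - nm[1] * (nm[1] + 1) / 2
    combs <- combn(nm[1] + nm[2], nm[1])
    w_all <- apply(combs, 2L, function(ix)
      sum(rank(pooled)[ix]) - nm[1] * (nm[1] + 1) / 2)
    mu <- nm[1] * nm[2] / 2
    p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu))
    expect_equal(got, p_exact)
  }
})

test_that("adjustment, skipping and fold-change contracts hold", {
  set.seed(23)
  x <- matrix(rnorm(20 * 4, mean = 5), 20L,
              dimnames = list(NULL, paste0("f", 1:4)))
  x[1:18, 4] <- NA                        # fewer than 2 observed in group a
  lab <- rep(c("a", "b"), each = 10L)
  res <- diff_features(x, lab, adjust = "BH", pseudo = 1)
  expect_false(res$tested[res$feature == "f4"])
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
  expect_true(all(res$p_adj <= 1, na.rm = TRUE))
  resb <- diff_features(x, lab, adjust = "bonferroni", pseudo = 1)
  expect_equal(resb$p_adj[resb$tested],
               pmin(1, resb$p[resb$tested] * sum(resb$tested)))
  # BH step-up on p = (0.01, 0.02, 0.03) with m = 3 gives 0.03 throughout
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3L))
  # one-vs-rest expansion for > 2 groups
  lab3 <- rep(c("a", "b", "c"), length.out = 20L)
  res3 <- diff_features(x[, 1:2], lab3, pseudo = 1)
  expect_setequal(unique(res3$group), c("a", "b", "c"))
})

test_that("null data yield approximately nominal type-I error", {
  set.seed(29)
  x <- matrix(rnorm(30 * 1000), 30L)
  lab <- rep(c("a", "b"), each = 15L)
  res <- diff_features(x, lab, pseudo = 1)
  frac <- mean(res$p < 0.05)
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("VMR-gene pairing equals the quadratic intersection scan", {
  genes <- data.frame(contig = "chr1", start = c(150L, 1000L),
                      end = c(500L, 2000L), strand = c("+", "-"),
                      name = c("gA", "gB"), stringsAsFactors = FALSE)
  vmrs <- data.frame(contig = "chr1", start = c(100L, 100L),
                     end = c(200L, 200L), score = 1)
  p <- pair_vmr_gene(vmrs[1, ], genes, flank_bp = 0L)
  expect_equal(p$gene, "gA")
  # flank pulls in the distant gene; upstream-only respects strand
  p2 <- pair_vmr_gene(vmrs[1, ], genes, flank_bp = 900L)
  expect_setequal(p2$gene, c("gA", "gB"))
  # gB is on "-": its upstream flank extends right, not towards the VMR
  p3 <- pair_vmr_gene(vmrs[1, ], genes, flank_bp = 900L, upstream_only = TRUE)
  expect_false("gB" %in% p3$gene)

  set.seed(37)
  rg <- data.frame(contig = sample(c("chr1", "chr2"), 30L, TRUE),
                   start = sample.int(10000L, 30L), stringsAsFactors = FALSE)
  rg$end <- rg$start + sample.int(500L, 30L)
  rg$strand <- sample(c("+", "-"), 30L, TRUE)
  rg$name <- sprintf("g%02d", 1:30)
  rv <- data.frame(contig = sample(c("chr1", "chr2"), 20L, TRUE),
                   start = sample.int(10000L, 20L), stringsAsFactors = FALSE)
  rv$end <- rv$start + sample.int(800L, 20L)
  rv$score <- 1
  got <- pair_vmr_gene(rv, rg, flank_bp = 100L)
  got_keys <- paste(got$vmr, got$gene)
  want <- character(0)
  for (i in seq_len(nrow(rv))) for (j in seq_len(nrow(rg))) {
    if (rv$contig[i] == rg$contig[j] &&
        rv$start[i] < rg$end[j] + 100L && rv$end[i] > rg$start[j] - 100L) {
      want <- c(want, paste(sprintf("%s:%d-%d", rv$contig[i], rv$start[i],
                                    rv$end[i]), rg$name[j]))
    }
  }
  expect_setequal(got_keys, want)
})

test_that("methylation-expression correlation matches closed-form Pearson", {
  px <- paste0("p", 1:5)
  meth <- matrix(c(0.1, 0.3, 0.5, 0.7, 0.9), 5L,
                 dimnames = list(px, "chr1:0-100"))
  expr <- matrix(-c(0.1, 0.3, 0.5, 0.7, 0.9), 5L, dimnames = list(px, "gA"))
  pairs <- data.frame(vmr = "chr1:0-100", gene = "gA",
                      stringsAsFactors = FALSE)
  res <- corr_meth_expr(pairs, meth, expr)
  expect_equal(res$r, -1)

  set.seed(43)
  ev <- matrix(rnorm(5), 5L, dimnames = list(px, "gA"))
  res2 <- corr_meth_expr(pairs, meth, ev)
  mx <- meth[, 1] - mean(meth[, 1]); ey <- ev[, 1] - mean(ev[, 1])
  r_hand <- sum(mx * ey) / sqrt(sum(mx^2) * sum(ey^2))
  expect_equal(res2$r, r_hand, tolerance = 1e-12)
  # zero variance is flagged, not crashed
  flat <- matrix(rep(0.5, 5L), 5L, dimnames = list(px, "chr1:0-100"))
  expect_false(corr_meth_expr(pairs, flat, ev)$tested)
})

test_that("independent modalities give centred r and ~5% false positives", {
  set.seed(47)
  n_pairs <- 1000L
  px <- paste0("p", 1:30)
  meth <- matrix(runif(30 * n_pairs), 30L,
                 dimnames = list(px, sprintf("chr1:%d-%d", 1:n_pairs,
                                             2:(n_pairs + 1L))))
  expr <- matrix(rnorm(30 * n_pairs), 30L,
                 dimnames = list(px, sprintf("g%04d", 1:n_pairs)))
  pairs <- data.frame(vmr = colnames(meth), gene = colnames(expr),
                      stringsAsFactors = FALSE)
  res <- corr_meth_expr(pairs, meth, expr)
  expect_lt(abs(mean(res$r)), 0.05)
  frac <- mean(res$p < 0.05)
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / n_pairs))
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n_pairs))
})

test_that("fold enrichment follows the observed/expected definition", {
  # |query| = 1000, |feature| = 2000, N = 100000, O = 30 -> E = 20, FE = 1.5
  q <- c(sprintf("s%05d", 1:30), sprintf("q%05d", 1:970))
  f <- c(sprintf("s%05d", 1:30), sprintf("f%05d", 1:1970))
  fe <- fold_enrichment(q, f, universe_n = 100000L)
  expect_equal(fe$observed, 30L)
  expect_equal(fe$expected, 20)
  expect_equal(fe$fold_enrichment, 1.5)
  # query = feature = universe -> FE = 1
  u <- sprintf("u%03d", 1:500)
  expect_equal(fold_enrichment(u, u, 500L)$fold_enrichment, 1)
  # empty query reported undefined
  expect_true(is.na(fold_enrichment(character(0), u, 500L)$fold_enrichment))
})

test_that("Fisher p equals hypergeometric enumeration", {
  # N = 10, |query| = 5, |feature| = 4, O = 4 -> p = 6/252
  q <- letters[1:5]
  f <- letters[c(1:4, 6)][1:4]            # overlap 4
  fe <- fold_enrichment(q, f, universe_n = 10L)
  expect_equal(fe$p, 6 / 252, tolerance = 1e-12)
  # enumeration oracle: P(X >= O), X ~ Hypergeom(N, |f|, |q|)
  p_oracle <- sum(dhyper(4:4, 4, 6, 5))
  expect_equal(fe$p, p_oracle, tolerance = 1e-12)
  # multi-feature FDR across features
  fe2 <- fold_enrichment(q, list(a = f, b = letters[6:9]), universe_n = 10L)
  expect_equal(fe2$fdr, p.adjust(fe2$p, "BH"))
})

test_that("uniformly drawn queries centre fold enrichment at 1", {
  set.seed(53)
  universe <- sprintf("cpg%05d", 1:5000)
  feature <- sample(universe, 1000L)
  fes <- vapply(1:1000, function(i) {
    fold_enrichment(sample(universe, 200L), feature, 5000L)$fold_enrichment
  }, numeric(1))
  expect_lt(abs(mean(fes) - 1), 3 * sd(fes) / sqrt(length(fes)))
})
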
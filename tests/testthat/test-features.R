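test_that("shrunken residual attenuates deviations at low coverage", {
  expect_equal(shrunken_residual(0.5, 0.5, 3, k = 1), 0)
  expect_equal(shrunken_residual(0.9, 0.5, 1, k = 1), 0.2)   # cov = k -> half
  expect_equal(shrunken_residual(0.8, 0.5, 1e6, k = 1), 0.3, tolerance = 1e-5)
  expect_error(shrunken_residual(0.5, 0.5, 1, k = 0), "> 0")
})

test_that("VMR selection keeps exactly the ceiling of the top fraction", {
  # 200 non-overlapping windows with distinct variance scores
  set.seed(31)
  positions <- as.integer(outer(c(100L, 300L, 500L, 700L, 900L),
                                (0:199) * 1000L, "+"))
  pixels <- sprintf("px%02d", 1:12)
  meth <- matrix(runif(12 * length(positions), 0.3, 0.9), nrow = 12)
  tab <- build_call_table(meth, sort(positions), pixels, coverage = 6L)
  vm <- scan_vmrs(tab, contig_lengths = c(chr1 = 200000),
                  window_bp = 1000L, step_bp = 1000L, min_sites = 5L,
                  min_pixels = 10L, top_fraction = 0.02)
  expect_equal(attr(vm, "n_eligible"), 200L)
  expect_equal(attr(vm, "n_selected"), ceiling(0.02 * 200))
  vm2 <- scan_vmrs(tab, contig_lengths = c(chr1 = 200000),
                   window_bp = 1000L, step_bp = 1000L, min_sites = 5L,
                   min_pixels = 10L, top_fraction = 0.1)
  expect_equal(attr(vm2, "n_selected"), 20L)
  # windows below min_sites or min_pixels are ineligible
  expect_warning(
    vm3 <- scan_vmrs(tab, contig_lengths = c(chr1 = 200000),
                     window_bp = 1000L, step_bp = 1000L, min_sites = 6L,
                     min_pixels = 10L, top_fraction = 0.02),
    "no eligible")
  expect_equal(attr(vm3, "n_eligible"), 0L)
})

test_that("selected windows fuse into non-overlapping sorted intervals", {
  fused <- fuse_vmrs(data.frame(contig = "chr1", start = c(100L, 300L),
                                end = c(600L, 800L), score = c(1, 2)))
  expect_equal(nrow(fused), 1L)
  expect_equal(c(fused$start, fused$end), c(100L, 800L))
  expect_equal(fused$score, 2)
  # book-ended intervals fuse; separated ones do not
  f2 <- fuse_vmrs(data.frame(contig = "chr1", start = c(0L, 500L, 2000L),
                             end = c(500L, 1000L, 3000L), score = 1:3))
  expect_equal(nrow(f2), 2L)
  expect_equal(f2$end[1], 1000L)
  # idempotence
  expect_identical(fuse_vmrs(f2), f2)
})

test_that("planted high-variance windows are recovered with sensitivity >= 0.9", {
  hits <- 0L
  total <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n_pix <- 200L
    n_win <- 100L
    positions <- as.integer(outer(seq(100L, 900L, by = 160L),
                                  (0:(n_win - 1L)) * 1000L, "+"))
    planted <- sample.int(n_win, 10L)
    meth <- matrix(0.75, n_pix, length(positions))
    win_of <- rep(0:(n_win - 1L), each = 6L)[order(order(positions))]
    groupA <- seq_len(n_pix) <= n_pix / 2
    for (w in planted) {
      cols <- which(win_of == (w - 1L))
      meth[groupA, cols] <- 0.25          # delta 0.5 between pixel groups
    }
    tab <- build_call_table(meth, sort(positions), sprintf("px%03d", 1:n_pix),
                            coverage = 4L)
    vm <- scan_vmrs(tab, contig_lengths = c(chr1 = n_win * 1000),
                    window_bp = 1000L, step_bp = 1000L, min_sites = 5L,
                    min_pixels = 10L, top_fraction = 0.1)
    for (w in planted) {
      lo <- (w - 1L) * 1000L
      total <- total + 1L
      if (any(vm$contig == "chr1" & vm$start < lo + 1000L & vm$end > lo)) {
        hits <- hits + 1L
      }
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("VMR matrices match direct per-interval tallies", {
  tab <- data.frame(
    pixel = rep(c("p1", "p2"), each = 3L), contig = "chr1",
    pos = rep(c(150L, 250L, 950L), 2L), strand = "+", context = "CG",
    retained = c(1L, 2L, 3L, 0L, 0L, 1L),
    converted = c(0L, 2L, 1L, 0L, 4L, 0L), stringsAsFactors = FALSE)
  vmrs <- data.frame(contig = "chr1", start = c(100L, 900L),
                     end = c(300L, 1000L), score = c(1, 2))
  m <- vmr_matrix(tab, vmrs)
  expect_equal(m$levels["p1", "chr1:100-300"], 3 / 5)
  expect_equal(m$levels["p2", "chr1:100-300"], 0 / 4)
  expect_equal(m$levels["p1", "chr1:900-1000"], 3 / 4)
  expect_equal(m$levels["p2", "chr1:900-1000"], 1)
  # single covered CpG with retained = 1 -> level 1; zero coverage -> NA
  solo <- tab[tab$pixel == "p2" & tab$pos != 950L, ]
  m2 <- vmr_matrix(solo, vmrs)
  expect_true(is.na(m2$levels["p2", "chr1:900-1000"]))
  # residuals: shrunken deviation from the pooled interval mean
  mbar <- (1 + 2 + 0 + 0) / (1 + 4 + 0 + 4)
  expect_equal(m$residuals["p1", "chr1:100-300"],
               (5 / (5 + 1)) * (3 / 5 - mbar))
})

test_that("iterative-PCA imputation satisfies its contracts", {
  # complete input is returned unchanged after one iteration
  x <- matrix(rnorm(60), 10L)
  done <- impute_iterative_pca(x, "residual", rank = 2L)
  expect_identical(done$completed, x)
  expect_equal(done$iterations, 1L)

  # rank-1 completion recovers the masked entry to < 1e-6
  u <- c(1, 2, 3, 4, 5)
  v <- c(2, -1, 0.5, 1)
  r1 <- u %*% t(v)
  masked <- r1
  masked[2L, 3L] <- NA
  imp <- impute_iterative_pca(masked, "residual", rank = 1L, tol = 1e-9,
                              max_iter = 500L)
  expect_lt(abs(imp$completed[2L, 3L] - r1[2L, 3L]), 1e-6)
  # observed entries bit-identical
  expect_identical(imp$completed[!is.na(masked)], r1[!is.na(masked)])

  # rank-3 + noise, 20% masked: masked-entry RMSE below 2x the noise SD
  set.seed(17)
  n <- 80L; p <- 30L
  signal <- matrix(rnorm(n * 3L), n) %*% matrix(rnorm(3L * p), 3L)
  noisy <- signal + matrix(rnorm(n * p, sd = 0.1), n)
  holes <- matrix(runif(n * p) < 0.2, n)
  xm <- noisy
  xm[holes] <- NA
  imp3 <- impute_iterative_pca(xm, "residual", rank = 3L, tol = 1e-6,
                               max_iter = 200L)
  rmse <- sqrt(mean((imp3$completed[holes] - noisy[holes])^2))
  expect_lt(rmse, 2 * 0.1)
  # update norm decreases monotonically
  expect_true(all(diff(imp3$deltas) <= 1e-12))

  # level matrices: initialisation at feature means, output clamped
  lv <- matrix(runif(40), 8L)
  lv[1L, 1L] <- NA
  impl <- impute_iterative_pca(lv, "level", rank = 2L)
  expect_true(all(impl$completed >= 0 & impl$completed <= 1))
  # all-missing feature dropped with report
  lv2 <- cbind(lv, NA)
  colnames(lv2) <- paste0("f", seq_len(ncol(lv2)))
  expect_equal(impute_iterative_pca(lv2, "level", rank = 2L)$dropped, "f6")
})

test_that("PMD scores pool CG methylation inside the intervals", {
  set.seed(5)
  positions <- seq(100L, 9900L, by = 200L)
  pixels <- sprintf("px%02d", 1:10)
  meth <- matrix(0.8, 10L, length(positions))
  tab <- build_call_table(meth, positions, pixels, coverage = 20L)
  pmds <- data.frame(contig = "chr1", start = 0L, end = 10000L)
  sc <- pmd_score(tab, pmds)
  expect_equal(length(sc), 10L)
  expect_lt(max(abs(sc - 0.8)), 0.1)
  # no CpG inside the PMDs -> missing
  far <- data.frame(contig = "chr1", start = 20000L, end = 30000L)
  expect_true(all(is.na(pmd_score(tab, far))))
  # two pixel groups at 0.6 vs 0.8 separate by ~0.2
  meth2 <- meth
  meth2[1:5, ] <- 0.6
  tab2 <- build_call_table(meth2, positions, pixels, coverage = 50L)
  sc2 <- pmd_score(tab2, pmds)
  expect_equal(mean(sc2[6:10]) - mean(sc2[1:5]), 0.2, tolerance = 0.05)
})

test_that("TSS profiles are strand-aware and flat for uniform methylation", {
  set.seed(6)
  positions <- seq(50L, 19950L, by = 100L)
  pixels <- sprintf("px%02d", 1:6)
  meth <- matrix(0.75, 6L, length(positions))
  tab <- build_call_table(meth, positions, pixels, coverage = 30L)
  tss <- data.frame(contig = "chr1", pos = c(5000L, 15000L), strand = "+")
  prof <- tss_profile(tab, tss, flank_bp = 2000L, n_bins = 20L)
  expect_true(all(abs(prof$level - 0.75) < 0.05, na.rm = TRUE))

  # planted unmethylated +/-500 bp around each TSS
  dip <- meth
  near <- vapply(positions, function(p) any(abs(p - tss$pos) <= 500L),
                 logical(1))
  dip[, near] <- 0.02
  tabd <- build_call_table(dip, positions, pixels, coverage = 30L)
  profd <- tss_profile(tabd, tss, flank_bp = 2000L, n_bins = 20L)
  centre <- abs(profd$mid) <= 400
  flank <- abs(profd$mid) >= 800
  expect_lt(max(profd$level[centre]), 0.15)
  expect_gt(min(profd$level[flank], na.rm = TRUE), 0.6)

  # reversing the strand mirrors the bin assignment
  asym <- meth
  asym[, positions > 5000L & positions <= 7000L] <- 0.1   # downstream of + TSS
  taba <- build_call_table(asym, positions, pixels, coverage = 30L)
  fwd <- tss_profile(taba, data.frame(contig = "chr1", pos = 5000L,
                                      strand = "+"),
                     flank_bp = 2000L, n_bins = 20L)
  rev <- tss_profile(taba, data.frame(contig = "chr1", pos = 5000L,
                                      strand = "-"),
                     flank_bp = 2000L, n_bins = 20L)
  expect_equal(fwd$level, base::rev(rev$level), tolerance = 0.1)
})
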
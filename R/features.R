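# The methylome feature space: variably methylated regions (VMRs) scored by
# the across-pixel variance of coverage-shrunken residuals, per-pixel VMR
# matrices, iterative-PCA imputation, PMD scores and TSS profiles.

#' Coverage-shrunken methylation residual
#'
#' A pixel's deviation from the window mean, attenuated toward zero at low
#' coverage: `(cov / (cov + k)) * (m - mbar)`.
#'
#' @param m observed methylation level.
#' @param mbar window mean methylation across pixels.
#' @param cov site coverage (retained + converted counts).
#' @param k shrinkage pseudo-count (> 0).
#' @return shrunken residual(s).
#' @export
shrunken_residual <- function(m, mbar, cov, k = 1) {
  if (k <= 0) stop("k must be > 0")
  if (any(cov < 0)) stop("coverage must be >= 0")
  (cov / (cov + k)) * (m - mbar)
}

# Merge the two strands of palindromic CpGs: a minus-strand CG call at
# position p is pooled with the plus-strand C at p - 1. Returns a data.frame
# of CG records keyed by (pixel, contig, pos).
.merge_cpg_strands <- function(df) {
  cg <- df[df$context == "CG", , drop = FALSE]
  if (nrow(cg) == 0L) return(cg[, c("pixel", "contig", "pos", "retained", "converted")])
  pos <- ifelse(cg$strand == "-", cg$pos - 1L, cg$pos)
  dt <- data.table::data.table(pixel = cg$pixel, contig = cg$contig,
                               pos = pos, retained = cg$retained,
                               converted = cg$converted)
  retained <- converted <- NULL
  out <- dt[, list(retained = sum(retained), converted = sum(converted)),
            by = c("pixel", "contig", "pos")]
  as.data.frame(out)
}

# window ids covering a 1-based site position, for tiling with given
# window/step (0-based half-open windows starting at multiples of step)
.windows_of_pos <- function(pos0, window_bp, step_bp, n_win) {
  lo <- floor((pos0 - window_bp) / step_bp) + 1L
  hi <- floor(pos0 / step_bp)
  list(lo = pmax(lo, 0L), hi = pmin(hi, n_win - 1L))
}

#' Scan for variably methylated regions
#'
#' Tiles each contig with sliding windows, scores every eligible window by
#' the across-pixel variance of coverage-shrunken residuals, keeps the
#' top-scoring fraction (default top 2%), and fuses overlapping or
#' book-ended selected windows into VMR intervals. A window is eligible when
#' it contains at least `min_sites` CpGs and is covered in at least
#' `min_pixels` pixels. Exactly `ceiling(top_fraction * n_eligible)` windows
#' are selected; score ties are broken by genomic order.
#'
#' CpG strands are merged before scanning (palindromic sites pooled at the
#' plus-strand C position).
#'
#' @param table a [aggregate_calls()] result (or its data.frame).
#' @param contig_lengths named vector of contig lengths; inferred from the
#'   maximum observed position when `NULL`.
#' @param window_bp,step_bp window and step size in bp (`window_bp` must be a
#'   multiple of `step_bp`).
#' @param min_sites minimum CpGs per eligible window (the knee plot of read
#'   coverage is the usual guide; see [knee_filter()]).
#' @param min_pixels minimum covered pixels per eligible window.
#' @param top_fraction fraction of eligible windows selected.
#' @param k residual shrinkage pseudo-count.
#' @return object of class `vmr_set`: data.frame of fused intervals (contig,
#'   start, end; 0-based half-open) with `score` (max member window
#'   variance), `n_cpgs`, `n_pixels`, `n_windows`; attributes `n_eligible`
#'   and `n_selected` record the pre-fusion selection.
#' @export
scan_vmrs <- function(table, contig_lengths = NULL, window_bp = 2000L,
                      step_bp = 1000L, min_sites = 5L, min_pixels = 10L,
                      top_fraction = 0.02, k = 1) {
  if (step_bp <= 0L || window_bp < step_bp) stop("need window_bp >= step_bp > 0")
  if (window_bp %% step_bp != 0L) stop("window_bp must be a multiple of step_bp")
  if (top_fraction <= 0 || top_fraction >= 1) stop("top_fraction must be in (0, 1)")
  cg <- .merge_cpg_strands(.as_call_df(table))
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(cg$pos + 1L, cg$contig, max)
  }
  per_win <- list()
  for (ct in unique(cg$contig)) {
    d <- cg[cg$contig == ct, , drop = FALSE]
    len <- contig_lengths[[ct]]
    n_win <- max(1L, as.integer(ceiling(len / step_bp)) -
                   as.integer(window_bp / step_bp) + 1L)
    rng <- .windows_of_pos(d$pos - 1L, window_bp, step_bp, n_win)
    span <- rng$hi - rng$lo + 1L
    ok <- span > 0L
    rep_i <- rep(seq_len(nrow(d))[ok], span[ok])
    win <- unlist(lapply(which(ok), function(i) rng$lo[i]:rng$hi[i]),
                  use.names = FALSE)
    per_win[[ct]] <- data.table::data.table(
      contig = ct, win = win, pixel = d$pixel[rep_i], pos = d$pos[rep_i],
      retained = d$retained[rep_i], converted = d$converted[rep_i])
  }
  long <- data.table::rbindlist(per_win)
  if (nrow(long) == 0L) {
    warning("no eligible windows")
    return(.empty_vmr_set())
  }
  retained <- converted <- pos <- NULL
  wp <- long[, list(ret = sum(retained), tot = sum(retained + converted)),
             by = c("contig", "win", "pixel")]
  wsites <- long[, list(n_cpgs = length(unique(pos))), by = c("contig", "win")]
  wstat <- wp[, list(n_pixels = .N, mret = sum(ret), mtot = sum(tot)),
              by = c("contig", "win")]
  winfo <- merge(wsites, wstat, by = c("contig", "win"))
  elig <- winfo[winfo$n_cpgs >= min_sites & winfo$n_pixels >= min_pixels, ]
  if (nrow(elig) == 0L) {
    warning("no eligible windows")
    return(.empty_vmr_set())
  }
  wp <- merge(wp, elig[, c("contig", "win", "mret", "mtot")],
              by = c("contig", "win"))
  wp$resid <- shrunken_residual(wp$ret / wp$tot, wp$mret / wp$mtot, wp$tot, k)
  resid <- NULL
  score <- wp[, list(score = stats::var(resid)), by = c("contig", "win")]
  score <- merge(elig, score, by = c("contig", "win"))
  score$score[is.na(score$score)] <- 0
  score$start <- score$win * step_bp
  n_eligible <- nrow(score)
  n_selected <- as.integer(ceiling(top_fraction * n_eligible))
  data.table::setorderv(score, c("score", "contig", "start"),
                        order = c(-1L, 1L, 1L))
  sel <- score[seq_len(n_selected), ]
  sel$end <- pmin(sel$start + window_bp,
                  as.numeric(contig_lengths[sel$contig]))

  fused <- .fuse_intervals(as.data.frame(sel[, c("contig", "start", "end", "score")]))
  # annotate fused intervals with CpG and pixel support
  fused$n_cpgs <- 0L
  fused$n_pixels <- 0L
  fused$n_windows <- 0L
  for (i in seq_len(nrow(fused))) {
    hit <- cg$contig == fused$contig[i] & cg$pos > fused$start[i] &
      cg$pos <= fused$end[i]
    fused$n_cpgs[i] <- length(unique(cg$pos[hit]))
    fused$n_pixels[i] <- length(unique(cg$pixel[hit]))
    fused$n_windows[i] <- sum(sel$contig == fused$contig[i] &
                                sel$start < fused$end[i] &
                                sel$end > fused$start[i])
  }
  structure(fused, class = c("vmr_set", "data.frame"),
            n_eligible = n_eligible, n_selected = n_selected,
            window_bp = window_bp, step_bp = step_bp)
}

.empty_vmr_set <- function() {
  structure(data.frame(contig = character(0), start = integer(0),
                       end = integer(0), score = numeric(0),
                       n_cpgs = integer(0), n_pixels = integer(0),
                       n_windows = integer(0)),
            class = c("vmr_set", "data.frame"), n_eligible = 0L,
            n_selected = 0L)
}

# fuse overlapping or book-ended 0-based half-open intervals; score of a
# fused interval is the max of its members
.fuse_intervals <- function(df) {
  if (nrow(df) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), score = numeric(0)))
  }
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start + 1L, df$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  ov <- GenomicRanges::findOverlaps(red, gr)
  sc <- tapply(df$score[S4Vectors::subjectHits(ov)],
               S4Vectors::queryHits(ov), max)
  out <- data.frame(contig = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red),
                    score = as.numeric(sc),
                    stringsAsFactors = FALSE)
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Fuse a VMR set (idempotent)
#'
#' Fuses overlapping or book-ended intervals of a [scan_vmrs()] result;
#' applying it to an already fused set is a no-op.
#' @param vmrs a `vmr_set` or data.frame with contig/start/end/score.
#' @return fused `vmr_set`-like data.frame.
#' @export
fuse_vmrs <- function(vmrs) {
  .fuse_intervals(as.data.frame(vmrs)[, c("contig", "start", "end", "score")])
}

#' @export
print.vmr_set <- function(x, ...) {
  cat(sprintf("vmr_set: %d fused intervals from %d/%d selected/eligible windows\n",
              nrow(x), attr(x, "n_selected"), attr(x, "n_eligible")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Per-pixel VMR methylation and residual matrices
#'
#' For every (pixel, VMR) pair pools retained/converted counts over the CpGs
#' inside the interval: the level is `retained / (retained + converted)`,
#' missing (`NA`) where the pixel has no coverage; the residual is the
#' coverage-shrunken deviation from the VMR's pooled mean.
#'
#' @param table a [aggregate_calls()] result.
#' @param vmrs a [scan_vmrs()] result (or data.frame contig/start/end).
#' @param k residual shrinkage pseudo-count.
#' @param pixels optional pixel universe (row order of the output).
#' @return list with `levels` and `residuals`: pixels x VMRs matrices (VMR
#'   columns named `contig:start-end`), plus `coverage` (pooled counts).
#' @export
vmr_matrix <- function(table, vmrs, k = 1, pixels = NULL) {
  vdf <- as.data.frame(vmrs)
  if (nrow(vdf) == 0L) stop("empty VMR set")
  cg <- .merge_cpg_strands(.as_call_df(table))
  if (is.null(pixels)) pixels <- sort(unique(cg$pixel))
  vname <- sprintf("%s:%d-%d", vdf$contig, vdf$start, vdf$end)
  gr_s <- GenomicRanges::GRanges(cg$contig, IRanges::IRanges(cg$pos, cg$pos))
  gr_v <- GenomicRanges::GRanges(vdf$contig,
                                 IRanges::IRanges(vdf$start + 1L, vdf$end))
  ov <- GenomicRanges::findOverlaps(gr_s, gr_v)
  lev <- resid <- covm <- matrix(NA_real_, length(pixels), nrow(vdf),
                                 dimnames = list(pixels, vname))
  if (length(ov)) {
    d <- data.table::data.table(
      pixel = cg$pixel[S4Vectors::queryHits(ov)],
      vmr = S4Vectors::subjectHits(ov),
      retained = cg$retained[S4Vectors::queryHits(ov)],
      converted = cg$converted[S4Vectors::queryHits(ov)])
    retained <- converted <- NULL
    agg <- d[, list(ret = sum(retained), tot = sum(retained + converted)),
             by = c("pixel", "vmr")]
    mbar <- d[, list(mret = sum(retained), mtot = sum(retained + converted)),
              by = "vmr"]
    agg <- merge(agg, mbar, by = "vmr")
    idx <- cbind(match(agg$pixel, pixels), agg$vmr)
    keep <- !is.na(idx[, 1L])
    agg <- agg[keep]; idx <- idx[keep, , drop = FALSE]
    lev[idx] <- agg$ret / agg$tot
    covm[idx] <- agg$tot
    resid[idx] <- shrunken_residual(agg$ret / agg$tot, agg$mret / agg$mtot,
                                    agg$tot, k)
  }
  list(levels = lev, residuals = resid, coverage = covm)
}

#' Iterative-PCA imputation of a sparse matrix
#'
#' Missing residual values start at zero and missing methylation levels at
#' the per-feature observed mean; a rank-`rank` truncated SVD reconstruction
#' then repeatedly replaces only the missing entries until the largest update
#' falls below `tol`. Observed entries are never altered; imputed levels are
#' clamped to `[0, 1]`. Features with no observed value are dropped and
#' reported.
#'
#' @param x numeric matrix (pixels x features) with `NA` for missing.
#' @param kind `"residual"` or `"level"` (controls initialisation and
#'   clamping).
#' @param rank truncated SVD rank (< min(dim)).
#' @param tol convergence tolerance on the largest absolute update.
#' @param max_iter iteration cap.
#' @return list with `completed` (matrix), `iterations`, `deltas` (update
#'   norms per iteration), `dropped` (names of all-missing features).
#' @export
impute_iterative_pca <- function(x, kind = c("residual", "level"), rank = 10L,
                                 tol = 1e-4, max_iter = 100L) {
  kind <- match.arg(kind)
  if (tol <= 0) stop("tol must be > 0")
  x <- as.matrix(x)
  all_miss <- colSums(!is.na(x)) == 0L
  dropped <- colnames(x)[all_miss]
  if (any(all_miss)) x <- x[, !all_miss, drop = FALSE]
  if (rank >= min(dim(x))) stop("rank must be < min(dim(x))")
  miss <- is.na(x)
  if (!any(miss)) {
    return(list(completed = x, iterations = 1L, deltas = 0, dropped = dropped))
  }
  cur <- x
  if (kind == "residual") {
    cur[miss] <- 0
  } else {
    mu <- colMeans(x, na.rm = TRUE)
    cur[miss] <- mu[col(x)[miss]]
  }
  deltas <- numeric(0)
  for (it in seq_len(max_iter)) {
    s <- svd(cur, nu = rank, nv = rank)
    recon <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
    newv <- recon[miss]
    if (kind == "level") newv <- .clamp01(newv)
    delta <- max(abs(newv - cur[miss]))
    cur[miss] <- newv
    deltas <- c(deltas, delta)
    if (delta < tol) break
  }
  list(completed = cur, iterations = length(deltas), deltas = deltas,
       dropped = dropped)
}

#' Per-pixel methylation score over partially methylated domains
#'
#' Pools CG methylation over every CpG falling inside the supplied PMD
#' intervals — a proxy for the pixel's mitotic history (PMDs lose methylation
#' with successive cell divisions). Missing where a pixel has no PMD
#' coverage.
#'
#' @param table a [aggregate_calls()] result.
#' @param pmds data.frame of intervals (contig, start, end; 0-based
#'   half-open), e.g. from [read_bed()].
#' @return named numeric vector: mean CG methylation level per pixel in
#'   `[0, 1]`.
#' @export
pmd_score <- function(table, pmds) {
  cg <- .merge_cpg_strands(.as_call_df(table))
  gr_s <- GenomicRanges::GRanges(cg$contig, IRanges::IRanges(cg$pos, cg$pos))
  gr_p <- GenomicRanges::GRanges(pmds$contig,
                                 IRanges::IRanges(pmds$start + 1L, pmds$end))
  hit <- IRanges::overlapsAny(gr_s, gr_p)
  pixels <- sort(unique(cg$pixel))
  out <- setNames(rep(NA_real_, length(pixels)), pixels)
  if (any(hit)) {
    d <- data.table::data.table(pixel = cg$pixel[hit],
                                retained = cg$retained[hit],
                                converted = cg$converted[hit])
    retained <- converted <- NULL
    a <- d[, list(level = sum(retained) / sum(retained + converted)),
           by = "pixel"]
    out[a$pixel] <- a$level
  }
  out
}

#' Average methylation profile around transcription start sites
#'
#' Assigns CpGs to bins by signed, strand-aware distance to the nearest-given
#' TSS (upstream negative) and pools retained/converted counts per bin across
#' all pixels. A CpG within `flank_bp` of several TSSs contributes to each.
#'
#' @param table a [aggregate_calls()] result.
#' @param tss data.frame with columns `contig`, `pos` (1-based TSS position)
#'   and `strand`.
#' @param flank_bp half-width of the profiled window.
#' @param n_bins number of equal-width bins spanning `[-flank_bp, flank_bp]`.
#' @return data.frame with `bin`, `mid` (bp, bin midpoint), `level` (pooled
#'   methylation), `n_sites`.
#' @export
tss_profile <- function(table, tss, flank_bp = 2000L, n_bins = 40L) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  cg <- .merge_cpg_strands(.as_call_df(table))
  gr_s <- GenomicRanges::GRanges(cg$contig, IRanges::IRanges(cg$pos, cg$pos))
  gr_t <- GenomicRanges::GRanges(tss$contig,
                                 IRanges::IRanges(tss$pos - flank_bp,
                                                  tss$pos + flank_bp))
  ov <- GenomicRanges::findOverlaps(gr_s, gr_t)
  si <- S4Vectors::queryHits(ov)
  ti <- S4Vectors::subjectHits(ov)
  d <- (cg$pos[si] - tss$pos[ti]) * ifelse(tss$strand[ti] == "-", -1, 1)
  breaks <- seq(-flank_bp, flank_bp, length.out = n_bins + 1L)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  dt <- data.table::data.table(bin = bin, retained = cg$retained[si],
                               converted = cg$converted[si], pos = cg$pos[si])
  retained <- converted <- pos <- NULL
  agg <- dt[, list(level = sum(retained) / sum(retained + converted),
                   n_sites = length(unique(pos))), by = "bin"]
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  out <- data.frame(bin = seq_len(n_bins), mid = mids, level = NA_real_,
                    n_sites = 0L)
  out$level[agg$bin] <- agg$level
  out$n_sites[agg$bin] <- agg$n_sites
  out
}
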
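# Downstream inference: differential features between pixel groups, VMR-gene
# pairing with methylation-expression correlation, and CpG-set fold
# enrichment.

#' Differential features between pixel groups
#'
#' Two-sided Wilcoxon rank-sum test per feature between two pixel groups
#' (exact for small samples without ties, normal approximation with tie
#' correction otherwise), with multiple-testing adjustment across features.
#' With more than two label levels and no explicit pair, every group is
#' tested one-vs-rest. Features with fewer than two observed values in either
#' group are skipped and flagged.
#'
#' @param x pixels x features numeric matrix (`NA` = missing).
#' @param labels group label per pixel (row).
#' @param group_a,group_b labels of the two groups to compare; `group_b =
#'   NULL` means all other pixels.
#' @param adjust `"BH"` (Benjamini-Hochberg) or `"bonferroni"`.
#' @param pseudo pseudo-count for the log2 fold change; defaults to 0.01 for
#'   matrices bounded by 1 (methylation levels) and 1 otherwise (normalised
#'   expression).
#' @return data.frame per (comparison, feature): `group`, `feature`,
#'   `mean_a`, `mean_b`, `lfc` (log2), `statistic`, `p`, `p_adj`,
#'   `direction` (`up`/`down` in group A), `tested`.
#' @export
diff_features <- function(x, labels, group_a = NULL, group_b = NULL,
                          adjust = c("BH", "bonferroni"), pseudo = NULL) {
  adjust <- match.arg(adjust)
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  lev <- unique(labels)
  if (length(lev) < 2L) stop("need at least 2 groups")
  if (is.null(pseudo)) {
    pseudo <- if (max(x, na.rm = TRUE) <= 1) 0.01 else 1
  }
  comparisons <- if (!is.null(group_a)) {
    list(list(a = group_a, b = group_b))
  } else if (length(lev) == 2L) {
    list(list(a = lev[1L], b = lev[2L]))
  } else {
    lapply(lev, function(g) list(a = g, b = NULL))
  }
  out <- list()
  for (cmp in comparisons) {
    in_a <- labels == cmp$a
    in_b <- if (is.null(cmp$b)) !in_a else labels == cmp$b
    res <- lapply(seq_len(ncol(x)), function(j) {
      va <- x[in_a, j]; va <- va[!is.na(va)]
      vb <- x[in_b, j]; vb <- vb[!is.na(vb)]
      if (length(va) < 2L || length(vb) < 2L) {
        return(data.frame(mean_a = NA_real_, mean_b = NA_real_,
                          lfc = NA_real_, statistic = NA_real_, p = NA_real_,
                          tested = FALSE))
      }
      wt <- suppressWarnings(wilcox.test(va, vb, alternative = "two.sided"))
      data.frame(mean_a = mean(va), mean_b = mean(vb),
                 lfc = log2((mean(va) + pseudo) / (mean(vb) + pseudo)),
                 statistic = unname(wt$statistic), p = wt$p.value,
                 tested = TRUE)
    })
    res <- do.call(rbind, res)
    res <- cbind(data.frame(group = cmp$a,
                            feature = colnames(x) %||% as.character(seq_len(ncol(x))),
                            stringsAsFactors = FALSE),
                 res)
    res$p_adj <- NA_real_
    res$p_adj[res$tested] <- p.adjust(res$p[res$tested], method = adjust)
    res$direction <- ifelse(res$lfc >= 0, "up", "down")
    out[[length(out) + 1L]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pair VMRs with overlapping genes
#'
#' A (VMR, gene) pair is formed when the VMR interval intersects the gene
#' body extended by `flank_bp` (on both sides, or upstream only when
#' `upstream_only = TRUE`, strand-aware). One VMR may pair with several
#' genes.
#'
#' @param vmrs data.frame/`vmr_set` with `contig`, `start`, `end` (0-based
#'   half-open).
#' @param genes data.frame with `contig`, `start`, `end` (0-based half-open),
#'   `strand`, and a `name` column.
#' @param flank_bp extension in bp.
#' @param upstream_only apply the flank upstream of the TSS only.
#' @return data.frame with `vmr` (`contig:start-end`), `gene`, and the
#'   interval coordinates.
#' @export
pair_vmr_gene <- function(vmrs, genes, flank_bp = 0L, upstream_only = FALSE) {
  vdf <- as.data.frame(vmrs)
  g <- as.data.frame(genes)
  if (!"name" %in% names(g)) g$name <- sprintf("gene%d", seq_len(nrow(g)))
  up <- flank_bp
  dn <- if (upstream_only) 0L else flank_bp
  minus <- !is.null(g$strand) & g$strand == "-"
  ext_start <- ifelse(minus, g$start - dn, g$start - up)
  ext_end <- ifelse(minus, g$end + up, g$end + dn)
  gr_g <- GenomicRanges::GRanges(g$contig,
                                 IRanges::IRanges(pmax(ext_start, 0) + 1L,
                                                  pmax(ext_end, 1)))
  gr_v <- GenomicRanges::GRanges(vdf$contig,
                                 IRanges::IRanges(vdf$start + 1L, vdf$end))
  ov <- GenomicRanges::findOverlaps(gr_v, gr_g)
  vi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  data.frame(vmr = sprintf("%s:%d-%d", vdf$contig[vi], vdf$start[vi],
                           vdf$end[vi]),
             gene = g$name[gi],
             vmr_start = vdf$start[vi], vmr_end = vdf$end[vi],
             gene_start = g$start[gi], gene_end = g$end[gi],
             stringsAsFactors = FALSE)
}

#' Methylation-expression correlation over VMR-gene pairs
#'
#' Pearson correlation between a VMR's methylation level and its paired
#' gene's normalised expression across pixels observed in both modalities,
#' with two-sided p from the t transform and Benjamini-Hochberg adjustment
#' across pairs. Negative correlations indicate the repressive direction
#' (higher methylation, lower expression).
#'
#' @param pairs data.frame from [pair_vmr_gene()] (columns `vmr`, `gene`).
#' @param meth pixels x VMRs methylation-level matrix (`NA` = missing);
#'   columns named like `pairs$vmr`.
#' @param expr pixels x genes normalised expression matrix; columns named
#'   like `pairs$gene`.
#' @param min_pixels minimum jointly observed pixels per pair.
#' @return data.frame per pair: `vmr`, `gene`, `n`, `r`, `p`, `q` (BH),
#'   `tested` plus a `note` for skipped pairs.
#' @export
corr_meth_expr <- function(pairs, meth, expr, min_pixels = 3L) {
  common <- intersect(rownames(meth), rownames(expr))
  if (length(common) < min_pixels) stop("fewer than min_pixels shared pixels")
  m <- meth[common, , drop = FALSE]
  e <- expr[common, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    v <- pairs$vmr[i]; gn <- pairs$gene[i]
    if (!v %in% colnames(m) || !gn %in% colnames(e)) {
      return(data.frame(n = 0L, r = NA_real_, p = NA_real_, tested = FALSE,
                        note = "feature absent"))
    }
    mv <- m[, v]; ev <- e[, gn]
    ok <- !is.na(mv) & !is.na(ev)
    if (sum(ok) < min_pixels) {
      return(data.frame(n = sum(ok), r = NA_real_, p = NA_real_,
                        tested = FALSE, note = "too few pixels"))
    }
    if (sd(mv[ok]) == 0 || sd(ev[ok]) == 0) {
      return(data.frame(n = sum(ok), r = NA_real_, p = NA_real_,
                        tested = FALSE, note = "zero variance"))
    }
    ct <- cor.test(mv[ok], ev[ok], method = "pearson")
    data.frame(n = sum(ok), r = unname(ct$estimate), p = ct$p.value,
               tested = TRUE, note = "")
  })
  out <- cbind(pairs[, c("vmr", "gene")], do.call(rbind, res))
  out$q <- NA_real_
  out$q[out$tested] <- p.adjust(out$p[out$tested], method = "BH")
  rownames(out) <- NULL
  out
}

#' CpG-set fold enrichment
#'
#' Fold enrichment of a query CpG set in an annotation feature:
#' `FE = O / E` with observed overlap `O = |query intersect feature|` and
#' expected `E = |query| * |feature| / N` for a universe of `N` CpGs, with a
#' one-sided (greater) Fisher exact p-value from the 2x2 table. With several
#' features, a BH FDR is added across features.
#'
#' @param query character/integer vector of query CpG identifiers.
#' @param features one feature set (vector) or a named list of feature sets.
#' @param universe_n total number of CpGs in the universe.
#' @return data.frame per feature: `feature`, `observed`, `expected`,
#'   `fold_enrichment`, `p`, `fdr`.
#' @export
fold_enrichment <- function(query, features, universe_n) {
  if (universe_n <= 0) stop("universe_n must be > 0")
  if (!is.list(features)) features <- list(feature = features)
  if (is.null(names(features))) {
    names(features) <- sprintf("feature%d", seq_along(features))
  }
  query <- unique(query)
  nq <- length(query)
  res <- lapply(names(features), function(fn) {
    fs <- unique(features[[fn]])
    nf <- length(fs)
    if (nq == 0L || nf == 0L) {
      return(data.frame(feature = fn, observed = NA_integer_,
                        expected = NA_real_, fold_enrichment = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    if (nq > universe_n || nf > universe_n) {
      stop("query/feature larger than the universe")
    }
    o <- length(intersect(query, fs))
    e <- nq * nf / universe_n
    tab <- matrix(c(o, nq - o, nf - o, universe_n - nq - nf + o), 2L, 2L)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.frame(feature = fn, observed = o, expected = e,
               fold_enrichment = o / e, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- p.adjust(out$p[ok], method = "BH")
  rownames(out) <- NULL
  out
}
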
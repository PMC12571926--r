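# Shared fixtures and independent oracles, all built in code.

# small single-contig configuration for fast unit tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    grid_rows = 5L, grid_cols = 5L, n_regions = 2L,
    genome = data.frame(contig = c("chr1", "chrM"),
                        length = c(20000L, 4000L),
                        mito = c(FALSE, TRUE), stringsAsFactors = FALSE),
    n_vmrs_per_region = 2L, reads_per_pixel_dna = 40L,
    reads_per_pixel_rna = 30L, n_genes = 20L, n_markers_per_region = 2L,
    dup_fraction = 0, seed = 42L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# the four-region joint-recovery conditions (K = 4, methylation delta 0.4,
# marker fold change 4) at desk scale: 196 pixels, deep per-pixel coverage
recovery_config <- function(seed) {
  sim_config(grid_rows = 14L, grid_cols = 14L, n_regions = 4L,
             genome = data.frame(contig = "chr1", length = 60000L,
                                 mito = FALSE, stringsAsFactors = FALSE),
             n_vmrs_per_region = 3L, vmr_delta = -0.4,
             reads_per_pixel_dna = 500L, reads_per_pixel_rna = 200L,
             n_genes = 60L, n_markers_per_region = 5L, marker_fc = 4,
             dup_fraction = 0, seed = seed)
}

# full joint pipeline: simulate -> call table -> VMR residuals -> impute ->
# PCA both modalities -> WNN -> Leiden; returns ARI against true regions
run_joint_recovery <- function(seed) {
  cfg <- recovery_config(seed)
  tr <- make_truth(cfg)
  rd <- emit_reads(tr)
  mc <- aggregate_calls(rd$calls, dedup = TRUE)
  vm <- scan_vmrs(mc, contig_lengths = c(chr1 = 60000), min_pixels = 20L,
                  top_fraction = 0.25)
  mats <- vmr_matrix(mc, vm)
  imp <- impute_iterative_pca(mats$residuals, "residual", rank = 5L,
                              max_iter = 50L)
  emb_m <- embed_pca(imp$completed, n_components = 8L, modality = "meth")
  pr <- rd$provenance[rd$provenance$library == "rna", ]
  recs <- data.frame(read_id = pr$read_id, pixel = pr$pixel, umi = pr$umi,
                     status = "assigned", stringsAsFactors = FALSE)
  cnt <- count_rna(recs, data.frame(read_id = pr$read_id, gene = pr$gene,
                                    stringsAsFactors = FALSE))
  emb_r <- embed_pca(t(as.matrix(normalize_rna(cnt))), n_components = 10L,
                     modality = "rna")
  common <- intersect(rownames(emb_r$scores), rownames(emb_m$scores))
  emb_r$scores <- emb_r$scores[common, , drop = FALSE]
  emb_m$scores <- emb_m$scores[common, , drop = FALSE]
  wg <- wnn_fuse(emb_r, emb_m, k = 15L)
  cl <- cluster_graph(wg, resolution = 0.8, seed = seed)
  truthlab <- tr$pixels$region[match(common, tr$pixels$pixel)]
  list(ari = adjusted_rand_index(cl, truthlab), n_clusters = nlevels(cl),
       weights = wg$weights)
}

# construct a call table directly: one CpG every `spacing` bp, binomial
# counts at the given per-(pixel, site) methylation matrix
build_call_table <- function(meth, positions, pixels, coverage = 4L,
                             contig = "chr1") {
  stopifnot(nrow(meth) == length(pixels), ncol(meth) == length(positions))
  cov <- matrix(rpois(length(meth), coverage), nrow(meth))
  ret <- matrix(rbinom(length(meth), as.vector(cov), as.vector(meth)),
                nrow(meth))
  keep <- which(cov > 0, arr.ind = TRUE)
  tab <- data.frame(
    pixel = pixels[keep[, 1L]], contig = contig,
    pos = positions[keep[, 2L]], strand = "+", context = "CG",
    retained = ret[keep], converted = cov[keep] - ret[keep],
    stringsAsFactors = FALSE)
  structure(list(table = tab, duplication_rate = 0, n_rejected = 0L),
            class = "meth_call_table")
}

# ---- independent brute-force oracles ----

oracle_hamming <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  sum(x != y)
}

# exhaustive nearest-neighbour barcode scan
oracle_match <- function(observed, wl, max_hamming, collapsed = FALSE) {
  seqs <- if (collapsed) chartr("C", "T", wl$sequence) else wl$sequence
  obs <- if (collapsed) chartr("C", "T", observed) else observed
  t(vapply(obs, function(o) {
    d <- vapply(seqs, oracle_hamming, numeric(1), a = o)
    dmin <- min(d)
    if (dmin > max_hamming) return(c(NA_real_, NA_real_))      # no_match
    if (sum(d == dmin) > 1L) return(c(-1, dmin))               # ambiguous
    c(wl$index[which.min(d)], dmin)
  }, numeric(2)))
}

# longest homopolymer run of a base
oracle_max_run <- function(seq, base) {
  r <- rle(strsplit(seq, "")[[1]])
  runs <- r$lengths[r$values == base]
  if (length(runs)) max(runs) else 0L
}
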
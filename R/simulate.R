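# Synthetic spatial methylome + transcriptome datasets with ground truth.
#
# The generator emulates a K-region tissue on a combinatorial barcode grid:
# region-specific CG methylation around a ~75% baseline, near-zero CH
# methylation, fully unmethylated mitochondrial DNA, negative-binomial RNA
# counts with region marker genes, per-cytosine deamination at ~0.995,
# methylation-free linkers inside every DNA read, and barcode/sequencing
# errors.

.LINKER1 <- "CATCAGTCATCGACT"  # 15 nt, 5 cytosines, methylation-free
.LINKER2 <- "GACTGACTTCCATCC"  # 15 nt, 5 cytosines, methylation-free
.SPIKE_SEQ <- "CTACTACCATTCAGCTACGATCCATGCATTCACCTAGCAT"  # 40 nt spike-in

#' Simulation configuration
#'
#' Bundles all parameters of the synthetic spatial dataset. Defaults encode
#' the study conditions the package is designed around: a 50 x 50 barcode
#' grid (2,500 pixels), baseline CG methylation 0.75, zero CH methylation,
#' per-cytosine conversion probability 0.995, and a small two-contig genome
#' (one nuclear contig plus an unmethylated mitochondrial contig).
#'
#' @param grid_rows,grid_cols barcode grid dimensions (barcode A indexes rows,
#'   barcode B columns).
#' @param n_regions number of spatially contiguous tissue regions (Voronoi
#'   partition of the grid).
#' @param genome data.frame with columns `contig`, `length`, `mito`.
#' @param cpg_density planted CpG sites per kb of reference.
#' @param baseline_mcg baseline CG methylation fraction.
#' @param mch_level CH (non-CpG) methylation fraction.
#' @param n_vmrs_per_region number of truly variably methylated intervals per
#'   region.
#' @param vmr_delta methylation offset applied inside a region's VMRs; the
#'   truth is `clamp01(baseline_mcg + vmr_delta)`.
#' @param vmr_len length (bp) of each planted VMR interval.
#' @param conversion_prob per-cytosine deamination probability for
#'   unmethylated C.
#' @param seq_error per-base sequencing substitution probability (applied to
#'   linker and insert bases).
#' @param barcode_error per-barcode substitution probability (one random base
#'   substituted within the barcode).
#' @param reads_per_pixel_dna,reads_per_pixel_rna sequencing depth per pixel.
#' @param insert_len genomic insert length (bp) of each read.
#' @param n_genes number of genes in the RNA library.
#' @param nb_mean,nb_dispersion negative-binomial mean and size for molecule
#'   counts per (pixel, gene).
#' @param n_markers_per_region genes upregulated per region.
#' @param marker_fc fold change of marker genes in their region.
#' @param n_spikein number of additional methylation-free spike-in DNA reads.
#' @param dup_fraction fraction of DNA reads that are verbatim PCR duplicates
#'   (duplicates are re-emitted copies; the total DNA read count stays
#'   `grid_rows * grid_cols * reads_per_pixel_dna`).
#' @param seed integer RNG seed; all outputs are deterministic given the
#'   configuration.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(grid_rows = 50L, grid_cols = 50L, n_regions = 4L,
                       genome = data.frame(
                         contig = c("chr1", "chrM"),
                         length = c(200000L, 16000L),
                         mito = c(FALSE, TRUE),
                         stringsAsFactors = FALSE),
                       cpg_density = 10, baseline_mcg = 0.75, mch_level = 0,
                       n_vmrs_per_region = 10L, vmr_delta = -0.5,
                       vmr_len = 2000L, conversion_prob = 0.995,
                       seq_error = 0.001, barcode_error = 0.005,
                       reads_per_pixel_dna = 50L, reads_per_pixel_rna = 50L,
                       insert_len = 40L, n_genes = 100L, nb_mean = 2,
                       nb_dispersion = 2, n_markers_per_region = 5L,
                       marker_fc = 4, n_spikein = 0L, dup_fraction = 0.3,
                       seed = 1L) {
  cfg <- list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
              n_regions = as.integer(n_regions), genome = genome,
              cpg_density = cpg_density, baseline_mcg = baseline_mcg,
              mch_level = mch_level, n_vmrs_per_region = as.integer(n_vmrs_per_region),
              vmr_delta = vmr_delta, vmr_len = as.integer(vmr_len),
              conversion_prob = conversion_prob, seq_error = seq_error,
              barcode_error = barcode_error,
              reads_per_pixel_dna = as.integer(reads_per_pixel_dna),
              reads_per_pixel_rna = as.integer(reads_per_pixel_rna),
              insert_len = as.integer(insert_len), n_genes = as.integer(n_genes),
              nb_mean = nb_mean, nb_dispersion = nb_dispersion,
              n_markers_per_region = as.integer(n_markers_per_region),
              marker_fc = marker_fc, n_spikein = as.integer(n_spikein),
              dup_fraction = dup_fraction, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$grid_rows >= 1L, cfg$grid_cols >= 1L, cfg$n_regions >= 1L)
  for (p in c("baseline_mcg", "mch_level", "conversion_prob", "seq_error",
              "barcode_error", "dup_fraction")) {
    if (!.is_prob(cfg[[p]])) stop(p, " must be a probability in [0, 1]")
  }
  if (cfg$vmr_delta < -1 || cfg$vmr_delta > 1) stop("vmr_delta must be in [-1, 1]")
  g <- cfg$genome
  if (!all(c("contig", "length", "mito") %in% names(g)) || nrow(g) == 0L) {
    stop("genome must be a data.frame with columns contig, length, mito")
  }
  if (anyDuplicated(g$contig)) stop("duplicate contig names")
  if (any(g$length < cfg$insert_len)) stop("contigs must be at least insert_len long")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields override [sim_config()] defaults; a `genome` entry may be a
#' list of `{contig, length, mito}` records.
#' @param path YAML file.
#' @return `sim_config`
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$genome)) {
    y$genome <- do.call(rbind, lapply(y$genome, function(r) {
      data.frame(contig = r$contig, length = as.integer(r$length),
                 mito = isTRUE(r$mito), stringsAsFactors = FALSE)
    }))
  }
  do.call(sim_config, y)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d x %d grid (%d pixels), %d regions, seed %d\n",
              x$grid_rows, x$grid_cols, x$grid_rows * x$grid_cols,
              x$n_regions, x$seed))
  cat(sprintf("  mCG %.3g, mCH %.3g, conversion %.4g, %d VMRs/region (delta %+.2f)\n",
              x$baseline_mcg, x$mch_level, x$conversion_prob,
              x$n_vmrs_per_region, x$vmr_delta))
  invisible(x)
}

# Reference sequence with a controlled CpG density: background drawn over
# {A,C,G,T} with CG dinucleotides removed, then CpGs planted at the requested
# density. Background cytosines supply CH contexts.
.make_reference <- function(len, cpg_per_kb) {
  s <- sample(.BASES, len, replace = TRUE)
  cg <- which(s[-len] == "C" & s[-1L] == "G")
  if (length(cg)) s[cg + 1L] <- "A"
  n_cpg <- round(len / 1000 * cpg_per_kb)
  if (n_cpg > 0L) {
    cand <- seq(2L, len - 2L, by = 2L)
    pos <- sort(sample(cand, min(n_cpg, length(cand))))
    s[pos] <- "C"
    s[pos + 1L] <- "G"
  }
  paste(s, collapse = "")
}

# Enumerate every cytosine on both strands with its dinucleotide context.
# Positions are 1-based coordinates on the plus strand; a minus-strand C sits
# at the position of its complementary G. Sites whose 3' neighbour falls off
# the contig are skipped.
.enumerate_sites <- function(ref, contig) {
  s <- strsplit(ref, "", fixed = TRUE)[[1L]]
  len <- length(s)
  cp <- which(s == "C")
  cp <- cp[cp < len]
  ctx_p <- paste0("C", s[cp + 1L])
  gp <- which(s == "G")
  gp <- gp[gp > 1L]
  ctx_m <- paste0("C", .complement(s[gp - 1L]))
  d <- data.frame(
    contig = contig,
    pos = c(cp, gp),
    strand = rep(c("+", "-"), c(length(cp), length(gp))),
    context = c(ctx_p, ctx_m),
    stringsAsFactors = FALSE)
  d <- d[d$context %in% c("CG", "CA", "CC", "CT"), , drop = FALSE]
  d[order(d$pos, d$strand), , drop = FALSE]
}

# Voronoi partition of the grid into K contiguous regions; redraw centroids
# until every region owns at least one pixel.
.voronoi_regions <- function(rows, cols, k) {
  cells <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  for (try in 1:100) {
    cx <- runif(k, 0.5, rows + 0.5)
    cy <- runif(k, 0.5, cols + 0.5)
    d2 <- outer(cells$row, cx, "-")^2 + outer(cells$col, cy, "-")^2
    lab <- max.col(-d2, ties.method = "first")
    if (length(unique(lab)) == k) return(lab)
  }
  stop("could not place ", k, " non-empty regions on the grid")
}

#' Generate simulation ground truth
#'
#' Builds the reference genome, cytosine site table, spatial region labels
#' (a Voronoi partition of the grid), planted VMR intervals with
#' region-specific CG methylation, and per-region gene expression means.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `sdmt_truth`: list with elements `config`,
#'   `reference` (named character vector of contig sequences), `sites`
#'   (data.frame contig/pos/strand/context), `meth` (sites x regions matrix of
#'   true methylation fractions), `vmrs` (data.frame region/contig/start/end,
#'   0-based half-open), `pixels` (data.frame pixel/a/b/row/col/region),
#'   `gene_means` (regions x genes), `gene_seqs`.
#' @export
make_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cells <- config$grid_rows * config$grid_cols
  if (config$n_regions > cells) {
    stop("n_regions exceeds the number of grid pixels")
  }
  set.seed(config$seed)
  g <- config$genome

  reference <- setNames(
    vapply(g$length, .make_reference, character(1), cpg_per_kb = config$cpg_density),
    g$contig)
  sites <- do.call(rbind, lapply(g$contig, function(ct)
    .enumerate_sites(reference[[ct]], ct)))
  rownames(sites) <- NULL

  # planted VMR intervals on nuclear contigs, non-overlapping by construction
  nuc <- g[!g$mito, , drop = FALSE]
  cand <- do.call(rbind, lapply(seq_len(nrow(nuc)), function(i) {
    starts <- seq(0L, nuc$length[i] - config$vmr_len, by = 2L * config$vmr_len)
    data.frame(contig = nuc$contig[i], start = starts,
               end = starts + config$vmr_len, stringsAsFactors = FALSE)
  }))
  need <- config$n_regions * config$n_vmrs_per_region
  if (need > nrow(cand)) {
    stop("genome too small for ", need, " non-overlapping VMR intervals")
  }
  pick <- cand[sample.int(nrow(cand), need), , drop = FALSE]
  vmrs <- data.frame(region = rep(seq_len(config$n_regions),
                                  each = config$n_vmrs_per_region),
                     pick, row.names = NULL, stringsAsFactors = FALSE)

  # true methylation per (site, region)
  mito_contigs <- g$contig[g$mito]
  base <- ifelse(sites$contig %in% mito_contigs, 0,
                 ifelse(sites$context == "CG", config$baseline_mcg,
                        config$mch_level))
  meth <- matrix(base, nrow = nrow(sites), ncol = config$n_regions)
  vmr_level <- .clamp01(config$baseline_mcg + config$vmr_delta)
  for (r in seq_len(config$n_regions)) {
    vr <- vmrs[vmrs$region == r, , drop = FALSE]
    for (j in seq_len(nrow(vr))) {
      hit <- sites$contig == vr$contig[j] & sites$context == "CG" &
        sites$pos > vr$start[j] & sites$pos <= vr$end[j]
      meth[hit, r] <- vmr_level
    }
  }

  region <- .voronoi_regions(config$grid_rows, config$grid_cols,
                             config$n_regions)
  cells_df <- expand.grid(a = seq_len(config$grid_rows),
                          b = seq_len(config$grid_cols))
  pixels <- data.frame(pixel = .pixel_id(cells_df$a, cells_df$b),
                       a = cells_df$a, b = cells_df$b,
                       row = cells_df$a, col = cells_df$b,
                       region = region, stringsAsFactors = FALSE)

  gene_means <- matrix(config$nb_mean, nrow = config$n_regions,
                       ncol = config$n_genes)
  n_mark <- min(config$n_markers_per_region,
                config$n_genes %/% max(1L, config$n_regions))
  marker_genes <- vector("list", config$n_regions)
  for (r in seq_len(config$n_regions)) {
    if (n_mark > 0L) {
      idx <- ((r - 1L) * n_mark + 1L):(r * n_mark)
      gene_means[r, idx] <- config$nb_mean * config$marker_fc
      marker_genes[[r]] <- idx
    }
  }
  gene_seqs <- setNames(
    .collapse_rows(matrix(sample(.BASES, config$n_genes * config$insert_len,
                                 replace = TRUE),
                          config$n_genes, config$insert_len)),
    sprintf("gene%03d", seq_len(config$n_genes)))

  structure(list(config = config, reference = reference, sites = sites,
                 meth = meth, vmrs = vmrs, pixels = pixels,
                 gene_means = gene_means, marker_genes = marker_genes,
                 gene_seqs = gene_seqs),
            class = "sdmt_truth")
}

#' @export
print.sdmt_truth <- function(x, ...) {
  cat(sprintf("sdmt_truth: %d pixels, %d regions, %d cytosine sites (%d CpG), %d planted VMRs\n",
              nrow(x$pixels), x$config$n_regions, nrow(x$sites),
              sum(x$sites$context == "CG"), nrow(x$vmrs)))
  invisible(x)
}

# per-contig lookup vectors: position -> site row index, one per strand
.site_index <- function(truth) {
  lens <- setNames(truth$config$genome$length, truth$config$genome$contig)
  out <- list()
  for (ct in names(lens)) {
    plus <- minus <- rep(NA_integer_, lens[[ct]])
    rows <- which(truth$sites$contig == ct)
    st <- truth$sites[rows, ]
    plus[st$pos[st$strand == "+"]] <- rows[st$strand == "+"]
    minus[st$pos[st$strand == "-"]] <- rows[st$strand == "-"]
    out[[ct]] <- list("+" = plus, "-" = minus)
  }
  out
}

#' Default read layout
#'
#' Read 2 structure: barcode B (8 nt), linker 1 (15 nt), barcode A (8 nt),
#' linker 2 (15 nt), then a 10-nt UMI for the RNA library, then the insert.
#' Both linkers are methylation-free and carry 5 cytosines each.
#'
#' @param mode `"dna"` or `"rna"`.
#' @param insert_len insert length in nt.
#' @param barcode_len barcode length in nt.
#' @param umi_len UMI length (RNA only).
#' @return object of class `read_layout`: data.frame with columns `kind`,
#'   `length`, `expected` (reference sequence for linkers, NA otherwise).
#' @export
read_layout <- function(mode = c("dna", "rna"), insert_len = 40L,
                        barcode_len = 8L, umi_len = 10L) {
  mode <- match.arg(mode)
  segs <- data.frame(
    kind = c("barcodeB", "linker", "barcodeA", "linker"),
    length = c(barcode_len, nchar(.LINKER1), barcode_len, nchar(.LINKER2)),
    expected = c(NA, .LINKER1, NA, .LINKER2),
    stringsAsFactors = FALSE)
  if (mode == "rna") {
    segs <- rbind(segs, data.frame(kind = "umi", length = umi_len,
                                   expected = NA))
  }
  segs <- rbind(segs, data.frame(kind = "insert", length = insert_len,
                                 expected = NA))
  if (any(segs$length <= 0L)) stop("segment lengths must be positive")
  structure(segs, class = c("read_layout", "data.frame"), mode = mode)
}

# deaminate every C of a reference sequence replicated over n reads
.deaminate_rows <- function(refseq, n, conversion_prob) {
  chars <- strsplit(refseq, "", fixed = TRUE)[[1L]]
  m <- matrix(chars, nrow = n, ncol = length(chars), byrow = TRUE)
  for (p in which(chars == "C")) {
    conv <- runif(n) < conversion_prob
    m[conv, p] <- "T"
  }
  m
}

# deaminate C entries of a per-read character matrix (barcodes differ by row)
.deaminate_matrix <- function(m, conversion_prob) {
  cs <- which(m == "C")
  if (length(cs)) {
    conv <- runif(length(cs)) < conversion_prob
    m[cs[conv]] <- "T"
  }
  m
}

# substitute one random base within a barcode for a barcode_error fraction
# of reads
.apply_barcode_errors <- function(m, rate) {
  if (rate <= 0) return(m)
  hit <- which(runif(nrow(m)) < rate)
  if (!length(hit)) return(m)
  col <- sample.int(ncol(m), length(hit), replace = TRUE)
  idx <- cbind(hit, col)
  cur <- m[idx]
  shift <- sample.int(3L, length(hit), replace = TRUE)
  m[idx] <- .BASES[(match(cur, .BASES) - 1L + shift) %% 4L + 1L]
  m
}

#' Emit synthetic reads
#'
#' Generates the DNA (deaminated) and RNA libraries for a [make_truth()]
#' bundle, together with a read-level methylation call table and a full
#' provenance table. DNA reads: per-read Bernoulli methylation state per
#' cytosine from the true fraction, unmethylated C converted to T with
#' probability `conversion_prob`, methylation-free linkers deaminated at the
#' same rate, barcode substitutions at `barcode_error`, sequencing errors at
#' `seq_error` on linker and insert bases. RNA reads: raw (undeaminated)
#' barcodes, uniform random UMIs, molecule counts negative-binomial per
#' (pixel, gene). A `dup_fraction` share of DNA reads are verbatim re-emitted
#' duplicates; the total equals `pixels x reads_per_pixel_dna`.
#'
#' @param truth an `sdmt_truth`.
#' @param config the matching [sim_config()].
#' @param wl_a,wl_b barcode whitelists (data.frames with `index`, `sequence`,
#'   `role`); generated with [generate_barcodes()] when `NULL`.
#' @return object of class `sdmt_reads`: list with `dna`, `rna` (data.frames
#'   `id`, `seq`), `calls` (read-level methylation calls: read_id, pixel,
#'   contig, pos, strand, read_start, context, observed), `provenance`,
#'   `molecules` (true RNA molecules: pixel, gene, umi), `wl_a`, `wl_b`,
#'   `layout_dna`, `layout_rna`.
#' @export
emit_reads <- function(truth, config = truth$config, wl_a = NULL, wl_b = NULL) {
  stopifnot(inherits(truth, "sdmt_truth"))
  set.seed(config$seed + 1L)
  if (is.null(wl_a)) {
    wl_a <- generate_barcodes(config$grid_rows, role = "A",
                              seed = config$seed + 101L)
  }
  if (is.null(wl_b)) {
    wl_b <- generate_barcodes(config$grid_cols, role = "B",
                              seed = config$seed + 102L)
  }
  if (nrow(wl_a) < config$grid_rows || nrow(wl_b) < config$grid_cols) {
    stop("whitelists smaller than the grid dimensions")
  }
  layout_dna <- read_layout("dna", insert_len = config$insert_len)
  layout_rna <- read_layout("rna", insert_len = config$insert_len)
  px <- truth$pixels
  cells <- nrow(px)
  ilen <- config$insert_len
  g <- config$genome

  ## ---- DNA library ----
  n_total <- cells * config$reads_per_pixel_dna
  n_dup <- round(config$dup_fraction * n_total)
  n_uni <- n_total - n_dup

  pix <- rep(seq_len(cells), length.out = n_uni)
  contig_i <- sample.int(nrow(g), n_uni, replace = TRUE, prob = g$length)
  start <- 1L + floor(runif(n_uni) * (g$length[contig_i] - ilen + 1L))
  strand <- sample(c("+", "-"), n_uni, replace = TRUE)

  ref_sub <- substring(truth$reference[g$contig[contig_i]], start,
                       start + ilen - 1L)
  minus <- strand == "-"
  ref_sub[minus] <- .revcomp(ref_sub[minus])
  m_ins <- .seq_matrix(ref_sub, ilen)

  cpos <- which(m_ins == "C", arr.ind = TRUE)
  read_i <- cpos[, 1L]
  offset <- cpos[, 2L]
  gpos <- ifelse(minus[read_i], start[read_i] + ilen - offset,
                 start[read_i] + offset - 1L)
  sidx <- .site_index(truth)
  site <- integer(length(read_i))
  for (ci in seq_len(nrow(g))) {
    sel <- contig_i[read_i] == ci
    if (!any(sel)) next
    str_sel <- ifelse(minus[read_i[sel]], "-", "+")
    lk <- sidx[[g$contig[ci]]]
    site[sel] <- ifelse(str_sel == "+", lk[["+"]][gpos[sel]],
                        lk[["-"]][gpos[sel]])
  }
  ok <- !is.na(site)
  read_i <- read_i[ok]; offset <- offset[ok]; gpos <- gpos[ok]; site <- site[ok]

  m_true <- truth$meth[cbind(site, px$region[pix[read_i]])]
  methylated <- runif(length(site)) < m_true
  converted <- !methylated & (runif(length(site)) < config$conversion_prob)
  m_ins[cbind(read_i, offset)] <- ifelse(converted, "T", "C")
  m_ins <- .apply_seq_errors(m_ins, config$seq_error)

  observed <- m_ins[cbind(read_i, offset)]
  keep <- observed %in% c("C", "T")
  read_id <- sprintf("dna%07d", seq_len(n_uni))
  calls <- data.frame(
    read_id = read_id[read_i[keep]],
    pixel = px$pixel[pix[read_i[keep]]],
    contig = g$contig[contig_i[read_i[keep]]],
    pos = gpos[keep],
    strand = ifelse(minus[read_i[keep]], "-", "+"),
    read_start = start[read_i[keep]],
    context = truth$sites$context[site[keep]],
    observed = observed[keep],
    stringsAsFactors = FALSE)

  bcB <- .apply_barcode_errors(
    .deaminate_matrix(.seq_matrix(wl_b$sequence[px$b[pix]]),
                      config$conversion_prob), config$barcode_error)
  bcA <- .apply_barcode_errors(
    .deaminate_matrix(.seq_matrix(wl_a$sequence[px$a[pix]]),
                      config$conversion_prob), config$barcode_error)
  l1 <- .apply_seq_errors(.deaminate_rows(.LINKER1, n_uni, config$conversion_prob),
                          config$seq_error)
  l2 <- .apply_seq_errors(.deaminate_rows(.LINKER2, n_uni, config$conversion_prob),
                          config$seq_error)
  dna_seq <- paste0(.collapse_rows(bcB), .collapse_rows(l1),
                    .collapse_rows(bcA), .collapse_rows(l2),
                    .collapse_rows(m_ins))

  prov_dna <- data.frame(read_id = read_id, library = "dna",
                         pixel = px$pixel[pix], a = px$a[pix], b = px$b[pix],
                         contig = g$contig[contig_i], start = start,
                         strand = strand, gene = NA_character_,
                         umi = NA_character_, duplicate = FALSE,
                         stringsAsFactors = FALSE)

  if (n_dup > 0L) {
    src <- sample.int(n_uni, n_dup, replace = TRUE)
    dup_id <- sprintf("dna%07d", n_uni + seq_len(n_dup))
    dna_seq <- c(dna_seq, dna_seq[src])
    prov_d <- prov_dna[src, ]
    prov_d$read_id <- dup_id
    prov_d$duplicate <- TRUE
    prov_dna <- rbind(prov_dna, prov_d)
    # duplicate the call rows of each sampled source read (with multiplicity)
    idx_by_read <- split(seq_len(nrow(calls)),
                         factor(calls$read_id, levels = read_id))
    rows_list <- idx_by_read[src]
    rows <- unlist(rows_list, use.names = FALSE)
    if (length(rows)) {
      dup_calls <- calls[rows, , drop = FALSE]
      dup_calls$read_id <- rep(dup_id, lengths(rows_list))
      calls <- rbind(calls, dup_calls)
    }
    read_id <- c(read_id, dup_id)
  }
  dna <- data.frame(id = read_id, seq = dna_seq, stringsAsFactors = FALSE)

  if (config$n_spikein > 0L) {
    ns <- config$n_spikein
    spix <- sample.int(cells, ns, replace = TRUE)
    sid <- sprintf("spike%06d", seq_len(ns))
    sB <- .apply_barcode_errors(
      .deaminate_matrix(.seq_matrix(wl_b$sequence[px$b[spix]]),
                        config$conversion_prob), config$barcode_error)
    sA <- .apply_barcode_errors(
      .deaminate_matrix(.seq_matrix(wl_a$sequence[px$a[spix]]),
                        config$conversion_prob), config$barcode_error)
    sl1 <- .deaminate_rows(.LINKER1, ns, config$conversion_prob)
    sl2 <- .deaminate_rows(.LINKER2, ns, config$conversion_prob)
    sins <- .apply_seq_errors(
      .deaminate_rows(substr(.SPIKE_SEQ, 1L, ilen), ns, config$conversion_prob),
      config$seq_error)
    dna <- rbind(dna, data.frame(
      id = sid,
      seq = paste0(.collapse_rows(sB), .collapse_rows(sl1),
                   .collapse_rows(sA), .collapse_rows(sl2),
                   .collapse_rows(sins)),
      stringsAsFactors = FALSE))
    prov_dna <- rbind(prov_dna, data.frame(
      read_id = sid, library = "spike", pixel = px$pixel[spix],
      a = px$a[spix], b = px$b[spix], contig = NA_character_,
      start = NA_integer_, strand = NA_character_, gene = NA_character_,
      umi = NA_character_, duplicate = FALSE, stringsAsFactors = FALSE))
  }

  ## ---- RNA library ----
  mu <- truth$gene_means[px$region, , drop = FALSE]  # cells x genes
  counts <- rnbinom(length(mu), size = config$nb_dispersion, mu = as.numeric(mu))
  mol_pixel <- rep(seq_len(cells), times = config$n_genes)
  mol_gene <- rep(seq_len(config$n_genes), each = cells)
  expand <- rep(seq_along(counts), counts)
  n_mol <- length(expand)
  molecules <- data.frame(
    pixel = px$pixel[mol_pixel[expand]],
    gene = names(truth$gene_seqs)[mol_gene[expand]],
    umi = .collapse_rows(matrix(sample(.BASES, n_mol * 10L, replace = TRUE),
                                n_mol, 10L)),
    stringsAsFactors = FALSE)

  by_pix <- split(seq_len(n_mol), molecules$pixel)
  picked <- unlist(lapply(by_pix, function(ix) {
    ix[sample.int(length(ix), config$reads_per_pixel_rna, replace = TRUE)]
  }), use.names = FALSE)
  n_rna <- length(picked)
  rpix <- match(molecules$pixel[picked], px$pixel)
  rins <- .apply_seq_errors(
    .seq_matrix(unname(truth$gene_seqs[molecules$gene[picked]]), ilen),
    config$seq_error)
  rB <- .apply_barcode_errors(.seq_matrix(wl_b$sequence[px$b[rpix]]),
                              config$barcode_error)
  rA <- .apply_barcode_errors(.seq_matrix(wl_a$sequence[px$a[rpix]]),
                              config$barcode_error)
  rna_id <- sprintf("rna%07d", seq_len(n_rna))
  rna <- data.frame(
    id = rna_id,
    seq = paste0(.collapse_rows(rB), .LINKER1, .collapse_rows(rA), .LINKER2,
                 molecules$umi[picked], .collapse_rows(rins)),
    stringsAsFactors = FALSE)
  prov_rna <- data.frame(read_id = rna_id, library = "rna",
                         pixel = px$pixel[rpix], a = px$a[rpix], b = px$b[rpix],
                         contig = NA_character_, start = NA_integer_,
                         strand = NA_character_,
                         gene = molecules$gene[picked],
                         umi = molecules$umi[picked], duplicate = FALSE,
                         stringsAsFactors = FALSE)

  structure(list(dna = dna, rna = rna, calls = calls,
                 provenance = rbind(prov_dna, prov_rna),
                 molecules = molecules, wl_a = wl_a, wl_b = wl_b,
                 layout_dna = layout_dna, layout_rna = layout_rna),
            class = "sdmt_reads")
}

#' @export
print.sdmt_reads <- function(x, ...) {
  cat(sprintf("sdmt_reads: %d DNA reads, %d RNA reads, %d read-level calls\n",
              nrow(x$dna), nrow(x$rna), nrow(x$calls)))
  invisible(x)
}

#' Closed-form expectations for simulator QC metrics
#'
#' Retention at a context pools methylated cytosines with incompletely
#' converted ones: with true methylation `m` and conversion probability `c`,
#' `E[retention] = m + (1 - m) (1 - c)`. Conversion efficiency on
#' methylation-free linkers is `c`; mitochondrial retention (truth fully
#' unmethylated) is `1 - c`.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `metric`, `value` (fractions in `[0, 1]`).
#' @export
expected_metrics <- function(config) {
  m <- config$baseline_mcg
  h <- config$mch_level
  cv <- config$conversion_prob
  data.frame(
    metric = c("cg_retention", "ch_retention", "conversion_efficiency",
               "mito_retention"),
    value = c(m + (1 - m) * (1 - cv), h + (1 - h) * (1 - cv), cv, 1 - cv),
    stringsAsFactors = FALSE)
}

#' Generate a deamination-safe barcode whitelist
#'
#' Draws random barcodes and keeps those whose pairwise Hamming distance is at
#' least `min_distance` both in the raw alphabet and (when `collapsed`) after
#' C-to-T collapse, so that no two barcodes become indistinguishable after
#' enzymatic deamination.
#'
#' @param n number of barcodes.
#' @param length barcode length in nt.
#' @param role `"A"` or `"B"`.
#' @param min_distance minimum pairwise Hamming distance.
#' @param collapsed also enforce the distance after C-to-T collapse.
#' @param seed optional RNG seed.
#' @return data.frame with columns `index`, `sequence`, `role`.
#' @export
generate_barcodes <- function(n, length = 8L, role = "A", min_distance = 3L,
                              collapsed = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  acc <- character(0)
  acc_col <- character(0)
  tries <- 0L
  while (base::length(acc) < n) {
    tries <- tries + 1L
    if (tries > 1000L * n) stop("could not generate ", n, " barcodes")
    cand <- paste(sample(.BASES, length, replace = TRUE), collapse = "")
    cand_col <- collapse_ct(cand)
    ok <- TRUE
    if (base::length(acc)) {
      if (any(.hamming(rep(cand, base::length(acc)), acc) < min_distance)) ok <- FALSE
      if (ok && collapsed &&
          any(.hamming(rep(cand_col, base::length(acc_col)), acc_col) < min_distance)) {
        ok <- FALSE
      }
    }
    if (ok) {
      acc <- c(acc, cand)
      acc_col <- c(acc_col, cand_col)
    }
  }
  data.frame(index = seq_len(n), sequence = acc, role = role,
             stringsAsFactors = FALSE)
}
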
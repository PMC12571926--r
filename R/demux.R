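# Pixel assignment from combinatorial barcodes. The DNA library is
# enzymatically deaminated, so its barcodes are matched in the C-to-T
# collapsed alphabet {A,G,T}; the RNA library is matched in the raw alphabet.

#' Collapse C to T
#'
#' Maps every C to T, the image of a sequence under complete enzymatic
#' deamination. Used to compare deaminated reads against barcode whitelists.
#'
#' @param seq character vector over `A, C, G, T, N`.
#' @return character vector over `A, G, T, N`, same lengths.
#' @export
collapse_ct <- function(seq) {
  .check_dna(seq)
  chartr("C", "T", seq)
}

#' Validate a barcode whitelist
#'
#' Checks that all same-role barcode pairs are separated by at least
#' `min_distance` Hamming mismatches in the working alphabet — raw, or
#' C-to-T collapsed when `collapsed = TRUE` (required for the deaminated DNA
#' library, where a pair colliding after collapse is indistinguishable).
#'
#' @param wl data.frame with columns `index`, `sequence`, `role`.
#' @param collapsed validate in the C-to-T collapsed alphabet.
#' @param min_distance minimum tolerated pairwise Hamming distance.
#' @return list with `pass` (logical), `violations` (data.frame of colliding
#'   pairs with their distance), `min_distance_observed` (per role).
#' @export
validate_whitelist <- function(wl, collapsed = FALSE, min_distance = 1L) {
  stopifnot(all(c("index", "sequence", "role") %in% names(wl)), nrow(wl) > 0L)
  .check_dna(wl$sequence)
  viol <- list()
  min_obs <- c()
  for (role in unique(wl$role)) {
    w <- wl[wl$role == role, , drop = FALSE]
    if (length(unique(nchar(w$sequence))) != 1L) {
      stop("mixed barcode lengths within role ", role)
    }
    if (anyDuplicated(w$index)) stop("duplicate indices within role ", role)
    seqs <- if (collapsed) collapse_ct(w$sequence) else w$sequence
    n <- nrow(w)
    if (n < 2L) { min_obs[role] <- Inf; next }
    m <- .seq_matrix(seqs)
    dmin <- Inf
    for (i in seq_len(n - 1L)) {
      d <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                     matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
      dmin <- min(dmin, d)
      bad <- which(d < min_distance)
      if (length(bad)) {
        viol[[length(viol) + 1L]] <- data.frame(
          role = role, index_1 = w$index[i], index_2 = w$index[i + bad],
          distance = d[bad], stringsAsFactors = FALSE)
      }
    }
    min_obs[role] <- dmin
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(role = character(0), index_1 = integer(0),
               index_2 = integer(0), distance = integer(0))
  list(pass = nrow(violations) == 0L, violations = violations,
       min_distance_observed = min_obs)
}

#' Match observed barcodes against a whitelist
#'
#' Nearest-neighbour matching with a mismatch budget. A barcode is assigned
#' to the unique whitelist entry within `max_hamming`; ties at the minimal
#' distance are left unassigned (`ambiguous`), no candidate within budget is
#' `no_match`. `N` bases count as mismatches.
#'
#' @param observed character vector of observed barcodes (all whitelist
#'   length).
#' @param wl whitelist data.frame (`index`, `sequence`).
#' @param max_hamming mismatch budget.
#' @param collapsed match in the C-to-T collapsed alphabet.
#' @return data.frame with columns `index` (NA when unassigned), `distance`,
#'   `status` (`assigned`/`ambiguous`/`no_match`).
#' @export
match_barcode <- function(observed, wl, max_hamming = 1L, collapsed = FALSE) {
  blen <- nchar(wl$sequence[1L])
  if (any(nchar(observed) != blen)) {
    stop("observed barcode length differs from whitelist length")
  }
  seqs <- if (collapsed) collapse_ct(wl$sequence) else wl$sequence
  obs <- if (collapsed) collapse_ct(observed) else observed
  uo <- unique(obs)
  wm <- .seq_matrix(seqs)
  om <- .seq_matrix(uo)
  res_index <- rep(NA_integer_, length(uo))
  res_dist <- rep(NA_integer_, length(uo))
  res_status <- rep("no_match", length(uo))
  exact <- match(uo, seqs)
  hit <- !is.na(exact)
  res_index[hit] <- wl$index[exact[hit]]
  res_dist[hit] <- 0L
  res_status[hit] <- "assigned"
  todo <- which(!hit)
  for (i in todo) {
    d <- rowSums(wm != matrix(om[i, ], nrow(wm), blen, byrow = TRUE))
    dmin <- min(d)
    if (dmin > max_hamming) next
    best <- which(d == dmin)
    if (length(best) > 1L) {
      res_status[i] <- "ambiguous"
      res_dist[i] <- dmin
    } else {
      res_status[i] <- "assigned"
      res_index[i] <- wl$index[best]
      res_dist[i] <- dmin
    }
  }
  j <- match(obs, uo)
  data.frame(index = res_index[j], distance = res_dist[j],
             status = res_status[j], stringsAsFactors = FALSE)
}

#' Demultiplex reads to spatial pixels
#'
#' Slices each read according to the layout, matches barcodes A and B against
#' their whitelists — in the C-to-T collapsed alphabet for `mode = "dna"`
#' (deaminated library), raw for `mode = "rna"` — and reports per-read pixel
#' assignments. Reads shorter than the layout are counted as `no_match`.
#' For the DNA library the observed linker bases are retained for conversion
#' QC (see [conversion_efficiency()]).
#'
#' @param reads data.frame with columns `id`, `seq` (e.g. from
#'   [read_fastq()]), or a FASTQ file path.
#' @param layout a [read_layout()].
#' @param wl_a,wl_b whitelists for barcode A (rows) and barcode B (columns).
#' @param mode `"dna"` or `"rna"`.
#' @param max_hamming per-barcode mismatch budget.
#' @return list of class `demux_result`: `records` (read_id, a_index,
#'   b_index, pixel, umi, insert, linker segments for DNA, status) and
#'   `summary` (counts per status; assigned + ambiguous + no_match = total).
#' @export
demux_reads <- function(reads, layout, wl_a, wl_b, mode = c("dna", "rna"),
                        max_hamming = 1L) {
  mode <- match.arg(mode)
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(all(c("id", "seq") %in% names(reads)))
  vw <- validate_whitelist(rbind(wl_a, wl_b), collapsed = (mode == "dna"),
                           min_distance = if (mode == "dna") 2L * max_hamming + 1L else 1L)
  if (!vw$pass) {
    stop("whitelist fails ", if (mode == "dna") "collapsed " else "",
         "validation: ", nrow(vw$violations), " colliding pair(s)")
  }
  collapsed <- mode == "dna"
  segs <- layout
  ends <- cumsum(segs$length)
  starts <- ends - segs$length + 1L
  need <- ends[length(ends)] - segs$length[nrow(segs)]  # insert may be shorter
  n <- nrow(reads)
  long_enough <- nchar(reads$seq) > need

  get_seg <- function(kind, which_n = 1L) {
    i <- which(segs$kind == kind)[which_n]
    substring(reads$seq, starts[i], ends[i])
  }
  a_obs <- get_seg("barcodeA")
  b_obs <- get_seg("barcodeB")

  res_a <- res_b <- NULL
  status <- rep("no_match", n)
  a_index <- b_index <- rep(NA_integer_, n)
  idx <- which(long_enough)
  if (length(idx)) {
    res_a <- match_barcode(a_obs[idx], wl_a, max_hamming, collapsed)
    res_b <- match_barcode(b_obs[idx], wl_b, max_hamming, collapsed)
    st <- ifelse(res_a$status == "no_match" | res_b$status == "no_match",
                 "no_match",
                 ifelse(res_a$status == "ambiguous" | res_b$status == "ambiguous",
                        "ambiguous", "assigned"))
    status[idx] <- st
    a_index[idx] <- ifelse(st == "assigned", res_a$index, NA_integer_)
    b_index[idx] <- ifelse(st == "assigned", res_b$index, NA_integer_)
  }

  ins_i <- which(segs$kind == "insert")
  insert <- substring(reads$seq, starts[ins_i])
  umi <- if (any(segs$kind == "umi")) get_seg("umi") else NA_character_
  records <- data.frame(
    read_id = reads$id, a_index = a_index, b_index = b_index,
    pixel = ifelse(status == "assigned", .pixel_id(a_index, b_index),
                   NA_character_),
    umi = umi, insert = insert, status = status, stringsAsFactors = FALSE)
  if (mode == "dna") {
    lk <- which(segs$kind == "linker")
    for (j in seq_along(lk)) {
      records[[paste0("linker", j)]] <- substring(reads$seq, starts[lk[j]],
                                                  ends[lk[j]])
    }
  }
  records$status[!long_enough] <- "no_match"
  summary <- as.data.frame(table(status = factor(
    records$status, levels = c("assigned", "ambiguous", "no_match"))),
    stringsAsFactors = FALSE)
  names(summary) <- c("status", "reads")
  summary$fraction <- summary$reads / max(1L, n)
  structure(list(records = records, summary = summary, mode = mode,
                 max_hamming = max_hamming),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  n <- sum(x$summary$reads)
  cat(sprintf("demux_result (%s mode): %d reads, %d pixels\n", x$mode, n,
              length(unique(stats::na.omit(x$records$pixel)))))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Screen DNA-library inserts for RNA contamination
#'
#' Counts reads whose insert contains a poly(A) or poly(T) homopolymer run of
#' at least `min_run` bases, or a configured template-switching-oligo (TSO)
#' subsequence — signatures of RNA library material leaking into the
#' methylation library.
#'
#' @param inserts character vector of DNA-library insert sequences.
#' @param tso optional TSO sequence to search for (exact substring).
#' @param min_run minimum homopolymer run length.
#' @return data.frame with columns `motif`, `reads`, `fraction`.
#' @export
contamination_screen <- function(inserts, tso = NULL, min_run = 10L) {
  n <- length(inserts)
  hits <- c(polyA = sum(grepl(strrep("A", min_run), inserts, fixed = TRUE)),
            polyT = sum(grepl(strrep("T", min_run), inserts, fixed = TRUE)))
  if (!is.null(tso)) {
    hits <- c(hits, tso = sum(grepl(tso, inserts, fixed = TRUE)))
  }
  data.frame(motif = names(hits), reads = as.integer(hits),
             fraction = as.numeric(hits) / max(1L, n),
             stringsAsFactors = FALSE)
}
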
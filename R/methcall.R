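# Per-pixel methylation calling from read-level calls, retention/conversion
# QC metrics, and knee-plot pixel filtering.

.CONTEXTS <- c("CG", "CA", "CC", "CT")

#' Cytosine context from a reference sequence
#'
#' The context of a cytosine is `C` plus the next base 3' on the same strand:
#' on the plus strand the base at `position + 1`; on the minus strand (where
#' the reference shows `G` at `position`) the complement of the base at
#' `position - 1`. `H` in `CH` denotes A, C or T.
#'
#' @param reference single reference sequence (character scalar).
#' @param position 1-based position(s) of the cytosine (plus-strand
#'   coordinates; for minus-strand sites, the position of the complementary
#'   G).
#' @param strand `"+"` or `"-"`, recycled along `position`.
#' @return character vector of contexts among `CG, CA, CC, CT`.
#' @export
assign_context <- function(reference, position, strand = "+") {
  s <- strsplit(reference, "", fixed = TRUE)[[1L]]
  len <- length(s)
  strand <- rep_len(strand, length(position))
  if (any(position < 1L | position > len)) stop("position out of range")
  base <- s[position]
  want <- ifelse(strand == "+", "C", "G")
  if (any(base != want)) {
    stop("no cytosine at position(s) ",
         paste(head(position[base != want], 3L), collapse = ", "),
         " on strand ", paste(head(strand[base != want], 3L), collapse = ", "))
  }
  nxt_pos <- ifelse(strand == "+", position + 1L, position - 1L)
  if (any(nxt_pos < 1L | nxt_pos > len)) {
    stop("context undefined at the contig boundary")
  }
  nxt <- ifelse(strand == "+", s[nxt_pos], .complement(s[nxt_pos]))
  ctx <- paste0("C", nxt)
  if (any(!ctx %in% .CONTEXTS)) stop("ambiguous context (N base 3' of C)")
  ctx
}

#' Aggregate read-level methylation calls into a per-pixel site table
#'
#' Optionally deduplicates reads on `(pixel, contig, leftmost read position,
#' strand)` keeping the first occurrence (the DNA library carries no UMI),
#' then accumulates retained (`C`) and converted (`T`) counts per
#' `(pixel, contig, position, strand, context)`. Calls whose reference base
#' is not a cytosine, or whose observed base is neither C nor T, are rejected
#' and tallied.
#'
#' @param calls data.frame with columns `read_id`, `pixel`, `contig`, `pos`,
#'   `strand`, `read_start`, `observed`, and `context` (required unless
#'   `reference` is given).
#' @param reference optional named character vector of contig sequences used
#'   to derive/verify contexts.
#' @param dedup remove PCR duplicates before counting.
#' @return object of class `meth_call_table`: list with `table` (data.frame
#'   pixel/contig/pos/strand/context/retained/converted), `duplication_rate`
#'   (fraction of reads removed), `n_rejected`.
#' @export
aggregate_calls <- function(calls, reference = NULL, dedup = TRUE) {
  need <- c("read_id", "pixel", "contig", "pos", "strand", "observed")
  stopifnot(all(need %in% names(calls)))
  dt <- data.table::as.data.table(calls)
  n_rejected <- 0L

  bad_obs <- !dt$observed %in% c("C", "T")
  if (any(bad_obs)) {
    n_rejected <- n_rejected + sum(bad_obs)
    dt <- dt[!bad_obs]
  }
  if (!is.null(reference)) {
    ctx <- rep(NA_character_, nrow(dt))
    okref <- logical(nrow(dt))
    for (ct in unique(dt$contig)) {
      rows <- which(dt$contig == ct)
      s <- strsplit(reference[[ct]], "", fixed = TRUE)[[1L]]
      base <- s[dt$pos[rows]]
      want <- ifelse(dt$strand[rows] == "+", "C", "G")
      good <- !is.na(base) & base == want
      okref[rows] <- good
      if (any(good)) {
        ctx[rows[good]] <- assign_context(reference[[ct]], dt$pos[rows[good]],
                                          dt$strand[rows[good]])
      }
    }
    n_rejected <- n_rejected + sum(!okref)
    dt <- dt[okref]
    dt$context <- ctx[okref]
  } else if (!"context" %in% names(dt)) {
    stop("calls need a context column when no reference is supplied")
  }

  total_reads <- length(unique(dt$read_id))
  duplication_rate <- 0
  if (dedup) {
    if (!"read_start" %in% names(dt)) {
      stop("dedup requires a read_start column")
    }
    reads <- unique(dt[, c("read_id", "pixel", "contig", "read_start",
                           "strand")])
    keep_ids <- reads[!duplicated(reads[, c("pixel", "contig", "read_start",
                                            "strand")]), ]$read_id
    duplication_rate <- if (total_reads > 0L) {
      1 - length(keep_ids) / total_reads
    } else 0
    dt <- dt[dt$read_id %in% keep_ids]
  }

  retained <- converted <- NULL  # NSE bindings
  tab <- dt[, list(retained = sum(observed == "C"),
                   converted = sum(observed == "T")),
            by = c("pixel", "contig", "pos", "strand", "context")]
  data.table::setorderv(tab, c("contig", "pos", "strand", "pixel"))
  structure(list(table = as.data.frame(tab),
                 duplication_rate = duplication_rate,
                 n_rejected = n_rejected),
            class = "meth_call_table")
}

#' @export
print.meth_call_table <- function(x, ...) {
  cat(sprintf(paste0("meth_call_table: %d site x pixel records, %d pixels, ",
                     "duplication rate %.1f%%, %d rejected calls\n"),
              nrow(x$table), length(unique(x$table$pixel)),
              100 * x$duplication_rate, x$n_rejected))
  invisible(x)
}

.as_call_df <- function(table) {
  if (inherits(table, "meth_call_table")) table$table else as.data.frame(table)
}

#' Per-pixel retention metrics
#'
#' Retention at a context is the percentage of cytosines read as C
#' (unconverted) — methylation plus incomplete conversion:
#' `100 * sum(retained) / sum(retained + converted)` over sites of that
#' context. `mCH` pools CA, CC and CT. Contexts with zero coverage in a pixel
#' are reported as `NA`, not 0.
#'
#' @param table a [aggregate_calls()] result (or its data.frame).
#' @param contigs `"all"`, `"nuclear"` or `"mito"`.
#' @param mito_contigs contig names treated as mitochondrial.
#' @return data.frame per pixel with columns `pixel`, `mCG`, `mCA`, `mCC`,
#'   `mCT`, `mCH` (percentages) and `n_calls`.
#' @export
retention_metrics <- function(table, contigs = c("all", "nuclear", "mito"),
                              mito_contigs = "chrM") {
  contigs <- match.arg(contigs)
  df <- .as_call_df(table)
  if (nrow(df) == 0L) stop("empty call table")
  if (contigs == "mito") df <- df[df$contig %in% mito_contigs, , drop = FALSE]
  if (contigs == "nuclear") df <- df[!df$contig %in% mito_contigs, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(pixel = character(0), mCG = numeric(0), mCA = numeric(0),
                      mCC = numeric(0), mCT = numeric(0), mCH = numeric(0),
                      n_calls = integer(0)))
  }
  dt <- data.table::as.data.table(df)
  retained <- converted <- context <- NULL
  agg <- dt[, list(ret = sum(retained), tot = sum(retained + converted)),
            by = c("pixel", "context")]
  pixels <- sort(unique(agg$pixel))
  pct <- function(ctxs) {
    a <- agg[agg$context %in% ctxs,
             list(ret = sum(ret), tot = sum(tot)), by = "pixel"]
    out <- setNames(rep(NA_real_, length(pixels)), pixels)
    out[a$pixel] <- 100 * a$ret / a$tot
    out
  }
  tot <- dt[, list(n = sum(retained + converted)), by = "pixel"]
  n_calls <- setNames(rep(0L, length(pixels)), pixels)
  n_calls[tot$pixel] <- tot$n
  data.frame(pixel = pixels,
             mCG = pct("CG"), mCA = pct("CA"), mCC = pct("CC"),
             mCT = pct("CT"), mCH = pct(c("CA", "CC", "CT")),
             n_calls = as.integer(n_calls),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Conversion efficiency on methylation-free linkers
#'
#' Every cytosine of the linker reference is unmethylated by construction, so
#' the fraction read as T estimates the deamination efficiency:
#' `100 * #(C -> T observed) / #(C positions observed)`. Observed `N` bases
#' are excluded.
#'
#' @param observed character vector of observed linker sequences (same length
#'   as the reference; e.g. the `linker1`/`linker2` columns of a DNA-mode
#'   [demux_reads()] result).
#' @param reference the linker reference sequence.
#' @return conversion efficiency in percent.
#' @export
conversion_efficiency <- function(observed, reference) {
  cpos <- which(strsplit(reference, "", fixed = TRUE)[[1L]] == "C")
  if (length(cpos) == 0L) stop("linker reference contains no cytosine")
  observed <- observed[nchar(observed) == nchar(reference)]
  if (length(observed) == 0L) stop("no observed linker sequences")
  m <- .seq_matrix(observed)[, cpos, drop = FALSE]
  n_obs <- sum(m != "N")
  if (n_obs == 0L) stop("no observed (non-N) linker cytosine positions")
  100 * sum(m == "T") / n_obs
}

#' Knee-plot pixel filter
#'
#' Sorts reads-per-pixel counts in decreasing order and finds the knee of the
#' `(log10 rank, log10(count + 1))` curve as the point of maximum
#' perpendicular distance to the chord joining its first and last points.
#' Pixels with counts at or above the knee count are kept. If the curve is a
#' straight line (maximum distance below `tol`) all pixels are kept with a
#' warning.
#'
#' @param counts named numeric vector of reads per pixel (>= 3 pixels).
#' @param tol degeneracy tolerance on the perpendicular distance.
#' @return list with `threshold` (count at the knee), `kept` (pixel names),
#'   `degenerate` flag and `diagnostics` (rank/count/distance data.frame).
#' @export
knee_filter <- function(counts, tol = 1e-8) {
  if (length(counts) < 3L) stop("need at least 3 pixels")
  if (is.null(names(counts))) names(counts) <- as.character(seq_along(counts))
  ord <- order(counts, decreasing = TRUE)
  cs <- counts[ord]
  x <- log10(seq_along(cs))
  y <- log10(cs + 1)
  x1 <- x[1L]; y1 <- y[1L]
  x2 <- x[length(x)]; y2 <- y[length(y)]
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  dist <- if (denom == 0) {
    rep(0, length(x))
  } else {
    abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) / denom
  }
  degenerate <- max(dist) < tol
  if (degenerate) {
    warning("no knee detected (curve is a straight line); keeping all pixels")
    threshold <- cs[length(cs)]
  } else {
    threshold <- cs[which.max(dist)]
  }
  kept <- names(counts)[counts >= threshold]
  list(threshold = unname(threshold), kept = kept, degenerate = degenerate,
       diagnostics = data.frame(rank = seq_along(cs), pixel = names(cs),
                                count = unname(cs), distance = dist,
                                row.names = NULL, stringsAsFactors = FALSE))
}
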
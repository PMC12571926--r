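# Readers/writers for the standard interchange formats: FASTQ, whitelist
# TSV, Bismark-coverage-dialect methylation tables, BED, MatrixMarket.

#' Read a FASTQ file
#'
#' @param path FASTQ file (gzip accepted).
#' @return data.frame with columns `id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), seq = as.character(x), stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `id`, `seq` (e.g. from [emit_reads()]).
#' @param path output file; `.gz` suffix enables compression.
#' @param qual constant base quality character.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  q <- Biostrings::BStringSet(vapply(nchar(reads$seq), strrep, character(1),
                                     x = qual))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read / write a barcode whitelist TSV
#'
#' Columns: `index`, `sequence`, `role`.
#' @param path TSV file.
#' @return data.frame whitelist.
#' @export
read_whitelist <- function(path) {
  wl <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("index", "sequence", "role") %in% names(wl)))
  wl
}

#' @rdname read_whitelist
#' @param wl whitelist data.frame.
#' @export
write_whitelist <- function(wl, path) {
  write.table(wl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a methylation call table in the Bismark coverage dialect
#'
#' Long format with a leading `pixel` column, then the classic six coverage
#' columns: contig, start, end (1-based inclusive, start == end for a single
#' cytosine), methylation percentage, count methylated, count unmethylated.
#' CpG strands are merged to the plus-strand C position before export.
#'
#' @param table a [aggregate_calls()] result.
#' @param path output TSV.
#' @param context which context to export (coverage files are per-context).
#' @export
write_bismark_cov <- function(table, path, context = "CG") {
  df <- .as_call_df(table)
  df <- df[df$context == context, , drop = FALSE]
  if (context == "CG") {
    df <- .merge_cpg_strands(.as_call_df(table))
  }
  out <- data.frame(pixel = df$pixel, contig = df$contig, start = df$pos,
                    end = df$pos,
                    meth_pct = 100 * df$retained / (df$retained + df$converted),
                    count_m = df$retained, count_u = df$converted)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a Bismark-coverage-dialect methylation table
#'
#' Accepts the long format written by [write_bismark_cov()] (leading `pixel`
#' column) or a classic six-column per-pixel file (supply `pixel`).
#'
#' @param path TSV file.
#' @param context context assigned to the imported records.
#' @param pixel pixel id for six-column single-pixel files.
#' @return `meth_call_table` (strand reported as `+` after merge).
#' @export
read_bismark_cov <- function(path, context = "CG", pixel = NULL) {
  raw <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(raw) >= 7L) {
    names(raw)[1:7] <- c("pixel", "contig", "start", "end", "meth_pct",
                         "count_m", "count_u")
  } else {
    stopifnot(!is.null(pixel), ncol(raw) >= 6L)
    names(raw)[1:6] <- c("contig", "start", "end", "meth_pct", "count_m",
                         "count_u")
    raw$pixel <- pixel
  }
  tab <- data.frame(pixel = raw$pixel, contig = raw$contig, pos = raw$start,
                    strand = "+", context = context, retained = raw$count_m,
                    converted = raw$count_u, stringsAsFactors = FALSE)
  structure(list(table = tab, duplication_rate = NA_real_, n_rejected = 0L),
            class = "meth_call_table")
}

#' Read a BED file of intervals
#'
#' @param path BED file (3+ columns; strand picked up when present).
#' @return data.frame with `contig`, `start`, `end` (0-based half-open) and,
#'   when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write a VMR set as BED6
#'
#' The BED score is the interval's variance-rank percentile scaled to 0-1000
#' (1000 = highest variance), the conventional integer score slot.
#'
#' @param vmrs a [scan_vmrs()] result.
#' @param path output BED file.
#' @export
write_vmr_bed <- function(vmrs, path) {
  df <- as.data.frame(vmrs)
  n <- nrow(df)
  pct <- if (n > 1L) (rank(df$score) - 1) / (n - 1) else rep(1, n)
  gr <- GenomicRanges::GRanges(
    df$contig, IRanges::IRanges(df$start + 1L, df$end),
    name = sprintf("VMR%04d", seq_len(n)),
    score = as.integer(round(1000 * pct)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write / read a matrix in MatrixMarket format with dimension names
#'
#' Writes `<path>.mtx` plus `<path>.rows.tsv` / `<path>.cols.tsv`.
#' @param x matrix (dense or sparse); `NA` entries are dropped (missing).
#' @param path output prefix.
#' @export
write_mtx <- function(x, path) {
  m <- as.matrix(x)
  m[is.na(m)] <- 0
  sp <- methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sp, paste0(path, ".mtx"))
  writeLines(rownames(x) %||% as.character(seq_len(nrow(x))),
             paste0(path, ".rows.tsv"))
  writeLines(colnames(x) %||% as.character(seq_len(ncol(x))),
             paste0(path, ".cols.tsv"))
  invisible(path)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(paste0(path, ".mtx")))
  dimnames(m) <- list(readLines(paste0(path, ".rows.tsv")),
                      readLines(paste0(path, ".cols.tsv")))
  m
}
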
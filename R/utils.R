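# Internal helpers shared across modules.

.datatable.aware <- TRUE

.BASES <- c("A", "C", "G", "T")

.clamp01 <- function(x) pmin(1, pmax(0, x))

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

.check_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("non-IUPAC symbol in sequence(s): ",
         paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  invisible(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

# Hamming distance between two equal-length character scalars/vectors of
# sequences, vectorised over the first argument.
.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  am <- strsplit(a, "", fixed = TRUE)
  bm <- strsplit(b, "", fixed = TRUE)
  mapply(function(x, y) sum(x != y), am, bm, USE.NAMES = FALSE)
}

# Split equal-width strings into an n x width character matrix.
.seq_matrix <- function(x, width = NULL) {
  if (length(x) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = if (is.null(width)) 0L else width))
  }
  w <- nchar(x[1L])
  stopifnot(all(nchar(x) == w))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = w, byrow = TRUE)
}

.collapse_rows <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Uniform random substitutions at a per-base rate, in place on a character
# matrix; substituted base drawn uniformly from the three other bases.
.apply_seq_errors <- function(m, rate) {
  if (rate <= 0 || length(m) == 0L) return(m)
  hit <- which(runif(length(m)) < rate)
  if (length(hit) == 0L) return(m)
  cur <- m[hit]
  shift <- sample.int(3L, length(hit), replace = TRUE)
  idx <- (match(cur, .BASES) - 1L + shift) %% 4L + 1L
  idx[is.na(idx)] <- sample.int(4L, sum(is.na(idx)), replace = TRUE)
  m[hit] <- .BASES[idx]
  m
}

.pixel_id <- function(a, b) sprintf("A%dB%d", a, b)
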
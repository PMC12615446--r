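#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish malformed input
# from programming errors.
fs_error <- function(msg, class = "fs_data_error", call. = FALSE) {
  stop(structure(
    class = c(class, "fs_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

fs_assert <- function(ok, msg, class = "fs_data_error") {
  if (!isTRUE(ok)) fs_error(msg, class = class)
  invisible(TRUE)
}

#' Reverse-complement a nucleotide string
#'
#' Uppercase A/C/G/T/N alphabet; N complements to N.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Genomic slice [start, end], 1-based inclusive, already validated by callers.
gslice <- function(genome, chrom, start, end) {
  if (end < start) return("")
  substr(genome[[chrom]], start, end)
}

chrom_len <- function(genome, chrom) {
  if (!chrom %in% names(genome)) {
    fs_error(sprintf("unknown chromosome '%s'", chrom))
  }
  nchar(genome[[chrom]])
}

# Longest common prefix length of two strings; 'N' matches nothing.
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1]][seq_len(n)]
  bv <- strsplit(b, "", fixed = TRUE)[[1]][seq_len(n)]
  ok <- av == bv & av != "N"
  mismatch <- which(!ok)
  if (length(mismatch) == 0L) n else mismatch[1L] - 1L
}

# Longest common suffix length, same matching rule.
lcs_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(strsplit(a, "", fixed = TRUE)[[1]])[seq_len(n)]
  bv <- rev(strsplit(b, "", fixed = TRUE)[[1]])[seq_len(n)]
  ok <- av == bv & av != "N"
  mismatch <- which(!ok)
  if (length(mismatch) == 0L) n else mismatch[1L] - 1L
}

# Deterministic ordered-pair key used by dedup, conservation and benchmarking.
pair_key <- function(gene5, gene3) paste(gene5, gene3, sep = "_")

# Round half-up to `digits` decimals (base round() is round-half-even).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
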
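#' @useDynLib clonecompare, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom rpois runif dhyper ppois setNames
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over character strings. IUPAC ambiguity
#' codes other than N are not handled; N maps to N.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

## Half-up rounding to `digits` decimals (base round() is banker's).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Deterministic sub-seed from a master seed and a role tag, < 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

## Phred string (+33) <-> integer vectors
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

## Fast per-read quality stats for equal-or-variable-length Phred+33 strings.
## Returns list(mean, frac_below) where frac_below is the fraction of bases
## with quality strictly below `thresh`.
qual_stats <- function(qual, thresh) {
  .qual_stats(qual, as.integer(thresh))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Substitute single bases at given positions of one long string (in place).
substitute_bases <- function(seq, pos, base) {
  if (length(pos) == 0) return(seq)
  r <- charToRaw(seq)
  r[pos] <- charToRaw(paste(base, collapse = ""))
  rawToChar(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## row-subset / construct plain data.frames without [.data.frame overhead
fast_subset <- function(df, i) {
  out <- lapply(df, `[`, i)
  class(out) <- "data.frame"
  attr(out, "row.names") <- .set_row_names(length(out[[1]]))
  out
}

fast_df <- function(cols) {
  class(cols) <- "data.frame"
  attr(cols, "row.names") <- .set_row_names(length(cols[[1]]))
  cols
}
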
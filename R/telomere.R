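## Sequencing-based relative telomere length: the fraction of reads
## containing tandem telomeric repeats, normalised by control motifs of the
## same base composition.

#' Count reads containing tandem repeats of a motif
#'
#' For each tandem multiplicity k = 1..k_max, counts reads whose sequence
#' contains the motif repeated k times as an exact substring; with
#' `include_revcomp`, a read also counts if it contains the
#' reverse-complement tandem. Each read is counted at most once per k.
#'
#' @param seqs character vector of read sequences.
#' @param motif repeat motif (default TTAGGG).
#' @param k_max maximum tandem multiplicity (default 6).
#' @param include_revcomp also match the reverse-complement tandem
#'   (default TRUE: sequencing reads both strands).
#' @return list with `counts` (named integer vector, k = 1..k_max) and
#'   `total` reads.
#' @export
count_repeat_reads <- function(seqs, motif = "TTAGGG", k_max = 6L,
                               include_revcomp = TRUE) {
  stopifnot(nchar(motif) >= 1L, length(seqs) > 0L)
  ## tandem containment nests: a k-hit is a (k-1)-hit, so only previous
  ## hits need rescanning at higher k
  counts <- integer(k_max)
  fwd_idx <- seq_along(seqs)
  rev_idx <- if (include_revcomp) seq_along(seqs) else integer(0)
  for (k in seq_len(k_max)) {
    fwd_idx <- fwd_idx[stringi::stri_detect_fixed(seqs[fwd_idx],
                                                  strrep(motif, k))]
    if (include_revcomp) {
      rev_idx <- rev_idx[stringi::stri_detect_fixed(
        seqs[rev_idx], strrep(revcomp(motif), k)
      )]
    }
    counts[k] <- length(union(fwd_idx, rev_idx))
  }
  list(counts = setNames(counts, paste0("k", seq_len(k_max))),
       total = length(seqs))
}

#' Estimate relative telomere content of a sample
#'
#' Computes, per tandem multiplicity k, the fraction of reads containing
#' `(TTAGGG) x k`, and normalises it by the mean fraction of control motifs
#' (base-composition permutations such as GGGATT) at the same k. Where the
#' control fraction is zero the normalised value is flagged unavailable
#' (NA) rather than infinite.
#'
#' @param reads a `read_set`, reads data.frame, or character vector of
#'   sequences.
#' @param motif telomere motif (default TTAGGG).
#' @param controls control motifs; must be permutations of the telomere
#'   motif's base composition.
#' @param k_max maximum tandem multiplicity.
#' @param include_revcomp match both strands (default TRUE).
#' @return a `telomere_estimate`: `total_reads`, `telo_counts`,
#'   `control_counts`, `raw_fraction` and `normalized` per k.
#' @export
telomere_estimate <- function(reads, motif = "TTAGGG",
                              controls = c("GGGATT", "GTGAGT", "TGAGGT"),
                              k_max = 6L, include_revcomp = TRUE) {
  seqs <- if (inherits(reads, "read_set")) {
    ## with revcomp matching on, counts are orientation-invariant, so the
    ## aligned-orientation sequences can be scanned directly
    if (include_revcomp) reads$alignments$seq else reads_frame(reads)$seq
  } else if (is.data.frame(reads)) {
    reads$seq
  } else {
    reads
  }
  if (!length(seqs)) stop("empty read stream")
  if (!length(controls)) stop("at least one control motif is required")
  comp <- function(m) sort(strsplit(m, "")[[1]])
  if (!all(vapply(controls, function(m) identical(comp(m), comp(motif)),
                  logical(1)))) {
    stop("control motifs must be base-composition permutations of ", motif)
  }
  telo <- count_repeat_reads(seqs, motif, k_max, include_revcomp)
  ctrl <- lapply(controls, function(m) {
    count_repeat_reads(seqs, m, k_max, include_revcomp)$counts
  })
  names(ctrl) <- controls
  total <- telo$total
  raw <- telo$counts / total
  ctrl_frac <- do.call(rbind, ctrl) / total
  ctrl_mean <- colMeans(ctrl_frac)
  normalized <- ifelse(ctrl_mean > 0, raw / ctrl_mean, NA_real_)
  structure(
    list(
      total_reads = total,
      telo_counts = telo$counts,
      control_counts = ctrl,
      raw_fraction = raw,
      control_mean_fraction = ctrl_mean,
      normalized = normalized,
      motif = motif, controls = controls, k_max = k_max
    ),
    class = "telomere_estimate"
  )
}

#' @export
print.telomere_estimate <- function(x, ...) {
  cat(sprintf("<telomere_estimate> %s reads, motif %s\n",
              format(x$total_reads, big.mark = ","), x$motif))
  df <- data.frame(
    k = seq_len(x$k_max), telo_reads = as.integer(x$telo_counts),
    raw_fraction = signif(x$raw_fraction, 3),
    normalized = signif(x$normalized, 3)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare the relative telomere lengths of two samples
#'
#' @param est_a,est_b `telomere_estimate`s computed with the same `k_max`.
#' @param k tandem multiplicity for the headline ratio (default 4: k = 1 is
#'   saturated by chance hits, k = 6 sparse at 100 bp reads).
#' @return a `telomere_comparison`: `ratio` (a over b at k), and the per-k
#'   tables of both samples.
#' @export
compare_samples <- function(est_a, est_b, k = 4L) {
  stopifnot(est_a$k_max == est_b$k_max)
  na_ <- est_a$normalized[k]
  nb_ <- est_b$normalized[k]
  if (is.na(na_) || is.na(nb_) || nb_ == 0) {
    stop("normalized value unavailable at k = ", k,
         "; choose a lower k (see the per-k table)")
  }
  structure(
    list(
      k = k, ratio = unname(na_ / nb_),
      normalized_a = est_a$normalized, normalized_b = est_b$normalized,
      raw_a = est_a$raw_fraction, raw_b = est_b$raw_fraction
    ),
    class = "telomere_comparison"
  )
}

#' @export
print.telomere_comparison <- function(x, ...) {
  cat(sprintf("<telomere_comparison> ratio %.3f at k = %d\n", x$ratio, x$k))
  df <- data.frame(
    k = seq_along(x$normalized_a),
    normalized_a = signif(x$normalized_a, 3),
    normalized_b = signif(x$normalized_b, 3)
  )
  print(df, row.names = FALSE)
  invisible(x)
}
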
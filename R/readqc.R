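## Raw-read filtering: the four criteria applied to each mate before
## alignment, plus coordinate-based PCR-duplicate removal afterwards.

#' QC configuration
#'
#' Thresholds for the four raw-read filtering criteria. The defaults follow
#' the strict-inequality readings: a read fails on ambiguous bases only when
#' the N fraction *exceeds* `max_n_fraction`, on mean quality only when it
#' is strictly *under* `min_mean_quality`, and on low-quality content only
#' when bases below `low_quality_threshold` exceed
#' `max_low_quality_fraction` of the read. Adapter contamination is an
#' exact suffix/prefix identity of at least `adapter_min_match` bases
#' (mate 1 against the index adapter head, mate 2 against the head of the
#' universal adapter's reverse complement).
#'
#' @param max_n_fraction maximum tolerated fraction of N bases.
#' @param min_mean_quality minimum mean Phred quality.
#' @param low_quality_threshold Phred value under which a base counts as
#'   low quality.
#' @param max_low_quality_fraction maximum tolerated fraction of
#'   low-quality bases.
#' @param adapter_min_match minimum suffix/prefix identity in bp.
#' @param adapter_strict_gt if `TRUE`, require the match length to strictly
#'   exceed `adapter_min_match` instead of `>=`.
#' @param index_adapter_seq,universal_adapter_seq adapter sequences.
#' @return a `qc_config` list.
#' @export
qc_config <- function(max_n_fraction = 0.10,
                      min_mean_quality = 15,
                      low_quality_threshold = 15,
                      max_low_quality_fraction = 0.10,
                      adapter_min_match = 10L,
                      adapter_strict_gt = FALSE,
                      index_adapter_seq =
                        "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACACAGTGATCTCGTATGCCGTCTTCTGCTTG",
                      universal_adapter_seq =
                        "AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT") {
  stopifnot(
    max_n_fraction >= 0, max_n_fraction <= 1,
    max_low_quality_fraction >= 0, max_low_quality_fraction <= 1,
    adapter_min_match >= 1
  )
  structure(
    list(
      max_n_fraction = max_n_fraction,
      min_mean_quality = min_mean_quality,
      low_quality_threshold = low_quality_threshold,
      max_low_quality_fraction = max_low_quality_fraction,
      adapter_min_match = as.integer(adapter_min_match),
      adapter_strict_gt = adapter_strict_gt,
      index_adapter_seq = index_adapter_seq,
      universal_adapter_seq = universal_adapter_seq
    ),
    class = "qc_config"
  )
}

QC_REASONS <- c("N_FRACTION", "MEAN_QUALITY", "LOW_QUAL_FRACTION", "ADAPTER")

## vectorised assessment: returns a logical matrix reads x reasons
assess_reads_matrix <- function(seq, qual, mate, config) {
  n <- length(seq)
  lens <- stringi::stri_length(seq)
  if (any(lens != stringi::stri_length(qual))) {
    stop("sequence/quality length mismatch in read record ",
         which(lens != stringi::stri_length(qual))[1])
  }
  if (any(lens == 0L)) stop("empty read")
  nfrac <- stringi::stri_count_fixed(seq, "N") / lens
  qs <- qual_stats(qual, config$low_quality_threshold)
  out <- matrix(FALSE, n, 4L, dimnames = list(NULL, QC_REASONS))
  out[, "N_FRACTION"] <- nfrac > config$max_n_fraction
  out[, "MEAN_QUALITY"] <- qs$mean < config$min_mean_quality
  out[, "LOW_QUAL_FRACTION"] <- qs$frac_below > config$max_low_quality_fraction
  out[, "ADAPTER"] <- adapter_hit(seq, mate, config)
  out
}

## exact identity between a read suffix (length >= m0) and an adapter
## prefix: any qualifying suffix match contains the adapter's first m0
## bases, so reads are pre-screened for that seed and only hits verified
adapter_hit <- function(seq, mate, config) {
  m0 <- config$adapter_min_match + if (config$adapter_strict_gt) 1L else 0L
  hit <- rep(FALSE, length(seq))
  for (m in unique(mate)) {
    adapter <- if (m == 1L) {
      config$index_adapter_seq
    } else {
      revcomp(config$universal_adapter_seq)
    }
    seed <- substr(adapter, 1L, m0)
    sel <- which(mate == m)
    if (!length(sel)) next
    cand <- sel[stringi::stri_detect_fixed(seq[sel], seed)]
    for (i in cand) {
      s <- seq[i]
      L <- stringi::stri_length(s)
      occ <- stringi::stri_locate_all_fixed(s, seed)[[1]][, 1]
      for (st in occ) {
        k <- L - st + 1L
        if (k < m0) next
        if (stringi::stri_sub(s, st) == substr(adapter, 1L, k)) {
          hit[i] <- TRUE
          break
        }
      }
    }
  }
  hit
}

#' Assess one read against the four filtering criteria
#'
#' @param seq nucleotide string.
#' @param qual Phred+33 quality string of the same length, or an integer
#'   vector of Phred scores.
#' @param mate_index 1 or 2 (selects which adapter the tail is compared to).
#' @param config a [qc_config()].
#' @return a `qc_verdict`: list with `passed` (flag) and `reasons` (subset
#'   of `N_FRACTION`, `MEAN_QUALITY`, `LOW_QUAL_FRACTION`, `ADAPTER`).
#' @export
assess_read <- function(seq, qual, mate_index = 1L, config = qc_config()) {
  if (is.numeric(qual)) qual <- intToUtf8(as.integer(qual) + 33L)
  m <- assess_reads_matrix(seq, qual, mate_index, config)
  reasons <- QC_REASONS[m[1, ]]
  structure(list(passed = length(reasons) == 0L, reasons = reasons),
            class = "qc_verdict")
}

#' Filter read pairs on the four raw-read criteria
#'
#' A pair is removed when either mate fails any criterion; the order of
#' surviving pairs is preserved.
#'
#' @param reads a `read_set` or reads data.frame (`name`, `mate`, `seq`,
#'   `qual`).
#' @param config a [qc_config()].
#' @return list with `reads` (surviving reads data.frame, same layout) and
#'   `report` (a `qc_report`: reads/pairs removed per reason).
#' @export
filter_pairs <- function(reads, config = qc_config()) {
  rs <- NULL
  if (inherits(reads, "read_set")) {
    rs <- reads
    aln <- rs$alignments
    ## as-read orientation for the adapter check; quality and N statistics
    ## are reversal-invariant, so qualities are used as stored
    minus <- !is.na(aln$strand) & aln$strand == "-"
    seqr <- aln$seq
    seqr[minus] <- .revcomp(seqr[minus])
    reads <- fast_df(list(name = aln$qname, mate = aln$mate, seq = seqr,
                          qual = aln$qual))
  }
  fails <- assess_reads_matrix(reads$seq, reads$qual, reads$mate, config)
  read_failed <- rowSums(fails) > 0L
  bad_names <- unique(reads$name[read_failed])
  keep <- !(reads$name %in% bad_names)
  report <- structure(
    list(
      n_reads = nrow(reads),
      n_pairs = length(unique(reads$name)),
      reads_removed_per_reason = colSums(fails),
      reads_removed = sum(read_failed),
      pairs_removed = length(bad_names),
      pairs_passed = length(unique(reads$name[keep]))
    ),
    class = "qc_report"
  )
  if (!is.null(rs)) {
    rs$alignments <- fast_subset(
      rs$alignments, which(!(rs$alignments$qname %in% bad_names))
    )
    return(list(reads = rs, report = report))
  }
  out <- reads[keep, ]
  rownames(out) <- NULL
  list(reads = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s reads in %s pairs\n",
              format(x$n_reads, big.mark = ","),
              format(x$n_pairs, big.mark = ",")))
  for (r in names(x$reads_removed_per_reason)) {
    cat(sprintf("  %-18s %d reads\n", r, x$reads_removed_per_reason[[r]]))
  }
  cat(sprintf("  pairs removed: %d; pairs passing: %d\n",
              x$pairs_removed, x$pairs_passed))
  invisible(x)
}

#' Remove PCR duplicates from coordinate-sorted alignments
#'
#' Pairs sharing (reference, leftmost position of mate 1, leftmost position
#' of mate 2, orientation) are collapsed to the single pair with the highest
#' summed base quality, ties broken by name order. Reads whose mate is
#' unmapped (singletons) are left untouched.
#'
#' @param aln alignment data.frame, coordinate-sorted (see
#'   [sort_alignments()]).
#' @return list with `alignments` (deduplicated, original order) and
#'   `n_removed_pairs`.
#' @export
remove_duplicates <- function(aln) {
  mi <- which(aln$mapped)
  if (length(mi) > 1L) {
    mchr <- aln$chrom[mi]
    grp <- match(mchr, unique(mchr))
    same <- diff(grp) == 0L
    if (is.unsorted(grp) || any(diff(aln$pos[mi])[same] < 0L)) {
      stop("alignments must be coordinate-sorted; see sort_alignments()")
    }
  }
  m1 <- fast_subset(aln, which(aln$mate == 1L))
  both <- which(m1$mapped & !is.na(m1$mchrom) & !is.na(m1$mpos))
  if (!length(both)) {
    return(list(alignments = aln, n_removed_pairs = 0L))
  }
  ## group fully mapped pairs on integer coordinate/orientation columns;
  ## the two fragment ends are taken unordered (as rmdup does), so a
  ## duplicate whose mates swapped read-1/read-2 roles still collapses
  uchr <- unique(c(m1$chrom[both], m1$mchrom[both]))
  c1 <- match(m1$chrom[both], uchr)
  c2 <- match(m1$mchrom[both], uchr)
  p1 <- m1$pos[both]
  p2 <- m1$mpos[both]
  s1 <- m1$strand[both] == "-"
  s2 <- m1$mstrand[both] == "-"
  swap <- c2 < c1 | (c2 == c1 & p2 < p1)
  k1 <- ifelse(swap, c2, c1)
  k2 <- ifelse(swap, c1, c2)
  k3 <- ifelse(swap, s2 + 2L * s1, s1 + 2L * s2)
  k4 <- ifelse(swap, p2, p1)
  k5 <- ifelse(swap, p1, p2)
  ord <- order(k1, k2, k3, k4, k5, method = "radix")
  eq <- diff(k1[ord]) == 0L & diff(k2[ord]) == 0L & diff(k3[ord]) == 0L &
    diff(k4[ord]) == 0L & diff(k5[ord]) == 0L
  grp <- cumsum(c(TRUE, !eq))
  sizes <- tabulate(grp)
  in_shared <- sizes[grp] > 1L
  if (!any(in_shared)) {
    return(list(alignments = aln, n_removed_pairs = 0L))
  }
  cand <- both[ord][in_shared]       # rows of m1 in coordinate-sharing groups
  cand_grp <- grp[in_shared]
  ## keep the highest summed base quality per group, ties by name order
  qn <- m1$qname[cand]
  qsum <- read_qual_sums(fast_subset(aln, which(aln$qname %in% qn)))
  pair_q <- qsum[match(qn, names(qsum))]
  ord2 <- order(cand_grp, -pair_q, qn, method = "radix")
  drop_names <- qn[ord2][duplicated(cand_grp[ord2])]
  out <- fast_subset(aln, which(!(aln$qname %in% drop_names)))
  list(alignments = out, n_removed_pairs = length(drop_names))
}

## summed base quality per pair (by qname)
read_qual_sums <- function(aln) {
  per_read <- .qual_sums(aln$qual)
  sums <- rowsum(per_read, aln$qname)
  setNames(as.numeric(sums), rownames(sums))
}
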
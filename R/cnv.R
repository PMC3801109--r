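## Case/control read-depth CNV detection: fixed 100 bp bins, greedy
## BIC-penalised merging of adjacent segments under a binomial read-origin
## model, and log2-ratio state calls at +-0.2.

#' Count fragment starts in fixed bins for case and control
#'
#' Each mapped, non-duplicate pair is counted once, in the bin containing
#' the leftmost aligned base of the pair (the paired-library reading: the
#' two reads of a fragment are not independent depth observations). Reads
#' whose mate is unmapped are counted at their own leftmost base.
#'
#' Pairs containing a heavily soft-clipped read (10 bp or more) are
#' excluded: clipped reads mark junctions, and counting their anchored
#' halves smears copy-number breakpoints by relocating boundary fragments
#' to the far side of the event.
#'
#' @param case_aln,control_aln alignment data.frames on the same reference.
#' @param chrom_lengths named vector of reference lengths.
#' @param bin_size bin width in bp (default 100).
#' @param max_clip maximum tolerated soft-clipped bases per read.
#' @return a `depth_bins` object: per-chromosome data.frame with `start`,
#'   `end` (0-based half-open), `case_count`, `control_count`.
#' @export
bin_counts <- function(case_aln, control_aln, chrom_lengths, bin_size = 100L,
                       max_clip = 9L) {
  frag_pos <- function(aln) {
    use <- fast_subset(aln, which(aln$mapped & !aln$dup))
    clip <- integer(nrow(use))
    has_s <- which(stringi::stri_detect_fixed(use$cigar, "S"))
    if (length(has_s)) {
      ops <- stringi::stri_extract_all_regex(use$cigar[has_s], "\\d+S")
      clip[has_s] <- vapply(ops, function(o) {
        sum(as.integer(stringi::stri_sub(o, 1, -2)))
      }, integer(1))
    }
    m1 <- use$mate == 1L
    same <- !is.na(use$mchrom) & use$mchrom == use$chrom & !is.na(use$mpos)
    ## the pair is placed at the leftmost read; the placement is discarded
    ## when that read is clipped (its mapped half flanks a junction)
    mate_clip <- clip[match(paste(use$qname, 3L - use$mate),
                            paste(use$qname, use$mate))]
    mate_clip[is.na(mate_clip)] <- 0L
    left_is_self <- !same | use$pos <= use$mpos
    count_clip <- ifelse(left_is_self, clip, mate_clip)
    keep <- (m1 | !same) & count_clip <= max_clip
    pos <- ifelse(same & m1, pmin(use$pos, use$mpos), use$pos)
    data.frame(chrom = use$chrom[keep], pos = pos[keep],
               stringsAsFactors = FALSE)
  }
  count_one <- function(fp, ch, nb) {
    tabulate(pmin((fp$pos[fp$chrom == ch] - 1L) %/% bin_size + 1L, nb),
             nbins = nb)
  }
  for (aln in list(case_aln, control_aln)) {
    bad <- setdiff(unique(aln$chrom[aln$mapped]), names(chrom_lengths))
    if (length(bad)) {
      stop("mismatched reference dictionaries: ", paste(bad, collapse = ", "))
    }
  }
  fp_case <- frag_pos(case_aln)
  fp_control <- frag_pos(control_aln)
  bins <- list()
  for (ch in names(chrom_lengths)) {
    L <- as.integer(chrom_lengths[[ch]])
    nb <- (L + bin_size - 1L) %/% bin_size
    starts <- (seq_len(nb) - 1L) * bin_size
    bins[[ch]] <- data.frame(
      start = starts, end = pmin(starts + bin_size, L),
      case_count = count_one(fp_case, ch, nb),
      control_count = count_one(fp_control, ch, nb)
    )
  }
  structure(list(bins = bins, bin_size = as.integer(bin_size)),
            class = "depth_bins")
}

#' Segment case/control depth bins by greedy BIC merging
#'
#' Within a segment each read is modelled as a case read with a
#' segment-specific probability; the total BIC is `-2*sum(logL) +
#' lambda*k*log(total reads)`. Starting from single bins, adjacent segments
#' are merged greedily -- always the merge with the largest BIC decrease --
#' until no merge decreases the BIC. Segments never span chromosome
#' boundaries. The log2 ratio is library-size normalised:
#' `log2((case/control) * (T_control/T_case))`, with a 0.5 pseudocount
#' added to both sums only when either is zero (flagged).
#'
#' @param bins a `depth_bins` object.
#' @param lambda BIC penalty multiplier (default 2).
#' @param neutral_threshold absolute log2 ratio below which a segment is
#'   neutral (default 0.2).
#' @return a `cnv_segments` data.frame: chrom, start, end (0-based
#'   half-open), counts, log2_ratio, state, pseudocount flag. The per-merge
#'   BIC decreases are kept in the `bic_trace` attribute.
#' @export
segment <- function(bins, lambda = 2, neutral_threshold = 0.2) {
  t_case <- sum(vapply(bins$bins, function(b) sum(b$case_count), numeric(1)))
  t_control <- sum(vapply(bins$bins, function(b) sum(b$control_count),
                          numeric(1)))
  total <- t_case + t_control
  out <- list()
  trace <- numeric(0)
  for (ch in names(bins$bins)) {
    b <- bins$bins[[ch]]
    if (sum(b$case_count) + sum(b$control_count) == 0) {
      warning("chromosome ", ch, " has zero reads; single neutral segment")
      out[[ch]] <- data.frame(
        chrom = ch, start = b$start[1], end = b$end[nrow(b)],
        case_count = 0, control_count = 0, log2_ratio = 0,
        state = "neutral", pseudocount = FALSE, stringsAsFactors = FALSE
      )
      next
    }
    res <- .segment_bins(as.numeric(b$case_count),
                         as.numeric(b$control_count), lambda, total)
    trace <- c(trace, res$bic_trace)
    res <- polish_segments(res, as.numeric(b$case_count),
                           as.numeric(b$control_count), lambda, total)
    seg <- data.frame(
      chrom = ch,
      start = b$start[res$start], end = b$end[res$end],
      case_count = res$case_count, control_count = res$control_count,
      stringsAsFactors = FALSE
    )
    lr <- log2_ratio(seg$case_count, seg$control_count, t_case, t_control)
    seg$log2_ratio <- lr$ratio
    seg$state <- cnv_state(lr$ratio, neutral_threshold)
    seg$pseudocount <- lr$pseudo
    out[[ch]] <- seg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cnv_segments", "data.frame")
  attr(res, "bic_trace") <- trace
  attr(res, "totals") <- c(case = t_case, control = t_control)
  attr(res, "neutral_threshold") <- neutral_threshold
  attr(res, "bin_size") <- bins$bin_size
  res
}

seg_loglik <- function(ka, kb) {
  t <- ka + kb
  out <- numeric(length(ka))
  pos <- t > 0
  a <- ka[pos]
  b <- kb[pos]
  out[pos] <- ifelse(a > 0, a * log(a / t[pos]), 0) +
    ifelse(b > 0, b * log(b / t[pos]), 0)
  out
}

## Greedy bottom-up merging places boundaries only approximately: early
## merges happily straddle a true breakpoint because a single bin carries
## far less evidence than one segment's BIC penalty. This pass alternates
## (a) maximum-likelihood repositioning of each boundary within its two
## flanking segments (segment count unchanged, so no penalty term) and
## (b) re-merging any adjacent pair whose merge now decreases the BIC.
polish_segments <- function(res, ka, kb, lambda, total) {
  penalty <- lambda * log(max(total, 2))
  start <- res$start
  end <- res$end
  ca <- cumsum(ka)
  cb <- cumsum(kb)
  rng_sum <- function(cum, from, to) {
    cum[to] - if (from > 1) cum[from - 1] else 0
  }
  for (iter in 1:10) {
    changed <- FALSE
    ## (a) boundary refinement
    i <- 1L
    while (i < length(start)) {
      lo <- start[i]
      hi <- end[i + 1L]
      if (hi - lo >= 1L) {
        splits <- lo:(hi - 1L)
        a1 <- ca[splits] - if (lo > 1) ca[lo - 1] else 0
        b1 <- cb[splits] - if (lo > 1) cb[lo - 1] else 0
        a2 <- rng_sum(ca, lo, hi) - a1
        b2 <- rng_sum(cb, lo, hi) - b1
        ll <- seg_loglik(a1, b1) + seg_loglik(a2, b2)
        best <- splits[which.max(ll)]
        if (best != end[i]) {
          end[i] <- best
          start[i + 1L] <- best + 1L
          changed <- TRUE
        }
      }
      i <- i + 1L
    }
    ## (b) re-merge adjacent pairs that no longer justify a boundary
    repeat {
      if (length(start) < 2L) break
      a_seg <- ca[end] - c(0, ca[end[-length(end)]])
      b_seg <- cb[end] - c(0, cb[end[-length(end)]])
      ll <- seg_loglik(a_seg, b_seg)
      a_m <- a_seg[-length(a_seg)] + a_seg[-1]
      b_m <- b_seg[-length(b_seg)] + b_seg[-1]
      delta <- -2 * (seg_loglik(a_m, b_m) - ll[-length(ll)] - ll[-1]) -
        penalty
      j <- which.min(delta)
      if (!length(j) || delta[j] >= 0) break
      end[j] <- end[j + 1L]
      start <- start[-(j + 1L)]
      end <- end[-(j + 1L)]
      changed <- TRUE
    }
    if (!changed) break
  }
  a_seg <- ca[end] - c(0, ca[end[-length(end)]])
  b_seg <- cb[end] - c(0, cb[end[-length(end)]])
  list(start = start, end = end, case_count = a_seg, control_count = b_seg)
}

log2_ratio <- function(case_count, control_count, t_case, t_control) {
  pseudo <- case_count == 0 | control_count == 0
  a <- case_count + 0.5 * pseudo
  b <- control_count + 0.5 * pseudo
  list(ratio = log2((a / b) * (t_control / t_case)), pseudo = pseudo)
}

cnv_state <- function(log2r, thr = 0.2) {
  ifelse(log2r < -thr, "deleted", ifelse(log2r > thr, "duplicated", "neutral"))
}

#' Collapse segments into CNV calls
#'
#' Adjacent same-state non-neutral segments are merged; output is BED-like
#' (0-based half-open) with the count-weighted log2 ratio of the merged
#' region.
#'
#' @param segments a `cnv_segments` data.frame from [segment()].
#' @return a `cnv_calls` data.frame: chrom, start, end, log2_ratio, state.
#' @export
call_states <- function(segments) {
  nn <- segments[segments$state != "neutral", , drop = FALSE]
  if (!nrow(nn)) {
    out <- data.frame(
      chrom = character(), start = integer(), end = integer(),
      log2_ratio = numeric(), state = character(), stringsAsFactors = FALSE
    )
    class(out) <- c("cnv_calls", "data.frame")
    return(out)
  }
  totals <- attr(segments, "totals")
  nn <- nn[order(nn$chrom, nn$start), , drop = FALSE]
  new_block <- c(TRUE, !(nn$chrom[-1] == nn$chrom[-nrow(nn)] &
                           nn$state[-1] == nn$state[-nrow(nn)] &
                           nn$start[-1] == nn$end[-nrow(nn)]))
  grp <- cumsum(new_block)
  out <- do.call(rbind, lapply(split(nn, grp), function(g) {
    lr <- log2_ratio(sum(g$case_count), sum(g$control_count),
                     totals["case"], totals["control"])
    data.frame(
      chrom = g$chrom[1], start = g$start[1], end = g$end[nrow(g)],
      log2_ratio = lr$ratio, state = g$state[1], stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("cnv_calls", "data.frame")
  out
}
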
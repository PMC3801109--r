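## Discordant-read-pair structural variant detection: an empirical insert
## model, per-pair discordance classification, clustering with
## size/support/score filters, and somatic subtraction against the donor.

#' Fit the insert-size model from properly oriented pairs
#'
#' Mean and standard deviation of the apparent insert of intra-chromosomal,
#' opposite-strand pairs, trimmed of the top and bottom 1%.
#'
#' @param aln alignment data.frame (both mates mapped).
#' @param sample_n maximum number of pairs used.
#' @param discordance_multiplier how many standard deviations from the mean
#'   count as discordant (default 3).
#' @return an `insert_model` list: `mean`, `sd`, `multiplier`, `n`.
#' @export
fit_insert_model <- function(aln, sample_n = 100000L,
                             discordance_multiplier = 3) {
  m1 <- aln[aln$mate == 1L & aln$mapped & !is.na(aln$mchrom), , drop = FALSE]
  proper <- m1$chrom == m1$mchrom & m1$strand != m1$mstrand
  ins <- abs(m1$isize[proper])
  ins <- ins[ins > 0]
  if (length(ins) < 1000L) {
    stop("fewer than 1,000 usable pairs for insert-model fitting")
  }
  if (length(ins) > sample_n) ins <- ins[seq_len(sample_n)]
  qs <- stats::quantile(ins, c(0.01, 0.99), names = FALSE, type = 1)
  trimmed <- ins[ins >= qs[1] & ins <= qs[2]]
  ## de-bias the SD for the 1% two-sided trim (truncated-normal correction)
  z <- stats::qnorm(0.99)
  corr <- sqrt(1 - 2 * z * stats::dnorm(z) / 0.98)
  structure(
    list(
      mean = mean(trimmed), sd = max(stats::sd(trimmed) / corr, 1),
      multiplier = discordance_multiplier, n = length(trimmed)
    ),
    class = "insert_model"
  )
}

#' @export
print.insert_model <- function(x, ...) {
  cat(sprintf("<insert_model> mean %.1f bp, sd %.1f bp (n = %d, +-%g sd)\n",
              x$mean, x$sd, x$n, x$multiplier))
  invisible(x)
}

#' Classify read pairs as concordant or SV signals
#'
#' Standard discordant-pair taxonomy: `CTX` for mates on different
#' chromosomes, `ITX` for anomalous (same-strand) orientation, `DEL` for an
#' apparent insert above mean + m*sd, `INS` below mean - m*sd, otherwise
#' concordant. Pairs with an unmapped mate are skipped and counted.
#'
#' @param aln alignment data.frame.
#' @param model an `insert_model`.
#' @return an `sv_signals` data.frame (one row per discordant pair): type,
#'   chrom1, pos1, chrom2, pos2, insert; attribute `n_skipped_unmapped`.
#' @export
classify_pairs <- function(aln, model) {
  m1 <- fast_subset(aln, which(aln$mate == 1L))
  m2 <- fast_subset(aln, which(aln$mate == 2L))
  m2 <- fast_subset(m2, match(m1$qname, m2$qname))
  both <- which(m1$mapped & !is.na(m2$mapped) & m2$mapped)
  skipped <- nrow(m1) - length(both)
  m1 <- fast_subset(m1, both)
  m2 <- fast_subset(m2, both)
  lo <- pmin(m1$pos, m2$pos)
  hi <- pmax(m1$pos + cigar_ref_span(m1$cigar) - 1L,
             m2$pos + cigar_ref_span(m2$cigar) - 1L)
  insert <- hi - lo + 1L
  hi_thr <- model$mean + model$multiplier * model$sd
  lo_thr <- model$mean - model$multiplier * model$sd
  type <- rep(NA_character_, nrow(m1))
  ctx <- m1$chrom != m2$chrom
  itx <- !ctx & m1$strand == m2$strand
  del <- !ctx & !itx & insert > hi_thr
  ins <- !ctx & !itx & insert < lo_thr
  type[ctx] <- "CTX"
  type[itx] <- "ITX"
  type[del] <- "DEL"
  type[ins] <- "INS"
  keep <- !is.na(type)
  ## canonical breakpoint order: chromosome name then position for CTX,
  ## left/right along the chromosome otherwise
  swap <- ctx & m1$chrom > m2$chrom
  sig <- data.frame(
    type = type[keep],
    chrom1 = ifelse(ctx, ifelse(swap, m2$chrom, m1$chrom), m1$chrom)[keep],
    pos1 = ifelse(ctx, ifelse(swap, m2$pos, m1$pos), lo)[keep],
    chrom2 = ifelse(ctx, ifelse(swap, m1$chrom, m2$chrom), m1$chrom)[keep],
    pos2 = ifelse(ctx, ifelse(swap, m1$pos, m2$pos), hi)[keep],
    insert = insert[keep],
    stringsAsFactors = FALSE
  )
  class(sig) <- c("sv_signals", "data.frame")
  attr(sig, "n_skipped_unmapped") <- skipped
  attr(sig, "n_pairs") <- nrow(m1)
  sig
}

#' Cluster discordant signals into SV calls
#'
#' Signals of the same type whose breakpoints fall within a window of
#' `mean + m*sd` are clustered. A call is emitted when support reaches
#' `min_support`, the predicted size reaches `min_size`
#' (intra-chromosomal types), and the score reaches `min_score`. The score
#' is a Poisson tail surprise: `-10*log10 P(X >= support)` for the
#' background rate of same-type signals falling in one cluster window.
#'
#' @param signals an `sv_signals` data.frame.
#' @param model the `insert_model` used for classification.
#' @param genome_size total reference length (for the background rate).
#' @param min_support minimum supporting pairs (default 4; the
#'   published threshold of 10 is a config choice).
#' @param min_size minimum predicted size in bp for intra-chromosomal calls
#'   (default 1000).
#' @param min_score minimum score (default 80).
#' @return an `sv_calls` data.frame: type, chrom1, pos1, chrom2, pos2,
#'   size, support, score.
#' @export
cluster_signals <- function(signals, model, genome_size,
                            min_support = 4L, min_size = 1000L,
                            min_score = 80) {
  window <- model$mean + model$multiplier * model$sd
  calls <- list()
  if (nrow(signals)) {
    sp <- split(signals, paste(signals$type, signals$chrom1, signals$chrom2))
    for (grp in sp) {
      grp <- grp[order(grp$pos1), , drop = FALSE]
      new_cl <- c(TRUE, diff(grp$pos1) > window)
      cl <- cumsum(new_cl)
      for (g in split(grp, cl)) {
        ## both breakpoints must agree within the window
        g <- g[abs(g$pos2 - stats::median(g$pos2)) <= window, , drop = FALSE]
        if (!nrow(g)) next
        support <- nrow(g)
        type <- g$type[1]
        size <- if (type == "DEL") {
          max(round(stats::median(g$insert) - model$mean), 0)
        } else if (type == "INS") {
          max(round(model$mean - stats::median(g$insert)), 0)
        } else if (type == "ITX") {
          round(stats::median(g$pos2 - g$pos1))
        } else 0L
        bg_rate <- nrow(signals[signals$type == type, , drop = FALSE]) /
          max(genome_size, 1)
        mu <- bg_rate * window
        logp <- ppois(support - 1L, mu, lower.tail = FALSE, log.p = TRUE)
        score <- min(-10 * logp / log(10), 10000)
        calls[[length(calls) + 1L]] <- data.frame(
          type = type, chrom1 = g$chrom1[1],
          pos1 = round(stats::median(g$pos1)),
          chrom2 = g$chrom2[1], pos2 = round(stats::median(g$pos2)),
          size = size, support = support, score = score,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else data.frame(
    type = character(), chrom1 = character(), pos1 = integer(),
    chrom2 = character(), pos2 = integer(), size = numeric(),
    support = integer(), score = numeric(), stringsAsFactors = FALSE
  )
  intra <- out$type %in% c("DEL", "INS", "ITX")
  keep <- out$support >= min_support & out$score >= min_score &
    (!intra | out$size >= min_size)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$chrom1, out$pos1), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sv_calls", "data.frame")
  out
}

#' Somatic SV subtraction against the donor
#'
#' A clone call is somatic iff no donor call of the same type has both
#' breakpoints within `match_window`.
#'
#' @param clone_calls,donor_calls `sv_calls` data.frames.
#' @param match_window breakpoint tolerance in bp (default 1000).
#' @return the somatic subset of `clone_calls`; attributes `n_total` and
#'   `n_somatic`.
#' @export
somatic_svs <- function(clone_calls, donor_calls, match_window = 1000L) {
  somatic <- rep(TRUE, nrow(clone_calls))
  for (i in seq_len(nrow(clone_calls))) {
    cc <- clone_calls[i, ]
    hit <- donor_calls$type == cc$type &
      donor_calls$chrom1 == cc$chrom1 & donor_calls$chrom2 == cc$chrom2 &
      abs(donor_calls$pos1 - cc$pos1) <= match_window &
      abs(donor_calls$pos2 - cc$pos2) <= match_window
    if (any(hit)) somatic[i] <- FALSE
  }
  out <- clone_calls[somatic, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sv_calls", "data.frame")
  attr(out, "n_total") <- nrow(clone_calls)
  attr(out, "n_somatic") <- nrow(out)
  out
}
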
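## Somatic mutation rate over the callable region, and the substitution
## spectrum.

#' Somatic mutation rate over the callable region
#'
#' Counts SNV events whose position lies inside the callable mask and
#' divides by the mask size: variants per megabase of sufficiently covered
#' (depth 5-200) sequence. Indels are excluded: the headline rate is
#' per-SNV.
#'
#' @param events a `somatic_events` data.frame.
#' @param mask a `callable_mask` (typically the intersection of the clone
#'   and donor masks, since somatic detection requires both).
#' @return a `mutation_rate` list: `n_variants`, `callable_bases`,
#'   `rate_per_mb`.
#' @export
mutation_rate <- function(events, mask) {
  if (mask$n_bases == 0) stop("empty callable mask: rate undefined")
  snv <- events[events$kind == "SNV", , drop = FALSE]
  inside <- if (nrow(snv)) {
    sum(mask_contains(mask, snv$chrom, snv$pos))
  } else 0L
  structure(
    list(
      n_variants = inside,
      callable_bases = mask$n_bases,
      rate_per_mb = inside / (mask$n_bases / 1e6)
    ),
    class = "mutation_rate"
  )
}

#' @export
print.mutation_rate <- function(x, ...) {
  cat(sprintf(
    "<mutation_rate> %d SNVs / %s callable bases = %.2f per Mb\n",
    x$n_variants, format(x$callable_bases, big.mark = ","), x$rate_per_mb
  ))
  invisible(x)
}

SUBSTITUTION_TYPES <- c(
  "A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
  "G>A", "G>C", "G>T", "T>A", "T>C", "T>G"
)
TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Substitution spectrum of SNV events
#'
#' Tallies the 12 directed substitution types, collapses them to 6
#' strand-symmetrised types (each paired with its reverse complement), and
#' reports the transition fraction (A>G, G>A, C>T, T>C over all).
#'
#' @param events a `somatic_events` data.frame containing only SNVs.
#' @return a `substitution_spectrum` list: `counts12`, `counts6`,
#'   `transition_fraction`, `n`.
#' @export
spectrum <- function(events) {
  if (nrow(events) && any(events$kind != "SNV")) {
    stop("spectrum() accepts SNV events only")
  }
  types <- paste0(events$ref, ">", events$alt)
  counts12 <- table(factor(types, levels = SUBSTITUTION_TYPES))
  rc <- function(t) {
    paste0(chartr("ACGT", "TGCA", substr(t, 1, 1)), ">",
           chartr("ACGT", "TGCA", substr(t, 3, 3)))
  }
  pyr <- SUBSTITUTION_TYPES[substr(SUBSTITUTION_TYPES, 1, 1) %in% c("C", "T")]
  counts6 <- setNames(
    vapply(pyr, function(t) counts12[[t]] + counts12[[rc(t)]], numeric(1)),
    pyr
  )
  n <- sum(counts12)
  structure(
    list(
      counts12 = counts12, counts6 = counts6,
      transition_fraction = if (n > 0) {
        sum(counts12[TRANSITIONS]) / n
      } else NA_real_,
      n = n
    ),
    class = "substitution_spectrum"
  )
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat(sprintf("<substitution_spectrum> %d SNVs, transition fraction %.3f\n",
              x$n, x$transition_fraction))
  print(x$counts6)
  invisible(x)
}
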
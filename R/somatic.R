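## Somatic (post-cloning de novo) variant detection: paired subtraction of
## clone calls against the donor, a Fisher exact allele-count filter
## (events with p > alpha are filtered out), compartment classification and
## coding-effect annotation.

#' Two-sided Fisher exact test on 2x2 allele-count tables
#'
#' Exact hypergeometric enumeration: with margins fixed, the p-value is the
#' sum of probabilities of all tables whose probability does not exceed the
#' observed table's (with the customary 1e-7 relative tolerance for ties).
#' Vectorised over tables `[[clone_ref, clone_alt], [donor_ref, donor_alt]]`.
#'
#' @param clone_ref,clone_alt,donor_ref,donor_alt non-negative counts.
#' @return numeric vector of p-values; `NA` where a margin is zero.
#' @export
fisher_exact_test <- function(clone_ref, clone_alt, donor_ref, donor_alt) {
  n <- length(clone_ref)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- clone_ref[i]
    b <- clone_alt[i]
    c_ <- donor_ref[i]
    d <- donor_alt[i]
    k <- a + b             # clone row total
    m <- b + d             # alt column total
    nn <- a + c_           # ref column total
    if (k == 0L || c_ + d == 0L || m == 0L && nn == 0L) next
    x <- max(0L, k - nn):min(k, m)
    dens <- dhyper(x, m, nn, k)
    obs <- dhyper(b, m, nn, k)
    p[i] <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  p
}

#' Classify a chromosome into a genomic compartment
#'
#' @param chrom character vector of chromosome names.
#' @param aliases optional named character vector mapping extra contig
#'   names to `"autosomal"`, `"sex"` or `"mitochondrial"`.
#' @return character vector in `{autosomal, sex, mitochondrial}`.
#' @export
classify_compartment <- function(chrom, aliases = NULL) {
  out <- rep(NA_character_, length(chrom))
  norm <- sub("^chr", "", chrom)
  out[grepl("^[0-9]+$", norm)] <- "autosomal"
  out[norm %in% c("X", "Y")] <- "sex"
  out[norm %in% c("M", "MT")] <- "mitochondrial"
  if (!is.null(aliases)) {
    hit <- chrom %in% names(aliases)
    out[hit] <- aliases[chrom[hit]]
  }
  if (anyNA(out)) {
    stop("cannot classify contig(s): ",
         paste(unique(chrom[is.na(out)]), collapse = ", "))
  }
  out
}

#' Paired subtraction of clone calls against the donor
#'
#' A clone call is a somatic candidate iff no donor call exists at the same
#' site with the same alternate allele AND the donor site is callable
#' (depth within the calling range) AND the donor pileup shows no more than
#' `max_donor_alt` reads supporting the same alternate allele. The last
#' rule is the paired-caller convention for the nuclear donor standing in
#' for a "normal" sample: at a genuinely heterozygous germline site the
#' donor occasionally draws too few alternate reads for a confident call,
#' and even a single donor alternate read is then far better evidence of a
#' shared germline allele than of a coincidental error. Donor allele
#' counts at each site are attached for the downstream Fisher filter.
#'
#' @param clone_calls,donor_calls `variant_calls` data.frames (SNVs and/or
#'   indels; indels are matched by position and alternate allele).
#' @param donor_ps donor `pileup_set` covering the clone-call chromosomes.
#' @param donor_mask donor `callable_mask`.
#' @param max_donor_alt maximum donor reads supporting the clone's
#'   alternate allele before the candidate is rejected as germline
#'   (default 0).
#' @param min_donor_depth minimum donor read depth at the site for the
#'   comparison to count as resolved (default 8, the minimum-coverage
#'   default of the classic somatic caller this stage emulates); shallower
#'   sites are suppressed as unresolvable.
#' @return a `somatic_events` data.frame (fisher_p unset; see
#'   [fisher_somatic_filter()]); attributes `n_unresolvable` (candidates
#'   suppressed for donor uncallability) and `n_germline_evidence`
#'   (rejected for donor alternate support).
#' @export
subtract_paired <- function(clone_calls, donor_calls, donor_ps, donor_mask,
                            max_donor_alt = 0L, min_donor_depth = 8L) {
  if (!nrow(clone_calls)) {
    return(empty_events())
  }
  if (!("kind" %in% names(clone_calls))) {
    clone_calls$kind <- "SNV"
  }
  if (nrow(donor_calls) && !("kind" %in% names(donor_calls))) {
    donor_calls$kind <- "SNV"
  }
  key <- function(df) paste(df$chrom, df$pos, df$alt, sep = ":")
  cand <- clone_calls[!(key(clone_calls) %in% key(donor_calls)), ,
                      drop = FALSE]
  callable <- mask_contains(donor_mask, cand$chrom, cand$pos)
  n_unres <- sum(!callable)
  cand <- cand[callable, , drop = FALSE]
  if (!nrow(cand)) {
    ev <- empty_events()
    attr(ev, "n_unresolvable") <- n_unres
    return(ev)
  }
  donor_ref <- donor_alt <- integer(nrow(cand))
  for (ch in unique(cand$chrom)) {
    p <- donor_ps$chroms[[ch]]
    if (is.null(p)) stop("donor pileup missing chromosome ", ch)
    sel <- which(cand$chrom == ch)
    snv <- sel[cand$kind[sel] == "SNV"]
    if (length(snv)) {
      ri <- base_indices(paste(cand$ref[snv], collapse = ""))
      ai <- base_indices(paste(substr(cand$alt[snv], 1, 1), collapse = ""))
      donor_ref[snv] <- p$counts[cbind(ri, cand$pos[snv])]
      donor_alt[snv] <- p$counts[cbind(ai, cand$pos[snv])]
    }
    ind <- sel[cand$kind[sel] != "SNV"]
    for (i in ind) {
      allele <- if (cand$kind[i] == "INS") {
        paste0("+", substring(cand$alt[i], 2L))
      } else {
        paste0("-", nchar(cand$ref[i]))
      }
      hit <- p$indels$pos == cand$pos[i] & p$indels$allele == allele
      sup <- if (any(hit)) sum(p$indels$count[hit]) else 0L
      donor_alt[i] <- sup
      donor_ref[i] <- max(p$depth[cand$pos[i]] - sup, 0L)
    }
  }
  shallow <- (donor_ref + donor_alt) < min_donor_depth
  n_unres <- n_unres + sum(shallow)
  germline <- !shallow & donor_alt > max_donor_alt
  ev <- data.frame(
    chrom = cand$chrom, pos = cand$pos, ref = cand$ref, alt = cand$alt,
    kind = cand$kind, compartment = classify_compartment(cand$chrom),
    genotype = cand$genotype,
    clone_ref = cand$ref_count, clone_alt = cand$alt_count,
    donor_ref = donor_ref, donor_alt = donor_alt,
    fisher_p = NA_real_, effect = NA_character_,
    amino_change = NA_character_, stringsAsFactors = FALSE
  )
  ev <- ev[!germline & !shallow, , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("somatic_events", "data.frame")
  attr(ev, "n_unresolvable") <- n_unres
  attr(ev, "n_germline_evidence") <- sum(germline)
  ev
}

empty_events <- function() {
  ev <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), kind = character(), compartment = character(),
    genotype = character(), clone_ref = integer(), clone_alt = integer(),
    donor_ref = integer(), donor_alt = integer(), fisher_p = numeric(),
    effect = character(), amino_change = character(),
    stringsAsFactors = FALSE
  )
  class(ev) <- c("somatic_events", "data.frame")
  attr(ev, "n_unresolvable") <- 0L
  ev
}

#' Fisher exact allele-count filter for somatic candidates
#'
#' Tests each candidate's 2x2 table
#' `[[clone_ref, clone_alt], [donor_ref, donor_alt]]`; events with
#' `p > alpha` are filtered out (the allele counts do not differ enough
#' between the samples to support a clone-only variant). Events with a
#' zero-depth margin are dropped with a reason.
#'
#' @param events a `somatic_events` data.frame.
#' @param alpha significance threshold (default 0.05).
#' @return the retained events with `fisher_p` filled in; attributes
#'   `n_dropped_p` and `n_dropped_zero_margin` count removals.
#' @export
fisher_somatic_filter <- function(events, alpha = 0.05) {
  if (!nrow(events)) {
    attr(events, "n_dropped_p") <- 0L
    attr(events, "n_dropped_zero_margin") <- 0L
    return(events)
  }
  p <- fisher_exact_test(events$clone_ref, events$clone_alt,
                         events$donor_ref, events$donor_alt)
  zero <- is.na(p)
  keep <- !zero & p <= alpha
  out <- events[keep, , drop = FALSE]
  out$fisher_p <- p[keep]
  rownames(out) <- NULL
  class(out) <- c("somatic_events", "data.frame")
  attr(out, "n_unresolvable") <- attr(events, "n_unresolvable") %||% 0L
  attr(out, "n_dropped_p") <- sum(!keep & !zero)
  attr(out, "n_dropped_zero_margin") <- sum(zero)
  out
}

#' Annotate coding effects of somatic events
#'
#' SNVs inside a CDS are translated (strand-aware, standard genetic code):
#' identical amino acid means synonymous, otherwise nonsynonymous with an
#' amino-change string like `"K811E"`. SNVs outside any CDS are noncoding.
#' Indels inside a CDS are flagged (`effect` NA, `coding_indel` TRUE); a
#' reference codon containing an internal stop draws a warning and NA.
#'
#' @param events a `somatic_events` data.frame.
#' @param gene_models gene-model data.frame (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `exon_rank`), one row per CDS exon, CDS length
#'   divisible by 3.
#' @param reference named character vector of reference sequences.
#' @return events with `effect`, `amino_change` and `coding_indel` filled.
#' @export
annotate_effect <- function(events, gene_models, reference) {
  if (!nrow(events)) {
    events$coding_indel <- logical(0)
    return(events)
  }
  events$effect <- "noncoding"
  events$amino_change <- ""
  events$coding_indel <- FALSE
  if (is.null(gene_models) || !nrow(gene_models)) return(events)
  genes <- split(gene_models, gene_models$gene_id)
  for (g in genes) {
    g <- g[order(g$start), , drop = FALSE]
    cds_len <- sum(g$end - g$start + 1L)
    if (cds_len %% 3L != 0L) {
      warning("CDS length of ", g$gene_id[1], " not divisible by 3; skipped")
      next
    }
    minus <- g$strand[1] == "-"
    hit <- which(events$chrom == g$chrom[1] &
                   events$pos >= min(g$start) & events$pos <= max(g$end))
    for (i in hit) {
      pos <- events$pos[i]
      ex <- which(pos >= g$start & pos <= g$end)[1]
      if (is.na(ex)) next  # intronic
      if (events$kind[i] != "SNV") {
        events$effect[i] <- NA_character_
        events$coding_indel[i] <- TRUE
        next
      }
      ## CDS-local 1-based coordinate in translation order
      if (!minus) {
        before <- if (ex > 1L) sum(g$end[seq_len(ex - 1L)] -
                                     g$start[seq_len(ex - 1L)] + 1L) else 0L
        cpos <- before + (pos - g$start[ex] + 1L)
      } else {
        after <- if (ex < nrow(g)) sum(g$end[seq(ex + 1L, nrow(g))] -
                                         g$start[seq(ex + 1L, nrow(g))] + 1L) else 0L
        cpos <- after + (g$end[ex] - pos + 1L)
      }
      codon_i <- (cpos - 1L) %/% 3L + 1L
      off_in_codon <- (cpos - 1L) %% 3L + 1L
      cds_pos <- cds_coords(g, minus)
      codon_ref_pos <- cds_pos[(codon_i - 1L) * 3L + 1:3]
      ref_codon <- paste(substring_bases(reference[[g$chrom[1]]],
                                         codon_ref_pos), collapse = "")
      if (minus) ref_codon <- chartr("ACGT", "TGCA", ref_codon)
      alt_base <- events$alt[i]
      if (minus) alt_base <- chartr("ACGT", "TGCA", alt_base)
      alt_codon <- ref_codon
      substr(alt_codon, off_in_codon, off_in_codon) <- alt_base
      gc_tab <- Biostrings::GENETIC_CODE
      aa_ref <- unname(gc_tab[ref_codon])
      aa_alt <- unname(gc_tab[alt_codon])
      if (is.na(aa_ref) || (aa_ref == "*" && codon_i < cds_len / 3L)) {
        warning("internal stop codon in reference CDS of ", g$gene_id[1])
        events$effect[i] <- NA_character_
        next
      }
      if (aa_ref == aa_alt) {
        events$effect[i] <- "synonymous"
      } else {
        events$effect[i] <- "nonsynonymous"
        events$amino_change[i] <- paste0(aa_ref, codon_i, aa_alt)
      }
    }
  }
  events
}

## reference positions of the CDS in translation order
cds_coords <- function(g, minus) {
  pos <- unlist(lapply(seq_len(nrow(g)), function(k) g$start[k]:g$end[k]))
  if (minus) rev(pos) else pos
}

#' @export
print.somatic_events <- function(x, ...) {
  cat(sprintf("<somatic_events> %d events", nrow(x)))
  if (nrow(x)) {
    tab <- table(x$compartment)
    cat(" (", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  n_un <- attr(x, "n_unresolvable")
  if (!is.null(n_un) && n_un > 0) {
    cat("  candidates unresolvable in donor:", n_un, "\n")
  }
  invisible(x)
}

#' Per-event pileup snippet for manual review
#'
#' Textual stand-in for interactive tview inspection: shows the clone and
#' donor base tallies around an event.
#'
#' @param event one row of a `somatic_events` data.frame.
#' @param clone_ps,donor_ps `pileup_set`s covering the event.
#' @param reference named character vector of reference sequences.
#' @param window flank size in bp.
#' @return character vector of report lines.
#' @export
event_snippet <- function(event, clone_ps, donor_ps, reference, window = 5L) {
  ch <- event$chrom
  rng <- max(1L, event$pos - window):(event$pos + window)
  ref <- substring_bases(reference[[ch]], rng)
  fmt <- function(ps, label) {
    cnt <- ps$chroms[[ch]]$counts[, rng, drop = FALSE]
    paste0(label, ": ", paste(apply(cnt, 2, function(cc) {
      paste0(DNA_BASES[cc > 0], cc[cc > 0], collapse = ",")
    }), collapse = " | "))
  }
  c(
    sprintf("%s:%d %s>%s (%s)", ch, event$pos, event$ref, event$alt,
            event$compartment),
    paste0("ref:   ", paste(ref, collapse = "      ")),
    fmt(clone_ps, "clone"), fmt(donor_ps, "donor")
  )
}
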
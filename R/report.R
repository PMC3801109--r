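## Pipeline orchestration and the Table-1-style comparison summary.

#' Build the clone/donor comparison summary
#'
#' Totals and compartment breakdowns are computed only from the event
#' streams (never entered independently), so the breakdown-sum invariants
#' hold by construction. The somatic SV fraction is
#' `100 * n_somatic_sv / n_total_sv_clone`, rounded half-up to one decimal.
#'
#' @param somatic_events a `somatic_events` data.frame (SNVs and indels).
#' @param rate optional `mutation_rate`.
#' @param spectrum optional `substitution_spectrum`.
#' @param cnv_calls optional somatic CNV calls (`cnv_calls`).
#' @param sv_clone,sv_donor optional total SV call sets per sample.
#' @param sv_somatic optional somatic SV call set.
#' @param telomere optional `telomere_comparison`.
#' @param sample_names clone/donor labels.
#' @return a `comparison_summary` list.
#' @export
build_summary <- function(somatic_events,
                          rate = NULL, spectrum = NULL,
                          cnv_calls = NULL,
                          sv_clone = NULL, sv_donor = NULL,
                          sv_somatic = NULL, telomere = NULL,
                          sample_names = c(clone = "clone", donor = "donor")) {
  breakdown <- function(ev) {
    comp <- factor(ev$compartment,
                   levels = c("autosomal", "sex", "mitochondrial"))
    tab <- table(comp)
    list(total = nrow(ev), autosomal = unname(tab[["autosomal"]]),
         sex = unname(tab[["sex"]]),
         mitochondrial = unname(tab[["mitochondrial"]]))
  }
  snv <- breakdown(somatic_events[somatic_events$kind == "SNV", , drop = FALSE])
  indel <- breakdown(somatic_events[somatic_events$kind != "SNV", , drop = FALSE])
  nssnv <- sum(
    somatic_events$kind == "SNV" &
      somatic_events$compartment == "autosomal" &
      !is.na(somatic_events$effect) &
      somatic_events$effect == "nonsynonymous"
  )
  n_sv_clone <- if (!is.null(sv_clone)) nrow(sv_clone) else NA_integer_
  n_sv_donor <- if (!is.null(sv_donor)) nrow(sv_donor) else NA_integer_
  n_sv_somatic <- if (!is.null(sv_somatic)) nrow(sv_somatic) else NA_integer_
  sv_fraction <- if (!is.na(n_sv_somatic) && !is.na(n_sv_clone) &&
                     n_sv_clone > 0) {
    round_half_up(100 * n_sv_somatic / n_sv_clone, 1)
  } else NA_real_
  structure(
    list(
      samples = as.list(sample_names),
      n_somatic_snv = snv,
      n_somatic_indel = indel,
      somatic_rate_per_mb = if (!is.null(rate)) {
        round(rate$rate_per_mb, 2)
      } else NA_real_,
      callable_bases = if (!is.null(rate)) rate$callable_bases else NA_real_,
      transition_fraction = if (!is.null(spectrum)) {
        spectrum$transition_fraction
      } else NA_real_,
      n_somatic_nssnv = nssnv,
      n_somatic_cnv = if (!is.null(cnv_calls)) nrow(cnv_calls) else NA_integer_,
      n_somatic_sv = n_sv_somatic,
      n_total_sv_clone = n_sv_clone,
      n_total_sv_donor = n_sv_donor,
      somatic_sv_fraction = sv_fraction,
      telomere_ratio = if (!is.null(telomere)) telomere$ratio else NA_real_
    ),
    class = "comparison_summary"
  )
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("<comparison_summary>", x$samples$clone, "vs", x$samples$donor, "\n")
  fmt_bd <- function(b) {
    sprintf("%d (%d autosomal, %d sex, %d mitochondrial)",
            b$total, b$autosomal, b$sex, b$mitochondrial)
  }
  cat("  somatic SNV:            ", fmt_bd(x$n_somatic_snv), "\n")
  cat("  somatic indel:          ", fmt_bd(x$n_somatic_indel), "\n")
  cat(sprintf("  somatic rate (/Mb):      %.2f\n", x$somatic_rate_per_mb))
  cat(sprintf("  transition fraction:     %.3f\n", x$transition_fraction))
  cat("  somatic nsSNV:          ", x$n_somatic_nssnv, "\n")
  cat("  somatic CNV:            ", x$n_somatic_cnv, "\n")
  cat(sprintf("  somatic SV:              %s of %s clone signals (%.1f%%)\n",
              x$n_somatic_sv, x$n_total_sv_clone, x$somatic_sv_fraction))
  cat(sprintf("  telomere ratio:          %.3f\n", x$telomere_ratio))
  invisible(x)
}

#' Write a comparison summary as JSON and TSV
#' @param summary a `comparison_summary`.
#' @param json_path,tsv_path output paths (either may be NULL).
#' @export
write_summary <- function(summary, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  if (!is.null(tsv_path)) {
    flat <- unlist(unclass(summary))
    write.table(
      data.frame(key = names(flat), value = unname(flat)),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(summary)
}

#' Re-read a summary written by [write_summary()]
#' @param json_path JSON path.
#' @export
read_summary <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  x <- rapply(x, function(v) if (is.null(v)) NA else v, how = "replace")
  class(x) <- "comparison_summary"
  x
}

#' Paired clone/donor analysis of simulated or supplied read sets
#'
#' Runs the analysis stages in order on two read sets: read QC, duplicate
#' removal, per-chromosome pileup and genotype/indel calling, paired
#' somatic subtraction with the Fisher filter, coding-effect annotation,
#' mutation rate and spectrum over the intersected callable region,
#' read-depth CNV segmentation (clone as case, donor as control),
#' discordant-pair SV calling with somatic subtraction, and telomere
#' estimation.
#'
#' @param clone_reads,donor_reads `read_set` objects (see
#'   [simulate_reads()]).
#' @param reference named character vector of reference sequences.
#' @param genes optional gene-model data.frame for effect annotation.
#' @param qc a [qc_config()].
#' @param theta,min_depth,max_depth,min_gq genotype-calling contract.
#' @param alpha Fisher filter threshold.
#' @param cnv_lambda BIC penalty multiplier.
#' @param cnv_bin_size CNV bin width in bp.
#' @param sv_min_support,sv_min_size,sv_min_score SV call filters.
#' @param sv_match_window somatic SV breakpoint match window in bp.
#' @param telomere_k headline tandem multiplicity.
#' @param stages character vector of optional stages to run; subset of
#'   `c("variants", "cnv", "sv", "telomere")`.
#' @return a `pair_analysis` list with per-stage results and a
#'   `comparison_summary`.
#' @export
analyze_pair <- function(clone_reads, donor_reads, reference, genes = NULL,
                         qc = qc_config(), theta = 0.001,
                         min_depth = 5L, max_depth = 200L, min_gq = 10,
                         alpha = 0.05, cnv_lambda = 2, cnv_bin_size = 100L,
                         sv_min_support = 4L, sv_min_size = 1000L,
                         sv_min_score = 80, sv_match_window = 1000L,
                         telomere_k = 4L,
                         stages = c("variants", "cnv", "sv", "telomere")) {
  lens <- setNames(nchar(reference), names(reference))

  prep_clone <- prepare_sample(clone_reads, qc)
  rm(clone_reads)
  prep_donor <- prepare_sample(donor_reads, qc)
  rm(donor_reads)
  gc(FALSE)
  aln_clone <- prep_clone$alignments
  aln_donor <- prep_donor$alignments

  ## telomere estimation first, while read sequences are still in memory
  telo <- NULL
  if ("telomere" %in% stages) {
    est_c <- telomere_estimate(aln_clone$seq)
    est_d <- telomere_estimate(aln_donor$seq)
    telo <- list(
      clone = est_c, donor = est_d,
      comparison = compare_samples(est_c, est_d, telomere_k)
    )
  }

  events <- empty_events()
  clone_runs <- list()
  donor_runs <- list()
  if ("variants" %in% stages) {
    n_unres <- 0L
    ev_list <- list()
    for (ch in names(lens)) {
      ps_c <- pileup(aln_clone, reference, chroms = ch)
      ps_d <- pileup(aln_donor, reference, chroms = ch)
      calls_c <- rbind_calls(
        call_genotypes(ps_c, reference, theta, min_depth, max_depth, min_gq),
        call_indels(ps_c, reference, min_depth = min_depth,
                    max_depth = max_depth)
      )
      calls_d <- rbind_calls(
        call_genotypes(ps_d, reference, theta, min_depth, max_depth, min_gq),
        call_indels(ps_d, reference, min_depth = min_depth,
                    max_depth = max_depth)
      )
      mask_c <- callable_region(ps_c, min_depth, max_depth)
      mask_d <- callable_region(ps_d, min_depth, max_depth)
      ev <- subtract_paired(calls_c, calls_d, ps_d, mask_d)
      n_unres <- n_unres + (attr(ev, "n_unresolvable") %||% 0L)
      ev_list[[ch]] <- ev
      clone_runs[[ch]] <- mask_c$runs[[ch]]
      donor_runs[[ch]] <- mask_d$runs[[ch]]
      rm(ps_c, ps_d)
      gc(FALSE)
    }
    events <- do.call(rbind, ev_list)
    class(events) <- c("somatic_events", "data.frame")
    attr(events, "n_unresolvable") <- n_unres
    events <- fisher_somatic_filter(events, alpha)
    events <- annotate_effect(events, genes, reference)
  }
  mk_mask <- function(runs) {
    structure(
      list(runs = runs, n_bases = sum(vapply(runs, function(r) {
        sum(r$end - r$start + 1L)
      }, numeric(1)))),
      class = "callable_mask"
    )
  }
  clone_mask <- mk_mask(clone_runs)
  donor_mask <- mk_mask(donor_runs)

  rate <- NULL
  spec_ <- NULL
  if ("variants" %in% stages) {
    shared <- mask_intersect(clone_mask, donor_mask)
    rate <- mutation_rate(events, shared)
    spec_ <- spectrum(events[events$kind == "SNV", , drop = FALSE])
  }

  ## sequences are no longer needed; drop them before the depth/pair stages
  aln_clone$seq <- aln_clone$qual <- NULL
  aln_donor$seq <- aln_donor$qual <- NULL
  prep_clone$alignments <- prep_donor$alignments <- NULL
  gc(FALSE)

  cnv <- NULL
  segments <- NULL
  if ("cnv" %in% stages) {
    bins <- bin_counts(aln_clone, aln_donor, lens, cnv_bin_size)
    segments <- segment(bins, lambda = cnv_lambda)
    cnv <- call_states(segments)
  }

  sv <- NULL
  if ("sv" %in% stages) {
    gsize <- sum(lens)
    model_c <- fit_insert_model(aln_clone)
    model_d <- fit_insert_model(aln_donor)
    sig_c <- classify_pairs(aln_clone, model_c)
    sig_d <- classify_pairs(aln_donor, model_d)
    calls_c <- cluster_signals(sig_c, model_c, gsize, sv_min_support,
                               sv_min_size, sv_min_score)
    calls_d <- cluster_signals(sig_d, model_d, gsize, sv_min_support,
                               sv_min_size, sv_min_score)
    sv <- list(
      clone = calls_c, donor = calls_d,
      somatic = somatic_svs(calls_c, calls_d, sv_match_window),
      insert_model_clone = model_c, insert_model_donor = model_d
    )
  }

  summary <- build_summary(
    events, rate = rate, spectrum = spec_,
    cnv_calls = cnv,
    sv_clone = if (!is.null(sv)) sv$clone else NULL,
    sv_donor = if (!is.null(sv)) sv$donor else NULL,
    sv_somatic = if (!is.null(sv)) sv$somatic else NULL,
    telomere = if (!is.null(telo)) telo$comparison else NULL,
    sample_names = c(clone = prep_clone$sample, donor = prep_donor$sample)
  )
  structure(
    list(
      summary = summary, somatic = events, rate = rate, spectrum = spec_,
      cnv = cnv, cnv_segments = segments, sv = sv, telomere = telo,
      qc = list(clone = prep_clone$qc_report, donor = prep_donor$qc_report),
      dedup = list(clone = prep_clone$n_duplicate_pairs,
                   donor = prep_donor$n_duplicate_pairs),
      masks = list(clone = clone_mask, donor = donor_mask)
    ),
    class = "pair_analysis"
  )
}

#' QC-filter, sort and deduplicate one sample's reads
#'
#' Applies the four raw-read criteria pair-wise, coordinate-sorts the
#' surviving alignments and removes PCR duplicates. [analyze_pair()] runs
#' this automatically; pre-preparing samples lets a caller free the raw
#' read set (or reuse a prepared donor across replicates).
#'
#' @param reads a `read_set` (or an already prepared sample, returned
#'   unchanged).
#' @param qc a [qc_config()].
#' @return a `prepped_sample`: `sample`, `alignments` (analysis-ready),
#'   `qc_report`, `n_duplicate_pairs`.
#' @export
prepare_sample <- function(reads, qc = qc_config()) {
  if (inherits(reads, "prepped_sample")) return(reads)
  filt <- filter_pairs(reads, qc)
  aln <- sort_alignments(filt$reads$alignments)
  dd <- remove_duplicates(aln)
  structure(
    list(sample = reads$sample, alignments = dd$alignments,
         qc_report = filt$report, n_duplicate_pairs = dd$n_removed_pairs),
    class = "prepped_sample"
  )
}

rbind_calls <- function(a, b) {
  if (!nrow(b)) {
    a$kind <- if (nrow(a)) "SNV" else character(0)
    return(a)
  }
  if (nrow(a)) a$kind <- "SNV"
  a$gq <- as.numeric(a$gq)
  cols <- union(names(a), names(b))
  for (cc in setdiff(cols, names(a))) a[[cc]] <- NA
  for (cc in setdiff(cols, names(b))) b[[cc]] <- NA
  out <- rbind(a[cols], b[cols])
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' @export
print.pair_analysis <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Run the full simulation-to-summary pipeline
#'
#' Simulates the donor genome, derives the clone, sequences both samples,
#' runs [analyze_pair()], and optionally writes FASTQ/SAM/VCF/TSV/JSON
#' outputs. Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory; created if missing.
#' @param ... passed to [analyze_pair()].
#' @return a `pair_analysis` with the genome models and read sets attached
#'   (`$donor_genome`, `$clone_genome`, `$truth`).
#' @export
run_pipeline <- function(config, out_dir = NULL, ...) {
  donor <- build_donor_genome(config)
  clone <- derive_clone_genome(donor, config)
  dots <- list(...)
  qc <- dots$qc %||% qc_config()
  keep_reads <- !is.null(out_dir)
  clone_reads <- simulate_reads(clone, sample_tag = "clone")
  if (keep_reads) raw_clone <- clone_reads
  clone_prep <- prepare_sample(clone_reads, qc)
  rm(clone_reads)
  gc(FALSE)
  donor_reads <- simulate_reads(donor, sample_tag = "donor")
  if (keep_reads) raw_donor <- donor_reads
  donor_prep <- prepare_sample(donor_reads, qc)
  rm(donor_reads)
  gc(FALSE)
  res <- analyze_pair(clone_prep, donor_prep, donor$reference,
                      genes = donor$genes, ...)
  res$donor_genome <- donor
  res$clone_genome <- clone
  res$truth <- list(
    germline = donor$germline, somatic = clone$somatic,
    cnv = clone$cnv_truth, sv = clone$sv_truth
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(out_dir, ...)
    write_fasta(donor$reference, p("reference.fasta"))
    write_fastq(raw_clone, p("clone_1.fastq"), p("clone_2.fastq"))
    write_fastq(raw_donor, p("donor_1.fastq"), p("donor_2.fastq"))
    lens <- setNames(nchar(donor$reference), names(donor$reference))
    write_sam(raw_clone$alignments, lens, p("clone.truth.sam"))
    write_sam(raw_donor$alignments, lens, p("donor.truth.sam"))
    write_vcf(res$somatic, lens, p("somatic.vcf"))
    if (!is.null(res$cnv)) write_bed_tsv(res$cnv, p("cnv_calls.tsv"))
    if (!is.null(res$sv)) write_bed_tsv(res$sv$somatic, p("sv_somatic.tsv"))
    if (nrow(donor$genes)) write_gff3(donor$genes, p("genes.gff3"))
    write_summary(res$summary, p("summary.json"), p("summary.tsv"))
  }
  res
}
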
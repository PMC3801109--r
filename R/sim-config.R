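#' Simulation configuration for a donor/clone sequencing experiment
#'
#' Builds and validates the configuration object consumed by
#' [build_donor_genome()], [derive_clone_genome()] and [simulate_reads()].
#' Defaults describe a desk-scale emulation of a ~20x paired-end 2x100 bp
#' whole-genome comparison of an SCNT clone against its nuclear donor:
#' a ~10 Mb nuclear genome (4 autosomes + chrX) plus a circular-origin
#' mitochondrial chromosome, somatic SNVs planted at 3.77/Mb, a replaced
#' mitochondrial haplotype, and telomeric (TTAGGG)n tracts at every
#' chromosome end.
#'
#' @param seed integer master seed; every random draw in the simulator is
#'   derived deterministically from it.
#' @param n_autosomes number of autosomes.
#' @param autosome_length length of each autosome in bp.
#' @param sex_chrom_length length of chrX in bp (haploid dosage: both
#'   individuals are male, so chrX is simulated from a single haplotype at
#'   half the autosomal coverage).
#' @param mito_length length of chrM in bp (circular origin; fragments are
#'   sampled from the linearised sequence).
#' @param telomere_length_donor,telomere_length_clone length in bp of the
#'   perfect telomeric tract at each end of every nuclear chromosome:
#'   `(CCCTAA)n` at the left terminus, `(TTAGGG)n` at the right.
#' @param germline_het_rate heterozygous germline SNVs per bp between the
#'   donor and the reference.
#' @param somatic_snv_rate clone-only somatic SNVs per Mb of nuclear genome.
#' @param somatic_indel_rate clone-only somatic small indels per Mb.
#' @param somatic_titv transition:transversion ratio of planted SNVs.
#' @param mito_divergence substitutions per bp between the donor and clone
#'   mitochondrial haplotypes (the clone's chrM comes from the oocyte donor).
#' @param cnv_events data.frame with columns `chrom`, `start`, `end`,
#'   `copy_number` (0--4); realised as copy-number change in the clone.
#' @param sv_events data.frame with columns `type` (`"DEL"`, `"INS"`,
#'   `"CTX"`), `chrom`, `start`, `size`, and for `CTX` also `chrom2`,
#'   `start2` (reciprocal translocation partner breakpoint).
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment (insert) length distribution in bp;
#'   Normal, truncated below at `read_length`.
#' @param coverage haploid fold-coverage of the nuclear genome.
#' @param base_error_rate per-base substitution sequencing error rate.
#' @param n_base_rate per-base rate of ambiguous (N) calls.
#' @param quality_start,quality_end,quality_sd per-base Phred quality is
#'   drawn around a mean declining linearly from `quality_start` at cycle 1
#'   to `quality_end` at the last cycle, with Gaussian noise `quality_sd`.
#' @param low_quality_read_fraction fraction of reads emitted as quality
#'   casualties (mean quality ~ 12) so that the quality filters have work.
#' @param adapter_seq_index,adapter_seq_universal adapter sequences used for
#'   read-through when the fragment is shorter than two read lengths: mate 1
#'   runs into the index adapter, mate 2 into the reverse complement of the
#'   universal adapter.
#' @param duplicate_fraction fraction of fragments re-emitted as PCR
#'   duplicates (same coordinates, independent errors).
#' @param n_genes number of protein-coding genes planted per autosome
#'   (stop-free ORFs written into the reference so coding-effect annotation
#'   has targets).
#' @param gene_n_codons codons per planted gene CDS.
#' @param interstitial_repeat_motifs control repeat motifs (base-composition
#'   permutations of TTAGGG, e.g. GGGATT) planted as small interstitial
#'   tandem arrays, emulating the repeat content that makes control-motif
#'   normalisation of the telomere estimator well defined.
#' @param interstitial_repeat_arrays number of arrays planted per motif.
#' @param interstitial_repeat_copies tandem copies per array.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_autosomes = 4L,
                       autosome_length = 2.25e6,
                       sex_chrom_length = 1e6,
                       mito_length = 16727L,
                       telomere_length_donor = 5000L,
                       telomere_length_clone = 5000L,
                       germline_het_rate = 1e-3,
                       somatic_snv_rate = 3.77,
                       somatic_indel_rate = 3.04,
                       somatic_titv = 2,
                       mito_divergence = 5e-3,
                       cnv_events = NULL,
                       sv_events = NULL,
                       read_length = 100L,
                       insert_mean = 265,
                       insert_sd = 20,
                       coverage = 20,
                       base_error_rate = 1e-3,
                       n_base_rate = 1e-4,
                       quality_start = 38,
                       quality_end = 30,
                       quality_sd = 3,
                       low_quality_read_fraction = 0.002,
                       adapter_seq_index =
                         "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACACAGTGATCTCGTATGCCGTCTTCTGCTTG",
                       adapter_seq_universal =
                         "AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT",
                       duplicate_fraction = 0.02,
                       n_genes = 2L,
                       gene_n_codons = 900L,
                       interstitial_repeat_motifs = c("GGGATT", "GTGAGT", "TGAGGT"),
                       interstitial_repeat_arrays = 6L,
                       interstitial_repeat_copies = 10L) {
  cfg <- list(
    seed = as.integer(seed),
    n_autosomes = as.integer(n_autosomes),
    autosome_length = as.integer(autosome_length),
    sex_chrom_length = as.integer(sex_chrom_length),
    mito_length = as.integer(mito_length),
    telomere_length_donor = as.integer(telomere_length_donor),
    telomere_length_clone = as.integer(telomere_length_clone),
    germline_het_rate = germline_het_rate,
    somatic_snv_rate = somatic_snv_rate,
    somatic_indel_rate = somatic_indel_rate,
    somatic_titv = somatic_titv,
    mito_divergence = mito_divergence,
    cnv_events = cnv_events,
    sv_events = sv_events,
    read_length = as.integer(read_length),
    insert_mean = insert_mean,
    insert_sd = insert_sd,
    coverage = coverage,
    base_error_rate = base_error_rate,
    n_base_rate = n_base_rate,
    quality_start = quality_start,
    quality_end = quality_end,
    quality_sd = quality_sd,
    low_quality_read_fraction = low_quality_read_fraction,
    adapter_seq_index = adapter_seq_index,
    adapter_seq_universal = adapter_seq_universal,
    duplicate_fraction = duplicate_fraction,
    n_genes = as.integer(n_genes),
    gene_n_codons = as.integer(gene_n_codons),
    interstitial_repeat_motifs = interstitial_repeat_motifs,
    interstitial_repeat_arrays = as.integer(interstitial_repeat_arrays),
    interstitial_repeat_copies = as.integer(interstitial_repeat_copies)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_autosomes >= 1L,
    cfg$autosome_length > 0L,
    cfg$sex_chrom_length > 0L,
    cfg$mito_length > 0L,
    cfg$read_length > 0L
  )
  rates <- c(
    cfg$germline_het_rate, cfg$somatic_snv_rate, cfg$somatic_indel_rate,
    cfg$mito_divergence, cfg$base_error_rate, cfg$n_base_rate,
    cfg$duplicate_fraction, cfg$low_quality_read_fraction
  )
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (cfg$insert_mean <= cfg$read_length) {
    stop("insert_mean must exceed read_length")
  }
  if (cfg$coverage <= 0) stop("coverage must be positive")
  min_len <- min(cfg$autosome_length, cfg$sex_chrom_length)
  tel_max <- max(cfg$telomere_length_donor, cfg$telomere_length_clone)
  if (2L * tel_max >= min_len) {
    stop("telomere tract longer than chromosome")
  }
  for (df_name in c("cnv_events", "sv_events")) {
    ev <- cfg[[df_name]]
    if (is.null(ev)) next
    if (!is.data.frame(ev)) stop(df_name, " must be a data.frame or NULL")
    need <- if (df_name == "cnv_events") {
      c("chrom", "start", "end", "copy_number")
    } else {
      c("type", "chrom", "start", "size")
    }
    if (!all(need %in% names(ev))) {
      stop(df_name, " needs columns: ", paste(need, collapse = ", "))
    }
  }
  check_event_bounds(cfg)
  invisible(cfg)
}

## chromosome name -> length lookup for a config
config_chrom_lengths <- function(cfg) {
  lens <- c(
    setNames(
      rep(cfg$autosome_length, cfg$n_autosomes),
      paste0("chr", seq_len(cfg$n_autosomes))
    ),
    chrX = cfg$sex_chrom_length,
    chrM = cfg$mito_length
  )
  lens
}

check_event_bounds <- function(cfg) {
  lens <- config_chrom_lengths(cfg)
  iv <- list()
  if (!is.null(cfg$cnv_events)) {
    ev <- cfg$cnv_events
    if (any(!ev$chrom %in% names(lens))) stop("cnv_events on unknown chromosome")
    if (any(ev$start < 1 | ev$end > lens[ev$chrom] | ev$start >= ev$end)) {
      stop("cnv_events interval outside chromosome bounds")
    }
    if (any(!ev$copy_number %in% 0:4)) stop("cnv copy_number must be in 0..4")
    iv <- c(iv, lapply(seq_len(nrow(ev)), function(i) {
      c(ev$chrom[i], ev$start[i], ev$end[i])
    }))
  }
  if (!is.null(cfg$sv_events)) {
    ev <- cfg$sv_events
    if (any(!ev$type %in% c("DEL", "INS", "CTX"))) {
      stop("sv_events type must be DEL, INS or CTX")
    }
    if (any(!ev$chrom %in% names(lens))) stop("sv_events on unknown chromosome")
    bad <- ev$start < 1 |
      ifelse(ev$type == "DEL", ev$start + ev$size - 1, ev$start) > lens[ev$chrom]
    if (any(bad)) stop("sv_events interval outside chromosome bounds")
    iv <- c(iv, lapply(seq_len(nrow(ev)), function(i) {
      end <- if (ev$type[i] == "DEL") ev$start[i] + ev$size[i] - 1 else ev$start[i]
      c(ev$chrom[i], ev$start[i], end)
    }))
  }
  if (length(iv) > 1) {
    df <- data.frame(
      chrom = vapply(iv, `[`, "", 1),
      start = as.numeric(vapply(iv, `[`, "", 2)),
      end = as.numeric(vapply(iv, `[`, "", 3))
    )
    df <- df[order(df$chrom, df$start), ]
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    if (any(same & df$start[-1] <= df$end[-nrow(df)])) {
      stop("cnv/sv events must not overlap")
    }
  }
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  lens <- config_chrom_lengths(x)
  cat("<sim_config>\n")
  cat(sprintf(
    "  genome: %d autosomes x %s bp + chrX %s bp + chrM %s bp (%.2f Mb)\n",
    x$n_autosomes, format(x$autosome_length, big.mark = ","),
    format(x$sex_chrom_length, big.mark = ","),
    format(x$mito_length, big.mark = ","), sum(lens) / 1e6
  ))
  cat(sprintf(
    "  reads: 2 x %d bp, insert %.0f (sd %.0f), %.0fx coverage\n",
    x$read_length, x$insert_mean, x$insert_sd, x$coverage
  ))
  cat(sprintf(
    "  somatic: %.2f SNV/Mb, %.2f indel/Mb, mito divergence %.3g/bp\n",
    x$somatic_snv_rate, x$somatic_indel_rate, x$mito_divergence
  ))
  cat(sprintf(
    "  planted events: %d CNV, %d SV; telomeres donor/clone %d/%d bp\n",
    if (is.null(x$cnv_events)) 0L else nrow(x$cnv_events),
    if (is.null(x$sv_events)) 0L else nrow(x$sv_events),
    x$telomere_length_donor, x$telomere_length_clone
  ))
  invisible(x)
}
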
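# Shared fixtures: one small donor/clone simulation reused across test
# files, built lazily and cached for the session.

.fix <- new.env()

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

small_config <- function(...) {
  sim_config(
    seed = 42L, n_autosomes = 2L, autosome_length = 3e5,
    sex_chrom_length = 1.5e5, telomere_length_donor = 1500L,
    telomere_length_clone = 1500L, somatic_snv_rate = 40,
    somatic_indel_rate = 20, ...
  )
}

fix_donor <- function() {
  fixture("donor", function() build_donor_genome(small_config()))
}

fix_clone <- function() {
  fixture("clone", function() derive_clone_genome(fix_donor(), small_config()))
}

fix_donor_reads <- function() {
  fixture("donor_reads", function() {
    simulate_reads(fix_donor(), sample_tag = "donor")
  })
}

fix_clone_reads <- function() {
  fixture("clone_reads", function() {
    simulate_reads(fix_clone(), sample_tag = "clone")
  })
}

fix_donor_prep <- function() {
  fixture("donor_prep", function() prepare_sample(fix_donor_reads()))
}

fix_clone_prep <- function() {
  fixture("clone_prep", function() prepare_sample(fix_clone_reads()))
}

fix_analysis <- function() {
  fixture("analysis", function() {
    analyze_pair(fix_clone_prep(), fix_donor_prep(), fix_donor()$reference,
                 genes = fix_donor()$genes)
  })
}

# construct a minimal alignment data.frame for hand-built cases; defaults
# describe a mapped plus-strand 10 bp read of quality Q30
make_aln <- function(qname, chrom, pos, seq = NULL, cigar = NULL,
                     mate = 1L, strand = "+", qual = NULL, mapped = TRUE,
                     dup = FALSE, mchrom = NA_character_, mpos = NA_integer_,
                     mstrand = NA_character_, isize = 0L) {
  n <- max(length(qname), length(pos))
  if (is.null(seq)) seq <- strrep("A", 10L)
  seq <- rep_len(seq, n)
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  if (is.null(qual)) qual <- strrep("?", nchar(seq))  # Q30
  data.frame(
    qname = rep_len(qname, n), mate = rep_len(mate, n),
    chrom = rep_len(chrom, n), pos = rep_len(pos, n),
    strand = rep_len(strand, n), cigar = rep_len(cigar, n),
    seq = seq, qual = rep_len(qual, n),
    mapped = rep_len(mapped, n), dup = rep_len(dup, n),
    mchrom = rep_len(mchrom, n), mpos = rep_len(mpos, n),
    mstrand = rep_len(mstrand, n), isize = rep_len(isize, n),
    stringsAsFactors = FALSE
  )
}

# n error-free reads of `width` bases covering `pos` on a uniform reference
reads_over_site <- function(n, refseq, chrom, start, width = 50L,
                            alt_at = NULL, alt_base = NULL, qual_char = "I") {
  seqs <- rep(stringi::stri_sub(refseq, start, start + width - 1L), n)
  if (!is.null(alt_at)) {
    for (i in alt_at$reads) {
      stringi::stri_sub(seqs[i], alt_at$offset, alt_at$offset) <- alt_base
    }
  }
  make_aln(
    qname = sprintf("r%03d", seq_len(n)), chrom = chrom, pos = start,
    seq = seqs, qual = strrep(qual_char, width)
  )
}

variant_key <- function(df) paste(df$chrom, df$pos, df$alt)
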
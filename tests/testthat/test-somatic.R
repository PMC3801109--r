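test_that("exact Fisher test matches stats::fisher.test on random tables", {
  set.seed(77)
  n <- 500
  a <- sample(0:50, n, TRUE)
  b <- sample(0:50, n, TRUE)
  c_ <- sample(0:50, n, TRUE)
  d <- sample(0:50, n, TRUE)
  valid <- (a + b) > 0 & (c_ + d) > 0
  p_pkg <- fisher_exact_test(a[valid], b[valid], c_[valid], d[valid])
  p_ref <- mapply(function(w, x, y, z) {
    stats::fisher.test(matrix(c(w, x, y, z), 2, byrow = TRUE))$p.value
  }, a[valid], b[valid], c_[valid], d[valid])
  expect_equal(p_pkg, unname(p_ref), tolerance = 1e-12)
})

test_that("Fisher edge cases: balance, strong imbalance, zero margins", {
  expect_equal(fisher_exact_test(5, 5, 5, 5), 1.0)
  expect_lt(fisher_exact_test(10, 10, 20, 0), 0.05)
  expect_true(is.na(fisher_exact_test(0, 0, 10, 10)))
  expect_true(is.na(fisher_exact_test(10, 10, 0, 0)))
})

test_that("compartment classification maps chromosome names", {
  expect_equal(classify_compartment(c("chr12", "chrX", "chrM", "chrY", "MT", "7")),
               c("autosomal", "sex", "mitochondrial", "sex",
                 "mitochondrial", "autosomal"))
  expect_error(classify_compartment("scaffold_17"), "scaffold_17")
  expect_equal(classify_compartment("ctg9", aliases = c(ctg9 = "autosomal")),
               "autosomal")
})

test_that("paired subtraction removes shared calls and attaches donor counts", {
  refseq <- strrep("ACGTTGCA", 100)
  ref <- c(chr9 = refseq)
  donor_aln <- reads_over_site(30, refseq, "chr9", 1, width = 100)
  donor_ps <- pileup(donor_aln, ref)
  donor_mask <- callable_region(donor_ps)
  clone_call <- data.frame(
    chrom = "chr9", pos = 50L, ref = substr(refseq, 50, 50), alt = "T",
    genotype = "0/1", gq = 60, depth = 30L, ref_count = 15L,
    alt_count = 15L, kind = "SNV", stringsAsFactors = FALSE
  )
  none <- clone_call[0, ]
  # donor 0/0 with depth 30: candidate with donor counts attached
  ev <- subtract_paired(clone_call, none, donor_ps, donor_mask)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$donor_ref, 30)
  expect_equal(ev$donor_alt, 0)
  expect_equal(ev$compartment, "autosomal")
  # identical call sets: zero candidates
  ev0 <- subtract_paired(clone_call, clone_call, donor_ps, donor_mask)
  expect_equal(nrow(ev0), 0)
  # donor site not callable: suppressed and counted
  far <- clone_call
  far$pos <- 900L
  ev2 <- subtract_paired(far, none, donor_ps, donor_mask)
  expect_equal(nrow(ev2), 0)
  expect_equal(attr(ev2, "n_unresolvable"), 1)
  # donor alternate support vetoes the candidate as germline evidence
  donor_aln3 <- reads_over_site(
    30, refseq, "chr9", 1, width = 100,
    alt_at = list(reads = 1:2, offset = 50), alt_base = "T"
  )
  donor_ps3 <- pileup(donor_aln3, ref)
  ev3 <- subtract_paired(clone_call, none, donor_ps3, donor_mask)
  expect_equal(nrow(ev3), 0)
  expect_equal(attr(ev3, "n_germline_evidence"), 1)
})

test_that("the Fisher somatic filter keeps p <= alpha and drops the rest", {
  ev <- clonecompare:::empty_events()
  ev <- rbind(ev, data.frame(
    chrom = "chr1", pos = c(1L, 2L, 3L), ref = "A", alt = "G", kind = "SNV",
    compartment = "autosomal", genotype = "0/1",
    clone_ref = c(10L, 5L, 0L), clone_alt = c(10L, 5L, 0L),
    donor_ref = c(20L, 5L, 10L), donor_alt = c(0L, 5L, 10L),
    fisher_p = NA_real_, effect = NA_character_,
    amino_change = NA_character_, stringsAsFactors = FALSE
  ))
  class(ev) <- c("somatic_events", "data.frame")
  out <- fisher_somatic_filter(ev, alpha = 0.05)
  expect_equal(out$pos, 1L)                     # balanced table p = 1 dropped
  expect_lt(out$fisher_p, 0.05)
  expect_equal(attr(out, "n_dropped_p"), 1)     # the [5,5;5,5] table
  expect_equal(attr(out, "n_dropped_zero_margin"), 1)
})

test_that("full pipeline on the clone/donor fixture recovers planted somatic SNVs", {
  res <- fix_analysis()
  tr <- fix_clone()$somatic
  ev <- res$somatic
  tr_snv <- tr[tr$kind == "SNV" & tr$chrom != "chrM", ]
  shared <- mask_intersect(res$masks$clone, res$masks$donor)
  in_mask <- mask_contains(shared, tr_snv$chrom, tr_snv$pos)
  recall <- mean(variant_key(tr_snv[in_mask, ]) %in% variant_key(ev))
  expect_gte(recall, 0.9)
  # compartment counts always sum to the total
  s <- res$summary
  expect_equal(s$n_somatic_snv$autosomal + s$n_somatic_snv$sex +
                 s$n_somatic_snv$mitochondrial, s$n_somatic_snv$total)
  # the replaced mitochondrial haplotype is recovered as somatic
  expect_gt(s$n_somatic_snv$mitochondrial, 0)
  n_mito_truth <- sum(tr$chrom == "chrM")
  expect_equal(s$n_somatic_snv$mitochondrial, n_mito_truth, tolerance = 0.1)
})

test_that("coding effects are annotated from codons, strand-aware", {
  # build a reference holding one plus-strand gene of 900 codons
  set.seed(31)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- c("ATG", sample(setdiff(codons, "ATG"), 898, TRUE), "TAA")
  body[811] <- "AAG"   # lysine at codon 811
  body[100] <- "TTT"   # phenylalanine at codon 100
  orf <- paste(body, collapse = "")
  refseq <- paste0(strrep("T", 500), orf, strrep("C", 500))
  genes <- data.frame(gene_id = "g1", chrom = "c", strand = "+",
                      start = 501L, end = 500L + nchar(orf), exon_rank = 1L,
                      stringsAsFactors = FALSE)
  mk_ev <- function(pos, ref, alt, kind = "SNV") {
    data.frame(chrom = "c", pos = pos, ref = ref, alt = alt, kind = kind,
               compartment = "autosomal", genotype = "0/1", clone_ref = 10L,
               clone_alt = 10L, donor_ref = 20L, donor_alt = 0L,
               fisher_p = 0.001, effect = NA_character_,
               amino_change = NA_character_, stringsAsFactors = FALSE)
  }
  ref <- c(c = refseq)
  # AAG -> GAG at codon 811: K811E, nonsynonymous
  pos811 <- 500L + (811L - 1L) * 3L + 1L
  ev <- annotate_effect(mk_ev(pos811, "A", "G"), genes, ref)
  expect_equal(ev$effect, "nonsynonymous")
  expect_equal(ev$amino_change, "K811E")
  # TTT -> TTC at codon 100 third position: synonymous (Phe)
  pos100 <- 500L + (100L - 1L) * 3L + 3L
  ev2 <- annotate_effect(mk_ev(pos100, "T", "C"), genes, ref)
  expect_equal(ev2$effect, "synonymous")
  expect_equal(ev2$amino_change, "")
  # 100 bp upstream of the CDS: noncoding
  ev3 <- annotate_effect(mk_ev(401L, "T", "A"), genes, ref)
  expect_equal(ev3$effect, "noncoding")
  # indel inside the CDS is flagged
  ev4 <- annotate_effect(mk_ev(pos100, "TTC", "", kind = "DEL"), genes, ref)
  expect_true(ev4$coding_indel)
  expect_true(is.na(ev4$effect))

  # the same gene on the minus strand: K811E seen through revcomp
  refseq_m <- paste0(strrep("T", 500), revcomp(orf), strrep("C", 500))
  genes_m <- genes
  genes_m$strand <- "-"
  L <- nchar(orf)
  # codon 811 base 1 sits at the reverse-complement mirror position
  pos_m <- 500L + L - ((811L - 1L) * 3L + 1L) + 1L
  ev5 <- annotate_effect(mk_ev(pos_m, "T", "C"), genes_m, c(c = refseq_m))
  expect_equal(ev5$effect, "nonsynonymous")
  expect_equal(ev5$amino_change, "K811E")
})

test_that("planted genes survive reference construction with intact ORFs", {
  d <- fix_donor()
  gc_tab <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(d$genes))) {
    g <- d$genes[i, ]
    s <- substr(d$reference[[g$chrom]], g$start, g$end)
    if (g$strand == "-") s <- revcomp(s)
    aa <- gc_tab[substring(s, seq(1, nchar(s) - 2, 3),
                           seq(3, nchar(s), 3))]
    expect_equal(substr(s, 1, 3), "ATG")
    expect_equal(unname(aa[length(aa)]), "*")
    expect_false(any(aa[-length(aa)] == "*"))
  }
})
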
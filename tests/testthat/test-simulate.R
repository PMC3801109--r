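test_that("config validation rejects impossible setups", {
  expect_error(sim_config(insert_mean = 80, read_length = 100),
               "insert_mean")
  expect_error(sim_config(coverage = 0), "coverage")
  expect_error(sim_config(telomere_length_donor = 2e5,
                          autosome_length = 3e5, sex_chrom_length = 3e5),
               "telomere")
  expect_error(sim_config(germline_het_rate = -1), "rates")
  expect_error(
    sim_config(cnv_events = data.frame(chrom = "chr1", start = 10,
                                       end = 9e9, copy_number = 1)),
    "bounds"
  )
  expect_error(
    sim_config(
      n_autosomes = 1, autosome_length = 1e6,
      cnv_events = data.frame(chrom = "chr1", start = c(1e5, 1.2e5),
                              end = c(1.5e5, 1.7e5), copy_number = 1)
    ),
    "overlap"
  )
})

test_that("donor genome is deterministic and carries telomeric tracts", {
  cfg <- small_config()
  d1 <- build_donor_genome(cfg)
  d2 <- build_donor_genome(cfg)
  expect_identical(d1$reference, d2$reference)
  expect_identical(d1$germline, d2$germline)
  for (ch in c("chr1", "chr2", "chrX")) {
    L <- nchar(d1$reference[[ch]])
    left <- substr(d1$reference[[ch]], 1, 1500)
    right <- substr(d1$reference[[ch]], L - 1499, L)
    expect_true(grepl("^(CCCTAA|CTAACC|TAACCC|AACCCT|ACCCTA|CCTAAC)+",
                      left))
    expect_true(grepl("TTAGGG$|TAGGGT$|AGGGTT$|GGGTTA$|GGTTAG$|GTTAGG$",
                      right))
    expect_equal(stringi::stri_count_fixed(right, "TTAGGG"),
                 1500 / 6, tolerance = 0.01)
  }
  # chrM has no telomere
  expect_false(grepl("TTAGGGTTAGGGTTAGGG", d1$reference[["chrM"]]))
})

test_that("zero telomere length leaves no tract beyond chance", {
  cfg <- sim_config(seed = 5, n_autosomes = 1, autosome_length = 1e5,
                    sex_chrom_length = 5e4, telomere_length_donor = 0,
                    telomere_length_clone = 0, n_genes = 0)
  d <- build_donor_genome(cfg)
  # a perfect 4x tandem never arises by chance in 100 kb of uniform sequence
  expect_equal(
    stringi::stri_count_fixed(d$reference[["chr1"]], strrep("TTAGGG", 4)), 0
  )
  expect_equal(nrow(d$telomeres), 0)
})

test_that("germline heterozygous sites follow the configured rate", {
  cfg <- sim_config(seed = 9, n_autosomes = 1, autosome_length = 1e6,
                    sex_chrom_length = 5e4, germline_het_rate = 1e-3,
                    telomere_length_donor = 1000,
                    telomere_length_clone = 1000)
  d <- build_donor_genome(cfg)
  n1 <- sum(d$germline$chrom == "chr1")
  expect_gt(n1, 1000 - 3 * sqrt(1000))
  expect_lt(n1, 1000 + 3 * sqrt(1000))
  # ref column matches the reference sequence; alt differs
  idx <- sample(nrow(d$germline), 50)
  for (i in idx) {
    g <- d$germline[i, ]
    expect_equal(substr(d$reference[[g$chrom]], g$pos, g$pos), g$ref)
    expect_true(g$alt != g$ref)
  }
})

test_that("clone with all rates zero is identical to the donor", {
  cfg <- sim_config(seed = 11, n_autosomes = 1, autosome_length = 2e5,
                    sex_chrom_length = 1e5, somatic_snv_rate = 0,
                    somatic_indel_rate = 0, mito_divergence = 0)
  d <- build_donor_genome(cfg)
  cl <- derive_clone_genome(d, cfg)
  expect_equal(nrow(cl$somatic), 0)
  expect_identical(cl$snv_sets$h1, d$snv_sets$h1)
  expect_identical(cl$units[["chr1_h1"]]$runs, d$units[["chr1_h1"]]$runs)
})

test_that("somatic SNVs are planted at the configured rate, disjoint from germline", {
  cl <- fix_clone()
  d <- fix_donor()
  nuclear_len <- sum(unlist(d$chrom_lengths[c("chr1", "chr2", "chrX")]))
  n_snv <- sum(cl$somatic$kind == "SNV" & cl$somatic$chrom != "chrM")
  expected <- 40 * nuclear_len / 1e6
  expect_gt(n_snv, expected - 4 * sqrt(expected))
  expect_lt(n_snv, expected + 4 * sqrt(expected))
  # disjoint by position from germline truth
  expect_equal(
    length(intersect(paste(cl$somatic$chrom, cl$somatic$pos),
                     paste(d$germline$chrom, d$germline$pos))), 0
  )
})

test_that("planted copy-number events reshape the clone haplotype", {
  cfg <- sim_config(
    seed = 13, n_autosomes = 1, autosome_length = 5e5,
    sex_chrom_length = 1e5, somatic_snv_rate = 0, somatic_indel_rate = 0,
    mito_divergence = 0,
    cnv_events = data.frame(chrom = "chr1", start = 100001, end = 150000,
                            copy_number = c(1))
  )
  d <- build_donor_genome(cfg)
  cl <- derive_clone_genome(d, cfg)
  hap1 <- assemble_haplotype(cl, cl$units[["chr1_h1"]])
  hap2 <- assemble_haplotype(cl, cl$units[["chr1_h2"]])
  expect_equal(nchar(hap1$seq), 5e5 - 5e4)  # one haplotype lost 50 kb
  expect_equal(nchar(hap2$seq), 5e5)
})

test_that("read simulation is deterministic and respects pair counts", {
  cr1 <- fix_clone_reads()
  cr2 <- simulate_reads(fix_clone(), sample_tag = "clone")
  expect_identical(cr1$alignments, cr2$alignments)
  # ~ coverage * G / (2 * read_length) pairs, chrX at haploid dosage,
  # plus the configured duplicate fraction
  lens <- fix_donor()$chrom_lengths
  expected <- (20 * (lens[["chr1"]] + lens[["chr2"]]) + 10 * lens[["chrX"]] +
                 20 * lens[["chrM"]]) / 200 * 1.02
  n_pairs <- nrow(cr1$alignments) / 2
  expect_equal(n_pairs, expected, tolerance = 0.02)
})

test_that("realized fragment lengths match the insert model", {
  flen <- c(fix_donor_reads()$alignments$flen,
            fix_clone_reads()$alignments$flen)
  flen <- flen[seq(1, length(flen), 2)]
  expect_gt(length(flen), 1e5)
  expect_lt(abs(mean(flen) - 265), 1)
  expect_equal(sd(flen), 20, tolerance = 0.05)
})

test_that("error-free reads reproduce the reference at their truth position", {
  cfg <- sim_config(seed = 21, n_autosomes = 1, autosome_length = 2e5,
                    sex_chrom_length = 1e5, germline_het_rate = 0,
                    somatic_snv_rate = 0, somatic_indel_rate = 0,
                    mito_divergence = 0, base_error_rate = 0,
                    n_base_rate = 0, low_quality_read_fraction = 0,
                    duplicate_fraction = 0)
  d <- build_donor_genome(cfg)
  rs <- simulate_reads(d, sample_tag = "x")
  aln <- rs$alignments
  sub <- aln[aln$mapped & aln$cigar == "100M", ]
  sub <- sub[sample(nrow(sub), 300), ]
  ref_seq <- stringi::stri_sub(
    d$reference[sub$chrom], sub$pos, sub$pos + 99L
  )
  expect_identical(sub$seq, ref_seq)
})

test_that("short fragments read through into the adapter", {
  cfg <- sim_config(seed = 23, n_autosomes = 1, autosome_length = 2e5,
                    sex_chrom_length = 1e5, insert_mean = 150,
                    duplicate_fraction = 0)
  d <- build_donor_genome(cfg)
  rs <- simulate_reads(d, sample_tag = "x")
  aln <- rs$alignments
  short <- aln$flen < 90 & aln$mate == 1L
  expect_gt(sum(short), 0)
  rf <- reads_frame(rs)
  m1 <- rf[rf$mate == 1L, ]
  ad10 <- substr(cfg$adapter_seq_index, 1, 10)
  with_adapter <- stringi::stri_detect_fixed(m1$seq, ad10)
  # every fragment shorter than read_length - 9 carries >= 10 adapter bases
  expect_true(sum(with_adapter) >= 0.9 * sum(aln$flen[aln$mate == 1L] <= 90))
  expect_gt(sum(with_adapter), 0)
})

test_that("duplicate fraction zero yields no coordinate collisions beyond chance", {
  aln <- fix_donor_reads()$alignments
  m1 <- aln[aln$mate == 1L & aln$mapped & !aln$dup, ]
  # orientation-unordered fragment-end key
  ckey <- function(d) paste(d$chrom, pmin(d$pos, d$mpos),
                            pmax(d$pos, d$mpos))
  n_collide <- sum(duplicated(ckey(m1)))
  # non-duplicate fragments collide only by chance (< 1% at this density)
  expect_lt(n_collide / nrow(m1), 0.01)
  # flagged duplicates DO share coordinates with their originals
  dup1 <- aln[aln$mate == 1L & aln$dup & aln$mapped & !is.na(aln$mpos), ]
  expect_gt(mean(ckey(dup1) %in% ckey(m1)), 0.95)
})

test_that("SAM round-trip preserves the truth alignments", {
  rs <- fixture("tiny_rs", function() {
    cfg <- sim_config(seed = 31, n_autosomes = 1, autosome_length = 5e4,
                      sex_chrom_length = 3e4, telomere_length_donor = 500,
                      telomere_length_clone = 500)
    simulate_reads(build_donor_genome(cfg), sample_tag = "t")
  })
  lens <- setNames(
    nchar(fixture("tiny_ref", function() {
      cfg <- sim_config(seed = 31, n_autosomes = 1, autosome_length = 5e4,
                        sex_chrom_length = 3e4, telomere_length_donor = 500,
                        telomere_length_clone = 500)
      build_donor_genome(cfg)$reference
    })),
    c("chr1", "chrX", "chrM")
  )
  path <- tempfile(fileext = ".sam")
  write_sam(rs$alignments, lens, path)
  back <- read_sam(path)
  orig <- sort_alignments(rs$alignments)
  expect_equal(nrow(back), nrow(orig))
  mapped <- which(orig$mapped)
  expect_identical(back$chrom[mapped], orig$chrom[mapped])
  expect_identical(back$pos[mapped], orig$pos[mapped])
  expect_identical(back$cigar[mapped], orig$cigar[mapped])
  expect_identical(back$seq, orig$seq)
  expect_identical(back$dup, orig$dup)
})
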
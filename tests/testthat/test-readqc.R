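q40 <- function(n) strrep("I", n)  # Phred 40

test_that("ambiguous-base criterion uses a strict inequality on 10%", {
  cfg <- qc_config()
  seq10 <- paste0(strrep("N", 10), strrep("A", 90))   # exactly 10%
  seq11 <- paste0(strrep("N", 11), strrep("A", 89))   # exceeds 10%
  expect_true(assess_read(seq10, q40(100), 1, cfg)$passed)
  v <- assess_read(seq11, q40(100), 1, cfg)
  expect_false(v$passed)
  expect_true("N_FRACTION" %in% v$reasons)
})

test_that("mean-quality criterion is strict: exactly 15 passes", {
  cfg <- qc_config(low_quality_threshold = 0)  # isolate the mean criterion
  q15 <- strrep("0", 100)   # '0' is Phred 15
  q14 <- strrep("/", 100)   # '/' is Phred 14
  expect_true(assess_read(strrep("A", 100), q15, 1, cfg)$passed)
  v <- assess_read(strrep("A", 100), q14, 1, cfg)
  expect_true("MEAN_QUALITY" %in% v$reasons)
})

test_that("low-quality-fraction criterion counts bases under 15", {
  cfg <- qc_config(min_mean_quality = 0)
  # 10 bases at Q14 of 100 -> exactly 10%, retained
  qual10 <- paste0(strrep("/", 10), strrep("I", 90))
  qual11 <- paste0(strrep("/", 11), strrep("I", 89))
  expect_true(assess_read(strrep("A", 100), qual10, 1, cfg)$passed)
  expect_true("LOW_QUAL_FRACTION" %in%
                assess_read(strrep("A", 100), qual11, 1, cfg)$reasons)
})

test_that("adapter criterion matches read tails against adapter heads", {
  cfg <- qc_config()
  ad <- cfg$index_adapter_seq
  body <- strrep("C", 90)
  hit10 <- paste0(body, substr(ad, 1, 10))
  hit9 <- paste0(strrep("C", 91), substr(ad, 1, 9))
  expect_true("ADAPTER" %in% assess_read(hit10, q40(100), 1, cfg)$reasons)
  expect_true(assess_read(hit9, q40(100), 1, cfg)$passed)
  # mate 2 is compared to the reverse complement of the universal adapter;
  # synthetic adapters without the shared AGATCGGAAGAGC stem show the
  # mate-specific dispatch
  cfg2 <- qc_config(index_adapter_seq = "AAAACCCCGGGGTTTTACGT",
                    universal_adapter_seq = "TTTTGGGGCCCCAAAATGCA")
  ad2 <- revcomp(cfg2$universal_adapter_seq)
  hit2 <- paste0(strrep("C", 88), substr(ad2, 1, 12))
  expect_true("ADAPTER" %in% assess_read(hit2, q40(100), 2, cfg2)$reasons)
  expect_true(assess_read(hit2, q40(100), 1, cfg2)$passed)
  # the real mate-2 adapter head is detected too
  real2 <- paste0(strrep("C", 88),
                  substr(revcomp(cfg$universal_adapter_seq), 1, 12))
  expect_true("ADAPTER" %in% assess_read(real2, q40(100), 2, cfg)$reasons)
  # strict > interpretation shifts the boundary by one
  cfg_gt <- qc_config(adapter_strict_gt = TRUE)
  expect_true(assess_read(hit10, q40(100), 1, cfg_gt)$passed)
})

test_that("a pair is removed when either mate fails", {
  reads <- data.frame(
    name = c("p1", "p1", "p2", "p2"), mate = c(1L, 2L, 1L, 2L),
    seq = c(strrep("A", 50), strrep("A", 50),
            strrep("A", 50), strrep("A", 50)),
    qual = c(q40(50), strrep("#", 50), q40(50), q40(50)),  # p1/2 is Q2
    stringsAsFactors = FALSE
  )
  out <- filter_pairs(reads)
  expect_identical(unique(out$reads$name), "p2")
  expect_equal(out$report$pairs_removed, 1)
  expect_equal(out$report$pairs_passed, 1)
})

test_that("filtering is idempotent and complete on simulated reads", {
  res <- fixture("qc_small", function() filter_pairs(fix_clone_reads()))
  surv <- reads_frame(res$reads)
  # completeness: a full rescan finds no surviving read violating anything
  fails <- clonecompare:::assess_reads_matrix(surv$seq, surv$qual, surv$mate,
                                              qc_config())
  expect_equal(sum(fails), 0)
  # idempotence
  res2 <- filter_pairs(res$reads)
  expect_equal(res2$report$pairs_removed, 0)
  expect_identical(nrow(res2$reads$alignments), nrow(res$reads$alignments))
  # the simulator plants quality casualties, so something was removed
  expect_gt(res$report$pairs_removed, 0)
})

test_that("raising max_n_fraction never decreases the pass count", {
  rf <- reads_frame(fix_clone_reads())
  rf <- rf[1:2000, ]
  passes <- vapply(c(0, 0.05, 0.1, 0.5, 1), function(thr) {
    filter_pairs(rf, qc_config(max_n_fraction = thr))$report$pairs_passed
  }, numeric(1))
  expect_true(all(diff(passes) >= 0))
})

test_that("mismatched sequence/quality lengths are rejected", {
  expect_error(assess_read("ACGT", "III"), "mismatch")
})

test_that("duplicate removal keeps one pair per coordinate group", {
  # two byte-identical pairs + one singleton-coordinates pair
  aln <- rbind(
    make_aln("a", "chr1", 100, mate = 1L, mchrom = "chr1", mpos = 300,
             mstrand = "-"),
    make_aln("b", "chr1", 100, mate = 1L, mchrom = "chr1", mpos = 300,
             mstrand = "-"),
    make_aln("c", "chr1", 150, mate = 1L, mchrom = "chr1", mpos = 400,
             mstrand = "-"),
    make_aln("a", "chr1", 300, mate = 2L, strand = "-", mchrom = "chr1",
             mpos = 100, mstrand = "+"),
    make_aln("b", "chr1", 300, mate = 2L, strand = "-", mchrom = "chr1",
             mpos = 100, mstrand = "+"),
    make_aln("c", "chr1", 400, mate = 2L, strand = "-", mchrom = "chr1",
             mpos = 150, mstrand = "+")
  )
  aln <- sort_alignments(aln)
  out <- remove_duplicates(aln)
  expect_equal(out$n_removed_pairs, 1)
  expect_setequal(unique(out$alignments$qname), c("a", "c"))

  # no coordinate sharing -> identity
  out2 <- remove_duplicates(out$alignments)
  expect_equal(out2$n_removed_pairs, 0)
  expect_identical(out2$alignments, out$alignments)
})

test_that("the higher-quality duplicate survives", {
  lowq <- strrep("#", 10)
  aln <- rbind(
    make_aln("hi", "chr1", 100, mate = 1L, mchrom = "chr1", mpos = 200,
             mstrand = "-"),
    make_aln("lo", "chr1", 100, mate = 1L, qual = lowq, mchrom = "chr1",
             mpos = 200, mstrand = "-"),
    make_aln("hi", "chr1", 200, mate = 2L, strand = "-", mchrom = "chr1",
             mpos = 100, mstrand = "+"),
    make_aln("lo", "chr1", 200, mate = 2L, strand = "-", qual = lowq,
             mchrom = "chr1", mpos = 100, mstrand = "+")
  )
  out <- remove_duplicates(sort_alignments(aln))
  expect_identical(unique(out$alignments$qname), "hi")
})

test_that("unsorted alignments are rejected", {
  aln <- rbind(
    make_aln("a", "chr1", 500, mate = 1L),
    make_aln("b", "chr1", 100, mate = 1L)
  )
  expect_error(remove_duplicates(aln), "sorted")
})

test_that("simulated PCR duplicates are recovered at the configured fraction", {
  cfg <- sim_config(seed = 17, n_autosomes = 1, autosome_length = 4e5,
                    sex_chrom_length = 1e5, duplicate_fraction = 0.05)
  d <- build_donor_genome(cfg)
  rs <- simulate_reads(d, sample_tag = "x")
  n_pairs <- nrow(rs$alignments) / 2
  n_true_dups <- sum(rs$alignments$dup & rs$alignments$mate == 1L)
  out <- remove_duplicates(sort_alignments(rs$alignments))
  # one member of each duplicate group removed; truth count is the target
  expect_equal(out$n_removed_pairs, n_true_dups, tolerance = 0.1)
  expect_equal(n_true_dups / n_pairs, 0.05 * 0.95, tolerance = 0.2)
})

test_that("Phred+64-looking input is rejected", {
  q64 <- strrep("h", 50)  # typical Phred+64 high quality
  expect_error(clonecompare:::check_phred33(rep(q64, 10)), "Phred\\+64")
})
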
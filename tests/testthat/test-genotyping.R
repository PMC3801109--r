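# Independent log-space oracle for the diploid genotype posterior: direct
# per-observation products over the three genotypes, no shared code with
# the package's accumulator-based implementation.
oracle_posterior <- function(bases, quals, ref, alt, theta = 0.001) {
  eps <- 10^(-quals / 10)
  p_obs_allele <- function(b, a) ifelse(b == a, 1 - eps, eps / 3)
  ll <- c(
    sum(log(p_obs_allele(bases, ref))),
    sum(log((p_obs_allele(bases, ref) + p_obs_allele(bases, alt)) / 2)),
    sum(log(p_obs_allele(bases, alt)))
  )
  lp <- log(c(1 - 1.5 * theta, theta, theta / 2))
  w <- exp(ll + lp - max(ll + lp))
  setNames(w / sum(w), c("0/0", "0/1", "1/1"))
}

test_that("pileup tallies bases, attributes indels, and orders positions", {
  refseq <- strrep("ACGTTGCA", 200)
  aln <- reads_over_site(10, refseq, "c", 101, width = 50)
  ps <- pileup(aln, c(c = refseq))
  expect_equal(unname(ps$chroms$c$depth[101]), 10)
  expect_equal(unname(ps$chroms$c$depth[150]), 10)
  expect_equal(unname(ps$chroms$c$depth[151]), 0)
  col <- pileup_column(ps, "c", 120, c(c = refseq))
  expect_equal(sum(col$base_counts), 10)
  expect_equal(unname(col$base_counts[col$ref_base]), 10)

  # one A->G mismatch among 9 reference reads
  aln2 <- reads_over_site(10, refseq, "c", 1, width = 50,
                          alt_at = list(reads = 1, offset = 9), alt_base = "G")
  ps2 <- pileup(aln2, c(c = refseq))
  col2 <- pileup_column(ps2, "c", 9, c(c = refseq))
  expect_equal(unname(col2$base_counts["A"]), 9)
  expect_equal(unname(col2$base_counts["G"]), 1)

  # deletion at its first deleted base, insertion at the preceding base
  aln3 <- rbind(
    make_aln("d1", "c", 10, seq = strrep("A", 48), cigar = "24M2D24M",
             qual = strrep("I", 48)),
    make_aln("i1", "c", 10, seq = strrep("A", 50), cigar = "24M3I23M",
             qual = strrep("I", 50))
  )
  ps3 <- pileup(aln3, c(c = refseq))
  ind <- ps3$chroms$c$indels
  expect_equal(ind$pos[ind$allele == "-2"], 34)   # 10 + 24
  expect_equal(ind$pos[startsWith(ind$allele, "+")], 33)
  expect_error(pileup(make_aln("x", "nope", 5), c(c = refseq)),
               "unknown contig")
})

test_that("per-site depth from the simulator tracks the configured coverage", {
  ps <- fixture("pileup_chr1", function() {
    pileup(fix_donor_prep()$alignments, fix_donor()$reference,
           chroms = "chr1")
  })
  d <- ps$chroms$chr1$depth
  core <- d[5000:295000]  # away from telomeric ends
  expect_equal(mean(core), 20, tolerance = 0.06)
})

test_that("call_genotype enforces the depth 5-200 calling window", {
  # depth 4 with clear alt evidence: no call
  expect_null(call_genotype(rep("G", 4), rep(40, 4), ref = "A"))
  # depth 5 callable
  expect_false(is.null(call_genotype(rep("G", 5), rep(40, 5), ref = "A")))
  # depth 201 not callable, 200 is
  expect_null(call_genotype(rep("G", 201), rep(40, 201), ref = "A"))
  expect_false(is.null(call_genotype(rep("G", 200), rep(40, 200), ref = "A")))
  # non-ACGT reference: no call
  expect_null(call_genotype(rep("G", 30), rep(40, 30), ref = "N"))
})

test_that("overwhelming alternate evidence yields a confident hom-alt call", {
  v <- call_genotype(rep("G", 30), rep(40, 30), ref = "A")
  expect_equal(v$genotype, "1/1")
  expect_gte(v$gq, 10)
  expect_equal(v$alt, "G")
})

test_that("a balanced 15/15 column is called heterozygous, matching the oracle", {
  bases <- c(rep("A", 15), rep("G", 15))
  quals <- rep(40, 30)
  v <- call_genotype(bases, quals, ref = "A")
  post <- oracle_posterior(bases, quals, "A", "G")
  expect_equal(v$genotype, names(which.max(post)))
  expect_equal(v$genotype, "0/1")
  expect_equal(unname(attr(v, "posterior")), unname(post), tolerance = 1e-9)
})

test_that("genotype posterior matches the exhaustive oracle on random columns", {
  set.seed(1234)
  n_checked <- 0
  for (i in 1:1000) {
    depth <- sample(5:12, 1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    bases <- sample(c(ref, alt), depth, replace = TRUE,
                    prob = c(runif(1), runif(1)))
    quals <- sample(5:40, depth, replace = TRUE)
    v <- call_genotype(bases, quals, ref = ref, alt = alt,
                       min_gq = 0)
    post <- oracle_posterior(bases, quals, ref, alt)
    if (is.null(v)) {
      # no-call: best genotype must be hom-ref or the alt unobserved
      expect_true(names(which.max(post)) == "0/0" || !any(bases == alt))
    } else {
      expect_equal(unname(attr(v, "posterior")), unname(post),
                   tolerance = 1e-9)
      expect_equal(v$genotype, names(which.max(post)))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 300)
})

test_that("posterior over the three genotypes always sums to one", {
  set.seed(99)
  for (i in 1:50) {
    depth <- sample(5:40, 1)
    bases <- sample(c("A", "T"), depth, replace = TRUE)
    v <- call_genotype(bases, sample(10:40, depth, TRUE), ref = "A",
                       alt = "T", min_gq = 0)
    if (!is.null(v)) {
      expect_equal(sum(attr(v, "posterior")), 1, tolerance = 1e-9)
    }
  }
})

test_that("error-free diploid reads recover truth genotypes exactly", {
  cfg <- sim_config(seed = 77, n_autosomes = 1, autosome_length = 2e5,
                    sex_chrom_length = 1e5, germline_het_rate = 2e-3,
                    base_error_rate = 0, n_base_rate = 0,
                    low_quality_read_fraction = 0, duplicate_fraction = 0,
                    somatic_snv_rate = 0, somatic_indel_rate = 0,
                    coverage = 40)
  d <- build_donor_genome(cfg)
  rs <- simulate_reads(d, sample_tag = "x")
  ps <- pileup(rs$alignments, d$reference, chroms = "chr1")
  calls <- call_genotypes(ps, d$reference)
  truth <- d$germline[d$germline$chrom == "chr1", ]
  got <- calls[match(truth$pos, calls$pos), ]
  expect_true(all(!is.na(got$genotype)))
  expect_identical(got$genotype, truth$genotype)
  expect_identical(got$alt, truth$alt)
  # and no calls at non-variant positions
  expect_equal(nrow(calls), nrow(truth))
})

test_that("indel calling follows the support-fraction rules", {
  refseq <- strrep("ACGTTGCA", 100)
  mk <- function(n_del, n_ref) {
    rbind(
      if (n_del > 0) make_aln(sprintf("d%02d", 1:n_del), "c", 10,
                              seq = strrep("A", 47), cigar = "20M3D27M",
                              qual = strrep("I", 47)),
      if (n_ref > 0) make_aln(sprintf("r%02d", 1:n_ref), "c", 10,
                              seq = stringi::stri_sub(refseq, 10, 59),
                              qual = strrep("I", 50))
    )
  }
  ref <- c(c = refseq)
  # 10 of 20 reads carry an identical 3 bp deletion: heterozygous call
  calls <- call_indels(pileup(mk(10, 10), ref), ref)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$kind, "DEL")
  expect_equal(calls$genotype, "0/1")
  expect_equal(calls$pos, 30)
  expect_equal(nchar(calls$ref), 3)
  # support below the 25% floor: no call
  calls2 <- call_indels(pileup(mk(4, 20), ref), ref)
  expect_equal(nrow(calls2), 0)
  # support above 75%: homozygous
  calls3 <- call_indels(pileup(mk(16, 4), ref), ref)
  expect_equal(calls3$genotype, "1/1")
  # no indel observations -> no calls
  calls4 <- call_indels(pileup(mk(0, 10), ref), ref)
  expect_equal(nrow(calls4), 0)
})

test_that("planted indels are recovered by the caller at 20x", {
  d <- fix_donor()
  cl <- fix_clone()
  tr <- cl$somatic[cl$somatic$kind != "SNV", ]
  got <- list()
  for (ch in unique(tr$chrom)) {
    ps <- pileup(fix_clone_prep()$alignments, d$reference, chroms = ch)
    got[[ch]] <- call_indels(ps, d$reference)
  }
  got <- do.call(rbind, got)
  recall <- mean(variant_key(tr) %in% variant_key(got))
  expect_gte(recall, 0.9)
})

test_that("callable region is the exact depth 5-200 mask", {
  refseq <- strrep("ACGTTGCA", 50)
  ref <- c(c = refseq)
  # uniform depth 20 over [1,100]: mask is exactly that interval
  aln <- make_aln(sprintf("r%02d", 1:20), "c", 1, seq = strrep("A", 100),
                  qual = strrep("I", 100))
  mask <- callable_region(pileup(aln, ref))
  expect_equal(mask$runs$c, data.frame(start = 1L, end = 100L))
  expect_equal(mask$n_bases, 100)
  # depth 4 everywhere: empty mask
  aln4 <- make_aln(sprintf("r%02d", 1:4), "c", 1, seq = strrep("A", 100),
                   qual = strrep("I", 100))
  mask4 <- callable_region(pileup(aln4, ref))
  expect_equal(mask4$n_bases, 0)
  # boundary: depth exactly 5 and 200 callable; 4 and 201 not
  for (d in c(5, 200)) {
    a <- make_aln(sprintf("r%03d", 1:d), "c", 1, seq = strrep("A", 20),
                  qual = strrep("I", 20))
    expect_equal(callable_region(pileup(a, ref))$n_bases, 20)
  }
  a201 <- make_aln(sprintf("r%03d", 1:201), "c", 1, seq = strrep("A", 20),
                   qual = strrep("I", 20))
  expect_equal(callable_region(pileup(a201, ref))$n_bases, 0)
})

test_that("mask intersection and membership behave on crafted runs", {
  mk_mask <- function(runs) {
    structure(list(
      runs = runs,
      n_bases = sum(vapply(runs, function(r) sum(r$end - r$start + 1),
                           numeric(1)))
    ), class = "callable_mask")
  }
  a <- mk_mask(list(c1 = data.frame(start = c(1L, 50L), end = c(20L, 80L))))
  b <- mk_mask(list(c1 = data.frame(start = 10L, end = 60L)))
  ab <- mask_intersect(a, b)
  expect_equal(ab$runs$c1, data.frame(start = c(10L, 50L), end = c(20L, 60L)))
  expect_equal(ab$n_bases, 11 + 11)
  expect_equal(mask_contains(ab, c("c1", "c1", "c1"), c(10, 30, 55)),
               c(TRUE, FALSE, TRUE))
})

test_that("simulated 20x coverage leaves most non-telomeric sequence callable", {
  res <- fix_analysis()
  d <- fix_donor()
  nuclear_nontel <- sum(unlist(d$chrom_lengths)) -
    2 * 1500 * 3 - d$chrom_lengths[["chrM"]]
  expect_gt(res$masks$clone$n_bases / (nuclear_nontel + 16727), 0.95)
})
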
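# clonecompare

Whole-genome identity analysis for a clone and its nuclear donor.

Somatic cell nuclear transfer (SCNT) produces an animal whose nuclear
genome comes from a donor somatic cell and whose mitochondria come from
the oocyte. How identical the two genomes really are is an empirical
question answered by paired whole-genome sequencing: count the
post-cloning de novo ("somatic") SNVs and indels, test for copy-number and
structural differences, and compare relative telomere content.
`clonecompare` implements that comparison end-to-end for R users —
geneticists and bioinformaticians validating paired-sample somatic
pipelines, and anyone who needs a fully truth-tracked synthetic benchmark
for clone/donor (or twin/twin) designs.

## What it computes

* **Read QC** — the four classic raw-read filters (ambiguous bases > 10%,
  mean quality < 15, bases under Q15 > 10%, adapter tail identity >= 10 bp)
  applied pair-wise, plus coordinate-based PCR-duplicate removal.
* **Genotypes** — a simplified Bayesian biallelic caller: per-base
  likelihoods P(b|a) = 1−ε (match) or ε/3, heterozygosity prior
  θ = 0.001, calls restricted to depth 5–200 with genotype quality >= 10.
* **Somatic events** — paired subtraction (clone minus donor) with
  donor-evidence vetoes and a two-sided Fisher exact test on the
  2x2 allele-count table [[clone ref, clone alt], [donor ref, donor alt]];
  events with p > 0.05 are filtered out. Coding effects are annotated by
  codon translation (e.g. `K811E`).
* **Rates** — somatic SNVs per Mb of the callable (depth 5–200)
  region shared by both samples, and the 12/6-type substitution spectrum
  with its transition fraction.
* **CNVs** — case/control fragment counts in 100 bp bins, greedy
  BIC-penalised segmentation (λ = 2) with boundary polishing, states
  deleted/duplicated at log2 ratio below −0.2 / above +0.2.
* **SVs** — discordant-pair classification (DEL/INS/ITX/CTX) against a
  trimmed insert model (265 ± 20 by default), clustering with
  support/size ≥ 1000 bp/score ≥ 80 filters, somatic subtraction within
  1 kb windows.
* **Telomeres** — the fraction of reads containing `(TTAGGG) x k`
  (k = 1..6, both strands), normalised by permuted control motifs such as
  `GGGATT`; headline statistic at k = 4.
* **Simulator** — `build_donor_genome()` / `derive_clone_genome()` /
  `simulate_reads()` generate a diploid donor, a clone with planted somatic
  SNVs/indels, CNVs, SVs, a replaced mitochondrial haplotype and
  configurable telomere tracts, and paired-end reads with truth alignments
  — no external aligner needed.

## Worked example

```r
library(clonecompare)

cfg <- sim_config(seed = 7, n_autosomes = 2, autosome_length = 4e5,
                  sex_chrom_length = 2e5, somatic_snv_rate = 20,
                  somatic_indel_rate = 10)
res <- run_pipeline(cfg)
print(res$summary)
```

```
<comparison_summary> clone vs donor
  somatic SNV:             105 (17 autosomal, 0 sex, 88 mitochondrial)
  somatic indel:           12 (11 autosomal, 1 sex, 0 mitochondrial)
  somatic rate (/Mb):      107.65
  transition fraction:     0.667
  somatic nsSNV:           0
  somatic CNV:             0
  somatic SV:              0 of 0 clone signals (NA%)
  telomere ratio:          0.871
```

Reading the output: at this deliberately exaggerated somatic rate
(20 SNVs/Mb planted on a 1 Mb toy genome) the pipeline recovers all 17
planted nuclear SNVs plus ~88 of the ~90 substitutions of the replaced
mitochondrial haplotype — the mitochondrial excess is the expected
signature of SCNT, not an error. No copy-number or structural differences
were planted, and none are called. The telomere ratio compares clone to
donor normalised telomeric-read fractions at k = 4; both samples share
the same tract length here, so it sits near 1. Every number in the
summary is computed from the event streams, so compartment breakdowns
always add up to their totals.

Truth tables for benchmarking live in `res$truth` (planted germline and
somatic variants, CNV/SV intervals), and `res$somatic`, `res$cnv`,
`res$sv`, `res$telomere` hold the full per-stage results. Use
`run_pipeline(cfg, out_dir = "out")` to write FASTQ/SAM/VCF/TSV/JSON.

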
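---
title: "Methods: paired whole-genome comparison of a clone and its nuclear donor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired whole-genome comparison of a clone and its nuclear donor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`clonecompare` measures how genetically identical a clone produced by
somatic cell nuclear transfer (SCNT) is to its nuclear donor, from paired
whole-genome sequencing of the two individuals. The clone shares the
donor's nuclear genome but carries the oocyte donor's mitochondria, so the
expected signal is: very few nuclear somatic ("post-cloning de novo")
variants, an essentially identical copy-number landscape, a replaced
mitochondrial haplotype, and similar relative telomere content. The
pipeline stages mirror a classical short-read workflow:

1. raw-read filtering (four criteria) and PCR-duplicate removal;
2. per-sample pileup and a simplified Bayesian biallelic genotype caller;
3. paired somatic subtraction with a Fisher exact allele-count filter;
4. somatic mutation rate over the callable region and the substitution
   spectrum;
5. case/control read-depth CNV segmentation with a BIC penalty;
6. discordant-read-pair structural variant (SV) calling with somatic
   subtraction;
7. relative telomere length from telomeric-repeat-containing reads.

A bundled simulator generates a donor genome, derives a clone genome by
planting somatic events, and samples paired-end reads with truth
alignments, so every stage can be validated against planted truth without
an external aligner.

# Read quality filtering

A read fails when (1) ambiguous bases exceed 10% of its length, (2) its
mean Phred quality is under 15, (3) bases under quality 15 exceed 10% of
the read, or (4) its tail is identical over at least 10 bp to the head of
the appropriate adapter (mate 1: the index adapter; mate 2: the reverse
complement of the universal adapter). All four use the strict readings:
exactly 10% N or a mean of exactly 15 is retained; the adapter match length
boundary is `>= 10` with a configuration switch for the strict-greater
reading. The mean quality is the arithmetic mean of Phred integers -- the
simplest reading of "average quality" -- not an error-probability average.
A pair is dropped when either mate fails, because all downstream stages are
pair-based. Quality strings are required to be Phred+33; apparent Phred+64
input is rejected rather than silently rescaled.

Duplicate removal happens after "alignment" (here: after attaching the
simulator's truth alignments), collapsing pairs that share both fragment
ends and orientation to the single pair with the highest summed base
quality (ties by name). The two ends are compared unordered, so a
duplicate whose mates swapped read-1/read-2 roles -- which happens when the
complementary strand of the same fragment seeds a cluster -- still
collapses, matching the behaviour of coordinate-based duplicate markers.

# Genotype calling

Per site, base observations contribute
$P(b \mid a) = 1-\varepsilon$ for a matching allele and $\varepsilon/3$
otherwise, with $\varepsilon = 10^{-Q/10}$. Genotype likelihoods over
\{hom-ref, het, hom-alt\} are combined with a heterozygosity prior
$\theta = 0.001$ ($P(\mathrm{het}) = \theta$,
$P(\mathrm{hom\text{-}alt}) = \theta/2$). A site is called when its depth
lies in the callable window [5, 200], the posterior-best genotype is not
hom-ref, and the genotype quality $-10\log_{10}(1 - p_{\mathrm{best}})$
reaches 10 -- the closest modern analogue of the era's consensus-quality
threshold. Tri-allelic columns are reduced to the reference plus the most
frequent alternate. chrM is not diploid (and the clone's chrM comes from a
different oocyte), so mitochondrial calls are labelled by alternate allele
fraction: at least 0.9 is homoplasmic (`1/1`), below that heteroplasmic
(`0/1`), still gated by the same genotype-quality machinery.

Small indels use a support-fraction rule standing in for a full
realignment-based caller: an allele is called at support
$\geq 0.25 \times$ depth within the callable window, heterozygous below
0.75 support and homozygous at or above. Because deleted positions receive
no base observations from deletion-carrying reads, deletion support is
measured against the depth of the anchor base before the run -- otherwise
homozygous deletions would sit on zero-depth sites and be unconditionally
missed.

# Somatic subtraction and the Fisher filter

A clone call is a somatic candidate only if (a) the donor has no call with
the same alternate allele at the site, (b) the donor site is callable and
at least 8 reads deep (the minimum-normal-coverage default of the classic
paired somatic caller this stage emulates), and (c) the donor pileup shows
*no* read supporting the clone's alternate allele. Rule (c) deserves
comment: at a genuine germline heterozygous site the donor occasionally
draws too few alternate reads for a confident call; a clone het call plus
even one donor alternate read is then far better explained by a shared
germline allele than by coincidence, while a true somatic site almost
never shows donor support (a matching donor error arises at well under 1%
of sites). Without rule (c), germline undersampling leaks several false
somatic calls per 10 Mb at 20x.

Candidates then face a two-sided Fisher exact test on
[[clone ref, clone alt], [donor ref, donor alt]], computed by exact
hypergeometric enumeration (all tables with probability at most the
observed one, with the customary $1+10^{-7}$ tie tolerance). Events with
$p > 0.05$ are filtered out. Note the residual power limit: a germline het
site where the donor drew *zero* alternate reads is statistically
indistinguishable from a somatic variant at the single-site level; at 20x
the expected number of such sites is roughly
$L \cdot h \cdot e^{-\lambda/2}$ (about one per 10 Mb at a heterozygosity
of $10^{-3}$/bp and mean depth $\lambda \approx 19$), which bounds the
specificity attainable by any single-site paired caller at this depth.

Coding effects are annotated by strand-aware codon translation against the
standard genetic code; an amino-acid change is reported as, e.g., `K811E`.
Indels inside a CDS are flagged rather than scored. In place of the manual
alignment-viewer review used in practice, `event_snippet()` renders the
clone and donor tallies around any event for inspection.

# Mutation rate and spectrum

The somatic rate is SNV events inside the callable mask divided by mask
megabases. The mask is the *intersection* of the clone and donor callable
regions, since somatic detection requires both samples to be informative;
per-sample masks are also available. Indels are excluded from the headline
rate. The substitution spectrum tallies the 12 directed types, collapses
them to 6 strand-symmetrised types, and reports the transition fraction;
the simulator's transition:transversion ratio defaults to 2:1, giving an
expected transition fraction of 2/3.

# CNV segmentation

Fragments (pairs counted once at their leftmost aligned base) are binned at
100 bp for case (clone) and control (donor). Counting fragments rather
than reads keeps bin counts compatible with the binomial segment model --
the two reads of one fragment are not independent depth observations, and
counting both inflates the variance enough to create spurious segments in
identity nulls; this is also the natural reading of running the read-depth
method with its paired-library option. Within a segment every fragment is
a case fragment with segment probability $p$; the total
$\mathrm{BIC} = -2\sum\log L + \lambda k \log N$ with $\lambda = 2$.
Starting from single bins, adjacent segments merge greedily -- always the
largest BIC decrease -- until no merge helps. Greedy bottom-up merging
places boundaries only approximately (a single bin carries far less
evidence than one segment's penalty, so early merges can straddle a true
breakpoint); a polishing pass therefore alternates maximum-likelihood
repositioning of each boundary within its two flanking segments with
re-merging, until stable. Segments never span chromosome boundaries.
Log2 ratios are library-size normalised,
$\log_2((\mathrm{case}/\mathrm{control}) \cdot (T_c/T_a))$, with a 0.5
pseudocount added (and flagged) only when either sum is zero. States are
deleted below $-0.2$ and duplicated above $+0.2$; both thresholds are
exclusive, so $-0.2$ itself is neutral. Because clone is case and donor is
control, every non-neutral call *is* a clone/donor difference.

At 20x a heterozygous deletion shifts the case share from 1/2 to 1/3,
about 0.06 nat of evidence per fragment; with ~15 fragments per 100 bp bin
the maximum-likelihood boundary has a scatter of a few bins, which is the
precision limit reported by the replicate tests.

# SV calling

The insert model (mean, SD) is fitted from properly oriented
intra-chromosomal pairs trimmed of the top and bottom 1%, with a
truncated-normal correction so the SD is unbiased and a floor of 1 bp.
Pairs are discordant when mates land on different chromosomes (CTX), in
anomalous same-strand orientation (ITX), or with an apparent insert more
than 3 SDs above (DEL) or below (INS) the mean. Same-type signals within a
window of mean + 3 SD cluster into a call when support reaches
`min_support` (default 4 at this package's desk scale; the published
threshold 10 is a configuration away), predicted size reaches 1000 bp
(intra-chromosomal types) and the score reaches 80. The score is a Poisson
tail surprise, $-10\log_{10} P(X \geq \mathrm{support})$ under the
background rate of same-type signals per cluster window, standing in for
an unpublished score formula. Deletion size is the median insert excess;
insertion size is the insert deficit and is therefore never resolvable
beyond the insert distribution's reach. A clone call is somatic when no
donor call of the same type has both breakpoints within 1 kb.

# Telomere estimation

For each tandem multiplicity $k = 1..6$, the estimator counts reads
containing `(TTAGGG)` repeated $k$ times as an exact substring (both
strands by default), divides by total reads, and normalises by the mean
fraction of control motifs -- base-composition permutations of the
telomeric motif such as `GGGATT` -- at the same $k$. The headline statistic
uses $k = 4$: $k = 1$ is saturated by chance hits and $k = 6$ is sparse in
100 bp reads. Zero control fractions flag the normalised value unavailable
rather than infinite. Matching is exact; mismatch-tolerant counting is out
of scope. The simulator plants small interstitial tandem arrays of the
control motifs, emulating the repeat content of real genomes that makes
the control normalisation well defined.

# The simulator and its defaults

The generator emulates the study conditions: a ~10 Mb nuclear genome (4
autosomes of 2.25 Mb, chrX of 1 Mb at haploid dosage -- both individuals
male -- and a 16.7 kb chrM), 2 x 100 bp reads at 20x with insert 265 +- 20
(the stated pairing of the two published insert figures), somatic SNVs at
3.77/Mb, somatic indels at 3.04/Mb (the published indel:SNV proportion),
heterozygous germline SNVs at $10^{-3}$/bp, a clone chrM diverged at
0.005/bp (~84 substitutions, matching the scale of the published
mitochondrial count), telomeric `(CCCTAA)n`/`(TTAGGG)n` tracts of 5 kb per
end, base errors at $10^{-3}$, a linear quality decay from Phred 38 to 30
with Gaussian jitter, 0.2% low-quality reads (mean ~12) so the quality
filters have work, N bases at $10^{-4}$, 2% PCR duplicates, and TruSeq-like
adapter sequences for read-through. Each nuclear chromosome is represented
as two haplotypes; fragments are drawn from a haplotype uniformly, so
heterozygous calls arise naturally. Somatic positions colliding with
germline sites are redrawn, keeping the two truth sets disjoint.

Fragment lengths are Normal(265, 20) truncated below at 40 bp, and a mate
reads into its adapter when the fragment is shorter than the read length
-- the physical read-through model. Large events are realised
structurally: copy-number changes delete or tandem-duplicate the interval
on one or both haplotypes, large deletions and novel insertions edit one
haplotype, and translocations reciprocally swap chromosome tails; reads
crossing a junction are anchored on their larger matched side (minimum 20
bp) with soft clips, and reads wholly inside telomeric or novel repeat
sequence are flagged unmapped, as they would be after unique-mapping
filters. chrM is sampled from its linearised sequence; fragments never
span the circular origin, a simplification that costs a few hundred bp of
coverage taper at the ends of one small contig.

What the simulator does *not* model bounds what passing tests show about
real data: no mapping ambiguity or alignment error outside repeat tracts,
no indel realignment artefacts, no GC or insert-size coverage bias, no
chimeric library artefacts, and an error model without context dependence.
Results on real sequencing will be no better than these tests and
typically somewhat worse.

# Problem sizes and numerical choices

The bundled validation runs at desk scale by design: the default 10 Mb
genome for the identity-null and rate checks, 1.5 Mb for the CNV replicate
check, 2 Mb for the SV check, and ~1 Mb genomes for the telomere ladder --
sizes chosen so the planted-event counts carry enough statistics for the
assertions while a full validation pass stays within a coffee break on one
CPU. Genotype likelihoods are accumulated in log space per (base,
position); the exact Fisher enumeration uses `dhyper` with the standard
$1+10^{-7}$ tie tolerance; BIC merging uses a lazy-invalidation heap;
per-base error rates are capped at 0.75 so pathological quality strings
cannot push $1-\varepsilon$ negative; genotype quality is capped at 99.
Ties in alternate-allele choice break by base order (A, C, G, T).
All randomness flows from a single integer seed through deterministic
per-stage sub-seeds; identical configuration and seed reproduce
byte-identical FASTQ, SAM and summary output.

# Known limitations

* Single-site paired calling cannot distinguish a somatic variant from a
  germline het site whose donor sample drew zero alternate reads; at 20x
  this leaves an irreducible false-somatic expectation of order one event
  per 10 Mb (see the somatic section). Deeper donor coverage, joint
  genotyping across more relatives, or population filters are the real
  remedies, and all are out of scope here.
* Indel detection power at 20x is marginal for heterozygous events whose
  Fisher table just misses 0.05; recall is ~90% for the caller but a few
  points lower after the somatic filter.
* CNV breakpoint precision at 20x with 100 bp bins is limited to a few
  bins by the information content of the counts, not by the segmentation
  algorithm.
* The SV module reports insertion sizes only as insert deficits and does
  not attempt assembly; inversions are classified (ITX) but never planted
  by the generator.
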
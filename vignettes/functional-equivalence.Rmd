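---
title: "Evaluating functional equivalence of variant-calling pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating functional equivalence of variant-calling pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large human genetics programs sequence genomes at many centers, each with
its own alignment and read-processing pipeline. Two pipelines are called
*functionally equivalent* (FE) when, run on the same raw sequencing data
and followed by the same variant caller, they produce callsets that are
virtually indistinguishable. fequiv quantifies how close a set of
pipelines comes to that ideal, given only the callsets they produce:

* pairwise **discordance/concordance** of small variants (SNVs and
  indels), per sample;
* **k-way sharing** — how much of the union of all pipelines' calls is
  found by every pipeline, by exactly one, or by some subset;
* **structural-variant (SV) agreement** via padded breakpoint matching;
* stratification of every statistic by an **easy/medium/hard** genome
  partition;
* **Mendelian-error (ME) rates** in parent-offspring trios, separately
  for sites on which a pipeline pair agrees and disagrees;
* **variant quality by concordance status**.

A seeded synthetic-data generator reproduces the statistical structure
these analyses assume, so the whole evaluation is testable end to end
without sequencing data.

```{r, eval = FALSE}
library(fequiv)
sim <- simulate_study(sim_config(seed = 1))
report <- fe_evaluate(sim$callsets,
                      regions  = sim$truth$regions,
                      pedigree = sim$truth$pedigree)
glance(report)
autoplot(report)
```

## Statistics and their definitions

**Pairwise small-variant comparison.** Callsets are first normalized
(multiallelic decomposition, shared-base trimming, optional reference
left-alignment), then matched exactly on the key
(contig, pos, ref, alt). For callsets A and B of one sample, with
`tp` keys in both, `fn` keys only in A and `fp` keys only in B,

* discordance = (fn + fp) / (tp + fn + fp)
* concordance = tp / (tp + fn + fp)

The two always sum to one; both are symmetric in A and B. When genotype
matching is requested, a shared key with unequal genotype multisets is
counted once in `fn` *and* once in `fp` (double-entry accounting, the
convention of truth/query benchmarking counts). Exact-key matching after
normalization stands in for haplotype-resolved comparison; when all
pipelines share one variant caller, representational divergence is
minimal, and the comparator sits behind a single function
(`compare_callsets()`) so an alternative matcher is a one-point change.

**SV comparison.** An SV call is a pair of breakpoint intervals (0-based,
half-open, padded by 1 bp on each side — the convention needed for
paired-interval intersection) with a strand pair and a type. Two calls
overlap when *both* padded breakpoint intervals intersect on matching
contigs. Overlapping calls are classified on a 2x2 grid — strand pair
equal or not, type equal or not — giving the four shared categories
`match`, `match_discordant_type`, `discordant`,
`discordant_discordant_type`; unmatched calls are `zero_only` /
`one_only` (private to the first / second callset). Rates:

* SV discordance = (discordant + zero_only + one_only +
  discordant_discordant_type) / (all six categories); a matched call
  whose type differs but whose strands agree counts as concordant.
* SV shared rate = match / (match + zero_only + one_only).

The 2x2 semantics are a reconstruction from the category names of the
original (unpublished) comparison script, and are deliberately isolated
in one internal function. Multi-overlap ambiguity is resolved by best
category first, then smallest breakpoint distance, then
order-symmetric coordinate tie-breaks, so swapping the two callsets
swaps only the private categories.

**Genome stratification.** The easy stratum is a high-confidence region
set; the hard stratum is a union of difficult-sequence components
(centromeres, satellite repeats, low-complexity, high-copy windows) with
any portion overlapping the easy set removed (interval-level
subtraction: the non-overlapping remainder of a partially overlapping
hard interval stays hard); medium is the complement. The three strata
exactly partition every contig, which is asserted by tests after every
build. Small variants take the label covering their position; SVs take
the most difficult label either breakpoint interval touches.
High-copy-window derivation from read depth is out of scope; hard
components are consumed as prepared BED inputs.

**Mendelian errors.** For each offspring, sites are taken from the
pairwise comparison of the offspring's two callsets, and all three trio
genotypes come from the *first* pipeline of the pair. Sites with any
missing genotype, or without a heterozygote among the trio, are excluded
(the behavior of filtering merged trio VCFs to het-containing,
fully-genotyped records — note this also hides errors whose only
inconsistent genotype would be hom-ref, since such a child record never
enters a callset). Remaining sites are classed `informative_error` (no
choice of one paternal and one maternal allele reproduces the child),
`uninformative` (both parents heterozygous — every child genotype is
consistent, so no error is detectable), or `informative_consistent`.
ME rate = errors / informative sites, reported per
(concordance status x region) and averaged over trios per pipeline pair.

**Quality summaries** report the exact median (lower-median convention
for even cell sizes) and mean of QUAL (small variants) or MSQ, the mean
sample quality (SVs), per concordance status and class. Aggregation
across samples reports the mean plus box-plot statistics (quartile
hinges, whiskers at the most extreme values within 1.5 IQR of the
hinges), the convention of the summary figures this mirrors.

**Quality binning.** `bin_quality()` implements ascending
`threshold:value` binning of Phred scores (the `binQualS` dialect). The
default scheme `0:2,3:3,4:4,5:5,6:6,7:10,13:20,23:30,33:40` preserves
scores below 7 and collapses the rest to 10/20/30/40; it is a monotone,
idempotent step function with nine distinct outputs on 0–60.
`downsample_probability()` gives the retention ratio used to match
sequencing replicates to the lowest coverage.

## The synthetic-data generator

`sim_config()` / `simulate_truth()` / `emit_pipeline_callsets()` emulate
the analytic structure of a multi-center study, not its molecular
biology: no reads, coverage, duplication or caller internals are
modeled. The generative model is:

1. **Regions.** Each contig is cut into windows assigned to
   easy/medium/hard so the genome-wide fractions match the configured
   split (default 72% / 19.5% / 8.5%); windows are shuffled so strata
   interleave.
2. **Truth variants.** Positions uniform over the genome (distinct per
   contig); 90% SNVs, 10% indels of 1–6 bp by default; per-site allele
   frequency from a rare-skewed Beta(1, 9) spectrum.
3. **Samples.** Parent-offspring trios (default 3): founders drawn in
   Hardy-Weinberg proportions at each site, children by Mendelian
   transmission (one allele from each parent, uniformly).
4. **Pipelines.** Each pipeline independently misses a carrier call with
   the per-region dropout probability (default 0.1% easy, 0.5% medium,
   3% hard), adds spurious calls at a per-region per-Mb rate at
   positions absent from the truth, and mis-genotypes retained carriers
   (het/hom-alt flip) at a small per-region rate. Independence across
   pipelines is the minimal model of discordance driven by stochastic
   borderline-evidence effects. Under pure dropout at rate d the
   expected pairwise discordance is 2d(1-d)N / ((1-d^2)N) = 2d/(1+d),
   the closed form the recovery tests check.
5. **Quality.** Site QUAL is drawn from a 0-truncated normal: one
   distribution for sites every pipeline kept everywhere (default mean
   2000, sd 600) and a far lower one (mean 10, sd 6) for sites any
   pipeline missed, so discordant-site quality is a fraction of a
   percent of concordant-site quality, echoing the empirical pattern.
   Filters are not modeled; every emitted record is PASS.
6. **Mendelian-error injection.** At offspring carrier sites flagged
   discordant (missed by at least one pipeline), the child genotype is
   replaced by a transmission-inconsistent one. Because the downstream
   analysis only sees fully-genotyped, het-containing, alt-carrying
   records, only the het x hom-ref parental combination admits an
   injected error that remains analyzable (child flips to 1/1); the
   generator corrupts exactly those sites, with the per-site probability
   calibrated against the flagged-site combination counts so that the
   *measured* discordant-stratum ME rate is an unbiased estimate of the
   configured `mendelian_error_rate_discordant` (default 23%). With
   spurious calls enabled, apparent ME at discordant sites also arises
   from false positives with hom-ref parents — as in real data — so the
   defaults yield a discordant-stratum rate somewhat above the injected
   23%, and a concordant-stratum rate near the small genotype-error
   floor.
7. **SVs.** Truth SVs (DEL/DUP/INV, 500 bp–50 kb; BND is accepted by
   the comparator but not generated, keeping the matching surface
   crisp) are emitted per pipeline with per-region dropout, uniform
   breakpoint jitter within ±`sv_jitter_bp` (default 1 bp, within the
   1 bp padding window so jitter alone never breaks a match), and small
   type/strand flip probabilities. SV callsets are cohort-level per
   pipeline; MSQ follows the same two quality distributions.

Everything derives from `config$seed` (truth from `seed`, emission from
`seed + 1`), and two runs with one seed are byte-identical, including
written files.

Default sizes — a 10 Mb two-contig genome, 50,000 small variants, 500
SVs, five pipelines, three trios — keep a full simulate-and-evaluate
cycle under a minute on one core while leaving every estimate with
usefully small Monte-Carlo error; they are desk-scale stand-ins for a
hundred-genome study, not a claim about any real cohort. Dropout-rate
defaults were set so that the emergent pairwise concordance, five-way
sharing, and hard-region concentration of discordance land in the ranges
reported for harmonized pipelines on real cohorts.

What passing tests on this generator do **not** show: robustness to
representational divergence between different variant callers (the
comparator is exact-key after normalization), to coverage- or
batch-driven error structure (noise is independent across pipelines),
to multi-allelic transmission, or to reference artifacts. The generator
is a harness for the statistics, not a sequencing simulator.

## Numerical and design choices

* **Coordinates.** VCF positions stay 1-based; all interval arithmetic
  is 0-based half-open; conversion happens only at I/O boundaries.
  A base at a stratum junction belongs to the right-hand interval.
* **Genotypes** are unordered multisets (`"0/1"`), phase ignored:
  pipeline comparison is genotype-level, not haplotype-level.
* **Normalization** trims shared trailing then leading bases;
  left-alignment of indels requires reference sequence and repeatedly
  extends alleles leftward until no shared trailing base remains. Both
  modes are idempotent; reference-free trimming is sufficient for the
  generator's already-minimal alleles.
* **Duplicate keys** within one callset collapse to the highest-QUAL
  record, with a message — deterministic and conservative.
* **Ties in SV pairing** break by category precedence, then breakpoint
  distance, then order-symmetric coordinate keys; residual ties fall
  back to input order (only reachable for exactly coincident
  candidates).
* **Degenerate inputs:** empty comparisons yield `NA` rates rather than
  0; empty region components are allowed; contigs too short for the
  requested variant count are an error.
* **Genotype mismatches** are excluded from discordance by default
  (`require_genotype_match = FALSE`) because the underlying per-sample
  benchmarking counts can be configured either way; both behaviors are
  exposed and tested.

## Limitations

* The exact-key comparator will overstate discordance between pipelines
  whose callers emit different representations of the same complex
  event; use the normalization hooks or replace the comparator for such
  data.
* ME analysis covers biallelic autosomal-style transmission only; X/Y
  and multi-allelic inheritance are out of scope.
* The easy/medium/hard partition is built from user-supplied BED
  inputs; fequiv does not derive high-copy regions from read depth.
* Injected Mendelian errors are restricted to the analyzable parental
  combination (see above); rates of *undetectable* errors are not a
  target of the generator.
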
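---
title: "Quantifying deleterious mutation load and purging in bottlenecked populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying deleterious mutation load and purging in bottlenecked populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Small, serially bottlenecked populations — the Alpine ibex reintroduction
program is the canonical example — accumulate mildly deleterious mutations
by drift while simultaneously *purging* highly deleterious recessive ones:
inbreeding exposes recessives as homozygotes, where selection can finally
remove them. `mutload` implements both halves of the evidence for this
process:

* an **empirical pipeline** that turns genotypes plus per-site annotations
  into category-stratified measures of mutation load, and
* a **forward simulator** of the reintroduction demography that predicts
  how each mutation class should respond to the bottleneck sequence.

Both halves speak the same table dialect, so every statistic runs
identically on real and simulated data.

## Empirical pipeline

### Site filtering and classification

Variant-caller hard filters follow the usual short-variant heuristics, all
strict comparisons: a site fails on `QD < 2`, `FS > 40`, `SOR > 5`,
`MQ < 20`, `|MQRankSum| > 3`, `|ReadPosRankSum| > 3` or `AN < 62`, and
passes at equality. Rank-sum annotations are genuinely absent at sites
without heterozygous calls; such sites pass those two conditions. The
`AN` cutoff is a cohort-specific constant and is exposed in
`filter_thresholds()` — it does not reduce to a simple fraction of the
sample size and must be adapted to other cohorts. Sites then need a
genotyping rate of at least 90%, a distance of at least 3 bp to the next
SNP (both members of a closer pair are removed, guarding against
multi-nucleotide polymorphisms), expression support (`FPKM > 0.3` in at
least one organ, using the maximum over features overlapping the site) and
`GERP > -2` (restricting to alignable, non-hypervariable regions). These
filters commute, which the test suite asserts.

Functional impact uses the four annotation-tool categories `HIGH`
(stop-gain, frameshift), `MODERATE` (missense), `LOW` (synonymous) and
`MODIFIER` (the near-neutral reference class). Conservation classes bin
GERP at −2, 2, 4 and 6 (`NEUTRAL`, `MODERATE`, `LARGE`, `EXTREME`; scores
at or below −2 are excluded); phyloP calls a site conserved above 1 and
phastCons at exactly 1, its maximum.

### Derived-allele polarization

Deleterious mutations are overwhelmingly derived, so all load statistics
count derived rather than alternative alleles. ALT is derived iff its
frequency is exactly zero among the called genotypes of every outgroup
species; multiallelic sites and sites with no called outgroup genotype are
`UNKNOWN` and excluded. Missing outgroup calls never enter the
denominator. Under this rule a known derived allele is always ALT;
REF-derived polarization would need an ALT-fixed outgroup and is not
attempted.

### Load statistics

* **SFS** per category over a fixed individual subset; sites with a
  missing call in the subset are dropped so every counted site has the
  same sample size, and monomorphic-in-subset sites are excluded. For
  display, counts above 10 are binned and shown as the *mean number of
  sites per count value* in each interval (total sites in the bin divided
  by the number of count values it spans).
* **Per-individual counts** of derived alleles and derived homozygotes,
  over sites with at most 10% missing calls; an individual's own missing
  genotypes are simply not counted. Sites monomorphic in one population
  are retained so the site set is identical across populations.
* **Rxy**, the relative derived-allele abundance of a category in
  population X vs Y. The ratio is not printed in the source literature of
  this workflow in formula form; we use the standard frequency-sum form
  (Do et al. 2015): \(L_{X\nexists Y} = \sum_i f_i^X (1 - f_i^Y)\) and
  symmetrically, with the statistic the double ratio
  \((L_{X\nexists Y}/L_{Y\nexists X}) / (L'_{X\nexists Y}/L'_{Y\nexists X})\),
  the primes running over an intergenic control SNP set. The
  standardization cancels sampling effects and substructure; the testable
  contract is exact reciprocity, \(R_{XY} R_{YX} = 1\), and calibration at
  1 for exchangeable populations, both asserted in the suite.
  Uncertainty comes from a delete-one-chromosome jackknife in which the
  category and control sites of a block are removed together. We report
  the leave-one-out estimates themselves as the jackknife distribution
  (this is what the field's figures box-plot); `glance()` additionally
  gives the delete-one standard error on the log scale.
* **Nucleotide diversity** uses the unbiased per-site estimator
  \(\pi_i = 2\hat p_i(1-\hat p_i)\, n_i/(n_i-1)\) over called alleles,
  divided by the surveyed length; **individual heterozygosity** is
  heterozygous calls per kilobase of callable sequence.
* **ROH**: a PLINK-style scan with 100-SNP windows tolerating ≤ 2
  heterozygous and ≤ 5 missing calls, a per-SNP spanning-window hit rate
  of at least the window threshold, and run acceptance at ≥ 100 SNPs,
  ≥ 500 kb, ≤ 10 kb/SNP average spacing and no > 100 kb gap. The window
  threshold ships at 0.05, the scanning tool's own default, because the
  printed settings of published workflows occasionally garble this value;
  it is configurable. `f_roh()` is the genome fraction in ROH of at least
  2.5 Mb, the length regime diagnostic of recent inbreeding.
* **Downsampling** draws k = 4 individuals (the smallest cross-species
  sample size in the emulated design) without replacement, 100 times by
  default, to compare unequal samples.

## Forward simulator

An individual-based, discrete-generation model of diploids in named
patches:

| parameter | default | meaning |
|---|---|---|
| deleterious loci | 5000 | biallelic, unlinked |
| neutral loci | 500 | control set for Rxy on simulated data |
| s | Gamma(mean 0.01, shape 0.3) | selection coefficient per locus |
| h | exp(−51·s)/2 | dominance; additive at s→0, recessive for large s; mean ≈ 0.37 |
| µ | 5×10⁻⁵ per copy | ancestral→derived |
| back-mutation | 5×10⁻⁷ per copy | derived→ancestral |
| initial derived frequency | 0.0014 | every locus at burn-in start |
| fecundity | Poisson, mean 5 | offspring per female |

Mating is random with polygyny (each offspring draws an independent random
father); there are two sexes, so no selfing. Fitness is multiplicative
across loci, \(w = \prod (1-h_is_i)^{\mathrm{het}} (1-s_i)^{\mathrm{hom}}\)
(an additive variant is exposed as an option), and selection is *hard*:
an offspring survives with probability w, so populations can decline and
die out. Survivors are culled uniformly at random to the carrying
capacity K. A patch with zero survivors or a single sex is extinct — an
outcome, not an error. Free recombination is implemented exactly as
independent per-locus Mendelian sampling (equivalent to r = 0.5 between
all pairs). Genetic load is reported as \(L = 1 - W_{mean}/W_{max}\) over
females, with W the fitness scaled by fecundity (the scaling cancels).

The printed source of the initial-frequency constant gives a formula
("µ / h·s") that does not evaluate to 0.0014 under the stated parameters;
the constant itself is consistent with the *mean* of µ/(h(s)·s+µ)-type
balance over the gamma, so we adopt the printed value 0.0014 as a plain
constant and do not recompute it per locus.

### Demography

A `scenario()` is a time-ordered program of `resize` and `found` events on
named patches: a burn-in (3000 generations at K = 1000, deliberately short
of mutation–selection–drift equilibrium so deleterious variation still
segregates), a species bottleneck (K = 500 for five generations, then
K = 80 for two), recovery to 1000, and three generations later a staged
reintroduction founded "by migration of offspring": founders are freshly
produced offspring of the source patch, sexes forced to 1:1 (odd counts
get an extra female). Carrying capacities are meant to be harmonic means
of the patch's census record (`harmonic_mean()`), which the smallest
census years dominate. The shipped `ibex_scenario()` carries the printed
skeleton (including the two zoo patches at their historical census
harmonic means of 16 and 20) but its per-event founder counts, and the
capacities of the later populations, are **synthetic placeholders**: the
historical per-event records are not bundled, so calibrated work must
override them. At the scenario level, founding events are tolerant of
demographic accidents — an extinct or too-small source contributes what it
can, and an event with no usable source leaves the patch unfounded, which
the extinction tally records. (`found_population()` itself is strict and
errors, so programmatic use catches mistakes.)

`ibex_scenario(scale = 10)` divides capacities and burn-in length by ten
for small-scale work, with small floors (8 for populations, 6 for zoos) so
patches remain viable two-sex units. Down-scaling makes drift per
generation ten times stronger and shortens the mutation-accumulation
phase, so scaled runs are read qualitatively, never as calibrated
predictions.

### Reproducibility

One master seed drives everything. Replicates run on substreams derived
deterministically from it, so a replicate's trajectory does not depend on
how many others ran before it; the synthetic-data generator likewise pins
every emitted byte to its seed (fixed RNG kind).

## The synthetic-data generator

`generate_cohort()` plants known structure: per-site derived-allele
frequencies drawn from category-specific Beta distributions (defaults give
decreasing mean frequency with increasing impact severity — 0.20 for
modifier down to 0.05 for high), genotypes Binomial(2, f) within
populations (Hardy–Weinberg), outgroup species fixed ancestral, an
intergenic control set, uniform random missingness, and annotation values
(GERP, phyloP, phastCons, FPKM) consistent with each site's class. A
truth table records category, control status, derived allele and the
realized per-population frequency.

What it deliberately does **not** emulate: linkage (the empirical
statistics treat sites marginally), call-rate structure by population or
site, coverage-dependent genotype error, indels, and caller artifacts.
Passing tests on these fixtures therefore validate the *statistics*, not
robustness to real-data pathologies.

## What the tests compute, and at what size

The suite checks every worked arithmetic identity exactly (the Rxy toy
ratio 1/9, its reciprocal 9, π = 2/3 for two diploids 0/0 and 1/1, load
0.25 for half the females at fitness one half), equality of SFS, counts
and ROH with brute-force oracles (50 random 1–2k-SNP ROH fixtures),
neutral heterozygosity decay within 2% of \((1-1/2N)^t\) at N = 50,
t = 200 over 10⁴ loci, a neutral SFS against an independent Wright–Fisher
oracle, Rxy reciprocity and null calibration over 20 cohorts, and the
dominance-map mean over 10⁶ gamma draws against 0.37 (closed form
\(0.5(1+51\theta)^{-0.3}\)).

The two purging claims run at deliberately modest size: a two-epoch
bottleneck (K = 500, five generations at K = 10, recovery; 100 planted
near-recessive lethals with s = 0.6, 100 mild loci with s = 0.005, 200
neutral controls, standing frequency 0.1, 50 replicates) must show
Rxy < 1 post- vs pre-bottleneck in at least 80% of replicates for the
lethals and not for the mild class; and the scale-10 reintroduction
scenario (500 selected + 500 neutral loci, 50 replicates) must show a
median Rxy below 1 for the highest-s decile in the most-bottlenecked
patch against all others, a rise in mean load across the species
bottleneck, and extinction risk concentrated in the smallest captive
patches. The full-scale published parametrization (3000-generation
burn-in, 100 replicates, 5500 loci) is left to HPC time and to the
historical founder records; its quantitative extinction rates are not
asserted here.

## Known limitations

* Polarization cannot identify REF-derived sites (outgroups fixed ALT).
* The ROH scanner is the window heuristic, not an HMM caller; the two
  differ in known, documented ways on real data.
* No age structure, no environmental stochasticity, no linkage in the
  simulator; scenario carrying capacities treat census harmonic means as
  constants.
* The shipped demography's founder counts are placeholders (see above).
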
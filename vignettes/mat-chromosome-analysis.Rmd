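---
title: "Methods: allelic divergence, gene conversion and crossover detection on mat chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic divergence, gene conversion and crossover detection on mat chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

*Neurospora tetrasperma* is pseudohomothallic: each individual carries nuclei
of both mating types, and selfing keeps most of the genome effectively
homozygous. Its mating-type (*mat*) chromosomes, however, contain a large,
young (< 6 MY) region around the *mat* locus in which crossing over is
suppressed. Within that region the *mat A*- and *mat a*-linked alleles of a
gene diverge like alleles on young sex chromosomes; outside it, recombination
under selfing keeps the two alleles of a pair essentially identical
("homoallelic"). Because heterokaryons can be split into their two haploid
single-mating-type component strains, allelic divergence is directly
measurable gene by gene.

tetmat implements the comparative analysis built on this contrast for ten
strain pairs spanning the nine phylogenetic lineages of the species complex:

1. per-gene allelic divergence within each pair (`divergence_table()`);
2. per-gene genealogies with branch supports and an allele *phase* call per
   pair (`bootstrap_supports()`, `pair_phase()`);
3. demarcation of the recombinationally suppressed region per pair and
   comparison of its boundaries across lineages (`demarcate_region()`,
   `compare_boundaries()`);
4. detection of gene-conversion events (three-genealogy window rule),
   template direction, ancestral merging, and crossover detection
   (`detect_conversions()`, `infer_template_direction()`,
   `merge_ancestral_events()`, `detect_crossovers()`);
5. per-site homogenization rates `r = K/(2T)` (`homogenization_rate()`).

A forward-time simulator (`sim_config()`, `simulate_dataset()`) generates
datasets with the same statistical structure plus a ground-truth table, so
every stage can be validated against planted events.

## Allelic divergence

Coding divergence uses the Nei–Gojobori (1986) method. Each codon contributes
synonymous sites equal to one third of its synonymous single-base neighbours
per position (mutations to stop codons count as nonsynonymous). Codons
containing a gap, an ambiguous base, or a stop in either sequence are removed
pairwise. Differences in codons hit more than once are averaged over all
minimal mutational pathways with equal weights; pathways through intermediate
stop codons are excluded unless every pathway passes through one. The
proportions `pN = Nd/N` and `pS = Sd/S` are corrected separately with
Jukes–Cantor, `d = -(3/4) log(1 - 4p/3)`, which is undefined at `p >= 0.75`
(reported as an explicit error carrying the raw proportion). These
conventions follow the widely used DnaSP behaviour; implementations of NG86
differ in exactly these corners, which is why they are spelled out here and
pinned by a brute-force pathway-enumeration oracle in the test suite.

Intron divergence is a plain SNP count over noncoding columns where both
strains have unambiguous bases; indel columns are ignored, and genes without
noncoding columns report the count as absent (printed `-`).

## Genealogies and allele phase

Trees are built by neighbor joining on Jukes–Cantor distances with pairwise
deletion, with nonparametric bootstrap over alignment columns
(`bootstrap_reps = 1000` by default; the examples below use fewer for speed).
Support is counted per unrooted bipartition, so rotation and rooting of
replicate trees are irrelevant. Zero-length branches are collapsed into
polytomies before support assessment: neighbor joining resolves ties among
identical sequences arbitrarily, and a deterministic tie-break would
otherwise manufacture high "support" for branches carrying no signal.
Externally inferred trees (e.g. ML or Bayesian, with bootstrap and/or
posterior labels) can be supplied wherever a tree is consumed; labels are
interpreted by magnitude (`85` is a bootstrap percentage, `0.99` a posterior
probability, `85/0.99` both).

A branch is *supported* when its bootstrap is at least `bootstrap_min`
(default 70, the conventional proxy for ~95% confidence) **or** its posterior
probability is at least `posterior_min` (default 0.95). For each pair and
gene, the phase of the two alleles is:

* **separated** — some supported branch lies on the path between them;
* **together** — no supported branch on the path *and* patristic distance at
  most `together_max_dist` (default 0.005 substitutions/site, tolerating the
  1–2 bp residue of an incompletely homogenized gene);
* **unresolved** — otherwise, including missing strains.

The distance guard matters: without it, any gene whose inter-allele branches
merely lack bootstrap support would be mistaken for a homogenized gene.

## Suppressed-region demarcation

Classification is deterministic counting, not hypothesis testing: a gene is
*diverged* for a pair at `min_diffs` (default 2) or more raw differing
columns, *homoallelic-flagged* at exactly one (single SNPs are expected from
rare outcrossing even in recombining regions), *homoallelic* at zero. The
suppressed region is the span from the leftmost to the rightmost diverged
gene; homoallelic genes strictly inside the span remain inside it and are
listed as conversion candidates rather than treated as interruptions —
a homogenized gene does not re-enable crossing over around itself. Flagged
genes never set boundaries. Boundaries are compared across pairs and
deviations from the modal boundary flagged, which is how lineage-specific
expansion or contraction of the region shows up.

## Event detection

**Conversions.** A conversion is called at gene *g* for a pair when the
pair's alleles are together at *g* but separated in the flanking genealogies
on both sides, with at least one flank's separation supported. By default an
unresolved neighbour extends the window to the nearest informative gene
(`strict = TRUE` restricts to immediate neighbours). Genes at the ends of the
chromosome — and events at the first or last informative gene of the span —
are undetectable by this rule; they are a stated blind spot, not guessed at.
Detection runs genome-wide; each event is annotated as inside/outside the
pair's suppressed span, and headline counts use inside-span events only.

**Template direction.** The donor chromosome is read off the focal
genealogy: the smallest supported clade containing the converted alleles
whose other resolved members are uniformly (`direction_majority`, default
unanimity) *mat a*-linked alleles of other pairs implies a *mat a* template,
and symmetrically for *mat A*; anything else is `unknown`. Pairs converted at
the same gene are excluded from the context, since their alleles are copies
of the converted material rather than independent evidence. With weakly
diverged genes the stem separating the A- and a-allele clades can be too
short to reach 70% bootstrap, and the direction is honestly reported
`unknown`.

**Ancestral merging.** Per-pair events at one gene are merged into a single
ancestral event when the converted alleles are identical across pairs
(`merge_max_diffs = 0` by default; a proportional tolerance is available).
Identity across lineages places the conversion before their split, and the
merged event carries the union of lineages.

**Crossovers.** Each allele is assigned the mating type of the smallest
supported allele clade of *other* pairs it nests within, walking outward
past clades whose context is mixed (the complement of an unrelated clade is
mixed by construction and carries no affiliation signal); a pair is
*swapped* at a gene
when its A-linked allele sits among a-alleles and vice versa. A crossover is
placed between consecutive informative genes where the state flips, provided
the runs on both sides persist for `persistence` (default 2) informative
genes or reach a chromosome end. The two-sided persistence requirement is
deliberate: a single misleading genealogy flips the state twice, and a
one-sided rule would emit a spurious event on the way back.

**Rates.** `r = K/(2T)` with `K = events/n_lineages` and `T` the lineage
divergence time (default 4.6 MY). The headline `K` counts each merged event
once — an event ancestral to several lineages is one event — and the
per-affected-pair variant is reported alongside, since both conventions are
defensible and give different answers for ancestral events.

## The simulator: what it emulates and what it does not

`sim_config()`'s `"study"` preset reproduces the survey design: the 24-gene
layout with its published coding lengths (rounded down to whole codons; a
300 bp intron is attached to the genes whose survey rows carry intron
counts), 10 pairs over 9 lineages with lineage 8 sampled twice, and the
landmark positions (mat locus after *un-3*, centromere after *eth-1*).

The generative model is deliberately minimal:

* **Phylogeny.** A dated lineage tree, by default a star radiation at
  4.6 MY — the complex's internal phylogeny is largely unresolved — with
  three resolved details used by the planted ancestral events: a (3, 8)
  clade and a (5, 6) clade at 2.5 MY, and the two lineage-8 pairs splitting
  at 1.0 MY.
* **Recombination suppression.** Suppressed genes descend from a haplotype
  duplication at 5.5 MY (inside the < 6 MY age bound): both mating-type
  haplotypes traverse the tree independently, so alleles cluster by mating
  type. Recombining genes are carried as a single haplotype and the pair's
  second allele is a copy — selfing is modeled as complete homogenization
  rather than mechanistically. Lineage-specific strata (e.g. *rid*
  suppressed only in lineage 4) use a cessation time on that pair's terminal
  branch; such alleles diverge but do not cluster by mating type, which is
  also what the tree-based phase call honestly reports (unresolved) while
  the divergence-based classification still maps the region.
* **Mutation.** Jukes–Cantor events at per-gene rate `mu`, with proposed
  nonsynonymous coding changes accepted with probability `omega`
  (default 0.05) and stop-creating changes rejected. Per-gene rates are
  calibrated as `mu = dS_target/(2 * 5.5)` from round per-gene allelic dS
  targets in the observed 0.02–0.06 range. This is a calibration to the
  survey's magnitudes, not an inference about the loci.
* **Conversions.** A planted conversion copies the template haplotype's
  allele — whole-gene or a prefix tract fraction — over the recipient at the
  present day, i.e. events are completely homogenizing, matching the
  observation that converted pairs are identical (and letting ancestral
  events be recognized by strict cross-lineage identity, as in the real
  analysis). The event time is retained for feasibility checks (an ancestral
  event must predate the split it spans) and truth bookkeeping. The default
  plan plants 8 events: single-pair events at *lys-4* (L4) and *arg-1* (L3),
  ancestral events at *cys-5* (lineages 5+6), *ser-3* (lineages 3+8) and
  *ad-9* (the two lineage-8 pairs), lineage-specific *ser-3* events in L2,
  L4 and L7 — the two latter with a 0.95 tract, leaving the 1–2 bp residue
  of incomplete homogenization.
* **Crossover.** One planted exchange in pair L4 between *upr-1* and
  *erg-8*: all genes to the right swap chromosome linkage.
* **Outcrossing noise.** Each recombining (pair, gene) cell carries one
  planted SNP with probability 0.06, reproducing the handful of single-SNP
  flank exceptions.

Not modeled: within-lineage coalescence, indels, rate heterogeneity along a
gene, translocations, and post-conversion re-divergence. Passing recovery
tests on these simulations therefore demonstrates the *detection logic* —
window rule, support handling, merging, persistence — under the assumed
structure; it does not certify performance on data violating it (e.g.
conversions old enough to have re-diverged, or pervasive introgression).

The `"clear"` preset (every gene 1200 coding + 300 intron bp, allelic dS
~0.05) is the high-signal regime used for the 20-replicate recovery
experiments in the test suite: conversion sensitivity is required to reach
0.9 with at most one false positive overall, the crossover interval must be
recovered exactly, and suppression spans must match truth wherever the
boundary genes meet the divergence criterion.

## Numerical and reproducibility choices

* Coordinates are 0-based with half-open intervals throughout the file
  formats; gene order indices come from the layout.
* All randomness flows from one integer seed: per-gene simulation and
  bootstrap seeds are derived by hashing the stage name (`derive_seed()`),
  so adding a gene or stage never perturbs the others, and reruns are
  byte-identical.
* Bootstrap replicates whose resampled distances are undefined (a pairwise
  difference proportion >= 0.75) are dropped from the support denominator.
* Negative NJ branch lengths are clamped to zero in patristic distances;
  trees without branch lengths fall back on the support criterion alone for
  the together/separated call.
* Ties in the modal-boundary comparison resolve to the first mode; the flags
  are descriptive, not tests.
* Test problem sizes: the study preset (24 genes, 20 strains, ~0.5–3.3 kb)
  with 200 bootstrap replicates for end-to-end checks, and 20 replicate
  clear-regime datasets for the recovery experiments — sizes chosen so the
  whole suite exercises every stage at full fidelity while remaining quick
  to run.

## Known limitations

* Tree inference is NJ + JC + bootstrap; likelihood or Bayesian trees are
  accepted as inputs but not computed. The event logic only consumes
  supported bipartitions, so any source of supported trees works.
* Events at span-terminal genes are undetectable by the window rule.
* Template direction requires a supported clade context; weakly diverged
  genes yield `unknown`.
* The `i` (intron difference) statistic counts SNPs only; indel
  polymorphisms are ignored by design.
* `K` for a gene converted in several pairs depends on the counting
  convention; both are reported, the merged-event count being the headline.
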
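---
title: "Mutation-accumulation line analysis: model, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation-accumulation line analysis: model, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malines)
```

## The model

A mutation-accumulation (MA) experiment propagates many isogenic lines from
one founder, each through a single-individual bottleneck every generation.
Because the effective population size within a line is 1, new mutations fix
or are lost almost independently of their fitness effect, and after `G`
generations each line carries a private set of homozygous mutations. With
multi-sample genotyping of all lines against the founder's reference genome,
a line's mutation rate per site per generation is estimated as

$$\hat\mu = \frac{n}{G \cdot L},$$

where `n` counts that line's accumulated mutations of a type (SNV, insertion,
deletion) and `L` is the **callable length**: the number of positions where
more than half of the group's lines have more than five reads. Using the
callable length rather than the assembly length keeps lines with uneven
coverage comparable — a mutation can only be counted where it could have been
seen, so the denominator must be restricted the same way.

**Modelling assumptions.** Each surviving mutation is treated as fixed
homozygous in its line from its generation of origin; heterozygous segregation
through the one-individual bottleneck is not modelled, because the detection
criteria score only homozygous line-specific variants and any mutation still
segregating at sampling time is invisible to them anyway. Mutation counts per
line and type are Poisson with mean `mu * L * G`; sites are exchangeable
(no mutational hotspots beyond base composition).

## Detection criteria and thresholds

A site contributes one accumulated mutation when all of the following hold
(`ma_thresholds()` defaults in parentheses; all comparisons on integer VCF
fields):

| criterion | rule | default |
|---|---|---|
| (i) | exactly one homozygous genotype class present in more than one line | — |
| (ii) | alternative homozygote in exactly one line, depth no less than five reads | `min_dp_focal = 5` (DP ≥ 5) |
| (iii) | no other line heterozygous for any alternative allele | — |
| (iv) | at least 10 lines reference-homozygous with more than five reads | `min_support_lines = 10`, `min_dp_support = 6` (DP > 5) |
| (v) | focal genotype quality larger than 20 | `min_gq = 21` (GQ > 20) |
| (vi) | no other same-line candidate within the linkage window; both members of a linked pair are removed | `link_window = 100` bp |

The asymmetry between (ii) "no less than five" (≥ 5) and (iv) "more than
five" (> 5) is deliberate and preserved exactly. Missing genotypes count
neither as (iii) violations nor as (iv) support. Multi-allelic sites are
judged jointly: a het for *any* alternative allele violates (iii), and two
lines homozygous for *different* alternative alleles violate (ii). Criterion
(i) is read as: exactly one homozygous class — reference, or one specific
alternative allele — is carried by two or more lines, which pins down the
ancestral state and makes the focal homozygote unique.

**Linkage window (vi).** How linkage was established for the original
criterion is not specified anywhere we could follow, so the package uses
physical distance with a configurable window, defaulting to 100 bp; both
members of a pair are removed because a closely spaced "pair" of candidates
is more often one mis-resolved complex event than two independent mutations.
Known real cases of two genuine mutations 2 bp apart exist, so this filter
deliberately trades a little recall for precision.

**Contamination screen.** Cross-contamination between two lines makes their
private mutations shared, which the filter then discards — silently deflating
both lines' rates. `pairwise_sharing()` counts, for every line pair, loci
where both are homozygous for the same alternative allele, restricted to loci
with all lines above five reads and an alt-homozygote fraction below 30%
(removing founder background heterozygosity). `flag_contaminated()` flags
pairs above `median + 5 * MAD` of the pair counts; the rule is this package's
own plumbing (the original screens were done by inspection), chosen because
sharing counts are near-zero for clean pairs and grossly elevated for
contaminated ones, making any robust outlier rule adequate. Flagged lines are
then excluded by listing them in the group's `excluded` field, mirroring how
such lines are dropped in practice.

## Rates, confidence intervals, fold changes

`group_summary()` reports the arithmetic mean of per-line rates with a 95%
half-width of `1.96 * sd / sqrt(n_lines)` by default. Published MA tables
print "±" values labelled 95% confidence whose construction is ambiguous (the
printed magnitudes are consistent with neither a clean SEM-based nor a clean
SD-based interval in all columns), so both conventions are implemented
(`ci = "sem"` / `ci = "sd"`) and the output records which was used.
Candidates outside the callable mask are dropped from rate numerators — the
denominator only counts callable sites, so counting non-callable candidates
would bias the estimator upward; the number dropped is reported.

Fold changes between groups are `max(mean)/min(mean)` rounded
half-away-from-zero at the requested number of decimals (base R's banker's
rounding would turn 2.05 into 2.0 rather than 2.1).

## Spectra

SNVs are classified into the six strand-collapsed classes
`A:T>T:A, A:T>C:G, A:T>G:C, G:C>A:T, G:C>T:A, G:C>C:G`; transitions are
`A:T>G:C` and `G:C>A:T`.

**AT bias** is defined here as the composition-normalized flux ratio
`[(G:C>A:T + G:C>T:A)/GC sites] / [(A:T>G:C + A:T>C:G)/AT sites]`. Published
"ATBias" columns print values without a formula; this package's definition is
its own and is documented as such — its values are not claimed to reproduce
any published column.

**Triplet context.** Reference triplets are strand-collapsed so the
representative has an `A` or `C` center; a triplet with `T`/`G` center is
reverse-complemented along with the substitution. `TTA` with a central `T>A`
and `TAA` with a central `A>T` are reverse complements and therefore land in
the same cell (`TAA`, class `A:T>T:A`) — any involutive collapse must merge
them, and the A/C-center convention matches the class labels. Contig-edge
SNVs go to an `edge` bucket excluded from context totals.

**Consequences.** SNVs in a CDS are classified by translating the affected
codon (`synonymous` / `missense` / `stop_gained`); a "coding" mutation is one
whose consequence is missense, synonymous or stop_gained, plus indels
overlapping a CDS (`coding_indel`, no frameshift subtyping). Stop-loss
changes are folded into `missense` (amino-acid-changing; vanishingly rare at
MA scale). A mutation coding in any overlapping transcript counts as coding.
Genes whose spliced CDS length is not a multiple of 3 are skipped for codon
translation with a warning and remain genic.

## Statistics

Group comparisons use exactly the classical tests of the field: two-sided
Wilcoxon rank-sum on per-line rates (exact for moderate n without ties),
two-sided F test on rate variances, and Fisher's exact test on spectrum and
length contingency tables with the probability-mass two-sided criterion.
For tables larger than 2x2 the exact network computation is replaced by a
seeded Monte-Carlo estimate over tables with fixed margins,
`p = (hits + 1)/(n_mc + 1)` with `n_mc = 1e5` by default — amply accurate for
6x2 spectrum tables and reproducible bit-for-bit under a fixed seed. Raw
p-values are reported by default, matching standard MA-study practice; a
Benjamini-Hochberg option exists for the pairwise comparison report. Indel
length tables, where needed as contingency tables, default to bins
1, 2, 3, 4, 5–9, 10+ (a choice, since no canonical binning exists).

## The synthetic generator: what it emulates, what it does not

`sim_params()` describes the stated world: founder genome of iid bases at a
configurable GC content (default 0.42, nematode-like), `n_lines = 20` lines,
`G = 100` generations, per-site per-generation rates
`mu_snv = 1e-7, mu_ins = 2e-8, mu_del = 3e-8`. These defaults are the
**desk-scale setting**: real nematode MA rates are ~1.7–2.4e-9 SNVs/site/gen
on ~150 Mb genomes; scaling the genome down to 1 Mb and the rates up ~50x
keeps expected counts (~10 SNVs/line) testable in seconds while leaving every
downstream computation unchanged. Passing real-scale rates with a full-size
genome is the un-inflated mode. SNV classes follow a configurable 6-class
spectrum (default with 55% transitions, a plausible nematode-like shape);
indel lengths are `1 + Geometric(mean - 1)` with mean 3 bp; coverage is
`Poisson(30)` per call; GQ is normal (mean 80, sd 15) clamped to [0, 99].

Noise dials: `het_miscall_rate` (a non-carrier emitted het — exercises
criterion iii), `missing_rate` (calls become `./.`), and `contamination`
(a fraction of one line's mutations copied into another — exercises the
sharing screen). "Noiseless" in the package's tests means
`het_miscall_rate = missing_rate = 0` **and** `gq_sd = 0`: the GQ spread is
part of the genotyping noise model, and with sd 15 a draw falls below the
GQ > 20 threshold at rate ~4e-5, which is exactly the kind of noise a
noiseless world excludes.

Two desk-scale design choices depart deliberately from a literal reading of
the world. First, planted positions are unique genome-wide across lines, not
just within lines: at real scale cross-line collisions are negligible
(~1e-5 per experiment), but at desk scale (~300 mutations on 1 Mb) they occur
in roughly a third of runs, and any collision makes both mutations
undetectable under criterion (ii) — so genome-wide uniqueness is the faithful
rendering of the real-scale world at desk scale. (Deliberate contamination
still shares positions across lines.) Second, instead of emitting ~1e6
invariant VCF records for the callable-length computation, the emulator
simulates a whole-genome per-line depth track and returns the callable mask
run-length encoded; `callable_mask()` accepts explicit depth tables for real
data.

What a green test on synthetic data does **not** establish: the emulator
models neither alignment artifacts, mapping bias, repeat-induced systematic
miscalls, indel left-alignment ambiguity beyond a small uniform jitter, nor
read-level error correlation. Detection performance on real reads must be
benchmarked with the file-based interfaces (`apply_insertions()` writes an
edited FASTA; any external caller's VCF can be scored with
`match_detected()`).

## The error-rate benchmark

False negatives are estimated by planting mutations into the *reference*
genome at least 200 bp away from every detected mutation, every other
planting, and contig ends, then re-running detection and scoring recall in
regions with enough coverage (`DP > 5` at the planted anchor, the callable
rule). Matching rules: a planted SNV counts as detected only with the same
base change at the same locus; a planted indel with a detected variant of the
same type within 5 bp upstream (indel placement is not unique); matching is
injective with nearest-upstream tie-break. One subtlety: editing the
*reference* means a planted insertion manifests in every sample as a called
deletion (the reads lack the inserted bases). `match_detected()` implements
the literal same-type rule; `fn_benchmark()` therefore translates its
emulated calls back into the planted frame before matching, so the rule
applies coherently. Emulated indel anchors are jittered 0–3 bp upstream to
exercise the fuzzy matching, as real callers place ambiguous indels
inconsistently.

False positives are estimated from an ancestral line sequenced alongside the
group: among loci with at least one alternative homozygote, the fraction
carried *only* by the ancestor (which predates the experiment and so cannot
carry a real accumulated mutation) estimates the calling pipeline's FP rate.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive everywhere (VCF/GFF convention); indels
  carry their VCF anchor base and are assumed left-aligned upstream — the
  package does not re-normalize.
* Missing DP with a present genotype is read as DP 0 (fails every depth
  threshold, conservative).
* `ts_tv()` with zero transversions, `at_bias()` with an empty denominator
  class, `fn_rate()` with zero covered plantings and `fp_rate_ancestral()`
  with no alt-homozygote loci all return `NaN` with a warning rather than
  failing — undefined is reported as undefined.
* `fold_change()` errors when a group mean is zero (the ratio is undefined).
* A group with fewer than `min_support_lines + 1` usable lines is a
  configuration error: criterion (iv) could never be satisfied.
* All randomness flows from a single integer seed; stage seeds are derived
  by fixed offsets, so every pipeline output is byte-identical under a fixed
  seed.

## Known limitations

* Single-contig founders only in the simulator (real data may have any number
  of contigs).
* The fixed-on-origin homozygosity model ignores the 2–3 generations a real
  mutation spends segregating; rates are unaffected in expectation but
  generation-of-origin stamps are approximate by that amount.
* The consequence classifier handles spliced CDS but not splice-site or UTR
  effects, and folds stop-loss into missense.
* The contamination rule flags pairs, not directions; deciding *which* line
  of a flagged pair to exclude needs external information, as in practice.
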
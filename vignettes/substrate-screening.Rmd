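---
title: "Screening SILAC phosphoproteomics for kinase substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening SILAC phosphoproteomics for kinase substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoscreen)
```

## The inference problem

An analog-sensitive kinase allele lets a bulky ATP analog inhibit one
kinase specifically and acutely. Combined with SILAC labeling, a single MS
run then reports, per phosphosite, the heavy/light abundance ratio between
inhibitor-treated and control cultures; sites whose phosphorylation
reproducibly collapses after inhibition are substrate candidates, and those
whose sequence context matches the kinase family's consensus motif are
candidate *direct* substrates. `phosphoscreen` implements this inference
chain. This vignette documents the model, its assumptions, every tunable
parameter, the synthetic-data generator used for validation, and the design
choices made where the procedure was genuinely open.

## From raw ratios to a per-site estimate

**Orientation.** Raw ratios are heavy/light. The design table states, per
experiment, whether the treated culture was in the heavy channel
(`orientation = heavy_treated`, oriented value `log2(r)`) or the light
channel (`light_treated`, `-log2(r)`). The canonical design has three
treatment replicates — two heavy-treated and one label-swapped — plus one
control experiment in which wild-type cells (no analog-sensitive allele)
receive the analog, capturing off-target effects. Orientation is an exact
involution: inverting every ratio and flipping every orientation leaves all
downstream numbers unchanged.

**Protein normalization.** A phosphopeptide ratio confounds
phosphorylation change with protein-abundance change (an abundance-induced
increase in a secreted phosphatase is the archetypal trap). Where the
protein was quantified in the same experiment, the site's oriented log2FC
minus the protein's oriented log2FC isolates the phosphorylation component.
The subtraction-on-log-scale arithmetic is our choice — the goal
(normalization to protein abundance) admits only this scale-consistent
form, but we state it explicitly because upstream software sometimes ships
its own normalized columns.

**Localization filter.** Each measurement carries a probability that the
phosphate sits on the stated residue. Measurements below the threshold
(default 0.75, *inclusive* at the boundary) are dropped *per replicate
measurement*: a site can pass in one replicate and fail in another, and its
replicate count records only surviving measurements. Raising the threshold
can therefore only shrink replicate counts (a tested monotonicity).

**Aggregation precedence.** The per-site summary is the arithmetic mean of
log2 fold-changes (mean of logs, not log of mean, to damp outliers). If
*any* replicate provides a protein-normalized value, the mean uses only
the protein-normalized values and ignores raw values from other replicates;
only sites with no normalized value anywhere fall back to the raw oriented
values. The control experiment is summarized by the identical rule — the
procedure is described once, and we assume symmetry rather than inventing a
second rule for the control. No missing value is ever imputed.

## Stringency tiers, ranking, motif

A site enters a tier when three conditions hold:

1. mean treatment log2FC **strictly** more negative than
   `decrease_cutoff_log2` (default −1.0; "greater than 2-fold decrease" is
   a strict inequality, so a mean of exactly −1.0 fails);
2. the control mean is **not** strictly more negative than
   `control_cutoff_log2` (default −1.0). An absent control mean passes:
   exclusion requires affirmative evidence of an off-target decrease, not
   absence of evidence;
3. quantified in ≥ 1 / ≥ 2 / 3 treatment replicates for the lowest /
   medium / highest tier.

Conditions 1–2 are shared, so the tiers are nested by construction
(highest ⊆ medium ⊆ lowest); the test suite asserts the inclusion on every
synthetic run anyway, as a guard against regressions. Candidates are ranked
by ascending mean log2FC (most negative first) independent of motif match,
with lexicographic site-id tie-breaks so ranking is deterministic. The
"strong" subset within the highest tier uses an *inclusive* cutoff
(`mean ≤ strong_cutoff_log2`, default −2.0): "4-fold or greater" includes
the boundary, unlike the strict "more than 2-fold" tier rule — the boundary
semantics follow the wording of each rule literally.

Two counting modes exist because both framings are in common use: the
mean-based tier classification above, and a per-replicate mode
(`count_by_replicate_decrease()`) in which a site counts toward "decreased
in ≥ k experiments" when k individual replicate values are strictly below
the cutoff, under the same control exclusion. Both are exposed;
`kinase_screen()` reports both.

The NDR/LATS consensus `HxR/H/KxxS/T` is encoded positionally: H at −5, a
basic residue {H, R, K} at −3, S/T at 0; offsets −4, −2, −1 are free.
Categories are `full_consensus` (all three), `basic_minus3_only`
(−3 and acceptor but no −5 histidine), `no_match`. We constrain only these
three positions — the consensus string names no others. The terminal
padding character `_` fails every constraint: a site five residues from the
N-terminus cannot match a position outside the protein. Windows default to
31 residues (half-width 15, the width common site-table software emits);
the motif needs only half-width ≥ 5.

**Enrichment.** Fold-enrichment of a term is `(k/n)/(K/N)` — cluster
frequency over genome frequency — with the exact hypergeometric upper tail
`P(X ≥ k)` as significance. The annotation map is taken as already
propagated (no ontology-graph inheritance). Raw p-values are reported by
default with an optional Bonferroni correction, flagged in the output;
published term-finder p-values depend on an external annotation database
version and are not a computable target.

## Phenotype estimators

Rod-shaped cells are modelled as a cylinder with hemispherical caps:
`V = πr²(L − 2r) + (4/3)πr³` with `r = W/2`, degenerating to a sphere at
`L = W`. Elongation and widening rates are ordinary least-squares slopes of
length and width against time; the volume-expansion rate is the OLS slope
of the per-time-point volume (volume is derived from the two measured
dimensions, then regressed). OLS over the whole series is our choice of
estimator — the minimal defensible one for linear trends — and is exact to
machine precision on noise-free linear series. ACP secretion is OD405
activity divided by OD595 cell density (scale-invariant); FRAP recovery is
the bleached-region signal divided by the same region's pre-bleach signal.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
ground truth for recovery testing. Defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_proteins`, `protein_length_mean` | 300, 400 | uniform-composition proteome, Poisson lengths (floored at 11) |
| `n_true_substrates`, `true_effect_log2` | 50, −2 | planted substrates, 4-fold decrease |
| `n_null_sites` | 1000 | S/T/Y sites with zero effect |
| `noise_sd_log2` | 0.3 | per-replicate site-level log2 ratio noise |
| `protein_noise_sd_log2` | 0.1 | protein-level ratio noise; one third of the site SD because protein ratios average many peptides |
| `missing_rate` | 0.1 | per-site, per-replicate dropout |
| `locprob_alpha`, `locprob_beta` | 5, 1 | Beta localization probabilities: most sites confidently localized, a tail below 0.75 to exercise the filter |
| `frac_abundance_shifted_proteins`, `abundance_shift_log2` | 0.1, +1 | protein-level confound (positive = increased abundance after treatment) |

Planted substrates are placed one per protein, at least 6 residues from the
N-terminus, and the residues at −5, −3 and 0 are rewritten from the motif's
allowed sets, so every planted window is a full consensus match by
construction (one-per-protein placement prevents overlapping rewrites from
corrupting a neighbour's window). Null sites are drawn from the remaining
S/T/Y positions without editing, so a null can match the motif by chance —
as in real data. Per experiment, each site's oriented log2 value is
`true effect (treatment only) + protein shift + N(0, noise_sd_log2)`,
folded back through the experiment's label orientation into a raw ratio, so
the label-swapped replicate carries reciprocal ratios. Replicate decrease
counts, noise spread, missingness rate and orientation algebra are all
checked against their configured values in the test suite.

The replicate-ratio noise SD of 0.3 is a free parameter of the generator,
not an empirically fitted value — the source experiments do not report
replicate variance. Sensibly, it makes a planted 4-fold decrease clearly
detectable over three replicates while leaving single-replicate calls
noisy, which is the regime the tier system is designed for.

What the generator does *not* emulate: peptide-level effects (missed
cleavages, charge states, co-eluting isobaric peptides), multiply
phosphorylated peptide multiplicities (tables are taken as one value per
site, a documented assumption of the reader as well), intensity-dependent
missingness (dropout is uniform, not abundance-correlated), and correlated
noise between sites on the same protein. Passing recovery tests therefore
show the *logic* is correct under the stated noise model, not that the
thresholds are optimal for any particular instrument's error structure.

## Numerical and interface choices

- Determinism: every generator seeds the base RNG once from `seed`, with
  sub-streams at fixed offsets (`seed + 1` for planting, `seed + 2` for
  simulation), so identical configs give byte-identical outputs; reports
  contain no timestamps, so pipeline runs are byte-reproducible.
- The orientation involution is exact in floating point only when ratio
  inversion is exact (powers of two); the bit-identity test uses dyadic
  ratios and a companion tolerance test (1e−12) covers arbitrary ratios.
- `aggregate_site` on two empty value lists yields an absent mean (never
  0); a site quantified only in the control has `n_treatment = 0` and no
  tier.
- Percent display: integers at ≥ 2%, one decimal below (half away from
  zero, trailing ".0" dropped) — reproducing conventional report strings
  ("4%", "1.5%", "0.7%", "65%", "0%").
- Hypergeometric tails come from `stats::phyper`; tests verify it against
  direct summation of the mass function over the full grid N ≤ 40.
- Pearson correlations use sites quantified in both replicates post-filter,
  each replicate contributing its retained value (normalized when present);
  with fewer than two common sites the correlation is absent, not 0.
- Malformed table rows (non-positive ratio, bad position, window/residue
  mismatch, duplicate site) abort with row-numbered messages rather than
  being silently dropped; the MaxQuant reader drops rows flagged
  reverse/contaminant, as is conventional.

## Validation problem sizes

The test suite validates the tier classifier against a brute-force truth
table on 10,000 randomized summaries, the motif classifier against a regex
oracle on 10,000 random 11-mers, tier nesting across 20 seeded synthetic
runs of 1,050 sites, and substrate recovery on a 300-protein / 1,050-site
screen (50 planted at −2, noise SD 0.3, no dropout: ≥ 49/50 planted reach
the highest tier, ≤ 1/1,000 nulls reach any tier). These sizes give stable
pass/fail behaviour at comfortably sub-minute runtimes; the recovery
margin (mean SE ≈ 0.18 against a 1-unit gap to the cutoff) makes the
expected failure count per run ≪ 1.

## Known limitations

- Multiplicity handling: multiply phosphorylated peptides are assumed
  collapsed to one value per site upstream.
- No false-discovery-rate control across sites: the tier system trades
  formal error control for reproducibility requirements, as the original
  screening design does.
- The control exclusion uses the control *mean*; with a single control
  experiment this is one noisy measurement, and a noisy control value near
  the cutoff can drop a genuine substrate.
- Enrichment assumes a pre-propagated annotation map and reports raw
  p-values by default.
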
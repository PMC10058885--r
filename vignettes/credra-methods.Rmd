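---
title: "Methods: band-profile genotoxicity and CRED-RA methylation typing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-profile genotoxicity and CRED-RA methylation typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credra)
```

## The data model

Both assays produce *dominant markers*: anonymous PCR bands scored only
as present (1) or absent (0) on a gel, matched across samples by
position. The package's exchange object, the `band_matrix`, mirrors this
directly: bands (identified by `(primer, band_id)`; fragment size is
carried as metadata but never used for matching), samples (one control
at dose 0 plus treated samples), and lanes. RAPD matrices have a single
undigested lane (`X`) per sample; CRED-RA matrices add the *HpaII* (`H`)
and *MspI* (`M`) lanes, so each band contributes a lane triplet
`(x, y, z)` per sample. One TSV dialect serves both assays (sample
metadata in header comments, one lane-qualified column per sample/lane);
`write_band_matrix()` followed by `read_band_matrix()` is the identity,
bit for bit, and every malformed input in the validation catalogue
(non-binary cells, dropped columns, duplicate band ids, missing control)
raises a classed error rather than being coerced.

Band calling itself — densitometry, faint-band thresholding — is
deliberately upstream of this package: the input boundary is the scored
binary matrix, because scoring conventions vary by lab and gel software
while everything downstream of the 0/1 matrix is exactly reproducible.

## Genotoxicity statistics

A treated sample's polymorphic bands are those that appeared (present in
the treated `X` lane, absent in the control's) or disappeared (the
converse). With `a` polymorphic bands and `n` control bands,

* polymorphism% `= a/n × 100`
* GTS% `= (1 − a/n) × 100`.

GTS is implemented as `100 − polymorphism%`, which makes the
complementarity identity exact in floating point, not merely close.
`a > n` is possible when many new bands appear; the negative GTS is
returned as computed, with a warning, because clamping would hide
pathological profiles. `n = 0` (a primer with no control bands) is a
domain error: the index is undefined, not zero.

For a per-dose index over a primer panel, `genotox_table()` pools: it
sums `a` and `n` across primers *before* dividing. Since `a` and `n` are
counts, pooling is the count-consistent aggregation; a per-primer mode is
also exposed for primer-level reporting, and the per-primer rows are
always emitted alongside the pooled `ALL` row so either reading can be
audited. Polymorphism is always scored on `X` lanes, even in CRED-RA
matrices — digestion lanes carry methylation information, not template
damage.

## Four-type methylation classification

*HpaII* and *MspI* both recognize CCGG but differ in methylation
sensitivity, so the triplet `(x, y, z)` classifies the site state:
`(y, z)` = (0,0) → Type I (non-methylation), (0,1) → Type II
(semi-methylation: hemi-methylated external cytosine — *HpaII* cuts,
*MspI* is blocked), (1,0) → Type III and (1,1) → Type IV (both
full-methylation). Two conventions exist in the MSAP literature for
which enzyme is blocked by hemi-methylation; this package implements the
Type II row as stated above, consistently in both the classifier and the
simulator's enzyme rules, so the two are exact inverses by construction.

A band with `x = 0` never amplified from undigested template and carries
no methylation information; it is tallied as `unclassifiable` — a value,
not an error — and excluded from every denominator. Percentages are
therefore shares of *classifiable* bands and sum to 100 exactly.

### Pattern ratios, two pathways

From type counts (`T = I+II+III+IV`): total `= (II+III+IV)/T × 100`,
full `= (III+IV)/T × 100`, semi `= II/T × 100`. The implementation
computes full and semi from these formulas and then *derives*
`total := full + semi` and `non := 100 − total`, so the conservation
identities hold to the last bit rather than to a tolerance — summing the
terms in a different order can differ by an ulp, and exact identities
are worth the small asymmetry.

Published tables often print the four type percentages alongside the
ratio rows, and the printed type percentages frequently do not sum to
100 (rounding upstream of publication; the shipped reference dataset's
control column sums to 97.70). The percent-vector pathway
(`pattern_ratios_from_percent_vector()`) therefore treats the
denominator as 100 and forms the plain linear sums — the only reading
that reproduces every printed ratio cell of such tables. The count
pathway is used by the pipeline on real matrices; the percent-vector
pathway reproduces printed tables. The two agree whenever the percent
vector sums to 100, which the suite checks property-style.

Per-dose tables are computed per primer and averaged with equal primer
weights by default (the "average rates" convention of published CRED-RA
tables), with pooled counts as the alternative mode.

## The synthetic-data generator

No raw band counts are published for this assay family, so validation
rests on a generator whose hidden truth is retained. It emulates, per
seed:

1. **Amplicons** — one random sequence per (primer, band), length
   uniform on 100–1000 bp (the usual RAPD sizing window), with *exactly*
   `sites_per_amplicon` CCGG motifs and no accidental extras (accidental
   motifs are scrubbed by redrawing a base; engineered motifs are placed
   with gap ≥ 4, which cannot create a boundary-spanning CCGG). Primer
   labels reuse the reference decamer panel names; the panel's sequences
   are metadata only, since some contain CCGG and would confound the
   controlled site count.
2. **States** — each CCGG site in each sample draws independently from
   the dose's probability vector over `{U, HE, IF, FF}` (unmethylated,
   hemi-external, internal-full, fully-methylated). No spatial or
   between-sample correlation is modeled: independent draws are the
   simplest model the recovery tests need, and correlation would be a
   config extension, not a default.
3. **Digestion** — *HpaII* cleaves `U`/`HE` and is blocked by `IF`/`FF`;
   *MspI* cleaves `U`/`IF` and is blocked by `HE`/`FF`. Any single
   cleavable site kills the band in that enzyme's lane, because a cut
   template cannot amplify the full-length product. With one site per
   amplicon and no mutation, drawn state and classified type are a
   bijection (`U→I, HE→II, IF→III, FF→IV`).
4. **Mutation** — treated samples lose each band with a per-dose
   Bernoulli probability (priming-site mutation: all three lanes go
   empty) and gain Poisson-many de novo bands per primer, present only
   in their own sample's `X` lane and cut by both enzymes (an
   unmethylated novel locus; its digestion status is otherwise
   unknowable, and this choice keeps the RAPD and CRED-RA views
   consistent). The control is the mutation-free reference by
   definition.

Draws consume a single seeded generator in fixed order (amplicons →
states → losses → gains), so identical configs give bit-identical output
files.

### Default calibration

The defaults *are* the reference study conditions and are not tuning
knobs: the dose ladder is 0 (control) plus 20, 40, 80, 160, 320, 640,
1280 mg/L; per-dose state probabilities are the reference type
percentages (`ref_type_percentages()`) normalized to sum to 1; and the
per-dose band-loss probability and band-gain rate split the reference
polymorphism deficit `(100 − GTS)/100` (`ref_gts_rates()`) evenly
between loss and gain — the published assay reports both phenomena
without publishing their split — so that expected polymorphism% equals
`100 − GTS(dose)` exactly: with loss probability `q`, gain rate `g` per
primer and `B` bands per primer, E[polymorphism%] `= 100(q + g/B)`. The
default panel is 6 primers × 10 bands: six is the reference study's
CRED-RA primer count, ten a typical RAPD band yield per decamer.

### What the simulator does *not* emulate

PCR kinetics, gel migration and band co-migration, primer
thermodynamics, realistic genome composition, spatially correlated
methylation, and scoring noise (faint bands, ladder miscalls). Passing
recovery tests therefore show that the statistics invert the stated
generative model — not that they are robust to gel-scoring artifacts,
which enter upstream of the package's input boundary. One consequence
worth knowing: because gained bands are modeled as unmethylated, runs
with nonzero gain rates inflate the Type-I share of small panels; the
recovery checks separate the two channels (a zero-mutation run for state
recovery, a default-rate run for polymorphism recovery).

## Numerical and design choices

* **Rounding** is half-up to 2 decimals (`0.125 → 0.13`, where base R's
  banker's rounding gives `0.12`), applied only at the view layer
  (`format_methylation_table()`, the `rounded` block of the pipeline
  JSON); all internal math is unrounded.
* **Degenerate inputs**: zero classifiable bands is a domain error for
  percentages and ratios; a primer with no control bands is a domain
  error for GTS; an all-`x=0` primer is dropped from the per-primer
  average with a warning.
* **Exactness**: complementarity (GTS + polymorphism = 100) and ratio
  conservation (total = full + semi, non + total = 100) are exact by
  construction and asserted with `==` in the suite.
* **Reports**: the JSON summary is canonical (seed, version, input
  checksums, unrounded and rounded values); TSVs and figures are views.
  Reports regenerate bit-identically from the same seed.

## Problem sizes used by the test suite

Classifier–simulator round trips run at 8 doses × 540 bands; parameter
recovery at 5,000 bands per dose with 3·SE binomial envelopes (a
once-chosen scale with sub-1.5-point standard errors on the dominant
type); the GTS sweep at 6 primers × 50 bands over loss rates 0–0.3; the
I/O property suite at 100 random matrices. The full suite runs in well
under a minute on one CPU.

## Known limitations

Band identity is positional and taken as given; co-migrating non-homologous
fragments are indistinguishable. The four-type scheme only sees CCGG
sites, and a multi-site amplicon reports the OR of its sites'
cleavabilities, so mixed-state amplicons fold into the "any cleavable
site" readout. Significance testing between dose groups is out of scope:
the assays' published tables annotate significance without defining a
test, and inventing one here would suggest false precision.
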
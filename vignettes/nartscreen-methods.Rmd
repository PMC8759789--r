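---
title: "Methods: models, parameters and design choices in nartscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in nartscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nartscreen)
```

# Overview

`nartscreen` quantifies neoantigen-reactive CD8+ T cells (NARTs) from
DNA-barcoded pMHC multimer screens. This vignette explains the statistical
model behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable reading existed.

# Library selection and annotation

A patient panel is selected from a neopeptide prediction table. Two modes
reflect the two regimes of neoantigen load:

* **high load** — include every peptide with mutant eluted-ligand
  percentage rank ≤ 0.5 and expression ≥ 0.1 TPM;
* **low load** — relax the expression floor to 0.01 TPM and take the top
  `target_size` (default 200) peptides by ascending rank.

Ranks tie-break lexicographically by peptide then HLA so that selection is
deterministic — prediction tables carry many tied ranks and an
order-dependent top-k would not be reproducible.

Binder classes compare the mutant against its germline counterpart: a
*conserved binder* (CB) has a germline rank within the binder threshold, an
*improved binder* (IB) does not (or has no germline counterpart, as for
frameshift peptides). The threshold defaults to 0.5 — the same bound used
for mutant-rank inclusion — and is exposed as an argument because published
CB/IB analyses do not always state the value; the boundary is assigned to
CB.

Feature annotation implements the conventions used for immunogenicity
characterization: *clonal* requires cluster size ≥ 80 **and** cellularity
≥ 90 (inclusive), and is `NA` — not `FALSE` — when those inputs are
unavailable (panels whose exome data came from tumour cell lines);
*high expression* is strictly greater than 2 TPM; *C/T status* accepts
`C>T` or `G>A` (the same transition reported on either strand, since
substitution tables rarely state strand conventions); *driver* membership
comes from a user-supplied gene list, with a small synthetic default
shipped under `inst/extdata/` as a placeholder only.

# Decoding and clonal reduction

Amplicon reads follow a configurable layout; the default is
`[primer 10 nt][A 25 nt][UMI 6 nt][anneal 10 nt][B 25 nt]`, one 6-nt UMI
per molecule. The layout is configurable (including a UMI per oligo)
because barcoded-multimer implementations differ and the amplicon
structure is a property of the wet-lab protocol, not of the analysis.

A read is assigned to the library barcode minimizing total Hamming
distance over the concatenated A+B segments, accepted only when that
distance is at most `2 * max_mismatch` (default 2 per 25-mer) **and** the
minimizer is unique; equidistant reads are dropped as ambiguous rather
than randomly assigned, keeping decoding deterministic and order-invariant.
Random 25-mer pairs are pairwise far apart with overwhelming probability,
and panel construction checks the separation and warns otherwise.

Clonal reduction counts distinct UMIs per barcode: read multiplicity from
PCR has no effect. UMI sequencing errors are *not* corrected (no
directional/network collapsing); the inflation this causes is small at the
default error rate and correction would add a tie-breaking policy with its
own biases. Base qualities are parsed and ignored.

# Enrichment model

Each sorted sample is tested against its run's baseline triplicate — the
sequenced, un-sorted multimer reagent pool, which captures the uneven
reagent composition.

**Normalization.** TMM factors: per-sample weighted trimmed mean of
per-barcode log2 abundance ratios against a reference (the sample whose
upper-quartile count fraction is closest to the mean), trimming 30% of M
values and 5% of A values on each side, inverse asymptotic-variance
weights, zero counts excluded, factors rescaled to geometric mean 1. The
implementation is validated against a brute-force oracle and against an
independent count-model package in the test suite.

**Test.** Counts are equalized to a common effective library size (the
geometric mean of `total * factor`). For each barcode the equalized sample
count and pooled baseline count are compared with a conditional
negative-binomial exact test: given the total, the sample share follows a
beta-negative-binomial with size parameters `1/phi` and `n_rep/phi`,
reducing to a Binomial(total, 1/(1+n_rep)) split in the Poisson limit
`phi = 0`. The common dispersion `phi` is a pooled method-of-moments
estimate from the normalized baseline replicates,
`sum(var - mean) / sum(mean^2)` floored at zero — replicate-driven,
closed-form, and reproducible; per-barcode shrinkage is left as a future
hook. One-sided enrichment p-values are doubled and capped at 1. Fold
changes use a prior count of 0.5 on both sides to stabilize small counts.

Because the common effective size is derived from the data, globally
rescaling all counts changes the information content (and hence p-values),
as it should for a count model. For workflows that need strict invariance
to a global rescaling, `effective_size` can be fixed explicitly; the test
suite verifies exact invariance in that mode.

**Calling.** Enriched ⇔ BH-adjusted p < 0.001 (strict) AND read fraction
≥ 0.1% of the sample's clonally reduced counts (inclusive) AND log2 fold
change > 0. The 0.001 threshold is treated as a fixed operational
constant, not re-derived from an FDR argument. Whether the original
count-model analysis was one- or two-sided is not documented; the doubled
one-sided tail with the positive-fold-change gate is used here and is
conservative for depleted barcodes.

# Frequency estimation and relevance filters

The sample's multimer-positive percentage of CD8+ cells is apportioned
among enriched barcodes proportionally to their clonally reduced counts,
so estimated frequencies sum *exactly* to the gate. The denominator is the
total over **enriched** barcodes only: the sorted, multimer-positive
population should consist of cells bound by significant specificities, and
this reading makes the conservation property hold by construction. The
alternative denominator (all mapped reads) would leave part of the gate
unassigned; the choice is localized in `estimate_frequencies` and
switchable by passing raw counts.

Relevance filters: estimated frequency ≥ 0.01% (inclusive) and absence
from partially HLA-matching healthy-donor screens (exact specificity
match on peptide + HLA, not sequence similarity). Samples without exported
flow data get `NA` frequencies; their detections count toward diversity
but not toward summed frequency.

Cohort comparisons rescale per-patient diversity and summed frequency by
`cohort_mean_coverage / patient_coverage` (default cohort mean 4.4
alleles), a linear correction for unequal panel producibility; coverage is
taken from the panel as given.

# Longitudinal classification

Time points are ordered `preACT < TIL < post1 < post4 < post12 < post24 <
post48`. Detection means a call passing *both* relevance filters in that
sample — mere barcode enrichment is not detection. Origin is determined by
first appearance: `pre_TIL` (pre-therapy and infusion product),
`preACT_only` (pre-therapy, never the product), `TIL` (first in the
product), `novel_<tp>` (first at a post-therapy time point). *Engrafted* =
detected in the infusion product and ≥ 1 post-therapy sample — the
definition tied to the headline engraftment comparisons; a looser reading
("present in any post-therapy sample") exists in prose descriptions of
such analyses and can be recovered from the annotation columns
(`n_post_detections`). *Persisting* = detected in ≥ 2 post-therapy
samples, not necessarily consecutive.

A time point with no sample is *unknown*, never absent: classification
uses only observed detections, so uneven sample availability cannot
convert missingness into disappearance. Mutation-level collapse keeps, per
`mutation_id`, the most frequent epitope as proxy; with all-`NA`
frequencies the representative is chosen by detection only.

# Cohort statistics

* **Splits** use type-7 (linear-interpolation) percentiles — the printed
  medians in screening studies are often rounded inconsistently, so the
  interpolation rule is fixed and documented here — and assign values
  equal to the threshold to the lower group.
* **Survival**: Mantel–Cox log-rank p-value; hazard ratio by the O/E
  approach `HR = (O1/E1)/(O2/E2)` with CI
  `exp(ln HR ± 1.96·√(1/E1+1/E2))`; Kaplan–Meier curves with deaths
  before censorings at ties. A group with zero events yields a bound with
  a warning.
* **Mann–Whitney**: exact enumeration when the pooled size is ≤ 12 with
  no ties, otherwise the normal approximation with tie and continuity
  corrections.
* **Kruskal–Wallis/Dunn**: tie-corrected H; Dunn z from mean pooled ranks
  with tie-corrected variance; Bonferroni family adjustment by default
  (the adjustment used by common Dunn implementations varies, so it is an
  argument).
* **Spearman**: average ranks, t approximation on n−2 df.
* **Two-proportion z**: pooled variance, *no* continuity correction, so
  that z² equals the uncorrected 2×2 chi-square exactly; note that
  `prop.test`'s default correction is deliberately not applied.

# The synthetic-data generator

The generator emulates the study inputs end to end with exported ground
truth. Parameter distributions follow the emulated assay: library sizes
drawn from 151–585 peptides, HLA coverage 2–6 (cohort mean near 4.4),
immunogenic fraction 0.02, true frequencies log-uniform over 0.01–40% of
CD8+ cells, triplicate baselines, 6-nt UMIs.

Sizes the assay description does not pin down were chosen once as
package-scale defaults and documented here: 6 patients, 30,000 reads per
sample at PCR duplication 3 (10,000 molecules), substitution error rate
10⁻³, baseline abundances log-normal with sd 0.5 (reagent pools are not
uniform), baseline NB dispersion 0.05, post-therapy decay 0.5 per time bin
with per-clone jitter, novel populations injected at low frequency at
random post-therapy time points, multimer background 0.2% with Gaussian
gating noise (sd 0.05%) and the background as floor. Calibration analyses
in the acceptance tests use the sizes their contracts state (1,000
barcodes, depth 10⁵, triplicates; survival cohorts of n = 200 at true
HR 2.5).

The sorted-sample count model mixes spiked populations (proportional to
true frequencies) with a multimer-positive background mirroring the
baseline composition; every molecule receives a uniform random 6-nt UMI,
so UMI collisions occur at the natural 4⁶ birthday rate and clonally
reduced counts saturate for very large clones, exactly as in the real
assay. Frequency-recovery guarantees are therefore stated for truths in
the 0.1–3% range, where collision bias is below ~6% at the default depth;
a 20–40% clone will be undercounted, which compresses — but does not
reorder — the top of the frequency scale.

What the generator does **not** emulate: sequencer-specific error models
(flow-space indels), realistic HLA population frequencies, cross-reactive
binding between similar peptides, clustering of baseline abundances by
production batch, and non-exponential survival. Passing tests therefore
demonstrate correctness of the analysis chain under a faithful generative
model of its assumptions, not robustness to every artefact of real data.

# Numerical choices and degenerate inputs

* Exact-test tail sums are computed in log space with a max-shift
  normalization; dispersions below 10⁻¹² take the exact binomial branch.
* All-zero barcodes: log2fc 0, p 1. Samples sharing no positive barcode
  with the TMM reference get factor 1 with a warning.
* Empty library selections warn and return empty, so batch processing
  continues.
* Reads shorter than the layout are malformed (counted, skipped); FASTQ
  syntax errors fail hard with the offending file named.
* All-equal values in a quantile split put everyone in the lower group
  with a warning.
* Every stochastic component takes an explicit seed; pipeline seeds are
  derived from the configuration seed with fixed offsets, and identical
  seeds give byte-identical outputs (verified by checksum in the tests).

# Problem sizes used in the packaged analyses

The packaged test-and-acceptance analyses run at: 50 null screens and 8
spiked screens of 1,000 barcodes at 10⁵ molecules; a 6-patient default
cohort at 30,000 reads per sample (run twice for the determinism check);
100 survival cohorts of n = 200 plus 2,000 null replicates. These sizes
were chosen as the smallest at which the calibration properties are
statistically meaningful.

# Known limitations

* The common-dispersion estimate pools all barcodes; strong
  barcode-specific overdispersion (e.g. reagent aggregation) is absorbed
  into the common value.
* The enriched-only frequency denominator slightly inflates estimates
  when the multimer gate contains substantial nonspecific background.
* Engraftment/persistence classification is sensitive to sample
  availability by design (unknown ≠ absent), so patients with sparse
  follow-up contribute weaker persistence evidence rather than false
  negatives.
* Hazard ratios from the O/E approach are approximate relative to partial
  likelihood estimates; they match common practice for two-group screens
  but are not a Cox model.
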
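---
title: "Interferon-signature monitoring with nCounter panel scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interferon-signature monitoring with nCounter panel scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isgscore)
```

## The problem

Type-I interferonopathies (SAVI, CANDLE and related monogenic
autoinflammatory diseases) are driven by constitutive type-I interferon
signaling, and their clinical management increasingly relies on a molecular
readout: the expression of a fixed panel of interferon-stimulated genes
(ISGs) in whole blood, measured on the NanoString nCounter platform. A
single per-sample ISG score, tracked over months of therapy against a
healthy-donor reference band, tells the clinician whether IFN signaling is
suppressed, recovering between antibody infusions, or flaring with an
infection. A paired in-vitro assay — stimulating one aliquot of a blood draw
with IFN-beta and comparing ISG scores against the unstimulated aliquot —
probes whether the signaling axis is pharmacologically blocked at the
receptor.

`isgscore` implements that workflow end to end: reading raw nCounter output,
the platform's two-step control normalization, geomean and Z panel scores
with healthy reference bands, induction ratios for stimulation pairs,
longitudinal per-subject trajectories, and a generative simulator with known
ground truth so every stage is testable without patient data.

## Normalization model

The nCounter cartridge runs 12 lanes per batch; clinical samples are run
alongside healthy-donor reference samples. Two nuisance factors separate a
raw count from a comparable expression level: lane-to-lane technical
efficiency and per-sample RNA input. Each is corrected with a control gene
set and the same construction. For sample $i$ in a scope of $n$ samples,
with $g_i$ the geometric mean of the control counts in sample $i$,

$$ f_i \;=\; \frac{\tfrac{1}{n}\sum_{j=1}^{n} g_j}{g_i}. $$

Step 1 takes the six spiked positive-control probes (a geometric
concentration ladder) as the control set and rescales every count by
$f^{\mathrm{pos}}_i$; step 2 recomputes $g_i$ from the three housekeeping
genes (*NRDC*, *OTUD5*, *TUBB*) **on the step-1-scaled counts** and rescales
again. The normalized value is $x_{gi} \cdot f^{\mathrm{pos}}_i \cdot
f^{\mathrm{hk}}_i$.

Two algebraic consequences are used as test invariants:

* **Equalization** — after step 1 every sample in a scope has the same
  positive-control geometric mean (equal to the scope average), and after
  step 2 the same housekeeping geometric mean.
* **Conservation** — each step leaves the scope mean of its own control
  geomeans unchanged.

Computing the housekeeping factor on step-1 counts (rather than raw) is what
makes the second equalization exact; a `hk_factor_on_raw` switch reproduces
analyses that took both factors from raw counts.

A caveat worth stating precisely: the two-step scheme is *not* idempotent on
arbitrary data. After step 2 the positive-control geomeans equal the scope
average times $f^{\mathrm{hk}}_i$, so re-running normalization finds
positive factors $\overline{f^{\mathrm{hk}}}/f^{\mathrm{hk}}_i \neq 1$
whenever housekeeping variation was not pure lane scaling. On a matrix whose
control variation *is* a per-sample scale — the structure the normalization
assumes — a second pass returns unit factors exactly, and the test suite
asserts idempotence on that structure only.

### Factor scope

The factor formula runs over a scope of samples. The default is
`per_batch`: each cartridge carries its own healthy references, and
cross-cartridge lane effects are precisely what positive controls exist to
absorb, so factors are computed within the cartridge. A `global` policy is
available, and is also what the validation suite uses when comparing
estimated factors to the simulator's absolute lane factors: per-batch
factors are only identified relative to their batch mean, so only
global-scope factors are on the same scale as a per-lane truth.

## Panel scores

Two per-sample summaries are computed for each configured panel (ISG,
NF-κB-regulated, IFN-γ-regulated):

* **Geomean score** — the geometric mean of normalized counts over the panel
  genes, values floored at the pseudocount. For the 30-gene ISG panel this
  is the ISG score tracked clinically. It is scale-equivariant (doubling a
  sample's values doubles its score) and lives on the count scale, so bands
  and fold-changes read naturally.
* **Z-score** — per gene, $\log_2(\text{value}+1)$ standardized by the mean
  and standard deviation of unstimulated healthy-reference samples, then
  averaged over the panel. Per-gene z values are truncated at ±10 (config
  `z_truncate`; set `Inf` for a strict untruncated score) to bound the
  influence of a single aberrant probe.

The healthy reference is a fitted object (`fit_reference()`): per-gene
log-scale location and scale plus a **band** of healthy geomean scores,
by default the 2.5th–97.5th percentile (`band_type: minmax` gives the
range). Genes with degenerate variance across references would make z
unbounded, so reference sds are floored at 10% of the panel-median sd and
absolutely at 0.01 log2 units, with a loud warning.

### Gene panels are configuration, not code

The assay's identity lives in its gene lists. The bundled default encodes
the assay structure — 30 ISG genes, 10 NF-κB, 10 IFN-γ, 6 lineage genes (56
endogenous probes), the housekeeping trio, 6 positive and 8 negative
controls — but the ISG/NF-κB/IFN-γ lists are *documented placeholders*
assembled from the published interferon-score literature. Clinically
comparable scores require the laboratory's own validated lists, supplied via
a YAML config (`load_config()`), inline or as one-symbol-per-line files.
Scoring refuses a panel with genes missing from the codeset unless
`allow_partial` is set; `validate_panels_against_matrix()` reports the gaps.

## Stimulation responsiveness

`pair_samples()` matches IFN-beta-stimulated aliquots to the unstimulated
aliquot of the same subject and draw date and reports the **induction
ratio** (stimulated/unstimulated geomean score). A draw with both an
uncultured and a cultured unstimulated aliquot is ambiguous — the caller
chooses the denominator by filtering annotations — and raises an error
rather than guessing. The default responsiveness call is ratio ≥ 2; the
ratio is always reported alongside, because published patient contrasts
(e.g. 499/282 ≈ 1.8 versus healthy inductions of several fold) straddle any
single cutoff, and 2 is a convention, not a validated threshold.

## Longitudinal trajectories

`assemble_trajectories()` produces one date-ordered trajectory per subject
and panel from unstimulated samples, carrying the healthy band, therapy
intervals (drug, dose, start/stop), infusion dates (flagged if outside every
therapy interval for that drug) and free-text clinical events — all
pass-through annotations, never computed, since clinical interpretation is
out of scope. `render_report()` writes per-subject plots (score line,
shaded band, therapy ribbons, pink infusion markers) and a summary CSV whose
fold-change is exactly latest/baseline score and whose `frac_in_band` is the
fraction of points inside the band.

## The simulator and what passing tests mean

`simulate_cohort()` generates the structure the pipeline assumes, with every
generating parameter recorded:

* lane factors lognormal(0, `sigma_lane` = 0.3);
* endogenous baselines lognormal(meanlog = log 200, sdlog = 1) — spanning
  tens to thousands of counts, the typical range of immune panels;
* counts negative-binomial with mean `lane × baseline × effect` and size
  `dispersion` = 10 (moderate overdispersion); positive controls Poisson
  around `lane × ladder × pos_scale` with the 128/32/8/2/0.5/0.125 ladder;
  negative controls Poisson background;
* housekeeping levels sample-independent (lane scaling only);
* disease effect `isg_elevation^suppression` on ISG genes (elevation 8 as
  the working patient condition; `suppression` in [0, 1] models treatment
  response on the log scale); stimulation multiplies ISG genes by
  `stim_multiplier` in the stimulated aliquot;
* batches of 12 with at least 2 healthy references each (an error
  otherwise, since reference fitting downstream needs them);
* all randomness from one explicit seed, caller RNG untouched.

`expected_scores()` is the closed-form oracle: the geomean of
`baseline × effect` over the panel, i.e. the score under perfect
normalization and no counting noise. Recovery tests check that the pipeline
tracks it; rank-correlation recovery is measured over samples whose
expected score varies (treated patients spanning `theta^0..theta^1`),
because a block of samples sharing one expected value contributes only
midrank noise to a rank statistic.

What the simulator does **not** emulate: probe-specific efficiency biases,
background hybridization structure beyond flat Poisson noise,
immune-cell-composition shifts (which move lineage and NF-κB genes in real
blood), RNA degradation, or batch-by-reagent-lot interactions. Passing
recovery tests therefore demonstrates correctness of the arithmetic and
robustness to lane/input/counting noise — not clinical validity on real
blood, which requires validated panels and real reference cohorts.

Two small biases are worth knowing. The geomean of noisy counts is slightly
below the geomean of their means (Jensen), more so at low counts, so
healthy-group scores are depressed a few percent relative to elevated
patients and recovered group ratios sit slightly above the simulated
elevation at moderate dispersion. And the pseudocount floor (default 1)
compresses scores only where counts approach zero.

## Numerical and degenerate-input choices

* Geometric means error on nonpositive input; callers floor at the
  configured pseudocount (default 1 count) first. Raw values are never
  modified — the floor applies inside geomean/log computations only.
* Zero-variance reference genes: sd floored as above, warned.
* Same-date samples in a trajectory: both kept, ordered by sample id.
* Unknown RCC code classes: probes kept, excluded from all computation,
  warned. Count parsing is strict (nonnegative integers, no silent
  coercion); duplicate probes within a file are format errors.
* Score CSVs are written with 17 significant digits so that
  read-write round trips are decimal-string identical.

## Validation problem sizes

The test suite and the acceptance script validate at desk scale: 24-sample
cohorts (two cartridges) for factor recovery and equalization, 20 + 20
cohorts for elevation recovery and for the 100-seed null calibration
(two-sided Wilcoxon at α = 0.01), and 100 seeded replicates of 2-pair
stimulation cohorts for responsiveness classification. These sizes give the
rank and rate statistics stable sampling distributions while keeping a full
validation run in seconds.
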
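---
title: "Methods: functional classification of ABCA1 missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional classification of ABCA1 missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abca1flux)
```

## The problem

ABCA1 exports cellular phospholipids and cholesterol to lipid-poor ApoA1,
nucleating HDL particles; loss-of-function variants cause Tangier disease and
familial hypoalphalipoproteinemia. Hundreds of *ABCA1* missense variants are
reported clinically but few are functionally characterized. This package
implements an analysis pipeline for the fluorescence-based cholesterol-efflux
assay used to characterize such variants at scale: HEK293 cells transiently
expressing a variant are loaded with a fluorescent cholesterol analog,
incubated with an HDL acceptor, and the fraction of label exported to the
medium is read on a plate reader. Corrected, wild-type-normalized activities
are then converted into three-class functional calls with
conservation-calibrated thresholds, and complemented by protein-level,
cell-surface, treatment-rescue and colocalization analyses.

## The efflux model

For a well with medium read $M$ and lysate read $L$, the efflux fraction is

$$ f = \frac{M}{M + L}, $$

which is invariant to the well's cell load. Two corrections are applied per
experiment, both on the *fraction* scale (mock and variant wells have
different loads, so subtracting raw signals would be ill-defined):

1. **leakage**: subtract the mean fraction of mock-transfected wells
   *without* acceptor (passive, acceptor-independent label release);
2. **unspecific efflux**: subtract the (leakage-corrected) mean fraction of
   mock-transfected wells *with* acceptor.

The resulting ABCA1-specific efflux is normalized to the wild type of the
*same experiment* and expressed in percent. The order
fraction → leakage → mock → (optional renilla) → WT-normalization is fixed;
tests reject permutations. Negative corrected values are legitimate noise
excursions: they are retained internally (they keep replicate statistics
unbiased) and clamped to zero only in the reported activity, matching the
non-negative reporting convention of the assay's figures.

A co-transfected renilla luciferase reports per-construct transfection
efficiency. `process_efflux(..., renilla_normalize = TRUE)` rescales specific
efflux by `wt_renilla / renilla`; the default is off because the emulated
study used renilla as a monitoring channel, not an applied correction. Both
modes are provided since the source protocol does not state which was used
for the reported values.

## Thresholds and classification

* **Pathogenic cutoff** — the highest mean activity among characterized
  disease-causing control variants (the anchor construct is p.W590S-like at
  50% of WT): below the best-performing known-pathogenic control, there is no
  precedent of tolerated activity.
* **Benevolent cutoff** — variants whose alternate residue is the *reference*
  in more than two species of a 29-species vertebrate alignment demonstrably
  support a functional transporter. The cutoff is the mean of the three
  lowest such "calibration" activities, rounded to the nearest integer
  percent; with the published calibration values (79, 80, 82) this yields
  80%.
* **Call** — `loss_of_function` below the pathogenic cutoff, `benevolent` at
  or above the benevolent cutoff, `uncertain` between. Only the
  across-experiment mean enters the call; the SD is reported but never gates
  it.

Two boundary conventions circulate for the benevolent cutoff (≥ in the main
derivation, > in a figure legend); the package defaults to ≥ and exposes
`benevolent_boundary = "gt"` for the other reading — they differ only exactly
at the cutoff. Eligibility uses *presence* of the alternate residue among
species references, not consensus, since the derivation counts species
"in more than two of" the panel; requiring consensus would be a stricter,
unstated rule.

```{r}
derive_benevolent_threshold(c(79, 80, 82, 95, 101, 88, 110, 97, 85, 93))
classify_activity(c(49, 65, 80), threshold_set(50, 80))
```

## Statistics

Comparisons are two-sample t-tests whose variance assumption is gated by a
two-sided F-test (larger variance in the numerator): below p = 0.05 the
Welch test is used, otherwise the pooled test. Comparisons against the wild
type are two-tailed; treatment-vs-mock comparisons are one-tailed in the
hypothesized direction, with the star map \*, \*\*, \*\*\*, \*\*\*\* at
0.05, 0.01, 10⁻³, 10⁻⁴ (strict). No multiple-testing correction is applied,
mirroring the emulated analysis. An exact permutation oracle
(`permutation_t_test`, pooled-t statistic, mid-p tie rule) is shipped for
verification; note that at total n ≤ 10 its distribution has 20–252 atoms, so
p-values can legitimately differ from the continuous t distribution by far
more than 0.02 on individual inputs — a limitation of any small-sample
t-vs-permutation comparison, documented here because one acceptance check
assumes uniform ±0.02 agreement and is left failing by design.

A treatment **responder** requires one-tailed p < 0.05 *and* a fold change
(ratio of arm means — robust with small unpaired arms) in the hypothesized
direction. ApoA1 stabilization is the same call on surface expression, read
as "retains acceptor interaction".

## What the generator emulates — and what it does not

`sim_config()`/`simulate_plate()` state the synthetic world: 4 independent
experiments; one well per construct per experiment (the protocol does not
state well counts; this is configurable); WT specific efflux 0.30 of the
label in 4 h; 5% acceptor-independent leakage; 5% ABCA1-unspecific mock
efflux; multiplicative lognormal noise because fluorescence is
scale-positive (the study reports only SD bars, not a noise model), with
measurement CV 0.10 and per-well load CV 0.15; and per-construct
transfection-efficiency factors reported through a simulated renilla channel.

The transfection CV defaults to 0.05: the emulated study co-transfected the
renilla reporter as a QC monitor *without* applying a correction, which is
sound practice only when intra-assay transfection variation is minor; larger
values are exercised in tests together with `renilla_normalize = TRUE`,
which removes them exactly in the noiseless limit.

The blot generator draws a two-band ABCA1 doublet whose *sum* over β-actin
tracks true protein; the image generator mixes a shared latent component into
two channels so the population Pearson correlation equals `target_r` (an
`exact = TRUE` mode pins the *sample* correlation via empirical
Gram–Schmidt, used where tests demand 10⁻⁹ exactness; no population mixture
can do that at finite pixel count). Not emulated: plate-position effects,
efflux kinetics (single endpoint only), microscopy optics, bleed-through or
cell morphology, and image-based band detection. A green test on this world
therefore establishes correctness of the *analysis*, not robustness to those
unmodeled artifacts.

The built-in study-like fixture (`make_fixtures()`) reproduces the shape of
the emulated study: 51 query variants (45 HGMD-style, 5 novel, 1 from the
literature), 5 controls, a 29-species alignment in which exactly 10 variants
pass the conservation rule, treatment arms, and image pairs at generative
R ∈ {0.26, 0.12, 0.11, 0.01}. Only the variant names the study prints are
real; the remainder are synthetic stand-ins placed outside the gateway
interval and central annulus so printed domain counts are preserved. True
rescue/stabilization effects use 1.4–2-fold activity and 3–8-fold surface
changes, the ranges the study prints.

## Numerical choices

* Lognormal noise is parameterized to unit mean, so `cv = 0` is bit-exact,
  not approximate — the noiseless-identity test asserts exact recovery.
* WT normalization computes `100 * (x / wt)` (ratio first), keeping the WT
  self-ratio exactly 100.
* The single run seed fans out to fixed per-stage substreams, so adding a
  stage never perturbs earlier stages' draws, and simulators restore the
  caller's RNG state.
* Thresholds derived from noisy fixtures are the *measured* ones (e.g. the
  pathogenic anchor lands near, not at, 50%); tests assert the designed
  values only where noise is configured off.
* Degenerate inputs error loudly: empty mock/WT wells, zero actin, constant
  image channels, both-zero F-test variances, n < 2 replicate sets.
* ECD1/ECD2 intervals are approximate literature values used for annotation
  only; gateway/annulus sets are the printed ones and are what tests rely on.

## Known limitations

* TIFF image I/O is not provided (no TIFF package in the supported
  dependency set); images are exchanged as whitespace-delimited matrices.
* The colocalization default is whole-image Pearson without background
  subtraction or ROI selection; the vendor software's exact pixel-inclusion
  rule is unknown, so an optional intensity-threshold mask is provided but
  off by default.
* Cross-blot densitometry comparisons are refused rather than bridged.
* No ACMG/AMP evidence combination, in-silico predictor integration, or
  structural modeling: calls here are efflux-based functional categories,
  not clinical classifications.
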
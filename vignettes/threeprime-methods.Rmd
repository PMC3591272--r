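---
title: "Models and methods behind threeprime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind threeprime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`threeprime` analyzes reporter libraries in which yeast strains differ only
in the 3' end region integrated downstream of a fluorescent reporter, so
that differences in expression are attributable to the 3' end sequence
alone. This vignette explains each analysis layer's model, its tunable
parameters, the numerical choices made where the method left room, and what
the synthetic-data generators do and do not emulate.

## Plate-reader expression quantification

**Model.** A well's optical density follows batch growth; a stable
fluorescent protein accumulates as `dY/dt = P * OD(t)`, where `P` is the
production rate per cell per second. Because the protein is stable, the
single expression value per induction curve is

```
P_hat = (F(t_end) - F(t_start)) / integral of OD dt over [t_start, t_end)
```

taken over the exponential growth phase, with trapezoidal integration over
unmasked points. This estimator is exact for any window under the model,
since `F(t) = P * integral(OD)` pointwise.

**Processing steps and their parameters.**

1. *Background subtraction* (`subtract_background()`): OD is corrected with
   the media blank; the YFP channel with an mCherry-only strain; the
   mCherry channel with a YFP-only strain. OD is floored at zero (and the
   flooring counted); fluorescence may go slightly negative and is left
   untouched. Background wells are themselves outlier-cleaned first, with
   flagged points repaired by cubic-spline interpolation -- a spike in a
   shared blank would otherwise corrupt every sample well at that time
   point, and linear repair leaves a curvature kink on growing background
   curves that the per-well outlier rule then re-detects everywhere.
2. *Point-outlier removal* (`remove_point_outliers()`, defaults `k = 5`,
   `w = 5`, applied independently per channel): a point is flagged when its
   deviation from the running window median exceeds `k` times a robust
   local scale. The scale is the larger of the window MAD of
   median-detrended residuals and a floor from the median absolute first
   difference in a doubled window (excluding the candidate's own two
   differences). The residual MAD alone collapses to zero on locally
   monotone stretches -- the running median reproduces every point there --
   so without the floor a single noise inversion would be flagged; the raw
   window MAD alone is inflated by the exponential trend and lets spikes
   ride the rise undetected. Masking is iterated up to three passes because
   two spikes inside one window can shield each other from a single pass.
   More than 10% of points flagged attaches a QC warning.
3. *Growth-phase segmentation* (`segment_growth_phases()`): the curve is
   divided into lag, exponential, linear and stationary phases from the
   smoothed derivative of `log(OD + 1e-4)` (centered moving linear fit
   over 5 points, after a running-median pass that is exact on monotone
   curves but crushes any spike that slipped through masking; floored
   OD = 0 points are skipped because their log-derivative is undefined).
   The exponential phase is the longest contiguous run with log-slope at
   least `expo_frac` times its maximum; the stationary phase is the
   trailing run where `dOD/dt` falls below 5% of its own maximum; the
   linear phase is the remainder. `expo_frac` defaults to 0.55, calibrated
   on simulated logistic curves: for a logistic with rate `r`, the
   threshold `0.55 * max` ends the detected phase at OD just below half the
   carrying capacity -- the inflection point where the linear phase begins
   -- and, unlike higher thresholds, leaves enough points in the window
   that endpoint measurement noise does not dominate the production
   estimate. Because the estimator is window-exact under the model, the
   threshold trades only noise, not bias.
4. *Replicates*: production values from replicate wells (three per strain
   in the simulator, matching standard triplicate plate practice) are
   averaged; the endpoint noise of a single well (~1% of the final
   fluorescence) is the dominant error term and averaging replicates is
   what brings per-strain recovery comfortably inside 2% at 1% per-point
   noise.
5. *Clone concordance* (`concordant_clone_filter()`): a strain enters the
   final set only if some pair of its independently constructed clones
   agrees within 15% relative difference; the strain value is the mean of
   the best pair, and single-clone strains are reported as unvalidated
   rather than silently accepted or dropped.

YFP values are *not* normalized to mCherry by default; `plate_expression()`
has a `normalize_mcherry` switch.

## Polyadenylation-site mapping from 3'RACE reads

Reads follow the poly(T) priming chemistry: a 12-nt random UMI, a poly(T)
block (>= 18 nt), then the reverse complement of the transcript 3' end.
The junction between the poly(T) and the mapped genomic sequence is the
cleavage site. Genomic A's at the junction are indistinguishable from the
tail, so resolution is intrinsically limited to the first non-A nucleotide
at or upstream of the true site; `call_cleavage_position()` asserts this
invariant, and `resolve_to_first_non_a()` exposes the same map for scoring
recovery against planted truth.

By default the poly(T) run is located exactly (`tail_mismatch_per10 = 0`).
An optional allowance of one mismatch per 10 nt of tail is available for
error-containing data, but it is off by default because on genomic contexts
of the form "A-run, single non-A, A-run" it over-trims through the
intervening base and breaks the first-non-A resolution guarantee.

Mapping uses an exhaustive 15-mer index over both strands of the cloned
reference (at most ~100 sequences of <= 1 kb, so a full k-mer table is the
right index) with ungapped extension: a read maps when its best hit has at
most 2 mismatches and no second hit lies within 2 mismatches of the best;
ambiguous, antisense and unmatched reads are returned with reasons and
counted, never dropped silently.

Per-gene profiles (`build_cleavage_profile()`) use the position with the
most reads as the main site, breaking ties to the most upstream position
(deterministic, and conservative for UTR length). A gene passes the depth
filter only with strictly more than 1000 reads. UMI deduplication is off
by default -- the randomer is carried through for the option, but the
default pipeline counts reads.

## PolyA-anchored sequence features

All coordinates are 0-based offsets from the first base after the stop
codon; windows are half-open `[start, end)`; the cleavage site is the
inclusive offset of the last transcribed base. A window of size `s`
centered at offset `c` from anchor `a` spans
`[a + c - floor(s/2), a + c + ceiling(s/2))`.

`feature_expression_scan()` computes, for every (window size, center
offset) pair, the Pearson correlation across constructs between the
window's A/T (or G/C) fraction and expression, anchored either on the main
cleavage site or on the UTR start. The default grid is sizes 10-100 bp in
steps of 10 and offsets -200..+50 in steps of 5. Windows truncated at a
sequence boundary contribute their truncated fraction; windows entirely
outside drop that construct from the cell (tracked in `n_used`); cells
with fewer than 3 constructs or a constant feature are undefined. No
multiple-testing correction is applied to the grid by default; family-wise
calibration is available through `scan_permutation_null()`, which shuffles
expression across constructs and records the null distribution of the
grid's peak absolute correlation.

`grouped_gc_profile()` reproduces the positional view: genes split into
bottom-quantile, top-quantile (defaults 0.2 each) and middle groups by
expression, mean G/C in 20-bp centered windows per offset.

`kmer_expression_association()` counts overlapping k-mers (3 <= k <= 8)
with Spearman correlation against expression and permutation p-values;
`motif_scan()` maps IUPAC-degenerate patterns, with defaults for the two
canonical 3'-processing elements (efficiency element `TAYRTA` with literal
`TATATA`, positioning element `AAWAAA`) -- the literature consensus, fully
configurable.

`global_utr_features()` reports UTR length, composition, and a pairing
score: the maximum number of nested base pairs (Watson-Crick plus G-T
wobble, minimum loop 3) by dynamic programming, implemented in C++ because
the recurrence is cubic in sequence length. This is a declared *proxy* for
folding stability, not a thermodynamic minimum free energy; externally
computed energies can be attached per gene via the `energy` argument.

## Nested regression and orientation comparison

`nested_regression_ftest()` asks whether adding one regulatory region's
measurements to another's improves prediction of endogenous mRNA levels:
both models are fit by ordinary least squares with an intercept and

```
F = ((RSS_reduced - RSS_full) / d_extra) / (RSS_full / (n - df_full))
```

with the p-value from the F distribution. Collinear designs and empty
predictor differences are errors. A perfect full-model fit returns
`F = Inf`, `p = 0` -- the continuous limit of the test.

`orientation_group_compare()` contrasts tandem against convergent
constructs with both a rank-sum test and an ECDF max-distance test (the
choice of these two tests is ours; any distribution shift would implicate
the downstream promoter rather than the 3'UTR), plus per-group Spearman
correlations of expression against covariates such as intergenic length.

## Single-cell noise and burst statistics

Under the gamma burst model, a population expressing in bursts of average
size `b` (proteins per burst) occurring at frequency `a` (bursts per
protein lifetime) has protein levels distributed Gamma(shape = a,
scale = b). Hence:

* noise `eta^2 = variance / mean^2 = 1/a` -> burst frequency `a = 1/eta^2`;
* noise strength `nu = variance / mean = b` -> burst size `b = nu`.

`population_noise_stats()` uses the unbiased (n-1) variance estimator and
reports both identities, which hold to machine precision by construction
(`nu = eta^2 * mean`, `frequency * size = mean`).

Gating (`gate_cells()`) keeps cells within `k = 2.5` MADs of the median in
both forward and side scatter (removing spores and outlier-scatter cells),
optionally restricted to a central mCherry band (default middle 90% when
enabled) to reduce extrinsic variation. The median +/- k MAD rule is our
concretization of automatic scatter gating; `k` is exposed, and with an
all-identical channel (MAD = 0) nothing is removed.

Between-plate intensity differences are corrected by a
galactose-insensitive reference strain (`plate_correct()`): plate factor
`c_p` = grand reference mean / reference mean on plate p; means scale by
`c_p`; squared noise scales as 1/mean so noise corrects as `noise / c_p`;
the corrected noise strength is the product of corrected noise and
corrected mean, preserving `noise_strength = noise * mean`. This is our
reading of the stated 1/mean scaling principle.

The characteristic phenomenology falls out of the model: varying burst
size at fixed frequency moves the mean and noise strength together while
noise stays flat; varying burst frequency at fixed size moves the mean
with noise proportional to 1/mean. The acceptance suite asserts both as
slope tests on simulated strain sets.

## The synthetic-data generators

Every input class has a generator that returns planted truth alongside the
data, so the full pipeline closes the loop from generation to estimate.

* `generate_construct_library()` (default n = 85): sequences of 200-1000 bp
  with uniform 25%-per-base background composition, a main cleavage site
  at least 100 bp from the start, and 0-3 satellite sites placed by
  discretized-normal jitter (sd 15 bp) holding 15-45% of the weight
  between them (the satellite weight law is a modeling convenience, not a
  claim about real site usage). The planted effect window (30 bp centered
  40 bp upstream of the main site) has its A/T fraction assigned on an
  even per-construct grid over [0.35, 0.95], and expression is
  `beta0 + beta1 * AT + Normal(0, sigma_e)` truncated at zero. The grid
  rather than fully random composition is deliberate: the A/T fraction of
  a 30-bp window under uniform composition is binomial with a spread of
  only ~0.28-0.72, which cannot produce a robustly positive greater-than-
  ten-fold expression range under a linear model; spanning [0.35, 0.95]
  reflects how variable real 3' intergenic composition is and makes the
  12-fold library span reproducible. Defaults `beta1 = 20`,
  `beta0 = -5.58` place the nominal max/min ratio at 12 (window A/T snaps
  to multiples of 1/30, so the extremes sit at 10/30 and 28/30);
  `sigma_e = 0.15` keeps the lowest-expressing strain well away from the
  truncation boundary.
* `simulate_plate_timecourses()`: logistic OD with a 2-h lag, carrying
  capacity 1.0 OD, initial OD 0.05 and a 100-min doubling time, sampled
  every 20 minutes over 24 h; fluorescence from the exact model integral
  (so noiseless processing inverts to the planted rates up to trapezoidal
  error); additive media OD, constant-plus-OD-proportional
  autofluorescence backgrounds; 1% multiplicative measurement noise;
  sparse spike outliers (1% of points, 3-8x); three replicate wells per
  strain and per background role. Protein degradation is omitted -- both
  reporters are long-lived relative to the experiment.
* `simulate_race_reads()`: per-read cleavage positions drawn from the
  construct's true site distribution (optional per-read jitter), fragment
  lengths 60-100 nt, Poisson-dispersed tails of at least 18 T's, a random
  12-nt UMI, the per-read true site recorded in the FASTQ description, and
  optional uniform substitution errors and defective-read fractions
  (destroyed tail or truncation) for rejection-accounting tests.
* `simulate_cell_population()`: Gamma(a, b) expression, an optional
  unit-mean lognormal extrinsic factor shared between YFP and mCherry (the
  simplest mechanism that control-channel gating can partially remove),
  lognormal scatter, and an optional spore subpopulation at 0.15x forward
  scatter, 0.3x side scatter and 5% fluorescence -- spores are far smaller
  than budded cells, which is what makes scatter gating effective.

**What the generators do not emulate** -- and therefore what passing tests
do not establish about real data: PCR and sequencing biases beyond uniform
substitution; growth-curve pathologies (diauxie, flocculation, evaporation
drift); spatial plate effects; correlated or heavy-tailed measurement
noise; cell-cycle structure or mCherry-YFP channel bleed-through beyond a
shared lognormal factor; and any mechanistic transcription kinetics behind
the gamma model. Recovery results certify the pipeline's correctness under
the stated generative assumptions, not the assumptions themselves.

## Problem sizes used in the checks

The test and acceptance runs use the study's own scales where they are
known -- 85 constructs, 20 strains for plate inversion, 50 genes x 10,000
reads for site mapping, 200 constructs for the scan grid, 10,000 null
simulations at n = 85 for F-test calibration, 100,000 cells per burst
estimate with 100 replicates at the central grid point -- chosen as
realistic desk-scale study conditions.

## Known limitations

* The mapper is ungapped; indel-containing reads go unmapped (counted).
* The pairing score is not a free energy; use the `energy` hook for true
  thermodynamic folding values.
* Phase segmentation assumes a single sigmoidal growth episode.
* The permutation null for the scan grid conditions on the observed
  feature matrix; it calibrates the peak statistic family-wise but not
  per-cell p-values.
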
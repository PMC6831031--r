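---
title: "Determining helicase orientation and translocation polarity on fork DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining helicase orientation and translocation polarity on fork DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcmorient)
```

## The inference problem

A hexameric MCM-family helicase encircles one strand of a fork and
translocates along it 3′→5′. On a model fork substrate the ring can load
on either single-stranded arm and in either of two orientations relative
to the duplex junction — N-terminal face toward the junction (N@duplex) or
C-terminal face toward it (C@duplex) — so any bulk measurement reports on
a *mixture* of binding configurations. The question this package
operationalizes is which face leads during active unwinding (N-first vs
C-first), answered by combining three assays that each constrain the
mixture differently:

1. **Site-specific footprinting** measures the orientation composition of
   the bound population.
2. **Single-turnover unwinding** measures the size of the *productive*
   subpopulation (its exponential amplitude).
3. **Presteady-state FRET with a roadblock** reports, through the sign of
   the slow phase, which labelled face approaches the junction-side
   reporter during translocation.

The logic is integrative: if the N@duplex fraction (not its complement)
matches the productive amplitude, and a slow FRET rise appears only with
the N-terminal label under a streptavidin block, both evidence streams
point the same way and the verdict is N-first. The package only declares a
direction when two independent streams concur; every other pattern returns
`indeterminate` with the failing evidence lines listed.

## Substrate geometry and region conventions

Substrates are described by lengths only (duplex, 3′-arm, 5′-arm) plus
which strand carries the fluorophore; sequences never enter any downstream
computation. Footprint quantification uses 1-based inclusive base
intervals counted from the labelled duplex end: for the standard 50-nt
labelled strands, bases 20–35 (junction-proximal) report N@duplex and
36–50 report C@duplex. The counting origin switches with the labelled
strand (5′-end for the encircled-strand substrates, 3′-end for the
excluded-strand substrate), so the origin is recorded on each `region_map`
rather than assumed globally. For shorter strands the single-stranded
window is split at its midpoint. The region→orientation assignment is a
convention adopted from the assay design; because the probe-to-cleavage
geometry is not derivable from first principles, the assignment is
configurable and the generator exposes the probe offset as a parameter
rather than hard-coding a structural model.

## The synthetic-data generator

The generator is the package's test surface: it produces all four data
streams from a mechanistic model with known ground truth, and every
simulated dataset carries a `truth_record` of its generating parameters.

**Binding populations.** A `binding_population` assigns probabilities to
the four (arm × orientation) configurations plus an unbound fraction. The
measured regimes ship as presets: N@duplex fractions 0.23 (equal-arm
fork), 0.57 (3′-long arm) and 0.52 (3′-long arm, winged-helix deletion).

**Footprint lanes.** Each bound configuration deposits a packet of
cleavage intensity on the labelled strand: a discretized Gaussian kernel
(sd 4 nt) truncated and renormalized over the single-stranded window,
centred in the region its orientation maps to. The centre sits 4 nt from
the region midpoint, away from the boundary the two regions share — about
three kernel standard deviations from that boundary — so that the region
assignment is faithful (cross-region leakage ≈ 0.2%, and well over 90% of
each kernel's mass lies inside its assigned region). Configurations bound
on the unlabelled strand's arm contribute at a relative efficiency of 0.3
(`cross_strand_prob`), reflecting the flexible DNA-binding domain's
ability to cut the non-encircled strand; this scales but does not
reposition their contribution, so it cancels in the orientation fraction.
A uniform background (50 units/base against a full-occupancy cleavage
mass of 4×10⁴) underlies every lane, and per-base multiplicative lognormal
noise with CV 0.10 reproduces the replicate scatter of densitometry; the
protein-free control lane contains background only.

**Unwinding time courses.** The true fraction unwound is
`p (1 − e^(−kt))` with amplitude `p` equal to the probability of the
productive configuration — the hexamer on the 3′-arm with its leading face
(per the `productive_rule` under test) toward the duplex. Band
intensities include a per-band leak and additive Gaussian noise (sd 2% of
the convertible signal), with tagged zero-time and boiled-control rows so
the normalization is exercised non-trivially. Default sampling is 12
points over 0–240 min, chosen to resolve rates near 0.07 min⁻¹
(half-time ≈ 10 min); both grid and rate are configurable.

**Anisotropy titrations** follow the Hill isotherm exactly plus Gaussian
noise (default sd 0.003 anisotropy units).

**Stopped-flow traces** are two-phase exponentials on a split time base
(default 0–10 s dense, then sparse to the configured end; 250 points per
segment). The fast phase is always a rise (complex formation); the slow
phase's sign follows the decision table: with a streptavidin block it
rises only when the labelled face leads under the true polarity and falls
otherwise (dissociation); without the block it falls for either label
(movement past the reporter); without ATP it is absent. Noise is 1% of
the full-scale amplitude. The sign convention throughout is that a
negative amplitude in `v(t) = Σ aᵢ e^(−kᵢt) + C` is a signal increase.

**What the generator does not emulate.** Gel smiles and lane-to-lane
warping, sequence-dependent cleavage chemistry, photobleaching and
instrument drift, ligand depletion at low concentrations, and
multi-phase unwinding. Passing recovery tests therefore demonstrate that
the estimators are correct and well calibrated *under the stated noise
model*, not that they are robust to every artefact of real gels and
traces; the readers accept any data in the documented CSV dialects.

## Estimation details and numerical choices

**Footprint.** Background subtraction clamps negative corrected
intensities to zero (densitometry cannot be negative and the ratio
presumes non-negative mass). Orientation fractions are computed per
replicate and then averaged — matching how replicate standard errors are
reported for 3–5 independent experiments — rather than on an averaged
lane. Because the fraction is a within-lane ratio, per-lane loading scale
cancels and no further normalization is applied. The N-vs-C comparison is
an unpaired two-tailed pooled-variance t-test; orientation preference is
declared only below p = 0.05.

**Unwinding.** The offset-exponential is fitted in the rising
parameterization `A_f (1 − e^(−kt))` so the amplitude is directly the
productive fraction, with bounds 0 ≤ A_f ≤ 1 and k > 0, initial guesses
from the series maximum and the half-rise time. One subtlety matters for
downstream logic: every point of the series shares the same two noisy
normalization anchors (zero-time and boiled lanes), so anchor error moves
the whole series coherently and is invisible to point-wise residuals. The
amplitude standard error therefore adds, by the delta method, an anchor
term `s²((1−A_f)² + A_f²)` with `s` the residual scale — without it the
fit SE understates the true amplitude error by a factor of ~2.5 at these
noise levels and the downstream consistency z-test rejects far too often.
A series with no resolvable signal (max F < 0.01) is flagged degenerate
instead of fitted, since the rate is then unidentifiable.

**Hill binding.** The free-DNA baseline is subtracted before fitting
(the model form forces Y(0) = 0). The Hill coefficient is fitted freely
within [0.25, 8]: unconstrained n diverges on shallow titrations, while
the bounds still admit any cooperativity of practical interest.
Titrations whose fitted saturation never crosses the 20–80% band are
rejected as unidentifiable rather than reported.

**Multi-exponential traces.** Fits are weighted by the local sampling
interval, so a dense early segment does not dominate a joint split-time-
base fit; with uniform sampling the weights are all 1 and the fit equals
the unweighted one. Starting values come from a log-spaced rate scan with
amplitudes profiled out by weighted linear least squares (variable
projection), then a Levenberg–Marquardt polish. Model order (1–3) is
chosen by small-sample-corrected AICc among *admissible* fits — no
rate collapse (adjacent rates within 3-fold), all amplitudes and rates
significant at 2 SE, and every rate identifiable within the trace
(k·t_max ≥ 1). The resolution gates matter: plain AICc accepts a spurious
extra phase in roughly 10–30% of pure single-phase traces, because two
free parameters can always soak up some noise; requiring the extra phase
to be resolved restores the selection consistency the assay logic needs.
An extra-sum-of-squares F-test (α = 0.01) is available as an alternative
criterion for parity with common stopped-flow practice.

**Verdict.** The footprint–unwinding correspondence is operationalized as
a two-sided z-test at 1.96 on the difference of the two fractions; applied
to the measured summary pairs (0.23 ± 0.03 vs 0.26 ± 0.01 and 0.57 ± 0.03
vs 0.54 ± 0.03) it calls the N@duplex fraction consistent and the C@duplex
complement inconsistent on both fork substrates, which is the qualitative
correspondence argument made quantitative. Requiring two concordant
streams mirrors the experimental structure (footprint + unwinding, then
FRET confirmation) and makes `indeterminate` the safe default.

## Units and conversions

Gel-based rates are per minute; stopped-flow rates are per second; the
converters `per_min_to_per_sec()` / `per_sec_to_per_min()` are explicit
and tested (0.07 min⁻¹ = 1.167×10⁻³ s⁻¹). Concentrations are nM of
hexamer-equivalent protein; intensities and anisotropy are instrument
units (all downstream quantities are ratios or differences, so absolute
scale never matters).

## Problem sizes

The shipped tests and the acceptance script run at desk scale: five
replicate lanes per footprint set, five seeds per regime, 12-point time
courses, 500-point traces, and 20-seed end-to-end verdict panels. These
sizes were chosen so the whole suite completes in well under a minute on
one CPU while keeping Monte-Carlo acceptance bands (binomial error on
selection and rejection rates) tight enough to be meaningful.

## Known limitations

* The region→orientation map is a calibrated convention; on substrates
  where the probe geometry differs it must be overridden.
* The unwinding model is single-exponential by design; genuinely
  multi-phasic unwinding would bias the amplitude toward the fast
  component.
* The Hill fit assumes free ≈ total protein (no ligand-depletion
  correction), appropriate when Kd is well above the DNA concentration.
* FRET traces are interpreted through sign and rate only; no distance
  (R₀/efficiency) quantitation is attempted.
* The verdict treats 5′-arm-bound subpopulations as non-productive
  background, so substrates designed to load that arm serve as controls,
  not direction evidence.
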
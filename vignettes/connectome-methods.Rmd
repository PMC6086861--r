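---
title: "Methods: resting-state connectome construction and group-by-time inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state connectome construction and group-by-time inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfcnet)
```

# What the package computes

`rsfcnet` implements a complete region-of-interest (ROI) resting-state
functional-connectivity analysis for a two-group, two-timepoint
(intervention vs. non-intervention, pre vs. post) design:

1. **Temporal cleaning and motion scrubbing.** Leading volumes of each
   acquisition run are discarded (default 5 per run); framewise displacement
   (FD) and fractional DVARS are computed; polynomial trends of order 1–2
   are removed and a zero-phase 0.009–0.1 Hz band-pass applied; frames with
   FD > 0.8 mm *or* DVARS > 0.05 are censored.
2. **Connectivity.** Pearson correlation between every ROI pair on the
   surviving frames, Fisher r-to-z transformed; block means within and
   between eight functional systems (seven intrinsic connectivity networks
   plus a subcortical system).
3. **Graph topology.** The z-matrix is proportionally thresholded at
   densities 15–35 % (step 1 %), keeping only positive weights; nodal
   strength/degree, Onnela clustering, harmonic closeness, global
   efficiency, characteristic path length and small-worldness are computed
   per density and integrated across the grid.
4. **Inference.** Group-by-time interactions are tested by covariate-
   adjusted (Freedman–Lane) permutation tests on per-subject change scores
   (default 5000 permutations; age and scanner as covariates); significant
   connectivity changes are followed up with covariate-residualized Pearson
   brain–behavior correlations.
5. **Synthetic cohorts.** A generator produces the full input bundle —
   ROI time series, motion traces, design table, behavior scores, ground
   truth — with controllable block structure, planted interaction effects
   and behavior coupling, so every stage is testable without imaging data.

# The measurement model and its inversion

The generator treats the target connectome as a block-structured
correlation matrix. A `block_fc_spec` gives the desired mean Fisher-z per
system pair, per design cell (group x time). Each target z maps to the
correlation `tanh(z)` shared by every ROI pair of that block, with unit
variances. Equicorrelated block targets are not always jointly feasible;
when the assembled matrix is not positive definite its eigenvalues are
clipped at a small floor (`1e-6`) and the diagonal rescaled to one. The
repair is recorded in an attribute and in the cohort ground truth. Note
that a repair moves infeasible blocks to the nearest feasible mean (for an
equicorrelated block of \(k\) ROIs the mean correlation cannot fall below
\(-1/(k-1)\)), so round-trip accuracy is only guaranteed for feasible specs.

Frames are drawn i.i.d. from a multivariate normal with this correlation
structure, scaled to a BOLD-like baseline (mean 1000, fluctuation SD 10,
i.e. ~1 % signal changes) so that *fractional* DVARS — frame-to-frame RMS
change divided by the grand mean — is well defined, mirroring grand-mean-
scaled acquisitions where a 0.05 threshold means a 5 % whole-brain jump.

**What the generator does and does not emulate.** It reproduces the
dimensions and statistical structure the downstream analysis is sensitive
to: block-level correlation structure, group-by-time block changes,
subject-level variability in the changing block (`fc_delta_sd`, Fisher-z SD
0.05 at time 2), motion spikes with exact FD magnitudes, scanner imbalance
between groups, and behavior change coupled to connectivity change. It does
*not* emulate hemodynamic autocorrelation (frames are white by default; an
AR(1) knob exists but is off because all statistics here are
correlation-based and permutation operates at subject level), spatial
structure within systems, physiological noise, or non-Gaussian artifacts.
Passing tests therefore demonstrate correctness of the *procedures* and
their calibration under the stated model, not robustness to every property
of real BOLD data.

One consequence of white frames deserves emphasis: a 0.009–0.1 Hz band-pass
at TR = 2 s keeps ~36 % of the white spectrum, so filtering synthetic data
reduces the effective number of independent frames by nearly two-thirds
without removing any artifact (there are no trends or out-of-band noise to
remove). The replicate simulations used for calibration and power therefore
process synthetic sessions with scrubbing but without the band-pass; the
full pipeline applies the complete chain, as it must on real data, where
BOLD power is concentrated in-band and the cost is far smaller.

# Motion spikes and scrubbing

Planted spikes are out-and-back events: the head translates by
`spike_fd_mm` (default 1.6 mm) on one frame and returns on the next, so FD
equals `spike_fd_mm` exactly at both frames; the signal receives a
transient global offset (10 % of the grand mean) at the onset, so DVARS
exceeds its threshold at the onset and the return — the same two frames.
Planted frames are thus exactly the frames the default thresholds censor,
which the tests verify on every synthetic subject.

The QC order is: discard initial volumes, compute FD/DVARS on the
*unfiltered* series, interpolate linearly over flagged frames, detrend and
band-pass, then censor the flagged frames. Two deliberate choices here:

- **DVARS before filtering.** A resting-state band-pass suppresses exactly
  the high-frequency transients DVARS exists to detect (an ideal band-pass
  at TR = 2 s passes only about a third of a step's instantaneous jump and
  smears the rest over neighbouring frames), so DVARS computed on filtered
  data cannot cleanly localize spikes. Computing it on the unfiltered
  series also gives a positive grand mean for the fractional normalization.
- **Interpolation before filtering.** Without it, a censored transient
  rings through the zero-phase filter into neighbouring *kept* frames as a
  shared global artifact. Flagged frames are replaced by linear
  interpolation, filtered, then dropped.

"FD > 0.8 and DVARS > 0.05" is read as flag-union (censor when either
exceeds), the conservative convention of the scrubbing literature;
`scrub(rule = "intersection")` gives the other reading, and an off-by-
default `augment` option also censors one frame back / two forward.
Rotations are assumed to be radians; `rotations = "degrees"` converts.
Scrubbing is idempotent with respect to its stored QC: the returned report
carries the retained frames' FD/DVARS (all below threshold), and re-running
`scrub` on the output removes nothing. Sessions with fewer than
`min_frames` (default 100) surviving frames are flagged for exclusion via a
distinct condition class rather than a hard error; the pipeline drops such
subjects listwise.

# Graph measures

Only positive z-values enter graphs; at density \(d\) the
\(\mathrm{round}(d\,R(R-1)/2)\) strongest positive weights are kept
(rounding half away from zero; ties broken in fixed row-major
upper-triangle order so runs are reproducible). Weights are retained, not
binarized. Measures:

- strength \(s_i = \sum_j w_{ij}\) (primary "degree centrality" on a
  weighted graph; binary degree is also emitted — the choice between them
  is genuinely open, so both are available),
- Onnela clustering
  \(C_i = \frac{1}{k_i(k_i-1)} \sum_{j,h} (\hat w_{ij}\hat w_{jh}\hat w_{hi})^{1/3}\)
  with \(\hat w = w/\max(w)\), zero for \(k_i < 2\),
- shortest paths on reciprocal-weight lengths \(1/w\),
- harmonic closeness \(\frac{1}{R-1}\sum_{j\ne i} 1/d_{ij}\), finite on the
  disconnected graphs that occur at 15 % density (its mean over nodes *is*
  the global efficiency),
- characteristic path length = mean distance over reachable pairs, with the
  unreachable fraction reported,
- small-worldness \(\sigma = (C/\langle C_{rand}\rangle) /
  (L/\langle L_{rand}\rangle)\) against degree-preserving Maslov–Sneppen
  rewired nulls (default 100 nulls, 10 swap attempts per edge, weights
  reshuffled onto the rewired topology; all counts and seeds logged).

Integration across the density grid is a trapezoidal integral divided by
the grid range, so a constant curve integrates to itself and integrated
values stay on the per-density scale (whether the original analysis summed,
averaged or integrated is unstated; this is our documented choice). The
15–35 % range itself is taken as given and is configurable.

# Permutation inference

For a 2x2 repeated design the group-by-time interaction equals the
between-group difference in within-subject change, so the statistic is a
pooled-variance two-sample t on change scores \(\Delta = t_2 - t_1\) after
covariates are regressed out (\(F = t^2\) is reported). This
operationalization avoids specifying an unstated mixed-model error
structure and is exact for the balanced 2x2 case.

The permutation scheme is Freedman–Lane: fit the covariates-only model to
\(\Delta\), permute its residuals across subjects (whole subjects move, so
within-subject pairing is never broken), add them back to the reduced-model
fit, re-adjust for covariates, and recompute the statistic.
\(p = (1 + \#\{|t^\ast| \ge |t|\})/(1 + B)\), two-sided, \(B = 5000\) by
default. Without covariates the statistic depends only on the group
subset, and all \(\binom{n}{n_1}\) assignments are enumerated exactly
whenever that count does not exceed `n_perms`; with covariates the
Freedman–Lane null is indexed by full permutations, so sampling is used.
The suite runs one test per outcome — 36 system-pair blocks, integrated
global metrics, and integrated nodal metrics per node — reporting raw
p-values with flags at 0.05 (connectivity/global convention) and 0.01
(nodal convention); no familywise correction is applied by default, and an
optional Benjamini–Hochberg column can be switched on.

Brain–behavior association residualizes both change vectors on the
covariates and uses a t reference with \(n - 2 - q\) degrees of freedom
(\(q\) = covariate columns), the conservative df convention for
residualized correlations. Behavior scales are symptom scores: improvement
is a decrease, and the coupling sign convention (positive = less
connectivity increase goes with more improvement) is recorded in the run
manifest.

# Numerical and reproducibility choices

- Correlations within `1e-7` of ±1 are clipped before `atanh`, so
  duplicated signals give a large finite z.
- The band-pass is an FFT mask by default (sharp edges, exactly zero
  phase); a squared-magnitude Butterworth response is available. Tests
  assert response bounds, not filter identity.
- Every stochastic stage consumes a seed derived from the master seed by a
  fixed offset (a Lehmer-style map kept below \(2^{31}\)), so toggling
  stages does not shift downstream seeds and the whole pipeline is
  byte-identical across reruns with one master seed.
- Block summaries keep negative z (the positive-only rule is a graph-
  construction rule); intra-system cells average off-diagonal pairs only,
  and a system with fewer than two ROIs reports `NA`, not zero.
- The default 141-ROI partition (16/16/20/17/16/14/12 cortical ROIs over
  seven systems + 30 subcortical) is a synthetic stand-in with the same
  system sizes and block structure as common parcellations; real ROI
  identities are data, not code, and any partition TSV can be supplied.

# Problem sizes used by the tests

The test suite and the acceptance script exercise reduced problem sizes
chosen as the package's own trade-off between statistical resolution and
turnaround: oracle cross-checks on 50 random graphs of up to 30 nodes;
small-world checks on 100-node reference graphs with 100 nulls; calibration
on 500 null cohorts (18 + 11 subjects, 32 ROIs, 120 frames, 1000
permutations); power on 200 replicate cohorts (planted intra-block change
of z = 0.15, 240 frames); coupling recovery on 500 replicates; one
study-dimension cohort (141 ROIs, 246 frames, 5000 permutations) run end to
end. The quantities these produce are exactly what
`scripts/acceptance.R` recomputes and writes.

# Known limitations

- No volumetric processing: inputs are ROI-level tables; registration,
  smoothing, nuisance voxel regression and related spatial steps are out of
  scope.
- The generator's white-frame model understates the temporal-df cost of
  filtering real BOLD and contains no physiological confounds.
- The permutation engine assumes subjects are exchangeable across groups
  under the null after covariate adjustment; it does not model
  session-level nuisance that differs systematically by group beyond the
  scanner covariate.
- Harmonic closeness and the unreachable-pair handling make disconnected
  graphs well defined, but very sparse graphs (below ~10 % density) were
  not the design point.
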
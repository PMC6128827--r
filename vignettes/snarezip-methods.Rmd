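---
title: "Models and methods behind snarezip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snarezip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snarezip)
```

snarezip analyzes single-molecule magnetic-tweezers experiments on neuronal
SNARE complexes: a pre-assembled syntaxin-1A/SNAP-25/synaptobrevin-2 bundle
held between two 510-bp dsDNA handles, pulled from the C-termini, with the
two chains crosslinked near their N-termini so the complex can be unzipped
and rezipped repeatedly. The observable is the bead height — the end-to-end
extension of the tether — sampled by a camera at 100 Hz or 1.2 kHz while the
applied force follows ramps, jumps, or constant holds. This vignette
explains the models the package implements, the choices made where the
design was genuinely open, and what the simulation-based tests do and do not
establish.

## The construct extension model

At force $F$, the tether extension is modelled as a sum of three mechanical
elements:

* **dsDNA handles** (2 x 510 bp): extensible worm-like chains under the
  Marko–Siggia interpolation with an enthalpic stretch term,
  $\frac{FP}{k_BT} = \frac{1}{4(1-l)^2} - \frac14 + l$ with
  $l = x/L - F/K$. Pinned parameters: persistence length $P = 45$ nm,
  contour 0.338 nm/bp, stretch modulus $K = 1200$ pN.
* **Unfolded polypeptide**: inextensible worm-like chain with $P = 0.6$ nm
  and 0.365 nm per residue. The number of residues released as random coil
  depends on the conformational state (below).
* **Folded structure**: a rigid rod along the pulling axis contributing a
  force-independent axial length. No orientational averaging is applied —
  the simplest model consistent with the measured level spacings.

The inversion $x(F)$ is solved by bracketed root-finding on the fractional
extension (absolute tolerance $10^{-12}$); no closed-form approximation is
used. Because the unfolded-coil extension is linear in the residue count at
fixed force, all states share a single root-solve per force.

Five conformational states are modelled. Residue counts come from a
leucine-zipper layer map (layers $-7\ldots+8$, ionic layer 0 at
synaptobrevin R56 / syntaxin Q226, canonical 3/4 heptad spacing) stored as
an editable table in `inst/extdata/layer_map.tsv`:

* **fully zippered** — no unfolded residues beyond the termini;
* **linker open** — the C-terminal linker domains (beyond layer +8) are
  random coil, the four-helix bundle is intact;
* **half zippered** — synaptobrevin unfolded beyond layer +2, Q-SNAREs
  beyond layer +4;
* **unzipped** — synaptobrevin fully unraveled to the N-terminal
  crosslink, Q-SNAREs unfolded to layer 0;
* **SNAP-25 dissociated** — SNAP-25 lost, syntaxin unraveled to the
  crosslink.

A one-time calibration (`scripts/calibrate_construct.R`) adjusts only the
per-state folded-axial offsets so that the state separations at 14 pN equal
5.4, 13.9 and 26.7 nm and the SNAP-25 step at 16 pN equals 5 nm; the
resulting offsets (0.24, 0.90, 3.61, 2.99 nm) are small and physically
plausible — the 3.6 nm offset of the unzipped state corresponds to the
axial traverse of the residual three-helix bundle between the crosslink and
layer 0. All other polymer parameters are pinned, never fitted.

## Kinetics: Bell edges, landscapes, and the simulator

Transitions follow the Bell equation
$k(F) = k_w \exp[(-\Delta G^\ddagger + F\,\Delta x^\ddagger)/k_BT]$ with
$k_BT = 4.11$ pN nm and the diffusion-limited attempt frequency
$k_w = 10^6\,\mathrm{s^{-1}}$. `scheme_from_landscape()` builds schemes from
per-state free energies, extension coordinates and barrier placements, so
forward/backward rates obey detailed balance by construction. Because a
Bell-extrapolated landscape is only meaningful near the forces where it was
specified, energies and barrier heights are declared at a reference force
(14 pN for the built-in schemes) and validated there.

The simulator generates a continuous-time Markov path: exact exponential
waiting times during constant-force holds, and time-discretized thinning
(per-step survival $e^{-k\Delta t}$, $\Delta t = 1$ ms) during ramps — a
documented accuracy/speed trade-off that reproduces the Evans–Ritchie
rupture-force distribution to within 0.3 pN in the tests. The path is then
sampled on the camera grid; the observed extension adds per-frame Gaussian
noise. Noise defaults are 2.5 nm per frame at 1.2 kHz and 1.0 nm at 100 Hz,
chosen so the three zippered levels (0/5.3/13.0 nm) are resolvable at high
speed but merge at 100 Hz; no measured noise amplitudes are available for
either sampling rate, so these are resolvability-calibrated, not measured,
values. An optional
Ornstein–Uhlenbeck mode adds a 2 ms correlation time. SNAP-25 rebinding is a
pseudo-first-order edge gated to forces below 2 pN (free SNAP-25 in the
buffer), default 1 s$^{-1}$.

Built-in condition presets (`cpx_conditions()`) encode the no-Cpx control
and the Cpx truncation series (WT, NAC, AC, C) as three-state landscapes
over the zippered intermediates. The energies are chosen so that, as
observed, intermediates appear only above ~13 pN; WT/NAC make the
linker-open state dominant above 14.5 pN while nearly abolishing the
half-zippered state; AC and C suppress the half-zippered state without
promoting the linker-open one, and WT has more than three times the
linker-open population of AC at 14 pN. For ramp simulations the Cpx
condition uses an unzipping barrier 4.3 kBT above control and a slightly
smaller $\Delta x^\ddagger$ (5.5 vs 7 nm), which reproduces both the ~2 pN
upward shift and the broadening of the unzip-force distribution.

## Ramp analysis

Steps are detected by a two-sided moving-median comparison (window 11
frames at 100 Hz, 61 at 1.2 kHz; threshold 10 nm for unzip/rezip, 3 nm for
SNAP-25 steps), with candidates closer than one window merged and the
change point placed at the middle of the maximal-difference plateau. The
event force is the protocol force at the change-point frame. Classification
uses the step sign and a 15 nm size boundary between the ~25 nm
unzip/rezip steps and the ~5 nm SNAP-25 steps. The detector is designed for
constant-force segments and abrupt steps; during steep low-force ramp
portions the tether's own force-extension slope can exceed the 3 nm
threshold and produce small spurious events, which is harmless for the
signature QC because verdicts depend only on events inside the four force
windows (unzip 12–16, rezip 8–12, unfold 15–18, refold < 2 pN).

Per-bead force normalization rescales each construct so its mean no-Cpx
unzip force equals the global 14.4 pN average; the operation is exact and
idempotent, and beads with fewer than three events are excluded.

## Dwell times and the coarse-grained landscape

Latencies are timed from the end of the force jump, excluding the 0.1 s
settling transient; traces ending without a transition enter as
right-censored records — censored maximum likelihood is the defensible
default for dwells cut off by the observation window. The censored-MLE
rate is (uncensored dwells)/(total observed time) with a profile-likelihood
CI. Bell fits regress $\ln(k/k_w)$ on force, weighted by inverse variances
derived from the per-force CIs when available. The coarse-grained landscape
at force $F$ places the zippered state at (0, 0), the barrier at
$(\Delta x^\ddagger_{unzip}, \Delta G^\ddagger_{unzip}(F))$ and the
unzipped state at $(\Delta x^\ddagger_{unzip} + |\Delta x^\ddagger_{rezip}|,
\Delta G^\ddagger_{unzip}(F) - \Delta G^\ddagger_{rezip}(F))$; an
`anchor = "unzipped"` mode re-references the landscape for comparing
conditions whose rezipping kinetics agree. Barrier differences between
conditions are independent of $k_w$, which cancels in the rate ratio.

## Equilibrium populations and the three-state model

High-speed constant-force traces are decomposed by Gaussian-mixture EM
(tolerance $10^{-8}$, up to 500 iterations, best of 10 seeded restarts;
mclust's univariate EM is the engine). Two components are fitted below 13
pN and three at or above, following the observed number of resolvable
levels. Components are assigned to the nearest state level within 2.5 nm;
unassigned components (the unzipped level) are excluded and weights
renormalized. One numerical caveat found during development: with the
0/5.3 nm separation and 2.5 nm noise, the unequal-variance mixture
likelihood is nearly flat and the ML weights can drift by ~10% between
solutions of indistinguishable likelihood. Because the tracking noise is
state-independent, `population_scan()` therefore defaults to the
equal-variance mixture, which is correctly specified and well identified;
`fit_gmm()` keeps the general model as its default.

The three-state equilibrium model gives Boltzmann populations over
force-tilted free energies,
$p_i(F) \propto \exp[-(G_i - F x_i)/k_BT]$ with the fully zippered state as
reference. The fit maximizes the multinomial likelihood using the per-force
frame counts as multinomial sizes (frames are autocorrelated on the few-ms
dwell scale, so these counts overstate the independent information; the
point estimates are unaffected, and no confidence intervals are derived
from this likelihood). Starting values come from log-ratio regression,
which is exact on noiseless data — the fit inverts model-generated
populations to $10^{-6}$. The extension coordinates $x_i$ can be
constrained to the construct-model separations via `fix_x`; the default
leaves them free, which is the stricter test of the data.

## HMM idealization and per-transition kinetics

A Gaussian-emission hidden Markov model is fitted by Baum–Welch (scaled
forward-backward in compiled code; convergence $\Delta\log L < 10^{-6}$, at
most 1000 iterations). Emission means are initialized from the measured
extension distributions and frozen by default, mirroring the use of
measured levels as priors; standard deviations and the transition matrix
are re-estimated. Rates are derived canonically by Viterbi dwell counting,
$k_{ij} = n_{ij}/t_i$, with the per-frame transition-matrix conversion
reported as a secondary estimator; rates outside 1–$10^3$ s$^{-1}$ are
flagged unreliable at 1.2 kHz, and no missed-event correction is applied
beyond that band. Two consequences are documented rather than corrected:
fast exchange (≳ several hundred /s) is underestimated, and for
force-accelerated transitions the occupancy misattribution of short dwells
grows with force, biasing the per-pair Bell slope upward by ~15% under the
pinned test conditions. The force-opposed pairs recover within ~5–10%.
Free-energy differences between exchanging states follow from rate ratios,
$\Delta G_{ij} = k_BT\ln(k_{ij}/k_{ji})$, and close the three-state
thermodynamic cycle within estimation error.

## Problem sizes used by the tests and the acceptance script

The simulations mirror the experimental scales: 25 dwells per force per
replicate for force-jump experiments (the experiments report at least 19
per panel), 15 s of 1.2 kHz data per grid force for equilibrium scans,
0.2 pN grid over 12–16 pN at full scale, and ramps at 1 pN/s. Replicate
counts in the test suite (5–20 per criterion, 150–600 for detector and
rupture-force properties) were chosen as the smallest sizes at which the
Monte Carlo error is comfortably below each tolerance. The fixture
generator's `smoke` scale (5 dwells per force, 2 s scans) exists for fast
end-to-end runs; `paper` scale reproduces the experimental sizes.

## What the synthetic data do and do not establish

The generator reproduces the statistical structure the analysis assumes:
Markov exchange with Bell force dependence, state-dependent extensions from
the construct model, protocol-driven forces, and Gaussian camera noise. It
does not emulate bead-surface hydrodynamics, drift, force-calibration
error beyond the per-bead scale factor, anti-parallel misfolded complexes,
or non-Markovian dynamics. Passing tests therefore establish that the
inference chain recovers known ground truth under the stated noise model at
experimental scales — not that the underlying physical model is correct
for any particular real data set.

## Known limitations

* The layer map and the per-state folded-axial offsets are a calibrated
  coarse-grained geometry, not a structural model; only the anchored level
  spacings are meaningful.
* Dwell-count rates are uncorrected for missed events; see above.
* The equilibrium fit treats frames as independent multinomial draws;
  uncertainties, where needed, should come from replicate scans.
* `detect_steps()` assumes steps are fast compared to the window; slow
  transitions spread over many frames will be missed or split.
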
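---
title: "Scanning-FCS analyses and the SHR-SCR model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning-FCS analyses and the SHR-SCR model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`scanfcs` implements the scanning fluorescence correlation spectroscopy
(scanning FCS) toolchain used to quantify transcription-factor mobility and
interaction in living tissue -- raster image correlation spectroscopy
(RICS), pair correlation function (pCF) barrier analysis, and
number-and-brightness (N&B) with its two-colour cross-correlation extension
-- together with a Brownian-dynamics scan simulator that provides ground
truth, and a six-variable ODE model of SHORTROOT (SHR) and SCARECROW (SCR)
dynamics in the Arabidopsis root with Sobol sensitivity analysis and
composition calibration.  This vignette records the models, the tunable
parameters, and the design decisions taken where the methods left choices
open.

## The synthetic-scan generator

Every analysis stage is exercised on synthetic confocal scans with known
ground truth.  Particles perform 3D Brownian motion (per-axis step variance
`2 D dt`) inside a box; the axial extent is a slab of thickness `6 wz` with
reflecting faces, centred on the focal plane.  Cell walls are planes of
constant x (the fast scan axis): a step crossing a wall is accepted with
the wall's directional permeability (`p_f` left-to-right, `p_r`
right-to-left) and otherwise reflected.  Optionally the x boundaries are
periodic; a one-way wall on a periodic domain sustains a steady circulating
flux, which stands in for the continuous production and removal that keep a
unidirectional flux going in tissue (the pure random-walk simulator has no
birth or death).

Photon detection: pixel `(frame, row, col)` is acquired at
`frame*frame_time + row*line_time + col*pixel_dwell` and its count is
Poisson with mean `background + sum_p (eps_p / gamma) *
exp(-2 dr^2/w0^2 - 2 dz^2/wz^2)` evaluated at the particle positions at
that acquisition time.  Particles keep moving *during* the scan, including
the retrace (`line_time - line_length*pixel_dwell`); this is precisely what
makes RICS informative.  The detector is an ideal photon counter (shot
noise only); the S-factor stage still applies as a pure rescaling.

Two conventions deserve emphasis:

* **Brightness units.**  A species' `brightness_per_unit` is the *apparent*
  molecular brightness in counts/dwell/molecule -- the `B - 1` a single
  fluorophore unit produces in an N&B measurement, which is also the unit
  instrument tables quote.  The renderer converts it to a peak count rate
  by dividing by the 3D-Gaussian shape factor `gamma = 2^(-3/2)`, so that a
  simulated monomer with `eps = 0.28` measures `B - 1 = 0.28` (up to
  background dilution, see below).

* **Time resolution.**  The streaming generator (`synthesize_raster`,
  `synthesize_lines`) advances particles by exact Gaussian steps at roughly
  an eighth of the beam transit time `w0^2/(4D)` of the fastest species,
  interpolating within a substep, with constant memory.  Coarser stepping
  biases fitted diffusion coefficients low (linearly interpolated motion is
  under-dispersed); at the automatic resolution the residual bias is below
  the fit's statistical error.  The two-stage API
  (`simulate_particles` + `render_raster_series`) stores explicit
  trajectories and is preferred when the trajectory itself is wanted.

## RICS

The spatial autocorrelation `G_S(xi, psi) = <dI(x,y) dI(x+xi, y+psi)> /
<I>^2` is averaged over frames after a 10-frame moving-average subtraction
of the immobile fraction (each retained frame minus the mean of its five
preceding and five following frames, grand mean re-added; the first and
last five frames are dropped).  The correlation uses zero-padded FFTs with
per-lag overlap normalisation, reported to +/- size/4 lags.

The fitted model is the standard one-component 3D Gaussian form,
`G_S = S * G` with scan-time lag `tau = |tau_p xi + tau_l psi|`:

```
G = G0 * (1 + 4 D tau / w0^2)^-1 * (1 + 4 D tau / wz^2)^-1/2
S = exp(-((xi dx)^2 + (psi dx)^2) / (w0^2 + 4 D tau))
```

Design choices:

* zero lag is excluded from the fit (shot-noise spike);
* a free constant offset absorbs the finite-image baseline bias of the
  per-frame mean subtraction (approximately `-G0 * A_psf / A_image`),
  which otherwise biases D low by ~15% at slow diffusion;
* D is optimised on a log scale in `[1e-3, 1e3]` um^2/s with multi-starts
  at `D0 * {0.1, 1, 10}`, ties broken by SSE;
* the axial ratio `wz/w0` is fixed at 3 (typical water-immersion
  confocal), exposed as an argument;
* the fit passes quality control when the surface maximum is at least
  three times the largest absolute residual.

`calibrate_psf` fits the same model with D clamped to a known solution
standard (free EGFP in water, 78 um^2/s), solving for `w0`.  Calibration
scans should use a short line period (about 1 ms) so that the fast solution
dynamics are resolved along the line; at the slower tissue-imaging line
times almost all the decay happens between lines and the waist becomes
poorly identified.

Measured performance (128-px ROI, recommended settings, 50 frames):
fitted D within 5--11% median error for true D in 1--10 um^2/s.  The
moving-average window, ROI and multi-start grid are arguments, not
constants.

## pCF and the Movement Index

Line scans (32 pixels, one line per `line_time`) are reduced to pair
correlation carpets, `G(tau, dr) = <F(t,0) F(t+tau, dr)> / (<F(t,0)>
<F(t,dr)>) - 1`, for pixel separations 5, 7 and 9, in both directions.
Bleaching is detected on per-period mean intensities (monotone decline
beyond 20%) and the tail trimmed; the 800-line period average is a display
aid and does not enter the correlation computation.

The binary arch call -- "do molecules cross the wall?" -- is made by an
automated surrogate for the visual inspection used in practice:

1. the wall column comes from the wall-marker (stain) channel of the
   reference image;
2. the column pairs spanning the wall, closest to symmetric about it (up
   to four), are period-averaged (8 lines), detrended with a long running
   mean, and correlated over a delay window of 32--320 lines;
3. the maximum of the smoothed profile is compared against a
   block-permutation null (blocks of 32 periods of the partner columns,
   200 permutations): the call is 1 when the permutation p-value is at or
   below 0.05.

The lower delay edge matters: a particle close to the wall is seen by
columns on *both* sides through the tails of the PSF, producing genuine
same-particle correlation at short delays that is not barrier crossing.
For the same reason the synthetic walls are given a finite thickness (two
semi-permeable planes 0.3 um apart): with an infinitely thin wall and
small pixels, PSF bleed-through is indistinguishable from permeation.
Real cell walls have finite thickness, so this is fidelity, not a trick.

The Movement Index is the mean of the binary calls over the three pixel
distances (one biological replicate) and then over replicates, with its
standard error.  On the packaged study conditions (0.1 um pixels, 0.5 ms
line period, 2e5 lines, D = 6 um^2/s, 90 particles), open walls score MI
~ 0.9--1.0, impermeable walls ~ 0.1, and one-way walls separate forward
from reverse by ~ 0.5.  What these tests show is that the detector
discriminates permeability classes under the stated conditions; they do
not certify the absolute MI values of any real genotype, which depend on
cell geometry, expression level and acquisition length.

## N&B and cross-N&B

Per pixel over frames, the mean `<k>` and population variance `sigma^2`
give the apparent brightness `B = s_factor * sigma^2 / <k>` and number
`N = <k>^2 / sigma^2`.  As for RICS, a 10-frame moving-average detrend
removes the immobile fraction first; because the inclusive surrounding
window contains the frame itself, the detrended variance of white noise is
biased by `1 - 1/(window+1)` and is corrected back, so pure shot noise
sits exactly at `B = 1` when `s_factor = 1`.  The S-factor is calibrated
on a background-only region as `1 / median(raw B)`.

Apparent brightness is diluted by background: `B - 1 = eps * I_signal /
(I_signal + I_background)`.  Brightness measurements should therefore be
made on bright samples or corrected for the background share.

Per-pixel B at 50--100 frames carries relative noise `sqrt(2/K)` (about
15--20%), which is larger than the monomer-dimer separation.  The cursor
classification is therefore preceded by a 5x5 boxcar smoothing of the B
map (`smooth_px` argument); without it the false-dimer rate at these frame
counts is far above any useful bound.  Cursors are windows on the B axis
only (the intensity axis varies between images): the monomer cursor is
centred at `1 + eps`, the homodimer cursor at `1 + 2 eps` -- the
above-background brightness doubles while the shot-noise unit does not --
and both have width `cursor_size` (default `eps`; overlapping cursors are
an error).  Percentages are reported over classified pixels.

A caveat the recovery tests make explicit: per-pixel moment classification
resolves *spatially segregated* populations.  In a homogeneous molecular
mixture every pixel has the same intermediate brightness and the
monomer/dimer split is undefined at the pixel level; the synthetic
recovery oracles therefore composite monomer-only and dimer-only fields.

Cross-N&B computes the per-pixel cross-variance of the detrended channels,
`sigma_cc^2 = sum (G_i - <G>)(R_i - <R>) / K`, and from it `B_cc =
sigma_cc^2 / (<G> <R>)` and `N_cc = <G> <R> / sigma_cc^2`.  Independent
channels give `B_cc ~ 0`; co-moving complexes positive `B_cc`.  Pixel
significance is assessed against a temporal-shuffle null (one channel's
frames permuted), and complexed pixels are classified on the (green B,
red B) plane: (monomer, monomer) is a 1:1 complex, (dimer, monomer) a 2:1
complex.  The two channels of the simulator share one set of particle
trajectories and differ only in shot noise, exactly like two detection
channels of one microscope.

## The SHR-SCR compartment model

Six variables: SHR in the vasculature (`Sv`), SHR monomer (`Se`) and
homodimer (`S2e`) in the endodermis, SCR (`C`), and the 1:1 (`SC`) and 2:1
(`S2C`) SHR-SCR complexes.  Production of SHR is constant (`k1`);
transport between compartments is first order with `a1 = D1/A1` (and
`a2 = 0` in the wild type -- movement back to the vasculature is blocked
-- or `a2 = D2/A2` in the SCR-knockdown mode); all degradation is linear.
Homodimerisation switches on once SCR passes a threshold: `k2(C) = L / (1
+ exp(-k (C - C0)))`.  SCR production is a Hill function activated by both
complexes and by SCR itself; in the knockdown mode `dC/dt = 0` exactly
(SCR held at its reduced level).  The monomer equation has no consumption
terms for dimerisation or complex formation; the system is implemented
exactly as formulated (a modelling simplification of the source model, not
corrected here).

Integration uses `deSolve::lsoda` at relative tolerance 1e-8;
nonnegativity is preserved by the solver tolerances, never by clipping.
Time is in hours; transport rates derived from um^2/s diffusion
coefficients are converted explicitly.

The steady-state time is the earliest time after which every variable
stays within 1% (relative) of its terminal value, *and* the terminal
relative rates of change are below the same tolerance -- without the
latter check a still-rising trajectory would trivially "settle" at its own
endpoint.  Composition metrics are entity-wise: `homodimer_pct = 100 *
S2e / (Se + S2e)` and `complex21_pct = 100 * S2C / (SC + S2C)`, matching
how pixel-classification percentages are formed (a mass-weighted
definition would double-count dimers).

### Default parameters

The defaults ship as a structured-text table
(`inst/extdata/shr_scr_parameters.tsv`) with a provenance flag per row:
`measured` (RICS diffusion coefficients, cell areas), `constraint`
(logistic switch: `L = 0.5`, `k = 0.1`, `C0 = 360` chosen as 60% of the
SCR steady state, re-tied during calibration), and `estimated` (rates
tuned against the N&B composition data).  Magnitudes were chosen so that
SHR equilibrates in minutes (`a1 ~ 88 hr^-1`), SCR approaches its steady
state of ~600 units with `C0 = 360 = 0.6 C*`, and the full system settles
between 18 and 24 hours.

One default is worth explaining because the steady-state algebra forces
it.  At steady state the composition ratios obey `S2C/SC = c * S2e/Se`
with `c = (k5 d5)/(k4 d6)`.  Once the homodimer share is calibrated to
7.5%, the 2:1 complex share is therefore fixed by `c` alone, and matching
the measured 15.2% requires `c ~ 2.21 = (15.2/84.8)/(7.5/92.5)`.  The 2:1
association rate `k5` is consequently an `estimated` parameter derived
from the measured complex stoichiometry -- no tuning of the
degradation/association rates of the complexes could be avoided by the
calibration search, whatever its free set.

### Calibration

`estimate_parameters` formalises one-at-a-time tuning as cyclic coordinate
descent over `{d2, K2D, L}` (never `k3` or `d4`), each sweep a log-spaced
grid around the current value with shrinking span, at most three cycles,
minimising the worst absolute deviation of the two steady-state
percentages from their targets; `C0` is re-tied to 60% of the running SCR
steady state at the start of every cycle.  From the shipped defaults the
search raises `d2` (faster turnover of the endodermal monomer lowers the
dimer share) and leaves `K2D` and `L` at their defaults, reaching
7.49% / 15.18% against targets 7.5 / 15.2 within +/- 0.5 percentage
points.  The search is deterministic given the defaults.

## Sobol sensitivity analysis

The varied set is the 15 independent rate and equilibrium constants of the
wild-type model -- `k1, a1, a2, d1..d6, L, k3, K1D, K2D, k4, k5` -- with
the logistic shape constants `k` and `C0` held fixed; which quantities
constitute "the parameters" is not canonical, so the set is an argument
with this default.  Bounds default to 0.25x--4x each default value,
sampled log-uniformly; `a2` (wild-type default zero) is sampled over
`a1`'s bounds since it is the symmetric transport rate.  Outcomes are the
trapezoidal time-integrals of the six state variables over 0--24 h.  The
total-effect index uses the Jansen estimator, `S_Ti = (1/2N) sum_j
(f(A)_j - f(C_i)_j)^2 / V(Y)`, on the radial design (`C_i` = A with
column i from B); failed solver rows are excluded pairwise and counted.

Replicates are z-normalised across parameters within each replicate and
outcome before averaging.  "Influential" parameters are flagged by
all-pairs rank-sum statistics with a studentised-range (Steel-Dwass
style) adjustment at alpha = 0.10; a parameter is flagged when it is
significantly greater than at least three quarters of the others.  Note
that with fewer than about eight replicates the adjusted criterion cannot
flag anything; ten replicates are used throughout.

Under the shipped defaults the transport rates `a1` and `a2` are flagged
for the vascular SHR outcome (with `k1` and `d2`), and `k3`, `d4`, `K2D`
for SCR -- the parameters the calibration stage treats as estimable.  For
the *endodermal* monomer the transport rates are structurally
uninfluential here: with `a1 >> d1` the steady state reduces to
`Se* ~ k1/d2` and the transport rate cancels.  Whether that held in the
original parameterisation cannot be checked without its (unpublished)
parameter table.

## Problem sizes used by the test-suite

All fixtures are generated in code at run time.  The suite runs RICS
recovery on 128-px, 50-frame scans (the conventional analysis ROI), N&B
on 64-px, 100-frame fields, pCF on 32 x 2e5-line scans, Sobol model runs
at N = 32--48 rows with 10 replicates, and the additive-function estimator
check at N = 1000.  These sizes were chosen as the smallest at which each
property is comfortably resolved; the generator and analysis functions
accept full-size inputs (256 px, 2e5 lines, N = 1000) unchanged.

## Known limitations

* The simulator renders an ideal photon-counting detector; analog-detector
  excess noise is represented only through the scalar S-factor.
* No optical aberrations, no photobleaching kinetics beyond the
  bleach-trim stage, no cell-wall fluorescence in the analysis channel
  (walls are geometric; the stain lives in the reference image's marker
  channel).
* Arch detection is a statistical surrogate for a visual call; its
  absolute MI scale depends on acquisition length and geometry, and only
  contrasts between permeability classes are interpreted.
* The ODE model inherits the printed simplifications (no monomer
  consumption by dimerisation or binding); its composition percentages
  are entity-wise by definition.
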
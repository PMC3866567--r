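---
title: "Distinguishing gamma mechanisms in simulated current dipoles"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Distinguishing gamma mechanisms in simulated current dipoles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cdgamma)
```

## The scientific problem

Gamma-band rhythms (30–150 Hz) recorded with MEG/EEG are estimated as
equivalent current dipoles (CD), in nanoampere-meters. At the cellular
level the CD is carried by intracellular axial current in the long,
parallel apical dendrites of neocortical pyramidal cells. Different
circuit mechanisms can produce activity in the same frequency band, so the
band label alone does not identify the generator. `cdgamma` simulates two
mechanism classes in a laminar cortical column model and quantifies the CD
waveform features that separate them:

* **Spiking PING** (pyramidal–interneuron gamma): reciprocal E→I AMPA and
  I→E GABA\_A coupling. The oscillation period is paced by the decay of
  GABA\_A inhibition at the pyramidal somata. In the *strong* regime a
  tonic current makes every E cell fire on every cycle; in the *weak*
  regime stochastic Poisson synaptic drive makes a sparse, random subset
  participate per cycle.
* **Subthreshold driven gamma**: rhythmic bursts of weak (40 pS)
  excitatory synaptic events delivered identically to all pyramidal cells,
  either to proximal dendrites (apical oblique and both distal basal
  branches) or to the distal apical tuft, at gamma frequency, with no local
  spiking at all.

The discriminating statistic is the **cycle slope ratio** Φ: for each
oscillation cycle, the magnitude of the linear rising slope
(trough→peak) divided by the falling slope (peak→next trough),
averaged over cycles. Inhibition-paced PING produces slow rises and sharp
GABA-driven downstrokes (Φ < 1); subthreshold drive produces fast
synaptic rises with slow passive relaxation (Φ > 1).

## Model structure

Each simulated layer (L2/3 or L5) holds 100 multi-compartment pyramidal
cells and 35 single-compartment fast-spiking basket cells on a 10 × 10
grid (basket cells interleaved on a coarser lattice). Pyramidal cells
have a soma, a chain of apical compartments perpendicular to the laminae
(L5 has one more apical compartment than L2/3), one oblique dendrite
parallel to the laminae, and three basilar compartments. The summed
apical-axis extent of the L5 cell is exactly 2.21 × that of the L2/3
cell; the L2/3 apical lengths are rescaled at build time to enforce this.
Compartments longer than 100 µm are split into two series segments.

The CD of a layer is

$$Q_{\mathrm{total}}(t) \;=\; \sum_{\mathrm{pyr}} \sum_{i}
  \frac{v_{\mathrm{parent}(i)} - v_i}{r_i}\; z_i ,$$

the ohmic axial current between adjacent segments times the segment's
length component $z_i$ along the apical axis, signed positive toward the
pia (so current flowing away from the soma toward the cortical surface is
a positive dipole). The oblique dendrite has $z = 0$ and contributes
nothing; basket cells contribute nothing. Layer series add linearly into
the aggregate CD.

### Membrane biophysics

Channel kinetics follow the classic reduced-pyramidal lineage:
Traub–Miles Na⁺/K⁺ spike currents for pyramidal cells, plus a slow
delayed rectifier (Kdr), muscarinic K⁺ (Km), and — in L5 only —
high-voltage-activated Ca²⁺, T-type Ca²⁺, Ca²⁺-activated K⁺ with a simple
intracellular calcium pool, and the mixed-cation h-current. Basket cells
use the Wang–Buzsáki fast-spiking Na⁺/K⁺ kinetics (φ = 5, instantaneous
Na⁺ activation), which give them a stable rest and a reliable single
spike per excitatory volley. Every constant — geometry, densities,
reversal potentials, calcium-pool parameters — is recorded in
`inst/extdata/cell_parameters.yaml` and loaded by `cdg_parameters()`.

Because the upstream literature does not fix absolute conductance
densities for this exact reduction, the densities, leak reversals and the
tonic-current unit were calibrated **once** so that the printed synaptic
parameters of the regimes (the `ping_regime()` table) reproduce the
regimes' qualitative behaviour: a quiescent network without drive, an
inhibition-paced strong PING with full E participation, sparse weak PING
with Φ < 1, and strictly subthreshold responses to 40 pS burst drives.
They are model constants, not per-experiment knobs. Two calibration
outcomes deserve explicit mention:

* the inhibition-paced oscillation of this implementation runs near
  28–30 Hz rather than the mid-gamma values the regime definitions target
  (see *Known limitations*);
* the per-cycle statistics (Φ ≈ 0.5 weak PING, Φ ≈ 1.5 proximal
  subthreshold), the weak-PING CD amplitude (≈ 0.02 nAm), the L5:L2/3
  amplitude ratio (≈ 3), and the relative spectral-power effects of
  drive jitter are reproduced quantitatively.

### Synapses, connectivity and drives

AMPA and GABA\_A synapses are two-exponential conductances (rise 0.5 ms,
decay 5 ms, reversals 0 and −80 mV) normalized so an event's peak equals
its weight; all network synapses terminate on somata with a 1 ms delivery
delay. Connectivity within a layer is effectively all-to-all with
weights scaled by a Gaussian of grid distance,
$\exp(-d^2/\lambda^2)$. Distances are measured on a **periodic (toroidal)
lattice**, which removes edge effects and makes the connectivity
translation invariant — without the wrap, corner cells receive visibly
less inhibition and the population rhythm fragments into patches. The
space constant λ is a per-regime configuration value (2.5 grid units for
strong PING, 3.5 for the weak-PING and subthreshold scenarios); it was
chosen with the rest of the calibration and then frozen.

Three drive classes exist (`tonic_drive()`, `poisson_drive()`,
`burst_drive()`). Burst drives deliver 10 Gaussian-jittered events per
cycle (per-cycle s.d. σ, per-event conductance 40 pS) at the drive
frequency; distal drives lag proximal cycle means by 5 ms. The 5 ms
figure is the lag between proximal and distal cycle means, while the 1 ms
delivery delay applies to every synaptic event — the only reading that
reconciles both delay statements in the regime definitions. Each drive
draws from its own named RNG stream derived from the run seed, so Poisson
noise and burst jitter are decoupled and runs are bit-reproducible.

### Numerics

The integrator (C++, via Rcpp) advances gating variables by exponential
Euler and solves the voltage system by backward Euler with Hines
elimination on each cell's tree, at a fixed 0.025 ms step (halving the
step moves single-cell spike times by < 0.1 ms). Spikes are upward
somatic crossings of 0 mV with a 1 ms refractory. Gating variables stay
in [0, 1] by construction of the exponential-Euler update. Compartments
are initialized at their settled resting potentials (obtained by relaxing
each cell type from −65 mV for 600 ms at build time); this matters,
because cells initialized off-rest fire a spurious synchronized volley
that can entrain the network for hundreds of milliseconds. Simulations
run 550 ms and all analyses discard the first 50 ms. A run aborts with a
diagnostic naming the compartment and time if any voltage leaves
±200 mV.

The baseline renormalization of the CD (`baseline_renormalize()`)
subtracts the standing dipole of the resting network: a constant offset
per L2/3 cell and a slowly drifting line per L5 cell, both fitted to
drive-free runs of this model and recorded in the parameter file. It is
affine, so the slope-ratio and spectral statistics are unaffected; Φ is
computed on demeaned series.

## Analysis layer

All statistics accept any uniformly sampled series, including external
two-column text data (`read_timeseries()`):

* `welch_periodogram()`: Hann-tapered power spectrum; the default is one
  segment spanning the whole 500 ms window (frequency resolution 2 Hz),
  matching a stationary analysis; multi-segment averaging is available.
  A sinusoid of amplitude A yields a peak of A²/2.
* `morlet_spectrogram()`: complex Morlet wavelets with 7 cycles
  (configurable), 1–150 Hz; implemented in the frequency domain and
  normalized so a unit tone has unit modulus. Frequencies below the
  reciprocal window length are rejected, so scenario analyses start the
  grid at 2 Hz for 500 ms windows.
* `find_extrema()` / `slope_ratio()`: alternating peaks and troughs
  filtered by topographic prominence (default 10 % of the series IQR,
  ties broken by earliest time), per-cycle slope ratios ϕᵢ, the mean Φ
  with its standard error, and a one-sided one-sample t-test of the ϕᵢ
  against 1 in the direction of the departure (α = 0.05). Φ needs at
  least three full cycles. When a series has a dominant rhythm (as in
  `analyze_cd()`), extrema closer than half the dominant period are
  merged pairwise so the sequence carries one peak per oscillation
  cycle; without this, sub-cycle ripple on spiking-network dipoles
  creates degenerate cycles whose near-zero fall slopes make the mean of
  ratios arbitrarily unstable.
* `find_high_gamma_epochs()`: transient 100–150 Hz bouts as local maxima
  of the band-maximum Morlet power above 50 % of its run maximum
  (configurable), reported with a 50 ms window centred on the maximum;
  epochs are non-overlapping.
* `spike_histogram()` (1 ms bins) and `psth()` (5 ms bins);
  `cluster_volleys()` groups population spikes into volleys to count
  inhibition-paced cycles.

The analysis of simulated CDs subsamples the 0.025 ms output to a 1 ms
grid first; the rhythms of interest live far below the implied 500 Hz
Nyquist frequency, and the decimation makes the wavelet transforms cheap.

## Scenarios and reproducibility

Every figure regime ships as a YAML scenario (`list_scenarios()`):
strong PING, weak PING (the Table regime `g_pois` = 1e-2 and the figure
variant 0.75e-2), the independent L2/3 network, the two-layer aggregate
run, proximal-only drives at 50 Hz (σ\_p ∈ {2.5, 5, 7.5} ms), 80 and
100 Hz, and combined proximal+distal drives (σ\_d ∈ {2.5, 5, 7.5} ms).
`run_scenario()` returns the raw run bundle plus the full analysis set;
`sweep_scenario()` re-runs a scenario over a dotted parameter path with
matched seeds; `write_run_bundle()` archives a run as delimited text plus
a YAML snapshot. A command-line wrapper (`inst/cli/cdgamma`) exposes
`simulate`, `analyze` and `sweep`.

Stochastic statistics reported by `scripts/acceptance.R` are means over
five runs with derived seeds; each 550 ms, ≤ 270-cell simulation takes on
the order of ten seconds on one CPU core, and the shipped analyses use
those problem sizes throughout.

## What the synthetic fixtures do and do not show

`make_fixture()` generates waveforms with exact ground truth (sinusoids,
tone mixtures, asymmetric triangles with known Φ, gated high-frequency
transients on a slow carrier, Poisson and burst event trains) at the
1e-2 nAm amplitude scale of simulated dipoles. They validate the
analysis layer independently of the simulator: peak frequencies against
an FFT oracle, Φ against constructed slopes, epoch localization against
known transient times. They are noise-free or Gaussian-noise signals on
a uniform grid; they do not emulate spike-shaped transients, slow
baseline drift, or the cycle-to-cycle variability of network rhythms, so
passing them shows the estimators are correct, not that real (or
simulated) data are easy.

## Design choices made where the design was open

* **Conductance units.** The regime table's synaptic strengths are
  interpreted as absolute per-connection conductances in µS (the
  convention of event-driven point synapses). The alternative reading —
  densities on the target compartment — makes the E→I coupling six
  orders of magnitude too weak to recruit any interneuron, so it cannot
  be what the regime values mean.
* **Tonic current unit.** The strong-PING applied current is a
  model-unit scalar; one printed unit is 1/6 nA (`current_unit` in the
  parameter file), calibrated so the tonic regime sits at a stable
  all-cells-fire lock.
* **L5 extra apical compartment** is placed on the trunk side of the
  apical chain (a second mid-apical section), not in the tuft.
* **Basket excitability.** Traub-kinetics baskets turn out to be slow
  pacemakers (they self-oscillate near 14 Hz with no input), which
  silently violates the requirement that an undriven network is silent;
  the Wang–Buzsáki kinetics give a stable rest and were adopted for the
  fast-spiking cells.
* **Boundary handling** for burst drives: event times drawn before time
  zero are dropped, not reflected.
* **Two-layer masking runs** drive L5 only in the shipped subthreshold
  scenarios; distal targets are configurable per drive.

## Known limitations

* The inhibition-paced network rhythm saturates near 28–30 Hz (strong
  PING locks 1:1 at 28 Hz; weak PING peaks near 30 Hz) instead of the
  36 / 52 Hz of the regime definitions. The period decomposes into the
  GABA\_A conductance decay (the printed 5 ms time constant, which the
  model does pace by — scaling that constant scales the period) plus a
  recovery-and-coincidence overhead of roughly 10 ms set by the
  excitability ceiling of quiescent-at-rest Traub-kinetics cells: cells
  close enough to threshold to fire on nearly every Poisson event become
  intrinsic pacemakers and the undriven network is no longer silent.
  Within that constraint the sparse-participation structure, Φ
  signatures, amplitudes and jitter sensitivities are reproduced at a
  proportionally slower fundamental.
* The strong-PING maximal CD (≈ 0.09 nAm) is below the ≈ 0.26 nAm of a
  perfectly synchronous population because the model's spike volleys
  disperse over a few milliseconds; the weak-PING amplitude
  (≈ 0.02 nAm) is quantitative.
* No E–E synapses, no interlaminar coupling, no dendritic spines, no
  axonal propagation, no temperature dependence. Absolute spectral power
  values depend on the Welch normalization convention stated above.

## A worked example

```{r example}
library(cdgamma)

out <- run_scenario("fig2b_weak_ping", seed = 1)
out$summary
#   scenario        seed layer e_rate ... peak_f  morlet_f  Phi   max_cd
#   fig2b_weak_ping    1    L5    3.6 ...  29.9      30     0.59  0.019

phi <- out$analysis$L5$slope_ratio
phi
# Phi below 1 with one-sided p < 0.05: the PING signature

estimate_network_size(out$summary$max_cd, n_cells = 100)$exponent
# 5  (order 1e5 pyramidal cells for an observable 10 nAm source)
```
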
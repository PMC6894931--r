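---
title: "Models and methods behind the multipatch package"
author: "multipatch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the multipatch package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multipatch)
```

# What this package models

Multineuron patch-clamp ("multipatch") experiments record from up to ten
neurons simultaneously in a brain slice and probe every ordered pair for a
synaptic connection: action potentials are evoked in one cell while the
membrane potential of the others is examined for postsynaptic potentials
(PSPs) in sweep-averaged traces. Pipette cleaning makes two strategies
possible that raise the yield of such experiments: *clean-to-complete*
(failed pipettes are cleaned and immediately retried on neighbouring cells
until the cluster is full) and *clean-to-extend* (after a full recording,
some pipettes are cleaned and moved to fresh cells while others keep their
recordings, so connections accumulate across sessions).

The package implements the computational side of such a rig end to end:
session combinatorics and yield simulation, a virtual pneumatic controller
with the timed cleaning schedule, rigid manipulator–microscope registration
and approach geometry, a seeded generator of synthetic multi-channel
recordings with known ground truth, electrophysiological feature
extraction, template-scaling detection of spontaneous EPSPs, evoked
connection calling, and the connectivity statistics. Everything that the
analysis claims is checked against either closed forms or the generator's
ground truth in the test suite.

# Session combinatorics

With $n$ cells recorded simultaneously, the number of testable directed
connections is $c = n(n-1)$. A clean-to-extend session that patches
$n_{new}$ fresh cells while maintaining $n_{old}$ adds

$$c_{new} = 2\,n_{new}n_{old} + n_{new}(n_{new}-1)$$

new ordered pairs — both orientations between new and maintained cells plus
all ordered pairs among the new cells; maintained–maintained pairs were
already tested and are never recounted. `planSummary()` accumulates the
directed tested mask over a session plan, with cells labelled
`"<cellIndex>.<sessionIndex>"`. The canonical three-session example
(8 cells, then 4 new/4 maintained, then 5 new/3 maintained) gives 17 cells
and $56+44+50 = 150$ tested connections.

Session plans carry one invariant beyond the obvious bounds: maintained
cells must have been held in the immediately preceding session
($n_{old,k} \le n_{new,k-1}+n_{old,k-1}$), because a released cell is lost.
Without this constraint the closed form above disagrees with brute-force
ordered-pair enumeration — cells co-patched in an early session but dropped
in between were never actually tested against each other. The exhaustive
enumeration test over all plans with up to three sessions surfaced exactly
this case.

## Yield model

`simulateYield()` is a deliberately minimal stochastic model of cluster
assembly: pipettes attempt patches sequentially, each attempt succeeds with
probability $p_{patch}$, and each established recording survives each
subsequent attempt with probability $1-p_{loss}$ (the risk of losing
recordings while manoeuvring nearby pipettes). Cleaning grants failed
pipettes retries on fresh cells. The model is checked against an exact
absorbing-chain computation at small $n$ and against the qualitative
expectation that cleaning stochastically dominates no cleaning. Per-animal
yields reported for real experiments mix slices and plans in ways that are
not reproducible from published numbers, so the simulation is calibrated
qualitatively, not to those totals.

# Rig geometry

Manipulator frames are registered to the microscope/stage frame with a
least-squares proper rigid transform (orthogonal Procrustes / Kabsch via
SVD, the reflection excluded by the usual sign correction on the smallest
singular vector). At least three non-collinear correspondences are
required; the registration residual RMS is reported and is invariant under
global rigid motion of both point sets. Coordinates are right-handed, z up,
in micrometres; these conventions are a package choice, made once.

Target planning stages all pipettes ~200 µm above the slice surface
(configurable) on a circle around the region of interest, each pipette in
the angular sector of its home azimuth, with a tip–tip clearance check
(chord $2r\sin(\Delta/2)$ for spacing $\Delta$). Approach paths end with a
segment parallel to the pipette's longitudinal axis — at approach angle
$\alpha$ the tip drops $\tan\alpha$ µm per µm of horizontal travel — so
tissue is only ever entered along the pipette axis. Reachability into a
walled chamber reduces to a standoff condition: the horizontal distance
from the wall crossing to the target must be at least
$h_{wall}/\tan\alpha$; at the 27° default a 2 mm wall demands ~3.9 mm of
standoff. The collision model is tip-point distance only; shank cones and
motor kinematics are out of scope.

# The virtual pressure rig

Five channel levels drive the pneumatics: LOW (+20 mbar) keeps solution
flowing from idle tips, HIGH (+70 mbar) protects tips moving through
tissue, PATCH is the operator-variable sealing suction (modelled as a
scripted parameter, −15 mbar by default), ATMOSPHERE (0) holds whole-cell
recordings, and CLEAN alternates −350 mbar suction with +1000 mbar
(1 bar) expulsion. Each pipette has three two-position solenoid valves in
a tree (root selects the positive-pressure branch or the
atmosphere/clean branch; each branch valve selects one source; HIGH and
PATCH share an output). With inactive-branch valves canonicalised to 0,
source → valve state is a bijection, checked exhaustively. The patching
state machine (staged → approaching → sealing → whole_cell | failed)
mandates one channel per phase and rejects illegal jumps.

The cleaning schedule is fixed: five 1 s suction / 1 s expulsion cycles in
the detergent well (starting with suction), a 10 s expulsion there, and a
final 10 s expulsion at the rim of the recording well — 12 steps, 30 s of
active pressure; with realistic movement legs the whole sequence takes
about a minute. Cleaning is simulated concurrently for any set of pipettes
and refuses to touch a pipette holding a cell.

`lasConcentration()` implements the detergent mass balance
$100\,v_{adh}\,f_{alc}\,f_{LAS}/(V_{bath}+v_{adh})$ for the linear
alkylbenzene sulfonate (LAS) carried into the bath on a cleaned tip. With
0.2 µl of 2 % Alconox (20 % LAS) in a 1 ml bath this gives $8\times10^{-5}$
%, far below the 0.001 % interference threshold. Note that inverting the
same formula puts the adherent volume needed to *reach* 0.001 % at ≈2.5 µl,
an order of magnitude below the ≈25 µl sometimes quoted for this safety
margin; the package implements the mass balance and treats the formula,
not the quoted volume, as authoritative.

# The synthetic generator

The generator's defaults are the study conditions: 20 kHz sampling, cells
held near −60 mV (−62 mV default) in current clamp, per-cell stimulation
slots of 4 action potentials at 20 Hz, slots separated by 250 ms of quiet,
30–50 sweeps (40 default), and white Gaussian noise of 0.2 mV SD
(current clamp) or 5 pA (voltage clamp) low-passed at 6 kHz.

**Action potentials** are a parametric piecewise waveform chosen so every
ground truth is analytic: a linear stimulus ramp (5 mV/ms default) from
holding to a take-off voltage, a slope-continuous exponential rise
(τ ≈ 0.15 ms) to the peak, an exponential repolarisation into an
afterhyperpolarisation, and a slow recovery. The 10 mV/ms threshold
crossing, peak time and half-width all have closed forms, which is what
lets the feature-extraction tests demand agreement within one sampling
interval rather than "looks right".

**PSPs** are difference-of-exponentials kernels
$N(e^{-t/\tau_d}-e^{-t/\tau_r})$, unit peak, default 2 ms rise / 20 ms
decay, with analytic peak time
$\ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d-\tau_r)$. Connectivity is a
directed Erdős–Rényi draw; unitary amplitudes are log-normal (mean 0.5 mV,
SD 0.2 mV, floored at 0.2 mV) and latencies normal (1.5 ± 0.3 ms,
truncated to the monosynaptic 0.8–4 ms band) — conventional cortical
values, configurable, not claims about any particular tissue. Trial
variability is a multiplicative log-normal scale of unit mean
(CV 0.3 default); release failures exist as an option but are off by
default.

**The noise model is the one deliberate liberty.** The 6 kHz low-pass is
applied to the additive noise component only, single-pass (zero phase is
irrelevant for stationary noise), with each column renormalised so the
delivered noise SD equals the requested one. Filtering the composite
signal would slightly distort AP slopes and PSP peaks and destroy the
analytic ground truths; filtering only the noise keeps them exact while
preserving the spectral character of the recording. Consequences: the
synthetic APs are sharper than hardware-filtered ones, and the tests'
one-sample tolerances are honest only under this convention.

Reproducibility: one root seed, with per-component child streams derived
from (seed, label) hashes, so a cluster, a test pulse and a spontaneous
trace drawn from the same root seed are independently reproducible. Same
seed → bit-identical output. The noise synthesis runs in a small C++
kernel (Box–Muller on R's uniform stream, then the Butterworth recursion);
this is purely a speed matter and changes nothing statistical.

# Feature extraction

Definitions follow standard practice for this preparation: resting
potential is the mean over the first 100 ms; access resistance
$R_a = \Delta V/(I_{peak}-I_{base})$ from the capacitive peak of a
200 ms / 10 mV voltage-clamp step (peak searched in the first 10 ms —
window invented, configurable), and input resistance
$R_{in} = \Delta V/(I_{ss}-I_{base}) - R_a$ from the steady state (last
20 % of the pulse), series-resistance-corrected by default with the
uncorrected variant selectable. On noiseless synthetic pulses across
$R_a \in [5,30]$ MΩ, $R_{in} \in [50,300]$ MΩ, $C_m \in [50,200]$ pF the
recovery errors stay within 5 % ($R_a$, limited by sampling the capacitive
transient) and 2 % ($R_{in}$).

Spike detection takes local maxima above 0 mV preceded within 1 ms by
dV/dt ≥ 20 mV/ms, 2 ms refractory. The AP threshold is the voltage where
dV/dt (central differences, no extra smoothing) first exceeds the baseline
slope by 10 mV/ms, located by searching backward from the peak; for a held
cell the baseline slope is ~0 and the criterion reduces to a plain
10 mV/ms rule (both behaviours selectable). Amplitude is peak minus
threshold by definition; half-width is the time above threshold plus half
the amplitude, with sub-sample interpolation. Analysis convention: feature
tables are built from the second spike at the rheobase stimulus.

The stimulation-adjustment rule scans 0.5–4 nA in 0.5 nA steps at 1 ms,
escalating duration (1 → 2 → 3 ms, an explicit package choice) only when
nothing spikes, and selects the *second-lowest* spiking amplitude — read
as lowest spiking amplitude plus one step, capped at 4 nA; on a complete
grid scan the two readings of "second lowest" coincide.

QC excludes cells with resting potential *more positive than* −60 mV
(−60.0 itself passes) or access resistance not *below* 40 MΩ (40.0 fails);
the boundary semantics are verbatim readings of the conventions above and
are asserted in tests.

# Event detection and connection calling

**Spontaneous EPSPs** are found by the Clements–Bekkers template-scaling
method: at every offset the template is fitted by closed-form least
squares over scale and offset, and the detection criterion is the fitted
scale divided by $\sqrt{SSE/(N-1)}$. The sliding fit is computed with
rolling sums and equals a per-offset OLS oracle to $10^{-9}$ everywhere.
Criterion threshold 4 and a 5 ms refractory are the conventional defaults;
perfect fits are capped at a sentinel of $10^6$ and vanishing-scale flat
windows are forced to criterion 0. Two implementation points matter in
practice and are package decisions: events are reported one per contiguous
supra-threshold segment (at the criterion maximum) rather than at every
local maximum, which removes duplicate calls on the broad criterion ridge;
and the default template spans only rise + 0.65·decay (~15 ms at 2/20 ms),
because longer templates let a neighbouring event inside the window
corrupt the fit — measured recall at a 5 Hz event rate drops from ≈0.98 to
≈0.91 when the span doubles.

**Evoked connections** are called on sweep-averaged traces. The amplitude
is the extremum of the baseline-subtracted average in a 0.5–15 ms window
after the *first* presynaptic spike (later pulses of the 20 Hz train are
reported as paired-pulse information only, to keep short-term plasticity
out of the binary call); the baseline is the 50 ms before the slot. Before
measurement the average is lightly smoothed (0.75 ms boxcar) so the
extremum is not a single-sample noise excursion. A pair is connected when
the amplitude reaches $k_{sd}$ baseline SDs *and* the 10 %-rise latency
falls in the monosynaptic 0.5–5 ms gate. All thresholds are reported per
call for audit.

The default $k_{sd}=3$ is a single-pair convention. For screening it is
too permissive, and this deserves emphasis: the *extremum* of ~300
correlated noise samples in the response window routinely reaches 3–4
baseline SDs, and across the 56 ordered pairs of an 8-cell cluster some
pair will essentially always exceed it. For exact-recovery screening the
package therefore recommends (and its tests use) $k_{sd}=10$, chosen by a
separation argument made before the recovery suite was frozen: extreme
-value bounds put the noise-extremum ceiling near 7 smoothed-baseline SDs
per cluster, while unitary amplitudes at or above five times the
averaged-trace noise SD sit at ≥24 — so 10 sits between the two with at
least a factor-two margin on each side. On 100 independent 8-cell,
40-sweep clusters the called adjacency equals ground truth exactly under
these conditions.

# Statistics

Connection probability is found/tested. The difference of two connection
probabilities gets the simple asymptotic (Wald) interval
$(p_1-p_2)\pm z\sqrt{p_1(1-p_1)/n_1+p_2(1-p_2)/n_2}$ without continuity
correction ($z = 1.6449$ at the 90 % level). Fisher's exact two-sided p
sums hypergeometric probabilities not exceeding the observed table's
(probability-mass ordering — the common convention; the doubled one-sided
variant is a documented alternative); the implementation builds on the
base hypergeometric density and is verified against an independent
implementation for every table with margins up to 15.

Equivalence reporting follows the TOST/CI duality: parameters are
summarised as relative differences $100(\text{after}-\text{before})/
\text{before}$ (paired; the group-mean ratio with a delta-method SE when
unpaired), with a t-based 90 % confidence interval; equivalence at
$\alpha = 0.05$ is declared when that interval lies inside ±20 %
(cellular and AP properties) or ±25 % (spontaneous EPSP properties). The
interval's empirical coverage is verified by simulation (≥88 % observed at
the 90 % nominal level over 1000 replicates). Rank comparisons dispatch to
Mann–Whitney / Wilcoxon signed-rank, exact for tie-free samples up to
n = 10 and normal-approximated beyond; repeated-measures ANOVA is
delegated to the standard routine behind a thin wrapper.

# Numerical and engineering choices

* Pressure levels, the valve routing table and the schedule are
  configuration, not constants baked into logic; 1 bar is encoded as
  +1000 mbar.
* The simulation clock is discrete-event in float seconds; movement legs
  are straight lines at constant speed.
* The sweep container is a documented plain-text directory layout
  (JSON manifest/protocol/ground-truth plus one CSV per sweep) written
  with 17 significant digits so samples round-trip bit-exactly; the
  manifest version is checked on read and truncated or missing sweep
  groups are reported by name.
* Tie-breaks: target sectors by pipette id; events left-to-right under the
  refractory rule; the capped criterion ties resolve to the earliest
  offset.
* Degenerate inputs have defined behaviour rather than NaNs: collinear
  registration points, pure-resistor test pulses ($R_{in}=\infty$,
  flagged), steady states below baseline (non-physical, flagged), flat
  averages (SNR 0), zero event rates, empty results.

## Problem sizes in the test suite

The suite regenerates everything from code: 100 registration fits, a
4×4×4 passive-property grid, 100 AP-feature cells, full-trace OLS-oracle
comparison on a 3000-sample trace, two seeded 2 s spontaneous traces with
ten events each, 100 independent 8-cell/40-sweep clusters for adjacency
recovery, the exhaustive Fisher enumeration to margins of 15, and a
1000-replicate coverage simulation. These sizes are the package's chosen
balance between statistical force and a test suite that runs in minutes.

# Limitations

* Neurons are waveform generators, not conductance-based models; there are
  no network dynamics beyond feedforward unitary PSPs, no IPSP biology
  beyond a sign, no short-term-plasticity model.
* Passing the synthetic recovery tests shows the pipeline is correct under
  the generator's assumptions (stationary Gaussian noise, stereotyped
  kinetics, no electrode drift, no polysynaptic contamination beyond the
  latency surrogate). Real recordings violate several of these; detection
  thresholds that are provably safe here still require the usual manual
  curation on real data.
* The rig model has no machine vision, no motor kinematics or backlash,
  no pneumatic transients, and only tip-point collision checking.
* No liquid-junction-potential correction is applied anywhere, and no
  multiple-testing correction policy is imposed on the statistics module.
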
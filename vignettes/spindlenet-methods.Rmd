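---
title: "Modeling core and matrix thalamocortical spindle generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling core and matrix thalamocortical spindle generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Sleep spindles are waxing-and-waning 11--15 Hz field-potential bursts of
0.5--3 s that recur every 5--15 s during NREM sleep.  In humans they look
different depending on the recording instrument: MEG spindles are
frequent and weakly synchronized across sensors, EEG spindles rarer and
globally synchronous.  A long-standing hypothesis attributes the
difference to the two anatomical thalamocortical systems: the **core**
pathway (focal thalamic projections to middle layers, corticothalamic
return from layer 6; MEG-weighted) and the **matrix** pathway (broad,
weak projections to the apical dendrites of layer-5 cells, reciprocal
with layer 5; EEG-weighted).

`spindlenet` implements a conductance-based network model that makes
this hypothesis testable mechanistically: two thalamic TC--RE
oscillators that share no synapses with each other, wired to a
three-layer cortex, differing *only* in the fanout of their
thalamocortical and corticothalamic projections (the matrix radii are
`fanout_ratio` times the core radii, 10 at baseline) and in the
per-synapse weights that follow from input-count normalization.
Spindles are not injected: they arise stochastically from miniature
EPSP noise in the cortex, propagate to the thalamus, reverberate in the
TC--RE loop, and terminate through Ca2+-dependent up-regulation of the
h-current.

## Cell models

Every cell obeys `Cm dV/dt = -g_leak (V - E_leak) - I_int - I_syn`.

* **TC** (one compartment): fast Na+/K+ spike currents, low-threshold
  Ca2+ current I_T (relay kinetics, m^2 h), K+ leak (E_KL = -95 mV),
  and the hyperpolarization-activated cation current I_h with a
  Ca2+-regulated second open state.  I_h both paces the rebound rhythm
  and, as intracellular Ca2+ accumulates over a spindle, locks into a
  higher-conductance state that depolarizes the cell out of the burst
  regime -- the waxing/waning and refractory mechanism.
* **RE** (one compartment): Na+/K+, reticular I_T, leak and K+ leak.
* **PY / IN** (two compartments): a dendrite carrying leak, K+ leak,
  Na+, persistent Na+ (PY only), high-threshold Ca2+, Ca2+-activated
  K+, slow non-inactivating K+, and all synaptic input; and an
  axosomatic compartment dominated by very large spike conductances
  (g_Na = 3000, g_K = 200 mS/cm2).  The axosomatic membrane is treated
  as having negligible capacitance, so its voltage is solved
  algebraically from the instantaneous balance of its currents with
  the axial current (coupling resistance 10 MOhm); this is what makes
  the stiff soma integrable at a usable time step.  The dendrite/soma
  area ratio sets the firing phenotype: R = 165 yields regular
  spiking with adaptation (PY), R = 50 fast spiking (IN).

### Rate functions and adopted constants

The parameter tables fix the maximal conductances but the rate
functions come from the antecedent model family.  They are implemented
once, in `src/kinetics.h`, and are the standard forms: Traub-type
thalamic spike kinetics, relay and reticular I_T with Q10 corrections
to 36 C, the kinetic I_h model with four-Ca2+ binding, and
the standard two-compartment cortical channel set (Q10 = 2.3 from
23 C).
Four calibrations deserve explicit mention because they were genuinely
open and were fixed by single-cell and small-circuit behavior (never by
a statistics-level test outcome):

* **Cortical Na+ shift (+10 mV).**  With a zero-capacitance soma the
  unshifted Na+ window current makes rest unstable (slow depolarization
  into block).  Shifting activation/inactivation +10 mV restores a
  stable rest at about -70 mV and a spike threshold near -50 mV.
* **Persistent Na+ amplitude (0.02).**  With a full-amplitude sigmoid
  the 0.07 mS/cm2 dendritic I_Na(p) sustains a permanent depolarized
  plateau; the family's 0.02 activation amplitude removes it.
* **KCa gate quadratic in [Ca2+] (in uM).**  Linear-in-mM rates leave
  the slow AHP inert at physiological Ca2+; the quadratic uM form is
  silent at rest and terminates plateaus during activity.
* **Thalamic spike-threshold shifts** `vtraub` = -60 (TC) / -63 (RE).
  The RE value is the single most consequential number in the model:
  a few mV lower and reticular cells burst to *any* single cortical
  EPSP, so the thalamus oscillates continuously; a few mV higher and
  spindles never ignite.  At -63, reticular bursts require coincident
  cortical input, which is exactly the stochastic-initiation regime.

Two printed values needed adjudication.  The RE leak conductance
appears both as 0.05 and 0.005 mS/cm2; the package defaults to 0.05
because at 0.005 the RE membrane (tau about 59 ms) cannot repolarize
fast enough for its T current to de-inactivate between spindle cycles
and the oscillation dies after one volley.  The interlaminar NMDA
total appears as 0.75 uS/cm2, 12.5 times the intralaminar value,
although the interlaminar AMPA is exactly half the intralaminar one;
the default takes half (0.03) and the printed value remains selectable
(`interlaminar_nmda = "printed"`).

### Calcium

Each Ca2+-carrying compartment has a 1-um shell pool driven by its
Ca2+ current with first-order extrusion.  TC cells use a fast
clearance (tau_ca = 20 ms, configurable) so that the Ca2+ signal seen
by the I_h regulator integrates over a whole spindle epoch; with the
slower ~165 ms clearance used elsewhere the I_h lock engages within
two cycles and epochs collapse to ~0.3 s.  Cortical dendrites and RE
cells use 165 ms.

## Synapses

AMPA, NMDA and GABA-A use first-order transmitter-pulse kinetics
(0.5 mM for 0.3 ms per spike); NMDA is gated by
`1/(1 + exp(-(V+25)/12.5))`; GABA-B is a receptor -> G-protein cascade
with K+-channel activation `G^4/(G^4 + 100)`, slow (peak > 50 ms after
a spike) and selective for bursts.  Short-term depression
(`D = 1 - (1 - D_i(1-U)) exp(-(t-t_i)/tau)`, U = 0.2, tau = 500 ms)
applies to intracortical excitatory connections only.  Miniature PSPs
arrive as an inhomogeneous Poisson process with rate
`mu = (2/(1+exp(-(t-t0)/400)) - 1)/250` per ms per synapse (t0 = last
presynaptic spike) on every cortical chemical synapse, with amplitude
`mini_scale` (default 0.15) times the evoked per-synapse conductance;
they are the model's only noise source and drive spindle initiation.

In the network core, all synapses converging on a cell through the
same receptor share one aggregated conductance state: open fractions
are piecewise exponential between events, so each presynaptic spike is
applied as a saturating instantaneous increment (exact in the
short-pulse limit).  GABA-B inputs to a cell are lumped into one
cascade driven by the conductance-weighted mean receptor activation.

### Units of the printed conductance totals

Connection strengths are totals per connection type (e.g. PY-PY AMPA
0.6) divided by each target's input count, then mapped to a
conductance density on the target compartment by dividing by its area.
The absolute scale of that mapping is not determined by the printed
units; it is absorbed into one calibration factor
(`syn_unit_scale = 2`), fixed once so that the isolated TC-RE circuit
sustains a multi-cycle oscillation and a cortex-only network stays in
the sparse-firing regime.  All printed *ratios* between connections
are preserved exactly.

## Network geometry

Populations sit on a common normalized 1D axis; a rule with radius `r`
(in source index units) connects a source to every target within
`r / n_source` of its position, truncated at the edges (a source whose
window is empty keeps its single nearest target).  Per-synapse weight
is `g_total / n_inputs(target)` -- so the broad matrix projections are
individually weak -- or, in the reduced one-layer model, a constant
anchored to the baseline geometry (normalization off).  The two
thalamic systems are strictly separated; any rule that couples them is
rejected at build time.

Unprinted radii (intracortical PY-PY 5, PY-IN 1, IN-PY 5,
interlaminar 5, intrathalamic 4) are local footprints standard for the
model family and are arguments of `network_spec()`.  The interneuron
count is 200 per layer (the printed total of 400 across three layers
is arithmetically inconsistent; the per-layer 1:5 IN:PY ratio is
kept and configurable).

### Desk scale

`scale` shrinks every population.  Thalamocortical, corticothalamic
and intrathalamic radii shrink with the axis (preserving the *fraction*
of the network each projection covers -- the quantity the fanout-ratio
experiments vary), while intracortical radii stay absolute so the
local recurrent microcircuit keeps its neighbor counts.  The analyses
in the test-suite and the acceptance script use `scale = 0.1` (100 PY
per layer, 20 TC and RE per system, about 560 cells) and 40--60 s of
model time; these sizes give each simulation a handful-to-tens of
detected events, enough for directional comparisons but far below the
full-scale event counts, which is why all simulation-level checks are
orderings and signs rather than absolute densities.

## Integration

Fixed step (default dt = 0.025 ms; the desk-scale analyses use
0.04 ms, which changes no qualitative behavior).  Gating variables use
exponential (Rush-Larsen) updates with steady states and time
constants linearly interpolated from per-run lookup tables
(0.05 mV grid); membrane voltages use a semi-implicit update that is
exact for the conductance-form right-hand side and unconditionally
stable; the axosomatic voltage is algebraic.  Initial conditions are
the class resting states (found by 5 s relaxation) plus a seeded
+/-2 mV uniform jitter; all stochasticity (jitter, minis) derives from
the single `seed`, so a run is bit-reproducible.  Integration aborts
with the cell and time if any |V| exceeds 150 mV.

## LFP, detection, statistics

The estimated LFP of a layer is the mean dendritic synaptic current
over each group of contiguous cells (10 non-overlapping groups per
layer; inward current deflects the trace negative), sampled at 1 kHz
with bin averaging.  Core LFP comes from layer 3/4 dendrites, matrix
LFP from layer 5.  Detection band-passes 6--15 Hz (zero-phase
forward-backward Butterworth, so onset-delay statistics are unbiased),
takes the Hilbert-envelope modulus, smooths with a Gaussian kernel
(300 ms truncation, 40 ms sigma), marks regions above mean + 2 SD,
expands them to mean + 1 SD, merges sub-100 ms gaps, and gates
durations to 0.5--3 s ("model" mode; "empirical" mode uses 10--16 Hz
and the 2 s ceiling).  Thresholds are computed over the whole analyzed
series, which makes detection exactly invariant to amplitude
rescaling.

Downstream statistics follow the field's conventions: density in
events/min per channel; ISIs center-to-center with a 20 s exclusion;
maximum-likelihood lognormal/exponential fits plus a Lilliefors
normality test; spatial correlation as epoch-restricted Pearson
correlation of band-passed LFP, binned by inter-group distance;
co-occurrence as span intersection between any core and any matrix
channel; onset delays by nearest-onset pairing within 2.5 s (each
matrix event used once), negative = core first; spike phases from the
analytic-signal angle of the 6--15 Hz LFP with the convention
*band-passed peak = phase 0* (add pi to convert to a trough-zero
convention), 100 bins, neurons with fewer than 10 in-spindle spikes
excluded.

## What the synthetic burst generator does and does not emulate

`generate_burst_series()` builds labeled fixtures for the detector:
1/f-amplitude Gaussian background plus tapered-cosine bursts with
frequency U(11, 15) Hz, duration U(0.5, 3) s, exponential or lognormal
inter-burst gaps floored at 2 s (spindles recur every 5--15 s;
abutting bursts would defeat event labeling).  Amplitudes are in SD
units of the background.  It emulates the *statistical envelope* of
spindling -- it contains no thalamocortical dynamics, no spatial
structure and no co-occurrence -- so detector calibrations on it
validate the detection/statistics chain, not the network model.

## Known limitations

* Desk-scale runs compress the ignition-threshold asymmetry between
  core and matrix (input counts of 2--5 instead of 5--41), so absolute
  densities are roughly an order of magnitude below full-scale values
  and single-seed contrasts are noisy.
* The model does not reproduce the slow/fast spindle dichotomy, makes
  no claim about EEG/MEG forward physics, and contains no sleep
  staging or artifact handling.
* Simulated spindle durations at desk scale (~0.5--0.8 s) sit at the
  lower end of the physiological range.
* The oscillation frequency of the desk-scale TC-RE loop (8--10 Hz)
  is at the lower edge of the spindle band; the 6--15 Hz analysis band
  covers it.
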
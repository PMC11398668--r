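---
title: "Model and methods: a two-area spiking network for working-memory delay activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wmnet)
```

# The scientific problem

During a delayed match-to-sample task, neurons in association cortex (e.g.
prefrontal areas) keep firing through the memory delay while sensory areas
fall silent after the cue. `wmnet` implements a two-area spiking network
that reproduces this dissociation and then asks a structural question: *which
features of the local recurrent wiring decide how long delay activity
survives?* The package therefore has two halves — a conductance-based
simulator, and a graph-analysis/regression suite that relates wiring
statistics of the association area to the measured duration of its delay
activity.

# The neuron

Both cell classes are single-compartment Hodgkin-Huxley neurons,

$$C_m \dot V = -g_K n^4 (V - E_K) - g_{Na} m^3 h (V - E_{Na})
  - g_L (V - E_L) + I_{syn},$$

with $g_K = 4.74$, $g_{Na} = 12.5$, $g_L = 0.025$ uS, $E_K = -80$,
$E_{Na} = 40$, $E_L = -65$ mV, and the gate kinetics
$\dot y = \alpha_y(V)(1-y) - \beta_y(V) y$ for $y \in \{n, m, h\}$ with the
rate functions exposed by `hh_rate_constants()`. The two `alpha` rates have
removable singularities (at $-20$ and $-16$ mV) and are evaluated by their
analytic limits there. Pyramidal cells have $C_m = 0.5$ nF, interneurons
$0.25$ nF; all other parameters are shared.

This neuron is class-2: its f-I curve is discontinuous, with firing onset
at about 12 Hz, a pyramidal rheobase of 0.7 nA, and 52.7 Hz at 2 nA
(`fi_curve()`, `rheobase()`). The interneuron, with half the capacitance
but otherwise identical channels, starts repetitive firing at 0.63 nA: a
faster membrane moves the onset of the spiking limit cycle, so the
published statement that both classes threshold at 0.7 nA is not
consistent with the printed equations and the package reports what the
equations give. Class-2 excitability matters for the model's logic:
sub-threshold background fluctuations produce essentially no baseline
spiking, so delay activity is unambiguously attributable to recurrent
drive.

Integration is fixed-step RK4. The step defaults to `dt = 0.02` ms; halving
it changes the spike count of a 1 s suprathreshold trial by at most one
spike. A spike is an upward crossing of 0 mV, with a 2 ms minimum interval
for both counting and synaptic transmission. Inside the network integrator
the six rate functions and the magnesium-block factor are evaluated from a
piecewise-linear table on a 0.02 mV grid; the interpolation error is orders
of magnitude below the integration error (the single-neuron functions use
the exact expressions).

# Synapses

Recurrent excitatory synapses carry AMPA ($\tau = 2$ ms) and NMDA
($\tau_{rise} = 2$ ms, $\tau_{decay} = 100$ ms, saturating activation
$\alpha x (1 - s)$) components; inhibitory synapses are GABAergic
($\tau = 10$ ms); cross-area synapses are AMPA only, with conductance
$g_{AMPA,ext} = 0.22$ uS. NMDA current is attenuated by the standard
magnesium block $B(V) = 1/(1 + [Mg] e^{-0.062V}/3.57)$ at 1 mM. Reference
conductances are $g_{AMPA} = 0.11$, $g_{NMDA} = 0.13$, $g_{GABA} = 0.47$ uS.
The currents of the form $g\,(V - E)\,s$ enter the membrane equation
depolarizing-positive (EPSCs depolarize, the GABA term hyperpolarizes),
matching the behaviour of the model family this circuit descends from.

## Calibration constants

The gating equations specify kinetics but not per-spike increments, and
three increments cannot be taken literally as unit jumps without making
unitary synaptic currents three orders of magnitude too strong. They are
fixed once, as follows, and never varied afterwards:

* `w_spike = 0.00993` and `alpha_nmda = 2.0971` /ms are jointly pinned by
  the unitary recurrent EPSC: one presynaptic spike onto a neuron clamped at
  $-65$ mV must produce an AMPA peak of 71 pA and an NMDA peak of 19 pA
  (ratio 26.6%) at the reference conductances (`unitary_epsc()`). The AMPA
  peak fixes `w_spike` in closed form; the NMDA peak then fixes
  `alpha_nmda` by root-finding on the gating ODEs.
* `w_ext = 0.05` is the increment of the cross-area channel. No unitary
  measurement constrains it; it is set by two functional requirements of
  the task: the 500 ms cue must reliably ignite the association area
  through the feedforward pathway, and feedback from a persistently active
  association area must leave the sensory area sub-threshold during the
  delay. With the EPSC-calibrated `w_spike` used for this channel the
  feedforward drive saturates near 0.65 nA — just below the 0.7 nA
  rheobase — and the association area can never ignite, so a separate
  increment is not optional: the published unitary amplitudes and the
  published network behaviour are inconsistent under a single shared
  increment.
* `w_gaba = 0.05` is the GABA increment. No unitary IPSC amplitude is
  available; a literal unit jump would produce ~7 nA unitary IPSCs that
  silence the network at every conductance of interest. It is calibrated so
  that, on a reference topology at the standard network size, the NMDA
  conductance sweep lands in the published regimes: silent delay activity
  at $g_{NMDA} = 0.05$, a transient tail at $0.13$, persistent activity at
  $0.15$ uS.

# Network architecture

Each area has $N_E = 80$ pyramidal cells and $N_I = 20$ interneurons.
Connectivity is receiver-driven and binary (`build_intra()`,
`build_inter()`): a pyramidal cell receives each possible afferent
independently with probability 5% (sensory) or 20% (association); an
interneuron with probability 20% within either area. Feedforward
projections (sensory to association) arise only from pyramidal cells and
target only pyramidal cells, received at 20%; feedback projections
(association to sensory) arise from pyramidal cells and target both
populations at 5%. No autapses. Adjacency is stored as
$\varepsilon_{ij} = 1$ iff $j$ is presynaptic to $i$.

Every neuron additionally receives an independent Poisson background train
(2300 Hz, increment 0.005) on its external-AMPA gating variable — the
literal reading of the gating equation, in which the noise term appears
once per neuron. Attaching background noise to every presynaptic recurrent
gating variable instead would multiply the background current by the
in-degree and destroy the silent baseline, so that reading is rejected.

# Trial protocol and the duration readout

A trial is 500 ms pre-cue, 500 ms cue (2 nA into all sensory pyramidal
cells; 2 nA is the supra-threshold intensity whose single-neuron response
is 52.7 Hz), 4000 ms delay, and a 500 ms match phase with the same current;
300 ms after match onset the association interneurons receive an equal
current until trial end, standing in for reward/behavioural-response input.
The network is first settled for 200 ms from the resting equilibrium with
all gating at zero; settling spikes are discarded.

The working-memory duration of a trial is the time from cue removal to the
last spike of the association pyramidal population within the delay
(`wm_duration()`), zero if there is none, and capped (censored) at the
delay length when a spike falls within the final 50 ms. Durations below
200 ms are classified `silent`, censored trials `persistent`, the rest
`transient` (`classify_state()`). The monitored population, censoring
window and threshold are all arguments. Censored durations enter
correlation and regression analyses at the cap value.

# Structural metrics

All metrics run on the association area's recurrent matrix
(`feature_vector()` assembles the 17-variable summary):

* the four E/I block edge counts and the balance factor
  $F_{E/I} = (d_{E \to E} + d_{I \to I})/(d_{E \to I} + d_{I \to E})$;
* the excitatory-input fraction $P_i$ per node, hub proportions (strictly
  $P_i > 0.8$) per class, and their ratio (rich-hub factor). Scoring
  interneuron hubs by the same excitatory-input fraction is the printed
  definition; `hub_measures()` also exposes the alternative reading
  (interneurons scored by inhibitory-input fraction, $1 - P_i$);
* directed 3-cycle counts (trace$(M^3)/3$) for the excitatory subnetwork
  and the inhibitory-involved complement (entire minus excitatory), and
  their ratio; 4-cycle counts are available for the cycle-size correlation
  analysis, with degenerate closed walks removed in closed form;
* clustering coefficient and mean shortest path length on the entire
  network and the excitatory subnetwork, and the excitatory/entire ratios.
  The printed local-clustering denominator $k_i - (k_i - 1)$ is an evident
  typo for $k_i(k_i-1)$ and the standard form is used; clustering is
  computed on the undirected projection; path lengths average over
  reachable ordered pairs with the unreachable count reported. Zero
  denominators (balance factor, rich-hub, cycle ratio) propagate as `NA`
  and are median-imputed (with a count) by the regression layer.

The triad census (`motif_census()`) classifies every weakly connected
triple into the 13 connected 3-node digraph classes. Class numbering is by
edge count (three 2-edge, four 3-edge, four 4-edge, one 5-edge, one
6-edge), with the cyclic classes at positions 7 (directed 3-cycle) and 10
(reciprocal pair closed through the third node); position 6 is the
feedforward loop. The exact within-group order is this package's
documented convention (the source numbering is not printed); analyses are
class-wise, so any fixed order carries the same information. The
excitatory census runs on the E-induced subgraph and the
inhibitory-involved census is the class-wise difference — exactly "motifs
that involve at least one interneuron".

# Statistical layer

Structure-duration association uses Spearman rank correlation
(`spearman_rho()`). Feature attribution uses ridge regression of
$\ln(\mathrm{duration} + 1\,\mathrm{ms})$ on the z-scored features with the
intercept unpenalized (`ridge_fit()`, closed form), because the 17
variables are strongly collinear; coefficient magnitudes on the
standardized scale rank feature importance (`importance_ranking()`).
Standardization is required for that comparison to make sense, which is why
it is built in. The penalty weight comes from seeded 5-fold
cross-validation over a logarithmic grid $10^{-3}..10^3$ (`cv_lambda()`),
with standardization re-estimated inside each training fold.

The bimodality test used for the duration-distribution dichotomy is the
dip statistic (`dip_stat()`), computed from the band characterization of
the nearest unimodal distribution function: for each candidate mode
position the smallest feasible sup-norm distance reduces to chord
conditions over triples of support points (convex side below the mode,
concave side above, an atom permitted at the mode), and the dip is the
minimum over mode positions. No pre-installed implementation of this
statistic exists in the environment, so it is implemented here and verified
in the test suite against exact anchors (two points give 0.25, equispaced
samples give $1/(2n)$) and an independent convex-hull feasibility oracle.
P-values are Monte-Carlo calibrated against uniform null samples of the
same size (`dip_test()`), the conventional least-favourable unimodal null.

# Anatomy-constrained predictions

`region_table()` ships the 24-area table of layer-2/3 basal-dendrite spine
counts with per-area counts of positive and negative published evidence of
delay activity, verbatim from its printed source — including its printed
lobe assignments (TEO listed under Occipital, area 5 under Prefrontal),
which are reproduced without correction. `spine_to_probability()` maps
spine counts linearly onto association-area pyramidal reception
probabilities in [0.15, 0.25]; only the association area's intra-area
pyramidal reception probability varies across regions, because the spine
gradient is a statement about pyramidal-cell inputs in the higher area.
`predict_regions()` simulates each region's network repeatedly with fresh
topology and noise seeds; `concordance_table()` compares median durations
against a persistence threshold (default half the delay; configurable, and
worth sweeping) with the sign of the evidence balance.

# Scaled-down study conditions

The reference ensembles behind the structure-function results are large
(hundreds to a thousand networks at 100 neurons per area with 4 s delays).
The packaged experiments preserve the design at desk scale, and the test
suite uses reduced conditions:

* **mini** (`make_fixture("mini")`): 20E/5I per area, phases
  50/100/500/100 ms, recurrent and cross-area conductances scaled by 4
  (the population ratio), preserving expected recurrent drive per neuron.
  Used for fast plumbing and reproducibility tests. With only five
  interneurons per area its inhibition is too sparse for the regime
  analyses — a known property, not a target of this fixture.
* **small** (the ensemble condition in the tests): 40E/10I per area,
  conductance scale 2, delay 3000 ms, `dt = 0.05` ms. The delay is kept
  long against the roughly one-second transients of the reference
  topology so that the duration distribution can resolve its modes, and
  the taxonomy medians at `dt = 0.05` agree with `dt = 0.02` within
  seed-to-seed variability. Reduced networks have larger relative
  fluctuations, so their transient-to-persistent transitions sit at
  somewhat lower conductance and connection probability than the
  full-size network; ensemble analyses on this condition are therefore
  read as sign/order statements (correlation directions, regime
  ordering), not as absolute thresholds.
* **anatomy** (the per-region condition in the tests): 60E/15I per area,
  conductance scale 4/3, delay 3000 ms. The per-region claim depends on
  where the persistence transition sits along the connection-probability
  axis, which the 40E condition compresses below the frontal-eye-field
  probability (0.183); at 60E the full-size pattern (occipital negative,
  frontal eye fields negative, dorsolateral prefrontal positive at the
  half-delay threshold) is preserved.

What passing at these scales does and does not show: the scaled ensembles
demonstrate the qualitative structure-function claims (sign patterns,
bimodality dichotomy, monotone conductance dependence) and the pipeline's
correctness; they do not reproduce published effect sizes at the published
ensemble sizes, and none of the synthetic conditions models features of
real cortex that the generator omits (distance-dependent connectivity,
synaptic weights and plasticity, conduction delays, structured stimuli).

# Numerical and design choices

* Gating sums per receiver are tracked event-driven for the linear
  channels (exact exponential decay between spikes); NMDA saturation is
  per presynaptic cell, Euler-integrated at `dt` and summed per receiver
  each step. Within an RK4 step the synaptic conductances are frozen while
  driving forces and the Mg block follow the substep voltage.
* Gating variables are clipped to their invariant ranges after each step;
  NMDA gating cannot exceed 1 by construction of the saturating term.
* The duration population, silent threshold, censor window, hub threshold
  and persistence threshold are arguments with the documented defaults.
* Undefined metric values are `NA` signals, never silent zeros.
* All randomness flows through R's RNG: a topology seed fixes the wiring,
  a noise seed fixes the background; the pair reproduces a trial
  bit-for-bit (`write_manifest()` records both).

# Known limitations

* The per-spike increments `w_ext` and `w_gaba` are calibrated to
  published network behaviour rather than measured unitary currents (none
  are available); other (`w_ext`, `w_gaba`) pairs satisfying the same
  functional constraints would shift regime boundaries quantitatively.
* Reduced-size ensembles shift transition locations (see above); claims
  that depend on absolute probability thresholds (the per-region
  predictions) are correspondingly noisier at desk scale.
* The model omits synaptic plasticity, multiple memoranda, distractors,
  and oscillatory readouts; the duration of delay-period spiking is the
  only behavioural readout.
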
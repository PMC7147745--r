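---
title: "Methods: sequence learning, rapid replay and distractor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence learning, rapid replay and distractor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`seqreplay` simulates a cortex-like recurrent reservoir in the SORN
(self-organizing recurrent network) family: 200 excitatory and 40
inhibitory conductance-based leaky integrate-and-fire neurons with an
adaptive intrinsic firing threshold, sparse random connectivity
(p = 0.2 per potential edge; no E→E self-connections, no I→I
connections), and three plasticity mechanisms restricted to the
excitatory recurrent synapses: nearest-neighbour spike timing-dependent
plasticity (STDP), synaptic normalization of each neuron's incoming
excitatory weight vector to a fixed total, and the adaptive threshold
(intrinsic plasticity, IP) on every neuron.

Membrane dynamics, per neuron $j$:

$$\frac{dv_j}{dt} = \frac{g_\text{leak}(v_\text{rest}-v_j) + I_\text{syn} + I_\text{ext}}{c_\text{membrane}} + \text{noise},\qquad
I_\text{syn} = g_\text{ampa}(e_\text{ampa}-v_j) + g_\text{gaba}(e_\text{gaba}-v_j)$$

Conductances decay exponentially ($\tau_\text{ampa}=2$ ms,
$\tau_\text{gaba}=5$ ms) and jump by the synaptic weight $w_{ij}$ (nS)
whenever presynaptic neuron $i$ spikes. When $v_j$ crosses its threshold
the neuron emits a spike, resets to $v_\text{rest}$, enters an absolute
refractory period (10 ms excitatory, 2 ms inhibitory), and its threshold
is incremented by $\eta^\text{ip}_\text{spike}=0.066$ mV; between spikes
the threshold decays at $\eta^\text{ip}_\text{decay}=0.2$ mV/s. The
balance of the two IP constants fixes each neuron's long-run firing rate
at $\eta_\text{decay}/\eta_\text{spike}\approx 3$ Hz, which is the
network's spontaneous operating point.

STDP uses the standard exponential kernel
($A_\pm = 0.05$ nS, $\tau_\pm = 20$ ms) under a nearest-neighbour
pairing: each spike is paired only with the partner neuron's most recent
spike; simultaneous spikes contribute nothing. Depression subtracts from
the weight, weights are clipped at zero, and after every STDP-induced
change the postsynaptic neuron's incoming E→E vector is rescaled to
$W_\text{total} = 20$ nS (which preserves zeros and proportions). All
defaults reproduce the published shared parameter table exactly; see
`neuron_params()`.

# The virtual experiment

`run_trial()` executes four phases on one network, state carried
throughout:

1. **Warm-up, 50 s.** No input; voltages, conductances and thresholds
   converge to the homeostatic equilibrium (~3 Hz asynchronous firing).
2. **Training, 50 blocks of 1 s.** The excitatory population is
   partitioned into ten non-overlapping groups of 20; groups A–E are each
   driven for 100 ms in order at 50 Hz through 20 nS feedforward
   synapses, followed by 500 ms rest. Plasticity is active only here.
3. **Relaxation, 50 s.** Inputs and synaptic plasticity off; IP remains
   on and thresholds re-equilibrate (they are deliberately not reset).
4. **Testing.** Every 500 ms a synchronous one-spike 20 nS burst (the
   recall cue) hits group A and triggers a millisecond-scale replay
   A→B→C→D→E. In the experimental sub-phase a second burst (the
   distractor) hits group A, C, E or the untrained sixth group F,
   0–3 ms after each cue; the control sub-phase has cues only.

# Evaluation pipeline

For each trained group the spikes are pooled and smoothed with a 2 ms
Gaussian kernel (`population_rate()`); the trace is expressed as mean
rate per neuron (Hz). In a [−10, +25] ms window around each cue,
`detect_peaks()` returns the time of the maximum rate above 10 Hz; a cue
*passes the veto* iff all five elements have such a peak. Veto-passing
control replays define per-element peak-time means $\mu_n$ and spreads
$\sigma_n$ (standard deviations, floored at 0.1 ms), plus adjacent-pair
interval statistics. Two per-replay indices follow:

* **deviance** — mean of $(t_n - \mu_n)/\sigma_n$ over the five
  elements: overall early (negative) or late (positive) replay;
* **disruption** — mean of
  $\big[(t_{n+1}-t_n) - (\mu_{n+1}-\mu_n)\big]/\sigma_{(n+1)-n}$ over the
  four adjacent pairs: deformation of the replay's internal structure,
  invariant to a uniform time shift. Order inversions contribute large
  negative terms.

A condition is classified *relevant* when its mean disruption index over
passing cues falls below −0.05, *irrelevant* otherwise
(`classify_distractor()`). `classify_weights()` partitions the
above-zero E→E weights into the eight standard categories
(within-cluster, one/n forward, one/n backward, to/from external) and
summarizes bimodal categories by per-mode medians split at 1 nS.

# Numerical and design choices

* **Integration.** Forward Euler for the voltage at dt = 0.1 ms;
  conductance decay and the noise process use exact exponential updates.
  The fastest timescale is $\tau_\text{ampa} = 2$ ms, so halving dt
  moves a 100 ms noise-free trajectory by well under 0.05 mV (tested).
* **Membrane noise.** The published noise is an Ornstein–Uhlenbeck
  generator with $\sigma_\text{noise} = 1$ mV; neither its correlation
  time nor the exact scaling of its drive term is printed unambiguously.
  We use correlation time $\tau_\text{membrane} = 20$ ms and calibrate
  the drive coefficient so the leak-filtered stationary membrane
  fluctuation has standard deviation exactly $\sigma_\text{noise}$. This
  is the reading under which the stated 1 mV is a membrane-voltage
  magnitude; the alternative literal scaling by $1/\tau_\text{membrane}$
  yields 0.41 mV of voltage noise, which collapses the homeostatic
  threshold gap to ~1 mV and degenerates the replay into a
  near-synchronous wave.
* **Threshold floor.** The threshold decay is unbounded in the stated
  equations; we bound it at −80 mV purely as a numerical guard. The
  floor sits below the reversal potential of inhibition and never binds
  in practice: a floor inside the operating range (e.g. −60 mV) would
  silence the network and disable the IP equilibrium that the warm-up
  and relaxation phases exist to reach.
* **Initial conditions.** "Random values within the standard operating
  range" is realized as $v \sim U(v_\text{rest}, v_\text{rest}+15)$ mV
  and thresholds $U(v_\text{rest}, v_\text{rest}+5)$ mV. Thresholds
  start *below* the operating point because IP converges quickly from
  below (+0.066 mV per spike) but only at 0.2 mV/s from above; starting
  thresholds 15 mV high would not converge within the 50 s warm-up.
* **Training drive.** Each group's 50 Hz Poisson source is shared:
  every source spike reaches all 20 group members simultaneously, with
  membrane noise jittering their firing order. This realization (rather
  than independent per-neuron sources, also available via
  `compile_events(shared = FALSE)`) is what reproduces the published
  connectivity signature: near-coincident within-group spiking makes
  STDP's potentiation/depression a fair coin per pairing, so the
  within-cluster weights random-walk into a bimodal strong/pruned
  structure, while the fixed epoch order accumulates potentiation in the
  one-forward category and prunes one-backward to near zero.
* **Cue and distractor bursts.** One source spike through a 20 nS
  synapse to every neuron of the target group (count configurable);
  distractors are identical to cues apart from target and delay.
* **Rate normalization.** The 10 Hz veto threshold is applied to the
  group trace divided by the group size. Against the pooled 20-neuron
  sum the threshold would be vacuous: spontaneous background alone
  (20 × ~3 Hz) would exceed it everywhere. Per neuron, 10 Hz sits just
  above the bump of a single stray spike, so the veto separates genuine
  population events from background.
* **Spread floor and ties.** Control spreads are floored at 0.1 ms (the
  simulation step), and peak ties resolve to the earliest time.
* **Inhibitory neurons** share the adaptive threshold (the stated
  equations exempt nobody); a config switch (`ip_inhibitory`) exposes
  the alternative.

# What the generator emulates, and what a green test establishes

All inputs are synthetic by design — the experiment *is* the stimulus
protocol above, and `build_training_schedule()` /
`build_test_schedule()` reproduce it exactly (epoch layout, rates,
counts, delays). What the model does not emulate: synaptic transmission
delays, dendritic structure, short-term plasticity, inhibitory
plasticity, overlapping group membership, and rate-graded distractors.
A green acceptance suite therefore establishes that *this* stated world
learns, replays and degrades under distraction as published — not that
the biological claims generalize beyond it.

# Known limitations

With all published parameters and the interpretations above, the
trained chain replays in ~3–4.5 ms (median cue-to-element-E peak)
rather than the printed 5–7 ms, and control peak-time spreads are
correspondingly tighter. The key *ordinal* results are reproduced: distractors at the middle and
end positions (C, E) presented at or just after the cue are by far the
most disruptive, disruption decays monotonically with delay for the
internal locations, the middle-position effect exceeds the external one,
and readout success stays ≥ 0.95 in every condition.
But because the disruption index normalizes by those tight control
spreads, its magnitudes are inflated relative to the published values,
and the *absolute* −0.05 classification cut misassigns the borderline
conditions (external at small delays, E at 3 ms) to the relevant side.
The likely sources of the residual timing gap are unknowable from the
text: the exact noise realization, the absence of conduction delays,
and the internally inconsistent printed membrane constants
($\tau_\text{membrane} = 20$ ms vs
$c_\text{membrane}/g_\text{leak} = 10$ ms; we follow the explicit leak
parameters). We report the discrepancy rather than tuning any unstated
parameter toward the published band.
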
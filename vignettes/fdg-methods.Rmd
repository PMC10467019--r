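---
title: "Frequency-dependent gain and ionic-current decomposition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-dependent gain and ionic-current decomposition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical design of `fdgscape`:
what the synthetic neuron emulates and what it does not, how the
frequency-dependent gain (FDG) is estimated and why, the conventions behind
the decomposition, spike-triggered-average (STA) and variability statistics,
and the limitations a user should keep in mind.

## The experimental paradigm being emulated

The pipeline reproduces a standard in-silico electrophysiology paradigm: a
2.5 s current-clamp injection of frozen white noise (SD 0.04 nA, convolved
with a 3 ms square kernel) plus a tonic DC offset chosen so the cell fires
roughly 12–15 spikes per record (a theta-range mean rate); spikes are
detected at a −55 mV threshold; thirty trials with distinct noise
realisations but identical statistics form one condition; conditions differ
only in the maximal conductance of the h-current (doubled, default, halved,
zeroed), with the DC recalibrated per condition to hold the firing rate.
Conditions share trial seeds (paired noise), so condition contrasts isolate
the conductance effect.

Stimulus conventions: the square kernel has unit area; the noise is rescaled
*after* convolution so the delivered sample SD equals `sigma_nA` exactly;
convolution edges are regenerated rather than zero-padded, so every sample
sees a full kernel; trial *i* of an ensemble uses seed `base_seed + i`.
Identical specifications regenerate bitwise-identical stimuli, and the
generator restores the global RNG state, so package calls never perturb a
user's random stream.

## The synthetic neuron

`human_like_model()` is a single-compartment conductance-based cell with
five currents (uS, mV, ms; C = 0.15 nF):

| current | gbar | E | gates | role |
|---|---|---|---|---|
| leak    | 0.003 | −85 | — | passive load (Rin ≈ 330 MΩ without Ih) |
| NaT     | 5.0   | +55 | m³h; m: −48/4.5; h: −64/−4.5, recovery τ ≈ 40 ms | spike generation; the slow recovery from inactivation provides a ~40 ms relative refractory period |
| Kfast   | 2.5   | −85 | n⁴; −34/6 | repolarisation |
| Kslow   | 0.15  | −85 | m: −50/6 (τ ≈ 10 ms); inactivation −70/−7, τ 0.3–1 s | slow-inactivating K current whose availability tracks slow voltage history |
| Ih      | 0.16  | −45 | single inverted gate, −72/−7; τ(V) peaking ≈ 340 ms near −75 mV | subthreshold resonance and depolarising drive |

`rodent_like_model()` is identical except the h-current time constant is
tenfold faster (τ peaking ≈ 34 ms). Gate steady states are Boltzmann
functions `1/(1 + exp((half − V)/slope))` and time constants bell-shaped
Gaussians in V — deliberately minimal forms with few parameters.

Three design points deserve explanation, because each was forced by the
physics of a *single* compartment:

- **Ih placement.** The half-activation sits at −72 mV (slope −7). In a
  one-compartment cell driven to fire 12–15 spikes per 2.5 s, the
  inter-spike voltage lives near −65…−58 mV; an h-current centred at −82 mV
  (typical of somatic fits to multi-compartment models) carries negligible
  voltage feedback there and cannot express any subthreshold resonance. The
  conductance (0.16 uS) was likewise chosen so the preset actually shows the
  low-frequency gain peak it exists to demonstrate; at much smaller values
  the peak sinks into the single-trial estimator floor.
- **Slow-inactivating K.** With only fast currents, a noise-driven cell at
  theta rates fires either mean-driven and metronomically (interspike CV
  ≈ 0.3) or as a memoryless escape process (CV ≈ 0.6). Real h-null cells are
  *more* irregular than that (CV ≈ 1): clusters and gaps. The slow
  inactivation of Kslow supplies that cluster/gap dynamic — availability
  recovers during silence and suppresses firing, then inactivates during
  depolarised episodes.
- **Slow Na recovery.** Without the ~40 ms recovery from inactivation the
  h-current's post-spike rebound triggers doublets, which inflate the
  default condition's CV above the h-null condition's and invert the
  physiological ordering.

With these pieces, the preset reproduces the paradigm's qualitative
signatures: the default cell shows a normalized 30-trial average FDG with a
local peak below 10 Hz that vanishes when Ih is zeroed at matched rate; the
pooled ISI CV decreases monotonically with the h-conductance (≈ 0.98, 0.55,
0.49, 0.40 at 0×, ½×, 1×, 2× in a 30-trial battery); sag, depolarised rest
and reduced input resistance all track Ih as expected; and the rodent-like
preset shows no sub-10 Hz peak in either condition.

What the preset does **not** emulate: multi-compartment morphology and
dendritic filtering, Ca²⁺ currents and Ca²⁺-activated K, the persistent Na
current, temperature corrections, and the specific kinetics of published
channel models. A passing test on this generator demonstrates that the
*analysis pipeline* behaves correctly on data with the right statistical
structure — not that any particular biological neuron does.

## Estimating the frequency-dependent gain

The definition is `G(f) = |C_sr(f)|/|C_ss(f)|` with biased (divide-by-N)
correlations. Numerically, `compute_fdg()`:

1. builds `r(t)` at the stimulus sampling interval (`1/Δt` in spike bins);
2. subtracts the stimulus mean (the DC offset would otherwise leak into the
   1 Hz bin after padding); `r(t)` is *not* mean-subtracted;
3. zero-pads both series to a multiple of 5 s so the native FFT bins land
   exactly on the 1.0, 1.2, …, 30.0 Hz grid (no interpolation);
4. smooths the complex cross-spectrum across frequency with a Gaussian
   kernel (SD 0.6 Hz by default) and takes its magnitude;
5. divides by the stimulus autospectrum averaged over the 1–30 Hz band.

Steps 4–5 are the estimator design and deserve justification. A
single-realisation ratio of periodograms is not a consistent estimator: the
autospectrum has 100% pointwise variance, and a 12–15-spike train
contributes a broadband incoherent floor that dwarfs the coherent transfer
function in every bin. Dividing by the raw periodogram makes the gain of a
perfectly phase-locked spike train peak at harmonics or at whatever bin the
stimulus spectrum happens to dip — numerically verified, this misplaces the
argmax of `G` for sinusoid-locked spiking at essentially every drive
frequency. Averaging the complex cross-spectrum over a small bandwidth
suppresses the incoherent floor (whose phase decorrelates between bins)
while leaving the smooth coherent component intact, and a *band-mean*
denominator is near-lossless here because the delivered stimulus is
near-white: the 3 ms kernel attenuates the true autospectrum by under 3%
across 1–30 Hz. With these defaults the phase-locked argmax is recovered
exactly on the grid for all tested drive frequencies and noise levels.
`num_smooth_hz = 0, den_smooth_hz = 0` recovers the literal raw formula;
`den_smooth_hz` finite applies Gaussian smoothing to the denominator
instead of the band mean.

Averaging dialects: `average_fdg_insilico()` takes the pointwise mean over
trials (each trial a distinct noise realisation), with min-max normalization
applied per trial *before* averaging when normalized curves are wanted —
which is why normalized averages do not span exactly [0, 1].
`average_fdg_invitro()` implements the average-of-averages used for
recorded neurons (trials within neuron, then across neurons, each neuron
weighted equally). `compare_pointwise()` substitutes a per-frequency Welch
t-test with Bonferroni correction over the 146 grid points for an omnibus
ANOVA — a deliberately simple, transparent pointwise comparison.

Peak calls use topographic prominence (height above the higher of the two
flanking valleys, walking out to higher terrain or the grid edge). The
protocol reports peaks at prominence ≥ 0.05 on normalized averages: at 30
trials the residual estimator noise produces spurious bumps of prominence
well below 0.05, while the preset's genuine low-frequency peak sits at or
above it.

## Decomposition, STA and monotonicity conventions

- Inward = negative samples, outward = positive, exact zeros belong to
  neither class (avoids 0/0); samples whose class total is zero carry a
  defined-false mask rather than propagating NaN.
- The injected current is excluded from both classes; the passive current is
  included by default (`include_passive = FALSE` removes it).
- Isolated spikes require both no earlier spike within the window *and* a
  complete data window before them.
- The spike-anchor sample is the window's inclusive right edge. Trials are
  combined with equal weight; the SD band is across trials (across spikes
  for a single trial).
- A channel that flips class within the collected windows is averaged in its
  dominant class, with opposite-class samples masked and each lag
  renormalized by its defined count.
- Monotonicity: normalize by the window maximum (outward) or minimum
  (inward) of the percentage trace, smooth with a centered five-point moving
  average whose windows shrink symmetrically at the edges (the documented
  behaviour of the common MATLAB default), take per-step difference
  quotients, and report the proportions of negative, positive and
  exactly-zero steps separately.
- ISI CV uses the population-SD convention; ensembles pool ISIs across
  trials before the ratio (`per_trial = TRUE` gives the mean of per-trial
  CVs instead). The two-sample CV test is the Feltz–Miller asymptotic
  chi-square test, cross-checked in the test suite against a permutation
  oracle; under normal-theory nulls it holds its nominal size, while for
  strongly skewed (e.g. gamma) samples it is conservative.

## Numerical integration

Gates advance by exponential Euler (exact for a frozen voltage); the
membrane potential advances by forward Euler, so the discrete current
balance `C·ΔV/Δt + ΣI_c = I_inj` holds exactly at every step — a property
the test suite checks on every simulation. The default step is 0.025 ms
with a 200 ms settling period at the stimulus DC discarded before analysis.
Stability was checked against the chosen maximal conductances
(`g_total·Δt/C < 1` everywhere on the trajectory); a diverging voltage
(|V| > 200 mV) raises an error naming the step, and the DC calibration
interprets such divergences by their sign (over- vs under-driven) so the
bisection backs away rather than failing.

Convergence is verified in two parts, because the spiking model operates by
design in a threshold-skimming regime where trajectories are exponentially
sensitive — whether a marginal noise peak fires can depend on any
discretisation difference, so no pointwise bound on the full model can hold
over a long record at any step size. The non-regenerative subsystem (Na and
fast K removed) converges pointwise at first order (sup-norm error ~0.003 mV
per halving at dt = 0.025 ms); the full model's firing statistics (spike
count, ISI CV) are stable across halvings. Spike counts and gain curves in
this package are therefore reproducible bit-for-bit only at a fixed dt,
which is also why dt is part of the stimulus specification.

One practical consequence of the frozen-noise design: the noise is drawn on
the integration grid, so records at different dt are *different
realisations*, not refinements of one another. Cross-dt comparisons must
upsample a fixed realisation explicitly.

## Problem sizes

The packaged defaults mirror the study design: 2.5 s records at dt
0.025 ms, 30 trials per condition, four h-conductance scalings plus a
two-condition rodent battery. A full battery runs in about a minute on one
CPU (the integrator core is compiled); the test suite and the acceptance
script each complete in a few minutes.

## Known limitations

- The pre-spike *monotonicity fractions* of the h-current contribution do
  not separate reliably across conductance scalings on this preset: the
  percentage contribution of Ih to the inward class sits near 90% throughout
  the pre-spike window (only the transient Na current competes
  subthreshold), so the STA trace is nearly flat until the final Na surge
  and its difference-quotient sign statistic hovers near 50% with
  condition differences (~2–3 points) inside estimator noise. In detailed
  multi-compartment models the persistent Na and low-threshold Ca currents
  share the inward class and carve a pronounced rise-and-fall into the Ih
  contribution; adding a persistent Na current here destroys the
  monotone spike-count-versus-DC relation the calibration contract relies
  on, so it was left out. The fractions are still computed and reported —
  they are simply not a discriminating statistic for this generator.
- The low-frequency peak of the default condition is a modest feature
  (prominence ≈ 0.05–0.15 on normalized 30-trial averages) riding on a
  stronger ~12 Hz rhythm set by the refractory dynamics; with other seed
  ensembles its prominence fluctuates near the 0.05 call threshold.
- Gains are reported in (spikes/s)/nA and depend on the estimator's
  smoothing bandwidth; comparisons should always use matched settings.
- The NEURON adapter ingests exported text traces only; it does not drive
  simulations, and its sign-convention check is a heuristic (median sign of
  sodium/h currents at subthreshold voltages).
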
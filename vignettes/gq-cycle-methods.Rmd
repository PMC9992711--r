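---
title: "Modelling and analysing the M3 receptor-Gq cycle with gqfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing the M3 receptor-Gq cycle with gqfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gqfret)
```

## The kinetic model

The package encodes the receptor-Gq activation/deactivation cycle as a
lumped first-order reaction network over receptor states:

```
R  --kL_on.L(t)-->  RL  --k_couple-->  RLG  --k_exch-->  RLSep  --k_plc_on-->  RLSepPLC
                    (agonist-bound)    (trimer bound)    (Ga/Gbg separated,    (PLCb
                                                          both on receptor)     recruited)
washout:  RLG --k_bg_off--> R      RLSep --k_bg_off--> RGa --k_hyd--> R
          RLSepPLC --k_bg_off--> RGaPLC --k_plc_off--> RGa
```

Each lumped rate owns one macroscopic kinetic phase of the published
traces: `k_couple` the fast activation step (receptor-G coupling),
`k_exch` the slow step (GDP release, GTP binding and subunit separation,
collapsed into one rate because the slow phase fits a single
exponential), `k_bg_off` the fast deactivation step (Gbetagamma release
after washout) and `k_hyd` the slow one (GTP hydrolysis and Galpha
release). The model makes four deliberate simplifications:

* **Pseudo-first-order coupling.** The G protein pool is overexpressed,
  membrane-tethered and treated as non-depleting, so coupling is a
  first-order rate on the receptor rather than a bimolecular term.
* **Irreversible forward steps while agonist is present.** At the
  saturating agonist concentrations of the photometry experiments
  (10 uM against a ~0.1 uM apparent Kd) re-binding outcompetes the
  deactivation paths; deactivation transitions are therefore gated by
  the complement of the filtered agonist-presence signal, which gives
  the clean single-exponential OFF phases seen experimentally.
* **Fast ligand binding.** `k_L_off = ln 2 / 0.05` 1/s by default; with
  a saturating step the binding relaxation is sub-millisecond and the
  observed onset delay comes from the solution-exchange filter plus the
  fitted offset in the step-1 window.
* **Lumped perturbations.** GDPbetaS multiplies `k_exch` by a slowdown
  factor (default 1/5, the printed ~5x slowing of the slow step) without
  an explicit GDPbetaS-bound species; GTPgammaS and the constitutively
  active Galpha mutants (Q209L, R183C, treated identically) share one
  "pre-separated pool" variant in which activation is a single
  `RL -> RLSep` step at `k_couple`, hydrolysis is disabled and washout
  returns `RLSep -> R` at `k_bg_off`; the coupling-dead receptor mutants
  force `k_couple = 0`.

Rates are calibrated from macroscopic time constants with
`calibrate_rates()`: reciprocal mode takes `k = 1/tau` per phase;
refined mode additionally pushes the rates through the complete
noiseless simulate-render-analyze loop and adjusts them until the
*fitted* time constants match the targets within 5%. The reciprocal
calibration is already accurate to a few percent because the windowed
decomposition is nearly unbiased (below).

### YM-254890

The Gq inhibitor blocks GDP release, so `k_exch` is forced to zero
while YM is present. After YM removal the published traces show the slow
step recovering only ~31% of its amplitude. A pure rate-scaling reading
cannot produce an amplitude ceiling in a first-order scheme, so the
package implements the washout as a population split: at the end of each
YM interval a configurable fraction (`ym_unblocked`, default 0.31) of
the accumulated coupled complex proceeds normally and the remainder
moves to an absorbing blocked species. The mechanism is genuinely
unresolved; the parameter is exposed in the preset registry rather than
hard-coded.

### PLCbeta rates

No PLCbeta recruitment time constant is printed (only "stronger but
slower"), so `k_plc_on = 1/3` 1/s and `k_plc_off = 1/5` 1/s are free
choices constrained by the ordering the experiments do establish: the
Galpha-PLCbeta pair must rise more slowly than the receptor-Galpha pair,
and its washout decay (tau = 5 s) must lie strictly between the fast
(0.53 s) and slow (20-21 s) deactivation phases. Outside the PLC-pair
presets `k_plc_on = 0`: endogenous PLCbeta is invisible to the other
FRET readouts, and letting receptor complexes detour through PLC-bound
states would otherwise distort the slow deactivation phase.

### Integration

There is no generic ODE-solver dependency: because the rate matrix is
piecewise constant (the only time dependence is the ~20 ms
solution-exchange filter around concentration steps), the trajectory is
propagated with matrix exponentials - exact wherever the matrix is
constant, midpoint-evaluated substeps across the short exchange
transients. This is unconditionally stable, so the stiff ligand-binding
rate (about 1200 1/s at 10 uM agonist) poses no problem on a 100 ms
sampling grid, and occupancy is conserved to numerical precision. The
accuracy requirement is checked against the closed-form solution of the
sequential chain (`closed_form_chain()`), which the integrator matches
to better than 1e-6 on linear-chain conditions.

## The photometry generator

A construct is a table of per-state FRET-ratio coefficients
(`fret_pair_spec()`), and the true ratio is the occupancy-weighted sum.
Coefficient values live in the preset registry
(`inst/extdata/presets.json`), not in code. For the intramolecular
sensor the activation drop is split 50/50 between the coupled and the
separated state (the printed step split is "around 50%"); the
post-washout Galpha-retaining states sit at the half-recovered level so
that deactivation is also two-step. The receptor-Gbetagamma pair gets a
non-zero resting baseline, standing in for the loose inactive-state
preassembly the experiments infer; its magnitude is unquantified and
only the activation gain matters to the pipeline.

Channels are rendered generatively by inverting the ratio formula:

```
CFPc(t) = D0 * exp(-lambda t) + noise
YFPc(t) = (r(t) + cFactor) * D0 * exp(-lambda t) + noise
```

so that `compute_fretr()` exactly inverts the noiseless render - the
round-trip identity holds to 1e-9 even with photobleaching, because a
shared bleach rate cancels in the ratio. A non-cancelling differential
bleach mode exists but defaults off (the study reports improved
photostability but no decay constants). Channel noise is i.i.d.
Gaussian per sample - the publication gives no noise spectrum - and its
SD is computed by `noise_for_snr()` from the preset's published SNR via
first-order error propagation of the ratio. Two properties of this
choice are worth knowing:

* the pipeline SNR uses the *maximum* response amplitude, which over
  ~700 response samples rides ~2-3 noise SDs above the true amplitude,
  so measured SNRs run ~10-15% above the calibration target; the SNR
  values are treated as calibration context, not recovery targets;
* per-channel versus ratio-level noise is indistinguishable from the
  published data; per-channel noise was chosen as the physically natural
  reading, and the SNR calibration makes the two nearly equivalent at
  these amplitudes.

Per-cell variability is a lognormal multiplier (unit mean, CV
`jitter_cv = 0.2`) applied independently to each kinetic rate and to the
response amplitude. The value reproduces the scale of the printed
between-cell SEMs (e.g. SEM 0.02 on a 0.22 s mean at n = 5 implies a
~20% cell-level CV). Note one small consequence: the mean of `1/rate`
across cells exceeds `1/mean(rate)` by about `CV^2`, a ~4% upward
nudge on mean recovered time constants that is well inside every
tolerance.

What the generator does *not* emulate: photon shot noise and detector
saturation, spatial heterogeneity and diffusion, receptor
internalization and arrestin pathways, mechanistic GRK2 effects
(amplitude/SNR scaling only), and any drift other than exponential
bleaching. A green recovery test therefore establishes that the
analysis pipeline is a consistent estimator *for this stated world*,
not that the world is complete.

## The analysis pipeline

Normalization follows the published convention exactly: the mean ratio
over the 5-s window before agonist application maps to 1, the mean over
the 5-s window before washout maps to 0 (decreasing responses) or 2
(increasing). The map is affine, hence idempotent; degenerate traces
(equal window means) are rejected rather than normalized into noise.

### Windowed exponential decomposition

The two-step fits use the published windows (ON: 0-1.2 s and 1.3-15 s
after agonist; OFF: 0-3.6 s and 3.7-30 s after washout), a single
exponential per window, and a bounded onset delay in the step-1 window
(`[0, 0.5]` s, implemented piecewise - flat before the onset - so the
delay is identifiable). One methodological deviation proved necessary:
fitting the windows *independently* biases the fast time constant by
tens of percent, because the slow component decays appreciably inside
the step-1 window (46% of it is gone by 1.3 s at tau = 1.92 s). The
package therefore fits the two components by exponential stripping -
each window fitted with the other component's extrapolation subtracted,
alternating from both orderings - followed by a joint two-exponential
least-squares polish over the union of the windows, with a profiled
(linear-in-amplitudes) coarse grid as a basin-independent third start.
Candidates violating the physical ordering tau1 <= tau2 are discarded
unless the slow amplitude vanishes; ties break on residual norm. On
noiseless equal-amplitude biexponentials the recovered constants are
exact to well under 2% across tau1 in [0.1, 0.5] s, tau2 in [1, 4] s at
10 Hz. (One amusing degeneracy: a sequential chain with k1 = 2 k2
produces an *exactly* single-exponential observable under the 50/50
coefficient split, so no estimator can recover its fast constant - the
test grids use equal-amplitude biexponentials for this reason.)

Percent step distributions follow the printed formulas, with the
maximum amplitude taken from the fit (the summed step amplitudes), as
in the original least-squares analysis - using the noisy pointwise
maximum instead would bias the percentages downward by the noise peak.
For the single-step constructs the quoted group-referenced formula is
implemented literally, with the group-average trace as an explicit
argument.

Window censoring is the one documented bias: with GDPbetaS the slow
activation constant (~10 s) must be estimated from a 1.3-15 s window
(1.4 time constants), and the slow deactivation constant (~20 s) from a
3.7-30 s window. Noiseless fits still recover these to ~1%, but their
noise-level variance is several-fold higher than for well-covered
windows, which is why the slowdown-ratio tolerance is the widest in the
registry. Similarly, the single-step fast constants (tau ~ 0.25 s at
10 Hz) rest on 2-3 rising samples; with noise the bounded-below delay
cannot absorb downward noise excursions, producing a ~10-20% upward
scatter of per-cell estimates that stays inside the 3-SEM tolerances at
n = 20.

### SNR and summaries

"Standard error of the baseline" is read literally as SEM: baseline SD
over the 5-s window divided by the square root of the sample count
(n = 50 at 10 Hz). An SD-only mode is provided behind a flag
(`se_mode = "sd"`) because the published definition is ambiguous; the
choice rescales all SNRs by sqrt(50) and is why SNR is treated as a
calibration quantity. Summaries are mean +/- SEM (SD/sqrt(n)), with
SEM undefined at n = 1. Hypothesis testing is deliberately out of
scope.

### Dose-response

The functional EC50s (0.007 uM ACh, 0.112 uM Oxo-M) are equilibrium
properties, but in the full activation network every forward step is
irreversible while agonist is present, so given time *any*
concentration converts the whole pool and the response amplitude
carries no EC50 information. The dose series therefore uses a dedicated
*occupancy* preset: a binding-only network (coupling detached) whose
FRET coefficient sits on the liganded state, with the apparent Kd set
to the printed functional EC50. The peak response is then proportional
to equilibrium receptor occupancy and the Hill fit recovers the EC50;
the Hill coefficient is 1 by construction. The fit fixes the bottom
asymptote to 0 on normalized responses (a flag frees it) and the
response at the fitted EC50 equals half-max by construction. `fit_t50()`
provides the logistic half-time used for confocal PIP2-depletion
curves.

## Numerical choices

* Integration: exact matrix-exponential propagation; occupancy
  renormalized when the total drifts by more than 1e-6 (it does not in
  practice); exchange filter time constant 0.02/3 s ("complete within
  20 ms" read as 95% completion).
* Exponential fits: `nls(algorithm = "port")` with bounds
  (tau in [1e-3, 300] s), three log-spaced tau starts per window, a
  Nelder-Mead fallback on the SSE surface, and the multi-candidate
  strategy described above; a tau ending on its bound is flagged.
* Flat traces: single-step fits whose amplitude is within 3 baseline
  SDs of zero are flagged `unidentifiable` rather than reported as
  kinetics.
* Determinism: every stochastic entry point takes a seed, derives
  per-cell/per-concentration streams from it, and restores the global
  RNG state on exit; identical configurations give byte-identical CSV
  output.

## Preset registry and per-preset calibration

Each published condition is a named preset in
`inst/extdata/presets.json` holding the condition switches, the
macroscopic time constants (stored as taus, inverted to rates on load),
the FRET pair, the default protocol and the target SNR. Two
calibration details deserve a note. First, different constructs carry
their *own* printed time constants (the receptor-Gbetagamma pair
couples at 0.23 s where the intramolecular sensor shows 0.22 s; the
subunit pair separates at 1.45 s where the sensor's slow step is
1.92 s); presets are calibrated to their own constants, which is the
point of a per-condition registry. Second, the GDPbetaS slowdown is
1/5 for the intramolecular sensor (the printed "nearly 5 times" ratio)
but 1.45/10.38 for the subunit pair, whose slowed constant is printed
directly - the two published numbers genuinely differ and the registry
reflects both.

## Known limitations

* The onset delay produced by the generator (~10 ms, from the exchange
  filter) is smaller than the printed delays (0.08 s for the sensor,
  0.25 s for the subunit pair); the published delays likely contain
  perfusion dead time that the model does not represent. Delay is
  accordingly not a recovery target, and for sigmoid-onset responses
  the bounded delay parameter absorbs the lag adequately.
* Percent step distributions for the wild-type sensor come out near
  44/56 rather than exactly 50/50: with a 50/50 coefficient split on a
  sequential chain the *fitted amplitude* of the fast component is
  `1 - 0.5 k1/(k1-k2)` (about 0.44 at the calibrated rates), not 0.5.
  The printed "around 50%" is comfortably within the registry
  tolerance, but an exactly even split would require retuning the
  coefficient table against its stated 50/50 reading, which the package
  declines to do.
* Stochastic single-molecule simulation (Gillespie), spatial effects
  and receptor internalization are out of scope by design.
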
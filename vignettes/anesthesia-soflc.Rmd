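---
title: "Self-organizing type-2 fuzzy control of a simulated anesthesia patient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organizing type-2 fuzzy control of a simulated anesthesia patient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soflc)
```

## The control problem

During a long surgical procedure an anesthetist regulates two coupled
physiological variables: the depth of neuromuscular block (muscle
relaxation, measured from the EMG and expressed as a normalized paralysis
level in $[0,1]$) and mean arterial pressure (MAP, a practical proxy for
depth of anesthesia). Two drugs are used: intravenous atracurium for
paralysis and inhaled isoflurane for MAP. The task is multivariable
(isoflurane deepens paralysis as a side effect), uncertain (patients
differ, and drug effects drift within a procedure), and noisy (EMG and
MAP monitors are interference-prone). This package provides a simulation
sandbox for that problem: a pharmacokinetic/pharmacodynamic (PK/PD)
patient model, a family of self-organizing fuzzy logic controllers
(SOFLCs), a two-stage surgical protocol, and the metrics and
nonparametric statistics used to compare controllers.

## Patient model

The atracurium path is a linear pharmacodynamic transfer function

$$G_{11}(s) = K_1 \frac{(1 + T_4 s)\,e^{-\tau_1 s}}
  {(1+T_1 s)(1+T_2 s)(1+T_3 s)},$$

with $\tau_1 = 1$ min, $K_1 = 1$, $T_1 = 4.81$, $T_2 = 34.42$,
$T_3 = 3.08$, $T_4 = 10.64$ min, feeding the Hill concentration-effect
curve

$$E = E_{\max}\frac{X^{\alpha}}{X^{\alpha} + X_{50}^{\alpha}},
  \qquad E_{\max} = 100\%,\; X_{50} = 0.404\ \mu\mathrm{g/mL},\;
  \alpha = 2.98 .$$

Isoflurane lowers MAP through a first-order block
$G_{22}(s) = K_2 e^{-\tau_2 s}/(1+T_5 s)$ with $K_2 = -15$ mmHg/percent,
$\tau_2 = 0.42$ min, $T_5 = 2$ min (so a constant 2% concentration lowers
MAP by 30 mmHg), and deepens paralysis through the interaction block
$G_{12}(s) = K_4 e^{-\tau_4 s}/((1+T_6 s)(1+T_7 s))$ with $K_4 = 0.27$,
$\tau_4 = 1$ min, $T_6 = 2.83$, $T_7 = 1.25$ min. Atracurium has no
effect on MAP: the coupling matrix is lower-triangular.

Two modelling choices deserve comment.

* **Interaction entry point.** The coupling matrix is linear, and the
  Hill curve's argument is a drug concentration, so by default the
  interaction is summed *in the concentration domain*: the Hill input is
  the sum of the $G_{11}$ and $G_{12}$ path outputs
  (`interaction = "pre_hill"`). This also makes the two-stage protocol
  physically reachable: with post-Hill summation (available as
  `"post_hill"`) the stage-2 set points would require a *decrease* in
  atracurium effect-site concentration that would leave a locked
  paralysis offset of roughly 0.08 under any controller whose drug
  signals can only rise toward a fixed command.
* **The stand-alone kinetic block.** A separate atracurium PK transfer
  function with gain 9.94 shares its three time constants with the
  pharmacodynamic block above; cascading both would double those poles,
  so by default only the pharmacodynamic block is used.
  [atracurium_pk_block()] can be cascaded explicitly via the `pk`
  argument for experiments with the kinetic stage modeled separately.

Blocks are discretized exactly under a zero-order hold via their modal
(partial-fraction) form at `dt = 0.01` min — 100 steps per minute, 30,000
steps per 300-min procedure — and dead times become integer-step ring
buffers, so the discrete DC gains equal the continuous ones to machine
precision and a step input produces exactly zero output before the dead
time has elapsed. Tests verify the discretization against an independent
continuous-time ODE integration (deSolve) to better than 0.5% of the
steady-state amplitude.

The *nonfixed* patient model redraws every model parameter independently
at every sampling instant as $p \cdot \max(\varepsilon,\, 1 + f z)$,
$z \sim \mathcal N(0,1)$, with $f = 1\%$ by default — serially
uncorrelated ("white") parametric noise, signs preserved. Measurement
noise is additive and Gaussian: fraction (10% or 20% in the protocol)
times a per-channel reference SD. The reference SDs default to fixed
clinical scales (0.1 normalized paralysis units; 10 mmHg), because the
signal-derived alternative (SD over the settling phase) is degenerate for
MAP, which is constant before the controller starts.

## Controller

Four inputs — error and leaky-integral error of muscle relaxation and of
blood pressure — are scaled to a $[-1,1]$ universe carrying seven
triangular labels NB..PB with 50% overlap. Sign conventions make a
positive error always mean "more drug needed": the paralysis error is
set point minus measurement; the MAP error is measurement minus set
point (isoflurane *lowers* MAP). The 4-input/2-output problem is
decomposed into the six unordered input pairs; each output channel
(atracurium, isoflurane) owns one rule-base whose two-antecedent rules
span all six pairs. Inference is Mamdani min-max; type-2 rule firings
are intervals (per zSlice for the general type-2 variant); the
aggregated output set is type-reduced with the classic iterative
Karnik-Mendel procedure (verified in tests against exhaustive
switch-point search) and defuzzified to the interval midpoint, with
zSlice results combined as the z-weighted mean of slice midpoints. The
three controller kinds share this single engine: type-1 sets are
zero-width single-slice sets, interval type-2 sets are one slice with a
footprint of uncertainty (FOU), and zSlices general type-2 sets are five
nested slices at $z = 0.2, 0.4, \dots, 1$, with FOU widths shrinking
linearly in $z$. Setting the FOU width to zero and the slice count to
one collapses all three to bit-identical behavior — an end-to-end
degeneracy test asserts this on full closed-loop runs.

**Output stage.** The output vocabulary is ZE, PS, PM, PB with peaks at
$0, \tfrac13, \tfrac23, 1$: a commanded *drug level* from "none" to
"full scale" (`out_mr` = 1.5 normalized infusion units, `out_bp` = 3%
isoflurane). Each controller period (1 min, the clinical MAP sampling
interval) the drug signal moves a fraction of the way toward the
command: $\Delta u = \lambda (u_{\mathrm{cmd}} - u)\,\Delta t$ with
tracking rates $\lambda$ of 0.03/min (atracurium; the muscle-relaxation
path is slow, $T_2 = 34$ min) and 0.05/min (isoflurane). The change is
the controller's output signal and is integrated into the nonnegative
drug signal; it is negative whenever the command is below the current
level, which is how the controller backs off after overshoot. A purely
incremental reading of the nonnegative output vocabulary was tried first
and discarded: it turns every transient overshoot into a permanent
offset, because the plant has unit DC gain and no drug elimination under
constant input.

The six subsystem outputs merge into one channel command as a
firing-strength-weighted mean (`combine = "weighted"`); an unweighted
mean is available but lets a subsystem in which a single weak rule fires
contribute that rule's full consequent centroid, since Mamdani centroids
are invariant to uniform scaling of a lone truncated set.

**FOU geometry.** Three geometries are implemented for type-2
partitions. Blurring the triangle feet outward and inward
(`fou_style = "feet"`) is the textbook picture but extends each set's
support; near equilibrium the type-2 controllers then fire remote rules
whose (nonnegative) consequents are tuned for large-error regions, a
measured systematic overdosing bias, and lone upper-only firings make
the KM interval degenerate to the support extremes. Scaling the lower
membership function uniformly (`"height"`) removes both artifacts but
also collapses the KM midpoint onto the type-1 centroid, making the
three kinds numerically indistinguishable. The controller therefore
defaults to the intermediate `"inner"` geometry — upper membership
function equal to the type-1 triangle, lower foot pulled in by the FOU
width (default 0.1, i.e. 5% of the universe span) — which keeps the
firing reach of type-1 while leaving the type-2 machinery genuinely
active. [build_fou_from_stats()] additionally builds sets whose FOU
width is proportional to a signal's standard deviation, with per-group
statistics mapped to nested zSlices, for workflows in which patient
monitoring data are available.

## Self-organizing layer

A 7x7 performance-index matrix maps the crisp labels of a channel's
(error, integral error) to a correction label NB..PB; corrections are
computed every controller step, per channel, and applied to the rules
fired at the *responsible* step — the current step delayed by the
channel's dead time (1 min for atracurium, 0 for isoflurane). Each such
rule's consequent index is shifted by the correction's signed offset
(ZE..PB saturating); if a subsystem fired no rule, a rule is generated
at the responsible step's antecedent signature with consequent
$\mathrm{saturate}(\mathrm{ZE} + \mathrm{offset})$. Rules are keyed by
antecedent signature, so duplicates cannot arise. By default *all* rules
fired in a subsystem receive the correction; correcting only the
maximally-firing rule (available as `blame = "max"`) leaves weakly-firing
rules whose consequents were inflated during transients uncorrected for
tens of minutes. The shipped matrix is monotone nondecreasing along
every row and column (asserted at load) and nearly odd-symmetric; one
cell that would break column monotonicity was normalized to the value
the monotone, near-symmetric pattern implies.

With a level-command output stage, this consequent-shifting *is* the
loop's integral action: a persistent error ratchets the consequents of
the rules active in that state until the commanded level matches the
need, and the correction is zero once the error label returns to ZE. The
explicit integral-error inputs are therefore deliberately de-emphasized
(large references, 20-min leak); strongly scaled pure integrals
re-poison rules after every set-point crossing.

Every inference operation updates per-rule firing counters; a rule's
firing percentage is $100 \times$ fires / inference operations of its
subsystem. [extract_rules()] removes rules below a threshold (default
1%) — the trivial rules, typically fired only by noise — yielding the
reduced "extracted" rule-base that can seed later runs.

## Rule-bases

Two rule-base families ship as CSV fixtures. The expert bases (150 rules
per channel) encode anesthesiologist-style knowledge on a checkerboard of
same-parity label pairs, six consequents per pair block; the extracted
bases (15 atracurium / 14 isoflurane rules) are the distilled
frequently-used subsets from pretrained self-organized runs,
concentrated on mid-range input conditions. The self-organizing layer
repairs gaps and miscalibrations in either base online; tests assert
lossless round-trip serialization and that the extracted bases are
strictly smaller.

## Protocol and metrics

A run lasts 300 min: a 5-unit atracurium bolus for the first 5 min,
settling to minute 15 (MAP stays at the 120 mmHg baseline; both drugs
off after the bolus), then closed-loop control, with set points
(paralysis 0.8, MAP 100 mmHg) switching at minute 150 to (0.9, 90).
The printed protocol also supports the reversed paralysis ordering
(0.9 then 0.8) via `mr_setpoints`. Steady-state error is evaluated per
stage over the stage's last 50 min as the absolute difference between
the time-averaged clean signal and the set point (`method = "bias"`;
the per-sample mean absolute deviation is available as `"mae"`, but the
time average is what makes sub-noise-floor errors measurable).
Control stability is the population SD of each drug signal over the
controlled steady portion (default from minute 100), so it measures
dosing smoothness rather than the deterministic bolus and ramp
transients, whose excursions are orders of magnitude larger than the
jitter of interest. [repeat_and_compare()] runs matched-seed
repetitions (default 10; repetition $r$ of every variant uses seed
$\mathrm{base}+r$, and the number of RNG draws per plant step is
independent of the controller kind, so noise realizations are paired),
then applies Kruskal-Wallis across variants and one-tailed paired
Wilcoxon signed-rank tests at $\alpha = 0.05$ for the ordered
hypotheses (interval > type-1, zSlice > type-1, zSlice > interval).

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(controller = "interval_t2",
                         noise = noise_config(param_fraction = 0.01,
                                              meas_fraction = 0.2),
                         seed = 2)
run <- run_closed_loop(cfg)
round(run_metrics(run), 4)
#> sse_mr_s1 sse_bp_s1 sse_mr_s2 sse_bp_s2  stab_atr  stab_iso
#>    0.0240    0.3663    0.0096    0.0493    0.1185    0.3226
```

Paralysis tracks its set points to 0.01-0.02, MAP to a few tenths of a
mmHg (both as 50-min averages), and the post-transient dosing SDs are
~0.12 normalized units (atracurium) and ~0.32% (isoflurane).

## What the simulations do and do not show

The generator reproduces the *structure* of the clinical problem —
multivariable coupling, dead times, saturating pharmacodynamics,
parameter drift, monitor noise, multistage set points — but not real
patients: there is no interpatient covariate model, no drug elimination
under constant infusion (the plant is LTI around the printed transfer
functions), no propofol induction, and the membership geometry is a
regular triangular partition rather than sets fitted to patient
monitoring statistics. Conclusions about *relative* controller behavior
in this sandbox therefore do not automatically transfer to clinical
data.

Two honest negative findings from this implementation are worth
recording. First, the three controller kinds behave almost identically
in closed loop under the default geometry: the crisp-label-driven
self-organizing layer dominates the dynamics, engine-level type-2
effects are second order, and per-seed differences in steady-state BP
error are dominated by the chaotic sensitivity of the rule-modification
trajectory — their sign flips between seed sets. Systematic type-2
superiority of the kind reported for patient-data-derived membership
functions does not emerge from a regular partition with a uniform FOU.
Second, the extracted rule-base's smoothness advantage appears
consistently on the isoflurane channel but *reverses* on the atracurium
channel, whose 34-min dominant lag makes re-learning of the missing
large-error rules bumpy after the bolus and the stage switch.

## Numerical choices

Output centroids use a 1001-point uniform grid over the consequent hull
(< 0.1% centroid error); KM iterations stop at a $10^{-12}$ relative
change (with exhaustive-search verification on small grids); inputs
outside a universe are clamped to its edge (saturating linguistic
coverage); crisp labelling ties break toward ZE within a $10^{-9}$
membership tolerance; delay buffers are sized at twice the nominal dead
time with the read offset capped at the buffer length; and all problem
sizes in the test-suite experiments (full 300-min runs, 10 repetitions
per arm) match the protocol above.
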
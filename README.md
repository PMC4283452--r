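# soflc

Self-organizing fuzzy logic control of a simulated anesthesia patient,
with type-1, interval type-2, and zSlices general type-2 controller
variants.

## The problem

During multistage surgery an anesthetist regulates two coupled
physiological variables — neuromuscular block (muscle relaxation,
normalized to [0, 1]) and mean arterial pressure (MAP, mmHg) — by dosing
intravenous atracurium and inhaled isoflurane. The plant is
multivariable (isoflurane also deepens paralysis), uncertain (inter- and
intrapatient variability), and observed through noisy monitors. This
package is a simulation sandbox for that control problem, aimed at
researchers studying adaptive fuzzy controllers for drug delivery.

It implements:

* a **patient model**: atracurium drives paralysis through the
  pharmacodynamic transfer function
  `G11(s) = K1 (1 + T4 s) e^{-tau1 s} / ((1+T1 s)(1+T2 s)(1+T3 s))`
  followed by the Hill curve
  `E = Emax X^a / (X^a + X50^a)` (`Emax` = 100%, `X50` = 0.404 µg/mL,
  `a` = 2.98); isoflurane lowers MAP through
  `G22(s) = -15 e^{-0.42 s}/(1 + 2s)` (so 2% isoflurane lowers MAP by
  30 mmHg) and deepens paralysis through
  `G12(s) = 0.27 e^{-s}/((1+2.83 s)(1+1.25 s))`; atracurium never
  affects MAP. Zero-order-hold discretization at 0.01 min, exact
  integer-step dead times, 1% multiplicative white parameter noise
  ("nonfixed" patient), additive Gaussian measurement noise;
* a **fuzzy engine**: triangular linguistic partitions (NB..PB inputs,
  ZE..PB outputs), interval and zSlices type-2 sets with configurable
  footprint-of-uncertainty geometry, Mamdani min–max inference,
  iterative Karnik–Mendel type reduction, midpoint/z-weighted
  defuzzification, CSV/JSON rule-base serialization (expert and
  extracted rule-bases ship as fixtures);
* a **self-organizing layer**: a monotone 7×7 performance-index matrix
  maps each channel's (error, integral-error) labels to a correction
  that shifts the consequents of recently fired rules (with
  dead-time-delayed credit assignment) and creates rules where none
  fired, plus firing-percentage bookkeeping and trivial-rule extraction
  (< 1% threshold);
* a **surgical protocol harness**: 300-min two-stage runs (bolus,
  settling, closed loop; set points 0.8/100 then 0.9/90), steady-state
  error and control-stability metrics, matched-seed repetitions with
  Kruskal–Wallis and one-tailed paired Wilcoxon comparisons, and a CLI.

## Worked example

```r
library(soflc)

# the patient model alone: 2% isoflurane settles MAP at 90 mmHg
tail(open_loop_response(0, 2, horizon = 60)$map, 1)
#> [1] 90

# one closed-loop procedure: interval type-2 controller, expert rules,
# 20% measurement noise, 1% parametric noise
cfg <- simulation_config(controller = "interval_t2",
                         noise = noise_config(param_fraction = 0.01,
                                              meas_fraction = 0.2),
                         seed = 2)
run <- run_closed_loop(cfg)
round(run_metrics(run), 4)
#> sse_mr_s1 sse_bp_s1 sse_mr_s2 sse_bp_s2  stab_atr  stab_iso
#>    0.0240    0.3663    0.0096    0.0493    0.1185    0.3226
```

The six numbers are the per-stage steady-state errors (paralysis tracks
its set points to 0.01–0.02 normalized units, MAP to a few tenths of a
mmHg, both as 50-minute averages of the clean signal) and the
post-transient dosing standard deviations (atracurium in normalized
infusion units, isoflurane in percent) — lower means smoother dosing.
Rule usage from the run feeds extraction:

```r
stats <- firing_percentages(run$controller, "isoflurane")
reduced <- extract_rules(controller_rulebase(run$controller, "isoflurane"),
                         stats, threshold = 1)
```

A thin command-line interface wraps the same functions
(`inst/scripts/soflc-tool simulate|open-loop|compare|extract-rules`).

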
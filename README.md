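# sentlen

Simulation and analysis tools for **sentence-length perception**
experiments: two-alternative "does this sentence contain more or fewer
than 17 words?" judgements made on full-page text, in a 2 x 2 mixed
factorial design (mirror-reversed vs upside-down flip type between groups,
standard vs flipped orientation within participant).

The package is for psychophysicists and behavioural researchers who want
to (a) prototype and power such designs against explicit generative
observer models, and (b) run the complete analysis chain those designs
need on trial-level data -- their own or simulated.

## What it computes

* **Psychometric functions.** The proportion of "more" responses per
  relative sentence length `x = words − 17` is fitted with the sigmoid
  `p(x) = 1 / (1 + exp(−K (x − Xo)))` by multi-start bounded least
  squares. Derived indices: PSE `= Xo`, JND `= ln 3 / K` (half the
  0.25→0.75 response-rate span), Weber fraction `= JND / 17`.
* **Signal detection theory** under a half-SD z convention,
  `z(p) = 0.5 Φ⁻¹(p)`: sensitivity `d′ = z(H) − z(F)` (so unbiased 75%
  correct ↔ d′ = 0.67) and bias `β = φ(z(H)) / φ(z(F))` (β > 1 =
  underestimation), with the 0.5/35 extreme-rate correction generalised to
  any cell size.
* **Monte Carlo permutation tests** on median differences
  (between-group, paired sign-flip, and interaction variants; 10,000
  reshuffles, directional 95th-percentile criterion, plus-one p-values,
  seeded).
* **Lapse and heuristic probes.** Error rates on the extreme 10/11- and
  23/24-word sentences, and the "mischievous sentence" contrast -- a
  16-word page laid out over three text lines that defeats observers who
  judge length by counting lines rather than words -- against exact or
  normal-approximation chance bands (0.32/0.68 at n = 22).
* **Design statistics.** Exact binomial practice stopping rule and
  inclusion thresholds, ω² effect size from a prior F statistic, and
  φ-based per-group sample size.
* **A generative cohort simulator** (`simulate_cohort()`): word-counting
  or line-counting observers with Weber-scaled or line noise, per-cell
  criterion shifts, lapses, log-normal reaction times, and seeded
  per-participant heterogeneity, producing the canonical trial table for
  the full 88-participant design.

## Worked example

```r
library(sentlen)

trials <- simulate_cohort(design_config(), observer_params(), seed = 42)
report <- analyze_cohort(trials, n_iter = 10000, seed = 42)
report
#> Sentence-length perception analysis report
#>   88 participants, 12320 analysis trials (seed 42)
#>   group JNDs: 1.43-1.97 words (Weber 8.4-11.6%)
#>   median d' = 1.199, median beta = 1.027
#>   permutation tests:
#>     d_prime: standard - flipped                      diff =   0.1281  p = 0.0006 *
#>     beta: mirror - upside_down                       diff =   0.2552  p = 0.0001 *
#>     underestimate lapse diff: mirror - upside_down   diff =   0.1000  p = 0.0005 *
#>     rt median: flipped - standard                    diff =   0.0051  p = 0.0422 *
```

The default observer counts text lines (noise 0.21 lines, ~1% lapses) and
carries a +0.3-line criterion shift only in the (mirror, flipped) cell, so
the simulated cohort shows the signature pattern: a raised median β and
elevated 23/24-word underestimation lapses confined to mirror-reversed
flipped text, while precision (d′, JND) stays broadly comparable across
cells. Per-cell fits are in `report$fits`:

```r
dplyr::filter(report$fits, flip_type == "upside_down", sample_id == 1)
#>   orientation     K  jnd weber_fraction    pse var_explained
#> 1     flipped 0.735 1.49         0.0879 -0.305         0.994
#> 2    standard 0.766 1.43         0.0843 -0.284         0.993
```

JNDs of ~1.4-1.5 words mean these observers resolve sentence length to
within about a word and a half around the 17-word boundary (Weber fraction
~9%); PSEs near zero indicate nearly unbiased responding in unshifted
cells, and the sigmoid explains >99% of the response variability.
`write_report(report, dir)` emits all result tables as CSV plus a JSON
summary; `plot_group_psychometrics()`, `plot_sdt()` and `autoplot()`
produce the standard figures.

`audit_anchors()` recomputes the package's numerical conventions against
their worked reference values (the d′ = 0.67 ↔ 75% correspondence, the β
anchors 1.351 and 1.0, ω² = 0.1975, n = 21.49 → 22, the Weber fractions
9.41%/10.65%, the 0.32/0.68 chance band, and the 140-trial schedule) and
reports each expected-vs-computed pair.

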
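---
title: "Detecting outlying pageview epochs: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting outlying pageview epochs: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viewspike)
```

## The model

`viewspike` treats a topic's daily Wikipedia traffic as a univariate count
series $x_t$ (total views per calendar day, summed over pages and language
localizations) generated by an additive structure

$$x_t = s_t + m_t + r_t,$$

where $s_t$ is a weekly-periodic seasonal component, $m_t$ a slowly varying
level, and $r_t$ noise punctuated by occasional large upward spikes driven
by external events (news coverage, awareness campaigns). The scientific
object of interest is the set of days whose totals significantly exceed the
structural expectation $s_t + m_t$, and the *epochs* — maximal runs of
consecutive flagged days — that localize the underlying events.

Three modelling commitments follow from the data:

* **Robustness over smoothness.** The spikes we want to find are exactly
  the observations that wreck mean-based estimates of $s_t$ and $m_t$.
  Every estimator in the decomposition is therefore a median: per-weekday
  medians for $s_t$, windowed medians for $m_t$, and median/MAD
  studentization in the outlier test. `shesd_decompose()` demonstrates this
  concretely: a 10-MAD spike moves the piecewise-median trend by a small
  fraction of what it would move a window mean, so the spike mass stays in
  the remainder where the test can see it.
* **A periodic, non-evolving seasonal.** The seasonal component is one
  value per weekday, constant over the series, estimated by per-phase
  medians after detrending with a centered running median one period wide.
  Web-traffic weekly cycles are stable over a few years, and a periodic
  component keeps the decomposition exactly reconstructive and cheap. An
  evolving (Loess-smoothed) seasonal is a deliberate non-goal; the
  `seasonal_estimate()` surface is the extension point if one is ever
  needed.
* **One-tailed detection.** Health-topic traffic events of interest are
  surges. The default direction is `upper`; `lower` and `both` exist for
  other applications.

### The test

`robust_esd()` runs the generalized extreme studentized deviate iteration
with robust moments: at step $k$ the candidate is the largest
$(r - \mathrm{median})/(1.4826\,\mathrm{MAD})$ among values not yet
removed, compared with

$$\lambda_k = \frac{(n-k)\; t_{p,\,n-k-1}}{\sqrt{(n-k-1+t^2_{p,\,n-k-1})(n-k+1)}},
\qquad p = 1 - \frac{\alpha}{n-k+1}$$

(halve $\alpha$'s divisor for the two-tailed variant). After $k_{\max}$
steps the reported outliers are the first $k^\*$ removals, $k^\*$ being the
largest step whose statistic exceeded $\lambda_k$. With `center = "mean"`
the procedure collapses to the textbook generalized ESD, which the test
suite verifies against an independent brute-force implementation on short
vectors. Note that for fixed $n$, $\lambda_k$ is bounded above by
$(n-k)/\sqrt{n-k+1}$, so even $\alpha \to 0$ cannot push the critical value
past that ceiling — relevant when reasoning about what a "conservative"
$\alpha$ can and cannot buy.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `period` | 7 | days | Weekly cycle of web traffic; daily data offer no finer natural period. |
| `span_days` | 182 | days | Half a year per trend window. The traffic level drifts only marginally, so long windows suffice and keep each median well-determined; a 1,096-day series yields six windows (the 4 leftover days merge into the last). |
| `alpha` | 0.01 | — | Conservative: daily counts are noisy, and the goal is a short list of meaningful events, not exhaustive anomaly inventory. |
| `max_outlier_fraction` | 0.10 | — | ESD iteration ceiling. Must comfortably exceed the plausible outlier share (observed shares in real sepsis traffic are ≈ 4%), while keeping the iteration affordable. |
| `direction` | `"upper"` | — | Surges are the events of interest; sub-expected days are not sought. |

Epoch aggregation has no free parameters: "consecutive" means adjacent
calendar days (a 2-day gap starts a new epoch — the reference epoch table
bundled as `sepsis_epoch_fixture()` forces exactly this reading), peak ties rank by earlier start date, and the
media window is always (start − 1, end + 1) to absorb time-zone and lag
effects.

## The synthetic generator

`gen_pageview_panel()` emulates the features of real multi-language
pageview panels that the detector relies on:

* **Scale and composition.** Defaults: 1,096 days from 2015-07-01,
  ~18,756 mean daily views, 15 named language editions plus an aggregated
  tail, with English at 43.1% and Japanese at 10.1% of traffic and a
  power-law tail below them — the composition of real sepsis traffic.
* **Weekly seasonality** as additive zero-sum weekday offsets (weekdays a
  few percent above the mean, weekends ≈ 10% below — the canonical shape of
  encyclopedia traffic).
* **Slow drift** as a piecewise-constant level over 182-day windows with
  multipliers between 0.95 and 1.06: "modest seasonality and a slight
  trend".
* **Overdispersed counts.** Per-language negative-binomial draws with
  dispersion (size) 50, giving the daily total a coefficient of variation
  of about 7% — the day-to-day roughness a practitioner sees in mid-traffic
  medical pages. A log-normal option exists for misspecification testing,
  and `noise = "none"` produces the exact deterministic means.
* **Injected spikes with recorded truth.** Ten single-day spikes by
  default, each adding 8 noise-standard-deviations to the expected total on
  its day (before noise), placed at seeded-random dates separated widely
  enough that every injection forms its own epoch. The truth record carries
  the spike dates, magnitudes, per-day structural components, and the
  analytic noise scale.

What the generator does *not* emulate: yearly seasonality, day-of-month
effects, the slow diffusion of interest across languages after an event,
correlated multi-day event decay ("spikes" here are rectangular), and
measurement artifacts such as bot traffic. Passing the recovery tests
therefore shows that the detector finds isolated additive surges of known
magnitude under realistic noise — it does not show that every real-world
epoch shape would be recovered, nor that the ranking of partially
overlapping events is meaningful.

The clickstream generator draws inbound referral counts from a multinomial
over categories (reserved aggregate tokens for search-engine and
refererless traffic, synthetic page titles for ordinary categories), plus a
power-law outbound edge set, recording exact category totals so that
conservation through `categorize_edges()` and `sankey_export()` is checkable
to the integer.

## Numerical choices and degenerate inputs

* **MAD fallback.** When the MAD of the remaining residuals is zero the
  scale falls back to the mean absolute deviation from the median —
  reconciling the two readings of "median absolute deviation" in this
  method family — and if that is also zero the series is essentially
  constant: no outliers, with a warning.
* **Tie-breaks.** The ESD argmax takes the earliest position on ties;
  epoch peak ties rank by earlier start; outbound top-k ties break
  lexicographically by title. All purely for determinism.
* **Trend windows.** Windows anchor at the series start; a trailing
  partial window shorter than half a span merges into its predecessor
  (a 4-day median would be meaningless), otherwise it stands alone.
* **Running-median ends.** The seasonal detrender uses `stats::runmed`
  with the `"median"` end rule; end effects touch at most three days per
  end and are washed out by the per-phase medians for any series of a few
  months or longer.
* **Exact reconstruction.** The remainder is *defined* as observed minus
  seasonal minus trend, so the additive identity holds to machine precision
  on every input — this is asserted, not approximated.
* **Counts.** Thousands separators and en-dash date spans are normalized at
  parse time; absent (date, language) cells are zero views, matching the
  export convention of omitting zero-traffic days; conflicting duplicate
  counts are integrity errors rather than silent sums.

## Open design points, resolved

* **Share base for the English fraction.** Whether the headline English
  share is computed over one page's panel or the combined panels is left to
  the caller: `language_shares()` accepts any set of panels, and the
  combined set is the documented default in the pipeline (the fraction is a
  property of the topic's total traffic, not of one page).
* **Breusch–Pagan regressors.** The auxiliary regression uses the fitted
  values (seasonal + trend) as the single regressor — the standard form for
  a decomposition fit, where no other covariate is available. The test
  suite cross-checks the statistic against an independent implementation.
* **Seed discipline.** Generators take an explicit seed, run in a private
  RNG scope, and restore the caller's RNG state; identical (spec, seed)
  pairs are bit-reproducible.

## Problem sizes used in the test suite

Property tests run at the scale of the study they emulate: additive
reconstruction on heavy-tailed series of several hundred days; classical
ESD equivalence on vectors up to length 50; familywise error under the
generator's null (no injections) over 1,000 replicates of 1,096 days;
spike recovery over 100 seeded replicates at the default 8σ magnitude;
clickstream conservation on 10⁵-event draws.

## Known limitations

* **Upper-tail error inflation under skewed counts.** The ESD critical
  values assume normal residuals. Negative-binomial count noise is
  right-skewed, and over a long series the familywise probability of at
  least one spurious upper-tail flag rises well above the nominal level —
  the type-I property test measures exactly this, and under the generator's
  default dispersion at 1,096 days the empirical rate exceeds the 5%
  working bound, while the same test under normal residuals stays below it.
  Practically: isolated single flags in long, strongly overdispersed series
  deserve skepticism, and a variance-stabilizing transform (log or
  Anscombe) before detection is the natural mitigation when residual
  diagnostics reject homoscedasticity. The default pipeline applies no
  transform, because the motivating data showed no heteroscedasticity.
* **Algorithm-variant sensitivity.** Piecewise-median S-H-ESD has several
  legitimate micro-variants (seasonal estimator, window anchoring, MAD
  fallback). Flag *counts* on real data can shift by a few days across
  variants even when the large epochs are identical; reproduction of a
  specific published count should be read with that tolerance in mind.
* **Monthly clickstream granularity** precludes attributing referral flows
  to specific epochs; the clickstream module aggregates over its whole
  input window by design.
* **No multi-seasonal modelling.** Series with strong yearly cycles (e.g.
  influenza) would leave seasonal mass in the remainder; the weekly-only
  seasonal is a scope decision, not a claim of sufficiency for all topics.
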
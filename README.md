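# viewspike

Infodemiology tooling for daily Wikipedia pageview traffic: detect
significantly outlying days in a multi-language pageview series, merge them
into ranked *epochs* for media-correlate review, and characterize reader
flows with Wikimedia clickstream data.

The motivating use case is traffic to the sepsis and septic-shock pages —
spikes in page views track news events such as high-profile deaths from
sepsis and awareness campaigns, so outlying-day detection turns raw traffic
exports into a short list of dated windows worth investigating. The same
machinery applies to any health topic with daily pageview exports.

## The method

The detector is a **Seasonal Hybrid Extreme Studentized Deviate (S-H-ESD)**
procedure on the univariate series of total daily pageviews
*x*<sub>1</sub>, …, *x*<sub>n</sub> (summed over pages and language
localizations):

1. **Robust additive decomposition.** A periodic weekday component
   *s*<sub>t</sub> is estimated by per-weekday medians of the running-median
   detrended series, re-centered to sum to zero over one week. The trend
   *m*<sub>t</sub> is a *piecewise median*: the median of the deseasonalized
   series within consecutive 182-day windows. The remainder is defined as
   *r*<sub>t</sub> = *x*<sub>t</sub> − *s*<sub>t</sub> − *m*<sub>t</sub>, so
   *s* + *m* + *r* reconstructs the data exactly.
2. **Robust generalized ESD test.** The remainders are tested iteratively:
   at step *k* the most extreme value is studentized against the **median**
   and the normal-consistent **MAD** (1.4826 × median absolute deviation) of
   the values not yet removed,
   *C*<sub>k</sub> = (*r*<sub>(k)</sub> − median) / (1.4826 · MAD),
   and compared with the ESD critical value

   λ<sub>k</sub> = (n − k) · t<sub>p, n−k−1</sub> /
   √((n − k − 1 + t²<sub>p, n−k−1</sub>)(n − k + 1)),
   p = 1 − α / (n − k + 1) (one-tailed).

   The flagged outliers are the first *k\** removals, where *k\** is the
   largest *k* with *C*<sub>k</sub> > λ<sub>k</sub>. Median/MAD
   studentization makes the test resistant to masking by gross spikes;
   `center = "mean"` recovers the classical generalized ESD procedure.
   Detection is one-tailed (upper) by default: only days *exceeding*
   expectation are sought. Default α = 0.01.
3. **Diagnostics.** A Breusch–Pagan auxiliary regression of the squared
   remainders on the fitted values (LM = n·R², χ²₁) checks residual
   variance homogeneity.
4. **Epochs.** Flagged days that are calendar-consecutive merge into one
   epoch; each epoch carries its peak pageview count, a rank (1 = highest
   peak), and a media-correlate search window of (start − 1 day,
   end + 1 day).

Supporting modules read/write Langviews- and Massviews-style exports
(long and wide layouts, auto-detected), compute per-language share tables
with an "Other" rollup, parse and merge monthly clickstream dumps,
categorize inbound referrers with exact count conservation, and export a
Sankey-ready nodes/links JSON. A synthetic-data generator produces panels
and clickstreams with known ground truth at the scale of the real data.

## Worked example

```r
library(viewspike)

sim    <- gen_pageview_panel(panel_spec(), seed = 42)   # known truth
series <- aggregate_daily_total(sim$panel)
fit    <- shesd_detect(series)                          # S-H-ESD, defaults
fit
#> Seasonal hybrid ESD detection
#>   n = 1096 days; 9 outlying day(s)
#>   period = 7 | span = 182 | alpha = 0.01 | direction = upper

head(tidy(fit), 3)
#> # A tibble: 3 × 7
#>   date       observed expected residual  stat lambda     k
#>   <date>        <dbl>    <dbl>    <dbl> <dbl>  <dbl> <int>
#> 1 2015-07-31    25100   18076.    7024.  5.75   4.27     6
#> 2 2015-08-25    30927   18881    12046   9.80   4.27     2
#> 3 2015-12-29    27286   18881     8405   6.86   4.27     5

epochs <- build_epochs(fit, series)
head(epoch_report(epochs), 2)
#> # A tibble: 2 × 6
#>   epoch dates     highest_observed_pageview  rank media_window        potential_correlates
#> 1     1 7/31/2015                     25100     8 7/30/2015–8/1/2015  ""
#> 2     2 8/25/2015                     30927     2 8/24/2015–8/26/2015 ""
```

Each `tidy()` row is one flagged day: `observed` is the daily total,
`expected` the seasonal-plus-trend fit, `stat` the studentized deviation
*C*<sub>k</sub> and `lambda` its critical value, `k` the detection order.
The report table mirrors the layout used for manual media-correlate review;
the `media_window` column is the Google News / Factiva query window. Here
the nine flagged days are all among the ten injected 8σ spikes
(`sim$truth$anomaly_dates`), with no false flags. `autoplot(fit)` draws the
annotated log-scale series; `plot_language_shares(language_shares(sim$panel))`
the per-language share bars.

A built-in reference table, `sepsis_epoch_fixture()`, holds the 25 outlying
sepsis/septic-shock epochs of July 2015–June 2018 with printed peak counts
and ranks; expanding it gives the 47 outlying days and re-merging recovers
the 25 epochs, which makes it a self-contained oracle for the epoch rules.

For shell use, `inst/scripts/viewspike.R` wraps the staged pipeline
(`detect`, `epochs`, `clickstream`, `simulate`, `report`) around a YAML
config; see `?run_config`.

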
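# ppchron

Time-series homeostasis analysis of volatile organic compound (VOC)
emission monitored by ambient ionization mass spectrometry, built around
the extracted-ion chronogram of 6-pentyl-alpha-pyrone (6-PP, [M+H]⁺ at
m/z 167.1) during the *Trichoderma atroviride* – *Arabidopsis thaliana*
interaction.

The package is for metabolomics / chemical-ecology researchers who
monitor a target ion over days and want to characterize the *dynamics*
of emission rather than its average: is the signal background noise, an
unregulated **physiological** variable (heavy-tailed, bursty), or a
**stabilized** one (reduced tails, high autocorrelation), as expected
when a partner organism modulates production?

## What it computes

For a chronogram $x_1, \dots, x_n$ (intensity vs. hours since
inoculation), the homeostasis descriptor suite:

* moment-based skewness $g_1 = m_3 / m_2^{3/2}$ and excess kurtosis
  $g_2 = m_4 / m_2^2 - 3$, with denominator-$n$ central moments $m_k$;
* the biased autocorrelation function
  $\hat\rho_k = \sum_{t=1}^{n-k}(x_t-\bar x)(x_{t+k}-\bar x) \big/
  \sum_{t=1}^{n}(x_t-\bar x)^2$;
* Poincaré-plot descriptors: with $a = (x_2,\dots,x_n)$,
  $b = (x_1,\dots,x_{n-1})$,
  $\mathrm{SD1} = \mathrm{sd}\!\left[(a-b)/\sqrt2\right]$ (short-term
  variability), $\mathrm{SD2} = \mathrm{sd}\!\left[(a+b)/\sqrt2\right]$
  (long-term variability), and their ratio, satisfying exactly
  $\mathrm{SD1}^2 + \mathrm{SD2}^2 = \mathrm{Var}(a) + \mathrm{Var}(b)$
  and, for long stationary series,
  $(\mathrm{SD1}/\mathrm{SD2})^2 = (1-\rho_1)/(1+\rho_1)$;
* area under the intensity–time curve (trapezoidal) as total production,
  and production fold changes between conditions;
* hour-of-day emission profiles, peak clock hour, and the night/day mean
  ratio under a 16:8 photoperiod;
* value histograms.

Around the suite: mzML/CSV ingestion, extracted-ion chronogram
construction (window sum with configurable m/z tolerance, micro-scan
averaging), technical-then-biological replicate aggregation into
mean ± SD series, a rule-based background / physiological / stabilized
classifier, and a calibrated three-condition synthetic chronogram
generator (circadian night pulses, Poisson-gamma bursts, AR(1)
intensity-dependent instrument noise) so the full pipeline is testable
without instrument data.

## Worked example

```r
library(ppchron)

sim <- simulate_replicate_set(default_config("fungus", seed = 1))
describe(sim$replicates$mean)
#> <descriptor_set> fungus (n = 192)
#>   skewness 3.328 | excess kurtosis 11.887 | lag-1 ACF 0.596
#>   SD1 0.007093 | SD2 0.01412 | SD1/SD2 0.5024 | AUC 1.537

circadian_summary(sim$replicates$mean)
#> <circadian_summary> peak at 20:00 | night/day ratio 2.252
```

The fungal signal for this seed is strongly right-skewed (3.33) and
heavy-tailed (excess kurtosis 11.9) — short nightly emission excursions
over a low baseline — with an SD1/SD2 of 0.50 (dominant long-term
variability) and the characteristic 20:00 emission peak.

The full three-condition study:

```r
res <- run_study(run_config(seed = 1, out_dir = "study"), quiet = TRUE)
res$descriptors[, c("condition", "skewness", "excess_kurtosis", "acf1", "sd_ratio", "auc")]
#>     condition skewness excess_kurtosis  acf1 sd_ratio   auc
#> 1       plant   -0.112          -0.171 0.257    0.769 0.192
#> 2      fungus    3.401          12.574 0.569    0.523 1.529
#> 3 interaction    2.857           6.937 0.669    0.444 7.699

sapply(res$classifications, `[[`, "label")
#>           plant          fungus     interaction
#>    "background" "physiological"    "stabilized"

production_fold_change(res$sets$interaction$mean, res$sets$fungus$mean)
#> [1] 5.04
```

Read top to bottom, this is the three-regime pattern the analysis is
designed to expose: the plant alone is
indistinguishable from background; the fungus alone emits constitutively
with non-Gaussian, weakly autocorrelated bursts (physiological); in
co-culture, production rises about five-fold while skewness and kurtosis
drop and autocorrelation rises (stabilized) — the signature of the
partner regulating the volatile.  `run_study()` also writes the
chronogram tables, a mean ± SD series per condition, the descriptor
table, a classification report with full evidence, and a reproducibility
manifest.

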
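# restingalpha

Resting-state EEG alpha-band biomarkers of schizotypy: feature
extraction, group statistics and a nested cross-validated pattern
classifier, with a ground-truth synthetic EEG cohort generator.

## The problem

Subclinical schizotypy is a risk marker for schizophrenia-spectrum
psychosis, and the resting alpha rhythm (7–13 Hz) is one of the few
EEG signatures consistently altered across that spectrum. This package
implements, end to end, an analysis that separates high- (HSG) from
low-schizotypy (LSG) individuals from two minutes of eyes-closed EEG
using four quantities per subject, computed over left/right frontal and
parieto-occipital electrode clusters:

* **IAF** — individual alpha frequency, the strict local maximum of the
  Savitzky–Golay-smoothed power spectrum in 7–13 Hz;
* **alpha amplitude** — maximum alpha power, 10·log10(µV²);
* **wPLI** — weighted phase lag index,
  |⟨Im S<sub>xy</sub>⟩| / ⟨|Im S<sub>xy</sub>|⟩ over 2500 ms windows
  (phase coupling in [0, 1], insensitive to zero-lag mixing);
* **TLI** — time lag index, the circular-mean cross-spectral phase in
  milliseconds at the subject's alpha frequency (sign = direction of
  lead/lag).

The 14 features per subject (4 IAF, 4 amplitude, 3 wPLI, 3 TLI) enter
2×2×2 mixed ANOVAs with partial η², planned t tests with Cohen's d and
Dunn–Šidák correction, and a tenfold **nested stratified
cross-validation** that jointly selects a feature combination,
classifier family (linear SVM / L2 logistic regression) and
regularisation strength C ∈ {0.1, 0.2, 0.3} by balanced accuracy in the
inner loop, evaluating only on untouched outer folds.

So that every stage can be exercised and validated without any EEG
download, the package includes a first-class synthetic cohort generator
(`generate_cohort()`): subject-specific narrow-band alpha sources with a
posterior > frontal amplitude gradient, 1/f background, lagged
intra-hemispheric coupling with configurable sign, Gaussian scalp
projection and sensor noise — plus the ground-truth table that makes
parameter-recovery testing possible.

## Worked example

```r
library(restingalpha)

# simulate a 48-subject cohort with the shipped group configurations
cohort <- generate_cohort(n_per_group = 24, seed = 101)
feats  <- extract_cohort_features(cohort)   # one row per subject
#> 1 subject(s) without a detectable alpha peak excluded listwise

dplyr::count(feats, group)
#> # A tibble: 2 × 2
#>   group     n
#>   <chr> <int>
#> 1 HSG      23
#> 2 LSG      24

# group statistics: the right-posterior IAF comparison
rep <- stat_report(feats)
rep$tests[1, c("comparison", "statistic", "p_value", "cohens_d")]

# nested stratified CV (the full protocol uses n_repeats = 1000)
cv <- nested_cv(feats, n_repeats = 8, seed = 89)
glance(cv)[, c("sensitivity", "specificity", "balanced_accuracy", "auc")]
#> # A tibble: 1 × 4
#>   sensitivity specificity balanced_accuracy   auc
#>         <dbl>       <dbl>             <dbl> <dbl>
#> 1       0.852       0.640             0.746 0.791

head(ranking_report(cv), 3)
#> # A tibble: 3 × 4
#>   combination                 scope n_selected frequency_pct
#>   <chr>                       <chr>      <int>         <dbl>
#> 1 R.posterior_activity_intra  R             37         46.2
#> 2 LR.posterior_activity_intra LR            37         46.2
#> 3 LR.all_activity_intra       LR             5          6.25

autoplot(cv)                  # averaged ROC with SD band and 99.9% CI
plot_selection_ranking(cv)    # feature-combination selection frequencies
```

Balanced accuracy ~0.75 with posterior-plus-connectivity feature sets
dominating the selection ranking — the high-schizotypy signature in
this synthetic cohort is carried by right-hemisphere posterior alpha
and right fronto-posterior coupling, which is exactly what the shipped
generator configuration encodes (slower/weaker right posterior alpha,
weaker and direction-reversed right fronto-posterior coupling in HSG).

Recordings can also be written/read as delimited text with a JSON
sidecar (`write_cohort()` / `read_cohort()`), and the whole chain runs
under one configuration object via `run_pipeline(pipeline_config())`.

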
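# cycloc

Colocalization and reproducibility analysis for **cyclic multiplexed
immunofluorescence** — experiments in which a resin-stabilized specimen
is repeatedly immunolabeled, imaged, stripped with a high-pH elution
wash, and relabeled, so that many proteins are imaged on one specimen
and overlaid digitally.

The package is aimed at microscopists and image analysts running such
multi-round experiments. It covers the full analysis chain:

* **Synthetic scene simulation** — punctate epitope fields with planted
  multi-channel colocalization domains, stochastic per-round labeling,
  residual post-elution signal, round-over-round intensity gain, rigid
  drift, smooth background and noise (`scene_config()`,
  `generate_scene()`, `render_round()`, `simulate_dataset()`).
* **Dataset I/O** — multi-page 16-bit grayscale TIFFs plus a plain-text
  manifest (`read_dataset()`, `write_dataset()`), CSV result tables.
* **Preprocessing** — rolling-ball background subtraction (grayscale
  disc opening, default radius 50 px), FFT translation registration with
  optional subpixel refinement, mean-brightness equalization
  (`rolling_ball_subtract()`, `register_rounds()`, `equalize_means()`).
* **Round comparison** — the minmax shared/difference decomposition of
  two rounds of the same stain, Pearson correlation, log-ratio
  histogram, and elution efficiency (`minmax_decompose()`,
  `ratio_histogram()`, `elution_efficiency()`).
* **Occupancy colocalization statistics** — Otsu and percentile
  thresholding, 2^k joint-occupancy contingency tables, chi-squared
  tests of mutual independence, and threshold-sweep exceedance-ratio
  curves (`otsu_threshold()`, `percentile_threshold()`,
  `build_occupancy_table()`, `chi2_mutual_independence()`,
  `exceedance_sweep()`).
* **Depth profiling** — exact (anisotropic, 2-D/3-D) Euclidean distance
  from the specimen exterior and mean-intensity-versus-depth profiles
  with optional exclusion masks (`exterior_distance_map()`,
  `profile_by_depth()`).
* **Pipeline orchestration** — `run_pipeline()` drives
  simulate → preprocess → minmax/occupancy/depth from one seeded
  configuration (R list or YAML) and writes all artifacts
  deterministically; `inst/scripts/run_pipeline.R` is a thin shell
  wrapper.

## The statistics at the core

For two mean-equalized imaging rounds *a*, *b* of the same stain, the
**minmax decomposition** forms a two-color composite with channels

    shared     = min(a, b)        (signal reproduced in both rounds)
    difference = |a − b|          (round-specific signal)

so that `shared + difference = max(a, b)` exactly, alongside the Pearson
correlation of the rounds and the histogram of
`log2((shared + 1)/(difference + 1))`. **Elution efficiency** is
`100·(1 − Σpost/Σpre)` per cent.

For *k* binarized channels, the **mutual-independence chi-squared** test
compares the observed 2^k pattern counts with expectations formed from
the empirical marginals,

    X² = Σ (O − E)²/E,   df = 2^k − 1 − k        (k = 3 → df = 4),

and the **exceedance ratio** of a channel subset *S* is

    P(jointly occupied) / Π_{c∈S} P(occupied in c),

equal to 1 under independence, swept over threshold percentiles from 1%
to 95%. Pixels are the sampling unit; the vignette discusses the
effective-sample-size caveat for diffraction-blurred images.

## A worked example

```r
library(cycloc)
res <- run_pipeline(list(seed = 1, output_dir = "demo_run"))
str(res$summary)
#> List of 7
#>  $ seed                  : num 1
#>  $ pearson_r             : num 0.953
#>  $ elution_efficiency_pct: num 90.1
#>  $ chi2_statistic        : num 1174163
#>  $ chi2_df               : num 4
#>  $ chi2_p_value          : num 0
#>  $ depth_bins            : int 6
```

This simulates a three-channel, three-round experiment under the default
study conditions (256×256 frames, 40 colocalization domains with channel
affinity 0.9, 5.5% post-elution residual), preprocesses it, and reports:

* `pearson_r` — correlation between rounds 1 and 3 of the same stain
  after background subtraction, registration and mean equalization
  (high, because only labeling stochasticity separates the rounds);
* `elution_efficiency_pct` — percentage of round-1 signal removed by the
  simulated elution (the noise-free generator residual is 5.5%, i.e.
  94.5% stripped; on noisy frames the global-sum estimator is biased a
  few points low, as discussed in the vignette);
* `chi2_statistic`/`chi2_df`/`chi2_p_value` — mutual-independence test
  over the Otsu-thresholded channels of round 1: the planted domains
  produce a massive departure from independence at 4 degrees of freedom;
* per-artifact CSVs in `demo_run/`, including the exceedance curve,
  where the triple-occupancy ratio rises above every pairwise ratio at
  stringent thresholds — the signature of genuinely shared domains.

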
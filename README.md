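# ca1quant

Quantification toolkit for studies of hippocampal CA1 microcircuitry under
cellular heterotopia — settings in which the single principal cell layer
(PCL) fragments into stacked deep and superficial bands and late-born,
calbindin-expressing pyramidal cells end up mispositioned. The package is
aimed at slice physiologists and anatomists who need the full quantitative
stack of such a study as tested, scriptable functions rather than
GUI-bound workflows.

Five analysis surfaces, each with a matching seeded synthetic-data
generator carrying known ground truth:

* **Morphometry** — SWC ingest, apical-tree isolation, and the
  branch-structure indices used to classify *complex* (calbindin-
  predictive) versus *simple* pyramidal cells. At the first prominent
  bifurcation (smaller daughter carrying ≥ 20% of the remaining cable),
  with soma-to-node path length `Lp`, daughter cable lengths `Ld1, Ld2`
  and daughter bifurcation counts `Nd1, Nd2`:

  ```
  LRI = ln((Ld1 + Ld2) / Lp)          ORI = ln((Nd1 + Nd2 + 2) / (Np + 1))
  ```

  both scaled by `D0/Lp` when `Lp > D0` (default 150 µm). Plus
  first-bifurcation distance and Sholl profiles.
* **Clustering** — supervised k-means (k = 2, k-means++ seeding, best of
  50 restarts, deterministic under a seed) on the (LRI, ORI) plane;
  z-score + PCA + k-means for the eight intrinsic-physiology features;
  elbow diagnostics; nearest-centre assignment of new cells; and
  morphology–physiology concordance tables.
* **Electrophysiology** — resting potential, sag index, input resistance
  and spike-train features from current-clamp sweeps; series-resistance
  QC (>30% change fails); wash-in percent-of-baseline in the 10–12 min
  window with the ≥30%-reduction inclusion rule; feedforward I/E ratios
  with monosynaptic subtraction.
* **Synaptic puncta** — max-intensity projection, Laplacian-of-Gaussian
  spot detection, the three distance rules (gephyrin within 1 µm of a
  soma; boutons within 1 µm of a retained gephyrin punctum; counting
  within 0.2 µm of a soma), and the innervation bias: summed counts on
  six calbindin-positive somas over summed counts on six negative ones.
* **Gamma-band LFP** — zero-phase 8–100 Hz band-pass, Welch spectra with
  the peak searched in 18–50 Hz, within-experiment normalized peak power,
  and FFT cross-correlation between deep and superficial channels with a
  signed millisecond lag (positive = deep leads).

A census module handles somatic-position bookkeeping (the PCL-front and
radial depth conventions, band marker fractions, normalized position
histograms, birth-dating colocalization), and `run_synthetic_study()`
orchestrates everything into one deterministic JSON report.

## Worked example

```r
library(ca1quant)

## classify a synthetic cohort from its branch indices
coh   <- gen_tree_cohort(n_complex = 30, n_simple = 30, seed = 7)
feats <- morpho_feature_table(coh)
km    <- km_cluster(as.matrix(feats[, c("lri", "ori")]), k = 2, seed = 7)
round(km$centers, 2)
#>     lri  ori
#> 1  1.15 1.81
#> 2 -0.35 0.21
mean(ifelse(km$labels == 1, "complex", "simple") == attr(coh, "truth"))
#> [1] 1

## two-channel gamma oscillation with a +1 ms injected lag and a 7% drug
## effect on power
ex  <- gen_lfp(f0_Hz = 25, lag_ms = 1.0, drug_power_factor = 0.93, seed = 7)
res <- analyze_lfp(ex$pre)
res$peak_freq_Hz          #> 25  (Hz)
res$xcorr$lag_at_max_ms   #> 0.9 (ms; one sample off the injected 1.0)

fs   <- ex$pre$sampling_rate
pre  <- power_spectrum(lfp_preprocess(ex$pre$channel_deep,  fs), fs)
post <- power_spectrum(lfp_preprocess(ex$post$channel_deep, fs), fs)
normalized_peak_power(pre, post)
#> [1] 0.929

## a puncta scene with a true calbindin preference of 1.32
scene <- gen_scene(bias = 1.32, seed = 7)
res2  <- quantify_scene(scene)
c(res2$total_pos, res2$total_neg, round(res2$bias_ratio, 3))
#> [1] 325  262  1.24
```

The cluster centres separate the complex (high LRI/ORI) and simple
archetypes cleanly and every cell is recovered; the oscillation analysis
returns the injected frequency, recovers the inter-channel lag to within
one sample at 10 kHz, and reads the drug's amplitude factor off the peak
bin; the single-scene bias estimate scatters around its true value of
1.32 (averaging over scenes tightens it — see the acceptance script).

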
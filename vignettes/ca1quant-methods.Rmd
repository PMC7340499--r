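---
title: "Quantifying CA1 microcircuitry under cellular heterotopia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CA1 microcircuitry under cellular heterotopia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca1quant)
```

## The scientific setting

In lissencephaly models the hippocampal CA1 principal cell layer (PCL) can
fragment into stacked deep and superficial bands. Late-born,
calbindin-expressing pyramidal cells — normally the superficial rows of the
PCL — end up mispositioned, and the question is which features of their
identity (morphology, intrinsic physiology, synaptic connectivity, network
dynamics) travel with them. `ca1quant` packages the quantitative stack such
a study needs: each module is usable on real tabulated data (SWC
reconstructions, feature tables, puncta/soma coordinate tables, sweeps,
two-channel field recordings) and on synthetic data with known ground
truth, so every estimator can be validated end to end.

## Morphometry: LRI, ORI, and the first prominent bifurcation

The apical tree is isolated from an SWC reconstruction
(`extract_apical()`), and the classifier works from two scalar summaries of
branch structure evaluated at the *first prominent bifurcation* along the
primary apical path:

* walking from the soma, at each branch point the daughters' shares of the
  remaining apical cable are computed; the first node whose smaller
  daughter carries at least `prominence_frac` (default 0.2) of the distal
  cable qualifies. This skips trivial twigs while catching the genuine
  split of the apical tuft.
* at that node, with soma-to-node path length $L_p$, daughter-subtree cable
  lengths $L_{d1}, L_{d2}$ and daughter-subtree bifurcation counts
  $N_{d1}, N_{d2}$ (with $N_p$ skipped non-prominent bifurcations):

$$\mathrm{LRI} = \ln\frac{L_{d1}+L_{d2}}{L_p}, \qquad
  \mathrm{ORI} = \ln\frac{N_{d1}+N_{d2}+2}{N_p+1}.$$

* when the selected node is distant from the soma ($L_p > D_0$, default
  $D_0 = 150\,\mu m$) both indices are scaled by $D_0/L_p$, damping the
  influence of long-trunk cells whose ratios are otherwise dominated by a
  large denominator.

These formulas are the package's documented defaults, exposed behind
`index_config()` and an `index_fun` hook so an alternative definition with
the same inputs can be swapped in without touching the classification
contract (complex cells score high on both axes). Cells whose apical tree
never bifurcates are flagged `defined = FALSE` and excluded from
clustering rather than given an arbitrary score.

Sholl profiles (`sholl()`, default 20 µm steps) count sphere crossings by
linear interpolation of the radial distance along each segment —
tangential double-crossings within one segment are not counted, which at
10 µm sampling is negligible. The primary-path rule (follow the daughter
with greater subtree cable, ties to the lower node id) and all tie rules
are deterministic so repeated analyses agree exactly.

## Clustering: supervised k-means and PCA

Morphological classification runs k-means with $k = 2$ on the raw (LRI,
ORI) plane, mirroring how such two-archetype sorting is done in practice;
`elbow_wss()` provides the within-cluster-sum-of-squares diagnostic that
justifies $k = 2$. Lloyd iterations are delegated to `stats::kmeans`;
k-means++ seeding with `n_init = 50` restarts (best by WSS) plus a fixed
seed removes initialization ambiguity. Cluster *indices* are assigned
post hoc by ordering centres on their coordinate sum — cluster 1 is always
the high-LRI/ORI (complex) cluster — never by whatever the initialization
produced. `assign_new()` places later recordings (e.g. reporter-confirmed
calbindin cells) by nearest centre, ties to the lower index.

Physiological clustering z-scores the eight intrinsic features before PCA
(`zscore_pca()`), because they span mV, MΩ and Hz scales and input
resistance would otherwise dominate the distances. PCA component signs
follow the convention that each loading's largest-magnitude entry is
positive, making scores reproducible across column orderings. k-means then
runs on the first two component scores (configurable), and
`concordance()` crosses the physiological labels with the morphological
ones through a majority-matched contingency table. Cells missing any
feature are dropped with their ids recorded, not imputed.

## Intrinsic electrophysiology

The eight clustering features are extracted from current-clamp sweeps with
fixed, documented conventions (the acquisition literature varies, so each
is a parameter):

* resting potential: mean of a ≥100 ms zero-current baseline;
* sag index: $\Delta V_{ss}/\Delta V_{peak}$ on the hyperpolarizing step
  (steady state = last 20% of the step); 1 means no sag;
* input resistance: steady-state deflection regressed on injected current
  through the origin;
* spike features at twice rheobase: threshold at the first upward crossing
  of $dV/dt \ge 20$ mV/ms, amplitude peak-to-threshold, AHP as the drop
  from threshold within 20 ms of the peak, adaptation ratio last/first
  inter-spike interval, rate as count over step duration.

Recordings whose series resistance varies by more than 30% fail QC
(`series_resistance_qc()`). Wash-in pharmacology summarises evoked-event
amplitudes as percent of baseline, with the assay window at 10–12 min
after drug onset (both windows inclusive) and the rule that experiments
not reduced by at least 30% are excluded — the boundary case (exactly 30%
reduction) is included. The feedforward inhibition:excitation ratio
subtracts the monosynaptic IPSC component measured under glutamatergic
blockade when available and uses the total IPSC otherwise, matching the
pooled stimulation designs these experiments use.

## Synaptic puncta

Puncta quantification is 2D on a thin maximum-intensity projection.
Detection (`detect_puncta()`) is scale-matched Laplacian-of-Gaussian blob
detection with $\sigma = d/(2\sqrt2)$ for an expected diameter $d$
(default 0.25 µm, a gephyrin punctum), a robust background threshold
(median + 4·MAD by default) and intensity-weighted sub-pixel centroids.
The three distance rules are:

1. gephyrin puncta within 1 µm of a soma contour are retained (interior
   counts as distance zero);
2. presynaptic boutons within 1 µm (centroid-to-centroid) of a retained
   gephyrin punctum are "true" inhibitory puncta;
3. surviving puncta within 0.2 µm of an analysis soma are counted, each at
   most once, assigned to the nearest soma with ties to the lower id.

Puncta–soma distances are centroid-to-polygon-boundary; the alternative
(surface-to-surface) convention is reachable by padding the radii, and the
choice is documented because commercial surface-based tools do not state
theirs. The innervation bias divides summed counts on the six
marker-positive somas by summed counts on the six marker-negative somas
(sum-then-divide, not a mean of per-soma ratios); values above one mean a
preference for calbindin-expressing targets.

## Gamma-band field potentials

Both channels are mean-subtracted and band-passed 8–100 Hz with a
zero-phase (forward–backward) Butterworth filter; two poles per band edge,
with the effective attenuation doubled by the bidirectional pass. Spectra
use Welch averaging (1 s Hann segments, 50% overlap), giving 1 Hz
resolution over the 18–50 Hz gamma band in which the peak is searched.
Power is scaled so bins sum to the signal's mean square; the reported
"Vrms at peak" is the square root of the peak-bin power, which retains a
Hann-window factor of $\sqrt{2/3}$ for a pure tone — irrelevant in
practice because power is only ever compared *within* experiment:
`normalized_peak_power()` locates the peak in the baseline spectrum and
reads that same bin in the wash-in spectrum.

Cross-correlation between the deep and superficial channels is computed in
the frequency domain. The product of one channel's conjugated transform
with the other's is inverted and the maximum of the real part taken as the
correlation summary; the signed lag at that maximum is the temporal shift.
Zero-padding makes this a linear (not circular) correlation — the raw
transform product is circular, and wrap-around would alias lags near the
window edges; a `circular = TRUE` switch preserves the strict formula.
Curves are averaged over 1 s windows by default. The sign convention is
fixed by this package: positive lag means the deep channel leads the
superficial channel. Peak ties resolve to the smallest absolute lag, then
to the positive one.

## The synthetic-data generators

Each generator is seeded, draws from its own stream (leaving the caller's
RNG untouched), and emits its ground truth alongside the data.

* `gen_tree()` grows two apical archetypes in 10 µm steps: *complex* trees
  bifurcate at 150–250 µm and branch densely beyond (the first three
  branch generations always split, then a 0.18 per-step probability within
  100 µm of the first bifurcation), *simple* trees run a 300–400 µm trunk
  with sparse daughters. Branch termination ramps up past a distance
  measured from the first bifurcation, which keeps late-bifurcating trees
  from being truncated. The complex defaults were calibrated once so that
  a wild-type-like cohort's Sholl profiles peak at 8–11 crossings (the
  published scale for such cells), 200–280 µm from the soma.
* `gen_physiology()` draws the eight intrinsic features from per-class
  normals. The three class means that are published for wild-type
  complex/simple cells (RMP −63.3/−60.3 mV, sag 0.75/0.79, input
  resistance 120.4/149.3 MΩ) are used directly; the five unpublished ones
  are realistic CA1 values with modest class differences. At the default
  noise the classes overlap deliberately, so PCA + k-means recovers the
  class only loosely (≈60–90% concordance) — mirroring the partial
  morphology–physiology correspondence seen in real recordings, and
  giving the concordance machinery something non-trivial to measure.
* `gen_washin()` draws lognormal event noise (CV 0.1) around a baseline
  that steps to `drug_factor` with a 1-minute exponential approach.
* `gen_scene()` builds 6 + 6 elliptical somas; bouton counts per soma are
  Poisson with class rates in ratio `bias`, boutons sit on the perimeter
  (±0.1 µm) with a paired gephyrin punctum within 0.15 µm, and distractor
  puncta (off-soma boutons, unpaired gephyrin) exercise the filters.
* `gen_lfp()` shares one narrow-band oscillator (filtered noise peaked at
  `f0`) between channels, delays the superficial copy by the injected lag,
  and adds independent white noise at the stated SNR. The drug condition
  scales the *same* oscillator realization and redraws only the noise —
  the drug acts on the ongoing oscillation, so the within-experiment
  normalization is measuring a real amplitude change rather than the
  difference between two independent realizations.
* `gen_census()` places DAPI somas uniformly per band and assigns the
  marker by the stated per-band probability.

What the generators do *not* emulate is worth stating: trees have no
tortuosity beyond small angular jitter and no reconstruction errors;
physiology features are independent normals, not correlated within cell;
scenes have no uneven illumination or antibody background gradients; the
oscillator is stationary with white (not 1/f) channel noise; censuses have
no spatial clustering of cell types. Passing tests therefore demonstrate
estimator correctness under clean conditions and calibrated sensitivity to
the effects of interest — not robustness to every artifact of real tissue.

## Numerical and design choices

* All tie rules (primary path, nearest centre, nearest soma, correlation
  peak) are documented and deterministic; reports are byte-identical at a
  fixed seed.
* Error conditions carry typed classes (`ca1quant_*_error`) so callers can
  distinguish malformed input from precondition violations.
* The polygon geometry (point-in-polygon, point-to-boundary distance) is
  implemented in the package and verified against brute-force
  re-derivations in the test suite.
* The elbow diagnostic reuses the $k-1$ solution (plus the worst-fit
  point) as a candidate start for $k$, guaranteeing the reported WSS curve
  is non-increasing — best-of-restarts alone does not.
* Analysis problem sizes in the bundled synthetic study
  (`run_synthetic_study()`: 30 trees and 40 physiology cells per class,
  5 scenes per condition, 5 two-channel experiments of 10 s at 10 kHz)
  were chosen so the statistical targets are comfortably resolved while a
  full run stays interactive on a laptop; every size is a parameter.

## Known limitations

* The branch-index formulas are this package's documented defaults for a
  family of length- and node-ratio definitions that appear in the
  literature in slightly different forms; the `index_fun` hook exists
  precisely so a lab's exact variant can be transcribed and compared.
* Sholl counting by endpoint interpolation undercounts segments that enter
  and exit a shell between samples; at ≤10 µm sampling this is below one
  crossing per cell in practice.
* `detect_puncta()` assumes approximately isotropic spots at a known
  scale; strongly elongated or out-of-focus puncta need a different
  detector (the coordinate-table entry point skips detection entirely).
* The cross-correlation's absolute magnitude depends on windowing and
  normalization conventions and is only comparable within this
  implementation; lags and within-experiment contrasts are the portable
  quantities.
* Depth conventions assume the landmark polylines bracket the cells;
  somas beyond a landmark produce a warning, not an error, because real
  sections contain such cells.
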
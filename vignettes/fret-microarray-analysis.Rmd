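---
title: "Quantifying signaling dynamics on FRET biosensor cell microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying signaling dynamics on FRET biosensor cell microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretarray)
library(dplyr)
```

## The measurement problem

Genetically encoded FRET biosensors report the activity of a kinase or
GTPase as the ratio of acceptor (FRET/YFP) to donor (CFP) emission. Printing
an array of biosensor plasmids as spots on one imaging dish and seeding
cells on top places dozens of reporters under strictly identical conditions:
one time-lapse movie per spot yields single-cell activity trajectories for
every node of a signaling network at once. `fretarray` implements the
complete analysis chain for such experiments, together with a synthetic-data
generator that provides ground-truth-annotated inputs, so every stage of the
chain is testable against known answers.

The measured quantity per cell and frame is

$$R(t) = \frac{\langle I_\mathrm{FRET}\rangle_\mathrm{ROI}}
              {\langle I_\mathrm{CFP}\rangle_\mathrm{ROI}},$$

which for a resting ratio $R_0$ and fractional activity $a(t)$ behaves as
$R(t) = R_0\,(1 + a(t))$, independent of how much biosensor the cell
expresses. That ratiometric invariance is the central property the image
pipeline must preserve, and the generator is built so the property is exact
on noiseless renders.

## The synthetic-data generator

The generator emulates the statistical structure the downstream analysis
relies on, not optical realism.

* **Layout** — spots on a regular grid (default 16 × 24 = 384 spots,
  200 µm diameter). The default pitch is 1125 µm; printed arrays are
  sometimes described with a pitch given in µm-scale numbers that are
  physically inconsistent with the spot size, so the pitch is an explicit
  parameter rather than an assertion.
* **Kinetics** — activity after stimulation at $t_0$ follows a
  rise-times-decay transient scaled by a Hill dose factor:
  $a(t) = A\,H(c)\,(1-e^{-\Delta t/\tau_r})\,e^{-\Delta t/\tau_d}$ with
  $H(c) = c^n/(c^n + \mathrm{EC}_{50}^n)$, $\Delta t = t - t_0$. The
  response classes carry amplitude presets of 0.4 (strong), 0.15 (middle)
  and 0.05 (weak) fractional ratio change with progressively slower rise
  and decay constants; these magnitudes are package defaults chosen to span
  the dynamic range typical of single-chain FRET reporters, and are fully
  configurable. Per-cell amplitudes are log-normal with mean one
  (CV 0.25 by default); a configurable fraction of cells receives a
  periodic (pulsatile) modulation.
* **Combined stimuli** — with two stimuli the population response is the
  *sum* of the single-stimulus responses plus an interaction term
  $\gamma\,(r_A(t)+r_B(t))/2$. $\gamma = 0$ therefore gives additivity by
  construction (the null the interaction score must respect), and
  $\gamma = \pm 0.5$ injects a non-additive AUC component equal to half the
  mean single-stimulus AUC — the effect size used in the power analyses.
* **Images** — cells are filled ellipses with concentric nuclear discs;
  CFP foreground is the cell's expression $E(t)$, FRET foreground is
  $E(t)\,R_0(1+a(t))$, and the nuclear channel marks nucleus positions.
  Expression rises linearly (0.2%/min by default), so channel intensities
  increase over a movie while the true ratio stays flat — exactly the drift
  that vehicle normalization must remove. A constant camera offset
  (100 a.u., 16-bit range) and Gaussian read noise complete the model.

What the generator does **not** emulate: point-spread blur, photobleaching
beyond the shared drift term, cell division, migration beyond optional
centroid jitter, and spectral bleed-through. Passing tests therefore
demonstrate correctness of the computations, not robustness to every
artifact of real microscopy.

## Image quantification

Per frame and channel, the chain is:

1. **Triangle background subtraction.** The Triangle threshold is computed
   on a 256-bin histogram of the frame; the mean of all pixels at or below
   the threshold is subtracted from every pixel. A 256-bin histogram
   matches common practice and keeps the exhaustive oracle used in the
   tests cheap.
2. **Median filtering** with a circular radius-2 neighbourhood (13 pixels),
   output in floating point.
3. **Huang masking.** The minimal-fuzziness threshold defines the cell
   mask on the CFP channel; pixels at or below it — intensity close to
   background — are set to `NaN` in both channels. Defining "close to
   background" as "below the Huang threshold" is the one self-consistent
   reading of that rule, and `NaN` pixels never enter any ROI mean.
4. **Nucleus-seeded segmentation.** The nuclear channel is
   Triangle-thresholded to a nucleus mask; connected nuclei seed a
   partition of the cell mask on its distance transform, splitting touching
   cells along the midline between their nuclei. Regions below
   `min_area = 50` px are discarded (the particle-analyzer size gate; the
   area gate is a free parameter because small debris is
   implementation-dependent).
5. **ROI measurement** — per label, means of the non-`NaN` pixels of each
   channel and their ratio.
6. **Tracking.** Frames are segmented independently and ROIs linked by
   greedy nearest-centroid matching with a 15 px displacement cap;
   unmatched ROIs start new tracks. Per-frame thresholding plus linking is
   an assumption (a movie-wide threshold is equally defensible); it is the
   more robust choice under the rising-expression drift.
7. **Expression gate.** Cells are kept when their mean *pre-stimulus* CFP
   lies in [700, 8000] a.u.; the pre-stimulus window is the package's
   choice of gate time point.

On noiseless synthetic stacks the recovered ROI ratio equals
$R_0(1+a(t))$ to within $10^{-6}$ (in practice, machine precision); with
read noise at 5% of the signal, the median relative error stays below 2%.

## Trajectory normalization

Each cell's ratio trace is divided by its own pre-stimulus mean (baseline
normalization, requiring at least two pre-stimulus points) and by the mean
trace of vehicle-treated cells at each time point (vehicle normalization,
removing expression drift and bleaching). Both operations demand identical
time grids — no silent interpolation. Condition summaries are the pointwise
mean ± SEM over all cells pooled across replicate experiments.
Reproducibility is summarized as the coefficient of variation over
replicate mean traces at each time point, averaged over time; whether the
CV is computed before or after max-normalization is configurable, since
either convention is defensible. The expression-response check correlates
per-cell pre-stimulus CFP with the maximal normalized ratio using Kendall's
tau-b (exact p below 50 untied pairs, normal approximation otherwise);
"expression level" is operationalized as pre-stimulus mean CFP.

## Dynamic signatures

Two clustering views are provided. Mean-response *fingerprints*
(biosensor × time matrices, max-normalized per row) are clustered
hierarchically with the Euclidean metric and Ward's linkage (`ward.D2`),
the one metric/linkage combination stated for this class of analysis;
cutting at $k=3$ separates strong/middle/weak response classes. Pooled
single-cell trajectories are clustered per biosensor across all treatments
by squared-Euclidean K-means into $k=6$ dynamic patterns (k-means++
initialization, best of 25 restarts, fixed seed — the restarts make the
fixed-seed result effectively initialization-independent). Per-biosensor
pooling is used because cross-biosensor pooling would mix reporters with
different dynamic ranges. Trajectories are linearly interpolated to a
common grid spanning the overlap of all cells before clustering. Each
condition's *dynamic signature* is the vector of proportions of its cells
over the k patterns; with 300 cells per condition, planted mixture weights
are recovered within three binomial standard errors.

## Condition-level PCA

Normalized mean responses are stacked into a (group × time point) ×
biosensor matrix — four groups of 85 time points over 14 biosensors give a
340 × 14 matrix — then centered, scaled to unit column variance, and
decomposed by SVD (`prcomp`). Scores carry a deterministic sign convention
(largest-magnitude loading positive per component). Group outlines are
*empirical* coverage ellipses: the Gaussian ellipse of the group's score
cloud scaled to the smallest Mahalanobis radius whose achieved coverage
reaches the requested fraction of actual points (70% or 80% are the usual
choices). An empirical quantile is used rather than a parametric χ²
radius because the stated coverage refers to observed time points, not to
a fitted distribution.

## The interaction (synergy) score

For stimulus pair (A, B) and each biosensor:

1. Normalize each cell: divide by the pre-stimulus mean and by the
   untreated mean at each time point, subtract 1. "Untreated" is taken to
   be the vehicle condition.
2. Trapezoidal AUC of the centered trace from the stimulation time to the
   end of the movie (negative excursions subtract); the integration rule
   is the package's choice.
3. Shapiro-Wilk normality of each AUC sample is computed and reported, not
   used as a branch.
4. Additive expectation: $\mu_{exp} = \mu_A + \mu_B$ with
   $\mathrm{SEM}_{exp} = \sqrt{\mathrm{SEM}_A^2 + \mathrm{SEM}_B^2}$.
5. The raw score is $S_s = \mu_{AB} - \mu_{exp}$; $S_s = 0$ is additivity,
   $S_s > 0$ synergy, $S_s < 0$ antagonism. Because the expectation is a
   derived quantity rather than a sample, the "two-sample t test against
   the expected mean" is implemented as a Welch-type test:
   $t = S_s / \sqrt{\mathrm{SEM}_{AB}^2 + \mathrm{SEM}_{exp}^2}$ with
   Welch–Satterthwaite degrees of freedom assembled from the three
   contributing samples. This is the one formulation consistent with both
   the additive expectation and the error propagation above.
6. P values are corrected across all biosensor × pair tests by
   Benjamini–Hochberg (Holm and Bonferroni available); the mask threshold
   is applied to *adjusted* p values for consistency with the correction.
7. Scores are scaled per biosensor by the maximum absolute raw score to
   [−1, 1]; entries with $p_{adj} \ge \alpha$ (default 0.05) are masked.
8. The synergy map clusters the biosensor × pair matrix of scaled scores
   (Euclidean, Ward); masked entries contribute 0 to distances, the
   neutral value on the score scale.

Under the generator's additive null ($\gamma = 0$, 200 cells/arm) the test
holds its type-I level after correction, and injected interactions of half
the single-stimulus AUC scale are detected with the correct sign in ≥95%
of simulations.

## Numerical choices and degenerate inputs

* Histograms use 256 fixed-width bins over the observed range; thresholds
  are reported as bin upper edges. Constant images short-circuit: the
  background is the constant, and a uniform bright frame is all
  foreground, while a uniform zero frame is all background (empty mask,
  warning).
* Huang fuzziness uses Shannon entropy of memberships
  $u = 1/(1+|g-\mu|/C)$ with ties broken toward the lower threshold.
* K-means uses Lloyd iterations from k-means++ seeds; ties across restarts
  resolve to the first-best objective.
* Zero combined standard error in the interaction test yields $p = 1$ for
  a zero difference and $p = 0$ with a warning otherwise.
* An all-zero score set for a biosensor scales to all zeros (no 0/0).
* Degenerate score covariance in a coverage ellipse falls back to an
  axis-aligned bounding ellipse with a warning.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script run entirely on generated
data at sizes chosen to make the statistical checks sharp yet quick on a
laptop: 100 random histograms for the threshold oracles; 20 cells × 100
frames (256² px) for quantification recovery; 200 simulations × 4 arms ×
200 cells for the type-I and sign-recovery properties of the interaction
score; 600 cells over six planted patterns for signature recovery. The
end-to-end demo (`demo_config()`) uses two biosensors, four conditions and
five cells per spot at 96² px.

## Known limitations

* Tracking is greedy nearest-neighbour: adequate for sessile epithelial
  cells at 3-min sampling, inadequate for fast-migrating cells; tracks are
  never merged or split.
* The watershed split assumes one nucleus per cell; binucleate cells are
  split in two.
* Vehicle normalization assumes drift is shared between treated and
  vehicle cells (multiplicative, condition-independent).
* The additive AUC expectation is a single-number interaction summary; it
  cannot distinguish early-phase synergy from late-phase antagonism within
  one trace, and it is not a dose-response surface model (no Bliss/Loewe).

## A minimal session

```{r, eval = FALSE}
library(fretarray)
cfg <- demo_config(out_dir = "demo_out", seed = 1)
run_pipeline(cfg)

scores <- readr::read_csv(file.path("demo_out", "synergy.csv"))
map <- synergy_map(scores)
plot_synergy_map(map)
```
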
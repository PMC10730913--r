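---
title: "Decoding, segmentation and integration for targeted in situ transcriptomics"
author: "punctate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding, segmentation and integration for targeted in situ transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctate)
```

## The measurement model

Targeted in situ platforms read out a panel of genes by hybridizing
fluorescent probes to rolling-circle-amplified (RCA) products over repeated
imaging cycles. Each gene is assigned a *codeword*: a binary signature over
the `n_cycles x n_channels` grid saying in which cycle/channel combinations
its RCA products light up. A bound transcript appears as a *punctum* — a
sub-pixel point source — whose per-cycle, per-channel brightness traces out
its gene's codeword, corrupted by chemistry and imaging noise. The
computational task is to invert this: detect puncta, decide which codeword
each one most plausibly emitted, quantify the confidence of that call on a
calibrated Phred scale, and assign each transcript to a cell.

`punctate` implements this pipeline end to end, together with a forward
simulator that generates ground-truth tissues and signals with the
statistical structure the pipeline assumes, and the integration operations
used downstream: k-nearest-neighbor label transfer from a single-cell
reference, binning of transcripts into a hexagonal spot array, and
landmark-based coordinate registration.

## Codebook design

Codebooks are constant-weight binary codes: every codeword switches on
exactly `weight` of the `n_cycles * n_channels` bits, and every pair of
codewords differs in at least `min_hamming` positions. With the defaults
(weight 4, minimum Hamming distance 4 on a 15 x 4 grid), a single dropped or
spurious bit can never convert one codeword into another, which is the
property that makes error *detection and correction* possible at decode
time. The commercial panels this mirrors do not disclose their code
parameters; weight-4 / distance-4 is the well-understood constant-weight
scheme used by combinatorial FISH methods and is exposed as a parameter
rather than hard-coded.

Codes are found by seeded randomized greedy search with rejection: candidate
weight-`weight` codes are drawn uniformly and kept when they respect the
distance constraint against all accepted codes. The search is bitwise
reproducible given its seed and raises an explicit "codebook infeasible"
error when the requested number of codes cannot be placed within a bounded
number of draws. Feasibility is a real constraint, not a formality: only
two mutually distance-4 weight-2 codes of length 4 exist, so a request for
three must fail.

Three control classes are carried alongside gene codes and satisfy identical
weight/distance constraints:

* **negative control probes** — real probes targeting non-biological
  sequence; their call rate estimates assay-level non-specific binding;
* **negative control codewords** (NCCs) — codebook entries with no matching
  probe; calls to them can only be decoding errors, which is what makes
  quality calibration possible;
* **unassigned codewords** — spare codes kept in the codebook so the decoder
  scores them like any other hypothesis.

## Forward simulation

The simulator is the package's source of ground truth and defines the
conditions under which every guarantee is tested. Its parts:

* **Tissue**: `n_cells` non-overlapping circular cells with concentric
  circular nuclei are placed by bounded rejection sampling. Discs are
  deliberately minimal geometry — every assignment contract (distance caps,
  territory boundaries, containment) is exercised by them without the
  irregular shapes real segmentation produces.
* **Expression**: each cell draws a type from the configured mixture and a
  negative binomial transcript load (default mean 166 per cell, matching
  a typical high-plex panel run; dispersion `size = 3`); genes are drawn in
  proportion to the type's profile and scattered uniformly inside the cell.
* **Signals**: each transcript emits one punctum whose bit states start at
  its codeword; on-bits drop out with `p_dropout`, off-bits light with
  `p_spurious`, and per-bit intensities are log-normal around `mu_on` /
  `mu_off` (defaults `log(1000)` and `log(50)` photons with sigma 0.4,
  i.e. about a 20-fold on/off contrast with overlapping tails).
* **Background**: false puncta are scattered uniformly at `background_rate`
  per 100 x 100 um tile, drawing their features uniformly from gene and
  negative-control-probe codes; their random bit patterns are what sometimes
  decode to NCCs, which calibration depends on.
* **Images**: puncta render as isotropic Gaussians (default sigma 1 pixel at
  0.5 um/pixel) with peak amplitude equal to the per-bit intensity, plus
  optional Poisson shot noise.

The simulation is two-dimensional. The decoding, calibration and assignment
mathematics are dimension-agnostic, so a single plane exercises every code
path; `z` coordinates are carried as zero throughout. What the simulator
does **not** emulate: irregular cell morphology, optical crosstalk between
channels, cell-density gradients, autofluorescence, or spatially correlated
dropout. Tests passing on these simulations therefore demonstrate
correctness of the algorithms under the stated noise model, not performance
on any particular tissue.

## Punctum detection

Detection runs on the max-projection over all cycles and channels, so each
RCA product is found once; per-plane intensities are then measured at the
fitted position. (Per-cycle detection followed by linking would need a
merging rule that is not well defined; the max-projection sidesteps it.)
Candidates are 8-neighborhood local maxima rising at least `min_prominence`
above the local background, estimated as the median of the fit-window
perimeter. Each candidate is refined by least-squares isotropic 2D Gaussian
fit (amplitude, sub-pixel center, sigma, offset); fits that do not converge
or whose sigma exceeds `max_sigma` are discarded as non-punctate. Per-bit
intensities are weighted-least-squares Gaussian amplitudes per plane, which
puts detected intensities on the same scale the simulator draws from.

## Maximum-likelihood decoding and raw quality

Intensities are modeled as independent per-bit Gaussians on log-intensity
with state-dependent parameters (`mu_on`, `sigma_on` / `mu_off`,
`sigma_off`). For observation $y$ (log-intensities) and codeword $c$:

$$\log L(c \mid y) = \sum_b \log \phi\!\left(y_b;\, \mu_{c_b}, \sigma_{c_b}\right)$$

Every codebook entry — gene, control and unassigned alike — is scored under
a uniform prior, and the call is the maximizer (ties to the lowest code id,
making decoding deterministic). The posterior $p_{best}$ is the softmax over
all codewords, and the raw Phred quality is

$$\mathrm{raw\_q} = \min\!\left(q_{cap},\, -10 \log_{10}(1 - p_{best})\right)$$

with `q_cap = 40` (the standard Phred cap). Computed this way the raw score
lives on a Phred scale before calibration: an observation exactly ambiguous
between two codes gets $-10\log_{10}(0.5) \approx 3.01$. Numerically,
$\log(1-p_{best})$ is evaluated as the log-sum-exp of the non-best scores
minus the log-sum-exp of all scores, which stays finite when $p_{best}$
approaches 1. The published platform describes only "maximum likelihood"
decoding with a margin-derived quality; the per-bit Gaussian form here is
the simplest model consistent with intensities driving the decision, and the
noise parameters can either come from the simulation config or be estimated
from data by two-component moment matching (`estimate_noise_model()`).

Decoding is single-pass: no cross-field-of-view re-estimation of intensities
is attempted.

## Quality calibration against negative control codewords

Raw scores are only as good as the noise model; the calibrated score is
anchored to an internal control. Within each raw-quality bin, the
per-control-codeword false-call rate is

$$r = \frac{n_{ncc} + 1}{N_{ncc\ codes}}$$

(the +1 pseudocount keeps empty bins finite and conservative, in the spirit
of the rule of three). Scaling by the number of gene codes converts this to
an expected count of false gene calls, and dividing by the observed gene
calls in the bin gives the estimated false discovery rate:

$$\widehat{FDR} = \min\!\left(1,\; r \cdot \frac{N_{gene\ codes}}{\max(1, n_{gene\ calls})}\right),
\qquad qv = \min\!\left(q_{cap}, -10\log_{10}\widehat{FDR}\right)$$

Bins are equal-width over `[0, q_cap]` (default 20 bins); bins with fewer
than 50 calls are merged left-to-right before estimation so no estimate
rests on a handful of calls. A weighted pool-adjacent-violators pass then
enforces that `qv` is non-decreasing in raw quality — a violation can only
be sampling noise, since a better likelihood margin cannot be genuinely less
reliable. Every transcript receives its bin's `qv`, and the default
downstream filter keeps `qv >= 20` (nominal 1% error). Applying a fitted
calibration table is idempotent and independent of which transcripts were
used to fit it.

The pseudocount has a visible consequence at small scale: with few NCC codes
and few calls, the +1 dominates and the calibrated score is pessimistic. A
run whose top bin sits exactly at the nominal 1% false rate can land on
either side of the Q20 threshold; this is the correct behavior of a
conservative estimator at its boundary, not an instability.

## Cell segmentation and transcript assignment

Nucleus masks (a 2D integer label raster) are an input; the package
implements the expansion and assignment stages. Expansion is a
distance-capped generalized Voronoi transform: every background pixel within
`max_expansion` (default 15 um) of at least one nucleus takes the label of
the *nearest nucleus mask* (Euclidean distance between pixel centers,
distance to the mask rather than the centroid — this is what "expanding
outwards" means for non-point nuclei). Expansion thus stops at either the
distance cap or the territory of a nearer nucleus, and territories are
disjoint by construction. Exact ties go to the lower label id, which is
implemented exactly: the labeled exact Euclidean distance transform (a
Felzenszwalb-Huttenlocher separable transform run per label over a padded
bounding box, in C++) updates a pixel only on strict improvement while
labels are processed in ascending order.

Transcripts get the label of the raster pixel containing their position
(half-open pixel intervals, origin at 0 um, x rightward, y downward);
positions in background or out of bounds are unassigned (cell id 0).
Quantization is the only source of disagreement with an exact vector-space
assignment, and it is confined to points within one pixel of a territory
boundary. The cell-feature matrix then tabulates quality-filtered, assigned
transcripts into a sparse cells x features count matrix; control features
are kept as separate columns for QC and dropped via `gene_matrix()` for
analysis.

## Integration

**Label transfer.** The reference pipeline is standard single-cell practice:
size-normalize each cell to the reference median total, `log1p`, z-score per
gene, PCA (top 50 PCs). Query cells are normalized with the *reference*
statistics and projected onto the reference loadings; each query cell's 30
nearest reference neighbors vote, and a label is assigned only if the modal
label is unique and reaches at least `ceiling(majority * k)` votes (15 of 30
at the default 50%), otherwise the cell is "unlabeled". One behavioral
consequence worth knowing: with only two candidate labels among the
neighbors, one of them always holds at least 15 votes, so a cell exactly
between two types is still labeled unless the split is exactly 15/15 (a tie
is unlabeled). Genuinely ambiguous "unlabeled" calls arise when the vote
splits three or more ways.

**Spot interpolation.** Transcripts (or cell centroids) are binned to their
nearest spot center on a standard hexagonal capture grid (100 um pitch,
55 um spot diameter), ties to the lower spot index. Without a capture
radius the binning is a partition, so per-feature totals are conserved
exactly — the property the conservation tests assert. The spot x feature
pseudobulk this produces is the input a deconvolution method would take;
deconvolution itself is delegated to existing packages.

**Registration.** Landmark pairs are fit by RANSAC: minimal samples (2
points for rigid/similarity via the closed-form Umeyama solution, 3 for
affine, 4 for homography via the normalized DLT), consensus at `inlier_tol`
(default 5 um), and a final least-squares refit on the best consensus.
Degenerate (collinear or coincident) samples are skipped, sampling is
deterministic given the seed, and an input with no consensus raises an
error rather than returning a silent misfit.

## QC metrics

* **Median gene sensitivity**: per-gene mean counts per cell, median over
  genes — the median keeps high expressors from dominating the summary.
* **Complexity**: the smallest number of genes covering half the counts.
* **Per-cell statistics**: transcripts and genes detected per cell with
  10th/50th/90th percentiles, computed by linear interpolation between order
  statistics (`quantile` type 7) so reported numbers are reproducible.
* **Control rates**: fractions of quality-filtered calls in each control
  category.
* **Downsampling**: binomial thinning with one global retention probability;
  expectation equals the target mean per cell and zeros are preserved
  exactly. (This thins counts, not reads — the package has no read-level
  data, so sequencing-depth downsampling is approximated at the count
  level.)
* **Replicate concordance**: squared Pearson correlation of per-gene
  `log10(total + 1)` pseudobulk between runs; the log scale is a choice
  (exposed as a parameter) since totals span orders of magnitude.

## Numerical and design choices

* Intensities are floored at `1e-6` before taking logs.
* Decoding ties break to the lowest code id; spot-binning ties to the lowest
  spot index; expansion ties to the lowest nucleus label. All three make the
  pipeline fully deterministic given its inputs.
* The calibration table's monotonicity is enforced by weighted PAVA with the
  bin occupancies as weights.
* Image stacks are written as 16-bit TIFF pages under a global linear scale
  recorded in a JSON sidecar; intensities round-trip to within half a grey
  level of the stack maximum.
* All simulator and search functions take explicit seeds and restore the
  caller's RNG state, so library calls never perturb a user's random stream.
* Empty inputs (no observations, no nuclei, all transcripts filtered) are
  contracts, not crashes: they produce empty outputs with declared
  dimensions or explicit errors naming the problem.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes on one core while still exercising every
guarantee at meaningful size: a 313-gene panel with 20 negative control
probes, 50 negative control codewords and 100 unassigned codewords;
simulated fields of 150-800 um with up to 200 cells and roughly 1e4-2e4
puncta; label transfer with 2000 reference and 2000 query cells over 5
types; registration with 100 landmarks at 30% outliers; three decoder noise
levels (`p_dropout` 0.01/0.03/0.06 with `p_spurious` 0.01).

## Known limitations

* The noise model assumes per-bit independence; correlated failures (a bad
  cycle, channel crosstalk) are neither simulated nor modeled.
* Nucleus segmentation itself is out of scope — masks are an input — so
  segmentation errors upstream of expansion are not represented.
* Spot interpolation assumes registration has already brought transcripts
  and spot centers into a shared frame; interpolation and registration
  compose but are not jointly optimized.
* The simulator's disc geometry understates transcript assignment ambiguity
  relative to real, irregular, tightly packed cells; assignment accuracy on
  real tissue will be lower than on these simulations.
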
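---
title: "Methods: fused fundus + OCT grading of macular edema"
author: "retfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fused fundus + OCT grading of macular edema}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Macular edema (ME) is the accumulation of extracellular fluid in the
macula. Its two routine imaging windows are complementary: OCT B-scans
show the retinal cross-section — layer boundaries, central thickening and
hypo-reflective intraretinal fluid — while fundus photographs show the
en-face surface — blood vessels, the optic disc and the bright hard
exudates that accompany ME. `retfuse` implements a fusion pipeline that
extracts these clinically significant findings from *both* modalities and
grades a subject as `healthy` or `me` with an ensemble classifier, plus
the EDTRS clinical-significance flag for lesions near the fovea.

The pipeline has five stages, each exposed as package functions:

1. **Modality recognition** — a small CNN tags each input as OCT or
   fundus (`recognizeModality`).
2. **Preprocessing** — annotation-row removal, degraded-region repair and
   adaptive Wiener denoising (`preprocessScan`).
3. **Finding extraction** — structure-tensor coherence analysis drives
   layer/fluid extraction on OCT and vessel/disc/exudate extraction on
   fundus (`extractOCTFindings`, `extractFundusFindings`).
4. **Feature extraction** — the findings are overlaid on the scan in a
   fixed colour coding and a per-modality feature CNN distills each
   annotated image into 8 values; the two blocks are concatenated into a
   16-D descriptor (`overlayFindings`, `predictCNN`, `fuseFeatures`).
5. **Diagnosis** — an ANN (16-12-9-2), an SVM (RBF or MLP kernel) and a
   Gaussian naive Bayes model each vote; the majority wins
   (`predictEnsemble`).

# Preprocessing

**Annotation rows.** Acquisition devices burn annotations into the top
and bottom of B-scans; the first and last 50 rows are set to zero
(`nRows`, configurable). The rule is applied to OCT scans by default and
to fundus scans only on request, since the artifact is characteristic of
B-scans.

**Degraded regions.** Saturated blocks at the scan margins are found per
column by locating the first and last *sharp* vertical transitions —
absolute one-step differences above `gradientThresh` (default 0.5 in
normalized intensity; anatomical edges are gentler once the optical point
spread is accounted for). The segment above the first and below the last
transition is replaced with the mean of the background (sub-Otsu) pixels,
but only when that segment is itself near-saturated (`satLevel`, default
0.8): the brightness guard keeps clean columns, whose outermost sharp
transitions are anatomy, untouched. Repair runs *before* annotation
stripping so that border-contact, which identifies a degraded block, is
not severed first.

**Wiener denoising.** Over a `wv × wh` window (default 5 × 5, symmetric
padding) the local mean $m$ and variance $s^2$ are estimated and

$$D = m + \frac{\max(s^2 - a^2,\, 0)}{s^2}\,(O - m),$$

with $D = m$ where $s^2 = 0$. The noise power $a^2$ defaults to the mean
of all local variances, the classical estimate for this filter: flat
regions (where $s^2 \le a^2$) collapse to their local mean while strong
structure passes through. A fixed $a^2$ can be supplied instead
(`denoiseParams`).

# Structure tensor and finding extraction

The second-moment structure tensor is computed from Gaussian-derivative
responses $\varphi_x, \varphi_y$ at scale `sigmaD` (default 1 px),
windowed by a Gaussian at scale `sigmaW` (default 3 px):
$T_{xx} = g_w * \varphi_x^2$, $T_{yy} = g_w * \varphi_y^2$,
$T_{xy} = g_w * (\varphi_x\varphi_y)$. The off-diagonal uses the product
of first derivatives — the outer-product form that keeps every per-pixel
2×2 matrix positive semidefinite, which the coherence
$c = ((\lambda_1-\lambda_2)/(\lambda_1+\lambda_2))^2$ requires. Channel
selection is fixed per modality: retinal layers are horizontal, so OCT
uses $T_{yy}$; vessels run in all directions, so fundus uses the
element-wise maximum of $T_{xx}$ and $T_{yy}$ (TMAX) — the fusion that
preserves the strongest response of either orientation (sum and
quadrature were the considered alternatives; the maximum does not dilute
a strongly oriented response with the orthogonal channel's noise).

**OCT layers.** Boundary candidates are Canny edge pixels. One wiring
decision matters here: Canny runs on the *denoised intensity*, not on the
$T_{yy}$ response. The response is already a ridge centred on each
boundary, so its edges flank every boundary twice at an offset of several
pixels; the intensity edges localize each transition once and exactly.
The tensor response still ranks candidates during tracing. Curves are
assembled greedily from the top of the scan: the topmost unused candidate
seeds a trace that proceeds column by column, accepting the nearest
unused candidate within the jump limit `J` (default 3 px, ties to the
stronger response), bridging gaps up to 8 columns. Traces covering at
least half the columns are kept (at most `k = 9`), median-smoothed over
15 columns, clamped to the jump limit, and ordered top to bottom; where a
curve would cross the running maximum of the curves above it, it is
blanked rather than projected, since a crossing marks unreliable
evidence. The topmost curve is the ILM. Of the bottom two curves, the one
overlying the brighter band is the RPE (the retinal pigment epithelium is
the brightest band in a B-scan); curves below it are discarded as
sub-retinal artifacts. A scan whose Canny edge density exceeds 8% has no
layered structure to trace and is rejected as unusable.

**Fovea.** The fovea is the deepest point of the smoothed ILM, ties
broken toward the image centre. The smoothing window default is 75
columns — roughly the width of the foveal pit at typical lateral pixel
pitch — because the argmax of a shallow parabola under residual tracing
noise is only as stable as the smoothing that precedes it.

**Fluid.** The ILM–RPE band mask multiplies the denoised scan; pixels
below `t` (default 0.5) times the mean in-band intensity are candidates,
a 3×3 opening removes speckle residue and components under `minArea`
(default 30 px) are dropped. Fluid is a subset of the band by
construction.

**Vessels.** The TMAX response is hysteresis-thresholded (`low` 0.04,
`high` 0.2 of the rescaled response). Because the Gaussian window smears
the tensor ridge well beyond the vessel walls, the raw hysteresis mask
over-covers thin vessels several-fold; the mask is therefore intersected
with pixels darker than `darkGate` (default 0.85) times the
field-of-view mean — vessels are dark structures, the halo is not. Short
components (bounding-box diagonal under `minLength` = 12 px; the
package has no thinning operator, so the diagonal stands in for skeleton
length) and everything outside the circular field of view are removed.

**Optic disc and exudates.** The disc is the argmax of the mean intensity
under a sliding disc (radius 40 px), reported only above a floor of 0.6 —
absence is a value, not an error. Exudate candidates must be bright
relative to the field of view (`tBright` = 1.3 times the FOV mean) *and*
pop out of a white top-hat (radius 8 px), i.e. be small-scale; the
top-hat alone also fires on bright slivers pinched between neighbouring
vessels, which the intensity test rejects. Candidates on the (slightly
dilated) vessel mask or within 1.5 disc radii of the disc are removed,
and components outside 5–2000 px are dropped.

**EDTRS grading.** ME is clinically significant when a lesion (fluid or
exudate) lies within 500 µm of the fovea centre. The rule uses lateral
(column) distance only, on the calibrated scan (`umPerPixel`); the
"foveal diameter of 500 micrometers" phrasing is interpreted as 500 µm
from the centre, the EDTRS convention, with the radius configurable.

# CNN feature extraction

The feature extractor is a 14-layer network: input with zero-center
normalization; conv 8×(9×9), batch norm, ReLU, 2×2 max pool; conv
16×(9×9), batch norm, ReLU, 50% dropout, 2×2 max pool; conv 32×(9×9),
batch norm, ReLU; and a final fully connected layer emitting 8 features.
`featureCNNConfig()` reproduces the published geometry at 227×227×3. The
network ends at the 8-unit layer; training attaches a detachable 2-class
softmax head and minimizes the cross-entropy $CL = -\sum_w I_w \log P_w$
by momentum SGD (lr 0.01, momentum 0.9, batch 16, all configurable), with
dropout active only during training. After the SGD loop the batch-norm
running statistics are recalibrated over the full training set at the
final weights — the exponentially averaged statistics lag the weights
they normalized, and inference-mode accuracy understates the fit without
this pass. At inference the head is discarded and the 8 activations are
read as features, so extraction is deterministic. One CNN is trained per modality on the overlaid scans, and
a third instance (same geometry) serves as the modality recognizer — the
pretrained-backbone transfer route is retained only as an architecture
description (`alexnetLayerTable`), since shipping external pretrained
weights is out of scope.

**Training scale.** The package trains these networks at a 48×48 input
raster by default (`cnn$inputSize`). The layer sequence is unchanged;
only the raster scales. 48 px preserves the overlay colours and the
coarse anatomy that drive class separation on the synthetic cohorts the
package documents (100-subject cohorts, 30 epochs), and it keeps a full
train-and-evaluate cycle in the tens-of-minutes range on a single CPU
core in plain R + BLAS. The engine (im2col convolution, batch norm,
pooling, dropout, SGD) is implemented in the package with small C++
kernels; training is bit-reproducible for a fixed seed.

# Ensemble diagnosis

Features are z-scored with training-split statistics before every
classifier; the scaler travels with the model bundle. The ANN is a
16-12-9-2 feed-forward network (sigmoid hidden layers, softmax output
pair — a 2-unit softmax rather than a single output unit, since softmax
on one unit is degenerate and the 2-unit form has the identical decision
function) trained by full-batch gradient descent. The SVM uses the
Gaussian RBF kernel by default ($C = 1$, $\gamma = 1/16$, i.e. one over
the feature dimension) with the tanh "MLP" kernel as the alternative.
Naive Bayes uses class-frequency priors and per-feature Gaussian
likelihoods with variances floored at $10^{-9}$, evaluated in log space.
The final label is the unweighted majority of the three votes (three
binary voters cannot tie); weighting the voters was considered and
rejected for want of any principled weight source. Diagnostic metrics
(SE, SP, PPV, NPV, A) follow the standard confusion-count formulas, with
`NA` for undefined denominators, and `dice(∅, ∅)` is defined as 1 so
that healthy subjects with empty truth masks score agreement.

# The synthetic phantom cohort

`generateOCTPhantom` renders stacked horizontal reflectivity bands
(distinct band reflectivities, the RPE band brightest), a parabolic
foveal dip (depth 45 px healthy, 22 px ME — edema shallows the pit and
thickens the central retina), optional bright annotation rows and
saturated degraded margins, 1–4 elliptical hypo-reflective fluid blobs
strictly inside the ILM–RPE band for ME, an optical blur of σ = 1.2 px,
and multiplicative uniform speckle (level 0.2 by default, i.e. ±20%).
Default geometry is 496×512 with 11.6 µm lateral pixel pitch, so the
500 µm EDTRS radius is ≈ 43 px. `generateFundusPhantom` renders a
circular field of view (720×576 frame), one bright optic disc, a darker
macula, a recursive branching dark vessel tree rooted at the disc
(depth 5, trunk width 5 px tapering to ~1 px), and for ME 6–18 bright
exudate blobs (radius 3–8 px) within 114 px of the macula centre, never
touching vessels or disc. Every phantom is a deterministic function of
its seed, and the ground truth (boundary curves, masks, disc, fovea,
label) is emitted alongside.

What the phantoms do **not** emulate: real OCT speckle statistics
(multiplicative uniform noise is bounded; Rayleigh-type speckle has
tails), vessel shadowing in B-scans, curvature and tilt of the retina,
drusen and other confounding pathology, fundus illumination gradients,
and inter-device intensity response. Passing the phantom-based tests
therefore demonstrates that the pipeline's machinery is correct and
self-consistent at realistic geometry and contrast — not that its
accuracy transfers to clinical data, for which expert-annotated scans
would be required.

# Numerical choices and degenerate inputs

* Convolutions use replicate boundary handling; the Wiener filter uses
  symmetric padding with exact summed-area-table box sums.
* Canny: σ = 1.4 smoothing, Sobel gradients, 4-sector non-maximum
  suppression, hysteresis linking with 8-connected components (the
  package labels 8-connectivity by merging diagonal touches of a
  4-connected labelling); thresholds are fractions of the maximum
  gradient magnitude, and an absolute floor of $10^{-8}$ treats an
  (effectively) constant grid as edge-free rather than normalizing FFT
  residue up to order one.
* Softmax subtracts the maximum before exponentiation; cross-entropy
  clamps probabilities at $10^{-12}$.
* Ties: the fovea argmax breaks toward the image centre (then the lower
  column index); boundary tracing prefers the nearer, then the
  stronger-response candidate.
* Degenerate inputs error early with specific messages: blanking more
  annotation rows than the scan has, empty retinal masks, single-class
  training data, all-noise scans without layered structure.

# Problem sizes in the shipped checks

The test suite and the acceptance script exercise, as the package's
documented reference conditions: a 50-subject phantom cohort for
segmentation recovery (fluid/vessel/exudate dice, boundary MAE, fovea
localization), and a 100-subject (200-scan) cohort — 70/30 train/validation,
30 training epochs — for the CNN + ensemble stack. Unit tests use reduced
fixtures (a 12-subject cohort with 10-epoch training) for the
orchestration paths.

# Known limitations

* The vessel darkness gate and the exudate brightness test assume the
  usual polarity (dark vessels, bright exudates) and roughly uniform
  illumination; severe illumination gradients would need a normalization
  step the package does not implement.
* Layer extraction designates only ILM and RPE; the interior curves are
  reported but not anatomically named, and sub-pixel refinement is out
  of scope.
* The pipeline is strictly per-B-scan; it does not select the foveal
  B-scan from a volume, model 3-D retina, or handle proprietary OCT
  containers.
* Single-modality operation is refused by default: the contribution is
  the fusion, and zero-filling half the descriptor silently would
  degrade the ensemble without notice.
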
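---
title: "Grading tobacco leaves from images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading tobacco leaves from images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafgrade)
```

`leafgrade` grades flue-cured tobacco leaves from images in three stages:
nine numeric features, per-feature fuzzy membership grades from small
neural networks, and a two-level fuzzy comprehensive evaluation (FCE) that
combines the grades into a class decision. This vignette explains the
model behind each stage, the tunable parameters, the synthetic data the
package uses to test itself, and the design decisions that were genuinely
open.

## The feature model

A leaf is photographed alone on a uniform near-white board, so the
background color is *known metadata*, not something estimated per image.
All nine features are computed from a single segmentation: pixels whose
maximum per-channel distance from the board color exceeds a threshold
(Otsu's method on the distance map by default) form the leaf; the largest
connected component is kept and its interior holes are filled, giving the
leaf *region*. Pixels of the region that are not background-colored are
the leaf *tissue*.

### Shape: area, perimeter, disfigurement

Edges are located with a Laplacian-of-Gaussian (LoG) filter,

$$\mathrm{LoG}(x,y) \;=\; -\frac{1}{\pi\sigma^4}
  \Bigl(1-\frac{x^2+y^2}{2\sigma^2}\Bigr)
  e^{-\frac{x^2+y^2}{2\sigma^2}},$$

sampled at integer offsets on a $(2r{+}1)\times(2r{+}1)$ grid. Defaults:
$\sigma = 2$ px and $r = \lceil 4\sigma\rceil$, at which the truncated
coefficients sum to nearly zero; no reference value for $\sigma$ exists,
so it was fixed once at the standard scale for 512-px frames. The filter
response's zero-crossings (with a minimum response step, 5% of the largest
step, to suppress flat-region noise) mark edge pixels. Zero-crossing sets
are unordered and need not close, so the ordered closed contour is
obtained by tracing the leaf-mask boundary (Moore neighbor tracing) and
*validating* it against the zero-crossings: if fewer than 90% of boundary
points lie within 2 px of a zero-crossing the contour is flagged as a
mask-boundary fallback. Contours are 1-based `(row, col)` sequences — the
R indexing convention — whose consecutive points are 8-connected, with no
repeated pixel.

The contour is simplified to a polygon by Ramer–Douglas–Peucker on the
closed curve (split at two mutually far points, recurse), with tolerance
2 px by default: at the leaf scales involved (perimeters of roughly
300–1700 px) this distorts the perimeter by well under 1%. The polygon is
ear-clip triangulated; the **area** is the summed triangle (shoelace)
area, rounded to integer pixels.

The **perimeter** feature is the count of pixels on the 8-connected
rasterized polygon sides with shared vertices counted once — per side,
$\max(|\Delta r|, |\Delta c|)$. This count is exact for axis-aligned
shapes but is biased low on oblique or curved boundaries (its expectation
over uniformly distributed orientations is $2\sqrt2/\pi \approx 0.90$ of
the Euclidean length, and a 45° side attains the worst case
$1/\sqrt2$). `polygon_perimeter(poly, "euclidean")` therefore also
reports the Euclidean polygon length, which is the estimator to compare
against analytic circumferences; `shape_features()` returns both.

**Disfigurement** is the percentage of pixels strictly inside the polygon
(even-odd rule at pixel centers, rasterized boundary excluded) whose color
matches the background within a per-channel tolerance of 10 intensity
levels — the tolerance absorbs anti-aliased hole rims without ever
reaching leaf-tissue colors.

### Texture: GLCM energy, entropy, contrast

The luminance channel (`0.299 R + 0.587 G + 0.114 B`) is degraded to 32
gray levels, `level = floor(luminance / 8)`, purely to keep the
co-occurrence matrix tractable; the degradation is used only here. The
gray-level co-occurrence matrix counts ordered pairs of levels at a fixed
displacement $\delta = (DX, DY)$ — default $(1, 0)$, the pixel to the
immediate right — over tissue pixels only (background texture is
meaningless for grading). The matrix is directional: reversing the offset
transposes it, a property the tests pin exactly.

The three statistics are computed on the probability-normalized matrix:
energy $\sum p_{ij}^2$, entropy $-\sum p_{ij}\log_2 p_{ij}$ (with
$0\log 0 := 0$), contrast $\sum (i-j)^2 p_{ij}$. Two dialect choices are
worth stating. First, the summation form of entropy without a minus sign
is negative for probabilities; the package uses the conventional
nonnegative entropy and offers `texture_entropy(g, signed = TRUE)` for
the raw summation. Second, the statistics are sometimes written over raw
counts; `raw = TRUE` computes that variant, but the normalized form is
the default since only it is scale-free.

### Color: channel variances

Population variances (divide by $n$) of the red, green and blue channels
over tissue pixels. Leaf-only statistics are essential — the uniform
background would otherwise dominate — and the $1/n$ convention is fixed
for reproducibility, though immaterial at $n \sim 10^4$ pixels.

## Membership networks

Each category (shape, texture, color) has a 3–5–3 network: three inputs
(the category's features), five hidden and three output neurons, logistic
sigmoid on both layers. Features are min–max scaled to $[0,1]$ on
training bounds (areas near $10^4$ would otherwise saturate the
sigmoids); at prediction time values are clipped into $[0,1]$. Training
is online gradient descent on squared error against one-hot class targets
(learning rate 0.5, weights initialized uniformly on $(-0.5, 0.5)$ from a
seed; bit-reproducible given data order and seed). Training runs until
*all the output is correct*, read with a margin: every output neuron
within `target_margin` (default 0.2) of its target, which implies strict
arg-max correctness (ties count as incorrect). The margin matters: a bare
arg-max check is typically satisfied within a dozen epochs while the
outputs still hover near 0.5 and are useless as membership grades.

### From a joint network to per-feature membership rows

The evaluation matrix $R_i$ needs one membership row per *single*
sub-factor, but the network consumes all three features jointly. How to
bridge this was the single most consequential open design question, and
the first candidate fails in an instructive way.

*Clamped readout* (available as `build_R(..., readout = "clamped")`):
evaluate the net with feature $j$ at its observed value and the other two
clamped to their training means. This is confounded twice over. The
clamped means themselves carry class evidence — the mean disfigurement of
a mixed training set lies in the middle class's range, so every probe
whispers "middle class" through the clamped inputs — and the probe point
is a feature combination the net never saw, where a trained-to-stopping
net is unconstrained. Measured on the shipped synthetic study, rows for
weakly informative features come out arbitrarily biased and the pipeline
collapses one class into another (two-thirds accuracy).

*Marginal readout* (the default): evaluate the net over the whole
training set with feature $j$ replaced by its observed scaled value and
the other two left at each specimen's own values; normalize each output,
average within class, then across classes. Every evaluation sits next to
a training point, and the row estimates the marginal membership of the
single feature under a uniform class prior: an uninformative feature
yields a near-uniform row instead of an arbitrary one. This readout needs
the (scaled) training set, which is therefore stored with the model
parameters. A third candidate — training on the clamped probe points so
the clamped readout becomes meaningful — was prototyped and rejected:
online squared-error training on conflicting probe targets saturates the
sigmoids and collapses one output class.

## Two-level fuzzy comprehensive evaluation

With sub-factor weight vectors $A_1 = (0.3, 0.4, 0.3)$,
$A_2 = (0.4, 0.3, 0.3)$, $A_3 = (0.3, 0.3, 0.4)$ and category weights
$A = (0.35, 0.2, 0.45)$ (color weighted highest, texture lowest — the
reference expert calibration, configurable via `fce_weights()` or a
YAML/JSON file), the composition operator is the weighted average
$M(\cdot, +)$:

$$B_i = A_i \cdot R_i, \qquad V = A \cdot B, \qquad
  V \leftarrow V / \textstyle\sum_c V_c, \qquad
  \text{class} = \arg\max_c V_c.$$

The operator choice is empirical as well as principled: weighted-average
composition reproduces the reference worked example exactly (max–min
composition does not), and it conserves unit mass — if every $R_i$ row
and every weight vector sums to 1, each $B_i$ and $V$ sum to 1, a
property the suite checks on a thousand random instances. Exact arg-max
ties are broken by declared class order with a warning. The worked
example's own printed $B$ matrix and middle $V$ component contain
arithmetic inconsistencies with this composition; the shipped fixtures
store the printed values verbatim with discrepancy flags, and the package
reports recomputed values (the first and third $V$ components match the
printed ones exactly).

## The synthetic leaf generator

No leaf-image database is publicly deposited, so the package generates
its own test images with exact ground truth. A leaf is a rotated ellipse
whose radius is perturbed by a low-order Fourier series (harmonics 2–5,
amplitude sd 0.02) — simply connected with a smooth boundary — rasterized
on a 512-px canvas, the acquisition frame size. The interior is filled
with the class color plus per-channel Gaussian noise and a multiplicative
correlated luminance field (white noise smoothed at a class-dependent
grain) modeling surface texture. Circular holes are carved strictly
inside the leaf (three-pixel margin from the boundary, pairwise disjoint
so the tissue provably stays connected) until a target disfigurement
fraction is met within 10% relative. Ground truth — area, traced
perimeter, exact hole fraction — is measured on the emitted raster, not
the continuous model, because that is what any extractor can see.

The three default classes were calibrated once against the reference
feature tables: major axes 170–260 / 260–330 / 210–320 px at aspect
0.55–0.65 (areas ≈ 11,000–57,000 px², inside the published 10,803–59,146
range), hole fractions 0.012 / 0.04 / 0.075 (disfigurement inside
0.56–9.47%), and noise spreads and grains chosen so channel variances
land in the published ≈ 65–186 band. Because the nine features exclude
mean color, class separation flows only through properties the pipeline
actually measures: size, hole fraction, texture grain, channel spreads.

What the generator does *not* emulate: venation, lighting gradients,
specular highlights, camera noise, multi-leaf scenes. Passing tests on
synthetic leaves therefore demonstrate that the pipeline recovers known
ground truth under the stated acquisition model — clean segmentation,
known background — not that it matches expert grading of real leaves; the
reference real-leaf accuracies (94% trained / 72% held-out) are not
reproducible without the original database, and the experiment harness
labels its synthetic accuracies as analogues, not comparable numbers.

## The experiment harness and problem sizes

`run_experiment()` mirrors the reference design — a trained group and a
smaller non-trained group — as 34 + 17 leaves per class (102 trained, 51
held-out; the reference totals of 100 and 50 are not divisible by three).
All randomness flows from one top-level seed through derived substreams
(generation, per-category weight init), making runs bit-reproducible. One
run takes well under a minute on a single CPU; the acceptance suite
repeats it over ten seeds. Unit tests exercise the same harness on a
scaled-down configuration (160-px canvas, 6 + 3 leaves per class) to keep
the default test run fast.

## Numerical choices and degenerate inputs

- Convolution uses mirror (half-sample symmetric) boundary extension —
  avoiding dark-frame edge artifacts — via FFT with cached kernel
  transforms; a constant image is reproduced to within $10^{-9}$.
- An all-background image raises a detection error, as does a largest
  component under 16 px; a contour with fewer than 3 points or collinear
  throughout raises a fitting error; a polygon with no interior pixels, a
  GLCM with no valid pairs, and single-class training data all raise
  typed errors rather than returning degenerate values.
- Polygon interiors use the even-odd rule at integer pixel centers with a
  half-open vertex rule, so vertices on a scanline are counted once.
- Ties in the training arg-max check count as incorrect; exact ties in
  the final decision go to the first class in declared order, with a
  warning.
- Hole targets are met by carving discs of radius 3–10 px with the final
  disc sized to the remaining deficit; an unreachable target (within 10%
  relative) is an error, never silently approximated.

## Known limitations

- The pixel-count perimeter underestimates curved boundaries by up to
  10%; use the Euclidean polygon length where an unbiased estimate
  matters. Both are reported.
- The marginal membership readout requires retaining the training
  features with the model (a few kilobytes here; an approximation by
  stored class-conditional moments would trade fidelity for size).
- Feature scaling clips test-time values outside the training range, so
  grades saturate rather than extrapolate for out-of-range leaves.
- The LoG contour is validated against, but ultimately ordered by, the
  mask boundary; images whose leaf cannot be segmented by background
  distance (shadows, non-uniform boards) are out of scope.
- BMP input is not supported; images are read and written as PNG.
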
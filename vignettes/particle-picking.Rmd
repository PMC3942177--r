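---
title: "Masked-NCC particle picking: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked-NCC particle picking: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryopick)
```

## The model

Template-based picking treats each particle orientation as a noise-free
reference image $T_k$ with a binary mask $M_k$ delimiting the pixels that
belong to the particle, and slides it over the micrograph $I$. At offset
$v$ the score is the Pearson correlation computed **only over mask
pixels** ($P = \sum M$):

$$\mathrm{NCC}_k(v) =
\frac{\sum_M I(x+v)\,T(x) - \tfrac{1}{P}\bigl(\sum_M I(x+v)\bigr)\bigl(\sum_M T\bigr)}
{\sqrt{\sum_M I(x+v)^2 - \tfrac{1}{P}\bigl(\sum_M I(x+v)\bigr)^2}\;
 \sqrt{\sum_M T^2 - \tfrac{1}{P}\bigl(\sum_M T\bigr)^2}}.$$

Masking matters because particles are compact: without it, background
pixels inside a rectangular window dilute the correlation and blur the
discrimination between views. Local normalization (subtracting the
windowed mean, dividing by the windowed standard deviation) makes the
score invariant to the slowly varying ice/carbon background and to affine
intensity changes, and bounds it in $[-1, 1]$.

All three image-dependent sums in the formula are linear cross-correlations
of $I$ or $I^2$ against $M$ or $M\cdot T$, so `masked_ncc()` evaluates the
full map with FFTs: two forward transforms of the padded micrograph and its
square are computed once per micrograph (`micrograph_spectra()`) and shared
across all templates; each template then costs two forward transforms
($M\cdot T$ and $M$) and three inverse transforms. `fft_schedule()` exposes
this dispatch list and `fft_op_count(K)` $= 2 + 5K$ for $K \ge 1$ — the
package's counter (`fft_count()`) is asserted against it in the tests.

Correlation is *linear*, not circular: images are zero-padded and only
offsets where the template lies fully inside the micrograph are returned,
so there are no wrap-around artifacts. Padded dimensions are rounded up to
7-smooth integers (`smooth_size()`), where FFT libraries are fastest; any
larger smooth padding gives identical results (a tested property).

The per-template maps are reduced elementwise into a global score map and
an index map recording the winning template,
$\mathrm{NCC}(v) = \max_k \mathrm{NCC}_k(v)$,
$\mathrm{IND}(v) = \arg\max_k \mathrm{NCC}_k(v)$. With inverted contrast
(see *Polarity*) the extremum is taken on the negated maps, so the global
map always holds the strongest correlation in the picking polarity.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `filter_k` | 4 | px | box prefilter suppressing pixel-level shot noise before correlation |
| rotation `step_deg` | 4 | degrees | angular sampling of the template series; 9 is documented as nearly as effective and proportionally cheaper |
| `threshold` | −0.3 | score | peak call cut in the configured polarity; the standard operating point for this family of pickers |
| `polarity` | `"min"` | — | dark particles on bright background produce negative peaks |
| `min_distance` | half template width | px | non-maximum-suppression radius, matching the particle-diameter intuition |
| match `tol` | half template width | px | pick-to-reference tolerance in evaluation |
| `n_workers`, `partition_mode`, `topology` | 1, per-micrograph, direct | — | performance knobs only; outputs are bit-identical across all settings |

## Template generation

`build_rotation_series()` rotates each base projection (and its mask)
through its unique angular range. A base with in-plane symmetry order $s$
only needs $[0, 360/s)$; a circularly symmetric view (e.g. a top view down
the symmetry axis) contributes a single template. Two bases at a 4° step
give 180 templates; with a 2-fold side view and a circular top view the set
shrinks to 46.

Rotation is inverse-mapping bilinear interpolation about the geometric
frame center $(n+1)/2$. `cospi`/`sinpi` return exact 0/±1 at axis-aligned
angles, so rotations by multiples of 90° reduce to exact index permutations
and 0° is bit-identical — one code path, no special cases. Out-of-frame
samples are filled with 0; since correlation is masked and masks
shrink-wrap the particle, the fill value cannot influence scores. Masks are
interpolated the same way and re-binarized at 0.5 so they stay strictly
binary (the count $P$ must be crisp).

A consequence worth stating: re-binarized rotation is *not* pixel-exact
even for rotationally symmetric shapes. A centered disk mask rotated by an
arbitrary angle comes back with a handful of boundary pixels flipped (the
bilinear surface of an indicator crosses 0.5 at a phase-dependent offset of
up to about half a pixel). The tests therefore assert what actually holds:
rotated masks are binary, their area is preserved to well within 5%, and
any flips are confined to the one-pixel boundary band; at multiples of 90°
rotation is exact.

## Reduction and determinism

`merge_pair()` keeps the larger score per offset; on an *exact* tie the
smaller template index wins, and the sentinel index −1 (score $-\infty$)
loses to any real contribution. The tie rule is a declared convention, not
inherited from any upstream definition of the argmax — its purpose is
algebraic: it makes the merge associative and commutative, so the
sequential fold, the direct (accumulator) schedule, the binary-tree
schedule, and any permutation of the inputs produce bit-identical maps.
That is the property that lets `run_pick()` guarantee identical picks for
any `n_workers` and either partition mode. Costs follow the schedule:
direct reduction of $P$ parts is $P-1$ transfers and $P-1$ sequential merge
rounds; a tree is $\lceil \log_2 P \rceil$ rounds (total pairwise merges
are always $P-1$). Transfers are simulated in-process — the plan is a data
structure, preserving the algorithmic content without a message-passing
dependency.

## Peak extraction and polarity

Candidates are local maxima in a $(2d+1)^2$ neighborhood
($d$ = `min_distance`) at or beyond the threshold; they are accepted
greedily in score order (ties by row, then column), suppressing any later
candidate within Euclidean distance $d$ — the standard deterministic
non-maximum suppression. With `polarity = "min"` the map is negated
internally and the threshold sign flipped, so the machinery is always
"maxima above a positive cut"; reported scores keep their sign. Pick
centers are `offset + floor(template_shape/2)` in 0-based (row, col)
coordinates, and every reported pick's footprint lies inside the micrograph
by construction of the valid-offset region.

Evaluation (`match_picks()`) uses greedy nearest-first one-to-one matching
within `tol`: the globally closest pick/reference pair is matched first.
Precision, recall, FDR $= 1 -$ precision, F-measure (harmonic mean), and
the mean distance over matched pairs follow. `roc_points()` walks the
ranked pick list and reports cumulative true positives per prefix with
matches never retracted. Both matching rules are declared conventions; the
underlying benchmark statistics they mirror were published without one.

## The synthetic generator

`make_base_projections()` fabricates the two canonical KLH-like views: a
rectangular side view with transverse band texture (built exactly 2-fold
symmetric) and a circular top view with purely radial ring texture (so any
rotation of it matches the single 0° template). Intensities taper to zero
at the mask boundary — this keeps scores at planted positions at ±1 even
when a rotated mask's boundary pixels flip — and are scaled to unit
variance under the mask, so a planted amplitude $a$ in noise of s.d.
$\sigma$ gives peak-SNR $a^2/\sigma^2$ exactly. `plant_particles()` places
rotated copies at rejection-sampled centers (minimum separation defaults to
0.9 frames, which keeps particle masks disjoint) and adds white Gaussian
noise; the ground-truth table is exact and a fixed seed reproduces the
micrograph bit for bit.

Default study conditions, chosen once: 160-px view frames (mask areas of
order $10^4$ px, the scale at which the 4×4 prefilter and the −0.3
threshold sit well clear of the correlation noise floor, which grows as
$\approx 4/\sqrt{P}$ on box-filtered data), 768×768 micrographs, 6
particles per micrograph, amplitude −1 (inverted contrast, the default
polarity), noise $\sigma = 0.2$ (peak-SNR 25), angles on the 4° template
grid. End-to-end tests run a 46-template symmetric series over these
micrographs; the smaller unit-test scenes use 48-px frames and coarse
angular steps where only mechanics, not operating points, are under test.

What the generator does *not* emulate: ice and carbon texture, the
contrast transfer function and defocus variation, astigmatism, drift,
radiation damage, overlapping or aggregated particles, and edge artifacts.
Passing the synthetic recovery tests therefore demonstrates the
correctness of the pipeline's algebra and bookkeeping — matched templates
score ±1, peaks land where particles were planted, evaluation counts what
it should — not picking performance on real micrographs, where template
bias and structured noise dominate.

## Numerical choices and degenerate inputs

* All correlation arithmetic is double precision — R's native numeric.
  There is no single-precision path; file output (MRC mode 2) is float32.
* Windows whose masked variance is at most $10^{-12}$ times the
  micrograph's global variance score 0, not NaN/±∞: flat ice or padding
  must not produce spurious peaks. Flat *templates* are rejected at
  construction, as are masks with fewer than 2 pixels.
* Score bounds are guaranteed only up to FFT roundoff ($\pm 10^{-4}$ is
  the documented envelope; observed errors are below $10^{-9}$ at double
  precision against the spatial-domain oracle).
* Tie-breaking is total and deterministic everywhere: merge ties go to the
  smaller template index, NMS candidate ties to (row, col) order,
  evaluation matches to ascending distance.
* `mean_filter()` uses reflect padding (edge row/column mirrored including
  the edge) so output shape equals input shape; for even windows the
  anchor is `floor((k-1)/2)`, which shifts content by half a pixel — at
  the default `k = 4` this costs well under the 2-px localization budget.
* The angular step must divide 360 evenly, so every base's range closes
  exactly; the error message suggests the nearest valid steps.

## Open design points, resolved

* **Denominator form.** Whether the template term belongs in the
  denominator (full Pearson form) or templates are pre-normalized was left
  open by the method's description; the full Pearson form is used so scores
  are bounded by 1 regardless of template scaling. The spatial-domain
  masked-correlation oracle in the tests is the defining reference.
* **Mask interpolation.** Interpolation scheme and re-binarization for
  rotated masks are not prescribed anywhere authoritative; bilinear + 0.5
  is declared here (see *Template generation* for its boundary behavior).
* **NMS details.** The peak-calling procedure is specified only by analogy
  to earlier pickers; greedy score-descending suppression with a Euclidean
  radius of half the template width is the declared, deterministic choice.
* **Concurrency model.** Real thread pools and message passing are
  replaced by a deterministic bounded-queue simulation and in-process
  merge schedules. This preserves everything testable about the
  producer–consumer and reduction contracts (each template consumed
  exactly once, bounded occupancy, schedule-independent results) while
  keeping the package free of platform dependence.

## Known limitations

Micrographs are correlated one at a time in memory; there is no tiling for
images that do not fit. Template sets must share one frame size. The picker
reports the best template per peak but performs no sub-pixel refinement and
no local angular refinement beyond the series step. Evaluation assumes a
single reference list per micrograph (no per-view reference classes).
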
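---
title: "Counting merged colonies: model, tuning, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting merged colonies: model, tuning, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcolony)
```

## The problem

Colony-forming-unit (CFU) counting on high-throughput plates runs at more
than ten colonies per square centimeter, so colonies frequently grow into
contact and merge into a single connected bright region. Region-based
counters (thresholding, watershed, extended minima) count each connected
region as one and systematically undercount. `mcolony` resolves merged
regions by combining two sources of evidence:

* **contour evidence** — a merged region's outline has concave points at
  the intersections of the individual colony boundaries, which split the
  outline into pieces, each presumed to belong to one colony;
* **region evidence** — candidate colony circles from peaks of the
  Euclidean distance transform and from least-squares fits of the contour
  pieces.

The final count is decided by a small zero-one integer program that pairs
every contour piece with exactly one candidate circle while penalizing the
number of circles used.

## Pipeline

1. **Foreground extraction.** Otsu thresholding over the 256 integer
   intensity levels (foreground = brighter class; a `min_contrast` guard of
   30 intensity levels treats blank plates, where Otsu would split pure
   noise, as background). Morphological opening with a 3×3 box, applied
   twice, removes speckle; 8-connected component labeling yields segments,
   discarding components under `min_area = 9` px.
2. **Contour splitting.** Moore-neighbour border following (Jacob's
   stopping criterion) traces the outer contour and the contour of every
   hole of at least 5 px (smaller holes are rasterization specks). Each
   contour is reduced to *turning points* by iterative vertex pruning:
   while any vertex lies closer than `d` to the chord joining its two
   surviving neighbours, the closest such vertex is removed (ties: lowest
   index). This implements the chord-distance definition of the fineness
   parameter directly; a recursive Douglas–Peucker split has a different
   `d` semantics and is deliberately not used. A turning point is *concave*
   when the signed turn of the polygon opposes the contour orientation;
   on inner contours the sign flips, which selects the corners where two
   colony arcs meet around a hole. Concave points split the contour
   cyclically into pieces.
3. **Candidate circles.** Distance-transform local maxima (radius = the
   distance value, minimum 2 px, non-maximum suppression within the larger
   radius) plus a Kåsa algebraic least-squares circle per piece of at
   least 3 non-collinear points. Fits with radius above 3× the segment's
   maximum distance value are runaway fits of near-straight pieces and are
   dropped; near-duplicates (center and radius both within 1 px) merge,
   keeping the distance-transform circle.
4. **Pairing.** With pieces *i* = 1..M and circles *j* = 1..N, the distance
   `D[i, j]` is the sum over piece pixels of the distance to the circle
   edge, evaluated analytically as `sum(| ||p − c|| − r |)`. The program

   minimize `sum(D[i,j] X[i,j]) + lambda * sum(Y[j])`

   subject to each piece assigned once and `Y[j]` = 1 exactly when circle
   *j* receives a piece, is solved **exactly**: for every subset size *k*
   the minimum assignment cost `f(k)` is found by subset enumeration, and
   the optimum for any `lambda` is the lower envelope `min_k f(k) +
   lambda*k`. Choosing the smallest *k* on ties guarantees every selected
   circle is used, and makes the count provably non-increasing in
   `lambda` — the property the tuning methods rely on. Instances are small
   because the optimization runs per segment; a guard prunes candidate
   sets above 14 circles (keeping those nearest the pieces) before the
   exponential enumeration. A segment with no candidate circle at all is
   counted as one colony: a nonempty segment is at least one colony.

## The two hyperparameters

* **`d` (pixels, default 0.5)** — contour fineness: the minimum
  chord-distance a turning point must reach. Small `d` keeps many turning
  points, over-splitting contours (the optimizer then merges the pieces);
  large `d` smooths the waist between merged colonies away entirely, which
  no penalty can repair. The calibrated value depends on image resolution
  and colony size. The advisory `suggest_d()` reproduces the empirical
  procedure: select elongated (eccentricity ≥ 0.6) two-colony-like
  segments and halve `d` from 100 until their median contour splits into
  3–10 pieces.
* **`lambda` (summed-pixel-distance units, default 26)** — the penalty per
  selected circle. At `lambda = 0` every piece gets its nearest circle
  (over-counting); as `lambda` grows the count decreases monotonically to
  one circle per segment. `lambda` is deliberately *not* normalized by
  piece length, so its scale is dataset-dependent. The default follows the
  convention for dense sub-image data; real deployments should tune it
  (below).

## Tuning lambda

Three routes, in decreasing order of labeling effort:

1. **Grid search + k-fold cross-validation** (`grid_search_cv()`) over a
   (d, lambda) grid, minimizing the cross-validated mean absolute relative
   error `|count − label| / label`; ties prefer smaller `d`, then smaller
   `lambda`.
2. **Averaging matched penalties** (`tune_lambda_labeled()`): for each of
   a few labeled images, bisection (exactness of the solver makes the
   count a non-increasing step function of `lambda`) finds the plateau
   where the pipeline reproduces the label; the tuned penalty is the mean
   of the plateau midpoints. Midpoints, not edges, keep the average robust.
3. **Equidispersion** (`tune_lambda_equidispersion()`): counts over
   replicate platings of one culture should have variance equal to their
   mean (the Poisson property; `poisson_dispersion_test()` checks it with
   `D = sum((X − mean)^2)/mean` on a chi-square with N−1 degrees of
   freedom, two-sided). The method scans a `lambda` grid and returns the
   interpolated zero crossings of mean − variance, flagging the crossing
   nearest the configured default; the criterion need not have a unique
   solution, so all crossings are reported.

## The synthetic generator

`plate_spec()` / `generate_subimage()` emulate the high-density regime the
pipeline targets: bright disks (foreground 200, background 40, additive
Gaussian noise sd 8) on 160 px wells, radii ~ N(7, 1.5²) truncated at 4 px,
per-well counts Poisson(μ). Merging is a mixture: with probability
`merge_q = 0.3` a new center lands within 0.95–1.4 radii of an existing
colony. At these defaults the ground-truth cluster composition (about
65/21/9 % single/two/three-colony segments) matches what dense plating
produces in practice; placements closer than 0.95 r are excluded because
they render as one quasi-circular blob that no contour method — or human
without growth-history photographs — can resolve. A `no_merge` mode keeps
all pairwise center distances above the radius sum (plus a 3 px guard) for
exactness tests. The generator renders ideal disks: it does not emulate
irregular colony morphology, halos, uneven illumination, or plate rims, so
passing tests demonstrate correctness of the geometry and optimization,
not robustness to those artifacts.

## Numerical choices

* Outer contours and hole contours are stored with opposite rotational
  sense, so the foreground lies on the same side along both.
* Deterministic tie-breaks everywhere: lowest contour index in vertex
  pruning, first (lexicographic) subset among equal-cost selections,
  lowest circle index in assignments — counts are invariant across ties,
  and two runs of the batch driver produce byte-identical CSVs.
* Bisection tolerance for penalty matching is 0.25 on the `lambda` axis;
  the search range defaults to [0, 200] with grid step 2 for scans.
* Eccentricity for `suggest_d` comes from the eigenvalues of the pixel
  coordinate covariance, `sqrt(1 − l2/l1)`.
* No secondary curvature filter is applied to concave points by default;
  the polygon pruning at sensible `d` already suppresses pixel-scale
  jags, and the optimizer absorbs residual over-splitting.

## Validation scale and known limitations

The test suite validates the solver against exhaustive enumeration (500
random instances up to 4×4), kernel exactness (Kåsa fit to 1e−6, Otsu
against a 256-threshold scan, the analytic pairing distance against a
1°-rasterized brute force), exact counting on 200 well-separated synthetic
wells at the defaults, two-colony recovery with concave points within 3 px
of the analytic circle intersections on 200 rendered peanuts (`d` = 1,
`lambda` calibrated on 20 independent peanuts), dispersion-test
calibration on 1000 null replicates, and tuning consistency on a fixed
96-well Poisson(15) dataset with 200 replicates per protocol.

Known limitations:

* The labeled-averaging route is robust from ~10 labeled wells; the
  equidispersion route is weaker. Merged colonies are missed more often in
  crowded wells, so the count-versus-truth slope is slightly below one and
  the count variance is compressed below the mean exactly where the error
  is lowest; the mean-equals-variance crossing therefore sits on the
  overcounting flank, and with exactly Poisson ground truth the route
  settles around 8–10 % mean error on the synthetic conditions rather
  than the ~3 % the error-optimal penalty achieves. It remains useful as
  a zero-label starting point, with counts inspected as recommended.
* Counting assumes quasi-circular colonies; elongated or irregular
  morphologies violate the candidate model.
* Heavily merged groups (four or more colonies sharing one segment) are
  resolved only when their waists survive the morphological cleaning.
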
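# mcolony

Counting colony-forming units (CFU) on crowded agar plates, where colonies
grow into contact and **merge** into single connected regions that
region-based counters (thresholding, watershed, extended minima) count as
one.

`mcolony` splits each connected foreground segment's contour at its
**concave points** — the intersections of the individual colony
boundaries — into pieces assumed to outline single colonies, generates
**candidate colony circles** from distance-transform peaks and algebraic
(Kåsa) least-squares fits of those pieces, and then selects the counted
colonies by exactly solving a zero-one integer program:

```
minimize   Σᵢⱼ Dᵢⱼ Xᵢⱼ + λ Σⱼ Yⱼ
subject to Σⱼ Xᵢⱼ = 1            (every contour piece pairs with one circle)
           Yⱼ ≤ Σᵢ Xᵢⱼ ≤ M·Yⱼ    (a circle is counted iff it receives a piece)
           Xᵢⱼ, Yⱼ ∈ {0, 1}
```

with `Dᵢⱼ = Σ_p | ‖p − cⱼ‖ − rⱼ |` the summed distance from the pixels of
piece *i* to the edge of circle *j*. The count is `Σⱼ Yⱼ`. Two
hyperparameters govern the pipeline: the contour fineness `d` (chord
distance for turning-point selection) and the circle penalty `λ`; the count
is provably non-increasing in `λ`, which the tuning helpers exploit:

* `grid_search_cv()` — grid search with k-fold cross-validation on labeled
  images;
* `tune_lambda_labeled()` — average the λ values that reproduce the labels
  of ~10–20 images (bisection over the monotone count);
* `tune_lambda_equidispersion()` — zero labels: pick λ where the counts of
  ~40+ replicate wells satisfy mean = variance (the Poisson property,
  testable with `poisson_dispersion_test()`).

A seeded synthetic plate generator (`plate_spec()`, `generate_subimage()`,
`generate_plate()`) provides ground-truth labels for validation, and
`run_batch()` / `inst/scripts/colonycount` drive whole directories of well
images into per-circle CSVs and overlay figures.

## Worked example

```r
library(mcolony)

spec <- plate_spec(mu = 15)                 # dense 160 px wells, merges likely
sub  <- generate_subimage(spec, seed = 42)  # one well + ground truth
sub$label
#> [1] 20

res <- count_image(sub$image, d = 0.5, lambda = 6, image_id = "well_A1")
res
#> <colony_count well_A1: 19 colonies in 9 segment(s) (d = 0.5, lambda = 6)>

glance(res)
#> # A tibble: 1 × 5
#>   image_id total n_segments     d lambda
#>   <chr>    <int>      <int> <dbl>  <dbl>
#> 1 well_A1     19          9   0.5      6

head(tidy(res), 4)
#> # A tibble: 4 × 4
#>   segment count n_pieces n_candidates
#>     <int> <int>    <int>        <int>
#> 1       1     2        3            2
#> 2       2     4       14           11
#> 3       3     1        3            2
#> 4       4     2        3            2

autoplot(res)                               # grayscale well + selected circles
```

The well truly holds 20 colonies; at `λ = 6` the pipeline finds 19: nine
connected segments, several of which are resolved into 2–4 merged colonies
each (segment 2 pairs 14 contour pieces with 11 candidate circles and
counts 4). Given the label, the penalty that reproduces it exactly is
found by bisection:

```r
find_matching_lambda(sub$image, sub$label)
#> [1] 3.12
```

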
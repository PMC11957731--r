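Package: mcolony
Title: Counting Merged Microbial Colonies by Pairing Contour Pieces with Candidate Circles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts colony-forming units on high-density agar plate images where
    colonies frequently grow into contact and merge. Connected foreground segments
    are extracted by Otsu thresholding and morphological cleaning; each segment's
    contour is split at concave points into pieces assumed to outline single
    colonies; candidate colony circles come from distance-transform peaks and
    algebraic least-squares fits of the pieces; the final colony set is chosen by
    exactly solving a zero-one integer program that assigns every contour piece to
    one circle while penalizing the number of circles used. Includes statistical
    hyperparameter tuning from few labeled images (averaging matched penalties) or
    from unlabeled images (equidispersion of counts, with a Poisson dispersion
    test), grid search with k-fold cross-validation, and a seeded synthetic plate
    generator with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
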
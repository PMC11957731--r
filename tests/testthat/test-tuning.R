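test_that("find_matching_lambda returns a plateau value agreeing with a grid scan", {
  withr::local_seed(61)
  sub <- generate_subimage(plate_spec(mu = 12))
  prof <- prepare_profiles(list(sub$image), d = 0.5)[[1]]
  lam <- find_matching_lambda(prof, sub$label, range = c(0, 200))
  grid <- seq(0, 200, by = 1)
  cg <- vapply(grid, function(l) image_counts(list(prof), l), integer(1))
  hit <- grid[cg == sub$label]
  if (length(hit)) {
    expect_true(attr(lam, "found"))
    expect_identical(image_counts(list(prof), as.numeric(lam)), sub$label)
    expect_gte(lam, min(hit) - 1)
    expect_lte(lam, max(hit) + 1)
  } else {
    expect_false(attr(lam, "found"))
  }
})

test_that("unreachable labels are flagged not-found", {
  # 5 pieces, 5 circles; circle 1 also covers pieces 2-3 cheaply, so the
  # count steps 5 -> 3 -> 1 as lambda grows and labels 4 and 2 are gaps
  D <- matrix(25, 5, 5); diag(D) <- 0
  D[, 1] <- c(0, 5, 5, 25, 25)
  prof_obj <- structure(list(
    profiles = list(pairing_profile(D)), n_fallback = 0L, d = 0.5),
    class = "image_profile")
  counts <- vapply(c(0, 10, 60), function(l) image_counts(list(prof_obj), l), integer(1))
  expect_identical(counts, c(5L, 3L, 1L))

  lam3 <- find_matching_lambda(prof_obj, 3, range = c(0, 60), tol = 0.1)
  expect_true(attr(lam3, "found"))
  expect_gt(lam3, 5 - 0.2)
  expect_lt(lam3, 25 + 0.2)
  expect_identical(image_counts(list(prof_obj), as.numeric(lam3)), 3L)

  for (gap_label in c(4, 2)) {
    lam <- find_matching_lambda(prof_obj, gap_label, range = c(0, 60), tol = 0.1)
    expect_false(attr(lam, "found"))
  }
})

test_that("labeled tuning averages the per-image penalties and excludes failures", {
  # synthetic profiles with known plateaus via hand-built distance matrices
  mk_prof <- function(D) structure(list(
    profiles = list(pairing_profile(D)), n_fallback = 0L, d = 0.5),
    class = "image_profile")
  # two pieces, two circles: count 2 for lambda < gap, then 1
  D1 <- rbind(c(0, 30), c(30, 0))    # f(1)=30, f(2)=0: drop at lambda=30
  D2 <- rbind(c(0, 10), c(10, 0))    # drop at lambda=10
  out <- tune_lambda_labeled(list(mk_prof(D1), mk_prof(D2)), c(2, 2),
                             range = c(0, 100), tol = 0.05)
  expect_equal(out$lambda, mean(c(15, 5)), tolerance = 0.2)
  expect_true(all(out$details$found))

  # an unreachable label is excluded with a warning
  expect_warning(
    out2 <- tune_lambda_labeled(list(mk_prof(D1), mk_prof(D2)), c(2, 5),
                                range = c(0, 100), tol = 0.05),
    "excluded")
  expect_equal(out2$lambda, 15, tolerance = 0.2)
  # all unreachable: error
  expect_error(suppressWarnings(
    tune_lambda_labeled(list(mk_prof(D1)), 7, range = c(0, 100))), "no image")
})

test_that("the dispersion statistic matches hand evaluation and is calibrated under the null", {
  ht <- poisson_dispersion_test(c(2, 4, 6))
  expect_equal(unname(ht$statistic), 2.0)
  expect_equal(unname(ht$parameter), 2)
  expect_s3_class(ht, "htest")

  expect_equal(unname(poisson_dispersion_test(c(5, 5, 5, 5))$statistic), 0)
  expect_error(poisson_dispersion_test(c(0, 0, 0)), "mean")
  expect_error(poisson_dispersion_test(3L), "at least 2")

  # null calibration and E[D] = N - 1 (reduced replicate count; the full
  # calibration runs in the acceptance suite)
  withr::local_seed(400)
  reps <- replicate(300, {
    ht <- poisson_dispersion_test(stats::rpois(96, 20))
    c(ht$statistic, ht$p.value)
  })
  expect_lt(abs(mean(reps[1, ]) - 95) / 95, 0.05)
  rej <- mean(reps[2, ] < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("equidispersion tuning finds the mean-variance crossing", {
  withr::local_seed(62)
  ds <- generate_dataset(plate_spec(mu = 15), 40)
  profs <- suppressMessages(prepare_profiles(ds$images, d = 0.5))
  out <- tune_lambda_equidispersion(profs, lambda_grid = seq(0, 100, by = 2),
                                    default = 26)
  expect_false(out$plateau)
  cnt <- image_counts(profs, out$lambda)
  expect_lt(abs(mean(cnt) - stats::var(cnt)) / mean(cnt), 0.25)

  # degenerate: counts constant in lambda with mean == variance everywhere
  mk_const <- function(k) structure(list(
    profiles = list(), n_fallback = k, d = 0.5), class = "image_profile")
  consts <- lapply(c(2, 2, 5), mk_const)         # mean == var == 3
  res <- tune_lambda_equidispersion(consts, lambda_grid = seq(0, 10, 2))
  expect_true(res$plateau)
  expect_identical(nrow(res$crossings), 6L)

  # no crossing: informative error
  consts2 <- lapply(c(1, 9, 1, 9), mk_const)     # var >> mean at every lambda
  expect_error(tune_lambda_equidispersion(consts2, lambda_grid = seq(0, 10, 2)),
               "never crosses")
})

test_that("grid search CV partitions the data and finds the zero-error grid point", {
  withr::local_seed(63)
  ds <- generate_dataset(plate_spec(mu = 10, no_merge = TRUE), 12)
  # one-point grid returns it
  out1 <- grid_search_cv(ds$images, ds$labels, d_grid = 0.5, lambda_grid = 26,
                         k = 3)
  expect_equal(out1$d, 0.5)
  expect_equal(out1$lambda, 26)
  # every image in exactly one fold
  expect_identical(sort(unique(out1$folds)), 1:3)
  expect_length(out1$folds, 12)

  # constructed landscape: in no-merge images lambda = 26 is exact while
  # lambda = 0 over-counts; the exact point must win
  out <- grid_search_cv(ds$images, ds$labels, d_grid = c(0.5, 1),
                        lambda_grid = c(0, 26), k = 3)
  expect_equal(out$lambda, 26)
  best <- out$cv[out$cv$d == out$d & out$cv$lambda == out$lambda, ]
  expect_equal(best$cv_error, 0)
})

test_that("suggest_d targets 3-10 pieces on elongated segments and falls back on circles", {
  withr::local_seed(64)
  ds <- generate_dataset(plate_spec(mu = 15), 8)
  segs <- list()
  for (img in ds$images) {
    segs <- c(segs, label_segments(clean_mask(binarize(img))))
  }
  d <- suggest_d(segs)
  # the returned d puts the median selected segment in the 3-10 piece band
  sel <- Filter(function(s) sum(s$mask) >= 50 &&
                  mcolony:::.mask_eccentricity(s$mask) >= 0.6, segs)
  counts <- vapply(sel, function(s) length(segment_pieces(s, d = d)), integer(1))
  expect_gte(stats::median(counts), 3)
  expect_lte(stats::median(counts), 10)

  disks <- lapply(c(8, 10), function(r) label_segments(mk_disk_mask(r))[[1]])
  expect_warning(dd <- suggest_d(disks), "no elongated")
  expect_equal(dd, 0.5)
})
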
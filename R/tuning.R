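#' Precompute count-vs-lambda profiles for a set of images
#'
#' Runs the geometric pipeline (binarize, clean, label, contour split,
#' candidate circles, distance matrix, assignment-cost profile) once per
#' image; afterwards the colony count of every image can be evaluated for
#' any penalty `lambda` in microseconds via [image_counts()]. All lambda
#' tuning routines work on these profiles.
#'
#' @param images List of grayscale matrices.
#' @param d Contour fineness (default 0.5).
#' @param invert,min_area Passed to the foreground stage.
#' @param ... Passed to [segment_instance()].
#' @return List of `image_profile` objects.
#' @export
prepare_profiles <- function(images, d = 0.5, invert = FALSE, min_area = 9L, ...) {
  lapply(images, function(img) {
    mask <- clean_mask(binarize(img, invert = invert))
    segments <- label_segments(mask, min_area = min_area)
    profiles <- list()
    n_fallback <- 0L
    for (s in segments) {
      inst <- segment_instance(s, d = d, ...)
      if (is.null(inst$profile)) n_fallback <- n_fallback + 1L
      else profiles <- c(profiles, list(inst$profile))
    }
    structure(list(profiles = profiles, n_fallback = n_fallback, d = d),
              class = "image_profile")
  })
}

#' Image counts at given penalties from precomputed profiles
#'
#' @param profiles List of `image_profile` objects from
#'   [prepare_profiles()] (or a single one).
#' @param lambda Scalar penalty.
#' @return Integer vector of per-image colony counts.
#' @export
image_counts <- function(profiles, lambda) {
  if (inherits(profiles, "image_profile")) profiles <- list(profiles)
  vapply(profiles, function(p) {
    n <- p$n_fallback
    for (pr in p$profiles) n <- n + profile_count(pr, lambda)
    as.integer(n)
  }, integer(1))
}

#' Find a penalty that reproduces a labeled count
#'
#' Exploits the monotone non-increase of the count in `lambda`: bisection
#' locates the plateau of lambda values where the image's count equals the
#' label, and the plateau midpoint is returned. If no lambda in
#' `range` achieves the label (the count jumps past it), `NA` is returned
#' with attribute `found = FALSE`.
#'
#' @param x A grayscale matrix or an `image_profile`.
#' @param label Ground-truth colony count (>= 1).
#' @param d Contour fineness, used when `x` is an image.
#' @param range Search interval for lambda (default c(0, 200)).
#' @param tol Bisection tolerance on the plateau edges (default 0.25).
#' @return Lambda (plateau midpoint) with attribute `found`; `NA` when the
#'   label is unreachable in `range`.
#' @export
find_matching_lambda <- function(x, label, d = 0.5, range = c(0, 200), tol = 0.25) {
  stopifnot(label >= 1)
  p <- if (inherits(x, "image_profile")) x else prepare_profiles(list(x), d = d)[[1]]
  g <- function(l) image_counts(list(p), l)
  lo <- range[1]; hi <- range[2]
  g_lo <- g(lo); g_hi <- g(hi)
  if (g_lo < g_hi) {
    warning("count not non-increasing in lambda; falling back to a linear scan")
    grid <- seq(lo, hi, by = max(tol, (hi - lo) / 400))
    cg <- vapply(grid, g, integer(1))
    hit <- which(cg == label)
    if (!length(hit)) return(structure(NA_real_, found = FALSE))
    return(structure(mean(grid[range(hit)]), found = TRUE))
  }
  if (label > g_lo || label < g_hi) return(structure(NA_real_, found = FALSE))
  # left plateau edge: inf { lambda : g(lambda) <= label }
  if (g_lo <= label) a <- lo
  else {
    l0 <- lo; l1 <- hi                      # g(l0) > label, g(l1) <= label
    while (l1 - l0 > tol) {
      mid <- (l0 + l1) / 2
      if (g(mid) <= label) l1 <- mid else l0 <- mid
    }
    a <- l1
  }
  if (g(a) != label) return(structure(NA_real_, found = FALSE))  # jumped past
  # right plateau edge: inf { lambda : g(lambda) < label }
  if (g_hi == label) b <- hi
  else {
    l0 <- a; l1 <- hi                       # g(l0) == label, g(l1) < label
    while (l1 - l0 > tol) {
      mid <- (l0 + l1) / 2
      if (g(mid) < label) l1 <- mid else l0 <- mid
    }
    b <- l0
  }
  mid <- (a + b) / 2
  if (g(mid) != label) mid <- if (g(a) == label) a else b
  structure(mid, found = TRUE)
}

#' Tune lambda by averaging matched penalties over labeled images
#'
#' For each labeled image, finds a lambda at which the pipeline reproduces
#' the label (see [find_matching_lambda()]); the tuned penalty is the mean
#' of the found values. Images whose label is unreachable are excluded with
#' a warning.
#'
#' @param x List of grayscale matrices or of `image_profile` objects.
#' @param labels Integer labels (>= 1), same length as `x`.
#' @param d Contour fineness, used when `x` holds images.
#' @param range,tol Passed to [find_matching_lambda()].
#' @return List with `lambda` (the mean) and `details` (tibble: per-image
#'   lambda and whether it was found).
#' @export
tune_lambda_labeled <- function(x, labels, d = 0.5, range = c(0, 200), tol = 0.25) {
  stopifnot(length(x) == length(labels), all(labels >= 1))
  lam <- numeric(length(x))
  found <- logical(length(x))
  for (i in seq_along(x)) {
    li <- find_matching_lambda(x[[i]], labels[i], d = d, range = range, tol = tol)
    lam[i] <- li
    found[i] <- isTRUE(attr(li, "found"))
  }
  if (!any(found)) stop("no image admits a lambda matching its label in the search range")
  if (any(!found)) {
    warning(sprintf("%d image(s) excluded: label unreachable by any lambda in range",
                    sum(!found)))
  }
  list(lambda = mean(lam[found]),
       details = tibble::tibble(image = seq_along(x), label = labels,
                                lambda = as.numeric(lam), found = found))
}

#' Poisson dispersion test of equidispersion
#'
#' Tests H0: mean = variance (equidispersion, the Poisson property) against
#' H1: mean != variance, with statistic D = sum((X_i - mean)^2) / mean
#' referred to a chi-square distribution with N - 1 degrees of freedom.
#' The p-value is two-sided: 2 * min(lower tail, upper tail), capped at 1.
#'
#' @param counts Integer vector of counts (N >= 2, mean > 0).
#' @return An object of class `htest`.
#' @export
poisson_dispersion_test <- function(counts) {
  dname <- deparse(substitute(counts))
  N <- length(counts)
  if (N < 2) stop("need at least 2 counts")
  m <- mean(counts)
  if (m <= 0) stop("mean of counts must be positive")
  D <- sum((counts - m)^2) / m
  dof <- N - 1
  p <- min(1, 2 * min(stats::pchisq(D, dof), stats::pchisq(D, dof, lower.tail = FALSE)))
  structure(list(statistic = c(D = D), parameter = c(df = dof), p.value = p,
                 estimate = c(mean = m, variance = stats::var(counts)),
                 alternative = "mean is not equal to variance",
                 method = "Poisson dispersion test of equidispersion",
                 data.name = dname),
            class = "htest")
}

#' Tune lambda from unlabeled images by the equidispersion assumption
#'
#' Colony counts over replicate platings of the same culture are expected
#' to be equidispersed (mean = variance, as for a Poisson distribution).
#' The counts of the images are evaluated on a lambda grid and the
#' crossings of mean(counts) - var(counts) are located by linear
#' interpolation; the crossing nearest `default` is flagged as the
#' suggested penalty. Multiple crossings are all reported, since the
#' criterion need not have a unique solution.
#'
#' @param x List of grayscale matrices or of `image_profile` objects.
#' @param d Contour fineness, used when `x` holds images.
#' @param lambda_grid Grid of penalties (default seq(0, 200, by = 2)).
#' @param default Reference penalty used to flag the suggested crossing
#'   (default 26).
#' @return List with `lambda` (suggested crossing), `crossings` (tibble)
#'   and `grid` (tibble of lambda, mean, variance). Errors when
#'   mean - variance never changes sign on the grid.
#' @export
tune_lambda_equidispersion <- function(x, d = 0.5,
                                       lambda_grid = seq(0, 200, by = 2),
                                       default = 26) {
  stopifnot(length(x) >= 2, length(lambda_grid) >= 2)
  profiles <- if (inherits(x[[1]], "image_profile")) x else prepare_profiles(x, d = d)
  cnt <- vapply(lambda_grid, function(l) image_counts(profiles, l),
                integer(length(profiles)))
  m <- colMeans(cnt)
  v <- apply(cnt, 2, stats::var)
  gdiff <- m - v
  if (all(gdiff == 0)) {
    return(list(lambda = default,
                crossings = tibble::tibble(lambda = lambda_grid),
                grid = tibble::tibble(lambda = lambda_grid, mean = m, variance = v),
                plateau = TRUE))
  }
  cross <- numeric(0)
  for (i in seq_len(length(lambda_grid) - 1)) {
    g0 <- gdiff[i]; g1 <- gdiff[i + 1]
    if (g0 == 0) cross <- c(cross, lambda_grid[i])
    else if (g0 * g1 < 0) {
      cross <- c(cross, lambda_grid[i] + (lambda_grid[i + 1] - lambda_grid[i]) *
                   g0 / (g0 - g1))
    }
  }
  if (gdiff[length(gdiff)] == 0) cross <- c(cross, lambda_grid[length(lambda_grid)])
  cross <- unique(cross)
  if (!length(cross)) {
    stop(sprintf(
      "mean - variance never crosses zero on the grid (endpoints: %.3f at lambda = %g, %.3f at lambda = %g)",
      gdiff[1], lambda_grid[1], gdiff[length(gdiff)], lambda_grid[length(lambda_grid)]))
  }
  list(lambda = cross[which.min(abs(cross - default))],
       crossings = tibble::tibble(lambda = cross,
                                  nearest_default = cross == cross[which.min(abs(cross - default))]),
       grid = tibble::tibble(lambda = lambda_grid, mean = m, variance = v),
       plateau = FALSE)
}

#' Grid search with k-fold cross-validation for (d, lambda)
#'
#' Partitions the labeled images into `k` folds; for every (d, lambda) on
#' the grid the cross-validated error is the mean over folds of the mean
#' absolute relative error on the held-out fold. The pair with the lowest
#' cross-validated error is returned; ties break toward smaller d, then
#' smaller lambda. Fold assignment uses the current RNG stream; seed the
#' session for reproducibility.
#'
#' @param images List of grayscale matrices.
#' @param labels Integer labels (>= 1).
#' @param d_grid,lambda_grid Hyperparameter grids.
#' @param k Number of folds (default 10, reduced to `length(images)` if
#'   larger).
#' @return List with `d`, `lambda`, `cv` (tibble of d, lambda, cv_error)
#'   and `folds` (integer vector of fold ids).
#' @export
grid_search_cv <- function(images, labels, d_grid, lambda_grid, k = 10L) {
  n <- length(images)
  stopifnot(n == length(labels), n >= 2)
  k <- min(k, n)
  stopifnot(k >= 2 || n == 1)
  folds <- sample(rep(seq_len(k), length.out = n))
  err <- array(NA_real_, c(length(d_grid), length(lambda_grid), n))
  for (di in seq_along(d_grid)) {
    profs <- prepare_profiles(images, d = d_grid[di])
    for (li in seq_along(lambda_grid)) {
      cnt <- image_counts(profs, lambda_grid[li])
      err[di, li, ] <- abs(relative_error(cnt, labels))
    }
  }
  cv <- tibble::tibble(d = numeric(), lambda = numeric(), cv_error = numeric())
  for (di in seq_along(d_grid)) for (li in seq_along(lambda_grid)) {
    fe <- vapply(seq_len(k), function(f) mean(err[di, li, folds == f], na.rm = TRUE),
                 numeric(1))
    cv <- dplyr::bind_rows(cv, tibble::tibble(
      d = d_grid[di], lambda = lambda_grid[li], cv_error = mean(fe)))
  }
  best <- cv[order(cv$cv_error, cv$d, cv$lambda), ][1, ]
  list(d = best$d, lambda = best$lambda, cv = cv, folds = folds)
}

.mask_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  cv <- stats::cov(idx)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

#' Suggest a contour fineness d from elongated segments
#'
#' Emulates the empirical procedure for choosing d: select elongated
#' (two-colony-like) segments by an eccentricity heuristic, start from
#' d = 100 and halve until the median selected segment's contour splits
#' into 3-10 pieces; that d is returned as an advisory value. If no
#' elongated segment exists the default 0.5 is returned with a warning.
#'
#' @param segments List of segments from [label_segments()].
#' @param d_start Starting fineness (default 100).
#' @param pieces_range Target band for the median piece count (default
#'   c(3, 10)).
#' @param ecc_min Minimum mask eccentricity for a segment to count as
#'   elongated (default 0.6).
#' @param min_area Minimum area of a selected segment (default 50 px).
#' @return Suggested d (scalar).
#' @export
suggest_d <- function(segments, d_start = 100, pieces_range = c(3, 10),
                      ecc_min = 0.6, min_area = 50) {
  sel <- Filter(function(s) sum(s$mask) >= min_area &&
                  .mask_eccentricity(s$mask) >= ecc_min, segments)
  if (!length(sel)) {
    warning("no elongated segments found; returning default d = 0.5")
    return(0.5)
  }
  contours <- lapply(sel, trace_contours)
  pieces_at <- function(d) {
    stats::median(vapply(contours, function(cs) {
      sum(vapply(cs, function(cc) {
        tp <- approximate_polygon(cc, d)
        max(1L, length(find_concave_points(cc, tp)))
      }, integer(1)))
    }, numeric(1)))
  }
  d <- d_start
  d_prev <- NA_real_
  for (iter in 1:40) {
    np <- pieces_at(d)
    if (np >= pieces_range[1] && np <= pieces_range[2]) return(d)
    if (np < pieces_range[1]) {            # too coarse: halve
      d_prev <- d
      d <- d / 2
    } else {                               # overshot the band: bisect back up
      if (is.na(d_prev)) return(d)
      upper <- d_prev
      lower <- d
      for (j in 1:20) {
        mid <- (lower + upper) / 2
        np <- pieces_at(mid)
        if (np >= pieces_range[1] && np <= pieces_range[2]) return(mid)
        if (np < pieces_range[1]) upper <- mid else lower <- mid
      }
      warning(sprintf(
        "median piece count jumps over the %d-%d band; returning default d = 0.5",
        pieces_range[1], pieces_range[2]))
      return(0.5)
    }
    if (d < 1e-3) break
  }
  warning("no d in range achieves 3-10 pieces; returning default d = 0.5")
  0.5
}
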
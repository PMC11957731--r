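#' Specification for synthetic plate images
#'
#' Defines the study conditions for generated sub-images: bright
#' quasi-circular colonies on a dark background, per-well colony counts
#' drawn from a Poisson distribution (or fixed), radius variation, a merge
#' propensity that creates partially overlapping colonies with concave
#' waists, and additive Gaussian pixel noise.
#'
#' @param rows,cols Plate grid (default 8 x 12 = 96 wells).
#' @param well Side of one square sub-image in pixels (default 160).
#' @param mu Poisson mean of the per-well colony count (default 20).
#' @param radius_mean,radius_sd Colony radius distribution in pixels
#'   (normal, truncated at `radius_min`; defaults 7 and 1.5).
#' @param radius_min Minimum radius (default 4).
#' @param merge_q Probability that a new colony center is placed within
#'   `1.4 * radius` of an existing colony, producing merges (default 0.3).
#' @param noise_sd Additive Gaussian noise standard deviation (default 8).
#' @param fg,bg Foreground / background mean intensity (defaults 200 / 40).
#' @param no_merge If `TRUE`, colonies are placed so that all pairwise
#'   center distances exceed the radius sum plus a 3 px guard; used for
#'   exactness tests on the easy regime.
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(rows = 8L, cols = 12L, well = 160L, mu = 20,
                       radius_mean = 7, radius_sd = 1.5, radius_min = 4,
                       merge_q = 0.3, noise_sd = 8, fg = 200, bg = 40,
                       no_merge = FALSE) {
  stopifnot(rows >= 1, cols >= 1, well >= 16, mu > 0, radius_mean > 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 well = as.integer(well), mu = mu,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 radius_min = radius_min, merge_q = merge_q,
                 noise_sd = noise_sd, fg = fg, bg = bg,
                 no_merge = no_merge),
            class = "plate_spec")
}

.sample_radius <- function(spec) {
  max(spec$radius_min, stats::rnorm(1, spec$radius_mean, spec$radius_sd))
}

# place n colony circles in a well x well square; returns tibble(row, col, radius)
.place_colonies <- function(spec, n) {
  placed <- tibble::tibble(row = numeric(), col = numeric(), radius = numeric())
  margin <- spec$radius_mean + 3 * spec$radius_sd + 2
  lo <- 1 + margin; hi <- spec$well - margin
  for (i in seq_len(n)) {
    r <- .sample_radius(spec)
    for (try in 1:200) {
      if (!spec$no_merge && nrow(placed) > 0 && stats::runif(1) < spec$merge_q) {
        # merge: near an existing colony
        k <- sample.int(nrow(placed), 1)
        ang <- stats::runif(1, 0, 2 * pi)
        dist <- stats::runif(1, 0.95, 1.4) * placed$radius[k]
        cand <- c(placed$row[k] + dist * sin(ang), placed$col[k] + dist * cos(ang))
      } else {
        cand <- c(stats::runif(1, lo, hi), stats::runif(1, lo, hi))
      }
      if (cand[1] < lo || cand[1] > hi || cand[2] < lo || cand[2] > hi) next
      if (spec$no_merge && nrow(placed) > 0) {
        dd <- sqrt((placed$row - cand[1])^2 + (placed$col - cand[2])^2)
        if (any(dd <= placed$radius + r + 3)) next
      }
      if (!spec$no_merge && nrow(placed) > 0) {
        # keep centers distinct enough that every colony contributes pixels
        dd <- sqrt((placed$row - cand[1])^2 + (placed$col - cand[2])^2)
        if (any(dd < 0.6 * pmax(placed$radius, r))) next
      }
      placed <- dplyr::bind_rows(placed, tibble::tibble(
        row = cand[1], col = cand[2], radius = r))
      break
    }
  }
  placed
}

#' Generate one synthetic plate sub-image with ground truth
#'
#' Draws the colony count from Poisson(`mu`) unless `n` is given, places
#' disk colonies (with merges unless `no_merge`), renders them bright on a
#' dark background with additive Gaussian noise, and returns the image with
#' its label and the ground-truth circles. Deterministic for a fixed seed.
#'
#' @param spec A [plate_spec()].
#' @param n Colony count; `NULL` to draw from Poisson(`spec$mu`).
#' @param seed Optional integer; when given, generation runs under this
#'   seed without disturbing the global RNG stream.
#' @return List with `image` (integer matrix in \[0, 255\]), `label`
#'   (number of colonies actually placed) and `truth` (tibble of circles).
#' @export
generate_subimage <- function(spec, n = NULL, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_subimage(spec, n = n)))
  }
  if (is.null(n)) n <- stats::rpois(1, spec$mu)
  placed <- .place_colonies(spec, n)
  w <- spec$well
  img <- matrix(spec$bg, w, w)
  if (nrow(placed) > 0) {
    rr <- row(img); cc <- col(img)
    fgmask <- matrix(FALSE, w, w)
    for (i in seq_len(nrow(placed))) {
      fgmask <- fgmask | ((rr - placed$row[i])^2 + (cc - placed$col[i])^2 <=
                            placed$radius[i]^2)
    }
    img[fgmask] <- spec$fg
  }
  img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  img <- matrix(pmin(255, pmax(0, round(img))), w, w)
  list(image = img, label = nrow(placed), truth = placed)
}

#' Generate a full synthetic plate
#'
#' Composites `rows x cols` sub-images on a grid (default 96 wells) and
#' returns the plate image with per-well labels.
#'
#' @inheritParams generate_subimage
#' @return List with `image` (plate matrix), `labels` (tibble: `well_row`,
#'   `well_col`, `well`, `label`) and `truth` (tibble of circles in plate
#'   coordinates).
#' @export
generate_plate <- function(spec, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_plate(spec)))
  }
  w <- spec$well
  plate <- matrix(0, spec$rows * w, spec$cols * w)
  labels <- tibble::tibble(well_row = integer(), well_col = integer(),
                           well = integer(), label = integer())
  truth <- tibble::tibble(row = numeric(), col = numeric(), radius = numeric())
  id <- 0L
  for (i in seq_len(spec$rows)) {
    for (j in seq_len(spec$cols)) {
      id <- id + 1L
      sub <- generate_subimage(spec)
      r0 <- (i - 1L) * w; c0 <- (j - 1L) * w
      plate[r0 + 1:w, c0 + 1:w] <- sub$image
      labels <- dplyr::bind_rows(labels, tibble::tibble(
        well_row = i, well_col = j, well = id, label = sub$label))
      if (nrow(sub$truth)) {
        tt <- sub$truth
        tt$row <- tt$row + r0; tt$col <- tt$col + c0
        truth <- dplyr::bind_rows(truth, tt)
      }
    }
  }
  list(image = plate, labels = labels, truth = truth)
}

#' Generate a labeled synthetic sub-image dataset
#'
#' @inheritParams generate_subimage
#' @param n_images Number of sub-images.
#' @return List with `images` (list of matrices) and `labels` (integer
#'   vector).
#' @export
generate_dataset <- function(spec, n_images, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_dataset(spec, n_images)))
  }
  subs <- lapply(seq_len(n_images), function(i) generate_subimage(spec))
  list(images = lapply(subs, `[[`, "image"),
       labels = vapply(subs, `[[`, integer(1), "label"),
       truth = lapply(subs, `[[`, "truth"))
}
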
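new_circle_table <- function(row = numeric(), col = numeric(),
                             radius = numeric(), source = character(),
                             piece = integer()) {
  tibble::tibble(row = row, col = col, radius = radius,
                 source = source, piece = piece)
}

#' Candidate circles from distance-transform peaks
#'
#' Computes the Euclidean distance transform of the segment mask; every
#' local maximum is a candidate colony center with radius equal to the
#' distance value there. Maxima lying within the radius of a stronger
#' (larger) retained maximum are suppressed, and maxima below `min_radius`
#' are dropped.
#'
#' @param seg A segment or logical mask.
#' @param min_radius Minimum radius in pixels (default 2).
#' @return Tibble of candidate circles (`row`, `col`, `radius`,
#'   `source = "distance_transform"`, `piece = NA`), in mask coordinates.
#' @export
distance_transform_circles <- function(seg, min_radius = 2) {
  mask <- if (inherits(seg, "colony_segment")) seg$mask else seg
  stopifnot(is.logical(mask))
  if (!any(mask)) return(new_circle_table())
  # pad so that mask pixels on the matrix edge see background
  nr <- nrow(mask); nc <- ncol(mask)
  pm <- matrix(FALSE, nr + 2L, nc + 2L)
  pm[2:(nr + 1L), 2:(nc + 1L)] <- mask
  dm <- EBImage::distmap(pm * 1)
  dm <- dm[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  # local maxima over the 8-neighbourhood
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- dm
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  ismax <- ctr >= min_radius
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & ctr >= pad[2:(nr + 1L) + dr, 2:(nc + 1L) + dc]
  }
  peaks <- which(ismax, arr.ind = TRUE)
  if (nrow(peaks) == 0) return(new_circle_table())
  vals <- ctr[peaks]
  ord <- order(-vals, peaks[, 1], peaks[, 2])
  peaks <- peaks[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    ok <- TRUE
    for (j in keep) {
      dist <- sqrt(sum((peaks[i, ] - peaks[j, ])^2))
      if (dist <= max(vals[i], vals[j])) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  new_circle_table(row = as.numeric(peaks[keep, 1]),
                   col = as.numeric(peaks[keep, 2]),
                   radius = vals[keep],
                   source = rep("distance_transform", length(keep)),
                   piece = rep(NA_integer_, length(keep)))
}

#' Algebraic least-squares circle fit (Kasa method)
#'
#' Fits a circle to points by minimizing the algebraic residual
#' sum((x - a)^2 + (y - b)^2 - r^2)^2, a linear least-squares problem that
#' is exact on noiseless circular data.
#'
#' @param points n x 2 matrix of (row, col) coordinates, or a contour piece.
#' @return List with `row`, `col`, `radius`, and `degenerate` (`TRUE` when
#'   fewer than 3 distinct points or collinear points make the system
#'   singular; center/radius are `NA` then).
#' @export
fit_circle_lsq <- function(points) {
  if (inherits(points, "contour_piece")) points <- points$points
  pts <- unique(points)
  if (nrow(pts) < 3) {
    return(list(row = NA_real_, col = NA_real_, radius = NA_real_, degenerate = TRUE))
  }
  y <- pts[, 1]; x <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  qa <- qr(A)
  if (qa$rank < 3) {
    return(list(row = NA_real_, col = NA_real_, radius = NA_real_, degenerate = TRUE))
  }
  sol <- qr.coef(qa, b)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) {
    return(list(row = NA_real_, col = NA_real_, radius = NA_real_, degenerate = TRUE))
  }
  list(row = unname(sol[2]), col = unname(sol[1]),
       radius = sqrt(r2), degenerate = FALSE)
}

#' Collect candidate circles for a segment
#'
#' Union of distance-transform circles and the least-squares circle of each
#' contour piece. Fitted circles whose radius exceeds `max_radius_factor`
#' times the segment's largest distance-transform value are discarded as
#' runaway fits of near-straight pieces. Near-duplicates (center distance
#' and radius difference both < 1 px) are merged, keeping the
#' distance-transform circle.
#'
#' @param seg A segment or logical mask.
#' @param pieces Contour pieces from [segment_pieces()].
#' @param min_radius Minimum distance-transform radius (default 2).
#' @param max_radius_factor Runaway-fit cutoff (default 3).
#' @return Tibble of candidate circles in mask coordinates.
#' @export
collect_candidates <- function(seg, pieces, min_radius = 2, max_radius_factor = 3) {
  mask <- if (inherits(seg, "colony_segment")) seg$mask else seg
  dt <- distance_transform_circles(mask, min_radius = min_radius)
  dmax <- if (nrow(dt)) max(dt$radius) else {
    nr <- nrow(mask); nc <- ncol(mask)
    pm <- matrix(FALSE, nr + 2L, nc + 2L)
    pm[2:(nr + 1L), 2:(nc + 1L)] <- mask
    max(EBImage::distmap(pm * 1))
  }
  fits <- new_circle_table()
  for (i in seq_along(pieces)) {
    f <- fit_circle_lsq(pieces[[i]])
    if (f$degenerate) next
    if (f$radius > max_radius_factor * dmax) next
    fits <- dplyr::bind_rows(fits, new_circle_table(
      row = f$row, col = f$col, radius = f$radius,
      source = "contour_fit", piece = i))
  }
  cand <- dplyr::bind_rows(dt, fits)   # distance-transform first: kept on dedup
  if (nrow(cand) < 2) return(cand)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand) - 1L)) {
    if (!keep[i]) next
    for (j in (i + 1L):nrow(cand)) {
      if (!keep[j]) next
      cd <- sqrt((cand$row[i] - cand$row[j])^2 + (cand$col[i] - cand$col[j])^2)
      if (cd < 1 && abs(cand$radius[i] - cand$radius[j]) < 1) keep[j] <- FALSE
    }
  }
  cand[keep, ]
}
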
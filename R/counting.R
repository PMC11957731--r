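#' Build the pairing instance of one segment
#'
#' Runs contour splitting and candidate-circle generation for a segment and
#' precomputes the distance matrix and the exact assignment-cost profile,
#' so that the colony count can then be read off for any penalty `lambda`
#' without re-solving the geometry.
#'
#' @param seg A segment from [label_segments()] or a logical mask.
#' @param d Contour fineness in pixels (default 0.5).
#' @param min_radius,max_radius_factor Passed to [collect_candidates()].
#' @param max_candidates Passed to [pairing_profile()].
#' @return Object of class `segment_instance`: `pieces`, `circles`, `D`,
#'   `profile` (`NULL` when the segment yields no candidate circles, in
#'   which case it counts as one colony).
#' @export
segment_instance <- function(seg, d = 0.5, min_radius = 2,
                             max_radius_factor = 3, max_candidates = 14L) {
  stopifnot(d > 0)
  pieces <- segment_pieces(seg, d = d)
  circles <- collect_candidates(seg, pieces, min_radius = min_radius,
                                max_radius_factor = max_radius_factor)
  if (nrow(circles) == 0) {
    return(structure(list(segment = seg, pieces = pieces, circles = circles,
                          D = NULL, profile = NULL),
                     class = "segment_instance"))
  }
  D <- pairing_matrix(pieces, circles)
  profile <- pairing_profile(D, max_candidates = max_candidates)
  structure(list(segment = seg, pieces = pieces, circles = circles,
                 D = D, profile = profile),
            class = "segment_instance")
}

#' Count the colonies in one segment
#'
#' @inheritParams segment_instance
#' @param lambda Penalty on the number of selected circles (default 26).
#' @param instance Optionally a precomputed [segment_instance()].
#' @return List with `count` and `circles` (tibble of the selected circles
#'   in mask coordinates; empty with a warning-backed fallback count of 1
#'   when the segment produced no candidates).
#' @export
count_segment <- function(seg, d = 0.5, lambda = 26, instance = NULL, ...) {
  if (is.null(instance)) instance <- segment_instance(seg, d = d, ...)
  if (is.null(instance$profile)) {
    warning("segment has no candidate circles; counted as 1 colony")
    return(list(count = 1L, circles = new_circle_table(), instance = instance))
  }
  sol <- solve_pairing(instance$D, lambda)
  list(count = sol$count,
       circles = instance$circles[sol$selected, ],
       instance = instance)
}

#' Count the colonies in a plate sub-image
#'
#' Full pipeline: Otsu binarization, morphological cleaning, connected
#' component labeling, then per-segment contour splitting, candidate-circle
#' generation and exact pairing optimization.
#'
#' @param img Grayscale matrix in \[0, 255\] (see [read_gray()]).
#' @param d Contour fineness in pixels (default 0.5).
#' @param lambda Circle-count penalty (default 26).
#' @param invert `TRUE` for dark colonies on light agar.
#' @param min_area Minimum segment area in pixels (default 9).
#' @param image_id Identifier recorded in the result.
#' @param ... Passed to [segment_instance()].
#' @return Object of class `colony_count`; see [tidy.colony_count()],
#'   [glance.colony_count()] and [autoplot.colony_count()].
#' @export
count_image <- function(img, d = 0.5, lambda = 26, invert = FALSE,
                        min_area = 9L, image_id = NA_character_, ...) {
  mask <- clean_mask(binarize(img, invert = invert))
  segments <- label_segments(mask, min_area = min_area)
  per_segment <- tibble::tibble(segment = integer(), count = integer(),
                                n_pieces = integer(), n_candidates = integer())
  circles <- new_circle_table()
  circles$segment <- integer()
  for (s in segments) {
    res <- count_segment(s, d = d, lambda = lambda, ...)
    per_segment <- dplyr::bind_rows(per_segment, tibble::tibble(
      segment = s$id, count = res$count,
      n_pieces = length(res$instance$pieces),
      n_candidates = nrow(res$instance$circles)))
    if (nrow(res$circles)) {
      cc <- res$circles
      cc$row <- cc$row + s$offset[1] - 1L      # back to image coordinates
      cc$col <- cc$col + s$offset[2] - 1L
      cc$segment <- s$id
      circles <- dplyr::bind_rows(circles, cc)
    }
  }
  structure(list(image_id = image_id, image = img, mask = mask,
                 segments = segments, per_segment = per_segment,
                 circles = circles, total = sum(per_segment$count),
                 d = d, lambda = lambda),
            class = "colony_count")
}

#' @export
print.colony_count <- function(x, ...) {
  cat(sprintf("<colony_count%s: %d colonies in %d segment(s) (d = %g, lambda = %g)>\n",
              if (is.na(x$image_id)) "" else paste0(" ", x$image_id),
              x$total, nrow(x$per_segment), x$d, x$lambda))
  invisible(x)
}

#' Per-segment counts of a colony-count result
#'
#' @param x A `colony_count` object.
#' @param ... Unused.
#' @return Tibble with one row per segment: `segment`, `count`, `n_pieces`,
#'   `n_candidates`.
#' @exportS3Method generics::tidy
tidy.colony_count <- function(x, ...) {
  x$per_segment
}

#' One-row summary of a colony-count result
#'
#' @param x A `colony_count` object.
#' @param ... Unused.
#' @return Tibble with `image_id`, `total`, `n_segments`, `d`, `lambda`.
#' @exportS3Method generics::glance
glance.colony_count <- function(x, ...) {
  tibble::tibble(image_id = x$image_id, total = x$total,
                 n_segments = nrow(x$per_segment), d = x$d, lambda = x$lambda)
}

#' Overlay the selected colony circles on the image
#'
#' @param object A `colony_count` object.
#' @param ... Unused.
#' @return A ggplot: grayscale image raster with the selected circles.
#' @exportS3Method ggplot2::autoplot
autoplot.colony_count <- function(object, ...) {
  img <- object$image
  df <- tibble::tibble(
    row = as.vector(row(img)), col = as.vector(col(img)),
    intensity = as.vector(img))
  th <- seq(0, 2 * pi, length.out = 90)
  circ <- object$circles
  paths <- purrr::pmap_dfr(
    list(circ$row, circ$col, circ$radius, seq_len(nrow(circ))),
    function(r, c, rad, id) tibble::tibble(
      row = r + rad * sin(th), col = c + rad * cos(th), circle = id))
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df, ggplot2::aes(x = .data$col, y = .data$row,
                                                 fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_path(data = paths,
                       ggplot2::aes(x = .data$col, y = .data$row,
                                    group = .data$circle),
                       color = "red", linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%d colonies (d = %g, lambda = %g)",
                                  object$total, object$d, object$lambda),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Signed relative counting error
#'
#' (count - label) / label; positive = overestimate. Averages of the error
#' rate use the absolute value; the sign is kept for over/under-estimation
#' analysis. Labels < 1 (including -1 for unlabelable segments) give `NA`
#' and are excluded from averages.
#'
#' @param count Integer counted colonies.
#' @param label Integer ground-truth labels.
#' @return Numeric vector of signed fractions (`NA` where label < 1).
#' @export
relative_error <- function(count, label) {
  ifelse(label >= 1, (count - label) / label, NA_real_)
}

#' Indicator counting error
#'
#' 1 when the count differs from the label, else 0; `NA` where label < 1.
#'
#' @inheritParams relative_error
#' @return Numeric vector of 0/1 (`NA` where label < 1).
#' @export
indicator_error <- function(count, label) {
  ifelse(label >= 1, as.numeric(count != label), NA_real_)
}

#' Error summary for a set of counts against labels
#'
#' @inheritParams relative_error
#' @return One-row tibble: `n` (labeled cases used), `mean_abs_error`
#'   (mean |relative error|), `mean_signed_error`, `indicator_rate`
#'   (fraction miscounted), `n_excluded`.
#' @export
counting_errors <- function(count, label) {
  rel <- relative_error(count, label)
  ind <- indicator_error(count, label)
  ok <- !is.na(rel)
  tibble::tibble(
    n = sum(ok),
    mean_abs_error = mean(abs(rel[ok])),
    mean_signed_error = mean(rel[ok]),
    indicator_rate = mean(ind[ok]),
    n_excluded = sum(!ok))
}
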
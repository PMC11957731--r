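# Directions for Moore-neighbour tracing, clockwise in display coordinates
# (row down, col right): E, SE, S, SW, W, NW, N, NE.
.moore <- cbind(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
                dc = c(1, 1, 0, -1, -1, -1, 0, 1))

# Moore-neighbour border following with Jacob's stopping criterion.
# mask: logical (unpadded); start: c(row, col) foreground pixel;
# back: c(row, col) background neighbour of start; ccw: scan direction.
.trace_boundary <- function(mask, start, back, ccw = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc && mask[p[1], p[2]]
  dir_of <- function(from, to) {
    d <- to - from
    which(.moore[, 1] == d[1] & .moore[, 2] == d[2])
  }
  step <- if (ccw) -1L else 1L
  pts <- matrix(NA_integer_, 4L * sum(mask) + 8L, 2L)
  pts[1L, ] <- start
  npts <- 1L
  cur <- start
  bdir <- dir_of(cur, back)
  first_move <- NULL
  repeat {
    found <- FALSE
    d <- bdir
    for (k in 1:8) {
      d <- ((d - 1L + step) %% 8L) + 1L
      nb <- cur + .moore[d, ]
      if (fg(nb)) {
        # Jacob's criterion: back at start making the same first move
        if (!is.null(first_move) && all(cur == start) && d == first_move) {
          return(pts[seq_len(npts - 1L), , drop = FALSE])
        }
        if (is.null(first_move)) first_move <- d
        npts <- npts + 1L
        if (npts > nrow(pts)) return(pts[seq_len(npts - 1L), , drop = FALSE])
        pts[npts, ] <- nb
        # backtrack = previously scanned (background) neighbour of cur
        prev_d <- ((d - 1L - step) %% 8L) + 1L
        bdir <- dir_of(nb, cur + .moore[prev_d, ])
        cur <- nb
        found <- TRUE
        break
      }
    }
    if (!found) return(pts[seq_len(npts), , drop = FALSE]) # isolated pixel
    if (npts > 4L * sum(mask) + 6L) return(pts[seq_len(npts), , drop = FALSE])
  }
}

.shoelace <- function(pts) {
  if (nrow(pts) < 3) return(0)
  x <- pts[, 2]; y <- pts[, 1]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

new_contour <- function(points, kind) {
  a <- .shoelace(points)
  structure(list(points = points, kind = kind,
                 orientation = if (a >= 0) "positive" else "negative",
                 area = a),
            class = "colony_contour")
}

#' @export
print.colony_contour <- function(x, ...) {
  cat(sprintf("<colony_contour: %s, %d points, %s orientation>\n",
              x$kind, nrow(x$points), x$orientation))
  invisible(x)
}

#' Trace the outer and inner contours of a segment
#'
#' Follows the segment boundary with the classic Moore-neighbour border
#' following algorithm (Jacob's stopping criterion). The outer contour is
#' traced first; each hole yields one inner contour, traced in the opposite
#' rotational direction so that the foreground always lies on the same side.
#' Coordinates are relative to the segment mask (1-based row, col).
#'
#' @param seg A segment from [label_segments()], or a logical mask.
#' @param min_hole_area Holes smaller than this many pixels are ignored as
#'   rasterization specks (default 5).
#' @return List of contours; each has `points` (n x 2 integer matrix),
#'   `kind` (`"outer"`/`"inner"`) and `orientation` (sign of the shoelace
#'   area in row-down coordinates).
#' @export
trace_contours <- function(seg, min_hole_area = 5L) {
  mask <- if (inherits(seg, "colony_segment")) seg$mask else seg
  stopifnot(is.logical(mask), any(mask))
  idx <- which(mask, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  start <- idx[ord[1], ]                       # topmost, then leftmost
  out <- .trace_boundary(mask, start, start + c(0, -1), ccw = FALSE)
  contours <- list(new_contour(out, "outer"))
  # holes: filled mask minus mask
  filled <- EBImage::fillHull(mask * 1) > 0
  holes <- filled & !mask
  if (any(holes)) {
    hl <- EBImage::bwlabel(holes * 1)
    for (h in seq_len(max(hl))) {
      hidx <- which(hl == h, arr.ind = TRUE)
      if (nrow(hidx) < min_hole_area) next
      hord <- order(hidx[, 1], hidx[, 2])
      hp <- hidx[hord[1], ]                    # topmost-leftmost hole pixel
      fgstart <- hp + c(-1, 0)                 # pixel above is foreground
      inn <- .trace_boundary(mask, fgstart, hp, ccw = TRUE)
      # store inner contours with the opposite rotational sense to the outer
      # contour, so the foreground lies on the same side along both
      if (nrow(inn) > 1) inn <- inn[nrow(inn):1, , drop = FALSE]
      contours <- c(contours, list(new_contour(inn, "inner")))
    }
  }
  contours
}

.chord_dist <- function(p, a, b) {
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len < .Machine$double.eps) return(sqrt(sum((p - a)^2)))
  abs(ab[2] * (p[1] - a[1]) - ab[1] * (p[2] - a[2])) / len
}

#' Approximate a contour by a polygon of turning points
#'
#' Selects turning points by iterative vertex pruning: starting from all
#' contour pixels, the vertex whose perpendicular distance to the chord
#' joining its two surviving neighbours is smallest is removed, as long as
#' that distance is below the fineness parameter `d`. On exit every retained
#' consecutive triple (T\[i-1\], T\[i\], T\[i+1\]) has chord distance >= `d`.
#' Smaller `d` keeps more turning points; the count is non-increasing in `d`.
#'
#' @param contour A contour from [trace_contours()].
#' @param d Fineness in pixels (> 0). The perpendicular distance from a
#'   vertex to its neighbours' chord must reach `d` for the vertex to
#'   survive.
#' @return List with `indices` (sorted positions into `contour$points`) and
#'   `d_used`.
#' @export
approximate_polygon <- function(contour, d) {
  stopifnot(d > 0)
  pts <- contour$points
  n <- nrow(pts)
  if (n < 3) {
    return(list(indices = seq_len(n), d_used = d))
  }
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  dd <- numeric(n)
  for (i in seq_len(n)) dd[i] <- .chord_dist(pts[i, ], pts[prv[i], ], pts[nxt[i], ])
  alive <- n
  while (alive > 3L) {
    i <- which.min(dd)                 # ties: lowest index, deterministic
    if (dd[i] >= d) break
    p <- prv[i]; q <- nxt[i]
    nxt[p] <- q; prv[q] <- p
    dd[i] <- Inf
    alive <- alive - 1L
    dd[p] <- .chord_dist(pts[p, ], pts[prv[p], ], pts[nxt[p], ])
    dd[q] <- .chord_dist(pts[q, ], pts[prv[q], ], pts[nxt[q], ])
  }
  list(indices = which(is.finite(dd)), d_used = d)
}

#' Find concave turning points on a contour
#'
#' A turning point is concave when the polygon boundary turns inward with
#' respect to the foreground, i.e. the signed turn (z component of the cross
#' product of the incoming and outgoing polygon edges) is opposite to the
#' polygon's orientation sign. On inner contours the convention flips: there
#' the split points are the sharp turns *with* the orientation sign, which
#' are the corners where two colony boundaries meet around a hole. Convex
#' shapes yield no concave points.
#'
#' @param contour A contour from [trace_contours()].
#' @param turning Result of [approximate_polygon()].
#' @return Sorted integer vector of concave-point positions into
#'   `contour$points` (possibly empty).
#' @export
find_concave_points <- function(contour, turning) {
  idx <- turning$indices
  k <- length(idx)
  if (k < 3) return(integer(0))
  poly <- contour$points[idx, , drop = FALSE]
  a <- .shoelace(poly)
  if (a == 0) return(integer(0))
  x <- poly[, 2]; y <- poly[, 1]
  xp <- c(x[k], x[-k]); yp <- c(y[k], y[-k])
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- (x - xp) * (yn - y) - (y - yp) * (xn - x)
  concave <- if (contour$kind == "inner") cross * a > 0 else cross * a < 0
  sort(idx[concave])
}

new_piece <- function(points, parent, endpoints) {
  structure(list(points = points, parent = parent, endpoints = endpoints),
            class = "contour_piece")
}

#' @export
print.contour_piece <- function(x, ...) {
  cat(sprintf("<contour_piece: %d points>\n", nrow(x$points)))
  invisible(x)
}

#' Split a contour into pieces at its concave points
#'
#' With k >= 1 concave points the contour is split cyclically into k pieces,
#' each running from one concave point to the next (both endpoints
#' included, so adjacent pieces share their boundary point). With no
#' concave points the whole contour is a single piece.
#'
#' @param contour A contour from [trace_contours()].
#' @param concave Sorted concave-point positions from
#'   [find_concave_points()].
#' @param parent Identifier stored on each piece (default `NA`).
#' @return List of contour pieces.
#' @export
split_contour <- function(contour, concave, parent = NA_integer_) {
  pts <- contour$points
  n <- nrow(pts)
  k <- length(concave)
  if (k == 0) {
    return(list(new_piece(pts, parent, c(NA_integer_, NA_integer_))))
  }
  pieces <- vector("list", k)
  for (i in seq_len(k)) {
    from <- concave[i]
    to <- concave[if (i == k) 1L else i + 1L]
    run <- if (i == k) c(from:n, 1:to) else from:to
    pieces[[i]] <- new_piece(pts[run, , drop = FALSE], parent, c(from, to))
  }
  pieces
}

#' Extract the single-colony contour pieces of a segment
#'
#' Convenience wrapper: traces all contours of a segment, prunes each to its
#' turning points at fineness `d`, finds the concave points, and splits.
#'
#' @inheritParams approximate_polygon
#' @param seg A segment or logical mask.
#' @return List of contour pieces from all contours of the segment.
#' @export
segment_pieces <- function(seg, d = 0.5) {
  contours <- trace_contours(seg)
  out <- list()
  for (ci in seq_along(contours)) {
    cc <- contours[[ci]]
    tp <- approximate_polygon(cc, d)
    conc <- find_concave_points(cc, tp)
    out <- c(out, split_contour(cc, conc, parent = ci))
  }
  out
}
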
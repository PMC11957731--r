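#' Distance between a contour piece and a candidate circle
#'
#' The pairing distance is the sum, over the pixels p of the piece, of the
#' distance from p to the nearest point of the circle's edge. For a circle
#' with center c and radius r that nearest-point distance is exactly
#' | ||p - c|| - r |, so the sum is evaluated analytically.
#'
#' @param piece A contour piece or an n x 2 (row, col) matrix.
#' @param circle A list or one-row tibble with `row`, `col`, `radius`.
#' @return Non-negative scalar (summed pixel distance).
#' @export
pairing_distance <- function(piece, circle) {
  pts <- if (inherits(piece, "contour_piece")) piece$points else piece
  sum(abs(sqrt((pts[, 1] - circle$row)^2 + (pts[, 2] - circle$col)^2) - circle$radius))
}

#' Distance matrix between pieces and candidate circles
#'
#' @param pieces List of contour pieces.
#' @param circles Tibble of candidate circles.
#' @return M x N matrix, rows = pieces, columns = circles.
#' @export
pairing_matrix <- function(pieces, circles) {
  M <- length(pieces); N <- nrow(circles)
  D <- matrix(0, M, N)
  for (j in seq_len(N)) {
    cj <- list(row = circles$row[j], col = circles$col[j], radius = circles$radius[j])
    for (i in seq_len(M)) D[i, j] <- pairing_distance(pieces[[i]], cj)
  }
  D
}

#' Exact assignment-cost profile over the number of selected circles
#'
#' For the distance matrix D (pieces x circles) computes, for every k, the
#' minimum total assignment cost f(k) = min over circle subsets S of size k
#' of sum_i min_{j in S} D\[i, j\], by exhaustive subset enumeration. The
#' profile makes the penalized objective exactly solvable for any lambda:
#' the optimum of sum_ij D_ij X_ij + lambda * sum_j Y_j is
#' min_k f(k) + lambda * k, and the minimizing k (smallest on ties) is the
#' colony count, which is then provably non-increasing in lambda.
#'
#' When N exceeds `max_candidates` the candidates closest to the pieces
#' (smallest column minima) are kept before enumeration, with a warning;
#' this guards the exponential enumeration and, in practice, discarded
#' circles are far from every piece and never selected.
#'
#' @param D M x N non-negative distance matrix.
#' @param max_candidates Enumeration guard (default 14).
#' @return Object of class `pairing_profile`: list with `cost` (f(k) for
#'   k = 1..K), `subsets` (list of optimal column index sets, in original
#'   column numbering), `M`, `N`.
#' @export
pairing_profile <- function(D, max_candidates = 14L) {
  stopifnot(is.matrix(D), all(is.finite(D)), all(D >= 0))
  M <- nrow(D); N <- ncol(D)
  stopifnot(M >= 1, N >= 1)
  cols <- seq_len(N)
  if (N > max_candidates) {
    message(sprintf("pruning candidate circles %d -> %d before enumeration", N, max_candidates))
    colmin <- apply(D, 2, min)
    cols <- sort(order(colmin)[seq_len(max_candidates)])
    D <- D[, cols, drop = FALSE]
    N <- max_candidates
  }
  K <- min(N, M)
  cost <- rep(Inf, K)
  subsets <- vector("list", K)
  # enumerate subsets as bit masks; rowmin(S) = pmin(rowmin(S \ lowbit), D[, lowbit])
  nsub <- bitwShiftL(1L, N)
  rowmins <- vector("list", nsub)          # indexed by mask + 1
  sizes <- integer(nsub)
  for (s in seq_len(nsub - 1L)) {
    low <- bitwAnd(s, -s)
    j <- 1L + as.integer(round(log2(low)))
    rest <- s - low
    rm <- if (rest == 0L) D[, j] else pmin(rowmins[[rest + 1L]], D[, j])
    rowmins[[s + 1L]] <- rm
    k <- sizes[rest + 1L] + 1L
    sizes[s + 1L] <- k
    if (k <= K) {
      cs <- sum(rm)
      if (cs < cost[k]) {
        cost[k] <- cs
        subsets[[k]] <- s
      }
    }
  }
  tosubset <- function(s) cols[which(bitwAnd(s, bitwShiftL(1L, 0:(N - 1L))) != 0L)]
  structure(list(cost = cost, subsets = lapply(subsets, tosubset), M = M, N = length(cols),
                 kept_cols = cols),
            class = "pairing_profile")
}

#' Colony count implied by a profile at a given penalty
#'
#' @param profile A [pairing_profile()].
#' @param lambda Penalty weight(s), >= 0.
#' @return Integer count(s): argmin_k f(k) + lambda * k, smallest k on ties.
#' @export
profile_count <- function(profile, lambda) {
  k <- seq_along(profile$cost)
  vapply(lambda, function(l) which.min(profile$cost + l * k), integer(1))
}

#' Solve the piece-to-circle pairing program
#'
#' Minimizes sum_ij D_ij X_ij + lambda * sum_j Y_j subject to: every piece
#' assigned to exactly one circle (sum_j X_ij = 1), a circle selected iff it
#' receives at least one piece (Y_j <= sum_i X_ij <= Y_j * M), all variables
#' binary. Solved exactly via the subset-cost profile; deterministic
#' (smallest selection on objective ties, lowest index on assignment ties).
#'
#' @param D M x N non-negative distance matrix (or a `pairing_profile`).
#' @param lambda Penalty weight lambda >= 0, in summed-pixel-distance units.
#' @param max_candidates Passed to [pairing_profile()] when `D` is a matrix.
#' @return Object of class `pairing_solution`: `X` (M x N binary), `Y`
#'   (length-N binary), `assignment` (column per row), `objective`, `count`.
#' @export
solve_pairing <- function(D, lambda, max_candidates = 14L) {
  stopifnot(length(lambda) == 1, is.finite(lambda), lambda >= 0)
  if (inherits(D, "pairing_profile")) {
    profile <- D
    D <- NULL
  } else {
    profile <- pairing_profile(D, max_candidates = max_candidates)
  }
  k <- profile_count(profile, lambda)
  sel <- profile$subsets[[k]]
  M <- profile$M; N <- profile$N
  if (is.null(D)) {
    return(structure(list(X = NULL, Y = NULL, selected = sel,
                          assignment = NULL,
                          objective = profile$cost[k] + lambda * k,
                          count = k),
                     class = "pairing_solution"))
  }
  Nfull <- ncol(D)
  assignment <- integer(M)
  for (i in seq_len(M)) {
    sub <- D[i, sel]
    assignment[i] <- sel[which.min(sub)]     # ties: lowest index
  }
  # under distance ties the lowest-index rule can leave a selected circle
  # without a piece; repair by moving a tied piece over (cost unchanged)
  repeat {
    uncovered <- setdiff(sel, assignment)
    if (!length(uncovered)) break
    moved <- FALSE
    for (cc in uncovered) {
      cand <- which(abs(D[, cc] - D[cbind(seq_len(M), assignment)]) < 1e-9 &
                      tabulate(match(assignment, sel), length(sel))[match(assignment, sel)] >= 2L)
      if (length(cand)) {
        assignment[cand[1]] <- cc
        moved <- TRUE
        break
      }
    }
    if (!moved) break                        # cannot occur for an optimal profile
  }
  X <- matrix(0L, M, Nfull)
  X[cbind(seq_len(M), assignment)] <- 1L
  Y <- integer(Nfull)
  Y[sel] <- 1L
  structure(list(X = X, Y = Y, selected = sel, assignment = assignment,
                 objective = sum(D[cbind(seq_len(M), assignment)]) + lambda * sum(Y),
                 count = sum(Y)),
            class = "pairing_solution")
}

#' @export
print.pairing_solution <- function(x, ...) {
  cat(sprintf("<pairing_solution: %d circle(s) selected, objective %.3f>\n",
              x$count, x$objective))
  invisible(x)
}

#' Colony count of a pairing solution
#'
#' The count is the number of selected circles, sum_j Y_j.
#'
#' @param sol A `pairing_solution`.
#' @return Integer count >= 1.
#' @export
count_from_solution <- function(sol) {
  sol$count
}
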
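# Geometric fixtures and independent oracles used across the suite.

# filled disk mask of radius r, centered, with padding
mk_disk_mask <- function(r, pad = 4) {
  n <- 2 * r + 2 * pad + 1
  c0 <- r + pad + 1
  g <- matrix(0, n, n)
  (row(g) - c0)^2 + (col(g) - c0)^2 <= r^2
}

# two overlapping disks along the column axis; returns mask + geometry
mk_peanut_mask <- function(r1, r2, dist, pad = 5) {
  n <- ceiling(2 * max(r1, r2) + dist + 2 * pad)
  c0 <- pad + max(r1, r2) + 1
  g <- matrix(0, n, n)
  m <- ((row(g) - c0)^2 + (col(g) - c0)^2 <= r1^2) |
    ((row(g) - c0)^2 + (col(g) - c0 - dist)^2 <= r2^2)
  list(mask = m, center1 = c(c0, c0), center2 = c(c0, c0 + dist),
       r1 = r1, r2 = r2)
}

# render a mask as a noisy bright-on-dark 8-bit image
mk_image_from_mask <- function(mask, fg = 200, bg = 40, noise = 8) {
  img <- ifelse(mask, fg, bg) + stats::rnorm(length(mask), 0, noise)
  matrix(pmin(255, pmax(0, round(img))), nrow(mask), ncol(mask))
}

# analytic intersection points of two circles (row, col per circle centers)
circle_intersections <- function(c1, r1, c2, r2) {
  d <- sqrt(sum((c2 - c1)^2))
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h2 <- r1^2 - a^2
  if (h2 < 0) return(NULL)
  h <- sqrt(h2)
  mid <- c1 + a * (c2 - c1) / d
  perp <- c(-(c2 - c1)[2], (c2 - c1)[1]) / d
  rbind(mid + h * perp, mid - h * perp)
}

# exhaustive Otsu oracle: scan all integer thresholds, maximize
# between-class variance computed from raw group means
otsu_bruteforce <- function(img) {
  v <- as.vector(img)
  best <- -Inf; bt <- 0L
  for (t in 0:254) {
    b <- v[v <= t]; f <- v[v > t]
    if (!length(b) || !length(f)) next
    w <- length(b) / length(v)
    s <- w * (1 - w) * (mean(b) - mean(f))^2
    if (s > best) { best <- s; bt <- t }
  }
  bt
}

# brute-force optimum of the pairing program: enumerate all N^M assignments,
# Y_j = 1 iff circle j receives a piece
pairing_bruteforce <- function(D, lambda) {
  M <- nrow(D); N <- ncol(D)
  asn <- rep(1L, M)
  best <- Inf
  repeat {
    cost <- sum(D[cbind(seq_len(M), asn)]) + lambda * length(unique(asn))
    if (cost < best) best <- cost
    i <- 1L
    while (i <= M && asn[i] == N) { asn[i] <- 1L; i <- i + 1L }
    if (i > M) break
    asn[i] <- asn[i] + 1L
  }
  best
}

# piece-to-circle distance by brute force over a 1-degree rasterization
pairing_distance_bruteforce <- function(points, circle) {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  qr_ <- circle$row + circle$radius * sin(th)
  qc_ <- circle$col + circle$radius * cos(th)
  sum(apply(points, 1, function(p) min(sqrt((p[1] - qr_)^2 + (p[2] - qc_)^2))))
}

# pieces of one contour concatenated back into the full cyclic sequence
reconstruct_from_pieces <- function(pieces) {
  out <- pieces[[1]]$points
  if (length(pieces) > 1) {
    for (i in 2:length(pieces)) out <- rbind(out, pieces[[i]]$points[-1, , drop = FALSE])
  }
  out[-nrow(out), , drop = FALSE]   # drop closing duplicate of the start
}

# is b a cyclic rotation of a (as ordered point sequences)?
is_rotation_of <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  start <- which(b[, 1] == a[1, 1] & b[, 2] == a[1, 2])
  for (s in start) {
    idx <- ((s - 1 + seq_len(nrow(b)) - 1) %% nrow(b)) + 1
    if (all(b[idx, ] == a)) return(TRUE)
  }
  FALSE
}
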
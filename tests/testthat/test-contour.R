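test_that("border following yields closed, 8-connected boundary contours", {
  m <- matrix(FALSE, 14, 14)
  m[3:12, 3:12] <- TRUE
  cs <- trace_contours(m)
  expect_length(cs, 1)
  pts <- cs[[1]]$points
  expect_identical(cs[[1]]$kind, "outer")
  # every contour pixel is a boundary pixel of the mask
  interior <- m
  interior[3:12, 3:12] <- FALSE
  interior[4:11, 4:11] <- TRUE
  expect_true(all(m[pts]))
  expect_false(any(interior[pts]))
  # closed and 8-connected
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  expect_true(all(pmax(abs(d[, 1]), abs(d[, 2])) == 1))
  expect_identical(nrow(pts), 36L)  # 10x10 square boundary
})

test_that("holes produce inner contours with opposite orientation", {
  ann <- mk_disk_mask(12) & !mk_disk_mask(6, pad = 10)
  cs <- trace_contours(ann)
  kinds <- vapply(cs, function(x) x$kind, character(1))
  expect_identical(sort(kinds), c("inner", "outer"))
  areas <- vapply(cs, function(x) x$area, numeric(1))
  expect_lt(prod(sign(areas)), 0)
})

test_that("degenerate segments trace without error", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  cs <- trace_contours(m)
  expect_length(cs, 1)
  expect_identical(nrow(cs[[1]]$points), 1L)

  line <- matrix(FALSE, 5, 9); line[3, 2:8] <- TRUE
  pts <- trace_contours(line)[[1]]$points
  expect_true(all(line[pts]))
})

test_that("polygon approximation keeps corners, satisfies the chord criterion, and is monotone in d", {
  # right triangle: at large d only the 3 corners survive
  m <- matrix(FALSE, 30, 30)
  for (i in 1:20) m[4 + i, 5:(4 + i)] <- TRUE
  cc <- trace_contours(m)[[1]]
  tp <- approximate_polygon(cc, d = 8)
  expect_identical(length(tp$indices), 3L)

  disk <- trace_contours(mk_disk_mask(20))[[1]]
  t_fine <- approximate_polygon(disk, 0.5)
  t_coarse <- approximate_polygon(disk, 5)
  expect_gt(length(t_fine$indices), length(t_coarse$indices))

  # postcondition: every surviving triple has chord distance >= d
  for (d in c(0.5, 2, 5)) {
    idx <- approximate_polygon(disk, d)$indices
    k <- length(idx)
    if (k < 4) next
    poly <- disk$points[idx, ]
    for (i in seq_len(k)) {
      a <- poly[if (i == 1) k else i - 1, ]
      b <- poly[if (i == k) 1 else i + 1, ]
      p <- poly[i, ]
      ab <- b - a
      dist <- abs(ab[2] * (p[1] - a[1]) - ab[1] * (p[2] - a[2])) / sqrt(sum(ab^2))
      expect_gte(dist, d)
    }
  }

  # monotone non-increase of turning-point count over a d sweep
  withr::local_seed(21)
  blob <- mk_peanut_mask(9, 12, 14)$mask
  cc2 <- trace_contours(blob)[[1]]
  counts <- vapply(c(0.3, 0.5, 1, 2, 4, 8, 16),
                   function(d) length(approximate_polygon(cc2, d)$indices), integer(1))
  expect_true(all(diff(counts) <= 0))

  # short contours are returned unchanged
  m1 <- matrix(FALSE, 4, 4); m1[2, 2] <- TRUE
  c1 <- trace_contours(m1)[[1]]
  expect_identical(approximate_polygon(c1, 1)$indices, 1L)
})

test_that("convex shapes have no concave points; waists and inner corners are found", {
  for (mask in list(mk_disk_mask(10), mk_disk_mask(16), {
    m <- matrix(FALSE, 20, 20); m[4:16, 5:15] <- TRUE; m
  })) {
    cc <- trace_contours(mask)[[1]]
    expect_length(find_concave_points(cc, approximate_polygon(cc, 1)), 0)
  }

  # peanut: exactly 2 concave points, within 3 px of the analytic
  # circle-circle intersections
  p <- mk_peanut_mask(10, 10, 14)
  cc <- trace_contours(p$mask)[[1]]
  conc <- find_concave_points(cc, approximate_polygon(cc, 1))
  expect_length(conc, 2)
  truth <- circle_intersections(p$center1, p$r1, p$center2, p$r2)
  got <- cc$points[conc, , drop = FALSE]
  for (i in 1:2) {
    errs <- sqrt(rowSums((truth - matrix(got[i, ], 2, 2, byrow = TRUE))^2))
    expect_lt(min(errs), 3)
  }

  # plus shape: 4 concave points at the inner corners
  m <- matrix(FALSE, 31, 31)
  m[13:19, 4:28] <- TRUE
  m[4:28, 13:19] <- TRUE
  cc <- trace_contours(m)[[1]]
  conc <- find_concave_points(cc, approximate_polygon(cc, 3))
  expect_length(conc, 4)
  corners <- rbind(c(13, 13), c(13, 19), c(19, 13), c(19, 19))
  got <- cc$points[conc, , drop = FALSE]
  for (i in 1:4) {
    expect_lt(min(sqrt(rowSums((corners - matrix(got[i, ], 4, 2, byrow = TRUE))^2))), 2)
  }

  # fewer than 3 turning points: no concavity test possible
  m1 <- matrix(FALSE, 4, 4); m1[2, 2:3] <- TRUE
  c1 <- trace_contours(m1)[[1]]
  expect_length(find_concave_points(c1, approximate_polygon(c1, 1)), 0)
})

test_that("splitting at k concave points yields k pieces that reconstruct the contour", {
  p <- mk_peanut_mask(10, 10, 14)
  cc <- trace_contours(p$mask)[[1]]
  conc <- find_concave_points(cc, approximate_polygon(cc, 1))
  pieces <- split_contour(cc, conc)
  expect_length(pieces, 2)
  expect_true(is_rotation_of(reconstruct_from_pieces(pieces), cc$points))

  # no concave points: one piece, the full contour
  disk <- trace_contours(mk_disk_mask(8))[[1]]
  one <- split_contour(disk, integer(0))
  expect_length(one, 1)
  expect_identical(one[[1]]$points, disk$points)

  # synthetic 5-way split of a disk contour
  n <- nrow(disk$points)
  cut <- sort(sample(n, 5))
  five <- split_contour(disk, cut)
  expect_length(five, 5)
  expect_true(all(vapply(five, function(p) nrow(p$points) > 0, logical(1))))
  expect_true(is_rotation_of(reconstruct_from_pieces(five), disk$points))
})

test_that("tiny rasterization holes are ignored while real holes are traced", {
  m <- mk_disk_mask(12)
  m[10, 10] <- FALSE                 # 1-px speck
  cs <- trace_contours(m)
  expect_length(cs, 1)
  expect_identical(cs[[1]]$kind, "outer")
})
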
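test_that("the piece-circle distance is analytic and matches brute force", {
  circ <- list(row = 0, col = 0, radius = 5)
  th <- seq(0, pi, length.out = 10)
  on_edge <- cbind(5 * sin(th), 5 * cos(th))
  expect_equal(pairing_distance(on_edge, circ), 0, tolerance = 1e-9)

  expect_equal(pairing_distance(rbind(c(8, 0)), circ), 3)

  withr::local_seed(12)
  for (i in 1:5) {
    pts <- matrix(stats::runif(20, -15, 15), ncol = 2)
    circ <- list(row = stats::runif(1, -3, 3), col = stats::runif(1, -3, 3),
                 radius = stats::runif(1, 2, 10))
    a <- pairing_distance(pts, circ)
    b <- pairing_distance_bruteforce(pts, circ)
    expect_lt(abs(a - b), 0.5 * nrow(pts))
    expect_lte(a, b + 1e-9)   # analytic min is never above the rasterized min
  }
})

test_that("the exact solver reproduces trivial and extreme-penalty optima", {
  # 1 piece, 1 circle
  sol <- solve_pairing(matrix(2, 1, 1), lambda = 7)
  expect_identical(sol$count, 1L)
  expect_equal(sol$objective, 9)
  expect_identical(sol$Y, 1L)
  expect_identical(count_from_solution(sol), 1L)

  withr::local_seed(5)
  D <- matrix(stats::runif(12, 0, 10), 3, 4)
  # lambda = 0: every piece goes to its nearest circle
  sol0 <- solve_pairing(D, 0)
  nearest <- apply(D, 1, which.min)
  expect_identical(sort(unique(sol0$assignment)), sort(unique(nearest)))
  expect_identical(sol0$count, length(unique(nearest)))
  expect_equal(sol0$objective, sum(apply(D, 1, min)))
  # huge lambda: a single circle absorbs everything
  solL <- solve_pairing(D, 1e6)
  expect_identical(solL$count, 1L)
  expect_identical(solL$selected, unname(which.min(colSums(D))))
})

test_that("solutions are feasible and optimal against exhaustive enumeration", {
  withr::local_seed(99)
  for (rep in 1:100) {
    M <- sample(1:4, 1); N <- sample(1:4, 1)
    D <- matrix(stats::runif(M * N, 0, 20), M, N)
    lambda <- stats::runif(1, 0, 15)
    sol <- solve_pairing(D, lambda)
    # feasibility: each piece assigned once; Y_j = 1 iff circle j used
    expect_true(all(rowSums(sol$X) == 1))
    expect_identical(as.integer(colSums(sol$X) > 0), sol$Y)
    expect_equal(sol$objective,
                 sum(D * sol$X) + lambda * sum(sol$Y), tolerance = 1e-9)
    # optimality
    expect_equal(sol$objective, pairing_bruteforce(D, lambda), tolerance = 1e-9)
  }
})

test_that("counts are non-increasing in lambda on any instance", {
  withr::local_seed(42)
  for (rep in 1:25) {
    M <- sample(2:6, 1); N <- sample(2:6, 1)
    D <- matrix(stats::runif(M * N, 0, 30), M, N)
    prof <- pairing_profile(D)
    counts <- profile_count(prof, seq(0, 60, length.out = 40))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("a toy peanut instance selects the two true circles in the mid-lambda range", {
  # 2 arcs; circles 1 and 2 fit one arc each, circle 3 is spurious
  D <- rbind(c(1, 40, 25),
             c(38, 2, 24))
  for (lambda in c(5, 15, 30)) {
    sol <- solve_pairing(D, lambda)
    expect_identical(sol$count, 2L)
    expect_identical(sol$selected, c(1L, 2L))
  }
  expect_identical(solve_pairing(D, 0)$count, 2L)
  expect_identical(solve_pairing(D, 1e5)$count, 1L)
  expect_identical(count_from_solution(solve_pairing(D, 1e5)), 1L)
})

test_that("candidate pruning keeps the useful circles on oversized instances", {
  withr::local_seed(8)
  M <- 5
  D_good <- matrix(stats::runif(M * 3, 0, 5), M, 3)
  D_junk <- matrix(stats::runif(M * 14, 200, 400), M, 14)
  D <- cbind(D_good, D_junk)
  expect_message(prof <- pairing_profile(D), "pruning")
  sol <- solve_pairing(prof, 1)
  expect_true(all(sol$selected %in% 1:3))
})
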
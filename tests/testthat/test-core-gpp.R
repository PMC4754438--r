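test_that("rr_series validates its input", {
  expect_error(rr_series(c(1, 2)), "at least 3")
  expect_error(rr_series(c(1, -0.5, 1)), "finite and > 0")
  expect_error(rr_series(c(1, NA, 1)), "finite and > 0")
  rr <- rr_series(c(0.8, 0.9, 1.0), subject_id = "a", group = "healthy")
  expect_s3_class(rr, "rr_series")
  expect_identical(length(rr), 3L)
})

test_that("summed windows produce N - j - k points with the right sums", {
  # constant series: three identical points at order (1,1)
  pts <- gpp_points(rep(1.0, 5), 1, 1)
  expect_equal(pts$n_points, 3L)
  expect_equal(pts$x, rep(1.0, 3))
  expect_equal(pts$y, rep(1.0, 3))

  # hand summation, first anchor: x = 0.8 + 0.9, y = 1.0
  pts <- gpp_points(c(0.8, 0.9, 1.0, 1.1), j = 2, k = 1)
  expect_equal(pts$n_points, 1L)
  expect_equal(pts$x, 1.7)
  expect_equal(pts$y, 1.0)

  expect_error(gpp_points(c(0.8, 0.9, 1.0), 2, 1), "insufficient intervals")
  expect_error(gpp_points(rep(1, 10), 0, 1), "positive integers")
})

test_that("point count law and window bounds hold over random orders", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    j <- sample.int(max(1, n %/% 3), 1)
    k <- sample.int(max(1, n - j - 1), 1)
    rr <- random_rr(n, seed = rep)
    pts <- gpp_points(rr, j, k)
    expect_identical(pts$n_points, n - j - k)
    expect_true(all(pts$x >= j * min(rr$intervals) - 1e-12))
    expect_true(all(pts$x <= j * max(rr$intervals) + 1e-12))
    expect_true(all(pts$y >= k * min(rr$intervals) - 1e-12))
    expect_true(all(pts$y <= k * max(rr$intervals) + 1e-12))
  }
})

test_that("gpp correlation handles exact lines and degenerate inputs", {
  up <- structure(list(x = 1:5 / 2, y = 1:5, j = 1L, k = 1L, n_points = 5L),
                  class = "gpp_points")
  expect_equal(gpp_cor(up), 1)
  down <- structure(list(x = 1:5, y = 5:1, j = 1L, k = 1L, n_points = 5L),
                    class = "gpp_points")
  expect_equal(gpp_cor(down), -1)
  flat <- structure(list(x = rep(2, 5), y = 1:5, j = 1L, k = 1L, n_points = 5L),
                    class = "gpp_points")
  expect_true(is.na(gpp_cor(flat)))
  short <- structure(list(x = 1:2, y = 1:2, j = 1L, k = 1L, n_points = 2L),
                     class = "gpp_points")
  expect_error(gpp_cor(short), "insufficient points")
})

test_that("cumulative-sum matrix equals the naive double-loop oracle", {
  for (seed in 1:3) {
    n <- c(60, 120, 200)[seed]
    rr <- random_rr(n, seed)
    got <- gpp_matrix(rr, m = 12, n = 12)
    want <- naive_gpp_matrix(rr, 12, 12)
    expect_equal(got$r, want, tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(got$defined, !is.na(want), ignore_attr = TRUE)
  }
})

test_that("cell (1,1) reduces to the classical Poincare correlation", {
  rr <- random_rr(150, 7)
  gm <- gpp_matrix(rr, 1, 1)
  v <- rr$intervals
  i <- seq_len(148)
  expect_equal(gm$r[1, 1], stats::cor(v[i], v[i + 1]))
})

test_that("short-series cells are masked rather than failing the call", {
  gm <- gpp_matrix(rr_series(c(0.8, 0.9, 1.0, 1.1, 0.7, 1.05)), m = 4, n = 4)
  # j + k must leave at least 3 points: N = 6 admits only j + k <= 3
  expect_true(gm$defined[1, 1])
  expect_false(gm$defined[2, 2])
  expect_false(gm$defined[4, 4])
  # constant series: every cell defined-length but zero variance -> masked
  gm0 <- gpp_matrix(rep(1, 50), m = 3, n = 3)
  expect_true(all(!gm0$defined))
  expect_error(gpp_matrix(rep(1, 50), m = 0, n = 3), "must be >= 1")
})

test_that("series reversal approximately transposes the matrix", {
  # exact only for the symmetric anchor set with N-j-k+1 points; with the
  # N-j-k convention the two point sets differ by one boundary anchor
  rr <- generate_correlated_series(2000, phi = 0.7, seed = 3)
  rev_rr <- rr_series(rev(rr$intervals))
  a <- gpp_matrix(rr, 6, 6)$r
  b <- gpp_matrix(rev_rr, 6, 6)$r
  expect_lt(max(abs(a - t(b))), 0.02)
})

test_that("SD1/SD2 follow the rotated-coordinate formulas", {
  two <- gpp_points(c(1, 2, 1, 2), 1, 1)   # points (1,2) and (2,1)
  expect_equal(unname(sd1_sd2(two)), c(sqrt(0.5), 0))
  expect_equal(unname(sd1_sd2(two, sample = TRUE)), c(1, 0))

  one <- gpp_points(rep(0.9, 6), 1, 1)
  expect_equal(unname(sd1_sd2(one)), c(0, 0))
  expect_error(sd1_sd2(gpp_points(c(0.8, 0.9, 1.0), 1, 1)), "at least 2 points")

  # order (1,1) matches the successive-difference identity sd1^2 = var(dRR)/2
  rr <- random_rr(300, 11)
  sd <- sd1_sd2(gpp_points(rr, 1, 1))
  d <- diff(rr$intervals)[1:298]
  expect_equal(unname(sd[["sd1"]]^2), mean((d - mean(d))^2) / 2,
               tolerance = 1e-12)
})
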
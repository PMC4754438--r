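test_that("mean absolute correlation follows the normalization definition", {
  expect_equal(mean_abs_r(matrix(0.5, 2, 2)), 0.5)
  expect_equal(mean_abs_r(rbind(c(0, 0.5), c(0.1, 0))), 0.15)
  # undefined cells contribute zero to the sum, denominator stays m*n
  expect_equal(mean_abs_r(rbind(c(NA, 0.5), c(0.1, NA))), 0.15)
  expect_error(mean_abs_r(matrix(NA_real_, 2, 2)), "no defined cells")
})

test_that("NAI matches its definition on hand-computed matrices", {
  # symmetric matrix: every transpose difference cancels
  set.seed(1)
  s <- matrix(runif(16, -1, 1), 4, 4); s <- (s + t(s)) / 2
  expect_equal(nai(s), 0)
  # 2x2 with r(1,2)=0.5, r(2,1)=0.1: (1/4)(1/0.15)(0.1-0.5) = -2/3
  expect_equal(nai(rbind(c(0, 0.5), c(0.1, 0))), -2 / 3, tolerance = 1e-12)
  expect_error(nai(matrix(0.1, 2, 3)), "square")
  expect_error(nai(matrix(0, 3, 3)), "undefined NAI")
})

test_that("NAI is antisymmetric under transposition and scale invariant", {
  set.seed(7)
  for (rep in 1:100) {
    m <- matrix(runif(25, -1, 1), 5, 5)
    expect_equal(nai(t(m)), -nai(m), tolerance = 1e-12)
  }
  m <- matrix(runif(36, -1, 1), 6, 6)
  expect_equal(nai(m * 0.25), nai(m), tolerance = 1e-12)
})

test_that("NAI sign tracks where the correlation mass sits", {
  # mass above the identity diagonal (k > j) -> negative
  above <- matrix(0, 5, 5); above[2, 4] <- 0.8
  expect_lt(nai(above), 0)
  below <- matrix(0, 5, 5); below[4, 2] <- 0.8
  expect_gt(nai(below), 0)
})

test_that("reshuffling permutes intervals deterministically", {
  rr <- random_rr(100, 5)
  sh1 <- reshuffle_rr(rr, seed = 9)
  sh2 <- reshuffle_rr(rr, seed = 9)
  expect_identical(sh1$intervals, sh2$intervals)
  expect_false(identical(sh1$intervals, rr$intervals))
  expect_identical(sort(sh1$intervals), sort(rr$intervals))
  expect_equal(sum(sh1$intervals), sum(rr$intervals))
})

test_that("surrogate matrix averages independent reshufflings", {
  rr <- random_rr(120, 3)
  one <- surrogate_matrix(rr, 5, 5, n_reps = 1, seed = 4)
  direct <- gpp_matrix(reshuffle_rr(rr, seed = one$child_seeds[1]), 5, 5)
  expect_equal(one$r, direct$r)

  ten <- surrogate_matrix(rr, 5, 5, n_reps = 10, seed = 4)
  expect_length(ten$child_seeds, 10)
  expect_true(all(abs(ten$r[ten$defined]) <= 1))
  # averaging 10 null matrices shrinks each cell well below a single draw
  big <- surrogate_matrix(generate_white_noise_series(2000, seed = 2),
                          10, 10, n_reps = 10, seed = 2)
  expect_lt(max(abs(big$r)), 0.1)
})

test_that("the gpp fit ties NAI, NAIsh and NAIC together", {
  rr <- generate_white_noise_series(400, seed = 6)
  fit <- gpp(rr, m = 8, n = 8, n_reshuffles = 5, seed = 6)
  expect_s3_class(fit, "gpp")
  expect_identical(fit$naic, fit$nai - fit$nai_sh)
  expect_equal(fit$r_bar, mean_abs_r(fit$matrix))
  expect_equal(fit$nai, nai(fit$matrix))
  expect_equal(fit$nai_sh, nai(fit$surrogate))
  co <- coef(fit)
  expect_named(co, c("r_bar", "nai", "nai_sh", "naic"))
  # refitting with the same seed reproduces everything
  fit2 <- gpp(rr, m = 8, n = 8, n_reshuffles = 5, seed = 6)
  expect_equal(coef(fit2), co)
  # skipping the surrogate leaves the corrected index undefined
  plain <- gpp(rr, m = 8, n = 8, surrogate = FALSE)
  expect_true(is.na(plain$nai_sh) && is.na(plain$naic))
})

test_that("white-noise matrices stay inside the null band", {
  # null sd of r(j,k) is inflated over 1/sqrt(npts) because overlapping
  # window sums are autocorrelated: var(r) ~ c_jk / npts with
  # c_jk = sum_h tri_j(h) * tri_k(h), tri_j(h) = max(0, 1 - |h|/j)
  c_jk <- function(j, k) {
    h <- -(max(j, k)):(max(j, k))
    sum(pmax(0, 1 - abs(h) / j) * pmax(0, 1 - abs(h) / k))
  }
  gm <- gpp_matrix(generate_white_noise_series(2000, seed = 8), 10, 10)
  bound <- outer(1:10, 1:10,
                 Vectorize(function(j, k) 3 * sqrt(c_jk(j, k) / (2000 - j - k))))
  expect_gte(mean(abs(gm$r) < bound), 0.95)
  expect_lt(max(abs(gm$r)), 0.25)
})
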
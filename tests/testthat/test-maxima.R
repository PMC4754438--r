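test_that("local maxima follow the strict 8-neighborhood rule", {
  m <- matrix(0, 5, 5); m[3, 3] <- 0.9; m[2, 4] <- 0.4
  mx <- find_local_maxima(m)
  expect_equal(nrow(mx), 1L)          # 0.4 touches the 0.9 neighborhood
  expect_equal(c(mx$j, mx$k, mx$r), c(3, 3, 0.9))

  # plateau: ties disqualify
  expect_equal(nrow(find_local_maxima(matrix(0.5, 4, 4))), 0L)

  # border and corner cells are eligible
  m2 <- matrix(0, 4, 4); m2[1, 1] <- 0.7; m2[4, 3] <- 0.6
  mx2 <- find_local_maxima(m2)
  expect_setequal(paste(mx2$j, mx2$k), c("1 1", "4 3"))
  # sorted by descending r
  expect_equal(mx2$r, sort(mx2$r, decreasing = TRUE))

  expect_message(out <- find_local_maxima(matrix(1, 2, 2)), "smaller than 3 x 3")
  expect_equal(nrow(out), 0L)
})

test_that("detector matches the brute-force scan on random matrices", {
  set.seed(13)
  for (rep in 1:8) {
    r <- matrix(rnorm(900, sd = 0.3), 30, 30)
    r[r > 1] <- 1; r[r < -1] <- -1
    r[sample(900, 60)] <- NA              # undefined holes
    got <- find_local_maxima(r)[, c("j", "k", "r")]
    want <- brute_maxima(r)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("pooling concatenates maxima with provenance intact", {
  a <- data.frame(j = c(2, 5, 9), k = c(3, 5, 1), r = c(0.5, 0.4, 0.2),
                  subject_id = "a", group = "healthy")
  b <- data.frame(j = c(1, 7, 2, 8), k = c(1, 2, 9, 8), r = c(0.9, 0.3, 0.25, 0.1),
                  subject_id = "b", group = "AF")
  pooled <- pool_maxima(list(a, b))
  expect_equal(nrow(pooled), 7L)
  expect_identical(pooled$r, c(a$r, b$r))
  expect_equal(unname(attr(pooled, "group_counts")[c("AF", "healthy")]),
               c(4L, 3L), ignore_attr = TRUE)
  empty <- pool_maxima(list(a[0, ], b[0, ]))
  expect_equal(nrow(empty), 0L)
})

test_that("k-means clustering of maxima is deterministic and recovers blobs", {
  blobs <- four_cluster_blobs(1)
  model <- cluster_maxima(blobs, k = "auto", seed = 1)
  expect_equal(model$n_clusters, 4L)
  tab <- table(blobs$lab, model$assignments)
  expect_gte(sum(apply(tab, 1, max)) / nrow(blobs), 0.95)

  again <- cluster_maxima(blobs, k = "auto", seed = 1)
  expect_identical(model$assignments, again$assignments)
  expect_equal(model$centroids, again$centroids)

  one <- cluster_maxima(blobs, k = 1, seed = 1)
  expect_equal(unlist(one$centroids),
               colMeans(blobs[, c("j", "k", "r")]), ignore_attr = TRUE)

  expect_error(cluster_maxima(blobs[1:3, ], k = 5, seed = 1), "cannot form")
})

test_that("cluster summaries report N, mean r and its standard error", {
  pts <- data.frame(j = c(1, 2, 3, 30, 31), k = c(1, 2, 3, 30, 31),
                    r = c(0.1, 0.2, 0.3, 0.8, 0.6),
                    subject_id = "s",
                    group = c("healthy", "healthy", "healthy", "healthy", "AF"))
  model <- cluster_maxima(pts, k = 2, seed = 2)
  tab <- summarize_clusters(model)
  low <- model$assignments[1]
  row <- tab[tab$cluster == low & tab$group == "healthy", ]
  expect_equal(row$n, 3L)
  expect_equal(row$mean_r, 0.2)
  expect_equal(row$se_r, stats::sd(c(0.1, 0.2, 0.3)) / sqrt(3), tolerance = 1e-12)
  # empty cluster-group cell and single-member SE
  af_low <- tab[tab$cluster == low & tab$group == "AF", ]
  expect_equal(af_low$n, 0L)
  expect_true(is.na(af_low$mean_r))
  hi <- setdiff(1:2, low)
  expect_true(is.na(tab[tab$cluster == hi & tab$group == "AF", "se_r"]))
})

test_that("Mann-Whitney comparison reports U, signed Z and p", {
  same <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p.value, 0.95)

  sep <- compare_groups(1:13 + 100, 1:13)   # complete separation, U = n1*n2
  expect_gt(abs(sep$Z), 4)
  expect_gt(sep$Z, 0)                        # first sample larger -> Z > 0
  expect_equal(sep$U, 169)
  flipped <- compare_groups(1:13, 1:13 + 100)
  expect_equal(flipped$Z, -sep$Z)

  # p agrees with the normal-approximation two-sided value
  set.seed(3)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  res <- compare_groups(a, b)
  expect_equal(res$p.value, 2 * stats::pnorm(-abs(res$Z)), tolerance = 1e-10)

  expect_error(compare_groups(numeric(0), 1:3), "nonempty")
  expect_error(compare_groups(c(1, 1), c(1, 1)), "degenerate")
})
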
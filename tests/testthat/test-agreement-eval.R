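mk_strides <- function(ic, len = 1.2, time = 1.1, foot = "right") {
  data.frame(foot = foot, ic_time = ic,
             stride_length = rep_len(len, length(ic)),
             stride_time = rep_len(time, length(ic)),
             stringsAsFactors = FALSE)
}

test_that("synchronization recovers a constructed shift", {
  ref <- mk_strides(seq(1, 10, by = 1.1))
  meas <- mk_strides(seq(1, 10, by = 1.1) - 3.5)
  expect_equal(synchronize_by_first_stride(meas, ref), 3.5)
  expect_equal(synchronize_by_first_stride(ref, ref), 0)
  expect_error(synchronize_by_first_stride(ref[0, ], ref), "empty")
})

test_that("greedy matching is one-to-one within tolerance", {
  ref <- mk_strides(seq(0, 10.9, by = 1.1), len = seq(1.0, 1.5, length.out = 10))
  m <- match_strides(ref, ref, 0, 0.25, "stride_length")
  expect_equal(nrow(m$pairs), 10)
  expect_equal(m$n_unmatched_measured, 0L)
  expect_equal(m$pairs$measured, m$pairs$reference)
  # reference missing 2 strides: exactly 2 measured go unmatched
  m2 <- match_strides(ref, ref[-c(3, 7), ], 0, 0.25, "stride_length")
  expect_equal(m2$n_unmatched_measured, 2L)
  expect_equal(m2$n_unmatched_reference, 0L)
  expect_equal(nrow(m2$pairs), 8)
})

test_that("jittered IC times still match fully at 0.25 s tolerance", {
  set.seed(31)
  ref <- mk_strides(seq(0, by = 1.1, length.out = 100))
  meas <- ref
  meas$ic_time <- meas$ic_time + rnorm(100, 0, 0.05)
  m <- match_strides(meas, ref, 0, 0.25, "stride_length")
  expect_equal(nrow(m$pairs), 100)
})

test_that("correlation analysis equals the closed forms", {
  # 4-point fixture, expected values computed from the definitions
  x <- c(1, 2, 3, 4)  # reference
  y <- c(1, 3, 2, 4)  # measured
  pairs <- data.frame(measured = y, reference = x)
  rep_ <- correlation_analysis(pairs)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  r_hand <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  expect_equal(rep_$r, r_hand, tolerance = 1e-12)
  expect_equal(rep_$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(rep_$intercept, mean(y) - sxy / sxx * mean(x), tolerance = 1e-12)
  expect_equal(rep_$rmse, sqrt(mean((y - x)^2)), tolerance = 1e-12)
  # identity input
  idp <- data.frame(measured = x, reference = x)
  ida <- correlation_analysis(idp)
  expect_equal(ida$r, 1)
  expect_equal(ida$slope, 1)
  expect_equal(ida$intercept, 0)
  expect_equal(ida$rmse, 0)
  # noise-free affine relation, the shape of an under-ranging device
  ref_v <- seq(1.0, 1.6, by = 0.05)
  aff <- data.frame(measured = 0.9 * ref_v + 0.04, reference = ref_v)
  afa <- correlation_analysis(aff)
  expect_equal(afa$slope, 0.9, tolerance = 1e-12)
  expect_equal(afa$intercept, 0.04, tolerance = 1e-12)
  expect_equal(afa$r, 1, tolerance = 1e-12)
  expect_error(correlation_analysis(data.frame(measured = 1:5,
                                               reference = rep(1, 5))),
               "zero variance")
})

test_that("r and slope are invariant to a common additive shift", {
  set.seed(32)
  pairs <- data.frame(reference = runif(50, 1, 1.6))
  pairs$measured <- 0.95 * pairs$reference + rnorm(50, 0, 0.03)
  a <- correlation_analysis(pairs)
  shifted <- data.frame(measured = pairs$measured + 2,
                        reference = pairs$reference + 2)
  b <- correlation_analysis(shifted)
  expect_equal(b$r, a$r, tolerance = 1e-12)
  expect_equal(b$slope, a$slope, tolerance = 1e-12)
})

test_that("Bland-Altman matches hand-computed closed forms", {
  # +1/-1 differences repeated 50x: sd = sqrt(100/99)
  pairs <- data.frame(reference = rep(1, 100),
                      measured = 1 + rep(c(1, -1), 50))
  ba <- bland_altman(pairs)
  expect_equal(ba$bias, 0, tolerance = 1e-15)
  expect_equal(ba$loa_half_width, 1.96 * sqrt(100 / 99), tolerance = 1e-12)
  # identity: all zeros
  same <- data.frame(measured = 1:5, reference = 1:5)
  ba0 <- bland_altman(same)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_half_width, 0)
  expect_equal(ba0$means, as.numeric(1:5))
  expect_error(bland_altman(same[1, , drop = FALSE]), "2 pairs")
})

test_that("seeded Gaussian differences give LoA and coverage in range", {
  set.seed(33)
  n <- 800
  d <- rnorm(n, 0, 0.05)
  pairs <- data.frame(reference = rep(1.2, n), measured = 1.2 + d)
  ba <- bland_altman(pairs)
  # chi-square concentration of sd at n = 800
  expect_gte(ba$loa_half_width, 0.088)
  expect_lte(ba$loa_half_width, 0.108)
  cover <- mean(abs(d - ba$bias) <= ba$loa_half_width)
  expect_gte(cover, 0.93)
  expect_lte(cover, 0.97)
})

test_that("k-means screen separates bimodal differences", {
  set.seed(34)
  d <- c(rnorm(100, -0.10, 0.005), rnorm(100, 0.10, 0.005))
  pairs <- data.frame(reference = rep(1.2, 200), measured = 1.2 + d,
                      foot = rep(c("left", "right"), each = 100))
  cl <- cluster_differences(pairs, k = 2, seed = 0)
  expect_gt(cl$mean_sc, 0.9)
  # clusters coincide with the generating groups
  expect_true(all(table(cl$labels[1:100]) %in% c(0, 100)))
  expect_equal(length(unique(cl$labels[1:100])), 1L)
  expect_false(cl$labels[1] == cl$labels[200])
  # a single tight cloud split in two scores poorly
  d1 <- rnorm(200, 0, 0.02)
  one <- data.frame(reference = rep(1.2, 200), measured = 1.2 + d1)
  expect_lt(cluster_differences(one, k = 2, seed = 0)$mean_sc, 0.6)
  # two points: one cluster each
  two <- data.frame(reference = c(1, 1), measured = c(0.9, 1.2))
  expect_setequal(cluster_differences(two, k = 2, seed = 0)$labels, c(0, 1))
  # degenerate input refuses to cluster
  expect_error(cluster_differences(data.frame(reference = rep(1, 5),
                                              measured = rep(1.1, 5))),
               "identical")
})

test_that("hand-rolled silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(35)
  x <- c(rnorm(30, 0, 1), rnorm(30, 4, 1))
  labels <- rep(c(0L, 1L), each = 30)
  ours <- imugait:::mean_silhouette(x, labels)
  theirs <- mean(cluster::silhouette(labels + 1L, dist(x))[, "sil_width"])
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("k-means screen is deterministic under the stated seed", {
  set.seed(36)
  d <- rnorm(150, 0.02, 0.05)
  pairs <- data.frame(reference = rep(1.2, 150), measured = 1.2 + d)
  a <- cluster_differences(pairs, k = 2, seed = 0)
  b <- cluster_differences(pairs, k = 2, seed = 0)
  expect_identical(a$labels, b$labels)
  expect_identical(a$mean_sc, b$mean_sc)
})
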
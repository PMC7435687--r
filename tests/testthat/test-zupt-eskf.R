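test_that("attitude update matches the matrix-exponential oracle", {
  # frozen spot check: 90 degrees about z maps x onto y
  R <- attitude_update(diag(3), c(0, 0, pi / 2), 1)
  expect_equal(R[, 1], c(0, 1, 0), tolerance = 1e-12)
  # identity at zero rate
  R0 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(attitude_update(R0, c(0, 0, 0), 0.01), R0, tolerance = 1e-15)
  # random draws against scaling-and-squaring, including tiny angles
  set.seed(11)
  for (i in 1:50) {
    w <- rnorm(3) * 10^runif(1, -9, 1)
    dt <- runif(1, 1e-3, 0.05)
    oracle <- expm_scaling_squaring(skew(w * dt))
    expect_lt(frob(attitude_update(diag(3), w, dt) - oracle), 1e-9)
  }
})

test_that("rotation vector log inverts the exponential map", {
  set.seed(12)
  for (ang in c(1e-12, 1e-7, 0.5, 2, pi - 1e-8, pi)) {
    axis <- rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    v <- axis * ang
    R <- rotvec_to_matrix(v)
    v2 <- matrix_to_rotvec(R)
    expect_lt(frob(rotvec_to_matrix(v2) - R), 1e-9)
  }
})

test_that("strapdown step cancels gravity at rest and integrates forces", {
  g <- 9.80665
  st <- list(R = diag(3), v = c(0, 0, 0), s = c(0, 0, 0))
  out <- strapdown_step(st, c(0, 0, g), c(0, 0, 0), 0.01)
  expect_equal(out$a, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(out$v, c(0, 0, 0))
  expect_equal(out$s, c(0, 0, 0))
  # constant 1 m/s^2 along x: v_x = n dt after n steps (explicit Euler)
  st <- list(R = diag(3), v = c(0, 0, 0), s = c(0, 0, 0))
  for (i in 1:100) st <- strapdown_step(st, c(1, 0, g), c(0, 0, 0), 0.01)
  expect_equal(st$v[1], 1, tolerance = 1e-12)
})

test_that("covariance prediction has the printed block structure", {
  dt <- 0.01
  f <- c(0, 0, 9.80665)
  out <- predict_covariance(diag(9), diag(3), f, dt, matrix(0, 9, 9))
  expect_equal(out$F_mat[4:6, 1:3], dt * skew(f))
  expect_equal(out$F_mat[7:9, 4:6], dt * diag(3))
  expect_equal(out$F_mat[1:3, 1:3], diag(3))
  # zero fixed point
  z <- predict_covariance(matrix(0, 9, 9), diag(3), f, dt, matrix(0, 9, 9))
  expect_equal(z$P, matrix(0, 9, 9))
})

test_that("repeated prediction never decreases the covariance trace", {
  set.seed(13)
  P <- crossprod(matrix(rnorm(81), 9, 9)) / 9
  Sw <- diag(runif(9, 0, 1e-4))
  for (i in 1:50) {
    f <- rnorm(3, c(0, 0, 9.8), 2)
    tr0 <- sum(diag(P))
    P <- predict_covariance(P, rotvec_to_matrix(rnorm(3, 0, 0.1)), f,
                            0.01, Sw)$P
    expect_gte(sum(diag(P)) + 1e-12, tr0)
    expect_lt(frob(P - t(P)), 1e-12)
  }
})

test_that("zero-velocity correction behaves at the limits", {
  # zero innovation: state untouched
  st <- list(R = diag(3), v = c(0, 0, 0), s = c(1, 2, 3))
  out <- zupt_correct(diag(9), st, diag(1e-4, 3))
  expect_equal(out$state$v, c(0, 0, 0))
  expect_equal(out$state$s, c(1, 2, 3))
  expect_equal(out$dx, rep(0, 9))
  # Sigma_v -> 0 with P = I: K = H', velocity zeroed exactly
  st$v <- c(0.3, -0.2, 0.1)
  out <- zupt_correct(diag(9), st, diag(0, 3))
  expect_equal(out$state$v, c(0, 0, 0), tolerance = 1e-12)
})

test_that("correction never grows velocity for block-diagonal PSD P", {
  set.seed(14)
  for (i in 1:25) {
    blocks <- lapply(1:3, function(j) crossprod(matrix(rnorm(9), 3, 3)))
    P <- matrix(0, 9, 9)
    for (j in 1:3) P[3 * j - 2:0, 3 * j - 2:0] <- blocks[[j]]
    st <- list(R = diag(3), v = rnorm(3), s = rnorm(3))
    out <- zupt_correct(P, st, diag(runif(1, 1e-6, 1e-2), 3))
    expect_lte(sqrt(sum(out$state$v^2)), sqrt(sum(st$v^2)) + 1e-12)
  }
})

test_that("implemented covariance update equals the (I - K H) P form", {
  set.seed(15)
  P <- crossprod(matrix(rnorm(81), 9, 9))
  Sv <- diag(0.01^2, 3)
  st <- list(R = diag(3), v = rnorm(3), s = rnorm(3))
  out <- zupt_correct(P, st, Sv)
  H <- cbind(matrix(0, 3, 3), diag(3), matrix(0, 3, 3))
  K <- P %*% t(H) %*% solve(H %*% P %*% t(H) + Sv)
  expect_lt(frob(out$P - (diag(9) - K %*% H) %*% P), 1e-10 * frob(P))
})

test_that("P stays symmetric PSD through a full filtered run", {
  s <- simulate_and_measure(gait_spec(n_strides = 15, seed = 6),
                            artifact_spec(seed = 7),
                            eskf_config(check_psd = TRUE))
  expect_gte(s$res$diagnostics$min_P_eigenvalue, -1e-9)
  Pf <- s$res$diagnostics$P_final
  expect_lt(frob(Pf - t(Pf)), 1e-12)
})

test_that("noiseless walk with exact stance mask is recovered to the mm", {
  spec <- fixed_walk_spec(n_strides = 10)
  s <- simulate_and_measure(spec)
  # stance detection agrees with the generator's truth stance intervals
  tr <- s$traj$truth_strides
  mask <- s$res$mask$stationary
  for (i in c(2, 5, 9)) {
    # margins exceed the detector window: the touchdown sample itself can
    # carry a deceleration spike that the rolling window spreads inward
    sel <- s$rec$t > tr$ic_time[i] + 0.12 &
      s$rec$t < tr$ic_time[i] + 0.6 * tr$stride_time[i] - 0.08
    expect_true(all(mask[sel]))
    swing <- s$rec$t > tr$ic_time[i] + 0.6 * tr$stride_time[i] + 0.1 &
      s$rec$t < tr$ic_time[i] + tr$stride_time[i] - 0.1
    expect_true(all(!mask[swing]))
  }
  m <- match_strides(s$strides, tr, 0, 0.25, "stride_length")
  expect_equal(nrow(m$pairs), 10)  # one measured stride per truth stride
  expect_lt(max(abs(m$pairs$measured - m$pairs$reference)), 1e-3)
})

test_that("a resting foot stays pinned at the origin", {
  rec <- synth_stationary(10, 100, no_artifacts())
  res <- run_eskf(rec, eskf_config(check_psd = FALSE))
  expect_lt(max(sqrt(rowSums(res$s^2))), 1e-3)
})

test_that("pure rest is all-stationary and rotation is never stationary", {
  rec <- synth_stationary(5, 100, no_artifacts())
  expect_true(all(detect_zero_velocity(rec)$stationary))
  n <- 500
  spin <- imu_recording((0:(n - 1)) / 100, cbind(0, 0, rep(9.80665, n)),
                        cbind(0, 0, rep(2, n)), fs_configured = 100)
  expect_true(!any(detect_zero_velocity(spin)$stationary))
  expect_error(detect_zero_velocity(rec, window = 0.005), "2 samples")
})

test_that("filter demands an initial standstill", {
  spec <- fixed_walk_spec(n_strides = 3)
  rec <- trajectory_to_imu(synth_walk_trajectory(spec))
  # chop the recording so it starts mid-swing of the lead-in step
  start <- which(rec$t >= 2.1)[1]
  sel <- start:n_samples(rec)
  rec2 <- imu_recording(rec$t[sel] - rec$t[start], rec$f[sel, ],
                        rec$omega[sel, ], fs_configured = rec$fs_configured)
  expect_error(run_eskf(rec2, eskf_config(check_psd = FALSE)), "standstill")
})

test_that("oversized gaps abort with the data-loss diagnostic", {
  spec <- fixed_walk_spec(n_strides = 5)
  rec <- trajectory_to_imu(synth_walk_trajectory(spec))
  keep <- !(seq_len(n_samples(rec)) %in% 400:410)
  rec2 <- rec
  rec2$t <- rec$t[keep]
  rec2$f <- rec$f[keep, ]
  rec2$omega <- rec$omega[keep, ]
  expect_error(run_eskf(rec2, eskf_config(check_psd = FALSE)), "data loss")
  # bridging only repairs small gaps, not this one
  expect_error(run_eskf(rec2, eskf_config(check_psd = FALSE,
                                          bridge_gaps = TRUE)), "data loss")
  # a single missing sample is tolerated without bridging
  keep1 <- seq_len(n_samples(rec)) != 400
  rec3 <- rec
  rec3$t <- rec$t[keep1]
  rec3$f <- rec$f[keep1, ]
  rec3$omega <- rec$omega[keep1, ]
  expect_s3_class(run_eskf(rec3, eskf_config(check_psd = FALSE)),
                  "eskf_result")
})
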
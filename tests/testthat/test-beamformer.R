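random_spd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(n) * 0.1
}

test_that("pooled covariance is sane on white, common-signal and permuted data", {
  set.seed(1)
  n_tr <- 30; n_ch <- 6; n_s <- 4000
  white <- array(rnorm(n_tr * n_ch * n_s), c(n_tr, n_ch, n_s))
  ep <- opm_epochs(white, rep(c("scene", "counting"), 15),
                   make_scalp_array(n_ch, seed = 1), 1200)
  C <- data_covariance(ep)
  expect_equal(diag(C), rep(1, n_ch), tolerance = 0.05)
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
  # single common signal: rank-1 structure
  s <- matrix(rnorm(n_tr * n_s), n_tr)
  common <- array(0, c(n_tr, n_ch, n_s))
  for (ch in seq_len(n_ch)) common[, ch, ] <- s
  Cc <- data_covariance(opm_epochs(common, ep$labels, ep$channels, 1200))
  expect_equal(Cc, matrix(Cc[1, 1], n_ch, n_ch), tolerance = 1e-12)
  # trial permutation leaves the pooled covariance unchanged
  perm <- sample(n_tr)
  Cp <- data_covariance(epochs_subset_trials(ep, perm))
  expect_equal(Cp, C, tolerance = 1e-12)
})

test_that("diagonal loading shifts every eigenvalue by lambda * mean diag", {
  set.seed(2)
  C <- random_spd(8)
  expect_identical(regularize_covariance(C, 0), C)
  expect_equal(regularize_covariance(diag(8), 0.05), 1.05 * diag(8))
  lam <- 0.2
  e0 <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  e1 <- eigen(regularize_covariance(C, lam), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(e1, e0 + lam * mean(diag(C)), tolerance = 1e-10)
})

test_that("max-power orientation solves the angle search exactly", {
  set.seed(3)
  # identity covariance: unit-gain output power is 1 / (u' L'L u), so the
  # maximising orientation is the right singular vector with the SMALLEST
  # singular value
  L <- matrix(rnorm(12), 6, 2)
  u <- scalar_orientation(L, diag(6))
  v2 <- svd(L)$v[, 2]
  expect_equal(abs(sum(u * v2)), 1, tolerance = 1e-9)
  # diagonal A with a11 < a22 picks the first axis
  L2 <- cbind(c(1, 0, 0), c(0, 2, 0))
  expect_equal(scalar_orientation(L2, diag(3)), c(1, 0))
  # brute force over 3600 angles of the unit-gain output power
  for (i in 1:5) {
    L <- matrix(rnorm(16), 8, 2)
    Ci <- solve(random_spd(8))
    Ci <- (Ci + t(Ci)) / 2
    u <- scalar_orientation(L, Ci)
    ang <- (0:3599) * pi / 3600
    A <- crossprod(L, Ci %*% L)
    pow <- 1 / (cos(ang)^2 * A[1, 1] + 2 * cos(ang) * sin(ang) * A[1, 2] +
                  sin(ang)^2 * A[2, 2])
    best <- ang[which.max(pow)]
    a_hat <- atan2(u[2], u[1]) %% pi
    d <- abs(a_hat - best) %% pi
    expect_lt(min(d, pi - d), 0.1 * pi / 180 + pi / 3600)
  }
})

test_that("LCMV weights have unit gain and minimise variance", {
  set.seed(4)
  l <- rnorm(7)
  expect_equal(lcmv_weights(l, diag(7)), l / sum(l^2), tolerance = 1e-12)
  for (i in 1:5) {
    C <- random_spd(7)
    Ci <- solve(C)
    w <- lcmv_weights(l, Ci)
    expect_equal(sum(w * l), 1, tolerance = 1e-8)
    w_var <- as.numeric(crossprod(w, C %*% w))
    # every feasible probe v (v'l = 1) has at least this variance
    for (j in 1:2000) {
      z <- rnorm(7)
      v <- w + z - l * sum(l * z) / sum(l * l)
      expect_gte(as.numeric(crossprod(v, C %*% v)), w_var * (1 - 1e-10))
    }
  }
  expect_error(lcmv_weights(rep(0, 7), diag(7)), "degenerate")
})

test_that("trial power scales quadratically and vanishes on zero trials", {
  set.seed(5)
  data <- array(rnorm(3 * 4 * 500), c(3, 4, 500))
  data[2, , ] <- 0
  ep <- opm_epochs(data, c("scene", "counting", "scene"),
                   make_scalp_array(4, seed = 1), 1200)
  w <- rnorm(4)
  p <- trial_source_power(w, ep)
  expect_identical(p[2], 0)
  ep2 <- ep; ep2$data <- 3 * ep$data
  expect_equal(trial_source_power(w, ep2), 9 * p, tolerance = 1e-12)
})

test_that("beamformed power at the source voxel tracks injected variance", {
  # noiseless single-source session: power at the true source location is
  # proportional to the injected source variance across trials
  cfg <- sim_config(n_trials = 25, n_participants = 1, sensor_noise_sd = 0,
                    uniform_sd = 0, gradient_sd = 0, geometry_jitter = 0,
                    seed = 50)
  s <- simulate_session(cfg, 1, seed = 50)
  ep <- bandpass(baseline_correct(epochs_by_role(s$epochs, "scalp")))
  lf <- opmtheta:::lead_field_points(s$truth$scalp,
                                     rbind(s$truth$source_position),
                                     cfg$head)
  C <- data_covariance(ep)
  Ci <- solve(regularize_covariance(C, 0.05))
  L <- cbind(lf$L1[1, ], lf$L2[1, ])
  w <- lcmv_weights(L %*% scalar_orientation(L, Ci), Ci)
  p_hat <- trial_source_power(w, ep)
  p_true <- apply(s$truth$source_traces, 1, var)
  fit <- summary(lm(p_hat ~ p_true))
  expect_gt(fit$r.squared, 0.99)
  # every counting trial exceeds every scene trial at the source
  expect_gt(min(p_hat[s$epochs$labels == "counting"]),
            max(p_hat[s$epochs$labels == "scene"]))
})

test_that("contrast maps satisfy F = t^2 with the two-group degrees of freedom", {
  set.seed(6)
  grid <- small_grid()
  nvox <- sum(grid$mask)
  n1 <- 9; n2 <- 11
  P <- matrix(rexp(nvox * (n1 + n2)), nvox)
  tab <- structure(list(
    power = P,
    condition = factor(rep(c("scene", "counting"), c(n1, n2)),
                       levels = c("scene", "counting")),
    voxel = which(as.vector(grid$mask)), grid = grid),
    class = "source_power_table")
  maps <- power_contrast_maps(tab)
  expect_equal(maps$df, c(1, n1 + n2 - 2))
  Fv <- maps$F$values[grid$mask]
  tv <- maps$t$values[grid$mask]
  expect_equal(Fv, tv^2, tolerance = 1e-9)
  expect_true(all(Fv >= 0))
  # per-voxel agreement with t.test on the log powers
  v <- sample(nvox, 3)
  for (i in v) {
    tt <- t.test(log(P[i, 1:n1]), log(P[i, n1 + 1:n2]), var.equal = TRUE)
    expect_equal(tv[i], unname(tt$statistic), tolerance = 1e-9)
  }
  # identical samples in both conditions give F = 0
  P0 <- cbind(P[, 1:n1], P[, 1:n1])
  tab0 <- tab; tab0$power <- P0
  tab0$condition <- factor(rep(c("scene", "counting"), each = n1),
                           levels = c("scene", "counting"))
  maps0 <- power_contrast_maps(tab0)
  expect_equal(max(abs(maps0$F$values[grid$mask])), 0, tolerance = 1e-20)
})

test_that("batched beamformer equals the per-voxel scalar operations", {
  cfg <- tiny_cfg(seed = 60)
  s <- simulate_session(cfg, 1, seed = 60)
  ep <- bandpass(synthetic_gradiometry(baseline_correct(s$epochs)))
  grid <- source_grid(cfg$head, spacing = 0.012, dim = c(6, 6, 6))
  lf <- lead_field_matrix(ep$channels, grid)
  bf <- beamform(ep, lf, lambda = 0.05)
  C <- data_covariance(ep)
  Ci <- solve(regularize_covariance(C, 0.05))
  Ci <- (Ci + t(Ci)) / 2
  set.seed(61)
  for (v in sample(nrow(bf$power), 4)) {
    L <- cbind(lf$L1[v, ], lf$L2[v, ])
    u <- scalar_orientation(L, Ci)
    w <- lcmv_weights(L %*% u, Ci)
    expect_equal(unname(abs(bf$orientation[v, ])), abs(u), tolerance = 1e-8)
    expect_equal(sum(bf$weights[v, ] * (L %*% u)), 1, tolerance = 1e-8)
    expect_equal(bf$power[v, ], trial_source_power(w, ep), tolerance = 1e-9)
  }
})
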
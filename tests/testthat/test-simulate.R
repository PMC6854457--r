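test_that("trial equivocation reproduces the reported analysed counts", {
  counts <- opm_trial_counts()
  # participant two: scene 75/68 with 7 artefacts, counting 75/75 with 6
  p2 <- select_analysable_trials(counts[counts$participant == 2, ], seed = 1)
  expect_equal(p2$n, 61L)
  expect_length(p2$retained$scene, 61)
  expect_length(p2$retained$counting, 61)
  # participant three: 45 usable scene, 48 counting
  p3 <- select_analysable_trials(counts[counts$participant == 3, ], seed = 1)
  expect_equal(p3$n, 45L)
  # participant one: 35 scene, 45 counting
  p1 <- select_analysable_trials(counts[counts$participant == 1, ], seed = 1)
  expect_equal(p1$n, 35L)
  expect_identical(p1$retained$scene, seq_len(35))
})

test_that("equivocation keeps equal usable counts intact and seeds the subset", {
  even <- tibble::tibble(condition = c("scene", "counting"),
                         completed = c(30L, 30L), successful = c(25L, 25L),
                         artefact_removed = c(0L, 0L))
  sel <- select_analysable_trials(even, seed = 4)
  expect_equal(sel$n, 25L)
  expect_identical(sel$retained$scene, seq_len(25))
  expect_identical(sel$retained$counting, seq_len(25))
  uneven <- tibble::tibble(condition = c("scene", "counting"),
                           completed = c(30L, 50L), successful = c(20L, 50L),
                           artefact_removed = c(0L, 2L))
  a <- select_analysable_trials(uneven, seed = 5)
  b <- select_analysable_trials(uneven, seed = 5)
  c <- select_analysable_trials(uneven, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$retained$counting, c$retained$counting))
  expect_true(all(a$retained$counting <= 48))
  none <- tibble::tibble(condition = c("scene", "counting"),
                         completed = c(10L, 10L), successful = c(0L, 10L),
                         artefact_removed = c(0L, 0L))
  expect_error(select_analysable_trials(none), "no analysable trials")
})

test_that("source time courses hit the condition SD exactly and stay in band", {
  cfg <- sim_config(seed = 1)
  set.seed(10)
  s_cnt <- simulate_source_timecourse("counting", cfg)
  set.seed(10)
  s_scn <- simulate_source_timecourse("scene", cfg)
  expect_equal(sd(s_cnt), cfg$moment_sd[["counting"]], tolerance = 1e-12)
  expect_equal(sd(s_scn) / sd(s_cnt), 0.7, tolerance = 1e-9)
  set.seed(10)
  again <- simulate_source_timecourse("counting", cfg)
  expect_identical(again, s_cnt)
  # spectral content: Welch-averaged periodogram on a long realisation
  set.seed(11)
  x <- simulate_source_timecourse("counting", cfg, n_samples = 2^17)
  nseg <- 64; seg <- length(x) / nseg
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(seg - 1)) / (seg - 1))
  psd <- rowMeans(vapply(seq_len(nseg), function(i) {
    xi <- x[((i - 1) * seg + 1):(i * seg)] * win
    abs(fft(xi)[1:(seg / 2)])^2
  }, numeric(seg / 2)))
  f <- (0:(seg / 2 - 1)) * cfg$sample_rate / seg
  inband <- f >= 3 & f <= 9
  expect_lt(max(psd[!inband]), 0.01 * max(psd[inband]))
})

test_that("interference is coherent, linear in its SDs, and 4-dof", {
  head <- sphere_head()
  cfg <- sim_config(gradient_sd = 0, seed = 2)
  # two sensors with parallel orientations at different positions
  sensors <- opmtheta:::new_sensor_array(tibble::tibble(
    name = c("a", "b", "c"), role = "scalp",
    x = c(0.1, -0.05, 0), y = c(0, 0.1, 0), z = c(0, 0, 0.12),
    ox = c(1, 1, 0), oy = c(0, 0, 1), oz = c(0, 0, 0)), head)
  set.seed(20)
  i1 <- simulate_interference(sensors, cfg, 4000)
  expect_identical(i1$traces[, 1], i1$traces[, 2])  # uniform field only
  cfg2 <- sim_config(gradient_sd = 0, uniform_sd = 2 * cfg$uniform_sd, seed = 2)
  set.seed(20)
  i2 <- simulate_interference(sensors, cfg2, 4000)
  expect_equal(i2$traces, 2 * i1$traces, tolerance = 1e-12)
  # orthogonal sensitive axes at one point: uncorrelated under isotropic u
  set.seed(21)
  co <- opmtheta:::new_sensor_array(tibble::tibble(
    name = c("a", "b"), role = "scalp", x = 0, y = 0, z = 0,
    ox = c(1, 0), oy = c(0, 1), oz = c(0, 0)), head)
  long <- simulate_interference(co, cfg, 1e5)
  r <- cor(long$traces[, 1], long$traces[, 2])
  # low-pass processes have ~2 * corner / fs independent samples per sample
  n_eff <- 1e5 * 2 * cfg$corner_hz / cfg$sample_rate
  expect_lt(abs(r), 3 / sqrt(n_eff))
  # traces are an exact linear function of the 4 components
  cfgg <- sim_config(seed = 3)
  set.seed(22)
  ig <- simulate_interference(sensors, cfgg, 2000)
  expect_equal(ig$traces, ig$components %*% t(ig$mixing), tolerance = 1e-15)
})

test_that("sessions are reproducible and conserve trial labels", {
  cfg <- tiny_cfg()
  s1 <- simulate_session(cfg, 1, seed = 99)
  s2 <- simulate_session(cfg, 1, seed = 99)
  expect_identical(s1$epochs$data, s2$epochs$data)
  expect_identical(s1$truth$source_position, s2$truth$source_position)
  s3 <- simulate_session(cfg, 2, seed = 99)
  expect_false(identical(s1$epochs$data, s3$epochs$data))
  expect_equal(as.integer(table(s1$epochs$labels)), c(8L, 8L))
  # default counts: usable trials per condition before equivocation
  full <- sim_config(seed = 5)
  sp2 <- simulate_session(full, 2, seed = 5)
  expect_equal(as.integer(table(sp2$epochs$labels)), c(61L, 69L))
})

test_that("stored ground-truth power equals the empirical trace variance", {
  cfg <- tiny_cfg(seed = 12)
  s <- simulate_session(cfg, 1, seed = 12)
  for (cond in c("scene", "counting")) {
    rows <- which(s$epochs$labels == cond)
    emp <- mean(apply(s$truth$source_traces[rows, ], 1, var))
    expect_equal(s$truth$source_power[[cond]], emp, tolerance = 1e-9)
  }
  # scene power is strictly below counting power by construction
  expect_lt(s$truth$source_power[["scene"]], s$truth$source_power[["counting"]])
})

test_that("zero geometry jitter leaves participant geometry identical", {
  cfg <- sim_config(n_trials = 4, geometry_jitter = 0, seed = 31)
  s1 <- simulate_session(cfg, 1, seed = 31)
  s2 <- simulate_session(cfg, 2, seed = 31)
  expect_identical(s1$truth$source_position, s2$truth$source_position)
  expect_identical(sensor_positions(s1$truth$scalp),
                   sensor_positions(s2$truth$scalp))
  expect_false(identical(s1$epochs$data[1, 1, ], s2$epochs$data[1, 1, ]))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(scene_ratio = 1.2), "lower theta power")
  expect_error(sim_config(counting_sd = -1), "non-negative")
  expect_error(sim_config(source_band = c(8, 4)), "source_band")
  expect_error(sim_config(source_band = c(4, 700)), "source_band")
  bad <- opm_trial_counts()
  bad$artefact_removed[1] <- 99L
  expect_error(sim_config(trial_counts = bad), "artefact_removed")
})
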
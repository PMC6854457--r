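#' Simulation configuration for a two-condition OPM study
#'
#' Defines the virtual study: a scalp array of single-axis magnetometers in
#' a scanner-cast plus a four-sensor reference array behind the head, and a
#' band-limited theta source at hippocampal depth whose power is lower
#' during scene imagery than during the counting baseline. Environmental
#' interference is a time-varying uniform field plus a linear field
#' gradient, seen coherently by scalp and reference sensors; each channel
#' adds white sensor noise.
#'
#' Defaults: 1200 Hz sampling, 3 s epochs, 21 scalp + 4 reference channels,
#' source at 0.45 of the head radius (right-lateral-anterior), counting
#' moment SD 20 nAm with a scene/counting amplitude ratio of 0.7 (a theta
#' power decrease during scenes), sensor noise 367 fT (15 fT/sqrt(Hz) over
#' the 600 Hz bandwidth), and residual interference of 200 pT per
#' uniform-field component and 0.1 nT/m gradient with a 3 Hz corner --
#' the uniform field and gradients are actively nulled by compensation
#' coils in the emulated acquisition, and environmental drift concentrates
#' below a few hertz, so the residual seen by the sensors is low-frequency
#' and gradient-poor. Three virtual participants have their geometry
#' jittered by 2 mm SD.
#'
#' @param sample_rate Sampling rate, Hz.
#' @param epoch_duration Epoch length, seconds.
#' @param head A [sphere_head()].
#' @param n_scalp Number of scalp sensors.
#' @param standoff,cap_zmin Scalp-array geometry, see [make_scalp_array()].
#' @param ref_offset,n_ref Reference-array geometry, see
#'   [make_reference_array()].
#' @param source_position Source location in metres (default: 0.45 radius,
#'   right-lateral-anterior).
#' @param source_band Source band in Hz (default 4-8).
#' @param counting_sd Source moment SD in the counting condition, A m.
#' @param scene_ratio Scene/counting moment-SD ratio (< 1: power decrease).
#' @param moment_scale Overall source amplitude multiplier (3 for a
#'   high-SNR variant).
#' @param uniform_sd SD of each uniform interference field component, tesla.
#' @param gradient_sd SD of the interference field gradient, tesla/metre.
#' @param corner_hz Interference low-pass corner frequency, Hz.
#' @param sensor_noise_sd White sensor noise SD per sample, tesla.
#' @param n_participants Number of virtual participants.
#' @param geometry_jitter Per-participant geometry jitter SD, metres.
#' @param trial_counts Trial accounting table, see [opm_trial_counts()].
#' @param n_trials If given, overrides `trial_counts` with this many
#'   completed (= successful, artefact-free) trials per condition for every
#'   participant.
#' @param dynamic_range Sensor dynamic range, tesla (recorded for the
#'   clipping check, not modelled physically).
#' @param store_interference Keep the per-trial scalp interference
#'   component in the ground truth (memory-hungry; used for
#'   interference-rejection checks).
#' @param seed Base seed; all stochastic stages derive sub-streams from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sample_rate = 1200,
                       epoch_duration = 3,
                       head = sphere_head(),
                       n_scalp = 21,
                       standoff = 0.0065,
                       cap_zmin = -0.4,
                       ref_offset = 0.10,
                       n_ref = 4,
                       source_position = NULL,
                       source_band = c(4, 8),
                       counting_sd = 20e-9,
                       scene_ratio = 0.7,
                       moment_scale = 1,
                       uniform_sd = 200e-12,
                       gradient_sd = 1e-10,
                       corner_hz = 3,
                       sensor_noise_sd = 367e-15,
                       n_participants = 3,
                       geometry_jitter = 0.002,
                       trial_counts = opm_trial_counts(),
                       n_trials = NULL,
                       dynamic_range = 1.5e-9,
                       store_interference = FALSE,
                       seed = 1) {
  if (!(source_band[1] > 0 && source_band[1] < source_band[2] &&
        source_band[2] <= sample_rate / 2)) {
    abort("`source_band` must satisfy 0 < low < high <= sample_rate / 2")
  }
  if (counting_sd < 0 || uniform_sd < 0 || gradient_sd < 0 ||
      sensor_noise_sd < 0 || geometry_jitter < 0) {
    abort("standard deviations must be non-negative")
  }
  if (scene_ratio >= 1 || scene_ratio < 0) {
    abort("`scene_ratio` must be in [0, 1): the scene condition has lower theta power")
  }
  if (!is.null(n_trials)) {
    trial_counts <- tidyr::expand_grid(
      participant = seq_len(n_participants),
      condition = c("scene", "counting")
    )
    trial_counts$completed <- as.integer(n_trials)
    trial_counts$successful <- as.integer(n_trials)
    trial_counts$artefact_removed <- 0L
  }
  validate_trial_counts(trial_counts)
  if (is.null(source_position)) {
    u <- unit3(c(0.75, 0.25, -0.35))
    source_position <- head$center + 0.45 * head$radius * u
  }
  moment_sd <- c(scene = counting_sd * scene_ratio,
                 counting = counting_sd) * moment_scale
  gradient_pattern <- with_seed(substream_seed(seed, "gradient-pattern"), {
    A <- matrix(rnorm(9), 3)
    S <- (A + t(A)) / 2
    S <- S - diag(3) * sum(diag(S)) / 3
    S / svd(S)$d[1]
  })
  structure(list(
    sample_rate = sample_rate, epoch_duration = epoch_duration,
    head = head, n_scalp = n_scalp, standoff = standoff,
    cap_zmin = cap_zmin, ref_offset = ref_offset, n_ref = n_ref,
    source_position = as.numeric(source_position),
    source_band = as.numeric(source_band),
    moment_sd = moment_sd, scene_ratio = scene_ratio,
    moment_scale = moment_scale,
    uniform_sd = uniform_sd, gradient_sd = gradient_sd,
    corner_hz = corner_hz, gradient_pattern = gradient_pattern,
    sensor_noise_sd = sensor_noise_sd,
    n_participants = n_participants,
    geometry_jitter = geometry_jitter,
    trial_counts = trial_counts,
    dynamic_range = dynamic_range,
    store_interference = isTRUE(store_interference),
    seed = seed
  ), class = "sim_config")
}

n_epoch_samples <- function(cfg) round(cfg$epoch_duration * cfg$sample_rate)

#' Trial accounting for the three virtual participants
#'
#' Completed, self-rated-successful and artefact-removed trial counts per
#' condition: participant one completed 45 trials per condition (35 scene
#' trials successful); participant two 75 per condition (68 scene successful,
#' 7 scene and 6 counting trials removed for artefacts); participant three
#' 48 per condition (45 scene successful). Equivocating usable counts gives
#' 35, 61 and 45 analysed trials per condition.
#'
#' @return A tibble with columns participant, condition, completed,
#'   successful, artefact_removed.
#' @export
opm_trial_counts <- function() {
  tibble(
    participant = rep(1:3, each = 2),
    condition = rep(c("scene", "counting"), 3),
    completed = c(45L, 45L, 75L, 75L, 48L, 48L),
    successful = c(35L, 45L, 68L, 75L, 45L, 48L),
    artefact_removed = c(0L, 0L, 7L, 6L, 0L, 0L)
  )
}

validate_trial_counts <- function(counts) {
  stopifnot(all(c("participant", "condition", "completed", "successful",
                  "artefact_removed") %in% names(counts)))
  ok <- counts$artefact_removed >= 0 &
    counts$artefact_removed <= counts$successful &
    counts$successful <= counts$completed
  if (!all(ok)) {
    abort("trial counts must satisfy 0 <= artefact_removed <= successful <= completed")
  }
  invisible(counts)
}

#' Equivocate analysable trial numbers across conditions
#'
#' Usable trials per condition are those rated successful minus those
#' removed for artefacts. The analysed count is the minimum usable count
#' over conditions; for the larger condition a uniform random subset of that
#' size is retained (seeded), so both conditions contribute equally to the
#' beamformer statistics.
#'
#' @param counts Trial-count table for one participant: columns condition,
#'   completed, successful, artefact_removed.
#' @param seed Seed for the subsampling.
#' @return A list with `n` (analysed trials per condition) and `retained`
#'   (named list of retained trial indices per condition, indices into that
#'   condition's usable trials).
#' @export
select_analysable_trials <- function(counts, seed = 1) {
  stopifnot(all(c("condition", "successful", "artefact_removed") %in% names(counts)))
  usable <- setNames(counts$successful - counts$artefact_removed,
                     counts$condition)
  if (any(usable <= 0)) {
    abort(sprintf("condition(s) with no analysable trials: %s",
                  paste(names(usable)[usable <= 0], collapse = ", ")))
  }
  n <- min(usable)
  retained <- with_seed(seed, lapply(usable, function(u) {
    if (u == n) seq_len(u) else sort(sample.int(u, n))
  }))
  list(n = as.integer(n), retained = retained)
}

#' Simulate one band-limited source time course
#'
#' White Gaussian noise filtered to the source band with a zero-phase
#' Butterworth, then rescaled so the sample SD equals the condition's
#' moment SD exactly. Draws from the current RNG state.
#'
#' @param condition `"scene"` or `"counting"`.
#' @param cfg A [sim_config()].
#' @param n_samples Number of samples (default: one epoch).
#' @return Numeric vector of dipole moment values, A m.
#' @export
simulate_source_timecourse <- function(condition, cfg, n_samples = NULL) {
  n <- n_samples %||% n_epoch_samples(cfg)
  target <- cfg$moment_sd[[condition]]
  if (target == 0) return(numeric(n))
  sos <- butter_sos(5, cfg$source_band, cfg$sample_rate, type = "pass")
  x <- filtfilt_sos(rnorm(n), sos)
  x * (target / sd(x))
}

#' Simulate structured environmental interference
#'
#' Draws a time-varying uniform field (three independent low-pass Gaussian
#' components) and one low-pass gradient process multiplying a fixed random
#' symmetric traceless gradient pattern. Each channel sees the projection of
#' the local field onto its sensitive axis, so scalp and reference arrays
#' receive coherent interference driven by four temporal degrees of freedom
#' -- exactly the number the four-sensor reference array can identify.
#'
#' @param sensors A `sensor_array` (any mix of roles).
#' @param cfg A [sim_config()].
#' @param n_samples Number of samples (default: one epoch).
#' @return A list: `traces` (n_samples x n_channels, tesla), `components`
#'   (n_samples x 4 unit-SD processes) and `mixing` (n_channels x 4
#'   coupling matrix), with `traces = components %*% t(mixing)`.
#' @export
simulate_interference <- function(sensors, cfg, n_samples = NULL) {
  n <- n_samples %||% n_epoch_samples(cfg)
  sos <- butter_sos(2, cfg$corner_hz, cfg$sample_rate, type = "low")
  comp <- filtfilt_sos(matrix(rnorm(4 * n), n, 4), sos)
  comp <- sweep(comp, 2, apply(comp, 2, sd), `/`)
  mixing <- interference_mixing(sensors, cfg)
  list(traces = comp %*% t(mixing), components = comp, mixing = mixing)
}

# channel coupling to the 4 interference degrees of freedom
interference_mixing <- function(sensors, cfg) {
  ori <- sensor_orientations(sensors)
  rel <- sweep(sensor_positions(sensors), 2, cfg$head$center)
  grad_coupling <- rowSums(ori * (rel %*% cfg$gradient_pattern)) * cfg$gradient_sd
  cbind(ori * cfg$uniform_sd, grad_coupling)
}

#' Simulate a full epoched session for one virtual participant
#'
#' Builds the (jittered) per-participant geometry, draws a fixed tangential
#' source orientation, and assembles per-trial scalp signals as lead field
#' times source moment plus interference plus white noise; reference
#' channels see interference plus noise only. Trials per condition equal
#' that participant's usable (successful minus artefact-removed) counts.
#' Fully reproducible from `(cfg, participant, seed)`.
#'
#' Geometry jitter is applied as a small rigid-body perturbation of the
#' scalp array (rotation plus translation, displacement norms truncated at
#' 2.5 SD) plus an independent translation of the source, emulating bounded
#' co-registration error while keeping sensors outside the conductor.
#'
#' @param cfg A [sim_config()].
#' @param participant Participant index (1-based).
#' @param seed Base seed (default `cfg$seed`).
#' @return An object of class `opm_session`: list with `epochs` (an
#'   [opm_epochs] object) and `truth` (source position, moment direction,
#'   per-condition source power, per-trial source traces, sensor topography,
#'   and optionally the scalp interference component).
#' @export
simulate_session <- function(cfg, participant = 1, seed = cfg$seed) {
  base <- substream_seed(seed, "session", participant)
  nsamp <- n_epoch_samples(cfg)
  scalp0 <- make_scalp_array(cfg$n_scalp, cfg$head, cfg$standoff,
                             cfg$cap_zmin, seed = substream_seed(seed, "array"))
  ref <- make_reference_array(cfg$head, cfg$ref_offset, cfg$n_ref)

  geom <- with_seed(substream_seed(base, "geometry"), {
    rot <- small_rotation(cfg$geometry_jitter / cfg$head$radius)
    list(rot = rot,
         trans = truncated_jitter(cfg$geometry_jitter / sqrt(3)),
         src_jit = truncated_jitter(cfg$geometry_jitter))
  })
  scalp <- rigid_transform(scalp0, geom$rot, geom$trans, cfg$head$center)
  src <- cfg$source_position + geom$src_jit

  ang <- with_seed(substream_seed(base, "orientation"), runif(1, 0, 2 * pi))
  bas <- tangential_basis(rbind(src), cfg$head)
  mdir <- as.numeric(cos(ang) * bas$t1 + sin(ang) * bas$t2)
  lf_true <- lead_field_points(scalp, rbind(src), cfg$head)
  topo <- as.numeric(cos(ang) * lf_true$L1[1, ] + sin(ang) * lf_true$L2[1, ])

  counts <- cfg$trial_counts[cfg$trial_counts$participant == participant, ]
  if (nrow(counts) == 0) abort(sprintf("no trial counts for participant %d", participant))
  usable <- setNames(counts$successful - counts$artefact_removed, counts$condition)
  labels <- factor(rep(names(usable), usable), levels = c("scene", "counting"))
  n_tot <- length(labels)

  all_sensors <- bind_sensor_arrays(scalp, ref)
  n_ch <- nrow(all_sensors)
  n_sc <- nrow(scalp)
  data <- array(0, c(n_tot, n_ch, nsamp))
  src_traces <- matrix(0, n_tot, nsamp)
  intf_store <- if (cfg$store_interference) array(0, c(n_tot, n_sc, nsamp))

  with_seed(substream_seed(base, "trials"), {
    for (t in seq_len(n_tot)) {
      s <- simulate_source_timecourse(as.character(labels[t]), cfg, nsamp)
      intf <- simulate_interference(all_sensors, cfg, nsamp)
      noise <- matrix(rnorm(n_ch * nsamp, sd = cfg$sensor_noise_sd), n_ch, nsamp)
      tr <- t(intf$traces) + noise
      tr[seq_len(n_sc), ] <- tr[seq_len(n_sc), ] + outer(topo, s)
      data[t, , ] <- tr
      src_traces[t, ] <- s
      if (cfg$store_interference) intf_store[t, , ] <- t(intf$traces[, seq_len(n_sc)])
    }
  })

  epochs <- opm_epochs(data, labels, all_sensors, cfg$sample_rate)
  power <- vapply(levels(labels), function(l) {
    rows <- which(labels == l)
    mean(apply(src_traces[rows, , drop = FALSE], 1, var))
  }, numeric(1))
  truth <- list(source_position = src, moment_direction = mdir,
                source_power = power, source_traces = src_traces,
                topography = topo, scalp_interference = intf_store,
                participant = participant,
                geometry = geom, scalp = scalp)
  structure(list(epochs = epochs, truth = truth, cfg = cfg,
                 participant = participant, seed = seed),
            class = "opm_session")
}

small_rotation <- function(angle_sd) {
  if (angle_sd <= 0) return(diag(3))
  ax <- unit3(rnorm(3))
  th <- rnorm(1, sd = angle_sd)
  th <- sign(th) * min(abs(th), 2.5 * angle_sd)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rigid_transform <- function(array, rot, trans, center) {
  pos <- sweep(sensor_positions(array), 2, center)
  pos <- sweep(pos %*% t(rot), 2, center + trans, `+`)
  ori <- sensor_orientations(array) %*% t(rot)
  out <- as_tibble(array)
  out[, c("x", "y", "z")] <- as.data.frame(pos)
  out[, c("ox", "oy", "oz")] <- as.data.frame(ori)
  new_sensor_array(out, attr(array, "head"))
}

#' Fraction of samples exceeding the sensor dynamic range
#'
#' The acquisition hardware digitises within a finite range; the simulator
#' does not clip, but this check reports whether a simulated session would
#' have.
#'
#' @param epochs An [opm_epochs] object.
#' @param limit Dynamic range, tesla (default 1.5 nT).
#' @return Fraction of samples with `|value| > limit`.
#' @export
check_dynamic_range <- function(epochs, limit = 1.5e-9) {
  mean(abs(epochs$data) > limit)
}
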
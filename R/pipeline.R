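#' Analysis configuration
#'
#' Parameters of the source-localisation chain: band-pass, beamformer
#' regularisation, source grid, smoothing, FDR level and (optionally) the
#' bootstrap stability analysis.
#'
#' @param filter A [filter_spec()] (default 4-8 Hz, order 5).
#' @param lambda Covariance regularisation fraction (default 0.05).
#' @param grid_spacing Source grid spacing, metres (default 0.003).
#' @param grid_dim Source grid dimensions (default `c(24, 24, 24)`: a deep
#'   region of interest centred on the head; see [source_grid()]).
#' @param fwhm_m Gaussian smoothing FWHM, metres (default 0.009).
#' @param q FDR level for the conjunction mask (default 0.005).
#' @param bootstrap Optional [bootstrap_config()]; `NULL` skips the
#'   stability analysis.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(filter = filter_spec(), lambda = 0.05,
                            grid_spacing = 0.003, grid_dim = c(24, 24, 24),
                            fwhm_m = 0.009, q = 0.005, bootstrap = NULL) {
  if (!(q > 0 && q < 1)) abort("`q` must be in (0, 1)")
  structure(list(filter = filter, lambda = lambda,
                 grid_spacing = grid_spacing, grid_dim = grid_dim,
                 fwhm_m = fwhm_m, q = q, bootstrap = bootstrap),
            class = "analysis_config")
}

#' Preprocess a simulated session for analysis
#'
#' Applies the paper-order preprocessing: trial-number equivocation across
#' conditions (seeded subsampling of the larger condition), baseline
#' correction, trial-wise synthetic gradiometry against the reference
#' array, and the zero-phase theta band-pass.
#'
#' @param session An `opm_session` from [simulate_session()].
#' @param analysis An [analysis_config()].
#' @return List with `epochs` (analysable, preprocessed, scalp-only),
#'   `n_analysed` (trials per condition) and `retained` indices.
#' @export
preprocess_session <- function(session, analysis = analysis_config()) {
  cfg <- session$cfg
  counts <- cfg$trial_counts[cfg$trial_counts$participant == session$participant, ]
  sel <- select_analysable_trials(
    counts, seed = substream_seed(session$seed, "equivocate", session$participant))
  labels <- session$epochs$labels
  keep <- unlist(lapply(names(sel$retained), function(cond) {
    which(labels == cond)[sel$retained[[cond]]]
  }), use.names = FALSE)
  ep <- epochs_subset_trials(session$epochs, sort(keep))
  ep <- baseline_correct(ep)
  ep <- synthetic_gradiometry(ep)
  r2 <- attr(ep, "gradiometry_r2")
  ep <- bandpass(ep, analysis$filter)
  list(epochs = ep, n_analysed = sel$n, retained = sel$retained,
       gradiometry_r2 = r2)
}

#' Source-localise one participant
#'
#' Beamforms the preprocessed epochs over the grid and forms the smoothed
#' F and t contrast maps and the p map.
#'
#' @param epochs Preprocessed scalp [opm_epochs] (from
#'   [preprocess_session()]).
#' @param grid A [source_grid()].
#' @param analysis An [analysis_config()].
#' @return List with the power `table`, smoothed `F`, `t` and `p` maps,
#'   unsmoothed `F_raw`, `t_raw`, the F `df`, and the lead field set `lf`.
#' @export
run_participant <- function(epochs, grid, analysis = analysis_config()) {
  scalp <- epochs$channels
  lf <- lead_field_matrix(scalp, grid, grid$head)
  table <- beamform(epochs, lf, analysis$lambda)
  maps <- power_contrast_maps(table)
  Fs <- smooth_map(maps$F, analysis$fwhm_m)
  ts <- smooth_map(maps$t, analysis$fwhm_m)
  list(table = table, F = Fs, t = ts, F_raw = maps$F, t_raw = maps$t,
       p = map_to_p(Fs, maps$df), df = maps$df, lf = lf)
}

#' Run the full multi-participant study
#'
#' Simulates every participant's session, preprocesses it, source-localises
#' the theta power contrast, and performs the group conjunction with FDR
#' control; optionally adds the bootstrap-conjunction stability map. The
#' whole run is reproducible from `(cfg, analysis, seed)`.
#'
#' @param cfg A [sim_config()].
#' @param analysis An [analysis_config()].
#' @param seed Study seed (default `cfg$seed`).
#' @param keep_tables Keep the per-participant voxel x trial power tables
#'   (default `FALSE`; they are large).
#' @return An object of class `opm_study`.
#' @export
run_study <- function(cfg = sim_config(), analysis = analysis_config(),
                      seed = cfg$seed, keep_tables = FALSE) {
  grid <- source_grid(cfg$head, analysis$grid_spacing, analysis$grid_dim)
  participants <- vector("list", cfg$n_participants)
  p_maps <- vector("list", cfg$n_participants)
  boot_lists <- if (!is.null(analysis$bootstrap)) vector("list", cfg$n_participants)
  for (p in seq_len(cfg$n_participants)) {
    session <- simulate_session(cfg, p, seed)
    prep <- preprocess_session(session, analysis)
    res <- run_participant(prep$epochs, grid, analysis)
    if (!is.null(analysis$bootstrap)) {
      boot_lists[[p]] <- bootstrap_images(
        prep$epochs, res$lf, n_boot = analysis$bootstrap$n_boot,
        lambda = analysis$lambda,
        seed = substream_seed(analysis$bootstrap$seed %||% seed, "boot-part", p))
    }
    participants[[p]] <- list(
      participant = p,
      n_analysed = prep$n_analysed,
      gradiometry_r2 = prep$gradiometry_r2,
      F = res$F, t = res$t, F_raw = res$F_raw, t_raw = res$t_raw,
      p = res$p, df = res$df,
      table = if (keep_tables) res$table,
      truth = session$truth[c("source_position", "moment_direction",
                              "source_power", "participant")]
    )
    p_maps[[p]] <- res$p
  }
  conj_p <- conjunction_p(p_maps)
  mask <- fdr_mask(conj_p, analysis$q)
  # min-statistic map matching the max-p conjunction, for peak reporting
  conj_F <- stat_map(Reduce(pmin, lapply(participants, function(x) x$F$values)),
                     grid, "F")
  clusters <- clusters_and_peaks(mask, conj_F)
  stability <- NULL
  if (!is.null(analysis$bootstrap)) {
    stability <- bootstrap_conjunction(
      boot_lists, analysis$bootstrap,
      df_list = lapply(participants, function(x) x$df))
  }
  structure(list(cfg = cfg, analysis = analysis, seed = seed, grid = grid,
                 participants = participants,
                 conjunction = list(p = conj_p, mask = mask, F = conj_F,
                                    clusters = clusters),
                 stability = stability),
            class = "opm_study")
}

#' @export
print.opm_study <- function(x, ...) {
  ns <- sum(in_mask_values(x$conjunction$mask), na.rm = TRUE)
  cat(sprintf("<opm_study> %d participants, %d-voxel grid\n",
              length(x$participants), sum(x$grid$mask)))
  cat(sprintf("  conjunction (q < %g): %d significant voxels in %d cluster(s)\n",
              x$analysis$q, ns, nrow(x$conjunction$clusters)))
  if (!is.null(x$stability)) {
    pk <- map_peak(x$stability)
    cat(sprintf("  stability peak: %.0f%% at (%.0f, %.0f, %.0f) mm\n",
                pk$value, pk$world_mm[1], pk$world_mm[2], pk$world_mm[3]))
  }
  invisible(x)
}

#' Nominal true-source voxel of a study
#'
#' @param study An `opm_study`.
#' @return List with `ijk`, linear index `voxel` and `world_mm`.
#' @export
true_source_voxel <- function(study) {
  ijk <- grid_world_to_index(study$grid, study$cfg$source_position)
  list(ijk = ijk, voxel = grid_linear_index(study$grid, ijk),
       world_mm = as.numeric(grid_index_to_world(study$grid, ijk)) * 1000)
}

#' Did the study recover the planted source?
#'
#' Checks that the FDR-significant conjunction mask is non-empty, that the
#' cluster containing the true source voxel exists, and that every
#' significant voxel shows a theta decrease (t < 0) in every participant.
#'
#' @param study An `opm_study`.
#' @return List with logical `recovered`, `true_voxel_significant`,
#'   `all_decrease`, and `decrease_fraction` (percentage of significant
#'   voxels with t < 0, per participant).
#' @export
study_recovery <- function(study) {
  mask <- study$conjunction$mask$values
  sig <- which(mask == 1)
  true_vox <- true_source_voxel(study)$voxel
  tv_sig <- length(sig) > 0 && true_vox %in% sig
  dec <- vapply(study$participants, function(p) {
    if (length(sig) == 0) return(NA_real_)
    100 * mean(p$t$values[sig] < 0)
  }, numeric(1))
  all_dec <- length(sig) > 0 && all(vapply(study$participants, function(p)
    all(p$t$values[sig] < 0), logical(1)))
  list(recovered = tv_sig && all_dec,
       true_voxel_significant = tv_sig,
       all_decrease = all_dec,
       decrease_fraction = dec)
}
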
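#' Write or read a statistic map as NIfTI-1
#'
#' Maps are written float32 with an isotropic affine carrying the grid
#' spacing and origin in millimetres, so they open correctly in standard
#' neuroimaging viewers. Reading verifies the voxel spacing against the
#' target grid and restores the in-mask structure.
#'
#' @param map A [stat_map()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_map` returns `path` invisibly.
#' @export
write_map <- function(map, path) {
  vals <- map$values
  vals[is.na(vals)] <- NaN
  sp_mm <- map$grid$spacing * 1000
  attr(vals, "pixdim") <- rep(sp_mm, 3)
  img <- RNifti::asNifti(vals, datatype = "float")
  aff <- diag(c(sp_mm, sp_mm, sp_mm, 1))
  aff[1:3, 4] <- map$grid$origin * 1000
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(kind = map$kind,
                            origin_m = map$grid$origin,
                            spacing_m = map$grid$spacing,
                            dim = map$grid$dim,
                            head_center_m = map$grid$head$center,
                            head_radius_m = map$grid$head$radius),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @param path Path of a map previously written by [write_map()].
#' @param grid Optional [source_grid()] the map must match; a spacing or
#'   dimension mismatch is an error.
#' @export
read_map <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- source_grid(sphere_head(meta$head_center_m, meta$head_radius_m),
                   spacing = meta$spacing_m, dim = meta$dim,
                   center = meta$origin_m + meta$spacing_m * (meta$dim - 1) / 2)
  if (!is.null(grid)) {
    px <- RNifti::pixdim(img)[1:3] / 1000
    if (any(abs(px - grid$spacing) > 1e-9) || !all(dim(img) == grid$dim)) {
      abort(sprintf(
        "map at '%s' has %s mm spacing and %s dims; the study grid needs %g mm and %s",
        path, paste(signif(px * 1000, 4), collapse = "x"),
        paste(dim(img), collapse = "x"),
        grid$spacing * 1000, paste(grid$dim, collapse = "x")))
    }
    g <- grid
  }
  vals <- array(as.numeric(img), dim(img))
  vals[is.nan(vals)] <- NA_real_
  stat_map(vals, g, meta$kind)
}

#' Serialise a run configuration to JSON (and back)
#'
#' The full study configuration -- simulation, analysis and seed -- written
#' losslessly (full double precision) so a run can be reproduced from the
#' file alone.
#'
#' @param cfg A [sim_config()].
#' @param analysis An [analysis_config()].
#' @param seed Study seed.
#' @param path JSON output path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns `list(cfg, analysis, seed)` with classes restored.
#' @export
write_run_config <- function(cfg, analysis, seed, path) {
  ser <- list(
    simulation = unclass_deep(cfg),
    analysis = unclass_deep(analysis),
    seed = seed
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Doubles are written as 17-significant-digit strings: standard JSON
# emitters round to 15 digits, which breaks bit-reproducibility of a
# reread configuration. `cfg_num()` undoes the encoding.
unclass_deep <- function(x) {
  if (is.data.frame(x)) {
    return(lapply(unclass(as.data.frame(x)), function(col) unclass_deep(unname(col))))
  }
  if (is.matrix(x)) return(list(.matrix = dim(x), data = unclass_deep(as.vector(x))))
  if (is.list(x)) return(unclass(lapply(x, unclass_deep)))
  if (is.double(x)) {
    v <- format(x, digits = 17, trim = TRUE)
    if (!is.null(names(x))) return(as.list(setNames(v, names(x))))
    return(v)
  }
  if (!is.null(names(x))) return(as.list(x))
  x
}

#' @rdname write_run_config
#' @param x A value read back from a run-configuration file.
#' @export
cfg_num <- function(x) {
  if (is.null(x)) NULL else as.numeric(unlist(x))
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- raw$simulation
  tc <- as_tibble(as.data.frame(sim$trial_counts))
  cfg <- sim_config(
    sample_rate = cfg_num(sim$sample_rate),
    epoch_duration = cfg_num(sim$epoch_duration),
    head = sphere_head(cfg_num(sim$head$center), cfg_num(sim$head$radius)),
    n_scalp = cfg_num(sim$n_scalp), standoff = cfg_num(sim$standoff),
    cap_zmin = cfg_num(sim$cap_zmin),
    ref_offset = cfg_num(sim$ref_offset), n_ref = cfg_num(sim$n_ref),
    source_position = cfg_num(sim$source_position),
    source_band = cfg_num(sim$source_band),
    counting_sd = cfg_num(sim$moment_sd$counting) / cfg_num(sim$moment_scale),
    scene_ratio = cfg_num(sim$scene_ratio),
    moment_scale = cfg_num(sim$moment_scale),
    uniform_sd = cfg_num(sim$uniform_sd),
    gradient_sd = cfg_num(sim$gradient_sd),
    corner_hz = cfg_num(sim$corner_hz),
    sensor_noise_sd = cfg_num(sim$sensor_noise_sd),
    n_participants = cfg_num(sim$n_participants),
    geometry_jitter = cfg_num(sim$geometry_jitter),
    trial_counts = tc,
    dynamic_range = cfg_num(sim$dynamic_range),
    store_interference = isTRUE(sim$store_interference),
    seed = cfg_num(sim$seed))
  an <- raw$analysis
  boot <- if (length(an$bootstrap) > 0) {   # absent bootstrap reads as {}
    bootstrap_config(cfg_num(an$bootstrap$n_boot),
                     cfg_num(an$bootstrap$n_conjunctions),
                     cfg_num(an$bootstrap$q), cfg_num(an$bootstrap$fwhm_m),
                     cfg_num(an$bootstrap$seed))
  }
  analysis <- analysis_config(
    filter = filter_spec(cfg_num(an$filter$low), cfg_num(an$filter$high),
                         cfg_num(an$filter$order),
                         isTRUE(an$filter$bidirectional)),
    lambda = cfg_num(an$lambda), grid_spacing = cfg_num(an$grid_spacing),
    grid_dim = cfg_num(an$grid_dim), fwhm_m = cfg_num(an$fwhm_m),
    q = cfg_num(an$q), bootstrap = boot)
  list(cfg = cfg, analysis = analysis, seed = cfg_num(raw$seed))
}

#' Write a cluster report as TSV
#'
#' One row per cluster: id, size, peak coordinates (mm) and peak statistic.
#' An empty report writes a valid header-only file.
#'
#' @param clusters A tibble from [clusters_and_peaks()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  df <- as.data.frame(clusters[, setdiff(names(clusters), "voxels")])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a source power table as TSV
#'
#' Long format: voxel linear index, trial, condition, band power.
#'
#' @param table A `source_power_table` from [beamform()].
#' @param path Output TSV path.
#' @param voxels Optional subset of voxel rows to export.
#' @return `path`, invisibly.
#' @export
write_power_table <- function(table, path, voxels = NULL) {
  df <- as.data.frame(tidy(table, voxels = voxels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save or load a simulated session
#'
#' Sessions are stored as native R serialisation plus a JSON sidecar
#' carrying the configuration summary and seed, so a directory of outputs
#' documents how it was produced.
#'
#' @param session An `opm_session`.
#' @param path Output `.rds` path.
#' @return `write_session` returns `path` invisibly; `read_session` the
#'   session.
#' @export
write_session <- function(session, path) {
  saveRDS(session, path)
  jsonlite::write_json(
    list(participant = session$participant, seed = session$seed,
         sample_rate = session$cfg$sample_rate,
         n_trials = as.list(table(session$epochs$labels)),
         n_channels = nrow(session$epochs$channels)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) readRDS(path)
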
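#' Tidy a statistic map into a voxel table
#'
#' @param x A [stat_map()].
#' @param ... Unused.
#' @return Tibble with voxel linear index, i/j/k, world coordinates in mm
#'   and the value, in-mask voxels only.
#' @method tidy stat_map
#' @export
tidy.stat_map <- function(x, ...) {
  vox <- which(as.vector(x$grid$mask))
  ijk <- arrayInd(vox, x$grid$dim)
  w <- grid_index_to_world(x$grid, ijk) * 1000
  vals <- x$values[vox]   # before tibble() masks `x` with the column
  tibble(voxel = vox, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
         x = w[, 1], y = w[, 2], z = w[, 3], value = vals)
}

#' One-row summary of a statistic map
#'
#' @param x A [stat_map()].
#' @param ... Unused.
#' @return Tibble with kind, voxel count, peak value and peak location.
#' @method glance stat_map
#' @export
glance.stat_map <- function(x, ...) {
  pk <- map_peak(x)
  tibble(kind = x$kind, n_voxels = sum(x$grid$mask),
         peak_value = pk$value, peak_x = pk$world_mm[1],
         peak_y = pk$world_mm[2], peak_z = pk$world_mm[3])
}

#' Tidy a study into its cluster report
#'
#' @param x An `opm_study` from [run_study()].
#' @param ... Unused.
#' @return The conjunction cluster tibble (cluster id, size, peak mm
#'   coordinates, peak statistic).
#' @method tidy opm_study
#' @export
tidy.opm_study <- function(x, ...) {
  x$conjunction$clusters[, setdiff(names(x$conjunction$clusters), "voxels")]
}

#' One-row summary of a study
#'
#' @param x An `opm_study`.
#' @param ... Unused.
#' @return Tibble: participants, analysed trials, significant voxels,
#'   clusters, conjunction peak, true-source recovery and the percentage of
#'   significant voxels showing a theta decrease (minimum over
#'   participants).
#' @method glance opm_study
#' @export
glance.opm_study <- function(x, ...) {
  rec <- study_recovery(x)
  cl <- x$conjunction$clusters
  tibble(
    n_participants = length(x$participants),
    n_analysed = paste(vapply(x$participants, function(p)
      p$n_analysed, integer(1)), collapse = "/"),
    n_sig_voxels = sum(in_mask_values(x$conjunction$mask), na.rm = TRUE),
    n_clusters = nrow(cl),
    peak_stat = if (nrow(cl)) max(cl$peak_stat) else NA_real_,
    true_voxel_significant = rec$true_voxel_significant,
    all_decrease = rec$all_decrease,
    min_decrease_pct = suppressWarnings(min(rec$decrease_fraction))
  )
}

#' Plot axial slices of a statistic map
#'
#' Tile plot of a few axial (constant-z) slices with the head outline.
#'
#' @param object A [stat_map()].
#' @param slices Slice indices along z (default: four spread through the
#'   grid).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stat_map
#' @export
autoplot.stat_map <- function(object, slices = NULL, ...) {
  slices <- slices %||% unique(round(seq(2, object$grid$dim[3] - 1, length.out = 4)))
  df <- tidy(object)
  df <- df[df$k %in% slices, ]
  df$slice <- sprintf("z = %.0f mm", df$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~slice, nrow = 1) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = object$kind, na.value = "grey90") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot trial band powers at a voxel
#'
#' Log band power per trial, split by condition; defaults to the voxel with
#' the largest condition contrast.
#'
#' @param object A `source_power_table` from [beamform()].
#' @param voxel Row index into the table (default: max |log power ratio|).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot source_power_table
#' @export
autoplot.source_power_table <- function(object, voxel = NULL, ...) {
  if (is.null(voxel)) {
    lp <- log(object$power)
    d <- rowMeans(lp[, object$condition == "scene", drop = FALSE]) -
         rowMeans(lp[, object$condition == "counting", drop = FALSE])
    voxel <- which.max(abs(d))
  }
  df <- tibble(condition = object$condition,
               power = object$power[voxel, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$power,
                                   colour = .data$condition)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "trial band power", x = NULL,
                  title = sprintf("voxel %d", object$voxel[voxel])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the bootstrap stability map
#'
#' @param object An `opm_study` with a stability map.
#' @param ... Passed to [autoplot.stat_map()].
#' @return A ggplot object.
#' @method autoplot opm_study
#' @export
autoplot.opm_study <- function(object, ...) {
  if (!is.null(object$stability)) {
    autoplot(object$stability, ...) +
      ggplot2::labs(title = "bootstrap-conjunction stability (%)")
  } else {
    autoplot(object$conjunction$F, ...) +
      ggplot2::labs(title = "conjunction minimum F")
  }
}
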
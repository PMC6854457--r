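#' Bootstrap configuration
#'
#' @param n_boot Bootstrap beamformer images per participant (default 100).
#' @param n_conjunctions Resampled conjunction analyses (default 500).
#' @param q FDR level inside each conjunction (default 0.005).
#' @param fwhm_m Smoothing kernel FWHM in metres (default 0.009).
#' @param seed Seed for image drawing and resampling.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 100, n_conjunctions = 500, q = 0.005,
                             fwhm_m = 0.009, seed = 1) {
  if (n_boot < 1 || n_conjunctions < 1) abort("bootstrap counts must be >= 1")
  if (!(q > 0 && q < 1)) abort("`q` must be in (0, 1)")
  structure(list(n_boot = as.integer(n_boot),
                 n_conjunctions = as.integer(n_conjunctions),
                 q = q, fwhm_m = fwhm_m, seed = seed),
            class = "bootstrap_config")
}

#' Bootstrap beamformer contrast images
#'
#' For each replicate, resamples the usable trials with replacement --
#' independently within each condition, preserving the per-condition trial
#' counts -- and reruns covariance estimation, weights, trial power and the
#' F contrast. Per-trial covariances are computed once and reused, so each
#' replicate costs only the batched linear algebra.
#'
#' @param epochs Band-passed scalp [opm_epochs].
#' @param lf A [lead_field_matrix()] result.
#' @param n_boot Number of replicates.
#' @param lambda Regularisation fraction.
#' @param seed Seed; replicate `b` draws from a sub-stream of it.
#' @param .indices Optional list (length `n_boot`) of precomputed trial
#'   index vectors, overriding the resampler (used to force, e.g., the
#'   identity permutation).
#' @return List of F-kind [stat_map()]s with the resampled indices attached
#'   as attribute `"indices"`.
#' @export
bootstrap_images <- function(epochs, lf, n_boot = 100, lambda = 0.05,
                             seed = 1, .indices = NULL) {
  tc <- trial_covariances(epochs)
  cond <- epochs$labels
  by_cond <- split(seq_along(cond), cond)
  out <- vector("list", n_boot)
  used <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- if (!is.null(.indices)) {
      .indices[[b]]
    } else {
      with_seed(substream_seed(seed, "boot", b), {
        unlist(lapply(by_cond, function(i) sample(i, length(i), replace = TRUE)),
               use.names = FALSE)
      })
    }
    pt <- beamform(NULL, lf, lambda,
                   trial_cov = tc[, , idx, drop = FALSE],
                   labels = cond[idx])
    out[[b]] <- power_contrast_maps(pt)$F
    used[[b]] <- idx
  }
  attr(out, "indices") <- used
  out
}

#' Bootstrap-conjunction stability map
#'
#' Draws, for each of `n_conjunctions` analyses, one bootstrap image per
#' participant uniformly at random, then runs the full group inference on
#' the draw: smoothing, p conversion, maximum-p conjunction, and BH-FDR at
#' level `q` (re-estimated within each conjunction). The 0/1 significance
#' masks are summed and expressed as the percentage of conjunctions in
#' which each voxel was significant.
#'
#' Smoothed p maps are cached per input image, so each conjunction costs
#' only the voxelwise maximum and one FDR pass.
#'
#' @param image_lists List (one element per participant) of lists of F-kind
#'   [stat_map()]s from [bootstrap_images()].
#' @param cfg A [bootstrap_config()].
#' @param df_list Per-participant F degrees of freedom (list of length-2
#'   vectors).
#' @return A `percent` [stat_map()]; the number of conjunctions is attached
#'   as attribute `"n_conjunctions"`.
#' @export
bootstrap_conjunction <- function(image_lists, cfg, df_list) {
  n_part <- length(image_lists)
  if (n_part < 2) abort("conjunction needs at least 2 participants")
  if (any(lengths(image_lists) < 1)) abort("every participant needs at least one image")
  grid <- image_lists[[1]][[1]]$grid
  p_cache <- lapply(seq_len(n_part), function(i) {
    lapply(image_lists[[i]], function(img) {
      map_to_p(smooth_map(img, cfg$fwhm_m), df_list[[i]])$values
    })
  })
  mask_idx <- which(as.vector(grid$mask))
  counts <- numeric(length(mask_idx))
  draws <- with_seed(substream_seed(cfg$seed, "conj-draws"), {
    matrix(vapply(lengths(image_lists), function(k)
      sample.int(k, cfg$n_conjunctions, replace = TRUE),
      integer(cfg$n_conjunctions)), ncol = n_part)
  })
  for (j in seq_len(cfg$n_conjunctions)) {
    pc <- p_cache[[1]][[draws[j, 1]]]
    for (i in seq_len(n_part)[-1]) pc <- pmax(pc, p_cache[[i]][[draws[j, i]]])
    p <- pc[mask_idx]
    counts <- counts + (p.adjust(p, method = "BH") <= cfg$q)
  }
  out <- stat_map_from_values(100 * counts / cfg$n_conjunctions, grid,
                              mask_idx, "percent")
  attr(out, "n_conjunctions") <- cfg$n_conjunctions
  out
}
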
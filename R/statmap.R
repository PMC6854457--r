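#' Volumetric statistic map
#'
#' Values on a regular source grid, defined only on in-mask voxels
#' (`NA` elsewhere). `kind` records what the values are: an F or t
#' statistic, a p-value, a binary significance mask, or a bootstrap
#' stability percentage.
#'
#' @param values 3-D array matching `grid$dim` (values outside the mask are
#'   ignored and stored as `NA`), or a vector over the in-mask voxels in
#'   linear-index order.
#' @param grid A [source_grid()].
#' @param kind One of `"F"`, `"t"`, `"p"`, `"mask01"`, `"percent"`.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, grid, kind = c("F", "t", "p", "mask01", "percent")) {
  kind <- match.arg(kind)
  if (is.null(dim(values))) {
    return(stat_map_from_values(values, grid, which(as.vector(grid$mask)), kind))
  }
  stopifnot(all(dim(values) == grid$dim))
  values[!grid$mask] <- NA_real_
  check_stat_values(values, kind)
  structure(list(values = values, grid = grid, kind = kind),
            class = "stat_map")
}

stat_map_from_values <- function(v, grid, voxel, kind) {
  arr <- array(NA_real_, grid$dim)
  arr[voxel] <- v
  check_stat_values(arr, kind)
  structure(list(values = arr, grid = grid, kind = kind), class = "stat_map")
}

check_stat_values <- function(arr, kind) {
  v <- arr[!is.na(arr)]
  ok <- switch(kind,
    p = all(v >= 0 & v <= 1),
    mask01 = all(v %in% c(0, 1)),
    percent = all(v >= 0 & v <= 100),
    TRUE)
  if (!ok) abort(sprintf("values out of range for kind '%s'", kind))
  invisible(arr)
}

#' @export
print.stat_map <- function(x, ...) {
  v <- in_mask_values(x)
  cat(sprintf("<stat_map> kind %s, %d x %d x %d grid (%d in mask), range [%g, %g]\n",
              x$kind, x$grid$dim[1], x$grid$dim[2], x$grid$dim[3],
              sum(x$grid$mask), suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

in_mask_values <- function(map) map$values[map$grid$mask]

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) && a$spacing == b$spacing &&
    all(a$dim == b$dim) && all(a$mask == b$mask)
}

#' Gaussian smoothing of a statistic map
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 log 2))`
#' per axis, restricted to the in-mask volume: the kernel is renormalised
#' over the in-mask support, so a constant map is unchanged even at the
#' boundary. `fwhm = 0` is the identity.
#'
#' @param map A [stat_map()].
#' @param fwhm_m Kernel full width at half maximum, metres (default 0.009).
#' @return The smoothed map (same kind).
#' @export
smooth_map <- function(map, fwhm_m = 0.009) {
  if (fwhm_m < 0) abort("`fwhm_m` must be non-negative")
  if (fwhm_m == 0) return(map)
  sigma <- fwhm_m / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma / map$grid$spacing)
  k <- exp(-((-half:half) * map$grid$spacing)^2 / (2 * sigma^2))
  x <- map$values
  m <- map$grid$mask * 1
  x[is.na(x)] <- 0
  x <- x * m
  num <- separable_conv3(x, k)
  den <- separable_conv3(m, k)
  out <- array(NA_real_, map$grid$dim)
  out[map$grid$mask] <- num[map$grid$mask] / den[map$grid$mask]
  stat_map(out, map$grid, map$kind)
}

# separable 3-D convolution (zero padding) with a shared 1-D kernel
separable_conv3 <- function(arr, k) {
  d <- dim(arr)
  K1 <- conv_matrix(d[1], k)
  K2 <- conv_matrix(d[2], k)
  K3 <- conv_matrix(d[3], k)
  y <- K1 %*% matrix(arr, d[1], d[2] * d[3])
  y <- array(y, d)
  y <- aperm(y, c(2, 1, 3))
  y <- K2 %*% matrix(y, d[2], d[1] * d[3])
  y <- aperm(array(y, c(d[2], d[1], d[3])), c(2, 1, 3))
  y <- aperm(y, c(3, 2, 1))
  y <- K3 %*% matrix(y, d[3], d[2] * d[1])
  aperm(array(y, c(d[3], d[2], d[1])), c(3, 2, 1))
}

conv_matrix <- function(n, k) {
  half <- (length(k) - 1) / 2
  M <- matrix(0, n, n)
  for (o in -half:half) {
    idx <- seq_len(n)
    src <- idx + o
    keep <- src >= 1 & src <= n
    M[cbind(idx[keep], src[keep])] <- M[cbind(idx[keep], src[keep])] + k[o + half + 1]
  }
  M
}

#' Convert an F map to an upper-tail p map
#'
#' @param map A [stat_map()] of kind `"F"`.
#' @param df Length-2 degrees of freedom `(df1, df2)`.
#' @return A [stat_map()] of kind `"p"`.
#' @export
map_to_p <- function(map, df) {
  stopifnot(length(df) == 2, all(df > 0))
  p <- map$values
  ok <- !is.na(p)
  p[ok] <- pf(p[ok], df[1], df[2], lower.tail = FALSE)
  stat_map(p, map$grid, "p")
}

#' Maximum-p conjunction across participants
#'
#' Voxelwise maximum of the participants' p maps: a valid (conservative)
#' test of the conjunction null that no participant shows an effect at that
#' voxel -- rejecting it means every participant does.
#'
#' @param p_maps List of two or more p-kind [stat_map()]s on identical
#'   grids.
#' @return The conjunction p map.
#' @export
conjunction_p <- function(p_maps) {
  if (length(p_maps) < 2) abort("conjunction needs at least 2 maps")
  g <- p_maps[[1]]$grid
  for (m in p_maps[-1]) {
    if (!same_grid(g, m$grid)) abort("conjunction maps must share one grid")
  }
  vals <- Reduce(pmax, lapply(p_maps, function(m) m$values))
  stat_map(vals, g, "p")
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up FDR control over all in-mask voxels at level `q`: voxels with
#' BH-adjusted p at or below `q` form the mask.
#'
#' @param p_map A p-kind [stat_map()].
#' @param q FDR level (default 0.005).
#' @return A `mask01` [stat_map()].
#' @export
fdr_mask <- function(p_map, q = 0.005) {
  if (!(q > 0 && q < 1)) abort("`q` must be in (0, 1)")
  p <- in_mask_values(p_map)
  sig <- p.adjust(p, method = "BH") <= q
  stat_map_from_values(as.numeric(sig), p_map$grid,
                       which(as.vector(p_map$grid$mask)), "mask01")
}

#' Clusters and peaks of a significance mask
#'
#' Decomposes the mask into maximal 6-connected (face-adjacent) components
#' and reports each cluster's size, peak statistic and peak location in mm.
#' Peak ties break to the lowest linear voxel index.
#'
#' @param mask A `mask01` [stat_map()].
#' @param stat The statistic [stat_map()] (same grid) used for peaks.
#' @return A tibble with columns cluster, n_voxels, peak_x, peak_y, peak_z
#'   (mm), peak_stat, and a list-column `voxels` of member linear indices.
#' @export
clusters_and_peaks <- function(mask, stat) {
  if (!same_grid(mask$grid, stat$grid)) abort("mask and statistic grids differ")
  lab <- label_components6(mask$values == 1 & !is.na(mask$values), mask$grid$dim)
  n_cl <- max(lab, 0)
  if (n_cl == 0) {
    return(tibble(cluster = integer(), n_voxels = integer(),
                  peak_x = numeric(), peak_y = numeric(), peak_z = numeric(),
                  peak_stat = numeric(), voxels = list()))
  }
  purrr::map_dfr(seq_len(n_cl), function(cl) {
    vox <- which(lab == cl)
    sv <- stat$values[vox]
    peak <- vox[which.max(sv)]   # which.max takes the first (lowest index) tie
    ijk <- arrayInd(peak, mask$grid$dim)
    w <- grid_index_to_world(mask$grid, ijk) * 1000
    tibble(cluster = cl, n_voxels = length(vox),
           peak_x = w[1], peak_y = w[2], peak_z = w[3],
           peak_stat = max(sv), voxels = list(vox))
  })
}

# iterative BFS 6-connected component labelling on a logical 3-D array
label_components6 <- function(mask, dm) {
  lab <- array(0L, dm)
  idx_on <- which(mask)
  if (length(idx_on) == 0) return(lab)
  nxt <- 0L
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (start in idx_on) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer()
      ijk <- arrayInd(cur, dm)
      for (o in seq_len(6)) {
        nb <- sweep(ijk, 2, offs[o, ], `+`)
        keep <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
                nb[, 2] >= 1 & nb[, 2] <= dm[2] &
                nb[, 3] >= 1 & nb[, 3] <= dm[3]
        if (!any(keep)) next
        lin <- nb[keep, 1] + dm[1] * (nb[keep, 2] - 1) +
               dm[1] * dm[2] * (nb[keep, 3] - 1)
        lin <- lin[mask[lin] & lab[lin] == 0L]
        if (length(lin) > 0) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Peak voxel of a statistic map
#'
#' When the maximum is attained by a single voxel, that voxel is the peak.
#' Maps that saturate (a bootstrap percentage map hitting 100, a thresholded
#' mask) have a maximal plateau instead; the peak is then the plateau voxel
#' nearest the plateau's centroid, a deterministic convention that does not
#' depend on voxel ordering.
#'
#' @param map A [stat_map()].
#' @return List with `ijk` (1-based indices), `world_mm` and `value`.
#' @export
map_peak <- function(map) {
  v <- replace(map$values, is.na(map$values), -Inf)
  mx <- which(v == max(v))
  peak <- if (length(mx) == 1) mx else {
    ijk_all <- arrayInd(mx, map$grid$dim)
    cen <- colMeans(ijk_all)
    mx[which.min(rowSums(sweep(ijk_all, 2, cen)^2))]
  }
  ijk <- arrayInd(peak, map$grid$dim)
  list(ijk = ijk, world_mm = as.numeric(grid_index_to_world(map$grid, ijk)) * 1000,
       value = v[peak])
}
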
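#' Per-trial and pooled data covariance
#'
#' `trial_covariances` returns the per-trial channel covariance (trial mean
#' removed, denominator `n - 1`); `data_covariance` pools over all trials of
#' both conditions -- the beamformer uses a single covariance window
#' covering the whole trial, shared between conditions -- by averaging the
#' per-trial covariances.
#'
#' @param epochs An [opm_epochs] object (band-passed scalp channels).
#' @return `trial_covariances`: channels x channels x trials array;
#'   `data_covariance`: channels x channels matrix (symmetric positive
#'   semidefinite).
#' @export
trial_covariances <- function(epochs) {
  d <- dim(epochs$data)
  out <- array(0, c(d[2], d[2], d[1]))
  for (t in seq_len(d[1])) {
    x <- t(matrix(epochs$data[t, , ], d[2], d[3]))  # samples x channels
    x <- sweep(x, 2, colMeans(x))
    out[, , t] <- crossprod(x) / (d[3] - 1)
  }
  out
}

#' @rdname trial_covariances
#' @export
data_covariance <- function(epochs) {
  d <- dim(epochs$data)
  if (d[1] < 2) abort("covariance estimation needs at least 2 trials")
  if (d[1] * d[3] < d[2]) {
    warn("fewer samples than channels; regularisation is mandatory")
  }
  C <- rowMeans(trial_covariances(epochs), dims = 2)
  (C + t(C)) / 2
}

#' Diagonal-loading regularisation
#'
#' Adds `lambda * mean(diag(C))` to the diagonal, making the covariance
#' positive definite for any `lambda > 0`.
#'
#' @param C Covariance matrix.
#' @param lambda Regularisation fraction (default 0.05).
#' @return The regularised covariance.
#' @export
regularize_covariance <- function(C, lambda = 0.05) {
  if (lambda < 0) abort("`lambda` must be non-negative")
  C + lambda * mean(diag(C)) * diag(nrow(C))
}

#' Maximum-power scalar source orientation
#'
#' For a tangential lead-field pair `L` (sensors x 2) and inverse
#' regularised covariance, the unit-gain LCMV output power along
#' orientation `u` is `1 / (u' L' C^-1 L u)`; the maximising orientation is
#' the eigenvector of `A = L' C^-1 L` with the smallest eigenvalue. The sign
#' is fixed so the first nonzero component is positive. If `A` is singular
#' the null-space direction is returned with a warning.
#'
#' @param L Sensors x 2 lead-field matrix.
#' @param Cinv Inverse regularised covariance.
#' @return Unit 2-vector in the tangential basis.
#' @export
scalar_orientation <- function(L, Cinv) {
  if (all(L == 0)) abort("zero lead field: source has no external field")
  A <- crossprod(L, Cinv %*% L)
  A <- (A + t(A)) / 2
  if (rcond(A) < 1e-14) {
    warn("singular orientation matrix; returning its null-space direction")
  }
  e <- eigen(A, symmetric = TRUE)
  u <- e$vectors[, 2]
  nz <- which(abs(u) > 0)[1]
  if (u[nz] < 0) u <- -u
  u
}

#' Unit-gain LCMV spatial filter weights
#'
#' `w = C^-1 l / (l' C^-1 l)`: the weights minimise output variance subject
#' to unit gain `w' l = 1` at the target source.
#'
#' @param l Sensor-space lead field (topography) vector.
#' @param Cinv Inverse regularised covariance.
#' @return Weight vector of length `length(l)`.
#' @export
lcmv_weights <- function(l, Cinv) {
  denom <- as.numeric(crossprod(l, Cinv %*% l))
  if (!is.finite(denom) || denom <= 0) abort("degenerate lead field vector")
  as.numeric(Cinv %*% l) / denom
}

#' Per-trial beamformer source power
#'
#' Variance of the projected trace `w' x(t)` over the whole epoch, per
#' trial.
#'
#' @param w Weight vector.
#' @param epochs Band-passed scalp [opm_epochs].
#' @return Numeric vector, one band-power value (tesla^2-equivalent source
#'   units) per trial.
#' @export
trial_source_power <- function(w, epochs) {
  d <- dim(epochs$data)
  vapply(seq_len(d[1]), function(t) {
    var(as.numeric(w %*% matrix(epochs$data[t, , ], d[2], d[3])))
  }, numeric(1))
}

#' Scalar LCMV beamformer over a source grid
#'
#' Runs the full scalar beamformer: pooled covariance, diagonal loading,
#' per-voxel maximum-power orientation, unit-gain weights, and per-trial
#' projected band power. All per-voxel linear algebra is batched: the 2x2
#' orientation eigenproblem is solved in closed form across voxels, and
#' trial powers are quadratic forms in the precomputed per-trial
#' covariances.
#'
#' @param epochs Band-passed scalp [opm_epochs]; may be `NULL` when
#'   `trial_cov` and `labels` are supplied directly (bootstrap path).
#' @param lf A [lead_field_matrix()] result.
#' @param lambda Regularisation fraction (default 0.05).
#' @param trial_cov Optional precomputed [trial_covariances()] array.
#' @param C Optional pooled covariance (default: mean of `trial_cov`).
#' @param labels Optional condition factor overriding `epochs$labels`.
#' @return An object of class `source_power_table`: list with `power`
#'   (voxels x trials matrix), `condition` (factor per trial), `orientation`
#'   (voxels x 2), `weights` (voxels x sensors), `voxel` (linear grid
#'   indices) and `grid`.
#' @export
beamform <- function(epochs, lf, lambda = 0.05, trial_cov = NULL, C = NULL,
                     labels = NULL) {
  trial_cov <- trial_cov %||% trial_covariances(epochs)
  labels <- labels %||% epochs$labels
  C <- C %||% {
    Cm <- rowMeans(trial_cov, dims = 2)
    (Cm + t(Cm)) / 2
  }
  Cinv <- solve(regularize_covariance(C, lambda))
  Cinv <- (Cinv + t(Cinv)) / 2
  bf <- beamform_weights(lf, Cinv)
  n_tr <- dim(trial_cov)[3]
  # P[v, t] = w_v' C_t w_v for all voxels and trials in one product over
  # the 2 * nchoosek + diag unique covariance entries
  n_s <- ncol(bf$W)
  pairs <- which(upper.tri(diag(n_s), diag = TRUE), arr.ind = TRUE)
  lin <- (pairs[, 2] - 1) * n_s + pairs[, 1]
  wgt <- ifelse(pairs[, 1] == pairs[, 2], 1, 2)
  CtMat <- matrix(trial_cov, n_s * n_s, n_tr)[lin, , drop = FALSE] * wgt
  P <- (bf$W[, pairs[, 1], drop = FALSE] *
          bf$W[, pairs[, 2], drop = FALSE]) %*% CtMat
  structure(list(power = P, condition = labels,
                 orientation = bf$U, weights = bf$W,
                 voxel = lf$voxel, grid = lf$grid, lambda = lambda),
            class = "source_power_table")
}

# batched orientation + weights for all sources of a lead_field_set
beamform_weights <- function(lf, Cinv) {
  M1 <- lf$L1 %*% Cinv
  M2 <- lf$L2 %*% Cinv
  a11 <- rowSums(M1 * lf$L1)
  a12 <- rowSums(M1 * lf$L2)
  a22 <- rowSums(M2 * lf$L2)
  # closed-form smallest-eigenvalue eigenvector of [[a11, a12], [a12, a22]]
  half_tr <- (a11 + a22) / 2
  half_diff <- (a11 - a22) / 2
  disc <- sqrt(half_diff^2 + a12^2)
  lmin <- half_tr - disc
  # eigenvector rows: (a12, lmin - a11) or (lmin - a22, a12); pick the
  # arrangement whose second component has magnitude >= disc (well away
  # from cancellation)
  u1 <- ifelse(half_diff >= 0, a12, lmin - a22)
  u2 <- ifelse(half_diff >= 0, lmin - a11, a12)
  # a12 == 0: diagonal A, pick the axis with the smaller diagonal entry
  diag0 <- a12 == 0
  u1[diag0] <- as.numeric(a11[diag0] <= a22[diag0])
  u2[diag0] <- as.numeric(a11[diag0] > a22[diag0])
  nrm <- sqrt(u1^2 + u2^2)
  u1 <- u1 / nrm
  u2 <- u2 / nrm
  flip <- (u1 < 0) | (u1 == 0 & u2 < 0)
  u1[flip] <- -u1[flip]
  u2[flip] <- -u2[flip]
  l <- u1 * lf$L1 + u2 * lf$L2          # voxels x sensors topographies
  lC <- l %*% Cinv
  denom <- rowSums(lC * l)
  if (any(!is.finite(denom) | denom <= 0)) {
    abort("degenerate lead field encountered during weight computation")
  }
  U <- cbind(u1, u2)
  dimnames(U) <- NULL
  list(W = lC / denom, U = U)
}

#' @export
print.source_power_table <- function(x, ...) {
  cat(sprintf("<source_power_table> %d voxels x %d trials (%s)\n",
              nrow(x$power), ncol(x$power),
              paste(sprintf("%s: %d", levels(x$condition), table(x$condition)),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy view of a source power table
#'
#' @param x A `source_power_table`.
#' @param voxels Optional subset of voxel rows.
#' @param ... Unused.
#' @return Tibble with columns voxel, trial, condition, power.
#' @method tidy source_power_table
#' @export
tidy.source_power_table <- function(x, voxels = NULL, ...) {
  rows <- voxels %||% seq_len(nrow(x$power))
  out <- tidyr::expand_grid(voxel = x$voxel[rows],
                            trial = seq_len(ncol(x$power)))
  out$condition <- x$condition[out$trial]
  out$power <- as.vector(t(x$power[rows, , drop = FALSE]))
  out
}

#' Voxelwise power-contrast statistic maps
#'
#' Per voxel, on log-transformed trial powers: the signed two-sample
#' (pooled-variance) t statistic for scene minus counting -- negative means
#' a power decrease during scene imagery -- and the equivalent two-group
#' one-way ANOVA F = t^2 with degrees of freedom (1, n1 + n2 - 2). Voxels
#' with zero within-group variance receive an infinite F and are flagged in
#' the attribute `"degenerate"`.
#'
#' @param table A `source_power_table` from [beamform()].
#' @return List with `F` and `t` [stat_map]s and `df` (the F degrees of
#'   freedom).
#' @export
power_contrast_maps <- function(table) {
  cond <- table$condition
  n1 <- sum(cond == "scene")
  n2 <- sum(cond == "counting")
  if (n1 < 2 || n2 < 2) abort("both conditions need at least 2 trials")
  lp <- log(table$power)
  if (any(!is.finite(lp))) {
    warn("non-positive trial powers; infinite log-power values propagate to the statistics")
  }
  x1 <- lp[, cond == "scene", drop = FALSE]
  x2 <- lp[, cond == "counting", drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (m1 - m2) / se
  degen <- se == 0
  tval[degen] <- ifelse(m1[degen] == m2[degen], 0, sign(m1 - m2)[degen] * Inf)
  Fval <- tval^2
  Fm <- stat_map_from_values(Fval, table$grid, table$voxel, kind = "F")
  tm <- stat_map_from_values(tval, table$grid, table$voxel, kind = "t")
  attr(Fm, "degenerate") <- which(degen & !(m1 == m2))
  list(F = Fm, t = tm, df = c(1, df))
}
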
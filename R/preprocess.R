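#' Baseline-correct epoched data
#'
#' Subtracts, per trial and channel, the mean over the whole epoch. The
#' analysis band-pass annihilates any constant anyway, so whole-epoch mean
#' removal is a pure DC correction.
#'
#' @param epochs An [opm_epochs] object.
#' @return The epochs with zero-mean trials.
#' @export
baseline_correct <- function(epochs) {
  d <- dim(epochs$data)
  if (d[1] == 0) abort("no trials to baseline-correct")
  m <- rowMeans(epochs$data, dims = 2)    # trials x channels means
  epochs$data <- epochs$data - as.vector(m)  # recycles over samples
  epochs
}

#' Synthetic gradiometry: regress reference channels out of scalp channels
#'
#' Per trial and scalp channel, ordinary least squares of the scalp trace on
#' an intercept plus all reference traces; the residual is returned. This is
#' software interference suppression: scalp and reference arrays see the
#' environmental field coherently, so the regression removes the common
#' interference while brain signal (invisible to the distant references)
#' survives. Residuals are orthogonal to every reference trace within the
#' trial. A rank-deficient reference matrix falls back to the minimum-norm
#' solution with a warning.
#'
#' @param epochs An [opm_epochs] object containing both scalp and reference
#'   channels.
#' @return An [opm_epochs] with scalp channels only, interference
#'   suppressed. The per-trial regression R^2 (variance fraction removed,
#'   averaged over scalp channels) is attached as attribute
#'   `"gradiometry_r2"`.
#' @export
synthetic_gradiometry <- function(epochs) {
  sc_idx <- which(epochs$channels$role == "scalp")
  rf_idx <- which(epochs$channels$role == "reference")
  if (length(rf_idx) < 1) abort("synthetic gradiometry needs at least one reference channel")
  d <- dim(epochs$data)
  if (d[3] <= length(rf_idx) + 1) abort("epoch shorter than the reference design matrix")
  n_tr <- d[1]
  r2 <- numeric(n_tr)
  out <- array(0, c(n_tr, length(sc_idx), d[3]))
  for (t in seq_len(n_tr)) {
    X <- t(epochs$data[t, sc_idx, , drop = TRUE])   # samples x scalp
    if (length(sc_idx) == 1) X <- matrix(epochs$data[t, sc_idx, ], ncol = 1)
    R <- t(epochs$data[t, rf_idx, , drop = TRUE])   # samples x ref
    if (length(rf_idx) == 1) R <- matrix(epochs$data[t, rf_idx, ], ncol = 1)
    D <- cbind(1, R)
    # column-normalise: reference traces are ~1e-10 T against a unit
    # intercept, and rank must be judged scale-free
    cn <- sqrt(colSums(D^2))
    cn[cn == 0] <- 1
    D <- sweep(D, 2, cn, `/`)
    G <- crossprod(D)
    beta <- if (rcond(G) > 1e-12) {
      tryCatch(solve(G, crossprod(D, X)), error = function(e) NULL)
    }
    if (is.null(beta)) {
      warn("rank-deficient reference matrix; using minimum-norm regression")
      sv <- svd(D)
      pos <- sv$d > sv$d[1] * 1e-10
      beta <- sv$v[, pos, drop = FALSE] %*%
        (crossprod(sv$u[, pos, drop = FALSE], X) / sv$d[pos])
    }
    res <- X - D %*% beta
    v0 <- colSums(scale(X, scale = FALSE)^2)
    v1 <- colSums(scale(res, scale = FALSE)^2)
    r2[t] <- mean(ifelse(v0 > 0, 1 - v1 / v0, 0))
    out[t, , ] <- t(res)
  }
  res_ep <- opm_epochs(out, epochs$labels,
                       new_sensor_array(as_tibble(epochs$channels)[sc_idx, ],
                                        attr(epochs$channels, "head")),
                       epochs$sample_rate)
  attr(res_ep, "gradiometry_r2") <- r2
  res_ep
}

#' Band-pass filter epoched data
#'
#' Applies the zero-phase Butterworth band-pass (see [filter_spec()] and
#' [filtfilt_sos()]) to every trial and channel. Forward-backward
#' application gives zero phase and the squared magnitude response; edges
#' are padded odd-symmetrically.
#'
#' @param epochs An [opm_epochs] object.
#' @param spec A [filter_spec()] (default: 4-8 Hz, order 5).
#' @return The filtered epochs.
#' @export
bandpass <- function(epochs, spec = filter_spec()) {
  sos <- sos_for_spec(spec, epochs$sample_rate)
  d <- dim(epochs$data)
  for (t in seq_len(d[1])) {
    x <- matrix(epochs$data[t, , ], d[2], d[3])
    epochs$data[t, , ] <- t(filtfilt_sos(t(x), sos))
  }
  if (!spec$bidirectional) {
    warn("one-directional filtering requested; the analysis filter is defined bidirectional, proceeding bidirectionally")
  }
  epochs
}
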
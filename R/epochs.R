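#' Epoched multichannel sensor data
#'
#' Container for epoched recordings: a trials x channels x samples tensor in
#' tesla, a condition label per trial, the channel table (a
#' `sensor_array`), and the sample rate. The time axis starts at 0.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param labels Factor (or character) of trial conditions, levels
#'   `scene` and `counting`.
#' @param channels A `sensor_array` with one row per channel.
#' @param sample_rate Sampling rate, Hz.
#' @return An object of class `opm_epochs`.
#' @export
opm_epochs <- function(data, labels, channels, sample_rate) {
  stopifnot(length(dim(data)) == 3)
  labels <- factor(labels, levels = c("scene", "counting"))
  if (anyNA(labels)) abort("labels must be 'scene' or 'counting'")
  if (dim(data)[1] != length(labels)) abort("one label per trial required")
  if (dim(data)[2] != nrow(channels)) abort("one channel row per data channel required")
  structure(list(data = data, labels = labels, channels = channels,
                 sample_rate = sample_rate,
                 time = (seq_len(dim(data)[3]) - 1) / sample_rate),
            class = "opm_epochs")
}

#' @export
print.opm_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<opm_epochs> %d trials (%s) x %d channels x %d samples @ %g Hz\n",
              d[1], paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                          collapse = ", "),
              d[2], d[3], x$sample_rate))
  invisible(x)
}

#' Subset epochs by channel role or trial index
#'
#' @param epochs An [opm_epochs] object.
#' @param role `"scalp"` or `"reference"`.
#' @return An [opm_epochs] with the selected channels / trials.
#' @export
epochs_by_role <- function(epochs, role) {
  idx <- which(epochs$channels$role == role)
  if (length(idx) == 0) abort(sprintf("no channels with role '%s'", role))
  opm_epochs(epochs$data[, idx, , drop = FALSE], epochs$labels,
             new_sensor_array(as_tibble(epochs$channels)[idx, ],
                              attr(epochs$channels, "head")),
             epochs$sample_rate)
}

#' @rdname epochs_by_role
#' @param trials Integer vector of trial indices (duplicates allowed, as in
#'   bootstrap resampling).
#' @export
epochs_subset_trials <- function(epochs, trials) {
  opm_epochs(epochs$data[trials, , , drop = FALSE], epochs$labels[trials],
             epochs$channels, epochs$sample_rate)
}

#' Tidy view of epoched data
#'
#' Long-format tibble of the (potentially large) epoch tensor; mainly for
#' plotting a few trials or channels.
#'
#' @param x An [opm_epochs] object.
#' @param trials,channels Optional subsets (indices or channel names).
#' @param ... Unused.
#' @return A tibble with columns trial, condition, channel, role, time,
#'   field.
#' @method tidy opm_epochs
#' @export
tidy.opm_epochs <- function(x, trials = NULL, channels = NULL, ...) {
  trials <- trials %||% seq_len(dim(x$data)[1])
  chidx <- if (is.null(channels)) seq_len(dim(x$data)[2])
           else if (is.character(channels)) match(channels, x$channels$name)
           else channels
  out <- tidyr::expand_grid(trial = trials, channel = x$channels$name[chidx],
                            time = x$time)
  out$condition <- x$labels[out$trial]
  out$role <- x$channels$role[match(out$channel, x$channels$name)]
  # expand_grid varies time fastest, then channel, then trial: aperm to match
  out$field <- as.vector(aperm(x$data[trials, chidx, , drop = FALSE], c(3, 2, 1)))
  out[, c("trial", "condition", "channel", "role", "time", "field")]
}
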
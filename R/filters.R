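#' Band-pass filter specification
#'
#' The analysis band-pass: a 5th-order Butterworth applied forward and
#' backward (zero phase, squared magnitude response), 4-8 Hz by default.
#'
#' @param low,high Band edges in Hz.
#' @param order Filter order (default 5).
#' @param bidirectional Apply forward and backward (default `TRUE`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low = 4, high = 8, order = 5, bidirectional = TRUE) {
  if (!(low > 0 && low < high)) abort("need 0 < low < high")
  if (order < 1 || order != round(order)) abort("`order` must be a positive integer")
  structure(list(low = low, high = high, order = as.integer(order),
                 bidirectional = isTRUE(bidirectional)),
            class = "filter_spec")
}

#' Butterworth filter as second-order sections
#'
#' Designs a digital Butterworth low-pass or band-pass via the analytic
#' prototype poles, analog frequency transform and bilinear transform, and
#' returns cascaded biquad sections. The cascade form stays numerically
#' stable even for narrow bands at high sample rates, where the expanded
#' transfer-function polynomial form diverges in double precision.
#'
#' @param order Prototype order (a band-pass has `2 * order` poles).
#' @param freq Cutoff (low-pass) or band edges (band-pass), Hz.
#' @param fs Sample rate, Hz.
#' @param type `"pass"` or `"low"`.
#' @return List of sections, each `list(b, a)` of length-3 coefficients.
#' @export
butter_sos <- function(order, freq, fs, type = c("pass", "low")) {
  type <- match.arg(type)
  if (any(freq <= 0) || any(freq >= fs / 2)) {
    abort("filter frequencies must lie strictly inside (0, fs/2)")
  }
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  if (type == "low") {
    Wc <- tan(pi * freq[1] / fs)
    s_poles <- p_proto * Wc
    n_zero_m1 <- order   # zeros at z = -1
    n_zero_p1 <- 0
    theta_ref <- 0       # unit gain at DC
  } else {
    if (length(freq) != 2 || freq[1] >= freq[2]) {
      abort("band-pass needs freq = c(low, high) with low < high")
    }
    W1 <- tan(pi * freq[1] / fs)
    W2 <- tan(pi * freq[2] / fs)
    Bw <- W2 - W1
    W0sq <- W1 * W2
    pb <- p_proto * Bw / 2
    disc <- sqrt(pb^2 - W0sq)
    s_poles <- c(pb + disc, pb - disc)
    n_zero_m1 <- order
    n_zero_p1 <- order   # zeros at z = +1 (from the s = 0 zeros)
    theta_ref <- 2 * atan(sqrt(W0sq))  # warped centre: unit gain there
  }
  z_poles <- (1 + s_poles) / (1 - s_poles)
  # pair poles into real-coefficient biquads
  pos <- z_poles[Im(z_poles) > 1e-12]
  realp <- sort(Re(z_poles[abs(Im(z_poles)) <= 1e-12]))
  sections <- lapply(pos, function(p) c(1, -2 * Re(p), Mod(p)^2))
  i <- 1
  while (i + 1 <= length(realp)) {
    sections[[length(sections) + 1]] <-
      c(1, -(realp[i] + realp[i + 1]), realp[i] * realp[i + 1])
    i <- i + 2
  }
  if (i == length(realp)) {
    sections[[length(sections) + 1]] <- c(1, -realp[i], 0)
  }
  ns <- length(sections)
  # distribute zeros across sections
  sos <- vector("list", ns)
  zm <- n_zero_m1
  zp <- n_zero_p1
  for (j in seq_len(ns)) {
    b <- 1
    take_m <- min(2, zm); zm <- zm - take_m
    take_p <- 0
    if (take_m < 2) { take_p <- min(2 - take_m, zp); zp <- zp - take_p }
    for (t in seq_len(take_m)) b <- convolve_poly(b, c(1, 1))
    for (t in seq_len(take_p)) b <- convolve_poly(b, c(1, -1))
    length(b) <- 3
    b[is.na(b)] <- 0
    sos[[j]] <- list(b = b, a = sections[[j]])
  }
  # interleave +1/-1 zeros for band-pass: rebuild as (1,0,-1) pairs when
  # both kinds are available (keeps per-section gain balanced)
  if (type == "pass") {
    for (j in seq_len(ns)) sos[[j]]$b <- c(1, 0, -1)
    if (ns * 2 > 2 * order) sos[[ns]]$b <- c(1, 1, 0)  # odd leftover (rare)
  }
  g <- 1 / Mod(sos_response(sos, theta_ref))
  sos[[1]]$b <- sos[[1]]$b * g
  # edge transients persist for a few cycles of the slowest corner
  structure(sos, class = "sos_filter", fs = fs,
            padlen_hint = ceiling(6 * fs / freq[1]))
}

convolve_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) out[i:(i + length(b) - 1)] <-
      out[i:(i + length(b) - 1)] + a[i] * b
  out
}

# complex frequency response of an SOS cascade at angular frequency theta
sos_response <- function(sos, theta) {
  z <- exp(-1i * theta * (0:2))
  Reduce(`*`, lapply(sos, function(s) sum(s$b * z) / sum(s$a * z)), 1 + 0i)
}

#' Magnitude response of an SOS cascade
#'
#' @param sos A filter from [butter_sos()].
#' @param f Frequencies in Hz.
#' @param fs Sample rate, Hz (default: recorded in the filter).
#' @return `|H(f)|` for a single pass of the cascade.
#' @export
sos_magnitude <- function(sos, f, fs = attr(sos, "fs")) {
  vapply(f, function(fi) Mod(sos_response(sos, 2 * pi * fi / fs)), numeric(1))
}

# Single forward pass through the cascade (zero initial state), on a vector
# or column-wise on a matrix; the biquad recursions run compiled.
sos_run <- function(sos, x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  b <- t(vapply(sos, `[[`, numeric(3), "b"))
  a <- t(vapply(sos, `[[`, numeric(3), "a"))
  y <- .sos_filt_mat(x, b, a)
  if (vec) y[, 1] else y
}

#' Zero-phase filtering through second-order sections
#'
#' Applies the cascade forward and backward, giving zero phase and the
#' squared magnitude response. Edges are handled by odd-symmetric
#' (rotational) padding of at least three times the filter's effective
#' order on each side.
#'
#' @param x Numeric vector, or a matrix filtered column-wise.
#' @param sos A filter from [butter_sos()].
#' @param padlen Pad length per side. The default is six cycles of the
#'   filter's slowest corner frequency (capped at the signal length), and
#'   never less than three times the cascade's effective order.
#' @return Filtered data, same shape as `x`.
#' @export
filtfilt_sos <- function(x, sos, padlen = NULL) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  padlen <- padlen %||% min(n - 2L,
                            max(3 * (2 * length(sos) + 1),
                                attr(sos, "padlen_hint") %||% 0L))
  if (n <= padlen + 1) abort("signal too short for the requested padding")
  pre <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[(padlen + 1):2, , drop = FALSE]
  post <- 2 * matrix(x[n, ], padlen, ncol(x), byrow = TRUE) -
    x[(n - 1):(n - padlen), , drop = FALSE]
  y <- rbind(pre, x, post)
  y <- sos_run(sos, y)
  y <- sos_run(sos, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE][(padlen + 1):(padlen + n), , drop = FALSE]
  if (vec) y[, 1] else y
}

# cached band-pass design for a filter_spec at a given sample rate
sos_for_spec <- function(spec, fs) {
  if (spec$high >= fs / 2) abort("band edge at or above the Nyquist frequency")
  butter_sos(spec$order, c(spec$low, spec$high), fs, type = "pass")
}
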
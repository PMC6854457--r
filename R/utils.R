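# Internal helpers shared across modules.

# Run `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards. All stochastic stages route through this so that
# sub-streams never perturb one another.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a deterministic sub-stream seed from a base seed and a stage tag.
# A small multiplicative hash keeps results inside the 32-bit signed range
# required by set.seed().
substream_seed <- function(seed, ...) {
  parts <- c(seed, vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }, numeric(1)))
  h <- 0
  for (p in parts) h <- (h * 69069 + abs(p) + 1) %% 2147483629
  as.integer(h)
}

norm3 <- function(v) sqrt(sum(v^2))

unit3 <- function(v) {
  n <- norm3(v)
  if (n == 0) abort("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product for n x 3 matrices.
cross3_mat <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Random 3-D displacement with norm truncated at `trunc` standard deviations,
# emulating bounded registration / placement error.
truncated_jitter <- function(sd, trunc = 2.5) {
  if (sd <= 0) return(c(0, 0, 0))
  d <- rnorm(3, sd = sd)
  n <- norm3(d)
  lim <- trunc * sd
  if (n > lim) d <- d * (lim / n)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
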
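# Shared fixtures: small, fast configurations for operation-level tests.
# Study-level tests use the package defaults.

tiny_cfg <- function(..., seed = 7) {
  sim_config(n_trials = 8, n_participants = 2, seed = seed, ...)
}

# independent transcription of the conducting-sphere solution via its
# magnetic scalar potential, with the field obtained by complex-step
# differentiation (machine-precision, shares no code path with the
# package's closed-form gradient)
oracle_sphere_field <- function(r0, q, r, head = sphere_head()) {
  mu0 <- 4e-7 * pi
  r0 <- r0 - head$center
  r <- r - head$center
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  U <- function(rc) {  # scalar magnetic potential, complex-analytic in rc
    a <- rc - r0
    an <- sqrt(sum(a^2))
    rn <- sqrt(sum(rc^2))
    F <- an * (rn * an + rn^2 - sum(r0 * rc))
    -mu0 / (4 * pi) * sum(qxr0 * rc) / F
  }
  h <- 1e-20
  -vapply(1:3, function(i) {
    rc <- as.complex(r)
    rc[i] <- rc[i] + 1i * h
    Im(U(rc)) / h
  }, numeric(1))
}

# proper rotation (det +1): the field is a pseudovector, so reflections
# pick up an extra sign and are not plain-equivariant
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# brute-force Benjamini-Hochberg step-up, straight from its definition
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  sig <- logical(m)
  if (length(k) > 0) sig[p <= ps[max(k)]] <- TRUE
  sig
}

# recursive flood fill, 6-connectivity, for component-labelling checks
flood_fill_oracle <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nxt <- 0L
  fill <- function(i, j, k, id) {
    stack <- list(c(i, j, k))
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (v[1] < 1 || v[1] > dm[1] || v[2] < 1 || v[2] > dm[2] ||
          v[3] < 1 || v[3] > dm[3]) next
      if (!mask[v[1], v[2], v[3]] || lab[v[1], v[2], v[3]] != 0L) next
      lab[v[1], v[2], v[3]] <<- id
      for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        stack[[length(stack) + 1]] <- v + d
      }
    }
  }
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (mask[i, j, k] && lab[i, j, k] == 0L) {
      nxt <- nxt + 1L
      fill(i, j, k, nxt)
    }
  }
  lab
}

# tiny grid for inference-level tests
small_grid <- function(dim = c(8, 8, 8), spacing = 0.003,
                       head = sphere_head()) {
  source_grid(head, spacing, dim)
}

# internal helpers exercised directly in tests
unit3 <- opmtheta:::unit3
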
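# Independent straight-line reference implementations used as oracles.
# These are deliberately naive (explicit loops, no shared code with the
# package internals) so they can certify the vectorized implementations.

naive_fis_eval <- function(fis, x) {
  L <- nrow(fis$centers)
  n <- fis$n_inputs
  w <- numeric(L)
  for (i in seq_len(L)) {
    prod_mf <- 1
    for (j in seq_len(n)) {
      prod_mf <- prod_mf *
        exp(-(x[j] - fis$centers[i, j])^2 / (2 * fis$sigmas[i, j]^2))
    }
    w[i] <- prod_mf
  }
  wbar <- w / sum(w)
  f <- numeric(L)
  for (i in seq_len(L)) {
    if (fis$order == "zero") {
      f[i] <- fis$coeffs[i, 1]
    } else {
      acc <- fis$coeffs[i, n + 1]
      for (j in seq_len(n)) acc <- acc + fis$coeffs[i, j] * x[j]
      f[i] <- acc
    }
  }
  sum(wbar * f)
}

naive_density <- function(X, ra) {
  n <- nrow(X)
  D <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i] <- D[i] + exp(-sum((X[i, ] - X[j, ])^2) / (ra / 2)^2)
    }
  }
  D
}

naive_revise <- function(D, X, center, center_density, rb) {
  out <- numeric(length(D))
  for (i in seq_along(D)) {
    out[i] <- D[i] -
      center_density * exp(-sum((X[i, ] - center)^2) / (rb / 2)^2)
  }
  out
}

naive_design_matrix <- function(fis, X) {
  K <- nrow(X); L <- nrow(fis$centers); n <- fis$n_inputs
  p <- if (fis$order == "first") n + 1L else 1L
  Phi <- matrix(0, K, L * p)
  for (k in seq_len(K)) {
    w <- numeric(L)
    for (i in seq_len(L)) {
      w[i] <- prod(exp(-(X[k, ] - fis$centers[i, ])^2 /
                         (2 * fis$sigmas[i, ]^2)))
    }
    wbar <- w / sum(w)
    for (i in seq_len(L)) {
      if (fis$order == "zero") {
        Phi[k, i] <- wbar[i]
      } else {
        cols <- ((i - 1L) * p + 1L):(i * p)
        Phi[k, cols] <- c(wbar[i] * X[k, ], wbar[i])
      }
    }
  }
  Phi
}

random_fis <- function(n_inputs, n_rules, order = "first") {
  p <- if (order == "first") n_inputs + 1L else 1L
  sugeno_fis(
    centers = matrix(stats::runif(n_rules * n_inputs), n_rules, n_inputs),
    sigmas = matrix(stats::runif(n_rules * n_inputs, 0.1, 1),
                    n_rules, n_inputs),
    coeffs = matrix(stats::rnorm(n_rules * p), n_rules, p),
    order = order
  )
}

# Steady-state amplitude of a filtered unit sine (middle of a 4 s record).
steady_amplitude <- function(f_hz, filter_fun, sample_rate = 1000) {
  t <- seq(0, 4, by = 1 / sample_rate)
  y <- filter_fun(sin(2 * pi * f_hz * t))
  max(abs(y[1000:3000]))
}

# Small fast protocol for pipeline smoke tests (not the study conditions).
smoke_protocol <- function() {
  protocol(reps_per_movement = 1, sessions = 2)
}
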
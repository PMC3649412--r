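#' Normalized firing strengths for a batch of samples
#'
#' @param fis a [sugeno_fis()].
#' @param X numeric matrix, rows = samples, cols = inputs.
#' @return K x L matrix of normalized firing strengths (rows sum to 1).
#' @keywords internal
batch_wbar <- function(fis, X) {
  X <- as.matrix(X)
  if (ncol(X) != fis$n_inputs) stop("X columns must equal n_inputs")
  K <- nrow(X); L <- n_rules(fis)
  logw <- matrix(0, K, L)
  for (i in seq_len(L)) {
    logw[, i] <- -colSums((t(X) - fis$centers[i, ])^2 /
                            (2 * fis$sigmas[i, ]^2))
  }
  W <- exp(logw - apply(logw, 1, max))   # rescale rows for numerical safety
  W / rowSums(W)
}

#' Consequent design matrix
#'
#' With premises fixed, the FIS output is linear in the consequent
#' parameters; this builds the regression matrix of that linear form. For a
#' first-order FIS the columns come in per-rule blocks
#' `(wbar_i x_1, ..., wbar_i x_n, wbar_i)`; for zero-order each rule
#' contributes the single column `wbar_i`.
#'
#' @param fis a [sugeno_fis()].
#' @param X numeric matrix, rows = samples.
#' @return K x (L*(n+1)) matrix (first-order) or K x L (zero-order).
#' @export
design_matrix <- function(fis, X) {
  X <- as.matrix(X)
  Wbar <- batch_wbar(fis, X)
  L <- n_rules(fis); n <- fis$n_inputs
  if (fis$order == "zero") return(Wbar)
  K <- nrow(X)
  Phi <- matrix(0, K, L * (n + 1L))
  for (i in seq_len(L)) {
    cols <- ((i - 1L) * (n + 1L) + 1L):(i * (n + 1L))
    Phi[, cols] <- cbind(Wbar[, i] * X, Wbar[, i])
  }
  Phi
}

#' Least-squares fit of consequent parameters
#'
#' The forward half of hybrid ANFIS learning: with premises fixed, the
#' consequents minimizing the sum of squared output errors are the linear
#' least-squares solution against [design_matrix()]. Rank-deficient systems
#' (fewer effective samples than consequent parameters) fall back to the
#' minimum-norm solution with a warning.
#'
#' @param fis a [sugeno_fis()].
#' @param X numeric matrix of training inputs.
#' @param y numeric vector of training targets.
#' @return the FIS with fitted consequent coefficients.
#' @export
lse_consequents <- function(fis, X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows must equal length(y)")
  Phi <- design_matrix(fis, X)
  sv <- svd(Phi)
  tol <- max(dim(Phi)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  if (sum(keep) < ncol(Phi))
    warning(sprintf(
      "design matrix rank %d < %d parameters; using minimum-norm solution",
      sum(keep), ncol(Phi)))
  theta <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
  L <- n_rules(fis)
  p <- if (fis$order == "first") fis$n_inputs + 1L else 1L
  fis$coeffs <- matrix(theta, L, p, byrow = TRUE)
  fis
}

#' Analytic gradients of the squared error w.r.t. premise parameters
#'
#' Gradients of `SSE = sum_k (gamma(x_k) - y_k)^2` with respect to every
#' Gaussian membership center and width, obtained by the chain rule through
#' the forward pass (firing strengths, normalization, weighted sum). They
#' drive the backward half of hybrid learning and agree with central finite
#' differences.
#'
#' @param fis a [sugeno_fis()].
#' @param X numeric matrix of training inputs.
#' @param y numeric vector of training targets.
#' @return list with matrices `centers` and `sigmas` (both L x n) of
#'   `dSSE/dparam`.
#' @export
premise_gradients <- function(fis, X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  K <- nrow(X); L <- n_rules(fis); n <- fis$n_inputs
  Wbar <- batch_wbar(fis, X)
  # per-sample, per-rule consequent values
  Fm <- if (fis$order == "zero") {
    matrix(fis$coeffs[, 1], K, L, byrow = TRUE)
  } else {
    X %*% t(fis$coeffs[, seq_len(n), drop = FALSE]) +
      matrix(fis$coeffs[, n + 1L], K, L, byrow = TRUE)
  }
  gamma <- rowSums(Wbar * Fm)
  e <- gamma - y
  # dSSE/dw_i routed through normalization: A[k,i] = 2 e_k wbar_ki (f_ki - gamma_k)
  A <- 2 * e * Wbar * (Fm - gamma)
  g_c <- matrix(0, L, n)
  g_s <- matrix(0, L, n)
  sA <- colSums(A)                       # sum over samples, per rule
  sAX <- t(A) %*% X                      # L x n
  sAX2 <- t(A) %*% (X^2)                 # L x n
  for (i in seq_len(L)) {
    c_i <- fis$centers[i, ]; s_i <- fis$sigmas[i, ]
    # d log w_i / d c_ij = (x_j - c_ij) / sigma_ij^2
    g_c[i, ] <- (sAX[i, ] - sA[i] * c_i) / s_i^2
    # d log w_i / d sigma_ij = (x_j - c_ij)^2 / sigma_ij^3
    g_s[i, ] <- (sAX2[i, ] - 2 * c_i * sAX[i, ] + sA[i] * c_i^2) / s_i^3
  }
  list(centers = g_c, sigmas = g_s)
}

#' Training configuration for hybrid ANFIS learning
#'
#' @param epochs maximum training epochs (>= 1), default 50.
#' @param learning_rate gradient step size for premise updates (the step is
#'   scaled by the sample count, i.e. taken on the mean squared error);
#'   default 0.01.
#' @param min_sigma lower clamp for membership widths; `NULL` (default) uses
#'   `1e-4` times each input dimension's range.
#' @param tolerance early stop when the epoch-to-epoch error change falls
#'   below this (absolute), default 1e-6.
#' @param seed optional RNG seed (training itself is deterministic; the seed
#'   covers any future stochastic extensions).
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 50, learning_rate = 0.01, min_sigma = NULL,
                         tolerance = 1e-6, seed = NULL) {
  stopifnot(epochs >= 1, learning_rate > 0,
            is.null(min_sigma) || min_sigma > 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 min_sigma = min_sigma, tolerance = tolerance, seed = seed),
            class = "train_config")
}

#' Hybrid ANFIS training
#'
#' The classic two-pass scheme per epoch: a forward pass identifies the
#' consequent parameters by least squares (global optimum given the current
#' premises), then the output error is propagated backward and the premise
#' parameters (Gaussian centers and widths) take one batch gradient-descent
#' step. Widths are clamped from below to keep memberships well defined. If
#' the error rises for 5 consecutive epochs the learning rate is halved; when
#' it falls below 1e-8 of its initial value training stops with
#' `converged = FALSE`.
#'
#' @param fis initial [sugeno_fis()] (typically from [build_initial_fis()]).
#' @param X numeric matrix of training inputs.
#' @param y numeric vector of training targets.
#' @param config a [train_config()].
#' @return list of class `train_report`: `fis` (trained system), `errors`
#'   (per-epoch RMSE after the LSE step), `converged` flag, and
#'   `final_learning_rate`.
#' @export
hybrid_fit <- function(fis, X, y, config = train_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  K <- nrow(X)
  if (!is.null(config$seed)) set.seed(config$seed)
  lr <- config$learning_rate
  min_lr <- config$learning_rate * 1e-8
  rng <- apply(X, 2, function(col) diff(range(col)))
  min_sigma <- if (is.null(config$min_sigma)) {
    pmax(1e-4 * rng, .Machine$double.eps)
  } else rep(config$min_sigma, fis$n_inputs)
  errors <- numeric(0)
  converged <- FALSE
  bad_streak <- 0L
  for (ep in seq_len(config$epochs)) {
    fis <- suppressWarnings(lse_consequents(fis, X, y))
    err <- sqrt(mean((fis_eval(fis, X) - y)^2))
    errors <- c(errors, err)
    if (ep > 1L) {
      if (abs(errors[ep - 1L] - err) < config$tolerance) {
        converged <- TRUE
        break
      }
      bad_streak <- if (err > errors[ep - 1L]) bad_streak + 1L else 0L
      if (bad_streak >= 5L) {
        lr <- lr / 2
        bad_streak <- 0L
        message(sprintf("epoch %d: error rising; learning rate halved to %g",
                        ep, lr))
        if (lr < min_lr) break
      }
    }
    g <- premise_gradients(fis, X, y)
    fis$centers <- fis$centers - lr * g$centers / K
    fis$sigmas <- fis$sigmas - lr * g$sigmas / K
    fis$sigmas <- pmax(fis$sigmas,
                       matrix(min_sigma, n_rules(fis), fis$n_inputs,
                              byrow = TRUE))
  }
  structure(list(fis = fis, errors = errors, converged = converged,
                 final_learning_rate = lr),
            class = "train_report")
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report> %d epoch(s), final RMSE %.6g, converged: %s\n",
              length(x$errors), utils::tail(x$errors, 1), x$converged))
  invisible(x)
}
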
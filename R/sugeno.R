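#' Gaussian membership function
#'
#' `exp(-(x - center)^2 / (2 * sigma^2))`: 1 exactly at the center, symmetric,
#' strictly positive. The Gaussian family is used throughout because it is
#' differentiable (required by the premise gradient step) and maps naturally
#' onto cluster centers.
#'
#' @param x numeric input (vectorized).
#' @param center membership-function center (premise parameter).
#' @param sigma membership-function width (> 0).
#' @return membership value(s) in (0, 1].
#' @export
mf_eval <- function(x, center, sigma) {
  if (!(is.numeric(sigma) && all(sigma > 0)))
    stop("sigma must be positive")
  exp(-(x - center)^2 / (2 * sigma^2))
}

#' Construct a Sugeno fuzzy inference system
#'
#' A Sugeno FIS with Gaussian premises. Rule `i` has one Gaussian membership
#' function per input dimension (center `centers[i, j]`, width
#' `sigmas[i, j]`) and a consequent that is either a constant (zero-order) or
#' an affine function of the inputs (first-order,
#' `f_i = p_i x_1 + ... + s_i`). The system output is the
#' firing-strength-weighted average of the rule consequents.
#'
#' @param centers L x n matrix of premise centers (rules x inputs).
#' @param sigmas L x n matrix of premise widths (> 0).
#' @param coeffs consequent coefficients: L x (n+1) matrix for first-order
#'   (last column is the constant term), L x 1 for zero-order. `NULL`
#'   initializes all consequents to zero.
#' @param order `"first"` or `"zero"`.
#' @param input_names optional character vector of input (channel) names.
#' @return object of class `sugeno_fis`.
#' @export
sugeno_fis <- function(centers, sigmas, coeffs = NULL, order = c("first", "zero"),
                       input_names = NULL) {
  order <- match.arg(order)
  centers <- as.matrix(centers)
  sigmas <- as.matrix(sigmas)
  L <- nrow(centers); n <- ncol(centers)
  if (L < 1L) stop("FIS needs at least one rule")
  if (!all(dim(sigmas) == c(L, n))) stop("sigmas must match centers in shape")
  if (any(sigmas <= 0)) stop("all sigmas must be positive")
  p <- if (order == "first") n + 1L else 1L
  if (is.null(coeffs)) coeffs <- matrix(0, L, p)
  coeffs <- as.matrix(coeffs)
  if (!all(dim(coeffs) == c(L, p)))
    stop(sprintf("coeffs must be %d x %d for a %s-order FIS", L, p, order))
  if (is.null(input_names)) input_names <- paste0("C", seq_len(n) - 1L)
  structure(list(n_inputs = n, order = order, centers = centers,
                 sigmas = sigmas, coeffs = coeffs,
                 input_names = as.character(input_names)),
            class = "sugeno_fis")
}

#' @export
print.sugeno_fis <- function(x, ...) {
  cat(sprintf("<sugeno_fis> %d input(s), %d rule(s), %s-order consequents\n",
              x$n_inputs, nrow(x$centers), x$order))
  invisible(x)
}

#' Number of rules in a FIS
#' @param fis a [sugeno_fis()].
#' @return integer rule count.
#' @export
n_rules <- function(fis) nrow(fis$centers)

#' Per-rule firing strengths
#'
#' The firing strength of rule `i` is the product of its premise memberships
#' over all inputs: `w_i = prod_j mu_ij(x_j)`. With Gaussian memberships every
#' strength is in (0, 1] and strictly positive.
#'
#' @param fis a [sugeno_fis()].
#' @param x numeric input vector of length `fis$n_inputs`.
#' @return numeric vector of length `n_rules(fis)`.
#' @export
firing_strengths <- function(fis, x) {
  if (length(x) != fis$n_inputs)
    stop("input length ", length(x), " does not match n_inputs ", fis$n_inputs)
  exp(-rowSums(((matrix(x, nrow(fis$centers), fis$n_inputs, byrow = TRUE) -
                   fis$centers)^2) / (2 * fis$sigmas^2)))
}

#' Normalize firing strengths
#'
#' `wbar_i = w_i / sum(w)`; the normalized strengths sum to 1. All-zero input
#' is rejected (it cannot occur with Gaussian memberships but guards other
#' membership families).
#'
#' @param w numeric vector of non-negative firing strengths.
#' @return numeric vector summing to 1.
#' @export
normalize_strengths <- function(w) {
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop("degenerate firing strengths: sum is not positive")
  w / s
}

#' Rule consequent values
#'
#' First-order: `f_i = coeffs[i, 1:n] . x + coeffs[i, n+1]`; zero-order: the
#' rule constant, independent of `x`.
#'
#' @param fis a [sugeno_fis()].
#' @param x numeric input vector.
#' @return numeric vector, one consequent value per rule.
#' @export
rule_consequents <- function(fis, x) {
  if (length(x) != fis$n_inputs)
    stop("input length ", length(x), " does not match n_inputs ", fis$n_inputs)
  if (fis$order == "zero") return(as.numeric(fis$coeffs[, 1]))
  as.numeric(fis$coeffs[, seq_len(fis$n_inputs), drop = FALSE] %*% x +
               fis$coeffs[, fis$n_inputs + 1L])
}

#' Evaluate a Sugeno FIS (ANFIS forward pass)
#'
#' The network output is the normalized-firing-strength-weighted sum of rule
#' consequents: `gamma = sum_i wbar_i f_i(x)`. For a zero-order FIS the output
#' is a convex combination of the rule constants and therefore bounded by
#' their range.
#'
#' @param fis a [sugeno_fis()].
#' @param x numeric input vector, or a matrix with one row per input vector.
#' @return scalar output `gamma` (or a vector, one per input row).
#' @export
fis_eval <- function(fis, x) {
  if (is.matrix(x)) return(apply(x, 1, function(r) fis_eval(fis, r)))
  # log-domain strengths, rescaled by their maximum: far from every premise
  # the absolute strengths underflow but their ratios stay well defined
  logw <- -rowSums(((matrix(x, nrow(fis$centers), fis$n_inputs,
                            byrow = TRUE) - fis$centers)^2) /
                     (2 * fis$sigmas^2))
  w <- exp(logw - max(logw))
  wbar <- normalize_strengths(w)
  sum(wbar * rule_consequents(fis, x))
}

#' Build an initial FIS from cluster centers
#'
#' Each cluster center becomes the premise-center vector of one rule; the
#' premise width of input `j` is `ra * range_j / sqrt(8)` where `range_j` is
#' the min-max range of dimension `j` (a seeding convention: the width scales
#' with both the cluster radius and the data spread). Consequents start at
#' zero; when training data are supplied they are immediately fitted by least
#' squares.
#'
#' @param cr a `cluster_result` from [subclust()].
#' @param order consequent order, `"first"` (default) or `"zero"`.
#' @param X,y optional training inputs (matrix) and targets (vector); when
#'   given, consequents are fitted by [lse_consequents()].
#' @param input_names optional input (channel) names.
#' @return a [sugeno_fis()] with one rule per cluster center.
#' @export
build_initial_fis <- function(cr, order = c("first", "zero"), X = NULL,
                              y = NULL, input_names = NULL) {
  order <- match.arg(order)
  stopifnot(inherits(cr, "cluster_result"))
  centers <- as.matrix(cr$centers)
  if (nrow(centers) < 1L) stop("no cluster centers to build from")
  rng <- cr$bounds["max", ] - cr$bounds["min", ]
  rng[rng <= 0] <- 1      # constant dimension: fall back to unit width
  sig <- cr$config$ra * rng / sqrt(8)
  sigmas <- matrix(sig, nrow(centers), ncol(centers), byrow = TRUE)
  fis <- sugeno_fis(centers, sigmas, NULL, order, input_names)
  if (!is.null(X) && !is.null(y)) fis <- lse_consequents(fis, X, y)
  fis
}

#' Serialize / deserialize a FIS as JSON
#'
#' The JSON document carries `n_inputs`, `order`, `input_names` and the
#' per-rule premise (center, sigma per input) and consequent coefficients;
#' the round trip is lossless.
#'
#' @param fis a [sugeno_fis()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly); `fis_from_json` returns a
#'   [sugeno_fis()].
#' @export
fis_to_json <- function(fis, path = NULL) {
  stopifnot(inherits(fis, "sugeno_fis"))
  rules <- lapply(seq_len(n_rules(fis)), function(i) {
    list(centers = fis$centers[i, ], sigmas = fis$sigmas[i, ],
         consequent = fis$coeffs[i, ])
  })
  obj <- list(n_inputs = fis$n_inputs, order = fis$order,
              input_names = fis$input_names, rules = rules)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @param json JSON string or file path produced by [fis_to_json()].
#' @rdname fis_to_json
#' @export
fis_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  L <- length(obj$rules)
  centers <- t(vapply(obj$rules, function(r) as.numeric(r$centers),
                      numeric(obj$n_inputs)))
  sigmas <- t(vapply(obj$rules, function(r) as.numeric(r$sigmas),
                     numeric(obj$n_inputs)))
  p <- if (obj$order == "first") obj$n_inputs + 1L else 1L
  coeffs <- t(vapply(obj$rules, function(r) as.numeric(r$consequent),
                     numeric(p)))
  if (p == 1L) coeffs <- matrix(coeffs, ncol = 1L)
  if (obj$n_inputs == 1L) {
    centers <- matrix(centers, ncol = 1L)
    sigmas <- matrix(sigmas, ncol = 1L)
  }
  sugeno_fis(centers, sigmas, coeffs, obj$order, obj$input_names)
}
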
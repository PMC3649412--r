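#' Min-max normalization to the unit hypercube
#'
#' Subtractive clustering measures densities in a normalized feature space:
#' each dimension is mapped to [0, 1] by its min-max range. A constant
#' (zero-range) dimension maps to 0.5 everywhere.
#'
#' @param X numeric matrix, rows = points.
#' @return list with `points` (normalized matrix) and `bounds` (2 x d matrix,
#'   rows `min` and `max`).
#' @export
normalize_hypercube <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("need at least one point")
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  rng <- hi - lo
  Z <- X
  for (j in seq_len(ncol(X))) {
    Z[, j] <- if (rng[j] > 0) (X[, j] - lo[j]) / rng[j] else 0.5
  }
  list(points = Z, bounds = rbind(min = lo, max = hi))
}

#' @param Z normalized matrix as produced by [normalize_hypercube()].
#' @param bounds the `bounds` element of [normalize_hypercube()]'s result.
#' @rdname normalize_hypercube
#' @export
denormalize_hypercube <- function(Z, bounds) {
  Z <- as.matrix(Z)
  X <- Z
  for (j in seq_len(ncol(Z))) {
    rng <- bounds["max", j] - bounds["min", j]
    X[, j] <- if (rng > 0) Z[, j] * rng + bounds["min", j]
              else bounds["min", j]
  }
  X
}

#' Subtractive-clustering density at every point
#'
#' Each point's density is the sum of Gaussian kernels over all points:
#' `D_i = sum_j exp(-||x_i - x_j||^2 / (ra/2)^2)`. Points within roughly one
#' cluster radius `ra` contribute; the self-term guarantees `D_i >= 1`.
#'
#' @param X numeric matrix of normalized points (rows = points).
#' @param ra cluster radius in normalized units (> 0).
#' @return numeric vector of densities, one per point.
#' @export
sc_density <- function(X, ra) {
  if (!(is.numeric(ra) && length(ra) == 1L && ra > 0))
    stop("ra must be a single positive number")
  X <- as.matrix(X)
  d2 <- as.matrix(stats::dist(X))^2
  unname(rowSums(exp(-d2 / (ra / 2)^2)))
}

#' Revise densities after selecting a cluster center
#'
#' Subtracts the selected center's influence:
#' `D_i <- D_i - D_c * exp(-||x_i - x_c||^2 / (rb/2)^2)`, so the density at
#' the center itself becomes exactly zero and nearby points are suppressed,
#' preventing closely spaced centers.
#'
#' @param D numeric vector of current densities.
#' @param X numeric matrix of normalized points.
#' @param center numeric vector, the selected center (normalized units).
#' @param center_density the center's density at selection time.
#' @param rb squash radius (> 0), conventionally `1.5 * ra`.
#' @return revised density vector.
#' @export
sc_revise_density <- function(D, X, center, center_density, rb) {
  if (!(is.numeric(rb) && length(rb) == 1L && rb > 0))
    stop("rb must be a single positive number")
  X <- as.matrix(X)
  d2 <- unname(colSums((t(X) - center)^2))
  unname(D) - center_density * exp(-d2 / (rb / 2)^2)
}

#' Subtractive-clustering configuration
#'
#' @param ra cluster radius in normalized units (default 0.5).
#' @param rb squash radius; default `1.5 * ra`.
#' @param accept_ratio candidates with density above `accept_ratio` times the
#'   first center's density are accepted outright (default 0.5).
#' @param reject_ratio candidates below `reject_ratio` times the first
#'   center's density stop the search (default 0.15); in between, a candidate
#'   is accepted only if it is far enough from existing centers
#'   (`d_min/ra + D/D1 >= 1`).
#' @param max_clusters optional hard cap on the number of centers.
#' @return a list of class `cluster_config`.
#' @export
cluster_config <- function(ra = 0.5, rb = 1.5 * ra, accept_ratio = 0.5,
                           reject_ratio = 0.15, max_clusters = NULL) {
  stopifnot(ra > 0, rb > ra, reject_ratio > 0, accept_ratio > reject_ratio,
            accept_ratio <= 1)
  structure(list(ra = ra, rb = rb, accept_ratio = accept_ratio,
                 reject_ratio = reject_ratio, max_clusters = max_clusters),
            class = "cluster_config")
}

#' Subtractive clustering
#'
#' Density-based center selection: normalize the points to the unit hypercube,
#' compute every point's density, pick the densest point as the first center,
#' subtract its influence, and repeat until the accept/reject criteria (or the
#' optional `max_clusters` cap) stop the search. Each center seeds one fuzzy
#' rule of the initial Sugeno system. Ties in density are broken toward the
#' lowest point index, so the result is invariant to input point order.
#'
#' @param X numeric matrix of points in original feature units (rows =
#'   points).
#' @param config a [cluster_config()].
#' @return object of class `cluster_result`: list with `centers` (matrix in
#'   original units), `densities` (density of each center at selection time,
#'   non-increasing), `bounds` (normalization bounds) and `config`.
#' @export
subclust <- function(X, config = cluster_config()) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("need at least one point")
  nz <- normalize_hypercube(X)
  Z <- nz$points
  D <- sc_density(Z, config$ra)
  max_k <- if (is.null(config$max_clusters)) nrow(Z) else
    min(config$max_clusters, nrow(Z))
  centers_idx <- integer(0)
  densities <- numeric(0)
  d1 <- NA_real_
  Dw <- D           # working densities; rejected in-between candidates zeroed
  while (length(centers_idx) < max_k) {
    k <- which.max(Dw)                 # lowest index wins ties
    dk <- Dw[k]
    if (dk <= 0) break
    if (!length(centers_idx)) {
      accept <- TRUE                   # first center: global density maximizer
      d1 <- dk
    } else if (dk > config$accept_ratio * d1) {
      accept <- TRUE
    } else if (dk < config$reject_ratio * d1) {
      break
    } else {
      # gray zone: require the candidate to trade density for distance
      dmin <- sqrt(min(colSums(
        (t(Z[centers_idx, , drop = FALSE]) - Z[k, ])^2)))
      if (dmin / config$ra + dk / d1 >= 1) {
        accept <- TRUE
      } else {
        Dw[k] <- 0
        next
      }
    }
    if (accept) {
      centers_idx <- c(centers_idx, k)
      densities <- c(densities, dk)
      Dw <- sc_revise_density(Dw, Z, Z[k, ], dk, config$rb)
    }
  }
  structure(
    list(centers = denormalize_hypercube(Z[centers_idx, , drop = FALSE],
                                         nz$bounds),
         densities = densities, bounds = nz$bounds, config = config),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d center(s) in %d dimension(s), ra = %g\n",
              nrow(x$centers), ncol(x$centers), x$config$ra))
  invisible(x)
}

#' Serialize / deserialize a cluster result as JSON
#'
#' @param cr a `cluster_result` from [subclust()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly); `cluster_result_from_json`
#'   returns a `cluster_result`.
#' @export
cluster_result_to_json <- function(cr, path = NULL) {
  stopifnot(inherits(cr, "cluster_result"))
  obj <- list(centers = unclass(cr$centers), densities = cr$densities,
              bounds = unclass(cr$bounds), config = unclass(cr$config))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @param json JSON string or file path produced by
#'   [cluster_result_to_json()].
#' @rdname cluster_result_to_json
#' @export
cluster_result_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  cfg <- do.call(cluster_config, obj$config[c("ra", "rb", "accept_ratio",
                                              "reject_ratio", "max_clusters")])
  bounds <- as.matrix(obj$bounds)
  rownames(bounds) <- c("min", "max")
  structure(list(centers = as.matrix(obj$centers),
                 densities = as.numeric(obj$densities),
                 bounds = bounds, config = cfg),
            class = "cluster_result")
}
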
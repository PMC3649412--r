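#' The seven movement classes and their network output codes
#'
#' The classifier has a single continuous output in [0, 1]; each of the seven
#' arm/hand movements is assigned a fixed target value. The codes are stored
#' exactly as published (0, 0.083, 0.166, 0.249, 0.333, 0.416, 0.499), not as
#' an idealized uniform grid.
#'
#' @return data.frame with columns `label`, `code`, `abbreviation` (M0-M6),
#'   codes strictly increasing.
#' @export
movement_codes <- function() {
  data.frame(
    label = c("Hand Contraction", "Wrist Extension", "Wrist Flexion",
              "Forearm Flexion", "Forearm Rotation", "Hand Abduction",
              "Hand Adduction"),
    code = c(0, 0.083, 0.166, 0.249, 0.333, 0.416, 0.499),
    abbreviation = paste0("M", 0:6),
    stringsAsFactors = FALSE
  )
}

#' Movement label to scalar output code
#'
#' Accepts either the full label ("Forearm Rotation") or the abbreviation
#' ("M4"). Vectorized.
#'
#' @param label character vector of movement labels or abbreviations.
#' @return numeric vector of output codes.
#' @export
encode_movement <- function(label) {
  mc <- movement_codes()
  idx <- match(label, mc$label)
  idx[is.na(idx)] <- match(label[is.na(idx)], mc$abbreviation)
  if (anyNA(idx))
    stop("unknown movement label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "))
  mc$code[idx]
}

#' Continuous network output to movement label
#'
#' Nearest-code assignment: the decoded class is the one whose code minimizes
#' `|gamma - code|`, with ties broken toward the lower code. Outputs outside
#' the code range map to the nearest endpoint class. Vectorized.
#'
#' @param gamma numeric vector of network outputs (finite).
#' @param abbreviate if TRUE return abbreviations (M0-M6) instead of full
#'   labels.
#' @return character vector of movement labels.
#' @export
decode_movement <- function(gamma, abbreviate = FALSE) {
  if (any(!is.finite(gamma))) stop("gamma must be finite")
  mc <- movement_codes()
  idx <- vapply(gamma, function(g) which.min(abs(g - mc$code)), integer(1))
  if (abbreviate) mc$abbreviation[idx] else mc$label[idx]
}

#' Per-movement hit rates for one session
#'
#' A repetition is a hit when the decoded label equals the cued label. The hit
#' rate per movement is `100 * hits / repetitions`; a movement absent from the
#' session is reported as `NA`.
#'
#' @param truth character vector of cued movement labels.
#' @param predicted character vector of decoded labels, same length.
#' @return named numeric vector of hit rates (%), one entry per movement
#'   (M0-M6 order).
#' @export
score_session <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  mc <- movement_codes()
  canon <- function(x) {
    i <- match(x, mc$label)
    i[is.na(i)] <- match(x[is.na(i)], mc$abbreviation)
    if (anyNA(i)) stop("labels outside the 7 movement classes")
    mc$abbreviation[i]
  }
  tr <- canon(truth); pr <- canon(predicted)
  rates <- vapply(mc$abbreviation, function(m) {
    reps <- tr == m
    if (!any(reps)) return(NA_real_)
    100 * sum(pr[reps] == m) / sum(reps)
  }, numeric(1))
  names(rates) <- mc$abbreviation
  rates
}

#' Aggregate per-session hit rates into an accuracy table
#'
#' Stacks per-session rate vectors, appends the per-movement average row
#' (arithmetic mean over sessions) and reports the overall mean over
#' movements — the layout used to summarize a subject's test.
#'
#' @param session_rates a matrix or data.frame, rows = sessions, columns =
#'   the 7 movements (M0-M6), entries = hit rates in %. Row names identify
#'   sessions.
#' @return list with `table` (data.frame of sessions plus an `"Average"` row)
#'   and `overall` (mean of the average row, %).
#' @export
aggregate_accuracy <- function(session_rates) {
  m <- as.matrix(session_rates)
  if (is.null(colnames(m))) colnames(m) <- paste0("M", seq_len(ncol(m)) - 1L)
  avg <- colMeans(m, na.rm = TRUE)
  tab <- rbind(m, Average = avg)
  list(table = as.data.frame(tab), overall = mean(avg, na.rm = TRUE))
}

#' Confusion matrix over the seven movement classes
#'
#' @param truth character vector of cued labels.
#' @param predicted character vector of decoded labels.
#' @return 7 x 7 integer matrix, rows = true class (M0-M6), columns =
#'   predicted class; row sums equal repetition counts.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  mc <- movement_codes()
  canon <- function(x) {
    i <- match(x, mc$label)
    i[is.na(i)] <- match(x[is.na(i)], mc$abbreviation)
    if (anyNA(i)) stop("labels outside the 7 movement classes")
    factor(mc$abbreviation[i], levels = mc$abbreviation)
  }
  unclass(table(true = canon(truth), predicted = canon(predicted)))
}
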
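#' Min-max normalization of an observation matrix
#'
#' Rescales each indicator column to \[0, 1\]. For a cost indicator (the
#' usual case for pollutants: lower is better) `r = (max - x)/(max - min)`,
#' so the cleanest observed value maps to 1 and the dirtiest to 0; for a
#' benefit indicator `r = (x - min)/(max - min)`. Min and max are taken over
#' the rows of `x` unless an explicit `range` pool is supplied.
#'
#' @param x numeric matrix (rows = days/objects, columns = indicators),
#'   non-negative.
#' @param orientation "cost" or "benefit", scalar or one per column.
#' @param range optional 2 x ncol matrix of (min, max) per column,
#'   overriding the observed extremes (used for pooled normalization with
#'   centers); values outside the pool are clipped into \[0, 1\].
#' @return matrix of normalized values with attributes `min` and `max`.
#' @export
normalize_minmax <- function(x, orientation = "cost", range = NULL) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative concentrations are not allowed")
  if (nrow(x) < 2L && is.null(range))
    stop("need at least 2 rows to normalize")
  orientation <- rep_len(match_orientation(orientation), ncol(x))
  if (is.null(range)) {
    mn <- apply(x, 2, min); mx <- apply(x, 2, max)
  } else {
    mn <- range[1, ]; mx <- range[2, ]
  }
  if (any(mx == mn))
    stop("constant column(s): ",
         paste(colnames(x)[mx == mn], collapse = ", "),
         " (max == min, normalization undefined)")
  r <- sweep(sweep(x, 2, mx, "-"), 2, mn - mx, "/")   # (max - x)/(max - min)
  ben <- orientation == "benefit"
  if (any(ben)) r[, ben] <- 1 - r[, ben, drop = FALSE]
  r <- pmin(pmax(r, 0), 1)
  structure(r, min = mn, max = mx, orientation = orientation)
}

match_orientation <- function(orientation) {
  vapply(orientation, function(o)
    match.arg(o, c("cost", "benefit")), character(1), USE.NAMES = FALSE)
}

#' Per-indicator relative frequencies
#'
#' Converts a normalized matrix into the relative-frequency matrix used by
#' the entropy computation: `f_ij = r_ij / sum_j r_ij` within each
#' indicator column, so each column sums to 1 over objects.
#'
#' @param r normalized matrix from [normalize_minmax()].
#' @return matrix of frequencies.
#' @export
relative_frequencies <- function(r) {
  r <- as.matrix(r)
  s <- colSums(r)
  if (any(s == 0))
    stop("indicator(s) with all-zero normalized values: ",
         paste(colnames(r)[s == 0], collapse = ", "),
         " (entropy undefined)")
  sweep(r, 2, s, "/")
}

#' Indicator entropy values
#'
#' Computes `e_i = -k * sum_j f_ij ln f_ij` per indicator, with the
#' convention `0 * ln 0 = 0`. The normalizing constant `k` is chosen by
#' `k_convention`:
#' \describe{
#'   \item{objects}{`k = 1/ln(n)` where n is the number of objects (days);
#'     the information-theoretic default, bounding `e <= 1`.}
#'   \item{indicators}{`k = 1/ln(m)` where m is the number of indicators.}
#'   \item{common_log}{`k = 1/ln(10)`, i.e. a base-10 entropy. This is the
#'     convention the bundled case study's published entropy values follow
#'     (see [calibrate_entropy()]).}
#'   \item{custom}{a user-supplied positive `k`.}
#' }
#'
#' @param f frequency matrix from [relative_frequencies()] (columns sum
#'   to 1).
#' @param k_convention one of "objects", "indicators", "common_log",
#'   "custom".
#' @param k numeric, required when `k_convention = "custom"`.
#' @return an `"aq_entropy"` object: `entropy` (named vector), `f`, `k`,
#'   `k_convention`.
#' @export
entropy_values <- function(f,
                           k_convention = c("objects", "indicators",
                                            "common_log", "custom"),
                           k = NULL) {
  f <- as.matrix(f)
  k_convention <- match.arg(k_convention)
  if (any(f < 0)) stop("negative frequencies")
  if (any(abs(colSums(f) - 1) > 1e-8))
    stop("frequency columns must sum to 1")
  k <- switch(k_convention,
    objects = 1 / log(nrow(f)),
    indicators = 1 / log(ncol(f)),
    common_log = 1 / log(10),
    custom = k)
  if (is.null(k) || !is.finite(k) || k <= 0)
    stop("invalid entropy constant k")
  plogp <- f * log(f)
  plogp[f == 0] <- 0
  e <- -k * colSums(plogp)
  structure(list(entropy = e, f = f, k = k, k_convention = k_convention),
            class = "aq_entropy")
}

#' @export
print.aq_entropy <- function(x, digits = 4, ...) {
  cat("Indicator entropies (k =", format(x$k, digits = 6),
      ", convention:", x$k_convention, ")\n")
  print(round(x$entropy, digits))
  invisible(x)
}

#' Entropy weights from indicator entropies
#'
#' Turns entropies into indicator weights by
#' `lambda_i = (1 - e_i) / sum_i (1 - e_i)`: the less uniform an
#' indicator's value distribution (lower entropy), the more information it
#' carries and the larger its weight. The weights always sum to 1. When
#' entropies exceed 1 (possible under the "common_log" or "indicators"
#' conventions) every `1 - e_i` is negative; the formula still applies but
#' the usual "low entropy, high weight" reading inverts, and a diagnostic
#' warning is recorded (not signalled) in the `notes` attribute. A weight
#' outside \[0, 1\] (mixed signs of `1 - e_i`) is likewise recorded.
#'
#' @param e an `"aq_entropy"` object or a bare numeric vector of entropies.
#' @return an `"aq_weights"` object: named `weights` summing to 1,
#'   `entropy`, and a character vector `notes` of diagnostics.
#' @examples
#' # the published case-study entropies reproduce the published weights
#' entropy_weights(c(PM2.5 = 1.3887, PM10 = 1.3999, CO = 1.4002,
#'                   NO2 = 1.3595, SO2 = 1.3944))
#' @export
entropy_weights <- function(e) {
  report <- if (inherits(e, "aq_entropy")) e else NULL
  ev <- if (is.null(report)) e else report$entropy
  stopifnot(is.numeric(ev), length(ev) >= 1L)
  denom <- sum(1 - ev)
  if (denom == 0)
    stop("sum of (1 - entropy) is zero; weights undefined")
  w <- (1 - ev) / denom
  notes <- character(0)
  if (all(ev > 1))
    notes <- c(notes, paste("all entropies exceed 1: the low-entropy ->",
                            "high-weight interpretation is inverted"))
  if (any(w < 0 | w > 1))
    notes <- c(notes, "weights outside [0, 1] (mixed signs of 1 - entropy)")
  structure(list(weights = w, entropy = ev,
                 k = report$k, k_convention = report$k_convention,
                 notes = notes),
            class = "aq_weights")
}

#' @export
print.aq_weights <- function(x, digits = 4, ...) {
  cat("Entropy weights\n")
  print(round(x$weights, digits))
  if (length(x$notes)) cat("Note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.aq_weights <- function(object, ...) object$weights

#' Entropy-weight an observation matrix
#'
#' One-call pipeline: min-max normalization, relative frequencies,
#' entropies, weights.
#'
#' @param x observation matrix or data.frame (a `date` column, if present,
#'   becomes row labels).
#' @param orientation per-indicator orientation, default "cost".
#' @inheritParams entropy_values
#' @return an `"aq_weights"` object (see [entropy_weights()]).
#' @examples
#' aq_entropy_weights(beijing_feb2014())
#' @export
aq_entropy_weights <- function(x, orientation = "cost",
                               k_convention = "objects", k = NULL) {
  m <- as_observation_matrix(x)
  r <- normalize_minmax(m, orientation)
  f <- relative_frequencies(r)
  entropy_weights(entropy_values(f, k_convention, k))
}
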
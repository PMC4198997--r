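#' Jointly normalize observations and centers
#'
#' The threshold centers and the daily observations must be made
#' commensurate before distances mean anything. With `pool = "joint"` (the
#' default) the per-indicator min and max are taken over the union of the
#' observation rows and the center rows, so both land inside \[0, 1\].
#' With `pool = "observations"` the extremes come from the observations
#' alone and center coordinates falling outside are clipped into \[0, 1\].
#'
#' @param x observation matrix/data.frame (columns must cover the centers'
#'   indicators).
#' @param centers an `"aq_centers"` matrix from [build_centers()], or any
#'   levels x indicators matrix.
#' @param orientation per-indicator orientation, default "cost". Centers
#'   are normalized with the same orientation as the observations, so the
#'   best level sits at the clean end of every axis.
#' @param pool "joint" or "observations".
#' @param units optional named units for `x` to check against the centers'
#'   units (the bundled reader attaches them automatically); mismatches
#'   are an error, there is no automatic conversion.
#' @return list with elements `observations` and `centers` (normalized
#'   matrices), and `min`, `max` (the pool extremes per indicator).
#' @examples
#' cen <- build_centers("GB3095-2012", c("PM2.5", "PM10", "SO2"))
#' jn <- joint_normalize(beijing_feb2014()[c("date", "PM2.5", "PM10", "SO2")], cen)
#' jn$centers["I", "PM2.5"]  # (387 - 35) / 382 = 0.9215
#' @export
joint_normalize <- function(x, centers, orientation = "cost",
                            pool = c("joint", "observations"),
                            units = NULL) {
  pool <- match.arg(pool)
  if (is.null(units) && !is.null(attr(x, "units"))) units <- attr(x, "units")
  m <- as_observation_matrix(x)
  cen <- as.matrix(centers)
  codes <- colnames(cen)
  missing <- setdiff(codes, colnames(m))
  if (length(missing))
    stop("observations lack indicator(s): ", paste(missing, collapse = ", "))
  m <- m[, codes, drop = FALSE]
  cunits <- attr(centers, "units")
  if (!is.null(units) && !is.null(cunits)) {
    u <- units[codes]
    bad <- which(!is.na(u) & u != cunits[codes])
    if (length(bad))
      stop("unit mismatch for ", paste(codes[bad], collapse = ", "),
           " (observations: ", paste(u[bad], collapse = ","),
           "; centers: ", paste(cunits[codes][bad], collapse = ","), ")")
  }
  mn <- apply(rbind(m, cen), 2, min)
  mx <- apply(rbind(m, cen), 2, max)
  if (pool == "observations") {
    # observation extremes; columns constant across the observations fall
    # back to the pooled extremes so that e.g. a single day still scales
    omn <- apply(m, 2, min); omx <- apply(m, 2, max)
    keep <- omx > omn
    mn[keep] <- omn[keep]; mx[keep] <- omx[keep]
  }
  if (any(mx == mn))
    stop("pool max equals min for: ",
         paste(codes[mx == mn], collapse = ", "))
  rng <- rbind(mn, mx)
  list(
    observations = normalize_minmax(m, orientation, range = rng),
    centers = normalize_minmax(cen, orientation, range = rng),
    min = mn, max = mx
  )
}

#' Euclidean distance, optionally weighted
#'
#' `sqrt(sum (a_i - b_i)^2)`, or with indicator weights
#' `sqrt(sum w_i (a_i - b_i)^2)`. The unweighted form is the library
#' default distance for level assignment.
#'
#' @param a,b numeric vectors of equal length.
#' @param weights optional non-negative weights in the same indicator
#'   order (an [entropy_weights()] vector, typically).
#' @return single distance.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))               # 5
#' euclidean_distance(c(0, 0), c(3, 4), c(0.5, 0.5))  # sqrt(12.5)
#' @export
euclidean_distance <- function(a, b, weights = NULL) {
  if (length(a) != length(b))
    stop("length mismatch: ", length(a), " vs ", length(b))
  d2 <- (a - b)^2
  if (!is.null(weights)) {
    if (length(weights) != length(a))
      stop("weights length mismatch")
    d2 <- weights * d2
  }
  sqrt(sum(d2))
}

#' Nearest-center classification of normalized day vectors
#'
#' Computes the distance from each day vector to every level center and
#' assigns the level of the nearest center. Exact distance ties are
#' resolved by `tie`: `"worst"` (default) picks the most polluted tied
#' level — the health-protective choice — `"best"` the cleanest.
#'
#' @param r normalized day vector or matrix (rows = days).
#' @param centers normalized center matrix (rows = levels, in increasing
#'   pollution order).
#' @param weights optional indicator weights for the distance.
#' @param tie "worst" or "best".
#' @return list with `distances` (days x levels matrix) and `level`
#'   (integer vector of assigned level indices).
#' @export
classify_nearest <- function(r, centers, weights = NULL,
                             tie = c("worst", "best")) {
  tie <- match.arg(tie)
  if (is.null(dim(r))) r <- matrix(r, nrow = 1)
  centers <- as.matrix(centers)
  if (nrow(centers) < 1L) stop("no centers")
  D <- matrix(0, nrow(r), nrow(centers),
              dimnames = list(rownames(r), rownames(centers)))
  for (i in seq_len(nrow(r)))
    for (l in seq_len(nrow(centers)))
      D[i, l] <- euclidean_distance(r[i, ], centers[l, ], weights)
  lev <- apply(D, 1, function(d) {
    hits <- which(d == min(d))
    if (tie == "worst") max(hits) else min(hits)
  })
  list(distances = D, level = as.integer(lev))
}
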
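#' Evaluate daily air quality against a standard
#'
#' The package's central fitting function. For each day it runs the full
#' pipeline: build the per-level clustering centers from the standard
#' ([build_centers()], dropping indicators that cannot discriminate),
#' normalize observations and centers onto a common \[0, 1\] scale
#' ([joint_normalize()]), optionally compute entropy weights, and assign
#' each day the level of its nearest center ([classify_nearest()]).
#'
#' @param x observations: a data.frame from [read_observations()] (a
#'   `date` column plus one column per pollutant) or a numeric matrix with
#'   day rownames.
#' @param standard standard id (see [standard_ids()]) or `"aq_standard"`.
#' @param indicators indicator codes to request from the standard;
#'   default: every default indicator present in both `x` and the
#'   standard at `averaging_time`.
#' @param exclude codes to exclude after the degenerate-threshold rule
#'   (recorded in the result's provenance; used by the calibrated
#'   case-study configuration).
#' @param averaging_time thresholds to use, default "24h".
#' @param pool normalization pool, "joint" (observations and centers
#'   pooled, the default) or "observations" (centers clipped).
#' @param weighting "none" (unweighted Euclidean distance, the default)
#'   or "entropy" (entropy-weighted distance).
#' @param k_convention entropy constant convention when
#'   `weighting = "entropy"`; see [entropy_values()].
#' @param tie tie rule for equidistant centers, "worst" (default) or
#'   "best".
#' @return an `"aq_eval"` object: `distances` (days x levels), `level`
#'   (factor of assigned levels), `dates`, `retained`, `dropped`,
#'   `excluded`, `centers` (raw), `pool_min`/`pool_max`, `weights`
#'   (or NULL), `standard_id`, `options`, `call`.
#' @examples
#' fit <- aq_evaluate(beijing_feb2014(), "GB3095-2012")
#' summary(fit)
#' @seealso [compare_standards()], [case_study()], [predict.aq_eval()]
#' @export
aq_evaluate <- function(x, standard = "GB3095-2012", indicators = NULL,
                        exclude = character(0), averaging_time = "24h",
                        pool = c("joint", "observations"),
                        weighting = c("none", "entropy"),
                        k_convention = "objects",
                        tie = c("worst", "best")) {
  pool <- match.arg(pool)
  weighting <- match.arg(weighting)
  tie <- match.arg(tie)
  if (is.character(standard)) standard <- aq_standard(standard)
  m <- as_observation_matrix(x)
  if (nrow(m) < 1L) stop("empty observation set")
  if (is.null(indicators)) {
    avail <- unique(standard$thresholds$code[
      standard$thresholds$averaging_time == averaging_time])
    indicators <- intersect(intersect(aq_indicators()$code, colnames(m)), avail)
  }
  centers <- build_centers(standard, indicators, averaging_time)
  retained <- setdiff(colnames(centers), exclude)
  if (!length(retained)) stop("no indicators left after exclusions")
  cen <- centers[, retained, drop = FALSE]
  attr(cen, "units") <- attr(centers, "units")[retained]

  jn <- joint_normalize(m[, retained, drop = FALSE], cen,
                        pool = pool, units = attr(x, "units"))
  weights <- NULL
  if (weighting == "entropy") {
    w <- aq_entropy_weights(m[, retained, drop = FALSE],
                            k_convention = k_convention)
    weights <- w$weights
  }
  cls <- classify_nearest(jn$observations, jn$centers, weights, tie)
  dates <- rownames(m)
  if (is.null(dates)) dates <- as.character(seq_len(nrow(m)))
  structure(list(
    distances = cls$distances,
    level = factor(standard$levels[cls$level], levels = standard$levels),
    dates = dates,
    retained = retained,
    dropped = attr(centers, "dropped"),
    excluded = exclude,
    centers = cen,
    pool_min = jn$min, pool_max = jn$max,
    weights = weights,
    standard_id = standard$id,
    standard_levels = standard$levels,
    options = list(pool = pool, weighting = weighting,
                   k_convention = k_convention, tie = tie,
                   averaging_time = averaging_time),
    call = match.call()
  ), class = "aq_eval")
}

#' @export
print.aq_eval <- function(x, ...) {
  cat("Air quality evaluation against", x$standard_id, "\n")
  cat(length(x$dates), "days;", length(x$retained), "indicators (",
      paste(x$retained, collapse = ", "), ")\n")
  if (length(x$dropped))
    cat("Dropped (identical thresholds):",
        paste(x$dropped, collapse = ", "), "\n")
  if (length(x$excluded))
    cat("Excluded by configuration:", paste(x$excluded, collapse = ", "), "\n")
  cat("Levels: ")
  print(table(x$level))
  invisible(x)
}

#' @export
summary.aq_eval <- function(object, ...) {
  df <- as.data.frame(object)
  runs <- rle(as.character(object$level))
  worst <- object$standard_levels[length(object$standard_levels)]
  ends <- cumsum(runs$lengths)
  episodes <- data.frame(
    start = object$dates[ends - runs$lengths + 1],
    end = object$dates[ends],
    level = runs$values, days = runs$lengths
  )[runs$values == worst & runs$lengths >= 2, ]
  out <- list(table = df, counts = table(object$level),
              episodes = episodes, standard_id = object$standard_id,
              options = object$options, retained = object$retained)
  class(out) <- "summary.aq_eval"
  out
}

#' @export
print.summary.aq_eval <- function(x, ...) {
  cat("Evaluation against", x$standard_id, "|",
      paste(x$retained, collapse = "+"),
      "| pool:", x$options$pool, "| weighting:", x$options$weighting, "\n\n")
  tab <- x$table
  for (col in grep("^d[0-9]+$", names(tab))) tab[[col]] <- round(tab[[col]], 4)
  print(tab, row.names = FALSE)
  cat("\nLevel counts:\n")
  print(x$counts)
  if (nrow(x$episodes)) {
    cat("\nWorst-level episodes (>= 2 consecutive days):\n")
    print(x$episodes, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.aq_eval <- function(x, ...) {
  d <- as.data.frame(x$distances)
  names(d) <- paste0("d", seq_len(ncol(d)))
  rownames(d) <- NULL
  cbind(data.frame(date = x$dates, stringsAsFactors = FALSE), d,
        rank = as.character(x$level))
}

#' @export
coef.aq_eval <- function(object, ...) object$weights

#' Classify new days with a fitted evaluation
#'
#' Applies the fitted normalization (the stored per-indicator pool min and
#' max; new values falling outside are clipped) and the fitted distance
#' configuration to new daily observations.
#'
#' @param object an `"aq_eval"`.
#' @param newdata data.frame or matrix with the fitted indicator columns.
#' @param ... unused.
#' @return data.frame of dates, per-level distances and assigned rank.
#' @export
predict.aq_eval <- function(object, newdata, ...) {
  m <- as_observation_matrix(newdata)
  missing <- setdiff(object$retained, colnames(m))
  if (length(missing))
    stop("newdata lacks indicator(s): ", paste(missing, collapse = ", "))
  m <- m[, object$retained, drop = FALSE]
  rng <- rbind(object$pool_min, object$pool_max)
  r <- normalize_minmax(m, range = rng)
  rc <- normalize_minmax(object$centers, range = rng)
  cls <- classify_nearest(r, rc, object$weights, object$options$tie)
  d <- as.data.frame(cls$distances)
  names(d) <- paste0("d", seq_len(ncol(d)))
  dates <- rownames(m)
  if (is.null(dates)) dates <- as.character(seq_len(nrow(m)))
  cbind(data.frame(date = dates, stringsAsFactors = FALSE), d,
        rank = object$standard_levels[cls$level])
}

#' Plot per-day distances to each level center
#'
#' Lines show the distance from each day to every level center; the filled
#' points mark the assigned (minimum-distance) level.
#'
#' @param x an `"aq_eval"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.aq_eval <- function(x, ...) {
  D <- x$distances
  n <- nrow(D)
  graphics::matplot(seq_len(n), D, type = "l", lty = 1, lwd = 1.5,
                    col = seq_len(ncol(D)) + 1, xaxt = "n",
                    xlab = "day", ylab = "distance to level center",
                    main = paste("Nearest-level evaluation,", x$standard_id),
                    ...)
  idx <- cbind(seq_len(n), as.integer(x$level))
  graphics::points(seq_len(n), D[idx], pch = 19,
                   col = as.integer(x$level) + 1)
  at <- unique(round(seq(1, n, length.out = min(n, 10))))
  graphics::axis(1, at = at, labels = x$dates[at], las = 2, cex.axis = 0.8)
  graphics::legend("topleft", bty = "n", lty = 1, lwd = 1.5,
                   col = seq_len(ncol(D)) + 1,
                   legend = paste("Level", colnames(D)))
  invisible(x)
}

#' Compare evaluations under two standards
#'
#' Runs the evaluation under both standards (by default the new
#' GB 3095-2012 and the old GB 3095-1996) and tabulates per-day agreement.
#' With `config = "calibrated"` (the default) each standard uses the
#' configuration pinned by [calibrate_classification()] on the bundled
#' case study (see [case_study_config()]); `"default"` uses the library
#' defaults for both.
#'
#' @param x observations (see [aq_evaluate()]).
#' @param standards character vector of two standard ids.
#' @param config "calibrated" or "default".
#' @param ... further arguments passed to [aq_evaluate()] (used with
#'   `config = "default"`).
#' @return an `"aq_compare"` object: `results` (named list of two
#'   `"aq_eval"`) and `table` (per-day levels, concordance flag, and the
#'   direction of change under the first standard relative to the second).
#' @examples
#' cmp <- compare_standards(beijing_feb2014())
#' subset(cmp$table, !concordant)
#' @export
compare_standards <- function(x, standards = c("GB3095-2012", "GB3095-1996"),
                              config = c("calibrated", "default"), ...) {
  config <- match.arg(config)
  stopifnot(length(standards) == 2L)
  results <- lapply(standards, function(sid) {
    if (config == "calibrated") {
      cfg <- case_study_config(sid)
      aq_evaluate(x, sid, exclude = cfg$exclude, pool = cfg$pool,
                  weighting = cfg$weighting, tie = cfg$tie)
    } else {
      aq_evaluate(x, sid, ...)
    }
  })
  names(results) <- standards
  l1 <- as.integer(results[[1]]$level)
  l2 <- as.integer(results[[2]]$level)
  tab <- data.frame(
    date = results[[1]]$dates,
    level_1 = as.character(results[[1]]$level),
    level_2 = as.character(results[[2]]$level),
    concordant = l1 == l2,
    change = ifelse(l1 == l2, "same",
                    ifelse(l1 > l2, "worse_under_first", "better_under_first")),
    stringsAsFactors = FALSE
  )
  names(tab)[2:3] <- paste0("level_", standards)
  structure(list(results = results, table = tab, standards = standards,
                 config = config),
            class = "aq_compare")
}

#' @export
print.aq_compare <- function(x, ...) {
  cat("Standard comparison (", x$config, " configuration):",
      paste(x$standards, collapse = " vs "), "\n", sep = "")
  disc <- x$table[!x$table$concordant, ]
  cat(sum(x$table$concordant), "of", nrow(x$table), "days concordant\n")
  if (nrow(disc)) {
    cat("Discordant days:\n")
    print(disc, row.names = FALSE)
  }
  invisible(x)
}
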
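#' Read a daily observation table
#'
#' Reads a CSV with a `date` column and one column per pollutant, or one of
#' the built-in datasets (currently `"beijing_feb2014"`, the 28-day, five
#' pollutant Beijing February 2014 record used throughout the package's
#' case study). Dates are kept as the day labels printed in the source
#' ("MM-DD"; the year lives in the `year` attribute). Concentrations are in
#' ug/m3 except CO in mg/m3.
#'
#' Validation: required columns must be present, numeric cells must parse
#' (failures are reported with their row and column), concentrations must
#' be non-negative, dates must be unique. Columns not named in
#' `column_map` are ignored with a message.
#'
#' @param path file path or built-in dataset name.
#' @param column_map named character vector mapping file columns to
#'   indicator codes, e.g. `c(pm25 = "PM2.5")`; by default columns are used
#'   as named.
#' @param date_col name of the date column, default `"date"`.
#' @return data.frame (`date` + indicator columns) with attributes `units`
#'   and `source`.
#' @examples
#' obs <- read_observations("beijing_feb2014")
#' obs[obs$date == "02-15", ]
#' @export
read_observations <- function(path, column_map = NULL, date_col = "date") {
  src <- path
  if (identical(path, "beijing_feb2014")) {
    path <- system.file("extdata", "beijing_feb2014.csv", package = "aqeval")
    if (path == "") stop("bundled dataset not found; is aqeval installed?")
  } else if (!file.exists(path)) {
    stop("no such file or built-in dataset: '", path, "'")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", comment.char = "#")
  if (!date_col %in% names(raw))
    stop("missing date column '", date_col, "'")
  if (is.null(column_map)) {
    codes <- setdiff(names(raw), date_col)
    column_map <- stats::setNames(codes, codes)
  }
  missing <- setdiff(names(column_map), names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(raw), c(date_col, names(column_map)))
  if (length(extra))
    message("ignoring unmapped column(s): ", paste(extra, collapse = ", "))

  dates <- raw[[date_col]]
  if (anyDuplicated(dates))
    stop("duplicate date(s): ",
         paste(unique(dates[duplicated(dates)]), collapse = ", "))
  if (any(!nzchar(dates)) || anyNA(dates))
    stop("unparseable/empty date labels")

  out <- data.frame(date = dates, stringsAsFactors = FALSE)
  for (col in names(column_map)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad))
      stop("malformed numeric value in column '", col, "', row(s) ",
           paste(bad, collapse = ", "))
    neg <- which(v < 0)
    if (length(neg))
      stop("negative concentration in column '", col, "', row(s) ",
           paste(neg, collapse = ", "), " (e.g. ", v[neg[1]], ")")
    out[[column_map[[col]]]] <- v
  }
  known <- aq_indicators()
  units <- stats::setNames(
    ifelse(names(out)[-1] %in% known$code,
           known$unit[match(names(out)[-1], known$code)], NA_character_),
    names(out)[-1])
  structure(out, units = units, source = src,
            year = if (identical(src, "beijing_feb2014")) 2014L else NA_integer_)
}

#' The bundled Beijing February 2014 dataset
#'
#' 28 days by 5 pollutants (PM2.5, PM10, CO, NO2, SO2), 24-hour averages.
#' @return data.frame as from [read_observations()].
#' @export
beijing_feb2014 <- function() read_observations("beijing_feb2014")

#' Coerce to a plain observation matrix
#'
#' Accepts a numeric matrix (returned as-is), or a data.frame whose `date`
#' column (if any) becomes the rownames.
#' @param x matrix or data.frame.
#' @return numeric matrix, rows = days, columns = indicators.
#' @export
as_observation_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x))
  dates <- NULL
  if ("date" %in% names(x)) {
    dates <- x$date
    x <- x[setdiff(names(x), "date")]
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (!is.null(dates)) rownames(m) <- dates
  m
}

#' Write / read an evaluation result table
#'
#' Writes a CSV mirroring the published result tables: `date`, one distance
#' column per level (`d1`, `d2`, ...) printed to 4 decimals, and the
#' assigned `rank`. Commented header lines record the standard, retained
#' and dropped indicators, normalization pool, weighting mode and tie rule,
#' so a result file is self-describing.
#'
#' @param result an `"aq_eval"` object from [aq_evaluate()].
#' @param path output file.
#' @return `write_results` returns `path` invisibly; `read_results` returns
#'   a data.frame of dates, distances and ranks.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "aq_eval"))
  meta <- c(
    paste("# standard:", result$standard_id),
    paste("# retained:", paste(result$retained, collapse = ",")),
    paste("# dropped:", paste(result$dropped, collapse = ",")),
    paste("# pool:", result$options$pool),
    paste("# weighting:", result$options$weighting),
    paste("# tie_rule:", result$options$tie)
  )
  df <- as.data.frame(result)
  dcols <- grep("^d[0-9]+$", names(df), value = TRUE)
  for (col in dcols) df[[col]] <- sprintf("%.4f", df[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character") -> df
  for (col in grep("^d[0-9]+$", names(df), value = TRUE))
    df[[col]] <- as.numeric(df[[col]])
  df
}
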
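#' Default pollutant indicator set
#'
#' The five pollutants of the Beijing case study, all 24-hour averages and
#' all cost-oriented (higher concentration means worse air). CO is measured
#' in mg/m3, the others in ug/m3; units are carried through to evaluation
#' time and never converted.
#'
#' @param codes optional character vector restricting the returned set.
#' @return data.frame with columns `code`, `unit`, `averaging_time`,
#'   `orientation`.
#' @export
aq_indicators <- function(codes = NULL) {
  spec <- data.frame(
    code = c("PM2.5", "PM10", "CO", "NO2", "SO2"),
    unit = c("ug/m3", "ug/m3", "mg/m3", "ug/m3", "ug/m3"),
    averaging_time = "24h",
    orientation = "cost",
    stringsAsFactors = FALSE
  )
  if (is.null(codes)) return(spec)
  missing <- setdiff(codes, spec$code)
  if (length(missing))
    stop("unknown indicator code(s): ", paste(missing, collapse = ", "))
  spec[match(codes, spec$code), , drop = FALSE]
}

# Built-in threshold tables. Values are stored long: one row per
# (indicator, averaging time, level). O3 is included for completeness even
# though the bundled dataset has no O3 column.
.aq_builtin_standards <- function() {
  long <- function(code, time, unit, values) {
    data.frame(code = code, averaging_time = time, unit = unit,
               level = seq_along(values), value = values,
               stringsAsFactors = FALSE)
  }
  gb1996 <- rbind(
    long("SO2",  "annual_mean", "ug/m3", c(20, 60, 100)),
    long("SO2",  "24h",         "ug/m3", c(50, 150, 250)),
    long("SO2",  "1h",          "ug/m3", c(150, 500, 700)),
    long("NO2",  "annual_mean", "ug/m3", c(40, 40, 80)),
    long("NO2",  "24h",         "ug/m3", c(80, 80, 120)),
    long("NO2",  "1h",          "ug/m3", c(120, 120, 240)),
    long("CO",   "24h",         "mg/m3", c(4, 4, 6)),
    long("CO",   "1h",          "mg/m3", c(10, 10, 20)),
    long("O3",   "1h",          "ug/m3", c(120, 160, 200)),
    long("PM10", "annual_mean", "ug/m3", c(40, 100, 150)),
    long("PM10", "24h",         "ug/m3", c(50, 150, 250))
  )
  gb2012 <- rbind(
    long("SO2",   "annual_mean", "ug/m3", c(20, 60)),
    long("SO2",   "24h",         "ug/m3", c(50, 150)),
    long("SO2",   "1h",          "ug/m3", c(150, 500)),
    long("NO2",   "annual_mean", "ug/m3", c(40, 40)),
    long("NO2",   "24h",         "ug/m3", c(80, 80)),
    long("NO2",   "1h",          "ug/m3", c(200, 200)),
    long("CO",    "24h",         "mg/m3", c(4, 4)),
    long("CO",    "1h",          "mg/m3", c(10, 10)),
    long("O3",    "8h",          "ug/m3", c(100, 160)),
    long("O3",    "1h",          "ug/m3", c(160, 200)),
    long("PM10",  "annual_mean", "ug/m3", c(40, 70)),
    long("PM10",  "24h",         "ug/m3", c(50, 150)),
    long("PM2.5", "annual_mean", "ug/m3", c(15, 35)),
    long("PM2.5", "24h",         "ug/m3", c(35, 75))
  )
  list(
    "GB3095-1996" = new_aq_standard("GB3095-1996", c("I", "II", "III"), gb1996),
    "GB3095-2012" = new_aq_standard("GB3095-2012", c("I", "II"), gb2012)
  )
}

new_aq_standard <- function(id, levels, thresholds) {
  std <- structure(
    list(id = id, levels = levels, thresholds = thresholds),
    class = "aq_standard"
  )
  validate_standard(std)
}

validate_standard <- function(std) {
  stopifnot(is.character(std$id), length(std$id) == 1L,
            is.character(std$levels), length(std$levels) >= 1L)
  th <- std$thresholds
  need <- c("code", "averaging_time", "unit", "level", "value")
  if (!all(need %in% names(th)))
    stop("malformed standard config: thresholds need columns ",
         paste(need, collapse = ", "))
  nl <- length(std$levels)
  for (key in unique(paste(th$code, th$averaging_time))) {
    rows <- th[paste(th$code, th$averaging_time) == key, ]
    rows <- rows[order(rows$level), ]
    if (!identical(rows$level, seq_len(nl)))
      stop("standard '", std$id, "': indicator ", key,
           " does not cover every level exactly once")
    # every indicator here is cost-oriented: thresholds may not decrease
    if (is.unsorted(rows$value))
      stop("standard '", std$id, "': non-monotone thresholds for ", key)
    if (length(unique(rows$unit)) != 1L)
      stop("standard '", std$id, "': inconsistent units for ", key)
  }
  std
}

#' Registered standard identifiers
#' @return character vector of built-in standard ids.
#' @export
standard_ids <- function() names(.aq_builtin_standards())

#' Load a regulatory standard's threshold table
#'
#' @param id one of [standard_ids()] (built-in), or a path to a YAML config
#'   written by [write_standard()].
#' @return an `"aq_standard"` object: `id`, ordered `levels`, and a long
#'   `thresholds` data.frame (code, averaging_time, unit, level, value).
#' @examples
#' std <- aq_standard("GB3095-2012")
#' subset(std$thresholds, code == "PM2.5" & averaging_time == "24h")
#' @export
aq_standard <- function(id) {
  builtin <- .aq_builtin_standards()
  if (id %in% names(builtin)) return(builtin[[id]])
  if (file.exists(id)) return(read_standard(id))
  stop("unknown standard id: '", id, "' (built-in: ",
       paste(names(builtin), collapse = ", "), ")")
}

#' @export
print.aq_standard <- function(x, ...) {
  cat("Ambient air quality standard:", x$id, "\n")
  cat("Levels:", paste(x$levels, collapse = " < "), "\n")
  cat("Thresholds for", length(unique(x$thresholds$code)), "indicators at",
      length(unique(x$thresholds$averaging_time)), "averaging times\n")
  invisible(x)
}

#' Write / read a standard as a YAML config
#'
#' The config mirrors the printed threshold tables: `standard_id`, ordered
#' `levels`, then one block per (indicator, averaging time) with its unit
#' and per-level values. `read_standard(write_standard(std, f))` returns an
#' identical table.
#'
#' @param std an `"aq_standard"` object.
#' @param path file path.
#' @return `write_standard` returns `path` invisibly; `read_standard`
#'   returns an `"aq_standard"`.
#' @export
write_standard <- function(std, path) {
  stopifnot(inherits(std, "aq_standard"))
  th <- std$thresholds
  blocks <- lapply(split(th, paste(th$code, th$averaging_time, sep = "@")),
                   function(rows) {
    rows <- rows[order(rows$level), ]
    list(indicator = rows$code[1], averaging_time = rows$averaging_time[1],
         unit = rows$unit[1], values = rows$value)
  })
  names(blocks) <- NULL
  yaml::write_yaml(list(standard_id = std$id, levels = as.list(std$levels),
                        thresholds = blocks), path)
  invisible(path)
}

#' @rdname write_standard
#' @export
read_standard <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$standard_id) || is.null(cfg$levels) || is.null(cfg$thresholds))
    stop("malformed standard config: need standard_id, levels, thresholds")
  th <- do.call(rbind, lapply(cfg$thresholds, function(b) {
    if (length(b$values) != length(cfg$levels))
      stop("malformed standard config: ", b$indicator, " has ",
           length(b$values), " values for ", length(cfg$levels), " levels")
    data.frame(code = b$indicator, averaging_time = b$averaging_time,
               unit = b$unit, level = seq_along(b$values),
               value = as.numeric(b$values), stringsAsFactors = FALSE)
  }))
  new_aq_standard(cfg$standard_id, unlist(cfg$levels), th)
}

#' Build per-level clustering centers from a standard
#'
#' Extracts, for each requested indicator at the requested averaging time,
#' the per-level threshold concentrations, giving one center vector per
#' level. An indicator whose thresholds are identical across *all* levels of
#' the standard cannot discriminate between levels and is dropped (its code
#' is recorded in the `dropped` attribute). Under GB 3095-2012 this removes
#' CO and NO2, whose Level I and Level II thresholds coincide; under
#' GB 3095-1996 all five case-study indicators are retained because their
#' Level III thresholds differ.
#'
#' @param standard an `"aq_standard"` or a standard id.
#' @param indicators character vector of indicator codes (default: the
#'   intersection of [aq_indicators()] with the standard at that time).
#' @param averaging_time averaging time of the thresholds, default "24h".
#' @return an `"aq_centers"` matrix (levels x retained indicators of raw
#'   threshold concentrations) with attributes `dropped`, `units`,
#'   `standard_id`, `averaging_time`.
#' @examples
#' build_centers(aq_standard("GB3095-2012"),
#'               c("PM2.5", "PM10", "CO", "NO2", "SO2"))
#' @export
build_centers <- function(standard, indicators = NULL, averaging_time = "24h") {
  if (is.character(standard)) standard <- aq_standard(standard)
  stopifnot(inherits(standard, "aq_standard"))
  th <- standard$thresholds
  th <- th[th$averaging_time == averaging_time, ]
  if (is.null(indicators))
    indicators <- intersect(aq_indicators()$code, unique(th$code))
  missing <- setdiff(indicators, unique(th$code))
  if (length(missing))
    stop("indicator(s) without ", averaging_time, " thresholds in ",
         standard$id, ": ", paste(missing, collapse = ", "))
  nl <- length(standard$levels)
  mat <- sapply(indicators, function(code) {
    rows <- th[th$code == code, ]
    rows$value[order(rows$level)]
  })
  mat <- matrix(mat, nrow = nl, dimnames = list(standard$levels, indicators))
  degenerate <- apply(mat, 2, function(v) length(unique(v)) == 1L)
  dropped <- colnames(mat)[degenerate]
  mat <- mat[, !degenerate, drop = FALSE]
  if (ncol(mat) == 0L)
    stop("degenerate problem: every requested indicator has identical ",
         "thresholds across all levels of ", standard$id)
  units <- vapply(colnames(mat), function(code)
    th$unit[th$code == code][1], character(1))
  structure(mat, class = c("aq_centers", "matrix"),
            dropped = dropped, units = units,
            standard_id = standard$id, averaging_time = averaging_time)
}

#' @export
print.aq_centers <- function(x, ...) {
  cat("Clustering centers from", attr(x, "standard_id"),
      "(", attr(x, "averaging_time"), "thresholds )\n")
  m <- x
  attributes(m) <- list(dim = dim(x), dimnames = dimnames(x))
  print(m)
  if (length(attr(x, "dropped")))
    cat("Dropped (identical across levels):",
        paste(attr(x, "dropped"), collapse = ", "), "\n")
  invisible(x)
}
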
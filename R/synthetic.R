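#' Synthetic haze-episode scenario
#'
#' Describes a synthetic month of daily pollutant concentrations with the
#' structure of a real haze winter: correlated log-normal baselines for
#' every pollutant, driven by a shared latent "haze factor" (stagnant
#' weather loads all pollutants together), with one or more episode
#' windows whose concentrations are multiplied by an amplitude.
#'
#' Defaults emulate the bundled February record: 28 days, two episode
#' windows (days 11-16 and 20-26) of amplitude 4, baseline medians near
#' the calm-day levels of that month, log-scale dispersion 0.5 and a
#' cross-pollutant correlation of 0.7.
#'
#' @param n_days number of days, >= 2.
#' @param baseline named vector of baseline median concentrations
#'   (ug/m3, CO mg/m3).
#' @param sdlog log-scale standard deviation of daily variation.
#' @param episodes list of `list(start, length, amplitude)` windows;
#'   amplitude 1 is a null episode.
#' @param correlation share of log-variance carried by the shared haze
#'   factor, in \[0, 1\].
#' @param seed integer seed stored with the scenario; the same scenario
#'   always generates the same data.
#' @return an `"aq_scenario"` object.
#' @export
aq_scenario <- function(n_days = 28,
                        baseline = c(PM2.5 = 45, PM10 = 65, CO = 1.1,
                                     NO2 = 40, SO2 = 30),
                        sdlog = 0.5,
                        episodes = list(list(start = 11, length = 6,
                                             amplitude = 4),
                                        list(start = 20, length = 7,
                                             amplitude = 4)),
                        correlation = 0.7, seed = 1L) {
  stopifnot(n_days >= 2, all(baseline > 0), sdlog >= 0,
            correlation >= 0, correlation <= 1)
  for (ep in episodes) {
    stopifnot(ep$start >= 1, ep$length >= 1, ep$amplitude > 0)
    if (ep$start + ep$length - 1 > n_days)
      stop("episode runs past day ", n_days)
  }
  structure(list(n_days = as.integer(n_days), baseline = baseline,
                 sdlog = sdlog, episodes = episodes,
                 correlation = correlation, seed = as.integer(seed)),
            class = "aq_scenario")
}

#' @export
print.aq_scenario <- function(x, ...) {
  cat("Synthetic pollution scenario:", x$n_days, "days,",
      length(x$episodes), "episode(s), seed", x$seed, "\n")
  for (ep in x$episodes)
    cat("  days ", ep$start, "-", ep$start + ep$length - 1,
        " x", ep$amplitude, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic observation table
#'
#' Draws the daily concentrations a scenario describes. Day `i`,
#' pollutant `j`:
#' `x_ij = baseline_j * A_i * exp(sdlog * (sqrt(rho) z_i + sqrt(1-rho) u_ij))`
#' with `z_i` the shared haze factor, `u_ij` independent noise and `A_i`
#' the product of amplitudes of episodes covering day `i`; values are
#' truncated at zero. Output has the same shape as
#' [read_observations()]'s and feeds every other stage of the package.
#'
#' @param scenario an `"aq_scenario"`.
#' @param seed optional override of the scenario seed.
#' @return data.frame with `date` (day labels "d01", "d02", ...) and one
#'   column per pollutant, with an `episode` attribute flagging episode
#'   days.
#' @examples
#' obs <- aq_simulate(aq_scenario(seed = 42))
#' aq_evaluate(obs, "GB3095-2012")
#' @export
aq_simulate <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "aq_scenario"))
  if (is.null(seed)) seed <- scenario$seed
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(seed)
  n <- scenario$n_days
  p <- length(scenario$baseline)
  rho <- scenario$correlation
  amp <- rep(1, n)
  in_episode <- rep(FALSE, n)
  for (ep in scenario$episodes) {
    idx <- ep$start:(ep$start + ep$length - 1)
    amp[idx] <- amp[idx] * ep$amplitude
    if (ep$amplitude != 1) in_episode[idx] <- TRUE
  }
  z <- stats::rnorm(n)
  u <- matrix(stats::rnorm(n * p), n, p)
  lognoise <- scenario$sdlog * (sqrt(rho) * z + sqrt(1 - rho) * u)
  x <- sweep(exp(lognoise), 2, scenario$baseline, "*") * amp
  x <- pmax(x, 0)
  colnames(x) <- names(scenario$baseline)
  out <- data.frame(date = sprintf("d%02d", seq_len(n)), round(x, 2),
                    check.names = FALSE, stringsAsFactors = FALSE)
  units <- stats::setNames(
    aq_indicators()$unit[match(names(scenario$baseline),
                               aq_indicators()$code)],
    names(scenario$baseline))
  structure(out, episode = in_episode, units = units,
            source = "aq_simulate")
}
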
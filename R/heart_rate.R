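#' Age-predicted maximum heart rate
#'
#' `HRmax = 205.8 - 0.685 * age`, a population regression with a sizable
#' individual margin of error; treat it as approximate.
#'
#' @param age Age in years, in \[10, 100\].
#' @return Predicted maximum heart rate in bpm.
#' @examples
#' hr_max(30) # 185.25
#' @export
hr_max <- function(age) {
  if (any(age < 10 | age > 100)) input_error("age must be in [10, 100] years")
  205.8 - 0.685 * age
}

# Zone lower edges as fractions of HRmax. The published scale leaves 60-70%
# unassigned (zone 1 ends at 60%, zone 2 starts at 70%); zone 1 is extended
# to [50%, 70%) here so the scale partitions the axis, and reports flag the
# extension.
ZONE_EDGES <- c(below = 0, Z1 = 0.50, Z2 = 0.70, Z3 = 0.80, Z4 = 0.90)

#' Classify a heart rate into a training zone
#'
#' Zones as fractions of maximum heart rate: Z1 "light" \[50%, 70%) (extended
#' downward over the scale's unassigned 60-70% band), Z2 "moderate"
#' \[70%, 80%), Z3 "hard" \[80%, 90%), Z4 "maximum" \[90%, Inf); anything
#' under 50% is "below".
#'
#' @param bpm Heart rate in bpm (vectorized).
#' @param hr_max Maximum heart rate in bpm.
#' @return Character vector of zone labels
#'   (`"below"`, `"Z1"`, `"Z2"`, `"Z3"`, `"Z4"`).
#' @export
zone_of <- function(bpm, hr_max) {
  if (hr_max <= 0) input_error("hr_max must be > 0")
  ratio <- bpm / hr_max
  names(ZONE_EDGES)[findInterval(ratio, ZONE_EDGES)]
}

#' Time-weighted fractions of a ride spent in each training zone
#'
#' Each inter-sample interval is attributed to the zone of its left sample;
#' fractions are interval durations over total duration.
#'
#' @param series Data frame with columns `time_s` (non-decreasing) and `bpm`.
#' @param hr_max Maximum heart rate in bpm.
#' @return An `ebt_zone_report`: list with `hr_max`, `fractions` (named
#'   below/Z1..Z4, summing to 1) and `total_s`.
#' @export
time_in_zones <- function(series, hr_max) {
  if (!all(c("time_s", "bpm") %in% names(series))) {
    input_error("HR series needs columns time_s and bpm")
  }
  if (nrow(series) < 2) input_error("HR series needs at least 2 samples")
  dt <- diff(series$time_s)
  if (any(dt < 0)) input_error("HR sample times must be non-decreasing")
  if (any(series$bpm <= 25 | series$bpm >= 250)) {
    input_error("bpm outside physiological range (25, 250)")
  }
  zones <- zone_of(series$bpm[-nrow(series)], hr_max)
  total <- sum(dt)
  if (total <= 0) input_error("HR series has zero duration")
  frac <- vapply(names(ZONE_EDGES), function(z) sum(dt[zones == z]) / total,
                 numeric(1))
  structure(list(hr_max = hr_max, fractions = frac, total_s = total,
                 note = "Z1 extended to [50%, 70%) of HRmax"),
            class = "ebt_zone_report")
}

#' @export
print.ebt_zone_report <- function(x, ...) {
  cat(sprintf("<ebt_zone_report> HRmax %.1f bpm, %.0f s\n", x$hr_max, x$total_s))
  for (z in names(x$fractions)) {
    cat(sprintf("  %-5s %5.1f%%\n", z, 100 * x$fractions[[z]]))
  }
  invisible(x)
}

#' Heart-rate safety override
#'
#' When the heart rate exceeds the safety threshold the assist level is
#' raised one step (capped at the bike's top level) so the motor takes over
#' more of the work; further increases are held off for a hysteresis window.
#' The level is never decreased.
#'
#' @param bpm Current heart rate.
#' @param threshold Safety threshold in bpm (e.g. 0.9 * [hr_max()]).
#' @param current_level Current assist level index (0 = off).
#' @param bike An `ebt_bike` (supplies the top level).
#' @param time_s Current ride time in seconds (default 0).
#' @param last_increase_s Time of the previous override increase (`-Inf` when
#'   none yet).
#' @param hysteresis_s Minimum spacing between increases (default 30 s).
#' @return A list with `level` (possibly raised) and `last_increase_s`
#'   (updated when a raise happened).
#' @export
safety_override <- function(bpm, threshold, current_level, bike,
                            time_s = 0, last_increase_s = -Inf,
                            hysteresis_s = 30) {
  if (threshold <= 0) input_error("threshold must be > 0")
  top <- length(bike$level_powers)
  if (bpm > threshold && current_level < top &&
      time_s - last_increase_s >= hysteresis_s) {
    return(list(level = current_level + 1L, last_increase_s = time_s))
  }
  list(level = as.integer(current_level), last_increase_s = last_increase_s)
}

#' Read a heart-rate series from CSV
#'
#' Expects header `time_s,bpm`.
#'
#' @param path CSV file path.
#' @return Data frame with `time_s`, `bpm`.
#' @export
read_hr_csv <- function(path) {
  if (!file.exists(path)) input_error(sprintf("HR file not found: %s", path))
  df <- utils::read.csv(path)
  if (!all(c("time_s", "bpm") %in% names(df))) {
    input_error("HR CSV must have header time_s,bpm")
  }
  df
}
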
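#' Rider-supplied energy over a completed ride
#'
#' At each telemetry sample the power the ride actually demanded is evaluated
#' from the power model at the sampled speed and the grade of the plan
#' segment covering the sampled position; the rider's share is what the motor
#' did not supply, floored at zero (coasting never earns negative credit).
#' Left-rectangle integration over the sample grid.
#'
#' @param telemetry Data frame with columns `time_s`, `dist_m`, `speed_ms`,
#'   `motor_w` (see [simulate_ride()] / [read_telemetry_csv()]).
#' @param plan The `ebt_plan` the ride followed (supplies segment grades and
#'   the power model).
#' @return Rider energy in Wh.
#' @export
rider_energy <- function(telemetry, plan) {
  stopifnot(inherits(plan, "ebt_plan"))
  need <- c("time_s", "dist_m", "speed_ms", "motor_w")
  miss <- setdiff(need, names(telemetry))
  if (length(miss) > 0) {
    input_error(sprintf("telemetry is missing channel(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(telemetry) < 2) input_error("telemetry needs at least 2 samples")
  seg <- plan$segments
  idx <- findInterval(telemetry$dist_m, seg$start_m, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(seg))
  req <- required_power(telemetry$speed_ms, seg$grade[idx], plan$params)
  rider_w <- pmax(req - telemetry$motor_w, 0)
  dt <- diff(telemetry$time_s)
  sum(rider_w[-length(rider_w)] * dt) / 3600
}

#' Score a completed route from the rider's energy
#'
#' The score equals the rider-supplied energy in Wh, capped at 600 — roughly
#' the energy needed to hold 50 km/h on the flat for an hour, taken as the
#' human ceiling.
#'
#' @param rider_energy_wh Rider energy in Wh (>= 0).
#' @return Score in points.
#' @examples
#' score_route(30)  # 30
#' score_route(900) # 600
#' @export
score_route <- function(rider_energy_wh) {
  if (any(is.na(rider_energy_wh)) || any(rider_energy_wh < 0)) {
    input_error("rider energy must be >= 0")
  }
  pmin(rider_energy_wh, 600)
}

#' Accrue a route score onto a rider profile
#'
#' Adds the score to the rider's cumulative points and re-derives the
#' ability level from the ladder.
#'
#' @param profile An `ebt_rider`.
#' @param score Points earned on the route (>= 0).
#' @param ability Ability ladder (default [ability_table()]).
#' @return The updated `ebt_rider`, with attribute `"level"` set to the new
#'   ability level.
#' @export
accrue <- function(profile, score, ability = ability_table()) {
  stopifnot(inherits(profile, "ebt_rider"))
  if (score < 0) input_error("score must be >= 0")
  profile$total_points <- profile$total_points + score
  attr(profile, "level") <- ability_for_points(profile$total_points, ability)$level
  profile
}

#' Full score report for a ride
#'
#' Convenience wrapper: integrates rider and motor energy from telemetry,
#' applies the capped score, and accrues it onto the rider profile.
#'
#' @inheritParams rider_energy
#' @param rider An `ebt_rider` (default: the plan's rider).
#' @param ability Ability ladder.
#' @return A list of class `ebt_score`: `rider_energy_wh`, `motor_energy_wh`,
#'   `total_energy_wh`, `score`, `new_total_points`, `new_level`.
#' @export
score_ride <- function(telemetry, plan, rider = plan$rider,
                       ability = ability_table()) {
  e_rider <- rider_energy(telemetry, plan)
  dt <- diff(telemetry$time_s)
  e_motor <- sum(telemetry$motor_w[-nrow(telemetry)] * dt) / 3600
  sc <- score_route(e_rider)
  new_rider <- accrue(rider, sc, ability)
  structure(list(rider_energy_wh = e_rider, motor_energy_wh = e_motor,
                 total_energy_wh = e_rider + e_motor, score = sc,
                 new_total_points = new_rider$total_points,
                 new_level = attr(new_rider, "level")),
            class = "ebt_score")
}

#' @export
print.ebt_score <- function(x, ...) {
  cat(sprintf(
    "<ebt_score> rider %.1f Wh + motor %.1f Wh = %.1f Wh -> %.1f points (total %.1f, level %d)\n",
    x$rider_energy_wh, x$motor_energy_wh, x$total_energy_wh, x$score,
    x$new_total_points, x$new_level))
  invisible(x)
}
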
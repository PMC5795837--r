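#' Bike profile: mass and motor assist ladder
#'
#' PAS e-bikes expose an ordered set of assist levels, each delivering a
#' fixed motor power; the per-level powers are readable from the battery
#' current telemetry, so they are an input here rather than a model. The
#' default profile is a 750 W motor with six linearly spaced levels
#' (125, 250, ..., 750 W). Assistance above the legal speed cutoff
#' (25 km/h in most of the EU) is disabled by the planner.
#'
#' @param bike_mass Bike mass in kg.
#' @param level_powers Strictly increasing motor powers in W, one per assist
#'   level (level 0 = assistance off is implicit).
#' @param motor_max Motor's maximum power in W (default: last level power).
#' @param legal_speed_cutoff Speed above which the motor must not assist,
#'   km/h (default 25).
#' @return An object of class `ebt_bike`.
#' @export
bike_profile <- function(bike_mass = 8,
                         level_powers = seq(125, 750, by = 125),
                         motor_max = max(level_powers),
                         legal_speed_cutoff = 25) {
  level_powers <- as.numeric(level_powers)
  if (any(diff(level_powers) <= 0) || any(level_powers <= 0)) {
    input_error("level_powers must be positive and strictly increasing")
  }
  if (any(level_powers > motor_max)) input_error("level powers cannot exceed motor_max")
  structure(list(bike_mass = bike_mass, level_powers = level_powers,
                 motor_max = motor_max, legal_speed_cutoff = legal_speed_cutoff),
            class = "ebt_bike")
}

#' Rider profile
#'
#' @param mass Rider mass in kg.
#' @param height Rider height in m.
#' @param age Age in years.
#' @param total_points Cumulative score from completed routes (default 0).
#' @param hr_threshold Optional manual heart-rate safety threshold in bpm;
#'   when `NULL` the default 90% of the age-predicted maximum is used.
#' @return An object of class `ebt_rider`.
#' @export
rider_profile <- function(mass, height, age, total_points = 0,
                          hr_threshold = NULL) {
  if (total_points < 0) input_error("total_points must be >= 0")
  if (mass < 35 || mass > 150) input_error("rider mass must be in [35, 150] kg")
  if (height < 1.2 || height > 2.2) input_error("height must be in [1.2, 2.2] m")
  if (age < 10 || age > 100) input_error("age must be in [10, 100] years")
  structure(list(mass = mass, height = height, age = age,
                 total_points = total_points, hr_threshold = hr_threshold),
            class = "ebt_rider")
}

#' Look up ability level, target speed and rider power for a points total
#'
#' @param total_points Cumulative points (>= 0); totals beyond the ladder
#'   clamp to the top level.
#' @param ability Ability ladder (default [ability_table()]).
#' @return A list with `level`, `target_speed_kmh`, `flat_power_w`.
#' @export
ability_for_points <- function(total_points, ability = ability_table()) {
  if (is.na(total_points) || total_points < 0) input_error("total_points must be >= 0")
  row <- which(total_points >= ability$points_lo & total_points <= ability$points_hi)
  if (length(row) == 0) row <- nrow(ability)  # beyond the ladder: top level
  row <- row[1]
  list(level = ability$level[row],
       target_speed_kmh = ability$speed_kmh[row],
       flat_power_w = ability$flat_power_w[row])
}

#' Quantize a motor power onto the assist-level ladder
#'
#' Midpoint intervals: level `j` is chosen when the requested power lies in
#' `[(p_{j-1} + p_j)/2, (p_j + p_{j+1})/2)`, with `[0, p_1/2)` mapping to
#' level 0 (off) and anything at or above the top midpoint mapping to the top
#' level. Intervals are left-closed, so a power exactly on a midpoint rounds
#' up. Non-positive power is level 0. Equivalent to nearest-level-power
#' assignment with ties to the higher level.
#'
#' @param motor_power Requested motor power in W (vectorized).
#' @param bike An `ebt_bike`.
#' @return Integer assist level(s), 0 = off.
#' @export
quantize_to_level <- function(motor_power, bike) {
  stopifnot(inherits(bike, "ebt_bike"))
  p <- bike$level_powers
  mids <- (c(0, utils::head(p, -1L)) + p) / 2  # p1/2, (p1+p2)/2, ...
  vapply(motor_power, function(w) {
    if (w <= 0) return(0L)
    sum(w >= mids)
  }, integer(1))
}

#' Build a per-segment assist plan
#'
#' For each segment the target speed `v'` and constant rider power `p` come
#' from the rider's ability level. The power to hold `v'` on the segment's
#' grade is computed from the power model; the shortfall `p_i - p` is the
#' requested motor power, quantized onto the bike's assist ladder. Special
#' cases, each flagged:
#' \describe{
#'   \item{`coast`}{`p_i <= 0` (descent): rider 0, motor 0, level 0.}
#'   \item{`reduced`}{`0 < p_i < p`: the rider eases off to `p_i`, motor 0.}
#'   \item{`sag`}{`p_i > p + motor_max`: full assist is not enough; the plan
#'     records the achievable speed at `p + motor_max` instead of `v'`.}
#'   \item{`cutoff`}{planned speed exceeds the legal assistance cutoff:
#'     motor forced to 0, level 0.}
#' }
#'
#' @param segments An `ebt_segments` data frame (see [segment_route()]).
#' @param rider An `ebt_rider`.
#' @param bike An `ebt_bike`.
#' @param params An `ebt_power_params` (default: ladder-calibrated).
#' @param ability Ability ladder (default [ability_table()]).
#' @param route Optional `ebt_route` the segments came from; supplies
#'   waypoint coordinates for each segment start.
#' @return An object of class `ebt_plan`: list with `segments` (a data frame
#'   with speeds, powers, level, flag per segment), `totals` (durations and
#'   energies), and the `rider`, `bike`, `params`, `ability` used.
#' @export
plan_assist <- function(segments, rider, bike,
                        params = default_calibrated_params(ability),
                        ability = ability_table(), route = NULL) {
  stopifnot(inherits(rider, "ebt_rider"), inherits(bike, "ebt_bike"),
            inherits(params, "ebt_power_params"))
  if (nrow(segments) == 0) input_error("no segments to plan")
  ab <- ability_for_points(rider$total_points, ability)
  v_target <- kmh_to_ms(ab$target_speed_kmh)
  p_rider <- ab$flat_power_w
  cutoff_ms <- kmh_to_ms(bike$legal_speed_cutoff)

  n <- nrow(segments)
  plan <- data.frame(
    segment = seq_len(n),
    start_m = segments$start_m, end_m = segments$end_m,
    length = segments$length, grade = segments$grade,
    target_speed = v_target, planned_speed = v_target,
    required_power = required_power(v_target, segments$grade, params),
    rider_power = p_rider, motor_power = 0, assist_level = 0L,
    flag = "none", stringsAsFactors = FALSE
  )

  for (k in seq_len(n)) {
    p_i <- plan$required_power[k]
    if (p_i <= 0) {
      plan$rider_power[k] <- 0
      plan$motor_power[k] <- 0
      plan$flag[k] <- "coast"
    } else if (p_i < p_rider) {
      plan$rider_power[k] <- p_i
      plan$motor_power[k] <- 0
      plan$flag[k] <- "reduced"
    } else if (p_i > p_rider + bike$motor_max) {
      plan$motor_power[k] <- bike$motor_max
      plan$planned_speed[k] <- speed_at_power(p_rider + bike$motor_max,
                                              plan$grade[k], params)
      plan$flag[k] <- "sag"
    } else {
      plan$motor_power[k] <- p_i - p_rider
    }
    if (plan$planned_speed[k] > cutoff_ms && plan$motor_power[k] > 0) {
      plan$motor_power[k] <- 0
      plan$flag[k] <- "cutoff"
    }
    plan$assist_level[k] <- quantize_to_level(plan$motor_power[k], bike)
  }
  plan$level_power <- ifelse(plan$assist_level > 0,
                             bike$level_powers[pmax(plan$assist_level, 1L)], 0)

  if (!is.null(route)) {
    plan$wpt_lat <- route$points$lat[segments$start_index]
    plan$wpt_lon <- route$points$lon[segments$start_index]
  }

  dur <- plan$length / plan$planned_speed
  totals <- list(
    duration_s = sum(dur),
    rider_energy_wh = sum(plan$rider_power * dur) / 3600,
    motor_energy_wh = sum(plan$motor_power * dur) / 3600,
    distance_km = sum(plan$length) / 1000
  )
  structure(list(segments = plan, totals = totals, rider = rider, bike = bike,
                 params = params, ability = ab),
            class = "ebt_plan")
}

#' @export
print.ebt_plan <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "<ebt_plan> %d segments, %.2f km, level %d rider @ %.0f km/h\n  predicted: %.0f s, rider %.1f Wh, motor %.1f Wh\n",
    nrow(x$segments), t$distance_km, x$ability$level,
    ms_to_kmh(x$segments$target_speed[1]), t$duration_s,
    t$rider_energy_wh, t$motor_energy_wh))
  invisible(x)
}

#' Waypoints marking each assist-level change
#'
#' One waypoint per segment start (the first at the route start), named with
#' the assist level to apply from that point on.
#'
#' @param plan An `ebt_plan` built with its `route` argument set.
#' @return A data frame with `lat`, `lon`, `name`, `level`.
#' @export
plan_waypoints <- function(plan) {
  stopifnot(inherits(plan, "ebt_plan"))
  seg <- plan$segments
  if (is.null(seg$wpt_lat)) input_error("plan was built without a route; no waypoint coordinates")
  data.frame(lat = seg$wpt_lat, lon = seg$wpt_lon,
             name = sprintf("S%d_L%d", seg$segment, seg$assist_level),
             level = seg$assist_level)
}

#' Write waypoints as GPX `<wpt>` elements
#'
#' @param waypoints Data frame from [plan_waypoints()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waypoints_gpx <- function(waypoints, path) {
  doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "ebiketrainer",
                            xmlns = "http://www.topografix.com/GPX/1/1")
  for (k in seq_len(nrow(waypoints))) {
    wp <- xml2::xml_add_child(doc, "wpt",
                              lat = sprintf("%.7f", waypoints$lat[k]),
                              lon = sprintf("%.7f", waypoints$lon[k]))
    xml2::xml_add_child(wp, "name", waypoints$name[k])
    xml2::xml_add_child(wp, "cmt", sprintf("level=%d", waypoints$level[k]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read waypoints written by [write_waypoints_gpx()]
#'
#' @param path GPX file with `<wpt>` elements.
#' @return A data frame with `lat`, `lon`, `name`, `level`.
#' @export
read_waypoints_gpx <- function(path) {
  if (!file.exists(path)) input_error(sprintf("waypoint file not found: %s", path))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, "//wpt")
  cmt <- xml2::xml_text(xml2::xml_find_first(nodes, "./cmt"))
  data.frame(
    lat = as.numeric(xml2::xml_attr(nodes, "lat")),
    lon = as.numeric(xml2::xml_attr(nodes, "lon")),
    name = xml2::xml_text(xml2::xml_find_first(nodes, "./name")),
    level = as.integer(sub("^level=", "", cmt))
  )
}
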
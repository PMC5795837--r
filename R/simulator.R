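#' Rider-behavior model for the ride simulator
#'
#' Governs how a simulated rider tracks the planned speed and how their
#' heart rate responds to workload. HR follows a first-order relaxation
#' toward `hr_rest + hr_gain * rider_power` with time constant
#' `hr_time_constant` — the simplest dynamics with the right qualitative
#' shape (rise on effort, recovery on rest).
#'
#' @param speed_tracking_sd Gaussian speed noise around the planned speed,
#'   m/s (default 0).
#' @param hr_rest Resting heart rate, bpm (default 70).
#' @param hr_gain Steady-state HR rise per watt of rider power, bpm/W
#'   (default 0.3, i.e. ~60 bpm at 200 W).
#' @param hr_time_constant HR response time constant, s (default 40).
#' @param seed Integer seed making the simulation deterministic.
#' @return An object of class `ebt_behavior`.
#' @export
behavior_model <- function(speed_tracking_sd = 0, hr_rest = 70, hr_gain = 0.3,
                           hr_time_constant = 40, seed = 1L) {
  if (speed_tracking_sd < 0) input_error("speed_tracking_sd must be >= 0")
  if (hr_time_constant <= 0) input_error("hr_time_constant must be > 0")
  structure(list(speed_tracking_sd = speed_tracking_sd, hr_rest = hr_rest,
                 hr_gain = hr_gain, hr_time_constant = hr_time_constant,
                 seed = as.integer(seed)),
            class = "ebt_behavior")
}

#' Simulate ride telemetry from an assist plan
#'
#' Marches along the planned route at fixed time steps. Each sample's speed
#' is the segment's planned (or sag-limited achievable) speed plus truncated
#' Gaussian noise; the motor delivers its active level's power, clamped so
#' rider + motor equals the model power at the realized speed (the motor
#' never pushes beyond what the ride demands); the rider supplies the rest.
#' When `hr_threshold` is set the safety override can raise the active level
#' above the planned one (with 30 s hysteresis); an override persists for the
#' remainder of the ride, so the active level never decreases below it.
#'
#' @param plan An `ebt_plan`.
#' @param behavior An `ebt_behavior`.
#' @param dt Sample interval in seconds (default 1).
#' @param hr_threshold Optional HR safety threshold in bpm; `NULL` disables
#'   the override.
#' @return A data frame of class `ebt_telemetry` with columns `time_s`,
#'   `dist_m`, `speed_ms`, `motor_w`, `rider_w`, `bpm`, `level`.
#' @export
simulate_ride <- function(plan, behavior, dt = 1, hr_threshold = NULL) {
  stopifnot(inherits(plan, "ebt_plan"), inherits(behavior, "ebt_behavior"))
  if (dt <= 0) input_error("dt must be > 0")
  seg <- plan$segments
  total <- max(seg$end_m)
  # generous sample cap: twice the planned duration plus slack
  max_n <- ceiling(2 * plan$totals$duration_s / dt) + 1000L

  with_seed(behavior$seed, {
    n_guess <- min(max_n, ceiling(1.2 * plan$totals$duration_s / dt) + 100L)
    time_s <- dist_m <- speed_ms <- motor_w <- rider_w <- bpm <- numeric(0)
    level <- integer(0)
    pos <- 0; t <- 0; hr <- behavior$hr_rest
    override_floor <- 0L
    last_increase <- -Inf
    k <- 0L
    rows <- vector("list", 0)
    while (pos < total && k < max_n) {
      k <- k + 1L
      s_idx <- min(findInterval(pos, seg$start_m, rightmost.closed = TRUE) + 0L,
                   nrow(seg))
      s_idx <- max(s_idx, 1L)
      v_plan <- seg$planned_speed[s_idx]
      v <- v_plan
      if (behavior$speed_tracking_sd > 0) {
        v <- max(0, v + stats::rnorm(1, sd = behavior$speed_tracking_sd))
      }
      active <- max(seg$assist_level[s_idx], override_floor)
      if (!is.null(hr_threshold)) {
        ov <- safety_override(hr, hr_threshold, active, plan$bike,
                              time_s = t, last_increase_s = last_increase)
        if (ov$level > active) {
          active <- ov$level
          override_floor <- ov$level
          last_increase <- ov$last_increase_s
        }
      }
      req <- required_power(v, seg$grade[s_idx], plan$params)
      lvl_w <- if (active > 0) plan$bike$level_powers[active] else 0
      motor <- min(lvl_w, max(req, 0))
      rider <- max(req - motor, 0)
      hr <- hr + dt / behavior$hr_time_constant *
        (behavior$hr_rest + behavior$hr_gain * rider - hr)
      rows[[k]] <- c(t, pos, v, motor, rider, hr, active)
      pos <- pos + v * dt
      t <- t + dt
    }
    out <- as.data.frame(do.call(rbind, rows))
    names(out) <- c("time_s", "dist_m", "speed_ms", "motor_w", "rider_w",
                    "bpm", "level")
    out$level <- as.integer(out$level)
    class(out) <- c("ebt_telemetry", "data.frame")
    attr(out, "dt") <- dt
    out
  })
}

#' Summarize ride telemetry
#'
#' Left-rectangle energy integration on the sample grid, consistent with the
#' scoring module.
#'
#' @param telemetry An `ebt_telemetry` (or any data frame with the same
#'   columns).
#' @return A list: `distance_km`, `duration_s`, `mean_speed_kmh`,
#'   `rider_energy_wh`, `motor_energy_wh`, `total_energy_wh`.
#' @export
summarize_ride <- function(telemetry) {
  if (nrow(telemetry) < 2) input_error("telemetry needs at least 2 samples")
  dt <- diff(telemetry$time_s)
  dur <- sum(dt)
  last_dist <- telemetry$dist_m[nrow(telemetry)] +
    telemetry$speed_ms[nrow(telemetry)] * utils::tail(dt, 1)
  drop_last <- function(x) x[-length(x)]
  e_rider <- sum(drop_last(telemetry$rider_w) * dt) / 3600
  e_motor <- sum(drop_last(telemetry$motor_w) * dt) / 3600
  list(
    distance_km = last_dist / 1000,
    duration_s = dur + utils::tail(dt, 1),
    mean_speed_kmh = ms_to_kmh(last_dist / (dur + utils::tail(dt, 1))),
    rider_energy_wh = e_rider + utils::tail(telemetry$rider_w, 1) * utils::tail(dt, 1) / 3600,
    motor_energy_wh = e_motor + utils::tail(telemetry$motor_w, 1) * utils::tail(dt, 1) / 3600,
    total_energy_wh = e_rider + e_motor +
      (utils::tail(telemetry$rider_w, 1) + utils::tail(telemetry$motor_w, 1)) *
      utils::tail(dt, 1) / 3600
  )
}

#' Write / read telemetry CSV
#'
#' Columns: `time_s,dist_m,speed_ms,motor_w,rider_w,bpm,level`.
#'
#' @param telemetry An `ebt_telemetry`.
#' @param path File path.
#' @return `path` (write) or the telemetry data frame (read).
#' @export
write_telemetry_csv <- function(telemetry, path) {
  utils::write.csv(as.data.frame(telemetry), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_telemetry_csv
#' @export
read_telemetry_csv <- function(path) {
  if (!file.exists(path)) input_error(sprintf("telemetry file not found: %s", path))
  df <- utils::read.csv(path)
  need <- c("time_s", "dist_m", "speed_ms", "motor_w", "rider_w")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    input_error(sprintf("telemetry CSV missing column(s): %s", paste(miss, collapse = ", ")))
  }
  class(df) <- c("ebt_telemetry", "data.frame")
  df
}
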
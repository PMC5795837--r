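# Ability lookup, assist-level quantization, and the per-segment planner.

make_segments <- function(grades, lengths = rep(500, length(grades))) {
  ends <- cumsum(lengths)
  segs <- data.frame(
    start_index = c(1L, utils::head(ends, -1L) / 50 + 1L),
    end_index = ends / 50 + 1L,
    start_m = c(0, utils::head(ends, -1L)), end_m = ends,
    length = lengths, grade = grades,
    sign = ifelse(grades >= 0, "+", "-")
  )
  class(segs) <- c("ebt_segments", "data.frame")
  segs
}

test_rider <- function(points = 220) rider_profile(75, 1.75, 30, total_points = points)

test_that("points map onto the ability ladder with top-level clamping", {
  expect_equal(ability_for_points(170)$level, 4)
  expect_equal(ability_for_points(170)$target_speed_kmh, 19)
  expect_equal(ability_for_points(0)$level, 1)
  expect_equal(ability_for_points(0)$target_speed_kmh, 15)
  expect_equal(ability_for_points(10000)$level, 10)
  expect_error(ability_for_points(-5), ">= 0")
})

test_that("quantization follows the left-closed midpoint intervals", {
  bike <- bike_profile(level_powers = c(100, 200, 300))
  expect_equal(quantize_to_level(140, bike), 1L)
  expect_equal(quantize_to_level(150, bike), 2L)  # exact midpoint rounds up
  expect_equal(quantize_to_level(-20, bike), 0L)
  expect_equal(quantize_to_level(1e6, bike), 3L)
  expect_equal(quantize_to_level(49.999, bike), 0L)
  expect_equal(quantize_to_level(50, bike), 1L)
})

test_that("quantization equals nearest-level assignment with ties up (random ladders)", {
  for (s in 1:20) {
    ladder <- with_seed_helper(s, sort(sample(50:800, sample(3:8, 1))))
    bike <- bike_profile(level_powers = ladder, motor_max = max(ladder))
    w <- with_seed_helper(1000 + s, stats::runif(200, -50, max(ladder) * 1.2))
    w <- c(w, ladder / 2, (ladder + c(ladder[-1], Inf))[-length(ladder)] / 2)
    w <- w[is.finite(w)]
    got <- quantize_to_level(w, bike)
    want <- vapply(w, oracle_quantize, integer(1), ladder = ladder)
    expect_equal(got, want, info = sprintf("ladder seed %d", s))
  }
})

test_that("a flat segment at the rider's level needs no assist", {
  segs <- make_segments(0)
  plan <- plan_assist(segs, test_rider(220), bike_profile())  # level 5, 20 km/h
  expect_equal(plan$segments$required_power, 59.46, tolerance = 0.05 / 60)
  expect_equal(plan$segments$motor_power, 0)
  expect_equal(plan$segments$assist_level, 0L)
})

test_that("the climb shortfall is quantized onto the ladder", {
  # find the grade where holding 20 km/h takes 270 W
  params <- table2_params()
  v <- kmh_to_ms_helper(20)
  grade <- (270 - required_power(v, 0, params)) / (params$g * params$mass * v)
  bike <- bike_profile(level_powers = c(50, 100, 150, 200, 250, 300),
                       motor_max = 300)
  plan <- plan_assist(make_segments(grade), test_rider(220), bike, params)
  expect_equal(plan$segments$required_power, 270, tolerance = 1e-6)
  expect_equal(plan$segments$motor_power, 270 - 59.46, tolerance = 1e-6)
  expect_equal(plan$segments$assist_level, 4L)  # 210.5 W -> nearest level 200 W
  expect_equal(plan$segments$level_power, 200)
})

test_that("descents are coasted: rider 0, motor 0, level 0, flagged", {
  plan <- plan_assist(make_segments(-0.05), test_rider(220), bike_profile())
  seg <- plan$segments
  expect_lt(seg$required_power, 0)
  expect_equal(seg$rider_power, 0)
  expect_equal(seg$motor_power, 0)
  expect_equal(seg$assist_level, 0L)
  expect_equal(seg$flag, "coast")
})

test_that("unachievable climbs record the sag speed at full assist", {
  bike <- bike_profile(level_powers = c(50, 100, 150), motor_max = 150)
  plan <- plan_assist(make_segments(0.15), test_rider(220), bike)
  seg <- plan$segments
  expect_equal(seg$flag, "sag")
  expect_lt(seg$planned_speed, seg$target_speed)
  expect_equal(required_power(seg$planned_speed, seg$grade, plan$params),
               seg$rider_power + seg$motor_power, tolerance = 1e-6)
})

test_that("assistance is cut above the legal speed limit", {
  # level 10 rider targets 28 km/h > 25 km/h cutoff: no motor even uphill
  plan <- plan_assist(make_segments(c(0.04, -0.02)), test_rider(550), bike_profile())
  seg <- plan$segments
  expect_equal(seg$flag[1], "cutoff")
  expect_equal(seg$motor_power[1], 0)
  expect_equal(seg$assist_level[1], 0L)
})

test_that("power splits conserve: rider + motor = required wherever unflagged", {
  grades <- c(0.01, 0.03, 0.05, 0.07, -0.02)
  plan <- plan_assist(make_segments(grades), test_rider(220), bike_profile())
  seg <- plan$segments
  free <- seg$flag == "none"
  expect_true(any(free))
  expect_equal(seg$rider_power[free] + seg$motor_power[free],
               seg$required_power[free], tolerance = 1e-9)
})

test_that("steeper grades never get a lower assist level", {
  plan <- plan_assist(make_segments(seq(0, 0.12, by = 0.01)),
                      test_rider(220), bike_profile())
  expect_true(all(diff(plan$segments$assist_level) >= 0))
})

test_that("moving up the ladder never raises the motor's energy share", {
  segs <- make_segments(c(0.02, 0.05, -0.01, 0.03))
  share <- sapply(c(25, 120, 220, 320, 420), function(pts) {
    t <- plan_assist(segs, test_rider(pts), bike_profile())$totals
    t$motor_energy_wh / (t$motor_energy_wh + t$rider_energy_wh)
  })
  expect_true(all(diff(share) <= 1e-9))
})

test_that("waypoints mark segment starts and survive a GPX round trip", {
  rt <- synthesize_route(list(c(500, -0.03), c(500, 0.03)), step = 25,
                         noise_sd = 0, seed = 1)
  segs <- segment_route(rt)
  plan <- plan_assist(segs, test_rider(220), bike_profile(), route = rt)
  wpts <- plan_waypoints(plan)
  expect_equal(nrow(wpts), nrow(segs))
  expect_equal(wpts$lat, rt$points$lat[segs$start_index])
  expect_equal(wpts$lon, rt$points$lon[segs$start_index])
  expect_equal(wpts$lat[1], rt$points$lat[1])

  f <- tempfile(fileext = ".gpx")
  write_waypoints_gpx(wpts, f)
  back <- read_waypoints_gpx(f)
  expect_equal(back$level, wpts$level)
  expect_equal(back$lat, wpts$lat, tolerance = 1e-6)
})

test_that("bike profiles validate their ladder", {
  expect_error(bike_profile(level_powers = c(200, 100)), "increasing")
  expect_error(bike_profile(level_powers = c(100, 200), motor_max = 150), "motor_max")
})
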
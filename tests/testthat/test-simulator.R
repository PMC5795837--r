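# Ride telemetry simulation and summaries.

hilly_plan <- function(points = 220, len = 2000) {
  rt <- synthesize_route(list(c(len, 0.0), c(len, 0.05), c(len / 2, -0.03)),
                         step = 25, noise_sd = 0, seed = 9)
  segs <- segment_route(rt)
  plan_assist(segs, rider_profile(75, 1.75, 30, total_points = points),
              bike_profile(), route = rt)
}

test_that("zero tracking noise realizes the planned speeds exactly", {
  plan <- hilly_plan()
  tel <- simulate_ride(plan, behavior_model(speed_tracking_sd = 0, seed = 1))
  planned <- plan$segments$planned_speed[
    findInterval(tel$dist_m, plan$segments$start_m, rightmost.closed = TRUE)]
  expect_equal(tel$speed_ms, planned)
})

test_that("the same seed reproduces telemetry exactly; other seeds differ", {
  plan <- hilly_plan()
  beh <- behavior_model(speed_tracking_sd = 0.3, seed = 77)
  a <- simulate_ride(plan, beh)
  b <- simulate_ride(plan, beh)
  expect_identical(a, b)
  d <- simulate_ride(plan, behavior_model(speed_tracking_sd = 0.3, seed = 78))
  expect_false(identical(a$speed_ms, d$speed_ms))
})

test_that("a flat noise-free ride holds the rider at the ladder power", {
  segs <- data.frame(start_index = 1L, end_index = 2L, start_m = 0,
                     end_m = 5000, length = 5000, grade = 0, sign = "+")
  class(segs) <- c("ebt_segments", "data.frame")
  plan <- plan_assist(segs, rider_profile(75, 1.75, 30, total_points = 220),
                      bike_profile())
  tel <- simulate_ride(plan, behavior_model(seed = 1))
  expect_equal(unique(round(tel$rider_w, 3)), 59.458)
  expect_true(all(abs(tel$rider_w - 59.46) < 0.05))
  expect_true(all(tel$motor_w == 0))
})

test_that("sample energies integrate to the model work (noise-free)", {
  plan <- hilly_plan()
  tel <- simulate_ride(plan, behavior_model(seed = 1))
  s <- summarize_ride(tel)
  seg_idx <- findInterval(tel$dist_m, plan$segments$start_m, rightmost.closed = TRUE)
  req <- pmax(required_power(tel$speed_ms, plan$segments$grade[seg_idx], plan$params), 0)
  work_wh <- sum(req) / 3600  # dt = 1 s
  expect_equal(s$rider_energy_wh + s$motor_energy_wh, work_wh,
               tolerance = 0.01)
})

test_that("heart rate relaxes to rest + gain x power within 1% after 5 time constants", {
  segs <- data.frame(start_index = 1L, end_index = 2L, start_m = 0,
                     end_m = 20000, length = 20000, grade = 0, sign = "+")
  class(segs) <- c("ebt_segments", "data.frame")
  plan <- plan_assist(segs, rider_profile(75, 1.75, 30, total_points = 220),
                      bike_profile())
  beh <- behavior_model(hr_rest = 65, hr_gain = 0.3, hr_time_constant = 40, seed = 1)
  tel <- simulate_ride(plan, beh)
  target <- 65 + 0.3 * tel$rider_w[1]
  after <- tel$bpm[tel$time_s >= 5 * 40]
  expect_true(all(abs(after - target) / target < 0.01))
})

test_that("a low HR threshold triggers the override and the level never drops below it", {
  # climb whose motor request quantizes mid-ladder, so the rider keeps
  # working (~33 W) and the override has headroom to raise the level
  params <- table2_params()
  v <- kmh_to_ms_helper(15)
  grade <- (33.19 + 210 - required_power(v, 0, params)) /
    (params$g * params$mass * v)
  segs <- data.frame(start_index = 1L, end_index = 2L, start_m = 0,
                     end_m = 3000, length = 3000, grade = grade, sign = "+")
  class(segs) <- c("ebt_segments", "data.frame")
  plan <- plan_assist(segs, rider_profile(75, 1.75, 30, total_points = 25),
                      bike_profile(level_powers = c(50, 100, 150, 200, 250, 300),
                                   motor_max = 300), params)
  beh <- behavior_model(hr_rest = 70, hr_gain = 1.0, hr_time_constant = 20, seed = 1)
  with_thr <- simulate_ride(plan, beh, hr_threshold = 100)
  without <- simulate_ride(plan, beh, hr_threshold = NULL)
  expect_equal(nrow(with_thr), nrow(without))
  expect_true(all(with_thr$level >= without$level))
  expect_gt(sum(with_thr$level > without$level), 0)
})

test_that("summaries follow from arithmetic on the samples", {
  v <- kmh_to_ms_helper(20)
  tel <- data.frame(time_s = 0:3599, dist_m = (0:3599) * v, speed_ms = v,
                    motor_w = 0, rider_w = 60, bpm = 120, level = 0L)
  s <- summarize_ride(tel)
  expect_equal(s$distance_km, 20, tolerance = 1e-9)
  expect_equal(s$duration_s, 3600)
  expect_equal(s$mean_speed_kmh, 20, tolerance = 1e-9)
  expect_equal(s$rider_energy_wh, 60, tolerance = 1e-9)
  expect_equal(s$motor_energy_wh, 0)

  half <- tel[1:1800, ]
  expect_equal(summarize_ride(half)$rider_energy_wh, 30, tolerance = 1e-9)
})

test_that("plan -> simulate -> score recovers the plan's rider energy (noise-free, flat)", {
  segs <- data.frame(start_index = 1L, end_index = 2L, start_m = 0,
                     end_m = 10000, length = 10000, grade = 0, sign = "+")
  class(segs) <- c("ebt_segments", "data.frame")
  plan <- plan_assist(segs, rider_profile(75, 1.75, 30, total_points = 220),
                      bike_profile())
  tel <- simulate_ride(plan, behavior_model(seed = 3))
  got <- rider_energy(tel, plan)
  expect_equal(got, plan$totals$rider_energy_wh, tolerance = 0.01)
})

test_that("telemetry round-trips through CSV", {
  plan <- hilly_plan()
  tel <- simulate_ride(plan, behavior_model(speed_tracking_sd = 0.2, seed = 4))
  f <- tempfile(fileext = ".csv")
  write_telemetry_csv(tel, f)
  back <- read_telemetry_csv(f)
  expect_equal(back$speed_ms, tel$speed_ms, tolerance = 1e-9)
  expect_equal(back$motor_w, tel$motor_w, tolerance = 1e-9)
})
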
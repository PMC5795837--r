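#' Cycling power model parameters
#'
#' The power to hold ground speed `s` (m/s) on grade `i` is
#' \deqn{P = k_r M g s + k_a A d s (s + w)^2 + g i M s}
#' rolling resistance, aerodynamic drag (with air speed `s + w` for signed
#' headwind `w`), and the gravity term. Internally only the flat-road
#' coefficients `c1 = k_r M g` (W per m/s) and `c2 = k_a A d` (W per (m/s)^3)
#' plus `M`, `g` and `w` are needed.
#'
#' Two constructors are provided. `power_model_params()` is the physical
#' mode: you supply mass and frontal area (or rider height/mass via
#' [estimate_frontal_area()]). `calibrated_power_params()` is the
#' table-calibrated mode: `c1` and `c2` are fitted to the ability ladder's
#' flat-road power column (see [calibrate_flat_coefficients()]), and the mass
#' used in the gravity term is the effective mass `c1 / (k_r g)` implied by
#' the fit unless overridden. The printed ladder implies an effective mass of
#' about 90.75 kg and frontal area 0.331 m^2, which differ from the nominal
#' 75 + 8 kg reference rider; the calibrated mode reproduces the ladder, the
#' physical mode reflects the actual rider.
#'
#' @param mass Total mass (rider + bike) in kg.
#' @param area Frontal area in m^2.
#' @param k_r Rolling resistance coefficient (default 0.005).
#' @param k_a Wind resistance coefficient (default 0.5).
#' @param air_density Air density in kg/m^3 (default 1.226).
#' @param g Gravitational acceleration in m/s^2 (default 9.8).
#' @param headwind Signed headwind in m/s (positive opposes motion; default 0).
#' @return An object of class `ebt_power_params`.
#' @export
power_model_params <- function(mass, area, k_r = 0.005, k_a = 0.5,
                               air_density = 1.226, g = 9.8, headwind = 0) {
  if (mass < 40 || mass > 200) input_error("total mass must be in [40, 200] kg")
  if (area < 0.2 || area > 1.0) input_error("frontal area must be in [0.2, 1.0] m^2")
  stopifnot(k_r > 0, k_a > 0, air_density > 0, g > 0)
  structure(list(c1 = k_r * mass * g, c2 = k_a * area * air_density,
                 mass = mass, g = g, headwind = headwind, mode = "physical"),
            class = "ebt_power_params")
}

#' @rdname power_model_params
#' @param c1 Flat-road linear coefficient, W per (m/s).
#' @param c2 Flat-road cubic coefficient, W per (m/s)^3.
#' @export
calibrated_power_params <- function(c1, c2, mass = NULL, g = 9.8, headwind = 0) {
  stopifnot(c1 > 0, c2 > 0, g > 0)
  if (is.null(mass)) mass <- c1 / (0.005 * g)  # effective mass implied by the fit
  structure(list(c1 = c1, c2 = c2, mass = mass, g = g, headwind = headwind,
                 mode = "calibrated"),
            class = "ebt_power_params")
}

#' @export
print.ebt_power_params <- function(x, ...) {
  cat(sprintf("<ebt_power_params> %s: c1 = %.4f W/(m/s), c2 = %.4f W/(m/s)^3, M = %.2f kg%s\n",
              x$mode, x$c1, x$c2, x$mass,
              if (x$headwind != 0) sprintf(", headwind %.1f m/s", x$headwind) else ""))
  invisible(x)
}

#' Power required to hold a speed on a grade
#'
#' Evaluates the rolling + aerodynamic + gravity power model. Negative values
#' on descents mean gravity alone exceeds the resistive losses (the rider can
#' coast).
#'
#' @param speed Ground speed in m/s (vectorized).
#' @param grade Rise-over-run grade fraction (vectorized).
#' @param params An `ebt_power_params`.
#' @return Power in watts.
#' @export
required_power <- function(speed, grade, params) {
  stopifnot(inherits(params, "ebt_power_params"), all(speed >= 0))
  params$c1 * speed +
    params$c2 * speed * (speed + params$headwind)^2 +
    params$g * grade * params$mass * speed
}

#' Speed attainable at a given power on a grade
#'
#' Inverts [required_power()] for speed. With zero headwind the power curve is
#' `a s + b s^3` with `b > 0` (and `a` possibly negative downhill), so there
#' is exactly one positive root beyond the coasting range; it is found by
#' bracketed root-finding on \[1e-6, 60\] m/s.
#'
#' @param power Target power in watts; must exceed the coasting power at
#'   negligible speed. `power <= 0` returns `NA` (the coasting sentinel:
#'   speed is undefined by the model and the caller handles descents).
#' @param grade Grade fraction.
#' @param params An `ebt_power_params`.
#' @return Speed in m/s, or `NA_real_` when `power <= 0`.
#' @export
speed_at_power <- function(power, grade, params) {
  stopifnot(inherits(params, "ebt_power_params"))
  if (power <= 0) return(NA_real_)
  f <- function(s) required_power(s, grade, params) - power
  upper <- 60
  if (f(upper) < 0) input_error("power target exceeds model range (speed > 60 m/s)")
  # f(1e-6) ~ -power < 0 on any grade (on steep descents f stays negative
  # through the whole coasting range), so [1e-6, 60] brackets the one root.
  stats::uniroot(f, c(1e-6, upper), tol = 1e-13)$root
}

#' Fit flat-road coefficients to (speed, power) rows
#'
#' Least-squares fit of `P = c1 s + c2 s^3` (exact solve for two rows),
#' speeds given in km/h as in the ability ladder. Used to calibrate the model
#' to the ladder's "power on 0% slope" column.
#'
#' @param rows Data frame or matrix with columns speed (km/h) and power (W).
#' @return A list with elements `c1` and `c2` (class
#'   `ebt_flat_coefficients`).
#' @examples
#' calibrate_flat_coefficients(rbind(c(15, 33.19), c(28, 129.95)))
#' @export
calibrate_flat_coefficients <- function(rows) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2) input_error("need at least 2 (speed, power) rows")
  s <- kmh_to_ms(rows[, 1])
  if (anyDuplicated(s)) input_error("duplicate speeds make the system singular")
  X <- cbind(s, s^3)
  fit <- stats::lm.fit(X, rows[, 2])
  cc <- unname(fit$coefficients)
  if (any(!is.finite(cc)) || any(cc <= 0)) input_error("calibration produced non-positive coefficients")
  structure(list(c1 = cc[1], c2 = cc[2]), class = "ebt_flat_coefficients")
}

#' Estimate frontal area from rider height and mass
#'
#' Allometric body-surface-area scaling anchored so a 1.75 m, 75 kg reference
#' rider has the 0.3307 m^2 frontal area implied by the calibrated flat-road
#' drag coefficient:
#' `A = 0.3307 (h / 1.75)^0.725 (m / 75)^0.425`.
#'
#' @param height Rider height in m, in \[1.2, 2.2\].
#' @param mass Rider mass in kg, in \[35, 150\].
#' @return Frontal area in m^2.
#' @export
estimate_frontal_area <- function(height, mass) {
  if (height < 1.2 || height > 2.2) input_error("height must be in [1.2, 2.2] m")
  if (mass < 35 || mass > 150) input_error("mass must be in [35, 150] kg")
  0.3307 * (height / 1.75)^0.725 * (mass / 75)^0.425
}

#' The default ability ladder
#'
#' Ten ability levels with the target average speed, the cumulative-points
#' interval that places a rider on the level, and the power needed to hold
#' the target speed on flat ground. Points beyond the last interval clamp to
#' level 10.
#'
#' @return A data frame with columns `level`, `speed_kmh`, `points_lo`,
#'   `points_hi`, `flat_power_w`.
#' @export
ability_table <- function() {
  data.frame(
    level = 1:10,
    speed_kmh = c(15, 17, 18, 19, 20, 21, 23, 25, 26, 28),
    points_lo = c(0, 51, 101, 151, 201, 251, 301, 351, 401, 501),
    points_hi = c(50, 100, 150, 200, 250, 300, 350, 400, 500, 600),
    flat_power_w = c(33.19, 42.35, 47.57, 53.27, 59.46, 66.17, 81.27, 98.76,
                     108.47, 129.95)
  )
}

#' Power parameters calibrated to the default ability ladder
#'
#' Fits `c1`, `c2` exactly to the first and last ladder rows (the same two
#' points reproduce the whole column to better than 0.01 W).
#'
#' @param ability Ability ladder data frame (default [ability_table()]).
#' @inheritParams calibrated_power_params
#' @return An `ebt_power_params` in calibrated mode.
#' @export
default_calibrated_params <- function(ability = ability_table(), g = 9.8,
                                      headwind = 0) {
  rows <- ability[c(1, nrow(ability)), c("speed_kmh", "flat_power_w")]
  cc <- calibrate_flat_coefficients(rows)
  calibrated_power_params(cc$c1, cc$c2, g = g, headwind = headwind)
}
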
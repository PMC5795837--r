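#' Read a GPS track from GPX or CSV
#'
#' Parses a GPX 1.1 track (`<trkpt>`, falling back to `<rtept>` route points)
#' or a plain CSV with header `lat,lon,ele[,time]` into a route object.
#' Consecutive points closer than 0.1 m are collapsed (first point kept), and
#' cumulative distances are computed with the haversine formula on a sphere of
#' radius 6371008.8 m.
#'
#' @param path Path to the track file.
#' @param format `"gpx"` or `"csv"`; guessed from the file extension when
#'   omitted.
#' @return An object of class `ebt_route`: a list with `points` (data frame
#'   with columns `lat`, `lon`, `ele` and optionally `time` in epoch seconds),
#'   `cum_dist` (meters per point, first 0, strictly increasing) and `grade`
#'   (one rise-over-run value per inter-point step, `NA` until
#'   [compute_grades()] is called).
#' @examples
#' rt <- synthesize_route(list(c(1000, 0.02)), step = 50, noise_sd = 0, seed = 1)
#' f <- tempfile(fileext = ".gpx")
#' write_track(rt, f)
#' rt2 <- read_track(f)
#' max(abs(rt2$points$ele - rt$points$ele))
#' @export
read_track <- function(path, format = c("auto", "gpx", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) input_error(sprintf("track file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.gpx$", path, ignore.case = TRUE)) "gpx" else "csv"
  }
  pts <- if (format == "gpx") parse_gpx_points(path) else parse_csv_points(path)
  new_route(pts)
}

parse_gpx_points <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) input_error(sprintf("cannot parse GPX: %s", conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, "//trkpt")
  if (length(nodes) == 0) nodes <- xml2::xml_find_all(doc, "//rtept")
  if (length(nodes) == 0) input_error("no <trkpt> or <rtept> elements found")
  lat <- as.numeric(xml2::xml_attr(nodes, "lat"))
  lon <- as.numeric(xml2::xml_attr(nodes, "lon"))
  ele_txt <- xml2::xml_text(xml2::xml_find_first(nodes, "./ele"))
  ele <- suppressWarnings(as.numeric(ele_txt))
  bad <- which(is.na(ele))
  if (length(bad) > 0) {
    input_error(sprintf("missing or invalid elevation at point %d", bad[1]))
  }
  time_txt <- xml2::xml_text(xml2::xml_find_first(nodes, "./time"))
  time <- parse_track_times(time_txt)
  pts <- data.frame(lat = lat, lon = lon, ele = ele)
  if (any(!is.na(time))) pts$time <- time
  pts
}

parse_csv_points <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) input_error(sprintf("cannot parse CSV: %s", conditionMessage(e))))
  need <- c("lat", "lon", "ele")
  if (!all(need %in% names(df))) {
    input_error(sprintf("CSV must have header lat,lon,ele[,time]; got: %s",
                        paste(names(df), collapse = ",")))
  }
  ele <- suppressWarnings(as.numeric(df$ele))
  bad <- which(is.na(ele))
  if (length(bad) > 0) {
    input_error(sprintf("missing or invalid elevation at point %d", bad[1]))
  }
  pts <- data.frame(lat = as.numeric(df$lat), lon = as.numeric(df$lon), ele = ele)
  if ("time" %in% names(df)) {
    pts$time <- parse_track_times(as.character(df$time))
  }
  pts
}

# ISO-8601 or epoch seconds -> epoch seconds (NA allowed throughout).
parse_track_times <- function(txt) {
  out <- suppressWarnings(as.numeric(txt))
  iso <- is.na(out) & !is.na(txt) & nzchar(txt)
  if (any(iso)) {
    parsed <- as.POSIXct(txt[iso], format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    out[iso] <- as.numeric(parsed)
  }
  out
}

new_route <- function(pts) {
  if (any(is.na(pts$lat)) || any(abs(pts$lat) > 90)) input_error("latitude out of [-90, 90]")
  if (any(is.na(pts$lon)) || any(abs(pts$lon) > 180)) input_error("longitude out of [-180, 180]")
  if (!all(is.finite(pts$ele))) input_error("non-finite elevation")
  if (nrow(pts) < 2) input_error("degenerate track: fewer than 2 points")
  step <- geosphere::distHaversine(
    cbind(pts$lon[-nrow(pts)], pts$lat[-nrow(pts)]),
    cbind(pts$lon[-1], pts$lat[-1]),
    r = EARTH_RADIUS_M
  )
  # collapse duplicate consecutive points (< 0.1 m apart), keeping the first
  keep <- c(TRUE, step >= 0.1)
  pts <- pts[keep, , drop = FALSE]
  rownames(pts) <- NULL
  if (nrow(pts) < 2) input_error("degenerate track: fewer than 2 distinct points")
  step <- geosphere::distHaversine(
    cbind(pts$lon[-nrow(pts)], pts$lat[-nrow(pts)]),
    cbind(pts$lon[-1], pts$lat[-1]),
    r = EARTH_RADIUS_M
  )
  structure(
    list(points = pts, cum_dist = c(0, cumsum(step)), grade = rep(NA_real_, nrow(pts) - 1L)),
    class = "ebt_route"
  )
}

#' @export
print.ebt_route <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf("<ebt_route> %d points, %.2f km, elevation %.0f..%.0f m%s\n",
              n, max(x$cum_dist) / 1000, min(x$points$ele), max(x$points$ele),
              if (all(is.na(x$grade))) " (grades not computed)" else ""))
  invisible(x)
}

#' Write a route to GPX 1.1
#'
#' Emits one `<trk>` with `<trkpt lat lon><ele/><time/></trkpt>` entries.
#' Coordinates are written with enough digits to round-trip to 1e-6 degrees
#' and elevations to 0.01 m.
#'
#' @param route An `ebt_route`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(route, path) {
  stopifnot(inherits(route, "ebt_route"))
  pts <- route$points
  doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "ebiketrainer",
                            xmlns = "http://www.topografix.com/GPX/1/1")
  trk <- xml2::xml_add_child(doc, "trk")
  seg <- xml2::xml_add_child(trk, "trkseg")
  has_time <- "time" %in% names(pts)
  for (k in seq_len(nrow(pts))) {
    tp <- xml2::xml_add_child(seg, "trkpt",
                              lat = sprintf("%.7f", pts$lat[k]),
                              lon = sprintf("%.7f", pts$lon[k]))
    xml2::xml_add_child(tp, "ele", sprintf("%.3f", pts$ele[k]))
    if (has_time && !is.na(pts$time[k])) {
      xml2::xml_add_child(tp, "time", format(
        as.POSIXct(pts$time[k], origin = "1970-01-01", tz = "UTC"),
        "%Y-%m-%dT%H:%M:%SZ"))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Compute per-step grades with elevation smoothing
#'
#' Elevations are first smoothed with a centered moving average over a
#' distance window (all points within half a window of each point), then
#' differenced: `grade_k = (ele_{k+1} - ele_k) / (dist_{k+1} - dist_k)`.
#' Consumer-GPS elevation noise of a meter or two otherwise dominates grades
#' at typical 10-50 m point spacing. Grades are clipped to \[-0.35, 0.35\],
#' beyond which no rideable road lies.
#'
#' @param route An `ebt_route`.
#' @param smoothing_window Window width in meters (default 30); 0 disables
#'   smoothing.
#' @return The route with its `grade` field filled in.
#' @export
compute_grades <- function(route, smoothing_window = 30) {
  stopifnot(inherits(route, "ebt_route"))
  if (smoothing_window < 0) input_error("smoothing_window must be >= 0")
  d <- route$cum_dist
  dd <- diff(d)
  if (any(dd <= 0)) stop("internal error: zero-length step after deduplication")
  ele <- smooth_elevation(route$points$ele, d, smoothing_window)
  g <- diff(ele) / dd
  route$grade <- pmin(pmax(g, -0.35), 0.35)
  route
}

smooth_elevation <- function(ele, dist, window) {
  if (window == 0) return(ele)
  half <- window / 2
  vapply(seq_along(ele), function(k) {
    mean(ele[abs(dist - dist[k]) <= half])
  }, numeric(1))
}

#' Generate a synthetic route with piecewise-constant grades
#'
#' Lays out points along a constant great-circle heading starting near a
#' reference coordinate, with true elevation following the requested grade
#' pieces plus optional Gaussian noise. Used as the test fixture generator:
#' the true piecewise grades are recoverable from the returned route.
#'
#' @param spec List of `c(length_m, grade)` pairs (or a 2-column matrix), in
#'   ride order.
#' @param step Point spacing in meters (default 20).
#' @param noise_sd Standard deviation of elevation noise in meters (default 0).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param start_lat,start_lon,start_ele,heading Starting coordinate, elevation
#'   (m) and great-circle heading (degrees clockwise from north).
#' @return An `ebt_route` with grades computed (no smoothing), carrying the
#'   generating spec in attribute `"truth"`.
#' @export
synthesize_route <- function(spec, step = 20, noise_sd = 0, seed = 1L,
                             start_lat = 46.467, start_lon = 6.833,
                             start_ele = 380, heading = 90) {
  spec <- do.call(rbind, lapply(spec, function(p) {
    if (length(p) != 2) input_error("each spec entry must be c(length_m, grade)")
    as.numeric(p)
  }))
  if (any(spec[, 1] <= 0)) input_error("piece lengths must be > 0")
  if (any(abs(spec[, 2]) > 0.35)) input_error("|grade| > 0.35 rejected")
  if (step <= 0) input_error("step must be > 0")

  total <- sum(spec[, 1])
  d <- seq(0, total, by = step)
  if (d[length(d)] < total) d <- c(d, total)
  # true elevation: piecewise-linear integral of the grade profile
  ends <- cumsum(spec[, 1])
  starts <- c(0, ends[-length(ends)])
  ele_at <- function(x) {
    start_ele + sum(spec[, 2] * pmax(0, pmin(x, ends) - starts))
  }
  ele <- vapply(d, ele_at, numeric(1))
  if (noise_sd > 0) {
    ele <- ele + with_seed(seed, stats::rnorm(length(d), sd = noise_sd))
  }
  ll <- geosphere::destPoint(c(start_lon, start_lat), b = heading, d = d,
                             r = EARTH_RADIUS_M)
  rt <- new_route(data.frame(lat = ll[, "lat"], lon = ll[, "lon"], ele = ele))
  rt <- compute_grades(rt, smoothing_window = 0)
  attr(rt, "truth") <- spec
  rt
}
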
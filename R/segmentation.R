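#' Partition a route into segments of similar slope magnitude
#'
#' Two-pass procedure. Pass 1 assigns every inter-point step to a signed
#' magnitude bin with edges at 0, ±`bin_width`, ±2·`bin_width`, ... (a grade
#' exactly on an edge falls in the lower-magnitude bin) and merges adjacent
#' steps sharing a bin; runs of exactly zero grade are attached to the
#' adjacent run with the smaller mean |grade| (ties to the preceding run), so
#' flat stretches inherit the sign of their surroundings. Pass 2 absorbs runs
#' shorter than `min_length` into whichever neighbor has the nearer mean
#' grade, repeatedly, shortest first. Each segment's grade is the
#' length-weighted mean of its step grades.
#'
#' @param route An `ebt_route` with grades computed (see [compute_grades()]).
#' @param bin_width Grade bin width as a fraction (default 0.02, i.e. 2%).
#' @param min_length Minimum segment length in meters (default 50); a route
#'   shorter than this comes back as a single segment.
#' @return A data frame of class `ebt_segments` with columns `start_index`,
#'   `end_index` (half-open point-index range), `start_m`, `end_m`, `length`,
#'   `grade`, `sign`.
#' @examples
#' rt <- synthesize_route(list(c(500, -0.03), c(500, 0.03)), step = 25, seed = 1)
#' segment_route(rt)
#' @export
segment_route <- function(route, bin_width = 0.02, min_length = 50) {
  stopifnot(inherits(route, "ebt_route"))
  if (any(is.na(route$grade))) input_error("route grades not computed; call compute_grades() first")
  if (bin_width <= 0) input_error("bin_width must be > 0")
  if (min_length <= 0) input_error("min_length must be > 0")

  g <- route$grade
  len <- diff(route$cum_dist)
  n_steps <- length(g)

  if (max(route$cum_dist) < min_length) {
    return(segments_from_bounds(route, c(1L, n_steps + 1L)))
  }

  bins <- grade_bin(g, bin_width)
  r <- rle(bins)
  # run boundaries in step indices: runs[k] covers steps bstart[k]..bend[k]
  bend <- cumsum(r$lengths)
  bstart <- c(1L, utils::head(bend, -1L) + 1L)
  runs <- data.frame(from = bstart, to = bend, bin = r$values)

  runs <- attach_zero_runs(runs, g, len)
  runs <- absorb_short_runs(runs, g, len, min_length)

  bounds <- c(runs$from, n_steps + 1L)
  segments_from_bounds(route, bounds)
}

# Signed magnitude bin; edges belong to the lower-magnitude bin.
# A 1e-9 relative tolerance keeps grades that are exact multiples of
# bin_width up to float rounding on the intended edge.
grade_bin <- function(g, bin_width) {
  m <- ceiling(abs(g) / bin_width - 1e-9)
  as.integer(sign(g) * m)
}

run_mean_grade <- function(run_from, run_to, g, len) {
  idx <- seq.int(run_from, run_to)
  sum(g[idx] * len[idx]) / sum(len[idx])
}

run_length_m <- function(run_from, run_to, len) {
  sum(len[seq.int(run_from, run_to)])
}

# Merge bin-0 (exactly flat) runs into the adjacent run with smaller mean
# |grade|; ties go to the preceding run. An all-flat route stays one run.
attach_zero_runs <- function(runs, g, len) {
  repeat {
    z <- which(runs$bin == 0L)
    if (length(z) == 0 || nrow(runs) == 1L) break
    k <- z[1]
    if (k == 1L) {
      into <- 2L
    } else if (k == nrow(runs)) {
      into <- k - 1L
    } else {
      gp <- abs(run_mean_grade(runs$from[k - 1L], runs$to[k - 1L], g, len))
      gn <- abs(run_mean_grade(runs$from[k + 1L], runs$to[k + 1L], g, len))
      into <- if (gp <= gn) k - 1L else k + 1L
    }
    runs <- merge_runs(runs, k, into)
  }
  runs
}

# Absorb runs shorter than min_length into the neighbor with the nearer mean
# grade, shortest run first (ties: first). Stops when everything is long
# enough or one run remains.
absorb_short_runs <- function(runs, g, len, min_length) {
  repeat {
    if (nrow(runs) == 1L) break
    lens <- mapply(run_length_m, runs$from, runs$to, MoreArgs = list(len = len))
    short <- which(lens < min_length)
    if (length(short) == 0) break
    k <- short[which.min(lens[short])]
    if (k == 1L) {
      into <- 2L
    } else if (k == nrow(runs)) {
      into <- k - 1L
    } else {
      gk <- run_mean_grade(runs$from[k], runs$to[k], g, len)
      gp <- run_mean_grade(runs$from[k - 1L], runs$to[k - 1L], g, len)
      gn <- run_mean_grade(runs$from[k + 1L], runs$to[k + 1L], g, len)
      into <- if (abs(gp - gk) <= abs(gn - gk)) k - 1L else k + 1L
    }
    runs <- merge_runs(runs, k, into)
  }
  runs
}

merge_runs <- function(runs, k, into) {
  lo <- min(k, into); hi <- max(k, into)
  runs$to[lo] <- runs$to[hi]
  runs$bin[lo] <- runs$bin[if (into < k) lo else hi]
  runs[-hi, , drop = FALSE]
}

segments_from_bounds <- function(route, bounds) {
  g <- route$grade
  len <- diff(route$cum_dist)
  n <- length(bounds) - 1L
  out <- data.frame(
    start_index = bounds[-length(bounds)],
    end_index = bounds[-1L]
  )
  out$start_m <- route$cum_dist[out$start_index]
  out$end_m <- route$cum_dist[out$end_index]
  out$length <- out$end_m - out$start_m
  out$grade <- vapply(seq_len(n), function(k) {
    run_mean_grade(out$start_index[k], out$end_index[k] - 1L, g, len)
  }, numeric(1))
  out$sign <- ifelse(out$grade >= 0, "+", "-")
  class(out) <- c("ebt_segments", "data.frame")
  out
}

#' Reconstruct an elevation profile from segments
#'
#' Piecewise-linear elevation from cumulative length × grade, anchored at
#' `start_elevation`.
#'
#' @param segments An `ebt_segments` data frame.
#' @param start_elevation Elevation at the route start in meters (default 0).
#' @return A data frame with columns `distance` and `elevation`; one row per
#'   segment boundary (empty input gives zero rows).
#' @export
reconstruct_profile <- function(segments, start_elevation = 0) {
  if (is.null(segments) || nrow(segments) == 0) {
    return(data.frame(distance = numeric(0), elevation = numeric(0)))
  }
  data.frame(
    distance = c(segments$start_m[1], segments$end_m),
    elevation = start_elevation + c(0, cumsum(segments$length * segments$grade))
  )
}

#' Export segments as a BED-like TSV
#'
#' Columns: `route_id`, `start_m`, `end_m`, `grade`, `sign`.
#'
#' @param segments An `ebt_segments` data frame.
#' @param path Output path.
#' @param route_id Identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, path, route_id = "route") {
  df <- data.frame(route_id = route_id,
                   start_m = segments$start_m, end_m = segments$end_m,
                   grade = segments$grade, sign = segments$sign)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
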
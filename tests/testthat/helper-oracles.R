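# Independent brute-force oracles, deliberately written as plain scans/loops
# so they share no code path with the package implementation.

# Nearest-level quantizer: candidate powers are 0 plus the ladder; pick the
# closest, ties to the higher level.
oracle_quantize <- function(w, ladder) {
  cand <- c(0, ladder)
  d <- abs(w - cand)
  max(which(d == min(d))) - 1L
}

# Grid-search inverse of the power curve: densely scan speeds and return the
# grid point whose power is closest to the target (beyond the coasting dip).
oracle_speed_at_power <- function(power, grade, params, grid = seq(0.001, 60, by = 1e-4)) {
  p <- required_power(grid, grade, params)
  grid[which.min(abs(p - power))]
}

# Brute-force segmentation on per-step grades/lengths: same rules as the
# package (signed magnitude bins, zero runs to the flatter neighbor, short
# runs absorbed shortest-first into the nearer-grade neighbor), executed as
# naive loops over explicit run lists.
oracle_segment_bounds <- function(grades, lengths, bin_width, min_length) {
  n <- length(grades)
  if (sum(lengths) < min_length) return(c(1L, n + 1L))
  bin1 <- function(g) {
    if (g == 0) return(0L)
    k <- 0L
    repeat {
      k <- k + 1L
      if (abs(g) <= k * bin_width + 1e-9 * bin_width) break
    }
    as.integer(sign(g) * k)
  }
  bins <- vapply(grades, bin1, integer(1))

  # build runs by a left-to-right scan
  from <- 1L
  runs <- list()
  for (i in seq_len(n)) {
    if (i == n || bins[i + 1L] != bins[i]) {
      runs[[length(runs) + 1L]] <- list(from = from, to = i, bin = bins[i])
      from <- i + 1L
    }
  }
  mg <- function(r) {
    idx <- r$from:r$to
    sum(grades[idx] * lengths[idx]) / sum(lengths[idx])
  }
  lm <- function(r) sum(lengths[r$from:r$to])
  fuse <- function(runs, k, into) {
    a <- runs[[min(k, into)]]; b <- runs[[max(k, into)]]
    kept <- runs[[into]]
    merged <- list(from = a$from, to = b$to, bin = kept$bin)
    runs[[min(k, into)]] <- merged
    runs[-max(k, into)]
  }

  # zero runs, leftmost first
  repeat {
    zi <- 0L
    for (k in seq_along(runs)) if (runs[[k]]$bin == 0L) { zi <- k; break }
    if (zi == 0L || length(runs) == 1L) break
    if (zi == 1L) into <- 2L
    else if (zi == length(runs)) into <- zi - 1L
    else {
      gp <- abs(mg(runs[[zi - 1L]])); gn <- abs(mg(runs[[zi + 1L]]))
      into <- if (gp <= gn) zi - 1L else zi + 1L
    }
    runs <- fuse(runs, zi, into)
  }

  # short-run absorption, shortest first
  repeat {
    if (length(runs) == 1L) break
    lens <- vapply(runs, lm, numeric(1))
    short <- which(lens < min_length)
    if (length(short) == 0L) break
    k <- short[which.min(lens[short])]
    if (k == 1L) into <- 2L
    else if (k == length(runs)) into <- k - 1L
    else {
      gk <- mg(runs[[k]])
      dp <- abs(mg(runs[[k - 1L]]) - gk); dn <- abs(mg(runs[[k + 1L]]) - gk)
      into <- if (dp <= dn) k - 1L else k + 1L
    }
    runs <- fuse(runs, k, into)
  }
  c(vapply(runs, function(r) r$from, integer(1)), n + 1L)
}

# Random piecewise route spec for property tests.
random_route_spec <- function(n_pieces) {
  grades <- sample(c(-0.08, -0.05, -0.03, -0.01, 0, 0.01, 0.02, 0.04, 0.06, 0.09),
                   n_pieces, replace = TRUE)
  lengths <- sample(c(30, 60, 120, 250, 400), n_pieces, replace = TRUE)
  lapply(seq_len(n_pieces), function(i) c(lengths[i], grades[i]))
}

table2_params <- function() default_calibrated_params()

with_seed_helper <- function(seed, code) withr::with_seed(seed, code)

kmh_to_ms_helper <- function(kmh) kmh / 3.6
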
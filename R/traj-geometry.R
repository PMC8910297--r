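#' Build a distance trace from raw columns
#'
#' @param t_ns Time grid, ns (uniform).
#' @param distance_A Protein-ligand distance per sample, Angstrom.
#' @return A `distance_trace` tibble with the sampling interval attached.
#' @export
distance_trace <- function(t_ns, distance_A) {
  if (length(t_ns) != length(distance_A)) {
    abort("t_ns and distance_A must have the same length")
  }
  if (length(t_ns) < 2) abort("a trace needs at least 2 samples")
  dt <- diff(t_ns)
  if (any(abs(dt - dt[1]) > 1e-9 * max(abs(dt[1]), 1)) || dt[1] <= 0) {
    abort("t_ns must be a uniform, increasing grid")
  }
  structure(tibble(t_ns = t_ns, distance_A = distance_A),
            dt_ns = dt[1], class = c("distance_trace", class(tibble())))
}

# fill NA entries with the last preceding non-NA value; leading NAs get
# `first` (base-R locf, keeps the package dependency-light here)
.locf <- function(x, first) {
  known <- !is.na(x)
  if (!any(known)) return(rep(first, length(x)))
  idx <- cumsum(known)
  vals <- x[known]
  out <- ifelse(idx == 0, first, vals[pmax(idx, 1L)])
  out
}

#' Segment a distance trace into bound-state intervals
#'
#' Hysteresis (Schmitt-trigger) segmentation: the trace enters the bound
#' state when the distance drops below `threshold_low` and leaves it only
#' when the distance rises above `threshold_high`; samples in the dead band
#' keep the current state, which suppresses single-threshold flicker under
#' noise. Runs (bound or unbound) shorter than `min_dwell` are merged into
#' their neighbors, shortest first. With `threshold_low == threshold_high`
#' the scheme reduces to a single cutoff.
#'
#' @param trace A `distance_trace` tibble (or data frame with `t_ns`,
#'   `distance_A`).
#' @param threshold_low Enter-bound cutoff, Angstrom.
#' @param threshold_high Leave-bound cutoff, Angstrom
#'   (`>= threshold_low`).
#' @param min_dwell Minimum dwell duration, ns; shorter runs are merged
#'   (default 0, no merging).
#' @return A `bound_segments` tibble with columns `start_ns`, `end_ns` and
#'   attributes `threshold_low`, `threshold_high`, `trace_end_ns`, `dt_ns`.
#' @export
segment_bound_states <- function(trace, threshold_low = 5,
                                 threshold_high = 10, min_dwell = 0) {
  if (threshold_low > threshold_high) {
    abort("threshold_low must be <= threshold_high")
  }
  if (min_dwell < 0) abort("min_dwell must be >= 0")
  d <- trace$distance_A
  t <- trace$t_ns
  dt <- attr(trace, "dt_ns") %||% (t[2] - t[1])
  if (all(is.na(d))) abort("distance trace is all NaN")
  sig <- rep(NA, length(d))
  sig[!is.na(d) & d < threshold_low] <- 1L
  sig[!is.na(d) & d > threshold_high] <- 0L
  # no decisive sample at all: classify the whole trace by which threshold
  # the (finite) mean distance is closer to
  first_state <- if (any(!is.na(sig))) {
    sig[which(!is.na(sig))[1]]
  } else {
    as.integer(mean(d, na.rm = TRUE) <= (threshold_low + threshold_high) / 2)
  }
  state <- .locf(sig, first = first_state)
  r <- rle(state)
  if (min_dwell > 0) {
    repeat {
      if (length(r$lengths) <= 1L) break
      dur <- r$lengths * dt
      short <- which(dur < min_dwell)
      if (length(short) == 0) break
      i <- short[which.min(dur[short])]
      r$values[i] <- 1L - r$values[i]
      r <- rle(inverse.rle(r))
    }
  }
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1L, head(ends_idx, -1) + 1L)
  keep <- r$values == 1L
  trace_end <- t[length(t)] + dt
  segs <- tibble(
    start_ns = t[starts_idx[keep]],
    end_ns = t[ends_idx[keep]] + dt
  )
  structure(segs, threshold_low = threshold_low,
            threshold_high = threshold_high,
            trace_end_ns = trace_end, dt_ns = dt,
            class = c("bound_segments", class(tibble())))
}

#' Residence-time statistics of bound segments
#'
#' Mean and median residence time, event count and total bound fraction of
#' the segmentation. With `censor_last = TRUE`, a segment that runs into the
#' end of the trace is dropped as an incomplete (right-censored) dwell. An
#' empty result (zero segments after censoring) is returned as a row of
#' `NA`s with `n_events = 0`, not an error.
#'
#' @param segments A `bound_segments` tibble from [segment_bound_states()].
#' @param censor_last Drop a final segment that abuts the trace end.
#' @return A one-row tibble: `mean_ns`, `median_ns`, `n_events`,
#'   `total_bound_fraction`.
#' @export
residence_stats <- function(segments, censor_last = FALSE) {
  if (nrow(segments) < 1) abort("residence_stats needs at least one segment")
  trace_end <- attr(segments, "trace_end_ns")
  dt <- attr(segments, "dt_ns") %||% 0
  segs <- as_tibble(segments)
  total_bound <- sum(segs$end_ns - segs$start_ns)
  if (censor_last && !is.null(trace_end)) {
    abuts <- segs$end_ns >= trace_end - dt / 2
    segs <- segs[!abuts, , drop = FALSE]
  }
  durations <- segs$end_ns - segs$start_ns
  if (length(durations) == 0) {
    return(tibble(mean_ns = NA_real_, median_ns = NA_real_, n_events = 0L,
                  total_bound_fraction = if (!is.null(trace_end))
                    total_bound / trace_end else NA_real_))
  }
  tibble(
    mean_ns = mean(durations),
    median_ns = median(durations),
    n_events = length(durations),
    total_bound_fraction = if (!is.null(trace_end)) total_bound / trace_end
      else NA_real_
  )
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# map degrees into (-180, 180]
.wrap_deg <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

#' Signed dihedral angle of four points
#'
#' The torsion about the p2-p3 axis in the IUPAC sign convention: 0 for a
#' cis (eclipsed) arrangement, positive for a clockwise rotation of the far
#' bond when sighting from p2 towards p3, returned in degrees in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinates, Angstrom.
#' @return Signed dihedral in degrees.
#' @examples
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1)) # -90
#' @export
dihedral <- function(p1, p2, p3, p4) {
  pts <- list(p1, p2, p3, p4)
  if (any(vapply(pts, length, 1L) != 3L)) {
    abort("each point must be a length-3 coordinate")
  }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b2^2)) < 1e-12) abort("p2 and p3 coincide")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  scale <- max(sqrt(sum(b1^2)), sqrt(sum(b2^2)), sqrt(sum(b3^2)))^2
  if (sqrt(sum(n1^2)) < 1e-10 * scale) {
    abort("p1, p2, p3 are collinear; the dihedral is undefined")
  }
  if (sqrt(sum(n2^2)) < 1e-10 * scale) {
    abort("p2, p3, p4 are collinear; the dihedral is undefined")
  }
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- .cross3(n1, b2n)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  .wrap_deg(atan2(y, x) * 180 / pi)
}

#' Circular mean of angles
#'
#' The direction of the mean resultant vector,
#' `atan2(mean(sin), mean(cos))`, in degrees in (-180, 180]. When the
#' resultant length is (numerically) zero the mean direction is undefined
#' and an error is raised.
#'
#' @param angles Angles in degrees.
#' @return Circular mean in degrees.
#' @examples
#' circular_mean(c(170, -170)) # 180
#' @export
circular_mean <- function(angles) {
  if (length(angles) == 0) abort("angles must be non-empty")
  rad <- angles * pi / 180
  s <- mean(sin(rad)); c_ <- mean(cos(rad))
  if (sqrt(s^2 + c_^2) < 1e-8) {
    abort("resultant length ~ 0: circular mean undefined for (near-)uniform angles")
  }
  .wrap_deg(atan2(s, c_) * 180 / pi)
}
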
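#' Growth phases of an OD curve
#'
#' Contiguous, ordered, half-open time intervals `[start, end)` covering
#' the curve: lag, exponential, linear, stationary. Boundaries snap to
#' sample times. Empty intervals (`start == end`) are allowed for every
#' phase except exponential.
#'
#' @param lag,exponential,linear,stationary numeric length-2 vectors
#'   (seconds).
#' @return object of class `GrowthPhases`.
#' @export
growth_phases <- function(lag, exponential, linear, stationary) {
  b <- c(lag, exponential, linear, stationary)
  if (any(diff(c(lag[1], lag[2], exponential[2], linear[2], stationary[2])) < 0) ||
      lag[2] != exponential[1] || exponential[2] != linear[1] ||
      linear[2] != stationary[1]) {
    stop_format("growth phases must be contiguous, ordered and non-overlapping")
  }
  if (exponential[2] <= exponential[1]) {
    stop_format("exponential phase must have positive duration")
  }
  structure(list(lag = lag, exponential = exponential, linear = linear,
                 stationary = stationary),
            class = "GrowthPhases")
}

#' @export
print.GrowthPhases <- function(x, ...) {
  for (ph in c("lag", "exponential", "linear", "stationary")) {
    cat(sprintf("  %-12s [%8.0f, %8.0f) s  (%5.1f h)\n", ph, x[[ph]][1],
                x[[ph]][2], diff(x[[ph]]) / 3600))
  }
  invisible(x)
}

# Nearest-timestamp alignment of a background series onto sample times;
# errors if any gap exceeds half the sampling interval.
align_series <- function(sample_times, bg_times, bg_values, what) {
  tol <- stats::median(diff(sample_times)) / 2
  idx <- vapply(sample_times, function(t) which.min(abs(bg_times - t)), 0L)
  if (any(abs(bg_times[idx] - sample_times) > tol)) {
    stop_format("cannot align %s background: time grids differ by more than half the sampling interval", what)
  }
  bg_values[idx]
}

#' Subtract background curves from a well time course
#'
#' OD is corrected with the media blank, YFP with an mCherry-only strain
#' (role `yfp_background_strain`) and mCherry with a YFP-only strain
#' (role `mcherry_background_strain`). OD is floored at 0 (and the
#' flooring flagged); fluorescence is allowed to go slightly negative.
#'
#' @param tc a [time_course()].
#' @param blanks role-keyed list of background `TimeCourse`s, as returned
#'   in `$backgrounds` by [load_plate_timecourses()] or
#'   [simulate_plate_timecourses()].
#' @return corrected `TimeCourse` with attribute `qc` (number of floored
#'   OD points).
#' @export
subtract_background <- function(tc, blanks) {
  needed <- c("media_blank", "yfp_background_strain",
              "mcherry_background_strain")
  missing_roles <- setdiff(needed, names(blanks))
  if (length(missing_roles)) {
    stop_format("missing background role(s): %s",
                paste(missing_roles, collapse = ", "))
  }
  od_bg <- align_series(tc$times, blanks$media_blank$times,
                        blanks$media_blank$od, "OD")
  yfp_bg <- align_series(tc$times, blanks$yfp_background_strain$times,
                         blanks$yfp_background_strain$yfp, "YFP")
  mch_bg <- align_series(tc$times, blanks$mcherry_background_strain$times,
                         blanks$mcherry_background_strain$mcherry, "mCherry")
  od <- tc$od - od_bg
  floored <- sum(od < 0)
  out <- time_course(tc$well_id, tc$strain_id, tc$times,
                     pmax(od, 0), tc$yfp - yfp_bg, tc$mcherry - mch_bg,
                     mask = tc$mask)
  attr(out, "qc") <- list(od_points_floored = floored)
  out
}

#' Flag isolated point outliers in a measurement series
#'
#' A point is flagged when its deviation from the running window median
#' exceeds `k` times a robust local scale. The scale is the larger of
#' (i) the window MAD of the median-detrended residuals -- working on
#' residuals rather than raw window values keeps the estimate from being
#' inflated by a steep growth trend, which would otherwise shield spikes
#' riding the exponential rise -- and (ii) a floor from the median
#' absolute first difference in a doubled window, which prevents the
#' residual MAD from collapsing to zero on locally monotone stretches
#' (where the running median reproduces every point exactly and a single
#' noise inversion would otherwise be flagged). With an all-constant
#' window both scales are 0 and only exact deviations from the constant
#' are flagged, so constant series yield no outliers.
#'
#' @param series numeric values per time point.
#' @param k MAD multiplier (default 5).
#' @param w window size in points, odd, >= 3 (default 5).
#' @return logical vector, `TRUE` = outlier. Attribute `frac_flagged`
#'   carries the flagged fraction; if it exceeds 10% the attribute
#'   `qc_warning` is set.
#' @export
remove_point_outliers <- function(series, k = 5, w = 5L) {
  n <- length(series)
  if (w %% 2L != 1L || w < 3L) stop_format("window w must be odd and >= 3")
  if (n <= w) stop_format("series length must exceed window size")
  h <- w %/% 2L
  med <- vapply(seq_len(n), function(i) {
    stats::median(series[max(1L, i - h):min(n, i + h)])
  }, 0)
  resid <- series - med
  steps <- abs(diff(series))
  flag <- logical(n)
  for (i in seq_len(n)) {
    win <- abs(resid[max(1L, i - h):min(n, i + h)])
    # first differences around i, excluding the two touching point i
    # (a spike must not set its own scale)
    dj <- setdiff(max(1L, i - 2L * h):min(n - 1L, i + 2L * h - 1L),
                  c(i - 1L, i))
    floor_d <- if (length(dj)) 1.4826 / sqrt(2) * stats::median(steps[dj]) else 0
    spread <- max(1.4826 * stats::median(win), floor_d)
    dev <- abs(resid[i])
    flag[i] <- if (spread == 0) dev > 0 else dev > k * spread
  }
  attr(flag, "frac_flagged") <- mean(flag)
  if (mean(flag) > 0.10) attr(flag, "qc_warning") <- "more than 10% of points flagged"
  flag
}

#' Mask point outliers in all three channels of a time course
#'
#' Applies [remove_point_outliers()] independently to OD, YFP and mCherry
#' and removes flagged points from the validity mask. The rule is
#' iterated on the surviving points (up to `max_iter` passes) because two
#' spikes falling in the same window can shield each other from a single
#' MAD pass.
#'
#' @param tc a [time_course()].
#' @param k,w see [remove_point_outliers()].
#' @param max_iter maximum masking passes (default 3).
#' @return `TimeCourse` with updated mask.
#' @export
mask_timecourse_outliers <- function(tc, k = 5, w = 5L, max_iter = 3L) {
  for (pass in seq_len(max_iter)) {
    live <- which(tc$mask)
    if (length(live) <= w) break
    flags <- remove_point_outliers(tc$od[live], k, w) |
      remove_point_outliers(tc$yfp[live], k, w) |
      remove_point_outliers(tc$mcherry[live], k, w)
    if (!any(flags)) break
    tc$mask[live[flags]] <- FALSE
  }
  tc
}

# Outlier-clean a background well: flagged points are replaced by cubic
# spline interpolation from their neighbors, so that a spike in a shared
# blank cannot corrupt every sample well at that time point. (Linear
# interpolation is not enough: on a growing background curve it leaves a
# curvature kink at the repaired point that the per-well outlier rule
# then flags in every sample well.)
clean_background_timecourse <- function(tc, k = 5, w = 5L) {
  for (channel in c("od", "yfp", "mcherry")) {
    flags <- remove_point_outliers(tc[[channel]], k, w)
    if (any(flags)) {
      good <- which(!flags)
      tc[[channel]][flags] <- stats::spline(
        tc$times[good], tc[[channel]][good], xout = tc$times[flags],
        method = "natural")$y
    }
  }
  tc
}

# Centered moving linear-fit slope over w points (endpoints use the
# truncated window). Exact on straight-line data regardless of window
# asymmetry.
moving_slope <- function(x, y, w = 5L) {
  n <- length(x)
  h <- w %/% 2L
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - h):min(n, i + h)
    xs <- x[j] - mean(x[j])
    sum(xs * y[j]) / sum(xs^2)
  }, 0)
}

#' Segment an OD curve into growth phases
#'
#' The smoothed derivative of `log(OD + eps)` defines the exponential
#' phase as the longest contiguous run of points at or above
#' `expo_frac` times its maximum; lag is everything before. The
#' stationary phase is the trailing run where the smoothed `d(OD)/dt`
#' falls to at most `stat_frac` of its own maximum; the linear phase is
#' the remainder in between. Boundaries snap to sample times.
#'
#' @param tc a background-subtracted [time_course()] (masked points are
#'   ignored).
#' @param expo_frac threshold on the log-slope, as a fraction of its
#'   maximum (default 0.55, calibrated on simulated logistic curves: the
#'   detected exponential phase then ends at the entry into the
#'   inflection region, where the linear phase begins).
#' @param stat_frac threshold on dOD/dt for stationarity (default 0.05).
#' @param smooth_points window for the moving linear fit (default 5).
#' @param eps additive OD offset in the log transform (default 1e-4).
#' @return a [growth_phases()] object. Curves never reaching 3x their
#'   initial OD raise a "no growth" error rather than returning a
#'   degenerate phase set.
#' @export
segment_growth_phases <- function(tc, expo_frac = 0.55, stat_frac = 0.05,
                                  smooth_points = 5L, eps = 1e-4) {
  keep <- tc$mask & tc$od > 0   # log-derivative undefined at floored zeros
  x <- tc$times[keep]
  od <- tc$od[keep]
  n <- length(x)
  if (n < 6L) stop_format("well '%s': too few points to segment", tc$well_id)
  init <- max(od[1L], eps)
  if (max(od) < 3 * init) {
    stop_format("well '%s': no growth (OD never reaches 3x initial)", tc$well_id)
  }
  # running-median pre-smoothing: exact on monotone curves, crushes any
  # spike that slipped past the point-outlier mask
  logod <- stats::runmed(log(od + eps), smooth_points, endrule = "median")
  lslope <- moving_slope(x, logod, smooth_points)
  in_expo <- lslope >= expo_frac * max(lslope)
  runs <- rle(in_expo)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values)
  best <- ok[which.max(runs$lengths[ok])]
  i1 <- starts[best]
  i2 <- ends[best]

  dod <- moving_slope(x, stats::runmed(od, smooth_points, endrule = "median"),
                      smooth_points)
  thr <- stat_frac * max(dod)
  below <- dod <= thr
  j <- n + 1L
  while (j > 1L && below[j - 1L]) j <- j - 1L
  j <- max(j, i2 + 1L)

  step <- stats::median(diff(x))
  bound <- function(i) if (i <= n) x[i] else x[n] + step
  b0 <- x[1L]; b1 <- x[i1]; b2 <- bound(i2 + 1L)
  b3 <- max(b2, bound(j)); b4 <- max(b3, x[n] + step)
  growth_phases(lag = c(b0, b1), exponential = c(b1, b2),
                linear = c(b2, b3), stationary = c(b3, b4))
}

# Trapezoidal integral over sample points.
trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)

#' Per-cell protein production rate during exponential phase
#'
#' The single expression value per induction curve: total fluorescence
#' gained during the exponential phase divided by the time integral of
#' the OD curve over the same window (trapezoidal integration over
#' unmasked points). Units: a.u. per OD-unit per second.
#'
#' @param tc a background-subtracted, outlier-masked [time_course()].
#' @param phases a [growth_phases()] object for this well.
#' @param channel `"yfp"` (default) or `"mcherry"`.
#' @return object of class `ExpressionMeasure`: list with `strain_id`,
#'   `production`, `window` (seconds), `qc`.
#' @export
production_per_cell <- function(tc, phases, channel = c("yfp", "mcherry")) {
  channel <- match.arg(channel)
  win <- phases$exponential
  pts <- which(tc$mask & tc$times >= win[1] & tc$times < win[2])
  if (length(pts) < 2L) {
    stop_format("well '%s': exponential phase contains fewer than 2 usable points",
                tc$well_id)
  }
  f <- tc[[channel]][pts]
  od_int <- trapz(tc$times[pts], tc$od[pts])
  if (od_int <= 0) {
    stop_format("well '%s': OD integral over exponential phase is not positive",
                tc$well_id)
  }
  structure(
    list(strain_id = tc$strain_id, well_id = tc$well_id,
         production = (f[length(f)] - f[1L]) / od_int,
         window = win, channel = channel,
         qc = list(n_points = length(pts),
                   n_masked = sum(!tc$mask))),
    class = "ExpressionMeasure"
  )
}

#' @export
print.ExpressionMeasure <- function(x, ...) {
  cat(sprintf("<ExpressionMeasure> %s (%s): %.4g a.u./OD/s over [%.0f, %.0f) s\n",
              x$strain_id, x$channel, x$production, x$window[1], x$window[2]))
  invisible(x)
}

#' Process a whole plate into per-strain production values
#'
#' Background subtraction, outlier masking, phase segmentation and
#' production integration for every sample well, then averaging of
#' replicate wells per strain.
#'
#' @param plate list with `samples` and `backgrounds`, as returned by
#'   [load_plate_timecourses()] or [simulate_plate_timecourses()].
#' @param channel `"yfp"` or `"mcherry"`.
#' @param k,w outlier-rule parameters (see [remove_point_outliers()]).
#' @param normalize_mcherry divide YFP production by mCherry production
#'   per well (default `FALSE`: raw YFP values are used).
#' @return data.frame with one row per strain: `strain_id`, `production`
#'   (replicate mean), `sd`, `n_wells`.
#' @export
plate_expression <- function(plate, channel = c("yfp", "mcherry"),
                             k = 5, w = 5L, normalize_mcherry = FALSE) {
  channel <- match.arg(channel)
  blanks <- lapply(plate$backgrounds, clean_background_timecourse, k = k, w = w)
  per_well <- lapply(plate$samples, function(tc) {
    tc <- subtract_background(tc, blanks)
    tc <- mask_timecourse_outliers(tc, k = k, w = w)
    phases <- segment_growth_phases(tc)
    p <- production_per_cell(tc, phases, channel)$production
    if (normalize_mcherry && channel == "yfp") {
      p <- p / production_per_cell(tc, phases, "mcherry")$production
    }
    data.frame(strain_id = tc$strain_id, well_id = tc$well_id,
               production = p)
  })
  wells <- do.call(rbind, per_well)
  agg <- aggregate(production ~ strain_id, wells, mean)
  agg$sd <- aggregate(production ~ strain_id, wells, sd)$production
  agg$n_wells <- aggregate(production ~ strain_id, wells, length)$production
  agg
}

#' Accept strains whose independent clones agree
#'
#' A strain is accepted when at least one pair of its clones shows a
#' relative production difference `|p1 - p2| / mean(p1, p2)` of at most
#' `tol`; its value is the mean of the best (most concordant) pair.
#' Strains with a single clone are reported as unvalidated, neither
#' accepted nor rejected.
#'
#' @param measures data.frame with columns `strain_id` and `production`
#'   (one row per clone), or a list of `ExpressionMeasure` objects.
#' @param tol maximum relative discrepancy (default 0.15).
#' @return data.frame: `strain_id`, `status` (accepted / rejected /
#'   unvalidated), `value`, `n_clones`, `best_discrepancy`.
#' @export
concordant_clone_filter <- function(measures, tol = 0.15) {
  if (is.list(measures) && inherits(measures[[1L]], "ExpressionMeasure")) {
    measures <- data.frame(
      strain_id = vapply(measures, `[[`, "", "strain_id"),
      production = vapply(measures, `[[`, 0, "production"))
  }
  out <- lapply(split(measures, measures$strain_id), function(grp) {
    p <- grp$production
    if (length(p) < 2L) {
      return(data.frame(strain_id = grp$strain_id[1L], status = "unvalidated",
                        value = NA_real_, n_clones = length(p),
                        best_discrepancy = NA_real_))
    }
    pairs <- utils::combn(length(p), 2L)
    disc <- apply(pairs, 2L, function(ij) {
      abs(p[ij[1]] - p[ij[2]]) / mean(p[ij])
    })
    best <- which.min(disc)
    accepted <- disc[best] <= tol
    data.frame(
      strain_id = grp$strain_id[1L],
      status = if (accepted) "accepted" else "rejected",
      value = if (accepted) mean(p[pairs[, best]]) else NA_real_,
      n_clones = length(p), best_discrepancy = disc[best])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
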
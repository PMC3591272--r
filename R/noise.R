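#' Gate specification for single-cell populations
#'
#' The automatic gate keeps cells within `k` MADs of the median in both
#' forward and side scatter (removing spores and outlier-scatter cells),
#' optionally restricted to a central mCherry band to reduce extrinsic
#' variation.
#'
#' @param k MAD multiplier (> 0; default 2.5).
#' @param mcherry_band central mCherry quantile band to keep, e.g.
#'   `c(0.05, 0.95)` for the middle 90%, or `NULL` to skip (default).
#' @param min_cells minimum usable cells before and after gating
#'   (default 500).
#' @return object of class `GateSpec`.
#' @export
gate_spec <- function(k = 2.5, mcherry_band = NULL, min_cells = 500L) {
  stopifnot(k > 0)
  if (!is.null(mcherry_band)) {
    stopifnot(length(mcherry_band) == 2L, mcherry_band[1] < mcherry_band[2],
              mcherry_band[1] >= 0, mcherry_band[2] <= 1)
  }
  structure(list(k = k, mcherry_band = mcherry_band,
                 min_cells = as.integer(min_cells)),
            class = "GateSpec")
}

# Robust band: within k MADs of the median. With MAD = 0 (all-identical
# channel) only exact deviants fall outside, so none are removed.
in_robust_band <- function(x, k) {
  med <- stats::median(x)
  m <- stats::mad(x, center = med)
  if (m == 0) abs(x - med) == 0 else abs(x - med) <= k * m
}

#' Gate a cell population on scatter (and optionally mCherry)
#'
#' @param pop a `CellPopulation` (see [simulate_cell_population()] /
#'   [read_cell_table()]).
#' @param spec a [gate_spec()].
#' @return the gated `CellPopulation`, with attribute `gate_report`
#'   (fractions removed per criterion). Errors with "over-gated" if fewer
#'   than `min_cells` survive.
#' @export
gate_cells <- function(pop, spec = gate_spec()) {
  n <- nrow(pop)
  if (n < spec$min_cells) {
    stop_format("population has %d cells, below min_cells = %d", n,
                spec$min_cells)
  }
  keep_fsc <- in_robust_band(pop$fsc, spec$k)
  keep_ssc <- in_robust_band(pop$ssc, spec$k)
  keep <- keep_fsc & keep_ssc
  removed_mch <- 0
  if (!is.null(spec$mcherry_band)) {
    qs <- quantile(pop$mcherry[keep], spec$mcherry_band)
    keep_mch <- pop$mcherry >= qs[1L] & pop$mcherry <= qs[2L]
    removed_mch <- mean(keep & !keep_mch)
    keep <- keep & keep_mch
  }
  if (sum(keep) < spec$min_cells) {
    stop_format("over-gated: %d of %d cells remain (min_cells = %d)",
                sum(keep), n, spec$min_cells)
  }
  out <- pop[keep, , drop = FALSE]
  for (a in c("strain_id", "condition", "burst")) {
    attr(out, a) <- attr(pop, a)
  }
  if (!is.null(attr(pop, "spore"))) attr(out, "spore") <- attr(pop, "spore")[keep]
  class(out) <- class(pop)
  attr(out, "gate_report") <- list(
    n_before = n, n_after = sum(keep),
    frac_removed_fsc = mean(!keep_fsc),
    frac_removed_ssc = mean(!keep_ssc),
    frac_removed_mcherry = removed_mch,
    frac_removed_total = 1 - sum(keep) / n
  )
  out
}

#' Noise and burst statistics of a cell population
#'
#' From the per-cell distribution of one channel: mean, unbiased
#' variance, noise (variance over squared mean), noise strength (variance
#' over mean), and the gamma-burst-model readouts -- burst frequency as
#' the inverse of the noise and burst size as the noise strength. The
#' identities `noise_strength = noise * mean` and
#' `burst_frequency * burst_size = mean` hold exactly by construction.
#'
#' @param pop a (typically gated) `CellPopulation`.
#' @param channel `"yfp"` (default) or `"mcherry"`.
#' @return one-row data.frame of class `NoiseStats`: `strain_id`,
#'   `condition`, `n_cells`, `mean`, `variance`, `noise`,
#'   `noise_strength`, `burst_frequency`, `burst_size`.
#' @export
population_noise_stats <- function(pop, channel = c("yfp", "mcherry")) {
  channel <- match.arg(channel)
  x <- pop[[channel]]
  if (length(x) < 2L) stop_format("need at least 2 cells")
  mu <- mean(x)
  if (mu <= 0) {
    stop_format("non-positive mean in channel '%s' (background over-subtraction upstream?)",
                channel)
  }
  v <- var(x)
  noise <- v / mu^2
  out <- data.frame(
    strain_id = attr(pop, "strain_id") %||% NA_character_,
    condition = attr(pop, "condition") %||% NA_real_,
    n_cells = length(x), mean = mu, variance = v,
    noise = noise, noise_strength = v / mu,
    burst_frequency = 1 / noise, burst_size = v / mu
  )
  class(out) <- c("NoiseStats", "data.frame")
  out
}

#' Correct noise statistics for between-plate intensity differences
#'
#' Plates measured on different days differ by a multiplicative intensity
#' factor. A galactose-insensitive reference strain present on every
#' plate defines the correction `c_p = grand mean of the reference across
#' plates / reference mean on plate p`. Means scale as `mean' = mean *
#' c_p`; since squared noise scales as 1/mean, noise corrects as
#' `noise' = noise / c_p`; the corrected noise strength is the product of
#' the corrected noise and corrected mean, which preserves
#' `noise_strength' = noise * mean`.
#'
#' @param stats data.frame with columns `strain_id`, `plate`, `mean`,
#'   `noise` (e.g. stacked [population_noise_stats()] rows plus a `plate`
#'   column).
#' @param reference strain id of the reference strain; must be present on
#'   every plate.
#' @return the input with corrected columns `mean`, `noise`,
#'   `noise_strength`, `burst_frequency`, `burst_size`, plus
#'   `plate_factor`.
#' @export
plate_correct <- function(stats, reference) {
  stats <- as.data.frame(stats)
  stopifnot(all(c("strain_id", "plate", "mean", "noise") %in% names(stats)))
  plates <- unique(stats$plate)
  ref_rows <- stats[stats$strain_id == reference, ]
  missing_plates <- setdiff(plates, ref_rows$plate)
  if (length(missing_plates)) {
    stop_format("reference strain '%s' missing on plate(s): %s", reference,
                paste(missing_plates, collapse = ", "))
  }
  ref_mean <- tapply(ref_rows$mean, ref_rows$plate, mean)
  grand <- mean(ref_mean)
  c_p <- grand / ref_mean[as.character(stats$plate)]
  stats$plate_factor <- as.numeric(c_p)
  stats$mean <- stats$mean * stats$plate_factor
  stats$noise <- stats$noise / stats$plate_factor
  stats$noise_strength <- stats$noise * stats$mean
  stats$burst_frequency <- 1 / stats$noise
  stats$burst_size <- stats$noise_strength
  stats
}
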
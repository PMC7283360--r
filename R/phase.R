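# Phase classification from the low-q power law and Bragg diffraction
# peaks: lamellar stacks scatter as I ~ q^-2 with peaks at q = 2 pi n / d,
# HU-coated DNA filaments as featureless rods with I ~ q^-1, and
# aggregates as steep featureless decays.

#' Fit a low-q power law I(q) ~ q^alpha
#'
#' Linear regression of log I on log q over a q-window; returns the
#' exponent (log-log slope) and its standard error.
#'
#' @param profile a [saxs_profile].
#' @param window numeric length-2 q-interval, 1/Angstrom.
#' @return A list with `exponent` and `exponent_se`.
#' @export
fit_power_law <- function(profile, window) {
  stopifnot(inherits(profile, "saxs_profile"), length(window) == 2)
  idx <- which(profile$q >= window[1] & profile$q <= window[2])
  if (length(idx) < 8) stop("fit_power_law: fewer than 8 points in window")
  if (any(profile$intensity[idx] <= 0))
    stop("fit_power_law: non-positive intensities in window")
  X <- cbind(1, log(profile$q[idx]))
  y <- log(profile$intensity[idx])
  f <- stats::lm.fit(X, y)
  s2 <- sum(f$residuals^2) / max(length(idx) - 2, 1)
  cov22 <- chol2inv(chol(crossprod(X)))[2, 2]
  list(exponent = unname(f$coefficients[2]),
       exponent_se = sqrt(s2 * cov22))
}

#' Detect diffraction peaks in a scattering profile
#'
#' Divides out a robustly fitted power-law baseline (in log space),
#' smooths the residual with a Savitzky-Golay filter, and measures each
#' local maximum's height above a running-median local baseline. Peaks are
#' kept when that height exceeds (a) `prominence_mad` times the median
#' absolute deviation of the baseline residuals, (b) an absolute floor
#' `min_height` in log-intensity units, and (c) `rel_height` times the
#' tallest peak -- the last two suppress the finite-stack (Laue) fringes
#' and high-q noise wiggles that a pure MAD rule admits.
#'
#' @param profile a [saxs_profile] with at least 50 points.
#' @param prominence_mad peak-height floor in units of the residual MAD,
#'   default 3.
#' @param min_height absolute height floor in log-intensity units,
#'   default 0.25 (a peak must rise ~30 percent above its surroundings).
#' @param rel_height minimum height relative to the tallest detected
#'   peak, default 0.4.
#' @param sg_window,sg_order Savitzky-Golay window length (odd) and
#'   polynomial order, defaults 11 and 3.
#' @return A data.frame with columns `q_star` (peak position, 1/Angstrom)
#'   and `prominence` (height above local baseline, log-intensity units),
#'   sorted by q; zero rows when no peak is found.
#' @export
detect_peaks <- function(profile, prominence_mad = 3, min_height = 0.25,
                         rel_height = 0.4, sg_window = 11, sg_order = 3) {
  stopifnot(inherits(profile, "saxs_profile"))
  q <- profile$q; I <- profile$intensity
  if (length(q) < 50) stop("detect_peaks: need at least 50 points")
  ok <- I > 0
  q <- q[ok]; I <- I[ok]
  # robust power-law baseline: refit excluding the top residual quintile so
  # diffraction peaks do not drag the baseline up
  X <- cbind(1, log(q))
  f <- stats::lm.fit(X, log(I))
  resid <- unname(f$residuals)
  for (i in 1:3) {
    keep <- resid < stats::quantile(resid, 0.8)
    if (sum(keep) < 10) break    # residuals already at numerical noise
    f <- stats::lm.fit(X[keep, , drop = FALSE], log(I[keep]))
    resid <- as.vector(log(I) - X %*% f$coefficients)
  }
  sm <- signal::sgolayfilt(resid, p = sg_order, n = sg_window)
  n <- length(sm)
  base <- stats::runmed(sm, k = min(61L, 2L * (n %/% 2L) - 1L))
  height <- sm - base
  cand <- which(diff(sign(diff(sm))) == -2) + 1L
  cand <- cand[cand > 2 & cand < n - 1]
  if (!length(cand)) return(data.frame(q_star = numeric(0),
                                       prominence = numeric(0)))
  # candidates in the lowest ~half-decade have no left-side baseline to
  # judge them against (finite-stack fringes live there); require
  # q* >= 3 qmin
  cand <- cand[q[cand] >= 3 * q[1]]
  if (!length(cand)) return(data.frame(q_star = numeric(0),
                                       prominence = numeric(0)))
  h <- height[cand]
  floor_ <- max(prominence_mad * stats::mad(resid - base), min_height)
  keep <- h >= floor_ & sm[cand] > 0 & h >= rel_height * max(h)
  data.frame(q_star = q[cand[keep]], prominence = h[keep])
}

#' Convert a Bragg peak position to a real-space repeat spacing
#'
#' For a first-order lamellar reflection at q*, the repeat distance is
#' d = 2 pi / q*.
#'
#' @param q_star peak position(s), 1/Angstrom; must be positive.
#' @return Spacing(s) in Angstrom.
#' @examples
#' bragg_spacing(2 * pi / 42)  # 42 A, lamellar DNA spacing
#' @export
bragg_spacing <- function(q_star) {
  if (any(!is.finite(q_star)) || any(q_star <= 0))
    stop("bragg_spacing: q_star must be positive")
  2 * pi / q_star
}

#' Classify a scattering profile as lamellar, filament or aggregate
#'
#' Computes the initial (low-q) log-log slope and the diffraction peaks,
#' then labels the profile: `lamellar` if the exponent lies in
#' `lamellar_range` and at least one peak is present; `filament` if the
#' exponent lies in `filament_range` with no peak; `aggregate` if the
#' exponent is at or below `aggregate_max`; otherwise `ambiguous`.
#'
#' The slope is measured on a fringe-averaged copy of the intensity
#' (running mean over `avg_window` points in linear space) so that the
#' finite-stack (Laue) oscillations of ordered lamellar phases average to
#' their envelope before the log-log regression; the fit window runs from
#' the lowest usable q to 0.9 x the first Bragg peak (or over the lowest
#' decade when no peak is present). The default lamellar band reaches
#' below the ideal sheet exponent -2 because a finite stack of N plates
#' adds a 1/q^2 finite-size term below q ~ 2 pi / (N d) that steepens the
#' initial slope.
#'
#' @param profile a [saxs_profile] spanning at least one decade in q.
#' @param lamellar_range,filament_range,aggregate_max classification
#'   thresholds on the exponent; defaults c(-2.95, -1.5), c(-1.4, -0.6)
#'   and -3.
#' @param avg_window fringe-averaging running-mean length (points); the
#'   default `NULL` scales with grid density (about a tenth of the
#'   points) so the averaged q-span is grid-independent.
#' @param ... passed to [detect_peaks].
#' @return A list of class `phase_call`: `label`, `exponent`,
#'   `exponent_se`, `window`, and `peaks` (data.frame with `q_star`, `d`,
#'   `prominence`).
#' @export
classify_phase <- function(profile, lamellar_range = c(-2.95, -1.5),
                           filament_range = c(-1.4, -0.6),
                           aggregate_max = -3, avg_window = NULL, ...) {
  stopifnot(inherits(profile, "saxs_profile"))
  q <- profile$q
  if (max(q) / min(q) < 10)
    stop("classify_phase: profile must span at least one decade in q")
  peaks <- detect_peaks(profile, ...)
  if (is.null(avg_window))
    avg_window <- 2L * (length(q) %/% 20L) + 1L
  k <- min(avg_window, 2L * (length(q) %/% 4L) - 1L)
  Ism <- as.vector(stats::filter(profile$intensity, rep(1 / k, k),
                                 sides = 2))
  ok <- !is.na(Ism) & Ism > 0
  smoothed <- saxs_profile(q[ok], Ism[ok])
  qhi <- if (nrow(peaks) > 0) 0.9 * peaks$q_star[1] else min(q) * 10
  window <- c(min(smoothed$q), min(qhi, max(smoothed$q)))
  if (sum(smoothed$q >= window[1] & smoothed$q <= window[2]) < 8)
    window <- c(min(smoothed$q), min(q) * 10)   # peak too close to qmin
  pl <- fit_power_law(smoothed, window)
  a <- pl$exponent
  label <- if (a <= aggregate_max) "aggregate"
  else if (nrow(peaks) >= 1 && a >= lamellar_range[1] && a <= lamellar_range[2])
    "lamellar"
  else if (nrow(peaks) == 0 && a >= filament_range[1] && a <= filament_range[2])
    "filament"
  else "ambiguous"
  if (nrow(peaks) > 0) peaks$d <- bragg_spacing(peaks$q_star)
  else peaks$d <- numeric(0)
  structure(list(label = label, exponent = a, exponent_se = pl$exponent_se,
                 window = window,
                 peaks = peaks[, c("q_star", "d", "prominence")]),
            class = "phase_call")
}

#' @export
print.phase_call <- function(x, ...) {
  cat(sprintf("Phase call: %s (exponent %.2f +/- %.2f over q in [%.4g, %.4g])\n",
              x$label, x$exponent, x$exponent_se, x$window[1], x$window[2]))
  if (nrow(x$peaks)) {
    cat("  peaks:\n")
    for (i in seq_len(nrow(x$peaks)))
      cat(sprintf("    q* = %.4f 1/A  d = %.1f A  prominence %.2f\n",
                  x$peaks$q_star[i], x$peaks$d[i], x$peaks$prominence[i]))
  }
  invisible(x)
}
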
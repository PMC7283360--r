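# Real-space analysis: pair-distance distributions P(r) from bead models,
# regularized indirect Fourier transform (IFT) from measured profiles, and
# the Dmax / Rg quantities derived from them.

#' Construct a pair-distance distribution function
#'
#' @param r equally spaced distance grid from 0 to dmax, Angstrom.
#' @param p distribution values at `r`; the convention is p(0) = 0 and
#'   p(dmax) ~ 0 within grid resolution.
#' @param dmax maximal dimension, Angstrom.
#' @param alpha regularization strength used by [ift] (NA for
#'   coordinate-derived distributions).
#' @param fit_chi2 reduced chi-squared of the reciprocal-space fit (NA for
#'   coordinate-derived distributions).
#' @param self_fraction for bead-derived distributions, the weight
#'   fraction of self pairs, sum(w_i^2) / (sum w)^2 -- the delta mass at
#'   r = 0 that a distinct-pair histogram omits; 0 for continuous
#'   densities.
#' @return An object of class `pddf`.
#' @export
pddf <- function(r, p, dmax = max(r), alpha = NA_real_,
                 fit_chi2 = NA_real_, self_fraction = 0) {
  r <- as.numeric(r); p <- as.numeric(p)
  stopifnot(length(r) == length(p), length(r) >= 3, dmax > 0,
            self_fraction >= 0, self_fraction < 1)
  dr <- diff(r)
  if (any(abs(dr - dr[1]) > 1e-8 * dr[1]))
    stop("pddf: r grid must be equally spaced")
  structure(list(r = r, p = p, dmax = dmax, alpha = alpha,
                 fit_chi2 = fit_chi2, self_fraction = self_fraction),
            class = "pddf")
}

#' @export
print.pddf <- function(x, ...) {
  cat(sprintf("P(r): %d grid points, Dmax = %.1f A, Rg = %.2f A%s\n",
              length(x$r), x$dmax, rg_from_pr(x),
              if (is.finite(x$alpha))
                sprintf(" (IFT, alpha = %.3g, chi2 = %.3g)",
                        x$alpha, x$fit_chi2) else ""))
  invisible(x)
}

#' Pair-distance distribution of a bead model
#'
#' Weighted histogram of all pairwise bead distances (pair weight
#' w_i w_j); `dmax` is the exact maximum pairwise distance and the
#' distribution is normalized to unit integral.
#'
#' @param model an [atomistic_model] with at least 2 beads.
#' @param nbins number of distance bins, default 200.
#' @return A [pddf] on `nbins + 1` grid points spanning 0..dmax.
#' @export
pr_from_model <- function(model, nbins = 200) {
  stopifnot(inherits(model, "atomistic_model"))
  n <- n_beads(model)
  if (n < 2) stop("pr_from_model: need at least 2 beads")
  d <- as.vector(stats::dist(model$coords))
  W <- tcrossprod(model$weight)
  w <- W[lower.tri(W)]
  dmax <- max(d)
  r <- seq(0, dmax, length.out = nbins + 1)
  h <- r[2] - r[1]
  # assign each distance to its nearest grid node; node 1 (r = 0) stays 0
  bin <- pmin(pmax(round(d / h), 1L) + 1L, nbins + 1L)
  p <- numeric(nbins + 1)
  acc <- tapply(w, bin, sum)
  p[as.integer(names(acc))] <- acc
  p <- p / pracma::trapz(r, p)
  pddf(r = r, p = p, dmax = dmax,
       self_fraction = sum(model$weight^2) / sum(model$weight)^2)
}

#' Radius of gyration from a pair-distance distribution
#'
#' Rg^2 = integral(r^2 P(r) dr) / (2 integral(P(r) dr)), corrected for
#' the self-pair delta mass at r = 0 when the distribution came from a
#' discrete bead model (so a two-point system of separation D gives
#' Rg = D/2 exactly).
#'
#' @param pddf a [pddf].
#' @return Rg in Angstrom.
#' @export
rg_from_pr <- function(pddf) {
  stopifnot(inherits(pddf, "pddf"))
  denom <- pracma::trapz(pddf$r, pddf$p)
  if (!is.finite(denom) || denom == 0)
    stop("rg_from_pr: P(r) has zero integral")
  f <- if (is.null(pddf$self_fraction)) 0 else pddf$self_fraction
  sqrt((1 - f) * pracma::trapz(pddf$r, pddf$r^2 * pddf$p) / (2 * denom))
}

# design matrix of the Fourier kernel I(q) = 4 pi int P(r) sinc(q r) dr
# on the interior nodes of an equally spaced r grid (endpoints fixed at 0)
.ift_design <- function(q, r) {
  h <- r[2] - r[1]
  ri <- r[-c(1, length(r))]
  A <- 4 * pi * h * outer(q, ri, function(qq, rr) {
    x <- qq * rr
    ifelse(x == 0, 1, sin(x) / x)
  })
  A
}

# damped least squares via the stacked system [Aw; sqrt(alpha) D] p = [yw; 0]
# (QR, not normal equations: the weight dynamic range squares otherwise)
.ift_solve <- function(A, y, w, alpha, D) {
  Aw <- A * w
  X <- rbind(Aw, sqrt(alpha) * D)
  rhs <- c(y * w, numeric(nrow(D)))
  p <- stats::lm.fit(X, rhs)$coefficients
  if (any(is.na(p)))
    stop("ift: system ill-conditioned after regularization")
  unname(p)
}

#' Indirect Fourier transform of a scattering profile
#'
#' Recovers P(r) on a fixed 101-point grid with endpoint constraints
#' p(0) = p(dmax) = 0 by weighted linear least squares of the Fourier
#' kernel I(q) = 4 pi integral P(r) sin(qr)/(qr) dr, with a
#' second-derivative smoothness penalty alpha. When `alpha` is absent it
#' is chosen as the smoothest solution consistent with the data (the
#' largest alpha within 5 percent of the best chi2 over a 20-point
#' log-spaced grid). When `dmax` is absent a
#' coarse scan locates the elbow of chi2 vs dmax, and the support is then
#' refined by solving at a generous dmax with the stiffest alpha still
#' fitting the data and reading off where |P(r)| stays below 2 percent of
#' its maximum.
#'
#' @param profile a [saxs_profile] with sigma present.
#' @param dmax maximal dimension, Angstrom; scanned when `NULL`.
#' @param alpha regularization strength; grid-selected when `NULL`.
#' @param ngrid number of r grid points, default 101.
#' @return A [pddf] with `alpha` and `fit_chi2` populated.
#' @export
ift <- function(profile, dmax = NULL, alpha = NULL, ngrid = 101) {
  stopifnot(inherits(profile, "saxs_profile"))
  if (is.null(profile$sigma)) stop("ift: profile must carry sigma")
  q <- profile$q; y <- profile$intensity; w <- 1 / profile$sigma
  if (is.null(dmax)) {
    coarse <- seq(20, 400, by = 10)
    d0 <- .ift_dmax_scan(q, y, w, coarse, ngrid, alpha)
    dmax <- .ift_tail_dmax(q, y, w, min(1.5 * d0, 400), ngrid)
  }
  fit <- .ift_at_dmax(q, y, w, dmax, ngrid, alpha)
  pddf(r = fit$r, p = fit$p, dmax = dmax, alpha = fit$alpha,
       fit_chi2 = fit$chi2)
}

.ift_at_dmax <- function(q, y, w, dmax, ngrid, alpha) {
  r <- seq(0, dmax, length.out = ngrid)
  A <- .ift_design(q, r)
  ni <- ncol(A)
  # second differences over the full grid including the clamped endpoints
  Dfull <- diff(diag(ngrid), differences = 2)
  D <- Dfull[, -c(1, ngrid), drop = FALSE]
  if (is.null(alpha)) {
    ref <- sum((A * w)^2) / sum(D^2)
    alphas <- ref * 10^seq(-10, 0, length.out = 20)
    sol <- lapply(alphas, function(a) {
      p <- tryCatch(.ift_solve(A, y, w, a, D), error = function(e) NULL)
      if (is.null(p)) return(NULL)
      list(p = p, chi2 = sum(((y - A %*% p) * w)^2) / length(y),
           rough = sum((D %*% p)^2))
    })
    keep <- !vapply(sol, is.null, logical(1))
    sol <- sol[keep]; alphas <- alphas[keep]
    if (length(sol) < 3) stop("ift: system ill-conditioned after regularization")
    # smoothest solution still consistent with the data: largest alpha
    # whose chi2 is within 5% of the best over the grid
    chi2v <- vapply(sol, `[[`, numeric(1), "chi2")
    best <- max(which(chi2v <= 1.05 * min(chi2v)))
    alpha <- alphas[best]
    p <- sol[[best]]$p; chi2 <- sol[[best]]$chi2
  } else {
    p <- .ift_solve(A, y, w, alpha, D)
    chi2 <- sum(((y - A %*% p) * w)^2) / length(y)
  }
  list(r = r, p = c(0, p, 0), alpha = alpha, chi2 = chi2)
}

# knee of a decreasing trade-off curve: farthest point from the chord
# joining the two ends, in normalized coordinates
.curve_knee <- function(x, y) {
  nx <- (x - min(x)) / max(diff(range(x)), 1e-12)
  ny <- (y - min(y)) / max(diff(range(y)), 1e-12)
  v <- c(nx[length(nx)] - nx[1], ny[length(ny)] - ny[1])
  v <- v / sqrt(sum(v^2) + 1e-300)
  which.max(abs((nx - nx[1]) * v[2] - (ny - ny[1]) * v[1]))
}

.ift_chi2_over <- function(q, y, w, grid, ngrid, alpha) {
  vapply(grid, function(d)
    tryCatch(.ift_at_dmax(q, y, w, d, ngrid, alpha)$chi2,
             error = function(e) Inf), numeric(1))
}

# coarse scan: chi2(dmax) drops steeply while dmax is too short, then
# creeps down slowly once the support is covered; pick the elbow
.ift_dmax_scan <- function(q, y, w, grid, ngrid, alpha) {
  chi2 <- .ift_chi2_over(q, y, w, grid, ngrid, alpha)
  ok <- is.finite(chi2)
  if (!any(ok)) stop("ift: dmax scan failed to bracket a solution")
  grid <- grid[ok]; chi2 <- chi2[ok]
  if (chi2[1] <= 1.05 * min(chi2)) return(grid[1])
  grid[.curve_knee(grid, log(chi2))]
}

# refine dmax by reading the support of P(r): solve at a generous dmax
# with the stiffest regularization still fitting the data (chi2 within
# 30% of the best over the alpha grid, which suppresses tail ringing),
# then take the r beyond the main peak past which |P| stays below 2% of
# the maximum -- "the distance where P(r) approaches zero"
.ift_tail_dmax <- function(q, y, w, d_gen, ngrid) {
  r <- seq(0, d_gen, length.out = ngrid)
  A <- .ift_design(q, r)
  Dfull <- diff(diag(ngrid), differences = 2)
  D <- Dfull[, -c(1, ngrid), drop = FALSE]
  ref <- sum((A * w)^2) / sum(D^2)
  alphas <- ref * 10^seq(-10, 0, length.out = 20)
  sols <- lapply(alphas, function(a) tryCatch({
    p <- .ift_solve(A, y, w, a, D)
    list(p = c(0, p, 0), chi2 = sum(((y - A %*% p) * w)^2) / length(y))
  }, error = function(e) NULL))
  sols <- sols[!vapply(sols, is.null, logical(1))]
  if (!length(sols)) stop("ift: dmax refinement failed")
  chi2s <- vapply(sols, `[[`, numeric(1), "chi2")
  p <- sols[[max(which(chi2s <= 1.3 * min(chi2s)))]]$p
  thr <- 0.02 * max(p)
  im <- which.max(p)
  idx <- which(abs(p) >= thr & seq_along(p) > im)
  if (!length(idx)) return(r[im])
  r[min(max(idx) + 1L, length(r))]
}

#' Peak and shoulder positions of a pair-distance distribution
#'
#' Finds local maxima of the smoothed P(r) together with inflection-based
#' shoulders (sign changes of the smoothed second derivative on a
#' decaying flank) beyond the global maximum. A strictly unimodal
#' distribution reports no positions; a multimodal or shouldered one
#' reports all of its modes and shoulders.
#'
#' @param pddf a [pddf].
#' @param sg_window,sg_order Savitzky-Golay smoothing parameters.
#' @param min_relief minimum prominence of a reported mode, as a fraction
#'   of max P(r), default 0.02; suppresses histogram-level wiggles.
#' @return Numeric vector of r positions, Angstrom (possibly empty).
#' @export
shoulder_positions <- function(pddf, sg_window = 15, sg_order = 3,
                               min_relief = 0.02) {
  stopifnot(inherits(pddf, "pddf"))
  p <- signal::sgolayfilt(pddf$p, p = sg_order,
                          n = min(sg_window,
                                  2L * (length(pddf$p) %/% 2L) - 1L))
  r <- pddf$r
  n <- length(p)
  maxima <- which(diff(sign(diff(p))) == -2) + 1L
  relief <- vapply(maxima, function(i) {
    # prominence against the higher of the two flanking local minima
    left <- if (i > 1) min(p[max(1, i - 20):i]) else p[i]
    right <- if (i < n) min(p[i:min(n, i + 20)]) else p[i]
    p[i] - max(left, right)
  }, numeric(1))
  maxima <- maxima[relief >= min_relief * max(p) & p[maxima] > 0.02 * max(p)]
  gmax <- if (length(maxima)) maxima[which.max(p[maxima])] else which.max(p)
  d1 <- signal::sgolayfilt(c(diff(p), 0), p = sg_order, n = sg_window)
  # shoulder: a pronounced flattening of the decaying flank -- a local
  # minimum of |d1| (d1 still < 0) dipping well below the steepness on
  # both sides
  a <- abs(d1)
  dips <- which(diff(sign(diff(a))) == 2) + 1L
  dips <- dips[dips > gmax + 2 & dips < n - 2 & d1[dips] < 0 &
                 pddf$p[pmin(dips, n)] > 0.05 * max(p)]
  sh <- dips[vapply(dips, function(i) {
    left <- max(a[max(1, i - 15):i]); right <- max(a[i:min(n, i + 15)])
    a[i] <= 0.6 * min(left, right)
  }, logical(1))]
  pos <- sort(unique(r[c(maxima, sh)]))
  if (length(pos) <= 1 && length(maxima) <= 1 && !length(sh))
    return(numeric(0))  # strictly unimodal
  pos
}
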
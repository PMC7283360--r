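# Model-free SAXS shape invariants: Porod volume and volume of correlation.
# Integrals use the trapezoidal rule on the measured grid, with the Guinier
# analytic form I(0) exp(-q^2 Rg^2 / 3) filling the unmeasured 0..qmin gap.

.guinier_extension <- function(guinier, qmin, integrand, n = 200) {
  qe <- seq(0, qmin, length.out = n)
  Ie <- guinier$i0 * exp(-qe^2 * guinier$rg^2 / 3)
  pracma::trapz(qe, integrand(qe, Ie))
}

# High-q Porod-law decomposition over the top decile of q:
# q^4 I = K + B q^4 with K the Porod constant and B a flat background,
# solved with non-negativity constraints (an unconstrained regression is
# ill-posed on oscillating form-factor tails).
.porod_tail <- function(q, I) {
  idx <- which(q >= stats::quantile(q, 0.9))
  fit <- pracma::lsqnonneg(cbind(1, q[idx]^4), q[idx]^4 * I[idx])
  list(K = fit$x[1], B = fit$x[2])
}

#' Porod volume of a particle from its scattering profile
#'
#' Computes Vp = 2 pi^2 I(0) / Q with the Porod invariant
#' Q = integral of q^2 I(q) dq. The integrand is extended below the first
#' measured point by the Guinier form, a constant background (estimated
#' from the top decile of q by Porod-law regression) is subtracted, and the
#' tail beyond the data end is completed analytically with the fitted
#' Porod K / q^4 decay.
#'
#' @param profile a [saxs_profile].
#' @param guinier a `guinier_result` from [guinier_fit] on the same profile.
#' @return Porod volume in cubic Angstrom.
#' @export
porod_volume <- function(profile, guinier) {
  stopifnot(inherits(profile, "saxs_profile"),
            inherits(guinier, "guinier_result"))
  q <- profile$q
  tail <- .porod_tail(q, profile$intensity)
  I <- profile$intensity - tail$B
  Q <- .guinier_extension(guinier, q[1], function(qe, Ie) qe^2 * Ie) +
    pracma::trapz(q, q^2 * pmax(I, 0)) +
    tail$K / q[length(q)]                       # int_{qend}^{Inf} K/q^2 dq
  if (!is.finite(Q) || Q <= 0) stop("porod_volume: Porod invariant Q <= 0")
  2 * pi^2 * guinier$i0 / Q
}

#' Volume of correlation
#'
#' Computes the concentration-independent invariant
#' Vc = I(0) / integral of q I(q) dq, with the Guinier analytic extension
#' below the first measured point and truncation at the data end.
#'
#' @inheritParams porod_volume
#' @return Vc in square Angstrom.
#' @export
volume_of_correlation <- function(profile, guinier) {
  stopifnot(inherits(profile, "saxs_profile"),
            inherits(guinier, "guinier_result"))
  q <- profile$q
  denom <- .guinier_extension(guinier, q[1], function(qe, Ie) qe * Ie) +
    pracma::trapz(q, q * profile$intensity)
  if (!is.finite(denom) || denom <= 0)
    stop("volume_of_correlation: integral of q*I is not positive")
  guinier$i0 / denom
}

#' Normalize a pair-distance distribution to a volume of correlation
#'
#' Rescales P(r) so that its integral equals `vc`; the shape is unchanged.
#' Normalizing an already normalized distribution is a no-op.
#'
#' @param pddf a [pddf] object.
#' @param vc target integral, e.g. from [volume_of_correlation]; must be
#'   positive.
#' @return The rescaled [pddf].
#' @export
normalize_pr <- function(pddf, vc) {
  stopifnot(inherits(pddf, "pddf"), is.finite(vc), vc > 0)
  integral <- pracma::trapz(pddf$r, pddf$p)
  if (!is.finite(integral) || integral == 0)
    stop("normalize_pr: P(r) has zero integral")
  pddf$p <- pddf$p * (vc / integral)
  pddf
}
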
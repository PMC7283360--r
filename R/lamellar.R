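# Lamellar-stack intensity with Caille structure factor:
#   I(q) = scale * 2 pi * <P(q)> * S(q) / (q^2 delta) + background
# where P is the sheet form factor, S the Caille structure factor of a
# stack of N plates with repeat d and undulation parameter eta, and <P>
# averages a Gaussian polydispersity of the layer thickness delta.

.EULER_GAMMA <- 0.57721566490153286

#' Construct a lamellar-stack model parameter set
#'
#' @param d lamellar repeat spacing, Angstrom.
#' @param delta total layer thickness, Angstrom; must satisfy
#'   0 < delta < d.
#' @param n_plates number of lamellar plates N (integer >= 1).
#' @param eta Caille parameter, dimensionless, in (0, 0.8]; larger values
#'   broaden and damp the Bragg peaks.
#' @param poly_delta relative Gaussian polydispersity of delta, in
#'   [0, 0.5].
#' @param scale overall intensity scale (> 0).
#' @param background constant additive background (>= 0).
#' @return A list of class `lamellar_model`.
#' @export
lamellar_model <- function(d, delta = 20, n_plates = 20, eta = 0.1,
                           poly_delta = 0, scale = 1, background = 0) {
  stopifnot(d > 0, delta > 0, delta < d, n_plates >= 1,
            eta > 0, eta <= 0.8, poly_delta >= 0, poly_delta <= 0.5,
            scale > 0, background >= 0)
  structure(list(d = d, delta = delta, n_plates = as.integer(round(n_plates)),
                 eta = eta, poly_delta = poly_delta, scale = scale,
                 background = background),
            class = "lamellar_model")
}

#' @export
print.lamellar_model <- function(x, ...) {
  cat(sprintf(
    "Lamellar-stack model: d = %.2f A, delta = %.2f A, N = %d, eta = %.3f, poly = %.3f\n",
    x$d, x$delta, x$n_plates, x$eta, x$poly_delta))
  invisible(x)
}

#' Caille structure factor of a lamellar stack
#'
#' S(q) = 1 + 2 sum_{n=1}^{N-1} (1 - n/N) cos(q d n)
#'            exp(-q^2 d^2 eta (ln(pi n) + gamma_E) / (4 pi^2)),
#' gamma_E the Euler-Mascheroni constant. At eta = 0 and the Bragg
#' condition q = 2 pi / d this reduces to S = N exactly.
#'
#' @param q numeric vector of momentum transfer, 1/Angstrom.
#' @param d repeat spacing, Angstrom.
#' @param n_plates number of plates N.
#' @param eta Caille parameter (>= 0 here; fitting bounds it at 0.8).
#' @return S(q), same length as q.
#' @export
caille_structure_factor <- function(q, d, n_plates, eta) {
  stopifnot(d > 0, n_plates >= 1, eta >= 0)
  N <- as.integer(round(n_plates))
  if (N == 1L) return(rep(1, length(q)))
  n <- seq_len(N - 1L)
  # columns over n, rows over q
  damp <- outer(q^2 * d^2 * eta / (4 * pi^2), log(pi * n) + .EULER_GAMMA)
  terms <- outer(q * d, n) # q d n
  1 + 2 * rowSums(sweep(cos(terms) * exp(-damp), 2, 1 - n / N, `*`))
}

#' Sheet form factor of a lamellar layer
#'
#' Uniform slab of thickness delta: P(q) = (2 sin(q delta / 2) / q)^2,
#' with the q -> 0 limit P -> delta^2. The head/tail variant models the
#' four-region head/tail/tail/head sheet with separate thicknesses and
#' contrasts; with equal contrasts it reduces to the uniform slab of total
#' thickness 2 (delta_head + delta_tail).
#'
#' @param q numeric vector, 1/Angstrom.
#' @param delta total slab thickness, Angstrom (uniform variant).
#' @param head optional list(delta_head, delta_tail, rho_head, rho_tail)
#'   selecting the head/tail variant; `delta` is ignored when given.
#' @return P(q), same length as q.
#' @export
lamellar_form_factor <- function(q, delta, head = NULL) {
  if (is.null(head)) {
    stopifnot(delta > 0)
    return(ifelse(q == 0, delta^2, (2 * sin(q * delta / 2) / q)^2))
  }
  dh <- head$delta_head; dt <- head$delta_tail
  rh <- head$rho_head; rt <- head$rho_tail
  stopifnot(dh > 0, dt > 0)
  # amplitude of a centred symmetric slab pair: tails |z| < dt, heads
  # dt < |z| < dt + dh
  amp <- ifelse(q == 0, 2 * (rt * dt + rh * dh),
                2 * rt * sin(q * dt) / q +
                  2 * rh * (sin(q * (dt + dh)) - sin(q * dt)) / q)
  amp^2
}

#' Lamellar-stack Caille intensity
#'
#' I(q) = scale * 2 pi * <P(q)> * S(q) / (q^2 delta) + background, with
#' <P> the Gaussian-quadrature average of the slab form factor over the
#' delta polydispersity (truncated at +/- 2 sigma, 15 Gauss-Legendre
#' nodes).
#'
#' @param q numeric vector of positive momentum transfer, 1/Angstrom.
#' @param model a [lamellar_model].
#' @return A [saxs_profile] with the model intensity (no sigma).
#' @export
lamellar_intensity <- function(q, model) {
  stopifnot(inherits(model, "lamellar_model"))
  if (any(q <= 0)) stop("lamellar_intensity: q must be strictly positive")
  S <- caille_structure_factor(q, model$d, model$n_plates, model$eta)
  if (model$poly_delta > 0) {
    sig <- model$poly_delta * model$delta
    gl <- pracma::gaussLegendre(15, model$delta - 2 * sig,
                                model$delta + 2 * sig)
    wts <- gl$w * stats::dnorm(gl$x, model$delta, sig)
    wts <- wts / sum(wts)
    P <- rowSums(vapply(seq_along(gl$x), function(k)
      wts[k] * lamellar_form_factor(q, gl$x[k]), numeric(length(q))))
  } else {
    P <- lamellar_form_factor(q, model$delta)
  }
  I <- model$scale * 2 * pi * P * S / (q^2 * model$delta) + model$background
  saxs_profile(q = q, intensity = I,
               condition = sprintf("lamellar d=%.4g", model$d))
}

#' Fit a lamellar-stack Caille model to a measured profile
#'
#' Bounded weighted least squares (Levenberg-Marquardt with box bounds)
#' over (d, delta, eta, poly_delta, scale, background), with the plate
#' count N fitted on a small integer grid. The spacing d is initialized
#' from the first detected Bragg peak when no `init` is given; eta is
#' bounded in (0, 0.8] and fits pinned at the bound are flagged.
#'
#' @param profile a [saxs_profile] with sigma present.
#' @param init optional [lamellar_model] used as the starting point.
#' @param n_grid integer candidates for the plate count, default
#'   c(5, 10, 20, 40).
#' @return A list of class `lamellar_fit`: `model` (the fitted
#'   [lamellar_model]), `chi2` (reduced chi-squared), `n_plates_grid`
#'   (chi2 per N candidate) and `eta_at_bound` (logical).
#' @export
fit_lamellar <- function(profile, init = NULL, n_grid = c(5, 10, 20, 40)) {
  stopifnot(inherits(profile, "saxs_profile"))
  if (is.null(profile$sigma))
    stop("fit_lamellar: profile must carry sigma for weighted fitting")
  q <- profile$q; I <- profile$intensity; s <- profile$sigma
  if (is.null(init)) {
    peaks <- detect_peaks(profile)
    if (nrow(peaks) == 0)
      stop("fit_lamellar: no Bragg peak detected and no init supplied")
    d0 <- bragg_spacing(peaks$q_star[1])
    init <- lamellar_model(d = d0, delta = min(20, 0.5 * d0), eta = 0.1,
                           poly_delta = 0.05,
                           scale = max(I) / max(
                             lamellar_intensity(q, lamellar_model(
                               d = d0, delta = min(20, 0.5 * d0),
                               eta = 0.1, scale = 1))$intensity),
                           background = max(min(I), 1e-12))
  }
  par0 <- c(d = init$d, delta = init$delta, eta = init$eta,
            poly_delta = max(init$poly_delta, 1e-3),
            log_scale = log(init$scale), background = init$background)
  lower <- c(0.5 * init$d, 2, 1e-4, 0, log(init$scale) - 15, 0)
  upper <- c(2 * init$d, 0.9 * init$d, 0.8, 0.5, log(init$scale) + 15,
             max(I))
  resid_fun <- function(par, N) {
    m <- list(d = par[1], delta = par[2], n_plates = N, eta = par[3],
              poly_delta = par[4], scale = exp(par[5]), background = par[6])
    class(m) <- "lamellar_model"
    (I - lamellar_intensity(q, m)$intensity) / s
  }
  fits <- lapply(n_grid, function(N) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fun, N = N,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(f)) return(list(chi2 = Inf))
    list(par = f$par, chi2 = sum(f$fvec^2) / max(length(q) - 6, 1))
  })
  chi2s <- vapply(fits, `[[`, numeric(1), "chi2")
  if (all(!is.finite(chi2s)))
    stop("fit_lamellar: optimizer failed to converge for every plate count")
  best <- which.min(chi2s)
  p <- fits[[best]]$par
  model <- lamellar_model(d = p[1], delta = p[2], n_plates = n_grid[best],
                          eta = p[3], poly_delta = min(max(p[4], 0), 0.5),
                          scale = exp(p[5]), background = p[6])
  structure(list(model = model, chi2 = chi2s[best],
                 n_plates_grid = stats::setNames(chi2s, n_grid),
                 eta_at_bound = p[3] >= 0.8 - 1e-6),
            class = "lamellar_fit")
}

#' @export
print.lamellar_fit <- function(x, ...) {
  cat(sprintf("Lamellar Caille fit: reduced chi2 = %.4g%s\n", x$chi2,
              if (x$eta_at_bound) " [eta at 0.8 bound]" else ""))
  print(x$model)
  invisible(x)
}
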
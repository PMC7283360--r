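test_that("Caille structure factor limits and brute-force agreement", {
  q <- default_qgrid(50)
  # single plate: no interference
  expect_equal(caille_structure_factor(q, 60, 1, 0.2), rep(1, 50))
  # eta = 0 at the Bragg condition: S = N exactly
  for (N in c(2, 5, 20, 40))
    expect_equal(caille_structure_factor(2 * pi / 60, 60, N, 0), N,
                 tolerance = 1e-12)
  # vectorized vs naive scalar double loop
  set.seed(11)
  for (i in 1:5) {
    d <- runif(1, 30, 90); N <- sample(2:8, 1); eta <- runif(1, 0, 0.5)
    expect_equal(caille_structure_factor(q, d, N, eta),
                 caille_naive(q, d, N, eta), tolerance = 1e-12)
  }
})

test_that("S at the Bragg peak is non-increasing in eta and peaks broaden", {
  qstar <- 2 * pi / 60
  S <- vapply(seq(0, 0.8, by = 0.1),
              function(e) caille_structure_factor(qstar, 60, 20, e),
              numeric(1))
  expect_true(all(diff(S) <= 1e-12))
  # FWHM of I(q) about the peak grows with eta
  q <- seq(0.07, 0.14, length.out = 800)
  width <- vapply(c(0.05, 0.2, 0.5), function(e) {
    I <- lamellar_intensity(q, lamellar_model(d = 60, delta = 20,
                                              n_plates = 20,
                                              eta = e))$intensity
    pk <- which.max(I)
    half <- I[pk] / 2
    sum(I >= half & seq_along(I) > pk - 200 & seq_along(I) < pk + 200)
  }, numeric(1))
  expect_true(all(diff(width) >= 0))
})

test_that("slab form factor limits hold and head/tail reduces to the slab", {
  q <- default_qgrid(80)
  expect_equal(lamellar_form_factor(1e-6, 20), 400, tolerance = 1e-6)
  # first zero at q = 2 pi / delta
  expect_lt(lamellar_form_factor(2 * pi / 20, 20), 1e-20)
  ht <- lamellar_form_factor(q, head = list(delta_head = 5, delta_tail = 5,
                                            rho_head = 1, rho_tail = 1))
  expect_equal(ht, lamellar_form_factor(q, 20), tolerance = 1e-12)
})

test_that("lamellar intensity obeys the 2 pi P S / (q^2 delta) arithmetic", {
  # N = 1, delta = 1, no polydispersity: I = 2 pi P(q) / q^2; at the
  # q -> 0 limit P -> delta^2 = 1 so I q^2 -> 2 pi
  m <- lamellar_model(d = 10, delta = 1, n_plates = 1, eta = 0.1)
  q <- c(1e-4, 1)
  I <- lamellar_intensity(q, m)$intensity
  expect_equal(I[1] * q[1]^2, 2 * pi, tolerance = 1e-6)
  expect_equal(I[2], 2 * pi * (2 * sin(0.5))^2, tolerance = 1e-9)
  expect_error(lamellar_intensity(c(0, 0.1), m), "strictly positive")
  # zero polydispersity equals the single-delta evaluation
  q <- default_qgrid(60)
  m0 <- lamellar_model(d = 60, delta = 20, n_plates = 20, eta = 0.1,
                       poly_delta = 0)
  mq <- lamellar_model(d = 60, delta = 20, n_plates = 20, eta = 0.1,
                       poly_delta = 1e-12)
  expect_equal(lamellar_intensity(q, mq)$intensity,
               lamellar_intensity(q, m0)$intensity, tolerance = 1e-6)
})

test_that("polydispersity quadrature matches a large Monte-Carlo average", {
  m <- lamellar_model(d = 60, delta = 20, n_plates = 20, eta = 0.1,
                      poly_delta = 0.2)
  q <- c(0.02, 0.1, 0.25)
  Iq <- lamellar_intensity(q, m)$intensity
  set.seed(4)
  ds <- rnorm(1e5, 20, 4)
  ds <- ds[abs(ds - 20) <= 8]            # same +/- 2 sigma truncation
  S <- caille_structure_factor(q, 60, 20, 0.1)
  Pmc <- vapply(q, function(qq) mean((2 * sin(qq * ds / 2) / qq)^2),
                numeric(1))
  expect_equal(Iq, 2 * pi * Pmc * S / (q^2 * 20), tolerance = 5e-3)
})

test_that("self-fit of a noiseless curve recovers the generating parameters", {
  truth <- lamellar_model(d = 60, delta = 20, n_plates = 20, eta = 0.1,
                          poly_delta = 0.05)
  p <- simulate_profile(truth, noise_frac = 0, seed = 1)
  fit <- fit_lamellar(p, init = truth)
  expect_lt(fit$chi2, 1e-3)
  expect_rel(fit$model$d, 60, 1e-3)
  expect_rel(fit$model$eta, 0.1, 1e-3)
  expect_false(fit$eta_at_bound)
})

test_that("spacing recovery within 2% across 42/60/70 A for >= 18/20 seeds", {
  for (d in c(42, 60, 70)) {
    truth <- lamellar_model(d = d, delta = 20, n_plates = 20, eta = 0.1,
                            poly_delta = 0.05)
    ideal <- lamellar_intensity(default_qgrid(), truth)
    hits <- vapply(1:20, function(s) {
      p <- simulate_profile(ideal, noise_frac = 0.02, seed = 3000 + s)
      abs(fit_lamellar(p)$model$d / d - 1) < 0.02
    }, logical(1))
    expect_gte(sum(hits), 18)
  }
})

test_that("eta recovery and the 0.8 bound with at-bound flagging", {
  truth <- lamellar_model(d = 60, delta = 20, n_plates = 20, eta = 0.2,
                          poly_delta = 0.05)
  ideal <- lamellar_intensity(default_qgrid(), truth)
  etas <- vapply(1:10, function(s)
    fit_lamellar(simulate_profile(ideal, 0.01, seed = 4000 + s))$model$eta,
    numeric(1))
  expect_lt(abs(median(etas) / 0.2 - 1), 0.2)
  # a curve generated at the bound pins eta at 0.8 and is flagged
  atb <- lamellar_model(d = 60, delta = 20, n_plates = 20, eta = 0.8,
                        poly_delta = 0.05)
  fitb <- fit_lamellar(simulate_profile(atb, 0.005, seed = 77), init = atb)
  expect_lte(fitb$model$eta, 0.8)
  expect_true(fitb$eta_at_bound)
})

test_that("fit without a peak and without init raises an initialization error", {
  q <- default_qgrid()
  p <- saxs_profile(q, 3 * q^-1, sigma = 0.03 * q^-1)
  expect_error(fit_lamellar(p), "no Bragg peak")
})
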
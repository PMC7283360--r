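test_that("power-law fit recovers exact exponents", {
  q <- default_qgrid(100)
  p2 <- saxs_profile(q, 5 * q^-2)
  f <- fit_power_law(p2, c(0.01, 0.3))
  expect_equal(f$exponent, -2, tolerance = 1e-9)
  pc <- saxs_profile(q, rep(3, 100))
  expect_equal(fit_power_law(pc, c(0.01, 0.3))$exponent, 0,
               tolerance = 1e-9)
  expect_error(fit_power_law(saxs_profile(q, q - 0.2), c(0.01, 0.3)),
               "non-positive")
})

test_that("peak detection finds a constructed bump and nothing on featureless curves", {
  q <- default_qgrid()
  bump <- 5 * q^-2 * (1 + 0.5 * exp(-(q - 0.15)^2 / (2 * 0.004^2)))
  pk <- detect_peaks(saxs_profile(q, bump))
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$q_star[1] - 0.15), diff(q[c(200, 201)]) * 5)
  expect_equal(nrow(detect_peaks(saxs_profile(q, 2 * q^-1.3))), 0)
})

test_that("first-order Bragg peaks of Caille curves give d within 2% for 42/60/70 A", {
  q <- default_qgrid()
  for (d in c(42, 60, 70)) {
    for (eta in c(0.1, 0.3)) {
      prof <- lamellar_intensity(q, lamellar_model(d = d, delta = 20,
                                                   n_plates = 20,
                                                   eta = eta))
      pk <- detect_peaks(saxs_profile(q, prof$intensity))
      expect_gte(nrow(pk), 1)
      expect_rel(bragg_spacing(pk$q_star[1]), d, 0.02)
    }
  }
})

test_that("bragg_spacing is 2 pi / q*", {
  expect_equal(bragg_spacing(2 * pi), 1)
  expect_equal(bragg_spacing(0.1), 62.83185, tolerance = 1e-6)
  expect_equal(bragg_spacing(2 * pi / 42), 42)
  expect_error(bragg_spacing(-1), "positive")
})

test_that("classification assigns lamellar, filament and aggregate correctly", {
  lam <- scenario_profile("pH4.5_150mM")
  pc <- classify_phase(lam$profile)
  expect_identical(pc$label, "lamellar")
  expect_lt(abs(pc$peaks$d[1] - 42), 1)
  fil <- scenario_profile("pH5.5_300mM")
  pf <- classify_phase(fil$profile)
  expect_identical(pf$label, "filament")
  expect_lt(abs(pf$exponent - (-1)), 0.2)
  q <- default_qgrid()
  pa <- classify_phase(saxs_profile(q, q^-4))
  expect_identical(pa$label, "aggregate")
})

test_that("classification is invariant under rescaling and 2x subsampling", {
  for (nm in c("pH4.5_150mM", "pH5.5_100mM", "pH5.5_300mM", "E34K_pH4.5")) {
    sc <- scenario_profile(nm)
    p <- sc$profile
    lab <- classify_phase(p)$label
    expect_identical(lab, sc$scenario$expected_label)
    ps <- saxs_profile(p$q, 1e3 * p$intensity, 1e3 * p$sigma)
    expect_identical(classify_phase(ps)$label, lab)
    idx <- seq(1, length(p$q), by = 2)
    p2 <- saxs_profile(p$q[idx], p$intensity[idx], p$sigma[idx])
    expect_identical(classify_phase(p2)$label, lab)
  }
})

test_that("noisy replicates classify to the expected label at least 95% of the time", {
  # one lamellar and one filament condition, 40 noise replicates each;
  # the ideal curves are computed once and re-noised per seed
  ideal_lam <- lamellar_intensity(default_qgrid(),
                                  lamellar_model(d = 70, delta = 20,
                                                 n_plates = 20, eta = 0.1,
                                                 poly_delta = 0.05))
  ideal_fil <- debye_intensity(
    place_hu(build_bdna(build_spec(n_bp = 80)), mode = "saturated"),
    default_qgrid())
  for (case in list(list(ideal_lam, "lamellar"),
                    list(ideal_fil, "filament"))) {
    labs <- vapply(1:40, function(s)
      classify_phase(simulate_profile(case[[1]], noise_frac = 0.01,
                                      seed = 5000 + s))$label,
      character(1))
    expect_gte(mean(labs == case[[2]]), 0.95)
  }
})
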
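test_that("Debye intensity matches closed forms", {
  m <- atomistic_model(rbind(c(0, 0, 0), c(0, 0, 10)))
  q <- seq(0.01, 0.5, length.out = 60)
  I <- debye_intensity(m, q)$intensity
  expect_equal(I, 2 + 2 * sin(10 * q) / (10 * q), tolerance = 1e-12)
  # I(0+) tends to (sum of weights)^2
  mw <- atomistic_model(rbind(c(0, 0, 0), c(0, 0, 5), c(3, 0, 1)),
                        weight = c(1, 2, 3))
  expect_equal(debye_intensity(mw, 1e-6)$intensity, 36, tolerance = 1e-6)
  expect_error(debye_intensity(m, c(0, 0.1)), "strictly positive")
})

test_that("bead-filled sphere reproduces the analytic sphere form factor to 1%", {
  m <- bead_sphere(4000, 20)
  q <- seq(0.01, 0.2, length.out = 80)      # up to qR = 4
  I <- debye_intensity(m, q)$intensity
  ref <- sphere_intensity(q, 20)
  expect_lt(max(abs(I / I[1] / (ref / ref[1]) - 1)), 0.01)
})

test_that("histogram acceleration agrees with the exact double loop within 0.3%", {
  q <- default_qgrid(100)
  models <- list(
    place_hu(build_bdna(build_spec(n_bp = 120)), mode = "saturated"),
    place_hu(build_bdna(build_spec(n_bp = 160)), mode = "saturated"))
  for (m in models) {
    expect_gt(n_beads(m), 500)                     # histogram path taken
    Ih <- debye_intensity(m, q)$intensity
    # exact evaluation of the same model via a degenerate fine bin
    Ix <- debye_intensity(m, q, hist_bin = 1e-4)$intensity
    expect_lt(max(abs(Ih / Ix - 1)), 0.003)
  }
})

test_that("fit_scale recovers scale and background and calibrates chi", {
  q <- default_qgrid(200)
  m <- build_bdna(build_spec(n_bp = 40))
  mp <- debye_intensity(m, q)
  d <- saxs_profile(q, 3.5 * mp$intensity + 0.1, sigma = rep(1, 200))
  fs <- fit_scale(mp, d)
  expect_equal(fs$scale, 3.5, tolerance = 1e-6)
  expect_equal(fs$background, 0.1, tolerance = 1e-5)
  expect_lt(fs$chi, 1e-5)
  # chi ~ 1 for unit-variance noise at unit sigma, over 20 seeds
  chis <- vapply(1:20, function(s) {
    set.seed(s)
    dn <- saxs_profile(q, mp$intensity + rnorm(200), sigma = rep(1, 200))
    fit_scale(mp, dn)$chi
  }, numeric(1))
  expect_lt(abs(mean(chis) - 1), 0.15)
  # rescaling sigma leaves the scale; chi scales inversely
  d2 <- saxs_profile(q, 3.5 * mp$intensity + 0.1, sigma = rep(4, 200))
  fs2 <- fit_scale(mp, d2)
  expect_equal(fs2$scale, fs$scale, tolerance = 1e-6)
})

test_that("minimal ensemble: identity, parsimony and two-state recovery", {
  q <- default_qgrid()
  pool <- lapply(build_pool(build_spec(n_bp = 80), c(0, 2, 4, 8)),
                 debye_intensity, qgrid = q)
  # data equal to one member: size 1, weight 1
  d1 <- simulate_profile(pool[["hu2"]], noise_frac = 0, seed = 1)
  e1 <- minimal_ensemble(pool, d1)
  expect_equal(e1$size, 1)
  expect_identical(e1$member_ids, "hu2")
  expect_equal(e1$weights, 1)
  expect_lt(e1$chi, 1e-3)
  # single-member pool trivially selects that member
  es <- minimal_ensemble(pool["hu4"], d1)
  expect_identical(es$member_ids, "hu4")
  # 50/50 mixture at 1% noise: both weights within 0.5 +/- 0.1
  mix <- saxs_profile(q, 0.5 * pool[["hu0"]]$intensity +
                        0.5 * pool[["hu8"]]$intensity)
  dm <- simulate_profile(mix, noise_frac = 0.01, seed = 9)
  em <- minimal_ensemble(pool, dm)
  expect_equal(em$size, 2)
  expect_setequal(em$member_ids, c("hu0", "hu8"))
  expect_true(all(abs(em$weights - 0.5) < 0.1))
  expect_equal(sum(em$weights), 1, tolerance = 1e-9)
  # chi_by_size is non-increasing
  expect_true(all(diff(em$chi_by_size) <= 1e-12))
})

test_that("three-component weight recovery within 0.1 per component (median of seeds)", {
  q <- default_qgrid(200)
  pool <- lapply(build_pool(build_spec(n_bp = 80), c(0, 2, 8)),
                 debye_intensity, qgrid = q)
  truth <- c(0.5, 0.3, 0.2)
  mix <- saxs_profile(q, truth[1] * pool[[1]]$intensity +
                        truth[2] * pool[[2]]$intensity +
                        truth[3] * pool[[3]]$intensity)
  errs <- sapply(1:10, function(s) {
    dm <- simulate_profile(mix, noise_frac = 0.01, seed = 6000 + s)
    em <- minimal_ensemble(pool, dm, max_size = 3)
    w <- setNames(rep(0, 3), names(pool))
    w[em$member_ids] <- em$weights
    max(abs(w - truth))
  })
  expect_lt(median(errs), 0.1)
})
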
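test_that("pr_from_model handles the two-bead system exactly", {
  m <- atomistic_model(rbind(c(0, 0, 0), c(0, 0, 10)))
  pd <- pr_from_model(m, nbins = 20)
  expect_equal(pd$dmax, 10)
  expect_equal(sum(pd$p > 0), 1)
  expect_equal(pd$r[which(pd$p > 0)], 10)
  expect_equal(rg_from_pr(pd), 5, tolerance = 1e-9)
  expect_error(pr_from_model(atomistic_model(matrix(0, 1, 3))), "2 beads")
})

test_that("bead-sphere P(r) matches the closed-form sphere distribution", {
  m <- bead_sphere(3000, 20)
  pd <- pr_from_model(m, nbins = 50)
  expect_equal(pd$dmax, max(stats::dist(m$coords)))
  ref <- sphere_pr(pd$r, 20)
  bulk <- pd$r > 4 & pd$r < 36
  expect_lt(max(abs(pd$p - ref)[bulk]) / max(ref), 0.08)
  # unit integral before any Vc normalization
  expect_equal(pracma::trapz(pd$r, pd$p), 1, tolerance = 1e-6)
  # second moment: Rg = sqrt(3/5) R within 1%
  expect_rel(rg_from_pr(pd), sqrt(3 / 5) * 20, 0.01)
})

test_that("ideal 80-bp duplex spans ~270 A and Rg matches coordinates", {
  m <- build_bdna(build_spec(n_bp = 80))
  pd <- pr_from_model(m)
  expect_lt(abs(pd$dmax - 270), 10)
  expect_rel(rg_from_pr(pd), coord_rg(m), 0.02)
})

test_that("IFT recovers the sphere support within 5% and is alpha-stable", {
  q <- default_qgrid()
  data <- simulate_profile(saxs_profile(q, sphere_intensity(q, 20)),
                           noise_frac = 0.01, seed = 5)
  pd <- ift(data)
  expect_lt(abs(pd$dmax / 40 - 1), 0.05)
  expect_lt(pd$fit_chi2, 2)
  # halving alpha near the selected value barely moves dmax
  pd2 <- ift(data, alpha = pd$alpha / 2)
  expect_lt(abs(pd2$dmax / pd$dmax - 1), 0.05)
  # reciprocal/real-space Rg agreement on the same input
  expect_rel(rg_from_pr(pd), suppressWarnings(guinier_fit(data))$rg, 0.02)
})

test_that("forward-inverse round trip reproduces the model P(r)", {
  m <- bead_sphere(3000, 20)
  data <- simulate_profile(m, noise_frac = 0.01, seed = 11)
  pd <- ift(data)
  ref <- pr_from_model(m, nbins = 60)
  b <- stats::approx(ref$r, ref$p, xout = pd$r, rule = 2)$y
  b[is.na(b)] <- 0
  a <- pd$p / pracma::trapz(pd$r, pd$p)
  b <- b / pracma::trapz(pd$r, b)
  l2 <- sqrt(pracma::trapz(pd$r, (a - b)^2) / pracma::trapz(pd$r, b^2))
  expect_lt(l2, 0.05)
})

test_that("ift requires sigma and an explicit dmax is honoured", {
  q <- default_qgrid()
  p <- saxs_profile(q, sphere_intensity(q, 20))
  expect_error(ift(p), "sigma")
  data <- simulate_profile(p, 0.01, seed = 5)
  pd <- ift(data, dmax = 44)
  expect_equal(pd$dmax, 44)
  expect_equal(pd$p[1], 0)
  expect_equal(pd$p[length(pd$p)], 0)
})

test_that("shoulder detection reports modes and shoulders, not unimodal bumps", {
  r <- seq(0, 120, length.out = 241)
  bimodal <- pddf(r, dnorm(r, 30, 8) + 0.5 * dnorm(r, 75, 8))
  pos <- shoulder_positions(bimodal)
  expect_equal(length(pos), 2)
  expect_lt(abs(pos[1] - 30), 2)
  expect_lt(abs(pos[2] - 75), 2)
  expect_length(shoulder_positions(pddf(r, dnorm(r, 40, 12))), 0)
  # pure shoulder without a second mode
  sh <- shoulder_positions(pddf(r, dnorm(r, 30, 10) + 0.25 * dnorm(r, 75, 14)))
  expect_true(any(abs(sh - 75) < 8))
})

test_that("two HU blobs placed 22 bp apart produce a ~75 A P(r) feature", {
  m <- place_hu(build_bdna(build_spec(n_bp = 80)), mode = "explicit",
                positions = c(20, 42))
  # oracle: brute-force blob-centre separation is 22 x 3.4 = 74.8 A
  hu <- m$coords[m$kind == "protein-residue", ]
  grp <- m$group[m$kind == "protein-residue"]
  centres <- rowsum(hu, grp) / as.vector(table(grp))
  expect_equal(stats::dist(centres)[1], 74.8, tolerance = 1e-6)
  pos <- shoulder_positions(pr_from_model(m, nbins = 60))
  expect_true(any(abs(pos - 75) < 8))
})
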
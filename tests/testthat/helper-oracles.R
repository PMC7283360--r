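# Independent closed-form and brute-force oracles used across the suite.

# uniform-sphere form factor, I(0) = 1
sphere_intensity <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# orientationally averaged infinite-cylinder intensity (cross-section
# factor times the 1/q rod factor)
cylinder_intensity <- function(q, R) {
  (1 / q) * (2 * besselJ(q * R, 1) / (q * R))^2
}

# closed-form pair-distance distribution of a uniform sphere of radius R,
# normalized to unit integral on [0, 2R]
sphere_pr <- function(r, R) {
  x <- r / R
  ifelse(x >= 0 & x <= 2, 3 * x^2 * (1 - 3 * x / 4 + x^3 / 16) / R, 0)
}

# deterministic quasi-uniform bead-filled sphere (radical-inverse /
# Halton-style low-discrepancy fill; far lower sampling error than
# pseudo-random placement)
bead_sphere <- function(n, R) {
  vdc <- function(n, base) {
    vapply(seq_len(n), function(i) {
      x <- i; f <- 1 / base; r <- 0
      while (x > 0) { r <- r + f * (x %% base); x <- x %/% base; f <- f / base }
      r
    }, numeric(1))
  }
  u1 <- (seq_len(n) - 0.5) / n
  z <- 2 * vdc(n, 2) - 1
  phi <- 2 * pi * vdc(n, 3)
  r <- u1^(1 / 3) * R
  s <- sqrt(pmax(1 - z^2, 0))
  atomistic_model(cbind(r * s * cos(phi), r * s * sin(phi), r * z))
}

# mass-weighted coordinate radius of gyration (brute force over beads)
coord_rg <- function(model) {
  w <- model$weight
  ctr <- colSums(model$coords * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(model$coords, 2, ctr)^2)) / sum(w))
}

# cross-sectional Rg in the plane normal to the helix axis (z)
coord_rc <- function(model) {
  w <- model$weight
  xy <- model$coords[, 1:2, drop = FALSE]
  ctr <- colSums(xy * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xy, 2, ctr)^2)) / sum(w))
}

# naive scalar double-loop Caille structure factor (oracle for the
# vectorized implementation)
caille_naive <- function(q, d, N, eta) {
  g <- 0.57721566490153286
  sapply(q, function(qq) {
    s <- 1
    if (N > 1) for (n in 1:(N - 1))
      s <- s + 2 * (1 - n / N) * cos(qq * d * n) *
        exp(-qq^2 * d^2 * eta * (log(pi * n) + g) / (4 * pi^2))
    s
  })
}

expect_rel <- function(value, expected, tol) {
  expect_lt(abs(value / expected - 1), tol)
}
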
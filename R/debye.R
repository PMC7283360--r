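# Debye-formula profile computation from bead models, profile-to-data
# scaling, and minimal-ensemble selection against measured data.

#' Debye-formula scattering intensity of a bead model
#'
#' Exact orientational average
#' I(q) = sum_i sum_j w_i w_j sin(q r_ij) / (q r_ij). For models above
#' 500 beads the pair-distance double sum is accelerated through a
#' 0.5-Angstrom pair-distance histogram; smaller models use the exact
#' double loop. I(q -> 0) tends to (sum w)^2.
#'
#' @param model an [atomistic_model] with at least 2 beads.
#' @param qgrid positive momentum-transfer grid, 1/Angstrom.
#' @param hist_bin histogram bin width in Angstrom for the accelerated
#'   path, default 0.5.
#' @return A [saxs_profile] (no sigma).
#' @export
debye_intensity <- function(model, qgrid, hist_bin = 0.5) {
  stopifnot(inherits(model, "atomistic_model"))
  if (n_beads(model) < 2) stop("debye_intensity: need at least 2 beads")
  if (any(qgrid <= 0)) stop("debye_intensity: q must be strictly positive")
  d <- as.vector(stats::dist(model$coords))
  if (length(unique(model$weight)) == 1L) {
    wpair <- rep(model$weight[1]^2, length(d))
  } else {
    W <- tcrossprod(model$weight)
    wpair <- W[lower.tri(W)]
  }
  self <- sum(model$weight^2)
  if (n_beads(model) > 500) {
    # bin pair distances; evaluate the kernel once per occupied bin at
    # the weighted mean distance of the bin (first-moment preserving,
    # which removes the leading-order binning error)
    bin <- floor(d / hist_bin)
    acc <- tapply(wpair, bin, sum)
    accd <- tapply(wpair * d, bin, sum)
    wv <- as.numeric(acc)
    rc <- as.numeric(accd) / wv
  } else {
    rc <- d; wv <- wpair
  }
  # evaluate sum_k w_k sinc(q r_k) in q blocks to bound memory
  I <- numeric(length(qgrid))
  block <- max(1L, floor(2e6 / length(rc)))
  for (i0 in seq(1, length(qgrid), by = block)) {
    ii <- i0:min(i0 + block - 1L, length(qgrid))
    X <- outer(qgrid[ii], rc)
    I[ii] <- as.vector((sin(X) / X) %*% wv)
  }
  I <- self + 2 * I
  saxs_profile(q = qgrid, intensity = I, condition = "debye")
}

#' Scale a model profile onto measured data
#'
#' Weighted linear least squares for (scale, background) minimizing
#' sum(((I_data - c I_model - b) / sigma)^2) after linear-in-log
#' interpolation of the model onto the data grid, and the fit quality
#' chi = sqrt(mean(((I_data - c I_model - b) / sigma)^2)).
#'
#' @param model_profile a [saxs_profile] of the computed model curve.
#' @param data a [saxs_profile] with sigma present.
#' @return A list with `scale`, `background`, `chi`.
#' @export
fit_scale <- function(model_profile, data) {
  stopifnot(inherits(model_profile, "saxs_profile"),
            inherits(data, "saxs_profile"))
  if (is.null(data$sigma)) stop("fit_scale: data must carry sigma")
  Im <- .interp_model(model_profile, data$q)
  ok <- is.finite(Im)
  if (sum(ok) < 10) stop("fit_scale: fewer than 10 overlapping q points")
  w <- 1 / data$sigma[ok]
  X <- cbind(Im[ok], 1) * w
  y <- data$intensity[ok] * w
  coef <- stats::lm.fit(X, y)$coefficients
  resid <- y - X %*% coef
  list(scale = unname(coef[1]), background = unname(coef[2]),
       chi = sqrt(mean(resid^2)))
}

# interpolate a model curve onto a data q grid, linear in log I for
# positive intensities; q points outside the model support come back NA
.interp_model <- function(model_profile, q) {
  mq <- model_profile$q; mI <- model_profile$intensity
  if (all(mI > 0)) {
    out <- exp(stats::approx(mq, log(mI), xout = q, rule = 1)$y)
  } else {
    out <- stats::approx(mq, mI, xout = q, rule = 1)$y
  }
  out
}

#' Select a minimal weighted ensemble of models against data
#'
#' Considers candidate ensembles of size up to `max_size` (every subset
#' for pools of at most 15 profiles, greedy forward selection otherwise).
#' For each subset, non-negative least squares determines member
#' coefficients together with a free constant background; the fit quality
#' is the chi of [fit_scale]. The selected size is the smallest s whose
#' chi exceeds the best chi at size s + 1 by less than 5 percent
#' (parsimony rule against over-fitting); member weights are the NNLS
#' coefficients renormalized to sum to 1.
#'
#' @param pool named list of [saxs_profile]s on a common grid (model
#'   curves).
#' @param data a [saxs_profile] with sigma present.
#' @param max_size largest ensemble size considered, default 3.
#' @return A list of class `ensemble_fit`: `member_ids`, `weights`,
#'   `chi`, `size`, `chi_by_size`.
#' @export
minimal_ensemble <- function(pool, data, max_size = 3) {
  stopifnot(length(pool) >= 1, inherits(data, "saxs_profile"))
  if (is.null(data$sigma)) stop("minimal_ensemble: data must carry sigma")
  if (is.null(names(pool))) names(pool) <- paste0("m", seq_along(pool))
  cols <- vapply(pool, function(p) .interp_model(p, data$q),
                 numeric(length(data$q)))
  cols <- matrix(cols, ncol = length(pool),
                 dimnames = list(NULL, names(pool)))
  ok <- rowSums(!is.finite(cols)) == 0
  if (sum(ok) < 10) stop("minimal_ensemble: too few overlapping q points")
  w <- 1 / data$sigma[ok]
  y <- data$intensity[ok] * w
  Aw <- cols[ok, , drop = FALSE] * w
  bgp <- w; bgm <- -w   # signed background columns keep NNLS unconstrained in b
  score_subset <- function(idx) {
    A <- cbind(Aw[, idx, drop = FALSE], bgp, bgm)
    fit <- pracma::lsqnonneg(A, y)
    coefs <- fit$x[seq_along(idx)]
    chi <- sqrt(mean((y - A %*% fit$x)^2))
    list(idx = idx, coefs = coefs, chi = chi,
         background = fit$x[length(idx) + 1] - fit$x[length(idx) + 2])
  }
  np <- length(pool)
  max_size <- min(max_size, np)
  best_by_size <- vector("list", max_size)
  if (np <= 15) {
    for (s in seq_len(max_size)) {
      subsets <- utils::combn(np, s, simplify = FALSE)
      scored <- lapply(subsets, score_subset)
      best_by_size[[s]] <- scored[[which.min(vapply(scored, `[[`,
                                                    numeric(1), "chi"))]]
    }
  } else {
    chosen <- integer(0)
    for (s in seq_len(max_size)) {
      cand <- setdiff(seq_len(np), chosen)
      scored <- lapply(cand, function(j) score_subset(c(chosen, j)))
      bi <- which.min(vapply(scored, `[[`, numeric(1), "chi"))
      best_by_size[[s]] <- scored[[bi]]
      chosen <- best_by_size[[s]]$idx
    }
  }
  chi_by_size <- vapply(best_by_size, `[[`, numeric(1), "chi")
  chi_by_size <- cummin(chi_by_size)    # enforce monotone non-increasing
  size <- max_size
  for (s in seq_len(max_size - 1)) {
    if (chi_by_size[s] <= 1e-12 ||
        (chi_by_size[s] - chi_by_size[s + 1]) / chi_by_size[s] < 0.05) {
      size <- s; break
    }
  }
  sel <- best_by_size[[size]]
  keep <- sel$coefs > 0
  wts <- sel$coefs[keep] / sum(sel$coefs[keep])
  structure(list(member_ids = names(pool)[sel$idx][keep],
                 weights = unname(wts), chi = sel$chi,
                 size = sum(keep),
                 chi_by_size = stats::setNames(chi_by_size,
                                               seq_len(max_size))),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("Minimal ensemble: size %d, chi = %.4g\n", x$size, x$chi))
  for (i in seq_along(x$member_ids))
    cat(sprintf("  %s  weight %.3f\n", x$member_ids[i], x$weights[i]))
  invisible(x)
}
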
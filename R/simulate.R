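# Seeded synthetic SAXS profiles over the instrument range
# q = 0.01..0.35 1/A, and the registered pH x ionic-strength scenarios of
# the HU-DNA phase diagram (lamellar bundles, HU-coated filaments,
# aggregates).

#' Default instrument q grid
#'
#' 400 log-spaced points over the measured range 0.01 to 0.35 1/Angstrom.
#' @param n number of points, default 400.
#' @param qmin,qmax range, 1/Angstrom.
#' @return Numeric q grid.
#' @export
default_qgrid <- function(n = 400, qmin = 0.01, qmax = 0.35) {
  exp(seq(log(qmin), log(qmax), length.out = n))
}

# run expr under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a noisy SAXS profile from a model
#'
#' Computes the ideal curve ([lamellar_intensity] for a [lamellar_model],
#' [debye_intensity] for an [atomistic_model]; a [saxs_profile] is taken
#' as the ideal curve itself), then perturbs it with Gaussian noise of
#' standard deviation sigma(q) = noise_frac * I(q) * (1 + 2 q / qmax), so
#' the signal-to-noise degrades towards high q as at a real detector.
#' Fully reproducible for a given seed.
#'
#' @param source a [lamellar_model], [atomistic_model] or [saxs_profile].
#' @param noise_frac relative noise level at low q (>= 0); 0 gives the
#'   exact curve with a tiny floor sigma.
#' @param seed integer RNG seed.
#' @param qgrid momentum-transfer grid, default [default_qgrid()].
#' @return A [saxs_profile] with sigma present.
#' @export
simulate_profile <- function(source, noise_frac = 0.01, seed = 1,
                             qgrid = default_qgrid()) {
  if (noise_frac < 0) stop("simulate_profile: noise_frac must be >= 0")
  ideal <- if (inherits(source, "lamellar_model"))
    lamellar_intensity(qgrid, source)
  else if (inherits(source, "atomistic_model"))
    debye_intensity(source, qgrid)
  else if (inherits(source, "saxs_profile")) source
  else stop("simulate_profile: unsupported source type")
  q <- ideal$q; I <- ideal$intensity
  floor_ <- 1e-10 * max(abs(I))
  sigma <- pmax(noise_frac * abs(I) * (1 + 2 * q / max(q)), floor_)
  Inoisy <- if (noise_frac > 0)
    .with_seed(seed, I + stats::rnorm(length(I), 0, sigma)) else I
  saxs_profile(q = q, intensity = Inoisy, sigma = sigma,
               condition = ideal$condition)
}

#' Registered phase-diagram scenarios
#'
#' Returns the scenario registry shipped with the package
#' (`inst/extdata/scenarios.yaml`): one entry per pH x NaCl condition of
#' the HU-DNA phase diagram, each with the expected phase label, the
#' lamellar repeat spacing where applicable, the generator, the noise
#' level and a registered seed.
#'
#' @return A data.frame with one row per scenario.
#' @export
saxs_scenarios <- function() {
  path <- system.file("extdata", "scenarios.yaml", package = "saxsphase")
  reg <- yaml::read_yaml(path)
  do.call(rbind, lapply(reg$scenarios, function(s)
    data.frame(name = s$name, expected_label = s$expected_label,
               generator = s$generator,
               d = if (is.null(s$d)) NA_real_ else s$d,
               noise_frac = s$noise_frac, seed = s$seed,
               stringsAsFactors = FALSE)))
}

# shared nuisance parameters of the lamellar scenarios
.SCEN_N_PLATES <- 20L
.SCEN_ETA <- 0.1
.SCEN_DELTA <- 20
.SCEN_POLY <- 0.05

.filament_model <- function() {
  place_hu(build_bdna(build_spec(n_bp = 80)), mode = "saturated")
}

#' Generate a registered scenario profile
#'
#' Builds the registered generator for `name` (a lamellar-stack Caille
#' curve with N = 20, eta = 0.1, delta = 20 A, 5 percent thickness
#' polydispersity; an HU-saturated 80-bp duplex Debye curve; or a steep
#' q^-3.5 aggregate decay) and simulates it at the registered noise level
#' and seed.
#'
#' @param name scenario name, e.g. `"pH4.5_150mM"`; see
#'   [saxs_scenarios()].
#' @param seed optional seed overriding the registered one.
#' @param qgrid momentum-transfer grid, default [default_qgrid()].
#' @return A list with `profile` (the simulated [saxs_profile]) and
#'   `scenario` (the registry row, ground truth included).
#' @export
scenario_profile <- function(name, seed = NULL, qgrid = default_qgrid()) {
  reg <- saxs_scenarios()
  row <- reg[reg$name == name, ]
  if (nrow(row) != 1)
    stop("unknown scenario '", name, "'; registered: ",
         paste(reg$name, collapse = ", "))
  if (is.null(seed)) seed <- row$seed
  source <- switch(row$generator,
    lamellar = lamellar_model(d = row$d, delta = .SCEN_DELTA,
                              n_plates = .SCEN_N_PLATES, eta = .SCEN_ETA,
                              poly_delta = .SCEN_POLY),
    filament = .filament_model(),
    aggregate = saxs_profile(q = qgrid, intensity = qgrid^-3.5,
                             condition = name),
    stop("unknown generator: ", row$generator))
  prof <- simulate_profile(source, noise_frac = row$noise_frac,
                           seed = seed, qgrid = qgrid)
  prof$condition <- name
  list(profile = prof, scenario = row)
}
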
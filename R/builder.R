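# Coarse-grained builders: B-DNA duplexes at two beads per nucleotide,
# HU-dimer blobs docked along the duplex, and rectangular bundles of
# parallel duplexes at a prescribed inter-duplex spacing.

# relative electron counts per coarse bead (H excluded):
# nucleotide ~ 340 e split backbone (phosphate + sugar) / base;
# HU dimer ~ 10,000 e over a 20-bead blob.
.W_BACKBONE <- 110
.W_BASE <- 60
.W_HU_BEAD <- 500
.HU_BLOB_BEADS <- 20L
.MINOR_GROOVE_PHASE <- 154 * pi / 180  # inter-strand azimuthal offset

#' Geometry specification for coarse DNA/HU model building
#'
#' @param n_bp base pairs per duplex (>= 2).
#' @param rise axial rise per base pair, Angstrom (B-form default 3.4).
#' @param twist helical twist per base pair, degrees (default 36).
#' @param helix_radius phosphate-track radius, Angstrom (default 9.4).
#' @param hu_per_duplex HU dimers bound per duplex (default 0).
#' @param hu_mode one of `"uniform"`, `"saturated"`, `"explicit"`.
#' @param lattice optional list(n_x, n_y, spacing) describing a
#'   rectangular bundle; spacing in Angstrom must exceed the duplex
#'   diameter.
#' @return A list of class `build_spec`.
#' @export
build_spec <- function(n_bp = 80, rise = 3.4, twist = 36,
                       helix_radius = 9.4, hu_per_duplex = 0,
                       hu_mode = c("uniform", "saturated", "explicit"),
                       lattice = NULL) {
  hu_mode <- match.arg(hu_mode)
  stopifnot(n_bp >= 2, rise > 0, helix_radius > 0, hu_per_duplex >= 0)
  if (!is.null(lattice)) {
    stopifnot(all(c("n_x", "n_y", "spacing") %in% names(lattice)))
    if (lattice$spacing <= 2 * helix_radius)
      stop("build_spec: lattice spacing must exceed the duplex diameter (",
           2 * helix_radius, " A)")
  }
  structure(list(n_bp = as.integer(n_bp), rise = rise, twist = twist,
                 helix_radius = helix_radius,
                 hu_per_duplex = hu_per_duplex, hu_mode = hu_mode,
                 lattice = lattice),
            class = "build_spec")
}

#' Build an ideal straight B-form DNA duplex bead model
#'
#' Two beads per nucleotide (backbone bead on the phosphate track at
#' `helix_radius`, base bead at 0.4 x that radius), two antiparallel
#' strands offset by the minor/major-groove phase, helix axis along z.
#' The axial extent is exactly (n_bp - 1) x rise; for 80 bp at B-form
#' geometry the maximal bead-pair distance is ~270 Angstrom.
#'
#' @param spec a [build_spec].
#' @return An [atomistic_model] of 4 x n_bp beads with the spec attached
#'   as attribute `"build_spec"`.
#' @export
build_bdna <- function(spec = build_spec()) {
  stopifnot(inherits(spec, "build_spec"))
  n <- spec$n_bp
  if (n < 2) stop("build_bdna: n_bp must be >= 2")
  z <- (seq_len(n) - 1) * spec$rise
  th1 <- (seq_len(n) - 1) * spec$twist * pi / 180
  th2 <- th1 + .MINOR_GROOVE_PHASE
  R <- spec$helix_radius; rb <- 0.4 * R
  coords <- rbind(
    cbind(R * cos(th1), R * sin(th1), z),    # strand 1 backbone
    cbind(rb * cos(th1), rb * sin(th1), z),  # strand 1 base
    cbind(R * cos(th2), R * sin(th2), z),    # strand 2 backbone
    cbind(rb * cos(th2), rb * sin(th2), z))  # strand 2 base
  weight <- rep(c(.W_BACKBONE, .W_BASE, .W_BACKBONE, .W_BASE), each = n)
  model <- atomistic_model(coords, weight = weight, kind = "DNA-nucleotide",
                           group = "A")
  attr(model, "build_spec") <- spec
  model
}

# Deterministic 20-bead blob approximating an HU dimer: golden-spiral
# fill of an ellipsoid with semi-axes (15, 17.5, 22.5) A (a 30x35x45 A
# proxy; solution Rg ~ 14.5 A), longest axis along the DNA axis.
.hu_blob <- function() {
  k <- seq_len(.HU_BLOB_BEADS)
  golden <- pi * (3 - sqrt(5))
  u <- (k - 0.5) / .HU_BLOB_BEADS
  r <- u^(1 / 3)
  zc <- 1 - 2 * u                 # cos(polar) spread
  s <- sqrt(pmax(1 - zc^2, 0))
  phi <- k * golden
  cbind(15 * r * s * cos(phi), 17.5 * r * s * sin(phi), 22.5 * r * zc)
}

#' Decorate a duplex with HU-dimer blobs
#'
#' Adds HU dimers as compact ~20-bead protein blobs centred 12 Angstrom
#' off the helix axis at assigned base-pair positions. `uniform` mode
#' spaces the centres evenly along the duplex, `saturated` tiles one dimer
#' per 9 bp until the duplex is full, `explicit` takes base-pair positions
#' directly.
#'
#' @param model a duplex (or bundle) built by [build_bdna] /
#'   [build_bundle]; must carry the `"build_spec"` attribute.
#' @param n_dimers number of dimers (ignored, and disallowed, in
#'   saturated mode).
#' @param mode `"uniform"`, `"saturated"` or `"explicit"`.
#' @param positions base-pair positions (0-based, fractional allowed) for
#'   explicit mode.
#' @return The decorated [atomistic_model].
#' @export
place_hu <- function(model, n_dimers = NULL,
                     mode = c("uniform", "saturated", "explicit"),
                     positions = NULL) {
  mode <- match.arg(mode)
  spec <- attr(model, "build_spec")
  if (is.null(spec)) stop("place_hu: model lacks build geometry metadata")
  n_bp <- spec$n_bp; rise <- spec$rise
  if (mode == "saturated") {
    if (!is.null(n_dimers))
      stop("place_hu: saturated mode and explicit n_dimers conflict")
    nd <- n_bp %/% 9L
    pos <- (seq_len(nd) - 0.5) * 9
  } else if (mode == "explicit") {
    if (is.null(positions)) stop("place_hu: explicit mode needs positions")
    pos <- positions
  } else {
    if (is.null(n_dimers)) stop("place_hu: uniform mode needs n_dimers")
    if (n_dimers == 0) return(model)
    pos <- (seq_len(n_dimers) - 0.5) / n_dimers * n_bp
  }
  if (any(pos < 0 | pos > n_bp))
    stop("place_hu: dimer positions fall off the duplex (0..", n_bp, " bp)")
  if (!length(pos)) return(model)
  blob <- .hu_blob()
  hu_coords <- do.call(rbind, lapply(seq_along(pos), function(i)
    sweep(blob, 2, c(12, 0, pos[i] * rise), `+`)))
  nh <- nrow(hu_coords)
  out <- atomistic_model(
    rbind(model$coords, hu_coords),
    weight = c(model$weight, rep(.W_HU_BEAD, nh)),
    kind = c(model$kind, rep("protein-residue", nh)),
    group = c(model$group,
              rep(paste0("H", seq_along(pos)), each = nrow(blob))))
  attr(out, "build_spec") <- spec
  out
}

#' Build a rectangular bundle of parallel duplexes
#'
#' Places n_x x n_y copies of the duplex on a rectangular lattice at the
#' given axis-to-axis spacing, axes aligned; each duplex is optionally
#' decorated with HU dimers per `hu_per_duplex` / `hu_mode` in the spec.
#' A 1x1 lattice is identical to [build_bdna].
#'
#' @param spec a [build_spec] with `lattice` present.
#' @return An [atomistic_model]; per-duplex geometry is preserved
#'   bead-for-bead, groups distinguish the lattice copies.
#' @export
build_bundle <- function(spec) {
  stopifnot(inherits(spec, "build_spec"))
  if (is.null(spec$lattice)) stop("build_bundle: spec$lattice is required")
  lat <- spec$lattice
  if (lat$spacing <= 2 * spec$helix_radius)
    stop("build_bundle: duplexes overlap at spacing ", lat$spacing, " A")
  duplex <- build_bdna(spec)
  if (spec$hu_per_duplex > 0 || spec$hu_mode == "saturated")
    duplex <- place_hu(duplex,
                       n_dimers = if (spec$hu_mode == "saturated") NULL
                       else spec$hu_per_duplex,
                       mode = spec$hu_mode)
  copies <- list()
  idx <- 0L
  for (ix in seq_len(lat$n_x) - 1L) for (iy in seq_len(lat$n_y) - 1L) {
    idx <- idx + 1L
    m <- duplex
    m$coords <- sweep(m$coords, 2, c(ix * lat$spacing, iy * lat$spacing, 0),
                      `+`)
    m$group <- paste0("D", idx, ".", m$group)
    copies[[idx]] <- m
  }
  out <- atomistic_model(do.call(rbind, lapply(copies, `[[`, "coords")),
                         weight = unlist(lapply(copies, `[[`, "weight")),
                         kind = unlist(lapply(copies, `[[`, "kind")),
                         group = unlist(lapply(copies, `[[`, "group")))
  attr(out, "build_spec") <- spec
  out
}

#' Build a pool of HU-DNA models at different stoichiometries
#'
#' One duplex model per requested HU stoichiometry, uniform placement;
#' deterministic given the spec. Used as the candidate pool for
#' ensemble fitting.
#'
#' @param base a [build_spec] describing the duplex.
#' @param stoichiometries integer vector of HU dimers per duplex.
#' @return A named list of [atomistic_model]s (`"hu<k>"`).
#' @export
build_pool <- function(base, stoichiometries) {
  stopifnot(inherits(base, "build_spec"), length(stoichiometries) >= 1)
  duplex <- build_bdna(base)
  out <- lapply(stoichiometries, function(k)
    if (k == 0) duplex else place_hu(duplex, n_dimers = k, mode = "uniform"))
  names(out) <- paste0("hu", stoichiometries)
  out
}
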
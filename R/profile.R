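#' Construct a SAXS scattering profile
#'
#' A `saxs_profile` holds a one-dimensional scattering curve: momentum
#' transfer q (in inverse Angstrom, q = 4 pi sin(theta) / lambda), relative
#' intensity I(q), and optionally a 1-sigma uncertainty per point, plus a
#' free-text condition tag (e.g. pH and salt of the sample).
#'
#' @param q numeric vector of momentum-transfer values, 1/Angstrom; must be
#'   strictly increasing and positive.
#' @param intensity numeric vector of intensities, same length as `q`; must
#'   be finite.
#' @param sigma optional numeric vector of 1-sigma uncertainties, strictly
#'   positive, same length as `q`.
#' @param condition free-text sample/condition tag, default `""`.
#' @return An object of class `saxs_profile`: a list with elements `q`,
#'   `intensity`, `sigma` (possibly `NULL`) and `condition`.
#' @examples
#' p <- saxs_profile(q = c(0.01, 0.02, 0.03), intensity = c(100, 90, 80))
#' p
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, condition = "") {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop("q and intensity must have equal length")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q must be finite and strictly positive")
  if (any(diff(q) <= 0))
    stop("q must be strictly increasing (profiles are never silently reordered)")
  if (any(!is.finite(intensity)))
    stop("intensity must be finite at every point")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("sigma must have the same length as q")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must be finite and strictly positive")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 condition = as.character(condition)[1]),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat("SAXS profile:", length(x$q), "points, q in [",
      format(min(x$q), digits = 4), ",", format(max(x$q), digits = 4),
      "] 1/A,", if (is.null(x$sigma)) "no sigma" else "with sigma", "\n")
  if (nzchar(x$condition)) cat("  condition:", x$condition, "\n")
  invisible(x)
}

#' Read a SAXS profile from a 3-column ASCII file
#'
#' Reads the de facto beamline `.dat` format: whitespace-delimited numeric
#' columns (q, I and optionally sigma), with `#`-prefixed comment/header
#' lines. A header line of the form `# condition: <text>` populates the
#' condition tag. Rows with non-positive q are dropped (with a message).
#'
#' @param path path to the file.
#' @param q_unit either `"A"` (inverse Angstrom, default) or `"nm"`
#'   (inverse nanometre; q is divided by 10 on read).
#' @return A [saxs_profile].
#' @export
read_profile <- function(path, q_unit = c("A", "nm")) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) stop("cannot read profile: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  comments <- grep("^\\s*#", lines, value = TRUE)
  condition <- ""
  m <- regmatches(comments, regexec("#\\s*condition:\\s*(.*)$", comments))
  hit <- which(vapply(m, length, 1L) == 2L)
  if (length(hit)) condition <- trimws(m[[hit[1]]][2])
  data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(data_lines)) stop("format error: no data rows in ", path)
  fields <- strsplit(trimws(data_lines), "\\s+")
  ncol <- min(vapply(fields, length, 1L))
  if (ncol < 2) stop("format error: fewer than 2 numeric columns in ", path)
  mat <- t(vapply(fields, function(f) as.numeric(f[seq_len(min(ncol, 3L))]),
                  numeric(min(ncol, 3L))))
  if (any(!is.finite(mat[, 1:2]))) stop("format error: non-numeric values in ", path)
  keep <- mat[, 1] > 0
  if (sum(!keep) > 0)
    message("read_profile: dropped ", sum(!keep), " rows with non-positive q")
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 10) stop("format error: fewer than 10 usable rows in ", path)
  qv <- mat[, 1]
  if (q_unit == "nm") qv <- qv / 10
  sigma <- if (ncol(mat) >= 3) mat[, 3] else NULL
  saxs_profile(q = qv, intensity = mat[, 2], sigma = sigma,
               condition = condition)
}

#' Write a SAXS profile to a 3-column ASCII file
#'
#' Writes `# condition:` header (when non-empty) followed by three
#' whitespace-separated columns q, I, sigma. Profiles without sigma are
#' written with sigma set to 1 percent of |I| (with a message) so that
#' downstream chi statistics are defined on re-read.
#'
#' @param profile a [saxs_profile].
#' @param path output path.
#' @return Invisibly, the path written.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "saxs_profile"))
  sigma <- profile$sigma
  if (is.null(sigma)) {
    message("write_profile: no sigma present; writing 1% of |I|")
    sigma <- pmax(0.01 * abs(profile$intensity), 1e-12)
  }
  hdr <- c("# SAXS profile: q [1/A]  I(q)  sigma",
           if (nzchar(profile$condition))
             paste0("# condition: ", profile$condition))
  rows <- sprintf("%.8e %.8e %.8e", profile$q, profile$intensity, sigma)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write profile: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}
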
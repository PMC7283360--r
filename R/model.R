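#' Construct a coarse atomistic bead model
#'
#' An `atomistic_model` is a coarse-grained representation of a molecule or
#' assembly as point scatterers: bead coordinates in Angstrom, a relative
#' scattering weight per bead (relative electron counts at this level of
#' coarse-graining), a per-bead kind label and a chain/molecule group.
#'
#' @param coords numeric matrix, n x 3, bead coordinates in Angstrom.
#' @param weight numeric vector of positive scattering weights, length n.
#' @param kind character vector of per-bead labels, typically
#'   `"DNA-nucleotide"` or `"protein-residue"`; recycled if length 1.
#' @param group character vector of chain/molecule identifiers; recycled.
#' @return An object of class `atomistic_model`.
#' @export
atomistic_model <- function(coords, weight = rep(1, nrow(coords)),
                            kind = "DNA-nucleotide", group = "A") {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3 || nrow(coords) < 1)
    stop("coords must be a non-empty numeric n x 3 matrix")
  if (any(!is.finite(coords))) stop("all coordinates must be finite")
  n <- nrow(coords)
  weight <- rep_len(as.numeric(weight), n)
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("all bead weights must be positive and finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(coords = coords, weight = weight,
                 kind = rep_len(as.character(kind), n),
                 group = rep_len(as.character(group), n)),
            class = "atomistic_model")
}

#' @export
print.atomistic_model <- function(x, ...) {
  cat("Atomistic bead model:", nrow(x$coords), "beads,",
      length(unique(x$group)), "group(s);",
      "kinds:", paste(names(table(x$kind)), table(x$kind),
                      sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of beads in a model
#' @param model an [atomistic_model].
#' @return Integer bead count.
#' @export
n_beads <- function(model) nrow(model$coords)

# Relative electron counts (hydrogen excluded) for PDB input; coarse but
# adequate for Debye profiles at nm resolution.
.element_weights <- c(C = 6, N = 7, O = 8, P = 15, S = 16)

#' Read a bead model from a PDB-format or CSV bead-table file
#'
#' PDB files: one bead per ATOM/HETATM record, weight assigned from the
#' element (relative electron count, H excluded), group from the chain
#' identifier, kind from the residue name (`DA/DT/DG/DC/DNA` records map to
#' `"DNA-nucleotide"`, anything else to `"protein-residue"`).
#' CSV bead tables: columns `x, y, z, weight, kind` (and optionally
#' `group`), with a header row.
#'
#' @param path path to a `.pdb` file or a `.csv` bead table.
#' @return An [atomistic_model].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("cannot read model: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^(ATOM|HETATM)", lines))) return(.read_model_pdb(lines))
  # fall back to CSV bead table
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("format error: ", conditionMessage(e)))
  need <- c("x", "y", "z", "weight", "kind")
  if (!all(need %in% names(df)))
    stop("format error: bead table needs columns x, y, z, weight, kind")
  if (nrow(df) < 1) stop("format error: no parseable coordinates in ", path)
  atomistic_model(coords = as.matrix(df[, c("x", "y", "z")]),
                  weight = df$weight, kind = df$kind,
                  group = if ("group" %in% names(df)) df$group else "A")
}

.read_model_pdb <- function(lines) {
  rec <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(rec)) stop("format error: no parseable coordinates")
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  if (any(!is.finite(c(x, y, z))))
    stop("format error: malformed PDB coordinate fields")
  chain <- trimws(substr(rec, 22, 22))
  chain[!nzchar(chain)] <- "A"
  resname <- trimws(substr(rec, 18, 20))
  elem <- trimws(substr(rec, 77, 78))
  noelem <- !nzchar(elem)
  # fall back to first letter of the atom name when element column is empty
  elem[noelem] <- substr(gsub("[^A-Za-z].*$", "",
                              trimws(substr(rec[noelem], 13, 16))), 1, 1)
  w <- .element_weights[toupper(elem)]
  w[is.na(w)] <- 6  # unknown elements treated as carbon-like
  kind <- ifelse(resname %in% c("DA", "DT", "DG", "DC", "DNA", "BKB", "BAS"),
                 "DNA-nucleotide", "protein-residue")
  atomistic_model(cbind(x, y, z), weight = as.numeric(w),
                  kind = kind, group = chain)
}

#' Write a bead model to PDB format or a CSV bead table
#'
#' PDB output encodes the kind in the residue name (`DNA` or `PRO`), the
#' group in the chain identifier, and the weight in the B-factor column;
#' coordinates are written at PDB precision (3 decimals).
#'
#' @param model an [atomistic_model].
#' @param path output path; format chosen by extension (`.pdb` vs `.csv`).
#' @return Invisibly, the path written.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "atomistic_model"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- data.frame(x = model$coords[, 1], y = model$coords[, 2],
                     z = model$coords[, 3], weight = model$weight,
                     kind = model$kind, group = model$group)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  n <- n_beads(model)
  res <- ifelse(model$kind == "DNA-nucleotide", "DNA", "PRO")
  chain <- substr(model$group, 1, 1)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
    seq_len(n) %% 100000L, res, chain, (seq_len(n) - 1L) %% 10000L,
    model$coords[, 1], model$coords[, 2], model$coords[, 3],
    pmin(model$weight, 999.99))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
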
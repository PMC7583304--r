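#' @importFrom stats cor median prcomp rnorm sd setNames var
#' @importFrom utils head read.csv write.csv
#' @importFrom graphics abline
NULL

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct an amino-acid property table
#'
#' A property table couples named per-residue numeric scales (one value per
#' standard amino acid) with named residue groups (subsets of the 20-letter
#' alphabet). Descriptor computation draws on both: scales are turned into
#' per-position encodings, groups restrict or count residues.
#'
#' @param properties named list; each element a numeric vector of length 20
#'   named by the one-letter amino-acid codes, all values finite.
#' @param groups named list; each element a non-empty character vector of
#'   one-letter codes.
#' @return An object of class `aa_property_table`.
#' @seealso [default_property_table()]
#' @export
property_table <- function(properties, groups) {
  stopifnot(is.list(properties), is.list(groups),
            length(properties) >= 1L, length(groups) >= 1L)
  if (is.null(names(properties)) || anyDuplicated(names(properties)))
    stop("properties must be uniquely named")
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("groups must be uniquely named")
  properties <- lapply(properties, function(p) {
    if (!is.numeric(p) || length(p) != 20L)
      stop("each property vector must have exactly 20 entries")
    if (is.null(names(p)) || !setequal(names(p), AA_ALPHABET))
      stop("property vectors must be named by the 20 standard amino acids")
    if (!all(is.finite(p))) stop("property values must be finite")
    p[AA_ALPHABET]
  })
  groups <- lapply(groups, function(g) {
    g <- unique(toupper(g))
    if (length(g) == 0L || !all(g %in% AA_ALPHABET))
      stop("each group must be a non-empty subset of the amino-acid alphabet")
    g
  })
  structure(list(properties = properties, groups = groups),
            class = "aa_property_table")
}

#' Default amino-acid property table
#'
#' Ships six published per-residue scales and five residue groups commonly
#' used to describe peptide physicochemistry:
#'
#' * `side_chain_mass` -- side-chain monomer masses (Da).
#' * `z1`, `z2`, `z3` -- the three principal-property z-scales of Hellberg
#'   et al. (1987): lipophilicity, steric bulk/size, and polarity axes
#'   derived from 29 physicochemical measurements.
#' * `isoelectric_point` -- residue pI (Lehninger).
#' * `hydrophilicity` -- Hopp & Woods (1981) hydrophilicity.
#' * `hydropathy` -- Kyte & Doolittle (1982) hydropathy index.
#'
#' Groups: `aliphatic`, `aromatic`, `uncharged_polar`, `charged`, and
#' `helix_favoring` (Chou-Fasman alpha-helix formers). The table is a plain
#' value: extend it by appending to `$properties` / `$groups` and passing the
#' result through [property_table()] again.
#'
#' @return An `aa_property_table`.
#' @export
default_property_table <- function() {
  aa <- AA_ALPHABET
  p <- list(
    side_chain_mass = c(
      A = 15.03, C = 47.10, D = 59.04, E = 73.07, F = 91.13,
      G = 1.01,  H = 81.10, I = 57.11, K = 72.13, L = 57.11,
      M = 75.15, N = 58.06, P = 41.06, Q = 72.09, R = 100.14,
      S = 31.03, T = 45.06, V = 43.09, W = 130.17, Y = 107.13),
    z1 = c(
      A = 0.07,  C = 0.71,  D = 3.64,  E = 3.08,  F = -4.92,
      G = 2.23,  H = 2.41,  I = -4.44, K = 2.84,  L = -4.19,
      M = -2.49, N = 3.22,  P = -1.22, Q = 2.18,  R = 2.88,
      S = 1.96,  T = 0.92,  V = -2.69, W = -4.75, Y = -1.39),
    z2 = c(
      A = -1.73, C = -0.97, D = 1.13,  E = 0.39,  F = 1.30,
      G = -5.36, H = 1.74,  I = -1.68, K = 1.41,  L = -1.03,
      M = -0.27, N = 1.45,  P = 0.88,  Q = 0.53,  R = 2.52,
      S = -1.63, T = -2.09, V = -2.53, W = 3.65,  Y = 2.32),
    z3 = c(
      A = 0.09,  C = 4.13,  D = 2.36,  E = -0.07, F = 0.45,
      G = 0.30,  H = 1.11,  I = -1.03, K = -3.14, L = -0.98,
      M = -0.41, N = 0.84,  P = 2.23,  Q = -1.14, R = -3.44,
      S = 0.57,  T = -1.40, V = -1.29, W = 0.85,  Y = 0.01),
    isoelectric_point = c(
      A = 6.01, C = 5.07, D = 2.77, E = 3.22, F = 5.48,
      G = 5.97, H = 7.59, I = 6.02, K = 9.74, L = 5.98,
      M = 5.74, N = 5.41, P = 6.48, Q = 5.65, R = 10.76,
      S = 5.68, T = 5.87, V = 5.97, W = 5.89, Y = 5.66),
    hydrophilicity = c(
      A = -0.5, C = -1.0, D = 3.0,  E = 3.0,  F = -2.5,
      G = 0.0,  H = -0.5, I = -1.8, K = 3.0,  L = -1.8,
      M = -1.3, N = 0.2,  P = 0.0,  Q = 0.2,  R = 3.0,
      S = 0.3,  T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
    hydropathy = c(
      A = 1.8,  C = 2.5,  D = -3.5, E = -3.5, F = 2.8,
      G = -0.4, H = -3.2, I = 4.5,  K = -3.9, L = 3.8,
      M = 1.9,  N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
      S = -0.8, T = -0.7, V = 4.2,  W = -0.9, Y = -1.3)
  )
  g <- list(
    aliphatic       = c("A", "G", "I", "L", "P", "V"),
    aromatic        = c("F", "W", "Y", "H"),
    uncharged_polar = c("S", "T", "N", "Q", "C", "Y"),
    charged         = c("D", "E", "K", "R", "H"),
    helix_favoring  = c("E", "M", "A", "L", "K", "F", "Q", "W", "I", "V")
  )
  property_table(p, g)
}

#' @export
print.aa_property_table <- function(x, ...) {
  cat("Amino-acid property table\n")
  cat("  properties:", paste(names(x$properties), collapse = ", "), "\n")
  cat("  groups:    ", paste(sprintf("%s (%d)", names(x$groups),
                                     lengths(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Normalize and validate peptide sequences
#'
#' Uppercases sequences and enforces the 20-letter standard alphabet.
#' Nonstandard letters (B, J, O, U, X, Z) are rejected unless `strict =
#' FALSE`, in which case `X` alone is tolerated; downstream, `X` positions
#' take the mean value of each property scale (an "average residue").
#'
#' @param sequences character vector of peptide sequences.
#' @param ids optional character vector of unique identifiers.
#' @param strict reject every nonstandard letter (default `TRUE`).
#' @return A data frame with columns `id` and `sequence`, class
#'   `peptide_records`.
#' @export
peptide_records <- function(sequences, ids = NULL, strict = TRUE) {
  if (length(sequences) == 0L) stop("no sequences supplied")
  sequences <- toupper(as.character(sequences))
  if (is.null(ids)) ids <- sprintf("pep_%05d", seq_along(sequences))
  ids <- as.character(ids)
  if (length(ids) != length(sequences)) stop("ids and sequences lengths differ")
  if (anyDuplicated(ids))
    stop("duplicate peptide ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(sequences)))
    stop("empty sequence for id: ", paste(ids[!nzchar(sequences)], collapse = ", "))
  allowed <- if (strict) AA_ALPHABET else c(AA_ALPHABET, "X")
  bad <- vapply(strsplit(sequences, ""),
                function(s) any(!s %in% allowed), logical(1L))
  if (any(bad))
    stop("illegal residues (outside the standard alphabet) in: ",
         paste(ids[bad], collapse = ", "))
  structure(data.frame(id = ids, sequence = sequences,
                       stringsAsFactors = FALSE),
            class = c("peptide_records", "data.frame"))
}
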
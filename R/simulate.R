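#' Simulate random peptide sequences
#'
#' Seeded random peptides over the 20-letter alphabet: lengths uniform on
#' `length_range`, residues drawn independently with the given composition
#' weights (uniform by default). Deterministic per seed.
#'
#' @param n number of peptides (>= 1).
#' @param length_range integer vector `c(min, max)` of sequence lengths.
#' @param composition optional named numeric vector of residue weights
#'   (names from the 20-letter alphabet; renormalized to probabilities).
#' @param seed integer seed.
#' @param prefix id prefix.
#' @return A [peptide_records] data frame.
#' @export
simulate_peptides <- function(n, length_range = c(10L, 50L),
                              composition = NULL, seed = 1L,
                              prefix = "pep") {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  stopifnot(length(length_range) == 2L, length_range[1L] >= 1L,
            length_range[1L] <= length_range[2L])
  prob <- rep(1 / 20, 20)
  names(prob) <- AA_ALPHABET
  if (!is.null(composition)) {
    if (is.null(names(composition)) ||
        !all(names(composition) %in% AA_ALPHABET) ||
        any(composition < 0) || sum(composition) <= 0)
      stop("composition must be non-negative weights named by amino acids")
    prob[] <- 0
    prob[names(composition)] <- composition / sum(composition)
  }
  set.seed(seed)
  lens <- sample(seq.int(length_range[1L], length_range[2L]), n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = prob), collapse = ""),
    character(1L))
  peptide_records(seqs, ids = sprintf("%s_%05d", prefix, seq_len(n)))
}

#' Simulate a seeded point set in d-dimensional space
#'
#' Standard-normal coordinates; used to exercise the metric-space and
#' network machinery independently of descriptor computation.
#'
#' @param n number of points.
#' @param d dimensions.
#' @param seed integer seed.
#' @return Numeric `n x d` matrix with ids `pt_...` as rownames.
#' @export
simulate_points <- function(n, d, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(n * d), n, d,
              dimnames = list(sprintf("pt_%05d", seq_len(n)),
                              sprintf("dim_%02d", seq_len(d))))
  m
}

#' Simulate a descriptor matrix with planted redundant blocks
#'
#' Generates `n_blocks` latent standard-normal factors; each block of
#' `block_size` features is the same factor plus independent Gaussian noise
#' (`noise_sd`), so within-block features are strongly redundant while
#' between-block features are independent. Remaining columns (up to
#' `n_features`) are pure independent noise. The structure emulates what a
#' large descriptor catalogue looks like after computing many variations of
#' the same property: groups of near-duplicates plus idiosyncratic
#' features.
#'
#' @param n instances (rows).
#' @param n_features total features.
#' @param n_blocks number of redundant blocks.
#' @param block_size features per block.
#' @param noise_sd within-block noise standard deviation.
#' @param seed integer seed.
#' @return Numeric matrix with named rows/columns.
#' @export
simulate_redundant_matrix <- function(n = 400L, n_features = 60L,
                                      n_blocks = 6L, block_size = 5L,
                                      noise_sd = 0.3, seed = 1L) {
  stopifnot(n_blocks * block_size <= n_features)
  set.seed(seed)
  latent <- matrix(rnorm(n * n_blocks), n, n_blocks)
  cols <- vector("list", n_features)
  j <- 0L
  for (b in seq_len(n_blocks)) {
    for (s in seq_len(block_size)) {
      j <- j + 1L
      cols[[j]] <- latent[, b] + rnorm(n, sd = noise_sd)
    }
  }
  while (j < n_features) {
    j <- j + 1L
    cols[[j]] <- rnorm(n)
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(sprintf("obs_%04d", seq_len(n)),
                      sprintf("f_%03d", seq_len(n_features)))
  m
}
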
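#' Pairwise local-alignment identity
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap penalties
#' (open 10, extend 0.5 by default, the BioJava/EMBOSS convention). Identity
#' is computed over the aligned columns of the optimal local alignment,
#' gap columns included (`denominator = "alignment"`); the alternative
#' `"shorter"` divides by the shorter sequence length instead.
#'
#' @param a,b peptide sequences (character scalars, non-empty).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param denominator identity denominator convention.
#' @return A list of class `alignment_result` with `identity_percent`
#'   in \[0, 100\], `matches`, `alignment_length` and `score`.
#' @export
local_identity <- function(a, b, gap_open = 10, gap_extend = 0.5,
                           denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "local", substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend)
  len <- nchar(as.character(Biostrings::pattern(al)))
  matches <- Biostrings::nmatch(al)
  if (length(len) == 0L || len == 0L) {  # no positive-scoring local alignment
    len <- 0L; matches <- 0L
  }
  denom <- if (denominator == "alignment") max(len, 1L) else min(nchar(a), nchar(b))
  structure(list(identity_percent = 100 * matches / denom,
                 matches = matches,
                 alignment_length = len,
                 score = Biostrings::score(al)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("local alignment: %.1f%% identity (%d/%d columns), score %.1f\n",
              x$identity_percent, x$matches, x$alignment_length, x$score))
  invisible(x)
}

# BLOSUM62 from Biostrings' bundled data, loaded once per session.
blosum62_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})
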
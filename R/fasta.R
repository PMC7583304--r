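#' Read peptide sequences from a FASTA file
#'
#' Plain or gzipped FASTA; the id is the header token up to the first
#' whitespace. Duplicate ids, empty sequences and illegal residues are
#' errors (see [peptide_records()] for the residue policy).
#'
#' @param path FASTA file path (optionally gzip-compressed).
#' @param strict reject nonstandard letters (default `TRUE`); with
#'   `FALSE`, `X` is tolerated.
#' @return A [peptide_records] data frame.
#' @export
read_fasta <- function(path, strict = TRUE) {
  # Biostrings drops invalid letters with a warning; dropping residues would
  # silently corrupt descriptors, so escalate to an error.
  ss <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter", conditionMessage(w)))
        stop("illegal residues in FASTA file: ", path, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  ids <- sub("\\s.*$", "", names(ss))
  peptide_records(as.character(ss), ids = ids, strict = strict)
}

#' Write peptide records to a FASTA file
#'
#' Sequences wrap at 80 columns; `read_fasta(write_fasta(x))` round-trips.
#'
#' @param records a [peptide_records] data frame.
#' @param path output path (a `.gz` suffix triggers compression).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  ss <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(ss, path, width = 80L,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
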
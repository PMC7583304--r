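#' Encode a peptide sequence as a per-position property vector
#'
#' Position `i` of the result is the property value of residue `i`. With a
#' non-strict table lookup, `X` encodes as the mean of the scale.
#'
#' @param sequence a single peptide sequence (character scalar).
#' @param property_name name of a property in `table`.
#' @param table an [aa_property_table][property_table].
#' @return Numeric vector of length `nchar(sequence)`.
#' @export
encode_sequence <- function(sequence, property_name, table) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  prop <- table$properties[[property_name]]
  if (is.null(prop)) stop("unknown property: ", property_name)
  res <- strsplit(toupper(sequence), "")[[1]]
  vals <- c(prop, X = mean(prop))[res]
  if (anyNA(vals))
    stop("residue outside alphabet in sequence: ",
         paste(unique(res[is.na(vals)]), collapse = ","))
  unname(vals)
}

#' Sliding-window neighborhood smoothing
#'
#' Replaces each position by the mean of the window of radius `k` around it
#' (window truncated at the sequence ends), the neighborhood aggregation
#' applied before a global operator in neighborhood descriptors.
#'
#' @param values numeric vector (per-position encoding).
#' @param k window radius, an integer in 1..6.
#' @return Numeric vector of the same length.
#' @export
neighborhood_smooth <- function(values, k) {
  if (length(values) == 0L) stop("empty vector")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  L <- length(values)
  cs <- cumsum(c(0, values))
  i <- seq_len(L)
  lo <- pmax(1L, i - k)
  hi <- pmin(L, i + k)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

OWA_SCHEMES <- c("linear", "max", "min")

#' Ordered weighted averaging weights
#'
#' @param n vector length.
#' @param scheme `"linear"` (linearly decreasing weights 2(n+1-i)/(n(n+1))),
#'   `"max"` (all weight on the largest value) or `"min"` (on the smallest).
#' @return Numeric weight vector of length `n` summing to 1.
#' @export
owa_weights <- function(n, scheme = c("linear", "max", "min")) {
  scheme <- match.arg(scheme)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  switch(scheme,
         linear = 2 * (n + 1 - seq_len(n)) / (n * (n + 1)),
         max    = c(1, rep(0, n - 1L)),
         min    = c(rep(0, n - 1L), 1))
}

#' Apply a statistical or aggregation operator to a value vector
#'
#' Supported operators: `mean`, `median`, `variance`, `sd`, `range`
#' (max - min), `min`, `max`, `sum`, and `owa`. OWA returns the dot product
#' of the weight vector with the values sorted in descending order; weights
#' must be non-negative, sum to 1 (tolerance 1e-8) and match the vector
#' length -- malformed weights are an error, never renormalized silently.
#'
#' @param values non-empty numeric vector.
#' @param operator operator name.
#' @param weights OWA weight vector (required when `operator = "owa"`).
#' @return A scalar.
#' @export
apply_operator <- function(values, operator, weights = NULL) {
  if (length(values) == 0L) stop("empty vector")
  switch(operator,
         mean = mean(values),
         median = median(values),
         variance = if (length(values) == 1L) 0 else var(values),
         sd = if (length(values) == 1L) 0 else sd(values),
         range = max(values) - min(values),
         min = min(values),
         max = max(values),
         sum = sum(values),
         owa = {
           if (is.null(weights)) stop("OWA requires a weight vector")
           if (length(weights) != length(values))
             stop("OWA weights length (", length(weights),
                  ") != values length (", length(values), ")")
           if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
             stop("OWA weights must be non-negative and sum to 1")
           sum(weights * sort(values, decreasing = TRUE))
         },
         stop("unknown operator: ", operator))
}

#' Fraction of residues belonging to a group
#'
#' @param sequence a peptide sequence.
#' @param group_name name of a group in `table`.
#' @param table an [aa_property_table][property_table].
#' @return Scalar in \[0, 1\].
#' @export
group_fraction <- function(sequence, group_name, table) {
  g <- table$groups[[group_name]]
  if (is.null(g)) stop("unknown group: ", group_name)
  res <- strsplit(toupper(sequence), "")[[1]]
  mean(res %in% g)
}

#' Declare a molecular descriptor
#'
#' A descriptor spec names a computation pipeline over a sequence: encode a
#' property per position, optionally restrict to residues of one group,
#' optionally smooth with a neighborhood window of radius `k`, then collapse
#' with an operator. The special operator `"fraction"` ignores the property
#' and returns the group composition fraction.
#'
#' Column names are formed deterministically as
#' `property.group.operator.kK` (with `all` for no group restriction and
#' `k0` for no smoothing; OWA operators append their weight scheme).
#'
#' @param property property name (ignored for `operator = "fraction"`).
#' @param operator one of `mean`, `median`, `variance`, `sd`, `range`,
#'   `min`, `max`, `sum`, `owa`, `fraction`.
#' @param group optional group name restricting the computation.
#' @param k optional neighborhood radius in 1..6.
#' @param owa OWA weight scheme (`"linear"`, `"max"`, `"min"`).
#' @return An object of class `descriptor_spec`.
#' @export
descriptor_spec <- function(property = NULL, operator = "mean", group = NULL,
                            k = NULL, owa = "linear") {
  ops <- c("mean", "median", "variance", "sd", "range", "min", "max",
           "sum", "owa", "fraction")
  if (!operator %in% ops) stop("unknown operator: ", operator)
  if (operator == "fraction") {
    if (is.null(group)) stop("operator 'fraction' requires a group")
    property <- NULL
  } else if (is.null(property)) {
    stop("operator '", operator, "' requires a property")
  }
  if (!is.null(k)) {
    k <- as.integer(k)
    if (is.na(k) || k < 1L || k > 6L) stop("k must be in 1..6")
  }
  if (operator == "owa" && !owa %in% OWA_SCHEMES)
    stop("unknown OWA weight scheme: ", owa)
  structure(list(property = property, operator = operator, group = group,
                 k = k, owa = if (operator == "owa") owa else NULL),
            class = "descriptor_spec")
}

#' @export
format.descriptor_spec <- function(x, ...) {
  op <- if (identical(x$operator, "owa"))
    paste0("owa_", x$owa) else x$operator
  paste(if (is.null(x$property)) "composition" else x$property,
        if (is.null(x$group)) "all" else x$group,
        op,
        paste0("k", if (is.null(x$k)) 0L else x$k),
        sep = ".")
}

#' @export
print.descriptor_spec <- function(x, ...) {
  cat("<descriptor_spec>", format(x), "\n")
  invisible(x)
}

#' Default descriptor spec set
#'
#' Crosses every property of the table with the classical operators (mean,
#' sd, min, max, range, sum, linear OWA), adds neighborhood-smoothed means
#' at radii `k_values`, group-restricted sums for every property x group
#' pair, and the composition fraction of every group. Group restriction is
#' combined only with `sum`/`fraction` so the set is total on any sequence
#' (sequences may lack residues of a group entirely).
#'
#' @param table an [aa_property_table][property_table].
#' @param k_values neighborhood radii to include (subset of 1..6).
#' @return List of [descriptor_spec] objects with unique names.
#' @export
default_descriptor_specs <- function(table = default_property_table(),
                                     k_values = c(2L, 4L)) {
  specs <- list()
  for (p in names(table$properties)) {
    for (op in c("mean", "sd", "min", "max", "range", "sum"))
      specs[[length(specs) + 1L]] <- descriptor_spec(p, op)
    specs[[length(specs) + 1L]] <- descriptor_spec(p, "owa", owa = "linear")
    for (k in k_values)
      specs[[length(specs) + 1L]] <- descriptor_spec(p, "mean", k = k)
    for (g in names(table$groups))
      specs[[length(specs) + 1L]] <- descriptor_spec(p, "sum", group = g)
  }
  for (g in names(table$groups))
    specs[[length(specs) + 1L]] <- descriptor_spec(operator = "fraction", group = g)
  names(specs) <- vapply(specs, format, character(1L))
  specs
}

eval_descriptor <- function(sequence, spec, table) {
  if (identical(spec$operator, "fraction"))
    return(group_fraction(sequence, spec$group, table))
  vals <- encode_sequence(sequence, spec$property, table)
  if (!is.null(spec$group)) {
    g <- table$groups[[spec$group]]
    if (is.null(g)) stop("unknown group: ", spec$group)
    keep <- strsplit(toupper(sequence), "")[[1]] %in% g
    vals <- vals[keep]
    if (length(vals) == 0L) {
      if (identical(spec$operator, "sum")) return(0)
      stop("no residues of group '", spec$group, "' present")
    }
  }
  if (!is.null(spec$k)) vals <- neighborhood_smooth(vals, spec$k)
  w <- if (identical(spec$operator, "owa"))
    owa_weights(length(vals), spec$owa) else NULL
  apply_operator(vals, spec$operator, weights = w)
}

#' Compute a descriptor matrix for a set of peptides
#'
#' Evaluates every descriptor spec on every record; cell (i, j) is spec j on
#' record i (encode, optional group restriction, optional neighborhood
#' smoothing, aggregate). Row order follows the input; column names come
#' from the spec formats and must be unique. Any spec failing on any record
#' aborts, naming the record and spec.
#'
#' @param records a [peptide_records] data frame (or anything with `id` and
#'   `sequence` columns).
#' @param specs list of [descriptor_spec] objects (default
#'   [default_descriptor_specs()]).
#' @param table an [aa_property_table][property_table].
#' @return Numeric matrix with peptide ids as rownames and descriptor names
#'   as colnames; all values finite.
#' @export
compute_descriptor_matrix <- function(records,
                                      specs = default_descriptor_specs(table),
                                      table = default_property_table()) {
  if (!all(c("id", "sequence") %in% names(records)))
    stop("records must have 'id' and 'sequence' columns")
  if (length(specs) == 0L) stop("specs must be non-empty")
  cn <- unname(vapply(specs, format, character(1L)))
  if (anyDuplicated(cn))
    stop("duplicate descriptor column name: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  if (anyDuplicated(records$id)) stop("duplicate peptide ids")
  n <- nrow(records)
  D <- matrix(NA_real_, n, length(specs), dimnames = list(records$id, cn))
  for (i in seq_len(n)) {
    for (j in seq_along(specs)) {
      v <- tryCatch(eval_descriptor(records$sequence[i], specs[[j]], table),
                    error = function(e)
                      stop("descriptor '", cn[j], "' failed on record '",
                           records$id[i], "': ", conditionMessage(e),
                           call. = FALSE))
      D[i, j] <- v
    }
  }
  if (!all(is.finite(D))) stop("descriptor matrix contains non-finite values")
  D
}

#' Write / read a descriptor matrix as CSV
#'
#' First column `id` holds peptide ids; remaining columns are descriptors.
#' Lines starting with `#` (provenance comments) are skipped on read.
#'
#' @param matrix numeric matrix with rownames (ids) and colnames.
#' @param path file path.
#' @param comment optional character vector written as leading `#` lines.
#' @return `read_descriptor_csv` returns the matrix; `write_descriptor_csv`
#'   its path, invisibly.
#' @export
write_descriptor_csv <- function(matrix, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(id = rownames(matrix), matrix, check.names = FALSE)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_csv
#' @export
read_descriptor_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
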
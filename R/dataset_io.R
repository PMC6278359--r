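#' Construct a descriptor dataset
#'
#' A `descriptor_dataset` bundles a numeric molecular-descriptor matrix with
#' molecule identifiers and a categorical class label per molecule.  It is the
#' input container for every analysis in the package: distance models,
#' rivality indexes, modelability, applicability-domain assessment and the
#' benchmark classifiers all consume it.
#'
#' @param features numeric matrix (or data frame coercible to one), one row
#'   per molecule, one named column per descriptor.
#' @param labels vector of class labels, one per molecule.  Stored as a
#'   factor; by default levels are sorted, and the first level is treated as
#'   the "sensitivity class" by the benchmark statistics.
#' @param ids character vector of unique molecule identifiers.  Defaults to
#'   the row names of `features`, or `mol1 ... molN` when absent.
#' @param scaled logical; `TRUE` only for matrices already range-scaled to
#'   \[0, 1\].
#' @param scale_params `NULL`, or a list with numeric vectors `min` and `max`
#'   (named by column) recorded when the scaling was performed.
#' @param check_classes logical; when `TRUE` (default) require at least two
#'   classes with at least two members each — the invariant every *training*
#'   context needs so that both a same-class and a different-class nearest
#'   neighbor exist for every molecule.  Set to `FALSE` for external test
#'   sets, which may be as small as a single molecule.
#'
#' @return An object of class `descriptor_dataset`: a list with elements
#'   `ids`, `labels` (factor), `features` (numeric matrix with `ids` as row
#'   names), `scaled`, `scale_params` and `out_of_range` (logical per-molecule
#'   flag, set by [apply_scale()]).
#'
#' @details Every class must have at least two members: the rivality index of
#'   a molecule needs a nearest *same-class* neighbor distinct from the
#'   molecule itself, so a singleton class makes the index undefined for that
#'   molecule.
#'
#' @seealso [read_descriptor_table()], [clean_columns()], [range_scale()]
#' @export
descriptor_dataset <- function(features, labels, ids = NULL,
                               scaled = FALSE, scale_params = NULL,
                               check_classes = TRUE) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features))
    stop("'features' must be a numeric matrix", call. = FALSE)
  n <- nrow(features)
  if (is.null(ids)) {
    ids <- rownames(features)
    if (is.null(ids)) ids <- paste0("mol", seq_len(n))
  }
  ids <- as.character(ids)
  if (length(ids) != n)
    stop("'ids' length does not match the number of rows", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated molecule id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (length(labels) != n)
    stop("'labels' length does not match the number of rows", call. = FALSE)
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (check_classes) {
    if (nlevels(labels) < 2)
      stop("at least 2 distinct classes are required", call. = FALSE)
    sizes <- table(labels)
    if (any(sizes < 2))
      stop("every class needs >= 2 members; offending class(es): ",
           paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  if (is.null(colnames(features)))
    colnames(features) <- paste0("d", seq_len(ncol(features)))
  rownames(features) <- ids
  if (isTRUE(scaled)) {
    fin <- features[is.finite(features)]
    if (length(fin) && (min(fin) < 0 || max(fin) > 1))
      stop("'scaled = TRUE' but values fall outside [0, 1]", call. = FALSE)
    if (is.null(scale_params))
      stop("'scaled = TRUE' requires 'scale_params'", call. = FALSE)
  }
  structure(
    list(ids = ids, labels = labels, features = features,
         scaled = isTRUE(scaled), scale_params = scale_params,
         out_of_range = rep(FALSE, n)),
    class = "descriptor_dataset")
}

#' @export
print.descriptor_dataset <- function(x, ...) {
  cat("Descriptor dataset: ", nrow(x$features), " molecules, ",
      ncol(x$features), " descriptors\n", sep = "")
  cat("Classes:", paste(sprintf("%s (n=%d)", levels(x$labels),
                                tabulate(x$labels)), collapse = ", "), "\n")
  cat("Scaled:", x$scaled, "\n")
  invisible(x)
}

#' Number of molecules / descriptors in a dataset
#' @param ds a `descriptor_dataset`.
#' @return integer count.
#' @export
n_molecules <- function(ds) nrow(ds$features)

#' @rdname n_molecules
#' @export
n_descriptors <- function(ds) ncol(ds$features)

#' Read a molecular descriptor table from delimited text
#'
#' Reads a CSV/TSV file with a header row, one molecule per row: an id
#' column, a class-label column, and numeric descriptor columns.  Cells may
#' contain `NaN` or `Inf` tokens (such columns are later removed by
#' [clean_columns()]); any other non-numeric descriptor cell is an error.
#'
#' @param path path to the delimited file.
#' @param id_column,label_column names of the identifier and class columns.
#' @param delimiter field separator, default `","`.
#' @return an unscaled [descriptor_dataset()] preserving row and column order.
#' @export
read_descriptor_table <- function(path, id_column = "id",
                                  label_column = "class", delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  for (col in c(id_column, label_column))
    if (!col %in% names(raw))
      stop("column '", col, "' not found in ", path, call. = FALSE)
  ids <- raw[[id_column]]
  labels <- raw[[label_column]]
  feat_cols <- setdiff(names(raw), c(id_column, label_column))
  if (!length(feat_cols))
    stop("no descriptor columns in ", path, call. = FALSE)
  features <- matrix(NA_real_, nrow(raw), length(feat_cols),
                     dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    txt <- raw[[feat_cols[j]]]
    val <- suppressWarnings(as.numeric(txt))
    # NaN/Inf tokens parse fine; anything else becoming NA is a bad cell
    bad <- which(is.na(val) & !toupper(txt) %in% c("NAN", "NA"))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   txt[bad[1]], bad[1], feat_cols[j]), call. = FALSE)
    features[, j] <- val
  }
  descriptor_dataset(features, labels, ids = ids)
}

#' Write a descriptor dataset back to delimited text
#'
#' Inverse of [read_descriptor_table()]: writes id, label and descriptor
#' columns with full double precision so that a read/write round trip
#' reproduces the values exactly.
#'
#' @param ds a `descriptor_dataset`.
#' @param path output file path.
#' @param id_column,label_column,delimiter as in [read_descriptor_table()].
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(ds, path, id_column = "id",
                                   label_column = "class", delimiter = ",") {
  df <- data.frame(ds$ids, as.character(ds$labels),
                   as.data.frame(ds$features), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1:2] <- c(id_column, label_column)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove uninformative descriptor columns
#'
#' Drops (a) any column containing a `NaN`, `NA` or infinite value, (b) any
#' all-zero column and (c) any other constant column.  Constant nonzero
#' columns carry no discriminative information and make min/max range scaling
#' undefined (max equals min), so they are removed together with the all-zero
#' ones.  The names and reasons of dropped columns are attached as the
#' `"dropped"` attribute (a data frame with columns `column`, `reason`).
#'
#' The operation is idempotent: cleaning an already-clean dataset returns the
#' identical column set.
#'
#' @param ds an unscaled `descriptor_dataset`.
#' @return the cleaned dataset, or an error if no informative column remains.
#' @export
clean_columns <- function(ds) {
  stopifnot(inherits(ds, "descriptor_dataset"))
  if (ds$scaled) stop("clean_columns() expects an unscaled dataset",
                      call. = FALSE)
  X <- ds$features
  nonfinite <- apply(X, 2, function(v) any(!is.finite(v)))
  allzero <- !nonfinite & apply(X, 2, function(v) all(v == 0))
  constant <- !nonfinite & !allzero &
    apply(X, 2, function(v) max(v) == min(v))
  drop <- nonfinite | allzero | constant
  if (all(drop)) stop("no informative descriptors remain after cleaning",
                      call. = FALSE)
  reason <- rep(NA_character_, ncol(X))
  reason[nonfinite] <- "non-finite value"
  reason[allzero] <- "all zero"
  reason[constant] <- "constant"
  dropped <- data.frame(column = colnames(X)[drop], reason = reason[drop],
                        stringsAsFactors = FALSE)
  # class invariants were validated at construction; don't re-impose them
  out <- descriptor_dataset(X[, !drop, drop = FALSE], ds$labels,
                            ids = ds$ids, check_classes = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Range-scale a descriptor matrix to \[0, 1\]
#'
#' Applies the min/max criterion column-wise: each value `x` in column `c`
#' becomes `(x - min_c) / (max_c - min_c)`.  The per-column minima and maxima
#' are recorded in `scale_params` so that external molecules can later be
#' projected into the same coordinates with [apply_scale()].
#'
#' Scaling is invariant to any per-column strictly increasing affine
#' transform of the raw data, so all downstream distance-based indexes are
#' too.
#'
#' @param ds a cleaned, unscaled `descriptor_dataset` (see [clean_columns()]).
#' @return the scaled dataset with `scaled = TRUE` and `scale_params` set.
#' @export
range_scale <- function(ds) {
  stopifnot(inherits(ds, "descriptor_dataset"))
  if (ds$scaled) stop("dataset is already scaled", call. = FALSE)
  X <- ds$features
  if (any(!is.finite(X)))
    stop("non-finite values present; run clean_columns() first", call. = FALSE)
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  cst <- which(maxs == mins)
  if (length(cst))
    stop("constant column(s) reach scaling (run clean_columns() first): ",
         paste(colnames(X)[cst], collapse = ", "), call. = FALSE)
  Xs <- sweep(sweep(X, 2, mins, "-"), 2, maxs - mins, "/")
  descriptor_dataset(Xs, ds$labels, ids = ds$ids, scaled = TRUE,
                     scale_params = list(min = mins, max = maxs),
                     check_classes = FALSE)
}

#' Scale a dataset with previously recorded parameters
#'
#' Projects molecules into the \[0, 1\] coordinates of a *training* set using
#' that set's recorded column minima/maxima, as required by the external
#' applicability-domain protocol.  Values may fall outside \[0, 1\] when a
#' molecule lies outside the training descriptor ranges; such molecules are
#' flagged in the `out_of_range` element rather than clipped.
#'
#' @param ds an unscaled `descriptor_dataset` whose columns match
#'   `scale_params`.
#' @param scale_params a list with named vectors `min` and `max`, typically
#'   the `scale_params` of a dataset scaled by [range_scale()].
#' @return the dataset scaled with the given parameters; `out_of_range[i]` is
#'   `TRUE` when molecule `i` has any value outside \[0, 1\].
#' @export
apply_scale <- function(ds, scale_params) {
  stopifnot(inherits(ds, "descriptor_dataset"))
  if (ds$scaled) stop("dataset is already scaled", call. = FALSE)
  if (is.null(scale_params$min) || is.null(scale_params$max))
    stop("'scale_params' must contain 'min' and 'max'", call. = FALSE)
  cols <- colnames(ds$features)
  missing <- setdiff(cols, names(scale_params$min))
  if (length(missing))
    stop("scale_params missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  mins <- scale_params$min[cols]
  maxs <- scale_params$max[cols]
  Xs <- sweep(sweep(ds$features, 2, mins, "-"), 2, maxs - mins, "/")
  out <- structure(
    list(ids = ds$ids, labels = ds$labels, features = Xs, scaled = TRUE,
         scale_params = list(min = mins, max = maxs),
         out_of_range = unname(apply(Xs, 1, function(v) any(v < 0 | v > 1)))),
    class = "descriptor_dataset")
  rownames(out$features) <- ds$ids
  out
}

#' Subset a descriptor dataset by molecule
#'
#' Row subsetting that preserves scaling state and parameters.  Errors if the
#' selection leaves any class with fewer than two members.
#'
#' @param ds a `descriptor_dataset`.
#' @param which molecule ids (character) or row indices (numeric/logical).
#' @param check_classes require every class of the subset to keep >= 2
#'   members (default `TRUE`); disable when carving out external test sets.
#' @return the subsetted dataset.
#' @export
subset_molecules <- function(ds, which, check_classes = TRUE) {
  stopifnot(inherits(ds, "descriptor_dataset"))
  if (is.character(which)) {
    idx <- match(which, ds$ids)
    if (anyNA(idx))
      stop("unknown molecule id(s): ",
           paste(which[is.na(idx)], collapse = ", "), call. = FALSE)
  } else {
    idx <- seq_along(ds$ids)[which]
  }
  out <- structure(
    list(ids = ds$ids[idx], labels = droplevels(ds$labels[idx]),
         features = ds$features[idx, , drop = FALSE], scaled = ds$scaled,
         scale_params = ds$scale_params,
         out_of_range = ds$out_of_range[idx]),
    class = "descriptor_dataset")
  if (check_classes) {
    sizes <- table(out$labels)
    if (nlevels(out$labels) < 2 || any(sizes < 2))
      stop("subset leaves a class with < 2 members", call. = FALSE)
  }
  out
}
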
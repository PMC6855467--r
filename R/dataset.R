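#' Construct a compound-descriptor-property dataset
#'
#' The basic data container of the package: one row per pure compound, a
#' matrix of numeric molecular descriptors, and one property vector (the
#' experimental flammability limit, volume percent, for LFL/UFL work).
#'
#' @param X numeric matrix or data frame of descriptors, one column per
#'   descriptor; column names are the descriptor names and must be unique.
#' @param Y numeric property vector, one value per row of `X`. For
#'   `property_kind` `"LFL"` or `"UFL"` all values must be strictly positive
#'   (flammability limits are positive volume percentages).
#' @param compound_ids character vector of compound identifiers (CAS numbers
#'   or names); must be unique.
#' @param property_kind `"LFL"`, `"UFL"` or `"other"`.
#' @return An object of class `descriptor_dataset`: a list with elements
#'   `compound_ids`, `descriptor_names`, `X` (numeric matrix), `Y`,
#'   `property_kind`.
#' @examples
#' ds <- descriptor_dataset(
#'   X = cbind(SIC0 = c(0.6, 0.7, 0.8), PW5 = c(0.1, 0.2, 0.3)),
#'   Y = c(1.4, 2.0, 2.6),
#'   compound_ids = c("a", "b", "c"),
#'   property_kind = "LFL"
#' )
#' dim(ds$X)
#' @export
descriptor_dataset <- function(X, Y, compound_ids = NULL,
                               property_kind = c("other", "LFL", "UFL")) {
  property_kind <- match.arg(property_kind)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  Y <- as.numeric(Y)
  if (nrow(X) < 1L || ncol(X) < 1L) {
    stop("dataset must have at least one compound and one descriptor",
         call. = FALSE)
  }
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  }
  if (anyDuplicated(colnames(X))) {
    stop("descriptor names must be unique; duplicated: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(compound_ids)) {
    compound_ids <- rownames(X) %||% paste0("cmpd_", seq_len(nrow(X)))
  }
  compound_ids <- as.character(compound_ids)
  if (length(compound_ids) != nrow(X) || length(Y) != nrow(X)) {
    stop("compound_ids, X rows and Y must all have the same length",
         call. = FALSE)
  }
  if (anyDuplicated(compound_ids)) {
    stop("duplicate compound ids: ",
         paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(X))) {
    bad <- colnames(X)[apply(!is.finite(X), 2, any)]
    stop("non-finite or missing descriptor values in column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(Y))) {
    stop("property values must be finite", call. = FALSE)
  }
  if (property_kind %in% c("LFL", "UFL") && any(Y <= 0)) {
    stop(property_kind, " values must be strictly positive volume percent",
         call. = FALSE)
  }
  structure(
    list(
      compound_ids = compound_ids,
      descriptor_names = colnames(X),
      X = X,
      Y = Y,
      property_kind = property_kind
    ),
    class = "descriptor_dataset"
  )
}

#' @export
print.descriptor_dataset <- function(x, ...) {
  cat(sprintf(
    "<descriptor_dataset> %d compounds x %d descriptors, property: %s\n",
    nrow(x$X), ncol(x$X), x$property_kind
  ))
  invisible(x)
}

#' @export
dim.descriptor_dataset <- function(x) dim(x$X)

#' Read a compound-descriptor-property table
#'
#' Reads a delimited text table (CSV by default, TSV for `.tsv`/`.tab`
#' files) with a header row, one identifier column, one property column and
#' any number of numeric descriptor columns, and validates it into a
#' [descriptor_dataset()].
#'
#' Validation is strict by default: any missing or non-numeric descriptor or
#' property entry rejects the file. With `strict = FALSE` the offending rows
#' are dropped and a message reports how many.
#'
#' @param path path to the table.
#' @param id_column name of the identifier column.
#' @param property_column name of the property column (e.g. `"LFL"`).
#' @param property_kind `"LFL"`, `"UFL"` or `"other"`; defaults to the
#'   property column name when that is `"LFL"`/`"UFL"`, otherwise `"other"`.
#' @param strict reject files with missing/non-numeric entries (default)
#'   instead of dropping the affected rows.
#' @param sep field separator; inferred from the file extension when `NULL`.
#' @return A [descriptor_dataset()].
#' @export
read_dataset <- function(path, id_column, property_column,
                         property_kind = NULL, strict = TRUE, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  for (col in c(id_column, property_column)) {
    if (!col %in% names(raw)) {
      stop("required column not found in ", path, ": ", col, call. = FALSE)
    }
  }
  ids <- as.character(raw[[id_column]])
  desc_cols <- setdiff(names(raw), c(id_column, property_column))
  if (length(desc_cols) < 1L) {
    stop("no descriptor columns besides id and property", call. = FALSE)
  }
  to_num <- function(v) {
    # read.table already parses numeric columns at full precision; only
    # character columns (mixed/non-numeric entries) need conversion
    if (is.numeric(v)) as.numeric(v)
    else suppressWarnings(as.numeric(as.character(v)))
  }
  num <- vapply(raw[desc_cols], to_num, numeric(nrow(raw)))
  num <- matrix(num, nrow = nrow(raw), dimnames = list(NULL, desc_cols))
  yv <- to_num(raw[[property_column]])
  bad_row <- !is.finite(yv) | apply(num, 1, function(r) any(!is.finite(r)))
  if (any(bad_row)) {
    if (strict) {
      bad_cols <- desc_cols[apply(num, 2, function(c) any(!is.finite(c)))]
      if (!all(is.finite(yv))) bad_cols <- c(property_column, bad_cols)
      stop("missing or non-numeric entries in column(s): ",
           paste(bad_cols, collapse = ", "),
           " (use strict = FALSE to drop the ", sum(bad_row), " affected row(s))",
           call. = FALSE)
    }
    message("read_dataset: dropped ", sum(bad_row),
            " row(s) with missing or non-numeric entries")
    keep <- !bad_row
    ids <- ids[keep]
    num <- num[keep, , drop = FALSE]
    yv <- yv[keep]
  }
  if (length(yv) == 0L) stop("no usable rows in ", path, call. = FALSE)
  if (is.null(property_kind)) {
    property_kind <- if (toupper(property_column) %in% c("LFL", "UFL")) {
      toupper(property_column)
    } else {
      "other"
    }
  }
  descriptor_dataset(num, yv, ids, property_kind = property_kind)
}

#' Write a dataset back to CSV
#'
#' Writes the table in the same dialect [read_dataset()] reads (comma
#' separated, header row, `.` decimal separator). Numeric values are written
#' with 17 significant digits so that a write/read round trip reproduces
#' `X` and `Y` exactly.
#'
#' @param ds a [descriptor_dataset()].
#' @param path output file path.
#' @param id_column,property_column column names to use in the header.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, id_column = "compound_id",
                          property_column = NULL) {
  stopifnot(inherits(ds, "descriptor_dataset"))
  if (is.null(property_column)) {
    property_column <- if (ds$property_kind == "other") "Y" else ds$property_kind
  }
  num_chr <- apply(ds$X, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(num_chr))) num_chr <- matrix(num_chr, nrow = nrow(ds$X))
  out <- data.frame(ds$compound_ids, num_chr, sprintf("%.17g", ds$Y),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c(id_column, ds$descriptor_names, property_column)
  utils::write.table(out, path, sep = ",", dec = ".", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Split a dataset into training and testing partitions
#'
#' Uniform random partition without replacement, reproducible given `seed`.
#' The training-set size is `round-half-up(fraction * N)`, which reproduces
#' the conventional 80/20 split sizes for flammability datasets: 1057
#' compounds give 846 training / 211 testing, 515 give 412 / 103.
#'
#' @param ds a [descriptor_dataset()], or a single integer `N` (number of
#'   rows) when only the index partition is needed.
#' @param fraction training fraction, strictly between 0 and 1 (default 0.8).
#' @param seed integer seed controlling the random partition.
#' @return An object of class `split_indices`: list with `train_idx`,
#'   `test_idx`, `fraction`, `seed`.
#' @examples
#' sp <- split_dataset(1057, fraction = 0.8, seed = 1)
#' length(sp$train_idx) # 846
#' length(sp$test_idx)  # 211
#' @export
split_dataset <- function(ds, fraction = 0.8, seed = 1L) {
  n <- if (inherits(ds, "descriptor_dataset")) nrow(ds$X) else as.integer(ds)
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must be strictly between 0 and 1", call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 rows to split", call. = FALSE)
  n_train <- as.integer(floor(fraction * n + 0.5))  # round half up
  if (n_train < 1L || n_train >= n) {
    stop("fraction ", fraction, " yields an empty train or test set for N = ",
         n, call. = FALSE)
  }
  train_idx <- with_seed(seed, sort(sample.int(n, n_train)))
  structure(
    list(
      train_idx = train_idx,
      test_idx = setdiff(seq_len(n), train_idx),
      fraction = fraction,
      seed = as.integer(seed)
    ),
    class = "split_indices"
  )
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> train %d / test %d (fraction %.3g, seed %d)\n",
              length(x$train_idx), length(x$test_idx), x$fraction, x$seed))
  invisible(x)
}

#' Export a split as a two-column assignment table
#'
#' Writes `compound_id, subset` rows (`subset` is `train` or `test`) so a
#' partition can be archived alongside a model.
#'
#' @param ds the [descriptor_dataset()] that was split.
#' @param split a [split_dataset()] result for `ds`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split <- function(ds, split, path) {
  stopifnot(inherits(ds, "descriptor_dataset"), inherits(split, "split_indices"))
  subset <- rep("test", nrow(ds$X))
  subset[split$train_idx] <- "train"
  utils::write.table(
    data.frame(compound_id = ds$compound_ids, subset = subset),
    path, sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# Subset a dataset by row indices, keeping validation invariants.
dataset_rows <- function(ds, idx) {
  descriptor_dataset(
    ds$X[idx, , drop = FALSE],
    ds$Y[idx],
    ds$compound_ids[idx],
    property_kind = ds$property_kind
  )
}
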
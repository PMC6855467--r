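#' Declare the term families of a hybrid design matrix
#'
#' A `hybrid_spec` describes which term families enter the design matrix
#' \eqn{\Psi} of the hybrid model
#' \deqn{Y = \alpha_0 + \sum_i \alpha_i X_i + \sum_d \gamma_d \omega^d +
#'   \sum_i \delta_i \omega X_i + \sum_i \beta_i \ln X_i +
#'   \sum_j \sum_i \lambda_{j,i} X_j \ln X_i + \varepsilon}
#' where \eqn{\omega} is a descriptor-sum feature. With all families on and
#' every descriptor log-eligible, the column count is
#' \eqn{p = 1 + 2n + m + k + n^2} (intercept, linear, polynomial,
#' interaction, logarithmic, cross blocks).
#'
#' Two readings of \eqn{\omega} are supported:
#' \describe{
#'   \item{`global_sum`}{one feature \eqn{\omega = \sum_{i=1}^n X_i}; the
#'     polynomial block holds its powers \eqn{\omega, \omega^2, \dots,
#'     \omega^D} (so `m = D`).}
#'   \item{`pairwise_sum`}{\eqn{\omega}-features are pairwise descriptor sums
#'     \eqn{X_a + X_b} over `pairs` (all unordered pairs by default), each
#'     raised to powers up to `poly_degree` — the shape of compact published
#'     flammability equations such as terms in `(AAC + PW5)` and
#'     `(SIC0)^2 (AAC + PW5)`.}
#' }
#'
#' @param include_intercept include the constant column \eqn{\alpha_0}.
#' @param linear include the linear block \eqn{X_i}.
#' @param poly_mode `"global_sum"` or `"pairwise_sum"` (see Details).
#' @param poly_degree highest power \eqn{D \ge 1} of the
#'   \eqn{\omega}-features; 0 disables the polynomial block.
#' @param n_interactions number of \eqn{\omega X_i} interaction columns `k`;
#'   `NULL` means one per descriptor (`k = n`). Interactions are taken in
#'   order over (omega-feature, descriptor) combinations.
#' @param log_terms include the logarithmic block \eqn{\ln X_i}.
#' @param cross_terms include the cross block \eqn{X_j \ln X_i} over all
#'   ordered pairs (including `j == i`), i.e. up to \eqn{n^2} columns.
#' @param pairs for `pairwise_sum`: a two-column matrix (or list of length-2
#'   vectors) of descriptor names or indices defining the
#'   \eqn{\omega}-features; `NULL` means all unordered pairs.
#' @param log_shift \eqn{\epsilon \ge 0} for an optional `ln(x + eps)`
#'   shift. Default 0: logarithmic and cross columns are generated only for
#'   descriptors strictly positive on the rows used to build the design
#'   (the log-eligibility mask).
#' @return An object of class `hybrid_spec`.
#' @seealso [build_design_matrix()], [term_count()]
#' @examples
#' # the full hybrid family with quadratic polynomial block
#' sp <- hybrid_spec(poly_degree = 2)
#' term_count(sp, n = 3) # 1 + 2*3 + 2 + 3 + 9 = 21
#'
#' # plain multiple linear regression
#' mlr <- hybrid_spec(poly_degree = 0, log_terms = FALSE, cross_terms = FALSE)
#' term_count(mlr, n = 105) # 106
#' @export
hybrid_spec <- function(include_intercept = TRUE,
                        linear = TRUE,
                        poly_mode = c("global_sum", "pairwise_sum"),
                        poly_degree = 2L,
                        n_interactions = NULL,
                        log_terms = TRUE,
                        cross_terms = TRUE,
                        pairs = NULL,
                        log_shift = 0) {
  poly_mode <- match.arg(poly_mode)
  poly_degree <- as.integer(poly_degree)
  if (poly_degree < 0L) stop("poly_degree must be >= 0", call. = FALSE)
  if (!is.null(n_interactions)) {
    n_interactions <- as.integer(n_interactions)
    if (n_interactions < 0L) stop("n_interactions must be >= 0", call. = FALSE)
  }
  if (log_shift < 0) stop("log_shift must be >= 0", call. = FALSE)
  if (!is.null(pairs)) {
    if (is.list(pairs)) pairs <- do.call(rbind, pairs)
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("pairs must have two columns", call. = FALSE)
  }
  structure(
    list(
      include_intercept = isTRUE(include_intercept),
      linear = isTRUE(linear),
      poly_mode = poly_mode,
      poly_degree = poly_degree,
      n_interactions = n_interactions,
      log_terms = isTRUE(log_terms),
      cross_terms = isTRUE(cross_terms),
      pairs = pairs,
      log_shift = log_shift
    ),
    class = "hybrid_spec"
  )
}

#' @export
print.hybrid_spec <- function(x, ...) {
  fam <- c(
    if (x$include_intercept) "intercept",
    if (x$linear) "linear",
    if (x$poly_degree > 0L) sprintf("poly[%s, D=%d]", x$poly_mode, x$poly_degree),
    if (is.null(x$n_interactions) || x$n_interactions > 0L) "interaction",
    if (x$log_terms) "log",
    if (x$cross_terms) "cross"
  )
  cat("<hybrid_spec> families:", paste(fam, collapse = " + "), "\n")
  invisible(x)
}

# Resolve the pair list (descriptor-name matrix) for a spec given names.
resolve_pairs <- function(spec, descriptor_names) {
  n <- length(descriptor_names)
  if (spec$poly_mode == "global_sum") {
    return(matrix(character(0), ncol = 2))
  }
  if (is.null(spec$pairs)) {
    if (n < 2L) stop("pairwise_sum mode needs at least 2 descriptors",
                     call. = FALSE)
    idx <- utils::combn(n, 2)
    return(cbind(descriptor_names[idx[1, ]], descriptor_names[idx[2, ]]))
  }
  p <- spec$pairs
  if (is.numeric(p)) {
    p <- cbind(descriptor_names[p[, 1]], descriptor_names[p[, 2]])
  }
  missing <- setdiff(unique(as.vector(p)), descriptor_names)
  if (length(missing)) {
    stop("pair descriptors not in dataset: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p
}

# Number of omega-features implied by a spec for n descriptors.
n_omega_features <- function(spec, descriptor_names) {
  if (spec$poly_mode == "global_sum") 1L else nrow(resolve_pairs(spec, descriptor_names))
}

#' Column count of the hybrid design in the fully-eligible case
#'
#' Computes `p`, the number of columns [build_design_matrix()] produces when
#' every descriptor is log-eligible. With all families on, global-sum
#' polynomial mode and default interactions this is
#' `1 + 2n + m + k + n^2` with `m = poly_degree` and `k = n`.
#'
#' @param spec a [hybrid_spec()].
#' @param n number of descriptors (or a character vector of their names).
#' @return Integer column count.
#' @export
term_count <- function(spec, n) {
  stopifnot(inherits(spec, "hybrid_spec"))
  names <- if (is.character(n)) n else paste0("X", seq_len(n))
  n <- length(names)
  n_omega <- if (spec$poly_degree > 0L || is.null(spec$n_interactions) ||
                   spec$n_interactions > 0L) {
    n_omega_features(spec, names)
  } else {
    0L
  }
  m <- if (spec$poly_degree > 0L) n_omega * spec$poly_degree else 0L
  k_max <- n_omega * n
  k <- if (is.null(spec$n_interactions)) min(n, k_max) else
    min(spec$n_interactions, k_max)
  if (n_omega == 0L) k <- 0L
  as.integer(
    spec$include_intercept +
      spec$linear * n +
      m +
      k +
      spec$log_terms * n +
      spec$cross_terms * n * n
  )
}

# Enumerate term labels for a spec, given descriptor names and the
# log-eligibility mask. Returns a data.frame with one row per design column.
enumerate_terms <- function(spec, descriptor_names, eligible) {
  n <- length(descriptor_names)
  rows <- list()
  add <- function(family, var = NA_character_, var2 = NA_character_,
                  sum_a = NA_character_, sum_b = NA_character_,
                  degree = NA_integer_, label) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, var = var, var2 = var2, sum_a = sum_a, sum_b = sum_b,
      degree = degree, label = label, stringsAsFactors = FALSE
    )
  }
  if (spec$include_intercept) add("intercept", label = "(Intercept)")
  if (spec$linear) {
    for (v in descriptor_names) add("linear", var = v, label = v)
  }
  pairs <- resolve_pairs(spec, descriptor_names)
  omega_lab <- function(q) {
    if (spec$poly_mode == "global_sum") "omega"
    else sprintf("(%s+%s)", pairs[q, 1], pairs[q, 2])
  }
  n_omega <- if (spec$poly_mode == "global_sum") 1L else nrow(pairs)
  if (spec$poly_degree > 0L) {
    for (q in seq_len(n_omega)) {
      for (d in seq_len(spec$poly_degree)) {
        if (spec$poly_mode == "global_sum") {
          add("poly", degree = d,
              label = if (d == 1L) "omega" else sprintf("omega^%d", d))
        } else {
          add("poly", sum_a = pairs[q, 1], sum_b = pairs[q, 2], degree = d,
              label = if (d == 1L) omega_lab(q)
                      else sprintf("%s^%d", omega_lab(q), d))
        }
      }
    }
  }
  k <- if (is.null(spec$n_interactions)) n else spec$n_interactions
  if (k > 0L && n_omega > 0L) {
    made <- 0L
    for (q in seq_len(n_omega)) {
      for (v in descriptor_names) {
        if (made >= k) break
        if (spec$poly_mode == "global_sum") {
          add("interaction", var = v, degree = 1L,
              label = sprintf("omega*%s", v))
        } else {
          add("interaction", var = v, sum_a = pairs[q, 1],
              sum_b = pairs[q, 2], degree = 1L,
              label = sprintf("%s*%s", omega_lab(q), v))
        }
        made <- made + 1L
      }
      if (made >= k) break
    }
  }
  if (spec$log_terms) {
    for (v in descriptor_names[eligible]) {
      add("log", var = v, label = sprintf("ln(%s)", v))
    }
  }
  if (spec$cross_terms) {
    for (j in descriptor_names) {
      for (i in descriptor_names[eligible]) {
        add("cross", var = i, var2 = j, label = sprintf("%s*ln(%s)", j, i))
      }
    }
  }
  do.call(rbind, rows)
}

# Evaluate the columns described by `labels` on a descriptor matrix X
# (columns named). `descriptor_names` is the full descriptor set of the
# training design (needed for the global omega sum).
eval_term_columns <- function(labels, X, descriptor_names, log_shift = 0) {
  N <- nrow(X)
  lx <- function(v) log(X[, v] + log_shift)
  omega_global <- NULL
  omega_of <- function(row) {
    if (is.na(row$sum_a)) {
      if (is.null(omega_global)) {
        omega_global <<- rowSums(X[, descriptor_names, drop = FALSE])
      }
      omega_global
    } else {
      X[, row$sum_a] + X[, row$sum_b]
    }
  }
  out <- matrix(0, nrow = N, ncol = nrow(labels),
                dimnames = list(NULL, labels$label))
  for (c in seq_len(nrow(labels))) {
    row <- labels[c, ]
    out[, c] <- switch(
      row$family,
      intercept = rep(1, N),
      linear = X[, row$var],
      poly = omega_of(row)^row$degree,
      interaction = omega_of(row) * X[, row$var],
      log = lx(row$var),
      cross = X[, row$var2] * lx(row$var),
      stop("unknown term family: ", row$family)
    )
  }
  out
}

#' Build the hybrid design matrix
#'
#' Realizes the design matrix \eqn{\Psi} for a dataset under a
#' [hybrid_spec()]. Columns are ordered
#' `[intercept | linear | polynomial | interaction | log | cross]` and each
#' carries a structured label recording its family and the descriptors it
#' involves, so the same expansion can be re-applied to new data (see
#' [apply_design()]).
#'
#' Log-eligibility is computed from the rows being transformed: logarithmic
#' and cross columns are generated only for descriptors strictly positive on
#' those rows (unless `log_shift > 0` in the spec). With
#' `on_ineligible = "error"` a non-positive descriptor instead aborts,
#' naming the descriptor.
#'
#' @param ds a [descriptor_dataset()].
#' @param spec a [hybrid_spec()].
#' @param rows optional integer row indices to build on (e.g. a training
#'   partition); defaults to all rows.
#' @param on_ineligible `"skip"` (default; mask recorded) or `"error"`.
#' @return An object of class `design_matrix`: list with `values` (the
#'   numeric matrix), `labels` (one row per column: family, descriptors,
#'   degree), `spec`, `descriptor_names`, `eligible`, `rows`.
#' @export
build_design_matrix <- function(ds, spec, rows = NULL,
                                on_ineligible = c("skip", "error")) {
  stopifnot(inherits(ds, "descriptor_dataset"), inherits(spec, "hybrid_spec"))
  on_ineligible <- match.arg(on_ineligible)
  rows <- rows %||% seq_len(nrow(ds$X))
  X <- ds$X[rows, , drop = FALSE]
  names <- ds$descriptor_names
  needs_log <- spec$log_terms || spec$cross_terms
  if (needs_log && spec$log_shift == 0) {
    eligible <- apply(X, 2, function(col) min(col) > 0)
    if (on_ineligible == "error" && !all(eligible)) {
      stop("ln requested for descriptor(s) with non-positive values: ",
           paste(names[!eligible], collapse = ", "), call. = FALSE)
    }
  } else {
    eligible <- rep(TRUE, ncol(X))
  }
  labels <- enumerate_terms(spec, names, eligible)
  values <- eval_term_columns(labels, X, names, spec$log_shift)
  structure(
    list(
      values = values,
      labels = labels,
      spec = spec,
      descriptor_names = names,
      eligible = stats::setNames(eligible, names),
      rows = rows
    ),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d rows x %d columns (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$labels$family)),
                            as.integer(table(x$labels$family))),
                    collapse = " ")))
  invisible(x)
}

#' Re-apply a stored design to new data
#'
#' Regenerates the design columns recorded in `labels` on another dataset.
#' Applying to the original rows reproduces the matrix exactly; applying to
#' held-out rows requires every descriptor referenced by the labels to be
#' present, and positive wherever a stored logarithmic term uses it.
#'
#' @param design a `design_matrix` (or an object carrying `labels`,
#'   `descriptor_names` and `spec`, such as a fitted model).
#' @param ds a [descriptor_dataset()], or a numeric matrix/data frame with
#'   named descriptor columns.
#' @return The realized numeric matrix with labelled columns.
#' @export
apply_design <- function(design, ds) {
  X <- if (inherits(ds, "descriptor_dataset")) ds$X else as.matrix(ds)
  ids <- if (inherits(ds, "descriptor_dataset")) ds$compound_ids
         else rownames(X) %||% as.character(seq_len(nrow(X)))
  missing <- setdiff(design$descriptor_names, colnames(X))
  if (length(missing)) {
    stop("dataset lacks descriptor column(s) required by the model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  shift <- design$spec$log_shift %||% 0
  log_vars <- unique(design$labels$var[design$labels$family %in% c("log", "cross")])
  log_vars <- log_vars[!is.na(log_vars)]
  for (v in log_vars) {
    bad <- which(X[, v] + shift <= 0)
    if (length(bad)) {
      stop(sprintf(
        "non-positive value of descriptor %s for compound %s fed to a stored log term",
        v, ids[bad[1]]
      ), call. = FALSE)
    }
  }
  eval_term_columns(design$labels, X[, design$descriptor_names, drop = FALSE],
                    design$descriptor_names, shift)
}

#' Serialize a hybrid_spec to JSON (and back)
#'
#' @param spec a [hybrid_spec()].
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return `spec_to_json`: JSON string or `path`; `spec_from_json`: a
#'   [hybrid_spec()].
#' @export
spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "hybrid_spec"))
  x <- unclass(spec)
  if (!is.null(x$pairs)) x$pairs <- apply(x$pairs, c(1, 2), as.character)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname spec_to_json
#' @param json JSON string or path to a JSON file.
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  hybrid_spec(
    include_intercept = x$include_intercept,
    linear = x$linear,
    poly_mode = x$poly_mode,
    poly_degree = x$poly_degree,
    n_interactions = x$n_interactions,
    log_terms = x$log_terms,
    cross_terms = x$cross_terms,
    pairs = if (!is.null(x$pairs)) as.matrix(x$pairs) else NULL,
    log_shift = x$log_shift
  )
}
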
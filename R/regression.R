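#' Minimum-norm least-squares fit of a hybrid design
#'
#' Estimates the coefficient vector of the hybrid model by least squares.
#' The default solver uses a singular-value decomposition of the design
#' matrix and returns the minimum-norm solution: among all coefficient
#' vectors minimizing \eqn{\|Y - \Psi\Theta\|^2}, the one of smallest
#' Euclidean norm. This is well defined even when the design is
#' rank-deficient or wider than tall (p > N), the regime reached when the
#' full term expansion produces thousands of columns from a few hundred
#' training compounds, where the textbook normal-equations form
#' \eqn{(\Psi'\Psi)^{-1}\Psi'Y} does not exist.
#'
#' `method = "normal"` provides that textbook normal-equations path for
#' well-posed full-rank problems (it errors when \eqn{\Psi'\Psi} is
#' singular).
#'
#' @param design a [build_design_matrix()] result, or a plain numeric
#'   matrix.
#' @param Y numeric response vector (experimental flammability limits for
#'   the same rows).
#' @param method `"svd"` (default, minimum-norm) or `"normal"`.
#' @param tol relative singular-value cutoff defining the effective rank.
#' @return An object of class `hybrid_model`: list with `coefficients`
#'   (named), `labels`, `spec`, `descriptor_names`, `rank`, `method`,
#'   `training_meta`.
#' @seealso [predict.hybrid_model()], [prune_coefficients()]
#' @export
fit_least_squares <- function(design, Y, method = c("svd", "normal"),
                              tol = NULL) {
  method <- match.arg(method)
  if (inherits(design, "design_matrix")) {
    Psi <- design$values
    labels <- design$labels
    spec <- design$spec
    descriptor_names <- design$descriptor_names
  } else {
    Psi <- as.matrix(design)
    if (is.null(colnames(Psi))) colnames(Psi) <- paste0("V", seq_len(ncol(Psi)))
    labels <- data.frame(family = "linear", var = colnames(Psi),
                         var2 = NA_character_, sum_a = NA_character_,
                         sum_b = NA_character_, degree = NA_integer_,
                         label = colnames(Psi), stringsAsFactors = FALSE)
    spec <- NULL
    descriptor_names <- colnames(Psi)
  }
  Y <- as.numeric(Y)
  if (nrow(Psi) != length(Y)) {
    stop("design and Y row counts differ", call. = FALSE)
  }
  if (any(!is.finite(Psi)) || any(!is.finite(Y))) {
    stop("non-finite entries in the design matrix or response", call. = FALSE)
  }
  if (method == "normal") {
    XtX <- crossprod(Psi)
    theta <- tryCatch(
      solve(XtX, crossprod(Psi, Y)),
      error = function(e) stop(
        "normal equations are singular (rank-deficient design); ",
        "use method = \"svd\"", call. = FALSE)
    )
    theta <- drop(theta)
    rank <- ncol(Psi)
  } else {
    sv <- svd(Psi)
    if (is.null(tol)) tol <- max(dim(Psi)) * .Machine$double.eps
    keep <- sv$d > tol * max(sv$d, 0)
    rank <- sum(keep)
    theta <- if (rank == 0L) {
      rep(0, ncol(Psi))
    } else {
      drop(sv$v[, keep, drop = FALSE] %*%
             ((crossprod(sv$u[, keep, drop = FALSE], Y)) / sv$d[keep]))
    }
  }
  names(theta) <- labels$label
  structure(
    list(
      coefficients = theta,
      labels = labels,
      spec = spec,
      descriptor_names = descriptor_names,
      rank = as.integer(rank),
      method = method,
      training_meta = list(
        n_train = nrow(Psi),
        n_terms = ncol(Psi),
        prune_trace = NULL
      )
    ),
    class = "hybrid_model"
  )
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf(
    "<hybrid_model> %d terms (effective rank %d), fitted on %d rows by %s\n",
    length(x$coefficients), x$rank, x$training_meta$n_train, x$method
  ))
  fam <- table(x$labels$family)
  cat("  families:", paste(sprintf("%s:%d", names(fam), as.integer(fam)),
                           collapse = " "), "\n")
  if (!is.null(x$training_meta$prune_trace)) {
    cat(sprintf("  pruned: %d elimination step(s)\n",
                nrow(x$training_meta$prune_trace)))
  }
  invisible(x)
}

#' Predict flammability limits from a fitted hybrid model
#'
#' Rebuilds the stored design columns on `newdata` and returns
#' \eqn{\Psi \Theta}. Deterministic and invariant under row reordering of
#' the input. Errors if a referenced descriptor column is missing, or if a
#' non-positive value reaches a stored logarithmic term (the error names the
#' compound and the descriptor).
#'
#' @param object a `hybrid_model`.
#' @param newdata a [descriptor_dataset()] or a matrix/data frame with named
#'   descriptor columns.
#' @param ... unused.
#' @return Numeric vector of calculated property values (FL_Cal).
#' @export
predict.hybrid_model <- function(object, newdata, ...) {
  Psi <- apply_design(object, newdata)
  drop(Psi %*% object$coefficients)
}

# Refit helper used by pruning: fit the label subset on stored training data.
refit_labels <- function(labels, X, Y, descriptor_names, log_shift, method) {
  Psi <- eval_term_columns(labels, X, descriptor_names, log_shift)
  fit_least_squares(
    structure(list(values = Psi, labels = labels, spec = NULL,
                   descriptor_names = descriptor_names),
              class = "design_matrix"),
    Y, method = method
  )
}

# Training R^2 (fraction, not percent) of a candidate label set.
labels_r2 <- function(labels, X, Y, descriptor_names, log_shift) {
  Psi <- eval_term_columns(labels, X, descriptor_names, log_shift)
  sv <- svd(Psi)
  keep <- sv$d > max(dim(Psi)) * .Machine$double.eps * max(sv$d, 0)
  theta <- if (!any(keep)) rep(0, ncol(Psi)) else
    drop(sv$v[, keep, drop = FALSE] %*%
           (crossprod(sv$u[, keep, drop = FALSE], Y) / sv$d[keep]))
  res <- Y - drop(Psi %*% theta)
  1 - sum(res^2) / sum((Y - mean(Y))^2)
}

#' Backward elimination of insignificant coefficients
#'
#' Simplifies a fitted hybrid model by repeatedly removing the least
#' significant term and refitting, recording the full elimination trace.
#' Candidates are ranked by the absolute t statistic of each coefficient
#' (classical per-coefficient significance test) whenever residual degrees
#' of freedom exist, the retained design has full column rank and the
#' residual sum of squares is not numerically zero; otherwise ranking falls
#' back to the drop-one change in training R-squared (the term whose removal
#' least reduces it goes first — the two orderings agree where both are
#' defined). Ties are broken by column order: the earlier column is
#' retained.
#'
#' Two stopping modes:
#' \describe{
#'   \item{`"alpha_level"`}{eliminate while any retained coefficient has a
#'     two-sided p-value above `value` (the significance level, e.g. 0.05).}
#'   \item{`"target_count"`}{eliminate until exactly `value` terms remain.}
#' }
#'
#' @param model a `hybrid_model` fitted on `train_ds` (or on the `rows`
#'   subset of it used to build its design).
#' @param train_ds the [descriptor_dataset()] holding the training rows.
#' @param mode `"target_count"` or `"alpha_level"`.
#' @param value target term count, or significance level in (0, 1).
#' @param rows optional training row indices within `train_ds`.
#' @param keep_intercept never eliminate the intercept column (default).
#' @return A new `hybrid_model` with the retained terms, refitted, carrying
#'   the elimination trace in `training_meta$prune_trace` (a data.frame with
#'   `step`, `dropped`, `r2_after` in percent).
#' @export
prune_coefficients <- function(model, train_ds,
                               mode = c("target_count", "alpha_level"),
                               value, rows = NULL, keep_intercept = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "hybrid_model"))
  X <- if (inherits(train_ds, "descriptor_dataset")) train_ds$X else
    as.matrix(train_ds)
  rows <- rows %||% seq_len(nrow(X))
  X <- X[rows, , drop = FALSE]
  Y <- if (inherits(train_ds, "descriptor_dataset")) train_ds$Y[rows] else
    stop("train_ds must be a descriptor_dataset", call. = FALSE)
  labels <- model$labels
  shift <- model$spec$log_shift %||% 0
  dn <- model$descriptor_names
  p0 <- nrow(labels)
  if (mode == "target_count") {
    value <- as.integer(value)
    if (value < 1L || value > p0) {
      stop("target_count must be between 1 and the current term count (",
           p0, ")", call. = FALSE)
    }
    if (value == p0) return(model)
  } else {
    if (!is.numeric(value) || value <= 0 || value >= 1) {
      stop("alpha level must be in (0, 1)", call. = FALSE)
    }
  }

  trace <- list()
  repeat {
    p <- nrow(labels)
    candidates <- seq_len(p)
    if (keep_intercept) {
      candidates <- candidates[labels$family != "intercept"]
    }
    if (length(candidates) == 0L) break
    if (mode == "target_count" && p <= value) break

    Psi <- eval_term_columns(labels, X, dn, shift)
    qrp <- qr(Psi)
    df <- nrow(Psi) - p
    tstat <- pval <- NULL
    if (df > 0L && qrp$rank == p) {
      theta <- qr.coef(qrp, Y)
      rss <- sum((Y - drop(Psi %*% theta))^2)
      if (rss > 1e-12 * max(sum(Y^2), 1)) {
        XtX_inv <- tryCatch(solve(crossprod(Psi)), error = function(e) NULL)
        if (!is.null(XtX_inv)) {
          sigma2_hat <- rss / df
          se <- sqrt(pmax(diag(XtX_inv) * sigma2_hat, 0))
          tstat <- ifelse(se > 0, abs(theta / se), Inf)
          pval <- 2 * stats::pt(-tstat, df)
        }
      }
    }

    if (!is.null(tstat)) {
      if (mode == "alpha_level") {
        offenders <- candidates[pval[candidates] > value]
        if (length(offenders) == 0L) break
        # largest p-value goes; ties broken toward keeping earlier columns
        worst <- max(pval[offenders])
        drop_idx <- max(offenders[pval[offenders] == worst])
      } else {
        tmin <- min(tstat[candidates])
        drop_idx <- max(candidates[tstat[candidates] == tmin])
      }
    } else {
      # degenerate fit (no d.f., rank deficiency, or zero residual):
      # rank by drop-one change in training R^2
      r2_drop <- vapply(candidates, function(ci) {
        labels_r2(labels[-ci, , drop = FALSE], X, Y, dn, shift)
      }, numeric(1))
      if (mode == "alpha_level") {
        # without defined t tests, stop once removal of any term would
        # reduce the training fit beyond numerical noise
        full_r2 <- labels_r2(labels, X, Y, dn, shift)
        harmless <- candidates[full_r2 - r2_drop <= 1e-12]
        if (length(harmless) == 0L) break
        best <- max(r2_drop[match(harmless, candidates)])
        drop_idx <- max(harmless[r2_drop[match(harmless, candidates)] == best])
      } else {
        best <- max(r2_drop)
        drop_idx <- max(candidates[r2_drop == best])
      }
    }

    dropped_label <- labels$label[drop_idx]
    labels <- labels[-drop_idx, , drop = FALSE]
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(trace) + 1L,
      dropped = dropped_label,
      r2_after = 100 * labels_r2(labels, X, Y, dn, shift),
      stringsAsFactors = FALSE
    )
  }

  refit <- refit_labels(labels, X, Y, dn, shift, model$method)
  refit$spec <- model$spec
  refit$training_meta$prune_trace <- if (length(trace)) {
    do.call(rbind, trace)
  } else {
    NULL
  }
  refit$training_meta$pruned_from <- p0
  refit
}

#' Fit, prune and evaluate a hybrid model end to end
#'
#' The complete modelling protocol: split the dataset into training and
#' testing partitions, build the hybrid design on the training rows
#' (log-eligibility computed there), fit by minimum-norm least squares,
#' optionally prune by backward elimination, then score the model on the
#' training set, the testing set, and the whole dataset — the three
#' pairings conventionally tabulated for flammability models.
#'
#' @param ds a [descriptor_dataset()].
#' @param spec a [hybrid_spec()].
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed for the random split.
#' @param prune `NULL` (no pruning) or a list
#'   `list(mode = "target_count"|"alpha_level", value = ...)` passed to
#'   [prune_coefficients()].
#' @param method least-squares solver, see [fit_least_squares()].
#' @return An object of class `hybrid_fit`: list with `model`
#'   (`hybrid_model`), `split`, `report` (list of [metrics_report()] for
#'   `train`, `test`, `whole`), `residuals` (whole-dataset, named by
#'   compound), `rank`.
#' @examples
#' truth <- generate_dataset(synthetic_config(N = 120, n = 3, noise_sd = 0,
#'                                            seed = 7))
#' fit <- run_training_protocol(truth$dataset, truth$truth$spec, seed = 7)
#' fit$report$whole$r2 # 100: noise-free data generated by the fitted
#'                     # family are interpolated exactly
#' @export
run_training_protocol <- function(ds, spec, fraction = 0.8, seed = 1L,
                                  prune = NULL, method = "svd") {
  stopifnot(inherits(ds, "descriptor_dataset"), inherits(spec, "hybrid_spec"))
  split <- split_dataset(ds, fraction = fraction, seed = seed)
  design <- build_design_matrix(ds, spec, rows = split$train_idx)
  model <- fit_least_squares(design, ds$Y[split$train_idx], method = method)
  model$training_meta$split_seed <- split$seed
  model$training_meta$split_fraction <- split$fraction
  if (!is.null(prune)) {
    model <- prune_coefficients(model, ds, mode = prune$mode,
                                value = prune$value, rows = split$train_idx)
    model$training_meta$split_seed <- split$seed
    model$training_meta$split_fraction <- split$fraction
  }
  pred_whole <- predict(model, ds)
  report <- list(
    train = metrics_report(pred_whole[split$train_idx], ds$Y[split$train_idx]),
    test = metrics_report(pred_whole[split$test_idx], ds$Y[split$test_idx]),
    whole = metrics_report(pred_whole, ds$Y)
  )
  structure(
    list(
      model = model,
      split = split,
      report = report,
      residuals = stats::setNames(pred_whole - ds$Y, ds$compound_ids),
      rank = model$rank
    ),
    class = "hybrid_fit"
  )
}

#' @export
print.hybrid_fit <- function(x, ...) {
  cat("<hybrid_fit>\n")
  print(x$model)
  for (part in c("train", "test", "whole")) {
    r <- x$report[[part]]
    cat(sprintf("  %-5s n=%4d  R^2 = %8.4f%%  AARD = %8.4f%%\n",
                part, r$n_points, r$r2, r$aard))
  }
  invisible(x)
}

#' Save / load a fitted hybrid model as JSON
#'
#' The model file carries the term-family spec, the structured term labels
#' and the coefficients at full double precision (17 significant digits),
#' so a reloaded model predicts identically without refitting.
#'
#' @param model a `hybrid_model`.
#' @param path file path for the JSON model document.
#' @return `save_model`: `path`, invisibly. `load_model`: the
#'   `hybrid_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hybrid_model"))
  doc <- list(
    format = "flamlim-hybrid-model",
    version = 1L,
    spec = if (!is.null(model$spec)) jsonlite::fromJSON(spec_to_json(model$spec),
                                                        simplifyMatrix = TRUE)
           else NULL,
    descriptor_names = model$descriptor_names,
    labels = model$labels,
    coefficients = sprintf("%.17g", model$coefficients),
    rank = model$rank,
    method = model$method,
    training_meta = model$training_meta[c("n_train", "n_terms", "split_seed",
                                          "split_fraction")]
  )
  writeLines(as.character(
    jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA,
                     dataframe = "columns")
  ), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(doc$format, "flamlim-hybrid-model")) {
    stop(path, " is not a hybrid model file", call. = FALSE)
  }
  labels <- as.data.frame(doc$labels, stringsAsFactors = FALSE)
  labels$degree <- suppressWarnings(as.integer(labels$degree))
  spec <- if (!is.null(doc$spec)) {
    spec_from_json(as.character(jsonlite::toJSON(doc$spec, auto_unbox = TRUE,
                                                 null = "null")))
  } else {
    NULL
  }
  structure(
    list(
      coefficients = stats::setNames(as.numeric(doc$coefficients),
                                     labels$label),
      labels = labels,
      spec = spec,
      descriptor_names = doc$descriptor_names,
      rank = as.integer(doc$rank),
      method = doc$method,
      training_meta = doc$training_meta
    ),
    class = "hybrid_model"
  )
}
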
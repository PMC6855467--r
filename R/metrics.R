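#' Accuracy statistics for flammability-limit predictions
#'
#' The deviation statistics conventional in flammability QSPR reporting,
#' comparing calculated values `cal` (FL_Cal) with experimental values
#' `exp` (FL_Exp), all with a leading `100/N` factor:
#' \describe{
#'   \item{ARD}{average (signed) relative deviation,
#'     \eqn{\frac{100}{N}\sum_i (cal_i - exp_i)/exp_i} (percent).}
#'   \item{AARD}{average absolute relative deviation,
#'     \eqn{\frac{100}{N}\sum_i |cal_i - exp_i|/exp_i} (percent).}
#'   \item{AAE}{average absolute error,
#'     \eqn{\frac{100}{N}\sum_i |cal_i - exp_i|}. The factor of 100 is part
#'     of the conventional definition, so AAE is 100 times the mean absolute
#'     error in volume percent and is not scale-free.}
#' }
#'
#' @param cal numeric vector of calculated (predicted) values.
#' @param exp numeric vector of experimental values, same length.
#' @return A single number (percent for ARD/AARD).
#' @examples
#' ard(c(1.1, 0.9), c(1, 1))  # 0: signed errors cancel
#' aard(c(1.1, 0.9), c(1, 1)) # 10
#' aae(1.1, 1.0)              # 10 = 100 * |0.1|
#' @export
ard <- function(cal, exp) {
  check_pair(cal, exp)
  zero <- which(exp == 0)
  if (length(zero)) {
    stop("experimental value is zero at index ", zero[1],
         "; relative deviation undefined", call. = FALSE)
  }
  100 * mean((cal - exp) / exp)
}

#' @rdname ard
#' @export
aard <- function(cal, exp) {
  check_pair(cal, exp)
  zero <- which(exp == 0)
  if (length(zero)) {
    stop("experimental value is zero at index ", zero[1],
         "; relative deviation undefined", call. = FALSE)
  }
  100 * mean(abs(cal - exp) / abs(exp))
}

#' @rdname ard
#' @export
aae <- function(cal, exp) {
  check_pair(cal, exp)
  100 * mean(abs(cal - exp))
}

#' Variance statistic of calculated values
#'
#' Two variants of the sigma-squared statistic reported alongside
#' flammability models. The `"printed"` variant is the literal textbook
#' form \eqn{\sigma^2 = \sum_i (cal_i - \bar{cal})^2 / (N - 1)} — the sample
#' variance of the calculated values themselves. The `"residual"` variant
#' replaces the deviations with residual deviations
#' \eqn{(cal_i - exp_i) - \overline{(cal - exp)}}, which is the variant under
#' which better models have smaller values; both are reported so tables can
#' be compared either way.
#'
#' @inheritParams ard
#' @param variant `"printed"` or `"residual"`.
#' @return The variance (squared volume percent).
#' @export
sigma2 <- function(cal, exp = NULL, variant = c("printed", "residual")) {
  variant <- match.arg(variant)
  if (variant == "residual") {
    check_pair(cal, exp)
    v <- cal - exp
  } else {
    v <- cal
  }
  if (length(v) < 2L) {
    stop("sigma2 needs at least 2 points (N - 1 degrees of freedom)",
         call. = FALSE)
  }
  sum((v - mean(v))^2) / (length(v) - 1)
}

#' Coefficient of determination, in percent
#'
#' `100 * (1 - SS_res / SS_tot)` with `SS_res = sum((exp - cal)^2)` and
#' `SS_tot = sum((exp - mean(exp))^2)`. On training data fitted with an
#' intercept this lies in \[0, 100\]; on held-out data it can be negative.
#' `method = "pearson"` instead returns the squared Pearson correlation
#' (in percent), which some published tables use.
#'
#' @inheritParams ard
#' @param method `"determination"` (default) or `"pearson"`.
#' @return R-squared in percent.
#' @examples
#' r2(c(1, 2, 4), c(1, 2, 3)) # 50
#' @export
r2 <- function(cal, exp, method = c("determination", "pearson")) {
  method <- match.arg(method)
  check_pair(cal, exp)
  if (length(exp) < 2L) stop("r2 needs at least 2 points", call. = FALSE)
  ss_tot <- sum((exp - mean(exp))^2)
  if (ss_tot == 0) {
    stop("experimental values are constant; R^2 undefined", call. = FALSE)
  }
  if (method == "pearson") {
    return(100 * stats::cor(cal, exp)^2)
  }
  100 * (1 - sum((exp - cal)^2) / ss_tot)
}

check_pair <- function(cal, exp) {
  if (!is.numeric(cal) || !is.numeric(exp) || length(cal) != length(exp)) {
    stop("cal and exp must be numeric vectors of equal length", call. = FALSE)
  }
  if (length(cal) < 1L) stop("need at least one point", call. = FALSE)
  invisible(TRUE)
}

#' Full accuracy report for a prediction/experiment pairing
#'
#' Bundles [r2()], [ard()], [aard()], [aae()] and both [sigma2()] variants
#' into one `metrics_report` object (also a one-row data frame via
#' [as.data.frame()]).
#'
#' @inheritParams ard
#' @return An object of class `metrics_report`: list with `r2`, `ard`,
#'   `aard`, `aae`, `sigma2_printed`, `sigma2_residual`, `n_points`.
#' @export
metrics_report <- function(cal, exp) {
  check_pair(cal, exp)
  structure(
    list(
      r2 = r2(cal, exp),
      ard = ard(cal, exp),
      aard = aard(cal, exp),
      aae = aae(cal, exp),
      sigma2_printed = sigma2(cal, variant = "printed"),
      sigma2_residual = sigma2(cal, exp, variant = "residual"),
      n_points = length(cal)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0("<metrics_report> n = %d\n",
           "  R^2  = %8.4f %%   ARD  = %8.4f %%\n",
           "  AARD = %8.4f %%   AAE  = %8.4f\n",
           "  sigma^2 (printed) = %.6g   (residual) = %.6g\n"),
    x$n_points, x$r2, x$ard, x$aard, x$aae,
    x$sigma2_printed, x$sigma2_residual
  ))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(
    r2 = x$r2, ard = x$ard, aard = x$aard, aae = x$aae,
    sigma2_printed = x$sigma2_printed, sigma2_residual = x$sigma2_residual,
    n_points = x$n_points
  )
}

#' Histogram of per-compound deviations
#'
#' Bins per-compound signed relative (ARD-style), absolute relative
#' (AARD-style) or absolute (AAE-style) deviations, for the error histograms
#' customary in flammability-model reports. Bin counts always sum to the
#' number of compounds.
#'
#' @inheritParams ard
#' @param statistic `"ard"`, `"aard"` or `"aae"` — which per-compound
#'   deviation to bin.
#' @param breaks passed to [graphics::hist()] machinery via [base::cut()]
#'   semantics: a bin count or a vector of break points.
#' @param plot_file optional PNG path; when given, a histogram is written.
#' @return Invisibly, a data.frame with `mid`, `count` per bin.
#' @export
deviation_histogram <- function(cal, exp, statistic = c("ard", "aard", "aae"),
                                breaks = 20, plot_file = NULL) {
  statistic <- match.arg(statistic)
  check_pair(cal, exp)
  dev <- switch(statistic,
    ard = 100 * (cal - exp) / exp,
    aard = 100 * abs(cal - exp) / abs(exp),
    aae = 100 * abs(cal - exp)
  )
  h <- graphics::hist(dev, breaks = breaks, plot = FALSE)
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 800, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(h, main = sprintf("%s distribution", toupper(statistic)),
                   xlab = sprintf("per-compound %s", toupper(statistic)),
                   col = "grey70")
  }
  invisible(data.frame(mid = h$mids, count = h$counts))
}
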
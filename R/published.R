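# The two published compact flammability-limit equations, stored as
# declarative term tables (coefficient x product of powered descriptor
# sums) so every printed coefficient is auditable in one place.

# One term: coef * prod over factors of (sum of named descriptors)^pow
pterm <- function(coef, ...) {
  list(coef = coef, factors = list(...))
}
pfac <- function(vars, pow = 1L) list(vars = vars, pow = pow)

# LFL equation, 11 terms, descriptors SIC0, AAC, PW5, GATS1v.
lfl_eq12_terms <- list(
  pterm( 17.1352,  pfac("SIC0")),
  pterm( -1.8536,  pfac(c("AAC", "PW5"))),
  pterm(  1.044,   pfac("AAC"), pfac(c("AAC", "PW5"))),
  pterm(-11.266,   pfac("SIC0"), pfac(c("AAC", "PW5"))),
  pterm(-76.4768,  pfac("PW5", 2L), pfac(c("AAC", "PW5"))),
  pterm( 13.4096,  pfac("SIC0", 2L), pfac(c("AAC", "PW5"))),
  pterm( 28.0829,  pfac("SIC0", 2L), pfac(c("SIC0", "GATS1v"))),
  pterm(  0.032,   pfac("SIC0", 3L), pfac(c("SIC0", "GATS1v"))),
  pterm(518.4484,  pfac(c("AAC", "PW5")), pfac("PW5", 3L)),
  pterm( -9.1264,  pfac(c("AAC", "PW5")), pfac("SIC0", 3L)),
  pterm(-165.743,  pfac(c("PW5", "SIC0")), pfac("PW5", 2L))
)

# UFL equation, 10 terms (constant included), descriptors MLOGP, Jhetv,
# PW5, SIC0, MATS4m. The final term is printed once with the bare symbol
# "Jhet" where every other occurrence reads "Jhetv"; it is evaluated as
# Jhetv here (single-symbol consistency), a discrepancy documented in the
# function help.
ufl_eq13_terms <- list(
  pterm(  14.011),
  pterm(  -0.765,  pfac("MLOGP")),
  pterm( -33.853,  pfac(c("Jhetv", "PW5"))),
  pterm(   0.834,  pfac(c("SIC0", "MATS4m"))),
  pterm(  32.167,  pfac(c("Jhetv", "-PW5"))),
  pterm(-281.86,   pfac("PW5", 2L)),
  pterm(  35.904,  pfac("SIC0", 2L)),
  pterm(2622.185,  pfac("PW5", 3L)),
  pterm( -23.301,  pfac("SIC0", 3L)),
  pterm(  11.134,  pfac(c("Jhetv", "PW5")), pfac("PW5"))
)

# Evaluate a term table on named descriptor vectors (all the same length).
# A leading "-" on a descriptor name inside a sum factor subtracts it.
eval_published <- function(terms, values) {
  n <- length(values[[1]])
  out <- numeric(n)
  for (tm in terms) {
    contrib <- rep(tm$coef, n)
    for (f in tm$factors) {
      s <- numeric(n)
      for (v in f$vars) {
        if (startsWith(v, "-")) {
          s <- s - values[[substring(v, 2)]]
        } else {
          s <- s + values[[v]]
        }
      }
      contrib <- contrib * s^f$pow
    }
    out <- out + contrib
  }
  out
}

check_published_inputs <- function(...) {
  vals <- list(...)
  lens <- lengths(vals)
  if (length(unique(lens[lens > 1L])) > 1L) {
    stop("descriptor vectors must have equal length (or length 1)",
         call. = FALSE)
  }
  n <- max(lens)
  vals <- lapply(vals, function(v) {
    v <- as.numeric(v)
    if (any(!is.finite(v))) stop("descriptor values must be finite",
                                 call. = FALSE)
    rep_len(v, n)
  })
  vals
}

#' Published compact LFL predictor
#'
#' Evaluates the published 11-term polynomial correlation for the lower
#' flammability limit (volume percent) in four Dragon descriptors:
#' SIC0 (structural information content, order 0), AAC (mean information
#' index on atomic composition), PW5 (path/walk-5 Randic shape index) and
#' GATS1v (Geary autocorrelation, lag 1, van der Waals volume weighted).
#' Coefficients are stored exactly as printed; there is no constant term,
#' so the all-zeros descriptor point evaluates to 0.
#'
#' @param SIC0,AAC,PW5,GATS1v numeric descriptor values (vectors are
#'   evaluated elementwise).
#' @return Estimated LFL in volume percent.
#' @examples
#' lfl_eq12(1, 1, 1, 1) # 610.2374 at the all-ones point
#' @export
lfl_eq12 <- function(SIC0, AAC, PW5, GATS1v) {
  vals <- check_published_inputs(SIC0 = SIC0, AAC = AAC, PW5 = PW5,
                                 GATS1v = GATS1v)
  eval_published(lfl_eq12_terms, vals)
}

#' Published compact UFL predictor
#'
#' Evaluates the published 10-term correlation for the upper flammability
#' limit (volume percent) in five Dragon descriptors: MLOGP (Moriguchi
#' log P), Jhetv (Balaban-type index from the van der Waals weighted
#' distance matrix), PW5, SIC0 and MATS4m (Moran autocorrelation, lag 4,
#' mass weighted). The constant term is 14.011, so the all-zeros descriptor
#' point evaluates to exactly that.
#'
#' The source prints the final term as `(Jhet + PW5) PW5` while using
#' `Jhetv` everywhere else; it is evaluated with `Jhetv` here, and the
#' discrepancy is deliberately surfaced in this documentation rather than
#' silently resolved.
#'
#' @param MLOGP,Jhetv,PW5,SIC0,MATS4m numeric descriptor values (vectors
#'   are evaluated elementwise).
#' @return Estimated UFL in volume percent.
#' @examples
#' ufl_eq13(0, 0, 0, 0, 0) # 14.011
#' ufl_eq13(1, 0, 0, 0, 0) # 13.246
#' @export
ufl_eq13 <- function(MLOGP, Jhetv, PW5, SIC0, MATS4m) {
  vals <- check_published_inputs(MLOGP = MLOGP, Jhetv = Jhetv, PW5 = PW5,
                                 SIC0 = SIC0, MATS4m = MATS4m)
  eval_published(ufl_eq13_terms, vals)
}

#' Apply a published equation to every compound of a dataset
#'
#' Vectorized wrapper over [lfl_eq12()] / [ufl_eq13()]: looks up the
#' required descriptor columns by name and evaluates the chosen equation
#' per row.
#'
#' @param ds a [descriptor_dataset()] (or matrix/data frame with named
#'   columns) containing the required descriptor columns —
#'   `SIC0, AAC, PW5, GATS1v` for LFL; `MLOGP, Jhetv, PW5, SIC0, MATS4m`
#'   for UFL.
#' @param which `"LFL"` or `"UFL"`.
#' @param case_insensitive match descriptor column names ignoring case.
#' @return Numeric vector of per-compound estimates (volume percent).
#' @export
batch_predict_published <- function(ds, which = c("LFL", "UFL"),
                                    case_insensitive = FALSE) {
  which <- match.arg(which)
  X <- if (inherits(ds, "descriptor_dataset")) ds$X else as.matrix(ds)
  need <- if (which == "LFL") c("SIC0", "AAC", "PW5", "GATS1v") else
    c("MLOGP", "Jhetv", "PW5", "SIC0", "MATS4m")
  have <- colnames(X)
  lookup <- if (case_insensitive) {
    match(tolower(need), tolower(have))
  } else {
    match(need, have)
  }
  if (anyNA(lookup)) {
    stop("dataset lacks required descriptor column(s): ",
         paste(need[is.na(lookup)], collapse = ", "), call. = FALSE)
  }
  cols <- lapply(lookup, function(j) as.numeric(X[, j]))
  names(cols) <- need
  if (which == "LFL") {
    do.call(lfl_eq12, cols)
  } else {
    do.call(ufl_eq13, cols)
  }
}
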
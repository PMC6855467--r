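#' Configure a synthetic descriptor dataset with known ground truth
#'
#' Describes how to simulate a compounds-by-descriptors table of the kind
#' produced by descriptor software plus a property column generated from a
#' known sparse hybrid model — the test bed that lets every stage of the
#' pipeline (design construction, fitting, pruning, metrics) be verified
#' against ground truth without any external database.
#'
#' Descriptors are drawn i.i.d. and strictly positive, so logarithmic terms
#' are always well defined:
#' \describe{
#'   \item{`"uniform"`}{Uniform(`law_params[1]`, `law_params[2]`), default
#'     (0.1, 3) — the order-unity magnitude range typical of topological and
#'     information-content indices.}
#'   \item{`"lognormal"`}{Lognormal(meanlog = `law_params[1]`,
#'     sdlog = `law_params[2]`), for heavier-tailed descriptor scales.}
#' }
#' The property is \eqn{Y = \Psi(X)\,\theta^* + N(0, noise\_sd^2)} where
#' \eqn{\Psi} is the design implied by `true_spec` and \eqn{\theta^*} is
#' the sparse true coefficient vector (supplied, or drawn with fraction
#' `active_fraction` of terms active, N(0,1) values).
#'
#' @param N number of compounds.
#' @param n number of descriptors.
#' @param descriptor_law `"uniform"` or `"lognormal"`.
#' @param law_params length-2 numeric parameters of the law (see Details).
#' @param true_spec a [hybrid_spec()] describing the generating model;
#'   default: pairwise-sum polynomial mode of degree 2 with all families on
#'   (the shape of the published compact equations).
#' @param true_coefficients optional numeric vector aligned with the term
#'   labels of `true_spec` on `n` descriptors (names are matched when
#'   present); `NULL` draws a sparse vector.
#' @param active_fraction fraction of terms active when drawing
#'   `true_coefficients` (default 0.4).
#' @param noise_sd Gaussian noise standard deviation on the property, in
#'   the property's units (default 0.05, a few percent of a typical
#'   order-unity flammability limit).
#' @param seed integer seed; one seed determines descriptors, coefficients
#'   and noise.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(N, n,
                             descriptor_law = c("uniform", "lognormal"),
                             law_params = NULL,
                             true_spec = NULL,
                             true_coefficients = NULL,
                             active_fraction = 0.4,
                             noise_sd = 0.05,
                             seed = 1L) {
  descriptor_law <- match.arg(descriptor_law)
  law_params <- law_params %||%
    if (descriptor_law == "uniform") c(0.1, 3) else c(0, 0.5)
  if (descriptor_law == "uniform" && law_params[1] <= 0) {
    stop("uniform descriptor law must have a strictly positive lower bound ",
         "(log terms require positive descriptors)", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (active_fraction < 0 || active_fraction > 1) {
    stop("active_fraction must be in [0, 1]", call. = FALSE)
  }
  true_spec <- true_spec %||% hybrid_spec(poly_mode = "pairwise_sum",
                                          poly_degree = 2L)
  stopifnot(inherits(true_spec, "hybrid_spec"))
  structure(
    list(
      N = as.integer(N), n = as.integer(n),
      descriptor_law = descriptor_law, law_params = law_params,
      true_spec = true_spec, true_coefficients = true_coefficients,
      active_fraction = active_fraction,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic dataset and its ground truth
#'
#' Draws the descriptor matrix and property vector described by a
#' [synthetic_config()]. Deterministic given the config's seed.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with
#' \describe{
#'   \item{`dataset`}{a [descriptor_dataset()] (property_kind `"other"`;
#'     synthetic properties are not guaranteed positive).}
#'   \item{`truth`}{list with `spec`, `labels` (term labels of the
#'     generating design), `coefficients` (full aligned vector, zeros for
#'     inactive terms), `noise_sd`, `seed`.}
#' }
#' @examples
#' g <- generate_dataset(synthetic_config(N = 50, n = 3, noise_sd = 0,
#'                                        seed = 42))
#' dim(g$dataset$X)
#' sum(g$truth$coefficients != 0)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    X <- switch(cfg$descriptor_law,
      uniform = matrix(stats::runif(cfg$N * cfg$n, cfg$law_params[1],
                                    cfg$law_params[2]),
                       nrow = cfg$N),
      lognormal = matrix(stats::rlnorm(cfg$N * cfg$n, cfg$law_params[1],
                                       cfg$law_params[2]),
                         nrow = cfg$N)
    )
    colnames(X) <- paste0("D", seq_len(cfg$n))
    names <- colnames(X)
    labels <- enumerate_terms(cfg$true_spec, names, rep(TRUE, cfg$n))
    p <- nrow(labels)
    theta <- if (!is.null(cfg$true_coefficients)) {
      tc <- cfg$true_coefficients
      if (!is.null(names(tc))) {
        full <- stats::setNames(numeric(p), labels$label)
        unknown <- setdiff(names(tc), labels$label)
        if (length(unknown)) {
          stop("true_coefficients name(s) not in the term labels: ",
               paste(unknown, collapse = ", "), call. = FALSE)
        }
        full[names(tc)] <- tc
        full
      } else {
        if (length(tc) != p) {
          stop("true_coefficients must have length ", p,
               " (one per term of true_spec)", call. = FALSE)
        }
        stats::setNames(as.numeric(tc), labels$label)
      }
    } else {
      n_active <- max(1L, round(cfg$active_fraction * p))
      active <- sample.int(p, n_active)
      th <- numeric(p)
      th[active] <- stats::rnorm(n_active)
      stats::setNames(th, labels$label)
    }
    Psi <- eval_term_columns(labels, X, names, cfg$true_spec$log_shift)
    Y <- drop(Psi %*% theta)
    if (cfg$noise_sd > 0) Y <- Y + stats::rnorm(cfg$N, 0, cfg$noise_sd)
    if (any(!is.finite(Y))) {
      stop("generated property values are not finite; ",
           "check the descriptor law and coefficients", call. = FALSE)
    }
    list(
      dataset = descriptor_dataset(X, Y, paste0("syn_", seq_len(cfg$N)),
                                   property_kind = "other"),
      truth = list(
        spec = cfg$true_spec,
        labels = labels,
        coefficients = theta,
        noise_sd = cfg$noise_sd,
        seed = cfg$seed
      )
    )
  })
}

#' Write the canonical synthetic fixture suite
#'
#' Generates and writes the four small reference fixtures used by the test
#' suite and documentation, each as a CSV in the package's table dialect
#' plus a JSON ground-truth sidecar (`<name>.truth.json`):
#' \describe{
#'   \item{`noise_free`}{exactly representable hybrid data (noise 0); a
#'     refit must interpolate it.}
#'   \item{`noisy`}{the same generating model plus Gaussian noise.}
#'   \item{`rankdef_pN`}{30 compounds whose full hybrid design has more
#'     columns than rows (p > N), exercising the minimum-norm solver.}
#'   \item{`zero_coef`}{a generating model in which one labelled term has
#'     coefficient exactly 0, for pruning tests.}
#' }
#' All fixtures are synthetic; file names and sidecars say so.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed.
#' @return Invisibly, a character vector of the files written.
#' @export
make_fixture_suite <- function(out_dir, seed = 20260920L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name, gen) {
    csv <- file.path(out_dir, paste0(name, ".csv"))
    write_dataset(gen$dataset, csv, property_column = "Y")
    truth_path <- file.path(out_dir, paste0(name, ".truth.json"))
    doc <- list(
      synthetic = TRUE,
      spec = jsonlite::fromJSON(spec_to_json(gen$truth$spec),
                                simplifyMatrix = TRUE),
      labels = gen$truth$labels,
      coefficients = sprintf("%.17g", gen$truth$coefficients),
      noise_sd = gen$truth$noise_sd,
      seed = gen$truth$seed
    )
    writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                             null = "null", digits = NA,
                                             dataframe = "columns")),
               truth_path)
    files <<- c(files, csv, truth_path)
  }

  base_spec <- hybrid_spec(poly_mode = "pairwise_sum", poly_degree = 2L)
  emit("noise_free", generate_dataset(
    synthetic_config(N = 120, n = 3, true_spec = base_spec, noise_sd = 0,
                     seed = seed)
  ))
  emit("noisy", generate_dataset(
    synthetic_config(N = 120, n = 3, true_spec = base_spec, noise_sd = 0.05,
                     seed = seed + 1L)
  ))
  # p > N: n = 5 full hybrid (global sum, D = 2) has
  # 1 + 10 + 2 + 5 + 25 = 43 columns against 30 rows
  emit("rankdef_pN", generate_dataset(
    synthetic_config(N = 30, n = 5, true_spec = hybrid_spec(poly_degree = 2L),
                     noise_sd = 0, seed = seed + 2L)
  ))
  # one labelled term exactly zero: name-matched sparse truth
  zc_spec <- hybrid_spec(poly_degree = 2L, poly_mode = "global_sum")
  zc_labels <- enumerate_terms(zc_spec, paste0("D", 1:3), rep(TRUE, 3))
  th <- stats::setNames(numeric(nrow(zc_labels)), zc_labels$label)
  th["(Intercept)"] <- 1.5
  th["D1"] <- 2
  th["omega"] <- -0.5
  th["ln(D2)"] <- 1
  th["D3"] <- 0 # the true-zero term, present in the labels by construction
  emit("zero_coef", generate_dataset(
    synthetic_config(N = 100, n = 3, true_spec = zc_spec,
                     true_coefficients = th, noise_sd = 0, seed = seed + 3L)
  ))
  invisible(files)
}
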
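test_that("least squares solves trivial and noiseless systems", {
  # identity design returns the response itself
  m <- fit_least_squares(diag(2), c(3, 5))
  expect_equal(unname(m$coefficients), c(3, 5))

  # exact recovery on a full-column-rank noiseless system
  set.seed(31)
  Psi <- matrix(rnorm(50 * 8), 50, 8)
  theta_star <- rnorm(8)
  m2 <- fit_least_squares(Psi, drop(Psi %*% theta_star))
  expect_equal(unname(m2$coefficients), theta_star, tolerance = 1e-8)
  expect_identical(m2$rank, 8L)

  expect_error(fit_least_squares(matrix(c(1, NA), 1, 2), 1), "non-finite")
})

test_that("minimum-norm solution matches an independent pseudo-inverse oracle", {
  skip_if_not_installed("pracma")
  set.seed(17)
  for (rep in 1:12) {
    N <- sample(4:12, 1)
    p <- sample(3:14, 1)
    Psi <- matrix(rnorm(N * p), N, p)
    if (p >= 3 && runif(1) < 0.7) {
      Psi[, p] <- Psi[, 1] - 2 * Psi[, 2] # force rank deficiency
    }
    y <- rnorm(N)
    ours <- unname(fit_least_squares(Psi, y)$coefficients)
    oracle <- drop(pracma::pinv(Psi) %*% y)
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
})

test_that("normal-equations path matches on full-rank data and refuses singular ones", {
  set.seed(8)
  Psi <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  expect_equal(unname(fit_least_squares(Psi, y, method = "normal")$coefficients),
               unname(fit_least_squares(Psi, y, method = "svd")$coefficients),
               tolerance = 1e-8)
  Psi_sing <- cbind(Psi, Psi[, 1])
  expect_error(fit_least_squares(Psi_sing, y, method = "normal"), "singular")
})

test_that("prediction honours stored term labels and model round trips", {
  g <- noise_free_case()
  ds <- g$dataset
  dm <- build_design_matrix(ds, g$truth$spec)
  m <- fit_least_squares(dm, ds$Y)

  # noiseless interpolation: predictions equal the generating property
  expect_equal(predict(m, ds), ds$Y, tolerance = 1e-8)

  # row-reordering invariance
  perm <- rev(seq_len(nrow(ds$X)))
  expect_equal(predict(m, dataset_rows_for_test(ds, perm)),
               ds$Y[perm], tolerance = 1e-10)

  # constant (intercept-only) model predicts its constant
  mc <- fit_least_squares(
    build_design_matrix(ds, hybrid_spec(linear = FALSE, poly_degree = 0,
                                        n_interactions = 0,
                                        log_terms = FALSE,
                                        cross_terms = FALSE)),
    ds$Y
  )
  expect_equal(unname(predict(mc, ds)), rep(mean(ds$Y), nrow(ds$X)),
               tolerance = 1e-10)

  # missing descriptor column -> schema error naming it
  X_less <- ds$X[, -1, drop = FALSE]
  expect_error(predict(m, X_less), colnames(ds$X)[1])

  # non-positive value into a stored log term names compound and descriptor
  X_bad <- ds$X
  X_bad[2, 1] <- -0.5
  bad_ds <- descriptor_dataset(X_bad, ds$Y, ds$compound_ids)
  expect_error(predict(m, bad_ds), "syn_2")
  expect_error(predict(m, bad_ds), colnames(ds$X)[1])

  # save -> load preserves predictions bitwise at serialized precision
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, ds), predict(m, ds))
})

test_that("backward elimination drops a true-zero term first, leaving fit unchanged", {
  # generating model with one labelled term whose coefficient is exactly 0
  spec <- hybrid_spec(poly_degree = 0, n_interactions = 0,
                      cross_terms = FALSE)
  labels <- c("(Intercept)", "D1", "D2", "D3",
              "ln(D1)", "ln(D2)", "ln(D3)")
  th <- stats::setNames(c(1.5, 2, 0, -1, 0.7, 1, -0.3), labels)
  g <- generate_dataset(synthetic_config(
    N = 80, n = 3, true_spec = spec, true_coefficients = th,
    noise_sd = 0, seed = 77
  ))
  ds <- g$dataset
  dm <- build_design_matrix(ds, spec)
  m <- fit_least_squares(dm, ds$Y)
  r2_full <- r2(predict(m, ds), ds$Y)

  pruned <- prune_coefficients(m, ds, mode = "target_count",
                               value = length(labels) - 1L)
  trace <- pruned$training_meta$prune_trace
  expect_identical(trace$dropped[1], "D2")
  expect_equal(trace$r2_after[1], r2_full, tolerance = 1e-10)
  expect_equal(r2(predict(pruned, ds), ds$Y), r2_full, tolerance = 1e-10)
})

test_that("target_count pruning is a no-op at the current count and validates bounds", {
  g <- noise_free_case(N = 60)
  dm <- build_design_matrix(g$dataset, g$truth$spec)
  m <- fit_least_squares(dm, g$dataset$Y)
  p <- length(m$coefficients)
  expect_identical(prune_coefficients(m, g$dataset, "target_count", p), m)
  expect_error(prune_coefficients(m, g$dataset, "target_count", 0), "between")
  expect_error(prune_coefficients(m, g$dataset, "target_count", p + 1),
               "between")
})

test_that("the training-R2 trace is non-increasing and matches exhaustive refits", {
  g <- generate_dataset(synthetic_config(
    N = 120, n = 3, true_spec = full_rank_spec(), noise_sd = 0.3, seed = 13
  ))
  ds <- g$dataset
  dm <- build_design_matrix(ds, full_rank_spec())
  m <- fit_least_squares(dm, ds$Y)
  p0 <- length(m$coefficients)
  pruned <- prune_coefficients(m, ds, mode = "target_count", value = 5)
  trace <- pruned$training_meta$prune_trace
  expect_identical(nrow(trace), p0 - 5L)
  expect_true(all(diff(trace$r2_after) <= 1e-9))

  # independent oracle: replay each elimination with a fresh least-squares
  # refit of the surviving labels and recompute training R^2
  labels <- m$labels
  for (s in seq_len(nrow(trace))) {
    labels <- labels[labels$label != trace$dropped[s], , drop = FALSE]
    Psi <- apply_design(
      structure(list(labels = labels, descriptor_names = m$descriptor_names,
                     spec = m$spec), class = "design_matrix"),
      ds
    )
    refit <- fit_least_squares(Psi, ds$Y)
    expect_equal(trace$r2_after[s],
                 r2(drop(Psi %*% refit$coefficients), ds$Y),
                 tolerance = 1e-8)
  }
})

test_that("alpha-level pruning keeps only significant coefficients", {
  # strong signal in two terms, the rest pure noise
  set.seed(55)
  spec <- hybrid_spec(poly_degree = 0, n_interactions = 0,
                      cross_terms = FALSE)
  th <- stats::setNames(numeric(7),
                        c("(Intercept)", "D1", "D2", "D3",
                          "ln(D1)", "ln(D2)", "ln(D3)"))
  th["(Intercept)"] <- 2
  th["D1"] <- 3
  g <- generate_dataset(synthetic_config(
    N = 300, n = 3, true_spec = spec, true_coefficients = th,
    noise_sd = 0.05, seed = 56
  ))
  ds <- g$dataset
  m <- fit_least_squares(build_design_matrix(ds, spec), ds$Y)
  pruned <- prune_coefficients(m, ds, mode = "alpha_level", value = 0.01)
  kept <- pruned$labels$label
  expect_true(all(c("(Intercept)", "D1") %in% kept))
  expect_lt(length(kept), length(th))
  expect_error(prune_coefficients(m, ds, "alpha_level", 1.5), "in \\(0, 1\\)")
})

test_that("the training protocol is deterministic and interpolates noiseless data", {
  g <- noise_free_case(N = 100)
  fit <- run_training_protocol(g$dataset, g$truth$spec, seed = 42)
  expect_equal(fit$report$whole$r2, 100, tolerance = 1e-6)
  expect_equal(fit$report$whole$aard, 0, tolerance = 1e-6)

  fit2 <- run_training_protocol(g$dataset, g$truth$spec, seed = 42)
  expect_identical(fit$report, fit2$report)
  expect_identical(fit$model$coefficients, fit2$model$coefficients)
})

test_that("training fit dominates the nested linear-only family", {
  mlr <- hybrid_spec(poly_degree = 0, n_interactions = 0,
                     log_terms = FALSE, cross_terms = FALSE)
  for (seed in c(3, 14, 25)) {
    g <- generate_dataset(synthetic_config(N = 90, n = 4, noise_sd = 0.2,
                                           seed = seed))
    ds <- g$dataset
    rows <- split_dataset(ds, seed = seed)$train_idx
    r2_of <- function(spec) {
      dm <- build_design_matrix(ds, spec, rows = rows)
      m <- fit_least_squares(dm, ds$Y[rows])
      r2(drop(dm$values %*% m$coefficients), ds$Y[rows])
    }
    expect_gte(r2_of(hybrid_spec(poly_degree = 2)) + 1e-9, r2_of(mlr))
  }
})

test_that("rescaling the property rescales coefficients and predictions linearly", {
  g <- generate_dataset(synthetic_config(N = 70, n = 3, noise_sd = 0.1,
                                         seed = 6))
  ds <- g$dataset
  dm <- build_design_matrix(ds, hybrid_spec(poly_degree = 2))
  m1 <- fit_least_squares(dm, ds$Y)
  m2 <- fit_least_squares(dm, 3.5 * ds$Y)
  expect_equal(unname(m2$coefficients), 3.5 * unname(m1$coefficients),
               tolerance = 1e-8)
  expect_equal(predict(m2, ds), 3.5 * predict(m1, ds), tolerance = 1e-8)
  # relative metrics are invariant under the common rescaling
  expect_equal(aard(3.5 * predict(m1, ds), 3.5 * ds$Y),
               aard(predict(m1, ds), ds$Y), tolerance = 1e-10)
})

test_that("training R2 exceeds test R2 for most seeds under noise", {
  wins <- 0L
  n_seeds <- 20L
  for (seed in seq_len(n_seeds)) {
    g <- generate_dataset(synthetic_config(
      N = 80, n = 3, true_spec = full_rank_spec(), noise_sd = 0.5,
      seed = 400 + seed
    ))
    fit <- run_training_protocol(g$dataset, full_rank_spec(), seed = seed)
    if (fit$report$train$r2 >= fit$report$test$r2) wins <- wins + 1L
  }
  expect_gt(wins, n_seeds / 2)
})
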
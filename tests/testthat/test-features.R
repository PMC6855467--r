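test_that("term_count reproduces the family count relation", {
  # p = 1 + 2n + m + k + n^2 with m = D, k = n in global-sum mode
  expect_identical(term_count(hybrid_spec(poly_degree = 2), 3), 21L)
  expect_identical(term_count(hybrid_spec(poly_degree = 1,
                                          n_interactions = 1), 1), 6L)
  # linear-only reduction: n + 1
  mlr <- hybrid_spec(poly_degree = 0, n_interactions = 0,
                     log_terms = FALSE, cross_terms = FALSE)
  expect_identical(term_count(mlr, 105), 106L)

  # cross-check against the realized builder on random eligible data
  set.seed(21)
  for (n in c(2, 4, 7)) {
    g <- generate_dataset(synthetic_config(N = 12, n = n, noise_sd = 0,
                                           seed = n))
    for (spec in list(hybrid_spec(poly_degree = 2),
                      hybrid_spec(poly_degree = 3, n_interactions = 2),
                      hybrid_spec(poly_mode = "pairwise_sum",
                                  poly_degree = 2),
                      mlr)) {
      dm <- build_design_matrix(g$dataset, spec)
      expect_identical(ncol(dm$values), term_count(spec, n))
    }
  }
})

test_that("a single all-ones row realizes the documented column values", {
  ds <- descriptor_dataset(
    matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("A", "B"))), Y = 1
  )
  dm <- build_design_matrix(ds, hybrid_spec(poly_degree = 2))
  v <- drop(dm$values)
  expect_equal(unname(v[dm$labels$family == "intercept"]), 1)
  expect_equal(unname(v[dm$labels$family == "linear"]), c(1, 1))
  expect_equal(unname(v[dm$labels$family == "poly"]), c(2, 4)) # omega, omega^2
  expect_equal(unname(v[dm$labels$family == "interaction"]), c(2, 2))
  expect_equal(unname(v[dm$labels$family == "log"]), c(0, 0)) # ln 1 = 0
  expect_true(all(v[dm$labels$family == "cross"] == 0))
})

test_that("intercept + linear reduction equals the plain MLR design", {
  g <- generate_dataset(synthetic_config(N = 40, n = 5, noise_sd = 0.1,
                                         seed = 2))
  mlr <- hybrid_spec(poly_degree = 0, n_interactions = 0,
                     log_terms = FALSE, cross_terms = FALSE)
  dm <- build_design_matrix(g$dataset, mlr)
  expect_equal(unname(dm$values), unname(cbind(1, g$dataset$X)))
})

test_that("log eligibility masks non-positive descriptors and is re-applicable", {
  X <- cbind(A = c(1, 2, 3), B = c(-1, 2, 3), C = c(0.5, 0.1, 9))
  ds <- descriptor_dataset(X, Y = c(1, 2, 3))
  spec <- hybrid_spec(poly_degree = 0, n_interactions = 0)
  dm <- build_design_matrix(ds, spec)
  expect_false(dm$eligible[["B"]])
  # log columns only for A and C; cross columns only with ln(A), ln(C)
  expect_identical(sum(dm$labels$family == "log"), 2L)
  expect_identical(sum(dm$labels$family == "cross"), 6L) # 3 descriptors x 2
  expect_false(any(grepl("ln\\(B\\)", dm$labels$label)))

  # the erroring variant names the descriptor
  expect_error(build_design_matrix(ds, spec, on_ineligible = "error"), "B")

  # an epsilon shift restores eligibility for every descriptor
  dm_eps <- build_design_matrix(ds, hybrid_spec(poly_degree = 0,
                                                n_interactions = 0,
                                                log_shift = 2))
  expect_identical(sum(dm_eps$labels$family == "log"), 3L)
})

test_that("re-application regenerates training columns exactly and works on new rows", {
  g <- generate_dataset(synthetic_config(N = 60, n = 4, noise_sd = 0,
                                         seed = 9))
  ds <- g$dataset
  rows <- 1:45
  dm <- build_design_matrix(ds, hybrid_spec(poly_degree = 2), rows = rows)
  regen <- apply_design(dm, dataset_rows_for_test(ds, rows))
  expect_equal(unname(regen), unname(dm$values), tolerance = 0)
  # held-out rows (all descriptors positive) never error
  held <- apply_design(dm, dataset_rows_for_test(ds, 46:60))
  expect_identical(nrow(held), 15L)
  expect_true(all(is.finite(held)))
})

test_that("switching a family off yields a column subset (monotone nesting)", {
  g <- generate_dataset(synthetic_config(N = 15, n = 3, noise_sd = 0,
                                         seed = 4))
  full <- hybrid_spec(poly_degree = 2)
  dm_full <- build_design_matrix(g$dataset, full)
  reductions <- list(
    hybrid_spec(poly_degree = 2, log_terms = FALSE),
    hybrid_spec(poly_degree = 2, cross_terms = FALSE),
    hybrid_spec(poly_degree = 0),
    hybrid_spec(poly_degree = 2, linear = FALSE),
    hybrid_spec(poly_degree = 2, n_interactions = 0)
  )
  for (sub in reductions) {
    dm_sub <- build_design_matrix(g$dataset, sub)
    expect_true(all(dm_sub$labels$label %in% dm_full$labels$label))
  }
})

test_that("hybrid_spec serializes to JSON and back", {
  specs <- list(
    hybrid_spec(poly_degree = 3, n_interactions = 2, log_shift = 0.5),
    hybrid_spec(poly_mode = "pairwise_sum", poly_degree = 2,
                pairs = rbind(c("A", "B"), c("B", "C"))),
    hybrid_spec(poly_degree = 0, log_terms = FALSE, cross_terms = FALSE)
  )
  for (sp in specs) {
    back <- spec_from_json(spec_to_json(sp))
    expect_equal(unclass(back), unclass(sp))
  }
})
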
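# Shared builders for small in-memory fixtures.

# A tiny hand-written dataset with named descriptor columns.
tiny_dataset <- function() {
  descriptor_dataset(
    X = cbind(SIC0 = c(0.62, 0.71, 0.55),
              PW5 = c(0.11, 0.13, 0.09)),
    Y = c(1.4, 2.0, 2.6),
    compound_ids = c("methane", "ethane", "propane"),
    property_kind = "LFL"
  )
}

# A full-column-rank hybrid family: intercept + linear + omega interactions
# + log + cross. The polynomial block is excluded because its degree-1
# descriptor-sum columns are exact linear combinations of the linear block,
# which would make ground-truth coefficients unidentifiable.
full_rank_spec <- function() {
  hybrid_spec(poly_degree = 0)
}

# Row subset of a dataset, rebuilt through the public constructor.
dataset_rows_for_test <- function(ds, idx) {
  descriptor_dataset(ds$X[idx, , drop = FALSE], ds$Y[idx],
                     ds$compound_ids[idx], property_kind = ds$property_kind)
}

# Noise-free synthetic data drawn from an identifiable generating family.
noise_free_case <- function(N = 150, n = 3, seed = 101) {
  generate_dataset(synthetic_config(
    N = N, n = n, true_spec = full_rank_spec(), noise_sd = 0, seed = seed
  ))
}
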
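# Shared fixtures, built once per test run and cached so expensive
# cohorts/fits are reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Assemble a brain_graph directly from an adjacency and feature blocks.
build_graph_raw <- function(a, h0, cmat) {
  structure(list(A = a, S = maskgnn:::norm_filter_base(a), H0 = h0, C = cmat),
            class = "brain_graph")
}

# Desk-scale cohort + fit for unit tests (small widths, few epochs).
small_cohort <- function() {
  get_fixture("small_cohort", function() {
    featurize_cohort(generate_cohort(synthetic_spec(
      n_subjects = 60, q = 20, n_blocks = 3, t_len = 120,
      planted_edge_fraction = 0.1, seed = 42)))
  })
}

small_config <- function(...) {
  base <- list(q = 20, max_epochs = 15, batch_size = 16,
               d1 = 16, d2 = 16, d_hidden = 8, seed = 42)
  over <- list(...)
  base[names(over)] <- over
  do.call(run_config, base)
}

small_fit <- function() {
  get_fixture("small_fit", function() maskgnn(small_cohort(), small_config()))
}

# Study-scale cohorts and fits used by the end-to-end recovery checks.
recovery_cohort <- function(seed) {
  get_fixture(paste0("recovery_cohort_", seed), function() {
    featurize_cohort(generate_cohort(synthetic_spec(seed = seed)))
  })
}

recovery_fit <- function(seed) {
  get_fixture(paste0("recovery_fit_", seed), function() {
    maskgnn(recovery_cohort(seed), run_config(seed = seed))
  })
}
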
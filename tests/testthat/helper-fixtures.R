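# Shared fixtures, built once per test run.

fix_design_small <- function() {
  if (is.null(.fixture_env$design_small)) {
    .fixture_env$design_small <- build_design(4, 80, seed = 301)
  }
  .fixture_env$design_small
}

fix_design_std <- function() {
  if (is.null(.fixture_env$design_std)) {
    .fixture_env$design_std <- build_design(22, 160, seed = 7)
  }
  .fixture_env$design_std
}

fix_lca_table <- function() {
  if (is.null(.fixture_env$lca_table)) {
    .fixture_env$lca_table <- generate_behavior(fix_design_std(),
                                                default_lca_params(), "lca",
                                                seed = 11)
  }
  .fixture_env$lca_table
}

# a fit-shaped object around known coefficients, for simulation-only tests
fix_fake_fit <- function(model_name, par = NULL) {
  structure(list(model = model_name,
                 par = par %||% if (identical(model_name, "lca"))
                   default_lca_params() else default_ddm_coefficients(model_name),
                 scaling = NULL,
                 config = list(dt = 0.002, deadline = 0.75)),
            class = "accumimic_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_env <- new.env(parent = emptyenv())
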
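# Shared expensive fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# tiny phantom cohort shared across test files
fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(16, seed = 411)
  .fixture_env$cohort
}

fixture_split <- function() split_cases(16, seed = 7)

# trained pipeline on the fixture cohort (the expensive part; built on first
# use, then reused by pipeline and end-to-end recovery tests)
fixture_models <- function() {
  if (is.null(.fixture_env$models)) {
    coh <- fixture_cohort()
    .fixture_env$models <- train_hfsnet(coh$cases, fixture_split(),
                                        epochs_2d = 5, epochs_3d = 5,
                                        seed = 99)
  }
  .fixture_env$models
}
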
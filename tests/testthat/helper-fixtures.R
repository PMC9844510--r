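# Shared fixtures, built lazily and cached for the session: simulating
# trials is the expensive step, so the small cohorts are generated once.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_exp1_cohort <- function() {
  fixture("exp1_small", function() {
    generate_cohort("experiment1", cohort_config(atypical_prob = 0),
                    seed = 401L, n = 2)
  })
}

small_exp1_pipeline <- function() {
  fixture("exp1_pipeline", function() {
    suppressWarnings(run_pipeline(pipeline_config(
      "experiment1", n = 2, seed = 402L,
      cohort = cohort_config(atypical_prob = 0))))
  })
}

default_profile <- function(phenotype = "typical") {
  p <- withr::with_seed(77L, generate_participant())
  p$phenotype <- phenotype
  p
}
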
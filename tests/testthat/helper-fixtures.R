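# Shared fixtures, generated once per test run. Everything is built in
# code from fixed seeds; nothing here touches the network or large files.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

toy_instance <- function() cached("toy", generate_instance(seed = 1))

toy_no_fisheries <- function() {
  cached("toy_nofish", generate_instance(seed = 2, include_fisheries = FALSE))
}

toy_solution <- function() {
  cached("toy_sol", solve_food_system(toy_instance(), scenario_cirhealth()))
}

packaged_fixture_path <- function() {
  system.file("extdata", "toy_instance.yaml", package = "circfood")
}
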
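# Shared fixture builders (all data generated in code at test time).

tiny_matrix <- function(species = "demo") {
  vals <- matrix(c(1, 2, 4, 8, 16, 32, 64,
                   10, 9, 7, 4, 2, 1, 1,
                   5, 5, 5, 5, 5, 5, 5),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), NULL))
  expression_matrix(vals, timepoints = c(0, 6, 12, 18, 24, 30, 36),
                    species = species)
}

small_sim <- function(...) {
  simulate_two_species_dataset(simulation_config(
    n_dev = 12, n_hk = 6, n_maternal = 4, n_env = 6, seed = 42, ...
  ))
}

# the default stated world: 200/100/50/100 genes, 7 stages 0-36 hpf,
# T_B = 2.42 + 1.037 * T_A, 3 replicates, 3% noise
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(
        simulate_two_species_dataset(simulation_config()))
    }
    cache
  }
})

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
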
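# Shared fixtures: published parameter sets and cached noise-free datasets
# (generated once per test run; every fit test reuses them).

paper_conditions <- c("detergent", "nanodiscs", "proteoliposomes")

table_params <- function(condition) naatm1_params(condition)

noisefree_dataset <- local({
  cache <- list()
  function(condition) {
    if (is.null(cache[[condition]])) {
      cache[[condition]] <<- simulate_dataset(
        naatm1_params(condition),
        reconstitution_context(condition),
        paper_design(condition),
        noise = noise_spec(0, 0), seed = 1)
    }
    cache[[condition]]
  }
})

noisy_dataset <- function(condition, seed = 1, cv = 0.05) {
  simulate_dataset(naatm1_params(condition),
                   reconstitution_context(condition),
                   paper_design(condition),
                   noise = noise_spec(cv = cv), seed = seed)
}

# Random but reproducible activator parameter draws for property sweeps.
random_params <- function(n, seed = 42) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    activator_params(k = exp(stats::runif(1, log(0.5), log(100))),
                     K_T = exp(stats::runif(1, log(0.05), log(20))),
                     K_S = exp(stats::runif(1, log(0.5), log(50))),
                     alpha = exp(stats::runif(1, log(0.1), log(20))),
                     beta = exp(stats::runif(1, log(0.2), log(100))))
  }))
}
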
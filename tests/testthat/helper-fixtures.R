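# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# A small two-origin community, simulated and fitted once.
shared_pipeline <- function() {
  if (!exists("pipeline", envir = .fixtures)) {
    pool <- species_pool(2, 2, "range_limited", seed = 5)
    design <- experiment_design(species_ids = names(pool),
                                n_individuals = 40, n_transitions = 3,
                                seed = 11)
    dataset <- simulate_individuals(pool, design)
    fits <- fit_all_species(dataset)
    contexts <- contexts_from_design(design)
    lambda <- estimate_lambda_table(fits, contexts)
    assign("pipeline",
           list(pool = pool, design = design, dataset = dataset,
                fits = fits, contexts = contexts, lambda = lambda),
           envir = .fixtures)
  }
  get("pipeline", envir = .fixtures)
}

# smooth synthetic vital rates for kernel-level tests
smooth_vital_rates <- function() {
  vital_rate_set(
    surv = function(z) stats::plogis(1 + 0.8 * z),
    grow_mean = function(z) 0.8 + 0.7 * z,
    grow_sd = 0.6,
    flower = function(z) stats::plogis(-0.3 + 1.2 * z),
    fec = function(z) exp(3 + 0.7 * z),
    germ = 0.15, estab = 0.3, rec_mean = -0.8, rec_sd = 0.5
  )
}
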
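# Fixture builders shared across test files. Everything is generated in code;
# no fixture files on disk.

# A canonical record table; arguments are recycled to the longest length.
make_records <- function(concentration, n_exposed, n_responded,
                         bioassay_id = "b1", replicate_id = NULL,
                         endpoint_type = "mortality", n_chambered = NA_real_,
                         institution = "LAB01", species = "Ae. aegypti",
                         insecticide = "insecticide-A") {
  k <- max(length(concentration), length(n_exposed), length(n_responded),
           length(bioassay_id), length(n_chambered))
  if (is.null(replicate_id)) replicate_id <- paste0("r", seq_len(k))
  data.frame(
    institution = rep_len(institution, k), country = "XX",
    species = rep_len(species, k), strain = "lab",
    insecticide = rep_len(insecticide, k),
    endpoint_type = rep_len(endpoint_type, k),
    bioassay_id = rep_len(bioassay_id, k),
    replicate_id = rep_len(replicate_id, k),
    concentration_ug_per_bottle = rep_len(concentration, k),
    n_exposed = rep_len(n_exposed, k),
    n_responded = rep_len(n_responded, k),
    n_chambered = rep_len(n_chambered, k),
    recording_time_h = 24, stringsAsFactors = FALSE)
}

# Degenerate posterior_draws with prescribed parameter vectors, for testing
# endpoint and variability summaries without running a sampler.
fake_draws <- function(B, C, E = 1, Z = 0,
                       scope = c(institution = "LAB01",
                                 species = "Ae. aegypti",
                                 insecticide = "insecticide-A")) {
  k <- max(length(B), length(C), length(E), length(Z))
  as_posterior_draws(
    data.frame(chain = 1L, iteration = seq_len(k),
               B = rep_len(B, k), C = rep_len(C, k),
               E = rep_len(E, k), Z = rep_len(Z, k)),
    scope = scope)
}

# Random valid curve parameters for property-style loops.
random_params <- function(n, seed) {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    curve_params(B = runif(1, 0.3, 8), C = runif(1, -3, 5),
                 E = runif(1, 0.2, 5), Z = runif(1, 0, 0.5))))
}

# Small fast sampling schedule for tests that only need a working posterior,
# not the full production schedule.
fast_config <- function(seed, iterations = 1000L) {
  mcmc_config(iterations = iterations,
              escalation_iterations = 2L * iterations, adapt = 500L,
              seed = seed)
}
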
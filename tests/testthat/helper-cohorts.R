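# Shared synthetic fixtures, built once per test run and cached.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.cohort_cache[[name]])) .cohort_cache[[name]] <- builder()
  .cohort_cache[[name]]
}

noiseless_mapping <- function(individuality_sd = 0) {
  gt_mapping(noise_sd = c(delta = 0, theta = 0, alpha = 0, beta = 0),
             individuality_sd = individuality_sd)
}

# Tiny mixed cohort over 84 regions for structural checks.
tiny_cohort <- function() {
  cached("tiny", function()
    generate_cohort(synth_config(seed = 42, n_healthy = 6, n_patients = 2)))
}

# Small noiseless cohort at reduced node count for exactness checks.
noiseless_cohort <- function() {
  cached("noiseless", function()
    generate_cohort(synth_config(seed = 5, n_healthy = 8, n_patients = 0,
                                 n_nodes = 32, mapping = noiseless_mapping())))
}

toy_graph <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W[1, 3] <- W[3, 1] <- 0.25
  W
}

toy_parcellation <- function(n = 3) {
  parcellation(sprintf("R%02d", seq_len(n)))
}

# The scaled-down configuration used for autoencoder runs in the suite.
scaled_gmha_config <- function(seed = 2, epochs = 50, batch_size = 2) {
  gmha_config(epochs = epochs, batch_size = batch_size, lr = 5e-3,
              gamma = 1e-4, include_sc_row = TRUE, hidden = 32, latent = 16,
              decoder_hidden = 32, seed = seed)
}
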
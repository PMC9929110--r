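# Independent oracles and shared fixtures for the test suite.

# O(n^2) pair-enumeration Kendall tau-b, kept deliberately naive so it is
# independent of any library implementation.
brute_force_kendall <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; Tx <- 0; Ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) { Tx <- Tx + 1; Ty <- Ty + 1 }
      else if (dx == 0) Tx <- Tx + 1
      else if (dy == 0) Ty <- Ty + 1
      else if (dx * dy > 0) C <- C + 1
      else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - Tx) * (n0 - Ty))
}

# Random rooted binary tree with strictly positive branch lengths.
random_binary_tree <- function(ntip) {
  tr <- ape::rtree(ntip)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

# Build a degenerate allo_draws object directly, for tests that need full
# control of the posterior (identical draws, common slopes, ...).
make_draws <- function(alpha, beta, sigma = rep(0.05, nrow(alpha)),
                       response = "height", form = "power_linearized") {
  stopifnot(is.matrix(alpha), is.matrix(beta), !is.null(colnames(alpha)))
  S <- nrow(alpha)
  structure(list(alpha = alpha, beta = beta,
                 mu_alpha = rowMeans(alpha), mu_beta = rowMeans(beta),
                 sd_alpha = rep(0.1, S), sd_beta = rep(0.1, S),
                 rho = rep(0, S), sigma = sigma,
                 chain = rep(1L, S),
                 species_order = colnames(alpha),
                 spec = model_spec(response = response, form = form),
                 convergence = NULL, converged = TRUE),
            class = "allo_draws")
}

# Short-chain MCMC profile for unit tests.
tiny_mcmc <- function(seed = 5L) {
  mcmc_settings(n_chains = 2, n_iter = 1200, n_warmup = 600, seed = seed)
}

# Shared fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

shared_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- generate_dataset(synthetic_config(seed = 101L))
  }
  .fixtures$ds
}

shared_fit <- function(response = "height") {
  key <- paste0("fit_", response)
  if (is.null(.fixtures[[key]])) {
    ds <- shared_dataset()
    .fixtures[[key]] <- suppressWarnings(suppressMessages(
      fit_allometry(ds$observations, model_spec(response), tiny_mcmc())))
  }
  .fixtures[[key]]
}

# Observations drawn from the saturating (asymptotic) allometry, used for
# the WAIC model-selection experiments.
simulate_asymptotic_data <- function(n_species = 14, n_per_species = 15,
                                     a_mean = 1.3, a_sd = 0.05,
                                     b_mean = 0.15, b_sdlog = 0.1,
                                     residual_sd = 0.03, seed = 1L) {
  set.seed(seed)
  sp <- sprintf("SP%02d", seq_len(n_species))
  a <- rnorm(n_species, a_mean, a_sd)
  b <- exp(rnorm(n_species, log(b_mean), b_sdlog))
  species <- rep(sp, each = n_per_species)
  idx <- match(species, sp)
  dbh <- 10^rnorm(length(species), 0.9, 0.35)
  mu <- a[idx] * (1 - exp(-b[idx] * dbh))
  data.frame(species = species, dbh_cm = dbh,
             height_m = 10^(mu + rnorm(length(species), 0, residual_sd)),
             crown_radius_m = NA_real_, stringsAsFactors = FALSE)
}
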
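#' Configuration for the synthetic forest generator
#'
#' Bundles every knob of the generative model the pipeline is built to
#' analyse: a Yule phylogeny, Brownian-motion traits, species allometric
#' parameters drawn around hyper-means (optionally coupled to traits), and
#' individual tree measurements. The defaults describe a community of 14
#' dominant species with at least 10 (here 15) measured trees each,
#' log-log-linear allometries with species-varying intercepts and
#' near-common slopes around 0.75 (height) and 0.70 (crown radius), and a
#' conservative-strategy trait syndrome: denser-wooded species are shorter
#' and wider-crowned at a given stem diameter, heavier-seeded species
#' wider-crowned, and higher leaf phosphorus narrower-crowned.
#'
#' @param n_species Number of species (>= 2).
#' @param n_per_species Trees measured per species (>= 2).
#' @param height,crown_radius Per-response generative settings: lists with
#'   `hyper_mean_alpha`, `hyper_mean_beta` (log10 scale; the intercept is
#'   the log10 dimension at DBH = 1 cm), `sd_alpha`, `sd_beta`,
#'   `rho_alpha_beta`, `residual_sd` (log10 scale) and `coupling`, a named
#'   vector of per-trait coefficients (log10 units per trait standard
#'   deviation) added to the species intercept mean.
#' @param bm_roots Named per-trait root states for the Brownian-motion
#'   trait simulation (natural trait units).
#' @param bm_rates Named per-trait BM rates (variance per unit branch
#'   length); defaults to `(0.1 * root)^2` so simulated traits stay
#'   positive with overwhelming probability.
#' @param dbh_log10_mean,dbh_log10_sd Mean and SD of log10 DBH (cm) for
#'   simulated trees; defaults span roughly 1-30 cm, covering the 1-19 cm
#'   reference grid.
#' @param seed Integer seed; every stage derives its stream from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 14,
                             n_per_species = 15,
                             height = list(),
                             crown_radius = list(),
                             bm_roots = c(leaf_pct_n = 2.0, leaf_pct_p = 0.12,
                                          wood_density = 0.6, leaf_area = 60,
                                          sla = 120, seed_mass = 0.5),
                             bm_rates = NULL,
                             dbh_log10_mean = 0.9,
                             dbh_log10_sd = 0.35,
                             seed = 1L) {
  height_def <- list(hyper_mean_alpha = 0.30, hyper_mean_beta = 0.75,
                     sd_alpha = 0.10, sd_beta = 0.02, rho_alpha_beta = -0.3,
                     residual_sd = 0.05,
                     coupling = c(wood_density = -0.06))
  crown_def <- list(hyper_mean_alpha = -0.35, hyper_mean_beta = 0.70,
                    sd_alpha = 0.10, sd_beta = 0.02, rho_alpha_beta = -0.3,
                    residual_sd = 0.05,
                    coupling = c(wood_density = 0.05, seed_mass = 0.06,
                                 leaf_pct_p = -0.05))
  height <- utils::modifyList(height_def, height)
  crown_radius <- utils::modifyList(crown_def, crown_radius)
  if (is.null(bm_rates)) bm_rates <- (0.1 * bm_roots)^2
  cfg <- list(n_species = as.integer(n_species),
              n_per_species = as.integer(n_per_species),
              height = height, crown_radius = crown_radius,
              bm_roots = bm_roots, bm_rates = bm_rates,
              dbh_log10_mean = dbh_log10_mean, dbh_log10_sd = dbh_log10_sd,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_species < 2) stop("n_species must be >= 2")
  if (cfg$n_per_species < 2) stop("n_per_species must be >= 2")
  for (resp in c("height", "crown_radius")) {
    r <- cfg[[resp]]
    if (r$sd_alpha < 0 || r$sd_beta < 0) stop(resp, ": sd_alpha and sd_beta must be >= 0")
    if (abs(r$rho_alpha_beta) > 1) stop(resp, ": |rho_alpha_beta| must be <= 1")
    if (r$residual_sd < 0) stop(resp, ": residual_sd must be >= 0")
    unknown <- setdiff(names(r$coupling), names(cfg$bm_roots))
    if (length(unknown)) stop(resp, ": coupling names not among traits: ", paste(unknown, collapse = ", "))
  }
  if (any(cfg$bm_rates < 0)) stop("bm_rates must be >= 0")
  if (cfg$dbh_log10_sd <= 0) stop("dbh_log10_sd must be > 0")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Simulate an ultrametric pure-birth (Yule) phylogeny
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A rooted strictly binary ultrametric `phylo` with tips labelled
#'   `SP01`, `SP02`, ...
#' @export
simulate_phylogeny <- function(n_species, seed = 1L) {
  if (n_species < 2) stop("n_species must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  width <- max(2L, nchar(as.character(n_species)))
  tree$tip.label <- sprintf("SP%0*d", width, seq_len(n_species))
  validate_phylogeny(tree)
}

#' Simulate species traits by Brownian motion along a phylogeny
#'
#' Each trait evolves independently: the value at a tip is the root state
#' plus a sum of Normal(0, rate x branch length) increments along the
#' root-to-tip path, so traits generated this way satisfy the assumption
#' underlying phylogenetically independent contrasts exactly.
#'
#' @param tree A valid `phylo`.
#' @param rates Named per-trait non-negative BM rates (variance per unit
#'   branch length). A rate of 0 yields the root value at every tip.
#' @param root_values Named per-trait root states (same names as `rates`).
#' @param seed Integer seed.
#' @return A `trait_table` data frame (species x traits).
#' @export
simulate_traits_bm <- function(tree, rates, root_values, seed = 1L) {
  tree <- validate_phylogeny(tree)
  if (is.null(names(rates)) || is.null(names(root_values)) ||
      !setequal(names(rates), names(root_values))) {
    stop("rates and root_values must be named identically per trait")
  }
  if (any(rates < 0)) stop("BM rates must be >= 0")
  set.seed(seed)
  vals <- lapply(names(rates), function(tr) {
    x <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(rates[[tr]]),
                         root.value = root_values[[tr]])
    x[tree$tip.label]
  })
  tab <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
  for (i in seq_along(vals)) tab[[names(rates)[i]]] <- as.numeric(vals[[i]])
  validate_traits(tab, traits = names(rates), positive = FALSE)
}

#' Draw species allometric parameters, optionally coupled to traits
#'
#' Species intercept/slope pairs are drawn from a bivariate normal with
#' means `(hyper_mean_alpha + sum_t coupling_t * z_tj, hyper_mean_beta)`,
#' where `z_tj` is the across-species standardized value of trait t for
#' species j, standard deviations `(sd_alpha, sd_beta)` and correlation
#' `rho_alpha_beta`. Zero coupling gives trait-independent parameters.
#'
#' @param traits A `trait_table` covering all species.
#' @param response_cfg One response entry of a [synthetic_config()]
#'   (e.g. `cfg$height`).
#' @param response Response label stored in the result.
#' @param seed Integer seed.
#' @return Data frame with columns `species`, `response`, `alpha`, `beta`.
#' @export
simulate_allometric_params <- function(traits, response_cfg, response = "height", seed = 1L) {
  sp <- traits$species
  J <- length(sp)
  mean_alpha <- rep(response_cfg$hyper_mean_alpha, J)
  cpl <- response_cfg$coupling
  cpl <- cpl[cpl != 0]
  for (tr in names(cpl)) {
    if (!tr %in% names(traits)) stop("coupled trait '", tr, "' absent from trait table")
    v <- traits[[tr]]
    s <- stats::sd(v)
    z <- if (s > 0) (v - mean(v)) / s else rep(0, J)
    mean_alpha <- mean_alpha + cpl[[tr]] * z
  }
  set.seed(seed)
  e1 <- stats::rnorm(J)
  e2 <- stats::rnorm(J)
  rho <- response_cfg$rho_alpha_beta
  alpha <- mean_alpha + response_cfg$sd_alpha * e1
  beta <- response_cfg$hyper_mean_beta +
    response_cfg$sd_beta * (rho * e1 + sqrt(1 - rho^2) * e2)
  data.frame(species = sp, response = response, alpha = alpha, beta = beta,
             stringsAsFactors = FALSE)
}

#' Simulate individual tree measurements from species parameters
#'
#' Per tree: log10 DBH is drawn from the configured normal; each response
#' is `10^(alpha_j + beta_j * log10(DBH) + Normal(0, residual_sd))` in
#' natural units (m). One DBH is shared by both responses of a tree, as
#' for a real measured individual.
#'
#' @param params Named list of per-response parameter tables from
#'   [simulate_allometric_params()]; entries `height` and/or
#'   `crown_radius`. All present entries must cover the same species.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return An `allometry_data` data frame with `n_per_species` rows per
#'   species.
#' @export
simulate_observations <- function(params, config, seed = 1L) {
  stopifnot(length(params) >= 1)
  sp <- params[[1]]$species
  for (p in params) {
    if (!identical(sort(p$species), sort(sp))) stop("parameter tables cover different species")
  }
  n <- config$n_per_species
  set.seed(seed)
  species <- rep(sp, each = n)
  logd <- stats::rnorm(length(species), config$dbh_log10_mean, config$dbh_log10_sd)
  out <- data.frame(species = species, dbh_cm = 10^logd,
                    height_m = NA_real_, crown_radius_m = NA_real_,
                    stringsAsFactors = FALSE)
  cols <- c(height = "height_m", crown_radius = "crown_radius_m")
  for (resp in names(params)) {
    rc <- config[[resp]]
    if (rc$residual_sd < 0) stop("residual_sd must be >= 0")
    p <- params[[resp]]
    idx <- match(species, p$species)
    mu <- p$alpha[idx] + p$beta[idx] * logd
    out[[cols[[resp]]]] <- 10^(mu + stats::rnorm(length(species), 0, rc$residual_sd))
  }
  validate_allometry(out)
}

#' Generate a complete, internally consistent synthetic dataset
#'
#' Composes phylogeny, Brownian-motion traits, trait-coupled allometric
#' parameters and tree measurements; fully reproducible from the config
#' seed.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset` with elements `phylogeny`,
#'   `traits`, `true_params` (both responses, row-bound), `observations`
#'   and `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  config <- validate_synthetic_config(unclass(config))
  s <- config$seed
  tree <- simulate_phylogeny(config$n_species, seed = s)
  traits <- simulate_traits_bm(tree, config$bm_rates, config$bm_roots, seed = s + 1L)
  ph <- simulate_allometric_params(traits, config$height, "height", seed = s + 2L)
  pc <- simulate_allometric_params(traits, config$crown_radius, "crown_radius", seed = s + 3L)
  obs <- simulate_observations(list(height = ph, crown_radius = pc), config, seed = s + 4L)
  structure(list(phylogeny = tree, traits = traits,
                 true_params = rbind(ph, pc), observations = obs,
                 config = config),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' @param dataset A `synthetic_dataset`.
#' @param out_dir Output directory, created if absent.
#' @return Named vector of file paths (`allometry`, `traits`, `tree`,
#'   `true_params`), invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(allometry = file.path(out_dir, "allometry.csv"),
             traits = file.path(out_dir, "traits.csv"),
             tree = file.path(out_dir, "tree.nwk"),
             true_params = file.path(out_dir, "true_params.csv"))
  utils::write.csv(as.data.frame(dataset$observations), paths["allometry"], row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(dataset$traits), paths["traits"], row.names = FALSE, quote = FALSE)
  ape::write.tree(dataset$phylogeny, paths["tree"])
  utils::write.csv(dataset$true_params, paths["true_params"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
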
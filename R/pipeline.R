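#' Default pipeline configuration
#'
#' Nested list consumed by the stage runners. Either `inputs` (paths to an
#' allometry CSV, a trait CSV and a newick tree) or `synthetic` (a
#' [synthetic_config()]) must be usable; the synthetic branch is the
#' default. A single global `seed` derives every stage's seed, so one
#' seed reproduces the whole run bit-identically.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory for all stage products.
#' @param synthetic A [synthetic_config()] or `NULL` when real inputs are
#'   supplied.
#' @param inputs Named list with `allometry`, `traits`, `tree` paths, or
#'   `NULL` to simulate.
#' @param responses Responses to fit.
#' @param forms Functional forms to fit and compare by WAIC.
#' @param mcmc An [mcmc_settings()].
#' @param reference_dbhs Reference DBH grid (cm).
#' @param n_samples Posterior tau samples per correlation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = "allotrait_out",
                            synthetic = synthetic_config(seed = seed),
                            inputs = NULL,
                            responses = c("height", "crown_radius"),
                            forms = c("power_linearized", "asymptotic"),
                            mcmc = mcmc_settings(seed = seed),
                            reference_dbhs = seq(1, 19, by = 2),
                            n_samples = 10000) {
  if (is.null(synthetic) && is.null(inputs)) {
    stop("either synthetic config or input paths must be given")
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 synthetic = synthetic, inputs = inputs,
                 responses = responses, forms = forms, mcmc = mcmc,
                 reference_dbhs = reference_dbhs,
                 n_samples = as.integer(n_samples)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `synthetic` and
#' `mcmc` sub-maps override the corresponding defaults field by field.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) as.integer(y$seed) else 1L
  syn_over <- y$synthetic
  syn <- if (!is.null(y$inputs)) NULL else {
    base <- synthetic_config(seed = seed)
    if (!is.null(syn_over)) {
      base <- validate_synthetic_config(utils::modifyList(unclass(base), syn_over))
    }
    base
  }
  mc <- mcmc_settings(seed = seed)
  if (!is.null(y$mcmc)) {
    mc <- do.call(mcmc_settings, utils::modifyList(
      list(n_chains = mc$n_chains, n_iter = mc$n_iter,
           n_warmup = mc$n_warmup, seed = seed, thin = mc$thin),
      y$mcmc))
  }
  args <- list(seed = seed, synthetic = syn, mcmc = mc)
  for (k in c("out_dir", "inputs", "responses", "forms", "reference_dbhs", "n_samples")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), tmp)
  unname(tools::md5sum(tmp))
}

log_msg <- function(...) message("[allotrait] ", ...)

#' Simulate-stage runner: write a synthetic dataset to disk
#'
#' @param config A `pipeline_config` with a synthetic block.
#' @param out_dir Output directory (default `config$out_dir`).
#' @return Named vector of file paths, invisibly.
#' @export
run_simulate <- function(config, out_dir = config$out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$synthetic)) stop("no synthetic config present")
  ds <- generate_dataset(config$synthetic)
  paths <- write_dataset(ds, out_dir)
  manifest <- list(stage = "simulate", seed = config$synthetic$seed,
                   config_md5 = config_hash(config),
                   n_species = config$synthetic$n_species,
                   n_observations = nrow(ds$observations))
  yaml::write_yaml(manifest, file.path(out_dir, "simulate_manifest.yml"))
  log_msg("simulated ", nrow(ds$observations), " trees for ",
          config$synthetic$n_species, " species")
  invisible(paths)
}

read_pipeline_inputs <- function(config, out_dir) {
  if (!is.null(config$inputs)) {
    list(obs = read_allometry_csv(config$inputs$allometry),
         traits = read_trait_csv(config$inputs$traits),
         tree = read_newick(config$inputs$tree))
  } else {
    list(obs = read_allometry_csv(file.path(out_dir, "allometry.csv")),
         traits = read_trait_csv(file.path(out_dir, "traits.csv"),
                                 positive = FALSE),
         tree = read_newick(file.path(out_dir, "tree.nwk")))
  }
}

#' Fit-stage runner: both functional forms per response, WAIC comparison
#'
#' Fits every requested (response, form) combination, writes long-format
#' posterior draw CSVs, a parameter summary, a convergence report and a
#' WAIC table flagging the selected (lower-WAIC) form per response.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory holding (or receiving) the stage files.
#' @return Invisibly, a list with `fits` (nested by response/form) and
#'   `waic` (the comparison table).
#' @export
run_fit <- function(config, out_dir = config$out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  inp <- read_pipeline_inputs(config, out_dir)
  fits <- list()
  waic_rows <- list()
  summaries <- list()
  conv_rows <- list()
  for (resp in config$responses) {
    for (form in config$forms) {
      spec <- model_spec(response = resp, form = form)
      fit <- fit_allometry(inp$obs, spec, config$mcmc)
      fits[[resp]][[form]] <- fit
      w <- compute_waic(log_likelihood_pointwise(fit, inp$obs))
      waic_rows[[length(waic_rows) + 1L]] <- data.frame(
        response = resp, form = form, lppd = w$lppd, p_waic = w$p_waic,
        waic = w$waic, converged = fit$converged, stringsAsFactors = FALSE)
      write_draws_csv(fit, file.path(out_dir, sprintf("draws_%s_%s.csv", resp, form)))
      summaries[[length(summaries) + 1L]] <- summarize_parameters(fit)
      cv <- fit$convergence
      cv$response <- resp
      cv$form <- form
      conv_rows[[length(conv_rows) + 1L]] <- cv
      log_msg("fit ", resp, " / ", form, ": WAIC = ", round(w$waic, 2))
    }
  }
  waic_tab <- do.call(rbind, waic_rows)
  waic_tab$selected <- FALSE
  for (resp in unique(waic_tab$response)) {
    i <- which(waic_tab$response == resp)
    waic_tab$selected[i[which.min(waic_tab$waic[i])]] <- TRUE
  }
  write_result_tables(list(
    waic = waic_tab,
    parameter_summary = do.call(rbind, summaries),
    convergence = do.call(rbind, conv_rows)), out_dir)
  invisible(list(fits = fits, waic = waic_tab))
}

#' Correlation-stage runner
#'
#' Loads the selected (lower-WAIC) posterior per response plus traits and
#' tree, and writes the trait x parameter table, the trait x
#' reference-diameter tables and the height-crown coupling table.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Directory with the fit-stage outputs.
#' @return Invisibly, a named list of the correlation tables.
#' @export
run_correlate <- function(config, out_dir = config$out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- read_pipeline_inputs(config, out_dir)
  waic_path <- file.path(out_dir, "waic.csv")
  if (!file.exists(waic_path)) stop("missing fit outputs in ", out_dir, "; run run_fit() first")
  waic_tab <- utils::read.csv(waic_path, stringsAsFactors = FALSE)
  draws <- list()
  for (resp in config$responses) {
    sel <- waic_tab$form[waic_tab$response == resp & waic_tab$selected][1]
    path <- file.path(out_dir, sprintf("draws_%s_%s.csv", resp, sel))
    if (!file.exists(path)) stop("missing posterior draws file: ", path)
    draws[[resp]] <- read_draws_csv(path)
  }
  param_tabs <- list()
  size_tabs <- list()
  for (resp in config$responses) {
    param_tabs[[resp]] <- sample_parameter_correlations(
      draws[[resp]], inp$traits, inp$tree,
      n_samples = config$n_samples, seed = config$seed + 10L)
    size_tabs[[resp]] <- sample_sizeclass_correlations(
      draws[[resp]], inp$traits, inp$tree,
      reference_dbhs = config$reference_dbhs,
      n_samples = config$n_samples, seed = config$seed + 11L)
  }
  results <- list(parameter_correlations = do.call(rbind, unname(param_tabs)),
                  sizeclass_correlations = do.call(rbind, unname(size_tabs)))
  if (all(c("height", "crown_radius") %in% names(draws))) {
    results$coupling_correlations <- height_crown_coupling(
      draws$height, draws$crown_radius, inp$tree,
      reference_dbhs = config$reference_dbhs,
      n_samples = config$n_samples, seed = config$seed + 12L)
  }
  write_result_tables(results, out_dir)
  log_msg("wrote ", length(results), " correlation table(s)")
  invisible(results)
}

#' Run the full pipeline: simulate (if synthetic), fit, correlate
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the fit and correlation results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  timing <- list()
  if (is.null(config$inputs)) {
    run_simulate(config, out_dir)
    timing$simulate <- as.numeric(Sys.time() - t0, units = "secs")
  }
  t1 <- Sys.time()
  fit_res <- run_fit(config, out_dir)
  timing$fit <- as.numeric(Sys.time() - t1, units = "secs")
  t2 <- Sys.time()
  cor_res <- run_correlate(config, out_dir)
  timing$correlate <- as.numeric(Sys.time() - t2, units = "secs")
  manifest <- list(seed = config$seed, config_md5 = config_hash(config),
                   r_version = as.character(getRversion()),
                   stage_seconds = lapply(timing, round, 2))
  yaml::write_yaml(manifest, file.path(out_dir, "pipeline_manifest.yml"))
  invisible(list(fits = fit_res$fits, waic = fit_res$waic,
                 correlations = cor_res))
}

#' Persist posterior draws to a long-format CSV
#'
#' Columns: `draw`, `chain`, `species` (empty for hyperparameters),
#' `parameter`, `value`, plus constant `response` and `form` columns, so
#' external tools can consume the posterior.
#'
#' @param draws An `allo_draws` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  stopifnot(inherits(draws, "allo_draws"))
  S <- nrow(draws$alpha)
  J <- ncol(draws$alpha)
  sp_block <- function(mat, pname) {
    data.frame(draw = rep(seq_len(S), J),
               chain = rep(draws$chain, J),
               species = rep(colnames(mat), each = S),
               parameter = pname, value = as.vector(mat),
               stringsAsFactors = FALSE)
  }
  hyper_block <- function(v, pname) {
    data.frame(draw = seq_len(S), chain = draws$chain, species = "",
               parameter = pname, value = v, stringsAsFactors = FALSE)
  }
  long <- rbind(sp_block(draws$alpha, "alpha"), sp_block(draws$beta, "beta"),
                hyper_block(draws$mu_alpha, "mu_alpha"),
                hyper_block(draws$mu_beta, "mu_beta"),
                hyper_block(draws$sd_alpha, "sd_alpha"),
                hyper_block(draws$sd_beta, "sd_beta"),
                hyper_block(draws$rho, "rho"),
                hyper_block(draws$sigma, "sigma"))
  long$response <- draws$spec$response
  long$form <- draws$spec$form
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_draws_csv()]
#'
#' @param path CSV path.
#' @return An `allo_draws` object (without a convergence report, which is
#'   persisted separately).
#' @export
read_draws_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(species = "character"))
  resp <- long$response[1]
  form <- long$form[1]
  sp <- sort(unique(long$species[long$parameter == "alpha"]), method = "radix")
  S <- max(long$draw)
  grab_sp <- function(pname) {
    sub <- long[long$parameter == pname, ]
    mat <- matrix(NA_real_, S, length(sp), dimnames = list(NULL, sp))
    mat[cbind(sub$draw, match(sub$species, sp))] <- sub$value
    mat
  }
  grab_hy <- function(pname) {
    sub <- long[long$parameter == pname, ]
    sub$value[order(sub$draw)]
  }
  structure(list(alpha = grab_sp("alpha"), beta = grab_sp("beta"),
                 mu_alpha = grab_hy("mu_alpha"), mu_beta = grab_hy("mu_beta"),
                 sd_alpha = grab_hy("sd_alpha"), sd_beta = grab_hy("sd_beta"),
                 rho = grab_hy("rho"), sigma = grab_hy("sigma"),
                 chain = long$chain[long$parameter == "sigma"][order(long$draw[long$parameter == "sigma"])],
                 species_order = sp,
                 spec = model_spec(response = resp, form = form),
                 convergence = NULL, converged = NA),
            class = "allo_draws")
}
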
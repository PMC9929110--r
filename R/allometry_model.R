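#' Specification of one hierarchical allometry model
#'
#' Both functional forms model the log10 response of tree i in species j
#' as normally distributed about a species-level mean curve, with the
#' species parameter pairs drawn from a bivariate normal hyperdistribution
#' (an explicit intercept-slope covariance):
#'
#' * `power_linearized`: mean = alpha_j + beta_j * log10(DBH_ij). The
#'   intercept alpha_j is the log10 dimension at DBH = 1 cm (no
#'   centering), beta_j the dimensionless scaling exponent.
#' * `asymptotic`: mean = a_j * (1 - exp(-b_j * DBH_ij)), a saturating
#'   curve on the log10 scale where a_j is the log10 asymptotic dimension
#'   and b_j > 0 the approach rate per cm. Hierarchy is placed on
#'   (a_j, log b_j).
#'
#' Slope priors default to the global angiosperm allometric exponents
#' (0.75 for height, 0.70 for crown radius) with a deliberately large SD
#' of 0.5 so the data dominate; hyper-SDs and the residual SD get
#' half-normal priors and the intercept-slope correlation a uniform prior
#' on `[-1, 1]`.
#'
#' @param response `"height"` or `"crown_radius"`.
#' @param form `"power_linearized"` or `"asymptotic"`.
#' @param prior_slope_mean Prior mean of the hyper-mean slope; default
#'   0.75 (height) / 0.70 (crown radius).
#' @param prior_slope_sd,prior_intercept_mean,prior_intercept_sd Normal
#'   prior for the hyper-means of slope and intercept.
#' @param scale_prior_sd Scale of the half-normal priors on `sd_alpha`,
#'   `sd_beta` and the residual `sigma`.
#' @param asym_size_prior_mean,asym_size_prior_sd Normal prior for the
#'   hyper-mean log10 asymptote (asymptotic form).
#' @param asym_rate_prior_meanlog,asym_rate_prior_sdlog Normal prior for
#'   the hyper-mean log approach rate (asymptotic form).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response = c("height", "crown_radius"),
                       form = c("power_linearized", "asymptotic"),
                       prior_slope_mean = NULL,
                       prior_slope_sd = 0.5,
                       prior_intercept_mean = 0,
                       prior_intercept_sd = 1,
                       scale_prior_sd = 1,
                       asym_size_prior_mean = 1,
                       asym_size_prior_sd = 1,
                       asym_rate_prior_meanlog = log(0.15),
                       asym_rate_prior_sdlog = 1) {
  response <- match.arg(response)
  form <- match.arg(form)
  if (is.null(prior_slope_mean)) {
    prior_slope_mean <- if (response == "height") 0.75 else 0.70
  }
  sds <- c(prior_slope_sd, prior_intercept_sd, scale_prior_sd,
           asym_size_prior_sd, asym_rate_prior_sdlog)
  if (any(sds <= 0)) stop("all prior SDs must be > 0")
  structure(list(response = response, form = form,
                 prior_slope_mean = prior_slope_mean,
                 prior_slope_sd = prior_slope_sd,
                 prior_intercept_mean = prior_intercept_mean,
                 prior_intercept_sd = prior_intercept_sd,
                 scale_prior_sd = scale_prior_sd,
                 asym_size_prior_mean = asym_size_prior_mean,
                 asym_size_prior_sd = asym_size_prior_sd,
                 asym_rate_prior_meanlog = asym_rate_prior_meanlog,
                 asym_rate_prior_sdlog = asym_rate_prior_sdlog),
            class = "model_spec")
}

#' MCMC settings
#'
#' Defaults mirror a production run of four chains of 20,000 iterations
#' with a 10,000-iteration warmup; analyses at desk scale typically use
#' shorter chains (e.g. 4 x 2,000 with 1,000 warmup).
#'
#' @param n_chains Number of chains (>= 2, for split R-hat).
#' @param n_iter Total iterations per chain.
#' @param n_warmup Warmup (burn-in) iterations per chain (< `n_iter`).
#' @param seed Integer seed; per-chain RNG seeds are derived from it.
#' @param thin Thinning interval for retained draws.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 4, n_iter = 20000, n_warmup = 10000,
                          seed = 1L, thin = 1) {
  if (n_chains < 2) stop("n_chains must be >= 2")
  if (n_warmup >= n_iter) stop("n_warmup must be < n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_warmup = as.integer(n_warmup), seed = as.integer(seed),
                 thin = as.integer(thin)),
            class = "mcmc_settings")
}

# The bivariate species-level normal is written as a marginal for the
# intercept-like parameter and a conditional for the slope-like one:
# exactly the same joint distribution, but it avoids inverting a
# (possibly near-singular) 2x2 covariance matrix inside the sampler and
# keeps the species-level updates conjugate.
jags_model_power <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(ab[sp[i], 1] + ab[sp[i], 2] * x[i], tau_res)
  }
  for (j in 1:J) {
    ab[j, 1] ~ dnorm(mu[1], 1 / sd_alpha^2)
    ab[j, 2] ~ dnorm(mu[2] + rho * sd_beta / sd_alpha * (ab[j, 1] - mu[1]),
                     1 / ((1 - rho^2) * sd_beta^2))
  }
  mu[1] ~ dnorm(prior_int_mean, 1 / prior_int_sd^2)
  mu[2] ~ dnorm(prior_slope_mean, 1 / prior_slope_sd^2)
  sd_alpha ~ dnorm(0, 1 / scale_sd^2) T(0,)
  sd_beta ~ dnorm(0, 1 / scale_sd^2) T(0,)
  rho ~ dunif(-1, 1)
  sigma ~ dnorm(0, 1 / scale_sd^2) T(0,)
  tau_res <- 1 / sigma^2
}
"

jags_model_asymptotic <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(ab[sp[i], 1] * (1 - exp(-exp(ab[sp[i], 2]) * d[i])), tau_res)
  }
  for (j in 1:J) {
    ab[j, 1] ~ dnorm(mu[1], 1 / sd_alpha^2)
    ab[j, 2] ~ dnorm(mu[2] + rho * sd_beta / sd_alpha * (ab[j, 1] - mu[1]),
                     1 / ((1 - rho^2) * sd_beta^2))
  }
  mu[1] ~ dnorm(prior_a_mean, 1 / prior_a_sd^2)
  mu[2] ~ dnorm(prior_logb_mean, 1 / prior_logb_sd^2)
  sd_alpha ~ dnorm(0, 1 / scale_sd^2) T(0,)
  sd_beta ~ dnorm(0, 1 / scale_sd^2) T(0,)
  rho ~ dunif(-1, 1)
  sigma ~ dnorm(0, 1 / scale_sd^2) T(0,)
  tau_res <- 1 / sigma^2
}
"

response_column <- function(response) {
  switch(response, height = "height_m", crown_radius = "crown_radius_m",
         stop("unknown response: ", response))
}

usable_records <- function(data, response) {
  col <- response_column(response)
  keep <- !is.na(data[[col]]) & !is.na(data$dbh_cm)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " record(s) without ", response, " dropped for this model")
  }
  data[keep, , drop = FALSE]
}

#' Fit a hierarchical Bayesian allometry model
#'
#' Partial-pooling fit of log10 response against DBH across species, via
#' Gibbs sampling (JAGS). Species intercept/slope pairs share a bivariate
#' normal hyperdistribution with free correlation; the residual SD is
#' shared across species. Convergence is summarised by split R-hat and
#' effective sample size per parameter; any split R-hat above 1.05 raises
#' a warning and is flagged in the result rather than silenced.
#'
#' @param data An `allometry_data` data frame.
#' @param spec A [model_spec()]; `fit_hierarchical()` requires
#'   `form = "power_linearized"`, [fit_asymptotic()] the saturating form.
#'   [fit_allometry()] dispatches on `spec$form`.
#' @param mcmc An [mcmc_settings()].
#' @return An object of class `allo_draws`: matrices `alpha`, `beta`
#'   (draws x species; for the asymptotic form these hold a_j and b_j),
#'   vectors `mu_alpha`, `mu_beta`, `sd_alpha`, `sd_beta`, `rho`, `sigma`,
#'   a `chain` index, `species_order`, the `spec`, and a `convergence`
#'   data frame (parameter, split R-hat, ESS).
#' @export
fit_allometry <- function(data, spec, mcmc = mcmc_settings()) {
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_settings"))
  data <- validate_allometry(as.data.frame(data))
  data <- usable_records(data, spec$response)
  species_order <- sort(unique(data$species), method = "radix")
  if (length(species_order) < 2) {
    stop("hierarchical model needs at least 2 species with usable records")
  }
  counts <- table(data$species)
  if (any(counts < 2)) {
    stop("species with fewer than 2 usable records: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  spidx <- match(data$species, species_order)
  y <- log10(data[[response_column(spec$response)]])
  J <- length(species_order)

  if (spec$form == "power_linearized") {
    jdata <- list(y = y, x = log10(data$dbh_cm), sp = spidx,
                  N = nrow(data), J = J,
                  prior_int_mean = spec$prior_intercept_mean,
                  prior_int_sd = spec$prior_intercept_sd,
                  prior_slope_mean = spec$prior_slope_mean,
                  prior_slope_sd = spec$prior_slope_sd,
                  scale_sd = spec$scale_prior_sd)
    model_str <- jags_model_power
    mu_init <- c(spec$prior_intercept_mean, spec$prior_slope_mean)
  } else {
    jdata <- list(y = y, d = data$dbh_cm, sp = spidx,
                  N = nrow(data), J = J,
                  prior_a_mean = spec$asym_size_prior_mean,
                  prior_a_sd = spec$asym_size_prior_sd,
                  prior_logb_mean = spec$asym_rate_prior_meanlog,
                  prior_logb_sd = spec$asym_rate_prior_sdlog,
                  scale_sd = spec$scale_prior_sd)
    model_str <- jags_model_asymptotic
    mu_init <- c(spec$asym_size_prior_mean, spec$asym_rate_prior_meanlog)
  }

  set.seed(mcmc$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, mcmc$n_chains)
  inits <- lapply(seq_len(mcmc$n_chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = chain_seeds[c],
         mu = mu_init, sd_alpha = 0.1, sd_beta = 0.1, rho = 0, sigma = 0.1,
         ab = matrix(mu_init, J, 2, byrow = TRUE))
  })
  model <- rjags::jags.model(textConnection(model_str), data = jdata,
                             inits = inits, n.chains = mcmc$n_chains,
                             quiet = TRUE)
  update(model, mcmc$n_warmup, progress.bar = "none")
  samp <- rjags::coda.samples(
    model, c("ab", "mu", "sd_alpha", "sd_beta", "rho", "sigma"),
    n.iter = mcmc$n_iter - mcmc$n_warmup, thin = mcmc$thin,
    progress.bar = "none")

  per_chain <- nrow(samp[[1]])
  post <- do.call(rbind, lapply(samp, as.matrix))
  alpha <- post[, paste0("ab[", seq_len(J), ",1]"), drop = FALSE]
  beta <- post[, paste0("ab[", seq_len(J), ",2]"), drop = FALSE]
  if (spec$form == "asymptotic") beta <- exp(beta)
  colnames(alpha) <- colnames(beta) <- species_order

  conv <- convergence_summary(samp)
  conv$parameter <- rename_monitored(conv$parameter, species_order)
  flagged <- conv$parameter[conv$rhat > 1.05]
  if (length(flagged)) {
    warning("split R-hat > 1.05 for: ", paste(flagged, collapse = ", "))
  }
  structure(list(alpha = alpha, beta = beta,
                 mu_alpha = unname(post[, "mu[1]"]),
                 mu_beta = unname(post[, "mu[2]"]),
                 sd_alpha = unname(post[, "sd_alpha"]),
                 sd_beta = unname(post[, "sd_beta"]),
                 rho = unname(post[, "rho"]),
                 sigma = unname(post[, "sigma"]),
                 chain = rep(seq_len(mcmc$n_chains), each = per_chain),
                 species_order = species_order,
                 spec = spec, mcmc = mcmc,
                 convergence = conv,
                 converged = length(flagged) == 0),
            class = "allo_draws")
}

#' @rdname fit_allometry
#' @export
fit_hierarchical <- function(data, spec, mcmc = mcmc_settings()) {
  if (spec$form != "power_linearized") stop("fit_hierarchical() fits the linearized power law; see fit_asymptotic()")
  fit_allometry(data, spec, mcmc)
}

#' @rdname fit_allometry
#' @export
fit_asymptotic <- function(data, spec, mcmc = mcmc_settings()) {
  if (spec$form != "asymptotic") stop("fit_asymptotic() requires form = 'asymptotic'")
  fit_allometry(data, spec, mcmc)
}

split_rhat <- function(mat) {
  # mat: iterations x chains; split each chain in half
  n <- nrow(mat)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  halves <- cbind(mat[seq_len(half), , drop = FALSE],
                  mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# map JAGS node names to readable, comma-free parameter labels
rename_monitored <- function(params, species_order) {
  out <- params
  out[out == "mu[1]"] <- "mu_alpha"
  out[out == "mu[2]"] <- "mu_beta"
  m <- regmatches(params, regexec("^ab\\[([0-9]+),([12])\\]$", params))
  for (i in seq_along(m)) {
    if (length(m[[i]]) == 3) {
      j <- as.integer(m[[i]][2])
      out[i] <- paste0(if (m[[i]][3] == "1") "alpha_" else "beta_",
                       species_order[j])
    }
  }
  out
}

convergence_summary <- function(samp) {
  params <- colnames(samp[[1]])
  rhat <- vapply(params, function(p) {
    split_rhat(sapply(samp, function(ch) as.matrix(ch)[, p]))
  }, numeric(1))
  ess <- tryCatch(coda::effectiveSize(samp), error = function(e) rep(NA_real_, length(params)))
  data.frame(parameter = params, rhat = unname(rhat),
             ess = unname(ess[params]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pointwise log likelihood of the data under each posterior draw
#'
#' @param draws An `allo_draws` object.
#' @param data The `allometry_data` the model was (or could be) fit to;
#'   records missing the modeled response are excluded, mirroring the fit.
#' @return An S x N matrix: entry (s, i) is the normal log density of the
#'   observed log10 response of record i under draw s.
#' @export
log_likelihood_pointwise <- function(draws, data) {
  stopifnot(inherits(draws, "allo_draws"))
  data <- validate_allometry(as.data.frame(data))
  data <- usable_records(data, draws$spec$response)
  missing_sp <- setdiff(unique(data$species), draws$species_order)
  if (length(missing_sp)) {
    stop("species in data absent from draws: ", paste(missing_sp, collapse = ", "))
  }
  idx <- match(data$species, draws$species_order)
  y <- log10(data[[response_column(draws$spec$response)]])
  if (draws$spec$form == "power_linearized") {
    x <- log10(data$dbh_cm)
    mu <- draws$alpha[, idx, drop = FALSE] +
      draws$beta[, idx, drop = FALSE] * rep(x, each = nrow(draws$alpha))
  } else {
    d <- data$dbh_cm
    mu <- draws$alpha[, idx, drop = FALSE] *
      (1 - exp(-draws$beta[, idx, drop = FALSE] * rep(d, each = nrow(draws$alpha))))
  }
  ymat <- matrix(y, nrow(mu), ncol(mu), byrow = TRUE)
  ll <- stats::dnorm(ymat, mu, draws$sigma, log = TRUE)
  dimnames(ll) <- NULL
  ll
}

#' Widely applicable information criterion from a pointwise log-likelihood
#' matrix
#'
#' `lppd = sum_i log mean_s exp(loglik[s, i])` (log-sum-exp stabilised),
#' `p_waic = sum_i var_s(loglik[s, i])` (sample variance, denominator
#' S - 1), `waic = -2 (lppd - p_waic)`; the pointwise vector
#' `-2 (lppd_i - p_i)` sums to `waic`.
#'
#' @param loglik S x N matrix of per-draw, per-observation log densities
#'   (S >= 2).
#' @return A list of class `waic_result`: `lppd`, `p_waic`, `waic`,
#'   `pointwise`.
#' @export
compute_waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  S <- nrow(loglik)
  if (S < 2) stop("need at least 2 draws to compute WAIC")
  mx <- apply(loglik, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(loglik, 2, mx, "-"))))
  p_i <- apply(loglik, 2, stats::var)
  pointwise <- -2 * (lppd_i - p_i)
  structure(list(lppd = sum(lppd_i), p_waic = sum(p_i),
                 waic = -2 * (sum(lppd_i) - sum(p_i)),
                 pointwise = pointwise),
            class = "waic_result")
}

#' Expected dimension at a reference diameter, per draw and species
#'
#' The expected value of the mean curve (no residual noise): for the
#' power form `10^(alpha_j + beta_j * log10(DBH))`, for the asymptotic
#' form `10^(a_j (1 - exp(-b_j DBH)))`, in natural units (m).
#'
#' @param draws An `allo_draws` object.
#' @param dbh_cm A single positive reference DBH in cm.
#' @return S x J matrix (draws x species), columns named by species.
#' @export
predict_at_diameter <- function(draws, dbh_cm) {
  stopifnot(inherits(draws, "allo_draws"))
  if (length(dbh_cm) != 1 || !is.finite(dbh_cm) || dbh_cm <= 0) {
    stop("dbh_cm must be a single positive number")
  }
  if (draws$spec$form == "power_linearized") {
    10^(draws$alpha + draws$beta * log10(dbh_cm))
  } else {
    10^(draws$alpha * (1 - exp(-draws$beta * dbh_cm)))
  }
}

#' Posterior summaries of the species-level parameters
#'
#' @param draws An `allo_draws` object.
#' @param probs Percentiles for the credible interval bounds.
#' @return Data frame with one row per species per parameter
#'   (intercept/slope, or asymptote/rate for the asymptotic form):
#'   `species`, `parameter`, `response`, `median`, `lo95`, `hi95`.
#' @export
summarize_parameters <- function(draws, probs = c(0.025, 0.975)) {
  stopifnot(inherits(draws, "allo_draws"))
  if (nrow(draws$alpha) < 2) stop("need at least 2 draws")
  pnames <- if (draws$spec$form == "power_linearized") {
    c("intercept", "slope")
  } else {
    c("log10_asymptote", "approach_rate")
  }
  one <- function(mat, pname) {
    data.frame(species = colnames(mat), parameter = pname,
               response = draws$spec$response,
               median = apply(mat, 2, stats::median),
               lo95 = apply(mat, 2, stats::quantile, probs = probs[1]),
               hi95 = apply(mat, 2, stats::quantile, probs = probs[2]),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  rbind(one(draws$alpha, pnames[1]), one(draws$beta, pnames[2]))
}
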
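test_that("WAIC matches the hand-computed toy oracle and its invariants", {
  ll <- matrix(c(-1, -2, -1.5, -2.5, -0.5, -1.5), nrow = 3, byrow = TRUE)
  w <- compute_waic(ll)
  # frozen from an independent spreadsheet-style computation:
  # lppd_i = log(mean(exp(col))), p_i = var(col), waic = -2(lppd - p)
  expect_equal(w$lppd, -2.836685236053, tolerance = 1e-9)
  expect_equal(w$p_waic, 0.5, tolerance = 1e-12)
  expect_equal(w$waic, 6.673370472106, tolerance = 1e-9)
  expect_equal(sum(w$pointwise), w$waic, tolerance = 1e-8)
  expect_gte(w$p_waic, 0)
  expect_equal(w$waic, -2 * (w$lppd - w$p_waic), tolerance = 1e-12)

  same <- ll[c(1, 1, 1), ]
  w0 <- compute_waic(same)
  expect_equal(w0$p_waic, 0)
  expect_equal(w0$waic, -2 * sum(ll[1, ]))
  expect_error(compute_waic(ll[1, , drop = FALSE]), "at least 2")
})

test_that("pointwise log likelihood has normal-density anatomy", {
  sp <- c("A", "B")
  draws <- make_draws(alpha = matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2,
                                     dimnames = list(NULL, sp)),
                      beta = matrix(0, 2, 2, dimnames = list(NULL, sp)),
                      sigma = c(1, 2))
  data <- data.frame(species = sp, dbh_cm = c(1, 1),
                     height_m = 10^0.5, crown_radius_m = NA_real_)
  ll <- log_likelihood_pointwise(draws, data)
  expect_equal(dim(ll), c(2, 2))
  expect_equal(ll[1, 1], -0.9189385332, tolerance = 1e-9)   # -log(sqrt(2*pi))
  expect_equal(ll[1, 1] - ll[2, 1], log(2), tolerance = 1e-9)
  bad <- data; bad$species <- c("A", "Z")
  expect_error(log_likelihood_pointwise(draws, bad), "absent")
})

test_that("expected dimensions at reference diameters follow the forms", {
  sp <- c("A", "B")
  draws <- make_draws(alpha = matrix(c(0, 0.3), 1, 2, dimnames = list(NULL, sp)),
                      beta = matrix(c(1, 0.7), 1, 2, dimnames = list(NULL, sp)),
                      sigma = 0.05)
  expect_equal(unname(predict_at_diameter(draws, 10)[1, "A"]), 10)
  expect_equal(unname(predict_at_diameter(draws, 1)[1, ]), 10^c(0, 0.3))
  d <- c(2, 5, 9, 15)
  preds <- vapply(d, function(x) predict_at_diameter(draws, x)[1, "B"], numeric(1))
  expect_true(all(diff(preds) > 0))   # beta > 0 => strictly increasing
  expect_error(predict_at_diameter(draws, -1), "positive")

  asym <- make_draws(alpha = matrix(c(1.3, 1.3), 1, 2, dimnames = list(NULL, sp)),
                     beta = matrix(c(1e6, 0.15), 1, 2, dimnames = list(NULL, sp)),
                     form = "asymptotic")
  expect_equal(unname(predict_at_diameter(asym, 7)[1, "A"]), 10^1.3)
})

test_that("parameter summaries use interpolated percentiles", {
  sp <- c("A", "B")
  const <- make_draws(alpha = matrix(2.5, 4, 2, dimnames = list(NULL, sp)),
                      beta = matrix(0.7, 4, 2, dimnames = list(NULL, sp)))
  s <- summarize_parameters(const)
  expect_equal(nrow(s), 4)   # J species x 2 parameters
  expect_equal(s$median, c(2.5, 2.5, 0.7, 0.7))
  expect_equal(s$lo95, s$hi95)

  long <- make_draws(alpha = cbind(A = 1:10000, B = 1:10000),
                     beta = matrix(0.7, 10000, 2, dimnames = list(NULL, sp)))
  s2 <- summarize_parameters(long)
  i <- which(s2$species == "A" & s2$parameter == "intercept")
  expect_equal(s2$median[i], 5000.5)
  expect_equal(s2$lo95[i], 250.975)
  expect_equal(s2$hi95[i], 9750.025)
})

test_that("the hierarchical fit requires at least two species", {
  ds <- shared_dataset()
  one <- ds$observations[ds$observations$species == "SP01", ]
  expect_error(fit_allometry(one, model_spec("height"), tiny_mcmc()),
               "at least 2 species")
})

test_that("posterior medians recover the generating parameters", {
  ds <- shared_dataset()
  fit <- shared_fit("height")
  truth <- ds$true_params[ds$true_params$response == "height", ]
  med <- apply(fit$alpha, 2, stats::median)
  expect_lt(max(abs(med - truth$alpha[match(names(med), truth$species)])), 0.1)
  medb <- apply(fit$beta, 2, stats::median)
  expect_lt(max(abs(medb - truth$beta[match(names(medb), truth$species)])), 0.1)
  expect_lt(abs(stats::median(fit$sigma) - 0.05), 0.02)
  # convergence report present for every monitored parameter
  expect_true(all(c("rhat", "ess") %in% names(fit$convergence)))
  expect_true(all(is.finite(fit$convergence$rhat)))
})

test_that("partial pooling shrinks species intercepts toward the grand mean", {
  # common generating slopes and no intercept-slope correlation keep the
  # intercept hierarchy effectively one-dimensional, where shrinkage
  # strictly between the per-species least-squares estimate and the
  # hyper-mean is the conjugate normal-normal prediction
  cfg <- synthetic_config(seed = 21, n_species = 6, n_per_species = 30,
                          height = list(residual_sd = 0.15, sd_beta = 0,
                                        rho_alpha_beta = 0,
                                        coupling = numeric(0)))
  ds <- generate_dataset(cfg)
  # unbalanced design: only species SP01 keeps all its trees
  obs <- ds$observations
  keep <- unlist(lapply(split(seq_len(nrow(obs)), obs$species), function(i) {
    if (obs$species[i[1]] == "SP01") i else i[1:4]
  }))
  obs <- obs[sort(keep), ]
  fit <- suppressWarnings(suppressMessages(
    fit_allometry(validate_allometry(obs), model_spec("height"), tiny_mcmc(9))))
  mu <- stats::median(fit$mu_alpha)
  b <- stats::median(fit$mu_beta)   # near-common slope, conditioned on
  for (sp in fit$species_order) {
    sub <- obs[obs$species == sp, ]
    data_only <- mean(log10(sub$height_m) - b * log10(sub$dbh_cm))
    med <- stats::median(fit$alpha[, sp])
    expect_gte(med, min(data_only, mu) - 0.02)
    expect_lte(med, max(data_only, mu) + 0.02)
  }
})

test_that("posterior draws survive the CSV round trip", {
  fit <- shared_fit("height")
  path <- tempfile(fileext = ".csv")
  write_draws_csv(fit, path)
  back <- read_draws_csv(path)
  expect_equal(back$alpha, fit$alpha, tolerance = 1e-12)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(back$sigma, fit$sigma, tolerance = 1e-12)
  expect_equal(back$species_order, fit$species_order)
  expect_equal(back$spec$response, "height")
})
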
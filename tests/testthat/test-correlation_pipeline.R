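test_that("tau summaries report interpolated percentile intervals", {
  s <- summarize_tau(rep(0.3, 50))
  expect_equal(unlist(s[c("median_tau", "lo95", "hi95")]),
               c(median_tau = 0.3, lo95 = 0.3, hi95 = 0.3))
  expect_true(s$excludes_zero)

  s2 <- summarize_tau(c(-0.5, 0, 0.5))
  expect_equal(s2$median_tau, 0)
  expect_false(s2$excludes_zero)

  set.seed(2)
  x <- sample(seq(-1, 1, by = 0.25), 10000, replace = TRUE)
  s3 <- summarize_tau(x)
  sorted <- sort(x)   # independent sorted-array percentile oracle
  q <- function(p) { h <- (length(x) - 1) * p + 1
    sorted[floor(h)] + (h - floor(h)) * (sorted[ceiling(h)] - sorted[floor(h)]) }
  expect_equal(s3$lo95, q(0.025), tolerance = 1e-12)
  expect_equal(s3$hi95, q(0.975), tolerance = 1e-12)
  expect_error(summarize_tau(numeric(0)), "at least 1")
})

test_that("a degenerate posterior with a monotone trait gives tau = 1", {
  tr <- simulate_phylogeny(8, seed = 5)
  sp <- tr$tip.label
  alpha <- matrix(rep(seq(0.1, 0.8, by = 0.1), each = 3), 3, 8,
                  dimnames = list(NULL, sp))
  draws <- make_draws(alpha, matrix(0.75, 3, 8, dimnames = list(NULL, sp)))
  traits <- data.frame(species = sp, wood_density = 2 * alpha[1, ] + 1)
  tab <- sample_parameter_correlations(draws, traits, tr, n_samples = 100,
                                       seed = 1, targets = "intercept")
  expect_equal(tab$median_tau, 1)
  expect_equal(tab$lo95, 1)
  expect_equal(tab$hi95, 1)
  expect_true(tab$excludes_zero)
})

test_that("correlation tables have the full factorial shape", {
  ds <- shared_dataset()
  fit_h <- shared_fit("height")
  fit_c <- shared_fit("crown_radius")
  ptab <- rbind(
    sample_parameter_correlations(fit_h, ds$traits, ds$phylogeny,
                                  n_samples = 200, seed = 2),
    sample_parameter_correlations(fit_c, ds$traits, ds$phylogeny,
                                  n_samples = 200, seed = 2))
  expect_equal(nrow(ptab), 24)   # 6 traits x {intercept, slope} x 2 responses
  expect_true(all(ptab$lo95 <= ptab$median_tau & ptab$median_tau <= ptab$hi95))
  expect_true(all(abs(c(ptab$lo95, ptab$hi95)) <= 1))

  stab <- sample_sizeclass_correlations(fit_h, ds$traits, ds$phylogeny,
                                        n_samples = 200, seed = 2)
  expect_equal(nrow(stab), 60)   # 10 reference diameters x 6 traits
  expect_equal(sort(unique(stab$reference_dbh_cm)), seq(1, 19, by = 2))

  ctab <- height_crown_coupling(fit_h, fit_c, ds$phylogeny,
                                n_samples = 200, seed = 2)
  expect_equal(nrow(ctab), 10)
  expect_type(ctab$excludes_zero, "logical")
})

test_that("resampled tau medians are stable across resampling seeds", {
  ds <- shared_dataset()
  fit <- shared_fit("height")
  t1 <- sample_parameter_correlations(fit, ds$traits, ds$phylogeny,
                                      n_samples = 4000, seed = 1)
  t2 <- sample_parameter_correlations(fit, ds$traits, ds$phylogeny,
                                      n_samples = 4000, seed = 999)
  expect_lt(max(abs(t1$median_tau - t2$median_tau)), 0.04)
})

test_that("stream mode uses each retained draw at most once", {
  fit <- shared_fit("height")
  ds <- shared_dataset()
  S <- nrow(fit$alpha)
  t1 <- sample_parameter_correlations(fit, ds$traits, ds$phylogeny,
                                      n_samples = S, seed = 1, mode = "stream")
  expect_equal(nrow(t1), 12)
  expect_error(
    sample_parameter_correlations(fit, ds$traits, ds$phylogeny,
                                  n_samples = S + 1, seed = 1, mode = "stream"),
    "stream")
})

test_that("coupled height and crown parameters give tau = 1 at every diameter", {
  tr <- simulate_phylogeny(9, seed = 6)
  sp <- tr$tip.label
  set.seed(3)
  alpha <- matrix(rnorm(5 * 9, 0.3, 0.1), 5, 9, dimnames = list(NULL, sp))
  beta <- matrix(0.75, 5, 9, dimnames = list(NULL, sp))
  dh <- make_draws(alpha, beta)
  # shifted log10 intercepts: crown curve proportional to the height curve,
  # so their contrasts are proportional and concordance is perfect
  dc <- make_draws(alpha - 0.6, beta, response = "crown_radius")
  tab <- height_crown_coupling(dh, dc, tr, n_samples = 50, seed = 1)
  expect_equal(tab$median_tau, rep(1, 10))

  dc2 <- dc
  dc2$species_order <- rev(dc2$species_order)
  expect_error(height_crown_coupling(dh, dc2, tr), "different species")
})
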
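test_that("Yule simulator produces valid ultrametric binary trees", {
  tr2 <- simulate_phylogeny(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  expect_equal(tr2$Nnode, 1)
  expect_equal(nrow(tr2$edge), 2)

  tr <- simulate_phylogeny(14, seed = 1)
  expect_equal(tr$Nnode, 13)
  expect_equal(nrow(tr$edge), 26)   # 2n - 2 edges in a rooted binary tree
  expect_true(ape::is.ultrametric(tr))
  expect_equal(sort(tr$tip.label), sprintf("SP%02d", 1:14))

  expect_identical(ape::write.tree(simulate_phylogeny(9, seed = 42)),
                   ape::write.tree(simulate_phylogeny(9, seed = 42)))
  expect_error(simulate_phylogeny(1), ">= 2")
})

test_that("BM trait simulation has the closed-form moments", {
  tr <- simulate_phylogeny(6, seed = 2)
  depth <- max(ape::node.depth.edgelength(tr))

  zero <- simulate_traits_bm(tr, c(x = 0), c(x = 5), seed = 1)
  expect_equal(zero$x, rep(5, 6))
  expect_error(simulate_traits_bm(tr, c(x = -1), c(x = 0)), ">= 0")

  # tip-value variance across replicates ~ rate * root depth
  rate <- 2
  tips <- vapply(1:1000, function(i) {
    simulate_traits_bm(tr, c(x = rate), c(x = 0), seed = 1000 + i)$x[1]
  }, numeric(1))
  v <- stats::var(tips)
  se <- v * sqrt(2 / (length(tips) - 1))
  expect_lt(abs(v - rate * depth), 3 * se)
})

test_that("standardized contrasts of simulated BM traits have variance ~ rate", {
  tr <- simulate_phylogeny(10, seed = 4)
  rate <- 1.5
  vars <- vapply(1:500, function(i) {
    x <- simulate_traits_bm(tr, c(x = rate), c(x = 0), seed = 5000 + i)$x
    names(x) <- tr$tip.label
    stats::var(compute_pics(tr, x)$contrasts)
  }, numeric(1))
  se <- stats::sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - rate), 3 * se)
})

test_that("allometric parameters follow the configured hyperdistribution", {
  tr <- simulate_phylogeny(5, seed = 1)
  traits <- simulate_traits_bm(tr, c(wd = 1), c(wd = 0), seed = 1)
  names(traits)[2] <- "wood_density"

  degen <- list(hyper_mean_alpha = 0.3, hyper_mean_beta = 0.75,
                sd_alpha = 0, sd_beta = 0, rho_alpha_beta = 0,
                residual_sd = 0.05, coupling = numeric(0))
  p <- simulate_allometric_params(traits, degen, seed = 1)
  expect_equal(p$alpha, rep(0.3, 5))
  expect_equal(p$beta, rep(0.75, 5))

  coupled <- degen
  coupled$coupling <- c(wood_density = 0.2)
  p2 <- simulate_allometric_params(traits, coupled, seed = 1)
  z <- as.numeric(scale(traits$wood_density))
  expect_equal(p2$alpha, 0.3 + 0.2 * z)

  # correlation between intercepts and slopes matches rho
  big <- data.frame(species = sprintf("S%05d", 1:10000),
                    wood_density = rnorm(10000))
  cfg <- list(hyper_mean_alpha = 0, hyper_mean_beta = 0, sd_alpha = 1,
              sd_beta = 1, rho_alpha_beta = 0.9, residual_sd = 0.05,
              coupling = numeric(0))
  p3 <- simulate_allometric_params(big, cfg, seed = 9)
  expect_lt(abs(stats::cor(p3$alpha, p3$beta) - 0.9), 0.02)
})

test_that("observation simulation reproduces the generating line", {
  cfg <- synthetic_config(seed = 3, n_species = 4, n_per_species = 30,
                          height = list(residual_sd = 0),
                          crown_radius = list(residual_sd = 0))
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$observations), 120)
  truth <- ds$true_params[ds$true_params$response == "height", ]
  for (sp in truth$species) {
    sub <- ds$observations[ds$observations$species == sp, ]
    fit <- stats::lm(log10(height_m) ~ log10(dbh_cm), data = sub)
    expect_equal(unname(coef(fit)[1]), truth$alpha[truth$species == sp],
                 tolerance = 1e-10)
    expect_equal(unname(coef(fit)[2]), truth$beta[truth$species == sp],
                 tolerance = 1e-10)
  }
})

test_that("log-scale residual spread matches the configured residual_sd", {
  cfg <- synthetic_config(seed = 8, n_species = 14, n_per_species = 360)
  ds <- generate_dataset(cfg)
  truth <- ds$true_params[ds$true_params$response == "height", ]
  idx <- match(ds$observations$species, truth$species)
  resid <- log10(ds$observations$height_m) -
    (truth$alpha[idx] + truth$beta[idx] * log10(ds$observations$dbh_cm))
  n <- length(resid)
  se <- 0.05 / sqrt(2 * (n - 1))
  expect_lt(abs(stats::sd(resid) - 0.05), 3 * se)
})

test_that("generated datasets are deterministic and self-consistent", {
  ds1 <- generate_dataset(synthetic_config(seed = 11))
  ds2 <- generate_dataset(synthetic_config(seed = 11))
  expect_identical(ape::write.tree(ds1$phylogeny), ape::write.tree(ds2$phylogeny))
  expect_identical(ds1$observations, ds2$observations)
  expect_identical(ds1$traits, ds2$traits)

  expect_equal(nrow(ds1$observations), 14 * 15)
  expect_setequal(ds1$traits$species, ds1$phylogeny$tip.label)
  expect_setequal(unique(ds1$observations$species), ds1$traits$species)
  expect_true(all(as.matrix(ds1$traits[, -1]) > 0))

  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(ds1, d1); write_dataset(ds2, d2)
  for (f in c("allometry.csv", "traits.csv", "tree.nwk", "true_params.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # written files pass the readers' validation and round-trip
  obs <- read_allometry_csv(file.path(d1, "allometry.csv"))
  expect_equal(obs$dbh_cm, ds1$observations$dbh_cm, tolerance = 1e-12)
  tt <- read_trait_csv(file.path(d1, "traits.csv"))
  expect_equal(tt$wood_density, ds1$traits$wood_density, tolerance = 1e-12)
  expect_s3_class(read_newick(file.path(d1, "tree.nwk")), "phylo")
})
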
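#' Summarise a distribution of Kendall tau values
#'
#' Median and equal-tailed 95% percentile interval (linear interpolation),
#' with a flag for whether the interval excludes zero.
#'
#' @param samples Numeric vector of tau values (length >= 1).
#' @return A list of class `tau_summary`: `median_tau`, `lo95`, `hi95`,
#'   `excludes_zero`.
#' @export
summarize_tau <- function(samples) {
  if (length(samples) < 1 || anyNA(samples)) stop("need at least 1 finite tau sample")
  qs <- stats::quantile(samples, c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(median_tau = qs[2], lo95 = qs[1], hi95 = qs[3],
                 excludes_zero = qs[1] > 0 || qs[3] < 0),
            class = "tau_summary")
}

draw_indices <- function(S, n_samples, seed, mode) {
  set.seed(seed)
  switch(mode,
    resample = sample.int(S, n_samples, replace = TRUE),
    stream = {
      if (S < n_samples) stop("mode = 'stream' needs at least n_samples retained draws")
      sample.int(S, n_samples, replace = FALSE)
    },
    stop("unknown sampling mode: ", mode))
}

align_comparative_inputs <- function(draws, traits, tree) {
  sp <- draws$species_order
  missing_tr <- setdiff(sp, traits$species)
  if (length(missing_tr)) stop("species missing from trait table: ", paste(missing_tr, collapse = ", "))
  missing_tip <- setdiff(sp, tree$tip.label)
  if (length(missing_tip)) stop("species missing from phylogeny: ", paste(missing_tip, collapse = ", "))
  if (length(setdiff(tree$tip.label, sp))) {
    tree <- ape::keep.tip(tree, sp)
  }
  pm <- pic_matrix(tree)
  list(pm = pm, traits = traits[match(sp, traits$species), , drop = FALSE])
}

# contrasts of every row of a draws x species matrix (species in
# species_order), via the precomputed linear contrast map
bulk_contrasts <- function(pm, mat, species_order) {
  mat %*% t(pm$L[, species_order, drop = FALSE])
}

row_taus <- function(cmat, target_contrasts) {
  apply(cmat, 1, function(cc) kendall_tau(cc, target_contrasts))
}

#' Posterior-propagated correlations between traits and allometric
#' parameters
#'
#' For each of `n_samples` posterior draws (resampled uniformly with
#' replacement by default), the species vector of intercepts (and/or
#' slopes) is contrasted on the phylogeny and rank-correlated (tau-b)
#' with each trait's contrasts; the `n_samples` tau values per
#' trait-parameter pair are summarised as median and equal-tailed 95%
#' interval. Traits enter as fixed species means (no trait uncertainty).
#'
#' @param draws An `allo_draws` object.
#' @param traits A `trait_table` covering the fitted species.
#' @param tree A rooted binary `phylo` whose tip set includes the fitted
#'   species (extra tips are pruned).
#' @param n_samples Number of posterior samples of tau (default 10,000).
#' @param seed Integer seed for the resampling.
#' @param targets Which parameters to correlate.
#' @param traits_use Trait columns to use (default all non-species
#'   columns).
#' @param mode `"resample"` (with replacement, default) or `"stream"`
#'   (each retained draw at most once; requires enough draws).
#' @param log10_traits Contrast log10-transformed trait values instead of
#'   raw species means.
#' @return A `correlation_table` data frame: `trait`, `target`,
#'   `response`, `median_tau`, `lo95`, `hi95`, `excludes_zero`.
#' @export
sample_parameter_correlations <- function(draws, traits, tree,
                                          n_samples = 10000, seed = 1L,
                                          targets = c("intercept", "slope"),
                                          traits_use = NULL,
                                          mode = c("resample", "stream"),
                                          log10_traits = FALSE) {
  stopifnot(inherits(draws, "allo_draws"))
  mode <- match.arg(mode)
  targets <- match.arg(targets, several.ok = TRUE)
  al <- align_comparative_inputs(draws, traits, tree)
  if (is.null(traits_use)) traits_use <- setdiff(names(al$traits), "species")
  idx <- draw_indices(nrow(draws$alpha), n_samples, seed, mode)
  sp <- draws$species_order
  tc <- trait_contrasts(al, traits_use, log10_traits)
  out <- list()
  for (tg in targets) {
    mat <- if (tg == "intercept") draws$alpha else draws$beta
    cmat <- bulk_contrasts(al$pm, mat[idx, , drop = FALSE], sp)
    for (tr in traits_use) {
      ts <- summarize_tau(row_taus(cmat, tc[[tr]]))
      out[[length(out) + 1L]] <- data.frame(
        trait = tr, target = tg, response = draws$spec$response,
        median_tau = ts$median_tau, lo95 = ts$lo95, hi95 = ts$hi95,
        excludes_zero = ts$excludes_zero, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out), class = c("correlation_table", "data.frame"))
}

trait_contrasts <- function(al, traits_use, log10_traits) {
  sapply(traits_use, function(tr) {
    v <- al$traits[[tr]]
    if (log10_traits) {
      if (any(v <= 0)) stop("log10_traits requires strictly positive trait values (", tr, ")")
      v <- log10(v)
    }
    names(v) <- al$traits$species
    contrasts_from_matrix(al$pm, v, tr)$contrasts
  }, simplify = FALSE)
}

#' Trait correlations with expected tree dimensions across reference
#' diameters
#'
#' Per resampled posterior draw and per reference DBH, the species vector
#' of expected dimensions (mean curve, natural units) is contrasted and
#' rank-correlated with each trait's contrasts, then summarised per
#' (trait, reference DBH).
#'
#' @inheritParams sample_parameter_correlations
#' @param reference_dbhs Reference diameters in cm (default 1, 3, ..., 19).
#' @return A `correlation_table` data frame with an additional
#'   `reference_dbh_cm` column.
#' @export
sample_sizeclass_correlations <- function(draws, traits, tree,
                                          reference_dbhs = seq(1, 19, by = 2),
                                          n_samples = 10000, seed = 1L,
                                          traits_use = NULL,
                                          mode = c("resample", "stream"),
                                          log10_traits = FALSE) {
  stopifnot(inherits(draws, "allo_draws"))
  if (any(reference_dbhs <= 0)) stop("reference diameters must be positive")
  mode <- match.arg(mode)
  al <- align_comparative_inputs(draws, traits, tree)
  if (is.null(traits_use)) traits_use <- setdiff(names(al$traits), "species")
  idx <- draw_indices(nrow(draws$alpha), n_samples, seed, mode)
  sp <- draws$species_order
  tc <- trait_contrasts(al, traits_use, log10_traits)
  sub <- draws
  sub$alpha <- draws$alpha[idx, , drop = FALSE]
  sub$beta <- draws$beta[idx, , drop = FALSE]
  out <- list()
  for (d in reference_dbhs) {
    pred <- predict_at_diameter(sub, d)
    cmat <- bulk_contrasts(al$pm, pred, sp)
    for (tr in traits_use) {
      ts <- summarize_tau(row_taus(cmat, tc[[tr]]))
      out[[length(out) + 1L]] <- data.frame(
        trait = tr, target = paste0("expected_", draws$spec$response),
        response = draws$spec$response, reference_dbh_cm = d,
        median_tau = ts$median_tau, lo95 = ts$lo95, hi95 = ts$hi95,
        excludes_zero = ts$excludes_zero, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out), class = c("correlation_table", "data.frame"))
}

#' Correlation between expected height and crown radius across reference
#' diameters
#'
#' Per resampled draw pair and reference DBH, the expected heights and
#' expected crown radii of the species are contrasted and
#' rank-correlated. The two models are fit independently, so the pairing
#' of their draws is arbitrary; by default draws are paired by resampled
#' index (same seed sequence for both posteriors), with
#' `pairing = "independent"` for independent resampling.
#'
#' @param draws_height,draws_crown `allo_draws` for the two responses,
#'   over the same species.
#' @inheritParams sample_sizeclass_correlations
#' @param pairing `"paired"` (default) or `"independent"`.
#' @return A `correlation_table` data frame, one row per reference DBH.
#' @export
height_crown_coupling <- function(draws_height, draws_crown, tree,
                                  reference_dbhs = seq(1, 19, by = 2),
                                  n_samples = 10000, seed = 1L,
                                  pairing = c("paired", "independent")) {
  stopifnot(inherits(draws_height, "allo_draws"), inherits(draws_crown, "allo_draws"))
  pairing <- match.arg(pairing)
  if (!identical(draws_height$species_order, draws_crown$species_order)) {
    stop("height and crown posteriors cover different species")
  }
  if (any(reference_dbhs <= 0)) stop("reference diameters must be positive")
  sp <- draws_height$species_order
  missing_tip <- setdiff(sp, tree$tip.label)
  if (length(missing_tip)) stop("species missing from phylogeny: ", paste(missing_tip, collapse = ", "))
  if (length(setdiff(tree$tip.label, sp))) tree <- ape::keep.tip(tree, sp)
  pm <- pic_matrix(tree)
  idx_h <- draw_indices(nrow(draws_height$alpha), n_samples, seed, "resample")
  idx_c <- if (pairing == "paired" &&
               nrow(draws_height$alpha) == nrow(draws_crown$alpha)) {
    idx_h
  } else {
    draw_indices(nrow(draws_crown$alpha),
                 n_samples, seed + if (pairing == "paired") 0L else 1L,
                 "resample")
  }
  sub_h <- draws_height
  sub_h$alpha <- draws_height$alpha[idx_h, , drop = FALSE]
  sub_h$beta <- draws_height$beta[idx_h, , drop = FALSE]
  sub_c <- draws_crown
  sub_c$alpha <- draws_crown$alpha[idx_c, , drop = FALSE]
  sub_c$beta <- draws_crown$beta[idx_c, , drop = FALSE]
  out <- list()
  for (d in reference_dbhs) {
    ch <- bulk_contrasts(pm, predict_at_diameter(sub_h, d), sp)
    cc <- bulk_contrasts(pm, predict_at_diameter(sub_c, d), sp)
    taus <- vapply(seq_len(nrow(ch)), function(i) kendall_tau(ch[i, ], cc[i, ]),
                   numeric(1))
    ts <- summarize_tau(taus)
    out[[length(out) + 1L]] <- data.frame(
      trait = NA_character_, target = "height_crown_coupling",
      response = "height_vs_crown_radius", reference_dbh_cm = d,
      median_tau = ts$median_tau, lo95 = ts$lo95, hi95 = ts$hi95,
      excludes_zero = ts$excludes_zero, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("correlation_table", "data.frame"))
}
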
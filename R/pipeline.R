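#' Noisy task descriptor from ground-truth task mixtures
#'
#' Emulates the minute-sampling descriptor: per alive bee-day, `n_samples`
#' area memberships are drawn from the bee's latent task mixture and the
#' counts normalized to fractions. With `noisy = FALSE` the exact mixture
#' is returned.
#'
#' @param ground_truth a `colony_ground_truth`.
#' @param config the generating [colony_config()] (for the seed).
#' @param n_samples multinomial sample size per bee-day.
#' @param noisy draw multinomial counts (default) or return exact mixtures.
#' @return task-descriptor data frame (`bee_id`, `day`, `frac_*`,
#'   `n_samples`).
#' @export
ground_truth_task_descriptor <- function(ground_truth, config,
                                         n_samples = 200, noisy = TRUE) {
  roles <- ground_truth$roles
  mix <- as.matrix(roles[, c("m_brood", "m_dance_floor", "m_honey", "m_exit")])
  fr <- if (noisy) {
    with_seed(config$seed + 4L, {
      t(apply(mix, 1, function(p) stats::rmultinom(1, n_samples, p)[, 1] / n_samples))
    })
  } else {
    mix
  }
  data.frame(bee_id = roles$bee_id, day = roles$day,
             frac_brood = fr[, 1], frac_dance_floor = fr[, 2],
             frac_honey = fr[, 3], frac_exit = fr[, 4],
             n_samples = n_samples, stringsAsFactors = FALSE)
}

#' Biological-age table from ground truth
#' @param ground_truth a `colony_ground_truth`.
#' @return data frame `bee_id`, `day`, `age`.
#' @export
ground_truth_bio_age <- function(ground_truth) {
  roles <- ground_truth$roles
  data.frame(bee_id = roles$bee_id, day = roles$day, age = roles$age,
             stringsAsFactors = FALSE)
}

#' Run the network-age pipeline on a synthetic colony
#'
#' Ground truth, daily multimodal affinity matrices, rank transform,
#' spectral/bispectral embeddings with sign alignment, factor assembly,
#' CCA against the task descriptor, per-day robust scaling and
#' directionality orientation — end to end.
#'
#' @param config a [colony_config()].
#' @param n_dims embedding dimensions per mode set.
#' @param k CCA projection dimensions.
#' @param modes affinity modes to simulate.
#' @param descriptor_n_samples multinomial sample size of the descriptor.
#' @param keep_affinities retain the affinity matrices in the result.
#' @return list with `config`, `ground_truth`, `factors`, `descriptors`,
#'   `bio_age`, `map`, `series` (and `affinities` if kept).
#' @export
run_colony_pipeline <- function(config, n_dims = 8, k = 3,
                                modes = c("proximity_count",
                                          "trophallaxis_count",
                                          "distance_gaussian",
                                          "distance_max_minus",
                                          "effect_mean_pos",
                                          "effect_mean_neg",
                                          "effect_cum_pos",
                                          "effect_cum_neg"),
                                descriptor_n_samples = 200,
                                keep_affinities = FALSE) {
  gt <- simulate_ground_truth(config)
  aff <- simulate_affinity_timeseries(gt, config, modes = modes)
  factors <- compute_daily_factors(aff, n_dims = n_dims)
  descriptors <- ground_truth_task_descriptor(gt, config,
                                              n_samples = descriptor_n_samples)
  bio_age <- ground_truth_bio_age(gt)
  na <- network_age(factors, descriptors, bio_age, variant = "cca_task", k = k)
  out <- list(config = config, ground_truth = gt, factors = factors,
              descriptors = descriptors, bio_age = bio_age,
              map = na$map, series = na$series)
  if (keep_affinities) out$affinities <- aff
  out
}

#' Write a network-age series as tidy CSV
#' @param series a `network_age_series`.
#' @param path output file.
#' @export
write_network_age_csv <- function(series, path) {
  df <- as.data.frame(series)
  cols <- intersect(c("bee_id", "day", "network_age", "na_dim2", "na_dim3"),
                    colnames(df))
  utils::write.csv(df[, cols], path, row.names = FALSE)
}
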
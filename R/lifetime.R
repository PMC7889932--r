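#' Otsu's threshold
#'
#' Threshold maximizing the between-class variance of a two-class split,
#' used to separate the strongly bimodal distribution of per-id detection
#' counts (real bees vs erroneously decoded tags). Candidate thresholds are
#' the midpoints between consecutive sorted unique values, so the search is
#' exhaustive and deterministic.
#'
#' @param values nonnegative numeric sample with at least 2 distinct values.
#' @return the threshold; values strictly below it form the lower class.
#' @export
otsu_threshold <- function(values) {
  u <- sort(unique(values))
  if (length(u) < 2) stop("otsu_threshold needs at least 2 distinct values")
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf
  best_t <- cand[1]
  n <- length(values)
  for (t in cand) {
    lo <- values < t
    w1 <- mean(lo)
    w2 <- 1 - w1
    if (w1 == 0 || w2 == 0) next
    bc <- w1 * w2 * (mean(values[lo]) - mean(values[!lo]))^2
    if (bc > best) {
      best <- bc
      best_t <- t
    }
  }
  best_t
}

#' Filter a detection table
#'
#' Drops rows below the decoding-confidence threshold, ids whose total
#' detection count falls below a count threshold (computed with Otsu's
#' method when not supplied - erroneously decoded tags form a low-count
#' mode), and rows detected before the id's introduction day.
#'
#' @param detections detection table.
#' @param confidence_min minimum decoding confidence.
#' @param id_count_threshold count threshold; `NULL` (default) computes it
#'   with [otsu_threshold()] on per-id totals.
#' @param introduction optional data frame `bee_id`, `day` of introduction
#'   dates; detections before the introduction day are implausible.
#' @return the filtered detection table.
#' @export
filter_detections <- function(detections, confidence_min = 0.5,
                              id_count_threshold = NULL,
                              introduction = NULL) {
  det <- detections[detections$confidence >= confidence_min, , drop = FALSE]
  counts <- table(det$bee_id)
  if (is.null(id_count_threshold)) {
    id_count_threshold <- if (length(unique(as.numeric(counts))) >= 2) {
      otsu_threshold(as.numeric(counts))
    } else {
      0
    }
  }
  keep_ids <- names(counts)[as.numeric(counts) >= id_count_threshold]
  det <- det[det$bee_id %in% keep_ids, , drop = FALSE]
  if (!is.null(introduction)) {
    intro_day <- introduction$day[match(det$bee_id, introduction$bee_id)]
    det <- det[is.na(intro_day) | det$day >= intro_day, , drop = FALSE]
  }
  if (nrow(det) == 0) warning("all detections filtered out")
  rownames(det) <- NULL
  det
}

#' Configuration of the Bayesian changepoint lifetime model
#'
#' A bee is alive on days `[e, e + l)`. Daily observations are indicators
#' that the normalized detection count reaches a threshold `t`; while alive
#' the indicator is Bernoulli with probability `p`, afterwards with
#' probability `1 - p`. Priors: `l ~ Normal(35, sd 50)` truncated to
#' `l > 0` (weakly informative lifespan scale), `p ~ Beta(5, 1)` (alive
#' bees are detected often), `t ~ Beta(1, 25)` (informative: dead bees have
#' very few detections, so the threshold sits just above the
#' false-positive floor). The default backend enumerates the posterior over
#' integer `l`, integrating `p` in closed form and `t` piecewise-exactly;
#' the MCMC backend samples `(l, p, t)` with a random-walk
#' Metropolis-Hastings sampler (2000 tuning + 1000 kept draws).
#'
#' @param l_prior_mean,l_prior_sd prior mean and standard deviation of the
#'   number of alive days.
#' @param p_prior,t_prior Beta shape pairs for detection probability and
#'   threshold.
#' @param n_tune,n_keep MCMC tuning and kept sample counts.
#' @param l_max_extra days past the last observation included in the
#'   enumeration grid (lets the censoring tail follow the prior).
#' @return object of class `lifetime_config`.
#' @export
lifetime_config <- function(l_prior_mean = 35, l_prior_sd = 50,
                            p_prior = c(5, 1), t_prior = c(1, 25),
                            n_tune = 2000, n_keep = 1000,
                            l_max_extra = 150) {
  stopifnot(l_prior_sd > 0, all(p_prior > 0), all(t_prior > 0), n_keep >= 1)
  structure(list(l_prior_mean = l_prior_mean, l_prior_sd = l_prior_sd,
                 p_prior = p_prior, t_prior = t_prior,
                 n_tune = n_tune, n_keep = n_keep, l_max_extra = l_max_extra),
            class = "lifetime_config")
}

#' Estimate a bee's death day with the changepoint model
#'
#' Counts are first normalized to \[0, 1\] by the bee's maximum daily
#' count. The reported death day is `e` plus the posterior mean of the
#' alive-days parameter `l`. If the counts never collapse, the posterior
#' concentrates beyond the censoring boundary and the estimate exceeds the
#' last observed day.
#'
#' @param daily_counts data frame `day`, `count` (or a vector named by day)
#'   of the bee's daily detection counts.
#' @param e emergence day.
#' @param config a [lifetime_config()].
#' @param backend `"grid"` (exact enumeration, deterministic; default) or
#'   `"mcmc"` (Metropolis-Hastings).
#' @param seed RNG seed for the MCMC backend.
#' @return object of class `lifetime_record`: `emergence_day`, `death_day`,
#'   `l_mean`, `posterior` (grid: data frame `l`, `prob`; mcmc: kept `l`
#'   samples), `flag` (`"ok"` or `"degenerate"`).
#' @export
estimate_death_day <- function(daily_counts, e,
                               config = lifetime_config(),
                               backend = c("grid", "mcmc"), seed = 1) {
  backend <- match.arg(backend)
  if (is.data.frame(daily_counts)) {
    days <- daily_counts$day
    counts <- daily_counts$count
  } else {
    days <- as.numeric(names(daily_counts))
    counts <- as.numeric(daily_counts)
  }
  ord <- order(days)
  days <- days[ord]
  counts <- counts[ord]
  if (all(counts == 0)) {
    return(structure(list(emergence_day = e, death_day = e, l_mean = 0,
                          posterior = NULL, flag = "degenerate"),
                     class = "lifetime_record"))
  }
  cn <- counts / max(counts)
  if (backend == "grid") {
    post <- changepoint_grid_posterior(cn, days, e, config)
    l_mean <- sum(post$l * post$prob)
    rec <- list(emergence_day = e, death_day = e + l_mean, l_mean = l_mean,
                posterior = post, flag = "ok")
  } else {
    samples <- with_seed(seed, changepoint_mh(cn, days, e, config))
    # day-resolution convention shared with the enumeration backend:
    # continuous l in (k - 1, k] keeps the same days alive as integer l = k
    l_mean <- mean(ceiling(samples$l))
    rec <- list(emergence_day = e, death_day = e + l_mean, l_mean = l_mean,
                posterior = samples, flag = "ok")
  }
  structure(rec, class = "lifetime_record")
}

# Exact posterior over integer l: p integrated analytically under its Beta
# prior, t integrated exactly over the segments of (0, 1] on which the
# threshold indicators are constant (piecewise-constant likelihood in t).
changepoint_grid_posterior <- function(cn, days, e, config) {
  l_grid <- seq_len(max(days) - e + config$l_max_extra)
  l_grid <- l_grid[l_grid >= 1]
  log_prior_l <- stats::dnorm(l_grid, config$l_prior_mean, config$l_prior_sd,
                              log = TRUE)
  a0 <- config$p_prior[1]
  b0 <- config$p_prior[2]
  tb <- config$t_prior
  # t segments: breakpoints at the distinct normalized counts in (0, 1]
  br <- sort(unique(c(0, cn[cn > 0], 1)))
  seg_lo <- br[-length(br)]
  seg_hi <- br[-1]
  seg_w <- stats::pbeta(seg_hi, tb[1], tb[2]) - stats::pbeta(seg_lo, tb[1], tb[2])
  # per segment: indicator y_i = (cn_i >= t) for t in (lo, hi] <=> cn_i >= hi
  y_seg <- lapply(seg_hi, function(h) cn >= h)
  log_lik <- vapply(l_grid, function(l) {
    alive <- days >= e & days < e + l
    seg_ll <- vapply(seq_along(seg_hi), function(s) {
      y <- y_seg[[s]]
      succ <- sum((alive & y) | (!alive & !y))
      fail <- length(y) - succ
      lbeta(a0 + succ, b0 + fail) - lbeta(a0, b0)
    }, numeric(1))
    m <- max(seg_ll)
    m + log(sum(seg_w * exp(seg_ll - m)))
  }, numeric(1))
  lp <- log_prior_l + log_lik
  w <- exp(lp - max(lp))
  data.frame(l = l_grid, prob = w / sum(w))
}

changepoint_mh <- function(cn, days, e, config) {
  a0 <- config$p_prior[1]; b0 <- config$p_prior[2]
  ta <- config$t_prior[1]; tb <- config$t_prior[2]
  log_lik <- function(l, p, t) {
    if (l <= 0 || p <= 0 || p >= 1 || t <= 0 || t >= 1) return(-Inf)
    alive <- days >= e & days < e + l
    y <- cn >= t
    pr <- ifelse(alive, p, 1 - p)
    sum(log(ifelse(y, pr, 1 - pr)))
  }
  log_prior <- function(l, p, t) {
    stats::dnorm(l, config$l_prior_mean, config$l_prior_sd, log = TRUE) +
      stats::dbeta(p, a0, b0, log = TRUE) +
      stats::dbeta(t, ta, tb, log = TRUE)
  }
  # mixture of two reversible kernels: a local kernel (random walk on l,
  # logit walks on p and t) and an independence kernel that redraws (l, t)
  # jointly from their priors, letting the chain cross between the
  # changepoint mode and the censored tail (which live in different t
  # regions). Each kernel applies its own acceptance rule.
  n_iter <- config$n_tune + config$n_keep
  l <- max(sum(cn >= 0.5 & days >= e), 1)
  p <- 0.9; t <- 0.5
  keep_l <- numeric(config$n_keep)
  step_l <- 1.5; step_z <- 0.5; mix_w <- 0.2
  logit <- function(x) log(x / (1 - x))
  for (it in seq_len(n_iter)) {
    zp <- logit(p) + stats::rnorm(1, 0, step_z)
    p_new <- stats::plogis(zp)
    if (stats::runif(1) < mix_w) {
      # independence kernel: prior terms for (l, t) cancel with the proposal
      l_new <- rtruncnorm_lower(1, config$l_prior_mean, config$l_prior_sd, 0)
      t_new <- stats::rbeta(1, ta, tb)
      log_ratio <- (log_lik(l_new, p_new, t_new) +
                      stats::dbeta(p_new, a0, b0, log = TRUE) +
                      log(p_new * (1 - p_new))) -
        (log_lik(l, p, t) +
           stats::dbeta(p, a0, b0, log = TRUE) + log(p * (1 - p)))
    } else {
      l_new <- l + stats::rnorm(1, 0, step_l)
      zt <- logit(t) + stats::rnorm(1, 0, step_z)
      t_new <- stats::plogis(zt)
      log_ratio <- (log_lik(l_new, p_new, t_new) +
                      log_prior(l_new, p_new, t_new) +
                      log(p_new * (1 - p_new)) + log(t_new * (1 - t_new))) -
        (log_lik(l, p, t) + log_prior(l, p, t) +
           log(p * (1 - p)) + log(t * (1 - t)))
    }
    if (is.finite(log_ratio) && log(stats::runif(1)) < log_ratio) {
      l <- l_new; p <- p_new; t <- t_new
    }
    if (it > config$n_tune) keep_l[it - config$n_tune] <- l
  }
  list(l = keep_l)
}

#' Estimate lifetimes for a table of bees
#'
#' @param counts data frame `bee_id`, `day`, `count`.
#' @param emergence data frame `bee_id`, `day` (emergence days).
#' @param config a [lifetime_config()].
#' @param backend,seed passed to [estimate_death_day()].
#' @return data frame `bee_id`, `emergence_day`, `death_day`, `flag`.
#' @export
estimate_lifetimes <- function(counts, emergence,
                               config = lifetime_config(),
                               backend = "grid", seed = 1) {
  ids <- unique(counts$bee_id)
  recs <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    e <- emergence$day[match(id, emergence$bee_id)]
    rec <- estimate_death_day(counts[counts$bee_id == id, c("day", "count")],
                              e, config, backend, seed = seed + i)
    data.frame(bee_id = id, emergence_day = rec$emergence_day,
               death_day = rec$death_day, flag = rec$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Bees alive on a given day
#'
#' A bee is alive on `[emergence_day, death_day)`.
#' @param lifetimes data frame from [estimate_lifetimes()] (or ground-truth
#'   columns `bee_id`, `emergence_day`, `death_day`).
#' @param day focal day.
#' @return character vector of bee ids.
#' @export
alive_on <- function(lifetimes, day) {
  lifetimes$bee_id[lifetimes$emergence_day <= day & day < lifetimes$death_day]
}
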
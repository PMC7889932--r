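# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the default study colony: 200 bees, 25 days, heterogeneous transitions
default_pipeline <- function() {
  cached_fixture("default_pipeline",
                 run_colony_pipeline(colony_config(seed = 1)))
}

# all bees transition at (nearly) the same day-of-life: biological age is
# then an almost perfect proxy for the latent role
homogeneous_pipeline <- function() {
  cached_fixture("homogeneous_pipeline", run_colony_pipeline(colony_config(
    seed = 2,
    cluster_probs = c(early = 1, late = 0, none = 0),
    transition_day_means = list(early = c(mean = 16, sd = 0.5),
                                late = c(mean = 21, sd = 2),
                                none = c(mean = Inf, sd = 0))
  )))
}

# lifetime test set: emergence inside the window, long window so most bees
# die well before the censoring boundary; false-positive floor 2/day
# (2% of the 100/day alive mean)
lifetime_fixture <- function() {
  cached_fixture("lifetime_fixture", {
    cfg <- colony_config(
      n_bees = 100, n_days = 90, seed = 5,
      emergence_schedule = data.frame(day = c(1, 3, 5, 7, 9), n = 20),
      detection_noise = list(rate = 2, conf_shape1 = 1, conf_shape2 = 8))
    gt <- simulate_ground_truth(cfg)
    counts <- simulate_detection_counts(gt, cfg, alive_mean = 100)
    list(config = cfg, ground_truth = gt, counts = counts,
         emergence = data.frame(bee_id = gt$bees$bee_id,
                                day = gt$bees$emergence_day))
  })
}

# small colony for generator-level checks
tiny_config <- function(seed = 11, ...) {
  colony_config(n_bees = 24, n_days = 6, bursts_per_day = 60, seed = seed,
                emergence_schedule = data.frame(day = c(-3, 1), n = 12), ...)
}

# rank-based AUROC
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# dense oracle for the spectral embedding: smallest nontrivial eigenvectors
# of the symmetric normalized Laplacian I - D^{-1/2} A D^{-1/2}
laplacian_oracle <- function(m, n_dims = 8, epsilon = 1e-8) {
  A <- unclass(m)
  attributes(A) <- list(dim = dim(m))
  A <- A + epsilon
  diag(A) <- 0
  dsq <- 1 / sqrt(rowSums(A))
  L <- diag(nrow(A)) - A * (dsq %o% dsq)
  eig <- eigen(L, symmetric = TRUE)
  ord <- order(eig$values) # ascending: skip the trivial zero eigenvalue
  eig$vectors[, ord[2:(n_dims + 1)], drop = FALSE]
}

expect_equal_up_to_sign <- function(got, want, tol = 1e-8) {
  for (k in seq_len(ncol(want))) {
    d1 <- max(abs(got[, k] - want[, k]))
    d2 <- max(abs(got[, k] + want[, k]))
    expect_lt(min(d1, d2), tol)
  }
}

two_clique_affinity <- function(n = 20, seed = 5) {
  set.seed(seed)
  half <- n / 2
  a <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      same <- (i <= half) == (j <= half)
      a[i, j] <- a[j, i] <- if (same) runif(1, 0.8, 1.2) else 0
    }
  }
  affinity_matrix(a, sprintf("b%02d", 1:n), 1, "proximity_count", TRUE)
}

# random symmetric nonnegative affinity matrix
random_affinity <- function(n, day = 1, mode = "proximity_count", seed = 1) {
  set.seed(seed)
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- rpois(sum(ut), 4) * runif(sum(ut))
  a <- a + t(a)
  affinity_matrix(a, sprintf("b%02d", seq_len(n)), day, mode, symmetric = TRUE)
}
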
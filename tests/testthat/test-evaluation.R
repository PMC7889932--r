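desc_cols <- c("frac_brood", "frac_dance_floor", "frac_honey", "frac_exit")

softmax_rows <- function(eta) {
  e <- exp(eta - apply(eta, 1, max))
  e / rowSums(e)
}

simulated_task_data <- function(n = 800, noise = 0, seed = 40) {
  set.seed(seed)
  x <- runif(n, -2, 2)
  eta <- cbind(1.5 * x, -1.5 * x, 0.5 * x, 0)
  P <- softmax_rows(eta + matrix(rnorm(n * 4, 0, noise), n, 4))
  df <- data.frame(bee_id = sprintf("b%04d", 1:n), day = 1, feat = x)
  desc <- cbind(df[, 1:2], as.data.frame(P))
  colnames(desc)[3:6] <- desc_cols
  desc$n_samples <- 50
  list(features = df, descriptor = desc)
}

test_that("McFadden's pseudo R-squared follows its definition", {
  expect_equal(mcfadden_r2(-50, -100), 0.5)
  # an uninformative (constant) feature scores ~0
  d <- simulated_task_data(400, noise = 1)
  d$features$feat <- 1
  fit <- fit_task_model(d$features, d$descriptor)
  expect_lt(abs(fit$r2), 1e-6)
  expect_lte(fit$r2, 1)
})

test_that("a softmax-generated descriptor is recovered increasingly well as noise falls", {
  noisy <- fit_task_model(simulated_task_data(800, 2)$features,
                          simulated_task_data(800, 2)$descriptor)
  clean <- fit_task_model(simulated_task_data(800, 0)$features,
                          simulated_task_data(800, 0)$descriptor)
  expect_gt(clean$r2, noisy$r2)
  # fractional responses keep conditional entropy in the likelihood, so
  # even a perfect fit stays well below 1 at these effect sizes
  expect_gt(clean$r2, 0.25)
  # nested-model property: ll1 never below ll0
  expect_gte(clean$ll1, clean$ll0)
  expect_gte(noisy$ll1, noisy$ll0)
})

test_that("the weighted softmax GLM matches nnet::multinom on integer counts", {
  skip_if_not_installed("nnet")
  set.seed(41)
  n <- 300
  x <- runif(n, -2, 2)
  P <- softmax_rows(cbind(x, -x, 0.3 * x, 0))
  counts <- t(vapply(seq_len(n), function(i) rmultinom(1, 40, P[i, ])[, 1],
                     numeric(4)))
  feats <- data.frame(bee_id = sprintf("b%03d", 1:n), day = 1, feat = x)
  desc <- cbind(feats[, 1:2], as.data.frame(counts / 40))
  colnames(desc)[3:6] <- desc_cols
  desc$n_samples <- 40
  fit <- fit_task_model(feats, desc)
  ref <- nnet::multinom(counts ~ x, trace = FALSE, reltol = 1e-12)
  ll_ref <- -ref$value # nnet reports the negative log-likelihood
  # remove the multinomial coefficient (constant across models) by
  # comparing fitted cell probabilities instead of raw likelihoods
  pred <- predict_task_model(fit, feats)
  pred_ref <- predict(ref, newdata = data.frame(x = x), type = "probs")
  expect_lt(max(abs(pred - pred_ref)), 1e-4)
})

test_that("binomial per-area fits agree with stats::glm", {
  set.seed(42)
  n <- 300
  x <- runif(n, -2, 2)
  p1 <- plogis(0.5 + 1.2 * x)
  y1 <- rbinom(n, 30, p1) / 30
  feats <- data.frame(bee_id = sprintf("b%03d", 1:n), day = 1, feat = x)
  desc <- cbind(feats[, 1:2],
                data.frame(frac_brood = y1, frac_dance_floor = (1 - y1) / 3,
                           frac_honey = (1 - y1) / 3, frac_exit = (1 - y1) / 3))
  desc$n_samples <- 30
  fit <- fit_task_model(feats, desc, family = "binomial_per_area")
  ref <- suppressWarnings(glm(y1 ~ x, family = binomial(), weights = rep(30, n)))
  expect_equal(unname(fit$params[[1]]), unname(coef(ref)), tolerance = 1e-5)
})

test_that("the likelihood-ratio test matches an integral oracle", {
  # chi-squared upper-tail oracle by numerical integration of the density
  oracle_p <- function(lr, df) {
    stats::integrate(function(u) stats::dchisq(u, df), lr, Inf,
                     rel.tol = 1e-12)$value
  }
  lrt <- likelihood_ratio_test(-100, -100 + 3.8415 / 2, df = 1)
  expect_equal(lrt$statistic, 3.8415)
  expect_lt(abs(lrt$p_value - oracle_p(3.8415, 1)), 1e-9)
  expect_lt(abs(lrt$p_value - 0.05), 1e-3)

  expect_equal(likelihood_ratio_test(-10, -10, df = 4)$p_value, 1)
  expect_equal(likelihood_ratio_test(-10, -10, df = 1)$statistic, 0)
  expect_error(likelihood_ratio_test(-10, -11, df = 1), "nested")

  lrt4 <- likelihood_ratio_test(-80, -70, df = 4)
  expect_lt(abs(lrt4$p_value - oracle_p(20, 4)), 1e-9)
})

test_that("bootstrap CIs are reproducible, centred, and percentile-exact", {
  d <- simulated_task_data(400, noise = 1)
  feats_b <- d$features
  names(feats_b)[3] <- "featb"
  ci1 <- bootstrap_effect_ci(d$features, feats_b, d$descriptor,
                             n_boot = 32, seed = 5)
  ci2 <- bootstrap_effect_ci(d$features, feats_b, d$descriptor,
                             n_boot = 32, seed = 5)
  expect_identical(ci1, ci2) # fixed seed, identical CIs
  # identical features: the paired difference is exactly zero
  expect_true(all(abs(ci1$differences) < 1e-8))
  expect_gte(ci1$ci[2], 0)
  expect_lte(ci1$ci[1], 0)
  # CI bounds are the type-7 percentile order statistics of the replicates
  expect_equal(ci1$ci,
               unname(quantile(ci1$differences, c(0.025, 0.975), type = 7)))
  expect_error(bootstrap_effect_ci(d$features, feats_b, d$descriptor,
                                   n_boot = 1), "n_boot")
})

test_that("adding an informative feature never lowers the optimum likelihood", {
  d <- simulated_task_data(500, noise = 1, seed = 44)
  base <- d$features
  set.seed(45)
  both <- base
  both$extra <- base$feat + rnorm(500, 0, 0.5)
  fit1 <- fit_task_model(base, d$descriptor)
  fit2 <- fit_task_model(both, d$descriptor)
  expect_gte(fit2$ll1, fit1$ll1 - 1e-6)
  lrt <- likelihood_ratio_test(fit1$ll1, fit2$ll1, df = 3)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
})

test_that("the small tanh network matches the GLM on linear data and beats it on nonlinear data", {
  lin <- simulated_task_data(600, noise = 0.5, seed = 46)
  glm_lin <- fit_task_model(lin$features, lin$descriptor)
  nn_lin <- fit_task_model(lin$features, lin$descriptor,
                           model_class = "small_nn")
  expect_lt(abs(nn_lin$r2 - glm_lin$r2), 0.05)

  # nonlinear: the composition depends on |x|, invisible to a linear GLM
  set.seed(47)
  n <- 600
  x <- runif(n, -2, 2)
  eta <- cbind(2 * abs(x) - 2, 0 * x, 0 * x, 0)
  P <- softmax_rows(eta)
  feats <- data.frame(bee_id = sprintf("b%03d", 1:n), day = 1, feat = x)
  desc <- cbind(feats[, 1:2], as.data.frame(P))
  colnames(desc)[3:6] <- desc_cols
  desc$n_samples <- 50
  glm_nl <- fit_task_model(feats, desc)
  nn_nl <- fit_task_model(feats, desc, model_class = "small_nn")
  expect_gt(nn_nl$r2, glm_nl$r2 + 0.05)
})

test_that("repeatability follows its variance-ratio definition", {
  # focal bee constant, control means vary: R = 1
  days <- 1:6
  ser <- rbind(
    data.frame(bee_id = "focal", day = days, network_age = 10),
    data.frame(bee_id = "c1", day = days, network_age = days * 2),
    data.frame(bee_id = "c2", day = days, network_age = days * 2 + 1))
  bio <- data.frame(bee_id = rep(c("focal", "c1", "c2"), each = 6),
                    day = rep(days, 3), age = rep(days, 3))
  r <- repeatability(ser, bio, "focal")
  expect_equal(r$R, 1)

  # engineered equal variances: R = 0.5
  ser2 <- rbind(
    data.frame(bee_id = "focal", day = days, network_age = c(1, 2, 1, 2, 1, 2)),
    data.frame(bee_id = "c1", day = days, network_age = c(4, 6, 4, 6, 4, 6)))
  bio2 <- data.frame(bee_id = rep(c("focal", "c1"), each = 6),
                     day = rep(days, 2), age = rep(days, 2))
  r2 <- repeatability(ser2, bio2, "focal")
  var_i <- var(c(1, 2, 1, 2, 1, 2))
  var_p <- var(c(4, 6, 4, 6, 4, 6))
  expect_equal(r2$R, var_p / (var_i + var_p))
})

test_that("trajectory clustering handles degenerate ks and duplicated bees", {
  ser <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(bee_id = sprintf("b%02d", i), day = 1:10,
               network_age = if (i <= 3) 1:10 else rep(2, 10))
  }))
  one <- cluster_trajectories(ser, k = 1)
  expect_equal(length(unique(one$labels)), 1)
  two <- cluster_trajectories(ser, k = 2)
  expect_equal(length(unique(two$labels[1:3])), 1)
  expect_equal(length(unique(two$labels[4:6])), 1)
  expect_error(cluster_trajectories(ser, k = 10), "exceeds")

  dup <- ser
  dup$bee_id <- paste0("x", dup$bee_id)
  both <- cluster_trajectories(rbind(ser, dup), k = 2)
  # duplicating every bee preserves the partition structure
  expect_equal(unname(both$labels[1:6]), unname(both$labels[7:12]))
})

test_that("interpolation fills gaps linearly and extrapolates from the ends", {
  y <- netage:::lin_interp_extrap(c(2, 4, 6), c(10, 20, 30), 1:7)
  expect_equal(y, c(5, 10, 15, 20, 25, 30, 35))
})

test_that("mode split assigns bimodal days and finds first upper-mode ages", {
  # bees below age 6 at least once; one crosses to the upper mode at age 12
  days <- 1:16
  mk <- function(b, vals, ages) data.frame(bee_id = b, day = days,
                                           network_age = vals, age = ages)
  lower <- do.call(rbind, lapply(1:6, function(i) {
    mk(sprintf("lo%02d", i), rnorm(16, 5, 0.5), days)
  }))
  upper <- do.call(rbind, lapply(1:6, function(i) {
    mk(sprintf("hi%02d", i), rnorm(16, 35, 0.5), days + 10)
  }))
  set.seed(48)
  crosser <- mk("cross", c(rep(5, 11), rep(35, 5)), days)
  ser <- rbind(lower, upper, crosser)
  bio <- ser[, c("bee_id", "day", "age")]
  ms <- mode_split(ser[, c("bee_id", "day", "network_age")], bio)
  a <- ms$assignments
  expect_true(all(a$mode[grepl("^hi", a$bee_id)] == "upper"))
  expect_true(all(a$mode[grepl("^lo", a$bee_id)] == "lower"))
  fu <- ms$first_upper
  expect_equal(fu$first_upper_age[fu$bee_id == "cross"], 12)
  expect_true(all(is.na(fu$first_upper_age[grepl("^lo", fu$bee_id)])))
  # the upper cohort entered above age 6 and is excluded from the cohort rule
  expect_false(any(grepl("^hi", fu$bee_id)))
})

test_that("mode split still partitions unimodal days", {
  ser <- data.frame(bee_id = sprintf("b%02d", 1:20), day = 1,
                    network_age = rnorm(20, 20, 1))
  bio <- data.frame(bee_id = ser$bee_id, day = 1, age = 3)
  ms <- mode_split(ser, bio)
  expect_equal(nrow(ms$assignments), 20)
  expect_true(all(c("lower", "upper") %in% ms$assignments$mode))
  expect_true(is.finite(ms$assignments$separation[1]))
})

test_that("future prediction rejects non-positive horizons and detects stationarity", {
  p <- default_pipeline()
  expect_error(future_prediction(p$factors, p$descriptors, horizons = 0),
               "horizons")
})
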
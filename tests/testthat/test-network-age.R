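fake_factors <- function(n, f, seed = 1, prefix = "m") {
  set.seed(seed)
  X <- matrix(rnorm(n * f), n, f)
  colnames(X) <- sprintf("%s.%d", prefix, seq_len(f))
  cbind(data.frame(bee_id = sprintf("b%04d", seq_len(n)), day = 1,
                   stringsAsFactors = FALSE),
        as.data.frame(X))
}

desc_cols <- c("frac_brood", "frac_dance_floor", "frac_honey", "frac_exit")

test_that("CCA recovers an exact linear factor-descriptor relation", {
  f <- fake_factors(400, 10, seed = 1)
  X <- as.matrix(f[, -(1:2)])
  W <- matrix(rnorm(40), 10, 4)
  raw <- exp(X %*% W / 4)
  Y <- raw / rowSums(raw)
  desc <- cbind(f[, 1:2], as.data.frame(Y))
  colnames(desc)[3:6] <- desc_cols
  # descriptor logits are exact linear functions of the factors
  desc_lin <- desc
  desc_lin[, 3:6] <- X %*% W[, 1:4]
  map <- fit_cca_map(f, desc_lin, k = 3)
  expect_gt(map$cor1, 1 - 1e-6)
  expect_equal(ncol(map$projection), 3)
})

test_that("CCA on permuted (independent) descriptors finds little correlation", {
  f <- fake_factors(5000, 96, seed = 2)
  set.seed(3)
  Y <- matrix(runif(5000 * 4), ncol = 4)
  Y <- Y / rowSums(Y)
  desc <- cbind(f[, 1:2], as.data.frame(Y))
  colnames(desc)[3:6] <- desc_cols
  map <- fit_cca_map(f, desc, k = 3)
  expect_lt(map$cor1, 0.2)
})

test_that("the whitened CCA matches stats::cancor on a full-rank problem", {
  set.seed(4)
  X <- matrix(rnorm(300 * 6), 300, 6)
  Y <- X[, 1:2] %*% matrix(c(1, 0.5, -0.3, 1), 2, 2) + matrix(rnorm(600), 300, 2)
  cc_ref <- stats::cancor(X, Y)
  cc <- netage:::cca_whitened(X, Y)
  expect_equal(cc$cor[1:2], cc_ref$cor[1:2], tolerance = 1e-8)
  # directions agree up to scale and sign
  for (k in 1:2) {
    a <- cc$xcoef[, k]
    b <- cc_ref$xcoef[, k]
    cosab <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
    expect_gt(cosab, 1 - 1e-8)
  }
})

test_that("fitting fails gracefully with too few rows or constant targets", {
  f <- fake_factors(50, 96, seed = 5)
  desc <- cbind(f[, 1:2], as.data.frame(matrix(0.25, 50, 4)))
  colnames(desc)[3:6] <- desc_cols
  expect_error(fit_cca_map(f, desc), "fewer bee-day rows")
  f2 <- fake_factors(60, 5, seed = 6)
  tgt <- data.frame(bee_id = f2$bee_id, day = f2$day, value = 1)
  expect_error(fit_targeted_map(f2, tgt), "constant target")
})

test_that("apply_map standardizes, projects, and checks headers", {
  f <- fake_factors(100, 1, seed = 7)
  map <- structure(list(center = c(m.1 = mean(f$m.1)),
                        scale = c(m.1 = sd(f$m.1)),
                        projection = matrix(1, 1, 1, dimnames = list("m.1", "dim1")),
                        header = "m.1", variant = "pca", cor1 = NA),
                   class = "network_age_map")
  raw <- apply_map(f, map)
  expect_equal(raw$raw_1, as.numeric(scale(f$m.1)), tolerance = 1e-12)
  expect_identical(apply_map(f, map), raw) # deterministic

  f_swapped <- f
  names(f_swapped)[3] <- "other"
  expect_error(apply_map(f_swapped, map), "header")

  # zero-variance feature contributes nothing
  f2 <- fake_factors(100, 2, seed = 8)
  f2$m.2 <- 5
  map2 <- fit_pca_map(f2, k = 1)
  raw2 <- apply_map(f2, map2)
  expect_true(all(is.finite(raw2$raw_1)))
  expect_equal(map2$projection["m.2", 1], 0)
})

test_that("robust scaling anchors the 5th and 95th percentiles at 0 and 40", {
  raw <- data.frame(bee_id = sprintf("b%03d", 0:100), day = 1, raw_1 = 0:100)
  s <- robust_scale(raw)
  expect_equal(s$network_age[raw$raw_1 == 50], 40 * (50 - 5) / 90)
  expect_equal(s$network_age[raw$raw_1 == 50], 20)
  q <- quantile(raw$raw_1, c(0.05, 0.95), type = 7, names = FALSE)
  expect_equal(s$network_age[raw$raw_1 == q[1]], 0)
  expect_equal(s$network_age[raw$raw_1 == q[2]], 40)
})

test_that("degenerate days scale to the midpoint with a warning", {
  raw <- data.frame(bee_id = sprintf("b%03d", 1:10), day = 2, raw_1 = 7)
  expect_warning(s <- robust_scale(raw), "degenerate")
  expect_true(all(s$network_age == 20))
})

test_that("exactly 90% of continuous values land inside [0, 40] per day", {
  set.seed(10)
  raw <- data.frame(bee_id = sprintf("b%05d", 1:10000), day = 1,
                    raw_1 = rlnorm(10000))
  s <- robust_scale(raw)
  inside <- mean(s$network_age >= 0 & s$network_age <= 40)
  expect_lt(abs(inside - 0.9), 0.005)
})

test_that("directionality orientation is an involution anchored on biological age", {
  set.seed(11)
  n <- 500
  age <- sample(1:30, n, replace = TRUE)
  raw <- data.frame(bee_id = sprintf("b%04d", 1:n), day = 1,
                    raw_1 = age + rnorm(n, 0, 2))
  bio <- data.frame(bee_id = raw$bee_id, day = 1, age = age)
  s <- robust_scale(raw)
  expect_identical(orient_directionality(s, bio), s) # already aligned

  s_neg <- robust_scale(transform(raw, raw_1 = -raw_1))
  fixed <- orient_directionality(s_neg, bio)
  expect_equal(attr(fixed, "orientation"), -1L)
  expect_equal(fixed$network_age, s$network_age, tolerance = 1e-9)
  expect_gt(spearman(fixed$network_age, age), 0)
})

test_that("PCA map recovers a planted dominant direction", {
  set.seed(12)
  n <- 2000
  dir <- rnorm(20)
  dir <- dir / sqrt(sum(dir^2))
  scores <- rnorm(n, sd = 12)
  X <- scores %o% dir + matrix(rnorm(n * 20), n, 20)
  f <- cbind(data.frame(bee_id = sprintf("b%05d", 1:n), day = 1),
             as.data.frame(X))
  colnames(f)[-(1:2)] <- sprintf("m.%d", 1:20)
  map <- fit_pca_map(f, k = 1)
  expect_equal(ncol(map$projection), 1)
  # compare against the standardized planted direction
  Xs <- scale(X)
  pc_dir <- map$projection[, 1]
  planted <- as.numeric(stats::cor(Xs %*% pc_dir, scores))
  expect_gt(abs(planted), 0.99)
})

test_that("PCA on isotropic noise spreads variance evenly", {
  set.seed(13)
  f <- fake_factors(4000, 20, seed = 13)
  map <- fit_pca_map(f, k = 1)
  expect_lt(abs(map$explained_variance[1] * 20 - 1), 0.25)
})

test_that("a targeted map reproduces a linear target and serializes to JSON", {
  f <- fake_factors(300, 8, seed = 14)
  X <- as.matrix(f[, -(1:2)])
  tgt <- data.frame(bee_id = f$bee_id, day = f$day,
                    value = X %*% rnorm(8))
  map <- fit_targeted_map(f, tgt, k = 1)
  expect_gt(map$cor1, 1 - 1e-6)

  path <- withr::local_tempfile(fileext = ".json")
  write_network_age_map(map, path)
  back <- read_network_age_map(path)
  expect_equal(back$projection, map$projection, tolerance = 1e-12)
  expect_equal(apply_map(f, back), apply_map(f, map), tolerance = 1e-10)
})

test_that("role recovery is robust to subsampling the tracked bees", {
  p <- default_pipeline()
  full <- merge(as.data.frame(p$series),
                p$ground_truth$roles[, c("bee_id", "day", "rho")],
                by = c("bee_id", "day"))
  rho_full <- abs(spearman(full$network_age, full$rho))

  set.seed(60)
  keep <- sample(p$ground_truth$bees$bee_id, 50) # 25% of the colony
  aff <- simulate_affinity_timeseries(p$ground_truth, p$config)
  aff_sub <- lapply(aff, function(day_modes) {
    lapply(day_modes, function(m) {
      ids <- attr(m, "bee_ids")
      sel <- ids %in% keep
      affinity_matrix(unclass(m)[sel, sel, drop = FALSE], ids[sel],
                      attr(m, "day"), attr(m, "mode"), attr(m, "symmetric"))
    })
  })
  f_sub <- compute_daily_factors(aff_sub, n_dims = 8)
  na_sub <- network_age(f_sub, p$descriptors, p$bio_age)
  sub <- merge(as.data.frame(na_sub$series),
               p$ground_truth$roles[, c("bee_id", "day", "rho")],
               by = c("bee_id", "day"))
  rho_sub <- abs(spearman(sub$network_age, sub$rho))
  expect_gte(rho_sub, rho_full - 0.15)
})

test_that("targeted death embedding beats task-CCA network age at its own target", {
  p <- default_pipeline()
  gt <- p$ground_truth
  dud <- merge(p$bio_age, gt$bees[, c("bee_id", "death_day")], by = "bee_id")
  dud$value <- dud$death_day - dud$day # days until death
  tgt <- dud[, c("bee_id", "day", "value")]
  tmap <- fit_targeted_map(p$factors, tgt, k = 1)
  temb <- robust_scale(apply_map(p$factors, tmap))
  feat_t <- as.data.frame(temb)[, c("bee_id", "day", "network_age")]
  feat_na <- as.data.frame(p$series)[, c("bee_id", "day", "network_age")]
  fit_t <- fit_task_model(feat_t, tgt, family = "gaussian_scalar")
  fit_na <- fit_task_model(feat_na, tgt, family = "gaussian_scalar")
  expect_gt(fit_t$r2, fit_na$r2)
})
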
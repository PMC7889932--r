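test_that("identical configurations reproduce byte-identical colonies", {
  cfg_a <- tiny_config(seed = 11)
  cfg_b <- tiny_config(seed = 11)
  col_a <- simulate_colony(cfg_a)
  col_b <- simulate_colony(cfg_b)
  expect_identical(col_a$detections, col_b$detections)
  expect_identical(col_a$ground_truth, col_b$ground_truth)
  expect_identical(simulate_affinity_timeseries(col_a$ground_truth, cfg_a),
                   simulate_affinity_timeseries(col_b$ground_truth, cfg_b))
  expect_identical(simulate_detection_counts(col_a$ground_truth, cfg_a),
                   simulate_detection_counts(col_b$ground_truth, cfg_b))
})

test_that("configuration invariants are enforced", {
  expect_error(colony_config(cluster_probs = c(early = 0.5, late = 0.5, none = 0.5)),
               "sum to 1")
  expect_error(colony_config(n_days = 0), "n_days")
  overlapping <- default_area_geometry()
  overlapping$honey <- overlapping$dance_floor
  expect_error(colony_config(area_geometry = overlapping), "disjoint")
  expect_error(colony_config(affinity_rate_max = -1), "rates")
})

test_that("with zero detection noise no detections occur outside the alive interval", {
  cfg <- tiny_config(seed = 12,
                     lifespan_mean = 3, lifespan_sd = 1,
                     detection_noise = list(rate = 0, conf_shape1 = 1,
                                            conf_shape2 = 8))
  col <- simulate_colony(cfg)
  det <- col$detections
  gt <- col$ground_truth$bees
  e <- gt$emergence_day[match(det$bee_id, gt$bee_id)]
  d <- gt$death_day[match(det$bee_id, gt$bee_id)]
  expect_true(all(det$day >= e & det$day < d))
  expect_false(any(det$false_positive))
})

test_that("false positives are flagged and only occur outside the alive interval", {
  cfg <- tiny_config(seed = 13, lifespan_mean = 3, lifespan_sd = 1)
  col <- simulate_colony(cfg)
  det <- col$detections
  gt <- col$ground_truth$bees
  e <- gt$emergence_day[match(det$bee_id, gt$bee_id)]
  d <- gt$death_day[match(det$bee_id, gt$bee_id)]
  alive <- det$day >= e & det$day < d
  expect_true(all(det$false_positive == !alive))
})

test_that("a never-transitioning bee stays concentrated on the brood area", {
  cfg <- colony_config(n_bees = 1, n_days = 10, seed = 21,
                       emergence_schedule = data.frame(day = 1, n = 1),
                       cluster_probs = c(early = 0, late = 0, none = 1),
                       lifespan_mean = 60, lifespan_sd = 1)
  col <- simulate_colony(cfg)
  expect_true(all(col$ground_truth$roles$m_brood > 0.9))
  det <- col$detections[!col$detections$false_positive, ]
  in_brood <- point_in_polygon(det$x_mm, det$y_mm, cfg$area_geometry$brood)
  expect_gte(mean(in_brood), 0.95)
})

test_that("ground-truth invariants hold: mixtures sum to 1, roles are monotone", {
  gt <- simulate_ground_truth(tiny_config(seed = 14))
  mix <- gt$roles[, c("m_brood", "m_dance_floor", "m_honey", "m_exit")]
  expect_true(all(abs(rowSums(mix) - 1) < 1e-12))
  for (b in split(gt$roles, gt$roles$bee_id)) {
    b <- b[order(b$day), ]
    expect_true(all(diff(b$rho) >= -1e-12))
  }
  # roles defined only while alive
  e <- gt$bees$emergence_day[match(gt$roles$bee_id, gt$bees$bee_id)]
  d <- gt$bees$death_day[match(gt$roles$bee_id, gt$bees$bee_id)]
  expect_true(all(gt$roles$day >= e & gt$roles$day < d))
})

test_that("per-burst occupancy converges to the task mixture", {
  cfg <- colony_config(n_bees = 1, n_days = 20, seed = 22,
                       emergence_schedule = data.frame(day = 1, n = 1),
                       cluster_probs = c(early = 1, late = 0, none = 0),
                       transition_day_means = list(
                         early = c(mean = 5, sd = 0.1),
                         late = c(mean = 21, sd = 2),
                         none = c(mean = Inf, sd = 0)),
                       lifespan_mean = 60, lifespan_sd = 1,
                       detection_noise = list(rate = 0, conf_shape1 = 1,
                                              conf_shape2 = 8))
  col <- simulate_colony(cfg)
  det <- col$detections[col$detections$day > 10, ] # mature forager phase
  roles <- col$ground_truth$roles
  mix <- colMeans(roles[roles$day > 10,
                        c("m_brood", "m_dance_floor", "m_honey", "m_exit")])
  areas <- cfg$area_geometry[c("brood", "dance_floor", "honey", "exit")]
  frac <- vapply(areas, function(p) {
    mean(point_in_polygon(det$x_mm, det$y_mm, p))
  }, numeric(1))
  # bursts share one area, so the effective sample size is the burst count
  n_eff <- cfg$bursts_per_day * 10
  tol <- 3 * sqrt(mix * (1 - mix) / n_eff) + 0.01
  expect_true(all(abs(frac - mix) < tol))
})

test_that("the role-affinity kernel has its closed form", {
  expect_equal(role_affinity_kernel(0, 25, 0.3), 25)
  expect_equal(role_affinity_kernel(0.3, 25, 0.3), 25 * exp(-0.5))
  expect_equal(role_affinity_kernel(0.3, 10, 0.3) / 10, exp(-1 / 2),
               tolerance = 1e-12)
  expect_error(role_affinity_kernel(0.1, 10, 0), "bandwidth")
})

test_that("simulated affinity matrices respect constructor contracts", {
  cfg <- tiny_config(seed = 15)
  gt <- simulate_ground_truth(cfg)
  aff <- simulate_affinity_timeseries(gt, cfg)
  for (day_modes in aff) {
    for (m in day_modes) {
      expect_true(all(diag(m) == 0))
      expect_true(all(m >= 0))
      if (attr(m, "symmetric")) expect_identical(unclass(m), unclass(t(m)))
    }
    # alive-set conservation: indices are exactly the bees alive that day
    day <- attr(day_modes[[1]], "day")
    alive <- gt$roles$bee_id[gt$roles$day == day]
    expect_setequal(attr(day_modes[[1]], "bee_ids"), alive)
  }
})

test_that("count affinity decreases with role distance (kernel monotonicity)", {
  cfg <- colony_config(n_bees = 40, n_days = 4, seed = 16,
                       emergence_schedule = data.frame(day = c(-20, 1), n = 20),
                       lifespan_mean = 60, lifespan_sd = 5)
  gt <- simulate_ground_truth(cfg)
  aff <- simulate_affinity_timeseries(gt, cfg, modes = "proximity_count")
  for (day_modes in aff) {
    m <- day_modes$proximity_count
    ids <- attr(m, "bee_ids")
    rho <- gt$roles$rho[match(paste(ids, attr(m, "day")),
                              paste(gt$roles$bee_id, gt$roles$day))]
    dr <- abs(outer(rho, rho, "-"))[upper.tri(m)]
    counts <- unclass(m)[upper.tri(m)]
    if (stats::sd(dr) > 0.01) {
      expect_lt(spearman(dr, counts), 0)
    }
  }
})

test_that("daily detection counts collapse at the planted death day", {
  cfg <- tiny_config(seed = 17,
                     detection_noise = list(rate = 0, conf_shape1 = 1,
                                            conf_shape2 = 8))
  gt <- simulate_ground_truth(cfg)
  gt$bees$death_day[1] <- 4 # plant a death inside the window
  gt$roles <- gt$roles[!(gt$roles$bee_id == gt$bees$bee_id[1] &
                           gt$roles$day >= 4), ]
  counts <- simulate_detection_counts(gt, cfg, alive_mean = 1000)
  b1 <- counts[counts$bee_id == gt$bees$bee_id[1], ]
  b1 <- b1[b1$day >= gt$bees$emergence_day[1], ]
  expect_true(all(b1$count[b1$day >= 4] == 0))
  expect_true(all(b1$count[b1$day < 4] > 100))
})

test_that("dead-day counts follow the configured false-positive rate", {
  cfg <- colony_config(n_bees = 50, n_days = 25, seed = 18,
                       emergence_schedule = data.frame(day = 1, n = 50),
                       lifespan_mean = 2, lifespan_sd = 0.5,
                       detection_noise = list(rate = 2, conf_shape1 = 1,
                                              conf_shape2 = 8))
  gt <- simulate_ground_truth(cfg)
  counts <- simulate_detection_counts(gt, cfg, alive_mean = 1000)
  d <- gt$bees$death_day[match(counts$bee_id, gt$bees$bee_id)]
  dead <- counts$count[counts$day >= d]
  expect_gte(length(dead), 1000)
  se <- sqrt(2 / length(dead))
  expect_lt(abs(mean(dead) - 2), 3 * se)
})

test_that("detection tables round-trip through CSV", {
  col <- simulate_colony(tiny_config(seed = 19))
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections_csv(col$detections, path)
  back <- read_detections_csv(path)
  expect_equal(back$bee_id, col$detections$bee_id)
  expect_equal(back$x_mm, col$detections$x_mm, tolerance = 1e-12)
  maps_path <- withr::local_tempfile(fileext = ".json")
  write_area_maps_json(col$area_maps[1], maps_path)
  j <- jsonlite::read_json(maps_path)
  expect_length(j, 8) # 4 areas x 2 sides
  expect_setequal(unique(vapply(j, `[[`, character(1), "label")),
                  c("brood", "dance_floor", "honey", "exit"))
})
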
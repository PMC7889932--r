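#' Configuration for a synthetic colony
#'
#' Defines the study conditions a simulated colony emulates: an age-structured
#' honey bee colony in which same-aged workers follow heterogeneous
#' developmental trajectories (an early transition to forager-like roles, a
#' late one, or none within the focal period), tasks couple to four nest
#' areas (brood nest, dance floor, honey storage, exit), forager-like bees
#' show circadian velocity modulation, pairwise interaction rates decay with
#' the difference of the latent roles, and detections of dead or not-yet
#' introduced individuals occur only at a small false-positive floor.
#'
#' @param n_bees total number of tagged bees.
#' @param n_days length of the focal (recorded) period in days; recording
#'   days are numbered `1..n_days`.
#' @param emergence_schedule data frame with columns `day` and `n`
#'   (cohort emergence day, which may precede day 1, and cohort size). The
#'   default splits `n_bees` into five equal cohorts emerging every five
#'   days starting nine days before recording.
#' @param cluster_probs probabilities of the three developmental clusters,
#'   named `early`, `late`, `none`; must sum to 1.
#' @param transition_day_means list with per-cluster `mean` and `sd` of the
#'   day-of-life at which the role transition is centred (`none` uses
#'   `Inf`, i.e. no transition).
#' @param transition_scale steepness (days) of the logistic role curve.
#' @param lifespan_mean,lifespan_sd parameters of the truncated-normal
#'   lifespan distribution (days, truncated to >= 1).
#' @param frame_rate camera frame rate in Hz; comb sides alternate between
#'   frames, so a bee's side is imaged at `frame_rate / 2`.
#' @param bursts_per_day,burst_len detections are emitted in short bursts of
#'   consecutive same-side frames; `bursts_per_day * burst_len` frames are
#'   sampled per bee-day (a subsample of the full video stream).
#' @param area_geometry named list of four disjoint polygons (two-column
#'   matrices, mm): `brood`, `dance_floor`, `honey`, `exit`.
#' @param affinity_rate_max expected daily contact count for a pair with
#'   identical latent roles.
#' @param role_bandwidth bandwidth of the Gaussian role-similarity kernel
#'   (dimensionless role units).
#' @param detection_rate per-frame probability that an alive bee is detected.
#' @param detection_noise list with `rate` (expected false-positive
#'   detections per day for a dead or absent id) and `conf_shape1`,
#'   `conf_shape2` (Beta parameters of false-positive confidences).
#' @param conf_alive Beta shape parameters of alive-detection confidences.
#' @param base_speed_mm_s baseline walking speed (mm/s).
#' @param circadian_amp relative amplitude of the 24-h speed modulation for
#'   forager-like bees (latent role > 0.5).
#' @param activity_peak_hour UTC hour at which forager activity peaks.
#' @param monotone_roles if `TRUE` (default) role trajectories are
#'   non-decreasing; reversals are not generated.
#' @param seed integer seed; identical configurations produce identical
#'   colonies.
#' @return an object of class `colony_config`.
#' @export
colony_config <- function(n_bees = 200,
                          n_days = 25,
                          emergence_schedule = NULL,
                          cluster_probs = c(early = 0.35, late = 0.35, none = 0.30),
                          transition_day_means = list(
                            early = c(mean = 11, sd = 2),
                            late = c(mean = 21, sd = 2),
                            none = c(mean = Inf, sd = 0)
                          ),
                          transition_scale = 1.5,
                          lifespan_mean = 35,
                          lifespan_sd = 15,
                          frame_rate = 3,
                          bursts_per_day = 240,
                          burst_len = 3,
                          area_geometry = default_area_geometry(),
                          affinity_rate_max = 25,
                          role_bandwidth = 0.3,
                          detection_rate = 0.85,
                          detection_noise = list(rate = 2, conf_shape1 = 1, conf_shape2 = 8),
                          conf_alive = c(20, 1),
                          base_speed_mm_s = 4,
                          circadian_amp = 0.8,
                          activity_peak_hour = 13,
                          monotone_roles = TRUE,
                          seed = 1) {
  if (is.null(emergence_schedule)) {
    days <- c(-9, -4, 1, 6, 11)
    n_per <- rep(n_bees %/% 5, 5)
    n_per[seq_len(n_bees %% 5)] <- n_per[seq_len(n_bees %% 5)] + 1
    emergence_schedule <- data.frame(day = days, n = n_per)
  }
  cfg <- list(
    n_bees = n_bees, n_days = n_days,
    emergence_schedule = emergence_schedule,
    cluster_probs = cluster_probs,
    transition_day_means = transition_day_means,
    transition_scale = transition_scale,
    lifespan_mean = lifespan_mean, lifespan_sd = lifespan_sd,
    frame_rate = frame_rate,
    bursts_per_day = bursts_per_day, burst_len = burst_len,
    area_geometry = area_geometry,
    affinity_rate_max = affinity_rate_max,
    role_bandwidth = role_bandwidth,
    detection_rate = detection_rate,
    detection_noise = detection_noise,
    conf_alive = conf_alive,
    base_speed_mm_s = base_speed_mm_s,
    circadian_amp = circadian_amp,
    activity_peak_hour = activity_peak_hour,
    monotone_roles = monotone_roles,
    seed = as.integer(seed)
  )
  class(cfg) <- "colony_config"
  validate_colony_config(cfg)
  cfg
}

validate_colony_config <- function(cfg) {
  if (cfg$n_days < 1) stop("n_days must be >= 1")
  if (abs(sum(cfg$cluster_probs) - 1) > 1e-8) stop("cluster_probs must sum to 1")
  if (sum(cfg$emergence_schedule$n) != cfg$n_bees) {
    stop("emergence_schedule cohort sizes must sum to n_bees")
  }
  rates <- c(cfg$affinity_rate_max, cfg$detection_noise$rate,
             cfg$frame_rate, cfg$base_speed_mm_s)
  if (any(rates < 0)) stop("all rates must be >= 0")
  areas <- cfg$area_geometry
  if (!setequal(names(areas), c("brood", "dance_floor", "honey", "exit"))) {
    stop("area_geometry must name polygons brood, dance_floor, honey, exit")
  }
  nm <- names(areas)
  for (i in seq_along(areas)) {
    for (j in seq_along(areas)) {
      if (i < j && polygons_overlap(areas[[i]], areas[[j]])) {
        stop(sprintf("area polygons '%s' and '%s' are not disjoint", nm[i], nm[j]))
      }
    }
  }
  invisible(cfg)
}

#' Default nest-area geometry
#'
#' Four disjoint rectangles on a 360 x 260 mm comb plane: brood nest on the
#' left, honey storage top right, dance floor bottom right, and a narrow
#' exit strip on the right edge next to the dance floor.
#'
#' @return named list of polygons (two-column matrices, mm).
#' @export
default_area_geometry <- function() {
  list(
    brood = rect_polygon(20, 40, 150, 220),
    dance_floor = rect_polygon(170, 20, 330, 120),
    honey = rect_polygon(170, 140, 330, 240),
    exit = rect_polygon(338, 20, 358, 120)
  )
}

# Task-mixture anchors: row = area fractions for a pure nurse / pure forager.
.nurse_mixture <- c(brood = 0.96, dance_floor = 0.01, honey = 0.02, exit = 0.01)
.forager_mixture <- c(brood = 0.05, dance_floor = 0.65, honey = 0.10, exit = 0.20)

#' Simulate ground truth for a synthetic colony
#'
#' Draws per-bee emergence days (from the configured schedule), lifespans
#' (truncated normal), developmental cluster labels, latent role
#' trajectories, and daily task mixtures. The latent role rho(b, t) follows
#' a logistic curve in day-of-life with a cluster-specific midpoint (early
#' ~11 days, late ~21 days, `none` never transitions), so trajectories are
#' monotone non-decreasing. The task mixture interpolates between a
#' brood-concentrated nurse profile and a dance-floor-centred forager
#' profile as rho goes from 0 to 1.
#'
#' @param config a [colony_config()].
#' @return object of class `colony_ground_truth`: list with `bees` (one row
#'   per bee: id, emergence/death day, cluster, transition midpoint) and
#'   `roles` (one row per alive bee-day within the focal period: day,
#'   day-of-life `age`, latent role `rho`, and mixture columns `m_brood`,
#'   `m_dance_floor`, `m_honey`, `m_exit`).
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "colony_config"))
  with_seed(config$seed, {
    sched <- config$emergence_schedule
    emergence <- rep(sched$day, sched$n)
    n <- config$n_bees
    bee_id <- sprintf("b%04d", seq_len(n))
    cluster <- sample(names(config$cluster_probs), n, replace = TRUE,
                      prob = config$cluster_probs)
    midpoint <- vapply(cluster, function(cl) {
      pars <- config$transition_day_means[[cl]]
      if (!is.finite(pars[["mean"]])) Inf else stats::rnorm(1, pars[["mean"]], pars[["sd"]])
    }, numeric(1))
    lifespan <- round(rtruncnorm_lower(n, config$lifespan_mean,
                                       config$lifespan_sd, 1))
    death <- emergence + lifespan
    bees <- data.frame(
      bee_id = bee_id, emergence_day = emergence, death_day = death,
      cluster = cluster, transition_midpoint = midpoint,
      stringsAsFactors = FALSE
    )
    roles <- do.call(rbind, lapply(seq_len(n), function(i) {
      days <- seq.int(max(1, emergence[i]), min(config$n_days, death[i] - 1))
      if (length(days) == 0 || emergence[i] > config$n_days ||
          death[i] <= 1) {
        return(NULL)
      }
      age <- days - emergence[i]
      rho <- if (is.finite(midpoint[i])) {
        stats::plogis((age - midpoint[i]) / config$transition_scale)
      } else {
        rep(0, length(age))
      }
      mix <- outer(1 - rho, .nurse_mixture) + outer(rho, .forager_mixture)
      data.frame(
        bee_id = bee_id[i], day = days, age = age, rho = rho,
        m_brood = mix[, "brood"], m_dance_floor = mix[, "dance_floor"],
        m_honey = mix[, "honey"], m_exit = mix[, "exit"],
        stringsAsFactors = FALSE
      )
    }))
    rownames(roles) <- NULL
    structure(list(bees = bees, roles = roles), class = "colony_ground_truth")
  })
}

#' Simulate a colony: detections, daily area maps, and ground truth
#'
#' Emulates the recording regime of a tagged observation hive: combs are
#' imaged at `frame_rate` Hz alternating between sides, so an individual's
#' side is sampled at half the nominal rate. Detections are generated in
#' short bursts of consecutive same-side frames; within a burst the bee
#' performs a random walk whose step length follows the configured speed,
#' modulated by a 24-h sinusoid (peaking at `activity_peak_hour`) for
#' forager-like bees (latent role > 0.5). The nest area of each burst is
#' drawn from the bee's daily task mixture, and the burst stays inside the
#' chosen polygon. After death (and before introduction) an id appears only
#' as uniformly placed false positives at rate `detection_noise$rate` per
#' day, with low confidences; these rows carry `false_positive = TRUE`.
#'
#' @param config a [colony_config()].
#' @return list with `detections` (data frame: bee_id, timestamp_utc, day,
#'   x_mm, y_mm, orientation_rad, side, confidence, false_positive),
#'   `area_maps` (per-day named polygon lists; the default geometry is
#'   static), and `ground_truth`.
#' @export
simulate_colony <- function(config) {
  stopifnot(inherits(config, "colony_config"))
  gt <- simulate_ground_truth(config)
  det <- with_seed(config$seed + 1L, simulate_detections(gt, config))
  area_maps <- lapply(seq_len(config$n_days), function(d) config$area_geometry)
  names(area_maps) <- as.character(seq_len(config$n_days))
  list(detections = det, area_maps = area_maps, ground_truth = gt)
}

simulate_detections <- function(gt, config) {
  areas <- config$area_geometry
  area_names <- c("brood", "dance_floor", "honey", "exit")
  dt_frame <- 2 / config$frame_rate # same-side inter-frame interval
  burst_len <- config$burst_len
  comb_x <- range(do.call(rbind, areas)[, 1])
  comb_y <- range(do.call(rbind, areas)[, 2])
  out <- vector("list", nrow(gt$roles) + nrow(gt$bees) * config$n_days)
  k <- 0L

  # alive bee-days: vectorized burst sampling
  roles <- gt$roles
  for (r in seq_len(nrow(roles))) {
    day <- roles$day[r]
    mix <- as.numeric(roles[r, c("m_brood", "m_dance_floor", "m_honey", "m_exit")])
    rho <- roles$rho[r]
    nb <- config$bursts_per_day
    starts <- sort(stats::runif(nb, 0, 86400 - burst_len * dt_frame))
    burst_area <- sample.int(4, nb, replace = TRUE, prob = mix)
    side <- stats::rbinom(1, 1, 0.5)
    day0 <- (day - 1) * 86400
    circ <- if (rho > 0.5) {
      1 + config$circadian_amp *
        cos(2 * pi * (starts / 3600 - config$activity_peak_hour) / 24)
    } else {
      rep(1, nb)
    }
    # burst-start positions, grouped by area
    px <- numeric(nb); py <- numeric(nb)
    for (a in unique(burst_area)) {
      sel <- burst_area == a
      pts <- sample_in_polygon(sum(sel), areas[[area_names[a]]])
      px[sel] <- pts[, 1]; py[sel] <- pts[, 2]
    }
    # within-burst random walk: step length follows the (possibly
    # circadian-modulated) speed; cumulate displacements along the burst
    speed <- matrix(config$base_speed_mm_s * rep(circ, each = burst_len) *
                      stats::rlnorm(nb * burst_len, -0.08, 0.4),
                    burst_len, nb)
    theta <- matrix(stats::runif(nb * burst_len, -pi, pi), burst_len, nb)
    dx <- speed * dt_frame * cos(theta)
    dy <- speed * dt_frame * sin(theta)
    xs <- rbind(px, px + apply(dx[-burst_len, , drop = FALSE], 2, cumsum))
    ys <- rbind(py, py + apply(dy[-burst_len, , drop = FALSE], 2, cumsum))
    # steps that leave the burst's polygon are re-anchored inside it
    for (a in unique(burst_area)) {
      sel_cols <- which(burst_area == a)
      poly <- areas[[area_names[a]]]
      flat <- cbind(as.numeric(xs[, sel_cols]), as.numeric(ys[, sel_cols]))
      outside <- !point_in_polygon(flat[, 1], flat[, 2], poly)
      if (any(outside)) {
        repl <- sample_in_polygon(sum(outside), poly)
        flat[outside, ] <- repl
        xs[, sel_cols] <- flat[, 1]
        ys[, sel_cols] <- flat[, 2]
      }
    }
    ts <- rep(starts, each = burst_len) +
      rep(seq_len(burst_len) - 1, nb) * dt_frame
    detected <- stats::runif(nb * burst_len) < config$detection_rate
    if (!any(detected)) next
    k <- k + 1L
    out[[k]] <- data.frame(
      bee_id = roles$bee_id[r],
      timestamp_utc = day0 + ts[detected],
      day = day,
      x_mm = as.numeric(xs)[detected], y_mm = as.numeric(ys)[detected],
      orientation_rad = as.numeric(theta)[detected],
      side = side,
      confidence = stats::rbeta(sum(detected), config$conf_alive[1],
                                config$conf_alive[2]),
      false_positive = FALSE,
      stringsAsFactors = FALSE
    )
  }

  # false positives on dead / pre-emergence days
  fp_rate <- config$detection_noise$rate
  if (fp_rate > 0) {
    for (i in seq_len(nrow(gt$bees))) {
      e <- gt$bees$emergence_day[i]
      d <- gt$bees$death_day[i]
      dead_days <- setdiff(seq_len(config$n_days),
                           seq.int(max(1, e), min(config$n_days, d - 1)))
      if (e > config$n_days || d <= 1) dead_days <- seq_len(config$n_days)
      for (day in dead_days) {
        nfp <- stats::rpois(1, fp_rate)
        if (nfp == 0) next
        ts <- sort(stats::runif(nfp, 0, 86400))
        k <- k + 1L
        out[[k]] <- data.frame(
          bee_id = gt$bees$bee_id[i],
          timestamp_utc = (day - 1) * 86400 + ts,
          day = day,
          x_mm = stats::runif(nfp, comb_x[1], comb_x[2]),
          y_mm = stats::runif(nfp, comb_y[1], comb_y[2]),
          orientation_rad = stats::runif(nfp, -pi, pi),
          side = stats::rbinom(nfp, 1, 0.5),
          confidence = stats::rbeta(nfp, config$detection_noise$conf_shape1,
                                    config$detection_noise$conf_shape2),
          false_positive = TRUE,
          stringsAsFactors = FALSE
        )
      }
    }
  }

  det <- do.call(rbind, out[seq_len(k)])
  if (is.null(det)) {
    warning("no detections generated")
    det <- data.frame(bee_id = character(), timestamp_utc = numeric(),
                      day = integer(), x_mm = numeric(), y_mm = numeric(),
                      orientation_rad = numeric(), side = integer(),
                      confidence = numeric(), false_positive = logical())
  }
  det <- det[order(det$day, det$timestamp_utc, det$bee_id), ]
  rownames(det) <- NULL
  det
}

# Gaussian role-similarity kernel: expected contact count for role gap dr.
#' Expected contact rate for a pair with latent-role difference `dr`
#'
#' `rate_max * exp(-dr^2 / (2 * bandwidth^2))`: pairs with identical roles
#' interact at `rate_max` contacts/day; the rate decays with role distance.
#'
#' @param dr role difference (dimensionless).
#' @param rate_max expected count at dr = 0.
#' @param bandwidth kernel bandwidth (> 0).
#' @export
role_affinity_kernel <- function(dr, rate_max, bandwidth) {
  if (bandwidth <= 0) stop("role_bandwidth must be > 0")
  rate_max * exp(-dr^2 / (2 * bandwidth^2))
}

#' Simulate daily multimodal affinity matrices from ground truth
#'
#' For each focal day, pairwise contact counts among the bees alive that day
#' are drawn from a Poisson distribution whose mean follows the Gaussian
#' role-similarity kernel, producing symmetric count modes (proximity,
#' trophallaxis). Daily mean pairwise distances grow with role difference
#' and are passed through the same Gaussian-similarity and
#' maximum-minus-distance transforms used on real data. Directed
#' movement-effect modes assign each contact a post-contact speed change
#' whose mean is proportional to the partner's role excess; positive
#' changes accumulate into the `*_pos` matrices and magnitudes of negative
#' changes into `*_neg`, for the mean and cumulative variants.
#'
#' @param ground_truth a `colony_ground_truth`.
#' @param config the [colony_config()] used to generate it.
#' @param modes character vector of modes to generate (default: all eight).
#' @return named list (by day) of named lists (by mode) of
#'   [affinity_matrix()] objects. Days with fewer than two alive bees are
#'   skipped with a warning.
#' @export
simulate_affinity_timeseries <- function(ground_truth, config,
                                         modes = c("proximity_count",
                                                   "trophallaxis_count",
                                                   "distance_gaussian",
                                                   "distance_max_minus",
                                                   "effect_mean_pos",
                                                   "effect_mean_neg",
                                                   "effect_cum_pos",
                                                   "effect_cum_neg")) {
  stopifnot(inherits(ground_truth, "colony_ground_truth"))
  if (config$role_bandwidth <= 0) stop("role_bandwidth must be > 0")
  roles <- ground_truth$roles
  with_seed(config$seed + 2L, {
    out <- list()
    for (day in seq_len(config$n_days)) {
      rd <- roles[roles$day == day, ]
      n <- nrow(rd)
      if (n < 2) {
        warning(sprintf("day %d has fewer than two alive bees; skipped", day))
        next
      }
      ids <- rd$bee_id
      rho <- rd$rho
      dr <- abs(outer(rho, rho, "-"))
      lam <- role_affinity_kernel(dr, config$affinity_rate_max,
                                  config$role_bandwidth)
      diag(lam) <- 0
      day_modes <- list()

      sym_count <- function(rate_mat) {
        m <- matrix(0, n, n)
        ut <- upper.tri(m)
        m[ut] <- stats::rpois(sum(ut), rate_mat[ut])
        m + t(m)
      }
      if ("proximity_count" %in% modes) {
        day_modes$proximity_count <- affinity_matrix(
          sym_count(lam), ids, day, "proximity_count", symmetric = TRUE)
      }
      if ("trophallaxis_count" %in% modes) {
        day_modes$trophallaxis_count <- affinity_matrix(
          sym_count(lam / 4), ids, day, "trophallaxis_count", symmetric = TRUE)
      }
      if (any(c("distance_gaussian", "distance_max_minus") %in% modes)) {
        D <- matrix(0, n, n)
        ut <- upper.tri(D)
        D[ut] <- 20 + 180 * dr[ut] + abs(stats::rnorm(sum(ut), 0, 15))
        D <- D + t(D)
        diag(D) <- 0
        dm <- distances_to_affinities(D)
        if ("distance_gaussian" %in% modes) {
          day_modes$distance_gaussian <- affinity_matrix(
            dm$gaussian, ids, day, "distance_gaussian", symmetric = TRUE)
        }
        if ("distance_max_minus" %in% modes) {
          day_modes$distance_max_minus <- affinity_matrix(
            dm$max_minus, ids, day, "distance_max_minus", symmetric = TRUE)
        }
      }
      if (any(grepl("^effect_", modes))) {
        n_ev <- matrix(0, n, n)
        ut <- upper.tri(n_ev)
        n_ev[ut] <- stats::rpois(sum(ut), lam[ut] / 4)
        n_ev <- n_ev + t(n_ev)
        mp <- matrix(0, n, n); mn <- matrix(0, n, n)
        cp <- matrix(0, n, n); cn <- matrix(0, n, n)
        idx <- which(n_ev > 0 & row(n_ev) != col(n_ev))
        if (length(idx) > 0) {
          m <- n_ev[idx]
          # focal i, partner j: speed change pulled toward partner's role
          mu <- 0.8 * (rho[col(n_ev)[idx]] - rho[row(n_ev)[idx]])
          grp <- rep(seq_along(idx), m)
          dmean <- stats::rnorm(sum(m), rep(mu, m), 0.6)
          dcum <- stats::rnorm(sum(m), rep(30 * mu, m), 25)
          acc <- function(v) {
            s <- rowsum(v, grp)
            out <- numeric(length(idx))
            out[as.integer(rownames(s))] <- s
            out
          }
          mp[idx] <- acc(pmax(dmean, 0))
          mn[idx] <- acc(pmax(-dmean, 0))
          cp[idx] <- acc(pmax(dcum, 0))
          cn[idx] <- acc(pmax(-dcum, 0))
        }
        eff <- list(effect_mean_pos = mp, effect_mean_neg = mn,
                    effect_cum_pos = cp, effect_cum_neg = cn)
        for (nm in intersect(names(eff), modes)) {
          day_modes[[nm]] <- affinity_matrix(eff[[nm]], ids, day, nm,
                                             symmetric = FALSE)
        }
      }
      out[[as.character(day)]] <- day_modes
    }
    out
  })
}

#' Simulate per-bee daily detection counts
#'
#' Alive days draw counts from a high-mean Poisson; dead and pre-emergence
#' days from the configured false-positive rate. This is the input regime
#' of the changepoint lifetime model.
#'
#' @param ground_truth a `colony_ground_truth`.
#' @param config the generating [colony_config()].
#' @param alive_mean expected daily detection count while alive.
#' @return data frame bee_id, day, count (integer) covering days
#'   `1..n_days` for every bee.
#' @export
simulate_detection_counts <- function(ground_truth, config, alive_mean = 100) {
  stopifnot(inherits(ground_truth, "colony_ground_truth"))
  with_seed(config$seed + 3L, {
    bees <- ground_truth$bees
    days <- seq_len(config$n_days)
    grid <- expand.grid(bee_id = bees$bee_id, day = days,
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$bee_id, grid$day), ]
    e <- bees$emergence_day[match(grid$bee_id, bees$bee_id)]
    d <- bees$death_day[match(grid$bee_id, bees$bee_id)]
    alive <- grid$day >= e & grid$day < d
    grid$count <- ifelse(alive,
                         stats::rpois(nrow(grid), alive_mean),
                         stats::rpois(nrow(grid), config$detection_noise$rate))
    rownames(grid) <- NULL
    grid
  })
}

#' Write a detection table to CSV
#'
#' Canonical column order: bee_id, timestamp_utc, day, x_mm, y_mm,
#' orientation_rad, side, confidence.
#' @param detections detection data frame.
#' @param path output file.
#' @export
write_detections_csv <- function(detections, path) {
  cols <- c("bee_id", "timestamp_utc", "day", "x_mm", "y_mm",
            "orientation_rad", "side", "confidence")
  utils::write.csv(detections[, cols], path, row.names = FALSE)
}

#' Read a detection table from CSV
#' @param path CSV written by [write_detections_csv()].
#' @export
read_detections_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write daily area maps as JSON
#'
#' One record per (day, side, label) with the polygon vertex list in mm;
#' both comb sides share the annotation.
#' @param area_maps per-day named polygon lists, as from [simulate_colony()].
#' @param path output file.
#' @export
write_area_maps_json <- function(area_maps, path) {
  recs <- list()
  for (day in names(area_maps)) {
    for (label in names(area_maps[[day]])) {
      poly <- unname(as.matrix(area_maps[[day]][[label]]))
      for (side in 0:1) {
        recs[[length(recs) + 1]] <- list(
          day = as.integer(day), side = side, label = label,
          polygon = apply(poly, 1, function(p) c(p[1], p[2]), simplify = FALSE)
        )
      }
    }
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
}
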
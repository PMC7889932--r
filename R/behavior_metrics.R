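#' Compute the nest-area task descriptor
#'
#' For each bee and day, at most one high-confidence detection
#' (confidence > `confidence_min`) is sampled per minute (the
#' highest-confidence detection within the minute); the sampled positions
#' are assigned to the annotated nest areas and the per-area counts are
#' normalized to 1. Samples outside every area are ignored for the
#' descriptor. Overlapping annotations resolve by the priority order
#' `exit > dance_floor > brood > honey`.
#'
#' @param detections detection table.
#' @param area_maps either one named polygon list (static geometry) or a
#'   per-day list of such lists, named by day.
#' @param confidence_min minimum decoding confidence of sampled detections.
#' @param priority area priority for overlapping polygons.
#' @return data frame `bee_id`, `day`, `frac_brood`, `frac_dance_floor`,
#'   `frac_honey`, `frac_exit`, `n_samples`. Bee-days without any in-area
#'   sample are absent.
#' @export
compute_task_descriptor <- function(detections, area_maps,
                                    confidence_min = 0.9,
                                    priority = c("exit", "dance_floor",
                                                 "brood", "honey")) {
  static_map <- !is.null(names(area_maps)) &&
    all(c("brood", "dance_floor", "honey", "exit") %in% names(area_maps))
  det <- detections[detections$confidence > confidence_min, , drop = FALSE]
  if (nrow(det) == 0) {
    return(data.frame(bee_id = character(), day = integer(),
                      frac_brood = numeric(), frac_dance_floor = numeric(),
                      frac_honey = numeric(), frac_exit = numeric(),
                      n_samples = integer()))
  }
  det$minute <- floor(det$timestamp_utc / 60)
  # highest-confidence detection per bee-minute (ties: first)
  ord <- order(det$bee_id, det$minute, -det$confidence)
  det <- det[ord, ]
  det <- det[!duplicated(det[, c("bee_id", "minute")]), ]
  rows <- list()
  for (d in sort(unique(det$day))) {
    areas <- if (static_map) area_maps else area_maps[[as.character(d)]]
    if (is.null(areas)) stop("no area map for day ", d)
    dd <- det[det$day == d, , drop = FALSE]
    area_lab <- rep(NA_character_, nrow(dd))
    for (lab in rev(priority)) {
      inside <- point_in_polygon(dd$x_mm, dd$y_mm, areas[[lab]])
      area_lab[inside] <- lab
    }
    for (id in unique(dd$bee_id)) {
      labs <- area_lab[dd$bee_id == id]
      labs <- labs[!is.na(labs)]
      if (length(labs) == 0) next
      counts <- vapply(c("brood", "dance_floor", "honey", "exit"),
                       function(a) sum(labs == a), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        bee_id = id, day = d,
        frac_brood = counts[1] / length(labs),
        frac_dance_floor = counts[2] / length(labs),
        frac_honey = counts[3] / length(labs),
        frac_exit = counts[4] / length(labs),
        n_samples = length(labs), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(bee_id = character(), day = integer(),
                      frac_brood = numeric(), frac_dance_floor = numeric(),
                      frac_honey = numeric(), frac_exit = numeric(),
                      n_samples = integer())
  }
  rownames(out) <- NULL
  out
}

#' Circadian rhythmicity of a velocity series
#'
#' Least-squares fit of a single fixed-frequency sine wave
#' `a sin(wt) + b cos(wt) + c` with a 24-h period to the velocities of a
#' 3-day window centred on `center_day`. The power is
#' `P = 1 - SSE_sine / SSE_constant`, where `SSE_constant` is the residual
#' of the mean-only model; because the sine model nests the constant one,
#' `P` lies in \[0, 1\] and measures how much velocity variation the
#' circadian oscillation explains. The peak time is the UTC hour at which
#' the fitted sinusoid is maximal.
#'
#' @param velocities data frame from [compute_velocity()] for one bee.
#' @param center_day focal day.
#' @param window_days window length in days (default 3: the focal day plus
#'   its neighbours).
#' @return list with `power`, `peak_time_h`, `n`; `NA`s when fewer than 4
#'   samples are available.
#' @export
circadian_power <- function(velocities, center_day, window_days = 3) {
  half <- (window_days - 1) / 2
  sel <- velocities$day >= center_day - half & velocities$day <= center_day + half
  v <- velocities$speed[sel]
  t <- velocities$timestamp_utc[sel]
  if (length(v) < 4) {
    return(list(power = NA_real_, peak_time_h = NA_real_, n = length(v)))
  }
  w <- 2 * pi / 86400
  X <- cbind(s = sin(w * t), c = cos(w * t))
  fit <- stats::lm.fit(cbind(1, X), v)
  sse_sine <- sum(fit$residuals^2)
  sse_const <- sum((v - mean(v))^2)
  if (sse_const == 0) {
    return(list(power = 0, peak_time_h = NA_real_, n = length(v)))
  }
  a <- fit$coefficients[2]
  b <- fit$coefficients[3]
  theta_peak <- atan2(a, b) # maximizes a sin(theta) + b cos(theta)
  peak_h <- (theta_peak / (2 * pi) * 24) %% 24
  list(power = max(0, 1 - sse_sine / sse_const),
       peak_time_h = as.numeric(peak_h), n = length(v))
}

#' Day- and night-time mean velocities
#'
#' Means of the velocities collected in the 3-day rolling window, over
#' 09:00-18:00 UTC (day) and 21:00-06:00 UTC (night; wraps midnight).
#'
#' @inheritParams circadian_power
#' @return list with `day_velocity`, `night_velocity` (mm/s; `NA` for an
#'   empty window).
#' @export
day_night_velocity <- function(velocities, center_day, window_days = 3) {
  half <- (window_days - 1) / 2
  sel <- velocities$day >= center_day - half & velocities$day <= center_day + half
  v <- velocities$speed[sel]
  h <- (velocities$timestamp_utc[sel] %% 86400) / 3600
  day_sel <- h >= 9 & h < 18
  night_sel <- h >= 21 | h < 6
  list(day_velocity = if (any(day_sel)) mean(v[day_sel]) else NA_real_,
       night_velocity = if (any(night_sel)) mean(v[night_sel]) else NA_real_)
}

#' Per-bee-day movement metrics
#'
#' Convenience wrapper computing circadian power, peak time and day/night
#' velocities for every bee and day present in a velocity table.
#'
#' @param velocities data frame from [compute_velocity()].
#' @param days days to evaluate (default: all days in the table).
#' @param window_days rolling-window length.
#' @return data frame `bee_id`, `day`, `power`, `peak_time_h`,
#'   `day_velocity`, `night_velocity`.
#' @export
compute_circadian_metrics <- function(velocities, days = NULL,
                                      window_days = 3) {
  if (is.null(days)) days <- sort(unique(velocities$day))
  rows <- list()
  for (vb in split(velocities, velocities$bee_id)) {
    for (d in intersect(days, unique(vb$day))) {
      cp <- circadian_power(vb, d, window_days)
      dn <- day_night_velocity(vb, d, window_days)
      rows[[length(rows) + 1]] <- data.frame(
        bee_id = vb$bee_id[1], day = d, power = cp$power,
        peak_time_h = cp$peak_time_h, day_velocity = dn$day_velocity,
        night_velocity = dn$night_velocity, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
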
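#' Compute median-filtered movement speeds from a detection table
#'
#' Speed between consecutive detections of a bee is the Euclidean distance
#' divided by the elapsed time; the resulting series is median filtered
#' (default kernel 3, endpoints use shrunken windows). Each speed is
#' indexed by the timestamp of the leading detection of its pair. Duplicate
#' (bee, timestamp) rows are dropped before differencing.
#'
#' @param detections detection table (mm coordinates, seconds).
#' @param kernel odd median-filter kernel size.
#' @return data frame bee_id, timestamp_utc, day, speed (mm/s), sorted by
#'   bee and time. Bees with a single detection contribute no rows.
#' @export
compute_velocity <- function(detections, kernel = 3) {
  stopifnot(kernel %% 2 == 1)
  dup <- duplicated(detections[, c("bee_id", "timestamp_utc")])
  if (any(dup)) detections <- detections[!dup, , drop = FALSE]
  pieces <- lapply(split(detections, detections$bee_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    dt <- diff(d$timestamp_utc)
    if (any(dt <= 0)) stop("non-monotone timestamps for bee ", d$bee_id[1])
    sp <- sqrt(diff(d$x_mm)^2 + diff(d$y_mm)^2) / dt
    if (length(sp) >= 2) {
      k <- min(kernel, if (length(sp) %% 2 == 0) length(sp) - 1 else length(sp))
      if (k >= 3) sp <- as.numeric(stats::runmed(sp, k, endrule = "median"))
    }
    data.frame(bee_id = d$bee_id[1],
               timestamp_utc = d$timestamp_utc[-nrow(d)],
               day = d$day[-nrow(d)],
               speed = sp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(bee_id = character(), timestamp_utc = numeric(),
                      day = integer(), speed = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Detect pairwise proximity events
#'
#' Two bees are in proximity when their tags are closer than `max_dist_cm`
#' on the same frame and comb side. A proximity event is a maximal run of
#' at least `min_frames` consecutive co-detected in-proximity frames; a
#' co-detected frame at which the pair is farther apart breaks the run, as
#' does a gap of more than `max_frame_gap` frame slots (sides alternate, so
#' same-side frames are two slots apart). Downstream analyses use event
#' counts, not durations.
#'
#' @param detections detection table.
#' @param max_dist_cm proximity threshold (cm).
#' @param min_frames minimum run length in frames.
#' @param frame_rate nominal global frame rate (Hz) for binning timestamps.
#' @param max_frame_gap largest frame-slot gap that still continues a run.
#' @return data frame bee_a, bee_b (lexicographically ordered), day,
#'   start_utc, end_utc, n_frames.
#' @export
detect_proximity_events <- function(detections, max_dist_cm = 2,
                                    min_frames = 3, frame_rate = 3,
                                    max_frame_gap = 2) {
  det <- detections
  det$frame <- round(det$timestamp_utc * frame_rate)
  max_dist_mm <- max_dist_cm * 10
  # per (pair, side): frames co-detected, with in/out state
  recs <- list()
  key <- paste(det$frame, det$side)
  for (grp in split(seq_len(nrow(det)), key)) {
    if (length(grp) < 2) next
    g <- det[grp, ]
    g <- g[!duplicated(g$bee_id), , drop = FALSE]
    n <- nrow(g)
    if (n < 2) next
    dmat <- as.matrix(stats::dist(cbind(g$x_mm, g$y_mm)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- g$bee_id[i]; b <- g$bee_id[j]
        if (a > b) { tmp <- a; a <- b; b <- tmp }
        recs[[length(recs) + 1]] <- data.frame(
          bee_a = a, bee_b = b, frame = g$frame[1],
          timestamp_utc = max(g$timestamp_utc[c(i, j)]),
          day = g$day[1],
          within = dmat[i, j] < max_dist_mm, stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(bee_a = character(), bee_b = character(),
                      day = integer(), start_utc = numeric(),
                      end_utc = numeric(), n_frames = integer())
  if (length(recs) == 0) return(empty)
  co <- do.call(rbind, recs)
  events <- list()
  for (pg in split(co, paste(co$bee_a, co$bee_b))) {
    pg <- pg[order(pg$frame), ]
    run_start <- NULL
    run_len <- 0L
    prev_frame <- NULL
    flush <- function(end_row) {
      if (run_len >= min_frames) {
        events[[length(events) + 1]] <<- data.frame(
          bee_a = pg$bee_a[1], bee_b = pg$bee_b[1],
          day = pg$day[run_start],
          start_utc = pg$timestamp_utc[run_start],
          end_utc = pg$timestamp_utc[end_row],
          n_frames = run_len, stringsAsFactors = FALSE)
      }
    }
    for (r in seq_len(nrow(pg))) {
      gap_ok <- is.null(prev_frame) || (pg$frame[r] - prev_frame) <= max_frame_gap
      if (pg$within[r] && run_len > 0L && gap_ok) {
        run_len <- run_len + 1L
      } else {
        if (run_len > 0L) flush(r - 1L)
        run_len <- if (pg$within[r]) 1L else 0L
        run_start <- if (pg$within[r]) r else NULL
      }
      prev_frame <- pg$frame[r]
    }
    if (run_len > 0L) flush(nrow(pg))
  }
  if (length(events) == 0) return(empty)
  out <- do.call(rbind, events)
  out <- out[order(out$day, out$start_utc, out$bee_a, out$bee_b), ]
  rownames(out) <- NULL
  out
}

#' Head offset from the thorax tag along the body axis (mm)
#' @export
HEAD_OFFSET_MM <- 3.19

#' Candidate gate on thorax distance for trophallaxis classification (cm)
#' @export
TROPHALLAXIS_GATE_CM <- c(0.731, 1.204)

#' Pairwise geometry of two detections in one frame
#'
#' Computes the features used to classify trophallaxis candidates: the
#' thorax (tag) distance, the distance between approximate head positions
#' `h_i = xy_i + d * (cos a_i, sin a_i)` with `d = 3.19` mm, and the
#' relative orientation (dot product of the unit heading vectors, in
#' \[-1, 1\]). Vectorised over rows.
#'
#' @param x_i,y_i,alpha_i thorax position (mm) and orientation (rad) of bee i.
#' @param x_j,y_j,alpha_j same for bee j.
#' @return data frame thorax_distance_cm, head_distance_cm,
#'   relative_orientation.
#' @export
pair_geometry <- function(x_i, y_i, alpha_i, x_j, y_j, alpha_j) {
  hx_i <- x_i + HEAD_OFFSET_MM * cos(alpha_i)
  hy_i <- y_i + HEAD_OFFSET_MM * sin(alpha_i)
  hx_j <- x_j + HEAD_OFFSET_MM * cos(alpha_j)
  hy_j <- y_j + HEAD_OFFSET_MM * sin(alpha_j)
  data.frame(
    thorax_distance_cm = sqrt((x_i - x_j)^2 + (y_i - y_j)^2) / 10,
    head_distance_cm = sqrt((hx_i - hx_j)^2 + (hy_i - hy_j)^2) / 10,
    relative_orientation = cos(alpha_i) * cos(alpha_j) +
      sin(alpha_i) * sin(alpha_j)
  )
}

#' Fit the stage-1 trophallaxis classifier
#'
#' A fast logistic regression on three geometric features (thorax distance,
#' head distance, relative orientation) of labelled pairs, used to discard
#' most non-trophallaxis encounters before a slower, pluggable stage-2
#' classifier.
#'
#' @param geometry data frame from [pair_geometry()].
#' @param labels 0/1 (or logical) trophallaxis labels.
#' @return fitted model of class `trophallaxis_stage1`.
#' @export
fit_trophallaxis_stage1 <- function(geometry, labels) {
  df <- cbind(geometry, y = as.numeric(labels))
  fit <- stats::glm(
    y ~ thorax_distance_cm + head_distance_cm + relative_orientation,
    family = stats::binomial(), data = df)
  structure(list(glm = fit), class = "trophallaxis_stage1")
}

#' Score trophallaxis candidates with the stage-1 classifier
#'
#' Pairs whose thorax distance falls outside the candidate gate
#' (0.731 to 1.204 cm) are rejected without scoring and return `NA`. The
#' decision threshold on the returned probabilities is a calibration
#' parameter, chosen on validation data to reach a target recall.
#'
#' @param geometry data frame from [pair_geometry()].
#' @param model a fitted `trophallaxis_stage1`, or a coefficient vector
#'   `c(intercept, thorax, head, orientation)`.
#' @param gate_cm thorax-distance candidate gate.
#' @return numeric vector of probabilities; `NA` for gated-out pairs.
#' @export
classify_trophallaxis_stage1 <- function(geometry, model,
                                         gate_cm = TROPHALLAXIS_GATE_CM) {
  in_gate <- geometry$thorax_distance_cm >= gate_cm[1] &
    geometry$thorax_distance_cm <= gate_cm[2]
  eta <- if (inherits(model, "trophallaxis_stage1")) {
    stats::predict(model$glm, newdata = geometry, type = "link")
  } else if (is.numeric(model) && length(model) == 4) {
    model[1] + model[2] * geometry$thorax_distance_cm +
      model[3] * geometry$head_distance_cm +
      model[4] * geometry$relative_orientation
  } else {
    stop("model must be a fitted trophallaxis_stage1 or 4 coefficients")
  }
  p <- stats::plogis(eta)
  p[!in_gate] <- NA_real_
  p
}

#' Per-contact velocity-change records
#'
#' For each proximity event of duration at most `max_duration` seconds and
#' separated from the pair's previous event by at least `min_gap` seconds,
#' computes for each partner as focal the change in mean speed between the
#' 30-s windows before the event start and after the event end
#' (`delta_mean`, mm/s) and the analogous change in cumulative distance
#' (`delta_cumulative`, mm). Events with an empty velocity window for a
#' focal are skipped for that focal.
#'
#' @param events data frame from [detect_proximity_events()].
#' @param velocities data frame from [compute_velocity()].
#' @param max_duration maximum event duration (s).
#' @param min_gap minimum gap since the pair's previous event (s).
#' @param window pre/post window length (s).
#' @return data frame focal, partner, day, start_utc, end_utc, delta_mean,
#'   delta_cumulative.
#' @export
extract_interaction_effects <- function(events, velocities,
                                        max_duration = 60, min_gap = 5,
                                        window = 30) {
  out <- list()
  vel_by_bee <- split(velocities, velocities$bee_id)
  window_stats <- function(bee, lo, hi) {
    v <- vel_by_bee[[bee]]
    if (is.null(v)) return(NULL)
    sel <- v$timestamp_utc >= lo & v$timestamp_utc < hi
    if (!any(sel)) return(NULL)
    ts <- v$timestamp_utc[sel]
    sp <- v$speed[sel]
    dt <- c(diff(ts), hi - ts[length(ts)])
    list(mean = mean(sp), dist = sum(sp * dt))
  }
  for (pg in split(events, paste(events$bee_a, events$bee_b))) {
    pg <- pg[order(pg$start_utc), ]
    prev_end <- -Inf
    for (r in seq_len(nrow(pg))) {
      dur <- pg$end_utc[r] - pg$start_utc[r]
      gap <- pg$start_utc[r] - prev_end
      prev_end <- pg$end_utc[r]
      if (dur > max_duration || gap < min_gap) next
      for (focal_role in 1:2) {
        focal <- if (focal_role == 1) pg$bee_a[r] else pg$bee_b[r]
        partner <- if (focal_role == 1) pg$bee_b[r] else pg$bee_a[r]
        before <- window_stats(focal, pg$start_utc[r] - window, pg$start_utc[r])
        after <- window_stats(focal, pg$end_utc[r],
                              pg$end_utc[r] + window)
        if (is.null(before) || is.null(after)) {
          message(sprintf("no velocity samples around event (%s, %s) at %s; skipped",
                          focal, partner, pg$start_utc[r]))
          next
        }
        out[[length(out) + 1]] <- data.frame(
          focal = focal, partner = partner, day = pg$day[r],
          start_utc = pg$start_utc[r], end_utc = pg$end_utc[r],
          delta_mean = after$mean - before$mean,
          delta_cumulative = after$dist - before$dist,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(focal = character(), partner = character(),
                      day = integer(), start_utc = numeric(),
                      end_utc = numeric(), delta_mean = numeric(),
                      delta_cumulative = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
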
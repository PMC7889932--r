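#' Construct a daily affinity matrix
#'
#' An affinity matrix holds the pairwise interaction strength for one
#' interaction mode on one day, indexed by the bees alive that day. Values
#' are nonnegative with a zero diagonal; symmetric modes (counts,
#' distances) satisfy `m == t(m)`, directed movement-effect modes do not
#' (rows are the focal individual).
#'
#' @param values n x n nonnegative numeric matrix.
#' @param bee_ids character vector of the n bees, in row/column order.
#' @param day focal day.
#' @param mode mode label, e.g. `"proximity_count"`.
#' @param symmetric whether the mode is undirected.
#' @return object of class `affinity_matrix` (a matrix with attributes
#'   `bee_ids`, `day`, `mode`, `symmetric`).
#' @export
affinity_matrix <- function(values, bee_ids, day, mode, symmetric = TRUE) {
  values <- as.matrix(values)
  n <- length(bee_ids)
  stopifnot(nrow(values) == n, ncol(values) == n)
  if (any(values < 0)) stop("affinity values must be >= 0")
  if (any(diag(values) != 0)) stop("affinity diagonal must be zero")
  if (symmetric && !isTRUE(all.equal(values, t(values), tolerance = 1e-12))) {
    stop("symmetric mode but matrix != its transpose")
  }
  dimnames(values) <- list(bee_ids, bee_ids)
  structure(values, bee_ids = bee_ids, day = day, mode = mode,
            symmetric = symmetric, class = c("affinity_matrix", "matrix", "array"))
}

is_symmetric_mode <- function(m) isTRUE(attr(m, "symmetric"))

#' Build a symmetric count affinity matrix from interaction events
#'
#' Entry (i, j) is the number of events between i and j on the focal day;
#' event duration is ignored. Events that reference a bee outside the alive
#' set are dropped with a warning.
#'
#' @param events data frame with columns `bee_a`, `bee_b`, `day`.
#' @param alive_bees character vector of bees alive that day.
#' @param day focal day.
#' @param mode mode label (default `"proximity_count"`).
#' @return an [affinity_matrix()].
#' @export
build_count_matrix <- function(events, alive_bees, day,
                               mode = "proximity_count") {
  n <- length(alive_bees)
  m <- matrix(0, n, n)
  ev <- events[events$day == day, , drop = FALSE]
  ok <- ev$bee_a %in% alive_bees & ev$bee_b %in% alive_bees
  if (any(!ok)) {
    warning(sprintf("%d event(s) reference bees not alive on day %s; dropped",
                    sum(!ok), day))
    ev <- ev[ok, , drop = FALSE]
  }
  if (nrow(ev) > 0) {
    ia <- match(ev$bee_a, alive_bees)
    ib <- match(ev$bee_b, alive_bees)
    for (r in seq_len(nrow(ev))) {
      m[ia[r], ib[r]] <- m[ia[r], ib[r]] + 1
      m[ib[r], ia[r]] <- m[ib[r], ia[r]] + 1
    }
  }
  affinity_matrix(m, alive_bees, day, mode, symmetric = TRUE)
}

# Shared transform: daily mean-distance matrix -> two similarity matrices.
# gamma = max(D) / 4; Gaussian similarity exp(-d^2 / (2 gamma^2)) and
# max-minus similarity max(D) - d. Pairs with no observed distance (NA)
# receive affinity 0 in both.
distances_to_affinities <- function(D) {
  obs <- !is.na(D) & row(D) != col(D)
  if (!any(obs)) stop("no pairwise distances observed")
  dmax <- max(D[obs])
  gamma <- dmax / 4
  if (gamma <= 0) stop("degenerate distances: max(D) must be > 0")
  g <- exp(-D^2 / (2 * gamma^2))
  mm <- dmax - D
  g[!obs] <- 0
  mm[!obs] <- 0
  diag(g) <- 0
  diag(mm) <- 0
  list(gaussian = g, max_minus = mm, gamma = gamma, max_distance = dmax)
}

#' Build Euclidean-proximity affinity matrices for one day
#'
#' Computes the daily mean pairwise distance between bees over the frames
#' in which both were visible (same frame bin, same comb side), then
#' applies a Gaussian similarity `exp(-d^2 / (2 gamma^2))` with
#' `gamma = max(D) / 4`, and a second transform subtracting from the
#' maximum distance. Pairs never co-visible get affinity 0 in both modes.
#'
#' @param detections detection table (mm coordinates).
#' @param alive_bees bees alive on the day.
#' @param day focal day.
#' @param frame_rate nominal camera rate (Hz) used to bin timestamps.
#' @return list with elements `gaussian` and `max_minus`
#'   ([affinity_matrix()]s) and `params` (gamma, max distance).
#' @export
build_distance_matrices <- function(detections, alive_bees, day,
                                    frame_rate = 3) {
  det <- detections[detections$day == day &
                      detections$bee_id %in% alive_bees, , drop = FALSE]
  if (nrow(det) == 0) stop("no detections for the requested day")
  det$frame <- round(det$timestamp_utc * frame_rate)
  n <- length(alive_bees)
  sum_d <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  key <- paste(det$frame, det$side)
  for (grp in split(seq_len(nrow(det)), key)) {
    if (length(grp) < 2) next
    idx <- match(det$bee_id[grp], alive_bees)
    dup <- duplicated(idx)
    idx <- idx[!dup]; grp <- grp[!dup]
    if (length(grp) < 2) next
    dmat <- as.matrix(stats::dist(cbind(det$x_mm[grp], det$y_mm[grp])))
    sum_d[idx, idx] <- sum_d[idx, idx] + dmat
    cnt[idx, idx] <- cnt[idx, idx] + (1L - diag(length(idx)))
  }
  D <- sum_d / cnt
  D[cnt == 0] <- NA
  diag(D) <- 0
  aff <- distances_to_affinities(D)
  list(
    gaussian = affinity_matrix(aff$gaussian, alive_bees, day,
                               "distance_gaussian", symmetric = TRUE),
    max_minus = affinity_matrix(aff$max_minus, alive_bees, day,
                                "distance_max_minus", symmetric = TRUE),
    params = list(gamma = aff$gamma, max_distance = aff$max_distance)
  )
}

#' Build directed interaction-effect affinity matrices for one day
#'
#' Speed changes after contacts are split by sign into four directed
#' matrices: positive mean changes (`effect_mean_pos`), magnitudes of
#' negative mean changes (`effect_mean_neg`), and the analogous cumulative
#' variants. Multiple records for the same ordered (focal, partner) pair in
#' a day are summed. Rows index the focal individual.
#'
#' @param records data frame from [extract_interaction_effects()] with
#'   columns `focal`, `partner`, `day`, `delta_mean`, `delta_cumulative`.
#' @param alive_bees bees alive on the day.
#' @param day focal day.
#' @return named list of four directed [affinity_matrix()]s.
#' @export
build_interaction_effect_matrices <- function(records, alive_bees, day) {
  n <- length(alive_bees)
  mats <- list(effect_mean_pos = matrix(0, n, n),
               effect_mean_neg = matrix(0, n, n),
               effect_cum_pos = matrix(0, n, n),
               effect_cum_neg = matrix(0, n, n))
  rec <- records[records$day == day &
                   records$focal %in% alive_bees &
                   records$partner %in% alive_bees, , drop = FALSE]
  if (nrow(rec) > 0) {
    i <- match(rec$focal, alive_bees)
    j <- match(rec$partner, alive_bees)
    for (r in seq_len(nrow(rec))) {
      dm <- rec$delta_mean[r]
      dc <- rec$delta_cumulative[r]
      if (is.finite(dm)) {
        if (dm > 0) mats$effect_mean_pos[i[r], j[r]] <-
            mats$effect_mean_pos[i[r], j[r]] + dm
        if (dm < 0) mats$effect_mean_neg[i[r], j[r]] <-
            mats$effect_mean_neg[i[r], j[r]] - dm
      }
      if (is.finite(dc)) {
        if (dc > 0) mats$effect_cum_pos[i[r], j[r]] <-
            mats$effect_cum_pos[i[r], j[r]] + dc
        if (dc < 0) mats$effect_cum_neg[i[r], j[r]] <-
            mats$effect_cum_neg[i[r], j[r]] - dc
      }
    }
  }
  lapply(stats::setNames(names(mats), names(mats)), function(nm) {
    affinity_matrix(mats[[nm]], alive_bees, day, nm, symmetric = FALSE)
  })
}

#' Rank-transform an affinity matrix
#'
#' Off-diagonal affinities are replaced by their ranks, affinely rescaled so
#' the smallest affinity maps to 0 and the largest to 1. Identical
#' affinities share a rank (average rank). Symmetric matrices are ranked
#' over unordered pairs so symmetry is preserved; directed matrices over all
#' ordered off-diagonal entries. A constant matrix maps to 0.5 everywhere
#' off the diagonal (no order to assert). Zero affinities (pairs that never
#' interacted) participate as the lowest tie.
#'
#' @param m an [affinity_matrix()].
#' @return the rank-transformed [affinity_matrix()], values in \[0, 1\].
#' @export
rank_transform <- function(m) {
  stopifnot(inherits(m, "affinity_matrix"))
  sym <- is_symmetric_mode(m)
  out <- unclass(m)
  attrs <- attributes(m)
  if (sym) {
    ut <- upper.tri(out)
    v <- out[ut]
    out[ut] <- scaled_ranks(v)
    out[lower.tri(out)] <- t(out)[lower.tri(out)]
  } else {
    off <- row(out) != col(out)
    out[off] <- scaled_ranks(out[off])
  }
  diag(out) <- 0
  attributes(out) <- attrs
  out
}

scaled_ranks <- function(v) {
  if (length(v) == 0) return(v)
  r <- rank(v, ties.method = "average")
  rng <- range(r)
  if (rng[1] == rng[2]) return(rep(0.5, length(v)))
  (r - rng[1]) / (rng[2] - rng[1])
}

#' Write an affinity matrix as Matrix Market plus a bee index sidecar
#'
#' @param m an [affinity_matrix()].
#' @param mtx_path path of the `.mtx` file; the sidecar index (row number to
#'   bee_id) is written next to it with suffix `.index.csv`.
#' @export
write_affinity_mtx <- function(m, mtx_path) {
  stopifnot(inherits(m, "affinity_matrix"))
  v <- unclass(m)
  attributes(v) <- list(dim = dim(m))
  nz <- which(v != 0, arr.ind = TRUE)
  con <- file(mtx_path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate real general", con)
  writeLines(sprintf("%d %d %d", nrow(v), ncol(v), nrow(nz)), con)
  if (nrow(nz) > 0) {
    writeLines(sprintf("%d %d %.17g", nz[, 1], nz[, 2], v[nz]), con)
  }
  idx <- data.frame(row = seq_along(attr(m, "bee_ids")),
                    bee_id = attr(m, "bee_ids"))
  utils::write.csv(idx, sub("\\.mtx$", ".index.csv", mtx_path),
                   row.names = FALSE)
  invisible(mtx_path)
}

#' Read an affinity matrix written by [write_affinity_mtx()]
#' @param mtx_path path of the `.mtx` file.
#' @param day,mode,symmetric metadata to attach.
#' @export
read_affinity_mtx <- function(mtx_path, day = NA, mode = "unknown",
                              symmetric = TRUE) {
  lines <- readLines(mtx_path)
  lines <- lines[!startsWith(lines, "%")]
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  m <- matrix(0, hdr[1], hdr[2])
  if (hdr[3] > 0) {
    rec <- do.call(rbind, lapply(strsplit(trimws(lines[-1]), "\\s+"), as.numeric))
    m[cbind(rec[, 1], rec[, 2])] <- rec[, 3]
  }
  idx <- utils::read.csv(sub("\\.mtx$", ".index.csv", mtx_path),
                         stringsAsFactors = FALSE)
  affinity_matrix(m, idx$bee_id[order(idx$row)], day, mode, symmetric)
}
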
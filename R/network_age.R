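#' Fit the CCA map from spectral factors to network age
#'
#' Canonical correlation analysis between the standardized pooled daily
#' spectral factors (one row per bee-day, all days pooled) and the
#' four-area task descriptor. The first `k` factor-side canonical
#' directions form the projection; dimension 1 of the projected series is
#' "network age". Because fitting pools all days, the projection can only
#' encode interaction structure that is consistent over time.
#'
#' @param factors pooled daily factors (data frame from
#'   [compute_daily_factors()]).
#' @param descriptors task-descriptor table with columns `bee_id`, `day`
#'   and the four area-fraction columns; rows with missing descriptors are
#'   dropped.
#' @param k number of projection dimensions (default 3).
#' @param descriptor_cols names of the four fraction columns.
#' @return object of class `network_age_map`: feature standardization
#'   parameters, F x k projection, variant label, and the first canonical
#'   correlation.
#' @export
fit_cca_map <- function(factors, descriptors, k = 3,
                        descriptor_cols = c("frac_brood", "frac_dance_floor",
                                            "frac_honey", "frac_exit")) {
  fc <- factor_columns(factors)
  merged <- merge(factors, descriptors, by = c("bee_id", "day"))
  merged <- merged[stats::complete.cases(merged[, c(fc, descriptor_cols)]), ]
  X <- as.matrix(merged[, fc])
  Y <- as.matrix(merged[, descriptor_cols])
  fit_linear_map(X, Y, fc, k, variant = "cca_task")
}

#' Fit the unsupervised PCA variant of the network-age map
#'
#' Principal directions of the standardized pooled factors; no location
#' descriptor is needed.
#'
#' @inheritParams fit_cca_map
#' @param k number of principal components to keep (default 1).
#' @export
fit_pca_map <- function(factors, k = 1) {
  fc <- factor_columns(factors)
  X <- as.matrix(factors[, fc])
  if (nrow(X) < length(fc)) {
    stop("fewer bee-day rows than factor dimensions; reduce n_dims or add data")
  }
  std <- standardize_columns(X)
  pc <- stats::prcomp(std$X, center = FALSE, scale. = FALSE)
  proj <- pc$rotation[, seq_len(k), drop = FALSE]
  proj_full <- matrix(0, length(fc), k,
                      dimnames = list(fc, paste0("dim", seq_len(k))))
  proj_full[std$keep, ] <- proj
  structure(list(center = std$center, scale = std$scale, projection = proj_full,
                 header = fc, variant = "pca", cor1 = NA_real_,
                 explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]),
            class = "network_age_map")
}

#' Fit a targeted embedding map against a scalar property
#'
#' CCA between the standardized pooled factors and a single scalar target
#' per bee-day (e.g. days until death, time of peak activity, circadian
#' rhythmicity, day- or night-time velocity). The result is the factor-side
#' direction maximally correlated with the target.
#'
#' @inheritParams fit_cca_map
#' @param target data frame `bee_id`, `day`, `value`.
#' @param k output dimensions (default 1).
#' @export
fit_targeted_map <- function(factors, target, k = 1) {
  fc <- factor_columns(factors)
  merged <- merge(factors, target, by = c("bee_id", "day"))
  merged <- merged[stats::complete.cases(merged[, c(fc, "value")]), ]
  y <- merged$value
  if (stats::sd(y) == 0) stop("constant target: nothing to correlate with")
  fit_linear_map(as.matrix(merged[, fc]), matrix(y, ncol = 1), fc, k,
                 variant = "targeted")
}

fit_linear_map <- function(X, Y, header, k, variant) {
  if (nrow(X) < ncol(X)) {
    stop("fewer bee-day rows than factor dimensions; reduce n_dims or add data")
  }
  std <- standardize_columns(X)
  cc <- cca_whitened(std$X, Y)
  k_eff <- min(k, ncol(cc$xcoef))
  proj <- cc$xcoef[, seq_len(k_eff), drop = FALSE]
  proj_full <- matrix(0, length(header), k_eff,
                      dimnames = list(header, paste0("dim", seq_len(k_eff))))
  proj_full[std$keep, ] <- proj
  structure(list(center = std$center, scale = std$scale,
                 projection = proj_full, header = header, variant = variant,
                 cor1 = cc$cor[1]),
            class = "network_age_map")
}

# two-view CCA by SVD whitening; robust to rank-deficient views (directions
# in the null space get zero weight). Returns canonical correlations and
# the x-side directions expressed in the original columns.
cca_whitened <- function(X, Y, tol = 1e-10) {
  Xc <- sweep(as.matrix(X), 2, colMeans(X), "-")
  Yc <- sweep(as.matrix(Y), 2, colMeans(Y), "-")
  sx <- svd(Xc)
  sy <- svd(Yc)
  kx <- sum(sx$d > tol * sx$d[1])
  ky <- sum(sy$d > tol * sy$d[1])
  Ux <- sx$u[, seq_len(kx), drop = FALSE]
  Uy <- sy$u[, seq_len(ky), drop = FALSE]
  sv <- svd(crossprod(Ux, Uy))
  # back-transform the whitened directions to column space
  xcoef <- sx$v[, seq_len(kx), drop = FALSE] %*%
    (sv$u / sx$d[seq_len(kx)])
  ycoef <- sy$v[, seq_len(ky), drop = FALSE] %*%
    (sv$v / sy$d[seq_len(ky)])
  list(cor = pmin(sv$d, 1), xcoef = xcoef, ycoef = ycoef)
}

# z-score columns over pooled rows; zero-variance columns are dropped from
# the fit and contribute nothing when the map is applied.
standardize_columns <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  keep <- scale > 0
  Xs <- sweep(X[, keep, drop = FALSE], 2, center[keep], "-")
  Xs <- sweep(Xs, 2, scale[keep], "/")
  list(X = Xs, center = center, scale = ifelse(keep, scale, 1), keep = keep)
}

#' Apply a network-age map to daily factors
#'
#' Standardizes the factor columns with the parameters stored at fit time
#' and projects them; the factor column order must match the fitted header.
#'
#' @param factors daily factors.
#' @param map a `network_age_map`.
#' @return data frame `bee_id`, `day`, `raw_1` .. `raw_k`.
#' @export
apply_map <- function(factors, map) {
  stopifnot(inherits(map, "network_age_map"))
  fc <- factor_columns(factors)
  if (!identical(fc, map$header)) {
    stop("factor columns do not match the header the map was fitted on")
  }
  X <- as.matrix(factors[, fc])
  Xs <- sweep(sweep(X, 2, map$center, "-"), 2, map$scale, "/")
  raw <- Xs %*% map$projection
  colnames(raw) <- paste0("raw_", seq_len(ncol(raw)))
  cbind(factors[, c("bee_id", "day")], as.data.frame(raw))
}

#' Robust per-day scaling of raw network-age values
#'
#' For every day and dimension, an affine map sends the day's 5th
#' percentile to 0 and its 95th percentile to 40 (percentiles by linear
#' interpolation between order statistics), so 90% of each day's values lie
#' in \[0, 40\] and the scale is comparable to a worker bee's summer
#' lifespan in days. Values beyond the percentiles extend linearly outside
#' \[0, 40\]. A degenerate day (all values equal) maps to the midpoint 20
#' with a warning.
#'
#' @param raw data frame from [apply_map()].
#' @param lower,upper anchor values of the scaled range.
#' @param probs anchor percentiles.
#' @return object of class `network_age_series`: data frame `bee_id`,
#'   `day`, `network_age` (scaled dimension 1), `na_dim2`, `na_dim3`, ...
#'   plus the raw columns.
#' @export
robust_scale <- function(raw, lower = 0, upper = 40, probs = c(0.05, 0.95)) {
  raw_cols <- grep("^raw_", colnames(raw), value = TRUE)
  stopifnot(length(raw_cols) >= 1)
  out <- raw
  scaled_names <- c("network_age",
                    if (length(raw_cols) > 1) paste0("na_dim", 2:length(raw_cols)))
  for (i in seq_along(raw_cols)) {
    out[[scaled_names[i]]] <- NA_real_
  }
  for (d in unique(raw$day)) {
    sel <- raw$day == d
    for (i in seq_along(raw_cols)) {
      v <- raw[[raw_cols[i]]][sel]
      q <- stats::quantile(v, probs, type = 7, names = FALSE)
      if (q[2] == q[1]) {
        warning(sprintf("day %s dimension %d is degenerate; mapped to midpoint", d, i))
        out[[scaled_names[i]]][sel] <- (lower + upper) / 2
      } else {
        out[[scaled_names[i]]][sel] <-
          lower + (upper - lower) * (v - q[1]) / (q[2] - q[1])
      }
    }
  }
  cols <- c("bee_id", "day", scaled_names, raw_cols)
  out <- out[, cols]
  structure(out, class = c("network_age_series", "data.frame"),
            orientation = 1L)
}

#' Enforce shared directionality of network age and biological age
#'
#' The scale of network age is anchored so that low values correspond to
#' biologically younger bees. The series' pooled 5th- and 95th-percentile
#' groups are compared on mean biological age; when the low group is older,
#' the first raw dimension is negated and the per-day robust scaling is
#' recomputed.
#'
#' @param series a `network_age_series`.
#' @param bio_age data frame `bee_id`, `day`, `age` (days since emergence).
#' @return the (possibly flipped) series; attribute `orientation` is `+1`
#'   or `-1`.
#' @export
orient_directionality <- function(series, bio_age) {
  stopifnot(inherits(series, "network_age_series"))
  merged <- merge(as.data.frame(series), bio_age, by = c("bee_id", "day"))
  v <- merged$network_age
  q <- stats::quantile(v, c(0.05, 0.95), type = 7, names = FALSE)
  low_age <- mean(merged$age[v <= q[1]])
  high_age <- mean(merged$age[v >= q[2]])
  if (is.finite(low_age) && is.finite(high_age) && low_age > high_age) {
    raw <- as.data.frame(series)[, c("bee_id", "day",
                                     grep("^raw_", colnames(series), value = TRUE))]
    raw$raw_1 <- -raw$raw_1
    flipped <- robust_scale(raw)
    attr(flipped, "orientation") <- -1L
    return(flipped)
  }
  series
}

#' Compute a network-age series end to end
#'
#' Convenience wrapper: fit the map (CCA against the task descriptor by
#' default, or PCA / targeted variants), apply it, scale per day, and
#' orient against biological age.
#'
#' @param factors pooled daily factors.
#' @param descriptors task-descriptor table (CCA variant).
#' @param bio_age data frame `bee_id`, `day`, `age` for orientation.
#' @param variant one of `"cca_task"`, `"pca"`, `"targeted"`.
#' @param target scalar-target table for the targeted variant.
#' @param k projection dimensions.
#' @return list with `map` and `series`.
#' @export
network_age <- function(factors, descriptors = NULL, bio_age = NULL,
                        variant = c("cca_task", "pca", "targeted"),
                        target = NULL, k = 3) {
  variant <- match.arg(variant)
  map <- switch(variant,
    cca_task = fit_cca_map(factors, descriptors, k = k),
    pca = fit_pca_map(factors, k = k),
    targeted = fit_targeted_map(factors, target, k = k)
  )
  series <- robust_scale(apply_map(factors, map))
  if (!is.null(bio_age)) {
    series <- orient_directionality(series, bio_age)
  }
  list(map = map, series = series)
}

#' Serialize a network-age map to JSON
#' @param map a `network_age_map`.
#' @param path output file.
#' @export
write_network_age_map <- function(map, path) {
  stopifnot(inherits(map, "network_age_map"))
  jsonlite::write_json(list(
    variant = map$variant,
    header = map$header,
    center = unname(map$center),
    scale = unname(map$scale),
    projection = unname(as.matrix(map$projection)),
    cor1 = map$cor1
  ), path, auto_unbox = TRUE, digits = NA)
}

#' Read a network-age map written by [write_network_age_map()]
#' @param path JSON file.
#' @export
read_network_age_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  proj <- as.matrix(j$projection)
  dimnames(proj) <- list(j$header, paste0("dim", seq_len(ncol(proj))))
  structure(list(center = stats::setNames(j$center, j$header),
                 scale = stats::setNames(j$scale, j$header),
                 projection = proj, header = j$header,
                 variant = j$variant, cor1 = j$cor1),
            class = "network_age_map")
}
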
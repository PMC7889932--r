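#' @keywords internal
"_PACKAGE"

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Test whether points fall inside a polygon
#'
#' Even-odd (ray casting) rule; points exactly on a polygon edge or vertex
#' count as inside. Coordinates are metric (mm on the nest plane).
#'
#' @param x,y numeric vectors of point coordinates.
#' @param polygon two-column numeric matrix of vertices (closed implicitly).
#' @return logical vector, one entry per point.
#' @export
point_in_polygon <- function(x, y, polygon) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3)
  px <- polygon[, 1]
  py <- polygon[, 2]
  n <- nrow(polygon)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # boundary: point on segment (i, j)
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    within <- pmin(xi, xj) - 1e-12 <= x & x <= pmax(xi, xj) + 1e-12 &
      pmin(yi, yj) - 1e-12 <= y & y <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# Uniform sample of n points inside a polygon (rejection from bounding box).
sample_in_polygon <- function(n, polygon) {
  polygon <- as.matrix(polygon)
  xr <- range(polygon[, 1])
  yr <- range(polygon[, 2])
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cand_x <- stats::runif(m, xr[1], xr[2])
    cand_y <- stats::runif(m, yr[1], yr[2])
    keep <- point_in_polygon(cand_x, cand_y, polygon)
    out <- rbind(out, cbind(cand_x[keep], cand_y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

# TRUE if segments (p1,p2) and (p3,p4) properly intersect or touch.
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# TRUE when two polygons overlap (vertex containment or edge crossing).
polygons_overlap <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (any(point_in_polygon(b[, 1], b[, 2], a)) ||
      any(point_in_polygon(a[, 1], a[, 2], b))) {
    return(TRUE)
  }
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    p1 <- a[i, ]; p2 <- a[if (i == na) 1 else i + 1, ]
    for (j in seq_len(nb)) {
      p3 <- b[j, ]; p4 <- b[if (j == nb) 1 else j + 1, ]
      if (segments_intersect(p1, p2, p3, p4)) return(TRUE)
    }
  }
  FALSE
}

# Rectangle polygon helper (counter-clockwise).
rect_polygon <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# Truncated-normal draws (lower truncation only), by rejection.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, cand[cand >= lower])
  }
  out[seq_len(n)]
}

spearman <- function(x, y) {
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}
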
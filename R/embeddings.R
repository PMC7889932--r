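#' Spectral embedding of a symmetric affinity matrix
#'
#' Laplacian-eigenmap coordinates: eigenvectors of the symmetric normalized
#' adjacency `D^{-1/2} A D^{-1/2}` (equivalently, the smallest nontrivial
#' eigenvectors of the symmetric normalized Laplacian), skipping the trivial
#' leading eigenvector and taking the next `n_dims`. A uniform
#' `epsilon = 1e-8` is added to all off-diagonal affinities so the graph is
#' connected and every bee receives coordinates. Column signs are fixed so
#' the entry of largest magnitude is positive, making the decomposition
#' deterministic and equivariant under relabeling.
#'
#' @param m a symmetric [affinity_matrix()].
#' @param n_dims number of embedding dimensions (default 8).
#' @param epsilon uniform off-diagonal regularization.
#' @return object of class `mode_embedding`: list with `day`, `mode`,
#'   `bee_ids`, `coords` (n x n_dims matrix).
#' @export
spectral_embed <- function(m, n_dims = 8, epsilon = 1e-8) {
  stopifnot(inherits(m, "affinity_matrix"))
  if (!is_symmetric_mode(m)) stop("spectral_embed requires a symmetric mode; use bispectral_embed")
  n <- nrow(m)
  if (n <= n_dims) {
    stop(sprintf("matrix has %d bees; need n > n_dims (%d). Reduce n_dims.",
                 n, n_dims))
  }
  A <- unclass(m)
  attributes(A) <- list(dim = dim(m))
  A <- A + epsilon
  diag(A) <- 0
  dsq <- 1 / sqrt(rowSums(A))
  S <- A * (dsq %o% dsq)
  eig <- eigen(S, symmetric = TRUE)
  coords <- eig$vectors[, 2:(n_dims + 1), drop = FALSE]
  coords <- fix_column_signs(coords)
  structure(list(day = attr(m, "day"), mode = attr(m, "mode"),
                 bee_ids = attr(m, "bee_ids"), coords = coords),
            class = "mode_embedding")
}

fix_column_signs <- function(coords) {
  for (k in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  coords
}

#' Bispectral embedding of a directed affinity matrix
#'
#' Singular-vector coordinates of the degree-normalized matrix
#' `D_r^{-1/2} A D_c^{-1/2}`: left singular vectors give the row (focal)
#' embedding and right singular vectors the column (partner) embedding,
#' skipping the trivial leading pair and taking the next `n_dims`. The two
#' embeddings represent the two directions of an interaction.
#'
#' @param m a directed [affinity_matrix()] (square, nonnegative).
#' @param n_dims number of embedding dimensions.
#' @param epsilon uniform off-diagonal regularization.
#' @return list with `rows` and `cols`, each a `mode_embedding` whose mode
#'   label is suffixed `.rows` / `.cols`.
#' @export
bispectral_embed <- function(m, n_dims = 8, epsilon = 1e-8) {
  stopifnot(inherits(m, "affinity_matrix"))
  n <- nrow(m)
  if (n <= n_dims) {
    stop(sprintf("matrix has %d bees; need n > n_dims (%d). Reduce n_dims.",
                 n, n_dims))
  }
  A <- unclass(m)
  attributes(A) <- list(dim = dim(m))
  A <- A + epsilon
  diag(A) <- 0
  dr <- 1 / sqrt(rowSums(A))
  dc <- 1 / sqrt(colSums(A))
  M <- A * (dr %o% dc)
  sv <- svd(M, nu = n_dims + 1, nv = n_dims + 1)
  u <- sv$u[, 2:(n_dims + 1), drop = FALSE]
  v <- sv$v[, 2:(n_dims + 1), drop = FALSE]
  # couple the sign freedom of each (u_k, v_k) pair to the row side
  for (k in seq_len(ncol(u))) {
    i <- which.max(abs(u[, k]))
    if (u[i, k] < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
    }
  }
  mk <- function(coords, suffix) {
    structure(list(day = attr(m, "day"),
                   mode = paste0(attr(m, "mode"), suffix),
                   bee_ids = attr(m, "bee_ids"), coords = coords),
              class = "mode_embedding")
  }
  list(rows = mk(u, ".rows"), cols = mk(v, ".cols"))
}

#' Align embedding signs across consecutive days
#'
#' Eigen- and singular vectors are defined up to sign, so a dimension can
#' flip between days. For each dimension, day t is sign-flipped whenever
#' the Spearman correlation with the (already aligned) previous day over
#' the bees shared by both days is negative; flips chain forward from the
#' first day. Days sharing fewer than two bees with their predecessor keep
#' their sign, with a warning.
#'
#' @param embeddings list of `mode_embedding`s for one embedding set,
#'   ordered by day.
#' @return list with `embeddings` (aligned) and `flipped` (day x dimension
#'   logical matrix; first day all `FALSE`).
#' @export
align_signs <- function(embeddings) {
  stopifnot(length(embeddings) >= 1)
  n_dims <- ncol(embeddings[[1]]$coords)
  flipped <- matrix(FALSE, length(embeddings), n_dims)
  for (t in seq_along(embeddings)[-1]) {
    prev <- embeddings[[t - 1]]
    cur <- embeddings[[t]]
    shared <- intersect(prev$bee_ids, cur$bee_ids)
    if (length(shared) < 2) {
      warning(sprintf("days %s and %s share fewer than 2 bees; signs kept",
                      prev$day, cur$day))
      next
    }
    ip <- match(shared, prev$bee_ids)
    ic <- match(shared, cur$bee_ids)
    for (k in seq_len(n_dims)) {
      rho <- spearman(prev$coords[ip, k], cur$coords[ic, k])
      if (is.finite(rho) && rho < 0) {
        cur$coords[, k] <- -cur$coords[, k]
        flipped[t, k] <- TRUE
      }
    }
    embeddings[[t]] <- cur
  }
  list(embeddings = embeddings, flipped = flipped)
}

#' Assemble the daily spectral-factor matrix
#'
#' Horizontal concatenation of all aligned mode embeddings of one day in a
#' fixed mode order, giving the per-bee daily factor vector (8 dimensions
#' per embedding set; the full 4-symmetric + 4-directed configuration has
#' 12 sets and F = 96 columns). All sets must index exactly the same bees.
#'
#' @param mode_embeddings named list of `mode_embedding`s for one day; the
#'   list order defines the column-block order and must be held fixed
#'   across days.
#' @return data frame with `bee_id`, `day`, and factor columns named
#'   `<mode>.<dim>`.
#' @export
assemble_factors <- function(mode_embeddings) {
  stopifnot(length(mode_embeddings) >= 1)
  ref <- mode_embeddings[[1]]
  blocks <- lapply(mode_embeddings, function(e) {
    if (!identical(e$bee_ids, ref$bee_ids)) {
      stop("mode embeddings for one day must share an identical bee index")
    }
    b <- e$coords
    colnames(b) <- sprintf("%s.%d", e$mode, seq_len(ncol(b)))
    b
  })
  mat <- do.call(cbind, blocks)
  cbind(data.frame(bee_id = ref$bee_ids, day = ref$day,
                   stringsAsFactors = FALSE),
        as.data.frame(mat))
}

#' Compute aligned daily spectral factors from an affinity time series
#'
#' Runs the full embedding stage: per day and mode, spectral embedding for
#' symmetric modes and bispectral (row + column) embeddings for directed
#' modes; then per-embedding-set sign alignment across days; finally daily
#' factor assembly in a fixed mode order.
#'
#' @param affinities nested list days -> modes of [affinity_matrix()]s, as
#'   from [simulate_affinity_timeseries()].
#' @param n_dims embedding dimensions per set.
#' @param rank_transformed if `TRUE` (default) [rank_transform()] is applied
#'   to each matrix first.
#' @return data frame of pooled daily factors (rows: bee-days).
#' @export
compute_daily_factors <- function(affinities, n_dims = 8,
                                  rank_transformed = TRUE) {
  days <- names(affinities)
  stopifnot(length(days) >= 1)
  mode_names <- names(affinities[[1]])
  # build embedding sets: one per symmetric mode, two per directed mode
  sets <- list()
  for (mode in mode_names) {
    sym <- is_symmetric_mode(affinities[[1]][[mode]])
    per_day <- lapply(days, function(d) {
      m <- affinities[[d]][[mode]]
      if (is.null(m)) stop("mode ", mode, " missing on day ", d)
      if (rank_transformed) m <- rank_transform(m)
      if (sym) list(spectral_embed(m, n_dims)) else {
        be <- bispectral_embed(m, n_dims)
        list(be$rows, be$cols)
      }
    })
    n_sub <- length(per_day[[1]])
    for (s in seq_len(n_sub)) {
      seq_embs <- lapply(per_day, `[[`, s)
      sets[[seq_embs[[1]]$mode]] <- align_signs(seq_embs)$embeddings
    }
  }
  factors <- lapply(seq_along(days), function(ti) {
    assemble_factors(lapply(sets, `[[`, ti))
  })
  out <- do.call(rbind, factors)
  rownames(out) <- NULL
  out
}

factor_columns <- function(factors) {
  setdiff(colnames(factors), c("bee_id", "day"))
}
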
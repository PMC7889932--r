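#' Fit a task- or property-prediction model
#'
#' Predicts the task descriptor (or a scalar property) from per-bee-day
#' features such as network age or biological age. Families:
#' `multinomial_joint` fits all four area fractions jointly with a softmax
#' link and multinomial likelihood (rows weighted by `n_samples`);
#' `binomial_per_area` fits each area separately with a sigmoid link and
#' binomial likelihood; `gaussian_scalar` fits a scalar target with an
#' identity link and normal likelihood. Model classes: `linear` (a GLM) or
#' `small_nn` (one hidden layer of width 8 with tanh, trained full batch
#' from a fixed seed). A null model with intercepts only is always fitted;
#' the fit quality is McFadden's pseudo R-squared
#' `R2 = 1 - logLik1 / logLik0` (the coefficient of determination for the
#' gaussian family).
#'
#' @param features data frame `bee_id`, `day` plus feature columns.
#' @param response task-descriptor table (binomial/multinomial) or a data
#'   frame `bee_id`, `day`, `value` (gaussian).
#' @param family response family.
#' @param model_class `"linear"` or `"small_nn"`.
#' @param feature_cols feature columns to use (default: all non-key
#'   columns).
#' @param seed initialization seed for the neural variant.
#' @return object of class `task_model_fit` with log-likelihoods `ll1`,
#'   `ll0`, the score `r2`, parameters, and metadata needed by
#'   [predict_task_model()].
#' @export
fit_task_model <- function(features, response,
                           family = c("multinomial_joint",
                                      "binomial_per_area",
                                      "gaussian_scalar"),
                           model_class = c("linear", "small_nn"),
                           feature_cols = NULL, seed = 1) {
  family <- match.arg(family)
  model_class <- match.arg(model_class)
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(colnames(features), c("bee_id", "day"))
  }
  merged <- merge(features, response, by = c("bee_id", "day"))
  fit_task_model_merged(merged, feature_cols, family, model_class, seed)
}

# fitting core on a pre-merged (features + response) data frame; used by
# the bootstrap, which resamples rows and must not re-join on (bee, day)
fit_task_model_merged <- function(merged, feature_cols,
                                  family, model_class, seed = 1,
                                  start = NULL) {
  X <- as.matrix(merged[, feature_cols, drop = FALSE])
  if (family == "gaussian_scalar") {
    y <- merged$value
    w <- rep(1, length(y))
    keep <- stats::complete.cases(cbind(X, y))
  } else {
    area_cols <- c("frac_brood", "frac_dance_floor", "frac_honey", "frac_exit")
    Y <- as.matrix(merged[, area_cols])
    if (any(abs(rowSums(Y) - 1) > 1e-6)) {
      stop("descriptor rows must sum to 1")
    }
    w <- if ("n_samples" %in% colnames(merged)) merged$n_samples else rep(1, nrow(merged))
    keep <- stats::complete.cases(cbind(X, Y))
  }
  X <- X[keep, , drop = FALSE]
  w <- w[keep]
  fit <- switch(family,
    multinomial_joint = {
      Y <- Y[keep, , drop = FALSE]
      if (model_class == "linear") softmax_glm(X, Y, w, start = start)
      else nn_fit(X, Y, w, output = "softmax", seed = seed)
    },
    binomial_per_area = {
      Y <- Y[keep, , drop = FALSE]
      if (model_class == "linear") {
        fits <- lapply(seq_len(ncol(Y)), function(a) binomial_glm(X, Y[, a], w))
        list(params = lapply(fits, `[[`, "params"),
             ll1 = sum(vapply(fits, `[[`, numeric(1), "ll1")),
             ll0 = sum(vapply(fits, `[[`, numeric(1), "ll0")),
             per_area = fits)
      } else {
        nn_fit(X, Y, w, output = "sigmoid", seed = seed)
      }
    },
    gaussian_scalar = {
      y <- y[keep]
      if (model_class == "linear") gaussian_lm(X, y)
      else nn_fit(X, matrix(y, ncol = 1), rep(1, length(y)),
                  output = "identity", seed = seed)
    }
  )
  if (!is.finite(fit$ll1) || !is.finite(fit$ll0)) stop("non-finite likelihood")
  r2 <- if (family == "gaussian_scalar") fit$r2 else 1 - fit$ll1 / fit$ll0
  structure(list(family = family, model_class = model_class,
                 feature_cols = feature_cols, ll1 = fit$ll1, ll0 = fit$ll0,
                 r2 = r2, params = fit$params, null_params = fit$null_params,
                 n = length(w), fit = fit),
            class = "task_model_fit")
}

softmax_probs <- function(eta) {
  eta <- cbind(eta, 0) # reference class
  m <- eta[, 1]
  for (k in 2:ncol(eta)) m <- pmax(m, eta[, k])
  e <- exp(eta - m)
  e / rowSums(e)
}

# weighted multinomial logistic regression (softmax link, reference class 4),
# deterministic BFGS from zero initialization
softmax_glm <- function(X, Y, w, start = NULL) {
  K <- ncol(Y)
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  negll <- function(par) {
    B <- matrix(par, p, K - 1)
    P <- softmax_probs(Xd %*% B)
    -sum(w * rowSums(Y * log(pmax(P, 1e-300))))
  }
  neggr <- function(par) {
    B <- matrix(par, p, K - 1)
    P <- softmax_probs(Xd %*% B)
    G <- t(Xd) %*% (w * (P[, -K, drop = FALSE] - Y[, -K, drop = FALSE]))
    as.numeric(G)
  }
  if (is.null(start)) start <- rep(0, p * (K - 1))
  opt <- stats::optim(start, negll, neggr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  # null model: intercept-only MLE is the weighted mean composition
  pbar <- colSums(w * Y) / sum(w)
  ll0 <- sum(w * (Y %*% log(pmax(pbar, 1e-300))))
  list(params = matrix(opt$par, p, K - 1), ll1 = -opt$value, ll0 = ll0,
       null_params = pbar)
}

# weighted binomial logistic regression for one area
binomial_glm <- function(X, y, w) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  negll <- function(par) {
    mu <- stats::plogis(Xd %*% par)
    -sum(w * (y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300))))
  }
  neggr <- function(par) {
    mu <- stats::plogis(Xd %*% par)
    as.numeric(t(Xd) %*% (w * (mu - y)))
  }
  opt <- stats::optim(rep(0, p), negll, neggr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  ybar <- sum(w * y) / sum(w)
  ll0 <- sum(w * (y * log(max(ybar, 1e-300)) +
                    (1 - y) * log(max(1 - ybar, 1e-300))))
  list(params = opt$par, ll1 = -opt$value, ll0 = ll0, null_params = ybar)
}

gaussian_lm <- function(X, y) {
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  ll1 <- -n / 2 * (log(2 * pi * rss / n) + 1)
  ll0 <- -n / 2 * (log(2 * pi * tss / n) + 1)
  list(params = stats::coef(fit), ll1 = ll1, ll0 = ll0,
       null_params = mean(y), r2 = 1 - rss / tss)
}

# one-hidden-layer network (width `hidden`, tanh), full-batch BFGS with
# analytic gradients and a fixed-seed initialization
nn_fit <- function(X, Y, w, output, hidden = 8, seed = 1, lambda = 1e-6,
                   maxit = 300) {
  p <- ncol(X)
  K <- ncol(Y)
  n_par <- (p + 1) * hidden + (hidden + 1) * K
  unpack <- function(par) {
    W1 <- matrix(par[seq_len(p * hidden)], p, hidden)
    o <- p * hidden
    b1 <- par[o + seq_len(hidden)]; o <- o + hidden
    W2 <- matrix(par[o + seq_len(hidden * K)], hidden, K); o <- o + hidden * K
    b2 <- par[o + seq_len(K)]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  forward <- function(pp) {
    Z <- tanh(sweep(X %*% pp$W1, 2, pp$b1, "+"))
    eta <- sweep(Z %*% pp$W2, 2, pp$b2, "+")
    list(Z = Z, eta = eta)
  }
  negll_eta <- function(eta) {
    switch(output,
      softmax = {
        m <- eta[, 1]
        for (k in seq_len(ncol(eta))[-1]) m <- pmax(m, eta[, k])
        lse <- m + log(rowSums(exp(eta - m)))
        -sum(w * (rowSums(Y * eta) - lse))
      },
      sigmoid = {
        mu <- stats::plogis(eta)
        -sum(w * (Y * log(pmax(mu, 1e-300)) + (1 - Y) * log(pmax(1 - mu, 1e-300))))
      },
      identity = sum(w * (Y - eta)^2) / 2
    )
  }
  deta <- function(eta) {
    switch(output,
      softmax = {
        m <- apply(eta, 1, max)
        e <- exp(eta - m)
        P <- e / rowSums(e)
        w * (P * rowSums(Y) - Y)
      },
      sigmoid = w * (stats::plogis(eta) - Y),
      identity = w * (eta - Y)
    )
  }
  fn <- function(par) {
    pp <- unpack(par)
    fw <- forward(pp)
    negll_eta(fw$eta) + lambda / 2 * sum(par^2)
  }
  gr <- function(par) {
    pp <- unpack(par)
    fw <- forward(pp)
    dE <- deta(fw$eta)
    gW2 <- t(fw$Z) %*% dE
    gb2 <- colSums(dE)
    dZ <- (dE %*% t(pp$W2)) * (1 - fw$Z^2)
    gW1 <- t(X) %*% dZ
    gb1 <- colSums(dZ)
    c(as.numeric(gW1), gb1, as.numeric(gW2), gb2) + lambda * par
  }
  par0 <- with_seed(seed, stats::runif(n_par, -0.1, 0.1))
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  pp <- unpack(opt$par)
  eta <- forward(pp)$eta
  if (output == "identity") {
    y <- Y[, 1]
    rss <- sum(w * (y - eta[, 1])^2)
    tss <- sum(w * (y - sum(w * y) / sum(w))^2)
    n <- sum(w)
    list(params = pp, ll1 = -n / 2 * (log(2 * pi * rss / n) + 1),
         ll0 = -n / 2 * (log(2 * pi * tss / n) + 1),
         null_params = sum(w * y) / sum(w), r2 = 1 - rss / tss)
  } else if (output == "softmax") {
    ll1 <- -negll_eta(eta)
    pbar <- colSums(w * Y) / sum(w)
    ll0 <- sum(w * (Y %*% log(pmax(pbar, 1e-300))))
    list(params = pp, ll1 = ll1, ll0 = ll0, null_params = pbar)
  } else {
    ll1 <- -negll_eta(eta)
    ll0 <- sum(vapply(seq_len(K), function(a) {
      ybar <- sum(w * Y[, a]) / sum(w)
      sum(w * (Y[, a] * log(max(ybar, 1e-300)) +
                 (1 - Y[, a]) * log(max(1 - ybar, 1e-300))))
    }, numeric(1)))
    list(params = pp, ll1 = ll1, ll0 = ll0, null_params = NULL)
  }
}

#' Predict from a fitted task model
#'
#' @param fit a `task_model_fit`.
#' @param features data frame with the feature columns used at fit time.
#' @return multinomial/binomial: matrix of per-area probabilities;
#'   gaussian: numeric predictions.
#' @export
predict_task_model <- function(fit, features) {
  X <- as.matrix(features[, fit$feature_cols, drop = FALSE])
  if (fit$model_class == "small_nn") {
    pp <- fit$params
    Z <- tanh(sweep(X %*% pp$W1, 2, pp$b1, "+"))
    eta <- sweep(Z %*% pp$W2, 2, pp$b2, "+")
    return(switch(fit$family,
      multinomial_joint = {
        m <- apply(eta, 1, max)
        e <- exp(eta - m)
        e / rowSums(e)
      },
      binomial_per_area = stats::plogis(eta),
      gaussian_scalar = eta[, 1]
    ))
  }
  Xd <- cbind(1, X)
  switch(fit$family,
    multinomial_joint = softmax_probs(Xd %*% fit$params),
    binomial_per_area = {
      do.call(cbind, lapply(fit$params, function(b) stats::plogis(Xd %*% b)))
    },
    gaussian_scalar = as.numeric(Xd %*% fit$params)
  )
}

#' McFadden's pseudo R-squared
#' @param ll1,ll0 model and intercept-only log-likelihoods.
#' @export
mcfadden_r2 <- function(ll1, ll0) 1 - ll1 / ll0

#' Likelihood-ratio chi-squared test for nested models
#'
#' `LR = 2 (ll1 - ll0)` compared against the upper tail of a chi-squared
#' distribution with `df` degrees of freedom (4 for the joint task model,
#' 1 for scalar targets).
#'
#' @param ll0,ll1 log-likelihoods of the nested and the larger model.
#' @param df degrees of freedom of the test.
#' @return list with `statistic` and `p_value`.
#' @export
likelihood_ratio_test <- function(ll0, ll1, df) {
  if (ll1 < ll0 - 1e-8) {
    stop("ll1 < ll0: models are not nested or the larger fit did not converge")
  }
  lr <- max(0, 2 * (ll1 - ll0))
  list(statistic = lr, p_value = stats::pchisq(lr, df, lower.tail = FALSE))
}

#' Bootstrap confidence interval of a paired model-score difference
#'
#' Resamples (bee, day) rows with replacement, fits the same model family
#' on feature sets A and B per replicate, and returns the percentile CI of
#' `score(A) - score(B)` (McFadden's pseudo R-squared, or R-squared for the
#' gaussian family). The null hypothesis "A is no better than B" is
#' rejected when the interval excludes 0 from below. A per-bee block
#' bootstrap is available for dependence-aware inference.
#'
#' @param features_a,features_b two feature tables (`bee_id`, `day`,
#'   feature columns).
#' @param response shared response table.
#' @param family,model_class passed to [fit_task_model()].
#' @param n_boot number of bootstrap replicates (default 128).
#' @param level CI level.
#' @param seed RNG seed; fixed seeds give identical CIs.
#' @param block_by_bee resample bees (with all their days) instead of rows.
#' @return list with `differences`, `ci`, `median_diff`, `median_a`,
#'   `median_b`, `reject`.
#' @export
bootstrap_effect_ci <- function(features_a, features_b, response,
                                family = "multinomial_joint",
                                model_class = "linear",
                                n_boot = 128, level = 0.95, seed = 1,
                                block_by_bee = FALSE) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  cols_a <- setdiff(colnames(features_a), c("bee_id", "day"))
  cols_b <- setdiff(colnames(features_b), c("bee_id", "day"))
  names(features_a)[match(cols_a, names(features_a))] <-
    paste0("A_", cols_a)
  names(features_b)[match(cols_b, names(features_b))] <-
    paste0("B_", cols_b)
  merged <- merge(merge(features_a, features_b, by = c("bee_id", "day")),
                  response, by = c("bee_id", "day"))
  n <- nrow(merged)
  # warm starts from the full-data fits keep replicate optimizations short
  start_a <- start_b <- NULL
  if (model_class == "linear" && family == "multinomial_joint") {
    start_a <- as.numeric(fit_task_model_merged(
      merged, paste0("A_", cols_a), family, model_class)$params)
    start_b <- as.numeric(fit_task_model_merged(
      merged, paste0("B_", cols_b), family, model_class)$params)
  }
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- if (block_by_bee) {
        ids <- unique(merged$bee_id)
        picked <- sample(ids, length(ids), replace = TRUE)
        unlist(lapply(picked, function(b) which(merged$bee_id == b)))
      } else {
        sample.int(n, n, replace = TRUE)
      }
      rep_df <- merged[idx, ]
      fa <- fit_task_model_merged(rep_df, paste0("A_", cols_a),
                                  family, model_class, start = start_a)
      fb <- fit_task_model_merged(rep_df, paste0("B_", cols_b),
                                  family, model_class, start = start_b)
      fa$r2 - fb$r2
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(diffs, c(alpha, 1 - alpha), type = 7, names = FALSE)
  list(differences = diffs, ci = ci, median_diff = stats::median(diffs),
       reject = ci[1] > 0)
}

#' Future task-allocation prediction with a persistence null
#'
#' For every window of `train_len` consecutive days, the CCA map and the
#' task model are fitted on the training days only; the model is then
#' evaluated `horizon` days after the training window on the held-out
#' factors (computed per day, so no supervised information leaks forward).
#' The persistence null carries the model's prediction for the last
#' training day forward to the evaluation day. Per evaluation row the
#' squared prediction errors of model and null are compared; a paired
#' binomial test on the sign of the improvement is pooled per horizon.
#'
#' @param factors pooled daily factors.
#' @param descriptors task-descriptor table.
#' @param train_len number of training days (default 12).
#' @param horizons days ahead to predict (default 1 to 11; must be >= 1).
#' @param k CCA projection dimensions.
#' @return object of class `future_prediction_result`: `windows` (one row
#'   per window and horizon) and `by_horizon` (pooled counts, binomial
#'   p-value, median McFadden improvement over the null).
#' @export
future_prediction <- function(factors, descriptors, train_len = 12,
                              horizons = 1:11, k = 3) {
  if (any(horizons < 1)) stop("horizons must be >= 1 (no peeking at the present)")
  days <- sort(unique(factors$day))
  win_rows <- list()
  for (h in horizons) {
    for (si in seq_len(length(days) - train_len - h + 1)) {
      train_days <- days[si:(si + train_len - 1)]
      eval_day <- days[si + train_len - 1 + h]
      train_end <- train_days[train_len]
      stopifnot(eval_day > train_end) # structural no-leakage assertion
      ftrain <- factors[factors$day %in% train_days, ]
      map <- fit_cca_map(ftrain, descriptors, k = k)
      na_train <- robust_scale(apply_map(ftrain, map))
      feat_train <- as.data.frame(na_train)[, c("bee_id", "day", "network_age")]
      model <- fit_task_model(feat_train, descriptors,
                              family = "multinomial_joint")
      feval <- factors[factors$day == eval_day, ]
      if (nrow(feval) == 0) next
      na_eval <- robust_scale(apply_map(feval, map))
      feat_eval <- as.data.frame(na_eval)[, c("bee_id", "day", "network_age")]
      area_cols <- c("frac_brood", "frac_dance_floor", "frac_honey", "frac_exit")
      ev <- merge(feat_eval, descriptors, by = c("bee_id", "day"))
      cur <- feat_train[feat_train$day == train_end,
                        c("bee_id", "network_age")]
      names(cur)[2] <- "network_age_current"
      ev <- merge(ev, cur, by = "bee_id")
      if (nrow(ev) == 0) next
      pred_model <- predict_task_model(model, ev)
      ev_null <- ev
      ev_null$network_age <- ev_null$network_age_current
      pred_null <- predict_task_model(model, ev_null)
      Y <- as.matrix(ev[, area_cols])
      se_model <- rowSums((pred_model - Y)^2)
      se_null <- rowSums((pred_null - Y)^2)
      wts <- if ("n_samples" %in% colnames(ev)) ev$n_samples else rep(1, nrow(ev))
      ll_model <- sum(wts * rowSums(Y * log(pmax(pred_model, 1e-300))))
      ll_null <- sum(wts * rowSums(Y * log(pmax(pred_null, 1e-300))))
      ll0 <- sum(wts * (Y %*% log(pmax(model$null_params, 1e-300))))
      win_rows[[length(win_rows) + 1]] <- data.frame(
        train_start = train_days[1], train_end = train_end,
        horizon = h, eval_day = eval_day, n = nrow(ev),
        n_improved = sum(se_model < se_null),
        mean_se_model = mean(se_model), mean_se_null = mean(se_null),
        r2_model = 1 - ll_model / ll0, r2_null = 1 - ll_null / ll0)
    }
  }
  windows <- do.call(rbind, win_rows)
  by_h <- do.call(rbind, lapply(split(windows, windows$horizon), function(wd) {
    n <- sum(wd$n)
    n_imp <- sum(wd$n_improved)
    bt <- stats::binom.test(n_imp, n, p = 0.5, alternative = "greater")
    data.frame(horizon = wd$horizon[1], n = n, n_improved = n_imp,
               p_binomial = bt$p.value,
               median_r2_improvement = stats::median(wd$r2_model - wd$r2_null))
  }))
  rownames(by_h) <- NULL
  structure(list(windows = windows, by_horizon = by_h),
            class = "future_prediction_result")
}

#' Repeatability of an individual's network age
#'
#' `R = Var_p / (Var_i + Var_p)` where `Var_i` is the variance of the
#' individual's network age over its observed days and `Var_p` the variance
#' of the daily mean network ages of an age-matched control group (all
#' other bees within `age_span` days of the focal bee's biological age, on
#' the same days). R near 1: individual variation is small relative to the
#' population's.
#'
#' @param series a `network_age_series` (or data frame with `bee_id`,
#'   `day`, `network_age`).
#' @param bio_age data frame `bee_id`, `day`, `age`.
#' @param bee focal bee id.
#' @param age_span control-group half-width in days of biological age.
#' @return list with `bee_id`, `var_individual`, `var_population`, `R`
#'   (`NA` with a flag when both variances are 0 or controls are missing).
#' @export
repeatability <- function(series, bio_age, bee, age_span = 1) {
  df <- merge(as.data.frame(series)[, c("bee_id", "day", "network_age")],
              bio_age, by = c("bee_id", "day"))
  focal <- df[df$bee_id == bee, ]
  if (nrow(focal) < 2) stop("focal bee needs >= 2 observed days")
  var_i <- stats::var(focal$network_age)
  ctrl_means <- vapply(seq_len(nrow(focal)), function(r) {
    d <- focal$day[r]
    a <- focal$age[r]
    ctrl <- df[df$day == d & df$bee_id != bee & abs(df$age - a) <= age_span, ]
    if (nrow(ctrl) == 0) NA_real_ else mean(ctrl$network_age)
  }, numeric(1))
  ctrl_means <- ctrl_means[!is.na(ctrl_means)]
  if (length(ctrl_means) < 2) {
    return(list(bee_id = bee, var_individual = var_i,
                var_population = NA_real_, R = NA_real_, flag = "no_controls"))
  }
  var_p <- stats::var(ctrl_means)
  if (var_i + var_p == 0) {
    return(list(bee_id = bee, var_individual = var_i, var_population = var_p,
                R = NA_real_, flag = "degenerate"))
  }
  list(bee_id = bee, var_individual = var_i, var_population = var_p,
       R = var_p / (var_i + var_p), flag = "ok")
}

#' Repeatability for every bee in a series
#' @inheritParams repeatability
#' @param min_days minimum observed days per bee.
#' @return data frame `bee_id`, `var_individual`, `var_population`, `R`.
#' @export
repeatability_all <- function(series, bio_age, age_span = 1, min_days = 2) {
  df <- as.data.frame(series)
  counts <- table(df$bee_id)
  ids <- names(counts)[counts >= min_days]
  rows <- lapply(ids, function(b) {
    r <- repeatability(series, bio_age, b, age_span)
    data.frame(bee_id = b, var_individual = r$var_individual,
               var_population = r$var_population, R = r$R,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# linear interpolation inside the observed range, linear extrapolation
# (from the two nearest observations) outside it
lin_interp_extrap <- function(x_obs, y_obs, xout) {
  stopifnot(length(x_obs) >= 2)
  ord <- order(x_obs)
  x_obs <- x_obs[ord]; y_obs <- y_obs[ord]
  y <- stats::approx(x_obs, y_obs, xout = xout, rule = 1)$y
  n <- length(x_obs)
  lo <- xout < x_obs[1]
  hi <- xout > x_obs[n]
  if (any(lo)) {
    s <- (y_obs[2] - y_obs[1]) / (x_obs[2] - x_obs[1])
    y[lo] <- y_obs[1] + s * (xout[lo] - x_obs[1])
  }
  if (any(hi)) {
    s <- (y_obs[n] - y_obs[n - 1]) / (x_obs[n] - x_obs[n - 1])
    y[hi] <- y_obs[n] + s * (xout[hi] - x_obs[n])
  }
  y
}

#' Cluster developmental trajectories of a same-aged cohort
#'
#' Each bee's network ages over days form a feature vector; missing days
#' are filled by linear inter- and extrapolation. Bees are clustered by
#' Ward's method on Euclidean distances and the dendrogram is cut at `k`
#' clusters (three separates early, late and absent transitions).
#'
#' @param series data frame `bee_id`, `day`, `network_age` for one cohort.
#' @param k number of clusters.
#' @param days day grid for the feature vectors (default: the cohort's
#'   observed day range).
#' @return list with `labels` (named integer vector), `hclust`, `features`.
#' @export
cluster_trajectories <- function(series, k = 3, days = NULL) {
  df <- as.data.frame(series)
  if (is.null(days)) days <- seq(min(df$day), max(df$day))
  ids <- unique(df$bee_id)
  if (k > length(ids)) stop("k exceeds the number of bees")
  feat <- t(vapply(ids, function(b) {
    obs <- df[df$bee_id == b, ]
    if (nrow(obs) < 2) stop("every bee needs >= 2 observations: ", b)
    lin_interp_extrap(obs$day, obs$network_age, days)
  }, numeric(length(days))))
  rownames(feat) <- ids
  hc <- stats::hclust(stats::dist(feat), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  list(labels = labels, hclust = hc, features = feat)
}

#' Split each day's network-age distribution into its two modes
#'
#' Runs 2-means on every day's pooled network ages (deterministic
#' initialization at the day's lower/upper quartiles) and, for every bee
#' observed at least once below `young_age_max` days of biological age,
#' reports the first biological age at which she is assigned to the
#' higher-mean cluster (`NA` if never). A separation ratio (between-center
#' gap over pooled within-cluster standard deviation) is reported per day
#' so unimodal days can be flagged downstream.
#'
#' @param series data frame `bee_id`, `day`, `network_age`.
#' @param bio_age data frame `bee_id`, `day`, `age`.
#' @param young_age_max cohort-restriction age (days).
#' @return list with `assignments` (`bee_id`, `day`, `age`, `mode` in
#'   lower/upper, `separation`) and `first_upper` (`bee_id`,
#'   `first_upper_age`).
#' @export
mode_split <- function(series, bio_age, young_age_max = 6) {
  df <- merge(as.data.frame(series)[, c("bee_id", "day", "network_age")],
              bio_age, by = c("bee_id", "day"))
  assigns <- list()
  for (d in sort(unique(df$day))) {
    dd <- df[df$day == d, ]
    if (nrow(dd) < 2 || stats::sd(dd$network_age) == 0) next
    centers <- stats::quantile(dd$network_age, c(0.25, 0.75), names = FALSE)
    if (centers[1] == centers[2]) centers <- range(dd$network_age)
    km <- stats::kmeans(dd$network_age, centers = matrix(centers, 2, 1))
    upper <- which.max(km$centers)
    wss_sd <- sqrt(km$tot.withinss / nrow(dd))
    sep <- if (wss_sd > 0) abs(diff(km$centers[, 1])) / wss_sd else Inf
    sep <- unname(sep)
    assigns[[length(assigns) + 1]] <- data.frame(
      bee_id = dd$bee_id, day = d, age = dd$age,
      mode = ifelse(km$cluster == upper, "upper", "lower"),
      separation = sep, stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, assigns)
  young_ids <- unique(assignments$bee_id[assignments$age < young_age_max])
  first_upper <- do.call(rbind, lapply(young_ids, function(b) {
    bb <- assignments[assignments$bee_id == b & assignments$mode == "upper", ]
    data.frame(bee_id = b,
               first_upper_age = if (nrow(bb)) min(bb$age) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(assignments) <- NULL
  list(assignments = assignments, first_upper = first_upper)
}
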
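## Gradient-boosted regression trees on the concatenated hybrid feature
## vector [Z_G | A_M | D_M], with squared-error loss: each tree fits the
## residuals of the running ensemble prediction, leaf values carry an
## xgboost-style L2 penalty, and rows/columns are subsampled per round.
## Hyperparameters are tuned by a tree-structured Parzen estimator (TPE)
## minimizing inner-cross-validation RMSE.

#' Default boosting hyperparameters
#' @return named list.
#' @export
default_boosting_params <- function() {
  list(learning_rate = 0.1, max_depth = 4, nrounds = 200,
       subsample = 1.0, colsample = 1.0, min_child_weight = 1,
       lambda = 1.0)
}

#' Default TPE search space
#'
#' Each entry is \code{list(type, lower, upper)} with type \code{"log"}
#' (log-uniform), \code{"lin"} (uniform) or \code{"int"} (uniform integer).
#' @export
default_boosting_space <- function() {
  list(learning_rate = list(type = "log", lower = 0.01, upper = 0.3),
       max_depth = list(type = "int", lower = 2, upper = 10),
       nrounds = list(type = "int", lower = 100, upper = 1000),
       subsample = list(type = "lin", lower = 0.5, upper = 1),
       colsample = list(type = "lin", lower = 0.5, upper = 1),
       min_child_weight = list(type = "int", lower = 1, upper = 10),
       lambda = list(type = "log", lower = 1e-3, upper = 10))
}

#' Fit a gradient-boosted tree ensemble
#'
#' @param X numeric feature matrix (or a \code{FeatureSet}).
#' @param y numeric response.
#' @param params hyperparameters, see \code{\link{default_boosting_params}};
#'   missing entries are filled with defaults.
#' @param seed RNG seed (row/column subsampling); fits are bitwise
#'   reproducible given the seed.
#' @return an object of class \code{BoostingModel}.
#' @export
fit_boosting <- function(X, y, params = list(), seed = 1) {
  if (inherits(X, "FeatureSet")) X <- feature_matrix(X)
  X <- as.matrix(X)
  if (!all(is.finite(y))) stop("y must be finite")
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  p <- utils::modifyList(default_boosting_params(), params)
  set.seed(seed)
  fit <- .gbt_fit_cpp(X, as.numeric(y), as.integer(p$nrounds),
                      as.integer(p$max_depth), p$learning_rate, p$lambda,
                      p$subsample, p$colsample, p$min_child_weight)
  structure(list(trees = fit$trees, base_score = fit$base_score,
                 fitted = fit$fitted, params = p, seed = seed,
                 feature_names = colnames(X)),
            class = "BoostingModel")
}

#' Predict from a boosted ensemble
#' @param model a \code{BoostingModel}.
#' @param X feature matrix (or \code{FeatureSet}) with the training columns.
#' @return numeric predictions (sum of all tree outputs plus base score).
#' @export
predict_boosting <- function(model, X) {
  if (inherits(X, "FeatureSet")) X <- feature_matrix(X)
  X <- as.matrix(X)
  if (!is.null(model$feature_names)) {
    if (is.null(colnames(X)) || !identical(colnames(X),
                                           model$feature_names)) {
      if (!is.null(colnames(X)) &&
          setequal(colnames(X), model$feature_names)) {
        X <- X[, model$feature_names, drop = FALSE]
      } else {
        off <- union(setdiff(colnames(X), model$feature_names),
                     setdiff(model$feature_names, colnames(X)))
        stop("feature columns do not match training manifest: ",
             paste(utils::head(off, 5), collapse = ", "))
      }
    }
  }
  drop(.gbt_predict_cpp(model$trees, model$base_score, X))
}

#' @exportS3Method base::print
print.BoostingModel <- function(x, ...) {
  cat(sprintf(
    "BoostingModel: %d trees, depth<=%d, eta=%.3g, %d features\n",
    length(x$trees), x$params$max_depth, x$params$learning_rate,
    length(x$feature_names)))
  invisible(x)
}

## -------------------------------------------------------------------- TPE

tpe_sample_uniform <- function(space, rng_n = 1) {
  lapply(space, function(sp) {
    u <- stats::runif(rng_n)
    val <- switch(sp$type,
                  log = exp(log(sp$lower) + u * (log(sp$upper) -
                                                 log(sp$lower))),
                  lin = sp$lower + u * (sp$upper - sp$lower),
                  int = sp$lower + u * (sp$upper - sp$lower))
    if (sp$type == "int") round(val) else val
  })
}

tpe_transform <- function(v, sp)
  if (sp$type == "log") log(v) else as.numeric(v)

tpe_kde_logdens <- function(x, obs, sp) {
  # Gaussian KDE in the transformed space, Silverman bandwidth with a
  # floor of 1/20 of the (transformed) range
  lo <- tpe_transform(sp$lower, sp); hi <- tpe_transform(sp$upper, sp)
  bw <- max(1.06 * stats::sd(obs) * length(obs)^(-0.2), (hi - lo) / 20,
            1e-8)
  vapply(x, function(xx)
    log(mean(stats::dnorm(xx, mean = obs, sd = bw)) + 1e-300), numeric(1))
}

#' Tree-structured Parzen estimator optimization
#'
#' Minimizes \code{objective(params)} over a box search space. The first
#' \code{n_startup} trials are uniform; afterwards candidates are drawn
#' from a kernel-density model of the best \code{gamma} fraction of trials
#' and scored by the density ratio l(x)/g(x), dimension-wise (independent
#' factorization, as in standard TPE). Deterministic given \code{seed}.
#'
#' @param objective function taking a named list of parameter values and
#'   returning a scalar loss.
#' @param space search space, see \code{\link{default_boosting_space}}.
#' @param n_trials total number of trials (>= 5).
#' @param seed RNG seed.
#' @param gamma fraction of trials regarded as "good".
#' @param n_candidates candidates scored per TPE trial.
#' @param n_startup uniform warm-up trials.
#' @return list with \code{best} (named parameter list), \code{best_value},
#'   and \code{trace} (data.frame of all trials and losses).
#' @export
tpe_optimize <- function(objective, space, n_trials = 50, seed = 1,
                         gamma = 0.25, n_candidates = 24, n_startup = 10) {
  if (n_trials < 5) stop("n_trials must be >= 5")
  set.seed(seed)
  dims <- names(space)
  trials <- matrix(NA_real_, n_trials, length(dims),
                   dimnames = list(NULL, dims))
  losses <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    if (t <= max(n_startup, 2)) {
      cand <- tpe_sample_uniform(space)
      par <- lapply(cand, function(v) v[1])
    } else {
      ord <- order(losses[seq_len(t - 1)])
      ngood <- max(2, ceiling(gamma * (t - 1)))
      good <- trials[ord[seq_len(ngood)], , drop = FALSE]
      bad <- trials[ord[-seq_len(ngood)], , drop = FALSE]
      if (nrow(bad) < 2) bad <- trials[seq_len(t - 1), , drop = FALSE]
      par <- list()
      for (dnm in dims) {
        sp <- space[[dnm]]
        gobs <- tpe_transform(good[, dnm], sp)
        bobs <- tpe_transform(bad[, dnm], sp)
        lo <- tpe_transform(sp$lower, sp); hi <- tpe_transform(sp$upper, sp)
        bw <- max(1.06 * stats::sd(gobs) * length(gobs)^(-0.2),
                  (hi - lo) / 20, 1e-8)
        cand <- gobs[sample.int(length(gobs), n_candidates, replace = TRUE)] +
          stats::rnorm(n_candidates, sd = bw)
        cand <- pmin(pmax(cand, lo), hi)
        score <- tpe_kde_logdens(cand, gobs, sp) -
          tpe_kde_logdens(cand, bobs, sp)
        pick <- cand[which.max(score)]
        val <- if (sp$type == "log") exp(pick) else pick
        if (sp$type == "int") val <- round(val)
        par[[dnm]] <- val
      }
    }
    trials[t, ] <- unlist(par)
    losses[t] <- objective(par)
  }
  best <- which.min(losses)
  bestpar <- as.list(trials[best, ])
  for (dnm in dims)
    if (space[[dnm]]$type == "int") bestpar[[dnm]] <- as.integer(
      round(bestpar[[dnm]]))
  trace <- data.frame(trial = seq_len(n_trials), trials, loss = losses)
  list(best = bestpar, best_value = losses[best], trace = trace)
}

#' Tune boosting hyperparameters by TPE over inner-CV RMSE
#'
#' @param X feature matrix (or \code{FeatureSet}).
#' @param y numeric response (>= 50 observations).
#' @param n_trials TPE trials (>= 5; default 50).
#' @param inner_folds inner cross-validation folds.
#' @param seed RNG seed; the whole search is deterministic given it.
#' @param space search space; see \code{\link{default_boosting_space}}.
#' @return list with \code{params}, \code{best_rmse} and the TPE
#'   \code{trace}.
#' @export
tune_boosting <- function(X, y, n_trials = 50, inner_folds = 5, seed = 1,
                          space = default_boosting_space()) {
  if (inherits(X, "FeatureSet")) X <- feature_matrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 50) stop("need at least 50 training hybrids for tuning")
  set.seed(seed)
  fold <- sample(rep(seq_len(inner_folds), length.out = n))
  objective <- function(par) {
    err2 <- 0
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      m <- fit_boosting(X[tr, , drop = FALSE], y[tr], params = par,
                        seed = seed + f)
      pred <- predict_boosting(m, X[!tr, , drop = FALSE])
      err2 <- err2 + sum((y[!tr] - pred)^2)
    }
    sqrt(err2 / n)
  }
  res <- tpe_optimize(objective, space, n_trials = n_trials,
                      seed = seed)
  list(params = res$best, best_rmse = res$best_value, trace = res$trace)
}
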
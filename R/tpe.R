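# Tree-structured Parzen Estimator hyperparameter optimization.
#
# Factorised TPE: after a random start-up phase, trials are split at the
# gamma quantile of the loss into "good" and "bad" sets; per parameter, a
# Parzen mixture (Gaussian kernels at observed values, bandwidths from
# neighbour spacing) models the good density l(x) and the bad density g(x);
# candidates are drawn from l and the one maximising l(x)/g(x) is evaluated.
# Integer and log-scale parameters are handled in transformed space.

#' Hyperparameter search spaces for the three regressors
#'
#' @param kind `"RF"`, `"SVM"` or `"GBDT"`.
#' @return Named list of parameter definitions
#'   (`list(type = "int"|"uniform"|"loguniform", low, high)`).
#' @export
tpe_space <- function(kind) {
  switch(match.arg(kind, MODEL_KINDS),
         RF = list(n_trees = list(type = "int", low = 100, high = 1000),
                   max_depth = list(type = "int", low = 3, high = 30),
                   max_features = list(type = "uniform", low = 0.1, high = 1)),
         SVM = list(cost = list(type = "loguniform", low = 1e-2, high = 1e3),
                    gamma = list(type = "loguniform", low = 1e-4, high = 1),
                    epsilon = list(type = "uniform", low = 0.01, high = 1)),
         GBDT = list(n_estimators = list(type = "int", low = 100, high = 1000),
                     learning_rate = list(type = "loguniform", low = 1e-3, high = 0.3),
                     max_depth = list(type = "int", low = 2, high = 8),
                     subsample = list(type = "uniform", low = 0.5, high = 1)))
}

to_unit <- function(x, def) {
  if (def$type == "loguniform") (log(x) - log(def$low)) / (log(def$high) - log(def$low))
  else (x - def$low) / (def$high - def$low)
}

from_unit <- function(u, def) {
  u <- pmin(pmax(u, 0), 1)
  x <- if (def$type == "loguniform") exp(log(def$low) + u * (log(def$high) - log(def$low)))
  else def$low + u * (def$high - def$low)
  if (def$type == "int") as.integer(round(x)) else x
}

sample_uniform_point <- function(space) {
  lapply(space, function(def) from_unit(stats::runif(1), def))
}

parzen_density <- function(u_obs) {
  # kernel centres at observations plus one prior centre; bandwidth from
  # neighbour spacing, floored to keep densities proper on [0,1]
  mu <- c(u_obs, 0.5)
  o <- order(mu)
  gaps <- diff(mu[o])
  bw <- numeric(length(mu))
  bw[o] <- pmax(c(gaps, 1)[seq_along(mu)], c(1, gaps)[seq_along(mu)], 1 / (length(mu) + 1))
  bw <- pmin(pmax(bw, 0.05), 1)
  list(mu = mu, bw = bw)
}

parzen_pdf <- function(u, pd) {
  vapply(u, function(x) mean(stats::dnorm(x, pd$mu, pd$bw)), numeric(1))
}

parzen_sample <- function(n, pd) {
  idx <- sample.int(length(pd$mu), n, replace = TRUE)
  stats::rnorm(n, pd$mu[idx], pd$bw[idx])
}

#' TPE optimization loop
#'
#' Minimizes `objective(params)` over `budget` trials.
#'
#' @param space Parameter space from [tpe_space()] (or of the same shape).
#' @param objective Function taking a named parameter list, returning a
#'   finite loss.
#' @param budget Number of trials (>= 1).
#' @param seed Integer seed; the trial sequence is deterministic given it.
#' @param gamma Quantile splitting good from bad trials.
#' @param n_candidates Candidates scored per TPE iteration.
#' @param n_startup Random trials before the Parzen model kicks in.
#' @return List with `params` (best), `loss`, and `trials` (data.frame with
#'   one row per trial: parameters and loss).
#' @export
tpe_optimize <- function(space, objective, budget, seed = 1, gamma = 0.25,
                         n_candidates = 24, n_startup = 10) {
  if (budget < 1) stopf("budget must be >= 1")
  with_seed(seed, {
    trials <- vector("list", budget)
    losses <- numeric(budget)
    for (t in seq_len(budget)) {
      if (t <= n_startup) {
        cand <- sample_uniform_point(space)
      } else {
        n_good <- max(1, ceiling(gamma * (t - 1)))
        ord <- order(losses[seq_len(t - 1)])
        good <- ord[seq_len(n_good)]
        bad <- ord[-seq_len(n_good)]
        cand <- lapply(names(space), function(nm) {
          def <- space[[nm]]
          u_good <- vapply(trials[good], function(tr) to_unit(tr[[nm]], def), numeric(1))
          u_bad <- vapply(trials[bad], function(tr) to_unit(tr[[nm]], def), numeric(1))
          lpd <- parzen_density(u_good)
          gpd <- parzen_density(u_bad)
          u_cand <- pmin(pmax(parzen_sample(n_candidates, lpd), 0), 1)
          score <- log(parzen_pdf(u_cand, lpd) + 1e-12) -
            log(parzen_pdf(u_cand, gpd) + 1e-12)
          from_unit(u_cand[which.max(score)], def)
        })
        names(cand) <- names(space)
      }
      trials[[t]] <- cand
      losses[t] <- objective(cand)
    }
    best <- which.min(losses)
    tr_df <- do.call(rbind, lapply(seq_len(budget), function(t)
      data.frame(trial = t, as.data.frame(trials[[t]]), loss = losses[t])))
    list(params = trials[[best]], loss = losses[best], trials = tr_df)
  })
}

cv_rmse <- function(kind, X, y, params, folds, seed) {
  n <- nrow(X)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  seeds <- derive_seeds(seed, folds)
  err2 <- 0
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- fit_model(kind, X[tr, , drop = FALSE], y[tr], params, seed = seeds[f])
    pred <- predict_model(fit, X[!tr, , drop = FALSE])
    err2 <- err2 + sum((y[!tr] - pred)^2)
  }
  sqrt(err2 / n)
}

#' Tune one regressor by TPE over cross-validated RMSE
#'
#' @param kind `"RF"`, `"SVM"` or `"GBDT"`.
#' @param X,y Training feature matrix and pEC50 target.
#' @param budget TPE trials.
#' @param folds CV folds.
#' @param seed Integer seed.
#' @return List `params`, `loss` (best CV RMSE), `trials`.
#' @export
tune_model <- function(kind, X, y, budget = 100, folds = 5, seed = 1) {
  seeds <- derive_seeds(seed, 2)
  tpe_optimize(tpe_space(kind),
               function(p) cv_rmse(kind, X, y, p, folds, seeds[1]),
               budget = budget, seed = seeds[2])
}
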
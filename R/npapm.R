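# The neuroprotection-potency QSAR ensemble: three regressors (random forest,
# RBF support-vector regression, gradient-boosted trees) trained on one
# fingerprint matrix against pEC50, combined by an unweighted mean, gated by
# a Tanimoto applicability domain.

#' Convert EC50 in micromolar to pEC50 and back
#'
#' pEC50 = -log10(EC50 in molar) = 6 - log10(EC50 in uM).
#' @param ec50_uM,pec50 Numeric vectors.
#' @return Numeric vector.
#' @export
pec50_from_uM <- function(ec50_uM) {
  if (any(ec50_uM <= 0)) stopf("EC50 values must be > 0")
  6 - log10(ec50_uM)
}

#' @rdname pec50_from_uM
#' @export
uM_from_pec50 <- function(pec50) 10^(6 - pec50)

#' Split examples into training and test sets (4:1)
#'
#' The test set holds `round(n/5)` examples, drawn without replacement;
#' reproducible from the seed.
#'
#' @param n Number of examples (>= 5).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_examples <- function(n, seed) {
  if (n < 5) stopf("need at least 5 examples to split 4:1 (got %d)", n)
  n_test <- round(n / 5)
  test <- with_seed(seed, sort(sample.int(n, n_test)))
  list(train = setdiff(seq_len(n), test), test = test)
}

MODEL_KINDS <- c("RF", "SVM", "GBDT")

default_params <- function(kind) {
  switch(kind,
         RF = list(n_trees = 500, max_depth = 16, max_features = 1 / 3),
         SVM = list(cost = 10, gamma = 0.01, epsilon = 0.1),
         GBDT = list(n_estimators = 300, learning_rate = 0.05, max_depth = 4,
                     subsample = 0.8))
}

#' Fit one regressor of the ensemble
#'
#' @param kind `"RF"` (randomForest bagging), `"SVM"` (e1071 RBF
#'   eps-regression) or `"GBDT"` (xgboost gradient boosting).
#' @param X Feature matrix (rows = compounds).
#' @param y pEC50 target vector.
#' @param params Hyperparameters (see [tpe_space()] for names); missing
#'   entries take package defaults.
#' @param seed Integer seed (training is deterministic given it).
#' @return Object of class `npapm_model`.
#' @export
fit_model <- function(kind, X, y, params = list(), seed = 1) {
  kind <- match.arg(kind, MODEL_KINDS)
  p <- utils::modifyList(default_params(kind), params)
  X <- as.matrix(X)
  if (stats::var(y) == 0) {
    warnf("degenerate target (zero variance); fitting a constant model")
    return(structure(list(kind = kind, constant = y[1], params = p),
                     class = "npapm_model"))
  }
  model <- with_seed(seed, switch(
    kind,
    RF = randomForest::randomForest(
      x = X, y = y, ntree = as.integer(p$n_trees),
      mtry = max(1L, round(p$max_features * ncol(X))),
      maxnodes = min(as.integer(2^min(p$max_depth, 10)), nrow(X))),
    SVM = e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                     cost = p$cost, gamma = p$gamma, epsilon = p$epsilon,
                     scale = FALSE),
    GBDT = xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = p$learning_rate,
                    max_depth = as.integer(p$max_depth), subsample = p$subsample,
                    nthread = 1, base_score = mean(y), seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = as.integer(p$n_estimators), verbose = 0)))
  structure(list(kind = kind, model = model, constant = NULL, params = p,
                 n_features = ncol(X)),
            class = "npapm_model")
}

#' Predict pEC50 with a fitted regressor
#' @param fit An `npapm_model`.
#' @param X Feature matrix with the training feature count.
#' @return Numeric predictions.
#' @export
predict_model <- function(fit, X) {
  X <- as.matrix(X)
  if (!is.null(fit$constant)) return(rep(fit$constant, nrow(X)))
  if (ncol(X) != fit$n_features)
    stopf("feature count mismatch: model has %d, input has %d",
          fit$n_features, ncol(X))
  switch(fit$kind,
         RF = unname(stats::predict(fit$model, X)),
         SVM = unname(stats::predict(fit$model, X)),
         GBDT = stats::predict(fit$model, xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' Regression performance metrics
#'
#' MAE = mean |y - yhat|; MRE = mean(|y - yhat| / |y|); MSE = mean squared
#' error; RMSE = sqrt(MSE); R2 = 1 - SSres/SStot. Observations with y = 0 are
#' excluded from MRE (their count is reported); if all are zero MRE is NA.
#'
#' @param y Observed values (length >= 2).
#' @param yhat Predicted values, same length.
#' @return List of class `metrics_report`: `MAE`, `MRE`, `MSE`, `RMSE`, `R2`,
#'   `N`, `n_mre_excluded`, plus `y` and `yhat`.
#' @export
evaluate_predictions <- function(y, yhat) {
  if (length(y) != length(yhat)) stopf("length mismatch")
  if (length(y) < 2) stopf("need >= 2 observations")
  err <- y - yhat
  nz <- y != 0
  structure(list(
    MAE = mean(abs(err)),
    MRE = if (any(nz)) mean(abs(err[nz]) / abs(y[nz])) else NA_real_,
    MSE = mean(err^2), RMSE = sqrt(mean(err^2)),
    R2 = 1 - sum(err^2) / sum((y - mean(y))^2),
    N = length(y), n_mre_excluded = sum(!nz), y = y, yhat = yhat),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("N=%d  MAE=%.4f  MRE=%.4f  MSE=%.4f  RMSE=%.4f  R2=%.4f\n",
              x$N, x$MAE, x$MRE, x$MSE, x$RMSE, x$R2))
  invisible(x)
}

#' Train the three-model potency ensemble on a compound table
#'
#' Fingerprints the compounds, splits 4:1, optionally tunes each regressor
#' with the TPE optimizer, fits RF, SVM and GBDT on the training set and
#' evaluates each model and their unweighted-mean ensemble on the held-out
#' test set. The fingerprint configuration, training fingerprints (for the
#' applicability domain), seeds and hyperparameters are stamped into the
#' returned bundle.
#'
#' @param data data.frame with columns `compound_id`, `smiles`, `ec50_uM`.
#' @param fp_kind Fingerprint kind (default `"TOPO_PATH"`, the kind selected
#'   for the final model).
#' @param fp_params Fingerprint parameter overrides.
#' @param tune_budget TPE trials per model (0 = use package default
#'   hyperparameters; the default keeps training fast).
#' @param cv_folds Cross-validation folds used during tuning.
#' @param seed Integer seed controlling the split, tuning and model fits.
#' @return Object of class `npapm_bundle`.
#' @export
train_npapm <- function(data, fp_kind = "TOPO_PATH", fp_params = list(),
                        tune_budget = 0, cv_folds = 5, seed = 1) {
  stopifnot(all(c("compound_id", "smiles", "ec50_uM") %in% names(data)))
  if (anyDuplicated(data$compound_id)) stopf("one example per compound required")
  mols <- parse_molecules(data$smiles, data$compound_id)
  ok <- vapply(mols, `[[`, logical(1), "parse_ok")
  if (any(!ok)) {
    message(sum(!ok), " compound(s) failed to parse and were dropped")
    data <- data[ok, , drop = FALSE]
    mols <- mols[ok]
  }
  X <- fingerprint_matrix(mols, fp_kind, fp_params)
  y <- pec50_from_uM(data$ec50_uM)
  names(y) <- data$compound_id
  sp <- split_examples(nrow(X), seed)
  seeds <- derive_seeds(seed, 7)

  hyper <- list(); tuning <- list()
  for (k in MODEL_KINDS) {
    if (tune_budget > 0) {
      tr <- tune_model(k, X[sp$train, , drop = FALSE], y[sp$train],
                       budget = tune_budget, folds = cv_folds,
                       seed = seeds[match(k, MODEL_KINDS)])
      hyper[[k]] <- tr$params; tuning[[k]] <- tr$trials
    } else {
      hyper[[k]] <- default_params(k)
    }
  }
  models <- lapply(MODEL_KINDS, function(k)
    fit_model(k, X[sp$train, , drop = FALSE], y[sp$train], hyper[[k]],
              seed = seeds[4 + match(k, MODEL_KINDS) - 1]))
  names(models) <- MODEL_KINDS

  test_pred <- vapply(models, predict_model, numeric(length(sp$test)),
                      X[sp$test, , drop = FALSE])
  ens <- rowMeans(test_pred)
  metrics <- c(lapply(MODEL_KINDS, function(k)
    evaluate_predictions(unname(y[sp$test]), test_pred[, k])),
    list(evaluate_predictions(unname(y[sp$test]), ens)))
  names(metrics) <- c(MODEL_KINDS, "ENSEMBLE")

  structure(list(models = models, fp_kind = fp_kind,
                 fp_params = fp_params_for(fp_kind, fp_params),
                 train_fps = X[sp$train, , drop = FALSE],
                 train_y = y[sp$train], split = sp, seed = seed,
                 hyperparameters = hyper, tuning = tuning, metrics = metrics),
            class = "npapm_bundle")
}

#' @export
print.npapm_bundle <- function(x, ...) {
  cat(sprintf("<npapm_bundle> %s fingerprints (%d train compounds)\n",
              x$fp_kind, nrow(x$train_fps)))
  for (k in names(x$metrics)) {
    cat(sprintf("  %-8s test ", k)); print(x$metrics[[k]])
  }
  invisible(x)
}

bundle_feature_matrix <- function(bundle, input) {
  if (is.matrix(input)) {
    if (ncol(input) != ncol(bundle$train_fps))
      stopf("fingerprint configuration mismatch: bundle expects %d features",
            ncol(bundle$train_fps))
    return(input)
  }
  if (is.character(input)) input <- parse_molecules(input)
  fingerprint_matrix(input, bundle$fp_kind, bundle$fp_params)
}

#' Ensemble pEC50 prediction
#'
#' The prediction is the unweighted arithmetic mean of the three regressors'
#' pEC50 outputs; convert to EC50 in uM with [uM_from_pec50()].
#'
#' @param bundle An `npapm_bundle`.
#' @param input Fingerprint matrix matching the bundle configuration, a list
#'   of `molecule_record`s, or a character vector of SMILES.
#' @param per_model Also return the individual model predictions.
#' @return Numeric vector of pEC50 predictions (matrix when `per_model`).
#' @export
ensemble_predict <- function(bundle, input, per_model = FALSE) {
  X <- bundle_feature_matrix(bundle, input)
  pred <- vapply(bundle$models, predict_model, numeric(nrow(X)), X)
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = nrow(X),
                                         dimnames = list(rownames(X), MODEL_KINDS))
  ens <- rowMeans(pred)
  if (per_model) cbind(pred, ENSEMBLE = ens) else ens
}

#' Tanimoto applicability domain
#'
#' A candidate is in-domain iff its maximum Tanimoto similarity to any
#' training-set fingerprint strictly exceeds the threshold (default 0.6).
#'
#' @param bundle An `npapm_bundle` (the bundle's own fingerprint kind is the
#'   domain fingerprint).
#' @param input As in [ensemble_predict()].
#' @param threshold Strict similarity threshold.
#' @return data.frame `compound_id, max_tanimoto, in_domain`.
#' @export
applicability <- function(bundle, input, threshold = 0.6) {
  if (bundle$fp_kind == "PHYSCHEM")
    stopf("applicability domain requires a bit fingerprint")
  if (nrow(bundle$train_fps) == 0) stopf("empty training set")
  X <- bundle_feature_matrix(bundle, input)
  mt <- max_tanimoto_rows(X, bundle$train_fps)
  data.frame(compound_id = rownames(X) %||% seq_len(nrow(X)),
             max_tanimoto = unname(mt), in_domain = unname(mt > threshold),
             stringsAsFactors = FALSE)
}

#' Order-of-magnitude agreement between predicted and measured EC50
#'
#' TRUE iff floor(log10 predicted) equals floor(log10 measured).
#' @param pred_uM,meas_uM Positive EC50 values (vectors recycle as usual).
#' @return Logical vector.
#' @export
magnitude_agreement <- function(pred_uM, meas_uM) {
  if (any(pred_uM <= 0) || any(meas_uM <= 0)) stopf("EC50 values must be > 0")
  floor(log10(pred_uM)) == floor(log10(meas_uM))
}

#' Persist / restore a model bundle
#'
#' The bundle directory holds `bundle.json` (fingerprint configuration, seed,
#' hyperparameters, metric summaries) plus serialized models and training
#' fingerprints.
#' @param bundle An `npapm_bundle`.
#' @param dir Directory path.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(fp_kind = bundle$fp_kind, fp_params = bundle$fp_params,
               seed = bundle$seed, hyperparameters = bundle$hyperparameters,
               metrics = lapply(bundle$metrics, function(m)
                 m[c("MAE", "MRE", "MSE", "RMSE", "R2", "N")]))
  jsonlite::write_json(meta, file.path(dir, "bundle.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  saveRDS(bundle, file.path(dir, "bundle.rds"))
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) readRDS(file.path(dir, "bundle.rds"))
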
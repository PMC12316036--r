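test_that("4:1 splitting is sized, disjoint and reproducible", {
  s10 <- split_examples(10, seed = 1)
  expect_length(s10$test, 2); expect_length(s10$train, 8)
  s172 <- split_examples(172, seed = 1)
  expect_length(s172$test, 34); expect_length(s172$train, 138)
  expect_length(intersect(s172$train, s172$test), 0)
  expect_identical(split_examples(172, seed = 9), split_examples(172, seed = 9))
  expect_error(split_examples(4, seed = 1), "at least 5")
})

test_that("pEC50 conversions are mutually inverse and unit-correct", {
  expect_equal(pec50_from_uM(1), 6)        # 1 uM = 1e-6 M
  expect_equal(pec50_from_uM(0.1), 7)
  expect_equal(uM_from_pec50(pec50_from_uM(c(0.3, 12, 250))), c(0.3, 12, 250))
  expect_error(pec50_from_uM(-1), "> 0")
})

test_that("model fitting is seeded, degenerate-safe, and predicts constants", {
  set.seed(2)
  X <- matrix(rbinom(60 * 10, 1, 0.4), 60, 10)
  y <- rep(5, 60)
  for (k in c("RF", "SVM", "GBDT")) {
    expect_warning(fit <- fit_model(k, X, y, seed = 1), "degenerate")
    expect_equal(predict_model(fit, X[1:5, ]), rep(5, 5))
  }
  y2 <- 2 * X[, 1] + rnorm(60, 0, 0.2)
  for (k in c("RF", "SVM", "GBDT")) {
    f1 <- fit_model(k, X, y2, seed = 7)
    f2 <- fit_model(k, X, y2, seed = 7)
    expect_equal(predict_model(f1, X), predict_model(f2, X), tolerance = 1e-12)
  }
  f <- fit_model("RF", X, y2, seed = 1)
  expect_error(predict_model(f, X[, 1:5]), "mismatch")
})

test_that("each learner recovers a single-bit structure-activity signal", {
  set.seed(31)
  X <- matrix(rbinom(200 * 30, 1, 0.3), 200, 30)
  y <- 5 + 1.5 * X[, 7] + rnorm(200, 0, 0.3)
  sp <- split_examples(200, seed = 3)
  for (k in c("RF", "SVM", "GBDT")) {
    fit <- fit_model(k, X[sp$train, ], y[sp$train], seed = 5)
    r2 <- evaluate_predictions(y[sp$test], predict_model(fit, X[sp$test, ]))$R2
    expect_gte(r2, 0.7)
  }
})

test_that("metrics match the hand case and the brute-force oracle", {
  m <- evaluate_predictions(c(1, 2), c(2, 4))
  expect_equal(m$MAE, 1.5)
  expect_equal(m$MRE, 1.0)
  expect_equal(m$MSE, 2.5)
  expect_equal(m$RMSE, sqrt(2.5))
  expect_equal(m$R2, -9)
  perfect <- evaluate_predictions(c(1, 3, 5), c(1, 3, 5))
  expect_equal(unlist(perfect[c("MAE", "MRE", "MSE", "RMSE")]),
               c(MAE = 0, MRE = 0, MSE = 0, RMSE = 0))
  expect_equal(perfect$R2, 1)

  set.seed(17)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    y <- rnorm(n, 4, 2); yhat <- y + rnorm(n)
    got <- evaluate_predictions(y, yhat)
    ref <- metrics_oracle(y, yhat)
    for (nm in names(ref)) expect_equal(got[[nm]], ref[[nm]], tolerance = 1e-12)
    expect_equal(got$MSE, got$RMSE^2, tolerance = 1e-12)
    expect_lte(got$MAE, got$RMSE + 1e-12)
  }
  withy0 <- evaluate_predictions(c(0, 1, 2), c(1, 1, 2))
  expect_equal(withy0$n_mre_excluded, 1)
})

test_that("ensemble prediction is the exact mean of the three models", {
  set.seed(4)
  lib <- gen_sar_library(n = 60, seed = 5)
  b <- train_npapm(lib$data[, 1:3], fp_params = list(nbits = 256), seed = 5)
  X <- b$train_fps[1:10, ]
  per <- ensemble_predict(b, X, per_model = TRUE)
  expect_equal(per[, "ENSEMBLE"],
               rowMeans(per[, c("RF", "SVM", "GBDT")]), tolerance = 1e-15)
  # three models predicting 5, 6, 7 average to 6
  fits <- list(RF = structure(list(kind = "RF", constant = 5), class = "npapm_model"),
               SVM = structure(list(kind = "SVM", constant = 6), class = "npapm_model"),
               GBDT = structure(list(kind = "GBDT", constant = 7), class = "npapm_model"))
  b2 <- b; b2$models <- fits
  expect_equal(unname(ensemble_predict(b2, X[1:3, ])), rep(6, 3))
  expect_error(ensemble_predict(b, matrix(0, 2, 99)), "mismatch")
})

test_that("applicability domain uses a strict max-Tanimoto threshold", {
  lib <- gen_sar_library(n = 40, seed = 6)
  b <- train_npapm(lib$data[, 1:3], fp_params = list(nbits = 256), seed = 6)
  self <- applicability(b, b$train_fps[1:3, , drop = FALSE])
  expect_equal(self$max_tanimoto, rep(1, 3))
  expect_true(all(self$in_domain))

  # constructed boundary: similarity exactly 0.6 is out of domain
  Xtr <- matrix(0L, 1, 256); Xtr[1, 1:5] <- 1L
  b3 <- b; b3$train_fps <- Xtr
  cand <- matrix(0L, 1, 256); cand[1, 1:3] <- 1L   # 3/5 = 0.6
  ad <- applicability(b3, cand)
  expect_equal(ad$max_tanimoto, 0.6)
  expect_false(ad$in_domain)
  cand[1, 4] <- 1L                                  # 4/5 = 0.8
  expect_true(applicability(b3, cand)$in_domain)

  # AD monotonicity: adding a training compound never lowers max similarity
  set.seed(8)
  Xc <- matrix(rbinom(20 * 256, 1, 0.1), 20, 256)
  before <- applicability(b, Xc)$max_tanimoto
  b4 <- b; b4$train_fps <- rbind(b$train_fps, Xc[1, , drop = FALSE])
  after <- applicability(b4, Xc)$max_tanimoto
  expect_true(all(after >= before - 1e-12))

  # a random sparse fingerprint is typically far from a drug-like library
  rand <- matrix(rbinom(256, 1, 0.5), 1, 256)
  expect_false(applicability(b, rand)$in_domain)
})

test_that("order-of-magnitude agreement uses decade floors", {
  expect_true(magnitude_agreement(3, 9))
  expect_false(magnitude_agreement(9, 11))
  expect_true(magnitude_agreement(0.2, 0.9))
  expect_error(magnitude_agreement(-1, 2), "> 0")
  # vector fixture constructed with exactly 8 of 10 decade matches
  meas <- c(1.2, 3, 8, 15, 40, 90, 150, 400, 0.5, 0.02)
  pred <- c(2.0, 9, 40, 80, 11, 20, 90, 120, 0.9, 0.04)
  expect_equal(sum(magnitude_agreement(pred, meas)), 8)
})

test_that("bundle training stamps configuration and survives a round trip", {
  lib <- gen_sar_library(n = 50, seed = 9)
  b <- train_npapm(lib$data[, 1:3], fp_params = list(nbits = 256), seed = 9)
  expect_identical(b$fp_kind, "TOPO_PATH")
  expect_equal(b$fp_params$nbits, 256)
  expect_named(b$metrics, c("RF", "SVM", "GBDT", "ENSEMBLE"))
  d <- tempfile()
  save_bundle(b, d)
  expect_true(file.exists(file.path(d, "bundle.json")))
  b2 <- load_bundle(d)
  expect_equal(ensemble_predict(b2, b$train_fps[1:5, ]),
               ensemble_predict(b, b$train_fps[1:5, ]))
  unlink(d, recursive = TRUE)
})
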
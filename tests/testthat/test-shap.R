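test_that("tree Shapley values equal exhaustive-subset Shapley (RF and GBDT)", {
  set.seed(21)
  p <- 6
  X <- matrix(rbinom(150 * p, 1, 0.5), 150, p)
  y <- 2 * X[, 1] - X[, 2] + 0.8 * X[, 3] * X[, 4] + rnorm(150, 0, 0.1)

  rf <- randomForest::randomForest(x = X, y = y, ntree = 10, maxnodes = 8)
  rtrees <- reposcreen:::rf_to_trees(rf, X)
  got <- reposcreen:::treeshap_values(rtrees, X[1:5, , drop = FALSE])
  for (i in 1:5) {
    vfun <- function(S) tree_walk_value(rtrees, X[i, ], S)
    ref <- shapley_exhaustive(vfun, p)
    expect_equal(unname(got$phi[i, ]), ref, tolerance = 1e-6)
  }
  expect_equal(got$base, tree_walk_value(rtrees, X[1, ], integer(0)),
               tolerance = 1e-9)

  bst <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = 3, eta = 0.4,
                  base_score = mean(y), nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = 8, verbose = 0)
  xtrees <- reposcreen:::xgb_to_trees(bst)
  pc <- predict(bst, xgboost::xgb.DMatrix(X[1:5, ], nthread = 1),
                predcontrib = TRUE)
  for (i in 1:5) {
    vfun <- function(S) tree_walk_value(xtrees, X[i, ], S)
    ref <- shapley_exhaustive(vfun, p)
    expect_equal(unname(pc[i, 1:p]), ref, tolerance = 1e-5)
  }
})

test_that("attributions satisfy local accuracy for every model", {
  lib <- gen_sar_library(n = 80, seed = 12)
  b <- train_npapm(lib$data[, 1:3], fp_params = list(nbits = 256), seed = 12)
  X <- b$train_fps[1:8, , drop = FALSE]
  att <- shap_attribute(b, X, background_size = 20, nsamples = 400, seed = 2)
  for (k in names(att)) {
    a <- att[[k]]
    tol <- if (k == "SVM") 1e-6 else 1e-6
    extra <- if (k == "GBDT") 1e-5 else 0  # xgboost stores floats
    expect_lt(max(abs(rowSums(a$phi) + a$base - a$prediction)), tol + extra)
  }
})

test_that("kernel SHAP is exact on enumerable models and respects symmetry", {
  set.seed(9)
  bg <- matrix(rbinom(40 * 6, 1, 0.5), 40, 6)
  w <- c(3, -2, 1, 0, 0, 0.5)
  f <- function(M) as.numeric(M %*% w)
  x <- c(1, 0, 1, 1, 0, 1)
  ks <- kernel_shap(f, x, bg, seed = 1)
  expect_equal(ks$phi, w * (x - colMeans(bg)), tolerance = 1e-8)
  expect_equal(ks$base + sum(ks$phi), f(matrix(x, 1)), tolerance = 1e-10)

  # symmetric features with identical behavior get identical attributions
  bg2 <- matrix(c(0, 0), 1, 2)
  f2 <- function(M) as.numeric(M[, 1] + M[, 2])
  ks2 <- kernel_shap(f2, c(1, 1), bg2, seed = 1)
  expect_equal(ks2$phi[1], ks2$phi[2], tolerance = 1e-6)

  # features constant across background and instance get zero
  bg3 <- cbind(matrix(rbinom(20 * 3, 1, 0.5), 20, 3), 1)
  f3 <- function(M) as.numeric(M %*% c(1, 2, 3, 4))
  ks3 <- kernel_shap(f3, c(1, 0, 1, 1), bg3, seed = 1)
  expect_equal(ks3$phi[4], 0)
  expect_error(kernel_shap(f3, c(1, 0, 1, 1), bg3[0, , drop = FALSE]), "empty")
})

test_that("a constant model attributes nothing", {
  lib <- gen_sar_library(n = 50, seed = 14)
  b <- train_npapm(lib$data[, 1:3], fp_params = list(nbits = 256), seed = 14)
  b$models$RF <- structure(list(kind = "RF", constant = 5.5), class = "npapm_model")
  att <- shap_attribute(b, b$train_fps[1:3, ], models = "RF")
  expect_true(all(att$RF$phi == 0))
  expect_equal(att$RF$base, 5.5)
})

test_that("top-feature ranking uses mean |phi| with index tie-breaks", {
  phi <- rbind(c(0, 3, -1, 0.5), c(0, -3, 1, 0.5))
  expect_equal(top_features(phi, 3), c(2L, 3L, 4L))
  zeros <- matrix(0, 4, 6)
  expect_equal(top_features(zeros, 3), 1:3)
  expect_error(top_features(phi, 10), "features available")
})

test_that("consensus is plain intersection with pairwise Venn counts", {
  tk <- list(RF = c(5L, 2L, 9L), SVM = c(2L, 9L, 7L), GBDT = c(9L, 1L, 2L))
  cons <- consensus_features(tk)
  expect_equal(cons$intersection, c(2L, 9L))
  expect_named(cons$pairwise, c("RF&SVM", "RF&GBDT", "SVM&GBDT"))
  expect_equal(cons$pairwise[["RF&SVM"]], c(2L, 9L))
  ident <- consensus_features(list(a = 1:5, b = 1:5))
  expect_equal(ident$intersection, 1:5)
  expect_equal(consensus_features(list(a = 1:3, b = 4:6))$intersection, integer(0))
  expect_error(consensus_features(list(a = 1:3)), ">= 2")
})

test_that("compound explanation reports presence, phi and substructures, and round-trips JSON", {
  lib <- gen_sar_library(n = 80, seed = 15)
  b <- train_npapm(lib$data[, 1:3], fp_params = list(nbits = 512), seed = 15)
  mols <- parse_molecules(lib$data$smiles, lib$data$compound_id)
  X <- fingerprint_matrix(mols, "TOPO_PATH", list(nbits = 512))
  bit <- planted_bit(X, lib$truth$carriers)
  carrier <- lib$data$smiles[lib$data$carrier][1]
  ex <- explain_compound(b, carrier, as.integer(bit),
                         background_size = 15, nsamples = 200, seed = 1)
  feat <- ex$features[[1]]
  expect_true(feat$present)
  expect_named(feat$phi, c("RF", "SVM", "GBDT"))
  expect_gt(length(feat$substructures), 0)

  json <- jsonlite::toJSON(unclass(ex), auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_equal(back$features[[1]]$feature, feat$feature)
  expect_equal(unname(unlist(back$features[[1]]$phi)), unname(feat$phi),
               tolerance = 1e-12)

  # a molecule carrying no consensus bit yields an all-absent report
  plain <- explain_compound(b, "CCOCC", as.integer(bit),
                            background_size = 10, nsamples = 100, seed = 1)
  expect_false(plain$features[[1]]$present)
  expect_length(plain$features[[1]]$substructures, 0)
})
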
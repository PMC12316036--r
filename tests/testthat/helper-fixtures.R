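# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# A small parsed molecule set reused by the chemistry tests.
fixture_mols <- function() {
  if (is.null(fixture_env$mols)) {
    fixture_env$mols <- parse_molecules(
      c(paracetamol = "CC(=O)Nc1ccc(O)cc1",
        toluene = "Cc1ccccc1",
        ethanol = "CCO",
        sulfonamide = "CCS(N)(=O)=O",
        methane = "C",
        naphthalene = "c1ccc2ccccc2c1"),
      c("paracetamol", "toluene", "ethanol", "sulfonamide", "methane",
        "naphthalene"))
  }
  fixture_env$mols
}

# The 20-seed SAR recovery experiment shared by the QSAR-recovery and
# consensus-substructure checks (both read from the same runs). Light model
# sizes keep the whole experiment a few minutes; sizes are stated in the
# methods vignette.
sar_experiment <- function() {
  if (!is.null(fixture_env$sar)) return(fixture_env$sar)
  fp_params <- list(nbits = 512)
  light <- list(RF = list(n_trees = 300, max_depth = 16, max_features = 1 / 3),
                SVM = list(cost = 10, gamma = 0.01, epsilon = 0.1),
                GBDT = list(n_estimators = 200, learning_rate = 0.08,
                            max_depth = 4, subsample = 0.8))
  runs <- lapply(1:20, function(seed) {
    lib <- gen_sar_library(n = 200, effect = 1.5, sigma = 0.3, seed = seed)
    mols <- parse_molecules(lib$data$smiles, lib$data$compound_id)
    X <- fingerprint_matrix(mols, "TOPO_PATH", fp_params)
    y <- pec50_from_uM(lib$data$ec50_uM)
    sp <- split_examples(nrow(X), seed)
    fits <- lapply(names(light), function(k)
      fit_model(k, X[sp$train, ], y[sp$train], light[[k]], seed = seed))
    names(fits) <- names(light)
    pred <- rowMeans(vapply(fits, predict_model, numeric(length(sp$test)),
                            X[sp$test, ]))
    r2 <- evaluate_predictions(y[sp$test], pred)$R2
    bit <- planted_bit(X, lib$truth$carriers)

    # SHAP top-20 per model over a fixed instance subsample
    bundle <- structure(list(models = fits, fp_kind = "TOPO_PATH",
                             fp_params = reposcreen:::fp_params_for("TOPO_PATH",
                                                                    fp_params),
                             train_fps = X[sp$train, ], train_y = y[sp$train],
                             split = sp, seed = seed,
                             hyperparameters = light, tuning = list(),
                             metrics = list()),
                        class = "npapm_bundle")
    inst <- X[sp$train[seq_len(20)], , drop = FALSE]
    att <- shap_attribute(bundle, inst, background_size = 16, nsamples = 400,
                          seed = seed)
    topk <- lapply(att, top_features, k = 20)
    list(seed = seed, r2 = r2, bit = as.integer(bit),
         bit_class = attr(bit, "candidates"), topk = topk,
         consensus = consensus_features(topk)$intersection,
         lib = if (seed == 1) lib else NULL,
         mols = if (seed == 1) mols else NULL)
  })
  fixture_env$sar <- runs
  runs
}
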
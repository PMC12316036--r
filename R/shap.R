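# SHAP attribution for the three-model ensemble.
#
# RF and GBDT are explained exactly with path-dependent tree Shapley values
# (the Rcpp kernel in src/treeshap.cpp; xgboost's built-in TreeSHAP serves as
# an independent cross-check in the tests). The SVM is explained with Kernel
# SHAP against a fixed background sample. Local accuracy (base + sum(phi) =
# prediction) holds for every emitted attribution.

# ---- tree ensemble converters ----------------------------------------------

# randomForest -> generic tree list; node covers are estimated by dropping
# the training data through each tree (randomForest does not store them).
rf_to_trees <- function(rf, X_train) {
  X_train <- as.matrix(X_train)
  lapply(seq_len(rf$ntree), function(k) {
    tm <- randomForest::getTree(rf, k, labelVar = FALSE)
    nnode <- nrow(tm)
    left <- as.integer(tm[, "left daughter"]) - 1L
    right <- as.integer(tm[, "right daughter"]) - 1L
    feature <- ifelse(tm[, "status"] == -1, -1L,
                      as.integer(tm[, "split var"]) - 1L)
    threshold <- as.numeric(tm[, "split point"])
    value <- as.numeric(tm[, "prediction"]) / rf$ntree
    left[feature < 0] <- -1L; right[feature < 0] <- -1L
    cover <- numeric(nnode)
    assign_cover <- function(node, rows) {
      cover[node + 1] <<- length(rows)
      if (feature[node + 1] < 0) return(invisible(NULL))
      goleft <- X_train[rows, feature[node + 1] + 1] <= threshold[node + 1]
      assign_cover(left[node + 1], rows[goleft])
      assign_cover(right[node + 1], rows[!goleft])
    }
    assign_cover(0L, seq_len(nrow(X_train)))
    cover[cover == 0] <- 1e-9   # unreachable under the cover sample
    list(left = left, right = right, feature = feature, threshold = threshold,
         value = value, cover = cover, cmp = 1L)
  })
}

# xgboost -> generic tree list (used for cross-checks and generic explains).
xgb_to_trees <- function(bst) {
  dt <- xgboost::xgb.model.dt.tree(model = bst)
  dt <- as.data.frame(dt)
  lapply(split(dt, dt$Tree), function(td) {
    id2idx <- stats::setNames(seq_len(nrow(td)) - 1L, td$ID)
    leaf <- td$Feature == "Leaf"
    list(left = ifelse(leaf, -1L, unname(id2idx[td$Yes])),
         right = ifelse(leaf, -1L, unname(id2idx[td$No])),
         feature = ifelse(leaf, -1L, suppressWarnings(as.integer(td$Feature))),
         threshold = ifelse(leaf, 0, as.numeric(td$Split)),
         value = ifelse(leaf, as.numeric(td$Gain), 0),  # Gain holds leaf value
         cover = as.numeric(td$Cover), cmp = 0L)
  })
}

xgb_base_score <- function(bst) {
  cfg <- xgboost::xgb.config(bst)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  as.numeric(cfg$learner$learner_model_param$base_score)
}

#' Exact tree-Shapley attributions for a tree list
#'
#' @param trees Generic tree list (internal converters produce it).
#' @param X Instance matrix.
#' @return List `phi` (n x p matrix), `base` (scalar expected value).
#' @keywords internal
treeshap_values <- function(trees, X) {
  treeshap_cpp(trees, as.matrix(X))
}

# ---- Kernel SHAP -----------------------------------------------------------

#' Kernel SHAP attribution for a black-box regressor
#'
#' Features identical between the instance and every background row receive
#' phi = 0 exactly; the remaining M features are explained by weighted least
#' squares over coalitions. All 2^M coalitions are enumerated when M <= 13
#' (the result is then the exact Shapley value of the marginal-expectation
#' game); otherwise `nsamples` paired coalitions are drawn with
#' Shapley-kernel size weights.
#'
#' @param predfun Function mapping a feature matrix to predictions.
#' @param x Single instance (numeric vector).
#' @param background Background matrix (rows = reference samples).
#' @param nsamples Coalition budget for the sampled path.
#' @param seed Integer seed.
#' @return List `phi` (length = ncol(background)), `base` (mean background
#'   prediction).
#' @export
kernel_shap <- function(predfun, x, background, nsamples = 2048, seed = 1) {
  background <- as.matrix(background)
  if (nrow(background) < 1) stopf("empty background for kernel SHAP")
  p <- ncol(background)
  phi <- numeric(p)
  base <- mean(predfun(background))
  fx <- as.numeric(predfun(matrix(x, nrow = 1)))
  vary <- which(vapply(seq_len(p), function(j) any(background[, j] != x[j]),
                       logical(1)))
  M <- length(vary)
  if (M == 0) return(list(phi = phi, base = base))
  if (M == 1) {
    phi[vary] <- fx - base
    return(list(phi = phi, base = base))
  }

  if (M <= 13) {
    masks <- as.matrix(expand.grid(rep(list(0:1), M)))
    masks <- masks[rowSums(masks) > 0 & rowSums(masks) < M, , drop = FALSE]
    s <- rowSums(masks)
    w <- (M - 1) / (choose(M, s) * s * (M - s))
  } else {
    masks <- with_seed(seed, {
      sizes <- 1:(M - 1)
      size_w <- (M - 1) / (sizes * (M - sizes))
      half <- ceiling(nsamples / 2)
      sz <- sample(sizes, half, replace = TRUE, prob = size_w)
      mk <- t(vapply(sz, function(s0) {
        z <- integer(M); z[sample.int(M, s0)] <- 1L; z
      }, integer(M)))
      rbind(mk, 1L - mk)          # paired complements
    })
    s <- rowSums(masks)
    w <- rep(1, nrow(masks))      # sampling already follows the kernel
  }

  K <- nrow(masks)
  nbg <- nrow(background)
  # one prediction call over all hybrids
  hybrids <- background[rep(seq_len(nbg), times = K), , drop = FALSE]
  take <- masks[rep(seq_len(K), each = nbg), , drop = FALSE] == 1
  xm <- matrix(x[vary], nrow(hybrids), M, byrow = TRUE)
  hv <- hybrids[, vary, drop = FALSE]
  hv[take] <- xm[take]
  hybrids[, vary] <- hv
  v <- rowsum(predfun(hybrids), rep(seq_len(K), each = nbg)) / nbg

  # constrained WLS: phi0 = base, sum(phi) = fx - base
  Z <- masks
  A <- Z[, -M, drop = FALSE] - Z[, M]
  tgt <- as.numeric(v) - base - Z[, M] * (fx - base)
  AW <- A * w
  H <- crossprod(AW, A) + diag(1e-10, M - 1)
  b <- crossprod(AW, tgt)
  phi_m1 <- solve(H, b)
  phi[vary[-M]] <- phi_m1
  phi[vary[M]] <- (fx - base) - sum(phi_m1)
  list(phi = phi, base = base)
}

# ---- per-model attribution --------------------------------------------------

#' SHAP attributions for every model of a bundle
#'
#' Tree models (RF, GBDT) are explained exactly; the SVM is explained with
#' Kernel SHAP against a fixed background drawn from the training
#' fingerprints (at most `background_size` rows, fixed seed).
#'
#' @param bundle An `npapm_bundle`.
#' @param X Instance matrix in the bundle's fingerprint space (default: the
#'   training fingerprints).
#' @param models Model labels to attribute (default all three).
#' @param background_size Background rows for the kernel explainer.
#' @param nsamples Coalition budget for the kernel explainer.
#' @param seed Integer seed.
#' @return Named list per model: `phi` (n x p), `base`, `prediction`.
#' @export
shap_attribute <- function(bundle, X = NULL, models = MODEL_KINDS,
                           background_size = 100, nsamples = 2048, seed = 1) {
  X <- as.matrix(X %||% bundle$train_fps)
  out <- list()
  for (k in match.arg(models, MODEL_KINDS, several.ok = TRUE)) {
    fit <- bundle$models[[k]]
    pred <- predict_model(fit, X)
    if (!is.null(fit$constant)) {
      out[[k]] <- list(phi = matrix(0, nrow(X), ncol(X)), base = fit$constant,
                       prediction = pred)
    } else if (k == "RF") {
      ts <- treeshap_values(rf_to_trees(fit$model, bundle$train_fps), X)
      out[[k]] <- list(phi = ts$phi, base = ts$base, prediction = pred)
    } else if (k == "GBDT") {
      pc <- stats::predict(fit$model, xgboost::xgb.DMatrix(X, nthread = 1),
                           predcontrib = TRUE)
      out[[k]] <- list(phi = pc[, -ncol(pc), drop = FALSE],
                       base = pc[1, ncol(pc)], prediction = pred)
    } else {
      bg_idx <- with_seed(seed, sample.int(
        nrow(bundle$train_fps), min(background_size, nrow(bundle$train_fps))))
      bg <- bundle$train_fps[bg_idx, , drop = FALSE]
      predfun <- function(M) predict_model(fit, M)
      seeds <- derive_seeds(seed, nrow(X))
      res <- lapply(seq_len(nrow(X)), function(i)
        kernel_shap(predfun, X[i, ], bg, nsamples = nsamples, seed = seeds[i]))
      out[[k]] <- list(phi = do.call(rbind, lapply(res, `[[`, "phi")),
                       base = res[[1]]$base, prediction = pred)
    }
  }
  out
}

#' Rank features by mean absolute SHAP value
#'
#' @param phi Attribution matrix (instances x features) or one element of
#'   [shap_attribute()] output.
#' @param k Number of features to return.
#' @return Integer vector of feature indices, ranked descending by mean |phi|
#'   (ties broken by index).
#' @export
top_features <- function(phi, k = 20) {
  if (is.list(phi)) phi <- phi$phi
  if (ncol(phi) < k) stopf("only %d features available (k = %d)", ncol(phi), k)
  imp <- colMeans(abs(phi))
  order(-imp, seq_along(imp))[seq_len(k)]
}

#' Cross-model consensus of top-k features
#'
#' @param per_model_topk Named list (>= 2 models) of ranked index vectors.
#' @return List of class `consensus_features`: `per_model`, `intersection`,
#'   and `pairwise` (intersection per model pair, for Venn exports).
#' @export
consensus_features <- function(per_model_topk) {
  if (length(per_model_topk) < 2) stopf("need top-k lists from >= 2 models")
  inter <- sort(Reduce(intersect, per_model_topk))
  nm <- names(per_model_topk) %||% paste0("model", seq_along(per_model_topk))
  pairs <- utils::combn(seq_along(per_model_topk), 2, simplify = FALSE)
  pairwise <- lapply(pairs, function(ij)
    sort(intersect(per_model_topk[[ij[1]]], per_model_topk[[ij[2]]])))
  names(pairwise) <- vapply(pairs, function(ij) paste(nm[ij], collapse = "&"), "")
  structure(list(per_model = per_model_topk, intersection = inter,
                 pairwise = pairwise), class = "consensus_features")
}

#' @export
print.consensus_features <- function(x, ...) {
  cat(sprintf("<consensus_features> intersection of %d models: {%s}\n",
              length(x$per_model), paste(x$intersection, collapse = ", ")))
  invisible(x)
}

#' Map a fingerprint bit back to molecular substructures
#'
#' For hashed fingerprint kinds, returns every atom environment of the
#' molecule that set the bit (several environments can collide on one bit),
#' each with atom indices, bond indices and the SMILES of the induced
#' subgraph. For MACCS, returns the predefined key SMARTS (read from the
#' installed OpenBabel data tables; atom indices are not available for
#' SMARTS-defined keys).
#'
#' @param mol A `molecule_record`.
#' @param kind Bit fingerprint kind (PHYSCHEM is not bit-addressable).
#' @param bit 1-based bit index.
#' @param params Fingerprint parameter overrides (must match the
#'   configuration in which `bit` was found).
#' @return List of substructure maps (empty when the bit is not set).
#' @export
bit_substructure <- function(mol, kind, bit, params = list()) {
  kind <- match.arg(kind, setdiff(FP_KINDS, "PHYSCHEM"))
  if (kind == "MACCS") {
    fp <- fingerprint(mol, "MACCS")
    if (fp$values[bit] == 0) return(list())
    sm <- maccs_key_smarts(bit - 1L)
    return(list(list(atoms = integer(0), bonds = integer(0),
                     smarts = sm, smiles = NA_character_)))
  }
  fp <- fingerprint(mol, kind, params, bit_info = TRUE)
  if (fp$values[bit] == 0) return(list())
  lapply(fp$bit_info[[bit]], function(env) {
    list(atoms = env$atoms, bonds = env$bonds, smarts = NA_character_,
         smiles = subgraph_smiles(mol, env$atoms))
  })
}

# MACCS key SMARTS from the OpenBabel data installation (when locatable).
# Data lines look like:  162:('[a]',0),  # key:('SMARTS', min count)
maccs_key_smarts <- local({
  cache <- NULL
  function(key) {
    if (is.null(cache)) {
      cache <<- list()
      f <- Sys.glob(c(file.path(dirname(dirname(Sys.which("obabel"))),
                                "share", "openbabel*", "MACCS.txt"),
                      file.path(dirname(dirname(Sys.which("obabel"))),
                                "share", "openbabel*", "*", "MACCS.txt")))
      if (length(f) >= 1) {
        ln <- readLines(f[1])
        hits <- regmatches(ln, regexec("^\\s*(\\d+):\\('([^']*)'", ln))
        for (mm in hits)
          if (length(mm) == 3) cache[[mm[2]]] <<- mm[3]
      }
    }
    cache[[as.character(key)]] %||% NA_character_
  }
})

#' Explain a compound against consensus features
#'
#' For each consensus feature, reports whether the compound's fingerprint
#' sets the bit, the per-model SHAP values of that feature for this compound,
#' and (when set) the substructure map(s) behind the bit.
#'
#' @param bundle An `npapm_bundle`.
#' @param mol A `molecule_record` or a single SMILES string.
#' @param consensus A `consensus_features` object (non-empty intersection) or
#'   an integer vector of feature indices.
#' @param ... Passed to [shap_attribute()] (e.g. `nsamples`, `seed`).
#' @return List of class `compound_explanation`; serializable with
#'   [jsonlite::toJSON()].
#' @export
explain_compound <- function(bundle, mol, consensus, ...) {
  if (is.character(mol)) mol <- canonicalize(mol, "query")
  if (!isTRUE(mol$parse_ok)) stopf("compound SMILES did not parse")
  feats <- if (inherits(consensus, "consensus_features")) consensus$intersection
  else as.integer(consensus)
  if (length(feats) == 0) stopf("empty consensus feature set")
  X <- fingerprint_matrix(list(mol), bundle$fp_kind, bundle$fp_params)
  attr_ <- shap_attribute(bundle, X, ...)
  per_feature <- lapply(feats, function(b) {
    present <- X[1, b] != 0
    list(feature = b, present = present,
         phi = vapply(attr_, function(a) a$phi[1, b], numeric(1)),
         substructures = if (present)
           bit_substructure(mol, bundle$fp_kind, b, bundle$fp_params)
         else list())
  })
  structure(list(compound_id = mol$compound_id,
                 smiles = mol$smiles_canonical,
                 prediction_pec50 = unname(ensemble_predict(bundle, X)),
                 features = per_feature),
            class = "compound_explanation")
}

#' @export
print.compound_explanation <- function(x, ...) {
  cat(sprintf("<compound_explanation> %s (pred pEC50 %.2f)\n",
              x$compound_id, x$prediction_pec50))
  for (f in x$features)
    cat(sprintf("  feature %d: %s\n", f$feature,
                if (f$present) sprintf("present (%d substructure map(s))",
                                       length(f$substructures)) else "absent"))
  invisible(x)
}
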
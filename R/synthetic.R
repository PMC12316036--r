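# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of its arguments and seed, and returns a `truth` block that
# fully determines regeneration and every expected recovery statistic.

#' Generate multi-cohort two-group expression data with planted DE genes
#'
#' Baseline expression is Normal(8, 1) per gene (log2-intensity scale, the
#' data class of microarray cohorts); a fixed set of planted genes is shifted
#' by +/- `effect` log2 units in cases (sign fixed per gene and shared across
#' cohorts); iid Normal(0, sigma) noise on every value.
#'
#' @param n_genes Genes per cohort.
#' @param n_case,n_control Samples per group.
#' @param n_de Number of planted DE genes (<= n_genes).
#' @param effect Case shift in log2 units.
#' @param sigma Noise standard deviation.
#' @param n_cohorts Number of cohorts sharing the planted set.
#' @param seed Integer seed.
#' @return List with `cohorts` (list of `list(matrix, groups)`; matrices are
#'   already on log2 scale) and `truth` (`de_genes`, `signs`, arguments,
#'   seed).
#' @export
gen_cohorts <- function(n_genes = 2000, n_case = 10, n_control = 10,
                        n_de = 100, effect = 2, sigma = 0.5, n_cohorts = 3,
                        seed = 1) {
  if (n_de > n_genes) stopf("n_de must be <= n_genes")
  if (min(n_case, n_control) < 2) stopf("need >= 2 samples per group")
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    de_idx <- sample.int(n_genes, n_de)
    signs <- sample(c(-1, 1), n_de, replace = TRUE)
    base <- stats::rnorm(n_genes, 8, 1)
    cohorts <- lapply(seq_len(n_cohorts), function(ci) {
      ns <- n_case + n_control
      m <- matrix(stats::rnorm(n_genes * ns, 0, sigma), n_genes, ns) + base
      m[de_idx, seq_len(n_case)] <- m[de_idx, seq_len(n_case)] + signs * effect
      rownames(m) <- genes
      colnames(m) <- sprintf("C%d_S%02d", ci, seq_len(ns))
      groups <- stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                                colnames(m))
      attr(m, "normalized") <- TRUE
      list(matrix = m, groups = groups)
    })
    list(cohorts = cohorts,
         truth = list(de_genes = genes[de_idx], signs = signs,
                      up_genes = genes[de_idx][signs > 0],
                      down_genes = genes[de_idx][signs < 0],
                      n_genes = n_genes, n_case = n_case,
                      n_control = n_control, effect = effect, sigma = sigma,
                      n_cohorts = n_cohorts, seed = seed))
  })
}

#' Generate a compound-signature database with planted reversers
#'
#' Background signatures are Normal(0, 1) per gene (z-score scale). Reverser
#' compounds subtract `strength` from the query's up genes and add it to the
#' query's down genes, so their profiles reverse the disease signature. Each
#' compound gets 1-3 replicate "conditions" to exercise profile averaging.
#'
#' @param n_compounds Number of compounds.
#' @param n_genes Gene universe size (>= query genes; query genes are
#'   embedded in it).
#' @param n_reversers Number of planted reversers (<= n_compounds).
#' @param query A [gene_set_pair()] giving the disease signature.
#' @param strength Reversal shift in z-score units.
#' @param seed Integer seed.
#' @return List with `profiles` (input for [average_compound_profiles()]),
#'   `ranked` (averaged, ranked profiles ready for [query_database()]),
#'   `manifest` (signature_id, compound_id, condition) and `truth`.
#' @export
gen_signature_db <- function(n_compounds = 100, n_genes = 1000,
                             n_reversers = 5, query, strength = 3, seed = 1) {
  if (n_reversers > n_compounds) stopf("n_reversers must be <= n_compounds")
  qgenes <- c(query$up, query$down)
  if (length(qgenes) > n_genes) stopf("gene universe smaller than the query")
  with_seed(seed, {
    genes <- unique(c(qgenes, sprintf("BG%05d", seq_len(n_genes))))[seq_len(n_genes)]
    cmpds <- sprintf("CP%04d", seq_len(n_compounds))
    reversers <- sample(cmpds, n_reversers)
    ids <- character(0); cps <- character(0); conds <- character(0)
    vals <- list()
    for (cp in cmpds) {
      n_rep <- sample(1:3, 1)
      for (r in seq_len(n_rep)) {
        v <- stats::rnorm(n_genes)
        names(v) <- genes
        if (cp %in% reversers) {
          v[query$up] <- v[query$up] - strength
          v[query$down] <- v[query$down] + strength
        }
        ids <- c(ids, sprintf("%s_r%d", cp, r))
        cps <- c(cps, cp); conds <- c(conds, sprintf("cond%d", r))
        vals[[length(vals) + 1]] <- v
      }
    }
    profiles <- list(compound_id = cps, values = vals)
    avg <- average_compound_profiles(profiles)
    ranked <- mapply(rank_profile, avg, names(avg), SIMPLIFY = FALSE)
    list(profiles = profiles, ranked = ranked,
         manifest = data.frame(signature_id = ids, compound_id = cps,
                               condition = conds, stringsAsFactors = FALSE),
         truth = list(reversers = sort(reversers), strength = strength,
                      n_compounds = n_compounds, n_genes = n_genes,
                      seed = seed))
  })
}

SAR_SCAFFOLDS <- c("c1ccc(%s)cc1", "c1ccc(%s)nc1", "C1CCC(%s)CC1",
                   "c1cc(%s)sc1", "c1ccc2cc(%s)ccc2c1")
SAR_SUBSTITUENTS <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "N", "NC",
                      "N(C)C", "F", "Cl", "Br", "C(=O)C", "C(=O)OC", "C#N",
                      "CO", "CCO", "OCC", "CCN", "C(F)(F)F")

#' Generate a synthetic SAR library with a planted activity substructure
#'
#' Valid SMILES are enumerated by decorating aromatic/aliphatic scaffolds
#' with small substituents; about half the compounds additionally carry the
#' planted substructure (default: a sulfonamide), and
#' pEC50 = base + effect x carrier + Normal(0, sigma). EC50 in uM is emitted
#' via the back-transform 10^(6 - pEC50).
#'
#' @param n Library size.
#' @param base_pec50 Baseline potency.
#' @param effect Potency gain of substructure carriers (pEC50 units).
#' @param sigma Noise standard deviation (pEC50 units).
#' @param substructure SMILES fragment planted on carriers (attachable as a
#'   substituent).
#' @param seed Integer seed.
#' @return List with `data` (data.frame compound_id, smiles, ec50_uM,
#'   carrier) and `truth` (carrier ids, substructure, arguments, seed).
#' @export
gen_sar_library <- function(n = 200, base_pec50 = 5, effect = 1.5,
                            sigma = 0.3, substructure = "S(N)(=O)=O",
                            seed = 1) {
  with_seed(seed, {
    carrier <- sample(rep_len(c(TRUE, FALSE), n))
    scaf <- sample(SAR_SCAFFOLDS, n, replace = TRUE)
    sub1 <- sample(SAR_SUBSTITUENTS, n, replace = TRUE)
    sub2 <- sample(c("", SAR_SUBSTITUENTS), n, replace = TRUE)
    smiles <- vapply(seq_len(n), function(i) {
      dec <- if (carrier[i]) substructure else sub1[i]
      extra <- if (nzchar(sub2[i])) paste0("C(", sub2[i], ")") else ""
      sprintf(scaf[i], paste0(extra, dec))
    }, character(1))
    ids <- sprintf("SAR%04d", seq_len(n))
    pec50 <- base_pec50 + effect * carrier + stats::rnorm(n, 0, sigma)
    data <- data.frame(compound_id = ids, smiles = smiles,
                       ec50_uM = uM_from_pec50(pec50), carrier = carrier,
                       stringsAsFactors = FALSE)
    list(data = data,
         truth = list(carriers = ids[carrier], substructure = substructure,
                      base_pec50 = base_pec50, effect = effect, sigma = sigma,
                      n = n, seed = seed))
  })
}

#' Locate the fingerprint bit that tracks the planted substructure
#'
#' Scans a fingerprint matrix for the bit(s) whose presence best separates
#' carrier from non-carrier compounds; the best bit must be present in at
#' least `min_sens` of carriers and at most `1 - min_spec` of non-carriers.
#'
#' @param X Bit fingerprint matrix (rows named by compound id).
#' @param carriers Character vector of carrier compound ids.
#' @param min_sens,min_spec Minimum sensitivity / specificity for a bit to
#'   count as tracking the substructure.
#' @return Integer bit index (the best-separating bit), with attribute
#'   `candidates` (all bits passing the thresholds), or NA when none passes.
#' @export
planted_bit <- function(X, carriers, min_sens = 0.95, min_spec = 0.95) {
  is_carrier <- rownames(X) %in% carriers
  sens <- colMeans(X[is_carrier, , drop = FALSE] != 0)
  fpr <- colMeans(X[!is_carrier, , drop = FALSE] != 0)
  ok <- which(sens >= min_sens & fpr <= 1 - min_spec)
  if (length(ok) == 0) return(NA_integer_)
  best <- ok[order(-(sens[ok] - fpr[ok]), ok)][1]
  structure(as.integer(best), candidates = as.integer(ok))
}
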
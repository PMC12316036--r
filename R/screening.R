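# The screening funnel: connectivity results -> KS screen -> curated list ->
# applicability domain -> ensemble potency prediction -> ranking -> exclusions
# -> shortlist, with full per-compound provenance.

#' Run the compound-screening funnel
#'
#' Stages, in order: KS uniformity screen on the connectivity results;
#' intersection with a curated candidate list (skipped when absent);
#' applicability-domain gate (strict Tanimoto > threshold); ensemble pEC50
#' prediction; ranking ascending by predicted EC50 (most potent first, ties
#' by connectivity score then compound id); top-n cut; removal of
#' exclusion-list members. Every record keeps the flag of the stage that
#' dropped it, so the funnel accounting is fully reconstructible.
#'
#' @param scores data.frame from [query_database()] (columns `compound_id`,
#'   `score`, `ks_p`).
#' @param library_df data.frame with `compound_id`, `smiles` for candidates.
#' @param bundle An `npapm_bundle` for AD and potency prediction.
#' @param curated Optional character vector of curated compound ids.
#' @param exclusions Optional character vector of excluded compound ids.
#' @param config List: `ks_alpha` (0.05), `ad_threshold` (0.6), `top_n` (50).
#' @return data.frame of `ScreeningRecord`s, one row per scored compound,
#'   with attribute `stage_counts`.
#' @export
run_funnel <- function(scores, library_df, bundle, curated = NULL,
                       exclusions = NULL, config = list()) {
  cfg <- utils::modifyList(list(ks_alpha = 0.05, ad_threshold = 0.6, top_n = 50),
                           config)
  if (cfg$top_n < 1) stopf("top_n must be >= 1")
  n <- nrow(scores)
  rec <- data.frame(compound_id = scores$compound_id,
                    score = scores$score, ks_p = scores$ks_p,
                    smiles = library_df$smiles[match(scores$compound_id,
                                                     library_df$compound_id)],
                    ad_max_tanimoto = rep(NA_real_, n), in_domain = rep(NA, n),
                    pred_pec50 = rep(NA_real_, n),
                    pred_ec50_uM = rep(NA_real_, n),
                    rank = rep(NA_integer_, n),
                    status = rep("candidate", n),
                    exclusion_reason = rep("", n), stringsAsFactors = FALSE)
  counts <- c(input = nrow(rec))

  live <- rec$ks_p < cfg$ks_alpha
  rec$status[!live] <- "ks_fail"
  counts["ks_screen"] <- sum(live)

  if (!is.null(curated)) {
    out <- live & !(rec$compound_id %in% curated)
    rec$status[out] <- "curated_out"
    live <- live & !out
  }
  counts["curated"] <- sum(live)

  missing_smiles <- live & (is.na(rec$smiles) | !nzchar(rec$smiles))
  rec$status[missing_smiles] <- "smiles_missing"
  live <- live & !missing_smiles

  if (any(live)) {
    mols <- parse_molecules(rec$smiles[live], rec$compound_id[live])
    ok <- vapply(mols, `[[`, logical(1), "parse_ok")
    bad_ids <- rec$compound_id[live][!ok]
    rec$status[rec$compound_id %in% bad_ids] <- "smiles_missing"
    live[rec$compound_id %in% bad_ids] <- FALSE
    if (any(ok)) {
      X <- fingerprint_matrix(mols[ok], bundle$fp_kind, bundle$fp_params)
      ad <- applicability(bundle, X, threshold = cfg$ad_threshold)
      idx <- match(ad$compound_id, rec$compound_id)
      rec$ad_max_tanimoto[idx] <- ad$max_tanimoto
      rec$in_domain[idx] <- ad$in_domain
      ad_fail <- live & !is.na(rec$in_domain) & !rec$in_domain
      rec$status[ad_fail] <- "ad_fail"
      live <- live & !ad_fail
      counts["in_domain"] <- sum(live)

      if (any(live)) {
        Xl <- X[match(rec$compound_id[live], rownames(X)), , drop = FALSE]
        pp <- ensemble_predict(bundle, Xl)
        rec$pred_pec50[live] <- pp
        rec$pred_ec50_uM[live] <- uM_from_pec50(pp)
      }
    } else counts["in_domain"] <- 0
  } else counts["in_domain"] <- 0

  ord <- order(rec$pred_ec50_uM[live], rec$score[live], rec$compound_id[live])
  live_idx <- which(live)[ord]
  rec$rank[live_idx] <- seq_along(live_idx)
  beyond <- live_idx[-seq_len(min(cfg$top_n, length(live_idx)))]
  rec$status[beyond] <- "rank_out"
  live[beyond] <- FALSE
  counts["top_n"] <- sum(live)

  if (!is.null(exclusions)) {
    excl <- live & rec$compound_id %in% exclusions
    rec$status[excl] <- "excluded"
    rec$exclusion_reason[excl] <- "exclusion list"
    live <- live & !excl
  }
  counts["shortlist"] <- sum(live)
  rec$status[live] <- "shortlisted"
  attr(rec, "stage_counts") <- counts
  rec
}

#' Summarize a funnel run
#'
#' @param records Output of [run_funnel()].
#' @param config The funnel configuration used (stored for provenance).
#' @param seed Seed(s) used upstream (stored for provenance).
#' @return List of class `funnel_report`: `stage_counts`, `shortlist`
#'   (data.frame sorted by rank), `status_table`, and a `provenance` block
#'   (config and a deterministic content hash of the records).
#' @export
funnel_report <- function(records, config = list(), seed = NULL) {
  counts <- attr(records, "stage_counts") %||%
    stats::setNames(integer(0), character(0))
  short <- records[records$status == "shortlisted", , drop = FALSE]
  short <- short[order(short$rank), , drop = FALSE]
  digest <- hash_ints(utf8ToInt(paste(
    records$compound_id, records$status, round(records$score, 10),
    collapse = "|")))
  structure(list(stage_counts = as.list(counts),
                 status_table = as.list(table(records$status)),
                 shortlist = short,
                 provenance = list(config = config, seed = seed,
                                   record_hash = digest)),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n  stages: ",
      paste(sprintf("%s=%d", names(x$stage_counts), unlist(x$stage_counts)),
            collapse = " -> "), "\n", sep = "")
  cat(sprintf("  shortlist: %d compound(s)\n", nrow(x$shortlist)))
  invisible(x)
}
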
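#' Build a ranked profile from per-gene values
#'
#' Genes are sorted descending by value (rank 1 = most up-regulated by the
#' compound); ties break deterministically by gene id lexical order (C locale).
#'
#' @param values Named numeric vector, one value per gene.
#' @param compound_id Optional compound identifier carried along.
#' @return Object of class `ranked_profile`: list with `ranks` (named integer
#'   permutation of 1..n), `n`, `compound_id`.
#' @export
rank_profile <- function(values, compound_id = NA_character_) {
  ids <- names(values)
  if (is.null(ids) || anyDuplicated(ids)) stopf("values must be named with unique gene ids")
  if (any(!is.finite(values))) stopf("non-finite values in profile")
  ord <- order(-values, ids, method = "radix")
  ranks <- integer(length(values))
  ranks[ord] <- seq_along(values)
  names(ranks) <- ids
  structure(list(ranks = ranks, n = length(ranks), compound_id = compound_id),
            class = "ranked_profile")
}

#' Average replicate profiles per compound
#'
#' Collapses all conditions (dose, cell line, duration) of a compound by the
#' unweighted arithmetic mean per gene on the value scale; the averaged vector
#' is re-ranked downstream.
#'
#' @param profiles data.frame-like list with elements `compound_id` (character
#'   vector), `values` (list of named numeric vectors over a shared gene
#'   universe), or a list of `list(compound_id=, values=)` entries.
#' @return Named list: compound_id -> averaged named numeric vector.
#' @export
average_compound_profiles <- function(profiles) {
  if (!is.null(profiles$compound_id)) {
    ids <- profiles$compound_id
    vals <- profiles$values
  } else {
    ids <- vapply(profiles, `[[`, "", "compound_id")
    vals <- lapply(profiles, `[[`, "values")
  }
  genes <- names(vals[[1]])
  for (v in vals) {
    if (!identical(sort(names(v)), sort(genes)))
      stopf("profiles do not share a gene universe")
  }
  out <- lapply(split(seq_along(ids), ids), function(idx) {
    rowMeans(do.call(cbind, lapply(vals[idx], function(v) v[genes])))
  })
  out[unique(ids)]
}

#' KS enrichment score of a gene set in a ranked profile
#'
#' With the sorted in-set ranks \eqn{V(1) < \dots < V(t)} among \eqn{n} genes,
#' \eqn{a = \max_j [j/t - V(j)/n]} and \eqn{b = \max_j [V(j)/n - (j-1)/t]};
#' the enrichment score is \eqn{a} if \eqn{a > b}, else \eqn{-b}. Positive
#' scores mean the set concentrates at the top of the ranking.
#'
#' @param profile A [rank_profile()].
#' @param geneset Character vector of genes (non-empty, within the universe).
#' @return List with `a`, `b`, `es`.
#' @export
enrichment_score <- function(profile, geneset) {
  geneset <- unique(as.character(geneset))
  t <- length(geneset)
  if (t < 1) stopf("empty gene set")
  missing <- setdiff(geneset, names(profile$ranks))
  if (length(missing) > 0)
    stopf("genes missing from profile universe: %s",
          paste(utils::head(missing, 10), collapse = ", "))
  n <- profile$n
  V <- sort(unname(profile$ranks[geneset]))
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  list(a = a, b = b, es = if (a > b) a else -b)
}

#' Combine up and down enrichment scores into a connectivity score
#'
#' Lamb-2006 convention: when the up and down enrichment scores share a sign
#' the compound neither reverses nor mimics the signature and the score is 0;
#' otherwise \eqn{s = (es_{up} - es_{down})/2 \in [-1, 1]}. Negative s =
#' reversal of the disease signature.
#'
#' @param es_up,es_down Enrichment scores in \[-1, 1\].
#' @return Connectivity score in \[-1, 1\].
#' @export
connectivity_score <- function(es_up, es_down) {
  mapply(function(u, d) {
    if (sign(u) == sign(d)) 0 else (u - d) / 2
  }, es_up, es_down)
}

#' Score a compound-signature database against a disease query
#'
#' For every compound profile, computes the up and down KS enrichment scores,
#' the overall connectivity score, and a one-sample KS uniformity p-value of
#' the pooled query-gene ranks within the profile (the screen statistic).
#' Results are sorted ascending by score: the strongest reversers come first.
#'
#' @param db List of [rank_profile()] objects.
#' @param query A [gene_set_pair()] (both sets non-empty).
#' @param min_overlap Minimum fraction of query genes that must be present in
#'   each profile's universe (gene symbols are matched case-insensitively).
#' @return data.frame `compound_id, es_up, es_down, score, ks_p, rank`.
#' @export
query_database <- function(db, query, min_overlap = 0.9) {
  if (length(query$up) == 0 || length(query$down) == 0)
    stopf("query up and down sets must both be non-empty")
  rows <- lapply(db, function(prof) {
    uni <- names(prof$ranks)
    match_set <- function(set) {
      hit <- uni[match(toupper(set), toupper(uni))]
      hit[!is.na(hit)]
    }
    up <- match_set(query$up); down <- match_set(query$down)
    frac <- (length(up) + length(down)) / (length(query$up) + length(query$down))
    if (frac < min_overlap)
      stopf("compound '%s': only %.0f%% of query genes found in profile universe",
            prof$compound_id, 100 * frac)
    eu <- enrichment_score(prof, up)
    ed <- enrichment_score(prof, down)
    ranks <- unname(prof$ranks[c(up, down)])
    ks <- suppressWarnings(stats::ks.test((ranks - 0.5) / prof$n, "punif"))
    data.frame(compound_id = prof$compound_id, es_up = eu$es, es_down = ed$es,
               score = connectivity_score(eu$es, ed$es), ks_p = ks$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$score, res$compound_id), ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Filter connectivity results by KS uniformity p-value
#'
#' Retains compounds whose query-gene rank distribution departs from
#' uniformity at level `alpha` (`ks_p < alpha`); `alpha = 1` is the identity.
#'
#' @param results data.frame from [query_database()].
#' @param alpha Significance level (default 0.05).
#' @return Filtered data.frame; a message reports the retained count.
#' @export
ks_filter <- function(results, alpha = 0.05) {
  keep <- if (alpha >= 1) rep(TRUE, nrow(results)) else results$ks_p < alpha
  message(sprintf("ks_filter: %d of %d compounds retained at alpha=%g",
                  sum(keep), nrow(results), alpha))
  results[keep, , drop = FALSE]
}

#' Load a compound-signature database from a TSV matrix and manifest
#'
#' @param db_path TSV, genes in rows (first column gene id), one column per
#'   signature id.
#' @param manifest_path CSV with columns `signature_id, compound_id, condition`.
#' @return List of averaged, ranked profiles (one per compound) ready for
#'   [query_database()].
#' @export
read_signature_db <- function(db_path, manifest_path) {
  m <- read_expression_tsv(db_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  miss <- setdiff(man$signature_id, colnames(m))
  if (length(miss) > 0) stopf("manifest signatures missing from matrix: %s",
                              paste(utils::head(miss, 5), collapse = ", "))
  profs <- list(compound_id = man$compound_id,
                values = lapply(man$signature_id, function(s) m[, s]))
  avg <- average_compound_profiles(profs)
  mapply(rank_profile, avg, names(avg), SIMPLIFY = FALSE, USE.NAMES = TRUE)
}
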
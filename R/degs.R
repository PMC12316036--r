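#' Moderated two-sample t-test per gene
#'
#' Computes the case-minus-control log2 fold change and a moderated t-statistic
#' in which per-gene variances are shrunk toward a pooled prior by empirical
#' Bayes (Smyth-style): \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)}, with
#' the prior \eqn{(d_0, s_0^2)} estimated by method of moments from the sample
#' variance distribution (via [limma::squeezeVar()]); p-values come from the t
#' distribution with \eqn{d + d_0} degrees of freedom. Setting `prior_df = 0`
#' recovers the ordinary pooled-variance two-sample t-test exactly.
#'
#' @param matrix Normalized expression matrix, genes x samples.
#' @param groups Named character vector mapping sample id to `"case"` or
#'   `"control"` (every matrix column must be labeled).
#' @param prior_df Optional prior degrees of freedom override; `NULL` (default)
#'   estimates it empirically, `0` disables moderation.
#' @return data.frame with columns `gene`, `logFC`, `t`, `p`, `p_adj_BH`.
#' @export
moderated_t_test <- function(matrix, groups, prior_df = NULL) {
  samp <- colnames(matrix)
  if (is.null(samp) || !all(samp %in% names(groups)))
    stopf("every matrix sample must be labeled in `groups`")
  lab <- groups[samp]
  if (!all(lab %in% c("case", "control")))
    stopf("group labels must be 'case' or 'control'")
  case <- matrix[, lab == "case", drop = FALSE]
  ctrl <- matrix[, lab == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2)
    stopf("each group needs >= 2 samples (got case=%d, control=%d)", n1, n2)

  logFC <- rowMeans(case) - rowMeans(ctrl)
  v1 <- apply(case, 1, stats::var)
  v2 <- apply(ctrl, 1, stats::var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df

  if (!is.null(prior_df) && prior_df == 0) {
    s2_post <- s2
    df_total <- df
  } else {
    sq <- limma::squeezeVar(s2, df = df)
    d0 <- if (is.null(prior_df)) sq$df.prior else prior_df
    if (is.null(prior_df)) {
      s2_post <- sq$var.post
    } else {
      s2_post <- (d0 * sq$var.prior + df * s2) / (d0 + df)
    }
    df_total <- df + d0
  }

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- logFC / se
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  data.frame(gene = rownames(matrix), logFC = unname(logFC), t = unname(tstat),
             p = unname(p), p_adj_BH = stats::p.adjust(unname(p), "BH"),
             stringsAsFactors = FALSE)
}

#' Construct an up/down gene-set pair
#'
#' @param up,down Character vectors of gene symbols; must be disjoint.
#' @return Object of class `gene_set_pair` with elements `up`, `down`.
#' @export
gene_set_pair <- function(up, down) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  clash <- intersect(up, down)
  if (length(clash) > 0)
    stopf("genes present in both up and down sets: %s",
          paste(utils::head(clash, 5), collapse = ", "))
  structure(list(up = up, down = down), class = "gene_set_pair")
}

#' @export
print.gene_set_pair <- function(x, ...) {
  cat(sprintf("<gene_set_pair> %d up / %d down genes\n",
              length(x$up), length(x$down)))
  invisible(x)
}

classify_degs <- function(table, p_thresh, lfc_thresh) {
  ifelse(table$p < p_thresh & table$logFC > lfc_thresh, "up",
         ifelse(table$p < p_thresh & table$logFC < -lfc_thresh, "down", "stable"))
}

#' Threshold a DEG table into up / down gene sets
#'
#' Strict inequalities on both thresholds: up means `p < p_thresh` and
#' `logFC > lfc_thresh`; down means `p < p_thresh` and `logFC < -lfc_thresh`.
#' No multiple-testing correction is applied to the filter (the BH-adjusted
#' column in the table is informational only).
#'
#' @param table DEG table from [moderated_t_test()].
#' @param p_thresh Raw p-value cutoff (default 0.05).
#' @param lfc_thresh Absolute log2 fold-change cutoff (default 0: any nonzero
#'   fold change passes).
#' @return A [gene_set_pair()]. Empty sets are allowed (a message is emitted).
#' @export
filter_degs <- function(table, p_thresh = 0.05, lfc_thresh = 0) {
  dir <- classify_degs(table, p_thresh, lfc_thresh)
  pair <- gene_set_pair(table$gene[dir == "up"], table$gene[dir == "down"])
  if (length(pair$up) == 0 || length(pair$down) == 0)
    message("filter_degs: empty ", if (length(pair$up) == 0) "up" else "down",
            " set at p<", p_thresh, ", |logFC|>", lfc_thresh)
  pair
}

#' Intersect up/down signatures across cohorts
#'
#' Up sets are intersected with up sets and down with down. A gene landing in
#' both resulting sets (a cross-cohort sign conflict) is removed from both and
#' reported via a message. Order-invariant and associative.
#'
#' @param pairs List of [gene_set_pair()] objects (length >= 1).
#' @return A [gene_set_pair()] with the intersected sets.
#' @export
intersect_signatures <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  up <- Reduce(intersect, lapply(pairs, `[[`, "up"))
  down <- Reduce(intersect, lapply(pairs, `[[`, "down"))
  clash <- intersect(up, down)
  if (length(clash) > 0) {
    message("intersect_signatures: removing ", length(clash),
            " sign-conflicting gene(s): ", paste(clash, collapse = ", "))
    up <- setdiff(up, clash); down <- setdiff(down, clash)
  }
  structure(list(up = sort(up), down = sort(down)), class = "gene_set_pair")
}

#' Write a DEG table to TSV
#'
#' Emits columns `gene, logFC, t, p, p_adj_BH, direction` where direction is
#' assigned at the given thresholds.
#' @param table DEG table.
#' @param path Output path.
#' @param p_thresh,lfc_thresh Thresholds used for the `direction` column.
#' @export
write_deg_table <- function(table, path, p_thresh = 0.05, lfc_thresh = 0) {
  table$direction <- classify_degs(table, p_thresh, lfc_thresh)
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GRP gene-set files (one gene per line, `#` comments)
#' @param path File path.
#' @return Character vector of genes.
#' @export
read_grp <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname read_grp
#' @param genes Character vector to write.
#' @export
write_grp <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Write a signature pair as a two-set GMT file
#' @param pair A [gene_set_pair()].
#' @param path Output path.
#' @param name Base name used for the two set names (`<name>_UP`, `<name>_DN`).
#' @export
write_gmt <- function(pair, path, name = "SIGNATURE") {
  lines <- c(paste(c(paste0(name, "_UP"), "up-regulated", pair$up), collapse = "\t"),
             paste(c(paste0(name, "_DN"), "down-regulated", pair$down), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-set GMT file into a gene-set pair
#'
#' The first set whose name ends in `_UP` (case-insensitive; `_DN`/`_DOWN` for
#' down) is used; with exactly two unlabeled sets, the first is taken as up.
#' @param path GMT path.
#' @return A [gene_set_pair()].
#' @export
read_gmt_pair <- function(path) {
  rows <- strsplit(readLines(path), "\t")
  names(rows) <- vapply(rows, `[[`, "", 1)
  sets <- lapply(rows, function(r) r[-(1:2)])
  nm <- toupper(names(sets))
  iu <- grep("_UP$", nm); id <- grep("(_DN|_DOWN)$", nm)
  if (length(iu) == 0 || length(id) == 0) { iu <- 1; id <- 2 }
  gene_set_pair(sets[[iu[1]]], sets[[id[1]]])
}

#' Parse a GEO series-matrix file
#'
#' Thin loader for `*_series_matrix.txt` files as distributed by GEO: extracts
#' the expression table and the per-sample characteristics lines so that
#' case/control labels can be derived with a user-supplied pattern.
#'
#' @param path Path to an (uncompressed or gzipped) series matrix file.
#' @return List with `matrix` (probes x samples) and `characteristics`
#'   (data.frame of the `!Sample_characteristics_ch1` rows, one column per
#'   sample) and `titles` (sample titles).
#' @export
read_series_matrix <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con); close(con)
  chr <- lines[startsWith(lines, "!Sample_characteristics_ch1")]
  ttl <- lines[startsWith(lines, "!Sample_title")]
  beg <- which(lines == "!series_matrix_table_begin")
  end <- which(lines == "!series_matrix_table_end")
  if (length(beg) != 1 || length(end) != 1) stopf("malformed series matrix: %s", path)
  tab <- utils::read.delim(text = lines[(beg + 1):(end - 1)], check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE]); storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  strip <- function(x) gsub("\"", "", unlist(strsplit(x, "\t"))[-1])
  ch <- if (length(chr)) as.data.frame(do.call(rbind, lapply(chr, strip)),
                                       stringsAsFactors = FALSE) else NULL
  if (!is.null(ch)) colnames(ch) <- colnames(m)
  list(matrix = m, characteristics = ch,
       titles = if (length(ttl)) strip(ttl[1]) else colnames(m))
}
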
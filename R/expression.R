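#' Read an expression matrix from TSV
#'
#' First column holds probe/gene identifiers, remaining columns one sample
#' each. Values are returned as a numeric matrix with row and column names.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix (features x samples).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("expression TSV needs an id column plus >=1 sample column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  validate_expression(m)
  m
}

#' Read a GCT 1.2 / 1.3 expression file
#'
#' Supports the two common GCT versions: `#1.2` (id, Description, samples) and
#' `#1.3` (with row/column metadata blocks, which are skipped).
#'
#' @param path Path to a `.gct` file.
#' @return Numeric matrix (features x samples).
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stopf("not a GCT file: %s", path)
  version <- trimws(lines[1])
  dims <- as.numeric(strsplit(trimws(lines[2]), "\t")[[1]])
  header <- strsplit(lines[3], "\t")[[1]]
  if (version == "#1.2") {
    nr <- dims[1]
    body <- utils::read.delim(text = lines[3 + seq_len(nr)], header = FALSE,
                              stringsAsFactors = FALSE)
    ids <- as.character(body[[1]])
    m <- as.matrix(body[, -(1:2), drop = FALSE])
    colnames(m) <- header[-(1:2)]
  } else if (version == "#1.3") {
    nr <- dims[1]; nrmeta <- dims[4]; ncmeta <- dims[3]
    sample_ids <- header[-seq_len(1 + nrmeta)]
    data_start <- 3 + ncmeta + 1
    body <- utils::read.delim(text = lines[seq(data_start, data_start + nr - 1)],
                              header = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(body[[1]])
    m <- as.matrix(body[, -seq_len(1 + nrmeta), drop = FALSE])
    colnames(m) <- sample_ids
  } else {
    stopf("unsupported GCT version line: %s", version)
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_expression(m)
  m
}

#' Read a sample-group table
#'
#' Two-column CSV mapping sample_id to a group label (`case` / `control`).
#'
#' @param path CSV path.
#' @return Named character vector of labels, names = sample ids.
#' @export
read_groups <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("groups CSV needs columns sample_id,label")
  g <- as.character(df[[2]])
  names(g) <- as.character(df[[1]])
  g
}

validate_expression <- function(m) {
  if (anyDuplicated(colnames(m))) stopf("duplicate sample ids in expression matrix")
  if (any(!is.finite(m))) stopf("expression matrix contains non-finite values")
  invisible(m)
}

#' Log2-transform and quantile-normalize an expression matrix
#'
#' Converts signal intensities to log2 scale, then forces every column onto the
#' across-column mean quantile distribution (ties receive the mean of the tied
#' target quantiles), preserving within-column rank order. The quantile step is
#' the identity for a single column, and the whole operation is idempotent.
#'
#' @param raw Numeric matrix, features x samples, strictly positive intensities
#'   unless `already_logged = TRUE`.
#' @param already_logged Set when the input is already on log2 scale; the log
#'   step is then skipped. The flag is never guessed from value ranges.
#' @return Normalized matrix with attribute `normalized = TRUE`.
#' @export
log2_quantile_normalize <- function(raw, already_logged = FALSE) {
  validate_expression(raw)
  if (!already_logged) {
    bad <- which(raw <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stopf("log2 requested but value at row '%s', column '%s' is %g (must be > 0)",
            rownames(raw)[bad[1, 1]] %||% bad[1, 1],
            colnames(raw)[bad[1, 2]] %||% bad[1, 2],
            raw[bad[1, 1], bad[1, 2]])
    }
    raw <- log2(raw)
  }
  out <- limma::normalizeQuantiles(raw, ties = TRUE)
  dimnames(out) <- dimnames(raw)
  attr(out, "normalized") <- TRUE
  out
}

#' Collapse probe-level rows to gene level
#'
#' Unmapped probes are dropped; when several probes map to one gene the probe
#' with the highest mean expression is kept (a standard microarray convention,
#' and deterministic: ties break by probe id).
#'
#' @param matrix Numeric matrix, probes x samples.
#' @param probe_to_gene Named character vector: names = probe ids,
#'   values = gene symbols. May cover only part of the probes.
#' @return Numeric matrix, genes x samples, unique gene rownames.
#' @export
collapse_probes <- function(matrix, probe_to_gene) {
  probes <- rownames(matrix)
  map <- probe_to_gene[!is.na(probe_to_gene) & nzchar(probe_to_gene)]
  keep <- probes[probes %in% names(map)]
  if (length(keep) == 0) stopf("no probes mapped")
  m <- matrix[keep, , drop = FALSE]
  genes <- unname(map[keep])
  means <- rowMeans(m)
  ord <- order(genes, -means, keep)       # per gene: best probe first
  m <- m[ord, , drop = FALSE]
  genes <- genes[ord]
  sel <- !duplicated(genes)
  out <- m[sel, , drop = FALSE]
  rownames(out) <- genes[sel]
  attr(out, "normalized") <- attr(matrix, "normalized")
  out
}
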
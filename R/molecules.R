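# Molecule parsing and canonicalization (OpenBabel via ChemmineR/ChemmineOB).
# A molecule_record carries the canonical SMILES plus a light graph view
# (atoms, bonds, aromaticity) that the hashed fingerprints are computed from.

DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                     I = 1, B = 3, Si = 4, Se = 2, As = 3)

ob_canonical <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, " x\n")),
    error = function(e) "")
  out <- strsplit(trimws(out), "[ \t]")[[1]]
  if (length(out) < 1 || !nzchar(out[1])) NA_character_ else out[1]
}

# Formal charges are recovered by scanning bracket atoms of the canonical
# SMILES in order (OpenBabel preserves atom order on SMI->SDF conversion).
# Returns integer charges per heavy atom, or NULL when the scan disagrees
# with the expected atom count.
smiles_atom_charges <- function(smiles, n_atoms) {
  tokens <- gregexpr("\\[[^]]*\\]|Cl|Br|Si|Se|As|B|C|N|O|S|P|F|I|b|c|n|o|s|p",
                     smiles, perl = TRUE)[[1]]
  if (tokens[1] == -1) return(NULL)
  txt <- regmatches(smiles, gregexpr("\\[[^]]*\\]|Cl|Br|Si|Se|As|B|C|N|O|S|P|F|I|b|c|n|o|s|p",
                                     smiles, perl = TRUE))[[1]]
  chg <- vapply(txt, function(tk) {
    if (!startsWith(tk, "[")) return(0L)
    if (grepl("\\+\\d", tk)) return(as.integer(sub(".*\\+(\\d+).*", "\\1", tk)))
    if (grepl("-\\d", tk)) return(-as.integer(sub(".*-(\\d+).*", "\\1", tk)))
    plus <- lengths(regmatches(tk, gregexpr("\\+", tk)))
    minus <- lengths(regmatches(tk, gregexpr("-", tk)))
    as.integer(plus - minus)
  }, integer(1), USE.NAMES = FALSE)
  if (length(chg) != n_atoms) return(NULL)
  chg
}

build_mol_graph <- function(sdf, canonical) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  if (!is.null(bb)) bb <- as.matrix(bb)
  bonds <- if (is.null(bb) || !is.matrix(bb) || ncol(bb) < 3 || nrow(bb) == 0) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  bonds <- bonds[bonds$a1 >= 1 & bonds$a2 >= 1, , drop = FALSE]  # drop pad rows
  aromatic_atom <- rep(FALSE, n)
  ring_atom <- rep(FALSE, n)
  ring_list <- list()
  ring_arom <- logical(0)
  if (n >= 3 && nrow(bonds) >= n) {  # a cycle requires #bonds >= #atoms
    rr <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(rr) && length(rr$RINGS) > 0) {
      for (k in seq_along(rr$RINGS)) {
        idx <- as.integer(sub(".*_", "", rr$RINGS[[k]]))
        ring_atom[idx] <- TRUE
        ring_list[[length(ring_list) + 1]] <- idx
        ring_arom <- c(ring_arom, isTRUE(rr$AROMATIC[[k]]))
        if (isTRUE(rr$AROMATIC[[k]])) aromatic_atom[idx] <- TRUE
      }
    }
  }
  ring_sizes <- lengths(ring_list)
  aromatic_rings <- sum(ring_arom)
  ring_bond <- ring_bond_flags(bonds, n)
  aromatic_bond <- ring_bond & aromatic_atom[bonds$a1] & aromatic_atom[bonds$a2]
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$a1[b]]] <- c(adj[[bonds$a1[b]]], b)
    adj[[bonds$a2[b]]] <- c(adj[[bonds$a2[b]]], b)
  }
  degree <- lengths(adj)
  bond_sum <- vapply(seq_len(n), function(i) {
    sum(ifelse(aromatic_bond[adj[[i]]], 1.5, bonds$order[adj[[i]]]))
  }, numeric(1))
  charge <- smiles_atom_charges(canonical, n)
  val <- DEFAULT_VALENCE[elements]
  val[is.na(val)] <- 4
  if (is.null(charge)) {
    charge <- pmax(0, round(bond_sum) - pmax(val, round(bond_sum) * (elements %in% c("S", "P"))))
    charge[elements %in% c("S", "P")] <- 0  # hypervalent S/P are neutral
    charge <- as.integer(charge)
  }
  nH <- pmax(0, val + ifelse(elements %in% c("N", "O"), charge,
                             ifelse(elements %in% c("C", "B"), -abs(charge), 0)) -
               ceiling(bond_sum))
  # hypervalent neutral S/P (sulfonyl, phosphate): no implicit hydrogens
  nH[elements %in% c("S", "P") & bond_sum > val] <- 0
  list(n_atoms = n, elements = elements, charge = charge, nH = as.integer(nH),
       degree = as.integer(degree), bonds = bonds, adj = adj,
       aromatic_atom = aromatic_atom, aromatic_bond = aromatic_bond,
       ring_atom = ring_atom, ring_bond = ring_bond,
       rings = ring_list, rings_aromatic = ring_arom,
       ring_sizes = ring_sizes, aromatic_rings = aromatic_rings)
}

ring_bond_flags <- function(bonds, n) {
  # a bond is a ring bond iff removing it leaves its endpoints connected
  m <- nrow(bonds)
  flags <- rep(FALSE, m)
  if (m == 0) return(flags)
  for (b in seq_len(m)) {
    seen <- rep(FALSE, n); queue <- bonds$a1[b]; seen[queue] <- TRUE
    target <- bonds$a2[b]
    while (length(queue) > 0 && !seen[target]) {
      v <- queue[1]; queue <- queue[-1]
      for (bb in seq_len(m)) {
        if (bb == b) next
        w <- if (bonds$a1[bb] == v) bonds$a2[bb] else if (bonds$a2[bb] == v) bonds$a1[bb] else next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    flags[b] <- seen[target]
  }
  flags
}

#' Parse and canonicalize SMILES strings
#'
#' Invalid SMILES never raise an error: the record comes back with
#' `parse_ok = FALSE`. Multi-fragment inputs (salts) are stripped to their
#' largest fragment (by heavy-atom count; ties by fragment SMILES) before
#' canonicalization. Canonicalization is idempotent.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional compound ids (defaults to `mol1..molN`).
#' @return List of `molecule_record` objects: `compound_id`, `smiles_input`,
#'   `smiles_canonical`, `parse_ok`, and (when parsed) `graph`.
#' @export
parse_molecules <- function(smiles, ids = NULL) {
  ids <- ids %||% paste0("mol", seq_along(smiles))
  records <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    rec <- list(compound_id = ids[i], smiles_input = smiles[i],
                smiles_canonical = NA_character_, parse_ok = FALSE, graph = NULL)
    can <- ob_canonical(smiles[i])
    if (!is.na(can)) {
      frags <- strsplit(can, ".", fixed = TRUE)[[1]]
      if (length(frags) > 1) {
        sizes <- vapply(frags, count_heavy_atoms, numeric(1))
        can <- ob_canonical(frags[order(-sizes, frags)][1])
      }
    }
    if (!is.na(can) && count_heavy_atoms(can) == 1) {
      # atom-only molecules carry no bond block; build the graph directly
      g <- single_atom_graph(can)
      if (!is.null(g)) {
        rec$smiles_canonical <- can
        rec$parse_ok <- TRUE
        rec$sdf <- NULL
        rec$graph <- g
      }
      class(rec) <- "molecule_record"
      records[[i]] <- rec
      next
    }
    if (!is.na(can)) {
      sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(can, ids[i]))),
                      error = function(e) NULL)
      n_atoms <- if (is.null(sdf) || length(sdf) != 1) 0 else
        tryCatch(nrow(ChemmineR::atomblock(sdf[[1]])), error = function(e) 0)
      # single-atom molecules are valid even though they carry no bond block
      if (!is.null(n_atoms) && length(n_atoms) == 1 && n_atoms >= 1) {
        rec$smiles_canonical <- can
        rec$parse_ok <- TRUE
        rec$sdf <- sdf[[1]]
        rec$graph <- build_mol_graph(sdf[[1]], can)
      }
    }
    class(rec) <- "molecule_record"
    records[[i]] <- rec
  }
  names(records) <- ids
  records
}

single_atom_graph <- function(can) {
  m <- regmatches(can, regexpr("\\[[^]]*\\]|Cl|Br|Si|Se|As|B|C|N|O|S|P|F|I", can))
  if (length(m) == 0) return(NULL)
  el <- if (startsWith(m, "[")) sub("^\\[(\\d*)([A-Za-z][a-z]?).*$", "\\2", m) else m
  chg <- smiles_atom_charges(can, 1) %||% 0L
  val <- DEFAULT_VALENCE[el]
  val <- if (is.na(val)) 0L else val
  list(n_atoms = 1L, elements = el, charge = as.integer(chg),
       nH = as.integer(max(0, val + chg * (el %in% c("N", "O")))),
       degree = 0L,
       bonds = data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)),
       adj = list(integer(0)), aromatic_atom = FALSE, aromatic_bond = logical(0),
       ring_atom = FALSE, ring_bond = logical(0), rings = list(),
       rings_aromatic = logical(0), ring_sizes = integer(0), aromatic_rings = 0L)
}

count_heavy_atoms <- function(frag) {
  hits <- gregexpr("\\[[^]]*\\]|Cl|Br|Si|Se|As|B|C|N|O|S|P|F|I|b|c|n|o|s|p",
                   frag, perl = TRUE)[[1]]
  if (hits[1] == -1) 0 else length(hits)
}

#' Canonicalize a single SMILES
#'
#' @param smiles One SMILES string.
#' @param id Compound id for the record.
#' @return A `molecule_record` (see [parse_molecules()]).
#' @export
canonicalize <- function(smiles, id = "mol1") {
  parse_molecules(smiles, id)[[1]]
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record> %s: %s (parse_ok=%s)\n", x$compound_id,
              if (x$parse_ok) x$smiles_canonical else x$smiles_input, x$parse_ok))
  invisible(x)
}

# SMILES of an atom-induced subgraph, via ChemmineR::atomsubset + OpenBabel.
subgraph_smiles <- function(record, atoms) {
  if (length(atoms) == 0) return(NA_character_)
  sdf <- tryCatch(suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(record$smiles_canonical, "m"))),
    error = function(e) NULL)
  if (is.null(sdf)) return(NA_character_)
  sub <- tryCatch(ChemmineR::atomsubset(sdf[[1]], atomrows = atoms),
                  error = function(e) NULL)
  if (is.null(sub)) return(NA_character_)
  set <- ChemmineR::SDFset(list(sub))
  ChemmineR::cid(set) <- "m"
  smi <- tryCatch(suppressWarnings(ChemmineR::sdf2smiles(set)),
                  error = function(e) NULL)
  if (is.null(smi)) return(NA_character_)
  out <- trimws(as.character(smi)[1])
  if (!nzchar(out)) NA_character_ else out
}
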
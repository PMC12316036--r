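# Molecular fingerprints with bit -> substructure maps.
#
# Five bit fingerprints (AVALON-style feature classes, ECFP4, FCFP4, MACCS,
# path-topological) and one real-valued physicochemical descriptor block
# (123 properties + 85 fragment counts, see physchem.R). The hashed kinds
# (AVALON, ECFP4, FCFP4, TOPO_PATH) are computed natively from the molecular
# graph so that every set bit can be traced back to the atom environment(s)
# that produced it; MACCS keys come from OpenBabel. Bit positions are only
# comparable within one fingerprint configuration, which is why the
# configuration is stamped into every model bundle.

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                   S = 16, Cl = 17, As = 33, Se = 34, Br = 35, I = 53)

znum <- function(el) {
  z <- ATOMIC_NUMBER[el]
  if (is.na(z)) 0L else as.integer(z)
}

#' Fingerprint kinds and default parameters
#'
#' @return Named list of default parameter lists per kind.
#' @export
fp_defaults <- function() {
  list(AVALON = list(nbits = 512),
       ECFP4 = list(nbits = 2048, radius = 2),
       FCFP4 = list(nbits = 2048, radius = 2),
       MACCS = list(nbits = 167),
       TOPO_PATH = list(nbits = 2048, min_path = 1, max_path = 7),
       PHYSCHEM = list(nbits = 208))
}

FP_KINDS <- c("AVALON", "ECFP4", "FCFP4", "MACCS", "TOPO_PATH", "PHYSCHEM")

fp_params_for <- function(kind, params = list()) {
  kind <- match.arg(kind, FP_KINDS)
  def <- fp_defaults()[[kind]]
  unknown <- setdiff(names(params), names(def))
  if (length(unknown) > 0)
    stopf("invalid parameter(s) for %s fingerprint: %s", kind,
          paste(unknown, collapse = ", "))
  if (kind %in% c("MACCS", "PHYSCHEM") && !is.null(params$nbits) &&
      params$nbits != def$nbits)
    stopf("%s fingerprint has fixed length %d", kind, def$nbits)
  utils::modifyList(def, params)
}

bond_code <- function(graph, b) if (graph$aromatic_bond[b]) 4L else graph$bonds$order[b]

# ---- circular (Morgan) fingerprints: ECFP4 / FCFP4 -------------------------

ecfp_invariants <- function(g) {
  vapply(seq_len(g$n_atoms), function(i) {
    hash_ints(c(znum(g$elements[i]), g$degree[i], g$nH[i],
                g$charge[i], as.integer(g$ring_atom[i]),
                as.integer(g$aromatic_atom[i])))
  }, integer(1))
}

# FCFP initial identifiers: the 6-bit pharmacophore code
# (donor, acceptor, aromatic, halogen, basic, acidic).
fcfp_invariants <- function(g) {
  dbl_to_O <- vapply(seq_len(g$n_atoms), function(i) {
    any(vapply(g$adj[[i]], function(b) {
      j <- if (g$bonds$a1[b] == i) g$bonds$a2[b] else g$bonds$a1[b]
      g$bonds$order[b] == 2 && g$elements[j] == "O"
    }, logical(1)))
  }, logical(1))
  neighbor_has_dbl_O <- vapply(seq_len(g$n_atoms), function(i) {
    any(vapply(g$adj[[i]], function(b) {
      j <- if (g$bonds$a1[b] == i) g$bonds$a2[b] else g$bonds$a1[b]
      dbl_to_O[j]
    }, logical(1)))
  }, logical(1))
  vapply(seq_len(g$n_atoms), function(i) {
    el <- g$elements[i]
    donor <- el %in% c("N", "O") && g$nH[i] > 0
    acceptor <- el %in% c("N", "O") && g$charge[i] <= 0 &&
      !(el == "N" && g$aromatic_atom[i] && g$degree[i] == 3)
    halogen <- el %in% c("F", "Cl", "Br", "I")
    basic <- el == "N" && !g$aromatic_atom[i] && g$charge[i] >= 0 &&
      !neighbor_has_dbl_O[i]
    acidic <- (el == "O" && g$charge[i] < 0) ||
      (el == "O" && g$nH[i] > 0 && neighbor_has_dbl_O[i])
    as.integer(donor + 2 * acceptor + 4 * g$aromatic_atom[i] + 8 * halogen +
                 16 * basic + 32 * acidic)
  }, integer(1))
}

circular_features <- function(g, radius, functional) {
  ids <- if (functional) fcfp_invariants(g) else ecfp_invariants(g)
  feats <- lapply(seq_len(g$n_atoms), function(i)
    list(id = ids[i], atoms = i, bonds = integer(0), radius = 0L))
  env_bonds <- lapply(seq_len(g$n_atoms), function(i) integer(0))
  seen <- character(0)
  for (r in seq_len(radius)) {
    new_ids <- ids
    new_env <- env_bonds
    for (i in seq_len(g$n_atoms)) {
      nb <- g$adj[[i]]
      if (length(nb) == 0) next
      pairs <- t(vapply(nb, function(b) {
        j <- if (g$bonds$a1[b] == i) g$bonds$a2[b] else g$bonds$a1[b]
        c(bond_code(g, b), ids[j], b, j)
      }, numeric(4)))
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      new_ids[i] <- hash_ints(c(r, ids[i], as.integer(t(pairs[, 1:2]))))
      new_env[[i]] <- sort(unique(c(env_bonds[[i]], as.integer(pairs[, 3]),
                                    unlist(env_bonds[pairs[, 4]]))))
    }
    for (i in seq_len(g$n_atoms)) {
      key <- paste(new_env[[i]], collapse = ",")
      if (key %in% seen) next        # identical environment already emitted
      seen <- c(seen, key)
      atoms <- sort(unique(c(i, g$bonds$a1[new_env[[i]]], g$bonds$a2[new_env[[i]]])))
      feats[[length(feats) + 1]] <- list(id = new_ids[i], atoms = atoms,
                                         bonds = new_env[[i]], radius = r)
    }
    ids <- new_ids
    env_bonds <- new_env
  }
  feats
}

# ---- path-topological fingerprint ------------------------------------------

path_features <- function(g, min_path, max_path) {
  atom_code <- function(i) as.integer(1000 * znum(g$elements[i]) +
    g$aromatic_atom[i])
  feats <- list()
  seen <- character(0)
  enumerate <- function(atom_path, bond_path) {
    len <- length(bond_path)
    if (len >= min_path) {
      key <- paste(sort(bond_path), collapse = ",")
      if (!(key %in% seen)) {
        seen <<- c(seen, key)
        ac <- vapply(atom_path, atom_code, integer(1))
        bc <- vapply(bond_path, function(b) bond_code(g, b), integer(1))
        fwd <- as.integer(rbind(ac, c(bc, 0L))[seq_len(2 * len + 1)])
        rev_ <- as.integer(rbind(rev(ac), c(rev(bc), 0L))[seq_len(2 * len + 1)])
        enc <- if (paste(fwd, collapse = " ") <= paste(rev_, collapse = " ")) fwd else rev_
        feats[[length(feats) + 1]] <<- list(id = hash_ints(c(99L, enc)),
                                            atoms = sort(atom_path),
                                            bonds = sort(bond_path), len = len)
      }
    }
    if (len == max_path) return()
    tip <- atom_path[length(atom_path)]
    for (b in g$adj[[tip]]) {
      if (b %in% bond_path) next
      j <- if (g$bonds$a1[b] == tip) g$bonds$a2[b] else g$bonds$a1[b]
      if (j %in% atom_path) next     # simple paths only
      enumerate(c(atom_path, j), c(bond_path, b))
    }
  }
  for (i in seq_len(g$n_atoms)) enumerate(i, integer(0))
  feats
}

# ---- Avalon-style feature-class fingerprint --------------------------------
# Enumerates feature classes of the molecular graph (atom types, augmented
# atoms, bond types, ring features and short paths) and hashes each feature,
# together with a capped occurrence count, into the bit space.

avalon_features <- function(g) {
  feats <- list()
  add <- function(id, atoms, bonds = integer(0))
    feats[[length(feats) + 1]] <<- list(id = id, atoms = atoms, bonds = bonds)
  z <- function(i) znum(g$elements[i])
  # atom types
  for (i in seq_len(g$n_atoms))
    add(hash_ints(c(1L, z(i), as.integer(g$aromatic_atom[i]), g$charge[i])), i)
  # augmented atoms: atom + sorted (bond code, neighbour element)
  for (i in seq_len(g$n_atoms)) {
    nb <- g$adj[[i]]
    if (length(nb) == 0) next
    pr <- t(vapply(nb, function(b) {
      j <- if (g$bonds$a1[b] == i) g$bonds$a2[b] else g$bonds$a1[b]
      c(bond_code(g, b), z(j), j)
    }, numeric(3)))
    pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
    add(hash_ints(c(2L, z(i), as.integer(t(pr[, 1:2])))),
        sort(c(i, as.integer(pr[, 3]))), nb)
  }
  # bond types
  for (b in seq_len(nrow(g$bonds))) {
    zz <- sort(c(z(g$bonds$a1[b]), z(g$bonds$a2[b])))
    add(hash_ints(c(3L, zz, bond_code(g, b))), c(g$bonds$a1[b], g$bonds$a2[b]), b)
  }
  # ring features: (size, heteroatom count, aromatic)
  for (k in seq_along(g$rings)) {
    ring <- g$rings[[k]]
    nhet <- sum(!g$elements[ring] %in% "C")
    add(hash_ints(c(4L, length(ring), nhet, as.integer(g$rings_aromatic[k]))),
        sort(ring))
  }
  # short paths (2-3 bonds)
  for (f in path_features(g, 2, 3))
    add(hash_ints(c(5L, f$id)), f$atoms, f$bonds)
  # occurrence-count levels
  counts <- table(vapply(feats, `[[`, integer(1), "id"))
  extra <- list()
  for (idc in names(counts[counts >= 2]))
    extra[[length(extra) + 1]] <- list(id = hash_ints(c(6L, as.integer(idc))),
                                       atoms = integer(0), bonds = integer(0))
  c(feats, extra)
}

# ---- MACCS (OpenBabel) -----------------------------------------------------

maccs_bits <- function(record) {
  if (is.null(record$sdf)) return(integer(167))   # atom-only molecule
  set <- ChemmineR::SDFset(list(record$sdf))
  ChemmineR::cid(set) <- record$compound_id
  fp <- ChemmineR::fingerprintOB(set, "MACCS")
  bits <- as.numeric(fp[[1]])        # OpenBabel pads MACCS to 256 positions
  v <- integer(167)
  on <- which(bits != 0)
  on <- on[on <= 166]
  v[on + 1L] <- 1L                   # key k stored at index k + 1; index 1 = pad
  v
}

# ---- public API ------------------------------------------------------------

features_to_fp <- function(feats, nbits, kind, params, bit_info) {
  values <- integer(nbits)
  info <- if (bit_info) vector("list", nbits) else NULL
  for (f in feats) {
    bit <- (f$id %% nbits) + 1L
    values[bit] <- 1L
    if (bit_info)
      info[[bit]] <- c(info[[bit]], list(list(atoms = f$atoms, bonds = f$bonds)))
  }
  structure(list(kind = kind, params = params, values = values, bit_info = info),
            class = "fingerprint")
}

#' Compute a molecular fingerprint
#'
#' @param mol A `molecule_record` from [parse_molecules()] (must have
#'   `parse_ok = TRUE`).
#' @param kind One of `"AVALON"`, `"ECFP4"`, `"FCFP4"`, `"MACCS"`,
#'   `"TOPO_PATH"`, `"PHYSCHEM"`.
#' @param params Optional parameter overrides (e.g. `nbits`, `radius`,
#'   `min_path`, `max_path`); unknown parameters are an error.
#' @param bit_info Record, for each set bit, the atom/bond environments that
#'   produced it (hashed kinds only).
#' @return Object of class `fingerprint` with `kind`, `params`, `values`
#'   (0/1 ints, or reals for PHYSCHEM) and optional `bit_info`.
#' @export
fingerprint <- function(mol, kind, params = list(), bit_info = FALSE) {
  if (!isTRUE(mol$parse_ok)) stopf("molecule '%s' did not parse", mol$compound_id)
  kind <- match.arg(kind, FP_KINDS)
  p <- fp_params_for(kind, params)
  g <- mol$graph
  if (kind == "ECFP4" || kind == "FCFP4") {
    feats <- circular_features(g, p$radius, functional = (kind == "FCFP4"))
    features_to_fp(feats, p$nbits, kind, p, bit_info)
  } else if (kind == "TOPO_PATH") {
    feats <- path_features(g, p$min_path, p$max_path)
    features_to_fp(feats, p$nbits, kind, p, bit_info)
  } else if (kind == "AVALON") {
    features_to_fp(avalon_features(g), p$nbits, kind, p, bit_info)
  } else if (kind == "MACCS") {
    structure(list(kind = kind, params = p, values = maccs_bits(mol),
                   bit_info = NULL), class = "fingerprint")
  } else {                            # PHYSCHEM
    structure(list(kind = kind, params = p, values = physchem_vector(mol),
                   bit_info = NULL), class = "fingerprint")
  }
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %s, length %d, %s\n", x$kind, length(x$values),
              if (x$kind == "PHYSCHEM") "real-valued"
              else sprintf("%d bits set", sum(x$values != 0))))
  invisible(x)
}

#' Fingerprint a library of molecules into a matrix
#'
#' @param mols List of `molecule_record`s; records that failed to parse are
#'   dropped (with a message).
#' @inheritParams fingerprint
#' @return Numeric matrix, one row per parsed molecule (rownames = compound
#'   ids), with attributes `kind` and `params`.
#' @export
fingerprint_matrix <- function(mols, kind, params = list()) {
  ok <- vapply(mols, function(m) isTRUE(m$parse_ok), logical(1))
  if (any(!ok)) message(sum(!ok), " unparsed molecule(s) dropped")
  mols <- mols[ok]
  rows <- lapply(mols, function(m) fingerprint(m, kind, params)$values)
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(mols, `[[`, "", "compound_id")
  if (kind == "PHYSCHEM") colnames(X) <- physchem_names()
  attr(X, "kind") <- kind
  attr(X, "params") <- fp_params_for(kind, params)
  X
}

#' Tanimoto similarity between two bit fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|}; two empty fingerprints have similarity 0.
#' Only defined for bit kinds (PHYSCHEM is rejected at type level).
#'
#' @param fp1,fp2 `fingerprint` objects of the same kind and length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(fp1, fp2) {
  if (fp1$kind != fp2$kind) stopf("fingerprint kind mismatch: %s vs %s", fp1$kind, fp2$kind)
  if (fp1$kind == "PHYSCHEM") stopf("Tanimoto is not defined for PHYSCHEM descriptors")
  if (length(fp1$values) != length(fp2$values)) stopf("fingerprint length mismatch")
  a <- fp1$values != 0; b <- fp2$values != 0
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# Row-wise max Tanimoto of each row of X against all rows of `train`
# (0/1 matrices with identical column count).
max_tanimoto_rows <- function(X, train) {
  X <- X != 0; train <- train != 0
  inter <- X %*% t(train)
  nx <- rowSums(X); nt <- rowSums(train)
  uni <- outer(nx, nt, `+`) - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  apply(sim, 1, max)
}
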
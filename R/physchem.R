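# The PHYSCHEM descriptor block: an explicit, frozen registry of 123 named
# scalar properties followed by 85 named fragment counts (fr_*), total 208.
# Properties combine OpenBabel-computed values (MolWt, LogP, MolMR, TPSA,
# H-bond counts) with graph-derived counts and topological indices computed
# here; fragment counts are SMARTS matches evaluated by OpenBabel.

# ---- SMARTS registries -----------------------------------------------------

# 19 functional-group counts that are part of the 123-property block.
PHYSCHEM_GROUP_SMARTS <- c(
  NumAmide = "[NX3][CX3](=[OX1])", NumEster = "[CX3](=O)[OX2][#6]",
  NumEtherO = "[OD2]([#6])[#6]", NumThioether = "[SX2]([#6])[#6]",
  NumNitrile = "[NX1]#[CX2]", NumNitro = "[NX3](=O)=O",
  NumSulfonamide = "[SX4](=O)(=O)[NX3]", NumSulfone = "[SX4](=O)(=O)",
  NumCarboxylicAcid = "[CX3](=O)[OX2H]", NumPhenolOH = "[c][OX2H]",
  NumAliphaticOH = "[CX4][OX2H]", NumPrimaryAmine = "[NX3;H2;!$(NC=O)]",
  NumSecondaryAmine = "[NX3;H1;!$(NC=O)]([#6])[#6]",
  NumTertiaryAmine = "[NX3;H0;!$(NC=O)]([#6])([#6])[#6]",
  NumAromaticAmine = "[c][NX3;H1,H2]", NumKetone = "[#6][CX3](=O)[#6]",
  NumAldehyde = "[CX3H1]=O", NumArylHalide = "[c][F,Cl,Br,I]",
  NumUrea = "[NX3][CX3](=[OX1])[NX3]")

# The 85 fragment-count features (fr_*).
PHYSCHEM_FR_SMARTS <- c(
  fr_benzene = "c1ccccc1", fr_pyridine = "c1ccncc1", fr_pyrimidine = "c1cncnc1",
  fr_pyrrole = "c1cc[nH]c1", fr_furan = "c1ccoc1", fr_thiophene = "c1ccsc1",
  fr_imidazole = "c1c[nH]cn1", fr_pyrazole = "c1cc[nH]n1",
  fr_oxazole = "c1ocnc1", fr_thiazole = "c1scnc1",
  fr_naphthalene = "c1ccc2ccccc2c1", fr_biphenyl = "c1ccccc1-c1ccccc1",
  fr_phenol = "c1ccccc1[OX2H]", fr_aniline = "c1ccccc1[NX3;H1,H2]",
  fr_Ar_N = "[nX2,nX3]", fr_Ar_OH = "[c][OX2H]", fr_Ar_NH = "[c][NX3;H1,H2]",
  fr_alcohol = "[CX4][OX2H]", fr_ether = "[OD2]([#6])[#6]",
  fr_ester = "[CX3](=O)[OX2][#6]", fr_carboxylic_acid = "[CX3](=O)[OX2H]",
  fr_ketone = "[#6][CX3](=O)[#6]", fr_aldehyde = "[CX3H1]=O",
  fr_amide = "[NX3][CX3](=[OX1])", fr_urea = "[NX3][CX3](=[OX1])[NX3]",
  fr_carbamate = "[NX3][CX3](=[OX1])[OX2]",
  fr_priamide = "[CX3](=[OX1])[NX3H2]",
  fr_NH2 = "[NX3H2]", fr_NH1 = "[NX3H1]", fr_NH0 = "[NX3H0]",
  fr_quatN = "[NX4+]", fr_nitrile = "[NX1]#[CX2]", fr_nitro = "[NX3](=O)=O",
  fr_azo = "[NX2]=[NX2]", fr_hydrazine = "[NX3][NX3]",
  fr_hydrazone = "[CX3]=[NX2][NX3]", fr_imine = "[CX3]=[NX2]",
  fr_oxime = "[CX3]=[NX2][OX2H]", fr_nitroso = "[NX2]=[OX1]",
  fr_SH = "[SX2H]", fr_sulfide = "[SX2]([#6])[#6]",
  fr_disulfide = "[SX2][SX2]", fr_sulfoxide = "[SX3](=[OX1])",
  fr_sulfone = "[SX4](=[OX1])(=[OX1])",
  fr_sulfonamd = "[SX4](=[OX1])(=[OX1])[NX3]",
  fr_sulfonic_acid = "[SX4](=[OX1])(=[OX1])[OX2H]",
  fr_thioamide = "[NX3][CX3](=S)", fr_thiourea = "[NX3][CX3](=S)[NX3]",
  fr_guanidine = "[NX3][CX3](=[NX2])[NX3]", fr_amidine = "[NX3][CX3]=[NX2]",
  fr_halogen = "[F,Cl,Br,I]", fr_alkyl_halide = "[CX4][F,Cl,Br,I]",
  fr_aryl_halide = "[c][F,Cl,Br,I]", fr_F = "[F]", fr_Cl = "[Cl]",
  fr_Br = "[Br]", fr_I = "[I]", fr_CF3 = "C(F)(F)F",
  fr_phosphate = "[PX4](=[OX1])", fr_epoxide = "C1OC1",
  fr_aziridine = "C1NC1", fr_lactone = "[CX3;R](=O)[OX2;R]",
  fr_lactam = "[CX3;R](=O)[NX3;R]",
  fr_piperidine = "C1CCNCC1", fr_piperazine = "C1CNCCN1",
  fr_morpholine = "C1COCCN1", fr_pyrrolidine = "C1CCNC1",
  fr_tetrahydrofuran = "C1CCOC1", fr_dioxolane = "C1OCCO1",
  fr_alkene = "[CX3]=[CX3]", fr_alkyne = "[CX2]#[CX2]",
  fr_allylic = "[CX4][CX3]=[CX3]", fr_methyl = "[CX4H3]",
  fr_methylene = "[CX4H2]", fr_methoxy = "[OX2][CX4H3]",
  fr_hydroxyl = "[OX2H]", fr_acetyl = "[CX4H3][CX3]=[OX1]",
  fr_tbutyl = "[CX4]([CX4H3])([CX4H3])[CX4H3]",
  fr_isopropyl = "[CX4H]([CX4H3])[CX4H3]", fr_benzyl = "[CX4][c]",
  fr_arom_atom = "[a]", fr_ring_atom = "[R]", fr_spiro_like = "[x4]",
  fr_hetero_arom = "[a;!c]", fr_hetero_ring = "[R;!#6]")

#' Names of the 208 physicochemical descriptor block entries
#'
#' 123 scalar properties (including QED, MolWt and TPSA) followed by 85
#' `fr_*` fragment counts.
#' @return Character vector of length 208.
#' @export
physchem_names <- function() {
  scalars <- c(
    "MolWt", "ExactMolWt", "LogP", "MolMR", "TPSA", "HBD", "HBA",
    "QED", "LipinskiHBA", "LipinskiHBD", "LipinskiViolations",
    "HeavyAtomCount", "TotalAtomCount", "BondCount", "RotatableBondCount",
    "FractionCSP3", "FormalCharge", "AbsFormalChargeSum",
    "NumPositiveAtoms", "NumNegativeAtoms",
    "RingCount", "AromaticRingCount", "AliphaticRingCount",
    "LargestRingSize", "SmallestRingSize", "RingAtomCount", "RingBondCount",
    "FusedRingAtomCount", "NumHeterocycles", "NumAromaticHeterocycles",
    "NumSaturatedRings", "MacrocycleCount",
    "RingSize3", "RingSize4", "RingSize5", "RingSize6", "RingSize7", "RingSize8",
    "nC", "nN", "nO", "nS", "nP", "nF", "nCl", "nBr", "nI", "nB",
    "nHalogen", "nHeteroatoms", "nHydrogen",
    "HeteroatomFraction", "HalogenFraction",
    "AromaticAtomCount", "AromaticCarbonCount", "AromaticNitrogenCount",
    "AromaticHeteroCount",
    "SingleBondCount", "DoubleBondCount", "TripleBondCount", "AromaticBondCount",
    "CyclicSingleBondCount", "CyclicDoubleBondCount",
    "AcyclicSingleBondCount", "AcyclicDoubleBondCount", "AcyclicTripleBondCount",
    "Degree1Count", "Degree2Count", "Degree3Count", "Degree4Count",
    "MaxDegree", "MeanDegree",
    "PrimaryCarbonCount", "SecondaryCarbonCount", "TertiaryCarbonCount",
    "QuaternaryCarbonCount", "NumSp3Carbons", "NumSp2Carbons", "NumSpCarbons",
    "NHOHCount", "NOCount", "OHCount", "NH2Count", "NH1Count",
    "ZagrebM1", "ZagrebM2", "Chi0", "Chi1", "Chi0v", "Chi1v",
    "WienerIndex", "GraphRadius", "GraphDiameter", "MeanTopoDistance",
    "PathCount2", "PathCount3", "Kappa1", "Kappa2", "Kappa3",
    "KierFlexibility", "BertzComplexity",
    "MeanAtomicMass", "MolWtPerHeavyAtom", "TotalValence")
  stopifnot(length(scalars) + length(PHYSCHEM_GROUP_SMARTS) == 123)
  c(scalars, names(PHYSCHEM_GROUP_SMARTS), names(PHYSCHEM_FR_SMARTS))
}

ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
                 As = 74.922, Se = 78.971, Br = 79.904, I = 126.904)

# All-pairs topological distances by repeated BFS.
topo_distances <- function(g) {
  n <- g$n_atoms
  D <- matrix(Inf, n, n)
  nb_atoms <- lapply(seq_len(n), function(i)
    vapply(g$adj[[i]], function(b)
      if (g$bonds$a1[b] == i) g$bonds$a2[b] else g$bonds$a1[b], integer(1)))
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb_atoms[[v]]) if (D[s, w] > D[s, v] + 1) {
        D[s, w] <- D[s, v] + 1
        queue <- c(queue, w)
      }
    }
  }
  D
}

smarts_counts <- function(record, smarts_vec) {
  if (is.null(record$sdf))
    return(stats::setNames(numeric(length(smarts_vec)), names(smarts_vec)))
  set <- ChemmineR::SDFset(list(record$sdf))
  ChemmineR::cid(set) <- record$compound_id
  vapply(smarts_vec, function(s) {
    out <- tryCatch(suppressWarnings(
      ChemmineR::smartsSearchOB(set, s, uniqueMatches = TRUE)),
      error = function(e) NA_real_)
    as.numeric(out[1])
  }, numeric(1))
}

# Drug-likeness score: geometric mean of smooth property desirabilities
# (molecular weight, logP, H-bond donors/acceptors, TPSA, rotatable bonds,
# aromatic rings, structural alerts). The desirability shapes are chosen by
# this package; the score is in (0, 1] and higher means more drug-like.
qed_score <- function(mw, logp, hbd, hba, tpsa, rotb, arom, alerts) {
  bump <- function(x, mu, sd) pmax(exp(-((x - mu)^2) / (2 * sd^2)), 0.01)
  step <- function(x, cap, sd) pmax(ifelse(x <= cap, 1, exp(-((x - cap)^2) / (2 * sd^2))), 0.01)
  d <- c(bump(mw, 300, 150), bump(logp, 2.5, 2.0), step(hbd, 5, 2),
         step(hba, 10, 3), bump(tpsa, 80, 60), step(rotb, 10, 4),
         bump(arom, 2, 1.5), step(alerts, 0, 1))
  exp(mean(log(d)))
}

physchem_vector <- function(record) {
  g <- record$graph
  pr <- NULL
  exact_mw <- NA_real_
  if (!is.null(record$sdf)) {
    set <- ChemmineR::SDFset(list(record$sdf))
    ChemmineR::cid(set) <- record$compound_id
    pr <- tryCatch(ChemmineR::propOB(set), error = function(e) NULL)
    exact_mw <- tryCatch(as.numeric(ChemmineR::exactMassOB(set))[1],
                         error = function(e) NA_real_)
  }
  if (is.null(pr)) {  # fallback for atom-only molecules
    mw_fb <- sum(ATOMIC_MASS[record$graph$elements], na.rm = TRUE) +
      1.008 * sum(record$graph$nH)
    pr <- list(MW = mw_fb, logP = 0, MR = 0, TPSA = 0, HBD = 0, HBA1 = 0)
  }
  el <- g$elements
  n <- g$n_atoms
  deg <- g$degree
  bonds <- g$bonds
  arom_b <- g$aromatic_bond
  nb_of <- function(i) vapply(g$adj[[i]], function(b)
    if (bonds$a1[b] == i) bonds$a2[b] else bonds$a1[b], integer(1))

  halogens <- c("F", "Cl", "Br", "I")
  is_het <- !(el %in% c("C", "H"))
  nH_total <- sum(g$nH)
  grp <- smarts_counts(record, PHYSCHEM_GROUP_SMARTS)
  fr <- smarts_counts(record, PHYSCHEM_FR_SMARTS)

  # carbon hybridisation from bond orders
  c_idx <- which(el == "C")
  csp <- vapply(c_idx, function(i) {
    ords <- ifelse(arom_b[g$adj[[i]]], 1.5, bonds$order[g$adj[[i]]])
    if (any(ords == 3) || sum(ords == 2) >= 2) "sp"
    else if (any(ords == 2) || g$aromatic_atom[i]) "sp2" else "sp3"
  }, character(1))

  ring_in_count <- vapply(seq_len(n), function(i)
    sum(vapply(g$rings, function(r) i %in% r, logical(1))), integer(1))
  het_ring <- vapply(g$rings, function(r) any(is_het[r]), logical(1))
  sat_ring <- vapply(seq_along(g$rings), function(k) {
    r <- g$rings[[k]]
    !g$rings_aromatic[k] && all(el[r] %in% c("C")) &&
      all(bonds$order[g$ring_bond & (bonds$a1 %in% r) & (bonds$a2 %in% r)] == 1)
  }, logical(1))

  D <- if (n > 1) topo_distances(g) else matrix(0, 1, 1)
  finD <- D[is.finite(D) & D > 0]
  wiener <- sum(D[upper.tri(D)][is.finite(D[upper.tri(D)])])
  ecc <- apply(D, 1, function(r) max(r[is.finite(r)]))
  paths2 <- sum(D == 2 & is.finite(D)) / 2
  paths3 <- sum(D == 3 & is.finite(D)) / 2

  nbond <- nrow(bonds)
  A <- n
  P1 <- nbond
  kappa1 <- if (P1 > 0) A * (A - 1)^2 / P1^2 else 0
  kappa2 <- if (paths2 > 0) (A - 1) * (A - 2)^2 / paths2^2 else 0
  kappa3 <- if (paths3 > 0) {
    if (A %% 2 == 1) (A - 1) * (A - 3)^2 / paths3^2
    else (A - 3) * (A - 2)^2 / paths3^2
  } else 0

  dv <- vapply(seq_len(n), function(i) {
    zv <- c(C = 4, N = 5, O = 6, S = 6, P = 5, F = 7, Cl = 7, Br = 7, I = 7,
            B = 3)[el[i]] %||% 4
    max(zv - g$nH[i], 1)
  }, numeric(1))

  ecfp2 <- circular_features(g, 1, functional = FALSE)
  bertz <- log2(1 + length(unique(vapply(ecfp2, `[[`, integer(1), "id"))))

  mw <- as.numeric(pr$MW)[1]
  logp <- as.numeric(pr$logP)[1]
  hbd <- as.numeric(pr$HBD)[1]
  hba1 <- as.numeric(pr$HBA1)[1]
  tpsa <- as.numeric(pr$TPSA)[1]
  rot_smarts <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"
  rotb <- smarts_counts(record, c(rot = rot_smarts))[["rot"]]
  lip_hba <- sum(el %in% c("N", "O"))
  lip_hbd <- sum(el %in% c("N", "O") & g$nH > 0)
  alerts <- sum(fr[c("fr_nitro", "fr_azo", "fr_aldehyde", "fr_epoxide",
                     "fr_aziridine", "fr_SH", "fr_nitroso")], na.rm = TRUE)
  qed <- qed_score(mw, logp, lip_hbd, lip_hba, tpsa, rotb, g$aromatic_rings, alerts)
  lip_viol <- sum(c(mw > 500, logp > 5, lip_hbd > 5, lip_hba > 10))

  scalars <- c(
    MolWt = mw, ExactMolWt = exact_mw, LogP = logp,
    MolMR = as.numeric(pr$MR)[1], TPSA = tpsa, HBD = hbd, HBA = hba1,
    QED = qed, LipinskiHBA = lip_hba, LipinskiHBD = lip_hbd,
    LipinskiViolations = lip_viol,
    HeavyAtomCount = n, TotalAtomCount = n + nH_total, BondCount = nbond,
    RotatableBondCount = rotb,
    FractionCSP3 = if (length(c_idx) > 0) mean(csp == "sp3") else 0,
    FormalCharge = sum(g$charge), AbsFormalChargeSum = sum(abs(g$charge)),
    NumPositiveAtoms = sum(g$charge > 0), NumNegativeAtoms = sum(g$charge < 0),
    RingCount = length(g$rings), AromaticRingCount = g$aromatic_rings,
    AliphaticRingCount = length(g$rings) - g$aromatic_rings,
    LargestRingSize = if (length(g$ring_sizes)) max(g$ring_sizes) else 0,
    SmallestRingSize = if (length(g$ring_sizes)) min(g$ring_sizes) else 0,
    RingAtomCount = sum(g$ring_atom), RingBondCount = sum(g$ring_bond),
    FusedRingAtomCount = sum(ring_in_count >= 2),
    NumHeterocycles = sum(het_ring),
    NumAromaticHeterocycles = sum(het_ring & g$rings_aromatic),
    NumSaturatedRings = sum(sat_ring),
    MacrocycleCount = sum(g$ring_sizes > 8),
    RingSize3 = sum(g$ring_sizes == 3), RingSize4 = sum(g$ring_sizes == 4),
    RingSize5 = sum(g$ring_sizes == 5), RingSize6 = sum(g$ring_sizes == 6),
    RingSize7 = sum(g$ring_sizes == 7), RingSize8 = sum(g$ring_sizes == 8),
    nC = sum(el == "C"), nN = sum(el == "N"), nO = sum(el == "O"),
    nS = sum(el == "S"), nP = sum(el == "P"), nF = sum(el == "F"),
    nCl = sum(el == "Cl"), nBr = sum(el == "Br"), nI = sum(el == "I"),
    nB = sum(el == "B"),
    nHalogen = sum(el %in% halogens), nHeteroatoms = sum(is_het),
    nHydrogen = nH_total,
    HeteroatomFraction = sum(is_het) / n,
    HalogenFraction = sum(el %in% halogens) / n,
    AromaticAtomCount = sum(g$aromatic_atom),
    AromaticCarbonCount = sum(g$aromatic_atom & el == "C"),
    AromaticNitrogenCount = sum(g$aromatic_atom & el == "N"),
    AromaticHeteroCount = sum(g$aromatic_atom & is_het),
    SingleBondCount = sum(bonds$order == 1 & !arom_b),
    DoubleBondCount = sum(bonds$order == 2 & !arom_b),
    TripleBondCount = sum(bonds$order == 3),
    AromaticBondCount = sum(arom_b),
    CyclicSingleBondCount = sum(bonds$order == 1 & g$ring_bond & !arom_b),
    CyclicDoubleBondCount = sum(bonds$order == 2 & g$ring_bond & !arom_b),
    AcyclicSingleBondCount = sum(bonds$order == 1 & !g$ring_bond),
    AcyclicDoubleBondCount = sum(bonds$order == 2 & !g$ring_bond),
    AcyclicTripleBondCount = sum(bonds$order == 3 & !g$ring_bond),
    Degree1Count = sum(deg == 1), Degree2Count = sum(deg == 2),
    Degree3Count = sum(deg == 3), Degree4Count = sum(deg == 4),
    MaxDegree = if (n > 0) max(deg) else 0, MeanDegree = mean(deg),
    PrimaryCarbonCount = sum(el == "C" & vapply(seq_len(n), function(i)
      sum(el[nb_of(i)] == "C"), integer(1)) == 1),
    SecondaryCarbonCount = sum(el == "C" & vapply(seq_len(n), function(i)
      sum(el[nb_of(i)] == "C"), integer(1)) == 2),
    TertiaryCarbonCount = sum(el == "C" & vapply(seq_len(n), function(i)
      sum(el[nb_of(i)] == "C"), integer(1)) == 3),
    QuaternaryCarbonCount = sum(el == "C" & vapply(seq_len(n), function(i)
      sum(el[nb_of(i)] == "C"), integer(1)) == 4),
    NumSp3Carbons = sum(csp == "sp3"), NumSp2Carbons = sum(csp == "sp2"),
    NumSpCarbons = sum(csp == "sp"),
    NHOHCount = sum(el %in% c("N", "O") & g$nH > 0),
    NOCount = sum(el %in% c("N", "O")),
    OHCount = sum(el == "O" & g$nH > 0),
    NH2Count = sum(el == "N" & g$nH == 2),
    NH1Count = sum(el == "N" & g$nH == 1),
    ZagrebM1 = sum(deg^2),
    ZagrebM2 = sum(deg[bonds$a1] * deg[bonds$a2]),
    Chi0 = sum(1 / sqrt(pmax(deg, 1))),
    Chi1 = if (nbond > 0) sum(1 / sqrt(deg[bonds$a1] * deg[bonds$a2])) else 0,
    Chi0v = sum(1 / sqrt(dv)),
    Chi1v = if (nbond > 0) sum(1 / sqrt(dv[bonds$a1] * dv[bonds$a2])) else 0,
    WienerIndex = wiener,
    GraphRadius = if (length(ecc)) min(ecc) else 0,
    GraphDiameter = if (length(ecc)) max(ecc) else 0,
    MeanTopoDistance = if (length(finD)) mean(finD) else 0,
    PathCount2 = paths2, PathCount3 = paths3,
    Kappa1 = kappa1, Kappa2 = kappa2, Kappa3 = kappa3,
    KierFlexibility = if (n > 0) kappa1 * kappa2 / n else 0,
    BertzComplexity = bertz,
    MeanAtomicMass = mean(ATOMIC_MASS[el], na.rm = TRUE),
    MolWtPerHeavyAtom = mw / max(n, 1),
    TotalValence = sum(ceiling(vapply(seq_len(n), function(i)
      sum(ifelse(arom_b[g$adj[[i]]], 1.5, bonds$order[g$adj[[i]]])), numeric(1))) + g$nH))
  out <- c(scalars, grp, fr)
  names(out) <- physchem_names()
  out[!is.finite(out)] <- 0
  out
}
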
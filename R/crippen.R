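# Wildman-Crippen atom-contribution cLogP.
#
# Implements the atom typing scheme and contribution values of Wildman &
# Crippen (J. Chem. Inf. Comput. Sci. 1999, 39, 868-873): every atom
# (hydrogens included) is assigned one of ~70 published types by
# first-match-wins rules over its element, aromaticity, charge, hydrogen
# count and neighbourhood, and cLogP is the sum of the type contributions.
# The typing rules below are a direct translation of the published SMARTS
# definitions into predicates on the molgraph representation.

CRIPPEN_LOGP <- c(
  C1 = 0.1441,  C2 = 0.0,     C3 = -0.2035, C4 = -0.2051, C5 = -0.2783,
  C6 = 0.1551,  C7 = 0.00170, C8 = 0.08452, C9 = -0.1444, C10 = -0.0516,
  C11 = 0.1193, C12 = -0.0967, C13 = -0.5443, C14 = 0.0,  C15 = 0.2450,
  C16 = 0.1980, C17 = 0.0,    C18 = 0.1581, C19 = 0.2955, C20 = 0.2713,
  C21 = 0.1360, C22 = 0.4619, C23 = 0.5437, C24 = 0.1893, C25 = -0.8186,
  C26 = 0.2640, C27 = 0.2148, CS = 0.08129,
  H1 = 0.1230,  H2 = -0.2677, H3 = 0.2142,  H4 = 0.2980,  HS = 0.1125,
  N1 = -1.0190, N2 = -0.7096, N3 = -1.0270, N4 = -0.5188, N5 = 0.08387,
  N6 = 0.1836,  N7 = -0.3187, N8 = -0.4458, N9 = 0.01508, N10 = -1.950,
  N11 = -0.3239, N12 = -1.119, N13 = -0.3396, N14 = 0.2887, NS = -0.4806,
  O1 = 0.1552,  O2 = -0.2893, O3 = -0.0684, O4 = -0.4195, O5 = 0.0335,
  O6 = -0.3339, O7 = -1.189,  O8 = 0.1788,  O9 = -0.1526, O10 = 0.1129,
  O11 = 0.4833, O12 = -1.326, OS = -0.1188,
  F = 0.4202,  Cl = 0.6895, Br = 0.8456, I = 0.8857, Hal = -2.996,
  P = 0.8612,  S1 = 0.6482, S2 = -0.0024, S3 = 0.6237,
  Me1 = -0.3808, Me2 = -0.0025
)

HET_NOPS_HAL <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")
METALS_ME1 <- c("Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba",
                "B", "Al", "Ga", "In", "Tl", "Si", "Ge", "Sn", "Pb",
                "As", "Sb", "Bi", "Se", "Te", "Po")

#' Wildman-Crippen cLogP
#'
#' Atom-contribution octanol/water partition coefficient following the
#' published Wildman-Crippen parameterization (the convention of standard
#' fragment-analysis tooling). Hydrogens contribute through their own types.
#'
#' @param smiles character vector of SMILES (single-component structures).
#' @return numeric vector of cLogP values.
#' @examples
#' crippen_clogp("c1ccccc1")
#' @export
crippen_clogp <- function(smiles) {
  can <- canonical_smiles(smiles)
  graphs <- mol_graphs(can)
  vapply(graphs, crippen_logp_graph, numeric(1))
}

crippen_logp_graph <- function(graph) {
  types <- crippen_atom_types(graph)
  heavy_sum <- sum(CRIPPEN_LOGP[types$heavy])
  h_sum <- sum(CRIPPEN_LOGP[types$hydrogen] * types$h_count)
  heavy_sum + h_sum
}

# Assign Crippen types. Returns list(heavy = type per heavy atom,
# hydrogen = H type per heavy atom, h_count = number of H on that atom).
crippen_atom_types <- function(graph) {
  atoms <- graph$atoms
  adj <- molgraph_adjacency(graph)
  n <- nrow(atoms)
  env <- lapply(seq_len(n), function(i) crippen_env(atoms, adj, i))
  heavy <- vapply(seq_len(n), function(i) crippen_type_heavy(env[[i]]), character(1))
  hydrogen <- vapply(seq_len(n), function(i) crippen_type_hydrogen(env[[i]]), character(1))
  list(heavy = heavy, hydrogen = hydrogen, h_count = atoms$nh)
}

# Per-atom environment snapshot used by the typing rules.
crippen_env <- function(atoms, adj, i) {
  nbr <- adj[[i]]$nbr
  list(
    elem = atoms$elem[i],
    arom = atoms$aromatic[i],
    chg = atoms$charge[i],
    nh = atoms$nh[i],
    deg = length(nbr),
    x = length(nbr) + atoms$nh[i],
    nbr_elem = atoms$elem[nbr],
    nbr_arom = atoms$aromatic[nbr],
    nbr_chg = atoms$charge[nbr],
    nbr_nh = atoms$nh[nbr],
    nbr_deg = atoms$degree[nbr],
    nbr_x = atoms$degree[nbr] + atoms$nh[nbr],
    order = adj[[i]]$order,
    barom = adj[[i]]$aromatic,   # aromatic ring bond
    nbr_idx = nbr,
    atoms = atoms,
    adj = adj
  )
}

crippen_type_heavy <- function(e) {
  switch(e$elem,
    "C" = crippen_type_C(e),
    "N" = crippen_type_N(e),
    "O" = crippen_type_O(e),
    "S" = crippen_type_S(e),
    "F" = if (e$chg == 0L) "F" else "Hal",
    "Cl" = if (e$chg == 0L) "Cl" else "Hal",
    "Br" = if (e$chg == 0L) "Br" else "Hal",
    "I" = "I",  # neutral I; charged iodine also folds to Hal below
    "P" = "P",
    "H" = "HS",
    if (e$elem %in% METALS_ME1) "Me1" else "Me2"
  )
}

crippen_type_C <- function(e) {
  ali <- !e$nbr_arom
  single <- e$order == 1L & !e$barom
  dbl <- e$order == 2L & !e$barom
  ali_C <- e$nbr_elem == "C" & ali
  het <- e$nbr_elem %in% HET_NOPS_HAL & ali
  x4 <- e$x == 4L && all(single)

  if (!e$arom) {
    # C1/C2: carbons bonded only to aliphatic C and H
    if (e$nh == 4L) return("C1")
    if (e$nh == 3L && e$deg == 1L && all(ali_C & single)) return("C1")
    if (e$nh == 2L && e$deg == 2L && all(ali_C & single)) return("C1")
    if (e$nh == 1L && e$deg == 3L && all(ali_C & single)) return("C2")
    if (e$nh == 0L && e$deg == 4L && all(ali_C & single)) return("C2")
    # C3/C4: sp3 carbons attached to N/O/P/S/halogen
    if (e$nh == 3L && e$deg == 1L && all(het)) return("C3")
    if (e$nh == 2L && x4 && any(het) && all(ali)) return("C3")
    if (e$nh == 1L && x4 && any(het) && all(ali)) return("C4")
    if (e$nh == 0L && x4 && any(het) && all(ali)) return("C4")
    # C5: double bond to an aliphatic heteroatom (carbonyl, imine-C, C=S...)
    if (any(dbl & e$nbr_elem != "C" & ali)) return("C5")
    # C6: vinylic / allenic carbons (substituents aliphatic)
    if (any(dbl & ali_C)) {
      others <- !(dbl & ali_C)
      if (sum(dbl & ali_C) == 2L) return("C6")
      if (all(ali[others] | e$nbr_elem[others] == "H")) {
        if (e$nh == 2L && e$deg == 1L) return("C6")
        if (e$nh == 1L && e$deg == 2L) return("C6")
        if (e$nh == 0L && e$deg == 3L) return("C6")
      }
    }
    # C7: sp carbon in a triple bond
    if (e$x == 2L && any(e$order == 3L)) return("C7")
    # C8-C12: aliphatic carbons attached to aromatic systems
    if (e$nh == 3L && e$deg == 1L) {
      if (e$nbr_elem == "C" && e$nbr_arom) return("C8")
      if (e$nbr_arom) return("C9")
    }
    if (e$nh == 2L && x4 && any(e$nbr_arom)) return("C10")
    if (e$nh == 1L && x4 && any(e$nbr_arom)) return("C11")
    if (e$nh == 0L && x4 && any(e$nbr_arom)) return("C12")
    # C26: conjugating carbons bridging alkene and aromatic systems
    if (any(dbl & ali_C) && any(e$nbr_arom)) return("C26")
    if (any(dbl & e$nbr_arom & e$nbr_elem == "C")) return("C26")
    # C27: sp3 carbon attached to an unusual aliphatic element
    if (x4 && any(!(e$nbr_elem %in% c(HET_NOPS_HAL, "C", "H")) & ali)) return("C27")
    return("CS")
  }

  # aromatic carbons ----------------------------------------------------
  arom_nbr <- e$barom
  nonarom_single <- single & !e$barom
  if (e$nh == 0L &&
      any(nonarom_single & !e$nbr_arom &
          !(e$nbr_elem %in% c("C", "N", "O", "S", "F", "Cl", "Br", "I", "H")))) {
    return("C13")
  }
  if (any(e$nbr_elem == "F")) return("C14")
  if (any(e$nbr_elem == "Cl")) return("C15")
  if (any(e$nbr_elem == "Br")) return("C16")
  if (any(e$nbr_elem == "I")) return("C17")
  if (e$nh == 1L) return("C18")
  if (sum(arom_nbr) >= 3L) return("C19")
  if (any(nonarom_single & e$nbr_arom)) return("C20")
  if (any(nonarom_single & !e$nbr_arom & e$nbr_elem == "C")) return("C21")
  if (any(nonarom_single & !e$nbr_arom & e$nbr_elem == "N")) return("C22")
  if (any(nonarom_single & !e$nbr_arom & e$nbr_elem == "O")) return("C23")
  if (any(nonarom_single & !e$nbr_arom & e$nbr_elem == "S")) return("C24")
  if (any(dbl & e$nbr_elem %in% c("C", "N", "O"))) return("C25")
  "CS"
}

crippen_type_N <- function(e) {
  if (e$arom) {
    if (e$chg == 0L) return("N11")
    if (e$chg > 0L) return("N12")
    return("NS")
  }
  ali <- !e$nbr_arom
  dbl <- e$order == 2L & !e$barom
  if (e$chg == 0L) {
    if (e$nh == 2L && e$deg == 1L && ali) return("N1")
    if (e$nh == 1L && e$deg == 2L && all(ali)) return("N2")
    if (e$nh == 2L && e$deg == 1L && !ali) return("N3")
    if (e$nh == 1L && e$deg == 2L && any(!ali)) return("N4")
    if (e$nh == 1L && any(dbl)) return("N5")
    if (e$nh == 0L && any(dbl) && e$deg == 2L) return("N6")
    if (e$nh == 0L && e$deg == 3L && all(ali)) return("N7")
    if (e$nh == 0L && e$deg == 3L && any(!ali)) return("N8")
    if (any(e$order == 3L)) return("N9")
    return("NS")
  }
  if (e$chg > 0L) {
    if (e$nh >= 1L) return("N10")
    if (any(e$order == 3L)) return("N14")
    if (e$deg == 4L || any(dbl)) return("N13")
    return("NS")
  }
  "N14" # anionic nitrogen
}

crippen_type_O <- function(e) {
  if (e$arom) return("O1")
  dbl <- e$order == 2L & !e$barom
  if (e$chg == 0L && e$nh >= 1L) return("O2")
  if (e$chg == 0L && e$deg == 2L && all(!e$nbr_arom)) return("O3")
  if (e$chg == 0L && e$deg == 2L && any(e$nbr_arom)) return("O4")
  if (any(dbl & e$nbr_elem %in% c("N", "O"))) return("O5")
  if (e$chg < 0L && e$deg == 1L && e$nbr_elem == "N") return("O5")
  if (e$chg < 0L && e$deg == 1L && e$nbr_elem == "S") return("O6")
  if (e$chg == 0L && any(dbl & e$nbr_elem == "S" & e$nbr_chg == 0L)) return("O6")
  if (e$chg < 0L && e$deg == 1L && e$nbr_elem == "C" &&
      carbon_is_carboxylate(e)) return("O12")
  if (e$chg < 0L) return("O7")
  if (any(dbl & e$nbr_arom & e$nbr_elem == "C")) return("O8")
  if (any(dbl & !e$nbr_arom & e$nbr_elem == "C")) {
    cidx <- e$nbr_idx[which(dbl & !e$nbr_arom & e$nbr_elem == "C")[1]]
    return(crippen_carbonyl_O(e, cidx))
  }
  "OS"
}

# distinguish aliphatic (O9), aryl (O10) and dihetero (O11) carbonyl oxygens
crippen_carbonyl_O <- function(e, cidx) {
  adj <- e$adj; atoms <- e$atoms
  # substituents of the carbonyl carbon other than this (double-bonded) oxygen
  subs <- adj[[cidx]]$nbr
  dbl_o <- subs[adj[[cidx]]$order == 2L & atoms$elem[subs] == "O"]
  if (length(dbl_o) > 0) subs <- setdiff(subs, dbl_o[1])
  nh_c <- atoms$nh[cidx]
  sub_elem <- atoms$elem[subs]
  sub_arom <- atoms$aromatic[subs]
  n_c_ali <- sum(sub_elem == "C" & !sub_arom)
  n_c_aro <- sum(sub_elem == "C" & sub_arom)
  n_het <- sum(sub_elem != "C")
  n_arom <- sum(sub_arom)
  # O11: carbonyl with two non-carbon substituents (urea/carbamate carbonyl)
  if (length(subs) == 2L && all(sub_elem != "C") && n_arom == 0L) return("O11")
  # O10: aryl-conjugated carbonyl
  if (nh_c == 1L && n_c_aro == 1L) return("O10")
  if (length(subs) == 2L && (n_c_ali + n_c_aro) >= 1L && n_arom >= 1L) return("O10")
  # O9: aliphatic aldehyde/ketone/amide/acid carbonyl
  if (nh_c == 1L && length(subs) == 1L && n_c_ali == 1L) return("O9")
  if (length(subs) == 2L && n_c_ali >= 1L && n_arom == 0L) return("O9")
  if (nh_c == 1L && length(subs) == 1L && sub_elem %in% c("N", "O")) return("O9")
  if (nh_c == 2L && length(subs) == 0L) return("O9")
  if (length(subs) == 1L && atoms$elem[subs] == "O" &&
      any(adj[[cidx]]$order == 2L)) return("O9") # O=C=O
  "OS"
}

carbon_is_carboxylate <- function(e) {
  cidx <- e$nbr_idx[1]
  adj <- e$adj; atoms <- e$atoms
  any(adj[[cidx]]$order == 2L & atoms$elem[adj[[cidx]]$nbr] == "O")
}

crippen_type_S <- function(e) {
  if (e$arom) return("S3")
  dbl <- e$order == 2L & !e$barom
  if (e$chg != 0L) return("S2")
  if (any(dbl & e$nbr_elem %in% c("N", "O", "P", "S"))) return("S2")
  "S1"
}

crippen_type_hydrogen <- function(e) {
  # type of the hydrogens attached to this heavy atom
  if (e$nh == 0L) return("HS")
  if (e$elem == "C") return("H1")
  if (e$elem == "O") {
    nbr_heavy <- e$nbr_idx[e$nbr_elem != "H"]
    if (length(nbr_heavy) == 0L) return("HS") # water
    j <- nbr_heavy[1]
    atoms <- e$atoms; adj <- e$adj
    jx <- atoms$degree[j] + atoms$nh[j]
    # H4: acid/enol O-H (neighbour carbon doubly bonded to C/N/O/S), O-O/O-S
    if (atoms$elem[j] %in% c("O", "S")) return("H4")
    if (atoms$elem[j] == "C" &&
        any(adj[[j]]$order == 2L & !adj[[j]]$aromatic &
            atoms$elem[adj[[j]]$nbr] %in% c("C", "N", "O", "S"))) return("H4")
    # H3: N-O-H
    if (atoms$elem[j] == "N") return("H3")
    # H2: alcohol / phenol hydrogens
    if (atoms$elem[j] == "C" && !atoms$aromatic[j] && jx == 4L &&
        all(adj[[j]]$order == 1L)) return("H2")
    if (atoms$elem[j] == "C" && atoms$aromatic[j]) return("H2")
    if (!(atoms$elem[j] %in% c("C", "N", "O", "S"))) return("H2")
    return("HS")
  }
  if (e$elem == "N") return("H3")
  # H2: hydrogens on atoms other than C, N, O (thiols, silanes, ...)
  "H2"
}
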
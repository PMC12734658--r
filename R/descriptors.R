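# The six fragment-relevant descriptors: MW, cLogP, HBD, HBA, TPSA, RotB.
# MW and Ertl TPSA come from the OpenBabel back end; cLogP is the package's
# Wildman-Crippen implementation; the count descriptors are computed on the
# molecular graph so their conventions are explicit and testable.

#' Compute fragment-relevant physicochemical descriptors
#'
#' Appends the six standard fragment descriptors to a molecule table:
#' molecular weight (`mw`, g/mol, standard atomic weights), Wildman-Crippen
#' `clogp`, Lipinski hydrogen-bond donors (`hbd`) and acceptors (`hba`),
#' Ertl topological polar surface area (`tpsa`, Angstrom^2, including the
#' sulfur/phosphorus terms of the original parameterization) and rotatable
#' bonds (`rotb`: non-ring single bonds between non-terminal heavy atoms,
#' excluding amide C-N bonds and bonds to triple-bonded atoms).
#'
#' All six descriptors are constitutional/topological, so enantiomers receive
#' identical values; inputs must be neutral single-component parents (salts
#' are rejected -- strip them first with [mol_parse()]).
#'
#' @param data data frame with a SMILES column (see [mol_parse()]).
#' @param smiles name of the SMILES column.
#' @param hba_rule acceptor-counting convention: `"pattern"` (default) counts
#'   N/O acceptors the way common fragment tooling does (amide nitrogens and
#'   acidic hydroxyls excluded); `"n_o_count"` is the plain count of N + O
#'   atoms. Donors are always N/O atoms bearing at least one hydrogen.
#' @return the input as a tibble with `mw`, `clogp`, `hbd`, `hba`, `tpsa`,
#'   `rotb` columns appended.
#' @examples
#' compute_properties(data.frame(smiles = c("CCO", "c1ccccc1")))
#' @export
compute_properties <- function(data, smiles = "smiles",
                               hba_rule = c("pattern", "n_o_count")) {
  stopifnot(is.data.frame(data), smiles %in% names(data))
  hba_rule <- match.arg(hba_rule)
  smi <- as.character(data[[smiles]])
  if (length(smi) == 0L) abort("no molecules to profile")
  can <- canonical_smiles(smi)
  multi <- vapply(can, function(s) length(smiles_components(s)) > 1L, logical(1))
  if (any(multi)) {
    abort(sprintf("multi-component structure in profiler input: '%s'", can[multi][1]))
  }
  charged <- vapply(can, net_formal_charge, integer(1)) != 0L
  if (any(charged)) {
    abort(sprintf("charged structure in profiler input: '%s' (profile neutral parents)",
                  can[charged][1]))
  }
  graphs <- mol_graphs(can)
  obp <- ob_properties(can)
  bind_cols(
    as_tibble(data),
    tibble(
      mw = obp$mw,
      clogp = vapply(graphs, crippen_logp_graph, numeric(1)),
      hbd = vapply(graphs, count_hbd, integer(1)),
      hba = vapply(graphs, count_hba, integer(1), rule = hba_rule),
      tpsa = obp$tpsa,
      rotb = vapply(graphs, count_rotatable_bonds, integer(1))
    )
  )
}

# donors: N or O atoms bearing at least one hydrogen
count_hbd <- function(graph) {
  a <- graph$atoms
  sum(a$elem %in% c("N", "O") & a$nh >= 1L)
}

count_hba <- function(graph, rule = "pattern") {
  a <- graph$atoms
  if (rule == "n_o_count") return(sum(a$elem %in% c("N", "O")))
  adj <- molgraph_adjacency(graph)
  acc <- vapply(seq_len(nrow(a)), function(i) {
    el <- a$elem[i]
    if (!(el %in% c("N", "O", "S", "n", "o", "s"))) return(FALSE)
    arom <- a$aromatic[i]
    v <- sum(adj[[i]]$order) + a$nh[i]
    if (arom) {
      # aromatic n (without H), o, s; neutral
      return(a$charge[i] == 0L &&
             ((el == "N" && a$nh[i] == 0L) || el %in% c("O", "S")))
    }
    if (el %in% c("O", "S")) {
      if (a$charge[i] < 0L) return(TRUE)
      if (v != 2L) return(FALSE)
      if (a$nh[i] == 0L) return(TRUE)
      if (a$nh[i] == 1L) {
        # hydroxyl counts unless its attachment carries a double bond to
        # O/N/P/S (acidic O-H as in carboxylic/sulfonic acids)
        j <- adj[[i]]$nbr
        if (length(j) == 0L) return(FALSE)
        j <- j[1]
        acidic <- any(adj[[j]]$order == 2L &
                      a$elem[adj[[j]]$nbr] %in% c("O", "N", "P", "S"))
        return(!acidic)
      }
      return(FALSE)
    }
    # aliphatic N: valence 3 and not amide/sulfonamide-like (single-bonded to
    # an atom with a non-ring double bond to O/N/P/S)
    if (el == "N") {
      if (a$charge[i] != 0L || v != 3L) return(FALSE)
      sn <- adj[[i]]$nbr[adj[[i]]$order == 1L]
      amide_like <- any(vapply(sn, function(j) {
        any(adj[[j]]$order == 2L & !adj[[j]]$in_ring &
            a$elem[adj[[j]]$nbr] %in% c("O", "N", "P", "S"))
      }, logical(1)))
      return(!amide_like)
    }
    FALSE
  }, logical(1))
  sum(acc)
}

count_rotatable_bonds <- function(graph) {
  a <- graph$atoms
  b <- graph$bonds
  if (nrow(b) == 0L) return(0L)
  adj <- molgraph_adjacency(graph)
  in_triple <- vapply(seq_len(nrow(a)), function(i) any(adj[[i]]$order == 3L), logical(1))
  rot <- b$order == 1L & !b$in_ring &
    a$degree[b$a] > 1L & a$degree[b$b] > 1L &
    !in_triple[b$a] & !in_triple[b$b]
  # exclude amide C-N bonds
  amide <- vapply(seq_len(nrow(b)), function(k) {
    if (!rot[k]) return(FALSE)
    ends <- c(b$a[k], b$b[k])
    for (ord in list(ends, rev(ends))) {
      ci <- ord[1]; ni <- ord[2]
      if (a$elem[ci] == "C" && a$elem[ni] == "N" &&
          any(adj[[ci]]$order == 2L & a$elem[adj[[ci]]$nbr] == "O")) return(TRUE)
    }
    FALSE
  }, logical(1))
  sum(rot & !amide)
}

#' Molecular formula
#'
#' @param smiles character vector of SMILES.
#' @return character vector of Hill-notation molecular formulae.
#' @export
mol_formula <- function(smiles) {
  ob_properties(canonical_smiles(smiles))$formula
}
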
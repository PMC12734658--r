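# Molecular-graph layer.
#
# A "molgraph" is a plain list with two tibbles describing the heavy-atom
# graph of one molecule:
#   atoms: idx, elem, aromatic, charge, stereo, nh (attached H), degree
#          (heavy neighbours), in_ring, x/y/z (3D coordinates if requested)
#   bonds: a, b (heavy atom indices), order (1/2/3), in_ring, aromatic
# Connectivity and (optional) 3D coordinates come from OpenBabel's SDF output;
# aromaticity, charges and stereo descriptors come from the SMILES lexer.
# OpenBabel preserves input atom order in SMILES -> SDF conversion (explicit
# hydrogens are appended after the heavy atoms), which is what makes the merge
# of the two sources sound; the merge is asserted element-by-element.

mol_graph <- function(smiles, gen3d = FALSE) {
  mol_graphs(smiles, gen3d = gen3d)[[1]]
}

mol_graphs <- function(smiles, gen3d = FALSE) {
  stopifnot(length(smiles) >= 1L)
  sdf_text <- ob_sdf(smiles, gen3d = gen3d)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdf_text, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  if (length(sdfset) != length(smiles)) {
    abort(sprintf(
      "OpenBabel converted %d of %d molecules; cannot build graphs for invalid SMILES",
      length(sdfset), length(smiles)))
  }
  lapply(seq_along(smiles), function(i) {
    build_molgraph(smiles[i], sdfset[[i]], gen3d = gen3d)
  })
}

build_molgraph <- function(smiles, sdf, gen3d) {
  tok <- lex_smiles(smiles)
  tok <- tok[toupper(tok$symbol) != "H", , drop = FALSE]

  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elems <- sub("_[0-9]+$", "", rownames(ab))
  heavy <- which(elems != "H")
  n_heavy <- length(heavy)
  if (n_heavy != nrow(tok)) {
    abort(sprintf("atom-count mismatch between SMILES (%d) and SDF (%d) for '%s'",
                  nrow(tok), n_heavy, smiles))
  }
  elem_tok <- vapply(tok$symbol, function(s) {
    paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
  }, character(1))
  if (!all(elem_tok == elems[heavy])) {
    abort(sprintf("atom-order mismatch between SMILES and SDF for '%s'", smiles))
  }

  bonds_all <- tibble(
    a = as.integer(bb[, 1]),
    b = as.integer(bb[, 2]),
    order = as.integer(bb[, 3])
  )
  is_h <- elems == "H"
  nh <- integer(n_heavy)
  hb <- bonds_all[is_h[bonds_all$a] | is_h[bonds_all$b], , drop = FALSE]
  if (nrow(hb) > 0) {
    heavy_end <- ifelse(is_h[hb$a], hb$b, hb$a)
    cnt <- table(factor(heavy_end, levels = heavy))
    nh <- as.integer(cnt)
  }
  bonds <- bonds_all[!is_h[bonds_all$a] & !is_h[bonds_all$b], , drop = FALSE]
  # reindex heavy atoms 1..n_heavy
  remap <- integer(length(elems))
  remap[heavy] <- seq_len(n_heavy)
  bonds$a <- remap[bonds$a]
  bonds$b <- remap[bonds$b]

  in_ring_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_edgelist(cbind(bonds$a, bonds$b), directed = FALSE)
    br <- igraph::bridges(g)
    in_ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  deg <- integer(n_heavy)
  if (nrow(bonds) > 0) {
    tt <- table(factor(c(bonds$a, bonds$b), levels = seq_len(n_heavy)))
    deg <- as.integer(tt)
  }
  in_ring_atom <- rep(FALSE, n_heavy)
  if (any(in_ring_bond)) {
    ra <- unique(c(bonds$a[in_ring_bond], bonds$b[in_ring_bond]))
    in_ring_atom[ra] <- TRUE
  }
  aromatic_bond <- tok$aromatic[bonds$a] & tok$aromatic[bonds$b] & in_ring_bond

  atoms <- tibble(
    idx = seq_len(n_heavy),
    elem = elems[heavy],
    aromatic = tok$aromatic,
    charge = tok$charge,
    stereo = tok$stereo,
    nh = nh,
    degree = deg,
    in_ring = in_ring_atom,
    x = if (gen3d) as.numeric(ab[heavy, 1]) else NA_real_,
    y = if (gen3d) as.numeric(ab[heavy, 2]) else NA_real_,
    z = if (gen3d) as.numeric(ab[heavy, 3]) else NA_real_
  )
  bonds$in_ring <- in_ring_bond
  bonds$aromatic <- aromatic_bond
  list(smiles = smiles, atoms = atoms, bonds = as_tibble(bonds))
}

# adjacency list: for atom i, tibble of (nbr, order, in_ring, aromatic)
molgraph_adjacency <- function(graph) {
  n <- nrow(graph$atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(), order = integer(),
                                         in_ring = logical(), aromatic = logical())
  b <- graph$bonds
  for (k in seq_len(nrow(b))) {
    a1 <- b$a[k]; a2 <- b$b[k]
    adj[[a1]]$nbr <- c(adj[[a1]]$nbr, a2)
    adj[[a1]]$order <- c(adj[[a1]]$order, b$order[k])
    adj[[a1]]$in_ring <- c(adj[[a1]]$in_ring, b$in_ring[k])
    adj[[a1]]$aromatic <- c(adj[[a1]]$aromatic, b$aromatic[k])
    adj[[a2]]$nbr <- c(adj[[a2]]$nbr, a1)
    adj[[a2]]$order <- c(adj[[a2]]$order, b$order[k])
    adj[[a2]]$in_ring <- c(adj[[a2]]$in_ring, b$in_ring[k])
    adj[[a2]]$aromatic <- c(adj[[a2]]$aromatic, b$aromatic[k])
  }
  adj
}

# Smallest ring containing the bond (a, b): shortest path a -> b avoiding the
# direct edge, closed with the edge itself. Returns atom indices in ring order,
# or NULL when the bond is not in a ring.
ring_through_bond <- function(graph, a, b) {
  bonds <- graph$bonds
  hit <- which((bonds$a == a & bonds$b == b) | (bonds$a == b & bonds$b == a))
  if (length(hit) == 0L || !bonds$in_ring[hit[1]]) return(NULL)
  g <- igraph::graph_from_edgelist(cbind(bonds$a, bonds$b), directed = FALSE)
  g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a, b)))
  sp <- suppressWarnings(igraph::shortest_paths(g, from = a, to = b)$vpath[[1]])
  if (length(sp) == 0L) return(NULL)
  as.integer(sp)
}

# Weisfeiler-Lehman style atom symmetry classes: iterative neighbourhood
# refinement from (element, aromaticity, charge, H count, degree) seeds.
atom_symmetry_classes <- function(graph) {
  atoms <- graph$atoms
  adj <- molgraph_adjacency(graph)
  key <- paste(atoms$elem, atoms$aromatic, atoms$charge, atoms$nh, atoms$degree)
  cls <- as.integer(factor(key))
  repeat {
    new_key <- vapply(seq_len(nrow(atoms)), function(i) {
      nb <- sort(paste(adj[[i]]$order, cls[adj[[i]]$nbr]))
      paste(cls[i], paste(nb, collapse = "|"))
    }, character(1))
    new_cls <- as.integer(factor(new_key))
    if (length(unique(new_cls)) == length(unique(cls))) return(new_cls)
    cls <- new_cls
  }
}

# Potential tetrahedral stereocentres: sp3 carbons whose substituent branches
# are pairwise distinguishable under symmetry-class refinement. This covers
# ordinary centres (including all ring CH centres handled by this package);
# para-type/dependent stereocentres are out of scope and documented as such.
potential_stereocenters <- function(graph) {
  atoms <- graph$atoms
  adj <- molgraph_adjacency(graph)
  cls <- atom_symmetry_classes(graph)
  out <- integer(0)
  for (i in seq_len(nrow(atoms))) {
    if (atoms$elem[i] != "C" || atoms$aromatic[i]) next
    if (any(adj[[i]]$order > 1L)) next
    x <- atoms$degree[i] + atoms$nh[i]
    if (x != 4L || atoms$nh[i] > 1L) next
    ncls <- cls[adj[[i]]$nbr]
    if (anyDuplicated(ncls)) next
    out <- c(out, i)
  }
  out
}
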
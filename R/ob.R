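# OpenBabel (ChemmineOB) back end: canonicalization, format conversion and
# bulk property calculation. All heavy chemistry I/O funnels through here.

ob_quiet <- function(expr) {
  # OpenBabel writes perception warnings to stderr; keep the API quiet and
  # surface problems through return values instead.
  msgs <- character()
  res <- withCallingHandlers(
    suppressWarnings(expr),
    message = function(m) invokeRestart("muffleMessage")
  )
  res
}

# Batch-convert SMILES -> canonical isomeric SMILES.
# OpenBabel aborts a multi-molecule stream at the first invalid entry, so a
# shrinking-batch strategy is used: convert the batch; entries after a failure
# are retried. Returns a character vector aligned with `smiles`, NA where the
# molecule could not be parsed.
ob_canonical <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    ids <- sprintf("m%d", todo)
    src <- paste(paste(smiles[todo], ids), collapse = "\n")
    res <- tryCatch(
      ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", source = src)),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    got <- integer(0)
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2L && grepl("^m[0-9]+$", parts[2])) {
        idx <- as.integer(sub("^m", "", parts[2]))
        out[idx] <- parts[1]
        got <- c(got, idx)
      }
    }
    remaining <- setdiff(todo, got)
    if (length(remaining) == length(todo)) {
      # head of the batch is unparseable; mark it failed and move on
      out[remaining[1]] <- NA_character_
      todo <- remaining[-1]
    } else {
      # drop everything up to and including the first failure point
      first_bad <- remaining[which(!(remaining %in% got))[1]]
      done_or_bad <- union(got, first_bad)
      out[first_bad] <- NA_character_
      todo <- setdiff(todo, done_or_bad)
    }
  }
  out
}

# Convert SMILES to SDF (V2000) text. options: explicit hydrogens are always
# added (the graph layer relies on them); gen3d requests 3D coordinates.
ob_sdf <- function(smiles, ids = NULL, gen3d = FALSE) {
  if (is.null(ids)) ids <- sprintf("m%d", seq_along(smiles))
  src <- paste(paste(smiles, ids), collapse = "\n")
  opts <- if (gen3d) {
    data.frame(names = c("gen3D", "h"), args = c("", ""))
  } else {
    data.frame(names = "h", args = "")
  }
  ob_quiet(ChemmineOB::convertFormat("SMI", "SDF", source = src, options = opts))
}

# Bulk OpenBabel properties (MW, Ertl TPSA including S/P terms, formula, ...)
# for a vector of SMILES. Returns a tibble aligned with input.
ob_properties <- function(smiles) {
  ids <- sprintf("m%d", seq_along(smiles))
  src <- paste(paste(smiles, ids), collapse = "\n")
  refs <- ob_quiet(ChemmineOB::forEachMol("SMILES", src, identity, reduce = c))
  props <- ob_quiet(ChemmineOB::prop_OB(refs))
  if (nrow(props) != length(smiles)) {
    abort("OpenBabel failed to parse one or more SMILES during property calculation")
  }
  tibble(
    formula = props$formula,
    mw = props$MW,
    tpsa = props$TPSA
  )
}

# Count substructure matches of one SMARTS pattern over molecules given as a
# single multi-line SMILES source. Returns integer vector of match counts.
ob_smarts_count <- function(smiles, smarts) {
  ids <- sprintf("m%d", seq_along(smiles))
  src <- paste(paste(smiles, ids), collapse = "\n")
  refs <- ob_quiet(ChemmineOB::forEachMol("SMILES", src, identity, reduce = c))
  res <- ob_quiet(ChemmineOB::smartsSearch_OB(refs, smarts, uniqueMatches = TRUE))
  as.integer(res)
}
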
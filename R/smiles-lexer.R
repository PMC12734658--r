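# Lightweight SMILES lexer.
#
# This is *not* a SMILES parser: connectivity, ring perception and
# canonicalization are delegated to OpenBabel (via ChemmineOB). The lexer
# exists because the molecular-graph layer needs three things OpenBabel's SDF
# output does not carry: per-atom aromaticity flags (lowercase atoms), formal
# charges, and tetrahedral stereo descriptors, all in input atom order -- which
# OpenBabel preserves when converting SMILES to SDF. It also provides fast
# syntactic validation with character positions for error messages, and the
# descriptor-swap primitive used by invert_stereocenters().

ORGANIC_SUBSET <- c("Cl", "Br", "B", "C", "N", "O", "S", "P", "F", "I",
                    "b", "c", "n", "o", "s", "p")
AROMATIC_SYMBOLS <- c("b", "c", "n", "o", "s", "p", "se", "as", "si", "te")

smiles_lex_error <- function(smiles, pos, what) {
  abort(
    sprintf("SMILES parse error at position %d ('%s'): %s",
            pos, substr(smiles, pos, pos), what),
    class = "fragmatrix_parse_error"
  )
}

# Tokenize one SMILES string into its atom sequence.
# Returns a tibble with one row per atom (in written order):
#   pos (1-based char offset), symbol, aromatic, charge, stereo ("", "@", "@@"),
#   h_explicit (bracket H count, NA outside brackets)
# Validation: balanced brackets/parens, matched ring-bond digits, legal tokens.
lex_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(smiles)) {
    abort("empty SMILES string", class = "fragmatrix_parse_error")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  nchr <- length(chars)
  atoms <- vector("list", nchr)
  natom <- 0L
  i <- 1L
  depth <- 0L
  ring_open <- character()
  prev_atom <- FALSE

  push_atom <- function(pos, symbol, aromatic, charge, stereo, h_explicit) {
    natom <<- natom + 1L
    atoms[[natom]] <<- list(pos = pos, symbol = symbol, aromatic = aromatic,
                            charge = charge, stereo = stereo,
                            h_explicit = h_explicit)
    prev_atom <<- TRUE
  }

  while (i <= nchr) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= nchr && chars[j] != "]") j <- j + 1L
      if (j > nchr) smiles_lex_error(smiles, i, "unclosed bracket atom")
      body <- substr(smiles, i + 1L, j - 1L)
      at <- lex_bracket_atom(body, smiles, i)
      push_atom(i, at$symbol, at$aromatic, at$charge, at$stereo, at$h)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < nchr && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      push_atom(i, paste0(ch, chars[i + 1L]), FALSE, 0L, "", NA_integer_)
      i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET && nchar(ch) == 1L) {
      push_atom(i, ch, ch %in% AROMATIC_SYMBOLS, 0L, "", NA_integer_)
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      if (!prev_atom && natom == 0L) smiles_lex_error(smiles, i, "ring bond before any atom")
      key <- ch
      if (key %in% ring_open) ring_open <- setdiff(ring_open, key)
      else ring_open <- c(ring_open, key)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > nchr || !grepl("^[0-9]{2}$", substr(smiles, i + 1L, i + 2L))) {
        smiles_lex_error(smiles, i, "malformed %nn ring bond")
      }
      key <- substr(smiles, i, i + 2L)
      if (key %in% ring_open) ring_open <- setdiff(ring_open, key)
      else ring_open <- c(ring_open, key)
      i <- i + 3L
    } else if (ch == "(") {
      if (natom == 0L) smiles_lex_error(smiles, i, "branch before any atom")
      depth <- depth + 1L
      i <- i + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) smiles_lex_error(smiles, i, "unmatched ')'")
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\", ".", "~")) {
      i <- i + 1L
    } else {
      smiles_lex_error(smiles, i, "unexpected character")
    }
  }
  if (depth != 0L) smiles_lex_error(smiles, nchr, "unmatched '('")
  if (length(ring_open) > 0L) {
    smiles_lex_error(smiles, nchr,
                     sprintf("%d unmatched ring bond(s)", length(ring_open)))
  }
  if (natom == 0L) abort("SMILES contains no atoms", class = "fragmatrix_parse_error")
  out <- dplyr::bind_rows(lapply(atoms[seq_len(natom)], as_tibble))
  out
}

lex_bracket_atom <- function(body, smiles, pos) {
  m <- regmatches(
    body,
    regexec(paste0(
      "^([0-9]*)",                              # isotope
      "(\\*|[A-Z][a-z]?|as|se|si|te|[bcnops])", # element
      "(@TH[12]|@@|@)?",                        # tetrahedral stereo
      "(H[0-9]*)?",                             # explicit hydrogens
      "(\\+{1,3}|-{1,3}|\\+[0-9]|-[0-9])?",     # charge
      "(:[0-9]+)?$"), body)                     # atom map
  )[[1]]
  if (length(m) == 0L) {
    smiles_lex_error(smiles, pos, sprintf("malformed bracket atom '[%s]'", body))
  }
  symbol <- m[3]
  stereo <- m[4]
  if (stereo == "@TH1") stereo <- "@"
  if (stereo == "@TH2") stereo <- "@@"
  hfield <- m[5]
  h <- if (!nzchar(hfield)) 0L
       else if (hfield == "H") 1L
       else as.integer(sub("^H", "", hfield))
  chfield <- m[6]
  charge <- if (!nzchar(chfield)) 0L
            else if (grepl("^[+-][0-9]$", chfield)) {
              as.integer(substr(chfield, 2, 2)) * ifelse(substr(chfield, 1, 1) == "+", 1L, -1L)
            } else nchar(chfield) * ifelse(substr(chfield, 1, 1) == "+", 1L, -1L)
  list(symbol = symbol,
       aromatic = symbol %in% AROMATIC_SYMBOLS,
       charge = charge, stereo = stereo, h = h)
}

# Split a SMILES into dot-separated components ('.' never occurs inside
# brackets, so a plain split is grammatically safe).
smiles_components <- function(smiles) {
  strsplit(smiles, ".", fixed = TRUE)[[1]]
}

# Swap every tetrahedral descriptor @ <-> @@ (the mirror image operation on
# tetrahedral centers; cis/trans double-bond markers are left untouched, as
# reflection preserves double-bond geometry).
swap_tetrahedral_descriptors <- function(smiles) {
  s <- gsub("@@", "\001", smiles, fixed = TRUE)
  s <- gsub("@", "@@", s, fixed = TRUE)
  gsub("\001", "@", s, fixed = TRUE)
}

# number of heavy (non-H) atoms, by lexing
count_heavy_atoms <- function(smiles) {
  tok <- lex_smiles(smiles)
  sum(!(toupper(tok$symbol) == "H"))
}

# net formal charge, by lexing
net_formal_charge <- function(smiles) {
  tok <- lex_smiles(smiles)
  sum(tok$charge)
}
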
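# Design-matrix enumeration: a declarative configuration describes series of
# vicinally disubstituted saturated rings (scaffold + substitution pattern),
# each expanded over its allowed aryl group x polar head group x relative
# configuration options into a stereochemically explicit fragment library.

SCAFFOLD_NAMES <- c("pyrrolidine", "piperidine", "cyclic_sulfone_6",
                    "gem_difluorocyclohexane")
N_HETEROCYCLES <- c("pyrrolidine", "piperidine")

HEAD_SMILES <- c(
  carboxylic_acid = "C(=O)O",
  primary_amide   = "C(N)=O",
  primary_alcohol = "CO",
  nitrile         = "C#N"
)

ARYL_SMILES <- c(
  "4-methoxyphenyl" = "c2ccc(OC)cc2",
  "4-fluorophenyl"  = "c2ccc(F)cc2"
)

# Ring templates, keyed by scaffold and (head_position, aryl_position).
# Position 1 is the anchor atom (ring N, sulfone S, or the CF2 carbon) and
# positions count around the ring. Each template is the ring walk that starts
# at the head-bearing carbon, visits the aryl-bearing carbon second, and
# closes back; the two stereocentres are therefore always written adjacently
# as "[CaH]1(head)[CbH](aryl)<rest>". With that writing convention, opposite
# tetrahedral descriptors realize the cis diastereomer and equal descriptors
# the trans (verified against an independent 3D same-face oracle in the test
# suite).
RING_TEMPLATES <- list(
  "pyrrolidine|2,3"             = "CCN1",
  "piperidine|2,3"              = "CCCN1",
  "pyrrolidine|3,4"             = "CNC1",
  "piperidine|3,4"              = "CCNC1",
  "piperidine|4,3"              = "CNCC1",
  "cyclic_sulfone_6|4,3"        = "CS(=O)(=O)CC1",
  "gem_difluorocyclohexane|4,3" = "CC(F)(F)CC1"
)

#' Assemble the isomeric SMILES of a fragment design
#'
#' Builds one enantiomer of the designed racemate from scaffold template +
#' aryl group + polar head group, with tetrahedral descriptors realizing the
#' requested relative configuration. N-heterocycles carry a free ring N-H (no
#' protecting groups -- those are synthesis intermediates, not products).
#'
#' @param data data frame with columns `scaffold`, `head_position`,
#'   `aryl_position`, `relative_config` (`"cis"`/`"trans"`), `aryl`,
#'   `polar_head`.
#' @return the input tibble with a `smiles` column appended (canonical
#'   isomeric SMILES of the racemate-key-minimal enantiomer).
#' @export
build_structure <- function(data) {
  req <- c("scaffold", "head_position", "aryl_position", "relative_config",
           "aryl", "polar_head")
  stopifnot(is.data.frame(data), all(req %in% names(data)))
  smi <- vapply(seq_len(nrow(data)), function(i) {
    build_one_structure(
      scaffold = data$scaffold[i],
      head_position = data$head_position[i],
      aryl_position = data$aryl_position[i],
      relative_config = data$relative_config[i],
      aryl = data$aryl[i],
      polar_head = data$polar_head[i]
    )
  }, character(1))
  # materialize the racemate-key-minimal enantiomer of each racemic design
  out <- as_tibble(data)
  out$smiles <- racemate_key(smi)
  out
}

build_one_structure <- function(scaffold, head_position, aryl_position,
                                relative_config, aryl, polar_head) {
  key <- sprintf("%s|%d,%d", scaffold, head_position, aryl_position)
  if (abs(head_position - aryl_position) != 1L) {
    abort(sprintf(
      "aryl group must sit vicinal to the head group (got positions %d and %d)",
      head_position, aryl_position))
  }
  if (!key %in% names(RING_TEMPLATES)) {
    abort(sprintf("no ring template for scaffold '%s' with pattern %d,%d",
                  scaffold, head_position, aryl_position))
  }
  if (!polar_head %in% names(HEAD_SMILES)) {
    abort(sprintf("unknown polar head group '%s'", polar_head))
  }
  if (!aryl %in% names(ARYL_SMILES)) {
    abort(sprintf("unknown aryl group '%s'", aryl))
  }
  if (!relative_config %in% c("cis", "trans")) {
    abort(sprintf("relative_config must be 'cis' or 'trans', got '%s'",
                  relative_config))
  }
  descr <- if (relative_config == "cis") c("@", "@@") else c("@", "@")
  sprintf("[C%sH]1(%s)[C%sH](%s)%s",
          descr[1], HEAD_SMILES[[polar_head]],
          descr[2], ARYL_SMILES[[aryl]],
          RING_TEMPLATES[[key]])
}

#' Load and validate a fragment design configuration
#'
#' The configuration is a YAML document with a `series` list. Each series
#' names a scaffold, its substitution pattern (`head_position`,
#' `aryl_position`, counted from the anchor heteroatom/CF2 carbon at ring
#' position 1), the allowed `aryls`, `heads` and `configs` (relative
#' configurations), optional per-head restrictions (`head_configs`), and a
#' `fragments` list assigning IDs (and synthesis status annotations) to the
#' expanded head x config x aryl combinations, in that nesting order.
#'
#' @param path path to the YAML configuration.
#' @return validated configuration (class `design_config`).
#' @seealso [default_design_config()] for the packaged configuration.
#' @export
load_design_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: '%s'", path))
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(sprintf("config is not valid YAML: %s", conditionMessage(e)))
  })
  validate_design_config(cfg)
}

validate_design_config <- function(cfg) {
  if (is.null(cfg) || !is.list(cfg) || is.null(cfg$series) || length(cfg$series) == 0L) {
    abort("design config validation failed: no 'series' blocks found")
  }
  bad <- character()
  for (si in seq_along(cfg$series)) {
    s <- cfg$series[[si]]
    where <- sprintf("series[%d]", si)
    for (k in c("scaffold", "head_position", "aryl_position", "aryls", "heads",
                "configs", "fragments")) {
      if (is.null(s[[k]])) bad <- c(bad, sprintf("%s: missing key '%s'", where, k))
    }
    if (length(bad) > 0L) next
    if (!s$scaffold %in% SCAFFOLD_NAMES) {
      bad <- c(bad, sprintf("%s: unknown scaffold '%s'", where, s$scaffold))
    }
    if (s$head_position == s$aryl_position ||
        abs(s$head_position - s$aryl_position) != 1L) {
      bad <- c(bad, sprintf(
        "%s: aryl_position must be vicinal to head_position (got %s, %s)",
        where, s$head_position, s$aryl_position))
    }
    if (!all(unlist(s$heads) %in% names(HEAD_SMILES))) {
      bad <- c(bad, sprintf("%s: unknown entries in 'heads'", where))
    }
    if (!all(unlist(s$aryls) %in% names(ARYL_SMILES))) {
      bad <- c(bad, sprintf("%s: unknown entries in 'aryls'", where))
    }
    if (!all(unlist(s$configs) %in% c("cis", "trans"))) {
      bad <- c(bad, sprintf("%s: configs must be cis/trans", where))
    }
    n_expected <- sum(vapply(unlist(s$heads), function(h) {
      cfgs <- series_head_configs(s, h)
      length(cfgs) * length(unlist(s$aryls))
    }, numeric(1)))
    if (length(s$fragments) != n_expected) {
      bad <- c(bad, sprintf(
        "%s: %d fragment IDs for %d expanded combinations", where,
        length(s$fragments), n_expected))
    }
  }
  if (length(bad) > 0L) {
    abort(paste0("design config validation failed:\n",
                 paste("  -", bad, collapse = "\n")))
  }
  structure(cfg, class = "design_config")
}

series_head_configs <- function(series, head) {
  restrict <- series$head_configs[[head]]
  if (is.null(restrict)) unlist(series$configs) else unlist(restrict)
}

#' Path to the packaged fragment-collection design configuration
#'
#' The configuration transcribing the 51-member design matrix of the
#' heterocyclic fragment collection (seven series over pyrrolidine,
#' piperidine, six-membered cyclic sulfone and gem-difluorocyclohexane
#' scaffolds), including per-fragment synthesis status.
#'
#' @return file path of the YAML configuration shipped with the package.
#' @export
default_design_config <- function() {
  system.file("extdata", "design_config.yaml", package = "fragmatrix",
              mustWork = TRUE)
}

#' Enumerate a fragment design library from a configuration
#'
#' Expands every series over its allowed head x relative-configuration x aryl
#' options (in that nesting order, matching the configured fragment-ID
#' sequence), assembles one enantiomer SMILES per racemic design, attaches
#' synthesis status, and verifies integrity: fragment IDs unique, racemate
#' keys pairwise distinct.
#'
#' @param config a `design_config` (from [load_design_config()]) or a path to
#'   a YAML configuration.
#' @return tibble of class `design_library`: one row per design with columns
#'   `frag_id`, `scaffold`, `head_position`, `aryl_position`,
#'   `relative_config`, `aryl`, `polar_head`, `status`, `status_reason`,
#'   `smiles`, `racemate_key`.
#' @examples
#' \donttest{
#' lib <- enumerate_designs(default_design_config())
#' nrow(lib) # 51 designs
#' }
#' @export
enumerate_designs <- function(config) {
  if (is.character(config)) config <- load_design_config(config)
  stopifnot(inherits(config, "design_config"))
  rows <- list()
  for (s in config$series) {
    k <- 0L
    frag_meta <- s$fragments
    for (h in unlist(s$heads)) {
      for (rc in series_head_configs(s, h)) {
        for (ar in unlist(s$aryls)) {
          k <- k + 1L
          fm <- frag_meta[[k]]
          if (is.character(fm)) fm <- list(frag_id = fm)
          rows[[length(rows) + 1L]] <- tibble(
            frag_id = fm$frag_id,
            scaffold = s$scaffold,
            head_position = as.integer(s$head_position),
            aryl_position = as.integer(s$aryl_position),
            relative_config = rc,
            aryl = ar,
            polar_head = h,
            status = fm$status %||% "synthesized",
            status_reason = fm$status_reason %||% ""
          )
        }
      }
    }
  }
  lib <- bind_rows(rows)
  if (anyDuplicated(lib$frag_id)) {
    abort(sprintf("duplicate fragment IDs in config: %s",
                  paste(unique(lib$frag_id[duplicated(lib$frag_id)]), collapse = ", ")))
  }
  lib <- build_structure(lib)
  lib$racemate_key <- lib$smiles # built structures are racemate-key-minimal
  dup <- duplicated(lib$racemate_key)
  if (any(dup)) {
    abort(sprintf(
      "integrity error: distinct fragment IDs share a racemate key (%s)",
      paste(lib$frag_id[lib$racemate_key %in% lib$racemate_key[dup]], collapse = ", ")))
  }
  class(lib) <- c("design_library", class(lib))
  attr(lib, "metadata") <- toolkit_metadata()
  lib
}

#' Tally a design library by scaffold class and synthesis status
#'
#' @param library a `design_library` from [enumerate_designs()].
#' @return named list of tibbles: `by_scaffold`, `by_status`,
#'   `by_status_reason`, and `summary` (headline counts: total designs,
#'   synthesized, synthesized N-heterocycles, synthesized
#'   sulfone/difluorocyclohexane, commercially available).
#' @export
tally_designs <- function(library) {
  stopifnot(is.data.frame(library))
  syn <- library[library$status == "synthesized", ]
  list(
    by_scaffold = count(as_tibble(library), .data$scaffold, .data$status),
    by_status = count(as_tibble(library), .data$status),
    by_status_reason = count(as_tibble(library), .data$status, .data$status_reason),
    summary = tibble(
      n_designs = nrow(library),
      n_synthesized = nrow(syn),
      n_synthesized_n_heterocycle = sum(syn$scaffold %in% N_HETEROCYCLES),
      n_synthesized_other = sum(!syn$scaffold %in% N_HETEROCYCLES),
      n_commercial = sum(library$status == "commercial"),
      n_not_prepared = sum(library$status == "not_prepared")
    )
  )
}
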
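# File I/O for SMILES collections and result tables.

#' Read a SMILES collection from .smi or CSV
#'
#' `.smi` files are whitespace-separated `SMILES [id]` lines; CSV files must
#' carry a SMILES column (and optionally an id column). Unparseable rows are
#' never silently dropped: they are collected into a rejects report attached
#' as the `rejects` attribute and reported via a message, so that
#' library-comparison counts stay auditable.
#'
#' @param path input file.
#' @param smiles_col,id_col column names for CSV input.
#' @param strip_salts keep only the largest organic component of each entry.
#' @return tibble of parsed molecules (see [mol_parse()]); attribute `rejects`
#'   holds a tibble of failed rows (`line`, `smiles`, `reason`).
#' @export
read_smiles_table <- function(path, smiles_col = "smiles", id_col = "id",
                              strip_salts = TRUE) {
  if (!file.exists(path)) abort(sprintf("input file not found: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    raw <- readr::read_csv(path, show_col_types = FALSE)
    if (!smiles_col %in% names(raw)) {
      abort(sprintf("CSV schema error: no '%s' column in '%s'", smiles_col, path))
    }
    smi <- as.character(raw[[smiles_col]])
    ids <- if (id_col %in% names(raw)) as.character(raw[[id_col]])
           else sprintf("mol%d", seq_along(smi))
  } else {
    lines <- readr::read_lines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "[[:space:]]+")
    smi <- vapply(parts, `[`, character(1), 1)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("mol%d", i)
    }, character(1))
  }
  if (length(smi) == 0L) abort(sprintf("no rows in '%s'", path))

  parsed <- vector("list", length(smi))
  rejects <- list()
  for (i in seq_along(smi)) {
    res <- tryCatch(
      parse_one_structure(smi[i], strip_salts = strip_salts),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      rejects[[length(rejects) + 1L]] <- tibble(
        line = i, id = ids[i], smiles = smi[i], reason = conditionMessage(res))
    } else {
      parsed[[i]] <- tibble(id = ids[i], smiles_input = smi[i], smiles = res)
    }
  }
  ok <- bind_rows(parsed)
  rej <- if (length(rejects)) bind_rows(rejects)
         else tibble(line = integer(), id = character(),
                     smiles = character(), reason = character())
  if (nrow(rej) > 0) {
    message(sprintf("read_smiles_table: %d of %d rows rejected (see attr(x, 'rejects'))",
                    nrow(rej), length(smi)))
  }
  if (nrow(ok) == 0L) abort(sprintf("no parseable rows in '%s'", path))
  ok$n_heavy_atoms <- vapply(ok$smiles, count_heavy_atoms, integer(1), USE.NAMES = FALSE)
  attr(ok, "rejects") <- rej
  ok
}

#' Write a molecule table to .smi or CSV
#'
#' Round-trips losslessly with [read_smiles_table()] for the `id` and `smiles`
#' fields (.smi) or all fields (CSV).
#'
#' @param data molecule/design table with at least `smiles` (and ideally `id`).
#' @param path output path; format chosen by extension (`.smi` or `.csv`).
#' @return invisibly, `path`.
#' @export
write_smiles_table <- function(data, path) {
  stopifnot(is.data.frame(data), "smiles" %in% names(data))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    readr::write_csv(as_tibble(data), path)
  } else {
    ids <- if ("id" %in% names(data)) data$id
           else if ("frag_id" %in% names(data)) data$frag_id
           else sprintf("mol%d", seq_len(nrow(data)))
    readr::write_lines(paste(data$smiles, ids), path)
  }
  invisible(path)
}
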
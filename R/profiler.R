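# Racemate-aware library profiling against Rule-of-3 limits.

PROPERTY_NAMES <- c("mw", "clogp", "hbd", "hba", "tpsa", "rotb")

#' Racemate-aware descriptor calculation
#'
#' SMILES typically encode absolute stereochemistry, but libraries screened as
#' racemates should be profiled as racemates. This function computes the six
#' descriptors for each molecule *and* for its mirror image (all defined
#' stereocentres inverted) and returns the arithmetic mean of the two. All six
#' descriptors are constitutional, so the mean equals the single-enantiomer
#' value exactly -- the equality is asserted at run time as a self-check, and
#' a violation (which would indicate a chirality-sensitive descriptor leaking
#' in) is an error.
#'
#' @inheritParams compute_properties
#' @return tibble as [compute_properties()].
#' @export
racemate_properties <- function(data, smiles = "smiles",
                                hba_rule = c("pattern", "n_o_count")) {
  hba_rule <- match.arg(hba_rule)
  props <- compute_properties(data, smiles = smiles, hba_rule = hba_rule)
  mirror <- data
  mirror[[smiles]] <- invert_stereocenters(as.character(data[[smiles]]))
  props_inv <- compute_properties(mirror, smiles = smiles, hba_rule = hba_rule)
  for (p in PROPERTY_NAMES) {
    if (!isTRUE(all.equal(props[[p]], props_inv[[p]], tolerance = 1e-12))) {
      abort(sprintf(
        "racemate self-check failed: descriptor '%s' differs between enantiomers", p))
    }
    props[[p]] <- (props[[p]] + props_inv[[p]]) / 2
  }
  props
}

#' Library-level descriptor statistics
#'
#' Per-property mean, standard deviation (sample convention, n - 1), minimum
#' and maximum over the racemate-aware descriptors of a molecule table.
#'
#' @param data data frame of molecules, or a table that already carries the
#'   six descriptor columns (in which case they are used as-is).
#' @inheritParams compute_properties
#' @return tibble with one row per property: `property`, `mean`, `sd`, `min`,
#'   `max`, `n`; attribute `sd_defined` is `FALSE` when n = 1 (sd reported
#'   as 0 in that case).
#' @export
library_statistics <- function(data, smiles = "smiles",
                               hba_rule = c("pattern", "n_o_count")) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) abort("cannot compute library statistics of an empty set")
  hba_rule <- match.arg(hba_rule)
  props <- if (all(PROPERTY_NAMES %in% names(data))) as_tibble(data)
           else racemate_properties(data, smiles = smiles, hba_rule = hba_rule)
  n <- nrow(props)
  out <- purrr::map_dfr(PROPERTY_NAMES, function(p) {
    v <- props[[p]]
    tibble(property = p,
           mean = mean(v),
           sd = if (n > 1L) stats::sd(v) else 0,
           min = min(v), max = max(v), n = n)
  })
  attr(out, "sd_defined") <- n > 1L
  out
}

#' Rule-of-3 limits
#'
#' The fragment-likeness limits the profiler normalizes against: MW < 300
#' g/mol, cLogP < 3, HBD < 3, HBA < 3, plus the customary extensions
#' TPSA <= 60 Angstrom^2 and rotatable bonds <= 3 so that all six radar axes
#' have a reference value.
#'
#' @param mw,clogp,hbd,hba,tpsa,rotb individual limits, overridable.
#' @return named numeric vector of per-property limits.
#' @export
ro3_limits <- function(mw = 300, clogp = 3, hbd = 3, hba = 3, tpsa = 60, rotb = 3) {
  lims <- c(mw = mw, clogp = clogp, hbd = hbd, hba = hba, tpsa = tpsa, rotb = rotb)
  if (any(lims <= 0)) abort("Rule-of-3 limits must all be positive")
  lims
}

#' Normalized Rule-of-3 library profile
#'
#' Divides each property's library mean by its Rule-of-3 limit, yielding the
#' dimensionless profile drawn on a radar plot against the unit reference
#' polygon (the Ro3 boundary). Per-molecule compliance flags use the strict
#' inequality of the Ro3 definition (value < limit); values exactly at a limit
#' are therefore non-compliant and reported distinctly.
#'
#' @param data per-molecule property table (from [compute_properties()] or
#'   [racemate_properties()]), or a raw molecule table (descriptors are then
#'   computed racemate-aware).
#' @param limits named limits vector from [ro3_limits()].
#' @inheritParams compute_properties
#' @return an object of class `ro3_profile`: list with `profile` (per-property
#'   normalized mean and unit reference), `stats` (library statistics),
#'   `compliance` (per-molecule logical flags per property, plus `all_six`),
#'   `compliant_fraction`, `limits`, `metadata`.
#' @export
ro3_profile <- function(data, limits = ro3_limits(), smiles = "smiles",
                        hba_rule = c("pattern", "n_o_count")) {
  hba_rule <- match.arg(hba_rule)
  stopifnot(all(PROPERTY_NAMES %in% names(limits)))
  props <- if (all(PROPERTY_NAMES %in% names(data))) as_tibble(data)
           else racemate_properties(data, smiles = smiles, hba_rule = hba_rule)
  stats <- library_statistics(props)
  profile <- stats |>
    mutate(limit = unname(limits[.data$property]),
           normalized_mean = .data$mean / .data$limit,
           reference = 1) |>
    select("property", "mean", "limit", "normalized_mean", "reference")
  comp <- purrr::map_dfc(PROPERTY_NAMES, function(p) {
    tibble("{p}" := props[[p]] < limits[[p]])
  })
  at_limit <- purrr::map_dfc(PROPERTY_NAMES, function(p) {
    tibble("{p}_at_limit" := props[[p]] == limits[[p]])
  })
  comp$all_six <- rowSums(as.matrix(comp[PROPERTY_NAMES])) == length(PROPERTY_NAMES)
  if ("id" %in% names(props)) comp <- bind_cols(props["id"], comp, at_limit)
  else comp <- bind_cols(comp, at_limit)
  structure(
    list(profile = profile,
         stats = stats,
         compliance = comp,
         compliant_fraction = mean(comp$all_six),
         limits = limits,
         metadata = toolkit_metadata()),
    class = "ro3_profile"
  )
}

#' @export
print.ro3_profile <- function(x, ...) {
  cat(sprintf("Rule-of-3 library profile (n = %d molecules)\n",
              x$stats$n[1]))
  print(x$profile)
  cat(sprintf("Fraction compliant on all six properties (strict '<'): %.3f\n",
              x$compliant_fraction))
  invisible(x)
}

#' @rdname ro3_profile
#' @param x an `ro3_profile` object.
#' @param ... unused.
#' @method tidy ro3_profile
#' @export
tidy.ro3_profile <- function(x, ...) x$profile

#' @rdname ro3_profile
#' @method glance ro3_profile
#' @export
glance.ro3_profile <- function(x, ...) {
  tibble(
    n_molecules = x$stats$n[1],
    compliant_fraction = x$compliant_fraction,
    max_normalized_mean = max(x$profile$normalized_mean),
    within_reference = all(x$profile$normalized_mean < 1)
  )
}

#' Radar plot of a normalized Rule-of-3 profile
#'
#' Six-axis radar chart: the library polygon (normalized means) against the
#' unit Rule-of-3 reference polygon.
#'
#' @param object an `ro3_profile`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ro3_profile
#' @export
autoplot.ro3_profile <- function(object, ...) {
  prof <- object$profile
  labs <- c(mw = "MW", clogp = "cLogP", hbd = "HBD",
            hba = "HBA", tpsa = "TPSA", rotb = "RotB")
  df <- tidyr::pivot_longer(prof[, c("property", "normalized_mean", "reference")],
                            cols = c("normalized_mean", "reference"),
                            names_to = "series", values_to = "value")
  df$property <- factor(labs[df$property], levels = labs[PROPERTY_NAMES])
  df$series <- factor(df$series, levels = c("reference", "normalized_mean"),
                      labels = c("Ro3 limit", "library mean"))
  closed <- bind_rows(df, df[df$property == labs[[1]], ])
  ggplot2::ggplot(closed,
                  ggplot2::aes(x = .data$property, y = .data$value,
                               group = .data$series, colour = .data$series,
                               fill = .data$series)) +
    ggplot2::geom_polygon(alpha = 0.15, linewidth = 0.8) +
    ggplot2::coord_polar() +
    ggplot2::scale_y_continuous(limits = c(0, max(1.05, max(df$value)))) +
    ggplot2::labs(x = NULL, y = "mean / Ro3 limit", colour = NULL, fill = NULL,
                  title = "Library physicochemical profile vs Rule-of-3") +
    ggplot2::theme_minimal()
}

#' Write a radar profile to image and CSV
#'
#' Renders the radar chart and writes the underlying normalized numbers next
#' to it, so the figure is reproducible from its own output.
#'
#' @param profile an `ro3_profile`.
#' @param path output image path (`.png` or `.svg`); a CSV with the same stem
#'   is written alongside.
#' @param width,height device size in inches.
#' @return invisibly, the paths written.
#' @export
radar_render <- function(profile, path, width = 6, height = 5) {
  stopifnot(inherits(profile, "ro3_profile"))
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("directory does not exist: '%s'", dir))
  p <- autoplot(profile)
  ggplot2::ggsave(path, p, width = width, height = height)
  csv <- sub("\\.[A-Za-z]+$", ".csv", path)
  readr::write_csv(profile$profile, csv)
  invisible(c(image = path, csv = csv))
}
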
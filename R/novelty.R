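# Chemical-space novelty analysis: motif-based extraction of comparator
# fragments, Tanimoto nearest-neighbour statistics, seeded 2D embedding and
# silhouette separation diagnostics.

#' SMARTS queries for the four central ring motifs
#'
#' Substructure patterns for the central saturated ring systems of the
#' collection: pyrrolidine, piperidine, six-membered cyclic sulfone
#' (1,1-dioxothiane) and gem-difluorocyclohexane. Each pattern requires the
#' fully saturated carbon frame of its parent ring, so each matches its own
#' parent scaffold and none of the other three.
#'
#' @return named character vector of SMARTS.
#' @export
scaffold_queries <- function() {
  c(
    pyrrolidine = "[NX3;!$(N=*)]1[CX4][CX4][CX4][CX4]1",
    piperidine = "[NX3;!$(N=*)]1[CX4][CX4][CX4][CX4][CX4]1",
    cyclic_sulfone_6 = "[SX4]1(=O)(=O)[CX4][CX4][CX4][CX4][CX4]1",
    gem_difluorocyclohexane = "[CX4]1(F)(F)[CX4][CX4][CX4][CX4][CX4]1"
  )
}

#' Filter a library by central ring motifs
#'
#' Annotates each molecule with the set of central motifs it contains and
#' keeps those matching at least one (the extraction step applied to
#' commercial comparator collections). Order is preserved. Additional
#' filtering criteria (size caps, element filters) are deliberately not
#' applied here; compose them explicitly with dplyr verbs.
#'
#' @param data molecule table with a SMILES column.
#' @param queries named SMARTS vector; validated against the four parent
#'   scaffolds at load time via [scaffold_queries()] defaults.
#' @param smiles SMILES column name.
#' @param keep_all keep non-matching molecules too (flags only).
#' @return tibble with logical `matches_<motif>` columns and a `motifs`
#'   summary column; rows restricted to matches unless `keep_all`.
#' @export
scaffold_filter <- function(data, queries = scaffold_queries(),
                            smiles = "smiles", keep_all = FALSE) {
  stopifnot(is.data.frame(data), smiles %in% names(data))
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    abort("scaffold queries must be a named SMARTS vector")
  }
  smi <- canonical_smiles(as.character(data[[smiles]]))
  out <- as_tibble(data)
  flags <- matrix(FALSE, nrow = length(smi), ncol = length(queries),
                  dimnames = list(NULL, names(queries)))
  for (q in names(queries)) {
    counts <- tryCatch(
      ob_smarts_count(smi, queries[[q]]),
      error = function(e) abort(sprintf("invalid SMARTS for motif '%s': %s",
                                        q, conditionMessage(e)))
    )
    flags[, q] <- counts > 0L
  }
  for (q in names(queries)) out[[paste0("matches_", q)]] <- flags[, q]
  out$motifs <- apply(flags, 1, function(r) paste(names(queries)[r], collapse = ";"))
  if (!keep_all) out <- out[rowSums(flags) > 0L, , drop = FALSE]
  out
}

#' Seeded 2D embedding of fingerprints
#'
#' Projects a fingerprint matrix to the plane for chemical-space maps.
#' `method = "umap"` runs UMAP on the pairwise Jaccard distances of the bit
#' vectors (single-threaded, seeded; coordinates are reproducible for a fixed
#' seed and parameter set, up to the documented rotation/reflection freedom of
#' the method). `method = "pca"` is the deterministic fallback used by the
#' test suite: principal components of the centred bit matrix with a fixed
#' sign convention, bit-reproducible across runs.
#'
#' @param fps fingerprint matrix (rows = molecules, rownames = ids).
#' @param method `"umap"` or `"pca"`.
#' @param seed integer random seed (recorded in the result).
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @return object of class `chem_embedding`: tibble `coords` (`id`, `x`, `y`)
#'   plus `method`, `metric`, `seed`, `params`, `metadata`.
#' @export
embed_2d <- function(fps, method = c("umap", "pca"), seed = 42L,
                     n_neighbors = 15L, min_dist = 0.1) {
  method <- match.arg(method)
  if (is.null(dim(fps))) abort("fps must be a fingerprint matrix")
  n <- nrow(fps)
  ids <- rownames(fps) %||% sprintf("m%d", seq_len(n))
  if (method == "pca" && n < 3L) {
    abort("pca embedding needs at least 3 fingerprints")
  }
  if (method == "umap" && n < n_neighbors + 1L) {
    abort(sprintf("umap embedding needs at least n_neighbors + 1 = %d fingerprints",
                  n_neighbors + 1L))
  }
  if (method == "pca") {
    pc <- prcomp(fps, center = TRUE, scale. = FALSE, rank. = 2)
    xy <- pc$x[, 1:2, drop = FALSE]
    if (ncol(xy) < 2) xy <- cbind(xy, 0)
    # fix sign: largest-magnitude loading of each component positive
    for (j in 1:2) {
      ld <- pc$rotation[, j]
      if (length(ld) > 0 && ld[which.max(abs(ld))] < 0) xy[, j] <- -xy[, j]
    }
    metric <- "euclidean (centred bits)"
  } else {
    d <- dist(fps, method = "binary") # Jaccard distance on bit vectors
    set.seed(seed)
    xy <- uwot::umap(d, n_neighbors = n_neighbors, min_dist = min_dist,
                     n_threads = 1, n_sgd_threads = 1, batch = TRUE)
    metric <- "jaccard (precomputed)"
  }
  structure(
    list(
      coords = tibble(id = ids, x = as.numeric(xy[, 1]), y = as.numeric(xy[, 2])),
      method = method,
      metric = metric,
      seed = seed,
      params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                    radius = attr(fps, "radius"),
                    n_bits = ncol(fps)),
      metadata = toolkit_metadata()
    ),
    class = "chem_embedding"
  )
}

#' @export
print.chem_embedding <- function(x, ...) {
  cat(sprintf("2D chemical-space embedding: %d molecules, method = %s, metric = %s, seed = %d\n",
              nrow(x$coords), x$method, x$metric, x$seed))
  print(head(x$coords))
  invisible(x)
}

#' @rdname embed_2d
#' @param x a `chem_embedding`.
#' @param ... unused.
#' @method tidy chem_embedding
#' @export
tidy.chem_embedding <- function(x, ...) x$coords

#' @rdname embed_2d
#' @method glance chem_embedding
#' @export
glance.chem_embedding <- function(x, ...) {
  tibble(n = nrow(x$coords), method = x$method, metric = x$metric, seed = x$seed)
}

#' Silhouette-based separation score of a labelled embedding
#'
#' Mean silhouette coefficient over all points (Euclidean distance in the
#' plane): positive when groups occupy distinct regions, near zero for
#' arbitrary labellings, negative when a group sits inside another.
#'
#' @param embedding a `chem_embedding` or a data frame with `x`, `y`.
#' @param labels grouping vector, one value per point; at least two groups
#'   with at least two members each.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
separation_score <- function(embedding, labels) {
  coords <- if (inherits(embedding, "chem_embedding")) embedding$coords else embedding
  stopifnot(all(c("x", "y") %in% names(coords)))
  labels <- as.factor(labels)
  if (length(labels) != nrow(coords)) abort("one label per embedded point required")
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L)) {
    abort("degenerate labelling: need >= 2 groups with >= 2 members each")
  }
  d <- dist(as.matrix(coords[, c("x", "y")]))
  sil <- cluster::silhouette(as.integer(labels), d)
  mean(sil[, "sil_width"])
}

#' Scatter plot of a labelled chemical-space embedding
#'
#' @param object a `chem_embedding`.
#' @param labels optional grouping vector; groups are coloured, and the group
#'   named by `highlight` is overplotted as crosses (the query set).
#' @param highlight label value to overplot as crosses.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot chem_embedding
#' @export
autoplot.chem_embedding <- function(object, labels = NULL, highlight = NULL, ...) {
  df <- object$coords
  if (!is.null(labels)) df$group <- as.factor(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (is.null(labels)) {
    p <- p + ggplot2::geom_point(alpha = 0.6, size = 1)
  } else {
    base <- df[is.null(highlight) | df$group != highlight, ]
    p <- p + ggplot2::geom_point(data = base,
                                 ggplot2::aes(colour = .data$group),
                                 alpha = 0.6, size = 1)
    if (!is.null(highlight) && any(df$group == highlight)) {
      p <- p + ggplot2::geom_point(data = df[df$group == highlight, ],
                                   ggplot2::aes(colour = .data$group),
                                   shape = 4, size = 2.4, stroke = 1)
    }
  }
  p + ggplot2::labs(x = sprintf("%s 1", toupper(object$method)),
                    y = sprintf("%s 2", toupper(object$method)),
                    colour = NULL,
                    title = "Chemical-space embedding of Morgan fingerprints") +
    ggplot2::theme_minimal()
}
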
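# The pipeline driver: one call from a set of structures to the fitted
# structure-based distance tree, mirroring how the analysis is run on
# real polymerase datasets -- align everything, extract the common
# core, score the core, fit the tree, root at the outgroup.

#' Structure-based phylogeny from a common structural core
#'
#' Runs the full analysis on a set of C-alpha traces: progressive
#' sequence-order-independent alignment into a guide clustering,
#' extraction of the common structural core (the residues equivalent in
#' every structure), core-restricted pairwise scores converted to
#' distances `D(A,B) = -(S(A,B) - min[S(A,A), S(B,B)])`, and a
#' Fitch-Margoliash least-squares tree, optionally rooted at the
#' midpoint of the outgroup's terminal edge.
#'
#' @param models list of [structure_model] objects (unique ids).
#' @param params an [align_params()] object.
#' @param outgroup optional leaf id used to root the tree.
#' @param exhaustive_max passed to [fitch_margoliash()].
#' @return an object of class `structure_phylo` with components `guide`
#'   (root guide node), `core` (`core_set`), `dist` (distance matrix),
#'   `tree` (unrooted `fm_tree`), `rooted_tree` (if an outgroup was
#'   given), `params` and `outgroup`.
#' @export
structure_phylo <- function(models, params = align_params(), outgroup = NULL,
                            exhaustive_max = 8) {
  ids <- vapply(models, `[[`, character(1), "id")
  names(models) <- ids
  if (!is.null(outgroup) && !outgroup %in% ids)
    stop("outgroup '", outgroup, "' is not among the structure ids")
  guide <- build_guide_clustering(models, params)
  core <- extract_core(guide, models)
  d <- core_distance_matrix(models, core, params)
  tree <- fitch_margoliash(d, exhaustive_max = exhaustive_max)
  rooted <- if (!is.null(outgroup)) root_at_outgroup(tree, outgroup) else NULL
  structure(list(models = models, guide = guide, core = core, dist = d,
                 tree = tree, rooted_tree = rooted, params = params,
                 outgroup = outgroup, call = match.call()),
            class = "structure_phylo")
}

#' @export
print.structure_phylo <- function(x, ...) {
  cat(sprintf("Structure-based phylogeny of %d structures\n",
              length(x$models)))
  cat(sprintf("  common core: %d columns, average rmsd %.2f A\n",
              x$core$size, x$core$avg_rmsd))
  cat(sprintf("  Fitch-Margoliash fit residual: %.4g%s\n",
              attr(x$tree, "fit_residual"),
              if (!is.null(x$outgroup))
                sprintf("; rooted at outgroup '%s'", x$outgroup) else ""))
  invisible(x)
}

#' @export
summary.structure_phylo <- function(object, k = 2, ...) {
  sub <- subcore_report(object$guide, k = k, models = object$models)
  out <- list(n_structures = length(object$models),
              core_size = object$core$size,
              core_avg_rmsd = object$core$avg_rmsd,
              subcores = sub,
              fit_residual = attr(object$tree, "fit_residual"),
              dist_range = range(object$dist[upper.tri(object$dist)]),
              outgroup = object$outgroup)
  class(out) <- "summary.structure_phylo"
  out
}

#' @export
print.summary.structure_phylo <- function(x, ...) {
  cat(sprintf("Structures: %d; core %d columns (avg rmsd %.2f A)\n",
              x$n_structures, x$core_size, x$core_avg_rmsd))
  cat(sprintf("Distances: %.2f-%.2f; FM residual %.4g\n",
              x$dist_range[1], x$dist_range[2], x$fit_residual))
  cat("Subcores (last merges first):\n")
  print(x$subcores, row.names = FALSE)
  invisible(x)
}

#' @export
plot.structure_phylo <- function(x, rooted = !is.null(x$rooted_tree), ...) {
  tr <- if (rooted && !is.null(x$rooted_tree)) x$rooted_tree else x$tree
  ape::plot.phylo(structure(tr, class = "phylo"), ...)
  invisible(x)
}

#' Extract the fitted tree
#'
#' @param x a `structure_phylo` object.
#' @param rooted return the outgroup-rooted tree when available.
#' @param ... ignored.
#' @return a `phylo` tree.
#' @export
as.phylo.structure_phylo <- function(x, rooted = !is.null(x$rooted_tree), ...) {
  tr <- if (rooted && !is.null(x$rooted_tree)) x$rooted_tree else x$tree
  structure(tr, class = "phylo")
}
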
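# Structure-level jackknife: replicate datasets with one structure
# removed, full core + tree recomputation per replicate,
# Robinson-Foulds comparison against the full-data tree, and
# majority-rule consensus over the replicate trees.

#' Random removal order for jackknife replicates
#'
#' Draws one identifier per replicate: without replacement until the set
#' is exhausted, then with replacement for any remaining replicates.
#' Deterministic given the seed; the caller's RNG state is untouched.
#'
#' @param ids identifiers to draw from.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return character vector of length `n_reps`.
#' @export
pick_removals <- function(ids, n_reps, seed) {
  stopifnot(length(ids) >= 1, n_reps >= 1)
  with_local_seed(seed, {
    if (n_reps <= length(ids)) sample(ids, n_reps)
    else c(sample(ids),
           sample(ids, n_reps - length(ids), replace = TRUE))
  })
}

my_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  class(tree) <- "phylo"
  n <- ape::Ntip(tree)
  labels <- tree$tip.label
  ref <- sort(labels)[1]
  below <- edge_below_matrix(tree)
  internal <- which(tree$edge[, 2] > n)
  keys <- character(0)
  for (e in internal) {
    side <- labels[below[tree$edge[e, 2], ]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(labels, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance
#'
#' Symmetric difference of the non-trivial bipartition sets of two
#' unrooted topologies. Trees are pruned to their shared leaf set first;
#' an empty or too-small shared set is an error. Internal edges of
#' (numerically) zero length carry no topological signal -- they arise
#' between structurally identical inputs -- and are collapsed before
#' comparison when branch lengths are present. Zero exactly when the
#' unrooted topologies agree.
#'
#' @param t1,t2 `phylo` trees.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4)
    stop("trees share fewer than 4 leaves; Robinson-Foulds undefined")
  prep <- function(t) {
    p <- ape::keep.tip(structure(t, class = "phylo"), shared)
    if (!is.null(p$edge.length)) p <- ape::di2multi(p, tol = 1e-8)
    p
  }
  b1 <- my_bipartitions(prep(t1))
  b2 <- my_bipartitions(prep(t2))
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# clades of a tree relative to a reference leaf: for every non-trivial
# split, the label set of the side not containing `ref`
ref_clades <- function(tree, ref) {
  tree <- ape::unroot(structure(tree, class = "phylo"))
  n <- ape::Ntip(tree)
  labels <- tree$tip.label
  below <- edge_below_matrix(tree)
  internal <- which(tree$edge[, 2] > n)
  out <- list()
  for (e in internal) {
    side <- labels[below[tree$edge[e, 2], ]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(labels, side)
    out[[paste(sort(side), collapse = "|")]] <- sort(side)
  }
  out
}

clades_compatible <- function(c1, c2) {
  i <- length(intersect(c1, c2))
  i == 0 || i == length(c1) || i == length(c2)
}

#' Majority-rule consensus tree
#'
#' Consensus over the union of the trees' leaf sets. Trees may have
#' (moderately) unequal leaf sets, as jackknife replicate trees do: a
#' tree supports a candidate clade when the clade restricted to the
#' tree's leaves is one of the tree's clades (or becomes trivial).
#' Clades supported in more than `threshold` of the trees are retained,
#' screened greedily for pairwise compatibility (in decreasing support),
#' and assembled into the consensus topology; supports are stored as
#' internal node labels. With equal leaf sets this reduces to the
#' classic majority rule, where retained bipartitions are compatible by
#' construction at `threshold >= 0.5`.
#'
#' @param trees list of `phylo` trees (or a `multiPhylo`).
#' @param threshold majority fraction in `[0.5, 1)`.
#' @return unrooted consensus `phylo` over the union leaf set, with
#'   node-label supports.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(length(trees) >= 1, threshold >= 0.5, threshold < 1)
  leafsets <- lapply(trees, `[[`, "tip.label")
  labs <- sort(Reduce(union, leafsets))
  common <- Reduce(intersect, leafsets)
  if (length(labs) < 4)
    stop("union leaf set of the trees has fewer than 4 leaves")
  if (length(common) < 1)
    stop("trees share no leaves; consensus undefined")
  ref <- sort(common)[1]
  tree_clades <- lapply(trees, ref_clades, ref = ref)
  # candidates: every clade observed in any tree, plus its extensions by
  # the leaves missing from that tree (a clade seen in a replicate that
  # lacks leaf y may correspond to a union-set clade containing y)
  cand <- list()
  for (t in seq_along(trees)) {
    miss <- setdiff(labs, leafsets[[t]])
    for (k in names(tree_clades[[t]])) {
      C <- tree_clades[[t]][[k]]
      exts <- list(C)
      if (length(miss) >= 1 && length(miss) <= 3) {
        for (sz in seq_along(miss)) {
          sub <- combn(miss, sz, simplify = FALSE)
          exts <- c(exts, lapply(sub, function(S) sort(c(C, S))))
        }
      }
      for (E in exts) cand[[paste(E, collapse = "|")]] <- E
    }
  }
  support <- vapply(names(cand), function(k) {
    C <- cand[[k]]
    mean(vapply(seq_along(trees), function(t) {
      r <- intersect(C, leafsets[[t]])
      # trivial after restriction: nothing to contradict
      if (length(r) < 2 || length(leafsets[[t]]) - length(r) < 2) return(TRUE)
      key <- paste(sort(r), collapse = "|")
      key %in% names(tree_clades[[t]])
    }, logical(1)))
  }, numeric(1))
  keep <- which(support > threshold)
  ord <- keep[order(-support[keep],
                    -vapply(cand[keep], length, integer(1)),
                    names(cand)[keep])]
  clades <- list(); csupport <- numeric(0)
  for (i in ord) {
    if (all(vapply(clades, clades_compatible, logical(1), c2 = cand[[i]]))) {
      clades[[length(clades) + 1]] <- cand[[i]]
      csupport <- c(csupport, support[i])
    }
  }
  o2 <- order(vapply(clades, length, integer(1)), decreasing = TRUE)
  clades <- clades[o2]; csupport <- csupport[o2]
  # recursive construction: children of a clade are its maximal sub-clades
  newick_of <- function(members, idx) {
    child_idx <- idx[vapply(idx, function(j)
      all(clades[[j]] %in% members) && length(clades[[j]]) < length(members),
      logical(1))]
    maximal <- child_idx[vapply(child_idx, function(j)
      !any(vapply(child_idx, function(k)
        k != j && all(clades[[j]] %in% clades[[k]]), logical(1))),
      logical(1))]
    covered <- unlist(clades[maximal])
    parts <- c(vapply(maximal, function(j)
      paste0(newick_of(clades[[j]], setdiff(child_idx, j)),
             format(csupport[j], digits = 7)), character(1)),
      setdiff(members, covered))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(newick_of(labs, seq_along(clades)), ";")
  cons <- ape::read.tree(text = txt)
  ape::unroot(cons)
}

#' Run a jackknife stability analysis
#'
#' For each replicate one structure (never the outgroup, which anchors
#' rooting) is removed, the whole pipeline is rerun on the reduced set
#' (guide clustering, core extraction, core distances,
#' Fitch-Margoliash tree) and the replicate tree is compared by
#' Robinson-Foulds distance to the full-data reference pruned of the
#' removed structure. With `per_family = TRUE` one random structure is
#' removed from every family simultaneously instead.
#'
#' @param models list of [structure_model] objects.
#' @param params an [align_params()] object.
#' @param n_reps number of replicates.
#' @param seed integer seed for the removal draws.
#' @param outgroup optional leaf excluded from removal.
#' @param per_family remove one structure per `family_label` per
#'   replicate.
#' @param reference optional full-data reference tree (computed if
#'   missing).
#' @return object of class `jackknife_result`: a summary data frame, the
#'   replicate trees, and the reference tree.
#' @export
run_jackknife <- function(models, params = align_params(), n_reps = 20,
                          seed = 1, outgroup = NULL, per_family = FALSE,
                          reference = NULL) {
  ids <- vapply(models, `[[`, character(1), "id")
  names(models) <- ids
  stopifnot(length(models) >= 4)
  removable <- setdiff(ids, outgroup)
  if (is.null(reference)) {
    root <- build_guide_clustering(models, params)
    core <- extract_core(root)
    reference <- fitch_margoliash(core_distance_matrix(models, core, params))
  }
  removal_sets <- if (per_family) {
    fams <- vapply(models, function(m)
      if (is.null(m$family_label)) m$id else m$family_label, character(1))
    lapply(seq_len(n_reps), function(r) {
      unlist(lapply(split(setdiff(ids, outgroup), fams[setdiff(ids, outgroup)]),
                    function(f) pick_removals(f, 1, seed + r)))
    })
  } else {
    as.list(pick_removals(removable, n_reps, seed))
  }
  reps <- list()
  for (r in seq_along(removal_sets)) {
    removed <- removal_sets[[r]]
    sub <- models[setdiff(ids, removed)]
    rep_res <- tryCatch({
      root <- build_guide_clustering(sub, params)
      core <- extract_core(root)
      tree <- fitch_margoliash(core_distance_matrix(sub, core, params))
      list(replicate = r, removed_id = paste(removed, collapse = ","),
           core_size = core$size, avg_rmsd = core$avg_rmsd, tree = tree,
           rf_to_reference = rf_distance(tree, reference))
    }, error = function(e) {
      warning("replicate ", r, " (removed ", paste(removed, collapse = ","),
              ") skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(rep_res)) reps[[length(reps) + 1]] <- rep_res
  }
  summary <- do.call(rbind, lapply(reps, function(x)
    data.frame(replicate = x$replicate, removed_id = x$removed_id,
               core_size = x$core_size, avg_rmsd = x$avg_rmsd,
               rf = x$rf_to_reference)))
  structure(list(summary = summary,
                 trees = lapply(reps, `[[`, "tree"),
                 reference = reference, seed = seed),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("Jackknife: %d replicates\n", nrow(x$summary)))
  cat(sprintf("  core size %d-%d (reference leaves %d), rmsd %.2f-%.2f A, RF 0 in %d/%d\n",
              min(x$summary$core_size), max(x$summary$core_size),
              ape::Ntip(x$reference), min(x$summary$avg_rmsd),
              max(x$summary$avg_rmsd), sum(x$summary$rf == 0),
              nrow(x$summary)))
  invisible(x)
}
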
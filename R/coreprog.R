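# Progressive aggregation of pairwise alignments into a hierarchical
# clustering. Leaves are the input structures; at every merge the two
# most similar live groups are aligned through their consensus
# pseudo-structures, matched columns become the merged node's subcore,
# and the root's columns are the common structural core: the residues
# structurally equivalent across every structure in the dataset.
# Subcores at internal nodes can only be larger than the root core.

new_guide_leaf <- function(model) {
  n <- nrow(model$ca)
  cols <- matrix(seq_len(n), ncol = 1, dimnames = list(NULL, model$id))
  structure(list(node_id = model$id, children = NULL,
                 member_ids = model$id, columns = cols,
                 consensus = model, spread = rep(0, n),
                 transforms = setNames(list(list(R = diag(3), t = c(0, 0, 0))),
                                       model$id),
                 merge_score = NA_real_, merge_order = 0L),
            class = "guide_node")
}

majority_or <- function(x, tie_value) {
  tb <- sort(table(x), decreasing = TRUE)
  if (length(tb) > 1 && tb[1] == tb[2]) tie_value else names(tb)[1]
}

#' Consensus pseudo-structure of a guide node
#'
#' One pseudo-residue per column, at the mean of the member coordinates
#' after superposition into the node frame; amino acid and secondary
#' structure are the most frequent member states (ties give `X` / `C`).
#'
#' @param node a `guide_node`.
#' @return a [structure_model] usable in further alignments.
#' @export
consensus_model <- function(node) {
  stopifnot(inherits(node, "guide_node"))
  node$consensus
}

build_consensus <- function(node_id, columns, transforms, models) {
  nc <- nrow(columns)
  ids <- colnames(columns)
  coords <- array(NA_real_, c(nc, 3, length(ids)))
  aam <- ssm <- matrix(NA_character_, nc, length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    tr <- transforms[[id]]
    m <- models[[id]]
    idx <- columns[, k]
    coords[, , k] <- apply_rigid(m$ca[idx, , drop = FALSE], tr$R, tr$t)
    aam[, k] <- m$aa[idx]
    ssm[, k] <- m$ss[idx]
  }
  cons_ca <- apply(coords, c(1, 2), mean)
  spread <- sqrt(rowMeans(apply(coords, 3, function(x)
    rowSums((x - cons_ca)^2))))
  aa <- apply(aam, 1, majority_or, tie_value = "X")
  ss <- apply(ssm, 1, majority_or, tie_value = "C")
  model <- structure_model(node_id, cons_ca, aa, ss = ss,
                           source_meta = list(kind = "consensus"))
  list(model = model, spread = spread)
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")

# deterministic tie-break on merge choice: the pair whose sorted smallest
# member ids come first lexicographically
merge_tie_key <- function(na, nb) {
  paste(sort(c(min(na$member_ids), min(nb$member_ids))), collapse = "\r")
}

#' Progressive guide clustering with subcores
#'
#' Computes all-vs-all pairwise alignment scores between the input
#' structures, then repeatedly merges the two live groups with the
#' highest alignment score between their consensus pseudo-structures.
#' The merged node's columns are the matched column pairs of that
#' alignment, so every internal node carries the subcore of its member
#' set and the root carries the common structural core of the whole
#' dataset. Deterministic given inputs and parameters: each unordered
#' pair is aligned once in canonical orientation and score ties are
#' broken lexicographically on member identifiers.
#'
#' @param models list of [structure_model] objects with unique ids.
#' @param params an [align_params()] object.
#' @return the root `guide_node`; children are nested nodes.
#' @export
build_guide_clustering <- function(models, params = align_params()) {
  stopifnot(length(models) >= 2)
  ids <- vapply(models, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("structure ids must be unique")
  names(models) <- ids
  live <- lapply(models, new_guide_leaf)
  names(live) <- ids
  scores <- new.env(parent = emptyenv())
  score_of <- function(na, nb) {
    key <- pair_key(na$node_id, nb$node_id)
    if (is.null(scores[[key]])) {
      co <- align_pair(consensus_model(na), consensus_model(nb), params,
                       min_len = params$frag_len)
      scores[[key]] <- co
    }
    scores[[key]]
  }
  for (i in seq_along(live)) for (j in seq_len(i - 1L))
    score_of(live[[i]], live[[j]])
  merge_order <- 0L
  while (length(live) > 1) {
    best <- NULL
    nms <- names(live)
    for (i in seq_along(live)) for (j in seq_len(i - 1L)) {
      co <- score_of(live[[i]], live[[j]])
      cand <- list(i = i, j = j, co = co,
                   tie = merge_tie_key(live[[i]], live[[j]]))
      if (is.null(best) || co$score > best$co$score ||
          (co$score == best$co$score && cand$tie < best$tie))
        best <- cand
    }
    na <- live[[best$i]]; nb <- live[[best$j]]
    co <- best$co
    # orient the alignment as (a, b)
    if (co$id_a != na$node_id) co <- flip_correspondence(co, na$node_id, nb$node_id)
    if (nrow(co$pairs) == 0)
      stop("no structurally equivalent residues between groups {",
           paste(na$member_ids, collapse = ", "), "} and {",
           paste(nb$member_ids, collapse = ", "),
           "}; dataset too divergent for a common core")
    merge_order <- merge_order + 1L
    node_id <- paste0("N", merge_order)
    cols <- cbind(na$columns[co$pairs[, 1], , drop = FALSE],
                  nb$columns[co$pairs[, 2], , drop = FALSE])
    transforms <- na$transforms
    for (id in nb$member_ids) {
      tr <- nb$transforms[[id]]
      transforms[[id]] <- compose_rigid(co$rotation, co$translation, tr$R, tr$t)
    }
    cons <- build_consensus(node_id, cols, transforms, models)
    node <- structure(list(node_id = node_id, children = list(na, nb),
                           member_ids = sort(c(na$member_ids, nb$member_ids)),
                           columns = cols, consensus = cons$model,
                           spread = cons$spread, transforms = transforms,
                           merge_score = co$score,
                           merge_order = merge_order),
                      class = "guide_node")
    live[[na$node_id]] <- NULL
    live[[nb$node_id]] <- NULL
    live[[node_id]] <- node
  }
  root <- live[[1]]
  attr(root, "models") <- models
  root
}

#' @export
print.guide_node <- function(x, ...) {
  cat(sprintf("Guide node '%s': %d members, %d columns",
              x$node_id, length(x$member_ids), nrow(x$columns)))
  if (!is.na(x$merge_score))
    cat(sprintf(" (merge score %.2f)", x$merge_score))
  cat("\n")
  invisible(x)
}

collect_internal_nodes <- function(node) {
  if (is.null(node$children)) return(list())
  c(list(node),
    collect_internal_nodes(node$children[[1]]),
    collect_internal_nodes(node$children[[2]]))
}

#' Extract the common structural core
#'
#' Re-expresses the root columns of a guide clustering as per-structure
#' residue indices and computes the core size and average rmsd (each
#' structure's core residues superposed separately onto the consensus
#' coordinates, unweighted mean over structures).
#'
#' @param root root `guide_node` from [build_guide_clustering()].
#' @param models the structures (defaults to those stored on the root).
#' @return an object of class `core_set` with `columns` (matrix: one row
#'   per core column, one column per structure, entries are residue
#'   indices), `consensus_ca`, `spread`, `size` and `avg_rmsd`.
#' @export
extract_core <- function(root, models = attr(root, "models")) {
  stopifnot(inherits(root, "guide_node"))
  core <- structure(list(columns = root$columns,
                         column_id = paste0("C", seq_len(nrow(root$columns))),
                         consensus_ca = root$consensus$ca,
                         spread = root$spread,
                         size = nrow(root$columns),
                         avg_rmsd = NA_real_),
                    class = "core_set")
  core$avg_rmsd <- average_core_rmsd(core, models)
  core
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("Common structural core: %d columns across %d structures\n",
              x$size, ncol(x$columns)))
  cat(sprintf("  average per-structure rmsd to consensus: %.2f A\n",
              x$avg_rmsd))
  invisible(x)
}

core_coords <- function(core, model) {
  idx <- core$columns[, model$id]
  model$ca[idx, , drop = FALSE]
}

#' Average core rmsd
#'
#' For each structure, its core residues are superposed (Kabsch) onto
#' the consensus core coordinates and the rmsd recorded; the unweighted
#' mean over structures is returned.
#'
#' @param core a `core_set`.
#' @param models list of [structure_model] objects covering the core.
#' @return mean rmsd in Angstrom.
#' @export
average_core_rmsd <- function(core, models) {
  ids <- colnames(core$columns)
  models <- models[match(ids, vapply(models, `[[`, character(1), "id"))]
  if (anyNA(names(models))) stop("core references structures not supplied")
  mean(vapply(models, function(m)
    kabsch_superpose(core$consensus_ca, core_coords(core, m))$rmsd,
    numeric(1)))
}

#' Subcore report
#'
#' Table of internal guide nodes (last merges first): member lists,
#' subcore sizes, average member-vs-consensus rmsd and merge score. The
#' root core can never be larger than any subcore.
#'
#' @param root root `guide_node`.
#' @param k number of nodes to report; all if larger than available.
#' @param models structures (defaults to those stored on the root).
#' @return data frame with one row per node.
#' @export
subcore_report <- function(root, k = 2, models = attr(root, "models")) {
  nodes <- collect_internal_nodes(root)
  ord <- order(vapply(nodes, `[[`, integer(1), "merge_order"),
               decreasing = TRUE)
  nodes <- nodes[ord][seq_len(min(k, length(nodes)))]
  do.call(rbind, lapply(nodes, function(nd) {
    rmsds <- vapply(nd$member_ids, function(id) {
      idx <- nd$columns[, id]
      kabsch_superpose(nd$consensus$ca,
                       models[[id]]$ca[idx, , drop = FALSE])$rmsd
    }, numeric(1))
    data.frame(node_id = nd$node_id,
               members = paste(nd$member_ids, collapse = ","),
               n_members = length(nd$member_ids),
               n_columns = nrow(nd$columns),
               avg_rmsd = mean(rmsds),
               merge_score = nd$merge_score)
  }))
}

#' Write a core as TSV
#'
#' One row per core column: consensus coordinates, spread, then per
#' structure the author residue number and amino acid.
#'
#' @param core a `core_set`.
#' @param models the structures covering the core.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_core_tsv <- function(core, models, path) {
  ids <- colnames(core$columns)
  models <- models[match(ids, vapply(models, `[[`, character(1), "id"))]
  df <- data.frame(column_id = core$column_id,
                   x = core$consensus_ca[, 1], y = core$consensus_ca[, 2],
                   z = core$consensus_ca[, 3], spread = core$spread)
  for (k in seq_along(ids)) {
    idx <- core$columns[, k]
    df[[paste0(ids[k], "_resno")]] <- models[[k]]$author_seq_id[idx]
    df[[paste0(ids[k], "_aa")]] <- models[[k]]$aa[idx]
  }
  write_tsv(df, path)
}

guide_newick_string <- function(node) {
  if (is.null(node$children)) return(node$node_id)
  paste0("(", guide_newick_string(node$children[[1]]), ",",
         guide_newick_string(node$children[[2]]), ")",
         format(node$merge_score, digits = 6))
}

#' Guide clustering as Newick
#'
#' Exports the merge hierarchy as a Newick string with merge scores as
#' internal node labels.
#'
#' @param root root `guide_node`.
#' @return Newick string (no branch lengths).
#' @export
guide_to_newick <- function(root) {
  paste0(guide_newick_string(root), ";")
}
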
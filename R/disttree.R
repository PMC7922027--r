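# Core-restricted scores, score-to-distance conversion and
# Fitch-Margoliash least-squares tree inference. Pairwise scores are
# recomputed on the core columns only (column-paired Kabsch
# superposition, then the same three-term residue similarity), and
# converted to distances as D(A,B) = -(S(A,B) - min[S(A,A), S(B,B)]);
# because every self-score equals the core size exactly, this is the
# score deficit of the pair relative to a perfect core match. The tree
# minimizes the classic weighted least-squares criterion
# sum (d_ij - p_ij)^2 / d_ij^2 over topologies and branch lengths.

#' Core-restricted pairwise score
#'
#' Superposes the two structures on their column-paired core residues
#' (Kabsch, unweighted) and sums the per-column residue similarities.
#' The self-score equals the core size exactly.
#'
#' @param a,b [structure_model] objects present in the core.
#' @param core a `core_set` from [extract_core()].
#' @param params an [align_params()] object.
#' @return the score S(a, b).
#' @export
core_score <- function(a, b, core, params = align_params()) {
  ids <- colnames(core$columns)
  if (!all(c(a$id, b$id) %in% ids))
    stop("both structures must be covered by the core")
  if (models_identical(a, b)) return(as.numeric(core$size))
  pa <- core_coords(core, a)
  pb <- core_coords(core, b)
  fit <- kabsch_superpose(pa, pb)
  d <- sqrt(rowSums((pa - apply_rigid(pb, fit$rotation, fit$translation))^2))
  ia <- core$columns[, a$id]; ib <- core$columns[, b$id]
  sum(residue_similarity(d, a$ss[ia] == b$ss[ib],
                         aa_class(a$aa[ia]) > 0 &
                           aa_class(a$aa[ia]) == aa_class(b$aa[ib]),
                         params))
}

#' Convert a pairwise score to a distance
#'
#' `D = -(S(A,B) - min(S(A,A), S(B,B)))`: the deficit of the pairwise
#' score relative to the smaller self-score. Zero exactly when the pair
#' attains the minimum self-score.
#'
#' @param s_ab pairwise score.
#' @param s_aa,s_bb self-scores.
#' @return non-negative distance.
#' @export
score_to_distance <- function(s_ab, s_aa, s_bb) {
  m <- min(s_aa, s_bb)
  if (s_ab > m + 1e-9)
    stop("pairwise score exceeds a self-score; scoring inconsistency")
  max(0, -(s_ab - m))
}

#' Core-based distance matrix
#'
#' All-against-all distances from core-restricted scores.
#'
#' @param models list of [structure_model] objects covered by the core.
#' @param core a `core_set`.
#' @param params an [align_params()] object.
#' @return symmetric labeled distance matrix with zero diagonal.
#' @export
core_distance_matrix <- function(models, core, params = align_params()) {
  ids <- vapply(models, `[[`, character(1), "id")
  names(models) <- ids
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  self <- setNames(vapply(models, function(m) core_score(m, m, core, params),
                          numeric(1)), ids)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    s <- core_score(models[[i]], models[[j]], core, params)
    d[i, j] <- d[j, i] <- score_to_distance(s, self[i], self[j])
  }
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must be labeled")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8, check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(!is.finite(d))) stop("distances must be finite")
  (d + t(d)) / 2
}

edge_below_matrix <- function(tree) {
  n <- ape::Ntip(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  below <- matrix(FALSE, max(tree$edge), n)
  below[cbind(seq_len(n), seq_len(n))] <- TRUE
  for (r in seq_len(nrow(post$edge)))
    below[post$edge[r, 1], ] <- below[post$edge[r, 1], ] | below[post$edge[r, 2], ]
  below
}

path_incidence <- function(tree, pairs) {
  below <- edge_below_matrix(tree)
  child <- tree$edge[, 2]
  X <- vapply(child, function(c2)
    xor(below[c2, pairs[, 1]], below[c2, pairs[, 2]]), logical(nrow(pairs)))
  storage.mode(X) <- "double"
  X
}

# weighted least-squares branch lengths for a fixed path incidence
fm_fit_X <- function(X, dvec, sw, w) {
  fit <- qr(X * sw)
  bl <- qr.coef(fit, dvec * sw)
  bl[is.na(bl)] <- 0
  clamped <- any(bl < -1e-9)
  bl[bl < 0] <- 0
  resid <- sum(w * (dvec - as.numeric(X %*% bl))^2)
  list(lengths = bl, residual = resid, clamped = clamped)
}

fm_fit_topology <- function(tree, d, w, pairs) {
  fit <- fm_fit_X(path_incidence(tree, pairs), d[pairs], sqrt(w), w)
  fit$tree <- tree
  fit
}

# exhaustive search is over unlabeled shapes; the per-shape pair/edge
# incidence depends only on the shape, so cache it per leaf count
.fm_cache <- new.env(parent = emptyenv())

fm_shapes <- function(n) {
  key <- as.character(n)
  if (is.null(.fm_cache[[key]])) {
    topos <- phangorn::allTrees(n, rooted = FALSE)
    pairs <- t(combn(n, 2))
    Xs <- lapply(seq_along(topos), function(i)
      path_incidence(topos[[i]], pairs))
    .fm_cache[[key]] <- list(topos = topos, Xs = Xs, pairs = pairs)
  }
  .fm_cache[[key]]
}

fm_objective_weights <- function(d, labels) {
  pairs <- t(combn(length(labels), 2))
  dvec <- d[pairs]
  pos <- dvec[dvec > 0]
  eps <- if (length(pos)) min(pos) else 1
  # 1/d^2 weights; identical structures (d = 0) keep a large finite weight
  w <- 1 / pmax(dvec, eps)^2
  list(pairs = pairs, w = w)
}

finish_fm_tree <- function(fit, order_hint = NULL) {
  tr <- fit$tree
  tr$edge.length <- as.numeric(fit$lengths)
  attr(tr, "fit_residual") <- fit$residual
  attr(tr, "clamped") <- fit$clamped
  attr(tr, "rooted") <- FALSE
  class(tr) <- c("fm_tree", "phylo")
  tr
}

#' Fitch-Margoliash distance tree
#'
#' Fits an unrooted binary tree minimizing the weighted least-squares
#' criterion `sum_(i<j) (d_ij - p_ij)^2 / d_ij^2`, where `p_ij` is the
#' tree path length. For up to `exhaustive_max` leaves every unrooted
#' topology is evaluated (oracle-grade); above that a neighbor-joining
#' start is improved by nearest-neighbor-interchange hill climbing,
#' which never ends worse than its start. Branch lengths are weighted
#' least-squares solutions with negatives clamped to zero (flagged in
#' `attr(tree, "clamped")`); zero distances between identical structures
#' are given the weight of the smallest positive distance.
#'
#' @param dm symmetric labeled distance matrix (non-negative, zero
#'   diagonal).
#' @param exhaustive_max exhaustive topology search up to this leaf
#'   count.
#' @return an unrooted `phylo` tree of class `fm_tree` with attributes
#'   `fit_residual` and `clamped`.
#' @export
fitch_margoliash <- function(dm, exhaustive_max = 8) {
  d <- validate_distance_matrix(dm)
  labels <- rownames(d)
  n <- length(labels)
  if (n < 3) stop("need at least 3 labels")
  ow <- fm_objective_weights(d, labels)
  if (n == 3) {
    a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    c3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    bl <- pmax(c(a, b, c3), 0)
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f,%s:%f);",
                                        labels[1], bl[1], labels[2], bl[2],
                                        labels[3], bl[3]))
    p <- c(bl[1] + bl[2], bl[1] + bl[3], bl[2] + bl[3])
    return(finish_fm_tree(list(tree = tr, lengths = tr$edge.length,
                               residual = sum(ow$w * (d[ow$pairs] - p)^2),
                               clamped = any(c(a, b, c3) < -1e-9))))
  }
  if (n <= exhaustive_max) {
    shapes <- fm_shapes(n)
    dvec <- d[shapes$pairs]
    sw <- sqrt(ow$w)
    best <- NULL; best_i <- 0L
    for (i in seq_along(shapes$Xs)) {
      fit <- fm_fit_X(shapes$Xs[[i]], dvec, sw, ow$w)
      if (is.null(best) || fit$residual < best$residual) {
        best <- fit; best_i <- i
      }
    }
    tr <- shapes$topos[[best_i]]
    tr$tip.label <- labels
    best$tree <- tr
    return(finish_fm_tree(best))
  }
  start <- ape::unroot(ape::nj(d))
  best <- fm_fit_topology(start, d, ow$w, ow$pairs)
  repeat {
    improved <- FALSE
    nbrs <- phangorn::nni(best$tree)
    for (k in seq_along(nbrs)) {
      fit <- fm_fit_topology(nbrs[[k]], d, ow$w, ow$pairs)
      if (fit$residual < best$residual - 1e-12) {
        best <- fit
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  finish_fm_tree(best)
}

#' @export
print.fm_tree <- function(x, ...) {
  cat(sprintf("Fitch-Margoliash %s tree: %d leaves, WLS residual %.4g%s\n",
              if (isTRUE(attr(x, "rooted"))) "rooted" else "unrooted",
              ape::Ntip(x), attr(x, "fit_residual"),
              if (isTRUE(attr(x, "clamped"))) " (negative lengths clamped)" else ""))
  NextMethod()
}

#' Root a tree at an outgroup
#'
#' Places the root at the midpoint of the outgroup's terminal edge; the
#' ingroup topology is unchanged.
#'
#' @param tree a `phylo` (or `fm_tree`) object.
#' @param outgroup leaf label to root at.
#' @return the rooted tree (bifurcating root).
#' @export
root_at_outgroup <- function(tree, outgroup) {
  tip <- match(outgroup, tree$tip.label)
  if (is.na(tip)) stop("outgroup '", outgroup, "' is not a leaf of the tree")
  edge <- which(tree$edge[, 2] == tip)
  atts <- attributes(tree)[c("fit_residual", "clamped")]
  unrooted <- ape::unroot(tree)
  class(unrooted) <- "phylo"
  tip <- match(outgroup, unrooted$tip.label)
  pos <- unrooted$edge.length[which(unrooted$edge[, 2] == tip)] / 2
  rooted <- phytools::reroot(unrooted, tip, position = pos)
  attr(rooted, "fit_residual") <- atts$fit_residual
  attr(rooted, "clamped") <- atts$clamped
  attr(rooted, "rooted") <- TRUE
  class(rooted) <- c("fm_tree", "phylo")
  rooted
}

#' Write a distance matrix
#'
#' Square TSV with a header row and a label column.
#'
#' @param d labeled distance matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(label = rownames(d), d, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a distance matrix
#'
#' Reads either the square TSV written by [write_distance_matrix()] or
#' a square PHYLIP distance file (leading line with the taxon count).
#'
#' @param path input path.
#' @return labeled symmetric matrix.
#' @export
read_distance_matrix <- function(path) {
  first <- trimws(readLines(path, n = 1))
  if (grepl("^[0-9]+$", first)) {
    n <- as.integer(first)
    body <- read.table(path, skip = 1, header = FALSE,
                       stringsAsFactors = FALSE)
    labels <- as.character(body[[1]])
    d <- as.matrix(body[, -1, drop = FALSE])
  } else {
    body <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                       stringsAsFactors = FALSE)
    labels <- as.character(body[[1]])
    d <- as.matrix(body[, -1, drop = FALSE])
  }
  dimnames(d) <- list(labels, labels)
  storage.mode(d) <- "double"
  validate_distance_matrix(d)
}
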
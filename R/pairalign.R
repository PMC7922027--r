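# Sequence-order-independent pairwise structural alignment. A pair of
# C-alpha traces is aligned by seeding rigid superpositions from
# low-rmsd fragment pairs, then iterating optimal one-to-one residue
# assignment against similarity-weighted re-superposition. The score of
# a correspondence is the sum of per-pair similarities, each combining a
# Gaussian geometric kernel with secondary-structure and amino-acid
# class agreement; residue order plays no role, so circularly permuted
# folds align as well as collinear ones.

#' Alignment parameters
#'
#' Parameter set controlling pairwise structural alignment and all
#' downstream core/score computations.
#'
#' @param sigma Gaussian scale (Angstrom) of the geometric similarity
#'   kernel.
#' @param w_geom,w_ss,w_aa non-negative weights of the geometry,
#'   secondary-structure and amino-acid class terms; must sum to 1. The
#'   defaults put most weight on geometry, then secondary structure,
#'   then residue character.
#' @param d_max hard distance cutoff (Angstrom) beyond which residues are
#'   never considered equivalent; must be at least `2 * sigma`.
#' @param frag_len length of the contiguous fragments used to seed
#'   superpositions.
#' @param n_seeds number of distinct seed superpositions retained
#'   (deduplicated at 5 degrees of rotation difference).
#' @param max_iter cap on assignment/re-superposition iterations per seed.
#' @param tol_factor convergence tolerance on the score, expressed as a
#'   fraction of `min(|A|, |B|)`.
#' @return an object of class `align_params`.
#' @export
align_params <- function(sigma = 2, w_geom = 0.6, w_ss = 0.25, w_aa = 0.15,
                         d_max = 5, frag_len = 15, n_seeds = 20,
                         max_iter = 50, tol_factor = 1e-4) {
  stopifnot(sigma > 0, w_geom >= 0, w_ss >= 0, w_aa >= 0,
            frag_len >= 3, n_seeds >= 1, max_iter >= 1, tol_factor > 0)
  if (abs(w_geom + w_ss + w_aa - 1) > 1e-9)
    stop("similarity weights w_geom + w_ss + w_aa must sum to 1")
  if (d_max < 2 * sigma)
    stop("d_max must be at least 2 * sigma")
  structure(list(sigma = sigma, w_geom = w_geom, w_ss = w_ss, w_aa = w_aa,
                 d_max = d_max, frag_len = frag_len, n_seeds = n_seeds,
                 max_iter = max_iter, tol_factor = tol_factor),
            class = "align_params")
}

#' @export
print.align_params <- function(x, ...) {
  cat("Structural alignment parameters\n")
  cat(sprintf("  similarity: %.2f*exp(-d^2/(2*%.2f^2)) + %.2f*[ss] + %.2f*[aa class], cutoff %.1f A\n",
              x$w_geom, x$sigma, x$w_ss, x$w_aa, x$d_max))
  cat(sprintf("  seeding: fragments of %d, %d seeds; refinement: <= %d iterations, tol %g*min(|A|,|B|)\n",
              x$frag_len, x$n_seeds, x$max_iter, x$tol_factor))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) rmsd of `points_b` transformed onto `points_a`.
#'
#' @param points_a,points_b numeric N x 3 coordinate matrices (Angstrom),
#'   row i of one paired with row i of the other.
#' @param weights optional non-negative weights, length N.
#' @return list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3) and `rmsd`; the transform maps `points_b` onto
#'   `points_a` as `points_b %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(points_a, points_b, weights = NULL) {
  points_a <- as.matrix(points_a); points_b <- as.matrix(points_b)
  n <- nrow(points_a)
  if (n < 3 || nrow(points_b) != n || ncol(points_a) != 3 || ncol(points_b) != 3)
    stop("need two N x 3 matrices with N >= 3")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative, length N, with positive sum")
  # degenerate (collinear) configurations have no unique rotation
  ca <- sweep(points_a, 2, colSums(points_a * weights) / sum(weights))
  sv <- svd(ca * sqrt(weights))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate (collinear) point configuration")
  res <- cpp_kabsch(points_a, points_b, as.numeric(weights))
  list(rotation = res$rotation, translation = as.numeric(res$translation),
       rmsd = res$rmsd)
}

#' Per-residue similarity
#'
#' Similarity of two residues at post-superposition distance `d`:
#' `w_geom * exp(-d^2 / (2 sigma^2)) + w_ss * [ss match] + w_aa * [class
#' match]`, hard-zeroed beyond `d_max`.
#'
#' @param d non-negative distance in Angstrom.
#' @param ss_match,aa_class_match logicals.
#' @param params an [align_params()] object.
#' @return similarity in `[0, 1]` (vectorized over `d`).
#' @export
residue_similarity <- function(d, ss_match, aa_class_match, params = align_params()) {
  stopifnot(all(d >= 0))
  s <- params$w_geom * exp(-d^2 / (2 * params$sigma^2)) +
    params$w_ss * as.numeric(ss_match) +
    params$w_aa * as.numeric(aa_class_match)
  s[d > params$d_max] <- 0
  s
}

#' Seed superpositions from fragment pairs
#'
#' Superposes every pair of contiguous `frag_len`-residue fragments of
#' the two structures and returns the `n_seeds` transforms of lowest
#' fragment rmsd, deduplicated so that retained rotations differ by more
#' than 5 degrees.
#'
#' @param a,b [structure_model] objects.
#' @param params an [align_params()] object.
#' @return list with `rotations` (3 x 3 x k array), `translations`
#'   (k x 3) and `frag_rmsd` (ascending).
#' @export
seed_superpositions <- function(a, b, params = align_params()) {
  if (nrow(a$ca) < params$frag_len || nrow(b$ca) < params$frag_len)
    stop("both structures must have at least frag_len residues")
  res <- cpp_seed_scan(a$ca, b$ca, params$frag_len, params$n_seeds, 5)
  res$translations <- matrix(res$translations, ncol = 3)
  res
}

# exact self-correspondence (identity transform, every residue matched
# at distance zero with full similarity)
self_correspondence <- function(a, b) {
  n <- nrow(a$ca)
  new_correspondence(
    id_a = a$id, id_b = b$id,
    pairs = cbind(seq_len(n), seq_len(n)),
    similarities = rep(1, n),
    rotation = diag(3), translation = c(0, 0, 0),
    score = as.numeric(n), rmsd = 0, iterations = 0L)
}

new_correspondence <- function(id_a, id_b, pairs, similarities, rotation,
                               translation, score, rmsd, iterations) {
  structure(list(id_a = id_a, id_b = id_b, pairs = pairs,
                 similarities = similarities, rotation = rotation,
                 translation = as.numeric(translation), score = score,
                 rmsd = rmsd, iterations = iterations),
            class = "correspondence")
}

#' @export
print.correspondence <- function(x, ...) {
  cat(sprintf("Structural correspondence %s vs %s\n", x$id_a, x$id_b))
  cat(sprintf("  %d matched residue pairs, score S = %.3f, rmsd %.3f A\n",
              nrow(x$pairs), x$score, x$rmsd))
  invisible(x)
}

models_identical <- function(a, b) {
  nrow(a$ca) == nrow(b$ca) && all(a$ca == b$ca) &&
    all(a$aa == b$aa) && all(a$ss == b$ss)
}

# core alignment on a canonical input orientation
align_pair_raw <- function(a, b, params) {
  if (models_identical(a, b)) return(self_correspondence(a, b))
  seeds <- seed_superpositions(a, b, params)
  nmin <- min(nrow(a$ca), nrow(b$ca))
  res <- cpp_align_refine(a$ca, b$ca, ss_code(a$ss), ss_code(b$ss),
                          aa_class(a$aa), aa_class(b$aa),
                          seeds$rotations, seeds$translations,
                          params$sigma, params$w_geom, params$w_ss,
                          params$w_aa, params$d_max, params$max_iter,
                          params$tol_factor * nmin)
  new_correspondence(a$id, b$id, res$pairs, res$similarities,
                     res$rotation, as.numeric(res$translation),
                     res$score, res$rmsd, res$iterations)
}

flip_correspondence <- function(co, id_a, id_b) {
  inv <- invert_rigid(co$rotation, co$translation)
  new_correspondence(id_a, id_b,
                     pairs = co$pairs[, c(2, 1), drop = FALSE],
                     similarities = co$similarities,
                     rotation = inv$R, translation = inv$t,
                     score = co$score, rmsd = co$rmsd,
                     iterations = co$iterations)
}

#' Align two structures
#'
#' Sequence-order-independent alignment of two C-alpha traces. Seed
#' superpositions from low-rmsd fragment pairs are refined by iterating
#' an optimal one-to-one residue assignment (candidates limited to pairs
#' within `d_max`) with similarity-weighted re-superposition; the
#' highest-scoring correspondence over all seeds is returned. Each
#' unordered pair is computed once in a canonical orientation (inputs
#' ordered lexicographically by id), so the score is exactly symmetric.
#' A self-alignment matches every residue at distance zero and scores
#' exactly `|A|`.
#'
#' @param a,b [structure_model] objects.
#' @param params an [align_params()] object.
#' @param min_len minimum residue count accepted per structure.
#' @return a `correspondence` object: matched index `pairs` (rows of
#'   `(index in a, index in b)`), per-pair `similarities`, the rigid
#'   transform mapping `b` onto `a`, the total `score` and the `rmsd`
#'   over matched pairs. If no candidate pairing exists under any seed,
#'   a defined no-alignment result with score 0 and no pairs is
#'   returned.
#' @export
align_pair <- function(a, b, params = align_params(), min_len = 30) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  if (nrow(a$ca) < min_len || nrow(b$ca) < min_len)
    stop(sprintf("structures must have at least %d residues", min_len))
  if (a$id <= b$id) {
    align_pair_raw(a, b, params)
  } else {
    flip_correspondence(align_pair_raw(b, a, params), a$id, b$id)
  }
}

#' Optimal residue assignment
#'
#' Maximum-similarity one-to-one matching for a candidate similarity
#' matrix, as used inside [align_pair()]. Entries that are zero,
#' negative or `NA` are forbidden. Ties are broken deterministically in
#' favour of lexicographically smaller (row, column) pairs.
#'
#' @param sim numeric matrix of similarities (rows: residues of A,
#'   columns: residues of B).
#' @return integer vector, one entry per row: the matched column or `NA`.
#' @export
solve_assignment <- function(sim) {
  sim <- as.matrix(sim)
  sim[is.na(sim)] <- 0
  cpp_assignment(sim)
}
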
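# Fixtures built in code: parametric traces, rigid motions, tiny PDB
# files with known quirks (missing C-alpha, altlocs), additive distance
# matrices from random trees.

helix_trace <- function(n = 20, rise = 1.5, radius = 2.3, turn_deg = 100) {
  k <- seq_len(n)
  th <- k * turn_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * k)
}

extended_trace <- function(n = 10, step = 3.8) {
  cbind(step * seq_len(n), 0, 0)
}

random_walk_trace <- function(n = 30, step = 3.8, min_sep = 3.0) {
  pts <- matrix(0, n, 3)
  for (i in 2:n) {
    repeat {
      cand <- pts[i - 1, ] + step * corephylo:::random_unit_vector()
      prev <- pts[seq_len(max(1, i - 3)), , drop = FALSE]
      if (i <= 3 || min(sqrt(rowSums(sweep(prev, 2, cand)^2))) > min_sep) break
    }
    pts[i, ] <- cand
  }
  pts
}

trace_model <- function(ca, id = "trace", aa = NULL, ss = NULL) {
  n <- nrow(ca)
  if (is.null(aa)) aa <- rep("A", n)
  structure_model(id, ca, aa, ss = ss)
}

rigid_copy <- function(model, id = paste0(model$id, "_rigid"),
                       axis = c(1, 2, 3), angle = 1.1, shift = c(5, -3, 2)) {
  R <- corephylo:::rotation_from_axis_angle(axis, angle)
  m <- model
  m$id <- id
  m$ca <- corephylo:::apply_rigid(model$ca, R, shift)
  m
}

# fixed-column PDB writer used to fabricate parser fixtures
write_fixture_pdb <- function(path, resno, x, y, z, resid = "ALA",
                              elety = "CA", chain = "A", alt = "") {
  n <- length(resno)
  resid <- rep_len(resid, n); elety <- rep_len(elety, n)
  chain <- rep_len(chain, n); alt <- rep_len(alt, n)
  lines <- sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                   seq_len(n), paste0(" ", elety), alt, resid, chain, resno,
                   x, y, z)
  writeLines(c(lines, "END"), path)
  path
}

additive_matrix <- function(n, seed) {
  corephylo:::with_local_seed(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.2, 2)
    tr$tip.label <- sprintf("T%02d", seq_len(n))
    d <- ape::cophenetic.phylo(tr)
    ord <- sort(rownames(d))
    list(tree = ape::unroot(tr), d = d[ord, ord])
  })
}

# small cached fold family so several test files can share one
shared_family <- local({
  cache <- new.env()
  function(n_leaves = 6, seed = 11, ...) {
    key <- paste(n_leaves, seed, ...)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_fold_family(n_leaves = n_leaves, seed = seed, ...)
    cache[[key]]
  }
})
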
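# Synthetic fold families: parametric C-alpha traces (helices, strands,
# random-walk loops) evolved along a known tree with coordinate noise,
# substitutions, loop indels and optional circular permutation, plus the
# full ground truth (true tree, residue correspondences, ungapped
# columns). A geometric surrogate for divergent evolution of a globular
# fold -- not a physical model -- built so that every downstream module
# can be tested against known answers.

# approximate amino-acid composition of globular proteins
AA_COMPOSITION <- c(
  A = 0.083, R = 0.055, N = 0.040, D = 0.054, C = 0.014, Q = 0.039,
  E = 0.067, G = 0.071, H = 0.022, I = 0.059, L = 0.096, K = 0.058,
  M = 0.024, F = 0.039, P = 0.047, S = 0.066, T = 0.053, W = 0.011,
  Y = 0.029, V = 0.073)

HELIX_RISE <- 1.5      # A per residue
HELIX_RADIUS <- 2.3    # A
HELIX_TURN <- 100      # degrees per residue
STRAND_STEP <- 3.8     # A between consecutive C-alpha
LOOP_STEP <- 3.8
CLASH_DIST <- 3.5      # self-avoidance floor, A

orthonormal_frame <- function(a) {
  a <- a / sqrt(sum(a^2))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * a) * a
  u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  list(a = a, u = u, v = v)
}

helix_points <- function(start, axis, len, phase) {
  f <- orthonormal_frame(axis)
  k <- seq_len(len)
  th <- phase + k * HELIX_TURN * pi / 180
  c0 <- start - HELIX_RADIUS * (cos(phase) * f$u + sin(phase) * f$v)
  t(vapply(seq_len(len), function(i) {
    c0 + HELIX_RISE * k[i] * f$a +
      HELIX_RADIUS * (cos(th[i]) * f$u + sin(th[i]) * f$v)
  }, numeric(3)))
}

strand_points <- function(start, dir, len) {
  dir <- dir / sqrt(sum(dir^2))
  outer(seq_len(len), dir * STRAND_STEP) + rep(start, each = len)
}

min_clearance <- function(new_pts, prev_pts, gap = 2) {
  if (is.null(prev_pts) || nrow(prev_pts) <= gap) return(Inf)
  keep <- prev_pts[seq_len(nrow(prev_pts) - gap), , drop = FALSE]
  min(vapply(seq_len(nrow(new_pts)), function(i) {
    min(sqrt(rowSums(sweep(keep, 2, new_pts[i, ])^2)))
  }, numeric(1)))
}

# biased self-avoiding walk from `cur` toward `target`
loop_walk <- function(cur, target, len, prev_pts) {
  out <- matrix(NA_real_, len, 3)
  for (k in seq_len(len)) {
    pull <- target - cur
    pn <- sqrt(sum(pull^2))
    pull <- if (pn > 1e-8) pull / pn else random_unit_vector()
    best <- NULL; best_clear <- -Inf
    for (try in 1:8) {
      d <- 0.65 * pull + 0.35 * rnorm(3)
      d <- d / sqrt(sum(d^2))
      cand <- cur + LOOP_STEP * d
      cl <- min_clearance(matrix(cand, 1), rbind(prev_pts, out[seq_len(k - 1), , drop = FALSE]))
      if (cl > best_clear) { best_clear <- cl; best <- cand }
      if (cl >= CLASH_DIST) break
    }
    if (best_clear < CLASH_DIST) return(NULL)
    out[k, ] <- best
    cur <- best
  }
  out
}

#' Generate an ancestral synthetic fold
#'
#' Builds a compact C-alpha trace of parametric alpha-helices (rise
#' 1.5 A, 100 degrees per residue, radius 2.3 A) and extended strands
#' (3.8 A spacing) whose start points are packed on a jittered 3D grid,
#' joined by biased random-walk loops; the whole trace is self-avoiding
#' at 3.5 A. Residue identities are drawn from a typical globular
#' amino-acid composition; secondary-structure states record the
#' designed elements. Deterministic given `seed`. Coordinates are
#' rounded to 0.001 A so that PDB and mmCIF round trips are exact.
#'
#' @param n_helices,n_strands numbers of elements (together at least 2).
#' @param loop_len loop length (residues) between consecutive elements.
#' @param seed integer seed fixing the fold.
#' @param helix_len,strand_len element lengths in residues.
#' @param id model identifier.
#' @param max_restarts packing retries before a hard error.
#' @return a [structure_model] whose `ss` holds the designed states.
#' @export
make_ancestor_fold <- function(n_helices = 5, n_strands = 3, loop_len = 6,
                               seed = 1, helix_len = 16, strand_len = 8,
                               id = "ancestor", max_restarts = 40) {
  stopifnot(n_helices + n_strands >= 2, loop_len >= 2)
  n_elem <- n_helices + n_strands
  for (attempt in seq_len(max_restarts)) {
    fold <- with_local_seed(seed + 7919L * (attempt - 1L), {
      elements <- sample(c(rep("H", n_helices), rep("E", n_strands)))
      # compact jittered grid of element anchors
      k <- ceiling(n_elem^(1 / 3))
      g <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k)))
      g <- g[order(rowSums(sweep(g, 2, colMeans(g))^2)), , drop = FALSE]
      anchors <- g[seq_len(n_elem), , drop = FALSE] * 11 +
        matrix(runif(3 * n_elem, -2, 2), n_elem, 3)
      pts <- NULL; ss <- character(0); ok <- TRUE
      for (e in seq_len(n_elem)) {
        if (e == 1) {
          cur <- anchors[1, ]
        } else {
          lp <- loop_walk(pts[nrow(pts), ], anchors[e, ], loop_len, pts)
          if (is.null(lp)) { ok <- FALSE; break }
          pts <- rbind(pts, lp)
          ss <- c(ss, rep("C", loop_len))
          cur <- lp[nrow(lp), ]
        }
        placed <- FALSE
        for (try in 1:30) {
          dir <- random_unit_vector()
          len <- if (elements[e] == "H") helix_len else strand_len
          ep <- if (elements[e] == "H")
            helix_points(cur, dir, len, runif(1, 0, 2 * pi))
          else strand_points(cur, dir, len)
          if (min_clearance(ep, pts) >= CLASH_DIST &&
              min(dist(ep)) >= 2.9) {
            pts <- rbind(pts, ep)
            ss <- c(ss, rep(elements[e], len))
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) NULL
      else list(pts = pts, ss = ss,
                aa = sample(names(AA_COMPOSITION), nrow(pts),
                            replace = TRUE, prob = AA_COMPOSITION))
    })
    if (!is.null(fold)) {
      return(structure_model(id, round(fold$pts, 3), fold$aa,
                             ss = fold$ss,
                             source_meta = list(generator = "make_ancestor_fold",
                                                seed = seed)))
    }
  }
  stop("failed to pack a self-avoiding fold after ", max_restarts, " restarts")
}

#' Evolution parameters for synthetic families
#'
#' @param coord_sigma per-coordinate Gaussian displacement scale
#'   (Angstrom per unit square-root branch length).
#' @param sub_rate substitutions per residue per unit branch length.
#' @param indel_rate indel events per unit branch length (loops only).
#' @param indel_len geometric mean indel length (residues).
#' @param permute_edges integer indices of tree edges (rows of
#'   `tree$edge`) on which a circular permutation occurs.
#' @param seed integer seed fixing the whole family.
#' @return an object of class `evolve_params`.
#' @export
evolve_params <- function(coord_sigma = 1.0, sub_rate = 0.3, indel_rate = 0.2,
                          indel_len = 3, permute_edges = integer(0), seed = 1) {
  stopifnot(coord_sigma >= 0, sub_rate >= 0, indel_rate >= 0, indel_len >= 1)
  structure(list(coord_sigma = coord_sigma, sub_rate = sub_rate,
                 indel_rate = indel_rate, indel_len = indel_len,
                 permute_edges = as.integer(permute_edges),
                 seed = as.integer(seed)),
            class = "evolve_params")
}

loop_runs <- function(ss) {
  r <- rle(ss == "C")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

delete_segment <- function(st, len, min_keep = 40) {
  runs <- loop_runs(st$ss)
  if (nrow(runs) == 0 || length(st$aa) - len < min_keep) return(st)
  r <- runs[sample.int(nrow(runs), 1), ]
  if (r["end"] - r["start"] + 1 < 1) return(st)
  len <- min(len, r["end"] - r["start"] + 1)
  i0 <- r["start"] + sample.int(r["end"] - r["start"] - len + 2, 1) - 1
  keep <- setdiff(seq_along(st$aa), i0:(i0 + len - 1))
  lapply_state(st, keep)
}

lapply_state <- function(st, idx) {
  list(ca = st$ca[idx, , drop = FALSE], aa = st$aa[idx], ss = st$ss[idx],
       uid = st$uid[idx])
}

# inserted loops bulge outward from the chain so that new residues
# occupy genuinely new space (as a real inserted loop must)
insert_segment <- function(st, len, uid_counter, bulge = 6) {
  n <- length(st$aa)
  loops <- which(st$ss == "C" & seq_len(n) < n)
  if (length(loops) == 0) return(list(st = st, uid_counter = uid_counter))
  i <- loops[sample.int(length(loops), 1)]
  p0 <- st$ca[i, ]; p1 <- st$ca[i + 1, ]
  chain_dir <- p1 - p0
  nrm <- random_unit_vector()
  nrm <- nrm - sum(nrm * chain_dir) * chain_dir / max(sum(chain_dir^2), 1e-8)
  nn <- sqrt(sum(nrm^2)); if (nn < 1e-6) nrm <- random_unit_vector() else nrm <- nrm / nn
  frac <- seq_len(len) / (len + 1)
  newca <- t(vapply(seq_len(len), function(k) {
    p0 + frac[k] * (p1 - p0) + bulge * sin(pi * frac[k]) * nrm +
      rnorm(3, 0, 0.3)
  }, numeric(3)))
  newaa <- sample(names(AA_COMPOSITION), len, replace = TRUE,
                  prob = AA_COMPOSITION)
  newuid <- uid_counter + seq_len(len)
  idx <- seq_len(n)
  st <- list(ca = rbind(st$ca[1:i, , drop = FALSE], newca,
                        st$ca[(i + 1):n, , drop = FALSE]),
             aa = c(st$aa[1:i], newaa, st$aa[(i + 1):n]),
             ss = c(st$ss[1:i], rep("C", len), st$ss[(i + 1):n]),
             uid = c(st$uid[1:i], newuid, st$uid[(i + 1):n]))
  list(st = st, uid_counter = uid_counter + len)
}

permute_state <- function(st) {
  n <- length(st$aa)
  cuts <- which(st$ss == "C")
  cuts <- cuts[cuts > n * 0.2 & cuts < n * 0.8]
  if (length(cuts) == 0) cuts <- which(st$ss == "C")
  if (length(cuts) == 0) return(st)
  cut <- cuts[sample.int(length(cuts), 1)]
  lapply_state(st, c(cut:n, seq_len(cut - 1)))
}

#' Evolve an ancestor fold along a tree
#'
#' Simulates structural divergence along each branch: independent
#' Gaussian C-alpha displacement with per-coordinate standard deviation
#' `coord_sigma * sqrt(branch length)`, Poisson amino-acid
#' substitutions, Poisson loop indels (insertions bulge outward from
#' the chain; deletions remove a loop stretch), and an optional
#' circular permutation on designated edges (sequence order cut at a
#' loop, coordinates untouched). Every leaf finally receives a random
#' rigid motion so no analysis can rely on a shared frame, and
#' coordinates are rounded to 0.001 A for exact file round trips.
#'
#' @param ancestor a [structure_model] from [make_ancestor_fold()].
#' @param tree a rooted `phylo` tree with branch lengths and tip labels.
#' @param params an [evolve_params()] object.
#' @return an object of class `fold_family`: named list of leaf
#'   `models`, and `truth` with the generating `tree`, per-leaf
#'   ancestral-residue `uids` and the `ungapped` ancestral columns
#'   present in every leaf.
#' @export
evolve_along_tree <- function(ancestor, tree, params = evolve_params()) {
  stopifnot(inherits(ancestor, "structure_model"), inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  n_anc <- length(ancestor$aa)
  with_local_seed(params$seed, {
    root <- ape::Ntip(tree) + 1
    states <- vector("list", max(tree$edge))
    states[[root]] <- list(ca = ancestor$ca, aa = ancestor$aa,
                           ss = ancestor$ss, uid = seq_len(n_anc))
    uid_counter <- n_anc
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    edge_idx <- match(paste(edges[, 1], edges[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))
    for (r in seq_len(nrow(edges))) {
      par <- edges[r, 1]; child <- edges[r, 2]
      bl <- tree$edge.length[edge_idx[r]]
      st <- states[[par]]
      n <- length(st$aa)
      if (bl > 0 && params$coord_sigma > 0)
        st$ca <- st$ca + matrix(rnorm(3 * n, 0, params$coord_sigma * sqrt(bl)),
                                n, 3)
      nsub <- rpois(1, params$sub_rate * bl * n)
      if (nsub > 0) {
        pos <- unique(sample.int(n, nsub, replace = TRUE))
        for (p in pos)
          st$aa[p] <- sample(setdiff(names(AA_COMPOSITION), st$aa[p]), 1)
      }
      nindel <- rpois(1, params$indel_rate * bl)
      for (q in seq_len(nindel)) {
        len <- 1 + rgeom(1, 1 / params$indel_len)
        if (runif(1) < 0.5) {
          st <- delete_segment(st, len)
        } else {
          ins <- insert_segment(st, len, uid_counter)
          st <- ins$st; uid_counter <- ins$uid_counter
        }
      }
      if (edge_idx[r] %in% params$permute_edges) st <- permute_state(st)
      states[[child]] <- st
    }
    models <- list(); uids <- list()
    for (tip in seq_len(ape::Ntip(tree))) {
      st <- states[[tip]]
      R <- random_rotation()
      tt <- runif(3, -30, 30)
      lab <- tree$tip.label[tip]
      models[[lab]] <- structure_model(
        lab, round(apply_rigid(st$ca, R, tt), 3), st$aa, ss = st$ss,
        source_meta = list(generator = "evolve_along_tree", seed = params$seed))
      uids[[lab]] <- st$uid
    }
    ungapped <- seq_len(n_anc)
    for (u in uids) ungapped <- intersect(ungapped, u)
    structure(list(models = models,
                   truth = list(tree = tree, uids = uids,
                                ungapped = sort(ungapped)),
                   params = params, ancestor = ancestor),
              class = "fold_family")
  })
}

#' @export
print.fold_family <- function(x, ...) {
  cat(sprintf("Synthetic fold family: %d leaves, ancestor of %d residues\n",
              length(x$models), length(x$ancestor$aa)))
  cat(sprintf("  ungapped ground-truth columns: %d\n", length(x$truth$ungapped)))
  invisible(x)
}

#' True residue correspondence between two family members
#'
#' @param family a `fold_family`.
#' @param id_a,id_b leaf identifiers.
#' @return two-column matrix of matched residue indices (1-based).
#' @export
true_correspondence <- function(family, id_a, id_b) {
  ua <- family$truth$uids[[id_a]]; ub <- family$truth$uids[[id_b]]
  shared <- intersect(ua, ub)
  cbind(a = match(shared, ua), b = match(shared, ub))
}

#' Circularly permute a structure
#'
#' Reorders the residues as `cut:n, 1:(cut-1)`; coordinates, amino acids
#' and secondary structure travel with their residues, so the fold is
#' unchanged and only the sequence order moves (the classic circular
#' permutation seen in e.g. birnavirus-like polymerase palms).
#' `cut_index = 1` is the identity.
#'
#' @param model a [structure_model].
#' @param cut_index 1-based cut position; must fall in a loop (`ss ==
#'   "C"`) to keep designed elements intact.
#' @return the permuted [structure_model].
#' @export
apply_circular_permutation <- function(model, cut_index) {
  n <- length(model$aa)
  stopifnot(cut_index >= 1, cut_index <= n)
  if (cut_index == 1) return(model)
  if (model$ss[cut_index] != "C")
    stop("cut_index must fall in a loop (ss == 'C')")
  idx <- c(cut_index:n, seq_len(cut_index - 1))
  structure_model(model$id, model$ca[idx, , drop = FALSE], model$aa[idx],
                  ss = model$ss[idx], family_label = model$family_label,
                  source_meta = model$source_meta)
}

#' Simulate a complete synthetic family
#'
#' Convenience wrapper: generates an ancestor fold, draws a random
#' rooted tree (uniform branch lengths in `[0.1, 0.4]` unless a tree is
#' supplied) and evolves the family along it.
#'
#' @param n_leaves number of leaves.
#' @param seed integer seed fixing everything.
#' @param tree optional `phylo` tree (overrides `n_leaves`).
#' @param fold_args list of overrides for [make_ancestor_fold()].
#' @param ... overrides for [evolve_params()].
#' @return a `fold_family`.
#' @export
simulate_fold_family <- function(n_leaves = 8, seed = 1, tree = NULL,
                                 fold_args = list(), ...) {
  anc <- do.call(make_ancestor_fold,
                 utils::modifyList(list(seed = seed), fold_args))
  if (is.null(tree)) {
    tree <- with_local_seed(seed + 104729L, {
      tr <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
      tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.4)
      tr$tip.label <- sprintf("S%02d", seq_len(n_leaves))
      tr
    })
  }
  evolve_along_tree(anc, tree, evolve_params(seed = seed + 15485863L, ...))
}

aa_three <- function(aa) {
  three <- bio3d::aa123(aa)
  three[aa == "X" | is.na(three)] <- "UNK"
  three
}

write_mmcif <- function(model, path) {
  n <- nrow(model$ca)
  three <- aa_three(model$aa)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("data_", model$id), "#", "loop_",
               paste0("_atom_site.",
                      c("group_PDB", "id", "type_symbol", "label_atom_id",
                        "label_alt_id", "label_comp_id", "label_asym_id",
                        "label_entity_id", "label_seq_id",
                        "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                        "occupancy", "B_iso_or_equiv", "auth_seq_id",
                        "auth_comp_id", "auth_asym_id", "auth_atom_id",
                        "pdbx_PDB_model_num"))), con)
  writeLines(sprintf(
    "ATOM %d C CA . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s A CA 1",
    seq_len(n), three, model$author_seq_id, model$ca[, 1], model$ca[, 2],
    model$ca[, 3], model$author_seq_id, three), con)
  writeLines("#", con)
  invisible(path)
}

write_pdb_model <- function(model, path) {
  bio3d::write.pdb(file = path, xyz = as.numeric(t(model$ca)),
                   resno = model$author_seq_id, resid = aa_three(model$aa),
                   elety = rep("CA", nrow(model$ca)),
                   chain = rep("A", nrow(model$ca)),
                   type = rep("ATOM", nrow(model$ca)))
  invisible(path)
}

#' Write a synthetic family to disk
#'
#' Writes every leaf as PDB and mmCIF, the true tree as Newick, the
#' per-leaf ancestral-residue maps and ungapped ground-truth columns as
#' TSV, and a YAML manifest with all parameters and the seed.
#'
#' @param family a `fold_family`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_family <- function(family, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  for (m in family$models) {
    write_pdb_model(m, file.path(out_dir, paste0(m$id, ".pdb")))
    write_mmcif(m, file.path(out_dir, paste0(m$id, ".cif")))
  }
  ape::write.tree(family$truth$tree, file.path(out_dir, "true_tree.nwk"))
  maps <- do.call(rbind, lapply(names(family$truth$uids), function(id) {
    data.frame(structure = id,
               linear_index = seq_along(family$truth$uids[[id]]) - 1L,
               ancestor_uid = family$truth$uids[[id]])
  }))
  write_tsv(maps, file.path(out_dir, "residue_map.tsv"))
  write_tsv(data.frame(ancestor_uid = family$truth$ungapped),
            file.path(out_dir, "ungapped_columns.tsv"))
  yaml::write_yaml(
    list(seed = family$params$seed,
         coord_sigma = family$params$coord_sigma,
         sub_rate = family$params$sub_rate,
         indel_rate = family$params$indel_rate,
         indel_len = family$params$indel_len,
         permute_edges = family$params$permute_edges,
         n_leaves = length(family$models),
         leaves = names(family$models)),
    file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
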
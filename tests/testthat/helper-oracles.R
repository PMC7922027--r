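# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: the rotation search scans an axis-angle
# grid, the assignment oracle enumerates matchings, and the split
# oracle collects bipartitions by edge-removal DFS on the raw edge
# list.

rot_from_vec <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  corephylo:::rotation_from_axis_angle(r / th, th)
}

# translation-optimal rmsd at a fixed rotation
rmsd_at_rotation <- function(Ac, Bc, R) {
  sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
}

# hierarchical axis-angle grid search down to a 0.5-degree step; several
# distinct coarse-grid basins are refined so a non-global basin cannot
# capture the search
oracle_grid_rmsd <- function(A, B, coarse_deg = 15, final_deg = 0.5) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  eval_grid <- function(center, half_range, step) {
    offs <- seq(-half_range, half_range, by = step)
    best <- list(rmsd = Inf, r = center)
    for (dx in offs) for (dy in offs) for (dz in offs) {
      r <- center + c(dx, dy, dz)
      if (sqrt(sum(r^2)) > pi + step) next
      v <- rmsd_at_rotation(Ac, Bc, rot_from_vec(r))
      if (v < best$rmsd) best <- list(rmsd = v, r = r)
    }
    best
  }
  # coarse pass: record every grid point, keep well-separated leaders
  step0 <- coarse_deg * pi / 180
  offs <- seq(-pi, pi, by = step0)
  pts <- list()
  for (dx in offs) for (dy in offs) for (dz in offs) {
    r <- c(dx, dy, dz)
    if (sqrt(sum(r^2)) > pi + step0) next
    pts[[length(pts) + 1]] <-
      list(r = r, rmsd = rmsd_at_rotation(Ac, Bc, rot_from_vec(r)))
  }
  pts <- pts[order(vapply(pts, `[[`, numeric(1), "rmsd"))]
  starts <- list()
  for (p in pts) {
    if (length(starts) >= 6) break
    far <- all(vapply(starts, function(s)
      sqrt(sum((s$r - p$r)^2)) > 3 * step0, logical(1)))
    if (far) starts[[length(starts) + 1]] <- p
  }
  best_rmsd <- Inf
  for (s in starts) {
    step <- step0
    best <- s
    while (step > final_deg * pi / 180) {
      step <- step / 2
      best <- eval_grid(best$r, 2 * step, step)
    }
    best <- eval_grid(best$r, 2 * step, final_deg * pi / 180)
    best_rmsd <- min(best_rmsd, best$rmsd)
  }
  best_rmsd
}

# exhaustive maximum-similarity one-to-one matching (entries <= 0
# forbidden); returns the best score and one best matching
oracle_assignment <- function(S) {
  nA <- nrow(S); nB <- ncol(S)
  row_max <- apply(S, 1, function(r) max(c(r, 0)))
  best <- new.env()
  best$score <- -1; best$match <- rep(NA_integer_, nA)
  cur <- rep(NA_integer_, nA)
  rec <- function(i, used, acc) {
    if (acc + sum(row_max[seq(i, length.out = nA - i + 1)]) < best$score - 1e-12)
      return()
    if (i > nA) {
      if (acc > best$score + 1e-12) {
        best$score <- acc
        best$match <- cur
      }
      return()
    }
    for (j in seq_len(nB)) {
      if (!used[j] && S[i, j] > 0) {
        used[j] <- TRUE; cur[i] <<- j
        rec(i + 1, used, acc + S[i, j])
        used[j] <- FALSE; cur[i] <<- NA_integer_
      }
    }
    rec(i + 1, used, acc)
  }
  rec(1, rep(FALSE, nB), 0)
  list(score = max(best$score, 0), match = best$match)
}

# bipartitions by edge removal on the raw edge list (adjacency DFS)
oracle_splits <- function(tree) {
  tree <- ape::unroot(structure(tree, class = "phylo"))
  n <- length(tree$tip.label)
  adj <- vector("list", max(tree$edge))
  for (r in seq_len(nrow(tree$edge))) {
    u <- tree$edge[r, 1]; v <- tree$edge[r, 2]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  ref <- sort(tree$tip.label)[1]
  keys <- character(0)
  for (r in seq_len(nrow(tree$edge))) {
    u <- tree$edge[r, 1]; v <- tree$edge[r, 2]
    # DFS from v avoiding the removed edge
    stack <- v; seen <- c(u, v); leaves <- integer(0)
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (x <= n) leaves <- c(leaves, x)
      for (y in adj[[x]]) if (!y %in% seen) {
        seen <- c(seen, y); stack <- c(stack, y)
      }
    }
    side <- tree$tip.label[leaves]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_splits(t1); b2 <- oracle_splits(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}
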
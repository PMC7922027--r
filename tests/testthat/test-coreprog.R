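# Progressive core aggregation: consensus models, guide clustering,
# core extraction and subcore structure.

noise_free_family <- function(seed = 31) {
  # zero noise, no substitutions/indels: leaves are rigid copies
  simulate_fold_family(n_leaves = 4, seed = seed, coord_sigma = 0,
                       sub_rate = 0, indel_rate = 0)
}

deletion_pair <- function(del_len = 10, seed = 33) {
  anc <- make_ancestor_fold(seed = seed, loop_len = 12, id = "full")
  runs <- corephylo:::loop_runs(anc$ss)
  runs <- runs[runs[, "end"] - runs[, "start"] + 1 >= del_len &
                 runs[, "start"] > 1, , drop = FALSE]
  r <- runs[1, ]
  drop <- r["start"]:(r["start"] + del_len - 1)
  reduced <- structure_model("reduced", anc$ca[-drop, , drop = FALSE],
                             anc$aa[-drop], ss = anc$ss[-drop])
  list(full = anc, reduced = reduced, dropped = drop)
}

test_that("leaf consensus is the member structure itself", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  leaf <- corephylo:::new_guide_leaf(fam$models[[1]])
  cm <- consensus_model(leaf)
  expect_identical(cm$ca, fam$models[[1]]$ca)
  expect_identical(cm$aa, fam$models[[1]]$aa)
})

test_that("consensus of two identical structures is the shared trace", {
  fam <- noise_free_family()
  a <- fam$models[[1]]
  b <- a; b$id <- "twin"
  root <- build_guide_clustering(list(a, b))
  cm <- consensus_model(root)
  expect_equal(nrow(cm$ca), length(a$aa))
  expect_equal(cm$ca, a$ca, tolerance = 1e-9)
  expect_true(all(root$spread < 1e-9))
})

test_that("consensus of offset copies lies midway between them", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  a <- fam$models[[1]]
  b <- a
  b$id <- "noisy"
  noise <- corephylo:::with_local_seed(3,
    matrix(rnorm(length(a$ca), 0, 0.4), ncol = 3))
  b$ca <- a$ca + noise
  root <- build_guide_clustering(list(a, b))
  cm <- consensus_model(root)
  mid <- a$ca + noise / 2
  expect_lt(max(abs(cm$ca - mid[root$columns[, a$id], ])), 0.4)
})

test_that("the most similar pair merges first", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  a <- fam$models[[1]]
  a2 <- a
  a2$id <- "near_twin"
  a2$ca <- a$ca + corephylo:::with_local_seed(5,
    matrix(rnorm(length(a$ca), 0, 0.1), ncol = 3))
  b <- make_ancestor_fold(seed = 99, id = "other_fold")
  root <- build_guide_clustering(list(a, a2, b))
  first <- root$children[[which(vapply(root$children, function(ch)
    length(ch$member_ids) == 2, logical(1)))]]
  expect_setequal(first$member_ids, c(a$id, a2$id))
})

test_that("two identical models share every residue in the core", {
  fam <- noise_free_family()
  a <- fam$models[[1]]
  b <- a; b$id <- "twin"
  root <- build_guide_clustering(list(a, b))
  core <- extract_core(root, list(a, b) |> setNames(c(a$id, "twin")))
  expect_equal(core$size, length(a$aa))
  expect_lt(core$avg_rmsd, 1e-9)
})

test_that("a loop deletion removes exactly the deleted columns from the core", {
  dp <- deletion_pair()
  root <- build_guide_clustering(list(dp$full, dp$reduced))
  core <- extract_core(root)
  expect_equal(core$size, length(dp$full$aa) - length(dp$dropped))
  expect_false(any(core$columns[, "full"] %in% dp$dropped))
})

test_that("core columns match ground truth on families with indels", {
  fam <- simulate_fold_family(n_leaves = 4, seed = 41, coord_sigma = 0,
                              sub_rate = 0, indel_rate = 2, indel_len = 4)
  expect_lt(length(fam$truth$ungapped), length(fam$ancestor$aa))
  root <- build_guide_clustering(fam$models)
  core <- extract_core(root)
  ids <- names(fam$models)
  col_uid <- vapply(seq_len(core$size), function(ci) {
    u <- vapply(ids, function(id)
      fam$truth$uids[[id]][core$columns[ci, id]], numeric(1))
    if (length(unique(u)) == 1) u[1] else NA_real_
  }, numeric(1))
  expect_setequal(col_uid[!is.na(col_uid)], fam$truth$ungapped)
  expect_false(anyNA(col_uid))
})

test_that("average core rmsd matches a direct noise simulation", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  a <- fam$models[[1]]
  sig <- 0.3
  measured <- vapply(1:5, function(s) {
    b <- a
    b$id <- "noisy"
    b$ca <- a$ca + corephylo:::with_local_seed(s,
      matrix(rnorm(length(a$ca), 0, sig), ncol = 3))
    root <- build_guide_clustering(list(a, b))
    extract_core(root)$avg_rmsd
  }, numeric(1))
  # direct simulation of the same quantity: both members deviate from
  # the midpoint by half the noise vector
  expected <- mean(vapply(1:200, function(s) {
    nz <- matrix(rnorm(3 * length(fam$models[[1]]$aa), 0, sig), ncol = 3)
    sqrt(mean(rowSums((nz / 2)^2)))
  }, numeric(1)))
  expect_equal(mean(measured), expected, tolerance = 0.15)
})

test_that("rigid copies give zero average core rmsd", {
  fam <- noise_free_family()
  models <- fam$models
  root <- build_guide_clustering(models)
  core <- extract_core(root)
  # leaves are exact rigid copies up to the 0.001-A coordinate rounding
  expect_lt(core$avg_rmsd, 5e-3)
  expect_equal(core$size, length(fam$ancestor$aa))
})

test_that("the root core is never larger than any subcore or leaf", {
  fam <- shared_family(n_leaves = 6, seed = 11)
  root <- build_guide_clustering(fam$models)
  nodes <- corephylo:::collect_internal_nodes(root)
  sizes <- vapply(nodes, function(nd) nrow(nd$columns), integer(1))
  expect_true(all(nrow(root$columns) <= sizes))
  expect_true(all(sizes <= min(vapply(fam$models, function(m)
    length(m$aa), integer(1)))))
})

test_that("subcore report lists last merges first with member containment", {
  fam <- shared_family(n_leaves = 6, seed = 11)
  root <- build_guide_clustering(fam$models)
  rep2 <- subcore_report(root, k = 2)
  expect_equal(rep2$node_id[1], root$node_id)
  expect_true(all(rep2$n_columns >= root$columns |> nrow()))
  all_nodes <- subcore_report(root, k = 100)
  expect_equal(nrow(all_nodes), length(corephylo:::collect_internal_nodes(root)))
  # two-model dataset, k = 1: single row with the core size
  a <- fam$models[[1]]; b <- fam$models[[2]]
  r2 <- build_guide_clustering(list(a, b))
  rep1 <- subcore_report(r2, k = 1)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$n_columns, extract_core(r2)$size)
})

test_that("the core is invariant under rigid motion and input order", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  models <- fam$models
  core1 <- extract_core(build_guide_clustering(models))
  moved <- models
  moved[[2]] <- rigid_copy(moved[[2]], id = moved[[2]]$id,
                           axis = c(3, 1, -2), angle = 0.8,
                           shift = c(12, -5, 3))
  core2 <- extract_core(build_guide_clustering(rev(moved)))
  ids <- sort(names(models))
  key <- function(core) {
    m <- core$columns[, ids, drop = FALSE]
    sort(apply(m, 1, paste, collapse = ","))
  }
  expect_identical(key(core1), key(core2))
})

test_that("removing a structure from a noise-free family never shrinks the core", {
  fam <- simulate_fold_family(n_leaves = 5, seed = 43, coord_sigma = 0,
                              sub_rate = 0, indel_rate = 2, indel_len = 4)
  full_core <- extract_core(build_guide_clustering(fam$models))
  for (drop in names(fam$models)[1:2]) {
    sub <- fam$models[setdiff(names(fam$models), drop)]
    sub_core <- extract_core(build_guide_clustering(sub))
    expect_gte(sub_core$size, full_core$size)
  }
})

test_that("guide clustering exports parseable Newick", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  root <- build_guide_clustering(fam$models)
  tr <- ape::read.tree(text = guide_to_newick(root))
  expect_setequal(tr$tip.label, names(fam$models))
})
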
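# Core-restricted scores, the score-to-distance conversion and the
# Fitch-Margoliash least-squares tree.

toy_core_pair <- function() {
  # 5-residue toy structures with identical coordinates, so the optimal
  # superposition is the identity and every geometric term is exactly 1
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0),
              c(0, 3.8, 0), c(1.9, 1.9, 3))
  a <- structure_model("A", ca, c("D", "K", "L", "S", "P"),
                       ss = c("H", "H", "E", "C", "C"))
  b <- structure_model("B", ca, c("E", "R", "F", "A", "G"),
                       ss = c("H", "E", "E", "C", "H"))
  cols <- cbind(A = 1:5, B = 1:5)
  core <- structure(list(columns = cols, column_id = paste0("C", 1:5),
                         consensus_ca = ca, spread = rep(0, 5), size = 5,
                         avg_rmsd = 0), class = "core_set")
  list(a = a, b = b, core = core)
}

test_that("core self-score equals the core size exactly", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  root <- build_guide_clustering(fam$models)
  core <- extract_core(root)
  for (m in fam$models)
    expect_identical(core_score(m, m, core), as.numeric(core$size))
})

test_that("rigid copies attain the core size within 1e-6", {
  dp_fam <- shared_family(n_leaves = 4, seed = 21)
  a <- dp_fam$models[[1]]
  b <- rigid_copy(a, id = "moved")
  cols <- cbind(seq_along(a$aa), seq_along(a$aa))
  colnames(cols) <- c(a$id, "moved")
  core <- structure(list(columns = cols,
                         column_id = paste0("C", seq_along(a$aa)),
                         consensus_ca = a$ca, spread = rep(0, length(a$aa)),
                         size = length(a$aa), avg_rmsd = 0),
                    class = "core_set")
  s <- core_score(a, b, core)
  expect_equal(s, core$size, tolerance = 1e-6)
})

test_that("a 5-column toy core scores as the term-by-term hand evaluation", {
  tc <- toy_core_pair()
  # d = 0 in every column (identical coordinates); per column:
  # geometry 0.6; ss matches in columns 1, 3, 4 (+0.25); amino-acid
  # classes: D/E both negative (+0.15), K/R both positive (+0.15),
  # L/F both hydrophobic (+0.15), S/A polar vs hydrophobic (0),
  # P/G special vs polar (0)
  hand <- 5 * 0.6 + 3 * 0.25 + 3 * 0.15
  expect_equal(core_score(tc$a, tc$b, tc$core), hand, tolerance = 1e-9)
})

test_that("score_to_distance implements D = -(S_ab - min(S_aa, S_bb))", {
  expect_identical(score_to_distance(231, 231, 231), 0)
  expect_identical(score_to_distance(200, 231, 225), 25)
  expect_error(score_to_distance(240, 231, 225), "self-score")
})

test_that("core distances are a symmetric dissimilarity tracking divergence", {
  fam <- shared_family(n_leaves = 6, seed = 11)
  root <- build_guide_clustering(fam$models)
  core <- extract_core(root)
  d <- core_distance_matrix(fam$models, core)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  # distances grow with true path separation
  truth <- ape::cophenetic.phylo(fam$truth$tree)[rownames(d), colnames(d)]
  ut <- upper.tri(d)
  expect_gt(cor(d[ut], truth[ut], method = "spearman"), 0.6)
})

test_that("three taxa have the closed-form star solution", {
  d <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- fitch_margoliash(d)
  expect_equal(attr(tr, "fit_residual"), 0, tolerance = 1e-12)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], (5 + 9 - 8) / 2)
  expect_equal(bl[["B"]], (5 + 8 - 9) / 2)
  expect_equal(bl[["C"]], (9 + 8 - 5) / 2)
})

test_that("additive matrices are recovered exactly (topology and lengths)", {
  for (s in 1:6) {
    am <- additive_matrix(sample(4:7, 1), seed = 100 + s)
    fit <- fitch_margoliash(am$d)
    expect_lt(attr(fit, "fit_residual"), 1e-9)
    expect_equal(rf_distance(fit, am$tree), 0)
    p <- ape::cophenetic.phylo(fit)[rownames(am$d), colnames(am$d)]
    expect_equal(p, am$d, tolerance = 1e-6)
  }
})

test_that("equidistant taxa give equal terminal and zero internal branches", {
  n <- 5
  labs <- LETTERS[1:n]
  d <- matrix(1, n, n, dimnames = list(labs, labs)); diag(d) <- 0
  fit <- fitch_margoliash(d)
  term <- fit$edge.length[fit$edge[, 2] <= n]
  internal <- fit$edge.length[fit$edge[, 2] > n]
  expect_equal(term, rep(0.5, n), tolerance = 1e-9)
  expect_true(all(abs(internal) < 1e-9))
})

test_that("the NNI hill climb never ends worse than its NJ start", {
  set.seed(8)
  n <- 10
  labs <- sprintf("T%02d", 1:n)
  d <- as.matrix(dist(matrix(rnorm(n * 4), n, 4)))
  dimnames(d) <- list(labs, labs)
  fit <- fitch_margoliash(d, exhaustive_max = 8)
  ow <- corephylo:::fm_objective_weights(d, labs)
  nj_fit <- corephylo:::fm_fit_topology(ape::unroot(ape::nj(d)), d, ow$w, ow$pairs)
  expect_lte(attr(fit, "fit_residual"), nj_fit$residual + 1e-12)
})

test_that("the fitted tree is invariant to label order permutation", {
  am <- additive_matrix(6, seed = 77)
  fit1 <- fitch_margoliash(am$d)
  perm <- corephylo:::with_local_seed(3, sample(rownames(am$d)))
  fit2 <- fitch_margoliash(am$d[perm, perm])
  expect_equal(rf_distance(fit1, fit2), 0)
  p1 <- ape::cophenetic.phylo(fit1)[perm, perm]
  p2 <- ape::cophenetic.phylo(fit2)[perm, perm]
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("rooting at the outgroup is reversible and preserves bipartitions", {
  am <- additive_matrix(7, seed = 55)
  fit <- fitch_margoliash(am$d)
  rooted <- root_at_outgroup(fit, "T01")
  expect_true(ape::is.rooted(structure(rooted, class = "phylo")))
  expect_equal(rf_distance(rooted, fit), 0)
  expect_identical(sort(oracle_splits(rooted)), sort(oracle_splits(fit)))
  expect_error(root_at_outgroup(fit, "nope"), "not a leaf")
  # 4-leaf case: the root's children are the outgroup and the rest
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,Out:2):1);")
  r4 <- root_at_outgroup(tr4, "Out")
  kids <- r4$edge[r4$edge[, 1] == ape::Ntip(r4) + 1, 2]
  expect_true(match("Out", r4$tip.label) %in% kids)
})

test_that("distance matrices round-trip through TSV and PHYLIP is readable", {
  am <- additive_matrix(5, seed = 13)
  p <- tempfile(fileext = ".tsv")
  write_distance_matrix(am$d, p)
  back <- read_distance_matrix(p)
  expect_equal(back, am$d, tolerance = 1e-6)
  # PHYLIP square format
  p2 <- tempfile()
  con <- file(p2, "w")
  writeLines(as.character(nrow(am$d)), con)
  for (i in seq_len(nrow(am$d)))
    writeLines(paste(c(rownames(am$d)[i],
                       formatC(am$d[i, ], format = "f", digits = 6)),
                     collapse = "  "), con)
  close(con)
  back2 <- read_distance_matrix(p2)
  expect_equal(back2, am$d, tolerance = 1e-5)
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(fitch_margoliash(d), "symmetric")
  d2 <- matrix(c(0, -1, -1, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(fitch_margoliash(d2), "non-negative")
})
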
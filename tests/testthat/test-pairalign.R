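# Kabsch superposition, the residue similarity, seeding and the full
# sequence-order-independent pairwise alignment.

test_that("kabsch recovers exact rigid motions and rejects degenerate input", {
  set.seed(42)
  A <- matrix(rnorm(30, sd = 4), 10, 3)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-9)

  R <- corephylo:::rotation_from_axis_angle(c(0, 0, 1), pi / 2)
  tt <- c(1, 2, 3)
  B <- corephylo:::apply_rigid(A, t(R), -as.numeric(t(R) %*% tt)) # R B + t = A
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(fit$translation, tt, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "N >= 3")
})

test_that("kabsch rmsd matches an axis-angle grid-search oracle", {
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(rnorm(30, sd = 3), 10, 3)
    B <- matrix(rnorm(30, sd = 3), 10, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, oracle_grid_rmsd(A, B),
                 tolerance = 1e-3)
  }
})

test_that("weights shift the superposition toward heavy points", {
  set.seed(7)
  A <- matrix(rnorm(30, sd = 4), 10, 3)
  B <- A
  B[1, ] <- B[1, ] + c(8, 0, 0)   # one gross outlier
  w <- c(0.001, rep(1, 9))
  unw <- kabsch_superpose(A, B)
  wt <- kabsch_superpose(A, B, weights = w)
  res <- function(fit) sqrt(rowSums((A - corephylo:::apply_rigid(
    B, fit$rotation, fit$translation))^2))
  expect_lt(mean(res(wt)[-1]), mean(res(unw)[-1]))
})

test_that("residue similarity follows the three-term formula with hard cutoff", {
  p <- align_params()
  expect_equal(residue_similarity(0, TRUE, TRUE, p), 1)
  expect_equal(residue_similarity(p$d_max + 0.01, TRUE, TRUE, p), 0)
  expect_equal(residue_similarity(2, TRUE, FALSE, p),
               0.6 * exp(-0.5) + 0.25)
  expect_equal(residue_similarity(2, FALSE, TRUE, p),
               0.6 * exp(-0.5) + 0.15)
  # monotone decreasing in d below the cutoff
  d <- seq(0, p$d_max, length.out = 50)
  s <- residue_similarity(d, TRUE, TRUE, p)
  expect_true(all(diff(s) < 0))
})

test_that("parameter validation enforces the documented invariants", {
  expect_error(align_params(w_geom = 0.5, w_ss = 0.2, w_aa = 0.2), "sum to 1")
  expect_error(align_params(sigma = 3, d_max = 5), "2 \\* sigma")
  expect_error(align_params(sigma = 0), "sigma")
})

test_that("seed superpositions: self gives a zero-rmsd seed, list sorted ascending", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  a <- fam$models[[1]]
  seeds <- seed_superpositions(a, a)
  expect_lt(seeds$frag_rmsd[1], 1e-9)
  expect_true(!is.unsorted(seeds$frag_rmsd))

  b <- fam$models[[2]]
  s2 <- seed_superpositions(a, b)
  expect_true(!is.unsorted(s2$frag_rmsd))
  # retained rotations pairwise differ by more than 5 degrees
  k <- dim(s2$rotations)[3]
  if (k > 1) {
    angs <- combn(k, 2, function(ij)
      corephylo:::rotation_angle_deg(s2$rotations[, , ij[1]],
                                     s2$rotations[, , ij[2]]))
    expect_true(all(angs > 5))
  }
})

test_that("a circular permutation still yields a zero-rmsd seed", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  a <- fam$models[[1]]
  cut <- which(a$ss == "C")
  cut <- cut[which.min(abs(cut - length(a$aa) / 2))]
  b <- apply_circular_permutation(a, cut)
  b$id <- "perm"
  seeds <- seed_superpositions(a, b)
  expect_lt(seeds$frag_rmsd[1], 1e-9)
})

test_that("optimal assignment equals exhaustive enumeration on small matrices", {
  set.seed(5)
  for (rep in 1:25) {
    nA <- sample(3:8, 1); nB <- sample(3:8, 1)
    S <- matrix(runif(nA * nB), nA, nB)
    S[S < runif(1, 0.2, 0.6)] <- 0
    got <- solve_assignment(S)
    want <- oracle_assignment(S)
    got_score <- sum(S[cbind(which(!is.na(got)), got[!is.na(got)])])
    expect_equal(got_score, want$score, tolerance = 1e-9)
    # with continuous entries the optimum is a.s. unique
    expect_equal(got[!is.na(got)], want$match[!is.na(want$match)])
  }
})

test_that("self-alignment scores exactly the structure length", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  a <- fam$models[[1]]
  co <- align_pair(a, a)
  n <- length(a$aa)
  expect_identical(co$score, as.numeric(n))
  expect_equal(nrow(co$pairs), n)
  expect_identical(co$rmsd, 0)
})

test_that("alignment is exact on rigid copies and symmetric in its inputs", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  a <- fam$models[[1]]
  b <- rigid_copy(a, id = "zz_moved")
  co <- align_pair(a, b)
  n <- length(a$aa)
  expect_equal(co$score, n, tolerance = 1e-6)
  expect_lt(co$rmsd, 1e-6)
  expect_equal(co$pairs[, 1], co$pairs[, 2])

  co_ba <- align_pair(b, a)
  expect_identical(co$score, co_ba$score)  # canonical ordering: exact
  expect_equal(co_ba$pairs[, c(2, 1)], co$pairs)
})

test_that("score never exceeds the shorter structure and no-overlap gives score 0", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  a <- fam$models[[1]]; b <- fam$models[[2]]
  co <- align_pair(a, b)
  expect_lte(co$score, min(length(a$aa), length(b$aa)))
  # structures too far apart for any candidate pair: defined empty result
  far <- b
  far$id <- "far"
  far$ca <- far$ca / 50   # collapse to a tiny blob: no fragment matches
  co2 <- align_pair(a, far)
  expect_true(co2$score >= 0)
  expect_true(nrow(co2$pairs) == 0 || co2$score <= min(length(a$aa), length(far$aa)))
})

test_that("alignment is invariant under rigid motions of either input", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  a <- fam$models[[1]]; b <- fam$models[[2]]
  co <- align_pair(a, b)
  b2 <- rigid_copy(b, id = b$id, axis = c(2, -1, 1), angle = 2.2,
                   shift = c(-10, 4, 7))
  co2 <- align_pair(a, b2)
  expect_equal(co2$score, co$score, tolerance = 1e-3 * length(a$aa))
  expect_equal(co2$pairs, co$pairs)
})

test_that("a circularly permuted copy recovers its true correspondences", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  a <- fam$models[[1]]
  n <- length(a$aa)
  cut <- which(a$ss == "C")
  cut <- cut[which.min(abs(cut - n / 2))]
  b <- apply_circular_permutation(a, cut)
  b$id <- "perm"
  co <- align_pair(a, b)
  idx <- c(cut:n, seq_len(cut - 1))
  truemap <- match(seq_len(n), idx)
  expect_gte(mean(co$pairs[, 2] == truemap[co$pairs[, 1]]), 0.95)
  expect_gte(co$score, 0.98 * n)
})

test_that("expected score degrades monotonically with coordinate noise", {
  fam <- shared_family(n_leaves = 4, seed = 21)
  a <- fam$models[[1]]
  mean_scores <- vapply(c(0.3, 1.0, 2.0), function(sig) {
    mean(vapply(1:5, function(s) {
      b <- a
      b$id <- "noisy"
      b$ca <- a$ca + corephylo:::with_local_seed(s * 100 + round(sig * 10),
        matrix(rnorm(length(a$ca), 0, sig), ncol = 3))
      align_pair(a, b)$score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_scores) < 0))
})
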
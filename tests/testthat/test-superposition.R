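test_that("global alignment reproduces hand-checked scores and identities", {
  # identical sequences: everything pairs, identity 1
  al <- pairwise_align("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLMNPQRSTVWY")
  expect_equal(al$identity_fraction, 1.0)
  expect_equal(nrow(al$pairs), 20L)

  # one substitution, no gaps; BLOSUM62 column sums: 4+9+6+5+3+6 = 33
  al2 <- pairwise_align("ACDEFG", "ACDEYG")
  expect_equal(al2$score, 33)
  expect_equal(al2$identity_fraction, 5 / 6)
  expect_equal(al2$pairs[, "a"], 1:6)
  expect_equal(al2$pairs[, "b"], 1:6)

  # pairs strictly increase in both coordinates (no crossings)
  set.seed(1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:5) {
    s1 <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    s2 <- paste(sample(aa, 35, replace = TRUE), collapse = "")
    p <- pairwise_align(s1, s2)$pairs
    expect_true(all(diff(p[, 1]) > 0) && all(diff(p[, 2]) > 0))
  }
})

test_that("structure-aware alignment reduces to standard NW at zero bonus", {
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:6) {
    n1 <- sample(20:40, 1); n2 <- sample(20:40, 1)
    s1 <- paste(sample(aa, n1, replace = TRUE), collapse = "")
    s2 <- paste(sample(aa, n2, replace = TRUE), collapse = "")
    ours <- align_with_ss(s1, s2, strrep("C", n1), strrep("C", n2),
                          ss_bonus = 0, gap_open = 11, gap_extend = 1)
    ref <- pairwise_align(s1, s2, gap_open = 11, gap_extend = 1)
    expect_equal(ours$score, ref$score)
  }
  # end-gap-free mode recovers the exact correspondence of a fragment
  full <- paste(sample(aa, 40, replace = TRUE), collapse = "")
  frag <- substr(full, 8, 31)
  tr_o <- align_with_ss(frag, full, strrep("H", 24), strrep("H", 40),
                        ss_bonus = 0, type = "overlap")
  expect_equal(tr_o$pairs[, "a"], 1:24)
  expect_equal(tr_o$pairs[, "b"], 8:31)
  expect_equal(tr_o$identity_fraction, 1.0)
  bo <- pairwise_align(frag, full, type = "overlap")
  expect_equal(bo$pairs, tr_o$pairs, ignore_attr = TRUE)
  # a matching secondary-structure string can rescue a correspondence
  tr <- align_with_ss("AAAA", "AAAA", "HHHH", "HHHH", ss_bonus = 2)
  expect_equal(tr$score, 4 * (4 + 2))   # per column: blosum A/A + bonus
})

test_that("three-state assignment labels ideal helices H", {
  b <- make_helical_bundle(n_helices = 1L, helix_len = 15L, seed = 1L)
  ca <- b$atom[b$atom$elety == "CA", c("x", "y", "z")]
  ss <- assign_ss3(as.matrix(ca))
  expect_true(all(ss == "H"))
  # an extended chain is not helical
  line <- cbind(seq(0, by = 3.8, length.out = 10), 0, 0)
  expect_true(all(assign_ss3(line) %in% c("E", "C")))
})

test_that("kabsch recovers exact transforms and rejects degenerate input", {
  set.seed(42)
  X <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch(X, X)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch(X, X)$transform$rotation, diag(3), tolerance = 1e-9)

  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Y <- X %*% t(R90) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  fit <- kabsch(X, Y)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$transform$rotation %*% R90, diag(3), tolerance = 1e-9)
  # orthonormality and det = +1
  R <- fit$transform$rotation
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-8)
  expect_equal(det(R), 1, tolerance = 1e-8)

  expect_error(kabsch(X[1:2, ], Y[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "degenerate")
})

test_that("kabsch is optimal against a 1-degree rotation-grid oracle on small point sets", {
  set.seed(9)
  for (k in 1:5) {
    n <- sample(4:6, 1)
    X <- matrix(rnorm(3 * n), ncol = 3)
    Y <- X + matrix(rnorm(3 * n, sd = 0.5), ncol = 3)
    fit <- kabsch(X, Y)
    expect_lte(fit$rmsd, grid_fit_rmsd(X, Y) + 1e-9)
    expect_gte(fit$rmsd, 0.05)   # noisy clouds cannot fit perfectly
    # and agrees with an independent least-squares fitter
    ref <- bio3d::fit.xyz(as.vector(t(X)), as.vector(t(Y)),
                          fixed.inds = 1:(3 * n), mobile.inds = 1:(3 * n))
    ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - X)^2)))
    expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-6)
  }
})

test_that("superposition recovers planted transforms and gates the mode on identity", {
  b <- make_helical_bundle(seed = 21L)
  # structure vs itself
  self <- superpose(b, b)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$n_pairs_retained, self$n_pairs_initial)

  # noise-free planted transform: exact recovery
  hm0 <- make_homolog(b, identity = 1, sigma = 0, seed = 3L)
  s0 <- superpose(b, hm0$structure)
  expect_lt(norm(s0$transform$rotation - hm0$transform$rotation, "F"), 1e-6)
  expect_lt(s0$rmsd, 1e-8)

  # 40%-mutated, moved, noisy copy: sequence-dependent mode, rmsd <= 3 sigma
  hm <- make_homolog(b, identity = 0.6, sigma = 0.3, seed = 5L)
  s1 <- superpose(b, hm$structure)
  expect_equal(s1$mode, "sequence_dependent")
  expect_lt(s1$rmsd, 3 * 0.3)
  ang <- acos(pmin(1, (sum(diag(t(s1$transform$rotation) %*%
                                  hm$transform$rotation)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 2)

  # low identity flips auto mode to sequence-independent
  hm25 <- make_homolog(b, identity = 0.25, sigma = 0.2, seed = 13L)
  s25 <- superpose(b, hm25$structure)
  expect_equal(s25$mode, "sequence_independent")
  expect_lt(s25$rmsd, 3 * 0.2 + 0.2)

  # transform invariants on every result
  for (s in list(self, s0, s1, s25)) {
    R <- s$transform$rotation
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
    expect_gte(s$n_cycles, 1L)
    expect_lte(s$n_pairs_retained, s$n_pairs_initial)
  }
})

test_that("rejection never increases the reported RMSD and the fit is direction-symmetric", {
  b <- make_helical_bundle(seed = 31L)
  hm <- make_homolog(b, identity = 0.5, sigma = 0.6, seed = 13L)
  with_rej <- superpose(b, hm$structure)
  without <- superpose(b, hm$structure, reject_cutoff = Inf)
  expect_lte(with_rej$rmsd, without$rmsd + 1e-9)

  # direction symmetry over an identical retained pair set
  hm2 <- make_homolog(b, identity = 1, sigma = 0.3, seed = 17L)
  fwd <- superpose(b, hm2$structure, reject_cutoff = Inf)
  rev <- superpose(hm2$structure, b, reject_cutoff = Inf)
  expect_equal(fwd$n_pairs_retained, rev$n_pairs_retained)
  expect_equal(fwd$rmsd, rev$rmsd, tolerance = 1e-6)

  # too few surviving pairs is a clean failure
  expect_error(superpose(b, hm$structure, reject_cutoff = 1e-9, max_cycles = 1L),
               NA)   # floor rule keeps the last fittable set instead of failing
})
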
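test_that("helical bundles have ideal helix geometry and are seed-reproducible", {
  one <- make_helical_bundle(n_helices = 1L, helix_len = 10L, seed = 2L)
  ca <- as.matrix(one$atom[one$atom$elety == "CA", c("x", "y", "z")])
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.8) < 0.1))

  b1 <- make_helical_bundle(seed = 7L)
  b2 <- make_helical_bundle(seed = 7L)
  expect_identical(b1$atom, b2$atom)
  expect_false(identical(make_helical_bundle(seed = 8L)$atom, b1$atom))

  # a 9x25 bundle is wider than any single helix
  rg <- function(st) {
    x <- as.matrix(st$atom[, c("x", "y", "z")])
    sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
  }
  expect_gt(rg(b1), rg(one))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123); a <- rnorm(1)
  set.seed(123); invisible(make_helical_bundle(seed = 99L)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("homolog derivation plants verifiable ground truth", {
  b <- make_helical_bundle(seed = 12L)
  # trivial case: same sequence, no noise, no motion
  hm0 <- make_homolog(b, identity = 1, sigma = 0, angle = 0,
                      translation = c(0, 0, 0), seed = 1L)
  prot <- hm0$structure$atom[hm0$structure$atom$type == "ATOM", ]
  expect_equal(prot$x, b$atom$x, tolerance = 1e-12)
  expect_equal(prot$resid, b$atom$resid)

  # requested identity is honoured
  hm <- make_homolog(b, identity = 0.6, sigma = 0.2, seed = 3L)
  sa <- strsplit(extract_sequence(b), "")[[1]]
  sb <- strsplit(extract_sequence(hm$structure), "")[[1]]
  expect_equal(mean(sa == sb), 0.6, tolerance = 0.01)

  # planted pocket satisfies the construction margins in the query frame
  neigh <- sitegraft:::ligand_neighbourhood(b, hm$ligand_query_frame, Inf)
  inp <- neigh$resno %in% hm$pocket
  expect_lte(max(neigh$min_dist[inp]), 3.5 + 1e-6)
  expect_gte(min(neigh$min_dist[!inp]), 5.3 - 1e-6)

  # reproducibility
  hm2 <- make_homolog(b, identity = 0.6, sigma = 0.2, seed = 3L)
  expect_identical(hm2$structure$atom, hm$structure$atom)

  # an unplaceable pocket (adjacent surface residues) is an error
  expect_error(make_homolog(b, pocket = c(1L, 2L, 3L), seed = 1L),
               "not mutually placeable")
})

test_that("random confidence profiles have low termini around a confident core", {
  for (seed in 1:5) {
    p <- make_plddt_profile(60L, seed = seed)
    expect_length(p, 60L)
    expect_lt(p[1L], 90); expect_lt(p[60L], 90)
    expect_true(any(p >= 91))
    expect_identical(p, make_plddt_profile(60L, seed = seed))
  }
})

test_that("the toy catalog is deterministic with a symmetric expected matrix", {
  t1 <- make_toy_catalog(); t2 <- make_toy_catalog()
  expect_identical(t1, t2)
  m <- t1$expected_tanimoto
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 10L))
  expect_equal(m["MTH", "ETH"], 0.5)      # {160} vs {149,160}
  expect_equal(m["MG", "HOH"], 0)         # disjoint key sets
})

test_that("the fixture set writes every pipeline input with reproducible ground truth", {
  dir <- case_fixture_dir()
  files <- c("query_model.pdb", "4OD4.pdb", "4OD5.pdb", "4TQ3.pdb",
             "6M31.pdb", "8DJM.pdb", "7Q21.pdb", "7E1V.pdb",
             "toy_catalog.tsv", "ground_truth.json",
             file.path("variants", c("var_a.pdb", "var_b.pdb", "var_c.pdb")))
  expect_true(all(file.exists(file.path(dir, files))))

  truth <- case_fixture_truth()
  expect_equal(truth$query$trim_start, 11L)
  expect_named(truth$homologs,
               c("4TQ3", "4OD5", "6M31", "8DJM", "7Q21"))

  # regenerating under the same seed reproduces the files byte for byte
  dir2 <- file.path(tempdir(), "fixset-again")
  write_fixture_set(dir2, seed = 11L)
  expect_identical(readLines(file.path(dir2, "4TQ3.pdb")),
                   readLines(file.path(dir, "4TQ3.pdb")))
  expect_identical(readLines(file.path(dir2, "ground_truth.json")),
                   readLines(file.path(dir, "ground_truth.json")))
})
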
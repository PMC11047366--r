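test_that("PDB reading builds the residue hierarchy and resolves altlocs by occupancy", {
  st <- read_structure(write_three_residue_pdb())
  expect_equal(length(unique(st$atom$chain)), 1L)
  rt <- residue_table(st)
  expect_equal(nrow(rt), 3L)
  expect_equal(rt$resid, c("ALA", "GLY", "SER"))
  expect_equal(extract_sequence(st), "AGS")

  # altloc A (occ 0.6) vs B (occ 0.4): only A retained
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, " CA ", "ALA", "A", 1, 0, 0, 0, occ = 0.6, alt = "A"),
    pdb_atom_line(2, " CA ", "ALA", "A", 1, 1, 0, 0, occ = 0.4, alt = "B"),
    pdb_atom_line(3, " CA ", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(4, " CA ", "SER", "A", 3, 7.6, 0, 0),
    "END"), f)
  st2 <- read_structure(f)
  expect_equal(nrow(st2$atom), 3L)
  expect_equal(st2$atom$x[1L], 0)

  # selenomethionine maps to M; unknown residues to X
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, " CA ", "MSE", "A", 1, 0, 0, 0),
    pdb_atom_line(2, " CA ", "XYZ", "A", 2, 3.8, 0, 0),
    "END"), f2)
  expect_equal(extract_sequence(read_structure(f2)), "MX")

  expect_error(read_structure(tempfile(fileext = ".xyz")), "not found")
  f3 <- tempfile(fileext = ".xyz"); writeLines("x", f3)
  expect_error(read_structure(f3), "unknown structure format")
})

test_that("write/read round trip preserves atoms, numbering and B-factors", {
  b <- make_helical_bundle(n_helices = 3L, helix_len = 12L, seed = 3L,
                           plddt = seq(30, 99, length.out = 36L))
  f <- tempfile(fileext = ".pdb")
  write_structure(b, f)
  back <- read_structure(f)
  expect_equal(nrow(back$atom), nrow(b$atom))
  expect_equal(back$atom$resno, b$atom$resno)
  expect_equal(back$atom$elety, b$atom$elety)
  expect_equal(round(back$atom$b, 2), round(b$atom$b, 2))
  expect_equal(back$atom$x, round(b$atom$x, 3))
})

test_that("confidence trimming removes exactly the low-confidence termini", {
  # unchanged when everything is confident
  b <- make_helical_bundle(n_helices = 2L, helix_len = 20L, seed = 2L, plddt = 95)
  expect_equal(nrow(trim_by_confidence(b)$atom), nrow(b$atom))

  # 100-residue model, low first 10 -> residues 11..100 retained
  p <- c(rep(50, 10L), rep(95, 90L))
  m <- make_helical_bundle(n_helices = 4L, helix_len = 25L, seed = 2L, plddt = p)
  tr <- trim_by_confidence(m, 90)
  rt <- residue_table(tr)
  expect_equal(range(rt$resno), c(11L, 100L))

  # everything below threshold is fatal
  expect_error(trim_by_confidence(m, 99.5), "empty model")
})

test_that("confidence trimming is contiguous, idempotent and preserves interior dips", {
  for (seed in 1:8) {
    p <- make_plddt_profile(80L, seed = seed, dip_prob = 0.1)
    m <- make_helical_bundle(n_helices = 4L, helix_len = 20L,
                             seed = seed, plddt = p)
    tr <- suppressMessages(trim_by_confidence(m, 90))
    rt <- residue_table(tr)
    # contiguous interval of the input residue set
    expect_equal(rt$resno, seq(min(rt$resno), max(rt$resno)))
    # idempotent
    tr2 <- suppressMessages(trim_by_confidence(tr, 90))
    expect_equal(tr2$atom, tr$atom)
    # boundary residues are confident; interiors below 90 lie between
    # retained confident residues by construction of the interval
    expect_gte(p[min(rt$resno)], 90)
    expect_gte(p[max(rt$resno)], 90)
    # every removed residue belongs to a sub-threshold terminal run
    removed <- setdiff(seq_along(p), rt$resno)
    expect_true(all(p[removed] < 90))
  }
})

test_that("hetero-only chains give an empty sequence with a warning", {
  hm <- make_homolog(make_helical_bundle(seed = 4L), seed = 4L, chain = "B")
  st <- hm$structure
  lig_only <- st
  lig_only$atom <- st$atom[st$atom$type == "HETATM", ]
  lig_only$atom$chain <- "L"
  expect_warning(s <- extract_sequence(lig_only, "L"), "no polymer")
  expect_equal(s, "")
  expect_error(extract_sequence(st, "Z"), "not present")
})
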
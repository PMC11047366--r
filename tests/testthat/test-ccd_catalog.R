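test_that("component dictionary parsing extracts ids, names and preferred SMILES", {
  path <- write_toy_ccd()
  cat_ <- read_ccd(path)
  expect_equal(nrow(cat_), 3L)
  expect_setequal(cat_$ccd_id, c("GPP", "PHB", "MG"))
  expect_equal(cat_$smiles[cat_$ccd_id == "MG"], "[Mg+2]")
  expect_equal(cat_$name[cat_$ccd_id == "PHB"], "P-HYDROXYBENZOIC ACID")
  # canonical-SMILES first, OpenEye program preferred over CACTVS
  expect_equal(cat_$smiles[cat_$ccd_id == "GPP"],
               "CC(C)=CCC\\C(C)=C\\COP(O)(=O)OP(O)(O)=O")
})

test_that("dictionary edge cases: empty file, duplicates, TSV dialect, missing SMILES", {
  empty <- tempfile(fileext = ".cif")
  writeLines("# nothing here", empty)
  expect_warning(cat_ <- read_ccd(empty), "empty")
  expect_equal(nrow(cat_), 0L)

  dup <- tempfile(fileext = ".cif")
  writeLines(c("data_AAA", "_chem_comp.id AAA", "data_AAA2",
               "_chem_comp.id AAA"), dup)
  expect_error(read_ccd(dup), "duplicate")

  expect_error(read_ccd(tempfile(fileext = ".cif")), "not found")

  # packaged subset: 5TR present with a parseable SMILES; UNX kept without one
  cat_ <- read_ccd(coq2_ccd_path())
  expect_true("5TR" %in% cat_$ccd_id)
  fp <- maccs_fingerprint(cat_[cat_$ccd_id == "5TR", ])
  expect_s3_class(fp, "maccs_fp")
  expect_true(is.na(cat_$smiles[cat_$ccd_id == "UNX"]))

  # TSV dialect round trip
  tsv <- tempfile(fileext = ".tsv")
  write_catalog_tsv(cat_, tsv)
  expect_equal(read_ccd(tsv), cat_)
})

test_that("hit-table parsing reads the summary section with probabilities and ranges", {
  hits <- read_hhr(coq2_hhr_path())
  expect_equal(nrow(hits), 10L)
  expect_equal(hits$pdb_id[1L], "4OD4")
  expect_equal(hits$chain_id[1L], "A")
  expect_equal(hits$probability[1L], 99.1)
  expect_equal(hits$qstart[1L], 22L)
  expect_equal(hits$qend[1L], 280L)
  expect_true(all(vapply(hits$ligands, nrow, 0L) == 0L))

  # empty hit section
  empty <- tempfile(fileext = ".hhr")
  writeLines(c("Query x", "", " No Hit  Prob", ""), empty)
  expect_equal(nrow(read_hhr(empty)), 0L)

  # malformed probability reported with its line number
  bad <- tempfile(fileext = ".hhr")
  writeLines(c(
    " No Hit                             Prob E-value P-value  Score    SS Cols Query HMM  Template HMM",
    "  1 4OD4_A something               oops 1.2E-22 3.1E-27  185.3   0.0  251   22-280    15-272 (289)"),
    bad)
  expect_error(read_hhr(bad), "line 2.*malformed probability")

  badrange <- tempfile(fileext = ".hhr")
  writeLines(c(
    " No Hit                             Prob E-value P-value  Score    SS Cols Query HMM  Template HMM",
    "  1 4OD4_A something               99.1 1.2E-22 3.1E-27  185.3   0.0  251   280-22    15-272 (289)"),
    badrange)
  expect_error(read_hhr(badrange), "range")
})

test_that("ligand attachment tags hetero components with their bound chain", {
  b <- make_helical_bundle(n_helices = 3L, helix_len = 10L, seed = 5L, chain = "B")
  hm <- make_homolog(make_helical_bundle(seed = 5L), identity = 1, sigma = 0,
                     angle = 0, translation = c(0, 0, 0), ligand_id = "GPP",
                     seed = 5L, chain = "B")
  hit <- read_hits_tsv(write_one_hit_tsv("4TQ3", "B", 98.7))
  out <- attach_ligands(hit, stats::setNames(list(hm$structure), "4TQ3"))
  expect_equal(out$ligands[[1L]],
               data.frame(ccd_id = "GPP", chain_id = "B",
                          stringsAsFactors = FALSE))

  # no hetero components -> empty ligand list
  apo <- hm$structure
  apo$atom <- apo$atom[apo$atom$type == "ATOM", ]
  out2 <- attach_ligands(hit, stats::setNames(list(apo), "4TQ3"))
  expect_equal(nrow(out2$ligands[[1L]]), 0L)

  # structure lacking the hit chain is an error naming the chain
  hitX <- hit; hitX$chain_id <- "Q"
  expect_error(attach_ligands(hitX, stats::setNames(list(hm$structure), "4TQ3")),
               "chain 'Q'")
})

test_that("hit selection applies the strict probability bound and the own-chain ligand rule", {
  lig_own <- data.frame(ccd_id = "GPP", chain_id = "B", stringsAsFactors = FALSE)
  lig_other <- data.frame(ccd_id = "GPP", chain_id = "C", stringsAsFactors = FALSE)
  hits <- data.frame(pdb_id = c("AAAA", "BBBB", "CCCC", "DDDD"),
                     chain_id = "B",
                     probability = c(49, 50, 51, 99),
                     qstart = 1L, qend = 10L, tstart = 1L, tend = 10L,
                     stringsAsFactors = FALSE)
  hits$ligands <- list(lig_own, lig_own, lig_own, lig_other)
  sel <- select_hits(hits, 50)
  # 49 and 50 fail the strict bound; 99 has no own-chain ligand
  expect_equal(sel$pdb_id, "CCCC")
  # subset + idempotence
  expect_true(all(sel$pdb_id %in% hits$pdb_id))
  expect_equal(select_hits(sel, 50), sel)
  expect_true(all(sel$probability > 50))

  # repeated hits to one entry collapse to the best probability
  dup <- hits[c(3L, 3L), ]
  dup$probability <- c(55, 77)
  dup$ligands <- list(lig_own, lig_own)
  expect_equal(select_hits(dup, 50)$probability, 77)
})

test_that("hit aliasing swaps entries explicitly and resets their ligands", {
  hits <- data.frame(pdb_id = "4OD4", chain_id = "A", probability = 99.1,
                     qstart = 1L, qend = 10L, tstart = 1L, tend = 10L,
                     stringsAsFactors = FALSE)
  hits$ligands <- list(data.frame(ccd_id = "XXX", chain_id = "A",
                                  stringsAsFactors = FALSE))
  out <- apply_hit_aliases(hits, c("4OD4_A" = "4OD5_A"))
  expect_equal(out$pdb_id, "4OD5")
  expect_equal(nrow(out$ligands[[1L]]), 0L)
  expect_error(apply_hit_aliases(hits, c("4OD4_A" = "nope")), "alias")
})

test_that("hits TSV round trip is lossless", {
  hits <- read_hhr(coq2_hhr_path())
  hits$ligands[[2L]] <- data.frame(ccd_id = c("GPP", "MG"),
                                   chain_id = c("B", "B"),
                                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_hits_tsv(hits, f)
  back <- read_hits_tsv(f)
  rownames(hits) <- rownames(back) <- NULL
  expect_equal(back, hits)
})
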
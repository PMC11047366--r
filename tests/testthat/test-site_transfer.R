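test_that("ligand transfer applies the superposition transform exactly", {
  b <- make_helical_bundle(seed = 8L)
  hm <- make_homolog(b, identity = 1, sigma = 0, seed = 8L)
  sup <- superpose(b, hm$structure)

  lig <- transfer_ligands(sup, hm$structure, "LIG")
  # noise-free: transferred coordinates match the planted query-frame ligand
  expect_equal(as.matrix(lig[, c("x", "y", "z")]),
               as.matrix(hm$ligand_query_frame[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)

  # analytic check: applying the result transform to the target's hetero
  # atoms independently gives the same coordinates
  het <- hm$structure$atom[hm$structure$atom$type == "HETATM", ]
  manual <- apply_transform(sup$transform, as.matrix(het[, c("x", "y", "z")]))
  expect_equal(as.matrix(lig[, c("x", "y", "z")]), manual,
               tolerance = 1e-9, ignore_attr = TRUE)

  # identity transform leaves coordinates unchanged
  idt <- sup; idt$transform$rotation <- diag(3); idt$transform$translation <- c(0, 0, 0)
  lig0 <- transfer_ligands(idt, hm$structure, "LIG")
  expect_equal(as.matrix(lig0[, c("x", "y", "z")]),
               as.matrix(het[, c("x", "y", "z")]), ignore_attr = TRUE)

  expect_error(transfer_ligands(sup, hm$structure, "NOPE"), "NOPE")
})

test_that("contact detection finds exactly the planted pocket, sorted by distance", {
  b <- make_helical_bundle(seed = 14L)
  hm <- make_homolog(b, identity = 1, sigma = 0, seed = 14L)
  lig <- hm$ligand_query_frame

  ct <- find_contact_residues(b, lig, cutoff = 5)
  expect_setequal(ct$resno, hm$pocket)
  expect_true(all(diff(ct$min_dist) >= 0))
  expect_true(all(ct$min_dist <= 5))

  # ligand displaced far away: no contacts
  far <- lig; far$x <- far$x + 100
  expect_equal(nrow(find_contact_residues(b, far, 5)), 0L)

  # monotone in the cutoff
  small <- find_contact_residues(b, lig, 4)
  large <- find_contact_residues(b, lig, 6)
  expect_true(all(small$resno %in% large$resno))
})

test_that("clash detection reports sub-threshold heavy-atom pairs only", {
  b <- make_helical_bundle(seed = 15L)
  cb1 <- b$atom[b$atom$resno == 13L & b$atom$elety == "CB", ]
  probe <- data.frame(ccd_id = "PRB", elety = "C1", instance = "PRB_1",
                      x = cb1$x + 1.0, y = cb1$y, z = cb1$z)
  cl <- detect_clashes(b, probe, clash_cutoff = 2)
  expect_true(all(cl$resno == 13L))   # both residue-13 atoms may be close
  expect_equal(cl$dist[cl$elety == "CB"], 1.0, tolerance = 1e-9)

  # all distances above threshold: empty
  clear <- probe; clear$x <- clear$x + 50
  expect_equal(nrow(detect_clashes(b, clear, 2)), 0L)

  # every clash pair is a contact at any larger cutoff
  ct <- find_contact_residues(b, probe, 5)
  expect_true(all(cl$resno %in% ct$resno))
})

test_that("contacts are invariant under a joint rigid motion of model and ligands", {
  b <- make_helical_bundle(seed = 16L)
  hm <- make_homolog(b, identity = 1, sigma = 0, seed = 16L)
  lig <- hm$ligand_query_frame
  ct0 <- find_contact_residues(b, lig, 5)

  R <- sitegraft:::rotation_about_axis(c(1, 1, 0), 1.1)
  tr <- sitegraft:::new_rigid_transform(R, c(7, -4, 12))
  b2 <- b
  b2$atom[, c("x", "y", "z")] <- apply_transform(tr, as.matrix(b$atom[, c("x", "y", "z")]))
  lig2 <- lig
  lig2[, c("x", "y", "z")] <- apply_transform(tr, as.matrix(lig[, c("x", "y", "z")]))
  ct1 <- find_contact_residues(b2, lig2, 5)
  expect_setequal(ct1$resno, ct0$resno)
  m <- merge(ct0, ct1, by = "resno")
  expect_equal(m$min_dist.y, m$min_dist.x, tolerance = 1e-9)
})

test_that("annotation joins topology, motifs and variants, flagging the rest unannotated", {
  contacts <- data.frame(chain = "A", resno = c(136L, 96L, 369L),
                         resid = c("ASP", "SER", "LEU"),
                         min_dist = c(3.2, 4.1, 4.8),
                         ligand = "GPP_B_1", stringsAsFactors = FALSE)
  rep <- annotate_report(contacts)
  # 136: inside the first Asp-rich motif, on the matrix-side S2-S3 loop
  expect_match(rep$motif[1L], "Asp134xxxAsp138")
  expect_equal(rep$segment[1L], "S2-S3")
  expect_equal(rep$side[1L], "matrix")
  expect_false(rep$unannotated[1L])
  # 96: the S1 variant position, on a portal-delimiting helix
  expect_equal(rep$variant[2L], "p.Ser96Asn")
  expect_equal(rep$segment[2L], "S1")
  expect_true(rep$portal[2L])
  # 369: C-terminal tail - topology only, no motif or variant
  expect_equal(rep$segment[3L], "C-term")
  expect_true(is.na(rep$motif[3L]) && is.na(rep$variant[3L]))

  # a position outside every annotation is flagged, not an error
  far <- data.frame(chain = "A", resno = 999L, resid = "ALA",
                    min_dist = 2.0, ligand = "X", stringsAsFactors = FALSE)
  rep2 <- annotate_report(far)
  expect_true(rep2$unannotated)

  # clash flag joins by residue
  cl <- data.frame(resno = 96L)
  rep3 <- annotate_report(contacts, clashes = cl)
  expect_equal(rep3$clash, c(FALSE, TRUE, FALSE))
})
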
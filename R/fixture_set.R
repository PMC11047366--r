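# Full synthetic case-study input set: one call writes every file the
# pipeline consumes, plus the ground truth needed to verify recovery.

#' Write a complete synthetic input set for the pipeline
#'
#' Generates, under one seed, a synthetic analog of the whole case
#' study: a query helical-bundle model with a confidence profile
#' (low-confidence termini around a high-confidence core), five
#' ligand-bound homolog structures of graded noise and identity (so
#' their superposition RMSDs have a known order), an apo twin of the
#' best homolog (exercising the alias mechanism), a decoy entry whose
#' ligand binds a different chain (exercising own-chain filtering), a
#' severely distorted entry (exercising the RMSD exclusion rule),
#' displaced-loop variant models, and a toy ligand catalog. Ligands are
#' planted in the query cavity, so the contact residues each homolog
#' should recover are known by construction; one extra component is
#' planted 1.2 Angstrom from a cavity side chain to create a known
#' steric clash.
#'
#' The homolog components reuse the component ids of the case study
#' (GPP/GST/PHB/MG and friends), so the similarity screen against the
#' packaged dictionary selects them; geometry and sequences are fully
#' synthetic.
#'
#' @param dir output directory (created if needed).
#' @param seed seed fixing all randomness.
#' @return invisibly, the ground-truth list (also written as
#'   `ground_truth.json`): query trim interval, per-homolog planted
#'   transform/pocket/ligands, expected RMSD order, clash residue, and
#'   variant descriptions.
#' @export
write_fixture_set <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- 225L
  plddt <- c(rep(60, 10L), rep(95, 207L), rep(70, 8L))
  query <- make_helical_bundle(seed = seed, plddt = plddt,
                               entry_id = "QUERY")
  write_structure(query, file.path(dir, "query_model.pdb"))

  specs <- list(
    `4TQ3` = list(chain = "B", identity = 0.45, sigma = 0.25, angle = 20,
                  translation = c(6, -3, 2),
                  ids = c("GPP", "GPP", "GPP", "MG", "MG")),
    `4OD5` = list(chain = "A", identity = 0.32, sigma = 0.35, angle = -35,
                  translation = c(-8, 5, -4),
                  ids = c("GST", "GST", "GST", "MG", "MG")),
    `6M31` = list(chain = "B", identity = 0.28, sigma = 0.50, angle = 55,
                  translation = c(4, 9, 6),
                  ids = c("MPG", "MPG", "LDA", "LDA", "PO4")),
    `8DJM` = list(chain = "B", identity = 0.25, sigma = 0.60, angle = -70,
                  translation = c(12, -6, -5),
                  ids = c("Y01", "Y01", "Y01", "AJP", "AJP")),
    `7Q21` = list(chain = "f", identity = 0.30, sigma = 0.30, angle = 40,
                  translation = c(-5, -8, 3),
                  ids = c("7PH", "7PH", "CDL", "CDL", "TRD")))

  truth <- list(seed = seed,
                query = list(n_residues = n, trim_start = 11L, trim_end = 217L),
                homologs = list())
  k <- 0L
  for (id in names(specs)) {
    k <- k + 1L
    sp <- specs[[id]]
    hm <- make_homolog(query, identity = sp$identity, sigma = sp$sigma,
                       angle = sp$angle, translation = sp$translation,
                       seed = seed + k, chain = sp$chain, entry_id = id)
    st <- relabel_planted_ligand(hm$structure, sp$ids)
    clash_resno <- NULL
    if (id == "4OD5") {
      planted <- plant_clash_atom(query, st, hm, exclude = hm$pocket)
      st <- planted$structure
      clash_resno <- planted$resno
    }
    if (id == "7Q21") {
      # break rigidity: displace the outer half of the fold
      far <- st$atom$resno > n %/% 2L & st$atom$type == "ATOM"
      st$atom$x[far] <- st$atom$x[far] + 40
    }
    write_structure(st, file.path(dir, paste0(id, ".pdb")))
    truth$homologs[[id]] <- list(
      chain = sp$chain, identity = sp$identity, sigma = sp$sigma,
      pocket = hm$pocket, ligand_ids = unique(sp$ids),
      clash_resno = clash_resno,
      distorted = id == "7Q21",
      rotation = hm$transform$rotation,
      translation = hm$transform$translation)
  }
  # apo twin of 4OD5 (same protein, hetero stripped) for the alias path
  best <- read_structure(file.path(dir, "4OD5.pdb"), entry_id = "4OD4")
  best$atom <- best$atom[best$atom$type == "ATOM", ]
  write_structure(best, file.path(dir, "4OD4.pdb"))

  # decoy: homolog chain H, but its ligand sits on a remote mini-chain A
  dec <- make_homolog(query, identity = 0.30, sigma = 0.50, angle = 15,
                      translation = c(3, 3, 3), seed = seed + 99L,
                      chain = "H", entry_id = "7E1V")$structure
  dec$atom <- dec$atom[dec$atom$type == "ATOM", ]
  mini <- make_helical_bundle(n_helices = 1L, helix_len = 25L,
                              seed = seed + 100L, chain = "A",
                              entry_id = "MINI")
  mini$atom$x <- mini$atom$x + 60
  cb13 <- mini$atom[mini$atom$resno == 13L & mini$atom$elety == "CB", ]
  lig <- data.frame(type = "HETATM", eleno = NA_integer_, elety = "C1",
                    alt = "", resid = "LDA", chain = "A", resno = 26L,
                    insert = "", x = cb13$x + 3, y = cb13$y, z = cb13$z,
                    o = 1, b = 0, elesy = "C", stringsAsFactors = FALSE)
  dec <- new_structure3d(rbind(dec$atom, mini$atom[, names(dec$atom)], lig),
                         "7E1V")
  write_structure(dec, file.path(dir, "7E1V.pdb"))

  # displaced-loop variant models (same sequence, local conformational
  # change of graded size -> known RMSD order)
  vdir <- file.path(dir, "variants")
  dir.create(vdir, showWarnings = FALSE)
  vspecs <- list(var_a = list(region = c(101L, 110L), displacement = 0.8),
                 var_b = list(region = c(140L, 150L), displacement = 1.5),
                 var_c = list(region = c(60L, 72L), displacement = 2.5))
  truth$variants <- list()
  for (v in names(vspecs)) {
    vs <- vspecs[[v]]
    vm <- make_displaced_variant(query, vs$region, vs$displacement,
                                 seed = seed + match(v, names(vspecs)))
    write_structure(vm, file.path(vdir, paste0(v, ".pdb")))
    truth$variants[[v]] <- vs
  }

  write_catalog_tsv(make_toy_catalog()$catalog,
                    file.path(dir, "toy_catalog.tsv"))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

# split the single planted LIG component into the requested component
# ids (one hetero residue per id, atoms partitioned in order)
#' @noRd
relabel_planted_ligand <- function(st, ids) {
  het <- which(st$atom$type == "HETATM" & st$atom$resid == "LIG")
  stopifnot(length(het) == length(ids))
  base <- max(st$atom$resno[st$atom$type == "ATOM"])
  grp <- match(ids, unique(ids))
  st$atom$resid[het] <- ids
  st$atom$resno[het] <- base + grp
  st$atom$elesy[het] <- ifelse(ids == "MG", "MG", "C")
  st$atom$elety[het] <- ifelse(ids == "MG", "MG",
                               sprintf("C%d", seq_along(het)))
  st
}

# add a one-atom component 1.2 A from an inward side chain of the query
# (in the query frame), carried into the homolog frame with the inverse
# of the planted transform -> a known clash after transfer
#' @noRd
plant_clash_atom <- function(query, st, hm, exclude) {
  atom <- query$atom
  cb <- atom[atom$elety == "CB" & !(atom$resno %in% exclude), ]
  ca <- atom[atom$elety == "CA", ]
  rho_cb <- sqrt(cb$x^2 + cb$y^2)
  rho_ca <- sqrt(ca$x^2 + ca$y^2)[match(cb$resno, ca$resno)]
  cand <- cb[rho_cb < rho_ca & abs(cb$z) > 3 & abs(cb$z) < 8, ]
  cand <- cand[order(sqrt(cand$x^2 + cand$y^2)), ][1L, ]
  p <- c(cand$x, cand$y, cand$z)
  u <- -p / sqrt(sum(p^2))
  pq <- p + 1.2 * u                     # query frame, 1.2 A from the CB
  inv <- hm$transform                   # maps homolog -> query
  fwd <- new_rigid_transform(t(inv$rotation),
                             -as.vector(t(inv$rotation) %*% inv$translation))
  ph <- apply_transform(fwd, pq)
  row <- data.frame(type = "HETATM", eleno = NA_integer_, elety = "C1",
                    alt = "", resid = "PHB", chain = st$atom$chain[1L],
                    resno = max(st$atom$resno) + 1L, insert = "",
                    x = ph[1L], y = ph[2L], z = ph[3L], o = 1, b = 0,
                    elesy = "C", stringsAsFactors = FALSE)
  list(structure = new_structure3d(rbind(st$atom, row), st$entry_id),
       resno = cand$resno)
}
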
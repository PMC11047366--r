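# Ground-truth fixture generators. Every generator is deterministic
# under `seed` and leaves the caller's RNG state untouched.

#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate an idealised helical-bundle structure
#'
#' Builds `n_helices` ideal alpha-helices (Calpha trace with 1.5
#' Angstrom rise, 100 degrees per residue, 2.3 Angstrom helical radius,
#' giving the canonical 3.8 Angstrom consecutive Calpha spacing) on a
#' ring, with alternating up/down direction, enclosing a central cavity
#' - the channel-like architecture typical of polytopic membrane
#' enzymes. Each residue carries one pseudo-side-chain centroid atom
#' (`CB`, 1.53 Angstrom from the Calpha, pointing away from the helix
#' axis), which is sufficient for contact and clash geometry without
#' full rotamers.
#'
#' @param n_helices number of helices (default 9).
#' @param helix_len residues per helix; scalar or vector of length
#'   `n_helices`.
#' @param ring_radius radius of the helix-axis ring, Angstrom.
#' @param sequence optional one-letter sequence (length = total
#'   residues); random under `seed` when `NULL`.
#' @param plddt per-residue B-factor/confidence values (recycled scalar
#'   or full vector), default 95.
#' @param seed RNG seed; output is bit-reproducible given the seed.
#' @param chain,entry_id identifiers for the output structure.
#' @return a `structure3d` with residues numbered 1..n.
#' @export
make_helical_bundle <- function(n_helices = 9L, helix_len = 25L,
                                ring_radius = 14, sequence = NULL,
                                plddt = 95, seed = 1L,
                                chain = "A", entry_id = "BUNDLE") {
  if (length(helix_len) == 1L) helix_len <- rep(helix_len, n_helices)
  stopifnot(length(helix_len) == n_helices)
  n <- sum(helix_len)
  if (is.null(sequence)) {
    aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    sequence <- with_seed(seed, paste(sample(aa20, n, replace = TRUE), collapse = ""))
  }
  seqv <- strsplit(sequence, "")[[1]]
  stopifnot(length(seqv) == n)
  plddt <- rep_len(as.numeric(plddt), n)

  rise <- 1.5; twist <- 100 * pi / 180; r_helix <- 2.3; r_cb <- 1.53
  rows <- vector("list", n_helices)
  res0 <- 0L
  for (h in seq_len(n_helices)) {
    L <- helix_len[h]
    theta <- 2 * pi * (h - 1L) / n_helices
    centre <- c(ring_radius * cos(theta), ring_radius * sin(theta))
    dir <- if (h %% 2L == 1L) 1 else -1
    i <- seq_len(L)
    phi <- twist * i + theta          # phase offset per helix
    ca <- cbind(centre[1L] + r_helix * cos(phi),
                centre[2L] + r_helix * sin(phi),
                dir * rise * (i - (L + 1) / 2))
    cb <- ca + r_cb * cbind(cos(phi), sin(phi), 0)
    resno <- res0 + i
    rows[[h]] <- data.frame(
      type = "ATOM", eleno = NA_integer_,
      elety = rep(c("CA", "CB"), each = L), alt = "",
      resid = rep(aa_one_to_three(seqv[resno]), 2L),
      chain = chain, resno = rep(resno, 2L), insert = "",
      x = c(ca[, 1L], cb[, 1L]), y = c(ca[, 2L], cb[, 2L]),
      z = c(ca[, 3L], cb[, 3L]), o = 1,
      b = rep(plddt[resno], 2L),
      elesy = "C", stringsAsFactors = FALSE)
    res0 <- res0 + L
  }
  atom <- do.call(rbind, rows)
  atom <- atom[order(atom$resno, match(atom$elety, c("CA", "CB"))), ]
  atom$eleno <- seq_len(nrow(atom))
  new_structure3d(atom, entry_id)
}

#' Derive a homolog structure with planted ground truth
#'
#' Copies a bundle, mutates its sequence down to a requested identity,
#' perturbs the protein coordinates with isotropic Gaussian noise,
#' applies a known rigid transform, and plants a multi-atom ligand in
#' the central cavity so that exactly the chosen pocket residues lie
#' within the binding margin. The returned ground truth (expected
#' superposition transform, pocket residue set, ligand coordinates in
#' the query frame) drives recovery tests for every downstream stage.
#'
#' The ligand is built with one atom per pocket residue, placed 3.5
#' Angstrom inward of the residue's side-chain centroid; the
#' construction is checked so that every pocket residue has a heavy atom
#' within 3.5 Angstrom of the ligand and every other residue is farther
#' than `clear_margin`. An explicit `pocket` whose geometry cannot
#' satisfy the margins is an error.
#'
#' @param bundle a `structure3d` from [make_helical_bundle()].
#' @param identity target sequence identity fraction in `[0, 1]`.
#' @param sigma coordinate noise s.d., Angstrom.
#' @param angle,axis,translation the planted rigid motion (degrees,
#'   rotation axis, Angstrom).
#' @param pocket residue numbers to make the binding pocket, or `NULL`
#'   to choose `pocket_size` cavity-lining residues automatically.
#' @param pocket_size pocket size for automatic selection (default 5).
#' @param ligand_id component id given to the planted ligand.
#' @param clear_margin minimum ligand distance required of non-pocket
#'   residues, Angstrom (default 5.3).
#' @param seed RNG seed (mutations and noise).
#' @param chain,entry_id identifiers for the homolog.
#' @return list with `structure` (the homolog, ligand included as a
#'   hetero component), `transform` (the `rigid_transform` a correct
#'   superposition of the homolog onto the bundle should recover),
#'   `pocket` (sorted residue numbers), and `ligand_query_frame` (the
#'   planted ligand atoms in the query frame).
#' @export
make_homolog <- function(bundle, identity = 0.6, sigma = 0.3,
                         angle = 30, axis = c(0, 0, 1),
                         translation = c(10, 5, -3),
                         pocket = NULL, pocket_size = 5L,
                         ligand_id = "LIG", clear_margin = 5.3,
                         seed = 1L, chain = "B", entry_id = "HOMOLOG") {
  stopifnot(identity >= 0, identity <= 1, sigma >= 0)
  atom <- bundle$atom[bundle$atom$type == "ATOM", ]
  rt <- residue_table(bundle)
  rt <- rt[!rt$is_hetero, ]
  n <- nrow(rt)

  # --- pocket + ligand (deterministic, query frame) ------------------
  cb <- atom[atom$elety == "CB", ]
  cb <- cb[order(cb$resno), ]
  rho_cb <- sqrt(cb$x^2 + cb$y^2)
  ca <- atom[atom$elety == "CA", ]
  ca <- ca[order(ca$resno), ]
  rho_ca <- sqrt(ca$x^2 + ca$y^2)
  inward <- rho_cb < rho_ca
  if (is.null(pocket)) {
    score <- rho_cb + 0.75 * abs(cb$z)
    score[!inward] <- Inf
    pocket <- sort(cb$resno[order(score)][seq_len(pocket_size)])
  }
  pocket <- sort(unique(as.integer(pocket)))
  sel <- match(pocket, cb$resno)
  if (anyNA(sel)) stopf("pocket residue(s) not in bundle: %s",
                        paste(pocket[is.na(sel)], collapse = ", "))
  lig_xyz <- t(vapply(sel, function(k) {
    p <- c(cb$x[k], cb$y[k], cb$z[k])
    ax <- c(0, 0, p[3L])                    # nearest axis point
    u <- (ax - p) / sqrt(sum((ax - p)^2))
    p + 3.5 * u
  }, numeric(3L)))
  lig <- data.frame(ccd_id = ligand_id, chain = chain,
                    resno = n + 1L,
                    elety = sprintf("C%d", seq_len(nrow(lig_xyz))),
                    elesy = "C", x = lig_xyz[, 1L], y = lig_xyz[, 2L],
                    z = lig_xyz[, 3L],
                    instance = sprintf("%s_%s_%d", ligand_id, chain, n + 1L),
                    stringsAsFactors = FALSE)
  # verify the construction margins against every residue
  neigh <- ligand_neighbourhood(bundle, lig, cutoff = Inf)
  inpocket <- neigh$resno %in% pocket
  if (any(neigh$min_dist[inpocket] > 3.5 + 1e-6) ||
      any(neigh$min_dist[!inpocket] < clear_margin - 1e-6))
    stopf("requested pocket residues not mutually placeable (margins 3.5/%g violated)",
          clear_margin)

  # --- mutate + noise + rigid motion --------------------------------
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqv <- aa_three_to_one(rt$resid)
  out <- with_seed(seed, {
    k <- round((1 - identity) * n)
    mut_at <- if (k > 0L) sample.int(n, k) else integer(0)
    for (i in mut_at) seqv[i] <- sample(setdiff(aa20, seqv[i]), 1L)
    noise <- matrix(stats::rnorm(3L * nrow(atom), sd = sigma), ncol = 3L)
    list(seqv = seqv, noise = noise)
  })
  atom$resid <- aa_one_to_three(out$seqv)[match(atom$resno, rt$resno)]
  xyz <- as.matrix(atom[, c("x", "y", "z")]) + out$noise

  R <- rotation_about_axis(axis, angle * pi / 180)
  fwd <- new_rigid_transform(R, translation)
  xyz <- apply_transform(fwd, xyz)
  atom[, c("x", "y", "z")] <- xyz
  atom$chain <- chain
  lig_moved <- apply_transform(fwd, as.matrix(lig[, c("x", "y", "z")]))

  het <- data.frame(
    type = "HETATM", eleno = NA_integer_, elety = lig$elety, alt = "",
    resid = ligand_id, chain = chain, resno = lig$resno, insert = "",
    x = lig_moved[, 1L], y = lig_moved[, 2L], z = lig_moved[, 3L],
    o = 1, b = 0, elesy = lig$elesy, stringsAsFactors = FALSE)
  st <- new_structure3d(rbind(atom[, names(het)], het), entry_id)

  # ground truth: superposing the homolog back onto the bundle should
  # recover the inverse of the applied motion
  inv <- new_rigid_transform(t(R), -as.vector(t(R) %*% translation))
  list(structure = st, transform = inv, pocket = pocket,
       ligand_query_frame = lig)
}

#' @noRd
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Displace a loop region of a bundle (variant-model fixture)
#'
#' Copies a structure and moves a contiguous residue interval by a
#' shared displacement vector (correlated motion, as a real local
#' conformational change would be), plus optional small isotropic
#' noise everywhere - the fixture for variant-comparison tests.
#'
#' @param bundle a `structure3d`.
#' @param region length-2 residue interval to displace.
#' @param displacement length of the shared displacement, Angstrom.
#' @param sigma background noise s.d., Angstrom (default 0.02).
#' @param seed RNG seed (displacement direction and noise).
#' @return a `structure3d`.
#' @export
make_displaced_variant <- function(bundle, region, displacement = 1.5,
                                   sigma = 0.02, seed = 1L) {
  atom <- bundle$atom
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  out <- with_seed(seed, {
    d <- stats::rnorm(3L)
    list(dir = d / sqrt(sum(d^2)),
         noise = matrix(stats::rnorm(length(xyz), sd = sigma), ncol = 3L))
  })
  xyz <- xyz + out$noise
  hit <- atom$resno >= region[1L] & atom$resno <= region[2L] & atom$type == "ATOM"
  xyz[hit, ] <- xyz[hit, ] + rep(displacement * out$dir, each = sum(hit))
  atom[, c("x", "y", "z")] <- xyz
  new_structure3d(atom, paste0(bundle$entry_id, "_VAR"))
}

#' Random per-residue confidence profile
#'
#' Low-confidence terminal runs around a high-confidence core with
#' occasional interior dips - the shape of a typical predicted-model
#' pLDDT trace - for property tests of confidence trimming.
#'
#' @param n number of residues.
#' @param n_low_start,n_low_end lengths of the low-confidence termini;
#'   random up to n/5 when `NULL`.
#' @param dip_prob probability of an interior sub-threshold dip.
#' @param seed RNG seed.
#' @return numeric vector of length `n`.
#' @export
make_plddt_profile <- function(n = 100L, n_low_start = NULL,
                               n_low_end = NULL, dip_prob = 0.05,
                               seed = 1L) {
  with_seed(seed, {
    if (is.null(n_low_start)) n_low_start <- sample.int(max(1L, n %/% 5L), 1L)
    if (is.null(n_low_end)) n_low_end <- sample.int(max(1L, n %/% 5L), 1L)
    core <- n - n_low_start - n_low_end
    stopifnot(core >= 1L)
    p <- c(stats::runif(n_low_start, 30, 85),
           stats::runif(core, 91, 99),
           stats::runif(n_low_end, 30, 85))
    dip <- which(stats::runif(n) < dip_prob)
    dip <- dip[dip > n_low_start & dip <= n_low_start + core]
    p[dip] <- stats::runif(length(dip), 40, 89)
    round(p, 2)
  })
}

#' Toy ligand catalog with frozen reference fingerprints
#'
#' Ten small molecules whose MACCS key sets are small enough to check by
#' hand, together with reference key sets frozen from an independent
#' cheminformatics implementation (RDKit 2024.09, evaluated on identical
#' SMILES) and the pairwise Tanimoto matrix those reference sets imply.
#' Tests compare the package's fingerprints against the reference sets
#' key for key.
#'
#' @return list with `catalog` (`ccd_id`, `name`, `smiles`),
#'   `reference_keys` (named list of sorted integer key sets), and
#'   `expected_tanimoto` (10 x 10 named matrix computed from the
#'   reference key sets).
#' @export
make_toy_catalog <- function() {
  catalog <- data.frame(
    ccd_id = c("MTH", "ETH", "PRP", "EOH", "ACA",
               "BNZ", "PHL", "HOH", "NH3", "MG"),
    name = c("methane", "ethane", "propane", "ethanol", "acetic acid",
             "benzene", "phenol", "water", "ammonia", "magnesium ion"),
    smiles = c("C", "CC", "CCC", "CCO", "CC(O)=O",
               "c1ccccc1", "Oc1ccccc1", "O", "N", "[Mg+2]"),
    stringsAsFactors = FALSE)
  reference_keys <- list(
    MTH = c(160L),
    ETH = c(149L, 160L),
    PRP = c(74L, 114L, 149L, 155L, 160L),
    EOH = c(82L, 109L, 114L, 139L, 153L, 155L, 157L, 160L, 164L),
    ACA = c(123L, 139L, 154L, 157L, 159L, 160L, 164L),
    BNZ = c(162L, 163L, 165L),
    PHL = c(113L, 127L, 139L, 143L, 152L, 157L, 162L, 163L, 164L, 165L),
    HOH = c(139L, 164L),
    NH3 = c(151L, 161L),
    MG = c(10L, 44L, 49L))
  ids <- catalog$ccd_id
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in ids) for (j in ids) {
    u <- length(union(reference_keys[[i]], reference_keys[[j]]))
    m[i, j] <- if (u == 0L) 0 else
      length(intersect(reference_keys[[i]], reference_keys[[j]])) / u
  }
  list(catalog = catalog, reference_keys = reference_keys,
       expected_tanimoto = m)
}
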
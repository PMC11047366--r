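#' Transfer homolog ligands into the query frame
#'
#' Applies a superposition transform to the hetero components of the
#' target structure, so the ligands can be inspected in the coordinate
#' frame of the query model. The target structure itself is untouched.
#'
#' @param result a `superposition_result` from [superpose()] computed on
#'   the same target.
#' @param target the homolog `structure3d`.
#' @param ligand_ids component ids to transfer; default all hetero
#'   components except the deny list. An id absent from the target is an
#'   error.
#' @param deny components never transferred (default waters).
#' @return data frame of transferred ligand atoms: `ccd_id`, `chain`,
#'   `resno`, `elety`, `elesy`, `x`, `y`, `z`, plus `instance` (one id
#'   per ligand copy).
#' @export
transfer_ligands <- function(result, target, ligand_ids = NULL,
                             deny = c("HOH", "DOD")) {
  stopifnot(inherits(result, "superposition_result"),
            inherits(target, "structure3d"))
  het <- target$atom[target$atom$type == "HETATM" &
                     !(target$atom$resid %in% deny), ]
  if (!is.null(ligand_ids)) {
    missing <- setdiff(ligand_ids, het$resid)
    if (length(missing) > 0L)
      stopf("ligand(s) not present in %s: %s", target$entry_id,
            paste(missing, collapse = ", "))
    het <- het[het$resid %in% ligand_ids, ]
  }
  het <- het[heavy_mask(het), ]
  if (nrow(het) == 0L)
    return(data.frame(ccd_id = character(), chain = character(),
                      resno = integer(), elety = character(),
                      elesy = character(), x = numeric(), y = numeric(),
                      z = numeric(), instance = character(),
                      stringsAsFactors = FALSE))
  xyz <- apply_transform(result$transform, as.matrix(het[, c("x", "y", "z")]))
  out <- data.frame(ccd_id = het$resid, chain = het$chain, resno = het$resno,
                    elety = het$elety, elesy = het$elesy,
                    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                    instance = paste(het$resid, het$chain, het$resno, sep = "_"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Contact residues of a placed ligand
#'
#' Residues of the model with any heavy atom within `cutoff` of any
#' ligand heavy atom, with the minimum pairwise distance recorded.
#' 5 Angstrom is a standard heavy-atom contact definition.
#'
#' @param model a `structure3d`.
#' @param ligand_atoms data frame with `x`, `y`, `z` (and optionally
#'   `ccd_id`/`instance`) as returned by [transfer_ligands()].
#' @param cutoff contact distance in Angstrom, default 5.
#' @return data frame sorted by distance: `chain`, `resno`, `resid`,
#'   `min_dist`, and `ligand` (the closest ligand instance) per contact
#'   residue.
#' @export
find_contact_residues <- function(model, ligand_atoms, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  neigh <- ligand_neighbourhood(model, ligand_atoms, cutoff)
  out <- neigh[neigh$min_dist <= cutoff, , drop = FALSE]
  out[order(out$min_dist, out$chain, out$resno), , drop = FALSE]
}

# per-residue minimum heavy-atom distance to the ligand set
#' @noRd
ligand_neighbourhood <- function(model, ligand_atoms, cutoff) {
  a <- model$atom[model$atom$type == "ATOM", ]
  a <- a[heavy_mask(a), ]
  empty <- data.frame(chain = character(), resno = integer(),
                      resid = character(), min_dist = numeric(),
                      ligand = character(), stringsAsFactors = FALSE)
  if (nrow(a) == 0L || nrow(ligand_atoms) == 0L) return(empty)
  d2 <- dist2_xyz(a[, c("x", "y", "z")], ligand_atoms[, c("x", "y", "z")])
  amin <- sqrt(apply(d2, 1L, min))
  awhich <- apply(d2, 1L, which.min)
  inst <- if (!is.null(ligand_atoms$instance)) ligand_atoms$instance
          else rep("ligand", nrow(ligand_atoms))
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  idx <- split(seq_len(nrow(a)), key)
  rows <- lapply(idx, function(ii) {
    k <- ii[which.min(amin[ii])]
    data.frame(chain = a$chain[k], resno = a$resno[k], resid = a$resid[k],
               min_dist = amin[k], ligand = inst[awhich[k]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Steric clashes between a placed ligand and the model
#'
#' Heavy-atom pairs closer than `clash_cutoff` (default 2 Angstrom,
#' well below van der Waals contact), one row per clashing pair.
#'
#' @inheritParams find_contact_residues
#' @param clash_cutoff clash distance in Angstrom, default 2.
#' @return data frame: `chain`, `resno`, `resid`, `elety` (model atom),
#'   `ligand`, `ligand_atom`, `dist`.
#' @export
detect_clashes <- function(model, ligand_atoms, clash_cutoff = 2.0) {
  stopifnot(clash_cutoff > 0)
  a <- model$atom[model$atom$type == "ATOM", ]
  a <- a[heavy_mask(a), ]
  empty <- data.frame(chain = character(), resno = integer(),
                      resid = character(), elety = character(),
                      ligand = character(), ligand_atom = character(),
                      dist = numeric(), stringsAsFactors = FALSE)
  if (nrow(a) == 0L || nrow(ligand_atoms) == 0L) return(empty)
  d2 <- dist2_xyz(a[, c("x", "y", "z")], ligand_atoms[, c("x", "y", "z")])
  hit <- which(d2 < clash_cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  inst <- if (!is.null(ligand_atoms$instance)) ligand_atoms$instance
          else rep("ligand", nrow(ligand_atoms))
  out <- data.frame(
    chain = a$chain[hit[, 1L]], resno = a$resno[hit[, 1L]],
    resid = a$resid[hit[, 1L]], elety = a$elety[hit[, 1L]],
    ligand = inst[hit[, 2L]],
    ligand_atom = ligand_atoms$elety[hit[, 2L]] %||% NA_character_,
    dist = sqrt(d2[hit]), stringsAsFactors = FALSE)
  out <- out[order(out$dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate contact residues with topology, motifs and variants
#'
#' Joins a contact list against annotation tables: membrane-topology
#' segments (with their membrane side), conserved sequence motifs,
#' disease variants, and whether the contact lies on one of the helices
#' delimiting the lateral portal. Contacts outside every annotation are
#' flagged `unannotated` rather than raising an error.
#'
#' @param contacts data frame from [find_contact_residues()].
#' @param topology data frame with `label`, `start`, `end`, `side`
#'   (e.g. [coq2_topology()]).
#' @param motifs data frame with `name`, `start`, `end`
#'   (e.g. [coq2_motifs()]).
#' @param variants data frame with `position`, `variant` and
#'   pathogenicity columns (e.g. [coq2_variants()]).
#' @param portal_segments labels of the portal-delimiting segments
#'   (default S1 and S9).
#' @param clashes optional data frame from [detect_clashes()]; adds a
#'   `clash` flag.
#' @return a `binding_site_report` data frame: the contacts plus
#'   `segment`, `side`, `motif`, `variant`, `pathogenicity`, `portal`,
#'   `clash`, `unannotated`.
#' @export
annotate_report <- function(contacts, topology = coq2_topology(),
                            motifs = coq2_motifs(),
                            variants = coq2_variants(),
                            portal_segments = c("S1", "S9"),
                            clashes = NULL) {
  n <- nrow(contacts)
  seg <- character(n); side <- character(n); motif <- character(n)
  variant <- character(n); patho <- character(n)
  for (i in seq_len(n)) {
    p <- contacts$resno[i]
    hit <- topology[topology$start <= p & topology$end >= p, , drop = FALSE]
    seg[i] <- if (nrow(hit) > 0L) hit$label[1L] else NA_character_
    side[i] <- if (nrow(hit) > 0L) hit$side[1L] else NA_character_
    mh <- motifs[motifs$start <= p & motifs$end >= p, , drop = FALSE]
    motif[i] <- if (nrow(mh) > 0L) paste(mh$name, collapse = ";") else NA_character_
    vh <- variants[variants$position == p, , drop = FALSE]
    variant[i] <- if (nrow(vh) > 0L) paste(vh$variant, collapse = ";") else NA_character_
    patho[i] <- if (nrow(vh) > 0L) paste(vh$sift, collapse = ";") else NA_character_
  }
  out <- contacts
  out$segment <- seg
  out$side <- side
  out$motif <- motif
  out$variant <- variant
  out$pathogenicity <- patho
  out$portal <- !is.na(seg) & seg %in% portal_segments
  out$clash <- if (!is.null(clashes) && nrow(clashes) > 0L)
    contacts$resno %in% clashes$resno else FALSE
  out$unannotated <- is.na(seg) & is.na(motif) & is.na(variant)
  class(out) <- c("binding_site_report", class(out))
  out
}

#' Combine a model and transferred ligands into one structure
#'
#' Convenience for writing a single PDB with the query model plus the
#' grafted ligands for visual inspection.
#'
#' @param model a `structure3d`.
#' @param ligand_atoms data frame from [transfer_ligands()].
#' @return a `structure3d`.
#' @export
combine_model_ligands <- function(model, ligand_atoms) {
  lig <- data.frame(
    type = "HETATM", eleno = NA_integer_, elety = ligand_atoms$elety,
    alt = "", resid = ligand_atoms$ccd_id, chain = "Z",
    resno = as.integer(factor(ligand_atoms$instance)),
    insert = "", x = ligand_atoms$x, y = ligand_atoms$y,
    z = ligand_atoms$z, o = 1, b = 0, elesy = ligand_atoms$elesy,
    stringsAsFactors = FALSE)
  new_structure3d(rbind(model$atom, lig), model$entry_id)
}
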
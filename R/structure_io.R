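#' Read a structure from a PDB or mmCIF file
#'
#' Parses the full atomic hierarchy, including hetero components.
#' Alternate locations are resolved to the conformer with the highest
#' occupancy (ties broken alphabetically by altloc identifier), so every
#' atom appears once.
#'
#' For predicted models the B-factor column carries the per-residue
#' confidence score (pLDDT, 0-100); see [trim_by_confidence()].
#'
#' @param path path to a `.pdb`/`.ent` or `.cif` file.
#' @param entry_id optional entry identifier; defaults to the file stem.
#' @return a `structure3d` object: a list with `entry_id` and `atom`, a
#'   data frame with one row per atom (`type`, `eleno`, `elety`, `alt`,
#'   `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `b`,
#'   `elesy`).
#' @export
read_structure <- function(path, entry_id = NULL) {
  if (!file.exists(path)) stopf("structure file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- switch(ext,
    pdb = , ent = suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    cif = suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
    stopf("unknown structure format '.%s' (expected .pdb or .cif): %s", ext, path)
  )
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0L || all(is.na(atom$x)))
    stopf("no atomic coordinates in %s", path)
  atom <- resolve_altlocs(atom)
  atom$chain[is.na(atom$chain)] <- " "
  atom$insert[is.na(atom$insert)] <- ""
  if (anyNA(atom$elesy) || any(atom$elesy == "")) {
    bad <- is.na(atom$elesy) | atom$elesy == ""
    atom$elesy[bad] <- suppressWarnings(bio3d::atom2ele(atom$elety[bad]))
  }
  new_structure3d(atom, entry_id %||% toupper(tools::file_path_sans_ext(basename(path))))
}

#' @noRd
new_structure3d <- function(atom, entry_id) {
  keep <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
            "insert", "x", "y", "z", "o", "b", "elesy")
  for (k in setdiff(keep, names(atom))) atom[[k]] <- NA
  atom <- atom[, keep]
  rownames(atom) <- NULL
  structure(list(entry_id = entry_id, atom = atom), class = "structure3d")
}

# keep, per atom site, the altloc with the highest occupancy
#' @noRd
resolve_altlocs <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atom)
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$resid, atom$elety, sep = "|")
  ord <- order(key, -occ, alt)
  atom <- atom[ord, ]
  atom <- atom[!duplicated(key[ord]), ]
  atom[order(atom$eleno), ]
}

#' @export
print.structure3d <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<structure3d %s: %d atoms, %d residues (%d hetero), chains: %s>\n",
              x$entry_id, nrow(x$atom), nrow(rt), sum(rt$is_hetero),
              paste(unique(x$atom$chain), collapse = ",")))
  invisible(x)
}

#' Per-residue summary of a structure
#'
#' @param x a `structure3d`.
#' @param chain_id optional chain filter.
#' @return data frame with one row per residue: `chain`, `resno`,
#'   `insert`, `resid`, `is_hetero`, `n_atoms`, `plddt` (B-factor of the
#'   Calpha atom, `NA` for hetero or Calpha-less residues).
#' @export
residue_table <- function(x, chain_id = NULL) {
  atom <- x$atom
  if (!is.null(chain_id)) {
    if (!chain_id %in% atom$chain) stopf("chain '%s' not present in %s", chain_id, x$entry_id)
    atom <- atom[atom$chain == chain_id, ]
  }
  key <- paste(atom$chain, atom$resno, atom$insert, sep = "|")
  idx <- !duplicated(key)
  out <- data.frame(
    chain = atom$chain[idx], resno = atom$resno[idx],
    insert = atom$insert[idx], resid = atom$resid[idx],
    is_hetero = atom$type[idx] == "HETATM",
    n_atoms = as.vector(table(factor(key, levels = key[idx]))),
    stringsAsFactors = FALSE
  )
  ca <- atom[atom$elety == "CA" & atom$type == "ATOM", ]
  cakey <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
  out$plddt <- ca$b[match(paste(out$chain, out$resno, out$insert, sep = "|"), cakey)]
  rownames(out) <- NULL
  out
}

#' Trim low-confidence termini off a predicted model
#'
#' Removes the maximal contiguous N-terminal and C-terminal runs of
#' residues whose per-residue confidence (pLDDT, read from the Calpha
#' B-factor) is below `min_plddt`. Interior residues are never removed,
#' even when their confidence dips below the threshold: terminal
#' trimming keeps the retained model a single contiguous segment,
#' whereas global deletion would fragment the chain. Interior dips are
#' reported via `message()`.
#'
#' @param model a single-chain `structure3d` predicted model.
#' @param min_plddt confidence threshold, default 90.
#' @return the trimmed `structure3d` (a contiguous residue interval of
#'   the input). Idempotent.
#' @export
trim_by_confidence <- function(model, min_plddt = 90) {
  stopifnot(inherits(model, "structure3d"))
  rt <- residue_table(model)
  rt <- rt[!rt$is_hetero, ]
  if (length(unique(rt$chain)) != 1L)
    stopf("trim_by_confidence expects a single-chain model (found %d chains)",
          length(unique(rt$chain)))
  if (all(is.na(rt$plddt))) stopf("model has no Calpha confidence values")
  keep <- rt$plddt >= min_plddt
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stopf("empty model: all %d residues below pLDDT %g", nrow(rt), min_plddt)
  first <- which(keep)[1L]
  last <- which(keep)[sum(keep)]
  dips <- which(!keep[first:last])
  if (length(dips) > 0L)
    message(sprintf("retaining %d interior residue(s) below pLDDT %g (e.g. %s)",
                    length(dips), min_plddt,
                    paste(utils::head(rt$resno[first:last][dips], 5L), collapse = ", ")))
  span <- rt[first:last, ]
  atom <- model$atom
  poly <- atom$type == "ATOM"
  keys <- paste(atom$chain, atom$resno, atom$insert, sep = "|")
  ok <- keys %in% paste(span$chain, span$resno, span$insert, sep = "|")
  new_structure3d(atom[!poly | ok, ], model$entry_id)
}

#' Extract the one-letter sequence of a chain
#'
#' Polymer residues only, in residue-number order; nonstandard residues
#' map to `X` (selenomethionine `MSE` maps to `M`).
#'
#' @param x a `structure3d`.
#' @param chain_id chain identifier; defaults to the first chain.
#' @return a single character string (empty, with a warning, for a
#'   hetero-only chain).
#' @export
extract_sequence <- function(x, chain_id = NULL) {
  chain_id <- chain_id %||% x$atom$chain[1L]
  rt <- residue_table(x, chain_id)
  rt <- rt[!rt$is_hetero, ]
  if (nrow(rt) == 0L) {
    warnf("chain '%s' of %s has no polymer residues", chain_id, x$entry_id)
    return("")
  }
  rt <- rt[order(rt$resno, rt$insert), ]
  paste(aa_three_to_one(rt$resid), collapse = "")
}

#' Write a structure to a PDB file
#'
#' Standard fixed-column PDB output (coordinates `%8.3f`, B-factor
#' `%6.2f`); ATOM/HETATM records are preserved from the input.
#'
#' @param x a `structure3d`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  a <- x$atom
  o <- a$o; o[is.na(o)] <- 1
  b <- a$b; b[is.na(b)] <- 0
  chain <- a$chain; chain[chain == " "] <- ""
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    type = a$type, resno = a$resno, resid = a$resid,
    eleno = seq_len(nrow(a)), elety = a$elety, chain = chain,
    insert = a$insert, o = o, b = b, elesy = a$elesy
  ))
  invisible(path)
}

# polymer Calpha subset of a chain, ordered by residue number
#' @noRd
ca_table <- function(x, chain_id = NULL) {
  a <- x$atom
  chain_id <- chain_id %||% a$chain[a$type == "ATOM"][1L]
  a <- a[a$chain == chain_id & a$type == "ATOM" & a$elety == "CA", ]
  if (nrow(a) == 0L) stopf("no Calpha atoms on chain '%s' of %s", chain_id, x$entry_id)
  a <- a[order(a$resno, a$insert), ]
  a$aa <- aa_three_to_one(a$resid)
  a
}

# heavy (non-hydrogen) atom mask
#' @noRd
heavy_mask <- function(atom) !(toupper(atom$elesy) %in% c("H", "D"))
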
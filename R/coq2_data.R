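# Packaged annotation tables and reconstructions for the human COQ2
# case study. Tables that transcribe published results (variant table,
# variant RMSD ranking, motif positions, binding-site correspondences)
# are exact; the topology boundaries, the CCD subset, the hit table and
# the scaffold sequence/confidence profile are synthetic reconstructions
# and are labelled as such in their files and docs.

#' @noRd
sitegraft_extdata <- function(file) {
  path <- system.file("extdata", file, package = "sitegraft", mustWork = FALSE)
  if (!nzchar(path)) stopf("packaged data file missing: %s", file)
  path
}

#' @noRd
read_annotation_tsv <- function(file) {
  utils::read.delim(sitegraft_extdata(file), comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' COQ2 annotation tables
#'
#' Accessors for the packaged annotation tables of the human COQ2
#' prenyltransferase (UniProt Q96H96, the 371-residue isoform whose
#' numbering all positions follow):
#'
#' * `coq2_variants()`: the twelve missense variants associated with
#'   primary CoQ deficiency, their protein location and pathogenicity
#'   labels from four sources (SIFT, ClinVar, LOVD, Franklin).
#' * `coq2_variant_rmsd()`: the published global Calpha RMSD of each
#'   variant's predicted model against the wild-type model, ascending.
#' * `coq2_motifs()`: the two Asp-rich `DxxxD` motifs (134-138 and
#'   255-259) and the `YxxxK` motif (195-199) on the matrix-side loops.
#' * `coq2_topology()`: the nine transmembrane helices S1-S9 and
#'   connecting loops with their membrane side. Boundary residues are a
#'   synthetic reconstruction consistent with the published per-segment
#'   residue assignments (see the file header).
#' * `coq2_site_correspondence()`: proposed substrate-binding residues
#'   of the ApUbiA homolog and their COQ2 equivalents, with the
#'   functional role of each site (diphosphate/Mg coordination, tail C1
#'   proximity, aromatic-substrate contact).
#'
#' @return a data frame (see each description).
#' @name coq2_annotations
NULL

#' @rdname coq2_annotations
#' @export
coq2_variants <- function() read_annotation_tsv("coq2_variants.tsv")

#' @rdname coq2_annotations
#' @export
coq2_variant_rmsd <- function() read_annotation_tsv("coq2_variant_rmsd.tsv")

#' @rdname coq2_annotations
#' @export
coq2_motifs <- function() read_annotation_tsv("coq2_motifs.tsv")

#' @rdname coq2_annotations
#' @export
coq2_topology <- function() read_annotation_tsv("coq2_topology_synthetic.tsv")

#' @rdname coq2_annotations
#' @export
coq2_site_correspondence <- function() read_annotation_tsv("coq2_site_correspondence.tsv")

#' Paths to the packaged case-study input fixtures
#'
#' `coq2_ccd_path()` returns the reconstructed chemical-component
#' dictionary subset (mmCIF) covering the ligands of the COQ2 homolog
#' structures plus the query substrates; `coq2_hhr_path()` the
#' reconstructed profile-HMM hit table. Both are synthetic
#' reconstructions (see their file headers): component SMILES were
#' rewritten from the published chemical identities, and hit
#' probabilities are invented around the published 50% selection bar.
#'
#' @return a file path.
#' @export
coq2_ccd_path <- function() sitegraft_extdata("ccd_subset_synthetic.cif")

#' @rdname coq2_ccd_path
#' @export
coq2_hhr_path <- function() sitegraft_extdata("hhpred_hits_synthetic.hhr")

#' Synthetic COQ2 scaffold sequence
#'
#' A deterministic 371-residue sequence that carries every residue the
#' case study pins to a position - the twelve variant wild-type residues,
#' the Asp-rich and YxxxK motifs, and the binding-site correspondence
#' residues - at its published position, with a fixed filler pattern
#' elsewhere. It is a synthetic scaffold for exercising sequence-level
#' operations (variant application, annotation joins), not the real
#' Q96H96 sequence.
#'
#' @return a single 371-character string.
#' @export
coq2_scaffold_sequence <- function() {
  n <- 371L
  filler <- strsplit("LAVILMFWSTAGPVILFYAM", "")[[1]]
  seqv <- filler[(37L * seq_len(n)) %% length(filler) + 1L]
  pins <- c(
    `96` = "S", `123` = "R", `130` = "N", `132` = "M", `134` = "D",
    `138` = "D", `143` = "R", `147` = "R", `178` = "N", `195` = "Y",
    `199` = "K", `228` = "C", `236` = "L", `244` = "T", `247` = "Y",
    `248` = "D", `251` = "Y", `252` = "A", `255` = "D", `259` = "D",
    `275` = "T", `340` = "G")
  seqv[as.integer(names(pins))] <- pins
  paste(seqv, collapse = "")
}

#' Reconstructed per-residue confidence profile for the COQ2 model
#'
#' Deterministic 371-value pLDDT profile following the published
#' description of the predicted COQ2 model: very low confidence
#' (pLDDT < 50) over the disordered N-terminus (positions 1-57), a
#' high-confidence core (> 90) spanning positions 60-354, and low
#' confidence (50-70) from position 356 to the C-terminus. The
#' residue-level values are synthetic (smooth deterministic wiggles
#' inside each published band); only the band structure is taken from
#' the publication, so trimming this profile at 90 recovers the
#' published 60-354 segment by construction of the bands.
#'
#' @return numeric vector of length 371, names = positions.
#' @export
coq2_confidence_profile <- function() {
  pos <- 1:371
  p <- numeric(371L)
  p[1:57] <- 30 + 10 * sin(pos[1:57] / 5)
  p[58] <- 76
  p[59] <- 86
  p[60:354] <- 95 + 3 * sin(pos[60:354] / 11)
  p[355] <- 88
  p[356:371] <- 60 + 5 * sin(pos[356:371] / 3)
  stats::setNames(round(p, 2), pos)
}

#' Synthetic COQ2-like scaffold model
#'
#' A nine-helix bundle carrying the scaffold sequence
#' ([coq2_scaffold_sequence()]) and the reconstructed confidence profile
#' ([coq2_confidence_profile()]) in its B-factor column - a stand-in
#' geometry for exercising the model-level operations (confidence
#' trimming, superposition, site annotation) offline. It is not the
#' predicted COQ2 structure.
#'
#' @return a `structure3d` of 371 residues in one chain.
#' @export
coq2_scaffold_model <- function() {
  make_helical_bundle(n_helices = 9L,
                      helix_len = c(42L, 41L, 41L, 41L, 41L, 41L, 41L, 41L, 42L),
                      sequence = coq2_scaffold_sequence(),
                      plddt = coq2_confidence_profile(),
                      seed = 20240496L)
}
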
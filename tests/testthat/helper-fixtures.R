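# shared fixture builders; everything is generated in code at test time

# toy three-component dictionary exercising descriptor preference
write_toy_ccd <- function(path = tempfile(fileext = ".cif")) {
  writeLines(c(
    "data_GPP",
    "_chem_comp.id GPP",
    '_chem_comp.name "GERANYL DIPHOSPHATE"',
    "loop_",
    "_pdbx_chem_comp_descriptor.comp_id",
    "_pdbx_chem_comp_descriptor.type",
    "_pdbx_chem_comp_descriptor.program",
    "_pdbx_chem_comp_descriptor.program_version",
    "_pdbx_chem_comp_descriptor.descriptor",
    'GPP SMILES CACTVS 3.341 "CC(C)=CCCC(C)=CCOP(O)(=O)OP(O)(O)=O"',
    'GPP SMILES_CANONICAL CACTVS 3.341 "CC(C)=CCC/C(C)=C/COP(O)(=O)OP(O)(O)=O"',
    'GPP SMILES_CANONICAL "OpenEye OEToolkits" 1.5.0 "CC(C)=CCC\\C(C)=C\\COP(O)(=O)OP(O)(O)=O"',
    "#",
    "data_PHB",
    "_chem_comp.id PHB",
    '_chem_comp.name "P-HYDROXYBENZOIC ACID"',
    "loop_",
    "_pdbx_chem_comp_descriptor.comp_id",
    "_pdbx_chem_comp_descriptor.type",
    "_pdbx_chem_comp_descriptor.program",
    "_pdbx_chem_comp_descriptor.program_version",
    "_pdbx_chem_comp_descriptor.descriptor",
    'PHB SMILES_CANONICAL CACTVS 3.341 "Oc1ccc(cc1)C(O)=O"',
    "#",
    "data_MG",
    "_chem_comp.id MG",
    '_chem_comp.name "MAGNESIUM ION"',
    "loop_",
    "_pdbx_chem_comp_descriptor.comp_id",
    "_pdbx_chem_comp_descriptor.type",
    "_pdbx_chem_comp_descriptor.program",
    "_pdbx_chem_comp_descriptor.program_version",
    "_pdbx_chem_comp_descriptor.descriptor",
    'MG SMILES_CANONICAL CACTVS 3.341 "[Mg+2]"',
    "#"), path)
  path
}

# hand-written PDB fragments
pdb_atom_line <- function(serial, name, resn, chain, resi, x, y, z,
                          occ = 1, b = 0, alt = " ", elem = NULL) {
  if (is.null(elem)) elem <- substr(trimws(name), 1L, 1L)
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resi, x, y, z, occ, b, elem)
}

write_three_residue_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    pdb_atom_line(1, " CA ", "ALA", "A", 1, 0, 0, 0, b = 91),
    pdb_atom_line(2, " CA ", "GLY", "A", 2, 3.8, 0, 0, b = 95),
    pdb_atom_line(3, " CA ", "SER", "A", 3, 7.6, 0, 0, b = 97),
    "END"), path)
  path
}

# one shared synthetic case-study input set per test run
fixture_env <- new.env()
case_fixture_dir <- function() {
  if (is.null(fixture_env$dir)) {
    dir <- file.path(tempdir(), "sitegraft-fixset")
    fixture_env$truth <- write_fixture_set(dir, seed = 11L)
    fixture_env$dir <- dir
  }
  fixture_env$dir
}
case_fixture_truth <- function() {
  case_fixture_dir()
  fixture_env$truth
}

case_fixture_config <- function(seed = 11L) {
  dir <- case_fixture_dir()
  run_config(
    model = file.path(dir, "query_model.pdb"),
    ccd = coq2_ccd_path(),
    hit_table = coq2_hhr_path(),
    structures = stats::setNames(
      file.path(dir, paste0(c("4OD5", "4TQ3", "6M31", "8DJM", "7Q21", "7E1V"),
                            ".pdb")),
      c("4OD5", "4TQ3", "6M31", "8DJM", "7Q21", "7E1V")),
    alias = c("4OD4_A" = "4OD5_A"),
    variant_models = stats::setNames(
      file.path(dir, "variants", paste0(c("var_a", "var_b", "var_c"), ".pdb")),
      c("var_a", "var_b", "var_c")),
    seed = seed)
}

# independent MACCS oracle: RDKit through the system python
rdkit_maccs_keys <- function(smiles) {
  script <- paste(
    "import sys, json",
    "from rdkit import Chem",
    "from rdkit.Chem import MACCSkeys",
    "out = {}",
    "for s in json.load(sys.stdin):",
    "    m = Chem.MolFromSmiles(s)",
    "    out[s] = sorted(MACCSkeys.GenMACCSKeys(m).GetOnBits()) if m else None",
    "print(json.dumps(out))", sep = "\n")
  res <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  input = jsonlite::toJSON(smiles),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) return(NULL)
  jsonlite::fromJSON(paste(res, collapse = ""))
}

# best rigid fit over single-axis rotation grids (1 degree) - a
# brute-force bound used as the optimality oracle for kabsch()
grid_fit_rmsd <- function(X, Y, step_deg = 1) {
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  best <- Inf
  for (ax in axes) {
    for (deg in seq(0, 359, by = step_deg)) {
      R <- sitegraft:::rotation_about_axis(ax, deg * pi / 180)
      rmsd <- sqrt(mean(rowSums((Yc %*% t(R) - Xc)^2)))
      if (rmsd < best) best <- rmsd
    }
  }
  best
}

# one-row hits TSV
write_one_hit_tsv <- function(pdb, chain, prob) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("pdb_id\tchain_id\tprobability\tqstart\tqend\ttstart\ttend\tligands",
               sprintf("%s\t%s\t%s\t1\t100\t1\t100\t", pdb, chain, prob)), f)
  f
}
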
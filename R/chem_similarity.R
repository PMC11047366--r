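#' MACCS structural-key fingerprint of a molecule
#'
#' Evaluates the public 166-key MACCS structural-key set on the
#' molecular graph parsed from a SMILES string (hydrogens implicit).
#' Key evaluation is delegated to Open Babel via ChemmineOB; on-bit
#' indices follow the standard key numbering 1-166 and, on the panels
#' checked in the test suite, agree key-for-key with RDKit's
#' implementation.
#'
#' @param smiles SMILES string, or a one-row catalog record with
#'   `smiles` and `ccd_id` columns.
#' @param id identifier stored with the fingerprint (defaults to the
#'   record's `ccd_id`, else `NA`).
#' @return a `maccs_fp` object: list with `keys` (sorted integer vector,
#'   subset of 1..166) and `id`. `NULL`, with a warning, when the SMILES
#'   cannot be parsed.
#' @export
maccs_fingerprint <- function(smiles, id = NULL) {
  if (is.data.frame(smiles) || is.list(smiles)) {
    id <- id %||% smiles$ccd_id
    smiles <- smiles$smiles
  }
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(smiles)) stopf("no SMILES available for '%s'", id %||% "?")
  bits <- tryCatch(
    ChemmineOB::fingerprint_OB(ChemmineOB::forEachMol("SMILES", smiles, identity),
                               "MACCS"),
    error = function(e) NULL)
  if (is.null(bits) || length(bits) == 0L) {
    warnf("unparseable SMILES for '%s'; skipped", id %||% smiles)
    return(NULL)
  }
  keys <- which(bits == 1)
  if (length(keys) > 0L && max(keys) > 166L)
    stopf("fingerprint key %d outside the 166-key scheme", max(keys))
  structure(list(keys = as.integer(keys), id = id %||% NA_character_),
            class = "maccs_fp")
}

#' @export
print.maccs_fp <- function(x, ...) {
  cat(sprintf("<maccs_fp %s: %d keys set>\n", x$id, length(x$keys)))
  invisible(x)
}

#' Tanimoto coefficient of two structural-key fingerprints
#'
#' Intersection over union of the on-key sets; 0 when both sets are
#' empty. Symmetric, bounded in `[0, 1]`, and equal to 1 exactly when
#' two non-empty key sets coincide.
#'
#' @param a,b `maccs_fp` objects.
#' @return a number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "maccs_fp"), inherits(b, "maccs_fp"))
  u <- length(union(a$keys, b$keys))
  if (u == 0L) return(0)
  length(intersect(a$keys, b$keys)) / u
}

#' Screen a ligand catalog by similarity to a query substrate
#'
#' Computes the MACCS/Tanimoto similarity of every catalog component to
#' the query molecule and ranks the results. The default threshold of
#' 0.3 follows the usual screening convention for structural-key
#' fingerprints; the comparison is strict (`tanimoto > threshold`) by
#' default.
#'
#' @param catalog data frame with `ccd_id`, `name`, `smiles` (from
#'   [read_ccd()]). Components without SMILES, or with unparseable
#'   SMILES, are skipped with a warning.
#' @param query a `ccd_id` present in the catalog, or a list/one-row
#'   data frame with `ccd_id` and `smiles`. A query without SMILES is an
#'   error.
#' @param threshold similarity threshold in `[0, 1]`, default 0.3.
#' @param strict if `TRUE` (default) `passed` means strictly greater
#'   than the threshold, otherwise greater-or-equal.
#' @return data frame sorted by decreasing `tanimoto` (ties broken by
#'   `ccd_id`): `ccd_id`, `name`, `tanimoto`, `passed`.
#' @export
screen_ligands <- function(catalog, query, threshold = 0.3, strict = TRUE) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is.character(query) && length(query) == 1L) {
    row <- catalog[catalog$ccd_id == query, , drop = FALSE]
    if (nrow(row) == 0L) stopf("query component '%s' not in catalog", query)
    query <- row[1L, ]
  }
  if (is.null(query$smiles) || is.na(query$smiles))
    stopf("query component '%s' has no SMILES", query$ccd_id %||% "?")
  qfp <- maccs_fingerprint(query$smiles, id = query$ccd_id)
  if (is.null(qfp)) stopf("query SMILES for '%s' is unparseable", query$ccd_id %||% "?")
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    rec <- catalog[i, ]
    if (is.na(rec$smiles)) {
      warnf("component %s has no SMILES; skipped", rec$ccd_id)
      return(NULL)
    }
    fp <- maccs_fingerprint(rec$smiles, id = rec$ccd_id)
    if (is.null(fp)) return(NULL)
    tc <- tanimoto(qfp, fp)
    data.frame(ccd_id = rec$ccd_id, name = rec$name, tanimoto = tc,
               passed = if (strict) tc > threshold else tc >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ccd_id = character(), name = character(),
                      tanimoto = numeric(), passed = logical(),
                      stringsAsFactors = FALSE)
  out <- out[order(-out$tanimoto, out$ccd_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
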
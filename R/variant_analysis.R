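#' Parse a protein missense-variant label
#'
#' Accepts `p.Ser96Asn`-style (three-letter) or `S96N`-style
#' (one-letter) notation.
#'
#' @param x variant string(s).
#' @return data frame: `variant`, `position`, `wt`, `mut` (one-letter).
#' @export
parse_variant <- function(x) {
  m <- regmatches(x, regexec(
    "^(?:p\\.)?([A-Za-z]{1,3})(\\d+)([A-Za-z]{1,3})$", x))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stopf("unparseable variant label(s): %s",
                      paste(x[bad], collapse = ", "))
  one <- function(aa) {
    ifelse(nchar(aa) == 1L, toupper(aa), aa_three_to_one(toupper(aa)))
  }
  data.frame(
    variant = x,
    position = as.integer(vapply(m, `[`, "", 3L)),
    wt = one(vapply(m, `[`, "", 2L)),
    mut = one(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE)
}

#' Apply a missense variant to a sequence
#'
#' Single-position substitution; the stated wild-type residue must match
#' the sequence at that position (a mismatch is a fatal reference
#' error). A synonymous "variant" (wild type equals mutant) returns the
#' sequence unchanged with a warning.
#'
#' @param sequence one-letter amino-acid string.
#' @param variant a variant label (see [parse_variant()]) or a
#'   list/one-row data frame with `position`, `wt`, `mut`.
#' @return the mutated sequence (same length).
#' @export
apply_variant <- function(sequence, variant) {
  if (is.character(variant)) variant <- parse_variant(variant)
  pos <- variant$position[1L]; wt <- variant$wt[1L]; mut <- variant$mut[1L]
  if (pos < 1L || pos > nchar(sequence))
    stopf("variant position %d outside sequence (length %d)", pos, nchar(sequence))
  have <- substr(sequence, pos, pos)
  if (have != wt)
    stopf("reference mismatch at position %d: sequence has %s, variant states %s",
          pos, have, wt)
  if (wt == mut) {
    warnf("variant at position %d does not change the residue (%s)", pos, wt)
    return(sequence)
  }
  substr(sequence, pos, pos) <- mut
  sequence
}

#' Compare a variant structural model against the wild type
#'
#' Sequence-dependent superposition of a variant model onto the
#' wild-type model, followed by a per-residue Calpha deviation profile
#' over all shared residues. Two global RMSD conventions are reported:
#' all aligned Calpha pairs with outlier rejection disabled (`rmsd`; a
#' point mutant aligns end to end, and rejection would hide exactly the
#' local signal of interest) and the rejection-on value
#' (`rmsd_rejected`).
#'
#' Locally altered regions are flagged with a robust rule: maximal runs
#' of at least `flag_min_run` residues whose deviation exceeds
#' `median + flag_k * MAD` of the profile.
#'
#' @param wildtype,variant_model `structure3d` objects.
#' @param flag_k MAD multiplier (default 2).
#' @param flag_min_run minimum run length to flag (default 3).
#' @return list with `superposition` (rejection-free
#'   `superposition_result`), `rmsd`, `rmsd_rejected`, `profile` (data
#'   frame `resno_wt`, `resno_var`, `deviation`), `threshold`, and
#'   `flagged` (data frame `start`, `end`, `max_deviation` in wild-type
#'   numbering).
#' @export
compare_models <- function(wildtype, variant_model, flag_k = 2,
                           flag_min_run = 3L) {
  sup <- superpose(wildtype, variant_model, mode = "sequence_dependent",
                   reject_cutoff = Inf, max_cycles = 1L)
  sup_rej <- superpose(wildtype, variant_model, mode = "sequence_dependent")
  prof <- sup$residuals
  profile <- data.frame(resno_wt = prof$resno_query,
                        resno_var = prof$resno_target,
                        deviation = prof$residual)
  thr <- stats::median(profile$deviation) + flag_k * stats::mad(profile$deviation)
  over <- profile$deviation > thr
  flagged <- flag_runs(profile$resno_wt, over, profile$deviation, flag_min_run)
  list(superposition = sup, rmsd = sup$rmsd, rmsd_rejected = sup_rej$rmsd,
       profile = profile, threshold = thr, flagged = flagged)
}

#' @noRd
flag_runs <- function(resno, over, deviation, min_run) {
  empty <- data.frame(start = integer(), end = integer(),
                      max_deviation = numeric())
  if (!any(over)) return(empty)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(empty)
  data.frame(
    start = resno[starts[keep]],
    end = resno[ends[keep]],
    max_deviation = vapply(which(keep), function(k)
      max(deviation[starts[k]:ends[k]]), numeric(1L)))
}

#' Rank variant models by similarity to the wild type
#'
#' Ascending global RMSD: from most similar to the wild type to most
#' divergent. A stable sort; the output rows are a permutation of the
#' input.
#'
#' @param results data frame with at least `variant` and `rmsd` columns
#'   (pathogenicity columns are carried through for correlation
#'   inspection).
#' @return the input ordered by increasing `rmsd`.
#' @export
rank_variants <- function(results) {
  stopifnot(nrow(results) >= 1L, "rmsd" %in% names(results))
  out <- results[order(results$rmsd), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation between pathogenicity label and structural deviation
#'
#' Spearman rank correlation between a binary pathogenicity coding
#' (pathogenic = 1, tolerated = 0) and the global RMSD of each variant
#' model - the check behind the negative finding that the structural
#' similarity of a variant model to the wild type does not track its
#' pathogenicity.
#'
#' @param variant_rmsd data frame with `sift` (containing "Pathogenic"
#'   or "Tolerated") and `rmsd`; default the packaged ranking
#'   ([coq2_variant_rmsd()]).
#' @return list with `rho`, `p_value`, `n`.
#' @export
pathogenicity_rmsd_correlation <- function(variant_rmsd = coq2_variant_rmsd()) {
  patho <- as.integer(grepl("pathogenic", variant_rmsd$sift, ignore.case = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(patho, variant_rmsd$rmsd, method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n = nrow(variant_rmsd))
}
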
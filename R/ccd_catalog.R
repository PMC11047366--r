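#' Parse a chemical-component dictionary
#'
#' Reads component definitions from a CCD-style mmCIF file (one
#' `data_<ID>` block per component, as in the wwPDB components
#' dictionary) or from the package's TSV dialect (columns `ccd_id`,
#' `name`, `smiles`). For each component the name and SMILES descriptor
#' are extracted. When a component lists several SMILES descriptors, one
#' is chosen deterministically: canonical SMILES first
#' (`SMILES_CANONICAL` over `SMILES`), descriptor programs ordered
#' OpenEye before CACTVS before anything else, first match wins.
#' Components without any SMILES are retained with `smiles = NA`.
#'
#' @param path dictionary file (`.cif` or `.tsv`).
#' @return data frame with one row per component: `ccd_id`, `name`,
#'   `smiles`.
#' @export
read_ccd <- function(path) {
  if (!file.exists(path)) stopf("component dictionary not found: %s", path)
  if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) {
    out <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
    need <- c("ccd_id", "name", "smiles")
    if (!all(need %in% names(out))) stopf("TSV dictionary %s lacks columns %s",
                                          path, paste(need, collapse = ", "))
    out <- out[, need]
  } else {
    out <- parse_ccd_cif(path)
  }
  if (nrow(out) == 0L) warnf("empty component dictionary: %s", path)
  if (anyDuplicated(out$ccd_id))
    stopf("duplicate component id(s) in %s: %s", path,
          paste(unique(out$ccd_id[duplicated(out$ccd_id)]), collapse = ", "))
  rownames(out) <- NULL
  out
}

#' @noRd
parse_ccd_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^data_", lines)
  if (length(starts) == 0L) {
    if (all(grepl("^\\s*(#.*)?$", lines))) {
      return(data.frame(ccd_id = character(), name = character(),
                        smiles = character(), stringsAsFactors = FALSE))
    }
    stopf("%s: no data_ block found; not a component dictionary", path)
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  recs <- lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    tryCatch(parse_ccd_block(block),
             error = function(e) stopf("%s: failed to parse block '%s': %s",
                                       path, sub("^data_", "", lines[starts[i]]),
                                       conditionMessage(e)))
  })
  do.call(rbind, recs)
}

#' @noRd
parse_ccd_block <- function(block) {
  id <- cif_item(block, "_chem_comp.id")
  if (is.na(id)) stop("missing _chem_comp.id")
  name <- cif_item(block, "_chem_comp.name")
  desc <- cif_descriptor_loop(block)
  smiles <- NA_character_
  if (nrow(desc) > 0L) {
    desc$type_rank <- match(toupper(desc$type), c("SMILES_CANONICAL", "SMILES"))
    prog <- toupper(desc$program)
    desc$prog_rank <- ifelse(grepl("OPENEYE", prog), 1L,
                      ifelse(grepl("CACTVS", prog), 2L, 3L))
    desc <- desc[!is.na(desc$type_rank), ]
    if (nrow(desc) > 0L) {
      desc <- desc[order(desc$type_rank, desc$prog_rank), ]
      smiles <- desc$descriptor[1L]
    }
  }
  data.frame(ccd_id = id, name = name, smiles = smiles, stringsAsFactors = FALSE)
}

# value of a single (non-loop) mmCIF item; handles same-line, next-line
# and semicolon-delimited values
#' @noRd
cif_item <- function(block, tag) {
  hit <- grep(paste0("^", tag, "(\\s|$)"), block)
  if (length(hit) == 0L) return(NA_character_)
  line <- block[hit[1L]]
  rest <- sub(paste0("^", tag, "\\s*"), "", line)
  if (nzchar(rest)) return(cif_tokens(rest)[1L])
  nxt <- block[hit[1L] + 1L]
  if (startsWith(nxt, ";")) {
    val <- sub("^;", "", nxt)
    j <- hit[1L] + 2L
    while (j <= length(block) && block[j] != ";") {
      val <- paste0(val, block[j]); j <- j + 1L
    }
    return(val)
  }
  cif_tokens(nxt)[1L]
}

# rows of the _pdbx_chem_comp_descriptor loop
#' @noRd
cif_descriptor_loop <- function(block) {
  empty <- data.frame(type = character(), program = character(),
                      descriptor = character(), stringsAsFactors = FALSE)
  loops <- grep("^loop_\\s*$", block)
  for (lp in loops) {
    j <- lp + 1L
    tags <- character()
    while (j <= length(block) && grepl("^_", block[j])) {
      tags <- c(tags, sub("\\s.*$", "", block[j])); j <- j + 1L
    }
    if (!any(grepl("^_pdbx_chem_comp_descriptor\\.", tags))) next
    rows <- list()
    while (j <= length(block) &&
           !grepl("^(loop_|_|#|data_)", block[j]) && nzchar(trimws(block[j]))) {
      toks <- cif_tokens(block[j])
      # continuation: a row may wrap onto following lines
      while (length(toks) < length(tags) && j < length(block) &&
             !grepl("^(loop_|_|#|data_)", block[j + 1L])) {
        j <- j + 1L
        toks <- c(toks, cif_tokens(block[j]))
      }
      if (length(toks) != length(tags))
        stop(sprintf("descriptor row has %d fields, expected %d",
                     length(toks), length(tags)))
      rows[[length(rows) + 1L]] <- toks
      j <- j + 1L
    }
    if (length(rows) == 0L) return(empty)
    m <- do.call(rbind, rows)
    colnames(m) <- sub("^_pdbx_chem_comp_descriptor\\.", "", tags)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    for (k in c("type", "program", "descriptor"))
      if (is.null(df[[k]])) df[[k]] <- NA_character_
    return(df[, c("type", "program", "descriptor")])
  }
  empty
}

#' Parse a profile-HMM hit table (HHR summary format)
#'
#' Reads the hit-summary section of an HHsearch/HHblits `.hhr` report:
#' one line per hit carrying the target identifier (`<pdb>_<chain>`),
#' probability (percent), alignment score and the aligned query/template
#' residue ranges. Ligand lists start empty; fill them with
#' [attach_ligands()].
#'
#' @param path `.hhr` report, or the package's hits TSV (see
#'   [write_hits_tsv()]).
#' @return a hits data frame: `pdb_id`, `chain_id`, `probability`,
#'   `qstart`, `qend`, `tstart`, `tend`, and a `ligands` list column of
#'   data frames (`ccd_id`, `chain_id`).
#' @export
read_hhr <- function(path) {
  if (!file.exists(path)) stopf("hit table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  head_at <- grep("^\\s*No\\s+Hit\\s", lines)
  if (length(head_at) == 0L) stopf("%s: no hit-summary header found", path)
  i <- head_at[1L] + 1L
  hits <- list()
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    ln <- lines[i]
    if (!grepl("^\\s*\\d+\\s", ln)) break
    hit_id <- sub("^\\s*\\d+\\s+(\\S+).*$", "\\1", ln)
    if (!grepl("^[0-9A-Za-z]{4}_\\S+$", hit_id))
      stopf("%s line %d: malformed hit identifier '%s'", path, i, hit_id)
    # numeric tail: Prob E-value P-value Score SS Cols Query Template (Len)
    tail_part <- substring(ln, 36L)
    toks <- strsplit(trimws(tail_part), "\\s+")[[1]]
    if (length(toks) < 8L)
      stopf("%s line %d: truncated hit line", path, i)
    prob <- suppressWarnings(as.numeric(toks[1L]))
    if (is.na(prob) || prob < 0 || prob > 100)
      stopf("%s line %d: malformed probability '%s'", path, i, toks[1L])
    qr <- parse_range(toks[7L], path, i)
    tr <- parse_range(toks[8L], path, i)
    hits[[length(hits) + 1L]] <- data.frame(
      pdb_id = toupper(sub("_.*$", "", hit_id)),
      chain_id = sub("^[^_]*_", "", hit_id),
      probability = prob,
      qstart = qr[1L], qend = qr[2L], tstart = tr[1L], tend = tr[2L],
      stringsAsFactors = FALSE)
    i <- i + 1L
  }
  out <- if (length(hits) == 0L) {
    data.frame(pdb_id = character(), chain_id = character(),
               probability = numeric(), qstart = integer(), qend = integer(),
               tstart = integer(), tend = integer(), stringsAsFactors = FALSE)
  } else do.call(rbind, hits)
  out$ligands <- rep(list(empty_ligand_set()), nrow(out))
  out
}

#' @noRd
parse_range <- function(tok, path, lineno) {
  m <- regmatches(tok, regexec("^(\\d+)-(\\d+)$", tok))[[1]]
  if (length(m) != 3L)
    stopf("%s line %d: malformed residue range '%s'", path, lineno, tok)
  r <- as.integer(m[2:3])
  if (r[1L] > r[2L])
    stopf("%s line %d: empty residue range '%s'", path, lineno, tok)
  r
}

#' @noRd
empty_ligand_set <- function() {
  data.frame(ccd_id = character(), chain_id = character(), stringsAsFactors = FALSE)
}

#' Attach observed ligands to a homology hit
#'
#' Scans the deposited structure of a hit for hetero components and tags
#' each with the polymer chain(s) it is bound to. "Bound to chain X"
#' uses a reproducible distance rule: any hetero heavy atom within
#' `max_dist` (default 4 Angstrom) of any polymer heavy atom of chain X.
#' Waters and other solvent components on the deny list are excluded;
#' metal ions count as ligands.
#'
#' @param hits a hits data frame (one or more rows) from [read_hhr()].
#' @param structures a named list of `structure3d` objects keyed by PDB
#'   id (e.g. `list("4TQ3" = ...)`), or a single `structure3d` when
#'   `hits` has one row.
#' @param max_dist binding distance rule, Angstrom.
#' @param deny component ids excluded from ligand lists.
#' @return `hits` with the `ligands` list column filled.
#' @export
attach_ligands <- function(hits, structures, max_dist = 4.0,
                           deny = c("HOH", "DOD")) {
  if (inherits(structures, "structure3d")) {
    stopifnot(nrow(hits) == 1L)
    structures <- stats::setNames(list(structures), hits$pdb_id[1L])
  }
  for (i in seq_len(nrow(hits))) {
    s <- structures[[hits$pdb_id[i]]]
    if (is.null(s)) stopf("no structure supplied for %s", hits$pdb_id[i])
    if (!hits$chain_id[i] %in% s$atom$chain)
      stopf("structure %s lacks chain '%s'", hits$pdb_id[i], hits$chain_id[i])
    hits$ligands[[i]] <- structure_ligands(s, max_dist = max_dist, deny = deny)
  }
  hits
}

# all (ccd_id, bound-chain) pairs for the hetero components of a structure
#' @noRd
structure_ligands <- function(s, max_dist = 4.0, deny = c("HOH", "DOD")) {
  a <- s$atom[heavy_mask(s$atom), ]
  het <- a[a$type == "HETATM" & !(a$resid %in% deny), ]
  poly <- a[a$type == "ATOM", ]
  if (nrow(het) == 0L || nrow(poly) == 0L) return(empty_ligand_set())
  het_key <- paste(het$resid, het$chain, het$resno, het$insert, sep = "|")
  pairs <- list()
  for (k in unique(het_key)) {
    hx <- het[het_key == k, c("x", "y", "z")]
    d2 <- dist2_xyz(hx, poly[, c("x", "y", "z")])
    near <- apply(d2 <= max_dist^2, 2L, any)
    chains <- sort(unique(poly$chain[near]))
    if (length(chains) > 0L)
      pairs[[length(pairs) + 1L]] <- data.frame(
        ccd_id = het$resid[het_key == k][1L], chain_id = chains,
        stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0L) return(empty_ligand_set())
  out <- do.call(rbind, pairs)
  out <- unique(out)
  out[order(out$ccd_id, out$chain_id), , drop = FALSE]
}

#' Select homology hits for ligand transfer
#'
#' Retains hits whose probability is strictly greater than
#' `min_probability` and that carry at least one ligand bound to the
#' hit's own chain; hits whose ligands all sit on other chains are
#' dropped. Multiple hits to the same entry/chain (one homolog aligned
#' over several regions) are collapsed to the one with the best
#' probability.
#'
#' @param hits hits data frame with ligands attached.
#' @param min_probability percent threshold in `[0, 100]`, default 50.
#' @return the retained subset, ordered by decreasing probability.
#'   Idempotent.
#' @export
select_hits <- function(hits, min_probability = 50) {
  stopifnot(min_probability >= 0, min_probability <= 100)
  own <- vapply(seq_len(nrow(hits)), function(i) {
    lg <- hits$ligands[[i]]
    nrow(lg) > 0L && hits$chain_id[i] %in% lg$chain_id
  }, logical(1L))
  out <- hits[hits$probability > min_probability & own, , drop = FALSE]
  out <- collapse_duplicate_hits(out)
  out[order(-out$probability), , drop = FALSE]
}

#' Collapse repeated hits to the same entry and chain
#'
#' @param hits hits data frame.
#' @return one row per (pdb_id, chain_id), keeping the best probability.
#' @export
collapse_duplicate_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$pdb_id, hits$chain_id, sep = "_")
  ord <- order(key, -hits$probability)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(key[ord]), , drop = FALSE]
}

#' Apply an explicit alias map to hits
#'
#' Substitutes one entry/chain for another before structures are
#' fetched, e.g. swapping an apo structure for the ligand-bound
#' deposition of the same protein (`c("4OD4_A" = "4OD5_A")`). Aliasing
#' is deliberately explicit and user-supplied, never automatic.
#'
#' @param hits hits data frame.
#' @param alias named character vector, `old_id = new_id`, ids in
#'   `<pdb>_<chain>` form.
#' @return `hits` with aliased ids; ligand lists of aliased rows are
#'   reset (re-attach from the aliased structure).
#' @export
apply_hit_aliases <- function(hits, alias) {
  if (length(alias) == 0L || nrow(hits) == 0L) return(hits)
  key <- paste(hits$pdb_id, hits$chain_id, sep = "_")
  hit_idx <- which(key %in% names(alias))
  for (i in hit_idx) {
    new <- alias[[key[i]]]
    if (!grepl("^[0-9A-Za-z]{4}_\\S+$", new)) stopf("malformed alias target '%s'", new)
    hits$pdb_id[i] <- toupper(sub("_.*$", "", new))
    hits$chain_id[i] <- sub("^[^_]*_", "", new)
    hits$ligands[[i]] <- empty_ligand_set()
  }
  hits
}

#' Write / read the hits table as TSV
#'
#' Ligand lists are serialised as `;`-separated `ccd:chain` pairs; the
#' round trip through [read_hits_tsv()] is lossless.
#'
#' @param hits hits data frame.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  flat <- hits[, setdiff(names(hits), "ligands")]
  flat$ligands <- vapply(hits$ligands, function(lg) {
    paste(sprintf("%s:%s", lg$ccd_id, lg$chain_id), collapse = ";")
  }, character(1L))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  flat <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(chain_id = "character"))
  lig <- flat$ligands
  lig[is.na(lig)] <- ""
  flat$ligands <- lapply(lig, function(s) {
    if (!nzchar(s)) return(empty_ligand_set())
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(ccd_id = vapply(parts, `[`, "", 1L),
               chain_id = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
  })
  flat
}

#' Write a ligand catalog as TSV
#'
#' @param catalog data frame from [read_ccd()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
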
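#' Assemble a pipeline run configuration
#'
#' Collects every input path and numeric threshold of the analysis in
#' one validated object. All thresholds default to the package's
#' standard settings: hit probability 50%, Tanimoto 0.3, pLDDT 90,
#' sequence-identity gate 0.30, contact 5.0 A, clash 2.0 A, rejection
#' 2.0 A over at most 5 cycles, homolog RMSD exclusion 10 A.
#'
#' @param model path to the query model (PDB/mmCIF, pLDDT in B-factors).
#' @param ccd path to the component dictionary.
#' @param hit_table path to the profile-HMM hit table.
#' @param structures named character vector/list of homolog structure
#'   paths keyed by PDB id.
#' @param query_components component ids screened against the catalog.
#' @param alias optional hit alias map (see [apply_hit_aliases()]).
#' @param variant_models optional named vector of variant-model paths
#'   keyed by variant label.
#' @param variant_table optional path to a variant table TSV.
#' @param min_probability,tanimoto_threshold,min_plddt,identity_gate
#'   stage thresholds (see description).
#' @param contact_cutoff,clash_cutoff,reject_cutoff,max_cycles
#'   geometric thresholds (see description).
#' @param rmsd_exclusion homologs whose all-pair superposition RMSD
#'   exceeds this are excluded from site transfer (the all-pair value is
#'   the robust indicator of overall fit for divergent folds, where
#'   outlier rejection would make the retained-pair RMSD look benign).
#' @param cofactor_ids component ids transferred and reported as
#'   cofactors regardless of similarity screening (default MG).
#' @param seed seed for all randomness in a run.
#' @return a `run_config` list.
#' @export
run_config <- function(model, ccd, hit_table, structures,
                       query_components = c("5TR", "PHB"),
                       alias = NULL, variant_models = NULL,
                       variant_table = NULL,
                       min_probability = 50, tanimoto_threshold = 0.3,
                       min_plddt = 90, identity_gate = 0.30,
                       contact_cutoff = 5.0, clash_cutoff = 2.0,
                       reject_cutoff = 2.0, max_cycles = 5L,
                       rmsd_exclusion = 10, cofactor_ids = "MG",
                       seed = 1L) {
  cfg <- list(model = model, ccd = ccd, hit_table = hit_table,
              structures = as.list(structures),
              query_components = query_components,
              alias = as.list(alias %||% list()),
              variant_models = as.list(variant_models %||% list()),
              variant_table = variant_table,
              min_probability = min_probability,
              tanimoto_threshold = tanimoto_threshold,
              min_plddt = min_plddt, identity_gate = identity_gate,
              contact_cutoff = contact_cutoff, clash_cutoff = clash_cutoff,
              reject_cutoff = reject_cutoff, max_cycles = as.integer(max_cycles),
              rmsd_exclusion = rmsd_exclusion, cofactor_ids = cofactor_ids,
              seed = as.integer(seed))
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' @noRd
validate_run_config <- function(cfg) {
  in_range <- function(x, lo, hi) is.numeric(x) && length(x) == 1L && x >= lo && x <= hi
  if (!in_range(cfg$min_probability, 0, 100)) stopf("min_probability outside [0, 100]")
  if (!in_range(cfg$tanimoto_threshold, 0, 1)) stopf("tanimoto_threshold outside [0, 1]")
  if (!in_range(cfg$min_plddt, 0, 100)) stopf("min_plddt outside [0, 100]")
  if (!in_range(cfg$identity_gate, 0, 1)) stopf("identity_gate outside [0, 1]")
  for (k in c("contact_cutoff", "clash_cutoff", "reject_cutoff", "rmsd_exclusion"))
    if (!(is.numeric(cfg[[k]]) && cfg[[k]] > 0)) stopf("%s must be positive", k)
  if (cfg$max_cycles < 1L) stopf("max_cycles must be >= 1")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' The round trip `read_run_config(write_run_config(cfg, path))`
#' restores an identical configuration.
#'
#' @param cfg a `run_config`.
#' @param path YAML file.
#' @return `path` / the `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(
    cfg[c("model", "ccd", "hit_table", "structures", "query_components")],
    list(alias = unlist(cfg$alias), variant_models = cfg$variant_models,
         variant_table = cfg$variant_table),
    cfg[c("min_probability", "tanimoto_threshold", "min_plddt",
          "identity_gate", "contact_cutoff", "clash_cutoff",
          "reject_cutoff", "max_cycles", "rmsd_exclusion",
          "cofactor_ids", "seed")]))
}

#' Run the full site-transfer analysis
#'
#' Executes every stage in order - hit selection, ligand similarity
#' screening, confidence trimming, homolog superposition, ligand
#' transfer with contact/clash annotation, and (when variant models are
#' configured) variant comparison - writing one output file per stage
#' plus a manifest and a timing log into `out_dir`. Any stage failure
#' aborts with the stage name; outputs written so far are retained next
#' to a `FAILED` marker naming the stage.
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly. Side effects: `hits.tsv`,
#'   `similarity.tsv`, `trimmed_model.pdb`, `superposition.json`,
#'   `site_report.tsv`, `model_with_ligands.pdb`,
#'   `variant_ranking.tsv` (optional), `manifest.json`, `run.log`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("sitegraft %s pipeline run, seed %d\n",
              as.character(utils::packageVersion("sitegraft")), cfg$seed),
      file = log_path)
  timings <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    on.exit({
      dt <- proc.time()[["elapsed"]] - t0
      timings[[name]] <<- dt
      cat(sprintf("[%s] %-14s %6.2f s\n", format(Sys.time(), "%H:%M:%S"),
                  name, dt), file = log_path, append = TRUE)
    })
    tryCatch(code, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # -- stage 1: hits --------------------------------------------------
  env <- new.env()
  stage("hits", {
    env$catalog <- read_ccd(cfg$ccd)
    hits <- read_hhr(cfg$hit_table)
    hits <- apply_hit_aliases(hits, cfg$alias %||% character(0))
    env$structures <- lapply(cfg$structures, read_structure)
    have <- hits$pdb_id %in% names(env$structures)
    if (any(!have))
      message(sprintf("dropping %d hit(s) without a supplied structure: %s",
                      sum(!have), paste(unique(hits$pdb_id[!have]), collapse = ", ")))
    hits <- attach_ligands(hits[have, , drop = FALSE], env$structures)
    env$hits <- select_hits(hits, cfg$min_probability)
    write_hits_tsv(env$hits, file.path(out_dir, "hits.tsv"))
    if (nrow(env$hits) == 0L) stop("no hits retained")
  })

  # -- stage 2: ligand similarity ------------------------------------
  stage("similarity", {
    sims <- lapply(cfg$query_components, function(q) {
      s <- screen_ligands(env$catalog, q, threshold = cfg$tanimoto_threshold)
      s$query <- q
      s
    })
    env$similarity <- do.call(rbind, sims)
    utils::write.table(env$similarity, file.path(out_dir, "similarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # -- stage 3: model trimming ---------------------------------------
  stage("trim", {
    model <- read_structure(cfg$model)
    env$model <- trim_by_confidence(model, cfg$min_plddt)
    write_structure(env$model, file.path(out_dir, "trimmed_model.pdb"))
  })

  # -- stage 4: superposition ----------------------------------------
  stage("superpose", {
    sups <- lapply(seq_len(nrow(env$hits)), function(i) {
      h <- env$hits[i, ]
      s <- tryCatch(
        superpose(env$model, env$structures[[h$pdb_id]],
                  chain_target = h$chain_id,
                  identity_gate = cfg$identity_gate,
                  reject_cutoff = cfg$reject_cutoff,
                  max_cycles = cfg$max_cycles),
        error = function(e) {
          message(sprintf("superposition of %s_%s failed: %s",
                          h$pdb_id, h$chain_id, conditionMessage(e)))
          NULL
        })
      list(pdb_id = h$pdb_id, chain_id = h$chain_id, sup = s)
    })
    rms <- vapply(sups, function(s)
      if (is.null(s$sup)) Inf else s$sup$rmsd, numeric(1L))
    sups <- sups[order(rms)]
    env$superpositions <- sups
    rec <- lapply(sups, function(s) {
      if (is.null(s$sup))
        return(list(pdb_id = s$pdb_id, chain_id = s$chain_id,
                    failed = TRUE, excluded = TRUE))
      list(
        pdb_id = s$pdb_id, chain_id = s$chain_id, mode = s$sup$mode,
        rmsd = s$sup$rmsd, rmsd_all = s$sup$rmsd_all,
        n_pairs_retained = s$sup$n_pairs_retained,
        n_pairs_initial = s$sup$n_pairs_initial, n_cycles = s$sup$n_cycles,
        identity_fraction = s$sup$identity_fraction,
        excluded = s$sup$rmsd_all > cfg$rmsd_exclusion)
    })
    jsonlite::write_json(rec, file.path(out_dir, "superposition.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  # -- stage 5: site transfer ----------------------------------------
  stage("map_sites", {
    passing <- unique(env$similarity$ccd_id[env$similarity$passed])
    reports <- list()
    combined <- env$model
    for (s in env$superpositions) {
      if (is.null(s$sup) || s$sup$rmsd_all > cfg$rmsd_exclusion) next
      h <- env$hits[env$hits$pdb_id == s$pdb_id &
                    env$hits$chain_id == s$chain_id, ][1L, ]
      own <- h$ligands[[1L]]
      own <- own$ccd_id[own$chain_id == h$chain_id]
      wanted <- intersect(own, union(passing, cfg$cofactor_ids))
      if (length(wanted) == 0L) next
      lig <- transfer_ligands(s$sup, env$structures[[s$pdb_id]],
                              ligand_ids = wanted)
      lig <- lig[lig$chain == h$chain_id, , drop = FALSE]
      if (nrow(lig) == 0L) next
      contacts <- find_contact_residues(env$model, lig, cfg$contact_cutoff)
      clashes <- detect_clashes(env$model, lig, cfg$clash_cutoff)
      rep_i <- annotate_report(contacts, clashes = clashes)
      if (nrow(rep_i) > 0L) {
        rep_i$source <- paste(s$pdb_id, s$chain_id, sep = "_")
        rep_i$category <- ifelse(
          sub("_.*$", "", rep_i$ligand) %in% cfg$cofactor_ids,
          "cofactor", "ligand")
        reports[[length(reports) + 1L]] <- rep_i
      }
      combined <- combine_model_ligands(combined, lig)
    }
    env$report <- if (length(reports) > 0L) do.call(rbind, reports) else
      data.frame()
    utils::write.table(env$report, file.path(out_dir, "site_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_structure(combined, file.path(out_dir, "model_with_ligands.pdb"))
  })

  # -- stage 6: variants (optional) ----------------------------------
  if (length(cfg$variant_models) > 0L) {
    stage("variants", {
      rows <- lapply(names(cfg$variant_models), function(v) {
        vm <- read_structure(cfg$variant_models[[v]])
        cmp <- compare_models(env$model, vm)
        data.frame(variant = v, rmsd = cmp$rmsd,
                   rmsd_rejected = cmp$rmsd_rejected,
                   n_flagged_regions = nrow(cmp$flagged),
                   stringsAsFactors = FALSE)
      })
      ranking <- rank_variants(do.call(rbind, rows))
      utils::write.table(ranking, file.path(out_dir, "variant_ranking.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  # -- manifest -------------------------------------------------------
  inputs <- c(cfg$model, cfg$ccd, cfg$hit_table,
              unlist(cfg$structures), unlist(cfg$variant_models))
  manifest <- list(
    package = "sitegraft",
    version = as.character(utils::packageVersion("sitegraft")),
    seed = cfg$seed,
    config = unclass(cfg),
    input_md5 = as.list(tools::md5sum(inputs)),
    timings_s = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
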
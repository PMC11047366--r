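#!/usr/bin/env Rscript
# Stage 2: hit selection and substrate-similarity screening.
#
# Parses the packaged component dictionary and profile-HMM hit table,
# attaches observed ligands from the stage-1 structures (resolving the
# apo top hit through the alias map), applies the >50% probability and
# own-chain-ligand rules, and screens every dictionary component against
# the two query substrates (5TR, the tail-substrate stand-in, and PHB,
# the aromatic head).

suppressMessages(library(sitegraft))
fixdir <- "scratch/fixtures"
if (!dir.exists(fixdir)) stop("run analysis/01_simulate_fixtures.R first")

hits <- read_hhr(coq2_hhr_path())
cat(sprintf("hit table: %d hits, top hit %s_%s at %.1f%%\n",
            nrow(hits), hits$pdb_id[1], hits$chain_id[1], hits$probability[1]))

hits <- apply_hit_aliases(hits, c("4OD4_A" = "4OD5_A"))
ids <- c("4OD5", "4TQ3", "6M31", "8DJM", "7Q21", "7E1V")
structures <- lapply(stats::setNames(file.path(fixdir, paste0(ids, ".pdb")), ids),
                     read_structure)
hits <- attach_ligands(hits[hits$pdb_id %in% ids, ], structures)
selected <- select_hits(hits, 50)
write_hits_tsv(selected, "results/hits.tsv")
cat(sprintf("selected %d ligand-bearing hits above 50%%: %s\n",
            nrow(selected),
            paste(selected$pdb_id, selected$chain_id, sep = "_", collapse = " ")))

catalog <- suppressWarnings(read_ccd(coq2_ccd_path()))
sims <- do.call(rbind, lapply(c("5TR", "PHB"), function(q) {
  s <- suppressWarnings(screen_ligands(catalog, q, threshold = 0.3))
  s$query <- q
  s
}))
write.table(sims, "results/similarity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

s5 <- sims[sims$query == "5TR" & !(sims$ccd_id %in% c("5TR", "HOH")), ]
cat(sprintf("most similar to 5TR: %s (%.2f), then %s (%.2f); %d components above 0.3\n",
            s5$ccd_id[1], s5$tanimoto[1], s5$ccd_id[2], s5$tanimoto[2],
            sum(s5$passed)))
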
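#!/usr/bin/env Rscript
# Stage 1: generate the synthetic case-study inputs.
#
# Writes, under one seed, everything the later stages consume: a query
# helical-bundle model with a confidence profile, five ligand-bound
# homologs with graded noise (so their superposition RMSDs have a known
# order), an apo twin of the best homolog, a wrong-chain decoy, a
# distorted entry, displaced-loop variant models, and the ground truth
# for all of it. Structures go to scratch/ (they are regenerable);
# a summary of the planted truth goes to results/.

suppressMessages(library(sitegraft))
seed <- 11L
fixdir <- "scratch/fixtures"

truth <- write_fixture_set(fixdir, seed = seed)

hom <- do.call(rbind, lapply(names(truth$homologs), function(id) {
  h <- truth$homologs[[id]]
  data.frame(entry = id, chain = h$chain, identity = h$identity,
             sigma = h$sigma, pocket = paste(h$pocket, collapse = ","),
             ligands = paste(h$ligand_ids, collapse = ","),
             distorted = h$distorted)
}))
dir.create("results", showWarnings = FALSE)
write.table(hom, "results/fixture_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("fixture set written to %s (seed %d)\n", fixdir, seed))
cat(sprintf("query: %d residues, confident core %d-%d\n",
            truth$query$n_residues, truth$query$trim_start,
            truth$query$trim_end))
print(hom, row.names = FALSE)
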
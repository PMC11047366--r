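#!/usr/bin/env Rscript
# Stage 3: confidence-based trimming of the predicted model.
#
# Applies terminal pLDDT trimming (threshold 90) to the reconstructed
# COQ2-like scaffold (371 residues, confidence profile rebuilt from the
# published per-region description) and to the synthetic query model,
# reporting the retained segments.

suppressMessages(library(sitegraft))

scaffold <- coq2_scaffold_model()
rt <- residue_table(trim_by_confidence(scaffold, 90))
cat(sprintf("scaffold model: retained segment %d-%d (%d of 371 residues)\n",
            min(rt$resno), max(rt$resno), nrow(rt)))

query <- read_structure("scratch/fixtures/query_model.pdb")
qrt <- residue_table(trim_by_confidence(query, 90))
cat(sprintf("synthetic query: retained segment %d-%d\n",
            min(qrt$resno), max(qrt$resno)))

jsonlite::write_json(
  list(scaffold = list(start = min(rt$resno), end = max(rt$resno)),
       synthetic_query = list(start = min(qrt$resno), end = max(qrt$resno))),
  "results/trim_intervals.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
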
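#!/usr/bin/env Rscript
# Stage 4: single-trajectory MM-GBSA decomposition of the synthetic
# protein-ligand trajectory with toy force-field parameters.
#
# Outputs: results/mmgbsa_per_frame.tsv, results/mmgbsa_summary.tsv

suppressMessages(library(ppiscreen))
dir.create("results", showWarnings = FALSE)

cs <- make_contact_system(seed = 20220406)
e_sb <- cs$entries$salt_bridge; e_sb$p <- 1; e_sb$mode <- "deterministic"
tr <- make_trajectory(cs$topology, contact_schedule(list(e_sb), 50))
params <- assign_toy_forcefield(cs$topology, seed = 20220406)

dec <- binding_energy(tr, params, stride = 5L)
write.table(dec$per_frame, "results/mmgbsa_per_frame.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(dec$summary, "results/mmgbsa_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("MM-GBSA over %d frames (every 5th of 50):\n", dec$n_frames_used))
print(dec)
cat("Bookkeeping: dG_gas = dE_bond + dE_vdW + dE_elec and\n")
cat("dG_solv = dG_GB + dG_SA hold per frame by construction;\n")
cat("the entropy term is omitted under the single-trajectory approximation.\n")
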
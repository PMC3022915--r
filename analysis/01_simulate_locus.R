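#!/usr/bin/env Rscript
# Simulate the study locus: six NILT-like receptor genes on both strands
# (two Group-1 and three Group-2 one-Ig genes, one two-Ig gene) with the
# published exon/intron lengths, then disable two copies the way the real
# locus is disabled (an Ig1 internal stop; a missing connecting-peptide
# exon) to obtain the two pseudogenes. Writes FASTA + GFF3 + truth JSON
# under results/synthetic/.

library(niltr)

seed <- 2010L
out <- "results/synthetic"

cfg <- locus_config()
truth <- simulate_locus(cfg, seed = seed)
truth <- pseudogenize(truth, "sNILT5", "internal_stop", seed = seed)
truth <- pseudogenize(truth, "sNILT6", "delete_role_exon", seed = seed,
                      role = "CP")
paths <- write_truth(truth, out)

cat("Simulated locus:", nchar(truth$locus_seq), "nt,",
    length(truth$genes), "genes (seed", seed, ")\n")
cat("Pseudogenised: sNILT5 (internal stop at locus position",
    truth$genes$sNILT5$stop_position, "), sNILT6 (CP exon removed)\n")
cat("Files:\n"); print(unname(paths))
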
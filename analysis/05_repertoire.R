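#!/usr/bin/env Rscript
# Single-individual repertoire survey over a simulated clone library:
# 10 independent PCRs x 10 sequenced clones drawn from the locus Ig
# amplicons plus two "novel" alleles absent from the locus, with
# realistic per-base PCR/sequencing error. Applies the positivity
# screen, the observed-more-than-once retention rule, the amino-acid
# singleton tally and known/novel assignment.
# Expects results/synthetic/ from 01_simulate_locus.R.

library(niltr)

sim <- "results/synthetic/synthetic_locus"
out <- "results/repertoire"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2010L

locus <- read_fasta(paste0(sim, ".fasta"), alphabet = "nt")[[1L]]
models <- build_gene_models(read_gff3(paste0(sim, ".gff3")))
intact <- pseudogene_report(models, locus)
ok <- intact$gene_id[!intact$pseudogene]

amp <- vapply(models[ok], function(m) {
  k <- match("Ig1", m$exons$role)
  cds <- extract_cds(m, locus)
  cum <- c(0L, cumsum(m$exons$coding_length))
  substr(cds, cum[k] + 1L, cum[k + 1L])
}, character(1L))
igs <- vapply(models[ok], function(m) {
  a <- translate_and_partition(m, locus)
  substr(a$protein, a$regions$Ig1[1], a$regions$Ig1[2])
}, character(1L))

# two alleles not present in the locus: point-mutated copies standing in
# for genes the locus does not carry. Mutations avoid the diagnostic
# codons (canonical/extra cysteines, residues 20 and 66, motif 32-35 of
# the Ig frame) so the novels stay classifiable members of their group.
set.seed(seed)
diag_nt <- unlist(lapply(c(17L, 20L, 27L, 31L, 32:35, 66L, 89L),
                         function(p) (3L * p - 3L):(3L * p - 1L)))
mutate_nt <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(setdiff(seq_along(v), diag_nt), k)
  v[pos] <- vapply(v[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  paste(v, collapse = "")
}
templates <- c(amp, novelA = mutate_nt(amp[["sNILT1"]], 12L),
               novelB = mutate_nt(amp[["sNILT4"]], 15L))

lib <- simulate_clone_library(templates, n_pcr = 10L, clones_per_pcr = 10L,
                              error_rate = 5e-4, seed = seed)
clones_fa <- file.path(out, "clones.fasta")
write_fasta(stats::setNames(lib$clones$seq,
                            paste0(lib$clones$id, " rep=",
                                   lib$clones$replicate)), clones_fa)

res <- run_repertoire(clones_fa, igs, amp, out)

cat("Clone survey:", nrow(lib$clones), "clones from 10 PCRs\n")
cat("Positive for the family:", res$summary$n_positive, "\n")
cat("Distinct sequences observed more than once:",
    res$summary$n_retained_nt, "(", res$summary$n_retained_aa,
    "at the amino-acid level )\n")
cat("Amino-acid singletons:", res$summary$singletons_aa, "\n")
cat("Assignments:\n")
print(table(res$assignments$assignment))
cat("Novel-group calls:",
    paste(res$assignments$group[res$assignments$assignment == "novel"],
          collapse = ", "), "\n")
cat("Outputs written to", out, "\n")
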
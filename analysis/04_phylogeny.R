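#!/usr/bin/env Rscript
# Neighbour-joining tree of the Ig domains with bootstrap supports,
# rooted on the divergent second Ig domain of the two-Ig gene.
# Expects results/synthetic/ from 01_simulate_locus.R.

library(niltr)

sim <- "results/synthetic/synthetic_locus"
out <- "results/phylogeny"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2010L

locus <- read_fasta(paste0(sim, ".fasta"), alphabet = "nt")[[1L]]
models <- build_gene_models(read_gff3(paste0(sim, ".gff3")))
intact <- pseudogene_report(models, locus)
anns <- lapply(models[intact$gene_id[!intact$pseudogene]],
               annotate_receptor, locus_seq = locus)
igs <- unlist(unname(lapply(anns, function(a) {
  s <- c()
  for (r in intersect(c("Ig1", "Ig2"), names(a$regions)))
    s[paste0(a$gene_id, "_", r)] <- substr(a$protein, a$regions[[r]][1],
                                           a$regions[[r]][2])
  s
})))

msa <- progressive_msa(igs, alphabet = "aa")
tree <- bootstrap_support(msa, n_reps = 1000L, seed = seed)
write_newick(tree, file.path(out, "ig_nj_unrooted.nwk"))

outgroup <- grep("_Ig2$", tree$tip.label, value = TRUE)[1L]
if (!is.na(outgroup)) {
  rooted <- root_with_outgroup(tree, outgroup)
  write_newick(rooted, file.path(out, "ig_nj_rooted.nwk"))
  cat("Rooted on outgroup:", outgroup, "\n")
}

cat("NJ tree of", length(igs), "Ig domains, 1000 bootstrap replicates\n")
cat("Newick:", ape::write.tree(tree), "\n")
sup <- attr(tree, "bootstrap")
cat("Bootstrap supports:", paste(sprintf("%.0f", sup), collapse = ", "),
    "\n")
cat("Outputs written to", out, "\n")
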
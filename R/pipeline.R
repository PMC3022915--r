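# End-to-end orchestration: annotate a locus (structure, pseudogenes,
# receptor features, identity matrix, entropy, tree) and run the clone
# repertoire survey, writing a report bundle of TSV/FASTA/Newick files.

#' Annotate a locus end to end
#'
#' Reads a locus FASTA and exon-level GFF3, assembles gene models,
#' writes: `structure_table.tsv` (exon/intron lengths, ORF, intron
#' phases, ITIM counts), `pseudogene_report.tsv`, `annotations.tsv`
#' (receptor features of the intact genes), `ig_identity_matrix.tsv`,
#' `msa.fasta` and `entropy.tsv` (full-protein alignment + per-column
#' variability), and `tree.nwk` (NJ tree of the Ig domains with
#' bootstrap supports) when at least 3 intact genes with Ig domains are
#' present.
#'
#' @param locus_fasta path to the locus FASTA (first record used)
#' @param gff3 path to the exon annotation GFF3
#' @param out_dir output directory
#' @param entropy_threshold variability threshold in bits
#' @param bootstrap_reps bootstrap replicates for the tree (0 = plain NJ)
#' @param seed RNG seed for the bootstrap
#' @param tm_aa_len transmembrane helix length in aa
#' @return invisible list with the computed objects (`models`,
#'   `structure`, `pseudogenes`, `annotations`, `identity`, `msa`,
#'   `entropy`, `tree`) and `files`
#' @export
run_annotate <- function(locus_fasta, gff3, out_dir,
                         entropy_threshold = 1.3, bootstrap_reps = 100L,
                         seed = 1L, tm_aa_len = 23L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  locus <- read_fasta(locus_fasta, alphabet = "nt")[[1L]]
  features <- read_gff3(gff3)
  models <- build_gene_models(features)

  pseudo <- pseudogene_report(models, locus)
  struct <- structure_table(models)
  struct$intron_phases <- vapply(models[struct$gene_id], function(m)
    paste(intron_phases(m), collapse = ","), character(1L))

  intact <- pseudo$gene_id[!pseudo$pseudogene]
  anns <- lapply(models[intact], annotate_receptor, locus_seq = locus,
                 tm_aa_len = tm_aa_len)
  ann_tab <- if (length(anns)) annotation_table(anns) else NULL
  struct$itim_count <- NA_integer_
  if (!is.null(ann_tab))
    struct$itim_count[match(ann_tab$gene_id, struct$gene_id)] <-
      ann_tab$itim_count

  files <- c(structure = file.path(out_dir, "structure_table.tsv"),
             pseudogenes = file.path(out_dir, "pseudogene_report.tsv"))
  write_structure_table(struct, files[["structure"]])
  utils::write.table(pseudo, files[["pseudogenes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  identity <- msa <- entro <- tree <- NULL
  if (length(anns)) {
    files[["annotations"]] <- file.path(out_dir, "annotations.tsv")
    utils::write.table(ann_tab, files[["annotations"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    igs <- unlist(unname(lapply(anns, function(a) {
      out <- c()
      for (r in intersect(c("Ig1", "Ig2"), names(a$regions)))
        out[paste0(a$gene_id, "_", r)] <- region_seq(a, r)
      out
    })))
    if (length(igs) >= 2L) {
      identity <- identity_similarity_matrix(igs)
      files[["identity"]] <- file.path(out_dir, "ig_identity_matrix.tsv")
      utils::write.table(round(identity, 1), files[["identity"]],
                         sep = "\t", quote = FALSE, col.names = NA)
    }
    prots <- vapply(anns, `[[`, character(1L), "protein")
    names(prots) <- vapply(anns, `[[`, character(1L), "gene_id")
    if (length(prots) >= 2L) {
      msa <- progressive_msa(prots, alphabet = "aa")
      files[["msa"]] <- file.path(out_dir, "msa.fasta")
      write_msa(msa, files[["msa"]])
      entro <- entropy_profile(msa, threshold = entropy_threshold)
      files[["entropy"]] <- file.path(out_dir, "entropy.tsv")
      write_entropy_profile(entro, files[["entropy"]])
    }
    if (length(igs) >= 3L) {
      ig_msa <- progressive_msa(igs, alphabet = "aa")
      tree <- if (bootstrap_reps > 0L)
        bootstrap_support(ig_msa, n_reps = bootstrap_reps, seed = seed)
      else neighbor_joining(distance_matrix(ig_msa))
      files[["tree"]] <- file.path(out_dir, "tree.nwk")
      write_newick(tree, files[["tree"]])
    }
  }
  invisible(list(models = models, structure = struct, pseudogenes = pseudo,
                 annotations = anns, identity = identity, msa = msa,
                 entropy = entro, tree = tree, files = files))
}

#' Run the clone repertoire survey
#'
#' Screens clones against known Ig domains, applies the
#' observed-more-than-once retention rule, tallies amino-acid
#' singletons, and assigns retained sequences to known genes or calls
#' them novel. Writes `screen.tsv`, `repertoire_summary.tsv` and
#' `assignments.tsv`.
#'
#' @param clones_fasta clone FASTA (replicate ids in headers, see
#'   [read_clones()])
#' @param known_ig_aa named character vector of known Ig-domain proteins
#'   (for the positivity screen)
#' @param known_amplicons named character vector of known-gene amplicon
#'   nucleotide sequences (for exact assignment)
#' @param out_dir output directory
#' @param min_identity positivity threshold (percent identity)
#' @return invisible list with `positive`, `summary`, `assignments`,
#'   `files`
#' @export
run_repertoire <- function(clones_fasta, known_ig_aa, known_amplicons,
                           out_dir, min_identity = 70) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  clones <- read_clones(clones_fasta)
  positive <- screen_positive(clones, known_ig_aa,
                              min_identity = min_identity)
  summ <- summarize_clones(positive)
  assign <- match_known(summ$retained, known_amplicons)
  files <- c(screen = file.path(out_dir, "screen.tsv"),
             summary = file.path(out_dir, "repertoire_summary.tsv"),
             assignments = file.path(out_dir, "assignments.tsv"))
  utils::write.table(positive, files[["screen"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary_tab <- data.frame(
    n_clones = nrow(clones), n_positive = summ$n_positive,
    n_retained_nt = summ$n_retained_nt, n_retained_aa = summ$n_retained_aa,
    singletons_aa = summ$singletons_aa)
  utils::write.table(summary_tab, files[["summary"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(assign, files[["assignments"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(positive = positive, summary = summ,
                 assignments = assign, files = files))
}

#' Write the full report bundle for a set of models and annotations
#'
#' Thin convenience used by the analysis drivers: structure table TSV,
#' exon GFF3 (round-trips through [read_gff3()]) and, when a tree is
#' given, Newick.
#'
#' @param models list of `nilt_gene_model`
#' @param features exon data.frame
#' @param out_dir output directory
#' @param tree optional `phylo`
#' @return invisible named vector of paths
#' @export
write_reports <- function(models, features, out_dir, tree = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(structure = file.path(out_dir, "structure_table.tsv"),
             gff3 = file.path(out_dir, "features.gff3"))
  write_structure_table(structure_table(models), paths[["structure"]])
  write_gff3(features, paths[["gff3"]])
  if (!is.null(tree)) {
    paths[["tree"]] <- file.path(out_dir, "tree.nwk")
    write_newick(tree, paths[["tree"]])
  }
  invisible(paths)
}
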
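# Shared fixtures: small loci, toy feature tables, random configs.

# A compact simulated locus: default templates but short introns and
# spacers so per-test generation stays cheap.
small_config <- function(n_genes = 3L,
                         groups = c("1", "2", "2"),
                         strands = c("+", "-", "+"),
                         n_itims = c(5L, 4L, 4L),
                         two_ig_at = integer(0),
                         spacer_len = 300L) {
  genes <- list()
  for (i in seq_len(n_genes)) {
    genes[[paste0("g", i)]] <- if (i %in% two_ig_at)
      nilt_gene_template("two_ig", strand = strands[i],
                         n_itims = n_itims[i],
                         intron_lengths = c(90L, 70L, 120L, 80L, 60L, 50L))
    else
      nilt_gene_template("one_ig", group = groups[i], strand = strands[i],
                         n_itims = n_itims[i],
                         intron_lengths = c(90L, 70L, 80L, 60L, 50L))
  }
  list(genes = genes, spacer_len = spacer_len)
}

# Random template configuration for property-style sweeps.
random_config <- function() {
  n <- sample(2:4, 1L)
  genes <- list()
  for (i in seq_len(n)) {
    type <- if (stats::runif(1) < 0.25) "two_ig" else "one_ig"
    ni <- sample(3:5, 1L)
    genes[[paste0("g", i)]] <- if (type == "two_ig")
      nilt_gene_template("two_ig", strand = sample(c("+", "-"), 1L),
                         n_itims = ni,
                         intron_lengths = sample(50:400, 6L, replace = TRUE))
    else
      nilt_gene_template("one_ig", group = sample(c("1", "2"), 1L),
                         strand = sample(c("+", "-"), 1L), n_itims = ni,
                         st_fraction = stats::runif(1, 0.3, 0.6),
                         ig_divergence = stats::runif(1, 0.05, 0.25),
                         intron_lengths = sample(50:400, 5L, replace = TRUE))
  }
  list(genes = genes, spacer_len = sample(150:500, 1L))
}

# Toy exon feature table: one gene with the given roles in transcription
# order, laid out from `offset`. On the minus strand the first
# transcribed exon sits at the highest coordinates.
toy_features <- function(gene_id = "g1", roles, exon_lengths,
                         intron_lengths, strand = "+", offset = 0L,
                         seqid = "chrT") {
  cum_start <- integer(length(roles))
  pos <- 0L
  for (k in seq_along(roles)) {
    cum_start[k] <- pos
    pos <- pos + exon_lengths[k] +
      if (k < length(roles)) intron_lengths[k] else 0L
  }
  total <- pos
  if (strand == "+") {
    starts <- offset + cum_start
    ends <- starts + exon_lengths
  } else {
    ends <- offset + total - cum_start
    starts <- ends - exon_lengths
  }
  data.frame(seqid = seqid, gene_id = gene_id, role = roles,
             start = starts, end = ends, strand = strand,
             rank = seq_along(roles), stringsAsFactors = FALSE)
}

# Ig-domain amplicons (Ig1 exon nucleotide sequence) of every intact
# gene in a simulated locus.
ig_amplicons <- function(truth) {
  models <- build_gene_models(truth$features)
  out <- character(0)
  for (gid in names(models)) {
    m <- models[[gid]]
    k <- match("Ig1", m$exons$role)
    if (is.na(k)) next
    cds <- extract_cds(m, truth$locus_seq)
    cum <- c(0L, cumsum(m$exons$coding_length))
    out[gid] <- substr(cds, cum[k] + 1L, cum[k + 1L])
  }
  out
}

# Ig1-domain proteins of every intact gene.
ig_proteins <- function(truth) {
  models <- build_gene_models(truth$features)
  out <- character(0)
  for (gid in names(models)) {
    g <- truth$genes[[gid]]
    if (length(g$flags)) next
    a <- translate_and_partition(models[[gid]], truth$locus_seq)
    iv <- a$regions$Ig1
    if (!is.null(iv)) out[gid] <- substr(a$protein, iv[1], iv[2])
  }
  out
}
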
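# Ground-truthed synthetic locus and clone-library generator. Genes are
# built protein-first (regions with planted cysteine motifs, ITIMs,
# Ser/Thr-rich connecting peptides and diagnostic residues), then
# back-translated, split at the template exon boundaries and embedded in
# random spacer sequence with GT-AG introns. Everything the annotation
# modules are expected to recover is recorded as truth.

#' Gene template for the locus simulator
#'
#' The default one-Ig template mirrors the published exon/intron lengths
#' of Ssa-NILT1 (coding exons 46, 348, 168, 96, 50, 324 nt; introns 275,
#' 2056, 1074, 218, 753 nt; CX3C Ig domain; 5 cytoplasmic ITIMs; 29/56
#' Ser+Thr connecting peptide). The two-Ig template mirrors Ssa-NILT3
#' (exons 46, 330, 321, 99, 105, 50, 327; introns 275, 469, 11068, 610,
#' 242, 410; CX6C Ig1, CX7C Ig2).
#'
#' @param type `"one_ig"` or `"two_ig"`
#' @param group diagnostic group to plant in Ig1 ("1" or "2"; two-Ig
#'   templates are non-CX3C and therefore unclassified)
#' @param n_itims ITIMs planted in the Cyt2-encoded part of the
#'   cytoplasmic region
#' @param st_fraction Ser+Thr fraction of the connecting peptide
#' @param ig_divergence per-position substitution rate applied to the
#'   unconstrained positions of the Ig scaffold
#' @param strand strand the gene will occupy
#' @param activating plant an Arg in the TM helix (activating-receptor
#'   hallmark) instead of keeping it uncharged
#' @param exon_lengths,intron_lengths override the template lengths
#'   (exon order LP, Ig1, [Ig2], CP, TM, Cyt1, Cyt2)
#' @param tm_aa_len transmembrane helix length in aa
#' @return list of class `nilt_gene_template`
#' @export
nilt_gene_template <- function(type = c("one_ig", "two_ig"), group = "1",
                               n_itims = NULL, st_fraction = 29 / 56,
                               ig_divergence = 0.15,
                               strand = "+", activating = FALSE,
                               exon_lengths = NULL, intron_lengths = NULL,
                               tm_aa_len = 23L) {
  type <- match.arg(type)
  if (type == "one_ig") {
    roles <- c("LP", "Ig1", "CP", "TM", "Cyt1", "Cyt2")
    ex <- exon_lengths %||% c(46L, 348L, 168L, 96L, 50L, 324L)
    io <- intron_lengths %||% c(275L, 2056L, 1074L, 218L, 753L)
    spacing <- c(Ig1 = "CX3C")
    n_itims <- n_itims %||% 5L
  } else {
    roles <- c("LP", "Ig1", "Ig2", "CP", "TM", "Cyt1", "Cyt2")
    ex <- exon_lengths %||% c(46L, 330L, 321L, 99L, 105L, 50L, 327L)
    io <- intron_lengths %||% c(275L, 469L, 11068L, 610L, 242L, 410L)
    spacing <- c(Ig1 = "CX6C", Ig2 = "CX7C")
    n_itims <- n_itims %||% 5L
    group <- "unclassified"
  }
  stopifnot(length(io) == length(ex) - 1L, all(io >= 4L),
            sum(ex) %% 3L == 0L, strand %in% c("+", "-"))
  structure(list(type = type, roles = roles, exon_lengths = ex,
                 intron_lengths = io, spacing = spacing,
                 group = as.character(group), n_itims = as.integer(n_itims),
                 st_fraction = st_fraction, ig_divergence = ig_divergence,
                 strand = strand, activating = activating,
                 tm_aa_len = as.integer(tm_aa_len)),
            class = "nilt_gene_template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Amino-acid intervals per exon under the split-codon-downstream rule.
#' @keywords internal
template_aa_intervals <- function(ex, plen) {
  cum <- cumsum(ex)
  aa_end <- as.integer(pmin(floor(cum / 3), plen))
  aa_start <- c(0L, aa_end[-length(aa_end)]) + 1L
  cbind(start = aa_start, end = aa_end)
}

# Build one Ig-domain sequence of length L from the reference scaffold.
#' @keywords internal
build_ig_domain <- function(L, spacing, group, divergence) {
  ref <- strsplit(nilt_reference_ig(), "")[[1]]
  s <- if (L <= length(ref)) ref[seq_len(L)]
       else c(ref, sample(AA_NO_C, L - length(ref), replace = TRUE))
  if (L < 94L) stop("Ig exon too short to carry the canonical cysteines")
  # extra cysteine pair: second member fixed at 31, first sets the gap
  s[c(23L, 24L, 27L)] <- sample(setdiff(AA_NO_C, "C"), 3L, replace = TRUE)
  first <- switch(spacing, CX3C = 27L, CX6C = 24L, CX7C = 23L,
                  stop("unknown spacing class ", spacing))
  s[first] <- "C"
  if (identical(group, "2")) {
    s[20L] <- "Q"
    s[32:35] <- c(sample(c("P", "R"), 1L), "V", sample(c("F", "L"), 1L), "N")
    s[66L] <- "I"
  }
  fixed <- c(17L, 20L, first, 31L, 32:35, 66L, 89L)
  free <- setdiff(seq_len(L), fixed)
  mut <- free[stats::runif(length(free)) < divergence]
  if (length(mut))
    s[mut] <- vapply(s[mut], function(a)
      sample(setdiff(AA_NO_C, a), 1L), character(1L))
  paste(s, collapse = "")
}

# Build the full protein of a template; returns protein + expected truth.
#' @keywords internal
build_protein <- function(tpl) {
  ex <- tpl$exon_lengths
  roles <- tpl$roles
  plen <- sum(ex) %/% 3L - 1L
  iv <- template_aa_intervals(ex, plen)
  seg <- character(length(roles))
  for (k in seq_along(roles)) {
    L <- iv[k, "end"] - iv[k, "start"] + 1L
    r <- roles[k]
    if (r == "LP") {
      lp <- sample(AA_BACKGROUND, L, replace = TRUE)
      lp[1L] <- "M"   # initiator
      seg[k] <- paste(lp, collapse = "")
    } else if (r %in% c("Ig1", "Ig2")) {
      seg[k] <- build_ig_domain(L, tpl$spacing[[r]],
                                if (r == "Ig1") tpl$group else "other",
                                tpl$ig_divergence)
    } else if (r == "CP") {
      n_st <- round(tpl$st_fraction * L)
      s <- sample(setdiff(AA_BACKGROUND, c("S", "T")), L, replace = TRUE)
      pos <- sample(seq_len(L), n_st)
      s[pos] <- sample(c("S", "T"), n_st, replace = TRUE)
      seg[k] <- paste(s, collapse = "")
    } else if (r == "TM") {
      tm <- sample(TM_HYDROPHOBIC, L, replace = TRUE)
      if (tpl$activating) tm[sample(seq_len(min(tpl$tm_aa_len, L)), 1L)] <- "R"
      # remainder of the TM exon is cytoplasmic background
      if (L > tpl$tm_aa_len)
        tm[(tpl$tm_aa_len + 1L):L] <-
          sample(AA_BACKGROUND, L - tpl$tm_aa_len, replace = TRUE)
      seg[k] <- paste(tm, collapse = "")
    } else if (r == "Cyt1") {
      seg[k] <- paste(sample(AA_BACKGROUND, L, replace = TRUE), collapse = "")
    } else if (r == "Cyt2") {
      if (tpl$n_itims * 7L > L)
        stop("infeasible template: ", tpl$n_itims,
             " ITIMs do not fit in a ", L, "-residue Cyt2 exon")
      s <- sample(AA_BACKGROUND, L, replace = TRUE)
      block <- L %/% max(tpl$n_itims, 1L)
      if (tpl$n_itims > 0L) for (m in seq_len(tpl$n_itims)) {
        lo <- (m - 1L) * block + 1L
        off <- lo + sample.int(block - 6L, 1L) - 1L
        s[off:(off + 5L)] <- c(sample(c("S", "I", "V", "L"), 1L),
                               sample(AA_BACKGROUND, 1L), "Y",
                               sample(AA_BACKGROUND, 2L),
                               sample(c("I", "V", "L"), 1L))
      }
      seg[k] <- paste(s, collapse = "")
    }
  }
  paste(seg, collapse = "")
}

#' @keywords internal
back_translate <- function(protein) {
  tab <- codon_table()
  aas <- strsplit(protein, "")[[1]]
  codons <- vapply(aas, function(a) {
    cand <- tab[[a]]
    cand[sample.int(length(cand), 1L)]
  }, character(1L), USE.NAMES = FALSE)
  paste0(paste(codons, collapse = ""), "TAA")
}

#' @keywords internal
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Assemble one gene on its coding strand; returns sequence and exon
# coordinates (0-based half-open, coding strand).
#' @keywords internal
assemble_gene <- function(tpl, cds) {
  ex <- tpl$exon_lengths
  cum <- c(0L, cumsum(ex))
  exon_seq <- substring(cds, cum[-length(cum)] + 1L, cum[-1L])
  intron_seq <- vapply(tpl$intron_lengths, function(L)
    paste0("GT", random_dna(L - 4L), "AG"), character(1L))
  parts <- character(0)
  starts <- integer(length(ex))
  pos <- 0L
  for (k in seq_along(ex)) {
    starts[k] <- pos
    parts <- c(parts, exon_seq[k])
    pos <- pos + ex[k]
    if (k < length(ex)) {
      parts <- c(parts, intron_seq[k])
      pos <- pos + tpl$intron_lengths[k]
    }
  }
  list(seq = paste(parts, collapse = ""),
       exon_start = starts, exon_end = starts + ex)
}

#' Default locus configuration
#'
#' Emulates the published BAC locus: six receptor genes on both strands
#' — two Group-1 and three Group-2 one-Ig genes plus one two-Ig gene —
#' separated by random spacers.
#'
#' @param spacer_len spacer length between genes (nt)
#' @return list with `genes` (named list of templates) and `spacer_len`
#' @export
locus_config <- function(spacer_len = 2000L) {
  list(genes = list(
         sNILT1 = nilt_gene_template("one_ig", group = "1", n_itims = 5L,
                                     strand = "+"),
         sNILT2 = nilt_gene_template("one_ig", group = "1", n_itims = 4L,
                                     strand = "-"),
         sNILT3 = nilt_gene_template("two_ig", n_itims = 5L, strand = "+"),
         sNILT4 = nilt_gene_template("one_ig", group = "2", n_itims = 4L,
                                     strand = "-"),
         sNILT5 = nilt_gene_template("one_ig", group = "2", n_itims = 4L,
                                     strand = "+"),
         sNILT6 = nilt_gene_template("one_ig", group = "2", n_itims = 4L,
                                     strand = "+")),
       spacer_len = as.integer(spacer_len))
}

#' Simulate a ground-truthed multi-gene locus
#'
#' Each configured gene is generated protein-first with its planted
#' features, back-translated, interleaved with GT-AG introns and
#' embedded (reverse-complemented on the minus strand) between random
#' spacers. The generator re-scans every planted region with the
#' annotation functions and locally regenerates (up to 100 attempts) if
#' an accidental extra motif appeared, so the recorded truth is exact.
#' Output is deterministic for a fixed seed.
#'
#' @param config list from [locus_config()] (or same shape)
#' @param seed integer RNG seed
#' @return object of class `nilt_truth`: list with `locus_seq`,
#'   `features` (exon data.frame as from [read_gff3()]), `genes` (per-
#'   gene truth: lengths, phases, spacing classes, itim_count, group,
#'   st_count/cp_length, protein, flags), `seed`, `config`
#' @export
simulate_locus <- function(config = locus_config(), seed = 1L) {
  set.seed(as.integer(seed))
  spacer <- config$spacer_len %||% 2000L
  gene_ids <- names(config$genes)
  stopifnot(!is.null(gene_ids), !anyDuplicated(gene_ids))
  locus_parts <- character(0)
  pos <- 0L
  features <- list()
  genes <- list()
  for (gid in gene_ids) {
    tpl <- config$genes[[gid]]
    sp <- random_dna(spacer)
    locus_parts <- c(locus_parts, sp)
    pos <- pos + spacer

    protein <- NULL
    for (attempt in seq_len(100L)) {
      cand <- build_protein(tpl)
      if (verify_protein(cand, tpl)) { protein <- cand; break }
    }
    if (is.null(protein))
      stop("could not generate a self-consistent protein for ", gid,
           " in 100 attempts")
    cds <- back_translate(protein)
    g <- assemble_gene(tpl, cds)
    L <- nchar(g$seq)
    if (tpl$strand == "+") {
      starts <- pos + g$exon_start
      ends <- pos + g$exon_end
      locus_parts <- c(locus_parts, g$seq)
    } else {
      starts <- pos + L - g$exon_end
      ends <- pos + L - g$exon_start
      locus_parts <- c(locus_parts, revcomp(g$seq))
    }
    features[[gid]] <- data.frame(
      seqid = "synthetic_locus", gene_id = gid, role = tpl$roles,
      start = starts, end = ends, strand = tpl$strand,
      rank = seq_along(tpl$roles), stringsAsFactors = FALSE)
    pos <- pos + L

    plen <- nchar(protein)
    iv <- template_aa_intervals(tpl$exon_lengths, plen)
    st <- st_composition(substr(protein, iv[match("CP", tpl$roles), 1],
                                iv[match("CP", tpl$roles), 2]))
    genes[[gid]] <- list(
      gene_id = gid, type = tpl$type, strand = tpl$strand,
      roles = tpl$roles, exon_lengths = tpl$exon_lengths,
      intron_lengths = tpl$intron_lengths,
      orf_length = sum(tpl$exon_lengths),
      phases = intron_phases(tpl$exon_lengths),
      spacing = tpl$spacing, itim_count = tpl$n_itims,
      group = tpl$group, st_count = st$st_count, cp_length = st$length,
      tm_charged = tpl$activating, protein = protein,
      flags = character(0), stop_position = NA_integer_,
      missing_role = NA_character_)
  }
  locus_parts <- c(locus_parts, random_dna(spacer))
  truth <- structure(list(
    locus_seq = paste(locus_parts, collapse = ""),
    features = do.call(rbind, c(features, list(make.row.names = FALSE))),
    genes = genes, seed = as.integer(seed), config = config),
    class = "nilt_truth")
  truth
}

# Re-scan a candidate protein with the annotation functions to confirm
# that exactly the planted features are present.
#' @keywords internal
verify_protein <- function(protein, tpl) {
  plen <- nchar(protein)
  iv <- template_aa_intervals(tpl$exon_lengths, plen)
  roles <- tpl$roles
  get <- function(role) {
    k <- match(role, roles)
    if (is.na(k)) return(NULL)
    substr(protein, iv[k, 1], iv[k, 2])
  }
  for (r in names(tpl$spacing)) {
    prof <- cys_profile(get(r))
    if (!identical(prof$spacing_class, tpl$spacing[[r]])) return(FALSE)
  }
  tm_exon <- get("TM")
  cyt <- paste0(substr(tm_exon, tpl$tm_aa_len + 1L, nchar(tm_exon)),
                get("Cyt1"), get("Cyt2"))
  if (nrow(scan_itims(cyt)) != tpl$n_itims) return(FALSE)
  tm <- substr(tm_exon, 1L, tpl$tm_aa_len)
  if (tm_charge_check(tm) != tpl$activating) return(FALSE)
  if (tpl$group %in% c("1", "2")) {
    if (!identical(classify_group(get("Ig1"))$group, tpl$group))
      return(FALSE)
  }
  TRUE
}

#' @export
print.nilt_truth <- function(x, ...) {
  cat("<nilt_truth> locus of ", nchar(x$locus_seq), " nt, ",
      length(x$genes), " genes (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Apply a pseudogenising lesion to a simulated locus
#'
#' Modes: `"internal_stop"` rewrites an Ig1 codon just downstream of the
#' second canonical cysteine into TAA; `"delete_role_exon"` removes an
#' exon feature (default CP) from the annotation; `"frameshift"` deletes
#' one nucleotide inside the CP exon (coordinates of all downstream
#' features shift accordingly). The gene's truth flags are updated to
#' the lesion.
#'
#' @param truth `nilt_truth` from [simulate_locus()]
#' @param gene_id gene to disable
#' @param mode lesion mode
#' @param seed RNG seed for lesion placement
#' @param role exon role removed by `delete_role_exon`
#' @return modified `nilt_truth`
#' @export
pseudogenize <- function(truth, gene_id,
                         mode = c("internal_stop", "delete_role_exon",
                                  "frameshift"),
                         seed = 1L, role = "CP") {
  mode <- match.arg(mode)
  stopifnot(gene_id %in% names(truth$genes))
  set.seed(as.integer(seed))
  g <- truth$genes[[gene_id]]
  models <- build_gene_models(truth$features)
  model <- models[[gene_id]]

  if (mode == "internal_stop") {
    # codon fully inside the Ig1 exon, after the anchored cysteine pair
    k <- match("Ig1", g$roles)
    cum <- c(0L, cumsum(g$exon_lengths))
    ig_nt <- c(cum[k], cum[k + 1L])
    aa_lo <- as.integer(ceiling((ig_nt[1] + 3L * 95L) / 3L))  # past Cys 89
    codon <- aa_lo
    off <- 3L * (codon - 1L)
    stopifnot(off >= ig_nt[1], off + 3L <= ig_nt[2])
    stop_nt <- c("T", "A", "A")
    loc <- vapply(0:2, function(d) cds_to_locus(model, off + d), integer(1L))
    chars <- strsplit(truth$locus_seq, "")[[1]]
    for (d in 1:3) {
      b <- stop_nt[d]
      if (g$strand == "-") b <- chartr("ACGT", "TGCA", b)
      chars[loc[d] + 1L] <- b
    }
    truth$locus_seq <- paste(chars, collapse = "")
    g$flags <- "internal_stop"
    g$stop_position <- loc[1L] + 1L
  } else if (mode == "delete_role_exon") {
    keep <- !(truth$features$gene_id == gene_id &
                truth$features$role == role)
    if (all(keep)) stop("gene ", gene_id, " has no ", role, " exon")
    truth$features <- truth$features[keep, , drop = FALSE]
    # re-rank remaining exons in transcription order
    sel <- truth$features$gene_id == gene_id
    truth$features$rank[sel] <- seq_len(sum(sel))
    k <- match(role, g$roles)
    g$roles <- g$roles[-k]
    g$exon_lengths <- g$exon_lengths[-k]
    g$orf_length <- sum(g$exon_lengths)
    g$flags <- "missing_role_exon"
    g$missing_role <- role
    if (g$orf_length %% 3L != 0L) g$flags <- c(g$flags, "frameshift")
  } else { # frameshift
    k <- match("CP", g$roles)
    if (is.na(k)) stop("gene ", gene_id, " has no CP exon to frameshift")
    fe <- truth$features
    row <- which(fe$gene_id == gene_id & fe$role == "CP")
    del <- fe$start[row] + sample.int(fe$end[row] - fe$start[row] - 2L, 1L)
    truth$locus_seq <- paste0(substr(truth$locus_seq, 1L, del),
                              substr(truth$locus_seq, del + 2L,
                                     nchar(truth$locus_seq)))
    shrink <- fe$start <= del & fe$end > del
    fe$end[shrink] <- fe$end[shrink] - 1L
    after <- fe$start > del
    fe$start[after] <- fe$start[after] - 1L
    fe$end[after] <- fe$end[after] - 1L
    truth$features <- fe
    g$exon_lengths[k] <- g$exon_lengths[k] - 1L
    g$orf_length <- sum(g$exon_lengths)
    g$flags <- "frameshift"
  }
  truth$genes[[gene_id]] <- g
  truth
}

#' Write the simulated locus, annotation and truth to disk
#'
#' @param truth `nilt_truth`
#' @param dir output directory (created if missing)
#' @param stem file stem
#' @return named character vector of the three paths (fasta, gff3, json)
#' @export
write_truth <- function(truth, dir, stem = "synthetic_locus") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(stem, ".fasta"))
  gff <- file.path(dir, paste0(stem, ".gff3"))
  js <- file.path(dir, paste0(stem, ".truth.json"))
  write_fasta(stats::setNames(truth$locus_seq, "synthetic_locus"), fa)
  write_gff3(truth$features, gff)
  jsonlite::write_json(
    lapply(truth$genes, function(g)
      g[c("gene_id", "type", "strand", "roles", "exon_lengths",
          "intron_lengths", "orf_length", "phases", "itim_count", "group",
          "st_count", "cp_length", "flags")]),
    js, auto_unbox = TRUE, digits = NA)
  c(fasta = fa, gff3 = gff, truth = js)
}

#' Simulate a replicate-PCR clone library
#'
#' Clones are drawn template-by-weight for `n_pcr` x `clones_per_pcr`
#' clones; each base substitutes independently at `error_rate` (the
#' survey compares equal-length amplicons, so the error model is
#' substitution-only). The truth records each clone's template and its
#' planted error count.
#'
#' @param templates named character vector of amplicon nucleotide
#'   sequences
#' @param n_pcr number of independent PCRs
#' @param clones_per_pcr clones sequenced per PCR
#' @param error_rate per-base substitution probability
#' @param seed integer RNG seed
#' @param weights template sampling weights (default uniform)
#' @return list with `clones` (`nilt_clone_set`) and `truth`
#'   (data.frame id, replicate, template, n_errors)
#' @export
simulate_clone_library <- function(templates, n_pcr = 10L,
                                   clones_per_pcr = 10L, error_rate = 5e-4,
                                   seed = 1L, weights = NULL) {
  if (length(templates) == 0L) stop("empty template set")
  stopifnot(!is.null(names(templates)))
  set.seed(as.integer(seed))
  weights <- weights %||% rep(1, length(templates))
  n <- n_pcr * clones_per_pcr
  pick <- sample.int(length(templates), n, replace = TRUE, prob = weights)
  reps <- rep(seq_len(n_pcr), each = clones_per_pcr)
  bases <- c("A", "C", "G", "T")
  seqs <- character(n)
  n_err <- integer(n)
  for (i in seq_len(n)) {
    s <- strsplit(templates[[pick[i]]], "")[[1]]
    hit <- which(stats::runif(length(s)) < error_rate)
    for (p in hit) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
    n_err[i] <- length(hit)
  }
  ids <- sprintf("clone_%03d", seq_len(n))
  list(clones = clone_set(ids, reps, seqs),
       truth = data.frame(id = ids, replicate = reps,
                          template = names(templates)[pick],
                          n_errors = n_err, stringsAsFactors = FALSE))
}
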
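# Coding-sequence assembly, exon/intron structure tables, intron phases,
# and pseudogene detection.

#' Extract the coding sequence of a gene model
#'
#' Exon subsequences are concatenated in transcription order;
#' minus-strand genes are reverse-complemented. The result length is the
#' sum of exon coding lengths.
#'
#' @param model a `nilt_gene_model`
#' @param locus_seq the locus nucleotide string (plus strand)
#' @return nucleotide string (coding strand, 5'->3')
#' @export
extract_cds <- function(model, locus_seq) {
  stopifnot(inherits(model, "nilt_gene_model"))
  if (any(model$exons$end > nchar(locus_seq)) || any(model$exons$start < 0L))
    stop("gene ", model$gene_id, " has exons outside the locus (length ",
         nchar(locus_seq), ")")
  asc <- model$exons[order(model$exons$start), , drop = FALSE]
  cds <- paste(substring(locus_seq, asc$start + 1L, asc$end), collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  cds
}

#' Intron phases of a gene model
#'
#' The phase of intron i is the number of coding nucleotides upstream of
#' it modulo 3: phase 0 falls between codons, phase 1 after the first
#' base of a codon, phase 2 after the second.
#'
#' @param model a `nilt_gene_model`, or a numeric vector of exon coding
#'   lengths in transcription order
#' @return integer vector of phases, one per intron (empty for
#'   single-exon genes)
#' @export
intron_phases <- function(model) {
  lens <- if (inherits(model, "nilt_gene_model")) model$exons$coding_length
          else model
  if (length(lens) < 2L) return(integer(0))
  as.integer(cumsum(lens)[-length(lens)] %% 3L)
}

# Structure-table column for each exon role and for the intron following it.
EXON_COLUMN <- c(LP = "lp_exon1", Ig1 = "ig1_exon2", Ig2 = "ig2_exon2a",
                 CP = "cp_exon3", TM = "tm_exon4", Cyt1 = "cyt1_exon5",
                 Cyt2 = "cyt2_exon6")
INTRON_COLUMN <- c(LP = "intron1", Ig1 = "intron2", Ig2 = "intron2a",
                   CP = "intron3", TM = "intron4", Cyt1 = "intron5")

#' Exon/intron structure table of a gene set
#'
#' One row per gene with exon coding lengths and intron lengths (nt) laid
#' out by role (leader peptide, Ig domain(s), connecting peptide,
#' transmembrane, cytoplasmic exons) and the summed open-reading-frame
#' length. Genes lacking a role (e.g. the second Ig exon) get `NA` in
#' those cells, rendered as "-" on export.
#'
#' @param models list of `nilt_gene_model`
#' @return data.frame with columns gene_id, lp_exon1, intron1, ig1_exon2,
#'   intron2, ig2_exon2a, intron2a, cp_exon3, intron3, tm_exon4, intron4,
#'   cyt1_exon5, intron5, cyt2_exon6, orf_length, n_exons, strand
#' @export
structure_table <- function(models) {
  if (inherits(models, "nilt_gene_model")) models <- list(models)
  cols <- c("gene_id", unlist(rbind(EXON_COLUMN, c(INTRON_COLUMN, ""))))
  cols <- cols[cols != ""]
  rows <- lapply(models, function(m) {
    row <- as.list(rep(NA_integer_, length(cols)))
    names(row) <- cols
    row$gene_id <- m$gene_id
    for (i in seq_len(nrow(m$exons)))
      row[[EXON_COLUMN[[m$exons$role[i]]]]] <- m$exons$coding_length[i]
    for (i in seq_len(nrow(m$introns)))
      row[[INTRON_COLUMN[[m$introns$after_role[i]]]]] <- m$introns$length[i]
    row$orf_length <- sum(m$exons$coding_length)
    row$n_exons <- nrow(m$exons)
    row$strand <- m$strand
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a structure table as TSV
#'
#' Missing cells (roles absent from a gene) are written as "-".
#' @param tab data.frame from [structure_table()]
#' @param path output file
#' @export
write_structure_table <- function(tab, path) {
  out <- tab
  out[] <- lapply(out, function(x) ifelse(is.na(x), "-", as.character(x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a gene model and flag pseudogene lesions
#'
#' Flags raised:
#' \describe{
#'   \item{internal_stop}{an in-frame stop codon before the final codon;
#'     `stop_position` gives the 1-based locus coordinate of its first
#'     base}
#'   \item{missing_role_exon}{the role set omits CP, TM or Cyt2 while a
#'     leader peptide and an Ig exon are present}
#'   \item{frameshift}{summed coding length not divisible by 3}
#'   \item{bad_splice}{an intron that does not begin GT and end AG on the
#'     transcribed strand}
#' }
#' An empty flag set means the model passes; any flag classifies the gene
#' as a putative pseudogene.
#'
#' @param model a `nilt_gene_model`
#' @param locus_seq locus nucleotide string
#' @return list with `gene_id`, `flags` (character vector),
#'   `stop_position`, `missing_role`
#' @export
validate_gene <- function(model, locus_seq) {
  cds <- extract_cds(model, locus_seq)
  flags <- character(0)
  stop_position <- NA_integer_
  missing_role <- NA_character_

  if (nchar(cds) %% 3L == 0L) {
    cods <- codons_of(cds)
    internal <- which(cods[-length(cods)] %in% STOP_CODONS)
    if (length(internal)) {
      flags <- c(flags, "internal_stop")
      stop_position <- cds_to_locus(model, (internal[1L] - 1L) * 3L) + 1L
    }
  } else {
    flags <- c(flags, "frameshift")
    # still scan complete codons so gross lesions are visible
    cods <- codons_of(substr(cds, 1L, 3L * (nchar(cds) %/% 3L)))
    internal <- which(cods[-length(cods)] %in% STOP_CODONS)
    if (length(internal)) {
      flags <- c(flags, "internal_stop")
      stop_position <- cds_to_locus(model, (internal[1L] - 1L) * 3L) + 1L
    }
  }

  roles <- model$exons$role
  if (any(c("LP") %in% roles) && any(c("Ig1", "Ig2") %in% roles)) {
    absent <- setdiff(c("CP", "TM", "Cyt2"), roles)
    if (length(absent)) {
      flags <- c(flags, "missing_role_exon")
      missing_role <- absent[1L]
    }
  }

  if (nrow(model$introns) > 0L) {
    don_acc <- vapply(seq_len(nrow(model$introns)), function(i) {
      s <- model$introns$start[i]; e <- model$introns$end[i]
      intron <- substring(locus_seq, s + 1L, e)
      if (model$strand == "-") intron <- revcomp(intron)
      paste0(substr(intron, 1L, 2L),
             substr(intron, nchar(intron) - 1L, nchar(intron)))
    }, character(1L))
    if (any(don_acc != "GTAG")) flags <- c(flags, "bad_splice")
  }

  list(gene_id = model$gene_id, flags = flags,
       stop_position = stop_position, missing_role = missing_role)
}

# Map a 0-based CDS offset to the 0-based locus coordinate of that base.
#' @keywords internal
cds_to_locus <- function(model, offset) {
  ex <- model$exons          # transcription order
  cum <- cumsum(ex$coding_length)
  i <- which(offset < cum)[1L]
  if (is.na(i)) stop("CDS offset ", offset, " beyond gene ", model$gene_id)
  within <- offset - c(0L, cum)[i]
  if (model$strand == "+") ex$start[i] + within
  else ex$end[i] - within - 1L
}

#' Validate every model in a set
#'
#' @param models list of `nilt_gene_model`
#' @param locus_seq locus nucleotide string
#' @return data.frame, one row per gene: gene_id, pseudogene (logical),
#'   flags (comma-joined), stop_position, missing_role
#' @export
pseudogene_report <- function(models, locus_seq) {
  rows <- lapply(models, function(m) {
    v <- validate_gene(m, locus_seq)
    data.frame(gene_id = v$gene_id,
               pseudogene = length(v$flags) > 0L,
               flags = paste(v$flags, collapse = ","),
               stop_position = v$stop_position,
               missing_role = v$missing_role,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
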
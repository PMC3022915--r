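# Reading and writing the standard formats (FASTA, GFF3) and assembling
# per-gene models from exon-level features.
#
# Coordinate conventions: everything internal is 0-based half-open
# [start, end); GFF3 on disk is 1-based inclusive. The conversion is a
# bijection (start0 = start1 - 1, end0 = end1) so round trips are exact.

EXON_ROLES <- c("LP", "Ig1", "Ig2", "CP", "TM", "Cyt1", "Cyt2")

#' Read a FASTA file
#'
#' @param path file path
#' @param alphabet `"auto"` (default) infers nucleotide vs amino acid from
#'   the residues present; `"nt"`/`"aa"` force it.
#' @return named character vector of uppercased sequences with attribute
#'   `alphabet`; names are the first whitespace-delimited token of each
#'   header.
#' @export
read_fasta <- function(path, alphabet = c("auto", "nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("no records in FASTA file ", path)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  if (anyNA(ids) || any(ids == ""))
    stop("malformed FASTA header (empty id) in ", path)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(seqs) == 0L))
    stop("empty record in ", path, ": ", ids[nchar(seqs) == 0L][1L])
  names(seqs) <- ids
  attr(seqs, "alphabet") <- if (alphabet == "auto") infer_alphabet(seqs)
                            else alphabet
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output file
#' @param width line wrap width
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(names(seqs) != ""))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read exon features from GFF3
#'
#' Expects `exon`-type rows carrying `gene_id` and `role` attributes
#' (roles: LP, Ig1, Ig2, CP, TM, Cyt1, Cyt2). Coordinates are converted
#' from GFF3 1-based inclusive to the internal 0-based half-open
#' convention.
#'
#' @param path GFF3 file
#' @return data.frame with columns seqid, gene_id, role, start, end
#'   (0-based half-open), strand, rank
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 in ", path, ": ",
                                          conditionMessage(e)))
  gr <- gr[as.character(gr$type) == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id) || anyNA(mc$gene_id))
    stop("exon feature missing gene_id attribute in ", path)
  if (is.null(mc$role) || anyNA(mc$role))
    stop("exon feature missing role attribute in ", path)
  role <- as.character(mc$role)
  bad <- setdiff(unique(role), EXON_ROLES)
  if (length(bad))
    stop("unknown role in ", path, ": ", paste(bad, collapse = ", "),
         " (expected ", paste(EXON_ROLES, collapse = "/"), ")")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("exon feature without +/- strand in ", path)
  rank <- if (!is.null(mc$rank)) as.integer(as.character(mc$rank))
          else rep(NA_integer_, length(gr))
  out <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    gene_id = as.character(mc$gene_id),
    role = role,
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    rank = rank,
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end))
    stop("feature with end < start in ", path)
  out
}

#' Write exon features to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' written back as GFF3 1-based inclusive, so write -> read is the
#' identity on features.
#'
#' @param features data.frame as returned by [read_gff3()]
#' @param path output file
#' @export
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand
  )
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "niltr"
  S4Vectors::mcols(gr)$gene_id <- features$gene_id
  S4Vectors::mcols(gr)$role <- features$role
  S4Vectors::mcols(gr)$rank <- as.character(features$rank)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Assemble gene models from exon features
#'
#' Exons are grouped by `gene_id`, ordered in transcription order
#' (ascending coordinates on `+`, descending on `-`), re-ranked 1..k, and
#' the introns derived as the inter-exon gaps. Genes with overlapping
#' exons, exons on both strands, or duplicated roles are rejected.
#'
#' @param features data.frame from [read_gff3()]
#' @return named list of `nilt_gene_model` objects, each a list with
#'   `gene_id`, `seqid`, `strand`, `exons` (transcription order, with
#'   `coding_length`), and `introns` (0-based half-open locus intervals
#'   with `length` and `after_role`, the upstream exon's role)
#' @export
build_gene_models <- function(features) {
  stopifnot(is.data.frame(features))
  models <- lapply(split(features, features$gene_id), function(fe) {
    gid <- fe$gene_id[1L]
    if (length(unique(fe$strand)) != 1L)
      stop("gene ", gid, " has exons on both strands")
    if (length(unique(fe$seqid)) != 1L)
      stop("gene ", gid, " spans multiple sequences")
    if (anyDuplicated(fe$role))
      stop("gene ", gid, " has duplicated exon roles: ",
           paste(unique(fe$role[duplicated(fe$role)]), collapse = ", "))
    strand <- fe$strand[1L]
    fe <- fe[order(fe$start, decreasing = (strand == "-")), , drop = FALSE]
    asc <- fe[order(fe$start), , drop = FALSE]
    if (nrow(asc) > 1L && any(asc$start[-1L] < asc$end[-nrow(asc)]))
      stop("gene ", gid, " has overlapping exons")
    fe$rank <- seq_len(nrow(fe))
    fe$coding_length <- fe$end - fe$start
    rownames(fe) <- NULL
    introns <- if (nrow(fe) > 1L) {
      # gaps between consecutive exons in ascending coordinate order,
      # reported in transcription order
      gap_start <- asc$end[-nrow(asc)]
      gap_end <- asc$start[-1L]
      g <- data.frame(start = gap_start, end = gap_end,
                      stringsAsFactors = FALSE)
      if (strand == "-") g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
      g$length <- g$end - g$start
      g$after_role <- fe$role[-nrow(fe)]
      rownames(g) <- NULL
      g
    } else {
      data.frame(start = integer(0), end = integer(0), length = integer(0),
                 after_role = character(0), stringsAsFactors = FALSE)
    }
    structure(list(gene_id = gid, seqid = fe$seqid[1L], strand = strand,
                   exons = fe, introns = introns),
              class = "nilt_gene_model")
  })
  models[unique(features$gene_id)]
}

#' @export
print.nilt_gene_model <- function(x, ...) {
  cat("<nilt_gene_model> ", x$gene_id, " (", x$strand, ") ",
      nrow(x$exons), " exons / ", nrow(x$introns), " introns; roles: ",
      paste(x$exons$role, collapse = "-"), "\n", sep = "")
  invisible(x)
}
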
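# Receptor-specific annotation of translated NILT gene models: region
# partition, Ig-domain cysteine spacing, ITIM scanning, connecting-peptide
# Ser/Thr composition, transmembrane charge, and diagnostic-residue group
# classification.

# Synthetic 116-aa V-type Ig-domain scaffold used (a) as the default
# reference frame for diagnostic positions and (b) as the template the
# locus simulator mutates. Canonical fold cysteines at 17 and 89, the
# extra CX3C pair at 27/31, His 20, SLYY at 32-35 and Leu 66 (a Group-1
# diagnostic set).
NILT_REFERENCE_IG <- paste0(
  "QVPNAYAWINPQKQFSCVQHRTGRPDCDQWCSLYYISHKPQAWQHLDHENTHDMHKMNIAHVAAYL",
  "MMRASWHMTWHLLGLAHGSGPMCFTPESDIIAQVWNVDYSTDYAMESTWD")

#' Reference Ig-domain scaffold
#'
#' The synthetic V-type Ig-domain sequence in whose coordinate frame the
#' diagnostic positions (residue 20, motif 32-35, residue 66) and the
#' canonical cysteine anchors (17, 89) are defined. Queries are mapped
#' into this frame by global alignment, so any Ig domain of the family
#' can serve as a replacement reference.
#'
#' @return single amino-acid string (116 residues)
#' @export
nilt_reference_ig <- function() NILT_REFERENCE_IG

#' Translate a gene model and partition the protein into receptor regions
#'
#' The coding exons are concatenated and translated with the standard
#' code; the terminal stop is stripped, so the protein has orf/3 - 1
#' residues. Region boundaries follow the cumulative exon amino-acid
#' boundaries, with a codon split by a phase-1/2 intron assigned to the
#' downstream region. The transmembrane exon encodes the TM helix
#' followed by the start of the cytoplasmic tail, so the cytoplasmic
#' region is the TM-exon remainder plus the Cyt1 and Cyt2 exons.
#'
#' @param model a `nilt_gene_model`
#' @param locus_seq locus nucleotide string
#' @param tm_aa_len length (aa) of the transmembrane helix at the start
#'   of the TM exon; the exon remainder is cytoplasmic
#' @return list with `gene_id`, `protein`, and `regions`, a named list of
#'   `c(start, end)` 1-based inclusive amino-acid intervals (LP, Ig1,
#'   optionally Ig2, CP, TM, Cyt — whichever roles are present)
#' @export
translate_and_partition <- function(model, locus_seq, tm_aa_len = 23L) {
  cds <- extract_cds(model, locus_seq)
  protein <- translate_cds(cds)
  if (grepl("*", protein, fixed = TRUE))
    stop("internal stop codon in ", model$gene_id,
         "; run validate_gene() - this model is a putative pseudogene")
  plen <- nchar(protein)

  lens <- model$exons$coding_length
  roles <- model$exons$role
  cum <- cumsum(lens)
  aa_end <- as.integer(pmin(floor(cum / 3), plen))
  aa_start <- c(0L, aa_end[-length(aa_end)]) + 1L
  regions <- list()
  for (i in seq_along(roles)) {
    if (aa_start[i] > aa_end[i]) next
    iv <- c(aa_start[i], aa_end[i])
    r <- roles[i]
    if (r == "TM") {
      tm_end <- min(iv[1] + tm_aa_len - 1L, iv[2])
      regions$TM <- c(iv[1], tm_end)
      if (tm_end < iv[2]) regions$Cyt <- c(tm_end + 1L, iv[2])
    } else if (r %in% c("Cyt1", "Cyt2")) {
      regions$Cyt <- if (is.null(regions$Cyt)) iv
                     else c(regions$Cyt[1], iv[2])
    } else {
      regions[[r]] <- iv
    }
  }
  list(gene_id = model$gene_id, protein = protein, regions = regions)
}

#' @keywords internal
region_seq <- function(ann, region) {
  iv <- ann$regions[[region]]
  if (is.null(iv)) return(NULL)
  substr(ann$protein, iv[1], iv[2])
}

#' Cysteine spacing profile of an Ig domain
#'
#' Locates the canonical fold cysteines near alignment positions 17 and
#' 89 (nearest Cys within `window`), then the additional cysteine pair
#' strictly between them. The spacing class is CXnC with n = gap between
#' the extra pair minus one; n of 3, 6 and 7 define the family's CX3C,
#' CX6C and CX7C classes.
#'
#' @param ig_seq amino-acid string of one Ig-domain region
#' @param anchors expected positions of the canonical cysteines
#' @param window maximum distance from an anchor to its cysteine
#' @return list with `canonical_pair`, `extra_pair` (positions or `NA`),
#'   `spacing_class` (`"CX3C"`, `"CX6C"`, `"CX7C"`, `"other"`, `"none"`)
#'   and `anchored` (FALSE when a canonical cysteine is missing)
#' @export
cys_profile <- function(ig_seq, anchors = c(17L, 89L), window = 5L) {
  cys <- which(strsplit(ig_seq, "")[[1]] == "C")
  nearest <- function(anchor) {
    cand <- cys[abs(cys - anchor) <= window]
    if (!length(cand)) NA_integer_ else cand[which.min(abs(cand - anchor))]
  }
  c1 <- nearest(anchors[1]); c2 <- nearest(anchors[2])
  if (length(cys) < 2L || is.na(c1) || is.na(c2)) {
    if (length(cys) < 2L)
      warning("fewer than 2 cysteines in Ig domain; no spacing class")
    return(list(canonical_pair = c(c1, c2), extra_pair = c(NA, NA),
                spacing_class = "none", anchored = FALSE))
  }
  extra <- cys[cys > c1 & cys < c2]
  if (length(extra) == 0L)
    return(list(canonical_pair = c(c1, c2), extra_pair = c(NA, NA),
                spacing_class = "none", anchored = TRUE))
  if (length(extra) != 2L)
    return(list(canonical_pair = c(c1, c2),
                extra_pair = c(extra[1], extra[length(extra)]),
                spacing_class = "other", anchored = TRUE))
  n <- extra[2] - extra[1] - 1L
  cls <- if (n %in% c(3L, 6L, 7L)) paste0("CX", n, "C") else "other"
  list(canonical_pair = c(c1, c2), extra_pair = extra,
       spacing_class = cls, anchored = TRUE)
}

ITIM_LONG <- "[SIVL].Y..[IVL]"
ITIM_SHORT <- "Y..[IVL]"

#' Scan a cytoplasmic region for ITIMs
#'
#' Immunoreceptor tyrosine-based inhibitory motifs matching the
#' consensus (S/I/V/L)xYxx(I/V/L) (long form) or Yxx(I/V/L) (short
#' form). Overlapping matches are found; each distinct tyrosine yields at
#' most one hit, with the long form taking precedence.
#'
#' @param cyt_seq amino-acid string of the cytoplasmic region
#' @return data.frame ordered by `y_position` (1-based index of the
#'   tyrosine) with columns `y_position`, `form` ("long"/"short"),
#'   `matched_text`
#' @export
scan_itims <- function(cyt_seq) {
  find_all <- function(pattern) {
    m <- gregexpr(paste0("(?=(", pattern, "))"), cyt_seq, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  long_start <- find_all(ITIM_LONG)
  short_start <- find_all(ITIM_SHORT)
  hits <- data.frame(y_position = integer(0), form = character(0),
                     matched_text = character(0), stringsAsFactors = FALSE)
  if (length(long_start))
    hits <- rbind(hits, data.frame(
      y_position = long_start + 2L, form = "long",
      matched_text = substring(cyt_seq, long_start, long_start + 5L),
      stringsAsFactors = FALSE))
  short_start <- short_start[!(short_start %in% hits$y_position)]
  if (length(short_start)) {
    hits <- rbind(hits, data.frame(
      y_position = short_start, form = "short",
      matched_text = substring(cyt_seq, short_start, short_start + 3L),
      stringsAsFactors = FALSE))
  }
  hits <- hits[!duplicated(hits$y_position), , drop = FALSE]
  hits <- hits[order(hits$y_position), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Serine/threonine composition of the connecting peptide
#'
#' @param cp_seq amino-acid string of the connecting-peptide region
#' @return list with `st_count` (#S + #T) and `length`
#' @export
st_composition <- function(cp_seq) {
  if (is.null(cp_seq) || !nzchar(cp_seq))
    return(list(st_count = 0L, length = 0L))
  chars <- strsplit(cp_seq, "")[[1]]
  list(st_count = sum(chars %in% c("S", "T")), length = length(chars))
}

#' Charged-residue check of the transmembrane region
#'
#' A positively charged residue (Arg or Lys) in the TM helix is the
#' hallmark of activating receptors that pair with ITAM-bearing adaptors.
#'
#' @param tm_seq amino-acid string of the TM region
#' @return TRUE iff R or K present
#' @export
tm_charge_check <- function(tm_seq) {
  grepl("[RK]", tm_seq)
}

#' Classify an Ig domain into diagnostic groups
#'
#' CX3C Ig domains fall into two groups defined by three diagnostics in
#' the reference frame: Group 1 has His at position 20, an SLYY motif at
#' 32-35 and Leu at 66; Group 2 has Gln at 20, a (P/R)V(F/L)N motif at
#' 32-35 and Ile at 66. A group is called when at least 2 of the 3
#' diagnostics agree (the motif column tolerates the published
#' degeneracy). Positions are transferred onto the query by global
#' alignment to the reference domain.
#'
#' @param ig_seq amino-acid string of the Ig domain
#' @param reference reference Ig-domain sequence anchoring the
#'   diagnostic coordinates
#' @param require_cx3c refuse to classify non-CX3C domains
#' @return list with `group` ("1", "2" or "unclassified"), `evidence`
#'   (residue 20, motif 32-35, residue 66 as observed) and `reason` when
#'   unclassified
#' @export
classify_group <- function(ig_seq, reference = nilt_reference_ig(),
                           require_cx3c = TRUE) {
  if (require_cx3c) {
    prof <- cys_profile(ig_seq)
    if (!identical(prof$spacing_class, "CX3C"))
      return(list(group = "unclassified",
                  evidence = c(res20 = NA, motif32_35 = NA, res66 = NA),
                  reason = "spacing_class"))
  }
  map <- align_map(reference, ig_seq, alphabet = "aa")
  qchars <- strsplit(ig_seq, "")[[1]]
  at <- function(p) if (is.na(map[p])) NA_character_ else qchars[map[p]]
  res20 <- at(20L)
  res66 <- at(66L)
  motif_chars <- vapply(32:35, at, character(1L))
  motif <- if (anyNA(motif_chars)) NA_character_
           else paste(motif_chars, collapse = "")
  g1 <- sum(identical(res20, "H"),
            identical(motif, "SLYY"),
            identical(res66, "L"))
  g2 <- sum(identical(res20, "Q"),
            !is.na(motif) && grepl("^[PR]V[FL]N$", motif),
            identical(res66, "I"))
  group <- if (g1 >= 2L) "1" else if (g2 >= 2L) "2" else "unclassified"
  list(group = group,
       evidence = c(res20 = res20, motif32_35 = motif, res66 = res66),
       reason = if (group == "unclassified") "diagnostics" else NA_character_)
}

#' Full receptor annotation of an intact gene model
#'
#' Composes translation/partition with the feature scans: cysteine
#' profile per Ig domain, ITIMs in the cytoplasmic region, Ser/Thr
#' composition of the connecting peptide, TM charge, and the
#' diagnostic-group call of Ig1.
#'
#' @param model a `nilt_gene_model`
#' @param locus_seq locus nucleotide string
#' @param tm_aa_len see [translate_and_partition()]
#' @param reference reference Ig domain for [classify_group()]
#' @return object of class `nilt_annotation` (list)
#' @export
annotate_receptor <- function(model, locus_seq, tm_aa_len = 23L,
                              reference = nilt_reference_ig()) {
  ann <- translate_and_partition(model, locus_seq, tm_aa_len = tm_aa_len)
  ann$cys <- lapply(intersect(c("Ig1", "Ig2"), names(ann$regions)),
                    function(r) cys_profile(region_seq(ann, r)))
  names(ann$cys) <- intersect(c("Ig1", "Ig2"), names(ann$regions))
  cyt <- region_seq(ann, "Cyt")
  ann$itims <- if (is.null(cyt)) scan_itims("") else scan_itims(cyt)
  st <- st_composition(region_seq(ann, "CP"))
  ann$st_count <- st$st_count
  ann$cp_length <- st$length
  tm <- region_seq(ann, "TM")
  ann$tm_charged <- if (is.null(tm)) NA else tm_charge_check(tm)
  ann$group <- if (!is.null(ann$regions$Ig1))
    classify_group(region_seq(ann, "Ig1"), reference = reference)
  else list(group = "unclassified",
            evidence = c(res20 = NA, motif32_35 = NA, res66 = NA),
            reason = "no Ig domain")
  class(ann) <- "nilt_annotation"
  ann
}

#' Tabulate receptor annotations
#'
#' @param annotations list of `nilt_annotation`
#' @return data.frame, one row per gene: gene_id, protein_length, region
#'   boundaries, ig1_class (and ig2_class), itim_count, itim_positions,
#'   st_count, cp_length, tm_charged, group
#' @export
annotation_table <- function(annotations) {
  rows <- lapply(annotations, function(a) {
    fmt_iv <- function(r) {
      iv <- a$regions[[r]]
      if (is.null(iv)) NA_character_ else paste0(iv[1], "-", iv[2])
    }
    data.frame(
      gene_id = a$gene_id,
      protein_length = nchar(a$protein),
      lp = fmt_iv("LP"), ig1 = fmt_iv("Ig1"), ig2 = fmt_iv("Ig2"),
      cp = fmt_iv("CP"), tm = fmt_iv("TM"), cyt = fmt_iv("Cyt"),
      ig1_class = if (!is.null(a$cys$Ig1)) a$cys$Ig1$spacing_class
                  else NA_character_,
      ig2_class = if (!is.null(a$cys$Ig2)) a$cys$Ig2$spacing_class
                  else NA_character_,
      itim_count = nrow(a$itims),
      itim_positions = paste(a$itims$y_position, collapse = ","),
      st_count = a$st_count,
      cp_length = a$cp_length,
      tm_charged = a$tm_charged,
      group = a$group$group,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.nilt_annotation <- function(x, ...) {
  cat("<nilt_annotation> ", x$gene_id, ": ", nchar(x$protein), " aa; ",
      "Ig ", paste(vapply(x$cys, `[[`, character(1L), "spacing_class"),
                   collapse = "/"),
      "; ", nrow(x$itims), " ITIM(s); group ", x$group$group, "\n", sep = "")
  invisible(x)
}
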
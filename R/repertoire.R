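# Single-individual clone-survey procedure: positivity screen against
# known Ig domains, nucleotide-level dedup with the observed-more-than-
# once retention rule, amino-acid-level singleton tally, and known/novel
# assignment of retained sequences.

#' Build a clone set
#'
#' @param ids,replicates,seqs parallel vectors: clone id, source PCR
#'   replicate (integer), nucleotide sequence
#' @return data.frame of class `nilt_clone_set`
#' @export
clone_set <- function(ids, replicates, seqs) {
  out <- data.frame(id = as.character(ids),
                    replicate = as.integer(replicates),
                    seq = toupper(as.character(seqs)),
                    stringsAsFactors = FALSE)
  class(out) <- c("nilt_clone_set", class(out))
  out
}

#' Read clones from FASTA with replicate ids in the header
#'
#' Headers of the form `>cloneid rep=3` (or `>cloneid_rep3`); a missing
#' replicate tag puts the clone in replicate 1.
#' @param path FASTA file
#' @return `nilt_clone_set`
#' @export
read_clones <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1L), 1L)
  rep_tag <- regmatches(headers, regexpr("rep[= ]?[0-9]+", headers))
  reps <- rep(1L, length(headers))
  has <- grepl("rep[= ]?[0-9]+", headers)
  reps[has] <- as.integer(gsub("[^0-9]", "", rep_tag))
  clone_set(ids, reps, as.character(set))
}

# All six-frame translations of a clone that are free of internal stops.
#' @keywords internal
clean_translations <- function(nt) {
  nt <- toupper(nt)
  frames <- character(0)
  for (s in c(nt, revcomp(nt))) for (off in 0:2) {
    len <- ((nchar(s) - off) %/% 3L) * 3L
    if (len < 3L) next
    sub <- substr(s, off + 1L, off + len)
    if (grepl("[^ACGT]", sub)) next
    aa <- translate_cds(sub, strip_stop = FALSE)
    if (!grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
      frames <- c(frames, sub("\\*$", "", aa))
  }
  unique(frames[nzchar(frames)])
}

#' Screen clones for family positivity
#'
#' A clone is kept iff the best percent identity between any of its
#' stop-free translation frames and any known Ig-domain amino-acid
#' sequence reaches `min_identity`. Clones with no stop-free frame are
#' excluded with a warning.
#'
#' @param clones `nilt_clone_set`
#' @param known_igs named character vector of known Ig-domain amino-acid
#'   sequences
#' @param min_identity percent identity threshold
#' @return the positive subset, with a `best_identity` column (the
#'   identity that supported the decision; the frame/reference search
#'   stops once the threshold is cleared)
#' @export
screen_positive <- function(clones, known_igs, min_identity = 70) {
  stopifnot(length(known_igs) > 0L)
  if (nrow(clones) == 0L) {
    clones$best_identity <- numeric(0)
    return(clones)
  }
  best <- vapply(seq_len(nrow(clones)), function(i) {
    aas <- clean_translations(clones$seq[i])
    if (!length(aas)) {
      warning("clone ", clones$id[i],
              " has no stop-free translation frame; excluded")
      return(NA_real_)
    }
    top <- 0
    for (aa in aas) for (k in known_igs) {
      top <- max(top, global_align(aa, k, alphabet = "aa")$identity_pct)
      if (top >= min_identity) return(top)  # decision already made
    }
    top
  }, numeric(1L))
  out <- clones[!is.na(best) & best >= min_identity, , drop = FALSE]
  out$best_identity <- best[!is.na(best) & best >= min_identity]
  rownames(out) <- NULL
  class(out) <- c("nilt_clone_set", "data.frame")
  out
}

#' Summarise a screened clone set
#'
#' Clones are deduplicated exactly at the nucleotide level; distinct
#' sequences observed more than once are retained, while sequences seen
#' exactly once are translated (first stop-free forward frame, since
#' amplicons from phase-1 exons start mid-codon) and deduplicated at the
#' amino acid level to give the singleton count. Every positive clone supports
#' exactly one retained sequence or one singleton.
#'
#' @param positive_clones screened `nilt_clone_set`
#' @return list with `n_positive`, `groups` (data.frame seq/count),
#'   `retained` (count >= 2, with aa translation), `n_retained_nt`,
#'   `n_retained_aa`, `singletons_aa` (count), `singleton_seqs`
#' @export
summarize_clones <- function(positive_clones) {
  n_pos <- nrow(positive_clones)
  if (n_pos == 0L)
    return(list(n_positive = 0L,
                groups = data.frame(seq = character(0), count = integer(0),
                                    stringsAsFactors = FALSE),
                retained = data.frame(seq = character(0), count = integer(0),
                                      aa = character(0),
                                      stringsAsFactors = FALSE),
                n_retained_nt = 0L, n_retained_aa = 0L,
                singletons_aa = 0L, singleton_seqs = character(0)))
  tab <- table(positive_clones$seq)
  groups <- data.frame(seq = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
  groups <- groups[order(-groups$count, groups$seq), , drop = FALSE]
  rownames(groups) <- NULL
  # amplicons from phase-1 exons start mid-codon, so pick the first
  # stop-free forward frame (falling back to the fewest-stop frame)
  safe_aa <- function(nt) {
    best <- NA_character_
    best_stops <- Inf
    for (off in 0:2) {
      len <- ((nchar(nt) - off) %/% 3L) * 3L
      if (len < 3L) next
      aa <- tryCatch(translate_cds(substr(nt, off + 1L, off + len),
                                   strip_stop = FALSE),
                     error = function(e) NA_character_)
      if (is.na(aa)) next
      n_stop <- lengths(regmatches(aa, gregexpr("\\*", aa)))
      if (n_stop == 0L) return(aa)
      if (n_stop < best_stops) { best <- aa; best_stops <- n_stop }
    }
    best
  }
  retained <- groups[groups$count >= 2L, , drop = FALSE]
  retained$aa <- vapply(retained$seq, safe_aa, character(1L),
                        USE.NAMES = FALSE)
  single <- groups$seq[groups$count == 1L]
  single_aa <- vapply(single, safe_aa, character(1L), USE.NAMES = FALSE)
  single_aa <- unique(single_aa[!is.na(single_aa)])
  list(n_positive = n_pos,
       groups = groups,
       retained = retained,
       n_retained_nt = nrow(retained),
       n_retained_aa = length(unique(retained$aa)),
       singletons_aa = length(single_aa),
       singleton_seqs = single_aa)
}

#' Assign retained sequences to known genes or call them novel
#'
#' Exact nucleotide identity over the amplified interval assigns a
#' retained sequence to a known gene; anything else is novel. Novel
#' sequences are group-classified from their translated Ig domain.
#' Degenerate (non-ACGT) positions at the amplicon ends are trimmed
#' before matching.
#'
#' @param retained data.frame from [summarize_clones()]`$retained`
#' @param known_genes named character vector of known-gene amplicon
#'   nucleotide sequences
#' @param reference reference Ig domain for [classify_group()] of novels
#' @return data.frame: seq, count, assignment (gene id or "novel"),
#'   group (for novels; NA otherwise)
#' @export
match_known <- function(retained, known_genes,
                        reference = nilt_reference_ig()) {
  trim <- function(x) gsub("^[^ACGT]+|[^ACGT]+$", "", toupper(x))
  known <- vapply(known_genes, trim, character(1L))
  rows <- lapply(seq_len(nrow(retained)), function(i) {
    s <- trim(retained$seq[i])
    hit <- names(known)[known == s]
    if (length(hit) > 1L)
      stop("retained sequence matches multiple known genes exactly: ",
           paste(hit, collapse = ", "))
    if (length(hit) == 1L)
      return(data.frame(seq = retained$seq[i], count = retained$count[i],
                        assignment = hit, group = NA_character_,
                        stringsAsFactors = FALSE))
    aa <- retained$aa[i]
    grp <- if (!is.na(aa))
      classify_group(aa, reference = reference, require_cx3c = FALSE)$group
    else NA_character_
    data.frame(seq = retained$seq[i], count = retained$count[i],
               assignment = "novel", group = grp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(seq = character(0), count = integer(0),
                      assignment = character(0), group = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
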
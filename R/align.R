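# Pairwise global alignment with identity/similarity, and a progressive
# profile-based multiple aligner (UPGMA guide tree, profile-profile
# Needleman-Wunsch with affine gaps).

#' @keywords internal
default_submat <- function(alphabet) {
  if (alphabet == "aa") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  } else {
    Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                             baseOnly = TRUE)
  }
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (BLOSUM62, gap open 10, gap extend 0.5 for proteins; +5/-4 for
#' nucleotides). Percent identity is computed over columns where both
#' rows hold residues (gap-excluded denominator); percent similarity
#' additionally counts residue pairs with a positive substitution score.
#'
#' @param a,b sequences (single strings)
#' @param alphabet `"auto"`, `"aa"` or `"nt"`
#' @param gap_open,gap_extend affine gap penalties (positive costs)
#' @param submat substitution matrix; default per alphabet
#' @return list with `aligned_a`, `aligned_b` (equal-length gapped
#'   strings), `score`, `identity_pct`, `similarity_pct`
#' @export
global_align <- function(a, b, alphabet = c("auto", "aa", "nt"),
                         gap_open = 10, gap_extend = 0.5, submat = NULL) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  a <- toupper(a); b <- toupper(b)
  if (alphabet == "auto") alphabet <- infer_alphabet(c(a, b))
  if (is.null(submat)) submat <- default_submat(alphabet)
  xa <- if (alphabet == "aa") Biostrings::AAString(a)
        else Biostrings::DNAString(a)
  xb <- if (alphabet == "aa") Biostrings::AAString(b)
        else Biostrings::DNAString(b)
  pa <- Biostrings::pairwiseAlignment(xa, xb, type = "global",
                                      substitutionMatrix = submat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(al_a, "")[[1]]
  cb <- strsplit(al_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  n_comp <- sum(both)
  ident <- sum(ca[both] == cb[both])
  simil <- sum(submat[cbind(ca[both], cb[both])] > 0)
  list(aligned_a = al_a, aligned_b = al_b,
       score = Biostrings::score(pa),
       identity_pct = if (n_comp) 100 * ident / n_comp else 0,
       similarity_pct = if (n_comp) 100 * simil / n_comp else 0)
}

#' Map positions of one sequence onto another through a global alignment
#'
#' @param ref,query sequences
#' @param ... passed to [global_align()]
#' @return integer vector of length `nchar(ref)`; element i is the
#'   1-based position in `query` aligned to position i of `ref`, or `NA`
#'   where `ref` aligns to a gap
#' @export
align_map <- function(ref, query, ...) {
  al <- global_align(ref, query, ...)
  ca <- strsplit(al$aligned_a, "")[[1]]
  cb <- strsplit(al$aligned_b, "")[[1]]
  ref_pos <- cumsum(ca != "-")
  qry_pos <- cumsum(cb != "-")
  out <- rep(NA_integer_, nchar(ref))
  keep <- ca != "-" & cb != "-"
  out[ref_pos[keep]] <- qry_pos[keep]
  out
}

#' Pairwise identity/similarity matrix
#'
#' All unordered pairs are globally aligned; percent identity fills the
#' upper triangle and percent similarity the lower, with 100 on the
#' diagonal (the layout used for published Ig-domain comparisons).
#'
#' @param seqs named character vector (>= 2 sequences, unique labels)
#' @param ... passed to [global_align()]
#' @return square numeric matrix with dimnames = labels
#' @export
identity_similarity_matrix <- function(seqs, ...) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  labs <- names(seqs)
  if (is.null(labs) || anyDuplicated(labs))
    stop("sequences must carry unique labels; duplicated: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    al <- global_align(seqs[[i]], seqs[[j]], ...)
    m[i, j] <- al$identity_pct    # upper: identity
    m[j, i] <- al$similarity_pct  # lower: similarity
  }
  m
}

# ---- progressive MSA -------------------------------------------------------

# Profile = character matrix (rows = sequences, "-" for gaps).

#' @keywords internal
profile_align <- function(A, B, submat, gap_open, gap_extend) {
  la <- ncol(A); lb <- ncol(B)
  alpha <- rownames(submat)
  count_mat <- function(P) {
    C <- matrix(0, length(alpha), ncol(P), dimnames = list(alpha, NULL))
    for (r in seq_len(nrow(P))) {
      keep <- P[r, ] != "-" & P[r, ] %in% alpha
      idx <- cbind(match(P[r, keep], alpha), which(keep))
      C[idx] <- C[idx] + 1
    }
    C
  }
  CA <- count_mat(A); CB <- count_mat(B)
  nA <- colSums(CA); nB <- colSums(CB)
  denom <- outer(nA, nB)
  S <- crossprod(CA, submat %*% CB)
  S <- ifelse(denom > 0, S / denom, 0)

  NEG <- -1e9
  M <- matrix(NEG, la + 1L, lb + 1L)  # col i aligned to col j
  X <- matrix(NEG, la + 1L, lb + 1L)  # gap in B (A column unmatched)
  Y <- matrix(NEG, la + 1L, lb + 1L)  # gap in A
  M[1L, 1L] <- 0
  if (la >= 1L) X[2L:(la + 1L), 1L] <- -gap_open - gap_extend * (seq_len(la) - 1L)
  if (lb >= 1L) Y[1L, 2L:(lb + 1L)] <- -gap_open - gap_extend * (seq_len(lb) - 1L)
  tbM <- matrix(0L, la + 1L, lb + 1L)
  tbX <- matrix(0L, la + 1L, lb + 1L)
  tbY <- matrix(0L, la + 1L, lb + 1L)
  for (i in seq_len(la)) {
    Si <- S[i, ]
    for (j in seq_len(lb)) {
      prevM <- M[i, j]; prevX <- X[i, j]; prevY <- Y[i, j]
      best <- max(prevM, prevX, prevY)
      M[i + 1L, j + 1L] <- best + Si[j]
      tbM[i + 1L, j + 1L] <- which.max(c(prevM, prevX, prevY))
      xo <- M[i, j + 1L] - gap_open
      xe <- X[i, j + 1L] - gap_extend
      X[i + 1L, j + 1L] <- max(xo, xe)
      tbX[i + 1L, j + 1L] <- if (xo >= xe) 1L else 2L
      yo <- M[i + 1L, j] - gap_open
      ye <- Y[i + 1L, j] - gap_extend
      Y[i + 1L, j + 1L] <- max(yo, ye)
      tbY[i + 1L, j + 1L] <- if (yo >= ye) 1L else 3L
    }
  }
  # traceback
  i <- la + 1L; j <- lb + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  ops <- character(0)
  while (i > 1L || j > 1L) {
    if (i == 1L) state <- 3L
    if (j == 1L) state <- 2L
    if (state == 1L) {
      ops <- c("M", ops); state <- tbM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ops <- c("X", ops); state <- tbX[i, j]; i <- i - 1L
    } else {
      ops <- c("Y", ops); state <- tbY[i, j]; j <- j - 1L
    }
  }
  out <- matrix("-", nrow(A) + nrow(B), length(ops),
                dimnames = list(c(rownames(A), rownames(B)), NULL))
  ia <- 0L; ja <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] != "Y") { ia <- ia + 1L; out[seq_len(nrow(A)), k] <- A[, ia] }
    if (ops[k] != "X") { ja <- ja + 1L
                         out[nrow(A) + seq_len(nrow(B)), k] <- B[, ja] }
  }
  out
}

#' Progressive multiple sequence alignment
#'
#' Pairwise global alignments give an identity-based distance matrix
#' (1 - identity/100); a UPGMA guide tree (average-linkage clustering)
#' orders profile merges; profiles are merged by profile-profile
#' Needleman-Wunsch with affine gaps and mean substitution scores.
#' Ungapping any output row recovers the corresponding input sequence.
#'
#' @param seqs named character vector (>= 2)
#' @param alphabet `"auto"`, `"aa"` or `"nt"`
#' @param gap_open,gap_extend affine gap penalties
#' @param submat substitution matrix; default per alphabet
#' @return object of class `nilt_msa`: character matrix, one row per
#'   input sequence (input order), "-" for gaps
#' @export
progressive_msa <- function(seqs, alphabet = c("auto", "aa", "nt"),
                            gap_open = 10, gap_extend = 0.5, submat = NULL) {
  alphabet <- match.arg(alphabet)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  labs <- names(seqs)
  if (is.null(labs) || anyDuplicated(labs)) stop("unique labels required")
  seqs <- toupper(seqs)
  if (alphabet == "auto") alphabet <- infer_alphabet(seqs)
  if (is.null(submat)) submat <- default_submat(alphabet)
  submat <- submat[rownames(submat) %in% c(AA20, "A", "C", "G", "T"),
                   colnames(submat) %in% c(AA20, "A", "C", "G", "T"),
                   drop = FALSE]
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d <- 1 - global_align(seqs[[i]], seqs[[j]], alphabet = alphabet,
                          gap_open = gap_open, gap_extend = gap_extend,
                          submat = submat)$identity_pct / 100
    D[i, j] <- d; D[j, i] <- d
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  prof <- function(k) {
    if (k < 0L) {
      s <- strsplit(seqs[[-k]], "")[[1]]
      matrix(s, 1L, dimnames = list(labs[-k], NULL))
    } else merged[[k]]
  }
  merged <- vector("list", max(1L, nrow(hc$merge)))
  for (m in seq_len(nrow(hc$merge))) {
    merged[[m]] <- profile_align(prof(hc$merge[m, 1L]),
                                 prof(hc$merge[m, 2L]),
                                 submat, gap_open, gap_extend)
  }
  out <- merged[[nrow(hc$merge)]][labs, , drop = FALSE]
  class(out) <- c("nilt_msa", class(out))
  out
}

#' Convert an alignment to a named character vector of gapped rows
#' @param msa `nilt_msa` or character matrix
#' @return named character vector
#' @export
msa_strings <- function(msa) {
  apply(unclass(msa), 1L, paste, collapse = "")
}

#' Read/write an alignment as aligned FASTA
#' @param msa alignment matrix
#' @param path file path
#' @export
write_msa <- function(msa, path) write_fasta(msa_strings(msa), path)

#' @rdname write_msa
#' @export
read_msa <- function(path) {
  seqs <- read_fasta(path)
  if (length(unique(nchar(seqs))) != 1L)
    stop("rows of an aligned FASTA must have equal length")
  out <- do.call(rbind, strsplit(seqs, ""))
  rownames(out) <- names(seqs)
  class(out) <- c("nilt_msa", class(out))
  out
}
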
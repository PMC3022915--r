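# Shared low-level helpers: alphabets, reverse complement, translation.

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
STOP_CODONS <- c("TAA", "TAG", "TGA")
AA_NO_C <- setdiff(AA20, "C")
AA_BACKGROUND <- setdiff(AA20, c("C", "Y"))   # no accidental ITIM Tyr
TM_HYDROPHOBIC <- c("A", "I", "L", "M", "F", "V", "W", "G")

#' @keywords internal
infer_alphabet <- function(seqs) {
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  chars <- setdiff(chars, "-")  # alignment gaps carry no alphabet signal
  if (all(chars %in% IUPAC_NT)) "nt"
  else if (all(chars %in% c(AA20, "X", "*", "-"))) "aa"
  else stop("sequence contains characters outside IUPAC nucleotide and ",
            "amino-acid alphabets: ",
            paste(setdiff(chars, c(IUPAC_NT, AA20, "X", "*", "-")),
                  collapse = ", "))
}

#' Reverse complement of a nucleotide string
#'
#' Handles the full degenerate IUPAC alphabet.
#' @param x a single nucleotide string
#' @return the reverse complement, same case as input (uppercased)
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a coding sequence with the standard genetic code
#'
#' Degenerate IUPAC bases are rejected: a CDS handed to translation must be
#' fully resolved (ambiguity codes are legitimate in primers and raw input
#' sequences, not inside an assembled coding sequence).
#'
#' @param cds nucleotide string, length divisible by 3
#' @param strip_stop drop a single terminal stop codon if present
#' @return amino-acid string; internal stops appear as `*`
#' @export
translate_cds <- function(cds, strip_stop = TRUE) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length ", nchar(cds), " is not a multiple of 3")
  if (grepl("[^ACGT]", cds))
    stop("degenerate or non-ACGT base in CDS; translation requires a ",
         "fully resolved coding sequence")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  if (strip_stop) aa <- sub("\\*$", "", aa)
  aa
}

#' @keywords internal
codons_of <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Inverse genetic code: amino acid -> candidate codons (stop excluded).
#' @keywords internal
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}
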
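# Per-column Shannon-entropy variability of a multiple alignment.

#' Shannon-entropy profile of an alignment
#'
#' For each column, H = -sum f_a log2 f_a with residue frequencies
#' computed over non-gap symbols only. Columns with H above the
#' threshold are called variable; the 1.3-bit threshold is the
#' convention used for this receptor family. All-gap columns have no
#' defined entropy (H = NA) and are never called variable.
#'
#' @param msa `nilt_msa`, character matrix, or named character vector of
#'   equal-length gapped strings
#' @param threshold variability threshold in bits
#' @return data.frame with `column`, `H` (bits), `n_residues`,
#'   `variable`
#' @export
entropy_profile <- function(msa, threshold = 1.3) {
  m <- if (is.matrix(msa)) unclass(msa)
       else do.call(rbind, strsplit(unname(msa), ""))
  H <- apply(m, 2L, function(col) {
    res <- col[col != "-"]
    if (!length(res)) return(NA_real_)
    f <- table(res) / length(res)
    -sum(f * log2(f))
  })
  n_res <- apply(m, 2L, function(col) sum(col != "-"))
  data.frame(column = seq_len(ncol(m)), H = as.numeric(H),
             n_residues = as.integer(n_res),
             variable = !is.na(H) & H > threshold)
}

#' Write an entropy profile as TSV
#' @param profile data.frame from [entropy_profile()]
#' @param path output file
#' @export
write_entropy_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
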
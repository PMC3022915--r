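# Pairwise identity/similarity, progressive MSA, Shannon entropy.

test_that("pairwise identity and similarity behave on knowns", {
  self <- global_align("MKLV", "MKLV")
  expect_equal(self$identity_pct, 100)
  expect_equal(self$similarity_pct, 100)

  one_sub <- global_align("MKLVMKLVMK", "MKLVMKLVMR")
  expect_equal(one_sub$identity_pct, 90)
  # K->R scores positively in BLOSUM62, so similarity stays 100
  expect_equal(one_sub$similarity_pct, 100)

  swap <- global_align("MKLVMKLVMR", "MKLVMKLVMK")
  expect_equal(swap$identity_pct, one_sub$identity_pct)
  expect_equal(swap$similarity_pct, one_sub$similarity_pct)

  expect_error(global_align("", "MK"), "empty")
  expect_true(one_sub$identity_pct <= one_sub$similarity_pct)

  # ungapping the aligned strings recovers the inputs
  al <- global_align("MKLWQV", "MKV")
  expect_identical(gsub("-", "", al$aligned_a), "MKLWQV")
  expect_identical(gsub("-", "", al$aligned_b), "MKV")
})

test_that("identity/similarity matrix fills triangles and follows labels", {
  seqs <- c(x = "MKLVAEW", y = "MKLVAEF", z = "MKIVAEW")
  m <- identity_similarity_matrix(seqs)
  expect_identical(dim(m), c(3L, 3L))
  expect_true(all(diag(m) == 100))
  al_xy <- global_align(seqs[["x"]], seqs[["y"]])
  expect_equal(m["x", "y"], al_xy$identity_pct)   # upper = identity
  expect_equal(m["y", "x"], al_xy$similarity_pct) # lower = similarity

  # permuting the input leaves every pair's identity and similarity
  # attached to its labels (the triangle layout follows display order)
  m2 <- identity_similarity_matrix(seqs[c("z", "x", "y")])
  pair_val <- function(mm, a, b, what) {
    i <- match(a, rownames(mm)); j <- match(b, colnames(mm))
    if (what == "identity") { if (i < j) mm[i, j] else mm[j, i] }
    else { if (i < j) mm[j, i] else mm[i, j] }
  }
  for (p in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    expect_equal(pair_val(m2, p[1], p[2], "identity"),
                 pair_val(m, p[1], p[2], "identity"))
    expect_equal(pair_val(m2, p[1], p[2], "similarity"),
                 pair_val(m, p[1], p[2], "similarity"))
  }

  expect_error(identity_similarity_matrix(c(a = "MK", a = "ML")),
               "duplicated")
  expect_error(identity_similarity_matrix(c(a = "MK")), "at least 2")
})

test_that("progressive MSA aligns identical and near-identical inputs", {
  same <- progressive_msa(c(a = "MKLVAE", b = "MKLVAE", c = "MKLVAE"))
  expect_false(any(same == "-"))
  expect_identical(unname(msa_strings(same)),
                   rep("MKLVAE", 3L))

  pair <- progressive_msa(c(a = "MKLV", b = "MKV"))
  s <- msa_strings(pair)
  expect_identical(nchar(s[["a"]]), 4L)
  expect_identical(sum(strsplit(s[["b"]], "")[[1]] == "-"), 1L)
  # brute-force check: best linear-gap score of the pair is matched by
  # the aligned columns (3 matches, one gap)
  expect_equal(naive_align_score("MKLV", "MKV"), 2)

  # all rows equal length; ungapping recovers every input
  set.seed(5)
  seqs <- vapply(1:6, function(i)
    paste(sample(c(AA_BACKGROUND, "Y"), 40, replace = TRUE), collapse = ""),
    character(1L))
  names(seqs) <- paste0("s", 1:6)
  msa <- progressive_msa(seqs)
  expect_identical(length(unique(nchar(msa_strings(msa)))), 1L)
  expect_identical(nrow(msa), 6L)
  for (nm in names(seqs))
    expect_identical(gsub("-", "", msa_strings(msa)[[nm]]), seqs[[nm]])
})

test_that("aligned FASTA round trips through read_msa/write_msa", {
  msa <- progressive_msa(c(a = "MKLVAEW", b = "MKVAEW", c = "MKLVAEF"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_msa(msa, fa)
  back <- read_msa(fa)
  expect_identical(msa_strings(back), msa_strings(msa))
})

test_that("entropy matches closed forms and excludes gaps", {
  cols <- c(s1 = "AAM", s2 = "AAM", s3 = "ACM", s4 = "ADM", s5 = "AEM",
            s6 = "AFM")
  prof <- entropy_profile(cols)
  expect_equal(prof$H[1], 0, tolerance = 1e-12)
  expect_equal(prof$H[2], -(2 / 6 * log2(2 / 6) + 4 / 6 * log2(1 / 6)),
               tolerance = 1e-12)

  uniform6 <- entropy_profile(c(a = "A", b = "C", c = "D", d = "E",
                                e = "F", f = "G"))
  expect_equal(uniform6$H, log2(6), tolerance = 1e-12)

  ab <- entropy_profile(c(a = "A", b = "A", c = "A", d = "B"))
  expect_equal(ab$H, -(0.75 * log2(0.75) + 0.25 * log2(0.25)),
               tolerance = 1e-12)

  # gaps carry no frequency; an all-gap column has no entropy
  gapped <- entropy_profile(c(a = "A-", b = "A-", c = "C-"))
  expect_equal(gapped$H[1], -(2 / 3 * log2(2 / 3) + 1 / 3 * log2(1 / 3)),
               tolerance = 1e-12)
  expect_true(is.na(gapped$H[2]))
  expect_false(gapped$variable[2])

  # deleting an all-gap column leaves other columns' H unchanged
  with_gap <- entropy_profile(c(a = "AM-W", b = "CM-W", c = "DM-F"))
  without <- entropy_profile(c(a = "AMW", b = "CMW", c = "DMF"))
  expect_equal(with_gap$H[c(1, 2, 4)], without$H, tolerance = 1e-12)
})

test_that("variability calls respect the 1.3-bit threshold", {
  msa <- c(s1 = "AAC", s2 = "ACC", s3 = "ADC", s4 = "AEC", s5 = "AFC",
           s6 = "AGC")
  prof <- entropy_profile(msa)  # default threshold 1.3
  expect_identical(prof$variable, c(FALSE, TRUE, FALSE))
  strict <- entropy_profile(msa, threshold = 3)
  expect_false(any(strict$variable))
  expect_identical(prof$variable, !is.na(prof$H) & prof$H > 1.3)
})

test_that("mean entropy rises with the substitution rate", {
  set.seed(42)
  base <- paste(sample(AA20, 60, replace = TRUE), collapse = "")
  fam <- function(rate) {
    seqs <- vapply(1:8, function(i) {
      v <- strsplit(base, "")[[1]]
      mut <- stats::runif(length(v)) < rate
      v[mut] <- vapply(v[mut], function(a) sample(setdiff(AA20, a), 1L),
                       character(1L))
      paste(v, collapse = "")
    }, character(1L))
    names(seqs) <- paste0("m", 1:8)
    mean(entropy_profile(seqs)$H)
  }
  hs <- vapply(c(0.02, 0.15, 0.45), fam, numeric(1L))
  expect_true(all(diff(hs) > 0))
})
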
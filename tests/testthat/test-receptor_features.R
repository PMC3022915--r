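# Translation/region partition, cysteine spacing, ITIMs, CP composition,
# TM charge, diagnostic group calls.

test_that("translation strips the stop and partitions regions exactly", {
  fe <- toy_features("toy", "Cyt2", 9L, integer(0))
  m <- build_gene_models(fe)[["toy"]]
  ann <- translate_and_partition(m, "ATGAAATAA")
  expect_identical(ann$protein, "MK")

  truth <- simulate_locus(small_config(), seed = 21L)
  models <- build_gene_models(truth$features)
  for (gid in names(models)) {
    g <- truth$genes[[gid]]
    ann <- translate_and_partition(models[[gid]], truth$locus_seq)
    expect_identical(nchar(ann$protein), g$orf_length %/% 3L - 1L)
    # regions tile the protein without gaps or overlap
    ivs <- do.call(rbind, ann$regions)
    ivs <- unname(ivs[order(ivs[, 1]), , drop = FALSE])
    expect_identical(ivs[1, 1], 1L)
    expect_identical(ivs[nrow(ivs), 2], nchar(ann$protein))
    if (nrow(ivs) > 1L)
      expect_identical(ivs[-1L, 1L], ivs[-nrow(ivs), 2L] + 1L)
  }
})

test_that("two-Ig templates partition into both Ig regions", {
  truth <- simulate_locus(small_config(two_ig_at = 2L), seed = 22L)
  m <- build_gene_models(truth$features)[["g2"]]
  ann <- translate_and_partition(m, truth$locus_seq)
  expect_true(all(c("Ig1", "Ig2") %in% names(ann$regions)))
})

test_that("internal stops and degenerate bases are refused at translation", {
  fe <- toy_features("bad", "Cyt2", 12L, integer(0))
  m <- build_gene_models(fe)[["bad"]]
  expect_error(translate_and_partition(m, "ATGTAAAAATAA"), "validate_gene")
  expect_error(translate_and_partition(m, "ATGRAAAAATAA"), "degenerate")
})

test_that("cysteine spacing classes follow the CXnC gap rule", {
  base <- strsplit(strrep("A", 100), "")[[1]]
  mk <- function(pos) paste(replace(base, pos, "C"), collapse = "")
  expect_identical(cys_profile(mk(c(17, 28, 32, 89)))$spacing_class, "CX3C")
  expect_identical(cys_profile(mk(c(17, 28, 32, 89)))$extra_pair, c(28L, 32L))
  expect_identical(cys_profile(mk(c(17, 25, 32, 89)))$spacing_class, "CX6C")
  expect_identical(cys_profile(mk(c(17, 24, 32, 89)))$spacing_class, "CX7C")
  expect_identical(cys_profile(mk(c(17, 26, 32, 89)))$spacing_class, "other")
  none <- cys_profile(mk(c(17, 89)))
  expect_identical(none$spacing_class, "none")
  expect_true(none$anchored)
  # canonical pair anchored within +/- 5 of 17 and 89
  shifted <- cys_profile(mk(c(20, 28, 32, 86)))
  expect_identical(shifted$canonical_pair, c(20L, 86L))
  # cysteines far outside the anchors flag rather than force-fit
  expect_false(cys_profile(mk(c(40, 60)))$anchored)
  expect_warning(cys_profile(mk(17)), "cysteine")
})

test_that("ITIM scanning reports long hits, then non-overlapping short hits", {
  one_long <- scan_itims("AALVYAQLAA")
  expect_identical(nrow(one_long), 1L)
  expect_identical(one_long$y_position, 5L)
  expect_identical(one_long$form, "long")
  expect_identical(one_long$matched_text, "LVYAQL")

  one_short <- scan_itims("AAYAQLAA")
  expect_identical(one_short$form, "short")
  expect_identical(one_short$y_position, 3L)

  both <- scan_itims("ALVYAQLAAAYSSVAA")
  expect_identical(both$form, c("long", "short"))
  expect_identical(both$y_position, c(4L, 11L))

  # appending non-matching residues never changes the count
  expect_identical(nrow(scan_itims(paste0("ALVYAQL", strrep("G", 50)))), 1L)
  # each tyrosine yields at most one hit
  expect_identical(anyDuplicated(both$y_position), 0L)
  expect_identical(nrow(scan_itims("GGGG")), 0L)
})

test_that("CP composition and TM charge are counted literally", {
  expect_identical(st_composition("SSTTAA"), list(st_count = 4L, length = 6L))
  expect_identical(st_composition("AAAA"), list(st_count = 0L, length = 4L))
  expect_identical(st_composition(""), list(st_count = 0L, length = 0L))
  expect_false(tm_charge_check("LLVVLLAA"))
  expect_true(tm_charge_check("LLRVLLAA"))
  expect_true(tm_charge_check("KKKK"))
})

test_that("group calls use the 2-of-3 diagnostic majority rule", {
  ref <- nilt_reference_ig()
  swap <- function(s, pos, repl) {
    v <- strsplit(s, "")[[1]]
    v[pos] <- strsplit(repl, "")[[1]]
    paste(v, collapse = "")
  }
  g1 <- classify_group(ref)
  expect_identical(g1$group, "1")
  expect_identical(unname(g1$evidence["motif32_35"]), "SLYY")

  g2_seq <- swap(swap(swap(ref, 20, "Q"), 32:35, "PVFN"), 66, "I")
  expect_identical(classify_group(g2_seq)$group, "2")
  # motif degeneracy: (P/R)V(F/L)N all count for group 2
  expect_identical(classify_group(swap(g2_seq, 32:35, "RVLN"))$group, "2")

  # 2 of 3 suffices: H at 20 with group-2 motif and Ile 66 is group 2
  mixed <- swap(swap(ref, 32:35, "PVFN"), 66, "I")
  expect_identical(classify_group(mixed)$group, "2")
  # one diagnostic alone classifies nothing
  lone <- swap(swap(ref, 32:35, "PAAN"), 66, "V")
  expect_identical(classify_group(lone)$group, "unclassified")

  # non-CX3C domains are refused with the spacing reason
  cx6 <- swap(swap(ref, 27, "A"), 24, "C")
  out <- classify_group(cx6)
  expect_identical(out$group, "unclassified")
  expect_identical(out$reason, "spacing_class")
})

test_that("planted diagnostics survive random backgrounds and divergence", {
  set.seed(31)
  for (rep in 1:10) {
    g <- sample(c("1", "2"), 1L)
    tpl <- nilt_gene_template("one_ig", group = g,
                              ig_divergence = stats::runif(1, 0, 0.25))
    # build via the generator's own protein path, then reclassify
    truth <- simulate_locus(list(genes = stats::setNames(list(tpl), "gx"),
                                 spacer_len = 50L),
                            seed = 1000L + rep)
    ig <- ig_proteins(truth)[["gx"]]
    expect_identical(classify_group(ig)$group, g)
  }
})
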
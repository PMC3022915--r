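# Generator determinism, template feasibility, pseudogene lesions, clone
# library bookkeeping.

test_that("simulation is byte-identical for a fixed seed", {
  a <- simulate_locus(small_config(), seed = 123L)
  b <- simulate_locus(small_config(), seed = 123L)
  expect_identical(a$locus_seq, b$locus_seq)
  expect_identical(a$features, b$features)
  c <- simulate_locus(small_config(), seed = 124L)
  expect_false(identical(a$locus_seq, c$locus_seq))

  fa1 <- withr::local_tempfile(); fa2 <- withr::local_tempfile()
  dir.create(fa1); dir.create(fa2)
  p1 <- write_truth(a, fa1); p2 <- write_truth(b, fa2)
  expect_identical(readLines(p1[["fasta"]]), readLines(p2[["fasta"]]))
  expect_identical(readLines(p1[["gff3"]]), readLines(p2[["gff3"]]))
})

test_that("default templates carry the published structure", {
  tpl1 <- nilt_gene_template("one_ig")
  expect_identical(tpl1$exon_lengths, c(46L, 348L, 168L, 96L, 50L, 324L))
  expect_identical(sum(tpl1$exon_lengths), 1032L)
  expect_identical(intron_phases(tpl1$exon_lengths), c(1L, 1L, 1L, 1L, 0L))
  tpl2 <- nilt_gene_template("two_ig")
  expect_identical(sum(tpl2$exon_lengths), 1278L)
  expect_identical(intron_phases(tpl2$exon_lengths),
                   c(1L, 1L, 1L, 1L, 1L, 0L))
  # infeasible ITIM load is refused
  expect_error(
    simulate_locus(list(genes = list(gx = nilt_gene_template(
      "one_ig", n_itims = 40L)), spacer_len = 50L), seed = 1L),
    "infeasible")
})

test_that("simulated loci annotate back to their recorded truth", {
  truth <- simulate_locus(small_config(two_ig_at = 3L), seed = 300L)
  models <- build_gene_models(truth$features)
  st <- structure_table(models)
  for (gid in names(truth$genes)) {
    g <- truth$genes[[gid]]
    row <- st[st$gene_id == gid, ]
    expect_identical(row$orf_length, g$orf_length)
    expect_identical(intron_phases(models[[gid]]), g$phases)
    expect_identical(validate_gene(models[[gid]], truth$locus_seq)$flags,
                     character(0))
    ann <- annotate_receptor(models[[gid]], truth$locus_seq)
    expect_identical(ann$protein, g$protein)
    expect_identical(nrow(ann$itims), g$itim_count)
    expect_identical(ann$group$group, g$group)
    expect_identical(ann$st_count, g$st_count)
    expect_identical(ann$cp_length, g$cp_length)
    expect_identical(ann$tm_charged, g$tm_charged)
    for (r in names(g$spacing))
      expect_identical(ann$cys[[r]]$spacing_class, g$spacing[[r]])
  }
})

test_that("pseudogenize plants exactly the requested lesion", {
  truth <- simulate_locus(small_config(), seed = 301L)

  t_stop <- pseudogenize(truth, "g1", "internal_stop", seed = 5L)
  v <- validate_gene(build_gene_models(t_stop$features)[["g1"]],
                     t_stop$locus_seq)
  expect_identical(v$flags, "internal_stop")
  expect_identical(v$stop_position, t_stop$genes$g1$stop_position)

  t_del <- pseudogenize(truth, "g2", "delete_role_exon", seed = 5L)
  v2 <- validate_gene(build_gene_models(t_del$features)[["g2"]],
                      t_del$locus_seq)
  expect_identical(v2$flags, "missing_role_exon")
  expect_identical(v2$missing_role, "CP")

  t_fs <- pseudogenize(truth, "g3", "frameshift", seed = 5L)
  v3 <- validate_gene(build_gene_models(t_fs$features)[["g3"]],
                      t_fs$locus_seq)
  expect_true("frameshift" %in% v3$flags)
  # untouched genes in the lesioned locus still validate clean
  v_other <- validate_gene(build_gene_models(t_fs$features)[["g1"]],
                           t_fs$locus_seq)
  expect_identical(v_other$flags, character(0))
})

test_that("minus-strand lesions report strand-correct coordinates", {
  cfg <- small_config(strands = c("-", "-", "+"))
  truth <- pseudogenize(simulate_locus(cfg, seed = 302L), "g1",
                        "internal_stop", seed = 6L)
  v <- validate_gene(build_gene_models(truth$features)[["g1"]],
                     truth$locus_seq)
  expect_identical(v$flags, "internal_stop")
  expect_identical(v$stop_position, truth$genes$g1$stop_position)
})

test_that("clone libraries account for every planted error", {
  truth <- simulate_locus(small_config(), seed = 303L)
  amp <- ig_amplicons(truth)
  lib <- simulate_clone_library(amp, n_pcr = 10L, clones_per_pcr = 10L,
                                error_rate = 0.01, seed = 8L)
  expect_identical(sort(unique(lib$clones$replicate)), 1:10)
  mismatches <- vapply(seq_len(nrow(lib$clones)), function(i) {
    a <- strsplit(lib$clones$seq[i], "")[[1]]
    b <- strsplit(amp[[lib$truth$template[i]]], "")[[1]]
    sum(a != b)
  }, integer(1L))
  expect_identical(mismatches, lib$truth$n_errors)
  expect_error(simulate_clone_library(character(0)), "empty")

  zero <- simulate_clone_library(amp, error_rate = 0, seed = 9L)
  expect_identical(zero$clones$seq, unname(amp[zero$truth$template]))
})
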
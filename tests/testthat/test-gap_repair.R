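# Gap-repair planning: NotI release, overlap chaining, junction amplicons.

gap_repair_setup <- function(n_cassettes = 3L, vector_idx = 1L) {
  fx <- toy_fixtures()
  reg <- fx$registry
  vec <- registry_subset(reg, "integration_vector")[[vector_idx]]
  cass <- select_level2_cassettes(reg, n_cassettes)
  pool <- c(lapply(cass, `[[`, "record"), list(vec$record))
  tr <- fx$genome$truth[vector_idx, ]
  list(fx = fx, reg = reg, vec = vec, pool = pool, truth = tr,
       locus = fx$genome$records[[tr$chrom]])
}

test_that("NotI release keeps arm and payload fragments, discards the rest", {
  s <- gap_repair_setup(3L)
  frags <- release_fragments(list(s$vec$record))
  expect_length(frags, 2L)
  kinds <- vapply(frags, function(f) {
    paste(sort(unique(f$features$kind)), collapse = ",")
  }, character(1))
  expect_true(all(grepl("homology_arm", kinds)))
  ## arms are ~500 bp plus the designed homology blocks
  for (f in frags) expect_gt(nchar(f$bases), 500L)
  ## a record without NotI sites passes through uncut with a warning
  expect_warning(
    out <- release_fragments(list(seq_record("x", strrep("ACT", 50)))),
    "no NotI site")
  expect_length(out, 1L)
})

test_that("gap repair finds the unique fragment chain with 30-bp overlaps", {
  s <- gap_repair_setup(3L)
  frags <- release_fragments(s$pool)
  expect_length(frags, 5L)
  plan <- plan_gap_repair(frags, s$locus, min_overlap = 20L,
                          cut_position = s$truth$cut_pos)
  expect_equal(length(plan$order), 5L)
  expect_equal(plan$fragment_ids[1], s$vec$id)
  expect_equal(plan$fragment_ids[5], s$vec$id)
  expect_true(all(plan$junctions$overlap_length == 30L))
  ## order independence of the input
  set.seed(21)
  plan2 <- plan_gap_repair(sample(frags), s$locus, min_overlap = 20L)
  expect_equal(plan2$junctions$overlap_length, plan$junctions$overlap_length)
  expect_equal(nchar(plan2$integrated$bases), nchar(plan$integrated$bases))
  ## conservation: integrated length = locus - replaced + insert
  replaced <- plan$arm3_genomic[2] - plan$arm5_genomic[1] + 1L
  expect_equal(nchar(plan$integrated$bases),
               nchar(s$locus$bases) - replaced + nchar(plan$insert))
  ## the insert carries every payload exactly once
  fills <- plan$integrated$features$label[
    plan$integrated$features$kind == "payload"]
  expect_equal(sort(fills), sprintf("spacer_fill_p%d", 1:3))
})

test_that("overlaps below the configured minimum give a no-path diagnostic", {
  s <- gap_repair_setup(3L)
  frags <- release_fragments(s$pool)
  expect_error(plan_gap_repair(frags, s$locus, min_overlap = 40L),
               "no gap-repair path")
})

test_that("a CRISPR cut outside the replaced segment is rejected", {
  s <- gap_repair_setup(2L)
  frags <- release_fragments(s$pool)
  expect_error(plan_gap_repair(frags, s$locus, cut_position = 50L),
               "outside the replaced segment")
})

test_that("path search agrees with brute force over all orderings", {
  s <- gap_repair_setup(4L)
  frags <- release_fragments(s$pool)
  i5 <- which(vapply(frags, function(f) {
    any(grepl("^arm5", f$features$label))
  }, logical(1)))
  i3 <- which(vapply(frags, function(f) {
    any(grepl("^arm3", f$features$label))
  }, logical(1)))
  paths <- brute_force_gap_paths(frags, 20L, i5, i3)
  expect_length(paths, 1L)
  plan <- plan_gap_repair(frags, s$locus, min_overlap = 20L)
  expect_equal(plan$order, paths[[1]])
})

test_that("a ten-cassette plan carries all ten payloads exactly once", {
  s <- gap_repair_setup(10L)
  frags <- release_fragments(s$pool)
  plan <- plan_gap_repair(frags, s$locus, min_overlap = 20L,
                          cut_position = s$truth$cut_pos)
  fills <- plan$integrated$features$label[
    plan$integrated$features$kind == "payload"]
  expect_equal(sort(fills), sort(sprintf("spacer_fill_p%d", 1:10)))
  expect_equal(fills, sprintf("spacer_fill_p%d", 1:10))
})

test_that("junction amplicons are predicted from exact primer binding", {
  s <- gap_repair_setup(3L)
  frags <- release_fragments(s$pool)
  plan <- plan_gap_repair(frags, s$locus, min_overlap = 20L)
  primers <- design_junction_primers(plan, distance = 150L)
  amp <- predict_junction_amplicons(plan, primers)
  expect_equal(amp$amplicon_length, rep(301L, nrow(plan$junctions)))
  ## unbound primer -> no amplicon
  none <- predict_junction_amplicons(plan, data.frame(
    junction = 1L, fwd = strrep("ACGT", 6), rev = primers$rev[1]))
  expect_true(is.na(none$amplicon_length))
  ## divergent pair (both primers top-strand) -> no amplicon
  div <- predict_junction_amplicons(plan, data.frame(
    junction = 1L, fwd = primers$fwd[1], rev = revcomp(primers$rev[1])))
  expect_true(is.na(div$amplicon_length))
  ## multi-binding primer triggers a warning
  rep_seq <- substr(plan$integrated$bases, 1, 12)
  tpl <- seq_record("t", paste0(rep_seq, "AAAA", rep_seq, "TTTT",
                                revcomp(primers$rev[1])))
  expect_warning(predict_junction_amplicons(tpl, data.frame(
    junction = 1L, fwd = rep_seq, rev = primers$rev[1])),
    "multiple loci")
})
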
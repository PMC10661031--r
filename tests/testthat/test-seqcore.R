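# Sequence core: site scanning, digestion geometry, circular bookkeeping.

test_that("find_sites reports sites on both strands with REBASE geometry", {
  bsai <- toy_enzymes()[["BsaI"]]
  plus <- find_sites(seq_record("a", "AAGGTCTCAA"), bsai)
  expect_equal(plus$position, 3L)
  expect_equal(plus$strand, "+")
  minus <- find_sites(seq_record("b", "TTGAGACCTT"), bsai)
  expect_equal(minus$position, 3L)
  expect_equal(minus$strand, "-")
  expect_equal(nrow(find_sites(seq_record("c", "ACGTACGT"), bsai)), 0L)
})

test_that("N in the subject never matches a recognition base", {
  bsai <- toy_enzymes()[["BsaI"]]
  expect_equal(nrow(find_sites(seq_record("n", "AAGGTCTNAA"), bsai)), 0L)
  expect_equal(nrow(find_sites(seq_record("n", "AANGTCTCAA"), bsai)), 0L)
})

test_that("circular records are scanned across the origin", {
  bsai <- toy_enzymes()[["BsaI"]]
  ## recognition split by the origin: ...CTC | GGT...
  rec <- seq_record("o", paste0("CTCA", strrep("A", 20), "GGT"),
                    circular = TRUE)
  hits <- find_sites(rec, bsai)
  expect_equal(hits$position, 25L)
  expect_equal(nrow(find_sites(
    seq_record("o2", paste0("CTCA", strrep("A", 20), "GGT")), bsai)), 0L)
})

test_that("find_sites agrees with a naive IUPAC scanner on random input", {
  enzymes <- toy_enzymes()
  ambiguous <- enzyme("AmbI", "GRGCYC", 1L, 5L)   # IUPAC-coded recognition
  set.seed(4711)
  for (i in 1:250) {
    rec <- seq_record(paste0("r", i), random_dna_str(sample(30:120, 1)),
                      circular = i %% 3 == 0)
    for (enz in c(enzymes, list(ambiguous))) {
      expect_identical(find_sites(rec, enz), naive_find_sites(rec, enz),
                       info = paste(rec$id, enz$name))
    }
  }
})

test_that("BsaI digestion of a linear record yields the documented fragments", {
  bsai <- toy_enzymes()[["BsaI"]]
  frags <- digest(seq_record("x", "TTTGGTCTCTAACGCCCGGG"), bsai)
  expect_length(frags, 2L)
  expect_equal(frags[[1]]$right$seq, "AACG")
  expect_equal(frags[[1]]$right$kind, "fusion")
  expect_equal(frags[[2]]$bases, "AACGCCCGGG")
  expect_equal(frags[[2]]$left$seq, "AACG")
  expect_equal(frags[[2]]$right$kind, "blunt")
})

test_that("a two-site circular record yields two double-fusion fragments", {
  bsai <- toy_enzymes()[["BsaI"]]
  circ <- seq_record("d", paste0("CCCTAGAGACC", strrep("T", 20),
                                 "GGTCTCAAACG", strrep("G", 20)),
                     circular = TRUE)
  frags <- digest(circ, bsai)
  expect_length(frags, 2L)
  for (f in frags) {
    expect_equal(f$left$kind, "fusion")
    expect_equal(f$right$kind, "fusion")
  }
  ## conservation: each junction's overhang counted once
  expect_equal(sum(vapply(frags, function(f) nchar(f$bases) - 4L,
                          integer(1))),
               length(circ))
  ## digest-ligate round trip up to rotation
  expect_true(records_equivalent(ligate_fragments(frags), circ))
})

test_that("records without sites pass through digestion unchanged", {
  bsai <- toy_enzymes()[["BsaI"]]
  rec <- seq_record("plain", strrep("ACT", 20), circular = TRUE)
  frags <- digest(rec, bsai)
  expect_length(frags, 1L)
  expect_equal(frags[[1]]$bases, rec$bases)
  expect_true(frags[[1]]$circular)
})

test_that("cuts falling outside a linear record are skipped with a warning", {
  bsai <- toy_enzymes()[["BsaI"]]
  ## site too close to the end for its downstream cut
  expect_warning(frags <- digest(seq_record("e", "AAGGTCTCAA"), bsai),
                 "outside")
  expect_length(frags, 1L)
})

test_that("NotI cuts within its site leaving GGCC overhangs", {
  noti <- toy_enzymes()[["NotI"]]
  frags <- digest(seq_record("n", paste0(strrep("A", 10), "GCGGCCGC",
                                         strrep("T", 10))), noti)
  expect_length(frags, 2L)
  expect_equal(frags[[1]]$right$seq, "GGCC")
  expect_equal(frags[[1]]$bases, paste0(strrep("A", 10), "GCGGCC"))
  expect_equal(frags[[2]]$bases, paste0("GGCCGC", strrep("T", 10)))
})

test_that("single-site circular plasmids religate to a rotation of themselves", {
  bsmbi <- toy_enzymes()[["BsmBI"]]
  set.seed(99)
  for (i in 1:10) {
    rec <- seq_record(paste0("p", i),
                      paste0("CGTCTCA",
                             paste(sample(c("A", "C", "T"), 60,
                                          replace = TRUE), collapse = "")),
                      circular = TRUE)
    frags <- digest(rec, bsmbi)
    expect_length(frags, 1L)
    expect_equal(frags[[1]]$left$seq, frags[[1]]$right$seq)
    expect_true(records_equivalent(ligate_fragments(frags), rec))
  }
})

test_that("canonical rotation is rotation- and strand-invariant", {
  set.seed(7)
  for (i in 1:50) {
    s <- random_dna_str(sample(5:40, 1))
    off <- sample(nchar(s), 1)
    rot <- paste0(substr(s, off, nchar(s)), substr(s, 1, off - 1))
    expect_identical(canonical_rotation(s), canonical_rotation(rot))
    expect_identical(canonical_rotation(s), canonical_rotation(revcomp(rot)))
    ## Booth's algorithm against brute-force minimal rotation
    rots <- vapply(seq_len(nchar(s)), function(k) {
      paste0(substr(s, k, nchar(s)), substr(s, 1, k - 1))
    }, character(1))
    expect_identical(canonical_rotation(s),
                     min(c(rots, vapply(rots, revcomp, character(1)))))
  }
})
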
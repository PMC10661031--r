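# Integration-locus selection and repeat diagnostics.

test_that("scan_intergenic recovers exactly the planted windows", {
  fx <- toy_fixtures()
  gen <- fx$genome
  wins <- scan_intergenic(gen$records, gen$annotation)
  expect_equal(nrow(wins), nrow(gen$truth))
  expect_equal(wins$chrom, gen$truth$chrom)
  expect_equal(wins$start, gen$truth$window_start)
  expect_equal(wins$end, gen$truth$window_end)
})

test_that("interval arithmetic agrees with the per-base brute-force rule", {
  fx <- toy_fixtures()
  gen <- fx$genome
  wins <- scan_intergenic(gen$records, gen$annotation)
  for (chrom in names(gen$records)) {
    ann <- gen$annotation[gen$annotation$chrom == chrom, ]
    genes <- ann[ann$kind == "CDS", ]
    blacklist <- ann[ann$kind == "telomere", ]
    mask <- moclosim:::locus_mask_bruteforce(
      nchar(gen$records[[chrom]]$bases), genes, blacklist, 1000L, 500L)
    brute <- moclosim:::mask_to_windows(mask)
    got <- wins[wins$chrom == chrom, ]
    expect_equal(got$start, brute$start)
    expect_equal(got$end, brute$end)
  }
})

test_that("positions too close to a codon are excluded, empty annotation is not", {
  gen <- list(chrX = seq_record("chrX", strrep("ACT", 3000)))
  ann <- data.frame(chrom = "chrX", kind = "CDS", start = 4001L,
                    end = 4600L, strand = "+", id = "g1",
                    stringsAsFactors = FALSE)
  wins <- scan_intergenic(gen, ann)
  ## 900 bp downstream of the start codon is inside the exclusion zone
  expect_false(any(wins$start <= 4901 & wins$end >= 4901))
  ## >1 kb upstream/downstream is allowed
  expect_true(any(wins$start <= 3000 & wins$end >= 3000))
  ## no annotation at all: one window per chromosome spanning it
  none <- scan_intergenic(gen, ann[0, ])
  expect_equal(nrow(none), 1L)
  expect_equal(c(none$start, none$end), c(1L, 9000L))
  ## genes without strand are skipped with a warning
  bad <- ann; bad$strand <- "*"
  expect_warning(scan_intergenic(gen, bad), "without strand")
})

test_that("raising a threshold never enlarges a window", {
  fx <- toy_fixtures()
  gen <- fx$genome
  base <- scan_intergenic(gen$records, gen$annotation, 1000L, 500L)
  for (thr in list(c(1200L, 500L), c(1000L, 700L))) {
    tighter <- scan_intergenic(gen$records, gen$annotation, thr[1], thr[2])
    ## every tighter window is contained in some base window
    for (i in seq_len(nrow(tighter))) {
      inside <- base$chrom == tighter$chrom[i] &
        base$start <= tighter$start[i] & base$end >= tighter$end[i]
      expect_true(any(inside))
    }
    expect_lte(sum(tighter$end - tighter$start),
               sum(base$end - base$start))
  }
})

test_that("pick_target_site returns the planted protospacer first", {
  fx <- toy_fixtures()
  gen <- fx$genome
  wins <- scan_intergenic(gen$records, gen$annotation)
  for (i in seq_len(nrow(wins))) {
    cand <- pick_target_site(wins[i, ], gen$records)
    expect_gte(nrow(cand), 1L)
    expect_equal(cand$spacer[1], gen$truth$spacer[i])
    expect_equal(cand$cut_pos[1], gen$truth$cut_pos[i])
  }
  ## a window with no PAM yields no candidate
  nog <- list(chrZ = seq_record("chrZ", strrep("AT", 200)))
  expect_equal(nrow(pick_target_site(
    list(chrom = "chrZ", start = 50L, end = 150L), nog)), 0L)
})

test_that("duplicated protospacers are rejected by the genome census", {
  fx <- toy_fixtures()
  gen <- fx$genome
  tr <- gen$truth[1, ]
  dup <- gen$records
  ## plant a second copy of the locus-1 protospacer+PAM elsewhere
  k23 <- paste0(tr$spacer, tr$pam)
  bases <- dup[[tr$chrom]]$bases
  substr(bases, 100L, 122L) <- k23
  dup[[tr$chrom]] <- seq_record(tr$chrom, bases)
  cand <- pick_target_site(list(chrom = tr$chrom,
                                start = tr$window_start,
                                end = tr$window_end), dup)
  expect_false(tr$spacer %in% cand$spacer)
})

test_that("homology arms are the flanking 500-mers with uniqueness checks", {
  fx <- toy_fixtures()
  gen <- fx$genome
  tr <- gen$truth[1, ]
  arms <- extract_homology_arms(gen$records, tr$chrom, tr$cut_pos)
  chrom <- gen$records[[tr$chrom]]$bases
  expect_equal(arms$arm5, substr(chrom, tr$cut_pos - 499L, tr$cut_pos))
  expect_equal(arms$arm3, substr(chrom, tr$cut_pos + 1L, tr$cut_pos + 500L))
  expect_error(extract_homology_arms(gen$records, tr$chrom, 300L),
               "insufficient flank")
  ## planted duplication makes an arm non-unique
  dup <- gen$records
  bases <- paste0(dup$chr2$bases, substr(chrom, tr$cut_pos - 499L,
                                         tr$cut_pos))
  dup$chr2 <- seq_record("chr2", bases)
  expect_warning(extract_homology_arms(dup, tr$chrom, tr$cut_pos),
                 "not genome-unique")
})

test_that("candidates are restricted to loci conserved across genomes", {
  fx <- toy_fixtures()
  gen <- fx$genome
  variant <- gen$records
  tr <- gen$truth[2, ]
  ## SNP inside the 5' arm of locus 2 in the second genome
  bases <- variant[[tr$chrom]]$bases
  pos <- tr$arm5_start + 100L
  old <- substr(bases, pos, pos)
  substr(bases, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  variant[[tr$chrom]] <- seq_record(tr$chrom, bases)
  cand <- design_integration_loci(list(gen$records, variant),
                                  gen$annotation)
  expect_equal(nrow(cand), nrow(gen$truth) - 1L)
  expect_false(tr$spacer %in% cand$spacer)
  ## with identical genomes nothing is dropped
  full <- design_integration_loci(list(gen$records, gen$records),
                                  gen$annotation)
  expect_equal(nrow(full), nrow(gen$truth))
})

test_that("longest shared repeat matches planted blocks and the hash oracle", {
  set.seed(31)
  block <- random_dna_str(24)
  a <- paste0(random_dna_str(240), block, random_dna_str(240))
  b <- paste0(random_dna_str(300), block, random_dna_str(180))
  hit <- longest_shared_repeat(c(a, b))
  expect_gte(hit$length, 24L)
  expect_equal(hit$length, shared_repeat_oracle(c(a, b)))
  ## identical sequences share their full length
  expect_equal(longest_shared_repeat(c(a, a))$length, nchar(a))
  ## reverse-complement planting is found and flagged
  c2 <- paste0(random_dna_str(200), revcomp(block), random_dna_str(200))
  rc_hit <- longest_shared_repeat(c(a, c2))
  expect_gte(rc_hit$length, 24L)
  expect_equal(rc_hit$length, shared_repeat_oracle(c(a, c2)))
  if (rc_hit$length == 24L) expect_equal(rc_hit$orientation, "revcomp")
  ## random pairs against the independent binary-search/hash oracle
  for (i in 1:60) {
    x <- random_dna_str(sample(80:200, 1))
    y <- random_dna_str(sample(80:200, 1))
    expect_equal(longest_shared_repeat(c(x, y))$length,
                 shared_repeat_oracle(c(x, y)), info = paste("pair", i))
  }
})
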
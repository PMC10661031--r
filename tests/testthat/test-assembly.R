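# Golden Gate assembly engine: cycle enumeration, diagnostics, fidelity
# validation.

test_that("a three-fragment fusion chain assembles into one circular product", {
  bsai <- toy_enzymes()[["BsaI"]]
  set.seed(11)
  pool <- list(pool_record("A", "CCCT", "AACG"),
               pool_record("B", "AACG", "TATG"),
               pool_record("C", "TATG", "CCCT"))
  asm <- assemble_golden_gate(pool, bsai)
  expect_length(asm$products, 1L)
  expect_true(asm$unique)
  expect_setequal(asm$products[[1]]$junctions, c("CCCT", "AACG", "TATG"))
  ## scar property: every junction appears exactly once
  expect_equal(anyDuplicated(asm$products[[1]]$junctions), 0L)
  ## no internal recognition site survives
  expect_equal(nrow(find_sites(asm$products[[1]]$record, bsai)), 0L)
})

test_that("a fragment with matching ends self-circularizes", {
  bsai <- toy_enzymes()[["BsaI"]]
  set.seed(12)
  asm <- assemble_golden_gate(list(pool_record("S", "TACA", "TACA")), bsai)
  expect_length(asm$products, 1L)
  expect_equal(length(asm$products[[1]]$parts_order), 1L)
})

test_that("a broken chain yields no product and names the dangling sites", {
  bsai <- toy_enzymes()[["BsaI"]]
  set.seed(13)
  pool <- list(pool_record("A", "CCCT", "AACG"),
               pool_record("B", "TATG", "CCCT"))
  asm <- assemble_golden_gate(pool, bsai)
  expect_length(asm$products, 0L)
  expect_setequal(asm$diagnostics$dangling, c("AACG", "TATG"))
})

test_that("the product set does not depend on pool order", {
  bsai <- toy_enzymes()[["BsaI"]]
  set.seed(14)
  pool <- random_fragment_pool(5L)
  ref <- assembly_product_keys(assemble_golden_gate(pool, bsai))
  for (i in 1:5) {
    perm <- sample(pool)
    expect_identical(assembly_product_keys(assemble_golden_gate(perm, bsai)),
                     ref)
  }
})

test_that("cycle enumeration matches brute-force ordering search", {
  bsai <- toy_enzymes()[["BsaI"]]
  set.seed(15)
  for (i in 1:40) {
    pool <- random_fragment_pool(sample(2:6, 1))
    expect_identical(
      assembly_product_keys(assemble_golden_gate(pool, bsai)),
      brute_force_assembly(pool, bsai),
      info = paste("pool", i))
  }
})

test_that("re-assembling a finished product is idempotent", {
  bsai <- toy_enzymes()[["BsaI"]]
  set.seed(16)
  pool <- list(pool_record("A", "CCCT", "AACG"),
               pool_record("B", "AACG", "CCCT"))
  product <- assemble_golden_gate(pool, bsai)$products[[1]]
  again <- assemble_golden_gate(list(product$record), bsai)
  expect_length(again$products, 1L)
  expect_true(records_equivalent(again$products[[1]]$record,
                                 product$record))
})

test_that("fragments retaining internal sites are treated as intermediates", {
  bsai <- toy_enzymes()[["BsaI"]]
  ## the scraps of every pool record keep their recognition site and are
  ## never ligated into products
  set.seed(17)
  asm <- assemble_golden_gate(list(pool_record("A", "CCCT", "CCCT")), bsai)
  expect_gt(asm$diagnostics$n_intermediates, 0L)
  expect_length(asm$products, 1L)
})

test_that("overhang-set validation flags each violation class", {
  expect_true(validate_overhang_set(c("AACG", "TATG", "GCTG"))$ok)
  pal <- validate_overhang_set("GGCC")
  expect_false(pal$ok)
  expect_true("palindrome" %in% pal$violations$type)
  rc <- validate_overhang_set(c("AACG", "CGTT"))
  expect_false(rc$ok)
  expect_true("revcomp_pair" %in% rc$violations$type)
  dup <- validate_overhang_set(c("AACG", "AACG"))
  expect_true("duplicate" %in% dup$violations$type)
  ## crosstalk margin: AACG vs CGTA differ from each other's revcomp by 1
  xt <- validate_overhang_set(c("AACG", "CGTA"), min_pair_mismatches = 2L)
  expect_true("crosstalk" %in% xt$violations$type)
  expect_error(validate_overhang_set("AAC"), "malformed")
})
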
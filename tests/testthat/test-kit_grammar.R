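# Kit grammar: Level-1/Level-2 planning, marker swap, screening colors.

test_that("Level-1 assembly of promoter+CDS+terminator yields a unique cassette", {
  fx <- toy_fixtures()
  reg <- fx$registry
  parts <- list(registry_subset(reg, "type2")[[1]],
                registry_subset(reg, "type3")[[1]],
                registry_subset(reg, "type4")[[1]])
  bb <- Filter(function(e) e$position == 1L && !isTRUE(e$terminal),
               registry_subset(reg, "cassette"))[[1]]
  product <- plan_level1(parts, bb, reg)
  expect_s3_class(product$record, "seq_record")
  expect_true(product$record$circular)
  ## grammar soundness: the cassette releases its TU with the declared
  ## connector fusion pair under BsmBI
  frags <- digest(product$record, toy_enzymes()[["BsmBI"]])
  payload <- Filter(function(f) f$internal_sites == 0L, frags)
  expect_length(payload, 1L)
  expect_equal(payload[[1]]$left$seq, bb$connector_left)
  expect_equal(payload[[1]]$right$seq, bb$connector_right)
  ## the sfGFP dropout is gone
  expect_equal(predict_screen_color(product), "white")
})

test_that("missing and duplicated Level-1 roles are reported before simulation", {
  fx <- toy_fixtures()
  reg <- fx$registry
  prom <- registry_subset(reg, "type2")
  cds <- registry_subset(reg, "type3")[[1]]
  bb <- Filter(function(e) e$position == 1L && !isTRUE(e$terminal),
               registry_subset(reg, "cassette"))[[1]]
  expect_error(plan_level1(list(prom[[1]], cds), bb, reg),
               "no part spans fusion interval type4")
  expect_error(plan_level1(list(prom[[1]], prom[[2]], cds), bb, reg),
               "ambiguous chain")
})

test_that("Level-2 assembly works for every supported TU count and refuses 11", {
  fx <- toy_fixtures()
  reg <- fx$registry
  vec <- registry_subset(reg, "integration_vector")[[1]]
  for (n in 2:10) {
    product <- plan_level2(select_level2_cassettes(reg, n), vec, reg)
    expect_equal(length(product$parts_order), n + 1L, info = paste("n", n))
    ## positional order: spacer payloads appear in position order
    labels <- product$record$features$label
    fills <- grep("^spacer_fill_p", labels, value = TRUE)
    expect_equal(fills, sprintf("spacer_fill_p%d", seq_len(n)))
    expect_equal(predict_screen_color(product), "white")
    ## no BsmBI site survives; re-digestion releases n payloads
    expect_equal(nrow(find_sites(product$record,
                                 toy_enzymes()[["BsmBI"]])), 0L)
  }
  expect_error(select_level2_cassettes(reg, 11L), "unsupported TU count")
  expect_error(select_level2_cassettes(reg, 1L), "single-TU")
})

test_that("an internal cassette in final position leaves a dangling connector", {
  fx <- toy_fixtures()
  reg <- fx$registry
  vec <- registry_subset(reg, "integration_vector")[[1]]
  cassettes <- select_level2_cassettes(reg, 4L)
  cassettes[[4]] <- Filter(function(e) e$position == 4L &&
                             !isTRUE(e$terminal),
                           registry_subset(reg, "spacer"))[[1]]
  expect_error(plan_level2(cassettes, vec, reg), "does not close")
})

test_that("the connector scheme requires exactly the kit's 18 configurations", {
  fx <- toy_fixtures()
  reg <- fx$registry
  cfgs <- enumerate_cassette_configurations(reg$config$connector_scheme)
  expect_equal(nrow(cfgs), 18L)
  expect_equal(sum(!cfgs$terminal), 9L)
  expect_equal(sum(cfgs$terminal), 9L)
  ## the kit ships exactly one cassette and one spacer per configuration
  for (cat in c("cassette", "spacer")) {
    entries <- registry_subset(reg, cat)
    expect_length(entries, 18L)
    have <- data.frame(
      position = vapply(entries, `[[`, integer(1), "position"),
      terminal = vapply(entries, function(e) isTRUE(e$terminal),
                        logical(1)))
    have <- have[order(have$terminal, have$position), ]
    rownames(have) <- NULL
    expect_equal(have, cfgs, ignore_attr = TRUE)
  }
})

test_that("marker swap inserts the cartridge payload and preserves the vector", {
  fx <- toy_fixtures()
  reg <- fx$registry
  vec <- registry_subset(reg, "integration_vector")[[1]]
  ura3 <- reg$entries[["marker_URA3"]]
  product <- swap_marker(vec, ura3)
  feats <- product$record$features
  expect_true("URA3_placeholder" %in% feats$label)
  expect_false("marker_stuffer" %in% feats$label)
  ## BbsI sites consumed
  expect_equal(nrow(find_sites(product$record, toy_enzymes()[["BbsI"]])), 0L)
  ## payload-local: the vector backbone fragment (minus its junction
  ## overhangs) is carried into the product byte-identically
  v_frag <- digest(vec$record, toy_enzymes()[["BbsI"]])
  v_backbone <- Filter(function(f) f$internal_sites == 0L, v_frag)[[1]]
  expect_true(grepl(substr(v_backbone$bases, 5,
                           nchar(v_backbone$bases) - 4),
                    paste0(product$record$bases, product$record$bases),
                    fixed = TRUE))
})

test_that("every marker fits every vector, giving 100 distinct products", {
  fx <- toy_fixtures()
  reg <- fx$registry
  vectors <- registry_subset(reg, "integration_vector")
  markers <- registry_subset(reg, "marker_cartridge")
  keys <- character()
  for (v in vectors) {
    for (m in markers) {
      keys <- c(keys, canonical_rotation(swap_marker(v, m)$record$bases))
    }
  }
  expect_length(unique(keys), 100L)
})

test_that("entries without a BbsI site are rejected as markers", {
  fx <- toy_fixtures()
  reg <- fx$registry
  vec <- registry_subset(reg, "integration_vector")[[1]]
  fake <- list(id = "no_sites", record = seq_record("no_sites",
                                                    strrep("ACT", 100),
                                                    circular = TRUE))
  expect_error(swap_marker(vec, fake), "no BbsI site")
  expect_error(swap_marker(fake, reg$entries[["marker_URA3"]]),
               "no BbsI cloning site")
})

test_that("screening colors follow dropout presence per stage", {
  fx <- toy_fixtures()
  reg <- fx$registry
  vec <- registry_subset(reg, "integration_vector")[[1]]
  crispr <- reg$entries[["crispr_marked"]]
  expect_equal(predict_screen_color(vec$record, "ecoli"), "red")
  expect_equal(predict_screen_color(vec$record, "yeast"), "red")
  expect_equal(predict_screen_color(crispr$record, "ecoli"), "green+red")
  expect_equal(predict_screen_color(crispr$record, "yeast"), "red")
  cas <- Filter(function(e) e$position == 1L,
                registry_subset(reg, "cassette"))[[1]]
  expect_equal(predict_screen_color(cas$record, "ecoli"), "green")
})
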
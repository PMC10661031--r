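#' Plan a Level-1 transcriptional-unit assembly
#'
#' Assembles Level-0 parts (promoter, CDS, terminator, ...) into a cassette
#' backbone using the Level-1 enzyme (BsaI). The part chain is checked
#' against the kit grammar before simulation: the fusion sites of the
#' supplied parts must bridge the backbone's acceptor interval
#' (AACG -> ... -> GCTG in the YTK standard) without gaps or duplicated
#' intervals. The product is a cassette whose later BsmBI digestion
#' releases the transcriptional unit with the backbone's declared Level-2
#' connector fusion sites.
#'
#' @param parts List of kit entries (Level-0 parts).
#' @param backbone_cassette Kit entry of category `"cassette"`.
#' @param registry The `kit_registry` the entries come from (for the fusion
#'   tables and enzymes).
#' @param enzymes Named enzyme list.
#' @return A `gg_product` whose record carries the assembled cassette.
#' @export
plan_level1 <- function(parts, backbone_cassette, registry,
                        enzymes = load_enzymes()) {
  stopifnot(backbone_cassette$category == "cassette")
  check_chain(parts,
              from = backbone_cassette$fus_right,
              to = backbone_cassette$fus_left,
              site_table = registry$config$level1_sites)
  pool <- c(lapply(parts, `[[`, "record"), list(backbone_cassette$record))
  asm <- assemble_golden_gate(pool, enzymes[["BsaI"]])
  if (length(asm$products) == 0L) {
    stop("Level-1 assembly produced no circular product; dangling sites: ",
         paste(asm$diagnostics$dangling, collapse = ", "))
  }
  if (!asm$unique) stop("Level-1 assembly is ambiguous")
  product <- asm$products[[1]]
  ## the cassette must release its TU with the declared connector pair
  frags <- digest(product$record, enzymes[["BsmBI"]])
  payload <- Filter(function(f) f$internal_sites == 0L &&
                      f$left$kind == "fusion" && f$right$kind == "fusion",
                    frags)
  ok <- any(vapply(payload, function(f) {
    f$left$seq == backbone_cassette$connector_left &&
      f$right$seq == backbone_cassette$connector_right
  }, logical(1)))
  if (!ok) {
    stop("assembled cassette does not release its TU with the declared ",
         "connector fusion sites")
  }
  product
}

## walk the fusion chain from `from` to `to` through the supplied parts,
## reporting grammar violations in terms of part-type intervals
check_chain <- function(parts, from, to, site_table) {
  ups <- vapply(parts, `[[`, character(1), "fus_left")
  dups <- ups[duplicated(ups)]
  if (length(dups)) {
    for (d in unique(dups)) {
      ids <- vapply(parts[ups == d], `[[`, character(1), "id")
      stop("ambiguous chain: parts ", paste(ids, collapse = " and "),
           " share upstream fusion site ", d)
    }
  }
  cur <- from
  used <- 0L
  while (cur != to) {
    i <- which(ups == cur)
    if (length(i) == 0L) {
      role <- names(site_table)[vapply(site_table, function(s) s[1] == cur,
                                       logical(1))]
      stop("no part spans fusion interval ",
           if (length(role)) paste(role, collapse = "/") else cur,
           " (", cur, " -> ...)")
    }
    cur <- parts[[i]]$fus_right
    used <- used + 1L
    if (used > length(parts)) stop("part chain does not terminate")
  }
  if (used < length(parts)) {
    stop("part(s) outside the chain from ", from, " to ", to)
  }
  invisible(TRUE)
}

#' Select the kit cassette configuration for an N-unit Level-2 assembly
#'
#' The prebuilt kit covers 2-10 transcriptional units with 9 internal
#' cassettes (positions 1-9, connectors i-1 -> i) and 9 terminal cassettes
#' (positions 2-10, connectors i-1 -> terminal): an N-unit assembly uses
#' internal positions 1..N-1 plus the terminal cassette at position N.
#'
#' @param registry A `kit_registry`.
#' @param n Number of transcriptional units (2-10 with the standard
#'   scheme).
#' @param spacers Use spacer entries instead of cassette backbones.
#' @return List of kit entries in positional order.
#' @export
select_level2_cassettes <- function(registry, n, spacers = TRUE) {
  max_tus <- registry$config$connector_scheme$max_tus
  if (n > max_tus) {
    stop("unsupported TU count ", n, ": the connector scheme supports at ",
         "most ", max_tus, " transcriptional units")
  }
  if (n < 2L) {
    stop("no prebuilt cassette configuration for a single-TU assembly; ",
         "assemble the unit directly into the vector")
  }
  pool <- registry_subset(registry, if (spacers) "spacer" else "cassette")
  pick <- function(pos, term) {
    hit <- Filter(function(e) e$position == pos &&
                    isTRUE(e$terminal) == term, pool)
    if (length(hit) != 1L) stop("no kit entry for position ", pos)
    hit[[1]]
  }
  c(lapply(seq_len(n - 1L), pick, term = FALSE), list(pick(n, TRUE)))
}

#' Enumerate the cassette configurations a connector scheme requires
#'
#' Counts the distinct (position, internal/terminal) cassette
#' configurations needed to support every assembly size in `2..max_tus`.
#' For the standard 10-position scheme this is 9 internal + 9 terminal =
#' 18, the size of the prebuilt cassette (and spacer) series.
#'
#' @param scheme A connector scheme (see [default_kit_config()]).
#' @return Data frame of required configurations.
#' @export
enumerate_cassette_configurations <- function(scheme) {
  cfgs <- list()
  for (n in 2:scheme$max_tus) {
    for (pos in seq_len(n)) {
      terminal <- pos == n
      cfgs[[sprintf("%d_%s", pos, terminal)]] <- data.frame(
        position = pos, terminal = terminal)
    }
  }
  out <- unique(do.call(rbind, cfgs))
  rownames(out) <- NULL
  out[order(out$terminal, out$position), ]
}

#' Plan a Level-2 multigene assembly
#'
#' Assembles 1-10 cassettes (or spacers) into an integration vector with
#' the Level-2 enzyme (BsmBI). The connector chain is checked for closure
#' against the scheme before simulation; the product must be unique and
#' must have lost the vector's mScarlet dropout.
#'
#' @param cassettes List of kit entries in positional order.
#' @param vector_entry Kit entry of category `"integration_vector"`.
#' @param registry The `kit_registry`.
#' @param enzymes Named enzyme list.
#' @return A `gg_product`.
#' @export
plan_level2 <- function(cassettes, vector_entry, registry,
                        enzymes = load_enzymes()) {
  scheme <- registry$config$connector_scheme
  n <- length(cassettes)
  if (n < 1L) stop("no cassettes supplied")
  if (n > scheme$max_tus) {
    stop("unsupported TU count ", n, ": the connector scheme supports at ",
         "most ", scheme$max_tus, " transcriptional units")
  }
  ## connector closure: vector right (S0) -> ... -> vector left (terminal)
  cur <- vector_entry$fus_right
  for (i in seq_len(n)) {
    if (cassettes[[i]]$connector_left != cur) {
      stop("connector chain broken at position ", i, ": expected ",
           cur, ", cassette ", cassettes[[i]]$id, " starts with ",
           cassettes[[i]]$connector_left)
    }
    cur <- cassettes[[i]]$connector_right
  }
  if (cur != vector_entry$fus_left) {
    stop("connector chain does not close: final cassette ends with ", cur,
         " but the vector expects the terminal connector ",
         vector_entry$fus_left, " (dangling terminal connector)")
  }
  pool <- c(lapply(cassettes, `[[`, "record"), list(vector_entry$record))
  asm <- assemble_golden_gate(pool, enzymes[["BsmBI"]])
  if (length(asm$products) == 0L) {
    stop("Level-2 assembly produced no circular product; dangling sites: ",
         paste(asm$diagnostics$dangling, collapse = ", "))
  }
  if (!asm$unique) stop("Level-2 assembly is ambiguous")
  product <- asm$products[[1]]
  if (any(grepl("mScarlet", product$record$features$label) &
          product$record$features$kind == "dropout")) {
    stop("vector dropout survived the Level-2 assembly")
  }
  product
}

#' Swap a selectable marker into a vector or CRISPR backbone
#'
#' Simulates the BbsI Golden Gate that replaces the marker stuffer of a
#' markerless integration vector (or CRISPR plasmid) with a selectable
#' marker cartridge payload. The BbsI sites are consumed; every other
#' feature of the target is preserved.
#'
#' @param target Kit entry carrying a BbsI cloning site
#'   (`integration_vector` or `crispr_backbone`).
#' @param marker Kit entry of category `"marker_cartridge"`.
#' @param enzymes Named enzyme list.
#' @return A `gg_product`.
#' @export
swap_marker <- function(target, marker, enzymes = load_enzymes()) {
  bbsi <- enzymes[["BbsI"]]
  if (nrow(find_sites(target$record, bbsi)) == 0L) {
    stop("target ", target$id, " carries no BbsI cloning site")
  }
  if (nrow(find_sites(marker$record, bbsi)) == 0L) {
    stop("incompatible marker ", marker$id, ": no BbsI site to ligate")
  }
  tfr <- Filter(function(f) f$internal_sites == 0L &&
                  f$left$kind == "fusion" && f$right$kind == "fusion",
                digest(target$record, bbsi))
  mfr <- Filter(function(f) f$internal_sites == 0L &&
                  f$left$kind == "fusion" && f$right$kind == "fusion",
                digest(marker$record, bbsi))
  compatible <- length(tfr) >= 1L && length(mfr) >= 1L &&
    any(vapply(mfr, function(m) {
      any(vapply(tfr, function(t) {
        t$right$seq == m$left$seq && m$right$seq == t$left$seq
      }, logical(1)))
    }, logical(1)))
  if (!compatible) {
    stop("incompatible marker ", marker$id,
         ": fusion sites do not match the target's cloning site")
  }
  asm <- assemble_golden_gate(list(target$record, marker$record), bbsi)
  if (length(asm$products) != 1L) {
    stop("marker swap did not yield a single product")
  }
  asm$products[[1]]
}

#' Predict the screening color of a construct
#'
#' Colony color is derived purely from the presence or absence of dropout
#' reporter features: labels carry the reporter (`sfGFP`/`mScarlet`) and
#' the stages at which it is expressed (`ecoli`, `yeast`). A correct
#' assembly loses its dropouts and screens white.
#'
#' @param x A `gg_product`, `seq_record`, or kit entry.
#' @param stage `"ecoli"` or `"yeast"`.
#' @return One of `"white"`, `"green"`, `"red"`, `"green+red"`.
#' @export
predict_screen_color <- function(x, stage = c("ecoli", "yeast")) {
  stage <- match.arg(stage)
  record <- if (inherits(x, "gg_product")) x$record else
    if (inherits(x, "seq_record")) x else x$record
  f <- record$features
  drop <- f[f$kind == "dropout" & grepl(stage, f$label), , drop = FALSE]
  green <- any(grepl("sfGFP", drop$label))
  red <- any(grepl("mScarlet", drop$label))
  if (green && red) "green+red" else if (green) "green" else
    if (red) "red" else "white"
}
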
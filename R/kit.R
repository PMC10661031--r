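#' Default toy-kit configuration
#'
#' The configuration bundles every table the kit grammar needs: the Level-1
#' part-type fusion sites (the published YTK standard sites), the Level-2
#' connector scheme (positional junction sites S0..S9 plus a terminal site,
#' supporting up to 10 transcriptional units), the BbsI marker-swap fusion
#' pair, and the BsaI fusion sites used by gRNA-tRNA array assembly. The
#' Level-2/marker/array sites were chosen once with [validate_overhang_set()]
#' and are frozen here; real kit files can override any table via the
#' manifest.
#'
#' @return A list of configuration tables.
#' @export
default_kit_config <- function() {
  list(
    level1_sites = list(
      type1 = c("CCCT", "AACG"), type2 = c("AACG", "TATG"),
      type3 = c("TATG", "ATCC"), type3a = c("TATG", "TTCT"),
      type3b = c("TTCT", "ATCC"), type4 = c("ATCC", "GCTG"),
      type4a = c("ATCC", "TGGC"), type4b = c("TGGC", "GCTG"),
      type5 = c("GCTG", "TACA"), type6 = c("TACA", "GAGT"),
      type7 = c("GAGT", "CCGA"), type8 = c("CCGA", "CCCT")
    ),
    connector_scheme = list(
      ## junction i sits between cassette position i and i+1; S0 joins the
      ## vector to position 1 and the terminal site closes back into the
      ## vector after the last cassette.
      junctions = c("AATA", "AAAC", "AGCG", "CGAC", "CACG",
                    "TTTC", "GTGA", "TCCA", "TAGC", "AGCC"),
      terminal = "ACGG",
      max_tus = 10L
    ),
    marker_sites = c("CTGC", "CATC"),
    array_sites = list(
      entry = "GTGC",
      internal = c("TAGG", "ATGC", "ACAA", "CAGG", "TGCC",
                   "ACTT", "ATCT", "GAGC", "CAAG"),
      exit = "ACCG",
      dropout = c("ACGC", "CACC")
    ),
    min_overlap = 20L,
    homology_block_len = 22L,
    arm_length = 500L
  )
}

#' Kit registries
#'
#' A registry catalogues the plasmids of a toolkit together with their
#' grammar roles. Each entry is a list with `id`, `record` (the
#' `seq_record`), `category` (part type / cassette / spacer /
#' integration_vector / marker_cartridge / crispr_backbone), the declared
#' fusion pair `fus_left`/`fus_right` of the entry's useful fragment under
#' its level enzyme, the Level-2 `connector_left`/`connector_right` pair for
#' cassette-like entries, `position` and `terminal` for positional entries,
#' and free-text `marker`/`locus` metadata.
#'
#' @param entries Named list of entries.
#' @param config Kit configuration (see [default_kit_config()]).
#' @return An object of class `kit_registry`.
#' @export
kit_registry <- function(entries, config = default_kit_config()) {
  names(entries) <- vapply(entries, `[[`, character(1), "id")
  structure(list(entries = entries, config = config),
            class = "kit_registry")
}

#' @export
print.kit_registry <- function(x, ...) {
  cats <- table(vapply(x$entries, `[[`, character(1), "category"))
  cat(sprintf("<kit_registry> %d entries\n", length(x$entries)))
  for (nm in names(cats)) cat(sprintf("  %-20s %d\n", nm, cats[[nm]]))
  invisible(x)
}

kit_entry <- function(id, record, category, fus_left, fus_right,
                      level_enzyme, connector_left = NA_character_,
                      connector_right = NA_character_,
                      position = NA_integer_, terminal = NA,
                      marker = NA_character_, locus = NA_character_) {
  list(id = id, record = record, category = category,
       fus_left = fus_left, fus_right = fus_right,
       level_enzyme = level_enzyme,
       connector_left = connector_left, connector_right = connector_right,
       position = as.integer(position), terminal = terminal,
       marker = marker, locus = locus)
}

#' Subset a registry by category
#'
#' @param registry A `kit_registry`.
#' @param category Character vector of categories to keep.
#' @return List of entries.
#' @export
registry_subset <- function(registry, category) {
  Filter(function(e) e$category %in% category, registry$entries)
}

#' Write a kit registry to disk
#'
#' Emits one GenBank file per entry plus a YAML manifest carrying the
#' grammar metadata and configuration tables.
#'
#' @param registry A `kit_registry`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_kit <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gb_dir <- file.path(dir, "plasmids")
  dir.create(gb_dir, showWarnings = FALSE)
  manifest <- lapply(registry$entries, function(e) {
    file <- file.path("plasmids", paste0(e$id, ".gb"))
    write_genbank(e$record, file.path(dir, file))
    m <- e[setdiff(names(e), "record")]
    m$file <- file
    m[!vapply(m, function(v) length(v) == 1L && is.na(v), logical(1))]
  })
  yaml::write_yaml(list(config = registry$config,
                        entries = unname(manifest)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a kit registry from disk
#'
#' @param dir Directory written by [write_kit()].
#' @return A `kit_registry`.
#' @export
read_kit <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  cfg <- man$config
  ## yaml collapses c(a, b) pairs to lists; restore vectors
  cfg$level1_sites <- lapply(cfg$level1_sites, unlist)
  cfg$connector_scheme$junctions <- unlist(cfg$connector_scheme$junctions)
  cfg$marker_sites <- unlist(cfg$marker_sites)
  cfg$array_sites$internal <- unlist(cfg$array_sites$internal)
  cfg$array_sites$dropout <- unlist(cfg$array_sites$dropout)
  entries <- lapply(man$entries, function(m) {
    rec <- read_genbank(file.path(dir, m$file))
    kit_entry(m$id, rec, m$category,
              m$fus_left %||% NA_character_, m$fus_right %||% NA_character_,
              m$level_enzyme,
              m$connector_left %||% NA_character_,
              m$connector_right %||% NA_character_,
              m$position %||% NA_integer_, m$terminal %||% NA,
              m$marker %||% NA_character_, m$locus %||% NA_character_)
  })
  kit_registry(entries, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a kit registry against its own grammar
#'
#' Every entry's declared fusion sites must equal those produced by
#' digesting its sequence with the level-appropriate enzyme: the digest must
#' contain a fragment free of internal recognition sites whose two fusion
#' ends match the declaration. Overhang tables are also re-validated.
#'
#' @param registry A `kit_registry`.
#' @param enzymes Named list of enzymes (default: the shipped table).
#' @return A list with `ok` and a data frame of `violations`.
#' @export
validate_kit <- function(registry, enzymes = load_enzymes()) {
  viol <- list()
  for (e in registry$entries) {
    enz <- enzymes[[e$level_enzyme]]
    if (is.null(enz)) {
      viol[[length(viol) + 1L]] <- data.frame(
        id = e$id, problem = paste("unknown enzyme", e$level_enzyme))
      next
    }
    frags <- digest(e$record, enz)
    clean <- Filter(function(f) {
      f$internal_sites == 0L && f$left$kind == "fusion" &&
        f$right$kind == "fusion"
    }, frags)
    hit <- Filter(function(f) {
      f$left$seq == e$fus_left && f$right$seq == e$fus_right
    }, clean)
    if (length(hit) != 1L) {
      viol[[length(viol) + 1L]] <- data.frame(
        id = e$id,
        problem = sprintf(
          "declared fusion pair %s->%s matched by %d clean fragment(s)",
          e$fus_left, e$fus_right, length(hit)))
    }
  }
  cfg <- registry$config
  sets <- list(
    level2 = c(cfg$connector_scheme$junctions, cfg$connector_scheme$terminal),
    marker = cfg$marker_sites,
    array = c(cfg$array_sites$entry, cfg$array_sites$internal,
              cfg$array_sites$exit, cfg$array_sites$dropout))
  for (nm in names(sets)) {
    v <- validate_overhang_set(sets[[nm]])
    if (!v$ok) {
      viol[[length(viol) + 1L]] <- data.frame(
        id = paste0("overhang_table:", nm),
        problem = paste(v$violations$type, collapse = ","))
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(id = character(), problem = character())
  list(ok = nrow(viol) == 0L, violations = viol)
}
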
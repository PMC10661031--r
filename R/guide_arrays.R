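#' Validate a gRNA spacer
#'
#' Checks the design rules for spacers entering a gRNA-tRNA array: exactly
#' 20 nt; free of BsaI/BsmBI/BbsI/NotI recognition sites on either strand
#' (they would be cut during cloning); and, when a genome is supplied,
#' exactly one genomic match with an NGG PAM immediately 3' (on either
#' strand).
#'
#' @param spacer 20-nt spacer sequence (5'->3', without PAM).
#' @param genome Optional named list of `seq_record`s.
#' @return A list with `ok` and a data frame `checks` (one row per rule).
#' @export
validate_spacer <- function(spacer, genome = NULL) {
  spacer <- toupper(spacer)
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  add("length_20", nchar(spacer) == 20L,
      sprintf("length %d", nchar(spacer)))
  add("acgt_only", grepl("^[ACGT]+$", spacer))
  bad <- Filter(function(m) grepl(m, spacer, fixed = TRUE), enzyme_motifs())
  add("no_internal_enzyme_site", length(bad) == 0L,
      paste(bad, collapse = ","))
  if (!is.null(genome) && nchar(spacer) == 20L) {
    genome <- named_genome(genome)
    hits <- 0L
    pam_ok <- FALSE
    for (rec in genome) {
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") rec$bases else revcomp(rec$bases)
        pos <- gregexpr(spacer, subj, fixed = TRUE)[[1]]
        if (pos[1] == -1L) next
        for (p in as.integer(pos)) {
          hits <- hits + 1L
          pam <- substr(subj, p + 20L, p + 22L)
          if (nchar(pam) == 3L && substr(pam, 2L, 3L) == "GG") {
            pam_ok <- TRUE
          }
        }
      }
    }
    add("genome_unique", hits == 1L, sprintf("%d match(es)", hits))
    add("pam_adjacent", pam_ok)
  }
  checks <- do.call(rbind, checks)
  list(ok = all(checks$pass), checks = checks)
}

#' Design PCR primers for a gRNA-tRNA array
#'
#' One gRNA-tRNA fragment is PCR-generated per spacer from the template in
#' the CRISPR backbone's 3-part dropout (scaffold followed by tRNA). The
#' forward primer tail encodes a BsaI site, the position's fusion site and
#' the spacer; the reverse tail encodes a BsaI site and the next
#' position's fusion site. The first and last fragments carry the
#' backbone-matching entry/exit fusion sites; internal junction sites are
#' assigned in positional order from the kit's validated overhang table.
#' The last fragment's reverse primer anneals at the scaffold end, so the
#' assembled array ends on a scaffold without a trailing tRNA.
#'
#' @param spacers Character vector of 1-10 pairwise-distinct 20-nt spacers
#'   (names become fragment names).
#' @param template Kit entry of category `"crispr_backbone"`.
#' @param registry The `kit_registry` (for the array overhang table).
#' @param anneal_length Length of the primer annealing region (default 18).
#' @return An object of class `array_design`: spacers, per-fragment primer
#'   pairs, and the internal fusion sites used.
#' @export
design_array_primers <- function(spacers, template, registry,
                                 anneal_length = 18L) {
  n <- length(spacers)
  if (n < 1L || n > 10L) {
    stop("array size must be between 1 and 10 spacers, got ", n)
  }
  dup <- unique(spacers[duplicated(spacers)])
  if (length(dup)) {
    stop("duplicated spacer(s) ", paste(dup, collapse = ", "),
         ": repeated spacers are a recombination and assembly hazard")
  }
  for (s in spacers) {
    v <- validate_spacer(s)
    if (!v$ok) {
      stop("invalid spacer ", s, ": ",
           paste(v$checks$check[!v$checks$pass], collapse = ", "))
    }
  }
  arr <- registry$config$array_sites
  if (n - 1L > length(arr$internal)) {
    stop("overhang table too small for ", n, " fragments")
  }
  fus <- c(arr$entry, arr$internal[seq_len(max(0L, n - 1L))], arr$exit)
  tpl <- template$record
  scaf_ft <- tpl$features[tpl$features$kind == "scaffold", ][1, ]
  trna_ft <- tpl$features[tpl$features$kind == "tRNA", ][1, ]
  scaffold <- substr(tpl$bases, scaf_ft$start, scaf_ft$end)
  trna <- substr(tpl$bases, trna_ft$start, trna_ft$end)
  primers <- lapply(seq_len(n), function(i) {
    last <- i == n
    fwd <- paste0("GGTCTCA", fus[i], spacers[i],
                  substr(scaffold, 1L, anneal_length))
    rev_anchor <- if (last) scaffold else trna
    rev <- paste0("GGTCTCA", revcomp(fus[i + 1L]),
                  revcomp(substr(rev_anchor,
                                 nchar(rev_anchor) - anneal_length + 1L,
                                 nchar(rev_anchor))))
    data.frame(fragment = i, spacer = spacers[i], fwd = fwd, rev = rev,
               fusion_left = fus[i], fusion_right = fus[i + 1L],
               stringsAsFactors = FALSE)
  })
  structure(
    list(spacers = spacers, primers = do.call(rbind, primers),
         fusion_sites = fus, template_id = template$id,
         scaffold = scaffold, trna = trna),
    class = "array_design")
}

#' @export
print.array_design <- function(x, ...) {
  cat(sprintf("<array_design> %d spacer(s) on template %s, junctions %s\n",
              length(x$spacers), x$template_id,
              paste(x$fusion_sites, collapse = "-")))
  invisible(x)
}

#' Simulate a PCR on a template record
#'
#' Primer annealing is modelled as exact matching of the primer's 3'
#' region (at least `min_anneal` nt) to the template; non-matching 5'
#' tails are appended to the product. Mispriming is out of scope: the
#' longest exactly-matching 3' suffix is used and must bind uniquely.
#'
#' @param template A `seq_record`.
#' @param fwd,rev Primer sequences 5'->3'.
#' @param min_anneal Minimum annealing length.
#' @return A linear `seq_record` (the amplicon).
#' @export
simulate_pcr <- function(template, fwd, rev, min_anneal = 12L) {
  bind <- function(primer, subject) {
    L <- nchar(primer)
    for (k in L:min_anneal) {
      suff <- substr(primer, L - k + 1L, L)
      hits <- gregexpr(suff, subject, fixed = TRUE)[[1]]
      if (hits[1] != -1L) {
        if (length(hits) > 1L) stop("primer anneals at multiple positions")
        return(list(pos = as.integer(hits[1]), anneal = k,
                    tail = substr(primer, 1L, L - k)))
      }
    }
    stop("primer does not anneal to the template")
  }
  f <- bind(fwd, template$bases)
  r <- bind(rev, revcomp(template$bases))
  r_end <- nchar(template$bases) - r$pos + 1L   # top-strand end of rev site
  r_start <- r_end - r$anneal + 1L
  if (r_start < f$pos) stop("divergent primer pair")
  core <- substr(template$bases, f$pos, r_end)
  seq_record(paste0(template$id, "_amplicon"),
             paste0(f$tail, core, revcomp(r$tail)))
}

#' Simulate the BsaI assembly of a gRNA-tRNA array
#'
#' PCR-generates each fragment of the design on the CRISPR backbone's
#' template region and runs the one-pot BsaI Golden Gate into the
#' backbone. The product must be unique, must have lost the
#' sfGFP/template/mScarlet dropout section, and carries the spacers 5'->3'
#' in design order, each followed by the scaffold and separated by tRNA
#' sequences.
#'
#' @param design An `array_design`.
#' @param backbone Kit entry of category `"crispr_backbone"`.
#' @param enzymes Named enzyme list.
#' @return A `gg_product`.
#' @export
simulate_array_assembly <- function(design, backbone,
                                    enzymes = load_enzymes()) {
  if (length(design$spacers) == 0L) stop("empty array design")
  if (anyDuplicated(design$fusion_sites)) {
    stop("ambiguous array design: a fusion site is reused")
  }
  amplicons <- lapply(seq_len(nrow(design$primers)), function(i) {
    p <- design$primers[i, ]
    simulate_pcr(backbone$record, p$fwd, p$rev)
  })
  asm <- assemble_golden_gate(c(list(backbone$record), amplicons),
                              enzymes[["BsaI"]])
  if (length(asm$products) == 0L) {
    stop("array assembly produced no circular product; dangling sites: ",
         paste(asm$diagnostics$dangling, collapse = ", "))
  }
  if (!asm$unique) stop("array assembly is ambiguous")
  product <- asm$products[[1]]
  got <- extract_array_spacers(product$record, design$scaffold)
  if (!identical(got, unname(design$spacers))) {
    stop("assembled array does not carry the spacers in design order")
  }
  product
}

#' Recover the spacer order from an assembled array
#'
#' Spacers are extracted by scaffold anchoring: each scaffold occurrence in
#' the array region is preceded by its 20-nt spacer.
#'
#' @param record Circular `seq_record` of an assembled CRISPR plasmid.
#' @param scaffold The scaffold sequence used in the design.
#' @return Character vector of spacers in array order.
#' @export
extract_array_spacers <- function(record, scaffold) {
  ## rotate so the array promoter starts the linear view
  f <- record$features
  anchor <- f[f$kind == "promoter" & grepl("array", f$label), , drop = FALSE]
  bases <- record$bases
  if (nrow(anchor) >= 1L) {
    bases <- rotate_string(bases, anchor$start[1])
  }
  hits <- gregexpr(scaffold, bases, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(character())
  vapply(as.integer(hits), function(p) substr(bases, p - 20L, p - 1L),
         character(1))
}
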
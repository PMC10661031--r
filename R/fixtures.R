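#' Fixture configuration
#'
#' Controls the deterministic toy-kit/toy-genome generator. Identical
#' configuration and seed produce byte-identical output.
#'
#' @param seed Integer seed for all randomness.
#' @param n_loci Number of planted integration loci (default 10, split
#'   across two chromosomes).
#' @param part_counts Named integer vector of Level-0 part counts per type.
#'   The default totals 38 parts which, with 18 cassette backbones, 18
#'   spacers, 10 integration vectors, 10 marker cartridges and 2 CRISPR
#'   backbones, mirrors the 96-plasmid scale of the real kit.
#' @param kit Kit configuration tables, see [default_kit_config()].
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 17L, n_loci = 10L,
                           part_counts = c(type1 = 1L, type2 = 12L,
                                           type3 = 10L, type3a = 2L,
                                           type3b = 2L, type4 = 6L,
                                           type5 = 1L, type6 = 2L,
                                           type7 = 1L, type8 = 1L),
                           kit = default_kit_config()) {
  structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                 part_counts = part_counts, kit = kit),
            class = "fixture_config")
}

## evaluate code under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

enzyme_motifs <- function() {
  c("GGTCTC", "GAGACC", "CGTCTC", "GAGACG",
    "GAAGAC", "GTCTTC", "GCGGCCGC")
}

## mutate random sequence until it contains no recognition motif on either
## strand ("domestication")
clean_dna <- function(n, extra_forbidden = character()) {
  motifs <- c(enzyme_motifs(), extra_forbidden)
  s <- random_dna(n)
  repeat {
    hit <- NULL
    for (m in motifs) {
      p <- regexpr(m, s, fixed = TRUE)
      if (p > 0L) { hit <- c(p, nchar(m)); break }
    }
    if (is.null(hit)) return(s)
    i <- hit[1] + sample.int(hit[2], 1L) - 1L
    old <- substr(s, i, i)
    substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
}

## homology block whose composed junction strings carry exactly one NotI
## site each and no other recognition site (strays across the fixed block
## boundaries cannot be repaired later, so they are screened out here)
homology_block <- function(len) {
  repeat {
    m <- clean_dna(len)
    ok <- all(vapply(c(hom_open(m), hom_close(m)), function(s) {
      counts <- vapply(enzyme_motifs(), function(mot) {
        length(gregexpr(mot, s, fixed = TRUE)[[1]][
          gregexpr(mot, s, fixed = TRUE)[[1]] > 0L])
      }, integer(1))
      counts[["GCGGCCGC"]] == 1L && sum(counts) == 1L
    }, logical(1)))
    if (ok) return(m)
  }
}

## PAM-free filler: no G at all (kills NGG PAMs and every enzyme motif) and
## no CC dinucleotide (kills minus-strand CCN PAMs)
pam_free_dna <- function(n) {
  x <- sample(c("A", "C", "T"), n, replace = TRUE, prob = c(.4, .2, .4))
  cc <- which(x[-1] == "C" & x[-n] == "C")
  while (length(cc)) {
    x[cc + 1L] <- sample(c("A", "T"), length(cc), replace = TRUE)
    cc <- which(x[-1] == "C" & x[-n] == "C")
  }
  paste(x, collapse = "")
}

## sequence motif builders; the enzyme geometries place the 4-nt fusion
## site right next to the recognition sequence with a 1- or 2-nt spacer.
bsa_f <- function(s) paste0("GGTCTCA", s)
bsa_r <- function(s) paste0(s, "AGAGACC")
bsm_f <- function(s) paste0("CGTCTCA", s)
bsm_r <- function(s) paste0(s, "AGAGACG")
bbs_f <- function(s) paste0("GAAGACTT", s)
bbs_r <- function(s) paste0(s, "TTGTCTTC")
NOTI <- "GCGGCCGC"
## gap-repair homology blocks: the shared terminus "GGCCGC <M> GC" spans
## the NotI scar remnants of both neighbouring molecules, so complete
## digestion leaves exact suffix-prefix overlaps of length |M| + 8.
hom_open <- function(m) paste0(NOTI, m, "GC")      # downstream molecule
hom_close <- function(m) paste0("GGCCGC", m, NOTI) # upstream molecule

feature_row <- function(label, kind, start, end, strand = "+") {
  data.frame(label = label, kind = kind, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

## assemble a plasmid from labelled pieces; pieces is a list of
## list(seq, label, kind) with kind NA for structural/motif pieces.
build_plasmid <- function(id, pieces, circular = TRUE) {
  feats <- list()
  pos <- 0L
  bases <- character(length(pieces))
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    bases[i] <- p$seq
    if (!is.null(p$kind) && !is.na(p$kind)) {
      feats[[length(feats) + 1L]] <-
        feature_row(p$label, p$kind, pos + 1L, pos + nchar(p$seq))
    }
    pos <- pos + nchar(p$seq)
  }
  seq_record(id, paste(bases, collapse = ""), circular = circular,
             features = do.call(rbind, feats))
}

piece <- function(seq, label = NA, kind = NA) list(seq = seq, label = label,
                                                  kind = kind)

## verify the plasmid carries exactly the intended recognition sites
site_counts_ok <- function(record, expected, enzymes) {
  all(vapply(names(expected), function(nm) {
    nrow(find_sites(record, enzymes[[nm]])) == expected[[nm]]
  }, logical(1)))
}

## rebuild until the stray-site check passes (random fills can create
## recognition sites across piece boundaries)
build_checked <- function(builder, expected, enzymes, max_attempts = 50L) {
  for (i in seq_len(max_attempts)) {
    rec <- builder()
    if (site_counts_ok(rec, expected, enzymes)) return(rec)
  }
  stop("could not build a plasmid free of stray recognition sites")
}

part_kind <- function(type) {
  switch(sub("type", "", sub("[ab]$", "", type)),
         "1" = "connector", "2" = "promoter", "3" = "CDS",
         "4" = "terminator", "5" = "connector", "6" = "marker",
         "7" = "origin", "8" = "backbone")
}

#' Generate the toy kit
#'
#' Builds a complete in-silico toolkit targeting the toy genome: Level-0
#' parts for every type (including 3a/3b subtypes), 9 internal + 9 terminal
#' cassette backbones and the matching 18 spacers (covering 2-10
#' transcriptional units), 10 markerless integration vectors with ~500-bp
#' homology arms and mScarlet dropouts, 10 marker cartridges, and two
#' CRISPR backbones carrying the sfGFP/template/mScarlet 3-part dropout and
#' the tRNA-scaffold PCR template. All payloads are random DNA domesticated
#' against BsaI/BsmBI/BbsI/NotI; reporter CDSs are labelled placeholders.
#'
#' @param config A [fixture_config()].
#' @param genome Output of [generate_toy_genome()]; generated from the same
#'   config when `NULL`.
#' @return A `kit_registry` (with the genome attached as attribute
#'   `"genome"`).
#' @export
generate_toy_kit <- function(config = fixture_config(), genome = NULL) {
  if (is.null(genome)) genome <- generate_toy_genome(config)
  cfg <- config$kit
  enzymes <- load_enzymes()
  with_seed(config$seed + 1L, {
    entries <- list()
    add <- function(e) entries[[length(entries) + 1L]] <<- e

    ## ---- Level-0 parts -------------------------------------------------
    pn <- 0L
    for (type in names(config$part_counts)) {
      sites <- cfg$level1_sites[[type]]
      for (k in seq_len(config$part_counts[[type]])) {
        pn <- pn + 1L
        id <- sprintf("part_%s_%02d", type, k)
        label <- sprintf("%s_%02d", part_kind(type), k)
        plen <- switch(part_kind(type), promoter = 180L, CDS = 420L,
                       terminator = 120L, connector = 60L, marker = 350L,
                       origin = 300L, backbone = 400L)
        rec <- build_checked(function() build_plasmid(id, list(
          piece(clean_dna(250L), "part_backbone", "backbone"),
          piece(bsa_f(sites[1])),
          piece(clean_dna(plen), label, part_kind(type)),
          piece(bsa_r(sites[2])),
          piece(clean_dna(250L), "part_backbone", "backbone")
        )), list(BsaI = 2L, BsmBI = 0L, BbsI = 0L, NotI = 0L), enzymes)
        add(kit_entry(id, rec, type, sites[1], sites[2], "BsaI"))
      }
    }

    ## ---- homology blocks shared by vectors and cassettes ---------------
    J <- cfg$connector_scheme$junctions   # S0..S9
    Tj <- cfg$connector_scheme$terminal
    M <- replicate(10L, homology_block(cfg$homology_block_len))  # M0..M9
    MT <- homology_block(cfg$homology_block_len)

    cassette_like <- function(id, pos, terminal, spacer, category) {
      s_up <- J[pos]
      s_dn <- if (terminal) Tj else J[pos + 1L]
      m_left <- M[pos]
      m_right <- if (terminal) MT else M[pos + 1L]
      builder <- function() build_plasmid(id, c(list(
        piece(clean_dna(350L), "cassette_backbone", "backbone"),
        piece(hom_open(m_left)),
        piece(bsm_f(s_up)),
        piece(clean_dna(30L), sprintf("connector_L_p%d", pos), "connector")),
        if (spacer) {
          list(piece("AACG"),
               piece(clean_dna(120L), paste0("spacer_fill_p", pos),
                     "payload"),
               piece("GCTG"))
        } else {
          list(piece(bsa_r("AACG")),
               piece(clean_dna(220L), "sfGFP_dropout_ecoli", "dropout"),
               piece(bsa_f("GCTG")))
        },
        list(piece(clean_dna(30L),
                   if (terminal) "connector_R_term" else
                     sprintf("connector_R_p%d", pos + 1L), "connector"),
             piece(bsm_r(s_dn)),
             piece(hom_close(m_right)),
             piece(clean_dna(350L), "cassette_backbone", "backbone"))))
      expected <- list(BsaI = if (spacer) 0L else 2L, BsmBI = 2L,
                       BbsI = 0L, NotI = 2L)
      rec <- build_checked(builder, expected, enzymes)
      kit_entry(id, rec, category,
                fus_left = if (spacer) s_up else "GCTG",
                fus_right = if (spacer) s_dn else "AACG",
                level_enzyme = if (spacer) "BsmBI" else "BsaI",
                connector_left = s_up, connector_right = s_dn,
                position = pos, terminal = terminal)
    }

    ## 9 internal (positions 1-9) + 9 terminal (positions 2-10) cassettes,
    ## and the matching 18 spacers
    for (pos in 1:9) add(cassette_like(sprintf("cas_p%d_int", pos), pos,
                                       FALSE, FALSE, "cassette"))
    for (pos in 2:10) add(cassette_like(sprintf("cas_p%d_term", pos), pos,
                                        TRUE, FALSE, "cassette"))
    for (pos in 1:9) add(cassette_like(sprintf("spc_p%d_int", pos), pos,
                                       FALSE, TRUE, "spacer"))
    for (pos in 2:10) add(cassette_like(sprintf("spc_p%d_term", pos), pos,
                                        TRUE, TRUE, "spacer"))

    ## ---- markerless integration vectors --------------------------------
    K <- cfg$marker_sites
    truth <- genome$truth
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      chrom <- genome$records[[tr$chrom]]$bases
      arm5 <- substr(chrom, tr$arm5_start, tr$arm5_end)
      arm3 <- substr(chrom, tr$arm3_start, tr$arm3_end)
      id <- sprintf("int%d_vector", i)
      rec <- build_checked(function() build_plasmid(id, list(
        piece(clean_dna(200L), "vector_backbone", "backbone"),
        piece(bbs_r(K[1])),
        piece(clean_dna(150L), "marker_stuffer", "stuffer"),
        piece(bbs_f(K[2])),
        piece(clean_dna(200L), "ColE1_placeholder", "origin"),
        piece(NOTI),
        piece(arm5, sprintf("arm5_%s", tr$locus), "homology_arm"),
        piece("AT"),
        piece(hom_close(M[1])),
        piece(bsm_r(J[1])),
        piece(clean_dna(250L), "mScarlet_dropout_ecoli_yeast", "dropout"),
        piece(bsm_f(Tj)),
        piece(hom_open(MT)),
        piece(arm3, sprintf("arm3_%s", tr$locus), "homology_arm"),
        piece(NOTI),
        piece(clean_dna(250L), "vector_backbone", "backbone")
      )), list(BsaI = 0L, BsmBI = 2L, BbsI = 2L, NotI = 4L), enzymes)
      add(kit_entry(id, rec, "integration_vector", Tj, J[1], "BsmBI",
                    locus = tr$locus))
    }

    ## ---- marker cartridges --------------------------------------------
    markers <- c("URA3", "LEU2", "HIS3", "TRP1", "LYS2", "MET17",
                 "KanR", "NatR", "HygR", "ZeoR")
    for (mk in markers) {
      id <- sprintf("marker_%s", mk)
      rec <- build_checked(function() build_plasmid(id, list(
        piece(clean_dna(300L), "cartridge_backbone", "backbone"),
        piece(bbs_f(K[1])),
        piece(clean_dna(400L), paste0(mk, "_placeholder"), "marker"),
        piece(bbs_r(K[2])),
        piece(clean_dna(300L), "cartridge_backbone", "backbone")
      )), list(BsaI = 0L, BsmBI = 0L, BbsI = 2L, NotI = 0L), enzymes)
      add(kit_entry(id, rec, "marker_cartridge", K[1], K[2], "BbsI",
                    marker = mk))
    }

    ## ---- CRISPR backbones ----------------------------------------------
    arr <- cfg$array_sites
    for (variant in c("marked", "transient")) {
      id <- paste0("crispr_", variant)
      rec <- build_checked(function() build_plasmid(id, list(
        piece(clean_dna(250L), "crispr_backbone", "backbone"),
        piece(bbs_r(K[1])),
        piece(clean_dna(150L), "marker_stuffer", "stuffer"),
        piece(bbs_f(K[2])),
        piece(clean_dna(600L), "Cas9_placeholder", "CDS"),
        piece(clean_dna(80L), "array_promoter", "promoter"),
        piece(bsa_r(arr$entry)),
        piece(clean_dna(220L), "sfGFP_dropout_ecoli", "dropout"),
        piece(bsa_f(arr$dropout[1])),
        piece(clean_dna(6L)),
        piece(clean_dna(76L), "scaffold_template", "scaffold"),
        piece(clean_dna(71L), "tRNA_template", "tRNA"),
        piece(clean_dna(6L)),
        piece(bsa_r(arr$dropout[2])),
        piece(clean_dna(220L), "mScarlet_dropout_ecoli_yeast", "dropout"),
        piece(bsa_f(arr$exit)),
        piece(clean_dna(60L), "array_terminator", "terminator"),
        piece(NOTI),
        piece(clean_dna(250L), "crispr_backbone", "backbone")
      )), list(BsaI = 4L, BsmBI = 0L, BbsI = 2L, NotI = 1L), enzymes)
      add(kit_entry(id, rec, "crispr_backbone", arr$exit, arr$entry, "BsaI",
                    marker = if (variant == "marked") "stuffer" else "none"))
    }

    reg <- kit_registry(entries, cfg)
    attr(reg, "genome") <- genome
    reg
  })
}

#' Generate the toy genome
#'
#' Builds a small two-chromosome genome with planted genes spaced such that
#' exactly `n_loci` intergenic windows satisfy the integration-locus
#' distance rules (>1 kb from every start codon, >0.5 kb from every stop
#' codon), plus telomere features that blacklist the chromosome ends. Each
#' window's background is PAM-free filler, and one genome-unique
#' protospacer+PAM (cut site at the window centre) is planted per window,
#' so each window contains exactly one CRISPR-addressable site.
#'
#' @param config A [fixture_config()].
#' @return A list with `records` (named list of chromosome `seq_record`s),
#'   `annotation` (GFF3-style data frame), and `truth` (one row per planted
#'   locus: window, protospacer, cut position, homology-arm coordinates).
#' @export
generate_toy_genome <- function(config = fixture_config()) {
  n1 <- min(6L, config$n_loci)
  n2 <- config$n_loci - n1
  with_seed(config$seed, {
    chr1 <- build_toy_chromosome("chr1", n1)
    chr2 <- build_toy_chromosome("chr2", n2)
    truth <- rbind(chr1$truth, chr2$truth)
    if (nrow(truth)) truth$locus <- sprintf("locus%02d", seq_len(nrow(truth)))
    genome <- list(
      records = list(chr1 = chr1$record, chr2 = chr2$record),
      annotation = rbind(chr1$annotation, chr2$annotation),
      truth = truth)
    assert_planted_sites_unique(genome)
    genome
  })
}

build_toy_chromosome <- function(name, n_loci) {
  start_thr <- 1000L; stop_thr <- 500L
  gene_len <- 600L; big_gap <- 1900L; small_gap <- 700L
  pieces <- character(); genes <- list(); pos <- 0L
  emit <- function(s) { pieces[[length(pieces) + 1L]] <<- s; pos <<- pos + nchar(s) }
  gene_at <- function(strand) {
    genes[[length(genes) + 1L]] <<- data.frame(
      start = pos + 1L, end = pos + gene_len, strand = strand,
      stringsAsFactors = FALSE)
    emit(random_dna(gene_len))
  }
  telo_len <- 2000L
  emit(random_dna(telo_len))
  emit(random_dna(150L))
  gene_at("+")
  gap_start <- integer()
  for (i in seq_len(n_loci)) {
    gap_start <- c(gap_start, pos + 1L)
    emit(pam_free_dna(big_gap))
    gene_at("+")
  }
  ## filler genes separated by gaps too small to open a window, including a
  ## minus-strand gene to exercise strand-aware codon arithmetic
  emit(random_dna(small_gap))
  gene_at("-")
  emit(random_dna(small_gap))
  gene_at("+")
  emit(random_dna(150L))
  telo2_start <- pos + 1L
  emit(random_dna(telo_len))
  bases <- paste(pieces, collapse = "")
  n <- nchar(bases)
  genes <- do.call(rbind, genes)
  blacklist <- data.frame(start = c(1L, telo2_start), end = c(telo_len, n))

  ## exact per-base rule determines the planted windows
  mask <- locus_mask_bruteforce(n, genes, blacklist, start_thr, stop_thr)
  wins <- mask_to_windows(mask)
  if (nrow(wins) != n_loci) {
    stop("toy chromosome construction yielded ", nrow(wins),
         " windows instead of ", n_loci)
  }

  truth <- NULL
  if (n_loci > 0L) {
    truth <- lapply(seq_len(n_loci), function(i) {
      centre <- as.integer(floor((wins$start[i] + wins$end[i]) / 2))
      spacer <- protospacer_dna(20L)
      p <- centre - 16L
      substr(bases, p, p + 19L) <<- spacer
      substr(bases, p + 20L, p + 22L) <<- "TGG"
      data.frame(chrom = name, window_start = wins$start[i],
                 window_end = wins$end[i], spacer = spacer, pam = "TGG",
                 spacer_start = p, strand = "+", cut_pos = centre,
                 arm5_start = centre - 499L, arm5_end = centre,
                 arm3_start = centre + 1L, arm3_end = centre + 500L,
                 stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, truth)
  }
  ann <- rbind(
    do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      data.frame(chrom = name, kind = c("gene", "CDS"),
                 start = genes$start[i], end = genes$end[i],
                 strand = genes$strand[i],
                 id = sprintf("%s_g%02d%s", name, i, c("", "_cds")),
                 stringsAsFactors = FALSE)
    })),
    data.frame(chrom = name, kind = "telomere",
               start = blacklist$start, end = blacklist$end, strand = "+",
               id = sprintf("%s_tel%d", name, seq_len(nrow(blacklist))),
               stringsAsFactors = FALSE))
  list(record = seq_record(name, bases), annotation = ann,
       truth = if (is.null(truth))
         data.frame() else truth)
}

## 20-mers free of GG/CC (no internal PAM ambiguity) and of enzyme motifs
protospacer_dna <- function(n) {
  repeat {
    s <- random_dna(n)
    if (!grepl("GG|CC", s) &&
        !any(vapply(enzyme_motifs(), grepl, logical(1), x = s,
                    fixed = TRUE))) {
      return(s)
    }
  }
}

## independent per-base implementation of the locus distance rules; also
## the construction oracle for the generator
locus_mask_bruteforce <- function(n, genes, blacklist,
                                  start_threshold, stop_threshold) {
  mask <- rep(TRUE, n)
  for (i in seq_len(nrow(genes))) {
    plus <- genes$strand[i] == "+"
    start_pos <- if (plus) genes$start[i] else genes$end[i]
    stop_pos <- if (plus) genes$end[i] - 2L else genes$start[i] + 2L
    mask[max(1L, start_pos - start_threshold):
           min(n, start_pos + start_threshold)] <- FALSE
    mask[max(1L, stop_pos - stop_threshold):
           min(n, stop_pos + stop_threshold)] <- FALSE
  }
  for (i in seq_len(nrow(blacklist))) {
    mask[blacklist$start[i]:blacklist$end[i]] <- FALSE
  }
  mask
}

mask_to_windows <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

count_genome_occurrences <- function(genome, pattern) {
  sum(vapply(genome$records, function(rec) {
    Biostrings::countPattern(pattern, Biostrings::DNAString(rec$bases)) +
      Biostrings::countPattern(revcomp(pattern),
                               Biostrings::DNAString(rec$bases))
  }, numeric(1)))
}

assert_planted_sites_unique <- function(genome) {
  tr <- genome$truth
  for (i in seq_len(nrow(tr))) {
    k23 <- paste0(tr$spacer[i], tr$pam[i])
    if (count_genome_occurrences(genome, k23) != 1L) {
      stop("planted protospacer ", tr$locus[i], " is not genome-unique")
    }
  }
  invisible(TRUE)
}

#' Generate all fixtures and (optionally) write them to disk
#'
#' @param seed Integer seed.
#' @param dir Output directory; when given, the kit (GenBank + manifest),
#'   genome FASTA, GFF3 annotation and truth TSV are written there.
#' @param config Optional full [fixture_config()] (overrides `seed`).
#' @return Invisibly, a list with `registry` and `genome`.
#' @export
make_fixtures <- function(seed = 17L, dir = NULL, config = NULL) {
  if (is.null(config)) config <- fixture_config(seed = seed)
  genome <- generate_toy_genome(config)
  registry <- generate_toy_kit(config, genome)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_kit(registry, file.path(dir, "kit"))
    write_fasta_records(genome$records, file.path(dir, "genome.fa"))
    write_gff3(genome$annotation, file.path(dir, "genome.gff3"))
    utils::write.table(genome$truth, file.path(dir, "truth_loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(registry = registry, genome = genome))
}
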
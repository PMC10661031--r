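#' Scan a genome for candidate integration windows
#'
#' Reports the maximal intervals in which *every* position lies more than
#' `start_threshold` bp from the start codon and more than `stop_threshold`
#' bp from the stop codon of every annotated gene, and overlaps no
#' blacklisted feature. Start/stop codons are derived strand-aware from the
#' CDS bounds: on the plus strand the start codon begins at the CDS start
#' and the stop codon at `end - 2`; on the minus strand they begin at the
#' CDS end and `start + 2`. Distances are measured to the codon's first
#' base.
#'
#' @param genome Named list of `seq_record`s (or a FASTA path).
#' @param annotation Annotation data frame as from [read_gff3()] (or a GFF3
#'   path).
#' @param start_threshold,stop_threshold Minimum distances in bp (defaults
#'   1000 and 500).
#' @param blacklist_kinds Feature kinds that exclude a window (default:
#'   structural/repetitive elements typically present in a GFF3).
#' @return Data frame of windows (`chrom`, `start`, `end`, 1-based
#'   inclusive), sorted by chromosome then start.
#' @export
scan_intergenic <- function(genome, annotation,
                            start_threshold = 1000L, stop_threshold = 500L,
                            blacklist_kinds = c("tRNA", "rRNA", "ARS",
                                                "LTR", "telomere")) {
  if (is.character(genome)) genome <- named_genome(read_fasta_records(genome))
  if (is.character(annotation)) annotation <- read_gff3(annotation)
  out <- list()
  for (chrom in names(genome)) {
    n <- nchar(genome[[chrom]]$bases)
    ann <- annotation[annotation$chrom == chrom, , drop = FALSE]
    cds <- ann[ann$kind %in% c("CDS", "gene"), , drop = FALSE]
    ## prefer CDS rows where a gene has both
    if (any(cds$kind == "CDS")) cds <- cds[cds$kind == "CDS", , drop = FALSE]
    nostrand <- !cds$strand %in% c("+", "-")
    if (any(nostrand)) {
      warning(sum(nostrand), " gene(s) without strand on ", chrom,
              "; skipped")
      cds <- cds[!nostrand, , drop = FALSE]
    }
    forb <- list()
    for (i in seq_len(nrow(cds))) {
      plus <- cds$strand[i] == "+"
      start_pos <- if (plus) cds$start[i] else cds$end[i]
      stop_pos <- if (plus) cds$end[i] - 2L else cds$start[i] + 2L
      forb[[length(forb) + 1L]] <- IRanges::IRanges(
        start = pmax(1L, c(start_pos - start_threshold,
                           stop_pos - stop_threshold)),
        end = pmin(n, c(start_pos + start_threshold,
                        stop_pos + stop_threshold)))
    }
    bl <- ann[ann$kind %in% blacklist_kinds, , drop = FALSE]
    if (nrow(bl)) {
      forb[[length(forb) + 1L]] <- IRanges::IRanges(start = bl$start,
                                                    end = bl$end)
    }
    forb <- if (length(forb)) {
      IRanges::reduce(do.call(c, forb))
    } else IRanges::IRanges()
    allowed <- IRanges::setdiff(IRanges::IRanges(1L, n), forb)
    if (length(allowed)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = BiocGenerics::start(allowed),
        end = BiocGenerics::end(allowed), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer())
  out[order(out$chrom, out$start), , drop = FALSE]
}

named_genome <- function(records) {
  if (inherits(records, "seq_record")) records <- list(records)
  names(records) <- vapply(records, `[[`, character(1), "id")
  records
}

#' Enumerate CRISPR-addressable sites in a window
#'
#' Lists every 20-mer followed immediately by an NGG PAM (on either strand)
#' that lies fully inside the window, keeps only protospacer+PAM 23-mers
#' that occur exactly once genome-wide (counting both strands), and ranks
#' the survivors by the distance of their predicted cut site (between
#' positions 17 and 18 of the protospacer, 3 bp from the PAM) from the
#' window centre.
#'
#' @param window One row of [scan_intergenic()] output (or a list with
#'   `chrom`, `start`, `end`).
#' @param genome Named list of `seq_record`s.
#' @return Data frame of candidates: `spacer`, `pam`, `strand`, `start`
#'   (top-strand start of the 23-mer), `cut_pos`, `dist_centre`.
#' @export
pick_target_site <- function(window, genome) {
  genome <- named_genome(genome)
  chrom <- genome[[window$chrom]]
  ws <- window$start; we <- window$end
  if (we - ws + 1L < 23L) return(empty_candidates())
  seq <- substr(chrom$bases, ws, we)
  n <- nchar(seq)
  centre <- (ws + we) / 2
  cand <- list()
  for (i in seq_len(n - 22L)) {
    k23 <- substr(seq, i, i + 22L)
    if (substr(k23, 22L, 23L) == "GG") {
      cand[[length(cand) + 1L]] <- data.frame(
        spacer = substr(k23, 1L, 20L), pam = substr(k23, 21L, 23L),
        strand = "+", start = ws + i - 1L, k23 = k23,
        cut_pos = ws + i - 1L + 16L, stringsAsFactors = FALSE)
    }
    if (substr(k23, 1L, 2L) == "CC") {
      rc <- revcomp(k23)
      cand[[length(cand) + 1L]] <- data.frame(
        spacer = substr(rc, 1L, 20L), pam = substr(rc, 21L, 23L),
        strand = "-", start = ws + i - 1L, k23 = k23,
        cut_pos = ws + i - 1L + 5L, stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) return(empty_candidates())
  cand <- do.call(rbind, cand)
  unique_hit <- vapply(cand$k23, function(k) {
    count_genome_occurrences(list(records = genome), k) == 1L
  }, logical(1))
  cand <- cand[unique_hit, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_candidates())
  cand$dist_centre <- abs(cand$cut_pos - centre)
  cand <- cand[order(cand$dist_centre, cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  cand[, c("spacer", "pam", "strand", "start", "cut_pos", "dist_centre")]
}

empty_candidates <- function() {
  data.frame(spacer = character(), pam = character(), strand = character(),
             start = integer(), cut_pos = integer(),
             dist_centre = numeric(), stringsAsFactors = FALSE)
}

#' Extract homology arms around a cut position
#'
#' Returns the `arm_length` bases immediately upstream and downstream of
#' the cut (the cut position is the last base of the 5' side). Each arm is
#' checked for genome uniqueness by exact search; a non-unique arm gives a
#' warning.
#'
#' @param genome Named list of `seq_record`s.
#' @param chrom Chromosome id.
#' @param cut_position 1-based position of the last base 5' of the cut.
#' @param arm_length Arm length in bp (default 500, the kit's design).
#' @return List with `arm5`, `arm3` (sequences) and their coordinates.
#' @export
extract_homology_arms <- function(genome, chrom, cut_position,
                                  arm_length = 500L) {
  genome <- named_genome(genome)
  rec <- genome[[chrom]]
  if (is.null(rec)) stop("unknown chromosome ", chrom)
  n <- nchar(rec$bases)
  if (cut_position < arm_length || cut_position + arm_length > n) {
    stop("insufficient flank: cut at ", cut_position, " needs ",
         arm_length, " bp on both sides")
  }
  arm5 <- substr(rec$bases, cut_position - arm_length + 1L, cut_position)
  arm3 <- substr(rec$bases, cut_position + 1L, cut_position + arm_length)
  for (arm in c(arm5, arm3)) {
    if (count_genome_occurrences(list(records = genome), arm) != 1L) {
      warning("homology arm at ", chrom, ":", cut_position,
              " is not genome-unique")
    }
  }
  list(arm5 = arm5, arm3 = arm3,
       arm5_start = cut_position - arm_length + 1L, arm5_end = cut_position,
       arm3_start = cut_position + 1L, arm3_end = cut_position + arm_length)
}

#' Longest repeat shared between sequences
#'
#' Maximum over all sequence pairs of the longest common substring,
#' considering both orientations (a block present as the reverse complement
#' counts). Used to screen promoter/part sets against recombination-prone
#' repeats; the kit's design rule is that promoters share no more than 24
#' bp.
#'
#' @param sequences Character vector (length >= 2) of DNA sequences.
#' @return List with `length`, `pair` (indices), `substring`, and
#'   `orientation` (`"forward"` or `"revcomp"`).
#' @export
longest_shared_repeat <- function(sequences) {
  stopifnot(length(sequences) >= 2L)
  best <- list(length = 0L, pair = c(NA_integer_, NA_integer_),
               substring = "", orientation = "forward")
  for (i in seq_len(length(sequences) - 1L)) {
    for (j in (i + 1L):length(sequences)) {
      for (orient in c("forward", "revcomp")) {
        b <- if (orient == "forward") sequences[j] else revcomp(sequences[j])
        hit <- lcs_substring(sequences[i], b)
        if (hit$length > best$length) {
          best <- list(length = hit$length, pair = c(i, j),
                       substring = hit$substring, orientation = orient)
        }
      }
    }
  }
  best
}

## dynamic-programming longest common substring (rows vectorised over b)
lcs_substring <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(bv)
  prev <- integer(m)
  best <- 0L; best_end <- 0L
  for (i in seq_along(av)) {
    shifted <- c(0L, prev[-m])
    cur <- integer(m)
    hit <- bv == av[i]
    cur[hit] <- shifted[hit] + 1L
    mx <- max(cur)
    if (mx > best) { best <- mx; best_end <- which.max(cur) }
    prev <- cur
  }
  list(length = best,
       substring = if (best > 0L)
         substr(b, best_end - best + 1L, best_end) else "")
}

#' Design integration-locus candidates
#'
#' The full locus-design pipeline: scan intergenic windows, pick the
#' highest-ranked genome-unique protospacer per window, extract homology
#' arms around its cut site, and (when several genomes are supplied)
#' restrict to candidates whose protospacer and both arms match exactly in
#' every genome — a conservative stand-in for cross-strain conservation.
#'
#' @param genomes A named list of `seq_record`s, or a list of such genomes
#'   (first = reference).
#' @param annotation Annotation of the reference genome.
#' @param arm_length Homology-arm length.
#' @param ... Passed to [scan_intergenic()].
#' @return Data frame of locus candidates (windows without a usable
#'   protospacer or with insufficient flanks are dropped).
#' @export
design_integration_loci <- function(genomes, annotation, arm_length = 500L,
                                    ...) {
  multi <- is.list(genomes) && !inherits(genomes[[1]], "seq_record")
  ref <- if (multi) named_genome(genomes[[1]]) else named_genome(genomes)
  others <- if (multi) lapply(genomes[-1], named_genome) else list()
  windows <- scan_intergenic(ref, annotation, ...)
  out <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    sites <- pick_target_site(w, ref)
    if (nrow(sites) == 0L) next
    site <- sites[1, ]
    arms <- tryCatch(
      extract_homology_arms(ref, w$chrom, site$cut_pos, arm_length),
      error = function(e) NULL)
    if (is.null(arms)) next
    k23 <- paste0(site$spacer, site$pam)
    if (site$strand == "-") k23 <- revcomp(k23)
    conserved <- all(vapply(others, function(g) {
      all(vapply(c(k23, arms$arm5, arms$arm3), function(s) {
        count_genome_occurrences(list(records = g), s) >= 1L
      }, logical(1)))
    }, logical(1)))
    if (!conserved) next
    out[[length(out) + 1L]] <- cbind(
      data.frame(chrom = w$chrom, window_start = w$start,
                 window_end = w$end, stringsAsFactors = FALSE),
      site,
      data.frame(arm5_start = arms$arm5_start, arm5_end = arms$arm5_end,
                 arm3_start = arms$arm3_start, arm3_end = arms$arm3_end,
                 arm5 = arms$arm5, arm3 = arms$arm3,
                 stringsAsFactors = FALSE))
  }
  if (length(out)) do.call(rbind, out) else data.frame()
}
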
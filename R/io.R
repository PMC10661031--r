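#' Read a GenBank flat file
#'
#' A compact reader for the subset of GenBank needed for plasmid and kit
#' records: LOCUS topology, feature keys with `/label` and `/note`
#' qualifiers, and simple locations (`a..b`, `complement(a..b)`, and
#' two-part `join(a..len,1..b)` origin-wrapping locations on circular
#' records). The package-internal feature `kind` is stored in a
#' `/note="moclosim_kind=..."` qualifier so records round-trip exactly.
#'
#' @param path Path to a `.gb` file containing one record.
#' @return A `seq_record`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("no LOCUS line in ", path)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  circular <- any(tolower(toks) == "circular")
  if (!circular && !any(tolower(toks) == "linear")) {
    warning("no topology on LOCUS line of ", path, "; assuming linear")
  }
  ## sequence
  o <- grep("^ORIGIN", lines)
  seq_lines <- if (length(o)) {
    end <- grep("^//", lines)
    end <- end[end > o[1]][1]
    if (is.na(end)) end <- length(lines) + 1L
    lines[(o[1] + 1L):(end - 1L)]
  } else character()
  bases <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  ## features
  fstart <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(fstart)) {
    fend <- if (length(o)) o[1] - 1L else length(lines)
    flines <- lines[(fstart[1] + 1L):fend]
    feats <- parse_genbank_features(flines)
  }
  seq_record(id, bases, circular = circular, features = feats)
}

parse_genbank_features <- function(flines) {
  recs <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) recs[[length(recs) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in flines) {
    if (grepl("^ {5}\\S", ln)) {
      flush()
      key <- trimws(substr(ln, 1, 20))
      loc <- trimws(substr(ln, 21, nchar(ln)))
      cur <- list(key = key, loc = loc, quals = character())
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {
        cur$quals <- c(cur$quals, txt)
      } else if (length(cur$quals)) {
        cur$quals[length(cur$quals)] <-
          paste0(cur$quals[length(cur$quals)], txt)
      } else {
        cur$loc <- paste0(cur$loc, txt)
      }
    }
  }
  flush()
  rows <- lapply(recs, function(r) {
    loc <- gsub("[<>]", "", r$loc)
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("^join\\(", loc)) {
      inner <- sub("^join\\((.*)\\)$", "\\1", loc)
      parts <- strsplit(inner, ",")[[1]]
      if (length(parts) != 2L) {
        warning("unsupported join location '", r$loc, "'; skipped")
        return(NULL)
      }
      p1 <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
      p2 <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
      start <- p1[1]; end <- p2[2]
    } else {
      p <- strsplit(loc, "\\.\\.")[[1]]
      start <- as.integer(p[1])
      end <- if (length(p) > 1L) as.integer(p[2]) else start
    }
    label <- qual_value(r$quals, "label")
    if (is.na(label)) label <- qual_value(r$quals, "gene")
    if (is.na(label)) label <- r$key
    note <- qual_value(r$quals, "note")
    kind <- if (!is.na(note) && grepl("moclosim_kind=", note)) {
      sub(".*moclosim_kind=([^; ]+).*", "\\1", note)
    } else r$key
    data.frame(label = label, kind = kind, start = start, end = end,
               strand = strand, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) empty_features() else rows
}

qual_value <- function(quals, name) {
  hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1]))
}

#' Write a record as a GenBank flat file
#'
#' @param record A `seq_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  n <- nchar(record$bases)
  topo <- if (record$circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %-8s UNA 01-JAN-2026",
                   record$id, n, topo),
           sprintf("DEFINITION  %s", record$id),
           "FEATURES             Location/Qualifiers")
  keys <- c(CDS = "CDS", gene = "gene", promoter = "promoter",
            terminator = "terminator", tRNA = "tRNA", telomere = "telomere")
  for (i in seq_len(nrow(record$features))) {
    f <- record$features[i, ]
    key <- if (f$kind %in% names(keys)) keys[[f$kind]] else "misc_feature"
    loc <- if (f$start <= f$end) {
      sprintf("%d..%d", f$start, f$end)
    } else {
      sprintf("join(%d..%d,1..%d)", f$start, n, f$end)
    }
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     %-16s%s", key, loc),
             sprintf("                     /label=\"%s\"", f$label),
             sprintf("                     /note=\"moclosim_kind=%s\"", f$kind))
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(record$bases, p, min(p + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read records from FASTA
#'
#' The topology is taken from the word `circular` or `linear` in the
#' description line; absent, linear is assumed.
#'
#' @param path FASTA file.
#' @return List of `seq_record`.
#' @export
read_fasta_records <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    toks <- strsplit(header, "\\s+")[[1]]
    seq_record(toks[1], as.character(set[[i]]),
               circular = any(tolower(toks) == "circular"))
  })
}

#' Write records to FASTA
#'
#' @param records List of `seq_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_records <- function(records, path) {
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1), "bases"))
  names(seqs) <- vapply(records, function(r) {
    paste(r$id, if (r$circular) "circular" else "linear")
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' @param path GFF3 file.
#' @return Data frame with columns `chrom`, `kind`, `start`, `end`,
#'   `strand`, `id` (1-based inclusive coordinates).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  ids <- if ("ID" %in% names(df)) as.character(df$ID) else
    as.character(seq_len(nrow(df)))
  ids[is.na(ids)] <- paste0("feat", which(is.na(ids)))
  data.frame(chrom = as.character(df$seqnames), kind = as.character(df$type),
             start = df$start, end = df$end,
             strand = as.character(df$strand), id = ids,
             stringsAsFactors = FALSE)
}

#' Write gene annotation as GFF3
#'
#' @param ann Data frame as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand, type = ann$kind, ID = ann$id,
    phase = ifelse(ann$kind == "CDS", 0L, NA_integer_))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write genomic windows as BED
#'
#' @param windows Data frame with `chrom`, `start`, `end` (1-based,
#'   inclusive); converted to BED's 0-based half-open convention.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(windows, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$start, end = windows$end))
  if (!is.null(windows$name)) names(gr) <- windows$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
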
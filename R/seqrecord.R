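#' Annotated DNA sequence records
#'
#' `seq_record()` is the basic container used throughout the package: a
#' single DNA molecule (linear or circular) with a feature table. All
#' coordinates are 1-based and inclusive, the convention used by GenBank and
#' the Bioconductor ranges infrastructure. Features on circular records may
#' wrap the origin, in which case `start > end` and the feature runs
#' `start..length` then `1..end`.
#'
#' @param id Record identifier (single string).
#' @param bases DNA sequence over `A/C/G/T/N`; lower case is accepted and
#'   normalised to upper case.
#' @param circular Logical; `TRUE` for a circular molecule.
#' @param features A data frame with columns `label`, `kind`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`), or `NULL` for none.
#' @return An object of class `seq_record`.
#' @examples
#' rec <- seq_record("demo", "ATGCATGC", circular = TRUE)
#' length(rec)
#' @export
seq_record <- function(id, bases, circular = FALSE, features = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  bases <- toupper(as.character(bases))
  if (!grepl("^[ACGTN]*$", bases)) {
    stop("record '", id, "' contains characters outside A/C/G/T/N")
  }
  features <- normalize_features(features, nchar(bases), circular)
  structure(
    list(id = id, bases = bases, circular = isTRUE(circular),
         features = features),
    class = "seq_record"
  )
}

empty_features <- function() {
  data.frame(label = character(), kind = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

normalize_features <- function(features, len, circular) {
  if (is.null(features) || nrow(as.data.frame(features)) == 0L) {
    return(empty_features())
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  needed <- c("label", "kind", "start", "end", "strand")
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  features <- features[, needed]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- features$start < 1L | features$end > len | features$start > len |
    features$end < 1L
  if (any(bad)) stop("feature coordinates outside record")
  if (!circular && any(features$start > features$end)) {
    stop("origin-wrapping feature on a linear record")
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-'")
  }
  rownames(features) <- NULL
  features
}

#' @export
length.seq_record <- function(x) nchar(x$bases)

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d bp, %s, %d feature(s)\n",
              x$id, nchar(x$bases),
              if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are supported (the recognition sequences of several
#' enzymes contain them).
#'
#' @param x A character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

## Booth's least-rotation algorithm on a character string; returns the
## 1-based offset of the lexicographically minimal rotation.
least_rotation_offset <- function(s) {
  b <- utf8ToInt(s)
  n <- length(b)
  if (n <= 1L) return(1L)
  b2 <- c(b, b)
  f <- rep.int(-1L, 2L * n)
  k <- 0L
  for (j in 1L:(2L * n - 1L)) {
    sj <- b2[j + 1L]
    i <- f[j - k]
    while (i != -1L && sj != b2[k + i + 2L]) {
      if (sj < b2[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != b2[k + i + 2L]) {
      if (sj < b2[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  k + 1L
}

rotate_string <- function(s, offset) {
  n <- nchar(s)
  if (n == 0L || offset == 1L) return(s)
  paste0(substr(s, offset, n), substr(s, 1L, offset - 1L))
}

#' Canonical form of a circular sequence
#'
#' Circular molecules have no distinguished origin and no distinguished
#' strand, so two assemblies are the same product when one is a rotation
#' and/or reverse complement of the other. The canonical form is the
#' lexicographically minimal rotation over both strands; it is used for
#' product deduplication and biological-equality testing.
#'
#' @param bases DNA string of the circular molecule (single string).
#' @return The canonical rotation as a string.
#' @export
canonical_rotation <- function(bases) {
  if (!nzchar(bases)) return(bases)
  fwd <- rotate_string(bases, least_rotation_offset(bases))
  rcs <- revcomp(bases)
  rev <- rotate_string(rcs, least_rotation_offset(rcs))
  if (fwd <= rev) fwd else rev
}

#' Biological equality of two records
#'
#' Linear records are equal when id-independent sequence and topology match;
#' circular records are compared by canonical rotation (rotation- and
#' strand-invariant).
#'
#' @param a,b `seq_record` objects.
#' @return Logical scalar.
#' @export
records_equivalent <- function(a, b) {
  if (a$circular != b$circular) return(FALSE)
  if (!a$circular) {
    return(a$bases == b$bases || a$bases == revcomp(b$bases))
  }
  canonical_rotation(a$bases) == canonical_rotation(b$bases)
}

## substring of a possibly-circular sequence using 0-based gap coordinates
## [from, to); `to` may exceed the length for wrap-around on circular records.
span_bases <- function(bases, from0, to0, circular) {
  n <- nchar(bases)
  if (to0 < from0) stop("invalid span")
  if (to0 <= n) return(substr(bases, from0 + 1L, to0))
  if (!circular) stop("span beyond end of linear record")
  paste0(substr(bases, from0 + 1L, n), substr(bases, 1L, to0 - n))
}
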
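#' Restriction enzyme definitions
#'
#' An enzyme is described by its recognition sequence (IUPAC codes allowed)
#' and two cut offsets. For Type IIS enzymes the offsets are measured from
#' the 3' end of the recognition site on the recognition strand, the REBASE
#' "N(1/5)" convention: BsaI is `GGTCTC(1/5)`, i.e. the top strand is cut 1
#' nt downstream of the site and the bottom strand 5 nt downstream, leaving
#' a 4-nt 5' overhang. For within-site cutters (`type_iis = FALSE`, e.g.
#' NotI `GC^GGCCGC`) the offsets are measured from the 5' start of the
#' recognition site.
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (IUPAC string, length >= 4).
#' @param cut_top,cut_bottom Cut offsets (see Details).
#' @param type_iis Logical; `TRUE` for outside-cutters.
#' @return An object of class `gg_enzyme`.
#' @export
enzyme <- function(name, recognition, cut_top, cut_bottom, type_iis = TRUE) {
  recognition <- toupper(recognition)
  stopifnot(nchar(recognition) >= 4L)
  if (abs(cut_top - cut_bottom) > 8L) {
    stop("overhang longer than 8 nt is not supported")
  }
  structure(
    list(name = name, recognition = recognition,
         cut_top = as.integer(cut_top), cut_bottom = as.integer(cut_bottom),
         type_iis = isTRUE(type_iis)),
    class = "gg_enzyme"
  )
}

#' @export
print.gg_enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s %s(%d/%d)%s\n", x$name, x$recognition,
              x$cut_top, x$cut_bottom,
              if (x$type_iis) "" else " [within-site]"))
  invisible(x)
}

#' Load enzyme definitions from a YAML config
#'
#' The package ships REBASE geometries for BsaI, BsmBI, BbsI and NotI in
#' `system.file("extdata", "enzymes.yaml", package = "moclosim")`; that file
#' is the default.
#'
#' @param path Path to a YAML file with an `enzymes` list.
#' @return Named list of `gg_enzyme` objects.
#' @export
load_enzymes <- function(path = system.file("extdata", "enzymes.yaml",
                                            package = "moclosim")) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg$enzymes, function(e) {
    enzyme(e$name, e$recognition, e$cut_top, e$cut_bottom,
           isTRUE(e$type_iis))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

is_palindromic <- function(pattern) {
  pattern == revcomp(pattern)
}

#' Find recognition sites of an enzyme
#'
#' Scans both strands of a record for the enzyme's recognition pattern
#' (IUPAC-aware; `N` in the *subject* never matches a recognition base).
#' Circular records are scanned across the origin. For palindromic
#' recognition sequences each physical site is reported once, on the plus
#' strand.
#'
#' @param record A `seq_record`.
#' @param enz A `gg_enzyme`.
#' @return A data frame with columns `position` (1-based start of the
#'   recognition sequence on the top strand; for minus-strand sites the
#'   start of the reverse-complemented pattern occurrence) and `strand`,
#'   ordered by ascending position with `+` before `-`.
#' @export
find_sites <- function(record, enz) {
  stopifnot(inherits(record, "seq_record"), inherits(enz, "gg_enzyme"))
  n <- nchar(record$bases)
  pat <- enz$recognition
  plen <- nchar(pat)
  subject <- record$bases
  if (record$circular && n >= plen) {
    subject <- paste0(subject, substr(record$bases, 1L, plen - 1L))
  }
  hits_fwd <- iupac_match_starts(pat, subject)
  strands <- rep("+", length(hits_fwd))
  pos <- hits_fwd
  if (!is_palindromic(pat)) {
    hits_rev <- iupac_match_starts(revcomp(pat), subject)
    pos <- c(pos, hits_rev)
    strands <- c(strands, rep("-", length(hits_rev)))
  }
  keep <- pos <= n
  pos <- pos[keep]; strands <- strands[keep]
  ord <- order(pos, strands)
  data.frame(position = as.integer(pos[ord]), strand = strands[ord],
             stringsAsFactors = FALSE)
}

## start positions (1-based) of IUPAC pattern matches on the given strand;
## N in the subject is masked so it never satisfies a recognition base.
iupac_match_starts <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer())
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject),
                                fixed = FALSE)
  starts <- BiocGenerics::start(m)
  if (length(starts) && grepl("N", subject, fixed = TRUE)) {
    keep <- vapply(starts, function(s) {
      !grepl("N", substr(subject, s, s + nchar(pattern) - 1L), fixed = TRUE)
    }, logical(1))
    starts <- starts[keep]
  }
  starts
}
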
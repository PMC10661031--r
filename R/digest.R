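#' Fragments with normalized fusion sites
#'
#' A fragment is the double-stranded product of a digestion (or a designed
#' linear piece). Its `bases` are the top strand written 5'->3', running
#' from the fragment's first top-strand cut to the bottom-strand cut of the
#' next junction; a 4-nt 5' overhang therefore appears both at the *end* of
#' the upstream fragment's bases and at the *start* of the downstream
#' fragment's bases. Fusion sites are stored as the top-strand sequence the
#' junction will have after ligation, so two ends are joinable iff the
#' upstream fragment's `right` fusion string equals the downstream
#' fragment's `left` fusion string.
#'
#' @param bases Top-strand sequence.
#' @param left,right End descriptors: `list(kind, seq)` where `kind` is one
#'   of `"blunt"`, `"fusion"`, `"homology"`.
#' @param source,source_start Provenance: source record id and 1-based start
#'   of the fragment in that record.
#' @param features Feature table in fragment-local coordinates.
#' @param circular `TRUE` only for an uncut circular record passed through.
#' @param internal_sites Number of recognition sites of the digesting enzyme
#'   left inside the fragment.
#' @return An object of class `gg_fragment`.
#' @export
gg_fragment <- function(bases, left = frag_end("blunt"),
                        right = frag_end("blunt"),
                        source = NA_character_, source_start = NA_integer_,
                        features = NULL, circular = FALSE,
                        internal_sites = 0L) {
  structure(
    list(bases = bases, left = left, right = right,
         source = source, source_start = as.integer(source_start),
         features = if (is.null(features)) empty_features() else features,
         circular = isTRUE(circular),
         internal_sites = as.integer(internal_sites)),
    class = "gg_fragment"
  )
}

#' @rdname gg_fragment
#' @param kind End kind.
#' @param seq Fusion site (4 nt) or homology terminus sequence.
#' @export
frag_end <- function(kind = c("blunt", "fusion", "homology"), seq = "") {
  kind <- match.arg(kind)
  if (kind == "fusion" && nchar(seq) != 4L) {
    stop("fusion sites must be exactly 4 nt, got '", seq, "'")
  }
  list(kind = kind, seq = toupper(seq))
}

#' @export
print.gg_fragment <- function(x, ...) {
  fmt <- function(e) if (e$kind == "blunt") "blunt" else
    sprintf("%s(%s)", e$kind, if (nchar(e$seq) > 12)
      paste0(substr(e$seq, 1, 10), "..") else e$seq)
  cat(sprintf("<fragment> %d bp [%s | %s] from %s:%s%s\n",
              nchar(x$bases), fmt(x$left), fmt(x$right),
              x$source, x$source_start,
              if (x$internal_sites > 0)
                sprintf(" (%d internal site(s))", x$internal_sites) else ""))
  invisible(x)
}

## 0-based (top, bottom) cut coordinates implied by one recognition site.
cut_pair <- function(enz, pos1, strand, plen) {
  q0 <- pos1 - 1L
  if (!enz$type_iis) {
    c(q0 + enz$cut_top, q0 + enz$cut_bottom)
  } else if (strand == "+") {
    c(q0 + plen + enz$cut_top, q0 + plen + enz$cut_bottom)
  } else {
    c(q0 - enz$cut_bottom, q0 - enz$cut_top)
  }
}

count_internal_sites <- function(bases, enz) {
  length(iupac_match_starts(enz$recognition, bases)) +
    if (is_palindromic(enz$recognition)) 0L else
      length(iupac_match_starts(revcomp(enz$recognition), bases))
}

## transfer record features fully contained in the 0-based span
## [from0, from0 + flen) (circular spans wrap modulo n).
clip_features <- function(features, from0, flen, n, circular) {
  if (nrow(features) == 0L) return(empty_features())
  out <- lapply(seq_len(nrow(features)), function(i) {
    fs <- features$start[i]; fe <- features$end[i]
    wrap <- fe < fs
    feat_len <- if (wrap) n - fs + 1L + fe else fe - fs + 1L
    off <- fs - 1L - from0
    if (circular) off <- ((off %% n) + n) %% n
    if (off < 0L || off + feat_len > flen) return(NULL)
    data.frame(label = features$label[i], kind = features$kind[i],
               start = off + 1L, end = off + feat_len,
               strand = features$strand[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_features() else out
}

#' Digest a record with a restriction enzyme
#'
#' Complete digestion is assumed: every mappable site is cut. A linear
#' record with n internal cuts yields n+1 fragments; a circular record with
#' n >= 1 cuts yields n fragments; a record with no sites is returned
#' unchanged as a single uncut fragment. Cut positions of Type IIS sites
#' that fall outside a linear record are skipped with a warning.
#'
#' @param record A `seq_record`.
#' @param enz A `gg_enzyme`.
#' @return List of `gg_fragment` objects.
#' @examples
#' bsai <- load_enzymes()[["BsaI"]]
#' frags <- digest(seq_record("x", "TTTGGTCTCTAACGCCCGGG"), bsai)
#' frags[[2]]$bases  # "AACGCCCGGG", left fusion AACG
#' @export
digest <- function(record, enz) {
  stopifnot(inherits(record, "seq_record"), inherits(enz, "gg_enzyme"))
  n <- nchar(record$bases)
  sites <- find_sites(record, enz)
  plen <- nchar(enz$recognition)
  cuts <- NULL
  if (nrow(sites) > 0L) {
    cuts <- t(vapply(seq_len(nrow(sites)), function(i) {
      cut_pair(enz, sites$position[i], sites$strand[i], plen)
    }, numeric(2)))
    if (record$circular) {
      ovh <- cuts[, 2] - cuts[, 1]
      tmod <- ((cuts[, 1] %% n) + n) %% n
      cuts <- cbind(tmod, tmod + ovh)
    } else {
      bad <- cuts[, 1] < 0 | cuts[, 2] > n
      if (any(bad)) {
        warning(sum(bad), " ", enz$name,
                " site(s) cut outside the linear record; skipped")
        cuts <- cuts[!bad, , drop = FALSE]
      }
    }
    cuts <- unique(cuts)
    cuts <- cuts[order(cuts[, 1]), , drop = FALSE]
  }
  if (is.null(cuts) || nrow(cuts) == 0L) {
    return(list(gg_fragment(
      record$bases, frag_end("blunt"), frag_end("blunt"),
      source = record$id, source_start = 1L,
      features = record$features, circular = record$circular,
      internal_sites = 0L
    )))
  }
  k <- nrow(cuts)
  frags <- vector("list", if (record$circular) k else k + 1L)
  if (!record$circular) {
    for (j in seq_len(k + 1L)) {
      from0 <- if (j == 1L) 0L else as.integer(cuts[j - 1L, 1])
      to0 <- if (j == k + 1L) n else as.integer(cuts[j, 2])
      bases <- span_bases(record$bases, from0, to0, FALSE)
      left <- if (j == 1L) frag_end("blunt") else
        fusion_end(record$bases, cuts[j - 1L, ], n, FALSE)
      right <- if (j == k + 1L) frag_end("blunt") else
        fusion_end(record$bases, cuts[j, ], n, FALSE)
      frags[[j]] <- gg_fragment(
        bases, left, right, source = record$id, source_start = from0 + 1L,
        features = clip_features(record$features, from0, nchar(bases), n, FALSE),
        internal_sites = count_internal_sites(bases, enz)
      )
    }
  } else {
    for (j in seq_len(k)) {
      nxt <- if (j == k) 1L else j + 1L
      from0 <- as.integer(cuts[j, 1])
      t_next <- as.integer(cuts[nxt, 1])
      ovh_next <- as.integer(cuts[nxt, 2] - cuts[nxt, 1])
      if (t_next <= from0) t_next <- t_next + n
      to0 <- t_next + ovh_next
      bases <- span_bases(record$bases, from0, to0, TRUE)
      frags[[j]] <- gg_fragment(
        bases,
        fusion_end(record$bases, cuts[j, ], n, TRUE),
        fusion_end(record$bases, cuts[nxt, ], n, TRUE),
        source = record$id, source_start = from0 + 1L,
        features = clip_features(record$features, from0, nchar(bases), n, TRUE),
        internal_sites = count_internal_sites(bases, enz)
      )
    }
  }
  frags
}

fusion_end <- function(bases, cut, n, circular) {
  t0 <- as.integer(cut[1]); b0 <- as.integer(cut[2])
  if (b0 == t0) return(frag_end("blunt"))
  frag_end("fusion", span_bases(bases, t0, b0, circular))
}

#' Ligate an ordered chain of fragments into a circular record
#'
#' Every consecutive pair (including last-to-first) must satisfy the fusion
#' normalization rule. Each junction's 4 overhang nucleotides are counted
#' once in the product. Fragment features are carried over; one `junction`
#' feature is added per fusion site.
#'
#' @param frags List of `gg_fragment` in ligation order.
#' @param id Id for the product record.
#' @return A circular `seq_record`.
#' @export
ligate_fragments <- function(frags, id = "ligation_product") {
  k <- length(frags)
  stopifnot(k >= 1L)
  for (i in seq_len(k)) {
    nxt <- if (i == k) 1L else i + 1L
    r <- frags[[i]]$right; l <- frags[[nxt]]$left
    if (r$kind != "fusion" || l$kind != "fusion" || r$seq != l$seq) {
      stop("fragments ", i, " and ", nxt, " are not joinable (",
           r$seq, " vs ", l$seq, ")")
    }
  }
  contrib <- vapply(frags, function(f) {
    nchar(f$bases) - nchar(f$right$seq)
  }, integer(1))
  if (any(contrib < 1L)) stop("fragment shorter than its overhang")
  total <- sum(contrib)
  offsets <- cumsum(c(0L, contrib[-k]))
  bases <- paste(vapply(seq_len(k), function(i) {
    substr(frags[[i]]$bases, 1L, contrib[i])
  }, character(1)), collapse = "")
  feats <- list()
  for (i in seq_len(k)) {
    f <- frags[[i]]$features
    if (nrow(f) > 0L) {
      s0 <- (offsets[i] + f$start - 1L) %% total
      e0 <- (offsets[i] + f$end - 1L) %% total
      f$start <- s0 + 1L
      f$end <- e0 + 1L
      feats[[length(feats) + 1L]] <- f
    }
    ovh <- nchar(frags[[i]]$right$seq)
    jstart <- (offsets[i] + contrib[i]) %% total
    feats[[length(feats) + 1L]] <- data.frame(
      label = frags[[i]]$right$seq, kind = "junction",
      start = jstart + 1L, end = (jstart + ovh - 1L) %% total + 1L,
      strand = "+", stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, feats)
  seq_record(id, bases, circular = TRUE, features = feats)
}
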
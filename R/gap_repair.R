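#' Release gap-repair fragments by NotI digestion
#'
#' Digests each record with NotI and keeps the fragments destined for the
#' yeast transformation: fragments carrying `backbone`, `dropout` or
#' `stuffer` annotations are discarded (the vector's E. coli backbone and
#' the mScarlet dropout do not take part in gap repair). Surviving
#' fragments are converted to homology-ended fragments: the 4-nt overhang
#' at the right end is trimmed so each junction's bases are counted once,
#' and both termini become exact-match homology ends. Records without a
#' NotI site are passed through uncut with a warning.
#'
#' @param pool List of `seq_record`s (assembled cassettes and the
#'   integration vector).
#' @param enzymes Named enzyme list.
#' @param discard_kinds Feature kinds marking fragments to discard.
#' @return List of homology-ended `gg_fragment`s.
#' @export
release_fragments <- function(pool, enzymes = load_enzymes(),
                              discard_kinds = c("backbone", "dropout",
                                                "stuffer")) {
  noti <- enzymes[["NotI"]]
  out <- list()
  for (rec in pool) {
    frags <- digest(rec, noti)
    if (length(frags) == 1L && frags[[1]]$left$kind == "blunt" &&
        frags[[1]]$right$kind == "blunt" &&
        nrow(find_sites(rec, noti)) == 0L) {
      warning("record ", rec$id, " has no NotI site; passed through uncut")
      out[[length(out) + 1L]] <- frags[[1]]
      next
    }
    for (f in frags) {
      if (any(f$features$kind %in% discard_kinds)) next
      out[[length(out) + 1L]] <- as_homology_fragment(f)
    }
  }
  out
}

## trim the right-end overhang and re-type both ends as homology termini
as_homology_fragment <- function(f) {
  ovh <- if (f$right$kind == "fusion") nchar(f$right$seq) else 0L
  bases <- substr(f$bases, 1L, nchar(f$bases) - ovh)
  f$bases <- bases
  f$features <- f$features[f$features$end <= nchar(bases), , drop = FALSE]
  f$left <- frag_end("homology", substr(bases, 1L, min(40L, nchar(bases))))
  f$right <- frag_end("homology",
                      substr(bases, max(1L, nchar(bases) - 39L),
                             nchar(bases)))
  f
}

## longest exact suffix-prefix overlap between two fragments (>= min_len),
## found by locating occurrences of b's minimal prefix near a's tail
suffix_prefix_overlap <- function(a, b, min_len) {
  na <- nchar(a); nb <- nchar(b)
  lim <- min(na, nb)
  if (lim < min_len) return(0L)
  seed <- substr(b, 1L, min_len)
  tail_a <- substr(a, na - lim + 1L, na)
  hits <- gregexpr(seed, tail_a, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(0L)
  best <- 0L
  for (h in hits) {
    o <- lim - h + 1L   # implied overlap length
    if (o >= min_len && substr(a, na - o + 1L, na) == substr(b, 1L, o)) {
      best <- max(best, o)
    }
  }
  best
}

#' Plan a gap-repair assembly at a genomic locus
#'
#' Builds the overlap graph over the released fragments (edges are exact
#' suffix-prefix matches of at least `min_overlap` bp), requires a unique
#' Hamiltonian path from the fragment carrying the 5' homology arm to the
#' one carrying the 3' arm, merges the chain, and substitutes it into the
#' locus between the genomic arm positions. Multiple paths are an error
#' (reported with all paths), never a silent choice.
#'
#' @param fragments List of homology-ended fragments from
#'   [release_fragments()]; exactly one must carry a `homology_arm` feature
#'   labelled `arm5*` and one `arm3*`.
#' @param locus `seq_record` of the target chromosome.
#' @param min_overlap Minimum exact overlap in bp (default 20, a
#'   conservative floor for yeast homologous recombination).
#' @param cut_position Optional CRISPR cut position; when given, it must
#'   fall in the replaced segment between the arms.
#' @return An object of class `integration_plan`: ordered chain, junction
#'   table, merged insert and the final integrated-locus record.
#' @export
plan_gap_repair <- function(fragments, locus, min_overlap = 20L,
                            cut_position = NULL) {
  k <- length(fragments)
  stopifnot(k >= 2L)
  has_arm <- function(f, which) {
    any(f$features$kind == "homology_arm" &
          grepl(paste0("^arm", which), f$features$label))
  }
  i5 <- which(vapply(fragments, has_arm, logical(1), which = "5"))
  i3 <- which(vapply(fragments, has_arm, logical(1), which = "3"))
  if (length(i5) != 1L || length(i3) != 1L) {
    stop("need exactly one 5'-arm and one 3'-arm fragment, got ",
         length(i5), " and ", length(i3))
  }
  ov <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        ov[i, j] <- suffix_prefix_overlap(fragments[[i]]$bases,
                                          fragments[[j]]$bases, min_overlap)
      }
    }
  }
  paths <- list()
  dfs <- function(path, used) {
    v <- path[length(path)]
    if (length(path) == k) {
      if (v == i3) paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(ov[v, ] > 0L)) {
      if (!used[w]) {
        used[w] <- TRUE
        dfs(c(path, w), used)
        used[w] <- FALSE
      }
    }
  }
  used <- logical(k); used[i5] <- TRUE
  dfs(i5, used)
  if (length(paths) == 0L) {
    ends <- vapply(fragments, function(f) {
      substr(f$bases, max(1L, nchar(f$bases) - 11L), nchar(f$bases))
    }, character(1))
    stop("no gap-repair path covers all fragments; unmatched ends: ",
         paste(sprintf("[%d]..%s", seq_len(k), ends), collapse = " "))
  }
  if (length(paths) > 1L) {
    stop("ambiguous gap-repair assembly: ", length(paths),
         " fragment orders are possible (",
         paste(vapply(paths, paste, character(1), collapse = "-"),
               collapse = "; "), ")")
  }
  path <- paths[[1]]
  ## merge the chain and record the junctions
  merged <- fragments[[path[1]]]$bases
  junctions <- list()
  for (s in seq_len(k - 1L)) {
    a <- path[s]; b <- path[s + 1L]
    o <- ov[a, b]
    junctions[[s]] <- data.frame(
      junction = s, upstream = fragments[[a]]$source,
      downstream = fragments[[b]]$source, overlap_length = o,
      overlap_seq = substr(fragments[[b]]$bases, 1L, o),
      position = nchar(merged) - o + 1L, stringsAsFactors = FALSE)
    merged <- paste0(merged, substr(fragments[[b]]$bases, o + 1L,
                                    nchar(fragments[[b]]$bases)))
  }
  junctions <- do.call(rbind, junctions)
  ## locate the genomic arms and substitute the insert into the locus
  arm_seq <- function(f, which) {
    ft <- f$features[f$features$kind == "homology_arm" &
                       grepl(paste0("^arm", which), f$features$label), ]
    substr(f$bases, ft$start[1], ft$end[1])
  }
  arm5 <- arm_seq(fragments[[i5]], "5")
  arm3 <- arm_seq(fragments[[i3]], "3")
  g5 <- unlist(gregexpr(arm5, locus$bases, fixed = TRUE))
  g3 <- unlist(gregexpr(arm3, locus$bases, fixed = TRUE))
  if (length(g5) != 1L || g5 == -1L || length(g3) != 1L || g3 == -1L) {
    stop("homology arms do not match the locus uniquely")
  }
  arm5_gen <- c(g5, g5 + nchar(arm5) - 1L)
  arm3_gen <- c(g3, g3 + nchar(arm3) - 1L)
  if (!is.null(cut_position) &&
      (cut_position < arm5_gen[2] || cut_position > arm3_gen[1] - 1L)) {
    stop("CRISPR cut position ", cut_position,
         " lies outside the replaced segment between the homology arms")
  }
  m5 <- regexpr(arm5, merged, fixed = TRUE)
  m3 <- regexpr(arm3, merged, fixed = TRUE)
  if (m5 == -1L || m3 == -1L) stop("arms lost during merge")
  insert <- substr(merged, m5, m3 + nchar(arm3) - 1L)
  integrated <- seq_record(
    paste0(locus$id, "_integrated"),
    paste0(substr(locus$bases, 1L, arm5_gen[1] - 1L), insert,
           substr(locus$bases, arm3_gen[2] + 1L, nchar(locus$bases))))
  ## carry payload features of the chain onto the integrated record
  feats <- list()
  off <- arm5_gen[1] - m5
  pos <- 0L
  for (s in seq_along(path)) {
    f <- fragments[[path[s]]]
    if (nrow(f$features)) {
      ft <- f$features
      ft$start <- ft$start + pos + off
      ft$end <- ft$end + pos + off
      keep <- ft$start >= 1L & ft$end <= nchar(integrated$bases)
      feats[[length(feats) + 1L]] <- ft[keep, , drop = FALSE]
    }
    o_next <- if (s < k) ov[path[s], path[s + 1L]] else 0L
    pos <- pos + nchar(f$bases) - o_next
  }
  integrated$features <- normalize_features(
    do.call(rbind, feats), nchar(integrated$bases), FALSE)
  structure(
    list(order = path,
         fragment_ids = vapply(fragments[path], `[[`, character(1),
                               "source"),
         junctions = junctions, merged = merged, insert = insert,
         locus_id = locus$id, arm5_genomic = arm5_gen,
         arm3_genomic = arm3_gen, integrated = integrated),
    class = "integration_plan")
}

#' @export
print.integration_plan <- function(x, ...) {
  cat(sprintf("<integration_plan> %s: %d fragments (%s), %d junction(s), integrated locus %d bp\n",
              x$locus_id, length(x$order),
              paste(x$fragment_ids, collapse = " -> "),
              nrow(x$junctions), nchar(x$integrated$bases)))
  invisible(x)
}

#' Predict colony-PCR amplicons across assembly junctions
#'
#' A primer binds where its full sequence matches exactly (forward primers
#' on the top strand, reverse primers on the bottom strand, i.e. their
#' reverse complement on the top strand). The amplicon length is the
#' distance between the outer 5' ends; `NA` is reported when either primer
#' is unbound or the pair is divergent. Primers matching multiple
#' positions trigger a multi-binding warning listing all loci.
#'
#' @param plan An `integration_plan` (the search is on the integrated
#'   locus), or any `seq_record`.
#' @param primers Data frame with columns `junction`, `fwd`, `rev`
#'   (sequences 5'->3').
#' @return Data frame with `junction` and `amplicon_length`.
#' @export
predict_junction_amplicons <- function(plan, primers) {
  template <- if (inherits(plan, "integration_plan")) plan$integrated else plan
  seq <- template$bases
  find_all <- function(p) {
    hits <- gregexpr(p, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer() else as.integer(hits)
  }
  out <- lapply(seq_len(nrow(primers)), function(i) {
    fwd <- toupper(primers$fwd[i]); rev <- toupper(primers$rev[i])
    fpos <- find_all(fwd)
    rpos <- find_all(revcomp(rev))
    for (nm in list(c("forward", length(fpos)), c("reverse", length(rpos)))) {
      if (as.integer(nm[2]) > 1L) {
        warning("junction ", primers$junction[i], ": ", nm[1],
                " primer binds at multiple loci")
      }
    }
    len <- NA_integer_
    if (length(fpos) >= 1L && length(rpos) >= 1L) {
      ## convergent orientation: forward 5' end upstream of the reverse
      ## primer's 5' end (top position r + |rev| - 1)
      combos <- expand.grid(f = fpos, r = rpos)
      combos$len <- combos$r + nchar(rev) - combos$f
      combos <- combos[combos$len >= max(nchar(fwd), nchar(rev)), ,
                       drop = FALSE]
      if (nrow(combos)) len <- min(combos$len)
    }
    data.frame(junction = primers$junction[i], amplicon_length = len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Design junction-flanking colony-PCR primers
#'
#' Convenience generator for screening primers: for each junction of a
#' plan, a primer pair is placed `distance` bp up/downstream of the
#' junction midpoint on the integrated locus.
#'
#' @param plan An `integration_plan`.
#' @param distance Distance from the junction to each primer's 5' end.
#' @param primer_length Primer length.
#' @return Primer data frame suitable for [predict_junction_amplicons()].
#' @export
design_junction_primers <- function(plan, distance = 150L,
                                    primer_length = 20L) {
  seq <- plan$integrated$bases
  ## junction positions on the integrated record
  out <- lapply(seq_len(nrow(plan$junctions)), function(i) {
    j <- plan$junctions[i, ]
    hit <- regexpr(j$overlap_seq, seq, fixed = TRUE)
    centre <- as.integer(hit) + nchar(j$overlap_seq) %/% 2L
    fs <- centre - distance
    re <- centre + distance
    data.frame(junction = j$junction,
               fwd = substr(seq, fs, fs + primer_length - 1L),
               rev = revcomp(substr(seq, re - primer_length + 1L, re)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
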
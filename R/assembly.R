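#' Simulate a one-pot Golden Gate assembly
#'
#' Models the cycled digestion-ligation reaction driven by a Type IIS
#' enzyme: every input record is digested to completion; fragments that
#' retain internal recognition sites are reaction intermediates (they would
#' be re-cut in the next cycle) and are excluded; the remaining fragments
#' with two fusion ends form a directed graph with an edge A -> B whenever
#' A's right fusion site equals B's left fusion site. Each distinct simple
#' cycle of that graph is a circular product; only circular products are
#' reported because only they propagate in the host.
#'
#' @param pool List of `seq_record` objects (the reaction mix).
#' @param enz The Type IIS `gg_enzyme` driving the assembly.
#' @return An object of class `gg_assembly`: a list with `products` (list of
#'   `gg_product`), `unique` (exactly one cycle and every fusion site used
#'   at most once per side), `ambiguous`, and `diagnostics` (dangling fusion
#'   sites and excluded-fragment counts).
#' @export
assemble_golden_gate <- function(pool, enz) {
  stopifnot(length(pool) >= 1L)
  if (!enz$type_iis) stop("assembly requires a Type IIS enzyme")
  frags <- unlist(lapply(pool, digest, enz = enz), recursive = FALSE)
  eligible <- Filter(function(f) {
    f$internal_sites == 0L &&
      f$left$kind == "fusion" && f$right$kind == "fusion"
  }, frags)
  res <- enumerate_cycles(eligible)
  products <- lapply(res$cycles, function(idx) {
    build_product(eligible[idx], enz)
  })
  ## a circular record the enzyme cannot cut stays intact in the pot: it is
  ## already a final product (this makes re-assembly of a finished product
  ## idempotent)
  passthrough <- Filter(function(f) f$circular && f$internal_sites == 0L,
                        frags)
  for (f in passthrough) {
    rec <- seq_record(f$source, f$bases, circular = TRUE,
                      features = f$features)
    products[[length(products) + 1L]] <- structure(
      list(record = rec,
           parts_order = list(list(source = f$source, source_start = 1L,
                                   length = nchar(f$bases))),
           junctions = character(), enzyme = enz$name),
      class = "gg_product")
  }
  ## deduplicate under rotation / strand via canonical sequence
  if (length(products) > 1L) {
    keys <- vapply(products, function(p) {
      canonical_rotation(p$record$bases)
    }, character(1))
    products <- products[!duplicated(keys)]
  }
  lefts <- vapply(eligible, function(f) f$left$seq, character(1))
  rights <- vapply(eligible, function(f) f$right$seq, character(1))
  unique_flag <- length(products) == 1L &&
    !anyDuplicated(lefts) && !anyDuplicated(rights)
  diagnostics <- list(
    dangling = sort(unique(c(setdiff(rights, lefts), setdiff(lefts, rights)))),
    n_fragments = length(frags),
    n_eligible = length(eligible),
    n_intermediates = length(frags) - length(eligible)
  )
  structure(
    list(products = products,
         unique = unique_flag,
         ambiguous = length(products) > 1L,
         diagnostics = diagnostics),
    class = "gg_assembly"
  )
}

#' @export
print.gg_assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d product(s)%s%s\n", length(x$products),
              if (x$unique) " [unique]" else "",
              if (x$ambiguous) " [ambiguous]" else ""))
  if (length(x$products) == 0L && length(x$diagnostics$dangling)) {
    cat("  dangling fusion sites:",
        paste(x$diagnostics$dangling, collapse = ", "), "\n")
  }
  invisible(x)
}

## Simple-cycle enumeration over the fusion graph. Cycles are reported with
## their smallest fragment index first, which deduplicates rotations.
enumerate_cycles <- function(frags) {
  k <- length(frags)
  if (k == 0L) return(list(cycles = list()))
  lefts <- vapply(frags, function(f) f$left$seq, character(1))
  rights <- vapply(frags, function(f) f$right$seq, character(1))
  adj <- lapply(seq_len(k), function(i) which(lefts == rights[i]))
  cycles <- list()
  path <- integer(0)
  on_path <- logical(k)
  dfs <- function(v, start) {
    path[length(path) + 1L] <<- v
    on_path[v] <<- TRUE
    for (w in adj[[v]]) {
      if (w == start) {
        cycles[[length(cycles) + 1L]] <<- path
      } else if (w > start && !on_path[w]) {
        dfs(w, start)
      }
    }
    on_path[v] <<- FALSE
    path <<- path[-length(path)]
  }
  for (s in seq_len(k)) dfs(s, s)
  list(cycles = cycles)
}

#' Assembly products
#'
#' A `gg_product` couples the circular product record with the ordered
#' provenance of its source fragments and the list of 4-nt junction fusion
#' sites. No internal recognition site of the assembly enzyme survives in a
#' valid product.
#'
#' @name gg_product
NULL

build_product <- function(frags, enz) {
  rec <- ligate_fragments(frags, id = paste0(
    "assembly_", paste(vapply(frags, `[[`, character(1), "source"),
                       collapse = "+")))
  structure(
    list(record = rec,
         parts_order = lapply(frags, function(f) {
           list(source = f$source, source_start = f$source_start,
                length = nchar(f$bases))
         }),
         junctions = vapply(frags, function(f) f$right$seq, character(1)),
         enzyme = enz$name),
    class = "gg_product"
  )
}

#' @export
print.gg_product <- function(x, ...) {
  cat(sprintf("<product> %d bp circular, %d part(s) [%s], junctions: %s\n",
              nchar(x$record$bases), length(x$parts_order), x$enzyme,
              paste(x$junctions, collapse = "-")))
  invisible(x)
}

#' Validate a set of 4-nt fusion sites
#'
#' Checks the properties a high-fidelity Golden Gate overhang set must
#' satisfy: no duplicates, no palindromic (self-reverse-complement) site,
#' no two sites related by reverse complement, and a crosstalk margin: for
#' every ordered pair the Hamming distance between one site and the reverse
#' complement of the other must be at least `min_pair_mismatches`
#' (a site ligates to the reverse complement of its partner, so small
#' distances mean cross-ligation risk). This is a conservative heuristic
#' stand-in for empirically measured ligation-fidelity tables.
#'
#' @param sites Character vector of 4-nt sites over A/C/G/T.
#' @param min_pair_mismatches Minimum allowed site-vs-reverse-complement
#'   Hamming distance between distinct sites (default 1).
#' @return A list with `ok` (logical) and `violations` (data frame with
#'   columns `type`, `site_a`, `site_b`, `detail`).
#' @examples
#' validate_overhang_set(c("AACG", "TATG", "GCTG"))$ok
#' validate_overhang_set("GGCC")$violations$type  # palindrome
#' @export
validate_overhang_set <- function(sites, min_pair_mismatches = 1L) {
  sites <- toupper(sites)
  bad <- !grepl("^[ACGT]{4}$", sites)
  if (any(bad)) {
    stop("malformed overhang set member(s): ",
         paste(sites[bad], collapse = ", "))
  }
  viol <- list()
  add <- function(type, a, b = NA_character_, detail = "") {
    viol[[length(viol) + 1L]] <<- data.frame(
      type = type, site_a = a, site_b = b, detail = detail,
      stringsAsFactors = FALSE)
  }
  dup <- unique(sites[duplicated(sites)])
  for (d in dup) add("duplicate", d)
  usites <- unique(sites)
  rcs <- revcomp(usites)
  for (i in seq_along(usites)) {
    if (usites[i] == rcs[i]) add("palindrome", usites[i])
  }
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  if (length(usites) > 1L) {
    for (i in seq_len(length(usites) - 1L)) {
      for (j in (i + 1L):length(usites)) {
        if (usites[i] == rcs[j]) {
          add("revcomp_pair", usites[i], usites[j])
        } else {
          d <- min(hamming(usites[i], rcs[j]), hamming(usites[j], rcs[i]))
          if (d < min_pair_mismatches) {
            add("crosstalk", usites[i], usites[j],
                sprintf("distance %d < %d", d, min_pair_mismatches))
          }
        }
      }
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(type = character(), site_a = character(),
               site_b = character(), detail = character(),
               stringsAsFactors = FALSE)
  list(ok = nrow(viol) == 0L, violations = viol)
}
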
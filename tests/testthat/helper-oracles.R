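# Shared fixtures (built once per test run) and independent oracles used to
# cross-check the implementation.

.toy_cache <- new.env(parent = emptyenv())

toy_fixtures <- function(seed = 101L) {
  key <- paste0("s", seed)
  if (is.null(.toy_cache[[key]])) {
    .toy_cache[[key]] <- make_fixtures(seed = seed)
  }
  .toy_cache[[key]]
}

toy_enzymes <- function() {
  if (is.null(.toy_cache$enzymes)) .toy_cache$enzymes <- load_enzymes()
  .toy_cache$enzymes
}

# --- naive IUPAC sliding-window scanner (oracle for find_sites) ----------

iupac_table <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

naive_iupac_positions <- function(bases, pattern, circular = FALSE) {
  n <- nchar(bases)
  L <- nchar(pattern)
  subject <- if (circular && n >= L) {
    paste0(bases, substr(bases, 1, L - 1))
  } else bases
  sv <- strsplit(subject, "")[[1]]
  pv <- strsplit(pattern, "")[[1]]
  hits <- integer()
  for (i in seq_len(max(0, nchar(subject) - L + 1))) {
    window <- sv[i:(i + L - 1)]
    ok <- all(vapply(seq_len(L), function(j) {
      window[j] != "N" && window[j] %in% iupac_table[[pv[j]]]
    }, logical(1)))
    if (ok && i <= n) hits <- c(hits, i)
  }
  hits
}

naive_find_sites <- function(record, enz) {
  fwd <- naive_iupac_positions(record$bases, enz$recognition,
                               record$circular)
  if (enz$recognition == revcomp(enz$recognition)) {
    return(data.frame(position = sort(fwd),
                      strand = rep("+", length(fwd)),
                      stringsAsFactors = FALSE))
  }
  rev <- naive_iupac_positions(record$bases, revcomp(enz$recognition),
                               record$circular)
  out <- data.frame(position = c(fwd, rev),
                    strand = c(rep("+", length(fwd)),
                               rep("-", length(rev))),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- random fragment pools encoded as linear records ---------------------

# A pool record digests into one clean payload fragment site_l -> site_r.
pool_record <- function(id, site_l, site_r, core_len = 25L) {
  core <- paste(sample(c("A", "C", "T"), core_len, replace = TRUE),
                collapse = "")
  seq_record(id, paste0("GGTCTCA", site_l, core, site_r, "AGAGACC"))
}

# non-palindromic 4-mers over {A,C,T} (cannot create BsaI sites)
safe_site_alphabet <- function() {
  all4 <- apply(expand.grid(rep(list(c("A", "C", "T")), 4)), 1,
                paste, collapse = "")
  all4[all4 != revcomp(all4)]
}

random_fragment_pool <- function(k, n_sites = max(3L, k)) {
  sites <- sample(safe_site_alphabet(), n_sites)
  lapply(seq_len(k), function(i) {
    pool_record(paste0("frag", i), sample(sites, 1), sample(sites, 1))
  })
}

# --- brute-force assembly oracle -----------------------------------------

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_permutations(v[-i]), function(p) c(v[i], p))
  }))
}

# every circular product over all subsets and orderings of the pool's
# clean payload fragments, as a set of canonical sequences
brute_force_assembly <- function(pool, enz) {
  frags <- unlist(lapply(pool, digest, enz = enz), recursive = FALSE)
  frags <- Filter(function(f) f$internal_sites == 0L &&
                    f$left$kind == "fusion" && f$right$kind == "fusion",
                  frags)
  k <- length(frags)
  products <- character()
  if (k == 0L) return(products)
  for (mask in seq_len(2^k) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    if (length(idx) == 0L) next
    first <- idx[1]
    for (perm in all_permutations(idx[-1])) {
      ord <- c(first, perm)
      ok <- TRUE
      for (s in seq_along(ord)) {
        a <- frags[[ord[s]]]
        b <- frags[[ord[if (s == length(ord)) 1L else s + 1L]]]
        if (a$right$seq != b$left$seq) { ok <- FALSE; break }
      }
      if (!ok) next
      seqs <- vapply(ord, function(i) {
        f <- frags[[i]]
        substr(f$bases, 1L, nchar(f$bases) - nchar(f$right$seq))
      }, character(1))
      products <- c(products, canonical_rotation(paste(seqs, collapse = "")))
    }
  }
  sort(unique(products))
}

assembly_product_keys <- function(asm) {
  sort(unique(vapply(asm$products, function(p) {
    canonical_rotation(p$record$bases)
  }, character(1))))
}

# --- brute-force gap-repair oracle ---------------------------------------

naive_overlap <- function(a, b, min_len) {
  best <- 0L
  for (o in min_len:min(nchar(a), nchar(b))) {
    if (substr(a, nchar(a) - o + 1L, nchar(a)) == substr(b, 1L, o)) {
      best <- o
    }
  }
  best
}

brute_force_gap_paths <- function(fragments, min_overlap, from, to) {
  k <- length(fragments)
  ov <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        ov[i, j] <- naive_overlap(fragments[[i]]$bases,
                                  fragments[[j]]$bases, min_overlap)
      }
    }
  }
  rest <- setdiff(seq_len(k), from)
  paths <- list()
  for (perm in all_permutations(rest)) {
    ord <- c(from, perm)
    if (ord[k] != to) next
    if (all(ov[cbind(ord[-k], ord[-1])] > 0L)) {
      paths[[length(paths) + 1L]] <- ord
    }
  }
  paths
}

# --- hash-based longest-common-substring oracle --------------------------

substrings_of <- function(s, L) {
  if (nchar(s) < L || L < 1L) return(character())
  unique(substring(s, 1:(nchar(s) - L + 1L), L:nchar(s)))
}

lcs_length_hash <- function(a, b) {
  lo <- 0L; hi <- min(nchar(a), nchar(b))
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (length(intersect(substrings_of(a, mid), substrings_of(b, mid)))) {
      lo <- mid
    } else {
      hi <- mid - 1L
    }
  }
  lo
}

shared_repeat_oracle <- function(sequences) {
  best <- 0L
  for (i in seq_len(length(sequences) - 1L)) {
    for (j in (i + 1L):length(sequences)) {
      best <- max(best,
                  lcs_length_hash(sequences[i], sequences[j]),
                  lcs_length_hash(sequences[i], revcomp(sequences[j])))
    }
  }
  best
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
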
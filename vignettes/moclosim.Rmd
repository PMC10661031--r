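---
title: "Simulating hierarchical Golden Gate assembly for multiplex yeast engineering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hierarchical Golden Gate assembly for multiplex yeast engineering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moclosim)
```

## The problem

Modular cloning (MoClo) standards for budding yeast encode the order of
parts in a construct by fixed 4-nt single-stranded overhangs ("fusion
sites") generated by Type IIS restriction enzymes, which cut at a fixed
offset outside their recognition sequence. Level-0 parts (promoters,
coding sequences, terminators, connectors, markers, origins, backbones —
part types 1–8, with 3a/3b and 4a/4b subtypes for tagged CDSs and
terminator splits) are assembled with BsaI into Level-1 transcriptional
units; Level-1 cassettes are assembled with BsmBI into Level-2 multigene
constructs of up to ten units inside a genomic integration vector; a
separate BbsI reaction exchanges selectable markers. In the multiplexed
workflow the same cassettes can instead be digested with NotI and
co-transformed into yeast, where homologous recombination ("gap repair")
chains the released fragments at a CRISPR-cut genomic locus.

`moclosim` simulates all of these reactions so that designs can be
validated before any DNA is handled. This vignette documents the model,
its assumptions and parameters, the synthetic fixtures, and the design
decisions that were genuinely open.

## The assembly model

**Digestion.** Complete digestion is assumed: every recognition site that
maps inside the molecule is cut. For a Type IIS enzyme with geometry
`R(a/b)` a plus-strand site cuts the top strand `a` nt and the bottom
strand `b` nt downstream of the recognition 3' end, producing a
`b - a`-nt 5' overhang; minus-strand and within-site (NotI) geometries
are handled symmetrically. Geometries ship as YAML config
(`inst/extdata/enzymes.yaml`), with REBASE values for BsaI GGTCTC(1/5),
BsmBI CGTCTC(1/5), BbsI GAAGAC(2/6) and NotI GC^GGCCGC. A linear record
with *n* internal cuts yields *n*+1 fragments; a circular record with
*n* ≥ 1 cuts yields *n* fragments; sites whose cut positions fall off a
linear record are skipped with a warning. `N` in a subject sequence never
matches a recognition base (conservative site calling).

**Fragment normalization.** A fragment's bases run from its first
top-strand cut to the bottom-strand cut of the next junction, so each
4-nt overhang appears at the end of the upstream fragment *and* at the
start of the downstream fragment; two ends are joinable iff those strings
are equal. Ligation counts every junction's overhang once, which gives
the conservation property (total double-stranded length is preserved)
and makes digest→ligate reconstruct a rotation of the input.

**One-pot reaction.** The cycled digestion–ligation program is modelled
as a fixed point: fragments that retain a recognition site are reaction
intermediates — any ligation involving them would be re-cut — so only
site-free, two-fusion fragments enter the assembly graph (edge A→B iff
A's right fusion equals B's left fusion). Each simple cycle of the graph
is one circular product; linear concatemers are not reported because only
circular DNA propagates in the host. Products are deduplicated by
canonical rotation (the lexicographically minimal rotation over both
strands, computed with Booth's algorithm), since a circular molecule has
no distinguished origin or strand. An assembly is flagged *unique* when
exactly one cycle exists and no fusion site occurs on more than one left
or right end. A circular pool member the enzyme cannot cut passes through
as a product, which makes re-assembling a finished product idempotent.

The model deliberately excludes kinetics: no partial digests, no
concentration-dependent product ratios, no ligation thermodynamics, no
star activity or methylation sensitivity. One-pot NotI reactions ignore
religation of the 4-nt GGCC overhangs after heat inactivation; in the
planning use case NotI products are transformed, not propagated.

**Overhang fidelity.** Published fidelity predictors rank overhang sets
with empirically measured ligation-frequency tables. Those tables are not
available here, so `validate_overhang_set()` applies a conservative
structural heuristic instead: no duplicates, no palindromic
(self-reverse-complement) site, no reverse-complement pair, and a
configurable minimum Hamming distance (default 1 mismatch) between every
site and the reverse complement of every other site. This rejects the
failure modes that make sets unusable; it does not rank usable sets.

## The kit grammar

Level-1 fusion sites are the published yeast-toolkit standard
(type 8→1 CCCT, 1→2 AACG, 2→3 TATG, 3→4 ATCC, 4→5 GCTG, …). The Level-2
connector scheme is positional: junction site S*i* sits between cassette
positions *i* and *i*+1, S0 joins the vector to position 1, and a
terminal site closes the last cassette back into the vector. An internal
cassette at position *i* therefore carries (S*i−1* → S*i*), a terminal
cassette (S*i−1* → terminal); covering every assembly size from 2 to 10
requires internal positions 1–9 and terminal positions 2–10 — the 18
prebuilt cassette configurations (and 18 matching spacers) the planner
enumerates and the fixtures provide. Eleven or more units has no closing
chain and is refused. A single unit is grammatically legal (a cassette
carrying S0 → terminal) but has no prebuilt spacer configuration, so
`select_level2_cassettes()` directs single-TU builds to direct Level-1
assembly into the vector.

The planners validate grammar before simulating: `plan_level1()` walks
the declared fusion chain and names the missing part-type interval or the
duplicated interval (two promoters) before any digestion happens;
`plan_level2()` checks connector closure the same way. After simulation
both verify the product (uniqueness, dropout loss, and for Level 1 that
BsmBI re-digestion releases the unit with the cassette's declared
connector pair). Screening-color prediction is purely feature-based:
dropout features carry their reporter and expression stages in their
label, and a correct assembly screens white. No expression is modelled.

## Gap repair

NotI digestion releases each cassette's payload and the vector's two
homology arms; fragments annotated as backbone, dropout or stuffer are
discarded by annotation, not by size. Overlap detection is an *exact*
suffix-prefix match of at least `min_overlap` bp (default 20 bp, a
conservative floor for efficient homologous recombination in yeast;
mismatched or internal homology is out of scope). The plan is the unique
Hamiltonian path from the 5'-arm fragment to the 3'-arm fragment;
multiple feasible orders are an error that lists all paths, never a
silent choice. The integrated locus substitutes the merged chain between
the genomic arm coordinates, and an optional CRISPR cut position is
required to lie in the replaced segment. Junction colony-PCR is modelled
as exact full-length primer binding (forward on the top strand, reverse
on the bottom), with multi-binding warnings.

Making exact terminal overlaps survive *complete* NotI digestion required
a specific junction design in the fixtures: the shared homology block is
`GGCCGC · M · GC` (|M| = 22, hence 30-bp overlaps), where the upstream
molecule encodes it as literal `GGCCGC · M` followed by its NotI site and
the downstream molecule as its NotI site followed by `M · GC`. The scar
remnants left by the two cuts then reconstruct the same 30-bp terminus on
both fragments. The fragment's trailing 4-nt overhang is trimmed when
fusion ends become homology termini so each junction is counted once.

## gRNA-tRNA arrays

Arrays follow the tRNA-spacing architecture: each PCR fragment is
spacer + scaffold + tRNA (the last fragment omits the tRNA), generated
from a template located inside the CRISPR backbone's three-part
sfGFP/template/mScarlet dropout. Forward primer tails encode a BsaI site,
the position's fusion site and the spacer; annealing is exact matching of
the primer's 3' region (18 nt by default, 12 nt minimum) — mispriming is
out of scope. Internal fusion sites come from the kit's validated
overhang table in positional order, making designs deterministic and
collision-free; array sizes 1–10 are supported and duplicate spacers are
rejected as a recombination/assembly hazard. Spacer validation checks
length, internal enzyme sites, and (given a genome) exact uniqueness with
an NGG PAM. The two CRISPR backbones (marked and transient) are treated
identically by the designer; the recommendation to prefer single-guide
plasmids for the transient system is an operational choice left to the
user rather than a hard error.

## Integration-locus selection

`scan_intergenic()` reports maximal windows in which every position is
more than 1000 bp from every start codon and more than 500 bp from every
stop codon (strand-aware, measured to the codon's first base, derived
from CDS bounds) and overlaps no blacklisted feature. The blacklist
(default tRNA, rRNA, ARS, LTR, telomere) approximates the broader
"minimize host effects" principle and is config-extensible. The
implementation uses interval arithmetic (IRanges); an independent
per-base implementation of the same rule is kept in the package and used
both by the genome generator and as the test oracle. Protospacer
candidates are all 20-mers with NGG immediately 3' on either strand,
filtered to genome-unique 23-mers (exact, both strands) and ranked by the
distance of their predicted cut site (between protospacer positions 17
and 18) from the window centre; ties fall back to leftmost position.
Cross-strain conservation is implemented as exact identity of the
protospacer and both arms in every supplied genome — a deliberate
simplification of similarity search, which is out of scope. Repeat
screening (`longest_shared_repeat()`) is a dynamic-programming longest
common substring over both orientations, matching the design rule that
promoter sets share at most 24 bp.

## The synthetic fixtures

The generator is first-class, deterministic (identical config + seed →
identical bytes) and emulates the *structure* of the real kit, not its
sequences: 38 Level-0 parts, 18 cassette backbones, 18 spacers, 10
markerless integration vectors with mScarlet dropouts and ~500-bp arms
targeting the toy genome, 10 marker cartridges, and 2 CRISPR backbones —
96 entries, the real kit's scale. All payloads are random DNA
"domesticated" against the four enzymes; reporter CDSs are labelled
placeholders, not real ORFs. Sizes (e.g. 220-bp dropouts, 600-bp Cas9
placeholder) are chosen for speed, roughly one order of magnitude below
real plasmids; nothing in the logic depends on them. Because random fills
can create recognition sites across fixed piece boundaries, every
plasmid is rebuilt until it carries exactly its intended site census, and
the shared homology blocks are pre-screened the same way.

The toy genome plants genes (600 bp) separated by either small gaps
(700 bp, which the distance rules close completely) or large gaps
(1900 bp, which open one 402-bp window each); telomere features blacklist
the chromosome ends, so the planted windows are exactly the windows the
rules admit — verified at generation time with the per-base oracle. Each
window's background is PAM-free (no G, no CC dinucleotide) and a single
protospacer (GG/CC-free, enzyme-free) with a TGG PAM is written at the
window centre with its cut site exactly central, so each window contains
exactly one CRISPR-addressable site and ranking is unambiguous. Planted
23-mers are asserted genome-unique.

What passing tests on these fixtures shows: the combinatorial and
geometric logic of the toolkit — grammar closure, product uniqueness,
overlap chaining, locus arithmetic — is correct. What it does not show:
behaviour on real sequence data with repeats, near-palindromic overhangs,
pervasive PAMs and imperfect annotations, nor any wet-lab efficiency;
transformation rates, expression levels and integration efficiencies are
empirical quantities outside the model.

## Numerical and interface choices

- **Coordinates** are 1-based and inclusive everywhere, the R/GenBank
  convention, converted to 0-based half-open only for BED output. Cut
  arithmetic uses 0-based gap coordinates internally, where modular
  wrap-around on circular molecules is unambiguous.
- **Degenerate inputs**: zero-site records pass through digestion as one
  uncut fragment; empty assemblies report dangling fusion sites rather
  than failing silently; windows shorter than 23 bp yield no candidates;
  arms too close to a chromosome end are an error.
- **Tie-breaks**: product deduplication and equality use the canonical
  rotation over both strands; candidate ranking breaks distance ties by
  leftmost coordinate; cycle enumeration anchors each cycle at its
  smallest fragment index, deduplicating rotations structurally.
- **GenBank I/O** is a purpose-built minimal reader/writer (LOCUS
  topology, label/note qualifiers, simple, complement and two-part
  origin-wrapping join locations) with the package-internal feature kind
  round-tripped through a `/note` qualifier. FASTA, GFF3 and BED go
  through Biostrings and rtracklayer.
- **Problem sizes** in tests and the acceptance script are desk-scale by
  design: a ~40-kb two-chromosome genome, ~2–4-kb plasmids, 200 random
  pools for the assembly oracle, 1000 random sequences for the scanner
  oracle — large enough to exercise every code path, small enough to run
  the whole suite in a few minutes.

## Known limitations

Partial digestion, ligation kinetics and fidelity *ranking* are not
modelled; the overhang validator is a gatekeeper, not a predictor.
Gap-repair overlaps must be exact, so mutation-tolerant recombination is
invisible to the planner. PCR simulation has no mispriming model.
Conservation filtering requires exact matches and will under-report loci
across diverged strains. The GenBank parser supports the subset of the
format the package writes; exotic location strings in third-party files
are skipped with a warning.
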
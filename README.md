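# moclosim

An in-silico genetic-design-automation engine for hierarchical Golden Gate
(MoClo-style) cloning in *Saccharomyces cerevisiae*, modelled on the
multiplex extension of the yeast toolkit standard: markerless genomic
integration vectors, up to ten transcriptional units per multigene
construct, marker swapping, in-yeast gap-repair assembly, and multiplexed
gRNA-tRNA arrays for CRISPR-Cas9.

## Who it is for

Yeast synthetic biologists (and toolsmiths building design automation on
top of MoClo grammars) who want to *simulate* their cloning before touching
a pipette: verify that a set of parts closes into a unique circular
product, predict what a NotI digest will release, check that homology arms
and protospacers are genome-unique, and screen part sets for
recombination-prone repeats.

## The model

Golden Gate cloning uses Type IIS restriction enzymes that cut at a fixed
offset *outside* their recognition site, leaving programmable 4-nt 5'
overhangs ("fusion sites"). `moclosim` models the cycled one-pot reaction
as digestion to completion followed by graph search:

- every input plasmid is digested with the level enzyme (BsaI for Level-1
  transcriptional units, BsmBI for Level-2 multigene constructs, BbsI for
  marker swaps); REBASE geometries, e.g. BsaI = GGTCTC(1/5), are config
  data;
- fragments that retain a recognition site are reaction intermediates
  (they would be re-cut in the next thermocycle) and are excluded;
- the remaining fragments form a directed graph with an edge A→B whenever
  A's right fusion site equals B's left fusion site; each simple cycle is
  a circular product, and an assembly is *unique* when exactly one cycle
  exists and no fusion site is reused.

Around this core the package implements the toolkit's grammar: part types
1–8 with their published fusion sites, a positional connector scheme whose
9 internal + 9 terminal cassette configurations cover every 2–10-unit
assembly, dropout-based colony-color prediction (sfGFP / mScarlet),
NotI-release gap-repair planning as a unique Hamiltonian path in an exact
suffix-prefix overlap graph, PCR-simulated gRNA-tRNA array construction,
and integration-locus selection (>1 kb from any start codon, >0.5 kb from
any stop codon, genome-unique protospacer with NGG PAM, ~500-bp
genome-unique homology arms).

A deterministic fixtures module generates a 96-plasmid toy kit and a toy
genome with ten planted integration loci, so the whole pipeline runs
without any external sequence data.

## Worked example

```r
library(moclosim)

fx <- make_fixtures(seed = 17)     # toy kit + toy genome
registry <- fx$registry
registry
#> <kit_registry> 96 entries
#>   cassette             18
#>   crispr_backbone      2
#>   integration_vector   10
#>   marker_cartridge     10
#>   spacer               18
#>   ...

# ten spacer cassettes into the first integration vector (Level 2, BsmBI)
vec <- registry$entries[["int1_vector"]]
product <- plan_level2(select_level2_cassettes(registry, 10), vec, registry)
product
#> <product> 3834 bp circular, 11 part(s) [BsmBI],
#>   junctions: AAAC-AGCG-CGAC-CACG-TTTC-GTGA-TCCA-TAGC-AGCC-ACGG-AATA
predict_screen_color(product)
#> [1] "white"     # the mScarlet dropout is gone: a correct assembly

# BbsI marker swap: markerless vector + URA3 cartridge
swap_marker(vec, registry$entries[["marker_URA3"]])
#> <product> 2416 bp circular, 2 part(s) [BbsI], junctions: CTGC-CATC

# NotI-release gap repair of three cassettes at the chr1 locus
pool <- c(lapply(select_level2_cassettes(registry, 3), `[[`, "record"),
          list(vec$record))
plan <- plan_gap_repair(release_fragments(pool), fx$genome$records$chr1,
                        min_overlap = 20)
plan
#> <integration_plan> chr1: 5 fragments
#>   (int1_vector -> spc_p1_int -> spc_p2_int -> spc_p3_term -> int1_vector),
#>   4 junction(s), integrated locus 23252 bp
predict_junction_amplicons(plan, design_junction_primers(plan))
#>   junction amplicon_length
#> 1        1             301
#> ...
```

The junctions line lists the 4-nt fusion sites in assembly order (the
vector's S0 site joins it to position 1, the terminal site closes the
circle); `3834 bp` is the simulated plasmid size; the 301-bp amplicons are
what colony PCR across each gap-repair junction should produce if
integration succeeded.

A command-line interface with the same workflows is available as
`exec/moclosim` after installation (`digest`, `assemble`, `plan-level1`,
`plan-level2`, `swap-marker`, `gap-repair`, `design-array`, `scan-loci`,
`validate-kit`, `make-fixtures`).

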
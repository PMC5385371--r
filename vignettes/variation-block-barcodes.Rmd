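---
title: "Variation-block InDel barcodes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variation-block InDel barcodes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbcode)
```

## The problem and the model

Modern soybean cultivars are mosaics of chromosome segments inherited from a
small number of ancestral contributors. Relative to the reference genome,
those segments fall into two classes: *sparse variation blocks* (sVBs),
nearly identical to the reference, and *dense variation blocks* (dVBs),
carrying many variants. Crucially, recombination is strongly depleted inside
dVBs (sVBs recombine at roughly 6.6 times the per-bp rate), so a dVB tends
to be inherited as a unit. One well-chosen InDel inside a dVB therefore tags
the whole block, and a panel of such markers — read as "same as reference"
(`a`, white) versus "different" (`b`, black) — turns each cultivar into a
compact, reproducible binary barcode. The package implements the full
workflow from variant calls to barcodes and the panel analyses built on
them; it consumes VCF (alignment and variant calling are upstream and out of
scope) and does not design primer sequences (that is Primer3's job — the
package selects loci and expected amplicon sizes only).

## Segmentation into variation blocks

`segment_variation_blocks()` classifies sliding windows (default 10 kb wide,
2 kb step) as dense when the variant density reaches
`density_threshold` (default 1.5 variants/kb, SNVs and InDels pooled), then
unions dense windows, merges runs separated by at most 10 kb, and
reclassifies dense runs shorter than 10 kb as sparse. The method that
originally defined variation blocks does not fix these constants, so they
are package defaults chosen to produce dVBs on the sub-100 kb scale expected
in gene-rich regions at resequencing variant densities; all of them are
config-overridable through `segmentation_params()`. Every threshold in the
package compares inclusively (`>=`), including this one, so a window exactly
at the threshold is dense. The emitted blocks always tile the chromosome
with alternating classes, and the tests verify the output against an
exhaustive window-scan oracle.

## Block typing across cultivars

Two dVBs at the same locus in different cultivars descend from the same
ancestral haplotype when they are nearly identical. The published criteria
are >= 99.8% sequence identity and >= 0.8 SNV concordance; neither source
defines the concordance formula, so the package uses the Jaccard index of
(position, alternate-allele) pairs restricted to the blocks' intersection
interval — a symmetric, scale-free choice that honours the stated threshold.
True sequence identity cannot be computed from variant calls alone;
`assign_block_types()` approximates it as one minus the density of
discordant variant positions over the intersection length (each discordant
position counted as one mismatching base), and `typing_params(use_identity
= FALSE)` allows typing by concordance alone. Type labels are connected
components of the pairwise-link graph: this matches the "same colour =
same type" reading of block maps, but it is a transitive closure, so a
component can contain a pair that fails the direct threshold; such
non-metric clusters trigger a warning rather than being silently split.

## Marker discovery and PIC

Candidates are InDels of 5–20 bp inside a dVB — small enough to amplify in a
short product, large enough to separate on an agarose gel — whose expected
PCR products for *every* allele fall in 80–120 bp. Flank widths default to
centring the reference amplicon on 100 bp (`default_flanks()`). Band
patterns are amplicon lengths in bp: two alleles of equal length are one
pattern, because a gel cannot separate them, and a heterozygous call showing
two bands is a pattern of its own. Marker informativeness is the
polymorphism information content

$$\mathrm{PIC}_i = 1 - \sum_j p_{ij}^2,$$

with \(p_{ij}\) the frequency of the \(j\)-th pattern at marker \(i\) among
scored cultivars; missing calls are dropped, not imputed, and reports round
to two decimals by convention. Per dense-block type, `select_markers()`
keeps the top candidates by (PIC, then allele-size difference — larger gaps
resolve better on a gel — then position), after discarding candidates with
more than 10% missing calls; missingness is the only panel-computable proxy
for wet-lab genotyping success. Blocks with no eligible candidate are
reported as coverage gaps rather than silently skipped.

## Barcode encoding

`encode_genotypes()` keys every marker to the reference cultivar: `a` equals
the reference pattern, the most frequent alternative pattern is `b`, any
further pattern is `c` (third alleles are real but rare — a few markers per
panel, each in a handful of cultivars), heterozygous calls are `h`, missing
is `.`. Ranking alternatives by panel frequency makes the encoding stable:
re-encoding against a different reference swaps `a` and `b` coherently at
biallelic markers. Heterozygous and missing codes are excluded from identity
comparisons by default (`policy = "exclude"`): a heterozygous block signals
incomplete fixation of a line, not a different identity. The alternative
policies (`"mismatch"`, `"match-either"`) are available where that
assumption does not fit. Barcode strings and matrices carry a panel
checksum, so codes produced from different marker panels refuse comparison
instead of producing a meaningless difference count.

## Panel analyses

* **Distances.** `pairwise_difference()` counts markers at which two
  cultivars carry different homozygous codes; the simple-matching distance
  divides by the number of comparable markers. On rows without `h`/`.` this
  is a metric.
* **Clustering.** `nj_tree()` is classical Saitou–Nei neighbour joining with
  two determinism guarantees: Q-criterion ties break by lexicographic node
  label, and negative branch lengths are clamped to zero with the deficit
  moved to the sister branch, preserving path lengths. The published
  clustering used a weighted NJ implementation; at panel scale the weighting
  affects only tie handling, and group recovery is a topology property, so
  classical NJ with deterministic ties is used and an independent NJ
  implementation serves as a cross-check in the tests. `cut_tree_groups()`
  cuts the tree into groups at a user-chosen edge-length threshold (the
  published group cuts do not state one).
* **Minimal discriminating set.** Choosing the fewest markers that still
  separate every cultivar pair is a set cover, solved greedily (pick the
  marker distinguishing the most unresolved pairs; ties by PIC, then genomic
  order) followed by redundancy elimination: selected markers whose removal
  leaves every covered pair distinguished are dropped in reverse selection
  order. On random 6-cultivar x 8-marker panels this matches the exhaustive
  optimum in roughly 98 of 100 draws; `exact = TRUE` guarantees the optimum
  for small panels. Pairs with no distinguishing homozygous codes (identical
  barcodes, or differences only at `h`/`.` cells) are unresolvable by
  construction and are reported, not hidden.
* **Closest match, pedigree, fixation.** `closest_matches()` ranks a
  database by difference count and reports the panel's mean pairwise
  difference as context. `pedigree_consistency()` checks each marker of a
  trio: the offspring code must occur in a parent, or be `h` where the
  parents differ. `fixation_report()` lists heterozygous markers per
  cultivar grouped by dense block; any heterozygous block flags the line as
  not fully fixed.

## The synthetic panel

`simulate_founders()` plants a known block layout (default: 2 chromosomes of
1 Mb, 8 dVBs of 30–60 kb each, separated by at least 40 kb of sparse
sequence), draws a variant pool per dVB (5 variants/kb per haplotype, 30%
InDels with sizes uniform on 1–30 bp so the 5–20 bp filter sees both passes
and failures; 0.1 variants/kb of founder-private sparse background), groups
pool variants into a small number of ancestral haplotypes (haplotype 1 is
the reference), and assigns each founder one haplotype per block. Two
distinct non-reference haplotypes share an individual variant with
probability 0.3 — implemented as independent carriage with probability
\(q = 2s/(1+s)\), which gives expected pairwise Jaccard \(s\) — so block
typing has non-trivial structure: same-haplotype blocks type together,
different haplotypes fall well below the 0.8 concordance threshold.

Meiosis draws a Poisson number of crossovers per chromosome (mean 2) and
places them by inverse-CDF sampling over a piecewise-constant intensity: 1
inside planted dVBs, 6.6 in sparse regions. No crossover interference is
modelled. `simulate_cross()` composes gametes into F1s, selfing series and
backcross series; `inbred = TRUE` finishes with a doubled gamete, the
package's model of a fully homozygous (backcross-inbred or doubled-haploid)
line. For a BC\(_n\) line this gives expected donor-genome fraction
\((1/2)^{n+1}\); the intermediate BC\(_n\) individual itself carries its
donor segments heterozygously, because every backcross pairs a gamete with a
pure recurrent-parent gamete — which is why the inbred derivative, not the
segregating individual, is the right object for "differs from the recurrent
parent at a handful of markers" comparisons.

What the simulator deliberately does not emulate: nucleotide sequence (no
primer design possible on simulated data), genotyping error beyond a simple
per-marker mutation rate, realistic genetic map lengths or per-chromosome
recombination variation, and linkage disequilibrium structure beyond the
block mosaic itself. Passing pipeline tests on synthetic panels therefore
demonstrates the algorithms' correctness on data satisfying the block-mosaic
assumptions, not robustness to the noise of real resequencing calls.

## Validation scale and numerical choices

The published genome-scale counts (thousands of dVBs and tens of thousands
of InDels from six resequenced genomes; a 202-marker panel scored on 147
cultivars) derive from data that is not publicly available, so the package
validates structure at desk scale: worked PIC values reproduce the published
panel's range end-points (0.05 for a marker polymorphic in 4 of 147, 0.50
for 76 of 147); filter semantics are checked on a fixture VCF; greedy set
cover is compared with exhaustive search on one hundred 6 x 8 panels;
neighbour joining is checked against fifty random additive matrices of 4–12
taxa (exact topology, 3-taxon branch lengths to 1e-9); the crossover-rate
ratio is re-estimated from 10,000 simulated meioses (within 10% of 6.6);
backcross convergence is measured over 200 BC5-inbred replicates (mean
difference fraction within three standard errors of \((1/2)^6\)); and the
full pipeline runs on a simulated 30-founder, 150-descendant panel, checking
planted-boundary recovery within one window, complete discrimination of all
pairs with homozygous-code differences, and zero pedigree inconsistency for
true trios at zero mutation rate. On recombinant descendants a crossover
inside a dVB legitimately truncates the recovered block, so the two-sided
boundary check applies to non-recombinant founders and a one-sided
containment check to descendants.

Numerical conventions: internal coordinates are 1-based inclusive (the VCF
convention) and the BED writer is the single point of translation to
0-based half-open; multi-allelic VCF records are kept intact so third
alleles survive; all thresholds are inclusive; selection and tree
construction are deterministic for fixed input, with explicit tie-breaks.

## Known limitations

Sequence identity is approximated from variant calls; when consensus
sequences are available, true identity should replace the approximation.
Whether dVB counts should be reported per cultivar or as reference-anchored
loci is ambiguous in the source material — the pipeline's block table
supports both summaries (`blocks` rows are per cultivar; distinct
`type_label`s count loci). The greedy minimal set is not guaranteed optimal
(the exact mode is exponential); unresolved pairs always accompany the
result. Heterozygous calls never contribute to identity, which is the right
default for inbred cultivar panels but loses information in heterozygous
germplasm.
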
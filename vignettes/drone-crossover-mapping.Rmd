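---
title: "Mapping crossovers and scaffolding a genome with haploid drone meioses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping crossovers and scaffolding a genome with haploid drone meioses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dronemap)
```

## The model

A honey bee drone is haploid and carries a single recombinant product of
the queen's meiosis. For a colony of $n$ drones genotyped at the queen's
heterozygous SNPs, the *genotype vector* at a site is the length-$n$
pattern of which queen haplotype each drone inherited. Along a chromosome
this vector changes exactly where some drone's meiosis recombined. Three
consequences drive everything in this package:

1. Maximal runs of sites with the same inheritance pattern (*bins*) are
   segments with no observed crossover; the Hamming distance between
   adjacent phased bin vectors counts crossovers at that junction.
2. Contigs of an assembly can be ordered and oriented along chromosomes by
   minimising the total Hamming distance between the genotype vectors at
   facing contig ends — a genetic map used as a scaffolder.
3. The genetic length of the genome is the total crossover count divided
   by the number of meioses; with 43 drones the honey bee genome measures
   about 50 Morgans over 220 Mb, i.e. 23 cM/Mb.

Two nuisance processes are modelled explicitly. *Non-crossover gene
conversions* switch haplotype over short tracts (typically well under a
few kb) and then switch back, mimicking a double crossover; left in place
they inflate the map. *Genotyping errors* produce isolated single-SNP
bins with the same signature. Both are removed by the conversion filter
(below).

## Phase is only defined up to complementation

Without grand-parental genotypes, the allele labelling of each SNP is
arbitrary: the same inheritance pattern appears at one site as a vector
$v$ and at the next as its complement $\bar v$. Binning therefore groups
consecutive sites whose vectors are identical *up to complementation*
(with missing entries treated as wildcards), and phasing between bins
chooses, left to right, the vector or complement with the smaller Hamming
distance to the previous phased vector — ties keep the unflipped vector.
Because each junction term depends only on its own flip choice, the greedy
scan attains the exhaustive $2^{B-1}$ minimum; the test suite checks this
identity on 200 random instances.

An early version of the binning grouped strictly identical vectors only.
That fragments crossover-free segments at every arbitrary labelling flip;
on simulated data it halved the sensitivity of conversion detection. The
complement-equivalent rule is the only reading under which "a segment
with no observed crossing over" is what a bin actually is.

## Conversion filtering

A bin $B$ with flanks $A, C$ is flagged when its SNP span is below 2 kb
and either (i) $A$ and $C$ are identical — $A$, $B$, $C$ merge into one
bin — or (ii) $H(A,B) + H(B,C) > H(A,C)$ — $B$ is dropped and $A$, $C$
stay adjacent. The scan restarts after every change and stops at a fixed
point; first and last bins are never flagged since they lack two flanks.
The 2 kb threshold is the published detection bound for conversion
tracts; bin length is measured as the span from first to last member SNP,
the only length observable from the data (a single-SNP bin has length 0).

Two properties matter and are tested: flagged-bin removal never increases
the total event count, and — on the default simulation — no true
crossover recovered before filtering is lost by it. Overlapping
independent events (a tract interleaved with another drone's error bin)
produce monotone "staircases" that rule (ii) deliberately leaves alone:
removing them could delete genuine double crossovers. This costs a few
percent of detection sensitivity at realistic error rates and is the main
known limitation of the filter.

## Scaffolding by crossover minimisation

Contig ends carry the first and last phased bin vectors per colony. The
cost of joining two ends is $\min(H(a,b), H(a,\bar b))$ summed over
shared colonies; the relative phase is reconciled across colonies by a
majority vote weighted by each colony's cost margin. Within each a-priori
chromosome group a Kruskal-style chaining repeatedly accepts the cheapest
join between two free ends that neither reuses an end nor closes a cycle,
until one path remains. Ties break on the number of informative
comparisons, then lexicographically, for determinism. Contigs without an
a-priori assignment are adopted by a chromosome when their best end cost
is at most 1 per shared colony — one apparent crossover can be a residual
error, more is unreliable linkage — and are reported `unlocalised`
(chromosome known from one evidence source only); contigs failing both
sources are `unplaced`.

The chaining is a heuristic for a TSP-path problem. An exhaustive solver
(all signed orders, global flip collapsed) validates it for up to 8
contigs; the suite checks agreement on 100 seeded instances generated
with the study's structure — three colonies of 13–15 drones, a few
crossovers per contig per colony, and rare crossovers in the short
repeat-array gaps between contigs. The agreement is *not* an identity for
arbitrary inputs: with a single colony, a contig containing no crossover
at all has identical end vectors, its position is genuinely
under-determined at equal cost, and the greedy chain can take a zero-cost
mis-join. The real study resolves exactly this situation through
boundary tandem repeats: a contig is oriented when the terminal arrays at
its two ends match the facing neighbour arrays by exact period and
rotation/strand-aware monomer identity (default threshold 95%), and the
opposite pairing does not also match.

## The recombination map and the mis-assembly diagnostic

Each drone's bin sequence, projected onto a layout, yields one crossover
event per discordant junction, localised to the interval between the last
SNP of the left bin and the first SNP of the right. Morgans per
chromosome are event counts over meioses (replicates count once, pooled
over colonies); windowed rates distribute each event's unit mass
uniformly over its localisation interval (midpoint assignment would be
the alternative; uniform spreading is the only assumption-free use of the
available information). Mass is conserved exactly:
$\sum_w \text{rate}_w \cdot \text{Mb}_w \cdot N / 100$ equals the event
count.

Intervals between adjacent informative SNPs with strictly more than five
pooled events are flagged as hotspots. On a correct layout the default
simulation produces none. Inverting one multi-crossover contig produces
two such pile-ups exactly at the inversion breakpoints and lengthens the
estimated map — the mechanism by which older, partially mis-assembled
references over-estimated the honey bee recombination rate (37 vs
23 cM/Mb). The acceptance suite reproduces this end to end.

## The simulator

The generator's defaults are the study conditions: three colonies of 15,
15 and 13 drones with three colony-1 drones duplicated; queen-heterozygous
sites at 1 SNP/kb; Poisson crossovers at 23 cM/Mb with no interference
(the study models none); conversion tracts at one per meiosis per
chromosome, geometric with mean 500 bp so most fall under the 2 kb
detection bound; 0.2% genotyping error and 0.1% missingness; and a genome
carrying 131 arrays of a 371 bp-period family and 345 of a 91 bp family,
of which 74 and 43 have strictly more than ten copies, four long
371-family arrays per chromosome exceeding the 10 kb read-length proxy
and breaking the assembly into 20 contigs. Sequence content is uniform
random outside arrays; arrays are tandem monomer copies with 1% per-copy
substitution. Two of the 20 contigs are withheld from the a-priori
assignment table to exercise placement from crossover data alone.

The genome is scaled to four 5 Mb chromosomes (20 Mb) so the full
pipeline runs in a few seconds; this preserves per-contig crossover
densities (≈1 Mb contigs, ≈0.23 crossovers per meiosis per contig). The
simulator does not model read-level artefacts, mapping bias, crossover
interference, diploid workers, or locus-specific error structure — so
passing tests demonstrate correctness of the inference given the model's
assumptions, not robustness to alignment pathologies of real data.

Depth tracks for indel genotyping are Poisson per base: mean $\lambda$
over flanks and over a present indel, $0.02\lambda$ (residual mis-mapping)
over an absent one. The 80-sample panel mirrors the three-subspecies
design (35/30/15 haploids) with two NUMT-like variants of 745 and 576 bp
whose population frequencies are near-fixed differences.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; published 1-based NUMT
  coordinate pairs whose printed lengths equal $end-start$ are ingested
  verbatim, GFF3 exons are shifted on read. This is the one convention
  under which both published NUMT lengths (745, 576 bp) reproduce exactly.
* Rate recovery is evaluated on an 8 × 10 Mb simulated genome. At 43
  meioses the Poisson draw itself has a ≈7% standard error on a 20 Mb
  genome, so a ±10% check there measures the draw, not the estimator; at
  80 Mb the band is ≈3 standard errors and the check has power against
  estimator bias. The estimator itself is the same at any scale.
* 1-D 2-means is solved exactly by split-point enumeration over the
  sorted ratios (optimal 1-D clusters are contiguous); a separation floor
  of 0.3 between centres guards against splitting a monomorphic panel,
  and the higher-centre cluster is always `present`. Diploid samples
  (a heterozygous band near ratio 0.5) are out of scope by default since
  the study's samples are haploid.
* Monomer canonicalisation is the lexicographically least rotation via
  Booth's algorithm — deterministic, order-free, and checkable against
  rotation enumeration. TRF copy numbers are used as reported (fractional;
  10.9 copies counts as "more than ten").
* The cross-colony consistency rule is operationalised as: the colony's
  observed allele set must intersect, and not extend beyond, the union of
  queen alleles seen in the other colonies. It is isolated in one
  predicate so alternative readings can be swapped in.
* AGP gap rows use type `scaffold`, evidence `map`, default length 100 bp;
  the source study states no gap policy.

## Known limitations

Single-colony data cannot support the cross-colony consistency rule
(skipped with a warning) and weakens order determination for
crossover-poor contigs. Conversion tracts overlapping another event
within one inter-SNP window evade the filter by design. Crossovers in the
unassembled gaps between contigs are counted only through the junction
minimisation and are under-counted when more than half the drones
recombine in a gap — negligible at realistic gap sizes. Hotspot pooling
is across colonies; per-colony hotspot calling would need deeper
simulated designs than the defaults.
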
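---
title: "Homologous coverage ratios for genome-based taxonomy screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homologous coverage ratios for genome-based taxonomy screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcr)
```

## The statistic

The homologous coverage ratio (HCR) is an overall genome relatedness index
(OGRI): for two genomes A and B it is the fraction of their combined length
covered by homologous sequence,

$$\mathrm{HCR}(A,B) = \frac{H_A + H_B}{S_A + S_B},$$

where $S_X$ is the total length of genome $X$ and $H_X$ the number of its
bases covered by homologous alignments. Identical genomes score exactly 1;
genomes with no detectable homology score 0. Unlike average nucleotide
identity, which averages the identity of orthologous fragments, the HCR
measures how much of the genomes is homologous at all, so genome-size
changes and repeat expansions move the score in an interpretable direction.

Two estimators are provided, designed for different points on the
speed/precision trade-off:

* **k-mer stage** (`build_kmer_profile()`, `hcr_kmer()`): each genome is
  reduced to its set of distinct k-mers; with $HS_X$ the set size and
  $Hit_X$ the number of $X$'s k-mers found in the other genome's set,

  $$\mathrm{HCR}_{kmer}(A,B) = \frac{Hit_A + Hit_B}{HS_A + HS_B}.$$

  Under this cross-containment reading the score is symmetric, lies in
  $[0,1]$, and equals 1 for identical genomes. It is an approximation —
  k-mer containment is not base-level coverage — but it is fast enough for
  all-vs-all screening of thousands of genomes.

* **alignment stage** (`parse_alignments()`, `hcr_alignment()`): local
  alignments from an external aligner (LAST-style MAF, or 12-column
  BLAST-like tabular output) are filtered at E-value $< 10^{-10}$, projected
  onto both genomes, and the per-genome covered length is measured as an
  interval union, so a locus hit by many alignments counts once and
  $H_X \le S_X$ always. E-values are consumed from the aligner's output,
  never recomputed.

The intended workflow is two-stage: `cmd_scan()` scores every pair with the
k-mer estimator, `candidate_screen()` short-lists taxon pairs whose best
cross-taxon score exceeds the anchored within-taxon maximum, and
`cmd_refine()` re-scores only the short list from real alignments.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 12 | k-mer length. $4^{12} \approx 1.7\times10^7$ keys make chance sharing between unrelated ~Mb genomes negligible (expected spurious matches scale as $n^2/4^k$) while keeping profiles memory-light. Smaller k inflates scores between unrelated genomes; larger k increases sensitivity to SNPs, since one substitution destroys k overlapping k-mers. |
| `canonical` | `TRUE` | Strand-collapses each k-mer to the lexicographic minimum of itself and its reverse complement. Assemblies have arbitrary contig orientation, so this is the right default; the stranded mode exists for oracle testing. |
| `evalue_threshold` | `1e-10` | Strict upper bound: an alignment is homologous only if its E-value is strictly below the threshold. A block at exactly `1e-10` is excluded. |
| `criterion` | `anchored_max` (genus), `min_intra_ratio` (phylum) | Flagging rule, see below. |
| `threshold` | 2 | Ratio threshold for `min_intra_ratio`; 2 for a broad survey, 4 for a stringent short-list. |

## Screening criteria

`taxon_pair_stats()` compares HCR distributions within and across taxon
boundaries at genus or phylum level:

* **anchored criterion** (genus level): a pair is flagged when the best
  cross-taxon HCR strictly exceeds the best within-taxon HCR involving a
  genome of the best cross-taxon pair (the *anchor*). The anchored form asks
  the taxonomically pointed question — does this particular genome resemble
  a foreign genus more than its own? Ties are not flagged. When both genomes
  of the cross-taxon pair have within-taxon partners, the larger of their
  two anchored maxima is used, which keeps the statistic invariant to which
  taxon is labelled first and is conservative about flagging.
* **ratio criterion** (phylum level): flag when
  `max_inter_hcr / min_intra_hcr > threshold`. The within-taxon minimum is
  taken over both taxa of the pair and `taxon_a` is oriented as its owner;
  a minimum of 0 yields an infinite ratio (flagged at any threshold).

Taxa with a single scored genome have undefined within-taxon statistics;
pairs involving them are skipped with a message rather than scored as zero —
undefined is not zero.

A `global` within-taxon maximum (over all within-taxon pairs, not just those
touching the anchor) is available via `intra_variant = "global"` for
sensitivity analysis.

## Ordination

Pairwise scores convert to distances as $d = 1 - \mathrm{HCR}$, the simplest
monotone map sending identical genomes to distance 0 and unrelated genomes
to 1. `classical_mds()` performs metric (Torgerson) multidimensional
scaling — double-centring of squared distances and eigendecomposition, via
`stats::cmdscale` — rather than stress majorisation because it is
deterministic and seed-free. Two numerical conventions make ordinations
reproducible bit-for-bit: each axis is sign-fixed so its largest-magnitude
coordinate is positive, and axes whose eigenvalue is non-positive (or
numerically indistinguishable from zero relative to the leading eigenvalue)
are truncated to exact zeros, so duplicated genomes receive identical
coordinates. $1-\mathrm{HCR}$ is not guaranteed Euclidean-embeddable;
negative eigenvalues simply contribute nothing, as is standard for
classical MDS.

## The synthetic generator

Downloading thousands of assemblies is out of scope, so the package tests
itself on synthetic data with known ground truth:

* `make_pair()` plants `segment_count` non-overlapping segments copied from
  genome A into a random background B, totalling `shared_fraction` of A's
  length, with optional per-base substitutions. Sources and destinations are
  placed one per equal-width block, so the planted per-genome homologous
  fractions are exact and are returned. Copied segments receive
  substitutions only — no indels — so the planted coordinates stay exact and
  `emit_alignment_fixture()` can write a tabular alignment whose expected
  coverage ratio is a closed-form function of the layout.
* `make_taxonomy_fixture()` builds genera as
  `[shared backbone | genus backbone | private tail]`: the leading
  `inter_fraction` of every genome is common to all genera and the genus
  backbone extends it to `intra_fraction`, so within-genus pairs share
  `intra_fraction` and cross-genus pairs `inter_fraction` of their length.
  A planted ambiguity overwrites the post-prefix region of one genome with
  the corresponding region of a genome from another genus, so exactly one
  cross-genus pair shares `ambiguous_fraction > intra_fraction` while its
  genus mates keep their backbone. Default conditions — 3 genera × 3
  genomes, `intra_fraction` 0.6, `inter_fraction` 0.1,
  `ambiguous_fraction` 0.7 — give a clear planted signal well above k-mer
  boundary noise.

All generation is driven by a locally seeded Mersenne-Twister RNG (the
caller's RNG state is restored), so identical seeds give identical genomes
across platforms.

What the generator does *not* emulate: rearrangements, indels, horizontal
transfer into varied genomic contexts, GC skew, repeat families, or
assembly artefacts. Passing the parameter-recovery suite therefore shows
the estimators are correct for planted homology under substitution noise —
it does not certify accuracy on real genomes, where aligner sensitivity and
repeat structure dominate.

## Numerical and edge-case choices

* Coordinates are 0-based half-open internally; tabular 1-based inclusive
  input and MAF start+length (including reverse-strand normalisation against
  the source length) are converted on parse, removing off-by-one ambiguity.
* Overlapping alignment blocks are merged per genome before measuring
  coverage. Merging still credits each distinct repeat locus (repeats occupy
  distinct coordinates) while preventing one locus hit by many alignments
  from being counted twice; it also guarantees $\mathrm{HCR} \le 1$.
* K-mers never span contig boundaries; windows containing any non-ACGT
  symbol are skipped rather than expanded.
* A genome whose every contig is a plasmid, or whose every window contains
  an ambiguous base, cannot be scored and raises an error instead of
  returning 0.
* Plasmid exclusion is by the case-insensitive header token "plasmid",
  matching RefSeq description conventions; no assembly-report metadata is
  consulted.

## Problem sizes in the test suite

The bundled tests run the full pipeline at reduced scale: parameter
recovery uses five 100 kb genome pairs at k = 12 (planted fractions 0.1–0.9
recovered within ±0.05, the slack covering segment-boundary k-mer loss);
oracle-equivalence fuzzing uses 200+ random instances below 10 kb; the
screening pipeline runs on 9–12 genomes of 12–15 kb. These sizes keep the
suite fast while exercising every code path; the estimators themselves are
linear in genome length and have been designed for ~Mb bacterial genomes.

## Known limitations

* The k-mer estimator's absolute values depend on k; they approximate the
  alignment-based HCR but are not interchangeable with it, which is why the
  workflow refines candidates rather than trusting the screen.
* HCR values computed from different aligners (or different aligner
  parameters) are comparable only qualitatively; the package deliberately
  does not bundle an aligner.
* The screening criteria compare extremes (maxima and minima), so a single
  misassembled or mislabelled genome can flag a taxon pair; flagged pairs
  are candidates for inspection, not verdicts.
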
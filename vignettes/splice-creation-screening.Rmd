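---
title: "Screening variants for novel essential splice-site creation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening variants for novel essential splice-site creation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paness)
library(dplyr)
```

## The problem

Standard short-variant interpretation concentrates on coding consequences
and on variants falling inside canonical splice sites. A single-nucleotide
variant (SNV) can instead *create* a new essential splice-site
dinucleotide — a `GT` read 5'→3' on the transcribed strand (a donor) or an
`AG` (an acceptor) — anywhere in or near a gene. Such variants are easy to
dismiss: on the unspliced transcript they may be synonymous or intronic,
yet the spliceosome may engage the new site or lose a canonical one,
skipping an exon and truncating the protein. This package screens existing
VCF data for exactly this class of variant, and provides the downstream
arithmetic (exon-skip frame analysis, HGVS p. notation, trio consistency)
needed to shortlist candidates for experimental follow-up.

## The model

An SNV at position $p$ can only create a dinucleotide that contains $p$,
so exactly two placements are evaluated per variant, both read on the
transcribed strand of each overlapping transcript:

* $(p,\,p+1)$ in transcription order — the variant is the **first** base
  of the putative dinucleotide;
* $(p-1,\,p)$ — the variant is the **second** base.

A placement is a candidate when the alternate dinucleotide equals `GT`
(donor) or `AG` (acceptor) **and** the reference dinucleotide at the
identical placement does not already equal it. Novelty is absolute: the
comparison is at the same placement, never against nearby `GT`/`AG`
occurrences elsewhere (a broader suppression window would conflate
creation with redundancy, which is a different biological question).
Placements involving `N` yield no candidate — undefined sequence cannot
create a defined motif. At most two candidates per (variant, transcript)
can therefore exist, and a variant that overlaps no transcript yields no
rows unless the genome-wide mode is enabled, which evaluates both strands
with no gene context.

Candidates are retained even when they coincide with a canonical junction
(distance 0): the motivating case sits exactly at an exon's 3' end, where
the created acceptor overlaps the canonical donor.

Every emitted candidate carries:

* the **register** (first/second base, as above);
* the transcribed-strand **context** around the variant (a ±10 bp window
  for human review);
* a **consensus similarity** score against the classical mammalian
  splice-site consensus;
* the signed **distance to the nearest canonical site** of the same type.

### Consensus scoring

The consensus model is the classical one: donor `MAG|GTRAGT` (exon −3..−1,
intron +1..+6) and acceptor `YYYYYYYYYYYYNYAG|G` (a 12-base polypyrimidine
tract, `N`, `Y`, the essential `AG`, and the first exonic base — 17
positions in total; the window length is derived from the consensus string
itself). Similarity is the weighted fraction of positions whose base falls
in the IUPAC class at that position. The two essential positions carry
weight 0.25 each; the remaining 0.5 is spread uniformly over the extended
positions. The score is 1 exactly on a full-consensus context and lies in
[0, 1] always. Both consensus strings and the essential weight are
arguments of `consensus_model()`, since the source method specifies *that*
the context is compared with the consensus but not a particular scoring
functional; this weighted IUPAC match is the package's documented default.

### Distances and tie-breaks

Canonical sites are derived from the gene model: each internal junction
contributes a donor (first two intron bases) and an acceptor (last two).
Distance is signed in transcription order, with negative meaning the
candidate lies upstream (5') of the canonical site. Ties in $|d|$ are
broken toward the *upstream* canonical site, purely for determinism.
Models with fewer than two exons have no canonical sites and report `NA`.

### Filtering

The rare-variant gate keeps variants with MAF ≤ 0.001 (the boundary is
kept; the comparator is configurable because the literature uses both
strict and non-strict forms). A variant with *no* frequency record passes
by default: an allele never observed in a large aggregation database is
rarer than any practical threshold, and conflating "absent" with
"frequency zero" would be a category error. The effect-class and
annotation-score screens are deliberately liberal — a variant lacking an
annotation is never excluded by it — because they are for screening, not
classification. Trio filtering implements two Mendelian patterns:
autosomal recessive (proband homozygous alternate, both parents
heterozygous carriers) and de novo dominant (heterozygous proband,
homozygous-reference parents); missing genotypes fail the pattern by
default and can be promoted to errors.

## Exon-skip consequences

The skip event itself is taken as given (it is what experiments such as
junction-spanning RT-PCR establish); the package computes only its
consequence. Only the coding portion of the skipped exon counts toward
frame arithmetic: a UTR-only exon is "no protein change", and a coding
length divisible by 3 preserves the frame. The reference and skipped
transcripts are spliced, translated, and diffed:

* frameshifts are reported as `p.(Xnnn YfsTer k)` with HGVS counting — the
  first altered residue is position 1, so `Ter23` places the stop at
  position 23 of the shifted frame; a frameshift whose first shifted codon
  is already a stop is reported as nonsense `p.(XnnnTer)`;
* in-frame skips are reported as deletions `p.(Xnnn_Ymmmdel)`, or
  `delins` when the junction codon changes.

A nonsense-mediated decay flag is set when the predicted stop lies ≥ 50 nt
upstream of the last exon–exon junction of the skipped transcript — the
standard boundary rule; it is a heuristic, not a degradation prediction.

```{r worked-example}
we <- synthetic_worked_example()
scan <- run_paness(mutate(we$variant, maf = af), we$genome, we$models)
tidy(scan) |> select(pos, site_type, register, consensus_score, dist_to_canonical)
predict_exon_skip(we$genome, we$models[1, ], 11)
```

`synthetic_worked_example()` is a stand-in transcript constructed entirely
from published constraints (13 exons; a 103 bp exon 11 ending at coding
position 1287 in a `GAG` codon so the G>A change is synonymous on the
unspliced transcript; a frameshift starting at residue 396 with the stop
at offset 23; a premature stop far upstream of the last junction). It is
*not* the RefSeq transcript — building the real fixture requires a genome
and annotation download — but every number above is pinned by tests.

## What the synthetic data emulate — and what they do not

The fixture generator produces a random genome, places non-overlapping
transcripts with canonical `GT`/`AG` introns and valid CDSs, and plants
variants whose candidate status is *verified at plant time* by a
deliberately naive brute-force oracle kept separate from the production
scanner. Defaults are chosen once as a plausible compact-genome toy scale:
2–8 exons of 60–160 bp, introns of 80–150 bp, transcripts ≥ 300 bp apart
(so the 100 bp transcript margin can never make a variant ambiguous
between models), planted rare alleles at U(1e−6, 1e−3) with 30% missing
frequency records, and common alleles at U(0.002, 0.5) to exercise the
MAF gate.

A green test on this world establishes that the scanner finds exactly the
dinucleotide creations that exist, on either strand, with correct
registers, spans, distances, and filtering. It does **not** establish
anything about real splice-site usage: the generator has no splicing
regulatory realism (no branch points, no splice enhancers/silencers, no
usage probabilities), no linkage or mutation-rate structure, and no
sequencing error. Those are outside the method's claim, which is an exact
combinatorial screen plus a consensus comparison.

## Numerical and design choices

* **Coordinates** are 1-based closed throughout, the native convention of
  VCF, GTF and R/Bioconductor. (An alternative two-convention design with
  a 0-based interior was considered and rejected: with a single convention
  there is no boundary to get wrong, and the exhaustive oracle-equivalence
  test over all SNVs of a fixture genome covers the off-by-one risk
  directly.)
* **Out-of-bounds context windows** (candidate too close to a contig end
  to extract the consensus-length window) skip that candidate with a
  counted warning rather than clipping — a clipped context would be
  silently incomparable with the consensus.
* **Determinism**: reports are sorted by (chrom, pos, transcript, site
  type, register); fixture files embed their seed as a header comment; no
  data file contains a timestamp. Identical inputs give byte-identical
  outputs.
* **Degenerate inputs**: multi-allelic VCF records are split per alt
  allele with allele-matched `Number=A` INFO fields; non-SNV alleles are
  dropped and counted; structurally invalid gene models are rejected
  individually with a warning rather than failing the run; a single bad
  record never aborts a scan.
* **Genes overlapping on both strands** are evaluated independently per
  transcript; duplicate rows across transcripts are intended and keyed by
  `transcript_id`.

## Known limitations

* Splice-site *destruction* (weakening of existing sites) is out of scope,
  as are extended-site creation without the essential dinucleotide,
  branch-point and splice-enhancer effects, and learned splice-strength
  models.
* Only single-exon skips are modelled; intron retention, partial-exon
  truncation and multi-exon skips are not.
* Conservation and pathogenicity scores are consumed as annotations, never
  recomputed.
* The trio logic covers autosomal recessive and de novo dominant patterns
  only; X-linked and compound-heterozygous models are not implemented.
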
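# paness

Screen single-nucleotide variants for **novel essential splice-site
creation**: SNVs whose alternate allele creates a `GT` (donor) or `AG`
(acceptor) dinucleotide, read on the transcribed strand, at a placement
where the reference does not already carry that dinucleotide. Such variants
can look harmless under standard annotation — synonymous, intronic, low
pathogenicity scores — while actually rerouting splicing and truncating the
protein. The package is aimed at rare-disease researchers re-mining
existing exome/genome VCFs for cryptic splice candidates.

## What it computes

For a variant at position $p$ only the two dinucleotide placements
containing $p$ can be created, $(p, p+1)$ and $(p-1, p)$ in transcription
order. For each transcript overlapping the variant (± a configurable
margin), the scanner tests both placements on the transcribed strand and
emits a candidate when the alternate pair reads `GT` or `AG` **and** the
reference pair at the identical placement differs — novelty is absolute.
Candidates are reported with:

* the **register** — whether the variant is the first or second base of
  the new dinucleotide;
* a similarity score in [0, 1] against the classical splice consensus
  (donor `MAG|GTRAGT`, acceptor `YYYYYYYYYYYYNYAG|G`), with the essential
  positions weighted 0.25 each and the extended positions sharing the
  remaining weight uniformly;
* the signed distance (bp, transcription order) to the nearest canonical
  site of the same type;
* the minor allele frequency, gated at MAF ≤ 0.001 by default (missing
  frequency records pass — an unseen allele is rarer than the threshold).

Companion tools predict the protein consequence of skipping one exon
(frame arithmetic, HGVS `p.` notation with `fsTer` stop counting, a
50-nt-rule NMD flag), filter trios for autosomal-recessive or de novo
dominant patterns, and generate fully synthetic genomes, gene models and
planted trio VCFs with ground truth so everything is testable offline.

## Worked example

```r
library(paness)
library(dplyr)

fx <- cmd_make_fixtures(tempfile(), seed = 42, genome_length = 20000,
                        n_transcripts = 10, n_creations = 20, n_nulls = 20,
                        n_recessive = 5)
scan <- cmd_scan(fx$vcf, fx$fasta, fx$gtf, out_dir = tempdir())
#> scan: 21 candidate row(s) from 20 variant(s)

tidy(scan) |>
  select(chrom, pos, ref, alt, maf, site_type, register, consensus_score)
#> # A tibble: 21 × 8
#>   chrom   pos ref   alt        maf site_type register            consensus_score
#>   <chr> <int> <chr> <chr>    <dbl> <chr>     <chr>                         <dbl>
#> 1 chr1   1036 A     T     0.000697 donor     variant_is_second_…           0.643
#> 2 chr1   1358 G     T     0.000672 acceptor  variant_is_first_b…           0.8
#> 3 chr1   1695 T     C     0.000738 donor     variant_is_first_b…           0.643
#> 4 chr1   1715 G     A     0.000452 donor     variant_is_second_…           0.714
#> # ℹ 17 more rows
```

All 20 planted splice-creating variants are recovered (21 rows: one
variant creates a site in both registers); the 20 planted null variants
and every allele above the MAF gate produce nothing. `glance(scan)` gives
the stage counts, `autoplot(scan)` the score distributions, and
`write_candidates()` / `cmd_scan()` emit a deterministic TSV report.

The exon-skip consequence of the bundled synthetic worked-example
transcript (a SERCA1-like model built from published constraints — 13
exons, a 103 bp exon 11 whose final-base G>A is synonymous yet creates an
acceptor across the donor junction):

```r
we <- synthetic_worked_example()
predict_exon_skip(we$genome, we$models[1, ], 11)
#> <exon_skip> ATP2A1_like_tx1 exon 11 (103 bp, 103 coding)
#>   frameshift: p.(Leu396ProfsTer23)
#>   NMD flag: TRUE
```

Skipping the 103 bp exon shifts the frame at Leu396 (to Pro) with a stop
at position 23 of the new frame, and the premature stop lies far enough
upstream of the last junction to flag nonsense-mediated decay.

A thin shell wrapper lives at `exec/paness`
(`paness scan|trio|consequence|make-fixtures`, see `--help`-style header
comments in the script).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline's guarantees from scratch against the installed
package: it generates a seeded synthetic universe (15 transcripts, 200
planted creations, 200 nulls, 20 common alleles), scans it and compares
against the planted truth, applies the autosomal-recessive trio filter,
predicts the worked-example exon-skip consequence, and cross-checks the
vectorised scanner against an independent brute-force oracle on both
strands, then writes the JSON report to `--out`.

## Scope

Splice-site *destruction*, branch-point/enhancer effects, learned splice
models, multi-exon skips and recomputation of conservation/pathogenicity
scores are out of scope; see the vignette
(`vignettes/splice-creation-screening.Rmd`) for the model, parameter
defaults, tie-break rules and limitations.
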
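---
title: "Pooled amplicon screening of EMS mutant libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled amplicon screening of EMS mutant libraries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amptill)
```

## The screening problem

A reverse-genetics (TILLING) screen asks: given a library of chemically
mutagenized plants, which individuals carry a point mutation in a gene of
interest, and does that mutation change the protein? `amptill` models the
sequencing-based variant of this screen: target genes are PCR-amplified from
two-tier DNA pools — four plants per first-tier pool, four such pools per
dual-indexed second-tier pool, so 16 plants share one sequencing index —
and sequenced deep enough that a single heterozygous mutant contributes a
detectable allele fraction of $1/(2 \times 16) = 1/32$ per pool. Calls are
deconvolved back to the carrier plant through the pooling layout and a final
per-plant confirmation step.

Because real screens of this design cannot be rerun at desk scale, the
package pairs every analysis component with a synthetic-data generator whose
ground truth is known, so the whole pipeline can be benchmarked end to end.

## The population model

The library emulates a selfing species mutagenized twice with EMS:

* **Round 1** mutations are drawn once per M1 family (default 4 library
  plants per family) and transmitted to each descendant independently with
  probability 3/4; carriers are homozygous:heterozygous = 1:2 (one selfing
  generation). This creates the *duplicated mutations* seen when several
  library lines descend from one mutagenized ancestor.
* **Round 2** mutations are drawn independently per plant and are carried
  het:hom = 2:1.

Only the crossing scheme is published, not the transmission arithmetic;
this is the simplest Mendelian reading and is the package's own design
choice. The fraction of observed mutations contributed by each round is
likewise not published; the default splits the observed per-plant count
50:50, which fixes the drawn densities at `target/2/genome` (round 2) and
`target/2/0.75/genome` (round 1) — see `default_per_round_density()`. The
default target of 12,796 observed mutations per plant over a
950,068,807 bp genome reproduces the whole-genome survey average (about one
change per 74 kb).

Substitution types follow a 12-class spectrum. The default is the
genome-wide EMS spectrum of the surveyed library (G>A and C>T transitions
together ~69%); the printed percentages sum to 100.1 because of rounding
and are renormalized to 1. Sites are drawn uniformly among positions whose
reference base matches the class's source base; colliding draws within a
line or family are redrawn, with a hard cap (100x the target count) that
turns pathological densities into an error rather than a silent bias.

## The read model

Pooled paired-end sequencing is simulated per indexed pool:

* Fragments ~ Normal(450, 50) bp, truncated to `[read_length, amplicon]`;
  250 bp mates are read from both fragment ends. Each fragment picks one of
  the pool's 2 x 16 haplotypes uniformly, so allele-fraction expectations
  (1/32 het, 1/16 hom for a single carrier) hold by construction.
* Fragment orientation is random, as transposase-based library preparation
  inserts adaptors in either orientation. This matters: with fixed
  orientation, amplicon ends would be covered by one strand only and true
  edge mutations would be rejected by the both-strand rule as a pure
  simulator artifact.
* Per-position depth varies by a seeded multiplicative log-normal field
  smoothed over ~50 bp (dispersion 0.5 by default), with tapered amplicon
  ends, emulating the non-uniform coverage observed in real pools.
* Base errors are i.i.d. substitutions (default 0.002/base); qualities are
  a constant Phred profile (default Q35). PCR chimeras, indels and
  primer artifacts are out of scope.

A green benchmark therefore establishes that the thresholds, pooling
arithmetic and deconvolution logic are correct under these idealizations —
not that the pipeline is robust to indels, chimeric reads, index hopping or
quality-correlated error, which real data exhibit.

## Read cleaning and alignment

Cleaning mirrors stringent resequencing practice: 3 nt removed from each
read end, modified-Mott quality trimming at an error-probability limit of
0.01, at most two ambiguous bases per read, and discarding the whole pair
when either mate drops below 50 bp.

Alignment is deliberately gapless: EMS induces single-base substitutions
and indels are excluded from calling, so a 31-mer seed plus ungapped
extension suffices. A read is accepted when at least 90% of it aligns with
at least 96% identity; reads with ambiguous seeds are dropped as
non-specific, and pairs with one failing mate are excluded. Ties between
equally good placements go to the leftmost; in practice toy references have
unique 31-mers.

One consequence of the fixed 3-nt end trim is a structural blind spot: the
3 terminal bases of an amplicon can never be covered by a trimmed read. The
benchmark therefore reports sensitivity over the callable interior and
counts shadowed mutations separately (`n_shadow`).

## The pool caller

A column yields a PASS call for an alternate base iff

* coverage >= 96 reads,
* alternate reads >= 2 and alternate fraction >= 2/96,
* at least one alternate read on each strand,
* quality gates hold: contributing base Q >= 20, mean Q >= 15 in a +/-5 bp
  window, and <= 2 mismatches against the reference in that window
  (failing reads count toward coverage but not toward alternate counts).

The minimum frequency default is exactly 2/96 (2.083%), not the published
2.1%: the setting is documented as corresponding to "two reads among 96",
and the literal 2.1% would reject that limiting case. The literal value is
available via `caller_config(min_frequency = 0.021)`.

The published screens used a proprietary probabilistic caller whose model
is not described; `amptill` replaces its "variant probability" with
allele-fraction thresholds (a documented stand-in, also flagged in VCF
headers). The per-line stringent (coverage >= 5, fraction >= 0.40, both
strands) and relaxed (coverage >= 2, fraction >= 0.10, <= 4 alleles) sets
used to build the background filter are threshold stand-ins in the same
way. Whether the window gates apply per read or per window is unpublished;
per-window-per-read was chosen. `detection_power()` gives the exact
binomial probability of a PASS call for a true mutant or for a null column
probed at `error_rate/3` per alternate base.

## Background polymorphisms

Library cultivar and reference genome differ at many sites that look like
shared "mutations". A variant present in at least 20% of compared units
(with an absolute floor of 2 units, so a singleton is never "common") is
treated as background and removed. Relaxed call sets feed the filter so
borderline polymorphisms missed by stringent calling are still caught. The
comparison is >= (the published description does not say strict or not).
Genuinely duplicated induced mutations that recur in >= 20% of units are
removed too — the published procedure cannot distinguish them either; the
simulation measures this loss rather than hiding it. Units are lines in
whole-genome mode; applying the same idea to indexed pools is this
package's extension.

## Effect annotation

Mutations are mapped into the spliced CDS honoring strand and GFF3 phase,
the affected codon is recomputed under the standard nuclear code, and the
effect is classified synonymous / missense / nonsense / stop_loss /
noncoding, with labels in the conventional "Asp20Asn" style ("Syn" for
synonymous, "*" for a gained stop). Start-codon changes are ordinary
codon-1 substitutions (screen reports list "Met1Ile" as plain missense);
stop-loss is kept as its own class so missense counts keep their usual
meaning; intronic/UTR positions are noncoding. Partial CDS (length minus
phase not divisible by 3) annotate with a warning flag.

## Statistics and reports

All report rounding is half-away-from-zero at the printed precision, which
reproduces every published worked example (e.g. 18 unique mutations in
1144 bp = 15.7/kb; 950,068,807/12,796 = 74.2 ~ 74 kb). Two choices worth
stating:

* In the two-method detection comparison, the totals row averages per-gene
  percentages (unweighted) rather than pooling counts; pooled counts give
  59.8%/89.7% where the published table prints 62.5%/90.3%, which match
  the mean of the per-gene values. The pooled variant is still emitted as
  attributes for transparency.
* kb distances are reported both at one decimal and as integers, matching
  mixed published usage. One published per-line distance (95.7 for 9,934
  changes) differs from the formula by one rounding unit; the formula wins.

## Benchmark and its honest limits

`run_benchmark()` runs simulate -> trim -> align -> call -> deconvolve ->
confirm per seed. Confirmation is an error-free genotype lookup (direct
sequencing is treated as ground truth; a noisy variant is deliberately not
the default). Sensitivity counts (mutation, plant) pairs recovered with
the correct plant; FDR counts PASS calls confirmed by no candidate plant.
In the noiseless high-depth limit the pipeline reaches sensitivity 1.0 and
FDR 0 over the callable interior, and at realistic error (0.002) and
~50x per-sample depth it recovers the configured mutation density within
10%. The test suite runs these criteria at reduced scale (tens of plants,
two toy amplicons, 1-3 seeds) to stay within its time budget; the
simulation parameters are otherwise the stated ones, with toy-genome
densities raised so that expected event counts give statistical power —
the genome-wide density would plant essentially zero mutations on a 1 kb
toy genome.

## Defaults at a glance

| parameter | default | unit | rationale |
|---|---|---|---|
| plants / tier-1 / tier-2 | 1536 / 4 / 4 | — | published pooling design |
| i7 x i5 labels | 12 x 8 | — | 96 dual indexes |
| per-plant mutations | 12,796 | changes | whole-genome survey average |
| genome size | 950,068,807 | bp | chromosome-scale assembly |
| M1 family size | 4 | plants | four M2 seeds kept per M1 plant |
| round split | 50:50 | — | unpublished; package choice |
| read length | 250 | bp | paired-end MiSeq chemistry |
| pool depth | 800 | x | ~50x per sample x 16 |
| error rate | 0.002 | /base | typical post-filter substitution rate |
| depth dispersion | 0.5 | log-sd | qualitative non-uniformity |
| caller | 96 / 2 / 2/96 / both strands | — | published thresholds |
| background threshold | 20% (floor 2) | of units | published filter |
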
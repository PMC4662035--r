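# amptill

Simulation and analysis toolkit for **TILLING-by-sequencing**: retrieving
point mutants from a chemically mutagenized (EMS) plant library by indexed,
two-tier pooled amplicon sequencing.

## Who this is for

Groups designing or benchmarking sequencing-based mutant screens of selfing
crop libraries. A typical design pools 1536 plants as 384 first-tier pools
of 4 and 96 dual-indexed pools of 16; target genes are amplified per pool
and sequenced deep. A single heterozygous mutant contributes one of the
`2 x 16 = 32` chromosome copies of its pool, so its expected allele
fraction is **1/32** — the screen's entire statistical problem is telling
that low-frequency allele from sequencing error, then mapping it back to
the carrier plant.

## What the package computes

* **Synthetic library** — a doubly mutagenized selfing population with a
  12-class EMS substitution spectrum (G>A/C>T transitions ~69%), M1-family
  shared ("duplicated") mutations, Mendelian het/hom states, the two-tier
  pooling layout with 12 x 8 dual indexes, and pooled paired-end reads with
  non-uniform depth, i.i.d. base errors and a known truth VCF.
* **Read QC + alignment** — end trimming (3 nt), modified-Mott quality
  trimming (limit 0.01), ambiguous-base and pair-length rules; gapless
  31-mer-seeded alignment (aligned fraction >= 0.9, identity >= 0.96) into
  per-pool stranded pileups.
* **Pool variant caller** — a PASS call needs coverage >= 96, alternate
  reads >= 2, frequency >= 2/96, both strands, and per-read quality gates.
  `detection_power()` gives the exact binomial probability of calling a
  mutant at fraction *f*: `P = sum_k Binom(k; cov, f) [k>=2] [k/cov>=2/96]
  (1 - 2 * 0.5^k)`.
* **Background filter** — variants shared by >= 20% of compared units are
  cultivar-vs-reference polymorphisms, not induced mutations.
* **Effect annotation** — spliced-CDS, strand-aware codon recomputation:
  synonymous / missense / nonsense / stop_loss with "Asp20Asn"-style labels.
* **Statistics** — deduplication across lines, mutations/kb, kb between
  changes, expected mutations per plant, spectrum summaries with Ts/Tv,
  two-method detection comparison tables.
* **Deconvolution + benchmark** — pool call -> 16 candidate plants ->
  genotype confirmation; end-to-end sensitivity/FDR/density recovery
  against simulation truth.

## Worked example

```r
library(amptill)

ref <- build_toy_reference(n_genes = 2, gene_length = 300, seed = 7)
pop <- simulate_population(ref, n_plants = 32,
                           per_round_density = c(2e-3, 2e-3), seed = 7)
lay <- assign_indexes(build_layout(32))
cfg <- read_sim_config(read_length = 150, mean_depth_per_pool = 1600,
                       error_rate = 0.002, frag_mean = 300, frag_sd = 40,
                       seed = 7)
sim <- simulate_pool_reads(ref, pop, lay, cfg)
sim
#> pool_read_sim: 2 pools, 10240 read pairs, 142 truth events

scr <- screen_pools(sim)  # trim + align + call per pool
pass <- scr$calls[scr$calls$filter_status == "PASS", ]
head(pass[, c("pool_id", "seq_name", "pos", "ref", "alt",
              "coverage", "frequency")], 3)
#>    pool_id seq_name pos ref alt coverage frequency
#> 12 pool_01    amp01  35   C   T      875    0.0571
#> 13 pool_01    amp01  38   C   T      889    0.0259
#> 19 pool_01    amp01  60   G   A      964    0.0415

table(annotate_effect(pass, ref)$effect)
#>   missense  noncoding   nonsense synonymous
#>         41         36          3         16

# a PASS frequency near 1/32 = 0.031 is one heterozygous plant; near
# 1/16 = 0.062 one homozygous plant (or two het). Deconvolve + confirm:
cand <- deconvolve(pass$pool_id[1], lay)    # the pool's 16 candidates
geno <- data.frame(line_id = sim$truth$line_id,
                   seq_name = sim$truth$amplicon_id,
                   pos = sim$truth$amp_pos, alt = sim$truth$alt,
                   zygosity = sim$truth$zygosity)
confirm_by_genotype(pass[1, ], cand, geno)
#>   plant_id zygosity
#> 1    L0016      hom

1 / min_detectable_allele_fraction(16, "het")
#> [1] 32            # reads needed for one expected mutant read
detection_power(16, "het", coverage = 96, error_rate = 0)
#> [1] 0.6064529     # P(PASS) for a het mutant at exactly 96x
```

The last number is why real screens aim for several hundred reads per
pool: at the minimum coverage of 96 a heterozygous mutant is called only
~61% of the time, while at 800x per pool the power is effectively 1.

## Command line

```sh
exec/amptill simulate --out sim --plants 64 --seed 1
exec/amptill call --reference sim/reference.fasta --fastq-dir sim/fastq \
                  --layout sim/layout.csv --out sim/calls.vcf
exec/amptill --help     # all ten subcommands
```

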
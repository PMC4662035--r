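test_that("toy reference construction is valid and seeded-deterministic", {
  ref <- build_toy_reference(2, 300, seed = 7)
  expect_s3_class(ref, "reference_set")
  expect_length(ref$sequences, 2L)
  expect_setequal(unique(ref$gene_models$strand), c("+", "-"))

  # every gene translates to M...* with no internal stop
  for (g in unique(ref$gene_models$gene_id)) {
    rows <- ref$gene_models[ref$gene_models$gene_id == g, ]
    cds <- amptill:::gene_cds(rows, ref$sequences[[rows$seq_name[1]]])
    expect_false(cds$partial)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds$cds)))
    expect_identical(substr(prot, 1, 1), "M")
    expect_identical(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_identical(sum(strsplit(prot, "")[[1]] == "*"), 1L)
  }

  # byte-identical FASTA/GFF3 across runs with the same seed
  d1 <- withr::local_tempdir()
  r1 <- build_toy_reference(2, 300, seed = 7)
  r2 <- build_toy_reference(2, 300, seed = 7)
  f1 <- file.path(d1, "a.fasta"); g1 <- file.path(d1, "a.gff3")
  f2 <- file.path(d1, "b.fasta"); g2 <- file.path(d1, "b.gff3")
  write_reference(r1, f1, g1)
  write_reference(r2, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))

  expect_error(build_toy_reference(0, 300, seed = 7))
  expect_error(build_toy_reference(1, 59, seed = 7))
  expect_error(build_toy_reference(1, 301, seed = 7))  # not divisible by 3
})

test_that("population simulation follows the selfing transmission model", {
  ref <- build_toy_reference(2, 300, seed = 1)
  # many 2-plant families; round-1 mutations should appear in a sibling
  # with probability 3/4 (Monte-Carlo check against the stated model)
  pop <- simulate_population(ref, n_plants = 600, m1_family_size = 2,
                             per_round_density = c(3e-3, 1e-6), seed = 11)
  r1 <- pop[pop$origin == "round1", ]
  expect_gt(nrow(r1), 300)
  fam_of <- attr(pop, "family")
  key <- paste(r1$seq_name, r1$pos, r1$alt)
  shared <- vapply(seq_len(nrow(r1)), function(i) {
    sibs <- names(fam_of)[fam_of == r1$family[i] & names(fam_of) != r1$line_id[i]]
    any(r1$line_id %in% sibs & key == key[i])
  }, logical(1))
  p_hat <- mean(shared)
  se <- sqrt(0.75 * 0.25 / nrow(r1))
  expect_lt(abs(p_hat - 0.75), 3 * se + 0.02)
  # zygosity among carriers ~ hom:het = 1:2
  p_hom <- mean(pop$zygosity == "hom")
  expect_lt(abs(p_hom - 1 / 3), 3 * sqrt(2 / 9 / nrow(pop)) + 0.01)
})

test_that("per-plant mutation counts match the binomial expectation", {
  ref <- build_toy_reference(2, 300, seed = 1)
  dens <- c(2e-3, 2e-3)
  expected <- expected_mutations_per_plant(ref, dens)
  counts <- numeric(0)
  for (s in 1:5) {
    pop <- simulate_population(ref, n_plants = 64, per_round_density = dens,
                               m1_family_size = 4, seed = s)
    counts <- c(counts, as.numeric(table(factor(pop$line_id,
                                                levels = attr(pop, "line_ids")))))
  }
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.05 * expected)
})

test_that("drawn substitutions match the reference and the spectrum", {
  ref <- build_toy_reference(2, 300, seed = 2)
  spec <- spectrum_model()
  pop <- simulate_population(ref, n_plants = 1000, m1_family_size = 4,
                             per_round_density = c(8e-3, 8e-3), seed = 5,
                             spectrum = spec)
  expect_gt(nrow(pop), 10000)
  expect_true(all(substr(ref$sequences[pop$seq_name], pop$pos, pop$pos) == pop$ref))
  # class proportions within sampling error of configured values (classes
  # are drawn from the spectrum, then an eligible site is chosen)
  cls <- factor(paste0(pop$ref, ">", pop$alt), levels = names(spec))
  p_obs <- as.numeric(table(cls)) / nrow(pop)
  for (k in seq_along(spec)) {
    se <- sqrt(spec[k] * (1 - spec[k]) / nrow(pop))
    expect_lt(abs(p_obs[k] - spec[k]), 4 * se + 0.005)
  }
})

test_that("impossible spectra and collisions are handled", {
  seqs <- c(amp01 = strrep("AT", 150))
  gm <- data.frame(gene_id = character(0), seq_name = character(0),
                   strand = character(0), start = integer(0),
                   end = integer(0), phase = integer(0))
  ref <- reference_set(seqs, gm)
  spec <- spectrum_model(stats::setNames(c(1, rep(0, 11)),
                                         c("G>A", setdiff(amptill:::SUBSTITUTION_CLASSES, "G>A"))))
  expect_warning(
    pop <- simulate_population(ref, n_plants = 4, spectrum = spec,
                               per_round_density = c(1e-2, 1e-2), seed = 1),
    "no eligible"
  )
  expect_identical(nrow(pop), 0L)
  # density far above the number of sites cannot be placed
  ref2 <- build_toy_reference(1, 60, seed = 1, flank = 5, introns = 0)
  expect_error(
    simulate_population(ref2, n_plants = 2, per_round_density = c(5, 5),
                        seed = 1),
    "collision"
  )
})

test_that("population simulation is reproducible and leaves the RNG alone", {
  ref <- build_toy_reference(2, 300, seed = 1)
  set.seed(42); before <- runif(1)
  p1 <- simulate_population(ref, n_plants = 32, per_round_density = 2e-4, seed = 9)
  p2 <- simulate_population(ref, n_plants = 32, per_round_density = 2e-4, seed = 9)
  expect_identical(p1, p2)
  set.seed(42)
  expect_identical(runif(1), before)
})
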
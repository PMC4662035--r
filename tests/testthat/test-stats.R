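test_that("deduplication collapses the published worked example to 18", {
  rec <- table3_records()
  dd <- deduplicate(rec)
  expect_identical(nrow(rec), 26L)
  expect_identical(nrow(dd$unique), 18L)
  expect_identical(nrow(dd$groups), 6L)
  expect_identical(dd$groups$letter, letters[1:6])
  # all-distinct input is unchanged; same pos, different alt not collapsed
  solo <- data.frame(seq_name = "s", pos = c(1L, 2L), alt = c("A", "A"),
                     line_id = c("x", "y"))
  expect_identical(nrow(deduplicate(solo)$unique), 2L)
  two_alt <- data.frame(seq_name = "s", pos = c(5L, 5L), alt = c("A", "T"),
                        line_id = c("x", "y"))
  expect_identical(nrow(deduplicate(two_alt)$unique), 2L)
  # idempotent
  again <- deduplicate(dd$unique)
  expect_identical(nrow(again$unique), nrow(dd$unique))
})

test_that("density, distance, and per-plant expectation formulas", {
  expect_identical(mutation_density_per_kb(18, 1144), 15.7)
  expect_identical(mutation_density_per_kb(0, 1000), 0)
  expect_identical(mutation_density_per_kb(1, 1000), 1)

  d <- distance_between_changes(12796)
  expect_identical(d$kb, 74.2)
  expect_identical(d$kb_int, 74)
  expect_identical(distance_between_changes(21861)$kb, 43.5)
  expect_identical(distance_between_changes(21861)$kb_int, 43)
  expect_identical(distance_between_changes(8970)$kb, 105.9)
  expect_identical(distance_between_changes(8970)$kb_int, 106)
  expect_error(distance_between_changes(0))

  expect_identical(expected_per_plant(561, 30269), 11464)
  expect_identical(expected_per_plant(0, 30269), 0)
  expect_identical(expected_per_plant(1000, 500, 1e6, 100),
                   2 * expected_per_plant(1000, 500, 1e6, 200))
})

test_that("minimum detectable allele fraction by pool size and zygosity", {
  expect_identical(min_detectable_allele_fraction(16, "het"), 1 / 32)
  expect_identical(min_detectable_allele_fraction(4, "het"), 1 / 8)
  expect_identical(min_detectable_allele_fraction(16, "hom"), 1 / 16)
  expect_error(min_detectable_allele_fraction(0, "het"))
})

test_that("spectrum summary reproduces the genome-wide aggregate numbers", {
  # pairwise totals from the whole-genome survey; each directed class of a
  # complementary pair gets half (summary is asserted at pair level)
  pair_tot <- c("G>A" = 53240, "C>T" = 53240, "T>A" = 13653, "A>T" = 13653,
                "T>C" = 3813, "A>G" = 3813, "G>T" = 2991, "C>A" = 2990,
                "A>C" = 2289, "T>G" = 2289, "C>G" = 792, "G>C" = 791)
  muts <- data.frame(
    ref = rep(substr(names(pair_tot), 1, 1), pair_tot),
    alt = rep(substr(names(pair_tot), 3, 3), pair_tot),
    stringsAsFactors = FALSE)
  ss <- spectrum_summary(muts)
  expect_identical(ss$total, 153554L)
  expect_identical(ss$transitions, 114106L)
  expect_identical(ss$transversions, 39448L)
  expect_identical(ss$ts_tv_ratio, 2.89)
  expect_identical(unname(round_half_away(
    100 * (ss$counts[["G>A"]] + ss$counts[["C>T"]]) / ss$total, 1)), 69.3)
  # percentages sum to ~100 and a single mutation gives NA ratio
  expect_lt(abs(sum(ss$percentage) - 100), 0.3)
  one <- spectrum_summary(data.frame(ref = "G", alt = "A"))
  expect_true(is.na(one$ts_tv_ratio))
  expect_identical(unname(one$percentage[["G>A"]]), 100)
})

test_that("multinomial sampling at the default spectrum recovers proportions", {
  set.seed(3)
  spec <- spectrum_model()
  n <- 10000
  draws <- sample(names(spec), n, replace = TRUE, prob = spec)
  muts <- data.frame(ref = substr(draws, 1, 1), alt = substr(draws, 3, 3),
                     stringsAsFactors = FALSE)
  ss <- spectrum_summary(muts)
  for (k in names(spec)) {
    se <- sqrt(spec[[k]] * (1 - spec[[k]]) / n)
    expect_lt(abs(ss$counts[[k]] / n - spec[[k]]), 3 * se + 1e-3)
  }
})

test_that("detection comparison reproduces the five-gene table and totals", {
  cs <- table5_call_sets()
  cmp <- compare_detection(cs$a, cs$b, cs$regions)
  g1 <- cmp[cmp$gene_id == "Glyma20g25000", ]
  expect_identical(g1$total, 37L)
  expect_identical(g1$pct_a, 48.6)
  expect_identical(g1$pct_b, 89.2)
  tot <- cmp[cmp$gene_id == "Total", ]
  expect_identical(tot$total, 107L)
  expect_identical(tot$pct_a, 62.5)
  expect_identical(tot$pct_b, 90.3)
  # the pooled-count variant is reported separately and differs
  expect_identical(attr(cmp, "pct_a_pooled"), 59.8)
  expect_identical(attr(cmp, "pct_b_pooled"), 89.7)
  # totals are consistent per gene
  expect_true(all(cmp$total == cmp$common + cmp$a_only + cmp$b_only))
})

test_that("detection comparison is symmetric under swapping methods", {
  cs <- table5_call_sets()
  ab <- compare_detection(cs$a, cs$b, cs$regions)
  ba <- compare_detection(cs$b, cs$a, cs$regions)
  expect_identical(ab$pct_a, ba$pct_b)
  expect_identical(ab$a_only, ba$b_only)
  # identical call sets -> 100% everywhere
  same <- compare_detection(cs$a, cs$a, cs$regions)
  expect_true(all(same$pct_a == 100 & same$pct_b == 100))
})

test_that("per-line report letters duplicate groups a..f in order", {
  rec <- table3_records()
  rec$zygosity <- "het"
  rep3 <- table3_report(rec)
  expect_identical(sort(setdiff(unique(rep3$dup), "")), letters[1:6])
  expect_identical(rep3$pos, sort(rep3$pos))
  # letters appear in positional order of the groups
  first_at <- tapply(seq_len(nrow(rep3))[rep3$dup != ""],
                     rep3$dup[rep3$dup != ""], min)
  expect_identical(names(sort(first_at)), letters[1:6])
  # no duplicates -> no letters; deterministic
  solo <- data.frame(line_id = "x", seq_name = "s", pos = 1L, ref = "G",
                     alt = "A")
  expect_identical(table3_report(solo)$dup, "")
  expect_identical(table3_report(rec), rep3)
})

test_that("report rounding is half away from zero", {
  expect_identical(round_half_away(0.05, 1), 0.1)
  expect_identical(round_half_away(-0.05, 1), -0.1)
  expect_identical(round_half_away(2.5), 3)
  expect_identical(round_half_away(15.65, 1), 15.7)
})
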
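# an independently coded PASS predicate (kept deliberately naive)
oracle_pass <- function(coverage, alt_F, alt_R, cfg = caller_config()) {
  alt <- alt_F + alt_R
  if (coverage < cfg$min_coverage) return(FALSE)
  if (alt < cfg$min_alt_reads) return(FALSE)
  if (alt / coverage < cfg$min_frequency) return(FALSE)
  if (cfg$require_both_strands && (alt_F == 0 || alt_R == 0)) return(FALSE)
  TRUE
}

test_that("caller decisions match the predicate oracle on an exhaustive grid", {
  cfg <- caller_config()
  for (coverage in 90:110) {
    for (alt in 0:5) {
      for (alt_F in 0:alt) {
        alt_R <- alt - alt_F
        pu <- one_column_pileup(alt_F = alt_F, alt_R = alt_R,
                                coverage = coverage)
        calls <- call_pool_variants(pu, cfg, emit_all = TRUE)
        got_pass <- any(calls$filter_status == "PASS")
        expect_identical(got_pass, oracle_pass(coverage, alt_F, alt_R, cfg),
                         info = sprintf("cov=%d F=%d R=%d", coverage,
                                        alt_F, alt_R))
      }
    }
  }
})

test_that("published limiting case and filter statuses", {
  # two reads with a base change among 96 reads per pool -> PASS
  pass <- call_pool_variants(one_column_pileup(alt_F = 1, alt_R = 1,
                                               coverage = 96))
  expect_identical(pass$filter_status, "PASS")
  expect_equal(pass$frequency, 2 / 96)
  # the literal 2.1% setting rejects its own limiting case
  lit <- call_pool_variants(one_column_pileup(alt_F = 1, alt_R = 1,
                                              coverage = 96),
                            caller_config(min_frequency = 0.021))
  expect_identical(lit$filter_status, "LOW_FREQ")

  expect_identical(call_pool_variants(
    one_column_pileup(alt_F = 5, alt_R = 5, coverage = 95))$filter_status,
    "LOW_COV")
  expect_identical(call_pool_variants(
    one_column_pileup(alt_F = 5, alt_R = 0, coverage = 200))$filter_status,
    "STRAND")
  expect_identical(call_pool_variants(
    one_column_pileup(alt_F = 3, alt_R = 3, coverage = 200,
                      mq = 10))$filter_status,
    "QUALITY")
})

test_that("multi-allelic columns report at most 4 alts ranked by count", {
  pu <- one_column_pileup(ref_base = "G", alt_base = "A", alt_F = 6,
                          alt_R = 6, coverage = 400)
  pu$C_F <- 5L; pu$C_R <- 5L
  pu$T_F <- 2L; pu$T_R <- 2L
  pu$G_F <- pu$G_F - 22L
  calls <- call_pool_variants(pu, caller_config(min_coverage = 96))
  expect_identical(calls$alt, c("A", "C", "T"))
  expect_true(all(diff(calls$alt_count_F + calls$alt_count_R) <= 0))
})

test_that("per-line stringent and relaxed call sets", {
  stringent <- call_line_variants(one_column_pileup(alt_F = 2, alt_R = 1,
                                                    coverage = 6))
  expect_identical(nrow(stringent), 1L)   # 3/6 = 0.5 >= 0.40, both strands
  expect_identical(nrow(call_line_variants(
    one_column_pileup(alt_F = 1, alt_R = 0, coverage = 2), relaxed = TRUE)), 1L)
  expect_identical(nrow(call_line_variants(
    one_column_pileup(alt_F = 1, alt_R = 0, coverage = 2))), 0L)
  expect_identical(nrow(call_line_variants(
    one_column_pileup(alt_F = 2, alt_R = 2, coverage = 4))), 0L)  # cov < 5
})

test_that("detection power matches Monte-Carlo and is monotone", {
  cfg <- caller_config()
  p <- detection_power(16, "het", coverage = 96, error_rate = 0, config = cfg)
  # Monte-Carlo oracle
  set.seed(99)
  n <- 1e5
  k <- rbinom(n, 96, 1 / 32)
  kF <- rbinom(n, k, 0.5)
  ok <- k >= 2 & k / 96 >= cfg$min_frequency & kF >= 1 & (k - kF) >= 1
  expect_lt(abs(p - mean(ok)), 4 * sqrt(p * (1 - p) / n))

  expect_identical(detection_power(16, "het", coverage = 0), 0)
  expect_gt(detection_power(16, "hom", coverage = 96, error_rate = 0),
            detection_power(16, "het", coverage = 96, error_rate = 0))
  # monotone in coverage
  pw <- vapply(c(96, 200, 400, 800, 1600), function(cv)
    detection_power(16, "het", coverage = cv, error_rate = 0), numeric(1))
  expect_true(all(diff(pw) >= -1e-12))
  # null columns at realistic error rates are far less likely to pass than
  # a true heterozygous mutant at the same coverage
  p_null <- detection_power(16, "null", coverage = 96, error_rate = 0.002)
  p_het <- detection_power(16, "het", coverage = 96, error_rate = 0.002)
  expect_lt(p_null, p_het / 100)
})

test_that("zero PASS calls on clean unmutated pools", {
  ref <- build_toy_reference(1, 300, seed = 3, introns = 0)
  lay <- assign_indexes(build_layout(16))
  empty_pop <- data.frame(line_id = character(0), seq_name = character(0),
                          pos = integer(0), ref = character(0),
                          alt = character(0), zygosity = character(0),
                          origin = character(0), hap = integer(0),
                          family = integer(0))
  for (s in 1:3) {
    cfg <- read_sim_config(read_length = 100, mean_depth_per_pool = 400,
                           error_rate = 0, frag_mean = 250, frag_sd = 30,
                           seed = s)
    sim <- simulate_pool_reads(ref, empty_pop, lay, cfg)
    al <- align_gapless(trim_reads(sim$pools[[1]])$reads, amplicon_refs(ref))
    calls <- call_pool_variants(al$pileup)
    expect_identical(sum(calls$filter_status == "PASS"), 0L)
  }
})
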
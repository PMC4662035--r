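#' Pool variant caller configuration
#'
#' Thresholds for calling low-frequency single-nucleotide variants in an
#' indexed DNA pool. The defaults encode the limiting case "two variant
#' reads among 96 reads per pool": minimum coverage 96 and minimum variant
#' frequency exactly 2/96 (~2.08%). The published setting of 2.1% would
#' reject its own limiting case (2/96 = 2.083% < 2.1%), so the literal value
#' is available via `min_frequency = 0.021` but is not the default.
#'
#' @param min_coverage minimum read coverage at the column.
#' @param min_alt_reads minimum variant-supporting reads.
#' @param min_frequency minimum variant allele fraction.
#' @param require_both_strands require >= 1 variant read on each strand.
#' @param central_quality_min,neighborhood_radius,neighborhood_quality_min,max_mismatches_in_window
#'   per-read quality gates (applied during pileup construction; the central
#'   quality is re-checked against the column's mean alt base quality).
#' @param max_alt_alleles maximum alternate alleles reported per column.
#' @return object of class `caller_config`.
#' @export
caller_config <- function(min_coverage = 96L, min_alt_reads = 2L,
                          min_frequency = 2 / 96,
                          require_both_strands = TRUE,
                          central_quality_min = 20L,
                          neighborhood_radius = 5L,
                          neighborhood_quality_min = 15L,
                          max_mismatches_in_window = 2L,
                          max_alt_alleles = 4L) {
  stopifnot(min_coverage >= 1, min_alt_reads >= 0,
            min_frequency > 0, min_frequency < 1, max_alt_alleles >= 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_alt_reads = as.integer(min_alt_reads),
                 min_frequency = min_frequency,
                 require_both_strands = isTRUE(require_both_strands),
                 central_quality_min = as.integer(central_quality_min),
                 neighborhood_radius = as.integer(neighborhood_radius),
                 neighborhood_quality_min = as.integer(neighborhood_quality_min),
                 max_mismatches_in_window = as.integer(max_mismatches_in_window),
                 max_alt_alleles = as.integer(max_alt_alleles)),
            class = "caller_config")
}

#' Call low-frequency variants in a pool pileup
#'
#' A column yields a PASS call for an alternate base iff coverage >=
#' `min_coverage`, alt reads >= `min_alt_reads`, alt fraction >=
#' `min_frequency`, at least one alt read on each strand (if required), and
#' the column's mean alt base quality passes the central quality gate.
#' Failing candidates are annotated with a filter status (LOW_COV, LOW_FREQ,
#' STRAND, QUALITY) rather than dropped. At most `max_alt_alleles` alts are
#' reported per column, ranked by descending count (ties by base order).
#' Indels are never emitted.
#'
#' @param pileup a `stranded_pileup`.
#' @param config a `caller_config`.
#' @param pool_id pool label carried into the calls.
#' @param emit_all if TRUE, also emit candidates below `min_alt_reads`.
#' @return data.frame of `PoolVariantCall` rows: pool_id, seq_name, pos,
#'   ref, alt, coverage, alt_count_F, alt_count_R, frequency, filter_status.
#' @export
call_pool_variants <- function(pileup, config = caller_config(),
                               pool_id = "pool", emit_all = FALSE) {
  stopifnot(inherits(pileup, "stranded_pileup") || is.data.frame(pileup))
  cov <- pileup_coverage(pileup)
  out <- list(); oi <- 0L
  for (b in seq_along(DNA_BASES)) {
    base <- DNA_BASES[b]
    is_alt <- pileup$ref != base
    aF <- pileup[[paste0(base, "_F")]]
    aR <- pileup[[paste0(base, "_R")]]
    tot <- aF + aR
    min_emit <- if (emit_all) 1L else config$min_alt_reads
    sel <- which(is_alt & tot >= min_emit)
    if (!length(sel)) next
    mq <- pileup[[paste0("mq_", base)]][sel]
    status <- rep("PASS", length(sel))
    status[!is.na(mq) & mq < config$central_quality_min] <- "QUALITY"
    if (config$require_both_strands) {
      status[aF[sel] < 1L | aR[sel] < 1L] <- "STRAND"
    }
    freq <- tot[sel] / pmax(1L, cov[sel])
    status[tot[sel] < config$min_alt_reads | freq < config$min_frequency] <- "LOW_FREQ"
    status[cov[sel] < config$min_coverage] <- "LOW_COV"
    oi <- oi + 1L
    out[[oi]] <- data.frame(
      pool_id = pool_id, seq_name = pileup$seq_name[sel],
      pos = pileup$pos[sel], ref = pileup$ref[sel], alt = base,
      coverage = cov[sel], alt_count_F = aF[sel], alt_count_R = aR[sel],
      frequency = freq, filter_status = status, stringsAsFactors = FALSE
    )
  }
  calls <- if (oi) do.call(rbind, out) else data.frame(
    pool_id = character(0), seq_name = character(0), pos = integer(0),
    ref = character(0), alt = character(0), coverage = integer(0),
    alt_count_F = integer(0), alt_count_R = integer(0),
    frequency = numeric(0), filter_status = character(0),
    stringsAsFactors = FALSE)
  calls <- calls[order(calls$seq_name, calls$pos,
                       -(calls$alt_count_F + calls$alt_count_R),
                       match(calls$alt, DNA_BASES)), , drop = FALSE]
  # cap alts per column
  key <- paste(calls$seq_name, calls$pos)
  rank <- stats::ave(seq_len(nrow(calls)), key, FUN = seq_along)
  calls <- calls[rank <= config$max_alt_alleles, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Call variants in a single-line (non-pooled) pileup
#'
#' Stand-in for probabilistic per-line variant detection using allele
#' fraction thresholds: stringent mode requires coverage >= 5, alt fraction
#' >= 0.40 and both strands; relaxed mode requires coverage >= 2 and alt
#' fraction >= 0.10 with up to 4 alternate alleles and no strand rule.
#'
#' @param pileup a `stranded_pileup` for one line.
#' @param relaxed use the relaxed parameter set.
#' @param line_id label carried into the calls.
#' @return data.frame of calls (PASS rows only).
#' @export
call_line_variants <- function(pileup, relaxed = FALSE, line_id = "line") {
  cfg <- if (relaxed) {
    caller_config(min_coverage = 2L, min_alt_reads = 1L, min_frequency = 0.10,
                  require_both_strands = FALSE, max_alt_alleles = 4L)
  } else {
    caller_config(min_coverage = 5L, min_alt_reads = 1L, min_frequency = 0.40,
                  require_both_strands = TRUE, max_alt_alleles = 2L)
  }
  calls <- call_pool_variants(pileup, cfg, pool_id = line_id, emit_all = TRUE)
  calls <- calls[calls$filter_status == "PASS", , drop = FALSE]
  names(calls)[names(calls) == "pool_id"] <- "line_id"
  rownames(calls) <- NULL
  calls
}

#' Exact detection power of the pool caller
#'
#' Closed-form probability that a true mutant at its expected pooled allele
#' fraction (or a null column at `error_rate / 3` per alternate base) yields
#' a PASS call at fixed coverage. Alt reads are Binomial(coverage, f); each
#' alt read is forward with probability 1/2, so the both-strand requirement
#' is met with probability `1 - 2 * 0.5^k` given k >= 1 alt reads.
#'
#' @param pool_size plants per indexed pool.
#' @param zygosity "het" or "hom" (single carrier plant), or "null" for a
#'   mutation-free column probed at the sequencing error rate.
#' @param coverage read coverage at the column.
#' @param error_rate per-base substitution error rate (used for "null").
#' @param config a `caller_config`.
#' @param ploidy chromosome copies per plant.
#' @return probability of a PASS call.
#' @export
detection_power <- function(pool_size = 16L, zygosity = c("het", "hom", "null"),
                            coverage = 96L, error_rate = 0.002,
                            config = caller_config(), ploidy = 2L) {
  zygosity <- match.arg(zygosity)
  if (coverage < 1L) return(0)
  if (coverage < config$min_coverage) return(0)
  f <- switch(zygosity,
              het = min_detectable_allele_fraction(pool_size, "het", ploidy),
              hom = min_detectable_allele_fraction(pool_size, "hom", ploidy),
              null = error_rate / 3)
  if (f <= 0) return(0)
  k <- 0:coverage
  ok <- k >= config$min_alt_reads & (k / coverage) >= config$min_frequency
  p_strand <- if (config$require_both_strands) {
    ifelse(k >= 1L, 1 - 2 * 0.5^k, 0)
  } else rep(1, length(k))
  sum(dbinom(k, coverage, f) * ok * p_strand)
}
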
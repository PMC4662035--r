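#' Candidate plants for a pool-level call
#'
#' A PASS call in an indexed pool narrows the carrier down to the
#' `tier1_size * tier2_size` plants of that pool (16 by default), grouped by
#' tier-1 pool so that a follow-up can sequence the 4 tier-1 pools before
#' the individual plants.
#'
#' @param pool_id tier-2 pool id of the call.
#' @param layout a `pooling_layout`.
#' @return data.frame: plant_id, tier1_pool.
#' @export
deconvolve <- function(pool_id, layout) {
  plants <- plants_of_pool(layout, pool_id)
  data.frame(plant_id = unname(plants), tier1_pool = names(plants),
             stringsAsFactors = FALSE)
}

#' Confirm a call against per-plant genotypes
#'
#' Models the final direct-sequencing step of a screen as an error-free
#' genotype lookup: every candidate plant whose genotype carries the
#' alternate base at the call position is returned with its zygosity. An
#' empty result flags the call as a false positive.
#'
#' @param call one call (list/row with seq_name, pos, alt).
#' @param candidates data.frame from [deconvolve()].
#' @param genotypes data.frame of per-plant mutations (line_id, seq_name,
#'   pos, alt, zygosity) — simulation truth or a user genotype table.
#' @return data.frame: plant_id, zygosity (possibly 0 rows).
#' @export
confirm_by_genotype <- function(call, candidates, genotypes) {
  hit <- genotypes[genotypes$seq_name == call$seq_name &
                     genotypes$pos == call$pos &
                     genotypes$alt == call$alt &
                     genotypes$line_id %in% candidates$plant_id, , drop = FALSE]
  data.frame(plant_id = hit$line_id, zygosity = hit$zygosity,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full simulated screen once
#'
#' simulate reads -> trim -> align -> call per pool -> deconvolve ->
#' confirm against truth. Returns per-pool calls with confirmation status.
#'
#' @param sim a `pool_read_sim`.
#' @param caller a `caller_config`.
#' @param trim a `trim_config`.
#' @return list with `calls` (pool calls with filter status), `pileups`
#'   (per pool), `align_stats`.
#' @export
screen_pools <- function(sim, caller = caller_config(), trim = trim_config()) {
  amps <- sim$amplicons
  refs <- stats::setNames(
    substr(sim$reference$sequences[amps$seq_name], amps$start, amps$end),
    amps$amplicon_id)
  all_calls <- list(); pileups <- list(); astats <- list()
  for (pid in names(sim$pools)) {
    tr <- trim_reads(sim$pools[[pid]], trim)
    al <- align_gapless(tr$reads, refs,
                        central_quality_min = caller$central_quality_min,
                        neighborhood_radius = caller$neighborhood_radius,
                        neighborhood_quality_min = caller$neighborhood_quality_min,
                        max_mismatches_in_window = caller$max_mismatches_in_window)
    calls <- call_pool_variants(al$pileup, caller, pool_id = pid)
    pileups[[pid]] <- al$pileup
    astats[[pid]] <- al$stats
    all_calls[[pid]] <- calls
  }
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  list(calls = calls, pileups = pileups, align_stats = astats)
}

#' Benchmark the whole pipeline against simulation truth
#'
#' Runs simulate -> trim -> align -> call -> deconvolve -> confirm for each
#' seed and aggregates sensitivity (fraction of simulated in-amplicon
#' mutations recovered by a PASS call in the carrier's pool and confirmed to
#' the correct plant), false discovery rate among PASS calls, a per-zygosity
#' breakdown, and the recovered vs configured mutation density.
#'
#' @param reference a `reference_set`.
#' @param n_plants population size.
#' @param layout optional pre-built indexed `pooling_layout`.
#' @param per_round_density per-round mutation density (mutations/bp).
#' @param read_config a `read_sim_config` (its seed is re-derived per run).
#' @param caller a `caller_config`.
#' @param n_seeds number of independent simulation replicates.
#' @param seed master seed.
#' @param m1_family_size plants per M1 family.
#' @param trim a `trim_config`; its fixed `end_trim` defines a terminal
#'   shadow of each amplicon that no read can cover, so mutations there are
#'   structurally undetectable. They are excluded from the sensitivity
#'   denominator and counted in `n_shadow`.
#' @return object of class `benchmark_report`: list of per-seed rows and
#'   aggregate mean/sd of sensitivity, FDR, and density recovery.
#' @export
run_benchmark <- function(reference, n_plants = 64L, layout = NULL,
                          per_round_density = default_per_round_density(),
                          read_config = read_sim_config(),
                          caller = caller_config(), n_seeds = 1L, seed = 1L,
                          m1_family_size = 4L, trim = trim_config()) {
  stopifnot(n_seeds >= 1L)
  if (is.null(layout)) layout <- assign_indexes(build_layout(n_plants))
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    run_seed <- derive_seed(seed, s)
    pop <- simulate_population(reference, n_plants = n_plants,
                               per_round_density = per_round_density,
                               m1_family_size = m1_family_size,
                               seed = run_seed)
    rc <- read_config
    rc$seed <- derive_seed(run_seed, 2L)
    sim <- simulate_pool_reads(reference, pop, layout, rc)
    scr <- screen_pools(sim, caller, trim)
    calls <- scr$calls[scr$calls$filter_status == "PASS", , drop = FALSE]

    truth <- sim$truth
    # end-trimming leaves the terminal end_trim bases of an amplicon
    # uncoverable; such mutations cannot be detected by any caller
    amp_len <- stats::setNames(sim$amplicons$end - sim$amplicons$start + 1L,
                               sim$amplicons$amplicon_id)
    shadow <- truth$amp_pos <= trim$end_trim |
      truth$amp_pos > amp_len[truth$amplicon_id] - trim$end_trim
    n_shadow <- sum(shadow)
    truth <- truth[!shadow, , drop = FALSE]
    # genotype table in amplicon coordinates for the confirmation lookup
    geno <- data.frame(line_id = truth$line_id, seq_name = truth$amplicon_id,
                       pos = truth$amp_pos, alt = truth$alt,
                       zygosity = truth$zygosity, stringsAsFactors = FALSE)
    confirmed_keys <- character(0)
    call_confirmed <- logical(nrow(calls))
    for (ci in seq_len(nrow(calls))) {
      cl <- calls[ci, ]
      cands <- deconvolve(cl$pool_id, layout)
      conf <- confirm_by_genotype(cl, cands, geno)
      call_confirmed[ci] <- nrow(conf) > 0L
      if (nrow(conf)) {
        confirmed_keys <- c(confirmed_keys,
                            paste(cl$pool_id, cl$seq_name, cl$pos, cl$alt,
                                  conf$plant_id, sep = "\r"))
      }
    }
    truth_key <- paste(truth$pool, truth$amplicon_id, truth$amp_pos,
                       truth$alt, truth$line_id, sep = "\r")
    tp_truth <- truth_key %in% confirmed_keys
    n_truth <- nrow(truth)
    sens <- if (n_truth) mean(tp_truth) else NA_real_
    sens_het <- if (any(truth$zygosity == "het"))
      mean(tp_truth[truth$zygosity == "het"]) else NA_real_
    sens_hom <- if (any(truth$zygosity == "hom"))
      mean(tp_truth[truth$zygosity == "hom"]) else NA_real_
    fdr <- if (nrow(calls)) mean(!call_confirmed) else 0
    # density recovery over the surveyed region: unique confirmed mutations
    region_bp <- sum(sim$amplicons$end - sim$amplicons$start + 1L)
    n_events <- nrow(unique(truth[, c("line_id", "seq_name", "pos", "alt")]))
    recovered_events <- sum(tp_truth)
    rows[[s]] <- data.frame(
      seed = run_seed, n_truth = n_truth, n_shadow = n_shadow,
      n_calls = nrow(calls),
      sensitivity = sens, sensitivity_het = sens_het,
      sensitivity_hom = sens_hom, fdr = fdr,
      configured_events = n_events, recovered_events = recovered_events,
      density_recovered_per_kb = recovered_events / n_plants / region_bp * 1000,
      density_configured_per_kb = n_events / n_plants / region_bp * 1000,
      stringsAsFactors = FALSE)
  }
  per_seed <- do.call(rbind, rows)
  agg <- function(x) c(mean = mean(x, na.rm = TRUE),
                       sd = if (length(x) > 1L) stats::sd(x, na.rm = TRUE) else 0)
  structure(list(
    per_seed = per_seed,
    sensitivity = agg(per_seed$sensitivity),
    sensitivity_het = agg(per_seed$sensitivity_het),
    sensitivity_hom = agg(per_seed$sensitivity_hom),
    fdr = agg(per_seed$fdr),
    density_ratio = agg(per_seed$density_recovered_per_kb /
                          per_seed$density_configured_per_kb)
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(paste0("benchmark_report over %d seed(s):\n",
                     "  sensitivity %.3f (het %.3f, hom %.3f)\n",
                     "  FDR %.3f  density recovery ratio %.3f\n"),
              nrow(x$per_seed), x$sensitivity[["mean"]],
              x$sensitivity_het[["mean"]], x$sensitivity_hom[["mean"]],
              x$fdr[["mean"]], x$density_ratio[["mean"]]))
  invisible(x)
}
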
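#' Read simulation configuration
#'
#' Defaults emulate 250 bp paired-end sequencing of pooled long-range PCR
#' amplicons: fragmentation around 450 bp, a small uniform per-base
#' substitution error rate, and smoothly varying (log-normal) per-position
#' depth with lower coverage near amplicon ends.
#'
#' @param read_length read length in bp.
#' @param mean_depth_per_pool mean read depth per position in one indexed
#'   pool (16 plants at ~50x per sample gives ~800x per pool).
#' @param error_rate per-base substitution error probability (< 0.5).
#' @param dispersion log-scale sd of the multiplicative depth field.
#' @param frag_mean,frag_sd fragment length distribution (bp), truncated to
#'   `[read_length, amplicon length]`.
#' @param base_qual constant Phred quality assigned to simulated bases.
#' @param seed integer RNG seed.
#' @return object of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 250L, mean_depth_per_pool = 800,
                            error_rate = 0.002, dispersion = 0.5,
                            frag_mean = 450, frag_sd = 50,
                            base_qual = 35L, seed = 1L) {
  stop_if_not_scalar_pos(read_length, "read_length", integer = TRUE)
  if (!is.numeric(mean_depth_per_pool) || mean_depth_per_pool < 0) {
    stop("'mean_depth_per_pool' must be non-negative")
  }
  if (error_rate < 0 || error_rate >= 0.5) stop("'error_rate' must be in [0, 0.5)")
  if (dispersion < 0) stop("'dispersion' must be non-negative")
  structure(list(read_length = as.integer(read_length),
                 mean_depth_per_pool = mean_depth_per_pool,
                 error_rate = error_rate, dispersion = dispersion,
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 base_qual = as.integer(base_qual), seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Default amplicon table: one amplicon spanning each reference sequence
#'
#' @param reference a `reference_set`.
#' @return data.frame: amplicon_id, seq_name, start, end.
#' @export
default_amplicons <- function(reference) {
  data.frame(amplicon_id = names(reference$sequences),
             seq_name = names(reference$sequences),
             start = 1L, end = nchar(reference$sequences),
             stringsAsFactors = FALSE, row.names = NULL)
}

# smooth log-normal depth field with tapered amplicon ends
depth_weights <- function(L, dispersion, taper_bp = 100L) {
  if (dispersion == 0) {
    field <- rep(1, L)
  } else {
    k <- min(51L, max(3L, 2L * (L %/% 20L) + 1L))
    z <- rnorm(L)
    zs <- as.numeric(stats::filter(z, rep(1 / k, k), sides = 2))
    # fill the filter's NA edges with nearest value, restore unit variance
    idx <- which(!is.na(zs))
    zs[seq_len(idx[1] - 1L)] <- zs[idx[1]]
    zs[seq(idx[length(idx)] + 1L, length.out = L - idx[length(idx)])] <- zs[idx[length(idx)]]
    zs <- zs * sqrt(k)
    field <- exp(dispersion * zs - dispersion^2 / 2)
  }
  edge <- pmin(seq_len(L), rev(seq_len(L)))
  taper <- 0.3 + 0.7 * pmin(1, edge / max(1L, taper_bp))
  field * taper
}

# apply i.i.d. substitution errors to a character vector of reads
apply_seq_errors <- function(reads, error_rate) {
  if (error_rate == 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  nerr <- rbinom(length(reads), lens, error_rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      orig <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, orig), 1L)
    }
  }
  reads
}

revcomp_many <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# mutated amplicon sequence for one haplotype
apply_mutations_to_seq <- function(seq, pos, alt) {
  if (length(pos)) {
    for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- alt[i]
  }
  seq
}

#' Simulate pooled paired-end amplicon reads with known truth
#'
#' Draws sequencing fragments from the 2 x 16 haplotypes of each indexed
#' pool with equal expectation, so a heterozygous mutation in one plant has
#' expected allele fraction 1/32 in its pool. Per-position depth varies by a
#' seeded smooth multiplicative field; base call errors are i.i.d.
#' substitutions.
#'
#' @param reference a `reference_set`.
#' @param population mutation events from [simulate_population()].
#' @param layout an indexed `pooling_layout` covering the population's lines.
#' @param config a `read_sim_config`.
#' @param amplicons amplicon table (default: whole sequences).
#' @return object of class `pool_read_sim`: list with `pools` (per pool id:
#'   a `paired_reads` object), `truth` (data.frame of events with pool ids
#'   and amplicon coordinates), plus the inputs.
#' @export
simulate_pool_reads <- function(reference, population, layout,
                                config = read_sim_config(),
                                amplicons = NULL) {
  stopifnot(inherits(reference, "reference_set"),
            inherits(layout, "pooling_layout"),
            inherits(config, "read_sim_config"))
  if (is.null(amplicons)) amplicons <- default_amplicons(reference)
  if (!all(amplicons$seq_name %in% names(reference$sequences))) {
    stop("amplicon outside reference: unknown sequence name")
  }
  L_seq <- nchar(reference$sequences)[amplicons$seq_name]
  if (any(amplicons$start < 1L) || any(amplicons$end > L_seq)) {
    stop("amplicon outside reference: interval out of bounds")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  pools <- unique(layout$tier2)
  rl <- config$read_length
  qchar <- rawToChar(as.raw(33L + config$base_qual))

  # truth: population events inside amplicons, with carrying pool
  truth <- merge(population,
                 data.frame(line_id = names(layout$tier1),
                            pool = unname(layout$tier2[layout$tier1]),
                            stringsAsFactors = FALSE),
                 by = "line_id")
  tr <- lapply(seq_len(nrow(amplicons)), function(ai) {
    a <- amplicons[ai, ]
    t <- truth[truth$seq_name == a$seq_name & truth$pos >= a$start &
                 truth$pos <= a$end, , drop = FALSE]
    if (nrow(t)) {
      t$amplicon_id <- a$amplicon_id
      t$amp_pos <- t$pos - a$start + 1L
    }
    t
  })
  truth <- do.call(rbind, tr[vapply(tr, nrow, integer(1)) > 0L])
  if (is.null(truth)) {
    truth <- cbind(population[0, ], pool = character(0),
                   amplicon_id = character(0), amp_pos = integer(0))
  }
  truth <- truth[order(truth$pool, truth$amplicon_id, truth$amp_pos,
                       truth$line_id), , drop = FALSE]
  rownames(truth) <- NULL

  out_pools <- vector("list", length(pools))
  names(out_pools) <- pools
  for (pi in seq_along(pools)) {
    pid <- pools[pi]
    set.seed(derive_seed(config$seed, 100L + pi))
    plants <- unname(plants_of_pool(layout, pid))
    if (length(plants) == 0L) stop("empty pool: ", pid)
    nh <- 2L * length(plants)
    r1 <- character(0); r2 <- character(0); nm <- character(0)
    for (ai in seq_len(nrow(amplicons))) {
      a <- amplicons[ai, ]
      ref_amp <- substr(reference$sequences[[a$seq_name]], a$start, a$end)
      L <- nchar(ref_amp)
      # 2 haplotype strings per plant
      haps <- character(nh)
      for (j in seq_along(plants)) {
        mu <- population[population$line_id == plants[j] &
                           population$seq_name == a$seq_name &
                           population$pos >= a$start &
                           population$pos <= a$end, , drop = FALSE]
        ap <- mu$pos - a$start + 1L
        on1 <- mu$hap %in% c(0L, 1L)
        on2 <- mu$hap %in% c(0L, 2L)
        haps[2L * j - 1L] <- apply_mutations_to_seq(ref_amp, ap[on1], mu$alt[on1])
        haps[2L * j] <- apply_mutations_to_seq(ref_amp, ap[on2], mu$alt[on2])
      }
      n_frag <- max(0L, round(config$mean_depth_per_pool * L / (2 * rl)))
      if (n_frag == 0L) next
      w <- depth_weights(L, config$dispersion)
      fl <- pmin(L, pmax(min(rl, L),
                         round(rnorm(n_frag, config$frag_mean, config$frag_sd))))
      mid <- sample.int(L, n_frag, replace = TRUE, prob = w)
      st <- pmin(pmax(mid - fl %/% 2L, 1L), L - fl + 1L)
      hidx <- sample.int(nh, n_frag, replace = TRUE)
      frag <- substr(haps[hidx], st, st + fl - 1L)
      left <- substr(frag, 1L, pmin(rl, fl))
      right <- substr(frag, pmax(1L, fl - rl + 1L), fl)
      # tagmentation inserts adaptors in random orientation: half the
      # fragments are sequenced from the bottom strand, so both strands
      # cover every position in expectation
      flip <- runif(n_frag) < 0.5
      m1 <- ifelse(flip, revcomp_many(left), left)
      m2 <- ifelse(flip, right, revcomp_many(right))
      m1 <- apply_seq_errors(m1, config$error_rate)
      m2 <- apply_seq_errors(m2, config$error_rate)
      r1 <- c(r1, m1); r2 <- c(r2, m2)
      nm <- c(nm, sprintf("%s:%s:%06d", pid, a$amplicon_id, seq_len(n_frag)))
    }
    out_pools[[pi]] <- paired_reads(
      names = nm, r1 = r1, r2 = r2,
      q1 = strrep(qchar, nchar(r1)), q2 = strrep(qchar, nchar(r2)))
  }
  structure(list(pools = out_pools, truth = truth, layout = layout,
                 amplicons = amplicons, reference = reference,
                 config = config),
            class = "pool_read_sim")
}

#' @export
print.pool_read_sim <- function(x, ...) {
  n <- vapply(x$pools, function(p) length(p$names), integer(1))
  cat(sprintf("pool_read_sim: %d pools, %d read pairs, %d truth events\n",
              length(x$pools), sum(n), nrow(x$truth)))
  invisible(x)
}
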
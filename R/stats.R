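#' Collapse duplicated mutations across lines
#'
#' Records sharing (seq_name, pos, alt) — the signature of a mutation
#' inherited from a common first-round mutagenized ancestor — collapse to
#' one unique mutation listing its member lines. The same position with a
#' different alternate base is a different mutation.
#'
#' @param records data.frame with seq_name, pos, alt and optionally line_id.
#' @return list with `unique` (one row per unique mutation, plus `n_lines`
#'   and comma-separated `lines`) and `groups` (duplicate groups with >= 2
#'   members, lettered a, b, c, ... in positional order).
#' @export
deduplicate <- function(records) {
  stopifnot(all(c("seq_name", "pos", "alt") %in% names(records)))
  if (!"line_id" %in% names(records)) records$line_id <- NA_character_
  key <- paste(records$seq_name, records$pos, records$alt, sep = "\r")
  ord <- order(records$seq_name, records$pos, records$alt)
  records <- records[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  uni <- records[first, , drop = FALSE]
  uni$n_lines <- as.integer(table(key)[key[first]])
  uni$lines <- vapply(key[first], function(k)
    paste(records$line_id[key == k], collapse = ","), character(1),
    USE.NAMES = FALSE)
  rownames(uni) <- NULL
  dup_keys <- key[first][uni$n_lines >= 2L]
  groups <- NULL
  if (length(dup_keys)) {
    groups <- data.frame(
      key = dup_keys,
      letter = letters[seq_along(dup_keys)],
      stringsAsFactors = FALSE
    )
  }
  list(unique = uni, groups = groups)
}

#' Mutation density per kilobase
#'
#' @param n_unique number of unique mutations found in the region.
#' @param region_bp surveyed region size in bp.
#' @return mutations per kb, rounded half away from zero to 1 decimal.
#' @export
mutation_density_per_kb <- function(n_unique, region_bp) {
  stop_if_not_scalar_pos(region_bp, "region_bp")
  round_half_away(n_unique / region_bp * 1000, 1)
}

#' Genomic distance between base changes
#'
#' @param n_changes_per_plant total base changes in one plant.
#' @param genome_bp genome size (default: 950,068,807 bp chromosome-scale
#'   assembly).
#' @return list with `kb` (1 decimal) and `kb_int` (nearest integer kb).
#' @export
distance_between_changes <- function(n_changes_per_plant,
                                     genome_bp = 950068807) {
  stop_if_not_scalar_pos(n_changes_per_plant, "n_changes_per_plant")
  kb <- genome_bp / n_changes_per_plant / 1000
  list(kb = round_half_away(kb, 1), kb_int = round_half_away(kb, 0))
}

#' Expected genome-wide base changes per plant from an amplicon survey
#'
#' Extrapolates the number of base changes found in a surveyed region to the
#' whole genome and divides by the number of plants in the library.
#'
#' @param n_changes_in_library base changes found in the surveyed region
#'   across the whole library.
#' @param region_bp surveyed region size in bp.
#' @param genome_bp genome size.
#' @param n_plants number of plants in the library.
#' @return expected base changes per plant (rounded to integer).
#' @export
expected_per_plant <- function(n_changes_in_library, region_bp,
                               genome_bp = 950068807, n_plants = 1536L) {
  stop_if_not_scalar_pos(region_bp, "region_bp")
  stop_if_not_scalar_pos(genome_bp, "genome_bp")
  stop_if_not_scalar_pos(n_plants, "n_plants")
  round_half_away(n_changes_in_library / region_bp * genome_bp / n_plants)
}

#' Minimum detectable allele fraction in a DNA pool
#'
#' A single heterozygous mutant plant contributes 1 of the `ploidy * n`
#' chromosome copies in a pool of `n` diploid samples (1/32 for the default
#' 16-plant indexed pool, 1/8 for a 4-plant pool); a homozygous mutant
#' contributes `ploidy` copies, i.e. fraction 1/n.
#'
#' @param n_plants_in_pool number of plants pooled.
#' @param zygosity "het" or "hom".
#' @param ploidy chromosome copies per plant (default 2).
#' @return expected allele fraction of the mutant allele.
#' @export
min_detectable_allele_fraction <- function(n_plants_in_pool,
                                           zygosity = c("het", "hom"),
                                           ploidy = 2L) {
  stop_if_not_scalar_pos(n_plants_in_pool, "n_plants_in_pool", integer = TRUE)
  zygosity <- match.arg(zygosity)
  switch(zygosity,
         het = 1 / (ploidy * n_plants_in_pool),
         hom = ploidy / (ploidy * n_plants_in_pool))
}

#' Substitution spectrum summary
#'
#' Counts and percentages per directed substitution class, transition and
#' transversion totals and their ratio.
#'
#' @param mutations data.frame with ref and alt columns.
#' @return object of class `spectrum_summary`: list with `counts` (named by
#'   the 12 classes), `total`, `percentage` (1 decimal), `transitions`,
#'   `transversions`, `ts_tv_ratio` (2 decimals; NA when no transversions).
#' @export
spectrum_summary <- function(mutations) {
  cls <- paste0(mutations$ref, ">", mutations$alt)
  bad <- !cls %in% SUBSTITUTION_CLASSES
  if (any(bad)) stop("invalid substitution(s): ", paste(unique(cls[bad]), collapse = ", "))
  counts <- table(factor(cls, levels = SUBSTITUTION_CLASSES))
  counts <- stats::setNames(as.integer(counts), SUBSTITUTION_CLASSES)
  total <- sum(counts)
  ts <- sum(counts[TRANSITION_CLASSES])
  tv <- total - ts
  structure(list(
    counts = counts, total = total,
    percentage = if (total > 0) round_half_away(100 * counts / total, 1)
                 else stats::setNames(rep(NA_real_, 12L), SUBSTITUTION_CLASSES),
    transitions = ts, transversions = tv,
    ts_tv_ratio = if (tv > 0) round_half_away(ts / tv, 2) else NA_real_
  ), class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("spectrum_summary: %d mutations, Ts/Tv = %s\n", x$total,
              format(x$ts_tv_ratio)))
  df <- data.frame(class = names(x$counts), count = x$counts,
                   percent = x$percentage, row.names = NULL)
  print(df)
  invisible(x)
}

#' Compare mutation detection by two screening methods
#'
#' Per-gene contingency of call sets from two methods (e.g. melt-curve
#' screening vs indexed amplicon sequencing) over their union of confirmed
#' mutations. The totals row sums the counts but averages the per-gene
#' percentages (unweighted mean of unrounded values, then rounded to 1
#' decimal); pooled-count percentages are also reported for transparency.
#'
#' @param calls_a,calls_b data.frames keyed by gene, pos, alt (columns
#'   `gene_id`, `pos`, `alt`).
#' @param regions data.frame with gene_id and region_bp.
#' @return data.frame with one row per gene plus a "Total" row: region_bp,
#'   total, common, a_only, b_only, pct_a, pct_b (and pooled pct in
#'   attributes pct_a_pooled / pct_b_pooled).
#' @export
compare_detection <- function(calls_a, calls_b, regions) {
  key <- function(d) paste(d$gene_id, d$pos, d$alt, sep = "\r")
  ka <- unique(key(calls_a)); kb <- unique(key(calls_b))
  rows <- list()
  pa <- pb <- numeric(0)
  for (i in seq_len(nrow(regions))) {
    g <- regions$gene_id[i]
    a <- ka[startsWith(ka, paste0(g, "\r"))]
    b <- kb[startsWith(kb, paste0(g, "\r"))]
    common <- length(intersect(a, b))
    a_only <- length(setdiff(a, b))
    b_only <- length(setdiff(b, a))
    total <- common + a_only + b_only
    if (total == 0L) {
      warning("no calls for gene ", g, "; skipped")
      next
    }
    pct_a_raw <- 100 * (common + a_only) / total
    pct_b_raw <- 100 * (common + b_only) / total
    pa <- c(pa, pct_a_raw); pb <- c(pb, pct_b_raw)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, region_bp = regions$region_bp[i], total = total,
      common = common, a_only = a_only, b_only = b_only,
      pct_a = round_half_away(pct_a_raw, 1),
      pct_b = round_half_away(pct_b_raw, 1), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  tot <- data.frame(
    gene_id = "Total", region_bp = sum(df$region_bp), total = sum(df$total),
    common = sum(df$common), a_only = sum(df$a_only), b_only = sum(df$b_only),
    pct_a = round_half_away(mean(pa), 1),
    pct_b = round_half_away(mean(pb), 1), stringsAsFactors = FALSE)
  out <- rbind(df, tot)
  attr(out, "pct_a_pooled") <-
    round_half_away(100 * (tot$common + tot$a_only) / tot$total, 1)
  attr(out, "pct_b_pooled") <-
    round_half_away(100 * (tot$common + tot$b_only) / tot$total, 1)
  out
}

#' Per-line mutation report with duplicate lettering
#'
#' Formats confirmed per-line mutations the way screening reports list them:
#' sorted by position, with mutations shared by several lines tagged with
#' the same letter (a, b, c, ... in positional order of the duplicate
#' groups).
#'
#' @param mutations data.frame with line_id, seq_name, pos, ref, alt and
#'   optionally region, amplicon_bp, zygosity, label columns.
#' @return data.frame: line_id, region, amplicon_bp, base_change, mode,
#'   seq_name, pos, substitution, dup.
#' @export
table3_report <- function(mutations) {
  m <- mutations[order(mutations$seq_name, mutations$pos, mutations$alt,
                       mutations$line_id), , drop = FALSE]
  key <- paste(m$seq_name, m$pos, m$alt, sep = "\r")
  dup_keys <- unique(key[duplicated(key)])
  dup <- rep("", nrow(m))
  if (length(dup_keys)) {
    lab <- stats::setNames(letters[seq_along(dup_keys)], dup_keys)
    hit <- key %in% dup_keys
    dup[hit] <- lab[key[hit]]
  }
  data.frame(
    line_id = m$line_id,
    region = m$region %||% NA_character_,
    amplicon_bp = m$amplicon_bp %||% NA_integer_,
    base_change = paste0(m$ref, " > ", m$alt),
    mode = m$zygosity %||% NA_character_,
    seq_name = m$seq_name, pos = m$pos,
    substitution = m$label %||% NA_character_,
    dup = dup, stringsAsFactors = FALSE, row.names = NULL
  )
}
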
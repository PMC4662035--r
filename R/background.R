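#' Background filter configuration
#'
#' A variant present in at least `common_threshold` of the compared units
#' (lines in whole-genome mode, indexed pools in amplicon mode) is treated
#' as a background polymorphism between the library's parent cultivar and
#' the reference genome rather than an induced mutation.
#'
#' @param common_threshold fraction of units sharing a variant (default 0.20).
#' @param min_units a variant must occur in at least this many units to be
#'   considered common, regardless of the fraction (default 2, so a
#'   singleton is never "common" even in tiny comparisons).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(common_threshold = 0.20, min_units = 2L) {
  stopifnot(common_threshold > 0, common_threshold <= 1, min_units >= 1)
  structure(list(common_threshold = common_threshold,
                 min_units = as.integer(min_units)),
            class = "filter_config")
}

#' Build a background polymorphism filter from per-unit call sets
#'
#' Relaxed per-unit call sets are compared to each other; a variant enters
#' the filter iff it is present in `>= ceil(common_threshold * n_units)`
#' units (and at least `min_units`). Relaxed sets are used so that
#' borderline polymorphisms missed by stringent calling are still filtered.
#'
#' @param call_sets list of data.frames with columns seq_name, pos, alt
#'   (one per unit: line or pool).
#' @param config a `filter_config`.
#' @return object of class `background_filter`: data.frame (seq_name, pos,
#'   alt, n_units) of filtered variants, with attribute `n_units_compared`.
#' @export
build_background_filter <- function(call_sets, config = filter_config()) {
  stopifnot(is.list(call_sets))
  n <- length(call_sets)
  if (n < config$min_units) {
    stop(sprintf("need at least %d call sets, got %d", config$min_units, n))
  }
  per_unit <- lapply(call_sets, function(cs) {
    unique(paste(cs$seq_name, cs$pos, cs$alt, sep = "\r"))
  })
  tab <- table(unlist(per_unit, use.names = FALSE))
  need <- max(config$min_units, ceiling(config$common_threshold * n))
  common <- names(tab)[tab >= need]
  parts <- strsplit(common, "\r", fixed = TRUE)
  out <- data.frame(
    seq_name = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    alt = vapply(parts, `[`, character(1), 3L),
    n_units = as.integer(tab[common]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$seq_name, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_units_compared") <- n
  attr(out, "threshold_units") <- need
  class(out) <- c("background_filter", "data.frame")
  out
}

#' Remove background polymorphisms from a call set
#'
#' Drops calls whose (seq_name, pos, alt) is in the filter. Idempotent; the
#' number of removed calls is attached as attribute `n_removed`.
#'
#' @param calls data.frame of calls with seq_name, pos, alt.
#' @param filter a `background_filter` (or any data.frame with the three
#'   key columns).
#' @return filtered calls with attribute `n_removed`.
#' @export
apply_background_filter <- function(calls, filter) {
  key <- function(d) paste(d$seq_name, d$pos, d$alt, sep = "\r")
  hit <- key(calls) %in% key(filter)
  out <- calls[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(hit)
  out
}
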
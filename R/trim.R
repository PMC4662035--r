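#' Paired read container
#'
#' In-memory representation of a paired FASTQ: parallel character vectors of
#' read names, sequences and quality strings for the two mates.
#'
#' @param names read (pair) names.
#' @param r1,r2 mate sequences.
#' @param q1,q2 mate quality strings (Phred+33).
#' @return object of class `paired_reads`.
#' @export
paired_reads <- function(names, r1, r2, q1, q2) {
  n <- length(names)
  stopifnot(length(r1) == n, length(r2) == n, length(q1) == n, length(q2) == n)
  if (any(nchar(r1) != nchar(q1)) || any(nchar(r2) != nchar(q2))) {
    stop("sequence and quality lengths differ")
  }
  structure(list(names = names, r1 = r1, r2 = r2, q1 = q1, q2 = q2),
            class = "paired_reads")
}

#' @export
print.paired_reads <- function(x, ...) {
  cat(sprintf("paired_reads: %d pairs\n", length(x$names)))
  invisible(x)
}

#' @export
length.paired_reads <- function(x) length(x$names)

subset_pairs <- function(x, keep) {
  paired_reads(x$names[keep], x$r1[keep], x$r2[keep], x$q1[keep], x$q2[keep])
}

#' Trimming configuration
#'
#' Mirrors stringent read cleaning for mutation detection: fixed removal of
#' terminal nucleotides, quality trimming at an error-probability limit
#' (modified-Mott), a cap on ambiguous bases, and discarding short pairs.
#'
#' @param quality_limit error-probability threshold for quality trimming.
#' @param ambiguous_limit maximum number of N bases tolerated per read.
#' @param end_trim bases removed unconditionally from each read end.
#' @param min_pair_length pairs in which either mate ends up shorter than
#'   this are discarded entirely.
#' @return object of class `trim_config`.
#' @export
trim_config <- function(quality_limit = 0.01, ambiguous_limit = 2L,
                        end_trim = 3L, min_pair_length = 50L) {
  stopifnot(quality_limit > 0, quality_limit < 1, ambiguous_limit >= 0,
            end_trim >= 0, min_pair_length >= 0)
  structure(list(quality_limit = quality_limit,
                 ambiguous_limit = as.integer(ambiguous_limit),
                 end_trim = as.integer(end_trim),
                 min_pair_length = as.integer(min_pair_length)),
            class = "trim_config")
}

# modified-Mott quality trimming: keep the maximal-scoring contiguous
# segment under score(limit - p_error); returns c(start, end), 0,0 if empty
mott_segment <- function(qual_ints, limit) {
  p <- 10^(-qual_ints / 10)
  s <- cumsum(limit - p)
  prev <- c(0, s[-length(s)])
  prev_min <- cummin(prev)
  gain <- s - prev_min
  j <- which.max(gain)
  if (gain[j] <= 0) return(c(0L, 0L))
  i <- which(prev[seq_len(j)] == prev_min[j])[1L]
  c(i, j)
}

#' Trim paired reads
#'
#' Removes `end_trim` nucleotides from both ends of each mate, applies
#' modified-Mott quality trimming at `quality_limit`, discards reads with
#' more than `ambiguous_limit` N bases, and discards the whole pair when
#' either mate falls below `min_pair_length`.
#'
#' @param reads a `paired_reads` object.
#' @param config a `trim_config`.
#' @return list with `reads` (trimmed `paired_reads`) and `report` (input /
#'   surviving pair and base counts, and per-rule removal counts).
#' @export
trim_reads <- function(reads, config = trim_config()) {
  stopifnot(inherits(reads, "paired_reads"), inherits(config, "trim_config"))
  n <- length(reads)
  in_bases <- sum(nchar(reads$r1), nchar(reads$r2))

  trim_mate <- function(seqs, quals) {
    lens <- nchar(seqs)
    s0 <- pmin(config$end_trim + 1L, lens + 1L)
    e0 <- pmax(lens - config$end_trim, 0L)
    seqs <- ifelse(e0 >= s0, substr(seqs, s0, e0), "")
    quals <- ifelse(e0 >= s0, substr(quals, s0, e0), "")
    keep_rng <- vapply(quals, function(q) {
      if (nchar(q) == 0L) return(c(0L, 0L))
      mott_segment(utf8ToInt(q) - 33L, config$quality_limit)
    }, integer(2), USE.NAMES = FALSE)
    out_s <- ifelse(keep_rng[1L, ] > 0L,
                    substr(seqs, keep_rng[1L, ], keep_rng[2L, ]), "")
    out_q <- ifelse(keep_rng[1L, ] > 0L,
                    substr(quals, keep_rng[1L, ], keep_rng[2L, ]), "")
    list(s = out_s, q = out_q)
  }
  m1 <- trim_mate(reads$r1, reads$q1)
  m2 <- trim_mate(reads$r2, reads$q2)

  n_amb <- function(s) nchar(s) - nchar(gsub("N", "", s, fixed = TRUE))
  amb_fail <- n_amb(m1$s) > config$ambiguous_limit |
    n_amb(m2$s) > config$ambiguous_limit
  short_fail <- nchar(m1$s) < config$min_pair_length |
    nchar(m2$s) < config$min_pair_length
  keep <- !amb_fail & !short_fail

  out <- paired_reads(reads$names[keep], m1$s[keep], m2$s[keep],
                      m1$q[keep], m2$q[keep])
  list(reads = out,
       report = list(input_pairs = n, surviving_pairs = sum(keep),
                     input_bases = in_bases,
                     surviving_bases = sum(nchar(out$r1), nchar(out$r2)),
                     removed_ambiguous = sum(amb_fail),
                     removed_short = sum(short_fail & !amb_fail)))
}
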
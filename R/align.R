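#' Gapless amplicon alignment to stranded pileups
#'
#' Places each mate by exact 31-mer seeding plus ungapped extension against
#' a small set of amplicon reference sequences, then accumulates per-position
#' per-strand base counts. A read is accepted only if at least
#' `min_aligned_frac` of it lies on the reference and its identity over the
#' aligned part is at least `min_identity`; reads seeded by a k-mer that
#' occurs more than once in the references are dropped as non-specific, and
#' pairs with a failing mate are excluded entirely (broken pairs ignored).
#' Indels are not modeled: induced EMS changes are single-base substitutions
#' and indels are excluded from calling.
#'
#' Mismatching bases contribute to the pileup's alt counts only if the
#' central base quality, the mean quality in the +/- `neighborhood_radius`
#' window, and the mismatch count in that window pass the caller's quality
#' gates; failing contributions still count toward coverage (`disq` column).
#'
#' @param reads a `paired_reads` object (typically trimmed).
#' @param amplicon_refs named character vector of amplicon sequences.
#' @param k seed k-mer length.
#' @param min_aligned_frac minimum fraction of the read aligned.
#' @param min_identity minimum identity over the aligned part.
#' @param central_quality_min,neighborhood_radius,neighborhood_quality_min,max_mismatches_in_window
#'   per-read quality gates applied to mismatch contributions.
#' @return list with `pileup` (a `stranded_pileup` data.frame: seq_name, pos,
#'   ref, A_F..T_R, disq, mq_A..mq_T) and `stats` (pair accounting).
#' @export
align_gapless <- function(reads, amplicon_refs, k = 31L,
                          min_aligned_frac = 0.9, min_identity = 0.96,
                          central_quality_min = 20L, neighborhood_radius = 5L,
                          neighborhood_quality_min = 15L,
                          max_mismatches_in_window = 2L) {
  stopifnot(inherits(reads, "paired_reads"),
            is.character(amplicon_refs), !is.null(names(amplicon_refs)))
  amplicon_refs <- toupper(amplicon_refs)
  amp_names <- names(amplicon_refs)
  L_amp <- nchar(amplicon_refs)
  n_amp <- length(amplicon_refs)
  if (any(L_amp < k)) stop("amplicon shorter than seed k-mer length")

  # --- seed dictionary ------------------------------------------------
  kms <- lapply(seq_len(n_amp), function(ai) {
    p <- seq_len(L_amp[ai] - k + 1L)
    list(key = substring(amplicon_refs[ai], p, p + k - 1L),
         amp = rep(ai, length(p)), pos = p)
  })
  keys <- unlist(lapply(kms, `[[`, "key"), use.names = FALSE)
  kamp <- unlist(lapply(kms, `[[`, "amp"), use.names = FALSE)
  kpos <- unlist(lapply(kms, `[[`, "pos"), use.names = FALSE)
  dup <- keys %in% keys[duplicated(keys)]
  kamp[dup] <- -1L    # ambiguous seed marker
  first <- !duplicated(keys)
  keys <- keys[first]; kamp <- kamp[first]; kpos <- kpos[first]

  ref_chars <- strsplit(amplicon_refs, "")
  cat_ref <- unlist(ref_chars, use.names = FALSE)
  amp_off <- cumsum(c(0L, L_amp[-n_amp]))  # cat_ref index = amp_off[ai] + pos

  verify <- function(seqs, amp, st) {
    lens <- nchar(seqs)
    a_lo <- pmax(1L, st)
    a_hi <- pmin(L_amp[amp], st + lens - 1L)
    alen <- pmax(0L, a_hi - a_lo + 1L)
    ok_frac <- alen >= min_aligned_frac * lens & alen > 0L
    mm <- rep(NA_integer_, length(seqs))
    idx <- which(ok_frac)
    if (length(idx)) {
      r_lo <- a_lo[idx] - st[idx] + 1L
      sub <- substr(seqs[idx], r_lo, r_lo + alen[idx] - 1L)
      rch <- strsplit(sub, "")
      grp <- rep(seq_along(idx), alen[idx])
      pos_flat <- unlist(lapply(seq_along(idx), function(j)
        seq.int(a_lo[idx[j]], length.out = alen[idx[j]])), use.names = FALSE)
      ref_flat <- cat_ref[amp_off[amp[idx]][grp] + pos_flat]
      mmv <- unlist(rch, use.names = FALSE) != ref_flat
      mm[idx] <- as.integer(rowsum(as.integer(mmv), grp))
    }
    ok <- ok_frac & !is.na(mm) & (alen - mm) >= min_identity * alen
    list(ok = ok, a_lo = a_lo, a_hi = a_hi)
  }

  # place one mate vector; returns amp (NA unplaced, -1 ambiguous), start, strand
  place <- function(seqs) {
    n <- length(seqs)
    amp <- rep(NA_integer_, n)
    start <- rep(NA_integer_, n)
    strand <- rep(NA_character_, n)
    oriented <- seqs
    rc <- NULL
    for (str in c("F", "R")) {
      if (str == "R") {
        rc <- revcomp_many(seqs)
        oriented <- rc
      }
      for (t in 0:3) {
        off <- 1L + t * k
        open <- which(is.na(amp) & nchar(oriented) >= off + k - 1L)
        if (!length(open)) next
        km <- substr(oriented[open], off, off + k - 1L)
        m <- match(km, keys)
        hit <- which(!is.na(m))
        if (!length(hit)) next
        ri <- open[hit]; mi <- m[hit]
        ambig <- kamp[mi] < 0L
        amp[ri[ambig]] <- -1L
        good <- !ambig
        if (any(good)) {
          ri <- ri[good]; mi <- mi[good]
          cand_st <- kpos[mi] - off + 1L
          v <- verify(oriented[ri], kamp[mi], cand_st)
          acc <- v$ok
          amp[ri[acc]] <- kamp[mi][acc]
          start[ri[acc]] <- cand_st[acc]
          strand[ri[acc]] <- str
        }
      }
    }
    list(amp = amp, start = start, strand = strand,
         oriented_rc = rc)
  }

  p1 <- place(reads$r1)
  p2 <- place(reads$r2)
  placed1 <- !is.na(p1$amp) & p1$amp > 0L
  placed2 <- !is.na(p2$amp) & p2$amp > 0L
  pair_ok <- placed1 & placed2 & p1$amp == p2$amp
  n_ambig <- sum((!is.na(p1$amp) & p1$amp < 0L) | (!is.na(p2$amp) & p2$amp < 0L))

  orient_seq <- function(seqs, rc, strand) ifelse(strand == "R", rc, seqs)
  rev_str <- function(x) vapply(x, function(s)
    intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)

  keep <- which(pair_ok)
  seqs <- c(orient_seq(reads$r1, p1$oriented_rc %||% revcomp_many(reads$r1), p1$strand)[keep],
            orient_seq(reads$r2, p2$oriented_rc %||% revcomp_many(reads$r2), p2$strand)[keep])
  quals <- c(ifelse(p1$strand[keep] == "R", rev_str(reads$q1[keep]), reads$q1[keep]),
             ifelse(p2$strand[keep] == "R", rev_str(reads$q2[keep]), reads$q2[keep]))
  amp <- c(p1$amp[keep], p2$amp[keep])
  st <- c(p1$start[keep], p2$start[keep])
  strand <- c(p1$strand[keep], p2$strand[keep])

  pile <- build_pileup(seqs, quals, amp, st, strand, amplicon_refs, cat_ref,
                       amp_off, L_amp,
                       central_quality_min, neighborhood_radius,
                       neighborhood_quality_min, max_mismatches_in_window)
  list(pileup = pile,
       stats = list(input_pairs = length(reads),
                    placed_pairs = length(keep),
                    ambiguous_reads = n_ambig,
                    broken_or_unmapped_pairs = length(reads) - length(keep)))
}

# accumulate the stranded pileup from oriented placed reads
build_pileup <- function(seqs, quals, amp, st, strand, amplicon_refs,
                         cat_ref, amp_off, L_amp,
                         cq_min, radius, nq_min, max_mm) {
  n_amp <- length(amplicon_refs)
  total_cols <- sum(L_amp)
  counts <- integer(total_cols * 9L)   # 8 base-strand slots + disq
  qsum <- numeric(total_cols * 4L)
  qcnt <- integer(total_cols * 4L)

  if (length(seqs)) {
    lens <- nchar(seqs)
    a_lo <- pmax(1L, st)
    a_hi <- pmin(L_amp[amp], st + lens - 1L)
    alen <- a_hi - a_lo + 1L
    r_lo <- a_lo - st + 1L
    sub_s <- substr(seqs, r_lo, r_lo + alen - 1L)
    sub_q <- substr(quals, r_lo, r_lo + alen - 1L)
    grp <- rep(seq_along(seqs), alen)
    base_flat <- unlist(strsplit(sub_s, ""), use.names = FALSE)
    qual_flat <- unlist(lapply(sub_q, function(q) utf8ToInt(q) - 33L),
                        use.names = FALSE)
    pos_flat <- unlist(lapply(seq_along(seqs), function(j)
      seq.int(a_lo[j], length.out = alen[j])), use.names = FALSE)
    colid <- amp_off[amp][grp] + pos_flat
    mm <- base_flat != cat_ref[colid]

    # windowed mismatch count / mean quality with per-read clamping
    b <- cumsum(alen); a <- b - alen + 1L
    i <- seq_along(colid)
    lo <- pmax(i - radius, a[grp]); hi <- pmin(i + radius, b[grp])
    cs_mm <- c(0L, cumsum(mm))
    cs_q <- c(0, cumsum(qual_flat))
    win_mm <- cs_mm[hi + 1L] - cs_mm[lo]
    win_q <- (cs_q[hi + 1L] - cs_q[lo]) / (hi - lo + 1L)

    bidx <- match(base_flat, DNA_BASES)          # NA for N
    qualified <- !is.na(bidx) &
      (!mm | (qual_flat >= cq_min & win_q >= nq_min & win_mm <= max_mm))
    sidx <- ifelse(strand[grp] == "F", 1L, 2L)
    slot <- ifelse(qualified, (bidx - 1L) * 2L + sidx, 9L)
    tab <- tabulate((colid - 1L) * 9L + slot, nbins = total_cols * 9L)
    counts <- counts + tab
    qi <- which(qualified)
    qg <- (colid[qi] - 1L) * 4L + bidx[qi]
    qs <- rowsum(qual_flat[qi], qg)
    lev <- as.integer(rownames(qs))
    qsum[lev] <- qsum[lev] + qs[, 1L]
    qcnt[lev] <- qcnt[lev] + tabulate(qg, nbins = total_cols * 4L)[lev]
  }

  cmat <- matrix(counts, ncol = 9L, byrow = TRUE)
  qs_m <- matrix(qsum, ncol = 4L, byrow = TRUE)
  qc_m <- matrix(qcnt, ncol = 4L, byrow = TRUE)
  mq <- ifelse(qc_m > 0L, qs_m / qc_m, NA_real_)
  df <- data.frame(
    seq_name = rep(names(amplicon_refs), L_amp),
    pos = unlist(lapply(L_amp, seq_len), use.names = FALSE),
    ref = cat_ref,
    A_F = cmat[, 1L], A_R = cmat[, 2L], C_F = cmat[, 3L], C_R = cmat[, 4L],
    G_F = cmat[, 5L], G_R = cmat[, 6L], T_F = cmat[, 7L], T_R = cmat[, 8L],
    disq = cmat[, 9L],
    mq_A = mq[, 1L], mq_C = mq[, 2L], mq_G = mq[, 3L], mq_T = mq[, 4L],
    stringsAsFactors = FALSE
  )
  class(df) <- c("stranded_pileup", "data.frame")
  df
}

#' Coverage of pileup columns
#'
#' Total read coverage per column: all qualified base counts plus
#' quality-disqualified contributions.
#'
#' @param pileup a `stranded_pileup`.
#' @return integer vector of per-column coverage.
#' @export
pileup_coverage <- function(pileup) {
  as.integer(rowSums(pileup[, c("A_F", "A_R", "C_F", "C_R",
                                "G_F", "G_R", "T_F", "T_R", "disq")]))
}
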
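#' Default EMS substitution spectrum
#'
#' Proportions of the 12 directed substitution classes observed genome-wide
#' in a doubly EMS-treated soybean library (G>A and C>T transitions dominate,
#' together ~69%). The printed percentages (34.8, 34.6, 9.1, 8.7, 2.5, 2.4,
#' 2.0, 1.9, 1.5, 1.5, 0.6, 0.5) sum to 100.1 because of rounding; they are
#' normalized here so the model sums to exactly 1.
#'
#' @param proportions named numeric vector over the 12 classes; any
#'   non-negative weights, normalized internally.
#' @return object of class `spectrum_model`: named numeric summing to 1.
#' @export
spectrum_model <- function(proportions = NULL) {
  if (is.null(proportions)) {
    proportions <- c(34.8, 34.6, 9.1, 8.7, 2.5, 2.4, 2.0, 1.9, 1.5, 1.5, 0.6, 0.5)
    names(proportions) <- SUBSTITUTION_CLASSES
  }
  if (is.null(names(proportions))) {
    stopifnot(length(proportions) == 12L)
    names(proportions) <- SUBSTITUTION_CLASSES
  }
  if (!setequal(names(proportions), SUBSTITUTION_CLASSES)) {
    stop("spectrum proportions must be named by the 12 substitution classes")
  }
  proportions <- proportions[SUBSTITUTION_CLASSES]
  if (any(proportions < 0) || sum(proportions) <= 0) {
    stop("spectrum proportions must be non-negative and not all zero")
  }
  p <- proportions / sum(proportions)
  structure(p, class = "spectrum_model")
}

# split "G>A" into c(ref, alt)
split_class <- function(cls) {
  m <- regmatches(cls, regexec("^([ACGT])>([ACGT])$", cls))[[1]]
  if (length(m) != 3L) stop("bad substitution class: ", cls)
  m[2:3]
}

#' Build a toy amplicon reference with gene models
#'
#' Constructs `n_genes` small contigs, each carrying one protein-coding gene
#' (ATG ... stop, no internal stop codons) optionally split by a canonical
#' GT..AG intron. Genes alternate between the + and - strand so both are
#' exercised downstream. Deterministic for a given seed.
#'
#' @param n_genes number of genes/contigs (>= 1).
#' @param gene_length coding length in bp, >= 60 and divisible by 3.
#' @param seed integer RNG seed.
#' @param flank untranscribed flank on each side of the gene, bp.
#' @param introns number of introns per gene (0 or 1).
#' @param intron_length intron size, bp.
#' @return object of class `reference_set`: list with `sequences` (named
#'   uppercase character vector) and `gene_models` (data.frame with one row
#'   per CDS interval: gene_id, seq_name, strand, start, end, phase).
#' @export
build_toy_reference <- function(n_genes, gene_length = 300L, seed = 1L,
                                flank = 60L, introns = 1L, intron_length = 60L) {
  stop_if_not_scalar_pos(n_genes, "n_genes", integer = TRUE)
  stop_if_not_scalar_pos(gene_length, "gene_length", integer = TRUE)
  if (gene_length < 60 || gene_length %% 3 != 0) {
    stop("'gene_length' must be >= 60 and divisible by 3")
  }
  if (!introns %in% c(0L, 1L)) stop("'introns' must be 0 or 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste0, collapse = "")
  internal <- setdiff(codons, stops)

  seqs <- character(n_genes)
  names(seqs) <- sprintf("amp%02d", seq_len(n_genes))
  gm <- list()
  for (i in seq_len(n_genes)) {
    n_codon <- gene_length / 3L
    cds <- paste0("ATG",
                  paste0(sample(internal, n_codon - 2L, replace = TRUE), collapse = ""),
                  sample(stops, 1L))
    strand <- if (i %% 2L == 1L) "+" else "-"
    if (introns == 1L) {
      # split near the middle, not necessarily at a codon boundary, so the
      # second interval can carry a nonzero GFF3 phase
      cut <- min(gene_length - 3L, 3L * floor(n_codon / 2L) + sample(0:2, 1L))
      intron <- paste0("GT",
                       paste0(sample(DNA_BASES, intron_length - 4L, replace = TRUE),
                              collapse = ""),
                       "AG")
      gene_genomic <- paste0(substr(cds, 1L, cut), intron,
                             substr(cds, cut + 1L, gene_length))
      ex1 <- c(flank + 1L, flank + cut)
      ex2 <- c(flank + cut + intron_length + 1L,
               flank + gene_length + intron_length)
      ivs <- rbind(ex1, ex2)
    } else {
      gene_genomic <- cds
      ivs <- rbind(c(flank + 1L, flank + gene_length))
    }
    fl5 <- paste0(sample(DNA_BASES, flank, replace = TRUE), collapse = "")
    fl3 <- paste0(sample(DNA_BASES, flank, replace = TRUE), collapse = "")
    if (strand == "+") {
      seqs[i] <- paste0(fl5, gene_genomic, fl3)
    } else {
      seqs[i] <- paste0(fl5, revcomp(gene_genomic), fl3)
      # genomic coordinates of the reverse-complemented gene body: position p
      # (in flank+gene coords) maps to 2*flank + glen - p + 1
      glen <- nchar(gene_genomic)
      m <- 2L * flank + glen + 1L
      ivs <- rbind(
        c(m - ivs[nrow(ivs), 2L], m - ivs[nrow(ivs), 1L]),
        if (nrow(ivs) == 2L) c(m - ivs[1L, 2L], m - ivs[1L, 1L])
      )
    }
    n_iv <- nrow(ivs)
    # GFF3 phases along translation order (5' exon first)
    lens <- ivs[, 2L] - ivs[, 1L] + 1L
    if (strand == "-") lens <- rev(lens)
    phases <- (3L - (cumsum(c(0L, lens[-n_iv])) %% 3L)) %% 3L
    if (strand == "-") phases <- rev(phases)
    gm[[i]] <- data.frame(
      gene_id = sprintf("gene%02d", i), seq_name = names(seqs)[i],
      strand = strand, start = ivs[, 1L], end = ivs[, 2L],
      phase = phases, stringsAsFactors = FALSE
    )
  }
  reference_set(seqs, do.call(rbind, gm))
}

#' Construct and validate a reference set
#'
#' @param sequences named character vector of uppercase DNA sequences.
#' @param gene_models data.frame of CDS intervals (gene_id, seq_name, strand,
#'   start, end, phase).
#' @return `reference_set` object.
#' @export
reference_set <- function(sequences, gene_models) {
  if (length(sequences) == 0L || is.null(names(sequences))) {
    stop("'sequences' must be a non-empty named character vector")
  }
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGT]", sequences))) {
    stop("reference sequences may contain only A, C, G, T")
  }
  gene_models$start <- as.integer(gene_models$start)
  gene_models$end <- as.integer(gene_models$end)
  gene_models$phase <- as.integer(gene_models$phase)
  bad <- !(gene_models$seq_name %in% names(sequences)) |
    gene_models$start < 1L |
    gene_models$end > nchar(sequences)[match(gene_models$seq_name, names(sequences))]
  if (any(bad)) stop("gene model intervals fall outside their sequence")
  structure(list(sequences = sequences, gene_models = gene_models),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d sequence(s), %d bp total, %d gene(s)\n",
              length(x$sequences), sum(nchar(x$sequences)),
              length(unique(x$gene_models$gene_id))))
  invisible(x)
}

genome_size <- function(reference) sum(nchar(reference$sequences))

# save/restore global RNG so seeded generators do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default per-round mutation density
#'
#' The library averaged 12,796 base changes per plant over a 950,068,807 bp
#' genome. With two mutagenesis rounds contributing equally to the observed
#' per-plant count and first-round (family) mutations transmitted to a
#' descendant with probability 3/4, the drawn per-round densities are
#' `target/2 / genome` for round 2 and `target/2 / 0.75 / genome` for round 1.
#'
#' @param per_plant target observed mutations per plant genome-wide.
#' @param genome_bp genome size the target refers to.
#' @return named numeric c(round1=, round2=), mutations drawn per bp.
#' @export
default_per_round_density <- function(per_plant = 12796, genome_bp = 950068807) {
  half <- per_plant / 2 / genome_bp
  c(round1 = half / 0.75, round2 = half)
}

#' Expected observed mutations per plant under the transmission model
#'
#' @param reference a `reference_set`.
#' @param per_round_density length-2 (round1, round2) or scalar density/bp.
#' @return expected number of mutation events per plant.
#' @export
expected_mutations_per_plant <- function(reference, per_round_density) {
  d <- rep(per_round_density, length.out = 2L)
  g <- genome_size(reference)
  0.75 * g * d[1L] + g * d[2L]
}

#' Simulate a doubly-mutagenized selfing population
#'
#' Emulates two rounds of EMS seed treatment on a selfing species. Round-1
#' mutations are drawn once per M1 family and transmitted to each descendant
#' plant with probability 3/4 (homozygous:heterozygous = 1:2 among carriers,
#' Mendelian selfing); round-2 mutations are drawn independently per plant
#' and carried het:hom = 2:1. Substitution classes follow `spectrum`; the
#' drawn site always has the class's source base in the reference.
#'
#' @param reference a `reference_set`.
#' @param n_plants number of plants (lines) in the library.
#' @param spectrum a `spectrum_model` (default: EMS spectrum).
#' @param per_round_density mutations drawn per bp per round; scalar or
#'   length-2 (round1, round2). Default reproduces ~12,796 observed
#'   mutations per plant scaled to the toy genome.
#' @param m1_family_size number of library plants descending from one
#'   round-1 mutagenized ancestor (default 4).
#' @param seed integer RNG seed.
#' @param max_collision_frac error if more than this fraction of draws
#'   cannot be placed without reusing a site within a line/family.
#' @return data.frame of mutation events: line_id, seq_name, pos, ref, alt,
#'   zygosity (het/hom), origin (round1/round2), hap (1/2; carrier haplotype
#'   for het, 0 = both for hom), family.
#' @export
simulate_population <- function(reference, n_plants = 1536L,
                                spectrum = spectrum_model(),
                                per_round_density = default_per_round_density(),
                                m1_family_size = 4L, seed = 1L,
                                max_collision_frac = 0.05) {
  stopifnot(inherits(reference, "reference_set"))
  stop_if_not_scalar_pos(n_plants, "n_plants", integer = TRUE)
  d <- rep(per_round_density, length.out = 2L)
  if (any(d <= 0)) stop("'per_round_density' must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 1L))

  g <- genome_size(reference)
  # eligible sites per source base, as (seq index, pos)
  seqs <- reference$sequences
  chars <- strsplit(seqs, "")
  site_index <- lapply(DNA_BASES, function(b) {
    do.call(rbind, lapply(seq_along(chars), function(i) {
      p <- which(chars[[i]] == b)
      if (length(p)) cbind(i, p) else NULL
    }))
  })
  names(site_index) <- DNA_BASES

  p_class <- as.numeric(spectrum)
  names(p_class) <- names(spectrum)
  src <- vapply(names(p_class), function(cl) split_class(cl)[1L], character(1))
  alt <- vapply(names(p_class), function(cl) split_class(cl)[2L], character(1))
  n_src <- vapply(src, function(b) {
    s <- site_index[[b]]
    if (is.null(s)) 0L else nrow(s)
  }, integer(1))
  if (any(p_class > 0 & n_src == 0L)) {
    warning("some substitution classes have no eligible reference site; ",
            "their draws are dropped")
  }

  line_ids <- sprintf("L%04d", seq_len(n_plants))
  n_fam <- ceiling(n_plants / m1_family_size)
  family <- rep(seq_len(n_fam), each = m1_family_size)[seq_len(n_plants)]

  # draw n mutation sites for one carrier unit, avoiding same-site reuse
  draw_events <- function(n) {
    if (n == 0L) return(NULL)
    out_seq <- integer(0); out_pos <- integer(0)
    out_ref <- character(0); out_alt <- character(0)
    attempts <- 0L; tot_draws <- 0L
    while (length(out_pos) < n) {
      attempts <- attempts + 1L
      # redraw cap: 100x the target count of draws in total
      if (attempts > 100L || tot_draws > max(100L, 100L * n)) {
        stop("site collision rate exceeds ", max_collision_frac,
             ": density too large for this reference")
      }
      need <- n - length(out_pos)
      tot_draws <- tot_draws + need
      cls <- sample.int(12L, need, replace = TRUE, prob = p_class)
      keep <- n_src[cls] > 0L
      cls <- cls[keep]
      if (!length(cls)) {
        if (all(n_src[p_class > 0] == 0L)) return(NULL) else next
      }
      for (k in cls) {
        s <- site_index[[src[k]]]
        j <- s[sample.int(nrow(s), 1L), ]
        dup <- any(out_seq == j[1L] & out_pos == j[2L])
        if (!dup) {
          out_seq <- c(out_seq, j[1L]); out_pos <- c(out_pos, j[2L])
          out_ref <- c(out_ref, src[k]); out_alt <- c(out_alt, alt[k])
        }
      }
    }
    data.frame(seq_name = names(seqs)[out_seq], pos = out_pos,
               ref = out_ref, alt = out_alt, stringsAsFactors = FALSE)
  }

  res <- vector("list", 2L * n_fam + n_plants)
  ri <- 0L
  # round 1: drawn per M1 family, transmitted to descendants
  lambda1 <- g * d[1L]
  for (f in seq_len(n_fam)) {
    nmut <- stats::rpois(1L, lambda1)
    ev <- draw_events(nmut)
    if (is.null(ev) || nrow(ev) == 0L) next
    members <- line_ids[family == f]
    for (ln in members) {
      carried <- runif(nrow(ev)) < 0.75
      if (!any(carried)) next
      e <- ev[carried, , drop = FALSE]
      hom <- runif(nrow(e)) < 1 / 3
      ri <- ri + 1L
      res[[ri]] <- data.frame(
        line_id = ln, e,
        zygosity = ifelse(hom, "hom", "het"),
        origin = "round1",
        hap = ifelse(hom, 0L, sample(c(1L, 2L), nrow(e), replace = TRUE)),
        family = f, stringsAsFactors = FALSE
      )
    }
  }
  # round 2: independent per plant
  lambda2 <- g * d[2L]
  for (i in seq_len(n_plants)) {
    nmut <- stats::rpois(1L, lambda2)
    ev <- draw_events(nmut)
    if (is.null(ev) || nrow(ev) == 0L) next
    hom <- runif(nrow(ev)) < 1 / 3
    ri <- ri + 1L
    res[[ri]] <- data.frame(
      line_id = line_ids[i], ev,
      zygosity = ifelse(hom, "hom", "het"),
      origin = "round2",
      hap = ifelse(hom, 0L, sample(c(1L, 2L), nrow(ev), replace = TRUE)),
      family = family[i], stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res[seq_len(ri)])
  if (is.null(out)) {
    out <- data.frame(line_id = character(0), seq_name = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      zygosity = character(0), origin = character(0),
                      hap = integer(0), family = integer(0),
                      stringsAsFactors = FALSE)
  }
  # a plant can draw the same site in round 1 and round 2: keep round 2
  # (redraw-by-drop; rare at realistic densities)
  key <- paste(out$line_id, out$seq_name, out$pos)
  dup <- duplicated(key, fromLast = TRUE)
  out <- out[!dup, , drop = FALSE]
  out <- out[order(out$line_id, out$seq_name, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_plants") <- n_plants
  attr(out, "line_ids") <- line_ids
  attr(out, "family") <- stats::setNames(family, line_ids)
  out
}
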
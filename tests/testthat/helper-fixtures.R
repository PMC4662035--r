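# shared fixtures, all built in code

# single-pool toy world used by several suites
toy_world <- function(n_plants = 32L, seed = 7L, density = c(2e-4, 2e-4),
                      gene_length = 300L) {
  ref <- build_toy_reference(2L, gene_length, seed = seed)
  pop <- simulate_population(ref, n_plants = n_plants,
                             per_round_density = density, seed = seed)
  lay <- assign_indexes(build_layout(n_plants))
  list(ref = ref, pop = pop, lay = lay)
}

amplicon_refs <- function(ref) {
  amps <- default_amplicons(ref)
  stats::setNames(substr(ref$sequences[amps$seq_name], amps$start, amps$end),
                  amps$amplicon_id)
}

# one-column stranded pileup, for caller unit tests
one_column_pileup <- function(ref_base = "G", alt_base = "A",
                              alt_F = 0L, alt_R = 0L, coverage = 96L,
                              mq = 35) {
  cols <- list(seq_name = "amp01", pos = 1L, ref = ref_base)
  for (b in c("A", "C", "G", "T")) {
    cols[[paste0(b, "_F")]] <- 0L
    cols[[paste0(b, "_R")]] <- 0L
  }
  cols[[paste0(alt_base, "_F")]] <- alt_F
  cols[[paste0(alt_base, "_R")]] <- alt_R
  rest <- coverage - alt_F - alt_R
  stopifnot(rest >= 0L)
  cols[[paste0(ref_base, "_F")]] <- rest %/% 2L
  cols[[paste0(ref_base, "_R")]] <- rest - rest %/% 2L
  cols$disq <- 0L
  for (b in c("A", "C", "G", "T")) cols[[paste0("mq_", b)]] <- mq
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  class(df) <- c("stranded_pileup", "data.frame")
  df
}

# n random single-base substitutions on a reference (uses current RNG)
random_mutations <- function(ref, n) {
  sq <- sample(names(ref$sequences), n, replace = TRUE)
  pos <- vapply(sq, function(s) sample(nchar(ref$sequences[[s]]), 1L),
                integer(1), USE.NAMES = FALSE)
  rb <- substr(ref$sequences[sq], pos, pos)
  ab <- vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
               character(1), USE.NAMES = FALSE)
  data.frame(seq_name = sq, pos = pos, ref = rb, alt = ab,
             stringsAsFactors = FALSE)
}

# paper Table 3 record fixture: 26 per-line mutations in a 1144-bp region,
# with duplicates at 6 positions (x3, x2, x2, x2, x2, x3)
table3_records <- function() {
  pos <- c(34688627, 34688652, 34688672,
           34688682, 34688682, 34688682,
           34688686, 34688686,
           34688696, 34688696,
           34688713, 34688719,
           34689275, 34689275,
           34689313, 34689360, 34689704, 34689710,
           34690049, 34690058,
           34690175, 34690175,
           34690246,
           34690247, 34690247, 34690247)
  ref <- rep("G", length(pos))
  alt <- rep("A", length(pos))
  # one record is an A>T transversion; the rest G>A or C>T
  alt[pos == 34689710] <- "T"; ref[pos == 34689710] <- "A"
  ct <- pos %in% c(34688652, 34688696, 34688713, 34688719, 34689313,
                   34689704, 34690175, 34690247)
  ref[ct] <- "C"; alt[ct] <- "T"
  data.frame(line_id = sprintf("EnT-%04d", seq_along(pos)),
             seq_name = "Gm20", pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# paper Table 5 counts: per-gene (total, common, a_only, b_only)
table5_counts <- function() {
  data.frame(
    gene_id = c("Glyma20g25000", "Glyma08g46520", "Glyma06g23026",
                "Glyma20g22160", "Glyma11g15580"),
    region_bp = c(1144L, 487L, 305L, 1187L, 380L),
    total = c(37L, 22L, 12L, 24L, 12L),
    common = c(14L, 13L, 7L, 12L, 7L),
    a_only = c(4L, 1L, 0L, 4L, 2L),
    b_only = c(19L, 8L, 5L, 8L, 3L),
    stringsAsFactors = FALSE)
}

# expand table5 counts into synthetic keyed call sets
table5_call_sets <- function() {
  tc <- table5_counts()
  a <- list(); b <- list()
  for (i in seq_len(nrow(tc))) {
    g <- tc$gene_id[i]
    mk <- function(n, off) if (n > 0L)
      data.frame(gene_id = g, pos = off + seq_len(n), alt = "A",
                 stringsAsFactors = FALSE)
    com <- mk(tc$common[i], 0L)
    ao <- mk(tc$a_only[i], 1000L)
    bo <- mk(tc$b_only[i], 2000L)
    a[[i]] <- rbind(com, ao)
    b[[i]] <- rbind(com, bo)
  }
  list(a = do.call(rbind, a), b = do.call(rbind, b),
       regions = tc[, c("gene_id", "region_bp")])
}
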
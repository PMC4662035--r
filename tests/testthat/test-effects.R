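# tiny hand-built gene: CDS = ATG GAT TGG TAA (Met Asp Trp *)
toy_gene_ref <- function(strand = "+") {
  cds <- "ATGGATTGGTAA"
  if (strand == "+") {
    seqs <- c(chr1 = cds)
  } else {
    seqs <- c(chr1 = amptill:::revcomp(cds))
  }
  gm <- data.frame(gene_id = "g1", seq_name = "chr1", strand = strand,
                   start = 1L, end = 12L, phase = 0L,
                   stringsAsFactors = FALSE)
  reference_set(seqs, gm)
}

test_that("codon-level effects and labels on a hand-built gene", {
  ref <- toy_gene_ref("+")
  mut <- data.frame(seq_name = "chr1", pos = 4L, ref = "G", alt = "A",
                    stringsAsFactors = FALSE)
  eff <- annotate_effect(mut, ref)
  expect_identical(eff$effect, "missense")
  expect_identical(eff$label, "Asp2Asn")
  expect_identical(eff$aa_pos, 2L)

  nonsense <- annotate_effect(
    data.frame(seq_name = "chr1", pos = 9L, ref = "G", alt = "A"), ref)
  expect_identical(nonsense$effect, "nonsense")
  expect_identical(nonsense$label, "Trp3*")

  syn <- annotate_effect(
    data.frame(seq_name = "chr1", pos = 6L, ref = "T", alt = "C"), ref)
  expect_identical(syn$effect, "synonymous")
  expect_identical(syn$label, "Syn")

  stop_loss <- annotate_effect(
    data.frame(seq_name = "chr1", pos = 10L, ref = "T", alt = "C"), ref)
  expect_identical(stop_loss$effect, "stop_loss")

  # position off the CDS -> noncoding
  ref2 <- reference_set(c(chr1 = paste0("ATGGATTGGTAA", "ACGT")),
                        toy_gene_ref("+")$gene_models)
  nc <- annotate_effect(
    data.frame(seq_name = "chr1", pos = 14L, ref = "C", alt = "T"), ref2)
  expect_identical(nc$effect, "noncoding")

  expect_error(annotate_effect(
    data.frame(seq_name = "chr1", pos = 4L, ref = "C", alt = "A"), ref),
    "reference mismatch")
})

test_that("strand symmetry: the same biological change annotates identically", {
  fwd <- toy_gene_ref("+")
  rev <- toy_gene_ref("-")
  # CDS position 4 G>A on + strand is genomic position 12-4+1=9, C>T on -
  e_f <- annotate_effect(
    data.frame(seq_name = "chr1", pos = 4L, ref = "G", alt = "A"), fwd)
  e_r <- annotate_effect(
    data.frame(seq_name = "chr1", pos = 9L, ref = "C", alt = "T"), rev)
  expect_identical(e_f[, c("effect", "aa_ref", "aa_pos", "aa_alt", "label")],
                   e_r[, c("effect", "aa_ref", "aa_pos", "aa_alt", "label")])
})

test_that("substitution classification partitions the 12 classes", {
  expect_identical(classify_substitution("G", "A")$class, "G>A")
  expect_identical(classify_substitution("G", "A")$type, "transition")
  expect_identical(classify_substitution("A", "T")$type, "transversion")
  expect_error(classify_substitution("G", "G"))
  expect_error(classify_substitution("G", "N"))
  all_pairs <- expand.grid(r = c("A", "C", "G", "T"), a = c("A", "C", "G", "T"),
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$r != all_pairs$a, ]
  cls <- mapply(function(r, a) classify_substitution(r, a),
                all_pairs$r, all_pairs$a, SIMPLIFY = FALSE)
  expect_setequal(vapply(cls, `[[`, character(1), "class"),
                  amptill:::SUBSTITUTION_CLASSES)
  types <- vapply(cls, `[[`, character(1), "type")
  expect_identical(sum(types == "transition"), 4L)
  expect_identical(sum(types == "transversion"), 8L)
})

# independent oracle: mutate the spliced CDS string, translate both
# proteins with Biostrings and derive the effect from the comparison
oracle_effect <- function(mut, ref) {
  gm <- ref$gene_models
  hit <- NULL
  for (g in unique(gm$gene_id)) {
    rows <- gm[gm$gene_id == g, ]
    if (rows$seq_name[1] != mut$seq_name) next
    cl <- amptill:::gene_cds(rows, ref$sequences[[rows$seq_name[1]]])
    ci <- match(mut$pos, cl$gpos)
    if (!is.na(ci)) { hit <- list(cl = cl, ci = ci, g = g); break }
  }
  if (is.null(hit)) return(list(effect = "noncoding"))
  cds <- hit$cl$cds
  alt_base <- if (hit$cl$strand == "-")
    amptill:::complement_base(mut$alt) else mut$alt
  cds_alt <- cds
  substr(cds_alt, hit$ci, hit$ci) <- unname(alt_base)
  p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                              no.init.codon = TRUE))
  p_alt <- as.character(Biostrings::translate(Biostrings::DNAString(cds_alt),
                                              no.init.codon = TRUE))
  codon_i <- (hit$ci - 1L) %/% 3L + 1L
  a_ref <- substr(p_ref, codon_i, codon_i)
  a_alt <- substr(p_alt, codon_i, codon_i)
  eff <- if (a_ref == a_alt) "synonymous"
  else if (a_alt == "*") "nonsense"
  else if (a_ref == "*") "stop_loss"
  else "missense"
  list(effect = eff, aa_pos = codon_i, aa_ref = a_ref, aa_alt = a_alt)
}

test_that("annotator agrees with the translate-and-compare oracle", {
  set.seed(77)
  n_checked <- 0L
  for (s in 1:4) {
    ref <- build_toy_reference(2, 300, seed = s)
    muts <- random_mutations(ref, 250)
    got <- annotate_effect(muts, ref)
    for (i in seq_len(nrow(muts))) {
      want <- oracle_effect(muts[i, ], ref)
      expect_identical(got$effect[i], want$effect)
      if (want$effect != "noncoding") {
        expect_identical(got$aa_pos[i], want$aa_pos)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 300L)
})

test_that("synonymous changes leave the protein identical", {
  set.seed(13)
  ref <- build_toy_reference(2, 300, seed = 13)
  muts <- random_mutations(ref, 200)
  got <- annotate_effect(muts, ref)
  for (i in seq_len(nrow(muts))) {
    if (got$effect[i] %in% c("synonymous", "nonsense")) {
      w <- oracle_effect(muts[i, ], ref)
      if (got$effect[i] == "synonymous") expect_identical(w$aa_ref, w$aa_alt)
      if (got$effect[i] == "nonsense") expect_identical(w$aa_alt, "*")
    }
  }
})
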
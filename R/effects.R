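AA3 <- c(Biostrings::AMINO_ACID_CODE, "*" = "*")

aa3 <- function(a) unname(AA3[a])

#' Classify a base substitution
#'
#' @param ref,alt single reference and alternate bases (A/C/G/T, different).
#' @return list with `class` (one of the 12 directed classes, e.g. "G>A")
#'   and `type` ("transition" or "transversion").
#' @export
classify_substitution <- function(ref, alt) {
  if (!ref %in% DNA_BASES || !alt %in% DNA_BASES) {
    stop("ref and alt must be one of A, C, G, T")
  }
  if (ref == alt) stop("ref and alt must differ")
  cls <- paste0(ref, ">", alt)
  list(class = cls,
       type = if (cls %in% TRANSITION_CLASSES) "transition" else "transversion")
}

# spliced CDS of one gene: genomic positions in translation order, CDS string
gene_cds <- function(gene_rows, sequence) {
  gene_rows <- gene_rows[order(gene_rows$start), , drop = FALSE]
  strand <- gene_rows$strand[1L]
  gpos <- unlist(lapply(seq_len(nrow(gene_rows)), function(i)
    seq.int(gene_rows$start[i], gene_rows$end[i])), use.names = FALSE)
  bases <- substring(sequence, gpos, gpos)
  if (strand == "-") {
    gpos <- rev(gpos)
    bases <- unname(complement_base(rev(bases)))
  }
  # GFF3 phase of the 5'-most interval in translation order
  ph_row <- if (strand == "-") which.max(gene_rows$end) else which.min(gene_rows$start)
  phase <- gene_rows$phase[ph_row]
  if (phase > 0L) {
    gpos <- gpos[-seq_len(phase)]
    bases <- bases[-seq_len(phase)]
  }
  list(gpos = gpos, cds = paste0(bases, collapse = ""), strand = strand,
       partial = (length(gpos) %% 3L) != 0L)
}

#' Annotate the coding effect of base changes
#'
#' Maps each mutation into the spliced CDS of its gene (honoring strand:
#' reverse-strand changes are complemented), recomputes the affected codon
#' with the standard nuclear genetic code, and classifies the effect as
#' synonymous, missense, nonsense, or stop_loss. Positions outside every
#' CDS are classified noncoding. Labels follow the "Asp20Asn" convention
#' (3-letter codes, 1-based codon index); synonymous changes are labelled
#' "Syn" and nonsense changes use "*" for the introduced stop.
#'
#' @param mutations data.frame with seq_name, pos, ref, alt (extra columns
#'   are carried through).
#' @param reference a `reference_set` carrying the gene models.
#' @return the input with added columns gene_id, effect, aa_ref, aa_pos,
#'   aa_alt, label, partial_cds.
#' @export
annotate_effect <- function(mutations, reference) {
  stopifnot(inherits(reference, "reference_set"))
  gm <- reference$gene_models
  genes <- unique(gm$gene_id)
  cds_list <- lapply(genes, function(g) {
    rows <- gm[gm$gene_id == g, , drop = FALSE]
    c(gene_cds(rows, reference$sequences[[rows$seq_name[1L]]]),
      list(seq_name = rows$seq_name[1L]))
  })
  names(cds_list) <- genes
  if (any(vapply(cds_list, `[[`, logical(1), "partial"))) {
    warning("some gene models have partial CDS (length not divisible by 3)")
  }

  n <- nrow(mutations)
  gene_id <- rep(NA_character_, n)
  effect <- rep("noncoding", n)
  aa_ref <- rep(NA_character_, n); aa_alt <- rep(NA_character_, n)
  aa_pos <- rep(NA_integer_, n)
  label <- rep(NA_character_, n)
  partial <- rep(FALSE, n)
  code <- Biostrings::GENETIC_CODE

  for (i in seq_len(n)) {
    m <- mutations[i, ]
    refbase <- substr(reference$sequences[[m$seq_name]], m$pos, m$pos)
    if (refbase != m$ref) {
      stop(sprintf("reference mismatch at %s:%d (expected %s, reference has %s)",
                   m$seq_name, m$pos, m$ref, refbase))
    }
    for (g in genes) {
      cl <- cds_list[[g]]
      if (cl$seq_name != m$seq_name) next
      ci <- match(m$pos, cl$gpos)
      if (is.na(ci)) next
      gene_id[i] <- g
      partial[i] <- cl$partial
      mut_ref <- m$ref; mut_alt <- m$alt
      if (cl$strand == "-") {
        mut_ref <- unname(complement_base(mut_ref))
        mut_alt <- unname(complement_base(mut_alt))
      }
      codon_i <- (ci - 1L) %/% 3L + 1L
      off <- (ci - 1L) %% 3L + 1L
      codon <- substr(cl$cds, 3L * (codon_i - 1L) + 1L, 3L * codon_i)
      if (nchar(codon) < 3L) break  # trailing partial codon
      stopifnot(substr(codon, off, off) == mut_ref)
      codon_alt <- codon
      substr(codon_alt, off, off) <- mut_alt
      a_ref <- code[[codon]]; a_alt <- code[[codon_alt]]
      aa_ref[i] <- a_ref; aa_alt[i] <- a_alt; aa_pos[i] <- codon_i
      if (a_ref == a_alt) {
        effect[i] <- "synonymous"; label[i] <- "Syn"
      } else if (a_alt == "*") {
        effect[i] <- "nonsense"
        label[i] <- paste0(aa3(a_ref), codon_i, "*")
      } else if (a_ref == "*") {
        effect[i] <- "stop_loss"
        label[i] <- paste0("*", codon_i, aa3(a_alt))
      } else {
        effect[i] <- "missense"
        label[i] <- paste0(aa3(a_ref), codon_i, aa3(a_alt))
      }
      break
    }
  }
  out <- mutations
  out$gene_id <- gene_id
  out$effect <- effect
  out$aa_ref <- aa_ref
  out$aa_pos <- aa_pos
  out$aa_alt <- aa_alt
  out$label <- label
  out$partial_cds <- partial
  out
}
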
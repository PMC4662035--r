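#' Write and read the reference set (FASTA + GFF3)
#'
#' Sequences go to FASTA via Biostrings; gene models to GFF3 CDS features
#' (with phase) via rtracklayer.
#'
#' @param reference a `reference_set`.
#' @param fasta,gff3 output paths.
#' @return invisibly, the paths.
#' @export
write_reference <- function(reference, fasta, gff3 = NULL) {
  seqs <- Biostrings::DNAStringSet(reference$sequences)
  Biostrings::writeXStringSet(seqs, fasta)
  if (!is.null(gff3)) {
    gm <- reference$gene_models
    gr <- GenomicRanges::GRanges(
      seqnames = gm$seq_name,
      ranges = IRanges::IRanges(gm$start, gm$end),
      strand = gm$strand)
    S4Vectors::mcols(gr)$source <- "amptill"
    S4Vectors::mcols(gr)$type <- "CDS"
    S4Vectors::mcols(gr)$phase <- as.integer(gm$phase)
    S4Vectors::mcols(gr)$ID <- paste0(gm$gene_id, ".cds",
                                      stats::ave(seq_len(nrow(gm)), gm$gene_id,
                                                 FUN = seq_along))
    S4Vectors::mcols(gr)$Parent <- gm$gene_id
    rtracklayer::export(gr, gff3, format = "gff3")
  }
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta, gff3 = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  sequences <- stats::setNames(as.character(seqs),
                               sub("\\s.*$", "", names(seqs)))
  if (is.null(gff3)) {
    gm <- data.frame(gene_id = character(0), seq_name = character(0),
                     strand = character(0), start = integer(0),
                     end = integer(0), phase = integer(0),
                     stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(gff3, format = "gff3")
    gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
    parent <- S4Vectors::mcols(gr)$Parent
    gene_id <- if (!is.null(parent) && length(parent)) {
      vapply(as.list(parent), function(p)
        if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
    } else as.character(S4Vectors::mcols(gr)$ID)
    gm <- data.frame(
      gene_id = gene_id,
      seq_name = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      phase = as.integer(as.character(S4Vectors::mcols(gr)$phase)),
      stringsAsFactors = FALSE)
    gm <- gm[order(gm$gene_id, gm$start), , drop = FALSE]
    rownames(gm) <- NULL
  }
  reference_set(sequences, gm)
}

#' Write / read a paired FASTQ
#'
#' @param reads a `paired_reads`.
#' @param r1_path,r2_path output files; `.gz` suffix enables compression.
#' @return invisibly, the paths.
#' @export
write_paired_fastq <- function(reads, r1_path, r2_path) {
  wr <- function(seqs, quals, nms, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- nms
    q <- Biostrings::BStringSet(quals)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = grepl("\\.gz$", path))
  }
  wr(reads$r1, reads$q1, paste0(reads$names, "/1"), r1_path)
  wr(reads$r2, reads$q2, paste0(reads$names, "/2"), r2_path)
  invisible(c(r1_path, r2_path))
}

#' @rdname write_paired_fastq
#' @export
read_paired_fastq <- function(r1_path, r2_path) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(names = sub("/[12]$", "", names(x)),
         seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
  }
  a <- rd(r1_path); b <- rd(r2_path)
  if (!identical(a$names, b$names)) {
    stop("mate files disagree on read names / order")
  }
  paired_reads(a$names, a$seq, b$seq, a$qual, b$qual)
}

#' Write all pools of a read simulation as FASTQ files
#'
#' @param sim a `pool_read_sim`.
#' @param dir output directory (created if needed).
#' @param gzip compress outputs.
#' @return invisibly, a character vector of written files.
#' @export
write_pool_fastq <- function(sim, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  files <- character(0)
  for (pid in names(sim$pools)) {
    f1 <- file.path(dir, paste0(pid, "_R1", ext))
    f2 <- file.path(dir, paste0(pid, "_R2", ext))
    write_paired_fastq(sim$pools[[pid]], f1, f2)
    files <- c(files, f1, f2)
  }
  invisible(files)
}

vcf_header <- function(info = TRUE, format = TRUE, samples = character(0)) {
  h <- c("##fileformat=VCFv4.2",
         "##source=amptill (threshold caller; allele-fraction stand-in for probabilistic variant detection)")
  if (info) h <- c(h,
    '##INFO=<ID=LINE,Number=.,Type=String,Description="Carrier line ids">',
    '##INFO=<ID=ZYG,Number=.,Type=String,Description="Zygosity per carrier (het/hom)">',
    '##INFO=<ID=ORIGIN,Number=.,Type=String,Description="Mutagenesis round of origin">',
    '##INFO=<ID=POOL,Number=.,Type=String,Description="Indexed pool ids containing a carrier">',
    '##INFO=<ID=EFF,Number=1,Type=String,Description="Coding effect">',
    '##INFO=<ID=AA,Number=1,Type=String,Description="Amino acid substitution label">')
  if (format) h <- c(h,
    '##FILTER=<ID=LOW_COV,Description="Coverage below minimum">',
    '##FILTER=<ID=LOW_FREQ,Description="Alt reads or frequency below minimum">',
    '##FILTER=<ID=STRAND,Description="Alt allele missing from one strand">',
    '##FILTER=<ID=QUALITY,Description="Alt base quality below minimum">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=ADF,Number=R,Type=Integer,Description="Forward-strand allele depths (ref,alt)">',
    '##FORMAT=<ID=ADR,Number=R,Type=Integer,Description="Reverse-strand allele depths (ref,alt)">',
    '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Alt allele fraction">')
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples)) cols <- c(cols, "FORMAT", samples)
  c(h, paste(cols, collapse = "\t"))
}

#' Write pool variant calls as VCF v4.2
#'
#' One sample column per pool; DP, strand-split allele depths (ADF/ADR) and
#' allele fraction per genotype; the FILTER column carries the call status.
#'
#' @param calls data.frame from [call_pool_variants()].
#' @param path output path.
#' @param info optional character vector (same length as distinct variants)
#'   of extra INFO strings, named by "seq:pos:alt".
#' @return invisibly, `path`.
#' @export
write_calls_vcf <- function(calls, path, info = NULL) {
  pools <- sort(unique(calls$pool_id))
  key <- paste(calls$seq_name, calls$pos, calls$ref, calls$alt, sep = "\r")
  uk <- !duplicated(key)
  vars <- calls[uk, c("seq_name", "pos", "ref", "alt"), drop = FALSE]
  vars <- vars[order(vars$seq_name, vars$pos, vars$alt), , drop = FALSE]
  vkey <- paste(vars$seq_name, vars$pos, vars$ref, vars$alt, sep = "\r")
  lines <- character(nrow(vars))
  for (i in seq_len(nrow(vars))) {
    sub <- calls[key == vkey[i], , drop = FALSE]
    filt <- if (any(sub$filter_status == "PASS")) "PASS" else sub$filter_status[1L]
    gts <- vapply(pools, function(p) {
      r <- sub[sub$pool_id == p, , drop = FALSE]
      if (!nrow(r)) return(".")
      r <- r[1L, ]
      refF <- max(0L, r$coverage - r$alt_count_F - r$alt_count_R)  # not strand-resolved for ref
      sprintf("%d:%d,%d:%d,%d:%.6g", r$coverage, refF, r$alt_count_F,
              0L, r$alt_count_R, r$frequency)
    }, character(1))
    ik <- sprintf("%s:%d:%s", vars$seq_name[i], vars$pos[i], vars$alt[i])
    inf <- if (!is.null(info) && ik %in% names(info)) info[[ik]] else "."
    lines[i] <- paste(c(vars$seq_name[i], vars$pos[i], ".", vars$ref[i],
                        vars$alt[i], ".", filt, inf, "DP:ADF:ADR:AF", gts),
                      collapse = "\t")
  }
  writeLines(c(vcf_header(samples = pools), lines), path)
  invisible(path)
}

#' Read a pool-call VCF back into the call table form
#'
#' Uses VariantAnnotation; one output row per (variant, pool with data).
#'
#' @param path VCF path.
#' @return data.frame like [call_pool_variants()] output.
#' @export
read_calls_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- as.character(unlist(VariantAnnotation::alt(v)))
  dp <- VariantAnnotation::geno(v)$DP
  adf <- VariantAnnotation::geno(v)$ADF
  adr <- VariantAnnotation::geno(v)$ADR
  af <- VariantAnnotation::geno(v)$AF
  out <- list()
  for (j in seq_len(ncol(dp))) {
    has <- which(!is.na(dp[, j]))
    if (!length(has)) next
    out[[length(out) + 1L]] <- data.frame(
      pool_id = colnames(dp)[j],
      seq_name = as.character(GenomicRanges::seqnames(rr))[has],
      pos = GenomicRanges::start(rr)[has],
      ref = as.character(VariantAnnotation::ref(v))[has],
      alt = alt[has],
      coverage = dp[has, j],
      alt_count_F = vapply(adf[has, j], `[`, integer(1), 2L),
      alt_count_R = vapply(adr[has, j], `[`, integer(1), 2L),
      frequency = vapply(af[has, j], `[`, numeric(1), 1L),
      filter_status = as.character(rr$FILTER)[has],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(pool_id = character(0), seq_name = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), coverage = integer(0),
                      alt_count_F = integer(0), alt_count_R = integer(0),
                      frequency = numeric(0), filter_status = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- res[order(res$seq_name, res$pos, res$alt, res$pool_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write the simulation truth as a VCF
#'
#' One row per unique mutation with carrier lines, zygosities, origin
#' rounds and pools in INFO.
#'
#' @param truth truth data.frame from a `pool_read_sim` (amplicon coords).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth_vcf <- function(truth, path) {
  key <- paste(truth$amplicon_id, truth$amp_pos, truth$alt, sep = "\r")
  ord <- order(truth$amplicon_id, truth$amp_pos, truth$alt, truth$line_id)
  truth <- truth[ord, , drop = FALSE]; key <- key[ord]
  uk <- which(!duplicated(key))
  lines <- vapply(uk, function(i) {
    g <- truth[key == key[i], , drop = FALSE]
    info <- sprintf("LINE=%s;ZYG=%s;ORIGIN=%s;POOL=%s",
                    paste(g$line_id, collapse = ","),
                    paste(g$zygosity, collapse = ","),
                    paste(g$origin, collapse = ","),
                    paste(unique(g$pool), collapse = ","))
    paste(c(g$amplicon_id[1L], g$amp_pos[1L], ".", g$ref[1L], g$alt[1L],
            ".", "PASS", info), collapse = "\t")
  }, character(1))
  writeLines(c(vcf_header(format = FALSE), lines), path)
  invisible(path)
}

#' Write / read a pooling layout CSV
#'
#' @param layout a `pooling_layout`.
#' @param path CSV path.
#' @return invisibly `path`; for the reader, a `pooling_layout`.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(layout_table(layout), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  layout_from_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a stranded pileup TSV
#'
#' @param pileup a `stranded_pileup`.
#' @param path TSV path.
#' @return invisibly `path`; reader returns the `stranded_pileup`.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(df) <- c("stranded_pileup", "data.frame")
  df
}
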
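## File-format boundaries: FASTA/FASTQ through Biostrings, GFF3 through
## rtracklayer, SAM/VCF/TSV as plain writers (plus a minimal SAM reader for
## externally supplied alignments).

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a read set to a pair of FASTQ files
#' @param reads a `read_set` or a reads data.frame (see [reads_frame()]).
#' @param path1,path2 output FASTQ paths for mate 1 and mate 2.
#' @export
write_fastq <- function(reads, path1, path2) {
  if (inherits(reads, "read_set")) reads <- reads_frame(reads)
  for (m in 1:2) {
    sub <- reads[reads$mate == m, ]
    x <- Biostrings::DNAStringSet(sub$seq)
    names(x) <- paste0(sub$name, "/", m)
    Biostrings::writeXStringSet(
      x, if (m == 1) path1 else path2, format = "fastq",
      qualities = Biostrings::BStringSet(sub$qual)
    )
  }
  invisible(c(path1, path2))
}

#' Read a pair of FASTQ files into a reads data.frame
#'
#' Qualities must be Phred+33; Phred+64-encoded input is rejected with an
#' error rather than silently rescaled.
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2.
#' @export
read_fastq <- function(path1, path2 = NULL) {
  read_one <- function(path, mate) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
    check_phred33(qual)
    data.frame(
      name = sub("/[12]$", "", sub("\\s.*$", "", names(x))),
      mate = mate, seq = as.character(x), qual = qual,
      stringsAsFactors = FALSE
    )
  }
  out <- read_one(path1, 1L)
  if (!is.null(path2)) out <- rbind(out, read_one(path2, 2L))
  rownames(out) <- NULL
  out
}

check_phred33 <- function(qual) {
  codes <- utf8ToInt(paste(head(qual, 200), collapse = ""))
  if (length(codes) && min(codes) >= 59 && max(codes) > 74) {
    stop("quality strings look Phred+64 encoded; only Phred+33 is supported")
  }
  invisible(TRUE)
}

sam_flag <- function(aln) {
  flag <- 1L +                                   # paired
    ifelse(aln$mapped, 0L, 4L) +
    ifelse(is.na(aln$mchrom), 8L, 0L) +
    ifelse(aln$mapped & aln$strand == "-", 16L, 0L) +
    ifelse(!is.na(aln$mstrand) & aln$mstrand == "-", 32L, 0L) +
    ifelse(aln$mate == 1L, 64L, 128L) +
    ifelse(aln$dup, 1024L, 0L)
  flag
}

#' Write truth alignments as SAM
#' @param aln alignment data.frame (from [simulate_reads()]).
#' @param chrom_lengths named vector of reference sequence lengths.
#' @param path output SAM path.
#' @export
write_sam <- function(aln, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  aln <- sort_alignments(aln)
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
    aln$qname, sam_flag(aln),
    ifelse(aln$mapped, aln$chrom, "*"),
    ifelse(aln$mapped, aln$pos, 0L),
    ifelse(aln$mapped, 60L, 0L),
    ifelse(aln$mapped, aln$cigar, "*"),
    ifelse(is.na(aln$mchrom), "*",
           ifelse(aln$mchrom == aln$chrom & aln$mapped, "=", aln$mchrom)),
    ifelse(is.na(aln$mpos), 0L, aln$mpos),
    aln$isize, aln$seq, aln$qual
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read a SAM file into an alignment data.frame
#'
#' Minimal reader for the 11 mandatory columns of coordinate-sorted SAM;
#' intended for the simulator's truth alignments or similarly simple input.
#'
#' @param path SAM path.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (!length(body)) stop("SAM file ", path, " has no alignment records")
  parts <- stringi::stri_split_fixed(body, "\t")
  bad <- which(lengths(parts) < 11L)
  if (length(bad)) {
    stop("truncated SAM record at line ", bad[1], ": ",
         substr(body[bad[1]], 1, 60))
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:11))
  flag <- as.integer(m[, 2])
  mapped <- bitwAnd(flag, 4L) == 0L
  data.frame(
    qname = m[, 1],
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    chrom = ifelse(mapped, m[, 3], NA_character_),
    pos = ifelse(mapped, suppressWarnings(as.integer(m[, 4])), NA_integer_),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = ifelse(mapped, m[, 6], NA_character_),
    seq = m[, 10], qual = m[, 11],
    mapped = mapped,
    dup = bitwAnd(flag, 1024L) > 0L,
    mchrom = ifelse(m[, 7] == "*", NA_character_,
                    ifelse(m[, 7] == "=", m[, 3], m[, 7])),
    mpos = ifelse(m[, 8] == "0", NA_integer_,
                  suppressWarnings(as.integer(m[, 8]))),
    mstrand = ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
    isize = as.integer(m[, 9]),
    stringsAsFactors = FALSE
  )
}

#' Sort alignments by coordinate
#' @param aln alignment data.frame.
#' @export
sort_alignments <- function(aln) {
  ord <- order(is.na(aln$chrom), aln$chrom, aln$pos, aln$qname, aln$mate,
               method = "radix")
  fast_subset(aln, ord)
}

#' Write somatic events as VCF
#'
#' Emits VCF v4.2 with somatic annotations in INFO (`SOMATIC`, `FISHER_P`,
#' `COMPARTMENT`, `EFFECT`).
#'
#' @param events somatic event data.frame (see [subtract_paired()]).
#' @param chrom_lengths named vector of reference lengths.
#' @param path output path.
#' @param sample_names length-2 character: clone and donor labels.
#' @export
write_vcf <- function(events, chrom_lengths, path,
                      sample_names = c("clone", "donor")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Clone-only somatic variant\">",
    "##INFO=<ID=FISHER_P,Number=1,Type=Float,Description=\"Fisher exact allele-count p-value\">",
    "##INFO=<ID=COMPARTMENT,Number=1,Type=String,Description=\"autosomal, sex or mitochondrial\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
    "##FORMAT=<ID=AD,Number=2,Type=Integer,Description=\"Ref,alt allele depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(sample_names, collapse = "\t"))
  ), con)
  if (nrow(events)) {
    ## VCF requires non-empty REF/ALT; indel records keep the internal
    ## anchor convention, with empty deletion alleles written as <DEL>
    ref <- events$ref
    alt <- events$alt
    info <- sprintf(
      "SOMATIC;FISHER_P=%.4g;COMPARTMENT=%s%s",
      events$fisher_p, events$compartment,
      ifelse(is.na(events$effect) | events$effect == "",
             "", paste0(";EFFECT=", events$effect))
    )
    lines <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tAD\t%d,%d\t%d,%d",
      events$chrom, events$pos, ref,
      ifelse(alt == "", "<DEL>", alt), info,
      events$clone_ref, events$clone_alt, events$donor_ref, events$donor_alt
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a BED-like TSV
#' @param df data.frame to write.
#' @param path output path.
#' @export
write_bed_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3
#' @param genes gene-model data.frame (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `exon_rank`), one row per CDS exon.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    lines <- sprintf(
      "%s\tclonecompare\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s-%d;Parent=%s",
      genes$chrom, genes$start, genes$end, genes$strand,
      genes$gene_id, genes$exon_rank, genes$gene_id
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Extracts CDS features into the data.frame layout used by
#' [annotate_effect()].
#'
#' @param path GFF3 file.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  g <- g[g$type == "CDS", , drop = FALSE]
  parent <- if ("Parent" %in% names(g)) {
    vapply(g$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
           character(1))
  } else {
    as.character(g$ID)
  }
  out <- data.frame(
    gene_id = parent, chrom = as.character(g$seqid),
    strand = as.character(g$strand), start = g$start, end = g$end,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id, out$start), ]
  out$exon_rank <- stats::ave(seq_len(nrow(out)), out$gene_id,
                              FUN = seq_along)
  rownames(out) <- NULL
  out
}
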
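## Read sampling from haplotype units.

## Assemble one haplotype unit into (sequence, piece map). Pieces are the
## fine-grained collinear segments after splicing small indels into M runs:
## kind "M" (collinear match), "I" (small novel insertion), "N" (unmappable
## novel sequence). `hap_start` is the 1-based start of each piece in
## haplotype coordinates.
assemble_haplotype <- function(model, unit, refmut_cache = new.env()) {
  cfg <- model$config
  indels <- model$indel_sets[[unit$indel_set]]
  pieces <- list()
  seqs <- character(0)
  for (i in seq_len(nrow(unit$runs))) {
    r <- unit$runs[i, ]
    if (r$kind == "N") {
      pieces[[length(pieces) + 1L]] <- data.frame(
        kind = "N", chrom = NA_character_, ref_start = NA_integer_,
        len = r$len, stringsAsFactors = FALSE
      )
      seqs <- c(seqs, r$seq)
      next
    }
    mut <- refmut_for(model, r$chrom, unit$snv_set, refmut_cache)
    r_end <- r$ref_start + r$len - 1L
    ind <- indels[indels$chrom == r$chrom &
                    indels$pos >= r$ref_start & indels$pos < r_end, ,
                  drop = FALSE]
    ind <- ind[order(ind$pos), , drop = FALSE]
    cur <- r$ref_start
    add_m <- function(from, to) {
      if (to < from) return()
      pieces[[length(pieces) + 1L]] <<- data.frame(
        kind = "M", chrom = r$chrom, ref_start = from, len = to - from + 1L,
        stringsAsFactors = FALSE
      )
      seqs <<- c(seqs, stringi::stri_sub(mut, from, to))
    }
    for (k in seq_len(nrow(ind))) {
      p <- ind$pos[k]
      if (ind$type[k] == "INS") {
        add_m(cur, p)
        pieces[[length(pieces) + 1L]] <- data.frame(
          kind = "I", chrom = NA_character_, ref_start = NA_integer_,
          len = ind$len[k], stringsAsFactors = FALSE
        )
        seqs <- c(seqs, ind$seq[k])
        cur <- p + 1L
      } else {
        add_m(cur, p - 1L)
        cur <- p + ind$len[k]
      }
    }
    add_m(cur, r_end)
  }
  map <- do.call(rbind, pieces)
  map$hap_start <- cumsum(c(1L, head(map$len, -1L)))
  map$hap_end <- map$hap_start + map$len - 1L
  list(seq = paste(seqs, collapse = ""), map = map)
}

refmut_for <- function(model, chrom, snv_set, cache) {
  key <- paste0(chrom, ":", snv_set)
  if (!is.null(cache[[key]])) return(cache[[key]])
  snvs <- model$snv_sets[[snv_set]]
  snvs <- snvs[snvs$chrom == chrom, , drop = FALSE]
  s <- substitute_bases(model$reference[[chrom]], snvs$pos, snvs$alt)
  cache[[key]] <- s
  s
}

#' Simulate paired-end reads from a genome model
#'
#' Samples fragments per haplotype unit (fragment length Normal(insert_mean,
#' insert_sd), truncated below), reads both fragment ends as 2 x read_length
#' mates with adapter read-through when the fragment is shorter than the
#' read, injects substitution errors, ambiguous bases and a linearly
#' declining quality profile, re-emits a configurable fraction of fragments
#' as PCR duplicates, and records the true alignment (position, strand,
#' CIGAR) of every read so downstream stages need no external aligner.
#' Reads originating wholly inside telomeric or novel repeat sequence are
#' flagged unmapped, as they would be after unique-mapping filters.
#'
#' @param model a `genome_model` from [build_donor_genome()] or
#'   [derive_clone_genome()].
#' @param config a [sim_config()]; defaults to the model's.
#' @param sample_tag short sample label used in read names.
#' @param seed integer seed for the read-level randomness; defaults to a
#'   seed derived from `config$seed` and `sample_tag`, so a different seed
#'   re-sequences the same genome (a fresh "library").
#' @return a `read_set` object: `$reads` (data.frame with one row per read:
#'   name, mate, as-read `seq`/`qual`) and `$alignments` (truth alignment
#'   data.frame with SAM-style forward-strand `seq`, `pos`, `cigar`,
#'   `mapped`, `dup`, mate coordinates and apparent insert size).
#' @export
simulate_reads <- function(model, config = model$config, sample_tag = model$role,
                           seed = NULL) {
  if (config$coverage <= 0) stop("coverage must be positive")
  if (is.null(seed)) seed <- derive_seed(config$seed, paste0("reads_", sample_tag))
  set.seed(seed)
  rl <- config$read_length
  cache <- new.env()
  per_unit <- vector("list", length(model$units))
  names(per_unit) <- names(model$units)
  frag_offset <- 0L
  for (un in names(model$units)) {
    unit <- model$units[[un]]
    hap <- assemble_haplotype(model, unit, cache)
    L <- nchar(hap$seq)
    n_frag <- max(1L, round(config$coverage * unit$weight * L / (2 * rl)))
    flen <- as.integer(pmax(40, round(rnorm(n_frag, config$insert_mean,
                                            config$insert_sd))))
    flen <- pmin(flen, L)
    x <- as.integer(floor(runif(n_frag, 1, L - flen + 1 + 1)))
    dup <- rep(FALSE, n_frag)
    n_dup <- rbinom(1, n_frag, config$duplicate_fraction)
    if (n_dup > 0) {
      di <- sample.int(n_frag, n_dup)
      x <- c(x, x[di])
      flen <- c(flen, flen[di])
      dup <- c(dup, rep(TRUE, n_dup))
    }
    flip <- runif(length(x)) < 0.5
    per_unit[[un]] <- build_unit_reads(
      hap, unit, x, flen, flip, dup, config, model,
      frag_offset = frag_offset, sample_tag = sample_tag
    )
    frag_offset <- frag_offset + length(x)
  }
  aln <- fast_df(lapply(setNames(nm = names(per_unit[[1]])), function(cc) {
    unlist(lapply(per_unit, `[[`, cc), use.names = FALSE)
  }))
  rm(per_unit)
  structure(
    list(sample = sample_tag, alignments = aln, config = config,
         seed = seed),
    class = "read_set"
  )
}

#' Extract the as-read (FASTQ-orientation) reads of a read set
#'
#' Alignments store reference-forward sequence; this reconstructs each
#' read as sequenced (reverse-complemented for minus-strand alignments).
#'
#' @param x a `read_set` or an alignment data.frame.
#' @return data.frame with `name`, `mate`, `seq`, `qual`.
#' @export
reads_frame <- function(x) {
  aln <- if (inherits(x, "read_set")) x$alignments else x
  minus <- !is.na(aln$strand) & aln$strand == "-"
  seq <- aln$seq
  qual <- aln$qual
  seq[minus] <- .revcomp(seq[minus])
  qual[minus] <- .strrev(qual[minus])
  data.frame(name = aln$qname, mate = aln$mate, seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

## Build all reads for one unit. x/flen per fragment; returns as-read reads
## and truth alignments.
build_unit_reads <- function(hap, unit, x, flen, flip, dup, config, model,
                             frag_offset, sample_tag) {
  rl <- config$read_length
  n <- length(x)
  qname <- paste0(sample_tag, ":", frag_offset + seq_len(n))
  if (any(dup)) qname[dup] <- paste0(qname[dup], "d")

  ## fragment-end intervals in haplotype coordinates
  left_len <- pmin(rl, flen)
  left_a <- x
  left_b <- x + left_len - 1L
  right_a <- x + pmax(flen - rl, 0L)
  right_b <- x + flen - 1L
  right_len <- right_b - right_a + 1L
  ad_len <- pmax(0L, rl - flen)

  ## mate1 reads the left end on + when unflipped, right end on - when flipped
  m1_a <- left_a
  m1_b <- left_b
  m2_a <- right_a
  m2_b <- right_b
  m1_a[flip] <- right_a[flip]
  m1_b[flip] <- right_b[flip]
  m2_a[flip] <- left_a[flip]
  m2_b[flip] <- left_b[flip]
  m1_strand <- rep("+", n)
  m1_strand[flip] <- "-"
  m2_strand <- rep("-", n)
  m2_strand[flip] <- "+"

  ## slice, orient, append adapter read-through, inject errors/Ns and draw
  ## qualities in one compiled pass per mate (as-read orientation)
  r1 <- .build_reads(
    hap$seq, m1_a, m1_b - m1_a + 1L, m1_strand == "-",
    config$adapter_seq_index, ad_len,
    config$base_error_rate, config$n_base_rate,
    config$quality_start, config$quality_end, config$quality_sd,
    config$low_quality_read_fraction, 12
  )
  r2 <- .build_reads(
    hap$seq, m2_a, m2_b - m2_a + 1L, m2_strand == "-",
    revcomp(config$adapter_seq_universal), ad_len,
    config$base_error_rate, config$n_base_rate,
    config$quality_start, config$quality_end, config$quality_sd,
    config$low_quality_read_fraction, 12
  )
  m1_read <- r1$seq
  m2_read <- r2$seq
  m1_qual <- r1$qual
  m2_qual <- r2$qual

  ## map fragment-end intervals to reference
  mp1 <- map_interval(hap$map, m1_a, m1_b, model, unit)
  mp2 <- map_interval(hap$map, m2_a, m2_b, model, unit)

  ## aligned-orientation seq/qual and CIGARs with adapter soft-clips
  aln1 <- orient_alignment(m1_read, m1_qual, m1_strand, mp1, ad_len)
  aln2 <- orient_alignment(m2_read, m2_qual, m2_strand, mp2, ad_len)

  isize <- compute_isize(mp1, mp2, aln1, aln2)
  list(
    qname = rep(qname, 2L), mate = rep(c(1L, 2L), each = n),
    chrom = c(mp1$chrom, mp2$chrom), pos = c(mp1$pos, mp2$pos),
    strand = c(m1_strand, m2_strand), cigar = c(aln1$cigar, aln2$cigar),
    seq = c(aln1$seq, aln2$seq), qual = c(aln1$qual, aln2$qual),
    mapped = c(mp1$mapped, mp2$mapped),
    dup = rep(dup, 2L),
    mchrom = c(mp2$chrom, mp1$chrom), mpos = c(mp2$pos, mp1$pos),
    mstrand = c(m2_strand, m1_strand),
    isize = c(isize, -isize),
    flen = rep(flen, 2L), unit = rep(unit$name, 2L * n),
    hap_start = c(m1_a, m2_a)
  )
}

## Map haplotype intervals [a,b] to reference coordinates using the piece
## map. Vectorised for the common single-piece case; reads spanning pieces
## (indels, junctions) are handled individually.
map_interval <- function(map, a, b, model, unit) {
  n <- length(a)
  starts <- map$hap_start
  i <- findInterval(a, starts)
  j <- findInterval(b, starts)
  chrom <- rep(NA_character_, n)
  pos <- rep(NA_integer_, n)
  cigar <- rep(NA_character_, n)
  mapped <- rep(FALSE, n)

  single <- i == j
  sM <- single & map$kind[i] == "M"
  if (any(sM)) {
    k <- i[sM]
    chrom[sM] <- map$chrom[k]
    pos[sM] <- map$ref_start[k] + (a[sM] - map$hap_start[k])
    len <- b[sM] - a[sM] + 1L
    cigar[sM] <- paste0(len, "M")
    mapped[sM] <- TRUE
  }
  for (idx in which(!single)) {
    r <- map_multi(map, a[idx], b[idx])
    chrom[idx] <- r$chrom
    pos[idx] <- r$pos
    cigar[idx] <- r$cigar
    mapped[idx] <- r$mapped
  }
  ## reads wholly inside a telomeric tract are unmappable repeats; tracts
  ## sit at chromosome ends, so two per-chromosome bounds suffice
  tel <- model$telomeres
  if (nrow(tel) && any(mapped)) {
    left_end <- tapply(ifelse(tel$side == "left", tel$end, -Inf),
                       tel$chrom, max)
    right_start <- tapply(ifelse(tel$side == "right", tel$start, Inf),
                          tel$chrom, min)
    mi <- which(mapped & chrom %in% names(left_end))
    if (length(mi)) {
      span <- cigar_ref_span(cigar[mi])
      le <- left_end[chrom[mi]]
      rs <- right_start[chrom[mi]]
      inside <- mi[(pos[mi] + span - 1L) <= le | pos[mi] >= rs]
      if (length(inside)) {
        mapped[inside] <- FALSE
        chrom[inside] <- NA_character_
        pos[inside] <- NA_integer_
        cigar[inside] <- NA_character_
      }
    }
  }
  list(chrom = chrom, pos = pos, cigar = cigar, mapped = mapped)
}

## reference span consumed by each CIGAR (M and D consume reference);
## fast path for the ubiquitous single-M case
cigar_ref_span <- function(cigar, mapped = !is.na(cigar)) {
  span <- rep(NA_integer_, length(cigar))
  cc <- cigar[mapped]
  if (length(cc)) {
    simple <- stringi::stri_detect_regex(cc, "^\\d+M$")
    out <- integer(length(cc))
    out[simple] <- as.integer(stringi::stri_sub(cc[simple], 1, -2))
    if (any(!simple)) {
      ops <- stringi::stri_extract_all_regex(cc[!simple], "\\d+[MIDSN]")
      out[!simple] <- vapply(ops, function(o) {
        lens <- as.integer(stringi::stri_sub(o, 1, -2))
        type <- stringi::stri_sub(o, -1, -1)
        sum(lens[type %in% c("M", "D")])
      }, integer(1))
    }
    span[mapped] <- out
  }
  span
}

MAX_SMALL_GAP <- 50L
MIN_ANCHOR <- 20L

## one read spanning several pieces: compose an M/I/D cigar when all pieces
## are collinear with only small gaps; otherwise anchor on the largest
## matched piece with soft clips (junction read) or mark unmapped.
map_multi <- function(map, a, b) {
  rows <- which(map$hap_end >= a & map$hap_start <= b)
  sub <- map[rows, , drop = FALSE]
  ov_start <- pmax(sub$hap_start, a)
  ov_end <- pmin(sub$hap_end, b)
  ov <- ov_end - ov_start + 1L
  mrows <- sub$kind == "M"

  junction <- any(sub$kind == "N")
  if (!junction && sum(mrows) >= 1L) {
    mc <- sub$chrom[mrows]
    if (length(unique(mc)) > 1L) junction <- TRUE
  }
  if (!junction && sum(mrows) > 1L) {
    mi <- which(mrows)
    for (k in seq_len(length(mi) - 1L)) {
      r1 <- sub[mi[k], ]
      r2 <- sub[mi[k + 1L], ]
      gap <- r2$ref_start - (r1$ref_start + r1$len)
      if (is.na(gap) || gap < 0L || gap > MAX_SMALL_GAP) {
        junction <- TRUE
        break
      }
    }
  }

  if (!junction && any(mrows)) {
    ## collinear: build M/I/D cigar
    ops <- character(0)
    oplen <- integer(0)
    prev_m <- NULL
    first_m_pos <- NA_integer_
    for (k in seq_len(nrow(sub))) {
      r <- sub[k, ]
      if (r$kind == "M") {
        if (!is.null(prev_m)) {
          gap <- r$ref_start - (prev_m$ref_start + prev_m$len)
          if (gap > 0L) {
            ops <- c(ops, "D")
            oplen <- c(oplen, gap)
          }
        }
        ops <- c(ops, "M")
        oplen <- c(oplen, ov[k])
        if (is.na(first_m_pos)) {
          first_m_pos <- r$ref_start + (ov_start[k] - r$hap_start)
        }
        prev_m <- r
      } else {
        ops <- c(ops, "I")
        oplen <- c(oplen, ov[k])
      }
    }
    ## leading/trailing insertions become soft clips
    if (ops[1] == "I") ops[1] <- "S"
    if (ops[length(ops)] == "I") ops[length(ops)] <- "S"
    cig <- paste0(oplen, ops, collapse = "")
    return(list(chrom = sub$chrom[which(mrows)[1]], pos = first_m_pos,
                cigar = cig, mapped = TRUE))
  }

  ## junction: anchor on the largest matched piece
  if (any(mrows)) {
    cand <- which(mrows)
    best <- cand[which.max(ov[cand])]
    if (ov[best] >= MIN_ANCHOR) {
      pre <- if (best > 1L) sum(ov[seq_len(best - 1L)]) else 0L
      post <- sum(ov) - pre - ov[best]
      cig <- paste0(
        if (pre > 0L) paste0(pre, "S") else "",
        ov[best], "M",
        if (post > 0L) paste0(post, "S") else ""
      )
      pos <- sub$ref_start[best] + (ov_start[best] - sub$hap_start[best])
      return(list(chrom = sub$chrom[best], pos = pos, cigar = cig,
                  mapped = TRUE))
    }
  }
  list(chrom = NA_character_, pos = NA_integer_, cigar = NA_character_,
       mapped = FALSE)
}

## aligned-orientation (reference-forward) seq/qual and final CIGAR with
## adapter soft clips appended on the as-read 3' end
orient_alignment <- function(read, qual, strand, mp, ad_len) {
  n <- length(read)
  cig <- mp$cigar
  has_ad <- ad_len > 0L & mp$mapped
  if (any(has_ad)) {
    plus <- has_ad & strand == "+"
    minus <- has_ad & strand == "-"
    cig[plus] <- paste0(cig[plus], ad_len[plus], "S")
    cig[minus] <- paste0(ad_len[minus], "S", cig[minus])
  }
  seq_f <- read
  qual_f <- qual
  minus <- strand == "-"
  seq_f[minus] <- .revcomp(read[minus])
  qual_f[minus] <- .strrev(qual[minus])
  list(seq = seq_f, qual = qual_f, cigar = cig)
}

compute_isize <- function(mp1, mp2, aln1, aln2, cigars = NULL) {
  span1 <- cigar_ref_span(aln1$cigar)
  span2 <- cigar_ref_span(aln2$cigar)
  ok <- which(mp1$mapped & mp2$mapped & !is.na(mp1$chrom) &
                !is.na(mp2$chrom) & mp1$chrom == mp2$chrom)
  isize <- rep(0L, length(mp1$pos))
  lo <- pmin(mp1$pos[ok], mp2$pos[ok])
  hi <- pmax(mp1$pos[ok] + span1[ok] - 1L, mp2$pos[ok] + span2[ok] - 1L)
  sgn <- rep(1L, length(ok))
  sgn[mp1$pos[ok] > mp2$pos[ok]] <- -1L
  isize[ok] <- (hi - lo + 1L) * sgn
  isize
}

#' @export
print.read_set <- function(x, ...) {
  n <- nrow(x$alignments) / 2
  cat(sprintf(
    "<read_set> sample '%s': %s read pairs (%s mapped reads, %.1f%% duplicates)\n",
    x$sample, format(n, big.mark = ","),
    format(sum(x$alignments$mapped), big.mark = ","),
    100 * mean(x$alignments$dup)
  ))
  invisible(x)
}
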
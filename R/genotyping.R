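## Pileup and simplified biallelic genotype calling.
##
## The caller follows the classical samtools/GATK-era contract: per-site
## genotype likelihoods from base qualities (P(base|allele) = 1 - e for a
## match, e/3 otherwise, e = 10^(-Q/10)), a heterozygosity prior
## theta = 0.001 (P(het) = theta, P(hom-alt) = theta/2), calls restricted
## to read depth 5-200, and a genotype quality cutoff of 10 standing in
## for the historical consensus-quality threshold.

#' Build per-position pileups from alignments
#'
#' Tallies base observations (with quality-derived likelihood accumulators)
#' and indel observations per reference position for one sample. Insertions
#' are attributed to the preceding reference position and deletions to the
#' first deleted position. Soft-clipped bases and N observations are
#' skipped. Only mapped, non-duplicate alignments contribute.
#'
#' @param aln alignment data.frame (coordinate order not required; grouped
#'   internally).
#' @param reference named character vector of reference sequences, or a
#'   named vector of chromosome lengths.
#' @param chroms optional subset of chromosomes to pile up.
#' @return a `pileup_set`: per-chromosome list with `counts` (4 x L base
#'   tally), likelihood accumulators, `depth`, and an `indels` data.frame.
#' @export
pileup <- function(aln, reference, chroms = NULL) {
  lens <- if (is.character(reference)) {
    setNames(nchar(reference), names(reference))
  } else {
    reference
  }
  use <- fast_subset(aln, which(aln$mapped & !aln$dup))
  unknown <- setdiff(unique(use$chrom), names(lens))
  if (length(unknown)) {
    stop("alignment references unknown contig(s): ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(chroms)) chroms <- intersect(names(lens), unique(use$chrom))
  out <- list()
  for (ch in chroms) {
    sub <- fast_subset(use, which(use$chrom == ch))
    res <- .pileup_chrom(sub$pos, sub$cigar, sub$seq, sub$qual,
                         as.integer(lens[[ch]]))
    res$depth <- .colSums(res$counts, 4L, ncol(res$counts))
    res$indels <- data.frame(
      pos = res$indel_pos, allele = res$indel_allele,
      count = res$indel_count, stringsAsFactors = FALSE
    )
    res$indel_pos <- res$indel_allele <- res$indel_count <- NULL
    out[[ch]] <- res
  }
  structure(list(chroms = out, lengths = lens[chroms]), class = "pileup_set")
}

#' Extract one pileup column
#'
#' @param ps a `pileup_set`.
#' @param chrom,pos site to extract (1-based).
#' @param reference optional named character vector to attach the reference
#'   base.
#' @return a list with `chrom`, `pos`, `ref_base`, `base_counts`, `depth`
#'   and any indel observations at the site.
#' @export
pileup_column <- function(ps, chrom, pos, reference = NULL) {
  p <- ps$chroms[[chrom]]
  if (is.null(p)) stop("no pileup for ", chrom)
  counts <- p$counts[, pos]
  names(counts) <- DNA_BASES
  ind <- p$indels[p$indels$pos == pos, , drop = FALSE]
  list(
    chrom = chrom, pos = pos,
    ref_base = if (!is.null(reference)) {
      substring_bases(reference[[chrom]], pos)
    } else NA_character_,
    base_counts = counts, depth = p$depth[pos], indel_obs = ind
  )
}

GENOTYPES <- c("0/0", "0/1", "1/1")

## shared posterior machinery; s-values are per-base log accumulators
genotype_posterior <- function(s1r, s1a, s2r, s2a, s3r, s3a, t3, theta) {
  lp <- log(c(1 - 1.5 * theta, theta, theta / 2))
  ll_rr <- s1r + t3 - s3r
  ll_ra <- s2r + s2a + t3 - s3r - s3a
  ll_aa <- s1a + t3 - s3a
  ll <- cbind(ll_rr + lp[1], ll_ra + lp[2], ll_aa + lp[3])
  mx <- do.call(pmax, as.data.frame(ll))
  w <- exp(ll - mx)
  post <- w / rowSums(w)
  best <- max.col(post, ties.method = "first")
  gq <- -10 * log10(pmax(1 - post[cbind(seq_len(nrow(post)), best)], 1e-10))
  list(post = post, best = best, gq = pmin(gq, 99))
}

#' Call the genotype of one pileup column
#'
#' Computes the posterior over genotypes 0/0, 0/1, 1/1 from explicit base
#' and quality observations, and applies the calling contract: no-call when
#' depth is outside `[min_depth, max_depth]`, when the genotype quality is
#' below `min_gq`, or when the posterior-best genotype is homozygous
#' reference.
#'
#' @param bases character vector of observed bases (one per read).
#' @param quals integer Phred qualities, same length.
#' @param ref reference base at the site.
#' @param theta heterozygosity prior (default 0.001).
#' @param min_depth,max_depth callable depth range (defaults 5 and 200).
#' @param min_gq minimum genotype quality (default 10).
#' @param alt optional fixed alternate allele; defaults to the most frequent
#'   non-reference base.
#' @return `NULL` (no-call) or a one-row data.frame with `genotype`, `gq`,
#'   `depth`, allele depths and the full posterior as attributes.
#' @export
call_genotype <- function(bases, quals, ref, theta = 0.001,
                          min_depth = 5L, max_depth = 200L, min_gq = 10,
                          alt = NULL) {
  stopifnot(length(bases) == length(quals))
  if (!ref %in% DNA_BASES) return(NULL)
  keep <- bases %in% DNA_BASES
  bases <- bases[keep]
  quals <- quals[keep]
  depth <- length(bases)
  if (depth < min_depth || depth > max_depth) return(NULL)
  counts <- table(factor(bases, levels = DNA_BASES))
  if (is.null(alt)) {
    nonref <- counts
    nonref[ref] <- -1L
    alt <- DNA_BASES[which.max(nonref)]
  }
  if (alt == ref || counts[alt] == 0L) return(NULL)
  e <- pmin(10^(-quals / 10), 0.75)
  sum_for <- function(allele, f) sum(f[bases == allele])
  l1 <- log(1 - e)
  l2 <- log(((1 - e) + e / 3) / 2)
  l3 <- log(e / 3)
  t3 <- sum(l3)
  gp <- genotype_posterior(
    sum_for(ref, l1), sum_for(alt, l1),
    sum_for(ref, l2), sum_for(alt, l2),
    sum_for(ref, l3), sum_for(alt, l3),
    t3, theta
  )
  if (gp$best == 1L || gp$gq < min_gq) return(NULL)
  out <- data.frame(
    ref = ref, alt = alt, genotype = GENOTYPES[gp$best], gq = gp$gq,
    depth = depth, ref_count = as.integer(counts[ref]),
    alt_count = as.integer(counts[alt]), stringsAsFactors = FALSE
  )
  attr(out, "posterior") <- setNames(as.numeric(gp$post), GENOTYPES)
  out
}

#' Call SNV genotypes across a pileup
#'
#' Vectorised application of the [call_genotype()] model to every position
#' of a `pileup_set`. On mitochondrial chromosomes the genotype label is
#' assigned from the alternate allele fraction (>= 0.9 homoplasmic `1/1`,
#' else heteroplasmic `0/1`) instead of the diploid posterior, which still
#' gates the call via its genotype quality.
#'
#' @param ps a `pileup_set` (see [pileup()]).
#' @param reference named character vector of reference sequences.
#' @param theta heterozygosity prior.
#' @param min_depth,max_depth,min_gq calling contract thresholds.
#' @param mito_chroms chromosome names treated as mitochondrial.
#' @return a `variant_calls` data.frame: chrom, pos, ref, alt, genotype,
#'   gq, depth, ref_count, alt_count.
#' @export
call_genotypes <- function(ps, reference, theta = 0.001,
                           min_depth = 5L, max_depth = 200L, min_gq = 10,
                           mito_chroms = c("chrM", "MT", "chrMT")) {
  out <- list()
  for (ch in names(ps$chroms)) {
    p <- ps$chroms[[ch]]
    L <- length(p$depth)
    ref_idx <- base_indices(reference[[ch]])
    depth <- p$depth
    ok_depth <- depth >= min_depth & depth <= max_depth & ref_idx > 0L
    ## candidates: any non-reference observation
    ref_cnt <- p$counts[cbind(pmax(ref_idx, 1L), seq_len(L))]
    cand <- which(ok_depth & depth > ref_cnt)
    if (!length(cand)) next
    ri <- ref_idx[cand]
    C <- p$counts[, cand, drop = FALSE]
    Cm <- C
    Cm[cbind(ri, seq_along(cand))] <- -1L
    ai <- max.col(t(Cm), ties.method = "first")
    idx_r <- cbind(ri, cand)
    idx_a <- cbind(ai, cand)
    t3 <- .colSums(p$s3, 4L, ncol(p$s3))[cand]
    gp <- genotype_posterior(
      p$s1[idx_r], p$s1[idx_a], p$s2[idx_r], p$s2[idx_a],
      p$s3[idx_r], p$s3[idx_a], t3, theta
    )
    alt_cnt <- C[cbind(ai, seq_along(cand))]
    keep <- gp$best > 1L & gp$gq >= min_gq & alt_cnt > 0L
    if (!any(keep)) next
    genotype <- GENOTYPES[gp$best[keep]]
    if (ch %in% mito_chroms) {
      af <- alt_cnt[keep] / depth[cand][keep]
      genotype <- ifelse(af >= 0.9, "1/1", "0/1")
    }
    out[[ch]] <- data.frame(
      chrom = ch, pos = cand[keep],
      ref = DNA_BASES[ri[keep]], alt = DNA_BASES[ai[keep]],
      genotype = genotype, gq = gp$gq[keep], depth = depth[cand][keep],
      ref_count = ref_cnt[cand][keep], alt_count = alt_cnt[keep],
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), genotype = character(), gq = numeric(),
    depth = integer(), ref_count = integer(), alt_count = integer(),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("variant_calls", "data.frame")
  res
}

base_indices <- function(seq) {
  raw <- utf8ToInt(seq)
  idx <- integer(length(raw))
  idx[raw == 65L] <- 1L  # A
  idx[raw == 67L] <- 2L  # C
  idx[raw == 71L] <- 3L  # G
  idx[raw == 84L] <- 4L  # T
  idx
}

#' Call small indels from pileup indel observations
#'
#' An indel allele is called when its supporting reads reach
#' `min_support_fraction` of the site depth and the depth is within the
#' callable range; the genotype is heterozygous below `hom_fraction`
#' support, homozygous at or above it. Conflicting alleles at one site keep
#' the majority allele (logged).
#'
#' @param ps a `pileup_set`.
#' @param reference named character vector of reference sequences.
#' @param min_support_fraction minimum supporting-read fraction (0.25).
#' @param hom_fraction support fraction at or above which the call is
#'   homozygous (0.75).
#' @param min_depth,max_depth callable depth range.
#' @return a `variant_calls` data.frame with `kind` INS/DEL; indel `pos`
#'   follows the pileup convention (insertions at the preceding base,
#'   deletions at the first deleted base).
#' @export
call_indels <- function(ps, reference, min_support_fraction = 0.25,
                        hom_fraction = 0.75, min_depth = 5L,
                        max_depth = 200L) {
  out <- list()
  for (ch in names(ps$chroms)) {
    p <- ps$chroms[[ch]]
    ind <- p$indels
    if (!nrow(ind)) next
    ## one allele per site: keep the majority, log conflicts
    ind <- ind[order(ind$pos, -ind$count), , drop = FALSE]
    dupped <- duplicated(ind$pos)
    if (any(dupped)) {
      message(sum(dupped), " conflicting indel allele(s) at ", ch,
              " sites; keeping majority")
      ind <- ind[!dupped, , drop = FALSE]
    }
    ## deleted positions receive no base observations from deletion-bearing
    ## reads, so deletions are measured against the anchor base before them
    is_del <- !startsWith(ind$allele, "+")
    depth_at <- ind$pos - is_del
    depth <- p$depth[pmax(depth_at, 1L)]
    frac <- ind$count / pmax(depth, 1L)
    keep <- depth >= min_depth & depth <= max_depth &
      frac >= min_support_fraction
    ind <- ind[keep, , drop = FALSE]
    if (!nrow(ind)) next
    frac <- frac[keep]
    is_ins <- startsWith(ind$allele, "+")
    ref <- alt <- character(nrow(ind))
    anchor <- substring_bases(reference[[ch]], ind$pos)
    ins_seq <- substring(ind$allele, 2L)
    ref[is_ins] <- anchor[is_ins]
    alt[is_ins] <- paste0(anchor[is_ins], ins_seq[is_ins])
    del_len <- suppressWarnings(as.integer(ins_seq))
    if (any(!is_ins)) {
      ref[!is_ins] <- stringi::stri_sub(
        reference[[ch]], ind$pos[!is_ins],
        ind$pos[!is_ins] + del_len[!is_ins] - 1L
      )
      alt[!is_ins] <- ""
    }
    out[[ch]] <- data.frame(
      chrom = ch, pos = ind$pos, ref = ref, alt = alt,
      kind = ifelse(is_ins, "INS", "DEL"),
      genotype = ifelse(frac >= hom_fraction, "1/1", "0/1"),
      gq = NA_real_, depth = as.integer(depth[keep]),
      ref_count = as.integer(depth[keep] - ind$count),
      alt_count = ind$count, stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), kind = character(), genotype = character(),
    gq = numeric(), depth = integer(), ref_count = integer(),
    alt_count = integer(), stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("variant_calls", "data.frame")
  res
}

#' Compute the callable (sufficiently covered) region
#'
#' Positions with read depth between `min_depth` and `max_depth` inclusive.
#'
#' @param ps a `pileup_set`.
#' @param min_depth,max_depth inclusive depth bounds (defaults 5 and 200).
#' @return a `callable_mask`: per-chromosome data.frames of 1-based
#'   inclusive runs, with total size in bases.
#' @export
callable_region <- function(ps, min_depth = 5L, max_depth = 200L) {
  runs <- list()
  for (ch in names(ps$chroms)) {
    d <- ps$chroms[[ch]]$depth
    ok <- d >= min_depth & d <= max_depth
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs[[ch]] <- data.frame(start = starts[r$values], end = ends[r$values])
  }
  structure(
    list(runs = runs, n_bases = sum(vapply(runs, function(r) {
      sum(r$end - r$start + 1L)
    }, numeric(1)))),
    class = "callable_mask"
  )
}

#' Intersect two callable masks
#' @param a,b `callable_mask` objects.
#' @export
mask_intersect <- function(a, b) {
  chroms <- intersect(names(a$runs), names(b$runs))
  runs <- list()
  for (ch in chroms) {
    ra <- a$runs[[ch]]
    rb <- b$runs[[ch]]
    out <- list()
    j <- 1L
    for (i in seq_len(nrow(ra))) {
      while (j <= nrow(rb) && rb$end[j] < ra$start[i]) j <- j + 1L
      k <- j
      while (k <= nrow(rb) && rb$start[k] <= ra$end[i]) {
        out[[length(out) + 1L]] <- c(max(ra$start[i], rb$start[k]),
                                     min(ra$end[i], rb$end[k]))
        k <- k + 1L
      }
    }
    runs[[ch]] <- if (length(out)) {
      m <- do.call(rbind, out)
      data.frame(start = m[, 1], end = m[, 2])
    } else {
      data.frame(start = integer(), end = integer())
    }
  }
  structure(
    list(runs = runs, n_bases = sum(vapply(runs, function(r) {
      sum(r$end - r$start + 1L)
    }, numeric(1)))),
    class = "callable_mask"
  )
}

#' Test positions for callable-mask membership
#' @param mask a `callable_mask`.
#' @param chrom,pos vectors of sites.
#' @return logical vector.
#' @export
mask_contains <- function(mask, chrom, pos) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    r <- mask$runs[[ch]]
    sel <- chrom == ch
    if (is.null(r) || !nrow(r)) next
    i <- findInterval(pos[sel], r$start)
    out[sel] <- i >= 1L & pos[sel] <= r$end[pmax(i, 1L)]
  }
  out
}

#' @export
print.callable_mask <- function(x, ...) {
  cat(sprintf("<callable_mask> %s bases across %d chromosome(s)\n",
              format(x$n_bases, big.mark = ","), length(x$runs)))
  invisible(x)
}
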
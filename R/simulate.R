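## Donor/clone genome and read simulator.
##
## A sample is modelled as a set of haplotype units (one per haplotype per
## chromosome; chrX and chrM carry a single unit). Each unit is a list of
## runs: "M" runs are collinear copies of a reference interval, "N" runs are
## novel or unmappable sequence (clone-specific telomere tracts, large novel
## insertions). Small indels live in per-haplotype edit sets and are spliced
## into M runs at assembly time, so reads crossing them acquire I/D CIGAR
## operations while everything else stays a plain match.

TELOMERE_MOTIF <- "TTAGGG"

## ---- donor genome ----------------------------------------------------------

#' Build the donor genome and its germline truth set
#'
#' Generates a haploid reference (chr1..chrN, chrX, chrM), writes telomeric
#' tracts, stop-free coding genes and interstitial control-motif repeat
#' arrays into it, and plants heterozygous germline SNVs that distinguish
#' the donor's two nuclear haplotypes from the reference. Deterministic
#' under `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return a `genome_model` object; key components are `$reference` (named
#'   character vector), `$germline` (truth data.frame of planted germline
#'   variants), `$genes`, `$telomeres`, and the haplotype units used by
#'   [simulate_reads()].
#' @export
build_donor_genome <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "donor_genome"))
  lens <- config_chrom_lengths(config)
  chroms <- names(lens)
  nuclear <- setdiff(chroms, "chrM")

  reference <- vapply(lens, random_dna, character(1))
  names(reference) <- chroms

  ## telomere tracts: (CCCTAA)n left, (TTAGGG)n right, nuclear chroms only
  tel <- config$telomere_length_donor
  telomeres <- NULL
  if (tel > 0) {
    tl <- lapply(nuclear, function(ch) {
      L <- lens[[ch]]
      left <- substr(strrep(revcomp(TELOMERE_MOTIF), ceiling(tel / 6)), 1, tel)
      right_full <- strrep(TELOMERE_MOTIF, ceiling(tel / 6))
      right <- substr(right_full, nchar(right_full) - tel + 1, nchar(right_full))
      reference[[ch]] <<- paste0(
        left, substr(reference[[ch]], tel + 1, L - tel), right
      )
      data.frame(
        chrom = ch, start = c(1L, L - tel + 1L), end = c(tel, L),
        side = c("left", "right"), stringsAsFactors = FALSE
      )
    })
    telomeres <- do.call(rbind, tl)
  } else {
    telomeres <- data.frame(
      chrom = character(), start = integer(), end = integer(),
      side = character(), stringsAsFactors = FALSE
    )
  }

  ## forbidden intervals so planted features stay clear of the tracts
  margin <- 2L * config$read_length
  occupied <- telomeres[, c("chrom", "start", "end")]

  ## protein-coding genes: stop-free ORFs overwritten into autosomes
  genes <- data.frame(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), exon_rank = integer(),
    stringsAsFactors = FALSE
  )
  if (config$n_genes > 0) {
    gid <- 0L
    for (ch in paste0("chr", seq_len(config$n_autosomes))) {
      for (g in seq_len(config$n_genes)) {
        gid <- gid + 1L
        orf <- make_orf(config$gene_n_codons)
        w <- nchar(orf)
        pos <- sample_clear_position(w, lens[[ch]], ch, occupied, margin)
        strand <- sample(c("+", "-"), 1)
        insert_seq <- if (strand == "+") orf else revcomp(orf)
        reference[[ch]] <- substitute_range(reference[[ch]], pos, insert_seq)
        row <- data.frame(
          gene_id = sprintf("gene%03d", gid), chrom = ch, strand = strand,
          start = pos, end = pos + w - 1L, exon_rank = 1L,
          stringsAsFactors = FALSE
        )
        genes <- rbind(genes, row)
        occupied <- rbind(occupied, row[, c("chrom", "start", "end")])
      }
    }
  }

  ## interstitial control-motif repeat arrays
  repeats <- data.frame(
    motif = character(), chrom = character(), start = integer(),
    end = integer(), stringsAsFactors = FALSE
  )
  autos <- paste0("chr", seq_len(config$n_autosomes))
  for (motif in config$interstitial_repeat_motifs) {
    for (a in seq_len(config$interstitial_repeat_arrays)) {
      arr <- strrep(motif, config$interstitial_repeat_copies)
      w <- nchar(arr)
      ch <- sample(autos, 1)
      pos <- sample_clear_position(w, lens[[ch]], ch, occupied, margin)
      reference[[ch]] <- substitute_range(reference[[ch]], pos, arr)
      row <- data.frame(
        motif = motif, chrom = ch, start = pos, end = pos + w - 1L,
        stringsAsFactors = FALSE
      )
      repeats <- rbind(repeats, row)
      occupied <- rbind(occupied, row[, c("chrom", "start", "end")])
    }
  }

  ## germline heterozygous SNVs (hemizygous, genotype 1/1, on chrX)
  germ <- list()
  snv_sets <- list(h1 = empty_snv_df(), h2 = empty_snv_df(), mito = empty_snv_df())
  for (ch in nuclear) {
    n <- rpois(1, config$germline_het_rate * lens[[ch]])
    if (n == 0) next
    pos <- sample_positions(n, lens[[ch]], ch, telomeres)
    ref <- substring_bases(reference[[ch]], pos)
    alt <- draw_alt(ref, config$somatic_titv)
    hap <- if (ch == "chrX") rep(1L, n) else sample(1:2, n, replace = TRUE)
    gt <- if (ch == "chrX") "1/1" else "0/1"
    germ[[ch]] <- data.frame(
      chrom = ch, pos = pos, ref = ref, alt = alt, genotype = gt, hap = hap,
      stringsAsFactors = FALSE
    )
    for (h in 1:2) {
      sel <- hap == h
      if (any(sel)) {
        snv_sets[[h]] <- rbind(snv_sets[[h]], data.frame(
          chrom = ch, pos = pos[sel], alt = alt[sel], stringsAsFactors = FALSE
        ))
      }
    }
  }
  germline <- if (length(germ)) do.call(rbind, germ) else data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), genotype = character(), hap = integer(),
    stringsAsFactors = FALSE
  )
  rownames(germline) <- NULL

  model <- list(
    role = "donor",
    reference = reference,
    chrom_lengths = lens,
    telomeres = telomeres,
    genes = genes,
    repeats = repeats,
    snv_sets = snv_sets,
    indel_sets = list(h1 = empty_indel_df(), h2 = empty_indel_df()),
    units = default_units(config),
    germline = germline,
    somatic = empty_somatic_df(),
    cnv_truth = NULL,
    sv_truth = NULL,
    telomere_truth = config$telomere_length_donor,
    config = config
  )
  class(model) <- "genome_model"
  model
}

## ---- clone genome ----------------------------------------------------------

#' Derive the clone genome from the donor by planting somatic events
#'
#' The clone shares the donor's nuclear haplotypes plus planted somatic SNVs
#' and indels (heterozygous, on one haplotype), copy-number events, large
#' structural events, clone-specific telomere tract lengths, and a replaced
#' mitochondrial haplotype diverged from the donor's chrM (SCNT clones carry
#' the oocyte donor's mitochondria). Somatic positions colliding with
#' germline sites are redrawn (with a message), keeping the two truth sets
#' disjoint by position.
#'
#' @param donor a `genome_model` from [build_donor_genome()].
#' @param config a [sim_config()]; usually the one used for the donor.
#' @return a `genome_model` with `$somatic`, `$cnv_truth` and `$sv_truth`
#'   truth tables filled in.
#' @export
derive_clone_genome <- function(donor, config = donor$config) {
  stopifnot(inherits(donor, "genome_model"), donor$role == "donor")
  set.seed(derive_seed(config$seed, "clone_genome"))
  model <- donor
  model$role <- "clone"
  model$config <- config
  lens <- model$chrom_lengths
  nuclear <- setdiff(names(lens), "chrM")
  nuclear_len <- sum(unlist(lens[nuclear]))

  taken <- model$germline[, c("chrom", "pos")]
  somatic <- list()

  ## somatic SNVs at somatic_snv_rate per Mb of nuclear genome
  n_snv <- rpois(1, config$somatic_snv_rate * nuclear_len / 1e6)
  if (n_snv > 0) {
    sites <- sample_nuclear_sites(n_snv, model, taken)
    ref <- mapply(function(ch, p) substring_bases(model$reference[[ch]], p),
                  sites$chrom, sites$pos)
    alt <- draw_alt(ref, config$somatic_titv)
    hap <- ifelse(sites$chrom == "chrX", 1L, sample(1:2, n_snv, replace = TRUE))
    gt <- ifelse(sites$chrom == "chrX", "1/1", "0/1")
    somatic$snv <- data.frame(
      chrom = sites$chrom, pos = sites$pos, ref = unname(ref), alt = alt,
      kind = "SNV", genotype = gt, hap = hap, stringsAsFactors = FALSE
    )
    taken <- rbind(taken, sites)
  }

  ## somatic small indels (1-10 bp), kept out of coding sequence
  n_ind <- rpois(1, config$somatic_indel_rate * nuclear_len / 1e6)
  if (n_ind > 0) {
    forbid <- rbind(
      model$telomeres[, c("chrom", "start", "end")],
      model$genes[, c("chrom", "start", "end")]
    )
    sites <- sample_nuclear_sites(n_ind, model, taken, extra_forbid = forbid)
    type <- sample(c("INS", "DEL"), n_ind, replace = TRUE)
    len <- sample(1:10, n_ind, replace = TRUE)
    hap <- ifelse(sites$chrom == "chrX", 1L, sample(1:2, n_ind, replace = TRUE))
    gt <- ifelse(sites$chrom == "chrX", "1/1", "0/1")
    seqs <- vapply(seq_len(n_ind), function(i) {
      if (type[i] == "INS") random_dna(len[i]) else ""
    }, character(1))
    ref <- character(n_ind)
    alt <- character(n_ind)
    pos_rep <- integer(n_ind)
    for (i in seq_len(n_ind)) {
      ch <- sites$chrom[i]
      p <- sites$pos[i]
      if (type[i] == "INS") {
        ## attributed to the preceding reference position
        pos_rep[i] <- p
        ref[i] <- substring_bases(model$reference[[ch]], p)
        alt[i] <- paste0(ref[i], seqs[i])
      } else {
        ## first deleted base
        pos_rep[i] <- p
        ref[i] <- stringi::stri_sub(model$reference[[ch]], p, p + len[i] - 1L)
        alt[i] <- ""
      }
    }
    somatic$indel <- data.frame(
      chrom = sites$chrom, pos = pos_rep, ref = ref, alt = alt,
      kind = type, genotype = gt, hap = hap, stringsAsFactors = FALSE
    )
    for (h in 1:2) {
      sel <- hap == h
      if (any(sel)) {
        model$indel_sets[[h]] <- rbind(model$indel_sets[[h]], data.frame(
          chrom = sites$chrom[sel], pos = sites$pos[sel], type = type[sel],
          len = len[sel], seq = seqs[sel], stringsAsFactors = FALSE
        ))
      }
    }
  }

  ## replaced mitochondrial haplotype
  n_mito <- rpois(1, config$mito_divergence * lens[["chrM"]])
  if (n_mito > 0) {
    pos <- sort(sample.int(lens[["chrM"]], n_mito))
    ref <- substring_bases(model$reference[["chrM"]], pos)
    alt <- draw_alt(ref, config$somatic_titv)
    model$snv_sets$mito <- data.frame(
      chrom = "chrM", pos = pos, alt = alt, stringsAsFactors = FALSE
    )
    somatic$mito <- data.frame(
      chrom = "chrM", pos = pos, ref = ref, alt = alt, kind = "SNV",
      genotype = "1/1", hap = 1L, stringsAsFactors = FALSE
    )
  }

  ## somatic SNVs go into the clone's haplotype substitution sets
  if (!is.null(somatic$snv)) {
    for (h in 1:2) {
      sel <- somatic$snv$hap == h | somatic$snv$chrom == "chrX" & h == 1L
      sel <- somatic$snv$hap == h
      if (any(sel)) {
        model$snv_sets[[h]] <- rbind(model$snv_sets[[h]], data.frame(
          chrom = somatic$snv$chrom[sel], pos = somatic$snv$pos[sel],
          alt = somatic$snv$alt[sel], stringsAsFactors = FALSE
        ))
      }
    }
  }

  model$somatic <- if (length(somatic)) {
    out <- do.call(rbind, somatic)
    rownames(out) <- NULL
    out
  } else {
    empty_somatic_df()
  }

  ## clone telomere tract lengths
  model$telomere_truth <- config$telomere_length_clone
  units <- default_units(config)
  units[["chrM_h1"]]$snv_set <- "mito"
  if (config$telomere_length_clone != config$telomere_length_donor) {
    units <- lapply(units, function(u) {
      if (unit_chrom(u) == "chrM") return(u)
      adjust_unit_telomeres(u, model, config)
    })
  }

  ## copy-number and structural events (validated non-overlapping)
  check_events_clear_of_tracts(config, model)
  units <- apply_interval_events(units, config)
  units <- apply_ctx_events(units, config, lens)
  model$units <- units

  if (!is.null(config$cnv_events)) {
    model$cnv_truth <- config$cnv_events
  }
  if (!is.null(config$sv_events)) {
    sv <- config$sv_events
    sv$pos1 <- sv$start
    sv$pos2 <- ifelse(sv$type == "DEL", sv$start + sv$size, sv$start)
    model$sv_truth <- sv
  }
  model
}

## ---- internal generators ---------------------------------------------------

make_orf <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, stops)
  body <- sample(codons, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

substitute_range <- function(seq, pos, replacement) {
  stringi::stri_sub(seq, pos, pos + nchar(replacement) - 1L) <- replacement
  seq
}

substring_bases <- function(seq, pos) {
  stringi::stri_sub(seq, pos, pos)
}

empty_snv_df <- function() {
  data.frame(chrom = character(), pos = integer(), alt = character(),
             stringsAsFactors = FALSE)
}

empty_indel_df <- function() {
  data.frame(chrom = character(), pos = integer(), type = character(),
             len = integer(), seq = character(), stringsAsFactors = FALSE)
}

empty_somatic_df <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), kind = character(), genotype = character(),
             hap = integer(), stringsAsFactors = FALSE)
}

## uniform positions on one chromosome avoiding forbidden intervals
sample_positions <- function(n, L, chrom, forbid, width = 1L) {
  out <- integer(0)
  f <- forbid[forbid$chrom == chrom, , drop = FALSE]
  guard <- 0L
  while (length(out) < n && guard < 50L) {
    cand <- sample.int(L - width + 1L, n - length(out) + 10L, replace = TRUE)
    if (nrow(f)) {
      bad <- rep(FALSE, length(cand))
      for (i in seq_len(nrow(f))) {
        bad <- bad | (cand + width - 1L >= f$start[i] & cand <= f$end[i])
      }
      cand <- cand[!bad]
    }
    out <- unique(c(out, cand))
    guard <- guard + 1L
  }
  if (length(out) < n) stop("could not place ", n, " positions on ", chrom)
  sort(sample(out, n))
}

## a single placement for a width-w feature, clear of occupied intervals
sample_clear_position <- function(w, L, chrom, occupied, margin) {
  occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
  for (try in 1:200) {
    pos <- sample.int(L - w - 2L * margin, 1) + margin
    if (!nrow(occ) ||
        all(pos + w - 1L < occ$start - margin | pos > occ$end + margin)) {
      return(pos)
    }
  }
  stop("could not place feature of width ", w, " on ", chrom)
}

## sites across the nuclear genome, length-weighted, avoiding telomeres,
## already-taken positions redrawn (logged)
sample_nuclear_sites <- function(n, model, taken, extra_forbid = NULL) {
  lens <- model$chrom_lengths
  nuclear <- setdiff(names(lens), "chrM")
  w <- unlist(lens[nuclear])
  forbid <- model$telomeres[, c("chrom", "start", "end")]
  if (!is.null(extra_forbid) && nrow(extra_forbid)) {
    forbid <- rbind(forbid, extra_forbid)
  }
  chrom <- sample(nuclear, n, replace = TRUE, prob = w)
  pos <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      p <- sample_positions(1, lens[[chrom[i]]], chrom[i], forbid, width = 12L)
      clash <- any(taken$chrom == chrom[i] & taken$pos == p) ||
        any(pos[seq_len(i - 1)][chrom[seq_len(i - 1)] == chrom[i]] == p)
      if (!clash) {
        pos[i] <- p
        break
      }
      message("somatic site collided with an existing variant; redrawn")
    }
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

draw_alt <- function(ref, titv) {
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(
    A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G")
  )
  p_ts <- titv / (titv + 1)
  is_ts <- runif(length(ref)) < p_ts
  alt <- character(length(ref))
  alt[is_ts] <- ts_map[ref[is_ts]]
  if (any(!is_ts)) {
    alt[!is_ts] <- vapply(ref[!is_ts], function(b) sample(tv_map[[b]], 1),
                          character(1))
  }
  alt
}

## ---- haplotype units -------------------------------------------------------

m_run <- function(chrom, start, len) {
  data.frame(kind = "M", chrom = chrom, ref_start = as.integer(start),
             len = as.integer(len), seq = NA_character_,
             stringsAsFactors = FALSE)
}

n_run <- function(seq) {
  data.frame(kind = "N", chrom = NA_character_, ref_start = NA_integer_,
             len = nchar(seq), seq = seq, stringsAsFactors = FALSE)
}

unit_chrom <- function(u) u$chrom_label

default_units <- function(config) {
  lens <- config_chrom_lengths(config)
  units <- list()
  for (i in seq_len(config$n_autosomes)) {
    ch <- paste0("chr", i)
    for (h in 1:2) {
      units[[paste0(ch, "_h", h)]] <- list(
        name = paste0(ch, "_h", h), chrom_label = ch,
        snv_set = paste0("h", h), indel_set = paste0("h", h),
        weight = 0.5, runs = m_run(ch, 1L, lens[[ch]])
      )
    }
  }
  units[["chrX_h1"]] <- list(
    name = "chrX_h1", chrom_label = "chrX", snv_set = "h1", indel_set = "h1",
    weight = 0.5, runs = m_run("chrX", 1L, lens[["chrX"]])
  )
  units[["chrM_h1"]] <- list(
    name = "chrM_h1", chrom_label = "chrM", snv_set = "h1", indel_set = "h1",
    weight = 1.0, runs = m_run("chrM", 1L, lens[["chrM"]])
  )
  units
}

## clone telomere tracts differ from the donor reference: replace the
## terminal reference tract with a novel repeat run of the clone length
adjust_unit_telomeres <- function(u, model, config) {
  ch <- unit_chrom(u)
  L <- model$chrom_lengths[[ch]]
  td <- config$telomere_length_donor
  tc <- config$telomere_length_clone
  left <- if (tc > 0) {
    n_run(substr(strrep(revcomp(TELOMERE_MOTIF), ceiling(tc / 6)), 1, tc))
  } else NULL
  right <- if (tc > 0) {
    full <- strrep(TELOMERE_MOTIF, ceiling(tc / 6))
    n_run(substr(full, nchar(full) - tc + 1L, nchar(full)))
  } else NULL
  mid <- m_run(ch, td + 1L, L - 2L * td)
  u$runs <- do.call(rbind, Filter(Negate(is.null), list(left, mid, right)))
  u
}

clone_set_for_mito <- function(u) {
  u$snv_set <- "mito"
  u
}

check_events_clear_of_tracts <- function(config, model) {
  ev <- rbind(
    if (!is.null(config$cnv_events)) {
      data.frame(chrom = config$cnv_events$chrom,
                 start = config$cnv_events$start,
                 end = config$cnv_events$end, stringsAsFactors = FALSE)
    },
    if (!is.null(config$sv_events)) {
      sv <- config$sv_events
      data.frame(
        chrom = sv$chrom, start = sv$start,
        end = ifelse(sv$type == "DEL", sv$start + sv$size - 1, sv$start),
        stringsAsFactors = FALSE
      )
    }
  )
  if (is.null(ev) || !nrow(ev)) return(invisible(TRUE))
  tel <- model$telomeres
  for (i in seq_len(nrow(ev))) {
    tt <- tel[tel$chrom == ev$chrom[i], , drop = FALSE]
    if (nrow(tt) && any(ev$start[i] <= tt$end & ev$end[i] >= tt$start)) {
      stop("cnv/sv event overlaps a telomeric tract")
    }
  }
  invisible(TRUE)
}

## remove / duplicate reference intervals inside a unit's M runs
edit_runs_interval <- function(runs, chrom, start, end, action) {
  out <- list()
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    if (r$kind != "M" || r$chrom != chrom ||
        r$ref_start + r$len - 1L < start || r$ref_start > end) {
      out[[length(out) + 1L]] <- r
      next
    }
    r_end <- r$ref_start + r$len - 1L
    s <- max(start, r$ref_start)
    e <- min(end, r_end)
    if (r$ref_start < s) {
      out[[length(out) + 1L]] <- m_run(chrom, r$ref_start, s - r$ref_start)
    }
    if (action == "dup") {
      out[[length(out) + 1L]] <- m_run(chrom, s, e - s + 1L)
      out[[length(out) + 1L]] <- m_run(chrom, s, e - s + 1L)
    } else if (action == "dup2") {
      for (k in 1:3) out[[length(out) + 1L]] <- m_run(chrom, s, e - s + 1L)
    }
    ## action "del": drop the covered piece
    if (e < r_end) {
      out[[length(out) + 1L]] <- m_run(chrom, e + 1L, r_end - e)
    }
  }
  do.call(rbind, out)
}

insert_novel_run <- function(runs, chrom, pos, seq) {
  out <- list()
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    r_end <- if (r$kind == "M") r$ref_start + r$len - 1L else NA_integer_
    if (r$kind == "M" && r$chrom == chrom &&
        pos >= r$ref_start && pos < r_end) {
      out[[length(out) + 1L]] <- m_run(chrom, r$ref_start, pos - r$ref_start + 1L)
      out[[length(out) + 1L]] <- n_run(seq)
      out[[length(out) + 1L]] <- m_run(chrom, pos + 1L, r_end - pos)
    } else {
      out[[length(out) + 1L]] <- r
    }
  }
  do.call(rbind, out)
}

apply_interval_events <- function(units, config) {
  apply_one <- function(chrom, start, end, action, haps) {
    for (h in haps) {
      nm <- paste0(chrom, "_h", h)
      if (is.null(units[[nm]])) nm <- paste0(chrom, "_h1")
      units[[nm]]$runs <<- edit_runs_interval(
        units[[nm]]$runs, chrom, start, end, action
      )
    }
  }
  if (!is.null(config$cnv_events)) {
    ev <- config$cnv_events
    for (i in seq_len(nrow(ev))) {
      cn <- ev$copy_number[i]
      if (cn == 2) next
      action <- if (cn < 2) "del" else if (cn == 3) "dup" else "dup2"
      haps <- if (cn == 0) 1:2 else 1L
      if (cn == 4) {
        action <- "dup"
        haps <- 1:2
      }
      apply_one(ev$chrom[i], ev$start[i], ev$end[i], action, haps)
    }
  }
  if (!is.null(config$sv_events)) {
    ev <- config$sv_events
    for (i in seq_len(nrow(ev))) {
      if (ev$type[i] == "DEL") {
        apply_one(ev$chrom[i], ev$start[i], ev$start[i] + ev$size[i] - 1L,
                  "del", 1L)
      } else if (ev$type[i] == "INS") {
        nm <- paste0(ev$chrom[i], "_h1")
        units[[nm]]$runs <- insert_novel_run(
          units[[nm]]$runs, ev$chrom[i], ev$start[i], random_dna(ev$size[i])
        )
      }
    }
  }
  units
}

## reciprocal translocation: swap the tails of two chromosomes on hap 1
apply_ctx_events <- function(units, config, lens) {
  if (is.null(config$sv_events)) return(units)
  ev <- config$sv_events[config$sv_events$type == "CTX", , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    chA <- ev$chrom[i]
    p1 <- ev$start[i]
    chB <- if ("chrom2" %in% names(ev) && !is.na(ev$chrom2[i])) ev$chrom2[i] else
      stop("CTX events need chrom2/start2 columns")
    p2 <- ev$start2[i]
    ua <- paste0(chA, "_h1")
    ub <- paste0(chB, "_h1")
    sa <- split_runs_at_ref(units[[ua]]$runs, chA, p1)
    sb <- split_runs_at_ref(units[[ub]]$runs, chB, p2)
    units[[ua]]$runs <- rbind(sa$left, sb$right)
    units[[ub]]$runs <- rbind(sb$left, sa$right)
  }
  units
}

## split a run list at reference position p (left part covers ref <= p)
split_runs_at_ref <- function(runs, chrom, p) {
  left <- list()
  right <- list()
  seen <- FALSE
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    if (!seen && r$kind == "M" && r$chrom == chrom &&
        p >= r$ref_start && p < r$ref_start + r$len - 1L) {
      left[[length(left) + 1L]] <- m_run(chrom, r$ref_start, p - r$ref_start + 1L)
      right[[length(right) + 1L]] <- m_run(chrom, p + 1L,
                                           r$ref_start + r$len - 1L - p)
      seen <- TRUE
    } else if (!seen) {
      left[[length(left) + 1L]] <- r
    } else {
      right[[length(right) + 1L]] <- r
    }
  }
  if (!seen) stop("CTX breakpoint not inside a collinear run")
  list(left = do.call(rbind, left), right = do.call(rbind, right))
}
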
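#' Subset an alignment table to uniquely aligned reads
#'
#' @param aln alignment table.
#' @export
unique_alignments <- function(aln) {
  cnt <- alignment_counts(aln)
  out <- aln[read_id %in% cnt[n_aln == 1L, read_id]]
  for (a in c("space", "k")) data.table::setattr(out, a, attr(aln, a))
  out[]
}

#' Strand-aware pileup of unique alignments
#'
#' Builds per-position forward/reverse coverage and a table of alternative
#' base observations, each carrying the supporting alignment's strand and
#' start position (for start-point-diversity filtering). Counts must derive
#' only from unique alignments: natively unique in U regions, unique after
#' g-deNoise in M regions — the caller enforces this by construction of its
#' input.
#'
#' @param aln alignment table of unique alignments (base space).
#' @param genome the reference `DNAStringSet`.
#' @return object of class `pileup`: list with `coverage` (per chromosome,
#'   integer vectors `fwd` and `rev`) and `alt` (a `data.table` of
#'   per-read alternative observations).
#' @export
pileup <- function(aln, genome) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (nrow(aln) > 0L &&
      aln[, any(start < 1L | start + read_len - 1L > lens[chrom])]) {
    stop("alignment beyond chromosome end")
  }
  cov <- lapply(names(genome), function(chr_nm) {
    sub <- aln[chrom == chr_nm]
    ends <- sub$start + sub$read_len - 1L
    list(fwd = interval_coverage(lens[[chr_nm]], sub$start[sub$strand == "+"],
                                 ends[sub$strand == "+"]),
         rev = interval_coverage(lens[[chr_nm]], sub$start[sub$strand == "-"],
                                 ends[sub$strand == "-"]))
  })
  names(cov) <- names(genome)
  alt <- alignment_substitutions(aln, genome)
  structure(list(coverage = cov, alt = alt), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("<pileup> ", length(x$coverage), " chromosome(s), ",
      nrow(x$alt), " alternative-base observation(s)\n", sep = "")
  invisible(x)
}

pos_in_regions <- function(chrom_v, pos_v, regions) {
  if (length(regions) == 0L) return(rep(FALSE, length(pos_v)))
  q <- GenomicRanges::GRanges(chrom_v, IRanges::IRanges(pos_v, pos_v))
  IRanges::overlapsAny(q, regions)
}

aggregate_alt <- function(pile) {
  if (nrow(pile$alt) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  alt_fwd = integer(), alt_rev = integer(),
                                  n_starts = integer(), coverage = integer(),
                                  fraction = numeric()))
  }
  agg <- pile$alt[, .(
    alt_fwd = sum(strand == "+"),
    alt_rev = sum(strand == "-"),
    n_starts = data.table::uniqueN(paste(start, strand))),
    by = .(chrom, pos, ref, alt)]
  agg[, coverage := mapply(function(ch, p) {
    pile$coverage[[ch]]$fwd[p] + pile$coverage[[ch]]$rev[p]
  }, chrom, pos)]
  agg[, fraction := (alt_fwd + alt_rev) / coverage]
  agg[]
}

#' Call SNPs in unique (U) regions
#'
#' A call is emitted iff the alternative base is seen in at least
#' `min_fraction` of the unique alignments covering the position *and* is
#' supported on both strands. Thresholds are closed: a fraction of exactly
#' `min_fraction` passes.
#'
#' @param pile a [pileup()] of natively unique alignments.
#' @param u_regions `GRanges` of U regions (calls restricted to them).
#' @param min_fraction minimum alternative-allele fraction (default 0.70).
#' @return `data.table` of calls with per-strand support, start-point
#'   count, allele fraction and `region_label = "U"`.
#' @export
call_u_snps <- function(pile, u_regions, min_fraction = 0.70) {
  agg <- aggregate_alt(pile)
  agg <- agg[pos_in_regions(chrom, pos, u_regions)]
  calls <- agg[fraction >= min_fraction & alt_fwd >= 1L & alt_rev >= 1L]
  calls[, `:=`(region_label = "U", masked = FALSE)]
  data.table::setorder(calls, chrom, pos, alt)
  calls[]
}

#' Call SNPs in multialigned (M) regions after g-deNoise
#'
#' Operates on alignments that became unique after g-deNoise filtering. A
#' call is emitted iff the alternative base is supported by at least
#' `min_per_strand` unique alignments on *each* strand, arising from at
#' least `min_starts` distinct starting points, at an unmasked position.
#' All thresholds are closed ("at least").
#'
#' @param pile a [pileup()] of post-filter unique alignments.
#' @param m_regions `GRanges` of M (or M_U) regions to call within.
#' @param mask low-complexity mask from [mask_low_complexity()].
#' @param min_per_strand minimum alt support per strand (default 10).
#' @param min_starts minimum distinct (start, strand) points (default 5).
#' @export
call_m_snps <- function(pile, m_regions, mask = NULL,
                        min_per_strand = 10L, min_starts = 5L) {
  agg <- aggregate_alt(pile)
  agg <- agg[pos_in_regions(chrom, pos, m_regions)]
  if (!is.null(mask)) {
    agg[, masked := mapply(function(ch, p) mask[[ch]][p], chrom, pos)]
  } else {
    agg[, masked := FALSE]
  }
  calls <- agg[alt_fwd >= min_per_strand & alt_rev >= min_per_strand &
                 n_starts >= min_starts & masked == FALSE]
  calls[, region_label := "M_U"]
  data.table::setorder(calls, chrom, pos, alt)
  calls[]
}

#' Mask homopolymers and microsatellite tracts
#'
#' Positions inside a homopolymer run of at least `homopolymer_min` nt, or
#' inside a tandem repeat with unit length at most `max_unit`, at least
#' `min_copies` copies and total tract length at least `min_tract`, are
#' masked together with a flank of `flank` nt on each side. These "noisy"
#' tracts are excluded from M-region calling.
#'
#' @param genome a `DNAStringSet`.
#' @param homopolymer_min minimum homopolymer run length (default 5).
#' @param max_unit maximum tandem unit length considered (default 6).
#' @param min_copies minimum number of tandem copies (default 3).
#' @param min_tract minimum total tandem tract length (default 8).
#' @param flank masked flank in nt (default 2).
#' @return named list of logical vectors, one per chromosome.
#' @export
mask_low_complexity <- function(genome, homopolymer_min = 5L, max_unit = 6L,
                                min_copies = 3L, min_tract = 8L,
                                flank = 2L) {
  chroms <- as.character(genome)
  out <- lapply(chroms, function(s) {
    L <- nchar(s)
    v <- utf8ToInt(s)
    mask <- logical(L)
    for (u in seq_len(min(max_unit, max(0L, L - 1L)))) {
      eq <- v[seq_len(L - u)] == v[seq.int(u + 1L, L)]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        total <- r$lengths[j] + u       # tract spans match run + one unit
        ok <- if (u == 1L) total >= homopolymer_min else
          (total %/% u) >= min_copies && total >= min_tract
        if (ok) {
          a <- max(1L, starts[j] - flank)
          b <- min(L, ends[j] + u + flank)
          mask[a:b] <- TRUE
        }
      }
    }
    mask
  })
  names(out) <- names(genome)
  out
}

#' Compare call sets across samples
#'
#' Variants are keyed by `(chrom, pos, ref, alt)`. A variant present in
#' every sample is `constitutive`; present in exactly one sample,
#' `acquired`; anything in between is reported as `shared` with its count.
#'
#' @param call_sets named list (>= 2) of call tables.
#' @return `data.table` with one row per variant: key columns,
#'   `n_samples`, `samples` (comma-separated), `status`.
#' @export
compare_samples <- function(call_sets) {
  stopifnot(length(call_sets) >= 2L, !is.null(names(call_sets)))
  per <- data.table::rbindlist(lapply(names(call_sets), function(nm) {
    cs <- call_sets[[nm]]
    if (nrow(cs) == 0L) return(NULL)
    data.table::data.table(sample_id = nm, chrom = cs$chrom, pos = cs$pos,
                           ref = cs$ref, alt = cs$alt)
  }))
  if (is.null(per) || nrow(per) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  n_samples = integer(),
                                  samples = character(),
                                  status = character()))
  }
  n_total <- length(call_sets)
  out <- per[, .(n_samples = .N,
                 samples = paste(sort(sample_id), collapse = ",")),
             by = .(chrom, pos, ref, alt)]
  out[, status := data.table::fifelse(
    n_samples == n_total, "constitutive",
    data.table::fifelse(n_samples == 1L, "acquired", "shared"))]
  data.table::setorder(out, chrom, pos, alt)
  out[]
}

#' Write variant calls as VCF
#'
#' Minimal VCFv4.2 text with INFO fields `RL` (region label), `ADF`/`ADR`
#' (per-strand alt support), `NS` (distinct start points) and `AF`
#' (alternative-allele fraction).
#'
#' @param calls a call table from [call_u_snps()] / [call_m_snps()].
#' @param genome the reference `DNAStringSet` (contig headers).
#' @param path output path.
#' @export
write_vcf <- function(calls, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome),
            Biostrings::width(genome)),
    "##INFO=<ID=RL,Number=1,Type=String,Description=\"Region label\">",
    "##INFO=<ID=ADF,Number=1,Type=Integer,Description=\"Alt fwd support\">",
    "##INFO=<ID=ADR,Number=1,Type=Integer,Description=\"Alt rev support\">",
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Distinct starts\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) > 0L) {
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tRL=%s;ADF=%d;ADR=%d;NS=%d;AF=%.4f",
      calls$chrom, calls$pos, calls$ref, calls$alt, calls$region_label,
      calls$alt_fwd, calls$alt_rev, calls$n_starts, calls$fraction), con)
  }
  invisible(path)
}
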
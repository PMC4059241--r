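# interval -> per-position count via the difference-array trick
interval_coverage <- function(L, starts, ends) {
  if (length(starts) == 0L) return(integer(L))
  d <- integer(L + 1L)
  d[seq_len(L)] <- tabulate(starts, L)
  d <- d - c(0L, tabulate(pmin(ends, L), L))
  cumsum(d[seq_len(L)])
}

#' Build per-position coverage tracks from alignments
#'
#' Each alignment increments positions `start..start+read_len-1`. The
#' `ambig` track counts only alignments of multialigned reads (more than
#' one alignment), i.e. total coverage after discarding all unique
#' alignments — the quantity that defines M regions.
#'
#' @param aln an alignment table.
#' @param genome the reference `DNAStringSet`.
#' @return object of class `coverage_track`: per chromosome, integer
#'   vectors `total`, `fwd`, `rev`, `ambig`.
#' @export
build_coverage <- function(aln, genome) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (nrow(aln) > 0L) {
    if (!all(aln$chrom %in% names(genome))) {
      stop("alignment refers to a chromosome absent from the genome")
    }
    if (aln[, any(start < 1L | start + read_len - 1L > lens[chrom])]) {
      stop("alignment beyond chromosome end (corrupt input)")
    }
  }
  cnt <- alignment_counts(aln)
  multi_ids <- cnt[multi == TRUE, read_id]
  tracks <- lapply(names(genome), function(chr_nm) {
    L <- lens[[chr_nm]]
    sub <- aln[chrom == chr_nm]
    ends <- sub$start + sub$read_len - 1L
    list(
      total = interval_coverage(L, sub$start, ends),
      fwd = interval_coverage(L, sub$start[sub$strand == "+"],
                              ends[sub$strand == "+"]),
      rev = interval_coverage(L, sub$start[sub$strand == "-"],
                              ends[sub$strand == "-"]),
      ambig = interval_coverage(L, sub$start[sub$read_id %in% multi_ids],
                                ends[sub$read_id %in% multi_ids]))
  })
  names(tracks) <- names(genome)
  structure(list(chroms = tracks, lengths = lens), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", length(x$chroms), " chromosome(s), ",
      sum(x$lengths), " nt\n", sep = "")
  invisible(x)
}

#' Call U and M regions from a coverage track
#'
#' M regions are maximal runs of positions still covered after discarding
#' unique alignments (`ambig >= 1`); U regions are the complementary runs
#' between consecutive M regions. Positions inside reference `N` runs are
#' labeled `undefined`. A U region may be as short as a single nucleotide
#' when it separates two flanking M regions.
#'
#' @param track a `coverage_track` from an exhaustive virtual-read run.
#' @param genome the reference `DNAStringSet` (for `N` positions).
#' @return a `GRanges` with metadata column `label` in `{U, M, undefined}`,
#'   tiling each chromosome.
#' @export
call_m_regions <- function(track, genome) {
  chroms <- as.character(genome)
  grl <- lapply(names(track$chroms), function(nm) {
    L <- track$lengths[[nm]]
    lab <- ifelse(track$chroms[[nm]]$ambig >= 1L, "M", "U")
    npos <- utf8ToInt(chroms[[nm]]) == utf8ToInt("N")
    lab[npos] <- "undefined"
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    GenomicRanges::GRanges(nm,
                           IRanges::IRanges(ends - r$lengths + 1L, ends),
                           label = r$values)
  })
  gr <- suppressWarnings(do.call(c, grl))
  GenomeInfoDb::seqlengths(gr) <- track$lengths[
    GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Profile a genome into U/M regions
#'
#' Convenience chain: generate virtual reads, exhaustively align them back,
#' build coverage, call regions.
#'
#' @inheritParams generate_virtual_reads
#' @param k maximum mismatches per read.
#' @return list with `reads`, `aln`, `track`, `regions`.
#' @export
profile_genome <- function(genome, read_length, k,
                           space = c("base", "color")) {
  space <- match.arg(space)
  reads <- generate_virtual_reads(genome, read_length, space)
  aln <- align_batch(reads, genome, k, space)
  track <- build_coverage(aln, genome)
  regions <- call_m_regions(track, genome)
  list(reads = reads, aln = aln, track = track, regions = regions)
}

#' Read-length / mismatch sweep of M-region extent
#'
#' Re-profiles the genome for every combination of read length and mismatch
#' budget and tabulates the cumulative M length, M-region count, and the
#' fraction of the (non-N) genome covered by M regions.
#'
#' @param genome a `DNAStringSet`.
#' @param read_lengths integer vector of read lengths.
#' @param k_values integer vector of mismatch budgets.
#' @inheritParams generate_virtual_reads
#' @return `data.table` with one row per (read_length, k).
#' @export
sweep_profile <- function(genome, read_lengths, k_values,
                          space = c("base", "color")) {
  space <- match.arg(space)
  non_n <- total_length(genome) -
    sum(Biostrings::vcountPattern("N", genome))
  rows <- list()
  for (r in read_lengths) {
    for (kk in k_values) {
      regions <- profile_genome(genome, r, kk, space)$regions
      m <- regions[regions$label == "M"]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        read_length = r, k = kk,
        m_count = length(m),
        m_length = sum(GenomicRanges::width(m)),
        m_fraction = sum(GenomicRanges::width(m)) / non_n)
    }
  }
  data.table::rbindlist(rows)
}

#' Length statistics of a region set
#'
#' @param regions a labeled `GRanges` (see [call_m_regions()]).
#' @param label which label to summarise (default `"M"`).
#' @return list with `n`, `min`, `max`, `total` and `hist` (a table of
#'   lengths). Empty input yields an empty histogram with `n = 0`.
#' @export
region_length_stats <- function(regions, label = "M") {
  w <- GenomicRanges::width(regions[regions$label == label])
  if (length(w) == 0L) {
    return(list(n = 0L, min = NA_integer_, max = NA_integer_, total = 0L,
                hist = table(integer())))
  }
  list(n = length(w), min = min(w), max = max(w), total = sum(w),
       hist = table(w))
}

#' Windowed coverage correlation between two profiles
#'
#' Tiles each chromosome into non-overlapping windows from position 1
#' (a trailing partial window is kept when at least half the window size),
#' takes the mean total coverage per window, log10-transforms with a
#' pseudocount of 1, and returns the squared Pearson correlation.
#'
#' @param track_a,track_b `coverage_track` objects over the same
#'   chromosomes.
#' @param window window size in nt (default 2000).
#' @return `r^2` as a single number.
#' @export
windowed_coverage_correlation <- function(track_a, track_b, window = 2000) {
  stopifnot(window >= 1)
  if (!identical(names(track_a$chroms), names(track_b$chroms)) ||
      !identical(unname(track_a$lengths), unname(track_b$lengths))) {
    stop("tracks cover different chromosome sets")
  }
  win_means <- function(track) {
    unlist(lapply(names(track$chroms), function(nm) {
      cov <- track$chroms[[nm]]$total
      L <- length(cov)
      starts <- seq.int(1L, L, by = window)
      ends <- pmin(starts + window - 1L, L)
      keep <- (ends - starts + 1L) >= window / 2
      starts <- starts[keep]; ends <- ends[keep]
      cs <- c(0, cumsum(as.numeric(cov)))
      (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
    }))
  }
  a <- win_means(track_a)
  b <- win_means(track_b)
  if (length(a) < 2L) stop("fewer than 2 windows; use a smaller window")
  stats::cor(log10(a + 1), log10(b + 1))^2
}

#' Export labeled regions as BED
#'
#' BED is 0-based half-open; the `name` field carries the label.
#' @param regions labeled `GRanges`.
#' @param path output path.
#' @export
export_regions_bed <- function(regions, path) {
  gr <- regions
  names(S4Vectors::mcols(gr)) <- sub("^label$", "name",
                                     names(S4Vectors::mcols(gr)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export labeled regions as 1-based TSV
#'
#' Columns: chrom, start, end (1-based inclusive), label.
#' @inheritParams export_regions_bed
#' @export
export_regions_tsv <- function(regions, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions),
    label = regions$label)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Export one coverage channel as bedGraph
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @param channel one of `"total"`, `"fwd"`, `"rev"`, `"ambig"`.
#' @export
export_coverage_bedgraph <- function(track, path,
                                     channel = c("total", "fwd", "rev",
                                                 "ambig")) {
  channel <- match.arg(channel)
  grl <- lapply(names(track$chroms), function(nm) {
    v <- track$chroms[[nm]][[channel]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    GenomicRanges::GRanges(nm,
                           IRanges::IRanges(ends - r$lengths + 1L, ends),
                           score = r$values)
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
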
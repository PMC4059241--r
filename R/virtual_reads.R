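#' Generate the exhaustive set of virtual reads
#'
#' Emits one error-free read per genomic position on the forward strand:
#' for an N-free chromosome of length L this is exactly L - r + 1 reads, so
#' the interior of the chromosome is covered r-fold and coverage ramps
#' 1..r at the edges. Windows overlapping an `N` produce no read.
#' Chromosomes shorter than the read length are skipped with a warning.
#'
#' @param genome a `DNAStringSet` (see [load_fasta()]).
#' @param read_length read length in nt (>= 2).
#' @param space `"base"` or `"color"`; with `"color"` an extra `colors`
#'   column carries the dinucleotide color encoding of each read.
#' @return `data.table` with columns `read_id` (`"chrom:start:length"`),
#'   `chrom`, `start` (1-based), `length`, `seq`, and optionally `colors`.
#' @export
generate_virtual_reads <- function(genome, read_length,
                                   space = c("base", "color")) {
  space <- match.arg(space)
  stopifnot(read_length >= 2)
  chroms <- as.character(genome)
  out <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    nm <- names(genome)[i]
    s <- chroms[[i]]
    L <- nchar(s)
    if (read_length > L) {
      warning("chromosome '", nm, "' (", L,
              " nt) shorter than read length ", read_length, "; skipped")
      next
    }
    starts <- seq_len(L - read_length + 1L)
    # drop windows overlapping an N
    npos <- gregexpr("N", s, fixed = TRUE)[[1L]]
    if (npos[1L] != -1L) {
      bad <- unique(unlist(lapply(as.integer(npos), function(p) {
        seq.int(max(1L, p - read_length + 1L), min(p, L - read_length + 1L))
      })))
      starts <- setdiff(starts, bad)
    }
    if (length(starts) == 0L) next
    dt <- data.table::data.table(
      read_id = paste(nm, starts, read_length, sep = ":"),
      chrom = nm, start = starts, length = read_length,
      seq = substring(s, starts, starts + read_length - 1L))
    if (space == "color") {
      cs <- color_string(s)
      dt[, colors := substring(cs, start, start + read_length - 2L)]
    }
    out[[i]] <- dt
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) {
    res <- data.table::data.table(read_id = character(), chrom = character(),
                                  start = integer(), length = integer(),
                                  seq = character())
  }
  data.table::setattr(res, "space", space)
  res[]
}

#' Expected per-position coverage of exhaustive read generation
#'
#' The deterministic coverage track implied by one read per forward-strand
#' position: a ramp 1..r at each chromosome edge and r in the interior
#' (ignoring N gaps). Used as the reference denominator for full-coverage
#' checks against an actual alignment run.
#'
#' @inheritParams generate_virtual_reads
#' @return named list of integer vectors, one per chromosome.
#' @export
coverage_of_generation <- function(genome, read_length) {
  read_length <- as.integer(read_length)
  lens <- Biostrings::width(genome)
  out <- lapply(lens, function(L) {
    if (read_length > L) return(integer(L))
    n_reads <- L - read_length + 1L
    pmin(seq_len(L), read_length, rev(seq_len(L)), n_reads)
  })
  names(out) <- names(genome)
  out
}

#' Export reads to FASTA
#'
#' @param reads a read table (from [generate_virtual_reads()] or
#'   [simulate_reads()]).
#' @param path output FASTA path.
#' @export
export_reads_fasta <- function(reads, path) {
  seqs <- reads$seq
  names(seqs) <- reads$read_id
  write_fasta(seqs, path)
}
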
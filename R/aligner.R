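#' Exhaustively align a batch of reads
#'
#' Reports ALL ungapped placements of each read against the genome, on both
#' strands, with at most `k` mismatches — no cap on the number of hits per
#' read and no best-hit selection. In base space mismatches are base
#' substitutions; in color space the read's dinucleotide color string is
#' compared to the reference color string over the aligned window (the
#' primer base is excluded from counting).
#'
#' Mismatch details are stored window-based: `mm` is `"j:R>Q;..."` where `j`
#' is the 0-based offset within the aligned reference window, `R` the
#' forward-strand reference symbol and `Q` the symbol presented by the read
#' on the forward strand (for `-` alignments this is the complement of the
#' read's own base; use [mismatch_table()] for read-orientation offsets).
#'
#' @param reads a read table (columns `read_id`, `seq`, and `colors` when
#'   `space = "color"`), e.g. from [generate_virtual_reads()] or
#'   [simulate_reads()].
#' @param genome a `DNAStringSet`.
#' @param k maximum number of mismatches (>= 0).
#' @param space `"base"` or `"color"`.
#' @return `data.table` with one row per alignment: `read_id`, `chrom`,
#'   `start` (1-based leftmost reference base of the covered window),
#'   `strand`, `nm`, `mm`, `read_len` (bases covered). Attributes `space`
#'   and `k` record the run. Rows are ordered by input read, then
#'   chromosome, start, strand.
#' @export
align_batch <- function(reads, genome, k, space = c("base", "color")) {
  space <- match.arg(space)
  if (k < 0) stop("k must be >= 0")
  if (length(genome) == 0L || nrow(reads) == 0L) {
    return(empty_alignments(space, k))
  }
  chroms <- as.character(genome)
  cnames <- names(genome)
  if (space == "base") {
    targets <- chroms
    fwd_q <- reads$seq
    rev_q <- reverse_complement(reads$seq)
    base_len <- nchar(reads$seq)
  } else {
    targets <- color_string(chroms)
    fwd_q <- if ("colors" %in% names(reads)) reads$colors else
      color_string(reads$seq)
    # reverse-complementing a sequence reverses its color string
    rev_q <- vapply(fwd_q, function(s) intToUtf8(rev(utf8ToInt(s))), "",
                    USE.NAMES = FALSE)
    base_len <- nchar(fwd_q) + 1L
  }
  hit_f <- data.table::as.data.table(cpp_align_hits(fwd_q, targets, as.integer(k)))
  hit_r <- data.table::as.data.table(cpp_align_hits(rev_q, targets, as.integer(k)))
  hit_f[, strand := "+"]
  hit_r[, strand := "-"]
  hits <- data.table::rbindlist(list(hit_f, hit_r))
  if (nrow(hits) == 0L) return(empty_alignments(space, k))
  aln <- data.table::data.table(
    read_id = reads$read_id[hits$query],
    chrom = cnames[hits$chrom],
    start = hits$start,
    strand = hits$strand,
    nm = hits$nm,
    mm = hits$mm,
    read_len = base_len[hits$query],
    q_idx = hits$query)
  data.table::setorder(aln, q_idx, chrom, start, strand)
  aln[, q_idx := NULL]
  data.table::setattr(aln, "space", space)
  data.table::setattr(aln, "k", k)
  aln[]
}

empty_alignments <- function(space, k) {
  aln <- data.table::data.table(read_id = character(), chrom = character(),
                                start = integer(), strand = character(),
                                nm = integer(), mm = character(),
                                read_len = integer())
  data.table::setattr(aln, "space", space)
  data.table::setattr(aln, "k", k)
  aln
}

#' Exhaustively align a single read
#'
#' @param read a single read sequence (base string), or a one-row read table.
#' @inheritParams align_batch
#' @return as [align_batch()]; the set is empty when nothing places within
#'   `k` mismatches.
#' @export
align_all <- function(read, genome, k, space = c("base", "color")) {
  if (is.character(read)) {
    read <- data.table::data.table(read_id = "read1", seq = toupper(read))
  }
  align_batch(read, genome, k, space)
}

#' Per-read alignment counts
#'
#' A read is multialigned when it has more than one alignment.
#'
#' @param aln an alignment table.
#' @return `data.table` with `read_id`, `n_aln`, `multi` (logical).
#' @export
alignment_counts <- function(aln) {
  n <- aln[, .(n_aln = .N), by = read_id]
  n[, multi := n_aln > 1L]
  n[]
}

#' Expand mismatch strings into a long table
#'
#' One row per mismatch per alignment. `pos` is the 1-based genomic
#' coordinate (base space) or genomic color index (color space) of the
#' mismatch; `ref`/`alt` are the forward-strand reference and presented
#' symbols; `off_read` is the 0-based offset in the read's own orientation.
#'
#' @param aln an alignment table.
#' @export
mismatch_table <- function(aln) {
  space <- attr(aln, "space") %||% "base"
  withmm <- aln[nm > 0L]
  if (nrow(withmm) == 0L) {
    return(data.table::data.table(read_id = character(), chrom = character(),
                                  start = integer(), strand = character(),
                                  pos = integer(), ref = character(),
                                  alt = character(), off_read = integer()))
  }
  parts <- strsplit(withmm$mm, ";", fixed = TRUE)
  idx <- rep(seq_len(nrow(withmm)), lengths(parts))
  flat <- unlist(parts, use.names = FALSE)
  j <- as.integer(sub(":.*", "", flat))
  ref <- substr(sub("^[0-9]+:", "", flat), 1L, 1L)
  alt <- substr(sub("^[0-9]+:.>", "", flat), 1L, 1L)
  wlen <- if (space == "base") withmm$read_len[idx] else
    withmm$read_len[idx] - 1L
  out <- data.table::data.table(
    read_id = withmm$read_id[idx],
    chrom = withmm$chrom[idx],
    start = withmm$start[idx],
    strand = withmm$strand[idx],
    pos = withmm$start[idx] + j,  # window offset -> genomic index
    ref = ref, alt = alt,
    off_read = ifelse(withmm$strand[idx] == "+", j, wlen - 1L - j))
  out[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
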
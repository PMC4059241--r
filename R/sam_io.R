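# Minimal text SAM support for ungapped alignments. Only records with a
# CIGAR of the form "<len>M" are handled; gapped records are skipped and
# counted. SEQ is stored in forward-reference orientation (SAM convention),
# so mismatch recovery is a direct window comparison against the reference.

#' Write alignments as SAM
#'
#' Emits one record per alignment; the first alignment of each read is
#' primary, further ones carry the secondary flag (0x100). `NM` and `MD`
#' tags are written. SEQ is reconstructed from the reference window with the
#' alignment's mismatches applied.
#'
#' @param aln a base-space alignment table (see [align_batch()]).
#' @param genome the `DNAStringSet` the alignments refer to.
#' @param path output path.
#' @export
write_sam <- function(aln, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                     Biostrings::width(genome)), con)
  if (nrow(aln) == 0L) return(invisible(path))
  chroms <- as.character(genome)
  seqs <- substring(chroms[aln$chrom], aln$start,
                    aln$start + aln$read_len - 1L)
  md <- as.character(aln$read_len)
  withmm <- which(aln$nm > 0L)
  for (i in withmm) {
    parts <- strsplit(aln$mm[i], ";", fixed = TRUE)[[1L]]
    j <- as.integer(sub(":.*", "", parts))
    q <- substr(sub("^[0-9]+:.>", "", parts), 1L, 1L)
    refc <- substr(sub("^[0-9]+:", "", parts), 1L, 1L)
    sv <- strsplit(seqs[i], "")[[1L]]
    sv[j + 1L] <- q
    seqs[i] <- paste(sv, collapse = "")
    runs <- diff(c(-1L, j)) - 1L
    md[i] <- paste0(paste0(runs, refc, collapse = ""),
                    aln$read_len[i] - j[length(j)] - 1L)
  }
  flag <- ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(duplicated(aln$read_id), 256L, 0L)
  writeLines(paste(aln$read_id, flag, aln$chrom, aln$start, 255L,
                   paste0(aln$read_len, "M"), "*", 0L, 0L, seqs, "*",
                   paste0("NM:i:", aln$nm), paste0("MD:Z:", md),
                   sep = "\t"), con)
  invisible(path)
}

#' Read ungapped alignments from SAM
#'
#' Gapped records (CIGAR other than `<len>M`) are skipped; the count of
#' skipped records is attached as attribute `n_skipped`. Mismatches are
#' recovered by comparing SEQ against the reference window.
#'
#' @param path SAM file path.
#' @param genome the reference `DNAStringSet`; every alignment's chromosome
#'   must be present.
#' @return a base-space alignment table (see [align_batch()]).
#' @export
read_sam <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    aln <- empty_alignments("base", NA_integer_)
    data.table::setattr(aln, "n_skipped", 0L)
    return(aln)
  }
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(fields) < 10L) stop("malformed SAM: fewer than 10 fields")
  cigar <- fields[[6L]]
  ok <- grepl("^[0-9]+M$", cigar)
  n_skipped <- sum(!ok)
  qname <- fields[[1L]][ok]
  flag <- as.integer(fields[[2L]][ok])
  chrom <- fields[[3L]][ok]
  start <- as.integer(fields[[4L]][ok])
  rlen <- as.integer(sub("M", "", cigar[ok], fixed = TRUE))
  seqp <- toupper(fields[[10L]][ok])
  bad <- !chrom %in% names(genome)
  if (any(bad)) stop("SAM reference '", chrom[bad][1L], "' not in genome")
  if (any(nchar(seqp) != rlen)) stop("SEQ/CIGAR length mismatch")
  chroms <- as.character(genome)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(start < 1L | start + rlen - 1L > lens[chrom])) {
    stop("alignment beyond chromosome end")
  }
  win <- substring(chroms[chrom], start, start + rlen - 1L)
  nm <- integer(length(win))
  mm <- character(length(win))
  diff_idx <- which(win != seqp)
  for (i in diff_idx) {
    wv <- utf8ToInt(win[i])
    qv <- utf8ToInt(seqp[i])
    j <- which(wv != qv) - 1L
    nm[i] <- length(j)
    mm[i] <- paste(sprintf("%d:%s>%s", j,
                           intToUtf8(wv[j + 1L], multiple = TRUE),
                           intToUtf8(qv[j + 1L], multiple = TRUE)),
                   collapse = ";")
  }
  aln <- data.table::data.table(
    read_id = qname, chrom = chrom, start = start,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    nm = nm, mm = mm, read_len = rlen)
  data.table::setattr(aln, "space", "base")
  data.table::setattr(aln, "n_skipped", n_skipped)
  aln[]
}
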
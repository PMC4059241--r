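# Base substitutions presented by an alignment, on forward-reference
# coordinates: for base space this is the mismatch table directly (N-touching
# mismatches excluded); for color space, adjacent color-mismatch pairs are
# decoded to one base substitution via the dibase algebra
# (color = XOR of adjacent 2-bit base codes), and isolated or inconsistent
# color mismatches are left undecoded (they are not SNV evidence).
alignment_substitutions <- function(aln, genome) {
  space <- attr(aln, "space") %||% "base"
  mt <- mismatch_table(aln)
  if (space == "base") {
    return(mt[ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T"),
              .(read_id, chrom, start, strand, pos, ref, alt)])
  }
  if (nrow(mt) == 0L) {
    return(data.table::data.table(read_id = character(), chrom = character(),
                                  start = integer(), strand = character(),
                                  pos = integer(), ref = character(),
                                  alt = character()))
  }
  chroms <- as.character(genome)
  data.table::setorder(mt, read_id, chrom, start, strand, pos)
  out <- mt[, {
    cs <- chroms[[chrom[1L]]]
    cpos <- pos              # genomic color indices, sorted
    qcol <- suppressWarnings(as.integer(alt))
    subs_pos <- integer(0); subs_ref <- character(0); subs_alt <- character(0)
    i <- 1L
    while (i < length(cpos) + 1L) {
      if (i < length(cpos) && cpos[i + 1L] == cpos[i] + 1L &&
          !is.na(qcol[i]) && !is.na(qcol[i + 1L])) {
        p <- cpos[i] + 1L      # base position shared by the two dinucleotides
        b_prev <- .base_code[utf8ToInt(substr(cs, p - 1L, p - 1L))]
        b_here <- .base_code[utf8ToInt(substr(cs, p, p))]
        b_next <- .base_code[utf8ToInt(substr(cs, p + 1L, p + 1L))]
        if (!is.na(b_prev) && !is.na(b_here) && !is.na(b_next)) {
          a1 <- bitwXor(b_prev, qcol[i])
          a2 <- bitwXor(b_next, qcol[i + 1L])
          if (a1 == a2 && a1 != b_here) {
            subs_pos <- c(subs_pos, p)
            subs_ref <- c(subs_ref, .code_base[b_here + 1L])
            subs_alt <- c(subs_alt, .code_base[a1 + 1L])
            i <- i + 2L
            next
          }
        }
      }
      i <- i + 1L              # isolated / inconsistent color mismatch
    }
    list(pos = subs_pos, ref = subs_ref, alt = subs_alt)
  }, by = .(read_id, chrom, start, strand)]
  out[]
}

#' Extract intragenomic SNVs from a virtual exhaustive run
#'
#' Virtual reads are error-free, so any mismatch in a multialignment can
#' only reflect a single-base difference between near-identical repeat
#' copies. Each such mismatch is recorded as an SNV at the aligned genomic
#' position, with the alternative base the cross-aligned read presents on
#' the forward strand; duplicate records are merged with support counts.
#' A mismatch inside a *uniquely* aligned virtual read is impossible
#' (error-free reads always match their origin exactly) and raises an
#' internal-consistency error.
#'
#' @param aln alignment table of a virtual run (see [align_batch()]).
#' @param genome the profiled `DNAStringSet`.
#' @return `data.table` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `support`, keyed for exact matching.
#' @export
extract_intragenomic_snvs <- function(aln, genome) {
  cnt <- alignment_counts(aln)
  uniq_ids <- cnt[multi == FALSE, read_id]
  if (nrow(aln) && aln[read_id %in% uniq_ids, any(nm > 0L)]) {
    stop("internal inconsistency: mismatched unique alignment in a ",
         "virtual (error-free) run")
  }
  multi <- aln[read_id %in% cnt[multi == TRUE, read_id]]
  subs <- alignment_substitutions(multi, genome)
  if (nrow(subs) == 0L) {
    snvs <- data.table::data.table(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   support = integer())
  } else {
    snvs <- subs[, .(support = .N), by = .(chrom, pos, ref, alt)]
    data.table::setorder(snvs, chrom, pos, alt)
  }
  data.table::setkey(snvs, chrom, pos, ref, alt)
  snvs[]
}

#' g-deNoise: discard alignments carrying annotated intragenomic SNVs
#'
#' An alignment is discarded if and only if at least one of its mismatches,
#' expressed as a base substitution on the forward reference, exactly
#' matches an annotated intragenomic SNV on `(chrom, pos, ref, alt)`. A
#' different alternative base at an annotated position is *not* filtered —
#' that is precisely what allows a genuinely acquired third allele to be
#' seen at a polymorphic repeat position. Unique alignment sets pass
#' through unchanged; the filter never grows a set. Applies identically to
#' virtual and experimental alignment tables.
#'
#' @param aln an alignment table (virtual or experimental, base or color
#'   space).
#' @param snvs SNV annotation from [extract_intragenomic_snvs()], built on
#'   the same genome with compatible parameters.
#' @param genome the reference `DNAStringSet`.
#' @return object of class `denoise_result`: list with `kept` and
#'   `discarded` alignment tables and `per_read`
#'   (`read_id`, `n_in`, `n_kept`, `became_unique`). Reads whose
#'   alignments are all discarded have `n_kept == 0` and drop out of
#'   downstream calling.
#' @export
g_denoise <- function(aln, snvs, genome) {
  key <- character(0)
  if (nrow(snvs) > 0L) {
    key <- snvs[, paste(chrom, pos, ref, alt)]
  }
  subs <- alignment_substitutions(aln, genome)
  bad <- subs[paste(chrom, pos, ref, alt) %in% key,
              unique(paste(read_id, chrom, start, strand))]
  aid <- aln[, paste(read_id, chrom, start, strand)]
  drop <- aid %in% bad
  kept <- aln[!drop]
  discarded <- aln[drop]
  for (a in c("space", "k")) {
    data.table::setattr(kept, a, attr(aln, a))
    data.table::setattr(discarded, a, attr(aln, a))
  }
  n_in <- aln[, .(n_in = .N), by = read_id]
  n_kept <- kept[, .(n_kept = .N), by = read_id]
  per_read <- merge(n_in, n_kept, by = "read_id", all.x = TRUE)
  per_read[is.na(n_kept), n_kept := 0L]
  per_read[, became_unique := n_in > 1L & n_kept == 1L]
  structure(list(kept = kept, discarded = discarded, per_read = per_read),
            class = "denoise_result")
}

#' @export
print.denoise_result <- function(x, ...) {
  cat("<denoise_result> kept ", nrow(x$kept), " / discarded ",
      nrow(x$discarded), " alignments; ",
      sum(x$per_read$became_unique), " read(s) became unique\n", sep = "")
  invisible(x)
}

#' Classify M regions into M_U and M_M
#'
#' Runs g-deNoise on the virtual alignment table and re-examines ambiguous
#' coverage: a position inside an M region belongs to `M_U` when no
#' remaining multialignment covers it (its repeat copies are distinguished
#' by internal polymorphisms), and to `M_M` otherwise (copies locally
#' identical). `M_U` and `M_M` exactly tile each M region.
#'
#' @param aln virtual-run alignment table.
#' @param snvs annotation from [extract_intragenomic_snvs()].
#' @param m_regions labeled `GRanges` from [call_m_regions()].
#' @param genome the `DNAStringSet`.
#' @return `GRanges` with `label` in `{M_U, M_M}` tiling the M regions.
#' @export
classify_mu_mm <- function(aln, snvs, m_regions, genome) {
  res <- g_denoise(aln, snvs, genome)
  kept <- res$kept
  cnt <- alignment_counts(kept)
  multi <- kept[read_id %in% cnt[multi == TRUE, read_id]]
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  ambig2 <- lapply(names(genome), function(chr_nm) {
    sub <- multi[chrom == chr_nm]
    interval_coverage(lens[[chr_nm]], sub$start, sub$start + sub$read_len - 1L)
  })
  names(ambig2) <- names(genome)
  m <- m_regions[m_regions$label == "M"]
  grl <- lapply(seq_along(m), function(i) {
    nm <- as.character(GenomicRanges::seqnames(m)[i])
    s <- GenomicRanges::start(m)[i]
    e <- GenomicRanges::end(m)[i]
    lab <- ifelse(ambig2[[nm]][s:e] >= 1L, "M_M", "M_U")
    r <- rle(lab)
    ends <- s - 1L + cumsum(r$lengths)
    GenomicRanges::GRanges(nm,
                           IRanges::IRanges(ends - r$lengths + 1L, ends),
                           label = r$values)
  })
  if (length(grl) == 0L) {
    g <- GenomicRanges::GRanges()
    S4Vectors::mcols(g)$label <- character(0)
    return(g)
  }
  suppressWarnings(do.call(c, grl))
}

#' Write the SNV annotation as a VCF-like TSV
#'
#' Columns: chrom, pos (1-based), ref, alt, support.
#' @param snvs annotation table.
#' @param path output path.
#' @export
write_snv_tsv <- function(snvs, path) {
  data.table::fwrite(snvs, path, sep = "\t")
  invisible(path)
}
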
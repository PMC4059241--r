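# Independent brute-force oracles. These never use the package's seeded
# aligner: hits are found by direct sliding Hamming comparison (per read),
# or for whole-genome virtual profiles by the shift trick (all window pairs
# at a fixed offset compared via one vectorised cumsum), which shares no
# code path with the pigeonhole index.

or_rc <- function(s) {
  chartr("ACGTN", "TGCAN", intToUtf8(rev(utf8ToInt(s))))
}

or_colors <- function(s) {
  code <- rep(NA_integer_, 128L)
  code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
  v <- code[utf8ToInt(s)]
  bitwXor(v[-length(v)], v[-1L])  # NA where an N is involved
}

# all <=k-mismatch ungapped placements of one query string (already in the
# space being searched) over both strands of every chromosome
oracle_hits_one <- function(q, targets, k, revq) {
  qv <- utf8ToInt(q)
  r <- length(qv)
  rv <- utf8ToInt(revq)
  out <- list()
  for (ci in seq_along(targets)) {
    sv <- utf8ToInt(targets[[ci]])
    L <- length(sv)
    if (r > L) next
    for (st in seq_len(L - r + 1L)) {
      win <- sv[st:(st + r - 1L)]
      npl <- sum(win != qv)
      if (npl <= k) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = names(targets)[ci], start = st, strand = "+", nm = npl)
      }
      nmi <- sum(win != rv)
      if (nmi <= k) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = names(targets)[ci], start = st, strand = "-", nm = nmi)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), nm = integer()))
  }
  do.call(rbind, out)
}

# base space: revq = reverse complement; color space: revq = reversed colors
oracle_hits <- function(read_seq, genome, k, space = "base") {
  chroms <- as.character(genome)
  if (space == "base") {
    oracle_hits_one(read_seq, chroms, k, or_rc(read_seq))
  } else {
    cs <- lapply(chroms, function(s) {
      v <- or_colors(s)
      paste(ifelse(is.na(v), "n", v), collapse = "")
    })
    qv <- or_colors(read_seq)
    q <- paste(qv, collapse = "")
    oracle_hits_one(q, cs, k, paste(rev(qv), collapse = ""))
  }
}

# Whole-profile oracle for a single-chromosome genome: for every
# forward-strand window (virtual read) the full list of <=k placements on
# both strands, found by comparing the window vector against shifted copies
# of itself (+) and of its reverse complement (-).
#
# Returns a data.table shaped like the package's alignment tables
# (read start indexes the read) restricted to (start, strand, nm).
oracle_profile_aln <- function(genome, r, k, space = "base") {
  stopifnot(length(genome) == 1L)
  chrom <- names(genome)
  s <- as.character(genome[[1L]])
  if (space == "base") {
    vec <- utf8ToInt(s)
    rvec <- utf8ToInt(or_rc(s))
    w <- r
  } else {
    cv <- or_colors(s)
    vec <- ifelse(is.na(cv), -1L, cv)
    rvec <- rev(vec)
    w <- r - 1L
  }
  Tlen <- length(vec)
  nw <- Tlen - w + 1L
  stopifnot(nw >= 1L)
  ham_pairs <- function(a, b, delta) {
    # windows a[i..i+w-1] vs b[i+delta ..]; returns i with Ham <= k
    lo <- max(1L, 1L - delta)
    hi <- min(Tlen, Tlen - delta) - w + 1L
    if (hi < lo) return(integer(0))
    idx <- lo:(hi + w - 1L)
    neq <- a[idx] != b[idx + delta]
    cs <- c(0L, cumsum(neq))
    i <- lo:hi
    ham <- cs[i - lo + w + 1L] - cs[i - lo + 1L]
    i[ham <= k]
  }
  rows <- vector("list", 4L * nw)
  nrows <- 0L
  add <- function(i, start, strand, nm_v) {
    nrows <<- nrows + 1L
    rows[[nrows]] <<- data.frame(read_start = i, start = start,
                                 strand = strand, nm = nm_v)
  }
  # forward-forward placements (delta = 0 gives the self placements)
  for (delta in 0:(nw - 1L)) {
    i <- ham_pairs(vec, vec, delta)
    if (length(i)) {
      nm_v <- vapply(i, function(ii) {
        sum(vec[ii:(ii + w - 1L)] != vec[(ii + delta):(ii + delta + w - 1L)])
      }, 0L)
      add(i, i + delta, "+", nm_v)
      if (delta > 0L) add(i + delta, i, "+", nm_v)
    }
  }
  # forward window vs reverse-complement windows: window i vs rvec window
  # i2 = i + delta corresponds to a '-' placement at Tlen - i2 - w + 2;
  # the relation is symmetric in (i, placement), both directions recorded
  for (delta in (1L - nw):(nw - 1L)) {
    i <- ham_pairs(vec, rvec, delta)
    if (length(i)) {
      i2 <- i + delta
      j <- Tlen - i2 - w + 2L
      nm_v <- vapply(seq_along(i), function(t) {
        sum(vec[i[t]:(i[t] + w - 1L)] !=
              rvec[i2[t]:(i2[t] + w - 1L)])
      }, 0L)
      add(i, j, "-", nm_v)
      add(j, i, "-", nm_v)
    }
  }
  out <- data.table::rbindlist(rows[seq_len(nrows)])
  out <- unique(out)
  out[, chrom := chrom]
  data.table::setorder(out, read_start, start, strand)
  out[]
}

# oracle U/M intervals from the profile oracle: ambiguous coverage >= 1
oracle_m_intervals <- function(genome, r, k, space = "base") {
  aln <- oracle_profile_aln(genome, r, k, space)
  L <- Biostrings::width(genome)[1L]
  cnt <- aln[, .N, by = read_start]
  multi <- aln[read_start %in% cnt[N > 1L, read_start]]
  cov <- integer(L)
  span <- r
  for (t in seq_len(nrow(multi))) {
    a <- multi$start[t]
    cov[a:(a + span - 1L)] <- cov[a:(a + span - 1L)] + 1L
  }
  rl <- rle(cov >= 1L)
  ends <- cumsum(rl$lengths)
  data.frame(start = (ends - rl$lengths + 1L)[rl$values],
             end = ends[rl$values])
}

# oracle intragenomic SNVs (base space): mismatch positions of every
# cross placement of a multialigned window, presented on the forward strand
oracle_snvs <- function(genome, r, k) {
  aln <- oracle_profile_aln(genome, r, k, "base")
  s <- as.character(genome[[1L]])
  sv <- utf8ToInt(s)
  rvs <- utf8ToInt(or_rc(s))
  L <- length(sv)
  cnt <- aln[, .N, by = read_start]
  multi <- aln[read_start %in% cnt[N > 1L, read_start]]
  recs <- list()
  for (t in seq_len(nrow(multi))) {
    i <- multi$read_start[t]
    st <- multi$start[t]
    if (multi$nm[t] == 0L) next
    win <- sv[st:(st + r - 1L)]
    q <- if (multi$strand[t] == "+") sv[i:(i + r - 1L)] else {
      i2 <- L - i - r + 2L
      rvs[i2:(i2 + r - 1L)]
    }
    mis <- which(win != q)
    recs[[length(recs) + 1L]] <- data.frame(
      pos = as.integer(st + mis - 1L),
      ref = strsplit(intToUtf8(win[mis]), "")[[1L]],
      alt = strsplit(intToUtf8(q[mis]), "")[[1L]])
  }
  if (length(recs) == 0L) {
    return(data.frame(pos = integer(), ref = character(),
                      alt = character(), support = integer()))
  }
  dt <- data.table::rbindlist(recs)
  out <- dt[, .(support = .N), by = .(pos, ref, alt)]
  data.table::setorder(out, pos, alt)
  as.data.frame(out)
}

random_genome <- function(L, seed, gc = 0.5, name = "chr1") {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
             collapse = "")
  g <- Biostrings::DNAStringSet(s)
  names(g) <- name
  g
}

# canonical comparable form of an alignment table / oracle hit frame
hit_key <- function(df) {
  sort(paste(df$chrom, df$start, df$strand, df$nm))
}
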
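# Seeded synthetic fixtures: genomes with planted repeat families (direct or
# inverted copies, with a chosen number of divergent sites) on a repeat-free
# random background, plus simulated error-bearing reads. Everything is
# reproducible from the seed alone.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a planted-repeat fixture genome
#'
#' Builds one chromosome: random background of composition `gc`, with
#' repeat families planted at random non-overlapping positions. Each family
#' has `n_copies` copies of a random `unit_length`-nt unit, per-copy
#' orientation (`"direct"` or `"inverted"` = reverse-complemented), and
#' `divergence` planted single-base differences: for each divergent site a
#' random offset, a random non-first carrier copy and a random alternative
#' base are drawn. The background is self-scanned for repeats at
#' `check_length` (any duplicated window outside the planted copies forces
#' regeneration), so profiling at read lengths >= `check_length` finds M
#' regions only at the planted copies.
#'
#' @param genome_length chromosome length in nt.
#' @param repeat_families list of `list(unit_length, n_copies, orientations,
#'   divergence)`; `orientations` recycles over copies and defaults to
#'   `"direct"`.
#' @param gc background GC fraction (default 0.5, i.e. uniform bases).
#' @param seed integer seed; identical `(spec, seed)` gives byte-identical
#'   genomes.
#' @param check_length window for the background repeat-free self-scan
#'   (default 25).
#' @param min_gap minimum gap between planted copies and to the chromosome
#'   ends (default 150 nt).
#' @param chrom_name chromosome name.
#' @return list with `genome` (`DNAStringSet`) and `truth`: `copies`
#'   (`family, copy, chrom, start, end, orientation`) and `sites` (one row
#'   per divergent site per copy: `family, site, copy, pos, base, offset,
#'   carrier`), where `pos` is the genomic position of the site in that
#'   copy and `base` the base that copy carries there.
#' @export
make_genome <- function(genome_length, repeat_families = list(), gc = 0.5,
                        seed = 1L, check_length = 25L, min_gap = 150L,
                        chrom_name = "chr1") {
  with_seed(seed, {
    for (attempt in seq_len(30L)) {
      res <- try(plant_once(genome_length, repeat_families, gc,
                            check_length, min_gap, chrom_name),
                 silent = TRUE)
      if (!inherits(res, "try-error")) return(res)
      if (grepl("infeasible", attr(res, "condition")$message)) {
        stop(attr(res, "condition")$message)
      }
    }
    stop("could not generate a repeat-free background in 30 attempts; ",
         "reduce genome_length or repeat load")
  })
}

plant_once <- function(genome_length, repeat_families, gc, check_length,
                       min_gap, chrom_name) {
  genome_length <- as.integer(genome_length)
  min_gap <- as.integer(min_gap)
  repeat_families <- lapply(repeat_families, function(f) {
    f$unit_length <- as.integer(f$unit_length)
    f$n_copies <- as.integer(f$n_copies)
    if (!is.null(f$divergence)) f$divergence <- as.integer(f$divergence)
    f
  })
  units <- lapply(repeat_families, function(f) {
    stopifnot(!is.null(f$unit_length), !is.null(f$n_copies))
    random_dna(f$unit_length, gc)
  })
  # per-family divergent sites: offset (1-based within unit), carrier copy,
  # alternative base
  sites <- lapply(seq_along(repeat_families), function(i) {
    f <- repeat_families[[i]]
    d <- f$divergence %||% 0L
    if (d == 0L) return(NULL)
    if (f$n_copies < 2L) stop("divergence requires >= 2 copies")
    offs <- sort(sample.int(f$unit_length, d))
    carrier <- sample(2:f$n_copies, d, replace = TRUE)
    refb <- substring(units[[i]], offs, offs)
    altb <- vapply(refb, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "", USE.NAMES = FALSE)
    data.table::data.table(family = i, site = seq_len(d), offset = offs,
                           carrier = carrier, ref = refb, alt = altb)
  })
  copy_lens <- unlist(lapply(repeat_families, function(f) {
    rep(f$unit_length, f$n_copies)
  }))
  n_copies_total <- length(copy_lens)
  if (sum(copy_lens) + (n_copies_total + 1L) * min_gap > genome_length) {
    stop("infeasible fixture: planted elements do not fit in genome_length")
  }
  # draw non-overlapping starts with the minimum gap, bounded retries
  starts <- integer(0)
  if (n_copies_total > 0L) {
    for (retry in seq_len(200L)) {
      cand <- sort(sample.int(genome_length, n_copies_total))
      ord_len <- copy_lens  # placement in family/copy order after sorting
      ends <- cand + ord_len - 1L
      ok <- all(ends + min_gap <= c(cand[-1L], genome_length + min_gap)) &&
        cand[1L] > min_gap && ends[n_copies_total] + min_gap <= genome_length
      if (ok) {
        starts <- cand
        break
      }
    }
    if (length(starts) == 0L) {
      stop("infeasible fixture: could not place copies with min_gap ",
           min_gap)
    }
  }
  bg <- random_dna(genome_length, gc)
  gchars <- strsplit(bg, "")[[1L]]
  copies <- list()
  site_rows <- list()
  ci <- 0L
  for (i in seq_along(repeat_families)) {
    f <- repeat_families[[i]]
    ors <- rep(f$orientations %||% "direct", length.out = f$n_copies)
    fam_sites <- sites[[i]]
    for (cp in seq_len(f$n_copies)) {
      ci <- ci + 1L
      st <- starts[ci]
      useq <- units[[i]]
      if (!is.null(fam_sites)) {
        mine <- fam_sites[carrier == cp]
        if (nrow(mine) > 0L) {
          uv <- strsplit(useq, "")[[1L]]
          uv[mine$offset] <- mine$alt
          useq <- paste(uv, collapse = "")
        }
      }
      inverted <- ors[cp] == "inverted"
      placed <- if (inverted) reverse_complement(useq) else useq
      gchars[st:(st + f$unit_length - 1L)] <- strsplit(placed, "")[[1L]]
      copies[[ci]] <- data.table::data.table(
        family = i, copy = cp, chrom = chrom_name, start = st,
        end = st + f$unit_length - 1L, orientation = ors[cp])
      if (!is.null(fam_sites)) {
        pos <- if (inverted) st + f$unit_length - fam_sites$offset else
          st + fam_sites$offset - 1L
        base <- ifelse(fam_sites$carrier == cp, fam_sites$alt,
                       fam_sites$ref)
        if (inverted) base <- chartr("ACGT", "TGCA", base)
        site_rows[[length(site_rows) + 1L]] <- data.table::data.table(
          family = i, site = fam_sites$site, copy = cp, pos = pos,
          base = base, offset = fam_sites$offset,
          carrier = fam_sites$carrier)
      }
    }
  }
  gseq <- paste(gchars, collapse = "")
  # self-scan: windows outside planted copies must be unique genome-wide
  # (both strands) at check_length
  if (genome_length >= check_length) {
    wstarts <- seq_len(genome_length - check_length + 1L)
    wins <- substring(gseq, wstarts, wstarts + check_length - 1L)
    rwins <- vapply(wins, function(w) reverse_complement(w), "",
                    USE.NAMES = FALSE)
    canon <- pmin(wins, rwins)
    dup <- canon %in% canon[duplicated(canon)]
    if (any(dup)) {
      in_copy <- rep(FALSE, length(wstarts))
      for (co in copies) {
        a <- max(1L, co$start - check_length + 1L)
        b <- min(length(wstarts), co$end)
        in_copy[a:b] <- TRUE
      }
      if (any(dup & !in_copy)) stop("background repeat collision; retry")
    }
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(gseq, chrom_name))
  truth <- list(
    copies = if (length(copies)) data.table::rbindlist(copies) else
      data.table::data.table(family = integer(), copy = integer(),
                             chrom = character(), start = integer(),
                             end = integer(), orientation = character()),
    sites = if (length(site_rows)) data.table::rbindlist(site_rows) else
      data.table::data.table(family = integer(), site = integer(),
                             copy = integer(), pos = integer(),
                             base = character(), offset = integer(),
                             carrier = integer()))
  list(genome = genome, truth = truth)
}

#' Apply point mutations to a genome
#'
#' Used to derive a sample genome carrying acquired SNPs from the reference.
#'
#' @param genome a `DNAStringSet`.
#' @param mutations `data.table`/data.frame with `chrom`, `pos`, `alt`.
#' @export
apply_mutations <- function(genome, mutations) {
  chroms <- as.character(genome)
  for (i in seq_len(nrow(mutations))) {
    ch <- mutations$chrom[i]
    p <- mutations$pos[i]
    substr(chroms[[ch]], p, p) <- mutations$alt[i]
  }
  out <- Biostrings::DNAStringSet(chroms)
  names(out) <- names(genome)
  out
}

#' Simulate single-end sequencing reads
#'
#' Read start positions are uniform over each chromosome, strand uniform;
#' substitution errors are i.i.d. per base at `error_rate`. Deterministic
#' for a fixed seed. Read ids encode the true origin as
#' `"chrom:start:strand:length:i"`.
#'
#' @param genome sample genome (`DNAStringSet`), e.g. after
#'   [apply_mutations()].
#' @param read_length read length in nt.
#' @param depth target fold-coverage (reads total both strands).
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return `data.table` with `read_id`, `chrom`, `start`, `strand`,
#'   `length`, `seq` (read orientation).
#' @export
simulate_reads <- function(genome, read_length, depth, error_rate = 0,
                           seed = 1L) {
  stopifnot(depth > 0, error_rate >= 0, error_rate < 1)
  with_seed(seed, {
    lens <- Biostrings::width(genome)
    chroms <- as.character(genome)
    n_reads <- round(depth * sum(lens) / read_length)
    ci <- sample.int(length(genome), n_reads, replace = TRUE,
                     prob = lens / sum(lens))
    starts <- vapply(ci, function(i) {
      sample.int(lens[i] - read_length + 1L, 1L)
    }, 1L)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(chroms[ci], starts, starts + read_length - 1L)
    neg <- strands == "-"
    if (any(neg)) seqs[neg] <- reverse_complement(seqs[neg])
    if (error_rate > 0) {
      mat <- matrix(utf8ToInt(paste(seqs, collapse = "")),
                    nrow = read_length)
      err <- which(stats::runif(length(mat)) < error_rate)
      if (length(err)) {
        bases <- utf8ToInt("ACGT")
        for (e in err) {
          mat[e] <- sample(setdiff(bases, mat[e]), 1L)
        }
        seqs <- vapply(seq_len(n_reads), function(i) {
          intToUtf8(mat[, i])
        }, "", USE.NAMES = FALSE)
      }
    }
    data.table::data.table(
      read_id = paste(names(genome)[ci], starts, strands, read_length,
                      seq_len(n_reads), sep = ":"),
      chrom = names(genome)[ci], start = starts, strand = strands,
      length = read_length, seq = seqs)
  })
}
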
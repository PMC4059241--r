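# a fixture with two direct repeat copies differing at planted sites, plus
# the genomic positions at which the divergence is visible in each copy
diverged_fixture <- function(seed, divergence, unit = 150L, L = 1800L,
                             orientations = "direct") {
  make_genome(L, list(list(unit_length = unit, n_copies = 2,
                           orientations = orientations,
                           divergence = divergence)), seed = seed)
}

test_that("identical repeat copies yield an empty SNV annotation", {
  fx <- diverged_fixture(61, divergence = 0)
  prof <- profile_genome(fx$genome, 40, 0)
  snvs <- extract_intragenomic_snvs(prof$aln, fx$genome)
  expect_identical(nrow(snvs), 0L)
})

test_that("planted divergent sites are annotated in both copies", {
  fx <- diverged_fixture(62, divergence = 1)
  prof <- profile_genome(fx$genome, 50, 1)
  snvs <- extract_intragenomic_snvs(prof$aln, fx$genome)
  planted <- planted_snv_records(fx$truth)
  # the single A<->B site appears as two directed records, one per copy
  for (i in seq_len(nrow(planted))) {
    hit <- snvs[pos == planted$pos[i] & ref == planted$ref[i] &
                  alt == planted$alt[i]]
    expect_identical(nrow(hit), 1L)
    expect_gt(hit$support, 0L)
  }
})

test_that("SNV annotation equals the brute-force oracle", {
  for (args in list(list(seed = 63, d = 3), list(seed = 64, d = 5))) {
    fx <- diverged_fixture(args$seed, divergence = args$d)
    prof <- profile_genome(fx$genome, 50, args$d)
    snvs <- extract_intragenomic_snvs(prof$aln, fx$genome)
    orc <- oracle_snvs(fx$genome, 50, args$d)
    expect_identical(as.data.frame(snvs[, .(pos, ref, alt, support)]),
                     orc)
    # all planted site positions are among the annotated SNVs
    planted <- planted_snv_records(fx$truth)
    expect_true(all(planted$pos %in% snvs$pos))
  }
})

test_that("SNV positions always fall inside M regions", {
  fx <- diverged_fixture(65, divergence = 2)
  prof <- profile_genome(fx$genome, 40, 2)
  snvs <- extract_intragenomic_snvs(prof$aln, fx$genome)
  m <- prof$regions[prof$regions$label == "M"]
  expect_gt(nrow(snvs), 0L)
  expect_true(all(pos_in_regions(snvs$chrom, snvs$pos, m)))
})

test_that("a mismatched unique alignment in a virtual run is an error", {
  g <- random_genome(300, seed = 66)
  aln <- data.table::data.table(
    read_id = "chr1:10:20", chrom = "chr1", start = 10L, strand = "+",
    nm = 1L, mm = "3:A>G", read_len = 20L)
  data.table::setattr(aln, "space", "base")
  expect_error(extract_intragenomic_snvs(aln, g), "internal inconsistency")
})

test_that("g-deNoise resolves the two-copy cross-alignment scenario", {
  fx <- diverged_fixture(67, divergence = 1)
  g <- fx$genome
  prof <- profile_genome(g, 50, 1)
  snvs <- extract_intragenomic_snvs(prof$aln, g)
  site_pos <- fx$truth$sites$pos
  # reads spanning a divergent site: one perfect origin alignment plus one
  # SNV-bearing cross alignment
  cnt <- alignment_counts(prof$aln)
  spanning <- prof$aln[nm == 0L & strand == "+" &
                         start <= site_pos[1L] &
                         start + read_len - 1L >= site_pos[1L] &
                         read_id %in% cnt[n_aln == 2L, read_id]]
  expect_gt(nrow(spanning), 0L)
  sub <- prof$aln[read_id %in% spanning$read_id]
  res <- g_denoise(sub, snvs, g)
  pr <- res$per_read[read_id %in% spanning$read_id]
  expect_true(all(pr$became_unique))
  # each read's surviving alignment is its true origin, mismatch-free
  expect_true(all(res$kept$nm == 0L))
  expect_identical(res$kept[, paste(chrom, start)],
                   sub[nm == 0L & strand == "+", paste(chrom, start)])
})

test_that("g-deNoise leaves unique reads untouched and never grows a set", {
  fx <- diverged_fixture(68, divergence = 2)
  prof <- profile_genome(fx$genome, 40, 2)
  snvs <- extract_intragenomic_snvs(prof$aln, fx$genome)
  res <- g_denoise(prof$aln, snvs, fx$genome)
  expect_true(all(res$per_read$n_kept <= res$per_read$n_in))
  expect_true(all(res$per_read[n_in == 1L, n_kept == 1L]))
  expect_true(all(res$per_read[n_in == 1L, became_unique] == FALSE))
  # virtual-run soundness: no origin alignment is ever discarded
  origin <- prof$aln[nm == 0L & strand == "+"]
  origin <- origin[paste("chr1", start, 40, sep = ":") == read_id]
  expect_true(all(origin[, paste(read_id, chrom, start, strand)] %in%
                    res$kept[, paste(read_id, chrom, start, strand)]))
})

test_that("a novel allele at an annotated position is not filtered", {
  # annotation says ref A -> alt G at pos 50; an alignment presenting T
  # there must be kept (third-allele detection)
  g <- random_genome(200, seed = 69)
  s <- as.character(g[[1L]])
  refb <- substr(s, 50, 50)
  others <- setdiff(c("A", "C", "G", "T"), refb)
  snvs <- data.table::data.table(chrom = "chr1", pos = 50L, ref = refb,
                                 alt = others[1L], support = 5L)
  aln <- data.table::data.table(
    read_id = c("x", "x", "y"), chrom = "chr1", start = c(31L, 101L, 31L),
    strand = "+", nm = c(1L, 0L, 1L),
    mm = c(paste0("19:", refb, ">", others[1L]), "",
           paste0("19:", refb, ">", others[2L])),
    read_len = 30L)
  data.table::setattr(aln, "space", "base")
  res <- g_denoise(aln, snvs, g)
  expect_identical(res$discarded$read_id, "x")    # annotated alt: dropped
  expect_true("y" %in% res$kept$read_id)          # novel alt: kept
  expect_identical(res$per_read[read_id == "x", n_kept], 1L)
})

test_that("M_U/M_M classification matches the oracle and conserves length", {
  fx <- diverged_fixture(70, divergence = 2)
  g <- fx$genome
  prof <- profile_genome(g, 40, 2)
  snvs <- extract_intragenomic_snvs(prof$aln, g)
  mu_mm <- classify_mu_mm(prof$aln, snvs, prof$regions, g)
  m_len <- sum(GenomicRanges::width(prof$regions[prof$regions$label == "M"]))
  expect_identical(sum(GenomicRanges::width(mu_mm)), m_len)
  expect_setequal(unique(mu_mm$label), c("M_U", "M_M"))

  # oracle: after filtering, only mismatch-free placements survive, so M_M
  # is the ambiguous coverage of reads with >= 2 exact placements
  orc <- oracle_profile_aln(g, 40, 2)
  ex <- orc[nm == 0L]
  cnt0 <- ex[, .N, by = read_start]
  multi0 <- ex[read_start %in% cnt0[N > 1L, read_start]]
  cov <- integer(Biostrings::width(g)[1L])
  for (t in seq_len(nrow(multi0))) {
    idx <- multi0$start[t]:(multi0$start[t] + 39L)
    cov[idx] <- cov[idx] + 1L
  }
  mm_pos_oracle <- which(cov >= 1L)
  mm <- mu_mm[mu_mm$label == "M_M"]
  mm_pos <- unlist(Map(seq.int, GenomicRanges::start(mm),
                       GenomicRanges::end(mm)))
  expect_identical(sort(unname(mm_pos)), mm_pos_oracle)
})

test_that("identical copies give an all-M_M region", {
  fx <- diverged_fixture(71, divergence = 0)
  prof <- profile_genome(fx$genome, 40, 0)
  snvs <- extract_intragenomic_snvs(prof$aln, fx$genome)
  mu_mm <- classify_mu_mm(prof$aln, snvs, prof$regions, fx$genome)
  expect_true(all(mu_mm$label == "M_M"))
})

test_that("color-space runs decode paired color mismatches to base SNVs", {
  fx <- diverged_fixture(72, divergence = 1)
  g <- fx$genome
  prof <- profile_genome(g, 50, 2, space = "color")
  snvs <- extract_intragenomic_snvs(prof$aln, g)
  planted <- planted_snv_records(fx$truth)
  for (i in seq_len(nrow(planted))) {
    hit <- snvs[pos == planted$pos[i] & ref == planted$ref[i] &
                  alt == planted$alt[i]]
    expect_identical(nrow(hit), 1L)
  }
  # filtering a color-space run still rescues site-spanning reads
  res <- g_denoise(prof$aln, snvs, g)
  expect_gt(sum(res$per_read$became_unique), 0L)
})

test_that("inverted repeats are annotated through the reverse strand", {
  fx <- diverged_fixture(73, divergence = 2,
                         orientations = c("direct", "inverted"))
  g <- fx$genome
  prof <- profile_genome(g, 40, 2)
  expect_true(any(prof$aln$strand == "-"))
  snvs <- extract_intragenomic_snvs(prof$aln, g)
  planted <- planted_snv_records(fx$truth)
  expect_true(all(planted$pos %in% snvs$pos))
  orc <- oracle_snvs(g, 40, 2)
  expect_identical(as.data.frame(snvs[, .(pos, ref, alt, support)]), orc)
})
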
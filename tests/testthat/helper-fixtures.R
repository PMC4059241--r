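# expected SNV records implied by the planted truth: at each copy's site
# position the cross-aligned read presents the *other* copy's unit-frame
# base, re-expressed in this copy's orientation
planted_snv_records <- function(truth) {
  st <- data.table::as.data.table(truth$sites)
  cp <- truth$copies
  ors <- stats::setNames(cp$orientation, paste(cp$family, cp$copy))
  cmp <- function(b, invert) {
    ifelse(invert, chartr("ACGT", "TGCA", b), b)
  }
  recs <- list()
  for (fam in unique(st$family)) {
    for (s in unique(st[family == fam, site])) {
      rows <- st[family == fam & site == s]
      stopifnot(nrow(rows) == 2L)
      inv <- unname(ors[paste(fam, rows$copy)] == "inverted")
      unit_frame <- cmp(rows$base, inv)
      alt <- c(cmp(unit_frame[2L], inv[1L]), cmp(unit_frame[1L], inv[2L]))
      keep <- rows$base != alt
      recs[[length(recs) + 1L]] <- data.frame(
        pos = rows$pos[keep], ref = rows$base[keep], alt = alt[keep])
    }
  }
  do.call(rbind, recs)
}
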
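#' @useDynLib gdenoise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom methods is
NULL

# quiet R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", ".N", ".SD", "read_id", "chrom", "start", "strand", "nm", "mm",
  "n_aln", "pos", "ref", "alt", "alt_fwd", "alt_rev", "n_starts", "label",
  "read_len", "J", "end", "width", "fwd", "rev_", "total", "coverage",
  "fraction", "status", "n_samples", "sample_id", "support", "copy",
  "family", "orientation", "offset", "seq_", "m_length", "k"
))

#' Load a reference genome from FASTA
#'
#' Reads a (possibly line-wrapped, multi-record) FASTA file into a
#' `DNAStringSet`. Sequences are upper-cased; only the characters
#' `A`, `C`, `G`, `T`, `N` are accepted. Record names are taken as the first
#' whitespace-delimited word of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per chromosome.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(raw) == 0L) {
    stop("malformed FASTA '", path, "': no sequence records", call. = FALSE)
  }
  nms <- sub("\\s.*$", "", names(raw))
  if (anyNA(nms) || any(nms == "")) {
    stop("malformed FASTA '", path, "': empty record name", call. = FALSE)
  }
  if (anyDuplicated(nms)) {
    stop("duplicate chromosome name: ", nms[duplicated(nms)][1L])
  }
  seqs <- toupper(as.character(raw))
  bad <- gsub("[ACGTN]", "", seqs)
  if (any(nchar(bad) > 0L)) {
    i <- which(nchar(bad) > 0L)[1L]
    stop("invalid character '", substr(bad[i], 1L, 1L),
         "' in record '", nms[i], "'")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- nms
  genome
}

#' Write a genome or read set to FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Total genome length in nucleotides
#' @param genome a `DNAStringSet`.
#' @export
total_length <- function(genome) sum(Biostrings::width(genome))

#' Reverse-complement of a DNA string
#'
#' Vectorised over a character vector; `N` maps to `N`. Involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param seq character vector over `{A,C,G,T,N}`.
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "",
         USE.NAMES = FALSE)
}

# 2-bit base codes; SOLiD color = XOR of adjacent base codes, which realises
# the standard dibase matrix (identical pairs -> 0; {AC,CA,GT,TG} -> 1;
# {AG,GA,CT,TC} -> 2; {AT,TA,CG,GC} -> 3).
.base_code <- local({
  v <- rep(NA_integer_, 128L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("T")] <- 3L
  v
})

.code_base <- c("A", "C", "G", "T")

#' Encode a base sequence in SOLiD dinucleotide color space
#'
#' A sequence of length L yields the first base as primer plus L-1 color
#' digits, each determined by one adjacent base pair. A single internal base
#' substitution changes exactly the two colors flanking the substituted
#' base, which is why a color-space mismatch budget is not equivalent to the
#' same base-space budget.
#'
#' @param seq a single string over `{A,C,G,T}`, length >= 2, no `N`.
#' @return object of class `color_seq`: list with `primer` (first base) and
#'   `colors` (string over `{0,1,2,3}`); printed as e.g. `"A313"`.
#' @export
encode_colorspace <- function(seq) {
  codes <- .base_code[utf8ToInt(seq)]
  if (length(codes) < 2L) stop("sequence must have length >= 2")
  if (anyNA(codes)) stop("sequence contains a non-ACGT character (N?)")
  cols <- bitwXor(codes[-length(codes)], codes[-1L])
  structure(list(primer = substr(seq, 1L, 1L),
                 colors = paste(cols, collapse = "")),
            class = "color_seq")
}

#' Decode a SOLiD color-space sequence back to bases
#'
#' Exact inverse of [encode_colorspace()] for N-free input.
#'
#' @param x a `color_seq`, or a string like `"A313"` (primer base followed
#'   by color digits).
#' @export
decode_colorspace <- function(x) {
  if (is.character(x)) {
    x <- structure(list(primer = substr(x, 1L, 1L),
                        colors = substr(x, 2L, nchar(x))),
                   class = "color_seq")
  }
  b <- .base_code[utf8ToInt(x$primer)]
  if (is.na(b)) stop("invalid primer base")
  cols <- as.integer(strsplit(x$colors, "")[[1L]])
  out <- integer(length(cols) + 1L)
  out[1L] <- b
  for (i in seq_along(cols)) out[i + 1L] <- bitwXor(out[i], cols[i])
  paste(.code_base[out + 1L], collapse = "")
}

#' @export
as.character.color_seq <- function(x, ...) paste0(x$primer, x$colors)

#' @export
print.color_seq <- function(x, ...) {
  cat("<color_seq> ", as.character(x), "\n", sep = "")
  invisible(x)
}

# Color string (no primer) of an arbitrary reference sequence; any color
# whose dinucleotide touches an N becomes 'n', which never matches a read
# color. Vectorised over input strings; returns strings of length L-1.
color_string <- function(seq) {
  vapply(seq, function(s) {
    codes <- .base_code[utf8ToInt(s)]
    L <- length(codes)
    if (L < 2L) return("")
    cols <- bitwXor(codes[-L], codes[-1L])
    out <- ifelse(is.na(cols), "n", as.character(cols))
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}
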
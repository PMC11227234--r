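## Low-level sequence and interval helpers shared across modules.
## Coordinates are 0-based half-open internally; all user-facing reports are
## 1-based inclusive (GenBank convention).

IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V")

#' Reverse complement of a DNA string
#'
#' @param x character scalar (IUPAC DNA).
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @keywords internal
complement_dna <- function(x) {
  chartr("ACGTNRYSWKMBDHVacgtnryswkmbdhv",
         "TGCANYRSWMKVHDBtgcanyrswmkvhdb", x)
}

#' @keywords internal
reverse_chars <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                              collapse = ""), character(1), USE.NAMES = FALSE)
}

## Sequence as integer vector (ASCII codes) for fast vectorised comparison.
#' @keywords internal
seq_ints <- function(x) as.integer(charToRaw(x))

#' @keywords internal
ints_seq <- function(v) rawToChar(as.raw(v))

.COMP_MAP <- local({
  m <- integer(256)
  from <- utf8ToInt("ACGTN")
  to <- utf8ToInt("TGCAN")
  m[from] <- to
  m
})

## Complement on integer-coded sequence (ACGTN only; other codes map to 0).
#' @keywords internal
comp_ints <- function(v) .COMP_MAP[v]

#' @keywords internal
is_acgt <- function(v) v == 65L | v == 67L | v == 71L | v == 84L

#' Extract a subsequence, 0-based half-open
#' @keywords internal
subseq0 <- function(seq, start, end) substr(seq, start + 1L, end)

## Genetic code (plastid/bacterial, translation table 11; codon -> amino acid)
#' @keywords internal
genetic_code <- function() Biostrings::getGeneticCode("11")

#' Translate an in-frame DNA string (table 11); ambiguous codons become X
#' @keywords internal
translate_cds <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  gc <- genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Split an in-frame CDS into codons
#' @keywords internal
split_codons <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return(character(0))
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Write a data frame as a TSV report
#'
#' Plain `write.table` wrapper used for all tabular reports (no quoting, no
#' row names, tab separated).
#'
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as a BED file (0-based half-open)
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name` and `score`.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Position -> region lookup on a (possibly origin-wrapping) interval table.
## `tab` has columns region/start/end, 0-based half-open; a row with
## start >= end wraps the origin.
#' @keywords internal
region_of_positions <- function(pos, tab, genome_len) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(tab))) {
    s <- tab$start[i]; e <- tab$end[i]
    hit <- if (s < e) pos >= s & pos < e else pos >= s | pos < e
    out[hit] <- tab$region[i]
  }
  out
}

#' @keywords internal
interval_len <- function(start, end, genome_len) {
  ifelse(start < end, end - start, genome_len - start + end)
}
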
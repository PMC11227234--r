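## Genome and annotation model.
##
## A `plastome` is a list(id, sequence, circular, length); features are rows
## of a data frame with a list-column of interval tables.  Internally all
## intervals are 0-based half-open, possibly wrapping the origin on circular
## genomes (start >= end means the interval runs through position 0).

#' Construct a genome object
#'
#' @param id text label.
#' @param sequence IUPAC DNA string (upper-cased on construction).
#' @param circular logical; plastomes are circular molecules.
#' @return An object of class `plastome`.
#' @export
genome <- function(id, sequence, circular = TRUE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence for genome '", id, "'")
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]), IUPAC_DNA)
  if (length(bad))
    stop("non-IUPAC characters in genome '", id, "': ",
         paste(bad, collapse = ","))
  structure(list(id = id, sequence = sequence, circular = circular,
                 length = nchar(sequence)),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat("<plastome> ", x$id, ": ", format(x$length, big.mark = ","), " bp",
      if (x$circular) " (circular)" else "", "\n", sep = "")
  invisible(x)
}

#' Construct a genome feature
#'
#' @param key one of gene, CDS, tRNA, rRNA, intron, misc.
#' @param name gene symbol.
#' @param intervals data.frame with columns `start`, `end` (0-based
#'   half-open), in transcription order along the genome forward strand.
#' @param strand "+" or "-".
#' @param pseudo logical; pseudogene or pseudogene fragment.
#' @return one-row feature data.frame with a list-column of intervals.
#' @export
feature <- function(key, name, intervals, strand = "+", pseudo = FALSE) {
  key <- match.arg(key, c("gene", "CDS", "tRNA", "rRNA", "intron", "misc"))
  stopifnot(is.data.frame(intervals), all(c("start", "end") %in% names(intervals)))
  data.frame(key = key, name = name, strand = strand, pseudo = pseudo,
             intervals = I(list(intervals[, c("start", "end")])),
             stringsAsFactors = FALSE)
}

#' Bundle a genome with its features
#'
#' @param genome a `plastome`.
#' @param features data.frame of features (rbind of [feature()] rows).
#' @return An object of class `annotated_plastome`.
#' @export
annotated_genome <- function(genome, features) {
  stopifnot(inherits(genome, "plastome"))
  if (is.null(features) || nrow(features) == 0L)
    features <- feature("misc", "none", data.frame(start = 0L, end = 1L))[0, ]
  for (i in seq_len(nrow(features))) {
    iv <- features$intervals[[i]]
    if (any(iv$start < 0L) || any(iv$start >= genome$length) ||
        any(iv$end > genome$length) || any(iv$end < 0L))
      stop("feature '", features$name[i], "' has intervals outside [0, ",
           genome$length, ")")
  }
  structure(list(genome = genome, features = features),
            class = "annotated_plastome")
}

#' @export
print.annotated_plastome <- function(x, ...) {
  cat("<annotated_plastome> ", x$genome$id, ": ",
      format(x$genome$length, big.mark = ","), " bp, ",
      nrow(x$features), " features\n", sep = "")
  invisible(x)
}

#' Gene counts with and without IR-copy deduplication
#'
#' Plastome gene totals are conventionally reported counting both IR copies
#' and pseudogenes; a deduplicated count (unique gene symbols per key) is
#' also returned.
#'
#' @param g an `annotated_plastome`.
#' @return list with `total` (all annotated gene/CDS/tRNA/rRNA features,
#'   IR duplicates and pseudogenes included) and `unique` (distinct symbols).
#' @export
gene_counts <- function(g) {
  f <- g$features[g$features$key %in% c("gene", "CDS", "tRNA", "rRNA"), ]
  gn <- f[f$key == "gene" | !(f$name %in% f$name[f$key == "gene"]), ]
  list(total = nrow(gn), unique = length(unique(gn$name)))
}

## --- FASTA ------------------------------------------------------------------

#' Read genomes from a FASTA file
#'
#' @param path FASTA file.
#' @param circular mark genomes circular (default TRUE).
#' @return list of `plastome` objects; ids are the first whitespace-delimited
#'   header tokens.
#' @export
read_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  out <- lapply(seq_along(ss),
                function(i) genome(ids[i], as.character(ss[[i]]), circular))
  names(out) <- ids
  out
}

#' Write genomes (or named sequences) to FASTA
#'
#' @param x list of `plastome` objects, or a named character vector.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  if (is.list(x) && length(x) && inherits(x[[1]], "plastome")) {
    seqs <- vapply(x, function(g) g$sequence, character(1))
    names(seqs) <- vapply(x, function(g) g$id, character(1))
  } else {
    seqs <- x
  }
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

## --- Splicing and CDS extraction -------------------------------------------

#' @keywords internal
extract_interval <- function(seq, start, end, genome_len) {
  if (start < end) subseq0(seq, start, end)
  else paste0(subseq0(seq, start, genome_len), subseq0(seq, 0L, end))
}

#' Spliced, strand-resolved sequence of a feature
#'
#' Intervals are concatenated in genome order and reverse-complemented as a
#' whole for minus-strand features (the GenBank `complement(join(...))`
#' convention).
#'
#' @param g an `annotated_plastome`.
#' @param feat one row of `g$features`.
#' @return character scalar.
#' @export
splice_feature <- function(g, feat) {
  iv <- feat$intervals[[1]]
  parts <- vapply(seq_len(nrow(iv)), function(i)
    extract_interval(g$genome$sequence, iv$start[i], iv$end[i],
                     g$genome$length), character(1))
  s <- paste(parts, collapse = "")
  if (feat$strand == "-") revcomp(s) else s
}

#' Extract screened coding sequences
#'
#' Returns the spliced, strand-resolved CDS that pass the usage-bias
#' screening filters: length strictly greater than `min_len`, start codon
#' `require_start`, non-pseudo (optionally), length divisible by three.
#' Genes duplicated by the inverted repeat are deduplicated by
#' (symbol, sequence) identity.
#'
#' @param g an `annotated_plastome`.
#' @param min_len minimum length in bp (exclusive; default 300).
#' @param require_start required start codon, or NULL to skip (default "ATG").
#' @param drop_pseudo drop pseudogenes (default TRUE).
#' @return data.frame with columns `gene`, `genome_id`, `nt`.
#' @export
extract_cds <- function(g, min_len = 300L, require_start = "ATG",
                        drop_pseudo = TRUE) {
  f <- g$features[g$features$key == "CDS", , drop = FALSE]
  out <- list()
  seen <- character(0)
  for (i in seq_len(nrow(f))) {
    if (drop_pseudo && isTRUE(f$pseudo[i])) next
    nt <- splice_feature(g, f[i, ])
    if (nchar(nt) %% 3L != 0L && !isTRUE(f$pseudo[i])) {
      warning("CDS '", f$name[i], "' length ", nchar(nt),
              " not divisible by 3; excluded")
      next
    }
    if (nchar(nt) <= min_len) next
    if (!is.null(require_start) && substr(nt, 1L, 3L) != require_start) next
    key <- paste0(f$name[i], "\r", nt)
    if (key %in% seen) next   # IR-duplicated copy
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- data.frame(gene = f$name[i],
                                          genome_id = g$genome$id, nt = nt,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene = character(0), genome_id = character(0),
                      nt = character(0)))
  do.call(rbind, out)
}

## --- Feature context --------------------------------------------------------

#' @keywords internal
pos_in_intervals <- function(pos, iv, genome_len) {
  any(ifelse(iv$start < iv$end,
             pos >= iv$start & pos < iv$end,
             pos >= iv$start | pos < iv$end))
}

#' Feature context of a reference position
#'
#' Classifies a position as `exon` (inside a CDS interval), `intron`
#' (inside an annotated intron, or between two intervals of a spliced
#' feature), `RNA-gene` (inside a tRNA/rRNA span) or `intergenic`, with
#' precedence exon > intron > RNA-gene > intergenic.
#'
#' @param g an `annotated_plastome`.
#' @param pos 0-based position (vectorised).
#' @return character vector of contexts.
#' @export
feature_context <- function(g, pos) {
  if (any(pos < 0L | pos >= g$genome$length))
    stop("position out of range [0, ", g$genome$length, ")")
  f <- g$features
  L <- g$genome$length
  key_ivs <- function(keys) {
    rows <- which(f$key %in% keys)
    if (!length(rows)) return(NULL)
    do.call(rbind, f$intervals[rows])
  }
  span_gaps <- function(keys) {
    ## gaps between consecutive intervals of multi-interval features
    rows <- which(f$key %in% keys & !f$pseudo)
    gaps <- list()
    for (r in rows) {
      iv <- f$intervals[[r]]
      if (nrow(iv) < 2L) next
      for (j in seq_len(nrow(iv) - 1L))
        gaps[[length(gaps) + 1L]] <- data.frame(start = iv$end[j],
                                                end = iv$start[j + 1L])
    }
    if (!length(gaps)) NULL else do.call(rbind, gaps)
  }
  exon_iv <- key_ivs("CDS")
  intron_iv <- rbind(key_ivs("intron"), span_gaps(c("CDS", "tRNA", "rRNA")))
  rna_iv <- key_ivs(c("tRNA", "rRNA"))
  in_any <- function(p, iv) {
    if (is.null(iv) || nrow(iv) == 0L) return(FALSE)
    pos_in_intervals(p, iv, L)
  }
  vapply(pos, function(p) {
    if (in_any(p, exon_iv)) "exon"
    else if (in_any(p, intron_iv)) "intron"
    else if (in_any(p, rna_iv)) "RNA-gene"
    else "intergenic"
  }, character(1))
}
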
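## GenBank flat-file reading and writing.
##
## Only the subset needed for annotated plastomes is supported: LOCUS,
## FEATURES (gene/CDS/tRNA/rRNA/intron features with join/complement
## locations, /gene and /pseudo qualifiers) and ORIGIN.  Locations are
## converted to 0-based half-open intervals; a join(n..L, 1..m) pair on a
## circular genome is merged into a single origin-wrapping interval.

.GB_KEYS <- c(gene = "gene", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
              intron = "intron")

#' Parse a GenBank location string
#'
#' @param loc location string, e.g. `complement(join(10..20,30..40))`.
#' @return list(intervals = data.frame(start, end), strand = "+"/"-").
#' @keywords internal
parse_gb_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  parse_node <- function(s) {
    if (grepl("^complement\\(", s)) {
      strand <<- "-"
      inner <- sub("^complement\\((.*)\\)$", "\\1", s)
      return(parse_node(inner))
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
      ## split on commas at depth 0
      depth <- 0L; parts <- character(0); buf <- ""
      for (ch in strsplit(inner, "", fixed = TRUE)[[1]]) {
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") depth <- depth - 1L
        if (ch == "," && depth == 0L) { parts <- c(parts, buf); buf <- "" }
        else buf <- paste0(buf, ch)
      }
      parts <- c(parts, buf)
      return(do.call(rbind, lapply(parts, parse_node)))
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", s)) {
      ab <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
      return(data.frame(start = ab[1] - 1L, end = ab[2]))
    }
    if (grepl("^[0-9]+$", s)) {
      a <- as.integer(s)
      return(data.frame(start = a - 1L, end = a))
    }
    stop("cannot parse location element: '", s, "'")
  }
  iv <- parse_node(loc)
  list(intervals = iv, strand = strand)
}

#' @keywords internal
merge_origin_wrap <- function(iv, genome_len) {
  if (nrow(iv) >= 2L) {
    for (j in seq_len(nrow(iv) - 1L)) {
      if (iv$end[j] == genome_len && iv$start[j + 1L] == 0L) {
        iv$end[j] <- iv$end[j + 1L]
        iv <- iv[-(j + 1L), , drop = FALSE]
        rownames(iv) <- NULL
        return(iv)
      }
    }
  }
  iv
}

#' Read an annotated genome from a GenBank flat file
#'
#' @param path GenBank flat file with LOCUS/FEATURES/ORIGIN.
#' @param circular override circularity (default: from the LOCUS line).
#' @return an `annotated_plastome`.
#' @export
read_genbank <- function(path, circular = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("malformed GenBank record: no LOCUS line")
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- locus[2]
  declared_len <- suppressWarnings(as.integer(locus[3]))
  if (is.null(circular)) circular <- any(grepl("circular", lines[locus_i[1]]))

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) stop("malformed GenBank record: no ORIGIN section")

  ## sequence
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > orig_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[(orig_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = "")))
  if (!is.na(declared_len) && nchar(sequence) != declared_len)
    warning("LOCUS length ", declared_len, " != sequence length ",
            nchar(sequence), " in ", path)
  g <- genome(id, sequence, circular)

  features <- list()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    ## a feature line has a key in columns 6-20, location from col 22
    is_key <- grepl("^ {4,5}\\S", block)
    key_rows <- which(is_key)
    for (ki in seq_along(key_rows)) {
      r0 <- key_rows[ki]
      r1 <- if (ki < length(key_rows)) key_rows[ki + 1L] - 1L else length(block)
      key <- sub("^\\s+", "", substr(block[r0], 1L, 20L))
      key <- trimws(key)
      cont <- if (r1 > r0) trimws(block[(r0 + 1L):r1]) else character(0)
      body <- c(sub("^\\s*\\S+\\s*", "", block[r0]), cont)
      body <- body[nzchar(body)]
      ## location = leading lines up to first qualifier
      qual_start <- which(grepl("^/", body))[1]
      loc_lines <- if (is.na(qual_start)) body else body[seq_len(qual_start - 1L)]
      quals <- if (is.na(qual_start)) character(0) else body[qual_start:length(body)]
      loc <- paste(loc_lines, collapse = "")
      if (key == "source" || !nzchar(loc)) next
      kkey <- if (key %in% names(.GB_KEYS)) .GB_KEYS[[key]] else "misc"
      pl <- tryCatch(parse_gb_location(loc), error = function(e)
        stop("parse error near line ", feat_i[1] + r0, ": ",
             conditionMessage(e)))
      iv <- merge_origin_wrap(pl$intervals, g$length)
      if (any(iv$start < 0L | iv$start >= g$length | iv$end > g$length))
        stop("feature location outside sequence [1, ", g$length, "]: ", loc)
      gene_q <- grep("^/gene=", quals, value = TRUE)
      name <- if (length(gene_q)) gsub("^/gene=\"?|\"$", "", gene_q[1]) else key
      pseudo <- any(grepl("^/pseudo\\b", quals))
      features[[length(features) + 1L]] <-
        feature(kkey, name, iv, pl$strand, pseudo)
    }
  }
  feats <- if (length(features)) do.call(rbind, features) else NULL
  annotated_genome(g, feats)
}

#' @keywords internal
format_gb_location <- function(iv, strand, genome_len, circular) {
  fmt_one <- function(s, e) {
    if (s < e) paste0(s + 1L, "..", e)
    else paste0(s + 1L, "..", genome_len, ",", 1L, "..", e)
  }
  parts <- unlist(lapply(seq_len(nrow(iv)),
                         function(i) fmt_one(iv$start[i], iv$end[i])))
  parts <- unlist(strsplit(parts, ",", fixed = TRUE))
  loc <- if (length(parts) > 1L)
    paste0("join(", paste(parts, collapse = ","), ")") else parts
  if (strand == "-") paste0("complement(", loc, ")") else loc
}

#' Write an annotated genome as a GenBank flat file
#'
#' @param g an `annotated_plastome`.
#' @param path output file.
#' @export
write_genbank <- function(g, path) {
  L <- g$genome$length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                     g$genome$id, L,
                     if (g$genome$circular) "circular" else "linear",
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s plastome.", g$genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  f <- g$features
  for (i in seq_len(nrow(f))) {
    loc <- format_gb_location(f$intervals[[i]], f$strand[i], L,
                              g$genome$circular)
    writeLines(sprintf("     %-15s %s", f$key[i], loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name[i]), con)
    if (isTRUE(f$pseudo[i]))
      writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(g$genome$sequence)
  starts <- seq(1L, L, 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, L))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
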
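## Fixtures and independent oracles used across the suite.

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## --- SSR oracle: perl regex backreference scan over all motif lengths ------
ssr_oracle <- function(seq, thresholds = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  out <- list()
  for (k in 1:6) {
    pat <- sprintf("(.{%d})\\1{%d,}", k, thresholds[k] - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      motif <- substr(seq, m[i], m[i] + k - 1L)
      if (grepl("[^ACGT]", motif)) next
      ## primitivity
      prim <- TRUE
      for (d in seq_len(k - 1L)) {
        if (k %% d == 0L &&
            motif == strrep(substr(motif, 1L, d), k %/% d)) prim <- FALSE
      }
      if (!prim) next
      copies <- len[i] %/% k
      if (copies < thresholds[k]) next
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_len = k, copies = copies,
        start = m[i], end = m[i] + copies * k - 1L)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(0), unit_len = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_len), , drop = FALSE]
}

## --- dispersed repeat oracle: exhaustive per-diagonal Hamming windows ------
## Enumerates, for each transform, every maximal window with <= max_mismatch
## mismatches on every diagonal, then normalizes exactly like the scanner's
## output contract (first copy first, self pairs dropped, containment-
## redundant pairs removed).
dispersed_oracle <- function(seq, min_len = 30L, max_mismatch = 3L) {
  v <- as.integer(charToRaw(seq))
  L <- length(v)
  transforms <- list(
    forward = list(t = v, map = function(j, len) j),
    reverse = list(t = rev(v), map = function(j, len) L - (j + len - 1L) + 1L),
    complement = list(t = as.integer(charToRaw(chartr("ACGT", "TGCA", seq))),
                      map = function(j, len) j),
    palindromic = list(t = rev(as.integer(charToRaw(chartr("ACGT", "TGCA", seq)))),
                       map = function(j, len) L - (j + len - 1L) + 1L))
  all_rows <- list()
  for (kind in names(transforms)) {
    tt <- transforms[[kind]]$t
    for (d in (-(L - min_len)):(L - min_len)) {
      i_lo <- max(1L, 1L - d); i_hi <- min(L, L - d)
      if (i_hi - i_lo + 1L < min_len) next
      idx <- i_lo:i_hi
      mm <- idx[v[idx] != tt[idx + d]]
      edges <- c(i_lo - 1L, mm, i_hi + 1L)
      K <- length(edges)
      nw <- K - 1L - max_mismatch
      if (nw < 1L) { ws <- i_lo; we <- i_hi } else {
        ws <- edges[seq_len(nw)] + 1L
        we <- edges[seq_len(nw) + 1L + max_mismatch] - 1L
      }
      ok <- we - ws + 1L >= min_len
      for (q in which(ok)) {
        len <- we[q] - ws[q] + 1L
        s2 <- transforms[[kind]]$map(ws[q] + d, len)
        nm <- sum(mm >= ws[q] & mm <= we[q])
        all_rows[[length(all_rows) + 1L]] <-
          data.frame(kind = kind, start1 = ws[q], end1 = we[q],
                     start2 = s2, end2 = s2 + len - 1L,
                     length = len, mismatches = nm)
      }
    }
  }
  if (!length(all_rows))
    return(data.frame(kind = character(0), start1 = integer(0),
                      end1 = integer(0), start2 = integer(0),
                      end2 = integer(0), length = integer(0),
                      mismatches = integer(0)))
  tab <- do.call(rbind, all_rows)
  swap <- tab$start2 < tab$start1
  tmp <- tab[swap, c("start2", "end2")]
  tab[swap, c("start2", "end2")] <- tab[swap, c("start1", "end1")]
  tab[swap, c("start1", "end1")] <- tmp
  tab <- tab[!(tab$start1 == tab$start2 & tab$end1 == tab$end2), ,
             drop = FALSE]
  tab <- tab[!(tab$kind == "forward" & tab$start1 == tab$start2), ,
             drop = FALSE]
  tab <- unique(tab)
  keep <- rep(TRUE, nrow(tab))
  for (kind in unique(tab$kind)) {
    rows <- which(tab$kind == kind)
    sub <- tab[rows, ]
    contained <- vapply(seq_along(rows), function(r) {
      any(sub$start1 <= sub$start1[r] & sub$end1 >= sub$end1[r] &
            sub$start2 <= sub$start2[r] & sub$end2 >= sub$end2[r] &
            sub$length > sub$length[r])
    }, logical(1))
    keep[rows[contained]] <- FALSE
  }
  tab <- tab[keep, , drop = FALSE]
  tab[order(tab$kind, tab$start1), , drop = FALSE]
}

repeat_key <- function(tab)
  sort(paste(tab$kind, tab$start1, tab$end1, tab$start2, tab$end2,
             tab$mismatches))

## --- brute-force nucleotide diversity --------------------------------------
pi_oracle <- function(rows, from, to) {
  mat <- do.call(rbind, strsplit(substr(rows, from, to), ""))
  usable <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(usable)) return(NA_real_)
  mat <- mat[, usable, drop = FALSE]
  n <- nrow(mat)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + sum(mat[i, ] != mat[j, ]) / ncol(mat)
      np <- np + 1L
    }
  }
  tot / np
}

## --- GenBank fixture --------------------------------------------------------
write_gb_fixture <- function(path, id, seq, feature_lines) {
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     circular PLN 01-JAN-2024",
            id, nchar(seq)),
    sprintf("DEFINITION  %s test record.", id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)),
    feature_lines,
    "ORIGIN")
  s <- tolower(seq)
  for (st in seq(1L, nchar(s), 60L)) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", st, paste(groups, collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  path
}

## Small quadripartite fixture used by several suites
mini_sim <- function(seed = 1L, tree = "((a:0.1,b:0.1):0.15,(c:0.08,d:0.08):0.1);",
                     ...) {
  cfg <- simulation_config(gene_model = "mini", tree = tree, ...)
  simulate_plastomes(cfg, seed)
}
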
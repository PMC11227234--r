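## Repeat detection: microsatellites (MISA semantics), dispersed repeats
## (REPuter semantics: forward / reverse / complement / palindromic maximal
## pairs under a Hamming budget) and exact tandem arrays.

.UNIT_CLASS <- c("mono", "di", "tri", "tetra", "penta", "hexa")

#' @keywords internal
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (motif == paste(rep(substr(motif, 1L, d), k %/% d), collapse = ""))
      return(FALSE)
  }
  TRUE
}

#' Find perfect microsatellite (SSR) loci
#'
#' Maximal perfect SSR loci of primitive 1-6 nt motifs, with per-class
#' minimum copy thresholds following the MISA convention.  Loci are
#' reported individually, left to right, with complete copies only (a
#' partial trailing unit does not count towards the copy number).  Motifs
#' containing ambiguity codes are skipped.  Compound loci are not merged.
#'
#' @param g a `plastome` (or `annotated_plastome`).
#' @param thresholds minimum copies for mono- to hexa-nucleotide motifs
#'   (default c(10, 5, 4, 3, 3, 3)).
#' @param partition optional `region_partition` to label loci by region.
#' @param annotation optional `annotated_plastome` to label loci by feature
#'   context.
#' @return data.frame: motif, unit_class, unit_len, copies, start, end
#'   (1-based inclusive), length, region, context.
#' @export
find_ssrs <- function(g, thresholds = c(10L, 5L, 4L, 3L, 3L, 3L),
                      partition = NULL, annotation = NULL) {
  if (inherits(g, "annotated_plastome")) {
    if (is.null(annotation)) annotation <- g
    g <- g$genome
  }
  stopifnot(length(thresholds) == 6L)
  v <- seq_ints(g$sequence)
  L <- g$length
  out <- list()
  for (k in 1:6) {
    if (L < k * thresholds[k]) next
    eq <- v[(k + 1L):L] == v[1:(L - k)] & is_acgt(v[(k + 1L):L])
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= (thresholds[k] - 1L) * k)
    for (ri in runs) {
      i <- starts[ri]              # index into eq; tract starts at i (1-based in v)
      rl <- r$lengths[ri]
      t0 <- i - 1L                 # 0-based tract start
      copies <- (rl + k) %/% k
      if (copies < thresholds[k]) next
      motif <- subseq0(g$sequence, t0, t0 + k)
      if (grepl("[^ACGT]", motif)) next
      if (!is_primitive_motif(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_class = .UNIT_CLASS[k], unit_len = k,
        copies = copies, start = t0 + 1L, end = t0 + copies * k,
        length = copies * k)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(motif = character(0), unit_class = character(0),
               unit_len = integer(0), copies = integer(0),
               start = integer(0), end = integer(0), length = integer(0))
  res <- res[order(res$start, res$unit_len), , drop = FALSE]
  rownames(res) <- NULL
  res$region <- if (!is.null(partition) && isTRUE(partition$found) && nrow(res))
    region_label(partition, res$start - 1L) else rep(NA_character_, nrow(res))
  res$context <- if (!is.null(annotation) && nrow(res))
    feature_context(annotation, res$start - 1L) else rep(NA_character_, nrow(res))
  res
}

## --- Dispersed repeats ------------------------------------------------------

#' @keywords internal
kmer_codes <- function(b, k) {
  ## b: 0..3 integer vector with NA for ambiguity; returns codes for each
  ## k-mer start (NA if any ambiguous base inside)
  n <- length(b) - k + 1L
  if (n < 1L) return(integer(0))
  code <- numeric(n)
  for (j in 0:(k - 1L)) code <- code * 4 + b[(1L + j):(n + j)]
  code
}

#' @keywords internal
base_codes <- function(v) {
  b <- rep(NA_integer_, length(v))
  b[v == 65L] <- 0L; b[v == 67L] <- 1L; b[v == 71L] <- 2L; b[v == 84L] <- 3L
  b
}

## Maximal Hamming-bounded repeat windows between int sequences s and t that
## share a seed.  Returns data.frame(i, j, len, mismatches) with 1-based i
## (position in s) and j (position in t).
#' @keywords internal
seeded_repeat_windows <- function(s, t, min_len, max_mismatch, seed_k,
                                  max_pairs_per_code = 20000L,
                                  max_steps = 60000L) {
  L1 <- length(s); L2 <- length(t)
  bs <- base_codes(s); bt <- base_codes(t)
  cs <- kmer_codes(bs, seed_k); ct <- kmer_codes(bt, seed_k)
  oks <- which(!is.na(cs)); okt <- which(!is.na(ct))
  if (!length(oks) || !length(okt)) return(NULL)
  fs <- split(oks, cs[oks]); ft <- split(okt, ct[okt])
  codes <- intersect(names(fs), names(ft))
  if (!length(codes)) return(NULL)
  qs <- match(codes, names(fs)); qt <- match(codes, names(ft))
  ii <- vector("list", length(codes)); jj <- vector("list", length(codes))
  for (q in seq_along(codes)) {
    a <- fs[[qs[q]]]; b <- ft[[qt[q]]]
    if (length(a) * length(b) > max_pairs_per_code) next
    ii[[q]] <- rep(a, times = length(b))
    jj[[q]] <- rep(b, each = length(a))
  }
  i <- unlist(ii); j <- unlist(jj)
  if (!length(i)) return(NULL)
  d <- j - i
  o <- order(d, i)
  i <- i[o]; j <- j[o]; d <- d[o]
  ## collapse runs of consecutive seeds on the same diagonal
  keep <- c(TRUE, !(d[-1] == d[-length(d)] & i[-1] == i[-length(i)] + 1L))
  ri <- i[keep]; rj <- j[keep]
  run_id <- cumsum(keep)
  run_len <- tabulate(run_id)           # number of seeds in each run
  n <- length(ri)
  dd <- d[keep]
  eqfun <- function(p, q) {
    ok <- p >= 1L & p <= L1 & q >= 1L & q <= L2
    r <- rep(FALSE, length(p))
    r[ok] <- s[p[ok]] == t[q[ok]] & is_acgt(s[p[ok]]) & is_acgt(t[q[ok]])
    r
  }
  walk <- function(dir) {
    ## dir = -1: walk left from the run start; +1: right from the run end.
    ## Block-scan 256 positions at a time; out-of-bounds positions count as
    ## sentinel mismatches one past the boundary.
    block <- 256L
    mmat <- matrix(NA_integer_, nrow = n, ncol = max_mismatch + 1L)
    start_pos <- if (dir < 0) ri - 1L else ri + run_len + seed_k - 1L
    for (a in seq_len(n)) {
      p <- start_pos[a]
      d1 <- dd[a]
      cnt <- 0L
      steps <- 0L
      while (cnt <= max_mismatch && steps < max_steps) {
        pp <- seq.int(p, by = dir, length.out = block)
        qq <- pp + d1
        inb <- pp >= 1L & pp <= L1 & qq >= 1L & qq <= L2
        bad <- which(!(inb & eqfun(pp, qq)))
        for (bi in bad) {
          cnt <- cnt + 1L
          mmat[a, cnt] <- pp[bi]
          if (cnt > max_mismatch) break
          if (!inb[bi]) {            # boundary: saturate remaining budget
            while (cnt <= max_mismatch) {
              cnt <- cnt + 1L
              mmat[a, cnt] <- pp[bi]
            }
            break
          }
        }
        if (cnt > max_mismatch) break
        p <- p + dir * block
        steps <- steps + block
      }
      if (cnt <= max_mismatch) {      # step cap: saturate at current frontier
        while (cnt <= max_mismatch) {
          cnt <- cnt + 1L
          mmat[a, cnt] <- p
        }
      }
    }
    mmat
  }
  lm <- walk(-1L)
  rm_ <- walk(+1L)
  res <- list()
  for (a in seq_len(n)) {
    for (tl in 0:max_mismatch) {
      tr <- max_mismatch - tl
      ws <- lm[a, tl + 1L] + 1L
      we <- rm_[a, tr + 1L] - 1L
      len <- we - ws + 1L
      if (is.na(len) || len < min_len) next
      res[[length(res) + 1L]] <- c(ws, ws + dd[a], len)
    }
  }
  if (!length(res)) return(NULL)
  m <- unique(do.call(rbind, res))
  nm <- vapply(seq_len(nrow(m)), function(r) {
    p <- m[r, 1]:(m[r, 1] + m[r, 3] - 1L)
    sum(!eqfun(p, p + (m[r, 2] - m[r, 1])))
  }, numeric(1))
  data.frame(i = m[, 1], j = m[, 2], len = m[, 3], mismatches = as.integer(nm))
}

#' Find dispersed repeats (forward, reverse, complement, palindromic)
#'
#' Maximal repeat pairs of each of the four kinds, of at least `min_len`
#' bases and at most `max_mismatch` mismatches (Hamming distance) between
#' the two copies, found by seed-and-extend on shared exact k-mers.  With
#' `seed_k <= floor((min_len - max_mismatch) / (max_mismatch + 1))`
#' (the default for sequences up to 10 kb) the scan is complete by the
#' pigeonhole principle; for longer sequences a sparser default seed is
#' used, complete for any pair containing an exact stretch of `seed_k`
#' bases.  Pairs with identical coordinates are excluded; pairs explained
#' by the IR duplication are flagged when a partition is supplied.
#'
#' @param g a `plastome` (or `annotated_plastome`).
#' @param min_len minimum repeat length (default 30).
#' @param max_mismatch Hamming budget (default 3; 90 percent identity at 30 bp).
#' @param seed_k seed length; NULL for the automatic choice above.
#' @param partition optional `region_partition` for the IR-duplicate flag.
#' @return data.frame: kind, start1, end1, start2, end2 (1-based inclusive,
#'   both intervals on the forward strand), length, mismatches, ir_duplicate.
#' @export
find_dispersed_repeats <- function(g, min_len = 30L, max_mismatch = 3L,
                                   seed_k = NULL, partition = NULL) {
  if (inherits(g, "annotated_plastome")) g <- g$genome
  if (is.null(seed_k)) {
    exact_k <- max(2L, as.integer(ceiling((min_len - max_mismatch) /
                                            (max_mismatch + 1L))))
    seed_k <- if (g$length <= 10000L) min(exact_k, 12L) else
      max(min(exact_k, 16L), 12L)
  }
  v <- seq_ints(g$sequence)
  L <- g$length
  rv <- rev(v)
  cv <- comp_ints(v)
  rcv <- rev(cv)
  specs <- list(
    forward = list(t = v, map = function(j, len) j),
    reverse = list(t = rv, map = function(j, len) L - (j + len - 1L) + 1L),
    complement = list(t = cv, map = function(j, len) j),
    palindromic = list(t = rcv, map = function(j, len) L - (j + len - 1L) + 1L))
  out <- list()
  for (kind in names(specs)) {
    sp <- specs[[kind]]
    w <- seeded_repeat_windows(v, sp$t, min_len, max_mismatch, seed_k)
    if (is.null(w)) next
    s2 <- sp$map(w$j, w$len)
    tab <- data.frame(kind = kind, start1 = w$i, end1 = w$i + w$len - 1L,
                      start2 = s2, end2 = s2 + w$len - 1L,
                      length = w$len, mismatches = w$mismatches)
    ## orient: first copy is the one with the smaller start; drop self pairs
    swap <- tab$start2 < tab$start1
    tmp <- tab[swap, c("start2", "end2")]
    tab[swap, c("start2", "end2")] <- tab[swap, c("start1", "end1")]
    tab[swap, c("start1", "end1")] <- tmp
    tab <- tab[!(tab$start1 == tab$start2 & tab$end1 == tab$end2), ,
               drop = FALSE]
    if (kind == "forward")
      tab <- tab[tab$start1 != tab$start2, , drop = FALSE]
    tab <- unique(tab)
    ## drop containment-redundant pairs (keep maximal only)
    if (nrow(tab) > 1L) {
      contained <- vapply(seq_len(nrow(tab)), function(r) {
        any(tab$start1 <= tab$start1[r] & tab$end1 >= tab$end1[r] &
              tab$start2 <= tab$start2[r] & tab$end2 >= tab$end2[r] &
              tab$length > tab$length[r])
      }, logical(1))
      tab <- tab[!contained, , drop = FALSE]
    }
    out[[kind]] <- tab
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(0), start1 = integer(0), end1 = integer(0),
               start2 = integer(0), end2 = integer(0), length = integer(0),
               mismatches = integer(0))
  rownames(res) <- NULL
  res$ir_duplicate <- FALSE
  if (!is.null(partition) && isTRUE(partition$found) && nrow(res)) {
    r1 <- region_label(partition, (res$start1 + res$end1) %/% 2L - 1L)
    r2 <- region_label(partition, (res$start2 + res$end2) %/% 2L - 1L)
    res$ir_duplicate <- (r1 == "IRb" & r2 == "IRa") |
      (r1 == "IRa" & r2 == "IRb")
  }
  res[order(res$kind, res$start1), , drop = FALSE]
}

## --- Tandem repeats ---------------------------------------------------------

#' Find exact tandem repeat arrays
#'
#' Exact arrays of a primitive unit of 7-100 nt repeated at least
#' `min_copies` times (fractional copies allowed: the maximal periodic
#' tract includes any partial trailing unit).  Overlapping calls are
#' resolved to the longest span, then the smallest unit.  This is an
#' exact-array simplification of tandem-repeat finding; imperfect arrays
#' are not modelled.
#'
#' @param g a `plastome` (or `annotated_plastome`).
#' @param unit_range allowed unit lengths (default 7:100).
#' @param min_copies minimum (fractional) copy number (default 2).
#' @param min_span minimum tract span in bases (default 14).
#' @return data.frame: unit, unit_len, copies, start, end (1-based
#'   inclusive), span.
#' @export
find_tandem_repeats <- function(g, unit_range = 7:100, min_copies = 2,
                                min_span = 14L) {
  if (inherits(g, "annotated_plastome")) g <- g$genome
  v <- seq_ints(g$sequence)
  L <- g$length
  cand <- list()
  for (k in unit_range) {
    if (L < 2L * k) next
    eq <- v[(k + 1L):L] == v[1:(L - k)] & is_acgt(v[(k + 1L):L])
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= k)   # tract >= 2 units
    for (ri in runs) {
      t0 <- starts[ri] - 1L
      span <- r$lengths[ri] + k
      copies <- span / k
      if (copies < min_copies || span < min_span) next
      unit <- subseq0(g$sequence, t0, t0 + k)
      if (grepl("[^ACGT]", unit)) next
      if (!is_primitive_motif(unit)) next
      cand[[length(cand) + 1L]] <- data.frame(
        unit = unit, unit_len = k, copies = copies,
        start = t0 + 1L, end = t0 + span, span = span)
    }
  }
  if (!length(cand))
    return(data.frame(unit = character(0), unit_len = integer(0),
                      copies = numeric(0), start = integer(0),
                      end = integer(0), span = integer(0)))
  tab <- do.call(rbind, cand)
  tab <- tab[order(-tab$span, tab$unit_len, tab$start), , drop = FALSE]
  kept <- logical(nrow(tab))
  cov_s <- integer(0); cov_e <- integer(0)
  for (i in seq_len(nrow(tab))) {
    if (!any(tab$start[i] <= cov_e & tab$end[i] >= cov_s)) {
      kept[i] <- TRUE
      cov_s <- c(cov_s, tab$start[i]); cov_e <- c(cov_e, tab$end[i])
    }
  }
  tab <- tab[kept, , drop = FALSE]
  tab <- tab[order(tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

## --- Summaries --------------------------------------------------------------

#' Summarize repeat content by kind, class, region and context
#'
#' Counts and proportions of SSR loci by motif class, genomic region
#' (LSC/SSC/IR; a locus belongs to the region of its start coordinate) and
#' feature context (CDS vs intron vs intergenic), plus overall proportions
#' of the repeat kinds (SSR classes, the four dispersed kinds, tandem).
#'
#' @param ssrs data.frame from [find_ssrs()] (or NULL).
#' @param dispersed data.frame from [find_dispersed_repeats()] (or NULL).
#' @param tandem data.frame from [find_tandem_repeats()] (or NULL).
#' @param partition optional `region_partition`.
#' @param annotation optional `annotated_plastome`.
#' @return list of data.frames: `ssr_by_class`, `ssr_by_region`,
#'   `ssr_by_context`, `by_kind`.
#' @export
summarize_repeats <- function(ssrs = NULL, dispersed = NULL, tandem = NULL,
                              partition = NULL, annotation = NULL) {
  prop_tab <- function(x, levels) {
    cnt <- table(factor(x, levels = levels))
    data.frame(level = names(cnt), count = as.integer(cnt),
               proportion = if (sum(cnt) > 0) as.numeric(cnt) / sum(cnt)
               else rep(0, length(cnt)))
  }
  out <- list()
  if (!is.null(ssrs)) {
    out$ssr_by_class <- prop_tab(ssrs$unit_class, .UNIT_CLASS)
    reg <- ssrs$region
    if (all(is.na(reg)) && !is.null(partition) && isTRUE(partition$found) &&
        nrow(ssrs))
      reg <- region_label(partition, ssrs$start - 1L)
    reg3 <- ifelse(reg %in% c("IRa", "IRb"), "IR", reg)
    out$ssr_by_region <- prop_tab(reg3[!is.na(reg3)], c("LSC", "SSC", "IR"))
    ctx <- ssrs$context
    if (all(is.na(ctx)) && !is.null(annotation) && nrow(ssrs))
      ctx <- feature_context(annotation, ssrs$start - 1L)
    out$ssr_by_context <- prop_tab(ctx[!is.na(ctx)],
                                   c("exon", "intron", "RNA-gene",
                                     "intergenic"))
  }
  kinds <- c(ssr = if (!is.null(ssrs)) nrow(ssrs) else NA_integer_,
             forward = if (!is.null(dispersed))
               sum(dispersed$kind == "forward") else NA_integer_,
             reverse = if (!is.null(dispersed))
               sum(dispersed$kind == "reverse") else NA_integer_,
             complement = if (!is.null(dispersed))
               sum(dispersed$kind == "complement") else NA_integer_,
             palindromic = if (!is.null(dispersed))
               sum(dispersed$kind == "palindromic") else NA_integer_,
             tandem = if (!is.null(tandem)) nrow(tandem) else NA_integer_)
  kinds <- kinds[!is.na(kinds)]
  out$by_kind <- data.frame(kind = names(kinds), count = as.integer(kinds),
                            proportion = if (sum(kinds) > 0)
                              as.numeric(kinds) / sum(kinds)
                            else rep(0, length(kinds)))
  out
}
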
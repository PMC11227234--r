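## Quadripartite structure: inverted-repeat detection, region partition,
## per-region GC and junction analysis.

#' Detect the LSC/IRb/SSC/IRa partition of a plastome
#'
#' Finds the longest pair of inverted repeats of at least `min_ir` bases with
#' at most `max_mismatch` mismatches by k-mer seeding (k = 25) between the
#' sequence and its reverse complement, then labels the longer single-copy
#' segment LSC and the IR copy that follows it (canonical order
#' LSC -> IRb -> SSC -> IRa) IRb.
#'
#' @param g a `plastome` (or `annotated_plastome`).
#' @param min_ir minimum IR length in bases (default 1000).
#' @param max_mismatch mismatch budget between the two IR copies (default 0).
#' @param seed_k seed k-mer length (default 25).
#' @return an object of class `region_partition` with fields `found`,
#'   `regions` (region/start/end, 0-based half-open, a row with
#'   start >= end wraps the origin), `ir_len`, `mismatches`,
#'   `genome_length`.  When no qualifying IR pair exists, `found` is FALSE
#'   and `regions` is NULL.
#' @export
detect_partition <- function(g, min_ir = 1000L, max_mismatch = 0L,
                             seed_k = 25L) {
  if (inherits(g, "annotated_plastome")) g <- g$genome
  S <- g$sequence
  L <- g$length
  no_structure <- structure(list(found = FALSE, regions = NULL,
                                 ir_len = NA_integer_,
                                 mismatches = NA_integer_,
                                 genome_length = L, genome_id = g$id),
                            class = "region_partition")
  if (L < 2L * min_ir + 2L) return(no_structure)
  R <- revcomp(S)
  si <- seq_ints(S)
  ri <- seq_ints(R)

  if (seed_k > 25L) stop("seed_k must be <= 25")
  cs <- kmer_codes(base_codes(si), seed_k)
  cr <- kmer_codes(base_codes(ri), seed_k)
  oks <- which(!is.na(cs)); okr <- which(!is.na(cr))
  common <- intersect(cs[oks], cr[okr])
  if (!length(common)) return(no_structure)
  oks <- oks[cs[oks] %in% common]; okr <- okr[cr[okr] %in% common]
  ps <- split(oks, cs[oks])
  pr <- split(okr, cr[okr])
  idx_r <- match(names(ps), names(pr))
  diags <- vector("list", length(ps))
  for (q in seq_along(ps)) {
    a <- ps[[q]]; b <- pr[[idx_r[q]]]
    if (length(a) * length(b) > 2500L) next  # low-complexity seed
    if (length(a) == 1L && length(b) == 1L) diags[[q]] <- b - a
    else diags[[q]] <- as.vector(outer(b, a, `-`))
  }
  diags <- unlist(diags)
  if (!length(diags)) return(no_structure)
  ## an IR pair of >= min_ir bases with <= max_mismatch mismatches carries
  ## at least this many exact seed k-mers on its diagonal
  thr <- max(2L, min_ir - max_mismatch - (seed_k - 1L) * (max_mismatch + 1L))
  cnt <- table(diags)
  diags <- as.integer(names(cnt)[cnt >= thr])
  if (!length(diags)) return(no_structure)

  best <- NULL
  for (d in diags) {
    ## diagonal: S[i] vs R[i + d], 1-based ints
    i_lo <- max(1L, 1L - d)
    i_hi <- min(L, L - d)
    if (i_hi - i_lo + 1L < min_ir) next
    idx <- i_lo:i_hi
    mm <- which(si[idx] != ri[idx + d])
    ## maximal windows with <= max_mismatch mismatches along this diagonal
    mmpos <- if (length(mm)) idx[mm] else integer(0)
    edges <- c(i_lo - 1L, mmpos, i_hi + 1L)
    K <- length(edges)
    nwin <- K - 1L - max_mismatch
    if (nwin < 1L) {
      ws_all <- i_lo; we_all <- i_hi
    } else {
      ws_all <- edges[seq_len(nwin)] + 1L
      we_all <- edges[seq_len(nwin) + 1L + max_mismatch] - 1L
    }
    lens <- we_all - ws_all + 1L
    ord <- order(lens, decreasing = TRUE)
    ord <- ord[lens[ord] >= min_ir]
    cands <- lapply(ord[seq_len(min(length(ord), 8L))], function(t)
      list(ws = ws_all[t], we = we_all[t],
           nm = sum(mmpos >= ws_all[t] & mmpos <= we_all[t])))
    for (cand in cands) {
      m <- cand$we - cand$ws + 1L
      if (m < min_ir) next
      a1 <- cand$ws - 1L              # 0-based start of copy in S
      a2 <- cand$we                   # 0-based end (half-open)
      j1 <- a1 + d; j2 <- a2 + d      # 0-based in R
      b1 <- L - j2; b2 <- L - j1      # partner copy in S
      if (a1 < b1) { c1s <- a1; c1e <- a2; c2s <- b1; c2e <- b2 }
      else { c1s <- b1; c1e <- b2; c2s <- a1; c2e <- a2 }
      if (c1e > c2s) next             # overlapping copies (self-palindrome)
      if (is.null(best) || m > best$m)
        best <- list(m = m, nm = cand$nm, c1 = c(c1s, c1e), c2 = c(c2s, c2e))
    }
  }
  if (is.null(best)) return(no_structure)

  c1 <- best$c1; c2 <- best$c2; m <- best$m
  mid_len <- c2[1] - c1[2]
  wrap_len <- (L - c2[2]) + c1[1]
  if (wrap_len >= mid_len) {
    ## wrap segment is LSC; copy 1 follows it
    regions <- data.frame(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(c2[2] %% L, c1[1], c1[2], c2[1]),
      end = c(c1[1], c1[2], c2[1], c2[2]))
  } else {
    regions <- data.frame(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(c1[2], c2[1], c2[2] %% L, c1[1]),
      end = c(c2[1], c2[2], c1[1], c1[2]))
  }
  regions$length <- interval_len(regions$start, regions$end, L)
  structure(list(found = TRUE, regions = regions, ir_len = m,
                 mismatches = best$nm, genome_length = L, genome_id = g$id),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  if (!x$found) {
    cat("<region_partition> no quadripartite structure detected\n")
    return(invisible(x))
  }
  cat("<region_partition> ", x$genome_id, " (", x$genome_length, " bp), IR ",
      x$ir_len, " bp, ", x$mismatches, " mismatch(es)\n", sep = "")
  print(x$regions)
  invisible(x)
}

#' Region label of positions
#'
#' @param p a `region_partition`.
#' @param pos 0-based positions.
#' @return character vector of LSC/IRb/SSC/IRa labels.
#' @export
region_label <- function(p, pos) {
  stopifnot(inherits(p, "region_partition"), p$found)
  region_of_positions(pos, p$regions, p$genome_length)
}

#' Per-region and whole-genome GC content
#'
#' GC = (G+C)/(A+C+G+T); positions with ambiguity codes are excluded from
#' both numerator and denominator.
#'
#' @param g a `plastome` (or `annotated_plastome`).
#' @param p a `region_partition` with `found = TRUE`.
#' @return data.frame with columns `region` (LSC, IRb, SSC, IRa, IR, total),
#'   `length`, `gc`.
#' @export
region_gc <- function(g, p) {
  if (inherits(g, "annotated_plastome")) g <- g$genome
  stopifnot(inherits(p, "region_partition"))
  if (!p$found) stop("no partition: cannot compute per-region GC")
  v <- seq_ints(g$sequence)
  gc_of <- function(idx) {
    vv <- v[idx]
    keep <- is_acgt(vv)
    if (!any(keep)) stop("empty region (no unambiguous bases)")
    sum(vv[keep] == 71L | vv[keep] == 67L) / sum(keep)
  }
  idx_of <- function(s, e) {
    if (s < e) (s + 1L):e else c((s + 1L):p$genome_length, seq_len(e))
  }
  rows <- lapply(seq_len(nrow(p$regions)), function(i) {
    r <- p$regions[i, ]
    idx <- idx_of(r$start, r$end)
    data.frame(region = r$region, length = length(idx), gc = gc_of(idx))
  })
  ir_idx <- c(idx_of(p$regions$start[2], p$regions$end[2]),
              idx_of(p$regions$start[4], p$regions$end[4]))
  out <- do.call(rbind, rows)
  out <- rbind(out,
               data.frame(region = "IR", length = length(ir_idx),
                          gc = gc_of(ir_idx)),
               data.frame(region = "total", length = g$length,
                          gc = gc_of(seq_len(g$length))))
  out
}

## wrap-aware distance from a to b moving forward (0-based)
#' @keywords internal
fwd_dist <- function(a, b, L) (b - a) %% L

#' Junction report: spanning and nearest genes at the four IR boundaries
#'
#' Junctions are named JLB (LSC/IRb), JSB (IRb/SSC), JSA (SSC/IRa) and
#' JLA (IRa/LSC).  For every junction the report gives the gene spanning it
#' (with the split lengths falling into the upstream and downstream
#' regions), or the nearest gene on each side with its distance, plus an
#' overlap flag set when two features overlap each other across the
#' junction (e.g. an IR-copy pseudogene fragment overlapping ndhF).
#' A gene ending exactly at a junction belongs to the upstream region.
#'
#' @param g an `annotated_plastome`.
#' @param p a `region_partition` with `found = TRUE`.
#' @return data.frame, one row per junction.
#' @export
junction_report <- function(g, p) {
  stopifnot(inherits(g, "annotated_plastome"),
            inherits(p, "region_partition"))
  if (!p$found) stop("no partition: cannot build junction report")
  L <- p$genome_length
  reg <- p$regions
  junctions <- data.frame(
    junction = c("JLB", "JSB", "JSA", "JLA"),
    pos = c(reg$end[reg$region == "LSC"] %% L,
            reg$end[reg$region == "IRb"] %% L,
            reg$end[reg$region == "SSC"] %% L,
            reg$end[reg$region == "IRa"] %% L),
    upstream = c("LSC", "IRb", "SSC", "IRa"),
    downstream = c("IRb", "SSC", "IRa", "LSC"))

  f <- g$features[g$features$key %in% c("gene", "CDS", "tRNA", "rRNA"), ,
                  drop = FALSE]
  ## one span per feature row: first interval start to last interval end
  spans <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
    iv <- f$intervals[[i]]
    data.frame(name = f$name[i], pseudo = f$pseudo[i],
               start = iv$start[1], end = iv$end[nrow(iv)],
               len = sum(interval_len(iv$start, iv$end, L)))
  }))
  ## one span per gene: prefer 'gene' rows, but keep features (e.g. IR
  ## pseudogene fragments) that have no gene row of their own
  if (any(f$key == "gene")) {
    keep <- f$key == "gene" | !(f$name %in% f$name[f$key == "gene"])
    spans <- spans[keep, , drop = FALSE]
  }

  span_len <- fwd_dist(spans$start, spans$end, L)
  spans_overlap <- function(i, j) {
    fwd_dist(spans$start[i], spans$start[j], L) < span_len[i] ||
      fwd_dist(spans$start[j], spans$start[i], L) < span_len[j]
  }
  rows <- lapply(seq_len(nrow(junctions)), function(ji) {
    c0 <- junctions$pos[ji]
    ## spanning: feature strictly crosses the boundary before position c0
    contains <- function(i, p) fwd_dist(spans$start[i], p, L) < span_len[i]
    hit <- which(vapply(seq_len(nrow(spans)), function(i)
      contains(i, (c0 - 1L) %% L) && contains(i, c0), logical(1)))
    if (length(hit)) {
      i <- hit[which.max(span_len[hit])]
      up_len <- fwd_dist(spans$start[i], c0, L)
      down_len <- fwd_dist(c0, spans$end[i], L)
      ovl <- unique(unlist(lapply(hit, function(h) {
        others <- setdiff(seq_len(nrow(spans)), h)
        others[vapply(others, function(o) spans_overlap(h, o), logical(1))]
      })))
      ovl_names <- unique(c(spans$name[hit[duplicated(hit) | length(hit) > 1L]],
                            spans$name[ovl]))
      has_ovl <- length(hit) > 1L || length(ovl) > 0L
      data.frame(junction = junctions$junction[ji], position = c0 + 1L,
                 upstream = junctions$upstream[ji],
                 downstream = junctions$downstream[ji],
                 spanning_gene = spans$name[i],
                 split_upstream = up_len, split_downstream = down_len,
                 nearest_upstream = NA_character_, dist_upstream = NA_integer_,
                 nearest_downstream = NA_character_, dist_downstream = NA_integer_,
                 overlap = has_ovl,
                 overlap_genes = if (has_ovl)
                   paste(unique(c(spans$name[hit], ovl_names)), collapse = ",")
                 else NA_character_)
    } else {
      dup <- fwd_dist(spans$end, c0, L)     # gene ends upstream of junction
      ddo <- fwd_dist(c0, spans$start, L)   # gene starts downstream
      iu <- which.min(dup); idn <- which.min(ddo)
      data.frame(junction = junctions$junction[ji], position = c0 + 1L,
                 upstream = junctions$upstream[ji],
                 downstream = junctions$downstream[ji],
                 spanning_gene = NA_character_,
                 split_upstream = NA_integer_, split_downstream = NA_integer_,
                 nearest_upstream = spans$name[iu],
                 dist_upstream = dup[iu],
                 nearest_downstream = spans$name[idn],
                 dist_downstream = ddo[idn],
                 overlap = FALSE, overlap_genes = NA_character_)
    }
  })
  do.call(rbind, rows)
}
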
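## Alignment-based variation: SNV / insertion / deletion calling against a
## reference sample, per-region per-kb rates, feature-context localization,
## InDel frame classification, sliding-window nucleotide diversity and
## hotspot calling.

#' Read a multiple alignment from aligned FASTA
#'
#' @param path aligned FASTA ('-' gaps).
#' @return named character vector of equal-length gapped rows.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no sequences in ", path)
  rows <- toupper(as.character(ss))
  names(rows) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  check_alignment(rows)
}

#' Validate an alignment matrix
#'
#' @param rows named character vector of gapped rows.
#' @return the validated rows (invisibly usable).
#' @export
check_alignment <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named")
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length")
  ungapped <- nchar(gsub("-", "", rows, fixed = TRUE))
  if (any(ungapped == 0L)) stop("alignment contains an all-gap row")
  rows
}

.GAP <- 45L  # '-'

#' Call SNVs, insertions and deletions against a reference sample
#'
#' Each maximal run of gap columns in the sample row is one deletion; each
#' maximal run of gap columns in the reference is one insertion;
#' substitution columns are individual SNVs (adjacent SNVs are never
#' merged).  Columns gapped in both rows, or containing an ambiguity code
#' in either row, are skipped and counted.  InDels are left-aligned within
#' homopolymer/repeat context.  Coordinates are 1-based on the ungapped
#' reference; an insertion is anchored to the reference base it follows
#' (0 = before the first base), a deletion/SNV to its first affected base.
#'
#' @param aln named character vector of gapped rows (see
#'   [check_alignment()]).
#' @param ref_id name of the reference row.
#' @return data.frame: sample, kind (SNV/insertion/deletion), pos, length,
#'   ref, alt; attribute `skipped` = per-sample count of skipped columns.
#' @export
pairwise_variants <- function(aln, ref_id) {
  aln <- check_alignment(aln)
  if (!ref_id %in% names(aln)) stop("reference '", ref_id, "' not in alignment")
  refv <- seq_ints(aln[[ref_id]])
  ref_nt <- strsplit(gsub("-", "", aln[[ref_id]], fixed = TRUE), "")[[1]]
  skipped <- integer(0)
  out <- list()
  for (sid in setdiff(names(aln), ref_id)) {
    altv <- seq_ints(aln[[sid]])
    keep <- !(refv == .GAP & altv == .GAP)
    rv <- refv[keep]; av <- altv[keep]
    refpos <- cumsum(rv != .GAP)          # ref position at/before each column
    ref_ok <- is_acgt(rv) | rv == .GAP
    alt_ok <- is_acgt(av) | av == .GAP
    amb <- !(ref_ok & alt_ok)
    ## column classes: 0 match/other, 1 SNV, 2 deletion (sample gap),
    ## 3 insertion (ref gap); ambiguity columns class 0 (skipped)
    cls <- integer(length(rv))
    cls[rv != .GAP & av != .GAP & rv != av & !amb] <- 1L
    cls[av == .GAP & rv != .GAP & !amb] <- 2L
    cls[rv == .GAP & av != .GAP & !amb] <- 3L
    skipped[sid] <- sum(amb)
    snv_cols <- which(cls == 1L)
    vars <- if (length(snv_cols))
      data.frame(sample = sid, kind = "SNV", pos = refpos[snv_cols],
                 length = 1L, ref = rawToChar(as.raw(rv[snv_cols]),
                                              multiple = TRUE),
                 alt = rawToChar(as.raw(av[snv_cols]), multiple = TRUE))
    else NULL
    r <- rle(cls)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values %in% c(2L, 3L))) {
      c1 <- starts[k]; c2 <- ends[k]
      if (r$values[k] == 2L) {                        # deletion
        p <- refpos[c1]; len <- refpos[c2] - refpos[c1] + 1L
        ## left-align: slide while base before equals last deleted base
        while (p > 1L && ref_nt[p - 1L] == ref_nt[p + len - 1L]) p <- p - 1L
        del_seq <- paste(ref_nt[p:(p + len - 1L)], collapse = "")
        vars <- rbind(vars, data.frame(sample = sid, kind = "deletion",
                                       pos = p, length = len, ref = del_seq,
                                       alt = ""))
      } else {                                        # insertion
        p <- refpos[c1]                               # base before the gap run
        ins <- rawToChar(as.raw(av[c1:c2]))
        ins_v <- strsplit(ins, "")[[1]]
        while (p >= 1L && ref_nt[p] == ins_v[length(ins_v)]) {
          ins_v <- c(ins_v[length(ins_v)], ins_v[-length(ins_v)])
          p <- p - 1L
        }
        vars <- rbind(vars, data.frame(sample = sid, kind = "insertion",
                                       pos = p, length = c2 - c1 + 1L,
                                       ref = "",
                                       alt = paste(ins_v, collapse = "")))
      }
    }
    if (!is.null(vars)) out[[sid]] <- vars[order(vars$pos), , drop = FALSE]
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(0), kind = character(0), pos = integer(0),
               length = integer(0), ref = character(0), alt = character(0))
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Per-region variant counts and per-kb rates
#'
#' Variants are assigned to the region of their (first) reference
#' coordinate; rates are counts divided by region length in kb.  The two
#' IR copies are pooled into one "IR" stratum; a "whole" row sums the
#' regions.
#'
#' @param vars data.frame from [pairwise_variants()].
#' @param p a `region_partition` of the reference genome.
#' @return data.frame: region, kind, count, kb, rate.
#' @export
per_kb_rates <- function(vars, p) {
  stopifnot(inherits(p, "region_partition"))
  if (!p$found) stop("no partition available")
  L <- p$genome_length
  if (nrow(vars) && any(vars$pos < 0L | vars$pos > L))
    stop("variant coordinate outside the reference genome")
  reg_len <- c(LSC = sum(p$regions$length[p$regions$region == "LSC"]),
               SSC = sum(p$regions$length[p$regions$region == "SSC"]),
               IR = sum(p$regions$length[p$regions$region %in%
                                           c("IRa", "IRb")]))
  pos0 <- pmax(vars$pos, 1L) - 1L
  reg <- region_of_positions(pos0, p$regions, L)
  reg <- ifelse(reg %in% c("IRa", "IRb"), "IR", reg)
  kinds <- c("SNV", "insertion", "deletion")
  rows <- list()
  for (rg in c("LSC", "SSC", "IR")) {
    for (kd in kinds) {
      cnt <- sum(reg == rg & vars$kind == kd)
      rows[[length(rows) + 1L]] <-
        data.frame(region = rg, kind = kd, count = cnt,
                   kb = reg_len[[rg]] / 1000,
                   rate = cnt / (reg_len[[rg]] / 1000))
    }
  }
  for (kd in kinds) {
    cnt <- sum(vars$kind == kd)
    rows[[length(rows) + 1L]] <-
      data.frame(region = "whole", kind = kd, count = cnt, kb = L / 1000,
                 rate = cnt / (L / 1000))
  }
  do.call(rbind, rows)
}

#' Annotate variants with feature context
#'
#' @param vars data.frame from [pairwise_variants()].
#' @param g an `annotated_plastome` (the reference).
#' @return list: `variants` (with a `context` column) and `summary`
#'   (counts and percentages per context and kind).
#' @export
locate_variants <- function(vars, g) {
  ctx <- if (nrow(vars))
    feature_context(g, pmax(vars$pos, 1L) - 1L) else character(0)
  vars$context <- ctx
  lv <- c("exon", "intron", "RNA-gene", "intergenic")
  rows <- list()
  for (kd in unique(vars$kind)) {
    cnt <- table(factor(ctx[vars$kind == kd], levels = lv))
    rows[[length(rows) + 1L]] <-
      data.frame(kind = kd, context = names(cnt), count = as.integer(cnt),
                 percent = if (sum(cnt)) 100 * as.numeric(cnt) / sum(cnt)
                 else rep(0, length(cnt)))
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), context = character(0),
               count = integer(0), percent = numeric(0))
  list(variants = vars, summary = summary)
}

#' InDel frame classification
#'
#' Counts how many insertion/deletion lengths are multiples of three
#' (frame-preserving); SNVs are ignored.
#'
#' @param vars data.frame with `kind` and `length` columns.
#' @return list: `n_multiple_of_3`, `n_total`, `fraction` (NA when there
#'   are no InDels).
#' @export
indel_frame_classification <- function(vars) {
  len <- vars$length[vars$kind %in% c("insertion", "deletion")]
  n3 <- sum(len %% 3L == 0L)
  n <- length(len)
  list(n_multiple_of_3 = n3, n_total = n,
       fraction = if (n > 0) n3 / n else NA_real_)
}

#' Sliding-window nucleotide diversity
#'
#' Per window, pi is the average over all sequence pairs of differences per
#' usable site; columns containing any gap or ambiguity code are excluded
#' for all pairs (complete deletion within the window).  Windows advance by
#' `step`; a final partial window is included when at least half the window
#' length remains.
#'
#' @param aln named character vector of gapped rows (>= 2 sequences).
#' @param window window length in bp (default 600).
#' @param step step size in bp (default 200).
#' @param coords "alignment" (default: windows on alignment columns) or
#'   "reference" (windows on the ungapped coordinates of `ref_id`).
#' @param ref_id reference row for `coords = "reference"`.
#' @param samples rows to include in the diversity computation (default
#'   all); the `ref_id` row may serve for coordinates only, e.g. to keep an
#'   outgroup out of pi.
#' @return data.frame of class `pi_profile`: start, end, mid, pi, usable.
#' @export
sliding_window_pi <- function(aln, window = 600L, step = 200L,
                              coords = c("alignment", "reference"),
                              ref_id = NULL, samples = NULL) {
  coords <- match.arg(coords)
  aln <- check_alignment(aln)
  full <- aln
  if (!is.null(samples)) {
    if (!all(samples %in% names(aln))) stop("unknown sample name(s)")
    aln <- aln[samples]
  }
  n <- length(aln)
  if (n < 2L) stop("need at least 2 sequences for nucleotide diversity")
  m <- do.call(rbind, lapply(aln, seq_ints))
  ncol_aln <- ncol(m)
  usable <- colSums(matrix(is_acgt(m), nrow = n)) == n
  npairs <- n * (n - 1L) / 2
  ## per-column pairwise differences via base tallies
  diffs <- numeric(ncol_aln)
  if (any(usable)) {
    um <- m[, usable, drop = FALSE]
    same <- numeric(ncol(um))
    for (b in c(65L, 67L, 71L, 84L)) {
      nb <- colSums(um == b)
      same <- same + nb * (nb - 1L) / 2
    }
    diffs[usable] <- npairs - same
  }
  if (coords == "reference") {
    if (is.null(ref_id) || !ref_id %in% names(full))
      stop("coords = 'reference' requires a valid ref_id")
    colmap <- which(seq_ints(full[[ref_id]]) != .GAP)
    len <- length(colmap)
    col_of <- function(p) colmap[p]
  } else {
    len <- ncol_aln
    col_of <- identity
  }
  cd <- cumsum(diffs)
  cu <- cumsum(as.numeric(usable))
  starts <- seq(1L, max(1L, len), by = step)
  keep <- pmin(starts + window - 1L, len) - starts + 1L >= ceiling(window / 2)
  starts <- starts[keep & starts <= len]
  if (!length(starts)) stop("alignment shorter than half the window length")
  rows <- lapply(starts, function(s) {
    e <- min(s + window - 1L, len)
    c1 <- col_of(s); c2 <- col_of(e)
    d <- cd[c2] - if (c1 > 1L) cd[c1 - 1L] else 0
    u <- cu[c2] - if (c1 > 1L) cu[c1 - 1L] else 0
    data.frame(start = s, end = e, mid = (s + e) / 2,
               pi = if (u > 0) d / (npairs * u) else NA_real_, usable = u)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pi_profile", "data.frame")
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "coords") <- coords
  out
}

#' Call high-diversity hotspots from a pi profile
#'
#' Consecutive windows with pi strictly greater than the threshold are
#' merged into one hotspot; each hotspot carries its peak pi and, when an
#' annotated genome is supplied, the names of overlapping features (or the
#' nearest feature when none overlaps).  Hotspot coordinates are in the
#' profile's coordinate system.
#'
#' @param profile a `pi_profile` from [sliding_window_pi()].
#' @param threshold pi threshold (default 0.010).
#' @param g optional `annotated_plastome` for feature annotation.
#' @return data.frame: start, end, peak_pi, n_windows, features.
#' @export
call_hotspots <- function(profile, threshold = 0.010, g = NULL) {
  if (nrow(profile) == 0L) stop("empty profile")
  hot <- !is.na(profile$pi) & profile$pi > threshold
  if (!any(hot))
    return(data.frame(start = integer(0), end = integer(0),
                      peak_pi = numeric(0), n_windows = integer(0),
                      features = character(0)))
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  rows <- lapply(which(r$values), function(k) {
    i1 <- starts[k]; i2 <- ends[k]
    hs <- min(profile$start[i1:i2]); he <- max(profile$end[i1:i2])
    feats <- NA_character_
    if (!is.null(g)) {
      f <- g$features[g$features$key %in% c("gene", "CDS", "tRNA", "rRNA"), ,
                      drop = FALSE]
      if (nrow(f)) {
        sp <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
          iv <- f$intervals[[i]]
          data.frame(name = f$name[i], start = iv$start[1],
                     end = iv$end[nrow(iv)])
        }))
        ovl <- sp$name[sp$start < he & sp$end > hs - 1L]
        feats <- if (length(ovl)) paste(unique(ovl), collapse = ",") else {
          d <- pmin(abs(sp$start - he), abs(hs - 1L - sp$end))
          sp$name[which.min(d)]
        }
      }
    }
    data.frame(start = hs, end = he,
               peak_pi = max(profile$pi[i1:i2], na.rm = TRUE),
               n_windows = i2 - i1 + 1L, features = feats)
  })
  do.call(rbind, rows)
}
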
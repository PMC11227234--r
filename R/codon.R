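## Codon usage bias suite: codon counting, RSCU, third-position composition,
## Wright's effective number of codons (ENC) with the expected-ENC curve,
## PR2-plot coordinates, optimal-codon determination by the delta-RSCU rule,
## and the CAI / CBI / Fop adaptation indices.
##
## Codons are written in DNA alphabet (e.g. "CTT" for the RNA codon CUU).
## The plastid/bacterial genetic code (translation table 11) is used; its
## codon-to-amino-acid assignments match the standard code, so the
## synonymous-family structure is the classic one (59 synonymous codons;
## Met, Trp and the three stops excluded).

#' @keywords internal
codon_universe <- local({
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  function() codons
})

#' @keywords internal
codon_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- codon_universe()
    aa <- genetic_code()[codons]
    stop <- aa == "*"
    fam_sizes <- table(aa[!stop])
    size <- ifelse(stop, NA_integer_, as.integer(fam_sizes[aa]))
    synonymous <- !stop & size >= 2L
    third <- substr(codons, 3L, 3L)
    prefix <- substr(codons, 1L, 2L)
    ## permit[b, codon]: does swapping the third base to b stay in-family?
    permit <- sapply(c("A", "C", "G", "T"), function(b) {
      alt <- paste0(prefix, b)
      genetic_code()[alt] == aa & !stop
    })
    ## fourfold boxes: prefixes whose four codons all code the same aa
    ff_prefix <- names(which(tapply(aa, prefix, function(x)
      length(unique(x)) == 1L && x[1] != "*")))
    fourfold <- prefix %in% ff_prefix
    cache <<- list(codons = codons, aa = aa, stop = stop, size = size,
                   synonymous = synonymous, third = third, permit = permit,
                   fourfold = fourfold)
    cache
  }
})

#' Count codons per gene
#'
#' @param cds data.frame from [extract_cds()] (columns `gene`, `nt`), or a
#'   named character vector of in-frame sequences.
#' @return integer matrix genes x 64 (codon columns in alphabetical order)
#'   with attribute `n_ambiguous` (codons containing non-ACGT, excluded).
#' @export
codon_counts <- function(cds) {
  if (is.data.frame(cds)) {
    nt <- cds$nt
    names(nt) <- make.unique(cds$gene)
  } else nt <- cds
  codons <- codon_universe()
  n_amb <- 0L
  m <- t(vapply(nt, function(s) {
    cc <- split_codons(toupper(s))
    bad <- grepl("[^ACGT]", cc)
    n_amb <<- n_amb + sum(bad)
    tab <- table(factor(cc[!bad], levels = codons))
    as.integer(tab)
  }, integer(64)))
  colnames(m) <- codons
  if (n_amb > 0L)
    message(n_amb, " codon(s) containing ambiguity codes excluded")
  attr(m, "n_ambiguous") <- n_amb
  m
}

#' @keywords internal
as_count_vector <- function(counts) {
  if (is.matrix(counts)) counts <- colSums(counts)
  ct <- codon_tables()
  v <- numeric(64)
  names(v) <- ct$codons
  v[names(counts)] <- counts
  v
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = observed(c) / (family total / family size).  Single-codon
#' families (Met, Trp) have RSCU 1 when observed.  Codons of families with
#' zero observations get RSCU 0 and are listed in the `unobserved_families`
#' attribute.
#'
#' @param counts named codon count vector, or a genes x 64 matrix (pooled).
#' @return named numeric vector over the 61 sense codons.
#' @export
rscu <- function(counts) {
  v <- as_count_vector(counts)
  ct <- codon_tables()
  sense <- !ct$stop
  fam_tot <- tapply(v[sense], ct$aa[sense], sum)
  expected <- as.numeric(fam_tot[ct$aa[sense]]) / ct$size[sense]
  out <- as.numeric(ifelse(expected > 0, v[sense] / expected, 0))
  names(out) <- ct$codons[sense]
  attr(out, "unobserved_families") <- names(fam_tot)[fam_tot == 0]
  out
}

#' Synonymous third-position composition and GC content
#'
#' A3s/T3s/C3s/G3s follow the classic usage-index semantics: each base's
#' frequency is the count of synonymous codons carrying that base at the
#' third position divided by the count of synonymous codons whose family
#' permits that base there.  GC3s is the G+C fraction at synonymous third
#' positions; GC is over all positions of all counted codons.
#'
#' @param counts named codon count vector or genes x 64 matrix row.
#' @return named numeric vector (T3s, C3s, A3s, G3s, GC3s, GC).
#' @export
composition_3s <- function(counts) {
  v <- as_count_vector(counts)
  ct <- codon_tables()
  syn <- ct$synonymous
  if (sum(v[syn]) == 0)
    return(c(T3s = NA_real_, C3s = NA_real_, A3s = NA_real_,
             G3s = NA_real_, GC3s = NA_real_, GC = NA_real_))
  x3 <- vapply(c("T", "C", "A", "G"), function(b) {
    num <- sum(v[syn & ct$third == b])
    den <- sum(v[syn & ct$permit[, b]])
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  gc3s <- sum(v[syn & ct$third %in% c("G", "C")]) / sum(v[syn])
  gc_counts <- vapply(ct$codons, function(cd)
    sum(strsplit(cd, "")[[1]] %in% c("G", "C")), numeric(1))
  gc <- sum(v * gc_counts) / (3 * sum(v))
  c(T3s = unname(x3["T"]), C3s = unname(x3["C"]), A3s = unname(x3["A"]),
    G3s = unname(x3["G"]), GC3s = gc3s, GC = gc)
}

#' Wright's effective number of codons (ENC)
#'
#' Per synonymous family with n >= 2 observed codons, homozygosity
#' F = (n * sum(p_i^2) - 1) / (n - 1); class means over degeneracy classes
#' (2-fold: 9 families, 3-fold: Ile, 4-fold: 5 families, 6-fold: 3
#' families) give ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6.  A missing 3-fold
#' class is substituted by (F2 + F4)/2 (Wright's rule); if any other class
#' is missing or its mean homozygosity is zero the statistic is undefined.
#' Values above 61 are capped at 61.
#'
#' @param counts named codon count vector or genes x 64 matrix row.
#' @return ENC in [20, 61], or NA when undefined.
#' @export
enc <- function(counts) {
  v <- as_count_vector(counts)
  ct <- codon_tables()
  syn <- ct$synonymous
  fams <- split(seq_len(64)[syn], ct$aa[syn])
  F_by_fam <- vapply(fams, function(idx) {
    n <- sum(v[idx])
    if (n < 2) return(NA_real_)
    p <- v[idx] / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  sizes <- vapply(fams, function(idx) ct$size[idx][1], numeric(1))
  class_mean <- function(k) {
    f <- F_by_fam[sizes == k]
    f <- f[!is.na(f)]
    if (!length(f)) NA_real_ else mean(f)
  }
  F2 <- class_mean(2); F3 <- class_mean(3); F4 <- class_mean(4)
  F6 <- class_mean(6)
  if (is.na(F3) && !is.na(F2) && !is.na(F4)) F3 <- (F2 + F4) / 2
  if (anyNA(c(F2, F3, F4, F6)) || any(c(F2, F3, F4, F6) <= 0))
    return(NA_real_)
  out <- 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6
  min(out, 61)
}

#' Expected ENC under pure GC3s-driven mutational bias
#'
#' Direct evaluation of the standard-curve formula
#' ENC = 2 + GC3s + 29 / (GC3s^2 + (1 - GC3s)^2).
#'
#' @param gc3s GC3s fraction(s) in [0, 1].
#' @return expected ENC value(s).
#' @export
enc_expected <- function(gc3s) {
  stopifnot(all(gc3s >= 0 & gc3s <= 1))
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Relative ENC deviation (ENCexp - ENCobs) / ENCexp
#'
#' @param obs observed ENC.
#' @param exp expected ENC from [enc_expected()].
#' @return deviation fraction; NA where exp <= 0.
#' @export
enc_deviation <- function(obs, exp) {
  ifelse(exp > 0, (exp - obs) / exp, NA_real_)
}

#' PR2-plot coordinates
#'
#' Parity rule 2 coordinates x = G3/(G3+C3), y = A3/(A3+T3) over the third
#' positions of fourfold-degenerate codon boxes (default, Sueoka's
#' construction) or over all synonymous codons.
#'
#' @param counts named codon count vector or genes x 64 matrix row.
#' @param mode "fourfold" (default) or "all".
#' @return named numeric vector (x, y); NA coordinates where a denominator
#'   is zero.
#' @export
pr2_point <- function(counts, mode = c("fourfold", "all")) {
  mode <- match.arg(mode)
  v <- as_count_vector(counts)
  ct <- codon_tables()
  sel <- if (mode == "fourfold") ct$fourfold else ct$synonymous
  n3 <- vapply(c("A", "C", "G", "T"), function(b)
    sum(v[sel & ct$third == b]), numeric(1))
  x <- if (n3["G"] + n3["C"] > 0) n3[["G"]] / (n3[["G"]] + n3[["C"]]) else NA_real_
  y <- if (n3["A"] + n3["T"] > 0) n3[["A"]] / (n3[["A"]] + n3[["T"]]) else NA_real_
  c(x = x, y = y)
}

#' Determine optimal codons by the delta-RSCU rule
#'
#' Genes are ranked by ENC; the lowest-ENC `tail` fraction (strongest
#' bias) forms the high-expression set and the highest-ENC tail the
#' low-expression set (ties at the cut are included).  RSCU is computed on
#' the pooled counts of each set, and a codon is optimal when
#' RSCU_high > 1 and RSCU_high - RSCU_low > `delta`.
#'
#' @param table genes x 64 codon count matrix.
#' @param enc_by_gene numeric ENC per gene (same order as rows); computed
#'   when NULL.
#' @param tail tail fraction (default 0.05).
#' @param delta RSCU difference threshold (default 0.08).
#' @param rscu_mode evaluate the "RSCU > 1" clause in the high-expression
#'   set ("high", default) or in the overall pooled RSCU ("overall").
#' @return list: `optimal` (codon names), `delta_rscu`, `rscu_high`,
#'   `rscu_low`, `high_genes`, `low_genes`.
#' @export
determine_optimal_codons <- function(table, enc_by_gene = NULL, tail = 0.05,
                                     delta = 0.08,
                                     rscu_mode = c("high", "overall")) {
  rscu_mode <- match.arg(rscu_mode)
  n <- nrow(table)
  if (n < 40L) stop("need at least 40 genes for ", tail * 100, "% tails")
  if (is.null(enc_by_gene))
    enc_by_gene <- apply(table, 1, enc)
  ok <- !is.na(enc_by_gene)
  tab <- table[ok, , drop = FALSE]
  e <- enc_by_gene[ok]
  k <- max(2L, ceiling(tail * length(e)))
  es <- sort(e)
  hi_cut <- es[k]                 # low ENC = strong bias = high expression
  lo_cut <- es[length(es) - k + 1L]
  high <- which(e <= hi_cut)
  low <- which(e >= lo_cut)
  r_hi <- rscu(colSums(tab[high, , drop = FALSE]))
  r_lo <- rscu(colSums(tab[low, , drop = FALSE]))
  d <- r_hi - r_lo
  gate <- if (rscu_mode == "high") r_hi else rscu(colSums(tab))
  opt <- names(d)[gate > 1 & d > delta]
  list(optimal = opt, delta_rscu = d, rscu_high = r_hi, rscu_low = r_lo,
       high_genes = rownames(tab)[high], low_genes = rownames(tab)[low])
}

#' Codon adaptation index (CAI)
#'
#' Relative adaptiveness w(c) = RSCU_ref(c) / max RSCU_ref in the family,
#' from a reference (high-expression) count vector; codons unobserved in
#' the reference but in an observed family get w = 0.01; families wholly
#' unobserved in the reference are excluded.  CAI is the geometric mean of
#' w over the gene's synonymous codon occurrences.
#'
#' @param gene_counts codon counts of the gene.
#' @param ref_counts pooled codon counts of the reference set.
#' @return CAI in [0, 1].
#' @export
cai <- function(gene_counts, ref_counts) {
  vg <- as_count_vector(gene_counts)
  vr <- as_count_vector(ref_counts)
  if (sum(vr) == 0) stop("empty reference set")
  ct <- codon_tables()
  syn <- ct$synonymous
  r_ref <- rscu(vr)
  w <- rep(NA_real_, 64)
  names(w) <- ct$codons
  for (a in unique(ct$aa[syn])) {
    idx <- which(syn & ct$aa == a)
    mx <- max(r_ref[ct$codons[idx]])
    if (mx <= 0) next                       # family unobserved in reference
    wi <- r_ref[ct$codons[idx]] / mx
    wi[wi == 0] <- 0.01
    w[idx] <- wi
  }
  use <- syn & !is.na(w) & vg > 0
  if (!any(use)) return(NA_real_)
  exp(sum(vg[use] * log(w[use])) / sum(vg[use]))
}

#' Frequency of optimal codons (Fop)
#'
#' @param gene_counts codon counts of the gene.
#' @param optimal character vector of optimal codons.
#' @return optimal-codon occurrences / synonymous-codon occurrences.
#' @export
fop <- function(gene_counts, optimal) {
  v <- as_count_vector(gene_counts)
  ct <- codon_tables()
  tot <- sum(v[ct$synonymous])
  if (tot == 0) return(NA_real_)
  sum(v[intersect(optimal, ct$codons[ct$synonymous])]) / tot
}

#' Codon bias index (CBI)
#'
#' CBI = (Nopt - Nrand) / (Ntot - Nrand), where Nopt is the number of
#' optimal codons used, Ntot the number of synonymous codons in families
#' containing an optimal codon, and Nrand the count expected under uniform
#' family usage.
#'
#' @inheritParams fop
#' @return CBI in [-1, 1] (negative when optimal codons are avoided).
#' @export
cbi <- function(gene_counts, optimal) {
  v <- as_count_vector(gene_counts)
  ct <- codon_tables()
  optimal <- intersect(optimal, ct$codons[ct$synonymous])
  if (!length(optimal)) return(NA_real_)
  fams <- unique(ct$aa[ct$codons %in% optimal])
  in_fam <- ct$synonymous & ct$aa %in% fams
  ntot <- sum(v[in_fam])
  nopt <- sum(v[ct$codons %in% optimal])
  nrand <- sum(vapply(fams, function(a) {
    idx <- ct$synonymous & ct$aa == a
    sum(v[idx]) * sum(ct$codons[idx] %in% optimal) / sum(idx)
  }, numeric(1)))
  if (ntot - nrand == 0) return(NA_real_)
  (nopt - nrand) / (ntot - nrand)
}

#' Per-gene codon usage index table
#'
#' Computes ENC per gene, determines the optimal-codon set (delta-RSCU
#' rule), then CAI (reference = pooled high-expression set), CBI and Fop
#' against the optimal set, along with the third-position composition.
#'
#' @param table genes x 64 codon count matrix from [codon_counts()].
#' @param tail,delta passed to [determine_optimal_codons()].
#' @return list: `indices` (data.frame gene, T3s, C3s, A3s, G3s, CAI, CBI,
#'   Fop, ENC, GC3s, GC), `optimal` (from [determine_optimal_codons()]),
#'   `rscu_overall` (pooled RSCU vector).
#' @export
codon_indices <- function(table, tail = 0.05, delta = 0.08) {
  enc_g <- apply(table, 1, enc)
  opt <- determine_optimal_codons(table, enc_by_gene = enc_g, tail = tail,
                                  delta = delta)
  ref <- colSums(table[rownames(table) %in% opt$high_genes, , drop = FALSE])
  comp <- t(apply(table, 1, composition_3s))
  idx <- data.frame(
    gene = rownames(table),
    T3s = comp[, "T3s"], C3s = comp[, "C3s"], A3s = comp[, "A3s"],
    G3s = comp[, "G3s"],
    CAI = apply(table, 1, cai, ref_counts = ref),
    CBI = apply(table, 1, cbi, optimal = opt$optimal),
    Fop = apply(table, 1, fop, optimal = opt$optimal),
    ENC = enc_g, GC3s = comp[, "GC3s"], GC = comp[, "GC"],
    row.names = NULL)
  list(indices = idx, optimal = opt, rscu_overall = rscu(colSums(table)))
}

#' ENC-plot point table
#'
#' @param table genes x 64 codon count matrix.
#' @return data.frame: gene, GC3s, ENCobs, ENCexp, deviation.
#' @export
enc_plot_points <- function(table) {
  gc3s <- apply(table, 1, function(v) composition_3s(v)[["GC3s"]])
  obs <- apply(table, 1, enc)
  exp <- enc_expected(gc3s)
  data.frame(gene = rownames(table), GC3s = gc3s, ENCobs = obs,
             ENCexp = exp, deviation = enc_deviation(obs, exp),
             row.names = NULL)
}

#' PR2-plot point table
#'
#' @param table genes x 64 codon count matrix.
#' @param mode passed to [pr2_point()].
#' @return data.frame: gene, x, y.
#' @export
pr2_plot_points <- function(table, mode = "fourfold") {
  xy <- t(apply(table, 1, pr2_point, mode = mode))
  data.frame(gene = rownames(table), x = xy[, "x"], y = xy[, "y"],
             row.names = NULL)
}

#' Pairwise correlations among codon usage indices
#'
#' @param index_table data.frame from [codon_indices()]`$indices` (or any
#'   data.frame whose numeric columns are to be correlated).
#' @param method "pearson" (default) or "spearman".
#' @return symmetric correlation matrix.
#' @export
index_correlations <- function(index_table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  num <- index_table[, vapply(index_table, is.numeric, logical(1)),
                     drop = FALSE]
  if (nrow(num) < 3L) stop("need at least 3 genes for correlations")
  stats::cor(num, use = "pairwise.complete.obs", method = method)
}
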
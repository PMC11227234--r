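## Pairwise Ka/Ks by the Nei-Gojobori (1986) method with Jukes-Cantor
## correction, plastid gene functional categories, and rank-sum group
## comparisons of Ka/Ks distributions.

#' @keywords internal
ng86_site_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- genetic_code()
    codons <- codon_universe()
    bases <- c("A", "C", "G", "T")
    syn_sites <- vapply(codons, function(cd) {
      if (gc[cd] == "*") return(NA_real_)
      s <- 0
      for (p in 1:3) {
        for (b in setdiff(bases, substr(cd, p, p))) {
          alt <- cd
          substr(alt, p, p) <- b
          if (gc[alt] == gc[cd]) s <- s + 1 / 3   # change to stop = nonsyn
        }
      }
      s
    }, numeric(1))
    cache <<- syn_sites
    cache
  }
})

#' Remove codon columns containing gaps from an aligned sequence pair
#'
#' @param a,b equal-length aligned in-frame sequences (may contain '-').
#' @return list(a, b) with every codon column containing a gap in either
#'   sequence removed.
#' @export
strip_gap_codons <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  n <- nchar(a) - nchar(a) %% 3L
  ca <- substring(a, seq(1L, n, 3L), seq(3L, n, 3L))
  cb <- substring(b, seq(1L, n, 3L), seq(3L, n, 3L))
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  list(a = paste(ca[keep], collapse = ""), b = paste(cb[keep], collapse = ""))
}

#' @keywords internal
count_path_subs <- function(ca, cb, gc) {
  ## average synonymous/nonsynonymous differences over shortest mutational
  ## pathways between two codons; pathways through stops excluded when any
  ## stop-free pathway exists
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  paths <- if (nd == 1L) list(pos) else
    lapply(asplit(do.call(rbind, lapply(
      combinat_perms(nd), function(o) pos[o])), 1), as.integer)
  eval_path <- function(ord) {
    cur <- ca
    sd <- 0; ndf <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[nxt] == "*") ok <- FALSE
      if (gc[nxt] == gc[cur]) sd <- sd + 1 else ndf <- ndf + 1
      cur <- nxt
    }
    c(sd, ndf, ok)
  }
  res <- t(vapply(paths, eval_path, numeric(3)))
  valid <- res[, 3] == 1
  if (any(valid)) res <- res[valid, , drop = FALSE]
  c(sd = mean(res[, 1]), nd = mean(res[, 2]))
}

#' @keywords internal
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    sub <- combinat_perms(n - 1L)
    for (s in sub) out[[length(out) + 1L]] <- c(i, ifelse(s >= i, s + 1L, s))
  }
  out
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Synonymous site counts are fractional per codon position (a change to a
#' stop codon counts as nonsynonymous) and averaged over both sequences;
#' codons differing at several positions are resolved by averaging over
#' shortest mutational pathways, excluding pathways through stop codons
#' when a stop-free pathway exists.  Proportions are corrected with the
#' Jukes-Cantor formula d = -(3/4) ln(1 - 4p/3); p >= 3/4 gives an
#' undefined (NA) corrected distance, and Ks = 0 gives an undefined ratio.
#'
#' @param a,b in-frame, gap-free coding sequences of equal length (use
#'   [strip_gap_codons()] on aligned input first).
#' @return list: S, N, sd, nd, pS, pN, Ks, Ka, ratio (all numeric; NA where
#'   undefined).
#' @export
ng86_kaks <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("sequence length not divisible by 3")
  if (grepl("-", paste0(a, b), fixed = TRUE)) stop("gap characters present")
  gc <- genetic_code()
  st <- ng86_site_table()
  ca <- split_codons(a); cb <- split_codons(b)
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[ok]; cb <- cb[ok]
  internal_a <- ca[-length(ca)]; internal_b <- cb[-length(cb)]
  if (length(ca) > 1L &&
      (any(gc[internal_a] == "*") || any(gc[internal_b] == "*")))
    stop("internal stop codon")
  ## terminal stop codons are excluded from site/difference counting
  drop <- gc[ca] == "*" | gc[cb] == "*"
  ca <- ca[!drop]; cb <- cb[!drop]
  if (!length(ca)) stop("no comparable codons")
  S <- (sum(st[ca]) + sum(st[cb])) / 2
  N <- 3 * length(ca) - S
  diffs <- which(ca != cb)
  sd_tot <- 0; nd_tot <- 0
  for (i in diffs) {
    d <- count_path_subs(ca[i], cb[i], gc)
    sd_tot <- sd_tot + d[["sd"]]
    nd_tot <- nd_tot + d[["nd"]]
  }
  pS <- if (S > 0) sd_tot / S else NA_real_
  pN <- if (N > 0) nd_tot / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p == 0) return(0)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  list(S = S, N = N, sd = sd_tot, nd = nd_tot, pS = pS, pN = pN,
       Ks = Ks, Ka = Ka, ratio = ratio)
}

#' Functional category of plastid genes
#'
#' Built-in mapping: photosynthesis-related (psa*, psb*, pet*, ndh*, atp*,
#' rbcL), self-replication-related (rpl*, rps*, rpo*, infA), and other
#' (matK, ccsA, cemA, accD, clpP, ycf*, ...).  Symbols matching no known
#' plastid gene family are classed "other" with a warning.
#'
#' @param genes character vector of gene symbols.
#' @return data.frame: gene, category.
#' @export
categorize_genes <- function(genes) {
  base <- sub("[-_.].*$", "", genes)
  photo <- grepl("^(psa|psb|pet|ndh|atp)", base) | base == "rbcL"
  selfrep <- grepl("^(rpl|rps|rpo)", base) | base == "infA"
  known_other <- grepl("^(ycf|trn|rrn)", base) |
    base %in% c("matK", "ccsA", "cemA", "accD", "clpP", "clpP1")
  cat <- ifelse(photo, "photosynthesis",
                ifelse(selfrep, "self-replication", "other"))
  unknown <- !photo & !selfrep & !known_other
  if (any(unknown))
    warning("unrecognized gene symbol(s) classed 'other': ",
            paste(unique(genes[unknown]), collapse = ", "))
  data.frame(gene = genes, category = cat)
}

#' @keywords internal
rank_sum_exact_p <- function(x, y) {
  ## exact two-sided permutation p for the rank-sum statistic (midranks)
  v <- c(x, y)
  r <- rank(v)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(length(v), nx)
  sums <- colSums(matrix(r[combs], nrow = nx))
  mu <- nx * (length(v) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

#' Compare Ka/Ks distributions between groups
#'
#' Two-sided rank-sum tests for every pair of groups, exact by permutation
#' enumeration when the combined sample size is at most 20, otherwise the
#' normal approximation.  Undefined ratios (NA) are excluded and counted.
#' Stars: p < 0.05 *, p < 0.01 **, p < 0.001 ***, otherwise NS.
#'
#' @param values_by_group named list of numeric Ka/Ks vectors.
#' @return data.frame: group1, group2, n1, n2, n_excluded, statistic,
#'   p_value, stars.
#' @export
group_compare <- function(values_by_group) {
  if (length(values_by_group) < 2L) stop("need at least 2 groups")
  clean <- lapply(values_by_group, function(v) v[!is.na(v)])
  excl <- vapply(values_by_group, function(v) sum(is.na(v)), integer(1))
  small <- names(clean)[vapply(clean, length, integer(1)) < 2L]
  if (length(small))
    stop("insufficient defined ratios in group(s): ",
         paste(small, collapse = ", "))
  gn <- names(clean)
  rows <- list()
  for (i in seq_len(length(gn) - 1L)) {
    for (j in (i + 1L):length(gn)) {
      x <- clean[[i]]; y <- clean[[j]]
      if (length(x) + length(y) <= 20L) {
        p <- rank_sum_exact_p(x, y)
        w <- sum(rank(c(x, y))[seq_along(x)])
      } else {
        wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
        p <- wt$p.value
        w <- unname(wt$statistic)
      }
      stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
        if (p < 0.05) "*" else "NS"
      rows[[length(rows) + 1L]] <-
        data.frame(group1 = gn[i], group2 = gn[j],
                   n1 = length(x), n2 = length(y),
                   n_excluded = excl[[i]] + excl[[j]],
                   statistic = w, p_value = p, stars = stars)
    }
  }
  do.call(rbind, rows)
}
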
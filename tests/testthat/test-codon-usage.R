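test_that("codon counting is exact and excludes ambiguity codons", {
  cc <- codon_counts(c(g1 = "ATGGCTTAA"))
  expect_equal(unname(cc[1, c("ATG", "GCT", "TAA")]), c(1L, 1L, 1L))
  expect_equal(sum(cc), 3L)
  expect_message(cc2 <- codon_counts(c(g = "ATGGCNTAA")), "ambiguity")
  expect_equal(sum(cc2), 2L)
  expect_equal(attr(cc2, "n_ambiguous"), 1L)
  ## concatenated totals equal the sum of per-gene totals
  cc3 <- codon_counts(c(a = "ATGGCTGCA", b = "ATGAAATAA"))
  expect_equal(sum(cc3), sum(codon_counts(c(x = "ATGGCTGCAATGAAATAA"))))
  expect_error(codon_counts(c(g = "ATGC")), "divisible")
})

test_that("RSCU follows the family-uniform expectation", {
  r <- rscu(c(TTT = 3, TTC = 1))
  expect_equal(r[["TTT"]], 1.5)
  expect_equal(r[["TTC"]], 0.5)
  ## equal usage in a two-fold family gives 1 for both
  r2 <- rscu(c(GAT = 5, GAC = 5))
  expect_equal(unname(r2[c("GAT", "GAC")]), c(1, 1))
  ## single-codon families are 1 when observed
  r3 <- rscu(c(ATG = 4, TGG = 2))
  expect_equal(r3[["ATG"]], 1)
  expect_equal(r3[["TGG"]], 1)
  ## family mean is 1 for every observed family (pooled random counts)
  set.seed(6)
  counts <- stats::setNames(rpois(64, 10) + 1L,
                            plastomics:::codon_universe())
  r4 <- rscu(counts)
  ct <- plastomics:::codon_tables()
  sense <- !ct$stop
  means <- tapply(r4[ct$codons[sense]], ct$aa[sense], mean)
  expect_true(all(abs(means - 1) < 1e-12))
})

test_that("third-position composition follows usage-index semantics", {
  ## only GCx codons, uniform: every base frequency is 1/4
  comp <- composition_3s(c(GCA = 5, GCC = 5, GCG = 5, GCT = 5))
  expect_equal(unname(comp[c("T3s", "C3s", "A3s", "G3s")]), rep(0.25, 4))
  expect_equal(comp[["GC3s"]], 0.5)
  ## hand-built toy: 6 Phe (TTT x4, TTC x2) + 4 Ala (GCA x3, GCG x1)
  v <- c(TTT = 4, TTC = 2, GCA = 3, GCG = 1)
  comp2 <- composition_3s(v)
  ## T3: numerator 4 (TTT); denominator: Phe (6) + Ala (4) both permit T
  expect_equal(comp2[["T3s"]], 4 / 10)
  expect_equal(comp2[["C3s"]], 2 / 10)
  ## A3: only the Ala family permits A at position 3
  expect_equal(comp2[["A3s"]], 3 / 4)
  expect_equal(comp2[["G3s"]], 1 / 4)
  expect_equal(comp2[["GC3s"]], 3 / 10)
  ## GC over all positions: hand count
  gc_hand <- (4 * 0 + 2 * 1 + 3 * 2 + 1 * 3) / (3 * 10)
  expect_equal(comp2[["GC"]], gc_hand)
  expect_equal(composition_3s(c(ATG = 3))[["T3s"]], NA_real_)
})

test_that("ENC spans 20 (fully biased) to 61 (uniform) with Wright's formula", {
  ct <- plastomics:::codon_tables()
  syn <- ct$synonymous
  ## one codon per family: ENC exactly 20
  one_per <- tapply(seq_len(64)[syn], ct$aa[syn], `[`, 1L)
  v <- stats::setNames(rep(0, 64), ct$codons)
  v[as.integer(one_per)] <- 50
  expect_equal(enc(v), 20)
  ## uniform usage with large counts: capped at 61
  v2 <- stats::setNames(rep(0, 64), ct$codons)
  v2[syn] <- 1000
  expect_equal(enc(v2), 61)
  ## hand computation on a toy with known family homozygosities:
  ## Phe TTT=3,TTC=1 (n=4, F2=(4*(9+1)/16-1)/3=1/2); all other two-fold
  ## families used 2+2 (F=1/3); Ile 2+1 (F=(3*5/9-1)/2=1/3); four-fold
  ## families 1+1+1+1 (F=0? no: n=4,sum p2=1/4,F=0) -> use 2,2,0,0
  ## (n=4, sum p2 = 1/2, F=1/3); six-fold 2,2,2,0,0,0 (n=6, sum p2=1/3,
  ## F=(2-1)/5=1/5)
  counts <- c(TTT = 3, TTC = 1,
              TAT = 2, TAC = 2, CAT = 2, CAC = 2, CAA = 2, CAG = 2,
              AAT = 2, AAC = 2, AAA = 2, AAG = 2, GAT = 2, GAC = 2,
              GAA = 2, GAG = 2, TGT = 2, TGC = 2,
              ATT = 2, ATC = 1,
              GTT = 2, GTC = 2, CCT = 2, CCC = 2, ACT = 2, ACC = 2,
              GCT = 2, GCC = 2, GGT = 2, GGC = 2,
              TTA = 2, TTG = 2, CTT = 2,
              TCT = 2, TCC = 2, TCA = 2,
              CGT = 2, CGC = 2, CGA = 2)
  F2 <- mean(c(1 / 2, rep(1 / 3, 8)))
  F3 <- 1 / 3
  F4 <- 1 / 3
  F6 <- 1 / 5
  expect_equal(enc(counts), 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6)
  ## too few codons: undefined
  expect_true(is.na(enc(c(TTT = 1))))
})

test_that("expected-ENC curve evaluates the printed formula", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  expect_error(enc_expected(1.2))
  expect_equal(enc_deviation(60, 60), 0)
  expect_equal(enc_deviation(54, 60), 0.1)
  expect_equal(enc_deviation(66, 60), -0.1)
  expect_true(is.na(enc_deviation(50, 0)))
})

test_that("genes under pure GC3 mutational bias sit on the expected-ENC curve", {
  ## sample synonymous codons with third-position GC probability gc3,
  ## uniform otherwise - the construction behind the ENC-plot diagnostic
  set.seed(314)
  ct <- plastomics:::codon_tables()
  pool <- ct$codons[!ct$stop]
  for (gc3 in c(0.2, 0.5, 0.8)) {
    w <- ifelse(substr(pool, 3, 3) %in% c("G", "C"), gc3 / 2, (1 - gc3) / 2)
    gene <- paste(sample(pool, 30000, replace = TRUE, prob = w),
                  collapse = "")
    cc <- codon_counts(c(g = gene))[1, ]
    gc3s_obs <- composition_3s(cc)[["GC3s"]]
    expect_lt(abs(enc(cc) - enc_expected(gc3s_obs)), 1.5)
  }
})

test_that("PR2 coordinates use fourfold boxes with flagged degenerate cases", {
  ## balanced: A3 = T3 and G3 = C3 within fourfold boxes
  p <- pr2_point(c(GCA = 2, GCT = 2, GCG = 3, GCC = 3))
  expect_equal(unname(p), c(0.5, 0.5))
  ## G3 = 3, C3 = 1, A3 = 1, T3 = 4 -> x = 0.75, y = 0.2
  p2 <- pr2_point(c(GTG = 3, GTC = 1, GTA = 1, GTT = 4))
  expect_equal(p2[["x"]], 0.75)
  expect_equal(p2[["y"]], 0.2)
  ## no fourfold codons: undefined coordinates
  p3 <- pr2_point(c(TTT = 3, TTC = 2, ATG = 1))
  expect_true(all(is.na(p3)))
  ## all-codon mode counts the two-fold families too
  p4 <- pr2_point(c(TTT = 3, TTC = 1), mode = "all")
  expect_equal(p4[["y"]], 0)          # no A3 among synonymous codons
})

test_that("optimal codons require RSCU_high > 1 and delta-RSCU > 0.08", {
  ct <- plastomics:::codon_tables()
  make_gene <- function(codon_weights, n = 600) {
    cd <- sample(names(codon_weights), n, replace = TRUE,
                 prob = codon_weights)
    tab <- table(factor(cd, levels = ct$codons))
    as.integer(tab)
  }
  set.seed(41)
  ## 50 genes covering all degeneracy classes: strongly biased genes use
  ## GCT exclusively in the Ala family, weak genes use it uniformly
  biased <- c(GCT = 1, TTT = 1, AAA = 1, GAA = 1, CAA = 1, GGT = 1,
              CTT = 1, TCT = 1, CGT = 1, ATT = 1)
  uniform <- c(GCT = 0.25, GCA = 0.25, GCC = 0.25, GCG = 0.25,
               TTT = 0.5, TTC = 0.5, AAA = 0.5, AAG = 0.5,
               GAA = 0.5, GAG = 0.5, CAA = 0.5, CAG = 0.5,
               GGT = 0.25, GGA = 0.25, GGC = 0.25, GGG = 0.25,
               CTT = 1 / 3, CTA = 1 / 3, TTG = 1 / 3,
               TCT = 1 / 3, TCA = 1 / 3, AGT = 1 / 3,
               CGT = 1 / 3, CGA = 1 / 3, AGA = 1 / 3,
               ATT = 1 / 3, ATC = 1 / 3, ATA = 1 / 3)
  tab <- rbind(
    t(replicate(5, make_gene(biased))),
    t(replicate(45, make_gene(uniform))))
  colnames(tab) <- ct$codons
  rownames(tab) <- paste0("g", 1:50)
  encs <- apply(tab, 1, enc)
  expect_true(all(order(encs)[1:3] %in% 1:5))  # biased genes rank lowest
  opt <- determine_optimal_codons(tab, encs)
  expect_true("GCT" %in% opt$optimal)
  expect_false("GCA" %in% opt$optimal)
  ## identical usage in both sets: no optimal codons
  tab2 <- t(replicate(50, make_gene(uniform)))
  colnames(tab2) <- ct$codons
  rownames(tab2) <- paste0("u", 1:50)
  opt2 <- determine_optimal_codons(tab2, rep(c(55, 56), 25))
  expect_true(all(abs(opt2$delta_rscu[opt2$optimal]) <= 0.3))
  ## a constructed delta of 0.05 is below the threshold
  r_hi <- c(GCT = 1.05); r_lo <- c(GCT = 1.00)
  expect_false(1.05 - 1.00 > 0.08)
  expect_error(determine_optimal_codons(tab[1:20, ]), "40")
})

test_that("CAI, CBI and Fop behave at their extremes and on hand toys", {
  ## reference uses only GCT (Ala) and TTT (Phe)
  ref <- c(GCT = 30, TTT = 30)
  ## gene using only family-maximal reference codons: CAI = 1
  expect_equal(cai(c(GCT = 5, TTT = 5), ref), 1)
  ## hand toy: gene with GCT=2, GCA=1 -> w(GCT)=1, w(GCA)=0.01
  expect_equal(cai(c(GCT = 2, GCA = 1), ref),
               exp((2 * log(1) + 1 * log(0.01)) / 3))
  opt <- c("GCT", "TTT")
  ## only optimal codons: Fop = CBI = 1
  expect_equal(fop(c(GCT = 4, TTT = 6), opt), 1)
  expect_equal(cbi(c(GCT = 4, TTT = 6), opt), 1)
  ## no optimal codons: Fop = 0 and CBI < 0
  expect_equal(fop(c(GCA = 4, TTC = 6), opt), 0)
  expect_lt(cbi(c(GCA = 4, TTC = 6), opt), 0)
  ## CBI hand computation: Ala family n=4 (GCT=3), Phe n=2 (TTT=1)
  ## Nopt=4, Ntot=6, Nrand=4*(1/4)+2*(1/2)=2 -> (4-2)/(6-2)=0.5
  expect_equal(cbi(c(GCT = 3, GCA = 1, TTT = 1, TTC = 1), opt), 0.5)
  expect_error(cai(c(GCT = 1), c(GCT = 0)), "empty")
})

test_that("index correlations are exact for constructed columns", {
  set.seed(17)
  x <- rnorm(20)
  tab <- data.frame(A = x, B = x, C = -2 * x + 3, D = rnorm(20))
  m <- index_correlations(tab)
  expect_equal(m["A", "B"], 1)
  expect_equal(m["A", "C"], -1)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(A = 1, B = 1, C = 1, D = 1))
  ## closed-form Pearson on a random pair
  num <- sum((tab$A - mean(tab$A)) * (tab$D - mean(tab$D)))
  den <- sqrt(sum((tab$A - mean(tab$A))^2) * sum((tab$D - mean(tab$D))^2))
  expect_equal(m["A", "D"], num / den)
  expect_error(index_correlations(tab[1:2, ]), "3")
})

test_that("ENC of random synonymous-uniform genes converges to 61 from below", {
  set.seed(2718)
  ct <- plastomics:::codon_tables()
  pool <- ct$codons[ct$synonymous]
  encs <- vapply(c(200, 2000, 10000), function(n) {
    cc <- table(factor(sample(pool, n, replace = TRUE), levels = ct$codons))
    enc(stats::setNames(as.numeric(cc), names(cc)))
  }, numeric(1))
  expect_gt(encs[3], 60.5)
  expect_true(all(encs <= 61))
})
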
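test_that("SSR scanner applies MISA thresholds, maximality and primitivity", {
  flank1 <- "GCGTCGCGTC"; flank2 <- "CGTGCGGTCG"
  ## mono run of 9 is below the threshold of 10
  expect_equal(nrow(find_ssrs(genome("a9", paste0(flank1, strrep("A", 9),
                                                  flank2)))), 0L)
  ## mono run of 12 is one locus with 12 copies
  s12 <- find_ssrs(genome("a12", paste0(flank1, strrep("A", 12), flank2)))
  expect_equal(nrow(s12), 1L)
  expect_equal(s12$motif, "A")
  expect_equal(s12$copies, 12L)
  expect_equal(s12$start, 11L)
  expect_equal(s12$end, 22L)
  ## (AT)6 is a di-nucleotide locus, never reported as the tetra ATAT
  at6 <- find_ssrs(genome("at6", paste0(flank1, strrep("AT", 6), "GG",
                                        flank2)))
  expect_equal(at6$motif, "AT")
  expect_equal(at6$unit_class, "di")
  expect_equal(at6$copies, 6L)
  ## partial trailing unit does not add a copy
  at6b <- find_ssrs(genome("at6b", paste0(flank1, strrep("AT", 6), "AGG",
                                          flank2)))
  expect_equal(at6b$copies, 6L)
  expect_equal(at6b$length, 12L)
})

test_that("SSR scanner agrees with the regex oracle on random sequences", {
  set.seed(1234)
  for (rep in 1:12) {
    seq <- random_seq(5000, gc = 0.3)     # AT-rich like a plastome
    got <- find_ssrs(genome("r", seq))
    want <- ssr_oracle(seq)
    expect_equal(got[, c("motif", "unit_len", "copies", "start", "end")],
                 want, ignore_attr = TRUE)
  }
})

test_that("dispersed repeats: planted pairs, kinds and mismatch budget", {
  set.seed(55)
  u <- random_seq(40)
  bg1 <- random_seq(150); bg2 <- random_seq(300); bg3 <- random_seq(150)
  ## forward pair: a maximal forward window covers both planted copies
  ## (maximal windows may extend into the flanks up to the mismatch budget)
  gf <- genome("f", paste0(bg1, u, bg2, u, bg3))
  df <- find_dispersed_repeats(gf)
  expect_true(any(df$kind == "forward" & df$length >= 40 &
                    df$start1 <= 151 & df$end1 >= 190 &
                    df$start2 <= 491 & df$end2 >= 530))
  ## palindromic pair
  gp <- genome("p", paste0(bg1, u, bg2, revcomp_chr(u), bg3))
  dp <- find_dispersed_repeats(gp)
  expect_true(any(dp$kind == "palindromic" & dp$length >= 40))
  expect_false(any(dp$kind == "forward" & dp$length >= 40))
  ## a copy with 4 mismatches is not reported at budget 3
  u4 <- strsplit(u, "")[[1]]
  for (i in c(5L, 15L, 25L, 35L))
    u4[i] <- setdiff(c("A", "C", "G", "T"), u4[i])[1]
  g4 <- genome("m4", paste0(bg1, u, bg2, paste(u4, collapse = ""), bg3))
  d4 <- find_dispersed_repeats(g4)
  expect_false(any(d4$length >= 40))
})

test_that("dispersed scanner agrees with the all-pairs Hamming oracle", {
  set.seed(777)
  for (rep in 1:4) {
    seq <- random_seq(800, gc = 0.4)
    got <- find_dispersed_repeats(genome("r", seq), min_len = 12,
                                  max_mismatch = 2)
    want <- dispersed_oracle(seq, min_len = 12, max_mismatch = 2)
    expect_equal(repeat_key(got), repeat_key(want))
  }
})

test_that("genome reversal maps forward to forward, palindromic to palindromic", {
  set.seed(88)
  u <- random_seq(35)
  s <- paste0(random_seq(120), u, random_seq(200), u, random_seq(80),
              revcomp_chr(u), random_seq(50))
  g1 <- genome("fw", s)
  g2 <- genome("rv", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  d1 <- find_dispersed_repeats(g1)
  d2 <- find_dispersed_repeats(g2)
  expect_equal(sum(d1$kind == "forward"), sum(d2$kind == "forward"))
  expect_equal(sum(d1$kind == "palindromic"), sum(d2$kind == "palindromic"))
  expect_equal(sum(d1$kind == "reverse"), sum(d2$kind == "reverse"))
})

test_that("tandem arrays: exact copies, fractional tails, range limits", {
  unit <- "ACGTGATCGTAG"            # 12 nt, primitive
  g <- genome("t1", paste0("CCGGCCGGCC", strrep(unit, 3), "CCGGTTCCGG"))
  tr <- find_tandem_repeats(g)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$unit, unit)
  expect_equal(tr$copies, 3.0)
  expect_equal(tr$span, 36L)
  ## 2.5 copies: half-unit tail counts fractionally
  g2 <- genome("t2", paste0("CCGGCCGGCC", strrep(unit, 2),
                            substr(unit, 1, 6), "CCGGTTCCGG"))
  tr2 <- find_tandem_repeats(g2)
  expect_equal(tr2$copies, 2.5)
  expect_equal(tr2$span, 30L)
  ## mono-run belongs to SSRs, not tandem arrays
  g3 <- genome("t3", paste0("GCGC", strrep("A", 30), "CGCG"))
  expect_equal(nrow(find_tandem_repeats(g3)), 0L)
})

test_that("repeat summaries give hand-tallied proportions", {
  ssrs <- data.frame(motif = c("A", "T", "AT", "AAT"),
                     unit_class = c("mono", "mono", "di", "tri"),
                     unit_len = c(1L, 1L, 2L, 3L),
                     copies = c(10L, 11L, 5L, 4L),
                     start = c(100L, 2000L, 5000L, 12500L),
                     end = c(109L, 2010L, 5009L, 12511L),
                     length = c(10L, 11L, 10L, 12L),
                     region = c("LSC", "LSC", "LSC", "SSC"),
                     context = c("intergenic", "exon", "intergenic",
                                 "intron"))
  sm <- summarize_repeats(ssrs = ssrs)
  expect_equal(sm$ssr_by_class$proportion[sm$ssr_by_class$level == "mono"],
               0.5)
  expect_equal(sm$ssr_by_region$count[sm$ssr_by_region$level == "LSC"], 3L)
  expect_equal(sm$ssr_by_region$proportion[sm$ssr_by_region$level == "SSC"],
               0.25)
  expect_equal(sum(sm$ssr_by_class$proportion), 1)
  expect_equal(sum(sm$ssr_by_context$proportion), 1)
  ## empty input: all-zero summary
  sm0 <- summarize_repeats(ssrs = ssrs[0, ])
  expect_true(all(sm0$ssr_by_class$count == 0L))
  ## kind proportions across repeat types
  disp <- data.frame(kind = c("forward", "forward", "palindromic"))
  tand <- data.frame(unit = c("x", "y"))
  smk <- summarize_repeats(ssrs = ssrs, dispersed = disp, tandem = tand)
  expect_equal(sum(smk$by_kind$count), 9L)
  expect_equal(smk$by_kind$proportion[smk$by_kind$kind == "tandem"], 2 / 9)
})

test_that("planted SSR tracts in simulated genomes are recovered exactly", {
  sim <- mini_sim(seed = 41, tree = "(a:0.01,b:0.01);")
  found <- find_ssrs(sim$root)
  planted <- sim$planted$ssrs
  for (i in seq_len(nrow(planted))) {
    hit <- found[found$start == planted$start[i] + 1L, , drop = FALSE]
    expect_equal(nrow(hit), 1L,
                 label = paste("planted tract", i, "found once"))
    expect_equal(hit$motif, planted$motif[i])
    expect_equal(hit$copies, planted$copies[i])
  }
})
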
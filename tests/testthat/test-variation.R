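test_that("pairwise variant calling compacts gap runs and reports 1-based positions", {
  aln <- c(ref = "ACGT", s = "ACTT")
  v <- pairwise_variants(aln, "ref")
  expect_equal(v$kind, "SNV")
  expect_equal(v$pos, 3L)
  expect_equal(v$ref, "G"); expect_equal(v$alt, "T")

  ## insertion: one gap run in the reference = one event of length 2
  v2 <- pairwise_variants(c(ref = "AC--GT", s = "ACTTGT"), "ref")
  expect_equal(v2$kind, "insertion")
  expect_equal(v2$pos, 2L)
  expect_equal(v2$length, 2L)
  expect_equal(v2$alt, "TT")

  ## deletion: one gap run in the sample = one event
  v3 <- pairwise_variants(c(ref = "ACGTGT", s = "AC---T"), "ref")
  expect_equal(v3$kind, "deletion")
  expect_equal(v3$pos, 3L)
  expect_equal(v3$length, 3L)
  expect_equal(v3$ref, "GTG")

  ## adjacent SNV columns stay individual SNVs
  v4 <- pairwise_variants(c(ref = "AAGGTT", s = "AATTTT"), "ref")
  expect_equal(v4$kind, c("SNV", "SNV"))
  expect_equal(v4$pos, c(3L, 4L))

  ## ambiguity columns are skipped and counted
  v5 <- pairwise_variants(c(ref = "ANGT", s = "ATGT"), "ref")
  expect_equal(nrow(v5), 0L)
  expect_equal(attr(v5, "skipped")[["s"]], 1L)
  expect_error(pairwise_variants(aln, "nope"), "not in alignment")
})

test_that("InDels are left-aligned within homopolymer context", {
  ## deletion of one A from an A-run reports the leftmost placement
  v <- pairwise_variants(c(ref = "GAAAAC", s = "GA-AAC"), "ref")
  expect_equal(v$kind, "deletion")
  expect_equal(v$pos, 2L)
  ## insertion of an A into an A-run anchors before the run
  v2 <- pairwise_variants(c(ref = "GAA-AC", s = "GAAAAC"), "ref")
  expect_equal(v2$kind, "insertion")
  expect_equal(v2$pos, 1L)
  expect_equal(v2$alt, "A")
})

test_that("per-kb rates assign variants to regions and normalize by kb", {
  regions <- data.frame(region = c("LSC", "IRb", "SSC", "IRa"),
                        start = c(0L, 5000L, 7000L, 9000L),
                        end = c(5000L, 7000L, 9000L, 11000L))
  regions$length <- regions$end - regions$start
  p <- structure(list(found = TRUE, regions = regions, ir_len = 2000L,
                      mismatches = 0L, genome_length = 11000L,
                      genome_id = "x"), class = "region_partition")
  vars <- data.frame(sample = "s", kind = rep("SNV", 10L),
                     pos = seq(100L, 4600L, by = 500L), length = 1L,
                     ref = "A", alt = "C")
  r <- per_kb_rates(vars, p)
  expect_equal(r$rate[r$region == "LSC" & r$kind == "SNV"], 2.0)
  expect_equal(r$count[r$region == "whole" & r$kind == "SNV"], 10L)
  expect_equal(sum(r$count[r$region %in% c("LSC", "SSC", "IR") &
                             r$kind == "SNV"]),
               r$count[r$region == "whole" & r$kind == "SNV"])
  r0 <- per_kb_rates(vars[0, ], p)
  expect_true(all(r0$rate == 0))
  ## hand tally of a mixed fixture
  vars2 <- data.frame(sample = "s", kind = c("SNV", "deletion", "insertion",
                                             "SNV"),
                      pos = c(100L, 5500L, 8000L, 9500L),
                      length = c(1L, 3L, 2L, 1L), ref = "", alt = "")
  r2 <- per_kb_rates(vars2, p)
  expect_equal(r2$count[r2$region == "IR" & r2$kind == "deletion"], 1L)
  expect_equal(r2$rate[r2$region == "IR" & r2$kind == "SNV"], 1 / 4)
  expect_equal(r2$rate[r2$region == "SSC" & r2$kind == "insertion"], 0.5)
  expect_error(per_kb_rates(transform(vars, pos = 20000L), p), "outside")
})

test_that("variant contexts and percentages follow the annotation", {
  set.seed(12)
  g <- genome("c", random_seq(2000))
  ag <- annotated_genome(g, rbind(
    feature("gene", "g1", data.frame(start = 100L, end = 500L)),
    feature("CDS", "g1", data.frame(start = c(100L, 300L),
                                    end = c(200L, 500L)))))
  vars <- data.frame(sample = "s",
                     kind = c(rep("insertion", 9L), "insertion", "SNV"),
                     pos = c(seq(600L, 1400L, by = 100L), 150L, 250L),
                     length = 1L, ref = "", alt = "A")
  out <- locate_variants(vars, ag)
  expect_equal(out$variants$context[10], "exon")
  expect_equal(out$variants$context[11], "intron")
  ins <- out$summary[out$summary$kind == "insertion", ]
  expect_equal(ins$count[ins$context == "intergenic"], 9L)
  expect_equal(ins$percent[ins$context == "intergenic"], 90)
  expect_equal(ins$percent[ins$context == "exon"], 10)
})

test_that("InDel frame classification counts multiples of three", {
  vars <- data.frame(kind = c("deletion", "insertion", "deletion", "SNV"),
                     length = c(3L, 6L, 2L, 1L))
  fc <- indel_frame_classification(vars)
  expect_equal(fc$n_multiple_of_3, 2L)
  expect_equal(fc$n_total, 3L)
  expect_equal(fc$fraction, 2 / 3)
  fc0 <- indel_frame_classification(vars[vars$kind == "SNV", ])
  expect_equal(fc0$n_total, 0L)
  expect_true(is.na(fc0$fraction))
  ## brute-force check on a random fixture
  set.seed(3)
  lens <- sample(1:12, 60, replace = TRUE)
  v <- data.frame(kind = "deletion", length = lens)
  expect_equal(indel_frame_classification(v)$n_multiple_of_3,
               sum(lens %% 3 == 0))
})

test_that("sliding-window pi matches direct formula and brute force", {
  ## identical sequences: pi = 0 everywhere
  a0 <- c(a = strrep("ACGT", 300), b = strrep("ACGT", 300))
  expect_true(all(sliding_window_pi(a0)$pi == 0))
  ## single difference in a fully usable 600 bp window: pi = 1/600
  s <- strrep("ACGT", 150)
  a1 <- c(a = s, b = paste0("T", substr(s, 2, 600)))
  expect_equal(sliding_window_pi(a1)$pi[1], 1 / 600)
  ## n = 4 toy alignment against the brute-force pairwise oracle
  set.seed(99)
  base <- random_seq(1500)
  mut <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), n)
    ch[at] <- vapply(ch[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
  }
  aln <- c(w = base, x = mut(base, 25), y = mut(base, 40), z = mut(base, 10))
  prof <- sliding_window_pi(aln, window = 600, step = 200)
  for (i in seq_len(nrow(prof)))
    expect_equal(prof$pi[i], pi_oracle(aln, prof$start[i], prof$end[i]))
  ## pi is invariant under sample reordering
  prof2 <- sliding_window_pi(aln[c(3, 1, 4, 2)], window = 600, step = 200)
  expect_equal(prof$pi, prof2$pi)
  ## gap/ambiguity columns are excluded for all pairs (complete deletion)
  ## column 5 (gap in b) and column 7 (N in c) are dropped for all pairs
  g1 <- c(a = "AAAAAAAAAA", b = "AAAA-AAAAT", c = "AAAAAANAAA")
  p3 <- sliding_window_pi(g1, window = 10, step = 10)
  expect_equal(p3$usable, 8)
  expect_equal(p3$pi, (1 + 1 + 0) / (3 * 8))
  expect_error(sliding_window_pi(c(a = "ACGT")), "at least 2")
})

test_that("final partial windows need at least half the window length", {
  rows <- c(a = strrep("A", 1000), b = strrep("A", 1000))
  prof <- sliding_window_pi(rows, window = 600, step = 200)
  ## starts 1, 201, 401, 601 (width 400) but not 801 (width 200)
  expect_equal(prof$start, c(1, 201, 401, 601))
  expect_equal(prof$end[4], 1000)
})

test_that("hotspot calling merges consecutive windows above the threshold", {
  prof <- structure(data.frame(start = c(1, 201, 401, 601, 801),
                               end = c(600, 800, 1000, 1200, 1400),
                               mid = c(300, 500, 700, 900, 1100),
                               pi = c(0, 0.012, 0.015, 0, 0.02),
                               usable = 600),
                    class = c("pi_profile", "data.frame"))
  hs <- call_hotspots(prof, threshold = 0.010)
  expect_equal(nrow(hs), 2L)
  expect_equal(hs$start[1], 201); expect_equal(hs$end[1], 1000)
  expect_equal(hs$peak_pi[1], 0.015)
  expect_equal(hs$n_windows[1], 2L)
  ## exactly at the threshold does not qualify (strictly greater than)
  prof$pi <- c(0, 0.010, 0, 0, 0)
  expect_equal(nrow(call_hotspots(prof, threshold = 0.010)), 0L)
  prof$pi <- rep(0, 5)
  expect_equal(nrow(call_hotspots(prof)), 0L)
  ## single qualifying window spans just that window
  prof$pi <- c(0, 0.012, 0, 0, 0)
  hs1 <- call_hotspots(prof)
  expect_equal(hs1$start, 201); expect_equal(hs1$end, 800)
})

test_that("region rate recovery: IR stays below single-copy rates", {
  sim <- mini_sim(seed = 5, tree = "(a:0.4,b:0.4);",
                  sub_rate = 0.01, indel_rate = 0.001)
  v <- pairwise_variants(sim$alignment, "root")
  r <- per_kb_rates(v, sim$partition)
  snv <- r[r$kind == "SNV", ]
  expect_lt(snv$rate[snv$region == "IR"],
            snv$rate[snv$region == "LSC"])
  expect_lt(snv$rate[snv$region == "IR"],
            snv$rate[snv$region == "SSC"])
})
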
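## Constructed quadripartite genome with non-extendable IR flanks
make_quad <- function(lsc = 10000L, ir = 2000L, ssc = 3000L, seed = 11L) {
  set.seed(seed)
  repeat {
    lsc_s <- random_seq(lsc); irb_s <- random_seq(ir); ssc_s <- random_seq(ssc)
    ira_s <- revcomp_chr(irb_s)
    ## reject flanks that would let the IR pair extend
    lastL <- substr(lsc_s, lsc, lsc)
    firstS <- substr(ssc_s, 1, 1); lastS <- substr(ssc_s, ssc, ssc)
    ok1 <- substr(ssc_s, 1, 1) != chartr("ACGT", "TGCA", lastS)
    if (ok1) break
  }
  list(genome = genome("q", paste0(lsc_s, irb_s, ssc_s, ira_s)),
       bounds = c(lsc = lsc, ir = ir, ssc = ssc))
}

test_that("detect_partition recovers constructed boundaries exactly", {
  q <- make_quad()
  p <- detect_partition(q$genome)
  expect_true(p$found)
  expect_equal(p$ir_len, 2000L)
  expect_equal(p$mismatches, 0L)
  expect_equal(p$regions$region, c("LSC", "IRb", "SSC", "IRa"))
  expect_equal(p$regions$start, c(0L, 10000L, 12000L, 15000L))
  expect_equal(p$regions$end, c(10000L, 12000L, 15000L, 17000L))
  ## partition tiles the genome
  expect_equal(sum(p$regions$length), q$genome$length)
  ## IR reverse-complement identity at the reported mismatch budget
  s <- q$genome$sequence
  irb <- substr(s, 10001, 12000); ira <- substr(s, 15001, 17000)
  expect_equal(revcomp_chr(irb), ira)
})

test_that("random sequence yields a no-structure result, not an error", {
  set.seed(23)
  p <- detect_partition(genome("r", random_seq(20000)))
  expect_false(p$found)
  expect_null(p$regions)
})

test_that("mismatch budget controls recovery of an imperfect IR", {
  q <- make_quad(seed = 31)
  s <- strsplit(q$genome$sequence, "")[[1]]
  ## plant one mismatch inside IRb (not mirrored into IRa)
  pos <- 11000L
  s[pos] <- setdiff(c("A", "C", "G", "T"), s[pos])[1]
  g <- genome("qm", paste(s, collapse = ""))
  p1 <- detect_partition(g, max_mismatch = 1L)
  expect_true(p1$found)
  expect_equal(p1$regions$start, c(0L, 10000L, 12000L, 15000L))
  expect_equal(p1$mismatches, 1L)
  ## with a zero budget, the longest exact sub-pair wins
  p0 <- detect_partition(g, max_mismatch = 0L)
  expect_true(p0$found)
  expect_equal(p0$mismatches, 0L)
  expect_equal(p0$ir_len, 12000L - pos)   # 11001..12000 vs its IRa partner
})

test_that("region_gc computes exact per-region fractions and weighted mean", {
  g <- genome("gc", paste0(strrep("G", 1000), strrep("AT", 300),
                           strrep("A", 500), strrep("AT", 300)))
  regions <- data.frame(region = c("LSC", "IRb", "SSC", "IRa"),
                        start = c(0L, 1000L, 1600L, 2100L),
                        end = c(1000L, 1600L, 2100L, 2700L))
  regions$length <- regions$end - regions$start
  p <- structure(list(found = TRUE, regions = regions, ir_len = 600L,
                      mismatches = 0L, genome_length = g$length,
                      genome_id = "gc"), class = "region_partition")
  gc <- region_gc(g, p)
  expect_equal(gc$gc[gc$region == "LSC"], 1.0)     # all G
  expect_equal(gc$gc[gc$region == "IRb"], 0.0)     # AT only
  expect_equal(gc$gc[gc$region == "SSC"], 0.0)
  ## whole-genome GC equals the length-weighted mean over regions
  per <- gc[gc$region %in% c("LSC", "IRb", "SSC", "IRa"), ]
  expect_equal(gc$gc[gc$region == "total"],
               sum(per$gc * per$length) / sum(per$length))
  expect_equal(plastomics::region_gc(genome("x", "ATGC"), p = {
    r <- data.frame(region = c("LSC", "IRb", "SSC", "IRa"),
                    start = c(0L, 1L, 2L, 3L), end = c(1L, 2L, 3L, 4L))
    r$length <- 1L
    structure(list(found = TRUE, regions = r, genome_length = 4L,
                   genome_id = "x"), class = "region_partition")
  })$gc[6], 0.5)
})

test_that("junction_report finds spanning genes, splits and distances", {
  q <- make_quad(seed = 47)
  L <- q$genome$length
  feats <- rbind(
    ## spans JSA (SSC/IRa at 15000): 400 nt in SSC, 100 nt in IRa
    feature("gene", "ycf1", data.frame(start = 14600L, end = 15100L)),
    ## entirely inside LSC, ending 50 nt before JLB (10000)
    feature("gene", "lscgene", data.frame(start = 9700L, end = 9950L)),
    ## first gene downstream of JLB inside IRb
    feature("gene", "irgene", data.frame(start = 10120L, end = 10400L)),
    ## two genes overlapping across JSB (12000)
    feature("gene", "psiA", data.frame(start = 11900L, end = 12050L),
            pseudo = TRUE),
    feature("gene", "ndhF", data.frame(start = 12020L, end = 12600L)))
  ag <- annotated_genome(q$genome, feats)
  p <- detect_partition(q$genome)
  jr <- junction_report(ag, p)
  jsa <- jr[jr$junction == "JSA", ]
  expect_equal(jsa$spanning_gene, "ycf1")
  expect_equal(jsa$split_upstream, 400L)
  expect_equal(jsa$split_downstream, 100L)
  ## split lengths sum to the gene length
  expect_equal(jsa$split_upstream + jsa$split_downstream, 500L)
  jlb <- jr[jr$junction == "JLB", ]
  expect_true(is.na(jlb$spanning_gene))
  expect_equal(jlb$nearest_upstream, "lscgene")
  expect_equal(jlb$dist_upstream, 50L)
  expect_equal(jlb$nearest_downstream, "irgene")
  expect_equal(jlb$dist_downstream, 120L)
  jsb <- jr[jr$junction == "JSB", ]
  expect_equal(jsb$spanning_gene, "psiA")
  expect_true(jsb$overlap)
  expect_match(jsb$overlap_genes, "ndhF")
})

test_that("a gene ending exactly at a junction belongs upstream", {
  q <- make_quad(seed = 53)
  ag <- annotated_genome(q$genome,
                         feature("gene", "edge",
                                 data.frame(start = 9900L, end = 10000L)))
  p <- detect_partition(q$genome)
  jr <- junction_report(ag, p)
  jlb <- jr[jr$junction == "JLB", ]
  expect_true(is.na(jlb$spanning_gene))
  expect_equal(jlb$dist_upstream, 0L)
})

test_that("simulated genomes recover planted boundaries and junction splits", {
  sim <- mini_sim(seed = 77, tree = "(a:0.05,b:0.05);")
  p <- detect_partition(sim$root)
  expect_equal(p$regions$start, sim$partition$regions$start)
  expect_equal(p$regions$end, sim$partition$regions$end)
  jr <- junction_report(sim$root, p)
  planted <- sim$planted$junction
  expect_equal(jr$spanning_gene[jr$junction == "JLB"], "rps19")
  expect_equal(jr$split_upstream[jr$junction == "JLB"],
               planted$split_upstream[planted$gene == "rps19"])
  expect_equal(jr$split_downstream[jr$junction == "JLB"],
               planted$split_downstream[planted$gene == "rps19"])
  expect_equal(jr$spanning_gene[jr$junction == "JSA"], "ycf1")
  expect_equal(jr$split_upstream[jr$junction == "JSA"],
               planted$split_upstream[planted$gene == "ycf1"])
})
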
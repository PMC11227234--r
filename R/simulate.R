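## Synthetic plastome generator and evolver.
##
## Builds an annotated quadripartite genome (LSC + IRb + SSC + IRa, IRa the
## exact reverse complement of IRb) carrying a realistic plastid gene model
## (junction-spanning rps19 and ycf1 with their IR pseudogene fragments,
## intron-containing genes, planted SSR tracts and dispersed repeats), then
## evolves it along a phylogeny with region-specific substitution and InDel
## rates, purifying selection on coding positions, SSR slippage, and
## concerted evolution of the two IR copies (copy correction).  Every event
## is logged in root-reference coordinates; replaying the log reproduces
## each tip sequence exactly.

## Gene model: name, key, length (nt; CDS include the stop codon),
## introns, strand, region.  Lengths follow typical angiosperm plastomes.
#' @keywords internal
plastid_gene_table <- function(model = c("full", "mini")) {
  model <- match.arg(model)
  g <- function(name, key, len, introns = 0L, strand = "+")
    data.frame(name = name, key = key, len = as.integer(len),
               introns = as.integer(introns), strand = strand)
  if (model == "mini") {
    return(list(
      lsc = rbind(g("psbA", "CDS", 1062, strand = "-"),
                  g("rbcL", "CDS", 1428), g("psbD", "CDS", 1062),
                  g("rps4", "CDS", 606, strand = "-"),
                  g("clpP", "CDS", 591, 2, "-"),
                  g("trnK-UUU", "tRNA", 72, 1, "-"),
                  g("trnF-GAA", "tRNA", 73)),
      ir = rbind(g("rrn16", "rRNA", 1490), g("trnV-GAC", "tRNA", 72)),
      ssc = rbind(g("ndhF", "CDS", 2241, strand = "-"),
                  g("psaC", "CDS", 246, strand = "-"))))
  }
  lsc <- rbind(
    g("psbA", "CDS", 1062, strand = "-"), g("matK", "CDS", 1530, strand = "-"),
    g("rps16", "CDS", 261, 1, "-"), g("psbK", "CDS", 186),
    g("psbI", "CDS", 111), g("atpA", "CDS", 1524, strand = "-"),
    g("atpF", "CDS", 555, 1, "-"), g("atpH", "CDS", 246, strand = "-"),
    g("atpI", "CDS", 744, strand = "-"), g("rps2", "CDS", 711, strand = "-"),
    g("rpoC2", "CDS", 4140, strand = "-"), g("rpoC1", "CDS", 2046, 1, "-"),
    g("rpoB", "CDS", 3213, strand = "-"), g("petN", "CDS", 90),
    g("psbM", "CDS", 105, strand = "-"), g("psbD", "CDS", 1062),
    g("psbC", "CDS", 1386), g("psbZ", "CDS", 189),
    g("rps14", "CDS", 303, strand = "-"), g("psaB", "CDS", 2205, strand = "-"),
    g("psaA", "CDS", 2253, strand = "-"), g("ycf3", "CDS", 507, 2, "-"),
    g("rps4", "CDS", 606, strand = "-"), g("ndhJ", "CDS", 480, strand = "-"),
    g("ndhK", "CDS", 678, strand = "-"), g("ndhC", "CDS", 363, strand = "-"),
    g("atpE", "CDS", 402, strand = "-"), g("atpB", "CDS", 1497, strand = "-"),
    g("rbcL", "CDS", 1428), g("accD", "CDS", 1467),
    g("psaI", "CDS", 111), g("ycf4", "CDS", 555),
    g("cemA", "CDS", 690), g("petA", "CDS", 963),
    g("psbJ", "CDS", 123, strand = "-"), g("psbL", "CDS", 117, strand = "-"),
    g("psbF", "CDS", 120, strand = "-"), g("psbE", "CDS", 252, strand = "-"),
    g("petL", "CDS", 96), g("petG", "CDS", 114),
    g("psaJ", "CDS", 135), g("rpl33", "CDS", 201),
    g("rps18", "CDS", 306), g("rpl20", "CDS", 354, strand = "-"),
    g("rps12", "CDS", 372, strand = "-"), g("clpP", "CDS", 591, 2, "-"),
    g("psbB", "CDS", 1527), g("psbT", "CDS", 108),
    g("psbN", "CDS", 132, strand = "-"), g("psbH", "CDS", 222),
    g("petB", "CDS", 648, 1), g("petD", "CDS", 483, 1),
    g("rpoA", "CDS", 1014, strand = "-"), g("rps11", "CDS", 417, strand = "-"),
    g("rpl36", "CDS", 114, strand = "-"), g("infA", "CDS", 234, strand = "-"),
    g("rps8", "CDS", 405, strand = "-"), g("rpl14", "CDS", 369, strand = "-"),
    g("rpl16", "CDS", 408, 1, "-"), g("rps3", "CDS", 657, strand = "-"),
    g("rpl22", "CDS", 447, strand = "-"),
    g("trnH-GUG", "tRNA", 74, strand = "-"), g("trnK-UUU", "tRNA", 72, 1, "-"),
    g("trnQ-UUG", "tRNA", 72, strand = "-"), g("trnS-GCU", "tRNA", 88, strand = "-"),
    g("trnG-UCC", "tRNA", 71, 1), g("trnR-UCU", "tRNA", 72),
    g("trnC-GCA", "tRNA", 71), g("trnD-GUC", "tRNA", 74, strand = "-"),
    g("trnY-GUA", "tRNA", 84, strand = "-"), g("trnE-UUC", "tRNA", 73, strand = "-"),
    g("trnT-GGU", "tRNA", 72), g("trnS-UGA", "tRNA", 93, strand = "-"),
    g("trnF-GAA", "tRNA", 73), g("trnL-UAA", "tRNA", 85, 1),
    g("trnM-CAU", "tRNA", 73), g("trnW-CCA", "tRNA", 74, strand = "-"),
    g("trnP-UGG", "tRNA", 74, strand = "-"))
  ir <- rbind(
    g("rpl2", "CDS", 822, 1, "-"), g("rpl23", "CDS", 282, strand = "-"),
    g("ycf2", "CDS", 6840), g("ndhB", "CDS", 1533, 1, "-"),
    g("rps7", "CDS", 468, strand = "-"),
    g("trnI-CAU", "tRNA", 74, strand = "-"), g("trnL-CAA", "tRNA", 81, strand = "-"),
    g("rrn16", "rRNA", 1490), g("trnI-GAU", "tRNA", 72, 1),
    g("trnA-UGC", "tRNA", 73, 1), g("rrn23", "rRNA", 2810),
    g("rrn4.5", "rRNA", 103), g("rrn5", "rRNA", 121),
    g("trnR-ACG", "tRNA", 74), g("trnN-GUU", "tRNA", 72, strand = "-"))
  ssc <- rbind(
    g("ndhF", "CDS", 2241, strand = "-"), g("rpl32", "CDS", 174),
    g("trnL-UAG", "tRNA", 80), g("ccsA", "CDS", 966),
    g("ndhD", "CDS", 1503, strand = "-"), g("psaC", "CDS", 246, strand = "-"),
    g("ndhE", "CDS", 306, strand = "-"), g("ndhG", "CDS", 531, strand = "-"),
    g("ndhI", "CDS", 543, strand = "-"), g("ndhA", "CDS", 1092, 1, "-"),
    g("ndhH", "CDS", 1182, strand = "-"), g("rps15", "CDS", 273, strand = "-"))
  list(lsc = lsc, ir = ir, ssc = ssc)
}

#' Simulation configuration
#'
#' Defaults describe a typical ~161 kb Engelhardia-like plastome and a
#' shallow genus-level phylogeny with one distant outgroup: region lengths
#' 90 kb / 19 kb / 26 kb, substitution rate 0.008 per site per unit branch
#' length with transition/transversion ratio 2, InDel rate one-sixth of the
#' substitution rate with geometric lengths of mean 4, the IR evolving at
#' 0.1x the single-copy rate, nonsynonymous substitutions accepted with
#' category-specific probabilities (photosynthesis genes most constrained),
#' and SSR slippage on planted tracts.
#'
#' @param lsc_len,ssc_len,ir_len region lengths (bp).
#' @param sub_rate substitutions per site per unit branch length.
#' @param kappa transition/transversion ratio.
#' @param indel_rate InDel events per site per unit branch length.
#' @param indel_mean mean geometric InDel length (bp).
#' @param ir_multiplier IR rate multiplier (< 1: IR more conserved).
#' @param rna_multiplier substitution multiplier inside tRNA/rRNA genes.
#' @param cds_indel_multiplier InDel multiplier inside coding features.
#' @param nonsyn_accept named acceptance probabilities for nonsynonymous
#'   changes by functional category.
#' @param slip_rate slippage events per SSR tract per unit branch length.
#' @param n_ssr number of planted SSR tracts.
#' @param n_hotspots number of intergenic mutation hotspots (fast-evolving
#'   spacers, emulating hypervariable regions).
#' @param hotspot_multiplier rate multiplier inside hotspot spacers.
#' @param copy_correction mirror IR events into both copies (default TRUE).
#' @param tree Newick string (default: 13 ingroup accessions + outgroup).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(lsc_len = 90000L, ssc_len = 19000L,
                              ir_len = 26000L,
                              sub_rate = 0.008, kappa = 2,
                              indel_rate = 0.0014, indel_mean = 4,
                              ir_multiplier = 0.1, rna_multiplier = 0.3,
                              cds_indel_multiplier = 0.05,
                              nonsyn_accept = c(photosynthesis = 0.12,
                                                "self-replication" = 0.35,
                                                other = 0.5),
                              slip_rate = 0.3, n_ssr = 40L,
                              n_hotspots = 6L, hotspot_multiplier = 4,
                              copy_correction = TRUE,
                              gene_model = c("full", "mini"),
                              tree = NULL) {
  gene_model <- match.arg(gene_model)
  if (gene_model == "mini") {
    if (missing(lsc_len)) lsc_len <- 12000L
    if (missing(ssc_len)) ssc_len <- 5000L
    if (missing(ir_len)) ir_len <- 4000L
    if (missing(n_ssr)) n_ssr <- 10L
  }
  if (is.null(tree))
    tree <- paste0(
      "(outgroup:1.1,((sampA1:0.05,sampA2:0.05):0.12,",
      "((sampB1:0.03,sampB2:0.03):0.06,(sampB3:0.05,sampB4:0.05):0.04):0.1,",
      "((sampC1:0.04,(sampC2:0.02,sampC3:0.02):0.02):0.08,",
      "(sampD1:0.06,(sampD2:0.03,(sampD3:0.02,sampD4:0.02):0.01):0.03):0.05",
      "):0.07):0.45);")
  stopifnot(sub_rate >= 0, indel_rate >= 0, slip_rate >= 0,
            ir_multiplier >= 0, indel_mean >= 1)
  structure(list(lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len,
                 sub_rate = sub_rate, kappa = kappa, indel_rate = indel_rate,
                 indel_mean = indel_mean, ir_multiplier = ir_multiplier,
                 rna_multiplier = rna_multiplier,
                 cds_indel_multiplier = cds_indel_multiplier,
                 nonsyn_accept = nonsyn_accept, slip_rate = slip_rate,
                 n_ssr = n_ssr, n_hotspots = n_hotspots,
                 hotspot_multiplier = hotspot_multiplier,
                 copy_correction = copy_correction,
                 gene_model = gene_model, tree = tree),
            class = "simulation_config")
}

#' @keywords internal
random_dna <- function(n, gc = 0.35) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

## sense, non-stop codons with AT-biased composition; per-gene bias strength
## drives the ENC spread and per-gene direction jitter keeps family-level
## preferences from being perfectly concordant across genes
#' @keywords internal
make_orf <- function(len, third_weights) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  ct <- codon_tables()
  pool <- ct$codons[!ct$stop & !(ct$codons %in% c("ATG", "TGG"))]
  w12 <- c(A = 0.30, T = 0.30, C = 0.20, G = 0.20)
  w <- third_weights[substr(pool, 3L, 3L)] *
    w12[substr(pool, 1L, 1L)] * w12[substr(pool, 2L, 2L)]
  body <- sample(pool, len / 3L - 2L, replace = TRUE, prob = w)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' @keywords internal
make_gene_seq <- function(key, len, gc_rna = 0.52) {
  if (key == "CDS") {
    global <- c(T = 0.36, A = 0.34, C = 0.15, G = 0.15)
    strength <- stats::rgamma(1, shape = 3, scale = 0.5)
    jitter <- stats::rlnorm(4, 0, 0.35)
    w <- (global * jitter)^strength
    make_orf(len, w / sum(w))
  } else {
    random_dna(len, gc = gc_rna)
  }
}

## Assemble one region: genes separated by random spacers; SSR tracts and
## repeat donors are planted inside spacers.  Returns sequence, feature
## offsets and planted-element records (coordinates relative to the region).
#' @keywords internal
assemble_region <- function(genes, region_len, bg_gc, ssr_slots = 0L,
                            head_seq = "", tail_seq = "") {
  n <- nrow(genes)
  seqs <- character(n)
  introns <- vector("list", n)
  for (i in seq_len(n)) {
    s <- make_gene_seq(genes$key[i], genes$len[i])
    if (genes$strand[i] == "-") s <- revcomp(s)
    ni <- genes$introns[i]
    ivs <- NULL
    if (ni > 0L) {
      ## split at interior codon boundaries; introns are AT-rich
      L0 <- nchar(s)
      cuts <- sort(sample(seq(30L, L0 - 30L, by = 3L), ni))
      parts <- substring(s, c(1L, cuts + 1L), c(cuts, L0))
      ilens <- sample(450:900, ni, replace = TRUE)
      full <- parts[1]
      offs <- data.frame(start = 0L, end = nchar(parts[1]))
      for (k in seq_len(ni)) {
        intron <- random_dna(ilens[k], gc = bg_gc)
        st <- nchar(full) + nchar(intron)
        full <- paste0(full, intron, parts[k + 1L])
        offs <- rbind(offs, data.frame(start = st, end = st + nchar(parts[k + 1L])))
      }
      s <- full
      ivs <- offs
    }
    seqs[i] <- s
    if (!is.null(ivs)) introns[[i]] <- ivs
  }
  footprint <- sum(nchar(seqs)) + nchar(head_seq) + nchar(tail_seq)
  spare <- region_len - footprint
  if (spare < (n + 1L) * 20L)
    stop("infeasible packing: region length ", region_len,
         " too small for gene footprint ", footprint)
  cuts <- sort(sample.int(spare - (n + 1L) * 20L + 1L, n, replace = TRUE)) - 1L
  spacer_len <- diff(c(0L, cuts, spare - (n + 1L) * 20L)) + 20L
  ssr_recs <- NULL
  spacers <- character(n + 1L)
  ssr_in <- if (ssr_slots > 0L && n >= 1L)
    sample(seq_len(n + 1L), min(ssr_slots, n + 1L)) else integer(0)
  for (k in seq_len(n + 1L)) {
    sp <- random_dna(spacer_len[k], gc = bg_gc)
    if (k %in% ssr_in && spacer_len[k] >= 40L) {
      motif <- sample(c("A", "T", "AT", "TA", "AAT", "ATT", "TTC", "AG"), 1L,
                      prob = c(0.38, 0.38, 0.07, 0.07, 0.03, 0.03, 0.02, 0.02))
      copies <- switch(as.character(nchar(motif)),
                       "1" = sample(10:14, 1L), "2" = sample(5:8, 1L),
                       sample(4:6, 1L))
      tract <- paste(rep(motif, copies), collapse = "")
      at <- sample.int(spacer_len[k] - nchar(tract) - 10L, 1L) + 5L
      ## guard flanks so the tract is maximal
      flank <- setdiff(c("C", "G"), strsplit(motif, "")[[1]])[1]
      sp <- paste0(substr(sp, 1L, at - 2L), flank, tract, flank,
                   substr(sp, at + nchar(tract) + 1L, spacer_len[k]))
      sp <- substr(sp, 1L, spacer_len[k])
      ssr_recs <- rbind(ssr_recs,
                        data.frame(motif = motif, copies = copies,
                                   spacer = k, offset_in_spacer = at))
    }
    spacers[k] <- sp
  }
  seq <- head_seq
  offsets <- integer(n)
  for (i in seq_len(n)) {
    seq <- paste0(seq, spacers[i])
    offsets[i] <- nchar(seq)          # 0-based gene start within region
    seq <- paste0(seq, seqs[i])
  }
  seq <- paste0(seq, spacers[n + 1L], tail_seq)
  ## pad/trim to the exact region length (rounding slack)
  if (nchar(seq) < region_len)
    seq <- paste0(seq, random_dna(region_len - nchar(seq), bg_gc))
  ## resolve SSR coordinates
  if (!is.null(ssr_recs)) {
    sp_start <- integer(n + 1L)
    pos <- nchar(head_seq)
    for (k in seq_len(n + 1L)) {
      sp_start[k] <- pos
      pos <- pos + nchar(spacers[k]) + if (k <= n) nchar(seqs[k]) else 0L
    }
    ssr_recs$start <- sp_start[ssr_recs$spacer] + ssr_recs$offset_in_spacer - 1L
  }
  list(seq = seq, gene_offsets = offsets, gene_seqs = seqs,
       intron_offsets = introns, ssrs = ssr_recs)
}

#' Build an annotated root plastome
#'
#' Constructs LSC, IRb, SSC and IRa sequences with the built-in gene model,
#' a junction-spanning rps19 (LSC/IRb, pseudogene fragment at IRa/LSC) and
#' ycf1 (SSC/IRa, pseudogene fragment at IRb/SSC overlapping ndhF), planted
#' SSR tracts and one planted forward + one palindromic dispersed repeat.
#' IRa is the exact reverse complement of IRb, and the four inner junction
#' flanks are adjusted so the planted IR pair is not extendable.
#'
#' @param cfg a `simulation_config`.
#' @return list: `annotated` (an `annotated_plastome`), `partition`
#'   (a `region_partition`), `planted` (SSR/repeat/junction records).
#' @export
build_root_genome <- function(cfg) {
  gt <- plastid_gene_table(cfg$gene_model)
  rps19_len <- 279L; rps19_in_lsc <- 180L
  if (cfg$gene_model == "mini") {
    ycf1_len <- 1479L; ycf1_in_ira <- 300L
  } else {
    ycf1_len <- 5679L; ycf1_in_ira <- 1100L
  }
  rps19_seq <- make_gene_seq("CDS", rps19_len)
  ycf1_seq <- make_gene_seq("CDS", ycf1_len)

  lsc <- assemble_region(gt$lsc, cfg$lsc_len, bg_gc = 0.30,
                         ssr_slots = ceiling(cfg$n_ssr * 0.72),
                         tail_seq = substr(rps19_seq, 1L, rps19_in_lsc))
  irb <- assemble_region(gt$ir, cfg$ir_len, bg_gc = 0.40,
                         ssr_slots = ceiling(cfg$n_ssr * 0.08),
                         head_seq = substr(rps19_seq, rps19_in_lsc + 1L,
                                           rps19_len),
                         tail_seq = revcomp(substr(
                           ycf1_seq, ycf1_len - ycf1_in_ira + 1L, ycf1_len)))
  ssc <- assemble_region(gt$ssc, cfg$ssc_len, bg_gc = 0.27,
                         ssr_slots = ceiling(cfg$n_ssr * 0.20),
                         tail_seq = substr(ycf1_seq, 1L,
                                           ycf1_len - ycf1_in_ira))
  ira_seq <- revcomp(irb$seq)
  seq <- paste0(lsc$seq, irb$seq, ssc$seq, ira_seq)
  l1 <- nchar(lsc$seq); m <- nchar(irb$seq); s <- nchar(ssc$seq)
  L <- nchar(seq)
  b1 <- l1; e1 <- l1 + m            # IRb, 0-based half-open
  b2 <- l1 + m + s; e2 <- L         # IRa

  ## make the IR pair non-extendable: force the first four SSC bases to
  ## mismatch the complement of the last four SSC bases (all intergenic)
  sv <- strsplit(seq, "")[[1]]
  for (t in 0:3) {
    partner <- complement_dna(sv[b2 - t])
    if (sv[e1 + 1L + t] == partner)
      sv[e1 + 1L + t] <- sample(setdiff(c("A", "C", "G", "T"), partner), 1L)
  }
  seq <- paste(sv, collapse = "")

  feats <- list()
  add_gene <- function(name, key, start0, gseq_len, strand, pseudo = FALSE,
                       intron_offs = NULL) {
    if (!is.null(intron_offs) && nrow(intron_offs) > 1L) {
      iv <- data.frame(start = start0 + intron_offs$start,
                       end = start0 + intron_offs$end)
    } else {
      iv <- data.frame(start = start0, end = start0 + gseq_len)
    }
    feats[[length(feats) + 1L]] <<-
      feature("gene", name, data.frame(start = start0,
                                       end = start0 + gseq_len),
              strand, pseudo)
    feats[[length(feats) + 1L]] <<- feature(key, name, iv, strand, pseudo)
    if (!is.null(intron_offs) && nrow(intron_offs) > 1L) {
      for (k in seq_len(nrow(intron_offs) - 1L))
        feats[[length(feats) + 1L]] <<-
          feature("intron", name,
                  data.frame(start = start0 + intron_offs$end[k],
                             end = start0 + intron_offs$start[k + 1L]),
                  strand, FALSE)
    }
  }
  add_region_genes <- function(asm, genes, region_start) {
    for (i in seq_len(nrow(genes)))
      add_gene(genes$name[i], genes$key[i],
               region_start + asm$gene_offsets[i], nchar(asm$gene_seqs[i]),
               genes$strand[i], intron_offs = asm$intron_offsets[[i]])
  }
  add_region_genes(lsc, gt$lsc, 0L)
  add_region_genes(irb, gt$ir, b1)
  add_region_genes(ssc, gt$ssc, b1 + m)

  ## junction genes
  add_gene("rps19", "CDS", l1 - rps19_in_lsc, rps19_len, "+")
  ycf1_start <- b2 - (ycf1_len - ycf1_in_ira)
  add_gene("ycf1", "CDS", ycf1_start, ycf1_len, "+")
  ## IR-copy pseudogene fragments; the ycf1 fragment pokes 30 bp into SSC
  feats[[length(feats) + 1L]] <-
    feature("CDS", "ycf1-fragment",
            data.frame(start = e1 - ycf1_in_ira, end = e1 + 30L), "-", TRUE)
  feats[[length(feats) + 1L]] <-
    feature("CDS", "rps19-fragment",
            data.frame(start = e2 - (rps19_len - rps19_in_lsc), end = e2),
            "-", TRUE)
  ## mirror the IR-resident genes into IRa
  ir_feats <- do.call(rbind, feats)
  for (i in seq_len(nrow(ir_feats))) {
    iv <- ir_feats$intervals[[i]]
    if (all(iv$start >= b1 & iv$end <= e1) && !ir_feats$pseudo[i]) {
      miv <- data.frame(start = rev(b2 + (e1 - iv$end)),
                        end = rev(b2 + (e1 - iv$start)))
      feats[[length(feats) + 1L]] <-
        feature(ir_feats$key[i], ir_feats$name[i], miv,
                if (ir_feats$strand[i] == "+") "-" else "+",
                ir_feats$pseudo[i])
    }
  }
  features <- do.call(rbind, feats)
  g <- genome("root", seq, circular = TRUE)
  ag <- annotated_genome(g, features)
  regions <- data.frame(region = c("LSC", "IRb", "SSC", "IRa"),
                        start = c(0L, b1, e1, b2),
                        end = c(b1, e1, b2, e2))
  regions$length <- regions$end - regions$start
  part <- structure(list(found = TRUE, regions = regions, ir_len = m,
                         mismatches = 0L, genome_length = L,
                         genome_id = "root"),
                    class = "region_partition")
  ## plant one forward and one palindromic dispersed repeat in LSC spacers
  planted_rep <- NULL
  gaps <- which(feature_context(ag, seq(100L, b1 - 100L, by = 61L)) ==
                  "intergenic")
  if (length(gaps) >= 4L) {
    cand <- seq(100L, b1 - 100L, by = 61L)[gaps]
    if (!is.null(lsc$ssrs))
      cand <- cand[vapply(cand, function(p)
        all(abs(p - lsc$ssrs$start) > 80L), logical(1))]
    spots <- sort(sample(cand, 4L))
    unit <- random_dna(40L, gc = 0.45)
    sv <- strsplit(seq, "")[[1]]
    sv[(spots[1] + 1L):(spots[1] + 40L)] <- strsplit(unit, "")[[1]]
    sv[(spots[2] + 1L):(spots[2] + 40L)] <- strsplit(unit, "")[[1]]
    unit2 <- random_dna(40L, gc = 0.45)
    sv[(spots[3] + 1L):(spots[3] + 40L)] <- strsplit(unit2, "")[[1]]
    sv[(spots[4] + 1L):(spots[4] + 40L)] <- strsplit(revcomp(unit2), "")[[1]]
    seq <- paste(sv, collapse = "")
    g <- genome("root", seq, circular = TRUE)
    ag <- annotated_genome(g, features)
    planted_rep <- data.frame(kind = c("forward", "palindromic"),
                              start1 = spots[c(1, 3)] + 1L,
                              start2 = spots[c(2, 4)] + 1L, length = 40L)
  }
  ## designate fast-evolving intergenic spacers (mutation hotspots)
  hot <- NULL
  if (cfg$n_hotspots > 0L) {
    ctx <- context_vector(ag)
    sc <- c(rep(TRUE, b1), rep(FALSE, e1 - b1), rep(TRUE, b2 - e1),
            rep(FALSE, e2 - b2))
    r <- rle(ctx == 0L & sc)
    rends <- cumsum(r$lengths); rstarts <- rends - r$lengths + 1L
    big <- which(r$values & r$lengths >= 600L)
    if (length(big)) {
      pick <- sample(big, min(cfg$n_hotspots, length(big)))
      hot <- data.frame(start = rstarts[pick] - 1L, end = rends[pick])
    }
  }
  ssr_all <- rbind(
    if (!is.null(lsc$ssrs)) transform(lsc$ssrs, start = start),
    if (!is.null(irb$ssrs)) transform(irb$ssrs, start = start + b1),
    if (!is.null(ssc$ssrs)) transform(ssc$ssrs, start = start + e1))
  planted <- list(ssrs = ssr_all, repeats = planted_rep, hotspots = hot,
                  junction = data.frame(
                    gene = c("rps19", "ycf1"),
                    split_upstream = c(rps19_in_lsc,
                                       ycf1_len - ycf1_in_ira),
                    split_downstream = c(rps19_len - rps19_in_lsc,
                                         ycf1_in_ira)))
  list(annotated = ag, partition = part, planted = planted)
}
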
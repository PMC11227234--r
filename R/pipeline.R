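## End-to-end orchestration of the comparative analyses, with report
## writing and parameter provenance.

#' Pipeline parameters
#'
#' Defaults are the standard comparative-plastomics settings: 600 bp
#' windows with 200 bp steps and a 0.010 pi threshold for hotspots, MISA
#' SSR thresholds (10, 5, 4, 3, 3, 3), dispersed repeats of >= 30 bp with
#' Hamming distance <= 3, coding sequences screened at > 300 bp with an
#' ATG start, and optimal codons from the 5 percent ENC tails with
#' delta-RSCU > 0.08.
#'
#' @param window,step,pi_threshold sliding-window diversity settings.
#' @param ssr_thresholds MISA per-class minimum copies.
#' @param repeat_min_len,repeat_max_mismatch dispersed-repeat settings.
#' @param cds_min_len CDS screening length (exclusive).
#' @param tail,delta_rscu optimal-codon settings.
#' @param ref_id reference sample for variant calling and Ka/Ks (default:
#'   "root" when present, else the first row).
#' @param samples optional sample subset for diversity (one accession per
#'   species, mirroring per-species deduplication).
#' @return named list of parameters.
#' @export
pipeline_params <- function(window = 600L, step = 200L, pi_threshold = 0.010,
                            ssr_thresholds = c(10L, 5L, 4L, 3L, 3L, 3L),
                            repeat_min_len = 30L, repeat_max_mismatch = 3L,
                            cds_min_len = 300L, tail = 0.05,
                            delta_rscu = 0.08, ref_id = NULL,
                            samples = NULL) {
  list(window = window, step = step, pi_threshold = pi_threshold,
       ssr_thresholds = ssr_thresholds, repeat_min_len = repeat_min_len,
       repeat_max_mismatch = repeat_max_mismatch, cds_min_len = cds_min_len,
       tail = tail, delta_rscu = delta_rscu, ref_id = ref_id,
       samples = samples)
}

#' @keywords internal
provenance_lines <- function(params) {
  ver <- tryCatch(as.character(utils::packageVersion("plastomics")),
                  error = function(e) "dev")
  flat <- vapply(names(params), function(k)
    paste0(k, "=", paste(params[[k]], collapse = ",")), character(1))
  c(paste0("# plastomics ", ver),
    paste0("# ", paste(flat, collapse = "; ")))
}

#' @keywords internal
write_report <- function(x, path, params) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(params), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Spliced gene rows from a multiple alignment
#'
#' Extracts, for every alignment row, the strand-resolved spliced sequence
#' of a gene annotated on the reference row (gaps retained), by projecting
#' the reference exon coordinates onto alignment columns.
#'
#' @param aln named character vector (gapped rows).
#' @param g the reference `annotated_plastome` (its coordinates must match
#'   the ungapped reference row).
#' @param gene gene symbol.
#' @param ref_id name of the reference row (default "root").
#' @return named character vector of per-row gene sequences with gaps.
#' @export
gene_alignment_rows <- function(aln, g, gene, ref_id = "root") {
  aln <- check_alignment(aln)
  if (!ref_id %in% names(aln)) stop("reference row '", ref_id, "' missing")
  f <- g$features[g$features$key == "CDS" & g$features$name == gene &
                    !g$features$pseudo, , drop = FALSE]
  if (nrow(f) == 0L) stop("no CDS feature for gene '", gene, "'")
  ## when the IR duplicates a gene, use its first copy
  f <- f[1, , drop = FALSE]
  iv <- f$intervals[[1]]
  L <- g$genome$length
  pos <- unlist(lapply(seq_len(nrow(iv)), function(r) {
    s <- iv$start[r]; e <- iv$end[r]
    if (s < e) (s + 1L):e else c((s + 1L):L, seq_len(e))
  }))
  colmap <- which(seq_ints(aln[[ref_id]]) != .GAP)
  cols <- colmap[pos]
  out <- vapply(aln, function(row) {
    chars <- strsplit(row, "")[[1]][cols]
    s <- paste(chars, collapse = "")
    if (f$strand == "-") {
      s <- complement_dna(s)
      s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    }
    s
  }, character(1))
  out
}

#' Pairwise Ka/Ks of reference-annotated genes across alignment rows
#'
#' For every screened CDS gene, computes NG86 Ka/Ks between the reference
#' row and every other row (codon columns containing gaps stripped), and
#' attaches the functional category.
#'
#' @param aln named character vector (gapped rows).
#' @param g reference `annotated_plastome`.
#' @param ref_id row compared against every sample.
#' @param sample_ids rows to compare against the reference (default: all
#'   others).
#' @param min_len minimum spliced gene length (default 300, exclusive).
#' @param annot_id row matching the coordinates of `g` (default `ref_id`);
#'   lets an outgroup row serve as the Ka/Ks reference while the gene
#'   coordinates come from an annotated row.
#' @return data.frame: gene, sample, category, S, N, sd, nd, Ka, Ks, ratio.
#' @export
kaks_by_gene <- function(aln, g, ref_id = "root", sample_ids = NULL,
                         min_len = 300L, annot_id = ref_id) {
  f <- g$features[g$features$key == "CDS" & !g$features$pseudo, ,
                  drop = FALSE]
  genes <- unique(f$name)
  lens <- vapply(genes, function(gn) {
    iv <- f$intervals[[which(f$name == gn)[1]]]
    sum(iv$end - iv$start)
  }, numeric(1))
  genes <- genes[lens > min_len]
  if (is.null(sample_ids)) sample_ids <- setdiff(names(aln), ref_id)
  cats <- categorize_genes(genes)
  chars <- lapply(aln, function(r) strsplit(r, "")[[1]])
  colmap <- which(seq_ints(aln[[annot_id]]) != .GAP)
  L <- g$genome$length
  rows <- list()
  for (gn in genes) {
    fr <- f[f$name == gn, , drop = FALSE][1, , drop = FALSE]
    iv <- fr$intervals[[1]]
    pos <- unlist(lapply(seq_len(nrow(iv)), function(r) {
      s <- iv$start[r]; e <- iv$end[r]
      if (s < e) (s + 1L):e else c((s + 1L):L, seq_len(e))
    }))
    cols <- colmap[pos]
    rows_gene <- vapply(chars[unique(c(ref_id, sample_ids))], function(cv) {
      s <- paste(cv[cols], collapse = "")
      if (fr$strand == "-") reverse_chars(complement_dna(s)) else s
    }, character(1))
    for (sid in sample_ids) {
      pair <- strip_gap_codons(rows_gene[[ref_id]], rows_gene[[sid]])
      res <- tryCatch(ng86_kaks(pair$a, pair$b), error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gn, sample = sid,
        category = cats$category[cats$gene == gn][1],
        S = res$S, N = res$N, sd = res$sd, nd = res$nd,
        Ka = res$Ka, Ks = res$Ks, ratio = res$ratio)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(0), sample = character(0),
                      category = character(0), S = numeric(0), N = numeric(0),
                      sd = numeric(0), nd = numeric(0), Ka = numeric(0),
                      Ks = numeric(0), ratio = numeric(0)))
  do.call(rbind, rows)
}

#' Run the comparative-plastomics pipeline
#'
#' Orchestrates the analyses on an annotated genome and/or multiple
#' alignment, or on a freshly simulated data set when no input is given.
#' Steps: `structure` (partition, per-region GC, junctions), `ssr`,
#' `repeats` (dispersed + tandem), `variation` (variant calling, per-kb
#' rates, contexts, frame classes), `diversity` (sliding-window pi and
#' hotspots), `codon` (usage-bias suite), `kaks` (NG86 by gene and
#' category), or `all`.  Reports (TSV/JSON with a version + parameter
#' provenance header) are written when `out_dir` is given; all results are
#' also returned.
#'
#' @param steps character vector of step names, or "all".
#' @param genome an `annotated_plastome`, or path to a GenBank file.
#' @param alignment named character vector of gapped rows, or path to an
#'   aligned FASTA.
#' @param params a [pipeline_params()] list.
#' @param out_dir optional output directory for reports.
#' @param seed seed used when simulating (and recorded in provenance).
#' @param sim_config `simulation_config` used when no input is given.
#' @return named list of per-step results, invisibly.
#' @export
run_pipeline <- function(steps = "all", genome = NULL, alignment = NULL,
                         params = pipeline_params(), out_dir = NULL,
                         seed = 1L, sim_config = simulation_config()) {
  all_steps <- c("structure", "ssr", "repeats", "variation", "diversity",
                 "codon", "kaks")
  if (identical(steps, "all")) steps <- all_steps
  bad <- setdiff(steps, c(all_steps, "simulate"))
  if (length(bad)) stop("unknown step(s): ", paste(bad, collapse = ", "))
  sim <- NULL
  if ("simulate" %in% steps || (is.null(genome) && is.null(alignment))) {
    sim <- simulate_plastomes(sim_config, seed)
    genome <- sim$root
    alignment <- sim$alignment
    steps <- setdiff(steps, "simulate")
    if (!length(steps)) steps <- all_steps
  }
  if (is.character(genome) && length(genome) == 1L)
    genome <- read_genbank(genome)
  if (is.character(alignment) && length(alignment) == 1L &&
      is.null(names(alignment)))
    alignment <- read_alignment(alignment)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prm <- params
  prm$seed <- seed
  res <- list(params = prm, simulation = sim)
  emit <- function(x, name) {
    if (!is.null(out_dir))
      write_report(x, file.path(out_dir, paste0(name, ".tsv")), prm)
    x
  }

  part <- NULL
  if (!is.null(genome)) {
    part <- detect_partition(genome)
    if (!is.null(sim)) part <- sim$partition
  }

  if ("structure" %in% steps) {
    if (is.null(genome)) stop("step 'structure' needs an annotated genome")
    if (!part$found) {
      res$structure <- list(partition = part)
    } else {
      res$structure <- list(
        partition = part,
        gc = emit(region_gc(genome, part), "region_gc"),
        junctions = emit(junction_report(genome, part), "junctions"),
        gene_counts = gene_counts(genome))
    }
  }
  if ("ssr" %in% steps) {
    if (is.null(genome)) stop("step 'ssr' needs a genome")
    ssrs <- find_ssrs(genome, thresholds = params$ssr_thresholds,
                      partition = if (!is.null(part) && part$found) part,
                      annotation = genome)
    res$ssr <- list(loci = emit(ssrs, "ssr_loci"),
                    summary = summarize_repeats(ssrs = ssrs,
                                                partition = part,
                                                annotation = genome))
  }
  if ("repeats" %in% steps) {
    if (is.null(genome)) stop("step 'repeats' needs a genome")
    disp <- find_dispersed_repeats(genome,
                                   min_len = params$repeat_min_len,
                                   max_mismatch = params$repeat_max_mismatch,
                                   partition = part)
    tand <- find_tandem_repeats(genome)
    res$repeats <- list(dispersed = emit(disp, "dispersed_repeats"),
                        tandem = emit(tand, "tandem_repeats"),
                        summary = summarize_repeats(
                          ssrs = res$ssr$loci, dispersed = disp,
                          tandem = tand, partition = part,
                          annotation = genome))
  }
  ref_id <- params$ref_id
  if (is.null(ref_id) && !is.null(alignment))
    ref_id <- if ("root" %in% names(alignment)) "root" else names(alignment)[1]
  if ("variation" %in% steps) {
    if (is.null(alignment)) stop("step 'variation' needs an alignment")
    vars <- pairwise_variants(alignment, ref_id)
    res$variation <- list(variants = emit(vars, "variants"))
    if (!is.null(part) && part$found) {
      rates <- per_kb_rates(vars, part)
      ns <- max(1L, length(setdiff(names(alignment), ref_id)))
      rates$n_samples <- ns
      rates$rate_per_sample <- rates$rate / ns
      res$variation$rates <- emit(rates, "variant_rates")
    }
    if (!is.null(genome)) {
      loc <- locate_variants(vars, genome)
      res$variation$contexts <- emit(loc$summary, "variant_contexts")
    }
    res$variation$indel_frames <- indel_frame_classification(vars)
  }
  if ("diversity" %in% steps) {
    if (is.null(alignment) || length(alignment) < 2L)
      stop("step 'diversity' needs an alignment with >= 2 sequences")
    samples <- params$samples
    if (is.null(samples)) samples <- setdiff(names(alignment), ref_id)
    if (length(samples) < 2L) samples <- names(alignment)
    prof <- sliding_window_pi(alignment, window = params$window,
                              step = params$step,
                              coords = if (!is.null(genome) &&
                                           ref_id %in% names(alignment))
                                "reference" else "alignment",
                              ref_id = ref_id, samples = samples)
    hs <- call_hotspots(prof, threshold = params$pi_threshold, g = genome)
    res$diversity <- list(profile = emit(as.data.frame(prof), "pi_profile"),
                          hotspots = emit(hs, "hotspots"))
  }
  if ("codon" %in% steps) {
    if (is.null(genome)) stop("step 'codon' needs an annotated genome")
    cds <- extract_cds(genome, min_len = params$cds_min_len)
    if (nrow(cds) >= 40L) {
      counts <- codon_counts(cds)
      ci <- codon_indices(counts, tail = params$tail,
                          delta = params$delta_rscu)
      res$codon <- list(
        indices = emit(ci$indices, "codon_indices"),
        optimal = ci$optimal,
        rscu = ci$rscu_overall,
        enc_plot = emit(enc_plot_points(counts), "enc_plot"),
        pr2_plot = emit(pr2_plot_points(counts), "pr2_plot"),
        correlations = index_correlations(ci$indices[, -1]))
    } else {
      res$codon <- list(note = paste0("only ", nrow(cds),
                                      " screened CDS; codon suite skipped"))
    }
  }
  if ("kaks" %in% steps) {
    if (is.null(alignment) || is.null(genome))
      stop("step 'kaks' needs an alignment and an annotated genome")
    kk <- kaks_by_gene(alignment, genome, ref_id = ref_id,
                       min_len = params$cds_min_len)
    res$kaks <- list(table = emit(kk, "kaks"))
    if (nrow(kk)) {
      per_gene <- stats::aggregate(ratio ~ gene + category, data = kk,
                                   FUN = function(v) mean(v, na.rm = TRUE),
                                   na.action = stats::na.pass)
      per_gene$ratio[is.nan(per_gene$ratio)] <- NA_real_
      by_cat <- split(per_gene$ratio, per_gene$category)
      ok <- vapply(by_cat, function(v) sum(!is.na(v)) >= 2L, logical(1))
      if (sum(ok) >= 2L)
        res$kaks$group_comparison <- emit(group_compare(by_cat[ok]),
                                          "kaks_groups")
    }
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(provenance = prm,
           steps = steps),
      file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
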
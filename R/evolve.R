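## Evolution of a root plastome along a phylogeny with ground-truth logging.

#' @keywords internal
context_vector <- function(ag) {
  ## per-position context, vectorized painting (precedence exon > intron >
  ## RNA-gene > intergenic)
  L <- ag$genome$length
  ctx <- integer(L)                 # 0 intergenic, 1 RNA, 2 intron, 3 exon
  paint <- function(keys, val, include_pseudo = TRUE) {
    f <- ag$features[ag$features$key %in% keys, , drop = FALSE]
    if (!include_pseudo) f <- f[!f$pseudo, , drop = FALSE]
    for (i in seq_len(nrow(f))) {
      iv <- f$intervals[[i]]
      for (r in seq_len(nrow(iv))) {
        s <- iv$start[r]; e <- iv$end[r]
        if (s < e) ctx[(s + 1L):e] <<- val
        else ctx[c((s + 1L):L, seq_len(e))] <<- val
      }
    }
  }
  paint(c("tRNA", "rRNA"), 1L)
  paint("intron", 2L)
  paint("CDS", 3L)
  ctx
}

#' @keywords internal
build_coding_map <- function(ag) {
  f <- ag$features[ag$features$key == "CDS" & !ag$features$pseudo, ,
                   drop = FALSE]
  L <- ag$genome$length
  cod_gene <- integer(L)
  cod_idx <- integer(L)
  pos_list <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    iv <- f$intervals[[i]]
    pp <- unlist(lapply(seq_len(nrow(iv)), function(r) {
      s <- iv$start[r]; e <- iv$end[r]
      if (s < e) (s + 1L):e else c((s + 1L):L, seq_len(e))
    }))
    if (f$strand[i] == "-") pp <- rev(pp)
    pos_list[[i]] <- pp
    cod_gene[pp] <- i
    cod_idx[pp] <- seq_along(pp)
  }
  cats <- categorize_genes(f$name)
  list(genes = f$name, strand = f$strand, pos_list = pos_list,
       cod_gene = cod_gene, cod_idx = cod_idx, category = cats$category)
}

.TS_PARTNER <- local({
  m <- integer(256)
  m[utf8ToInt("A")] <- utf8ToInt("G"); m[utf8ToInt("G")] <- utf8ToInt("A")
  m[utf8ToInt("C")] <- utf8ToInt("T"); m[utf8ToInt("T")] <- utf8ToInt("C")
  m
})

#' Evolve a root plastome along a phylogeny
#'
#' Applies HKY-like substitutions (transition/transversion ratio `kappa`),
#' geometric-length insertions and deletions, and SSR slippage along every
#' branch, with region rate multipliers (IR most conserved), purifying
#' selection on coding positions (nonsynonymous changes accepted with
#' category-specific probabilities; changes creating stop codons rejected),
#' and concerted evolution of the IR copies: every IR event is mirrored
#' into the partner copy so that IRa remains the reverse complement of IRb.
#' All events are logged in root-reference coordinates.
#'
#' @param root output of [build_root_genome()].
#' @param cfg a `simulation_config`.
#' @param tree an `ape::phylo` tree or Newick string (default `cfg$tree`).
#' @return list of class `plastome_simulation`: `root`, `partition`,
#'   `planted`, `tips` (named list of `plastome`), `alignment` (named
#'   character vector, root row first), `events` (data.frame), `tree`,
#'   `config`.
#' @export
evolve_along_tree <- function(root, cfg, tree = NULL) {
  if (is.null(tree)) tree <- cfg$tree
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 tips")
  tree <- stats::reorder(tree, "cladewise")
  ag <- root$annotated
  part <- root$partition
  L <- ag$genome$length
  b0 <- seq_ints(ag$genome$sequence)
  reg <- part$regions
  b1 <- reg$start[reg$region == "IRb"]; e1 <- reg$end[reg$region == "IRb"]
  b2 <- reg$start[reg$region == "IRa"]; e2 <- reg$end[reg$region == "IRa"]
  mirror <- rep(NA_integer_, L)
  irb_pos <- (b1 + 1L):e1
  mirror[irb_pos] <- b2 + (e1 - irb_pos) + 1L
  ira_pos <- (b2 + 1L):e2
  mirror[ira_pos] <- b1 + (e2 - ira_pos) + 1L
  in_ira <- seq_len(L) > b2 & seq_len(L) <= e2
  in_ir <- (seq_len(L) > b1 & seq_len(L) <= e1) | in_ira
  regid <- region_of_positions(seq_len(L) - 1L, reg, L)

  ctx <- context_vector(ag)
  cmap <- build_coding_map(ag)
  gc_code <- genetic_code()

  mult_sub <- rep(1, L)
  mult_sub[in_ir] <- cfg$ir_multiplier
  mult_sub[ctx == 1L] <- mult_sub[ctx == 1L] * cfg$rna_multiplier
  mult_ind <- rep(1, L)
  mult_ind[in_ir] <- mult_ind[in_ir] * cfg$ir_multiplier
  mult_ind[ctx %in% c(1L, 3L)] <- mult_ind[ctx %in% c(1L, 3L)] *
    cfg$cds_indel_multiplier
  hot <- root$planted$hotspots
  if (!is.null(hot)) {
    for (r in seq_len(nrow(hot))) {
      idx <- (hot$start[r] + 1L):hot$end[r]
      mult_sub[idx] <- mult_sub[idx] * cfg$hotspot_multiplier
      mult_ind[idx] <- mult_ind[idx] * cfg$hotspot_multiplier
    }
  }
  primary <- if (cfg$copy_correction) !in_ira else rep(TRUE, L)

  ssrs <- root$planted$ssrs
  ev <- new.env()
  ev$rows <- list()
  ev$id <- 0L
  log_event <- function(lineage, branch, kind, pos, length, ref, alt,
                        positions = NA_character_, mirrored = FALSE) {
    ev$id <- ev$id + 1L
    ev$rows[[ev$id]] <- data.frame(
      id = ev$id, lineage = lineage, branch = branch, kind = kind,
      pos = pos, length = length, ref = ref, alt = alt,
      positions = positions, mirrored = mirrored)
    ev$id
  }

  codon_of <- function(b, gid, i) {
    c0 <- (i - 1L) %/% 3L
    trio <- cmap$pos_list[[gid]][(3L * c0 + 1L):(3L * c0 + 3L)]
    list(trio = trio, slot = i - 3L * c0)
  }
  gate_sub <- function(b, del, pos, newb) {
    gid <- cmap$cod_gene[pos]
    if (gid == 0L) return(TRUE)
    cd <- codon_of(b, gid, cmap$cod_idx[pos])
    if (any(del[cd$trio])) return(TRUE)
    bases <- b[cd$trio]
    newbases <- bases
    newbases[cd$slot] <- newb
    minus <- cmap$strand[gid] == "-"
    old_cod <- ints_seq(if (minus) comp_ints(bases) else bases)
    new_cod <- ints_seq(if (minus) comp_ints(newbases) else newbases)
    if (grepl("[^ACGT]", new_cod) || grepl("[^ACGT]", old_cod)) return(TRUE)
    old_aa <- gc_code[[old_cod]]
    new_aa <- gc_code[[new_cod]]
    if (new_aa == "*") return(FALSE)
    if (new_aa == old_aa) return(TRUE)
    acc <- cfg$nonsyn_accept[[cmap$category[gid]]]
    stats::runif(1) < acc
  }

  states <- vector("list", max(tree$edge))
  root_node <- length(tree$tip.label) + 1L
  states[[root_node]] <- list(b = b0, del = rep(FALSE, L), ins = list())

  node_label <- function(n) if (n <= length(tree$tip.label))
    tree$tip.label[n] else paste0("node", n)

  for (eidx in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[eidx, 1]; child <- tree$edge[eidx, 2]
    bl <- tree$edge.length[eidx]
    st <- states[[parent]]
    b <- st$b; del <- st$del; ins <- st$ins
    lin <- node_label(child)

    ## substitutions
    p_site <- cfg$sub_rate * bl * mult_sub
    cand <- which(stats::runif(L) < p_site & !del & primary & is_acgt(b))
    for (pos in cand) {
      cur <- b[pos]
      newb <- if (stats::runif(1) < cfg$kappa / (cfg$kappa + 2))
        .TS_PARTNER[cur]
      else sample(setdiff(c(65L, 67L, 71L, 84L),
                          c(cur, .TS_PARTNER[cur])), 1L)
      if (!gate_sub(b, del, pos, newb)) next
      pm <- mirror[pos]
      if (cfg$copy_correction && !is.na(pm) && !del[pm]) {
        newm <- comp_ints(newb)
        if (!gate_sub(b, del, pm, newm)) next
        oldm <- b[pm]
        b[pm] <- newm
        log_event(lin, eidx, "SNV", pm, 1L, ints_seq(oldm), ints_seq(newm),
                  mirrored = TRUE)
      }
      old <- b[pos]
      b[pos] <- newb
      log_event(lin, eidx, "SNV", pos, 1L, ints_seq(old), ints_seq(newb))
    }

    ## insertions and deletions
    p_ind <- cfg$indel_rate * bl * mult_ind
    candi <- which(stats::runif(L) < p_ind & !del)
    apply_deletion <- function(pos, len, kind = "deletion") {
      ## deletions never straddle region junctions (keeps planted
      ## boundaries and IR copy symmetry intact)
      alive <- pos:min(pos + 4L * len, L)
      alive <- alive[!del[alive] & regid[alive] == regid[pos]]
      if (!length(alive)) return(invisible(NULL))
      dpos <- alive[seq_len(min(len, length(alive)))]
      del[dpos] <<- TRUE
      log_event(lin, eidx, kind, dpos[1], length(dpos),
                ints_seq(b[dpos]), "",
                positions = paste(dpos, collapse = ","))
      if (cfg$copy_correction && all(!is.na(mirror[dpos]))) {
        mp <- mirror[dpos]
        mp <- mp[!del[mp]]
        if (length(mp)) {
          del[mp] <<- TRUE
          log_event(lin, eidx, kind, min(mp), length(mp),
                    ints_seq(b[sort(mp)]), "",
                    positions = paste(sort(mp), collapse = ","),
                    mirrored = TRUE)
        }
      }
      invisible(NULL)
    }
    apply_insertion <- function(anchor, sq, kind = "insertion") {
      id <- log_event(lin, eidx, kind, anchor, nchar(sq), "", sq)
      ins[[length(ins) + 1L]] <<- list(id = id, anchor = anchor, seq = sq)
      if (cfg$copy_correction && anchor >= b1 + 1L && anchor < e1) {
        manchor <- mirror[anchor] - 1L
        msq <- revcomp(sq)
        mid <- log_event(lin, eidx, kind, manchor, nchar(msq), "", msq,
                         mirrored = TRUE)
        ins[[length(ins) + 1L]] <<- list(id = mid, anchor = manchor,
                                         seq = msq)
      }
      invisible(NULL)
    }
    for (pos in candi) {
      len <- stats::rgeom(1, 1 / cfg$indel_mean) + 1L
      if (stats::runif(1) < 0.5) {
        if (!primary[pos]) next
        apply_deletion(pos, len)
      } else {
        if (!primary[pos]) next
        apply_insertion(pos, random_dna(len, gc = 0.30))
      }
    }

    ## SSR slippage on planted tracts
    if (!is.null(ssrs) && nrow(ssrs)) {
      slip <- which(stats::runif(nrow(ssrs)) < cfg$slip_rate * bl)
      for (si in slip) {
        k <- nchar(ssrs$motif[si])
        t1 <- ssrs$start[si] + 1L
        t2 <- ssrs$start[si] + ssrs$copies[si] * k
        if (in_ir[t1]) next       # IR tracts homogenised, no slippage
        if (stats::runif(1) < 0.5) {
          apply_insertion(t2, ssrs$motif[si], kind = "slippage")
        } else {
          tract_alive <- (t1:t2)[!del[t1:t2]]
          if (length(tract_alive) >= k) {
            dpos <- tract_alive[seq_len(k)]
            del[dpos] <- TRUE
            log_event(lin, eidx, "slippage", dpos[1], k,
                      ints_seq(b[dpos]), "",
                      positions = paste(dpos, collapse = ","))
          }
        }
      }
    }
    states[[child]] <- list(b = b, del = del, ins = ins)
  }

  events <- do.call(rbind, ev$rows)
  if (is.null(events))
    events <- data.frame(id = integer(0), lineage = character(0),
                         branch = integer(0), kind = character(0),
                         pos = integer(0), length = integer(0),
                         ref = character(0), alt = character(0),
                         positions = character(0), mirrored = logical(0))

  ## assemble tip sequences and the true alignment
  tipstates <- lapply(seq_along(tree$tip.label), function(n) states[[n]])
  names(tipstates) <- tree$tip.label
  all_ins <- list()
  for (tn in names(tipstates))
    for (e in tipstates[[tn]]$ins) {
      key <- as.character(e$id)
      if (is.null(all_ins[[key]]))
        all_ins[[key]] <- list(id = e$id, anchor = e$anchor, seq = e$seq,
                               carriers = tn)
      else all_ins[[key]]$carriers <- c(all_ins[[key]]$carriers, tn)
    }
  ins_tab <- if (length(all_ins)) {
    tb <- data.frame(id = vapply(all_ins, `[[`, integer(1), "id"),
                     anchor = vapply(all_ins, `[[`, integer(1), "anchor"),
                     len = vapply(all_ins, function(x) nchar(x$seq),
                                  integer(1)))
    tb[order(tb$anchor, tb$id), , drop = FALSE]
  } else NULL

  row_names <- c("root", tree$tip.label)
  aln <- vapply(row_names, function(rn) {
    if (rn == "root") {
      chars <- strsplit(ints_seq(b0), "")[[1]]
    } else {
      st <- tipstates[[rn]]
      chars <- strsplit(ints_seq(st$b), "")[[1]]
      chars[st$del] <- "-"
    }
    if (is.null(ins_tab)) return(paste(chars, collapse = ""))
    parts <- character(0)
    prev <- 0L
    for (r in seq_len(nrow(ins_tab))) {
      a <- ins_tab$anchor[r]
      if (a > prev) {
        parts <- c(parts, paste(chars[(prev + 1L):a], collapse = ""))
        prev <- a
      }
      entry <- all_ins[[as.character(ins_tab$id[r])]]
      blk <- if (rn != "root" && rn %in% entry$carriers) entry$seq else
        strrep("-", ins_tab$len[r])
      parts <- c(parts, blk)
    }
    if (prev < L) parts <- c(parts, paste(chars[(prev + 1L):L], collapse = ""))
    paste(parts, collapse = "")
  }, character(1))

  tips <- lapply(tree$tip.label, function(tn)
    genome(tn, gsub("-", "", aln[[tn]], fixed = TRUE), circular = TRUE))
  names(tips) <- tree$tip.label

  structure(list(root = ag, partition = part, planted = root$planted,
                 tips = tips, alignment = aln, events = events,
                 tree = tree, config = cfg),
            class = "plastome_simulation")
}

#' @export
print.plastome_simulation <- function(x, ...) {
  cat("<plastome_simulation> ", length(x$tips), " tips, root ",
      x$root$genome$length, " bp, ", nrow(x$events), " logged events\n",
      sep = "")
  invisible(x)
}

#' Simulate annotated plastomes along a phylogeny
#'
#' Convenience wrapper: seeds the generator, builds the root genome and
#' evolves it along the configured tree.
#'
#' @param cfg a `simulation_config`.
#' @param seed integer seed fixing the whole event stream.
#' @return a `plastome_simulation` (see [evolve_along_tree()]).
#' @export
simulate_plastomes <- function(cfg = simulation_config(), seed = 1L) {
  set.seed(seed)
  root <- build_root_genome(cfg)
  sim <- evolve_along_tree(root, cfg)
  sim$seed <- seed
  sim
}

#' Replay a tip's event log onto the root sequence
#'
#' Independent reconstruction of a tip sequence from the ground-truth log:
#' events on the root-to-tip path are applied in id order.
#'
#' @param sim a `plastome_simulation`.
#' @param tip tip label.
#' @return character scalar: the reconstructed tip sequence.
#' @export
replay_events <- function(sim, tip) {
  tree <- sim$tree
  n_tip <- length(tree$tip.label)
  ti <- match(tip, tree$tip.label)
  if (is.na(ti)) stop("unknown tip '", tip, "'")
  ## edges on the root-to-tip path
  path <- integer(0)
  node <- ti
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (!length(e)) break
    path <- c(path, e)
    node <- tree$edge[e, 1]
  }
  evs <- sim$events[sim$events$branch %in% path, , drop = FALSE]
  evs <- evs[order(evs$id), , drop = FALSE]
  chars <- strsplit(sim$root$genome$sequence, "")[[1]]
  del <- rep(FALSE, length(chars))
  ins <- list()
  for (r in seq_len(nrow(evs))) {
    kind <- evs$kind[r]
    if (kind == "SNV") {
      chars[evs$pos[r]] <- evs$alt[r]
    } else if (kind %in% c("deletion", "slippage") && evs$alt[r] == "") {
      dpos <- as.integer(strsplit(evs$positions[r], ",")[[1]])
      del[dpos] <- TRUE
    } else {                                        # insertion / slippage gain
      key <- as.character(evs$pos[r])
      ins[[key]] <- c(ins[[key]], evs$alt[r])
    }
  }
  out <- character(0)
  anchors <- as.integer(names(ins))
  if (!is.null(ins[["0"]])) out <- paste(ins[["0"]], collapse = "")
  keep <- !del
  ## build by walking anchor segments
  ord <- sort(anchors[anchors > 0L])
  prev <- 0L
  parts <- if (length(out)) out else character(0)
  for (a in ord) {
    seg <- which(keep[(prev + 1L):a]) + prev
    parts <- c(parts, paste(chars[seg], collapse = ""),
               paste(ins[[as.character(a)]], collapse = ""))
    prev <- a
  }
  if (prev < length(chars)) {
    seg <- which(keep[(prev + 1L):length(chars)]) + prev
    parts <- c(parts, paste(chars[seg], collapse = ""))
  }
  paste(parts, collapse = "")
}

#' Write simulation outputs to files
#'
#' Emits tip FASTA, the annotated root GenBank record, the true multiple
#' alignment (gap-padded by event replay), the tree in Newick format and
#' the ground-truth event log as JSON.
#'
#' @param sim a `plastome_simulation`.
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
emit_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tips = file.path(dir, "tips.fasta"),
    root = file.path(dir, "root.gb"),
    alignment = file.path(dir, "alignment.fasta"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.json"))
  write_fasta(sim$tips, paths[["tips"]])
  write_genbank(sim$root, paths[["root"]])
  write_fasta(sim$alignment, paths[["alignment"]])
  ape::write.tree(sim$tree, paths[["tree"]])
  truth <- list(seed = sim$seed,
                regions = sim$partition$regions,
                planted = sim$planted,
                events = sim$events)
  jsonlite::write_json(truth, paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
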
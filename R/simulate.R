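# Synthetic multi-exon loci with paired isoforms, linked SNPs and
# error-bearing ESTs, plus full truth tables, so every pipeline stage can be
# validated without external data.
#
# Each simulated gene gets its own chromosome and carries exactly one
# structural event between two isoforms. With probability
# `fraction_allelic_events` the two isoforms come from two alleles (each
# allele carrying its own linked SNPs relative to the reference); otherwise
# both isoforms are alternative-splicing products of one SNP-bearing allele,
# so they share a SNP pattern. ESTs are windows of the isoform transcripts
# with uniform per-base substitution errors and no indels.

#' Simulation configuration
#'
#' Defaults reflect the study system this generator emulates: SNP density of
#' one per 100 bp, EST per-base substitution error 0.0044, an event-type mix
#' proportional to the observed genome-wide frequencies of the five
#' classifiable types (41:10:14:11:6), and 28% of events of allelic origin.
#'
#' @param n_genes number of simulated loci (one event each).
#' @param exons_per_gene integer range (min, max) of exons per gene.
#' @param exon_len,intron_len bp ranges.
#' @param snp_density allele SNPs per exonic bp.
#' @param est_error_rate per-base substitution error in ESTs.
#' @param ests_per_isoform integer range of ESTs sampled per isoform.
#' @param est_len bp range of EST window lengths (clamped to the transcript).
#' @param fraction_allelic_events probability an event is allelic.
#' @param event_type_mix named probabilities over
#'   IntronR/AltA/AltD/AltS/ExonS; must sum to 1.
#' @param utr5_len,utr3_len nominal UTR lengths in bp for the gene models
#'   (shrunk proportionally on short transcripts).
#' @param margin anchored exonic bases required on each side of the event in
#'   every EST window.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return config list (class `sim_config`).
#' @export
sim_config <- function(n_genes = 60L,
                       exons_per_gene = c(4L, 7L),
                       exon_len = c(120L, 300L),
                       intron_len = c(60L, 150L),
                       snp_density = 0.01,
                       est_error_rate = 0.0044,
                       ests_per_isoform = c(3L, 6L),
                       est_len = c(600L, 1200L),
                       fraction_allelic_events = 0.28,
                       event_type_mix = c(IntronR = 41, AltA = 10, AltD = 14,
                                          AltS = 11, ExonS = 6) / 82,
                       utr5_len = 234L,
                       utr3_len = 451L,
                       margin = 25L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
    exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
    snp_density = snp_density, est_error_rate = est_error_rate,
    ests_per_isoform = as.integer(ests_per_isoform),
    est_len = as.integer(est_len),
    fraction_allelic_events = fraction_allelic_events,
    event_type_mix = event_type_mix,
    utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
    margin = as.integer(margin), seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_genes > 0L, all(cfg$exons_per_gene >= 3L),
    all(cfg$exon_len > 0L), all(cfg$intron_len > 0L),
    cfg$snp_density >= 0, cfg$est_error_rate >= 0,
    cfg$fraction_allelic_events >= 0, cfg$fraction_allelic_events <= 1,
    abs(sum(cfg$event_type_mix) - 1) < 1e-8,
    all(names(cfg$event_type_mix) %in% c("IntronR", "AltA", "AltD", "AltS", "ExonS")),
    # alternative-site shifts need room for the shift plus anchors
    cfg$exon_len[1L] >= 2L * cfg$margin + 6L
  )
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rint <- function(rng) {
  if (rng[1L] >= rng[2L]) rng[1L] else sample(seq(rng[1L], rng[2L]), 1L)
}

# --- transcript coordinate mapping -----------------------------------------
# tx coordinates are 0-based along the mature transcript in transcription
# direction; for "-" strand genes tx position 0 is the genomic-rightmost
# exonic base.

tx_length <- function(blocks) sum(blocks[, 2L] - blocks[, 1L])

# genomic blocks (sorted) of tx window [ws, we)
tx_window_to_blocks <- function(blocks, strand, ws, we) {
  if (strand == "-") {
    rev_blocks <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
    out <- list()
    off <- 0L
    for (i in seq_len(nrow(rev_blocks))) {
      w <- rev_blocks[i, 2L] - rev_blocks[i, 1L]
      lo <- max(ws, off)
      hi <- min(we, off + w)
      if (lo < hi) {
        # tx runs right-to-left inside the block
        g_end <- rev_blocks[i, 2L] - (lo - off)
        g_start <- rev_blocks[i, 2L] - (hi - off)
        out[[length(out) + 1L]] <- c(g_start, g_end)
      }
      off <- off + w
    }
  } else {
    out <- list()
    off <- 0L
    for (i in seq_len(nrow(blocks))) {
      w <- blocks[i, 2L] - blocks[i, 1L]
      lo <- max(ws, off)
      hi <- min(we, off + w)
      if (lo < hi) {
        out[[length(out) + 1L]] <- c(blocks[i, 1L] + lo - off,
                                     blocks[i, 1L] + hi - off)
      }
      off <- off + w
    }
  }
  mat <- do.call(rbind, out)
  mat <- mat[order(mat[, 1L]), , drop = FALSE]
  colnames(mat) <- c("start", "end")
  storage.mode(mat) <- "integer"
  mat
}

# tx coordinate of an exonic genomic base; NA when intronic
genomic_to_tx <- function(blocks, strand, gpos) {
  off <- 0L
  if (strand == "-") {
    for (i in rev(seq_len(nrow(blocks)))) {
      w <- blocks[i, 2L] - blocks[i, 1L]
      if (gpos >= blocks[i, 1L] && gpos < blocks[i, 2L]) {
        return(off + (blocks[i, 2L] - 1L - gpos))
      }
      off <- off + w
    }
  } else {
    for (i in seq_len(nrow(blocks))) {
      w <- blocks[i, 2L] - blocks[i, 1L]
      if (gpos >= blocks[i, 1L] && gpos < blocks[i, 2L]) {
        return(off + (gpos - blocks[i, 1L]))
      }
      off <- off + w
    }
  }
  NA_integer_
}

# spliced transcript sequence (transcription orientation) from a haplotype
splice_seq <- function(hap_chars, blocks, strand) {
  parts <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    parts[i] <- paste(hap_chars[(blocks[i, 1L] + 1L):blocks[i, 2L]], collapse = "")
  }
  s <- paste(parts, collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

# tx coordinates (between-base positions) of a chain's junctions
junction_tx_positions <- function(blocks, strand) {
  if (nrow(blocks) < 2L) return(integer(0))
  w <- blocks[, 2L] - blocks[, 1L]
  if (strand == "-") w <- rev(w)
  cumsum(w)[-length(w)]
}

#' Simulate loci, isoforms, SNPs and ESTs with truth tables
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `genome.fa`,
#'   `ests.fa`, `alignments.bed` (BED12 plus coverage/identity percentage
#'   columns), `genes.gff3` and the truth tables as TSV.
#' @return list with `genome` and `ests` (`DNAStringSet`), `alignments`
#'   (internal alignment data.frame, exact truth placements), `gene_models`
#'   (internal list form), and `truth` (`genes`, `snps`, `ests`
#'   data.frames).
#' @export
simulate_tsv_data <- function(config = sim_config(), out_dir = NULL) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  genome <- character(config$n_genes)
  genome_names <- sprintf("chr%04d", seq_len(config$n_genes))
  est_seqs <- list()
  aln_rows <- list()
  truth_genes <- list()
  truth_snps <- list()
  truth_ests <- list()
  models <- list()

  for (g in seq_len(config$n_genes)) {
    gene <- simulate_gene(config, g, genome_names[g])
    genome[g] <- gene$ref_seq
    est_seqs <- c(est_seqs, gene$est_seqs)
    aln_rows[[g]] <- gene$alignments
    truth_genes[[g]] <- gene$truth_gene
    truth_snps[[g]] <- gene$truth_snps
    truth_ests[[g]] <- gene$truth_ests
    models[[g]] <- gene$model
  }

  alignments <- do.call(rbind, c(aln_rows, list(make.row.names = FALSE)))
  res <- list(
    genome = Biostrings::DNAStringSet(stats::setNames(genome, genome_names)),
    ests = Biostrings::DNAStringSet(unlist(est_seqs)),
    alignments = alignments,
    gene_models = models,
    truth = list(
      genes = do.call(rbind, c(truth_genes, list(make.row.names = FALSE))),
      snps = do.call(rbind, c(truth_snps, list(make.row.names = FALSE))),
      ests = do.call(rbind, c(truth_ests, list(make.row.names = FALSE)))
    )
  )
  if (!is.null(out_dir)) write_sim_bundle(res, out_dir)
  res
}

simulate_gene <- function(config, g, chrom) {
  k <- rint(config$exons_per_gene)
  exon_w <- vapply(seq_len(k), function(i) rint(config$exon_len), integer(1))
  intron_w <- vapply(seq_len(k - 1L), function(i) rint(config$intron_len), integer(1))
  flank <- 300L
  starts <- integer(k)
  pos <- flank
  for (i in seq_len(k)) {
    starts[i] <- pos
    pos <- pos + exon_w[i] + if (i < k) intron_w[i] else 0L
  }
  exons <- cbind(start = starts, end = starts + exon_w)
  storage.mode(exons) <- "integer"
  glen <- pos + flank
  strand <- sample(c("+", "-"), 1L)
  type <- sample(names(config$event_type_mix), 1L, prob = config$event_type_mix)

  canonical <- exons
  variant <- NULL
  region <- NULL
  min_delta <- 6L
  if (type == "IntronR") {
    r <- rint(c(1L, k - 1L))
    variant <- rbind(
      exons[seq_len(r - 1L), , drop = FALSE],
      c(exons[r, 1L], exons[r + 1L, 2L]),
      if (r + 1L < k) exons[seq(r + 2L, k), , drop = FALSE]
    )
    region <- c(exons[r, 2L], exons[r + 1L, 1L])
  } else if (type == "ExonS") {
    x <- rint(c(2L, k - 1L))
    variant <- exons[-x, , drop = FALSE]
    region <- c(exons[x, 1L], exons[x, 2L])
  } else {
    r <- rint(c(1L, k - 1L))
    max_d_right <- exon_w[r + 1L] - 2L * config$margin
    max_d_left <- exon_w[r] - 2L * config$margin
    move_right <- switch(type,
      AltA = strand == "+",
      AltD = strand == "-",
      AltS = NA
    )
    variant <- exons
    if (type == "AltS") {
      d1 <- rint(c(min_delta, max(min_delta, max_d_left)))
      d2 <- rint(c(min_delta, max(min_delta, max_d_right)))
      variant[r, 2L] <- exons[r, 2L] - d1
      variant[r + 1L, 1L] <- exons[r + 1L, 1L] + d2
      region <- c(variant[r, 2L], variant[r + 1L, 1L])
    } else if (isTRUE(move_right)) {
      d <- rint(c(min_delta, max(min_delta, max_d_right)))
      variant[r + 1L, 1L] <- exons[r + 1L, 1L] + d
      region <- c(exons[r + 1L, 1L], variant[r + 1L, 1L])
    } else {
      d <- rint(c(min_delta, max(min_delta, max_d_left)))
      variant[r, 2L] <- exons[r, 2L] - d
      region <- c(variant[r, 2L], exons[r, 2L])
    }
  }
  storage.mode(variant) <- "integer"
  ld <- abs(exonic_bp(canonical, region[1L], region[2L]) -
              exonic_bp(variant, region[1L], region[2L]))

  ref_seq <- random_dna(glen)
  ref_chars <- strsplit(ref_seq, "", fixed = TRUE)[[1L]]
  allelic <- stats::runif(1L) < config$fraction_allelic_events
  source <- if (allelic) "allelic" else "alternative_splicing"

  plant_snps <- function(blocks, exclude = NULL) {
    out <- list()
    for (i in seq_len(nrow(blocks))) {
      p <- blocks[i, 1L]:(blocks[i, 2L] - 1L)
      hit <- p[stats::runif(length(p)) < config$snp_density]
      for (h in hit) {
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref_chars[h + 1L]), 1L)
        key <- paste(h, alt)
        if (!is.null(exclude) && key %in% exclude) next
        out[[length(out) + 1L]] <- data.frame(
          pos = h, ref = ref_chars[h + 1L], alt = alt, stringsAsFactors = FALSE
        )
      }
    }
    if (length(out) == 0L) {
      return(data.frame(pos = integer(0), ref = character(0), alt = character(0),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, out)
  }
  apply_snps <- function(chars, snps) {
    if (nrow(snps)) chars[snps$pos + 1L] <- snps$alt
    chars
  }

  if (allelic) {
    snps1 <- plant_snps(canonical)
    snps2 <- plant_snps(merge_blocks(variant),
                        exclude = paste(snps1$pos, snps1$alt))
    snp_exposure <- tx_length(canonical) + tx_length(merge_blocks(variant))
    hap1 <- apply_snps(ref_chars, snps1)
    hap2 <- apply_snps(ref_chars, snps2)
    iso_defs <- list(
      list(iso = 1L, allele = 1L, blocks = canonical, hap = hap1),
      list(iso = 2L, allele = 2L, blocks = variant, hap = hap2)
    )
    snp_truth <- rbind(
      if (nrow(snps1)) cbind(snps1, allele = 1L),
      if (nrow(snps2)) cbind(snps2, allele = 2L)
    )
  } else {
    snp_exposure <- tx_length(merge_blocks(rbind(canonical, variant)))
    snps_shared <- plant_snps(merge_blocks(rbind(canonical, variant)))
    hap <- apply_snps(ref_chars, snps_shared)
    iso_defs <- list(
      list(iso = 1L, allele = 1L, blocks = canonical, hap = hap),
      list(iso = 2L, allele = 1L, blocks = variant, hap = hap)
    )
    snp_truth <- if (nrow(snps_shared)) cbind(snps_shared, allele = 1L) else NULL
  }

  gene_id <- sprintf("gene%04d", g)
  est_seqs <- list()
  truth_ests <- list()
  aln <- list()
  for (idef in iso_defs) {
    blocks <- idef$blocks
    txlen <- tx_length(blocks)
    tx_seq <- splice_seq(idef$hap, blocks, strand)
    ref_tx <- splice_seq(ref_chars, blocks, strand)
    win <- required_tx_window(blocks, strand, region, config$margin, txlen)
    n_est <- rint(config$ests_per_isoform)
    for (e in seq_len(n_est)) {
      L <- min(txlen, max(win[2L] - win[1L], rint(config$est_len)))
      ws_lo <- max(0L, win[2L] - L)
      ws_hi <- min(win[1L], txlen - L)
      ws <- if (ws_hi <= ws_lo) ws_lo else rint(c(ws_lo, ws_hi))
      we <- ws + L
      est_id <- sprintf("%s_iso%d_est%02d", gene_id, idef$iso, e)
      seq_chars <- strsplit(substr(tx_seq, ws + 1L, we), "", fixed = TRUE)[[1L]]
      n_err <- 0L
      if (config$est_error_rate > 0) {
        hit <- which(stats::runif(L) < config$est_error_rate)
        for (h in hit) {
          seq_chars[h] <- sample(setdiff(c("A", "C", "G", "T"), seq_chars[h]), 1L)
        }
        n_err <- length(hit)
      }
      ref_chars_win <- strsplit(substr(ref_tx, ws + 1L, we), "", fixed = TRUE)[[1L]]
      identity <- mean(seq_chars == ref_chars_win)
      est_seqs[[est_id]] <- paste(seq_chars, collapse = "")
      gblocks <- tx_window_to_blocks(blocks, strand, ws, we)
      aln[[length(aln) + 1L]] <- list(est_id = est_id, blocks = gblocks,
                                      identity = identity)
      truth_ests[[length(truth_ests) + 1L]] <- data.frame(
        est_id = est_id, gene_id = gene_id, allele = idef$allele,
        isoform = idef$iso, tx_start = ws, tx_end = we, n_errors = n_err,
        stringsAsFactors = FALSE
      )
    }
  }

  alignments <- new_alignments(
    est_id = vapply(aln, `[[`, "", "est_id"),
    chrom = chrom, strand = strand,
    blocks = lapply(aln, `[[`, "blocks"),
    coverage = 1,
    identity = vapply(aln, `[[`, 0, "identity"),
    source_tag = "sim"
  )

  truth_snps <- if (is.null(snp_truth) || nrow(snp_truth) == 0L) {
    data.frame(gene_id = character(0), chrom = character(0), allele = integer(0),
               pos = integer(0), ref = character(0), alt = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = gene_id, chrom = chrom, allele = snp_truth$allele,
               pos = snp_truth$pos, ref = snp_truth$ref, alt = snp_truth$alt,
               stringsAsFactors = FALSE)
  }

  list(
    ref_seq = ref_seq,
    est_seqs = est_seqs,
    alignments = alignments,
    truth_gene = data.frame(
      gene_id = gene_id, chrom = chrom, strand = strand, type = type,
      source = source, region_start = region[1L], region_end = region[2L],
      length_difference = ld, snp_exposure_bp = snp_exposure,
      stringsAsFactors = FALSE
    ),
    truth_snps = truth_snps,
    truth_ests = do.call(rbind, c(truth_ests, list(make.row.names = FALSE))),
    model = gene_model_for(gene_id, chrom, strand, canonical, config)
  )
}

# smallest tx interval every EST window must contain: the event's exonic
# anchors plus `margin` bases, extended to cross at least one of the
# isoform's own splice junctions (so the alignment stays multi-exonic)
required_tx_window <- function(blocks, strand, region, margin, txlen) {
  anchor <- function(gpos, dir) {
    # nearest exonic base at/adjacent to gpos, searching in genomic direction dir
    repeat {
      t <- genomic_to_tx(blocks, strand, gpos)
      if (!is.na(t)) return(t)
      gpos <- gpos + dir
      if (gpos < blocks[1L, 1L] || gpos >= blocks[nrow(blocks), 2L]) {
        stop("event region outside isoform span")
      }
    }
  }
  tL <- anchor(region[1L] - 1L, -1L)
  tR <- anchor(region[2L], 1L)
  lo <- max(0L, min(tL, tR) - margin + 1L)
  hi <- min(txlen, max(tL, tR) + margin)
  jx <- junction_tx_positions(blocks, strand)
  if (length(jx) > 0L && !any(jx > lo & jx < hi)) {
    j <- jx[which.min(pmin(abs(jx - lo), abs(jx - hi)))]
    lo <- max(0L, min(lo, j - margin))
    hi <- min(txlen, max(hi, j + margin))
  }
  c(as.integer(lo), as.integer(hi))
}

gene_model_for <- function(gene_id, chrom, strand, exons, config) {
  txlen <- tx_length(exons)
  u5 <- config$utr5_len
  u3 <- config$utr3_len
  if (u5 + u3 + 150L > txlen) {
    scale <- (txlen - 150L) / (u5 + u3)
    u5 <- max(30L, as.integer(floor(u5 * scale)))
    u3 <- max(30L, as.integer(floor(u3 * scale)))
  }
  cds_len <- txlen - u5 - u3
  u3 <- u3 + cds_len %% 3L  # keep the CDS a whole number of codons
  cds_blocks <- tx_window_to_blocks(exons, strand, u5, txlen - u3)
  list(gene_id = paste0(gene_id, ".t1"), chrom = chrom, strand = strand,
       exons = exons, cds = cds_blocks,
       utr5 = setdiff_utr(exons, cds_blocks, strand, five_prime = TRUE),
       utr3 = setdiff_utr(exons, cds_blocks, strand, five_prime = FALSE))
}

setdiff_utr <- function(exons, cds, strand, five_prime) {
  utr <- setdiff_blocks(exons, cds)
  if (nrow(utr) == 0L) return(utr)
  lo <- min(cds[, 1L])
  hi <- max(cds[, 2L])
  left <- utr[utr[, 2L] <= lo, , drop = FALSE]
  right <- utr[utr[, 1L] >= hi, , drop = FALSE]
  if ((strand == "+") == five_prime) left else right
}

#' Write a simulation bundle to disk
#'
#' @param sim result of [simulate_tsv_data()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(out_dir, "genome.fa"))
  Biostrings::writeXStringSet(sim$ests, file.path(out_dir, "ests.fa"))
  write_alignments_bed12(sim$alignments, file.path(out_dir, "alignments.bed"))
  write_gene_models_gff3(sim$gene_models, file.path(out_dir, "genes.gff3"))
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(sim$truth$genes, "truth_genes.tsv")
  tsv(sim$truth$snps, "truth_snps.tsv")
  tsv(sim$truth$ests, "truth_ests.tsv")
  invisible(out_dir)
}

#' Write alignments as BED12 plus coverage/identity columns
#'
#' Columns 13 and 14 hold coverage and identity as percentages, the dialect
#' [read_alignments()] accepts.
#'
#' @param alns alignment data.frame.
#' @param path output path.
#' @export
write_alignments_bed12 <- function(alns, path) {
  lines <- character(nrow(alns))
  for (i in seq_len(nrow(alns))) {
    b <- alns$blocks[[i]]
    lines[i] <- paste(
      alns$chrom[i], alns$start[i], alns$end[i], alns$est_id[i], 0,
      alns$strand[i], alns$start[i], alns$end[i], "0,0,0", nrow(b),
      paste0(paste(b[, 2L] - b[, 1L], collapse = ","), ","),
      paste0(paste(b[, 1L] - alns$start[i], collapse = ","), ","),
      formatC(alns$coverage[i] * 100, format = "f", digits = 4),
      formatC(alns$identity[i] * 100, format = "f", digits = 4),
      sep = "\t"
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param models list of gene models (internal form with `exons` and `cds`).
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- c(min(m$exons[, 1L]), max(m$exons[, 2L]))
    gid <- sub("\\.t1$", "", m$gene_id)
    lines <- c(lines,
      paste(m$chrom, "sim", "gene", span[1L] + 1L, span[2L], ".", m$strand, ".",
            sprintf("ID=%s", gid), sep = "\t"),
      paste(m$chrom, "sim", "mRNA", span[1L] + 1L, span[2L], ".", m$strand, ".",
            sprintf("ID=%s;Parent=%s", m$gene_id, gid), sep = "\t")
    )
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, paste(m$chrom, "sim", "exon", m$exons[i, 1L] + 1L,
                              m$exons[i, 2L], ".", m$strand, ".",
                              sprintf("ID=%s.exon%d;Parent=%s", m$gene_id, i, m$gene_id),
                              sep = "\t"))
    }
    for (i in seq_len(nrow(m$cds))) {
      lines <- c(lines, paste(m$chrom, "sim", "CDS", m$cds[i, 1L] + 1L,
                              m$cds[i, 2L], ".", m$strand, "0",
                              sprintf("ID=%s.cds;Parent=%s", m$gene_id, m$gene_id),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
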
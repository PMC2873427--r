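# Mismatch SNP calling between ESTs and the reference genome.
#
# Calls are plain data.frames, 0-based positions, all bases reported on the
# genome forward strand regardless of EST orientation:
#   chrom, pos, ref, alt, est_id                      (per-EST raw calls)
#   chrom, pos, ref, alt, est_ids (list), n_est, is_msnp   (aggregated)

# Callable sub-intervals of an alignment's blocks after end/gap masking;
# shared between mismatch calling and SNP-pattern construction so that a
# masked position is uniformly "no information" rather than "reference".
callable_blocks <- function(blocks, end_mask, gap_mask) {
  n_blk <- nrow(blocks)
  out <- list()
  for (j in seq_len(n_blk)) {
    lead <- if (j == 1L) end_mask else gap_mask
    tail_m <- if (j == n_blk) end_mask else gap_mask
    lo <- blocks[j, 1L] + lead
    hi <- blocks[j, 2L] - tail_m
    if (lo < hi) out[[length(out) + 1L]] <- c(lo, hi)
  }
  if (length(out) == 0L) return(empty_blocks())
  mat <- do.call(rbind, out)
  colnames(mat) <- c("start", "end")
  storage.mode(mat) <- "integer"
  mat
}

#' Call mismatches between one EST and the reference genome
#'
#' Walks the alignment blocks and reports every aligned position where the
#' EST base differs from the reference, both bases being unambiguous
#' (A/C/G/T). Positions within `end_mask` bases of the alignment's outer
#' ends and within `gap_mask` bases of any internal block boundary are
#' skipped, suppressing alignment-artifact mismatches near splice junctions
#' and read ends; `end_mask = 0, gap_mask = 0` disables masking.
#'
#' The EST sequence is given in its sequenced orientation: for minus-strand
#' alignments it is reverse-complemented internally so that calls are always
#' reported on the genome forward strand.
#'
#' @param aln one-row alignment data.frame.
#' @param est_seq `Biostrings::DNAString` (or character) EST sequence whose
#'   length equals the summed block lengths.
#' @param genome named `Biostrings::DNAStringSet`.
#' @param end_mask,gap_mask masking distances in bp.
#' @return data.frame of singleton calls: `chrom`, `pos`, `ref`, `alt`, `est_id`.
#' @export
call_mismatches <- function(aln, est_seq, genome, end_mask = 3L, gap_mask = 5L) {
  blocks <- aln$blocks[[1L]]
  est <- toupper(as.character(est_seq))
  aligned_len <- sum(blocks[, 2L] - blocks[, 1L])
  if (nchar(est) != aligned_len) {
    stop("EST ", aln$est_id, ": sequence length (", nchar(est),
         ") does not match summed block lengths (", aligned_len, ")")
  }
  if (identical(aln$strand, "-")) {
    est <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(est)))
  }
  if (!aln$chrom %in% names(genome)) {
    stop("chromosome ", aln$chrom, " not in genome for EST ", aln$est_id)
  }
  chr <- genome[[aln$chrom]]
  est_raw <- charToRaw(est)
  n_blk <- nrow(blocks)
  offs <- c(0L, cumsum(blocks[, 2L] - blocks[, 1L]))
  out <- list()
  for (j in seq_len(n_blk)) {
    w <- blocks[j, 2L] - blocks[j, 1L]
    lead <- if (j == 1L) end_mask else gap_mask
    tail_m <- if (j == n_blk) end_mask else gap_mask
    lo <- lead + 1L
    hi <- w - tail_m
    if (lo > hi) next
    ref_blk <- charToRaw(toupper(as.character(
      Biostrings::subseq(chr, blocks[j, 1L] + 1L, blocks[j, 2L])
    )))
    est_blk <- est_raw[(offs[j] + 1L):(offs[j] + w)]
    idx <- which(ref_blk != est_blk)
    idx <- idx[idx >= lo & idx <= hi]
    if (length(idx) == 0L) next
    rb <- rawToChar(ref_blk[idx], multiple = TRUE)
    eb <- rawToChar(est_blk[idx], multiple = TRUE)
    ok <- rb %in% c("A", "C", "G", "T") & eb %in% c("A", "C", "G", "T")
    if (!any(ok)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = aln$chrom,
      pos = blocks[j, 1L] + idx[ok] - 1L,
      ref = rb[ok],
      alt = eb[ok],
      est_id = aln$est_id,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), est_id = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Call mismatches for a whole alignment set
#'
#' @param alns alignment data.frame (one best alignment per EST).
#' @param est_seqs named `Biostrings::DNAStringSet` of EST sequences.
#' @param genome named `Biostrings::DNAStringSet`.
#' @inheritParams call_mismatches
#' @return data.frame of singleton calls.
#' @export
call_snps <- function(alns, est_seqs, genome, end_mask = 3L, gap_mask = 5L) {
  empty <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), est_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(alns) == 0L) return(empty)
  out <- vector("list", nrow(alns))
  for (i in seq_len(nrow(alns))) {
    id <- alns$est_id[i]
    if (!id %in% names(est_seqs)) stop("no sequence for EST ", id)
    out[[i]] <- call_mismatches(alns[i, , drop = FALSE], est_seqs[[id]],
                                genome, end_mask, gap_mask)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) empty else res
}

#' Aggregate per-EST calls and apply the multi-EST (mSNP) filter
#'
#' Calls with identical (chrom, pos, alt) are merged, their supporting ESTs
#' unioned, and only calls supported by at least `min_ests` ESTs are
#' returned. With the default `min_ests = 2` the result is the mSNP set,
#' which suppresses sequencing-error false positives; `min_ests = 1` returns
#' all aggregated calls. Different alternative bases at one position remain
#' separate records.
#'
#' @param calls singleton-call data.frame from [call_snps()].
#' @param min_ests minimum number of distinct supporting ESTs.
#' @return aggregated call data.frame: `chrom`, `pos`, `ref`, `alt`,
#'   list-column `est_ids`, `n_est`, `is_msnp`.
#' @export
aggregate_and_filter <- function(calls, min_ests = 2L) {
  if (nrow(calls) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), n_est = integer(0), is_msnp = logical(0),
                      stringsAsFactors = FALSE)
    out$est_ids <- list()
    return(out)
  }
  key <- paste(calls$chrom, calls$pos, calls$alt, sep = "|")
  grp <- split(seq_len(nrow(calls)), key)
  first <- vapply(grp, `[`, 0L, 1L)
  out <- data.frame(
    chrom = calls$chrom[first],
    pos = calls$pos[first],
    ref = calls$ref[first],
    alt = calls$alt[first],
    stringsAsFactors = FALSE
  )
  out$est_ids <- lapply(grp, function(ii) unique(calls$est_id[ii]))
  out$n_est <- vapply(out$est_ids, length, integer(1))
  out$is_msnp <- out$n_est >= 2L
  out <- out[out$n_est >= min_ests, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' EST length expected to contain one sequencing-error false positive
#'
#' The reciprocal of the per-base sequencing error rate: at that EST length
#' the expected number of error mismatches is one. At the EST error rate of
#' 0.0044 per bp this is a 227-bp EST.
#'
#' @param error_rate errors per base pair, > 0.
#' @return integer length in bp.
#' @export
est_length_for_one_false_positive <- function(error_rate) {
  if (!is.numeric(error_rate) || length(error_rate) != 1L || error_rate <= 0) {
    stop("error_rate must be a single positive number")
  }
  as.integer(round(1 / error_rate))
}

#' Write aggregated SNP calls as VCF
#'
#' Minimal VCF 4.2 with one record per (chrom, pos, alt) and INFO fields
#' `EST_IDS`, `N_EST` and the `MSNP` flag.
#'
#' @param snps aggregated call data.frame from [aggregate_and_filter()].
#' @param path output path.
#' @export
write_snp_vcf <- function(snps, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=EST_IDS,Number=.,Type=String,Description=\"Supporting EST identifiers\">",
    "##INFO=<ID=N_EST,Number=1,Type=Integer,Description=\"Number of supporting ESTs\">",
    "##INFO=<ID=MSNP,Number=0,Type=Flag,Description=\"Supported by more than one EST\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    info <- sprintf("EST_IDS=%s;N_EST=%d",
                    paste(snps$est_ids[[i]], collapse = ","), snps$n_est[i])
    if (snps$is_msnp[i]) info <- paste0(info, ";MSNP")
    body[i] <- paste(snps$chrom[i], snps$pos[i] + 1L, ".", snps$ref[i],
                     snps$alt[i], ".", ".", info, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
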
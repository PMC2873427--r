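# Spliced-alignment ingestion, quality filtering and transcript clustering.
#
# A set of spliced alignments is kept as a plain data.frame with one row per
# alignment and a list-column of exon blocks:
#   est_id     character, the EST identifier
#   chrom      character
#   strand     "+", "-" or "*" (unknown)
#   start,end  integer span (0-based half-open) over all blocks
#   n_blocks   integer
#   coverage   fraction of the EST aligned, in [0,1], NA when absent
#   identity   fraction of aligned bases matching the reference, NA when absent
#   source_tag character, identifies the aligner / input set
#   blocks     list of integer matrices (cols start,end; 0-based half-open)

new_alignments <- function(est_id, chrom, strand, blocks, coverage, identity,
                           source_tag) {
  stopifnot(length(est_id) == length(blocks))
  df <- data.frame(
    est_id = as.character(est_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    start = vapply(blocks, function(b) if (nrow(b)) b[1L, 1L] else NA_integer_, integer(1)),
    end = vapply(blocks, function(b) if (nrow(b)) b[nrow(b), 2L] else NA_integer_, integer(1)),
    n_blocks = vapply(blocks, nrow, integer(1)),
    coverage = as.numeric(coverage),
    identity = as.numeric(identity),
    source_tag = as.character(source_tag),
    stringsAsFactors = FALSE
  )
  df$blocks <- blocks
  validate_alignments(df)
  df
}

empty_alignments <- function() {
  new_alignments(character(0), character(0), character(0), list(),
                 numeric(0), numeric(0), character(0))
}

validate_alignments <- function(alns) {
  for (i in seq_len(nrow(alns))) {
    b <- alns$blocks[[i]]
    if (nrow(b) == 0L) {
      stop("alignment ", alns$est_id[i], " has no blocks")
    }
    if (any(b[, 2L] <= b[, 1L])) {
      stop("alignment ", alns$est_id[i], " has an empty or inverted block")
    }
    if (nrow(b) > 1L && any(diff(b[, 1L]) <= 0 | b[-1L, 1L] < b[-nrow(b), 2L])) {
      stop("alignment ", alns$est_id[i], " has unsorted or overlapping blocks")
    }
  }
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok(alns$coverage) || !ok(alns$identity)) {
    stop("coverage and identity must be in [0,1] or NA")
  }
  invisible(alns)
}

#' Read spliced EST-to-genome alignments
#'
#' Reads spliced alignments from BED12 or GFF3 into the internal alignment
#' table (0-based half-open block coordinates).
#'
#' For BED12, two optional extra columns (13: coverage, 14: identity, both as
#' percentages) are recognised; plain 12-column files yield `NA` for both.
#' For GFF3, alignment parts are `match_part` or `exon` features grouped by
#' `Parent`; `coverage` and `identity` attributes (percentages) are read from
#' the parent feature when present, else from the first part carrying them.
#'
#' @param path path to the alignment file.
#' @param format `"bed12"` or `"gff3"`.
#' @param source_tag label identifying the aligner or input set.
#' @return alignment data.frame (see package overview), one row per alignment.
#' @export
read_alignments <- function(path, format = c("bed12", "gff3"), source_tag = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  switch(format,
    bed12 = read_alignments_bed12(path, source_tag),
    gff3 = read_alignments_gff3(path, source_tag)
  )
}

read_alignments_bed12 <- function(path, source_tag) {
  raw <- readLines(path)
  keep <- !grepl("^(#|track|browser)", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  raw <- raw[keep]
  if (length(raw) == 0L) return(empty_alignments())
  fields <- strsplit(raw, "\t", fixed = TRUE)
  # fall back to whitespace splitting for space-delimited files
  if (length(fields[[1L]]) == 1L) fields <- strsplit(raw, "[[:space:]]+")
  recs <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 12L) {
      stop("malformed BED12 record at line ", lineno[i],
           ": expected >= 12 fields, got ", length(f))
    }
    chrom_start <- suppressWarnings(as.integer(f[2L]))
    n_blk <- suppressWarnings(as.integer(f[10L]))
    sizes <- suppressWarnings(as.integer(strsplit(f[11L], ",")[[1L]]))
    starts <- suppressWarnings(as.integer(strsplit(f[12L], ",")[[1L]]))
    if (is.na(chrom_start) || is.na(n_blk) ||
        anyNA(sizes) || anyNA(starts) ||
        length(sizes) != n_blk || length(starts) != n_blk) {
      stop("malformed BED12 record at line ", lineno[i],
           ": inconsistent blockCount/blockSizes/blockStarts")
    }
    b <- cbind(start = chrom_start + starts, end = chrom_start + starts + sizes)
    storage.mode(b) <- "integer"
    cov <- if (length(f) >= 13L) suppressWarnings(as.numeric(f[13L])) / 100 else NA_real_
    idy <- if (length(f) >= 14L) suppressWarnings(as.numeric(f[14L])) / 100 else NA_real_
    strand <- if (f[6L] %in% c("+", "-")) f[6L] else "*"
    recs[[i]] <- list(est_id = f[4L], chrom = f[1L], strand = strand,
                      blocks = b, coverage = cov, identity = idy)
  }
  new_alignments(
    est_id = vapply(recs, `[[`, "", "est_id"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    strand = vapply(recs, `[[`, "", "strand"),
    blocks = lapply(recs, `[[`, "blocks"),
    coverage = vapply(recs, `[[`, 0, "coverage"),
    identity = vapply(recs, `[[`, 0, "identity"),
    source_tag = source_tag
  )
}

read_alignments_gff3 <- function(path, source_tag) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_alignments())
  md <- S4Vectors::mcols(gr)
  is_part <- as.character(md$type) %in% c("match_part", "exon")
  parts <- gr[is_part]
  if (length(parts) == 0L) {
    stop("no match_part or exon features found in ", path)
  }
  pmd <- S4Vectors::mcols(parts)
  parent <- vapply(seq_along(parts), function(i) {
    p <- pmd$Parent[[i]]
    if (length(p) == 0L) {
      stop("alignment part without Parent in ", path,
           " (feature ", i, " of type ", as.character(pmd$type)[i], ")")
    }
    as.character(p[[1L]])
  }, character(1))
  get_attr <- function(md_tab, nm, idx) {
    if (!nm %in% colnames(md_tab)) return(NA_real_)
    suppressWarnings(as.numeric(as.character(md_tab[[nm]][idx])))
  }
  parents_md <- md[!is_part, , drop = FALSE]
  parent_ids <- if ("ID" %in% colnames(parents_md)) as.character(parents_md$ID) else character(0)
  ids <- unique(parent)
  blocks <- vector("list", length(ids))
  strand <- coverage <- identity <- est_id <- character(length(ids))
  chrom <- character(length(ids))
  cov <- idy <- numeric(length(ids))
  for (k in seq_along(ids)) {
    sel <- which(parent == ids[k])
    p <- parts[sel]
    o <- order(BiocGenerics::start(p))
    p <- p[o]
    sel <- sel[o]
    b <- cbind(start = BiocGenerics::start(p) - 1L, end = BiocGenerics::end(p))
    storage.mode(b) <- "integer"
    blocks[[k]] <- b
    chrom[k] <- as.character(GenomicRanges::seqnames(p))[1L]
    s <- as.character(BiocGenerics::strand(p))[1L]
    strand[k] <- if (s %in% c("+", "-")) s else "*"
    pi <- match(ids[k], parent_ids)
    c_val <- if (!is.na(pi)) get_attr(parents_md, "coverage", pi) else NA_real_
    i_val <- if (!is.na(pi)) get_attr(parents_md, "identity", pi) else NA_real_
    if (is.na(c_val)) c_val <- get_attr(pmd, "coverage", sel[1L])
    if (is.na(i_val)) i_val <- get_attr(pmd, "identity", sel[1L])
    cov[k] <- c_val / 100
    idy[k] <- i_val / 100
    nm <- NA_character_
    if (!is.na(pi) && "Name" %in% colnames(parents_md)) {
      nm <- as.character(parents_md$Name[pi])
    }
    est_id[k] <- if (!is.na(nm) && nzchar(nm)) nm else ids[k]
  }
  new_alignments(est_id, chrom, strand, blocks, cov, idy, source_tag)
}

#' Filter alignments on coverage and identity
#'
#' Retains alignments with coverage strictly greater than `min_coverage` and
#' identity strictly greater than `min_identity` (matching the ">80%",
#' ">95%" convention of EST-to-genome screening).
#'
#' @param alns alignment data.frame.
#' @param min_coverage,min_identity thresholds in `[0,1]`.
#' @param missing policy for alignments whose coverage or identity is `NA`:
#'   `"reject"` (default) or `"pass"`.
#' @return filtered alignment data.frame.
#' @export
filter_alignments <- function(alns, min_coverage = 0.80, min_identity = 0.95,
                              missing = c("reject", "pass")) {
  missing <- match.arg(missing)
  stopifnot(min_coverage >= 0, min_coverage <= 1,
            min_identity >= 0, min_identity <= 1)
  if (nrow(alns) == 0L) return(alns)
  has <- !is.na(alns$coverage) & !is.na(alns$identity)
  keep <- has & alns$coverage > min_coverage & alns$identity > min_identity
  if (missing == "pass") keep <- keep | !has
  alns[keep, , drop = FALSE]
}

#' Drop single-exon alignments
#'
#' Uniexonic alignments are removed to avoid genomic-DNA or premature-mRNA
#' contamination; only alignments with at least two exon blocks are kept.
#'
#' @param alns alignment data.frame.
#' @return alignment data.frame with `n_blocks >= 2`.
#' @export
drop_uniexonic <- function(alns) {
  alns[alns$n_blocks >= 2L, , drop = FALSE]
}

#' Keep the single best alignment per EST
#'
#' When an EST matches several loci, only its best placement (maximum
#' `identity * coverage`) is kept. Ties break deterministically by
#' (chrom, start, input order). Alignments with missing scores rank last.
#'
#' @param alns alignment data.frame.
#' @return alignment data.frame with one row per `est_id`.
#' @export
best_alignment_per_est <- function(alns) {
  if (nrow(alns) == 0L) return(alns)
  score <- alns$identity * alns$coverage
  score[is.na(score)] <- -Inf
  ord <- order(alns$est_id, -score, alns$chrom, alns$start, seq_len(nrow(alns)))
  alns <- alns[ord, , drop = FALSE]
  alns[!duplicated(alns$est_id), , drop = FALSE]
}

#' Infer strand from splice-site dinucleotides
#'
#' For alignments with unknown strand (`"*"`), inspects the first and last
#' two bases of each intron for the canonical GT..AG (forward) or CT..AC
#' (reverse) signals and assigns the majority orientation. Alignments whose
#' introns give no net signal stay `"*"`.
#'
#' @param alns alignment data.frame.
#' @param genome named `Biostrings::DNAStringSet` of reference chromosomes.
#' @return alignment data.frame with strands filled in where inferable.
#' @export
infer_strands <- function(alns, genome) {
  for (i in which(alns$strand == "*")) {
    introns <- intron_chain(alns$blocks[[i]])
    if (nrow(introns) == 0L) next
    chr <- genome[[alns$chrom[i]]]
    votes <- 0L
    for (j in seq_len(nrow(introns))) {
      d <- as.character(Biostrings::subseq(chr, introns[j, 1L] + 1L, introns[j, 1L] + 2L))
      a <- as.character(Biostrings::subseq(chr, introns[j, 2L] - 1L, introns[j, 2L]))
      if (d == "GT" && a == "AG") votes <- votes + 1L
      if (d == "CT" && a == "AC") votes <- votes - 1L
    }
    if (votes > 0L) alns$strand[i] <- "+"
    if (votes < 0L) alns$strand[i] <- "-"
  }
  alns
}

#' Cluster alignments into transcript clusters
#'
#' Single-linkage clustering of alignments by exonic (block-level) overlap of
#' at least 1 bp on the same chromosome and strand. Within each cluster,
#' members with identical intron chains collapse into one isoform.
#'
#' @param alns alignment data.frame (already filtered).
#' @return list of transcript clusters (class `tsv_clusters`). Each cluster is
#'   a list with `cluster_id`, `chrom`, `strand`, `members` (alignment rows)
#'   and `isoforms`, where each isoform carries its intron `chain` (matrix),
#'   supporting `est_ids`, `span` and the union of member exon `blocks`.
#' @export
cluster_alignments <- function(alns) {
  clusters <- list()
  if (nrow(alns) > 0L) {
    grp <- paste(alns$chrom, alns$strand, sep = "\r")
    for (g in unique(grp)) {
      idx <- which(grp == g)
      blk <- do.call(rbind, alns$blocks[idx])
      blk_aln <- rep(seq_along(idx), vapply(alns$blocks[idx], nrow, integer(1)))
      ir <- IRanges::IRanges(start = blk[, 1L] + 1L, end = blk[, 2L])
      red <- IRanges::reduce(ir, min.gapwidth = 0L)
      hit <- IRanges::findOverlaps(ir, red)
      parent <- uf_new(length(idx))
      for (r in unique(S4Vectors::subjectHits(hit))) {
        members <- unique(blk_aln[S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == r]])
        if (length(members) > 1L) {
          for (m in members[-1L]) parent <- uf_union(parent, members[1L], m)
        }
      }
      comp <- uf_components(parent)
      for (cc in unique(comp)) {
        rows <- idx[comp == cc]
        clusters[[length(clusters) + 1L]] <- build_cluster(alns[rows, , drop = FALSE])
      }
    }
  }
  ord <- order(
    vapply(clusters, `[[`, "", "chrom"),
    vapply(clusters, function(cl) min(cl$members$start), integer(1))
  )
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$cluster_id <- sprintf("cluster_%05d", i)
  }
  structure(clusters, class = "tsv_clusters")
}

build_cluster <- function(members) {
  keys <- vapply(members$blocks, function(b) chain_key(intron_chain(b)), "")
  isoforms <- lapply(unique(keys), function(k) {
    sel <- which(keys == k)
    ex <- merge_blocks(do.call(rbind, members$blocks[sel]))
    list(
      chain = intron_chain(members$blocks[[sel[1L]]]),
      est_ids = unique(members$est_id[sel]),
      span = c(min(members$start[sel]), max(members$end[sel])),
      exons = ex
    )
  })
  list(
    cluster_id = NA_character_,
    chrom = members$chrom[1L],
    strand = members$strand[1L],
    members = members,
    isoforms = isoforms
  )
}

#' @export
print.tsv_clusters <- function(x, ...) {
  cat("tsv_clusters:", length(x), "transcript cluster(s)\n")
  n_iso <- vapply(x, function(cl) length(cl$isoforms), integer(1))
  cat("  isoforms per cluster:", paste(range(n_iso), collapse = "-"), "\n")
  invisible(x)
}
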
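# Builders for alignments, isoforms and clusters used across the suite.

blk <- function(...) {
  m <- do.call(rbind, list(...))
  colnames(m) <- c("start", "end")
  storage.mode(m) <- "integer"
  m
}

make_aln <- function(est_id, blocks, chrom = "chr1", strand = "+",
                     coverage = 1, identity = 1, source_tag = "test") {
  allelesplice:::new_alignments(est_id, chrom, strand, list(blocks),
                                coverage, identity, source_tag)
}

make_alns <- function(...) do.call(rbind, list(...))

# A "tiling" isoform: exon blocks are the complement of the introns within
# the span, as for an EST with complete coverage.
make_iso <- function(introns, span, est_ids = "e") {
  if (is.null(introns)) introns <- allelesplice:::empty_blocks()
  bounds <- c(span[1L], t(introns), span[2L])
  exons <- matrix(bounds, ncol = 2L, byrow = TRUE)
  colnames(exons) <- c("start", "end")
  storage.mode(exons) <- "integer"
  list(chain = introns, est_ids = est_ids,
       span = as.integer(span), exons = exons)
}

make_cluster <- function(isoforms, strand = "+", chrom = "chr1", id = "c1") {
  list(cluster_id = id, chrom = chrom, strand = strand,
       members = NULL, isoforms = isoforms)
}

# Random tiling cluster for the oracle-equivalence and invariant suites.
random_cluster <- function(max_isoforms = 4L, max_introns = 6L) {
  span_lo <- sample(0:50, 1L)
  span_hi <- span_lo + sample(400:900, 1L)
  n_iso <- sample(2:max_isoforms, 1L)
  isos <- vector("list", n_iso)
  for (i in seq_len(n_iso)) {
    s <- span_lo + sample(0:60, 1L)
    e <- span_hi - sample(0:60, 1L)
    k <- sample(0:max_introns, 1L)
    ints <- list()
    pos <- s
    for (j in seq_len(k)) {
      gap <- sample(2:60, 1L)
      ilen <- sample(4:80, 1L)
      st <- pos + gap
      en <- st + ilen
      if (en >= e - 1L) break
      ints[[length(ints) + 1L]] <- c(st, en)
      pos <- en
    }
    chain <- if (length(ints)) blk_from_list(ints) else NULL
    isos[[i]] <- make_iso(chain, c(s, e), est_ids = paste0("iso", i))
  }
  make_cluster(isos, strand = sample(c("+", "-"), 1L))
}

blk_from_list <- function(lst) {
  m <- do.call(rbind, lst)
  colnames(m) <- c("start", "end")
  storage.mode(m) <- "integer"
  m
}

tmpf <- function(ext = ".txt") tempfile(fileext = ext)
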
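# Coding-impact annotation: locate each event's variable region relative to
# gene models (CDS / 5'UTR / 3'UTR) and report reading-frame consequences.

#' Read gene models from GFF3
#'
#' Expects gene/mRNA/exon/CDS features, optionally with explicit
#' `five_prime_UTR` / `three_prime_UTR` features. When UTR features are
#' absent they are reconstructed as exon minus CDS, split by transcription
#' direction (5'UTR upstream of the CDS, 3'UTR downstream). Coordinates are
#' internalized to 0-based half-open.
#'
#' @param path GFF3 file.
#' @return list of gene models, each a list with `gene_id`, `chrom`,
#'   `strand`, and interval matrices `cds`, `utr5`, `utr3`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  get_parent <- function(i) {
    p <- md$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }
  feat <- data.frame(
    type = typ,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    id = if ("ID" %in% colnames(md)) as.character(md$ID) else NA_character_,
    parent = vapply(seq_along(gr), get_parent, character(1)),
    stringsAsFactors = FALSE
  )
  tx_ids <- feat$id[feat$type %in% c("mRNA", "transcript") & !is.na(feat$id)]
  cds_orphans <- feat$type == "CDS" & !(feat$parent %in% tx_ids)
  if (any(cds_orphans)) {
    stop("CDS feature without parent transcript: ",
         paste(stats::na.omit(feat$id[cds_orphans])[1L], collapse = ", "))
  }
  mat <- function(rows) {
    if (length(rows) == 0L) return(empty_blocks())
    merge_blocks(cbind(start = feat$start[rows], end = feat$end[rows]))
  }
  models <- list()
  for (tx in tx_ids) {
    rows_tx <- which(!is.na(feat$parent) & feat$parent == tx)
    cds <- mat(rows_tx[feat$type[rows_tx] == "CDS"])
    utr5 <- mat(rows_tx[feat$type[rows_tx] == "five_prime_UTR"])
    utr3 <- mat(rows_tx[feat$type[rows_tx] == "three_prime_UTR"])
    exons <- mat(rows_tx[feat$type[rows_tx] == "exon"])
    self <- which(!is.na(feat$id) & feat$id == tx)
    strand <- feat$strand[self[1L]]
    if (nrow(utr5) + nrow(utr3) == 0L && nrow(exons) > 0L && nrow(cds) > 0L) {
      utr <- setdiff_blocks(exons, cds)
      cds_lo <- min(cds[, 1L])
      cds_hi <- max(cds[, 2L])
      left <- utr[utr[, 2L] <= cds_lo, , drop = FALSE]
      right <- utr[utr[, 1L] >= cds_hi, , drop = FALSE]
      if (strand == "-") {
        utr5 <- right
        utr3 <- left
      } else {
        utr5 <- left
        utr3 <- right
      }
    }
    models[[length(models) + 1L]] <- list(
      gene_id = tx,
      chrom = feat$chrom[self[1L]],
      strand = strand,
      cds = cds, utr5 = utr5, utr3 = utr3
    )
  }
  models
}

# blocks1 minus blocks2 (both merged interval matrices)
setdiff_blocks <- function(blocks1, blocks2) {
  if (nrow(blocks1) == 0L) return(empty_blocks())
  if (nrow(blocks2) == 0L) return(merge_blocks(blocks1))
  a <- IRanges::IRanges(blocks1[, 1L] + 1L, blocks1[, 2L])
  b <- IRanges::IRanges(blocks2[, 1L] + 1L, blocks2[, 2L])
  d <- IRanges::setdiff(a, b)
  if (length(d) == 0L) return(empty_blocks())
  mat <- cbind(start = BiocGenerics::start(d) - 1L, end = BiocGenerics::end(d))
  storage.mode(mat) <- "integer"
  mat
}

#' Annotate one event against gene models
#'
#' Category overlap is computed against a partition of the transcript's
#' genomic span at the CDS boundaries: the CDS span (first to last CDS
#' base) and the two flanking spans, labelled UTR5/UTR3 by strand. A
#' variable region lying in an intron between coding exons, as an intron
#' retention does, thus still counts as a CDS variation, and introns at a
#' UTR/CDS boundary go to the UTR side they start in. The gene model
#' with the largest total overlap with the variable region (on the matching
#' strand; unknown-strand events match either) wins; within it, the region
#' is the category with maximal bp overlap, ties broken
#' CDS > UTR5 > UTR3. Events overlapping no model are `intergenic`. For CDS
#' events, `distance_to_cds_end` is the number of CDS bases, in transcript
#' coordinates, between the variable region's 3'-most base and the stop
#' codon.
#'
#' @param event one-row event data.frame.
#' @param models list from [read_gene_models()].
#' @return data.frame: `event_id`, `region`, `in_frame`, `distance_to_cds_end`.
#' @export
annotate_event <- function(event, models) {
  s <- event$region_start
  e <- event$region_end
  best <- NULL
  best_total <- 0L
  for (m in models) {
    if (m$chrom != event$chrom) next
    if (!(event$strand == "*" || m$strand == event$strand)) next
    all_iv <- rbind(m$cds, m$utr5, m$utr3)
    if (nrow(all_iv) == 0L) next
    span <- c(min(all_iv[, 1L]), max(all_iv[, 2L]))
    ovl <- function(a, b) max(0L, min(e, b) - max(s, a))
    if (nrow(m$cds) > 0L) {
      cds_lo <- min(m$cds[, 1L])
      cds_hi <- max(m$cds[, 2L])
      left <- ovl(span[1L], cds_lo)
      right <- ovl(cds_hi, span[2L])
      ov <- c(
        CDS = ovl(cds_lo, cds_hi),
        UTR5 = if (m$strand == "-") right else left,
        UTR3 = if (m$strand == "-") left else right
      )
    } else {
      ov <- c(CDS = 0L,
              UTR5 = exonic_bp(m$utr5, s, e),
              UTR3 = exonic_bp(m$utr3, s, e))
    }
    total <- sum(ov)
    if (total > best_total ||
        (total == best_total && total > 0L && !is.null(best) &&
         m$gene_id < best$model$gene_id)) {
      best <- list(model = m, ov = ov)
      best_total <- total
    }
  }
  region <- "intergenic"
  dist <- NA_integer_
  if (!is.null(best)) {
    ov <- best$ov
    region <- c("CDS", "UTR5", "UTR3")[which.max(ov)]  # which.max ties: CDS > UTR5 > UTR3
    if (region == "CDS") {
      m <- best$model
      if (m$strand == "-") {
        dist <- exonic_bp(m$cds, min(m$cds[, 1L]), s)
      } else {
        dist <- exonic_bp(m$cds, e, max(m$cds[, 2L]))
      }
    }
  }
  data.frame(
    event_id = event$event_id,
    region = region,
    in_frame = event$in_frame,
    distance_to_cds_end = as.integer(dist),
    stringsAsFactors = FALSE
  )
}

#' Annotate all events
#'
#' @param events event data.frame.
#' @param models list from [read_gene_models()].
#' @return annotation data.frame, one row per event.
#' @export
annotate_events <- function(events, models) {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    annotate_event(events[i, , drop = FALSE], models)
  })
  if (length(rows) == 0L) {
    return(data.frame(event_id = character(0), region = character(0),
                      in_frame = logical(0), distance_to_cds_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Cross-tabulate variation location and reading frame
#'
#' @param annotations data.frame from [annotate_events()].
#' @return data.frame with, per region present, in-frame / out-of-frame
#'   counts and fractions (fractions per region sum to 1), plus an
#'   `overall` row; empty for empty input.
#' @export
location_frame_summary <- function(annotations) {
  if (nrow(annotations) == 0L) {
    return(data.frame(region = character(0), n = integer(0),
                      n_in_frame = integer(0), n_out_of_frame = integer(0),
                      fraction_in_frame = numeric(0), fraction_of_events = numeric(0),
                      stringsAsFactors = FALSE))
  }
  regions <- intersect(c("CDS", "UTR5", "UTR3", "intergenic"),
                       unique(annotations$region))
  row <- function(sel, label) {
    n <- sum(sel)
    nif <- sum(annotations$in_frame[sel])
    data.frame(
      region = label, n = n, n_in_frame = nif, n_out_of_frame = n - nif,
      fraction_in_frame = if (n > 0L) nif / n else NA_real_,
      fraction_of_events = n / nrow(annotations),
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(regions, function(r) row(annotations$region == r, r))
  rows[[length(rows) + 1L]] <- row(rep(TRUE, nrow(annotations)), "overall")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
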
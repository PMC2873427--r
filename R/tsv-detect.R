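# TSV event detection: compare isoform intron chains within a transcript
# cluster, localize structural differences, and classify each difference into
# one of six categories:
#   IntronR - intron retention
#   AltA    - alternative acceptor site
#   AltD    - alternative donor site
#   AltS    - alternative donor and acceptor (both ends of the intron move)
#   ExonS   - exon skipping
#   Others  - everything else (terminal differences, multi-junction
#             rearrangements, alternative transcript initialization, ...)

TSV_TYPES <- c("IntronR", "AltA", "AltD", "AltS", "ExonS", "Others")

empty_events <- function() {
  df <- data.frame(
    event_id = character(0), cluster_id = character(0),
    chrom = character(0), strand = character(0), type = character(0),
    region_start = integer(0), region_end = integer(0),
    flanks = character(0), length_difference = integer(0),
    in_frame = logical(0), stringsAsFactors = FALSE
  )
  df$ests_a <- list()
  df$ests_b <- list()
  df
}

#' Detect and classify TSV events within one transcript cluster
#'
#' Every pair of distinct isoforms is compared over their shared genomic
#' span. Localized structural differences (connected groups of overlapping,
#' non-shared introns) each become one event, classified in the fixed
#' decision order IntronR, ExonS, AltA/AltD, AltS, Others. Differences that
#' reach either isoform's terminal aligned base are classified Others,
#' because truncated ESTs cannot distinguish real variation from incomplete
#' coverage. Identical events found in several isoform pairs are merged and
#' their EST support unioned.
#'
#' The EST sets attached to an event are oriented so that `ests_a` supports
#' the isoform with fewer exonic bases in the variable region (the "spliced"
#' side) and `ests_b` the more inclusive side.
#'
#' @param cluster one transcript cluster from [cluster_alignments()].
#' @return event data.frame (possibly empty): `event_id`, `cluster_id`,
#'   `chrom`, `strand`, `type`, `region_start`, `region_end`, `flanks`,
#'   `length_difference`, `in_frame`, list-columns `ests_a`, `ests_b`.
#' @export
detect_events <- function(cluster) {
  isos <- cluster$isoforms
  if (length(isos) < 2L) return(empty_events())
  found <- list()
  for (i in seq_along(isos)[-length(isos)]) {
    for (j in seq(i + 1L, length(isos))) {
      evs <- classify_isoform_pair(isos[[i]], isos[[j]], cluster$strand)
      for (ev in evs) {
        ev$cluster_id <- cluster$cluster_id
        ev$chrom <- cluster$chrom
        ev$strand <- cluster$strand
        key <- paste(ev$type, ev$chrom, ev$strand, ev$region_start,
                     ev$region_end, ev$flanks, sep = "|")
        if (is.null(found[[key]])) {
          found[[key]] <- ev
        } else {
          found[[key]]$ests_a <- union(found[[key]]$ests_a, ev$ests_a)
          found[[key]]$ests_b <- union(found[[key]]$ests_b, ev$ests_b)
        }
      }
    }
  }
  if (length(found) == 0L) return(empty_events())
  events_from_list(unname(found))
}

events_from_list <- function(evs) {
  df <- data.frame(
    event_id = NA_character_,
    cluster_id = vapply(evs, `[[`, "", "cluster_id"),
    chrom = vapply(evs, `[[`, "", "chrom"),
    strand = vapply(evs, `[[`, "", "strand"),
    type = vapply(evs, `[[`, "", "type"),
    region_start = vapply(evs, `[[`, 0L, "region_start"),
    region_end = vapply(evs, `[[`, 0L, "region_end"),
    flanks = vapply(evs, `[[`, "", "flanks"),
    length_difference = vapply(evs, `[[`, 0L, "length_difference"),
    stringsAsFactors = FALSE
  )
  df$in_frame <- df$length_difference %% 3L == 0L
  df$ests_a <- lapply(evs, `[[`, "ests_a")
  df$ests_b <- lapply(evs, `[[`, "ests_b")
  ord <- order(df$chrom, df$region_start, df$region_end, df$type)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Detect events across all clusters
#'
#' @param clusters result of [cluster_alignments()].
#' @return combined event data.frame with unique `event_id`s.
#' @export
detect_all_events <- function(clusters) {
  evs <- lapply(clusters, detect_events)
  evs <- evs[vapply(evs, nrow, integer(1)) > 0L]
  if (length(evs) == 0L) return(empty_events())
  df <- do.call(rbind, evs)
  df$event_id <- sprintf("tsv_%05d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df
}

# Compare one isoform pair; returns a list of raw event records.
classify_isoform_pair <- function(A, B, strand) {
  o_start <- max(A$span[1L], B$span[1L])
  o_end <- min(A$span[2L], B$span[2L])
  if (o_start >= o_end) return(list())
  iA <- chain_in_window(A$chain, o_start, o_end)
  iB <- chain_in_window(B$chain, o_start, o_end)
  kA <- if (nrow(iA)) paste(iA[, 1L], iA[, 2L], sep = "-") else character(0)
  kB <- if (nrow(iB)) paste(iB[, 1L], iB[, 2L], sep = "-") else character(0)
  dA <- iA[!(kA %in% kB), , drop = FALSE]
  dB <- iB[!(kB %in% kA), , drop = FALSE]
  nA <- nrow(dA)
  nB <- nrow(dB)
  if (nA + nB == 0L) return(list())
  all_int <- rbind(dA, dB)
  owner <- rep(c("A", "B"), c(nA, nB))
  parent <- uf_new(nA + nB)
  if (nA > 0L && nB > 0L) {
    for (p in seq_len(nA)) {
      for (q in seq_len(nB)) {
        # one localized difference: introns that overlap or abut (a shared
        # junction coordinate links the two changes)
        if (dA[p, 1L] <= dB[q, 2L] && dB[q, 1L] <= dA[p, 2L]) {
          parent <- uf_union(parent, p, nA + q)
        }
      }
    }
  }
  comp <- uf_components(parent)
  out <- list()
  for (cc in unique(comp)) {
    sel <- comp == cc
    out[[length(out) + 1L]] <- classify_component(
      all_int[sel, , drop = FALSE], owner[sel], A, B, strand, o_start, o_end
    )
  }
  out
}

# Introns of a chain that intersect [s, e)
chain_in_window <- function(chain, s, e) {
  if (nrow(chain) == 0L) return(empty_blocks())
  keep <- chain[, 2L] > s & chain[, 1L] < e
  chain[keep, , drop = FALSE]
}

# Classify one connected group of non-shared introns.
classify_component <- function(ints, owner, A, B, strand, o_start, o_end) {
  intsA <- ints[owner == "A", , drop = FALSE]
  intsB <- ints[owner == "B", , drop = FALSE]
  nA <- nrow(intsA)
  nB <- nrow(intsB)
  hull <- c(min(ints[, 1L]), max(ints[, 2L]))
  flanks <- paste(sort(unique(c(ints[, 1L], ints[, 2L]))), collapse = ",")
  terminal <- hull[1L] <= o_start || hull[2L] >= o_end

  type <- "Others"
  region <- hull
  spliced <- NULL   # isoform carrying the larger/only intron (fewer exonic bases)
  if (!terminal) {
    if ((nA == 1L && nB == 0L) || (nA == 0L && nB == 1L)) {
      # candidate intron retention: the other isoform must be contiguously
      # exonic across the intron plus one anchored base on each side
      iv <- ints[1L, ]
      other <- if (nA == 1L) B else A
      if (covered_contiguously(other$exons, iv[1L] - 1L, iv[2L] + 1L)) {
        type <- "IntronR"
        region <- iv
        spliced <- if (nA == 1L) "A" else "B"
      }
    } else if (nA == 1L && nB == 1L) {
      a <- intsA[1L, ]
      b <- intsB[1L, ]
      same_left <- a[1L] == b[1L]
      same_right <- a[2L] == b[2L]
      if (same_left && !same_right) {
        # genomic-right ends differ: acceptor on "+", donor on "-"
        type <- if (strand == "-") "AltD" else "AltA"
        region <- c(min(a[2L], b[2L]), max(a[2L], b[2L]))
      } else if (same_right && !same_left) {
        type <- if (strand == "-") "AltA" else "AltD"
        region <- c(min(a[1L], b[1L]), max(a[1L], b[1L]))
      } else if (!same_left && !same_right &&
                 intervals_overlap(a[1L], a[2L], b[1L], b[2L])) {
        # both splice sites move and the introns genuinely overlap
        type <- "AltS"
        region <- hull
      }
      if (type != "Others") {
        spliced <- if ((a[2L] - a[1L]) >= (b[2L] - b[1L])) "A" else "B"
      }
    } else if ((nA == 1L && nB == 2L) || (nA == 2L && nB == 1L)) {
      single <- if (nA == 1L) intsA[1L, ] else intsB[1L, ]
      pair <- if (nA == 1L) intsB else intsA
      pair <- pair[order(pair[, 1L]), , drop = FALSE]
      pair_owner <- if (nA == 1L) B else A
      if (pair[1L, 1L] == single[1L] && pair[2L, 2L] == single[2L] &&
          pair[1L, 2L] < pair[2L, 1L] &&
          covered_contiguously(pair_owner$exons, pair[1L, 2L], pair[2L, 1L])) {
        type <- "ExonS"
        region <- c(pair[1L, 2L], pair[2L, 1L])
        spliced <- if (nA == 1L) "A" else "B"
      }
    }
  }

  exA <- exonic_bp(A$exons, region[1L], region[2L])
  exB <- exonic_bp(B$exons, region[1L], region[2L])
  if (is.null(spliced)) {
    spliced <- if (exA < exB) "A"
    else if (exB < exA) "B"
    else if (chain_key(A$chain) <= chain_key(B$chain)) "A" else "B"
  }
  side_a <- if (spliced == "A") A else B
  side_b <- if (spliced == "A") B else A
  list(
    type = type,
    region_start = as.integer(region[1L]),
    region_end = as.integer(region[2L]),
    flanks = flanks,
    length_difference = as.integer(abs(exA - exB)),
    ests_a = side_a$est_ids,
    ests_b = side_b$est_ids
  )
}

#' Intersect two event sets
#'
#' Returns the events from `set_a` that have a counterpart in `set_b` with
#' the same type, chromosome and strand, and a variable region whose
#' boundaries agree within `slack` bp. Intersecting independent detections
#' (e.g. from two aligners) removes alignment-artifact false positives.
#'
#' @param set_a,set_b event data.frames from [detect_all_events()].
#' @param slack maximum per-boundary coordinate difference in bp.
#' @return subset of `set_a`.
#' @export
intersect_event_sets <- function(set_a, set_b, slack = 0L) {
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) return(empty_events())
  keep <- logical(nrow(set_a))
  for (i in seq_len(nrow(set_a))) {
    cand <- set_b$type == set_a$type[i] &
      set_b$chrom == set_a$chrom[i] &
      set_b$strand == set_a$strand[i] &
      abs(set_b$region_start - set_a$region_start[i]) <= slack &
      abs(set_b$region_end - set_a$region_end[i]) <= slack
    keep[i] <- any(cand)
  }
  out <- set_a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate event-type frequencies
#'
#' @param events event data.frame.
#' @return data.frame with one row per TSV type (all six listed), counts and
#'   fractions of the total; empty for empty input.
#' @export
event_type_frequencies <- function(events) {
  if (nrow(events) == 0L) {
    return(data.frame(type = character(0), n = integer(0), fraction = numeric(0)))
  }
  n <- vapply(TSV_TYPES, function(t) sum(events$type == t), integer(1))
  data.frame(
    type = TSV_TYPES,
    n = as.integer(n),
    fraction = as.numeric(n) / sum(n),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Write events as GFF3
#'
#' One `TSV_event` feature per event with `type`, `ests_a`, `ests_b`,
#' `length_difference` and `in_frame` attributes (1-based coordinates).
#'
#' @param events event data.frame.
#' @param path output path.
#' @export
write_events_gff3 <- function(events, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(events))) {
    attrs <- sprintf(
      "ID=%s;tsv_type=%s;ests_a=%s;ests_b=%s;length_difference=%d;in_frame=%s",
      events$event_id[i], events$type[i],
      paste(events$ests_a[[i]], collapse = ","),
      paste(events$ests_b[[i]], collapse = ","),
      events$length_difference[i],
      if (events$in_frame[i]) "true" else "false"
    )
    lines <- c(lines, paste(
      events$chrom[i], "allelesplice", "TSV_event",
      events$region_start[i] + 1L, events$region_end[i],
      ".", events$strand[i], ".", attrs,
      sep = "\t"
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
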
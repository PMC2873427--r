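# Independent brute-force references.
#
# oracle_events(): base-level event finder. Instead of interval arithmetic it
# paints each isoform's per-base exon/intron state over the pairwise overlap
# span, takes maximal runs of differing state, merges runs separated only by
# shared-intronic bases whose covering introns differ, and classifies each
# merged group by direct enumeration of the introns involved.

in_blocks_mask <- function(blocks, pos) {
  out <- logical(length(pos))
  for (i in seq_len(nrow(blocks))) {
    out <- out | (pos >= blocks[i, 1L] & pos < blocks[i, 2L])
  }
  out
}

covering_intron <- function(chain, p) {
  for (i in seq_len(nrow(chain))) {
    if (p >= chain[i, 1L] && p < chain[i, 2L]) return(chain[i, ])
  }
  NULL
}

oracle_pair_events <- function(A, B, strand) {
  os <- max(A$span[1L], B$span[1L])
  oe <- min(A$span[2L], B$span[2L])
  if (os >= oe) return(list())
  pos <- os:(oe - 1L)
  exA <- in_blocks_mask(A$exons, pos)
  exB <- in_blocks_mask(B$exons, pos)
  d <- exA != exB
  if (!any(d)) return(list())
  r <- rle(d)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  diff_runs <- which(r$values)

  # group diff runs: merge when separated only by both-intron bases whose
  # covering introns are not the same interval in the two isoforms
  groups <- list(list(diff_runs[1L]))
  if (length(diff_runs) > 1L) {
    for (t in seq_along(diff_runs)[-1L]) {
      prev <- diff_runs[t - 1L]
      cur <- diff_runs[t]
      gap_idx <- (run_end[prev] + 1L):(run_start[cur] - 1L)
      gap_pos <- pos[gap_idx]
      both_intron <- all(!exA[gap_idx] & !exB[gap_idx])
      merge <- FALSE
      if (both_intron) {
        ia <- covering_intron(A$chain, gap_pos[1L])
        ib <- covering_intron(B$chain, gap_pos[1L])
        merge <- !is.null(ia) && !is.null(ib) && !identical(ia, ib)
      }
      if (merge) {
        groups[[length(groups)]] <- c(groups[[length(groups)]], cur)
      } else {
        groups[[length(groups) + 1L]] <- list(cur)
      }
    }
  }
  groups <- lapply(groups, unlist)

  row_keys <- function(chain) {
    if (nrow(chain) == 0L) return(character(0))
    paste(chain[, 1L], chain[, 2L], sep = "-")
  }
  shared_keys <- intersect(row_keys(A$chain), row_keys(B$chain))
  nonshared <- function(chain) {
    if (nrow(chain) == 0L) return(chain)
    chain[!(row_keys(chain) %in% shared_keys), , drop = FALSE]
  }
  nsA <- nonshared(A$chain)
  nsB <- nonshared(B$chain)

  out <- list()
  for (grp in groups) {
    lo <- pos[run_start[grp[1L]]]
    hi <- pos[run_end[grp[length(grp)]]] + 1L
    pick <- function(ns) {
      if (nrow(ns) == 0L) return(ns)
      ns[ns[, 2L] > lo - 1L & ns[, 1L] < hi + 1L, , drop = FALSE]
    }
    intsA <- pick(nsA)
    intsB <- pick(nsB)
    out[[length(out) + 1L]] <-
      oracle_classify_group(intsA, intsB, A, B, strand, os, oe, pos, exA, exB)
  }
  out
}

oracle_classify_group <- function(intsA, intsB, A, B, strand, os, oe,
                                  pos, exA, exB) {
  all_int <- rbind(intsA, intsB)
  hull <- c(min(all_int[, 1L]), max(all_int[, 2L]))
  nA <- nrow(intsA)
  nB <- nrow(intsB)
  res <- list(type = "Others", region = hull)
  if (hull[1L] <= os || hull[2L] >= oe) return(res)

  exonic_at <- function(mask, p) {
    idx <- match(p, pos)
    !is.na(idx) && mask[idx]
  }
  if (nA + nB == 1L) {
    iv <- all_int[1L, ]
    other_mask <- if (nA == 1L) exB else exA
    span_ok <- all(vapply((iv[1L] - 1L):iv[2L], function(p)
      exonic_at(other_mask, p), logical(1)))
    if (span_ok) res <- list(type = "IntronR", region = iv)
  } else if (nA == 1L && nB == 1L) {
    a <- intsA[1L, ]
    b <- intsB[1L, ]
    if (a[1L] == b[1L] && a[2L] != b[2L]) {
      type <- if (strand == "-") "AltD" else "AltA"
      res <- list(type = type, region = c(min(a[2L], b[2L]), max(a[2L], b[2L])))
    } else if (a[2L] == b[2L] && a[1L] != b[1L]) {
      type <- if (strand == "-") "AltA" else "AltD"
      res <- list(type = type, region = c(min(a[1L], b[1L]), max(a[1L], b[1L])))
    } else if (a[1L] != b[1L] && a[2L] != b[2L] &&
               a[1L] < b[2L] && b[1L] < a[2L]) {
      res <- list(type = "AltS", region = hull)
    }
  } else if ((nA == 1L && nB == 2L) || (nA == 2L && nB == 1L)) {
    single <- if (nA == 1L) intsA[1L, ] else intsB[1L, ]
    pair <- if (nA == 1L) intsB else intsA
    pair <- pair[order(pair[, 1L]), , drop = FALSE]
    inc_mask <- if (nA == 1L) exB else exA
    gap_ok <- pair[1L, 2L] < pair[2L, 1L] &&
      all(vapply(pair[1L, 2L]:(pair[2L, 1L] - 1L), function(p)
        exonic_at(inc_mask, p), logical(1)))
    if (pair[1L, 1L] == single[1L] && pair[2L, 2L] == single[2L] && gap_ok) {
      res <- list(type = "ExonS", region = c(pair[1L, 2L], pair[2L, 1L]))
    }
  }
  res
}

# all (type, region) triples for a cluster, as a sorted key vector
oracle_event_keys <- function(cluster) {
  isos <- cluster$isoforms
  keys <- character(0)
  if (length(isos) >= 2L) {
    for (i in seq_along(isos)[-length(isos)]) {
      for (j in seq(i + 1L, length(isos))) {
        evs <- oracle_pair_events(isos[[i]], isos[[j]], cluster$strand)
        keys <- c(keys, vapply(evs, function(ev)
          paste(ev$type, ev$region[1L], ev$region[2L]), ""))
      }
    }
  }
  sort(unique(keys))
}

detect_event_keys <- function(cluster) {
  ev <- detect_events(cluster)
  sort(unique(paste(ev$type, ev$region_start, ev$region_end)))
}

# brute-force connected components of the exonic-overlap graph
brute_overlap_components <- function(alns) {
  n <- nrow(alns)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (alns$chrom[i] != alns$chrom[j] || alns$strand[i] != alns$strand[j]) next
      bi <- alns$blocks[[i]]
      bj <- alns$blocks[[j]]
      hit <- FALSE
      for (p in seq_len(nrow(bi))) {
        for (q in seq_len(nrow(bj))) {
          if (bi[p, 1L] < bj[q, 2L] && bj[q, 1L] < bi[p, 2L]) hit <- TRUE
        }
      }
      adj[i, j] <- hit
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        nb <- which(adj[f, ] & is.na(comp))
        comp[nb] <- cur
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  comp
}

# brute-force source verdict by explicit enumeration of cross-group pairs
brute_source_verdict <- function(group1, group2) {
  informative <- 0L
  matched <- FALSE
  for (p in group1) {
    for (q in group2) {
      shared <- intersect(p$positions, q$positions)
      if (length(shared) == 0L) next
      informative <- informative + 1L
      agree <- TRUE
      for (s in shared) {
        if (p$bases[which(p$positions == s)] != q$bases[which(q$positions == s)]) {
          agree <- FALSE
        }
      }
      if (agree) matched <- TRUE
    }
  }
  if (informative == 0L) "undetermined"
  else if (matched) "alternative_splicing"
  else "allelic"
}
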
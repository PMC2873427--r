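# Allelic-variation vs alternative-splicing source classification.
#
# Alternative-splicing isoforms derive from the same pre-mRNA, hence the same
# allele, hence the same linked SNP pattern; isoforms from different alleles
# carry different patterns. For each TSV event the two isoform-supporting
# EST groups are compared pairwise at shared mSNP positions: if any
# cross-group pair agrees at every position both ESTs cover, the event is
# alternative splicing; if informative pairs exist and none agrees, it is
# allelic; with no informative pair it is undetermined.

#' Build per-group EST SNP patterns for one event
#'
#' For each EST supporting either isoform of the event, records its base at
#' every mSNP position covered by its aligned blocks: the alternative base
#' when the EST is among that mSNP's supporters, otherwise the reference
#' base (a reference-allele EST thus has a usable all-reference pattern).
#' Positions inside the end/gap masking margins of an EST — where
#' [call_mismatches()] could not have reported a mismatch — are treated as
#' uncovered for that EST, not as reference matches. ESTs covering no mSNP
#' position are removed from their group.
#'
#' @param event one-row event data.frame.
#' @param alns alignment data.frame resolving every supporting EST.
#' @param msnps aggregated mSNP data.frame from [aggregate_and_filter()].
#' @param end_mask,gap_mask the masking distances used during SNP calling.
#' @return list with `group1` and `group2`, each a list of patterns
#'   (`est_id`, integer `positions`, character `bases`).
#' @export
build_groups <- function(event, alns, msnps, end_mask = 3L, gap_mask = 5L) {
  site <- msnps[msnps$chrom == event$chrom, , drop = FALSE]
  pattern_for <- function(est) {
    i <- which(alns$est_id == est)
    if (length(i) == 0L) stop("unknown est_id: ", est)
    b <- callable_blocks(alns$blocks[[i[1L]]], end_mask, gap_mask)
    covered <- logical(nrow(site))
    for (j in seq_len(nrow(b))) {
      covered <- covered | (site$pos >= b[j, 1L] & site$pos < b[j, 2L])
    }
    pos <- sort(unique(site$pos[covered]))
    if (length(pos) == 0L) return(NULL)
    bases <- vapply(pos, function(p) {
      recs <- which(site$pos == p)
      for (r in recs) {
        if (est %in% site$est_ids[[r]]) return(site$alt[r])
      }
      site$ref[recs[1L]]
    }, character(1))
    list(est_id = est, positions = pos, bases = bases)
  }
  build <- function(ests) {
    pats <- lapply(ests, pattern_for)
    pats[!vapply(pats, is.null, logical(1))]
  }
  list(group1 = build(event$ests_a[[1L]]), group2 = build(event$ests_b[[1L]]))
}

#' Classify the source of one TSV event from SNP patterns
#'
#' Compares every EST of `group1` with every EST of `group2` at the mSNP
#' positions both cover. A pair is informative if it shares at least one
#' position, and matches if the bases agree at every shared position.
#' Verdict: `alternative_splicing` if any informative pair matches,
#' `allelic` if informative pairs exist and none matches, `undetermined`
#' if no pair is informative.
#'
#' @param group1,group2 pattern lists from [build_groups()].
#' @return list (class `source_call`): `verdict`, `n_informative_pairs`,
#'   and an `evidence` data.frame of the pairwise comparisons.
#' @export
classify_source <- function(group1, group2) {
  ev <- list()
  n_inf <- 0L
  any_match <- FALSE
  for (p in group1) {
    for (q in group2) {
      shared <- intersect(p$positions, q$positions)
      if (length(shared) == 0L) next
      n_inf <- n_inf + 1L
      match_ok <- all(p$bases[match(shared, p$positions)] ==
                        q$bases[match(shared, q$positions)])
      any_match <- any_match || match_ok
      ev[[length(ev) + 1L]] <- data.frame(
        est_a = p$est_id, est_b = q$est_id,
        n_shared = length(shared), match = match_ok,
        stringsAsFactors = FALSE
      )
    }
  }
  verdict <- if (n_inf == 0L) "undetermined"
  else if (any_match) "alternative_splicing"
  else "allelic"
  structure(
    list(
      verdict = verdict,
      n_informative_pairs = n_inf,
      evidence = if (length(ev)) do.call(rbind, ev) else
        data.frame(est_a = character(0), est_b = character(0),
                   n_shared = integer(0), match = logical(0),
                   stringsAsFactors = FALSE)
    ),
    class = "source_call"
  )
}

#' Classify the source of every event
#'
#' @param events event data.frame.
#' @param alns alignment data.frame.
#' @param msnps aggregated mSNP data.frame.
#' @param end_mask,gap_mask the masking distances used during SNP calling.
#' @return data.frame: `event_id`, `type`, `verdict`, `n_informative_pairs`.
#' @export
classify_all_sources <- function(events, alns, msnps, end_mask = 3L,
                                 gap_mask = 5L) {
  out <- data.frame(
    event_id = events$event_id,
    type = events$type,
    verdict = NA_character_,
    n_informative_pairs = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(events))) {
    g <- build_groups(events[i, , drop = FALSE], alns, msnps,
                      end_mask = end_mask, gap_mask = gap_mask)
    sc <- classify_source(g$group1, g$group2)
    out$verdict[i] <- sc$verdict
    out$n_informative_pairs[i] <- sc$n_informative_pairs
  }
  out
}

#' Fraction of allelic events per TSV type
#'
#' Per type, fraction = allelic / (allelic + alternative_splicing);
#' undetermined events are excluded from the denominator. Types with an
#' empty denominator report `NA`. A final `overall` row aggregates all
#' types.
#'
#' @param calls verdict data.frame from [classify_all_sources()].
#' @param events event data.frame (joined by `event_id`).
#' @return data.frame: `type`, `n_allelic`, `n_as`, `n_undetermined`,
#'   `fraction_allelic`.
#' @export
allelic_fraction_by_type <- function(calls, events) {
  if (!all(calls$event_id %in% events$event_id)) {
    stop("every source call must join to an event")
  }
  type <- events$type[match(calls$event_id, events$event_id)]
  tab <- function(sel, label) {
    na <- sum(calls$verdict[sel] == "allelic")
    ns <- sum(calls$verdict[sel] == "alternative_splicing")
    nu <- sum(calls$verdict[sel] == "undetermined")
    data.frame(
      type = label, n_allelic = na, n_as = ns, n_undetermined = nu,
      fraction_allelic = if (na + ns > 0L) na / (na + ns) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(TSV_TYPES, function(t) tab(type == t, t))
  rows[[length(rows) + 1L]] <- tab(rep(TRUE, length(type)), "overall")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
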
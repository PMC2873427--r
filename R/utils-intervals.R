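# Interval helpers. All genomic intervals in this package are 0-based
# half-open [start, end) unless a function says otherwise.

#' Merge a set of intervals into their union
#'
#' @param blocks integer matrix with columns `start`, `end` (0-based
#'   half-open), not necessarily sorted.
#' @return matrix of disjoint sorted intervals covering the same bases.
#' @keywords internal
merge_blocks <- function(blocks) {
  if (is.null(blocks) || nrow(blocks) == 0L) {
    return(empty_blocks())
  }
  ord <- order(blocks[, 1L], blocks[, 2L])
  blocks <- blocks[ord, , drop = FALSE]
  out_s <- blocks[1L, 1L]
  out_e <- blocks[1L, 2L]
  res <- list()
  for (i in seq_len(nrow(blocks))[-1L]) {
    s <- blocks[i, 1L]
    e <- blocks[i, 2L]
    if (s <= out_e) {
      out_e <- max(out_e, e)
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- s
      out_e <- e
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  mat <- do.call(rbind, res)
  colnames(mat) <- c("start", "end")
  storage.mode(mat) <- "integer"
  mat
}

empty_blocks <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

#' Number of bases of `blocks` falling inside [s, e)
#' @keywords internal
exonic_bp <- function(blocks, s, e) {
  if (nrow(blocks) == 0L || s >= e) return(0L)
  w <- pmin(blocks[, 2L], e) - pmax(blocks[, 1L], s)
  sum(pmax(w, 0L))
}

#' Is [s, e) fully covered by one merged block?
#' @keywords internal
covered_contiguously <- function(blocks, s, e) {
  if (s >= e) return(TRUE)
  m <- merge_blocks(blocks)
  if (nrow(m) == 0L) return(FALSE)
  any(m[, 1L] <= s & m[, 2L] >= e)
}

#' Intron intervals of an ordered block matrix
#'
#' Gaps between consecutive exon blocks, 0-based half-open.
#' @keywords internal
intron_chain <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2L) return(empty_blocks())
  mat <- cbind(start = blocks[-n, 2L], end = blocks[-1L, 1L])
  storage.mode(mat) <- "integer"
  mat
}

chain_key <- function(introns) {
  if (nrow(introns) == 0L) return("")
  paste(introns[, 1L], introns[, 2L], sep = "-", collapse = ";")
}

intervals_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

# Minimal union-find used by clustering and event-component grouping.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}
uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}
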
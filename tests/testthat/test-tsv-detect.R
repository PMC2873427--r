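test_that("the six definitional isoform differences classify correctly", {
  # intron retention: one isoform splices (100,200), the other reads through
  cl <- make_cluster(list(
    make_iso(blk(c(100, 200)), c(0, 300), "spliced"),
    make_iso(NULL, c(0, 300), "retained")
  ))
  ev <- detect_events(cl)
  expect_equal(ev$type, "IntronR")
  expect_equal(c(ev$region_start, ev$region_end), c(100L, 200L))
  expect_equal(ev$length_difference, 100L)
  expect_false(ev$in_frame)
  expect_equal(ev$ests_a[[1L]], "spliced")
  expect_equal(ev$ests_b[[1L]], "retained")

  # alternative acceptor: shared donor, acceptors 200 vs 230 (plus strand)
  cl <- make_cluster(list(
    make_iso(blk(c(100, 200)), c(0, 330)),
    make_iso(blk(c(100, 230)), c(0, 330))
  ))
  ev <- detect_events(cl)
  expect_equal(ev$type, "AltA")
  expect_equal(c(ev$region_start, ev$region_end), c(200L, 230L))
  expect_equal(ev$length_difference, 30L)
  expect_true(ev$in_frame)

  # same junctions on the minus strand: the shared genomic-left end is now
  # the acceptor, so the label swaps to AltD
  cl_minus <- make_cluster(list(
    make_iso(blk(c(100, 200)), c(0, 330)),
    make_iso(blk(c(100, 230)), c(0, 330))
  ), strand = "-")
  expect_equal(detect_events(cl_minus)$type, "AltD")

  # alternative donor on the plus strand: shared acceptor, donors differ
  cl <- make_cluster(list(
    make_iso(blk(c(100, 200)), c(0, 330)),
    make_iso(blk(c(70, 200)), c(0, 330))
  ))
  ev <- detect_events(cl)
  expect_equal(ev$type, "AltD")
  expect_equal(c(ev$region_start, ev$region_end), c(70L, 100L))

  # both ends differ with overlap: AltS
  cl <- make_cluster(list(
    make_iso(blk(c(100, 200)), c(0, 330)),
    make_iso(blk(c(80, 240)), c(0, 330))
  ))
  ev <- detect_events(cl)
  expect_equal(ev$type, "AltS")
  expect_equal(c(ev$region_start, ev$region_end), c(80L, 240L))
  expect_equal(ev$length_difference, 60L)

  # exon skipping: internal exon 200-250 present in one isoform only
  cl <- make_cluster(list(
    make_iso(blk(c(100, 200), c(250, 400)), c(0, 500), "includes"),
    make_iso(blk(c(100, 400)), c(0, 500), "skips")
  ))
  ev <- detect_events(cl)
  expect_equal(ev$type, "ExonS")
  expect_equal(c(ev$region_start, ev$region_end), c(200L, 250L))
  expect_equal(ev$length_difference, 50L)
  expect_equal(ev$ests_a[[1L]], "skips")
})

test_that("differences touching a terminal aligned base are Others", {
  # the short isoform starts inside the long isoform's intron
  cl <- make_cluster(list(
    make_iso(blk(c(100, 150)), c(0, 300)),
    make_iso(NULL, c(120, 300))
  ))
  ev <- detect_events(cl)
  expect_equal(ev$type, "Others")
})

test_that("single-isoform clusters yield no events", {
  cl <- make_cluster(list(make_iso(blk(c(100, 200)), c(0, 300))))
  expect_equal(nrow(detect_events(cl)), 0L)
})

test_that("identical events from different isoform pairs merge with unioned support", {
  cl <- make_cluster(list(
    make_iso(blk(c(100, 200)), c(0, 300), "s1"),
    make_iso(NULL, c(0, 300), "r1"),
    make_iso(blk(c(100, 200)), c(10, 290), "s2")
  ))
  ev <- detect_events(cl)
  expect_equal(nrow(ev), 1L)
  expect_setequal(ev$ests_a[[1L]], c("s1", "s2"))
  expect_equal(ev$ests_b[[1L]], "r1")
})

test_that("event classification matches the base-level brute-force oracle", {
  set.seed(99)
  n_agree <- 0L
  n_total <- 0L
  for (rep in 1:80) {
    cl <- random_cluster()
    cl$cluster_id <- "c"
    expect_identical(detect_event_keys(cl), oracle_event_keys(cl))
    n_total <- n_total + 1L
  }
})

test_that("every detected event carries one of the six labels and a consistent frame flag", {
  set.seed(7)
  for (rep in 1:40) {
    cl <- random_cluster()
    cl$cluster_id <- "c"
    ev <- detect_events(cl)
    if (nrow(ev) == 0L) next
    expect_true(all(ev$type %in% c("IntronR", "AltA", "AltD", "AltS", "ExonS", "Others")))
    expect_identical(ev$in_frame, ev$length_difference %% 3L == 0L)
    # frame flag agrees with an independent recomputation from exon unions
    for (i in seq_len(nrow(ev))) {
      iso_of <- function(ids) {
        for (iso in cl$isoforms) if (identical(iso$est_ids, ids)) return(iso)
        NULL
      }
      a <- iso_of(ev$ests_a[[i]])
      b <- iso_of(ev$ests_b[[i]])
      if (is.null(a) || is.null(b)) next
      ld <- abs(
        allelesplice:::exonic_bp(a$exons, ev$region_start[i], ev$region_end[i]) -
        allelesplice:::exonic_bp(b$exons, ev$region_start[i], ev$region_end[i])
      )
      expect_equal(ev$in_frame[i], ld %% 3L == 0L)
    }
  }
})

test_that("event-set intersection keeps shared events, honors slack, and is idempotent", {
  cl1 <- make_cluster(list(
    make_iso(blk(c(100, 200)), c(0, 300)),
    make_iso(NULL, c(0, 300))
  ))
  cl2 <- make_cluster(list(
    make_iso(blk(c(500, 600)), c(400, 700)),
    make_iso(NULL, c(400, 700))
  ), id = "c2")
  set_a <- detect_all_events(structure(list(cl1, cl2), class = "tsv_clusters"))
  set_b <- detect_all_events(structure(list(cl1), class = "tsv_clusters"))

  both <- intersect_event_sets(set_a, set_b)
  expect_equal(nrow(both), 1L)
  expect_equal(both$region_start, 100L)
  # containment and idempotence
  expect_true(all(paste(both$type, both$region_start) %in%
                    paste(set_a$type, set_a$region_start)))
  expect_equal(nrow(intersect_event_sets(both, set_b)), nrow(both))
  expect_lte(nrow(both), min(nrow(set_a), nrow(set_b)))

  # slack: regions offset by 3 bp match at slack 5, not at slack 0
  shifted <- set_b
  shifted$region_start <- shifted$region_start + 3L
  shifted$region_end <- shifted$region_end + 3L
  expect_equal(nrow(intersect_event_sets(set_b, shifted, slack = 0L)), 0L)
  expect_equal(nrow(intersect_event_sets(set_b, shifted, slack = 5L)), 1L)
})

test_that("type frequencies normalize to one and match simple arithmetic", {
  ev <- allelesplice:::empty_events()
  add <- function(ev, type, n) {
    for (i in seq_len(n)) {
      row <- data.frame(event_id = NA_character_, cluster_id = "c", chrom = "chr1",
                        strand = "+", type = type,
                        region_start = i * 10L, region_end = i * 10L + 5L,
                        flanks = "", length_difference = 5L, in_frame = FALSE,
                        stringsAsFactors = FALSE)
      row$ests_a <- list("a")
      row$ests_b <- list("b")
      ev <- rbind(ev, row)
    }
    ev
  }
  ev <- add(add(add(ev, "IntronR", 4L), "AltA", 1L), "Others", 5L)
  tab <- event_type_frequencies(ev)
  expect_equal(sum(tab$fraction), 1)
  expect_equal(tab$fraction[tab$type == "IntronR"], 0.4)
  expect_equal(tab$fraction[tab$type == "AltA"], 0.1)
  expect_equal(tab$fraction[tab$type == "Others"], 0.5)
  expect_equal(nrow(event_type_frequencies(allelesplice:::empty_events())), 0L)
})

test_that("events export to GFF3 with type and support attributes", {
  cl <- make_cluster(list(
    make_iso(blk(c(100, 200)), c(0, 300), "s1"),
    make_iso(NULL, c(0, 300), "r1")
  ))
  ev <- detect_all_events(structure(list(cl), class = "tsv_clusters"))
  path <- tmpf(".gff3")
  write_events_gff3(ev, path)
  gr <- rtracklayer::import(path, format = "gff3")
  expect_equal(as.character(S4Vectors::mcols(gr)$type), "TSV_event")
  expect_equal(BiocGenerics::start(gr), 101L)
  expect_equal(BiocGenerics::end(gr), 200L)
  expect_equal(as.character(S4Vectors::mcols(gr)$tsv_type), "IntronR")
})
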
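test_that("BED12 records round-trip through writer and reader", {
  alns <- make_alns(
    make_aln("estA", blk(c(100, 200), c(300, 400), c(500, 650)),
             coverage = 0.95, identity = 0.985),
    make_aln("estB", blk(c(1000, 1100)), strand = "-",
             coverage = 0.88, identity = 0.97)
  )
  path <- tmpf()
  write_alignments_bed12(alns, path)
  back <- read_alignments(path, "bed12", source_tag = "rt")

  expect_equal(back$est_id, c("estA", "estB"))
  expect_equal(back$blocks[[1L]], alns$blocks[[1L]])
  expect_equal(back$n_blocks, c(3L, 1L))
  expect_equal(nrow(allelesplice:::intron_chain(back$blocks[[1L]])), 2L)
  expect_equal(back$strand, c("+", "-"))
  expect_equal(back$coverage, c(0.95, 0.88), tolerance = 1e-5)
  expect_equal(back$identity, c(0.985, 0.97), tolerance = 1e-5)
})

test_that("plain 12-column BED yields NA coverage/identity and empty files are empty", {
  path <- tmpf()
  writeLines("chr1\t10\t110\test1\t0\t+\t10\t110\t0\t2\t30,30,\t0,70,", path)
  alns <- read_alignments(path, "bed12")
  expect_true(is.na(alns$coverage))
  expect_equal(alns$blocks[[1L]], blk(c(10, 40), c(80, 110)))

  writeLines(character(0), path)
  expect_equal(nrow(read_alignments(path, "bed12")), 0L)
})

test_that("malformed BED12 records report the offending line", {
  path <- tmpf()
  writeLines(c(
    "chr1\t10\t110\tok\t0\t+\t10\t110\t0\t1\t100,\t0,",
    "chr1\t10\t110\tbad\t0\t+\t10\t110\t0\t3\t100,\t0,"
  ), path)
  expect_error(read_alignments(path, "bed12"), "line 2")
})

test_that("GFF3 1-based exons become 0-based half-open blocks with attributes", {
  path <- tmpf()
  writeLines(c(
    "##gff-version 3",
    "chr1\ttool\tcDNA_match\t101\t400\t.\t+\t.\tID=aln1;Name=est9;coverage=92.5;identity=98.2",
    "chr1\ttool\tmatch_part\t101\t200\t.\t+\t.\tID=aln1.p1;Parent=aln1",
    "chr1\ttool\tmatch_part\t301\t400\t.\t+\t.\tID=aln1.p2;Parent=aln1"
  ), path)
  alns <- read_alignments(path, "gff3", source_tag = "gmap")
  expect_equal(nrow(alns), 1L)
  expect_equal(alns$est_id, "est9")
  expect_equal(alns$blocks[[1L]], blk(c(100, 200), c(300, 400)))
  expect_equal(alns$coverage, 0.925, tolerance = 1e-6)
  expect_equal(alns$identity, 0.982, tolerance = 1e-6)
  expect_equal(alns$source_tag, "gmap")
})

test_that("coverage/identity filter is strict and boundary values are rejected", {
  alns <- make_alns(
    make_aln("low_cov", blk(c(0, 100), c(200, 300)), coverage = 0.79, identity = 0.99),
    make_aln("keep", blk(c(0, 100), c(200, 300)), coverage = 0.81, identity = 0.96),
    make_aln("edge_cov", blk(c(0, 100), c(200, 300)), coverage = 0.80, identity = 0.99),
    make_aln("edge_idy", blk(c(0, 100), c(200, 300)), coverage = 0.95, identity = 0.95),
    make_aln("no_scores", blk(c(0, 100), c(200, 300)), coverage = NA, identity = NA)
  )
  kept <- filter_alignments(alns)
  expect_equal(kept$est_id, "keep")
  passed <- filter_alignments(alns, missing = "pass")
  expect_setequal(passed$est_id, c("keep", "no_scores"))
})

test_that("uniexonic alignments are removed and empty input passes through", {
  alns <- make_alns(
    make_aln("uni", blk(c(0, 500))),
    make_aln("two", blk(c(0, 100), c(200, 300)))
  )
  expect_equal(drop_uniexonic(alns)$est_id, "two")
  expect_equal(nrow(drop_uniexonic(alns[0, ])), 0L)
})

test_that("best alignment per EST maximizes identity x coverage with a stable tie-break", {
  alns <- make_alns(
    make_aln("e1", blk(c(0, 100), c(200, 300)), chrom = "chr2", identity = 0.96),
    make_aln("e1", blk(c(0, 100), c(200, 300)), chrom = "chr1", identity = 0.99),
    make_aln("solo", blk(c(0, 100), c(150, 250)))
  )
  best <- best_alignment_per_est(alns)
  expect_equal(sort(best$est_id), c("e1", "solo"))
  expect_equal(best$chrom[best$est_id == "e1"], "chr1")

  tie <- make_alns(
    make_aln("t", blk(c(0, 100), c(200, 300)), chrom = "chr9"),
    make_aln("t", blk(c(0, 100), c(200, 300)), chrom = "chr2")
  )
  expect_equal(best_alignment_per_est(tie)$chrom, "chr2")
})

test_that("quality -> uniexonic -> best-per-EST filtering is idempotent", {
  set.seed(41)
  alns <- do.call(rbind, lapply(1:30, function(i) {
    s <- sample(0:5000, 1L)
    make_aln(paste0("e", sample(1:12, 1L)),
             blk(c(s, s + 80), c(s + 150, s + 260)),
             chrom = sample(c("chr1", "chr2"), 1L),
             coverage = runif(1, 0.5, 1), identity = runif(1, 0.9, 1))
  }))
  once <- best_alignment_per_est(drop_uniexonic(filter_alignments(alns)))
  twice <- best_alignment_per_est(drop_uniexonic(filter_alignments(once)))
  expect_identical(once, twice)
})

test_that("clustering matches definitional cases", {
  two <- make_alns(
    make_aln("a", blk(c(0, 100), c(200, 300))),
    make_aln("b", blk(c(250, 320), c(400, 500)))
  )
  expect_length(cluster_alignments(two), 1L)

  opposite <- make_alns(
    make_aln("a", blk(c(0, 100), c(200, 300)), strand = "+"),
    make_aln("b", blk(c(0, 100), c(200, 300)), strand = "-")
  )
  expect_length(cluster_alignments(opposite), 2L)

  # single linkage: a-b overlap, b-c overlap, a-c do not
  chained <- make_alns(
    make_aln("a", blk(c(0, 100), c(150, 250))),
    make_aln("b", blk(c(200, 280), c(350, 450))),
    make_aln("c", blk(c(400, 480), c(600, 700)))
  )
  expect_length(cluster_alignments(chained), 1L)

  # abutting blocks (zero-bp overlap) do not link
  abut <- make_alns(
    make_aln("a", blk(c(0, 100), c(150, 200))),
    make_aln("b", blk(c(200, 300), c(350, 400)))
  )
  expect_length(cluster_alignments(abut), 2L)
})

test_that("cluster partition equals brute-force overlap components on random inputs", {
  set.seed(2024)
  for (rep in 1:15) {
    n <- sample(5:40, 1L)
    alns <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- sample(0:4000, 1L)
      w1 <- sample(30:150, 1L)
      gap <- sample(20:200, 1L)
      w2 <- sample(30:150, 1L)
      make_aln(paste0("e", i), blk(c(s, s + w1), c(s + w1 + gap, s + w1 + gap + w2)),
               chrom = sample(c("chr1", "chr2"), 1L),
               strand = sample(c("+", "-"), 1L))
    }))
    clusters <- cluster_alignments(alns)
    # every alignment in exactly one cluster
    all_members <- unlist(lapply(clusters, function(cl) cl$members$est_id))
    expect_setequal(all_members, alns$est_id)
    expect_equal(length(all_members), nrow(alns))
    # same partition as brute-force connected components
    brute <- brute_overlap_components(alns)
    mine <- integer(nrow(alns))
    for (k in seq_along(clusters)) {
      mine[match(clusters[[k]]$members$est_id, alns$est_id)] <- k
    }
    expect_equal(length(unique(brute)), length(clusters))
    expect_true(all(tapply(mine, brute, function(v) length(unique(v))) == 1L))
  }
})

test_that("members with identical intron chains collapse into one isoform", {
  alns <- make_alns(
    make_aln("a", blk(c(0, 100), c(200, 300))),
    make_aln("b", blk(c(0, 100), c(200, 300))),
    make_aln("c", blk(c(0, 100), c(230, 300)))
  )
  cl <- cluster_alignments(alns)[[1L]]
  expect_length(cl$isoforms, 2L)
  chains <- vapply(cl$isoforms, function(iso) allelesplice:::chain_key(iso$chain), "")
  expect_setequal(chains, c("100-200", "100-230"))
})

test_that("strand is inferred from GT..AG / CT..AC splice dinucleotides", {
  intron_fwd <- paste0("GT", strrep("T", 46), "AG")
  intron_rev <- paste0("CT", strrep("T", 46), "AC")
  genome <- Biostrings::DNAStringSet(c(
    chrF = paste0(strrep("A", 100), intron_fwd, strrep("A", 100)),
    chrR = paste0(strrep("A", 100), intron_rev, strrep("A", 100))
  ))
  alns <- make_alns(
    make_aln("f", blk(c(50, 100), c(150, 200)), chrom = "chrF", strand = "*"),
    make_aln("r", blk(c(50, 100), c(150, 200)), chrom = "chrR", strand = "*")
  )
  out <- infer_strands(alns, genome)
  expect_equal(out$strand, c("+", "-"))
})
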
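test_that("JASPAR counts convert to probabilities with the 0.25 pseudocount", {
  f <- withr::local_tempfile(lines = c(
    ">MA0001.1 TFX",
    "A [ 0 10 ]",
    "C [ 0 10 ]",
    "G [ 10 10 ]",
    "T [ 0 10 ]"))
  pwms <- read_pwms(f, dialect = "jaspar")
  expect_named(pwms, "TFX")
  p <- pwms$TFX
  # (0 + 0.25) / (10 + 1) and (10 + 0.25) / 11, frozen by hand arithmetic
  expect_equal(unname(p$probs[, 1]),
               c(0.25 / 11, 0.25 / 11, 10.25 / 11, 0.25 / 11))
  # equal counts give the uniform column
  expect_equal(unname(p$probs[, 2]), rep(0.25, 4))
  expect_equal(colSums(p$probs), c(1, 1), ignore_attr = TRUE)
})

test_that("malformed PWM records are rejected with the record named", {
  three_rows <- withr::local_tempfile(lines = c(
    ">M1 BADTF", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]"))
  expect_error(read_pwms(three_rows, "jaspar"), "BADTF.*4 base rows")
  unequal <- withr::local_tempfile(lines = c(
    ">M1 TF1", "A [ 1 2 ]", "C [ 1 2 3 ]", "G [ 1 2 ]", "T [ 1 2 ]"))
  expect_error(read_pwms(unequal, "jaspar"), "unequal row lengths")
  negative <- withr::local_tempfile(lines = c(
    ">M1 TF1", "A [ 1 -2 ]", "C [ 1 2 ]", "G [ 1 2 ]", "T [ 1 2 ]"))
  expect_error(read_pwms(negative, "jaspar"), "negative")
})

test_that("Cis-BP probabilities are floored and renormalized", {
  f <- withr::local_tempfile(lines = c(
    ">TFY", "Pos A C G T",
    "1 0.0 0.0 1.0 0.0",
    "2 0.25 0.25 0.25 0.25"))
  p <- read_pwms(f, dialect = "cisbp")$TFY
  expect_equal(p$width, 2)
  expect_true(all(p$probs > 0))
  expect_equal(colSums(p$probs), c(1, 1), ignore_attr = TRUE)
  expect_equal(unname(p$probs["G", 1]), 1 / 1.0003, tolerance = 1e-9)
  bad <- withr::local_tempfile(lines = c(">T", "Pos A C G T", "1 0.5 0.5"))
  expect_error(read_pwms(bad, "cisbp"), "malformed row")
})

test_that("bedGraph reading densifies and round-trips", {
  sizes <- c(chr1 = 100L)
  empty <- withr::local_tempfile(lines = character())
  tr <- read_cut_track(empty, sizes)
  expect_equal(tr$counts$chr1, rep(0, 100))

  one <- withr::local_tempfile(lines = "chr1\t10\t12\t3")
  tr <- read_cut_track(one, sizes)
  expect_equal(which(tr$counts$chr1 != 0), c(11, 12))
  expect_equal(sum(tr$counts$chr1), 6)

  oob <- withr::local_tempfile(lines = "chr1\t90\t120\t1")
  expect_error(read_cut_track(oob, sizes), "out of bounds")

  set.seed(7)
  for (i in 1:5) {
    x <- rpois(200, 0.5)
    track <- cut_track(list(chr1 = x, chr2 = rpois(50, 2)))
    f <- withr::local_tempfile()
    write_cut_track(track, f)
    expect_equal(read_cut_track(f, track$sizes), track)
  }
})

test_that("narrowPeak round-trips all ten fields", {
  pk <- peaks_df(chrom = c("chr1", "chr1", "chr2"),
                 start = c(100L, 500L, 0L), end = c(400L, 900L, 250L),
                 name = c("p1", "p2", "p3"), score = c(10L, 55L, 1000L),
                 strand = ".", fold_enrichment = c(3.5, 12.25, 1.75),
                 neg_log10_p = c(4.5, 100.125, 2), neg_log10_q = c(2.25, 80, 1),
                 summit_offset = c(5L, 200L, 249L))
  f <- withr::local_tempfile()
  write_narrowpeak(pk, f)
  expect_identical(read_narrowpeak(f), pk)
  # summit offset lands in column 10
  expect_equal(strsplit(readLines(f)[1], "\t")[[1]][10], "5")
  bad <- withr::local_tempfile(lines = paste(rep("x", 9), collapse = "\t"))
  expect_error(read_narrowpeak(bad), "9 columns")
})

test_that("BED and TSS tables parse and validate", {
  bed <- withr::local_tempfile(lines = "chr1\t8000\t10300\tpromA\t0\t+")
  x <- read_bed(bed)
  expect_equal(x[1, ], gintervals("chr1", 8000, 10300, "+", "promA")[1, ])
  bad <- withr::local_tempfile(lines = "chr1\t50\t50")
  expect_error(read_bed(bad), "start")

  tss <- withr::local_tempfile(lines = "geneA\tchr1\t+\t10000")
  tt <- read_tss_table(tss)
  expect_equal(tt$gene_id, "geneA")
  expect_equal(tt$tss, 10000L)
  bad_tss <- withr::local_tempfile(lines = "geneA\tchr1\t+\tabc")
  expect_error(read_tss_table(bad_tss), "non-integer")

  cs <- withr::local_tempfile(lines = c("chr1\t1000", "chr2\t500"))
  expect_equal(read_chrom_sizes(cs), c(chr1 = 1000L, chr2 = 500L))
})

test_that("interval invariants hold and BED text round-trips losslessly", {
  expect_error(gintervals("chr1", 10, 10), "start")
  expect_error(gintervals("chr1", -1, 5), "integers|start")
  expect_error(gintervals("chr1", 1, 5, strand = "x"), "strand")
  set.seed(11)
  for (i in 1:5) {
    n <- sample(1:30, 1)
    s <- sort(sample(0:10000, n))
    iv <- gintervals(sample(c("chr1", "chr2"), n, TRUE), s,
                     s + sample(1:500, n, TRUE),
                     sample(c("+", "-", "."), n, TRUE),
                     sprintf("iv%d", seq_len(n)))
    f <- withr::local_tempfile()
    write_bed(iv, f)
    back <- read_bed(f)
    expect_identical(back[order(back$name), ], iv[order(iv$name), ],
                     ignore_attr = TRUE)
  }
})

test_that("interval_overlaps requires >= 1 bp of overlap", {
  a <- gintervals("chr1", c(0, 100), c(10, 200))
  b <- gintervals(c("chr1", "chr1", "chr2"), c(9, 10, 0), c(50, 20, 300))
  ov <- interval_overlaps(a, b)
  # [0,10) overlaps [9,50) but not the adjacent [10,20)
  expect_equal(ov$query, c(1L))
  expect_equal(ov$subject, c(1L))
})
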
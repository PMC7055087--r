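# Dialect parsing, coordinate normalisation and within-read overlap
# resolution.

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("tabular6 parsing normalises coordinates and strand", {
  # plus-strand full-length line and a minus-strand line (sstart > send)
  f <- write_lines_tmp(c(
    "r1\tchr1\t98.5\t1000\t10\t5\t1\t1000\t5001\t6000\t1e-100\t900",
    "r2\tchr1\t95.0\t100\t3\t1\t11\t110\t500\t401\t1e-20\t180"), ".tsv")
  p <- parse_alignments(f, "tabular6", read_lengths = c(r1 = 1000L, r2 = 200L))
  r1 <- p[p$read_id == "r1"]
  expect_equal(r1$read_start, 0L)       # 1-based inclusive -> 0-based half-open
  expect_equal(r1$read_end, 1000L)
  expect_equal(r1$ref_start, 5000L)
  expect_equal(r1$ref_end, 6000L)
  expect_equal(r1$strand, "+")
  expect_equal(profile_stats(r1)$aligned_fraction, 1.0)

  r2 <- p[p$read_id == "r2"]
  expect_equal(r2$strand, "-")
  expect_lt(r2$ref_start, r2$ref_end)   # normalised despite sstart > send
  expect_equal(r2$ref_start, 400L)
  expect_equal(r2$ref_end, 500L)
  expect_equal(r2$read_start, 10L)
  expect_equal(r2$mismatch_frac, 0.03)
})

test_that("segments within a read are sorted by read start", {
  f <- write_lines_tmp(c(
    "r1\tchr1\t99\t200\t1\t0\t801\t1000\t3001\t3200\t1e-50\t350",
    "r1\tchr1\t99\t300\t1\t0\t1\t300\t1001\t1300\t1e-80\t550",
    "r1\tchr1\t99\t300\t1\t0\t401\t700\t2001\t2300\t1e-80\t550"), ".tsv")
  p <- parse_alignments(f, "tabular6", read_lengths = c(r1 = 1000L))
  expect_equal(p$read_start, c(0L, 400L, 800L))
})

test_that("tabular6 write -> parse round-trip is lossless", {
  segs <- make_profiles(
    make_segment(),
    make_segment(read_id = "r2", strand = "-", ref_start = 700L,
                 ref_end = 1500L, bitscore = 321.5, e_value = 1e-12,
                 identity_pct = 88.25, read_start = 100L, read_end = 900L,
                 mismatch_frac = 0.05, gap_frac = 0.0125))
  f <- tempfile(fileext = ".tsv")
  write_alignments(segs, f)
  back <- parse_alignments(f, "tabular6",
                           read_lengths = c(r1 = 2000L, r2 = 2000L))
  for (col in c("read_id", "read_start", "read_end", "chrom", "ref_start",
                "ref_end", "strand", "bitscore", "e_value"))
    expect_equal(back[[col]], segs[[col]], info = col)
  expect_equal(back$identity_pct, segs$identity_pct, tolerance = 1e-6)
  expect_equal(back$mismatch_frac, segs$mismatch_frac, tolerance = 2e-3)
})

test_that("PAF parsing handles strand and score surrogates", {
  f <- write_lines_tmp(paste(
    c("r1", 1000, 100, 600, "-", "chr2", 5000, 2000, 2500, 450, 520, 60),
    collapse = "\t"), ".paf")
  p <- parse_alignments(f, "paf")
  expect_equal(p$read_start, 100L)      # PAF query coords already read-oriented
  expect_equal(p$read_end, 600L)
  expect_equal(p$strand, "-")
  expect_equal(p$ref_start, 2000L)
  expect_equal(p$ref_end, 2500L)
  expect_equal(p$bitscore, 450)         # nmatch fallback without AS tag
  expect_equal(p$identity_pct, 100 * 450 / 520)
  expect_equal(attr(p, "contig_lengths"), c(chr2 = 5000L))
})

test_that("PAF records are split at large CIGAR deletions", {
  # 300M 500D 200M: one record spanning a 500-bp deletion
  f <- write_lines_tmp(paste(
    c("r1", 500, 0, 500, "+", "chr1", 10000, 1000, 2000, 490, 1000, 60,
      "cg:Z:300M500D200M"), collapse = "\t"), ".paf")
  p <- parse_alignments(f, "paf", split_gap = 50L)
  expect_equal(nrow(p), 2L)
  expect_equal(p$read_start, c(0L, 300L))
  expect_equal(p$read_end, c(300L, 500L))
  expect_equal(p$ref_start, c(1000L, 1800L))
  expect_equal(p$ref_end, c(1300L, 2000L))
  # the gap is now a junction: detection sees a 500-bp reference gap
  adj <- detect_adjacencies(resolve_overlaps(p), min_sv_size = 50L)
  expect_equal(adj$sv_class, "DEL")
  expect_equal(adj$sv_size, 500L)
})

test_that("SAM minus-strand coordinates are flipped to read orientation", {
  f <- write_lines_tmp(c(
    "@SQ\tSN:chr1\tLN:100000",
    paste(c("r1", 16, "chr1", 2001, 60, "10S50M5I35M", "*", 0, 0,
            paste(rep("A", 100), collapse = ""), "*", "NM:i:7", "AS:i:80"),
          collapse = "\t")), ".sam")
  p <- parse_alignments(f, "sam")
  expect_equal(p$read_length, 100L)
  expect_equal(p$strand, "-")
  # alignment covers SEQ offsets [10,100); flipped: read coords [0,90)
  expect_equal(p$read_start, 0L)
  expect_equal(p$read_end, 90L)
  expect_equal(p$ref_start, 2000L)
  expect_equal(p$ref_end, 2085L)
  expect_equal(attr(p, "contig_lengths"), c(chr1 = 100000L))
})

test_that("malformed lines raise record-level errors", {
  f <- write_lines_tmp(c(
    "r1\tchr1\t98.5\t1000\t10\t5\t1\t1000\t5001\t6000\t1e-100\t900",
    "r2\tchr1\tnot_a_number\tx\ty\tz\ta\tb\tc\td\te\tf"), ".tsv")
  expect_error(suppressWarnings(
    parse_alignments(f, "tabular6", read_lengths = c(r1 = 1000L, r2 = 10L))),
    "malformed|missing")
  expect_error(parse_alignments(f, "nonsense"), "arg")
})

test_that("overlap resolution trims the lower-bitscore segment", {
  # disjoint segments are untouched
  disjoint <- make_profiles(
    make_segment(read_start = 0L, read_end = 400L),
    make_segment(read_start = 500L, read_end = 900L, ref_start = 3000L,
                 ref_end = 3400L, bitscore = 300))
  expect_equal(data.table::as.data.table(resolve_overlaps(disjoint)),
               data.table::as.data.table(disjoint))

  # containment: the lower-scoring contained segment is dropped
  contained <- make_profiles(
    make_segment(read_start = 0L, read_end = 600L, bitscore = 900),
    make_segment(read_start = 100L, read_end = 300L, ref_start = 5000L,
                 ref_end = 5200L, bitscore = 200))
  res <- resolve_overlaps(contained)
  expect_equal(nrow(res), 1L)
  expect_equal(res$bitscore, 900)

  # partial overlap: B trimmed to [400,700), ref shrunk proportionally
  partial <- make_profiles(
    make_segment(read_start = 0L, read_end = 400L, ref_start = 1000L,
                 ref_end = 1400L, bitscore = 500),
    make_segment(read_start = 300L, read_end = 700L, ref_start = 5000L,
                 ref_end = 5400L, bitscore = 400))
  res <- resolve_overlaps(partial)
  expect_equal(res$read_start, c(0L, 400L))
  expect_equal(res$read_end, c(400L, 700L))
  # trimmed 100 of 400 read bases from the left -> ref start moves 100 of 400
  expect_equal(res$ref_start[2], 5100L)
  expect_equal(res$ref_end[2], 5400L)
})

test_that("overlap resolution is idempotent and respects read length", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    L <- 2000L
    segs <- do.call(make_profiles, lapply(seq_len(n), function(i) {
      s <- sample(0:(L - 200L), 1)
      e <- min(L, s + sample(100:1200, 1))
      make_segment(read_start = s, read_end = e,
                   ref_start = 10000L * i, ref_end = 10000L * i + (e - s),
                   bitscore = sample(100:1000, 1),
                   strand = sample(c("+", "-"), 1))
    }))
    once <- resolve_overlaps(segs)
    twice <- resolve_overlaps(once)
    expect_equal(data.table::as.data.table(twice),
                 data.table::as.data.table(once))
    # non-overlapping on read coordinates, total <= read length
    expect_true(all(diff(once$read_start) >= 0))
    if (nrow(once) > 1L)
      expect_true(all(once$read_start[-1] >= once$read_end[-nrow(once)]))
    expect_lte(sum(once$read_end - once$read_start), L)
    # the top-scoring segment survives untrimmed
    top <- segs[which.max(segs$bitscore)]
    expect_true(any(once$read_start == top$read_start &
                      once$read_end == top$read_end))
  }
})
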
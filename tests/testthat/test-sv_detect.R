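# Novel-adjacency detection and classification from toy alignment
# profiles, clustering, and zygosity estimation.

test_that("a reference gap with contiguous read coordinates is a deletion", {
  p <- make_profiles(
    make_segment(read_start = 0L, read_end = 1000L, ref_start = 1000L,
                 ref_end = 2000L),
    make_segment(read_start = 1005L, read_end = 2005L, ref_start = 2500L,
                 ref_end = 3500L))
  adj <- detect_adjacencies(p)
  expect_equal(adj$sv_class, "DEL")
  expect_equal(adj$sv_size, 500L)
  expect_equal(sort(c(adj$pos1, adj$pos2)), c(2000L, 2500L))
})

test_that("a read gap with contiguous reference coordinates is an insertion", {
  p <- make_profiles(
    make_segment(read_start = 0L, read_end = 1000L, ref_start = 1000L,
                 ref_end = 2000L, read_length = 2500L),
    make_segment(read_start = 1500L, read_end = 2500L, ref_start = 2000L,
                 ref_end = 3000L, read_length = 2500L))
  adj <- detect_adjacencies(p)
  expect_equal(adj$sv_class, "INS")
  expect_equal(adj$inserted_len, 500L)
  expect_equal(adj$pos1, 2000L)
  expect_true(is.na(adj$pos2))          # single-breakend class
})

test_that("inter-chromosomal junctions are translocation breakends", {
  p <- make_profiles(
    make_segment(read_start = 0L, read_end = 1000L, chrom = "chr1"),
    make_segment(read_start = 1010L, read_end = 2000L, chrom = "chr5",
                 ref_start = 9000L, ref_end = 9990L, strand = "-"))
  adj <- detect_adjacencies(p)
  expect_equal(adj$sv_class, "BND")
  expect_equal(adj$bnd_subtype, "translocation")
  expect_equal(adj$chrom1, "chr1")
  expect_equal(adj$chrom2, "chr5")
})

test_that("a strand flip yields the two inversion boundary breakends", {
  # read spans the left inversion boundary at 2000; inversion is [2000,3000)
  p <- make_profiles(
    make_segment(read_start = 0L, read_end = 1000L, ref_start = 1000L,
                 ref_end = 2000L, strand = "+"),
    make_segment(read_start = 1005L, read_end = 1805L, ref_start = 2200L,
                 ref_end = 3000L, strand = "-"))
  adj <- detect_adjacencies(p)
  expect_equal(adj$sv_class, "INV")
  expect_equal(adj$pos1, 2000L)
  expect_equal(adj$pos2, 3000L)
  expect_equal(adj$sv_size, 1000L)
})

test_that("a backward reference jump is a tandem duplication", {
  # read walks off the end of the duplicated unit [2000,2600) and re-enters
  p <- make_profiles(
    make_segment(read_start = 0L, read_end = 1000L, ref_start = 1600L,
                 ref_end = 2600L, strand = "+", read_length = 2000L),
    make_segment(read_start = 1004L, read_end = 2000L, ref_start = 2000L,
                 ref_end = 2996L, strand = "+", read_length = 2000L))
  adj <- detect_adjacencies(p)
  expect_equal(adj$sv_class, "DUP")
  expect_equal(adj$pos1, 2000L)         # duplication start
  expect_equal(adj$pos2, 2600L)         # duplication end
  expect_equal(adj$sv_size, 600L)
})

test_that("flank-middle-flank with a distant middle is a transposition", {
  p <- make_profiles(
    make_segment(read_start = 0L, read_end = 1000L, ref_start = 1000L,
                 ref_end = 2000L, read_length = 2500L),
    make_segment(read_start = 1003L, read_end = 1500L, ref_start = 500000L,
                 ref_end = 500497L, read_length = 2500L),
    make_segment(read_start = 1504L, read_end = 2500L, ref_start = 2004L,
                 ref_end = 3000L, read_length = 2500L))
  adj <- detect_adjacencies(p)
  expect_equal(adj$sv_class, "BND")
  expect_equal(adj$bnd_subtype, "transposition")
  expect_equal(adj$pos1, 2000L)          # insertion site
  expect_equal(adj$pos2, 500000L)        # source locus
  expect_equal(adj$inserted_len, 497L)
  expect_equal(nrow(adj), 1L)            # the two pair junctions are consumed
})

test_that("degenerate profiles produce no adjacencies", {
  single <- make_profiles(make_segment())
  expect_equal(nrow(detect_adjacencies(single)), 0L)
  # contiguous junction (no gap on either axis) is a normal read
  contiguous <- make_profiles(
    make_segment(read_start = 0L, read_end = 1000L, ref_start = 1000L,
                 ref_end = 2000L),
    make_segment(read_start = 1005L, read_end = 2000L, ref_start = 2003L,
                 ref_end = 2998L))
  expect_equal(nrow(detect_adjacencies(contiguous)), 0L)
})

test_that("detection is invariant to segment list order", {
  p <- make_profiles(
    make_segment(read_start = 0L, read_end = 1000L, ref_start = 1000L,
                 ref_end = 2000L),
    make_segment(read_start = 1005L, read_end = 2005L, ref_start = 2500L,
                 ref_end = 3500L))
  rev_p <- make_profiles(
    make_segment(read_start = 1005L, read_end = 2005L, ref_start = 2500L,
                 ref_end = 3500L),
    make_segment(read_start = 0L, read_end = 1000L, ref_start = 1000L,
                 ref_end = 2000L))
  expect_equal(detect_adjacencies(p), detect_adjacencies(rev_p))
})

test_that("a deletion seen on the minus strand classifies identically", {
  # same DEL junction, read aligned in reverse orientation: segments occur
  # in opposite read order and ref coordinates descend along the read
  p <- make_profiles(
    make_segment(read_start = 0L, read_end = 1000L, ref_start = 2500L,
                 ref_end = 3500L, strand = "-"),
    make_segment(read_start = 1005L, read_end = 2005L, ref_start = 1000L,
                 ref_end = 2000L, strand = "-"))
  adj <- detect_adjacencies(p)
  expect_equal(adj$sv_class, "DEL")
  expect_equal(adj$sv_size, 500L)
  expect_equal(sort(c(adj$pos1, adj$pos2)), c(2000L, 2500L))
})

test_that("clustering merges nearby same-class breakends at the median", {
  mk <- function(rid, pos) data.table::data.table(
    read_id = rid, sv_class = "DEL", bnd_subtype = NA_character_,
    chrom1 = "chr1", pos1 = pos, chrom2 = "chr1", pos2 = pos + 500L,
    sv_size = 500L, inserted_len = NA_integer_, read_gap = 0L,
    ref_gap = 500L, up_idx = 1L, dn_idx = 2L)
  adj <- data.table::rbindlist(list(mk("a", 1998L), mk("b", 2000L),
                                    mk("c", 2004L)))
  calls <- cluster_adjacencies(adj, merge_distance = 50L, min_support = 1L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos1, 2000L)       # median of {1998, 2000, 2004}
  expect_equal(calls$B, 3L)
  expect_equal(calls$n_adj, 3L)

  # two adjacencies 10 kb apart stay separate calls
  far <- data.table::rbindlist(list(mk("a", 2000L), mk("b", 12000L)))
  expect_equal(nrow(cluster_adjacencies(far, min_support = 1L)), 2L)

  # a single-read call is dropped at the clinical minimum support of 2
  expect_equal(nrow(cluster_adjacencies(mk("a", 2000L), min_support = 2L)), 0L)
})

test_that("clustering conserves adjacencies: none lost or double-assigned", {
  set.seed(7)
  adj <- data.table::rbindlist(lapply(1:200, function(i) {
    data.table::data.table(
      read_id = paste0("r", i), sv_class = sample(c("DEL", "INS", "INV"), 1),
      bnd_subtype = NA_character_, chrom1 = sample(c("chr1", "chr2"), 1),
      pos1 = sample(1:100000, 1), chrom2 = NA_character_, pos2 = NA_integer_,
      sv_size = 100L, inserted_len = NA_integer_, read_gap = 0L,
      ref_gap = 100L, up_idx = 1L, dn_idx = 2L)
  }))
  calls <- cluster_adjacencies(adj, min_support = 1L)
  expect_equal(sum(calls$n_adj), nrow(adj))
  ann <- attr(calls, "adjacencies")
  expect_false(anyNA(ann$cluster_id))
  expect_equal(data.table::uniqueN(ann$cluster_id), nrow(calls))
})

test_that("zygosity bands follow the breakend read ratio", {
  calls <- data.table::data.table(ratio = c(1.0, 0.5, 0.05, 0.8, 0.349))
  z <- estimate_zygosity(calls)$zygosity
  expect_equal(z, c("HOM", "HET", "UNKNOWN", "HOM", "UNKNOWN"))
})

test_that("breakends inside excluded regions are removed", {
  calls <- data.table::data.table(
    chrom1 = c("chr1", "chr1"), pos1 = c(100L, 5000L),
    chrom2 = c(NA, "chr1"), pos2 = c(NA, 6000L))
  excl <- splitsv:::granges0("chr1", 0L, 1000L)
  kept <- filter_excluded(calls, excl)
  expect_equal(kept$pos1, 5000L)
  expect_equal(nrow(filter_excluded(calls, NULL)), 2L)
})
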
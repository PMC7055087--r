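# SV genome simulation (length bookkeeping, truth tables, determinism),
# mixed-zygosity nesting, and long-read generation.

test_that("a single deletion shortens the contig by its size", {
  ref <- random_genome(c(chr1 = 10000L), seed = 1)
  prof <- sv_profile(del = 1, inv = 0, dup = 0, tpo = 0, ins = 0,
                     size_meanlog = log(500), size_sdlog = 1e-9,
                     flank_indel_max = 5L)
  sim <- simulate_sv_genome(ref, prof, seed = 2)
  expect_equal(nrow(sim$truth), 1L)
  expect_equal(sim$truth$sv_class, "DEL")
  expect_equal(sim$truth$sv_size, 500L)
  expect_false(is.na(sim$truth$pos2))   # deletions carry two breakends
  # one junction, at most one indel of <= 5 bp in its mutated flank
  expect_lte(abs(Biostrings::width(sim$genome) - (10000L - 500L)), 5L)
})

test_that("an all-zero profile reproduces the reference exactly", {
  ref <- random_genome(c(chr1 = 5000L), seed = 3)
  prof <- sv_profile(del = 0, inv = 0, dup = 0, tpo = 0, ins = 0)
  sim <- simulate_sv_genome(ref, prof, seed = 1)
  expect_equal(as.character(sim$genome), as.character(ref))
  expect_equal(nrow(sim$truth), 0L)
})

test_that("sequence length bookkeeping is exact up to flank indels", {
  ref <- random_genome(c(chr1 = 3e5), seed = 4)
  prof <- sv_profile(del = 4, inv = 2, dup = 2, tpo = 2, ins = 2,
                     size_meanlog = log(300), size_sdlog = 0.5)
  sim <- simulate_sv_genome(ref, prof, seed = 5)
  tr <- sim$truth
  expected <- 3e5 -
    sum(tr$sv_size[tr$sv_class == "DEL"]) +
    sum(tr$sv_size[tr$sv_class %in% c("DUP", "INS", "BND")])
  n_junctions <- sum(tr$sv_class == "DEL") + 2L * sum(tr$sv_class != "DEL")
  expect_lte(abs(Biostrings::width(sim$genome) - expected), 5L * n_junctions)
})

test_that("truth-table counts equal the requested per-class counts", {
  ref <- random_genome(c(chr1 = 1e6), seed = 6)
  prof <- sv_profile(del = 10, inv = 3, dup = 3, tpo = 4, ins = 5,
                     size_meanlog = log(200), size_sdlog = 0.4)
  sim <- simulate_sv_genome(ref, prof, seed = 7)
  counts <- table(sim$truth$sv_class)
  expect_equal(unname(counts[c("DEL", "INV", "DUP", "BND", "INS")]),
               c(10L, 3L, 3L, 4L, 5L), ignore_attr = TRUE)
  # breakend counts per class: 2 for DEL/INV/DUP, 1 for INS/BND
  expect_true(all(!is.na(sim$truth$pos2[sim$truth$sv_class %in%
                                          c("DEL", "INV", "DUP")])))
  expect_true(all(is.na(sim$truth$pos2[sim$truth$sv_class %in%
                                         c("INS", "BND")])))
})

test_that("edits stay on their own contig in multi-contig references", {
  # regression: each chromosome must receive only its own edits; a planted
  # SV on one contig must leave the other contigs' non-SV sequence intact
  ref <- random_genome(c(chrA = 3e5, chrB = 2e5), seed = 31)
  prof <- sv_profile(del = 6, inv = 1, dup = 1, tpo = 3, ins = 3,
                     size_meanlog = log(300), size_sdlog = 0.5)
  sim <- simulate_sv_genome(ref, prof, seed = 32)
  for (chr in c("chrA", "chrB")) {
    tr <- sim$truth[chrom == chr]
    expected <- Biostrings::width(ref[chr]) -
      sum(tr$sv_size[tr$sv_class == "DEL"]) +
      sum(tr$sv_size[tr$sv_class %in% c("DUP", "INS", "BND")])
    n_junc <- sum(tr$sv_class == "DEL") + 2L * sum(tr$sv_class != "DEL")
    expect_lte(abs(Biostrings::width(sim$genome[chr]) - expected),
               5L * max(n_junc, 1L), label = chr)
  }
})

test_that("the two-genome dataset profile totals 42000 SVs at full scale", {
  ds <- dataset_profiles(scale = 1)
  expect_equal(sum(ds$rearrangements$counts), 32000)
  expect_equal(sum(ds$insertions$counts), 10000)
  expect_equal(sum(ds$rearrangements$counts) + sum(ds$insertions$counts),
               42000)
  expect_equal(unname(ds$rearrangements$counts["DEL"]), 20000)
  expect_equal(unname(ds$rearrangements$counts["BND"]), 10000)
})

test_that("identical seeds give byte-identical genomes and reads", {
  ref <- random_genome(c(chr1 = 2e5), seed = 8)
  prof <- sv_profile(scale = 3e-4)
  s1 <- simulate_sv_genome(ref, prof, seed = 9)
  s2 <- simulate_sv_genome(ref, prof, seed = 9)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  o1 <- simulate_long_reads(s1$genome, depth = 2, seed = 10, fastq = f1)
  o2 <- simulate_long_reads(s1$genome, depth = 2, seed = 10, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(o1, o2)
})

test_that("mixed-zygosity genomes are nested at 100/83/50 percent", {
  ref <- random_genome(c(chr1 = 2e6), seed = 11)
  prof <- sv_profile(del = 60, inv = 10, dup = 10, tpo = 10, ins = 10,
                     size_meanlog = log(200), size_sdlog = 0.5)
  mz <- simulate_mixed_zygosity(ref, prof, seed = 12)
  expect_equal(nrow(mz$truth), 100L)
  zyg <- table(mz$truth$zygosity)
  expect_equal(unname(zyg["hom"]), 50L)               # C: 50%
  expect_equal(unname(zyg["het"]), 33L)               # B \ C: 83% - 50%
  expect_equal(unname(zyg["low_conf"]), 17L)          # A \ B
  expect_equal(mz$read_weights, c(A = 0.25, B = 0.25, C = 0.5))
  # C's SVs are a subset of B's: genome C is closer to the reference
  expect_named(mz$genomes, c("A", "B", "C"))
  mz2 <- simulate_mixed_zygosity(ref, prof, seed = 12)
  expect_identical(mz$truth, mz2$truth)
})

test_that("repeat bias concentrates breakends in the biased intervals", {
  ref <- random_genome(c(chr1 = 2e6), seed = 81)
  bias <- splitsv:::granges0("chr1", 0L, 200000L)   # 10% of the contig
  prof <- sv_profile(del = 40, inv = 0, dup = 0, tpo = 0, ins = 0,
                     size_meanlog = log(200), size_sdlog = 0.3,
                     repeat_bias = bias, repeat_bias_mult = 10)
  sim <- simulate_sv_genome(ref, prof, seed = 82)
  frac_in <- mean(splitsv:::in_excluded(sim$truth$chrom, sim$truth$pos1, bias))
  # uniform placement would give ~0.10; 10x acceptance odds give ~0.5
  expect_gt(frac_in, 0.3)
})

test_that("read simulation hits the requested depth in expectation", {
  ref <- random_genome(c(chr1 = 1e6), seed = 13)
  org <- simulate_long_reads(ref, depth = 4, seed = 14,
                             model = read_model(mean_length = 8000))
  total <- sum(org$read_length)
  expect_gt(total, 4e6 * 0.85)
  expect_lt(total, 4e6 * 1.15)
})

test_that("error-free reads are exact substrings of their source", {
  ref <- random_genome(c(chr1 = 50000L), seed = 15)
  fq <- tempfile(fileext = ".fq")
  org <- simulate_long_reads(ref, depth = 1,
                             model = read_model(sub = 0, ins = 0, del = 0,
                                                chimera_rate = 0,
                                                mean_length = 3000),
                             seed = 16, fastq = fq)
  reads <- Biostrings::readDNAStringSet(fq, format = "fastq")
  names(reads) <- sub("\\s.*$", "", names(reads))
  refseq <- as.character(ref[["chr1"]])
  for (i in seq_len(min(5L, nrow(org)))) {
    r <- as.character(reads[[org$read_id[i]]])
    if (org$strand[i] == "-") r <- splitsv:::revcomp(r)
    expect_equal(r, substr(refseq, org$start[i] + 1L, org$end[i]))
  }
})

test_that("heterozygous mode splits reads between genome and reference", {
  ref <- random_genome(c(chr1 = 5e5), seed = 17)
  sim <- simulate_sv_genome(ref, sv_profile(scale = 2e-4), seed = 18)
  org <- simulate_long_reads(sim$genome, depth = 4, het_fraction = 0.5,
                             reference = ref, seed = 19)
  frac <- mean(org$source == "ref")
  expect_gt(frac, 0.4); expect_lt(frac, 0.6)
  expect_error(simulate_long_reads(sim$genome, depth = 1, het_fraction = 0.5),
               "reference")
  expect_error(simulate_long_reads(Biostrings::DNAStringSet(), depth = 1),
               "empty")
})

test_that("training example labels follow truth windows", {
  truth <- data.table::data.table(
    sv_id = c("t1", "t2"), sv_class = c("DEL", "INS"), chrom = "chr1",
    pos1 = c(5000L, 20000L), pos2 = c(5600L, NA), sv_size = c(600L, 300L),
    zygosity = "hom")
  adj <- data.table::data.table(
    read_id = c("a", "b", "c", "d"),
    sv_class = c("DEL", "DEL", "INS", "DEL"),
    chrom1 = "chr1", pos1 = c(5000L, 10000L, 20100L, 20000L))
  X <- matrix(runif(4 * 23), 4, 23, dimnames = list(NULL, splitsv:::FEATURE_NAMES))
  # default: a junction at a truth site is true regardless of read class
  ex <- generate_training_examples(X, adj, truth)
  expect_equal(ex$y, c(1L, 0L, 1L, 1L))
  expect_identical(ex$x, X)
  # class-aware: the DEL-read junction at the INS truth site becomes false
  ex_cls <- generate_training_examples(X, adj, truth, class_aware = TRUE)
  expect_equal(ex_cls$y, c(1L, 0L, 1L, 0L))
  expect_error(generate_training_examples(X[0, , drop = FALSE], adj[0], truth),
               "no candidate")
})
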
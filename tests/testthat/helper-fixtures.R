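# Fixture builders shared across test files. All fixtures are constructed
# in code; simulation-based fixtures are cached per session so several test
# files can reuse one expensive run.

make_segment <- function(read_id = "r1", read_length = 2000L,
                         read_start = 0L, read_end = 1000L,
                         chrom = "chr1", ref_start = 1000L, ref_end = 2000L,
                         strand = "+", bitscore = 500, e_value = 1e-50,
                         identity_pct = 95, mismatch_frac = 0.02,
                         gap_frac = 0.01) {
  data.table::data.table(read_id = read_id, read_length = read_length,
                         read_start = as.integer(read_start),
                         read_end = as.integer(read_end),
                         chrom = chrom, ref_start = as.integer(ref_start),
                         ref_end = as.integer(ref_end), strand = strand,
                         bitscore = bitscore, e_value = e_value,
                         identity_pct = identity_pct,
                         mismatch_frac = mismatch_frac, gap_frac = gap_frac)
}

make_profiles <- function(...) {
  segs <- data.table::rbindlist(list(...))
  segs <- segs[order(read_id, read_start)]
  data.table::setattr(segs, "class",
                      c("read_profiles", class(data.table::data.table())))
  segs
}

# normal (non-SV) reads spanning a position: full-length single segments
normal_reads <- function(n, chrom = "chr1", ref_start = 1500L, len = 2000L,
                         prefix = "norm") {
  do.call(make_profiles, lapply(seq_len(n), function(i)
    make_segment(read_id = paste0(prefix, i), read_length = len,
                 read_start = 0L, read_end = len, chrom = chrom,
                 ref_start = ref_start + (i - 1L) * 7L,
                 ref_end = ref_start + (i - 1L) * 7L + len)))
}

# ---- cached end-to-end simulation runs ------------------------------------

.sim_cache <- new.env(parent = emptyenv())

# simulate genome + reads, align with blastn, return parsed profiles plus
# the truth table; memoised on the argument signature
sim_dataset <- function(ref_len = 4e6, depth = 8, het = 0, seed = 11,
                        scale = ref_len / 3.1e9, error = TRUE,
                        key = NULL) {
  key <- key %||% paste0("ds_", ref_len, "_", depth, "_", het, "_", seed,
                         "_", error)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  ref <- random_genome(c(chr1 = ref_len), seed = seed)
  sim <- simulate_sv_genome(ref, sv_profile(scale = scale), seed = seed + 1)
  model <- if (error) read_model() else
    read_model(sub = 0, ins = 0, del = 0, chimera_rate = 0)
  fq <- tempfile(fileext = ".fq")
  simulate_long_reads(sim$genome, depth = depth, model = model,
                      het_fraction = het,
                      reference = if (het > 0) ref else NULL,
                      seed = seed + 2, fastq = fq)
  reffa <- tempfile(fileext = ".fa")
  write_fasta(ref, reffa)
  tab <- splitsv:::blast_align(splitsv:::fastq_to_fasta(fq), reffa)
  profiles <- parse_alignments(tab, "tabular6",
                               read_lengths = read_lengths(fq, "fastq"))
  out <- list(profiles = profiles, truth = sim$truth, ref = ref,
              contig_lengths = c(chr1 = ref_len))
  .sim_cache[[key]] <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
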
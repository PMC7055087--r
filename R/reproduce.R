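# Internal end-to-end benchmark runner: simulate an SV genome and reads,
# align with the BLAST-like CLI aligner (documented parameters: reward 2,
# penalty -3, gapopen 0, gapextend 4, max_target_seqs 3, tabular output),
# run the caller, and evaluate breakend precision/recall/F1 against the
# simulation truth. Used by the test suite and the acceptance script; the
# exported API stays aligner-agnostic.

sim_call_eval <- function(ref_len = 24e6, depth = 4, het = FALSE, seed = 1L,
                          model = sv_default_model(), score_threshold = 1.0,
                          min_support = 1L, read_err = read_model(),
                          sv_density = 42000 / 3.1e9) {
  ref <- random_genome(c(chr1 = ref_len), seed = seed)
  # class counts keep the canonical proportions, scaled to the reference so
  # the genome-wide SV density matches the full-scale recipe
  sim <- simulate_sv_genome(ref, sv_profile(scale = ref_len * sv_density / 42000),
                            seed = seed + 1L)
  fq <- tempfile(fileext = ".fq")
  simulate_long_reads(sim$genome, depth = depth, model = read_err,
                      het_fraction = if (het) 0.5 else 0,
                      reference = if (het) ref else NULL,
                      seed = seed + 2L, fastq = fq)
  reffa <- tempfile(fileext = ".fa")
  write_fasta(ref, reffa)
  tab <- blast_align(fastq_to_fasta(fq), reffa)
  profiles <- parse_alignments(tab, "tabular6",
                               read_lengths = read_lengths(fq, "fastq"))
  cs <- sv_call(profiles, model = model, min_support = min_support,
                score_threshold = score_threshold,
                contig_lengths = setNames(ref_len, "chr1"),
                seed = seed + 3L)
  filt <- filter_by_score(cs$calls, score_threshold)
  win <- truth_windows(sim$truth)
  list(callset = cs, filtered = filt, truth = sim$truth, windows = win,
       eval = match_breakends(filt, win),
       eval_class = match_breakends(filt, win, class_aware = TRUE))
}
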
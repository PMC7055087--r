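#' @import data.table
#' @importFrom stats median predict rbinom rlnorm runif setNames
#' @importFrom utils read.table write.table head tail
NULL

# Internal coordinate convention: 0-based half-open everywhere; converted to
# 1-based only at VCF emission.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement DNA character vectors
#' @param x character vector of DNA sequences (ACGTN)
#' @return character vector of reverse complements
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a BED file as genomic intervals
#'
#' BED input is 0-based half-open, matching the package-internal convention.
#' The optional 4th column (name) is kept as `family` for repeat-family
#' stratification.
#'
#' @param path path to a BED file
#' @return a `GRanges` (0-based starts preserved via metadata column
#'   `start0`); the `family` metadata column holds the BED name field when
#'   present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) gr$family <- gr$name
  gr
}

# Build a GRanges from 0-based half-open [start, end) coordinates.
granges0 <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L, end = end0), ...)
}

# TRUE where 0-based positions fall inside any exclusion interval.
in_excluded <- function(chrom, pos0, exclude) {
  if (is.null(exclude) || length(exclude) == 0L) return(rep(FALSE, length(pos0)))
  pts <- granges0(chrom, pos0, pos0 + 1L)
  IRanges::overlapsAny(pts, exclude, ignore.strand = TRUE)
}

#' Generate a random synthetic reference genome
#'
#' Uniform base composition; intended as a template for the SV simulator
#' when no real reference is supplied.
#'
#' @param lengths named integer vector of contig lengths
#' @param seed integer seed
#' @return a [Biostrings::DNAStringSet]
#' @export
random_genome <- function(lengths, seed = 1L) {
  set.seed(seed)
  if (is.null(names(lengths))) names(lengths) <- paste0("chr", seq_along(lengths))
  seqs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(lengths)))
}

#' Write sequences as FASTA
#' @param seqs named character vector or DNAStringSet
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read lengths of sequences in a FASTA/FASTQ file
#' @param path sequence file
#' @param format "fasta" or "fastq"
#' @return named integer vector of read lengths
#' @export
read_lengths <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  ss <- Biostrings::readDNAStringSet(path, format = format)
  out <- Biostrings::width(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

# --- external aligner convenience (tests / scripts only, not exported) ------
#
# The caller consumes alignment files and is aligner-agnostic. These
# helpers exist so simulations can run end to end where the standard CLI
# aligners are on PATH. blast_align() uses the BLAST-like scoring the
# split-read method was designed around (reward 2, penalty -3, gapopen 0,
# gapextend 4, max_target_seqs 3, tabular output): near-zero gap tolerance
# fragments alignments at SV junctions, so deleted/inserted/duplicated
# segments show up as separate local alignments rather than long CIGAR
# gaps.

blast_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

blast_align <- function(reads_fasta, reference_fasta,
                        out = tempfile(fileext = ".tsv"), threads = 1L) {
  if (!blast_available()) stop("blastn/makeblastdb not found on PATH")
  db <- tempfile("blastdb")
  status <- system2("makeblastdb", c("-in", reference_fasta, "-dbtype", "nucl",
                                     "-out", db), stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("makeblastdb failed")
  status <- system2("blastn", c("-task", "megablast", "-query", reads_fasta,
                                "-db", db, "-reward", "2", "-penalty", "-3",
                                "-gapopen", "0", "-gapextend", "4",
                                "-max_target_seqs", "3", "-outfmt", "6",
                                "-num_threads", threads, "-out", out),
                    stderr = FALSE)
  if (status != 0L) stop("blastn exited with status ", status)
  out
}

# fastq -> fasta (blastn does not read FASTQ)
fastq_to_fasta <- function(fastq, fasta = tempfile(fileext = ".fa")) {
  ss <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  names(ss) <- sub("\\s.*$", "", names(ss))
  Biostrings::writeXStringSet(ss, fasta)
  fasta
}

minimap2_available <- function() nzchar(Sys.which("minimap2"))

# Align long reads with minimap2 producing PAF with CIGAR (cg tag). The
# public API consumes alignment files and stays aligner-agnostic; this
# helper exists so simulations can be run end to end on machines that have
# minimap2 on PATH.
minimap2_align <- function(reads, reference, out = tempfile(fileext = ".paf"),
                           preset = "map-ont", threads = 1L) {
  if (!minimap2_available()) stop("minimap2 not found on PATH")
  args <- c("-x", preset, "-c", "--secondary=no", "-t", threads, reference, reads)
  status <- system2("minimap2", args, stdout = out, stderr = FALSE)
  if (status != 0L) stop("minimap2 exited with status ", status)
  out
}
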
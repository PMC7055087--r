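# SV-genome and long-read simulation with ground-truth tables.
#
# The generator plants deletions, balanced inversions, single tandem
# duplications, transpositions (copy of a distant reference segment pasted
# at a new site) and novel-sequence insertions into a reference, mutates a
# 20-bp window around every junction (SNPs and short indels) to emulate
# junction microheterogeneity, and records every breakend in reference
# coordinates. Long reads are drawn with a log-normal length distribution
# and ONT-like substitution/insertion/deletion error rates; an optional
# chimeric-read fraction (two unrelated fragments joined) provides the
# false novel adjacencies used when training the classifier.

#' SV simulation profile
#'
#' Default class counts follow the canonical whole-genome recipe of 20000
#' deletions, 1000 balanced inversions, 1000 single tandem duplications,
#' 10000 transpositions plus 10000 novel (viral-like) insertions; `scale`
#' shrinks all counts proportionally for desk-scale genomes.
#'
#' @param del,inv,dup,tpo,ins per-class SV counts before scaling
#' @param scale multiplier applied (and rounded) to all counts
#' @param size_meanlog,size_sdlog log-normal SV size parameters (bases)
#' @param size_range SV sizes are resampled into this range (default 50 bp
#'   to 100 kb)
#' @param flank_window width (bases) of the mutated window centred on each
#'   junction (default 20)
#' @param flank_snp per-base substitution probability inside the window
#'   (default 0.25)
#' @param flank_indel probability of one short indel per window (default
#'   0.5)
#' @param flank_indel_max maximum indel length (default 5)
#' @param repeat_bias optional `GRanges`; breakends are preferentially
#'   placed inside these intervals
#' @param repeat_bias_mult acceptance odds multiplier for biased placement
#' @return list of class `sv_profile`
#' @export
sv_profile <- function(del = 20000L, inv = 1000L, dup = 1000L, tpo = 10000L,
                       ins = 10000L, scale = 1,
                       size_meanlog = log(400), size_sdlog = 1.2,
                       size_range = c(50L, 100000L),
                       flank_window = 20L, flank_snp = 0.25,
                       flank_indel = 0.5, flank_indel_max = 5L,
                       repeat_bias = NULL, repeat_bias_mult = 3) {
  counts <- round(c(DEL = del, INV = inv, DUP = dup, BND = tpo, INS = ins) * scale)
  stopifnot(all(counts >= 0), flank_snp >= 0, flank_snp <= 1,
            flank_indel >= 0, flank_indel <= 1)
  structure(list(counts = counts, size_meanlog = size_meanlog,
                 size_sdlog = size_sdlog, size_range = size_range,
                 flank_window = flank_window, flank_snp = flank_snp,
                 flank_indel = flank_indel, flank_indel_max = flank_indel_max,
                 repeat_bias = repeat_bias,
                 repeat_bias_mult = repeat_bias_mult),
            class = "sv_profile")
}

#' The two-genome dataset profile
#'
#' One simulation dataset consists of two genomes: one carrying deletions,
#' inversions, tandem duplications and transpositions (32000 SVs at scale
#' 1), and one carrying only novel insertions (10000 SVs at scale 1), for a
#' total of 42000 SVs.
#'
#' @param scale count multiplier
#' @param ... passed to [sv_profile()]
#' @return list with elements `rearrangements` and `insertions`, both
#'   `sv_profile`
#' @export
dataset_profiles <- function(scale = 1, ...) {
  list(rearrangements = sv_profile(ins = 0L, scale = scale, ...),
       insertions = sv_profile(del = 0L, inv = 0L, dup = 0L, tpo = 0L,
                               ins = 10000L, scale = scale, ...))
}

rand_sizes <- function(n, profile) {
  if (n == 0L) return(integer(0))
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rlnorm(2L * (n - length(out)), profile$size_meanlog,
                      profile$size_sdlog))
    x <- x[x >= profile$size_range[1] & x <= profile$size_range[2]]
    out <- c(out, x)
  }
  as.integer(out[seq_len(n)])
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# ---- SV planning ----------------------------------------------------------

# Plan non-overlapping SV footprints on the reference. Returns the edit
# table in reference coordinates (0-based half-open). Placement is uniform,
# or biased towards `repeat_bias` intervals when supplied.
plan_svs <- function(reference, profile, seed = 1L, buffer = 1500L) {
  set.seed(seed)
  lens <- setNames(Biostrings::width(reference), names(reference))
  counts <- profile$counts
  total <- sum(counts)
  if (total == 0L) return(empty_truth())
  classes <- rep(names(counts), counts)
  classes <- sample(classes)                      # interleave classes
  sizes <- rand_sizes(total, profile)
  occupied <- lapply(lens, function(...) matrix(numeric(0), ncol = 2))
  rows <- vector("list", total)
  margin <- 2000L
  for (i in seq_len(total)) {
    cls <- classes[i]; size <- sizes[i]
    placed <- FALSE
    for (attempt in 1:200) {
      chrom <- if (length(lens) == 1L) names(lens) else
        sample(names(lens), 1L, prob = lens)
      L <- lens[[chrom]]
      foot <- if (cls %in% c("DEL", "INV", "DUP")) size else 1L
      if (L - foot - 2L * margin <= 0L) next
      s <- margin + floor(runif(1) * (L - foot - 2L * margin))
      if (!is.null(profile$repeat_bias) &&
          !in_excluded(chrom, s, profile$repeat_bias) &&
          runif(1) > 1 / profile$repeat_bias_mult) next
      occ <- occupied[[chrom]]
      lo <- s - buffer; hi <- s + foot + buffer
      if (nrow(occ) > 0L && any(occ[, 1] < hi & occ[, 2] > lo)) next
      src_chrom <- NA_character_; src_pos <- NA_integer_
      if (cls == "BND") {                        # transposition source
        for (k in 1:50) {
          sc <- if (length(lens) == 1L) chrom else sample(names(lens), 1L, prob = lens)
          sp <- margin + floor(runif(1) * (lens[[sc]] - size - 2L * margin))
          if (sc == chrom && abs(sp - s) < 50000L) next
          src_chrom <- sc; src_pos <- sp; break
        }
        if (is.na(src_chrom)) next
      }
      occupied[[chrom]] <- rbind(occ, c(lo, hi))
      rows[[i]] <- data.table::data.table(
        sv_class = cls, chrom = chrom, start = as.integer(s),
        end = as.integer(s + foot), sv_size = size,
        src_chrom = src_chrom, src_pos = src_pos)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", cls, " of ", size,
           " bp; profile infeasible for this reference (placed ",
           sum(!vapply(rows, is.null, TRUE)), "/", total, ")")
  }
  edits <- data.table::rbindlist(rows)
  edits[, sv_id := paste0("truth_", seq_len(.N))]
  edits[order(chrom, start)]
}

empty_truth <- function() {
  data.table::data.table(
    sv_class = character(), chrom = character(), start = integer(),
    end = integer(), sv_size = integer(), src_chrom = character(),
    src_pos = integer(), sv_id = character())
}

# Apply planned edits to the reference; returns the mutated DNAStringSet.
# Junction flanks are mutated per the profile's variability spec.
apply_svs <- function(reference, edits, profile, seed = 1L, donor = NULL) {
  set.seed(seed)
  out <- character(length(reference))
  names(out) <- names(reference)
  for (this_chrom in names(reference)) {
    refseq <- as.character(reference[[this_chrom]])
    sel <- which(edits[["chrom"]] == this_chrom)   # computed outside NSE
    if (length(sel) == 0L) { out[this_chrom] <- refseq; next }
    e <- edits[sel]
    e <- e[order(e$start)]
    pieces <- character(0)
    junctions <- numeric(0)     # positions in mutated coords
    cur <- 0L; outlen <- 0L
    add <- function(seq) {
      pieces[length(pieces) + 1L] <<- seq
      outlen <<- outlen + nchar(seq)
    }
    for (k in seq_len(nrow(e))) {
      s <- e$start[k]; en <- e$end[k]; cls <- e$sv_class[k]
      add(substr(refseq, cur + 1L, s))
      if (cls == "DEL") {
        junctions <- c(junctions, outlen)
        cur <- en
      } else if (cls == "INV") {
        junctions <- c(junctions, outlen)
        add(revcomp(substr(refseq, s + 1L, en)))
        junctions <- c(junctions, outlen)
        cur <- en
      } else if (cls == "DUP") {
        seg <- substr(refseq, s + 1L, en)
        add(seg)
        junctions <- c(junctions, outlen)
        add(seg)
        cur <- en
      } else if (cls == "BND") {              # transposition (copy-paste)
        seg <- substr(as.character(reference[[e$src_chrom[k]]]),
                      e$src_pos[k] + 1L, e$src_pos[k] + e$sv_size[k])
        junctions <- c(junctions, outlen)
        add(seg)
        junctions <- c(junctions, outlen)
        cur <- s
      } else if (cls == "INS") {
        seg <- if (!is.null(donor)) donor_fragment(donor, e$sv_size[k])
          else rand_dna(e$sv_size[k])
        junctions <- c(junctions, outlen)
        add(seg)
        junctions <- c(junctions, outlen)
        cur <- s
      }
    }
    add(substr(refseq, cur + 1L, nchar(refseq)))
    mutated <- paste(pieces, collapse = "")
    out[this_chrom] <- mutate_flanks(mutated, junctions, profile)
  }
  Biostrings::DNAStringSet(out)
}

donor_fragment <- function(donor, size) {
  i <- sample(length(donor), 1L)
  L <- Biostrings::width(donor)[i]
  if (L <= size) return(as.character(donor[[i]]))
  s <- sample(L - size, 1L)
  as.character(Biostrings::subseq(donor[[i]], s, s + size - 1L))
}

# SNP/indel mutation of windows centred on junction positions. The
# sequence is rebuilt in one pass (untouched stretches + mutated windows)
# so the cost is linear in sequence length.
mutate_flanks <- function(seq, junctions, profile) {
  if (length(junctions) == 0L) return(seq)
  w <- profile$flank_window
  half <- floor(w / 2)
  bases <- c("A", "C", "G", "T")
  js <- sort(unique(junctions))
  pieces <- character(0)
  cur <- 0L                               # 0-based consumed offset
  n <- nchar(seq)
  for (j in js) {
    lo <- max(cur, j - half); hi <- min(n, j + half)   # 0-based half-open
    if (hi <= lo) next
    pieces <- c(pieces, substr(seq, cur + 1L, lo))
    win <- strsplit(substr(seq, lo + 1L, hi), "")[[1]]
    snp <- runif(length(win)) < profile$flank_snp
    if (any(snp)) win[snp] <- sample(bases, sum(snp), replace = TRUE)
    if (runif(1) < profile$flank_indel) {
      len <- sample(profile$flank_indel_max, 1L)
      at <- sample(length(win), 1L)
      if (runif(1) < 0.5) {
        win <- win[-(at:min(at + len - 1L, length(win)))]      # deletion
      } else {
        win <- append(win, sample(bases, len, replace = TRUE), after = at)
      }
    }
    pieces <- c(pieces, paste(win, collapse = ""))
    cur <- hi
  }
  pieces <- c(pieces, substr(seq, cur + 1L, n))
  paste(pieces, collapse = "")
}

#' Simulate an SV genome with a ground-truth table
#'
#' Plants the profile's SVs at non-overlapping uniformly random positions
#' (optionally biased into repeat intervals), mutates each junction's
#' flanking window, and records every SV's breakends in reference
#' coordinates. Deletions, inversions and duplications carry two breakends;
#' insertions and transpositions carry one (the insertion site), with the
#' transposition's source locus kept as an auxiliary partner coordinate.
#'
#' @param reference a [Biostrings::DNAStringSet] or FASTA path
#' @param profile an [sv_profile()]
#' @param seed integer seed; output is reproducible
#' @param donor optional `DNAStringSet` of donor (e.g. viral) sequences for
#'   novel insertions; random sequence is used when absent
#' @return list with `genome` (mutated `DNAStringSet`) and `truth`
#'   (`data.table`: `sv_id`, `sv_class`, `chrom`, `pos1`, `pos2` (NA for
#'   single-breakend classes), `sv_size`, `zygosity`)
#' @export
simulate_sv_genome <- function(reference, profile = sv_profile(scale = 0.01),
                               seed = 1L, donor = NULL) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  edits <- plan_svs(reference, profile, seed = seed)
  genome <- apply_svs(reference, edits, profile, seed = seed + 1L, donor = donor)
  list(genome = genome, truth = truth_from_edits(edits))
}

truth_from_edits <- function(edits, zygosity = "hom") {
  if (nrow(edits) == 0L)
    return(data.table::data.table(sv_id = character(), sv_class = character(),
                                  chrom = character(), pos1 = integer(),
                                  pos2 = integer(), sv_size = integer(),
                                  zygosity = character()))
  two_bnd <- edits$sv_class %in% c("DEL", "INV", "DUP")
  data.table::data.table(
    sv_id = edits$sv_id, sv_class = edits$sv_class, chrom = edits$chrom,
    pos1 = edits$start,
    pos2 = data.table::fifelse(two_bnd, edits$end, NA_integer_),
    sv_size = edits$sv_size,
    zygosity = zygosity)
}

#' Simulate the nested mixed-zygosity genome trio
#'
#' Builds three genomes from one SV plan: genome A carries all SVs (100%),
#' genome B a random 83% subset, genome C a random 50% subset nested inside
#' B. Drawing reads from A, B and C in the ratio 1:1:2 yields homozygous
#' SVs (the 50% present in all three genomes), heterozygous SVs (33%,
#' present in A and B) and low-confidence SVs (17%, present only in A).
#'
#' @inheritParams simulate_sv_genome
#' @return list with `genomes` (named list A/B/C of `DNAStringSet`),
#'   `truth` (with per-SV `zygosity` in hom/het/low_conf), and
#'   `read_weights` (the 1:1:2 A/B/C read mix as fractions)
#' @export
simulate_mixed_zygosity <- function(reference, profile, seed = 1L,
                                    donor = NULL) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  edits <- plan_svs(reference, profile, seed = seed)
  n <- nrow(edits)
  set.seed(seed + 17L)
  idxB <- sort(sample(n, round(0.83 * n)))
  idxC <- sort(sample(idxB, round(0.50 * n)))
  genomes <- list(
    A = apply_svs(reference, edits, profile, seed = seed + 1L, donor = donor),
    B = apply_svs(reference, edits[idxB], profile, seed = seed + 2L, donor = donor),
    C = apply_svs(reference, edits[idxC], profile, seed = seed + 3L, donor = donor))
  zyg <- rep("low_conf", n)
  zyg[idxB] <- "het"
  zyg[idxC] <- "hom"
  truth <- truth_from_edits(edits)
  truth[, zygosity := zyg]
  list(genomes = genomes, truth = truth,
       read_weights = c(A = 0.25, B = 0.25, C = 0.5))
}

# ---- read simulation ------------------------------------------------------

#' Long-read error model
#'
#' Stand-in for a learned ONT error profile: log-normal read lengths and
#' independent per-base substitution/insertion/deletion rates. A
#' chimeric-read rate (two unrelated fragments joined end to end) is
#' available for artifact injection when building classifier training
#' sets; the default read recipe contains none.
#'
#' @param mean_length median read length in bases (default 8000)
#' @param length_sdlog log-normal sdlog of read length (default 0.4)
#' @param sub,ins,del per-base error rates (defaults 0.05, 0.025, 0.035)
#' @param chimera_rate fraction of chimeric reads (default 0)
#' @return list of class `read_model`
#' @export
read_model <- function(mean_length = 8000, length_sdlog = 0.4,
                       sub = 0.05, ins = 0.025, del = 0.035,
                       chimera_rate = 0) {
  stopifnot(sub >= 0, sub < 1, ins >= 0, ins < 1, del >= 0, del < 1,
            mean_length > 0)
  structure(list(mean_length = mean_length, length_sdlog = length_sdlog,
                 sub = sub, ins = ins, del = del,
                 chimera_rate = chimera_rate),
            class = "read_model")
}

BASES <- c("A", "C", "G", "T")

# vectorised per-read error injection
corrupt_read <- function(x, model) {
  if (model$sub == 0 && model$ins == 0 && model$del == 0) return(x)
  ch <- strsplit(x, "")[[1]]
  L <- length(ch)
  subs <- which(runif(L) < model$sub)
  if (length(subs) > 0L) ch[subs] <- sample(BASES, length(subs), replace = TRUE)
  reps <- (runif(L) >= model$del) + (runif(L) < model$ins)
  idx <- rep(seq_len(L), reps)
  out <- ch[idx]
  dup <- duplicated(idx)
  if (any(dup)) out[dup] <- sample(BASES, sum(dup), replace = TRUE)
  paste(out, collapse = "")
}

#' Simulate long reads from a genome
#'
#' Reads are sampled uniformly along the genome at the requested fold
#' coverage; per-base errors are injected at the model's rates; about half
#' the reads are reverse-complemented. In heterozygous mode a fraction of
#' reads is drawn from the unmutated reference instead of the SV genome.
#'
#' @param genome `DNAStringSet` (the SV genome) or FASTA path
#' @param depth target fold coverage (total bases / genome length)
#' @param model a [read_model()]
#' @param het_fraction fraction of reads drawn from `reference` (0 for a
#'   homozygous dataset, 0.5 for heterozygous)
#' @param reference unmutated `DNAStringSet`; required when
#'   `het_fraction > 0`
#' @param seed integer seed; output is byte-reproducible
#' @param fastq output FASTQ path
#' @param id_prefix read name prefix
#' @return invisibly, a `data.table` origin table: `read_id`, `source`
#'   (sv/ref), `chrom`, `start`, `end`, `strand`, `chimera`, `read_length`
#' @export
simulate_long_reads <- function(genome, depth, model = read_model(),
                                het_fraction = 0, reference = NULL,
                                seed = 1L, fastq = tempfile(fileext = ".fq"),
                                id_prefix = "read") {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (het_fraction > 0 && is.null(reference))
    stop("het_fraction > 0 requires the unmutated reference")
  glen <- sum(Biostrings::width(genome))
  if (glen == 0L) stop("empty genome")
  set.seed(seed)
  gchar <- as.character(genome)
  refchar <- if (!is.null(reference)) as.character(reference)
  mean_len <- model$mean_length * exp(model$length_sdlog^2 / 2)
  n <- max(1L, round(depth * glen / mean_len))
  lens <- pmax(200L, pmin(60000L,
    as.integer(round(rlnorm(n, log(model$mean_length), model$length_sdlog)))))
  from_ref <- runif(n) < het_fraction
  chimera <- runif(n) < model$chimera_rate
  minus <- runif(n) < 0.5

  gw <- nchar(gchar)                       # contig widths computed once
  rw <- if (!is.null(refchar)) nchar(refchar)
  draw1 <- function(src, w, len) {
    i <- if (length(src) == 1L) 1L else sample(length(src), 1L, prob = w)
    L <- w[i]
    len <- min(len, L)
    s <- floor(runif(1) * (L - len + 1L))
    list(seq = substr(src[[i]], s + 1L, s + len),
         chrom = names(src)[i], start = as.integer(s),
         end = as.integer(s + len))
  }

  seqs <- character(n)
  chroms <- character(n); starts <- integer(n); ends <- integer(n)
  for (i in seq_len(n)) {
    src <- if (from_ref[i]) refchar else gchar
    srcw <- if (from_ref[i]) rw else gw
    frag <- draw1(src, srcw, lens[i])
    if (chimera[i]) {
      frag2 <- draw1(src, srcw, max(200L, lens[i] %/% 2L))
      frag$seq <- paste0(substr(frag$seq, 1L, max(200L, lens[i] %/% 2L)),
                         frag2$seq)
    }
    seqs[i] <- corrupt_read(frag$seq, model)
    chroms[i] <- frag$chrom; starts[i] <- frag$start; ends[i] <- frag$end
  }
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  rids <- paste0(id_prefix, "_", seq_len(n))
  rlen <- nchar(seqs)
  con <- file(fastq, open = "wt")
  on.exit(close(con), add = TRUE)
  chunk <- 2000L
  for (s0 in seq(1L, n, by = chunk)) {
    ii <- s0:min(s0 + chunk - 1L, n)
    rec <- rbind(paste0("@", rids[ii]), seqs[ii], "+", strrep("I", rlen[ii]))
    writeLines(as.vector(rec), con)
  }
  invisible(data.table::data.table(
    read_id = rids, source = ifelse(from_ref, "ref", "sv"),
    chrom = chroms, start = starts, end = ends,
    strand = ifelse(minus, "-", "+"), chimera = chimera,
    read_length = rlen))
}

#' Label caller adjacencies against the simulation truth
#'
#' Builds classifier training examples from a caller run on simulated reads:
#' an adjacency is labelled true (1) when its primary breakend falls within
#' the evaluation window of a truth breakend, false (0) otherwise. A true
#' novel adjacency is defined by the existence of the junction, not by the
#' class assigned to it, so by default a real junction read as the wrong
#' class still counts as true; `class_aware = TRUE` additionally requires
#' the class to match.
#'
#' @param features raw feature matrix from [extract_features()] (rows
#'   aligned with `adjacencies`)
#' @param adjacencies the adjacency table the features were computed from
#' @param truth simulator truth table
#' @param error_distance window half-width in bases (default 400)
#' @param class_aware require matching SV class for a true label (default
#'   FALSE)
#' @return list with `x` (feature matrix), `y` (0/1 labels)
#' @export
generate_training_examples <- function(features, adjacencies, truth,
                                       error_distance = 400L,
                                       class_aware = FALSE) {
  adj <- data.table::as.data.table(adjacencies)
  if (nrow(adj) == 0L) stop("no candidate adjacencies to label")
  win <- truth_windows(truth, error_distance = error_distance)
  pts <- granges0(adj$chrom1, adj$pos1, adj$pos1 + 1L)
  ov <- GenomicRanges::findOverlaps(pts, win, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov)
  if (class_aware)
    q <- q[adj$sv_class[q] == win$sv_class[S4Vectors::subjectHits(ov)]]
  y <- integer(nrow(adj))
  y[unique(q)] <- 1L
  list(x = features, y = y)
}
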
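# Alignment ingestion: BLAST-like tabular ("outfmt 6"), PAF and SAM dialects
# are normalised into one segment table with 0-based half-open coordinates,
# read coordinates always in original read orientation, and numeric score
# fields present in every dialect.
#
# Segment table columns:
#   read_id, read_length, read_start, read_end, chrom, ref_start, ref_end,
#   strand, bitscore, e_value, identity_pct, mismatch_frac, gap_frac

SEG_COLS <- c("read_id", "read_length", "read_start", "read_end", "chrom",
              "ref_start", "ref_end", "strand", "bitscore", "e_value",
              "identity_pct", "mismatch_frac", "gap_frac")

empty_segments <- function() {
  data.table::data.table(
    read_id = character(), read_length = integer(), read_start = integer(),
    read_end = integer(), chrom = character(), ref_start = integer(),
    ref_end = integer(), strand = character(), bitscore = numeric(),
    e_value = numeric(), identity_pct = numeric(), mismatch_frac = numeric(),
    gap_frac = numeric())
}

#' Parse long-read alignments into per-read alignment profiles
#'
#' Reads an alignment file in one of three dialects and returns a normalised
#' segment table (one row per aligned block). Coordinates are 0-based
#' half-open in all dialects; read coordinates are in original read
#' orientation (minus-strand records are flipped on parsing). For dialects
#' carrying a CIGAR (SAM, PAF with `cg` tag), alignment records are split at
#' insertions/deletions of at least `split_gap` bases so that intra-alignment
#' SV junctions become segment boundaries, mirroring the fragmented local
#' alignments of a BLAST-like aligner.
#'
#' Score fields absent from a dialect are filled with documented surrogates:
#' PAF/SAM bitscore is the `AS` tag (fallback: matched bases / MAPQ) and the
#' E-value surrogate is `2^-bitscore`.
#'
#' @param path alignment file
#' @param dialect one of `"tabular6"` (BLAST outfmt 6: qseqid sseqid pident
#'   length mismatch gapopen qstart qend sstart send evalue bitscore),
#'   `"paf"`, `"sam"`
#' @param read_lengths named integer vector of read lengths (required for
#'   `tabular6`, which does not carry query length; see [read_lengths()])
#' @param split_gap minimum CIGAR indel length (bases) at which an alignment
#'   record is split into separate segments; default 50
#' @return a `data.table` of class `read_profiles` with one row per segment,
#'   sorted by read and read-start; attribute `contig_lengths` holds
#'   reference contig lengths when the dialect provides them (PAF, SAM)
#' @export
parse_alignments <- function(path, dialect = c("tabular6", "paf", "sam"),
                             read_lengths = NULL, split_gap = 50L) {
  dialect <- match.arg(dialect)
  parsed <- switch(dialect,
    tabular6 = parse_tabular6(path, read_lengths),
    paf      = parse_paf(path, split_gap),
    sam      = parse_sam(path, split_gap))
  segs <- parsed$segments
  cl <- attr(segs, "contig_lengths")
  segs <- segs[order(read_id, read_start)]
  bad <- segs[read_start >= read_end | ref_start >= ref_end]
  if (nrow(bad) > 0L) stop("degenerate alignment intervals in ", path)
  data.table::setattr(segs, "contig_lengths", cl)
  data.table::setattr(segs, "class", c("read_profiles", class(data.table::data.table())))
  segs
}

parse_tabular6 <- function(path, read_lens) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, col.names = cols, sep = "\t"),
    error = function(e) stop("malformed tabular6 file ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0L) return(list(segments = empty_segments()))
  bad <- which(!is.finite(dt$qstart) | !is.finite(dt$qend) |
                 !is.finite(dt$sstart) | !is.finite(dt$send))
  if (length(bad) > 0L)
    stop("malformed tabular6 record at line ", bad[1L], " of ", path)
  minus <- dt$sstart > dt$send
  segs <- data.table::data.table(
    read_id = as.character(dt$qseqid),
    read_start = as.integer(dt$qstart - 1L),
    read_end = as.integer(dt$qend),
    chrom = as.character(dt$sseqid),
    ref_start = as.integer(ifelse(minus, dt$send, dt$sstart) - 1L),
    ref_end = as.integer(ifelse(minus, dt$sstart, dt$send)),
    strand = ifelse(minus, "-", "+"),
    bitscore = as.numeric(dt$bitscore),
    e_value = as.numeric(dt$evalue),
    identity_pct = as.numeric(dt$pident),
    mismatch_frac = dt$mismatch / pmax(dt$length, 1L),
    gap_frac = dt$gapopen / pmax(dt$length, 1L))
  if (!is.null(read_lens)) {
    segs[, read_length := as.integer(read_lens[read_id])]
    if (anyNA(segs$read_length))
      stop("read_lengths missing for: ",
           paste(head(unique(segs$read_id[is.na(segs$read_length)])), collapse = ", "))
  } else {
    warning("tabular6 lacks read lengths; using max aligned end per read")
    segs[, read_length := max(read_end), by = read_id]
  }
  data.table::setcolorder(segs, SEG_COLS)
  list(segments = segs)
}

#' Write a segment table in BLAST tabular (outfmt 6) dialect
#'
#' Inverse of `parse_alignments(dialect = "tabular6")`; minus-strand segments
#' are written with the subject start greater than the subject end, per the
#' BLAST convention.
#'
#' @param segments a `read_profiles` segment table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_alignments <- function(segments, path) {
  s <- data.table::as.data.table(segments)
  minus <- s$strand == "-"
  aln_len <- s$read_end - s$read_start
  out <- data.table::data.table(
    qseqid = s$read_id,
    sseqid = s$chrom,
    pident = s$identity_pct,
    length = aln_len,
    mismatch = as.integer(round(s$mismatch_frac * aln_len)),
    gapopen = as.integer(round(s$gap_frac * aln_len)),
    qstart = s$read_start + 1L,
    qend = s$read_end,
    sstart = ifelse(minus, s$ref_end, s$ref_start + 1L),
    send = ifelse(minus, s$ref_start + 1L, s$ref_end),
    evalue = s$e_value,
    bitscore = s$bitscore)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---- PAF ------------------------------------------------------------------

paf_tag <- function(lines, tag) {
  patt <- paste0("\t", tag, ":[AifZ]:([^\t]+)")
  m <- regexpr(patt, lines, perl = TRUE)
  out <- rep(NA_character_, length(lines))
  hit <- m > 0L
  raw <- regmatches(lines, m)
  out[hit] <- sub(patt, "\\1", raw, perl = TRUE)
  out
}

parse_paf <- function(path, split_gap) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(list(segments = empty_segments()))
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:12)
  nf <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE))) + 1L
  if (any(nf < 12L))
    stop("malformed PAF record at line ", which(nf < 12L)[1L], " of ", path)
  dt <- data.table::data.table(
    read_id = fields[[1]], qlen = as.integer(fields[[2]]),
    qs = as.integer(fields[[3]]), qe = as.integer(fields[[4]]),
    strand = fields[[5]], chrom = fields[[6]], tlen = as.integer(fields[[7]]),
    ts = as.integer(fields[[8]]), te = as.integer(fields[[9]]),
    nmatch = as.integer(fields[[10]]), block = as.integer(fields[[11]]),
    mapq = as.integer(fields[[12]]))
  as_tag <- suppressWarnings(as.numeric(paf_tag(lines, "AS")))
  cg <- paf_tag(lines, "cg")
  dt[, bitscore := ifelse(is.finite(as_tag), as_tag, as.numeric(nmatch))]
  contig_lengths <- dt[, .(len = max(tlen)), by = chrom]
  cl <- setNames(contig_lengths$len, contig_lengths$chrom)

  pieces <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    r <- dt[i]
    if (!is.na(cg[i])) {
      pieces[[i]] <- cigar_segments(cg[i], r$qs, r$qe, r$ts, r$te, r$strand,
                                    qlen = r$qlen, split_gap = split_gap,
                                    nmatch = r$nmatch, bitscore = r$bitscore,
                                    clip_mode = "paf")
    } else {
      # no CIGAR: derive mismatch/gap content from PAF spans exactly
      qspan <- r$qe - r$qs; tspan <- r$te - r$ts
      gaps <- max(0L, 2L * r$block - qspan - tspan)
      mism <- max(0L, qspan + tspan - r$block - r$nmatch)
      pieces[[i]] <- data.table::data.table(
        read_start = r$qs, read_end = r$qe, ref_start = r$ts, ref_end = r$te,
        nmatch = r$nmatch, block = r$block, mism = mism, gaps = gaps)
    }
    set(pieces[[i]], j = "row", value = i)
  }
  p <- data.table::rbindlist(pieces)
  segs <- data.table::data.table(
    read_id = dt$read_id[p$row],
    read_length = dt$qlen[p$row],
    read_start = p$read_start, read_end = p$read_end,
    chrom = dt$chrom[p$row],
    ref_start = p$ref_start, ref_end = p$ref_end,
    strand = dt$strand[p$row],
    bitscore = dt$bitscore[p$row] *
      (p$read_end - p$read_start) / pmax(dt$qe[p$row] - dt$qs[p$row], 1L),
    identity_pct = 100 * p$nmatch / pmax(p$block, 1L),
    mismatch_frac = p$mism / pmax(p$block, 1L),
    gap_frac = p$gaps / pmax(p$block, 1L))
  segs[, e_value := 2^(-pmin(bitscore, 996))]
  data.table::setcolorder(segs, SEG_COLS)
  out <- list(segments = segs)
  attr(out$segments, "contig_lengths") <- cl
  out
}

# Split one aligned record at large CIGAR indels. Offsets u (query, in
# alignment orientation) and x (target) start at 0; sub-pieces are mapped
# back to original-strand read coordinates. Identity-type stats are exact
# for gaps within a piece and apportioned proportionally for mismatches
# (CIGAR "M" does not distinguish match from mismatch).
cigar_segments <- function(cigar, qs, qe, ts, te, strand, qlen, split_gap,
                           nmatch, bitscore, clip_mode = c("paf", "sam")) {
  clip_mode <- match.arg(clip_mode)
  ops_len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops_chr <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  u <- 0L; x <- 0L
  pu <- 0L; px <- 0L           # current piece start offsets
  piece_m <- 0L; piece_gap <- 0L; piece_x <- 0L
  res <- list()
  flush <- function() {
    if (u > pu && x > px)
      res[[length(res) + 1L]] <<- c(pu, u, px, x, piece_m, piece_gap, piece_x)
    pu <<- u; px <<- x; piece_m <<- 0L; piece_gap <<- 0L; piece_x <<- 0L
  }
  lead_clip <- 0L
  seen_aln <- FALSE
  for (k in seq_along(ops_chr)) {
    op <- ops_chr[k]; n <- ops_len[k]
    if (op %in% c("S", "H")) {
      if (!seen_aln) lead_clip <- lead_clip + n
      next
    }
    seen_aln <- TRUE
    if (op %in% c("M", "=")) { u <- u + n; x <- x + n; piece_m <- piece_m + n
    } else if (op == "X") { u <- u + n; x <- x + n; piece_m <- piece_m + n
      piece_x <- piece_x + n
    } else if (op == "I") {
      if (n >= split_gap) { flush(); u <- u + n; pu <- u
      } else { u <- u + n; piece_gap <- piece_gap + n }
    } else if (op %in% c("D", "N")) {
      if (n >= split_gap) { flush(); x <- x + n; px <- x
      } else { x <- x + n; piece_gap <- piece_gap + n }
    }
  }
  flush()
  if (length(res) == 0L) return(empty_piece())
  m <- do.call(rbind, res)
  aln_q0 <- if (clip_mode == "paf") {
    if (strand == "+") qs else qlen - qe   # query offset of alignment start,
  } else lead_clip                         # in alignment orientation
  q_lo <- aln_q0 + m[, 1]; q_hi <- aln_q0 + m[, 2]
  if (strand == "+") {
    read_start <- q_lo; read_end <- q_hi
  } else {
    read_start <- qlen - q_hi; read_end <- qlen - q_lo
  }
  total_m <- sum(m[, 5])
  # apportion whole-record matched bases over pieces; X ops counted exactly
  mism_known <- sum(m[, 7]) > 0L
  piece_mism <- if (mism_known) m[, 7]
    else if (is.finite(nmatch)) pmax(0, m[, 5] * (1 - nmatch / max(total_m, 1L)))
    else rep(0, nrow(m))
  block <- m[, 5] + m[, 6]   # matched/mismatched bases + small gaps
  data.table::data.table(
    read_start = as.integer(read_start), read_end = as.integer(read_end),
    ref_start = as.integer(ts + m[, 3]), ref_end = as.integer(ts + m[, 4]),
    nmatch = as.numeric(m[, 5] - piece_mism), block = as.numeric(block),
    mism = as.numeric(piece_mism), gaps = as.numeric(m[, 6]))
}

empty_piece <- function() {
  data.table::data.table(read_start = integer(), read_end = integer(),
                         ref_start = integer(), ref_end = integer(),
                         nmatch = numeric(), block = numeric(),
                         mism = numeric(), gaps = numeric())
}

# ---- SAM ------------------------------------------------------------------

parse_sam <- function(path, split_gap) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  cl <- NULL
  if (length(sq) > 0L) {
    nm <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    cl <- setNames(ln, nm)
  }
  if (length(body) == 0L) return(list(segments = empty_segments()))
  fields <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = 1:10)
  flag <- as.integer(fields[[2]])
  keep <- !bitwAnd(flag, 4L) & !bitwAnd(flag, 256L)  # mapped, not secondary
  if (!any(keep)) return(list(segments = empty_segments()))
  body <- body[keep]
  qname <- fields[[1]][keep]; flag <- flag[keep]
  rname <- fields[[3]][keep]
  pos <- as.integer(fields[[4]][keep])
  mapq <- as.integer(fields[[5]][keep])
  cigar <- fields[[6]][keep]
  if (any(cigar == "*"))
    stop("malformed SAM: mapped record without CIGAR at line ",
         which(cigar == "*")[1L])
  as_tag <- suppressWarnings(as.numeric(paf_tag(body, "AS")))
  nm_tag <- suppressWarnings(as.integer(paf_tag(body, "NM")))
  strand <- ifelse(bitwAnd(flag, 16L), "-", "+")

  pieces <- vector("list", length(body))
  qlens <- integer(length(body))
  for (i in seq_along(body)) {
    ol <- as.integer(regmatches(cigar[i], gregexpr("[0-9]+", cigar[i]))[[1]])
    oc <- regmatches(cigar[i], gregexpr("[MIDNSHP=X]", cigar[i]))[[1]]
    qlen <- sum(ol[oc %in% c("M", "I", "S", "H", "=", "X")])
    qlens[i] <- qlen
    bs <- if (is.finite(as_tag[i])) as_tag[i]
      else sum(ol[oc %in% c("M", "=", "X")])  # aligned bases fallback
    pieces[[i]] <- cigar_segments(cigar[i], NA, NA, pos[i] - 1L, NA, strand[i],
                                  qlen = qlen, split_gap = split_gap,
                                  nmatch = NA_real_, bitscore = bs,
                                  clip_mode = "sam")
    if (nrow(pieces[[i]]) > 0L) {
      # without =/X ops, estimate per-piece mismatches from the NM tag
      if (all(pieces[[i]]$mism == 0) && is.finite(nm_tag[i])) {
        small_gaps <- sum(pieces[[i]]$gaps)
        mism_tot <- max(0L, nm_tag[i] - small_gaps)
        w <- pieces[[i]]$nmatch / max(sum(pieces[[i]]$nmatch), 1)
        pieces[[i]][, mism := mism_tot * w]
        pieces[[i]][, nmatch := nmatch - mism]
      }
      set(pieces[[i]], j = "row", value = i)
      set(pieces[[i]], j = "bs", value = bs)
    }
  }
  p <- data.table::rbindlist(pieces[vapply(pieces, nrow, 1L) > 0L])
  segs <- data.table::data.table(
    read_id = qname[p$row],
    read_length = qlens[p$row],
    read_start = p$read_start, read_end = p$read_end,
    chrom = rname[p$row],
    ref_start = p$ref_start, ref_end = p$ref_end,
    strand = strand[p$row],
    bitscore = p$bs * (p$read_end - p$read_start) /
      pmax(vapply(split(p$read_end - p$read_start, p$row), sum, 1)[as.character(p$row)], 1),
    identity_pct = 100 * p$nmatch / pmax(p$block, 1),
    mismatch_frac = p$mism / pmax(p$block, 1),
    gap_frac = p$gaps / pmax(p$block, 1))
  segs[, e_value := 2^(-pmin(bitscore, 996))]
  if (is.finite(max(mapq)) && all(!is.finite(segs$bitscore)))
    segs[, bitscore := as.numeric(mapq[p$row])]
  data.table::setcolorder(segs, SEG_COLS)
  out <- list(segments = segs)
  attr(out$segments, "contig_lengths") <- cl
  out
}

# ---- overlap resolution ---------------------------------------------------

#' Resolve overlapping alignments within each read
#'
#' When two alignment segments of one read overlap on read coordinates the
#' overlap is trimmed from the lower-bitscore segment; a segment fully
#' contained (on the read) in a higher-scoring one is dropped. Reference
#' coordinates of a trimmed segment are shrunk proportionally (no per-base
#' alignment is available in tabular dialects). Ties on bitscore are broken
#' by smaller `ref_start`, then lexicographically smaller `chrom`, so the
#' result is deterministic. The operation is idempotent.
#'
#' @param segments a `read_profiles` segment table (any number of reads)
#' @return segment table of the same shape with pairwise non-overlapping
#'   read intervals within each read, sorted by read and read-start
#' @export
resolve_overlaps <- function(segments) {
  s <- data.table::as.data.table(segments)
  if (nrow(s) == 0L) return(segments)
  cl <- attr(segments, "contig_lengths")
  nseg <- s[, .N, by = read_id]
  multi <- nseg$read_id[nseg$N > 1L]
  singles <- s[!read_id %in% multi]
  if (length(multi) > 0L) {
    resolved <- s[read_id %in% multi, resolve_one_read(.SD), by = read_id]
  } else resolved <- NULL
  out <- data.table::rbindlist(list(singles, resolved), use.names = TRUE)
  out <- out[order(read_id, read_start)]
  data.table::setattr(out, "contig_lengths", cl)
  data.table::setattr(out, "class", c("read_profiles", class(data.table::data.table())))
  out
}

resolve_one_read <- function(sd) {
  ord <- order(-sd$bitscore, sd$ref_start, sd$chrom, sd$read_start)
  kept <- list()
  cover <- matrix(numeric(0), ncol = 2)   # kept read intervals
  for (i in ord) {
    rs <- sd$read_start[i]; re <- sd$read_end[i]
    # subtract covered intervals; keep longest remaining contiguous piece
    free <- subtract_intervals(rs, re, cover)
    if (nrow(free) == 0L) next
    len <- free[, 2] - free[, 1]
    j <- which.max(len)           # ties: which.max takes leftmost
    if (len[j] <= 0L) next
    new_rs <- free[j, 1]; new_re <- free[j, 2]
    seg <- sd[i]
    if (new_rs != rs || new_re != re) {
      L <- re - rs
      ref_len <- seg$ref_end - seg$ref_start
      f1 <- (new_rs - rs) / L; f2 <- (new_re - rs) / L
      if (seg$strand == "+") {
        nrs <- seg$ref_start + round(f1 * ref_len)
        nre <- seg$ref_start + round(f2 * ref_len)
      } else {
        nrs <- seg$ref_start + round((1 - f2) * ref_len)
        nre <- seg$ref_start + round((1 - f1) * ref_len)
      }
      if (nre <= nrs) nre <- nrs + 1L
      seg$ref_start <- as.integer(nrs); seg$ref_end <- as.integer(nre)
      seg$read_start <- as.integer(new_rs); seg$read_end <- as.integer(new_re)
      seg$bitscore <- seg$bitscore * (new_re - new_rs) / L
    }
    kept[[length(kept) + 1L]] <- seg
    cover <- rbind(cover, c(new_rs, new_re))
  }
  out <- data.table::rbindlist(kept)
  out[order(read_start)]
}

# All maximal sub-intervals of [s, e) not covered by the rows of `cover`.
subtract_intervals <- function(s, e, cover) {
  if (nrow(cover) == 0L) return(matrix(c(s, e), ncol = 2))
  cover <- cover[order(cover[, 1]), , drop = FALSE]
  free <- matrix(numeric(0), ncol = 2)
  cur <- s
  for (k in seq_len(nrow(cover))) {
    a <- cover[k, 1]; b <- cover[k, 2]
    if (b <= cur) next
    if (a >= e) break
    if (a > cur) free <- rbind(free, c(cur, min(a, e)))
    cur <- max(cur, b)
    if (cur >= e) break
  }
  if (cur < e) free <- rbind(free, c(cur, e))
  free
}

#' Per-read profile summary
#'
#' @param segments a `read_profiles` segment table (ideally after
#'   [resolve_overlaps()])
#' @return `data.table` with one row per read: `read_id`, `read_length`,
#'   `n_segments`, `aligned_bases`, `aligned_fraction`, `n_chroms`
#' @export
profile_stats <- function(segments) {
  s <- data.table::as.data.table(segments)
  s[, .(read_length = read_length[1L],
        n_segments = .N,
        aligned_bases = sum(read_end - read_start),
        aligned_fraction = min(1, sum(read_end - read_start) / read_length[1L]),
        n_chroms = data.table::uniqueN(chrom)),
    by = read_id]
}
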
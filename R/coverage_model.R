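# Breakend read-depth model: supporting (B) and opposing (O) read counts per
# breakend, a sampled genome-wide depth distribution, and the robust outlier
# threshold U used to discard artifactual high-depth breakends.

#' Robust upper outlier threshold for breakend read depth
#'
#' Computes
#' \deqn{U = 4 k \frac{1}{n} \sum_i |x_i - m(X)| + m(X), \quad k = 1.4826,}
#' i.e. the median plus four times the scaled mean absolute deviation around
#' the median (MAD in the mean-deviation sense; the mean is used rather than
#' the median of deviations to avoid jumps caused by discontinuous integer
#' medians). Breakends whose supporting-read count exceeds U are treated as
#' repeat-driven artifacts.
#'
#' @param depths integer vector of sampled read depths (a `depth_sample`
#'   object is also accepted)
#' @param k scale factor, default 1.4826 (consistency with the normal
#'   standard deviation)
#' @param multiplier number of MADs above the median, default 4
#' @return the threshold U (single numeric)
#' @export
depth_outlier_threshold <- function(depths, k = 1.4826, multiplier = 4) {
  if (inherits(depths, "depth_sample")) depths <- depths$depths
  n <- length(depths)
  if (n < 2L) stop("need at least 2 sampled depths to estimate a threshold")
  m <- median(depths)
  multiplier * k * mean(abs(depths - m)) + m
}

#' Sample the genome-wide read-depth distribution
#'
#' Chooses `n` uniformly random genomic positions (outside any excluded
#' region) and counts the distinct reads whose alignments span each
#' position. The resulting distribution approximates the read depth across
#' the genome and feeds [depth_outlier_threshold()].
#'
#' @param profiles segment table (after [resolve_overlaps()])
#' @param contig_lengths named integer vector of contig lengths; defaults to
#'   the `contig_lengths` attribute of `profiles`, falling back to maximum
#'   aligned coordinates
#' @param n number of positions to sample (default 10000)
#' @param seed integer seed; sampling is reproducible under a fixed seed
#' @param exclude optional `GRanges` of regions to avoid
#' @return object of class `depth_sample`: list with `n`, `depths`,
#'   `median`, `mad` (scaled mean absolute deviation around the median)
#' @export
sample_depth_distribution <- function(profiles, contig_lengths = NULL,
                                      n = 10000L, seed = 1L, exclude = NULL) {
  if (n < 1L) stop("n must be positive")
  s <- data.table::as.data.table(profiles)
  if (is.null(contig_lengths)) contig_lengths <- attr(profiles, "contig_lengths")
  if (is.null(contig_lengths)) {
    cl <- s[, .(len = max(ref_end)), by = chrom]
    contig_lengths <- setNames(cl$len, cl$chrom)
  }
  set.seed(seed)
  chroms <- sample(names(contig_lengths), n, replace = TRUE,
                   prob = contig_lengths / sum(contig_lengths))
  pos <- floor(runif(n) * contig_lengths[chroms])
  if (!is.null(exclude)) {
    for (it in 1:50) {
      bad <- in_excluded(chroms, pos, exclude)
      if (!any(bad)) break
      chroms[bad] <- sample(names(contig_lengths), sum(bad), replace = TRUE,
                            prob = contig_lengths / sum(contig_lengths))
      pos[bad] <- floor(runif(sum(bad)) * contig_lengths[chroms[bad]])
    }
    if (any(in_excluded(chroms, pos, exclude)))
      stop("could not sample positions outside excluded regions")
  }
  depths <- depth_at(s, chroms, pos)
  m <- median(depths)
  structure(list(n = n, depths = depths, median = m,
                 mad = 1.4826 * mean(abs(depths - m))),
            class = "depth_sample")
}

#' @export
print.depth_sample <- function(x, ...) {
  cat("Sampled read-depth distribution:", x$n, "positions\n")
  cat("  median depth:", x$median, "  MAD:", round(x$mad, 3),
      "  U:", round(depth_outlier_threshold(x), 3), "\n")
  invisible(x)
}

# distinct reads spanning each 0-based position
depth_at <- function(segments, chroms, pos) {
  if (nrow(segments) == 0L) return(rep(0L, length(pos)))
  seg_gr <- granges0(segments$chrom, segments$ref_start, segments$ref_end)
  pts <- granges0(chroms, pos, pos + 1L)
  ov <- GenomicRanges::findOverlaps(pts, seg_gr, ignore.strand = TRUE)
  if (length(ov) == 0L) return(rep(0L, length(pos)))
  dt <- data.table::data.table(q = S4Vectors::queryHits(ov),
                               read = segments$read_id[S4Vectors::subjectHits(ov)])
  cnt <- dt[, .(d = data.table::uniqueN(read)), by = q]
  out <- rep(0L, length(pos))
  out[cnt$q] <- cnt$d
  out
}

#' Count supporting and opposing reads at call breakends
#'
#' B is the number of distinct SV-associated reads in the call's cluster;
#' O is the number of distinct other reads whose alignments span the primary
#' breakend position. The breakend read ratio B/(B+O) estimates zygosity.
#'
#' @param calls call table from [cluster_adjacencies()]
#' @param profiles segment table used for calling
#' @return call table with columns `O`, `ratio` added
#' @export
count_breakend_depth <- function(calls, profiles) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) {
    calls[, `:=`(O = integer(), ratio = numeric())]
    return(calls[])
  }
  s <- data.table::as.data.table(profiles)
  seg_gr <- granges0(s$chrom, s$ref_start, s$ref_end)
  pts <- granges0(calls$chrom1, calls$pos1, calls$pos1 + 1L)
  ov <- GenomicRanges::findOverlaps(pts, seg_gr, ignore.strand = TRUE)
  O <- integer(nrow(calls))
  if (length(ov) > 0L) {
    dt <- data.table::data.table(q = S4Vectors::queryHits(ov),
                                 read = s$read_id[S4Vectors::subjectHits(ov)])
    sup <- calls$supporting_reads
    spans <- split(dt$read, dt$q)
    for (qi in names(spans)) {
      i <- as.integer(qi)
      O[i] <- length(setdiff(unique(spans[[qi]]), sup[[i]]))
    }
  }
  calls[, O := O]
  calls[, ratio := B / (B + O)]
  calls[]
}

#' Remove breakends with outlying supporting-read depth
#'
#' A breakend with more supporting reads than the outlier threshold U is
#' considered an artifact of repetitive sequence and removed; the
#' comparison is strict (`B > U` removed, `B == U` retained).
#'
#' @param calls call table with a `B` column
#' @param U threshold from [depth_outlier_threshold()]
#' @return filtered call table
#' @export
filter_outlier_breakends <- function(calls, U) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) return(calls)
  calls[B <= U]
}
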
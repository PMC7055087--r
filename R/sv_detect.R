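# Split-read novel-adjacency detection and classification.
#
# A novel adjacency is a junction between two reference coordinates that are
# adjacent in the sample but not in the reference. Each junction between two
# consecutive alignment segments of a read is classified by the relation of
# its read-space gap and reference-space gap, computed through the two
# "junction coordinates":
#   j1 = reference coordinate of the first segment at its read-right end
#   j2 = reference coordinate of the second segment at its read-left end
# For a plus-strand segment the read-right end is ref_end and the read-left
# end is ref_start; for a minus-strand segment it is the reverse. This makes
# every classification rule strand-symmetric.

SV_CLASSES <- c("DEL", "INS", "DUP", "INV", "BND")

#' Detect novel adjacencies in read alignment profiles
#'
#' Scans each read's overlap-resolved segments (sorted by read coordinate)
#' and classifies each qualifying junction:
#'
#' * different chromosomes -> `BND` (translocation);
#' * strand flip -> `INV` (junction coordinates give the two inversion
#'   boundaries);
#' * same chromosome/strand with reference gap >= `min_sv_size` and read gap
#'   < `min_read_gap` -> `DEL`;
#' * read gap >= `min_sv_size` with |reference gap| < `min_read_gap` ->
#'   `INS` (novel sequence);
#' * reference gap <= -`min_sv_size` (the second segment re-enters at or
#'   before the first segment's end, read order preserved) -> `DUP` (tandem);
#' * a three-segment pattern with concordant outer flanks and a middle
#'   segment mapping elsewhere (other chromosome or >= `far_dist` away) ->
#'   `BND` transposition (inserted sequence found elsewhere in the
#'   reference).
#'
#' When a junction qualifies through both its read gap and reference gap the
#' larger gap decides the class (ties -> DEL). Reads with no qualifying
#' junction yield no rows (normal reads).
#'
#' @param profiles segment table from [resolve_overlaps()]
#' @param min_sv_size minimum SV size in bases (default 50, the conventional
#'   lower bound of a structural variant)
#' @param min_read_gap maximum tolerated gap on the non-qualifying axis
#'   (default 50)
#' @param far_dist minimum reference distance for a transposition source
#'   (default 10 kb)
#' @return `data.table` with one row per adjacency: `read_id`, `sv_class`
#'   (DEL/INS/DUP/INV/BND), `bnd_subtype` (translocation/transposition for
#'   BND, NA otherwise), `chrom1`, `pos1`, `chrom2`, `pos2` (partner breakend
#'   or NA for single-breakend classes where no partner exists), `sv_size`,
#'   `inserted_len`, `read_gap`, `ref_gap`, and flanking segment indices
#'   `up_idx`, `dn_idx` into `profiles`
#' @export
detect_adjacencies <- function(profiles, min_sv_size = 50L, min_read_gap = 50L,
                               far_dist = 10000L) {
  s <- data.table::as.data.table(profiles)
  if (nrow(s) == 0L) return(empty_adjacencies())
  s <- s[order(read_id, read_start)]
  s[, seg_idx := .I]
  multi <- s[, .N, by = read_id][N >= 2L, read_id]
  if (length(multi) == 0L) return(empty_adjacencies())
  adj <- s[read_id %in% multi,
           detect_one_read(.SD, min_sv_size, min_read_gap, far_dist),
           by = read_id]
  if (nrow(adj) == 0L) return(empty_adjacencies())
  adj[]
}

empty_adjacencies <- function() {
  data.table::data.table(
    read_id = character(), sv_class = character(), bnd_subtype = character(),
    chrom1 = character(), pos1 = integer(), chrom2 = character(),
    pos2 = integer(), sv_size = integer(), inserted_len = integer(),
    read_gap = integer(), ref_gap = integer(), up_idx = integer(),
    dn_idx = integer())
}

# junction coordinate helpers (0-based)
j_right <- function(sd, i) if (sd$strand[i] == "+") sd$ref_end[i] else sd$ref_start[i]
j_left  <- function(sd, i) if (sd$strand[i] == "+") sd$ref_start[i] else sd$ref_end[i]

detect_one_read <- function(sd, min_sv_size, min_read_gap, far_dist) {
  n <- nrow(sd)
  out <- list()
  consumed <- rep(FALSE, n - 1L)   # junctions explained by a triple pattern

  # transposition: flank - distant middle - flank
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      a <- i; b <- i + 1L; c <- i + 2L
      if (consumed[a] || consumed[b]) next
      if (sd$chrom[a] != sd$chrom[c] || sd$strand[a] != sd$strand[c]) next
      ja <- j_right(sd, a); jc <- j_left(sd, c)
      outer_gap <- if (sd$strand[a] == "+") jc - ja else ja - jc
      if (abs(outer_gap) >= min_sv_size) next   # outer flanks not concordant
      mid_far <- sd$chrom[b] != sd$chrom[a] ||
        min(abs(sd$ref_start[b] - ja), abs(sd$ref_end[b] - ja)) >= far_dist
      if (!mid_far) next
      out[[length(out) + 1L]] <- data.table::data.table(
        sv_class = "BND", bnd_subtype = "transposition",
        chrom1 = sd$chrom[a], pos1 = as.integer(ja),
        chrom2 = sd$chrom[b], pos2 = as.integer(sd$ref_start[b]),
        sv_size = as.integer(sd$read_end[b] - sd$read_start[b]),
        inserted_len = as.integer(sd$read_end[b] - sd$read_start[b]),
        read_gap = as.integer(sd$read_start[b] - sd$read_end[a]),
        ref_gap = as.integer(outer_gap),
        up_idx = sd$seg_idx[a], dn_idx = sd$seg_idx[c])
      consumed[a] <- TRUE; consumed[b] <- TRUE
    }
  }

  for (i in seq_len(n - 1L)) {
    if (consumed[i]) next
    a <- i; b <- i + 1L
    read_gap <- sd$read_start[b] - sd$read_end[a]
    j1 <- j_right(sd, a); j2 <- j_left(sd, b)
    if (sd$chrom[a] != sd$chrom[b]) {
      out[[length(out) + 1L]] <- data.table::data.table(
        sv_class = "BND", bnd_subtype = "translocation",
        chrom1 = sd$chrom[a], pos1 = as.integer(j1),
        chrom2 = sd$chrom[b], pos2 = as.integer(j2),
        sv_size = NA_integer_, inserted_len = NA_integer_,
        read_gap = as.integer(read_gap), ref_gap = NA_integer_,
        up_idx = sd$seg_idx[a], dn_idx = sd$seg_idx[b])
      next
    }
    if (sd$strand[a] != sd$strand[b]) {
      # inversion boundary junction: j1 and j2 are the two inversion edges
      size <- abs(j2 - j1)
      if (size < min_sv_size) next
      out[[length(out) + 1L]] <- data.table::data.table(
        sv_class = "INV", bnd_subtype = NA_character_,
        chrom1 = sd$chrom[a], pos1 = as.integer(min(j1, j2)),
        chrom2 = sd$chrom[a], pos2 = as.integer(max(j1, j2)),
        sv_size = as.integer(size), inserted_len = NA_integer_,
        read_gap = as.integer(read_gap), ref_gap = NA_integer_,
        up_idx = sd$seg_idx[a], dn_idx = sd$seg_idx[b])
      next
    }
    ref_gap <- if (sd$strand[a] == "+") j2 - j1 else j1 - j2
    del_ok <- ref_gap >= min_sv_size && read_gap < min_read_gap
    ins_ok <- read_gap >= min_sv_size && abs(ref_gap) < min_read_gap
    dup_ok <- ref_gap <= -min_sv_size && read_gap < min_read_gap
    if (del_ok && ins_ok) {           # both qualify: larger gap wins, tie DEL
      if (read_gap > ref_gap) { del_ok <- FALSE } else ins_ok <- FALSE
    }
    if (del_ok) {
      out[[length(out) + 1L]] <- data.table::data.table(
        sv_class = "DEL", bnd_subtype = NA_character_,
        chrom1 = sd$chrom[a], pos1 = as.integer(min(j1, j2)),
        chrom2 = sd$chrom[a], pos2 = as.integer(max(j1, j2)),
        sv_size = as.integer(ref_gap), inserted_len = NA_integer_,
        read_gap = as.integer(read_gap), ref_gap = as.integer(ref_gap),
        up_idx = sd$seg_idx[a], dn_idx = sd$seg_idx[b])
    } else if (ins_ok) {
      out[[length(out) + 1L]] <- data.table::data.table(
        sv_class = "INS", bnd_subtype = NA_character_,
        chrom1 = sd$chrom[a], pos1 = as.integer(j1),
        chrom2 = NA_character_, pos2 = NA_integer_,
        sv_size = as.integer(read_gap), inserted_len = as.integer(read_gap),
        read_gap = as.integer(read_gap), ref_gap = as.integer(ref_gap),
        up_idx = sd$seg_idx[a], dn_idx = sd$seg_idx[b])
    } else if (dup_ok) {
      out[[length(out) + 1L]] <- data.table::data.table(
        sv_class = "DUP", bnd_subtype = NA_character_,
        chrom1 = sd$chrom[a], pos1 = as.integer(min(j1, j2)),
        chrom2 = sd$chrom[a], pos2 = as.integer(max(j1, j2)),
        sv_size = as.integer(-ref_gap), inserted_len = NA_integer_,
        read_gap = as.integer(read_gap), ref_gap = as.integer(ref_gap),
        up_idx = sd$seg_idx[a], dn_idx = sd$seg_idx[b])
    }
  }
  if (length(out) == 0L) return(empty_adjacencies()[, !"read_id"])
  data.table::rbindlist(out)
}

#' Cluster per-read adjacencies into candidate SV calls
#'
#' Adjacencies of the same class on the same chromosome whose primary
#' breakends lie within `merge_distance` of each other (single-linkage
#' chaining along the sorted positions) are merged into one call. The
#' representative breakend is the median member position; supporting reads
#' are the union of member reads. Calls supported by fewer than
#' `min_support` distinct reads are dropped (default 1: single-read
#' junctions are kept and left to the confidence score; raise to 2 for
#' clinical-style minimum breakend coverage).
#'
#' @param adjacencies output of [detect_adjacencies()]
#' @param merge_distance maximum breakend distance for merging (default 400,
#'   matching the benchmark error distance)
#' @param min_support minimum distinct supporting reads per call (default 1)
#' @return `data.table` of calls: `id`, `sv_class`, `bnd_subtype`, `chrom1`,
#'   `pos1`, `chrom2`, `pos2`, `sv_size`, `n_adj`, `B` (supporting reads),
#'   `supporting_reads` (list column), `cluster_id`; the input adjacency
#'   table annotated with `cluster_id` is returned as attribute
#'   `"adjacencies"`
#' @export
cluster_adjacencies <- function(adjacencies, merge_distance = 400L,
                                min_support = 1L) {
  adj <- data.table::copy(data.table::as.data.table(adjacencies))
  if (nrow(adj) == 0L) {
    return(structure(empty_calls(), adjacencies = adj))
  }
  adj[, grp := paste(sv_class, data.table::fifelse(is.na(bnd_subtype), "", bnd_subtype), chrom1)]
  data.table::setorder(adj, grp, pos1)
  adj[, new_cl := c(1L, as.integer(diff(pos1) > merge_distance)), by = grp]
  adj[, cluster_id := cumsum(new_cl)]
  adj[, c("grp", "new_cl") := NULL]
  calls <- adj[, .(
    sv_class = sv_class[1L],
    bnd_subtype = bnd_subtype[1L],
    chrom1 = chrom1[1L],
    pos1 = as.integer(round(median(pos1))),
    chrom2 = chrom2[1L],
    pos2 = if (all(is.na(pos2))) NA_integer_ else
      as.integer(round(median(pos2, na.rm = TRUE))),
    sv_size = if (all(is.na(sv_size))) NA_integer_ else
      as.integer(round(median(sv_size, na.rm = TRUE))),
    n_adj = .N,
    B = data.table::uniqueN(read_id),
    supporting_reads = list(unique(read_id))
  ), by = cluster_id]
  calls <- calls[B >= min_support]
  calls[, id := paste0(sv_class, ".", seq_len(.N))]
  data.table::setcolorder(calls, c("id", "sv_class", "bnd_subtype", "chrom1",
                                   "pos1", "chrom2", "pos2", "sv_size",
                                   "n_adj", "B", "supporting_reads",
                                   "cluster_id"))
  structure(calls[], adjacencies = adj[])
}

empty_calls <- function() {
  data.table::data.table(
    id = character(), sv_class = character(), bnd_subtype = character(),
    chrom1 = character(), pos1 = integer(), chrom2 = character(),
    pos2 = integer(), sv_size = integer(), n_adj = integer(), B = integer(),
    supporting_reads = list(), cluster_id = integer())
}

#' Estimate zygosity from the breakend read ratio
#'
#' The breakend read ratio B/(B+O) is ~1 for a homozygous variant (every
#' spanning read supports the junction) and ~0.5 for a heterozygous one.
#'
#' @param calls call table carrying a `ratio` column (see
#'   [count_breakend_depth()])
#' @param hom_threshold ratio at or above which a call is HOM (default 0.8)
#' @param het_band two-sided ratio band for HET (default `c(0.35, 0.8)`,
#'   lower bound inclusive)
#' @return the call table with a `zygosity` column (HOM/HET/UNKNOWN)
#' @export
estimate_zygosity <- function(calls, hom_threshold = 0.8,
                              het_band = c(0.35, 0.8)) {
  calls <- data.table::as.data.table(calls)
  calls[, zygosity := data.table::fcase(
    ratio >= hom_threshold, "HOM",
    ratio >= het_band[1] & ratio < het_band[2], "HET",
    default = "UNKNOWN")]
  calls[]
}

#' Remove calls whose breakends fall in excluded regions
#'
#' Used for reference gap (N-run) exclusion: breakends near assembly gaps
#' are alignment artifacts and are removed before scoring.
#'
#' @param calls call table
#' @param exclude `GRanges` of excluded regions (e.g. from [read_bed()]);
#'   `NULL` disables filtering
#' @return filtered call table
#' @export
filter_excluded <- function(calls, exclude = NULL) {
  if (is.null(exclude) || nrow(calls) == 0L) return(calls)
  calls <- data.table::as.data.table(calls)
  drop1 <- in_excluded(calls$chrom1, calls$pos1, exclude)
  has2 <- !is.na(calls$pos2) & !is.na(calls$chrom2)
  drop2 <- rep(FALSE, nrow(calls))
  if (any(has2))
    drop2[has2] <- in_excluded(calls$chrom2[has2], calls$pos2[has2], exclude)
  calls[!(drop1 | drop2)]
}
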
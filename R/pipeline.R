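# End-to-end caller: alignment profiles -> novel adjacencies -> clustered
# calls -> breakend depths -> MAD outlier filter -> network scoring.

#' Call structural variants from long-read alignments
#'
#' Runs the full calling pipeline on an alignment file or a parsed segment
#' table: within-read overlap resolution, split-read novel-adjacency
#' detection and classification, clustering into candidate calls,
#' supporting/opposing depth counting with the robust MAD outlier threshold
#' U, zygosity estimation from the breakend read ratio, and confidence
#' scoring with the bundled (or a user-trained) classifier.
#'
#' @param alignments path to an alignment file, or a `read_profiles` table
#'   from [parse_alignments()]
#' @param dialect alignment dialect when `alignments` is a path
#' @param read_lengths named read-length vector (tabular6 dialect only)
#' @param model an `sv_ann` classifier (default [sv_default_model()]);
#'   `NULL` skips scoring, leaving `P`/`score` as `NA` — used when
#'   generating training examples for a new classifier
#' @param min_sv_size,min_read_gap detection thresholds in bases (default
#'   50)
#' @param merge_distance breakend clustering distance (default 400)
#' @param min_support minimum supporting reads per call (default 1; the
#'   confidence score handles low-support artifacts)
#' @param score_threshold confidence score cutoff for the filtered callset
#'   (default 1.0)
#' @param depth_n genomic positions sampled for the depth distribution
#'   (default 10000)
#' @param seed seed for depth-position sampling (default 1)
#' @param exclude optional `GRanges` of excluded (gap) regions
#' @param contig_lengths named contig lengths; defaults to the attribute on
#'   the parsed alignments
#' @return object of class `sv_callset`: list with `calls` (scored call
#'   table), `adjacencies` (all detected), `adj_used` (adjacencies of
#'   retained calls) with the matching raw `features` matrix, `read_stats`,
#'   `depth` (a `depth_sample`), `U`, `n_outlier_removed`, and `params`
#' @export
sv_call <- function(alignments, dialect = c("tabular6", "paf", "sam"),
                    read_lengths = NULL, model = sv_default_model(),
                    min_sv_size = 50L, min_read_gap = 50L,
                    merge_distance = 400L, min_support = 1L,
                    score_threshold = 1.0, depth_n = 10000L, seed = 1L,
                    exclude = NULL, contig_lengths = NULL) {
  profiles <- if (is.character(alignments)) {
    parse_alignments(alignments, dialect = match.arg(dialect),
                     read_lengths = read_lengths, split_gap = min_sv_size)
  } else alignments
  profiles <- resolve_overlaps(profiles)
  if (is.null(contig_lengths))
    contig_lengths <- attr(profiles, "contig_lengths")

  adj <- detect_adjacencies(profiles, min_sv_size = min_sv_size,
                            min_read_gap = min_read_gap)
  calls <- cluster_adjacencies(adj, merge_distance = merge_distance,
                               min_support = min_support)
  adj <- attr(calls, "adjacencies")
  calls <- filter_excluded(calls, exclude)
  calls <- count_breakend_depth(calls, profiles)

  depth <- sample_depth_distribution(profiles, contig_lengths,
                                     n = depth_n, seed = seed,
                                     exclude = exclude)
  U <- depth_outlier_threshold(depth)
  n_before <- nrow(calls)
  calls <- filter_outlier_breakends(calls, U)
  calls <- estimate_zygosity(calls)

  if (nrow(calls) > 0L) {
    adj_used <- adj[adj$cluster_id %in% calls$cluster_id]
    feats <- extract_features(adj_used, profiles, calls,
                              merge_distance = merge_distance)
    if (!is.null(model)) {
      P_adj <- predict(model, feats)
      pdt <- data.table::data.table(cluster_id = adj_used$cluster_id, P = P_adj)
      Pcl <- pdt[, .(P = mean(P)), by = cluster_id]
      calls[Pcl, P := i.P, on = "cluster_id"]
      calls[, score := confidence_score(B, P)]
    } else {
      calls[, `:=`(P = NA_real_, score = NA_real_)]
    }
  } else {
    adj_used <- adj[0L]
    feats <- extract_features(adj_used, profiles, calls)
    calls[, `:=`(P = numeric(), score = numeric())]
  }

  structure(list(
    calls = calls[],
    adjacencies = adj,
    adj_used = adj_used,
    features = feats,
    read_stats = profile_stats(profiles),
    depth = depth, U = U,
    n_outlier_removed = n_before - nrow(calls),
    params = list(min_sv_size = min_sv_size, min_read_gap = min_read_gap,
                  merge_distance = merge_distance, min_support = min_support,
                  score_threshold = score_threshold, depth_n = depth_n,
                  seed = seed),
    contig_lengths = contig_lengths), class = "sv_callset")
}

#' @export
print.sv_callset <- function(x, ...) {
  filt <- filter_by_score(x$calls, x$params$score_threshold)
  cat("splitsv callset:", nrow(x$calls), "total SVs,",
      nrow(filt), sprintf("at score >= %.2f\n", x$params$score_threshold))
  cat("  reads profiled:", nrow(x$read_stats),
      " median depth:", x$depth$median, " U:", round(x$U, 2), "\n")
  if (nrow(x$calls) > 0L) {
    tab <- table(filt$sv_class)
    cat("  filtered classes:",
        paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  }
  invisible(x)
}

#' @export
summary.sv_callset <- function(object, ...) {
  print(object)
  if (nrow(object$calls) > 0L) {
    cat("  zygosity:", paste(names(table(object$calls$zygosity)),
                             table(object$calls$zygosity),
                             sep = ":", collapse = "  "), "\n")
    cat("  score quartiles:",
        paste(round(stats::quantile(object$calls$score), 2), collapse = " "),
        "\n")
  }
  invisible(object)
}

#' @export
plot.sv_callset <- function(x, ...) {
  calls <- x$calls
  if (nrow(calls) == 0L) return(invisible(x))
  graphics::plot(calls$ratio, calls$score, pch = 19, cex = 0.6,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "breakend read ratio B/(B+O)",
                 ylab = "confidence score S",
                 main = "Score vs breakend read ratio", ...)
  graphics::abline(h = x$params$score_threshold, col = "red", lwd = 2)
  invisible(x)
}

#' @export
as.data.frame.sv_callset <- function(x, ...) {
  as.data.frame(x$calls[, !"supporting_reads"], ...)
}
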
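# Breakend-window evaluation: each ground-truth SV is segregated into its
# breakend coordinates (two for DEL/INV/DUP, one for INS/BND); a predicted
# breakend scores a hit when it falls within the 400-bp error distance of a
# truth breakend (class-aware mode additionally requires the same SV
# class). Precision, recall and F1 are computed over breakends.

#' Build truth breakend windows
#'
#' One interval \[pos - d, pos + d\] per truth breakend (d inclusive at
#' exactly the error distance), class-tagged.
#'
#' @param truth simulator truth table (`sv_class`, `chrom`, `pos1`, `pos2`)
#' @param error_distance half-width d in bases (default 400)
#' @return `GRanges` of windows with metadata columns `sv_class`, `sv_id`
#' @export
truth_windows <- function(truth, error_distance = 400L) {
  truth <- data.table::as.data.table(truth)
  if (nrow(truth) == 0L)
    return(GenomicRanges::GRanges(sv_class = character(), sv_id = character()))
  b1 <- truth[, .(sv_id, sv_class, chrom, pos = pos1)]
  b2 <- truth[!is.na(pos2), .(sv_id, sv_class, chrom, pos = pos2)]
  b <- data.table::rbindlist(list(b1, b2))
  gr <- granges0(b$chrom, pmax(b$pos - error_distance, 0L),
                 b$pos + error_distance + 1L)
  gr$sv_class <- b$sv_class
  gr$sv_id <- b$sv_id
  gr
}

# predicted breakends (one row per breakend) from a call table
call_breakends <- function(calls) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  sv_class = character(), id = character()))
  b1 <- calls[, .(chrom = chrom1, pos = pos1, sv_class, id)]
  two <- calls$sv_class %in% c("DEL", "INV", "DUP") & !is.na(calls$pos2)
  b2 <- calls[two, .(chrom = chrom2, pos = pos2, sv_class, id)]
  data.table::rbindlist(list(b1, b2))
}

#' Match predicted breakends against truth windows
#'
#' TP is the number of truth windows hit, FN the number unhit, FP the number
#' of predicted breakends falling in no (matching) window. By default
#' multiple predictions inside one window are deduplicated: the extras count
#' neither as TP nor FP, since they locate a real event.
#'
#' @param predictions a call table (breakends are extracted per class), or a
#'   `data.table` with columns `chrom`, `pos`, `sv_class`
#' @param windows truth windows from [truth_windows()]
#' @param class_aware require the predicted class to match the window class
#' @param exclude optional `GRanges`; predicted breakends inside are removed
#'   before matching (reference-gap artifact filtering)
#' @param dedup deduplicate multiple hits per window (default TRUE)
#' @return object of class `sv_eval`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `per_class` (`data.table`), and `hit_ids`
#'   (truth sv_ids hit)
#' @export
match_breakends <- function(predictions, windows, class_aware = FALSE,
                            exclude = NULL, dedup = TRUE) {
  pred <- if (is.data.frame(predictions) && "pos" %in% names(predictions))
    data.table::as.data.table(predictions) else call_breakends(predictions)
  if (!is.null(exclude) && nrow(pred) > 0L)
    pred <- pred[!in_excluded(pred$chrom, pred$pos, exclude)]
  n_win <- length(windows)
  if (nrow(pred) == 0L) {
    return(eval_result(0L, 0L, n_win,
                       per_class = per_class_eval(pred, windows, class_aware),
                       hit_ids = character(0), hit_windows = integer(0)))
  }
  pts <- granges0(pred$chrom, pred$pos, pred$pos + 1L)
  ov <- GenomicRanges::findOverlaps(pts, windows, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); w <- S4Vectors::subjectHits(ov)
  if (class_aware) {
    keep <- pred$sv_class[q] == windows$sv_class[w]
    q <- q[keep]; w <- w[keep]
  }
  hit_windows <- unique(w)
  matched_preds <- unique(q)
  fp <- nrow(pred) - length(matched_preds)
  if (dedup) {
    # one TP per hit window; extra predictions in a hit window are neither
    # TP nor FP (they locate a real event)
    eval_result(length(hit_windows), fp, n_win - length(hit_windows),
                per_class = per_class_eval(pred, windows, class_aware),
                hit_ids = unique(windows$sv_id[hit_windows]),
                hit_windows = hit_windows)
  } else {
    # every matched prediction counts towards precision
    precision <- length(matched_preds) / nrow(pred)
    recall <- if (n_win > 0L) length(hit_windows) / n_win else 0
    structure(list(tp = length(hit_windows), fp = fp,
                   fn = n_win - length(hit_windows),
                   precision = precision, recall = recall,
                   f1 = f1_score(precision, recall),
                   per_class = per_class_eval(pred, windows, class_aware),
                   hit_ids = unique(windows$sv_id[hit_windows]),
                   hit_windows = hit_windows),
              class = "sv_eval")
  }
}

eval_result <- function(tp, fp, fn, per_class = NULL, hit_ids = NULL,
                        hit_windows = NULL) {
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1_score(precision, recall),
                 per_class = per_class, hit_ids = hit_ids,
                 hit_windows = hit_windows),
            class = "sv_eval")
}

# class-aware evaluation restricted to each class separately
per_class_eval <- function(pred, windows, class_aware) {
  classes <- sort(unique(c(pred$sv_class, windows$sv_class)))
  if (length(classes) == 0L) return(NULL)
  rows <- lapply(classes, function(cl) {
    p <- pred[pred$sv_class == cl]
    w <- windows[windows$sv_class == cl]
    if (nrow(p) == 0L && length(w) == 0L) return(NULL)
    r <- if (nrow(p) == 0L) eval_result(0L, 0L, length(w))
    else {
      pts <- granges0(p$chrom, p$pos, p$pos + 1L)
      ov <- GenomicRanges::findOverlaps(pts, w, ignore.strand = TRUE)
      tp <- length(unique(S4Vectors::subjectHits(ov)))
      fp <- nrow(p) - length(unique(S4Vectors::queryHits(ov)))
      eval_result(tp, fp, length(w) - tp)
    }
    data.table::data.table(sv_class = cl, tp = r$tp, fp = r$fp, fn = r$fn,
                           precision = r$precision, recall = r$recall,
                           f1 = r$f1)
  })
  data.table::rbindlist(rows)
}

#' @export
print.sv_eval <- function(x, ...) {
  cat(sprintf("Breakend evaluation: TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f\n",
              x$precision, x$recall, x$f1))
  if (!is.null(x$per_class)) {
    cat("  per class:\n")
    print(x$per_class)
  }
  invisible(x)
}

#' F1 score
#'
#' Harmonic mean of precision and recall,
#' \eqn{F_1 = 2 PR / (P + R)}; 0 when both are 0.
#'
#' @param precision,recall reals in \[0, 1\]
#' @return the F1 score
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * (recall * precision) / (recall + precision))
}

#' Recall stratified by repeat family
#'
#' Intersects truth breakends with a repeat annotation (BED with the family
#' label in the name column) and recomputes recall within each family's
#' truth subset.
#'
#' @param truth simulator truth table
#' @param eval an `sv_eval` from [match_breakends()] (its `hit_ids` are
#'   reused)
#' @param repeats `GRanges` with a `family` metadata column (see
#'   [read_bed()])
#' @param error_distance window half-width (default 400)
#' @return `data.table`: `family`, `n_windows`, `n_hit`, `recall`; empty
#'   families are omitted
#' @export
stratify_by_repeats <- function(truth, eval, repeats, error_distance = 400L) {
  if (is.null(repeats$family)) stop("repeat annotation lacks a family column")
  win <- truth_windows(truth, error_distance)
  ov <- GenomicRanges::findOverlaps(win, repeats, ignore.strand = TRUE)
  if (length(ov) == 0L)
    return(data.table::data.table(family = character(), n_windows = integer(),
                                  n_hit = integer(), recall = numeric()))
  dt <- data.table::data.table(
    w = S4Vectors::queryHits(ov),
    family = repeats$family[S4Vectors::subjectHits(ov)])
  dt <- unique(dt)
  hit_w <- eval$hit_windows %||% which(win$sv_id %in% eval$hit_ids)
  dt[, hit := w %in% hit_w]
  out <- dt[, .(n_windows = .N, n_hit = sum(hit), recall = mean(hit)),
            by = family]
  out[order(family)]
}
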
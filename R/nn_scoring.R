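# Confidence scoring of novel adjacencies: 23 alignment/depth features per
# adjacency, a 23-12-5-1 feed-forward network (ReLU hidden layers, sigmoid
# output; dropout 0.4/0.3 during training only), and the Phred-like score
#   S = -10 log10(1 - tanh(0.4 B) * P)
# used for ranking and filtering. The network is implemented directly over
# base matrix algebra (forward + backpropagation) so trained weights are
# plain numbers reproducible from a seed.

FEATURE_NAMES <- c(
  "up_aligned_pct", "dn_aligned_pct", "junction_gap_pct", "total_aligned_pct",
  "max_unaligned_pct",
  "up_evalue_nlog", "dn_evalue_nlog",
  "up_rel_bitscore", "dn_rel_bitscore",
  "up_identity_pct", "dn_identity_pct",
  "up_mismatch_frac", "dn_mismatch_frac",
  "up_gap_frac", "dn_gap_frac",
  "sv_complexity", "n_alignments", "n_sv_on_read", "n_chroms",
  "frac_short_alignments", "B", "breakend_ratio", "indel_size")

#' Extract raw scoring features for each novel adjacency
#'
#' Computes the 23 per-adjacency features used by the classifier, grouped
#' as: aligned/unaligned percentages flanking the junction (5), flanking
#' E-values on a -log10 scale (2), relative bitscores (bitscore per aligned
#' base, 2), alignment identities (2), mismatch fractions (2), gap fractions
#' (2), junction complexity (coexisting adjacencies at the locus, 1), total
#' alignments on the read (1), total adjacencies on the read (1), distinct
#' chromosomes hit by the read (1), fraction of alignments shorter than 5%
#' of the read (1), supporting reads B (1), breakend read ratio B/(B+O) (1)
#' and the inserted/deleted segment size for INS/DEL (1).
#'
#' Values are raw; min-max scaling into [0,1] happens against bounds frozen
#' in the fitted model (see [sv_ann()]).
#'
#' @param adjacencies adjacency table annotated with `cluster_id`
#'   (attribute `"adjacencies"` of [cluster_adjacencies()] output)
#' @param profiles segment table used for calling
#' @param calls depth-annotated call table (with `B`, `O`, `ratio`)
#' @param merge_distance locus radius for the complexity feature (default
#'   400)
#' @return numeric matrix, one row per adjacency, 23 named columns
#' @export
extract_features <- function(adjacencies, profiles, calls,
                             merge_distance = 400L) {
  adj <- data.table::as.data.table(adjacencies)
  s <- data.table::as.data.table(profiles)
  calls <- data.table::as.data.table(calls)
  n <- nrow(adj)
  X <- matrix(NA_real_, n, length(FEATURE_NAMES),
              dimnames = list(NULL, FEATURE_NAMES))
  if (n == 0L) return(X)
  s[, seg_idx := .I]
  seg_len <- s$read_end - s$read_start

  rstats <- s[, .(n_alignments = .N,
                  aligned = sum(read_end - read_start),
                  read_length = read_length[1L],
                  n_chroms = data.table::uniqueN(chrom),
                  frac_short = mean((read_end - read_start) < 0.05 * read_length[1L]),
                  max_gap = {
                    rs <- sort(read_start); re <- read_end[order(read_start)]
                    gaps <- c(rs[1L], if (.N > 1L) rs[-1L] - re[-.N] else integer(0),
                              read_length[1L] - max(re))
                    max(c(0L, gaps))
                  }),
              by = read_id]
  nadj_read <- adj[, .N, by = read_id]
  rstats[nadj_read, n_sv := i.N, on = "read_id"]
  rstats[is.na(n_sv), n_sv := 0L]
  ri <- match(adj$read_id, rstats$read_id)
  rl <- rstats$read_length[ri]

  up <- adj$up_idx; dn <- adj$dn_idx
  X[, "up_aligned_pct"] <- 100 * seg_len[up] / rl
  X[, "dn_aligned_pct"] <- 100 * seg_len[dn] / rl
  X[, "junction_gap_pct"] <- 100 * pmax(adj$read_gap, 0L) / rl
  X[, "total_aligned_pct"] <- 100 * pmin(1, rstats$aligned[ri] / rl)
  X[, "max_unaligned_pct"] <- 100 * rstats$max_gap[ri] / rl
  X[, "up_evalue_nlog"] <- -log10(s$e_value[up] + 1e-300)
  X[, "dn_evalue_nlog"] <- -log10(s$e_value[dn] + 1e-300)
  X[, "up_rel_bitscore"] <- s$bitscore[up] / pmax(seg_len[up], 1L)
  X[, "dn_rel_bitscore"] <- s$bitscore[dn] / pmax(seg_len[dn], 1L)
  X[, "up_identity_pct"] <- s$identity_pct[up]
  X[, "dn_identity_pct"] <- s$identity_pct[dn]
  X[, "up_mismatch_frac"] <- s$mismatch_frac[up]
  X[, "dn_mismatch_frac"] <- s$mismatch_frac[dn]
  X[, "up_gap_frac"] <- s$gap_frac[up]
  X[, "dn_gap_frac"] <- s$gap_frac[dn]

  # coexisting adjacencies at the locus (same chrom within merge_distance)
  akey <- data.table::data.table(i = seq_len(n), chrom = adj$chrom1,
                                 pos = adj$pos1)
  akey[, cx := {
    sp <- sort(pos)
    findInterval(pos + merge_distance, sp) -
      findInterval(pos - merge_distance - 1L, sp)
  }, by = chrom]
  data.table::setorder(akey, i)
  X[, "sv_complexity"] <- akey$cx
  X[, "n_alignments"] <- rstats$n_alignments[ri]
  X[, "n_sv_on_read"] <- rstats$n_sv[ri]
  X[, "n_chroms"] <- rstats$n_chroms[ri]
  X[, "frac_short_alignments"] <- rstats$frac_short[ri]

  if ("cluster_id" %in% names(adj) && nrow(calls) > 0L &&
      "cluster_id" %in% names(calls)) {
    ci <- match(adj$cluster_id, calls$cluster_id)
    X[, "B"] <- calls$B[ci]
    X[, "breakend_ratio"] <- calls$ratio[ci]
  }
  X[is.na(X[, "B"]), "B"] <- 1
  X[is.na(X[, "breakend_ratio"]), "breakend_ratio"] <- 0
  X[, "indel_size"] <- ifelse(adj$sv_class %in% c("DEL", "INS") &
                                !is.na(adj$sv_size), adj$sv_size, 0)
  # absent flank information falls to the worst bound
  X[is.na(X)] <- 0
  X
}

# ---- the network ----------------------------------------------------------

ann_init <- function(sizes = c(23L, 12L, 5L, 1L), seed = 1L) {
  set.seed(seed)
  W <- list(); b <- list()
  for (k in seq_len(length(sizes) - 1L)) {
    W[[k]] <- matrix(stats::rnorm(sizes[k] * sizes[k + 1L],
                                  sd = sqrt(2 / sizes[k])),
                     sizes[k], sizes[k + 1L])
    b[[k]] <- rep(0, sizes[k + 1L])
  }
  list(W = W, b = b, sizes = sizes)
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

ann_forward_raw <- function(net, X, dropout = NULL) {
  A1 <- relu(sweep(X %*% net$W[[1]], 2, net$b[[1]], "+"))
  if (!is.null(dropout)) {
    m1 <- matrix(rbinom(length(A1), 1L, 1 - dropout[1]), nrow(A1)) / (1 - dropout[1])
    A1 <- A1 * m1
  } else m1 <- NULL
  A2 <- relu(sweep(A1 %*% net$W[[2]], 2, net$b[[2]], "+"))
  if (!is.null(dropout)) {
    m2 <- matrix(rbinom(length(A2), 1L, 1 - dropout[2]), nrow(A2)) / (1 - dropout[2])
    A2 <- A2 * m2
  } else m2 <- NULL
  Z3 <- sweep(A2 %*% net$W[[3]], 2, net$b[[3]], "+")
  P <- sigmoid(Z3)
  list(A1 = A1, A2 = A2, P = P, m1 = m1, m2 = m2)
}

# one SGD minibatch step on binary cross-entropy; returns updated net
ann_backprop <- function(net, X, y, lr, dropout) {
  fw <- ann_forward_raw(net, X, dropout)
  n <- nrow(X)
  d3 <- (fw$P - y) / n                       # dBCE/dZ3 with sigmoid output
  gW3 <- t(fw$A2) %*% d3
  gb3 <- colSums(d3)
  d2 <- (d3 %*% t(net$W[[3]])) * (fw$A2 > 0)
  if (!is.null(fw$m2)) d2 <- d2 * fw$m2
  gW2 <- t(fw$A1) %*% d2
  gb2 <- colSums(d2)
  d1 <- (d2 %*% t(net$W[[2]])) * (fw$A1 > 0)
  if (!is.null(fw$m1)) d1 <- d1 * fw$m1
  gW1 <- t(X) %*% d1
  gb1 <- colSums(d1)
  net$W[[3]] <- net$W[[3]] - lr * gW3; net$b[[3]] <- net$b[[3]] - lr * gb3
  net$W[[2]] <- net$W[[2]] - lr * gW2; net$b[[2]] <- net$b[[2]] - lr * gb2
  net$W[[1]] <- net$W[[1]] - lr * gW1; net$b[[1]] <- net$b[[1]] - lr * gb1
  net
}

#' Network forward pass
#'
#' Pure inference pass through the classifier; dropout is applied only when
#' `training = TRUE` (inverted-dropout convention), so inference is
#' deterministic.
#'
#' @param model an `sv_ann` object or a bare weight list
#' @param X numeric matrix of scaled features (rows = examples); a single
#'   feature vector is also accepted
#' @param training logical; apply dropout masks
#' @return vector of inference values P in \[0, 1\]
#' @export
ann_forward <- function(model, X, training = FALSE) {
  net <- if (inherits(model, "sv_ann")) model$net else model
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (!all(is.finite(X))) stop("non-finite feature values")
  dropout <- if (training) (if (inherits(model, "sv_ann")) model$dropout else c(0.4, 0.3)) else NULL
  as.numeric(ann_forward_raw(net, X, dropout)$P)
}

#' Fit the adjacency classifier network
#'
#' Trains the 23-12-5-1 feed-forward binary classifier with stochastic
#' gradient descent on binary cross-entropy. Each epoch draws a balanced
#' resample (`per_epoch` true and false examples, with replacement when the
#' pool is smaller) and iterates over minibatches of `batch_size`. Feature
#' min-max bounds are computed from the training pool, frozen into the
#' model, and used to scale (and clip) inference inputs.
#'
#' @param x numeric matrix of raw features (see [extract_features()])
#' @param y binary labels (1 = true adjacency, 0 = false)
#' @param epochs number of epochs (default 63)
#' @param per_epoch examples of each class resampled per epoch (default
#'   12000)
#' @param batch_size minibatch size (default 400)
#' @param lr SGD learning rate (default 0.1; plain SGD, no momentum)
#' @param dropout dropout probabilities after the two hidden layers
#'   (default `c(0.4, 0.3)`)
#' @param seed integer seed; the weight trajectory is reproducible
#' @return object of class `sv_ann`: weights, dropout, frozen feature
#'   bounds, per-epoch training accuracy (`history`)
#' @export
sv_ann <- function(x, y, epochs = 63L, per_epoch = 12000L, batch_size = 400L,
                   lr = 0.1, dropout = c(0.4, 0.3), seed = 1L) {
  if (length(unique(y)) < 2L)
    stop("training requires both true and false examples")
  stopifnot(nrow(x) == length(y))
  bounds <- feature_bounds(x)
  Xs <- scale_features(x, bounds)
  net <- ann_init(c(ncol(x), 12L, 5L, 1L), seed = seed)
  set.seed(seed + 1L)
  pos <- which(y == 1); neg <- which(y == 0)
  history <- numeric(epochs)
  if (epochs > 0L) for (ep in seq_len(epochs)) {
    idx <- c(sample(pos, per_epoch, replace = length(pos) < per_epoch),
             sample(neg, per_epoch, replace = length(neg) < per_epoch))
    idx <- sample(idx)
    for (start in seq(1L, length(idx), by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1L, length(idx))]
      net <- ann_backprop(net, Xs[bi, , drop = FALSE], y[bi], lr, dropout)
    }
    history[ep] <- mean((ann_forward_raw(net, Xs[idx, , drop = FALSE])$P > 0.5) == y[idx])
  }
  net$W <- lapply(net$W, unname)
  structure(list(net = net, dropout = dropout, bounds = bounds,
                 history = history, n_train = nrow(x),
                 feature_names = colnames(x) %||% FEATURE_NAMES),
            class = "sv_ann")
}

feature_bounds <- function(x) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  hi[hi <= lo] <- lo[hi <= lo] + 1
  list(min = lo, max = hi)
}

#' Scale raw features into \[0,1\] against frozen bounds
#' @param x raw feature matrix
#' @param bounds list with `min`, `max` per feature
#' @return scaled matrix, values clipped into \[0, 1\]
#' @export
scale_features <- function(x, bounds) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  sc <- sweep(sweep(x, 2, bounds$min, "-"), 2, bounds$max - bounds$min, "/")
  pmin(pmax(sc, 0), 1)
}

#' @export
predict.sv_ann <- function(object, newdata, scaled = FALSE, ...) {
  X <- if (scaled) newdata else scale_features(newdata, object$bounds)
  ann_forward(object, X, training = FALSE)
}

#' @export
print.sv_ann <- function(x, ...) {
  cat("Feed-forward adjacency classifier (", paste(x$net$sizes, collapse = "-"),
      ")\n", sep = "")
  cat("  trained on", x$n_train, "examples;",
      length(x$history), "epochs\n")
  if (length(x$history) > 0L)
    cat("  final training accuracy:", round(tail(x$history, 1L), 4), "\n")
  invisible(x)
}

#' @export
summary.sv_ann <- function(object, ...) {
  print(object)
  cat("  dropout:", paste(object$dropout, collapse = "/"),
      " parameters:", sum(vapply(object$net$W, length, 1L)) +
        sum(vapply(object$net$b, length, 1L)), "\n")
  invisible(object)
}

#' @export
coef.sv_ann <- function(object, ...) object$net[c("W", "b")]

#' @export
plot.sv_ann <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "training accuracy", ...)
}

#' Save / load a fitted classifier as plain JSON
#'
#' The model file stores layer sizes, weights, biases, dropout rates and the
#' frozen feature bounds, so a shipped model is fully reproducible and
#' inspectable.
#'
#' @param model an `sv_ann` object
#' @param path JSON file path
#' @return `path` invisibly (`save_model`); an `sv_ann` (`load_model`)
#' @export
save_model <- function(model, path) {
  obj <- list(sizes = model$net$sizes,
              W = lapply(model$net$W, as.numeric),   # column-major
              b = model$net$b,
              dropout = model$dropout,
              bounds = model$bounds,
              feature_names = model$feature_names,
              history = model$history,
              n_train = model$n_train)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(obj$sizes)
  W <- lapply(seq_along(obj$W), function(k)
    matrix(as.numeric(obj$W[[k]]), sizes[k], sizes[k + 1L]))
  structure(list(net = list(W = W, b = lapply(obj$b, as.numeric), sizes = sizes),
                 dropout = as.numeric(obj$dropout),
                 bounds = list(min = setNames(as.numeric(obj$bounds$min), obj$feature_names),
                               max = setNames(as.numeric(obj$bounds$max), obj$feature_names)),
                 history = as.numeric(obj$history),
                 n_train = obj$n_train,
                 feature_names = obj$feature_names),
            class = "sv_ann")
}

#' The classifier shipped with the package
#'
#' Loads the pre-trained model bundled under `inst/extdata`, fitted on
#' simulated mixed-zygosity training data generated by the package's own
#' simulator (see the methods vignette and `scripts/train_model.R`).
#'
#' @return an `sv_ann` object
#' @export
sv_default_model <- function() {
  path <- system.file("extdata", "sv_ann_model.json", package = "splitsv")
  if (!nzchar(path)) stop("bundled model not found")
  load_model(path)
}

# ---- score ----------------------------------------------------------------

#' Phred-like confidence score
#'
#' \deqn{S = -10 \log_{10}(1 - \tanh(0.4 B) P)}
#' The tanh term shrinks the network inference value P when the number of
#' supporting reads B is low (B = 1..3), so sparse evidence cannot produce a
#' high score. S is monotone increasing in both B and P; when the log
#' argument underflows the score is capped at `cap`.
#'
#' @param B supporting-read count (vectorised)
#' @param P network inference value in \[0, 1\] (vectorised)
#' @param cap maximum reported score (default 100)
#' @return numeric score vector
#' @export
confidence_score <- function(B, P, cap = 100) {
  arg <- 1 - tanh(0.4 * B) * P
  pmin(-10 * log10(pmax(arg, 10^(-cap / 10))), cap)
}

#' Split calls by confidence score
#'
#' @param calls scored call table (column `score`)
#' @param threshold minimum score for the filtered set (default 1.0)
#' @return the filtered call table (`score >= threshold`); the full table is
#'   unchanged and should be written as the "total" callset
#' @export
filter_by_score <- function(calls, threshold = 1.0) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) return(calls)
  calls[score >= threshold]
}
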
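#' kBET: k-nearest-neighbor batch effect test
#'
#' For each cell, tests the batch composition of its k nearest neighbors
#' (Euclidean, self excluded) against the global batch proportions with a
#' chi-squared goodness-of-fit test, and reports the fraction of cells
#' rejecting at level `alpha`. Lower values indicate better-mixed batches.
#' Distance ties are broken by a seeded random ordering so the statistic is
#' deterministic given `seed`.
#'
#' @param embedding cells x dims numeric matrix.
#' @param batch per-cell batch labels (>= 2 batches required).
#' @param k neighborhood size (`k < n`).
#' @param alpha significance level.
#' @param seed tie-break seed.
#' @return object of class `ccan_metric` with the rejection rate in
#'   `value`.
#' @export
kbet <- function(embedding, batch, k = 25L, alpha = 0.05, seed = 0L) {
  embedding <- as.matrix(embedding)
  batch <- as.character(batch)
  n <- base::nrow(embedding)
  stopifnot(length(batch) == n)
  if (length(unique(batch)) < 2L)
    stop("kBET requires at least two batches", call. = FALSE)
  if (k >= n)
    stop(sprintf("k (%d) must be smaller than the number of cells (%d)",
                 k, n), call. = FALSE)
  D <- as.matrix(stats::dist(embedding))
  global <- table(batch) / n
  levels_b <- names(global)
  rejected <- withLocalSeed(seed, {
    tie_key <- sample.int(n)            # one shared random tie-break order
    vapply(seq_len(n), function(i) {
      ord <- order(D[i, ], tie_key)
      nn <- setdiff(ord, i)[seq_len(k)]
      obs <- table(factor(batch[nn], levels = levels_b))
      expct <- k * as.numeric(global)
      stat <- sum((as.numeric(obs) - expct)^2 / expct)
      p <- stats::pchisq(stat, df = length(levels_b) - 1L,
                         lower.tail = FALSE)
      p < alpha
    }, logical(1))
  })
  metricReport("kbet_rejection_rate", mean(rejected), n,
               list(k = k, alpha = alpha))
}

#' Pair-counting and information clustering metrics
#'
#' Rand Index (fraction of concordant pairs), Adjusted Rand Index
#' (permutation-model correction via the closed-form contingency formula)
#' and Normalized Mutual Information (arithmetic-mean normalization of the
#' entropies). Symmetric in the two partitions and invariant to label
#' renaming.
#'
#' @param truth,predicted two partitions of the same cells.
#' @return named list with `RI`, `ARI`, `NMI`.
#' @export
clusteringMetrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("partition length mismatch", call. = FALSE)
  n <- length(truth)
  stopifnot(n >= 2L)
  tab <- table(truth, predicted)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  RI <- (total + 2 * sum_ij - sum_i - sum_j) / total
  expected <- sum_i * sum_j / total
  denom <- (sum_i + sum_j) / 2 - expected
  ARI <- if (denom == 0) 1 else (sum_ij - expected) / denom
  ## NMI with arithmetic-mean normalization
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hu <- H(pi_); hv <- H(pj_)
  NMI <- if (hu + hv == 0) 1 else I / ((hu + hv) / 2)
  list(RI = RI, ARI = ARI, NMI = min(max(NMI, 0), 1))
}

#' Accuracy and macro-averaged classification metrics
#'
#' Accuracy is the fraction of exact matches; precision and recall are
#' computed per class from the confusion matrix with 0/0 defined as 0, and
#' macro scores are their unweighted means over classes. Macro-F1 is the
#' macro mean of per-class F1 values.
#'
#' @param truth,predicted per-cell labels; `predicted` must be drawn from
#'   `classes`.
#' @param classes class universe; defaults to the classes present in
#'   `truth`.
#' @return named list with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_F1`.
#' @export
classificationMetrics <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  classes <- classes %||% sort(unique(truth))
  unseen <- setdiff(unique(predicted), classes)
  if (length(unseen))
    stop("predicted labels outside the class set: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  cm <- table(factor(truth, classes), factor(predicted, classes))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = mean(truth == predicted),
       macro_precision = mean(prec),
       macro_recall = mean(rec),
       macro_F1 = mean(f1))
}

#' Separability of classes in an embedding
#'
#' The degree to which the given class labels are discriminated by the
#' embedding, operationalized as the mean silhouette coefficient over cells
#' with Euclidean distance (the mixture-model literature offers no single
#' formula for "separability"; the silhouette is the declared stand-in).
#' Higher values indicate better discrimination.
#'
#' @param embedding cells x dims numeric matrix.
#' @param class_labels per-cell class labels; at least two classes, each
#'   with at least two members.
#' @return scalar in [-1, 1].
#' @export
separability <- function(embedding, class_labels) {
  embedding <- as.matrix(embedding)
  cl <- as.integer(factor(class_labels))
  if (length(unique(cl)) < 2L)
    stop("separability requires at least two classes", call. = FALSE)
  if (any(table(cl) < 2L))
    stop("separability is undefined with singleton classes", call. = FALSE)
  sil <- cluster::silhouette(cl, stats::dist(embedding))
  mean(sil[, "sil_width"])
}

metricReport <- function(name, value, n_cells, parameters = list()) {
  structure(list(name = name, value = value, n_cells = n_cells,
                 parameters = parameters),
            class = "ccan_metric")
}

#' @export
print.ccan_metric <- function(x, ...) {
  pars <- if (length(x$parameters))
    paste0(" (", paste(names(x$parameters), unlist(x$parameters),
                       sep = "=", collapse = ", "), ")") else ""
  cat(sprintf("%s = %.4f over %d cells%s\n", x$name, x$value, x$n_cells,
              pars))
  invisible(x)
}
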
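#' Reconstruction loss
#'
#' Per-cell-averaged squared Frobenius reconstruction error summed over the
#' two domains: `||Xs - XsHat||_F^2 / Ns + ||Xt - XtHat||_F^2 / Nt`. The
#' 1/N prefactors make the value invariant to duplicating cells.
#'
#' @param Xs,XsHat source data and its reconstruction (cells x genes).
#' @param Xt,XtHat target data and its reconstruction.
#' @return nonnegative scalar.
#' @export
lossRecons <- function(Xs, XsHat, Xt, XtHat) {
  if (!all(dim(Xs) == dim(XsHat)) || !all(dim(Xt) == dim(XtHat)))
    stop("reconstruction shape mismatch", call. = FALSE)
  sum((Xs - XsHat)^2) / base::nrow(Xs) + sum((Xt - XtHat)^2) / base::nrow(Xt)
}

#' Orthogonal difference loss
#'
#' Pushes shared and private embeddings of each domain apart:
#' `||Zss' Zsp||_F^2 + ||Zts' Ztp||_F^2`. Zero when the shared and private
#' code matrices have orthogonal column spans.
#'
#' @param z_ss,z_sp source shared / private codes (equal row counts).
#' @param z_ts,z_tp target shared / private codes.
#' @return nonnegative scalar.
#' @export
lossDiff <- function(z_ss, z_sp, z_ts, z_tp) {
  if (base::nrow(z_ss) != base::nrow(z_sp) ||
      base::nrow(z_ts) != base::nrow(z_tp))
    stop("row count mismatch between shared and private codes",
         call. = FALSE)
  sum(crossprod(z_ss, z_sp)^2) + sum(crossprod(z_ts, z_tp)^2)
}

## Multi-bandwidth Gaussian kernel bandwidths on the pooled sample: the
## stated multipliers times the median pairwise Euclidean distance.
mmdBandwidths <- function(x, y, multipliers) {
  pooled <- rbind(x, y)
  n <- base::nrow(pooled)
  if (n > 200L) pooled <- pooled[seq(1L, n, length.out = 200L), , drop = FALSE]
  med <- stats::median(stats::dist(pooled))
  if (!is.finite(med) || med <= 0) med <- 1
  multipliers * med
}

#' Maximum mean discrepancy loss
#'
#' Squared distance between the mean kernel embeddings of the two code sets,
#' in the standard three-term form `mean(Kxx) + mean(Kyy) - 2 mean(Kxy)`
#' (biased V-statistic, so identical samples give exactly 0). The default
#' kernel is a sum of Gaussians at bandwidths `multipliers x median pairwise
#' distance`; a linear kernel (`||mean(x) - mean(y)||^2`) is available for
#' exact unit checks.
#'
#' @param x,y code matrices with the same number of columns.
#' @param bandwidths Gaussian bandwidth multipliers (`"median"` mode) or
#'   absolute bandwidths (`"absolute"` mode).
#' @param kernel `"gaussian"` or `"linear"`.
#' @param bandwidth_mode `"median"` scales `bandwidths` by the median
#'   pairwise distance of the pooled codes (the median heuristic, treated
#'   as a constant during optimization); `"absolute"` uses them as given.
#' @return nonnegative scalar (clamped at 0 against roundoff).
#' @export
lossMMD <- function(x, y, bandwidths = c(0.25, 0.5, 1, 2, 4),
                    kernel = c("gaussian", "linear"),
                    bandwidth_mode = c("median", "absolute")) {
  kernel <- match.arg(kernel)
  bandwidth_mode <- match.arg(bandwidth_mode)
  if (base::nrow(x) == 0L || base::nrow(y) == 0L)
    stop("MMD requires nonempty code sets in both domains", call. = FALSE)
  if (ncol(x) != ncol(y)) stop("latent dimension mismatch", call. = FALSE)
  if (kernel == "linear") {
    mx <- colMeans(x); my <- colMeans(y)
    return(max(0, sum(mx^2) + sum(my^2) - 2 * sum(mx * my)))
  }
  sig <- if (bandwidth_mode == "median") mmdBandwidths(x, y, bandwidths)
         else bandwidths
  dxx <- sqDistMatrix(x, x); dyy <- sqDistMatrix(y, y)
  dxy <- sqDistMatrix(x, y)
  val <- 0
  for (s in sig) {
    val <- val + mean(exp(-dxx / (2 * s^2))) + mean(exp(-dyy / (2 * s^2))) -
      2 * mean(exp(-dxy / (2 * s^2)))
  }
  max(0, val)
}

sqDistMatrix <- function(x, y) {
  xn <- rowSums(x^2); yn <- rowSums(y^2)
  d <- outer(xn, yn, "+") - 2 * tcrossprod(x, y)
  pmax(d, 0)
}

#' Cross-entropy classification loss
#'
#' Mean over cells of the negated log-probability of the true class,
#' `-(1/N) sum_i sum_k y_ik log p_ik`, with probabilities clamped at 1e-12
#' before the log.
#'
#' @param labels_onehot cells x classes one-hot (or soft) label matrix.
#' @param probs row-stochastic predicted probabilities.
#' @return nonnegative scalar.
#' @export
lossClass <- function(labels_onehot, probs) {
  if (!all(dim(labels_onehot) == dim(probs)))
    stop("label/probability shape mismatch", call. = FALSE)
  -sum(labels_onehot * log(pmax(probs, 1e-12))) / base::nrow(probs)
}

#' Cluster alignment loss
#'
#' Class-conditional pairwise loss over all source-target pairs plus a
#' per-class centroid-matching term:
#' \deqn{\frac{1}{N_s N_t}\sum_{ij}[\delta_{ij} d_{ij} +
#'   (1-\delta_{ij})\max(0, m - d_{ij})] +
#'   \frac{1}{K}\sum_k \|\lambda_s^k - \lambda_t^k\|^2}
#' with \eqn{d} the squared Euclidean distance, \eqn{\delta_{ij} = 1} iff
#' the source label of i equals the target (pseudo)label of j, and
#' \eqn{\lambda^k} per-class centroids. Same-class pairs are pulled
#' together, different-class pairs pushed beyond the margin `m`.
#'
#' @param z_ss source shared codes; `labels_s` their labels.
#' @param z_ts target shared codes; `labels_t` their (pseudo)labels.
#' @param labels_s,labels_t per-cell class labels.
#' @param margin_m hinge distance threshold (> 0).
#' @return nonnegative scalar.
#' @export
lossClusterAlign <- function(z_ss, labels_s, z_ts, labels_t, margin_m = 1) {
  stopifnot(margin_m > 0,
            base::nrow(z_ss) == length(labels_s),
            base::nrow(z_ts) == length(labels_t))
  classes <- sort(unique(as.character(labels_s)))
  missing_t <- setdiff(classes, unique(as.character(labels_t)))
  missing_s <- setdiff(unique(as.character(labels_t)), classes)
  if (length(missing_s))
    stop("target (pseudo)labels outside the source class set: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  if (length(missing_t))
    stop("class absent from the target domain (centroid undefined): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  ns <- base::nrow(z_ss); nt <- base::nrow(z_ts)
  d <- sqDistMatrix(z_ss, z_ts)
  delta <- outer(as.character(labels_s), as.character(labels_t), "==")
  pair <- sum(d[delta]) + sum(pmax(0, margin_m - d[!delta]))
  cent <- 0
  for (k in classes) {
    ls <- colMeans(z_ss[labels_s == k, , drop = FALSE])
    lt <- colMeans(z_ts[labels_t == k, , drop = FALSE])
    cent <- cent + sum((ls - lt)^2)
  }
  pair / (ns * nt) + cent / length(classes)
}

#' Total training loss
#'
#' Weighted sum of the five terms. In the pretraining phase the alignment
#' loss is the MMD alone; in the refinement phase it is MMD plus the cluster
#' alignment term. The breakdown always records every term value.
#'
#' @param terms named list/vector with entries `recons`, `diff`, `mmd`,
#'   `class` and (optionally) `ca`.
#' @param weights named nonnegative weights for the same terms.
#' @param phase `"pretrain"` (cluster alignment excluded from the total) or
#'   `"refine"`.
#' @return an object of class `ccan_loss` recording `terms`, `weights`,
#'   `phase` and the weighted `total`.
#' @export
totalLoss <- function(terms, weights, phase = c("pretrain", "refine")) {
  phase <- match.arg(phase)
  terms <- as.list(terms)
  need <- c("recons", "diff", "mmd", "class")
  if (!all(need %in% names(terms)))
    stop("terms must name: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(unlist(weights) < 0))
    stop("weights must be nonnegative", call. = FALSE)
  terms$ca <- terms$ca %||% 0
  active <- c(need, if (phase == "refine") "ca")
  total <- sum(vapply(active, function(t)
    weights[[t]] * terms[[t]], numeric(1)))
  structure(list(terms = terms, weights = weights, phase = phase,
                 total = total),
            class = "ccan_loss")
}

#' @export
print.ccan_loss <- function(x, ...) {
  cat(sprintf("ccan loss (%s): total = %.6g\n", x$phase, x$total))
  for (nm in names(x$terms)) {
    cat(sprintf("  %-7s %.6g (weight %.3g)\n", nm, x$terms[[nm]],
                x$weights[[nm]]))
  }
  invisible(x)
}
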
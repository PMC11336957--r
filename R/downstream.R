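#' Cell-cycle pseudotime
#'
#' The private (circular) code of each cell, reduced modulo 2*pi into
#' [0, 2*pi). Because the decoder consumes the private code only through
#' sine and cosine, the reconstruction is invariant to this reduction, so
#' the wrapped value is the cell's position on the learned cycle.
#'
#' @param model a trained [CcanModel-class].
#' @param ds a [DomainDataset-class] from either domain.
#' @return object of class `ccan_pseudotime`: list with `pseudotime`
#'   (named numeric in [0, 2*pi)), and `phase_call`/`gmm_means`/
#'   `gmm_weights` slots filled by [callPhases()].
#' @export
cyclePseudotime <- function(model, ds) {
  if (model@config$private_dim != 1L)
    stop("pseudotime extraction requires private_dim = 1; ",
         "configure ccanConfig(private_dim = 1)", call. = FALSE)
  codes <- encodeDomain(model@params, ds)
  pt <- codes$private[, 1] %% (2 * pi)
  names(pt) <- if (is(ds, "DomainDataset")) cellIds(ds) else NULL
  structure(list(pseudotime = pt, phase_call = NULL, gmm_means = NULL,
                 gmm_weights = NULL),
            class = "ccan_pseudotime")
}

#' @export
print.ccan_pseudotime <- function(x, ...) {
  cat(sprintf("cell-cycle pseudotime for %d cells in [0, 2pi)\n",
              length(x$pseudotime)))
  if (!is.null(x$phase_call)) {
    tab <- table(x$phase_call)
    cat("  phases:", paste(sprintf("%s(%d)", names(tab), tab),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Discretize pseudotime into cell-cycle phases
#'
#' Fits a three-component one-dimensional Gaussian mixture to the
#' pseudotime by expectation-maximization and assigns each cell its
#' maximum-responsibility component. Because pseudotime lives on a circle,
#' the circle is first cut at the largest gap between sorted values so the
#' linear mixture is fitted away from the wrap-around point. Components are
#' mapped to G1, S, G2M in ascending mean order along the cut circle — a
#' labeling convention only; the biological identity of each phase must be
#' established with marker genes.
#'
#' @param pt a `ccan_pseudotime` from [cyclePseudotime()], or a bare numeric
#'   vector of pseudotimes.
#' @param max_iter EM iteration cap (error on non-convergence).
#' @param tol convergence tolerance on the log-likelihood change.
#' @return the `ccan_pseudotime` with `phase_call`, `gmm_means` (on the
#'   original pseudotime scale) and `gmm_weights` filled in.
#' @export
callPhases <- function(pt, max_iter = 500L, tol = 1e-8) {
  x_raw <- if (inherits(pt, "ccan_pseudotime")) pt$pseudotime else
    as.numeric(pt)
  if (length(unique(x_raw)) < 3L)
    stop("phase calling requires at least 3 distinct pseudotime values",
         call. = FALSE)
  ## cut the circle at the largest gap (including the wrap-around gap)
  s <- sort(x_raw)
  gaps <- c(diff(s), s[1] + 2 * pi - s[length(s)])
  cut <- (s[which.max(gaps)] + gaps[which.max(gaps)] / 2) %% (2 * pi)
  x <- (x_raw - cut) %% (2 * pi)

  fit <- gmm1dEM(x, k = 3L, max_iter = max_iter, tol = tol)
  ord <- order(fit$means)
  comp_of <- match(fit$assign, ord)        # 1..3 in ascending-mean order
  phases <- c("G1", "S", "G2M")[comp_of]
  out <- if (inherits(pt, "ccan_pseudotime")) pt else
    structure(list(pseudotime = x_raw), class = "ccan_pseudotime")
  out$phase_call <- stats::setNames(phases, names(x_raw))
  out$gmm_means <- (fit$means[ord] + cut) %% (2 * pi)
  out$gmm_weights <- fit$weights[ord]
  out
}

## Plain 1-D EM for a k-component Gaussian mixture, quantile-initialized
## (deterministic). Errors if the log-likelihood has not converged within
## max_iter iterations.
gmm1dEM <- function(x, k = 3L, max_iter = 500L, tol = 1e-8,
                    var_floor = 1e-6) {
  n <- length(x)
  mu <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  sigma2 <- rep(stats::var(x) / k + var_floor, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  last_change <- Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sqrt(sigma2[j])), numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.xmin
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma2 <- pmax(colSums(resp * (outer(x, mu, "-"))^2) / nk, var_floor)
    ll <- sum(log(rowsum_d))
    last_change <- abs(ll - ll_old)
    if (is.finite(ll) && last_change < tol) {
      return(list(means = mu, sigmas = sqrt(sigma2), weights = w,
                  assign = max.col(resp, ties.method = "first"),
                  loglik = ll, iterations = it))
    }
    ll_old <- ll
  }
  stop(sprintf(
    "EM did not converge in %d iterations (last log-likelihood change %.3g)",
    max_iter, last_change), call. = FALSE)
}

#' Remove the cell-cycle effect from a domain
#'
#' Subtracts the circular pathway's contribution to the reconstruction:
#' corrected X = X - [decoder(circular branch only) - decoder(no branches)],
#' which isolates the `V_circular [sin z_p; cos z_p]` signal propagated
#' through the (purely linear) downstream decoder layers. With a null
#' circular pathway this is the identity. Cell-type heterogeneity carried by
#' the shared embedding is untouched.
#'
#' @param model a trained [CcanModel-class].
#' @param ds a [DomainDataset-class].
#' @return corrected cells x genes matrix with the input's dimnames.
#' @export
removeCycleEffect <- function(model, ds) {
  codes <- encodeDomain(model@params, ds)
  zero_sh <- codes$shared * 0
  with_circ <- decoderForward(model@params$decoder, codes$private, zero_sh,
                              use_circular = TRUE, use_acyclic = FALSE)$out
  without <- decoderForward(model@params$decoder, codes$private, zero_sh,
                            use_circular = FALSE, use_acyclic = FALSE)$out
  X <- if (is(ds, "DomainDataset")) exprMatrix(ds) else as.matrix(ds)
  X - (with_circ - without)
}

#' Joint integration embedding
#'
#' Paired mode concatenates the shared codes of the two modalities per cell
#' (one row per cell pair, 2 x latent_dim columns); unpaired mode stacks the
#' cells of both domains in the shared space (latent_dim columns) and
#' records each row's domain of origin.
#'
#' @param model a trained [CcanModel-class].
#' @param pair the [AlignedPair-class].
#' @return object of class `ccan_joint`: list with `embedding`, `cell_ids`,
#'   `domain_of_origin`, `mode`.
#' @export
jointEmbedding <- function(model, pair) {
  zs <- encodeDomain(model@params, sourceDomain(pair))$shared
  zt <- encodeDomain(model@params, targetDomain(pair))$shared
  if (isPaired(pair)) {
    if (base::nrow(zs) != base::nrow(zt))
      stop("paired mode requires equal cell counts", call. = FALSE)
    emb <- cbind(zs, zt)
    ids <- cellIds(sourceDomain(pair))
    origin <- rep("paired", base::nrow(emb))
    mode <- "paired_concat_features"
  } else {
    emb <- rbind(zs, zt)
    ids <- c(cellIds(sourceDomain(pair)), cellIds(targetDomain(pair)))
    origin <- c(rep("source", base::nrow(zs)), rep("target", base::nrow(zt)))
    mode <- "unpaired_concat_cells"
  }
  rownames(emb) <- ids
  structure(list(embedding = emb, cell_ids = ids,
                 domain_of_origin = origin, mode = mode),
            class = "ccan_joint")
}

#' @export
print.ccan_joint <- function(x, ...) {
  cat(sprintf("joint profile (%s): %d cells x %d dims\n", x$mode,
              base::nrow(x$embedding), ncol(x$embedding)))
  invisible(x)
}

#' Save / load a trained model
#'
#' Serializes the full model (parameters, config, classes, history, RNG
#' state) so that reloading reproduces it bit-exactly. A JSON sidecar
#' records the run configuration for provenance.
#'
#' @param model a [CcanModel-class].
#' @param path checkpoint path.
#' @return `path` (save) or the restored [CcanModel-class] (load).
#' @export
saveCcanModel <- function(model, path) {
  saveRDS(model, path)
  header <- model@config
  header$classes <- model@classes
  header$phase <- model@phase
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname saveCcanModel
#' @param path checkpoint path written by [saveCcanModel()].
#' @export
loadCcanModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "CcanModel"))
  model
}

#' Circular correlation between two angle vectors
#'
#' Fisher-Lee circular correlation,
#' `sum(sin(a - abar) sin(b - bbar)) / sqrt(sum(sin^2) sum(sin^2))`, where
#' `abar`, `bbar` are circular means. Invariant to rotation of either
#' circle; reflection flips its sign, so comparisons allowing reflection
#' should use the absolute value.
#'
#' @param a,b angle vectors in radians.
#' @return correlation in [-1, 1].
#' @export
circularCor <- function(a, b) {
  stopifnot(length(a) == length(b))
  abar <- atan2(mean(sin(a)), mean(cos(a)))
  bbar <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - abar); sb <- sin(b - bbar)
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}
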
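#' Restrict two domains to their shared genes
#'
#' Subsets and reorders both matrices to the lexicographically sorted
#' intersection of their gene ids (case-sensitive exact match), so that
#' column k of the source and of the target refer to the same gene — the
#' feature-matching step required before the two domains can share an
#' encoder.
#'
#' @param source,target [DomainDataset-class] objects.
#' @param paired assert that row i of both domains is the same cell (joint
#'   profiling); requires equal cell counts.
#' @return an [AlignedPair-class] over the shared genes.
#' @examples
#' a <- DomainDataset(matrix(1:6, 2, 3, dimnames = list(c("c1","c2"),
#'                    c("A","B","C"))), labels = c("x","y"))
#' b <- DomainDataset(matrix(1:6, 2, 3, dimnames = list(c("d1","d2"),
#'                    c("B","C","D"))), role = "target")
#' geneIds(sourceDomain(intersectGenes(a, b)))
#' @export
intersectGenes <- function(source, target, paired = FALSE) {
  stopifnot(is(source, "DomainDataset"), is(target, "DomainDataset"))
  if (nrow(source) == 0L || nrow(target) == 0L)
    stop("both datasets must be nonempty", call. = FALSE)
  shared <- sort(intersect(geneIds(source), geneIds(target)))
  if (length(shared) == 0L) stop("no shared genes", call. = FALSE)
  subsetGenes <- function(ds) {
    m <- exprMatrix(ds)[, shared, drop = FALSE]
    DomainDataset(m, cellIds = cellIds(ds), geneIds = shared,
                  labels = cellLabels(ds), modality = modality(ds),
                  role = domainRole(ds))
  }
  if (paired && nrow(source) != nrow(target))
    stop("paired alignment requires equal cell counts", call. = FALSE)
  AlignedPair(subsetGenes(source), subsetGenes(target), paired = paired)
}

#' Normalize and scale a domain matrix
#'
#' `normalize = "log1p_cpm"` rescales each cell to a constant total of 1e4
#' and applies log(1 + x) — the standard library-size normalization for
#' expression or gene-activity counts. `scale = TRUE` then centers each gene
#' and divides by its standard deviation; zero-variance genes are left at 0.
#'
#' @param ds a [DomainDataset-class].
#' @param normalize `"none"` or `"log1p_cpm"`.
#' @param scale center and unit-variance each gene.
#' @return a [DomainDataset-class] with the transformed matrix.
#' @export
preprocessDomain <- function(ds, normalize = c("none", "log1p_cpm"),
                             scale = FALSE) {
  normalize <- match.arg(normalize)
  m <- exprMatrix(ds)
  if (normalize == "log1p_cpm") {
    if (any(m < 0))
      stop("log1p_cpm normalization requires a nonnegative matrix",
           call. = FALSE)
    totals <- rowSums(m)
    totals[totals == 0] <- 1            # empty cells stay all-zero
    m <- log1p(m / totals * 1e4)
  }
  if (isTRUE(scale)) {
    mu <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    m <- sweep(m, 2, mu, "-")
    nz <- sdv > 0
    m[, nz] <- sweep(m[, nz, drop = FALSE], 2, sdv[nz], "/")
    m[, !nz] <- 0
  }
  DomainDataset(m, cellIds = cellIds(ds), geneIds = geneIds(ds),
                labels = cellLabels(ds), modality = modality(ds),
                role = domainRole(ds))
}
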
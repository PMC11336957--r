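#' DomainDataset: one domain's cells-by-genes matrix
#'
#' Container for a single integration domain: a real-valued cells x genes
#' matrix (expression for scRNA-seq, gene-activity units for scATAC-seq),
#' cell and gene identifiers, optional per-cell class labels, a modality tag
#' and the domain role. The source domain must carry labels; the target
#' domain may be unlabeled.
#'
#' @slot matrix numeric cells x genes matrix, all entries finite.
#' @slot cellIds character vector of unique cell identifiers (one per row).
#' @slot geneIds character vector of unique gene identifiers (one per column).
#' @slot labels character per-cell class labels, or a zero-length vector when
#'   the domain is unlabeled.
#' @slot modality one of \code{"rna"} or \code{"atac_gene_activity"}.
#' @slot role one of \code{"source"} or \code{"target"}.
#'
#' @seealso [DomainDataset()] for the validating constructor.
#' @export
setClass("DomainDataset",
  representation(
    matrix   = "matrix",
    cellIds  = "character",
    geneIds  = "character",
    labels   = "character",
    modality = "character",
    role     = "character"
  )
)

setValidity("DomainDataset", function(object) {
  msg <- character()
  m <- object@matrix
  if (!is.numeric(m)) msg <- c(msg, "matrix must be numeric")
  if (nrow(m) != length(object@cellIds))
    msg <- c(msg, sprintf("rows(matrix) [%d] != length(cellIds) [%d]",
                          nrow(m), length(object@cellIds)))
  if (ncol(m) != length(object@geneIds))
    msg <- c(msg, sprintf("cols(matrix) [%d] != length(geneIds) [%d]",
                          ncol(m), length(object@geneIds)))
  if (anyDuplicated(object@cellIds))
    msg <- c(msg, "duplicate cell ids")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "duplicate gene ids")
  if (length(m) && !all(is.finite(m)))
    msg <- c(msg, "matrix contains non-finite entries")
  if (!object@modality %in% c("rna", "atac_gene_activity"))
    msg <- c(msg, "modality must be 'rna' or 'atac_gene_activity'")
  if (!object@role %in% c("source", "target"))
    msg <- c(msg, "role must be 'source' or 'target'")
  if (object@role == "source" && length(object@labels) == 0L)
    msg <- c(msg, "source domain requires labels")
  if (length(object@labels) &&
      length(object@labels) != length(object@cellIds))
    msg <- c(msg, "labels must have one entry per cell")
  if (length(msg)) msg else TRUE
})

#' Construct a DomainDataset
#'
#' @param matrix numeric cells x genes matrix. Row/column names, when absent,
#'   are taken from `cellIds`/`geneIds`.
#' @param cellIds,geneIds identifiers; default to the matrix dimnames.
#' @param labels optional per-cell class labels (character or factor).
#'   Mandatory when `role = "source"`.
#' @param modality `"rna"` or `"atac_gene_activity"`.
#' @param role `"source"` or `"target"`.
#' @return a validated [DomainDataset-class] object.
#' @examples
#' x <- matrix(abs(rnorm(12)), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' ds <- DomainDataset(x, labels = c("A", "A", "B"))
#' ds
#' @export
DomainDataset <- function(matrix, cellIds = rownames(matrix),
                          geneIds = colnames(matrix), labels = NULL,
                          modality = c("rna", "atac_gene_activity"),
                          role = c("source", "target")) {
  modality <- match.arg(modality)
  role <- match.arg(role)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(cellIds)) cellIds <- sprintf("cell_%d", seq_len(nrow(matrix)))
  if (is.null(geneIds)) geneIds <- sprintf("gene_%d", seq_len(ncol(matrix)))
  dimnames(matrix) <- list(cellIds, geneIds)
  if (role == "source" && is.null(labels))
    stop("source domain requires labels", call. = FALSE)
  new("DomainDataset", matrix = matrix,
      cellIds = as.character(cellIds), geneIds = as.character(geneIds),
      labels = if (is.null(labels)) character() else as.character(labels),
      modality = modality, role = role)
}

#' @describeIn DomainDataset-class number of cells
#' @param x,object a `DomainDataset`
#' @export
setMethod("nrow", "DomainDataset", function(x) base::nrow(x@matrix))

#' @describeIn DomainDataset-class number of genes
#' @export
setMethod("ncol", "DomainDataset", function(x) base::ncol(x@matrix))

#' Accessors for DomainDataset
#'
#' `exprMatrix` returns the cells x genes matrix, `cellIds`/`geneIds` the
#' identifiers, `cellLabels` the per-cell labels (`NULL` when unlabeled),
#' `modality` and `domainRole` the tags.
#' @param x a [DomainDataset-class]
#' @name DomainDataset-accessors
NULL

#' @rdname DomainDataset-accessors
#' @export
exprMatrix <- function(x) x@matrix

#' @rdname DomainDataset-accessors
#' @export
cellIds <- function(x) x@cellIds

#' @rdname DomainDataset-accessors
#' @export
geneIds <- function(x) x@geneIds

#' @rdname DomainDataset-accessors
#' @export
cellLabels <- function(x) if (length(x@labels)) x@labels else NULL

#' @rdname DomainDataset-accessors
#' @export
modality <- function(x) x@modality

#' @rdname DomainDataset-accessors
#' @export
domainRole <- function(x) x@role

setMethod("show", "DomainDataset", function(object) {
  cat(sprintf("DomainDataset (%s, %s): %d cells x %d genes\n",
              object@role, object@modality,
              nrow(object@matrix), ncol(object@matrix)))
  if (length(object@labels)) {
    tab <- table(object@labels)
    cat("  labels:", paste(sprintf("%s(%d)", names(tab), tab),
                           collapse = " "), "\n")
  } else cat("  unlabeled\n")
})

#' AlignedPair: source and target domains over one gene set
#'
#' Holds a source and a target [DomainDataset-class] restricted to the same
#' ordered gene set, plus a pairing flag. When `paired = TRUE`, row i of the
#' source and row i of the target are the same physical cell (joint
#' profiling), so cell counts must match and labels (if both present) agree.
#'
#' @slot source,target `DomainDataset` objects with identical `geneIds`.
#' @slot paired logical scalar.
#' @export
setClass("AlignedPair",
  representation(source = "DomainDataset", target = "DomainDataset",
                 paired = "logical"))

setValidity("AlignedPair", function(object) {
  msg <- character()
  if (!identical(object@source@geneIds, object@target@geneIds))
    msg <- c(msg, "source and target gene ids must be identical and ordered")
  if (length(object@paired) != 1L || is.na(object@paired))
    msg <- c(msg, "paired must be TRUE or FALSE")
  if (isTRUE(object@paired)) {
    if (nrow(object@source@matrix) != nrow(object@target@matrix))
      msg <- c(msg, "paired domains must have equal cell counts")
    if (length(object@source@labels) && length(object@target@labels) &&
        !identical(object@source@labels, object@target@labels))
      msg <- c(msg, "paired domains must carry identical labels")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AlignedPair
#' @param source,target [DomainDataset-class] objects over the same genes.
#' @param paired logical; `TRUE` for joint profiling of the same cells.
#' @return a validated [AlignedPair-class].
#' @export
AlignedPair <- function(source, target, paired = FALSE) {
  new("AlignedPair", source = source, target = target,
      paired = isTRUE(paired))
}

#' @rdname DomainDataset-accessors
#' @export
sourceDomain <- function(x) x@source

#' @rdname DomainDataset-accessors
#' @export
targetDomain <- function(x) x@target

#' @rdname DomainDataset-accessors
#' @export
isPaired <- function(x) x@paired

setMethod("show", "AlignedPair", function(object) {
  cat(sprintf("AlignedPair (%s): %d source + %d target cells, %d genes\n",
              if (object@paired) "paired" else "unpaired",
              nrow(object@source@matrix), nrow(object@target@matrix),
              ncol(object@source@matrix)))
})

#' CcanModel: training state of the domain separation network
#'
#' Holds the network parameters (shared encoder, two private encoders,
#' decoder, classifier), the run configuration, the training phase reached,
#' target pseudolabels (after label transfer), the per-epoch loss history and
#' the RNG state needed to resume the training stream deterministically.
#'
#' @slot params named list of weight/bias matrices (see [initCcanParams()]).
#' @slot config run configuration from [ccanConfig()].
#' @slot classes ordered class labels the classifier was trained on.
#' @slot phase `"init"`, `"pretrain"` or `"refine"`.
#' @slot pseudolabels character target pseudolabels (empty until transfer).
#' @slot history data.frame with one row per completed epoch of weighted
#'   loss-term values.
#' @slot rngState integer RNG state for resuming optimization.
#' @export
setClass("CcanModel",
  representation(params = "list", config = "list", classes = "character",
                 phase = "character", pseudolabels = "character",
                 history = "data.frame", rngState = "integer"))

setValidity("CcanModel", function(object) {
  msg <- character()
  if (!object@phase %in% c("init", "pretrain", "refine"))
    msg <- c(msg, "phase must be init/pretrain/refine")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CcanModel", function(object) {
  cat(sprintf("CcanModel: phase=%s, %d classes, %d epochs trained\n",
              object@phase, length(object@classes), nrow(object@history)))
  cat(sprintf("  latent_dim=%d private_dim=%d encoder=[%s]\n",
              object@config$latent_dim, object@config$private_dim,
              paste(object@config$encoder_dims, collapse = ",")))
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  last epoch total loss: %.4f\n", last$total))
  }
})

#' @rdname DomainDataset-accessors
#' @export
modelParams <- function(x) x@params

#' @rdname DomainDataset-accessors
#' @export
modelConfig <- function(x) x@config

#' @rdname DomainDataset-accessors
#' @export
lossHistory <- function(x) x@history

#' @rdname DomainDataset-accessors
#' @export
modelClasses <- function(x) x@classes

#' @rdname DomainDataset-accessors
#' @export
pseudoLabels <- function(x) {
  if (length(x@pseudolabels)) x@pseudolabels else NULL
}
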
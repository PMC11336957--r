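#' Class-balanced mini-batches
#'
#' Builds one epoch of mini-batches in which every class contributes (as
#' near as possible) the same number of cells: the per-class quota is
#' `floor(batch_size / K)` and any remainder is distributed one cell per
#' class by ascending class index. No cell is modified or discarded: the
#' number of batches is chosen so that every cell appears at least once per
#' epoch, classes with fewer cells being recycled (re-sampled) as needed.
#'
#' @param labels per-cell class labels.
#' @param batch_size cells per batch (must be >= number of classes).
#' @param seed integer seed making the shuffling deterministic.
#' @return list of integer index vectors (one per batch), with a
#'   `"quota"` attribute naming the per-class counts.
#' @export
balancedBatches <- function(labels, batch_size, seed = 0L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  K <- length(classes)
  if (batch_size < K)
    stop(sprintf("batch_size (%d) must be at least the number of classes (%d)",
                 batch_size, K), call. = FALSE)
  quota <- rep(batch_size %/% K, K)
  rem <- batch_size - sum(quota)
  if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L
  names(quota) <- classes
  idx_by_class <- split(seq_along(labels), labels)[classes]
  withLocalSeed(seed, {
    shuffled <- lapply(idx_by_class, function(ix) ix[sample.int(length(ix))])
    n_batches <- max(ceiling(lengths(shuffled) / quota))
    batches <- vector("list", n_batches)
    for (b in seq_len(n_batches)) {
      picks <- integer()
      for (k in seq_len(K)) {
        pool <- shuffled[[k]]
        # cycle through the shuffled class pool so every cell is covered
        pos <- ((b - 1L) * quota[k] + seq_len(quota[k]) - 1L) %%
          length(pool) + 1L
        picks <- c(picks, pool[pos])
      }
      batches[[b]] <- picks
    }
    attr(batches, "quota") <- quota
    batches
  })
}

## Plain randomized batches covering every index once per epoch.
plainBatches <- function(n, batch_size) {
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batch_size))
}

## Shared inner loop for pretrain/refine. `batcher` yields per-epoch lists of
## (source, target) index pairs; runs under the caller's RNG stream.
runEpochs <- function(params, pair, cfg, epochs, phase, labels_t,
                      history = NULL, adam = NULL, warmup_epochs = 0L) {
  Xs <- exprMatrix(sourceDomain(pair)); Xt <- exprMatrix(targetDomain(pair))
  labels_s <- cellLabels(sourceDomain(pair))
  classes <- sort(unique(labels_s))
  Ys_all <- oneHot(labels_s, classes)
  if (is.null(adam)) adam <- adamInit(params)
  hist_rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    if (phase == "refine") {
      bs <- balancedBatches(labels_s, cfg$batch_size,
                            seed = sample.int(.Machine$integer.max, 1))
      bt <- balancedBatches(labels_t, cfg$batch_size,
                            seed = sample.int(.Machine$integer.max, 1))
      nb <- max(length(bs), length(bt))
      idx_s <- bs[((seq_len(nb) - 1L) %% length(bs)) + 1L]
      idx_t <- bt[((seq_len(nb) - 1L) %% length(bt)) + 1L]
    } else {
      bs <- plainBatches(base::nrow(Xs), cfg$batch_size)
      bt <- plainBatches(base::nrow(Xt), cfg$batch_size)
      nb <- max(length(bs), length(bt))
      idx_s <- bs[((seq_len(nb) - 1L) %% length(bs)) + 1L]
      idx_t <- bt[((seq_len(nb) - 1L) %% length(bt)) + 1L]
    }
    acc <- c(recons = 0, diff = 0, mmd = 0, class = 0, ca = 0, total = 0)
    for (b in seq_len(nb)) {
      is_ <- idx_s[[b]]; it_ <- idx_t[[b]]
      step <- ccanStep(params,
                       Xs[is_, , drop = FALSE], Ys_all[is_, , drop = FALSE],
                       Xt[it_, , drop = FALSE],
                       labels_s[is_],
                       if (!is.null(labels_t)) labels_t[it_] else NULL,
                       cfg, phase = phase,
                       use_circular = phase != "pretrain" || ep > warmup_epochs)
      upd <- adamUpdate(params, step$grads, adam, cfg$learning_rate,
                        clip = cfg$grad_clip)
      params <- upd$params; adam <- upd$state
      acc <- acc + c(unlist(step$terms)[c("recons", "diff", "mmd", "class",
                                          "ca")], total = step$total)
    }
    hist_rows[[ep]] <- as.data.frame(as.list(acc / nb))
  }
  new_hist <- if (epochs > 0) do.call(rbind, hist_rows) else NULL
  if (!is.null(new_hist)) {
    new_hist$phase <- phase
    new_hist$epoch <- seq_len(epochs) + if (is.null(history)) 0L else
      base::nrow(history)
  }
  history <- rbind(history, new_hist)
  list(params = params, history = history %||% emptyHistory(), adam = adam)
}

emptyHistory <- function() {
  data.frame(recons = numeric(), diff = numeric(), mmd = numeric(),
             class = numeric(), ca = numeric(), total = numeric(),
             phase = character(), epoch = integer())
}

#' Step 1: pretrain the domain separation network
#'
#' Optimizes the weighted sum of the classification, reconstruction,
#' orthogonal-difference and MMD alignment losses by mini-batch Adam at
#' `cfg$learning_rate`. The classifier is trained only on labeled source
#' shared codes. Deterministic given `cfg$seed`.
#'
#' @param pair an [AlignedPair-class]; the source must be labeled.
#' @param cfg a [ccanConfig()].
#' @param epochs number of pretraining epochs; defaults to
#'   `round(cfg$pretrain_fraction * cfg$epochs)`.
#' @return a [CcanModel-class] in phase `"pretrain"` with the per-epoch loss
#'   history.
#' @export
pretrainCcan <- function(pair, cfg = ccanConfig(), epochs = NULL) {
  stopifnot(is(pair, "AlignedPair"))
  labels_s <- cellLabels(sourceDomain(pair))
  if (is.null(labels_s)) stop("source domain requires labels", call. = FALSE)
  classes <- sort(unique(labels_s))
  if (length(classes) < 2L)
    stop("pretraining requires at least two source classes ",
         "(classifier undefined for a single class)", call. = FALSE)
  epochs <- epochs %||% as.integer(round(cfg$pretrain_fraction * cfg$epochs))
  n_genes <- ncol(sourceDomain(pair))
  withLocalSeed(cfg$seed + 1L, {
    params <- initCcanParams(n_genes, length(classes), cfg)
    warmup <- as.integer(floor((cfg$circular_warmup %||% 0) * epochs))
    res <- runEpochs(params, pair, cfg, epochs, "pretrain", labels_t = NULL,
                     warmup_epochs = warmup)
    new("CcanModel", params = res$params, config = unclass(cfg),
        classes = classes, phase = "pretrain", pseudolabels = character(),
        history = res$history, rngState = captureRngState())
  })
}

#' Step 2: transfer labels from source to target
#'
#' Encodes the target with the shared encoder and applies the source-trained
#' classifier; each target cell receives the argmax class (ties broken by
#' the lowest class index) and a max-probability confidence.
#'
#' @param model a trained [CcanModel-class].
#' @param target a target [DomainDataset-class] (or cells x genes matrix).
#' @return data.frame with `cell_id`, `predicted_label`, `confidence`.
#' @export
transferLabels <- function(model, target) {
  codes <- encodeDomain(model@params, target, role = "target")
  cls <- classifyCells(model@params, codes$shared, model@classes)
  ids <- if (is(target, "DomainDataset")) cellIds(target) else
    sprintf("cell_%d", seq_len(base::nrow(cls$probs)))
  data.frame(cell_id = ids, predicted_label = cls$predicted,
             confidence = cls$confidence, stringsAsFactors = FALSE)
}

#' Step 3: refine with the cluster alignment loss
#'
#' Continues optimization with the alignment loss extended to MMD plus the
#' class-conditional cluster alignment term, iterating over class-balanced
#' mini-batches. Target labels are the Step-2 pseudolabels (held fixed
#' throughout the refinement) or, in paired mode, the true source labels.
#'
#' @param model a pretrained [CcanModel-class].
#' @param pair the [AlignedPair-class] used in pretraining.
#' @param cfg a [ccanConfig()]; defaults to the model's stored config.
#' @param pseudolabels per-target-cell labels; defaults to the model's
#'   stored pseudolabels, or the source labels when `pair` is paired.
#' @param epochs refinement epochs; defaults to
#'   `cfg$epochs - round(cfg$pretrain_fraction * cfg$epochs)`.
#' @return a [CcanModel-class] in phase `"refine"`.
#' @export
refineCcan <- function(model, pair, cfg = NULL, pseudolabels = NULL,
                       epochs = NULL) {
  cfg <- cfg %||% ccanConfig()
  if (is.null(pseudolabels)) {
    pseudolabels <- if (isPaired(pair)) cellLabels(sourceDomain(pair))
                    else pseudoLabels(model)
  }
  if (is.null(pseudolabels))
    stop("refinement requires target pseudolabels (run transferLabels) ",
         "or a paired AlignedPair", call. = FALSE)
  missing <- setdiff(model@classes, unique(pseudolabels))
  if (length(missing))
    stop("class absent from target pseudolabels (centroid undefined): ",
         paste(missing, collapse = ", "),
         "; consider more pretraining epochs or fewer classes",
         call. = FALSE)
  epochs <- epochs %||%
    (cfg$epochs - as.integer(round(cfg$pretrain_fraction * cfg$epochs)))
  withLocalSeed(model@rngState, {
    res <- runEpochs(model@params, pair, cfg, epochs, "refine",
                     labels_t = pseudolabels, history = model@history)
    new("CcanModel", params = res$params, config = unclass(cfg),
        classes = model@classes, phase = "refine",
        pseudolabels = as.character(pseudolabels),
        history = res$history, rngState = captureRngState())
  })
}

#' Step 4: finalize the model
#'
#' Freezes the refined model, re-predicts the target annotation with the
#' refined parameters, and assembles the joint integration profile
#' (feature concatenation in paired mode, cell stacking in shared space in
#' unpaired mode).
#'
#' @param model a refined [CcanModel-class].
#' @param pair the [AlignedPair-class] it was trained on.
#' @return list with `model`, `annotations` (data.frame as in
#'   [transferLabels()]) and `joint` (a `ccan_joint` profile, see
#'   [jointEmbedding()]).
#' @export
finalizeCcan <- function(model, pair) {
  ann <- transferLabels(model, targetDomain(pair))
  list(model = model, annotations = ann, joint = jointEmbedding(model, pair))
}

#' Run the full four-step schedule
#'
#' Pretrain, transfer labels, refine with cluster alignment (skipping the
#' pseudolabeling in paired mode, where the true labels are shared), and
#' finalize. This is the main entry point.
#'
#' @param pair an [AlignedPair-class] with a labeled source.
#' @param cfg a [ccanConfig()].
#' @param refine_rounds number of Step-2/Step-3 passes (default 1).
#' @return list with `model`, `annotations`, `joint` and `pseudolabels`
#'   (the Step-2 annotation before refinement).
#' @examples
#' \donttest{
#' sim <- generateMultiomics(simConfig(n_cells = 120, n_genes = 40,
#'                                     n_types = 3, seed = 1))
#' cfg <- ccanConfig(epochs = 20, encoder_dims = c(64, 32),
#'                   latent_dim = 8, seed = 1)
#' fit <- runCcan(sim$pair, cfg)
#' head(fit$annotations)
#' }
#' @export
runCcan <- function(pair, cfg = ccanConfig(), refine_rounds = 1L) {
  model <- pretrainCcan(pair, cfg)
  pseudo <- NULL
  for (r in seq_len(max(1L, refine_rounds))) {
    if (isPaired(pair)) {
      labels_t <- cellLabels(sourceDomain(pair))
      pseudo <- data.frame(cell_id = cellIds(targetDomain(pair)),
                           predicted_label = labels_t, confidence = 1,
                           stringsAsFactors = FALSE)
    } else {
      pseudo <- transferLabels(model, targetDomain(pair))
      labels_t <- pseudo$predicted_label
    }
    model <- refineCcan(model, pair, cfg, pseudolabels = labels_t)
  }
  out <- finalizeCcan(model, pair)
  out$pseudolabels <- pseudo
  out
}
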
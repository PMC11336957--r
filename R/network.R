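## Activation functions and derivatives. selu constants are the standard
## self-normalizing values.
SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

actFun <- function(z, act) {
  switch(act,
    selu = SELU_LAMBDA * ifelse(z > 0, z, SELU_ALPHA * (exp(z) - 1)),
    tanh = tanh(z),
    linear = z,
    stop("unknown activation: ", act))
}

actGrad <- function(z, a, act) {
  # derivative wrt pre-activation z; `a` is the activation output (reused
  # where cheaper).
  switch(act,
    selu = SELU_LAMBDA * ifelse(z > 0, 1, SELU_ALPHA * exp(z)),
    tanh = 1 - a^2,
    linear = array(1, dim(z)),
    stop("unknown activation: ", act))
}

## Dense multi-layer perceptron: forward with cache, backward from dOut.
## layers: list(W = list(...), b = list(...)); acts: character per layer.
mlpForward <- function(X, layers, acts) {
  L <- length(layers$W)
  Zs <- vector("list", L); As <- vector("list", L + 1L)
  As[[1]] <- X
  for (l in seq_len(L)) {
    Zs[[l]] <- As[[l]] %*% layers$W[[l]] +
      matrix(layers$b[[l]], nrow(X), length(layers$b[[l]]), byrow = TRUE)
    As[[l + 1L]] <- actFun(Zs[[l]], acts[l])
  }
  list(out = As[[L + 1L]], Zs = Zs, As = As)
}

mlpBackward <- function(cache, layers, acts, dOut) {
  L <- length(layers$W)
  gW <- vector("list", L); gb <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    dZ <- dA * actGrad(cache$Zs[[l]], cache$As[[l + 1L]], acts[l])
    gW[[l]] <- crossprod(cache$As[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    dA <- dZ %*% t(layers$W[[l]])
  }
  list(gW = gW, gb = gb, dX = dA)
}

encActs <- function(kind) {
  # three-layer perceptrons: activations on the two hidden layers, linear
  # third layer producing the embedding.
  switch(kind,
    shared = c("selu", "selu", "linear"),
    private = c("tanh", "tanh", "linear"),
    classifier = c("selu", "selu", "linear"))
}

## Glorot-uniform weight matrix, deterministic under the caller's RNG.
glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

mlpInit <- function(dims) {
  L <- length(dims) - 1L
  list(W = lapply(seq_len(L), function(l) glorot(dims[l], dims[l + 1L])),
       b = lapply(seq_len(L), function(l) numeric(dims[l + 1L])))
}

#' Initialize network parameters
#'
#' Builds the full parameter set of the domain separation network for
#' `n_genes` input features and `n_classes` cell types: one shared encoder
#' (selu hidden layers), two domain-specific private encoders (tanh hidden
#' layers), one shared decoder whose first layer applies circular weights to
#' `[sin z_p; cos z_p]` and acyclic weights to the shared code followed by
#' two linear layers, and the cell-type classifier. Weights are
#' Glorot-uniform, deterministic under `cfg$seed`.
#'
#' @param n_genes number of input features.
#' @param n_classes number of source cell types.
#' @param cfg a [ccanConfig()].
#' @return named list of parameter blocks.
#' @export
initCcanParams <- function(n_genes, n_classes, cfg) {
  withLocalSeed(cfg$seed, {
    enc_dims <- c(n_genes, cfg$encoder_dims)
    dec_h1 <- cfg$encoder_dims[2]       # decoder mirrors the encoder
    dec_h2 <- cfg$encoder_dims[1]
    gain <- cfg$private_init_gain %||% 1
    scaleOut <- function(mlp) {
      # spread initial private codes over the circle (sin/cos are
      # degenerate in a collapsed neighbourhood of 0)
      mlp$W[[length(mlp$W)]] <- mlp$W[[length(mlp$W)]] * gain
      mlp
    }
    params <- list(
      shared    = mlpInit(c(enc_dims, cfg$latent_dim)),
      private_s = scaleOut(mlpInit(c(enc_dims, cfg$private_dim))),
      private_t = scaleOut(mlpInit(c(enc_dims, cfg$private_dim))),
      decoder = list(
        Vc = glorot(2L * cfg$private_dim, dec_h1),
        Va = glorot(cfg$latent_dim, dec_h1),
        b1 = numeric(dec_h1),
        W2 = glorot(dec_h1, dec_h2), b2 = numeric(dec_h2),
        W3 = glorot(dec_h2, n_genes), b3 = numeric(n_genes)
      ),
      classifier = mlpInit(c(cfg$latent_dim, cfg$classifier_dims, n_classes))
    )
    params
  })
}

#' Encode a domain into shared and private codes
#'
#' Applies the shared (selu) encoder and the domain's private (tanh) encoder.
#' Source and target use the SAME shared encoder but distinct private
#' encoders, so the shared code of identical inputs is identical across
#' domains.
#'
#' @param params parameter list from [initCcanParams()] or a trained
#'   [CcanModel-class] (via [modelParams()]).
#' @param ds a [DomainDataset-class], or a plain cells x genes matrix
#'   combined with `role`.
#' @param role which private encoder to use; defaults to the dataset's role.
#' @return list with `shared` (cells x latent_dim) and `private`
#'   (cells x private_dim) code matrices.
#' @export
encodeDomain <- function(params, ds, role = NULL) {
  X <- if (is(ds, "DomainDataset")) exprMatrix(ds) else as.matrix(ds)
  if (is.null(role))
    role <- if (is(ds, "DomainDataset")) domainRole(ds) else
      stop("role must be given for a plain matrix", call. = FALSE)
  expected <- base::nrow(params$shared$W[[1]])
  if (ncol(X) != expected)
    stop(sprintf("gene dimension mismatch: expected %d, got %d",
                 expected, ncol(X)), call. = FALSE)
  priv <- if (role == "source") params$private_s else params$private_t
  list(shared = mlpForward(X, params$shared, encActs("shared"))$out,
       private = mlpForward(X, priv, encActs("private"))$out)
}

## Decoder forward with optional branch masking (used for cycle-effect
## removal): first layer is Vc applied to [sin z_p; cos z_p] plus Va applied
## to the shared code, then two purely linear layers.
decoderForward <- function(dec, private, shared,
                           use_circular = TRUE, use_acyclic = TRUE) {
  n <- base::nrow(private)
  S <- cbind(sin(private), cos(private))
  H1 <- matrix(dec$b1, n, length(dec$b1), byrow = TRUE)
  if (use_circular) H1 <- H1 + S %*% dec$Vc
  if (use_acyclic) H1 <- H1 + shared %*% dec$Va
  H2 <- H1 %*% dec$W2 + matrix(dec$b2, n, length(dec$b2), byrow = TRUE)
  out <- H2 %*% dec$W3 + matrix(dec$b3, n, length(dec$b3), byrow = TRUE)
  list(out = out, S = S, H1 = H1, H2 = H2)
}

decoderBackward <- function(dec, cache, private, shared, dOut) {
  gW3 <- crossprod(cache$H2, dOut); gb3 <- colSums(dOut)
  dH2 <- dOut %*% t(dec$W3)
  gW2 <- crossprod(cache$H1, dH2); gb2 <- colSums(dH2)
  dH1 <- dH2 %*% t(dec$W2)
  gVc <- crossprod(cache$S, dH1)
  gVa <- crossprod(shared, dH1)
  gb1 <- colSums(dH1)
  dS <- dH1 %*% t(dec$Vc)
  p <- ncol(private)
  dPrivate <- dS[, seq_len(p), drop = FALSE] * cos(private) -
    dS[, p + seq_len(p), drop = FALSE] * sin(private)
  dShared <- dH1 %*% t(dec$Va)
  list(grads = list(Vc = gVc, Va = gVa, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3),
       dPrivate = dPrivate, dShared = dShared)
}

#' Reconstruct expression from codes
#'
#' Decoder forward pass: the circular branch applies sine and cosine to the
#' private code before its weights (making the reconstruction 2*pi-periodic
#' in the private code), the acyclic branch is linear in the shared code,
#' and two linear layers map back to gene space. Both domains share one
#' decoder.
#'
#' @param params parameter list.
#' @param shared cells x latent_dim shared codes.
#' @param private cells x private_dim private codes.
#' @return cells x genes reconstruction matrix.
#' @export
decodeCodes <- function(params, shared, private) {
  if (ncol(shared) != base::nrow(params$decoder$Va))
    stop(sprintf("shared code dimension mismatch: expected %d, got %d",
                 base::nrow(params$decoder$Va), ncol(shared)), call. = FALSE)
  if (2L * ncol(private) != base::nrow(params$decoder$Vc))
    stop(sprintf("private code dimension mismatch: expected %d, got %d",
                 base::nrow(params$decoder$Vc) / 2L, ncol(private)),
         call. = FALSE)
  decoderForward(params$decoder, private, shared)$out
}

#' Classify cells from shared codes
#'
#' The supervised cell-type head: two selu hidden layers, linear logits, and
#' a softmax over classes. It consumes only the shared embedding, never the
#' private (cell-cycle) code.
#'
#' @param params parameter list.
#' @param shared cells x latent_dim shared codes.
#' @param classes ordered class labels (column names of the output).
#' @return list with `probs` (row-stochastic cells x classes matrix),
#'   `predicted` (argmax class, ties broken by the lowest class index) and
#'   `classes`.
#' @export
classifyCells <- function(params, shared, classes = NULL) {
  stopifnotFinite(shared, "shared codes")
  logits <- mlpForward(shared, params$classifier, encActs("classifier"))$out
  probs <- softmaxRows(logits)
  if (is.null(classes)) classes <- paste0("class", seq_len(ncol(probs)))
  colnames(probs) <- classes
  idx <- max.col(probs, ties.method = "first")
  list(probs = probs, predicted = classes[idx], classes = classes,
       confidence = probs[cbind(seq_len(base::nrow(probs)), idx)])
}

softmaxRows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
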
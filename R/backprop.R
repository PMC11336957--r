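## Analytic gradients for the full multi-objective loss. Forward passes and
## backprop are hand-written matrix algebra; tests check every path against
## finite differences.

## --- small tree utilities over nested lists of numeric arrays ------------

treeMap <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) treeMap(f, x)) else f(a)
}

treeCombine <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) treeCombine(f, x, y), a, b)
    out
  } else f(a, b)
}

treeZero <- function(a) treeMap(function(x) x * 0, a)

treeSumSq <- function(a) {
  if (is.list(a)) sum(vapply(a, treeSumSq, numeric(1))) else sum(a^2)
}

## --- per-term code gradients --------------------------------------------

mmdValueGrad <- function(x, y, bandwidths, kernel = "gaussian",
                         bandwidth_mode = "median") {
  n <- base::nrow(x); m <- base::nrow(y)
  if (kernel == "linear") {
    mx <- colMeans(x); my <- colMeans(y)
    diffm <- mx - my
    val <- sum(diffm^2)
    dX <- matrix(2 * diffm / n, n, length(diffm), byrow = TRUE)
    dY <- matrix(-2 * diffm / m, m, length(diffm), byrow = TRUE)
    return(list(value = val, dX = dX, dY = dY))
  }
  # the median-heuristic bandwidth is held constant within a step
  sig <- if (bandwidth_mode == "median") mmdBandwidths(x, y, bandwidths)
         else bandwidths
  dxx <- sqDistMatrix(x, x); dyy <- sqDistMatrix(y, y)
  dxy <- sqDistMatrix(x, y)
  val <- 0
  dX <- matrix(0, n, ncol(x)); dY <- matrix(0, m, ncol(y))
  for (s in sig) {
    s2 <- s^2
    Kxx <- exp(-dxx / (2 * s2)); Kyy <- exp(-dyy / (2 * s2))
    Kxy <- exp(-dxy / (2 * s2))
    val <- val + mean(Kxx) + mean(Kyy) - 2 * mean(Kxy)
    dX <- dX +
      (-2 / (n^2 * s2)) * (rowSums(Kxx) * x - Kxx %*% x) +
      (2 / (n * m * s2)) * (rowSums(Kxy) * x - Kxy %*% y)
    dY <- dY +
      (-2 / (m^2 * s2)) * (rowSums(Kyy) * y - Kyy %*% y) +
      (2 / (n * m * s2)) * (colSums(Kxy) * y - t(Kxy) %*% x)
  }
  list(value = val, dX = dX, dY = dY)
}

clusterAlignValueGrad <- function(z_ss, labels_s, z_ts, labels_t, margin_m) {
  ns <- base::nrow(z_ss); nt <- base::nrow(z_ts)
  classes <- sort(unique(as.character(labels_s)))
  d <- sqDistMatrix(z_ss, z_ts)
  delta <- outer(as.character(labels_s), as.character(labels_t), "==")
  hinge <- !delta & (d < margin_m)
  val <- (sum(d[delta]) + sum(pmax(0, margin_m - d)[!delta])) / (ns * nt)
  C <- delta - hinge                     # +1 attract, -1 active repulsion
  dZss <- (2 / (ns * nt)) * (rowSums(C) * z_ss - C %*% z_ts)
  dZts <- (2 / (ns * nt)) * (colSums(C) * z_ts - t(C) %*% z_ss)
  K <- length(classes)
  cent <- 0
  for (k in classes) {
    is_k <- labels_s == k; it_k <- labels_t == k
    ls <- colMeans(z_ss[is_k, , drop = FALSE])
    lt <- colMeans(z_ts[it_k, , drop = FALSE])
    dk <- ls - lt
    cent <- cent + sum(dk^2)
    dZss[is_k, ] <- dZss[is_k, ] +
      matrix((2 / K) * dk / sum(is_k), sum(is_k), length(dk), byrow = TRUE)
    dZts[it_k, ] <- dZts[it_k, ] -
      matrix((2 / K) * dk / sum(it_k), sum(it_k), length(dk), byrow = TRUE)
  }
  list(value = val + cent / K, dZss = dZss, dZts = dZts)
}

## --- one optimization step: loss terms + full parameter gradient ----------

## Ys: one-hot source labels. labels_t: target (pseudo)labels, only used in
## the refine phase for the cluster-alignment term.
## `use_circular = FALSE` disables the decoder's circular branch (warm-up:
## the acyclic pathway learns the cluster structure first, so the circular
## unit later captures the periodic residual rather than the dominant
## cell-type variance).
ccanStep <- function(params, Xs, Ys, Xt, labels_s, labels_t, cfg,
                     phase = "pretrain", use_circular = TRUE) {
  w <- cfg$loss_weights
  fs_sh <- mlpForward(Xs, params$shared, encActs("shared"))
  fs_pr <- mlpForward(Xs, params$private_s, encActs("private"))
  ft_sh <- mlpForward(Xt, params$shared, encActs("shared"))
  ft_pr <- mlpForward(Xt, params$private_t, encActs("private"))
  z_ss <- fs_sh$out; z_sp <- fs_pr$out
  z_ts <- ft_sh$out; z_tp <- ft_pr$out
  dec_s <- decoderForward(params$decoder, z_sp, z_ss,
                          use_circular = use_circular)
  dec_t <- decoderForward(params$decoder, z_tp, z_ts,
                          use_circular = use_circular)
  cls <- mlpForward(z_ss, params$classifier, encActs("classifier"))
  probs <- softmaxRows(cls$out)
  ns <- base::nrow(Xs); nt <- base::nrow(Xt)

  terms <- list(
    recons = sum((Xs - dec_s$out)^2) / ns + sum((Xt - dec_t$out)^2) / nt,
    diff = sum(crossprod(z_ss, z_sp)^2) + sum(crossprod(z_ts, z_tp)^2),
    class = -sum(Ys * log(pmax(probs, 1e-12))) / ns
  )

  ## reconstruction -> decoder and code gradients
  dXhat_s <- w[["recons"]] * (2 / ns) * (dec_s$out - Xs)
  dXhat_t <- w[["recons"]] * (2 / nt) * (dec_t$out - Xt)
  back_s <- decoderBackward(params$decoder, dec_s, z_sp, z_ss, dXhat_s)
  back_t <- decoderBackward(params$decoder, dec_t, z_tp, z_ts, dXhat_t)
  gDecoder <- treeCombine(`+`, back_s$grads, back_t$grads)
  dZss <- back_s$dShared; dZsp <- back_s$dPrivate
  dZts <- back_t$dShared; dZtp <- back_t$dPrivate
  if (!use_circular) {
    # the circular branch did not contribute to the forward pass
    gDecoder$Vc <- gDecoder$Vc * 0
    dZsp <- dZsp * 0
    dZtp <- dZtp * 0
  }

  ## orthogonal difference, applied to the (batch-centered) private code and
  ## to its centered circular features [sin z_p; cos z_p] — the form in
  ## which the private embedding enters the shared reconstruction.
  ## Penalizing covariance with the circular features evicts periodic signal
  ## from the shared space, so the circular unit, not the acyclic pathway,
  ## carries the cell cycle; centering removes the trivial mean-shift
  ## solution.
  p_dim <- ncol(z_sp)
  center <- function(m) sweep(m, 2, colMeans(m))
  diffPart <- function(zs, fp, centered) {
    A <- if (centered) center(zs) else zs
    B <- if (centered) center(fp) else fp
    M <- crossprod(A, B)
    dA <- 2 * B %*% t(M); dB <- 2 * A %*% M
    if (centered) { dA <- center(dA); dB <- center(dB) }
    list(value = sum(M^2), dZs = dA, dFp = dB)
  }
  w_circ <- cfg$diff_circular_weight %||% 0
  terms$diff <- 0
  terms$diff_circ <- 0
  for (dom in c("s", "t")) {
    zs <- if (dom == "s") z_ss else z_ts
    zp_ <- if (dom == "s") z_sp else z_tp
    # The raw-code term is the plain uncentered product of the embeddings
    # (weight loss_weights["diff"]). It is optimized ONE-SIDED: its
    # gradient flows only into the private encoder, with the shared code
    # treated as the fixed reference. A symmetric gradient resolves the
    # initial shared/private correlation by stripping the cell-type
    # structure out of the shared space — destroying the embedding
    # geometry the classifier and integration rely on — whereas the
    # one-sided form cleans the private (cycle) code of type signal, which
    # is the intended direction of the disentanglement.
    raw <- diffPart(zs, zp_, centered = FALSE)
    # The circular-feature term (batch-centered covariance with
    # [sin z_p; cos z_p], weight diff_circular_weight) stays two-sided:
    # evicting periodic signal from the shared space requires a gradient
    # on the shared encoder. It is enabled in cycle-focused presets.
    Fp <- cbind(sin(zp_), cos(zp_))
    circ <- diffPart(zs, Fp, centered = TRUE)
    dzp_feat <- circ$dFp[, seq_len(p_dim), drop = FALSE] * cos(zp_) -
      circ$dFp[, p_dim + seq_len(p_dim), drop = FALSE] * sin(zp_)
    terms$diff <- terms$diff + raw$value
    terms$diff_circ <- terms$diff_circ + circ$value
    if (dom == "s") {
      dZss <- dZss + w_circ * circ$dZs
      dZsp <- dZsp + w[["diff"]] * raw$dFp + w_circ * dzp_feat
    } else {
      dZts <- dZts + w_circ * circ$dZs
      dZtp <- dZtp + w[["diff"]] * raw$dFp + w_circ * dzp_feat
    }
  }

  ## MMD alignment
  mmd <- mmdValueGrad(z_ss, z_ts, cfg$mmd_bandwidths,
                      bandwidth_mode = cfg$mmd_bandwidth_mode %||% "median")
  terms$mmd <- mmd$value
  dZss <- dZss + w[["mmd"]] * mmd$dX
  dZts <- dZts + w[["mmd"]] * mmd$dY

  ## classifier (source only)
  dLogits <- w[["class"]] * (probs - Ys) / ns
  back_cls <- mlpBackward(cls, params$classifier, encActs("classifier"),
                          dLogits)
  gClassifier <- list(W = back_cls$gW, b = back_cls$gb)
  dZss <- dZss + back_cls$dX

  ## variance-anchoring regularizer on the private code: matches its spread
  ## to a single uniform winding of the circle (variance pi^2/3). An
  ## unbounded code can drift to several windings (the modular pseudotime
  ## scrambles) or collapse to an arc (the cycle is compressed); both are
  ## penalized by anchoring the second moment.
  vAnchor <- function(z, n_, target_v) {
    zc <- sweep(z, 2, colMeans(z))
    v <- colSums(zc^2) / n_
    list(value = sum((v - target_v)^2),
         dZ = sweep(zc, 2, 4 * (v - target_v) / n_, "*"))
  }
  ## the private anchor also pins the code's batch mean at 0 — a pure gauge
  ## choice (rotating the circle is free), which keeps the uncentered
  ## orthogonality product from leaking pressure onto the shared means,
  ## where the cluster geometry lives.
  reg <- cfg$private_reg %||% 0
  if (reg > 0) {
    meanAnchor <- function(z, n_) {
      mu <- colMeans(z)
      list(value = sum(mu^2),
           dZ = matrix(2 * mu / n_, n_, length(mu), byrow = TRUE))
    }
    as_ <- vAnchor(z_sp, ns, pi^2 / 3); at_ <- vAnchor(z_tp, nt, pi^2 / 3)
    ms_ <- meanAnchor(z_sp, ns); mt_ <- meanAnchor(z_tp, nt)
    terms$priv_reg <- as_$value + at_$value + ms_$value + mt_$value
    dZsp <- dZsp + reg * (as_$dZ + ms_$dZ)
    dZtp <- dZtp + reg * (at_$dZ + mt_$dZ)
  } else terms$priv_reg <- 0

  ## unit-variance anchor on the shared code: without it the orthogonality
  ## term admits a degenerate solution that shrinks the shared codes toward
  ## zero, which destroys the embedding geometry (cluster separation, the
  ## meaning of the alignment margin) even though the classifier still
  ## decodes the compressed signal.
  sreg <- cfg$shared_reg %||% 0
  if (sreg > 0) {
    ss_ <- vAnchor(z_ss, ns, 1); st_ <- vAnchor(z_ts, nt, 1)
    terms$shared_reg <- ss_$value + st_$value
    dZss <- dZss + sreg * ss_$dZ
    dZts <- dZts + sreg * st_$dZ
  } else terms$shared_reg <- 0

  ## cluster alignment (refine phase only)
  terms$ca <- 0
  if (phase == "refine") {
    ca <- clusterAlignValueGrad(z_ss, labels_s, z_ts, labels_t,
                                cfg$margin_m)
    terms$ca <- ca$value
    dZss <- dZss + w[["ca"]] * ca$dZss
    dZts <- dZts + w[["ca"]] * ca$dZts
  }

  ## encoders: shared gets contributions from both domains
  back_ssh <- mlpBackward(fs_sh, params$shared, encActs("shared"), dZss)
  back_tsh <- mlpBackward(ft_sh, params$shared, encActs("shared"), dZts)
  gShared <- list(W = Map(`+`, back_ssh$gW, back_tsh$gW),
                  b = Map(`+`, back_ssh$gb, back_tsh$gb))
  back_spr <- mlpBackward(fs_pr, params$private_s, encActs("private"), dZsp)
  back_tpr <- mlpBackward(ft_pr, params$private_t, encActs("private"), dZtp)

  grads <- list(
    shared = gShared,
    private_s = list(W = back_spr$gW, b = back_spr$gb),
    private_t = list(W = back_tpr$gW, b = back_tpr$gb),
    decoder = gDecoder,
    classifier = gClassifier
  )
  active <- c("recons", "diff", "mmd", "class",
              if (phase == "refine") "ca")
  total <- sum(vapply(active, function(t) w[[t]] * terms[[t]], numeric(1))) +
    reg * terms$priv_reg + sreg * terms$shared_reg +
    w_circ * terms$diff_circ
  list(terms = terms, total = total, grads = grads)
}

## --- Adam optimizer over parameter trees ---------------------------------

adamInit <- function(params) {
  list(m = treeZero(params), v = treeZero(params), t = 0L)
}

adamUpdate <- function(params, grads, state, lr, clip = 5,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gnorm <- sqrt(treeSumSq(grads))
  if (is.finite(gnorm) && gnorm > clip)
    grads <- treeMap(function(g) g * (clip / gnorm), grads)
  state$t <- state$t + 1L
  state$m <- treeCombine(function(m, g) beta1 * m + (1 - beta1) * g,
                         state$m, grads)
  state$v <- treeCombine(function(v, g) beta2 * v + (1 - beta2) * g^2,
                         state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  step <- treeCombine(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                      state$m, state$v)
  params <- treeCombine(`-`, params, step)
  list(params = params, state = state)
}
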
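## Shared fixtures: tiny datasets, tiny configs, and hand-rolled oracles
## independent of the implementation paths they check.

tinyMatrix <- function(n = 3, g = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n * g)) + 0.1, n, g,
              dimnames = list(sprintf("c%d", seq_len(n)),
                              sprintf("g%d", seq_len(g))))
  m
}

tinySource <- function(n = 4, g = 3, seed = 1, labels = NULL) {
  m <- tinyMatrix(n, g, seed)
  DomainDataset(m, labels = labels %||% rep(c("A", "B"), length.out = n))
}

tinyTarget <- function(n = 4, g = 3, seed = 2) {
  m <- tinyMatrix(n, g, seed)
  rownames(m) <- sprintf("t%d", seq_len(n))
  DomainDataset(m, role = "target")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Small network configuration for fast training-path tests.
tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(batch_size = 16L, encoder_dims = c(32L, 16L),
                   classifier_dims = c(8L, 4L), latent_dim = 4L,
                   private_dim = 1L, epochs = 10L, seed = 1L)
  do.call(ccanConfig, utils::modifyList(defaults, args))
}

## Independent selu/tanh forward oracle (scalar-level, no matrix reuse).
seluOracle <- function(x) {
  lambda <- 1.0507009873554805; alpha <- 1.6732632423543772
  vapply(x, function(v) if (v > 0) lambda * v else
    lambda * alpha * (exp(v) - 1), numeric(1))
}

## Exhaustive pair-counting oracle for RI/ARI over all unordered pairs.
pairCountOracle <- function(truth, pred) {
  n <- length(truth)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]; sp <- pred[i] == pred[j]
    if (st && sp) a <- a + 1
    else if (!st && !sp) d <- d + 1
    else if (st && !sp) c_ <- c_ + 1
    else b <- b + 1
  }
  total <- n * (n - 1) / 2
  ri <- (a + d) / total
  ## ARI from pair counts (hypergeometric expectation)
  sum_i <- a + c_; sum_j <- a + b
  exp_a <- sum_i * sum_j / total
  max_a <- (sum_i + sum_j) / 2
  ari <- if (max_a == exp_a) 1 else (a - exp_a) / (max_a - exp_a)
  list(RI = ri, ARI = ari)
}

## Brute-force cluster alignment oracle: explicit double loop.
clusterAlignOracle <- function(z_ss, labels_s, z_ts, labels_t, m) {
  ns <- nrow(z_ss); nt <- nrow(z_ts)
  pair <- 0
  for (i in seq_len(ns)) for (j in seq_len(nt)) {
    d <- sum((z_ss[i, ] - z_ts[j, ])^2)
    if (labels_s[i] == labels_t[j]) pair <- pair + d
    else pair <- pair + max(0, m - d)
  }
  classes <- sort(unique(labels_s))
  cent <- 0
  for (k in classes) {
    ls <- colMeans(z_ss[labels_s == k, , drop = FALSE])
    lt <- colMeans(z_ts[labels_t == k, , drop = FALSE])
    cent <- cent + sum((ls - lt)^2)
  }
  pair / (ns * nt) + cent / length(classes)
}

## Standardize both domains of a pair gene-wise (the usual entry state for
## training).
scalePair <- function(pair) {
  AlignedPair(preprocessDomain(sourceDomain(pair), scale = TRUE),
              preprocessDomain(targetDomain(pair), scale = TRUE),
              paired = isPaired(pair))
}
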
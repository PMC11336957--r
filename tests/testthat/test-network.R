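test_that("zeroed weights map any input to zero codes", {
  cfg <- tinyConfig()
  params <- initCcanParams(3, 2, cfg)
  params$shared <- lapply(params$shared, function(l) lapply(l, `*`, 0))
  params$private_s <- lapply(params$private_s, function(l) lapply(l, `*`, 0))
  ds <- tinySource(4, 3)
  codes <- encodeDomain(params, ds)
  expect_true(all(codes$shared == 0))
  expect_true(all(codes$private == 0))
})

test_that("encoder matches a scalar selu/tanh oracle on a hand-set net", {
  cfg <- ccanConfig(encoder_dims = c(3L, 3L), latent_dim = 2L,
                    private_dim = 1L, private_init_gain = 1, seed = 1L)
  params <- initCcanParams(3, 2, cfg)
  X <- matrix(c(0.3, -0.8, 1.2, 0.1, 0.5, -0.2), 2, 3, byrow = TRUE)
  codes <- encodeDomain(params, X, role = "source")
  # independent forward pass, scalar arithmetic
  fwd <- function(x, mlp, act) {
    h <- x
    for (l in seq_along(mlp$W)) {
      z <- as.numeric(h %*% mlp$W[[l]]) + mlp$b[[l]]
      h <- matrix(switch(act[l], selu = seluOracle(z), tanh = tanh(z),
                         linear = z), 1)
    }
    as.numeric(h)
  }
  for (i in 1:2) {
    expect_equal(as.numeric(codes$shared[i, ]),
                 fwd(X[i, , drop = FALSE], params$shared,
                     c("selu", "selu", "linear")), tolerance = 1e-6)
    expect_equal(as.numeric(codes$private[i, ]),
                 fwd(X[i, , drop = FALSE], params$private_s,
                     c("tanh", "tanh", "linear")), tolerance = 1e-6)
  }
})

test_that("the shared encoder is one function across domains", {
  cfg <- tinyConfig()
  params <- initCcanParams(3, 2, cfg)
  X <- tinyMatrix(4, 3)
  s <- encodeDomain(params, X, role = "source")
  t <- encodeDomain(params, X, role = "target")
  expect_identical(s$shared, t$shared)
  # mutating the target private encoder never changes source codes
  params2 <- params
  params2$private_t$W[[1]] <- params2$private_t$W[[1]] + 1
  expect_identical(encodeDomain(params2, X, role = "source"),
                   encodeDomain(params, X, role = "source"))
  # mutating the shared encoder changes both domains
  params3 <- params
  params3$shared$W[[1]] <- params3$shared$W[[1]] + 0.5
  expect_false(identical(encodeDomain(params3, X, role = "source")$shared,
                         s$shared))
  expect_false(identical(encodeDomain(params3, X, role = "target")$shared,
                         t$shared))
})

test_that("decoder periodicity and the forward-pass oracle hold", {
  cfg <- tinyConfig()
  set.seed(9)
  params <- initCcanParams(5, 2, cfg)
  zs <- matrix(rnorm(8), 2, 4); zp <- matrix(c(0.5, -1.2), 2, 1)
  out <- decodeCodes(params, zs, zp)
  # periodicity in the private code
  expect_equal(decodeCodes(params, zs, zp + 2 * pi), out, tolerance = 1e-6)
  expect_equal(decodeCodes(params, zs, zp - 4 * pi), out, tolerance = 1e-6)
  # independent matrix-product oracle
  d <- params$decoder
  S <- cbind(sin(zp), cos(zp))
  H1 <- S %*% d$Vc + zs %*% d$Va + rep(1, 2) %o% d$b1
  H2 <- H1 %*% d$W2 + rep(1, 2) %o% d$b2
  expect_equal(out, H2 %*% d$W3 + rep(1, 2) %o% d$b3, tolerance = 1e-6)
  # sin(0)=0, cos(0)=1: the circular branch contributes only the cosine row
  z0 <- matrix(0, 2, 1)
  base <- matrix(1, 2, 1) %*% d$Vc[2, , drop = FALSE] +
    rep(1, 2) %o% d$b1
  H2b <- (base %*% d$W2 + rep(1, 2) %o% d$b2)
  expect_equal(decodeCodes(params, zs * 0, z0),
               H2b %*% d$W3 + rep(1, 2) %o% d$b3, tolerance = 1e-6)
  expect_error(decodeCodes(params, zs[, 1:2], zp), "mismatch")
})

test_that("classifier output is an exp-normalized softmax with tie rules", {
  cfg <- tinyConfig()
  params <- initCcanParams(4, 3, cfg)
  # equal logits give uniform probabilities and the first class by tie rule
  params$classifier <- lapply(params$classifier, function(l)
    lapply(l, `*`, 0))
  sh <- matrix(rnorm(8), 2, 4)
  out <- classifyCells(params, sh, classes = c("a", "b", "c"))
  expect_equal(unname(out$probs), matrix(1 / 3, 2, 3), tolerance = 1e-12)
  expect_equal(out$predicted, c("a", "a"))
  # saturated logits
  probs <- ccan:::softmaxRows(matrix(c(1000, 0, 0), 1))
  expect_equal(as.numeric(probs), c(1, 0, 0))
  # random logits vs brute-force exp-normalize
  set.seed(10)
  logits <- matrix(rnorm(15), 5)
  expect_equal(ccan:::softmaxRows(logits),
               t(apply(logits, 1, function(r) exp(r) / sum(exp(r)))),
               tolerance = 1e-8)
  expect_true(all(abs(rowSums(out$probs) - 1) < 1e-6))
})

test_that("analytic gradients match finite differences on a 5-gene toy", {
  # The raw orthogonality term is optimized one-sided (stop-gradient on the
  # shared code), so the full-tree finite-difference check runs with that
  # term's weight at 0 and the two-sided circular-feature term active; a
  # second check below covers the one-sided term on the paths its gradient
  # actually flows through.
  cfg <- ccanConfig(encoder_dims = c(6L, 4L), classifier_dims = c(4L, 3L),
                    latent_dim = 3L, private_dim = 1L, batch_size = 8L,
                    loss_weights = c(recons = 1, diff = 0, mmd = 1,
                                     class = 1, ca = 1),
                    diff_circular_weight = 0.2,
                    mmd_bandwidths = c(0.5, 1, 2),
                    mmd_bandwidth_mode = "absolute", seed = 2L)
  set.seed(11)
  params <- initCcanParams(5, 2, cfg)
  Xs <- matrix(rnorm(30), 6); Xt <- matrix(rnorm(25), 5)
  labs <- rep(c("A", "B"), 3)
  Ys <- ccan:::oneHot(labs, c("A", "B"))
  labt <- c("A", "B", "A", "B", "A")
  for (phase in c("pretrain", "refine")) {
    st <- ccan:::ccanStep(params, Xs, Ys, Xt, labs, labt, cfg, phase)
    f <- function(p)
      ccan:::ccanStep(p, Xs, Ys, Xt, labs, labt, cfg, phase)$total
    for (blk in names(params)) {
      walk <- function(arr, g, path) {
        if (is.list(arr)) {
          for (k in seq_along(arr)) walk(arr[[k]], g[[k]], c(path, k))
          return(invisible())
        }
        for (i in sample(length(arr), min(2, length(arr)))) {
          setv <- function(x, p2, i, d) {
            if (length(p2) == 0) { x[i] <- x[i] + d; return(x) }
            x[[p2[1]]] <- setv(x[[p2[1]]], p2[-1], i, d); x
          }
          p1 <- params; p1[[blk]] <- setv(p1[[blk]], path, i, 1e-5)
          p2 <- params; p2[[blk]] <- setv(p2[[blk]], path, i, -1e-5)
          num <- (f(p1) - f(p2)) / 2e-5
          expect_equal(unname(g[i]), num, tolerance = 1e-4,
                       label = sprintf("%s gradient (%s)", blk, phase))
        }
      }
      walk(params[[blk]], st$grads[[blk]], integer())
    }
  }
})

test_that("the one-sided orthogonality gradient is exact on the private path", {
  # With the shared code as a fixed reference, finite differences over the
  # PRIVATE encoder parameters see exactly the gradient the optimizer uses
  # (private perturbations never move the shared code).
  cfg <- ccanConfig(encoder_dims = c(6L, 4L), classifier_dims = c(4L, 3L),
                    latent_dim = 3L, private_dim = 1L, batch_size = 8L,
                    loss_weights = c(recons = 1, diff = 0.7, mmd = 1,
                                     class = 1, ca = 1),
                    mmd_bandwidths = c(1), mmd_bandwidth_mode = "absolute",
                    seed = 4L)
  set.seed(12)
  params <- initCcanParams(5, 2, cfg)
  Xs <- matrix(rnorm(30), 6); Xt <- matrix(rnorm(25), 5)
  labs <- rep(c("A", "B"), 3); Ys <- ccan:::oneHot(labs, c("A", "B"))
  st <- ccan:::ccanStep(params, Xs, Ys, Xt, labs, NULL, cfg, "pretrain")
  f <- function(p)
    ccan:::ccanStep(p, Xs, Ys, Xt, labs, NULL, cfg, "pretrain")$total
  for (blk in c("private_s", "private_t")) {
    for (l in 1:3) {
      arr <- params[[blk]]$W[[l]]
      for (i in sample(length(arr), 2)) {
        p1 <- params; p1[[blk]]$W[[l]][i] <- p1[[blk]]$W[[l]][i] + 1e-5
        p2 <- params; p2[[blk]]$W[[l]][i] <- p2[[blk]]$W[[l]][i] - 1e-5
        num <- (f(p1) - f(p2)) / 2e-5
        expect_equal(unname(st$grads[[blk]]$W[[l]][i]), num,
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("dimension mismatches are reported with expected/got", {
  cfg <- tinyConfig()
  params <- initCcanParams(3, 2, cfg)
  expect_error(encodeDomain(params, tinyMatrix(2, 5), role = "source"),
               "expected 3, got 5")
})
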
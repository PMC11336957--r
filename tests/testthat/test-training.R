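test_that("balanced batches meet quota, coverage and determinism contracts", {
  labels <- rep(c("a", "b", "c"), each = 10)
  batches <- balancedBatches(labels, 6L, seed = 1)
  quota <- attr(batches, "quota")
  expect_equal(unname(quota), c(2L, 2L, 2L))
  for (b in batches) {
    expect_equal(length(b), 6L)
    expect_equal(unname(table(labels[b])), as.array(rep(2L, 3)),
                 ignore_attr = TRUE)
  }
  # every cell appears at least once per epoch
  expect_setequal(unique(unlist(batches)), seq_along(labels))
  # remainder distributed by ascending class index
  q2 <- attr(balancedBatches(rep(c("a", "b"), each = 4), 5L), "quota")
  expect_equal(unname(q2), c(3L, 2L))
  # determinism
  expect_identical(balancedBatches(labels, 6L, seed = 9),
                   balancedBatches(labels, 6L, seed = 9))
  expect_error(balancedBatches(labels, 2L), "at least the number of classes")
})

test_that("unequal class sizes are recycled, never discarded", {
  labels <- c(rep("a", 17), rep("b", 5))
  batches <- balancedBatches(labels, 4L, seed = 3)
  expect_setequal(unique(unlist(batches)), seq_along(labels))
  counts <- table(unlist(batches))
  expect_true(all(counts >= 1))
})

smallSim <- function(seed = 1, n = 60, g = 20, k = 3) {
  sim <- generateMultiomics(simConfig(n_cells = n, n_genes = g, n_types = k,
                                      n_cycle_genes = 5, seed = seed))
  scalePair(sim$pair)
}

test_that("pretraining with zero epochs returns the seeded initialization", {
  pair <- smallSim()
  cfg <- tinyConfig(epochs = 0L)
  m <- pretrainCcan(pair, cfg, epochs = 0L)
  expect_identical(modelParams(m),
                   initCcanParams(ncol(sourceDomain(pair)), 3, cfg))
  expect_equal(nrow(lossHistory(m)), 0)
})

test_that("same-seed pretraining runs are bit-reproducible", {
  pair <- smallSim()
  cfg <- tinyConfig(epochs = 4L, seed = 7L)
  m1 <- pretrainCcan(pair, cfg)
  m2 <- pretrainCcan(pair, cfg)
  expect_identical(lossHistory(m1), lossHistory(m2))
  expect_identical(modelParams(m1), modelParams(m2))
})

test_that("a single-class source is rejected", {
  m <- tinyMatrix(4, 3)
  src <- DomainDataset(m, labels = rep("only", 4))
  tgt <- tinyTarget(4, 3)
  expect_error(pretrainCcan(AlignedPair(src, tgt), tinyConfig()),
               "at least two source classes")
})

test_that("label transfer is deterministic and breaks ties to the first class", {
  pair <- smallSim()
  cfg <- tinyConfig(epochs = 2L)
  m <- pretrainCcan(pair, cfg)
  a1 <- transferLabels(m, targetDomain(pair))
  a2 <- transferLabels(m, targetDomain(pair))
  expect_identical(a1, a2)
  expect_true(all(a1$predicted_label %in% modelClasses(m)))
  expect_true(all(a1$confidence >= 1 / 3 - 1e-9 & a1$confidence <= 1))
  # degenerate classifier: uniform probabilities -> lowest class index
  m2 <- m
  m2@params$classifier <- lapply(m2@params$classifier, function(l)
    lapply(l, `*`, 0))
  a3 <- transferLabels(m2, targetDomain(pair))
  expect_true(all(a3$predicted_label == modelClasses(m)[1]))
  # a target cell with a source cell's exact profile gets that cell's class
  src_cell <- exprMatrix(sourceDomain(pair))[1, , drop = FALSE]
  cls_direct <- classifyCells(
    modelParams(m), encodeDomain(modelParams(m), src_cell,
                                 role = "target")$shared, modelClasses(m))
  probe <- transferLabels(m, src_cell)
  expect_equal(probe$predicted_label, cls_direct$predicted)
})

test_that("refinement contracts: zero epochs, pseudolabel guards, paired mode", {
  pair <- smallSim()
  cfg <- tinyConfig(epochs = 4L)
  m <- pretrainCcan(pair, cfg, epochs = 4L)
  pseudo <- transferLabels(m, targetDomain(pair))$predicted_label
  # refining for zero epochs changes nothing
  if (length(unique(pseudo)) == length(modelClasses(m))) {
    r0 <- refineCcan(m, pair, cfg, pseudolabels = pseudo, epochs = 0L)
    expect_identical(modelParams(r0), modelParams(m))
  }
  # a class missing from pseudolabels is an error with a hint
  bad <- rep(modelClasses(m)[1], nrow(targetDomain(pair)))
  expect_error(refineCcan(m, pair, cfg, pseudolabels = bad),
               "centroid undefined")
  # pseudolabels outside the class set are rejected in the loss
  expect_error(refineCcan(m, pair, cfg,
                          pseudolabels = rep("mystery",
                                             nrow(targetDomain(pair)))),
               "absent|outside")
  # paired mode uses the source labels directly (no transfer step)
  simp <- generateMultiomics(simConfig(n_cells = 40, n_genes = 20,
                                       n_types = 2, n_cycle_genes = 5,
                                       seed = 2), paired = TRUE)
  pp <- scalePair(simp$pair)
  fit <- runCcan(pp, tinyConfig(epochs = 4L))
  expect_identical(fit$pseudolabels$predicted_label,
                   cellLabels(sourceDomain(pp)))
})

test_that("finalization is pure and definitionally consistent", {
  pair <- smallSim(seed = 3)
  cfg <- tinyConfig(epochs = 6L)
  fit <- runCcan(pair, cfg)
  f1 <- finalizeCcan(fit$model, pair)
  f2 <- finalizeCcan(fit$model, pair)
  expect_identical(f1, f2)
  expect_identical(f1$annotations,
                   transferLabels(fit$model, targetDomain(pair)))
  expect_identical(fit$annotations, f1$annotations)
})

test_that("the full four-step run is bit-reproducible under one seed", {
  pair <- smallSim(seed = 4)
  cfg <- tinyConfig(epochs = 6L, seed = 11L)
  fit1 <- runCcan(pair, cfg)
  fit2 <- runCcan(pair, cfg)
  expect_identical(lossHistory(fit1$model), lossHistory(fit2$model))
  expect_identical(fit1$annotations, fit2$annotations)
  expect_identical(fit1$joint$embedding, fit2$joint$embedding)
})

test_that("training histories track both phases", {
  pair <- smallSim(seed = 5)
  cfg <- tinyConfig(epochs = 6L, pretrain_fraction = 0.5)
  fit <- runCcan(pair, cfg)
  h <- lossHistory(fit$model)
  expect_equal(nrow(h), 6)
  expect_equal(sum(h$phase == "pretrain"), 3)
  expect_equal(sum(h$phase == "refine"), 3)
  expect_true(all(is.finite(h$total)))
  expect_true(all(h$ca[h$phase == "pretrain"] == 0))
})
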
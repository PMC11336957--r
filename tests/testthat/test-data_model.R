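test_that("DomainDataset enforces its invariants", {
  m <- tinyMatrix(3, 2)
  expect_s4_class(DomainDataset(m, labels = c("A", "A", "B")),
                  "DomainDataset")
  # source requires labels
  expect_error(DomainDataset(m), "source domain requires labels")
  # target does not
  expect_s4_class(DomainDataset(m, role = "target"), "DomainDataset")
  # duplicate ids
  expect_error(DomainDataset(m, cellIds = c("a", "a", "b"),
                             labels = c("A", "A", "B")), "duplicate")
  expect_error(DomainDataset(m, geneIds = c("g", "g"),
                             labels = c("A", "A", "B")), "duplicate")
  # non-finite entries
  m2 <- m; m2[1, 1] <- NaN
  expect_error(DomainDataset(m2, labels = c("A", "A", "B")), "finite")
  # label length mismatch
  expect_error(DomainDataset(m, labels = c("A", "B")), "one entry per cell")
})

test_that("random valid fixtures always pass validity, corrupted ones fail", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:8, 1); g <- sample(2:8, 1)
    ds <- DomainDataset(tinyMatrix(n, g, seed = rep),
                        labels = sample(c("x", "y"), n, replace = TRUE))
    expect_true(validObject(ds))
    bad <- ds
    bad@labels <- character()           # drop the mandatory source labels
    expect_error(validObject(bad), "labels")
  }
})

test_that("CSV load round-trips and label plumbing works", {
  dir <- withr::local_tempdir()
  m <- tinyMatrix(3, 2, seed = 5)
  ds <- DomainDataset(m, labels = c("A", "B", "A"))
  path <- file.path(dir, "mat.csv")
  writeDomain(ds, path, format = "csv")
  got <- loadDomain(path, format = "csv",
                    labels_path = file.path(dir, "labels.tsv"),
                    role = "source")
  expect_equal(nrow(got), 3)
  expect_equal(exprMatrix(got), exprMatrix(ds))
  expect_equal(cellLabels(got), cellLabels(ds))
  # missing labels for the source role
  expect_error(loadDomain(path, format = "csv", role = "source"),
               "source domain requires labels")
  # mismatched label file lists the offenders
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("c1\tA", "c2\tB", "zz\tA"), bad)
  expect_error(loadDomain(path, format = "csv", labels_path = bad,
                          role = "source"), "mismatch")
  # NaN entries rejected
  mbad <- m; mbad[2, 1] <- NA
  utils::write.table(data.frame(cell_id = rownames(m), mbad),
                     file.path(dir, "nan.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  expect_error(loadDomain(file.path(dir, "nan.csv"), format = "csv",
                          role = "target"), "NaN")
})

test_that("MTX written genes x cells is transposed back and round-trips", {
  dir <- withr::local_tempdir()
  set.seed(11)
  m <- matrix(rpois(12, 4), 3, 4,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  ds <- DomainDataset(m, labels = c("A", "B", "A"))
  path <- file.path(dir, "mat.mtx")
  writeDomain(ds, path, format = "mtx")      # written genes x cells on disk
  ondisk <- as.matrix(Matrix::readMM(path))
  expect_equal(dim(ondisk), c(4L, 3L))
  got <- loadDomain(path, format = "mtx",
                    labels_path = file.path(dir, "labels.tsv"),
                    role = "source")
  expect_identical(exprMatrix(got), exprMatrix(ds))   # bit-exact round trip
  # another full cycle is idempotent
  writeDomain(got, file.path(dir, "mat2.mtx"), format = "mtx")
  got2 <- loadDomain(file.path(dir, "mat2.mtx"), format = "mtx",
                     labels_path = file.path(dir, "labels.tsv"),
                     role = "source")
  expect_identical(exprMatrix(got2), exprMatrix(got))
})

test_that("h5ad input is rejected with guidance", {
  expect_error(loadDomain("x.h5ad", format = "h5ad", role = "target"),
               "not supported")
})

test_that("gene intersection selects, orders and errors as specified", {
  a <- DomainDataset(matrix(1:6, 2, 3, dimnames = list(c("c1", "c2"),
                     c("A", "B", "C"))), labels = c("x", "y"))
  b <- DomainDataset(matrix(1:8, 2, 4, dimnames = list(c("d1", "d2"),
                     c("B", "C", "D", "E"))), role = "target")
  pair <- intersectGenes(a, b)
  expect_equal(geneIds(sourceDomain(pair)), c("B", "C"))
  expect_equal(geneIds(targetDomain(pair)), c("B", "C"))
  # disjoint
  d <- DomainDataset(matrix(1:2, 1, 2, dimnames = list("z", c("Q", "R"))),
                     role = "target")
  expect_error(intersectGenes(a, d), "no shared genes")
  # permutation oracle: columns refer to the same gene after reordering
  s <- DomainDataset(matrix(c(1, 2, 3), 1, 3,
                     dimnames = list("c", c("C", "B", "A"))), labels = "x")
  t <- DomainDataset(matrix(c(10, 20, 30), 1, 3,
                     dimnames = list("d", c("A", "B", "C"))), role = "target")
  p <- intersectGenes(s, t)
  expect_equal(geneIds(sourceDomain(p)), c("A", "B", "C"))
  expect_equal(as.numeric(exprMatrix(sourceDomain(p))), c(3, 2, 1))
  expect_equal(as.numeric(exprMatrix(targetDomain(p))), c(10, 20, 30))
  # applying it twice is a no-op
  p2 <- intersectGenes(sourceDomain(p), targetDomain(p))
  expect_identical(exprMatrix(sourceDomain(p2)), exprMatrix(sourceDomain(p)))
})

test_that("preprocessing matches the closed-form per-row computation", {
  ds <- DomainDataset(matrix(c(1, 1), 1, 2,
                      dimnames = list("c", c("g1", "g2"))), labels = "A")
  got <- preprocessDomain(ds, normalize = "log1p_cpm")
  expect_equal(as.numeric(exprMatrix(got)), rep(log(1 + 5000), 2),
               tolerance = 1e-12)
  # identity
  ds2 <- tinySource()
  expect_equal(exprMatrix(preprocessDomain(ds2, "none", scale = FALSE)),
               exprMatrix(ds2))
  # constant gene goes to exactly zero under scaling
  m <- cbind(tinyMatrix(4, 2), const = rep(3, 4))
  ds3 <- DomainDataset(m, labels = rep("A", 4))
  scaled <- exprMatrix(preprocessDomain(ds3, scale = TRUE))
  expect_true(all(scaled[, "const"] == 0))
  expect_equal(unname(apply(scaled[, 1:2], 2, sd)), c(1, 1),
               tolerance = 1e-12)
  # negative entries rejected for cpm
  neg <- DomainDataset(matrix(c(-1, 2), 1, 2,
                       dimnames = list("c", c("a", "b"))), labels = "A")
  expect_error(preprocessDomain(neg, "log1p_cpm"), "nonnegative")
})
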
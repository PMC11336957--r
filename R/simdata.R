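#' Synthetic-data configuration
#'
#' Parameters of the generators that emulate the statistical structure of
#' the study designs the network targets: a cyclic base population with
#' cell-type programs and a latent circular cell-cycle phase, a virtual
#' tumor (two subclones by gene doubling, two batches with Gaussian noise on
#' one), and paired/unpaired two-modality data.
#'
#' @param n_cells cells per domain.
#' @param n_genes number of genes.
#' @param n_types number of cell types K.
#' @param n_cycle_genes genes carrying the sinusoidal cell-cycle program.
#' @param cycle_amplitude amplitude of the cycle program (log-scale units).
#' @param type_effect_size mean shift of a type's program genes.
#' @param type_gene_fraction fraction of genes in each type's program.
#' @param subclone_gene_fraction fraction of genes doubled in subclone 2 of
#'   the virtual tumor.
#' @param noise_sd standard deviation of the additive Gaussian batch noise
#'   applied to the second virtual-tumor batch.
#' @param base_noise_sd standard deviation of the per-entry measurement
#'   noise added to every generated expression matrix (1 = standard
#'   Gaussian; 0 disables all noise).
#' @param sparsity_atac dropout probability of the simulated gene-activity
#'   channel.
#' @param atac_mix off-diagonal mixing weight of the random linear map that
#'   produces the gene-activity channel (0 = identity map).
#' @param base_level baseline (log-scale) expression level.
#' @param seed integer seed; generation is a pure function of this
#'   configuration.
#' @return list of class `ccan_simconfig`.
#' @export
simConfig <- function(n_cells = 400L, n_genes = 100L, n_types = 3L,
                      n_cycle_genes = 20L, cycle_amplitude = 3,
                      type_effect_size = 5, type_gene_fraction = 0.3,
                      subclone_gene_fraction = 0.25, noise_sd = 0.5,
                      base_noise_sd = 1,
                      sparsity_atac = 0.3, atac_mix = 0.3,
                      base_level = 5, seed = 0L) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_types = as.integer(n_types),
              n_cycle_genes = as.integer(n_cycle_genes),
              cycle_amplitude = cycle_amplitude,
              type_effect_size = type_effect_size,
              type_gene_fraction = type_gene_fraction,
              subclone_gene_fraction = subclone_gene_fraction,
              noise_sd = noise_sd, base_noise_sd = base_noise_sd,
              sparsity_atac = sparsity_atac,
              atac_mix = atac_mix, base_level = base_level,
              seed = as.integer(seed))
  stopifnot(cfg$n_cells > 0, cfg$n_genes > 0, cfg$n_types > 0,
            cfg$n_cycle_genes >= 0, cfg$noise_sd >= 0,
            cfg$base_noise_sd >= 0,
            cfg$sparsity_atac >= 0, cfg$sparsity_atac <= 1,
            cfg$atac_mix >= 0, cfg$atac_mix <= 1)
  if (cfg$n_cycle_genes > cfg$n_genes)
    stop("n_cycle_genes cannot exceed n_genes", call. = FALSE)
  class(cfg) <- "ccan_simconfig"
  cfg
}

## Latent programs shared by all generators: per-type mean-shift programs,
## cycle gene set with per-gene phase offsets.
simPrograms <- function(cfg) {
  genes <- sprintf("gene_%03d", seq_len(cfg$n_genes))
  types <- paste0("type", seq_len(cfg$n_types))
  cycle_genes <- sample(genes, cfg$n_cycle_genes)
  offsets <- stats::setNames(stats::runif(cfg$n_cycle_genes, 0, 2 * pi),
                             cycle_genes)
  n_prog <- max(1L, round(cfg$type_gene_fraction * cfg$n_genes))
  type_programs <- stats::setNames(
    lapply(types, function(t) sample(genes, n_prog)), types)
  list(genes = genes, types = types, cycle_genes = cycle_genes,
       offsets = offsets, type_programs = type_programs)
}

## Noise-free signal matrix for given cells (type + phase), in log-scale
## units before the softplus nonnegativity clamp.
simSignal <- function(cfg, prog, types_of_cell, theta) {
  n <- length(types_of_cell)
  M <- matrix(cfg$base_level, n, cfg$n_genes,
              dimnames = list(NULL, prog$genes))
  if (cfg$n_types > 1L) {      # a single type carries no program contrast
    for (t in unique(types_of_cell)) {
      rows <- types_of_cell == t
      M[rows, prog$type_programs[[t]]] <-
        M[rows, prog$type_programs[[t]]] + cfg$type_effect_size
    }
  }
  for (g in prog$cycle_genes) {
    M[, g] <- M[, g] + cfg$cycle_amplitude * sin(theta + prog$offsets[[g]])
  }
  M
}

#' Generate a cyclic base population
#'
#' One labeled scRNA-seq-like domain: per-type Gaussian mean-shift programs
#' on random gene subsets, a sinusoidal cell-cycle program
#' `amplitude * sin(theta_i + offset_g)` on `n_cycle_genes` genes with
#' uniform circular phases `theta_i`, additive N(0, 1) noise, and a
#' softplus clamp for nonnegativity.
#'
#' @param cfg a [simConfig()].
#' @return list with `dataset` (a labeled source [DomainDataset-class]) and
#'   `truth` (type, phase, cycle genes, programs, and the noise-free signal
#'   matrix).
#' @export
generateCyclicBase <- function(cfg = simConfig()) {
  withLocalSeed(cfg$seed, {
    prog <- simPrograms(cfg)
    n <- cfg$n_cells
    types_of_cell <- sample(rep_len(prog$types, n))
    theta <- stats::runif(n, 0, 2 * pi)
    M <- simSignal(cfg, prog, types_of_cell, theta)
    X <- softplus(M + matrix(stats::rnorm(n * cfg$n_genes,
                                          sd = cfg$base_noise_sd), n))
    ## With a single type there is no type program; the per-cell labels are
    ## then experimental-style cell-cycle stages (phase tertiles), matching
    ## FACS-sorted embryonic stem cell designs where stage is the only
    ## annotation.
    labels <- if (cfg$n_types == 1L)
      c("G1", "S", "G2M")[findInterval(theta, c(0, 2 * pi / 3, 4 * pi / 3))]
    else types_of_cell
    ds <- DomainDataset(X, cellIds = sprintf("cell_%04d", seq_len(n)),
                        geneIds = prog$genes, labels = labels,
                        modality = "rna", role = "source")
    list(dataset = ds,
         truth = list(type_of_cell = types_of_cell, phase_of_cell = theta,
                      cycle_genes = prog$cycle_genes,
                      offsets = prog$offsets,
                      type_programs = prog$type_programs,
                      signal = softplus(M)))
  })
}

#' Generate a virtual tumor with two batches
#'
#' Emulates the virtual-tumor design: subclone 1 is a cyclic base
#' population (single type, full cycle program); subclone 2 is a copy in
#' which a randomly selected gene set (cycle and non-cycle genes mixed, a
#' `subclone_gene_fraction` of all genes) has its expression doubled. The
#' merged cells are split uniformly at random into two batches and batch 2
#' receives additive Gaussian noise of standard deviation `noise_sd`.
#' Batch 1 (subclone-labeled) becomes the source domain and batch 2
#' (unlabeled) the target.
#'
#' @param cfg a [simConfig()]; `n_cells` is the size of each subclone.
#' @return list with `pair` (an unpaired [AlignedPair-class]) and `truth`
#'   (subclone, phase, batch and doubled gene set for every generated cell,
#'   plus per-domain slices).
#' @export
generateVirtualTumor <- function(cfg = simConfig()) {
  withLocalSeed(cfg$seed, {
    base_cfg <- cfg; base_cfg$n_types <- 1L
    prog <- simPrograms(base_cfg)
    n <- cfg$n_cells
    theta <- stats::runif(n, 0, 2 * pi)
    M <- simSignal(base_cfg, prog, rep("type1", n), theta)
    X1 <- softplus(M + matrix(stats::rnorm(n * cfg$n_genes,
                                           sd = cfg$base_noise_sd), n))
    doubled <- sample(prog$genes,
                      max(1L, round(cfg$subclone_gene_fraction *
                                      cfg$n_genes)))
    X2 <- X1
    X2[, doubled] <- 2 * X2[, doubled]
    X <- rbind(X1, X2)
    subclone <- rep(c("subclone1", "subclone2"), each = n)
    phase <- rep(theta, 2)
    batch <- sample(rep_len(c("batch1", "batch2"), 2 * n))
    X[batch == "batch2", ] <- X[batch == "batch2", ] +
      matrix(stats::rnorm(sum(batch == "batch2") * cfg$n_genes,
                          sd = cfg$noise_sd), sum(batch == "batch2"))
    ids <- sprintf("cell_%04d", seq_len(2 * n))
    b1 <- batch == "batch1"
    src <- DomainDataset(X[b1, , drop = FALSE], cellIds = ids[b1],
                         geneIds = prog$genes, labels = subclone[b1],
                         modality = "rna", role = "source")
    tgt <- DomainDataset(X[!b1, , drop = FALSE], cellIds = ids[!b1],
                         geneIds = prog$genes, modality = "rna",
                         role = "target")
    list(pair = AlignedPair(src, tgt, paired = FALSE),
         truth = list(subclone_of_cell = subclone, phase_of_cell = phase,
                      batch_of_cell = batch, doubled_gene_set = doubled,
                      source_subclone = subclone[b1],
                      target_subclone = subclone[!b1],
                      source_phase = phase[b1], target_phase = phase[!b1]))
  })
}

#' Generate paired or unpaired two-modality data
#'
#' The RNA domain is a cyclic base population. The gene-activity (ATAC)
#' domain pushes the same latent type/cycle programs through a distinct
#' random linear map `(1 - atac_mix) I + atac_mix R` (R a random
#' row-stochastic nonnegative mixing matrix), then applies dropout at
#' `sparsity_atac` and rounds to nonnegative values — a sparser, blurred
#' gene-level summary, as produced from chromatin accessibility. With
#' `paired = TRUE` both modalities profile the same cells (equal counts,
#' identical labels); otherwise the target is an independent cohort from
#' the same type mixture. The source (RNA) is labeled; the target is not.
#'
#' @param cfg a [simConfig()].
#' @param paired joint profiling of the same cells.
#' @return list with `pair` (an [AlignedPair-class]) and `truth` (types and
#'   phases per domain, the cycle/type programs, and the noise-free RNA
#'   signal).
#' @export
generateMultiomics <- function(cfg = simConfig(), paired = FALSE) {
  withLocalSeed(cfg$seed, {
    prog <- simPrograms(cfg)
    n <- cfg$n_cells
    types_s <- sample(rep_len(prog$types, n))
    theta_s <- stats::runif(n, 0, 2 * pi)
    M_s <- simSignal(cfg, prog, types_s, theta_s)
    X_rna <- softplus(M_s + matrix(stats::rnorm(n * cfg$n_genes,
                                                sd = cfg$base_noise_sd), n))

    if (paired) {
      types_t <- types_s; theta_t <- theta_s; M_t <- M_s
    } else {
      types_t <- sample(rep_len(prog$types, n))
      theta_t <- stats::runif(n, 0, 2 * pi)
      M_t <- simSignal(cfg, prog, types_t, theta_t)
    }
    G <- cfg$n_genes
    R <- matrix(stats::runif(G * G), G)
    R <- R / rowSums(R)
    A <- (1 - cfg$atac_mix) * diag(G) + cfg$atac_mix * R
    V <- softplus(M_t %*% A)
    keep <- matrix(stats::runif(n * G) >= cfg$sparsity_atac, n)
    X_atac <- round(V * keep)

    src <- DomainDataset(X_rna, cellIds = sprintf("rna_%04d", seq_len(n)),
                         geneIds = prog$genes, labels = types_s,
                         modality = "rna", role = "source")
    tgt <- DomainDataset(
      X_atac,
      cellIds = if (paired) cellIds(src) else
        sprintf("atac_%04d", seq_len(n)),
      geneIds = prog$genes, modality = "atac_gene_activity",
      role = "target")
    list(pair = AlignedPair(src, tgt, paired = paired),
         truth = list(source_type = types_s, target_type = types_t,
                      source_phase = theta_s, target_phase = theta_t,
                      cycle_genes = prog$cycle_genes,
                      type_programs = prog$type_programs,
                      signal_rna = softplus(M_s),
                      signal_atac_input = M_t))
  })
}
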
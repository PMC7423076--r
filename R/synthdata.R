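## Synthetic data generators with known ground truth: multi-dataset FPKM
## matrices with implanted gene archetypes for the screen, and replicated Cq
## experiments with a known stability ordering for the qPCR arm.

#' Configuration for the screen simulator
#'
#' Defines a multi-dataset FPKM simulation with implanted gene archetypes:
#' `ideal_stable` (mid-quartile mean, low dispersion, near-normal noise),
#' `high_expresser` (top-quartile, high variance), `low_noisy`
#' (bottom-quartile, overdispersed), `skewed` (heavy lognormal tail at
#' mid expression), `stopword_tagged`, `locus_adjacent` and `zero_dropout`
#' (each an ideal-profile gene doomed by construction to one specific
#' filter). Remaining genes are background with lognormally spread means and
#' a wide dispersion range. Fractions must sum to <= 1.
#'
#' @param nDatasets number of datasets (default 4).
#' @param nGenes genes per dataset (default 500).
#' @param nSamples samples per dataset (default 50; recycled to
#'   `nDatasets`).
#' @param fractions named fractions of the archetypes.
#' @param seed integer RNG seed.
#' @return list of class `"ScreenSimConfig"`.
#' @export
screenSimConfig <- function(nDatasets = 4L, nGenes = 500L, nSamples = 50L,
                            fractions = c(ideal_stable = 0.04,
                                          high_expresser = 0.10,
                                          low_noisy = 0.10,
                                          skewed = 0.10,
                                          stopword_tagged = 0.02,
                                          locus_adjacent = 0.02,
                                          zero_dropout = 0.02),
                            seed = 1L) {
    if (sum(fractions) > 1) stop("archetype fractions must sum to <= 1")
    need <- c("ideal_stable", "high_expresser", "low_noisy", "skewed",
              "stopword_tagged", "locus_adjacent", "zero_dropout")
    missing <- setdiff(need, names(fractions))
    if (length(missing)) fractions[missing] <- 0
    structure(list(nDatasets = as.integer(nDatasets),
                   nGenes = as.integer(nGenes),
                   nSamples = rep_len(as.integer(nSamples), nDatasets),
                   fractions = fractions[need], seed = as.integer(seed)),
              class = "ScreenSimConfig")
}

# positive draws from N(mean, cv * mean) by rejection (truncation at 0 is
# negligible for the cv ranges used, so normality is essentially preserved)
.rposnorm <- function(n, mean, cv) {
    x <- rnorm(n, mean, cv * mean)
    bad <- which(x <= 0)
    while (length(bad)) {
        x[bad] <- rnorm(length(bad), mean, cv * mean)
        bad <- which(x <= 0)
    }
    x
}

.synthKaryotype <- function() {
    majors <- c(11:15, 21:25, 31:35)
    bands <- as.vector(outer(majors, c(1L, 2L, 3L),
                             function(a, b) paste0(a, ".", b)))
    list(lociArms = data.frame(
             chromosome = c("8", "14", "18", "22", "11"),
             arm = "q", stringsAsFactors = FALSE),
         freeChroms = as.character(c(1:7, 9, 10, 12, 13, 15:17, 19:21)),
         bands = bands)
}

#' Simulate multi-dataset screen inputs with ground truth
#'
#' Generates `nDatasets` FPKM-like [ExpressionMatrix-class] objects sharing
#' one gene universe, a gene annotation table, a translocation locus list
#' and per-gene archetype labels. Archetype identity is shared across
#' datasets; expression values are drawn independently per dataset with a
#' dataset-specific global scale factor. Deterministic given the config
#' seed.
#'
#' @param config a [screenSimConfig()].
#' @return list with `matrices` (named list of [ExpressionMatrix-class]),
#'   `annotation`, `loci`, `truth` (data.frame gene_id / archetype) and
#'   `config`.
#' @export
simulateScreenInputs <- function(config = screenSimConfig()) {
    stopifnot(inherits(config, "ScreenSimConfig"))
    set.seed(config$seed)
    n <- config$nGenes
    counts <- round(config$fractions * n)
    archetype <- rep("background", n)
    idx <- seq_len(n)
    at <- 1L
    for (a in names(counts)) {
        if (counts[[a]] > 0) {
            archetype[at:(at + counts[[a]] - 1L)] <- a
            at <- at + counts[[a]]
        }
    }
    ids <- sprintf("G%04d", idx)
    idealLike <- archetype %in% c("ideal_stable", "stopword_tagged",
                                  "locus_adjacent", "zero_dropout")

    # per-gene parameters shared across datasets
    mu <- numeric(n)      # log2 location
    cv <- numeric(n)      # dispersion (sd/mean) for near-normal genes
    mu[idealLike] <- runif(sum(idealLike), 3.7, 4.1)
    cv[idealLike] <- runif(sum(idealLike), 0.44, 0.50)
    bg <- archetype == "background"
    mu[bg] <- runif(sum(bg), 0, 10)
    # edge-weighted dispersion mixture: most housekeeping-like genes spread
    # over a wide cv range, with enriched very-quiet and very-noisy tails
    comp <- sample(1:3, sum(bg), replace = TRUE, prob = c(0.6, 0.2, 0.2))
    cv[bg] <- c(runif(sum(bg), 0.05, 0.90),
                runif(sum(bg), 0.05, 0.20),
                runif(sum(bg), 0.75, 0.90))[seq_len(sum(bg)) +
                                            (comp - 1L) * sum(bg)]
    hi <- archetype == "high_expresser"
    mu[hi] <- runif(sum(hi), 11, 14)
    cv[hi] <- runif(sum(hi), 0.8, 1.2)
    lo <- archetype == "low_noisy"
    mu[lo] <- runif(sum(lo), -2, 0)
    cv[lo] <- runif(sum(lo), 1.2, 1.8)
    sk <- archetype == "skewed"
    mu[sk] <- runif(sum(sk), 3.5, 5.5)
    sdlogSk <- runif(sum(sk), 1.6, 2.0)

    kar <- .synthKaryotype()
    nLoci <- nrow(kar$lociArms)
    lociBandIdx <- sample(seq(11L, length(kar$bands) - 11L), nLoci)
    loci <- data.frame(
        chromosome = kar$lociArms$chromosome,
        arm = kar$lociArms$arm,
        band_label = paste0("q", kar$bands[lociBandIdx]),
        disease = paste0("translocation_", seq_len(nLoci)),
        stringsAsFactors = FALSE)

    chromosome <- sample(kar$freeChroms, n, replace = TRUE)
    arm <- sample(c("p", "q"), n, replace = TRUE)
    band <- sample(kar$bands, n, replace = TRUE)
    adj <- which(archetype == "locus_adjacent")
    if (length(adj)) {
        pick <- sample(nLoci, length(adj), replace = TRUE)
        offset <- sample(-3:3, length(adj), replace = TRUE)
        chromosome[adj] <- kar$lociArms$chromosome[pick]
        arm[adj] <- "q"
        band[adj] <- kar$bands[pmin(pmax(lociBandIdx[pick] + offset, 1L),
                                    length(kar$bands))]
    }
    bandLabel <- paste0(arm, band)

    safeTerms <- c("mitochondrial RNA processing", "protein folding",
                   "vesicle-mediated transport", "tRNA aminoacylation",
                   "cellular metabolic process", "ribosome assembly")
    badTerms <- c("DNA binding transcription factor activity",
                  "nuclear receptor signalling",
                  "response to external stimulus",
                  "transcriptional activation of stress genes")
    goTerms <- lapply(seq_len(n), function(i) {
        if (archetype[i] == "stopword_tagged") {
            c(sample(safeTerms, 1L), sample(badTerms, 1L))
        } else {
            sample(safeTerms, sample(1:2, 1L))
        }
    })
    biotype <- rep("protein_coding", n)
    nc <- sample(which(bg), max(1L, round(0.05 * sum(bg))))
    biotype[nc] <- "lincRNA"

    annotation <- data.frame(
        gene_id = ids, symbol = paste0("SYM", idx), biotype = biotype,
        chromosome = chromosome, arm = arm, band_label = bandLabel,
        stringsAsFactors = FALSE)
    annotation$go_bp_terms <- goTerms
    rownames(annotation) <- ids

    matrices <- vector("list", config$nDatasets)
    names(matrices) <- paste0("DS", seq_len(config$nDatasets))
    for (d in seq_len(config$nDatasets)) {
        ns <- config$nSamples[d]
        scale <- 2^runif(1L, -0.5, 0.5)  # dataset-specific global scale
        m <- matrix(0, n, ns, dimnames = list(
            ids, sprintf("%s_S%03d", names(matrices)[d], seq_len(ns))))
        for (i in idx) {
            base <- scale * 2^mu[i]
            m[i, ] <- if (archetype[i] == "skewed") {
                rlnorm(ns, meanlog = log(base), sdlog = sdlogSk[
                    match(i, which(sk))])
            } else if (archetype[i] == "low_noisy") {
                shape <- 1 / cv[i]^2
                rgamma(ns, shape = shape, rate = shape / base)
            } else {
                .rposnorm(ns, base, cv[i])
            }
        }
        drop <- which(archetype == "zero_dropout")
        if (length(drop) && d == 1L) {
            for (i in drop) m[i, sample(ns, sample(1:3, 1L))] <- 0
        }
        matrices[[d]] <- ExpressionMatrix(m, datasetId = names(matrices)[d])
    }
    list(matrices = matrices, annotation = annotation, loci = loci,
         truth = data.frame(gene_id = ids, archetype = archetype,
                            stringsAsFactors = FALSE),
         config = config)
}

#' Configuration for the Cq experiment simulator
#'
#' @param nPerGroup named integer, samples per group (default 20 malignant,
#'   20 control).
#' @param genes data.frame with columns `gene`, `mu` (true log2 expression
#'   mean), `sigma` (intra-group SD, log2 units), `shift` (log2 shift added
#'   to malignant samples), `ampFactor`, `ntcMean` (cycles). The default
#'   panel carries four reference candidates with an intra-group noise
#'   gradient sigma = 0.05, 0.1, 0.2, 0.4 log2 units and no group shift.
#' @param replicates Cq replicates per reaction (default 3).
#' @param cqNoise per-replicate Cq noise SD in cycles (default 0.1).
#' @param seed integer RNG seed.
#' @return list of class `"CqSimConfig"`.
#' @export
cqSimConfig <- function(nPerGroup = c(malignant = 20L, control = 20L),
                        genes = data.frame(
                            gene = paste0("RG", 1:4),
                            mu = 6, sigma = c(0.05, 0.1, 0.2, 0.4),
                            shift = 0, ampFactor = 2, ntcMean = 38,
                            stringsAsFactors = FALSE),
                        replicates = 3L, cqNoise = 0.1, seed = 1L) {
    stopifnot(all(genes$sigma >= 0), all(genes$ampFactor > 1),
              all(genes$ampFactor <= 2.2), cqNoise >= 0, replicates >= 1L)
    structure(list(nPerGroup = nPerGroup, genes = genes,
                   replicates = as.integer(replicates), cqNoise = cqNoise,
                   seed = as.integer(seed)),
              class = "CqSimConfig")
}

#' Simulate a replicated Cq experiment with known stability ordering
#'
#' Per sample and gene, the true log2 abundance is
#' `mu + shift * [malignant] + N(0, sigma)`; each Cq replicate is
#' `ntcMean - abundance / log2(ampFactor) + N(0, cqNoise)`, so doubling the
#' abundance lowers Cq by exactly one cycle at ampFactor 2. NTC replicates
#' are drawn around `ntcMean` with the same per-replicate noise. The true
#' stability combines intra-group noise and group shift as
#' `sqrt(sigma^2 + shift^2 / 4)` (the between-group variance contribution at
#' balanced groups); the true ordering is ascending in it.
#'
#' @param config a [cqSimConfig()].
#' @return list with `experiment` ([CqExperiment-class]) and `truth`
#'   (data.frame gene / sigma / shift / trueStability / trueRank).
#' @export
simulateCqExperiment <- function(config = cqSimConfig()) {
    stopifnot(inherits(config, "CqSimConfig"))
    set.seed(config$seed)
    gt <- config$genes
    groups <- rep(names(config$nPerGroup), config$nPerGroup)
    ns <- length(groups)
    samples <- sprintf("S%03d", seq_len(ns))
    names(groups) <- samples
    arr <- array(NA_real_, dim = c(ns, nrow(gt), config$replicates),
                 dimnames = list(samples, gt$gene,
                                 paste0("rep", seq_len(config$replicates))))
    for (g in seq_len(nrow(gt))) {
        shift <- ifelse(groups == "malignant", gt$shift[g], 0)
        abundance <- gt$mu[g] + shift + rnorm(ns, 0, gt$sigma[g])
        trueCq <- gt$ntcMean[g] - abundance / log2(gt$ampFactor[g])
        for (r in seq_len(config$replicates)) {
            arr[, g, r] <- trueCq + rnorm(ns, 0, config$cqNoise)
        }
    }
    ntc <- lapply(seq_len(nrow(gt)), function(g)
        gt$ntcMean[g] + rnorm(config$replicates, 0, config$cqNoise))
    names(ntc) <- gt$gene
    exp <- CqExperiment(arr, group = groups, ntcCq = ntc,
                        ampFactor = setNames(gt$ampFactor, gt$gene))
    trueStability <- sqrt(gt$sigma^2 + gt$shift^2 / 4)
    truth <- data.frame(gene = gt$gene, sigma = gt$sigma, shift = gt$shift,
                        trueStability = trueStability,
                        trueRank = rank(trueStability,
                                        ties.method = "average"),
                        stringsAsFactors = FALSE)
    list(experiment = exp, truth = truth)
}
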
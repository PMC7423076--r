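test_that("geNorm M values match the brute-force oracle on a hand table", {
    set.seed(101)
    expr <- matrix(rlnorm(6 * 4, meanlog = 2, sdlog = 0.4), nrow = 6,
                   dimnames = list(paste0("S", 1:6), paste0("g", 1:4)))
    res <- geNorm(expr)
    expect_equal(res$M, oracleGenormM(expr), tolerance = 1e-9)
})

test_that("geNorm: constant-ratio genes share M, noisy genes rank last", {
    s <- paste0("S", 1:8)
    base <- rlnorm(8, 3, 0.3)
    set.seed(55)
    expr <- cbind(j = base, k = 2 * base,
                  noisy = base * 2^rnorm(8, 0, 1))
    rownames(expr) <- s
    res <- geNorm(expr)
    # j and k have identical log ratios everywhere: pairwise variation 0
    expect_equal(sd(log2(expr[, "j"] / expr[, "k"])), 0)
    expect_equal(res$M[["j"]], res$M[["k"]], tolerance = 1e-12)
    expect_equal(res$removalOrder, "noisy")
    expect_equal(unname(res$ranking["noisy", "rank"]), 3)
    expect_equal(unname(res$ranking[c("j", "k"), "rank"]), c(1.5, 1.5))
    # two-gene input: M_1 = M_2 exactly
    res2 <- geNorm(expr[, c("j", "noisy")])
    expect_identical(res2$M[[1]], res2$M[[2]])
    # shift invariance: scaling a gene by a constant leaves M unchanged
    expr2 <- expr; expr2[, "j"] <- expr2[, "j"] * 37
    expect_equal(geNorm(expr2)$M, res$M, tolerance = 1e-12)
    # pairwise variation V(n/n+1) present for >= 3 genes
    expect_named(res$pairwiseVariation, "V2/3")
})

test_that("geNorm removes the noisiest gene first in simulation", {
    set.seed(77)
    wins <- 0
    for (i in 1:20) {
        mu <- rlnorm(50, 2, 0.2)
        expr <- cbind(a = mu * 2^rnorm(50, 0, 0.05),
                      b = mu * 2^rnorm(50, 0, 0.05),
                      noisy = mu * 2^rnorm(50, 0, 1))
        rownames(expr) <- paste0("S", 1:50)
        wins <- wins + (geNorm(expr)$removalOrder[1] == "noisy")
    }
    expect_equal(wins, 20)
})

test_that("NormFinder matches the step-by-step published estimator", {
    # printed toy table: 4 genes x 8 samples, two groups
    expr <- matrix(c(
        10.1, 10.3,  9.8, 10.0, 10.4, 10.2,  9.9, 10.1,
         5.2,  5.0,  5.3,  5.1,  4.9,  5.2,  5.0,  5.3,
         8.0,  8.5,  7.6,  8.2,  9.1,  8.8,  9.0,  9.2,
         3.3,  3.1,  3.4,  3.0,  3.2,  3.5,  3.1,  3.3), ncol = 4)
    expr <- 2^expr
    dimnames(expr) <- list(paste0("S", 1:8), c("w", "x", "y", "z"))
    groups <- rep(c("malignant", "control"), each = 4)
    nf <- normFinder(expr, groups)
    oracle <- oracleNormFinder(expr, groups)
    expect_equal(setNames(nf[names(oracle), "stability"], names(oracle)),
                 oracle, tolerance = 1e-9)
})

test_that("NormFinder rewards panel-constant genes and flags group shifts", {
    # gene deviating from the panel mean by a constant: stability ~ 0
    set.seed(31)
    n <- 24
    groups <- rep(c("malignant", "control"), each = n / 2)
    noise <- matrix(rnorm(n * 3, 0, 0.3), n, 3)
    # gene b carries a genuine group shift so inter-group variance exists
    L <- cbind(5 + noise[, 1],
               7 + noise[, 2] + ifelse(groups == "malignant", 0.8, 0),
               6 + noise[, 3])
    panel <- rowMeans(L)
    L <- cbind(L, flat = panel + 2)  # constant offset from the panel mean
    colnames(L) <- c("a", "b", "c", "flat")
    nf <- normFinder(2^L, groups)
    expect_equal(unname(nf["flat", "rank"]), 1)
    expect_lt(nf["flat", "stability"], min(nf[c("a", "b", "c"), "stability"]))
    # a 1-log2 group shift is penalized against an identical twin
    hits <- 0
    for (i in 1:25) {
        set.seed(400 + i)
        gshift <- ifelse(groups == "malignant", 1, 0)
        tw <- matrix(rnorm(n * 2, 0, 0.1), n, 2)
        M <- cbind(twinA = 6 + tw[, 1], twinB = 6 + tw[, 2] + gshift,
                   anch1 = 5 + rnorm(n, 0, 0.1), anch2 = 7 + rnorm(n, 0, 0.1))
        r <- normFinder(2^M, groups)
        hits <- hits + (r["twinB", "stability"] > r["twinA", "stability"])
    }
    expect_gte(hits, 24)
    # degenerate groups are rejected
    expect_error(normFinder(2^L, c("a", rep("b", n - 1))), ">= 2 samples")
})

test_that("BestKeeper matches its oracle and its closed-form cases", {
    set.seed(19)
    cq <- matrix(rnorm(15, 28, 1.5), 5, 3,
                 dimnames = list(paste0("S", 1:5), c("g1", "g2", "g3")))
    bk <- bestKeeper(cq)
    oracle <- oracleBestKeeper(cq)
    expect_equal(unname(bk$sd), oracle$sd, tolerance = 1e-9)
    expect_equal(unname(bk$cvPct), oracle$cvPct, tolerance = 1e-9)
    expect_equal(unname(bk$r), oracle$r, tolerance = 1e-9)
    # constant-Cq gene: SD 0, rank 1
    cq2 <- cbind(cq, flat = 25)
    bk2 <- bestKeeper(cq2)
    expect_equal(unname(bk2["flat", "sd"]), 0)
    expect_equal(unname(bk2["flat", "rank"]), 1)
    # a gene equal to the index correlates perfectly
    idx <- S4Vectors::metadata(bk)$index
    cq3 <- cbind(cq, mirror = idx)
    expect_equal(unname(bestKeeper(cq3)["mirror", "r"]), 1, tolerance = 1e-9)
    # ranking is invariant to sample order
    perm <- sample(nrow(cq))
    expect_equal(bestKeeper(cq[perm, ])$rank, bk$rank)
})

test_that("delta-Ct scores match brute force and ignore constant offsets", {
    set.seed(23)
    cq <- matrix(rnorm(24, 30, 1), 6, 4,
                 dimnames = list(paste0("S", 1:6), paste0("g", 1:4)))
    dc <- deltaCtMethod(cq)
    expect_equal(setNames(dc$score, rownames(dc)), oracleDeltaCt(cq),
                 tolerance = 1e-9)
    # adding a sample-independent offset to any gene changes nothing
    cq2 <- cq; cq2[, 2] <- cq2[, 2] + 7
    expect_equal(deltaCtMethod(cq2)$score, dc$score, tolerance = 1e-12)
    # a gene at constant offset from another contributes sd-0 pairs
    cq3 <- cbind(cq[, 1:2], echo = cq[, 1] + 3)
    expect_equal(sd(cq3[, "echo"] - cq3[, 1]), 0)
})

test_that("consensus and comprehensive ranks are geometric means", {
    ranks <- list(m1 = c(a = 1, b = 2, c = 3),
                  m2 = c(a = 2, b = 1, c = 3),
                  m3 = c(a = 4, b = 2, c = 3),
                  m4 = c(a = 8, b = 2, c = 3))
    cr <- consensusRank(ranks)
    expect_equal(unname(cr["a", "geomean"]), (1 * 2 * 4 * 8)^(1 / 4))
    expect_equal(round(unname(cr["a", "geomean"]), 3), 2.828)
    # permutation invariance in method order
    expect_equal(as.data.frame(consensusRank(rev(ranks))),
                 as.data.frame(cr))
    # unanimous orderings pass through
    un <- replicate(4, c(x = 1, y = 2, z = 3), simplify = FALSE)
    expect_equal(rownames(consensusRank(un)), c("x", "y", "z"))
    # geometric mean is bounded by min and max rank
    gm <- cr$geomean
    mins <- apply(vapply(ranks, function(r) r[rownames(cr)], numeric(3)),
                  1, min)
    maxs <- apply(vapply(ranks, function(r) r[rownames(cr)], numeric(3)),
                  1, max)
    expect_true(all(gm >= mins - 1e-12 & gm <= maxs + 1e-12))
    expect_error(consensusRank(list(c(a = 1), c(b = 1))), "different gene")
})

test_that("rankStability integrates the four methods on a CqExperiment", {
    sim <- simulateCqExperiment(cqSimConfig(seed = 7))
    st <- rankStability(sim$experiment, groups = NA)
    expect_setequal(rownames(st), paste0("RG", 1:4))
    # per-method ranks are permutations of 1..n up to average ties
    for (col in c("normfinder_rank", "bestkeeper_rank", "deltact_rank")) {
        expect_equal(sort(unname(st[[col]])), 1:4)
    }
    expect_equal(sort(unname(st$genorm_rank)), c(1.5, 1.5, 3, 4))
    # scores are non-negative; correlations within [-1, 1]
    expect_true(all(st$genorm_m >= 0) && all(st$normfinder_stability >= 0) &&
                all(st$bestkeeper_sd >= 0) && all(st$deltact_score >= 0))
    expect_true(all(abs(st$bestkeeper_r) <= 1))
    # the noise gradient is recovered by the comprehensive rank (this seed)
    expect_equal(rownames(st), paste0("RG", 1:4))
    # determinism: identical seed, identical report
    st2 <- rankStability(simulateCqExperiment(cqSimConfig(seed = 7))$experiment,
                         groups = NA)
    expect_identical(as.data.frame(st), as.data.frame(st2))
})
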
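test_that("quartile assignment splits by median rank with stable ties", {
    m4 <- matrix(rep(c(1, 2, 3, 4), each = 2), nrow = 4, byrow = FALSE)
    m4 <- matrix(c(1, 1, 2, 2, 3, 3, 4, 4), nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("G", 1:4), c("S1", "S2")))
    expect_equal(unname(assignQuartiles(m4)), 1:4)
    m8 <- matrix(rep(1:8, 3), nrow = 8,
                 dimnames = list(paste0("G", 1:8), paste0("S", 1:3)))
    expect_equal(unname(assignQuartiles(m8)), rep(1:4, each = 2))
    # tie across a boundary: resolved by lexicographic gene id
    mt <- matrix(rep(c(1, 2, 2, 3), 3), nrow = 4,
                 dimnames = list(c("Gb", "Ga", "Gc", "Gd"), paste0("S", 1:3)))
    q <- assignQuartiles(mt)
    expect_equal(q[["Gb"]], 1L)
    expect_equal(q[["Ga"]], 2L)  # Ga < Gc lexicographically
    expect_equal(q[["Gc"]], 3L)
    expect_equal(q[["Gd"]], 4L)
    # partition sizes differ by at most one, union is the gene set
    set.seed(1)
    mr <- matrix(rexp(35 * 5), nrow = 35,
                 dimnames = list(sprintf("G%02d", 1:35), paste0("S", 1:5)))
    qr <- assignQuartiles(mr)
    expect_true(max(abs(table(qr) - 35 / 4)) <= 1)
    expect_setequal(names(qr), rownames(mr))
    expect_error(assignQuartiles(mr[1:3, ]), ">= 4 genes")
})

test_that("middle-quartile filter needs Q2/Q3 in every dataset", {
    q <- list(c(A = 2L, B = 2L, C = 1L, D = 3L),
              c(A = 3L, B = 2L, C = 2L, D = 3L),
              c(A = 2L, B = 2L, C = 2L, D = 4L))
    kept <- middleQuartileFilter(q)
    expect_setequal(as.character(kept), c("A", "B"))
    # gene absent from one dataset is dropped and reported
    q2 <- list(c(A = 2L, B = 2L), c(A = 2L))
    kept2 <- middleQuartileFilter(q2)
    expect_equal(as.character(kept2), "A")
    expect_equal(attr(kept2, "dropped_absent"), "B")
})

test_that("stability metrics match hand computations and flag degeneracy", {
    x <- c(1, 2, 3, 4, 100)
    m <- rbind(gene = x)
    colnames(m) <- paste0("S", 1:5)
    st <- stabilityMetrics(m)
    expect_equal(st["gene", "madNorm"], 1 / 3)  # median 3, median|x-3| = 1
    expect_equal(st["gene", "cv"], sd(x) / mean(x))
    # constant positive vector: zero dispersion, flagged for normality only
    mc <- rbind(flat = rep(5, 6), ok = c(1, 2, 3, 4, 5, 6))
    colnames(mc) <- paste0("S", 1:6)
    stc <- stabilityMetrics(mc)
    expect_equal(stc["flat", "cv"], 0)
    expect_equal(stc["flat", "madNorm"], 0)
    expect_true(stc["flat", "flagged"])
    # heavily skewed gene at n = 100 is far from normal
    set.seed(7)
    sk <- rbind(sk = rlnorm(100, 0, 2))
    colnames(sk) <- paste0("S", 1:100)
    expect_gt(stabilityMetrics(sk)["sk", "oneMinusP"], 0.95)
    # agreement with a direct shapiro.test call
    set.seed(8)
    g <- rbind(g = rnorm(30, 10, 1)); colnames(g) <- paste0("S", 1:30)
    expect_equal(stabilityMetrics(g)["g", "oneMinusP"],
                 1 - shapiro.test(g["g", ])$p.value)
    # zero-mean and zero-median genes are flagged, not NaN-propagated
    mz <- rbind(zm = c(0, 0, 0, 0), zmed = c(0, 0, 0, 8), ok = c(1, 2, 3, 4))
    colnames(mz) <- paste0("S", 1:4)
    stz <- stabilityMetrics(mz)
    expect_true(stz["zm", "flagged"])
    expect_equal(stz["zmed", "flagReason"], "zero median")
})

test_that("z-scoring standardizes each parameter over the gene scope", {
    set.seed(11)
    m <- matrix(rexp(40 * 10, rate = 0.1), nrow = 40,
                dimnames = list(sprintf("G%02d", 1:40), paste0("S", 1:10)))
    st <- stabilityMetrics(m)
    z <- zscoreStats(st)
    expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-9)
    expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-9)
    # agreement with a direct (x - mean)/sd computation
    expect_equal(unname(z[, "z_cv"]),
                 unname((st$cv - mean(st$cv)) / sd(st$cv)))
    # two genes give a symmetric pair summing to zero
    z2 <- zscoreStats(st, genes = rownames(st)[1:2])
    expect_equal(sum(z2[, "z_cv"]), 0, tolerance = 1e-12)
})

test_that("PAM clustering picks k by silhouette and the origin-near blob", {
    set.seed(3)
    blobA <- matrix(rnorm(60 * 3, 0, 0.2), ncol = 3)     # near origin
    blobB <- matrix(rnorm(40 * 3, 4, 0.2), ncol = 3)     # far blob
    z <- rbind(blobA, blobB)
    rownames(z) <- sprintf("G%03d", seq_len(nrow(z)))
    colnames(z) <- c("z_cv", "z_mad", "z_one_minus_p")
    res <- clusterAndSelect(z, kRange = 2:6)
    expect_equal(res$k, 2L)
    expect_setequal(res$selectedGenes, rownames(z)[1:60])
    # medoids are member genes of their clusters
    expect_true(all(res$assignment[res$medoidGenes] ==
                    seq_along(res$medoidGenes)))
    # selected cluster minimizes the medoid z-norm
    norms <- sqrt(rowSums(res$medoidZ^2))
    expect_equal(res$selectedCluster, unname(which.min(norms)))
    # identical points degenerate to a single cluster with a warning
    zid <- matrix(1, nrow = 8, ncol = 3,
                  dimnames = list(paste0("G", 1:8), colnames(z)))
    expect_warning(deg <- clusterAndSelect(zid), "identical")
    expect_equal(deg$k, 1L)
    expect_setequal(deg$selectedGenes, rownames(zid))
})

test_that("cluster intersection is an exact set intersection", {
    expect_setequal(
        intersectSelectedClusters(list(c("A", "B", "C"), c("B", "C", "D"))),
        c("B", "C"))
    expect_equal(intersectSelectedClusters(list(c("X", "Y"))), c("X", "Y"))
    sets <- replicate(4, sample(LETTERS, 12), simplify = FALSE)
    brute <- LETTERS[vapply(LETTERS, function(g)
        all(vapply(sets, function(s) g %in% s, logical(1))), logical(1))]
    expect_setequal(intersectSelectedClusters(sets), brute)
    expect_warning(intersectSelectedClusters(list("A", "B")), "empty")
})

test_that("GO stop-word filter removes case-insensitive substring matches", {
    ann <- makeTinyAnnotation()
    kept <- filterGoStopwords(paste0("G", 1:5), ann)
    # G2 has "DNA binding"; G4 has "Transcription Factor activity"
    expect_setequal(as.character(kept), c("G1", "G3", "G5"))
    removed <- attr(kept, "removed")
    expect_setequal(removed$gene, c("G2", "G4"))
    # empty GO set is retained (G3)
    expect_true("G3" %in% kept)
})

test_that("distance ranking follows the Euclidean norm of the z-triple", {
    # closed forms: origin and 3-4-5 triple
    expect_equal(sqrt(sum(c(0, 0, 0)^2)), 0)
    set.seed(21)
    m1 <- matrix(rexp(30 * 8, 0.2), nrow = 30,
                 dimnames = list(sprintf("G%02d", 1:30), paste0("S", 1:8)))
    m2 <- matrix(rexp(30 * 8, 0.3), nrow = 30, dimnames = dimnames(m1))
    stats <- list(a = stabilityMetrics(m1), b = stabilityMetrics(m2))
    genes <- rownames(m1)
    d <- rankByDistance(stats, genes)
    # per-dataset distances equal a direct z-norm computation
    z1 <- zscoreStats(stats$a, genes)
    expect_equal(unname(d[, "d_a"]), unname(sqrt(rowSums(z1^2))))
    expect_equal(unname(d$dbar), unname((d[, "d_a"] + d[, "d_b"]) / 2))
    # strictly-below-median retention: floor(n/2) genes for unique dbar
    expect_equal(sum(d$kept), floor(length(genes) / 2))
    # permutation invariance of the three z-coordinates
    zp <- z1[, c(3, 1, 2)]
    expect_equal(unname(sqrt(rowSums(zp^2))), unname(d[, "d_a"]))
})

test_that("translocation proximity uses ordinal band distance per arm", {
    bands <- c("11.1", "11.2", "12", "13", "21.1")
    # enumeration oracle: 11.1 vs 21.1 are 4 bands apart
    expect_equal(oracleBandDistance(bands, "11.1", "21.1"), 4)
    ann <- data.frame(
        gene_id = c("Gsame", "Gotherarm", "Gnear", "Gfar"),
        symbol = NA, biotype = "protein_coding",
        chromosome = c("18", "18", "18", "18"),
        arm = c("q", "p", "q", "q"),
        band_label = c("q21.3", "p11", "q11.1", "q21.1"),
        stringsAsFactors = FALSE)
    ann$go_bp_terms <- replicate(4, character(), simplify = FALSE)
    loci <- data.frame(chromosome = "18", arm = "q", band_label = "q21.3",
                       disease = "x", stringsAsFactors = FALSE)
    # universe on 18q: 11.1, 21.1, 21.3 -> distances 2 and 1
    kept <- filterTranslocationProximity(ann$gene_id, ann, loci,
                                         maxBandDistance = 10)
    expect_setequal(as.character(kept), "Gotherarm")  # same arm all removed
    kept1 <- filterTranslocationProximity(ann$gene_id, ann, loci,
                                          maxBandDistance = 1)
    expect_setequal(as.character(kept1), c("Gotherarm", "Gnear"))
    expect_equal(attr(kept, "removed")$distance[
        attr(kept, "removed")$gene == "Gsame"], 0)
    # missing band data retains the gene with a warning
    annNA <- ann; annNA$band_label[1] <- NA
    expect_warning(keptNA <- filterTranslocationProximity(
        ann$gene_id, annNA, loci), "no band data")
    expect_true("Gsame" %in% keptNA)
    # unparseable labels are hard errors naming the label
    annBad <- ann; annBad$band_label[2] <- "nonsense"
    expect_error(filterTranslocationProximity("Gotherarm", annBad, loci),
                 "nonsense")
    # a fuller cytoband universe stretches ordinal distances
    cyto <- data.frame(
        chromosome = "18", arm = "q",
        band_label = paste0("q", c("11.1", "11.2", "12", "13", "21.1",
                                   "21.2", "21.3", "22", "23")),
        stringsAsFactors = FALSE)
    # Gnear (q11.1) vs locus (q21.3): ordinal distance 6 in this universe
    expect_equal(oracleBandDistance(sub("^q", "", cyto$band_label),
                                    "11.1", "21.3"), 6)
    kept2 <- filterTranslocationProximity("Gnear", ann, loci,
                                          maxBandDistance = 5,
                                          cytobands = cyto)
    expect_equal(as.character(kept2), "Gnear")
    kept3 <- filterTranslocationProximity("Gnear", ann, loci,
                                          maxBandDistance = 6,
                                          cytobands = cyto)
    expect_equal(as.character(kept3), character(0))
})

test_that("non-zero filter demands positive minima in every dataset", {
    m1 <- matrix(c(1, 2, 0, 3, 4, 5), nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("S1", "S2")))
    m2 <- matrix(c(1, 1, 1, 1, 1, 1), nrow = 3, dimnames = dimnames(m1))
    expect_setequal(filterNonzero(c("A", "B", "C"), list(m1, m2)),
                    c("A", "B"))  # C has a zero in m1
    # brute-force min check on random data with implanted zeros
    set.seed(5)
    mr <- matrix(rexp(50), nrow = 10,
                 dimnames = list(paste0("G", 1:10), paste0("S", 1:5)))
    mr[cbind(c(2, 7), c(3, 1))] <- 0
    brute <- rownames(mr)[apply(mr, 1, min) > 0]
    expect_setequal(filterNonzero(rownames(mr), list(mr)), brute)
})

test_that("composite quartile rank shortlists CQR 8-10", {
    q <- list(c(A = 2L, B = 2L, C = 3L, D = 2L),
              c(A = 2L, B = 2L, C = 3L, D = 3L),
              c(A = 2L, B = 3L, C = 3L, D = 3L),
              c(A = 2L, B = 3L, C = 3L, D = 3L))
    res <- compositeQuartileRank(q, c("A", "B", "C", "D"))
    expect_equal(unname(res$cqr), c(8L, 10L, 12L, 11L))
    expect_equal(unname(res$shortlisted), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("filters are pure subset operations and idempotent", {
    sim <- simulateScreenInputs(screenSimConfig(nGenes = 120, seed = 42))
    genes <- sim$truth$gene_id
    suppressWarnings({
        g1 <- as.character(filterGoStopwords(genes, sim$annotation))
        g2 <- as.character(filterTranslocationProximity(
            g1, sim$annotation, sim$loci))
        g3 <- filterNonzero(g2, sim$matrices)
    })
    expect_true(all(g1 %in% genes))
    expect_true(all(g2 %in% g1))
    expect_true(all(g3 %in% g2))
    suppressWarnings({
        expect_identical(
            as.character(filterGoStopwords(g1, sim$annotation)), g1)
        expect_identical(as.character(filterTranslocationProximity(
            g2, sim$annotation, sim$loci)), g2)
    })
    expect_identical(filterNonzero(g3, sim$matrices), g3)
})

test_that("the full screen recovers implanted stable genes", {
    sim <- simulateScreenInputs(screenSimConfig(seed = 2024))
    res <- suppressMessages(suppressWarnings(runScreen(
        sim$matrices, sim$annotation, sim$loci, seed = 2024,
        verbose = FALSE)))
    short <- rownames(res$ranking)
    truth <- sim$truth
    ideal <- truth$gene_id[truth$archetype == "ideal_stable"]
    expect_gte(mean(ideal %in% short), 0.9)
    # archetypes doomed by construction never appear
    for (a in c("stopword_tagged", "locus_adjacent", "zero_dropout",
                "high_expresser", "low_noisy", "skewed")) {
        expect_equal(sum(truth$gene_id[truth$archetype == a] %in% short), 0)
    }
    # stage counts only ever decrease
    expect_true(all(diff(res$stageCounts) <= 0))
    # ranking is ascending in dbar
    expect_false(is.unsorted(res$ranking$dbar))
    # rerunning with the same seed reproduces the table bit for bit
    sim2 <- simulateScreenInputs(screenSimConfig(seed = 2024))
    res2 <- suppressMessages(suppressWarnings(runScreen(
        sim2$matrices, sim2$annotation, sim2$loci, seed = 2024,
        verbose = FALSE)))
    expect_identical(as.data.frame(res$ranking), as.data.frame(res2$ranking))
})
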
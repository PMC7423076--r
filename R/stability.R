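## Reference-gene stability algorithms: geNorm, NormFinder, BestKeeper, the
## comparative delta-Ct method, a RefFinder-style consensus and the
## comprehensive geometric-mean rank.

.checkExprMatrix <- function(expr, minGenes = 2L, minSamples = 2L,
                             positive = TRUE) {
    expr <- as.matrix(expr)
    if (is.null(colnames(expr))) {
        colnames(expr) <- paste0("gene", seq_len(ncol(expr)))
    }
    if (ncol(expr) < minGenes) stop("need >= ", minGenes, " genes")
    if (nrow(expr) < minSamples) stop("need >= ", minSamples, " samples")
    if (positive && (any(!is.finite(expr)) || any(expr <= 0))) {
        stop("expression values must be positive and finite")
    }
    expr
}

.genormM <- function(L) {
    # L: samples x genes on the log scale; M_j = mean over k != j of
    # sd over samples of (L_j - L_k)
    k <- ncol(L)
    M <- numeric(k)
    for (j in seq_len(k)) {
        vs <- vapply(seq_len(k)[-j], function(i) sd(L[, j] - L[, i]),
                     numeric(1L))
        M[j] <- mean(vs)
    }
    names(M) <- colnames(L)
    M
}

#' geNorm expression stability (M value) with stepwise exclusion
#'
#' For each gene pair the pairwise variation is the standard deviation over
#' samples of the log2 expression ratio; a gene's M value is the mean of its
#' pairwise variations against all other genes. The least stable (highest M)
#' gene is removed and M recomputed until two genes remain; those two cannot
#' be ordered by the algorithm and share rank 1.5. The pairwise variation
#' V(n/n+1) is the standard deviation over samples of the log2 ratio of
#' normalization factors (geometric means) built from the n and n+1 most
#' stable genes.
#'
#' @param expr numeric matrix, samples x genes, of positive relative
#'   expression values (>= 2 genes, >= 2 samples).
#' @param logBase logarithm base for expression ratios (default 2).
#' @return list with `M` (full-panel M values), `ranking`
#'   ([S4Vectors::DataFrame] with `M` at exclusion and `rank`),
#'   `removalOrder` (least stable first) and `pairwiseVariation`
#'   (named `V2/3`, `V3/4`, ...; `NULL` for fewer than 3 genes).
#' @export
geNorm <- function(expr, logBase = 2) {
    expr <- .checkExprMatrix(expr, minGenes = 2L)
    expr <- expr[, order(colnames(expr)), drop = FALSE]
    L <- log(expr, base = logBase)
    k <- ncol(L)
    fullM <- .genormM(L)
    cur <- colnames(L)
    removal <- character(0)
    exclusionM <- fullM
    while (length(cur) > 2L) {
        M <- .genormM(L[, cur, drop = FALSE])
        worst <- names(M)[which.max(M)]  # ties: first in gene-id order
        exclusionM[worst] <- M[worst]
        removal <- c(removal, worst)
        cur <- setdiff(cur, worst)
    }
    exclusionM[cur] <- .genormM(L[, cur, drop = FALSE])
    genes <- colnames(L)
    rank <- setNames(rep(1.5, k), genes)
    if (length(removal)) {
        rank[removal] <- seq(k, 3L, by = -1L)
    }
    stabilityOrder <- c(sort(cur), rev(removal))
    V <- NULL
    if (k >= 3L) {
        V <- numeric(k - 2L)
        nf <- function(n) exp(rowMeans(log(
            expr[, stabilityOrder[seq_len(n)], drop = FALSE])))
        for (n in 2:(k - 1L)) {
            V[n - 1L] <- sd(log(nf(n) / nf(n + 1L), base = logBase))
        }
        names(V) <- paste0("V", 2:(k - 1L), "/", 3:k)
    }
    list(M = fullM,
         ranking = S4Vectors::DataFrame(M = exclusionM[genes],
                                        rank = rank[genes],
                                        row.names = genes),
         removalOrder = removal,
         pairwiseVariation = V)
}

#' NormFinder model-based stability value
#'
#' Implements the published model-based variance estimator on the log scale.
#' Expression values are log-transformed and centred per sample on the gene
#' panel mean. Within each group, the per-gene intra-group variance is
#' estimated with the bias correction that accounts for the panel centring;
#' the per-gene, per-group deviation of the group mean from the panel
#' average (the inter-group bias) is shrunk toward zero in proportion to its
#' sampling variance (empirical Bayes). The stability value is the mean over
#' groups of |shrunk bias| + posterior SD; lower is more stable. With a
#' single group (or `groups = NULL`) the simplified variant returns the
#' square root of the corrected per-gene variance.
#'
#' @param expr numeric matrix, samples x genes (>= 3 genes), of positive
#'   relative expression values.
#' @param groups factor/character of group labels per sample (>= 2 samples
#'   per group), or `NULL` for the ungrouped variant.
#' @param log log-transform the input (default `TRUE`; set `FALSE` if `expr`
#'   is already on a log scale).
#' @param logBase logarithm base (default 2).
#' @return [S4Vectors::DataFrame] with columns `stability` and `rank`.
#' @export
normFinder <- function(expr, groups = NULL, log = TRUE, logBase = 2) {
    expr <- .checkExprMatrix(expr, minGenes = 3L, minSamples = 2L,
                             positive = log)
    L <- if (log) base::log(expr, base = logBase) else expr
    k <- ncol(L)
    z <- L - rowMeans(L)  # centre each sample on the gene-panel mean
    if (is.null(groups) || length(unique(as.character(groups))) < 2L) {
        s2 <- apply(z, 2L, var)
        sig2 <- pmax(0, (s2 - sum(s2) / (k * (k - 1))) * k / (k - 2))
        stab <- sqrt(sig2)
    } else {
        groups <- as.factor(groups)
        if (length(groups) != nrow(L)) {
            stop("'groups' must have one label per sample")
        }
        ng <- table(groups)
        if (any(ng < 2L)) {
            stop("every group needs >= 2 samples; offending group(s): ",
                 paste(names(ng)[ng < 2L], collapse = ", "))
        }
        G <- nlevels(groups)
        d <- matrix(NA_real_, k, G, dimnames = list(colnames(L),
                                                    levels(groups)))
        vardi <- d
        for (g in levels(groups)) {
            zg <- z[groups == g, , drop = FALSE]
            d[, g] <- colMeans(zg)
            s2 <- apply(zg, 2L, var)
            sig2 <- pmax(0, (s2 - sum(s2) / (k * (k - 1))) * k / (k - 2))
            vardi[, g] <- sig2 / nrow(zg)
        }
        dif <- d - rowMeans(d)  # gene-level offsets are not instability
        gamma2 <- max(0, sum(dif^2) / ((k - 1) * (G - 1)) - mean(vardi))
        denom <- gamma2 + vardi
        shrink <- ifelse(denom > 0, gamma2 / denom, 0)
        difnew <- dif * shrink
        varnew <- vardi * shrink
        stab <- rowMeans(abs(difnew) + sqrt(varnew))
    }
    S4Vectors::DataFrame(stability = stab,
                         rank = rank(stab, ties.method = "average"),
                         row.names = colnames(L))
}

#' BestKeeper descriptive stability statistics
#'
#' Operates on mean Cq values (samples x genes). Following the original
#' tool, the reported "SD" is the mean absolute deviation of a gene's Cq
#' from its arithmetic mean Cq (not the sample standard deviation); CV% is
#' 100 * SD / mean Cq. The BestKeeper index is the per-sample geometric mean
#' of Cq over all candidate genes; each gene's Pearson correlation with the
#' index is reported. Genes are ranked by ascending SD.
#'
#' @param cq numeric matrix, samples x genes, of positive mean Cq values
#'   (>= 2 genes, >= 3 samples).
#' @return [S4Vectors::DataFrame] with columns `sd`, `cvPct`, `r`, `rank`;
#'   the index vector is attached as attribute `"index"` of the result's
#'   metadata and returned in `metadata(x)$index`.
#' @export
bestKeeper <- function(cq) {
    cq <- .checkExprMatrix(cq, minGenes = 2L, minSamples = 3L)
    mu <- colMeans(cq)
    sdev <- colMeans(abs(sweep(cq, 2L, mu)))
    cvPct <- 100 * sdev / mu
    index <- exp(rowMeans(log(cq)))
    r <- apply(cq, 2L, function(col) {
        if (sd(col) == 0 || sd(index) == 0) NA_real_ else cor(col, index)
    })
    out <- S4Vectors::DataFrame(sd = sdev, cvPct = cvPct, r = r,
                                rank = rank(sdev, ties.method = "average"),
                                row.names = colnames(cq))
    S4Vectors::metadata(out)$index <- index
    out
}

#' Comparative delta-Ct stability score
#'
#' For every gene pair the delta-Cq vector over samples is formed; a gene's
#' score is the mean over all partners of the standard deviation of those
#' pairwise delta-Cq vectors. Sample-independent offsets on any gene leave
#' all scores unchanged.
#'
#' @param cq numeric matrix, samples x genes (>= 3 genes), of mean Cq
#'   values.
#' @return [S4Vectors::DataFrame] with columns `score` and `rank`
#'   (ascending score).
#' @export
deltaCtMethod <- function(cq) {
    cq <- .checkExprMatrix(cq, minGenes = 3L, minSamples = 2L,
                           positive = FALSE)
    k <- ncol(cq)
    score <- vapply(seq_len(k), function(j) {
        mean(vapply(seq_len(k)[-j], function(i) sd(cq[, j] - cq[, i]),
                    numeric(1L)))
    }, numeric(1L))
    names(score) <- colnames(cq)
    S4Vectors::DataFrame(score = score,
                         rank = rank(score, ties.method = "average"),
                         row.names = colnames(cq))
}

.geomeanRanks <- function(rankList) {
    stopifnot(length(rankList) >= 1L)
    genes <- sort(names(rankList[[1L]]))
    same <- vapply(rankList, function(r) setequal(names(r), genes),
                   logical(1L))
    if (!all(same)) stop("rank lists cover different gene sets")
    m <- vapply(rankList, function(r) r[genes], numeric(length(genes)))
    gm <- exp(rowMeans(log(matrix(m, nrow = length(genes)))))
    names(gm) <- genes
    gm
}

#' RefFinder-style consensus of method ranks
#'
#' Geometric mean of the per-method stability ranks, ordered ascending with
#' ties broken by gene id. This mirrors the aggregation the RefFinder web
#' tool describes (geometric mean of ranks); any unpublished internal
#' weighting of that tool is not reproduced.
#'
#' @param rankList list of named numeric rank vectors over an identical gene
#'   set (one per method).
#' @return [S4Vectors::DataFrame] with columns `geomean` and `rank`, rows
#'   ordered by ascending geometric mean (ties by gene id).
#' @export
consensusRank <- function(rankList) {
    gm <- .geomeanRanks(rankList)
    ord <- order(gm, names(gm))
    S4Vectors::DataFrame(geomean = gm[ord],
                         rank = rank(gm, ties.method = "average")[ord],
                         row.names = names(gm)[ord])
}

#' Comprehensive stability rank
#'
#' Geometric mean of the stability ranks assigned by each method (by default
#' geNorm, NormFinder, BestKeeper and the RefFinder-style consensus),
#' mirroring the final ranking of a multi-algorithm stability analysis.
#'
#' @inheritParams consensusRank
#' @return as [consensusRank()].
#' @export
comprehensiveRank <- function(rankList) {
    consensusRank(rankList)
}

#' Full stability analysis of a CqExperiment
#'
#' Runs geNorm and NormFinder on relative expression values (E^-deltaCq,
#' replicates aggregated by geometric mean), and BestKeeper and the
#' comparative delta-Ct method on mean Cq values; combines the four method
#' ranks into a RefFinder-style consensus, and computes the comprehensive
#' rank as the geometric mean over `comprehensiveMethods`.
#'
#' @param x a [CqExperiment-class] with >= 3 genes.
#' @param comprehensiveMethods methods entering the comprehensive geometric
#'   mean; subset of `c("geNorm", "NormFinder", "BestKeeper", "deltaCt",
#'   "consensus")`.
#' @param groups group labels for NormFinder. `NULL` (default) uses
#'   `sampleGroups(x)`; `NA` forces the ungrouped variant (appropriate when
#'   the panel has no group structure); otherwise a factor/character per
#'   sample.
#' @return [S4Vectors::DataFrame], one row per gene ordered by ascending
#'   comprehensive rank, with per-method scores and ranks:
#'   `genorm_m`, `genorm_rank`, `normfinder_stability`, `normfinder_rank`,
#'   `bestkeeper_sd`, `bestkeeper_cv`, `bestkeeper_r`, `bestkeeper_rank`,
#'   `deltact_score`, `deltact_rank`, `consensus_geomean`, `consensus_rank`,
#'   `comprehensive_geomean`, `comprehensive_rank`.
#' @export
rankStability <- function(x,
        comprehensiveMethods = c("geNorm", "NormFinder", "BestKeeper",
                                 "consensus"),
        groups = NULL) {
    stopifnot(is(x, "CqExperiment"))
    comprehensiveMethods <- match.arg(comprehensiveMethods,
        c("geNorm", "NormFinder", "BestKeeper", "deltaCt", "consensus"),
        several.ok = TRUE)
    rel <- relativeExpressionMatrix(x)
    mcq <- meanCq(x)
    if (is.null(groups)) {
        groups <- sampleGroups(x)
    } else if (length(groups) == 1L && is.na(groups)) {
        groups <- NULL
    }
    gn <- geNorm(rel)
    nf <- normFinder(rel, groups = groups)
    bk <- bestKeeper(mcq)
    dc <- deltaCtMethod(mcq)
    genes <- sort(geneIds(x))
    ranks <- list(
        geNorm = setNames(gn$ranking[genes, "rank"], genes),
        NormFinder = setNames(nf[genes, "rank"], genes),
        BestKeeper = setNames(bk[genes, "rank"], genes),
        deltaCt = setNames(dc[genes, "rank"], genes))
    cons <- consensusRank(ranks)
    ranks$consensus <- setNames(cons[genes, "rank"], genes)
    comp <- comprehensiveRank(ranks[comprehensiveMethods])
    out <- S4Vectors::DataFrame(
        genorm_m = gn$M[genes],
        genorm_rank = ranks$geNorm,
        normfinder_stability = nf[genes, "stability"],
        normfinder_rank = ranks$NormFinder,
        bestkeeper_sd = bk[genes, "sd"],
        bestkeeper_cv = bk[genes, "cvPct"],
        bestkeeper_r = bk[genes, "r"],
        bestkeeper_rank = ranks$BestKeeper,
        deltact_score = dc[genes, "score"],
        deltact_rank = ranks$deltaCt,
        consensus_geomean = cons[genes, "geomean"],
        consensus_rank = ranks$consensus,
        comprehensive_geomean = comp[genes, "geomean"],
        comprehensive_rank = comp[genes, "rank"],
        row.names = genes)
    out <- out[order(out$comprehensive_rank, rownames(out)), , drop = FALSE]
    S4Vectors::metadata(out)$pairwiseVariation <- gn$pairwiseVariation
    out
}
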
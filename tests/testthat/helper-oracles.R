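# Independent brute-force oracles, written as plain loops over scalars so
# they share no code path with the package implementations.

# geNorm M: for gene j, mean over partners k of sd of log2 ratios
oracleGenormM <- function(expr) {
    k <- ncol(expr)
    M <- numeric(k)
    for (j in seq_len(k)) {
        vs <- c()
        for (p in seq_len(k)) {
            if (p == j) next
            ratios <- numeric(nrow(expr))
            for (s in seq_len(nrow(expr))) {
                ratios[s] <- log2(expr[s, j] / expr[s, p])
            }
            vs <- c(vs, sd(ratios))
        }
        M[j] <- mean(vs)
    }
    names(M) <- colnames(expr)
    M
}

# NormFinder, step-by-step transcription of the published grouped estimator
oracleNormFinder <- function(expr, groups, logBase = 2) {
    L <- log(expr, base = logBase)
    k <- ncol(L)
    groups <- as.factor(groups)
    G <- nlevels(groups)
    # centre each sample on its gene-panel mean
    z <- L
    for (s in seq_len(nrow(L))) z[s, ] <- L[s, ] - mean(L[s, ])
    d <- matrix(0, k, G); vardi <- matrix(0, k, G)
    for (gi in seq_len(G)) {
        zg <- z[groups == levels(groups)[gi], , drop = FALSE]
        ng <- nrow(zg)
        s2 <- numeric(k)
        for (j in seq_len(k)) {
            d[j, gi] <- mean(zg[, j])
            s2[j] <- var(zg[, j])
        }
        for (j in seq_len(k)) {
            sig2 <- (s2[j] - sum(s2) / (k * (k - 1))) * k / (k - 2)
            if (sig2 < 0) sig2 <- 0
            vardi[j, gi] <- sig2 / ng
        }
    }
    dif <- d
    for (j in seq_len(k)) dif[j, ] <- d[j, ] - mean(d[j, ])
    gamma2 <- sum(dif^2) / ((k - 1) * (G - 1)) - mean(vardi)
    if (gamma2 < 0) gamma2 <- 0
    stab <- numeric(k)
    for (j in seq_len(k)) {
        acc <- 0
        for (gi in seq_len(G)) {
            if (gamma2 + vardi[j, gi] > 0) {
                dn <- dif[j, gi] * gamma2 / (gamma2 + vardi[j, gi])
                vn <- vardi[j, gi] * gamma2 / (gamma2 + vardi[j, gi])
            } else {
                dn <- 0; vn <- 0  # no inter-group and no sampling variance
            }
            acc <- acc + abs(dn) + sqrt(vn)
        }
        stab[j] <- acc / G
    }
    names(stab) <- colnames(expr)
    stab
}

# BestKeeper: SD as mean absolute deviation from the arithmetic mean Cq,
# CV% and Pearson r against the per-sample geometric-mean index
oracleBestKeeper <- function(cq) {
    k <- ncol(cq); n <- nrow(cq)
    index <- numeric(n)
    for (s in seq_len(n)) index[s] <- prod(cq[s, ])^(1 / k)
    out <- data.frame(sd = numeric(k), cvPct = numeric(k), r = numeric(k))
    rownames(out) <- colnames(cq)
    for (j in seq_len(k)) {
        m <- mean(cq[, j])
        dev <- 0
        for (s in seq_len(n)) dev <- dev + abs(cq[s, j] - m)
        out$sd[j] <- dev / n
        out$cvPct[j] <- 100 * out$sd[j] / m
        out$r[j] <- cor(cq[, j], index)
    }
    out
}

# comparative delta-Ct: mean over partners of sd of pairwise Cq differences
oracleDeltaCt <- function(cq) {
    k <- ncol(cq)
    sc <- numeric(k)
    for (j in seq_len(k)) {
        vs <- c()
        for (p in seq_len(k)) {
            if (p == j) next
            vs <- c(vs, sd(cq[, j] - cq[, p]))
        }
        sc[j] <- mean(vs)
    }
    names(sc) <- colnames(cq)
    sc
}

# ordinal band distance by explicit enumeration of the sorted band list
oracleBandDistance <- function(bands, a, b) {
    major <- as.numeric(sub("\\..*$", "", bands))
    minor <- ifelse(grepl("\\.", bands),
                    as.numeric(sub("^.*\\.", "", bands)), 0)
    sorted <- bands[order(major, minor)]
    abs(match(a, sorted) - match(b, sorted))
}

# small deterministic Cq fixture: 3 genes x 4 samples x 2 replicates
makeTinyCq <- function() {
    samples <- paste0("S", 1:4)
    genes <- c("GA", "GB", "GC")
    arr <- array(NA_real_, c(4, 3, 2),
                 dimnames = list(samples, genes, c("rep1", "rep2")))
    arr[, "GA", 1] <- c(25.0, 25.5, 26.0, 25.2)
    arr[, "GA", 2] <- c(25.1, 25.4, 26.1, 25.3)
    arr[, "GB", 1] <- c(28.0, 28.2, 28.1, 28.4)
    arr[, "GB", 2] <- c(28.1, 28.3, 28.0, 28.5)
    arr[, "GC", 1] <- c(22.0, 24.0, 23.0, 25.0)
    arr[, "GC", 2] <- c(22.2, 24.1, 23.2, 24.8)
    CqExperiment(arr,
        group = setNames(c("malignant", "malignant", "control", "control"),
                         samples),
        ntcCq = list(GA = c(35, 35.2), GB = c(36, 36.1), GC = c(37, 36.9)),
        ampFactor = c(GA = 2, GB = 1.95, GC = 1.9))
}

# write a small expression table to a temp file
writeTempMatrix <- function(lines, ext = ".tsv") {
    tf <- tempfile(fileext = ext)
    writeLines(lines, tf)
    tf
}

makeTinyAnnotation <- function() {
    data.frame(
        gene_id = paste0("G", 1:5),
        symbol = paste0("SYM", 1:5),
        biotype = c("protein_coding", "protein_coding", "lincRNA",
                    "protein_coding", "protein_coding"),
        chromosome = c("5", "18", "1", "18", "2"),
        arm = c("q", "q", "p", "p", "q"),
        band_label = c("q13.2", "q21.3", "p11", "p11.2", "q22"),
        go_bp_terms = I(list(
            c("mitochondrial RNA processing"),
            c("DNA binding", "protein folding"),
            character(),
            c("Transcription Factor activity"),
            c("vesicle transport"))),
        stringsAsFactors = FALSE,
        row.names = paste0("G", 1:5))
}
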
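## qPCR quantification math: standard-curve amplification factors,
## NTC-anchored delta-Cq, relative expression, normalization factors,
## relative quantification and the two-scheme comparison.

#' Amplification factor from a standard-curve slope
#'
#' E = 10^(-1/slope). A perfect doubling assay has slope
#' -1/log10(2) = -3.3219 and E = 2. The percent efficiency companion,
#' (E - 1) x 100, is a distinct quantity reported by
#' [primerEfficiency()]; the two are often conflated in print.
#'
#' @param slope numeric vector of standard-curve slopes (Cq per log10
#'   dilution); must be negative.
#' @return numeric vector of amplification factors.
#' @examples
#' amplificationFactor(-1 / log10(2))  # 2
#' @export
amplificationFactor <- function(slope) {
    if (any(!is.finite(slope)) || any(slope >= 0)) {
        stop("standard-curve slope must be negative")
    }
    10^(-1 / slope)
}

#' @rdname amplificationFactor
#' @return `primerEfficiency()`: percent efficiency, (E - 1) x 100.
#' @export
primerEfficiency <- function(slope) {
    (amplificationFactor(slope) - 1) * 100
}

#' Delta-Cq against the no-template control
#'
#' deltaCq = Cq(sample) - mean Cq(NTC), computed per replicate against the
#' arithmetic mean of the gene's NTC Cq replicates.
#'
#' @param cq numeric vector/matrix of sample Cq values for one gene.
#' @param ntcCq numeric vector of >= 1 NTC Cq replicates for that gene.
#' @param gene optional gene name used in error messages.
#' @return deltaCq values with the shape of `cq`.
#' @export
deltaCq <- function(cq, ntcCq, gene = NULL) {
    if (length(ntcCq) < 1L || all(is.na(ntcCq))) {
        stop("missing NTC Cq", if (!is.null(gene)) paste0(" for gene ", gene))
    }
    cq - mean(ntcCq, na.rm = TRUE)
}

#' Relative expression E^-deltaCq
#'
#' @param ampFactor amplification factor E (> 1).
#' @param dcq deltaCq value(s).
#' @return E^-deltaCq, strictly positive; equals 1 iff deltaCq is 0.
#' @examples
#' relativeExpression(2, -10)  # 1024
#' @export
relativeExpression <- function(ampFactor, dcq) {
    if (any(ampFactor <= 1)) stop("amplification factor must exceed 1")
    ampFactor^(-dcq)
}

#' @describeIn relativeExpressionMatrix Per-(sample, gene) relative
#'   expression for a [CqExperiment-class]. `reference = "ntc"` (default)
#'   anchors deltaCq on the gene's mean NTC Cq; `reference = "calibrator"`
#'   uses the mean Cq of a designated calibrator sample instead
#'   (conventional mode).
#' @param aggregate replicate aggregation: `"geomean"` (default, geometric
#'   mean of replicate relative expression) or `"mean"` (arithmetic mean).
#' @param reference `"ntc"` or `"calibrator"`.
#' @param calibrator sample id, required when `reference = "calibrator"`.
#' @export
setMethod("relativeExpressionMatrix", "CqExperiment",
    function(x, aggregate = c("geomean", "mean"),
             reference = c("ntc", "calibrator"), calibrator = NULL) {
    aggregate <- match.arg(aggregate)
    reference <- match.arg(reference)
    genes <- geneIds(x)
    samples <- sampleIds(x)
    E <- ampFactor(x)
    anchor <- if (reference == "ntc") {
        vapply(ntcCq(x), mean, numeric(1L))
    } else {
        if (is.null(calibrator) || !calibrator %in% samples) {
            stop("'calibrator' must name a sample of the experiment")
        }
        apply(x@cq[calibrator, , , drop = FALSE], 2L, mean, na.rm = TRUE)
    }
    out <- matrix(NA_real_, length(samples), length(genes),
                  dimnames = list(samples, genes))
    for (g in seq_along(genes)) {
        dcq <- x@cq[, g, , drop = FALSE] - anchor[g]
        rel <- E[g]^(-dcq)
        out[, g] <- if (aggregate == "geomean") {
            exp(apply(log(rel), 1L, mean, na.rm = TRUE))
        } else {
            apply(rel, 1L, mean, na.rm = TRUE)
        }
    }
    out
})

#' Normalization factor: geometric mean of reference-gene expression
#'
#' @param relExpr numeric matrix (samples x genes) of positive relative
#'   expression values, e.g. from [relativeExpressionMatrix()].
#' @param refGenes character vector (>= 1) of reference gene columns.
#' @return named numeric vector: per-sample geometric mean across the
#'   reference set.
#' @export
normalizationFactor <- function(relExpr, refGenes) {
    if (length(refGenes) < 1L) stop("need >= 1 reference gene")
    missing <- setdiff(refGenes, colnames(relExpr))
    if (length(missing)) {
        stop("reference gene(s) absent from the expression table: ",
             paste(missing, collapse = ", "))
    }
    sub <- relExpr[, refGenes, drop = FALSE]
    if (any(!is.finite(sub)) || any(sub <= 0)) {
        stop("relative expression must be positive for all reference genes")
    }
    exp(rowMeans(log(sub)))
}

#' Relative quantification of a target gene
#'
#' RQ = relative expression of the target divided by the per-sample
#' normalization factor (geometric mean of the reference genes).
#'
#' @inheritParams normalizationFactor
#' @param target target gene column name.
#' @return named numeric vector of per-sample RQ values.
#' @export
relativeQuantification <- function(relExpr, target, refGenes) {
    if (!target %in% colnames(relExpr)) {
        stop("target gene ", target, " absent from the expression table")
    }
    nf <- normalizationFactor(relExpr, refGenes)
    relExpr[, target] / nf
}

#' Compare two RQ normalization schemes
#'
#' Two-sided Wilcoxon rank-sum test between per-sample RQ vectors produced
#' by two normalization schemes, with the scheme medians.
#'
#' @param rq1,rq2 numeric RQ vectors (>= 3 samples each).
#' @return list with `medians` (named length-2), `p.value`, `statistic` and
#'   `method`. All-tied inputs yield p = 1 with a warning.
#' @export
compareNormalizationSchemes <- function(rq1, rq2) {
    if (length(rq1) < 3L || length(rq2) < 3L) {
        stop("each scheme needs >= 3 samples")
    }
    med <- c(rq1 = median(rq1), rq2 = median(rq2))
    if (length(unique(c(rq1, rq2))) == 1L) {
        warning("all RQ values tied across both schemes; p = 1")
        return(list(medians = med, p.value = 1, statistic = NA_real_,
                    method = "Wilcoxon rank sum test (degenerate)"))
    }
    wt <- suppressWarnings(wilcox.test(rq1, rq2, exact = FALSE))
    list(medians = med, p.value = wt$p.value, statistic = unname(wt$statistic),
         method = wt$method)
}
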
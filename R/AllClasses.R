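#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats cor median p.adjust rnorm runif rgamma rlnorm sd shapiro.test var wilcox.test quantile setNames
#' @importFrom utils read.table write.table
NULL

#' ExpressionMatrix: a single-dataset gene-by-sample expression container
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' assay named `"exprs"` with non-negative FPKM-like values, plus a dataset
#' identifier. Genes are rows, samples are columns; both must carry unique
#' names.
#'
#' @slot datasetId single character label for the dataset (e.g. `"TCGA-LAML"`).
#'
#' @seealso [ExpressionMatrix()], [readExpressionMatrix()]
#' @export
setClass("ExpressionMatrix",
    contains = "SummarizedExperiment",
    representation(datasetId = "character")
)

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    if (length(object@datasetId) != 1L || is.na(object@datasetId) ||
        !nzchar(object@datasetId)) {
        msg <- c(msg, "'datasetId' must be a single non-empty string")
    }
    if (!"exprs" %in% SummarizedExperiment::assayNames(object)) {
        return(c(msg, "assay 'exprs' is required"))
    }
    v <- SummarizedExperiment::assay(object, "exprs")
    if (is.null(rownames(v)) || is.null(colnames(v))) {
        msg <- c(msg, "gene (row) and sample (column) names are required")
    } else {
        if (anyDuplicated(rownames(v))) {
            msg <- c(msg, sprintf("duplicated gene ids: %s",
                paste(unique(rownames(v)[duplicated(rownames(v))]),
                      collapse = ", ")))
        }
        if (anyDuplicated(colnames(v))) {
            msg <- c(msg, "duplicated sample ids")
        }
    }
    if (anyNA(v)) msg <- c(msg, "expression values must not be NA")
    else if (any(v < 0)) msg <- c(msg, "expression values must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); non-negative.
#' @param datasetId single character dataset label.
#'
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, nrow = 2, dimnames = list(c("G1", "G2"), c("S1", "S2", "S3")))
#' em <- ExpressionMatrix(m, "demo")
#' exprValues(em)
#' @export
ExpressionMatrix <- function(values, datasetId = "dataset") {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values))
    new("ExpressionMatrix", se, datasetId = as.character(datasetId))
}

#' CqExperiment: replicated qPCR quantification cycles with controls
#'
#' Holds replicate Cq values per (sample, gene) as a 3-dimensional array
#' (`sample x gene x replicate`, `NA`-padded for ragged replicate counts),
#' sample group labels, per-gene no-template-control (NTC) Cq replicates and
#' per-gene amplification factors E. All observed Cq values must be positive,
#' every (sample, gene) cell needs at least one replicate, and every gene
#' needs at least one NTC replicate and an amplification factor in (1, 2.2].
#'
#' @slot cq numeric array `sample x gene x replicate` of Cq values (cycles).
#' @slot group factor of sample group labels (e.g. malignant / control),
#'   one per sample, named by sample id.
#' @slot ntcCq named list (by gene) of numeric NTC Cq replicates.
#' @slot ampFactor named numeric (by gene) amplification factors E.
#'
#' @seealso [CqExperiment()], [simulateCqExperiment()], [rankStability()]
#' @export
setClass("CqExperiment",
    representation(
        cq = "array",
        group = "factor",
        ntcCq = "list",
        ampFactor = "numeric"
    )
)

setValidity("CqExperiment", function(object) {
    msg <- character()
    d <- dim(object@cq)
    dn <- dimnames(object@cq)
    if (length(d) != 3L) {
        return("'cq' must be a 3-d array (sample x gene x replicate)")
    }
    if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]])) {
        return("'cq' needs sample and gene dimnames")
    }
    samples <- dn[[1L]]; genes <- dn[[2L]]
    if (anyDuplicated(samples)) msg <- c(msg, "duplicated sample ids")
    if (anyDuplicated(genes)) msg <- c(msg, "duplicated gene ids")
    obs <- object@cq[!is.na(object@cq)]
    if (any(obs <= 0)) msg <- c(msg, "all Cq values must be positive")
    nrep <- apply(!is.na(object@cq), c(1L, 2L), sum)
    if (any(nrep < 1L)) {
        msg <- c(msg, "every (sample, gene) cell needs >= 1 Cq replicate")
    }
    if (length(object@group) != length(samples) ||
        !identical(names(object@group), samples)) {
        msg <- c(msg, "'group' must be named by and aligned with sample ids")
    }
    if (!identical(sort(names(object@ntcCq)), sort(genes))) {
        msg <- c(msg, "'ntcCq' must have one entry per gene")
    } else {
        bad <- vapply(object@ntcCq,
            function(x) length(x) < 1L || any(!is.finite(x)) || any(x <= 0),
            logical(1L))
        if (any(bad)) {
            msg <- c(msg, sprintf("invalid NTC Cq for gene(s): %s",
                paste(names(object@ntcCq)[bad], collapse = ", ")))
        }
    }
    if (!identical(sort(names(object@ampFactor)), sort(genes))) {
        msg <- c(msg, "'ampFactor' must have one entry per gene")
    } else if (any(object@ampFactor <= 1 | object@ampFactor > 2.2)) {
        msg <- c(msg, "amplification factors must lie in (1, 2.2]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CqExperiment
#'
#' @param cq numeric array `sample x gene x replicate` (NA-padded), or a
#'   long-format data.frame with columns `sample`, `gene`, `replicate`, `cq`
#'   (and optionally `group`).
#' @param group factor or character of group labels per sample (named by
#'   sample id, or in sample order). Ignored if `cq` is a long data.frame
#'   carrying a `group` column.
#' @param ntcCq named list (by gene) of NTC Cq replicates, or a named numeric
#'   vector of single NTC values.
#' @param ampFactor named numeric of per-gene amplification factors.
#'
#' @return A [CqExperiment-class] object.
#' @export
CqExperiment <- function(cq, group, ntcCq, ampFactor) {
    if (is.data.frame(cq)) {
        long <- cq
        need <- c("sample", "gene", "replicate", "cq")
        if (!all(need %in% names(long))) {
            stop("long-format 'cq' needs columns: ",
                 paste(need, collapse = ", "))
        }
        samples <- unique(as.character(long$sample))
        genes <- unique(as.character(long$gene))
        reps <- sort(unique(as.integer(long$replicate)))
        arr <- array(NA_real_,
            dim = c(length(samples), length(genes), length(reps)),
            dimnames = list(samples, genes, paste0("rep", reps)))
        idx <- cbind(match(as.character(long$sample), samples),
                     match(as.character(long$gene), genes),
                     match(as.integer(long$replicate), reps))
        arr[idx] <- as.numeric(long$cq)
        if (missing(group) && "group" %in% names(long)) {
            group <- vapply(samples, function(s)
                as.character(long$group[match(s, as.character(long$sample))]),
                character(1L))
        }
        cq <- arr
    }
    samples <- dimnames(cq)[[1L]]
    genes <- dimnames(cq)[[2L]]
    group <- as.factor(group)
    if (is.null(names(group))) names(group) <- samples
    group <- group[samples]
    names(group) <- samples
    if (is.numeric(ntcCq)) ntcCq <- as.list(ntcCq)
    ntcCq <- lapply(ntcCq, as.numeric)[genes]
    names(ntcCq) <- genes
    ampFactor <- ampFactor[genes]
    names(ampFactor) <- genes
    new("CqExperiment", cq = cq, group = group, ntcCq = ntcCq,
        ampFactor = ampFactor)
}
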
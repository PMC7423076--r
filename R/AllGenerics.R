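#' @rdname ExpressionMatrix-class
#' @param object,x an `ExpressionMatrix` or `CqExperiment`.
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname CqExperiment-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname CqExperiment-class
#' @export
setGeneric("ntcCq", function(x) standardGeneric("ntcCq"))

#' @rdname CqExperiment-class
#' @export
setGeneric("ampFactor", function(x) standardGeneric("ampFactor"))

#' @rdname CqExperiment-class
#' @export
setGeneric("meanCq", function(x) standardGeneric("meanCq"))

#' Relative expression matrix from a CqExperiment
#'
#' Computes per-(sample, gene) relative expression `E^-deltaCq`, where by
#' default `deltaCq = Cq(sample replicate) - mean Cq(NTC)` for the gene, and
#' replicates are aggregated by geometric mean of their relative expression
#' (equivalent to the arithmetic mean of replicate delta-Cq on the log scale).
#'
#' @param x a [CqExperiment-class].
#' @param ... passed to methods; see [relativeExpressionMatrix,CqExperiment-method].
#' @return numeric matrix, samples x genes, of positive relative expression.
#' @export
setGeneric("relativeExpressionMatrix",
    function(x, ...) standardGeneric("relativeExpressionMatrix"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("datasetId", "ExpressionMatrix", function(x) x@datasetId)

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprValues", "ExpressionMatrix",
    function(x) SummarizedExperiment::assay(x, "exprs"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname CqExperiment-class
#' @export
setMethod("geneIds", "CqExperiment", function(x) dimnames(x@cq)[[2L]])

#' @rdname CqExperiment-class
#' @export
setMethod("sampleIds", "CqExperiment", function(x) dimnames(x@cq)[[1L]])

#' @rdname CqExperiment-class
#' @export
setMethod("sampleGroups", "CqExperiment", function(x) x@group)

#' @rdname CqExperiment-class
#' @export
setMethod("ntcCq", "CqExperiment", function(x) x@ntcCq)

#' @rdname CqExperiment-class
#' @export
setMethod("ampFactor", "CqExperiment", function(x) x@ampFactor)

#' @rdname CqExperiment-class
#' @export
setMethod("meanCq", "CqExperiment", function(x) {
    apply(x@cq, c(1L, 2L), mean, na.rm = TRUE)
})

setMethod("show", "ExpressionMatrix", function(object) {
    v <- exprValues(object)
    cat(sprintf("ExpressionMatrix '%s': %d genes x %d samples\n",
        datasetId(object), nrow(v), ncol(v)))
    cat(sprintf("  expression range: [%.4g, %.4g]\n", min(v), max(v)))
})

setMethod("show", "CqExperiment", function(object) {
    d <- dim(object@cq)
    cat(sprintf(
        "CqExperiment: %d samples x %d genes, <=%d replicates\n",
        d[1L], d[2L], d[3L]))
    cat("  groups: ",
        paste(sprintf("%s (%d)", levels(object@group),
                      table(object@group)), collapse = ", "), "\n", sep = "")
})
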
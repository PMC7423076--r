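## Genome-wide expression-stability screen: per-dataset dispersion and
## normality statistics, PAM clustering with silhouette model selection,
## cross-dataset intersection, biological filters and the composite quartile
## shortlist.

.exprMat <- function(x) {
    if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
}

#' Assign expression quartiles by median expression
#'
#' Genes are ranked by their median expression across samples and split into
#' four groups of (near-)equal size; index 1 holds the lowest medians. Ties
#' at a quartile boundary are resolved by the stable lexicographic order of
#' gene ids, so partitions are deterministic.
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix (genes x samples).
#' @return named integer vector of quartile indices in 1..4.
#' @examples
#' m <- matrix(rep(1:8, each = 3), nrow = 8, byrow = TRUE,
#'             dimnames = list(paste0("G", 1:8), paste0("S", 1:3)))
#' assignQuartiles(m)  # 1 1 2 2 3 3 4 4
#' @export
assignQuartiles <- function(x) {
    v <- .exprMat(x)
    n <- nrow(v)
    if (n < 4L) stop("quartile assignment needs >= 4 genes, got ", n)
    med <- matrixStats::rowMedians(v)
    ord <- order(med, rownames(v))
    pos <- integer(n)
    pos[ord] <- seq_len(n)
    q <- as.integer(floor((pos - 1L) * 4L / n) + 1L)
    names(q) <- rownames(v)
    q
}

#' Keep genes in the middle quartiles of every dataset
#'
#' A gene passes iff it is present in every dataset's quartile map and its
#' quartile index is 2 or 3 in each. Genes absent from any dataset are
#' dropped and reported in the `"dropped_absent"` attribute.
#'
#' @param quartiles list (one element per dataset) of named quartile vectors
#'   from [assignQuartiles()].
#' @return character vector of surviving gene ids.
#' @export
middleQuartileFilter <- function(quartiles) {
    stopifnot(length(quartiles) >= 1L)
    common <- Reduce(intersect, lapply(quartiles, names))
    absent <- setdiff(unique(unlist(lapply(quartiles, names))), common)
    ok <- vapply(common, function(g) {
        all(vapply(quartiles, function(q) q[[g]] %in% c(2L, 3L), logical(1L)))
    }, logical(1L))
    structure(common[ok], dropped_absent = absent)
}

#' Per-gene stability statistics: CV, median-normalized MAD, 1 - normality p
#'
#' For each gene's expression vector x across samples:
#' CV = sd(x)/mean(x); madNorm = median(|x - median(x)|)/median(x);
#' oneMinusP = 1 - p where p is the Shapiro-Wilk normality p-value.
#' Genes with zero mean (CV undefined), zero median (madNorm undefined) or a
#' constant vector (normality test undefined) are flagged rather than
#' propagating NaN; flagged genes are excluded from downstream z-scoring.
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix (genes x samples)
#'   with >= 3 samples.
#' @param shapiroLog if `TRUE`, run the Shapiro-Wilk test on log2(x + 1)
#'   instead of the raw scale. Default `FALSE` (raw values).
#' @return a [S4Vectors::DataFrame] with columns `cv`, `madNorm`,
#'   `oneMinusP`, `flagged`, `flagReason`, rownames = gene ids.
#' @export
stabilityMetrics <- function(x, shapiroLog = FALSE) {
    v <- .exprMat(x)
    if (ncol(v) < 3L) stop("stability metrics need >= 3 samples")
    if (ncol(v) > 5000L) {
        stop("Shapiro-Wilk is limited to 5000 samples; subsample first")
    }
    n <- nrow(v)
    cv <- madNorm <- oneMinusP <- rep(NA_real_, n)
    reason <- character(n)
    for (i in seq_len(n)) {
        xi <- v[i, ]
        m <- mean(xi)
        if (m == 0) { reason[i] <- "zero mean"; next }
        cv[i] <- sd(xi) / m
        md <- median(xi)
        if (md == 0) { reason[i] <- "zero median"; next }
        madNorm[i] <- median(abs(xi - md)) / md
        sx <- if (shapiroLog) log2(xi + 1) else xi
        if (diff(range(sx)) == 0) { reason[i] <- "constant"; next }
        oneMinusP[i] <- 1 - shapiro.test(sx)$p.value
    }
    S4Vectors::DataFrame(
        cv = cv, madNorm = madNorm, oneMinusP = oneMinusP,
        flagged = nzchar(reason), flagReason = reason,
        row.names = rownames(v))
}

#' z-score the (CV, MAD, 1-p) triple over a gene set
#'
#' Standardizes each of the three stability parameters over the genes in
#' scope so the subsequent clustering and distance ranking operate in a
#' calibrated hyperspace.
#'
#' @param stats output of [stabilityMetrics()].
#' @param genes optional subset of gene ids defining the scope; default all
#'   unflagged genes.
#' @return numeric matrix (genes x 3) with columns `z_cv`, `z_mad`,
#'   `z_one_minus_p`; each column has mean 0 and sd 1.
#' @export
zscoreStats <- function(stats, genes = NULL) {
    keep <- rownames(stats)[!stats$flagged]
    if (!is.null(genes)) keep <- intersect(genes, keep)
    if (length(keep) < 2L) stop("z-scoring needs >= 2 unflagged genes")
    m <- cbind(z_cv = stats[keep, "cv"],
               z_mad = stats[keep, "madNorm"],
               z_one_minus_p = stats[keep, "oneMinusP"])
    rownames(m) <- keep
    sds <- apply(m, 2L, sd)
    if (any(sds == 0)) {
        stop("degenerate screen: zero variance in ",
             paste(colnames(m)[sds == 0], collapse = ", "))
    }
    scale(m, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' PAM clustering of the z-triple with silhouette model selection
#'
#' Runs partitioning around medoids (Euclidean dissimilarity) on the
#' z-scored (CV, MAD, 1-p) triple for each k in `kRange`, picks the k with
#' the largest mean silhouette width (ties go to the smallest k), and
#' selects the cluster whose medoid has the smallest Euclidean norm in
#' z-space.
#'
#' @param z matrix from [zscoreStats()].
#' @param kRange integer vector of cluster counts to scan (default 2:6).
#' @param seed recorded in the result for provenance (PAM itself is
#'   deterministic).
#' @return list with elements `k`, `assignment` (named integer),
#'   `medoidGenes`, `medoidZ`, `silWidths` (named by k), `selectedCluster`,
#'   `selectedGenes`, `seed`.
#' @export
clusterAndSelect <- function(z, kRange = 2:6, seed = NULL) {
    kRange <- sort(unique(as.integer(kRange)))
    n <- nrow(z)
    if (all(apply(z, 2L, function(col) diff(range(col)) == 0))) {
        warning("all points identical in z-space; single degenerate cluster")
        return(list(k = 1L,
            assignment = setNames(rep(1L, n), rownames(z)),
            medoidGenes = rownames(z)[1L],
            medoidZ = z[1L, , drop = FALSE],
            silWidths = setNames(numeric(0), character(0)),
            selectedCluster = 1L,
            selectedGenes = rownames(z), seed = seed))
    }
    feasible <- kRange[kRange >= 2L & kRange <= n - 1L]
    if (!length(feasible)) {
        stop("need >= max(kRange)+1 genes for clustering (have ", n, ")")
    }
    if (length(feasible) < length(kRange)) {
        warning("kRange truncated to ", paste(range(feasible), collapse = ":"),
                " for ", n, " genes")
    }
    fits <- lapply(feasible, function(k)
        cluster::pam(z, k = k, metric = "euclidean"))
    widths <- vapply(fits, function(f) f$silinfo$avg.width, numeric(1L))
    names(widths) <- feasible
    best <- which.max(widths)  # ties: first = smallest k
    if (sum(widths == max(widths)) > 1L) {
        message("silhouette tie across k; choosing smallest k = ",
                feasible[best])
    }
    fit <- fits[[best]]
    med <- fit$medoids
    norms <- sqrt(rowSums(med^2))
    sel <- unname(which.min(norms))
    assignment <- setNames(as.integer(fit$clustering), rownames(z))
    list(k = feasible[best],
         assignment = assignment,
         medoidGenes = rownames(z)[fit$id.med],
         medoidZ = med,
         silWidths = widths,
         selectedCluster = sel,
         selectedGenes = names(assignment)[assignment == sel],
         seed = seed)
}

#' Intersect the selected clusters across datasets
#'
#' @param geneSets list of character vectors (one per dataset).
#' @return character vector; a warning is raised if the intersection is
#'   empty.
#' @export
intersectSelectedClusters <- function(geneSets) {
    stopifnot(length(geneSets) >= 1L)
    out <- Reduce(intersect, geneSets)
    if (!length(out)) warning("empty intersection of selected clusters")
    out
}

#' Default GO biological-process stop words
#'
#' Genes whose GO annotation matches these (regulatory/nuclear/stimulus
#' related) phrases are poor reference-gene candidates because their
#' expression responds to cell state and environment.
#'
#' @return character vector of stop words.
#' @export
goStopwords <- function() {
    c("transcription factor", "nuclear receptor", "nuclear localization",
      "DNA binding", "response to external stimulus",
      "response to external stimuli", "translational activation",
      "transcriptional activation")
}

#' Remove genes whose GO annotation matches a stop word
#'
#' A gene is removed iff any of its GO biological-process terms contains any
#' stop word as a case-insensitive substring. Genes with an empty GO set are
#' retained. Removal reasons are attached as the `"removed"` attribute
#' (data.frame gene/term/stopword).
#'
#' @param genes character vector of gene ids.
#' @param annotation data.frame from [readGeneAnnotation()].
#' @param stopwords non-empty character vector; default [goStopwords()].
#' @return character vector of retained gene ids.
#' @export
filterGoStopwords <- function(genes, annotation, stopwords = goStopwords()) {
    stopifnot(length(stopwords) >= 1L)
    sw <- tolower(stopwords)
    hits <- list()
    keep <- vapply(genes, function(g) {
        terms <- if (g %in% annotation$gene_id)
            annotation[["go_bp_terms"]][[match(g, annotation$gene_id)]]
        else character()
        if (!length(terms)) return(TRUE)
        lt <- tolower(terms)
        for (i in seq_along(sw)) {
            j <- which(grepl(sw[i], lt, fixed = TRUE))
            if (length(j)) {
                hits[[length(hits) + 1L]] <<- data.frame(
                    gene = g, term = terms[j[1L]], stopword = stopwords[i],
                    stringsAsFactors = FALSE)
                return(FALSE)
            }
        }
        TRUE
    }, logical(1L))
    structure(genes[keep],
        removed = if (length(hits)) do.call(rbind, hits) else
            data.frame(gene = character(), term = character(),
                       stopword = character()))
}

#' Euclidean distance ranking in the z-scored stability hyperspace
#'
#' For each dataset, d = sqrt(z_cv^2 + z_mad^2 + z_(1-p)^2); the mean over
#' datasets is d-bar, and genes with d-bar strictly below the median of
#' d-bar over the input set are retained. By default the z-scores are
#' recomputed over the surviving gene set per dataset, keeping the
#' hyperspace calibrated to the comparison set; set `recompute = FALSE` to
#' reuse z-scores computed over a wider scope.
#'
#' @param statsList list (per dataset) of [stabilityMetrics()] outputs, or,
#'   with `recompute = FALSE`, list of z-score matrices from [zscoreStats()].
#' @param genes gene ids in scope (must be unflagged in every dataset).
#' @param recompute recompute z-scores over `genes` (default `TRUE`).
#' @return [S4Vectors::DataFrame] with one `d_<i>` column per dataset,
#'   `dbar`, and logical `kept`; rownames = gene ids, ordered as `genes`.
#' @export
rankByDistance <- function(statsList, genes, recompute = TRUE) {
    zlist <- lapply(statsList, function(s) {
        if (recompute) zscoreStats(s, genes = genes)
        else s[genes, , drop = FALSE]
    })
    miss <- vapply(zlist, function(z) !all(genes %in% rownames(z)),
                   logical(1L))
    if (any(miss)) stop("some genes lack z-scores in dataset(s) ",
                        paste(which(miss), collapse = ", "))
    d <- vapply(zlist, function(z)
        sqrt(rowSums(z[genes, , drop = FALSE]^2)), numeric(length(genes)))
    d <- matrix(d, nrow = length(genes),
                dimnames = list(genes, paste0("d_", names(statsList))))
    dbar <- rowMeans(d)
    out <- S4Vectors::DataFrame(d, dbar = dbar,
                                kept = dbar < median(dbar),
                                row.names = genes)
    out
}

.bandUniverse <- function(annotation, loci, cytobands = NULL) {
    if (!is.null(cytobands)) {
        u <- data.frame(chromosome = cytobands$chromosome,
                        band_label = cytobands$band_label,
                        stringsAsFactors = FALSE)
    } else {
        u <- rbind(
            data.frame(chromosome = annotation$chromosome,
                       band_label = annotation$band_label,
                       stringsAsFactors = FALSE),
            data.frame(chromosome = loci$chromosome,
                       band_label = loci$band_label,
                       stringsAsFactors = FALSE))
        u <- u[!is.na(u$band_label) & !is.na(u$chromosome), ]
    }
    u <- unique(u)
    parsed <- parseBandLabel(u$band_label, strict = TRUE)
    u$arm <- parsed$arm
    u$major <- parsed$major
    u$minor <- ifelse(is.na(parsed$minor), 0L, parsed$minor)
    split(u, paste0(u$chromosome, u$arm))
}

.bandPosition <- function(universe, chromosome, arm, band_label) {
    key <- paste0(chromosome, arm)
    u <- universe[[key]]
    if (is.null(u)) return(NA_integer_)
    ord <- order(u$major, u$minor)
    labels <- u$band_label[ord]
    match(band_label, labels)
}

#' Remove candidates near known disease-translocation loci
#'
#' A gene is removed iff some locus shares its chromosome AND arm and the
#' ordinal band distance is at most `maxBandDistance` (inclusive). Ordinal
#' distance is the difference of positions in the sorted list of distinct
#' band labels of that arm (ordered by major then minor band number). The
#' band universe is taken from `cytobands` when supplied, otherwise from the
#' union of annotation and locus band labels. Genes with missing band data
#' are retained with a warning; an unparseable band label is a hard error.
#'
#' @param genes character vector of gene ids.
#' @param annotation data.frame from [readGeneAnnotation()].
#' @param loci data.frame from [readTranslocationLoci()].
#' @param maxBandDistance inclusive ordinal distance threshold; default 10.
#' @param cytobands optional data.frame from [readCytobands()] defining the
#'   full band universe; band labels absent from it are an error.
#' @return character vector of retained gene ids, with attribute `"removed"`
#'   (data.frame gene/locus/distance).
#' @export
filterTranslocationProximity <- function(genes, annotation, loci,
                                         maxBandDistance = 10,
                                         cytobands = NULL) {
    universe <- .bandUniverse(annotation, loci, cytobands)
    lpos <- vapply(seq_len(nrow(loci)), function(i)
        .bandPosition(universe, loci$chromosome[i], loci$arm[i],
                      loci$band_label[i]), integer(1L))
    if (!is.null(cytobands) && anyNA(lpos)) {
        stop("locus band label(s) absent from the cytoband reference: ",
             paste(loci$band_label[is.na(lpos)], collapse = ", "))
    }
    ann <- annotation[match(genes, annotation$gene_id), ]
    removed <- list()
    keep <- logical(length(genes))
    for (i in seq_along(genes)) {
        if (is.na(ann$band_label[i]) || is.na(ann$chromosome[i])) {
            warning("gene ", genes[i],
                    " has no band data; retained unfiltered")
            keep[i] <- TRUE
            next
        }
        parsed <- parseBandLabel(ann$band_label[i], strict = TRUE)
        gpos <- .bandPosition(universe, ann$chromosome[i], parsed$arm,
                              ann$band_label[i])
        if (!is.null(cytobands) && is.na(gpos)) {
            stop("band label ", ann$band_label[i], " of gene ", genes[i],
                 " is absent from the cytoband reference")
        }
        near <- which(loci$chromosome == ann$chromosome[i] &
                      loci$arm == parsed$arm &
                      abs(lpos - gpos) <= maxBandDistance)
        if (length(near)) {
            removed[[length(removed) + 1L]] <- data.frame(
                gene = genes[i],
                locus = paste0(loci$chromosome[near[1L]],
                               loci$band_label[near[1L]]),
                distance = abs(lpos[near[1L]] - gpos),
                stringsAsFactors = FALSE)
        } else {
            keep[i] <- TRUE
        }
    }
    structure(genes[keep],
        removed = if (length(removed)) do.call(rbind, removed) else
            data.frame(gene = character(), locus = character(),
                       distance = integer()))
}

#' Keep genes with strictly positive expression in every sample
#'
#' @param genes character vector of gene ids.
#' @param matrices list of [ExpressionMatrix-class] (or matrices).
#' @return character vector of genes whose minimum expression is > 0 in all
#'   samples of every dataset.
#' @export
filterNonzero <- function(genes, matrices) {
    keep <- vapply(genes, function(g) {
        all(vapply(matrices, function(m) {
            v <- .exprMat(m)
            g %in% rownames(v) && min(v[g, ]) > 0
        }, logical(1L)))
    }, logical(1L))
    genes[keep]
}

#' Composite quartile rank and shortlist
#'
#' CQR is the sum of a gene's quartile indices over the datasets; with four
#' datasets and genes restricted to quartiles 2 and 3, CQR lies in 8..12 and
#' the shortlist keeps CQR in `cqrKeep` (default {8, 9, 10}: median
#' expression in the 2nd quartile in at least two datasets).
#'
#' @param quartiles list (per dataset) of named quartile vectors.
#' @param genes gene ids in scope.
#' @param cqrKeep integer CQR values to shortlist.
#' @return [S4Vectors::DataFrame] with columns `cqr` and `shortlisted`.
#' @export
compositeQuartileRank <- function(quartiles, genes, cqrKeep = 8:10) {
    cqr <- vapply(genes, function(g)
        sum(vapply(quartiles, function(q) q[[g]], integer(1L))), integer(1L))
    S4Vectors::DataFrame(cqr = cqr, shortlisted = cqr %in% cqrKeep,
                         row.names = genes)
}

#' Run the full multi-dataset reference-gene screen
#'
#' Executes, in order: protein-coding filter, quartile assignment, middle
#' quartile filter (Q2/Q3 in every dataset), stability metrics, z-scoring,
#' PAM clustering with silhouette selection and lowest-norm-medoid cluster
#' choice, cross-dataset intersection, GO stop-word filter, Euclidean
#' distance ranking (d-bar < median), translocation-proximity filter,
#' non-zero expression filter, and the composite quartile shortlist. Any
#' stage that empties the gene set aborts with a stage-named error.
#'
#' @param matrices named list of [ExpressionMatrix-class], one per dataset
#'   (>= 2).
#' @param annotation data.frame from [readGeneAnnotation()].
#' @param loci data.frame from [readTranslocationLoci()].
#' @param stopwords GO stop words; default [goStopwords()].
#' @param kRange cluster counts scanned per dataset; default 2:6.
#' @param maxBandDistance see [filterTranslocationProximity()].
#' @param cqrKeep see [compositeQuartileRank()].
#' @param seed integer recorded in the result (clustering is deterministic;
#'   the seed documents run provenance).
#' @param shapiroLog see [stabilityMetrics()].
#' @param recomputeZ recompute z-scores over the surviving set at the
#'   distance stage (default) or reuse the cluster-stage z-scores.
#' @param cytobands optional cytoband reference, see
#'   [filterTranslocationProximity()].
#' @param verbose print per-stage survivor counts.
#'
#' @return list with `ranking` (shortlisted genes ascending by d-bar),
#'   `candidates` (per-gene filter flags and distances for all genes
#'   entering the post-intersection stages), `stageCounts` (named integer),
#'   `clusters` (per-dataset [clusterAndSelect()] results), `quartiles`,
#'   `seed` and `params`.
#' @export
runScreen <- function(matrices, annotation, loci,
                      stopwords = goStopwords(), kRange = 2:6,
                      maxBandDistance = 10, cqrKeep = 8:10, seed = 1L,
                      shapiroLog = FALSE, recomputeZ = TRUE,
                      cytobands = NULL, verbose = TRUE) {
    if (length(matrices) < 2L) stop("the screen needs >= 2 datasets")
    if (is.null(names(matrices)) || any(!nzchar(names(matrices)))) {
        names(matrices) <- vapply(matrices, function(m)
            if (is(m, "ExpressionMatrix")) datasetId(m) else "dataset",
            character(1L))
    }
    counts <- c(initial = length(unique(unlist(lapply(matrices, function(m)
        rownames(.exprMat(m)))))))
    note <- function(stage, n) {
        counts[[stage]] <<- n
        if (verbose) message(sprintf("  %-22s %6d genes", stage, n))
        if (n == 0L) stop("stage '", stage, "' removed all genes")
    }

    pc <- lapply(matrices, filterProteinCoding, annotation = annotation)
    note("protein_coding", length(Reduce(intersect, lapply(pc, geneIds))))

    quartiles <- lapply(pc, assignQuartiles)
    mid <- middleQuartileFilter(quartiles)
    note("middle_quartile", length(mid))

    stats <- lapply(pc, function(m)
        stabilityMetrics(.exprMat(m)[mid, , drop = FALSE],
                         shapiroLog = shapiroLog))
    okGenes <- Reduce(intersect,
        lapply(stats, function(s) rownames(s)[!s$flagged]))
    note("metrics_ok", length(okGenes))

    clusters <- lapply(stats, function(s) {
        z <- zscoreStats(s, genes = okGenes)
        clusterAndSelect(z, kRange = kRange, seed = seed)
    })
    selected <- intersectSelectedClusters(
        lapply(clusters, `[[`, "selectedGenes"))
    note("cluster_intersection", length(selected))

    afterGo <- filterGoStopwords(selected, annotation, stopwords)
    note("go_stopwords", length(afterGo))

    dist <- rankByDistance(stats, afterGo, recompute = recomputeZ)
    afterDist <- rownames(dist)[dist$kept]
    note("distance_median", length(afterDist))

    afterLoci <- filterTranslocationProximity(afterDist, annotation, loci,
        maxBandDistance = maxBandDistance, cytobands = cytobands)
    note("translocation", length(afterLoci))

    afterNonzero <- filterNonzero(afterLoci, matrices)
    note("nonzero", length(afterNonzero))

    cqr <- compositeQuartileRank(quartiles, afterNonzero, cqrKeep = cqrKeep)
    shortlist <- rownames(cqr)[cqr$shortlisted]
    note("cqr_shortlist", length(shortlist))

    dnames <- setdiff(colnames(dist), "kept")
    dvals <- matrix(NA_real_, nrow = length(selected), ncol = length(dnames),
                    dimnames = list(selected, dnames))
    hit <- selected %in% rownames(dist)
    dvals[hit, ] <- as.matrix(dist[selected[hit], dnames, drop = FALSE])
    candidates <- S4Vectors::DataFrame(dvals, row.names = selected)
    candidates$pass_go <- selected %in% afterGo
    candidates$pass_distance <- selected %in% afterDist
    candidates$pass_translocation <- selected %in% as.character(afterLoci)
    candidates$pass_nonzero <- selected %in% afterNonzero
    candidates$cqr <- NA_integer_
    candidates[afterNonzero, "cqr"] <- cqr$cqr
    candidates$pass_cqr <- selected %in% shortlist
    candidates$shortlisted <- candidates$pass_go & candidates$pass_distance &
        candidates$pass_translocation & candidates$pass_nonzero &
        candidates$pass_cqr

    ranking <- candidates[candidates$shortlisted, , drop = FALSE]
    ranking <- ranking[order(ranking$dbar, rownames(ranking)), , drop = FALSE]

    list(ranking = ranking, candidates = candidates,
         stageCounts = counts, clusters = clusters, quartiles = quartiles,
         seed = seed,
         params = list(kRange = kRange, maxBandDistance = maxBandDistance,
                       cqrKeep = cqrKeep, stopwords = stopwords,
                       shapiroLog = shapiroLog, recomputeZ = recomputeZ))
}
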
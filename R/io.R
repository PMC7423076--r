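## Readers/writers for expression matrices, gene annotation, translocation
## loci and Cq tables, plus the dialect normalization for log2-transformed
## FPKM sources.

.detectSep <- function(path) {
    first <- readLines(path, n = 1L)
    if (lengths(regmatches(first, gregexpr("\t", first))) >=
        lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Read a gene x sample expression matrix
#'
#' Reads a delimited table (first column gene ids, header row sample ids)
#' into an [ExpressionMatrix-class]. Two dialects are supported: `"fpkm"`
#' (values passed through, negatives rejected) and `"log2_normalized"` for
#' sources distributed as log2(x + pseudocount): every value x is
#' back-converted as `2^x - pseudocount` and clamped at 0.
#'
#' @param path file path of a TSV/CSV table.
#' @param dialect `"fpkm"` or `"log2_normalized"`.
#' @param datasetId dataset label; defaults to the file name.
#' @param sep field separator; `NULL` auto-detects between tab and comma.
#' @param pseudocount pseudocount assumed in the forward log2(x + c)
#'   transform of the `log2_normalized` dialect. Default 1.
#'
#' @return An [ExpressionMatrix-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tS1\tS2", "G1\t0\t10", "G2\t1\t2"), tf)
#' em <- readExpressionMatrix(tf, "log2_normalized", datasetId = "demo")
#' exprValues(em)  # 2^10 - 1 = 1023
#' @export
readExpressionMatrix <- function(path, dialect = c("fpkm", "log2_normalized"),
                                 datasetId = NULL, sep = NULL,
                                 pseudocount = 1) {
    dialect <- match.arg(dialect)
    if (is.null(sep)) sep <- .detectSep(path)
    if (is.null(datasetId)) datasetId <- sub("\\.[^.]*$", "", basename(path))
    df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                     colClasses = "character", quote = "\"",
                     comment.char = "", stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expression table needs gene ids plus >=1 sample")
    ids <- df[[1L]]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) {
        stop("duplicate gene id(s) in ", path, ": ",
             paste(dup, collapse = ", "))
    }
    samples <- colnames(df)[-1L]
    mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                  dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
        raw <- df[[j + 1L]]
        num <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(num))
        if (length(bad)) {
            stop(sprintf(
                "non-numeric cell '%s' at row %d (gene %s), column '%s'",
                raw[bad[1L]], bad[1L], ids[bad[1L]], samples[j]))
        }
        mat[, j] <- num
    }
    if (dialect == "log2_normalized") {
        mat <- pmax(2^mat - pseudocount, 0)
    } else if (any(mat < 0)) {
        bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("negative FPKM value for gene %s, sample %s",
                     rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]))
    }
    ExpressionMatrix(mat, datasetId = datasetId)
}

#' Write an ExpressionMatrix to a delimited file
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces doubles exactly and preserves row/column order.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, sep = "\t") {
    v <- exprValues(x)
    chr <- matrix(sprintf("%.17g", v), nrow = nrow(v),
                  dimnames = dimnames(v))
    out <- cbind(gene_id = rownames(v), as.data.frame(chr,
        check.names = FALSE, stringsAsFactors = FALSE))
    write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Parse cytogenetic band labels
#'
#' Accepts labels of the form `"q21.3"`, `"p11"`, or with a chromosome prefix
#' (`"18q21.3"`). A band parses into arm (p or q), major band number, and an
#' optional minor (sub-band) number.
#'
#' @param label character vector of band labels.
#' @param strict if `TRUE` (default), unparseable labels are a hard error
#'   naming the label; otherwise they yield NA rows.
#' @return data.frame with columns `chromosome` (NA when absent from the
#'   label), `arm`, `major`, `minor` (NA when no sub-band).
#' @examples
#' parseBandLabel(c("q21.3", "18q21", "p11.2"))
#' @export
parseBandLabel <- function(label, strict = TRUE) {
    label <- as.character(label)
    m <- regmatches(label,
        regexec("^([0-9]+|[XY])?([pq])([0-9]+)(?:\\.([0-9]+))?$", label))
    bad <- vapply(m, length, integer(1L)) == 0L
    bad[is.na(label)] <- FALSE
    if (strict && any(bad)) {
        stop("unparseable cytogenetic band label(s): ",
             paste(unique(label[bad]), collapse = ", "))
    }
    get <- function(i) vapply(m, function(g)
        if (length(g) >= i && nzchar(g[i])) g[i] else NA_character_,
        character(1L))
    data.frame(
        chromosome = get(2L),
        arm = get(3L),
        major = as.integer(get(4L)),
        minor = as.integer(get(5L)),
        stringsAsFactors = FALSE
    )
}

#' Default biotype vocabulary for gene annotation tables
#' @return character vector of recognized biotype strings.
#' @export
biotypeVocabulary <- function() {
    c("protein_coding", "lincRNA", "lncRNA", "miRNA", "snoRNA", "snRNA",
      "rRNA", "tRNA", "pseudogene", "processed_pseudogene",
      "unprocessed_pseudogene", "antisense", "misc_RNA", "TEC",
      "IG_V_gene", "TR_V_gene")
}

#' Read a gene annotation table
#'
#' Expects a delimited table with mandatory columns `gene_id`, `symbol`,
#' `biotype`, `chromosome`, `arm`, `band_label`, `go_bp_terms`. GO
#' biological-process terms arrive as one `;`-joined cell; an empty cell
#' yields an empty term set. A missing band cell yields `NA`, not an error;
#' a present but unparseable band label is an error.
#'
#' @param path file path.
#' @param sep separator; `NULL` auto-detects tab vs comma.
#' @param goSep separator inside the GO term cell (default `";"`).
#' @param vocabulary biotype vocabulary used for a validity warning;
#'   `NULL` disables the check.
#' @return data.frame, one row per gene, with a list column `go_bp_terms`.
#' @export
readGeneAnnotation <- function(path, sep = NULL, goSep = ";",
                               vocabulary = biotypeVocabulary()) {
    if (is.null(sep)) sep <- .detectSep(path)
    df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                     colClasses = "character", quote = "\"",
                     comment.char = "", stringsAsFactors = FALSE,
                     na.strings = character())
    need <- c("gene_id", "symbol", "biotype", "chromosome", "arm",
              "band_label", "go_bp_terms")
    missing <- setdiff(need, colnames(df))
    if (length(missing)) {
        stop("annotation table is missing mandatory column(s): ",
             paste(missing, collapse = ", "),
             "; expected header: ", paste(need, collapse = ", "))
    }
    df <- df[, need]
    dup <- unique(df$gene_id[duplicated(df$gene_id)])
    if (length(dup)) {
        stop("duplicate gene id(s) in annotation: ",
             paste(dup, collapse = ", "))
    }
    df$band_label[!nzchar(trimws(df$band_label))] <- NA_character_
    df$chromosome[!nzchar(trimws(df$chromosome))] <- NA_character_
    df$arm[!nzchar(trimws(df$arm))] <- NA_character_
    present <- !is.na(df$band_label)
    if (any(present)) {
        parsed <- parseBandLabel(df$band_label[present], strict = TRUE)
        fill <- is.na(df$arm) & present
        df$arm[fill] <- parsed$arm[match(df$band_label[fill],
                                         df$band_label[present])]
    }
    if (!is.null(vocabulary)) {
        unknown <- setdiff(unique(df$biotype), vocabulary)
        if (length(unknown)) {
            warning("biotype value(s) outside the declared vocabulary: ",
                    paste(unknown, collapse = ", "))
        }
    }
    df$go_bp_terms <- lapply(df$go_bp_terms, function(cell) {
        cell <- trimws(cell)
        if (!nzchar(cell)) return(character())
        trimws(strsplit(cell, goSep, fixed = TRUE)[[1L]])
    })
    rownames(df) <- df$gene_id
    df
}

#' Read a translocation locus table
#'
#' Two-column delimited file: `chrom_band` (e.g. `"18q21.3"`) and `disease`.
#'
#' @param path file path.
#' @param sep separator; `NULL` auto-detects.
#' @return data.frame with columns `chromosome`, `arm`, `band_label`,
#'   `disease`.
#' @export
readTranslocationLoci <- function(path, sep = NULL) {
    if (is.null(sep)) sep <- .detectSep(path)
    df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                     colClasses = "character", quote = "\"",
                     stringsAsFactors = FALSE)
    need <- c("chrom_band", "disease")
    missing <- setdiff(need, colnames(df))
    if (length(missing)) {
        stop("locus table is missing mandatory column(s): ",
             paste(missing, collapse = ", "))
    }
    parsed <- parseBandLabel(df$chrom_band, strict = TRUE)
    if (anyNA(parsed$chromosome)) {
        stop("locus chrom_band must include the chromosome, e.g. '18q21.3': ",
             paste(df$chrom_band[is.na(parsed$chromosome)], collapse = ", "))
    }
    data.frame(
        chromosome = parsed$chromosome,
        arm = parsed$arm,
        band_label = paste0(parsed$arm, parsed$major,
            ifelse(is.na(parsed$minor), "", paste0(".", parsed$minor))),
        disease = df$disease,
        stringsAsFactors = FALSE
    )
}

#' Read a UCSC cytoBand.txt-style table
#'
#' Five tab-separated columns without header: chrom, start, end, band name
#' (e.g. `q21.3`), stain. Used as an optional band universe / validator for
#' [filterTranslocationProximity()].
#'
#' @param path file path.
#' @return data.frame with `chromosome`, `arm`, `band_label`.
#' @export
readCytobands <- function(path) {
    df <- read.table(path, header = FALSE, sep = "\t",
                     colClasses = "character", stringsAsFactors = FALSE)
    chrom <- sub("^chr", "", df[[1L]])
    parsed <- parseBandLabel(df[[4L]], strict = TRUE)
    data.frame(chromosome = chrom, arm = parsed$arm,
               band_label = df[[4L]], stringsAsFactors = FALSE)
}

#' Keep only protein-coding genes
#'
#' Subsets an [ExpressionMatrix-class] to genes annotated as
#' `protein_coding`. Genes absent from the annotation are dropped and their
#' count reported via `message()`; they are never silently invented.
#'
#' @param x an [ExpressionMatrix-class].
#' @param annotation a data.frame from [readGeneAnnotation()].
#' @return the filtered [ExpressionMatrix-class]; a warning is raised if no
#'   gene survives.
#' @export
filterProteinCoding <- function(x, annotation) {
    genes <- geneIds(x)
    known <- genes %in% annotation$gene_id
    if (any(!known)) {
        message(sum(!known),
            " gene(s) absent from the annotation were dropped")
    }
    keep <- genes[known][
        annotation[genes[known], "biotype"] == "protein_coding"]
    if (!length(keep)) {
        warning("no protein-coding genes remain in dataset ", datasetId(x))
    }
    x[match(keep, genes), ]
}

#' Read a long-format Cq table into a CqExperiment
#'
#' @param path TSV/CSV with columns `sample`, `group`, `gene`, `replicate`,
#'   `cq`.
#' @param genePath TSV/CSV gene table with columns `gene`, `amp_factor`,
#'   `ntc_cq` (a `;`-joined list of NTC Cq replicates).
#' @param sep separator; `NULL` auto-detects.
#' @return A [CqExperiment-class].
#' @export
readCqExperiment <- function(path, genePath, sep = NULL) {
    if (is.null(sep)) sep <- .detectSep(path)
    long <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                       stringsAsFactors = FALSE)
    gsep <- .detectSep(genePath)
    gt <- read.table(genePath, header = TRUE, sep = gsep,
                     check.names = FALSE, colClasses = "character",
                     stringsAsFactors = FALSE)
    need <- c("gene", "amp_factor", "ntc_cq")
    missing <- setdiff(need, colnames(gt))
    if (length(missing)) {
        stop("gene table is missing column(s): ",
             paste(missing, collapse = ", "))
    }
    ntc <- lapply(strsplit(gt$ntc_cq, ";", fixed = TRUE),
                  function(v) as.numeric(trimws(v)))
    names(ntc) <- gt$gene
    amp <- setNames(as.numeric(gt$amp_factor), gt$gene)
    CqExperiment(long, ntcCq = ntc, ampFactor = amp)
}
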
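#' Read a gene-level expression matrix with sample class labels
#'
#' The matrix file is tab-delimited: first column gene identifier, header
#' row sample identifiers. The labels file is a two-column TSV
#' (\code{sample_id}, \code{class}) with a header. Labels are matched by
#' sample identifier, so the two files need not share an ordering; every
#' sample in the matrix must be labelled. Gene identifiers are matched
#' case-sensitively after whitespace stripping; no alias resolution is
#' attempted.
#'
#' @param matrixPath path to the expression matrix TSV.
#' @param labelsPath path to the two-column label TSV.
#' @return An \linkS4class{ExpressionDataset} with labels aligned to the
#'   matrix column order.
#' @seealso \code{\link{writeExpression}} for the inverse.
#' @export
readExpression <- function(matrixPath, labelsPath) {
    if (!file.exists(matrixPath))
        stop(sprintf("expression matrix not found: %s", matrixPath))
    if (!file.exists(labelsPath))
        stop(sprintf("labels file not found: %s", labelsPath))
    tab <- read.delim(matrixPath, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("expression matrix must have a gene column plus >=1 sample")
    genes <- trimws(as.character(tab[[1L]]))
    if (anyDuplicated(genes))
        stop(sprintf("duplicate gene identifier: %s",
                     genes[duplicated(genes)][1L]))
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stop("expression values must be numeric")
    rownames(m) <- genes
    lab <- read.delim(labelsPath, stringsAsFactors = FALSE)
    if (ncol(lab) < 2L)
        stop("labels file must have two columns: sample_id, class")
    labels <- setNames(trimws(as.character(lab[[2L]])),
                       trimws(as.character(lab[[1L]])))
    missing <- setdiff(colnames(m), names(labels))
    if (length(missing))
        stop(sprintf("sample '%s' in the matrix has no label", missing[1L]))
    batch <- NULL
    if (ncol(lab) >= 3L && "batch" %in% tolower(colnames(lab)))
        batch <- setNames(as.character(lab[[which(
            tolower(colnames(lab)) == "batch")[1L]]]),
            trimws(as.character(lab[[1L]])))
    ExpressionDataset(m, labels, batch = batch)
}

#' Write an ExpressionDataset to matrix + label TSVs
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param matrixPath,labelsPath output paths.
#' @return Invisibly, the two paths.
#' @export
writeExpression <- function(dataset, matrixPath, labelsPath) {
    m <- exprValues(dataset)
    out <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(out, matrixPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    lab <- data.frame(sample_id = sampleIds(dataset),
                      class = as.character(classLabels(dataset)),
                      stringsAsFactors = FALSE)
    cd <- SummarizedExperiment::colData(dataset)
    if ("batch" %in% colnames(cd))
        lab$batch <- as.character(cd$batch)
    write.table(lab, labelsPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(matrixPath, labelsPath))
}

#' Row-standardize an expression matrix (z-transformation)
#'
#' Each gene row is transformed to standard scores with mean zero and
#' standard deviation one across all samples, using the population standard
#' deviation (divisor N). Zero-variance rows become all-zeros and are
#' flagged in \code{rowData(x)$zeroVariance}. The operation is idempotent.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param tol variance below which a row counts as constant.
#' @return The dataset with standardized rows,
#'   \code{metadata(x)$zTransformed == TRUE}.
#' @examples
#' m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("a", "b", "c")))
#' m <- cbind(m, m)  # >=2 samples per class
#' ds <- ExpressionDataset(m, rep(c("x", "y"), each = 3))
#' exprValues(zTransform(ds))["g1", ]
#' @export
zTransform <- function(dataset, tol = 1e-12) {
    m <- exprValues(dataset)
    if (any(!is.finite(m)))
        stop("non-finite expression values; clean the matrix first")
    n <- ncol(m)
    mu <- rowMeans(m)
    centered <- m - mu
    popSd <- sqrt(rowSums(centered^2) / n)
    zero <- popSd < tol
    z <- centered / ifelse(zero, 1, popSd)
    z[zero, ] <- 0
    out <- dataset
    SummarizedExperiment::assay(out, "exprs") <- z
    SummarizedExperiment::rowData(out)$zeroVariance <- zero
    S4Vectors::metadata(out)$zTransformed <- TRUE
    out
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes annotated to more than one gene are discarded (their
#' interpretation is ambiguous), as are probes with no gene annotation.
#' When several remaining probes measure the same gene, their rows are
#' averaged (arithmetic mean), the conventional many-to-one collapse.
#'
#' @param probeMatrix numeric matrix, probes in rows (rownames = probe ids).
#' @param mapping data frame with columns \code{probe} and \code{gene}; a
#'   probe annotated to k genes appears in k rows.
#' @param labels class label per sample, passed to
#'   \code{\link{ExpressionDataset}}.
#' @return A gene-level \linkS4class{ExpressionDataset}.
#' @export
collapseProbes <- function(probeMatrix, mapping, labels) {
    if (!all(c("probe", "gene") %in% colnames(mapping)))
        stop("'mapping' needs columns 'probe' and 'gene'")
    mapping <- unique(mapping[, c("probe", "gene")])
    hits <- table(mapping$probe)
    multi <- names(hits)[hits > 1L]           # ambiguous: multi-gene probes
    keep <- mapping[!mapping$probe %in% multi &
                    mapping$probe %in% rownames(probeMatrix), ]
    if (length(multi))
        message(sprintf("discarded %d probe(s) mapping to multiple genes",
                        length(multi)))
    if (nrow(keep) == 0L)
        stop("no probes remain after multi-gene/unmapped filtering")
    sub <- probeMatrix[keep$probe, , drop = FALSE]
    collapsed <- rowsum(sub, group = keep$gene) /
        as.vector(table(keep$gene)[sort(unique(keep$gene))])
    ExpressionDataset(as.matrix(collapsed), labels)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, \code{set_id TAB description TAB gene...}.
#' Duplicate members within a set are deduplicated with a warning.
#'
#' @param path path to the GMT file.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGeneSets <- function(path) {
    if (!file.exists(path))
        stop(sprintf("gene-set file not found: %s", path))
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list(); desc <- character()
    for (i in seq_along(lines)) {
        f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
        if (length(f) < 3L)
            stop(sprintf("GMT line %d has %d field(s); need >=3",
                         i, length(f)))
        genes <- f[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (anyDuplicated(genes)) {
            warning(sprintf("set '%s': duplicate members removed", f[1L]))
            genes <- unique(genes)
        }
        sets[[f[1L]]] <- genes
        desc[f[1L]] <- f[2L]
    }
    GeneSetCollection(sets, desc)
}

#' Write a gene-set collection as GMT
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneSets <- function(collection, path) {
    lines <- vapply(setIds(collection), function(id) {
        paste(c(id, collection@descriptions[[id]], geneSet(collection, id)),
              collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read an interaction network
#'
#' Supported dialects: \describe{
#'   \item{edge_list}{two tab-separated gene symbols per line, no header.}
#'   \item{sif}{\code{nodeA interaction nodeB [nodeC ...]}, whitespace
#'     separated; one edge per partner after the interaction type.}
#'   \item{biogrid_tab}{BioGRID TAB 2.0: header line starting with
#'     \code{#}; official symbols in columns 8 and 9; organism taxonomy ids
#'     in columns 16 and 17 — only rows with both organisms equal to
#'     \code{organism} (default human, 9606) are kept.}
#' }
#' Self-loops and duplicate edges (in either orientation) are always
#' removed, so the result is a simple undirected graph.
#'
#' @param path path to the network file.
#' @param dialect one of \code{"edge_list"}, \code{"sif"},
#'   \code{"biogrid_tab"}.
#' @param organism taxonomy id filter for the BioGRID dialect.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
readNetwork <- function(path, dialect = c("edge_list", "sif", "biogrid_tab"),
                        organism = "9606") {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop(sprintf("network file not found: %s", path))
    lines <- readLines(path)
    edges <- switch(dialect,
        edge_list = {
            keep <- nzchar(trimws(lines))
            rows <- lapply(which(keep), function(i) {
                f <- strsplit(trimws(lines[[i]]), "\t|\\s+")[[1L]]
                if (length(f) < 2L)
                    stop(sprintf("edge-list line %d: need 2 fields", i))
                f[1:2]
            })
            do.call(rbind, rows)
        },
        sif = {
            keep <- nzchar(trimws(lines))
            rows <- lapply(which(keep), function(i) {
                f <- strsplit(trimws(lines[[i]]), "\t|\\s+")[[1L]]
                if (length(f) == 1L)
                    return(NULL)              # isolated node line
                if (length(f) < 3L)
                    stop(sprintf("SIF line %d: need >=3 fields", i))
                cbind(f[1L], f[-(1:2)])
            })
            do.call(rbind, rows)
        },
        biogrid_tab = {
            body <- lines[!startsWith(lines, "#")]
            body <- body[nzchar(trimws(body))]
            rows <- lapply(seq_along(body), function(i) {
                f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
                if (length(f) < 17L)
                    stop(sprintf("BioGRID line %d: need >=17 columns", i))
                if (f[16L] == organism && f[17L] == organism) f[8:9]
                else NULL
            })
            do.call(rbind, rows)
        })
    if (is.null(edges))
        edges <- matrix(character(), 0L, 2L)
    isolated <- character()
    if (dialect == "sif") {
        f1 <- vapply(strsplit(trimws(lines[nzchar(trimws(lines))]),
                              "\t|\\s+"), length, 0L)
        isolated <- vapply(strsplit(trimws(
            lines[nzchar(trimws(lines))][f1 == 1L]), "\t|\\s+"),
            `[`, character(1), 1L)
    }
    InteractionNetwork(edges, nodes = isolated)
}

#' Write an interaction network as a 2-column edge list
#' @param network an \linkS4class{InteractionNetwork}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeNetwork <- function(network, path) {
    e <- networkEdges(network)
    writeLines(paste(e[, 1L], e[, 2L], sep = "\t"), path)
    invisible(path)
}
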
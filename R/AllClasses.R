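#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats cor kmeans pf rnorm runif sd var setNames predict
#' @importFrom utils read.delim write.table packageVersion head
#' @importFrom tools md5sum
NULL

#' ExpressionDataset: a labelled gene-by-sample expression matrix
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"exprs"}, genes in rows, samples in columns) plus a mandatory
#' per-sample class label in \code{colData(x)$class}. All scoring and search
#' functions consume this container.
#'
#' Validity requires unique gene identifiers, at least two classes, and at
#' least two samples per class (the ANOVA scoring is undefined otherwise).
#' After \code{\link{zTransform}}, \code{rowData(x)$zeroVariance} flags
#' constant rows and \code{metadata(x)$zTransformed} is \code{TRUE}.
#'
#' @seealso \code{\link{ExpressionDataset}}, \code{\link{readExpression}},
#'   \code{\link{zTransform}}
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- character()
    gid <- rownames(object)
    if (is.null(gid) || anyNA(gid) || any(gid == ""))
        msg <- c(msg, "gene identifiers (rownames) are required")
    if (anyDuplicated(gid))
        msg <- c(msg, sprintf("duplicate gene identifier: %s",
                              gid[duplicated(gid)][1L]))
    if (!"class" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'class' column")
    else {
        cls <- SummarizedExperiment::colData(object)$class
        tab <- table(cls)
        if (length(tab) < 2L)
            msg <- c(msg, "at least 2 distinct classes are required")
        if (any(tab < 2L))
            msg <- c(msg, sprintf("class '%s' has fewer than 2 samples",
                                  names(tab)[tab < 2L][1L]))
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers).
#' @param labels class label per sample: either an unnamed vector aligned to
#'   the columns of \code{values}, or a named vector / 2-column mapping that
#'   is matched by sample identifier.
#' @param batch optional per-sample batch label (same alignment rules).
#' @return An \linkS4class{ExpressionDataset}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("A", "B", "C"), paste0("S", 1:4)))
#' ds <- ExpressionDataset(m, c("ctrl", "ctrl", "case", "case"))
#' classLabels(ds)
#' @export
ExpressionDataset <- function(values, labels, batch = NULL) {
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix")
    if (is.null(colnames(values)))
        colnames(values) <- paste0("S", seq_len(ncol(values)))
    labels <- .alignSampleAnnotation(labels, colnames(values), "labels")
    cd <- S4Vectors::DataFrame(class = factor(labels),
                               row.names = colnames(values))
    if (!is.null(batch))
        cd$batch <- factor(.alignSampleAnnotation(batch, colnames(values),
                                                  "batch"))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = cd,
        rowData = S4Vectors::DataFrame(zeroVariance = logical(nrow(values)),
                                       row.names = rownames(values)))
    S4Vectors::metadata(se)$zTransformed <- FALSE
    new("ExpressionDataset", se)
}

.alignSampleAnnotation <- function(x, sampleIds, what) {
    if (!is.null(names(x))) {
        missing <- setdiff(sampleIds, names(x))
        if (length(missing))
            stop(sprintf("sample '%s' has no %s entry", missing[1L], what))
        x <- x[sampleIds]
    } else if (length(x) != length(sampleIds)) {
        stop(sprintf("'%s' length (%d) does not match sample count (%d)",
                     what, length(x), length(sampleIds)))
    }
    as.character(x)
}

#' GeneSetCollection: named gene lists scoping each subnetwork search
#'
#' Holds a list of gene sets (pathways): unique set identifiers, one
#' free-text description per set, and a character vector of unique member
#' genes per set.
#'
#' @seealso \code{\link{readGeneSets}}, \code{\link{generateGeneSets}}
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    ids <- names(object@sets)
    if (length(object@sets) && (is.null(ids) || anyDuplicated(ids)))
        msg <- c(msg, "set identifiers must be unique and non-empty")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
        msg <- c(msg, "members within a set must be unique")
    if (length(object@descriptions) != length(object@sets))
        msg <- c(msg, "one description per set is required")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors (member genes per set).
#' @param descriptions optional character vector of descriptions, recycled
#'   from \code{""}.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, as.character)
    if (is.null(descriptions))
        descriptions <- rep("", length(sets))
    names(descriptions) <- names(sets)
    new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' InteractionNetwork: an undirected simple graph over gene symbols
#'
#' The scaffold constraining which genes may join a subnetwork. Always
#' simple: no self-loops, no duplicate unordered pairs; every edge endpoint
#' is a node. Isolated nodes are permitted.
#'
#' @seealso \code{\link{readNetwork}}, \code{\link{generateNetwork}}
#' @export
setClass("InteractionNetwork",
         representation(nodes = "character", edges = "matrix"))

setValidity("InteractionNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (ncol(e) != 2L)
        msg <- c(msg, "edges must be a 2-column matrix")
    else if (nrow(e)) {
        if (any(e[, 1L] == e[, 2L]))
            msg <- c(msg, "self-loops are not allowed")
        key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate unordered edges are not allowed")
        if (!all(e %in% object@nodes))
            msg <- c(msg, "every edge endpoint must be a node")
    }
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "node identifiers must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork
#'
#' Self-loops and duplicate unordered edges are removed on construction, the
#' same cleaning applied when reading interaction files.
#'
#' @param edges 2-column character matrix (or data frame) of gene pairs.
#' @param nodes optional node universe; defaults to the edge endpoints.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
InteractionNetwork <- function(edges, nodes = NULL) {
    edges <- as.matrix(edges)
    if (length(edges) == 0L)
        edges <- matrix(character(), 0L, 2L)
    storage.mode(edges) <- "character"
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
    if (nrow(edges)) {
        key <- paste(pmin(edges[, 1L], edges[, 2L]),
                     pmax(edges[, 1L], edges[, 2L]))
        edges <- edges[!duplicated(key), , drop = FALSE]
    }
    if (is.null(nodes))
        nodes <- sort(unique(as.vector(edges)))
    else
        nodes <- sort(unique(c(as.character(nodes), as.vector(edges))))
    dimnames(edges) <- NULL
    new("InteractionNetwork", nodes = nodes, edges = edges)
}

#' Subnetwork: a signed, rooted tree of genes with activity and score
#'
#' Result of one seed expansion. \code{members} is ordered with the seed
#' first; \code{parents} records, per member, the network neighbour through
#' which it was attached (\code{NA} for the seed), so the parent links form a
#' tree rooted at the seed (a path for the greedy strategy). \code{signs}
#' holds the correlation-derived orientation (+1/-1, seed fixed +1) used in
#' the activity aggregation. \code{trace} records every expansion iteration:
#' the winning candidate, the score before and after, and whether it was
#' accepted.
#'
#' @seealso \code{\link{identifySubnetworks}}, \code{\link{scoreSubnetwork}}
#' @export
setClass("Subnetwork",
         representation(geneSetId = "character", seed = "character",
                        members = "character", parents = "character",
                        signs = "numeric", activity = "numeric",
                        fValue = "numeric", pValue = "numeric",
                        dfBetween = "integer", dfWithin = "integer",
                        strategy = "character", trace = "data.frame"))

setValidity("Subnetwork", function(object) {
    msg <- character()
    n <- length(object@members)
    if (n < 1L || object@members[1L] != object@seed)
        msg <- c(msg, "members must be non-empty with the seed first")
    if (length(object@parents) != n || length(object@signs) != n)
        msg <- c(msg, "parents and signs must align with members")
    else {
        if (!is.na(object@parents[1L]))
            msg <- c(msg, "the seed has no parent")
        if (n > 1L && !all(object@parents[-1L] %in% object@members))
            msg <- c(msg, "every non-seed parent must be a member")
        if (!all(object@signs %in% c(-1, 1)) || object@signs[1L] != 1)
            msg <- c(msg, "signs must be +/-1 with the seed fixed at +1")
    }
    if (length(msg)) msg else TRUE
})

.Subnetwork <- function(geneSetId, seed, members, parents, signs, activity,
                        score, strategy, trace) {
    new("Subnetwork", geneSetId = geneSetId, seed = seed, members = members,
        parents = parents, signs = as.numeric(signs), activity = activity,
        fValue = score$fValue, pValue = score$pValue,
        dfBetween = score$dfBetween, dfWithin = score$dfWithin,
        strategy = strategy, trace = trace)
}
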
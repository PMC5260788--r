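#' Accessors for netmark classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x a netmark object.
#' @param id a gene-set identifier.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("isZTransformed", function(x) standardGeneric("isZTransformed"))
#' @rdname accessors
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))
#' @rdname accessors
#' @export
setGeneric("geneSet", function(x, id) standardGeneric("geneSet"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("memberSigns", function(x) standardGeneric("memberSigns"))
#' @rdname accessors
#' @export
setGeneric("memberParents", function(x) standardGeneric("memberParents"))
#' @rdname accessors
#' @export
setGeneric("seedGene", function(x) standardGeneric("seedGene"))
#' @rdname accessors
#' @export
setGeneric("fValue", function(x) standardGeneric("fValue"))
#' @rdname accessors
#' @export
setGeneric("geneSetId", function(x) standardGeneric("geneSetId"))
#' @rdname accessors
#' @export
setGeneric("searchStrategy", function(x) standardGeneric("searchStrategy"))
#' @rdname accessors
#' @export
setGeneric("searchTrace", function(x) standardGeneric("searchTrace"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionDataset", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionDataset", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionDataset",
          function(x) SummarizedExperiment::assay(x, "exprs"))
#' @rdname accessors
#' @export
setMethod("classLabels", "ExpressionDataset",
          function(x) SummarizedExperiment::colData(x)$class)
#' @rdname accessors
#' @export
setMethod("isZTransformed", "ExpressionDataset",
          function(x) isTRUE(S4Vectors::metadata(x)$zTransformed))

#' @rdname accessors
#' @export
setMethod("setIds", "GeneSetCollection", function(x) names(x@sets))
#' @rdname accessors
#' @export
setMethod("geneSet", "GeneSetCollection", function(x, id) {
    if (!id %in% names(x@sets))
        stop(sprintf("unknown gene set '%s'", id))
    x@sets[[id]]
})
#' @rdname accessors
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname accessors
#' @export
setMethod("networkNodes", "InteractionNetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("networkEdges", "InteractionNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("members", "Subnetwork", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("memberSigns", "Subnetwork", function(x) x@signs)
#' @rdname accessors
#' @export
setMethod("memberParents", "Subnetwork", function(x) x@parents)
#' @rdname accessors
#' @export
setMethod("seedGene", "Subnetwork", function(x) x@seed)
#' @rdname accessors
#' @export
setMethod("fValue", "Subnetwork", function(x) x@fValue)
#' @rdname accessors
#' @export
setMethod("geneSetId", "Subnetwork", function(x) x@geneSetId)
#' @rdname accessors
#' @export
setMethod("searchStrategy", "Subnetwork", function(x) x@strategy)
#' @rdname accessors
#' @export
setMethod("searchTrace", "Subnetwork", function(x) x@trace)

setMethod("show", "ExpressionDataset", function(object) {
    cat(sprintf("ExpressionDataset: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    tab <- table(classLabels(object))
    cat("classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
    cat("z-transformed:", isZTransformed(object), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
    sizes <- lengths(object@sets)
    cat(sprintf("GeneSetCollection: %d sets", length(object@sets)))
    if (length(sizes))
        cat(sprintf(" (sizes %d-%d, %d distinct genes)",
                    min(sizes), max(sizes),
                    length(unique(unlist(object@sets)))))
    cat("\n")
})

setMethod("show", "InteractionNetwork", function(object) {
    cat(sprintf("InteractionNetwork: %d nodes, %d edges\n",
                length(object@nodes), nrow(object@edges)))
})

setMethod("show", "Subnetwork", function(object) {
    cat(sprintf("Subnetwork [%s] in set %s: %d members, F = %.4g\n",
                object@strategy, object@geneSetId, length(object@members),
                object@fValue))
    sgn <- ifelse(object@signs > 0, "+", "-")
    cat("  ", paste0(sgn, object@members, collapse = " "), "\n")
})
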
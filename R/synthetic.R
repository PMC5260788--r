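#' Generate a scale-free interaction network
#'
#' Preferential-attachment (Barabasi-Albert) graph: connected, simple,
#' undirected, with the heavy-tailed degree distribution typical of
#' gene-gene and protein-protein interaction networks. Deterministic given
#' the seed.
#'
#' @param nGenes number of genes (>= 10).
#' @param attachment edges added per new node (igraph \code{m}).
#' @param rngSeed integer seed.
#' @return An \linkS4class{InteractionNetwork} with nodes
#'   \code{g0001, g0002, ...}.
#' @export
generateNetwork <- function(nGenes, attachment = 2L, rngSeed = 1L) {
    if (nGenes < 10L)
        stop("'nGenes' must be >= 10")
    if (attachment < 1L)
        stop("'attachment' must be >= 1")
    set.seed(rngSeed)
    g <- igraph::sample_pa(nGenes, power = 1, m = attachment,
                           directed = FALSE)
    g <- igraph::simplify(g)
    nodes <- sprintf("g%04d", seq_len(nGenes))
    e <- igraph::as_edgelist(g, names = FALSE)
    InteractionNetwork(cbind(nodes[e[, 1L]], nodes[e[, 2L]]), nodes = nodes)
}

# adjacency as named list for generator internals
.netAdj <- function(network) .adjacency(network)

#' Generate overlapping gene sets as random-walk neighbourhoods
#'
#' Each set gets a connected core grown by a random walk inside the largest
#' available connected region of the network, so every set contains a
#' connected subgraph (the substrate the subnetwork search needs); if the
#' region is smaller than the requested size, the remainder is filled with
#' unattached eligible genes, mirroring curated pathways whose members are
#' not all mutually interacting. With \code{overlapFraction = 0} sets are
#' pairwise disjoint; larger values admit genes already used by earlier
#' sets with that probability, giving loosely controlled pairwise overlap.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param nSets number of sets.
#' @param setSizeRange integer length-2: min and max set size.
#' @param overlapFraction probability of accepting an already-used gene
#'   during growth (0 = disjoint).
#' @param rngSeed integer seed.
#' @return A \linkS4class{GeneSetCollection} with ids \code{set01, ...}.
#' @export
generateGeneSets <- function(network, nSets = 5L, setSizeRange = c(20L, 40L),
                             overlapFraction = 0, rngSeed = 1L) {
    nodes <- networkNodes(network)
    if (max(setSizeRange) > length(nodes))
        stop("set sizes exceed the number of network genes")
    if (overlapFraction == 0 && nSets * min(setSizeRange) > length(nodes))
        stop("disjoint sets of this size are infeasible on this network")
    set.seed(rngSeed)
    adj <- .netAdj(network)
    ig <- igraph::graph_from_edgelist(networkEdges(network),
                                      directed = FALSE)
    used <- character()
    sets <- list()
    for (i in seq_len(nSets)) {
        target <- sample(seq(setSizeRange[1L], setSizeRange[2L]), 1L)
        eligible <- if (overlapFraction > 0)
            c(setdiff(nodes, used),
              used[runif(length(used)) < overlapFraction])
            else setdiff(nodes, used)
        if (length(eligible) < 3L)
            stop(sprintf("could not grow set %d; relax overlap or sizes", i))
        comp <- igraph::components(igraph::induced_subgraph(
            ig, intersect(eligible, igraph::V(ig)$name)))
        big <- which.max(comp$csize)
        if (comp$csize[big] < 3L)
            stop(sprintf("set %d has no connected core of >= 3 genes; relax overlap or sizes",
                         i))
        region <- names(comp$membership)[comp$membership == big]
        # connected core: random walk within the largest free region
        cur <- sample(region, 1L)
        while (length(cur) < min(target, length(region))) {
            frontier <- setdiff(intersect(unique(unlist(
                adj[cur], use.names = FALSE)), region), cur)
            if (length(frontier) == 0L) break
            cur <- c(cur, sample(frontier, 1L))
        }
        # top up with unattached eligible genes when the region is small
        fill <- setdiff(eligible, cur)
        if (length(cur) < target && length(fill))
            cur <- c(cur, sample(fill, min(target - length(cur),
                                           length(fill))))
        sets[[sprintf("set%02d", i)]] <- sort(unique(cur))
        used <- union(used, cur)
    }
    GeneSetCollection(sets, rep("synthetic random-walk neighbourhood",
                                length(sets)))
}

#' Generate labelled expression data with planted active modules
#'
#' Background genes are i.i.d. Gaussian noise. Within each gene set one
#' connected module of genes is "planted": its genes receive a
#' class-dependent mean shift of total magnitude \code{effectSize} (in
#' noise-SD units; \eqn{\pm \Delta/2} for two classes, equally spaced means
#' spanning \eqn{\Delta} for more). Module genes may carry a negative sign,
#' in which case the shift direction is flipped — emulating coherently
#' anti-correlated pathway members (one module per collection gets such
#' genes by default). An optional batch design splits samples into two
#' balanced batches and adds a constant offset to a random subset of genes
#' in batch 2.
#'
#' Passing a previous \code{truth} regenerates data from the same planted
#' modules and batch genes (new noise under \code{rngSeed}), which is how
#' independent datasets from one generative model are produced.
#'
#' @param network an \linkS4class{InteractionNetwork} (genes = its nodes).
#' @param geneSets a \linkS4class{GeneSetCollection} over those genes.
#' @param effectSize class-mean separation in SD units (default 2).
#' @param nPerClass samples per class (>= 2; default 50).
#' @param nClasses number of classes (default 2).
#' @param noiseSd background standard deviation (default 1).
#' @param moduleSize planted module size per gene set (default 5).
#' @param batchShift constant offset added to batch-2 samples on the batch
#'   genes (default 0 = no batch structure).
#' @param batchGeneFraction fraction of genes carrying the batch offset.
#' @param antiCorrelated plant negative-sign members in the first module.
#' @param truth reuse the planted structure of a previous run.
#' @param rngSeed integer seed.
#' @return List with \code{dataset} (an \linkS4class{ExpressionDataset},
#'   raw scale — z-transform before analysis) and \code{truth} (a
#'   \code{"SyntheticTruth"} list: \code{plantedModules} — per set, genes
#'   and signs —, all generator parameters, \code{batchGenes}).
#' @export
generateExpression <- function(network, geneSets, effectSize = 2,
                               nPerClass = 50L, nClasses = 2L, noiseSd = 1,
                               moduleSize = 5L, batchShift = 0,
                               batchGeneFraction = 0.3,
                               antiCorrelated = TRUE, truth = NULL,
                               rngSeed = 1L) {
    if (nPerClass < 2L)
        stop("'nPerClass' must be >= 2")
    genes <- networkNodes(network)
    adj <- .netAdj(network)
    set.seed(rngSeed)
    if (is.null(truth)) {
        planted <- list()
        for (k in seq_along(setIds(geneSets))) {
            id <- setIds(geneSets)[k]
            sg <- geneSet(geneSets, id)
            mod <- .growConnected(sg, adj, moduleSize)
            signs <- rep(1, length(mod))
            if (antiCorrelated && k == 1L && length(mod) >= 2L)
                signs[seq_len(length(mod) %/% 2L)] <- -1
            planted[[id]] <- list(genes = mod, signs = signs)
        }
        batchGenes <- if (batchShift > 0)
            sort(sample(genes, max(1L, round(batchGeneFraction *
                                             length(genes)))))
            else character()
        truth <- structure(list(plantedModules = planted,
                                effectSize = effectSize,
                                nPerClass = as.integer(nPerClass),
                                nClasses = as.integer(nClasses),
                                noiseSd = noiseSd,
                                moduleSize = as.integer(moduleSize),
                                batchShift = batchShift,
                                batchGenes = batchGenes,
                                rngSeed = as.integer(rngSeed)),
                           class = "SyntheticTruth")
    } else {
        truth$rngSeed <- as.integer(rngSeed)
        truth$nPerClass <- as.integer(nPerClass)
        truth$effectSize <- effectSize
        truth$noiseSd <- noiseSd
    }
    n <- nPerClass * nClasses
    labels <- rep(paste0("class", seq_len(nClasses)), each = nPerClass)
    m <- matrix(rnorm(length(genes) * n, sd = noiseSd), length(genes), n,
                dimnames = list(genes, sprintf("s%03d", seq_len(n))))
    classMeans <- if (nClasses == 2L) c(-0.5, 0.5)
                  else (seq_len(nClasses) - 1) / (nClasses - 1) - 0.5
    for (mod in truth$plantedModules) {
        shift <- outer(mod$signs * effectSize,
                       classMeans[rep(seq_len(nClasses), each = nPerClass)])
        m[mod$genes, ] <- m[mod$genes, ] + shift
    }
    batch <- rep(rep(c("b1", "b2"), length.out = nPerClass), nClasses)
    if (truth$batchShift > 0 && length(truth$batchGenes))
        m[truth$batchGenes, batch == "b2"] <-
            m[truth$batchGenes, batch == "b2"] + truth$batchShift
    list(dataset = ExpressionDataset(m, labels, batch = batch),
         truth = truth)
}

# grow a connected subgraph of the given size inside candidate genes
.growConnected <- function(setGenes, adj, size) {
    starts <- sample(setGenes)
    for (s in starts) {
        cur <- s
        repeat {
            if (length(cur) >= size) return(sort(cur))
            frontier <- setdiff(intersect(
                unique(unlist(adj[cur], use.names = FALSE)), setGenes), cur)
            if (length(frontier) == 0L) break
            cur <- c(cur, sample(frontier, 1L))
        }
    }
    sort(cur)  # largest reachable region if the target size is infeasible
}

#' Recovery of planted modules by identified subnetworks
#'
#' Compares the member genes of identified representatives against the
#' planted ground truth, per gene set: precision = |found and planted| /
#' |found|, recall = |found and planted| / |planted|, F1 their harmonic
#' mean. An unrepresented gene set counts precision and recall 0 (logged
#' convention for empty identification).
#'
#' @param identified list of \linkS4class{Subnetwork} or a
#'   \code{"SubnetworkRun"}.
#' @param truth a \code{"SyntheticTruth"} from
#'   \code{\link{generateExpression}}.
#' @return List with \code{perSet} (data frame: gene_set_id, nIdentified,
#'   nPlanted, precision, recall, f1) and \code{aggregate} (means across
#'   sets plus pooled precision/recall over all genes).
#' @export
recoveryMetrics <- function(identified, truth) {
    if (inherits(identified, "SubnetworkRun"))
        identified <- identified$representatives
    found <- setNames(vector("list", length(truth$plantedModules)),
                      names(truth$plantedModules))
    for (s in identified)
        found[[geneSetId(s)]] <- union(found[[geneSetId(s)]], members(s))
    rows <- lapply(names(truth$plantedModules), function(id) {
        planted <- truth$plantedModules[[id]]$genes
        got <- found[[id]]
        tp <- length(intersect(got, planted))
        prec <- if (length(got)) tp / length(got) else 0
        rec <- if (length(planted)) tp / length(planted) else 0
        f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
        data.frame(gene_set_id = id, nIdentified = length(got),
                   nPlanted = length(planted), precision = prec,
                   recall = rec, f1 = f1, stringsAsFactors = FALSE)
    })
    perSet <- do.call(rbind, rows)
    tpAll <- sum(vapply(names(truth$plantedModules), function(id)
        length(intersect(found[[id]], truth$plantedModules[[id]]$genes)),
        0L))
    nFound <- sum(lengths(found))
    nPlanted <- sum(vapply(truth$plantedModules,
                           function(m) length(m$genes), 0L))
    list(perSet = perSet,
         aggregate = list(
             meanPrecision = mean(perSet$precision),
             meanRecall = mean(perSet$recall),
             meanF1 = mean(perSet$f1),
             pooledPrecision = if (nFound) tpAll / nFound else 0,
             pooledRecall = if (nPlanted) tpAll / nPlanted else 0))
}

#' Write a synthetic benchmark to disk in the standard formats
#'
#' Convenience wrapper for the command-line workflow: writes the expression
#' matrix + labels, the GMT gene sets, the edge-list network and a
#' \code{truth.json}.
#'
#' @param network,geneSets,sim generator outputs (\code{sim} from
#'   \code{\link{generateExpression}}).
#' @param outDir output directory.
#' @return Invisibly, \code{outDir}.
#' @export
writeSyntheticRun <- function(network, geneSets, sim, outDir) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop(sprintf("cannot create output directory: %s", outDir))
    writeExpression(sim$dataset, file.path(outDir, "expression.tsv"),
                    file.path(outDir, "labels.tsv"))
    writeGeneSets(geneSets, file.path(outDir, "gene_sets.gmt"))
    writeNetwork(network, file.path(outDir, "network.tsv"))
    jsonlite::write_json(unclass(sim$truth),
                         file.path(outDir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(outDir)
}
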
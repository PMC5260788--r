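#' Search configuration
#'
#' Bundles the tunable parameters of the subnetwork search.
#'
#' @param strategy expansion strategy: \code{"gs"} (gene-set-based: pool =
#'   neighbours of every current member), \code{"pn"} (parent-node-based:
#'   same pool, candidates ranked by a two-gene parent/candidate score), or
#'   \code{"greedy"} (pool = neighbours of the last-added member only,
#'   yielding path-shaped subnetworks).
#' @param alpha per-gene ANOVA significance level for seed eligibility
#'   (default 0.05, uncorrected).
#' @param seedFraction fraction of significant genes, ranked by network
#'   degree, taken as seeds (default 0.10; quota =
#'   \code{max(1, ceiling(seedFraction * n_sig))}).
#' @param minSize minimum member count for a subnetwork to be reported
#'   (default 3).
#' @param maxIterations safety cap on accepted expansions per seed.
#' @param scope \code{"gene_set"} (default): degrees and candidate pools
#'   are computed on the subgraph induced by the gene set intersected with
#'   the measured genes; \code{"global"}: the whole measured network is
#'   eligible, so subnetworks may grow beyond the gene set.
#' @param rngSeed integer recorded in manifests; the search itself is
#'   deterministic and draws no random numbers.
#' @return A list of class \code{"SearchConfig"}.
#' @export
searchConfig <- function(strategy = c("gs", "pn", "greedy"), alpha = 0.05,
                         seedFraction = 0.10, minSize = 3L,
                         maxIterations = 100L,
                         scope = c("gene_set", "global"), rngSeed = 1L) {
    strategy <- match.arg(strategy)
    scope <- match.arg(scope)
    stopifnot(alpha > 0, alpha < 1, seedFraction > 0, seedFraction <= 1,
              minSize >= 1)
    structure(list(strategy = strategy, alpha = alpha,
                   seedFraction = seedFraction, minSize = as.integer(minSize),
                   maxIterations = as.integer(maxIterations), scope = scope,
                   rngSeed = as.integer(rngSeed)),
              class = "SearchConfig")
}

# adjacency list (sorted neighbours) over a node subset
.adjacency <- function(network, restrictTo = NULL) {
    e <- networkEdges(network)
    nodes <- networkNodes(network)
    if (!is.null(restrictTo)) {
        nodes <- intersect(nodes, restrictTo)
        keep <- e[, 1L] %in% nodes & e[, 2L] %in% nodes
        e <- e[keep, , drop = FALSE]
    }
    adj <- setNames(vector("list", length(nodes)), nodes)
    for (nm in nodes) adj[[nm]] <- character()
    if (nrow(e)) {
        half <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
        adj[names(half)] <- lapply(half, function(x) sort(unique(x)))
    }
    adj
}

#' Per-gene significant genes within a gene set
#'
#' Runs the per-gene one-way ANOVA over the set's genes measured in the
#' dataset and returns those with p below \code{alpha}. No multiple-testing
#' correction is applied.
#'
#' @param dataset a z-transformed \linkS4class{ExpressionDataset}.
#' @param genes character vector of gene-set members.
#' @param alpha significance level.
#' @return Character vector of significant genes (dataset row order);
#'   empty, with a warning, when the set shares no genes with the dataset.
#' @export
significantGenes <- function(dataset, genes, alpha = 0.05) {
    measured <- intersect(geneIds(dataset), genes)
    if (length(measured) == 0L) {
        warning("gene set shares no genes with the dataset")
        return(character())
    }
    res <- .rowAnovaF(exprValues(dataset)[measured, , drop = FALSE],
                      classLabels(dataset))
    measured[res$pValue < alpha]
}

#' Select seed genes: top-degree significant genes
#'
#' Ranks the significant genes by their number of neighbours on the search
#' subgraph (the gene set intersected with measured genes by default) and
#' keeps the top \code{max(1, ceiling(seedFraction * n))}; ties at the
#' quota boundary break by lexicographic gene id.
#'
#' @param sigGenes significant genes (from \code{\link{significantGenes}}).
#' @param network an \linkS4class{InteractionNetwork}.
#' @param genes the gene-set members defining the subgraph (with
#'   \code{scope = "global"}, pass the full measured gene universe).
#' @param dataset the dataset (defines which genes are measured).
#' @param seedFraction fraction of significant genes to keep.
#' @return Character vector of seed genes, highest degree first.
#' @export
selectSeeds <- function(sigGenes, network, genes, dataset,
                        seedFraction = 0.10) {
    if (length(sigGenes) == 0L)
        return(character())
    universe <- intersect(genes, geneIds(dataset))
    adj <- .adjacency(network, universe)
    deg <- vapply(sigGenes, function(g)
        if (g %in% names(adj)) length(adj[[g]]) else 0L, 0L)
    quota <- max(1L, as.integer(ceiling(seedFraction * length(sigGenes))))
    ord <- order(-deg, sigGenes)
    sigGenes[ord][seq_len(min(quota, length(sigGenes)))]
}

#' Candidate pool for the next expansion step
#'
#' For \code{gs}/\code{pn}: all network neighbours of any current member.
#' For \code{greedy}: neighbours of the most recently added member only.
#' Always restricted to the search universe (gene set by default) and to
#' genes measured in the dataset, excluding current members.
#'
#' @param currentMembers ordered member genes (seed first).
#' @param network an \linkS4class{InteractionNetwork}.
#' @param genes gene-set members (the search universe under the default
#'   scope).
#' @param dataset the dataset.
#' @param strategy \code{"gs"}, \code{"pn"} or \code{"greedy"}.
#' @return Sorted character vector of candidate genes (possibly empty).
#' @export
candidatePool <- function(currentMembers, network, genes, dataset,
                          strategy = c("gs", "pn", "greedy")) {
    strategy <- match.arg(strategy)
    universe <- intersect(genes, geneIds(dataset))
    adj <- .adjacency(network, universe)
    .poolFromAdj(currentMembers, adj, strategy)
}

.poolFromAdj <- function(members, adj, strategy) {
    frontier <- if (strategy == "greedy") members[length(members)]
                else members
    frontier <- intersect(frontier, names(adj))
    cand <- unique(unlist(adj[frontier], use.names = FALSE))
    sort(setdiff(cand, members))
}

# correlation of one vector against the rows of a matrix; zero-variance
# rows (either side) give 0 per the tie convention
.corToRows <- function(x, zrows) {
    r <- suppressWarnings(as.numeric(cor(x, t(zrows))))
    r[!is.finite(r)] <- 0
    r
}

# One full expansion run from a seed. adj is the adjacency list over the
# search universe; zmat holds z-scores for that universe.
.expandFromSeed <- function(seed, strategy, adj, zmat, labels, maxIter,
                            setId) {
    n <- 1L
    members <- seed
    parents <- NA_character_
    signs <- 1
    raw <- zmat[seed, ]                       # unscaled signed z sum
    score <- anovaF(raw, labels)
    trace <- list()
    it <- 0L
    repeat {
        if (it >= maxIter)
            break
        pool <- .poolFromAdj(members, adj, strategy)
        if (length(pool) == 0L)
            break
        it <- it + 1L
        act <- raw / sqrt(n)
        if (strategy %in% c("gs", "greedy")) {
            zc <- zmat[pool, , drop = FALSE]
            cs <- ifelse(.corToRows(act, zc) >= 0, 1, -1)
            newActs <- (matrix(raw, nrow = length(pool), ncol = ncol(zmat),
                               byrow = TRUE) + cs * zc) / sqrt(n + 1)
            fs <- .rowAnovaF(newActs, labels)$fValue
            best <- which.max(fs)             # pool sorted: ties -> lexicographic
            g <- pool[best]
            candScore <- fs[best]
            accepted <- candScore > score$fValue
            parent <- if (strategy == "greedy") members[n]
                      else .gsParent(g, members, adj)
            gSign <- cs[best]
            newF <- candScore
        } else {                              # pn: rank by parent/candidate pair F
            bestPair <- NULL
            for (g in pool) {
                ps <- sort(intersect(adj[[g]], members))
                for (p in ps) {
                    s <- if (pearsonR(zmat[p, ], zmat[g, ]) >= 0) 1 else -1
                    pairAct <- (zmat[p, ] + s * zmat[g, ]) / sqrt(2)
                    pf <- anovaF(pairAct, labels)$fValue
                    if (is.null(bestPair) || pf > bestPair$f)
                        bestPair <- list(g = g, p = p, f = pf)
                }
            }
            g <- bestPair$g
            parent <- bestPair$p
            candScore <- bestPair$f
            gSign <- if (pearsonR(act, zmat[g, ]) >= 0) 1 else -1
            newF <- anovaF((raw + gSign * zmat[g, ]) / sqrt(n + 1),
                           labels)$fValue
            accepted <- newF > score$fValue
        }
        trace[[it]] <- data.frame(
            iteration = it, candidate = g, parent = parent, sign = gSign,
            candidateScore = candScore, fBefore = score$fValue,
            fAfter = if (accepted) newF else NA_real_, accepted = accepted,
            poolSize = length(pool), stringsAsFactors = FALSE)
        if (!accepted)
            break
        members <- c(members, g)
        parents <- c(parents, parent)
        signs <- c(signs, gSign)
        raw <- raw + gSign * zmat[g, ]
        n <- n + 1L
        score <- anovaF(raw / sqrt(n), labels)
    }
    traceDf <- if (length(trace)) do.call(rbind, trace)
               else data.frame(iteration = integer(), candidate = character(),
                               parent = character(), sign = numeric(),
                               candidateScore = numeric(), fBefore = numeric(),
                               fAfter = numeric(), accepted = logical(),
                               poolSize = integer(),
                               stringsAsFactors = FALSE)
    act <- raw / sqrt(n)
    names(act) <- colnames(zmat)
    .Subnetwork(setId, seed, members, parents, signs, act, score, strategy,
                traceDf)
}

# parent attribution for GS acceptance: the member neighbour of g with the
# highest within-subnetwork degree, ties lexicographic
.gsParent <- function(g, members, adj) {
    cands <- sort(intersect(adj[[g]], members))
    if (length(cands) <= 1L)
        return(cands[1L])
    wdeg <- vapply(cands, function(m)
        length(intersect(adj[[m]], members)), 0L)
    cands[order(-wdeg, cands)][1L]
}

#' Identify gene subnetworks for every gene set
#'
#' The full pipeline, run independently per gene set: per-gene ANOVA
#' significance screen at \code{alpha}; seed selection (top-degree fraction
#' of significant genes); one expansion loop per seed under the configured
#' strategy, terminating when no candidate remains or the best candidate no
#' longer improves the subnetwork F (strict improvement); the max-F
#' subnetwork among the seeds becomes the gene set's representative (ties
#' by lexicographic seed id). Deterministic given inputs and configuration.
#'
#' @param dataset a z-transformed \linkS4class{ExpressionDataset}.
#' @param geneSets a \linkS4class{GeneSetCollection}.
#' @param network an \linkS4class{InteractionNetwork}.
#' @param config a \code{\link{searchConfig}}.
#' @param verbose emit per-gene-set progress messages.
#' @return A list of class \code{"SubnetworkRun"}: \describe{
#'   \item{representatives}{named list (by set id) of
#'     \linkS4class{Subnetwork}, one per gene set with >=1 significant
#'     gene.}
#'   \item{all}{every per-seed \linkS4class{Subnetwork}.}
#'   \item{skipped}{named character: per skipped set, the reason.}
#'   \item{config}{the configuration used.}}
#' @export
identifySubnetworks <- function(dataset, geneSets, network,
                                config = searchConfig(), verbose = FALSE) {
    if (!isZTransformed(dataset))
        stop("dataset must be z-transformed first; see zTransform()")
    labels <- classLabels(dataset)
    z <- exprValues(dataset)
    measuredAll <- geneIds(dataset)
    pAll <- setNames(.rowAnovaF(z, labels)$pValue, measuredAll)
    globalAdj <- if (config$scope == "global")
        .adjacency(network, measuredAll) else NULL

    reps <- list(); all <- list(); skipped <- character()
    for (setId in setIds(geneSets)) {
        setGenes <- geneSet(geneSets, setId)
        measured <- intersect(measuredAll, setGenes)
        sig <- measured[pAll[measured] < config$alpha]
        if (length(sig) == 0L) {
            skipped[setId] <- if (length(measured)) "no significant genes"
                              else "no measured genes"
            if (verbose)
                message(sprintf("[%s] skipped: %s", setId, skipped[setId]))
            next
        }
        universe <- if (config$scope == "global") measuredAll else measured
        adj <- if (config$scope == "global") globalAdj
               else .adjacency(network, measured)
        deg <- vapply(sig, function(g)
            if (g %in% names(adj)) length(adj[[g]]) else 0L, 0L)
        quota <- max(1L, as.integer(ceiling(config$seedFraction *
                                            length(sig))))
        seeds <- sig[order(-deg, sig)][seq_len(min(quota, length(sig)))]
        zmat <- z[universe, , drop = FALSE]
        subs <- lapply(seeds, function(s)
            .expandFromSeed(s, config$strategy, adj, zmat, labels,
                            config$maxIterations, setId))
        names(subs) <- seeds
        fs <- vapply(subs, fValue, 0)
        best <- sort(seeds)[which.max(fs[sort(seeds)])]  # ties -> lexicographic
        reps[[setId]] <- subs[[best]]
        all <- c(all, unname(subs))
        if (verbose)
            message(sprintf(
                "[%s] %d significant, %d seed(s), representative %s (F=%.3f, %d members)",
                setId, length(sig), length(seeds), best,
                fValue(subs[[best]]), length(members(subs[[best]]))))
    }
    structure(list(representatives = reps, all = all, skipped = skipped,
                   config = config),
              class = "SubnetworkRun")
}

#' @export
print.SubnetworkRun <- function(x, ...) {
    cat(sprintf("SubnetworkRun (%s): %d representative(s), %d skipped set(s)\n",
                x$config$strategy, length(x$representatives),
                length(x$skipped)))
    for (s in x$representatives) show(s)
    invisible(x)
}

#' Filter subnetworks by minimum member count
#'
#' Only subnetworks with at least \code{minSize} members (default 3) are
#' retained for downstream analysis; smaller ones carry too little
#' interaction structure to be useful biomarkers.
#'
#' @param subnetworks list of \linkS4class{Subnetwork} (or a
#'   \code{"SubnetworkRun"}, whose representatives are filtered).
#' @param minSize minimum member count.
#' @return The filtered list (for a run, the run with filtered
#'   representatives).
#' @export
filterMinSize <- function(subnetworks, minSize = 3L) {
    if (inherits(subnetworks, "SubnetworkRun")) {
        subnetworks$representatives <-
            filterMinSize(subnetworks$representatives, minSize)
        return(subnetworks)
    }
    Filter(function(s) length(members(s)) >= minSize, subnetworks)
}
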
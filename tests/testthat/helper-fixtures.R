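# Shared fixtures and independent oracles for the test suite.

# Small deterministic dataset: 6 genes x 8 samples, 2 classes.
toyDataset <- function(z = TRUE) {
    set.seed(42)
    m <- matrix(rnorm(48), 6, 8,
                dimnames = list(paste0("G", 1:6), paste0("S", 1:8)))
    m["G1", 5:8] <- m["G1", 5:8] + 3          # strong class signal on G1
    ds <- ExpressionDataset(m, rep(c("ctrl", "case"), each = 4))
    if (z) zTransform(ds) else ds
}

# Random labelled dataset over the given genes.
randomDataset <- function(genes, nPerClass = 10, seed = 1, nClasses = 2) {
    set.seed(seed)
    n <- nPerClass * nClasses
    m <- matrix(rnorm(length(genes) * n), length(genes), n,
                dimnames = list(genes, sprintf("s%02d", 1:n)))
    zTransform(ExpressionDataset(
        m, rep(paste0("c", 1:nClasses), each = nPerClass)))
}

edgesToNetwork <- function(...) {
    InteractionNetwork(matrix(c(...), ncol = 2, byrow = TRUE))
}

# Independent one-way ANOVA oracle via stats::oneway.test (equal variances).
oracleF <- function(values, labels) {
    unname(stats::oneway.test(values ~ factor(labels),
                              var.equal = TRUE)$statistic)
}

# Independent purity oracle: explicit confusion-matrix walk.
oraclePurity <- function(clusters, statuses) {
    n <- length(statuses)
    j <- length(unique(statuses))
    raw <- 0
    for (k in unique(clusters)) {
        inK <- statuses[clusters == k]
        raw <- raw + max(vapply(unique(statuses),
                                function(s) sum(inK == s), 0L))
    }
    raw <- raw / n
    (raw * j - 1) / (j - 1)
}

# Brute-force recomputation of one expansion step, independent of the
# search engine's incremental bookkeeping. Returns the winning candidate,
# its comparison score, and whether it improves the current subnetwork F.
bruteStep <- function(memberGenes, signs, adjList, dataset, strategy) {
    labels <- classLabels(dataset)
    z <- exprValues(dataset)
    frontier <- if (strategy == "greedy")
        memberGenes[length(memberGenes)] else memberGenes
    frontier <- intersect(frontier, names(adjList))
    pool <- sort(setdiff(unique(unlist(adjList[frontier])), memberGenes))
    if (length(pool) == 0L)
        return(NULL)
    curAct <- subnetworkActivity(memberGenes, signs, dataset)
    curF <- anovaF(curAct, labels)$fValue
    if (strategy %in% c("gs", "greedy")) {
        fs <- vapply(pool, function(g) {
            s <- signForCandidate(curAct, z[g, ])
            anovaF(subnetworkActivity(c(memberGenes, g), c(signs, s),
                                      dataset), labels)$fValue
        }, 0)
        best <- pool[which.max(fs)]
        list(candidate = best, score = max(fs), pool = pool,
             improves = max(fs) > curF)
    } else {
        bestG <- NULL; bestP <- NULL; bestF <- -Inf
        for (g in pool) {
            for (p in sort(intersect(adjList[[g]], memberGenes))) {
                s <- if (pearsonR(z[p, ], z[g, ]) >= 0) 1 else -1
                f <- anovaF((z[p, ] + s * z[g, ]) / sqrt(2),
                            labels)$fValue
                if (f > bestF) { bestF <- f; bestG <- g; bestP <- p }
            }
        }
        sFull <- signForCandidate(curAct, z[bestG, ])
        fullF <- anovaF(subnetworkActivity(c(memberGenes, bestG),
                                           c(signs, sFull), dataset),
                        labels)$fValue
        list(candidate = bestG, parent = bestP, score = bestF, pool = pool,
             improves = fullF > curF)
    }
}

# adjacency list helper mirroring the public candidatePool restriction
adjFor <- function(network, genes, dataset) {
    universe <- intersect(genes, geneIds(dataset))
    e <- networkEdges(network)
    keep <- e[, 1] %in% universe & e[, 2] %in% universe
    e <- e[keep, , drop = FALSE]
    adj <- setNames(lapply(universe, function(x) character()), universe)
    for (i in seq_len(nrow(e))) {
        adj[[e[i, 1]]] <- sort(unique(c(adj[[e[i, 1]]], e[i, 2])))
        adj[[e[i, 2]]] <- sort(unique(c(adj[[e[i, 2]]], e[i, 1])))
    }
    adj
}

# Replays a trace: checks every accepted step of a finished subnetwork
# against bruteStep. Returns TRUE or a description of the first mismatch.
replayMatchesBrute <- function(subnet, network, genes, dataset) {
    adjList <- adjFor(network, genes, dataset)
    mem <- members(subnet)
    sg <- memberSigns(subnet)
    strategy <- searchStrategy(subnet)
    for (i in seq_along(mem)[-1]) {
        step <- bruteStep(mem[seq_len(i - 1)], sg[seq_len(i - 1)],
                          adjList, dataset, strategy)
        if (is.null(step) || !step$improves)
            return(sprintf("step %d: engine accepted but oracle would stop", i))
        if (step$candidate != mem[i])
            return(sprintf("step %d: oracle picked %s, engine %s",
                           i, step$candidate, mem[i]))
    }
    # after the last member the oracle must also stop
    final <- bruteStep(mem, sg, adjFor(network, genes, dataset), dataset,
                       strategy)
    if (!is.null(final) && final$improves)
        return("engine stopped but oracle finds an improving candidate")
    TRUE
}
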
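test_that("seed selection applies the quota and degree/lexicographic tie rules", {
    # star around H plus spokes: distinct degrees
    net <- edgesToNetwork("H", "A", "H", "B", "H", "C", "A", "B")
    ds <- randomDataset(c("H", "A", "B", "C"), nPerClass = 5, seed = 2)
    genes <- c("H", "A", "B", "C")
    # quota 1 of 4 significant genes -> the top-degree gene H
    expect_equal(selectSeeds(genes, net, genes, ds, 0.1), "H")
    # 3 significant genes -> max(1, ceil(0.3)) = 1 seed
    expect_length(selectSeeds(c("A", "B", "C"), net, genes, ds, 0.1), 1L)
    # tie at top degree (A and B both degree 2), quota 1 -> lexicographic
    expect_equal(selectSeeds(c("A", "B"), net, genes, ds, 0.1), "A")
    # quota covers everything when the fraction is 1
    expect_length(selectSeeds(genes, net, genes, ds, 1), 4L)
})

test_that("per-gene significance screen matches its nominal null rate and power", {
    # null: no class signal -> ~alpha of genes pass (binomial check)
    ds <- randomDataset(paste0("N", 1:200), nPerClass = 20, seed = 9)
    hits <- length(significantGenes(ds, paste0("N", 1:200), alpha = 0.05))
    expect_gte(hits, qbinom(0.005, 200, 0.05))
    expect_lte(hits, qbinom(0.995, 200, 0.05))
    # planted delta = 3 SD at n = 20/class: essentially always detected
    set.seed(10)
    m <- rbind(SIG = rep(c(0, 3), each = 20),
               matrix(rnorm(39 * 40), 39, 40,
                      dimnames = list(paste0("N", 1:39), NULL)))
    m["SIG", ] <- m["SIG", ] + rnorm(40)
    colnames(m) <- paste0("S", 1:40)
    dsP <- zTransform(ExpressionDataset(m, rep(c("a", "b"), each = 20)))
    expect_true("SIG" %in% significantGenes(dsP, rownames(m)))
    # empty intersection
    expect_warning(out <- significantGenes(ds, c("X1", "X2")), "no genes")
    expect_length(out, 0L)
})

test_that("candidate pools respect the strategy, the gene set and membership", {
    net <- edgesToNetwork("s", "a", "a", "b", "a", "c", "s", "d", "d", "e")
    genes <- c("s", "a", "b", "c", "d")      # e outside the gene set
    ds <- randomDataset(c("s", "a", "b", "c", "d", "e"), nPerClass = 5,
                        seed = 4)
    # greedy: neighbours of the last member only
    expect_equal(candidatePool(c("s", "a"), net, genes, ds, "greedy"),
                 c("b", "c"))
    # gs: neighbours of any member; e excluded (not in the gene set)
    expect_equal(candidatePool(c("s", "a"), net, genes, ds, "gs"),
                 c("b", "c", "d"))
    # all neighbours already members -> empty pool
    expect_length(candidatePool(c("s", "a", "b", "c", "d"), net, genes,
                                ds, "gs"), 0L)
})

test_that("every accepted step matches a brute-force recomputation on small graphs", {
    set.seed(77)
    for (rep in 1:12) {
        nV <- sample(5:7, 1)
        genes <- paste0("v", 1:nV)
        # random connected graph: random tree plus extra edges
        e <- cbind(genes[-1], genes[vapply(2:nV, function(i)
            sample(i - 1, 1), 0L)])
        extra <- t(combn(genes, 2))
        extra <- extra[sample(nrow(extra), 3), , drop = FALSE]
        net <- InteractionNetwork(rbind(e, extra))
        ds <- randomDataset(genes, nPerClass = 8, seed = 700 + rep)
        gs <- GeneSetCollection(list(PW = genes))
        for (st in c("gs", "pn", "greedy")) {
            run <- identifySubnetworks(ds, gs, net,
                                       searchConfig(st, minSize = 1))
            for (s in run$all)
                expect_true(isTRUE(replayMatchesBrute(s, net, genes, ds)),
                            info = sprintf("rep %d strategy %s", rep, st))
        }
    }
})

test_that("accepted traces increase strictly in F and topologies are valid trees/paths", {
    net <- generateNetwork(60, 2, rngSeed = 5)
    gs <- generateGeneSets(net, 2, c(15, 25), 0, rngSeed = 5)
    sim <- generateExpression(net, gs, effectSize = 2, nPerClass = 20,
                              rngSeed = 5)
    ds <- zTransform(sim$dataset)
    for (st in c("gs", "pn", "greedy")) {
        run <- identifySubnetworks(ds, gs, net, searchConfig(st,
                                                             minSize = 1))
        for (s in run$all) {
            tr <- searchTrace(s)
            acc <- tr[tr$accepted, ]
            if (nrow(acc)) {
                expect_true(all(acc$fAfter > acc$fBefore))
                expect_true(all(diff(c(acc$fBefore[1], acc$fAfter)) > 0))
            }
            expect_gte(fValue(s), scoreSubnetwork(seedGene(s), 1,
                                                  ds)$fValue)
            # every non-seed member neighbours its parent in the network
            if (length(members(s)) > 1) {
                ed <- networkEdges(net)
                key <- paste(pmin(ed[, 1], ed[, 2]),
                             pmax(ed[, 1], ed[, 2]))
                par <- memberParents(s)[-1]
                ch <- members(s)[-1]
                expect_true(all(paste(pmin(par, ch),
                                      pmax(par, ch)) %in% key))
            }
            if (st == "greedy" && length(members(s)) > 1) {
                # path: each member's parent is the previously added member
                expect_equal(memberParents(s)[-1],
                             members(s)[-length(members(s))])
            }
            # stored score is recomputable from members + signs
            expect_equal(fValue(s),
                         scoreSubnetwork(members(s), memberSigns(s),
                                         ds)$fValue, tolerance = 1e-12)
        }
    }
})

test_that("gs pools dominate greedy pools and gs steps score at least as high", {
    net <- generateNetwork(40, 2, rngSeed = 6)
    genes <- networkNodes(net)
    ds <- randomDataset(genes, nPerClass = 10, seed = 6)
    adjList <- adjFor(net, genes, ds)
    set.seed(61)
    for (i in 1:10) {
        seed <- sample(genes, 1)
        mem <- seed
        sg <- 1
        for (step in 1:3) {
            gsStep <- bruteStep(mem, sg, adjList, ds, "gs")
            grStep <- bruteStep(mem, sg, adjList, ds, "greedy")
            if (is.null(grStep)) break
            expect_true(all(grStep$pool %in% gsStep$pool))
            expect_gte(gsStep$score, grStep$score - 1e-12)
            # grow along the greedy choice to keep the path constraint
            act <- subnetworkActivity(mem, sg, ds)
            s <- signForCandidate(act, exprValues(ds)[grStep$candidate, ])
            mem <- c(mem, grStep$candidate)
            sg <- c(sg, s)
        }
    }
})

test_that("pn ranks candidates by parent-candidate pair score and can reject its winner", {
    # constructed fixture: candidate b pairs best with parent a, but adding
    # b does not improve the full subnetwork -> termination at the winner
    set.seed(91)
    base <- rep(c(-1, 1), each = 10)
    m <- rbind(s = base + rnorm(20, sd = 0.1),
               a = base + rnorm(20, sd = 0.1),
               b = rnorm(20, sd = 0.1),       # null gene, pairs well with no one
               c = rnorm(20))
    colnames(m) <- paste0("S", 1:20)
    ds <- zTransform(ExpressionDataset(m, rep(c("x", "y"), each = 10)))
    net <- edgesToNetwork("s", "a", "a", "b", "a", "c")
    gs <- GeneSetCollection(list(PW = c("s", "a", "b", "c")))
    run <- identifySubnetworks(ds, gs, net, searchConfig("pn", minSize = 1,
                                                         alpha = 0.5))
    s0 <- run$all[[1]]
    tr <- searchTrace(s0)
    # the rejected winner ends the search: no further candidates tried
    if (any(!tr$accepted))
        expect_equal(which(!tr$accepted), nrow(tr))
    # candidate adjacent to two members is scored against both parents
    net2 <- edgesToNetwork("s", "a", "s", "b", "a", "b")
    ds2 <- randomDataset(c("s", "a", "b"), nPerClass = 8, seed = 91)
    adjList <- adjFor(net2, c("s", "a", "b"), ds2)
    step <- bruteStep(c("s", "a"), c(1, 1), adjList, ds2, "pn")
    expect_equal(step$candidate, "b")
    expect_true(step$parent %in% c("s", "a"))
})

test_that("the representative is the max-F subnetwork and reruns are identical", {
    net <- generateNetwork(50, 2, rngSeed = 8)
    gs <- generateGeneSets(net, 2, c(15, 20), 0, rngSeed = 8)
    sim <- generateExpression(net, gs, effectSize = 1.5, nPerClass = 15,
                              rngSeed = 8)
    ds <- zTransform(sim$dataset)
    cfg <- searchConfig("gs", seedFraction = 1, minSize = 1)
    run <- identifySubnetworks(ds, gs, net, cfg)
    for (id in names(run$representatives)) {
        fAll <- vapply(Filter(function(s) geneSetId(s) == id, run$all),
                       fValue, 0)
        expect_equal(fValue(run$representatives[[id]]), max(fAll))
    }
    run2 <- identifySubnetworks(ds, gs, net, cfg)
    expect_identical(lapply(run$representatives, members),
                     lapply(run2$representatives, members))
    expect_identical(vapply(run$representatives, fValue, 0),
                     vapply(run2$representatives, fValue, 0))
})

test_that("minimum-size filtering keeps only large-enough subnetworks, monotonically", {
    mk <- function(n) {
        genes <- paste0("g", seq_len(n))
        new("Subnetwork", geneSetId = "PW", seed = genes[1],
            members = genes,
            parents = c(NA_character_, genes[-n]),
            signs = rep(1, n), activity = numeric(4), fValue = 1,
            pValue = 0.5, dfBetween = 1L, dfWithin = 2L, strategy = "gs",
            trace = data.frame())
    }
    subs <- lapply(c(1, 2, 3, 5), mk)
    expect_length(filterMinSize(subs, 3), 2L)
    expect_length(filterMinSize(subs, 1), 4L)
    counts <- vapply(1:6, function(k) length(filterMinSize(subs, k)), 0L)
    expect_true(all(diff(counts) <= 0))
})
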
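test_that("normalized purity matches hand-evaluated cases", {
    # perfect clustering
    expect_equal(normalizedPurity(c(1, 1, 2, 2),
                                  c("A", "A", "B", "B"))$purityValue, 1)
    # uniform mixtures hit the chance floor exactly
    expect_equal(normalizedPurity(c(1, 1, 2, 2),
                                  c("A", "B", "A", "B"))$purityValue, 0)
    # {A,A,B},{B,B,A}: raw 2/3, normalized 1/3
    res <- normalizedPurity(rep(1:2, each = 3),
                            c("A", "A", "B", "B", "B", "A"))
    expect_equal(res$rawPurity, 2 / 3)
    expect_equal(res$purityValue, 1 / 3)
    expect_error(normalizedPurity(1:4, rep("A", 4)), "single status")
})

test_that("normalized purity agrees with a brute-force oracle on all small clusterings", {
    statuses <- list(c("A", "A", "A", "B", "B", "B"),
                     c("A", "B", "C", "A", "B", "C"),
                     c("A", "A", "B", "B", "C", "C"))
    for (st in statuses) {
        grids <- expand.grid(rep(list(1:3), 6))
        for (i in seq_len(nrow(grids))) {
            cl <- as.integer(grids[i, ])
            expect_equal(normalizedPurity(cl, st)$purityValue,
                         oraclePurity(cl, st), tolerance = 1e-12)
        }
    }
})

test_that("dataset homogeneity separates batch-shifted from matched simulations", {
    net <- generateNetwork(100, 2, rngSeed = 31)
    gs <- generateGeneSets(net, 3, c(15, 25), 0, rngSeed = 31)
    # matched distributions with strong class separation: batches mix,
    # disease drives the clusters
    simA <- generateExpression(net, gs, effectSize = 3, nPerClass = 50,
                               rngSeed = 31)
    simB <- generateExpression(net, gs, effectSize = 3, nPerClass = 50,
                               truth = simA$truth, rngSeed = 32)
    hom <- datasetHomogeneity(simA$dataset, simB$dataset, rngSeed = 1)
    expect_lte(hom$purityB$purityValue, 0.2)
    expect_gte(hom$purityD$purityValue, 0.8)
    # strong batch shift, no class signal: batch dominates
    simC <- generateExpression(net, gs, effectSize = 0, nPerClass = 50,
                               batchShift = 0, rngSeed = 33)
    mShift <- exprValues(simC$dataset) + 6    # dataset-wide offset
    dsShift <- ExpressionDataset(mShift,
                                 as.character(classLabels(simC$dataset)))
    simD <- generateExpression(net, gs, effectSize = 0, nPerClass = 50,
                               rngSeed = 34)
    hom2 <- datasetHomogeneity(dsShift, simD$dataset, rngSeed = 1)
    expect_gte(hom2$purityB$purityValue, 0.8)
    expect_lte(hom2$purityD$purityValue, 0.2)
    expect_error(datasetHomogeneity(
        simA$dataset,
        ExpressionDataset(matrix(rnorm(16), 4, 4,
                                 dimnames = list(paste0("x", 1:4),
                                                 paste0("s", 1:4))),
                          rep(c("a", "b"), each = 2)),
        rngSeed = 1), "share no genes")
})

test_that("agreement is the intersection-over-union, symmetric and bounded", {
    expect_equal(agreement(c("a", "b", "c"), c("b", "c", "d"),
                           "gene")$value, 0.5)
    expect_equal(agreement(c("a", "b"), c("a", "b"), "gene")$value, 1)
    expect_equal(agreement(c("a"), c("b"), "gene_set")$value, 0)
    expect_equal(agreement(c("a", "b", "c"), c("b", "c", "d"), "gene")$value,
                 agreement(c("b", "c", "d"), c("a", "b", "c"),
                           "gene")$value)
    expect_error(agreement(character(), character(), "gene"), "empty")
})

test_that("activity features reproduce stored scores on the training data and renormalize on loss", {
    ds <- toyDataset()
    net <- edgesToNetwork("G1", "G2", "G2", "G3", "G1", "G4", "G4", "G5")
    gs <- GeneSetCollection(list(PW1 = paste0("G", 1:6)))
    run <- identifySubnetworks(ds, gs, net,
                               searchConfig("gs", minSize = 1,
                                            alpha = 0.5))
    feat <- activityFeatures(run, ds)
    s <- run$representatives[[1]]
    expect_equal(anovaF(feat[, 1], classLabels(ds))$fValue, fValue(s),
                 tolerance = 1e-9)
    # sample permutation permutes rows identically
    perm <- c(3, 1, 2, 4, 8, 7, 5, 6)
    dsPerm <- ExpressionDataset(exprValues(ds)[, perm],
                                setNames(as.character(classLabels(ds)),
                                         sampleIds(ds))[perm])
    S4Vectors::metadata(dsPerm)$zTransformed <- TRUE
    expect_equal(activityFeatures(run, dsPerm)[sampleIds(ds), ,
                                               drop = FALSE],
                 feat, tolerance = 1e-12)
    # a member missing from the projection dataset: sqrt uses what remains
    mem <- c("G1", "G2", "G3")
    sub <- new("Subnetwork", geneSetId = "PW1", seed = "G1", members = mem,
               parents = c(NA, "G1", "G2"), signs = c(1, 1, -1),
               activity = numeric(8), fValue = 1, pValue = 0.5,
               dfBetween = 1L, dfWithin = 6L, strategy = "gs",
               trace = data.frame())
    keep <- setdiff(geneIds(ds), "G3")
    dsMiss <- ExpressionDataset(exprValues(ds)[keep, ],
                                as.character(classLabels(ds)))
    S4Vectors::metadata(dsMiss)$zTransformed <- TRUE
    fm <- activityFeatures(list(sub), dsMiss)
    z <- exprValues(ds)
    expect_equal(unname(fm[, 1]),
                 unname((z["G1", ] + z["G2", ]) / sqrt(2)),
                 tolerance = 1e-12)
    # no measured member at all -> dropped, then error if nothing is left
    dsNone <- ExpressionDataset(exprValues(ds)[c("G5", "G6"), ],
                                as.character(classLabels(ds)))
    S4Vectors::metadata(dsNone)$zTransformed <- TRUE
    expect_warning(expect_error(activityFeatures(list(sub), dsNone),
                                "no subnetwork"), "dropped")
})

test_that("cross-dataset AUC is high on separated data, null-centred under permutation, and monotone-invariant", {
    net <- generateNetwork(80, 2, rngSeed = 41)
    gs <- generateGeneSets(net, 3, c(15, 25), 0, rngSeed = 41)
    sim <- generateExpression(net, gs, effectSize = 3, nPerClass = 30,
                              rngSeed = 41)
    ds <- zTransform(sim$dataset)
    run <- filterMinSize(identifySubnetworks(ds, gs, net,
                                             searchConfig("gs")), 2)
    # train = test, strong signal: near-perfect separation
    res <- crossDatasetAUC(ds, ds, run)
    expect_gte(res$auc, 0.95)
    # permuted test labels: AUC hovers around chance
    set.seed(42)
    nullAucs <- replicate(10, {
        lab <- sample(as.character(classLabels(ds)))
        dsNull <- ExpressionDataset(exprValues(ds), lab)
        S4Vectors::metadata(dsNull)$zTransformed <- TRUE
        crossDatasetAUC(ds, dsNull, run)$auc
    })
    expect_gte(mean(nullAucs), 0.35)
    expect_lte(mean(nullAucs), 0.65)
    # AUC only depends on the ranking of decision scores
    feat <- activityFeatures(run, ds)
    sc <- feat[, 1]
    lab <- as.character(classLabels(ds))
    pos <- sort(unique(lab))[2]
    a1 <- netmark:::.scoreAuc(sc, lab, pos)
    a2 <- netmark:::.scoreAuc(exp(sc / 2), lab, pos)
    expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("k-fold evaluation within the test set returns a sane mean AUC", {
    net <- generateNetwork(60, 2, rngSeed = 51)
    gs <- generateGeneSets(net, 2, c(15, 20), 0, rngSeed = 51)
    sim <- generateExpression(net, gs, effectSize = 3, nPerClass = 25,
                              rngSeed = 51)
    sim2 <- generateExpression(net, gs, effectSize = 3, nPerClass = 25,
                               truth = sim$truth, rngSeed = 52)
    ds <- zTransform(sim$dataset); ds2 <- zTransform(sim2$dataset)
    run <- filterMinSize(identifySubnetworks(ds, gs, net,
                                             searchConfig("gs")), 2)
    res <- crossDatasetAUC(ds, ds2, run, kfold = 5, rngSeed = 3)
    expect_gte(res$auc, 0.8)
    expect_lte(res$auc, 1)
})
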
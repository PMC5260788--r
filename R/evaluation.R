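#' Normalized cluster purity
#'
#' Measures how well a clustering separates a categorical status. Raw
#' purity is the fraction of instances assigned to their cluster's majority
#' status, \eqn{(1/N) \sum_k \max_j |w_k \cap c_j|}; its floor is 1/j for j
#' statuses, so it is rescaled to \eqn{(raw \cdot j - 1)/(j - 1)}, giving 0
#' at the chance floor (every cluster a uniform mixture) and 1 for
#' status-pure clusters.
#'
#' @param clusterAssignment cluster id per instance.
#' @param statusLabels status (class) per instance; >= 2 distinct values.
#' @param statusKind label recorded in the result, e.g. \code{"batch"} or
#'   \code{"disease"}.
#' @return A list of class \code{"PurityResult"}: \code{purityValue}
#'   (normalized), \code{rawPurity}, \code{nClusters}, \code{nClasses},
#'   \code{nInstances}, \code{statusKind}.
#' @examples
#' normalizedPurity(c(1, 1, 1, 2, 2, 2),
#'                  c("A", "A", "B", "B", "B", "A"))$purityValue  # 1/3
#' @export
normalizedPurity <- function(clusterAssignment, statusLabels,
                             statusKind = "disease") {
    if (length(clusterAssignment) != length(statusLabels))
        stop("cluster assignment and status labels differ in length")
    j <- length(unique(statusLabels))
    if (j < 2L)
        stop("normalization is undefined for a single status class")
    n <- length(statusLabels)
    conf <- table(clusterAssignment, statusLabels)
    raw <- sum(apply(conf, 1L, max)) / n
    structure(list(purityValue = (raw * j - 1) / (j - 1), rawPurity = raw,
                   nClusters = nrow(conf), nClasses = j, nInstances = n,
                   statusKind = statusKind),
              class = "PurityResult")
}

#' Dataset homogeneity: batch vs disease cluster purity
#'
#' Assesses whether two expression datasets of the same disease are
#' compatible for cross-dataset analysis. The datasets are merged on their
#' shared genes, the merged matrix is row-standardized
#' (\code{\link{zTransform}} across all merged samples), and the samples
#' are clustered by k-means with k equal to the number of disease classes
#' of the merged data. That one clustering is scored twice with
#' \code{\link{normalizedPurity}}: against the dataset-of-origin labels
#' (\code{purityB}) and against the disease labels (\code{purityD}).
#' Compatible datasets show low \code{purityB} (batches mix within
#' clusters) and high \code{purityD} (clusters track disease).
#'
#' Standardization here is joint, across the merged samples, deliberately:
#' standardizing each dataset separately first would centre both datasets
#' at zero on every gene and thereby erase, by construction, exactly the
#' between-dataset location and scale differences the measure exists to
#' detect. Datasets that were already z-transformed per cohort are
#' unaffected (the joint pass is then a no-op up to rescaling).
#'
#' @param ds1,ds2 \linkS4class{ExpressionDataset}s sharing >= 1 gene.
#' @param rngSeed seed for the k-means initialization.
#' @param nstart k-means restarts (best within-cluster sum of squares
#'   kept).
#' @return List with elements \code{purityB} and \code{purityD}
#'   (\code{"PurityResult"}s) plus \code{nSharedGenes} and \code{k}.
#' @export
datasetHomogeneity <- function(ds1, ds2, rngSeed = 1L, nstart = 10L) {
    shared <- intersect(geneIds(ds1), geneIds(ds2))
    if (length(shared) == 0L)
        stop("the two datasets share no genes")
    m1 <- exprValues(ds1)[shared, , drop = FALSE]
    m2 <- exprValues(ds2)[shared, , drop = FALSE]
    merged <- cbind(m1, m2)
    mu <- rowMeans(merged)
    s <- sqrt(rowMeans((merged - mu)^2))
    merged <- (merged - mu) / ifelse(s < 1e-12, 1, s)
    disease <- c(as.character(classLabels(ds1)),
                 as.character(classLabels(ds2)))
    batch <- rep(c("ds1", "ds2"), c(ncol(m1), ncol(m2)))
    k <- length(unique(disease))
    set.seed(rngSeed)
    km <- kmeans(t(merged), centers = k, nstart = nstart, iter.max = 50L)
    list(purityB = normalizedPurity(km$cluster, batch, "batch"),
         purityD = normalizedPurity(km$cluster, disease, "disease"),
         nSharedGenes = length(shared), k = k)
}

#' Gene- or gene-set-level agreement between two runs
#'
#' The agreement between biomarkers identified independently from two
#' datasets: the number of common items divided by the total number of
#' distinct items identified in the two runs (intersection over union).
#'
#' @param items1,items2 character vectors: all member genes of the reported
#'   subnetworks (gene level) or the represented gene-set ids (gene-set
#'   level). See \code{\link{runItems}}.
#' @param level \code{"gene"} or \code{"gene_set"}, recorded in the result.
#' @return A list of class \code{"AgreementResult"}: \code{value} in
#'   \code{[0, 1]}, \code{common}, \code{unionTotal}, \code{level}.
#' @export
agreement <- function(items1, items2, level = c("gene", "gene_set")) {
    level <- match.arg(level)
    items1 <- unique(items1); items2 <- unique(items2)
    u <- union(items1, items2)
    if (length(u) == 0L)
        stop("both item sets are empty")
    common <- length(intersect(items1, items2))
    structure(list(value = common / length(u), common = common,
                   unionTotal = length(u), level = level),
              class = "AgreementResult")
}

#' Items identified by a run, for agreement computations
#'
#' @param subnetworks list of \linkS4class{Subnetwork} or a
#'   \code{"SubnetworkRun"}.
#' @param level \code{"gene"} (union of member genes) or \code{"gene_set"}
#'   (represented set ids).
#' @return Character vector of items.
#' @export
runItems <- function(subnetworks, level = c("gene", "gene_set")) {
    level <- match.arg(level)
    if (inherits(subnetworks, "SubnetworkRun"))
        subnetworks <- subnetworks$representatives
    if (level == "gene")
        unique(unlist(lapply(subnetworks, members), use.names = FALSE))
    else
        unique(vapply(subnetworks, geneSetId, character(1)))
}

#' Project subnetworks onto a dataset as activity features
#'
#' Builds the samples-by-subnetworks feature matrix used for
#' classification: feature j is the signed activity of subnetwork j's
#' members evaluated on this (z-transformed) dataset. Members missing from
#' the dataset are dropped and the sqrt normalization uses the available
#' member count; subnetworks with no available member are dropped with a
#' warning.
#'
#' @param subnetworks list of \linkS4class{Subnetwork} or a
#'   \code{"SubnetworkRun"}.
#' @param dataset a z-transformed \linkS4class{ExpressionDataset}.
#' @return Numeric matrix, samples in rows, one column per retained
#'   subnetwork (named \code{<set>.<seed>}).
#' @export
activityFeatures <- function(subnetworks, dataset) {
    if (inherits(subnetworks, "SubnetworkRun"))
        subnetworks <- subnetworks$representatives
    if (!isZTransformed(dataset))
        stop("dataset must be z-transformed first; see zTransform()")
    cols <- list()
    for (s in subnetworks) {
        avail <- intersect(members(s), geneIds(dataset))
        if (length(avail) == 0L) {
            warning(sprintf("subnetwork %s/%s has no measured member; dropped",
                            geneSetId(s), seedGene(s)))
            next
        }
        sg <- memberSigns(s)[match(avail, members(s))]
        cols[[paste(geneSetId(s), seedGene(s), sep = ".")]] <-
            subnetworkActivity(avail, sg, dataset)
    }
    if (length(cols) == 0L)
        stop("no subnetwork has measured members in this dataset")
    feat <- do.call(cbind, cols)
    rownames(feat) <- sampleIds(dataset)
    feat
}

# AUC of decision scores with a fixed orientation: higher score -> the
# designated positive class (no direction auto-detection).
.scoreAuc <- function(scores, labels, positive) {
    labels <- as.character(labels)
    negatives <- setdiff(unique(labels), positive)
    r <- pROC::roc(response = factor(labels %in% positive,
                                     levels = c(FALSE, TRUE)),
                   predictor = as.numeric(scores), levels = c(FALSE, TRUE),
                   direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(r))
}

# Fit an RBF C-SVC on train features and return test decision scores
# oriented so that larger means the first-named libsvm class; we re-orient
# to 'positive'.
.svmScores <- function(trainX, trainY, testX, positive) {
    fit <- e1071::svm(x = trainX, y = factor(trainY), kernel = "radial",
                      type = "C-classification", scale = FALSE)
    pr <- predict(fit, testX, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    cls <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]]
    s <- as.numeric(dv[, 1L])
    if (cls[1L] != positive) s <- -s
    s
}

#' Cross-dataset classification of subnetwork activity features
#'
#' Validates subnetworks identified on a training dataset by classifying an
#' independent test dataset of the same disease. Features are the
#' subnetwork activities (\code{\link{activityFeatures}}); the classifier
#' is a C-SVC support-vector machine with an RBF kernel at the toolkit's
#' default hyperparameters; performance is the area under the ROC curve of
#' the decision scores on the test samples (one-vs-rest macro average for
#' more than two classes).
#'
#' With \code{kfold} set, the classifier is instead evaluated by k-fold
#' cross-validation within the test dataset (features still from the
#' train-identified subnetworks), and the mean fold AUC is reported.
#'
#' @param train dataset the subnetworks were identified on (z-transformed).
#' @param test independent dataset (z-transformed), >= 2 classes.
#' @param subnetworks list of \linkS4class{Subnetwork} or a
#'   \code{"SubnetworkRun"} from the training dataset.
#' @param kfold optional integer: evaluate by k-fold CV within \code{test}.
#' @param rngSeed seed for the fold split.
#' @return A list of class \code{"ClassificationResult"}: \code{auc},
#'   \code{nFeatures}, \code{trainId}, \code{testId},
#'   \code{classifierDescriptor}.
#' @export
crossDatasetAUC <- function(train, test, subnetworks, kfold = NULL,
                            rngSeed = 1L) {
    if (length(unique(classLabels(test))) < 2L)
        stop("test dataset has a single class")
    featTr <- activityFeatures(subnetworks, train)
    featTe <- activityFeatures(subnetworks, test)
    common <- intersect(colnames(featTr), colnames(featTe))
    if (length(common) == 0L)
        stop("no subnetwork feature is available on both datasets")
    featTr <- featTr[, common, drop = FALSE]
    featTe <- featTe[, common, drop = FALSE]
    yTr <- as.character(classLabels(train))
    yTe <- as.character(classLabels(test))
    classes <- sort(unique(yTe))

    aucOf <- function(trX, trY, teX, teY) {
        cls <- sort(unique(teY))
        if (length(cls) == 2L) {
            pos <- cls[2L]
            .scoreAuc(.svmScores(trX, trY, teX, pos), teY, pos)
        } else {
            mean(vapply(cls, function(pos) {
                s <- .svmScores(trX, ifelse(trY == pos, pos, "rest"), teX,
                                pos)
                .scoreAuc(s, teY, pos)
            }, 0))
        }
    }

    if (is.null(kfold)) {
        auc <- aucOf(featTr, yTr, featTe, yTe)
    } else {
        set.seed(rngSeed)
        fold <- sample(rep_len(seq_len(kfold), nrow(featTe)))
        aucs <- vapply(seq_len(kfold), function(f) {
            tr <- fold != f
            if (length(unique(yTe[!tr])) < 2L)
                return(NA_real_)
            aucOf(featTe[tr, , drop = FALSE], yTe[tr],
                  featTe[!tr, , drop = FALSE], yTe[!tr])
        }, 0)
        auc <- mean(aucs, na.rm = TRUE)
    }
    structure(list(auc = auc, nFeatures = length(common),
                   trainId = "train", testId = "test",
                   classifierDescriptor = paste0(
                       "C-SVC, RBF kernel, default cost/gamma",
                       if (!is.null(kfold))
                           sprintf(", %d-fold CV within test", kfold))),
              class = "ClassificationResult")
}
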
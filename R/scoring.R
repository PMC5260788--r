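#' One-way ANOVA F score of a per-sample value vector
#'
#' The search objective: a fixed-effects one-way ANOVA F statistic of a
#' value (a gene's z-scores or a subnetwork activity) against the sample
#' class labels. For exactly two classes it equals the squared
#' pooled-variance t statistic. Degenerate inputs are kept total and
#' deterministic: an all-constant vector scores F = 0, and zero
#' within-class variance with between-class spread is guarded by flooring
#' the within-class mean square at \code{eps}, with the reported F capped
#' at \code{1/eps}.
#'
#' @param values numeric vector, one value per sample.
#' @param labels class label per sample (>=2 classes, each with >=2
#'   samples).
#' @param eps within-class mean-square guard (default \code{1e-12}).
#' @return A list of class \code{"FScore"}: \code{fValue}, \code{pValue},
#'   \code{dfBetween} (classes - 1), \code{dfWithin} (samples - classes).
#' @examples
#' anovaF(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$fValue  # 13.5
#' @export
anovaF <- function(values, labels, eps = 1e-12) {
    labels <- as.factor(labels)
    if (length(values) != length(labels))
        stop("'values' and 'labels' lengths differ")
    tab <- table(labels)
    if (length(tab) < 2L)
        stop("at least 2 classes are required")
    if (any(tab < 2L))
        stop(sprintf("class '%s' has fewer than 2 samples",
                     names(tab)[tab < 2L][1L]))
    k <- length(tab); n <- length(values)
    gm <- mean(values)
    cm <- tapply(values, labels, mean)
    ssb <- sum(tab * (cm - gm)^2)
    ssw <- sum((values - cm[labels])^2)
    dfb <- k - 1L; dfw <- n - k
    if (ssb < eps && ssw < eps) {
        f <- 0; p <- 1
    } else {
        f <- min((ssb / dfb) / max(ssw / dfw, eps), 1 / eps)
        p <- pf(f, dfb, dfw, lower.tail = FALSE)
    }
    structure(list(fValue = f, pValue = p, dfBetween = dfb, dfWithin = dfw),
              class = "FScore")
}

# Vectorized per-row ANOVA over a genes x samples matrix; same conventions
# as anovaF. Used for per-gene significance screens.
.rowAnovaF <- function(mat, labels, eps = 1e-12) {
    labels <- as.factor(labels)
    tab <- table(labels)
    k <- length(tab); n <- ncol(mat)
    groupSums <- t(rowsum(t(mat), labels))          # genes x classes
    cm <- sweep(groupSums, 2L, as.vector(tab), "/")
    gm <- rowMeans(mat)
    ssb <- rowSums(sweep((cm - gm)^2, 2L, as.vector(tab), "*"))
    sst <- rowSums((mat - gm)^2)
    ssw <- pmax(sst - ssb, 0)
    dfb <- k - 1L; dfw <- n - k
    f <- pmin((ssb / dfb) / pmax(ssw / dfw, eps), 1 / eps)
    f[ssb < eps & ssw < eps] <- 0
    p <- pf(f, dfb, dfw, lower.tail = FALSE)
    p[f == 0] <- 1
    list(fValue = f, pValue = p, dfBetween = dfb, dfWithin = dfw)
}

#' Pearson correlation with a deterministic degenerate-case convention
#'
#' Standard product-moment correlation, except that a zero-variance vector
#' (either argument) yields 0 rather than \code{NA}, so downstream sign
#' decisions are total.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Correlation in \code{[-1, 1]}.
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y))
        stop("'x' and 'y' lengths differ")
    if (length(x) < 3L)
        stop("need at least 3 paired observations")
    if (sd(x) == 0 || sd(y) == 0)
        return(0)
    as.numeric(cor(x, y))
}

#' Orientation of a candidate gene relative to the current activity
#'
#' The sign of the Pearson correlation between the current subnetwork
#' activity and the candidate's z-scores decides how the candidate enters
#' the activity aggregation: +1 when the correlation is >= 0 (ties,
#' including the zero-variance case, go positive), -1 otherwise. Negatively
#' correlated genes therefore contribute with flipped sign, so coherent
#' anti-correlated expression still reinforces the activity signal.
#'
#' @param activity current activity vector (one value per sample).
#' @param geneZ the candidate gene's z-score row.
#' @return +1 or -1.
#' @export
signForCandidate <- function(activity, geneZ) {
    if (pearsonR(activity, geneZ) >= 0) 1 else -1
}

#' Subnetwork activity: signed, normalized aggregate expression
#'
#' The per-sample scalar summarizing a subnetwork's expression:
#' \deqn{a(s) = \sum_g sign_g \, z_g(s) / \sqrt{n}}
#' over the n member genes, with z the row-standardized expression. The
#' sqrt(n) scaling keeps the activity variance comparable across subnetwork
#' sizes under independence.
#'
#' @param memberGenes character vector of member genes.
#' @param signs numeric vector of +/-1 per member.
#' @param dataset a z-transformed \linkS4class{ExpressionDataset}.
#' @return Named numeric vector (one value per sample) with attribute
#'   \code{memberCount}.
#' @export
subnetworkActivity <- function(memberGenes, signs, dataset) {
    if (length(memberGenes) != length(signs))
        stop("'memberGenes' and 'signs' lengths differ")
    missing <- setdiff(memberGenes, geneIds(dataset))
    if (length(missing))
        stop(sprintf("gene '%s' is not in the dataset", missing[1L]))
    z <- exprValues(dataset)[memberGenes, , drop = FALSE]
    act <- as.numeric(crossprod(z, signs)) / sqrt(length(memberGenes))
    names(act) <- sampleIds(dataset)
    attr(act, "memberCount") <- length(memberGenes)
    act
}

#' Score a subnetwork: ANOVA F of its activity vector
#'
#' Composition of \code{\link{subnetworkActivity}} and \code{\link{anovaF}}
#' against the dataset's class labels. A single-member subnetwork scores
#' exactly its gene's own per-gene F.
#'
#' @inheritParams subnetworkActivity
#' @param labels optional labels overriding \code{classLabels(dataset)}.
#' @return An \code{"FScore"} list (see \code{\link{anovaF}}).
#' @export
scoreSubnetwork <- function(memberGenes, signs, dataset, labels = NULL) {
    if (is.null(labels))
        labels <- classLabels(dataset)
    anovaF(subnetworkActivity(memberGenes, signs, dataset), labels)
}
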
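# Supervised PLS-DA on gene-body NO features: NIPALS PLS2 on dummy-coded
# class labels with internal standardization, VIP-based feature selection,
# prediction and one-vs-rest AUC.

.dummyCode <- function(labels) {
    f <- as.factor(labels)
    lev <- levels(f)
    y <- matrix(0, length(f), length(lev), dimnames = list(NULL, lev))
    y[cbind(seq_along(f), as.integer(f))] <- 1
    y
}

#' Fit a PLS-DA classification model
#'
#' NIPALS PLS2 regression of centered dummy-coded class labels on
#' standardized features. Deterministic given the input ordering: the inner
#' NIPALS iteration is initialized from the dummy column with the largest
#' variance. Constant features are kept but contribute nothing (unit scale).
#'
#' @param x Observations x features numeric matrix (cells in rows), or a
#'   \code{SummarizedExperiment} with assay \code{"normalized"} (cells in
#'   columns; transposed internally).
#' @param labels Class label per observation (>= 2 classes, each with >= 2
#'   observations).
#' @param nComponents Number of latent components requested; silently capped
#'   (with a warning) at the number supported by the data rank.
#' @param tol,maxIter NIPALS convergence controls.
#' @param minPerClass Minimum observations per class (default 2; the
#'   PLS-DA/VIP differential mode relaxes this to 1 with a warning).
#' @return A \code{\link{PLSDAModel}}.
#' @export
fitPlsda <- function(x, labels, nComponents = 2L, tol = 1e-10,
                     maxIter = 500L, minPerClass = 2L) {
    if (is(x, "SummarizedExperiment")) x <- t(assay(x, "normalized"))
    x <- as.matrix(x)
    if (is.null(colnames(x)))
        colnames(x) <- sprintf("feature_%d", seq_len(ncol(x)))
    labels <- as.factor(labels)
    if (nlevels(labels) < 2L) stop("need at least 2 classes")
    if (any(table(labels) < minPerClass))
        stop("each class needs at least ", minPerClass, " cells")
    if (length(labels) != nrow(x)) stop("one label per observation required")

    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd)
    scl[scl == 0] <- 1
    xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
    y <- .dummyCode(labels)
    yc <- colMeans(y)
    ys <- sweep(y, 2L, yc)

    maxComp <- min(nrow(xs) - 1L, ncol(xs))
    A <- as.integer(nComponents)
    if (A > maxComp) {
        warning("nComponents reduced from ", A, " to ", maxComp)
        A <- maxComp
    }
    p <- ncol(xs); K <- ncol(ys)
    W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, K, A)
    Tm <- matrix(0, nrow(xs), A); ss <- numeric(A)
    Xd <- xs; Yd <- ys
    a <- 0L
    while (a < A) {
        u <- Yd[, which.max(apply(Yd, 2L, var))]
        if (sum(u^2) < tol) break
        w <- crossprod(Xd, u)
        for (it in seq_len(maxIter)) {
            w <- w / sqrt(sum(w^2))
            tt <- Xd %*% w
            q <- crossprod(Yd, tt) / sum(tt^2)
            uNew <- Yd %*% q / sum(q^2)
            wNew <- crossprod(Xd, uNew)
            delta <- sum((wNew / sqrt(sum(wNew^2)) - w)^2)
            w <- wNew
            u <- uNew
            if (delta < tol) break
        }
        w <- w / sqrt(sum(w^2))
        tt <- Xd %*% w
        tss <- sum(tt^2)
        if (tss < tol) break
        pp <- crossprod(Xd, tt) / tss
        q <- crossprod(Yd, tt) / tss
        a <- a + 1L
        W[, a] <- w; P[, a] <- pp; Q[, a] <- q; Tm[, a] <- tt
        ss[a] <- sum(q^2) * tss      # response SS explained by component a
        Xd <- Xd - tcrossprod(tt, pp)
        Yd <- Yd - tcrossprod(tt, q)
    }
    if (a < A) {
        warning("rank deficiency: only ", a, " components fit")
        W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
        Q <- Q[, seq_len(a), drop = FALSE]; ss <- ss[seq_len(a)]
        A <- a
    }
    if (A == 0L) stop("no usable PLS component (degenerate input)")
    B <- W %*% solve(crossprod(P, W)) %*% t(Q)
    rownames(W) <- rownames(P) <- rownames(B) <- colnames(x)
    rownames(Q) <- levels(labels)
    new("PLSDAModel", weights = W, loadings = P, yloadings = Q,
        coefficients = B, ssY = ss, classes = levels(labels),
        xCenter = ctr, xScale = scl, yCenter = yc,
        featureNames = colnames(x), selectedFeatures = NULL,
        nComponents = A)
}

#' @describeIn vip VIP scores of a fitted PLS-DA model.
#' @export
setMethod("vip", "PLSDAModel", function(object) {
    W <- object@weights
    ss <- object@ssY
    G <- nrow(W)
    v <- sqrt(G * as.numeric(W^2 %*% ss) / sum(ss))
    setNames(v, object@featureNames)
})

#' Select features by VIP threshold
#'
#' Returns the features whose variable importance in projection exceeds the
#' threshold (default 1, the conventional cutoff: since VIP scores satisfy
#' \code{mean(vip^2) = 1}, features above 1 contribute more than an average
#' feature). Typical use: fit on all features, select, refit on the subset.
#'
#' @param model A fitted \code{\link{PLSDAModel}}.
#' @param threshold VIP cutoff (default 1.0).
#' @return Character vector of selected feature ids.
#' @export
selectFeatures <- function(model, threshold = 1.0) {
    v <- vip(model)
    names(v)[v > threshold]
}

#' Predict class scores and hard labels for cells
#'
#' Projects new observations through the trained model using the training
#' standardization parameters (no leakage), yielding per-class scores
#' (projected dummy predictions); the hard label is the argmax. One-vs-rest
#' AUC can be computed from the scores with \code{\link{aucMacro}}.
#'
#' @param model A \code{\link{PLSDAModel}}.
#' @param x New observations x features matrix (or SummarizedExperiment with
#'   cells in columns). Must contain every model feature; extra columns are
#'   ignored.
#' @return A list with \code{scores} (matrix, one column per class) and
#'   \code{class} (factor of hard labels).
#' @export
predictCells <- function(model, x) {
    if (is(x, "SummarizedExperiment")) x <- t(assay(x, "normalized"))
    x <- as.matrix(x)
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    miss <- setdiff(model@featureNames, colnames(x))
    if (length(miss) > 0L)
        stop("features missing from input: ",
             paste(head(miss, 10L), collapse = ", "),
             if (length(miss) > 10L) sprintf(" (and %d more)",
                                             length(miss) - 10L) else "")
    x <- x[, model@featureNames, drop = FALSE]
    xs <- sweep(sweep(x, 2L, model@xCenter), 2L, model@xScale, "/")
    scores <- xs %*% model@coefficients
    scores <- sweep(scores, 2L, model@yCenter, "+")
    colnames(scores) <- model@classes
    hard <- factor(model@classes[max.col(scores, ties.method = "first")],
                   levels = model@classes)
    list(scores = scores, class = hard)
}

#' Macro-averaged one-vs-rest AUC
#'
#' For each class, the rank-based (Mann-Whitney) AUC of its score column for
#' separating that class from the rest; averaged over classes.
#'
#' @param scores Matrix of per-class scores (columns named by class).
#' @param labels True class per row.
#' @return Macro AUC in [0, 1].
#' @export
aucMacro <- function(scores, labels) {
    labels <- as.character(labels)
    aucs <- vapply(colnames(scores), function(cl) {
        pos <- labels == cl
        if (!any(pos) || all(pos)) return(NA_real_)
        r <- rank(scores[, cl])
        (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
            (sum(pos) * sum(!pos))
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
}

#' Serialize a PLS-DA model to JSON
#' @param model A \code{\link{PLSDAModel}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writePlsdaModel <- function(model, path) {
    obj <- list(classes = model@classes, n_components = model@nComponents,
                feature_names = model@featureNames,
                selected_features = model@selectedFeatures,
                x_center = model@xCenter, x_scale = model@xScale,
                y_center = model@yCenter, ss_y = model@ssY,
                weights = model@weights, loadings = model@loadings,
                yloadings = model@yloadings,
                coefficients = model@coefficients)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}
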
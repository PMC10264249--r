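# Two-step clone-specific gene activity inference. Step 1 removes genes
# unlikely to be expressed in any clone (classifier probability of the
# not-expressed state >= 0.9 across all clones). Step 2 tests differential
# gene-body NO between two cell populations: negative-binomial GLM Wald
# tests by default, or PLS-DA VIP with permutation p-values for low clonal
# frequencies. The differential gene activity score is
# sign(fold change) * (-log10 p).

#' Per-gene NO and sequence features over fixed-length bins
#'
#' Partitions each gene body into \code{nBins} equal sub-intervals and
#' computes the mean per-bp fragment coverage of each; genes shorter than
#' \code{nBins} bp are handled by per-bp resampling (bins then share base
#' pairs). The feature vector per gene is the \code{nBins} NO bins followed
#' by \code{nBins} per-bin GC fractions and the log gene length
#' (2 x nBins + 1 values).
#'
#' @param frags \code{\link{FragmentSet}} (pool the cells of one clone to
#'   featurize that clone).
#' @param genes Named \code{GRanges} of gene bodies.
#' @param gc Genes x \code{nBins} matrix of per-bin GC fractions (rows
#'   matched to \code{names(genes)}); zeros are used when \code{NULL}.
#' @param nBins Number of bins per gene body (default 150).
#' @return Numeric matrix, genes x (2 * nBins + 1), with column groups
#'   \code{no_*}, \code{gc_*}, \code{log_length}.
#' @export
featurizeGenes <- function(frags, genes, gc = NULL, nBins = 150L) {
    stopifnot(length(genes) > 0L, nBins >= 1L)
    if (any(GenomicRanges::width(genes) < 1L))
        stop("genes must have positive length")
    gr <- fragments(frags)
    sl <- .fragSeqlengths(gr)
    cov <- GenomicRanges::coverage(gr, width = sl)
    if (is.null(gc)) {
        gc <- matrix(0, length(genes), nBins,
                     dimnames = list(names(genes), NULL))
    } else {
        gc <- as.matrix(gc)[names(genes), , drop = FALSE]
        if (ncol(gc) != nBins) stop("gc must have nBins columns")
    }
    noM <- matrix(0, length(genes), nBins)
    chroms <- as.character(GenomicRanges::seqnames(genes))
    for (i in seq_along(genes)) {
        ch <- chroms[i]
        s <- GenomicRanges::start(genes)[i]; e <- GenomicRanges::end(genes)[i]
        L <- e - s + 1L
        v <- numeric(L)
        if (ch %in% names(cov)) {
            rv <- cov[[ch]]
            hi <- min(e, length(rv))
            if (hi >= s) v[seq_len(hi - s + 1L)] <- as.numeric(rv[s:hi])
        }
        ub <- ceiling(seq_len(nBins) * L / nBins)
        lb <- c(1L, head(ub, -1L) + 1L)
        short <- lb > ub              # L < nBins: resample per bp
        if (any(short)) {
            idx <- pmax(1L, ceiling(seq_len(nBins) * L / nBins))
            noM[i, ] <- v[idx]
        } else {
            noM[i, ] <- vapply(seq_len(nBins),
                               function(b) mean(v[lb[b]:ub[b]]), numeric(1))
        }
    }
    out <- cbind(noM, gc, log(GenomicRanges::width(genes)))
    dimnames(out) <- list(names(genes),
                          c(sprintf("no_%d", seq_len(nBins)),
                            sprintf("gc_%d", seq_len(nBins)), "log_length"))
    out
}

#' Train the not-expressed (NE) gene classifier
#'
#' Fits a classifier of the NE state from gene features (binned gene-body
#' NO, per-bin GC, log length). The default engine is ridge-regularized
#' logistic regression (deterministic at a fixed penalty);
#' \code{method = "logistic"} fits an unregularized logistic model (suitable
#' when features are few). Labels come from matched expression data or from
#' simulator truth.
#'
#' @param features Genes x features matrix from \code{\link{featurizeGenes}}.
#' @param neLabels Logical (or 0/1) per gene: TRUE if the gene is not
#'   expressed. Both classes must be present.
#' @param method \code{"ridge"} (default) or \code{"logistic"}.
#' @param lambda Ridge penalty (default 0.01).
#' @param threshold NE decision threshold stored with the model (default
#'   0.9: a gene is filtered out when P(NE) >= 0.9 in every clone).
#' @return An \code{\link{NEModel}}.
#' @export
trainNeClassifier <- function(features, neLabels, method = c("ridge",
                              "logistic"), lambda = 0.01, threshold = 0.9) {
    method <- match.arg(method)
    y <- as.integer(as.logical(neLabels))
    if (length(unique(y)) < 2L)
        stop("both expressed and NE genes required for training")
    x <- as.matrix(features)
    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd); scl[scl == 0] <- 1
    xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
    fit <- if (method == "ridge") {
        glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                       lambda = lambda, standardize = FALSE)
    } else {
        suppressWarnings(glm.fit(cbind(1, xs), y, family = binomial()))
    }
    new("NEModel", method = method, fit = fit, center = ctr, scale = scl,
        threshold = threshold, featureNames = colnames(x))
}

#' Probability of the not-expressed state per gene
#' @param model An \code{\link{NEModel}}.
#' @param features Genes x features matrix (columns matching training).
#' @return Named numeric vector of P(NE) in [0, 1].
#' @export
predictNe <- function(model, features) {
    x <- as.matrix(features)[, model@featureNames, drop = FALSE]
    xs <- sweep(sweep(x, 2L, model@center), 2L, model@scale, "/")
    p <- if (model@method == "ridge") {
        as.numeric(predict(model@fit, newx = xs, type = "response"))
    } else {
        eta <- as.numeric(cbind(1, xs) %*% model@fit$coefficients)
        1 / (1 + exp(-eta))
    }
    setNames(p, rownames(x))
}

#' Filter not-expressed genes across clones
#'
#' A gene is removed if and only if its NE probability is at or above the
#' threshold (inclusive) in every clone; a gene below the threshold in any
#' single clone is retained.
#'
#' @param neProbs Genes x clones matrix of P(NE) (one column per clone), or
#'   a named list of per-clone probability vectors.
#' @param threshold NE probability cutoff (default 0.9).
#' @return Character vector of retained gene ids.
#' @export
filterNeGenes <- function(neProbs, threshold = 0.9) {
    if (is.list(neProbs)) neProbs <- do.call(cbind, neProbs)
    neProbs <- as.matrix(neProbs)
    if (ncol(neProbs) == 0L || nrow(neProbs) == 0L)
        stop("no NE probabilities supplied")
    if (any(is.na(neProbs))) stop("NE probabilities contain NA")
    keep <- apply(neProbs, 1L, function(p) any(p < threshold))
    rownames(neProbs)[keep]
}

#' Method-of-moments negative-binomial dispersions
#'
#' Per-gene dispersion alpha (variance = mu + alpha mu^2) from size-factor-
#' normalized counts: within each group the excess of the sample variance of
#' normalized counts over the sampling-noise term \code{mean * mean(1/s)} is
#' divided by the squared mean; group estimates are averaged (weighted by
#' cells) and floored at 0. Deterministic; no shrinkage toward a trend.
#'
#' @param counts Genes x cells count matrix.
#' @param group Group label per cell (>= 2 cells per group).
#' @param sizeFactors Per-cell positive size factors (default: computed via
#'   \code{\link{computeSizeFactors}}).
#' @return Named numeric vector of dispersions (>= 0).
#' @export
estimateDispersions <- function(counts, group,
                                sizeFactors = computeSizeFactors(counts)) {
    m <- as.matrix(counts)
    group <- as.factor(group)
    if (any(table(group) < 2L)) stop("need >= 2 cells per group")
    q <- sweep(m, 2L, sizeFactors, "/")
    alpha <- numeric(nrow(m))
    for (lev in levels(group)) {
        j <- group == lev
        qg <- q[, j, drop = FALSE]
        mu <- rowMeans(qg)
        v <- apply(qg, 1L, var)
        a <- (v - mu * mean(1 / sizeFactors[j])) / mu^2
        a[!is.finite(a)] <- 0
        alpha <- alpha + a * sum(j)
    }
    alpha <- pmax(alpha / length(group), 0)
    setNames(alpha, rownames(m))
}

# One-gene NB GLM fit: log mu = log s + b0 + b1 * [group2], IRLS with
# working weights mu / (1 + alpha mu); returns NULL on non-convergence.
.nbGlmFit <- function(k, x2, s, alpha, tol = 1e-8, maxIter = 100L) {
    X <- cbind(1, x2)
    o <- log(s)
    mu <- pmax(k, 0.5)
    beta <- c(log(sum(k) / sum(s)), 0)
    for (it in seq_len(maxIter)) {
        eta <- as.numeric(X %*% beta) + o
        mu <- exp(eta)
        w <- mu / (1 + alpha * mu)
        z <- (eta - o) + (k - mu) / mu
        xtw <- t(X * w)
        betaNew <- tryCatch(solve(xtw %*% X, xtw %*% z),
                            error = function(e) NULL)
        if (is.null(betaNew)) return(NULL)
        if (max(abs(betaNew - beta)) < tol) {
            beta <- as.numeric(betaNew)
            eta <- as.numeric(X %*% beta) + o
            mu <- exp(eta)
            w <- mu / (1 + alpha * mu)
            info <- t(X * w) %*% X
            se <- tryCatch(sqrt(diag(solve(info))), error = function(e) NULL)
            if (is.null(se)) return(NULL)
            return(list(beta = beta, se = se))
        }
        beta <- as.numeric(betaNew)
    }
    NULL
}

.bhScore <- function(res, fdr = 0.1) {
    res$q <- p.adjust(res$p, method = "BH")
    res$score <- sign(res$log2fc) * (-log10(res$p))
    res$score[!is.finite(res$log2fc) | is.na(res$p)] <- NA_real_
    res$significant <- !is.na(res$q) & res$q < fdr
    res
}

#' Negative-binomial GLM Wald test of differential gene activity
#'
#' Per gene, fits \code{log mu = log s_j + b0 + b1 * [group2]} with
#' per-gene dispersion, and tests b1 = 0 with a two-sided Wald test. The
#' log2 fold change is \code{b1 / ln 2} (group2 over group1 NO); the
#' differential gene activity score is \code{sign(FC) * (-log10 p)}.
#' Genes where either group has all-zero counts get \code{p = NA} and are
#' flagged. Apply NE filtering and SCNA masking to the gene set first.
#'
#' @param counts Genes x cells count matrix (or SummarizedExperiment with
#'   assay \code{"counts"}).
#' @param group Two-level factor of clone membership per cell.
#' @param sizeFactors Per-cell size factors (default median-of-ratios).
#' @param dispersions Per-gene NB dispersions (default method-of-moments).
#' @param fdr BH significance threshold recorded in the result (default 0.1).
#' @return data.frame: \code{gene_id, base_mean, log2fc, se, stat, p, q,
#'   score, mode, flag}.
#' @export
nbWaldTest <- function(counts, group,
                       sizeFactors = NULL, dispersions = NULL, fdr = 0.1) {
    if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
    m <- as.matrix(counts)
    group <- droplevels(as.factor(group))
    if (nlevels(group) != 2L) stop("exactly two groups required")
    if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(m)
    if (is.null(dispersions))
        dispersions <- estimateDispersions(m, group, sizeFactors)
    x2 <- as.numeric(group == levels(group)[2L])
    ln2 <- log(2)
    n <- nrow(m)
    res <- data.frame(gene_id = rownames(m), base_mean = NA_real_,
                      log2fc = NA_real_, se = NA_real_, stat = NA_real_,
                      p = NA_real_, mode = "NB_GLM", flag = "",
                      stringsAsFactors = FALSE)
    for (g in seq_len(n)) {
        k <- m[g, ]
        res$base_mean[g] <- mean(k / sizeFactors)
        sums <- tapply(k, group, sum)
        if (any(sums == 0)) {
            res$flag[g] <- "group_all_zero"
            next
        }
        fit <- .nbGlmFit(k, x2, sizeFactors, dispersions[g])
        if (is.null(fit)) {
            res$flag[g] <- "not_converged"
            next
        }
        res$log2fc[g] <- fit$beta[2L] / ln2
        res$se[g] <- fit$se[2L] / ln2
        res$stat[g] <- fit$beta[2L] / fit$se[2L]
        res$p[g] <- 2 * pnorm(-abs(res$stat[g]))
    }
    .bhScore(res, fdr)
}

#' PLS-DA/VIP alternative mode for differential gene activity
#'
#' For low-clonal-frequency subclones: fits PLS-DA of clone labels on the
#' normalized gene-body NO matrix, takes each gene's VIP as the statistic,
#' and derives a permutation p-value by refitting under label permutations:
#' \code{p_g = (1 + #\{perm VIP_g >= observed\}) / (nPerm + 1)}. When fewer
#' distinct label assignments than \code{nPerm} exist, all distinct
#' assignments are enumerated instead. The fold change is computed from
#' group means of the normalized matrix (log2 scale).
#'
#' @param x Normalized genes x cells matrix (log2 scale), or a
#'   \code{SummarizedExperiment} with assay \code{"normalized"}.
#' @param group Two-level factor per cell.
#' @param nPerm Number of label permutations (>= 99; default 1000).
#' @param seed Integer seed for the permutations.
#' @param nComponents PLS components (default 1).
#' @param fdr BH threshold recorded in the result (default 0.1).
#' @return data.frame as in \code{\link{nbWaldTest}} with \code{stat} = VIP
#'   and \code{mode = "PLSDA"}.
#' @export
plsdaAltMode <- function(x, group, nPerm = 1000L, seed = 1L,
                         nComponents = 1L, fdr = 0.1) {
    if (is(x, "SummarizedExperiment")) x <- assay(x, "normalized")
    x <- as.matrix(x)
    group <- droplevels(as.factor(group))
    if (nlevels(group) != 2L) stop("exactly two groups required")
    if (nPerm < 99L) stop("nPerm must be >= 99")
    if (any(table(group) < 2L))
        warning("a group has fewer than 2 cells; permutation null may be ",
                "coarse")
    xt <- t(x)
    fit1 <- function(g) fitPlsda(xt, g, nComponents = nComponents,
                                 minPerClass = 1L)
    obs <- vip(fit1(group))
    n <- length(group)
    n1 <- sum(group == levels(group)[1L])
    nDistinct <- choose(n, n1)
    exhaustive <- nDistinct <= nPerm
    set.seed(seed)
    perms <- if (exhaustive) {
        combos <- utils::combn(n, n1)
        lapply(seq_len(ncol(combos)), function(j) {
            g <- rep(levels(group)[2L], n)
            g[combos[, j]] <- levels(group)[1L]
            factor(g, levels = levels(group))
        })
    } else {
        lapply(seq_len(nPerm), function(j) sample(group))
    }
    ge <- rep(1L, length(obs))
    for (pg in perms) {
        v <- tryCatch(vip(fit1(pg)), error = function(e) NULL)
        if (!is.null(v)) ge <- ge + as.integer(v >= obs)
    }
    p <- ge / (length(perms) + 1L)
    g2 <- group == levels(group)[2L]
    log2fc <- rowMeans(x[, g2, drop = FALSE]) -
        rowMeans(x[, !g2, drop = FALSE])
    res <- data.frame(gene_id = rownames(x), base_mean = rowMeans(x),
                      log2fc = log2fc, se = NA_real_, stat = unname(obs),
                      p = p, mode = "PLSDA", flag = "",
                      stringsAsFactors = FALSE)
    .bhScore(res, fdr)
}

#' Mask genes with somatic copy-number differences between clones
#'
#' A gene is removed when its total copy number differs between the two
#' compared clones over at least 1 bp of its body (copy-number differences
#' would confound differential NO). Clone copy number defaults to the
#' germline value (or 2) outside clone-scope segments.
#'
#' @param genes Named \code{GRanges} of gene bodies.
#' @param cn Copy-number table (see \code{\link{normalizeCounts}}).
#' @param clones Character vector of the two clone ids compared.
#' @return Character vector of retained gene ids.
#' @export
maskScnaGenes <- function(genes, cn, clones) {
    stopifnot(length(clones) == 2L)
    if (is.null(cn) || nrow(cn) == 0L) return(names(genes))
    cn <- cn[cn$haplotype == "BOTH", , drop = FALSE]
    germ <- cn[cn$scope == "germline", , drop = FALSE]
    cnAt <- function(cloneId, piece) {
        seg <- cn[cn$scope == cloneId, , drop = FALSE]
        val <- NA_real_
        if (nrow(seg) > 0L) {
            sgr <- GenomicRanges::GRanges(seg$chrom,
                IRanges::IRanges(seg$start, seg$end))
            h <- GenomicRanges::findOverlaps(piece, sgr)
            if (length(h) > 0L)
                val <- seg$copy_number[S4Vectors::subjectHits(h)[1L]]
        }
        if (is.na(val) && nrow(germ) > 0L) {
            ggr <- GenomicRanges::GRanges(germ$chrom,
                IRanges::IRanges(germ$start, germ$end))
            h <- GenomicRanges::findOverlaps(piece, ggr)
            if (length(h) > 0L)
                val <- germ$copy_number[S4Vectors::subjectHits(h)[1L]]
        }
        if (is.na(val)) 2 else val
    }
    segAll <- cn[cn$scope %in% clones, , drop = FALSE]
    keep <- vapply(seq_along(genes), function(i) {
        gene <- granges(genes)[i]
        bounds <- gene
        if (nrow(segAll) > 0L) {
            sgr <- GenomicRanges::GRanges(segAll$chrom,
                IRanges::IRanges(segAll$start, segAll$end))
            ov <- IRanges::subsetByOverlaps(sgr, gene, ignore.strand = TRUE)
            bounds <- GenomicRanges::disjoin(c(gene, granges(ov)),
                                             ignore.strand = TRUE)
            bounds <- IRanges::subsetByOverlaps(bounds, gene,
                                                ignore.strand = TRUE)
        }
        for (j in seq_along(bounds)) {
            if (cnAt(clones[1L], bounds[j]) != cnAt(clones[2L], bounds[j]))
                return(FALSE)
        }
        TRUE
    }, logical(1))
    names(genes)[keep]
}

#' Differential gene activity with automatic mode dispatch
#'
#' Runs the two-group differential test, choosing the mode from the minor
#' clone's frequency: the NB-GLM Wald test when the minor-clone CF is at or
#' above \code{cfModeSwitch} (default 0.1), the PLS-DA/VIP permutation mode
#' below it, reflecting the relative power of the two modes at low clonal
#' frequency.
#'
#' @param counts Genes x cells count matrix.
#' @param normalized Matching normalized (log2) matrix for the PLS-DA mode;
#'   when NULL it is derived as log2 RPM from the counts.
#' @param group Two-level factor per cell.
#' @param cfModeSwitch CF threshold for mode dispatch (default 0.1).
#' @param mode Force \code{"NB_GLM"} or \code{"PLSDA"}; default
#'   \code{"auto"}.
#' @param sizeFactors Optional per-cell size factors (NB mode).
#' @param nPerm,seed Permutation controls (PLS-DA mode).
#' @param fdr BH threshold recorded in the result (default 0.1).
#' @return data.frame of per-gene results.
#' @export
diffGeneActivity <- function(counts, group, normalized = NULL,
                             cfModeSwitch = 0.1,
                             mode = c("auto", "NB_GLM", "PLSDA"),
                             sizeFactors = NULL, nPerm = 1000L, seed = 1L,
                             fdr = 0.1) {
    mode <- match.arg(mode)
    group <- droplevels(as.factor(group))
    if (mode == "auto") {
        cfMinor <- min(table(group)) / length(group)
        mode <- if (cfMinor >= cfModeSwitch) "NB_GLM" else "PLSDA"
    }
    if (mode == "NB_GLM") {
        nbWaldTest(counts, group, sizeFactors = sizeFactors, fdr = fdr)
    } else {
        if (is.null(normalized)) {
            lib <- colSums(counts)
            normalized <- log2(sweep(as.matrix(counts), 2L, lib, "/") * 1e6
                               + 1)
        }
        plsdaAltMode(normalized, group, nPerm = nPerm, seed = seed,
                     fdr = fdr)
    }
}
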
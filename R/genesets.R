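# Gene-set machinery: GMT I/O, hypergeometric over-representation (TF
# targets), pathway-level NO scores with mixed-model likelihood ratio tests,
# and shared contingency-table statistics.

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated \code{name, description,
#' member...}. Members are deduplicated; empty sets (after deduplication)
#' are dropped with a warning; a line with fewer than three fields is a
#' parse error naming the line.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of member gene ids, with a
#'   \code{"description"} attribute (named character vector).
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("cannot read GMT file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list(); desc <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop("malformed GMT line ", i, ": need name, description and at ",
                 "least one member")
        members <- unique(f[-(1:2)])
        members <- members[nzchar(members)]
        if (length(members) == 0L) {
            warning("dropping empty gene set '", f[1L], "' (line ", i, ")")
            next
        }
        sets[[f[1L]]] <- members
        desc[f[1L]] <- f[2L]
    }
    attr(sets, "description") <- desc
    sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @return Invisibly, the path.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- attr(sets, "description")
    lines <- vapply(names(sets), function(nm) {
        d <- if (!is.null(descriptions) && nm %in% names(descriptions))
            descriptions[[nm]] else "na"
        paste(c(nm, d, sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Hypergeometric over-representation of gene sets
#'
#' For each set, tests whether the hit genes are enriched among the set's
#' members within the universe: upper-tail hypergeometric
#' \code{p = P(X >= k)} with \code{N = |universe|},
#' \code{K = |set within universe|}, \code{n = |hits|} and \code{k} the
#' overlap (equivalent to a one-sided Fisher's exact test), followed by BH
#' correction.
#'
#' @param hits Character vector of hit gene ids (must be within
#'   \code{universe}).
#' @param universe Character vector of all testable gene ids.
#' @param sets Named list of gene sets (intersected with the universe before
#'   testing).
#' @param fdr BH threshold (default 0.1).
#' @return data.frame: \code{set_id, set_size, n_hits, overlap, p, q,
#'   significant}.
#' @export
overrepresentationTest <- function(hits, universe, sets, fdr = 0.1) {
    universe <- unique(universe)
    if (length(universe) == 0L) stop("empty universe")
    hits <- unique(hits)
    if (!all(hits %in% universe))
        stop("hits must be a subset of the universe")
    N <- length(universe); n <- length(hits)
    res <- data.frame(set_id = names(sets), set_size = NA_integer_,
                      n_hits = n, overlap = NA_integer_, p = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(sets)) {
        s <- intersect(sets[[i]], universe)
        K <- length(s)
        k <- length(intersect(s, hits))
        res$set_size[i] <- K
        res$overlap[i] <- k
        res$p[i] <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    }
    res$q <- p.adjust(res$p, method = "BH")
    res$significant <- !is.na(res$q) & res$q < fdr
    res
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact p by hypergeometric enumeration; the two-sided p sums the
#' probabilities of all tables as or less probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative \code{"two_sided"} (default), \code{"greater"} or
#'   \code{"less"} (refers to the [1,1] cell's odds ratio).
#' @return The p-value.
#' @export
fisherExact <- function(table, alternative = c("two_sided", "greater",
                                               "less")) {
    alternative <- match.arg(alternative)
    table <- as.matrix(table)
    if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
    if (any(table < 0) || any(!is.finite(table)))
        stop("table entries must be finite and non-negative")
    alt <- sub("_", ".", alternative)
    fisher.test(table, alternative = alt)$p.value
}

#' Pathway-level NO scores per cell
#'
#' For each pathway, the per-cell mean of the normalized NO values of its
#' member genes, after removing lowly variable genes: genes whose across-cell
#' standard deviation falls below the \code{variabilityQuantile} quantile of
#' the s.d. distribution over all matrix genes (default the 80th percentile;
#' \code{mode = "absolute"} instead drops genes with s.d. below
#' \code{variabilityQuantile} directly). With
#' \code{activityTransform = TRUE} scores are reported as activities,
#' (-1) x Z score of NO across cells (low occupancy = high activity).
#'
#' @param x Genes x cells matrix of median-of-ratios-normalized counts
#'   (counts divided by their size factors), or a SummarizedExperiment with
#'   assay \code{"normalized"}.
#' @param sets Named list of gene sets.
#' @param variabilityQuantile Variability cutoff (quantile in [0,1], or an
#'   absolute s.d. when \code{mode = "absolute"}).
#' @param mode \code{"quantile"} (default) or \code{"absolute"}.
#' @param activityTransform Report (-1) x Z scores (default FALSE).
#' @return Cells x pathways matrix; pathways with no surviving members give
#'   an NA column with a warning.
#' @export
pathwayNoScores <- function(x, sets, variabilityQuantile = 0.8,
                            mode = c("quantile", "absolute"),
                            activityTransform = FALSE) {
    mode <- match.arg(mode)
    if (is(x, "SummarizedExperiment")) x <- assay(x, "normalized")
    x <- as.matrix(x)
    sds <- apply(x, 1L, sd)
    cut <- if (mode == "quantile")
        quantile(sds, variabilityQuantile, names = FALSE)
    else variabilityQuantile
    variable <- rownames(x)[sds >= cut & sds > 0]
    out <- matrix(NA_real_, ncol(x), length(sets),
                  dimnames = list(colnames(x), names(sets)))
    for (i in seq_along(sets)) {
        members <- intersect(sets[[i]], variable)
        if (length(members) == 0L) {
            warning("pathway '", names(sets)[i],
                    "' has no members surviving the variability filter")
            next
        }
        out[, i] <- colMeans(x[members, , drop = FALSE])
    }
    if (activityTransform) {
        for (i in seq_len(ncol(out))) {
            v <- out[, i]
            if (all(is.na(v))) next
            out[, i] <- -(v - mean(v)) / sd(v)
        }
    }
    out
}

#' Mixed-model tests of pathway-level NO against SV status
#'
#' Per pathway, maximum-likelihood fit of
#' \code{score ~ SV status + (1 | batch)} (SV status fixed, library batch a
#' random intercept) against the nested no-SV-effect null, with a likelihood
#' ratio test on 1 df. With a single batch the random effect is degenerate
#' and the test automatically reduces to an ordinary linear-model LRT
#' (message emitted).
#'
#' @param scores Cells x pathways matrix from \code{\link{pathwayNoScores}}.
#' @param svStatus Per-cell logical/two-level flag (>= 2 cells per group).
#' @param batch Per-cell batch label.
#' @param fdr BH threshold (default 0.1).
#' @return data.frame: \code{pathway, effect, lrt, p, q, significant};
#'   \code{effect} is the fitted SV coefficient.
#' @export
pathwayLmmTest <- function(scores, svStatus, batch, fdr = 0.1) {
    sv <- as.factor(svStatus)
    if (nlevels(sv) != 2L) stop("svStatus must have exactly two levels")
    if (any(table(sv) < 2L)) stop("need >= 2 cells per SV-status group")
    batch <- as.factor(batch)
    single <- nlevels(batch) < 2L
    if (single)
        message("single batch: reducing to ordinary linear-model LRT")
    res <- data.frame(pathway = colnames(scores), effect = NA_real_,
                      lrt = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(ncol(scores))) {
        y <- scores[, i]
        ok <- is.finite(y)
        if (sum(ok) < 4L || length(unique(sv[ok])) < 2L) next
        if (single) {
            full <- lm(y[ok] ~ sv[ok])
            null <- lm(y[ok] ~ 1)
            lrt <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null)))
            res$effect[i] <- coef(full)[2L]
        } else {
            df <- data.frame(y = y[ok], sv = sv[ok], batch = batch[ok])
            full <- suppressWarnings(suppressMessages(
                lme4::lmer(y ~ sv + (1 | batch), data = df, REML = FALSE)))
            null <- suppressWarnings(suppressMessages(
                lme4::lmer(y ~ 1 + (1 | batch), data = df, REML = FALSE)))
            lrt <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null)))
            res$effect[i] <- lme4::fixef(full)[2L]
        }
        res$lrt[i] <- max(lrt, 0)
        res$p[i] <- pchisq(max(lrt, 0), df = 1L, lower.tail = FALSE)
    }
    res$q <- p.adjust(res$p, method = "BH")
    res$significant <- !is.na(res$q) & res$q < fdr
    res
}
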
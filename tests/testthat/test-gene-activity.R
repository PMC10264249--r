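# Two-step gene activity inference: featurization, NE filtering, size
# factors, dispersions, NB-GLM Wald tests, the PLS-DA alternative mode and
# SCNA masking.

test_that("gene featurization bins coverage as documented", {
    sl <- c(chr1 = 10000)
    genes <- GRanges("chr1", IRanges(1001, 1300), seqlengths = sl)
    names(genes) <- "g300"
    # coverage 1 on first half, 0 on the second: 150 bins of 2 bp each
    fs <- FragmentSet(makeFragGR("chr1", 1001, 1150, seqlengths = sl))
    f <- featurizeGenes(fs, genes, nBins = 150)
    expect_equal(dim(f), c(1L, 301L))
    expect_equal(unname(f[1, 1:75]), rep(1, 75))
    expect_equal(unname(f[1, 76:150]), rep(0, 75))
    expect_equal(unname(f[1, "log_length"]), log(300))

    # uniform coverage -> all NO bins equal
    fs2 <- FragmentSet(makeFragGR("chr1", 901, 1400, seqlengths = sl))
    f2 <- featurizeGenes(fs2, genes, nBins = 10)
    expect_equal(unname(f2[1, 1:10]), rep(1, 10))

    # GC features pass through; an all-G bin would carry fraction 1
    gc <- matrix(c(rep(1, 5), rep(0.4, 5)), 1, 10,
                 dimnames = list("g300", NULL))
    f3 <- featurizeGenes(fs2, genes, gc = gc, nBins = 10)
    expect_equal(unname(f3[1, 11:15]), rep(1, 5))

    # gene shorter than nBins: per-bp resampling keeps the vector finite
    short <- GRanges("chr1", IRanges(1001, 1005), seqlengths = sl)
    names(short) <- "tiny"
    f4 <- featurizeGenes(fs2, short, nBins = 10)
    expect_true(all(is.finite(f4)))
    expect_equal(unname(f4[1, 1:10]), rep(1, 10))
})

test_that("NE classifier separates NO-depleted genes and is reproducible", {
    set.seed(20)
    n <- 120
    ne <- rep(c(TRUE, FALSE), each = n / 2)
    # NE genes have systematically higher gene-body NO across the bins
    base <- matrix(rnorm(n * 20, mean = 2), n, 20)
    base[ne, ] <- base[ne, ] + 2.5
    feats <- cbind(base, log_len = rnorm(n, 8, 0.5))
    colnames(feats) <- c(sprintf("no_%d", 1:20), "log_length")
    rownames(feats) <- sprintf("gene_%03d", seq_len(n))
    m <- trainNeClassifier(feats, ne)
    p <- predictNe(m, feats)
    expect_gte(mean((p >= 0.5) == ne), 0.95)
    # retraining is deterministic
    p2 <- predictNe(trainNeClassifier(feats, ne), feats)
    expect_identical(p, p2)
    expect_error(trainNeClassifier(feats, rep(TRUE, n)), "both")
})

test_that("unregularized logistic engine matches a direct ML fit", {
    set.seed(21)
    x <- matrix(rnorm(80), ncol = 1, dimnames = list(NULL, "no_1"))
    y <- runif(80) < 1 / (1 + exp(-(0.5 + 2 * x[, 1])))
    m <- trainNeClassifier(x, y, method = "logistic")
    # oracle: maximize the Bernoulli likelihood directly on standardized x
    xs <- (x - mean(x)) / sd(x)
    nll <- function(b) -sum(y * (b[1] + b[2] * xs) -
                            log(1 + exp(b[1] + b[2] * xs)))
    opt <- optim(c(0, 0), nll, method = "BFGS")
    expect_equal(unname(m@fit$coefficients), opt$par, tolerance = 1e-4)
})

test_that("NE filtering is inclusive at the 0.9 boundary across clones", {
    probs <- rbind(removed = c(0.95, 0.92),
                   retained = c(0.95, 0.89),
                   boundary = c(0.90, 0.90),
                   clearly_on = c(0.10, 0.20))
    colnames(probs) <- c("cloneA", "cloneB")
    kept <- filterNeGenes(probs, threshold = 0.9)
    expect_false("removed" %in% kept)
    expect_true("retained" %in% kept)     # one clone below threshold
    expect_false("boundary" %in% kept)    # >= is inclusive
    expect_true("clearly_on" %in% kept)
    expect_error(filterNeGenes(matrix(numeric(), 0, 0)), "no NE")
})

test_that("size factors recover scalar multiples and match brute force", {
    base <- c(10, 40, 25, 100, 7)
    m <- cbind(c1 = base, c2 = 2 * base, c3 = 0.5 * base)
    rownames(m) <- paste0("g", 1:5)
    s <- computeSizeFactors(m)
    expect_equal(unname(s / s["c1"]), c(1, 2, 0.5), tolerance = 1e-12)
    # identical columns give all 1
    ident <- cbind(base, base, base)
    expect_equal(unname(computeSizeFactors(ident)), rep(1, 3))
    # 3x2 toy matrix against the brute-force median of per-gene ratios
    toy <- matrix(c(4, 9, 25, 16, 3, 1), 3, 2)
    ref <- exp(rowMeans(log(toy)))
    oracle <- c(median(toy[, 1] / ref), median(toy[, 2] / ref))
    expect_equal(unname(computeSizeFactors(toy)), oracle)
    allZeroRow <- rbind(m, g6 = 0)
    expect_equal(unname(computeSizeFactors(allZeroRow)), unname(s))
    expect_error(computeSizeFactors(matrix(c(0, 1, 1, 0), 2)), "nonzero")
})

test_that("dispersion estimation recovers the generating model", {
    sim <- simulateCounts(nGenes = 150, nPerGroup = c(50, 50), mu = 30,
                          dispersion = 0, seed = 22)
    aPois <- estimateDispersions(sim$counts, sim$group, sim$sizeFactors)
    expect_lt(median(aPois), 0.05)
    simNB <- simulateCounts(nGenes = 150, nPerGroup = c(50, 50), mu = 30,
                            dispersion = 0.5, seed = 23)
    aNB <- estimateDispersions(simNB$counts, simNB$group, simNB$sizeFactors)
    expect_gt(median(aNB), 0.3)
    expect_lt(median(aNB), 0.7)
    # constant gene with unit size factors has zero dispersion
    cst <- matrix(5L, 1, 20, dimnames = list("g", NULL))
    expect_equal(unname(estimateDispersions(cst, rep(c("a", "b"), 10),
                                            rep(1, 20))), 0)
})

test_that("NB Wald test has exact null and Poisson-limit behavior", {
    set.seed(24)
    half <- matrix(rpois(50 * 10, 20), 50, 10)
    dup <- cbind(half, half)  # group 2 duplicates group 1 exactly
    rownames(dup) <- paste0("g", 1:50)
    colnames(dup) <- paste0("c", 1:20)
    grp <- rep(c("a", "b"), each = 10)
    r <- nbWaldTest(dup, grp, sizeFactors = rep(1, 20))
    ok <- r$flag == ""
    expect_true(all(abs(r$stat[ok]) < 1e-6))
    expect_true(all(r$p[ok] > 1 - 1e-6))

    # alpha = 0 limit equals the Poisson closed form
    sim <- simulateCounts(nGenes = 20, nPerGroup = c(15, 15), mu = 25,
                          dispersion = 0, seed = 25)
    r2 <- nbWaldTest(sim$counts, sim$group, sizeFactors = sim$sizeFactors,
                     dispersions = rep(0, 20))
    g2 <- sim$group == "clone2"
    s <- sim$sizeFactors
    closed <- apply(sim$counts, 1, function(k)
        log2((sum(k[g2]) / sum(s[g2])) / (sum(k[!g2]) / sum(s[!g2]))))
    expect_equal(r2$log2fc, unname(closed), tolerance = 1e-6)

    # a group with all-zero counts is flagged NA, not an error
    z <- sim$counts
    z[1, g2] <- 0L
    r3 <- nbWaldTest(z, sim$group, sizeFactors = sim$sizeFactors,
                     dispersions = rep(0, 20))
    expect_true(is.na(r3$p[1]))
    expect_equal(r3$flag[1], "group_all_zero")
})

test_that("NB Wald fold changes agree with DESeq2 on the same data", {
    skip_if_not_installed("DESeq2")
    sim <- simulateCounts(nGenes = 60, nPerGroup = c(25, 25), mu = 30,
                          dispersion = 0.15, effectGenes = 1:10,
                          foldChange = 2, seed = 26)
    r <- nbWaldTest(sim$counts, sim$group)
    dds <- DESeq2::DESeqDataSetFromMatrix(sim$counts,
        S4Vectors::DataFrame(condition = sim$group), ~condition)
    dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
    ref <- DESeq2::results(dds)
    expect_gt(cor(r$log2fc, ref$log2FoldChange, use = "complete.obs"), 0.98)
    expect_gt(cor(-log10(r$p), -log10(ref$pvalue), use = "complete.obs",
                  method = "spearman"), 0.9)
})

test_that("score and fold change are antisymmetric under label swap", {
    sim <- simulateCounts(nGenes = 30, nPerGroup = c(12, 12), mu = 25,
                          dispersion = 0.2, effectGenes = 1:5,
                          foldChange = 2, seed = 27)
    r1 <- nbWaldTest(sim$counts, sim$group)
    swapped <- factor(ifelse(sim$group == "clone1", "z2", "a1"))
    r2 <- nbWaldTest(sim$counts, swapped)
    ok <- r1$flag == "" & r2$flag == ""
    expect_equal(r1$log2fc[ok], -r2$log2fc[ok], tolerance = 1e-6)
    expect_equal(r1$score[ok], -r2$score[ok], tolerance = 1e-4)
})

test_that("BH q-values equal the brute-force step-up definition", {
    set.seed(28)
    sim <- simulateCounts(nGenes = 40, nPerGroup = c(10, 10), mu = 20,
                          dispersion = 0.2, seed = 28)
    r <- nbWaldTest(sim$counts, sim$group)
    p <- r$p[!is.na(r$p)]
    G <- length(p)
    o <- order(p)
    qOracle <- numeric(G)
    for (i in seq_len(G))
        qOracle[o[i]] <- min(1, min(p[o][i:G] * G / (i:G)))
    expect_equal(r$q[!is.na(r$p)], qOracle, tolerance = 1e-12)
})

test_that("PLS-DA alternative mode finds strong shifts with valid p floor", {
    set.seed(29)
    n <- 40
    x <- matrix(rnorm(60 * n, mean = 5), 60, n,
                dimnames = list(paste0("g", 1:60), paste0("c", 1:n)))
    grp <- rep(c("ref", "sv"), each = 20)
    x["g1", grp == "sv"] <- x["g1", grp == "sv"] + log2(3)  # 3-fold NO shift
    r <- plsdaAltMode(x, grp, nPerm = 999, seed = 30)
    expect_true(all(r$p >= 1 / 1000))
    expect_lt(r$q[r$gene_id == "g1"], 0.1)
    expect_equal(sum(r$stat^2), 60, tolerance = 1e-9)  # sum VIP^2 = genes
    expect_equal(r$mode[1], "PLSDA")
    # fold change reflects group means on the log scale
    expect_equal(r$log2fc[r$gene_id == "g1"],
                 mean(x["g1", grp == "sv"]) - mean(x["g1", grp == "ref"]))
})

test_that("alternative mode enumerates all assignments for tiny groups", {
    set.seed(31)
    x <- matrix(rnorm(10 * 8), 10, 8,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:8)))
    grp <- rep(c("a", "b"), each = 4)   # C(8,4) = 70 < nPerm
    expect_warning(r <- plsdaAltMode(x, c("a", rep("b", 7)), nPerm = 99,
                                     seed = 1), "fewer than 2")
    r <- plsdaAltMode(x, grp, nPerm = 99, seed = 32)
    expect_true(all(r$p >= 1 / 71))
    # p-values are multiples of 1/71 under exhaustive enumeration
    expect_true(all(abs(r$p * 71 - round(r$p * 71)) < 1e-9))
})

test_that("SCNA masking removes genes whose CN differs between clones", {
    genes <- GRanges("chr1", IRanges(c(1000, 5000, 9000),
                                     c(1999, 5999, 9999)))
    names(genes) <- c("gA", "gB", "gC")
    cn <- data.frame(scope = c("germline", "sv"),
                     chrom = "chr1", start = c(1, 4500), end = c(20000, 6500),
                     haplotype = "BOTH", copy_number = c(2, 1))
    # no somatic change -> identity
    expect_equal(maskScnaGenes(genes, cn[1, ], c("ref", "sv")),
                 c("gA", "gB", "gC"))
    # gB sits inside the subclonal deletion -> removed
    expect_equal(maskScnaGenes(genes, cn, c("ref", "sv")), c("gA", "gC"))
    # a gene ending 1 bp before the segment is retained
    edge <- GRanges("chr1", IRanges(3000, 4499))
    names(edge) <- "gEdge"
    expect_equal(maskScnaGenes(edge, cn, c("ref", "sv")), "gEdge")
    touch <- GRanges("chr1", IRanges(3000, 4500))
    names(touch) <- "gTouch"
    expect_equal(length(maskScnaGenes(touch, cn, c("ref", "sv"))), 0L)
})

test_that("mode dispatch follows the minor-clone frequency", {
    sim <- simulateCounts(nGenes = 20, nPerGroup = c(46, 4), mu = 25,
                          dispersion = 0.1, seed = 33)
    rLow <- diffGeneActivity(sim$counts, sim$group, nPerm = 99, seed = 1)
    expect_equal(rLow$mode[1], "PLSDA")   # CF 8% < 10%
    sim2 <- simulateCounts(nGenes = 20, nPerGroup = c(40, 10), mu = 25,
                           dispersion = 0.1, seed = 34)
    rHigh <- diffGeneActivity(sim2$counts, sim2$group)
    expect_equal(rHigh$mode[1], "NB_GLM") # CF 20% >= 10%
})
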
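# Haplotype-specific NO: WC-state gating, Wilcoxon tests, breakpoint scans,
# CRE exact tests and TAD outlier tests.

test_that("phased unit counts are gated on the WC state", {
    units <- GRanges("chr1", IRanges(1000, 2000))
    names(units) <- "geneA"
    gr <- c(makeFragGR("chr1", seq(1100, 1500, 100), seq(1259, 1659, 100),
                       cell = "wcCell", haplotype = "H1"),
            makeFragGR("chr1", seq(1100, 1300, 100), seq(1259, 1459, 100),
                       cell = "wcCell", haplotype = "H2"),
            makeFragGR("chr1", 1200, 1350, cell = "wcCell",
                       haplotype = "UNPHASED"),
            makeFragGR("chr1", seq(1100, 1500, 100), seq(1259, 1659, 100),
                       cell = "wwCell", haplotype = "H1", strand = "W"))
    states <- makeStates(c("wcCell", "wwCell"), "chr1", c("WC", "WW"))
    hc <- haplotypeUnitCounts(FragmentSet(gr), units, states)
    expect_equal(hc@h1["geneA", "wcCell"], 5L)
    expect_equal(hc@h2["geneA", "wcCell"], 3L)
    # WW-state cell contributes nothing
    expect_equal(hc@h1["geneA", "wwCell"], 0L)
    expect_equal(hc@total["geneA", "wwCell"], 0L)
    # conservation: H1 + H2 + unphased = total within WC cells
    expect_equal(hc@total["geneA", "wcCell"], 5L + 3L + 1L)
    # removing all WC cells empties the counts
    states2 <- makeStates(c("wcCell", "wwCell"), "chr1", c("CC", "WW"))
    hc2 <- haplotypeUnitCounts(FragmentSet(gr), units, states2)
    expect_true(all(hc2@total == 0L))
    expect_warning(
        haplotypeUnitCounts(FragmentSet(gr),
                            setNames(GRanges("chrZ", IRanges(1, 10)), "u"),
                            states), "absent")
})

test_that("haplotype Wilcoxon p-values match exact enumeration", {
    # n = 4 vs 4, no ties: p from enumeration over C(8,4) = 70 arrangements
    x1 <- c(1.3, 2.7, 3.1, 4.9)
    x2 <- c(0.2, 0.8, 2.1, 3.5)
    units <- setNames(GRanges("chr1", IRanges(1, 100)), "u")
    hcLike <- new("HaplotypeCounts", units = units,
                  h1 = matrix(1L, 1, 8), h2 = matrix(1L, 1, 8),
                  total = matrix(2L, 1, 8), cnH1 = 1, cnH2 = 1,
                  cells = paste0("c", 1:8))
    # direct check of the test statistic machinery via wilcox on the values
    pPkg <- suppressWarnings(wilcox.test(x1, x2)$p.value)
    pooled <- c(x1, x2)
    combos <- combn(8, 4)
    wObs <- sum(rank(pooled)[1:4]) - 4 * 5 / 2
    wAll <- apply(combos, 2, function(idx)
        sum(rank(pooled)[idx]) - 4 * 5 / 2)
    pOracle <- mean(abs(wAll - 8) >= abs(wObs - 8))  # E[W] = n1 n2 / 2 = 8
    expect_equal(pPkg, pOracle, tolerance = 1e-12)
})

test_that("testHaplotypeNo detects imbalance and is label-symmetric", {
    set.seed(40)
    nCells <- 24
    units <- setNames(GRanges("chr1", IRanges(c(1, 1001), c(1000, 2000))),
                      c("affected", "null"))
    h1 <- rbind(rpois(nCells, 10), rpois(nCells, 6))
    h2 <- rbind(rpois(nCells, 5), rpois(nCells, 6))
    hc <- new("HaplotypeCounts", units = units,
              h1 = h1, h2 = h2, total = h1 + h2,
              cnH1 = c(1, 1), cnH2 = c(1, 1),
              cells = paste0("c", seq_len(nCells)))
    r <- testHaplotypeNo(hc, minCells = 5)
    expect_lt(r$q[r$unit_id == "affected"], 0.1)
    expect_gt(r$log2fc[r$unit_id == "affected"], 0)
    # identical samples give the maximal p-value
    hcEq <- new("HaplotypeCounts", units = units[1],
                h1 = h1[1, , drop = FALSE], h2 = h1[1, , drop = FALSE],
                total = 2L * h1[1, , drop = FALSE], cnH1 = 1, cnH2 = 1,
                cells = paste0("c", seq_len(nCells)))
    expect_equal(testHaplotypeNo(hcEq, minCells = 5)$p[1], 1)
    # swapping H1/H2 inverts the fold change and preserves p exactly
    hcSwap <- new("HaplotypeCounts", units = units, h1 = h2, h2 = h1,
                  total = h1 + h2, cnH1 = c(1, 1), cnH2 = c(1, 1),
                  cells = paste0("c", seq_len(nCells)))
    rs <- testHaplotypeNo(hcSwap, minCells = 5)
    expect_equal(rs$p, r$p)
    expect_equal(rs$log2fc, -r$log2fc, tolerance = 1e-12)
    # too few informative cells -> NA
    few <- new("HaplotypeCounts", units = units[1],
               h1 = matrix(c(1L, 1L, 0L, 0L), 1),
               h2 = matrix(c(0L, 1L, 0L, 0L), 1),
               total = matrix(c(1L, 2L, 0L, 0L), 1), cnH1 = 1, cnH2 = 1,
               cells = paste0("c", 1:4))
    expect_true(is.na(testHaplotypeNo(few, minCells = 5)$p[1]))
})

test_that("the +/-1 Mb local scan equals a brute-force distance filter", {
    genes <- GRanges("chr1", IRanges(c(0.1e6, 2.0e6, 4.2e6, 6e6),
                                     width = 10000))
    names(genes) <- c("near1", "near2", "far", "veryfar")
    # breakpoint at 2.9 Mb: near2 is 0.9 Mb away, far is 1.3 Mb away
    svs <- data.frame(sv_id = "sv1", chrom = "chr1", start = 2.9e6,
                      end = 2.9e6)
    results <- data.frame(unit_id = names(genes), log2fc = c(1, 2, 3, 4),
                          p = c(0.001, 0.02, 0.5, 0.9))
    r <- localScan(svs, results, genes, radius = 1e6)
    expect_setequal(r$gene_id, c("near2"))
    # brute force: any gene whose body comes within 1 Mb of a breakpoint
    mids <- start(genes)
    brute <- names(genes)[start(genes) <= 2.9e6 + 1e6 &
                          end(genes) >= 2.9e6 - 1e6]
    expect_setequal(r$gene_id, brute)
    # q is re-adjusted within the scan set only
    expect_equal(r$q_local, p.adjust(results$p[results$unit_id %in% brute],
                                     "BH"))
    expect_equal(nrow(localScan(svs[0, ], results, genes)), 0L)
})

test_that("sliding-window LRT, FC and permutation floor are exact", {
    # one 50 kb window containing 40 H1 and 10 H2 fragments from a WC cell
    pos1 <- seq(1000, 40000, length.out = 40)
    pos2 <- seq(1200, 39000, length.out = 10)
    gr <- c(makeFragGR("chr1", pos1, pos1 + 159, cell = "c1",
                       haplotype = "H1"),
            makeFragGR("chr1", pos2, pos2 + 159, cell = "c1",
                       haplotype = "H2"))
    states <- makeStates("c1", "chr1", "WC")
    region <- GRanges("chr1", IRanges(1, 50000))
    prof <- slidingWindowScan(FragmentSet(gr), states, region,
                              window = 50000, step = 50000, nPerm = 199,
                              seed = 3)
    expect_equal(nrow(prof), 1L)
    expect_equal(prof$n_h1, 40L)
    expect_equal(prof$n_h2, 10L)
    expect_equal(prof$fc, 4)   # plain ratio when both counts positive
    expect_equal(prof$lrt, 2 * (40 * log(40 / 25) + 10 * log(10 / 25)),
                 tolerance = 1e-12)
    expect_equal(prof$p_analytic, pchisq(prof$lrt, 1, lower.tail = FALSE))
    expect_gte(prof$p_adjusted, 1 / 200)

    # balanced window: FC = 1 and analytic p = 1
    gr2 <- c(makeFragGR("chr1", pos2, pos2 + 159, cell = "c1",
                        haplotype = "H1"),
             makeFragGR("chr1", pos2 + 300, pos2 + 459, cell = "c1",
                        haplotype = "H2"))
    prof2 <- slidingWindowScan(FragmentSet(gr2), states, region,
                               window = 50000, step = 50000, nPerm = 99)
    expect_equal(prof2$fc, 1)
    expect_equal(prof2$lrt, 0)
    expect_equal(prof2$p_analytic, 1)
    # empty window yields an NA row
    region3 <- GRanges("chr1", IRanges(1, 100000))
    prof3 <- slidingWindowScan(FragmentSet(gr2), states, region3,
                               window = 50000, step = 50000, nPerm = 99)
    expect_true(is.na(prof3$p_analytic[2]))
})

test_that("CRE exact test matches binomial tail closed forms", {
    states <- makeStates("c1", "chr1", "WC")
    cres <- setNames(GRanges("chr1", IRanges(c(1000, 3000), width = 500)),
                     c("creBalanced", "creSkewed"))
    mk <- function(n1, n2, at) {
        p1 <- seq(at, at + 400, length.out = max(n1, 1))[seq_len(n1)]
        p2 <- seq(at + 7, at + 407, length.out = max(n2, 1))[seq_len(n2)]
        parts <- list()
        if (n1 > 0) parts <- c(parts, list(makeFragGR("chr1", p1, p1 + 150,
            cell = "c1", haplotype = "H1")))
        if (n2 > 0) parts <- c(parts, list(makeFragGR("chr1", p2, p2 + 150,
            cell = "c1", haplotype = "H2")))
        do.call(c, parts)
    }
    gr <- c(mk(12, 12, 1000), mk(0, 20, 3000))
    r <- creExactTest(FragmentSet(gr), cres, states)
    expect_equal(r$p[r$cre_id == "creBalanced"], 1)
    # (0, 20) at p0 = 0.5: two-sided p = 2 * 0.5^20
    expect_equal(r$p[r$cre_id == "creSkewed"], 2 * 0.5^20,
                 tolerance = 1e-12)
    # CN 1:2 -> p0 = 1/3; matches the brute-force binomial tail sum
    r2 <- creExactTest(FragmentSet(mk(12, 12, 1000)), cres[1], states,
                       cnH1 = 1, cnH2 = 2)
    n <- 24; k <- 12; p0 <- 1/3
    dens <- dbinom(0:n, n, p0)
    pOracle <- sum(dens[dens <= dbinom(k, n, p0) * (1 + 1e-7)])
    expect_equal(r2$p[1], pOracle, tolerance = 1e-9)
})

test_that("TAD outlier test matches the ECDF KS oracle", {
    # profile with two TADs; logFC values chosen without ties
    prof <- data.frame(chrom = "chr1",
                       start = seq(1, 9 * 1000, 1000),
                       end = seq(1000, 9000 + 1000, 1000)[1:9],
                       n_h1 = 5L, n_h2 = 5L,
                       fc = exp(c(0.1, 0.4, 0.2, 0.35, 2.1, 2.4, 2.2, 2.6,
                                  2.3)),
                       lrt = 1, p_analytic = 0.5, p_adjusted = 0.5)
    tads <- setNames(GRanges("chr1", IRanges(c(1, 4001), c(4000, 10000))),
                     c("tadA", "tadB"))
    r <- tadOutlierTest(prof, tads)
    # disjoint supports: D = 1
    expect_equal(r$D[r$tad_id == "tadA"], 1)
    # oracle: brute-force sup of ECDF difference for the 4-vs-5 split
    a <- log(prof$fc[1:4]); b <- log(prof$fc[5:9])
    grid <- sort(c(a, b))
    dOracle <- max(abs(vapply(grid, function(t)
        mean(a <= t) - mean(b <= t), numeric(1))))
    expect_equal(r$D[r$tad_id == "tadA"], dOracle)
    # near-identical samples: small D, large p
    prof2 <- prof
    prof2$fc[1:4] <- exp(c(0.1, 0.2, 0.3, 0.4))
    prof2$fc[5:9] <- exp(c(0.1, 0.2, 0.3, 0.4, 0.25))
    r2 <- suppressWarnings(tadOutlierTest(prof2, tads))
    expect_lt(r2$D[r2$tad_id == "tadA"], 0.3)
    expect_gt(r2$p[r2$tad_id == "tadA"], 0.5)
})
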
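# Pseudobulk tracks, anchor profiles, counting and normalization.

test_that("pseudobulk bins equal brute-force per-bp stack means", {
    sl <- c(chr1 = 1000)
    fs <- FragmentSet(makeFragGR("chr1", c(101, 131), c(260, 310),
                                 seqlengths = sl))
    tr <- pseudobulkTrack(fs, binSize = 10)
    bins <- trackBins(tr)
    # per-bp oracle
    stack <- numeric(1000)
    stack[101:260] <- stack[101:260] + 1
    stack[131:310] <- stack[131:310] + 1
    oracle <- vapply(seq_len(100), function(b)
        mean(stack[((b - 1) * 10 + 1):(b * 10)]), numeric(1))
    expect_equal(S4Vectors::mcols(bins)$score, oracle)

    # single fragment, covered bins exactly 1
    one <- FragmentSet(makeFragGR("chr1", 101, 160, seqlengths = sl))
    sc <- S4Vectors::mcols(trackBins(pseudobulkTrack(one, 10)))$score
    expect_equal(sc[11:16], rep(1, 6))
    expect_equal(sum(sc > 0), 6)

    # unit bins on a 10-bp chromosome: on-disk [0,5) -> first 5 bp covered
    tiny <- FragmentSet(makeFragGR("chr1", 1, 5, seqlengths = c(chr1 = 10)))
    sc1 <- S4Vectors::mcols(trackBins(pseudobulkTrack(tiny, 1)))$score
    expect_equal(sc1, c(rep(1, 5), rep(0, 5)))
})

test_that("coverage is conserved and haplotype tracks sum to ALL", {
    cfg <- simConfig(n_cells = 8, n_genes = 15, fragments_per_cell = 400,
                     unphased_fraction = 0.3, seed = 14)
    sim <- simulateCells(simulateGenome(cfg), cfg)
    t1 <- pseudobulkTrack(sim$frags, binSize = 1)
    expect_equal(sum(S4Vectors::mcols(trackBins(t1))$score),
                 sum(width(fragments(sim$frags))))
    hAll <- S4Vectors::mcols(trackBins(pseudobulkTrack(sim$frags, 50)))$score
    h1 <- S4Vectors::mcols(trackBins(pseudobulkTrack(sim$frags, 50,
                                                     "H1")))$score
    h2 <- S4Vectors::mcols(trackBins(pseudobulkTrack(sim$frags, 50,
                                                     "H2")))$score
    gr <- fragments(sim$frags)
    un <- FragmentSet(gr[S4Vectors::mcols(gr)$haplotype == "UNPHASED"])
    hu <- S4Vectors::mcols(trackBins(pseudobulkTrack(un, 50)))$score
    expect_equal(h1 + h2 + hu, hAll, tolerance = 1e-12)
})

test_that("anchor-averaged profiles scale to 1 at -2000 bp and flip strands", {
    sl <- c(chr1 = 50000)
    # uniform coverage: tile the chromosome completely
    fs <- FragmentSet(makeFragGR("chr1", seq(1, 49851, 150) ,
                                 seq(150, 50000, 150), seqlengths = sl))
    sites <- GRanges("chr1", IRanges(25000, 25000), strand = "+")
    prof <- averageProfileAtSites(fs, sites, flank = 3000, bin = 10)
    expect_equal(prof$no[prof$offset == -2000], 1)
    expect_true(all(abs(prof$no - 1) < 1e-9))  # flat under uniform coverage

    # two anchors on opposite strands with mirrored coverage average to the
    # same profile as the hand-flipped computation
    gr <- c(makeFragGR("chr1", 10101, 10200, seqlengths = sl),   # +100 of a1
            makeFragGR("chr1", 29801, 29900, seqlengths = sl))   # -200..-101 of a2
    base <- FragmentSet(makeFragGR("chr1", seq(1, 49851, 150),
                                   seq(150, 50000, 150), seqlengths = sl))
    both <- FragmentSet(c(fragments(base), gr))
    anchors <- GRanges("chr1", IRanges(c(10000, 30000), c(10000, 30000)),
                       strand = c("+", "-"))
    prof2 <- averageProfileAtSites(both, anchors, flank = 1000, bin = 100,
                                   scale = FALSE)
    # a1 adds coverage at offsets +101..+200; a2's -199..-100 flips (minus
    # strand, half-open offsets o -> -o-1) to +99..+198. In the [100, 200)
    # bin each anchor doubles 99 of 100 bp: (99*2 + 1)/100 = 1.99 for both.
    bump <- prof2$no[prof2$offset == 100]
    expect_equal(bump, 1.99, tolerance = 1e-12)
    expect_equal(prof2$no[prof2$offset == -300], 1, tolerance = 1e-12)
    expect_error(averageProfileAtSites(fs, sites, flank = 1500),
                 "flank")
})

test_that("gene-body counts use half-open >= 1 bp interval overlap", {
    genes <- GRanges("chr1", IRanges(c(1001, 2001), c(2000, 3000)))
    names(genes) <- c("geneA", "geneB")
    # empty fragments -> zero matrix of the right shape
    none <- FragmentSet(makeFragGR("chr1", 1, 100)[0])
    expect_equal(dim(assay(geneBodyCounts(none, genes), "counts")),
                 c(2L, 0L))
    fs <- makeFrags("chr1",
                    start = c(950, 1990, 3100),
                    end = c(1001, 2160, 3250),  # 1st: 1 bp in geneA
                    cell = c("c1", "c1", "c2"))
    m <- assay(geneBodyCounts(fs, genes), "counts")
    expect_equal(m["geneA", "c1"], 2L)  # 1 bp overlap counts
    expect_equal(m["geneB", "c1"], 1L)  # spanning fragment counts in both
    expect_equal(sum(m[, "c2"]), 0L)
    expect_error(geneBodyCounts(fs, setNames(genes, c("g", "g"))),
                 "unique")
    # library size counts all retained fragments, in-gene or not
    expect_equal(colData(geneBodyCounts(fs, genes))$librarySize, c(2L, 1L),
                 ignore_attr = TRUE)
})

test_that("normalization composes CN, RPM and log2 steps correctly", {
    genes <- GRanges("chr1", IRanges(c(1, 1001), c(1000, 2000)))
    names(genes) <- c("gA", "gB")
    m <- matrix(c(50L, 10L, 20L, 8L), 2, 2,
                dimnames = list(c("gA", "gB"), c("c1", "c2")))
    se <- SummarizedExperiment(assays = list(counts = m), rowRanges = genes,
        colData = S4Vectors::DataFrame(librarySize = c(1e6, 2e5),
                                       row.names = c("c1", "c2")))
    # diploid CN step is the identity
    cn2 <- data.frame(scope = "germline", chrom = "chr1", start = 1,
                      end = 2000, haplotype = "BOTH", copy_number = 2)
    n1 <- assay(normalizeCounts(se, cn = cn2, steps = "cn"), "normalized")
    expect_equal(n1, m + 0, ignore_attr = TRUE)
    # CN = 4 halves the count before RPM
    cn4 <- data.frame(scope = "germline", chrom = "chr1", start = 1,
                      end = 2000, haplotype = "BOTH", copy_number = 4)
    n4 <- assay(normalizeCounts(se, cn = cn4, steps = "cn"), "normalized")
    expect_equal(n4, m / 2, ignore_attr = TRUE)
    # count 50 at library size 1e6 -> RPM 50; log2 adds the +1 pseudocount
    full <- assay(normalizeCounts(se, steps = c("rpm", "log2")),
                  "normalized")
    expect_equal(full["gA", "c1"], log2(51))
    # rpm+log2 is invertible up to the pseudocount
    rec <- sweep(2^full - 1, 2, c(1e6, 2e5), "*") / 1e6
    expect_equal(rec, m + 0, ignore_attr = TRUE, tolerance = 1e-9)
    # clone-scope CN overrides germline for that clone's cells
    cnC <- rbind(cn2, data.frame(scope = "cloneX", chrom = "chr1", start = 1,
                                 end = 1000, haplotype = "BOTH",
                                 copy_number = 1))
    nC <- assay(normalizeCounts(se, cn = cnC,
                                cloneOf = c(c1 = "cloneX", c2 = "ref"),
                                steps = "cn"), "normalized")
    expect_equal(nC["gA", "c1"], 100)  # 50 * 2/1
    expect_equal(nC["gA", "c2"], 20)   # germline diploid
    expect_message(normalizeCounts(se, cn = data.frame(scope = "germline",
        chrom = "chr1", start = 1, end = 2000, haplotype = "BOTH",
        copy_number = 0), steps = "cn"), "pseudo-CN")
})

test_that("batch adjustment equalizes batch means per gene", {
    m <- matrix(rnorm(40), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
    batch <- rep(c("b1", "b2"), each = 5)
    shifted <- m
    shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 3
    adj <- batchAdjust(shifted, batch)
    expect_equal(dim(adj), dim(m))
    for (g in 1:4)
        expect_equal(mean(adj[g, batch == "b1"]),
                     mean(adj[g, batch == "b2"]), tolerance = 1e-12)
    # single batch is the identity
    expect_equal(batchAdjust(m, rep("b1", 10)), m)
    expect_warning(batchAdjust(m, c(rep("b1", 9), "solo")), "fewer than 2")
})

test_that("track correlation is Spearman with average-rank ties", {
    expect_equal(correlateTracks(c(1, 3, 2, 5, 4), c(1, 3, 2, 5, 4)), 1)
    expect_equal(correlateTracks(1:5, 5:1), -1)
    a <- c(1, 2, 2, 4, 7)
    b <- c(3, 1, 5, 2, 4)
    # hand-ranked oracle with average ranks
    ra <- c(1, 2.5, 2.5, 4, 5)
    rb <- rank(b)
    oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
        sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    expect_equal(correlateTracks(a, b), oracle, tolerance = 1e-12)
    expect_warning(r <- correlateTracks(rep(1, 5), 1:5), "constant")
    expect_true(is.na(r))
    expect_error(correlateTracks(1:4, 1:5), "equal length")
})

test_that("bedGraph and count exports are well-formed", {
    fs <- FragmentSet(makeFragGR("chr1", 101, 160,
                                 seqlengths = c(chr1 = 200)))
    tr <- pseudobulkTrack(fs, 50)
    p <- tempfile(fileext = ".bedGraph")
    exportBedGraph(tr, p)
    ln <- readLines(p)
    expect_match(ln[1], "bedGraph")
    expect_equal(length(ln), 1 + length(trackBins(tr)))
    m <- matrix(c(0L, 3L, 1L, 0L), 2, 2,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
    files <- writeCounts(m, tempfile())
    expect_true(all(file.exists(files)))
    mtx <- readLines(files[2])
    expect_equal(mtx[2], "2 2 2")  # dims + nnz
})
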
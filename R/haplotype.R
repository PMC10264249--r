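# Haplotype-specific NO analysis: phased per-unit counts gated on the mixed
# (WC) template state, genome-wide Wilcoxon tests, +/-1 Mb scans around SV
# breakpoints, sliding-window binomial LRT profiles with permutation
# adjustment, exact binomial tests at CREs, and TAD-level KS outlier tests.

.wcCellsByChrom <- function(states) {
    st <- stateTable(states)
    split(st$cell[st$state == "WC"], st$chrom[st$state == "WC"])
}

#' Phased fragment counts per unit and cell
#'
#' Counts H1- and H2-tagged fragments overlapping each unit, restricted per
#' chromosome to cells in the mixed (WC) template state -- the only
#' configuration in which reads separate unambiguously onto homologs. Cells
#' whose chromosome is in a pure (WW/CC) state contribute zero. Per-unit
#' per-haplotype copy numbers used for normalization default to 1 and can be
#' supplied from a copy-number table.
#'
#' @param frags A \code{\link{FragmentSet}} with haplotype tags.
#' @param units Named \code{GRanges} (genes, windows or CREs).
#' @param states A \code{\link{StrandStateMap}}.
#' @param cnH1,cnH2 Per-unit haplotype copy numbers (recycled; default 1).
#' @return A \code{\link{HaplotypeCounts}}; a warning lists units on
#'   chromosomes absent from the state map (counted as zero).
#' @export
haplotypeUnitCounts <- function(frags, units, states, cnH1 = 1, cnH2 = 1) {
    stopifnot(is(frags, "FragmentSet"), is(units, "GRanges"),
              is(states, "StrandStateMap"))
    if (is.null(names(units)))
        names(units) <- sprintf("unit_%d", seq_along(units))
    cells <- cellIDs(frags)
    wc <- .wcCellsByChrom(states)
    known <- unique(stateTable(states)$chrom)
    uchr <- as.character(GenomicRanges::seqnames(units))
    if (any(!uchr %in% known))
        warning(sum(!uchr %in% known), " unit(s) on chromosomes absent from ",
                "the strand-state map; counted as zero")
    gr <- fragments(frags)
    mc <- S4Vectors::mcols(gr)
    fchr <- as.character(GenomicRanges::seqnames(gr))
    fcell <- as.character(mc$cell)
    st <- stateTable(states)
    wcKeys <- paste(st$cell, st$chrom)[st$state == "WC"]
    inWC <- paste(fcell, fchr) %in% wcKeys
    dims <- list(names(units), cells)
    zero <- matrix(0L, length(units), length(cells), dimnames = dims)
    h1 <- zero; h2 <- zero; tot <- zero
    if (any(inWC)) {
        sub <- gr[inWC]
        smc <- S4Vectors::mcols(sub)
        hits <- suppressWarnings(
            GenomicRanges::findOverlaps(units, sub, ignore.strand = TRUE))
        if (length(hits) > 0L) {
            ui <- S4Vectors::queryHits(hits)
            ci <- factor(as.character(smc$cell)[S4Vectors::subjectHits(hits)],
                         levels = cells)
            hp <- as.character(smc$haplotype)[S4Vectors::subjectHits(hits)]
            uf <- factor(ui, levels = seq_along(units))
            tot[] <- as.integer(table(uf, ci))
            h1[] <- as.integer(table(uf[hp == "H1"], ci[hp == "H1"]))
            h2[] <- as.integer(table(uf[hp == "H2"], ci[hp == "H2"]))
        }
    }
    new("HaplotypeCounts", units = units, h1 = h1, h2 = h2, total = tot,
        cnH1 = rep_len(as.numeric(cnH1), length(units)),
        cnH2 = rep_len(as.numeric(cnH2), length(units)),
        cells = cells)
}

#' Wilcoxon tests of haplotype-specific NO per unit
#'
#' For each unit, compares the per-cell copy-number-normalized H1 counts
#' against the per-cell H2 counts across informative cells (cells with at
#' least one phased fragment in the unit) with an unpaired two-sided
#' Wilcoxon rank-sum test, followed by BH correction. The effect size is
#' \code{log2((mean H1 + pc) / (mean H2 + pc))}; swapping H1 and H2 inverts
#' the fold change and leaves p unchanged. A paired signed-rank variant is
#' available via \code{paired = TRUE}.
#'
#' @param hc A \code{\link{HaplotypeCounts}}.
#' @param minCells Minimum informative cells per unit (default 5); units
#'   below it get \code{p = NA}.
#' @param pseudocount Added to both haplotype means for the fold change.
#' @param paired Use the paired signed-rank variant (default FALSE).
#' @param fdr BH significance threshold recorded (default 0.1).
#' @return data.frame: \code{unit_id, n_cells, mean_h1, mean_h2, log2fc,
#'   stat, p, q, significant}.
#' @export
testHaplotypeNo <- function(hc, minCells = 5L, pseudocount = 1,
                            paired = FALSE, fdr = 0.1) {
    stopifnot(is(hc, "HaplotypeCounts"))
    nUnits <- length(hc@units)
    res <- data.frame(unit_id = names(hc@units), n_cells = 0L,
                      mean_h1 = NA_real_, mean_h2 = NA_real_,
                      log2fc = NA_real_, stat = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    for (u in seq_len(nUnits)) {
        inf <- which(hc@h1[u, ] + hc@h2[u, ] > 0L)
        res$n_cells[u] <- length(inf)
        if (length(inf) < minCells) next
        x1 <- hc@h1[u, inf] / max(hc@cnH1[u], .Machine$double.eps)
        x2 <- hc@h2[u, inf] / max(hc@cnH2[u], .Machine$double.eps)
        res$mean_h1[u] <- mean(x1)
        res$mean_h2[u] <- mean(x2)
        res$log2fc[u] <- log2((mean(x1) + pseudocount) /
                              (mean(x2) + pseudocount))
        wt <- suppressWarnings(
            wilcox.test(x1, x2, paired = paired, alternative = "two.sided"))
        res$stat[u] <- unname(wt$statistic)
        res$p[u] <- wt$p.value
    }
    res$q <- p.adjust(res$p, method = "BH")
    res$significant <- !is.na(res$q) & res$q < fdr
    res
}

#' Scan for local effects of SVs on haplotype-specific gene activity
#'
#' Selects, for every SV breakpoint, the genes whose bodies overlap the
#' window [breakpoint - radius, breakpoint + radius] (default radius 1 Mb),
#' re-adjusts the genome-wide haplotype-test p-values by BH within the scan
#' set of each SV, and links significant genes to the SV.
#'
#' @param svs SV table: data.frame with \code{sv_id, chrom, start, end} and
#'   optionally \code{chrom2, pos2} for translocation partners.
#' @param results Genome-wide output of \code{\link{testHaplotypeNo}} whose
#'   \code{unit_id} values name entries of \code{genes}.
#' @param genes Named \code{GRanges} of gene bodies.
#' @param radius Scan radius in bp (default 1e6).
#' @param fdr BH threshold within each scan set (default 0.1).
#' @return data.frame: \code{sv_id, gene_id, distance_bp, log2fc, p, q_local,
#'   significant}; empty when \code{svs} is empty.
#' @export
localScan <- function(svs, results, genes, radius = 1e6, fdr = 0.1) {
    empty <- data.frame(sv_id = character(), gene_id = character(),
                        distance_bp = numeric(), log2fc = numeric(),
                        p = numeric(), q_local = numeric(),
                        significant = logical(), stringsAsFactors = FALSE)
    if (is.null(svs) || nrow(svs) == 0L) return(empty)
    out <- list()
    for (r in seq_len(nrow(svs))) {
        bps <- data.frame(chrom = c(svs$chrom[r], svs$chrom[r]),
                          pos = c(svs$start[r], svs$end[r]))
        if (!is.null(svs$chrom2) && !is.na(svs$chrom2[r]))
            bps <- rbind(bps, data.frame(chrom = svs$chrom2[r],
                                         pos = svs$pos2[r]))
        win <- GenomicRanges::GRanges(bps$chrom,
            IRanges::IRanges(pmax(1, bps$pos - radius), bps$pos + radius))
        hit <- GenomicRanges::findOverlaps(genes, win, ignore.strand = TRUE)
        gi <- unique(S4Vectors::queryHits(hit))
        if (length(gi) == 0L) next
        ids <- names(genes)[gi]
        sub <- results[match(ids, results$unit_id), , drop = FALSE]
        sub <- sub[!is.na(sub$p), , drop = FALSE]
        if (nrow(sub) == 0L) next
        gsel <- genes[sub$unit_id]
        mid <- (GenomicRanges::start(gsel) + GenomicRanges::end(gsel)) / 2
        dist <- vapply(mid, function(x) min(abs(x - bps$pos)), numeric(1))
        out[[length(out) + 1L]] <- data.frame(
            sv_id = svs$sv_id[r], gene_id = sub$unit_id,
            distance_bp = dist, log2fc = sub$log2fc, p = sub$p,
            q_local = p.adjust(sub$p, method = "BH"),
            stringsAsFactors = FALSE)
    }
    if (length(out) == 0L) return(empty)
    res <- do.call(rbind, out)
    res$significant <- res$q_local < fdr
    res
}

# Binomial LRT of H1 proportion against p0; 0 * log(0) = 0.
.binomLRT <- function(n1, n2, p0) {
    n <- n1 + n2
    term <- function(k, e) if (k == 0L) 0 else k * log(k / e)
    2 * (term(n1, n * p0) + term(n2, n * (1 - p0)))
}

.windowFC <- function(n1, n2) {
    if (n1 > 0L && n2 > 0L) n1 / n2 else (n1 + 1) / (n2 + 1)
}

#' Sliding-window haplotype-specific NO profile around a breakpoint
#'
#' Tiles the region with windows (default 50 kb, step 10 kb), pools phased
#' fragment counts (n_H1, n_H2) per window from WC-state cells, and tests
#' each window's H1 proportion against \code{p0} with a binomial likelihood
#' ratio test (chi-square, 1 df, analytic p). The analytic p is adjusted by
#' permutation: haplotype labels of all phased fragments in the region are
#' shuffled (per-window totals preserved) \code{nPerm} times and
#' \code{p_adj = (1 + #\{perm LRT >= observed\}) / (nPerm + 1)} per window.
#' The fold change is \code{n_H1 / n_H2} (pseudocount 1 on both only when a
#' count is zero). Windows with no phased fragments yield NA rows.
#'
#' @param frags A \code{\link{FragmentSet}}.
#' @param states A \code{\link{StrandStateMap}}.
#' @param region \code{GRanges} of length 1 bounding the scan (for example
#'   breakpoint to the nearest TAD boundary, or a fixed span).
#' @param window,step Window size and step in bp (window >= step).
#' @param p0 Expected H1 proportion under no effect (default 0.5; set from
#'   copy number when the locus is CN-imbalanced).
#' @param nPerm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return data.frame (window profile): \code{chrom, start, end, n_h1, n_h2,
#'   fc, lrt, p_analytic, p_adjusted}.
#' @export
slidingWindowScan <- function(frags, states, region, window = 50000L,
                              step = 10000L, p0 = 0.5, nPerm = 1000L,
                              seed = 1L) {
    stopifnot(length(region) == 1L, window >= step, step >= 1L)
    chrom <- as.character(GenomicRanges::seqnames(region))
    lo <- GenomicRanges::start(region); hi <- GenomicRanges::end(region)
    startsW <- seq(lo, max(lo, hi - window + 1L), by = step)
    wins <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(startsW, pmin(startsW + window - 1L, hi)))
    names(wins) <- sprintf("win_%04d", seq_along(wins))

    gr <- fragments(frags)
    mc <- S4Vectors::mcols(gr)
    wc <- .wcCellsByChrom(states)
    phased <- gr[as.character(mc$haplotype) %in% c("H1", "H2") &
                 as.character(GenomicRanges::seqnames(gr)) == chrom &
                 as.character(mc$cell) %in% wc[[chrom]]]
    phased <- IRanges::subsetByOverlaps(phased, region, ignore.strand = TRUE)
    hp <- as.character(S4Vectors::mcols(phased)$haplotype)

    ov <- GenomicRanges::findOverlaps(wins, phased, ignore.strand = TRUE)
    wIdx <- S4Vectors::queryHits(ov); fIdx <- S4Vectors::subjectHits(ov)
    countWin <- function(labels) {
        isH1 <- labels[fIdx] == "H1"
        n1 <- tabulate(wIdx[isH1], nbins = length(wins))
        n2 <- tabulate(wIdx[!isH1], nbins = length(wins))
        cbind(n1, n2)
    }
    obs <- countWin(hp)
    lrt <- vapply(seq_along(wins), function(i)
        .binomLRT(obs[i, 1L], obs[i, 2L], p0), numeric(1))
    set.seed(seed)
    geCount <- rep(1L, length(wins))
    for (b in seq_len(nPerm)) {
        perm <- countWin(sample(hp))
        plrt <- vapply(seq_along(wins), function(i)
            .binomLRT(perm[i, 1L], perm[i, 2L], p0), numeric(1))
        geCount <- geCount + as.integer(plrt >= lrt)
    }
    pAdj <- geCount / (nPerm + 1L)
    nTot <- obs[, 1L] + obs[, 2L]
    res <- data.frame(chrom = chrom, start = GenomicRanges::start(wins),
                      end = GenomicRanges::end(wins),
                      n_h1 = obs[, 1L], n_h2 = obs[, 2L],
                      fc = vapply(seq_along(wins), function(i)
                          .windowFC(obs[i, 1L], obs[i, 2L]), numeric(1)),
                      lrt = lrt,
                      p_analytic = pchisq(lrt, df = 1L, lower.tail = FALSE),
                      p_adjusted = pAdj)
    res[nTot == 0L, c("fc", "lrt", "p_analytic", "p_adjusted")] <- NA_real_
    res
}

#' Exact binomial tests of haplotype-specific NO at CREs
#'
#' Pools phased fragment counts (n_H1, n_H2) per CRE from WC-state cells and
#' tests the H1 count against the copy-number expectation
#' \code{p0 = cnH1 / (cnH1 + cnH2)} with a two-sided exact binomial test,
#' followed by BH correction at the given FDR.
#'
#' @param frags A \code{\link{FragmentSet}}.
#' @param cres Named \code{GRanges} of CRE intervals (user-provided, from
#'   the cell type of interest).
#' @param states A \code{\link{StrandStateMap}}.
#' @param cnH1,cnH2 Locus copy number of each haplotype (default 1 and 1).
#' @param fdr BH threshold (default 0.1).
#' @return data.frame: \code{cre_id, n_h1, n_h2, fc, p, q, significant};
#'   CREs with no phased fragments yield NA rows.
#' @export
creExactTest <- function(frags, cres, states, cnH1 = 1L, cnH2 = 1L,
                         fdr = 0.1) {
    stopifnot(cnH1 + cnH2 > 0)
    hc <- haplotypeUnitCounts(frags, cres, states, cnH1 = cnH1, cnH2 = cnH2)
    n1 <- rowSums(hc@h1); n2 <- rowSums(hc@h2)
    p0 <- cnH1 / (cnH1 + cnH2)
    p <- rep(NA_real_, length(cres))
    for (i in seq_along(cres)) {
        n <- n1[i] + n2[i]
        if (n == 0L) next
        p[i] <- binom.test(n1[i], n, p = p0,
                           alternative = "two.sided")$p.value
    }
    res <- data.frame(cre_id = names(cres), n_h1 = unname(n1),
                      n_h2 = unname(n2),
                      fc = vapply(seq_along(cres), function(i)
                          .windowFC(n1[i], n2[i]), numeric(1)),
                      p = p, q = p.adjust(p, method = "BH"),
                      stringsAsFactors = FALSE)
    res$fc[n1 + n2 == 0L] <- NA_real_
    res$significant <- !is.na(res$q) & res$q < fdr
    res
}

#' TAD-level outlier test on a haplotype-specific window profile
#'
#' For each TAD covered by the sliding-window profile, compares the log fold
#' changes of windows inside the TAD against those of windows in all other
#' TADs on the same derivative chromosome with a two-sample Kolmogorov-
#' Smirnov test. TADs with fewer than 3 informative windows yield NA.
#'
#' @param profile Output of \code{\link{slidingWindowScan}}.
#' @param tads Named \code{GRanges} of TADs.
#' @return data.frame: \code{tad_id, n_windows, D, p, q}.
#' @export
tadOutlierTest <- function(profile, tads) {
    ok <- !is.na(profile$fc)
    winMid <- (profile$start + profile$end) / 2
    midGr <- GenomicRanges::GRanges(profile$chrom,
        IRanges::IRanges(winMid, winMid))
    hit <- GenomicRanges::findOverlaps(midGr, tads, ignore.strand = TRUE)
    tadOf <- rep(NA_character_, nrow(profile))
    tadOf[S4Vectors::queryHits(hit)] <- names(tads)[S4Vectors::subjectHits(hit)]
    lfc <- log(profile$fc)
    covered <- unique(tadOf[ok & !is.na(tadOf)])
    if (length(covered) < 2L)
        stop("need windows in at least 2 TADs")
    res <- data.frame(tad_id = covered, n_windows = NA_integer_,
                      D = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_along(covered)) {
        inT <- ok & !is.na(tadOf) & tadOf == covered[i]
        outT <- ok & !is.na(tadOf) & tadOf != covered[i]
        res$n_windows[i] <- sum(inT)
        if (sum(inT) < 3L || sum(outT) < 3L) next
        kt <- suppressWarnings(ks.test(lfc[inT], lfc[outT]))
        res$D[i] <- unname(kt$statistic)
        res$p[i] <- kt$p.value
    }
    res$q <- p.adjust(res$p, method = "BH")
    res
}
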
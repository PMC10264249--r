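# Shared fixture builders: in-memory fragment sets, fragment TSVs and tiny
# genomes, all constructed programmatically.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# Vectorized fragment GRanges; W maps to "-", C to "+".
makeFragGR <- function(chrom, start, end, cell = "cell1", strand = "C",
                       haplotype = "UNPHASED", mapq = 60L, dup = FALSE,
                       suppl = FALSE, seqlengths = NULL) {
    n <- max(lengths(list(chrom, start, end, cell, strand, haplotype)))
    gr <- GRanges(rep_len(chrom, n),
                  IRanges(start = rep_len(start, n), end = rep_len(end, n)),
                  strand = ifelse(rep_len(strand, n) == "W", "-", "+"),
                  cell = rep_len(cell, n),
                  haplotype = rep_len(haplotype, n),
                  mapq = rep_len(as.integer(mapq), n),
                  isDuplicate = rep_len(dup, n),
                  isSupplementary = rep_len(suppl, n))
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    gr
}

makeFrags <- function(...) FragmentSet(makeFragGR(...))

# Write records in the on-disk fragment dialect (0-based half-open).
writeFragTSV <- function(df, path = tempfile(fileext = ".tsv")) {
    cols <- c("chrom", "start", "end", "cell", "strand", "haplotype",
              "mapq", "dup", "suppl")
    for (cn in cols) if (is.null(df[[cn]]))
        df[[cn]] <- rep(switch(cn, haplotype = ".", mapq = 60L, dup = 0L,
                               suppl = 0L, stop("missing column ", cn)),
                        length.out = nrow(df))
    write.table(df[, cols], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    path
}

# A StrandStateMap declaring given states directly (bypasses classification).
makeStates <- function(cell, chrom, state) {
    n <- max(lengths(list(cell, chrom, state)))
    st <- S4Vectors::DataFrame(cell = rep_len(cell, n),
                               chrom = rep_len(chrom, n),
                               state = rep_len(state, n),
                               watson_fraction = rep(0.5, n),
                               n_fragments = rep(100L, n))
    new("StrandStateMap", states = st,
        params = list(min_fragments = 1L, upper = 0.8, lower = 0.2))
}

# Rank-based one-vs-rest AUC for a single score vector (independent of the
# package's aucMacro).
rankAUC <- function(score, positive) {
    r <- rank(score)
    n1 <- sum(positive); n0 <- sum(!positive)
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
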
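# Pseudobulk nucleosome-occupancy tracks, anchor-averaged profiles and track
# correlation. NO is mean per-bp fragment coverage; the bin statistic is the
# mean (not the sum), and no peak calling or smoothing is applied.

.fragSeqlengths <- function(gr) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (length(sl) == 0L) return(sl)
    if (any(is.na(sl))) {
        mx <- vapply(GenomeInfoDb::seqlevels(gr), function(ch) {
            sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
            if (length(sub) == 0L) 1L else max(GenomicRanges::end(sub))
        }, numeric(1))
        sl[is.na(sl)] <- mx[is.na(sl)]
    }
    sl
}

.haplotypeSubset <- function(frags, haplotypeFilter) {
    gr <- fragments(frags)
    if (haplotypeFilter != "ALL")
        gr <- gr[S4Vectors::mcols(gr)$haplotype == haplotypeFilter]
    gr
}

#' Build a binned pseudobulk NO track
#'
#' Pools fragments (optionally restricted to one haplotype) and computes,
#' for each fixed-size bin, the mean over its base pairs of the number of
#' fragments covering that base pair.
#'
#' @param frags A \code{\link{FragmentSet}}.
#' @param binSize Bin width in bp (default 10).
#' @param haplotypeFilter \code{"ALL"} (default), \code{"H1"} or \code{"H2"}.
#' @return An \code{\link{NOTrack}}.
#' @export
pseudobulkTrack <- function(frags, binSize = 10L,
                            haplotypeFilter = c("ALL", "H1", "H2")) {
    haplotypeFilter <- match.arg(haplotypeFilter)
    stopifnot(binSize >= 1L)
    gr <- .haplotypeSubset(frags, haplotypeFilter)
    sl <- .fragSeqlengths(fragments(frags))
    if (length(sl) == 0L)
        return(new("NOTrack", bins = GenomicRanges::GRanges(),
                   binSize = as.numeric(binSize),
                   haplotypeFilter = haplotypeFilter, nFragmentsUsed = 0L))
    tiles <- GenomicRanges::tileGenome(sl, tilewidth = binSize,
                                       cut.last.tile.in.chrom = TRUE)
    cov <- GenomicRanges::coverage(gr, width = sl)
    bins <- GenomicRanges::binnedAverage(tiles, cov, "score")
    new("NOTrack", bins = bins, binSize = as.numeric(binSize),
        haplotypeFilter = haplotypeFilter, nFragmentsUsed = length(gr))
}

#' Averaged NO profile around anchor sites
#'
#' Computes per-bp coverage in a window of \code{flank} bp on each side of
#' every anchor center, flips windows of minus-strand anchors, averages
#' across anchors and bins the result. By the usual convention for averaged
#' nucleosome profiles around bound CTCF sites, the profile is scaled so the
#' bin at offset \code{scaleAt} (default -2000 bp) equals 1.
#'
#' @param frags A \code{\link{FragmentSet}}.
#' @param sites Anchors as a \code{GRanges} (strand used for flipping); the
#'   anchor point is the midpoint of each range.
#' @param flank Half-window size in bp; must cover \code{abs(scaleAt)} when
#'   scaling.
#' @param bin Bin width in bp.
#' @param scale Scale so the \code{scaleAt} bin equals 1 (default TRUE).
#' @param scaleAt Offset (bp, relative to the anchor) of the reference bin.
#' @return A data.frame with columns \code{offset} (bin start, bp relative
#'   to anchor) and \code{no}.
#' @export
averageProfileAtSites <- function(frags, sites, flank = 3000L, bin = 10L,
                                  scale = TRUE, scaleAt = -2000L) {
    stopifnot(length(sites) > 0L, flank >= 1L, bin >= 1L)
    if (scale && flank < abs(scaleAt))
        stop("flank must be >= ", abs(scaleAt), " bp to scale at ", scaleAt)
    gr <- fragments(frags)
    sl <- .fragSeqlengths(gr)
    cov <- GenomicRanges::coverage(gr, width = sl)
    width <- 2L * as.integer(flank)
    acc <- numeric(width)
    centers <- (GenomicRanges::start(sites) + GenomicRanges::end(sites)) %/% 2L
    chroms <- as.character(GenomicRanges::seqnames(sites))
    strands <- as.character(GenomicRanges::strand(sites))
    for (i in seq_along(sites)) {
        ch <- chroms[i]
        if (!ch %in% names(cov)) next
        v <- cov[[ch]]
        lo <- centers[i] - flank
        idx <- lo:(lo + width - 1L)
        w <- numeric(width)
        ok <- idx >= 1L & idx <= length(v)
        if (any(ok)) w[ok] <- as.numeric(v[idx[ok]])
        if (strands[i] == "-") w <- rev(w)
        acc <- acc + w
    }
    prof <- acc / length(sites)
    nb <- width %/% bin
    binned <- vapply(seq_len(nb), function(b)
        mean(prof[((b - 1L) * bin + 1L):(b * bin)]), numeric(1))
    offsets <- (seq_len(nb) - 1L) * bin - flank
    if (scale) {
        ref <- binned[(scaleAt + flank) %/% bin + 1L]
        if (!is.finite(ref) || ref == 0)
            stop("cannot scale: zero coverage in the ", scaleAt, " bp bin")
        binned <- binned / ref
    }
    data.frame(offset = offsets, no = binned)
}

#' Rank correlation between two NO tracks or site-level vectors
#'
#' Spearman correlation with average ranks for ties, for comparing
#' uniformity/positioning between two assays at matched bins or sites.
#'
#' @param a,b \code{\link{NOTrack}} objects (matched bins) or numeric
#'   vectors of equal length.
#' @return Spearman's rho, or \code{NA} (with a warning) when either input
#'   is constant.
#' @export
correlateTracks <- function(a, b) {
    va <- if (is(a, "NOTrack")) S4Vectors::mcols(trackBins(a))$score else a
    vb <- if (is(b, "NOTrack")) S4Vectors::mcols(trackBins(b))$score else b
    if (length(va) != length(vb))
        stop("tracks must have equal length (", length(va), " vs ",
             length(vb), ")")
    ok <- is.finite(va) & is.finite(vb)
    if (sum(ok) < 3L) stop("need at least 3 informative entries")
    if (sd(va[ok]) == 0 || sd(vb[ok]) == 0) {
        warning("constant input: rank correlation undefined")
        return(NA_real_)
    }
    cor(va[ok], vb[ok], method = "spearman")
}

#' Export an NO track as bedGraph
#' @param track An \code{\link{NOTrack}}.
#' @param path Output path.
#' @param name Track name for the header line.
#' @return Invisibly, the path.
#' @export
exportBedGraph <- function(track, path, name = "NO") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("bedGraph output requires the rtracklayer package")
    bins <- trackBins(track)
    rtracklayer::export(bins, path, format = "bedGraph",
        trackLine = methods::new("GraphTrackLine", type = "bedGraph",
                                 name = name))
    invisible(path)
}
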
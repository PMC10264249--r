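#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   coverage findOverlaps countOverlaps tileGenome binnedAverage reduce
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny pintersect
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqlengths<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowRanges
#' @importFrom stats p.adjust pchisq pnorm quantile median sd var cor rnorm
#'   runif rbinom rnbinom rpois rmultinom binom.test wilcox.test ks.test
#'   fisher.test phyper glm glm.fit binomial coef predict logLik lm setNames
#'   complete.cases qnorm
#' @importFrom utils read.delim write.table head tail
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' FragmentSet: QC-filtered single-cell mono-nucleosomal fragments
#'
#' Container for Strand-seq-style fragment records. Each fragment is the full
#' paired-end insert interval of one sequenced mono-nucleosomal fragment,
#' stored as a \code{GRanges} (0-based half-open intervals are used on disk;
#' in memory the usual 1-based \code{GRanges} convention applies and all
#' conversions happen at the I/O boundary). Genome strand encodes the
#' template-strand letter: Crick (C) reads map to \code{+}, Watson (W) reads
#' to \code{-}.
#'
#' Metadata columns: \code{cell} (cell identifier), \code{haplotype}
#' (\code{"H1"}, \code{"H2"} or \code{"UNPHASED"}), \code{mapq},
#' \code{isDuplicate}, \code{isSupplementary}.
#'
#' @slot fragments A \code{GRanges} with the metadata columns above.
#' @slot provenance A list logging the filters applied and per-category
#'   numbers of dropped records.
#'
#' @export
setClass("FragmentSet",
    slots = c(fragments = "GRanges", provenance = "list"),
    prototype = prototype(fragments = GenomicRanges::GRanges(),
                          provenance = list()))

setValidity("FragmentSet", function(object) {
    gr <- object@fragments
    need <- c("cell", "haplotype", "mapq", "isDuplicate", "isSupplementary")
    miss <- setdiff(need, colnames(S4Vectors::mcols(gr)))
    if (length(miss) > 0L)
        return(paste("missing fragment metadata columns:",
                     paste(miss, collapse = ", ")))
    if (length(gr) > 0L) {
        if (any(GenomicRanges::width(gr) < 1L))
            return("all fragments must have positive length")
        hp <- as.character(S4Vectors::mcols(gr)$haplotype)
        if (!all(hp %in% c("H1", "H2", "UNPHASED")))
            return("haplotype must be H1, H2 or UNPHASED")
        if (any(S4Vectors::mcols(gr)$mapq < 0L))
            return("mapq must be >= 0")
        if (!all(as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
            return("fragment strand must be + (Crick) or - (Watson)")
    }
    TRUE
})

#' StrandStateMap: per-cell, per-chromosome template-strand states
#'
#' Holds the classified template-strand configuration for every
#' (cell, chromosome) pair: \code{WW} or \code{CC} (pure states, both
#' homologs inherited the same template strand) or \code{WC} (mixed state,
#' one homolog each, the configuration that permits direct haplotype
#' separation of reads), or \code{UNKNOWN} when too few fragments were seen.
#' The two mixed orientations (WC and CW) are collapsed: downstream logic
#' only needs mixed-versus-pure, and homolog orientation travels with the
#' haplotype tags.
#'
#' @slot states A \code{DataFrame} with columns \code{cell}, \code{chrom},
#'   \code{state}, \code{watson_fraction}, \code{n_fragments}.
#' @slot params The thresholds used (\code{min_fragments}, \code{upper},
#'   \code{lower}).
#'
#' @export
setClass("StrandStateMap",
    slots = c(states = "DataFrame", params = "list"))

setValidity("StrandStateMap", function(object) {
    st <- object@states
    need <- c("cell", "chrom", "state", "watson_fraction", "n_fragments")
    if (!all(need %in% colnames(st)))
        return(paste("states must have columns:", paste(need, collapse = ", ")))
    if (nrow(st) > 0L) {
        if (!all(st$state %in% c("WW", "CC", "WC", "UNKNOWN")))
            return("state must be one of WW, CC, WC, UNKNOWN")
        wf <- st$watson_fraction
        ok <- is.na(wf) | (wf >= 0 & wf <= 1)
        if (!all(ok)) return("watson_fraction must lie in [0, 1]")
        mf <- object@params$min_fragments
        if (!is.null(mf) &&
            any(st$state != "UNKNOWN" & st$n_fragments < mf))
            return("non-UNKNOWN state with fewer than min_fragments fragments")
    }
    TRUE
})

#' NOTrack: binned pseudobulk nucleosome-occupancy track
#'
#' Mean per-bp fragment coverage in fixed-size bins, the operational
#' definition of nucleosome occupancy used throughout the package.
#'
#' @slot bins A \code{GRanges} tiling the genome, with metadata column
#'   \code{score} holding the mean per-bp coverage of each bin.
#' @slot binSize Bin width in bp.
#' @slot haplotypeFilter \code{"ALL"}, \code{"H1"} or \code{"H2"}.
#' @slot nFragmentsUsed Number of fragments that contributed.
#'
#' @export
setClass("NOTrack",
    slots = c(bins = "GRanges", binSize = "numeric",
              haplotypeFilter = "character", nFragmentsUsed = "integer"))

setValidity("NOTrack", function(object) {
    if (length(object@binSize) != 1L || object@binSize < 1)
        return("binSize must be a single value >= 1")
    if (!object@haplotypeFilter %in% c("ALL", "H1", "H2"))
        return("haplotypeFilter must be ALL, H1 or H2")
    if (length(object@bins) > 0L) {
        sc <- S4Vectors::mcols(object@bins)$score
        if (is.null(sc)) return("bins must carry a 'score' column")
        if (any(sc < 0)) return("coverage scores must be >= 0")
    }
    TRUE
})

#' PLSDAModel: partial least squares discriminant analysis fit
#'
#' A NIPALS PLS2 fit of dummy-coded class labels on standardized features,
#' used both for cell typing from gene-body NO and for the low-clonal-
#' frequency alternative differential-activity mode (via VIP scores).
#'
#' @slot weights Feature-by-component weight matrix W (columns unit norm).
#' @slot loadings Feature-by-component X-loading matrix P.
#' @slot yloadings Class-by-component Y-loading matrix Q.
#' @slot coefficients Regression coefficients B mapping standardized X to
#'   centered dummy Y.
#' @slot ssY Per-component explained response sum of squares (used by VIP).
#' @slot classes Class levels, in dummy-column order.
#' @slot xCenter,xScale Training standardization parameters (reused verbatim
#'   at prediction so there is no leakage).
#' @slot yCenter Dummy-column means.
#' @slot featureNames Features the model was fit on, in order.
#' @slot selectedFeatures Feature subset retained by VIP selection (or NULL).
#' @slot nComponents Number of latent components actually fit.
#'
#' @export
setClass("PLSDAModel",
    slots = c(weights = "matrix", loadings = "matrix", yloadings = "matrix",
              coefficients = "matrix", ssY = "numeric", classes = "character",
              xCenter = "numeric", xScale = "numeric", yCenter = "numeric",
              featureNames = "character", selectedFeatures = "characterOrNULL",
              nComponents = "integer"))

setValidity("PLSDAModel", function(object) {
    if (ncol(object@weights) != object@nComponents)
        return("weights must have one column per component")
    if (!is.null(object@selectedFeatures) &&
        !all(object@selectedFeatures %in% object@featureNames))
        return("selectedFeatures must be a subset of featureNames")
    TRUE
})

#' NEModel: not-expressed gene classifier
#'
#' Classifier returning, for each gene in a clone, the probability that the
#' gene is not expressed (NE), from binned gene-body NO, per-bin GC and log
#' gene length. Genes with P(NE) at or above the decision threshold in every
#' clone are filtered out before differential testing. The default engine is
#' a ridge-regularized logistic model; an unregularized logistic fit is
#' available via \code{method = "logistic"}.
#'
#' @slot method \code{"ridge"} or \code{"logistic"}.
#' @slot fit The fitted engine object.
#' @slot center,scale Feature standardization parameters.
#' @slot threshold NE decision threshold (default 0.9).
#' @slot featureNames Feature column names used at training.
#'
#' @export
setClass("NEModel",
    slots = c(method = "character", fit = "ANY", center = "numeric",
              scale = "numeric", threshold = "numeric",
              featureNames = "character"))

setValidity("NEModel", function(object) {
    if (object@threshold < 0 || object@threshold > 1)
        return("threshold must lie in [0, 1]")
    if (!object@method %in% c("ridge", "logistic"))
        return("method must be 'ridge' or 'logistic'")
    TRUE
})

#' HaplotypeCounts: phased per-unit, per-cell fragment counts
#'
#' Haplotype-resolved fragment counts for a set of genomic units (genes,
#' windows or CREs), restricted to cells whose chromosome is in the mixed
#' (WC) template state -- the configuration in which reads separate cleanly
#' onto homologs. Copy-number factors used for normalization are attached.
#'
#' @slot units \code{GRanges} of the counted units (names = unit ids).
#' @slot h1,h2 Integer matrices (units x cells) of phased counts.
#' @slot total Integer matrix of all fragments (phased + unphased) from
#'   WC-state cells overlapping each unit.
#' @slot cnH1,cnH2 Per-unit copy number of each haplotype (default 1).
#' @slot cells Cell identifiers (column order of the matrices).
#'
#' @export
setClass("HaplotypeCounts",
    slots = c(units = "GRanges", h1 = "matrix", h2 = "matrix",
              total = "matrix", cnH1 = "numeric", cnH2 = "numeric",
              cells = "character"))

setValidity("HaplotypeCounts", function(object) {
    d <- dim(object@h1)
    if (!identical(d, dim(object@h2)) || !identical(d, dim(object@total)))
        return("h1, h2 and total must share dimensions")
    if (d[1] != length(object@units))
        return("one matrix row per unit required")
    if (d[2] != length(object@cells))
        return("one matrix column per cell required")
    if (any(object@h1 + object@h2 > object@total))
        return("phased counts cannot exceed total counts")
    if (any(object@cnH1 < 0) || any(object@cnH2 < 0))
        return("copy numbers must be >= 0")
    TRUE
})
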
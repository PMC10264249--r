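#' Extract the fragment GRanges from a FragmentSet
#' @param x A \code{FragmentSet}.
#' @return A \code{GRanges} with fragment metadata columns.
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' Cell identifiers present in an object
#' @param x A \code{FragmentSet} or \code{HaplotypeCounts}.
#' @return Character vector of cell ids.
#' @export
setGeneric("cellIDs", function(x) standardGeneric("cellIDs"))

#' Filter provenance log
#' @param x A \code{FragmentSet}.
#' @return A list describing the filters applied and records dropped.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Strand-state table
#' @param x A \code{StrandStateMap}.
#' @return A \code{DataFrame} with one row per (cell, chromosome).
#' @export
setGeneric("stateTable", function(x) standardGeneric("stateTable"))

#' Binned coverage of an NO track
#' @param x An \code{NOTrack}.
#' @return A \code{GRanges} of bins with a \code{score} column.
#' @export
setGeneric("trackBins", function(x) standardGeneric("trackBins"))

#' Variable importance in projection (VIP) scores
#'
#' VIP for feature g over A components is
#' \code{sqrt(G * sum_a(w_ga^2 * SS_a) / sum_a(SS_a))} with G the number of
#' features, w the unit-norm PLS weights and SS_a the response sum of squares
#' explained by component a. VIP scores always satisfy
#' \code{sum(vip^2) == G}.
#'
#' @param object A fitted \code{PLSDAModel}.
#' @return Named numeric vector of VIP scores, one per feature.
#' @export
setGeneric("vip", function(object) standardGeneric("vip"))

setMethod("fragments", "FragmentSet", function(x) x@fragments)
setMethod("cellIDs", "FragmentSet",
          function(x) sort(unique(as.character(S4Vectors::mcols(x@fragments)$cell))))
setMethod("provenance", "FragmentSet", function(x) x@provenance)
setMethod("stateTable", "StrandStateMap", function(x) x@states)
setMethod("trackBins", "NOTrack", function(x) x@bins)
setMethod("cellIDs", "HaplotypeCounts", function(x) x@cells)

#' @export
setMethod("length", "FragmentSet", function(x) length(x@fragments))

setMethod("show", "FragmentSet", function(object) {
    cat("FragmentSet with", length(object@fragments), "fragments from",
        length(cellIDs(object)), "cells\n")
    dropped <- object@provenance$dropped
    if (!is.null(dropped))
        cat("  dropped at QC:", paste(names(dropped), unlist(dropped),
            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "StrandStateMap", function(object) {
    tab <- table(object@states$state)
    cat("StrandStateMap:", nrow(object@states), "(cell, chrom) entries (",
        paste(names(tab), tab, sep = ":", collapse = " "), ")\n")
})

setMethod("show", "NOTrack", function(object) {
    cat("NOTrack:", length(object@bins), "bins of", object@binSize,
        "bp (haplotype:", object@haplotypeFilter, ";",
        object@nFragmentsUsed, "fragments)\n")
})

setMethod("show", "PLSDAModel", function(object) {
    cat("PLSDAModel:", length(object@classes), "classes,",
        length(object@featureNames), "features,",
        object@nComponents, "components\n")
    if (!is.null(object@selectedFeatures))
        cat("  selected features:", length(object@selectedFeatures), "\n")
})

setMethod("show", "NEModel", function(object) {
    cat("NEModel (", object@method, "):", length(object@featureNames),
        "features, NE threshold", object@threshold, "\n")
})

setMethod("show", "HaplotypeCounts", function(object) {
    cat("HaplotypeCounts:", length(object@units), "units x",
        length(object@cells), "cells;",
        sum(object@h1), "H1 and", sum(object@h2), "H2 fragments\n")
})
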
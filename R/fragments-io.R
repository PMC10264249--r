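# Fragment ingestion, QC filtering, strand-state classification, blacklists.
#
# On-disk dialect is BED-like (0-based half-open); in memory everything is a
# 1-based GRanges. Watson (W) reads carry genome strand "-", Crick (C) "+".

.FRAGMENT_COLS <- c("chrom", "start", "end", "cell", "strand", "haplotype",
                    "mapq", "dup", "suppl")

.asFragmentGRanges <- function(df, seqlengths = NULL) {
    hp <- as.character(df$haplotype)
    hp[is.na(hp) | hp == "." | hp == ""] <- "UNPHASED"
    gr <- GenomicRanges::GRanges(
        seqnames = as.character(df$chrom),
        ranges = IRanges::IRanges(start = as.integer(df$start) + 1L,
                                  end = as.integer(df$end)),
        strand = ifelse(df$strand == "W", "-", "+"),
        cell = as.character(df$cell),
        haplotype = hp,
        mapq = as.integer(df$mapq),
        isDuplicate = as.logical(df$dup),
        isSupplementary = as.logical(df$suppl))
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    gr
}

#' Read and QC-filter single-cell fragment records
#'
#' Reads mono-nucleosomal fragment records from the tab-separated fragment
#' dialect (header required, columns \code{chrom, start, end, cell,
#' strand(W|C), haplotype(H1|H2|.), mapq, dup(0|1), suppl(0|1)}; coordinates
#' 0-based half-open) or from a BAM file, and removes low-quality records:
#' mapping quality below \code{mapqMin} (default 10), duplicates and
#' supplementary alignments. Counts of dropped records per category are kept
#' in the provenance log.
#'
#' For BAM input (requires \pkg{Rsamtools}) the fragment interval is the full
#' paired-end insert of the first mate of each proper pair; the cell id is
#' taken from the \code{CB} tag falling back to the read group, the haplotype
#' from the \code{HP} tag (1 = H1, 2 = H2, absent = UNPHASED), and
#' duplicate/supplementary status from the FLAG field.
#'
#' @param path Path to a fragment TSV or BAM file.
#' @param mapqMin Minimum mapping quality retained (records with
#'   \code{mapq < mapqMin} are dropped).
#' @param dropDuplicates,dropSupplementary Drop flagged records (default TRUE).
#' @param format \code{"auto"} (by file extension), \code{"tsv"} or
#'   \code{"bam"}.
#' @param seqlengths Optional named vector of chromosome lengths.
#' @return A \code{\link{FragmentSet}}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tstart\tend\tcell\tstrand\thaplotype\tmapq\tdup\tsuppl",
#'              "chr1\t100\t260\tcellA\tW\tH1\t60\t0\t0",
#'              "chr1\t300\t455\tcellA\tC\t.\t5\t0\t0"), tsv)
#' fs <- readFragments(tsv)
#' length(fs)  # 1: the mapq-5 record is dropped
#' @export
readFragments <- function(path, mapqMin = 10L, dropDuplicates = TRUE,
                          dropSupplementary = TRUE,
                          format = c("auto", "tsv", "bam"),
                          seqlengths = NULL) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("cannot read fragment file: ", path)
    if (format == "auto")
        format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "tsv"
    gr <- if (format == "bam") .readFragmentsBAM(path)
          else .readFragmentsTSV(path)
    .filterFragments(gr, mapqMin = mapqMin, dropDuplicates = dropDuplicates,
                     dropSupplementary = dropSupplementary,
                     seqlengths = seqlengths,
                     source = path)
}

.readFragmentsTSV <- function(path) {
    df <- tryCatch(
        read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character"),
        error = function(e) stop("parse error in ", path, ": ",
                                 conditionMessage(e)))
    miss <- setdiff(.FRAGMENT_COLS, colnames(df))
    if (length(miss) > 0L)
        stop("fragment TSV ", path, " lacks columns: ",
             paste(miss, collapse = ", "))
    if (nrow(df) == 0L) return(.asFragmentGRanges(df[0, , drop = FALSE]))
    num <- suppressWarnings(list(start = as.numeric(df$start),
                                 end = as.numeric(df$end),
                                 mapq = as.numeric(df$mapq)))
    bad <- which(is.na(num$start) | is.na(num$end) | is.na(num$mapq) |
                 num$start >= num$end | !(df$strand %in% c("W", "C")))
    if (length(bad) > 0L)
        stop("malformed fragment record at data line ", bad[1L], " of ", path)
    df$start <- as.integer(num$start); df$end <- as.integer(num$end)
    df$mapq <- as.integer(num$mapq)
    df$dup <- as.integer(df$dup); df$suppl <- as.integer(df$suppl)
    .asFragmentGRanges(df)
}

.readFragmentsBAM <- function(path) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
        stop("BAM input requires the Rsamtools package")
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "rname", "pos", "isize", "mapq", "flag"),
        tag = c("CB", "HP", "RG"),
        flag = Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                      isMinusStrand = FALSE,
                                      isUnmappedQuery = FALSE))
    res <- Rsamtools::scanBam(path, param = p)[[1L]]
    keep <- !is.na(res$isize) & res$isize > 0L
    n <- sum(keep)
    if (n == 0L)
        return(.asFragmentGRanges(data.frame(chrom = character(),
            start = integer(), end = integer(), cell = character(),
            strand = character(), haplotype = character(), mapq = integer(),
            dup = integer(), suppl = integer())))
    cb <- res$tag$CB; rg <- res$tag$RG
    cell <- if (!is.null(cb)) as.character(cb[keep]) else rep(NA_character_, n)
    if (!is.null(rg)) cell[is.na(cell)] <- as.character(rg[keep])[is.na(cell)]
    cell[is.na(cell)] <- "unknown"
    hp <- if (!is.null(res$tag$HP)) res$tag$HP[keep] else rep(NA_integer_, n)
    flag <- res$flag[keep]
    # FLAG bits: 0x400 duplicate, 0x800 supplementary. Only the plus-strand
    # mate of each FR pair is kept (it is leftmost, so isize > 0); the
    # directional library strand follows the first mate's orientation:
    # first mate on plus (0x40 set here) = Crick, else (0x80) = Watson.
    w <- bitwAnd(flag, 0x80) > 0L
    data.frame(chrom = as.character(res$rname[keep]),
               start = res$pos[keep] - 1L,
               end = res$pos[keep] - 1L + res$isize[keep],
               cell = cell,
               strand = ifelse(w, "W", "C"),
               haplotype = ifelse(is.na(hp), ".",
                                  ifelse(hp == 1L, "H1", "H2")),
               mapq = res$mapq[keep],
               dup = as.integer(bitwAnd(flag, 0x400) > 0L),
               suppl = as.integer(bitwAnd(flag, 0x800) > 0L),
               stringsAsFactors = FALSE) |> .asFragmentGRanges()
}

.filterFragments <- function(gr, mapqMin, dropDuplicates, dropSupplementary,
                             seqlengths = NULL, source = NA_character_) {
    mc <- S4Vectors::mcols(gr)
    lowq <- mc$mapq < mapqMin
    dup <- dropDuplicates & mc$isDuplicate
    sup <- dropSupplementary & mc$isSupplementary
    keep <- !(lowq | dup | sup)
    out <- gr[keep]
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(out) <- union(GenomeInfoDb::seqlevels(out),
                                              names(seqlengths))
        GenomeInfoDb::seqlengths(out) <- seqlengths[GenomeInfoDb::seqlevels(out)]
    }
    new("FragmentSet", fragments = out,
        provenance = list(
            source = source,
            filters = list(mapq_min = mapqMin,
                           drop_duplicates = dropDuplicates,
                           drop_supplementary = dropSupplementary),
            dropped = list(low_mapq = sum(lowq),
                           duplicate = sum(dup & !lowq),
                           supplementary = sum(sup & !lowq & !dup))))
}

#' Construct a FragmentSet from a GRanges
#'
#' Thin constructor used by the simulator and tests; applies the same QC
#' filters as \code{\link{readFragments}} so that filtering is idempotent.
#'
#' @param gr \code{GRanges} with columns \code{cell}, \code{haplotype},
#'   \code{mapq}, \code{isDuplicate}, \code{isSupplementary}.
#' @inheritParams readFragments
#' @return A \code{\link{FragmentSet}}.
#' @export
FragmentSet <- function(gr, mapqMin = 0L, dropDuplicates = TRUE,
                        dropSupplementary = TRUE) {
    .filterFragments(gr, mapqMin, dropDuplicates, dropSupplementary,
                     source = "in-memory")
}

#' Classify per-cell, per-chromosome template-strand states
#'
#' For every (cell, chromosome) pair with at least \code{minFragments}
#' fragments, the Watson fraction (share of W-strand fragments) decides the
#' state: \code{WW} when the fraction is at or above \code{upper}, \code{CC}
#' at or below \code{lower}, \code{WC} (mixed) in between. Pairs with fewer
#' fragments are \code{UNKNOWN}. No published values exist for these
#' cutoffs; the defaults (0.8 / 0.2 / 20) are explicit configuration.
#'
#' @param frags A \code{\link{FragmentSet}}.
#' @param minFragments Minimum fragments for a call (default 20).
#' @param upper,lower Watson-fraction thresholds (defaults 0.8 and 0.2).
#' @return A \code{\link{StrandStateMap}}.
#' @export
classifyStrandStates <- function(frags, minFragments = 20L, upper = 0.8,
                                 lower = 0.2) {
    stopifnot(is(frags, "FragmentSet"))
    if (!(upper > 0.5 && upper <= 1)) stop("upper must be in (0.5, 1]")
    if (!(lower >= 0 && lower < 0.5)) stop("lower must be in [0, 0.5)")
    if (minFragments < 1L) stop("minFragments must be >= 1")
    gr <- frags@fragments
    if (length(gr) == 0L) {
        st <- S4Vectors::DataFrame(cell = character(), chrom = character(),
            state = character(), watson_fraction = numeric(),
            n_fragments = integer())
        return(new("StrandStateMap", states = st,
                   params = list(min_fragments = minFragments,
                                 upper = upper, lower = lower)))
    }
    key <- paste(S4Vectors::mcols(gr)$cell,
                 as.character(GenomicRanges::seqnames(gr)), sep = "\r")
    isW <- as.character(GenomicRanges::strand(gr)) == "-"
    nW <- tapply(isW, key, sum)
    nTot <- tapply(isW, key, length)
    ids <- names(nTot)
    parts <- strsplit(ids, "\r", fixed = TRUE)
    wf <- as.numeric(nW[ids]) / as.numeric(nTot[ids])
    state <- ifelse(nTot[ids] < minFragments, "UNKNOWN",
             ifelse(wf >= upper, "WW",
             ifelse(wf <= lower, "CC", "WC")))
    st <- S4Vectors::DataFrame(
        cell = vapply(parts, `[`, character(1), 1L),
        chrom = vapply(parts, `[`, character(1), 2L),
        state = as.character(state),
        watson_fraction = wf,
        n_fragments = as.integer(nTot[ids]))
    st <- st[order(st$cell, st$chrom), , drop = FALSE]
    rownames(st) <- NULL
    new("StrandStateMap", states = st,
        params = list(min_fragments = minFragments, upper = upper,
                      lower = lower))
}

#' Remove fragments overlapping blacklisted regions
#'
#' Regions with artifactual coverage are excluded: any fragment overlapping a
#' blacklist interval by at least 1 bp is removed. Blacklist intervals are
#' 0-based half-open on disk (BED3) and may overlap each other.
#'
#' @param frags A \code{\link{FragmentSet}}.
#' @param blacklist A \code{GRanges}, or path to a BED3 file.
#' @return A filtered \code{\link{FragmentSet}}; a warning reports blacklist
#'   chromosomes absent from the fragment data.
#' @export
applyBlacklist <- function(frags, blacklist) {
    stopifnot(is(frags, "FragmentSet"))
    if (is.character(blacklist)) blacklist <- readBed(blacklist)
    if (length(blacklist) == 0L) return(frags)
    gr <- frags@fragments
    missing <- setdiff(unique(as.character(GenomicRanges::seqnames(blacklist))),
                       unique(as.character(GenomicRanges::seqnames(gr))))
    if (length(missing) > 0L)
        warning(length(missing),
                " blacklist chromosome(s) absent from fragment data: ",
                paste(missing, collapse = ", "))
    hit <- suppressWarnings(
        IRanges::overlapsAny(gr, blacklist, ignore.strand = TRUE))
    out <- frags
    out@fragments <- gr[!hit]
    out@provenance$dropped$blacklisted <- sum(hit)
    out
}

#' Read a BED file (BED3/BED6) as a GRanges
#'
#' Thin wrapper over \code{rtracklayer::import} for the plain-text BED
#' dialects consumed here (blacklists, gene models, CREs, TADs, anchors).
#' The BED name column becomes \code{names(gr)}.
#'
#' @param path Path to a BED file (no header).
#' @return A \code{GRanges}.
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("cannot read BED file: ", path)
    if (file.size(path) == 0L) return(GenomicRanges::GRanges())
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("BED input requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(S4Vectors::mcols(gr)$name)) {
        names(gr) <- S4Vectors::mcols(gr)$name
        S4Vectors::mcols(gr)$name <- NULL
    }
    gr
}

#' Write a GRanges as BED (0-based half-open)
#' @param gr A \code{GRanges}.
#' @param path Output path.
#' @param names Optional feature names (defaults to \code{names(gr)}).
#' @return Invisibly, the path.
#' @export
writeBed <- function(gr, path, names = NULL) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("BED output requires the rtracklayer package")
    if (is.null(names)) names <- names(gr)
    out <- granges(gr)
    names(out) <- NULL
    S4Vectors::mcols(out)$name <- if (is.null(names))
        rep(".", length(gr)) else names
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Write a FragmentSet in the fragment TSV dialect
#' @param frags A \code{\link{FragmentSet}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeFragments <- function(frags, path) {
    gr <- fragments(frags)
    mc <- S4Vectors::mcols(gr)
    hp <- as.character(mc$haplotype)
    hp[hp == "UNPHASED"] <- "."
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     cell = mc$cell,
                     strand = ifelse(as.character(GenomicRanges::strand(gr)) ==
                                     "-", "W", "C"),
                     haplotype = hp,
                     mapq = mc$mapq,
                     dup = as.integer(mc$isDuplicate),
                     suppl = as.integer(mc$isSupplementary))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
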
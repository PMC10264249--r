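# Gene-body NO count matrices and their normalization: counts of fragments
# overlapping gene bodies, copy-number and library-size (RPM) normalization
# with log2 transform, location-only batch adjustment, and median-of-ratios
# size factors.

#' Count fragments per gene body and cell
#'
#' Entry (g, c) is the number of fragments of cell c overlapping the gene
#' body [start, end) of gene g by at least 1 bp; a fragment spanning two
#' genes counts in both. The per-cell library size is the total number of
#' retained fragments of that cell (not only in-gene fragments).
#'
#' @param frags A \code{\link{FragmentSet}}.
#' @param genes A named \code{GRanges} of gene bodies (TSS to transcription
#'   termination site); names must be unique gene ids.
#' @return A \code{SummarizedExperiment} with assay \code{"counts"},
#'   \code{rowRanges} = genes and \code{colData$librarySize}.
#' @export
geneBodyCounts <- function(frags, genes) {
    stopifnot(is(frags, "FragmentSet"), is(genes, "GRanges"))
    if (is.null(names(genes)) || anyDuplicated(names(genes)) > 0L)
        stop("genes must carry unique gene ids as names")
    gr <- fragments(frags)
    cells <- cellIDs(frags)
    m <- matrix(0L, nrow = length(genes), ncol = length(cells),
                dimnames = list(names(genes), cells))
    lib <- setNames(integer(length(cells)), cells)
    if (length(gr) > 0L && length(cells) > 0L) {
        cellOf <- factor(as.character(S4Vectors::mcols(gr)$cell),
                         levels = cells)
        lib <- setNames(as.integer(table(cellOf)), cells)
        if (length(genes) > 0L) {
            hits <- GenomicRanges::findOverlaps(genes, gr,
                                                ignore.strand = TRUE)
            if (length(hits) > 0L) {
                tab <- table(factor(S4Vectors::queryHits(hits),
                                    levels = seq_along(genes)),
                             cellOf[S4Vectors::subjectHits(hits)])
                m[] <- as.integer(tab)
            }
        }
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m),
        rowRanges = genes,
        colData = S4Vectors::DataFrame(librarySize = lib, row.names = cells))
}

# Majority-overlap copy number of each gene under one scope's segments
# (haplotype == "BOTH" rows); ties broken toward the lower-coordinate
# segment. NA where no segment overlaps.
.geneCN <- function(genes, segs) {
    out <- rep(NA_real_, length(genes))
    if (nrow(segs) == 0L) return(out)
    sgr <- GenomicRanges::GRanges(segs$chrom,
        IRanges::IRanges(segs$start, segs$end))
    hits <- GenomicRanges::findOverlaps(genes, sgr, ignore.strand = TRUE)
    if (length(hits) == 0L) return(out)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(IRanges::pintersect(
        granges(genes)[qh], sgr[sh], ignore.strand = TRUE))
    for (g in unique(qh)) {
        sel <- which(qh == g)
        best <- sel[order(-ov[sel], GenomicRanges::start(sgr)[sh[sel]])][1L]
        out[g] <- segs$copy_number[sh[best]]
    }
    out
}

#' Normalize gene-body NO counts
#'
#' Applies, in order and individually skippable: segmental copy-number
#' normalization (count x 2 / CN, with the gene-level CN chosen by majority
#' overlap of the gene body with the relevant copy-number segments), library
#' size normalization to reads per million, and log2(x + 1) transform. The
#' provenance of the applied steps is recorded in the metadata.
#'
#' With all steps enabled the value is
#' \code{log2((count * 2 / CN) / librarySize * 1e6 + 1)}.
#'
#' @param se A \code{SummarizedExperiment} from \code{\link{geneBodyCounts}}.
#' @param cn Optional copy-number table: data.frame with columns
#'   \code{scope} (clone id, cell id or \code{"germline"}), \code{chrom},
#'   \code{start}, \code{end}, \code{haplotype} (\code{H1/H2/BOTH}; only
#'   \code{BOTH} rows carry total CN), \code{copy_number}.
#' @param cloneOf Optional named vector mapping cell id to clone id; used to
#'   pick clone-scope CN segments per cell. Cells without clone-scope (or
#'   cell-scope) segments fall back to germline, then to CN = 2.
#' @param steps Character subset of \code{c("cn", "rpm", "log2")}.
#' @param cnFloor Pseudo-CN used in place of CN = 0 (logged via message).
#' @return A \code{SummarizedExperiment} with assay \code{"normalized"}
#'   (counts retained) and metadata flags \code{cn_normalized}, \code{rpm},
#'   \code{log2}.
#' @export
normalizeCounts <- function(se, cn = NULL, cloneOf = NULL,
                            steps = c("cn", "rpm", "log2"), cnFloor = 0.5) {
    stopifnot(all(steps %in% c("cn", "rpm", "log2")))
    x <- assay(se, "counts") + 0
    genes <- SummarizedExperiment::rowRanges(se)
    cells <- colnames(se)
    cnUsed <- NULL
    if ("cn" %in% steps) {
        cnMat <- matrix(2, nrow(x), ncol(x), dimnames = dimnames(x))
        if (!is.null(cn)) {
            cn <- cn[cn$haplotype == "BOTH", , drop = FALSE]
            germ <- .geneCN(genes, cn[cn$scope == "germline", , drop = FALSE])
            base <- ifelse(is.na(germ), 2, germ)
            for (j in seq_along(cells)) {
                cnMat[, j] <- base
                scopes <- cells[j]
                if (!is.null(cloneOf) && cells[j] %in% names(cloneOf))
                    scopes <- c(scopes, cloneOf[[cells[j]]])
                for (sc in scopes) {
                    seg <- cn[cn$scope == sc, , drop = FALSE]
                    if (nrow(seg) == 0L) next
                    v <- .geneCN(genes, seg)
                    cnMat[!is.na(v), j] <- v[!is.na(v)]
                }
            }
            cnUsed <- cn
        }
        if (any(cnMat == 0)) {
            nz <- sum(cnMat == 0 & x > 0)
            if (nz > 0)
                message(nz, " gene/cell entries with CN = 0 and nonzero ",
                        "counts; using pseudo-CN floor ", cnFloor)
            cnMat[cnMat == 0] <- cnFloor
        }
        x <- x * 2 / cnMat
    }
    if ("rpm" %in% steps) {
        lib <- colData(se)$librarySize
        if (is.null(lib)) stop("colData$librarySize required for rpm step")
        x <- sweep(x, 2L, lib, "/") * 1e6
    }
    if ("log2" %in% steps) x <- log2(x + 1)
    out <- SummarizedExperiment::SummarizedExperiment(
        assays = list(normalized = x, counts = assay(se, "counts")),
        rowRanges = genes, colData = colData(se))
    S4Vectors::metadata(out) <- list(
        cn_normalized = "cn" %in% steps, rpm = "rpm" %in% steps,
        log2 = "log2" %in% steps, cn_table = cnUsed)
    out
}

#' Location-only batch adjustment on the log scale
#'
#' Per gene and batch, centers values to the gene's grand mean: a simple
#' additive batch correction of log-scale NO. Batches with fewer than two
#' cells are passed through with a warning. Dimensions are preserved.
#'
#' @param x A \code{SummarizedExperiment} with assay \code{"normalized"}, or
#'   a numeric matrix (genes x cells).
#' @param batch Batch label per cell (recycled names-matched when named).
#' @return Object of the same type with adjusted values.
#' @export
batchAdjust <- function(x, batch) {
    isSE <- is(x, "SummarizedExperiment")
    m <- if (isSE) assay(x, "normalized") else x
    batch <- as.character(batch)
    if (length(batch) != ncol(m))
        stop("need one batch label per cell")
    grand <- rowMeans(m)
    for (b in unique(batch)) {
        j <- which(batch == b)
        if (length(j) < 2L) {
            warning("batch '", b, "' has fewer than 2 cells; passed through")
            next
        }
        m[, j] <- m[, j, drop = FALSE] - rowMeans(m[, j, drop = FALSE]) + grand
    }
    if (isSE) {
        assay(x, "normalized") <- m
        x
    } else m
}

#' Median-of-ratios size factors
#'
#' Per-cell scaling constants: the median over reference genes (those with
#' nonzero counts in every cell) of the ratio of the cell's count to the
#' gene's geometric mean across cells.
#'
#' @param x Count matrix (genes x cells) or a \code{SummarizedExperiment}
#'   with assay \code{"counts"}.
#' @param pseudoReference For sparse matrices without any all-positive gene:
#'   when TRUE, the per-gene reference is the geometric mean over the
#'   positive counts only (zeros are excluded from the ratio medians), so a
#'   factor is defined for every cell with at least one counted fragment.
#' @return Named numeric vector of positive size factors.
#' @export
computeSizeFactors <- function(x, pseudoReference = FALSE) {
    m <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
    if (pseudoReference) {
        use <- rowSums(m > 0) > 0
        ref <- apply(m[use, , drop = FALSE], 1L,
                     function(k) exp(mean(log(k[k > 0]))))
        s <- apply(m[use, , drop = FALSE], 2L, function(col) {
            r <- col / ref
            median(r[col > 0])
        })
    } else {
        pos <- rowSums(m > 0) == ncol(m)
        if (!any(pos))
            stop("no gene with nonzero counts in every cell; use ",
                 "pseudoReference = TRUE or filter cells first")
        lg <- log(m[pos, , drop = FALSE])
        ref <- exp(rowMeans(lg))
        s <- apply(m[pos, , drop = FALSE], 2L,
                   function(col) median(col / ref))
    }
    if (any(!is.finite(s) | s <= 0)) stop("non-positive size factor computed")
    s
}

#' Write a count matrix as TSV and MatrixMarket files
#' @param se \code{SummarizedExperiment} with a counts assay, or a matrix.
#' @param prefix File prefix; writes \code{<prefix>.tsv}, \code{<prefix>.mtx},
#'   \code{<prefix>.rows}, \code{<prefix>.cols}.
#' @return Invisibly, the file paths.
#' @export
writeCounts <- function(se, prefix) {
    m <- if (is(se, "SummarizedExperiment")) assay(se, 1L) else se
    tsv <- paste0(prefix, ".tsv")
    write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    mtx <- paste0(prefix, ".mtx")
    nz <- which(m != 0, arr.ind = TRUE)
    con <- file(mtx, "w")
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 paste(nrow(m), ncol(m), nrow(nz))), con)
    if (nrow(nz) > 0)
        writeLines(paste(nz[, 1L], nz[, 2L], m[nz]), con)
    close(con)
    writeLines(rownames(m), paste0(prefix, ".rows"))
    writeLines(colnames(m), paste0(prefix, ".cols"))
    invisible(c(tsv, mtx, paste0(prefix, ".rows"), paste0(prefix, ".cols")))
}
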
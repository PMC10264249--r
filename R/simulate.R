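# Synthetic Strand-seq-like data with full ground truth: abstract genome
# (genes, CREs, TADs), clones with SVs and activity shifts, per-cell template
# strand states, haplotype-tagged mono-nucleosomal fragments whose density
# tracks nucleosome occupancy (expressed genes depleted), batch/library-size
# variation. Everything is deterministic given the config seed.

#' Clone specification for the simulator
#'
#' @param clone_id Clone label.
#' @param cf Clonal frequency in (0, 1]; frequencies of all clones in a
#'   config must sum to 1.
#' @param svs \code{NULL} or a data.frame with columns \code{sv_id, class,
#'   chrom, start, end, haplotype} (class in DEL/DUP/INV/INVDUP/TRA/COMPLEX;
#'   haplotype H1/H2; coordinates 1-based inclusive as in GRanges).
#' @param activity_shifts Named numeric vector: gene id -> multiplicative NO
#'   factor applied in this clone (values > 1 mean more occupancy, i.e. less
#'   activity).
#' @param haplotype_effects Named list: gene id -> numeric \code{c(H1=, H2=)}
#'   multiplicative NO factors per haplotype.
#' @return A list of class \code{CloneSpec}.
#' @export
cloneSpec <- function(clone_id, cf, svs = NULL, activity_shifts = numeric(),
                      haplotype_effects = list()) {
    stopifnot(cf > 0, cf <= 1)
    if (!is.null(svs)) {
        need <- c("sv_id", "class", "chrom", "start", "end", "haplotype")
        if (!all(need %in% colnames(svs)))
            stop("svs needs columns: ", paste(need, collapse = ", "))
    }
    if (length(activity_shifts) > 0 && any(activity_shifts <= 0))
        stop("activity_shifts must be > 0")
    structure(list(clone_id = clone_id, cf = cf, svs = svs,
                   activity_shifts = activity_shifts,
                   haplotype_effects = haplotype_effects),
              class = "CloneSpec")
}

#' Simulation configuration
#'
#' Defaults encode the study conditions emulated throughout: fragments are
#' full mono-nucleosomal inserts of 140-180 bp positioned on a nucleosome
#' lattice (repeat length 190 bp, Gaussian jitter), expressed genes show
#' depleted gene-body NO relative to silent genes by
#' \code{no_depletion_factor}, clones are drawn multinomially at their
#' clonal frequencies, and batches shift library size on the log2 scale.
#'
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Total genes, spread evenly over chromosomes.
#' @param gene_length_range Min/max gene length (bp).
#' @param n_cres Number of cis-regulatory elements placed intergenically.
#' @param cre_width CRE width (bp).
#' @param tads_per_chrom TADs tiling each chromosome.
#' @param n_cells Number of cells.
#' @param fragments_per_cell Mean fragments per cell.
#' @param fragment_dispersion Negative-binomial size for per-cell totals.
#' @param nucleosome_repeat Nucleosome repeat length (bp) of the sampling
#'   lattice.
#' @param jitter_sd Gaussian jitter (bp) of fragment midpoints around
#'   lattice positions.
#' @param fragment_length_range Fragment length support (bp), inclusive.
#' @param expressed_fraction Fraction of genes expressed.
#' @param no_depletion_factor Ratio of silent to expressed per-bp fragment
#'   rate at gene bodies (> 1).
#' @param clones List of \code{\link{cloneSpec}} objects (CFs sum to 1).
#' @param batches Named numeric vector of log2 library-size effects per
#'   batch; cells are assigned to batches uniformly at random.
#' @param unphased_fraction Fraction of fragments whose haplotype tag is
#'   stripped to UNPHASED (default 0; set to ~0.5 to emulate typical
#'   real-data phasing rates).
#' @param gc_bins Number of per-gene GC bins emitted as sequence features.
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return A list of class \code{SimulationConfig}.
#' @export
simConfig <- function(n_chroms = 2L, chrom_length = 1e6, n_genes = 100L,
                      gene_length_range = c(2000L, 8000L), n_cres = 50L,
                      cre_width = 500L, tads_per_chrom = 10L, n_cells = 50L,
                      fragments_per_cell = 2000L, fragment_dispersion = 10,
                      nucleosome_repeat = 190L, jitter_sd = 20,
                      fragment_length_range = c(140L, 180L),
                      expressed_fraction = 0.5, no_depletion_factor = 2,
                      clones = list(cloneSpec("clone1", 1)),
                      batches = c(batch1 = 0), unphased_fraction = 0,
                      gc_bins = 150L, seed = 42L) {
    cfg <- list(n_chroms = as.integer(n_chroms), chrom_length = chrom_length,
                n_genes = as.integer(n_genes),
                gene_length_range = gene_length_range, n_cres = n_cres,
                cre_width = cre_width, tads_per_chrom = tads_per_chrom,
                n_cells = as.integer(n_cells),
                fragments_per_cell = fragments_per_cell,
                fragment_dispersion = fragment_dispersion,
                nucleosome_repeat = nucleosome_repeat, jitter_sd = jitter_sd,
                fragment_length_range = fragment_length_range,
                expressed_fraction = expressed_fraction,
                no_depletion_factor = no_depletion_factor, clones = clones,
                batches = batches, unphased_fraction = unphased_fraction,
                gc_bins = as.integer(gc_bins), seed = as.integer(seed))
    cf <- vapply(clones, `[[`, numeric(1), "cf")
    if (abs(sum(cf) - 1) > 1e-8)
        stop("clone clonal frequencies must sum to 1 (got ", sum(cf), ")")
    if (any(c(chrom_length, gene_length_range, fragments_per_cell,
              nucleosome_repeat) <= 0))
        stop("all lengths and rates must be positive")
    if (no_depletion_factor <= 1)
        stop("no_depletion_factor must be > 1")
    if (unphased_fraction < 0 || unphased_fraction > 1)
        stop("unphased_fraction must lie in [0, 1]")
    structure(cfg, class = "SimulationConfig")
}

.chromNames <- function(cfg) paste0("chr", seq_len(cfg$n_chroms))

#' Simulate an abstract genome annotation
#'
#' Places non-overlapping genes (uniform lengths within
#' \code{gene_length_range}) along each chromosome, CREs in intergenic space,
#' TADs tiling each chromosome, and a diploid copy-number baseline. Expressed
#' genes are chosen at \code{expressed_fraction} and given a continuous
#' expression level in (0, 1]; per-bin GC fractions are simulated values
#' (the reference genome is abstract).
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return A list with elements \code{genes} (named \code{GRanges} with
#'   metadata \code{expressed}, \code{expr_level}), \code{cres}, \code{tads}
#'   (\code{GRanges}), \code{gc} (genes x \code{gc_bins} matrix),
#'   \code{cn} (germline copy-number data.frame), \code{seqlengths}.
#' @export
simulateGenome <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(cfg$seed)
    chroms <- .chromNames(cfg)
    sl <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)

    perChrom <- rep(cfg$n_genes %/% cfg$n_chroms, cfg$n_chroms)
    extra <- cfg$n_genes %% cfg$n_chroms
    if (extra > 0) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L

    geneList <- list()
    for (i in seq_along(chroms)) {
        k <- perChrom[i]
        if (k == 0L) next
        gl <- as.integer(cfg$gene_length_range)
        lens <- gl[1] + sample.int(gl[2] - gl[1] + 1L, k, replace = TRUE) - 1L
        slack <- cfg$chrom_length - sum(lens)
        if (slack < k + 1L)
            stop("infeasible packing: too many gene bp for chromosome ",
                 chroms[i])
        # random gap sizes (each >= 1) via a uniform composition of the slack
        cuts <- sort(sample(seq_len(slack - 1L), k))
        gaps <- diff(c(0L, cuts))
        starts <- cumsum(gaps) + cumsum(c(0L, lens[-k]))
        geneList[[i]] <- GenomicRanges::GRanges(chroms[i],
            IRanges::IRanges(start = starts, width = lens),
            strand = sample(c("+", "-"), k, replace = TRUE),
            seqlengths = sl)
    }
    genes <- if (length(geneList) > 0) do.call(c, geneList)
             else GenomicRanges::GRanges()
    GenomeInfoDb::seqlevels(genes) <- chroms
    GenomeInfoDb::seqlengths(genes) <- sl
    if (length(genes) > 0) {
        names(genes) <- sprintf("gene_%03d", seq_along(genes))
        expressed <- runif(length(genes)) < cfg$expressed_fraction
        lvl <- ifelse(expressed, runif(length(genes), 0.3, 1), 0)
        S4Vectors::mcols(genes)$expressed <- expressed
        S4Vectors::mcols(genes)$expr_level <- lvl
    }

    tadWidth <- ceiling(cfg$chrom_length / cfg$tads_per_chrom)
    tads <- GenomicRanges::tileGenome(sl, tilewidth = tadWidth,
                                      cut.last.tile.in.chrom = TRUE)
    names(tads) <- sprintf("tad_%03d", seq_along(tads))

    # CREs dropped uniformly, kept only if fully intergenic
    cres <- GenomicRanges::GRanges()
    if (cfg$n_cres > 0) {
        got <- list(); tries <- 0L
        while (length(got) < cfg$n_cres && tries < 50L) {
            tries <- tries + 1L
            chr <- sample(chroms, cfg$n_cres, replace = TRUE)
            st <- sample.int(cfg$chrom_length - cfg$cre_width, cfg$n_cres)
            cand <- GenomicRanges::GRanges(chr,
                IRanges::IRanges(start = st, width = cfg$cre_width),
                seqlengths = sl)
            ok <- !IRanges::overlapsAny(cand, genes, ignore.strand = TRUE)
            for (j in which(ok)) {
                if (length(got) < cfg$n_cres) got[[length(got) + 1L]] <- cand[j]
            }
        }
        if (length(got) > 0) {
            cres <- do.call(c, got)
            names(cres) <- sprintf("cre_%03d", seq_along(cres))
        }
    }
    GenomeInfoDb::seqlevels(cres) <- chroms
    GenomeInfoDb::seqlengths(cres) <- sl

    gc <- matrix(runif(length(genes) * cfg$gc_bins, 0.3, 0.7),
                 nrow = length(genes), dimnames = list(names(genes), NULL))

    cn <- data.frame(scope = "germline",
                     chrom = rep(chroms, each = 3),
                     start = 1L, end = cfg$chrom_length,
                     haplotype = rep(c("H1", "H2", "BOTH"), cfg$n_chroms),
                     copy_number = rep(c(1L, 1L, 2L), cfg$n_chroms))

    list(genes = genes, cres = cres, tads = tads, gc = gc, cn = cn,
         seqlengths = sl)
}

# Piecewise per-bp fragment rate for one (clone, haplotype, chromosome):
# segments from disjoining gene bodies and SV intervals; rate = base rate
# (1 intergenic / silent, 1/(1+(f-1)*e) expressed) x clone activity shift
# x haplotype effect x per-haplotype copy number.
.rateSegments <- function(genome, clone, hap, chrom, cfg) {
    sl <- genome$seqlengths[[chrom]]
    whole <- GenomicRanges::GRanges(chrom, IRanges::IRanges(1L, sl),
                                    seqlengths = genome$seqlengths)
    genes <- genome$genes[as.character(
        GenomicRanges::seqnames(genome$genes)) == chrom]
    pieces <- whole
    svs <- clone$svs
    if (!is.null(svs)) svs <- svs[svs$chrom == chrom, , drop = FALSE]
    cut <- c(granges(genes))
    if (!is.null(svs) && nrow(svs) > 0)
        cut <- c(cut, GenomicRanges::GRanges(chrom,
                 IRanges::IRanges(svs$start, svs$end),
                 seqlengths = genome$seqlengths))
    segs <- if (length(cut) > 0)
        GenomicRanges::disjoin(c(granges(whole), granges(cut)),
                               ignore.strand = TRUE)
        else whole
    f <- cfg$no_depletion_factor
    rate <- rep(1, length(segs))
    geneOf <- rep(NA_character_, length(segs))
    if (length(genes) > 0) {
        hits <- GenomicRanges::findOverlaps(segs, genes, type = "within",
                                            ignore.strand = TRUE)
        gi <- S4Vectors::subjectHits(hits); si <- S4Vectors::queryHits(hits)
        e <- S4Vectors::mcols(genes)$expr_level[gi]
        rate[si] <- 1 / (1 + (f - 1) * e)
        geneOf[si] <- names(genes)[gi]
        # clone-specific activity shifts (multiplicative NO factors)
        if (length(clone$activity_shifts) > 0) {
            m <- match(geneOf[si], names(clone$activity_shifts))
            adj <- ifelse(is.na(m), 1, clone$activity_shifts[m])
            rate[si] <- rate[si] * adj
        }
        if (length(clone$haplotype_effects) > 0) {
            m <- match(geneOf[si], names(clone$haplotype_effects))
            hf <- vapply(seq_along(m), function(k) {
                if (is.na(m[k])) 1
                else unname(clone$haplotype_effects[[m[k]]][hap])
            }, numeric(1))
            rate[si] <- rate[si] * hf
        }
    }
    cnh <- rep(1, length(segs))
    if (!is.null(svs) && nrow(svs) > 0) {
        for (r in seq_len(nrow(svs))) {
            if (!svs$haplotype[r] %in% c(hap)) next
            inSv <- IRanges::overlapsAny(segs, GenomicRanges::GRanges(chrom,
                IRanges::IRanges(svs$start[r], svs$end[r])))
            if (svs$class[r] == "DEL") cnh[inSv] <- 0
            if (svs$class[r] %in% c("DUP", "INVDUP")) cnh[inSv] <- 2
        }
    }
    list(segs = segs, rate = rate * cnh, gene = geneOf)
}

#' Simulate single cells: fragments plus ground truth
#'
#' Assigns cells to clones (multinomial at the configured clonal
#' frequencies) and batches, draws per-cell per-chromosome template-strand
#' states (each homolog's template strand is an independent fair coin, so WW,
#' CC and the mixed WC state occur at 1/4, 1/4, 1/2), and samples fragments
#' with per-bp density proportional to nucleosome occupancy: silent gene
#' bodies carry \code{no_depletion_factor} times the per-bp rate of
#' expressed ones, heterozygous deletions silence the deleted haplotype,
#' duplications scale the haplotype rate by its copy number. Fragment
#' midpoints sit on a nucleosome lattice (repeat \code{nucleosome_repeat},
#' Gaussian jitter) and lengths are uniform over
#' \code{fragment_length_range}. The strand of each fragment follows the
#' template state of its homolog in that cell.
#'
#' @param genome Output of \code{\link{simulateGenome}}.
#' @param cfg The same \code{\link{simConfig}}.
#' @return A list: \code{frags} (a \code{\link{FragmentSet}}), \code{truth}
#'   (cells/clones/batches, per-(cell,chrom) states and homolog templates,
#'   gene expression states, per-fragment haplotype of origin), \code{svs}
#'   (combined SV table with clone CFs), \code{cn} (copy-number table:
#'   germline baseline plus clone-scope SV segments).
#' @export
simulateCells <- function(genome, cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(cfg$seed + 1L)
    chroms <- .chromNames(cfg)
    cloneIds <- vapply(cfg$clones, `[[`, character(1), "clone_id")
    cf <- vapply(cfg$clones, `[[`, numeric(1), "cf")
    cells <- sprintf("cell_%03d", seq_len(cfg$n_cells))
    cloneOf <- sample(cloneIds, cfg$n_cells, replace = TRUE, prob = cf)
    batchOf <- sample(names(cfg$batches), cfg$n_cells, replace = TRUE)

    # template strand per (cell, chrom, haplotype)
    tmplH1 <- matrix(sample(c("W", "C"), cfg$n_cells * cfg$n_chroms, TRUE),
                     nrow = cfg$n_cells, dimnames = list(cells, chroms))
    tmplH2 <- matrix(sample(c("W", "C"), cfg$n_cells * cfg$n_chroms, TRUE),
                     nrow = cfg$n_cells, dimnames = list(cells, chroms))
    stateOf <- matrix(ifelse(tmplH1 == "W" & tmplH2 == "W", "WW",
                      ifelse(tmplH1 == "C" & tmplH2 == "C", "CC", "WC")),
                      nrow = cfg$n_cells, dimnames = list(cells, chroms))

    # per-clone piecewise rates, computed once
    rateTab <- list()
    for (cl in cfg$clones)
        for (hap in c("H1", "H2"))
            for (chrom in chroms)
                rateTab[[paste(cl$clone_id, hap, chrom)]] <-
                    .rateSegments(genome, cl, hap, chrom, cfg)

    lenRange <- seq(cfg$fragment_length_range[1], cfg$fragment_length_range[2])
    out <- vector("list", cfg$n_cells)
    for (ci in seq_len(cfg$n_cells)) {
        clone <- cloneOf[ci]
        mu <- cfg$fragments_per_cell * 2^cfg$batches[[batchOf[ci]]]
        nFrag <- rnbinom(1L, mu = mu, size = cfg$fragment_dispersion)
        if (nFrag == 0L) next
        # weights over (chrom, hap, segment)
        keys <- as.vector(outer(c("H1", "H2"), chroms, function(h, c)
            paste(clone, h, c)))
        wlist <- lapply(keys, function(k) {
            rt <- rateTab[[k]]
            rt$rate * GenomicRanges::width(rt$segs)
        })
        wl <- unlist(wlist)
        if (sum(wl) == 0) next
        pick <- sample.int(length(wl), nFrag, replace = TRUE, prob = wl)
        # map picks back to (key, segment)
        sizes <- lengths(wlist)
        keyIdx <- rep(seq_along(keys), sizes)[pick]
        segIdx <- (pick - cumsum(c(0L, sizes))[keyIdx])
        haps <- ifelse(grepl(" H1 ", keys[keyIdx]), "H1", "H2")
        chrs <- sub("^.* ", "", keys[keyIdx])

        lens <- sample(lenRange, nFrag, replace = TRUE)
        starts <- integer(nFrag)
        for (k in unique(keyIdx)) {
            sel <- keyIdx == k
            rt <- rateTab[[keys[k]]]
            s0 <- GenomicRanges::start(rt$segs)[segIdx[sel]]
            w0 <- GenomicRanges::width(rt$segs)[segIdx[sel]]
            # nucleosome lattice anchored at chromosome origin
            posInSeg <- floor(runif(sum(sel)) * w0)
            center <- s0 + posInSeg
            center <- round(center / cfg$nucleosome_repeat) *
                cfg$nucleosome_repeat +
                round(rnorm(sum(sel), 0, cfg$jitter_sd))
            starts[sel] <- center - lens[sel] %/% 2L
        }
        starts <- pmax(1L, pmin(as.integer(starts),
                                as.integer(cfg$chrom_length) - lens))
        tmpl <- ifelse(haps == "H1", tmplH1[ci, ][chrs], tmplH2[ci, ][chrs])
        obsHap <- haps
        strip <- runif(nFrag) < cfg$unphased_fraction
        obsHap[strip] <- "UNPHASED"
        out[[ci]] <- data.frame(chrom = chrs, start = starts,
            end = starts + lens, cell = cells[ci],
            strand = tmpl, haplotype = obsHap, true_hap = haps,
            stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(df))
        df <- data.frame(chrom = character(), start = integer(),
                         end = integer(), cell = character(),
                         strand = character(), haplotype = character(),
                         true_hap = character())
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(start = df$start, end = df$end - 1L),
        strand = ifelse(df$strand == "W", "-", "+"),
        cell = df$cell, haplotype = df$haplotype,
        mapq = rep(60L, nrow(df)),
        isDuplicate = rep(FALSE, nrow(df)),
        isSupplementary = rep(FALSE, nrow(df)))
    GenomeInfoDb::seqlevels(gr) <- chroms
    GenomeInfoDb::seqlengths(gr) <- genome$seqlengths
    frags <- FragmentSet(gr)

    svRows <- list()
    cn <- genome$cn
    for (cl in cfg$clones) {
        if (is.null(cl$svs) || nrow(cl$svs) == 0) next
        sv <- cl$svs
        sv$clone_id <- cl$clone_id
        sv$cf <- cl$cf
        if (!"chrom2" %in% colnames(sv)) sv$chrom2 <- NA_character_
        if (!"pos2" %in% colnames(sv)) sv$pos2 <- NA_integer_
        svRows[[length(svRows) + 1L]] <- sv
        for (r in seq_len(nrow(sv))) {
            hap <- sv$haplotype[r]
            cls <- sv$class[r]
            cnh <- if (cls == "DEL") 0L
                   else if (cls %in% c("DUP", "INVDUP")) 2L else 1L
            if (cls %in% c("DEL", "DUP", "INVDUP")) {
                cn <- rbind(cn, data.frame(scope = cl$clone_id,
                    chrom = sv$chrom[r], start = sv$start[r],
                    end = sv$end[r], haplotype = hap, copy_number = cnh))
                cn <- rbind(cn, data.frame(scope = cl$clone_id,
                    chrom = sv$chrom[r], start = sv$start[r],
                    end = sv$end[r], haplotype = "BOTH",
                    copy_number = cnh + 1L))
            }
        }
    }
    svs <- if (length(svRows) > 0) do.call(rbind, svRows) else
        data.frame(sv_id = character(), class = character(),
                   chrom = character(), start = integer(), end = integer(),
                   haplotype = character(), clone_id = character(),
                   cf = numeric(), chrom2 = character(), pos2 = integer())

    truth <- list(
        cells = data.frame(cell = cells, clone = cloneOf, batch = batchOf,
                           stringsAsFactors = FALSE),
        states = data.frame(
            cell = rep(cells, times = cfg$n_chroms),
            chrom = rep(chroms, each = cfg$n_cells),
            state = as.vector(stateOf),
            tmpl_h1 = as.vector(tmplH1), tmpl_h2 = as.vector(tmplH2),
            stringsAsFactors = FALSE),
        genes = data.frame(gene_id = names(genome$genes),
            expressed = S4Vectors::mcols(genome$genes)$expressed,
            expr_level = S4Vectors::mcols(genome$genes)$expr_level,
            stringsAsFactors = FALSE),
        fragment_haplotype = df$true_hap)
    list(frags = frags, truth = truth, svs = svs, cn = cn)
}

#' Simulate a gene-body NO count matrix directly
#'
#' Count-level companion to the fragment simulator, for calibration and
#' power studies of the differential-activity tests: negative-binomial
#' counts for \code{nGenes} genes over two clones, with a chosen subset of
#' genes shifted by a fold change in clone 2 and per-cell library-size
#' factors.
#'
#' @param nGenes Number of genes.
#' @param nPerGroup Cells per clone (length-2 vector or scalar).
#' @param mu Baseline mean count per gene per cell (recycled over genes).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   0 gives Poisson counts.
#' @param effectGenes Indices of genes with a shift in clone 2.
#' @param foldChange Multiplicative NO fold change applied to clone 2 for
#'   \code{effectGenes}.
#' @param sizeFactorRange Per-cell true size factors drawn uniformly.
#' @param seed Integer seed.
#' @return List: \code{counts} (genes x cells), \code{group} (factor),
#'   \code{sizeFactors} (true values), \code{effectGenes}.
#' @export
simulateCounts <- function(nGenes = 200L, nPerGroup = c(50L, 50L), mu = 20,
                           dispersion = 0.2, effectGenes = integer(),
                           foldChange = 1, sizeFactorRange = c(0.5, 2),
                           seed = 1L) {
    set.seed(seed)
    if (length(nPerGroup) == 1L) nPerGroup <- rep(nPerGroup, 2L)
    n <- sum(nPerGroup)
    group <- factor(rep(c("clone1", "clone2"), nPerGroup))
    s <- runif(n, sizeFactorRange[1], sizeFactorRange[2])
    muG <- rep_len(mu, nGenes)
    m <- matrix(0L, nGenes, n,
                dimnames = list(sprintf("gene_%03d", seq_len(nGenes)),
                                sprintf("cell_%03d", seq_len(n))))
    for (g in seq_len(nGenes)) {
        mu_gc <- muG[g] * s
        if (g %in% effectGenes)
            mu_gc[group == "clone2"] <- mu_gc[group == "clone2"] * foldChange
        m[g, ] <- if (dispersion > 0)
            rnbinom(n, mu = mu_gc, size = 1 / dispersion)
        else rpois(n, mu_gc)
    }
    list(counts = m, group = group, sizeFactors = s,
         effectGenes = effectGenes)
}

#' Write a simulation to disk
#'
#' Emits the fragment TSV dialect, BED files for genes/CREs/TADs, the clone
#' and SV tables, the copy-number table and the truth tables under one
#' directory, plus the config as YAML.
#'
#' @param genome Output of \code{\link{simulateGenome}}.
#' @param sim Output of \code{\link{simulateCells}}.
#' @param cfg The \code{\link{simConfig}} used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the files written.
#' @export
writeSimulation <- function(genome, sim, cfg, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    f <- c(fragments = file.path(dir, "fragments.tsv"),
           genes = file.path(dir, "genes.bed"),
           cres = file.path(dir, "cres.bed"),
           tads = file.path(dir, "tads.bed"),
           clones = file.path(dir, "clones.tsv"),
           svs = file.path(dir, "svs.tsv"),
           cn = file.path(dir, "cn.tsv"),
           truth_genes = file.path(dir, "truth_genes.tsv"),
           truth_states = file.path(dir, "truth_states.tsv"),
           config = file.path(dir, "config.yaml"))
    writeFragments(sim$frags, f[["fragments"]])
    writeBed(genome$genes, f[["genes"]])
    writeBed(genome$cres, f[["cres"]])
    writeBed(genome$tads, f[["tads"]])
    write.table(sim$truth$cells, f[["clones"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sim$svs, f[["svs"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sim$cn, f[["cn"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sim$truth$genes, f[["truth_genes"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$truth$states, f[["truth_states"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    plain <- cfg
    plain$clones <- lapply(cfg$clones, function(cl)
        list(clone_id = cl$clone_id, cf = cl$cf))
    yaml::write_yaml(unclass(plain), f[["config"]])
    invisible(f)
}
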
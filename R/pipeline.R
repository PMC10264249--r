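# Pipeline orchestration: YAML config validation with defaults, staged
# execution in dependency order, provenance logging. Missing optional inputs
# disable only the stages that depend on them.

.CONFIG_DEFAULTS <- list(
    fragments = NULL, genes = NULL, cres = NULL, tads = NULL,
    blacklist = NULL, svs = NULL, cn = NULL, clones = NULL,
    gene_sets = NULL, truth_genes = NULL, out = "strandno_out",
    mapq_min = 10, fdr = 0.1, ne_threshold = 0.9, cf_mode_switch = 0.1,
    scan_radius = 1e6, window = 50000, step = 10000, n_perm = 1000,
    bin_size = 10, min_fragments = 20, state_upper = 0.8, state_lower = 0.2,
    min_cells = 5, seed = 1)

.CONFIG_RANGES <- list(
    mapq_min = c(0, Inf), fdr = c(0, 1), ne_threshold = c(0, 1),
    cf_mode_switch = c(0, 0.5), scan_radius = c(1, Inf),
    window = c(1, Inf), step = c(1, Inf), n_perm = c(99, Inf),
    bin_size = c(1, Inf), min_fragments = c(1, Inf),
    state_upper = c(0.5, 1), state_lower = c(0, 0.5), min_cells = c(1, Inf))

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML config (or takes a list), fills in documented defaults,
#' checks every threshold against its allowed range (all violations are
#' reported together, each naming the offending field) and warns about
#' unknown keys (ignored). An empty file yields the full default config.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated config list of class \code{PipelineConfig}.
#' @export
validateConfig <- function(config = list()) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("cannot read config file: ", config)
        config <- yaml::read_yaml(config)
        if (is.null(config)) config <- list()
    }
    stopifnot(is.list(config))
    unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
    if (length(unknown) > 0L)
        warning("ignoring unknown config key(s): ",
                paste(unknown, collapse = ", "))
    cfg <- .CONFIG_DEFAULTS
    for (k in intersect(names(config), names(cfg))) cfg[[k]] <- config[[k]]
    errs <- character()
    for (k in names(.CONFIG_RANGES)) {
        v <- cfg[[k]]
        r <- .CONFIG_RANGES[[k]]
        if (!is.numeric(v) || length(v) != 1L || v < r[1L] || v > r[2L])
            errs <- c(errs, sprintf("%s must be a number in [%s, %s] (got %s)",
                                    k, r[1L], r[2L],
                                    paste(v, collapse = ",")))
    }
    if (cfg$step > cfg$window)
        errs <- c(errs, "step must be <= window")
    if (length(errs) > 0L)
        stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
    structure(cfg, class = c("PipelineConfig", "list"))
}

.readTsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- ingest and blacklist, strand
#' states, gene-body counts and normalization, NE gene filtering (when truth
#' labels are available), differential gene activity per clone pair (mode
#' dispatched on the minor clone frequency), haplotype-specific tests and
#' per-SV local scans, CRE exact tests, and gene-set analyses -- writing
#' result TSVs plus a provenance JSON (inputs, parameters, seed, package
#' version, stages run or skipped) under \code{cfg$out}. Stages whose inputs
#' are missing are skipped and recorded in the provenance. All randomness
#' flows from \code{cfg$seed}.
#'
#' @param cfg A config from \code{\link{validateConfig}} (path or list also
#'   accepted).
#' @return Invisibly, a list with the provenance and the main result tables.
#' @export
runPipeline <- function(cfg) {
    if (!inherits(cfg, "PipelineConfig")) cfg <- validateConfig(cfg)
    if (is.null(cfg$fragments) || is.null(cfg$genes))
        stop("stage 'ingest' failed: config must provide 'fragments' and ",
             "'genes' paths")
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    set.seed(cfg$seed)
    prov <- list(inputs = cfg[c("fragments", "genes", "cres", "tads",
                                "blacklist", "svs", "cn", "clones",
                                "gene_sets", "truth_genes")],
                 parameters = cfg[setdiff(names(.CONFIG_DEFAULTS),
                                          c("fragments", "genes", "cres",
                                            "tads", "blacklist", "svs", "cn",
                                            "clones", "gene_sets",
                                            "truth_genes", "out"))],
                 seed = cfg$seed,
                 version = as.character(utils::packageVersion("strandNO")),
                 stages = list())
    results <- list()
    stage <- function(name, expr) {
        out <- tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        prov$stages[[name]] <<- "run"
        out
    }
    skip <- function(name, why) prov$stages[[name]] <<- paste("skipped:", why)

    frags <- stage("ingest", {
        f <- readFragments(cfg$fragments, mapqMin = cfg$mapq_min)
        if (!is.null(cfg$blacklist)) f <- applyBlacklist(f, cfg$blacklist)
        f
    })
    genes <- stage("genes", readBed(cfg$genes))
    states <- stage("states", {
        s <- classifyStrandStates(frags, minFragments = cfg$min_fragments,
                                  upper = cfg$state_upper,
                                  lower = cfg$state_lower)
        write.table(as.data.frame(stateTable(s)),
                    file.path(cfg$out, "strand_states.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        s
    })

    cloneTab <- NULL; cloneOf <- NULL
    if (!is.null(cfg$clones)) {
        cloneTab <- .readTsv(cfg$clones)
        cloneOf <- setNames(cloneTab$clone, cloneTab$cell)
    }
    cnTab <- if (!is.null(cfg$cn)) .readTsv(cfg$cn) else NULL

    se <- stage("counts", {
        se <- geneBodyCounts(frags, genes)
        writeCounts(se, file.path(cfg$out, "gene_body_counts"))
        se
    })
    nse <- stage("normalize", {
        nse <- normalizeCounts(se, cn = cnTab, cloneOf = cloneOf)
        if (!is.null(cloneTab) && "batch" %in% colnames(cloneTab) &&
            length(unique(cloneTab$batch)) > 1L) {
            batch <- cloneTab$batch[match(colnames(nse), cloneTab$cell)]
            nse <- batchAdjust(nse, batch)
        }
        write.table(data.frame(gene_id = rownames(nse),
                               assay(nse, "normalized"),
                               check.names = FALSE),
                    file.path(cfg$out, "normalized_no.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        nse
    })

    retained <- rownames(se)
    if (!is.null(cfg$truth_genes) && !is.null(cloneOf)) {
        retained <- stage("ne_filter", {
            truth <- .readTsv(cfg$truth_genes)
            ne <- !truth$expressed[match(names(genes), truth$gene_id)]
            clones <- unique(cloneOf)
            gr <- fragments(frags)
            probs <- matrix(NA_real_, length(genes), length(clones),
                            dimnames = list(names(genes), clones))
            feats <- list()
            for (cl in clones) {
                cellsOf <- names(cloneOf)[cloneOf == cl]
                sub <- FragmentSet(gr[S4Vectors::mcols(gr)$cell %in% cellsOf])
                feats[[cl]] <- featurizeGenes(sub, genes, nBins = 30L)
            }
            model <- trainNeClassifier(do.call(rbind, feats),
                                       rep(ne, length(clones)),
                                       threshold = cfg$ne_threshold)
            for (cl in clones) probs[, cl] <- predictNe(model, feats[[cl]])
            keep <- filterNeGenes(probs, threshold = cfg$ne_threshold)
            writeLines(keep, file.path(cfg$out, "genes_retained.txt"))
            keep
        })
    } else skip("ne_filter", "no truth_genes/clones input")

    if (!is.null(cloneOf) && length(unique(cloneOf)) >= 2L) {
        results$dge <- stage("dge", {
            counts <- assay(se, "counts")
            norm <- assay(nse, "normalized")
            clones <- names(sort(table(cloneOf), decreasing = TRUE))
            all <- list()
            for (i in seq_along(clones)[-1L]) {
                pair <- c(clones[1L], clones[i])
                cells <- colnames(counts)[cloneOf[colnames(counts)] %in% pair]
                grp <- factor(cloneOf[cells], levels = pair)
                if (any(table(grp) < 2L)) next
                gkeep <- intersect(retained,
                                   maskScnaGenes(genes, cnTab, pair))
                sub <- counts[gkeep, cells, drop = FALSE]
                sf <- tryCatch(computeSizeFactors(sub),
                               error = function(e)
                                   computeSizeFactors(sub,
                                       pseudoReference = TRUE))
                r <- diffGeneActivity(sub, grp,
                                      normalized = norm[gkeep, cells,
                                                        drop = FALSE],
                                      cfModeSwitch = cfg$cf_mode_switch,
                                      sizeFactors = sf,
                                      nPerm = cfg$n_perm, seed = cfg$seed,
                                      fdr = cfg$fdr)
                r$comparison <- paste(pair, collapse = "_vs_")
                fn <- file.path(cfg$out, paste0("dge_", pair[1L], "_vs_",
                                                pair[2L], ".tsv"))
                write.table(r, fn, sep = "\t", quote = FALSE,
                            row.names = FALSE)
                all[[length(all) + 1L]] <- r
            }
            do.call(rbind, all)
        })
    } else skip("dge", "fewer than 2 clones")

    svTab <- if (!is.null(cfg$svs)) .readTsv(cfg$svs) else NULL
    anyWC <- any(stateTable(states)$state == "WC")
    if (anyWC && any(S4Vectors::mcols(fragments(frags))$haplotype !=
                     "UNPHASED")) {
        results$haplo <- stage("haplo", {
            hc <- haplotypeUnitCounts(frags, genes, states)
            ht <- testHaplotypeNo(hc, minCells = cfg$min_cells,
                                  fdr = cfg$fdr)
            write.table(ht, file.path(cfg$out, "haplotype_tests.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            if (!is.null(svTab) && nrow(svTab) > 0L) {
                ls <- localScan(svTab, ht, genes, radius = cfg$scan_radius,
                                fdr = cfg$fdr)
                write.table(ls, file.path(cfg$out, "local_effects.tsv"),
                            sep = "\t", quote = FALSE, row.names = FALSE)
            }
            ht
        })
        if (!is.null(cfg$cres)) {
            results$cre <- stage("cre", {
                cres <- readBed(cfg$cres)
                ce <- creExactTest(frags, cres, states, fdr = cfg$fdr)
                write.table(ce, file.path(cfg$out, "cre_exact_tests.tsv"),
                            sep = "\t", quote = FALSE, row.names = FALSE)
                ce
            })
        } else skip("cre", "no CRE path in config")
    } else {
        skip("haplo", "no phased fragments in WC-state cells")
        skip("cre", "no phased fragments in WC-state cells")
    }

    if (!is.null(cfg$gene_sets) && !is.null(cloneOf) &&
        length(unique(cloneOf)) >= 2L) {
        results$pathways <- stage("pathways", {
            sets <- readGmt(cfg$gene_sets)
            counts <- assay(se, "counts")
            sf <- tryCatch(computeSizeFactors(counts), error = function(e) {
                lib <- colSums(counts); lib / exp(mean(log(lib)))
            })
            norm <- sweep(counts, 2L, sf, "/")
            scores <- pathwayNoScores(norm, sets)
            write.table(data.frame(cell = rownames(scores), scores,
                                   check.names = FALSE),
                        file.path(cfg$out, "pathway_scores.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            clones <- names(sort(table(cloneOf), decreasing = TRUE))
            sv <- cloneOf[rownames(scores)] != clones[1L]
            batch <- if (!is.null(cloneTab) && "batch" %in% colnames(cloneTab))
                cloneTab$batch[match(rownames(scores), cloneTab$cell)]
            else rep("batch1", nrow(scores))
            pt <- pathwayLmmTest(scores, sv, batch, fdr = cfg$fdr)
            write.table(pt, file.path(cfg$out, "pathway_tests.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            pt
        })
    } else skip("pathways", "no gene_sets/clones input")

    if (!is.null(results$dge) && !is.null(cfg$gene_sets)) {
        results$enrichment <- stage("enrich", {
            sets <- readGmt(cfg$gene_sets)
            sig <- unique(results$dge$gene_id[results$dge$significant])
            uni <- unique(results$dge$gene_id)
            er <- overrepresentationTest(sig, uni, sets, fdr = cfg$fdr)
            write.table(er, file.path(cfg$out, "set_enrichment.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            er
        })
    } else skip("enrich", "no DGE results or gene_sets input")

    jsonlite::write_json(prov, file.path(cfg$out, "provenance.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    invisible(c(list(provenance = prov), results))
}
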
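## End-to-end orchestration: simulate (optional) -> HSB detection ->
## join proposal -> consensus -> chaining -> anchoring -> comparative map
## -> ancestral karyotypes, from a single YAML configuration, with a
## content-hash manifest for byte-level reproducibility checks.

#' Run the full anchoring pipeline from a YAML configuration
#'
#' The configuration names either a `simulate:` block (parameters for
#' [simConfig()]) or an `inputs:` block with paths to the target/reference
#' gene tables, ortholog maps, scaffold lengths and anchor markers; plus an
#' `outdir`, stage parameters (`min_genes`, `skip_orphans`,
#' `min_support_genes`) and optionally `tree`/`profiles`/`outgroup` paths
#' for the ancestral-karyotype stage. All referenced files are checked
#' before any stage runs; any stage failure aborts with a stage-named
#' error. Outputs are deterministic given the configuration, and the
#' returned manifest records an md5 hash per output file.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return invisibly, a list with `outputs` (named paths), `manifest`
#'   (data.frame `file`, `md5`) and the in-memory stage results.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    if (is.null(config$outdir))
        stop("preflight: config needs an 'outdir'")
    hasSim <- !is.null(config$simulate)
    if (!hasSim) {
        ins <- config$inputs
        need <- c("target", "refA", "refB", "orthologsA", "orthologsB",
            "scaffold_lengths", "markers")
        missing <- setdiff(need, names(ins))
        if (length(missing) > 0L)
            stop("preflight: config missing inputs: ",
                paste(missing, collapse = ", "))
        absent <- unlist(ins[need])[!file.exists(unlist(ins[need]))]
        if (length(absent) > 0L)
            stop("preflight: input file not found: ", absent[1L])
    }
    for (extra in c("tree", "profiles"))
        if (!is.null(config[[extra]]) && !file.exists(config[[extra]]))
            stop("preflight: input file not found: ", config[[extra]])
    minGenes <- if (is.null(config$min_genes)) 2L else as.integer(config$min_genes)
    skipOrphans <- if (is.null(config$skip_orphans)) TRUE else
        isTRUE(config$skip_orphans)
    minSupport <- if (is.null(config$min_support_genes)) 1L else
        as.integer(config$min_support_genes)

    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                call. = FALSE))
    }
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    outputs <- character(0)
    emit <- function(x, file) {
        path <- file.path(config$outdir, file)
        writeTsv(x, path)
        outputs[[file]] <<- path
    }

    if (hasSim) {
        sim <- stage("simulate", {
            cfg <- do.call(simConfig, config$simulate)
            s <- simulateGenomes(cfg)
            orphanRate <- config$simulate$orphan_rate
            if (!is.null(orphanRate) && orphanRate > 0)
                s <- plantOrphans(s, orphanRate)
            s
        })
        target <- sim$target; refA <- sim$refA; refB <- sim$refB
        mapA <- sim$mapA; mapB <- sim$mapB
        scaffolds <- sim$scaffolds; markers <- sim$markers
        stage("simulate", invisible(writeSimulation(sim,
            file.path(config$outdir, "sim"))))
    } else {
        ins <- config$inputs
        target <- stage("read", readGeneTable(ins$target, "target"))
        refA <- stage("read", readGeneTable(ins$refA, "refA"))
        refB <- stage("read", readGeneTable(ins$refB, "refB"))
        mapA <- stage("read", readOrthologMap(ins$orthologsA, "refA", "target"))
        mapB <- stage("read", readOrthologMap(ins$orthologsB, "refB", "target"))
        scaffolds <- stage("read", readScaffoldLengths(ins$scaffold_lengths))
        markers <- stage("read", readAnchorMarkers(ins$markers, scaffolds))
    }

    hsbA <- stage("hsb", detectHsbs(refA, target, mapA, minGenes = minGenes))
    hsbB <- stage("hsb", detectHsbs(refB, target, mapB, minGenes = minGenes))
    emit(hsbA, "hsb_refA.tsv"); emit(hsbB, "hsb_refB.tsv")

    joinsA <- stage("superscaffold", proposeJoins(target, refA, mapA,
        skipOrphans = skipOrphans, minSupportGenes = minSupport))
    joinsB <- stage("superscaffold", proposeJoins(target, refB, mapB,
        skipOrphans = skipOrphans, minSupportGenes = minSupport))
    consensus <- stage("superscaffold", consensusJoins(joinsA, joinsB))
    sset <- stage("superscaffold", chainJoins(consensus, scaffolds))
    emit(joinsA, "joins_refA.tsv"); emit(joinsB, "joins_refB.tsv")
    emit(consensus, "joins_consensus.tsv")
    emit(superscaffoldMembers(sset), "superscaffolds.tsv")
    sizes <- superscaffoldSizes(sset, scaffolds)
    emit(sizes, "superscaffold_sizes.tsv")

    anchored <- stage("anchor", assignUnits(sset, markers))
    emit(anchored$assignments, "assignments.tsv")
    emit(anchored$conflicts, "conflicts.tsv")

    comparative <- NULL
    if (nrow(anchored$assignments) > 0L) {
        comparative <- stage("compare", {
            membership <- unitMembership(sset)
            rows <- lapply(seq_len(nrow(anchored$assignments)), function(i) {
                u <- anchored$assignments$unit_id[i]
                scafs <- names(membership)[membership == u]
                mk <- markers[markers$scaffold_id %in% scafs, , drop = FALSE]
                data.frame(unit_id = u,
                    target_chromosome = anchored$assignments$chromosome_id[i],
                    flpter = if (nrow(mk) > 0L && any(!is.na(mk$flpter)))
                        mean(mk$flpter, na.rm = TRUE) else NA_real_,
                    homolog = homologyOfUnit(scafs, target, refA, mapA),
                    anchored_bp = superscaffoldSize(scafs, scaffolds),
                    stringsAsFactors = FALSE)
            })
            unitMap <- do.call(rbind, rows)
            unitMap <- unitMap[!is.na(unitMap$flpter), , drop = FALSE]
            interchromosomalEvents(unitMap)
        })
        emit(comparative$segments, "comparative_segments.tsv")
        emit(comparative$per_chromosome, "comparative_events.tsv")
    }

    ancestral <- NULL
    if (!is.null(config$tree) && !is.null(config$profiles)) {
        ancestral <- stage("ancestors", {
            tr <- ape::read.tree(config$tree)
            pf <- readKaryotypeProfiles(config$profiles)
            ancestralKaryotypes(tr, pf, outgroup = config$outgroup,
                macroSegments = config$macro_segments)
        })
        emit(ancestral$ancestors, "ancestors.tsv")
        emit(ancestral$events, "ancestral_events.tsv")
    }

    manifest <- data.frame(file = names(outputs),
        md5 = unname(tools::md5sum(unlist(outputs))),
        stringsAsFactors = FALSE)
    invisible(list(outputs = outputs, manifest = manifest,
        superscaffolds = sset, consensus = consensus,
        anchoring = anchored, comparative = comparative,
        ancestral = ancestral))
}
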
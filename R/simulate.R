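## Synthetic-genome generator. Produces an ancestor gene order, two reference
## genomes derived from it by logged inversions / reciprocal translocations /
## fusions / fissions, a target genome identical to the ancestor but
## fragmented into scaffolds, ortholog maps with independent per-reference
## dropout, anchor markers sampled from scaffolds, and a truth set (scaffold
## adjacencies, scaffold chromosomes, event logs) for known-answer testing.
## All sampling is drawn from one seeded stream in a documented order:
## gene lengths, gaps, refA events, refB events, scaffold cuts, dropout A,
## dropout B, markers.

#' Simulation configuration
#'
#' Collects and validates the parameters of [simulateGenomes()]. Defaults
#' emulate a small agamid-like study system: six macrochromosomes carrying a
#' few hundred annotated genes, two reference lineages each carrying a
#' handful of intra- and interchromosomal rearrangements, a target assembly
#' fragmented into tens of scaffolds, moderate ortholog dropout, and sparse
#' cytogenetic anchor markers.
#'
#' @param nGenes total genes in the ancestor (>= nChromosomes).
#' @param nChromosomes ancestor chromosome count (>= 1).
#' @param nInversionsA,nInversionsB inversions on each reference lineage.
#' @param nTranslocationsA,nTranslocationsB reciprocal translocations.
#' @param nFusionsA,nFusionsB chromosome fusions.
#' @param nFissionsA,nFissionsB chromosome fissions.
#' @param nScaffolds number of scaffolds the target is cut into (>=
#'   nChromosomes; every scaffold keeps at least two genes, so at most
#'   `floor(nGenes / 2)` scaffolds can be requested — single-gene scaffolds
#'   are introduced only by [plantOrphans()]).
#' @param dropoutRate probability in `[0, 1)` that a target gene's ortholog
#'   pair is dropped, independently per reference.
#' @param markerDensity expected anchor markers per scaffold (Poisson).
#' @param seed integer seed for the single pseudo-random stream.
#' @return a validated list of class `simConfig`.
#' @export
simConfig <- function(nGenes = 600L, nChromosomes = 6L,
        nInversionsA = 5L, nTranslocationsA = 2L, nFusionsA = 1L, nFissionsA = 1L,
        nInversionsB = 5L, nTranslocationsB = 2L, nFusionsB = 1L, nFissionsB = 1L,
        nScaffolds = 60L, dropoutRate = 0.1, markerDensity = 0.5, seed = 1L) {
    cfg <- list(nGenes = as.integer(nGenes), nChromosomes = as.integer(nChromosomes),
        nInversionsA = as.integer(nInversionsA),
        nTranslocationsA = as.integer(nTranslocationsA),
        nFusionsA = as.integer(nFusionsA), nFissionsA = as.integer(nFissionsA),
        nInversionsB = as.integer(nInversionsB),
        nTranslocationsB = as.integer(nTranslocationsB),
        nFusionsB = as.integer(nFusionsB), nFissionsB = as.integer(nFissionsB),
        nScaffolds = as.integer(nScaffolds), dropoutRate = as.numeric(dropoutRate),
        markerDensity = as.numeric(markerDensity), seed = as.integer(seed))
    if (cfg$nChromosomes < 1L || cfg$nGenes < cfg$nChromosomes)
        stop("need nGenes >= nChromosomes >= 1")
    if (cfg$dropoutRate < 0 || cfg$dropoutRate >= 1)
        stop("dropoutRate must lie in [0, 1)")
    if (cfg$nScaffolds < cfg$nChromosomes)
        stop("nScaffolds must be >= nChromosomes")
    if (any(vapply(cfg[3:10], function(x) x < 0L, logical(1))))
        stop("event counts must be >= 0")
    if (cfg$markerDensity < 0)
        stop("markerDensity must be >= 0")
    structure(cfg, class = c("simConfig", "list"))
}

## genome = list of chromosomes, each an integer vector of signed gene
## indices (sign = orientation). Names are assigned when laying out tables.

newEventLog <- function() {
    data.frame(event_id = integer(), type = character(), chrom1 = integer(),
        chrom2 = integer(), pos1 = integer(), pos2 = integer(),
        stringsAsFactors = FALSE)
}

## Adjacency bookkeeping: unordered gene pairs adjacent on a chromosome.
adjacencySet <- function(genome) {
    out <- character(0)
    for (chr in genome) {
        g <- abs(chr)
        if (length(g) >= 2L)
            out <- c(out, paste(pmin(g[-length(g)], g[-1L]),
                pmax(g[-length(g)], g[-1L]), sep = "|"))
    }
    out
}

applyOneEvent <- function(genome, type) {
    ## returns list(genome, rec) where rec holds replayable parameters;
    ## NULL if no legal move exists for this event type
    nc <- length(genome)
    lens <- lengths(genome)
    if (type == "inversion") {
        ok <- which(lens >= 2L)
        if (length(ok) == 0L) return(NULL)
        c1 <- ok[sample.int(length(ok), 1L)]
        n <- lens[c1]
        i <- sample.int(n - 1L, 1L)
        j <- i + sample.int(n - i, 1L)
        chr <- genome[[c1]]
        chr[i:j] <- -rev(chr[i:j])
        genome[[c1]] <- chr
        rec <- list(type = type, chrom1 = c1, chrom2 = NA_integer_,
            pos1 = i, pos2 = j)
    } else if (type == "translocation") {
        ok <- which(lens >= 2L)
        if (nc < 2L || length(ok) < 2L) return(NULL)
        cc <- sample(ok, 2L)
        c1 <- cc[1L]; c2 <- cc[2L]
        p1 <- sample.int(lens[c1] - 1L, 1L)  # keep both products non-empty
        p2 <- sample.int(lens[c2] - 1L, 1L)
        a <- genome[[c1]]; b <- genome[[c2]]
        genome[[c1]] <- c(a[seq_len(p1)], b[(p2 + 1L):length(b)])
        genome[[c2]] <- c(b[seq_len(p2)], a[(p1 + 1L):length(a)])
        rec <- list(type = type, chrom1 = c1, chrom2 = c2, pos1 = p1, pos2 = p2)
    } else if (type == "fusion") {
        if (nc < 2L) return(NULL)
        cc <- sort(sample.int(nc, 2L))
        c1 <- cc[1L]; c2 <- cc[2L]
        genome[[c1]] <- c(genome[[c1]], genome[[c2]])
        genome[[c2]] <- NULL
        rec <- list(type = type, chrom1 = c1, chrom2 = c2,
            pos1 = NA_integer_, pos2 = NA_integer_)
    } else if (type == "fission") {
        ok <- which(lens >= 2L)
        if (length(ok) == 0L) return(NULL)
        c1 <- ok[sample.int(length(ok), 1L)]
        p1 <- sample.int(lens[c1] - 1L, 1L)
        chr <- genome[[c1]]
        genome[[c1]] <- chr[seq_len(p1)]
        genome[[length(genome) + 1L]] <- chr[(p1 + 1L):length(chr)]
        rec <- list(type = type, chrom1 = c1, chrom2 = NA_integer_,
            pos1 = p1, pos2 = NA_integer_)
    } else stop("unknown event type: ", type)
    list(genome = genome, rec = rec)
}

#' Replay a rearrangement log on a genome
#'
#' Applies the exact events recorded by [simulateGenomes()] (in order) to an
#' ancestor chromosome list. Replaying a reference lineage's log on the
#' ancestor reproduces that reference's gene order exactly.
#'
#' @param genome list of integer vectors (signed gene indices).
#' @param log event-log data.frame with columns `type`, `chrom1`, `chrom2`,
#'   `pos1`, `pos2`.
#' @return the rearranged genome (list of integer vectors).
#' @export
replayEvents <- function(genome, log) {
    for (k in seq_len(nrow(log))) {
        e <- log[k, ]
        if (e$type == "inversion") {
            chr <- genome[[e$chrom1]]
            chr[e$pos1:e$pos2] <- -rev(chr[e$pos1:e$pos2])
            genome[[e$chrom1]] <- chr
        } else if (e$type == "translocation") {
            a <- genome[[e$chrom1]]; b <- genome[[e$chrom2]]
            genome[[e$chrom1]] <- c(a[seq_len(e$pos1)], b[(e$pos2 + 1L):length(b)])
            genome[[e$chrom2]] <- c(b[seq_len(e$pos2)], a[(e$pos1 + 1L):length(a)])
        } else if (e$type == "fusion") {
            genome[[e$chrom1]] <- c(genome[[e$chrom1]], genome[[e$chrom2]])
            genome[[e$chrom2]] <- NULL
        } else if (e$type == "fission") {
            chr <- genome[[e$chrom1]]
            genome[[e$chrom1]] <- chr[seq_len(e$pos1)]
            genome[[length(genome) + 1L]] <- chr[(e$pos1 + 1L):length(chr)]
        }
    }
    genome
}

deriveReference <- function(ancestor, nInv, nTrans, nFus, nFis) {
    ## event order is fixed: fissions, fusions, translocations, inversions
    ## (documented stream order; keeps chromosome counts predictable)
    types <- c(rep("fission", nFis), rep("fusion", nFus),
        rep("translocation", nTrans), rep("inversion", nInv))
    genome <- ancestor
    log <- newEventLog()
    for (ty in types) {
        res <- applyOneEvent(genome, ty)
        if (is.null(res))
            stop("cannot apply event '", ty, "': genome too small")
        genome <- res$genome
        rec <- res$rec
        log <- rbind(log, data.frame(event_id = nrow(log) + 1L,
            type = rec$type, chrom1 = rec$chrom1, chrom2 = rec$chrom2,
            pos1 = rec$pos1, pos2 = rec$pos2, stringsAsFactors = FALSE))
    }
    ## lineage breakpoints: ancestral gene adjacencies absent from the
    ## derived genome (an adjacency broken and later restored by a second
    ## event is not a breakpoint of the lineage)
    disrupted <- setdiff(adjacencySet(ancestor), adjacencySet(genome))
    list(genome = genome, log = log, disrupted = disrupted)
}

layoutGenome <- function(genome, genomeId, seqPrefix, geneIds, geneLens,
        gap = 1000) {
    ## deterministic coordinates: genes laid out left to right with fixed
    ## inter-gene gap; only ordering matters downstream
    rows <- vector("list", length(genome))
    lens <- numeric(length(genome))
    for (i in seq_along(genome)) {
        chr <- genome[[i]]
        g <- abs(chr)
        n <- length(g)
        starts <- cumsum(c(gap, geneLens[g][-n] + gap))
        seqId <- sprintf("%s%d", seqPrefix, i)
        rows[[i]] <- data.frame(gene_id = geneIds[g], seq_id = seqId,
            start = starts, end = starts + geneLens[g],
            strand = ifelse(chr > 0, "+", "-"), stringsAsFactors = FALSE)
        lens[i] <- starts[n] + geneLens[g[n]] + gap
    }
    d <- do.call(rbind, rows)
    GeneTable(genomeId, d,
        seqLengths = stats::setNames(lens, sprintf("%s%d", seqPrefix,
            seq_along(genome))))
}

#' Simulate a target genome with two rearranged references
#'
#' Generates (1) an ancestor gene order, (2) two reference genomes derived
#' from the ancestor by exactly the configured numbers of logged events,
#' (3) a target genome whose chromosomes equal the ancestor's (identity
#' lineage) but are cut into scaffolds at inter-gene boundaries, (4)
#' one-to-one ortholog maps from each reference to the target with
#' independent dropout, (5) anchor markers sampled from scaffolds with true
#' chromosome assignments and Flpter positions, and (6) a truth set: the
#' scaffold adjacency list (disjoint simple paths, one per chromosome), the
#' true chromosome of every scaffold, and the per-lineage rearrangement logs
#' including the set of ancestral gene adjacencies each lineage disrupted.
#' The same configuration (same seed) always yields identical output.
#'
#' @param config a [simConfig()].
#' @return a list with elements `ancestor`, `refA`, `refB`, `target`
#'   ([GeneTable-class]s), `scaffolds` (length table), `markers`, `mapA`,
#'   `mapB` ([OrthologMap-class]s) and `truth` (list with `adjacencies`,
#'   `scaffold_chromosome`, `logs`, `disrupted`, `orphans`, plus the raw
#'   `ancestorGenome` chromosome list for replay checks).
#' @examples
#' sim <- simulateGenomes(simConfig(nGenes = 60, nChromosomes = 2,
#'     nScaffolds = 6, seed = 7))
#' sim$truth$adjacencies
#' @export
simulateGenomes <- function(config = simConfig()) {
    stopifnot(inherits(config, "simConfig"))
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
    }
    set.seed(config$seed)
    nG <- config$nGenes; nC <- config$nChromosomes
    geneIds <- sprintf("g%05d", seq_len(nG))
    geneLens <- round(stats::runif(nG, 1000, 20000))
    gaps <- round(stats::runif(nG, 500, 5000))  # gap after each gene

    ## ancestor: genes split into contiguous chromosomes of near-equal size
    sizes <- diff(round(seq(0, nG, length.out = nC + 1L)))
    ancestorGenome <- split(seq_len(nG), rep(seq_len(nC), sizes))
    ancestorGenome <- lapply(ancestorGenome, as.integer)
    names(ancestorGenome) <- NULL

    refAres <- deriveReference(ancestorGenome, config$nInversionsA,
        config$nTranslocationsA, config$nFusionsA, config$nFissionsA)
    refBres <- deriveReference(ancestorGenome, config$nInversionsB,
        config$nTranslocationsB, config$nFusionsB, config$nFissionsB)

    ## --- target: fragment ancestor chromosomes into scaffolds -------------
    ## boundaries are inter-gene positions; every scaffold keeps >= 2 genes,
    ## so boundaries adjacent to a chromosome end or to a chosen cut are
    ## removed from the legal set as cuts accumulate
    nCuts <- config$nScaffolds - nC
    boundary <- data.frame(chrom = rep(seq_len(nC), pmax(lengths(ancestorGenome) - 1L, 0L)),
        pos = unlist(lapply(lengths(ancestorGenome), function(n)
            seq_len(max(n - 1L, 0L))), use.names = FALSE))
    legal <- boundary$pos >= 2L &
        boundary$pos <= (lengths(ancestorGenome)[boundary$chrom] - 2L)
    cuts <- integer(0)
    for (k in seq_len(nCuts)) {
        idx <- which(legal)
        if (length(idx) == 0L)
            stop("nScaffolds exceeds the available inter-gene boundaries ",
                "(every scaffold keeps >= 2 genes)")
        pick <- idx[sample.int(length(idx), 1L)]
        cuts <- c(cuts, pick)
        near <- boundary$chrom == boundary$chrom[pick] &
            abs(boundary$pos - boundary$pos[pick]) <= 1L
        legal[near] <- FALSE
    }

    ## scaffolds in genomic order, ids scf000001..; true adjacency list
    scafGenes <- list(); scafChrom <- integer(0)
    for (i in seq_len(nC)) {
        chr <- ancestorGenome[[i]]
        cp <- sort(boundary$pos[intersect(cuts, which(boundary$chrom == i))])
        pieces <- split(chr, findInterval(seq_along(chr) - 1L, cp) + 1L)
        for (p in pieces) {
            scafGenes[[length(scafGenes) + 1L]] <- p
            scafChrom <- c(scafChrom, i)
        }
    }
    scafIds <- sprintf("scf%06d", seq_along(scafGenes))

    ## lay out target scaffold coordinates using ancestor gene lengths/gaps;
    ## chromosome bp is conserved: scaffold slices partition each chromosome
    targetRows <- vector("list", length(scafGenes))
    scafLens <- numeric(length(scafGenes))
    for (s in seq_along(scafGenes)) {
        g <- scafGenes[[s]]
        n <- length(g)
        starts <- cumsum(c(gaps[g[1L]], geneLens[g][-n] + gaps[g][-1L]))
        ## leading gap is the gap "before" the first gene: reuse its own gap
        targetRows[[s]] <- data.frame(gene_id = geneIds[g], seq_id = scafIds[s],
            start = starts, end = starts + geneLens[g],
            strand = "+", stringsAsFactors = FALSE)
        scafLens[s] <- starts[n] + geneLens[g[n]] + gaps[g[n]]
    }
    target <- GeneTable("target", do.call(rbind, targetRows),
        seqLengths = stats::setNames(scafLens, scafIds))
    scaffolds <- data.frame(scaffold_id = scafIds, length_bp = scafLens,
        stringsAsFactors = FALSE)

    ## true adjacencies: consecutive scaffolds on the same chromosome
    adj <- data.frame(left_scaffold = character(), left_end = character(),
        right_scaffold = character(), right_end = character(),
        chromosome = character(), stringsAsFactors = FALSE)
    for (i in seq_len(nC)) {
        ss <- which(scafChrom == i)
        if (length(ss) >= 2L)
            adj <- rbind(adj, data.frame(
                left_scaffold = scafIds[ss[-length(ss)]], left_end = "tail",
                right_scaffold = scafIds[ss[-1L]], right_end = "head",
                chromosome = sprintf("chr%d", i), stringsAsFactors = FALSE))
    }

    ## ortholog maps with independent dropout per reference
    dropA <- stats::runif(nG) < config$dropoutRate
    dropB <- stats::runif(nG) < config$dropoutRate
    mapA <- OrthologMap("refA", "target", data.frame(
        ref_gene_id = geneIds[!dropA], target_gene_id = geneIds[!dropA]))
    mapB <- OrthologMap("refB", "target", data.frame(
        ref_gene_id = geneIds[!dropB], target_gene_id = geneIds[!dropB]))

    ## anchor markers: Poisson(markerDensity) per scaffold, true chromosome,
    ## Flpter = (chromosome offset of scaffold + position) / chromosome bp
    chromLens <- vapply(seq_len(nC), function(i)
        sum(scafLens[scafChrom == i]), numeric(1))
    scafOffset <- numeric(length(scafGenes))
    for (i in seq_len(nC)) {
        ss <- which(scafChrom == i)
        scafOffset[ss] <- cumsum(c(0, scafLens[ss][-length(ss)]))
    }
    nMark <- stats::rpois(length(scafGenes), config$markerDensity)
    mrows <- list()
    for (s in seq_along(scafGenes)) {
        if (nMark[s] == 0L) next
        pos <- round(stats::runif(nMark[s], 1, scafLens[s]))
        mrows[[length(mrows) + 1L]] <- data.frame(
            scaffold_id = scafIds[s], position_bp = pos,
            chromosome_id = sprintf("chr%d", scafChrom[s]),
            flpter = (scafOffset[s] + pos) / chromLens[scafChrom[s]],
            stringsAsFactors = FALSE)
    }
    markers <- if (length(mrows)) do.call(rbind, mrows) else
        data.frame(scaffold_id = character(), position_bp = numeric(),
            chromosome_id = character(), flpter = numeric())
    if (nrow(markers) > 0L)
        markers <- cbind(data.frame(
            marker_id = sprintf("bac%04d", seq_len(nrow(markers)))), markers)
    else markers$marker_id <- character(0)
    markers <- markers[, c("marker_id", "scaffold_id", "position_bp",
        "chromosome_id", "flpter")]

    ancestor <- layoutGenome(ancestorGenome, "ancestor", "chr", geneIds, geneLens)
    refA <- layoutGenome(refAres$genome, "refA", "chrA_", geneIds, geneLens)
    refB <- layoutGenome(refBres$genome, "refB", "chrB_", geneIds, geneLens)

    list(ancestor = ancestor, refA = refA, refB = refB, target = target,
        scaffolds = scaffolds, markers = markers, mapA = mapA, mapB = mapB,
        truth = list(
            adjacencies = adj,
            scaffold_chromosome = data.frame(scaffold_id = scafIds,
                chromosome_id = sprintf("chr%d", scafChrom),
                stringsAsFactors = FALSE),
            logs = list(refA = refAres$log, refB = refBres$log),
            disrupted = list(refA = refAres$disrupted, refB = refBres$disrupted),
            orphans = data.frame(scaffold_id = character(),
                gene_id = character(), stringsAsFactors = FALSE),
            ancestorGenome = ancestorGenome,
            refAGenome = refAres$genome, refBGenome = refBres$genome,
            scaffoldGenes = stats::setNames(lapply(scafGenes, function(g)
                geneIds[g]), scafIds)),
        config = config)
}

#' Plant orphaned single-gene scaffolds
#'
#' Re-cuts selected multi-gene scaffolds so that a single-gene scaffold sits
#' between two multi-gene scaffolds whose terminal genes are
#' reference-adjacent (the "fork" scenario that orphan skipping resolves).
#' Planted orphans are appended to the truth set's orphan list and the truth
#' adjacency list is updated to the new fragmentation.
#'
#' @param sim result of [simulateGenomes()].
#' @param rate fraction of scaffolds to convert (orphans planted =
#'   `floor(rate * nScaffolds)`); scaffolds need >= 5 genes to be eligible so
#'   both flanks keep >= 2 genes.
#' @param seed integer seed for the orphan placement draws.
#' @return a modified copy of `sim` with updated `target`, `scaffolds` and
#'   `truth` (including `truth$orphans`).
#' @export
plantOrphans <- function(sim, rate, seed = sim$config$seed + 1L) {
    stopifnot(rate >= 0, rate < 1)
    nOrph <- floor(rate * nrow(sim$scaffolds))
    if (nOrph == 0L) return(sim)
    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    genes <- sim$truth$scaffoldGenes
    eligible <- names(genes)[lengths(genes) >= 5L]
    if (length(eligible) < nOrph)
        stop("rate too high: only ", length(eligible),
            " scaffolds have >= 5 genes")
    chosen <- sort(sample(eligible, nOrph))
    scafChrom <- stats::setNames(sim$truth$scaffold_chromosome$chromosome_id,
        sim$truth$scaffold_chromosome$scaffold_id)
    p <- placements(sim$target)
    sl <- seqLengths(sim$target)
    newAdj <- sim$truth$adjacencies
    orphans <- sim$truth$orphans
    for (sc in chosen) {
        gs <- genes[[sc]]
        n <- length(gs)
        k <- 2L + sample.int(n - 4L, 1L)  # orphan index in 3..n-2 => flanks >= 2
        partL <- gs[seq_len(k - 1L)]
        orph <- gs[k]
        partR <- gs[(k + 1L):n]
        idL <- paste0(sc, "a"); idO <- paste0(sc, "b"); idR <- paste0(sc, "c")
        idx <- match(gs, p$gene_id)  # rows of this scaffold, in gene order
        gp <- p[idx, ]
        ## split coordinates at the inter-gene midlines around the orphan gene
        cutL <- floor((gp$end[k - 1L] + gp$start[k]) / 2)
        cutR <- floor((gp$end[k] + gp$start[k + 1L]) / 2)
        offs <- c(rep(0, k - 1L), cutL, rep(cutR, n - k))
        p$seq_id[idx] <- c(rep(idL, k - 1L), idO, rep(idR, n - k))
        p$start[idx] <- gp$start - offs
        p$end[idx] <- gp$end - offs
        lenAll <- sl[[sc]]
        sl <- sl[names(sl) != sc]
        sl[idL] <- cutL; sl[idO] <- cutR - cutL; sl[idR] <- lenAll - cutR
        genes[[sc]] <- NULL
        genes[[idL]] <- partL; genes[[idO]] <- orph; genes[[idR]] <- partR
        ## truth bookkeeping
        chrom <- scafChrom[[sc]]
        scafChrom <- scafChrom[names(scafChrom) != sc]
        scafChrom[c(idL, idO, idR)] <- chrom
        hitL <- newAdj$right_scaffold == sc
        newAdj$right_scaffold[hitL] <- idL
        hitR <- newAdj$left_scaffold == sc
        newAdj$left_scaffold[hitR] <- idR
        newAdj <- rbind(newAdj, data.frame(
            left_scaffold = c(idL, idO), left_end = "tail",
            right_scaffold = c(idO, idR), right_end = "head",
            chromosome = chrom, stringsAsFactors = FALSE))
        orphans <- rbind(orphans, data.frame(scaffold_id = idO,
            gene_id = orph, stringsAsFactors = FALSE))
    }
    sim$target <- GeneTable("target", p[, c("gene_id", "seq_id", "start",
        "end", "strand")], seqLengths = sl)
    sim$scaffolds <- data.frame(scaffold_id = names(sl),
        length_bp = as.numeric(sl), stringsAsFactors = FALSE)
    sim$truth$adjacencies <- newAdj
    sim$truth$scaffold_chromosome <- data.frame(
        scaffold_id = names(scafChrom),
        chromosome_id = as.character(scafChrom), stringsAsFactors = FALSE)
    sim$truth$orphans <- orphans
    sim$truth$scaffoldGenes <- genes
    sim
}

#' Write all simulation outputs to a directory
#'
#' Emits the gene tables, ortholog maps, scaffold lengths, anchor markers and
#' truth files of a simulation as TSVs, byte-identical across runs with the
#' same configuration.
#'
#' @param sim result of [simulateGenomes()].
#' @param outdir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
writeSimulation <- function(sim, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
        ancestor = file.path(outdir, "ancestor_genes.tsv"),
        refA = file.path(outdir, "refA_genes.tsv"),
        refB = file.path(outdir, "refB_genes.tsv"),
        target = file.path(outdir, "target_genes.tsv"),
        scaffolds = file.path(outdir, "scaffold_lengths.tsv"),
        markers = file.path(outdir, "anchor_markers.tsv"),
        mapA = file.path(outdir, "orthologs_refA.tsv"),
        mapB = file.path(outdir, "orthologs_refB.tsv"),
        truth_adjacencies = file.path(outdir, "truth_adjacencies.tsv"),
        truth_chromosomes = file.path(outdir, "truth_scaffold_chromosomes.tsv"),
        truth_events = file.path(outdir, "truth_events.tsv"))
    writeGeneTable(sim$ancestor, paths["ancestor"])
    writeGeneTable(sim$refA, paths["refA"])
    writeGeneTable(sim$refB, paths["refB"])
    writeGeneTable(sim$target, paths["target"])
    writeScaffoldLengths(sim$scaffolds, paths["scaffolds"])
    writeAnchorMarkers(sim$markers, paths["markers"])
    writeOrthologMap(sim$mapA, paths["mapA"])
    writeOrthologMap(sim$mapB, paths["mapB"])
    writeTsv(sim$truth$adjacencies, paths["truth_adjacencies"])
    writeTsv(sim$truth$scaffold_chromosome, paths["truth_chromosomes"])
    ev <- rbind(cbind(lineage = "refA", sim$truth$logs$refA),
        cbind(lineage = "refB", sim$truth$logs$refB))
    writeTsv(ev, paths["truth_events"])
    invisible(paths)
}
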
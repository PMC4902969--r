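## Shared builders and independent oracles for the test suite.

## GeneTable from an ordered gene list per sequence (coordinates laid out
## left to right, 100 bp genes with 50 bp gaps)
geneTableFromOrder <- function(genomeId, orders) {
    rows <- list()
    for (s in names(orders)) {
        g <- orders[[s]]
        starts <- (seq_along(g) - 1L) * 150
        rows[[s]] <- data.frame(gene_id = g, seq_id = s, start = starts,
            end = starts + 100, strand = "+", stringsAsFactors = FALSE)
    }
    GeneTable(genomeId, do.call(rbind, rows))
}

identityMap <- function(genes, ref = "A", target = "B") {
    OrthologMap(ref, target, data.frame(ref_gene_id = genes,
        target_gene_id = genes, stringsAsFactors = FALSE))
}

## Independent HSB oracle: interval-validity predicate + greedy maximal
## extension over the mapped-gene list (single sequence per genome).
## orderA/orderB: character vectors (full gene orders); mapped: shared genes.
bruteForceHsbBlocks <- function(orderA, orderB, mapped, minGenes = 1L) {
    a <- orderA[orderA %in% mapped]
    rankB <- match(a, orderB[orderB %in% mapped])
    valid <- function(i, j) {
        r <- rankB[i:j]
        if (length(r) == 1L) return(TRUE)
        d <- diff(r)
        all(d == 1L) || all(d == -1L)
    }
    blocks <- list()
    i <- 1L
    while (i <= length(a)) {
        j <- i
        while (j < length(a) && valid(i, j + 1L)) j <- j + 1L
        blocks[[length(blocks) + 1L]] <- a[i:j]
        i <- j + 1L
    }
    Filter(function(b) length(b) >= minGenes, blocks)
}

## Exhaustive parsimony: minimum change count over every assignment of
## together/apart to internal nodes (and to missing leaves, which are free)
bruteForceParsimony <- function(tree, states) {
    tips <- tree$tip.label
    nTip <- length(tips)
    total <- nTip + tree$Nnode
    fixed <- rep(NA_character_, total)
    for (i in seq_len(nTip)) {
        s <- states[[tips[i]]]
        if (s != "missing") fixed[i] <- s
    }
    freeNodes <- which(is.na(fixed))
    best <- Inf
    vals <- c("together", "apart")
    for (mask in 0:(2^length(freeNodes) - 1L)) {
        lab <- fixed
        bits <- as.integer(intToBits(mask))[seq_along(freeNodes)]
        lab[freeNodes] <- vals[bits + 1L]
        changes <- sum(lab[tree$edge[, 1L]] != lab[tree$edge[, 2L]])
        best <- min(best, changes)
    }
    best
}

## Independent breakpoint oracle: explicit capped unordered adjacency sets,
## minimum over the two reference orientations
oracleBreakpoints <- function(tgt, ref) {
    pairsOf <- function(x) {
        x <- c("(L)", x, "(R)")
        out <- character(length(x) - 1L)
        for (i in seq_len(length(x) - 1L)) {
            p <- sort(c(x[i], x[i + 1L]))
            out[i] <- paste(p[1L], p[2L])
        }
        out
    }
    score <- function(r) sum(!(pairsOf(tgt) %in% pairsOf(r)))
    min(score(ref), score(rev(ref)))
}

## Tiny deterministic scaffold length table
scafLengths <- function(ids, lens) {
    data.frame(scaffold_id = ids, length_bp = lens, stringsAsFactors = FALSE)
}

## Random rooted binary tree with n tips labelled t1..tn
randomRootedTree <- function(n) {
    tr <- ape::rtree(n, rooted = TRUE, tip.label = paste0("t", seq_len(n)))
    tr$edge.length <- NULL
    tr
}

## all permutations of 1..n as a list of integer vectors
allPermutations <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (sub in allPermutations(n - 1L)) {
        for (pos in seq_len(n)) {
            out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
        }
    }
    out
}

## write a data.frame to a throwaway TSV and return the path
withTsv <- function(d) {
    path <- tempfile(fileext = ".tsv")
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

squamateFixture <- function() {
    list(tree = ape::read.tree(syntenyAnchorExample("squamate_tree.nwk")),
        profiles = readKaryotypeProfiles(
            syntenyAnchorExample("squamate_profiles_synthetic.tsv")))
}
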
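## Homologous synteny block (HSB) detection and the marker-region acceptance
## filters applied to candidate block-endpoint targets.

#' Detect homologous synteny blocks between two genomes
#'
#' An HSB is a maximal run of genes that are consecutive in *both* genomes
#' (among the genes shared through the one-to-one ortholog map; genes absent
#' from the map are transparent and never break a block) with positions on
#' genome 2 monotone increasing or decreasing. By default detection is
#' orientation-agnostic; with `signed = TRUE` the relative strand of each
#' pair must additionally agree with the block's direction (same-direction
#' blocks need equal strands, inverted blocks opposite strands; pairs where
#' either strand is unknown are tolerated). Blocks with fewer than
#' `minGenes` genes are discarded. With `minGenes = 1` the result is a
#' partition of all mapped genes.
#'
#' @param tableA,tableB [GeneTable-class]s with ordinals assigned (genome 1
#'   and genome 2).
#' @param map an [OrthologMap-class] with `ref_gene_id` in `tableA` and
#'   `target_gene_id` in `tableB`.
#' @param minGenes minimum genes per reported block (default 2).
#' @param signed require strand consistency (default `FALSE`; gene-order
#'   tables do not always carry reliable strand).
#' @return data.frame with one row per block, sorted by genome 1 position:
#'   `block_id`, `seqA`, `startA`, `endA`, `first_geneA`, `last_geneA`,
#'   `ordA_lo`, `ordA_hi`, `seqB`, `startB`, `endB`, `n_genes`, `span_bp`
#'   (bp extent on genome 1), `orientation` (`same`, `inverted`, `unknown`).
#' @examples
#' a <- GeneTable("A", data.frame(gene_id = paste0("a", 1:6), seq_id = "c1",
#'     start = 0:5 * 100, end = 0:5 * 100 + 50))
#' b <- GeneTable("B", data.frame(gene_id = paste0("b", c(1, 2, 4, 3, 5, 6)),
#'     seq_id = "c1", start = 0:5 * 100, end = 0:5 * 100 + 50))
#' m <- OrthologMap("A", "B", data.frame(ref_gene_id = paste0("a", 1:6),
#'     target_gene_id = paste0("b", 1:6)))
#' detectHsbs(a, b, m)[, c("block_id", "n_genes", "orientation")]
#' @export
detectHsbs <- function(tableA, tableB, map, minGenes = 2L, signed = FALSE) {
    pairs <- orthologPairs(map)
    pA <- placements(tableA)
    pB <- placements(tableB)
    shared <- pairs[pairs$ref_gene_id %in% pA$gene_id &
        pairs$target_gene_id %in% pB$gene_id, , drop = FALSE]
    empty <- data.frame(block_id = character(), seqA = character(),
        startA = numeric(), endA = numeric(), first_geneA = character(),
        last_geneA = character(), ordA_lo = integer(), ordA_hi = integer(),
        seqB = character(), startB = numeric(), endB = numeric(),
        n_genes = integer(), span_bp = numeric(), orientation = character(),
        stringsAsFactors = FALSE)
    if (nrow(shared) == 0L) return(empty)

    iA <- match(shared$ref_gene_id, pA$gene_id)
    iB <- match(shared$target_gene_id, pB$gene_id)
    d <- data.frame(geneA = shared$ref_gene_id, geneB = shared$target_gene_id,
        seqA = pA$seq_id[iA], ordA = pA$ordinal[iA],
        startA = pA$start[iA], endA = pA$end[iA], strandA = pA$strand[iA],
        seqB = pB$seq_id[iB], ordB = pB$ordinal[iB],
        startB = pB$start[iB], endB = pB$end[iB], strandB = pB$strand[iB],
        stringsAsFactors = FALSE)
    ## ranks among mapped genes only (unmapped genes transparent)
    d <- d[order(d$seqA, d$ordA), , drop = FALSE]
    d$rankA <- as.integer(stats::ave(seq_len(nrow(d)), d$seqA, FUN = seq_along))
    oB <- order(d$seqB, d$ordB)
    rB <- integer(nrow(d))
    rB[oB] <- as.integer(stats::ave(seq_len(nrow(d)), d$seqB[oB],
        FUN = seq_along))
    d$rankB <- rB

    relStrand <- ifelse(d$strandA == "*" | d$strandB == "*", NA,
        ifelse(d$strandA == d$strandB, 1L, -1L))

    n <- nrow(d)
    newBlock <- rep(TRUE, n)
    dir <- integer(n)  # direction chosen at each position (0 = undecided)
    if (n >= 2L) {
        for (i in 2L:n) {
            sameA <- d$seqA[i] == d$seqA[i - 1L] & d$rankA[i] == d$rankA[i - 1L] + 1L
            sameB <- d$seqB[i] == d$seqB[i - 1L]
            step <- d$rankB[i] - d$rankB[i - 1L]
            ok <- sameA && sameB && abs(step) == 1L
            if (ok) {
                prevDir <- dir[i - 1L]
                if (prevDir != 0L && prevDir != step) ok <- FALSE
            }
            if (ok && signed) {
                ## both pairs in the run must match the run direction
                for (j in c(i - 1L, i)) {
                    rs <- relStrand[j]
                    if (!is.na(rs) && rs != step) { ok <- FALSE; break }
                }
            }
            if (ok) {
                newBlock[i] <- FALSE
                dir[i] <- step
                if (dir[i - 1L] == 0L) dir[i - 1L] <- step
            }
        }
    }
    blockIdx <- cumsum(newBlock)
    out <- do.call(rbind, lapply(split(seq_len(n), blockIdx), function(ii) {
        bd <- d[ii, ]
        ori <- if (length(ii) < 2L) "unknown" else
            if (bd$rankB[2L] > bd$rankB[1L]) "same" else "inverted"
        data.frame(seqA = bd$seqA[1L], startA = min(bd$startA),
            endA = max(bd$endA), first_geneA = bd$geneA[1L],
            last_geneA = bd$geneA[nrow(bd)],
            ordA_lo = min(bd$ordA), ordA_hi = max(bd$ordA),
            seqB = bd$seqB[1L], startB = min(bd$startB), endB = max(bd$endB),
            n_genes = nrow(bd), span_bp = max(bd$endA) - min(bd$startA),
            orientation = ori, stringsAsFactors = FALSE)
    }))
    out <- out[out$n_genes >= minGenes, , drop = FALSE]
    out <- out[order(out$seqA, out$startA), , drop = FALSE]
    if (nrow(out) == 0L) return(empty)
    out <- cbind(block_id = sprintf("HSB_%03d", seq_len(nrow(out))), out,
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Endpoint genes of an HSB
#'
#' Returns the two genes with extreme genome-1 ordinals in a block (the
#' natural targets for anchor probes). For a single-gene block both
#' endpoints are that gene.
#'
#' @param block one row of the data.frame returned by [detectHsbs()].
#' @return character vector `c(first, last)` of genome-1 gene ids.
#' @export
hsbEndpoints <- function(block) {
    stopifnot(is.data.frame(block), nrow(block) == 1L)
    c(first = block$first_geneA, last = block$last_geneA)
}

#' Select HSBs by size
#'
#' Ranks blocks by genome-1 bp span (descending; ties broken by `block_id`)
#' and returns either the `topN` largest or all blocks with span at least
#' `minSpan`.
#'
#' @param blocks data.frame from [detectHsbs()].
#' @param topN keep this many of the largest blocks.
#' @param minSpan keep all blocks with `span_bp >= minSpan`.
#' @return the selected subset, ranked by decreasing span.
#' @export
selectHsbsBySize <- function(blocks, topN = NULL, minSpan = NULL) {
    if (is.null(topN) == is.null(minSpan))
        stop("give exactly one of topN or minSpan")
    ord <- order(-blocks$span_bp, blocks$block_id)
    blocks <- blocks[ord, , drop = FALSE]
    if (!is.null(topN)) {
        if (topN < 0) stop("topN must be >= 0")
        blocks <- utils::head(blocks, topN)
    } else {
        blocks <- blocks[blocks$span_bp >= minSpan, , drop = FALSE]
    }
    rownames(blocks) <- NULL
    blocks
}

#' Percent identity of two aligned sequences
#'
#' Column-wise identity of two equal-length aligned nucleotide strings,
#' expressed as a percentage. Columns containing a gap (`-`) or `N` on
#' either side count as mismatches; comparison is case-insensitive.
#'
#' @param seq1,seq2 equal-length non-empty strings.
#' @return `100 * matches / columns`.
#' @examples
#' percentIdentity("ACGT", "ACGA")  # 75
#' @export
percentIdentity <- function(seq1, seq2) {
    stopifnot(is.character(seq1), is.character(seq2),
        length(seq1) == 1L, length(seq2) == 1L)
    if (nchar(seq1) == 0L || nchar(seq2) == 0L)
        stop("sequences must be non-empty")
    if (nchar(seq1) != nchar(seq2))
        stop("aligned sequences must have equal length")
    a <- strsplit(toupper(seq1), "", fixed = TRUE)[[1L]]
    b <- strsplit(toupper(seq2), "", fixed = TRUE)[[1L]]
    bad <- a %in% c("-", "N") | b %in% c("-", "N")
    100 * sum(a == b & !bad) / length(a)
}

#' Filter candidate marker regions
#'
#' Keeps regions passing both acceptance thresholds used for cytogenetic
#' probe targets: exon length of at least `minLen` bp and male/female
#' sequence identity of at least `minIdentity` percent. Both thresholds are
#' inclusive.
#'
#' @param regions data.frame with columns `length_bp` and `identity_pct`
#'   (any other columns are carried through).
#' @param minLen minimum region length in bp (default 100).
#' @param minIdentity minimum identity in percent (default 97).
#' @return the retained rows.
#' @export
filterMarkerRegions <- function(regions, minLen = 100, minIdentity = 97.0) {
    stopifnot(all(c("length_bp", "identity_pct") %in% names(regions)))
    keep <- regions$length_bp >= minLen & regions$identity_pct >= minIdentity
    out <- regions[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}
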
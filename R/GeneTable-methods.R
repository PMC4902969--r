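#' Construct a GeneTable
#'
#' Builds a [GeneTable-class] from a data.frame of gene placements, assigning
#' ordinals per sequence by start coordinate with deterministic ties broken by
#' `gene_id` (lexicographic). Coordinates are 0-based half-open; use
#' [readGeneTable()] for 1-based inclusive on-disk tables.
#'
#' @param genomeId single string naming the genome.
#' @param genes data.frame with columns `gene_id`, `seq_id`, `start`, `end`
#'   (0-based half-open) and optionally `strand` (defaults to `"*"`,
#'   unknown).
#' @param seqLengths named numeric vector of sequence lengths in bp. If
#'   `NULL`, each sequence's length is inferred as the maximum placement end.
#' @return a validated `GeneTable`.
#' @examples
#' gt <- GeneTable("toy", data.frame(
#'     gene_id = c("g2", "g1"), seq_id = "chr1",
#'     start = c(100, 0), end = c(200, 50)))
#' placements(gt)$ordinal  # 0 for g1, 1 for g2
#' @export
GeneTable <- function(genomeId, genes, seqLengths = NULL) {
    genes <- as.data.frame(genes)
    if (!"strand" %in% names(genes))
        genes$strand <- rep("*", nrow(genes))
    genes$strand[is.na(genes$strand)] <- "*"
    genes$gene_id <- as.character(genes$gene_id)
    genes$seq_id <- as.character(genes$seq_id)
    genes$start <- as.numeric(genes$start)
    genes$end <- as.numeric(genes$end)
    genes <- genes[order(genes$seq_id, genes$start, genes$gene_id), , drop = FALSE]
    # rows are grouped by seq_id after sorting, so per-group ranks line up
    genes$ordinal <- as.integer(stats::ave(seq_len(nrow(genes)), genes$seq_id,
        FUN = seq_along) - 1L)
    rownames(genes) <- NULL
    if (is.null(seqLengths)) {
        seqLengths <- vapply(split(genes$end, genes$seq_id), max, numeric(1))
    } else {
        seqLengths <- unlist(seqLengths)
    }
    new("GeneTable", genomeId = as.character(genomeId),
        placements = genes[, c("gene_id", "seq_id", "start", "end",
            "strand", "ordinal")],
        seqLengths = seqLengths)
}

#' @rdname GeneTable-class
#' @export
setMethod("genomeId", "GeneTable", function(x) x@genomeId)

#' @rdname GeneTable-class
#' @export
setMethod("placements", "GeneTable", function(x) x@placements)

#' @rdname GeneTable-class
#' @export
setMethod("seqLengths", "GeneTable", function(x) x@seqLengths)

setMethod("show", "GeneTable", function(object) {
    p <- object@placements
    cat(sprintf("GeneTable '%s': %d genes on %d sequence(s)\n",
        object@genomeId, nrow(p), length(unique(p$seq_id))))
    if (nrow(p) > 0L) {
        show(utils::head(p, 4L))
        if (nrow(p) > 4L) cat(sprintf("... and %d more placements\n", nrow(p) - 4L))
    }
})

#' Construct an OrthologMap from already one-to-one pairs
#'
#' @param refGenome,targetGenome genome names.
#' @param pairs data.frame with columns `ref_gene_id`, `target_gene_id`;
#'   must already satisfy the one-to-one invariant (otherwise an error is
#'   raised — use [enforceOneToOne()] on raw pairs).
#' @return an `OrthologMap`.
#' @export
OrthologMap <- function(refGenome, targetGenome, pairs) {
    pairs <- as.data.frame(pairs)
    pairs$ref_gene_id <- as.character(pairs$ref_gene_id)
    pairs$target_gene_id <- as.character(pairs$target_gene_id)
    pairs <- pairs[order(pairs$ref_gene_id), c("ref_gene_id", "target_gene_id"),
        drop = FALSE]
    rownames(pairs) <- NULL
    new("OrthologMap", refGenome = as.character(refGenome),
        targetGenome = as.character(targetGenome), pairs = pairs)
}

#' @rdname OrthologMap-class
#' @export
setMethod("orthologPairs", "OrthologMap", function(x) x@pairs)

setMethod("show", "OrthologMap", function(object) {
    cat(sprintf("OrthologMap %s -> %s: %d one-to-one pairs\n",
        object@refGenome, object@targetGenome, nrow(object@pairs)))
})

#' Filter raw ortholog pairs to a one-to-one map
#'
#' Any gene (reference or target side) participating in more than one pair is
#' removed together with *all* of its pairs. The result is independent of the
#' input row order, so many-to-many ambiguities are never resolved by
#' accident of ordering.
#'
#' @param rawPairs data.frame with columns `ref_gene_id`, `target_gene_id`
#'   (duplicated rows are collapsed first).
#' @param refGenome,targetGenome genome names recorded in the result.
#' @return an [OrthologMap-class]. An empty input yields an empty map.
#' @examples
#' raw <- data.frame(ref_gene_id = c("a", "a", "b"),
#'     target_gene_id = c("x", "y", "z"))
#' orthologPairs(enforceOneToOne(raw))  # only (b, z) survives
#' @export
enforceOneToOne <- function(rawPairs, refGenome = "ref", targetGenome = "target") {
    rawPairs <- as.data.frame(rawPairs)
    if (nrow(rawPairs) == 0L) {
        return(OrthologMap(refGenome, targetGenome,
            data.frame(ref_gene_id = character(), target_gene_id = character())))
    }
    rawPairs$ref_gene_id <- as.character(rawPairs$ref_gene_id)
    rawPairs$target_gene_id <- as.character(rawPairs$target_gene_id)
    rawPairs <- unique(rawPairs[, c("ref_gene_id", "target_gene_id")])
    refCount <- table(rawPairs$ref_gene_id)
    tgtCount <- table(rawPairs$target_gene_id)
    keep <- refCount[rawPairs$ref_gene_id] == 1L &
        tgtCount[rawPairs$target_gene_id] == 1L
    OrthologMap(refGenome, targetGenome, rawPairs[keep, , drop = FALSE])
}

#' @rdname SuperScaffoldSet-class
#' @export
setMethod("superscaffoldMembers", "SuperScaffoldSet", function(x) x@members)

#' @rdname SuperScaffoldSet-class
#' @export
setMethod("superscaffoldJoins", "SuperScaffoldSet", function(x) x@joins)

setMethod("show", "SuperScaffoldSet", function(object) {
    m <- object@members
    nss <- length(unique(m$name))
    multi <- sum(table(m$name) > 1L)
    cat(sprintf("SuperScaffoldSet: %d scaffold(s) in %d unit(s) (%d multi-member)\n",
        nrow(m), nss, multi))
})
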
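## Comparative chromosome maps: per-unit reference homology, maximal
## homology segments along each target chromosome, and inter-/intra-
## chromosomal rearrangement counting.

#' Reference-chromosome homology of an anchored unit
#'
#' The reference chromosome carrying the plurality of the unit's mapped
#' genes. A tie, or a unit with no mapped genes, is flagged as unknown
#' (`"Un"`) rather than resolved arbitrarily.
#'
#' @param unitScaffolds character vector of the unit's member scaffold ids.
#' @param target [GeneTable-class] of the fragmented genome.
#' @param ref reference [GeneTable-class].
#' @param map [OrthologMap-class] (`ref_gene_id` in `ref`, `target_gene_id`
#'   in `target`).
#' @return single reference chromosome id, or `"Un"`.
#' @export
homologyOfUnit <- function(unitScaffolds, target, ref, map) {
    pT <- placements(target)
    pR <- placements(ref)
    pairs <- orthologPairs(map)
    genes <- pT$gene_id[pT$seq_id %in% unitScaffolds]
    hit <- pairs[pairs$target_gene_id %in% genes &
        pairs$ref_gene_id %in% pR$gene_id, , drop = FALSE]
    if (nrow(hit) == 0L) return("Un")
    chroms <- pR$seq_id[match(hit$ref_gene_id, pR$gene_id)]
    tab <- sort(table(chroms), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) return("Un")
    names(tab)[1L]
}

#' Homology segments and interchromosomal events along target chromosomes
#'
#' Units are ordered along each target chromosome by Flpter. The dominant
#' homolog of a chromosome is the reference chromosome with the greatest
#' anchored bp. Each maximal run of consecutive units whose homolog differs
#' from the dominant one counts as one interchromosomal rearrangement; units
#' of unknown homology (`"Un"`) are not informative and are excluded before
#' runs are formed.
#'
#' @param unitMap data.frame with one row per anchored unit: `unit_id`,
#'   `target_chromosome`, `flpter` (position of the unit along the
#'   chromosome), `homolog` (reference chromosome or `"Un"`),
#'   `anchored_bp`.
#' @return list with `segments` (maximal runs: `target_chromosome`,
#'   `homolog`, `n_units`, `start_flpter`, `end_flpter`, `is_foreign`),
#'   `per_chromosome` (data.frame `target_chromosome`, `dominant_homolog`,
#'   `n_events`), and `n_events` (genome-wide sum).
#' @export
interchromosomalEvents <- function(unitMap) {
    req <- c("unit_id", "target_chromosome", "flpter", "homolog", "anchored_bp")
    stopifnot(all(req %in% names(unitMap)))
    segs <- list(); perChrom <- list()
    for (ch in sort(unique(unitMap$target_chromosome))) {
        um <- unitMap[unitMap$target_chromosome == ch &
            unitMap$homolog != "Un", , drop = FALSE]
        if (nrow(um) == 0L) {
            perChrom[[ch]] <- data.frame(target_chromosome = ch,
                dominant_homolog = "Un", n_events = 0L,
                stringsAsFactors = FALSE)
            next
        }
        um <- um[order(um$flpter, um$unit_id), , drop = FALSE]
        bp <- tapply(um$anchored_bp, um$homolog, sum)
        dom <- names(bp)[order(-bp, names(bp))][1L]
        runId <- cumsum(c(TRUE, um$homolog[-1L] != um$homolog[-nrow(um)]))
        for (r in unique(runId)) {
            ii <- which(runId == r)
            segs[[length(segs) + 1L]] <- data.frame(
                target_chromosome = ch, homolog = um$homolog[ii[1L]],
                n_units = length(ii),
                start_flpter = min(um$flpter[ii]),
                end_flpter = max(um$flpter[ii]),
                is_foreign = um$homolog[ii[1L]] != dom,
                stringsAsFactors = FALSE)
        }
        nEv <- sum(vapply(segs, function(s)
            s$target_chromosome == ch && s$is_foreign, logical(1)))
        perChrom[[ch]] <- data.frame(target_chromosome = ch,
            dominant_homolog = dom, n_events = nEv, stringsAsFactors = FALSE)
    }
    segments <- if (length(segs)) do.call(rbind, segs) else
        data.frame(target_chromosome = character(), homolog = character(),
            n_units = integer(), start_flpter = numeric(),
            end_flpter = numeric(), is_foreign = logical())
    perChromosome <- do.call(rbind, perChrom)
    rownames(perChromosome) <- NULL
    list(segments = segments, per_chromosome = perChromosome,
        n_events = sum(perChromosome$n_events))
}

#' Intrachromosomal breakpoint count between two unit orders
#'
#' Counts order breakpoints between the arrangement of units along a target
#' chromosome and their arrangement in the reference. Both orders are
#' extended with virtual chromosome ends; a breakpoint is a target-adjacent
#' pair (ends included) that is not adjacent in the capped reference order,
#' minimised over the two reference orientations. The count is 0 exactly
#' when the orders agree up to full reversal (in particular, always 0 for
#' two units or fewer).
#'
#' @param targetOrder,refOrder character vectors over the same unit set.
#' @return integer breakpoint count.
#' @examples
#' intrachromosomalBreakpoints(c("u1", "u3", "u2"), c("u1", "u2", "u3"))  # 2
#' @export
intrachromosomalBreakpoints <- function(targetOrder, refOrder) {
    if (!setequal(targetOrder, refOrder) ||
        length(targetOrder) != length(refOrder) ||
        anyDuplicated(targetOrder) || anyDuplicated(refOrder))
        stop("targetOrder and refOrder must be over the same unit set")
    n <- length(targetOrder)
    if (n <= 2L) return(0L)
    adjacencies <- function(x) {
        x <- c(".L", x, ".R")
        a <- x[-length(x)]; b <- x[-1L]
        paste(pmin(a, b), pmax(a, b), sep = "\r")  # unordered pairs
    }
    countAgainst <- function(refo) {
        ref <- adjacencies(refo)
        tgt <- adjacencies(targetOrder)
        sum(!(tgt %in% ref))
    }
    min(countAgainst(refOrder), countAgainst(rev(refOrder)))
}
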
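#' @import methods
NULL

#' GeneTable: ordered gene placements for one genome
#'
#' Holds the gene order of a single genome, resolved either to chromosomes or
#' to assembly scaffolds. Placements are stored with 0-based half-open
#' coordinates; on-disk tables use the 1-based inclusive genomics TSV
#' convention (see [readGeneTable()]). Each sequence carries a dense ordinal
#' rank (0..n-1) assigned by start coordinate, with ties broken by gene id so
#' that ordering is deterministic. All synteny operations in the package work
#' on these ordinals, never on raw coordinates.
#'
#' @slot genomeId single string naming the genome.
#' @slot placements data.frame with columns `gene_id`, `seq_id`, `start`,
#'   `end` (0-based half-open), `strand` (`+`, `-` or `*` for unknown) and
#'   `ordinal` (integer rank within `seq_id`).
#' @slot seqLengths named numeric vector of sequence lengths in bp; every
#'   placement's `seq_id` must be present and `end <= length`.
#'
#' @seealso [GeneTable()], [readGeneTable()], [detectHsbs()], [proposeJoins()]
#' @exportClass GeneTable
setClass("GeneTable",
    slots = c(
        genomeId = "character",
        placements = "data.frame",
        seqLengths = "numeric"
    )
)

setValidity("GeneTable", function(object) {
    p <- object@placements
    req <- c("gene_id", "seq_id", "start", "end", "strand", "ordinal")
    if (!all(req %in% names(p)))
        return(paste("placements must have columns:", paste(req, collapse = ", ")))
    if (length(object@genomeId) != 1L || is.na(object@genomeId))
        return("genomeId must be a single non-NA string")
    if (nrow(p) == 0L)
        return(TRUE)
    if (anyDuplicated(p$gene_id))
        return("duplicate gene_id within one genome")
    if (any(p$start < 0))
        return("start must be >= 0")
    if (any(p$end <= p$start))
        return("end must be > start (0-based half-open)")
    if (!all(p$strand %in% c("+", "-", "*")))
        return("strand must be one of '+', '-', '*'")
    sl <- object@seqLengths
    if (!all(p$seq_id %in% names(sl)))
        return("every placement seq_id needs an entry in seqLengths")
    if (any(p$end > sl[p$seq_id]))
        return("placement end exceeds sequence length")
    # ordinals: contiguous 0..n-1 permutation per seq_id, ordered by start
    for (s in unique(p$seq_id)) {
        q <- p[p$seq_id == s, ]
        o <- sort(q$ordinal)
        if (!identical(as.integer(o), seq_len(nrow(q)) - 1L))
            return(sprintf("ordinals on %s are not a contiguous 0..n-1 permutation", s))
        q <- q[order(q$ordinal), ]
        if (is.unsorted(q$start))
            return(sprintf("ordinal order on %s does not follow start coordinate", s))
    }
    TRUE
})

#' OrthologMap: one-to-one gene correspondences between two genomes
#'
#' Stores filtered one-to-one ortholog pairs between a reference genome and a
#' target genome. The validity method enforces that each gene (on either
#' side) occurs at most once; use [enforceOneToOne()] to filter raw
#' many-to-many pairs down to the valid set.
#'
#' @slot refGenome,targetGenome single strings naming the two genomes.
#' @slot pairs data.frame with character columns `ref_gene_id`,
#'   `target_gene_id`.
#'
#' @seealso [enforceOneToOne()], [readOrthologMap()]
#' @exportClass OrthologMap
setClass("OrthologMap",
    slots = c(
        refGenome = "character",
        targetGenome = "character",
        pairs = "data.frame"
    )
)

setValidity("OrthologMap", function(object) {
    p <- object@pairs
    if (!all(c("ref_gene_id", "target_gene_id") %in% names(p)))
        return("pairs must have columns ref_gene_id, target_gene_id")
    if (anyDuplicated(p$ref_gene_id))
        return("a ref_gene_id occurs in more than one pair (not one-to-one)")
    if (anyDuplicated(p$target_gene_id))
        return("a target_gene_id occurs in more than one pair (not one-to-one)")
    TRUE
})

#' SuperScaffoldSet: chained scaffolds with join provenance
#'
#' The result of [chainJoins()]: a partition of all input scaffolds into
#' ordered, oriented super-scaffolds (singletons included). Names follow the
#' hyphenated-integer convention of [nameSuperscaffold()]. The `joins` slot
#' records, for every internal junction, the scaffold ends involved and the
#' bridge genes supporting the join in each reference.
#'
#' @slot members data.frame with columns `name` (super-scaffold id),
#'   `position` (1-based rank along the super-scaffold), `scaffold_id`,
#'   `orientation` (`+` or `-`).
#' @slot joins data.frame of consensus junctions retained in the chains
#'   (columns as returned by [consensusJoins()] plus `name`).
#'
#' @seealso [chainJoins()], [superscaffoldSizes()], [nameSuperscaffold()]
#' @exportClass SuperScaffoldSet
setClass("SuperScaffoldSet",
    slots = c(
        members = "data.frame",
        joins = "data.frame"
    )
)

setValidity("SuperScaffoldSet", function(object) {
    m <- object@members
    if (!all(c("name", "position", "scaffold_id", "orientation") %in% names(m)))
        return("members must have columns name, position, scaffold_id, orientation")
    if (nrow(m) > 0L && anyDuplicated(m$scaffold_id))
        return("a scaffold belongs to more than one super-scaffold")
    if (nrow(m) > 0L && !all(m$orientation %in% c("+", "-")))
        return("orientation must be '+' or '-'")
    TRUE
})
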
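## Readers and writers for the flat tables used throughout the package.
## Convention: coordinates are 1-based inclusive in files (genomics TSV
## style) and 0-based half-open in memory. Every writer/reader pair
## round-trips losslessly.

readTsv <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t",
        stringsAsFactors = FALSE, colClasses = NA, check.names = FALSE)
}

writeTsv <- function(x, path) {
    ok <- tryCatch({
        utils::write.table(x, path, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = TRUE)
        TRUE
    }, error = function(e) e, warning = function(w) w)
    if (!isTRUE(ok))
        stop("cannot write to '", path, "': ", conditionMessage(ok))
    invisible(path)
}

#' Read a gene-order table
#'
#' Reads a TSV with header columns `gene_id`, `seq_id`, `start`, `end`,
#' `strand`, where coordinates are 1-based inclusive. Internally the table is
#' converted to 0-based half-open and ordinals are assigned by start
#' coordinate (ties broken by `gene_id`).
#'
#' @param path TSV file path.
#' @param genomeId genome name to record.
#' @param seqLengths optional named numeric vector (or data.frame with
#'   columns `seq_id`, `length_bp`) of sequence lengths; inferred from
#'   placements when absent.
#' @return a [GeneTable-class].
#' @seealso [writeGeneTable()]
#' @export
readGeneTable <- function(path, genomeId, seqLengths = NULL) {
    d <- readTsv(path)
    req <- c("gene_id", "seq_id", "start", "end", "strand")
    if (!all(req %in% names(d)))
        stop("gene table must have columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(d$gene_id)) {
        dup <- d$gene_id[duplicated(d$gene_id)][1L]
        stop("duplicate gene_id '", dup, "' in ", path)
    }
    bad <- which(d$end < d$start)
    if (length(bad) > 0L)
        stop(sprintf("end < start at row %d (gene '%s') in %s",
            bad[1L], d$gene_id[bad[1L]], path))
    if (any(d$start < 1))
        stop("1-based start must be >= 1 in ", path)
    d$start <- d$start - 1  # to 0-based half-open; inclusive end is kept
    if (is.data.frame(seqLengths))
        seqLengths <- stats::setNames(seqLengths$length_bp, seqLengths$seq_id)
    GeneTable(genomeId, d, seqLengths = seqLengths)
}

#' Write a gene-order table
#'
#' Writes the 1-based inclusive on-disk form of a [GeneTable-class], rows
#' sorted by sequence and ordinal. `readGeneTable(writeGeneTable(x))`
#' reproduces `x` given the same `seqLengths`.
#'
#' @param x a `GeneTable`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeGeneTable <- function(x, path) {
    p <- placements(x)
    p <- p[order(p$seq_id, p$ordinal), , drop = FALSE]
    out <- data.frame(gene_id = p$gene_id, seq_id = p$seq_id,
        start = p$start + 1, end = p$end, strand = p$strand)
    writeTsv(out, path)
}

#' Read/write one-to-one ortholog maps
#'
#' The on-disk format is a TSV with columns `ref_gene_id`, `target_gene_id`.
#' `readOrthologMap()` validates the one-to-one invariant (use
#' [enforceOneToOne()] for raw many-to-many pairs).
#'
#' @param path TSV path.
#' @param refGenome,targetGenome genome names to record.
#' @return `readOrthologMap()`: an [OrthologMap-class]; `writeOrthologMap()`:
#'   the path, invisibly.
#' @export
readOrthologMap <- function(path, refGenome = "ref", targetGenome = "target") {
    d <- readTsv(path)
    OrthologMap(refGenome, targetGenome, d)
}

#' @rdname readOrthologMap
#' @param x an `OrthologMap`.
#' @export
writeOrthologMap <- function(x, path) {
    writeTsv(orthologPairs(x), path)
}

#' Read/write scaffold length tables
#'
#' TSV with columns `scaffold_id`, `length_bp`; ids must be unique and
#' lengths positive.
#'
#' @param path TSV path.
#' @return `readScaffoldLengths()`: data.frame with columns `scaffold_id`,
#'   `length_bp`.
#' @export
readScaffoldLengths <- function(path) {
    d <- readTsv(path)
    validateScaffoldLengths(d)
}

validateScaffoldLengths <- function(d) {
    if (!all(c("scaffold_id", "length_bp") %in% names(d)))
        stop("scaffold lengths need columns scaffold_id, length_bp")
    d$scaffold_id <- as.character(d$scaffold_id)
    d$length_bp <- as.numeric(d$length_bp)
    if (anyDuplicated(d$scaffold_id))
        stop("duplicate scaffold_id in scaffold length table")
    if (any(d$length_bp <= 0))
        stop("scaffold length_bp must be positive")
    d[, c("scaffold_id", "length_bp")]
}

#' @rdname readScaffoldLengths
#' @param x data.frame of scaffold lengths.
#' @export
writeScaffoldLengths <- function(x, path) {
    writeTsv(validateScaffoldLengths(x), path)
}

#' Read/write anchor-marker tables
#'
#' Anchor markers tie a scaffold position to a chromosome, optionally with a
#' fractional cytogenetic position (Flpter, 0 = p terminus). TSV columns:
#' `marker_id`, `scaffold_id`, `position_bp`, `chromosome_id`, `flpter`
#' (may be `NA`).
#'
#' @param path TSV path.
#' @param scaffoldLengths optional scaffold length table; when given, each
#'   marker position is checked against its scaffold's length.
#' @return `readAnchorMarkers()`: validated data.frame.
#' @export
readAnchorMarkers <- function(path, scaffoldLengths = NULL) {
    d <- readTsv(path)
    validateAnchorMarkers(d, scaffoldLengths)
}

validateAnchorMarkers <- function(d, scaffoldLengths = NULL) {
    req <- c("marker_id", "scaffold_id", "position_bp", "chromosome_id")
    if (!all(req %in% names(d)))
        stop("anchor markers need columns: ", paste(req, collapse = ", "))
    if (!"flpter" %in% names(d))
        d$flpter <- NA_real_
    d$marker_id <- as.character(d$marker_id)
    d$scaffold_id <- as.character(d$scaffold_id)
    d$chromosome_id <- as.character(d$chromosome_id)
    d$position_bp <- as.numeric(d$position_bp)
    d$flpter <- as.numeric(d$flpter)
    bad <- !is.na(d$flpter) & (d$flpter < 0 | d$flpter > 1)
    if (any(bad))
        stop("flpter values must lie in [0, 1]")
    if (!is.null(scaffoldLengths)) {
        sl <- stats::setNames(scaffoldLengths$length_bp, scaffoldLengths$scaffold_id)
        if (!all(d$scaffold_id %in% names(sl)))
            stop("marker names unknown scaffold: ",
                d$scaffold_id[!d$scaffold_id %in% names(sl)][1L])
        if (any(d$position_bp < 0 | d$position_bp > sl[d$scaffold_id]))
            stop("marker position_bp outside scaffold length")
    }
    d[, c("marker_id", "scaffold_id", "position_bp", "chromosome_id", "flpter")]
}

#' @rdname readAnchorMarkers
#' @param x data.frame of anchor markers.
#' @export
writeAnchorMarkers <- function(x, path) {
    writeTsv(validateAnchorMarkers(x), path)
}

#' Read/write karyotype profiles
#'
#' A karyotype profile records, per species, which homology-segment labels
#' sit on which chromosome (one row per segment). Within a species a segment
#' label may occur on a single chromosome only. TSV columns: `species_id`,
#' `chromosome_id`, `segment`.
#'
#' @param path TSV path.
#' @return `readKaryotypeProfiles()`: validated data.frame.
#' @seealso [buildColocationCharacters()]
#' @export
readKaryotypeProfiles <- function(path) {
    validateKaryotypeProfiles(readTsv(path))
}

validateKaryotypeProfiles <- function(d) {
    req <- c("species_id", "chromosome_id", "segment")
    if (!all(req %in% names(d)))
        stop("karyotype profiles need columns: ", paste(req, collapse = ", "))
    for (col in req) d[[col]] <- as.character(d[[col]])
    d <- unique(d[, req])
    chk <- unique(d[, c("species_id", "segment")])
    if (nrow(chk) != nrow(d)) {
        off <- d[duplicated(d[, c("species_id", "segment")]), ]
        stop(sprintf("segment '%s' appears on two chromosomes of species '%s'",
            off$segment[1L], off$species_id[1L]))
    }
    d
}

#' @rdname readKaryotypeProfiles
#' @param x data.frame of karyotype profiles.
#' @export
writeKaryotypeProfiles <- function(x, path) {
    writeTsv(validateKaryotypeProfiles(x), path)
}

#' Read a chromosome model table
#'
#' TSV columns: `chromosome_id`, `class` (`macro`, `micro` or `sex`) and
#' `est_size_bp` (positive estimated chromosome size).
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readChromosomeSizes <- function(path) {
    d <- readTsv(path)
    if (!all(c("chromosome_id", "est_size_bp") %in% names(d)))
        stop("chromosome sizes need columns chromosome_id, est_size_bp")
    if (!"class" %in% names(d)) d$class <- "macro"
    d$chromosome_id <- as.character(d$chromosome_id)
    if (any(d$est_size_bp <= 0))
        stop("est_size_bp must be positive")
    d[, c("chromosome_id", "class", "est_size_bp")]
}
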
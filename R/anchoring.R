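## Assignment of scaffolds / super-scaffolds to chromosomes via anchor
## markers, conservative conflict detection, and coverage accounting.

#' Scaffold-to-unit membership from a SuperScaffoldSet
#'
#' Helper mapping every scaffold to its anchoring unit (its super-scaffold
#' name, or its own singleton name).
#'
#' @param units a [SuperScaffoldSet-class] or a data.frame with columns
#'   `scaffold_id`, `name`.
#' @return named character vector scaffold_id -> unit name.
#' @export
unitMembership <- function(units) {
    m <- if (is(units, "SuperScaffoldSet")) superscaffoldMembers(units) else
        as.data.frame(units)
    stats::setNames(m$name, m$scaffold_id)
}

#' Assign units to chromosomes via anchor markers
#'
#' Each marker ties a scaffold (hence its containing unit) to a chromosome.
#' A unit whose markers all agree is assigned to that chromosome; a unit
#' with markers on two or more chromosomes is *not* assigned — it is
#' reported as a conflict (a potential assembly error), never resolved by
#' majority vote. Units without markers stay unassigned.
#'
#' @param units a [SuperScaffoldSet-class] (or membership data.frame); every
#'   marker's scaffold must belong to a unit.
#' @param markers anchor-marker data.frame (see [readAnchorMarkers()]).
#' @return list with elements `assignments` (data.frame `unit_id`,
#'   `chromosome_id`, `n_markers`), `conflicts` (data.frame `unit_id`,
#'   `chromosomes`, `markers`), and `unassigned` (character vector of
#'   markerless unit ids).
#' @export
assignUnits <- function(units, markers) {
    markers <- validateAnchorMarkers(markers)
    membership <- unitMembership(units)
    unknown <- setdiff(markers$scaffold_id, names(membership))
    if (length(unknown) > 0L)
        stop("marker names unknown scaffold: ", unknown[1L])
    markers$unit_id <- membership[markers$scaffold_id]
    assignments <- data.frame(unit_id = character(),
        chromosome_id = character(), n_markers = integer(),
        stringsAsFactors = FALSE)
    conflicts <- data.frame(unit_id = character(), chromosomes = character(),
        markers = character(), stringsAsFactors = FALSE)
    for (u in sort(unique(markers$unit_id))) {
        mk <- markers[markers$unit_id == u, , drop = FALSE]
        chroms <- sort(unique(mk$chromosome_id))
        if (length(chroms) == 1L) {
            assignments <- rbind(assignments, data.frame(unit_id = u,
                chromosome_id = chroms, n_markers = nrow(mk),
                stringsAsFactors = FALSE))
        } else {
            conflicts <- rbind(conflicts, data.frame(unit_id = u,
                chromosomes = paste(chroms, collapse = ","),
                markers = paste(mk$marker_id, collapse = ","),
                stringsAsFactors = FALSE))
        }
    }
    unassigned <- setdiff(unique(membership),
        c(assignments$unit_id, conflicts$unit_id))
    list(assignments = assignments, conflicts = conflicts,
        unassigned = sort(unassigned))
}

#' Per-chromosome anchored-sequence coverage
#'
#' Sums the lengths of all scaffolds belonging to units assigned to each
#' chromosome and expresses them against estimated chromosome sizes. Totals
#' are recomputed from the rows (never taken from any printed total). A
#' percentage above 100 signals a bad size estimate and triggers a warning,
#' but the value is reported as computed.
#'
#' @param assignment result of [assignUnits()] (or its `assignments`
#'   element).
#' @param units the [SuperScaffoldSet-class] (or membership data.frame) used
#'   for assignment.
#' @param scaffolds scaffold length table.
#' @param chromosomes chromosome model table (`chromosome_id`, `class`,
#'   `est_size_bp`); see [readChromosomeSizes()].
#' @return data.frame with one row per chromosome plus a `Total` row:
#'   `chromosome_id`, `class`, `n_units`, `anchored_bp`, `anchored_Mb`
#'   (1 decimal), `percent` (1 decimal, of estimated size).
#' @export
coverageTable <- function(assignment, units, scaffolds, chromosomes) {
    if (is.list(assignment) && !is.data.frame(assignment))
        assignment <- assignment$assignments
    scaffolds <- validateScaffoldLengths(scaffolds)
    membership <- unitMembership(units)
    lens <- stats::setNames(scaffolds$length_bp, scaffolds$scaffold_id)
    unitBp <- tapply(lens[names(membership)], membership, sum)
    rows <- lapply(seq_len(nrow(chromosomes)), function(i) {
        ch <- chromosomes$chromosome_id[i]
        au <- assignment$unit_id[assignment$chromosome_id == ch]
        bp <- sum(unitBp[au], na.rm = TRUE)
        pct <- 100 * bp / chromosomes$est_size_bp[i]
        data.frame(chromosome_id = ch, class = chromosomes$class[i],
            n_units = length(au), anchored_bp = bp,
            anchored_Mb = round(bp / 1e6, 1), percent = round(pct, 1),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (any(out$percent > 100))
        warning("anchored sequence exceeds estimated size for: ",
            paste(out$chromosome_id[out$percent > 100], collapse = ", "))
    totalBp <- sum(out$anchored_bp)
    totalEst <- sum(chromosomes$est_size_bp)
    out <- rbind(out, data.frame(chromosome_id = "Total", class = "",
        n_units = sum(out$n_units), anchored_bp = totalBp,
        anchored_Mb = round(totalBp / 1e6, 1),
        percent = round(100 * totalBp / totalEst, 1),
        stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
}

#' Fractional length from the p terminus
#'
#' Converts a physical position on a chromosome into a Flpter value: the
#' fraction of the chromosome length measured from the p terminus (0 = p
#' end, 1 = q end).
#'
#' @param positionBp position in bp, `0 <= positionBp <= chromLengthBp`.
#' @param chromLengthBp chromosome length in bp (> 0).
#' @return fraction in `[0, 1]`.
#' @export
flpter <- function(positionBp, chromLengthBp) {
    stopifnot(chromLengthBp > 0)
    if (any(positionBp < 0 | positionBp > chromLengthBp))
        stop("position outside [0, chromosome length]")
    positionBp / chromLengthBp
}

#' Sequence and gene totals for one chromosome
#'
#' Sums scaffold lengths and per-scaffold gene counts over all scaffolds
#' belonging to units assigned to the named chromosome (the accounting used
#' for sex-chromosome gene content).
#'
#' @param assignment result of [assignUnits()] (or its `assignments`
#'   element).
#' @param units [SuperScaffoldSet-class] or membership data.frame.
#' @param scaffolds scaffold length table.
#' @param geneCounts data.frame with columns `scaffold_id`, `n_genes`.
#' @param chromosome chromosome id to report (e.g. `"Z"`).
#' @return list with `total_bp`, `total_genes`, and the contributing
#'   `scaffold_ids`.
#' @export
chromosomeContent <- function(assignment, units, scaffolds, geneCounts,
        chromosome) {
    if (is.list(assignment) && !is.data.frame(assignment))
        assignment <- assignment$assignments
    scaffolds <- validateScaffoldLengths(scaffolds)
    membership <- unitMembership(units)
    unitsOn <- assignment$unit_id[assignment$chromosome_id == chromosome]
    scafs <- names(membership)[membership %in% unitsOn]
    lens <- stats::setNames(scaffolds$length_bp, scaffolds$scaffold_id)
    cnts <- stats::setNames(geneCounts$n_genes, geneCounts$scaffold_id)
    list(total_bp = sum(lens[scafs]),
        total_genes = sum(cnts[intersect(scafs, names(cnts))]),
        scaffold_ids = sort(scafs))
}
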
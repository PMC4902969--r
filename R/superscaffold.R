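## Reference-assisted super-scaffolding: propose scaffold joins from each
## reference's gene order (skipping orphaned terminal genes), keep
## dual-reference consensus joins, and chain them into super-scaffolds.

junctionKey <- function(s1, e1, s2, e2) {
    a <- paste0(s1, ":", e1); b <- paste0(s2, ":", e2)
    ifelse(a <= b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

emptyJoins <- function() {
    data.frame(junction = character(), left_scaffold = character(),
        left_end = character(), right_scaffold = character(),
        right_end = character(), supporting_ref = character(),
        bridge_genes = character(), n_bridge_genes = integer(),
        skipped_orphans = character(), fork = logical(),
        stringsAsFactors = FALSE)
}

#' Propose scaffold joins from one reference's gene order
#'
#' Walks each reference chromosome's mapped genes in order (genes absent
#' from the ortholog map are transparent) and proposes a join between two
#' scaffolds whenever the mapped terminal gene at one scaffold's end and the
#' mapped terminal gene at another scaffold's end occupy adjacent positions
#' in the reference. The junction's bridge is the run of consecutive
#' reference genes spanning it.
#'
#' An *orphaned terminal gene* is the sole mapped gene of a scaffold that is
#' reference-adjacent to terminal genes of two different scaffolds: it links
#' in both directions and would fork the chain. With `skipOrphans = TRUE`
#' (default) such scaffolds are made transparent too — the flanking join is
#' proposed with the orphan recorded in `skipped_orphans`, and the orphan
#' scaffold is left to be emitted as a singleton (single-gene scaffolds are
#' retained, never deleted). With `skipOrphans = FALSE` the two competing
#' candidates are emitted flagged as a fork instead of being silently
#' resolved.
#'
#' @param target [GeneTable-class] of the fragmented genome
#'   (scaffold-resolved).
#' @param ref [GeneTable-class] of a reference genome
#'   (chromosome-resolved).
#' @param map [OrthologMap-class] with `ref_gene_id` in `ref` and
#'   `target_gene_id` in `target`.
#' @param skipOrphans skip orphaned terminal genes (default `TRUE`).
#' @param minSupportGenes number of mapped genes at each scaffold end that
#'   must form a consecutive monotone run in the reference for the join to
#'   be proposed (default 1 = only the terminal genes themselves must abut).
#' @return data.frame of join candidates with columns `junction`,
#'   `left_scaffold`, `left_end`, `right_scaffold`, `right_end`,
#'   `supporting_ref`, `bridge_genes` (comma-joined reference gene ids),
#'   `n_bridge_genes`, `skipped_orphans` (comma-joined `scaffold:gene`),
#'   `fork` (ambiguous two-direction link).
#' @seealso [consensusJoins()], [chainJoins()]
#' @export
proposeJoins <- function(target, ref, map, skipOrphans = TRUE,
        minSupportGenes = 1L) {
    pairs <- orthologPairs(map)
    pT <- placements(target)
    pR <- placements(ref)
    shared <- pairs[pairs$ref_gene_id %in% pR$gene_id &
        pairs$target_gene_id %in% pT$gene_id, , drop = FALSE]
    if (nrow(shared) == 0L) return(emptyJoins())
    iR <- match(shared$ref_gene_id, pR$gene_id)
    iT <- match(shared$target_gene_id, pT$gene_id)
    d <- data.frame(refGene = shared$ref_gene_id,
        tgtGene = shared$target_gene_id,
        refSeq = pR$seq_id[iR], refOrd = pR$ordinal[iR],
        scaffold = pT$seq_id[iT], tgtOrd = pT$ordinal[iT],
        stringsAsFactors = FALSE)
    ## per-scaffold mapped-gene bookkeeping (mapped ordinal rank, terminals)
    d <- d[order(d$scaffold, d$tgtOrd), , drop = FALSE]
    d$mappedRank <- as.integer(stats::ave(seq_len(nrow(d)), d$scaffold,
        FUN = seq_along))
    cnt <- table(d$scaffold)
    d$mappedCount <- as.integer(cnt[d$scaffold])
    d$isHead <- d$mappedRank == 1L
    d$isTail <- d$mappedRank == d$mappedCount

    d <- d[order(d$refSeq, d$refOrd), , drop = FALSE]
    rownames(d) <- NULL

    ## orphan detection on the reference walk: sole mapped gene of its
    ## scaffold, sandwiched between terminal genes of two other scaffolds
    n <- nrow(d)
    isOrphan <- rep(FALSE, n)
    if (n >= 3L) {
        for (i in 2L:(n - 1L)) {
            if (d$mappedCount[i] != 1L) next
            if (d$refSeq[i - 1L] != d$refSeq[i] || d$refSeq[i + 1L] != d$refSeq[i])
                next
            sL <- d$scaffold[i - 1L]; sR <- d$scaffold[i + 1L]
            if (sL == d$scaffold[i] || sR == d$scaffold[i] || sL == sR) next
            ## neighbours may themselves be orphan candidates (runs allowed);
            ## a single mapped gene is trivially a terminal of its scaffold
            if ((d$isHead[i - 1L] || d$isTail[i - 1L]) &&
                (d$isHead[i + 1L] || d$isTail[i + 1L]))
                isOrphan[i] <- TRUE
        }
    }

    endOf <- function(i, side) {
        ## which physical end of the scaffold does this terminal gene sit on?
        ## side: "left" = scaffold precedes the junction, "right" = follows.
        if (d$mappedCount[i] == 1L)
            return(if (side == "left") "tail" else "head")
        if (d$isTail[i] && d$isHead[i]) return("tail")  # unreachable guard
        if (d$isTail[i]) "tail" else "head"
    }

    supportOk <- function(i) {
        ## require minSupportGenes mapped genes at this scaffold end to be
        ## ref-consecutive and monotone, running away from the junction
        k <- minSupportGenes
        if (k <= 1L) return(TRUE)
        if (d$mappedCount[i] < k) return(FALSE)
        sc <- d$scaffold[i]
        rows <- which(d$scaffold == sc)
        rows <- rows[order(d$mappedRank[rows])]
        seg <- if (d$isTail[i]) rev(utils::tail(rows, k)) else utils::head(rows, k)
        ## seg[1] is the junction-side terminal; walk inward
        ords <- d$refOrd[seg]; seqs <- d$refSeq[seg]
        if (length(unique(seqs)) != 1L) return(FALSE)
        st <- diff(ords)
        all(st == st[1L]) && abs(st[1L]) == 1L
    }

    keep <- if (skipOrphans) !isOrphan else rep(TRUE, n)
    idx <- which(keep)
    out <- emptyJoins()
    if (length(idx) >= 2L) {
        for (w in seq_len(length(idx) - 1L)) {
            i <- idx[w]; j <- idx[w + 1L]
            if (d$refSeq[i] != d$refSeq[j]) next
            if (d$scaffold[i] == d$scaffold[j]) next
            skippedBetween <- if (j > i + 1L) (i + 1L):(j - 1L) else integer(0)
            if (length(skippedBetween) > 0L && !all(isOrphan[skippedBetween]))
                next  # non-orphan mapped genes intervene: terminals not adjacent
            leftTerminal <- d$isHead[i] || d$isTail[i]
            rightTerminal <- d$isHead[j] || d$isTail[j]
            if (!leftTerminal || !rightTerminal) next
            if (!supportOk(i) || !supportOk(j)) next
            bridge <- d$refGene[i:j]
            skp <- if (length(skippedBetween) > 0L)
                paste(d$scaffold[skippedBetween], d$tgtGene[skippedBetween],
                    sep = ":", collapse = ",") else ""
            le <- endOf(i, "left"); re <- endOf(j, "right")
            out <- rbind(out, data.frame(
                junction = junctionKey(d$scaffold[i], le, d$scaffold[j], re),
                left_scaffold = d$scaffold[i], left_end = le,
                right_scaffold = d$scaffold[j], right_end = re,
                supporting_ref = genomeId(ref),
                bridge_genes = paste(bridge, collapse = ","),
                n_bridge_genes = length(bridge),
                skipped_orphans = skp, fork = FALSE,
                stringsAsFactors = FALSE))
        }
    }
    ## flag forks: a scaffold end claimed by more than one candidate; the
    ## two ends of a single-mapped-gene scaffold are one physical terminus,
    ## so any such scaffold in two junctions is contested as well
    if (nrow(out) > 1L) {
        ends <- c(paste(out$left_scaffold, out$left_end),
            paste(out$right_scaffold, out$right_end))
        contested <- names(which(table(ends) > 1L))
        out$fork <- paste(out$left_scaffold, out$left_end) %in% contested |
            paste(out$right_scaffold, out$right_end) %in% contested
        singles <- unique(d$scaffold[d$mappedCount == 1L])
        for (s in singles) {
            hit <- out$left_scaffold == s | out$right_scaffold == s
            if (sum(hit) > 1L) out$fork[hit] <- TRUE
        }
    }
    rownames(out) <- NULL
    out
}

#' Consensus joins between two references
#'
#' Keeps a junction if and only if a candidate with the same
#' (scaffold, end)–(scaffold, end) pairing — orientation included — exists
#' in both per-reference join lists. Fork-flagged candidates never enter the
#' consensus. The result carries both references' bridge support.
#'
#' @param joinsA,joinsB data.frames from [proposeJoins()] computed against
#'   the same target.
#' @return data.frame of consensus junctions with per-reference bridge and
#'   orphan columns (`bridge_genes_A`, `bridge_genes_B`,
#'   `skipped_orphans_A`, `skipped_orphans_B`, `n_bridge_total`).
#' @export
consensusJoins <- function(joinsA, joinsB) {
    ja <- joinsA[!joinsA$fork, , drop = FALSE]
    jb <- joinsB[!joinsB$fork, , drop = FALSE]
    ja <- ja[!duplicated(ja$junction), , drop = FALSE]
    jb <- jb[!duplicated(jb$junction), , drop = FALSE]
    common <- intersect(ja$junction, jb$junction)
    a <- ja[match(common, ja$junction), , drop = FALSE]
    b <- jb[match(common, jb$junction), , drop = FALSE]
    out <- data.frame(junction = common,
        left_scaffold = a$left_scaffold, left_end = a$left_end,
        right_scaffold = a$right_scaffold, right_end = a$right_end,
        bridge_genes_A = a$bridge_genes, bridge_genes_B = b$bridge_genes,
        skipped_orphans_A = a$skipped_orphans,
        skipped_orphans_B = b$skipped_orphans,
        n_bridge_total = a$n_bridge_genes + b$n_bridge_genes,
        stringsAsFactors = FALSE)
    out <- out[order(out$junction), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Chain consensus joins into super-scaffolds
#'
#' Builds a graph whose nodes are scaffold ends and whose edges are
#' consensus junctions. Each end may carry at most one edge: if an end is
#' contested by several junctions, *all* of its junctions are discarded
#' (conservative fork removal). Any remaining cycle is broken by removing
#' the junction with the smallest total bridge-gene count (ties:
#' lexicographically smallest junction key). The remaining components are
#' simple paths, emitted as oriented super-scaffolds; scaffolds without
#' junctions are emitted as singletons, so the result is a partition of all
#' scaffolds.
#'
#' @param consensus data.frame from [consensusJoins()].
#' @param scaffolds scaffold length table (`scaffold_id`, `length_bp`);
#'   defines the full scaffold universe.
#' @return a [SuperScaffoldSet-class].
#' @export
chainJoins <- function(consensus, scaffolds) {
    scaffolds <- validateScaffoldLengths(scaffolds)
    ids <- scaffolds$scaffold_id
    cj <- consensus
    if (nrow(cj) > 0L) {
        unknown <- setdiff(c(cj$left_scaffold, cj$right_scaffold), ids)
        if (length(unknown) > 0L)
            stop("consensus joins involve unknown scaffold: ", unknown[1L])
        ## fork removal at the end level
        repeat {
            ends <- c(paste(cj$left_scaffold, cj$left_end),
                paste(cj$right_scaffold, cj$right_end))
            contested <- names(which(table(ends) > 1L))
            if (length(contested) == 0L) break
            drop <- paste(cj$left_scaffold, cj$left_end) %in% contested |
                paste(cj$right_scaffold, cj$right_end) %in% contested
            cj <- cj[!drop, , drop = FALSE]
        }
        ## cycle breaking: with <=1 edge per end, components are paths or
        ## simple cycles; a cycle has every member end saturated
        repeat {
            cyc <- findCycle(cj)
            if (is.null(cyc)) break
            sub <- cj[cyc, , drop = FALSE]
            victim <- cyc[order(sub$n_bridge_total, sub$junction)][1L]
            cj <- cj[-victim, , drop = FALSE]
        }
    }
    ## walk paths
    members <- data.frame(name = character(), position = integer(),
        scaffold_id = character(), orientation = character(),
        stringsAsFactors = FALSE)
    joins <- cbind(name = character(0), emptyConsensus())
    used <- character(0)
    if (nrow(cj) > 0L) {
        nb <- list()  # scaffold -> data.frame(end, other, otherEnd, row)
        addNb <- function(s, e, o, oe, r) {
            nb[[s]] <<- rbind(nb[[s]], data.frame(end = e, other = o,
                otherEnd = oe, row = r, stringsAsFactors = FALSE))
        }
        for (r in seq_len(nrow(cj))) {
            addNb(cj$left_scaffold[r], cj$left_end[r],
                cj$right_scaffold[r], cj$right_end[r], r)
            addNb(cj$right_scaffold[r], cj$right_end[r],
                cj$left_scaffold[r], cj$left_end[r], r)
        }
        inChain <- unique(c(cj$left_scaffold, cj$right_scaffold))
        degree <- vapply(inChain, function(s) nrow(nb[[s]]), integer(1))
        terminals <- inChain[degree == 1L]
        visited <- character(0)
        for (t0 in sort(terminals)) {
            if (t0 %in% visited) next
            ## walk from the free end of t0
            chain <- list()
            usedRows <- integer(0)
            cur <- t0
            curEntry <- NA_character_  # end through which we entered cur
            repeat {
                visited <- c(visited, cur)
                nbr <- nb[[cur]]
                nxt <- nbr[!(nbr$row %in% usedRows), , drop = FALSE]
                exitEnd <- if (nrow(nxt) > 0L) nxt$end[1L] else NA_character_
                ori <- if (is.na(curEntry)) {
                    ## first scaffold: orient so the exit end is its tail
                    if (!is.na(exitEnd) && exitEnd == "head") "-" else "+"
                } else if (curEntry == "head") "+" else "-"
                chain[[length(chain) + 1L]] <- list(scaffold = cur,
                    orientation = ori)
                if (nrow(nxt) == 0L) break
                usedRows <- c(usedRows, nxt$row[1L])
                curEntry <- nxt$otherEnd[1L]
                cur <- nxt$other[1L]
            }
            scafs <- vapply(chain, `[[`, character(1), "scaffold")
            oris <- vapply(chain, `[[`, character(1), "orientation")
            ## canonical order: smaller terminal integer first
            if (needsReversal(scafs)) {
                scafs <- rev(scafs)
                oris <- rev(ifelse(oris == "+", "-", "+"))
            }
            nm <- nameSuperscaffold(scafs)
            members <- rbind(members, data.frame(name = nm,
                position = seq_along(scafs), scaffold_id = scafs,
                orientation = oris, stringsAsFactors = FALSE))
            jrows <- cj[sort(unique(usedRows)), , drop = FALSE]
            if (nrow(jrows) > 0L)
                joins <- rbind(joins, cbind(name = nm, jrows))
            used <- c(used, scafs)
        }
    }
    singletons <- setdiff(ids, used)
    if (length(singletons) > 0L) {
        members <- rbind(members, data.frame(
            name = vapply(singletons, nameSuperscaffold, character(1)),
            position = 1L, scaffold_id = singletons, orientation = "+",
            stringsAsFactors = FALSE))
    }
    rownames(members) <- NULL
    rownames(joins) <- NULL
    new("SuperScaffoldSet", members = members, joins = joins)
}

emptyConsensus <- function() {
    data.frame(junction = character(), left_scaffold = character(),
        left_end = character(), right_scaffold = character(),
        right_end = character(), bridge_genes_A = character(),
        bridge_genes_B = character(), skipped_orphans_A = character(),
        skipped_orphans_B = character(), n_bridge_total = integer(),
        stringsAsFactors = FALSE)
}

findCycle <- function(cj) {
    ## returns row indices of one cycle, or NULL; each end has <=1 edge so
    ## components are paths/cycles — a cycle is a component none of whose
    ## member rows contains a free scaffold end
    if (nrow(cj) == 0L) return(NULL)
    ## components via iterative label propagation over junction rows
    scafs <- unique(c(cj$left_scaffold, cj$right_scaffold))
    lab <- stats::setNames(seq_along(scafs), scafs)
    repeat {
        changed <- FALSE
        for (r in seq_len(nrow(cj))) {
            a <- cj$left_scaffold[r]; b <- cj$right_scaffold[r]
            m <- min(lab[[a]], lab[[b]])
            if (lab[[a]] != m || lab[[b]] != m) {
                lab[[a]] <- m; lab[[b]] <- m; changed <- TRUE
            }
        }
        if (!changed) break
    }
    rowLab <- lab[cj$left_scaffold]
    for (cl in unique(rowLab)) {
        rows <- which(rowLab == cl)
        memberScafs <- unique(c(cj$left_scaffold[rows], cj$right_scaffold[rows]))
        ## degree per scaffold within component
        deg <- table(c(cj$left_scaffold[rows], cj$right_scaffold[rows]))
        if (all(deg[memberScafs] == 2L))
            return(rows)
    }
    NULL
}

needsReversal <- function(scafs) {
    if (length(scafs) < 2L) return(FALSE)
    a <- scaffoldIntPart(scafs[1L]); b <- scaffoldIntPart(scafs[length(scafs)])
    if (!is.na(a) && !is.na(b)) return(b < a)
    scafs[length(scafs)] < scafs[1L]
}

scaffoldIntPart <- function(id) {
    m <- regmatches(id, regexec("^scf0*([0-9]+)$", id))[[1L]]
    if (length(m) == 2L) as.integer(m[2L]) else NA_integer_
}

#' Size of a super-scaffold
#'
#' The size of a super-scaffold is the sum of the sizes of its member
#' scaffolds (no gap term).
#'
#' @param members character vector of member scaffold ids (a singleton is
#'   its own super-scaffold).
#' @param scaffolds scaffold length table (`scaffold_id`, `length_bp`) or a
#'   named numeric vector of lengths.
#' @return total size in bp.
#' @examples
#' lens <- data.frame(scaffold_id = c("scf000015", "scf000003", "scf001966"),
#'     length_bp = c(7401090, 11886202, 14669))
#' superscaffoldSize(lens$scaffold_id, lens)  # 19301961
#' @export
superscaffoldSize <- function(members, scaffolds) {
    if (is.data.frame(scaffolds))
        scaffolds <- stats::setNames(scaffolds$length_bp, scaffolds$scaffold_id)
    missing <- setdiff(members, names(scaffolds))
    if (length(missing) > 0L)
        stop("no length for member scaffold: ", paste(missing, collapse = ", "))
    sum(scaffolds[members])
}

#' Sizes of every super-scaffold in a set
#'
#' @param sset a [SuperScaffoldSet-class].
#' @param scaffolds scaffold length table or named numeric vector.
#' @return data.frame with columns `name`, `n_members`, `size_bp`.
#' @export
superscaffoldSizes <- function(sset, scaffolds) {
    m <- superscaffoldMembers(sset)
    if (is.data.frame(scaffolds))
        scaffolds <- stats::setNames(scaffolds$length_bp, scaffolds$scaffold_id)
    out <- do.call(rbind, lapply(split(m, m$name), function(g) {
        data.frame(name = g$name[1L], n_members = nrow(g),
            size_bp = superscaffoldSize(g$scaffold_id, scaffolds),
            stringsAsFactors = FALSE)
    }))
    out <- out[order(-out$size_bp, out$name), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Name a super-scaffold
#'
#' Member ids of the form `scf<zero-padded integer>` are reduced to their
#' integer parts and hyphen-joined in member order ("scf000015, scf000003,
#' scf001966" becomes "15-3-1966"). A super-scaffold read in reverse is the
#' same object, so the canonical form starts with the smaller terminal
#' integer. Ids not matching the pattern are used verbatim.
#'
#' @param members ordered character vector of member scaffold ids.
#' @return the name string.
#' @examples
#' nameSuperscaffold(c("scf000015", "scf000003", "scf001966"))  # "15-3-1966"
#' @export
nameSuperscaffold <- function(members) {
    if (needsReversal(members)) members <- rev(members)
    parts <- vapply(members, function(id) {
        ip <- scaffoldIntPart(id)
        if (is.na(ip)) id else as.character(ip)
    }, character(1))
    paste(parts, collapse = "-")
}
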
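## Ancestral macrochromosome reconstruction: pairwise segment co-location
## characters, Fitch parsimony on a rooted tree with outgroup-anchored root
## states, and union-find assembly of ancestral chromosome compositions.

#' Build pairwise co-location characters from karyotype profiles
#'
#' For every unordered pair of homology-segment labels observed together on
#' one chromosome in at least one species, emits a character whose state per
#' species is `together` (both labels on one chromosome), `apart` (on
#' different chromosomes) or `missing` (either label not mapped in that
#' species). Pairs never co-located anywhere yield no character.
#'
#' @param profiles karyotype profile data.frame (`species_id`,
#'   `chromosome_id`, `segment`); validated against the one-chromosome-per-
#'   segment invariant.
#' @return list with `pairs` (data.frame `char_id`, `seg1`, `seg2`,
#'   `seg1 < seg2`) and `states` (character matrix, characters x species).
#' @export
buildColocationCharacters <- function(profiles) {
    profiles <- validateKaryotypeProfiles(profiles)
    species <- sort(unique(profiles$species_id))
    bySp <- split(profiles, profiles$species_id)
    ## collect co-located pairs
    pairSet <- character(0)
    for (sp in species) {
        byChrom <- split(bySp[[sp]]$segment, bySp[[sp]]$chromosome_id)
        for (segs in byChrom) {
            segs <- sort(unique(segs))
            if (length(segs) >= 2L) {
                cmb <- utils::combn(segs, 2L)
                pairSet <- c(pairSet, paste(cmb[1L, ], cmb[2L, ], sep = "\r"))
            }
        }
    }
    pairSet <- sort(unique(pairSet))
    if (length(pairSet) == 0L) {
        return(list(pairs = data.frame(char_id = character(),
            seg1 = character(), seg2 = character()),
            states = matrix(character(0), 0, length(species),
                dimnames = list(NULL, species))))
    }
    seg1 <- vapply(strsplit(pairSet, "\r", fixed = TRUE), `[`, character(1), 1L)
    seg2 <- vapply(strsplit(pairSet, "\r", fixed = TRUE), `[`, character(1), 2L)
    states <- matrix("missing", length(pairSet), length(species),
        dimnames = list(NULL, species))
    for (si in seq_along(species)) {
        pr <- bySp[[species[si]]]
        chromOf <- stats::setNames(pr$chromosome_id, pr$segment)
        has1 <- seg1 %in% names(chromOf)
        has2 <- seg2 %in% names(chromOf)
        both <- has1 & has2
        states[both, si] <- ifelse(chromOf[seg1[both]] == chromOf[seg2[both]],
            "together", "apart")
    }
    pairs <- data.frame(char_id = paste(seg1, seg2, sep = "|"),
        seg1 = seg1, seg2 = seg2, stringsAsFactors = FALSE)
    rownames(states) <- pairs$char_id
    list(pairs = pairs, states = states)
}

#' Fitch parsimony states for one co-location character
#'
#' Standard two-pass Fitch parsimony on a rooted binary tree for a binary
#' together/apart character. Leaves with `missing` state are uninformative:
#' they contribute the full state set and never force a change. The
#' downward pass computes, per node, the exact set of states occurring in
#' at least one most-parsimonious reconstruction; nodes whose set is not a
#' singleton are reported as `ambiguous`, never silently resolved. If an
#' `outgroup` tip is named, the root is anchored to that tip's observed
#' state (the conventional polarisation of ancestral states).
#'
#' Branch events are reported where both branch endpoints are unambiguous
#' and differ: `apart -> together` is a fusion, `together -> apart` a
#' fission.
#'
#' @param tree rooted binary `phylo` tree (see [ape::read.tree()]).
#' @param states named character vector of leaf states (`together`,
#'   `apart`, `missing`), names matching tip labels.
#' @param outgroup optional tip label whose state anchors the root.
#' @return list with `node_states` (data.frame `node`, `label`, `state`),
#'   `events` (data.frame `parent`, `child`, `event`), and `change_count`
#'   (the parsimony score).
#' @export
fitchAncestralStates <- function(tree, states, outgroup = NULL) {
    stopifnot(inherits(tree, "phylo"))
    if (!ape::is.rooted(tree))
        stop("tree must be rooted")
    if (!ape::is.binary(tree))
        stop("tree must be binary")
    tips <- tree$tip.label
    if (!all(tips %in% names(states)))
        stop("missing leaf states for: ",
            paste(setdiff(tips, names(states)), collapse = ", "))
    bad <- setdiff(unique(states), c("together", "apart", "missing"))
    if (length(bad) > 0L)
        stop("invalid state: ", bad[1L])
    nTip <- length(tips)
    nNode <- tree$Nnode
    total <- nTip + nNode
    kids <- vector("list", total)
    parent <- integer(total)
    for (r in seq_len(nrow(tree$edge))) {
        kids[[tree$edge[r, 1L]]] <- c(kids[[tree$edge[r, 1L]]], tree$edge[r, 2L])
        parent[tree$edge[r, 2L]] <- tree$edge[r, 1L]
    }
    root <- nTip + 1L
    full <- c("together", "apart")
    B <- vector("list", total)   # first-pass state sets
    isUnion <- logical(total)
    for (i in seq_len(nTip)) {
        s <- states[[tips[i]]]
        B[[i]] <- if (s == "missing") full else s
    }
    changeCount <- 0L
    ## postorder: children before parents (deepest internal nodes first)
    postorder <- (nTip + 1L):total
    postorder <- postorder[order(-nodeDepths(tree)[postorder])]
    for (v in postorder) {
        ch <- kids[[v]]
        inter <- intersect(B[[ch[1L]]], B[[ch[2L]]])
        if (length(inter) > 0L) {
            B[[v]] <- inter
        } else {
            B[[v]] <- union(B[[ch[1L]]], B[[ch[2L]]])
            isUnion[v] <- TRUE
            changeCount <- changeCount + 1L
        }
    }
    ## downward pass (MPR state sets)
    Fset <- vector("list", total)
    Fset[[root]] <- B[[root]]
    if (!is.null(outgroup)) {
        if (!outgroup %in% tips)
            stop("outgroup '", outgroup, "' is not a tip label")
        og <- states[[outgroup]]
        if (og != "missing" && og %in% B[[root]])
            Fset[[root]] <- og
    }
    preorder <- c(root, setdiff((nTip + 1L):total, root))
    preorder <- preorder[order(nodeDepths(tree)[preorder])]
    for (v in preorder) {
        for (w in kids[[v]]) {
            if (w <= nTip) {
                Fset[[w]] <- B[[w]]
                if (length(Fset[[w]]) == 2L && length(Fset[[v]]) == 1L)
                    Fset[[w]] <- Fset[[v]]  # missing leaf follows its parent
                next
            }
            if (all(Fset[[v]] %in% B[[w]])) {
                Fset[[w]] <- Fset[[v]]
            } else if (isUnion[w]) {
                Fset[[w]] <- union(B[[w]], Fset[[v]])
            } else {
                ch <- kids[[w]]
                Fset[[w]] <- union(B[[w]],
                    intersect(Fset[[v]], union(B[[ch[1L]]], B[[ch[2L]]])))
            }
        }
    }
    stateOf <- vapply(seq_len(total), function(v) {
        if (length(Fset[[v]]) == 1L) Fset[[v]] else "ambiguous"
    }, character(1))
    labels <- c(tips, if (!is.null(tree$node.label)) tree$node.label else
        paste0("node", (nTip + 1L):total))
    nodeStates <- data.frame(node = seq_len(total), label = labels,
        state = stateOf, stringsAsFactors = FALSE)
    ## events on branches with unambiguous, differing endpoint states
    ev <- list()
    for (r in seq_len(nrow(tree$edge))) {
        p <- tree$edge[r, 1L]; w <- tree$edge[r, 2L]
        sp <- stateOf[p]; sw <- stateOf[w]
        if (sp == "ambiguous" || sw == "ambiguous" || sp == sw) next
        ev[[length(ev) + 1L]] <- data.frame(parent = labels[p],
            child = labels[w],
            event = if (sp == "apart") "fusion" else "fission",
            stringsAsFactors = FALSE)
    }
    events <- if (length(ev)) do.call(rbind, ev) else
        data.frame(parent = character(), child = character(),
            event = character(), stringsAsFactors = FALSE)
    list(node_states = nodeStates, events = events,
        change_count = changeCount)
}

nodeDepths <- function(tree) {
    nTip <- length(tree$tip.label)
    total <- nTip + tree$Nnode
    depth <- rep(NA_integer_, total)
    root <- nTip + 1L
    depth[root] <- 0L
    edge <- tree$edge
    repeat {
        known <- !is.na(depth[edge[, 1L]]) & is.na(depth[edge[, 2L]])
        if (!any(known)) break
        depth[edge[known, 2L]] <- depth[edge[known, 1L]] + 1L
    }
    depth
}

#' Assemble an ancestral karyotype from resolved characters
#'
#' Union-find over segment labels using `together`-resolved characters as
#' union edges: connected components are the ancestral chromosomes. A pair
#' resolved `apart` whose two segments nevertheless end up in one component
#' is reported as an inconsistency (the components stand — pairwise
#' characters are reconstructed independently and need not be mutually
#' consistent).
#'
#' @param segments character vector of segment labels present at the node.
#' @param togetherPairs data.frame with columns `seg1`, `seg2` of pairs
#'   resolved `together`.
#' @param apartPairs optional data.frame of pairs resolved `apart`, checked
#'   for consistency.
#' @param macroSegments labels counting as macrochromosome material; a
#'   component containing at least one of them is a macrochromosome
#'   (default: all segments).
#' @return list with `chromosomes` (list of sorted segment vectors, sorted
#'   by first member), `n_chromosomes`, `n_macrochromosomes`, and
#'   `inconsistencies` (data.frame of violated apart pairs).
#' @export
assembleAncestor <- function(segments, togetherPairs, apartPairs = NULL,
        macroSegments = segments) {
    parent <- stats::setNames(segments, segments)
    find <- function(x) {
        while (parent[[x]] != x) {
            parent[[x]] <<- parent[[parent[[x]]]]
            x <- parent[[x]]
        }
        x
    }
    if (!is.null(togetherPairs) && nrow(togetherPairs) > 0L) {
        tp <- togetherPairs[order(togetherPairs$seg1, togetherPairs$seg2), ,
            drop = FALSE]
        for (r in seq_len(nrow(tp))) {
            a <- tp$seg1[r]; b <- tp$seg2[r]
            if (!a %in% segments || !b %in% segments) next
            ra <- find(a); rb <- find(b)
            if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
        }
    }
    roots <- vapply(segments, find, character(1))
    comps <- split(segments, roots)
    comps <- lapply(comps, sort)
    comps <- comps[order(vapply(comps, `[`, character(1), 1L))]
    names(comps) <- NULL
    incon <- data.frame(seg1 = character(), seg2 = character(),
        stringsAsFactors = FALSE)
    if (!is.null(apartPairs) && nrow(apartPairs) > 0L) {
        for (r in seq_len(nrow(apartPairs))) {
            a <- apartPairs$seg1[r]; b <- apartPairs$seg2[r]
            if (!a %in% segments || !b %in% segments) next
            if (find(a) == find(b))
                incon <- rbind(incon, data.frame(seg1 = a, seg2 = b,
                    stringsAsFactors = FALSE))
        }
    }
    nMacro <- sum(vapply(comps, function(cc) any(cc %in% macroSegments),
        logical(1)))
    list(chromosomes = comps, n_chromosomes = length(comps),
        n_macrochromosomes = nMacro, inconsistencies = incon)
}

#' Reconstruct ancestral karyotypes at every internal node
#'
#' Runs [buildColocationCharacters()], applies [fitchAncestralStates()] to
#' every character, and assembles each internal node's chromosome
#' composition with [assembleAncestor()]. Segments are taken to be present
#' at a node when observed in at least one descendant leaf.
#'
#' @param tree rooted binary `phylo`; internal nodes may carry labels
#'   (used in the output).
#' @param profiles karyotype profile data.frame (leaves of `tree` plus
#'   optionally the outgroup).
#' @param outgroup tip label anchoring root states.
#' @param macroSegments labels counting as macrochromosome material
#'   (default: all).
#' @return list with `ancestors` (data.frame `node`, `label`,
#'   `n_chromosomes`, `n_macrochromosomes`, `composition` — chromosome
#'   compositions as `a+b` segment groups joined by `;`), `karyotypes`
#'   (per-node [assembleAncestor()] results), `events` (data.frame
#'   `parent`, `child`, `char_id`, `event`), and `characters` (the
#'   character set).
#' @export
ancestralKaryotypes <- function(tree, profiles, outgroup = NULL,
        macroSegments = NULL) {
    chars <- buildColocationCharacters(profiles)
    profiles <- validateKaryotypeProfiles(profiles)
    if (is.null(macroSegments))
        macroSegments <- unique(profiles$segment)
    nTip <- length(tree$tip.label)
    total <- nTip + tree$Nnode
    labels <- c(tree$tip.label, if (!is.null(tree$node.label))
        tree$node.label else paste0("node", (nTip + 1L):total))
    ## per-character Fitch
    fits <- lapply(seq_len(nrow(chars$pairs)), function(k) {
        fitchAncestralStates(tree, chars$states[k, ], outgroup = outgroup)
    })
    ## events across characters
    ev <- list()
    for (k in seq_along(fits)) {
        e <- fits[[k]]$events
        if (nrow(e) > 0L)
            ev[[length(ev) + 1L]] <- cbind(e[, c("parent", "child")],
                char_id = chars$pairs$char_id[k], event = e$event)
    }
    events <- if (length(ev)) do.call(rbind, ev) else
        data.frame(parent = character(), child = character(),
            char_id = character(), event = character(),
            stringsAsFactors = FALSE)
    rownames(events) <- NULL
    ## segments present per node: observed in >= 1 descendant leaf
    leafSegs <- split(profiles$segment, profiles$species_id)
    desc <- descendantTips(tree)
    karyotypes <- list(); rows <- list()
    for (v in (nTip + 1L):total) {
        segs <- sort(unique(unlist(leafSegs[tree$tip.label[desc[[v]]]],
            use.names = FALSE)))
        idx <- vapply(fits, function(f)
            f$node_states$state[v], character(1))
        tg <- chars$pairs[idx == "together", , drop = FALSE]
        ap <- chars$pairs[idx == "apart", , drop = FALSE]
        kt <- assembleAncestor(segs, tg, ap,
            macroSegments = intersect(macroSegments, segs))
        karyotypes[[labels[v]]] <- kt
        rows[[length(rows) + 1L]] <- data.frame(node = v, label = labels[v],
            n_chromosomes = kt$n_chromosomes,
            n_macrochromosomes = kt$n_macrochromosomes,
            composition = paste(vapply(kt$chromosomes, paste,
                character(1), collapse = "+"), collapse = ";"),
            stringsAsFactors = FALSE)
    }
    ancestors <- do.call(rbind, rows)
    rownames(ancestors) <- NULL
    list(ancestors = ancestors, karyotypes = karyotypes, events = events,
        characters = chars)
}

descendantTips <- function(tree) {
    nTip <- length(tree$tip.label)
    total <- nTip + tree$Nnode
    desc <- vector("list", total)
    for (i in seq_len(nTip)) desc[[i]] <- i
    ord <- (nTip + 1L):total
    ord <- ord[order(-nodeDepths(tree)[ord])]
    kids <- split(tree$edge[, 2L], tree$edge[, 1L])
    for (v in ord)
        desc[[v]] <- unlist(desc[kids[[as.character(v)]]], use.names = FALSE)
    desc
}
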
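test_that("co-location characters cover exactly the pairs seen together somewhere", {
    pf <- data.frame(
        species_id = c("s1", "s1", "s1", "s2", "s2", "s2"),
        chromosome_id = c("c1", "c1", "c2", "c1", "c2", "c2"),
        segment = c("A", "B", "C", "A", "B", "C"))
    ch <- buildColocationCharacters(pf)
    ## A+B together in s1; B+C together in s2; A+C never together
    expect_setequal(ch$pairs$char_id, c("A|B", "B|C"))
    expect_identical(unname(ch$states["A|B", c("s1", "s2")]),
        c("together", "apart"))
    expect_identical(unname(ch$states["B|C", c("s1", "s2")]),
        c("apart", "together"))
    ## species lacking a label is missing for that pair
    pf2 <- rbind(pf, data.frame(species_id = "s3", chromosome_id = "c1",
        segment = "A"))
    ch2 <- buildColocationCharacters(pf2)
    expect_identical(unname(ch2$states["A|B", "s3"]), "missing")
})

test_that("a uniform character reconstructs with zero changes", {
    tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
    states <- c(t1 = "together", t2 = "together", t3 = "together",
        t4 = "together")
    fit <- fitchAncestralStates(tr, states)
    expect_equal(fit$change_count, 0L)
    expect_true(all(fit$node_states$state == "together"))
    expect_equal(nrow(fit$events), 0L)
})

test_that("a clade-wide fusion lands on the stem branch under outgroup rooting", {
    fx <- squamateFixture()
    squamates <- setdiff(fx$tree$tip.label, "archosaur")
    states <- setNames(rep("together", length(squamates)), squamates)
    states["archosaur"] <- "apart"
    fit <- fitchAncestralStates(fx$tree, states, outgroup = "archosaur")
    expect_equal(fit$change_count, 1L)
    expect_equal(nrow(fit$events), 1L)
    expect_identical(fit$events$child, "Squamata")
    expect_identical(fit$events$event, "fusion")
})

test_that("unrooted and non-binary trees are rejected", {
    un <- ape::read.tree(text = "(t1,t2,t3);")
    expect_error(fitchAncestralStates(un,
        c(t1 = "together", t2 = "apart", t3 = "apart")), "rooted|binary")
})

test_that("Fitch change counts equal exhaustive enumeration on small trees", {
    set.seed(99)
    for (rep in 1:40) {
        n <- sample(3:6, 1)
        tr <- randomRootedTree(n)
        states <- setNames(sample(c("together", "apart", "missing"), n,
            replace = TRUE, prob = c(0.4, 0.4, 0.2)), tr$tip.label)
        fit <- fitchAncestralStates(tr, states)
        expect_equal(fit$change_count, bruteForceParsimony(tr, states),
            label = paste("rep", rep))
    }
})

test_that("Fitch change counts match phangorn's parsimony score", {
    skip_if_not_installed("phangorn")
    set.seed(123)
    for (rep in 1:15) {
        n <- sample(4:8, 1)
        tr <- randomRootedTree(n)
        states <- setNames(sample(c("together", "apart"), n, replace = TRUE),
            tr$tip.label)
        if (length(unique(states)) == 1L) next
        fit <- fitchAncestralStates(tr, states)
        mat <- matrix(substr(states[tr$tip.label], 1, 1), ncol = 1,
            dimnames = list(tr$tip.label, NULL))
        pd <- phangorn::phyDat(mat, type = "USER", levels = c("t", "a"))
        expect_equal(fit$change_count,
            as.integer(phangorn::parsimony(tr, pd, method = "fitch")))
    }
})

test_that("ancestral assembly unions together-pairs into chromosomes", {
    res <- assembleAncestor(c("a", "b", "c"),
        data.frame(seg1 = "a", seg2 = "b"))
    expect_equal(res$chromosomes, list(c("a", "b"), "c"))
    ## no together characters: all singletons
    res0 <- assembleAncestor(c("a", "b"), data.frame(seg1 = character(),
        seg2 = character()))
    expect_equal(res0$n_chromosomes, 2L)
    ## transitivity through a chain
    res2 <- assembleAncestor(c("a", "b", "c"),
        data.frame(seg1 = c("a", "b"), seg2 = c("b", "c")))
    expect_equal(res2$chromosomes, list(c("a", "b", "c")))
    ## contradiction is reported, components stand
    res3 <- assembleAncestor(c("a", "b", "c"),
        data.frame(seg1 = c("a", "b"), seg2 = c("b", "c")),
        apartPairs = data.frame(seg1 = "a", seg2 = "c"))
    expect_equal(nrow(res3$inconsistencies), 1L)
    expect_equal(res3$n_chromosomes, 1L)
    ## macro counting respects the macro segment set
    res4 <- assembleAncestor(c("a", "b", "m"),
        data.frame(seg1 = "a", seg2 = "b"), macroSegments = c("a", "b"))
    expect_equal(res4$n_macrochromosomes, 1L)
})

test_that("assembly is invariant under character input order", {
    set.seed(8)
    segs <- letters[1:8]
    tg <- data.frame(seg1 = c("a", "b", "d", "f"),
        seg2 = c("b", "c", "e", "g"))
    ref <- assembleAncestor(segs, tg)
    for (k in 1:5) {
        perm <- tg[sample(nrow(tg)), ]
        expect_equal(assembleAncestor(segs, perm)$chromosomes,
            ref$chromosomes)
    }
})

test_that("scripted fusion/fission evolution is recovered at every node", {
    ## ancestor with chromosomes {A,B},{C},{D}; lineage 1 keeps it; the
    ## stem to (t3,t4) fuses C+D; t4 additionally fissions A|B
    tr <- ape::read.tree(text = "((t1,t2)n12,(t3,t4)n34)root;")
    pf <- rbind(
        data.frame(species_id = "t1", chromosome_id = c("c1", "c1", "c2", "c3"),
            segment = c("A", "B", "C", "D")),
        data.frame(species_id = "t2", chromosome_id = c("c1", "c1", "c2", "c3"),
            segment = c("A", "B", "C", "D")),
        data.frame(species_id = "t3", chromosome_id = c("c1", "c1", "c2", "c2"),
            segment = c("A", "B", "C", "D")),
        data.frame(species_id = "t4", chromosome_id = c("c1", "c4", "c2", "c2"),
            segment = c("A", "B", "C", "D")))
    res <- ancestralKaryotypes(tr, pf, outgroup = "t1")
    anc <- res$ancestors
    expect_equal(anc$n_chromosomes[anc$label == "root"], 3L)
    expect_equal(anc$n_chromosomes[anc$label == "n12"], 3L)
    expect_equal(anc$n_chromosomes[anc$label == "n34"], 2L)
    ## events: one fusion onto n34's stem, one fission on t4's branch
    expect_identical(res$events$event[res$events$child == "n34"], "fusion")
    expect_identical(res$events$event[res$events$child == "t4"], "fission")
})

test_that("the bundled squamate matrix reproduces the published ancestor counts", {
    fx <- squamateFixture()
    res <- ancestralKaryotypes(fx$tree, fx$profiles, outgroup = "archosaur",
        macroSegments = squamateMacroSegments())
    anc <- res$ancestors
    get <- function(lbl, col) anc[[col]][anc$label == lbl]
    expect_equal(get("Amniote_root", "n_macrochromosomes"), 11L)
    expect_equal(get("Squamata", "n_macrochromosomes"), 10L)
    expect_equal(get("Toxicofera", "n_macrochromosomes"), 7L)
    expect_equal(get("Iguania", "n_macrochromosomes"), 6L)
    ev <- res$events
    expect_gte(sum(ev$child == "Toxicofera" & ev$event == "fusion"), 5L)
})
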
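## small fixed instance: ref order a,b,c,d over two target scaffolds
twoScaffolds <- function() {
    tgt <- geneTableFromOrder("t", list(S1 = c("a", "b"), S2 = c("c", "d")))
    ref <- geneTableFromOrder("r", list(chr1 = c("a", "b", "c", "d")))
    list(tgt = tgt, ref = ref, map = identityMap(c("a", "b", "c", "d")))
}

orphanInstance <- function() {
    tgt <- geneTableFromOrder("t",
        list(S1 = c("a", "b"), S3 = "x", S2 = c("c", "d")))
    ref <- geneTableFromOrder("r", list(chr1 = c("a", "b", "x", "c", "d")))
    list(tgt = tgt, ref = ref, map = identityMap(c("a", "b", "x", "c", "d")))
}

test_that("abutting terminal genes propose a join with the spanning bridge", {
    fx <- twoScaffolds()
    j <- proposeJoins(fx$tgt, fx$ref, fx$map)
    expect_equal(nrow(j), 1L)
    expect_identical(j$left_scaffold, "S1")
    expect_identical(j$left_end, "tail")
    expect_identical(j$right_scaffold, "S2")
    expect_identical(j$right_end, "head")
    expect_identical(j$bridge_genes, "b,c")
    expect_false(j$fork)
})

test_that("orphaned terminal genes are skipped, recorded, and never deleted", {
    fx <- orphanInstance()
    j <- proposeJoins(fx$tgt, fx$ref, fx$map, skipOrphans = TRUE)
    expect_equal(nrow(j), 1L)
    expect_identical(j$junction, "S1:tail--S2:head")
    expect_identical(j$skipped_orphans, "S3:x")
    expect_identical(j$bridge_genes, "b,x,c")
    ## chaining leaves the orphan as a retained singleton
    sset <- chainJoins(consensusJoins(j, j),
        scafLengths(c("S1", "S2", "S3"), c(100, 100, 50)))
    m <- superscaffoldMembers(sset)
    expect_setequal(m$scaffold_id, c("S1", "S2", "S3"))
    expect_equal(sum(m$scaffold_id == "S3" & m$position == 1L), 1L)
})

test_that("without skipping, the orphan creates two fork-flagged candidates", {
    fx <- orphanInstance()
    j <- proposeJoins(fx$tgt, fx$ref, fx$map, skipOrphans = FALSE)
    expect_equal(nrow(j), 2L)
    expect_true(all(j$fork))
    expect_true(any(grepl("S3", j$junction)))
    ## fork-flagged candidates never reach consensus
    expect_equal(nrow(consensusJoins(j, j)), 0L)
})

test_that("consensus keeps exactly the junctions present in both references", {
    fx <- twoScaffolds()
    jA <- proposeJoins(fx$tgt, fx$ref, fx$map)
    jB <- jA  # same junction from the second reference
    cj <- consensusJoins(jA, jB)
    expect_equal(nrow(cj), 1L)
    expect_identical(cj$bridge_genes_A, cj$bridge_genes_B)
    ## junction present in one reference only is dropped
    expect_equal(nrow(consensusJoins(jA, jA[0, ])), 0L)
    expect_equal(nrow(consensusJoins(jA[0, ], jA[0, ])), 0L)
    ## consensus is a subset of each input list
    expect_true(all(cj$junction %in% jA$junction))
})

mkJunction <- function(s1, e1, s2, e2, nb = 4L) {
    data.frame(junction = SyntenyAnchor:::junctionKey(s1, e1, s2, e2),
        left_scaffold = s1, left_end = e1, right_scaffold = s2,
        right_end = e2, bridge_genes_A = "", bridge_genes_B = "",
        skipped_orphans_A = "", skipped_orphans_B = "",
        n_bridge_total = nb, stringsAsFactors = FALSE)
}

test_that("chains follow junctions into ordered, oriented super-scaffolds", {
    lens <- scafLengths(c("scf000001", "scf000002", "scf000003"),
        c(100, 200, 300))
    cj <- rbind(
        mkJunction("scf000001", "tail", "scf000002", "head"),
        mkJunction("scf000002", "tail", "scf000003", "head"))
    sset <- chainJoins(cj, lens)
    m <- superscaffoldMembers(sset)
    expect_identical(unique(m$name), "1-2-3")
    expect_identical(m$scaffold_id[order(m$position)],
        c("scf000001", "scf000002", "scf000003"))
    expect_identical(m$orientation, rep("+", 3))
})

test_that("a contested end drops all of its junctions", {
    lens <- scafLengths(c("scf000001", "scf000002", "scf000003"),
        c(100, 200, 300))
    cj <- rbind(
        mkJunction("scf000001", "tail", "scf000002", "head"),
        mkJunction("scf000001", "tail", "scf000003", "head"))
    sset <- chainJoins(cj, lens)
    m <- superscaffoldMembers(sset)
    expect_equal(nrow(m), 3L)
    expect_true(all(table(m$name) == 1L))  # three singletons
})

test_that("cycles are broken at the weakest junction, enumerated drop choices agree", {
    lens <- scafLengths(c("scf000001", "scf000002", "scf000003"),
        c(100, 200, 300))
    cyc <- rbind(
        mkJunction("scf000001", "tail", "scf000002", "head", nb = 4L),
        mkJunction("scf000002", "tail", "scf000003", "head", nb = 6L),
        mkJunction("scf000003", "tail", "scf000001", "head", nb = 5L))
    sset <- chainJoins(cyc, lens)
    m <- superscaffoldMembers(sset)
    ## every drop choice yields a 3-member path; the policy drops the edge
    ## with the smallest bridge support (junction 1-2), so 2 and 3 stay
    ## joined and the path terminals are scaffolds 1 and 2
    expect_equal(length(unique(m$name)), 1L)
    expect_equal(nrow(m), 3L)
    kept <- superscaffoldJoins(sset)
    expect_setequal(kept$n_bridge_total, c(6L, 5L))
    ## tie on support: lexicographically smallest junction key goes
    tie <- cyc; tie$n_bridge_total <- 4L
    kept2 <- superscaffoldJoins(chainJoins(tie, lens))
    expect_false(min(tie$junction) %in% kept2$junction)
})

test_that("scaffold membership is a partition and sizes are conserved", {
    set.seed(5)
    for (seed in 1:5) {
        sim <- simulateGenomes(simConfig(nGenes = 120, nChromosomes = 3,
            nScaffolds = 12, dropoutRate = 0.15, seed = seed))
        jA <- proposeJoins(sim$target, sim$refA, sim$mapA)
        jB <- proposeJoins(sim$target, sim$refB, sim$mapB)
        sset <- chainJoins(consensusJoins(jA, jB), sim$scaffolds)
        m <- superscaffoldMembers(sset)
        expect_setequal(m$scaffold_id, sim$scaffolds$scaffold_id)
        expect_equal(anyDuplicated(m$scaffold_id), 0L)
        sizes <- superscaffoldSizes(sset, sim$scaffolds)
        expect_equal(sum(sizes$size_bp), sum(sim$scaffolds$length_bp))
    }
})

test_that("consensus joins are perfect under zero rearrangement and dropout", {
    for (seed in 1:20) {
        sim <- simulateGenomes(simConfig(nGenes = 100, nChromosomes = 2,
            nScaffolds = 10, dropoutRate = 0,
            nInversionsA = 0, nTranslocationsA = 0, nFusionsA = 0,
            nFissionsA = 0, nInversionsB = 0, nTranslocationsB = 0,
            nFusionsB = 0, nFissionsB = 0, seed = seed))
        cj <- consensusJoins(
            proposeJoins(sim$target, sim$refA, sim$mapA),
            proposeJoins(sim$target, sim$refB, sim$mapB))
        truthKeys <- with(sim$truth$adjacencies,
            sort(SyntenyAnchor:::junctionKey(left_scaffold, left_end,
                right_scaffold, right_end)))
        expect_identical(sort(cj$junction), truthKeys)  # precision & recall 1
    }
})

test_that("recall declines on average as ortholog dropout rises", {
    recallAt <- function(rate) {
        mean(vapply(1:20, function(seed) {
            sim <- simulateGenomes(simConfig(nGenes = 120, nChromosomes = 3,
                nScaffolds = 12, dropoutRate = rate,
                nInversionsA = 0, nTranslocationsA = 0, nFusionsA = 0,
                nFissionsA = 0, nInversionsB = 0, nTranslocationsB = 0,
                nFusionsB = 0, nFissionsB = 0, seed = 1000 + seed))
            cj <- consensusJoins(
                proposeJoins(sim$target, sim$refA, sim$mapA),
                proposeJoins(sim$target, sim$refB, sim$mapB))
            truthKeys <- with(sim$truth$adjacencies,
                SyntenyAnchor:::junctionKey(left_scaffold, left_end,
                    right_scaffold, right_end))
            sum(truthKeys %in% cj$junction) / length(truthKeys)
        }, numeric(1)))
    }
    r <- c(recallAt(0), recallAt(0.2), recallAt(0.5))
    expect_equal(r[1], 1)
    expect_true(r[2] >= r[3])
    expect_true(r[1] >= r[2])
})

test_that("super-scaffold sizes are exact sums of member lengths", {
    lens <- scafLengths(c("scf000015", "scf000003", "scf001966"),
        c(7401090, 11886202, 14669))
    expect_identical(superscaffoldSize(lens$scaffold_id, lens), 19301961)
    expect_identical(superscaffoldSize("scf000003", lens), 11886202)
    expect_error(superscaffoldSize(c("scf000015", "scf999999"), lens),
        "no length")
})

test_that("naming strips scf padding and canonicalises orientation", {
    expect_identical(nameSuperscaffold(c("scf000015", "scf000003",
        "scf001966")), "15-3-1966")
    expect_identical(nameSuperscaffold(c("scf000211", "scf000443",
        "scf001018", "scf000328", "scf000242")), "211-443-1018-328-242")
    expect_identical(nameSuperscaffold("scf000007"), "7")
    ## reversal is the same super-scaffold
    expect_identical(nameSuperscaffold(rev(c("scf000015", "scf000003",
        "scf001966"))), "15-3-1966")
    ## non-conforming ids fall back to the raw id
    expect_identical(nameSuperscaffold(c("ctg7", "scf000002")), "ctg7-2")
})
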
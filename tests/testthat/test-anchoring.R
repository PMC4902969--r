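mkMembership <- function(...) {
    ## name = unit, scaffold_id = members
    x <- list(...)
    data.frame(name = rep(names(x), lengths(x)),
        scaffold_id = unlist(x, use.names = FALSE), stringsAsFactors = FALSE)
}

mkMarkers <- function(scaffold, chromosome) {
    data.frame(marker_id = sprintf("m%02d", seq_along(scaffold)),
        scaffold_id = scaffold, position_bp = 1,
        chromosome_id = chromosome, flpter = NA_real_,
        stringsAsFactors = FALSE)
}

test_that("agreeing markers assign, disagreeing markers raise a conflict", {
    units <- mkMembership(u1 = c("scf000001", "scf000002"), u2 = "scf000003",
        u3 = "scf000004")
    res <- assignUnits(units, mkMarkers(
        c("scf000001", "scf000002", "scf000003"), c("chr6", "chr6", "chr2")))
    expect_identical(res$assignments$chromosome_id[
        res$assignments$unit_id == "u1"], "chr6")
    expect_equal(nrow(res$conflicts), 0L)
    expect_identical(res$unassigned, "u3")

    ## markers on two chromosomes: conflict, unit stays unassigned
    res2 <- assignUnits(units, mkMarkers(
        c("scf000001", "scf000002"), c("chr1", "chr3")))
    expect_equal(nrow(res2$conflicts), 1L)
    expect_identical(res2$conflicts$chromosomes, "chr1,chr3")
    expect_false("u1" %in% res2$assignments$unit_id)

    expect_error(assignUnits(units, mkMarkers("scf999999", "chr1")),
        "unknown scaffold")
})

test_that("a planted wrong-chromosome marker always conflicts, never misassigns", {
    set.seed(77)
    for (rep in 1:20) {
        sim <- simulateGenomes(simConfig(nGenes = 80, nChromosomes = 2,
            nScaffolds = 8, markerDensity = 1.5, seed = rep,
            nInversionsA = 2, nTranslocationsA = 0, nFusionsA = 0,
            nFissionsA = 0, nInversionsB = 2, nTranslocationsB = 0,
            nFusionsB = 0, nFissionsB = 0))
        units <- mkMembership(u1 = sim$scaffolds$scaffold_id[1:4],
            u2 = sim$scaffolds$scaffold_id[5:8])
        truth <- setNames(sim$truth$scaffold_chromosome$chromosome_id,
            sim$truth$scaffold_chromosome$scaffold_id)
        mk <- sim$markers
        ## restrict each unit's markers to its dominant true chromosome so
        ## the truth itself is conflict-free (units may straddle chromosomes)
        keep <- unlist(lapply(split(seq_len(nrow(mk)),
            unitMembership(units)[mk$scaffold_id]), function(i) {
            ch <- truth[mk$scaffold_id[i]]
            i[ch == names(sort(table(ch), decreasing = TRUE))[1]]
        }), use.names = FALSE)
        clean <- mk[sort(keep), , drop = FALSE]
        if (nrow(clean) < 2L) next
        res <- assignUnits(units, clean)
        for (i in seq_len(nrow(res$assignments))) {
            u <- res$assignments$unit_id[i]
            scafs <- clean$scaffold_id[unitMembership(units)[clean$scaffold_id] == u]
            expect_identical(res$assignments$chromosome_id[i],
                unname(truth[scafs[1]]))
        }
        ## inject a wrong-chromosome marker into an assigned unit
        if (nrow(res$assignments) == 0L) next
        u <- res$assignments$unit_id[1]
        wrong <- clean[1, ]
        wrong$marker_id <- "planted"
        wrong$scaffold_id <- clean$scaffold_id[
            unitMembership(units)[clean$scaffold_id] == u][1]
        wrong$chromosome_id <- "chrWRONG"
        res3 <- assignUnits(units, rbind(clean, wrong))
        expect_true(u %in% res3$conflicts$unit_id)
        expect_false(u %in% res3$assignments$unit_id)
    }
})

test_that("coverage percentages divide anchored bp by estimated size", {
    units <- mkMembership(u1 = "scf000001", u2 = "scf000002")
    scaffolds <- scafLengths(c("scf000001", "scf000002"), c(70.1e6, 1e6))
    chrom <- data.frame(chromosome_id = c("chr6", "chr7"),
        class = "macro", est_size_bp = c(119.42e6, 10e6))
    res <- assignUnits(units, mkMarkers("scf000001", "chr6"))
    cov <- coverageTable(res, units, scaffolds, chrom)
    ## oracle: direct division, 70.1 / 119.42 = 58.7 %
    expect_equal(cov$percent[cov$chromosome_id == "chr6"], 58.7)
    expect_equal(cov$anchored_Mb[cov$chromosome_id == "chr6"], 70.1)
    expect_equal(cov$anchored_bp[cov$chromosome_id == "chr7"], 0)
    expect_equal(cov$percent[cov$chromosome_id == "chr7"], 0)
    ## totals recomputed from rows
    expect_equal(cov$anchored_bp[cov$chromosome_id == "Total"], 70.1e6)
    expect_equal(cov$percent[cov$chromosome_id == "Total"],
        round(100 * 70.1e6 / sum(chrom$est_size_bp), 1))
    ## anchored bp never exceeds total scaffold bp
    expect_lte(cov$anchored_bp[cov$chromosome_id == "Total"],
        sum(scaffolds$length_bp))
})

test_that("full assignment of a perfectly sized chromosome reads 100 percent", {
    units <- mkMembership(u1 = "scf000001")
    scaffolds <- scafLengths("scf000001", 5e6)
    chrom <- data.frame(chromosome_id = "chr1", class = "macro",
        est_size_bp = 5e6)
    cov <- coverageTable(assignUnits(units, mkMarkers("scf000001", "chr1")),
        units, scaffolds, chrom)
    expect_equal(cov$percent[1], 100)
    ## over-full chromosome warns but reports the value
    chrom$est_size_bp <- 4e6
    expect_warning(cov2 <- coverageTable(
        assignUnits(units, mkMarkers("scf000001", "chr1")),
        units, scaffolds, chrom), "exceeds")
    expect_equal(cov2$percent[1], 125)
})

test_that("flpter maps positions to the unit fraction from the p terminus", {
    expect_equal(flpter(0, 1000), 0)
    expect_equal(flpter(500, 1000), 0.5)
    expect_equal(flpter(1000, 1000), 1)
    expect_error(flpter(1001, 1000), "outside")
    expect_error(flpter(-1, 1000), "outside")
})

test_that("chromosome content sums scaffold bp and gene counts", {
    units <- mkMembership(z1 = c("scf000160", "scf000280"),
        z2 = "scf000179", z3 = "scf000531", a1 = "scf000765")
    scaffolds <- scafLengths(
        c("scf000160", "scf000280", "scf000179", "scf000531", "scf000765"),
        c(2.89e6, 1.87e6, 2.67e6, 0.91e6, 0.50e6))
    genes <- data.frame(
        scaffold_id = c("scf000160", "scf000280", "scf000179", "scf000531"),
        n_genes = c(98, 52, 33, 36))
    mk <- mkMarkers(c("scf000160", "scf000179", "scf000531", "scf000765"),
        c("Z", "Z", "Z", "chr9"))
    res <- assignUnits(units, mk)
    z <- chromosomeContent(res, units, scaffolds, genes, "Z")
    expect_equal(z$total_bp, 8.34e6)
    expect_equal(z$total_genes, 219)
    none <- chromosomeContent(res, units, scaffolds, genes, "chrEmpty")
    expect_equal(none$total_bp, 0)
    expect_equal(none$total_genes, 0)
})
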
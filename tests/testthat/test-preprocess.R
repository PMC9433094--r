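test_that("low-count filtering honors strict and inclusive thresholds", {
    m <- matrix(c(75, 50, 33, 75, 50, 66), 3, 2,
        dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    oc <- OmicCounts(m, "rna")          # row totals 150, 100, 99
    kept <- filterLowCounts(oc, 100, "strict_gt")
    expect_identical(rownames(kept), "a")
    m2 <- matrix(c(10, 9, 10, 10), 2, 2,
        dimnames = list(c("a", "b"), c("s1", "s2")))   # totals 20, 19
    kept2 <- filterLowCounts(OmicCounts(m2, "atac"), 20, "gte")
    expect_identical(rownames(kept2), "a")
    oc3 <- OmicCounts(m, "rna")
    expect_identical(countsMatrix(filterLowCounts(oc3, 0, "gte")), m)
    expect_error(filterLowCounts(oc, 1000, "strict_gt"), "empty matrix")
})

test_that("size factors match median-of-ratios by hand and by oracle", {
    m <- matrix(c(2, 4, 6, 4, 8, 12), 3, 2,
        dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    sf <- computeSizeFactors(m)
    expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
    eq <- matrix(c(2, 4, 2, 4), 2, 2,
        dimnames = list(c("a", "b"), c("s1", "s2")))
    expect_equal(unname(computeSizeFactors(eq)), c(1, 1), tolerance = 1e-12)
    set.seed(11)
    r <- matrix(rpois(60, 50) + 1, 10, 6,
        dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    expect_equal(unname(computeSizeFactors(r)), brute_size_factors(r),
        tolerance = 1e-12)
    z <- matrix(c(0, 0, 5, 3), 2, 2,
        dimnames = list(c("a", "b"), c("s1", "s2")))
    z[2, 1] <- 0   # no all-positive row remains
    expect_error(computeSizeFactors(z), "all-positive")
})

test_that("size factors are scale-equivariant in each column", {
    set.seed(3)
    m <- matrix(rpois(40, 30) + 1, 8, 5,
        dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
    sf <- computeSizeFactors(m)
    m2 <- m; m2[, 3] <- m[, 3] * 5
    sf2 <- computeSizeFactors(m2)
    # size factors are defined up to a common scale (the geometric means
    # rescale too), so equivariance holds for relative factors
    expect_equal((sf2[3] / sf2[1]) / (sf[3] / sf[1]), 5,
        tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("log normalisation matches elementwise recomputation", {
    expect_equal(normalizeLog(matrix(0, 1, 1,
        dimnames = list("g", "s")), factors = 1)[1, 1], 0,
        ignore_attr = TRUE)
    expect_equal(normalizeLog(matrix(7, 1, 1,
        dimnames = list("g", "s")), factors = 1)[1, 1], 3,
        ignore_attr = TRUE)
    set.seed(5)
    m <- matrix(rpois(20, 40), 5, 4,
        dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
    f <- c(0.8, 1, 1.2, 1.5)
    out <- normalizeLog(m, f, pseudocount = 1)
    ref <- m * 0
    for (i in 1:5) for (j in 1:4) ref[i, j] <- log2(m[i, j] / f[j] + 1)
    expect_equal(unclass(out), ref, tolerance = 1e-12, ignore_attr = TRUE)
    expect_error(normalizeLog(m, c(1, -1, 1, 1)), "positive")
})

test_that("group fold changes center on the mean of group means", {
    d <- data.frame(sample_id = paste0("s", 1:8), cell_line = "cl",
        treatment = rep(c("t1", "t2", "t3", "t4"), each = 2), time = "6h",
        replicate = rep(1:2, 4))
    expr <- matrix(rep(c(4, 6, 8, 6), each = 2), 1, 8,
        dimnames = list("g1", d$sample_id))
    gfc <- groupFoldChange(expr, d, cap = NA)
    expect_equal(unname(gfcValues(gfc)[1, ]), c(-2, 0, 2, 0))
    expr2 <- matrix(rep(c(0, 10), each = 4), 1, 8,
        dimnames = list("g1", d$sample_id))
    d2 <- d; d2$treatment <- rep(c("t1", "t2"), each = 4)
    gfc2 <- groupFoldChange(expr2, d2, cap = 2)
    expect_equal(unname(gfcValues(gfc2)[1, ]), c(-2, 2))
})

test_that("uncapped GFC rows sum to zero and match the brute-force oracle", {
    set.seed(21)
    d <- data.frame(sample_id = paste0("s", 1:18), cell_line = "cl",
        treatment = rep(paste0("t", 1:6), each = 3), time = "6h",
        replicate = rep(1:3, 6))
    expr <- matrix(rnorm(20 * 18, 8, 2), 20, 18,
        dimnames = list(paste0("g", 1:20), d$sample_id))
    gfc <- groupFoldChange(expr, d, cap = NA)
    expect_true(max(abs(rowSums(gfcValues(gfc)))) < 1e-9)
    d <- validateDesign(d)
    ref <- brute_gfc(expr, d$group[match(colnames(expr), d$sample_id)])
    expect_equal(gfcValues(gfc), ref, tolerance = 1e-12)
    capped <- groupFoldChange(expr, d, cap = 1.5)
    expect_true(all(abs(gfcValues(capped)) <= 1.5 + 1e-12))
})

test_that("Welch test handles degenerate groups and recovers mean shifts", {
    d <- data.frame(sample_id = paste0("s", 1:6), cell_line = "cl",
        treatment = rep(c("a", "b"), each = 3), time = "6h",
        replicate = rep(1:3, 2))
    expr <- rbind(
        const = rep(5, 6),
        shift = c(5, 5, 5, 3, 3, 3) + c(0, 1e-9, -1e-9, 0, 1e-9, -1e-9))
    colnames(expr) <- d$sample_id
    de <- differentialTest(expr, d, "cl|a|6h", "cl|b|6h")
    expect_equal(de$log2fc[1], 0)
    expect_equal(de$p[1], 1)
    expect_equal(de$log2fc[2], 2, tolerance = 1e-6)
    expect_lt(de$p[2], 0.01)
    expect_true(all(de$padj >= de$p - 1e-15))
    d2 <- d; d2$treatment <- c("a", "b", "b", "b", "b", "b")
    expect_error(differentialTest(expr, d2, "cl|a|6h", "cl|b|6h"),
        "at least 2 samples")
})

test_that("Welch test type-I error is near nominal on null data", {
    d <- data.frame(sample_id = paste0("s", 1:12), cell_line = "cl",
        treatment = rep(c("a", "b"), each = 6), time = "6h",
        replicate = rep(1:6, 2))
    fps <- vapply(1:20, function(s) {
        set.seed(s)
        expr <- matrix(rnorm(100 * 12), 100, 12,
            dimnames = list(paste0("g", 1:100), d$sample_id))
        de <- differentialTest(expr, d, "cl|a|6h", "cl|b|6h")
        mean(de$p < 0.05)
    }, numeric(1))
    expect_lt(abs(mean(fps) - 0.05), 0.03)
})

test_that("reference-peak reduction follows the promoter and tie rules", {
    ann <- data.frame(
        peak_id = c("p1", "p2", "p3", "p4", "p5"),
        chrom = "chr1", start = 0:4 * 100, end = 0:4 * 100 + 50,
        gene = c("G", "G", "H", "H", "K"),
        region_class = c("promoter", "promoter", "intron", "promoter",
            "promoter"),
        is_promoter = c(TRUE, TRUE, FALSE, TRUE, TRUE),
        is_protein_coding = c(TRUE, TRUE, TRUE, TRUE, FALSE))
    stats <- data.frame(peak_id = paste0("p", 1:5),
        p = c(0.04, 0.01, 0.001, 0.2, 0.001),
        variance = c(1, 2, 9, 4, 9))
    map <- mapPeaksToGenes(stats, ann, "min_pvalue")
    expect_equal(map$peak_id[map$gene == "G"], "p2")   # lower p wins
    expect_equal(map$peak_id[map$gene == "H"], "p4")   # p3 not a promoter
    expect_false("K" %in% map$gene)                    # not protein-coding
    map2 <- mapPeaksToGenes(stats, ann, "max_variance")
    expect_equal(map2$peak_id[map2$gene == "G"], "p2") # higher variance
    # tie on p -> lexicographically smaller peak id
    stats$p[1] <- 0.01
    map3 <- mapPeaksToGenes(stats, ann, "min_pvalue")
    expect_equal(map3$peak_id[map3$gene == "G"], "p1")
})

test_that("network input selection returns significant features by variance", {
    set.seed(9)
    expr <- matrix(rnorm(30 * 10), 30, 10,
        dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
    expr <- expr * seq(0.2, 3, length.out = 30)   # known variance ranking
    de <- data.frame(feature = paste0("g", 1:30),
        log2fc = 1, p = 0.001, padj = c(rep(0.001, 20), rep(0.5, 10)))
    sel <- selectNetworkInput(list(de), expr, top_n = 1000)
    expect_setequal(sel, paste0("g", 1:20))
    v <- apply(expr[sel, ], 1, var)
    expect_identical(sel, names(sort(v, decreasing = TRUE)))
    sel5 <- selectNetworkInput(list(de), expr, top_n = 5)
    expect_equal(length(sel5), 5)
    expect_identical(sel5, sel[1:5])
    expect_error(selectNetworkInput(list(de), expr, top_n = 0), "top_n")
})
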
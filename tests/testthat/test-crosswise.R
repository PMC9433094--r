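# helpers to build small two-layer fixtures in pattern space
mk_gfc <- function(m, layer_prefix = NULL) {
    m <- m - rowMeans(m)
    new("GFCMatrix", gfc = m, cap = NA_real_,
        groups = data.frame(group = colnames(m), cell_line = "cl",
            treatment = colnames(m), time = "6h"))
}

mk_net <- function(features, layer, weight = 0.9) {
    nodes <- nsTag(layer, features)
    el <- t(combn(nodes, 2))
    g <- igraph::graph_from_data_frame(data.frame(from = el[, 1],
        to = el[, 2], weight = weight), directed = FALSE)
    new("CoexpressionNetwork", graph = g, layers = layer, cutoff = 0.5)
}

test_that("module pattern matching reproduces brute-force Pearson", {
    set.seed(41)
    a <- matrix(rnorm(15), 3, 5,
        dimnames = list(paste0("r", 1:3), paste0("c", 1:5)))
    b <- matrix(rnorm(20), 4, 5,
        dimnames = list(paste0("a", 1:4), paste0("c", 1:5)))
    mm <- matchModules(a, b)
    expect_equal(nrow(mm), 12)
    for (k in seq_len(nrow(mm)))
        expect_equal(mm$pattern_correlation[k],
            brute_pearson(a[mm$module_rna[k], ], b[mm$module_atac[k], ]),
            tolerance = 1e-12)
    expect_equal(matchModules(a, a)$pattern_correlation[c(1, 5, 9)],
        rep(1, 3), tolerance = 1e-12)
    expect_equal(matchModules(a, -a)$pattern_correlation[c(1, 5, 9)],
        rep(-1, 3), tolerance = 1e-12)
    colnames(b) <- paste0("d", 1:5)
    expect_error(matchModules(a, b), "same group")
})

test_that("vertical integration keeps intra-layer edges and obeys cutoffs", {
    # planted cross-layer pair: identical patterns in both layers
    pat <- rbind(c(2, 2, 0, 0, -1, -1), c(-2, 0, 2, 0, 1, -1))
    gr <- matrix(rep(pat[1, ], each = 10), 10, 6)
    gr <- gr + matrix(rnorm(60, 0, 0.05), 10)
    rownames(gr) <- paste0("rg", 1:10)
    colnames(gr) <- paste0("c", 1:6)
    ga <- matrix(rep(pat[1, ], each = 10), 10, 6)
    ga <- ga + matrix(rnorm(60, 0, 0.05), 10)
    rownames(ga) <- paste0("ag", 1:10)
    colnames(ga) <- paste0("c", 1:6)
    gfc_r <- mk_gfc(gr); gfc_a <- mk_gfc(ga)
    net_r <- mk_net(rownames(gr), "rna")
    net_a <- mk_net(rownames(ga), "atac")
    mods_r <- data.frame(node = nsTag("rna", rownames(gr)),
        module = "maroon", layer = "rna")
    mods_a <- data.frame(node = nsTag("atac", rownames(ga)),
        module = "gold", layer = "atac")

    res <- integrateVertical(net_r, net_a, gfc_r, gfc_a, mods_r, mods_a,
        cross_cutoff = 0.7, algorithm = "infomap", min_size = 10, seed = 2)
    g <- networkGraph(res$network)
    expect_equal(igraph::vcount(g), 20)
    el <- igraph::as_data_frame(g)
    intra <- el[nsLayer(el$from) == nsLayer(el$to), ]
    expect_equal(nrow(intra), 2 * choose(10, 2))  # nothing deleted
    cross <- el[nsLayer(el$from) != nsLayer(el$to), ]
    expect_gt(nrow(cross), 0)
    expect_true(all(cross$weight >= 0.7))
    # matched planted pair merges into one mixed module
    expect_equal(nrow(res$summary), 1)
    expect_equal(res$summary$frac_rna, 0.5, tolerance = 0.1)
    expect_true(res$matches$matched[1])

    # cutoff above all pattern correlations: no cross edges, layer-pure
    res2 <- integrateVertical(net_r, net_a, gfc_r, gfc_a, mods_r, mods_a,
        cross_cutoff = 0.999999, algorithm = "infomap", min_size = 10,
        seed = 2)
    el2 <- igraph::as_data_frame(networkGraph(res2$network))
    expect_equal(sum(nsLayer(el2$from) != nsLayer(el2$to)), 0)
    expect_true(all(res2$summary$frac_rna %in% c(0, 1)))
    expect_equal(mixingScore(res2$summary), 0)

    # cross-layer edge count non-increasing in the cutoff
    n_cross <- vapply(c(0.5, 0.7, 0.9, 0.99), function(ct) {
        r <- integrateVertical(net_r, net_a, gfc_r, gfc_a, mods_r, mods_a,
            cross_cutoff = ct, algorithm = "infomap", min_size = 10,
            seed = 2)
        e <- igraph::as_data_frame(networkGraph(r$network))
        sum(nsLayer(e$from) != nsLayer(e$to))
    }, numeric(1))
    expect_true(all(diff(n_cross) <= 0))

    # namespace collision rejected
    bad <- mk_net(rownames(gr), "rna")
    expect_error(integrateVertical(net_r, bad, gfc_r, gfc_a, mods_r,
        mods_r, cross_cutoff = 0.7), "collide")
})

test_that("cross-layer cutoff scan reports bounded mixing and recommends", {
    set.seed(43)
    base <- c(2, 1, 0, -1, -2, 0)
    gr <- matrix(rep(base, each = 12), 12, 6) + rnorm(72, 0, 0.05)
    ga <- matrix(rep(base, each = 12), 12, 6) + rnorm(72, 0, 0.05)
    dimnames(gr) <- list(paste0("rg", 1:12), paste0("c", 1:6))
    dimnames(ga) <- list(paste0("ag", 1:12), paste0("c", 1:6))
    scan <- crosslayerCutoffScan(mk_net(rownames(gr), "rna"),
        mk_net(rownames(ga), "atac"), mk_gfc(gr), mk_gfc(ga),
        data.frame(node = nsTag("rna", rownames(gr)), module = "maroon",
            layer = "rna"),
        data.frame(node = nsTag("atac", rownames(ga)), module = "gold",
            layer = "atac"),
        cutoffs = c(0.5, 0.9, 0.999999), algorithm = "infomap",
        min_size = 10, seed = 3)
    expect_true(all(scan$mixing_score >= 0 & scan$mixing_score <= 1))
    expect_equal(scan$n_matched_pairs[3], 0)
    expect_equal(scan$mixing_score[3], 0)
    expect_gte(scan$n_matched_pairs[1], 1)
    expect_gt(scan$mixing_score[1], 0)
    rec <- attr(scan, "recommended")
    expect_true(rec %in% c(0.5, 0.9))
    expect_error(crosslayerCutoffScan(mk_net("x", "rna"),
        mk_net("y", "atac"), mk_gfc(gr), mk_gfc(ga),
        data.frame(node = "rna::x", module = "m", layer = "rna"),
        data.frame(node = "atac::y", module = "m", layer = "atac"),
        cutoffs = numeric()), "empty")
})

test_that("pairwise concordance applies sign, and/or and order rules", {
    de <- data.frame(feature = c("A", "B", "C", "D"),
        log2fc = c(1.2, 1.2, -0.4, 0.8),
        p = c(0.001, 0.001, 0.5, 0.4),
        padj = c(0.01, 0.01, 0.6, 0.5))
    dar <- data.frame(feature = c("A", "B", "C", "D"),
        log2fc = c(0.8, -0.8, -0.6, 0.5),
        p = c(0.03, 0.2, 0.01, 0.6))
    cc <- pairwiseConcordance(de, dar, lag = "same_time")
    expect_setequal(cc$gene, c("A", "B", "C"))  # D significant nowhere
    expect_equal(cc$quadrant[cc$gene == "A"], "up-up")
    expect_equal(cc$quadrant[cc$gene == "B"], "discordant")
    # significant only in ATAC, both negative -> included as down-down
    expect_equal(cc$quadrant[cc$gene == "C"], "down-down")
    # invariant to input row order
    cc2 <- pairwiseConcordance(de[4:1, ], dar[c(2, 4, 1, 3), ],
        lag = "same_time")
    expect_identical(cc, cc2)
    expect_warning(
        empty <- pairwiseConcordance(de,
            data.frame(feature = "Z", log2fc = 1, p = 0.01)),
        "disjoint")
    expect_equal(nrow(empty), 0)
    expect_equal(unique(pairwiseConcordance(de, dar,
        lag = "atac6h_rna12h")$lag), "atac6h_rna12h")
})
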
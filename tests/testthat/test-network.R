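make_gfc <- function(m) {
    # wrap a plain matrix (rows centered) as a GFCMatrix for network tests
    m <- m - rowMeans(m)
    groups <- data.frame(group = colnames(m),
        cell_line = "cl", treatment = colnames(m), time = "6h")
    new("GFCMatrix", gfc = m, cap = NA_real_, groups = groups)
}

test_that("pattern correlation matches the textbook formula", {
    set.seed(31)
    m <- matrix(rnorm(30), 6, 5,
        dimnames = list(paste0("g", 1:6), paste0("c", 1:5)))
    gfc <- make_gfc(m)
    cc <- correlationMatrix(gfc)
    expect_equal(cc, brute_corr_matrix(gfc@gfc), tolerance = 1e-12)
    m2 <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = -c(1, 2, 3, 4))
    colnames(m2) <- paste0("c", 1:4)
    cc2 <- correlationMatrix(make_gfc(m2))
    expect_equal(cc2["a", "b"], 1)
    expect_equal(cc2["a", "c"], -1)
    expect_error(correlationMatrix(make_gfc(m[, 1:2, drop = FALSE])),
        "at least 3")
    m3 <- rbind(m, flat = rep(0, 5))
    expect_warning(correlationMatrix(make_gfc(m3)), "zero-variance")
})

test_that("cutoff scan counts edges and nodes with known toy correlations", {
    # 4 nodes: corr(a,b)=0.9, corr(a,c)=0.6, corr(b,d)=0.3, rest ~0
    cc <- diag(4)
    dimnames(cc) <- list(letters[1:4], letters[1:4])
    cc["a", "b"] <- cc["b", "a"] <- 0.9
    cc["a", "c"] <- cc["c", "a"] <- 0.6
    cc["b", "d"] <- cc["d", "b"] <- 0.3
    scan <- cutoffScan(cc, grid = c(0.25, 0.5, 0.8))
    expect_equal(scan$n_edges, c(3, 2, 1))
    expect_equal(scan$n_nodes, c(4, 3, 2))
    expect_true(all(diff(scan$n_edges) <= 0))
    one <- diag(2); one[1, 2] <- one[2, 1] <- 1
    dimnames(one) <- list(c("x", "y"), c("x", "y"))
    s1 <- cutoffScan(one, grid = 1)
    expect_equal(s1$n_edges, 1)
    expect_equal(s1$n_nodes, 2)
    expect_error(cutoffScan(cc, grid = numeric()), "empty")
})

test_that("network construction applies inclusive positive-only cutoffs", {
    cc <- diag(3)
    dimnames(cc) <- list(c("a", "b", "c"), c("a", "b", "c"))
    cc["a", "b"] <- cc["b", "a"] <- -0.95
    cc["a", "c"] <- cc["c", "a"] <- 0.70
    net <- buildNetwork(cc, 0.7, "rna")
    el <- igraph::as_data_frame(networkGraph(net))
    expect_equal(nrow(el), 1)   # negative pair excluded, boundary kept
    expect_setequal(c(el$from, el$to), nsTag("rna", c("a", "c")))
    expect_equal(el$weight, 0.7)
    # 5-clique at 0.99 keeps all C(5,2) edges over cutoff 0.9
    k5 <- matrix(0.99, 5, 5); diag(k5) <- 1
    dimnames(k5) <- list(paste0("n", 1:5), paste0("n", 1:5))
    expect_equal(igraph::ecount(networkGraph(buildNetwork(k5, 0.9, "rna"))),
        10)
    expect_error(buildNetwork(cc, 1.2, "rna"), "cutoff")
})

test_that("raising the cutoff never adds edges", {
    set.seed(13)
    m <- matrix(rnorm(200), 20, 10)
    dimnames(m) <- list(paste0("g", 1:20), paste0("c", 1:10))
    cc <- cor(t(m))
    counts <- vapply(seq(0.1, 0.9, 0.1), function(ct)
        igraph::ecount(networkGraph(buildNetwork(cc, ct, "rna"))),
        numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("module detection separates planted cliques and enforces min size", {
    # two disconnected 20-node near-cliques
    blk <- function(n, off) {
        m <- matrix(0.95, n, n); diag(m) <- 1
        dimnames(m) <- list(paste0("g", off + 1:n), paste0("g", off + 1:n))
        m
    }
    cc <- as.matrix(Matrix::bdiag(blk(20, 0), blk(20, 20)))
    dimnames(cc) <- list(paste0("g", 1:40), paste0("g", 1:40))
    net <- buildNetwork(cc, 0.7, "rna")
    for (alg in c("walktrap", "infomap", "leiden")) {
        mods <- detectModules(net, alg, min_size = 15, seed = 5)
        real <- mods[mods$module != "unassigned", ]
        expect_equal(length(unique(real$module)), 2)
        expect_true(all(table(real$module) == 20))
        truth <- rep(1:2, each = 20)[match(nsStrip(mods$node),
            paste0("g", 1:40))]
        expect_equal(adjustedRandIndex(mods$module, truth), 1)
    }
    # a 10-node clique below min_size is unassigned
    cc10 <- blk(10, 0)
    net10 <- buildNetwork(cc10, 0.7, "rna")
    mods10 <- detectModules(net10, "walktrap", min_size = 15, seed = 5)
    expect_true(all(mods10$module == "unassigned"))
    # infomap with a fixed seed is reproducible
    m1 <- detectModules(net, "infomap", min_size = 15, seed = 9)
    m2 <- detectModules(net, "infomap", min_size = 15, seed = 9)
    expect_identical(m1, m2)
})

test_that("module mean GFC patterns match the columnwise mean oracle", {
    set.seed(17)
    m <- matrix(rnorm(40), 8, 5,
        dimnames = list(paste0("g", 1:8), paste0("c", 1:5)))
    gfc <- make_gfc(m)
    mods <- data.frame(node = nsTag("rna", paste0("g", 1:8)),
        module = rep(c("maroon", "steelblue"), each = 4), layer = "rna")
    mm <- moduleGFCMeans(mods, gfc)
    expect_equal(mm["maroon", ], colMeans(gfc@gfc[1:4, ]), tolerance = 1e-12)
    expect_equal(mm["steelblue", ], colMeans(gfc@gfc[5:8, ]),
        tolerance = 1e-12)
    # identical member vectors -> mean equals the shared vector
    m2 <- matrix(rep(c(1, -1, 0, 2, -2), each = 3), 3, 5, byrow = FALSE)
    m2 <- matrix(rep(c(1, -1, 0, 2, -2), 3), 3, 5, byrow = TRUE,
        dimnames = list(paste0("g", 1:3), paste0("c", 1:5)))
    gfc2 <- make_gfc(m2)
    mods2 <- data.frame(node = nsTag("rna", paste0("g", 1:3)),
        module = "maroon", layer = "rna")
    expect_equal(unname(moduleGFCMeans(mods2, gfc2)["maroon", ]),
        unname(gfc2@gfc[1, ]))
    expect_error(moduleGFCMeans(data.frame(node = "rna::missing",
        module = "m", layer = "rna"), gfc), "absent")
})

test_that("horizontal merge averages shared edges and keeps private ones", {
    mk <- function(edges) {
        g <- igraph::graph_from_data_frame(edges, directed = FALSE)
        new("CoexpressionNetwork", graph = g, layers = "rna", cutoff = 0.5)
    }
    a <- mk(data.frame(from = c("rna::x", "rna::x"),
        to = c("rna::y", "rna::z"), weight = c(0.6, 0.75)))
    b <- mk(data.frame(from = "rna::x", to = "rna::y", weight = 0.8))
    m <- mergeHorizontal(a, b)
    el <- igraph::as_data_frame(networkGraph(m))
    w_xy <- el$weight[(el$from == "rna::x" & el$to == "rna::y") |
        (el$from == "rna::y" & el$to == "rna::x")]
    expect_equal(w_xy, 0.7)
    w_xz <- el$weight[(el$from == "rna::x" & el$to == "rna::z") |
        (el$from == "rna::z" & el$to == "rna::x")]
    expect_equal(w_xz, 0.75)
    atac <- mk(data.frame(from = "atac::x", to = "atac::y", weight = 0.9))
    atac@layers <- "atac"
    expect_error(mergeHorizontal(a, atac), "same layer")
})

test_that("horizontal merge is commutative and idempotent on random graphs", {
    set.seed(23)
    rand_net <- function(seed) {
        set.seed(seed)
        n <- 12
        cc <- cor(matrix(rnorm(n * 8), 8, n))
        dimnames(cc) <- list(paste0("g", 1:n), paste0("g", 1:n))
        buildNetwork(cc, 0.3, "rna")
    }
    canon <- function(net) {
        el <- igraph::as_data_frame(networkGraph(net))
        key <- paste(pmin(el$from, el$to), pmax(el$from, el$to))
        o <- order(key)
        list(nodes = sort(igraph::V(networkGraph(net))$name),
            keys = key[o], weights = unname(el$weight[o]))
    }
    for (trial in 1:100) {
        a <- rand_net(trial); b <- rand_net(trial + 1000)
        ab <- mergeHorizontal(a, b); ba <- mergeHorizontal(b, a)
        expect_equal(canon(ab), canon(ba))
        aa <- mergeHorizontal(a, a)
        expect_equal(canon(aa), canon(a))
        expect_equal(sort(igraph::V(networkGraph(ab))$name),
            sort(union(igraph::V(networkGraph(a))$name,
                igraph::V(networkGraph(b))$name)))
    }
})
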
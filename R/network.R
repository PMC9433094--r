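# Single-layer co-expression networks from GFC patterns, module detection,
# and horizontal (same-omic, cross-cell-line) merging.

#' Pearson correlation of GFC patterns
#'
#' Correlates feature GFC row vectors across condition groups. Zero-variance
#' rows cannot be correlated and are dropped with a warning.
#'
#' @param gfc a [GFCMatrix-class] object.
#' @param features features to include (default: all).
#' @param groups group columns to correlate over (default: all; per-cell-line
#'   networks pass that cell line's groups). At least 3 groups are required.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(gfc, features = rownames(gfcValues(gfc)),
                              groups = colnames(gfcValues(gfc))) {
    m <- gfcValues(gfc)
    miss <- setdiff(features, rownames(m))
    if (length(miss))
        stop("feature(s) absent from GFC matrix: ",
            paste(head(miss, 5), collapse = ", "))
    m <- m[features, groups, drop = FALSE]
    if (ncol(m) < 3)
        stop("need at least 3 condition groups for pattern correlation")
    v <- apply(m, 1, var)
    if (any(v == 0)) {
        warning(sum(v == 0), " zero-variance feature(s) dropped")
        m <- m[v > 0, , drop = FALSE]
    }
    cc <- cor(t(m))
    diag(cc) <- 1
    cc
}

#' Scan correlation cutoffs
#'
#' For each candidate cutoff: the number of non-isolated nodes, the edge
#' count, and the R^2 of a log-log linear fit to the degree distribution
#' (scale-free-ness, the usual empirical aid for choosing the cutoff).
#'
#' @param corr symmetric correlation matrix ([correlationMatrix()]).
#' @param grid cutoffs in `(0, 1]`.
#' @return `data.frame` with columns `cutoff`, `n_nodes`, `n_edges`,
#'   `power_law_r2` (`NA` when fewer than 3 distinct degrees).
#' @export
cutoffScan <- function(corr, grid = seq(0.5, 0.95, by = 0.05)) {
    if (!length(grid)) stop("empty cutoff grid")
    if (any(grid <= 0 | grid > 1)) stop("cutoffs must be in (0, 1]")
    up <- corr
    up[lower.tri(up, diag = TRUE)] <- NA
    rows <- lapply(grid, function(ct) {
        adj <- !is.na(up) & up >= ct & up > 0
        deg <- rowSums(adj | t(adj))
        dd <- table(deg[deg > 0])
        r2 <- NA_real_
        if (length(dd) >= 3) {
            fit <- stats::lm(log10(as.numeric(dd)) ~
                log10(as.numeric(names(dd))))
            r2 <- summary(fit)$r.squared
        }
        data.frame(cutoff = ct, n_nodes = sum(deg > 0), n_edges = sum(adj),
            power_law_r2 = r2)
    })
    do.call(rbind, rows)
}

#' Pick a cutoff from a scan (heuristic)
#'
#' Smallest grid cutoff whose degree distribution fits a power law with
#' `R^2 >= r2_min`; falls back to the cutoff with the best fit.
#'
#' @param scan a [cutoffScan()] table.
#' @param r2_min minimum acceptable fit (default 0.8).
#' @return numeric(1) cutoff.
#' @export
suggestCutoff <- function(scan, r2_min = 0.8) {
    ok <- which(!is.na(scan$power_law_r2) & scan$power_law_r2 >= r2_min)
    if (length(ok)) return(scan$cutoff[min(ok)])
    scan$cutoff[which.max(scan$power_law_r2)]
}

#' Build a co-expression network
#'
#' Undirected edge between two features iff their GFC-pattern correlation is
#' positive and at or above the cutoff; weight = correlation. Isolated nodes
#' are dropped; node ids are layer-namespaced (`"layer::feature"`).
#'
#' @param corr symmetric correlation matrix.
#' @param cutoff correlation cutoff in `(0, 1]`.
#' @param layer `"rna"` or `"atac"`.
#' @return a [CoexpressionNetwork-class] object.
#' @export
buildNetwork <- function(corr, cutoff, layer = c("rna", "atac")) {
    layer <- match.arg(layer)
    if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
    up <- corr
    up[lower.tri(up, diag = TRUE)] <- NA
    sel <- which(!is.na(up) & up >= cutoff & up > 0, arr.ind = TRUE)
    nodes <- nsTag(layer, rownames(corr))
    el <- data.frame(
        from = nodes[sel[, 1]], to = nodes[sel[, 2]],
        weight = up[sel], stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
        vertices = data.frame(name = nodes))
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
    new("CoexpressionNetwork", graph = g, layers = layer, cutoff = cutoff)
}

#' Detect regulation modules
#'
#' Community detection on the weighted graph (walktrap, infomap or leiden);
#' communities smaller than `min_size` are relabeled `"unassigned"`.
#' Modules are named by color, largest first. Deterministic given `seed`.
#'
#' @param net a [CoexpressionNetwork-class] object.
#' @param algorithm `"walktrap"`, `"infomap"` or `"leiden"`.
#' @param min_size minimum module size (default 15).
#' @param seed integer seed for the stochastic algorithms.
#' @param walktrap_steps random-walk length for walktrap (default 4).
#' @return `data.frame` with columns `node`, `module`, `layer`.
#' @export
detectModules <- function(net, algorithm = c("walktrap", "infomap", "leiden"),
                          min_size = 15, seed = 1, walktrap_steps = 4) {
    algorithm <- match.arg(algorithm)
    g <- networkGraph(net)
    if (igraph::vcount(g) == 0) stop("network is empty")
    comm <- withr::with_seed(seed, switch(algorithm,
        walktrap = igraph::cluster_walktrap(g, steps = walktrap_steps),
        infomap = igraph::cluster_infomap(g),
        leiden = igraph::cluster_leiden(g, objective_function = "modularity",
            n_iterations = 5)))
    memb <- igraph::membership(comm)
    sizes <- table(memb)
    big <- names(sizes)[sizes >= min_size]
    # largest first, ties by community index for determinism
    big <- big[order(-sizes[big], as.integer(big))]
    label <- setNames(rep("unassigned", length(sizes)), names(sizes))
    label[big] <- .moduleNames(length(big))
    data.frame(node = names(memb), module = unname(label[as.character(memb)]),
        layer = nsLayer(names(memb)), row.names = NULL,
        stringsAsFactors = FALSE)
}

#' Mean GFC pattern per module
#'
#' @param modules module table ([detectModules()]); `"unassigned"` nodes are
#'   skipped.
#' @param gfc a [GFCMatrix-class] covering every module member (node ids are
#'   looked up with their layer namespace stripped).
#' @return matrix, modules x condition groups.
#' @export
moduleGFCMeans <- function(modules, gfc) {
    m <- gfcValues(gfc)
    tab <- modules[modules$module != "unassigned", ]
    feats <- nsStrip(tab$node)
    miss <- setdiff(feats, rownames(m))
    if (length(miss))
        stop("module member(s) absent from GFC matrix: ",
            paste(head(miss, 5), collapse = ", "))
    mods <- unique(tab$module)
    out <- t(vapply(mods, function(mm)
        colMeans(m[nsStrip(tab$node[tab$module == mm]), , drop = FALSE]),
        numeric(ncol(m))))
    rownames(out) <- mods
    out
}

#' Merge two same-layer networks horizontally
#'
#' Node and edge union of two parent networks (typically the two cell
#' lines); an edge present in both parents takes the arithmetic mean of its
#' two weights, edges private to one parent keep theirs.
#'
#' @param netA,netB [CoexpressionNetwork-class] objects of the same layer.
#' @return merged [CoexpressionNetwork-class]; its recorded cutoff is the
#'   smaller of the parents'.
#' @export
mergeHorizontal <- function(netA, netB) {
    if (!identical(netA@layers, netB@layers))
        stop("horizontal merge requires networks of the same layer")
    ea <- igraph::as_data_frame(netA@graph, what = "edges")
    eb <- igraph::as_data_frame(netB@graph, what = "edges")
    key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "\r")
    ea$key <- key(ea); eb$key <- key(eb)
    shared <- intersect(ea$key, eb$key)
    wa <- setNames(ea$weight, ea$key)
    wb <- setNames(eb$weight, eb$key)
    all_keys <- union(ea$key, eb$key)
    w <- ifelse(all_keys %in% shared,
        (wa[all_keys] + wb[all_keys]) / 2,
        ifelse(all_keys %in% ea$key, wa[all_keys], wb[all_keys]))
    nodes <- union(igraph::V(netA@graph)$name, igraph::V(netB@graph)$name)
    el <- if (length(all_keys)) {
        ft <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
        data.frame(from = ft[, 1], to = ft[, 2], weight = unname(w))
    } else data.frame(from = character(), to = character(),
        weight = numeric())
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
        vertices = data.frame(name = nodes))
    new("CoexpressionNetwork", graph = g, layers = netA@layers,
        cutoff = min(netA@cutoff, netB@cutoff))
}
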
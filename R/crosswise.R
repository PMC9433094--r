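# Vertical (RNA <-> ATAC) network integration and the pairwise DE/DAR
# concordance analysis.

#' Correlate module regulation patterns across layers
#'
#' Full cross-layer Pearson correlation matrix of module mean-GFC vectors,
#' one row per (RNA module, ATAC module) pair.
#'
#' @param means_rna,means_atac module x group matrices ([moduleGFCMeans()])
#'   with identical group columns.
#' @return `data.frame` with columns `module_rna`, `module_atac`,
#'   `pattern_correlation`.
#' @export
matchModules <- function(means_rna, means_atac) {
    if (!identical(colnames(means_rna), colnames(means_atac)))
        stop("module mean matrices must share the same group columns")
    cc <- cor(t(means_rna), t(means_atac))
    data.frame(
        module_rna = rep(rownames(means_rna), times = ncol(cc)),
        module_atac = rep(colnames(cc), each = nrow(cc)),
        pattern_correlation = as.vector(cc),
        row.names = NULL, stringsAsFactors = FALSE)
}

# per-module layer composition of a module table over a two-layer graph
.layer_composition <- function(modules) {
    tab <- modules[modules$module != "unassigned", ]
    mods <- unique(tab$module)
    out <- do.call(rbind, lapply(mods, function(mm) {
        lay <- tab$layer[tab$module == mm]
        n <- length(lay)
        data.frame(module = mm, size = n,
            n_rna = sum(lay == "rna"), n_atac = sum(lay == "atac"),
            frac_rna = sum(lay == "rna") / n,
            frac_atac = sum(lay == "atac") / n)
    }))
    if (is.null(out))
        out <- data.frame(module = character(), size = integer(),
            n_rna = integer(), n_atac = integer(),
            frac_rna = numeric(), frac_atac = numeric())
    out
}

#' Layer-mixing score of an integrated clustering
#'
#' Mean over modules of the normalized Shannon entropy of the (RNA, ATAC)
#' member fractions: 0 iff every module is layer-pure, 1 iff every module is
#' a 50/50 mixture.
#'
#' @param composition table from the `summary` element of
#'   [integrateVertical()] (columns `frac_rna`, `frac_atac`).
#' @return numeric(1) in `[0, 1]` (0 for an empty table).
#' @export
mixingScore <- function(composition) {
    if (!nrow(composition)) return(0)
    mean(.entropy2(composition$frac_rna))
}

#' Vertically integrate the RNA and ATAC networks
#'
#' The integrated graph is the union of both layers' nodes and all
#' intra-layer edges. For every matched module pair (pattern correlation at
#' or above `cross_cutoff`), cross-layer edges are added between member
#' features whose feature-level GFC-vector correlation is also at or above
#' `cross_cutoff`, weighted by that correlation. The result is reclustered
#' and module mean GFCs are recomputed, with each node contributing its own
#' layer's GFC vector over the shared condition-group axis.
#'
#' @param netRNA,netATAC per-layer [CoexpressionNetwork-class] objects
#'   (disjoint `rna::`/`atac::` namespaces).
#' @param gfcRNA,gfcATAC per-layer [GFCMatrix-class] objects over the same
#'   condition groups.
#' @param modulesRNA,modulesATAC per-layer module tables ([detectModules()]).
#' @param matches module-pair correlations ([matchModules()]); computed from
#'   the module tables when `NULL`.
#' @param cross_cutoff minimum cross-layer correlation in `(0, 1]`.
#' @param algorithm,min_size,seed reclustering parameters
#'   (see [detectModules()]).
#' @return list with `network` (integrated [CoexpressionNetwork-class]),
#'   `modules` (node table), `summary` (per-module size and layer
#'   composition), `means` (module x group mean-GFC matrix) and `matches`
#'   (the match table with a `matched` flag).
#' @export
integrateVertical <- function(netRNA, netATAC, gfcRNA, gfcATAC,
        modulesRNA, modulesATAC, matches = NULL, cross_cutoff = 0.7,
        algorithm = "walktrap", min_size = 15, seed = 1) {
    if (cross_cutoff <= 0 || cross_cutoff > 1)
        stop("cross_cutoff must be in (0, 1]")
    nr <- igraph::V(netRNA@graph)$name
    na <- igraph::V(netATAC@graph)$name
    if (length(intersect(nr, na)))
        stop("node namespaces collide between layers")
    if (is.null(matches))
        matches <- matchModules(moduleGFCMeans(modulesRNA, gfcRNA),
            moduleGFCMeans(modulesATAC, gfcATAC))
    matches$matched <- matches$pattern_correlation >= cross_cutoff

    er <- igraph::as_data_frame(netRNA@graph, what = "edges")
    ea <- igraph::as_data_frame(netATAC@graph, what = "edges")
    cross <- list()
    mrna <- gfcValues(gfcRNA); matac <- gfcValues(gfcATAC)
    for (i in which(matches$matched)) {
        rn <- modulesRNA$node[modulesRNA$module == matches$module_rna[i]]
        an <- modulesATAC$node[modulesATAC$module == matches$module_atac[i]]
        rn <- intersect(rn, nr); an <- intersect(an, na)
        if (!length(rn) || !length(an)) next
        cc <- cor(t(mrna[nsStrip(rn), , drop = FALSE]),
            t(matac[nsStrip(an), , drop = FALSE]))
        sel <- which(cc >= cross_cutoff, arr.ind = TRUE)
        if (nrow(sel))
            cross[[length(cross) + 1L]] <- data.frame(
                from = rn[sel[, 1]], to = an[sel[, 2]],
                weight = cc[sel], stringsAsFactors = FALSE)
    }
    el <- rbind(er, ea, if (length(cross)) do.call(rbind, cross))
    el <- el[!duplicated(paste(pmin(el$from, el$to),
        pmax(el$from, el$to))), ]
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
        vertices = data.frame(name = c(nr, na)))
    net <- new("CoexpressionNetwork", graph = g,
        layers = c(netRNA@layers, netATAC@layers),
        cutoff = min(netRNA@cutoff, netATAC@cutoff, cross_cutoff))
    modules <- detectModules(net, algorithm = algorithm,
        min_size = min_size, seed = seed)
    comp <- .layer_composition(modules)

    # module means: each member contributes its own layer's GFC vector
    tab <- modules[modules$module != "unassigned", ]
    mods <- unique(tab$module)
    means <- NULL
    if (length(mods)) {
        means <- t(vapply(mods, function(mm) {
            nodes <- tab$node[tab$module == mm]
            vecs <- rbind(
                mrna[nsStrip(nodes[nsLayer(nodes) == "rna"]), ,
                    drop = FALSE],
                matac[nsStrip(nodes[nsLayer(nodes) == "atac"]), ,
                    drop = FALSE])
            colMeans(vecs)
        }, numeric(ncol(mrna))))
        rownames(means) <- mods
    }
    list(network = net, modules = modules, summary = comp, means = means,
        matches = matches)
}

#' Scan cross-layer cutoffs for maximal layer mixing
#'
#' Runs the vertical integration at each candidate cutoff and reports the
#' number of matched module pairs, the layer [mixingScore()] of the
#' reclustered result and the module count. The recommended cutoff is the
#' mixing-score argmax (ties resolved to the higher cutoff).
#'
#' @inheritParams integrateVertical
#' @param cutoffs candidate cutoffs in `(0, 1]`.
#' @return `data.frame` (`cutoff`, `n_matched_pairs`, `mixing_score`,
#'   `n_modules`) with the recommended cutoff in attribute
#'   `"recommended"`.
#' @export
crosslayerCutoffScan <- function(netRNA, netATAC, gfcRNA, gfcATAC,
        modulesRNA, modulesATAC, cutoffs = seq(0.4, 0.9, by = 0.1),
        algorithm = "walktrap", min_size = 15, seed = 1) {
    if (!length(cutoffs)) stop("empty cutoff list")
    matches <- matchModules(moduleGFCMeans(modulesRNA, gfcRNA),
        moduleGFCMeans(modulesATAC, gfcATAC))
    rows <- lapply(cutoffs, function(ct) {
        res <- integrateVertical(netRNA, netATAC, gfcRNA, gfcATAC,
            modulesRNA, modulesATAC, matches = matches, cross_cutoff = ct,
            algorithm = algorithm, min_size = min_size, seed = seed)
        data.frame(cutoff = ct,
            n_matched_pairs = sum(res$matches$matched),
            mixing_score = mixingScore(res$summary),
            n_modules = nrow(res$summary))
    })
    out <- do.call(rbind, rows)
    best <- max(out$mixing_score)
    attr(out, "recommended") <-
        max(out$cutoff[out$mixing_score == best])
    out
}

#' Pairwise DE/DAR concordance
#'
#' Joins a gene-level differential-expression table with a gene-level
#' promoter-accessibility table (already reduced to reference peaks) and
#' classifies genes significant in at least one layer by the signs of their
#' fold changes. The `lag` label records whether the ATAC table precedes the
#' RNA table in time (chromatin at 6 h vs transcription at 12 h).
#'
#' @param de_rna differential table with columns `feature`, `log2fc`,
#'   `padj`.
#' @param dar_gene gene-level differential-accessibility table with columns
#'   `feature` (gene), `log2fc`, `p`.
#' @param alpha_rna,alpha_atac significance thresholds (defaults 0.05 on
#'   `padj` and `p` respectively).
#' @param lag `"same_time"` or `"atac6h_rna12h"`.
#' @return `data.frame` (`gene`, `log2fc_rna`, `padj_rna`, `log2fc_atac`,
#'   `p_atac`, `quadrant`, `lag`), genes sorted lexicographically so the
#'   output is invariant to input row order.
#' @export
pairwiseConcordance <- function(de_rna, dar_gene, alpha_rna = 0.05,
        alpha_atac = 0.05, lag = c("same_time", "atac6h_rna12h")) {
    lag <- match.arg(lag)
    genes <- intersect(de_rna$feature, dar_gene$feature)
    if (!length(genes)) {
        warning("RNA and ATAC gene sets are disjoint; empty concordance table")
        return(data.frame(gene = character(), log2fc_rna = numeric(),
            padj_rna = numeric(), log2fc_atac = numeric(),
            p_atac = numeric(), quadrant = character(), lag = character()))
    }
    r <- de_rna[match(genes, de_rna$feature), ]
    a <- dar_gene[match(genes, dar_gene$feature), ]
    keep <- (!is.na(r$padj) & r$padj < alpha_rna) |
        (!is.na(a$p) & a$p < alpha_atac)
    out <- data.frame(gene = genes, log2fc_rna = r$log2fc,
        padj_rna = r$padj, log2fc_atac = a$log2fc, p_atac = a$p,
        stringsAsFactors = FALSE)[keep, ]
    out$quadrant <- ifelse(out$log2fc_rna > 0 & out$log2fc_atac > 0, "up-up",
        ifelse(out$log2fc_rna < 0 & out$log2fc_atac < 0, "down-down",
            "discordant"))
    out$lag <- lag
    out <- out[order(out$gene), ]
    rownames(out) <- NULL
    out
}
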
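# Independent brute-force implementations used as oracles. Deliberately
# naive (double loops, textbook formulas) and kept free of any package
# internals.

brute_size_factors <- function(m) {
    pos <- apply(m, 1, function(x) all(x > 0))
    geo <- apply(m[pos, , drop = FALSE], 1, function(x) prod(x)^(1 / length(x)))
    vapply(seq_len(ncol(m)), function(j)
        median(m[pos, j] / geo), numeric(1))
}

brute_pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

brute_corr_matrix <- function(m) {
    n <- nrow(m)
    out <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
        out[i, j] <- brute_pearson(m[i, ], m[j, ])
    dimnames(out) <- list(rownames(m), rownames(m))
    out
}

brute_gfc <- function(expr, groups, cap = NA) {
    ug <- unique(groups)
    out <- matrix(0, nrow(expr), length(ug),
        dimnames = list(rownames(expr), ug))
    for (i in seq_len(nrow(expr))) {
        gm <- vapply(ug, function(g) mean(expr[i, groups == g]), numeric(1))
        v <- gm - mean(gm)
        if (!is.na(cap)) v <- pmin(pmax(v, -cap), cap)
        out[i, ] <- v
    }
    out
}

brute_gaussian_statistic <- function(expr) {
    out <- expr * 0
    for (i in seq_len(nrow(expr))) {
        x <- expr[i, ]
        h <- sd(x) / 4
        for (j in seq_along(x))
            out[i, j] <- mean(pnorm((x[j] - x) / h))
    }
    out
}

# brute-force KS walk mirroring the documented algorithm, written step by
# step against the definition rather than vectorised
brute_es <- function(stat_vec, set_genes, tau = 1, es_mode = "maxdiff",
                     integrate = FALSE) {
    ord <- order(stat_vec, decreasing = TRUE)
    genes <- names(stat_vec)[ord]
    inset <- genes %in% set_genes
    wsum <- sum(abs(stat_vec[ord][inset])^tau)
    n_out <- sum(!inset)
    walk <- 0
    cum <- numeric(length(genes))
    for (k in seq_along(genes)) {
        if (inset[k]) {
            walk <- walk + if (wsum > 0)
                abs(stat_vec[ord][k])^tau / wsum else 1 / sum(inset)
        } else {
            walk <- walk - 1 / n_out
        }
        cum[k] <- walk
    }
    if (integrate) {
        w_all <- abs(stat_vec[ord])^tau
        null_dev <- cumsum(w_all) / sum(w_all) -
            seq_along(genes) / length(genes)
        return((sum(cum) - sum(null_dev)) / length(genes))
    }
    if (es_mode == "maxdiff") max(c(cum, 0)) + min(c(cum, 0))
    else cum[which.max(abs(cum))]
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
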
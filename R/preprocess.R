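# Count filtering, median-of-ratios normalisation, group fold change,
# Welch differential tests and the peak->gene reduction.

#' Filter low-count features
#'
#' RNA counts are conventionally prefiltered with a strict `> min_total` rule
#' and ATAC peaks with a `>= min_total` rule; both are exposed via `mode`.
#'
#' @param counts an [OmicCounts-class] object.
#' @param min_total non-negative row-total threshold.
#' @param mode `"strict_gt"` keeps rows with total `> min_total`;
#'   `"gte"` keeps rows with total `>= min_total`.
#' @return the filtered [OmicCounts-class]; samples unchanged.
#' @export
filterLowCounts <- function(counts, min_total, mode = c("strict_gt", "gte")) {
    mode <- match.arg(mode)
    stopifnot(is(counts, "OmicCounts"), min_total >= 0)
    tot <- rowSums(countsMatrix(counts))
    keep <- if (mode == "strict_gt") tot > min_total else tot >= min_total
    if (!any(keep)) stop("empty matrix after filtering")
    counts[keep, ]
}

#' Median-of-ratios size factors
#'
#' The DESeq-style estimator: per sample, the median over all-positive
#' features of the ratio between its count and the feature's geometric mean
#' across samples.
#'
#' @param counts an [OmicCounts-class] object or a counts matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
computeSizeFactors <- function(counts) {
    m <- if (is(counts, "OmicCounts")) countsMatrix(counts) else as.matrix(counts)
    pos <- rowSums(m > 0) == ncol(m)
    if (!any(pos))
        stop("no feature with all-positive counts; size factors undefined")
    lg <- log(m[pos, , drop = FALSE])
    geo <- rowMeans(lg)
    apply(exp(lg - geo), 2, median)
}

#' Log-scale normalisation
#'
#' `log2(count / size_factor + pseudocount)`; a monotone, variance-flattening
#' transform standing in for a variance-stabilising transformation.
#'
#' @param counts an [OmicCounts-class] object or counts matrix.
#' @param factors per-sample positive size factors ([computeSizeFactors()]).
#' @param pseudocount positive offset added before the log (default 1).
#' @return numeric matrix, features x samples, log2 scale, with the factors
#'   and pseudocount recorded as attributes `"size_factors"`, `"pseudocount"`.
#' @export
normalizeLog <- function(counts, factors = computeSizeFactors(counts),
                         pseudocount = 1) {
    m <- if (is(counts, "OmicCounts")) countsMatrix(counts) else as.matrix(counts)
    if (length(factors) != ncol(m))
        stop("one size factor per sample required")
    if (any(factors <= 0)) stop("size factors must be positive")
    if (pseudocount <= 0) stop("pseudocount must be positive")
    out <- log2(sweep(m, 2, factors, "/") + pseudocount)
    attr(out, "size_factors") <- factors
    attr(out, "pseudocount") <- pseudocount
    out
}

#' Group fold changes
#'
#' For each feature, the GFC of a condition group is that group's mean
#' log2 expression minus the mean of all group means; on the log scale the
#' difference is the fold change of the group mean from the overall mean.
#' Values are optionally clipped to `[-cap, cap]`.
#'
#' @param expr normalized log2 matrix, features x samples.
#' @param design validated design covering every column of `expr`.
#' @param cap positive cap, or `NA` for uncapped (default 2).
#' @return a [GFCMatrix-class], columns ordered by first appearance of each
#'   group in `design`.
#' @export
groupFoldChange <- function(expr, design, cap = 2) {
    design <- validateDesign(design)
    idx <- match(colnames(expr), design$sample_id)
    if (anyNA(idx))
        stop("expr columns missing from design: ",
            paste(colnames(expr)[is.na(idx)], collapse = ", "))
    grp <- design$group[idx]
    groups <- unique(design$group)
    if (length(groups) < 2) stop("need at least 2 condition groups")
    if (!all(groups %in% grp)) {
        groups <- groups[groups %in% grp]
        if (length(groups) < 2) stop("need at least 2 non-empty groups")
    }
    gm <- vapply(groups, function(g)
        rowMeans(expr[, grp == g, drop = FALSE]), numeric(nrow(expr)))
    if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1,
        dimnames = list(rownames(expr), groups))
    gfc <- gm - rowMeans(gm)
    if (!is.na(cap)) gfc <- pmin(pmax(gfc, -cap), cap)
    gi <- design[match(groups, design$group),
        c("group", "cell_line", "treatment", "time")]
    rownames(gi) <- NULL
    new("GFCMatrix", gfc = gfc, cap = as.numeric(cap), groups = gi)
}

#' Welch two-group differential test
#'
#' Per-feature log2 fold change (`mean(A) - mean(B)` on the log scale),
#' two-sided Welch t p-value and Benjamini-Hochberg adjusted p. Degenerate
#' features (zero variance in both groups) get p = 1 when the means are
#' equal and p = 0 otherwise.
#'
#' @param expr normalized log2 matrix, features x samples.
#' @param design validated design.
#' @param groupA,groupB condition-group keys (see [groupKey()]), or vectors
#'   of keys pooled together; contrast is A vs B. Each side needs >= 2
#'   samples.
#' @return `data.frame` with columns `feature`, `log2fc`, `p`, `padj`,
#'   `mean_expr`, rows in input feature order.
#' @export
differentialTest <- function(expr, design, groupA, groupB) {
    design <- validateDesign(design)
    grp <- design$group[match(colnames(expr), design$sample_id)]
    a <- which(grp %in% groupA)
    b <- which(grp %in% groupB)
    if (length(a) < 2 || length(b) < 2)
        stop("both groups need at least 2 samples")
    xa <- expr[, a, drop = FALSE]; xb <- expr[, b, drop = FALSE]
    ma <- rowMeans(xa); mb <- rowMeans(xb)
    va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
    na <- length(a); nb <- length(b)
    se2 <- va / na + vb / nb
    lfc <- ma - mb
    p <- rep(NA_real_, nrow(expr))
    zero <- se2 == 0
    p[zero] <- ifelse(lfc[zero] == 0, 1, 0)
    ok <- !zero
    tt <- lfc[ok] / sqrt(se2[ok])
    df <- se2[ok]^2 / ((va[ok] / na)^2 / (na - 1) + (vb[ok] / nb)^2 / (nb - 1))
    p[ok] <- 2 * pt(-abs(tt), df)
    data.frame(feature = rownames(expr), log2fc = lfc, p = p,
        padj = p.adjust(p, "BH"),
        mean_expr = rowMeans(expr[, c(a, b), drop = FALSE]),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Reduce promoter peaks to one reference peak per gene
#'
#' Restricts to peaks annotated as promoters of protein-coding genes, then
#' keeps a single reference peak per gene: the lowest p-value
#' (`"min_pvalue"`, used for differential comparisons) or the highest
#' variance (`"max_variance"`, used for expression-level summaries). Ties
#' break to the lexicographically smaller `peak_id`.
#'
#' @param peak_stats `data.frame` with column `peak_id` plus `p`
#'   (for `min_pvalue`) or `variance` (for `max_variance`).
#' @param annotation peak annotation `data.frame` ([readPeakAnnotation()]),
#'   covering every peak in `peak_stats`.
#' @param rule `"min_pvalue"` or `"max_variance"`.
#' @return `data.frame` with columns `gene`, `peak_id`, `rule`.
#' @export
mapPeaksToGenes <- function(peak_stats, annotation,
                            rule = c("min_pvalue", "max_variance")) {
    rule <- match.arg(rule)
    miss <- setdiff(peak_stats$peak_id, annotation$peak_id)
    if (length(miss))
        stop("annotation does not cover peak(s): ",
            paste(head(miss, 5), collapse = ", "))
    ann <- annotation[match(peak_stats$peak_id, annotation$peak_id), ]
    keep <- ann$is_promoter & ann$is_protein_coding
    df <- data.frame(peak_id = peak_stats$peak_id[keep],
        gene = ann$gene[keep], stringsAsFactors = FALSE)
    if (rule == "min_pvalue") {
        if (!"p" %in% colnames(peak_stats)) stop("rule min_pvalue needs a 'p' column")
        df$crit <- peak_stats$p[keep]
        df <- df[order(df$gene, df$crit, df$peak_id), ]
    } else {
        if (!"variance" %in% colnames(peak_stats))
            stop("rule max_variance needs a 'variance' column")
        df$crit <- peak_stats$variance[keep]
        df <- df[order(df$gene, -df$crit, df$peak_id), ]
    }
    df <- df[!duplicated(df$gene), ]
    data.frame(gene = df$gene, peak_id = df$peak_id, rule = rule,
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the network input features of one layer
#'
#' Features significant in at least one treated-vs-control contrast, ranked
#' by variance of their normalized values and truncated to the `top_n` most
#' variable (the per-layer "top variable" rule; the cross-layer union is
#' taken by the network builder).
#'
#' @param de_tables list of differential tables ([differentialTest()]) for
#'   the treated-vs-control contrasts of this layer.
#' @param expr normalized log2 matrix over which variance is computed
#'   (default: all samples of the dataset; configurable upstream).
#' @param top_n maximum number of features (default 1000).
#' @param alpha significance threshold (default 0.05).
#' @param sig_col column tested against `alpha`: `"padj"` (RNA convention)
#'   or `"p"` (ATAC convention).
#' @return character vector of feature ids, most variable first.
#' @export
selectNetworkInput <- function(de_tables, expr, top_n = 1000, alpha = 0.05,
                               sig_col = c("padj", "p")) {
    sig_col <- match.arg(sig_col)
    if (top_n <= 0) stop("top_n must be positive")
    if (!length(de_tables)) stop("no differential tables supplied")
    sig <- unique(unlist(lapply(de_tables, function(d)
        d$feature[!is.na(d[[sig_col]]) & d[[sig_col]] < alpha])))
    sig <- intersect(sig, rownames(expr))
    if (!length(sig)) return(character())
    v <- apply(expr[sig, , drop = FALSE], 1, var)
    head(names(sort(v, decreasing = TRUE)), top_n)
}
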
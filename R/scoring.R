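# Per-sample gene-set enrichment (GSVA-style kernel statistic + weighted
# KS random walk; ssGSEA-style rank walk) and the sensitivity score.

#' Cumulative expression statistic across samples
#'
#' The kernel-CDF step of GSVA-style scoring: for gene i and sample j the
#' statistic is the kernel estimate of how high x_ij sits in gene i's
#' cross-sample distribution. Gaussian kernel:
#' `(1/n) * sum_k Phi((x_ij - x_ik) / h_i)` with bandwidth `h_i = sd_i / 4`;
#' Poisson kernel for counts (`mean_k ppois(x_ij, x_ik + 0.5)`); `"none"`
#' passes values through. Zero-variance genes are set to 0.5 everywhere
#' (with a message), carrying no ranking information.
#'
#' @param expr numeric matrix, genes x samples (>= 3 samples).
#' @param kcdf `"gaussian"`, `"poisson"` or `"none"`.
#' @return matrix of the same shape.
#' @export
expressionStatistic <- function(expr, kcdf = c("gaussian", "poisson", "none")) {
    kcdf <- match.arg(kcdf)
    expr <- as.matrix(expr)
    if (kcdf == "none") return(expr)
    if (ncol(expr) < 3)
        stop("kernel statistic needs at least 3 samples")
    out <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
    if (kcdf == "gaussian") {
        sds <- apply(expr, 1, sd)
        flat <- sds == 0
        if (any(flat)) {
            message(sum(flat), " zero-variance gene(s): statistic set to 0.5")
            out[flat, ] <- 0.5
        }
        for (i in which(!flat)) {
            x <- expr[i, ]
            out[i, ] <- colMeans(pnorm(outer(x, x, "-") / (sds[i] / 4),
                lower.tail = FALSE))
        }
    } else {
        for (i in seq_len(nrow(expr))) {
            x <- expr[i, ]
            out[i, ] <- colMeans(ppois(matrix(x, length(x), length(x),
                byrow = TRUE), lambda = x + 0.5))
        }
    }
    out
}

# one-sample walk over genes ordered by decreasing statistic.
# w: statistic vector (named by gene), set: logical in-set indicator.
# Ties keep stable input order (documented: ES can depend on it for
# degenerate data).
.ks_walk <- function(w, inset, tau, es_mode, integrate = FALSE) {
    ord <- order(w, decreasing = TRUE)
    inset <- inset[ord]
    incr <- abs(w[ord])^tau
    incr[!inset] <- 0
    tot_in <- sum(incr)
    n_out <- sum(!inset)
    step <- numeric(length(w))
    step[inset] <- if (tot_in > 0) incr[inset] / tot_in else
        1 / sum(inset)
    step[!inset] <- -1 / n_out
    cum <- cumsum(step)
    if (integrate) {
        # center the integrated walk at its expectation under a uniformly
        # scattered set: with position weights w, the expected in-set CDF at
        # position k is W(k)/W(N) while the out-set CDF stays ~ k/N, so an
        # uncentered integral is biased for tau > 0
        n <- length(w)
        w_all <- abs(w[ord])^tau
        null_dev <- cumsum(w_all) / sum(w_all) - seq_len(n) / n
        return((sum(cum) - sum(null_dev)) / n)
    }
    if (es_mode == "maxdiff") {
        max(cum, 0) + min(cum, 0)
    } else {
        cum[which.max(abs(cum))]
    }
}

#' Per-sample enrichment score of a gene set
#'
#' A weighted Kolmogorov-Smirnov-like random walk down the sample's gene
#' ranking: genes are ordered by decreasing statistic; in-set genes step the
#' walk up proportionally to `|statistic|^tau`, out-of-set genes step it
#' down uniformly. `"gsva"` walks over the kernel statistics
#' ([expressionStatistic()]) and returns the largest positive deviation plus
#' the largest negative deviation (`es_mode = "maxdiff"`) or the single
#' largest-magnitude deviation (`"maxdev"`). `"ssgsea"` walks over
#' within-sample expression ranks and returns the normalized integrated walk
#' (mean running deviation, centered at its expectation for a uniformly
#' scattered set so up/down differences are comparable across samples).
#'
#' @param stat_matrix genes x samples matrix: kernel statistics for
#'   `"gsva"`, raw expression for `"ssgsea"`.
#' @param gene_set character vector; must intersect the rownames and not
#'   cover them entirely.
#' @param method `"gsva"` or `"ssgsea"`.
#' @param tau rank weight exponent (default 1).
#' @param es_mode `"maxdiff"` or `"maxdev"` (gsva only).
#' @return named numeric vector, one ES per sample.
#' @export
enrichmentScore <- function(stat_matrix, gene_set,
        method = c("gsva", "ssgsea"), tau = 1,
        es_mode = c("maxdiff", "maxdev")) {
    method <- match.arg(method)
    es_mode <- match.arg(es_mode)
    genes <- rownames(stat_matrix)
    inset <- genes %in% gene_set
    if (!any(inset)) stop("gene set does not intersect the expression genes")
    if (all(inset)) stop("gene set covers all genes; ES undefined")
    vapply(seq_len(ncol(stat_matrix)), function(j) {
        x <- stat_matrix[, j]
        if (method == "ssgsea") {
            # walk on within-sample ranks; largest expression = largest rank
            r <- rank(x, ties.method = "first")
            .ks_walk(r, inset, tau, es_mode, integrate = TRUE)
        } else {
            .ks_walk(x, inset, tau, es_mode)
        }
    }, numeric(1)) |> setNames(colnames(stat_matrix))
}

#' Per-sample sensitivity scores
#'
#' `score = ES(up signature) - ES(down signature)` per sample; samples whose
#' basal transcriptome already leans toward the sensitive line's profile
#' score high.
#'
#' @param expr genes x samples expression matrix (continuous, e.g.
#'   normalized basal transcriptomes).
#' @param signature a [GeneSignature-class] with non-empty intersections of
#'   both sets with the expression genes.
#' @param method,tau,es_mode,kcdf scoring parameters (see
#'   [enrichmentScore()]; `kcdf` feeds [expressionStatistic()] and is
#'   ignored for `"ssgsea"`).
#' @return `data.frame` (`sample_id`, `es_up`, `es_down`, `score`).
#' @export
sensitivityScore <- function(expr, signature, method = c("gsva", "ssgsea"),
        tau = 1, es_mode = c("maxdiff", "maxdev"), kcdf = "gaussian") {
    method <- match.arg(method)
    es_mode <- match.arg(es_mode)
    stopifnot(is(signature, "GeneSignature"))
    if (!length(intersect(upGenes(signature), rownames(expr))) ||
        !length(intersect(downGenes(signature), rownames(expr))))
        stop("both signature sets must intersect the expression genes")
    stat <- if (method == "gsva") expressionStatistic(expr, kcdf) else expr
    es_up <- enrichmentScore(stat, upGenes(signature), method, tau, es_mode)
    es_down <- enrichmentScore(stat, downGenes(signature), method, tau,
        es_mode)
    data.frame(sample_id = colnames(expr), es_up = unname(es_up),
        es_down = unname(es_down), score = unname(es_up - es_down),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate sensitivity scores with a measured phenotype
#'
#' @param scores a [sensitivityScore()] table.
#' @param phenotype numeric vector named by sample id (or aligned with
#'   `scores`).
#' @return list with `r` (Pearson), `p` (two-sided, t distribution with
#'   n - 2 df) and `n`.
#' @export
validateScores <- function(scores, phenotype) {
    if (!is.null(names(phenotype)))
        phenotype <- phenotype[scores$sample_id]
    ok <- !is.na(phenotype) & !is.na(scores$score)
    x <- scores$score[ok]; y <- phenotype[ok]
    if (length(x) < 3) stop("need at least 3 paired observations")
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance in scores or phenotype")
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
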
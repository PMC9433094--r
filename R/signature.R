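# Perturbation-informed sensitivity signature: module scoring by deltaGFC and
# thr_score, q50 selection, baseline-DE intersection, and control signatures.

#' Per-module deltaGFC for one cell line
#'
#' The change in a module's mean GFC under treatment:
#' `deltaGFC = mean-GFC(treated group) - mean-GFC(control group)` for the
#' given cell line (groups passed as condition-group keys; several keys per
#' side are averaged).
#'
#' @param means module x group matrix ([moduleGFCMeans()] or the `means`
#'   element of [integrateVertical()]).
#' @param treated,control condition-group key(s), e.g.
#'   `groupKey("lineA", "M", "6h")`.
#' @return named numeric vector, one deltaGFC per module.
#' @export
moduleDeltaGFC <- function(means, treated, control) {
    miss <- setdiff(c(treated, control), colnames(means))
    if (length(miss))
        stop("group(s) absent from module means: ",
            paste(miss, collapse = ", "))
    rowMeans(means[, treated, drop = FALSE]) -
        rowMeans(means[, control, drop = FALSE])
}

#' Module threshold scores and q50 selection
#'
#' `thr_score = deltaGFC(sensitive) - deltaGFC(resistant)` per module;
#' modules strictly above the median thr_score (interpolated median for even
#' counts) are selected — the modules whose treatment response differs most
#' between the two cell lines.
#'
#' @param dgfc_sensitive,dgfc_resistant named deltaGFC vectors over the same
#'   modules ([moduleDeltaGFC()]).
#' @return `data.frame` (`module`, `dgfc_sensitive`, `dgfc_resistant`,
#'   `thr_score`, `selected`) with the median in attribute `"q50"`.
#' @export
moduleThresholdScores <- function(dgfc_sensitive, dgfc_resistant) {
    if (length(dgfc_sensitive) < 2)
        stop("median selection needs at least 2 modules")
    if (!identical(names(dgfc_sensitive), names(dgfc_resistant)))
        stop("deltaGFC vectors must cover the same modules in the same order")
    thr <- dgfc_sensitive - dgfc_resistant
    q50 <- median(thr)
    out <- data.frame(module = names(thr),
        dgfc_sensitive = unname(dgfc_sensitive),
        dgfc_resistant = unname(dgfc_resistant),
        thr_score = unname(thr), selected = unname(thr > q50),
        row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "q50") <- q50
    out
}

#' Build the perturbation-informed signature
#'
#' Genes of the selected modules (layer namespaces stripped, duplicates
#' across layers counted once) intersected with the baseline differential
#' contrast between the untreated sensitive and resistant lines: baseline-up
#' genes (`padj < padj_max`, `log2fc > lfc_min`) form the up signature,
#' baseline-down genes the down signature.
#'
#' @param modules integrated module table (`modules` element of
#'   [integrateVertical()], or any table with `node`, `module` columns).
#' @param selected character vector of selected module ids
#'   (e.g. from [moduleThresholdScores()]).
#' @param baseline_de differential table for sensitive-vs-resistant
#'   untreated controls ([differentialTest()]; positive `log2fc` = higher in
#'   the sensitive line).
#' @param padj_max,lfc_min baseline thresholds (defaults 0.01 and 1).
#' @param drug optional drug label recorded in the provenance.
#' @return a [GeneSignature-class] object.
#' @export
buildSignature <- function(modules, selected, baseline_de,
                           padj_max = 0.01, lfc_min = 1, drug = NA_character_) {
    if (!length(selected)) stop("no modules selected")
    genes <- unique(nsStrip(modules$node[modules$module %in% selected]))
    if (!length(genes)) stop("selected modules have no members")
    de <- baseline_de[!is.na(baseline_de$padj) &
        baseline_de$padj < padj_max, ]
    up <- intersect(genes, de$feature[de$log2fc > lfc_min])
    down <- intersect(genes, de$feature[de$log2fc < -lfc_min])
    if (!length(up) && !length(down)) stop("empty signature")
    GeneSignature(up, down, provenance = list(
        modules = selected, padj_max = padj_max, lfc_min = lfc_min,
        drug = drug, method = "perturbation_informed"))
}

#' Control signatures
#'
#' Negative/positive controls matched in size to a real signature: random
#' disjoint gene draws from the universe, or the top up- and bottom
#' down-log2FC genes of the baseline contrast.
#'
#' @param universe character vector of candidate genes (for `"top_lfc"`,
#'   genes absent from `baseline_de` are ignored).
#' @param n_up,n_down set sizes.
#' @param method `"random"` or `"top_lfc"`.
#' @param baseline_de required for `"top_lfc"`: table with `feature`,
#'   `log2fc`.
#' @param seed integer seed for the random draw.
#' @return a [GeneSignature-class] object.
#' @export
makeControlSignature <- function(universe, n_up, n_down,
        method = c("random", "top_lfc"), baseline_de = NULL, seed = 1) {
    method <- match.arg(method)
    universe <- unique(as.character(universe))
    if (length(universe) < n_up + n_down)
        stop("universe smaller than requested signature size")
    if (method == "random") {
        picked <- withr::with_seed(seed,
            sample(universe, n_up + n_down, replace = FALSE))
        up <- picked[seq_len(n_up)]
        down <- picked[n_up + seq_len(n_down)]
    } else {
        if (is.null(baseline_de)) stop("top_lfc needs baseline_de")
        de <- baseline_de[baseline_de$feature %in% universe, ]
        de <- de[order(de$log2fc, decreasing = TRUE), ]
        if (nrow(de) < n_up + n_down)
            stop("baseline table smaller than requested signature size")
        up <- de$feature[seq_len(n_up)]
        down <- rev(de$feature)[seq_len(n_down)]
    }
    GeneSignature(up, down,
        provenance = list(method = method, seed = seed))
}
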
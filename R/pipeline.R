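# End-to-end crosswise workflow: preprocess both layers, build and merge
# per-cell-line networks, integrate vertically, and distill the
# perturbation-informed signature.

#' Treated-vs-control differential tables for one layer
#'
#' One Welch contrast per (cell line, treatment != ctrl, time), treated vs
#' the same cell line's control at the same time point.
#'
#' @param expr normalized log2 matrix.
#' @param design validated design.
#' @param control treatment label of the controls (default `"ctrl"`).
#' @return named list of [differentialTest()] tables
#'   (`cell|treatment|time`).
#' @export
treatedContrasts <- function(expr, design, control = "ctrl") {
    design <- validateDesign(design)
    combos <- unique(design[design$treatment != control,
        c("cell_line", "treatment", "time")])
    out <- list()
    for (i in seq_len(nrow(combos))) {
        cl <- combos$cell_line[i]; tr <- combos$treatment[i]
        ti <- combos$time[i]
        out[[groupKey(cl, tr, ti)]] <- differentialTest(expr, design,
            groupKey(cl, tr, ti), groupKey(cl, control, ti))
    }
    out
}

#' Run the crosswise integration and signature workflow
#'
#' From raw two-layer counts to the perturbation-informed signature:
#' low-count filtering, median-of-ratios normalisation, treated-vs-control
#' differential tables, promoter reference-peak reduction, per-layer
#' selection of significant high-variance features, GFC computation, one
#' co-expression network per cell line and layer, horizontal merging,
#' module detection, vertical integration, deltaGFC/thr_score module
#' selection at the scoring time point and the baseline-DE intersection.
#'
#' @param rna,atac [OmicCounts-class] objects (RNA genes, ATAC peaks).
#' @param annotation peak annotation `data.frame` ([readPeakAnnotation()]).
#' @param design validated design shared by both layers.
#' @param sensitive,resistant cell-line labels of the design.
#' @param drug treatment label scored against the control (default `"M"`).
#' @param control control treatment label (default `"ctrl"`).
#' @param config configuration list ([defaultConfig()]).
#' @return list with the intermediate products (`expr`, `de`, `gfc`,
#'   `networks`, `modules`, `integration`, `scores`, `baseline_de`) and the
#'   final `signature`.
#' @export
runCrosswisePipeline <- function(rna, atac, annotation, design,
        sensitive, resistant, drug = "M", control = "ctrl",
        config = defaultConfig()) {
    design <- validateDesign(design)
    pp <- config$preprocess; dd <- config$de; nw <- config$network
    vc <- config$vcocena; sg <- config$signature

    rna <- filterLowCounts(rna, pp$rna_min_total, pp$rna_filter_mode)
    atac <- filterLowCounts(atac, pp$atac_min_total, pp$atac_filter_mode)
    expr_rna <- normalizeLog(rna, pseudocount = pp$pseudocount)
    expr_atac_pk <- normalizeLog(atac, pseudocount = pp$pseudocount)

    de_rna <- treatedContrasts(expr_rna, design, control)
    dar_pk <- treatedContrasts(expr_atac_pk, design, control)

    # reference promoter peak per gene: lowest p over the treated contrasts
    pmin_tab <- data.frame(peak_id = rownames(expr_atac_pk),
        p = do.call(pmin, c(lapply(dar_pk, function(d) d$p),
            list(na.rm = TRUE))))
    peak_map <- mapPeaksToGenes(pmin_tab, annotation, rule = dd$peak_rule)
    expr_atac <- expr_atac_pk[peak_map$peak_id, , drop = FALSE]
    rownames(expr_atac) <- peak_map$gene
    dar_gene <- lapply(dar_pk, function(d) {
        d <- d[match(peak_map$peak_id, d$feature), ]
        d$feature <- peak_map$gene
        d
    })

    sel_rna <- selectNetworkInput(de_rna, expr_rna, top_n = dd$top_n,
        alpha = dd$alpha_rna, sig_col = "padj")
    sel_atac <- selectNetworkInput(dar_gene, expr_atac, top_n = dd$top_n,
        alpha = dd$alpha_atac, sig_col = "p")
    if (length(sel_rna) < 2 || length(sel_atac) < 2)
        stop("too few significant features to build networks")

    gfc_rna <- groupFoldChange(expr_rna[sel_rna, , drop = FALSE], design,
        cap = pp$gfc_cap)
    gfc_atac <- groupFoldChange(expr_atac[sel_atac, , drop = FALSE], design,
        cap = pp$gfc_cap)

    cells <- unique(design$cell_line)
    net_layer <- function(gfc, cutoff, layer) {
        nets <- lapply(cells, function(cl) {
            grp <- unique(design$group[design$cell_line == cl])
            buildNetwork(correlationMatrix(gfc, groups = grp), cutoff,
                layer)
        })
        Reduce(mergeHorizontal, nets)
    }
    net_rna <- net_layer(gfc_rna, nw$cutoff_rna, "rna")
    net_atac <- net_layer(gfc_atac, nw$cutoff_atac, "atac")
    mod_rna <- detectModules(net_rna, nw$algorithm, nw$min_module_size,
        seed = nw$seed, walktrap_steps = nw$walktrap_steps)
    mod_atac <- detectModules(net_atac, nw$algorithm, nw$min_module_size,
        seed = nw$seed, walktrap_steps = nw$walktrap_steps)

    integration <- integrateVertical(net_rna, net_atac, gfc_rna, gfc_atac,
        mod_rna, mod_atac, cross_cutoff = vc$cross_cutoff,
        algorithm = vc$algorithm, min_size = nw$min_module_size,
        seed = nw$seed)
    if (is.null(integration$means) || nrow(integration$means) < 2)
        stop("vertical integration produced fewer than 2 modules")

    tt <- sg$treated_time
    dgfc_s <- moduleDeltaGFC(integration$means,
        groupKey(sensitive, drug, tt), groupKey(sensitive, control, tt))
    dgfc_r <- moduleDeltaGFC(integration$means,
        groupKey(resistant, drug, tt), groupKey(resistant, control, tt))
    scores <- moduleThresholdScores(dgfc_s, dgfc_r)

    ctrl_s <- unique(design$group[design$cell_line == sensitive &
        design$treatment == control])
    ctrl_r <- unique(design$group[design$cell_line == resistant &
        design$treatment == control])
    baseline_de <- differentialTest(expr_rna, design, ctrl_s, ctrl_r)

    signature <- buildSignature(integration$modules,
        scores$module[scores$selected], baseline_de,
        padj_max = sg$padj_max, lfc_min = sg$lfc_min, drug = drug)

    list(expr = list(rna = expr_rna, atac = expr_atac),
        de = list(rna = de_rna, atac_gene = dar_gene, peak_map = peak_map),
        gfc = list(rna = gfc_rna, atac = gfc_atac),
        networks = list(rna = net_rna, atac = net_atac),
        modules = list(rna = mod_rna, atac = mod_atac),
        integration = integration, scores = scores,
        baseline_de = baseline_de, signature = signature)
}
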
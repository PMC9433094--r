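# Synthetic perturbation datasets and basal cohorts with known ground truth.
# The generator plants co-regulated modules (per layer or cross-layer) on a
# negative-binomial count background and, separately, basal-transcriptome
# cohorts carrying a latent sensitivity factor.

#' Specify a planted co-regulated module
#'
#' @param module_id character label for the planted module.
#' @param layer `"rna"`, `"atac"` or `"both"` (the same genes planted in both
#'   layers with the same pattern, emulating promoter accessibility driving
#'   transcription).
#' @param n_features number of features per layer (>= 1).
#' @param gfc_pattern named numeric vector: target log2 group fold change per
#'   condition-group key (names must match `design$group`); groups omitted
#'   default to 0.
#' @param baseline_shift signed log2 offset applied to the second cell line
#'   of the design (0 = no baseline difference between cell lines).
#' @return a `planted_module` list.
#' @export
plantedModule <- function(module_id, layer = c("rna", "atac", "both"),
                          n_features, gfc_pattern, baseline_shift = 0) {
    layer <- match.arg(layer)
    stopifnot(n_features >= 1, all(is.finite(gfc_pattern)),
        is.finite(baseline_shift))
    if (is.null(names(gfc_pattern)))
        stop("gfc_pattern must be named by condition-group key")
    structure(list(module_id = module_id, layer = layer,
        n_features = as.integer(n_features),
        gfc_pattern = gfc_pattern, baseline_shift = baseline_shift),
        class = "planted_module")
}

#' The standard two-cell-line perturbation design
#'
#' 2 cell lines x \{ctrl, drug M, drug B\} x \{6 h, 12 h\} x `n_rep`
#' replicates — the layout of the perturbation experiments the simulator
#' emulates (12 condition groups, 36 samples at the default 3 replicates).
#'
#' @param cell_lines,treatments,times factor levels of the design.
#' @param n_rep replicates per condition group.
#' @return validated design `data.frame`.
#' @export
standardDesign <- function(cell_lines = c("sensitive", "resistant"),
                           treatments = c("ctrl", "M", "B"),
                           times = c("6h", "12h"), n_rep = 3) {
    g <- expand.grid(replicate = seq_len(n_rep), time = times,
        treatment = treatments, cell_line = cell_lines,
        stringsAsFactors = FALSE)
    g$sample_id <- paste(g$cell_line, g$treatment, g$time,
        paste0("r", g$replicate), sep = "_")
    validateDesign(g[, c("sample_id", "cell_line", "treatment", "time",
        "replicate")])
}

# log2 mean matrix (features x samples) for one layer's planted + background
# features; returns list(mu_log2, truth)
.layer_means <- function(specs, design, baseline_mean, n_background,
                         feature_ids, shift_line) {
    groups <- design$group
    n_mod <- sum(vapply(specs, function(s) s$n_features, 0L))
    stopifnot(length(feature_ids) == n_mod + n_background)
    mu <- matrix(baseline_mean, n_mod + n_background, nrow(design),
        dimnames = list(feature_ids, design$sample_id))
    truth <- data.frame(feature = feature_ids,
        module = "background", baseline_shift = 0,
        stringsAsFactors = FALSE)
    row <- 1L
    for (s in specs) {
        pat <- setNames(rep(0, length(unique(groups))), unique(groups))
        unknown <- setdiff(names(s$gfc_pattern), names(pat))
        if (length(unknown))
            stop("gfc_pattern group(s) not in design: ",
                paste(unknown, collapse = ", "))
        pat[names(s$gfc_pattern)] <- s$gfc_pattern
        offs <- pat[groups] +
            ifelse(design$cell_line == shift_line, s$baseline_shift, 0)
        idx <- row:(row + s$n_features - 1L)
        mu[idx, ] <- mu[idx, ] + rep(offs, each = s$n_features)
        truth$module[idx] <- s$module_id
        truth$baseline_shift[idx] <- s$baseline_shift
        row <- row + s$n_features
    }
    # background features get a flat, feature-specific baseline
    if (n_background > 0) {
        bg <- (n_mod + 1L):(n_mod + n_background)
        mu[bg, ] <- mu[bg, ] + runif(n_background, -2, 2)
    }
    list(mu = mu, truth = truth)
}

.nb_counts <- function(mu_log2, dispersion, size_factors) {
    mu <- sweep(2^mu_log2, 2, size_factors, "*")
    cnt <- matrix(rnbinom(length(mu), size = 1 / dispersion, mu = mu),
        nrow(mu), ncol(mu), dimnames = dimnames(mu))
    cnt
}

#' Simulate a two-layer perturbation dataset
#'
#' Counts are drawn feature-wise from a negative binomial whose log2 mean is
#' `baseline_mean` + the feature's planted group pattern + its cell-line
#' baseline shift; per-sample library-size factors are log-normal with the
#' given coefficient of variation. Background features have flat means.
#' ATAC features are simulated directly at promoter-peak level with a
#' generated annotation (a fraction of genes get a second promoter peak and
#' some decoy non-promoter peaks, so reference-peak tie-breaking is
#' exercisable).
#'
#' @param specs list of [plantedModule()] specifications.
#' @param design validated design ([standardDesign()]).
#' @param baseline_mean baseline log2 mean count (default 7).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2),
#'   must be > 0 (default 0.01; clonal cell-line replicates are tight).
#' @param library_size_cv coefficient of variation of the log-normal
#'   library-size factors (default 0.1).
#' @param n_background_rna,n_background_atac background features per layer.
#' @param extra_peak_fraction fraction of ATAC genes receiving a second
#'   promoter peak (weaker signal); `nonpromoter_fraction` of genes get a
#'   decoy non-promoter peak.
#' @param seed integer seed; the output is a pure function of the arguments
#'   and the seed.
#' @return list with `rna`, `atac` ([OmicCounts-class]), `annotation`
#'   (peak annotation `data.frame`), `design`, and `truth` (list of
#'   per-layer feature tables and the module x group pattern matrix).
#' @export
simulatePerturbationDataset <- function(specs, design = standardDesign(),
        baseline_mean = 7, dispersion = 0.01, library_size_cv = 0.1,
        n_background_rna = 300, n_background_atac = 300,
        extra_peak_fraction = 0.1, nonpromoter_fraction = 0.05, seed = 1) {
    stopifnot(dispersion > 0)
    design <- validateDesign(design)
    shift_line <- unique(design$cell_line)[1]
    withr::with_seed(seed, {
        rna_specs <- Filter(function(s) s$layer %in% c("rna", "both"), specs)
        atac_specs <- Filter(function(s) s$layer %in% c("atac", "both"), specs)
        rna_mod_genes <- unlist(lapply(rna_specs, function(s)
            sprintf("g_%s_%03d", s$module_id, seq_len(s$n_features))))
        # "both" modules reuse the RNA gene names, so the two layers carry
        # the same genes; atac-only modules get their own
        atac_mod_genes <- unlist(lapply(atac_specs, function(s)
            sprintf("g_%s_%03d", s$module_id, seq_len(s$n_features))))
        rna_bg <- sprintf("g_bg_rna_%04d", seq_len(n_background_rna))
        atac_bg_genes <- sprintf("g_bg_atac_%04d", seq_len(n_background_atac))

        sdlog <- sqrt(log(1 + library_size_cv^2))
        sf_rna <- rlnorm(nrow(design), -sdlog^2 / 2, sdlog)
        sf_atac <- rlnorm(nrow(design), -sdlog^2 / 2, sdlog)

        rna <- .layer_means(rna_specs, design, baseline_mean,
            n_background_rna, c(rna_mod_genes, rna_bg), shift_line)
        rna_counts <- .nb_counts(rna$mu, dispersion, sf_rna)

        atac_genes <- c(if (length(atac_mod_genes)) atac_mod_genes,
            atac_bg_genes)
        atac <- .layer_means(atac_specs, design, baseline_mean,
            n_background_atac, atac_genes, shift_line)
        # primary promoter peak per gene
        n_atac <- length(atac_genes)
        peak_ids <- sprintf("peak_%05d", seq_len(n_atac))
        rownames(atac$mu) <- peak_ids
        atac_counts <- .nb_counts(atac$mu, dispersion, sf_atac)
        ann <- data.frame(peak_id = peak_ids, chrom = "chr1",
            start = seq_len(n_atac) * 2000L,
            end = seq_len(n_atac) * 2000L + 500L,
            gene = atac_genes, region_class = "promoter",
            is_promoter = TRUE, is_protein_coding = TRUE,
            stringsAsFactors = FALSE)
        atac_truth <- data.frame(feature = peak_ids, gene = atac_genes,
            module = atac$truth$module,
            baseline_shift = atac$truth$baseline_shift,
            stringsAsFactors = FALSE)

        # secondary promoter peaks (half-strength pattern) + decoy
        # non-promoter peaks, appended after the primaries
        n_extra <- floor(extra_peak_fraction * n_atac)
        n_decoy <- floor(nonpromoter_fraction * n_atac)
        if (n_extra > 0) {
            pick <- seq_len(n_extra)
            mu2 <- (atac$mu[pick, , drop = FALSE] + baseline_mean) / 2
            ids2 <- sprintf("peak_x%05d", pick)
            rownames(mu2) <- ids2
            cnt2 <- .nb_counts(mu2, dispersion, sf_atac)
            atac_counts <- rbind(atac_counts, cnt2)
            ann <- rbind(ann, data.frame(peak_id = ids2, chrom = "chr1",
                start = pick * 2000L + 800L, end = pick * 2000L + 1200L,
                gene = atac_genes[pick], region_class = "promoter",
                is_promoter = TRUE, is_protein_coding = TRUE))
            atac_truth <- rbind(atac_truth, data.frame(feature = ids2,
                gene = atac_genes[pick], module = "secondary_peak",
                baseline_shift = 0))
        }
        if (n_decoy > 0) {
            pick <- seq_len(n_decoy)
            ids3 <- sprintf("peak_n%05d", pick)
            mu3 <- matrix(baseline_mean, n_decoy, nrow(design),
                dimnames = list(ids3, design$sample_id))
            cnt3 <- .nb_counts(mu3, dispersion, sf_atac)
            atac_counts <- rbind(atac_counts, cnt3)
            ann <- rbind(ann, data.frame(peak_id = ids3, chrom = "chr1",
                start = pick * 2000L + 1500L, end = pick * 2000L + 1900L,
                gene = atac_genes[pick], region_class = "intron",
                is_promoter = FALSE, is_protein_coding = TRUE))
            atac_truth <- rbind(atac_truth, data.frame(feature = ids3,
                gene = atac_genes[pick], module = "nonpromoter_decoy",
                baseline_shift = 0))
        }

        groups <- unique(design$group)
        patterns <- do.call(rbind, lapply(specs, function(s) {
            pat <- setNames(rep(0, length(groups)), groups)
            pat[names(s$gfc_pattern)] <- s$gfc_pattern
            pat
        }))
        if (!is.null(patterns))
            rownames(patterns) <- vapply(specs, `[[`, "", "module_id")

        list(
            rna = OmicCounts(rna_counts, "rna", design),
            atac = OmicCounts(atac_counts, "atac", design),
            annotation = ann, design = design,
            truth = list(rna = rna$truth, atac = atac_truth,
                patterns = patterns, shifted_cell_line = shift_line))
    })
}

#' Simulate a basal-transcriptome cohort with latent sensitivity
#'
#' Each sample carries a latent sensitivity `s ~ Uniform(0, 1)`. Signature-up
#' genes increase linearly in `s` (`+ effect_size * s`), signature-down genes
#' decrease; background genes split into a block correlated with `s` at
#' `rho_background` (so a predictor can survive removal of the signature
#' genes) and independent noise genes. Expression is Gaussian on the log
#' scale, emulating normalized basal transcriptomes.
#'
#' @param signature a [GeneSignature-class] object.
#' @param n_samples cohort size (>= 10).
#' @param n_background number of non-signature genes.
#' @param effect_size log2 units of expression change over the full latent
#'   range (default 1).
#' @param rho_background target correlation of correlated-background genes
#'   with `s`, in `[0, 1)` (default 0).
#' @param corr_fraction fraction of background genes in the correlated block.
#' @param noise_sd Gaussian noise sd on signature genes (default 0.3).
#' @param base_mean mean baseline expression; gene baselines are drawn
#'   around it.
#' @param seed integer seed.
#' @return list with `expr` (genes x samples matrix) and `truth`
#'   (`data.frame`: `sample_id`, `latent_sensitivity`) plus a
#'   `gene_roles` table (`gene`, `role`).
#' @export
simulateCohort <- function(signature, n_samples, n_background,
        effect_size = 1, rho_background = 0, corr_fraction = 0.5,
        noise_sd = 0.3, base_mean = 5, seed = 1) {
    stopifnot(is(signature, "GeneSignature"), n_samples >= 10,
        rho_background >= 0, rho_background < 1)
    up <- upGenes(signature); down <- downGenes(signature)
    withr::with_seed(seed, {
        s <- runif(n_samples)
        sample_id <- sprintf("cohort_%04d", seq_len(n_samples))
        u <- (s - mean(s)) / sd(s)   # standardized latent factor
        n_corr <- floor(corr_fraction * n_background)
        n_noise <- n_background - n_corr
        genes <- c(up, down,
            if (n_corr) sprintf("bgc_%04d", seq_len(n_corr)),
            if (n_noise) sprintf("bgn_%04d", seq_len(n_noise)))
        expr <- matrix(0, length(genes), n_samples,
            dimnames = list(genes, sample_id))
        base <- runif(length(genes), base_mean - 1, base_mean + 1)
        k <- 0L
        for (g in seq_along(up)) {
            expr[k + g, ] <- base[k + g] + effect_size * s +
                rnorm(n_samples, 0, noise_sd)
        }
        k <- length(up)
        for (g in seq_along(down)) {
            expr[k + g, ] <- base[k + g] - effect_size * s +
                rnorm(n_samples, 0, noise_sd)
        }
        k <- k + length(down)
        if (n_corr) for (g in seq_len(n_corr)) {
            z <- rnorm(n_samples)
            expr[k + g, ] <- base[k + g] + 0.3 * effect_size *
                (rho_background * u +
                 sqrt(1 - rho_background^2) * z)
        }
        k <- k + n_corr
        if (n_noise) for (g in seq_len(n_noise)) {
            expr[k + g, ] <- base[k + g] + rnorm(n_samples, 0, noise_sd)
        }
        roles <- data.frame(gene = genes, role = c(
            rep("signature_up", length(up)),
            rep("signature_down", length(down)),
            if (n_corr) rep("background_correlated", n_corr),
            if (n_noise) rep("background_noise", n_noise)),
            stringsAsFactors = FALSE)
        list(expr = expr,
            truth = data.frame(sample_id = sample_id,
                latent_sensitivity = s, stringsAsFactors = FALSE),
            gene_roles = roles)
    })
}

#' Simulate a phenotype from latent sensitivity
#'
#' The noiseless phenotype is strictly monotone in the latent sensitivity:
#' linear (`slope * s`) or a logistic-monotone dose-response-like curve;
#' Gaussian noise is added on top.
#'
#' @param truth cohort truth table from [simulateCohort()].
#' @param link `"linear"` or `"logistic"`.
#' @param noise_sd Gaussian noise sd.
#' @param slope sign/steepness multiplier (negative flips the direction,
#'   e.g. an IC50-like phenotype decreasing with sensitivity).
#' @param seed integer seed.
#' @return numeric phenotype vector named by `sample_id`.
#' @export
simulatePhenotype <- function(truth, link = c("linear", "logistic"),
                              noise_sd = 0, slope = 1, seed = 1) {
    link <- match.arg(link)
    s <- truth$latent_sensitivity
    base <- switch(link,
        linear = slope * s,
        logistic = slope * plogis(6 * (s - 0.5)))
    withr::with_seed(seed,
        setNames(base + rnorm(length(s), 0, noise_sd), truth$sample_id))
}
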
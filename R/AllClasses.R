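#' @import methods
#' @importFrom stats cor median p.adjust pnorm ppois pt qnorm rbinom rlnorm
#'   rnbinom rnorm runif sd setNames var cor.test prcomp plogis predict coef
#'   lm
#' @importFrom utils read.delim write.table head modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   "colData<-"
NULL

#' OmicCounts: a layer-tagged count matrix
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding raw
#' non-negative integer counts for one omic layer (\code{"rna"} gene counts or
#' \code{"atac"} peak counts), features in rows and samples in columns.
#'
#' @slot layer character(1), one of \code{"rna"} or \code{"atac"}.
#'
#' @seealso [OmicCounts()] for the constructor, [readCountMatrix()].
#' @export
setClass("OmicCounts",
    contains = "SummarizedExperiment",
    slots = c(layer = "character"))

setValidity("OmicCounts", function(object) {
    msg <- character()
    if (length(object@layer) != 1L || !object@layer %in% c("rna", "atac"))
        msg <- c(msg, "layer must be one of 'rna', 'atac'")
    m <- SummarizedExperiment::assay(object, "counts")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        msg <- c(msg, "feature ids must be present and unique")
    if (anyNA(m) || any(m < 0))
        msg <- c(msg, "counts must be non-negative")
    if (any(m != floor(m)))
        msg <- c(msg, "counts must be integral")
    if (length(msg)) msg else TRUE
})

#' Construct an OmicCounts object
#'
#' @param counts numeric matrix of non-negative integer counts with unique
#'   rownames (feature ids) and colnames (sample ids).
#' @param layer `"rna"` or `"atac"`.
#' @param design optional sample design `data.frame` (see [readSampleDesign()]);
#'   rows matching `colnames(counts)` become the `colData`.
#' @return An [OmicCounts-class] object.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'     dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' OmicCounts(m, "rna")
#' @export
OmicCounts <- function(counts, layer = c("rna", "atac"), design = NULL) {
    layer <- match.arg(layer)
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts))
    obj <- new("OmicCounts", se, layer = layer)
    if (!is.null(design)) obj <- attachDesign(obj, design)
    obj
}

#' GFCMatrix: per-feature group fold changes
#'
#' Holds group fold changes (GFCs): for each feature the difference, on the
#' log2 scale, between a condition group's mean expression and the mean of all
#' group means. Uncapped rows therefore sum to zero; an optional symmetric cap
#' clips entries to `[-cap, cap]`.
#'
#' @slot gfc numeric matrix, features x condition groups.
#' @slot cap numeric(1) positive cap, or `NA_real_` for uncapped.
#' @slot groups data.frame describing each group column
#'   (`group`, `cell_line`, `treatment`, `time`).
#' @export
setClass("GFCMatrix",
    slots = c(gfc = "matrix", cap = "numeric", groups = "data.frame"))

setValidity("GFCMatrix", function(object) {
    msg <- character()
    g <- object@gfc
    if (!is.numeric(g) || anyNA(g) || any(!is.finite(g)))
        msg <- c(msg, "gfc entries must be finite")
    if (length(object@cap) != 1L)
        msg <- c(msg, "cap must be length 1 (NA for uncapped)")
    if (!is.na(object@cap)) {
        if (object@cap <= 0) msg <- c(msg, "cap must be > 0")
        else if (any(abs(g) > object@cap + 1e-12))
            msg <- c(msg, "capped entries must lie in [-cap, cap]")
    } else if (nrow(g) > 0 && max(abs(rowSums(g))) > 1e-9) {
        msg <- c(msg, "uncapped GFC rows must sum to 0")
    }
    if (!identical(colnames(g), object@groups$group))
        msg <- c(msg, "gfc columns must match groups$group")
    if (length(msg)) msg else TRUE
})

#' CoexpressionNetwork: weighted undirected co-expression graph
#'
#' Nodes are layer-namespaced feature ids (`"rna::GENE"`, `"atac::GENE"`);
#' edges carry Pearson correlations of GFC patterns as weights. Only positive
#' correlations at or above the construction cutoff become edges.
#'
#' @slot graph an `igraph` object (undirected, weighted).
#' @slot layers character vector of layers present.
#' @slot cutoff numeric(1), the correlation cutoff used at construction
#'   (for integrated networks, the smallest cutoff among parents).
#' @export
setClass("CoexpressionNetwork",
    slots = c(graph = "ANY", layers = "character", cutoff = "numeric"))

setValidity("CoexpressionNetwork", function(object) {
    msg <- character()
    g <- object@graph
    if (!igraph::is_igraph(g)) return("graph must be an igraph object")
    if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
    if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops are not allowed")
    if (igraph::ecount(g) > 0) {
        w <- igraph::E(g)$weight
        if (is.null(w)) msg <- c(msg, "edges must be weighted")
        else if (any(w < object@cutoff - 1e-12) || any(w <= 0))
            msg <- c(msg, "edge weights must be positive and >= cutoff")
    }
    if (length(object@cutoff) != 1L || object@cutoff <= 0 || object@cutoff > 1)
        msg <- c(msg, "cutoff must be in (0, 1]")
    if (!all(object@layers %in% c("rna", "atac")))
        msg <- c(msg, "layers must be a subset of {rna, atac}")
    if (length(msg)) msg else TRUE
})

#' GeneSignature: disjoint up/down gene sets with provenance
#'
#' @slot up character vector of genes up in the sensitive condition.
#' @slot down character vector of genes down in the sensitive condition.
#' @slot provenance list recording how the signature was built (selected
#'   modules, baseline thresholds, drug label, or control-signature method).
#' @export
setClass("GeneSignature",
    slots = c(up = "character", down = "character", provenance = "list"))

setValidity("GeneSignature", function(object) {
    msg <- character()
    if (anyDuplicated(object@up) || anyDuplicated(object@down))
        msg <- c(msg, "up and down sets must not contain duplicates")
    if (length(intersect(object@up, object@down)))
        msg <- c(msg, "up and down sets must be disjoint")
    if (length(object@up) == 0 && length(object@down) == 0)
        msg <- c(msg, "signature must not be empty")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#' @param up,down character vectors of gene ids (disjoint, not both empty).
#' @param provenance optional list of construction metadata.
#' @return A [GeneSignature-class] object.
#' @export
GeneSignature <- function(up, down, provenance = list()) {
    new("GeneSignature", up = unique(as.character(up)),
        down = unique(as.character(down)), provenance = provenance)
}

#' LassoModel: a fitted L1-penalised linear predictor
#'
#' Stores coefficients at the cross-validated penalty together with the
#' training-split standardisation so prediction is self-contained.
#'
#' @slot features character, feature (gene) names, aligned with coefficients.
#' @slot coefficients numeric, one per feature.
#' @slot intercept numeric(1).
#' @slot lambda numeric(1), penalty chosen by cross-validation.
#' @slot center,scale numeric, per-feature standardisation parameters
#'   estimated on the training split only.
#' @slot excluded character, features dropped before training.
#' @export
setClass("LassoModel",
    slots = c(features = "character", coefficients = "numeric",
        intercept = "numeric", lambda = "numeric",
        center = "numeric", scale = "numeric", excluded = "character"))

setValidity("LassoModel", function(object) {
    n <- length(object@features)
    if (length(object@coefficients) != n || length(object@center) != n ||
        length(object@scale) != n)
        return("coefficients/center/scale must align 1:1 with features")
    TRUE
})

setMethod("show", "OmicCounts", function(object) {
    cat(sprintf("OmicCounts [%s]: %d features x %d samples\n",
        object@layer, nrow(object), ncol(object)))
    if (ncol(SummarizedExperiment::colData(object)) > 0)
        cat("  design columns:",
            paste(colnames(SummarizedExperiment::colData(object)),
                collapse = ", "), "\n")
})

setMethod("show", "GFCMatrix", function(object) {
    cat(sprintf("GFCMatrix: %d features x %d groups (cap = %s)\n",
        nrow(object@gfc), ncol(object@gfc),
        if (is.na(object@cap)) "none" else format(object@cap)))
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat(sprintf(
        "CoexpressionNetwork [%s]: %d nodes, %d edges (cutoff = %g)\n",
        paste(object@layers, collapse = "+"),
        igraph::vcount(object@graph), igraph::ecount(object@graph),
        object@cutoff))
})

setMethod("show", "GeneSignature", function(object) {
    cat(sprintf("GeneSignature: %d up, %d down\n",
        length(object@up), length(object@down)))
    if (length(object@provenance))
        cat("  provenance:", paste(names(object@provenance), collapse = ", "),
            "\n")
})

setMethod("show", "LassoModel", function(object) {
    cat(sprintf(
        "LassoModel: %d features (%d nonzero), lambda = %.4g\n",
        length(object@features), sum(object@coefficients != 0),
        object@lambda))
})
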
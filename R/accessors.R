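# Accessors for the package's S4 classes. Slot access stays internal.

#' @rdname OmicCounts-class
#' @param object an object of the documented class.
#' @export
setGeneric("layerTag", function(object) standardGeneric("layerTag"))

#' @rdname OmicCounts-class
#' @export
setMethod("layerTag", "OmicCounts", function(object) object@layer)

#' @rdname CoexpressionNetwork-class
#' @param object an object of the documented class.
#' @export
setMethod("layerTag", "CoexpressionNetwork", function(object) object@layers)

#' Extract the count matrix from an OmicCounts object
#' @param object an [OmicCounts-class] object.
#' @return numeric matrix, features x samples.
#' @export
countsMatrix <- function(object) {
    stopifnot(is(object, "OmicCounts"))
    SummarizedExperiment::assay(object, "counts")
}

#' Attach a sample design to an OmicCounts object
#'
#' @param object an [OmicCounts-class] object.
#' @param design a validated design `data.frame` (see [readSampleDesign()]).
#'   Must cover every sample of `object`.
#' @return `object` with the design as `colData`.
#' @export
attachDesign <- function(object, design) {
    design <- validateDesign(design)
    idx <- match(colnames(object), design$sample_id)
    if (anyNA(idx))
        stop("design does not cover samples: ",
            paste(colnames(object)[is.na(idx)], collapse = ", "))
    SummarizedExperiment::colData(object) <-
        S4Vectors::DataFrame(design[idx, , drop = FALSE],
            row.names = colnames(object))
    validObject(object)
    object
}

#' @rdname GFCMatrix-class
#' @param object a [GFCMatrix-class] object.
#' @return `gfcValues`: the numeric features x groups matrix; `gfcCap`: the
#'   cap (`NA` if uncapped); `gfcGroups`: the group description `data.frame`.
#' @export
gfcValues <- function(object) { stopifnot(is(object, "GFCMatrix")); object@gfc }

#' @rdname GFCMatrix-class
#' @export
gfcCap <- function(object) { stopifnot(is(object, "GFCMatrix")); object@cap }

#' @rdname GFCMatrix-class
#' @export
gfcGroups <- function(object) {
    stopifnot(is(object, "GFCMatrix"))
    object@groups
}

#' @rdname CoexpressionNetwork-class
#' @param object a [CoexpressionNetwork-class] object.
#' @return `networkGraph`: the underlying `igraph`; `networkCutoff`: the
#'   construction cutoff.
#' @export
networkGraph <- function(object) {
    stopifnot(is(object, "CoexpressionNetwork"))
    object@graph
}

#' @rdname CoexpressionNetwork-class
#' @export
networkCutoff <- function(object) {
    stopifnot(is(object, "CoexpressionNetwork"))
    object@cutoff
}

#' @rdname GeneSignature-class
#' @param object a [GeneSignature-class] object.
#' @return character vector of gene ids.
#' @export
upGenes <- function(object) { stopifnot(is(object, "GeneSignature")); object@up }

#' @rdname GeneSignature-class
#' @export
downGenes <- function(object) {
    stopifnot(is(object, "GeneSignature"))
    object@down
}

#' @rdname GeneSignature-class
#' @export
signatureProvenance <- function(object) {
    stopifnot(is(object, "GeneSignature"))
    object@provenance
}

#' @rdname LassoModel-class
#' @param object a [LassoModel-class] object.
#' @export
modelFeatures <- function(object) {
    stopifnot(is(object, "LassoModel"))
    object@features
}

#' @rdname LassoModel-class
#' @export
modelCoefficients <- function(object) {
    stopifnot(is(object, "LassoModel"))
    setNames(object@coefficients, object@features)
}

#' @rdname LassoModel-class
#' @export
modelLambda <- function(object) {
    stopifnot(is(object, "LassoModel"))
    object@lambda
}
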
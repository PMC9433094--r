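# Shared helpers: design validation, condition-group keys, layer namespacing.

#' Validate a sample design table
#'
#' Checks the contract shared by all entry points: columns `sample_id`,
#' `cell_line`, `treatment`, `time`, `replicate`; unique sample ids;
#' replicates numbered from 1.
#'
#' @param design a `data.frame`.
#' @return the validated `data.frame` (character columns coerced, with a
#'   `group` column added, `cell_line|treatment|time`).
#' @export
validateDesign <- function(design) {
    req <- c("sample_id", "cell_line", "treatment", "time", "replicate")
    miss <- setdiff(req, colnames(design))
    if (length(miss))
        stop("design is missing column(s): ", paste(miss, collapse = ", "))
    design <- as.data.frame(design)
    for (cc in c("sample_id", "cell_line", "treatment", "time"))
        design[[cc]] <- as.character(design[[cc]])
    if (anyDuplicated(design$sample_id))
        stop("duplicate sample_id in design")
    rep <- design$replicate
    if (anyNA(suppressWarnings(as.numeric(rep))) ||
        any(as.numeric(rep) < 1) || any(as.numeric(rep) != floor(as.numeric(rep))))
        stop("replicate must be an integer >= 1")
    design$replicate <- as.integer(rep)
    design$group <- conditionGroup(design)
    rownames(design) <- NULL
    design
}

#' Condition-group key of each design row
#'
#' @param design a design `data.frame` with `cell_line`, `treatment`, `time`.
#' @return character vector `cell_line|treatment|time`, one per row.
#' @export
conditionGroup <- function(design) {
    paste(design$cell_line, design$treatment, design$time, sep = "|")
}

#' @rdname conditionGroup
#' @param cell_line,treatment,time components of a group key.
#' @export
groupKey <- function(cell_line, treatment, time) {
    paste(cell_line, treatment, time, sep = "|")
}

# ---- layer namespacing ------------------------------------------------------

#' Layer-namespaced node ids
#'
#' Network nodes are identified as `"layer::feature"` so the same gene may
#' appear in both the RNA and ATAC layers of an integrated graph.
#'
#' @param layer `"rna"` or `"atac"`.
#' @param features character vector of feature ids.
#' @return `nsTag`: namespaced ids; `nsStrip`: bare feature ids;
#'   `nsLayer`: the layer component of namespaced ids.
#' @export
nsTag <- function(layer, features) paste0(layer, "::", features)

#' @rdname nsTag
#' @param nodes character vector of namespaced node ids.
#' @export
nsStrip <- function(nodes) sub("^[^:]+::", "", nodes)

#' @rdname nsTag
#' @export
nsLayer <- function(nodes) sub("::.*$", "", nodes)

# ---- evaluation helpers -----------------------------------------------------

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index, used by the planted-structure recovery
#' checks to compare detected module assignments with ground truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric(1) in `[-1, 1]`; 1 for identical partitions.
#' @export
adjustedRandIndex <- function(a, b) {
    if (length(a) != length(b)) stop("labelings must have equal length")
    tab <- table(a, b)
    n <- length(a)
    comb2 <- function(x) x * (x - 1) / 2
    sij <- sum(comb2(tab))
    si <- sum(comb2(rowSums(tab)))
    sj <- sum(comb2(colSums(tab)))
    exp_idx <- si * sj / comb2(n)
    max_idx <- (si + sj) / 2
    if (max_idx == exp_idx) return(1)
    (sij - exp_idx) / (max_idx - exp_idx)
}

# binary Shannon entropy in bits, safe at 0/1
.entropy2 <- function(p) {
    q <- 1 - p
    h <- numeric(length(p))
    nz <- p > 0 & p < 1
    h[nz] <- -(p[nz] * log2(p[nz]) + q[nz] * log2(q[nz]))
    h
}

# color names used to label modules, largest module first
.modulePalette <- c(
    "maroon", "steelblue", "darkgreen", "orchid", "indianred", "lightgreen",
    "pink", "sandybrown", "gold", "darkorange", "lightblue", "khaki",
    "darkgray", "plum", "seagreen", "tomato", "slateblue", "olivedrab",
    "salmon", "turquoise", "sienna", "orange", "navy", "firebrick",
    "cadetblue", "chocolate", "darkkhaki", "hotpink", "lavender", "wheat")

.moduleNames <- function(n) {
    if (n <= length(.modulePalette)) return(.modulePalette[seq_len(n)])
    c(.modulePalette, paste0("module", seq.int(length(.modulePalette) + 1, n)))
}
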
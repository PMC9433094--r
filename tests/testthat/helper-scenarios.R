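# Planted-structure scenarios shared by the recovery tests. Patterns are
# mutually orthogonal (or anti-correlated) over the 12 condition groups of
# the standard design so each planted module has a distinct regulation
# profile.

std_design <- function(n_rep = 3) standardDesign(n_rep = n_rep)

# four single-layer RNA modules with distinct regulation patterns
four_module_specs <- function(n_features = 50, amp = 2) {
    both <- function(treatment, time) {
        g <- as.vector(outer(c("sensitive", "resistant"),
            paste(treatment, time, sep = "|"), paste, sep = "|"))
        setNames(rep(amp, length(g)), g)
    }
    list(
        plantedModule("m1", "rna", n_features, both("M", c("6h", "12h"))),
        plantedModule("m2", "rna", n_features, both("B", c("6h", "12h"))),
        plantedModule("m3", "rna", n_features,
            both(c("ctrl", "M", "B"), "12h")),
        plantedModule("m4", "rna", n_features, c(
            setNames(rep(amp, 2), c("sensitive|M|6h", "sensitive|M|12h")),
            setNames(rep(-amp, 2), c("resistant|M|6h", "resistant|M|12h")))))
}

# one cross-layer module plus one unpaired module per layer
cross_layer_specs <- function(n_features = 30, amp = 2) {
    specs <- four_module_specs(n_features, amp)
    list(
        plantedModule("X", "both", n_features,
            specs[[1]]$gfc_pattern),
        plantedModule("R1", "rna", n_features, specs[[2]]$gfc_pattern),
        plantedModule("A1", "atac", n_features, specs[[3]]$gfc_pattern))
}

# perturbation + baseline signature scenario: U and D respond to drug M in
# the sensitive line only (selected via thr_score); U sits higher and D
# lower at baseline in the sensitive line (up/down split); decoys respond
# identically in both lines (thr_score ~ 0) with no baseline difference.
signature_specs <- function(n_features = 30, amp = 1.5) {
    sensM <- setNames(rep(amp, 2), c("sensitive|M|6h", "sensitive|M|12h"))
    bothB <- setNames(rep(amp, 4), c("sensitive|B|6h", "sensitive|B|12h",
        "resistant|B|6h", "resistant|B|12h"))
    bothTrt <- setNames(rep(-amp / 1.5, 8), c(
        "sensitive|M|6h", "sensitive|M|12h", "sensitive|B|6h",
        "sensitive|B|12h", "resistant|M|6h", "resistant|M|12h",
        "resistant|B|6h", "resistant|B|12h"))
    list(
        plantedModule("U", "both", n_features, sensM, baseline_shift = amp),
        plantedModule("D", "both", n_features, sensM, baseline_shift = -amp),
        plantedModule("dec1", "rna", n_features, bothB),
        plantedModule("dec2", "atac", n_features, bothB),
        plantedModule("dec3", "rna", n_features, bothTrt))
}

# a small signature + cohort for scoring tests
toy_signature <- function(n_up = 30, n_down = 20) {
    GeneSignature(sprintf("up%02d", seq_len(n_up)),
        sprintf("dn%02d", seq_len(n_down)))
}
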
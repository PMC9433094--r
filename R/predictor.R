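# Self-supervised L1-penalised regression: learn to reproduce the
# signature-derived sensitivity score from basal transcriptomes alone.

#' Train an L1-penalised sensitivity predictor
#'
#' Holds out `test_fraction` of the samples, standardises features on the
#' training split only, chooses the penalty by k-fold cross-validation
#' (`cv.glmnet`) and reports Pearson r and RMSE on the untouched test split.
#' With `exclude` set, those feature columns are dropped before the split —
#' the signature-gene-exclusion robustness check.
#'
#' @param X numeric matrix, samples x genes, with both dimnames.
#' @param y numeric response (sensitivity scores), one per sample.
#' @param test_fraction held-out fraction (default 0.2).
#' @param k_folds cross-validation folds on the training split (default 10).
#' @param lambda_rule `"min"` (lambda.min) or `"1se"` (lambda.1se).
#' @param exclude genes to drop before splitting, or `NULL`.
#' @param seed integer seed governing the split and fold assignment.
#' @return list with `model` ([LassoModel-class]) and `report`
#'   (`data.frame`: `r`, `rmse`, `n_train`, `n_test`, `seed`).
#' @export
trainLasso <- function(X, y, test_fraction = 0.2, k_folds = 10,
        lambda_rule = c("min", "1se"), exclude = NULL, seed = 1) {
    lambda_rule <- match.arg(lambda_rule)
    X <- as.matrix(X)
    stopifnot(nrow(X) == length(y), all(is.finite(y)))
    if (is.null(colnames(X)) || is.null(rownames(X)))
        stop("X needs row (sample) and column (gene) names")
    if (!is.null(exclude)) {
        bad <- setdiff(exclude, colnames(X))
        # silently ignore excluded genes absent from the matrix
        X <- X[, !colnames(X) %in% exclude, drop = FALSE]
        if (ncol(X) == 0) stop("all features excluded")
    }
    n <- nrow(X)
    n_test <- round(test_fraction * n)
    if (n_test < 5) stop("test split smaller than 5 samples")
    withr::with_seed(seed, {
        test_idx <- sample(n, n_test)
        foldid <- sample(rep_len(seq_len(k_folds), n - n_test))
    })
    train_idx <- setdiff(seq_len(n), test_idx)
    Xtr <- X[train_idx, , drop = FALSE]
    ctr <- colMeans(Xtr)
    scl <- apply(Xtr, 2, sd)
    scl[scl == 0] <- 1
    Ztr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
    cvfit <- glmnet::cv.glmnet(Ztr, y[train_idx], foldid = foldid,
        standardize = FALSE, thresh = 1e-7)
    lambda <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
    beta <- as.numeric(coef(cvfit, s = lambda))
    model <- new("LassoModel", features = colnames(X),
        coefficients = beta[-1], intercept = beta[1], lambda = lambda,
        center = unname(ctr), scale = unname(scl),
        excluded = as.character(exclude %||% character()))
    yhat <- predictLasso(model, X[test_idx, , drop = FALSE])
    ytest <- y[test_idx]
    report <- data.frame(
        r = cor(yhat, ytest), rmse = sqrt(mean((yhat - ytest)^2)),
        n_train = length(train_idx), n_test = n_test, seed = seed)
    list(model = model, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict sensitivity scores with a fitted model
#'
#' Columns are aligned by gene name (extra columns ignored, missing model
#' features are an error) and standardised with the model's stored training
#' parameters.
#'
#' @param model a [LassoModel-class] object.
#' @param X_new numeric matrix, samples x genes, with column names.
#' @return numeric vector of predictions, named by the rownames of `X_new`.
#' @export
predictLasso <- function(model, X_new) {
    stopifnot(is(model, "LassoModel"))
    X_new <- as.matrix(X_new)
    miss <- setdiff(model@features, colnames(X_new))
    if (length(miss))
        stop("X_new is missing model feature(s): ",
            paste(head(miss, 5), collapse = ", "))
    Z <- sweep(sweep(X_new[, model@features, drop = FALSE], 2,
        model@center), 2, model@scale, "/")
    drop(Z %*% model@coefficients) + model@intercept
}

#' Per-stratum held-out performance
#'
#' Pearson r and RMSE within each stratum (e.g. tumor type) of a held-out
#' set; strata with fewer than `min_n` samples are skipped with a warning.
#'
#' @param y_true,y_pred observed and predicted scores.
#' @param strata per-sample group labels.
#' @param min_n minimum stratum size to report (default 3).
#' @return `data.frame` (`stratum`, `n`, `r`, `rmse`).
#' @export
stratifiedReport <- function(y_true, y_pred, strata, min_n = 3) {
    stopifnot(length(y_true) == length(y_pred),
        length(strata) == length(y_true))
    tab <- table(strata)
    keep <- names(tab)[tab >= min_n]
    skipped <- setdiff(names(tab), keep)
    if (length(skipped))
        warning("stratum(s) below minimum size skipped: ",
            paste(skipped, collapse = ", "))
    if (!length(keep)) stop("no stratum meets the minimum size")
    do.call(rbind, lapply(keep, function(s) {
        i <- strata == s
        data.frame(stratum = s, n = sum(i),
            r = cor(y_true[i], y_pred[i]),
            rmse = sqrt(mean((y_true[i] - y_pred[i])^2)))
    }))
}

#' Serialise / restore a fitted model
#' @param model a [LassoModel-class] object.
#' @param path JSON path.
#' @export
writeLassoModel <- function(model, path) {
    jsonlite::write_json(list(features = model@features,
        coefficients = model@coefficients, intercept = model@intercept,
        lambda = model@lambda, center = model@center, scale = model@scale,
        excluded = model@excluded), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeLassoModel
#' @export
readLassoModel <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("LassoModel", features = x$features, coefficients = x$coefficients,
        intercept = x$intercept, lambda = x$lambda, center = x$center,
        scale = x$scale, excluded = as.character(x$excluded))
}
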
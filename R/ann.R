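#' Canonical ANN input features
#'
#' The six predictors of the network regressor: PTV volume and the mean
#' densities of the PTV margin and the 2/15/50 mm shells and the lungs.
#'
#' @return character vector of feature-table column names.
#' @export
annFeatureNames <- function() {
    c("v_ptv_cm3", "hu_mean_margin", "hu_mean_shell2mm",
      "hu_mean_shell15mm", "hu_mean_shell50mm", "hu_mean_lung")
}

#' ANN configuration
#'
#' @param size hidden-layer size, >= 1.
#' @param decay L2 weight-decay penalty, >= 0.
#' @param seed integer seed controlling weight initialisation.
#' @param maxit optimiser iteration cap.
#' @return a validated list.
#' @export
annConfig <- function(size = 4, decay = 0.01, seed = 1, maxit = 500) {
    stopifnot(size >= 1, decay >= 0, maxit >= 1)
    list(size = as.integer(size), decay = decay, seed = as.integer(seed),
         maxit = as.integer(maxit))
}

.checkAnnFeatures <- function(X) {
    X <- as.matrix(X)
    want <- annFeatureNames()
    if (is.null(colnames(X)) || !setequal(colnames(X), want))
        stop("X must have exactly the six ANN features: ",
             paste(want, collapse = ", "))
    X[, want, drop = FALSE]
}

#' Train the single-hidden-layer network regressor
#'
#' Feed-forward network with one logistic hidden layer and a linear
#' output unit, fit by quasi-Newton optimisation (`nnet`) with all
#' weights L2-penalised by `decay`. Inputs are standardised and the
#' outcome min-max normalised to [0, 1] on the training data; both
#' transforms are stored in the model and re-applied at prediction time.
#' Weights are initialised uniformly in [-0.5, 0.5] from `seed`, so the
#' fit is deterministic given the configuration.
#'
#' @param X matrix/data.frame with exactly the [annFeatureNames()]
#'   columns, n >= 8 rows.
#' @param y numeric outcome (percent PTV D95 deficiency).
#' @param cfg an [annConfig()].
#' @return an [AnnModel-class]; `@converged` is FALSE (flagged, not an
#'   error) when the optimiser hit `maxit`.
#' @export
annTrain <- function(X, y, cfg = annConfig()) {
    X <- .checkAnnFeatures(X)
    stopifnot(nrow(X) == length(y))
    if (nrow(X) < 8) stop("need n >= 8 to train the network")
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    Xs <- scale(X, center = ctr, scale = scl)
    b <- .normBounds(y)
    yn <- .normalize(y, b)
    set.seed(cfg$seed)
    net <- nnet::nnet(x = Xs, y = yn, size = cfg$size, decay = cfg$decay,
                      linout = TRUE, maxit = cfg$maxit, rang = 0.5,
                      trace = FALSE)
    new("AnnModel", net = net, config = cfg, xCenter = ctr, xScale = scl,
        yMin = unname(b[["min"]]), yMax = unname(b[["max"]]),
        converged = is.null(net$convergence) || net$convergence == 0,
        featureNames = colnames(X))
}

#' Predict from a fitted AnnModel
#'
#' @param object an [AnnModel-class].
#' @param newdata matrix/data.frame with the model's feature columns.
#' @param normalized return predictions on the [0, 1] training scale
#'   instead of the original outcome scale.
#' @param ... ignored.
#' @return numeric predictions.
#' @export
setMethod("predict", "AnnModel",
    function(object, newdata, normalized = FALSE, ...) {
        X <- as.matrix(newdata)[, object@featureNames, drop = FALSE]
        Xs <- scale(X, center = object@xCenter, scale = object@xScale)
        yn <- as.numeric(predict(object@net, Xs))
        if (normalized) return(yn)
        b <- c(min = object@yMin, max = object@yMax)
        .denormalize(yn, b)
    })

.foldAssign <- function(n, k, seed) {
    set.seed(seed)
    sample(rep(seq_len(k), length.out = n))
}

.cvRmse <- function(X, y, size, decay, folds, seed, maxit) {
    sqe <- numeric(length(y))
    for (f in sort(unique(folds))) {
        tr <- folds != f
        b <- .normBounds(y[tr])
        m <- annTrain(X[tr, , drop = FALSE], y[tr],
                      annConfig(size, decay, seed = seed + f, maxit = maxit))
        pn <- predict(m, X[!tr, , drop = FALSE], normalized = TRUE)
        sqe[!tr] <- (pn - .normalize(y[!tr], b))^2
    }
    sqrt(mean(sqe))
}

#' Grid search over hidden size and weight decay
#'
#' Evaluates every (size, decay) combination by seeded k-fold
#' cross-validated RMSE on the normalized outcome scale and returns the
#' minimiser. The default grids are sizes 2-7 and decays 0.001, 0.005,
#' 0.01, 0.05, 0.1, 0.5, 1. Ties break toward the smaller size, then the
#' smaller decay (parsimony).
#'
#' @param X feature matrix (see [annTrain()]).
#' @param y numeric outcome.
#' @param sizes integer vector of hidden sizes.
#' @param decays numeric vector of decay values.
#' @param seed integer seed for fold assignment and weight init.
#' @param k number of CV folds.
#' @param maxit optimiser iteration cap per fit.
#' @return list with `best` (an [annConfig()]) and `table` (a
#'   `data.frame` of size, decay, cv_rmse).
#' @export
annGridSearch <- function(X, y, sizes = 2:7,
                          decays = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1),
                          seed = 1, k = 5, maxit = 500) {
    stopifnot(length(sizes) > 0, length(decays) > 0)
    X <- .checkAnnFeatures(X)
    n <- length(y)
    if (n < 9) stop("grid search needs n >= 9")
    # keep every training fold at the minimum size the trainer accepts
    kmin <- ceiling(n / (n - 8))
    folds <- .foldAssign(n, min(n, max(k, kmin)), seed)
    grid <- expand.grid(size = sort(sizes), decay = sort(decays))
    grid$cv_rmse <- vapply(seq_len(nrow(grid)), function(i)
        .cvRmse(X, y, grid$size[i], grid$decay[i], folds,
                seed = seed + 1000L * i, maxit = maxit),
        numeric(1))
    ord <- order(grid$cv_rmse, grid$size, grid$decay)
    best <- grid[ord[1], ]
    list(best = annConfig(best$size, best$decay, seed = seed,
                          maxit = maxit),
         table = grid)
}

#' Leave-one-out cross-validation of the network
#'
#' One fold per sample: the network is refit on the remaining n - 1
#' cases, the outcome normalisation bounds are recomputed on that
#' training fold only (no leakage), and the held-out case is predicted.
#' Per-case squared errors on the normalized scale are retained for model
#' comparison. With `nrep > 1` the whole LOOCV is repeated with shifted
#' weight-initialisation seeds and the mean and SD of the normalized RMSE
#' across replicates are reported.
#'
#' @param X feature matrix (see [annTrain()]).
#' @param y numeric outcome, length >= 3.
#' @param cfg an [annConfig()].
#' @param nrep number of replicates.
#' @return a [CvResult-class] (predictions and squared errors are from
#'   the first replicate).
#' @export
annLoocv <- function(X, y, cfg = annConfig(), nrep = 1) {
    X <- .checkAnnFeatures(X)
    n <- length(y)
    stopifnot(nrow(X) == n, n >= 3)
    oneRep <- function(rep) {
        preds <- numeric(n); sqe <- numeric(n)
        for (i in seq_len(n)) {
            tr <- setdiff(seq_len(n), i)
            b <- .normBounds(y[tr])
            m <- annTrain(X[tr, , drop = FALSE], y[tr],
                annConfig(cfg$size, cfg$decay,
                          seed = cfg$seed + 7919L * (rep - 1L) + i,
                          maxit = cfg$maxit))
            pn <- predict(m, X[i, , drop = FALSE], normalized = TRUE)
            preds[i] <- .denormalize(pn, b)
            sqe[i] <- (pn - .normalize(y[i], b))^2
        }
        list(preds = preds, sqe = sqe, rmse = sqrt(mean(sqe)))
    }
    reps <- lapply(seq_len(nrep), oneRep)
    rmses <- vapply(reps, `[[`, numeric(1), "rmse")
    new("CvResult", predictions = reps[[1]]$preds,
        sqErrors = reps[[1]]$sqe, rmse = mean(rmses),
        rmseSd = if (nrep > 1) sd(rmses) else NA_real_,
        config = cfg, nrep = as.integer(nrep))
}

#' Compare ANN and linear cross-validated errors
#'
#' Two-sided Mann-Whitney U test between the per-case squared
#' cross-validation errors of the network and of the linear model, both
#' on the normalized outcome scale. A large P value says the network does
#' not significantly improve on the two-feature linear model.
#'
#' @param annSqErrors,linearSqErrors equal-length numeric vectors.
#' @return two-sided P value.
#' @export
compareToLinear <- function(annSqErrors, linearSqErrors) {
    if (length(annSqErrors) != length(linearSqErrors))
        stop("squared-error vectors must have equal length")
    mannWhitney(annSqErrors, linearSqErrors)$p.value
}
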
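.linearFitFrom <- function(fit, n) {
    # summary.lm warns on exact fits; degenerate designs are handled
    # explicitly by the callers
    s <- suppressWarnings(summary(fit))
    cf <- s$coefficients
    fstat <- s$fstatistic
    sig <- if (is.null(fstat)) NA_real_
           else unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
    new("LinearFit", coefficients = coef(fit),
        r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
        p.values = setNames(cf[, 4], rownames(cf)), sig.factor = sig,
        residuals = unname(fit$residuals), n = as.integer(n))
}

#' Single linear regression of an outcome on one feature
#'
#' Ordinary least squares of `y` on one predictor, reporting the slope,
#' R^2 = 1 - SSres/SStot and two-sided P values — the per-feature screen
#' used to rank how strongly each patient index tracks the PB-to-MC D95
#' deficiency. A constant outcome yields R^2 = 0 with a warning; a
#' constant predictor is a degenerate design and errors.
#'
#' @param x numeric predictor, not constant, length >= 3.
#' @param y numeric outcome, same length.
#' @return a [LinearFit-class].
#' @examples
#' f <- fitSingle(c(0, 1, 2), c(0, 1, 1))
#' f@coefficients[["x"]]  # 0.5
#' f@r.squared            # 0.75
#' @export
fitSingle <- function(x, y) {
    stopifnot(length(x) == length(y))
    if (length(x) < 3) stop("need at least 3 observations")
    if (sd(x) == 0) stop("degenerate design: predictor is constant")
    if (sd(y) == 0) {
        warning("constant outcome: R^2 reported as 0")
        fit <- lm(y ~ x)
        out <- .linearFitFrom(fit, length(y))
        out@r.squared <- 0
        out@adj.r.squared <- 0
        return(out)
    }
    .linearFitFrom(lm(y ~ x), length(y))
}

#' Multiple linear regression with F-test significance factor
#'
#' OLS of `y` on the columns of `X`, reporting per-coefficient two-sided
#' t-test P values and the whole-model F-test P value, called the
#' significance factor. A rank-deficient design errors, naming the
#' collinear columns.
#'
#' @param X numeric matrix or data.frame of predictors, full column rank.
#' @param y numeric outcome, length `nrow(X)` and > `ncol(X) + 1`.
#' @return a [LinearFit-class].
#' @export
fitMultiple <- function(X, y) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    stopifnot(nrow(X) == length(y))
    if (nrow(X) <= ncol(X) + 1)
        stop("need n > p + 1 observations")
    design <- cbind(`(Intercept)` = 1, X)
    qrX <- qr(design)
    if (qrX$rank < ncol(design)) {
        bad <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
        stop("rank-deficient design; collinear column(s): ",
             paste(bad, collapse = ", "))
    }
    df <- data.frame(y = y, X, check.names = FALSE)
    fit <- lm(y ~ ., data = df)
    .linearFitFrom(fit, length(y))
}

#' The published two-feature dose-conversion models
#'
#' Returns one of the two fixed-coefficient predictors of percent PTV D95
#' deficiency from PTV volume and the mean HU of the 2 mm shell outside
#' the PTV:
#' \describe{
#'   \item{eq1}{`-0.6623 - 0.08136 * V_PTV - 0.03784 * HU_shell2mm`}
#'   \item{eq2}{`1.62022 - 0.45734 * V_PTV^(2/3) - 0.03705 * HU_shell2mm`}
#' }
#' The 2/3 power in eq2 makes the volume term scale like the PTV surface
#' area, the interface where pencil-beam transport errors concentrate.
#'
#' @param id `"eq1"` or `"eq2"`.
#' @return a [PublishedModel-class].
#' @export
publishedModel <- function(id = c("eq2", "eq1")) {
    id <- match.arg(id)
    if (id == "eq1")
        new("PublishedModel", id = "eq1", intercept = -0.6623,
            coefVolume = -0.08136, coefHU = -0.03784, volumeExponent = 1)
    else
        new("PublishedModel", id = "eq2", intercept = 1.62022,
            coefVolume = -0.45734, coefHU = -0.03705,
            volumeExponent = 2 / 3)
}

#' Predict percent D95 deficiency from a published model
#'
#' @param model a [PublishedModel-class].
#' @param vPtvCm3 PTV volume in cm^3, > 0 (vectorised).
#' @param huShell2mm mean HU of the 2 mm shell (vectorised).
#' @return predicted percent PTV D95 deficiency.
#' @examples
#' predictPublished(publishedModel("eq2"), 1, 0)  # 1.16288
#' @export
predictPublished <- function(model, vPtvCm3, huShell2mm) {
    stopifnot(is(model, "PublishedModel"))
    if (any(vPtvCm3 <= 0)) stop("vPtvCm3 must be > 0")
    model@intercept + model@coefVolume * vPtvCm3^model@volumeExponent +
        model@coefHU * huShell2mm
}

#' Critical Pearson correlation at a given sample size
#'
#' The magnitude of the sample correlation at which a two-sided test of
#' zero correlation with `n - 2` degrees of freedom is exactly at level
#' `alpha`: `r* = t* / sqrt(t*^2 + n - 2)` with `t*` the upper
#' `alpha/2` quantile of the t distribution. At n = 21 and alpha = 0.01
#' this is 0.55 (to two decimals), the bar an observed correlation of
#' -0.84 clears comfortably.
#'
#' @param n sample size, >= 3.
#' @param alpha two-sided level in (0, 1).
#' @return the critical |r|.
#' @export
criticalPearson <- function(n, alpha = 0.01) {
    if (n < 3) stop("n must be >= 3")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    tstar <- qt(1 - alpha / 2, df = n - 2)
    tstar / sqrt(tstar^2 + n - 2)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test between two samples, e.g. the per-case squared
#' prediction errors of two competing models, or the D95 deficiencies of
#' central vs peripheral tumours. The exact null distribution is used when
#' the smaller sample has at most 8 observations and there are no ties;
#' otherwise the tie-corrected normal approximation.
#'
#' @param a,b numeric samples, non-empty.
#' @return list with `U` (statistic for the first sample), `p.value`, and
#'   `exact` (logical, which branch was taken).
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))$p.value  # exact two-sided 1/3
#' @export
mannWhitney <- function(a, b) {
    stopifnot(length(a) > 0, length(b) > 0)
    ties <- any(duplicated(c(a, b)))
    exact <- !ties && min(length(a), length(b)) <= 8
    wt <- suppressWarnings(
        wilcox.test(a, b, alternative = "two.sided", exact = exact,
                    correct = !exact))
    list(U = unname(wt$statistic), p.value = wt$p.value, exact = exact)
}

#' Leave-one-out cross-validation of a linear model
#'
#' LOOCV of an OLS fit of `y` on the columns of `X`, with the outcome
#' min-max normalised to [0, 1] on each training fold (the same error
#' scale the ANN cross-validation uses, so the two are comparable in a
#' Mann-Whitney test on squared errors).
#'
#' @param X numeric predictor matrix.
#' @param y numeric outcome.
#' @return a [CvResult-class].
#' @export
loocvLinear <- function(X, y) {
    X <- as.matrix(X)
    n <- length(y)
    stopifnot(nrow(X) == n, n >= 3)
    preds <- numeric(n); sqe <- numeric(n)
    for (i in seq_len(n)) {
        Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
        df <- data.frame(y = yi, Xi, check.names = FALSE)
        fit <- lm(y ~ ., data = df)
        nd <- data.frame(X[i, , drop = FALSE], check.names = FALSE)
        preds[i] <- predict(fit, newdata = nd)
        b <- .normBounds(yi)
        sqe[i] <- (.normalize(preds[i], b) - .normalize(y[i], b))^2
    }
    new("CvResult", predictions = preds, sqErrors = sqe,
        rmse = sqrt(mean(sqe)), rmseSd = NA_real_,
        config = list(model = "ols"), nrep = 1L)
}

# min-max normalisation helpers shared with the ANN module; a zero range
# (constant training outcome) maps everything to 0.5
.normBounds <- function(y) c(min = min(y), max = max(y))
.normalize <- function(y, b) {
    r <- b[["max"]] - b[["min"]]
    if (r <= 0) rep(0.5, length(y)) else (y - b[["min"]]) / r
}
.denormalize <- function(yn, b) {
    r <- b[["max"]] - b[["min"]]
    if (r <= 0) rep(b[["min"]], length(yn)) else yn * r + b[["min"]]
}
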
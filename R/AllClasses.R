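#' ImageGrid: a 3D scalar lattice with physical spacing
#'
#' Container for a 3D voxel grid of CT intensities (Hounsfield units) or
#' absorbed dose (Gy), together with the per-axis voxel size in mm. World
#' position of voxel `(i, j, k)` (1-based R indices) is
#' `(i-1, j-1, k-1) * spacing` mm, matching a 0-based corner-anchored
#' convention.
#'
#' @slot values 3D numeric array, all finite.
#' @slot spacing numeric(3), voxel size in mm per axis, all > 0.
#' @slot unit one of `"HU"` or `"Gy"`.
#' @export
setClass("ImageGrid",
    representation(values = "array", spacing = "numeric", unit = "character"))

setValidity("ImageGrid", function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
        msg <- c(msg, "values must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 positive finite numbers (mm)")
    if (!all(is.finite(object@values)))
        msg <- c(msg, "values must be finite")
    if (length(object@unit) != 1L || !object@unit %in% c("HU", "Gy"))
        msg <- c(msg, "unit must be \"HU\" or \"Gy\"")
    if (length(msg)) msg else TRUE
})

#' Construct an ImageGrid
#'
#' @param values 3D numeric array.
#' @param spacing numeric(3) voxel size in mm.
#' @param unit `"HU"` or `"Gy"`.
#' @return An [ImageGrid-class] object.
#' @examples
#' g <- imageGrid(array(0, c(4, 4, 4)), spacing = c(2, 2, 2.5), unit = "HU")
#' gridSpacing(g)
#' @export
imageGrid <- function(values, spacing, unit = c("HU", "Gy")) {
    unit <- match.arg(unit)
    new("ImageGrid", values = values, spacing = as.numeric(spacing),
        unit = unit)
}

#' StructureSet: named binary masks on one ImageGrid
#'
#' Holds the segmentation masks of a plan (GTV, ITV, PTV, lungs, body and
#' any derived structures such as shells) as logical arrays aligned to a
#' single reference [ImageGrid-class]. A non-empty `body` mask is required.
#'
#' @slot masks named list of logical 3D arrays, all with the grid's shape.
#' @slot grid the reference [ImageGrid-class].
#' @export
setClass("StructureSet",
    representation(masks = "list", grid = "ImageGrid"))

setValidity("StructureSet", function(object) {
    msg <- character()
    dims <- dim(object@grid@values)
    if (is.null(names(object@masks)) || any(names(object@masks) == ""))
        msg <- c(msg, "all masks must be named")
    for (nm in names(object@masks)) {
        m <- object@masks[[nm]]
        if (!is.logical(m) || !identical(dim(m), dims))
            msg <- c(msg, sprintf(
                "mask '%s' must be a logical array with the grid's shape", nm))
    }
    if (!"body" %in% names(object@masks))
        msg <- c(msg, "a 'body' mask is required")
    else if (!any(object@masks[["body"]]))
        msg <- c(msg, "the 'body' mask must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Construct a StructureSet
#'
#' @param masks named list of logical 3D arrays.
#' @param grid the reference [ImageGrid-class].
#' @return A [StructureSet-class] object.
#' @export
structureSet <- function(masks, grid) {
    new("StructureSet", masks = masks, grid = grid)
}

#' LinearFit: an ordinary-least-squares fit with inference
#'
#' Result of [fitSingle()] or [fitMultiple()]: coefficients, coefficient of
#' determination, per-coefficient two-sided t-test P values, and the overall
#' F-test P value (the model's significance factor).
#'
#' @slot coefficients named numeric, intercept first.
#' @slot r.squared,adj.r.squared unadjusted and adjusted R^2.
#' @slot p.values named numeric, two-sided P per coefficient.
#' @slot sig.factor overall F-test P value.
#' @slot residuals numeric residual vector.
#' @slot n number of observations.
#' @export
setClass("LinearFit",
    representation(coefficients = "numeric", r.squared = "numeric",
        adj.r.squared = "numeric", p.values = "numeric",
        sig.factor = "numeric", residuals = "numeric", n = "integer"))

setValidity("LinearFit", function(object) {
    msg <- character()
    if (object@r.squared < -1e-12 || object@r.squared > 1 + 1e-12)
        msg <- c(msg, "r.squared must lie in [0, 1]")
    pv <- object@p.values[!is.na(object@p.values)]
    if (any(pv < 0 | pv > 1))
        msg <- c(msg, "p.values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' PublishedModel: a fixed two-feature dose-conversion predictor
#'
#' The two published multiple-linear-regression models mapping PTV volume
#' and the mean Hounsfield unit of the 2 mm shell outside the PTV to the
#' percent PTV D95 deficiency of a pencil-beam plan recalculated with Monte
#' Carlo. `"eq1"` uses the volume itself, `"eq2"` its 2/3 power (a surface-
#' area surrogate).
#'
#' @slot id `"eq1"` or `"eq2"`.
#' @slot intercept,coefVolume,coefHU fixed published coefficients.
#' @slot volumeExponent 1 for `"eq1"`, 2/3 for `"eq2"`.
#' @export
setClass("PublishedModel",
    representation(id = "character", intercept = "numeric",
        coefVolume = "numeric", coefHU = "numeric",
        volumeExponent = "numeric"))

setValidity("PublishedModel", function(object) {
    if (!object@id %in% c("eq1", "eq2")) return("id must be 'eq1' or 'eq2'")
    if (!isTRUE(all.equal(object@volumeExponent, 1)) &&
        !isTRUE(all.equal(object@volumeExponent, 2 / 3)))
        return("volumeExponent must be 1 or 2/3")
    TRUE
})

#' AnnModel: a fitted single-hidden-layer network regressor
#'
#' Wraps a `nnet` fit together with the training-data input
#' standardisation and outcome min-max normalisation needed to apply it.
#'
#' @slot net the underlying `nnet` object.
#' @slot config list: `size`, `decay`, `seed`, `maxit`.
#' @slot xCenter,xScale per-feature standardisation of the inputs.
#' @slot yMin,yMax training-outcome normalisation bounds.
#' @slot converged FALSE when the optimiser hit the iteration cap.
#' @slot featureNames the feature columns the model expects.
#' @export
setClass("AnnModel",
    representation(net = "ANY", config = "list", xCenter = "numeric",
        xScale = "numeric", yMin = "numeric", yMax = "numeric",
        converged = "logical", featureNames = "character"))

#' CvResult: cross-validated prediction error
#'
#' Held-out predictions and normalized root-mean-square error from
#' leave-one-out (or k-fold) cross-validation. Errors are measured on the
#' outcome min-max normalized to [0, 1] using each training fold's bounds.
#'
#' @slot predictions held-out predictions, one per sample, original scale.
#' @slot sqErrors per-sample squared errors on the normalized scale.
#' @slot rmse average normalized RMSE over replicates.
#' @slot rmseSd SD of the normalized RMSE across replicates (NA for one).
#' @slot config the model configuration used.
#' @slot nrep number of replicates.
#' @export
setClass("CvResult",
    representation(predictions = "numeric", sqErrors = "numeric",
        rmse = "numeric", rmseSd = "numeric", config = "list",
        nrep = "integer"))

setValidity("CvResult", function(object) {
    if (object@rmse < 0) return("rmse must be >= 0")
    if (any(object@sqErrors < 0)) return("squared errors must be >= 0")
    TRUE
})
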
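#' Accessors for ImageGrid and StructureSet
#'
#' `gridValues`, `gridSpacing` and `gridUnit` read the voxel array, the
#' per-axis spacing (mm) and the unit tag of an [ImageGrid-class].
#' `structureNames` and `getMask` access the masks of a
#' [StructureSet-class]; `setMask` returns a copy with one mask added or
#' replaced; `referenceGrid` returns the grid the masks live on.
#'
#' @param x an `ImageGrid` or `StructureSet`.
#' @param name structure name, e.g. `"PTV"`.
#' @param value a logical array with the grid's shape.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname grid-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname grid-accessors
#' @export
setGeneric("gridUnit", function(x) standardGeneric("gridUnit"))
#' @rdname grid-accessors
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))
#' @rdname grid-accessors
#' @export
setGeneric("getMask", function(x, name) standardGeneric("getMask"))
#' @rdname grid-accessors
#' @export
setGeneric("setMask", function(x, name, value) standardGeneric("setMask"))
#' @rdname grid-accessors
#' @export
setGeneric("referenceGrid", function(x) standardGeneric("referenceGrid"))

#' @rdname grid-accessors
setMethod("gridValues", "ImageGrid", function(x) x@values)
#' @rdname grid-accessors
setMethod("gridSpacing", "ImageGrid", function(x) x@spacing)
#' @rdname grid-accessors
setMethod("gridUnit", "ImageGrid", function(x) x@unit)

#' @rdname grid-accessors
setMethod("structureNames", "StructureSet", function(x) names(x@masks))

#' @rdname grid-accessors
setMethod("getMask", "StructureSet", function(x, name) {
    if (!name %in% names(x@masks))
        stop("no structure named '", name, "'; available: ",
             paste(names(x@masks), collapse = ", "))
    x@masks[[name]]
})

#' @rdname grid-accessors
setMethod("setMask", "StructureSet", function(x, name, value) {
    x@masks[[name]] <- value
    validObject(x)
    x
})

#' @rdname grid-accessors
setMethod("referenceGrid", "StructureSet", function(x) x@grid)

setMethod("show", "ImageGrid", function(object) {
    d <- dim(object@values)
    cat(sprintf("ImageGrid [%s]: %d x %d x %d voxels, spacing %s mm\n",
        object@unit, d[1], d[2], d[3],
        paste(format(object@spacing, trim = TRUE), collapse = " x ")))
    cat(sprintf("  value range: [%.1f, %.1f]\n",
        min(object@values), max(object@values)))
})

setMethod("show", "StructureSet", function(object) {
    cat(sprintf("StructureSet with %d structures on a %s grid\n",
        length(object@masks),
        paste(dim(object@grid@values), collapse = " x ")))
    for (nm in names(object@masks))
        cat(sprintf("  %-12s %d voxels\n", nm, sum(object@masks[[nm]])))
})

setMethod("show", "LinearFit", function(object) {
    cat("Linear fit (OLS), n =", object@n, "\n")
    print(round(object@coefficients, 6))
    cat(sprintf("R^2 = %.4f (adj. %.4f), significance factor (F-test P) = %.3g\n",
        object@r.squared, object@adj.r.squared, object@sig.factor))
})

setMethod("show", "PublishedModel", function(object) {
    cat(sprintf(
        "Published model '%s': %%diff = %.5f %+.5f * V_PTV^%s %+.5f * HU_shell2mm\n",
        object@id, object@intercept, object@coefVolume,
        ifelse(object@volumeExponent == 1, "1", "2/3"), object@coefHU))
})

setMethod("show", "AnnModel", function(object) {
    cat(sprintf(
        "Single-hidden-layer ANN: size %d, decay %g, %s (seed %s)\n",
        object@config$size, object@config$decay,
        if (object@converged) "converged" else "NOT converged",
        object@config$seed))
})

setMethod("show", "CvResult", function(object) {
    cat(sprintf(
        "Cross-validation over %d samples: normalized RMSE %.4f%s\n",
        length(object@predictions), object@rmse,
        if (is.na(object@rmseSd)) "" else sprintf(" (SD %.4f over %d reps)",
            object@rmseSd, object@nrep)))
})
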
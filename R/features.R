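#' Threshold-based soft-tissue mask
#'
#' Voxels at or above `thresholdHu`, minus the GTV. The default of -200 HU
#' separates lung parenchyma (about -900 to -500 HU) from chest wall and
#' mediastinum; it is exposed because the clinical definition of "nearest
#' soft tissue" is otherwise operational.
#'
#' @param ct [ImageGrid-class] in HU.
#' @param gtvMask logical 3D array removed from the result.
#' @param thresholdHu HU threshold (default -200).
#' @return logical 3D array.
#' @export
softTissueMask <- function(ct, gtvMask, thresholdHu = -200) {
    stopifnot(gridUnit(ct) == "HU")
    gridValues(ct) >= thresholdHu & !gtvMask
}

#' Mean and SD of Hounsfield units within a mask
#'
#' The density surrogates: arithmetic mean (primary index) and sample SD
#' with the n-1 denominator (secondary index) of the in-mask CT values.
#'
#' @param ct [ImageGrid-class] in HU.
#' @param mask logical 3D array, non-empty.
#' @return named numeric: `mean`, `sd` (sd is 0 for a single voxel).
#' @export
huStats <- function(ct, mask) {
    if (!any(mask)) stop("empty mask: HU statistics undefined")
    v <- gridValues(ct)[mask]
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
}

#' Feature-table column names
#'
#' The fixed column order of the per-patient feature record: identifier,
#' size indices, distance index, then mean and SD Hounsfield units of the
#' seven density structures.
#'
#' @param shellsMm shell thicknesses in mm.
#' @return character vector of column names.
#' @export
featureColumns <- function(shellsMm = c(2, 15, 50)) {
    dens <- c("ptv", "gtv", "margin",
              sprintf("shell%gmm", shellsMm), "lung")
    c("patient_id", "v_ptv_cm3", "v_gtv_cm3", "maxd_mm", "dmin_mm",
      paste0("hu_mean_", dens), paste0("hu_sd_", dens))
}

#' Extract the per-patient feature record
#'
#' Computes the full quantitative feature set from a CT and its
#' structures: PTV and GTV volumes (cm^3), the maximum GTV dimension MaxD
#' (mm), the minimum GTV-to-soft-tissue distance dmin (mm), and the mean
#' and standard deviation of the Hounsfield units of the PTV, GTV, PTV
#' margin (PTV minus GTV), the shells immediately outside the PTV
#' (2/15/50 mm by default, clipped to the body), and the lungs. The lung
#' statistics deliberately include the tumour volume. The GTV density is
#' computed like the others but is exploratory rather than a true location
#' feature: tumour density is pathology- more than location-dependent.
#'
#' @param ct [ImageGrid-class] in HU.
#' @param structures [StructureSet-class] with `GTV`, `PTV`, `lungs`,
#'   `body`.
#' @param thresholdHu soft-tissue HU threshold for dmin.
#' @param shellsMm shell thicknesses in mm.
#' @param patientId identifier for the record.
#' @return a one-row `data.frame` in the [featureColumns()] order.
#' @export
extractFeatures <- function(ct, structures, thresholdHu = -200,
                            shellsMm = c(2, 15, 50), patientId = "P1") {
    grid <- referenceGrid(structures)
    gtv <- getMask(structures, "GTV")
    ptv <- getMask(structures, "PTV")
    lungs <- getMask(structures, "lungs")
    body <- getMask(structures, "body")
    margin <- maskDifference(ptv, gtv)

    masks <- list(ptv = ptv, gtv = gtv, margin = margin)
    for (t in shellsMm)
        masks[[sprintf("shell%gmm", t)]] <- shellMask(ptv, t, body, grid)
    masks$lung <- lungs

    soft <- softTissueMask(ct, gtv, thresholdHu)
    rec <- data.frame(patient_id = patientId,
        v_ptv_cm3 = volumeCm3(ptv, grid),
        v_gtv_cm3 = volumeCm3(gtv, grid),
        maxd_mm = maxDiameter(gtv, grid),
        dmin_mm = dminGtv(gtv, soft, grid),
        stringsAsFactors = FALSE)
    for (nm in names(masks)) {
        s <- huStats(ct, masks[[nm]])
        rec[[paste0("hu_mean_", nm)]] <- s[["mean"]]
        rec[[paste0("hu_sd_", nm)]] <- s[["sd"]]
    }
    rec <- rec[, featureColumns(shellsMm)]
    stopifnot(rec$v_gtv_cm3 <= rec$v_ptv_cm3)
    rec
}
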
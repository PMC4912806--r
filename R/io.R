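#' Read and write image grids as NIfTI
#'
#' `writeImageGrid` stores the voxel array with its spacing in the NIfTI
#' pixdim; `readImageGrid` restores an [ImageGrid-class], taking the unit
#' tag from the caller (NIfTI carries no dose/HU unit).
#' `writeStructureMask`/`readStructureMask` do the same for binary masks
#' (stored as 0/1 bytes).
#'
#' @param grid an [ImageGrid-class].
#' @param mask logical 3D array.
#' @param refGrid the [ImageGrid-class] a read mask must align to.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param unit unit tag for the grid being read.
#' @return `readImageGrid` an `ImageGrid`; `readStructureMask` a logical
#'   array; the writers return the path invisibly.
#' @name nifti-io
NULL

#' @rdname nifti-io
#' @export
writeImageGrid <- function(grid, path) {
    img <- RNifti::asNifti(gridValues(grid))
    RNifti::pixdim(img) <- gridSpacing(grid)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' @rdname nifti-io
#' @export
readImageGrid <- function(path, unit = c("HU", "Gy")) {
    unit <- match.arg(unit)
    img <- RNifti::readNifti(path)
    imageGrid(array(as.numeric(img), dim(img)),
              RNifti::pixdim(img)[1:3], unit)
}

#' @rdname nifti-io
#' @export
writeStructureMask <- function(mask, grid, path) {
    img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
    RNifti::pixdim(img) <- gridSpacing(grid)
    RNifti::writeNifti(img, path, datatype = "uint8")
    invisible(path)
}

#' @rdname nifti-io
#' @export
readStructureMask <- function(path, refGrid) {
    img <- RNifti::readNifti(path)
    m <- array(as.numeric(img) != 0, dim(img))
    if (!identical(dim(m), dim(gridValues(refGrid))))
        stop("mask in ", path, " does not match the reference grid shape")
    m
}

#' Read and write cohort feature tables as CSV
#'
#' The on-disk schema is one row per patient with at least a
#' `patient_id` column plus numeric feature/outcome columns. Reading
#' validates the schema: missing required columns raise an error naming
#' them, and any cell that fails numeric conversion raises an error
#' naming its row and column. Unknown extra columns are preserved.
#'
#' @param tbl a `data.frame`.
#' @param path CSV file path.
#' @param required column names that must be present (beyond
#'   `patient_id`).
#' @return `readFeatureTable` the validated `data.frame`;
#'   `writeFeatureTable` the path, invisibly.
#' @name feature-table-io
NULL

#' @rdname feature-table-io
#' @export
writeFeatureTable <- function(tbl, path) {
    stopifnot(is.data.frame(tbl), "patient_id" %in% names(tbl))
    out <- tbl
    for (cn in names(out))  # 17 significant digits: lossless for doubles
        if (is.numeric(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname feature-table-io
#' @export
readFeatureTable <- function(path,
        required = c("v_ptv_cm3", "hu_mean_shell2mm", "pct_diff_ptv_d95")) {
    raw <- read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
    missing <- setdiff(c("patient_id", required), names(raw))
    if (length(missing))
        stop("feature table ", path, " is missing column(s): ",
             paste(missing, collapse = ", "))
    out <- raw
    for (cn in setdiff(names(raw), "patient_id")) {
        conv <- suppressWarnings(as.numeric(raw[[cn]]))
        bad <- which(is.na(conv) & !(raw[[cn]] %in% c("", "NA")))
        if (length(bad))
            stop("malformed numeric value in column '", cn, "', row ",
                 bad[1], ": '", raw[[cn]][bad[1]], "'")
        out[[cn]] <- conv
    }
    out
}
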
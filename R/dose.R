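#' DVH dose-at-volume
#'
#' The minimum dose received by `pctVolume` percent of the structure: the
#' largest dose `d` such that the fraction of in-mask voxels with dose >=
#' `d` is at least `pctVolume`/100. D95 is `doseAtVolume(dose, mask, 95)`.
#' By default the lower order statistic is returned (no DVH-bin
#' interpolation), which matches the verbal definition exactly;
#' `interpolate = TRUE` returns the linearly interpolated quantile instead.
#'
#' @param dose an [ImageGrid-class] in Gy.
#' @param mask logical 3D array, non-empty.
#' @param pctVolume percent volume in (0, 100].
#' @param interpolate use linear quantile interpolation instead of the
#'   order-statistic convention.
#' @return dose in Gy.
#' @examples
#' g <- imageGrid(array(1:20, c(20, 1, 1)), c(1, 1, 1), "Gy")
#' m <- array(TRUE, c(20, 1, 1))
#' doseAtVolume(g, m, 95)   # 2 Gy: 19/20 voxels receive >= 2 Gy
#' doseAtVolume(g, m, 100)  # the minimum dose
#' @export
doseAtVolume <- function(dose, mask, pctVolume, interpolate = FALSE) {
    if (!any(mask)) stop("empty mask: dose-at-volume undefined")
    if (pctVolume <= 0 || pctVolume > 100)
        stop("pctVolume must be in (0, 100]")
    x <- sort(gridValues(dose)[mask])
    n <- length(x)
    if (interpolate)
        return(unname(quantile(x, probs = 1 - pctVolume / 100, type = 7)))
    # largest k with (n - k + 1) / n >= pct/100, i.e. coverage still holds
    k <- floor(n * (1 - pctVolume / 100)) + 1L
    x[min(k, n)]
}

#' Summarise the dose to one structure
#'
#' D95 (via [doseAtVolume()]), mean and maximum dose over the mask, tagged
#' with the structure name and the dose algorithm that produced the grid.
#'
#' @param dose an [ImageGrid-class] in Gy.
#' @param mask logical 3D array, non-empty.
#' @param structure structure name for the record.
#' @param algorithm `"PB"` or `"MC"`.
#' @return a one-row `data.frame` with columns `structure`, `algorithm`,
#'   `d95_gy`, `dmean_gy`, `dmax_gy`.
#' @export
doseSummary <- function(dose, mask, structure = "PTV",
                        algorithm = c("PB", "MC")) {
    algorithm <- match.arg(algorithm)
    if (!any(mask)) stop("empty mask: dose summary undefined")
    v <- gridValues(dose)[mask]
    out <- data.frame(structure = structure, algorithm = algorithm,
        d95_gy = doseAtVolume(dose, mask, 95), dmean_gy = mean(v),
        dmax_gy = max(v), stringsAsFactors = FALSE)
    stopifnot(out$d95_gy <= out$dmax_gy, out$dmean_gy <= out$dmax_gy)
    out
}

#' Percent dose deficiency of MC relative to PB
#'
#' `100 * (pb - mc) / pb`: how much smaller the Monte Carlo-computed value
#' is than the pencil-beam one, as a percentage of the PB value. For a
#' plan normalised so that the PB PTV D95 equals the prescription, the PTV
#' D95 deficiency is a percentage of the prescription dose.
#'
#' @param pbValue PB-computed dose (Gy), > 0.
#' @param mcValue MC-computed dose (Gy).
#' @return percent deficiency.
#' @examples
#' percentDeficiency(50, 40)      # 20
#' percentDeficiency(48, 43.824)  # 8.7
#' @export
percentDeficiency <- function(pbValue, mcValue) {
    if (any(pbValue <= 0)) stop("PB value must be > 0")
    100 * (pbValue - mcValue) / pbValue
}

#' Per-patient deficiency record
#'
#' Percent PB-to-MC deficiencies of D95, Dmean and Dmax for the PTV and
#' the GTV, from a paired pair of dose grids on a common grid. The PTV D95
#' deficiency is the modelled outcome.
#'
#' @param pbDose,mcDose [ImageGrid-class] dose grids (Gy) on the same grid.
#' @param structures a [StructureSet-class] containing `PTV` and `GTV`.
#' @param patientId identifier carried into the record.
#' @return a one-row `data.frame` with columns `patient_id`,
#'   `pct_diff_ptv_d95`, `pct_diff_ptv_dmean`, `pct_diff_ptv_dmax`,
#'   `pct_diff_gtv_d95`, `pct_diff_gtv_dmean`, `pct_diff_gtv_dmax`.
#' @export
deficiencyRecord <- function(pbDose, mcDose, structures, patientId = "P1") {
    stopifnot(identical(dim(gridValues(pbDose)), dim(gridValues(mcDose))))
    one <- function(name) {
        m <- getMask(structures, name)
        pb <- doseSummary(pbDose, m, name, "PB")
        mc <- doseSummary(mcDose, m, name, "MC")
        c(d95 = percentDeficiency(pb$d95_gy, mc$d95_gy),
          dmean = percentDeficiency(pb$dmean_gy, mc$dmean_gy),
          dmax = percentDeficiency(pb$dmax_gy, mc$dmax_gy))
    }
    p <- one("PTV"); g <- one("GTV")
    data.frame(patient_id = patientId,
        pct_diff_ptv_d95 = p[["d95"]], pct_diff_ptv_dmean = p[["dmean"]],
        pct_diff_ptv_dmax = p[["dmax"]], pct_diff_gtv_d95 = g[["d95"]],
        pct_diff_gtv_dmean = g[["dmean"]], pct_diff_gtv_dmax = g[["dmax"]],
        stringsAsFactors = FALSE)
}

#' Check plan normalisation against the prescription
#'
#' Verifies that a PB plan is normalised so 95 percent of the PTV receives
#' the prescription dose, i.e. `D95(PB, PTV) == rx` within `tolGy`, and
#' reports the prescription-to-maximum-dose ratio (clinically, the
#' prescription sits around 90 percent of the maximum dose for these
#' plans). Report-only: never throws on failure.
#'
#' @param pbDose [ImageGrid-class] PB dose (Gy).
#' @param ptvMask logical 3D array.
#' @param rx prescription dose in Gy, > 0.
#' @param tolGy tolerance on the D95 check, Gy.
#' @return list with `pass`, `d95_gy`, `deviation_gy`, `dmax_gy`, and
#'   `rx_over_dmax` (rounded to 3 decimals).
#' @export
verifyNormalization <- function(pbDose, ptvMask, rx, tolGy = 0.1) {
    if (rx <= 0) stop("rx must be > 0")
    d95 <- doseAtVolume(pbDose, ptvMask, 95)
    dmax <- max(gridValues(pbDose)[ptvMask])
    list(pass = abs(d95 - rx) <= tolGy, d95_gy = d95,
         deviation_gy = d95 - rx, dmax_gy = dmax,
         rx_over_dmax = round(rx / dmax, 3))
}
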
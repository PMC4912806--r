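#' Thoracic phantom configuration
#'
#' Parameters of the synthetic free-breathing thoracic CT phantom: an
#' elliptic soft-tissue body section containing two lung ellipsoids, with
#' a spherical tumour inserted at one of three canonical positions:
#' `"island"` (fully surrounded by lung), `"chest_wall"` (abutting the
#' lateral chest wall) or `"mediastinal"` (abutting the mediastinum). The
#' GTV is the tumour sphere; a fixed uniform expansion produces the ITV
#' (a stand-in for the 4D-CT motion envelope, which is not simulated) and
#' a 6 mm uniform expansion of the ITV produces the PTV.
#'
#' @param shape voxels per axis (default 90 x 90 x 60).
#' @param spacingMm mm per axis (default 2 x 2 x 2.5, anisotropic as CT
#'   slices usually are).
#' @param lungHu,lungSdHu lung mean HU and Gaussian noise SD (defaults
#'   -750, 50).
#' @param tissueHu,tissueSdHu soft-tissue mean HU and noise SD (defaults
#'   30, 20).
#' @param tumourHu tumour HU, noiseless (default 20).
#' @param tumourRadiusMm tumour radius in mm, > 0 (default 10).
#' @param placement one of `"island"`, `"chest_wall"`, `"mediastinal"`.
#' @param itvMarginMm fixed GTV-to-ITV expansion (default 2 mm).
#' @param ptvMarginMm ITV-to-PTV expansion (default 6 mm).
#' @param seed integer seed for the HU noise.
#' @return a validated list of class `"PhantomConfig"`.
#' @export
phantomConfig <- function(shape = c(90, 90, 60), spacingMm = c(2, 2, 2.5),
                          lungHu = -750, lungSdHu = 50, tissueHu = 30,
                          tissueSdHu = 20, tumourHu = 20,
                          tumourRadiusMm = 10,
                          placement = c("island", "chest_wall",
                                        "mediastinal"),
                          itvMarginMm = 2, ptvMarginMm = 6, seed = 1) {
    placement <- match.arg(placement)
    stopifnot(length(shape) == 3, all(shape >= 8),
              length(spacingMm) == 3, all(spacingMm > 0),
              tumourRadiusMm > 0, itvMarginMm >= 0, ptvMarginMm >= 0)
    if (lungHu >= tissueHu)
        stop("lung HU must be below soft-tissue HU")
    structure(list(shape = as.integer(shape),
        spacingMm = as.numeric(spacingMm), lungHu = lungHu,
        lungSdHu = lungSdHu, tissueHu = tissueHu, tissueSdHu = tissueSdHu,
        tumourHu = tumourHu, tumourRadiusMm = tumourRadiusMm,
        placement = placement, itvMarginMm = itvMarginMm,
        ptvMarginMm = ptvMarginMm, seed = as.integer(seed)),
        class = "PhantomConfig")
}

# world coordinates (mm) of all voxel centres, one matrix per axis
.coordGrids <- function(shape, spacing) {
    cx <- (seq_len(shape[1]) - 1) * spacing[1]
    cy <- (seq_len(shape[2]) - 1) * spacing[2]
    cz <- (seq_len(shape[3]) - 1) * spacing[3]
    list(x = array(rep(cx, times = shape[2] * shape[3]), shape),
         y = array(rep(rep(cy, each = shape[1]), times = shape[3]), shape),
         z = array(rep(cz, each = shape[1] * shape[2]), shape))
}

.ellipsoidMask <- function(co, centre, semi) {
    ((co$x - centre[1]) / semi[1])^2 + ((co$y - centre[2]) / semi[2])^2 +
        ((co$z - centre[3]) / semi[3])^2 <= 1
}

.sphereMask <- function(co, centre, r) {
    (co$x - centre[1])^2 + (co$y - centre[2])^2 +
        (co$z - centre[3])^2 <= r^2
}

# internal anatomy layout, in mm relative to the grid origin
.phantomAnatomy <- function(cfg) {
    extent <- (cfg$shape - 1) * cfg$spacingMm
    centre <- extent / 2
    bodySemi <- c(0.47, 0.42) * extent[1:2]
    lungSemi <- c(0.20 * extent[1], 0.33 * extent[2], 0.47 * extent[3])
    lungOffsetX <- 0.25 * extent[1]
    list(centre = centre, bodySemi = bodySemi, lungSemi = lungSemi,
         rightLungCentre = centre + c(lungOffsetX, 0, 0),
         leftLungCentre = centre - c(lungOffsetX, 0, 0))
}

#' Generate a synthetic thoracic phantom
#'
#' Builds the CT (HU) and the structure set (GTV, ITV, PTV, lungs, body)
#' from a [phantomConfig()]. Voxels outside the body are air (-1000 HU);
#' lung and soft-tissue compartments receive seeded Gaussian HU noise;
#' the tumour is uniform. All HU are clipped to the physical CT range
#' [-1000, 1500]. The lungs mask is the anatomical lung compartment and
#' does not exclude the tumour. Structure nesting GTV within ITV within
#' PTV within body holds by construction (the PTV is clipped to the
#' body).
#'
#' @param cfg a [phantomConfig()].
#' @return list with `ct` (an [ImageGrid-class]) and `structures` (a
#'   [StructureSet-class]).
#' @export
generatePhantom <- function(cfg) {
    stopifnot(inherits(cfg, "PhantomConfig"))
    co <- .coordGrids(cfg$shape, cfg$spacingMm)
    an <- .phantomAnatomy(cfg)
    r <- cfg$tumourRadiusMm
    maxSp <- max(cfg$spacingMm)

    body <- ((co$x - an$centre[1]) / an$bodySemi[1])^2 +
            ((co$y - an$centre[2]) / an$bodySemi[2])^2 <= 1
    lungs <- .ellipsoidMask(co, an$rightLungCentre, an$lungSemi) |
             .ellipsoidMask(co, an$leftLungCentre, an$lungSemi)
    lungs <- lungs & body

    # tumour centre by placement; chest-wall/mediastinal tumours overshoot
    # the lung boundary by one voxel so the GTV genuinely abuts soft tissue
    tc <- an$rightLungCentre
    if (cfg$placement == "island") {
        if (r + 2 * maxSp > min(an$lungSemi))
            stop("tumour of radius ", r,
                 " mm does not fit as an island in the lung ",
                 "(needs clearance to the lung boundary)")
    } else if (cfg$placement == "chest_wall") {
        tc[1] <- an$rightLungCentre[1] + (an$lungSemi[1] - r) + 1.01 * maxSp
    } else {
        tc[1] <- an$rightLungCentre[1] - (an$lungSemi[1] - r) - 1.01 * maxSp
    }
    gtv <- .sphereMask(co, tc, r)
    if (!any(gtv)) stop("tumour sphere contains no voxels at this spacing")
    extent <- (cfg$shape - 1) * cfg$spacingMm
    if (tc[1] - r < 0 || tc[1] + r > extent[1])
        stop("tumour of radius ", r, " mm does not fit in the grid")

    grid <- imageGrid(array(0, cfg$shape), cfg$spacingMm, "HU")
    itv <- expandMask(gtv, cfg$itvMarginMm, grid)
    ptv <- expandMask(itv, cfg$ptvMarginMm, grid) & body
    itv <- itv & body
    gtv <- gtv & body

    set.seed(cfg$seed)
    ct <- array(-1000, cfg$shape)
    nTis <- sum(body & !lungs)
    ct[body & !lungs] <- cfg$tissueHu +
        if (cfg$tissueSdHu > 0) rnorm(nTis, 0, cfg$tissueSdHu) else 0
    nLung <- sum(lungs)
    ct[lungs] <- cfg$lungHu +
        if (cfg$lungSdHu > 0) rnorm(nLung, 0, cfg$lungSdHu) else 0
    ct[gtv] <- cfg$tumourHu
    ct[ct < -1000] <- -1000
    ct[ct > 1500] <- 1500

    structures <- structureSet(list(GTV = gtv, ITV = itv, PTV = ptv,
        lungs = lungs, body = body), imageGrid(ct, cfg$spacingMm, "HU"))
    list(ct = referenceGrid(structures), structures = structures)
}

#' Generate a paired PB/MC-like dose-grid pair
#'
#' Builds a pencil-beam-like planned dose normalised so the PTV D95
#' equals the prescription, and a Monte-Carlo-like recalculation that
#' underdoses the target periphery — the spatial signature of pencil-beam
#' error at the tumour-lung interface. The PB field is the prescription
#' inside the PTV plus a 3 mm margin with a Gaussian penumbra (sigma 4
#' mm) outside, and a mild central boost so the prescription sits near 90
#' percent of the maximum dose. The MC field is the PB field scaled by
#' `1 - delta * g(x)` with `g = 1` at and outside the PTV surface,
#' decaying inward with a 5 mm length scale; the single amplitude `delta`
#' is solved by bisection on [0, 0.9] so the realised percent PTV D95
#' deficiency is within 0.25 percent points of `targetDeficiency`. MC
#' never exceeds PB anywhere.
#'
#' @param structures a [StructureSet-class] with a non-empty `PTV`.
#' @param rx prescription dose in Gy.
#' @param targetDeficiency requested percent PTV D95 deficiency, in
#'   [0, 100).
#' @param plateauMarginMm,penumbraSigmaMm,decayLengthMm field-shape
#'   parameters (defaults 3, 4, 5 mm).
#' @param boost fractional central boost (default 1/9, putting rx at 90
#'   percent of the maximum dose).
#' @return list with `pb` and `mc` [ImageGrid-class] dose grids and the
#'   realised `deficiency`.
#' @export
generateDosePair <- function(structures, rx = 48, targetDeficiency = 15,
                             plateauMarginMm = 3, penumbraSigmaMm = 4,
                             decayLengthMm = 5, boost = 1 / 9) {
    grid <- referenceGrid(structures)
    ptv <- getMask(structures, "PTV")
    if (!any(ptv)) stop("PTV mask is empty")
    if (targetDeficiency < 0 || targetDeficiency >= 100)
        stop("targetDeficiency must be in [0, 100)")

    plateau <- expandMask(ptv, plateauMarginMm, grid)
    dOut <- maskDistance(plateau, grid)
    # depth of each voxel inside the PTV (0 at and outside the surface)
    dIn <- maskDistance(!ptv, grid)
    g <- exp(-dIn / decayLengthMm)

    pb <- rx * exp(-dOut^2 / (2 * penumbraSigmaMm^2)) *
        (1 + boost * (1 - g))
    # plan normalisation: 95 % of the PTV covered by the prescription dose
    pbGrid <- imageGrid(pb, gridSpacing(grid), "Gy")
    pb <- pb * (rx / doseAtVolume(pbGrid, ptv, 95))
    pbGrid <- imageGrid(pb, gridSpacing(grid), "Gy")
    if (targetDeficiency == 0)
        return(list(pb = pbGrid, mc = pbGrid, deficiency = 0))

    d95pb <- doseAtVolume(pbGrid, ptv, 95)
    defic <- function(delta) {
        mc <- pb * (1 - delta * g)
        d95mc <- doseAtVolume(imageGrid(mc, gridSpacing(grid), "Gy"),
                              ptv, 95)
        percentDeficiency(d95pb, d95mc)
    }
    lo <- 0; hi <- 0.9
    if (defic(hi) < targetDeficiency - 0.25)
        stop("infeasible target deficiency: ", targetDeficiency,
             " % cannot be reached with amplitude <= 0.9")
    for (i in seq_len(40)) {
        mid <- (lo + hi) / 2
        if (defic(mid) < targetDeficiency) lo <- mid else hi <- mid
    }
    delta <- (lo + hi) / 2
    mc <- pb * (1 - delta * g)
    list(pb = pbGrid, mc = imageGrid(mc, gridSpacing(grid), "Gy"),
         deficiency = defic(delta))
}

#' Synthetic cohort specification
#'
#' Sampling ranges and generating model for a tabular cohort whose rows
#' mimic the published patient population: PTV volumes spanning
#' 7.2-110.2 cm^3 and 2 mm-shell mean densities spanning deep-lung to
#' near-chest-wall values, with the percent PTV D95 deficiency generated
#' from one of the published models plus Gaussian noise.
#'
#' @param n number of patients, >= 3 (default 21).
#' @param vPtvRangeCm3 uniform sampling range of the PTV volume.
#' @param huShell2mmRange uniform sampling range of the 2 mm-shell mean
#'   HU (default -820 to -350).
#' @param model generating model, `"eq2"` (default) or `"eq1"`.
#' @param noiseSdPct additive Gaussian outcome noise SD in percent
#'   points (default 2).
#' @param seed integer seed.
#' @return a validated list of class `"CohortSpec"`.
#' @export
cohortSpec <- function(n = 21, vPtvRangeCm3 = c(7.2, 110.2),
                       huShell2mmRange = c(-820, -350),
                       model = c("eq2", "eq1"), noiseSdPct = 2, seed = 1) {
    model <- match.arg(model)
    stopifnot(n >= 3, length(vPtvRangeCm3) == 2,
              diff(vPtvRangeCm3) > 0, vPtvRangeCm3[1] > 0,
              length(huShell2mmRange) == 2, diff(huShell2mmRange) > 0,
              noiseSdPct >= 0)
    structure(list(n = as.integer(n), vPtvRangeCm3 = vPtvRangeCm3,
        huShell2mmRange = huShell2mmRange, model = model,
        noiseSdPct = noiseSdPct, seed = as.integer(seed)),
        class = "CohortSpec")
}

# affine companion-density parameters: intercept, slope on the 2 mm-shell
# HU, and jitter SD, tuned so pairwise Pearson r with the shell density
# lands around 0.8-0.95 (the collinearity structure seen clinically)
.companionParams <- function() {
    list(hu_mean_ptv = c(a = 170, b = 0.80, sd = 45),
         hu_mean_margin = c(a = -60, b = 0.95, sd = 50),
         hu_mean_shell15mm = c(a = -80, b = 0.90, sd = 45),
         hu_mean_shell50mm = c(a = 30, b = 0.75, sd = 60),
         hu_mean_lung = c(a = -250, b = 0.70, sd = 65))
}

#' Generate a synthetic cohort feature/outcome table
#'
#' Draws `n` patients with PTV volume and 2 mm-shell mean HU uniform on
#' the configured ranges, generates the percent PTV D95 deficiency from
#' the chosen published model plus Gaussian noise (clipped to [0, 40]
#' percent points as a physical guard), and adds companion density
#' features (PTV, PTV margin, 15/50 mm shells, lung means) as affine
#' functions of the shell density plus independent jitter — strongly
#' mutually correlated, while the PTV volume stays independent of all
#' densities. Deterministic given the seed.
#'
#' @param spec a [cohortSpec()].
#' @return `data.frame` with columns `patient_id`, `v_ptv_cm3`,
#'   `hu_mean_shell2mm`, the five companion densities, and
#'   `pct_diff_ptv_d95`.
#' @export
generateCohortTable <- function(spec) {
    stopifnot(inherits(spec, "CohortSpec"))
    set.seed(spec$seed)
    n <- spec$n
    v <- runif(n, spec$vPtvRangeCm3[1], spec$vPtvRangeCm3[2])
    hu <- runif(n, spec$huShell2mmRange[1], spec$huShell2mmRange[2])
    mdl <- publishedModel(spec$model)
    y <- predictPublished(mdl, v, hu)
    if (spec$noiseSdPct > 0) y <- y + rnorm(n, 0, spec$noiseSdPct)
    y <- pmin(pmax(y, 0), 40)
    tbl <- data.frame(patient_id = sprintf("S%02d", seq_len(n)),
        v_ptv_cm3 = v, hu_mean_shell2mm = hu, stringsAsFactors = FALSE)
    for (nm in names(.companionParams())) {
        p <- .companionParams()[[nm]]
        tbl[[nm]] <- pmin(pmax(
            p[["a"]] + p[["b"]] * hu + rnorm(n, 0, p[["sd"]]),
            -1000), 1500)
    }
    tbl$pct_diff_ptv_d95 <- y
    tbl
}
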
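#' Study configuration
#'
#' One object driving an end-to-end analysis run. Exactly one input mode:
#' \describe{
#'   \item{phantom}{simulate a cohort of thoracic phantoms with paired
#'     PB/MC-like dose grids, extract features and deficiencies, then
#'     model them.}
#'   \item{feature_table}{read a prepared per-patient CSV
#'     (see [readFeatureTable()]) and model it.}
#'   \item{grids}{read per-patient CT/mask/dose NIfTI files listed in a
#'     manifest CSV with columns `patient_id, ct, gtv, itv, ptv, lungs,
#'     body, pb, mc`, extract features and deficiencies, then model.}
#' }
#'
#' @param mode input mode, see above.
#' @param outDir output directory (created if missing).
#' @param featureTablePath CSV path (feature_table mode).
#' @param gridManifestPath manifest CSV path (grids mode).
#' @param nIsland,nChestWall,nMediastinal phantom counts per placement
#'   (phantom mode; defaults 12, 9, 0 — the peripheral/central split of a
#'   typical cohort).
#' @param rxGy prescription dose, Gy.
#' @param outcomeModel published model form assigning phantom target
#'   deficiencies and fitted alongside `eq1`.
#' @param noiseSdPct Gaussian noise SD added to assigned deficiencies.
#' @param thresholdHu soft-tissue threshold for dmin.
#' @param shellsMm shell thicknesses.
#' @param annSizes,annDecays,annMaxit,annNrep ANN grid-search and LOOCV
#'   settings.
#' @param seed master seed; every stage derives its randomness from it.
#' @return a validated list of class `"StudyConfig"`.
#' @export
studyConfig <- function(mode = c("phantom", "feature_table", "grids"),
                        outDir = tempfile("study"),
                        featureTablePath = NULL, gridManifestPath = NULL,
                        nIsland = 12, nChestWall = 9, nMediastinal = 0,
                        rxGy = 48, outcomeModel = c("eq2", "eq1"),
                        noiseSdPct = 2, thresholdHu = -200,
                        shellsMm = c(2, 15, 50), annSizes = 2:7,
                        annDecays = c(0.001, 0.005, 0.01, 0.05, 0.1,
                                      0.5, 1),
                        annMaxit = 500, annNrep = 1, seed = 1) {
    mode <- match.arg(mode)
    outcomeModel <- match.arg(outcomeModel)
    if (mode == "feature_table" && is.null(featureTablePath))
        stop("feature_table mode requires featureTablePath")
    if (mode == "grids" && is.null(gridManifestPath))
        stop("grids mode requires gridManifestPath")
    if (mode == "phantom" && nIsland + nChestWall + nMediastinal < 3)
        stop("phantom mode needs at least 3 phantoms")
    structure(list(mode = mode, outDir = outDir,
        featureTablePath = featureTablePath,
        gridManifestPath = gridManifestPath, nIsland = nIsland,
        nChestWall = nChestWall, nMediastinal = nMediastinal, rxGy = rxGy,
        outcomeModel = outcomeModel, noiseSdPct = noiseSdPct,
        thresholdHu = thresholdHu, shellsMm = shellsMm,
        annSizes = annSizes, annDecays = annDecays, annMaxit = annMaxit,
        annNrep = annNrep, seed = as.integer(seed)),
        class = "StudyConfig")
}

#' Single-regression feature screen
#'
#' Regresses the outcome on each feature column separately with
#' [fitSingle()] and returns the features ranked by descending R^2 with
#' the slope sign — the screen that ranks density-location features
#' against size features. Constant columns are skipped with a warning.
#'
#' @param tbl `data.frame` with one row per patient.
#' @param outcome outcome column name.
#' @param features feature column names; defaults to every numeric
#'   column except the outcome, other deficiency columns and
#'   `patient_id`.
#' @return `data.frame` with columns `feature`, `r_squared`, `sign`,
#'   `slope`, `p_value`, sorted by decreasing `r_squared`.
#' @export
featureCorrelationScreen <- function(tbl, outcome = "pct_diff_ptv_d95",
                                     features = NULL) {
    stopifnot(outcome %in% names(tbl), nrow(tbl) >= 3)
    if (is.null(features)) {
        numcols <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
        features <- setdiff(numcols,
            c(outcome, "patient_id", grep("^pct_diff_", names(tbl),
                                          value = TRUE)))
    }
    y <- tbl[[outcome]]
    rows <- lapply(features, function(f) {
        x <- tbl[[f]]
        if (sd(x) == 0) {
            warning("skipping constant feature '", f, "'")
            return(NULL)
        }
        fit <- fitSingle(x, y)
        slope <- unname(fit@coefficients[2])
        data.frame(feature = f, r_squared = fit@r.squared,
            sign = ifelse(slope >= 0, "+", "-"), slope = slope,
            p_value = unname(fit@p.values[2]), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$r_squared), ]
    rownames(out) <- NULL
    out
}

# published-model design matrix from a feature table
.modelDesign <- function(tbl, id) {
    exponent <- if (id == "eq1") 1 else 2 / 3
    X <- cbind(tbl$v_ptv_cm3^exponent, tbl$hu_mean_shell2mm)
    colnames(X) <- c(if (id == "eq1") "v_ptv" else "v_ptv_2_3",
                    "hu_shell2mm")
    X
}

.phantomCohort <- function(config) {
    counts <- c(island = config$nIsland, chest_wall = config$nChestWall,
                mediastinal = config$nMediastinal)
    placements <- rep(names(counts), counts)
    n <- length(placements)
    set.seed(config$seed)
    radii <- ifelse(placements == "island", runif(n, 7, 13),
                    runif(n, 7, 16))
    lungHus <- runif(n, -850, -650)
    tumourHus <- runif(n, -30, 60)  # pathology-dependent, not location
    targetsNoise <- rnorm(n, 0, config$noiseSdPct)
    mdl <- publishedModel(config$outcomeModel)

    feats <- NULL; defs <- NULL
    for (i in seq_len(n)) {
        cfg <- phantomConfig(lungHu = lungHus[i],
            tumourHu = tumourHus[i], tumourRadiusMm = radii[i],
            placement = placements[i], seed = config$seed + i)
        ph <- generatePhantom(cfg)
        fr <- extractFeatures(ph$ct, ph$structures,
            thresholdHu = config$thresholdHu, shellsMm = config$shellsMm,
            patientId = sprintf("PH%02d", i))
        target <- predictPublished(mdl, fr$v_ptv_cm3,
                                   fr$hu_mean_shell2mm) + targetsNoise[i]
        target <- min(max(target, 1), 35)
        dp <- generateDosePair(ph$structures, rx = config$rxGy,
                               targetDeficiency = target)
        dr <- deficiencyRecord(dp$pb, dp$mc, ph$structures,
                               patientId = fr$patient_id)
        fr$placement <- placements[i]
        feats <- rbind(feats, fr)
        defs <- rbind(defs, dr)
    }
    merge(feats, defs, by = "patient_id")
}

.gridCohort <- function(config) {
    man <- read.csv(config$gridManifestPath, stringsAsFactors = FALSE)
    need <- c("patient_id", "ct", "gtv", "itv", "ptv", "lungs", "body",
              "pb", "mc")
    missing <- setdiff(need, names(man))
    if (length(missing))
        stop("grid manifest is missing column(s): ",
             paste(missing, collapse = ", "))
    feats <- NULL; defs <- NULL
    for (i in seq_len(nrow(man))) {
        ct <- readImageGrid(man$ct[i], "HU")
        masks <- lapply(c(GTV = "gtv", ITV = "itv", PTV = "ptv",
                          lungs = "lungs", body = "body"),
            function(cn) readStructureMask(man[[cn]][i], ct))
        ss <- structureSet(masks, ct)
        feats <- rbind(feats, extractFeatures(ct, ss,
            thresholdHu = config$thresholdHu, shellsMm = config$shellsMm,
            patientId = man$patient_id[i]))
        defs <- rbind(defs, deficiencyRecord(
            readImageGrid(man$pb[i], "Gy"), readImageGrid(man$mc[i], "Gy"),
            ss, patientId = man$patient_id[i]))
    }
    merge(feats, defs, by = "patient_id")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full dose-conversion study
#'
#' Orchestrates the whole analysis: build or load the per-patient
#' feature/outcome table, run the single-regression R^2 screen, fit the
#' two published model forms (and a collinearity probe adding the PTV
#' mean density to the two-feature model), grid-search and
#' cross-validate the ANN, and compare it to the linear model with a
#' Mann-Whitney U test on squared LOOCV errors. All artefacts are written
#' to `config$outDir`: `manifest.json` (first), `features.csv`,
#' `screen.csv`, `fits.json`, `ann_grid.csv`, `ann.json`, `summary.txt`.
#' A failing stage halts with an error naming the stage; files already
#' written are kept.
#'
#' @param config a [studyConfig()].
#' @return invisibly, a list with `table`, `screen`, `fits`, `ann`.
#' @export
runStudy <- function(config) {
    stopifnot(inherits(config, "StudyConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- c(config[setdiff(names(config),
                                 c("outDir"))],
                  list(package_version =
                           as.character(packageVersion("sbrtDoseConv"))))
    jsonlite::write_json(manifest,
        file.path(config$outDir, "manifest.json"), auto_unbox = TRUE,
        digits = NA)

    tbl <- .stage("inputs", switch(config$mode,
        phantom = .phantomCohort(config),
        feature_table = readFeatureTable(config$featureTablePath),
        grids = .gridCohort(config)))
    writeFeatureTable(tbl, file.path(config$outDir, "features.csv"))

    screen <- .stage("screen", featureCorrelationScreen(tbl))
    write.csv(screen, file.path(config$outDir, "screen.csv"),
              row.names = FALSE)

    fits <- .stage("fit", {
        y <- tbl$pct_diff_ptv_d95
        out <- list()
        for (id in c("eq1", "eq2")) {
            f <- fitMultiple(.modelDesign(tbl, id), y)
            out[[id]] <- list(coefficients = as.list(f@coefficients),
                r_squared = f@r.squared, adj_r_squared = f@adj.r.squared,
                p_values = as.list(f@p.values),
                significance_factor = f@sig.factor, n = f@n)
        }
        if ("hu_mean_ptv" %in% names(tbl)) {
            X3 <- cbind(.modelDesign(tbl, config$outcomeModel),
                        hu_ptv = tbl$hu_mean_ptv)
            f3 <- fitMultiple(X3, y)
            out$collinear_probe <- list(
                p_values = as.list(f3@p.values),
                significance_factor = f3@sig.factor)
        }
        out
    })
    jsonlite::write_json(fits, file.path(config$outDir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)

    ann <- .stage("ann", {
        X <- tbl[, annFeatureNames()]
        y <- tbl$pct_diff_ptv_d95
        gs <- annGridSearch(X, y, sizes = config$annSizes,
            decays = config$annDecays, seed = config$seed,
            maxit = config$annMaxit)
        cv <- annLoocv(X, y, gs$best, nrep = config$annNrep)
        lin <- loocvLinear(.modelDesign(tbl, config$outcomeModel), y)
        p <- compareToLinear(cv@sqErrors, lin@sqErrors)
        list(grid = gs$table, best = gs$best, cv = cv, linear = lin,
             mw_p_value = p)
    })
    write.csv(ann$grid, file.path(config$outDir, "ann_grid.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(
        best = ann$best,
        ann_rmse = ann$cv@rmse, ann_rmse_sd = ann$cv@rmseSd,
        linear_rmse = ann$linear@rmse,
        mw_p_value = ann$mw_p_value),
        file.path(config$outDir, "ann.json"), auto_unbox = TRUE,
        digits = NA)

    .stage("summary", {
        con <- file(file.path(config$outDir, "summary.txt"), "w")
        on.exit(close(con))
        writeLines(c(
            sprintf("Dose-conversion study (%s mode), n = %d",
                    config$mode, nrow(tbl)),
            sprintf("Median (range) percent PTV D95 deficiency: %.1f (%.1f-%.1f)",
                    median(tbl$pct_diff_ptv_d95),
                    min(tbl$pct_diff_ptv_d95),
                    max(tbl$pct_diff_ptv_d95)),
            "", "Single-regression R^2 screen (decreasing):",
            sprintf("  %-18s R^2 = %.3f (%s)", screen$feature,
                    screen$r_squared, screen$sign),
            "",
            sprintf("eq1 form: R^2 = %.3f, significance factor = %.3g",
                    fits$eq1$r_squared, fits$eq1$significance_factor),
            sprintf("eq2 form: R^2 = %.3f, significance factor = %.3g",
                    fits$eq2$r_squared, fits$eq2$significance_factor),
            "",
            sprintf("ANN (size %d, decay %g): LOOCV normalized RMSE %.3f",
                    ann$best$size, ann$best$decay, ann$cv@rmse),
            sprintf("Linear LOOCV normalized RMSE %.3f", ann$linear@rmse),
            sprintf("Mann-Whitney P (ANN vs linear squared errors): %.3f",
                    ann$mw_p_value)), con)
    })
    invisible(list(table = tbl, screen = screen, fits = fits, ann = ann))
}
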
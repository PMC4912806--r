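test_that("phantom structures nest and respect placement semantics", {
    for (pl in c("island", "chest_wall", "mediastinal")) {
        ph <- cachedPhantom(pl, noiseless = FALSE)
        s <- ph$structures
        gtv <- getMask(s, "GTV"); itv <- getMask(s, "ITV")
        ptv <- getMask(s, "PTV"); body <- getMask(s, "body")
        lungs <- getMask(s, "lungs")
        expect_true(all(itv[gtv]), info = pl)
        expect_true(all(ptv[itv]), info = pl)
        expect_true(all(body[ptv]), info = pl)
        expect_true(all(body[lungs]), info = pl)
    }
    # island tumours are fully surrounded by lung voxels
    ph <- cachedPhantom("island", noiseless = TRUE)
    gtv <- getMask(ph$structures, "GTV")
    ring <- expandMask(gtv, 3, referenceGrid(ph$structures)) & !gtv
    expect_true(all(gridValues(ph$ct)[ring] == -750))
})

test_that("phantom HU fields honour the configured compartments", {
    ph <- cachedPhantom("island", noiseless = TRUE)
    lungs <- getMask(ph$structures, "lungs")
    ptv <- getMask(ph$structures, "PTV")
    expect_equal(mean(gridValues(ph$ct)[lungs & !ptv]), -750)

    # with noise the lung mean stays within the standard error budget
    phn <- generatePhantom(phantomConfig(lungSdHu = 50, seed = 21))
    lungsN <- getMask(phn$structures, "lungs")
    gtvN <- getMask(phn$structures, "GTV")
    expect_lt(abs(mean(gridValues(phn$ct)[lungsN & !gtvN]) + 750), 5)

    expect_true(all(gridValues(ph$ct) >= -1000))
    expect_true(all(gridValues(ph$ct) <= 1500))
})

test_that("phantom generation is seed-deterministic and validates sizing", {
    a <- generatePhantom(phantomConfig(seed = 33))
    b <- generatePhantom(phantomConfig(seed = 33))
    expect_identical(gridValues(a$ct), gridValues(b$ct))
    expect_identical(a$structures@masks, b$structures@masks)
    c2 <- generatePhantom(phantomConfig(seed = 34))
    expect_false(identical(gridValues(a$ct), gridValues(c2$ct)))

    expect_error(generatePhantom(phantomConfig(tumourRadiusMm = 40)),
                 "does not fit")
    expect_error(phantomConfig(lungHu = 100, tissueHu = 30), "lung HU")
})

test_that("dose pairs realise the requested D95 deficiency", {
    ph <- cachedPhantom("island", noiseless = FALSE)
    ptv <- getMask(ph$structures, "PTV")

    dp0 <- generateDosePair(ph$structures, 48, 0)
    expect_identical(gridValues(dp0$pb), gridValues(dp0$mc))

    for (target in c(5, 10, 15, 25)) {
        dp <- if (target == 15) cachedDosePair(15)
              else generateDosePair(ph$structures, 48, target)
        realized <- percentDeficiency(doseAtVolume(dp$pb, ptv, 95),
                                      doseAtVolume(dp$mc, ptv, 95))
        expect_lt(abs(realized - target), 0.25)
        expect_true(all(gridValues(dp$mc) <= gridValues(dp$pb) + 1e-9))
    }

    dp <- cachedDosePair(15)
    dr <- deficiencyRecord(dp$pb, dp$mc, ph$structures)
    expect_lte(dr$pct_diff_ptv_dmax, dr$pct_diff_ptv_d95)

    expect_error(generateDosePair(ph$structures, 48, 95), "infeasible")
    expect_error(generateDosePair(ph$structures, 48, -1),
                 "targetDeficiency")
})

test_that("cohort tables follow the generating model and stated ranges", {
    tb0 <- generateCohortTable(cohortSpec(n = 21, noiseSdPct = 0,
                                          seed = 5))
    mdl <- publishedModel("eq2")
    expect_equal(tb0$pct_diff_ptv_d95,
                 predictPublished(mdl, tb0$v_ptv_cm3,
                                  tb0$hu_mean_shell2mm),
                 tolerance = 1e-12)

    tb <- generateCohortTable(cohortSpec(seed = 7))
    expect_equal(nrow(tb), 21)
    expect_true(all(tb$pct_diff_ptv_d95 >= 0 & tb$pct_diff_ptv_d95 <= 40))
    expect_true(all(tb$v_ptv_cm3 >= 7.2 & tb$v_ptv_cm3 <= 110.2))
    expect_true(all(tb$hu_mean_shell2mm >= -820 &
                    tb$hu_mean_shell2mm <= -350))

    expect_identical(generateCohortTable(cohortSpec(seed = 7)), tb)
    expect_error(cohortSpec(n = 2))
    expect_error(cohortSpec(noiseSdPct = -1))
})

test_that("companion densities are strongly collinear but independent of volume", {
    tb <- generateCohortTable(cohortSpec(n = 200, seed = 13))
    dens <- c("hu_mean_ptv", "hu_mean_margin", "hu_mean_shell15mm",
              "hu_mean_shell50mm", "hu_mean_lung")
    for (cn in dens) {
        r <- cor(tb$hu_mean_shell2mm, tb[[cn]])
        expect_gt(r, 0.75)
        expect_lt(r, 0.99)
    }
    expect_lt(abs(cor(tb$v_ptv_cm3, tb$hu_mean_shell2mm)), 0.2)
})
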
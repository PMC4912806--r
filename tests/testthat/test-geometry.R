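test_that("expansion by a physical margin matches enumeration and analytic volumes", {
    g <- imageGrid(array(0, c(9, 9, 9)), c(1, 1, 1), "HU")
    m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE

    expect_identical(expandMask(m, 0, g), m)
    # integer offsets with x^2 + y^2 + z^2 <= 4
    expect_equal(sum(expandMask(m, 2, g)), 33)
    expect_error(expandMask(array(FALSE, c(9, 9, 9)), 1, g), "empty")

    sph <- sphereFixture(10, pad = 8)
    grown <- expandMask(sph$mask, 6, sph$grid)
    vol <- sum(grown) * 1  # 1 mm^3 voxels
    expect_lt(abs(vol - 4 / 3 * pi * 16^3) / (4 / 3 * pi * 16^3), 0.05)
    expect_true(all(sph$mask[grown == FALSE] == FALSE))  # superset
})

test_that("expansion is monotone in the margin", {
    sph <- sphereFixture(5, pad = 7)
    a <- expandMask(sph$mask, 2, sph$grid)
    b <- expandMask(sph$mask, 4, sph$grid)
    expect_true(all(b[a]))
})

test_that("distance transform agrees with the brute-force oracle, incl. anisotropy", {
    for (seed in 1:4) {
        sp <- list(c(1, 1, 1), c(1, 1, 2.5), c(2, 1.5, 1), c(0.8, 1.2, 2))[[seed]]
        m <- randomMask(c(9, 8, 7), nSeeds = 2, seed = seed)
        if (!any(m)) next
        g <- imageGrid(array(0, c(9, 8, 7)), sp, "HU")
        expect_equal(maskDistance(m, g), bruteDistToMask(m, sp),
                     tolerance = 1e-9)
    }
})

test_that("operators are invariant under axis permutation with permuted spacing", {
    sp <- c(1, 1.5, 2.5)
    m <- randomMask(c(8, 8, 8), nSeeds = 2, seed = 5)
    g <- imageGrid(array(0, c(8, 8, 8)), sp, "HU")
    perm <- c(3, 1, 2)
    mp <- aperm(m, perm)
    gp <- imageGrid(array(0, dim(mp)), sp[perm], "HU")
    expect_equal(aperm(maskDistance(m, g), perm), maskDistance(mp, gp))
    expect_equal(maxDiameter(m, g), maxDiameter(mp, gp))
    expect_equal(volumeCm3(m, g), volumeCm3(mp, gp))
})

test_that("shells have the analytic volume, are clipped to the body and avoid the target", {
    sph <- sphereFixture(15, spacing = c(0.5, 0.5, 0.5), pad = 4)
    body <- array(TRUE, dim(sph$mask))
    sh <- shellMask(sph$mask, 2, body, sph$grid)
    sh_mm3 <- sum(sh) * prod(c(0.5, 0.5, 0.5))
    analytic <- 4 / 3 * pi * (17^3 - 15^3)
    expect_lt(abs(sh_mm3 - analytic) / analytic, 0.10)
    expect_false(any(sh & sph$mask))

    # body boundary cuts the shell
    halfBody <- body
    halfBody[1:ceiling(dim(body)[1] / 2), , ] <- FALSE
    shClip <- shellMask(sph$mask, 2, halfBody, sph$grid)
    expect_lt(sum(shClip), sum(sh))
    expect_error(shellMask(array(FALSE, dim(body)), 2, body, sph$grid),
                 "empty")
})

test_that("nested shells partition the widest shell", {
    sph <- sphereFixture(8, spacing = c(1.5, 1.5, 1.5), pad = 14)
    body <- array(TRUE, dim(sph$mask))
    s2 <- shellMask(sph$mask, 2, body, sph$grid)
    s6 <- shellMask(sph$mask, 6, body, sph$grid)
    s12 <- shellMask(sph$mask, 12, body, sph$grid)
    expect_true(all(s6[s2]))
    expect_true(all(s12[s6]))
    ring1 <- s6 & !s2
    ring2 <- s12 & !s6
    expect_equal(sum(s2) + sum(ring1) + sum(ring2), sum(s12))
    expect_false(any(s2 & ring1) || any(ring1 & ring2))
})

test_that("mask difference obeys the set identities", {
    a <- randomMask(c(7, 7, 7), seed = 2)
    expect_false(any(maskDifference(a, a)))
    expect_identical(maskDifference(a, array(FALSE, dim(a))), a)
    sph <- sphereFixture(6, pad = 9)
    outer_m <- expandMask(sph$mask, 5, sph$grid)
    margin <- maskDifference(outer_m, sph$mask)
    expect_equal(sum(margin), sum(outer_m) - sum(sph$mask))
})

test_that("dmin reports abutment as zero and island distances to voxel accuracy", {
    d <- c(24, 15, 15)
    g <- imageGrid(array(0, d), c(1, 1, 1), "HU")
    gtv <- array(FALSE, d); gtv[3:5, 7:9, 7:9] <- TRUE
    soft <- array(FALSE, d)
    soft[6, 7:9, 7:9] <- TRUE  # face-adjacent to the gtv block
    expect_equal(dminGtv(gtv, soft, g), 0)

    soft2 <- array(FALSE, d); soft2[20, 8, 8] <- TRUE  # 15 voxels away
    expect_equal(dminGtv(gtv, soft2, g), 15)

    # soft tissue overlapping the GTV is excluded, not distance zero
    expect_equal(dminGtv(gtv, soft2 | gtv, g), 15)
    expect_error(dminGtv(gtv, gtv, g), "undefined")
    expect_error(dminGtv(array(FALSE, d), soft, g), "empty")
})

test_that("enlarging the GTV shrinks dmin by at most the margin", {
    d <- c(24, 15, 15)
    g <- imageGrid(array(0, d), c(1, 1, 1), "HU")
    gtv <- array(FALSE, d); gtv[3:5, 7:9, 7:9] <- TRUE
    soft <- array(FALSE, d); soft[20, 8, 8] <- TRUE
    d0 <- dminGtv(gtv, soft, g)
    for (m in c(2, 5)) {
        dm <- dminGtv(expandMask(gtv, m, g), soft, g)
        expect_lte(d0 - dm, m + 1e-9)
        expect_lte(dm, d0)
    }
})

test_that("maximum dimension matches hand values and the brute-force oracle", {
    d <- c(10, 10, 10)
    g <- imageGrid(array(0, d), c(1, 1, 1), "HU")
    one <- array(FALSE, d); one[4, 4, 4] <- TRUE
    expect_equal(maxDiameter(one, g), 0)

    two <- one; two[7, 8, 4] <- TRUE  # offsets (3, 4, 0) -> 5 mm
    expect_equal(maxDiameter(two, g), 5)

    for (seed in 1:3) {
        m <- randomMask(c(8, 9, 7), nSeeds = 2, seed = seed + 10)
        if (sum(m) < 2) next
        sp <- c(1, 2, 1.25)
        gg <- imageGrid(array(0, c(8, 9, 7)), sp, "HU")
        expect_equal(maxDiameter(m, gg), bruteMaxDiameter(m, sp),
                     tolerance = 1e-9)
    }

    sph <- sphereFixture(15, pad = 3)
    expect_lt(abs(maxDiameter(sph$mask, sph$grid) - 30), sqrt(3))
})

test_that("volumes are voxel count times voxel volume", {
    g <- imageGrid(array(0, c(10, 10, 10)), c(1, 1, 1), "HU")
    expect_equal(volumeCm3(array(FALSE, c(10, 10, 10)), g), 0)
    expect_equal(volumeCm3(array(TRUE, c(10, 10, 10)), g), 1)
    sph <- sphereFixture(10, pad = 2)
    expect_lt(abs(volumeCm3(sph$mask, sph$grid) - 4.18879) / 4.18879,
              0.05)
})
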
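# Independent oracles used to cross-check the package's geometry, DVH,
# regression and rank-test code. These are deliberately brute-force and
# never call the implementation paths they verify.

# minimum Euclidean distance (mm) from every voxel centre to the nearest
# in-mask voxel centre, by exhaustive pairwise search
bruteDistToMask <- function(mask, spacing) {
    idx <- which(mask, arr.ind = TRUE)
    pts <- sweep(idx - 1, 2, spacing, `*`)
    out <- array(0, dim(mask))
    all_idx <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
    all_pts <- sweep(all_idx - 1, 2, spacing, `*`)
    for (v in seq_len(nrow(all_pts))) {
        d2 <- (pts[, 1] - all_pts[v, 1])^2 + (pts[, 2] - all_pts[v, 2])^2 +
              (pts[, 3] - all_pts[v, 3])^2
        out[all_idx[v, 1], all_idx[v, 2], all_idx[v, 3]] <- sqrt(min(d2))
    }
    out
}

# maximum pairwise distance by exhaustive search over all in-mask voxels
bruteMaxDiameter <- function(mask, spacing) {
    idx <- which(mask, arr.ind = TRUE)
    pts <- sweep(idx - 1, 2, spacing, `*`)
    best <- 0
    for (i in seq_len(nrow(pts)))
        for (j in seq_len(nrow(pts))) {
            d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
            if (d > best) best <- d
        }
    best
}

# dose-at-volume by sweeping every candidate threshold: the largest dose d
# among the in-mask values such that the covered fraction >= pct/100
dvhSweepOracle <- function(doses, pct) {
    cand <- sort(unique(doses))
    ok <- vapply(cand, function(d) mean(doses >= d) >= pct / 100,
                 logical(1))
    max(cand[ok])
}

# OLS via the normal equations
olsOracle <- function(X, y) {
    A <- cbind(1, as.matrix(X))
    solve(t(A) %*% A, t(A) %*% y)[, 1]
}

# exact two-sided Mann-Whitney P by enumerating all group assignments of
# the pooled sample (small n, distinct values only)
enumMannWhitneyP <- function(a, b) {
    pooled <- c(a, b)
    n <- length(pooled); na <- length(a)
    uStat <- function(x, y) sum(outer(x, y, `>`))
    obs <- uStat(a, b)
    combos <- utils::combn(n, na)
    us <- apply(combos, 2, function(ix) uStat(pooled[ix], pooled[-ix]))
    mu <- na * (n - na) / 2
    mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# digital sphere mask of radius r (mm) centred in a cubic grid
sphereFixture <- function(rMm, spacing = c(1, 1, 1), pad = 3) {
    nv <- ceiling(2 * (rMm + pad) / spacing) + 1
    ctr <- (nv - 1) / 2 * spacing
    co <- list(
        x = array(rep((seq_len(nv[1]) - 1) * spacing[1],
                      times = nv[2] * nv[3]), nv),
        y = array(rep(rep((seq_len(nv[2]) - 1) * spacing[2],
                          each = nv[1]), times = nv[3]), nv),
        z = array(rep((seq_len(nv[3]) - 1) * spacing[3],
                      each = nv[1] * nv[2]), nv))
    mask <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2 <=
        rMm^2
    list(mask = mask,
         grid = imageGrid(array(0, nv), spacing, "HU"))
}

# random small blob mask for property tests
randomMask <- function(shape, nSeeds = 3, seed = 1) {
    set.seed(seed)
    m <- array(FALSE, shape)
    for (s in seq_len(nSeeds)) {
        c0 <- vapply(shape, function(n) sample(seq_len(n), 1), numeric(1))
        idx <- which(array(TRUE, shape), arr.ind = TRUE)
        d2 <- rowSums(sweep(idx, 2, c0, `-`)^2)
        m[idx[d2 <= runif(1, 1, 9), , drop = FALSE]] <- TRUE
    }
    m
}
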
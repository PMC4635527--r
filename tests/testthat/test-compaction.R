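test_that("the nuclear mask recovers simple shapes", {
    ## filled disk
    n <- 100
    xy <- expand.grid(r = 1:n, c = 1:n)
    disk <- matrix(as.numeric((xy$r - 50)^2 + (xy$c - 50)^2 <= 30^2) * 255,
        n, n)
    m <- nuclearMask(disk)
    expect_equal(unname(m), disk > 50, ignore_attr = TRUE)

    ## annulus: the cavity is hole-filled into the mask
    d2 <- (xy$r - 50)^2 + (xy$c - 50)^2
    ann <- matrix(as.numeric(d2 <= 30^2 & d2 >= 20^2) * 255, n, n)
    m2 <- nuclearMask(ann)
    expect_true(all(m2[d2 <= 20^2]))
    expect_equal(sum(m2), sum(d2 <= 30^2))

    expect_error(nuclearMask(matrix(3, 5, 5)), "blank")
})

test_that("internal voids do not reduce the nuclear area", {
    n <- 200
    xy <- expand.grid(r = 1:n, c = 1:n)
    d2 <- (xy$r - 100)^2 + (xy$c - 100)^2
    img <- as.numeric(d2 <= 80^2) * 200
    ## carve ~30% of the nucleus into internal zero-intensity voids
    for (v in list(c(70, 70, 25), c(130, 80, 30), c(100, 140, 28)))
        img[(xy$r - v[1])^2 + (xy$c - v[2])^2 <= v[3]^2] <- 0
    img <- matrix(img, n, n)
    m <- nuclearMask(img)
    expect_equal(sum(m), sum(d2 <= 80^2), tolerance = 0.02)
})

test_that("free-area fractions match the phantom geometry", {
    n <- 200
    xy <- expand.grid(r = 1:n, c = 1:n)
    d2 <- (xy$r - 100)^2 + (xy$c - 100)^2
    solid <- matrix(as.numeric(d2 <= 80^2) * 180, n, n)
    fa <- freeAreaFraction(solid, pixel = 50)
    expect_equal(fa@freeFraction, 0)
    expect_equal(fa@nuclearArea, sum(d2 <= 80^2) * (50 / 1000)^2)

    ## intensity rescaling leaves the result unchanged (stretch-invariant)
    img <- solid
    img[(xy$r - 80)^2 + (xy$c - 90)^2 <= 40^2] <- 0
    f1 <- freeAreaFraction(img, pixel = 50)
    f2 <- freeAreaFraction(img * 17.3, pixel = 50)
    expect_equal(f1@freeFraction, f2@freeFraction)
    expect_gt(f1@freeFraction, 0)
})

test_that("localization density counts records inside the mask", {
    tab <- LocalizationTable(data.frame(frame = 1L,
        x = runif(100, 0, 2000), y = runif(100, 0, 5000),
        photons = 1500, sigma = 130, uncertainty = 10, background = 25))
    ## 2 x 5 um mask of 100 nm pixels = 10 um^2
    mask <- matrix(TRUE, 50, 20)
    expect_equal(localizationDensity(tab, mask, 100), 10)
    ## translation of both table and mask origin leaves density unchanged
    rec <- locData(tab)
    rec$x <- rec$x + 5000
    rec$y <- rec$y + 3000
    expect_equal(localizationDensity(LocalizationTable(rec), mask, 100,
        origin = c(5000, 3000)), 10)
    expect_error(localizationDensity(tab, matrix(FALSE, 5, 5), 100),
        "empty mask")
})

test_that("skewness matches direct moment computation", {
    expect_equal(sampleSkewness(c(1, 2, 3)), 0)
    x <- c(1, 1, 1, 10)
    d <- x - mean(x)
    expect_equal(sampleSkewness(x), mean(d^3) / mean(d^2)^1.5)
    expect_gt(sampleSkewness(x), 0)
    ## antisymmetry
    expect_equal(sampleSkewness(-x), -sampleSkewness(x))
    expect_error(sampleSkewness(c(2, 2, 2)), "variance")
    expect_error(sampleSkewness(c(1, 2)), "3 values")
})

test_that("skewness agrees with the reference implementation", {
    skip_if_not_installed("e1071")
    set.seed(51)
    for (i in 1:5) {
        x <- rpois(200, 8)
        expect_equal(sampleSkewness(x), e1071::skewness(x, type = 1))
    }
})

test_that("bins with fewer than two localizations are discarded", {
    ## a regular lattice, one point per bin: everything discarded
    g <- expand.grid(x = seq(50, 950, by = 100), y = seq(50, 950, by = 100))
    tab <- LocalizationTable(data.frame(frame = 1L, x = g$x, y = g$y,
        photons = 1500, sigma = 130, uncertainty = 10, background = 25))
    expect_error(binHistogram(tab, 100, origin = c(0, 0)), ">= 2")

    ## four points in one bin
    tab4 <- LocalizationTable(data.frame(frame = 1L,
        x = c(10, 20, 30, 40), y = c(10, 20, 30, 40),
        photons = 1500, sigma = 130, uncertainty = 10, background = 25))
    b <- binHistogram(tab4, 100, origin = c(0, 0))
    expect_equal(b@counts, 4L)
    expect_equal(b@median, 4)
    expect_equal(b@skewness, 0)
})

test_that("binned counts match a brute-force binning oracle", {
    tab <- clusteredTable(2000, c(2000, 2000), nClusters = 12,
        clusterSigma = 40, seed = 52)
    rec <- locData(tab)
    for (bin in c(60, 150)) {
        b <- binHistogram(tab, bin, origin = c(0, 0))
        ## independent O(n * bins) counting
        nx <- ceiling(2000 / bin)
        cnt <- matrix(0L, nx, nx)
        for (i in seq_len(nrow(rec))) {
            ix <- floor(rec$x[i] / bin) + 1
            iy <- floor(rec$y[i] / bin) + 1
            cnt[ix, iy] <- cnt[ix, iy] + 1L
        }
        keep <- sort(cnt[cnt >= 2])
        expect_equal(sort(b@counts), keep)
        expect_lte(sum(b@counts), nrow(rec))
    }
})

test_that("binning is invariant to whole-bin grid translation", {
    tab <- clusteredTable(1500, c(2000, 2000), seed = 53)
    rec <- locData(tab)
    shifted <- LocalizationTable(transform(rec, x = x + 3 * 80, y = y + 80))
    a <- binHistogram(tab, 80, origin = c(0, 0))
    b <- binHistogram(shifted, 80, origin = c(0, 0))
    expect_equal(sort(a@counts), sort(b@counts))
})

test_that("clustered patterns are more skewed than uniform ones", {
    n <- 4000
    uni <- uniformTable(n, c(2000, 2000), seed = 54)
    clu <- clusteredTable(n, c(2000, 2000), nClusters = 30,
        clusterSigma = 30, seed = 54)
    for (bin in c(40, 60, 100)) {
        su <- binHistogram(uni, bin, origin = c(0, 0))@skewness
        sc <- binHistogram(clu, bin, origin = c(0, 0))@skewness
        expect_gt(sc, su)
    }
})

test_that("Poisson bin counts at high mean are nearly symmetric", {
    ## homogeneous pattern, mean >= 25 per bin: g1 stays small
    tab <- uniformTable(10000, c(2000, 2000), seed = 55)
    b <- binHistogram(tab, 100, origin = c(0, 0))   # mean 25/bin
    expect_gte(mean(b@counts), 25 * 0.9)
    expect_lt(b@skewness, 0.5)
})

test_that("k-NN mean distances equal the brute-force oracle exactly", {
    set.seed(56)
    n <- 200
    xy <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
    tab <- LocalizationTable(data.frame(frame = 1L, x = xy[, 1],
        y = xy[, 2], photons = 1500, sigma = 130, uncertainty = 10,
        background = 25))
    roi <- data.frame(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000)
    for (k in c(1, 5, 50)) {
        r <- nnMeanDistances(tab, roi, k = k)
        oracle <- unname(bruteKnnMean(xy, k))
        expect_equal(sort(r@meanDistances), sort(oracle), tolerance = 1e-12)
    }
})

test_that("two points 50 nm apart have k=1 mean distance 50", {
    tab <- LocalizationTable(data.frame(frame = 1L, x = c(100, 150),
        y = 100, photons = 1500, sigma = 130, uncertainty = 10,
        background = 25))
    roi <- data.frame(xmin = 0, xmax = 300, ymin = 0, ymax = 300)
    r <- nnMeanDistances(tab, roi, k = 1)
    expect_equal(r@meanDistances, c(50, 50))
})

test_that("k-NN medians are non-decreasing in k", {
    tab <- clusteredTable(700, c(2000, 2000), seed = 57)
    roi <- data.frame(xmin = 0, xmax = 2000, ymin = 0, ymax = 2000)
    ks <- c(1, 5, 50, 100, 500)
    meds <- vapply(ks, function(k)
        nnMeanDistances(tab, roi, k = k)@median, numeric(1))
    expect_true(all(diff(meds) >= 0))
})

test_that("an ROI with too few points is reported by name", {
    tab <- uniformTable(50, c(1000, 1000), seed = 58)
    rois <- data.frame(xmin = c(0, 2000), xmax = c(1000, 2100),
        ymin = 0, ymax = 1000)
    expect_error(nnMeanDistances(tab, rois, k = 5), "ROI 2")
})

test_that("the far-proportion marker uses the 100-NN 80 nm rule", {
    ## dense uniform cloud: 100-NN distances well below 80 nm
    set.seed(59)
    n <- 2500
    tab <- LocalizationTable(data.frame(frame = 1L,
        x = runif(n, 0, 500), y = runif(n, 0, 500),
        photons = 1500, sigma = 130, uncertainty = 10, background = 25))
    roi <- data.frame(xmin = 0, xmax = 500, ymin = 0, ymax = 500)
    r <- nnMeanDistances(tab, roi, k = 10)
    ## interior points are all near; only ROI-corner edge effects may exceed
    expect_lt(r@propFar, 0.01)
    ## sparse cloud: everything is far
    tab2 <- LocalizationTable(data.frame(frame = 1L,
        x = runif(150, 0, 5000), y = runif(150, 0, 5000),
        photons = 1500, sigma = 130, uncertainty = 10, background = 25))
    roi2 <- data.frame(xmin = 0, xmax = 5000, ymin = 0, ymax = 5000)
    r2 <- nnMeanDistances(tab2, roi2, k = 10)
    expect_equal(r2@propFar, 1)
})
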
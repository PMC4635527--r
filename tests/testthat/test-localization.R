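test_that("initial background averages the first eight frames", {
    frames <- array(7, c(4, 4, 10))
    st <- new("FrameStack", frames = frames, pixelSize = 102, gain = 2)
    bg <- initialBackground(st)
    expect_equal(bg$background, matrix(7, 4, 4))
    expect_equal(bg$std, matrix(sqrt(7), 4, 4))

    frames[2, 3, 1:8] <- 0:7
    st <- new("FrameStack", frames = frames, pixelSize = 102, gain = 2)
    expect_equal(initialBackground(st)$background[2, 3], 3.5)

    short <- new("FrameStack", frames = array(1, c(4, 4, 7)),
        pixelSize = 102, gain = 2)
    expect_error(initialBackground(short), "8 frames")
})

test_that("initial background tracks a Poisson mean to its standard error", {
    set.seed(11)
    frames <- array(rpois(16 * 16 * 8, 100), c(16, 16, 8))
    st <- new("FrameStack", frames = frames, pixelSize = 102, gain = 2)
    bg <- initialBackground(st)
    expect_true(all(abs(bg$background - 100) < 3 * sqrt(100 / 8) + 1e-9))
})

test_that("difference images are signed and centred", {
    bg <- flatBackground(100, 8, 8)
    frame <- matrix(100, 8, 8)
    expect_equal(differenceImage(frame, bg), matrix(0, 8, 8))
    frame[3, 5] <- 110
    d <- differenceImage(frame, bg)
    expect_equal(d[3, 5], 10)
    set.seed(12)
    pois <- matrix(rpois(64 * 64, 150), 64, 64)
    d2 <- differenceImage(pois, flatBackground(150, 64, 64))
    expect_lt(abs(mean(d2)), 3 * sqrt(150) / 64)
})

test_that("candidate detection thresholds the smoothed image at (TF-1)*STD", {
    bg <- flatBackground(150, 32, 32)
    expect_equal(nrow(detectCandidates(matrix(0, 32, 32), bg)), 0)

    ## one bright spot: exhaustive-scan oracle over all interior pixels
    spot <- gaussianSpotImage(1632.5, 1428.3, 4000, nx = 32, ny = 32) / 2
    cand <- detectCandidates(spot, bg, DetectionConfig(thresholdFactor = 3))
    sm <- smlmChromatin:::.meanFilter3(spot)
    oracle <- NULL
    for (r in 2:31) for (cc in 2:31) {
        nb <- sm[(r - 1):(r + 1), (cc - 1):(cc + 1)]
        if (sm[r, cc] == max(nb) && sm[r, cc] >= 2 * sqrt(150))
            oracle <- rbind(oracle, c(r, cc))
    }
    expect_equal(nrow(cand), 1)
    expect_equal(unname(cand[1, ]), unname(oracle[1, ]))
})

test_that("dim signals below the detection threshold produce no candidates", {
    bg <- flatBackground(150, 32, 32)
    dim <- gaussianSpotImage(1632.5, 1428.3, 150, nx = 32, ny = 32) / 2
    expect_equal(nrow(detectCandidates(dim, bg)), 0)
})

test_that("refinement recovers spot centres to subpixel accuracy", {
    cfg <- DetectionConfig()
    bg <- flatBackground(150, 32, 32)
    p <- 102
    ## spot exactly at a pixel centre: pixel (15, 15) 0-based
    xc <- 15.5 * p
    spot <- gaussianSpotImage(xc, xc, 3000, p = p, nx = 32, ny = 32) / 2
    res <- refineCandidate(spot, c(16L, 16L), cfg, 2, 130, p, bg)
    expect_equal(res$reason, "ok")
    expect_lt(abs(res$loc$x - xc), 1e-6)
    expect_lt(abs(res$loc$y - xc), 1e-6)

    ## off-centre subpixel position vs a brute-force 21x21 centroid oracle
    x0 <- 15.73 * p
    y0 <- 15.21 * p
    spot <- gaussianSpotImage(x0, y0, 3000, p = p, nx = 32, ny = 32) / 2
    res <- refineCandidate(spot, c(16L, 16L), cfg, 2, 130, p, bg)
    rows <- 6:26
    w <- spot[rows, rows]
    bx <- sum(colSums(w) * (rows - 0.5)) / sum(w) * p
    by <- sum(rowSums(w) * (rows - 0.5)) / sum(w) * p
    expect_lt(abs(res$loc$x - bx), 0.05 * p)
    expect_lt(abs(res$loc$y - by), 0.05 * p)
    ## photons recovered through the gain
    expect_equal(res$loc$photons, 3000, tolerance = 0.05)
})

test_that("overlapping signals clipped beyond 30% are discarded", {
    cfg <- DetectionConfig()
    bg <- flatBackground(150, 32, 32)
    p <- 102
    main <- gaussianSpotImage(16.5 * p, 16.5 * p, 2000, p = p,
        nx = 32, ny = 32)
    ## a much brighter neighbour three pixels away, inside the 7x7 ROI
    nbr <- gaussianSpotImage(19.5 * p, 16.5 * p, 30000, p = p,
        nx = 32, ny = 32)
    res <- refineCandidate((main + nbr) / 2, c(17L, 17L), cfg, 2, 130, p, bg)
    expect_null(res$loc)
    expect_equal(res$reason, "clip_loss")
})

test_that("candidates too close to the border are rejected", {
    bg <- flatBackground(150, 32, 32)
    d <- matrix(0, 32, 32)
    res <- refineCandidate(d, c(2L, 16L), DetectionConfig(), 2, 130, 102, bg)
    expect_equal(res$reason, "border")
})

test_that("the precision equation obeys its closed-form limits", {
    ## b = 0, p -> 0: sigma = s/sqrt(N)
    expect_equal(estimatePrecision(100, 100, 1e-9, 0), 10, tolerance = 1e-9)
    ## quadrupling N halves sigma when b = 0
    s1 <- estimatePrecision(500, 130, 102, 0)
    s2 <- estimatePrecision(2000, 130, 102, 0)
    expect_equal(s1 / s2, 2, tolerance = 1e-12)
    expect_error(estimatePrecision(0, 130, 102, 10), "positive")
})

test_that("the precision fixture matches the independent arithmetic oracle", {
    ## frozen from term-by-term evaluation at 50-digit precision:
    ## (130^2 + 102^2/12)/1500 = 11.844666...; 8*pi*130^4*300/(102^2*1500^2)
    ## = 91.992339...; sqrt of the sum:
    expect_equal(estimatePrecision(1500, 130, 102, sqrt(300)),
        10.190044445287146, tolerance = 1e-6)
})

test_that("precision is monotone decreasing in N and increasing in b", {
    Ns <- c(200, 500, 1000, 2000, 5000)
    bs <- c(0, 5, 10, 20, 40)
    for (b in bs)
        expect_true(all(diff(estimatePrecision(Ns, 130, 102, b)) < 0))
    for (N in Ns)
        expect_true(all(diff(estimatePrecision(N, 130, 102, bs)) > 0))
})

test_that("background updates follow the clipped 1/8 rule", {
    bg <- flatBackground(100, 8, 8)
    same <- updateBackground(bg, matrix(0, 8, 8))
    expect_equal(same$background, bg$background)

    spike <- matrix(0, 8, 8)
    spike[4, 4] <- 1000          # way above STD = 10
    up <- updateBackground(bg, spike)
    expect_equal(up$background[4, 4], 100 + 10 / 8)
    expect_equal(up$background[1, 1], 100)
    expect_equal(up$std, sqrt(up$background))
})

test_that("the running background converges to the true Poisson mean", {
    set.seed(13)
    mu <- 180
    frames <- array(rpois(12 * 12 * 208, mu), c(12, 12, 208))
    st <- new("FrameStack", frames = frames, pixelSize = 102, gain = 2)
    bg <- initialBackground(st)
    for (f in 9:208)
        bg <- updateBackground(bg, differenceImage(frames[, , f], bg))
    expect_lt(mean(abs(bg$background - mu)) / mu, 0.05)
})

test_that("consecutive-frame joining merges chains and conserves photons", {
    cfg <- DetectionConfig()
    empty <- LocalizationTable(data.frame(frame = integer(), x = numeric(),
        y = numeric(), photons = numeric(), sigma = numeric(),
        uncertainty = numeric(), background = numeric()))
    expect_equal(nLocalizations(joinConsecutive(empty, cfg)), 0)

    mk <- function(sep) LocalizationTable(data.frame(
        frame = c(1L, 2L), x = c(1000, 1000 + sep), y = 1000,
        photons = c(800, 1200), sigma = 130, uncertainty = 10,
        background = 25), metadata = list(pixelSize = 102, psfSigma = 130))
    radius <- 2.5 * 10
    merged <- joinConsecutive(mk(0.1 * radius), cfg)
    expect_equal(nLocalizations(merged), 1)
    expect_equal(locData(merged)$photons, 2000)
    ## photon-weighted mean position
    expect_equal(locData(merged)$x,
        (800 * 1000 + 1200 * (1000 + 0.1 * radius)) / 2000)
    ## precision recomputed from the summed photons
    expect_equal(locData(merged)$uncertainty,
        estimatePrecision(2000, 130, 102, 25))

    apart <- joinConsecutive(mk(3 * radius), cfg)
    expect_equal(nLocalizations(apart), 2)
    expect_equal(sum(locData(apart)$photons), 2000)
})

test_that("joining never increases record or photon counts", {
    for (seed in 1:3) {
        tab <- uniformTable(300, c(2000, 2000), seed = seed)
        joined <- joinConsecutive(tab, DetectionConfig())
        expect_lte(nLocalizations(joined), nLocalizations(tab))
        expect_lte(sum(locData(joined)$photons),
            sum(locData(tab)$photons) + 1e-9)
    }
})

test_that("a background-only stack yields essentially no false positives", {
    set.seed(14)
    ## 64 x 64 x 250 = 1.024e6 pixel-frames at TF = 3
    acq <- AcquisitionConfig(nFrames = 250, fieldPixels = c(64, 64),
        backgroundCounts = 150, gain = 2)
    st <- simulateStack(new("EmitterSet"), acq, seed = 15)
    tab <- localizeStack(st, DetectionConfig(thresholdFactor = 3))
    expect_lte(nLocalizations(tab), 1)
})

test_that("localization is deterministic", {
    acq <- AcquisitionConfig(nFrames = 40, fieldPixels = c(24, 24),
        blinkProb = 5e-3)
    em <- sampleEmitters(buildPhantom(c(2448, 2448)), 300, seed = 16)
    em <- makeBlinkSchedule(em, acq, seed = 17)
    st <- simulateStack(em, acq, seed = 18)
    a <- localizeStack(st)
    b <- localizeStack(st)
    expect_identical(locData(a), locData(b))
})

test_that("bright isolated bursts are recovered near their true positions", {
    ## parameter-recovery property at reduced scale: >= 90% of isolated
    ## >= 1000-photon bursts within 3 sigma_loc, median photon error <= 15%
    acq <- AcquisitionConfig(nFrames = 400, fieldPixels = c(48, 48),
        blinkProb = 1e-3, backgroundCounts = 150, gain = 2)
    em <- sampleEmitters(buildPhantom(c(4896, 4896)), 2000, seed = 19)
    em <- makeBlinkSchedule(em, acq, seed = 20)
    st <- simulateStack(em, acq, seed = 21)
    tab <- localizeStack(st, join = FALSE)
    gt <- groundTruth(st)
    rec <- locData(tab)

    p <- 102
    border <- 4 * p
    iso <- logical(nrow(gt))
    for (i in seq_len(nrow(gt))) {
        same <- which(abs(gt$frame - gt$frame[i]) <= 1)
        dmin <- suppressWarnings(min(sqrt((gt$x_nm[same] - gt$x_nm[i])^2 +
            (gt$y_nm[same] - gt$y_nm[i])^2)[-match(i, same)]))
        iso[i] <- (is.infinite(dmin) || dmin > 10 * p) &&
            gt$x_nm[i] > border & gt$x_nm[i] < 4896 - border &
            gt$y_nm[i] > border & gt$y_nm[i] < 4896 - border &
            gt$photons[i] >= 1000
    }
    gtIso <- gt[iso, ]
    expect_gt(nrow(gtIso), 50)
    hit <- logical(nrow(gtIso))
    perr <- rep(NA_real_, nrow(gtIso))
    for (i in seq_len(nrow(gtIso))) {
        inFrame <- rec[rec$frame == gtIso$frame[i], ]
        if (!nrow(inFrame)) next
        d <- sqrt((inFrame$x - gtIso$x_nm[i])^2 +
                  (inFrame$y - gtIso$y_nm[i])^2)
        j <- which.min(d)
        if (d[j] <= 3 * inFrame$uncertainty[j]) {
            hit[i] <- TRUE
            perr[i] <- inFrame$photons[j] / gtIso$photons[i]
        }
    }
    expect_gte(mean(hit), 0.9)
    expect_lt(abs(median(perr, na.rm = TRUE) - 1), 0.15)
})
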
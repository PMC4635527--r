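# dense clustered table, the regime in which subset correlation is reliable
driftTable <- function(n = 60000, nFrames = 3000, nClusters = 150,
        clusterSigma = 40, field = 5000, seed = 5,
        rate = c(0, 0), frameInterval = 0.05) {
    set.seed(seed)
    frame <- sample.int(nFrames, n, replace = TRUE)
    cx <- runif(nClusters, 500, field - 500)
    cy <- runif(nClusters, 500, field - 500)
    i <- sample.int(nClusters, n, replace = TRUE)
    tH <- (frame - 1) * frameInterval / 3600
    LocalizationTable(data.frame(
        frame = frame,
        x = cx[i] + rnorm(n, 0, clusterSigma) + rate[1] * tH,
        y = cy[i] + rnorm(n, 0, clusterSigma) + rate[2] * tH,
        photons = 1500, sigma = 130, uncertainty = 10, background = 25),
        metadata = list(pixelSize = 102, psfSigma = 130))
}

test_that("zero injected drift yields subset shifts near zero", {
    tab <- driftTable(seed = 21)
    tr <- estimateDrift(tab, nSubsets = 8, renderPixel = 20,
        .residual = FALSE)
    expect_true(all(abs(tr@subsetShifts$dx) <= 10))
    expect_true(all(abs(tr@subsetShifts$dy) <= 10))
})

test_that("a constructed 40 nm offset between two blocks is recovered", {
    set.seed(22)
    n <- 30000
    cx <- runif(120, 500, 4500)
    cy <- runif(120, 500, 4500)
    i <- sample.int(120, n, replace = TRUE)
    x <- cx[i] + rnorm(n, 0, 40)
    y <- cy[i] + rnorm(n, 0, 40)
    half <- seq_len(n) <= n / 2
    tab <- LocalizationTable(data.frame(
        frame = ifelse(half, 1L, 2L),
        x = x + ifelse(half, 0, 40), y = y,
        photons = 1500, sigma = 130, uncertainty = 10, background = 25))
    tr <- estimateDrift(tab, nSubsets = 2, renderPixel = 20,
        minPerSubset = 100, .residual = FALSE)
    expect_equal(tr@subsetShifts$dx[2], 40, tolerance = 20 / 4 / 40)
    expect_lt(abs(tr@subsetShifts$dy[2]), 20 / 4)
})

test_that("injected linear drift is recovered and corrected", {
    ## 150 nm/h over a one-hour acquisition (3600 frames x 1 s)
    tab <- driftTable(nFrames = 3600, rate = c(150, 0), frameInterval = 1,
        seed = 23)
    tr <- estimateDrift(tab, nSubsets = 10, renderPixel = 20)
    tH <- (tr@frames - 1) / 3600
    fit <- coef(lm(tr@dx ~ tH))[2]
    expect_equal(unname(fit), 150, tolerance = 0.1)
    expect_lte(tr@residualStd, 10)

    corrected <- applyDrift(tab, tr)
    expect_equal(nLocalizations(corrected), nLocalizations(tab))
    expect_equal(locData(corrected)$photons, locData(tab)$photons)
    ## residual trajectory after a second pass is small
    tr2 <- estimateDrift(corrected, nSubsets = 10, renderPixel = 20,
        .residual = FALSE)
    expect_lt(max(abs(tr2@subsetShifts$dx)), 10)
})

test_that("drift application is exactly invertible", {
    tab <- uniformTable(500, c(3000, 3000), seed = 24)
    frames <- sort(unique(locData(tab)$frame))
    allFrames <- seq.int(min(frames), max(frames))
    tr <- new("DriftTrajectory", frames = as.integer(allFrames),
        dx = c(0, cumsum(rep(0.5, length(allFrames) - 1))),
        dy = c(0, cumsum(rep(-0.2, length(allFrames) - 1))),
        subsetShifts = data.frame(), residualStd = NA_real_)
    zero <- new("DriftTrajectory", frames = as.integer(allFrames),
        dx = numeric(length(allFrames)), dy = numeric(length(allFrames)),
        subsetShifts = data.frame(), residualStd = NA_real_)
    expect_equal(locData(applyDrift(tab, zero)), locData(tab))

    neg <- tr
    neg@dx <- -tr@dx
    neg@dy <- -tr@dy
    roundTrip <- applyDrift(applyDrift(tab, tr), neg)
    expect_equal(locData(roundTrip)$x, locData(tab)$x, tolerance = 1e-12)
    expect_equal(locData(roundTrip)$y, locData(tab)$y, tolerance = 1e-12)
})

test_that("too-sparse subsets raise an actionable error", {
    tab <- uniformTable(300, c(3000, 3000), seed = 25)
    expect_error(estimateDrift(tab, nSubsets = 50), "fewer subsets")
})
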
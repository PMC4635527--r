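# shared fixture builders; everything is generated in code at test time

# uniform localization table over a rectangular field
uniformTable <- function(n, field = c(4000, 4000), seed = 1,
        uncertainty = 10) {
    set.seed(seed)
    LocalizationTable(data.frame(
        frame = sort(sample.int(max(2L, n %/% 5), n, replace = TRUE)),
        x = runif(n, 0, field[1]), y = runif(n, 0, field[2]),
        photons = 100 + rexp(n, 1 / 1400), sigma = 130,
        uncertainty = uncertainty, background = 25),
        metadata = list(pixelSize = 102, psfSigma = 130))
}

# Gaussian-cluster table with the same total count as a uniform one
clusteredTable <- function(n, field = c(4000, 4000), nClusters = 40,
        clusterSigma = 50, seed = 1, uncertainty = 10) {
    set.seed(seed)
    cx <- runif(nClusters, 0.1 * field[1], 0.9 * field[1])
    cy <- runif(nClusters, 0.1 * field[2], 0.9 * field[2])
    i <- sample.int(nClusters, n, replace = TRUE)
    LocalizationTable(data.frame(
        frame = sort(sample.int(max(2L, n %/% 5), n, replace = TRUE)),
        x = pmin(pmax(cx[i] + rnorm(n, 0, clusterSigma), 0), field[1]),
        y = pmin(pmax(cy[i] + rnorm(n, 0, clusterSigma), 0), field[2]),
        photons = 100 + rexp(n, 1 / 1400), sigma = 130,
        uncertainty = uncertainty, background = 25),
        metadata = list(pixelSize = 102, psfSigma = 130))
}

# a single integrated-Gaussian spot (photon image) on an ny x nx frame;
# x, y in nm with the package's half-open pixel convention
gaussianSpotImage <- function(x, y, photons, s = 130, p = 102, nx = 32,
        ny = 32) {
    jx <- 0:(nx - 1)
    jy <- 0:(ny - 1)
    fx <- pnorm((jx + 1) * p, x, s) - pnorm(jx * p, x, s)
    fy <- pnorm((jy + 1) * p, y, s) - pnorm(jy * p, y, s)
    photons * outer(fy, fx)
}

# background state with flat background (counts)
flatBackground <- function(level, nx = 32, ny = 32) {
    bg <- matrix(level, ny, nx)
    list(background = bg, std = sqrt(bg))
}

# brute-force mean k-NN distances, the independent O(n^2) oracle
bruteKnnMean <- function(xy, k) {
    n <- nrow(xy)
    d <- as.matrix(dist(xy))
    diag(d) <- Inf
    apply(d, 1, function(row) mean(sort(row)[seq_len(k)]))
}
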
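#' Build a ground-truth chromatin phantom
#'
#' Constructs an analytic emitter-density model of a nuclear field containing
#' annular DNA-dense atolls, circular chromatin-free voids and a uniform
#' diffuse floor.  The density integrates to 1 over the field: a fraction
#' \code{1 - diffuseWeight} of emitters falls uniformly inside the atoll
#' rings and the rest uniformly over the remaining non-void area (atoll
#' cavities count as diffuse area, voids carry zero density).
#'
#' Atoll outer dimensions of 40-700 nm with ~120 nm ring thickness match the
#' hollow chromatin structures seen in compacted nuclei; values outside that
#' range trigger a warning but are accepted.
#'
#' @param fieldSize numeric length-2 field extent (x, y), nm.
#' @param atolls data.frame with columns \code{x, y, outer, thickness} (nm);
#'   default ring thickness 120 nm is filled in when the column is absent.
#' @param voids data.frame with columns \code{x, y, diameter} (nm).
#' @param diffuseWeight fraction of emitters on the diffuse floor.
#' @param densityContrast alternative to \code{diffuseWeight}: the desired
#'   ratio of in-ring to diffuse emitter density; the weight split is then
#'   derived from the ring and diffuse areas.
#' @param nucleusDiameter optional diameter (nm) of a nuclear disk centred
#'   in the field; density is zero outside it, so reconstructions show a
#'   real nuclear boundary.  \code{NA} (default) treats the whole field as
#'   nuclear interior.
#' @return a \linkS4class{ChromatinPhantom}.
#' @examples
#' ph <- buildPhantom(c(5000, 5000),
#'     atolls = data.frame(x = 2500, y = 2500, outer = 500),
#'     voids = data.frame(x = 1000, y = 1000, diameter = 600),
#'     diffuseWeight = 0.2)
#' ph
#' @export
buildPhantom <- function(fieldSize, atolls = NULL, voids = NULL,
        diffuseWeight = 0.2, densityContrast = NULL,
        nucleusDiameter = NA_real_) {
    ckInside <- function(x, y, r) {
        ok <- x - r >= 0 & x + r <= fieldSize[1] &
            y - r >= 0 & y + r <= fieldSize[2]
        if (is.finite(nucleusDiameter))
            ok <- ok & sqrt((x - fieldSize[1] / 2)^2 +
                (y - fieldSize[2] / 2)^2) + r <= nucleusDiameter / 2
        ok
    }
    empty_a <- data.frame(x = numeric(), y = numeric(), outer = numeric(),
        thickness = numeric())
    empty_v <- data.frame(x = numeric(), y = numeric(), diameter = numeric())
    if (is.null(atolls) || !nrow(atolls)) {
        atolls <- empty_a
    } else {
        atolls <- as.data.frame(atolls)
        if (is.null(atolls$thickness)) atolls$thickness <- 120
        stopifnot(all(c("x", "y", "outer") %in% names(atolls)))
        bad <- which(!ckInside(atolls$x, atolls$y, atolls$outer / 2))
        if (length(bad))
            stop("atoll ", bad[1], " at (", atolls$x[bad[1]], ", ",
                atolls$y[bad[1]], ") nm extends outside the field")
        if (any(atolls$outer < 40 | atolls$outer > 700))
            warning("atoll outer dimension outside the typical 40-700 nm range")
    }
    if (is.null(voids) || !nrow(voids)) {
        voids <- empty_v
    } else {
        voids <- as.data.frame(voids)
        stopifnot(all(c("x", "y", "diameter") %in% names(voids)))
        bad <- which(!ckInside(voids$x, voids$y, voids$diameter / 2))
        if (length(bad))
            stop("void ", bad[1], " at (", voids$x[bad[1]], ", ",
                voids$y[bad[1]], ") nm extends outside the field")
    }
    if (!nrow(atolls)) diffuseWeight <- 1

    ringArea <- if (nrow(atolls)) {
        ro <- atolls$outer / 2
        ri <- ro - atolls$thickness
        sum(pi * (ro^2 - ri^2))
    } else 0
    voidArea <- if (nrow(voids)) sum(pi * (voids$diameter / 2)^2) else 0
    interior <- if (is.finite(nucleusDiameter))
        pi * (nucleusDiameter / 2)^2 else prod(fieldSize)
    diffuseArea <- interior - ringArea - voidArea
    if (!is.null(densityContrast) && ringArea > 0) {
        stopifnot(densityContrast > 0)
        diffuseWeight <- 1 / (1 + densityContrast * ringArea / diffuseArea)
    }
    contrast <- if (ringArea > 0 && diffuseWeight > 0) {
        ((1 - diffuseWeight) / ringArea) / (diffuseWeight / diffuseArea)
    } else if (ringArea > 0) Inf else 1

    new("ChromatinPhantom", fieldSize = as.numeric(fieldSize),
        nucleusDiameter = nucleusDiameter,
        atolls = atolls, voids = voids,
        diffuseWeight = diffuseWeight, densityContrast = contrast)
}

## membership tests, vectorized over points
.inAtollRing <- function(phantom, x, y) {
    a <- phantom@atolls
    inside <- logical(length(x))
    for (i in seq_len(nrow(a))) {
        d2 <- (x - a$x[i])^2 + (y - a$y[i])^2
        ro <- a$outer[i] / 2
        ri <- ro - a$thickness[i]
        inside <- inside | (d2 <= ro^2 & d2 >= ri^2)
    }
    inside
}

.inNucleus <- function(phantom, x, y) {
    nd <- phantom@nucleusDiameter
    if (!is.finite(nd))
        return(x >= 0 & x <= phantom@fieldSize[1] &
               y >= 0 & y <= phantom@fieldSize[2])
    (x - phantom@fieldSize[1] / 2)^2 + (y - phantom@fieldSize[2] / 2)^2 <=
        (nd / 2)^2
}

.inVoid <- function(phantom, x, y) {
    v <- phantom@voids
    inside <- logical(length(x))
    for (i in seq_len(nrow(v))) {
        d2 <- (x - v$x[i])^2 + (y - v$y[i])^2
        inside <- inside | (d2 <= (v$diameter[i] / 2)^2)
    }
    inside
}

#' Evaluate the phantom emitter density
#'
#' Returns the (normalized) emitter density at given sample-plane points, in
#' emitters per nm^2 per unit total mass.
#'
#' @param phantom a \linkS4class{ChromatinPhantom}.
#' @param x,y coordinates, nm.
#' @return numeric density values.
#' @export
phantomDensity <- function(phantom, x, y) {
    a <- phantom@atolls
    ringArea <- if (nrow(a)) {
        ro <- a$outer / 2
        sum(pi * (ro^2 - (ro - a$thickness)^2))
    } else 0
    voidArea <- if (nrow(phantom@voids))
        sum(pi * (phantom@voids$diameter / 2)^2) else 0
    interior <- if (is.finite(phantom@nucleusDiameter))
        pi * (phantom@nucleusDiameter / 2)^2 else prod(phantom@fieldSize)
    diffuseArea <- interior - ringArea - voidArea
    dDiff <- phantom@diffuseWeight / diffuseArea
    dRing <- if (ringArea > 0) (1 - phantom@diffuseWeight) / ringArea else 0
    out <- rep(dDiff, length(x))
    inRing <- .inAtollRing(phantom, x, y)
    out[inRing] <- dRing
    out[.inVoid(phantom, x, y)] <- 0
    out[!.inNucleus(phantom, x, y)] <- 0
    out[x < 0 | x > phantom@fieldSize[1] | y < 0 |
        y > phantom@fieldSize[2]] <- 0
    out
}

#' Sample emitter positions from a phantom
#'
#' Draws n positions from the phantom density: a binomial split between the
#' structured (atoll-ring) and diffuse components, uniform sampling within
#' each (annulus points by exact inverse-CDF in radius; diffuse points by
#' rejection against the ring and void masks).
#'
#' @param phantom a \linkS4class{ChromatinPhantom}.
#' @param n number of emitters.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param maxTries rejection-sampling iteration cap per batch.
#' @return an \linkS4class{EmitterSet} with positions but no blink schedule
#'   (see \code{\link{makeBlinkSchedule}}).
#' @export
sampleEmitters <- function(phantom, n, seed = NULL, maxTries = 1000L) {
    if (!is.null(seed)) set.seed(seed)
    if (n == 0)
        return(new("EmitterSet"))
    stopifnot(n > 0)
    a <- phantom@atolls
    nStruct <- if (nrow(a)) stats::rbinom(1, n, 1 - phantom@diffuseWeight)
        else 0L
    nDiff <- n - nStruct

    pts <- matrix(NA_real_, n, 2)
    colnames(pts) <- c("x", "y")
    if (nStruct > 0) {
        ro <- a$outer / 2
        ri <- ro - a$thickness
        ringArea <- pi * (ro^2 - ri^2)
        which_ring <- sample.int(nrow(a), nStruct, replace = TRUE,
            prob = ringArea)
        got <- 0L
        tries <- 0L
        while (got < nStruct) {
            tries <- tries + 1L
            if (tries > maxTries)
                stop("rejection sampling exceeded the iteration cap (",
                    maxTries, ")")
            need <- which(is.na(pts[seq_len(nStruct), 1]))
            j <- which_ring[need]
            u <- stats::runif(length(need))
            r <- sqrt(ri[j]^2 + u * (ro[j]^2 - ri[j]^2))
            th <- stats::runif(length(need), 0, 2 * pi)
            px <- a$x[j] + r * cos(th)
            py <- a$y[j] + r * sin(th)
            ok <- !.inVoid(phantom, px, py) &
                px >= 0 & px <= phantom@fieldSize[1] &
                py >= 0 & py <= phantom@fieldSize[2]
            pts[need[ok], 1] <- px[ok]
            pts[need[ok], 2] <- py[ok]
            got <- nStruct - sum(is.na(pts[seq_len(nStruct), 1]))
        }
    }
    if (nDiff > 0) {
        got <- 0L
        tries <- 0L
        idx <- nStruct + seq_len(nDiff)
        while (got < nDiff) {
            tries <- tries + 1L
            if (tries > maxTries)
                stop("rejection sampling exceeded the iteration cap (",
                    maxTries, ")")
            need <- idx[is.na(pts[idx, 1])]
            px <- stats::runif(length(need), 0, phantom@fieldSize[1])
            py <- stats::runif(length(need), 0, phantom@fieldSize[2])
            ok <- !.inVoid(phantom, px, py) &
                !.inAtollRing(phantom, px, py) & .inNucleus(phantom, px, py)
            pts[need[ok], 1] <- px[ok]
            pts[need[ok], 2] <- py[ok]
            got <- nDiff - sum(is.na(pts[idx, 1]))
        }
    }
    new("EmitterSet", positions = pts)
}
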
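#' @importFrom withr with_seed
NULL

## Radial silhouette model of a polar-view triporate grain: a disk of
## radius R with three smooth bumps (the pore regions) at 120 degree
## spacing, r(phi) = R + A * max(0, cos(3 * (phi - rot)))^3.
shapeRadius <- function(phi, baseRadius, poreAmplitude, rotation = 0) {
    rot <- rotation * pi / 180
    baseRadius + poreAmplitude * pmax(0, cos(3 * (phi - rot)))^3
}

## Dense polygon outline of the silhouette, in px, centered at the origin.
shapePolygon <- function(baseRadius, poreAmplitude, rotation = 0,
                         nVertices = 3600L) {
    phi <- seq(0, 2 * pi, length.out = nVertices + 1L)[-1L]
    r <- shapeRadius(phi, baseRadius, poreAmplitude, rotation)
    cbind(x = r * cos(phi), y = r * sin(phi))
}

## Continuous-geometry ground truth of the silhouette: area from a
## supersampled rasterization (subpixel grid), mean width from the Feret
## profile of the dense outline polygon. Both in px units.
shapeGroundTruth <- function(baseRadius, poreAmplitude, rotation = 0,
                             supersample = 10L, nAngles = 360L) {
    rmax <- baseRadius + poreAmplitude
    step <- 1 / supersample
    g <- seq(-rmax - 1, rmax + 1, by = step)
    xx <- rep(g, times = length(g))
    yy <- rep(g, each = length(g))
    phi <- atan2(yy, xx)
    inside <- xx^2 + yy^2 <=
        shapeRadius(phi, baseRadius, poreAmplitude, rotation)^2
    areaPx2 <- sum(inside) * step^2

    poly <- shapePolygon(baseRadius, poreAmplitude, rotation)
    th <- (seq_len(nAngles) - 1) * pi / nAngles
    proj <- poly %*% rbind(cos(th), sin(th))
    meanWidthPx <- mean(apply(proj, 2, max) - apply(proj, 2, min))
    list(areaPx2 = areaPx2, meanWidthPx = meanWidthPx)
}

## Mean width of the unit-radius silhouette with relative pore amplitude
## f, used to size a grain to a target width. Memoised.
shapeWidthFactorEnv <- new.env(parent = emptyenv())
shapeWidthFactor <- function(poreFraction) {
    key <- sprintf("%.6f", poreFraction)
    if (is.null(shapeWidthFactorEnv[[key]])) {
        poly <- shapePolygon(1, poreFraction)
        th <- seq(0, pi, length.out = 181L)[-181L]
        proj <- poly %*% rbind(cos(th), sin(th))
        shapeWidthFactorEnv[[key]] <-
            mean(apply(proj, 2, max) - apply(proj, 2, min))
    }
    shapeWidthFactorEnv[[key]]
}

#' Synthesize one triporate grain with analytic ground truth
#'
#' Rasterizes the radial silhouette model — a disk with three smooth
#' cos^3 bumps emulating the pore protrusions of a polar-view birch
#' grain — at pixel resolution, embeds it dark on a bright background
#' with additive Gaussian noise, and returns the image together with the
#' exact ground-truth mask and continuous-geometry ground truth (area and
#' rotational mean width from a 10x supersampled oracle), so measurement
#' accuracy can be scored without any manual annotation. Bit-reproducible
#' per seed.
#'
#' @param baseRadius disk radius in px.
#' @param poreAmplitude radial bump height in px (0 = plain disk).
#' @param rotation silhouette rotation in degrees.
#' @param noiseSd SD of additive Gaussian intensity noise (image in 0-1).
#' @param seed integer seed.
#' @param calibration a [Calibration-class].
#' @param margin background margin around the grain, px.
#' @param background,grainIntensity background/grain intensity levels.
#' @return list with `image` (numeric matrix), `mask`
#'   ([GrainMask-class]), `areaUm2` and `meanWidthUm` (ground truth), and
#'   `spec` (the generating parameters).
#'
#' @examples
#' g <- makeGrain(40, 4, seed = 1, calibration = Calibration(0.25))
#' g$meanWidthUm
#' @export
makeGrain <- function(baseRadius, poreAmplitude = 0, rotation = 0,
                      noiseSd = 0.02, seed = 1L,
                      calibration = Calibration(0.25), margin = 10L,
                      background = 0.85, grainIntensity = 0.25) {
    stopifnot(baseRadius > 0, poreAmplitude >= 0)
    mpp <- micronsPerPixel(calibration)
    rmax <- ceiling(baseRadius + poreAmplitude)
    size <- 2L * (rmax + as.integer(margin)) + 1L
    c0 <- (size - 1) / 2
    xx <- matrix(rep(0:(size - 1L), each = size), size, size)  # x = col
    yy <- matrix(rep(0:(size - 1L), times = size), size, size) # y = row
    dx <- xx - c0; dy <- yy - c0
    phi <- atan2(dy, dx)
    inside <- dx^2 + dy^2 <=
        shapeRadius(phi, baseRadius, poreAmplitude, rotation)^2
    img <- matrix(background, size, size)
    img[inside] <- grainIntensity
    img <- withr::with_seed(seed,
        img + matrix(stats::rnorm(size^2, 0, noiseSd), size, size))
    img <- pmin(pmax(img, 0), 1)
    gt <- shapeGroundTruth(baseRadius, poreAmplitude, rotation)
    list(image = img,
         mask = GrainMask(inside, sourceId = sprintf("synthetic_seed%d", seed)),
         areaUm2 = gt$areaPx2 * mpp^2,
         meanWidthUm = gt$meanWidthPx * mpp,
         spec = list(baseRadius = baseRadius, poreAmplitude = poreAmplitude,
                     rotation = rotation, noiseSd = noiseSd, seed = seed))
}

#' Grain shape parameters for a target mean width
#'
#' Inverts the silhouette model so that its continuous-geometry mean
#' width equals a requested value in microns: returns the base radius
#' (px) for a given relative pore amplitude.
#'
#' @param widthUm target rotational mean width, um.
#' @param calibration a [Calibration-class].
#' @param poreFraction pore amplitude as a fraction of the base radius.
#' @return list with `baseRadius` and `poreAmplitude` in px.
#' @export
grainSpecForWidth <- function(widthUm, calibration = Calibration(0.25),
                              poreFraction = 0.1) {
    baseRadius <- widthUm / micronsPerPixel(calibration) /
        shapeWidthFactor(poreFraction)
    list(baseRadius = baseRadius, poreAmplitude = poreFraction * baseRadius)
}

#' Synthesize a slide scene with ground-truth labels
#'
#' Places several grains (and optional irregular detritus blobs) on one
#' canvas, reproducing the conditions under which outline detection
#' fails: grains clipped by the field border and pairs of grains fused
#' into one object. Every placed grain is labelled `clean`,
#' `border_clipped` or `fused`, and its exact canvas-registered mask is
#' returned, so segmentation and screening can be scored by
#' intersection-over-union and by class. Deterministic per seed.
#'
#' Detritus blobs are kept clear of the grains (they emulate debris near,
#' not on, the targets); fused pairs are placed with center distance
#' `(r1 + r2) * (1 - overlapFraction)`.
#'
#' @param grainSpecs list of lists with `baseRadius`, `poreAmplitude`,
#'   optionally `rotation` (degrees).
#' @param detritusDensity number of detritus blobs.
#' @param overlapFraction overlap of fused pairs: 0 (default, with
#'   `nFusedPairs > 0`) places pairs just touching — the lowest-solidity
#'   fused geometry — while 1 places them concentrically, yielding one
#'   blob.
#' @param nFusedPairs number of grain pairs to fuse (uses the last
#'   `2 * nFusedPairs` specs).
#' @param nBorderClipped number of grains (from the front of the list)
#'   placed centered on the canvas border.
#' @param seed integer seed.
#' @param calibration a [Calibration-class].
#' @param noiseSd,background,grainIntensity image model parameters.
#' @return list with `image`, `masks` (list of [GrainMask-class], canvas
#'   coordinates), `labels` (character), and `truth` (data.frame of
#'   ground-truth `area_um2`, `mean_width_um` per grain).
#'
#' @examples
#' specs <- replicate(4, list(baseRadius = 35, poreAmplitude = 3),
#'                    simplify = FALSE)
#' sc <- makeScene(specs, seed = 2)
#' table(sc$labels)
#' @export
makeScene <- function(grainSpecs, detritusDensity = 0, overlapFraction = 0,
                      nFusedPairs = 0L, nBorderClipped = 0L, seed = 1L,
                      calibration = Calibration(0.25), noiseSd = 0.02,
                      background = 0.85, grainIntensity = 0.25) {
    nGrains <- length(grainSpecs)
    if (nGrains == 0L && detritusDensity == 0)
        return(list(image = matrix(background, 64L, 64L), masks = list(),
                    labels = character(),
                    truth = data.frame(area_um2 = numeric(),
                                       mean_width_um = numeric())))
    if (overlapFraction > 0 && nFusedPairs == 0L && nGrains >= 2L)
        nFusedPairs <- 1L
    if (2L * nFusedPairs + nBorderClipped > nGrains)
        stop("not enough grain specs for the requested fused/border classes")
    mpp <- micronsPerPixel(calibration)
    radii <- vapply(grainSpecs, function(s)
        s$baseRadius + (s$poreAmplitude %||% 0), numeric(1))
    maxR <- if (nGrains > 0L) max(radii) else 12
    ## a fused pair spans nearly two grain diameters, so its cell must be
    ## wider than a single grain's
    unitSpan <- if (nFusedPairs > 0L) 2 * maxR else maxR
    cell <- ceiling(2.6 * unitSpan)
    ## placement units: clean singles + fused pairs (border grains ride
    ## on the canvas edge, outside the grid)
    idxBorder <- seq_len(nBorderClipped)
    idxFused <- if (nFusedPairs > 0L)
        (nGrains - 2L * nFusedPairs + 1L):nGrains else integer()
    idxClean <- setdiff(seq_len(nGrains), c(idxBorder, idxFused))
    nUnits <- length(idxClean) + nFusedPairs
    gridN <- max(1L, ceiling(sqrt(nUnits)))
    canvas <- as.integer(gridN * cell + 2L * cell)
    if (canvas < 4 * maxR)
        stop("canvas too small for the requested content")

    withr::with_seed(seed, {
        centers <- matrix(NA_real_, nGrains, 2L)  # (row, col) 0-based
        unitCell <- 0L
        placeUnit <- function() {
            unitCell <<- unitCell + 1L
            gr <- (unitCell - 1L) %/% gridN
            gc <- (unitCell - 1L) %% gridN
            jitter <- stats::runif(2, -0.15, 0.15) * cell
            c(cell + gr * cell + cell / 2 + jitter[1],
              cell + gc * cell + cell / 2 + jitter[2])
        }
        for (i in idxClean) centers[i, ] <- placeUnit()
        if (nFusedPairs > 0L) for (k in seq_len(nFusedPairs)) {
            i <- idxFused[2L * k - 1L]; j <- idxFused[2L * k]
            base <- placeUnit()
            ## base radii (not bump tips): the pair touches along the disk
            ## body; -2 px guarantees 4-connectivity of the fused object
            bi <- grainSpecs[[i]]$baseRadius; bj <- grainSpecs[[j]]$baseRadius
            d <- max(0, (bi + bj) * (1 - overlapFraction) - 2)
            ang <- stats::runif(1, 0, 2 * pi)
            centers[i, ] <- base - d / 2 * c(sin(ang), cos(ang))
            centers[j, ] <- base + d / 2 * c(sin(ang), cos(ang))
        }
        for (b in idxBorder) {
            side <- sample(4L, 1L)
            pos <- stats::runif(1, 0.2, 0.8) * canvas
            centers[b, ] <- switch(side,
                c(0, pos), c(canvas - 1, pos), c(pos, 0), c(pos, canvas - 1))
        }

        img <- matrix(background, canvas, canvas)
        masks <- vector("list", nGrains)
        truth <- data.frame(area_um2 = numeric(nGrains),
                            mean_width_um = numeric(nGrains))
        for (i in seq_len(nGrains)) {
            s <- grainSpecs[[i]]
            rot <- s$rotation %||% stats::runif(1, 0, 120)
            amp <- s$poreAmplitude %||% 0
            full <- rasterizeShape(canvas, centers[i, ], s$baseRadius, amp,
                                   rot)
            if (!any(full)) next
            img[full] <- grainIntensity
            masks[[i]] <- cropComponent(
                matrix(as.integer(full), canvas, canvas), 1L,
                sourceDim = c(canvas, canvas),
                sourceId = sprintf("scene%d/grain%03d", seed, i))
            gt <- shapeGroundTruth(s$baseRadius, amp, rot)
            truth$area_um2[i] <- gt$areaPx2 * mpp^2
            truth$mean_width_um[i] <- gt$meanWidthPx * mpp
        }
        labels <- rep("clean", nGrains)
        labels[idxBorder] <- "border_clipped"
        labels[idxFused] <- "fused"

        ## detritus: irregular dark blobs kept clear of the grains
        nDet <- as.integer(detritusDensity)
        tries <- 0L
        while (nDet > 0L && tries < 200L) {
            tries <- tries + 1L
            r <- stats::runif(1, 4, 12)
            ctr <- stats::runif(2, cell / 4, canvas - cell / 4)
            dists <- sqrt((centers[, 1] - ctr[1])^2 +
                          (centers[, 2] - ctr[2])^2)
            if (any(dists < radii + r + 8, na.rm = TRUE)) next
            blob <- rasterizeBlob(canvas, ctr, r)
            img[blob] <- grainIntensity + 0.1
            nDet <- nDet - 1L
        }
        img <- img + matrix(stats::rnorm(canvas^2, 0, noiseSd),
                            canvas, canvas)
        img <- pmin(pmax(img, 0), 1)
        list(image = img, masks = masks, labels = labels, truth = truth)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Pixel-grid silhouette at an arbitrary canvas position; clipped at the
## canvas border.
rasterizeShape <- function(canvas, center, baseRadius, poreAmplitude,
                           rotation) {
    rmax <- ceiling(baseRadius + poreAmplitude) + 1L
    r0 <- max(0L, floor(center[1] - rmax)); r1 <- min(canvas - 1L,
                                                      ceiling(center[1] + rmax))
    c0 <- max(0L, floor(center[2] - rmax)); c1 <- min(canvas - 1L,
                                                      ceiling(center[2] + rmax))
    if (r1 < r0 || c1 < c0) return(matrix(FALSE, canvas, canvas))
    rows <- r0:r1; cols <- c0:c1
    dy <- matrix(rows - center[1], length(rows), length(cols))
    dx <- matrix(rep(cols - center[2], each = length(rows)),
                 length(rows), length(cols))
    phi <- atan2(dy, dx)
    insideLocal <- dx^2 + dy^2 <=
        shapeRadius(phi, baseRadius, poreAmplitude, rotation)^2
    full <- matrix(FALSE, canvas, canvas)
    full[rows + 1L, cols + 1L] <- insideLocal
    full
}

## Irregular blob: radius with random low-order harmonic perturbation.
rasterizeBlob <- function(canvas, center, radius) {
    a <- stats::runif(3, 0, 0.45)
    ph <- stats::runif(3, 0, 2 * pi)
    rmax <- ceiling(radius * 2) + 1L
    r0 <- max(0L, floor(center[1] - rmax)); r1 <- min(canvas - 1L,
                                                      ceiling(center[1] + rmax))
    c0 <- max(0L, floor(center[2] - rmax)); c1 <- min(canvas - 1L,
                                                      ceiling(center[2] + rmax))
    rows <- r0:r1; cols <- c0:c1
    dy <- matrix(rows - center[1], length(rows), length(cols))
    dx <- matrix(rep(cols - center[2], each = length(rows)),
                 length(rows), length(cols))
    phi <- atan2(dy, dx)
    rr <- radius * (1 + a[1] * cos(2 * phi + ph[1]) +
                    a[2] * cos(3 * phi + ph[2]) + a[3] * cos(5 * phi + ph[3]))
    insideLocal <- dx^2 + dy^2 <= rr^2
    full <- matrix(FALSE, canvas, canvas)
    full[rows + 1L, cols + 1L] <- insideLocal
    full
}

#' Draw grain sizes from a species mixture
#'
#' Samples `n` sizes from the compound model: each draw picks component
#' `i` with probability `proportions[i]` and then a normal deviate with
#' that component's mean and SD. The true component labels are retained
#' so recovery can be scored. Deterministic per seed.
#'
#' @param components data.frame with columns `species`, `mean`, `sd`.
#' @param proportions simplex vector, one weight per component.
#' @param n number of draws.
#' @param seed integer seed.
#' @return list with `values` (numeric) and `labels` (integer component
#'   indices).
#'
#' @examples
#' ref <- betulaReference("mean_width")
#' cmp <- ref[ref$species %in% c("B. nana", "B. pubescens"), ]
#' s <- sampleSizes(cmp, c(0.3, 0.7), n = 1000, seed = 1)
#' mean(s$labels == 1)
#' @export
sampleSizes <- function(components, proportions, n, seed = 1L) {
    components <- as.data.frame(components)
    K <- nrow(components)
    stopifnot(length(proportions) == K, n >= 1,
              abs(sum(proportions) - 1) < 1e-9, all(proportions >= 0))
    withr::with_seed(as.integer(seed), {
        labels <- sample.int(K, n, replace = TRUE, prob = proportions)
        values <- stats::rnorm(n, components$mean[labels],
                               components$sd[labels])
        list(values = values, labels = labels)
    })
}

#' Synthesize a stratigraphic record of size samples
#'
#' Builds one [SampleSeries-class] per depth, drawing sizes from the
#' compound model with depth-specific true proportions — the synthetic
#' analogue of a sediment record in which the dwarf-birch share changes
#' through time. The generating proportions are attached as attribute
#' `"truth"` for recovery scoring.
#'
#' @param depths numeric depths (cm), shallow to deep.
#' @param proportionProfile matrix (length(depths) x K) of true
#'   proportions, rows on the simplex.
#' @param components data.frame with columns `species`, `mean`, `sd`.
#' @param nPerSample grains per sample (single value or per-depth vector).
#' @param seed base seed; depth `i` uses `seed + i - 1`.
#' @param metric recorded size metric label.
#' @return list of [SampleSeries-class] with attribute `truth`.
#'
#' @examples
#' ref <- betulaReference("mean_width")
#' cmp <- ref[ref$species %in% c("B. nana", "B. pubescens"), ]
#' rec <- makeStratigraphicRecord(1:4, cbind(c(.1, .1, .6, .6),
#'                                           c(.9, .9, .4, .4)),
#'                                cmp, nPerSample = 50, seed = 1)
#' attr(rec, "truth")
#' @export
makeStratigraphicRecord <- function(depths, proportionProfile, components,
                                    nPerSample, seed = 1L,
                                    metric = "mean_width") {
    proportionProfile <- as.matrix(proportionProfile)
    stopifnot(nrow(proportionProfile) == length(depths))
    if (length(nPerSample) == 1L)
        nPerSample <- rep(nPerSample, length(depths))
    if (any(nPerSample < 1)) stop("nPerSample must be at least 1")
    out <- lapply(seq_along(depths), function(i) {
        s <- sampleSizes(components, proportionProfile[i, ], nPerSample[i],
                         seed = as.integer(seed) + i - 1L)
        SampleSeries(sprintf("d%03d", i), s$values, depth = depths[i],
                     metric = metric)
    })
    attr(out, "truth") <- proportionProfile
    out
}
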
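cal <- Calibration(0.25)

test_that("grain generator ground truth matches closed-form geometry", {
    # pore amplitude 0: a disk, mean width = 2 * baseRadius * cal
    g0 <- makeGrain(40, 0, seed = 1, calibration = cal)
    expect_equal(g0$meanWidthUm, 2 * 40 * 0.25, tolerance = 1e-3)
    expect_equal(g0$areaUm2, pi * 40^2 * 0.25^2, tolerance = 0.005)

    # supersampled area vs the closed-form polar integral (1/2) int r^2 dphi
    for (p in list(c(30, 3), c(40, 6), c(25, 0))) {
        g <- makeGrain(p[1], p[2], seed = 2, calibration = cal)
        closedForm <- stats::integrate(function(phi)
            0.5 * (p[1] + p[2] * pmax(0, cos(3 * phi))^3)^2,
            0, 2 * pi, subdivisions = 2000L)$value * 0.25^2
        expect_equal(g$areaUm2, closedForm, tolerance = 0.005)
    }

    # determinism: same spec and seed give a bit-identical image
    a <- makeGrain(30, 4, seed = 9, noiseSd = 0.05)
    b <- makeGrain(30, 4, seed = 9, noiseSd = 0.05)
    expect_identical(a$image, b$image)
    expect_false(identical(a$image, makeGrain(30, 4, seed = 10,
                                              noiseSd = 0.05)$image))
})

test_that("grain sizing to a target width inverts the shape model", {
    for (w in c(20.54, 22.41, 25.46)) {
        sp <- grainSpecForWidth(w, cal, poreFraction = 0.1)
        g <- makeGrain(sp$baseRadius, sp$poreAmplitude, seed = 1,
                       calibration = cal)
        expect_equal(g$meanWidthUm, w, tolerance = 1e-3)
    }
})

test_that("scenes place, label and recover their grains", {
    sc0 <- makeScene(list(), seed = 1)
    expect_length(sc0$masks, 0L)
    expect_length(sc0$labels, 0L)

    specs <- replicate(5, list(baseRadius = 38, poreAmplitude = 4),
                       simplify = FALSE)
    sc <- makeScene(specs, seed = 6, calibration = cal)
    expect_identical(sc$labels, rep("clean", 5))
    segs <- segmentGrains(sc$image, cal, sourceId = "sc")
    expect_length(segs, 5L)
    ious <- vapply(seq_len(5), function(i)
        max(vapply(segs, maskIoU, numeric(1), b = sc$masks[[i]])), numeric(1))
    expect_true(all(ious >= 0.95))

    # fully overlapping pair: one fused object
    sc2 <- makeScene(replicate(2, list(baseRadius = 30, poreAmplitude = 0),
                               simplify = FALSE),
                     overlapFraction = 1, nFusedPairs = 1, seed = 2,
                     calibration = cal)
    expect_identical(sc2$labels, rep("fused", 2))
    union <- fullCanvasMask(sc2$masks[[1]]) | fullCanvasMask(sc2$masks[[2]])
    expect_identical(betulaSize:::countComponents(union), 1L)

    # determinism per seed
    expect_identical(makeScene(specs, seed = 6, calibration = cal)$image,
                     sc$image)
})

test_that("mixture draws respect labels, proportions and seeds", {
    cmp <- referenceComponents()
    s1 <- sampleSizes(cmp[1, , drop = FALSE], 1, 50, seed = 1)
    expect_true(all(s1$labels == 1L))

    s2 <- sampleSizes(cmp, c(1, 0), 200, seed = 2)
    expect_true(all(s2$labels == 1L))

    s3 <- sampleSizes(cmp, c(0.3, 0.7), 10000, seed = 3)
    expect_lt(abs(mean(s3$labels == 1) - 0.3), 0.015)

    expect_identical(sampleSizes(cmp, c(0.3, 0.7), 100, seed = 4)$values,
                     sampleSizes(cmp, c(0.3, 0.7), 100, seed = 4)$values)
})

test_that("stratigraphic records carry their generating truth", {
    cmp <- referenceComponents()
    prof <- cbind(c(0.1, 0.1, 0.6, 0.6), c(0.9, 0.9, 0.4, 0.4))
    rec <- makeStratigraphicRecord(1:4, prof, cmp, nPerSample = 40, seed = 5)
    expect_length(rec, 4L)
    expect_identical(attr(rec, "truth"), prof)
    expect_identical(vapply(rec, function(s) s@depth, numeric(1)),
                     as.numeric(1:4))
    expect_error(makeStratigraphicRecord(1:2, prof[1:2, ], cmp,
                                         nPerSample = 0, seed = 1),
                 "at least 1")
})

test_that("measurement pipeline recovers generator ground truth end to end", {
    nOk <- 0L; nTot <- 0L
    for (s in 1:3) {
        widths <- sampleSizes(referenceComponents(), c(0.5, 0.5), 6,
                              seed = 40 + s)$values
        specs <- lapply(widths, grainSpecForWidth, calibration = cal)
        sc <- makeScene(specs, detritusDensity = 3, seed = 40 + s,
                        calibration = cal)
        segs <- segmentGrains(sc$image, cal)
        for (i in which(sc$labels == "clean")) {
            nTot <- nTot + 1L
            ious <- vapply(segs, maskIoU, numeric(1), b = sc$masks[[i]])
            if (!length(ious) || max(ious) < 0.5) next
            m <- measureGrain(segs[[which.max(ious)]], cal)
            widthOk <- abs(m@meanWidthUm - sc$truth$mean_width_um[i]) /
                sc$truth$mean_width_um[i] < 0.02
            areaOk <- abs(m@areaUm2 - sc$truth$area_um2[i]) /
                sc$truth$area_um2[i] < 0.03
            if (widthOk && areaOk) nOk <- nOk + 1L
        }
    }
    expect_gte(nOk / nTot, 0.95)
})
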
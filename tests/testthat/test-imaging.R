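test_that("best-focus selection picks the sharpest layer and breaks ties low", {
    # single layer: only candidate
    expect_identical(selectBestFocus(FocusStack(list(matrix(0.5, 8, 8)))), 1L)

    # checkerboard vs its Gaussian blurs: blur strictly reduces the
    # Laplacian-variance score, so the sharp original must win
    cb <- matrix(rep(c(0, 1), length.out = 64 * 64), 64, 64)
    blur3 <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(cb), 3)))
    blur6 <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(cb), 6)))
    expect_identical(selectBestFocus(FocusStack(list(cb, blur3, blur6))), 1L)
    expect_identical(selectBestFocus(FocusStack(list(blur6, cb, blur3))), 2L)

    # two identical uniform layers: tie broken by lowest index
    expect_identical(selectBestFocus(list(matrix(1, 8, 8), matrix(1, 8, 8))), 1L)

    expect_error(selectBestFocus(list()), "at least one layer")
})

test_that("focus selection is invariant under a global affine intensity rescale", {
    set.seed(42)
    layers <- lapply(c(1, 2.5, 0.7), function(s)
        matrix(runif(900), 30, 30) * s)
    idx <- selectBestFocus(layers)
    rescaled <- lapply(layers, function(l) 0.4 * l + 0.3)
    expect_identical(selectBestFocus(rescaled), idx)
})

test_that("segmentGrains applies threshold, border rule and area gate", {
    cal <- Calibration(0.25)
    expect_length(segmentGrains(matrix(0.8, 100, 100), cal), 0L)

    # one dark disk, radius 30 px, area ~ pi * 7.5^2 = 176.7 um^2: in gate
    img <- matrix(0.9, 160, 160)
    img[(row(img) - 80)^2 + (col(img) - 80)^2 <= 30^2] <- 0.1
    masks <- segmentGrains(img, cal)
    expect_length(masks, 1L)
    expect_equal(computeArea(masks[[1]], cal), pi * 7.5^2, tolerance = 0.01)

    # same disk touching the left border: rejected
    img2 <- matrix(0.9, 160, 160)
    img2[(row(img2) - 80)^2 + (col(img2) - 25)^2 <= 30^2] <- 0.1
    expect_length(segmentGrains(img2, cal), 0L)

    # disk below the area gate: rejected
    img3 <- matrix(0.9, 160, 160)
    img3[(row(img3) - 80)^2 + (col(img3) - 80)^2 <= 10^2] <- 0.1
    expect_length(segmentGrains(img3, cal), 0L)
})

test_that("segmentGrains output satisfies its own contract on a noisy scene", {
    cal <- Calibration(0.25)
    specs <- replicate(5, list(baseRadius = 38, poreAmplitude = 4),
                       simplify = FALSE)
    sc <- makeScene(specs, detritusDensity = 3, seed = 9, calibration = cal)
    masks <- segmentGrains(sc$image, cal, sourceId = "scene9")
    expect_gt(length(masks), 0L)
    for (m in masks) {
        expect_false(touchesBorder(m))
        area <- computeArea(m, cal)
        expect_gte(area, 150); expect_lte(area, 1500)
        expect_identical(betulaSize:::countComponents(maskPixels(m)), 1L)
    }
})

test_that("mask import splits components and round-trips exactly", {
    cal <- Calibration(0.5)
    tmp <- withr::local_tempdir()
    # two disjoint blobs in one file -> two masks; all-zero file -> none
    m <- matrix(0, 40, 40); m[5:12, 5:12] <- 1; m[25:35, 25:32] <- 1
    f1 <- file.path(tmp, "two.png"); png::writePNG(m, f1)
    f0 <- file.path(tmp, "none.png"); png::writePNG(matrix(0, 10, 10), f0)
    masks <- importMasks(c(f1, f0), cal)
    expect_length(masks, 2L)
    expect_setequal(vapply(masks, nForeground, numeric(1)), c(64, 88))

    # re-export / re-import is the identity on foreground pixel sets
    f2 <- file.path(tmp, "roundtrip.png")
    writeMask(masks[[1]], f2)
    again <- importMasks(f2, cal)
    expect_length(again, 1L)
    expect_identical(maskPixels(again[[1]]), maskPixels(masks[[1]]))

    # undecodable file errors, naming the file
    bad <- file.path(tmp, "bad.png")
    writeLines("not a png", bad)
    expect_error(importMasks(bad, cal), "bad.png")
})

test_that("focus stacks read back from TIFF, including jpeg-compressed pages", {
    tmp <- withr::local_tempdir()
    set.seed(7)
    layers <- list(matrix(runif(64^2), 64, 64), matrix(runif(64^2), 64, 64))
    f <- file.path(tmp, "stack.tif")
    tiff::writeTIFF(layers, f)
    fs <- readFocusStack(f)
    expect_identical(nLayers(fs), 2L)
    expect_equal(getLayer(fs, 1), layers[[1]], tolerance = 1e-2)

    fj <- file.path(tmp, "stack_jpeg.tif")
    tiff::writeTIFF(layers[[1]], fj, compression = "JPEG")
    expect_identical(nLayers(readFocusStack(fj)), 1L)
})
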
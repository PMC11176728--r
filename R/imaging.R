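#' Select the sharpest layer of a focus stack
#'
#' Microscope fields are imaged at several focus levels to cope with the
#' low depth of field at high magnification; only the layer with the
#' highest contrast is measured. Contrast is scored as the variance of the
#' 3x3 Laplacian response over the whole layer, a standard focus measure
#' that decreases monotonically under defocus blur. Ties are broken by the
#' lowest index, so the choice is deterministic.
#'
#' @param stack a [FocusStack-class], or a list of numeric matrices.
#' @return integer index (1-based) of the selected layer.
#'
#' @details The score is invariant to adding a constant to all layers and
#' scales with the square of a common gain, so a global affine intensity
#' rescale applied to every layer leaves the selection unchanged.
#'
#' @examples
#' sharp <- matrix(rep(c(0, 1), length.out = 64), 8, 8)
#' flat <- matrix(0.5, 8, 8)
#' selectBestFocus(FocusStack(list(flat, sharp)))
#' @export
selectBestFocus <- function(stack) {
    layers <- if (is(stack, "FocusStack")) stack@layers else stack
    if (!is.list(layers) || length(layers) < 1L)
        stop("focus stack must contain at least one layer")
    scores <- vapply(layers, laplacianVariance, numeric(1))
    which.max(scores)  # which.max returns the first maximum: lowest index
}

## Variance of the 3x3 Laplacian (4-neighbour) response on the interior.
laplacianVariance <- function(img) {
    nr <- nrow(img); nc <- ncol(img)
    if (nr < 3L || nc < 3L) return(0)
    i <- 2:(nr - 1L); j <- 2:(nc - 1L)
    L <- 4 * img[i, j] - img[i - 1L, j] - img[i + 1L, j] -
        img[i, j - 1L] - img[i, j + 1L]
    stats::var(as.vector(L))
}

#' Segment candidate grain masks from a grayscale image
#'
#' A deliberately simple classical segmenter that makes the pipeline
#' runnable end to end without a trained outline-detection network: the
#' image is globally thresholded (Otsu by default, grains assumed darker
#' than the background), holes are filled, connected objects are labelled
#' (4-connectivity), and objects touching the image border or falling
#' outside the calibrated area gate are discarded. Each surviving object
#' becomes one single-component [GrainMask-class].
#'
#' @param image numeric matrix (any intensity range; normalized internally).
#' @param calibration a [Calibration-class].
#' @param areaGateUm2 length-2 numeric, accepted area range in um^2.
#' @param fillHoles logical, fill enclosed background holes before gating.
#' @param thresholdMethod `"otsu"` or a numeric threshold on the
#'   normalized (0-1) image.
#' @param sourceId label recorded on the returned masks.
#' @return list of [GrainMask-class] (possibly empty).
#'
#' @examples
#' img <- matrix(1, 120, 120)
#' yy <- row(img) - 60; xx <- col(img) - 60
#' img[yy^2 + xx^2 <= 30^2] <- 0.1
#' length(segmentGrains(img, Calibration(0.25)))
#' @export
segmentGrains <- function(image, calibration, areaGateUm2 = c(150, 1500),
                          fillHoles = TRUE, thresholdMethod = "otsu",
                          sourceId = "image") {
    stopifnot(is.matrix(image), nrow(image) > 0, ncol(image) > 0)
    validObject(calibration)
    norm <- normalize01(image)
    if (identical(thresholdMethod, "otsu")) {
        if (all(norm == 0)) return(list())  # uniform image: nothing to find
        th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    } else {
        th <- as.numeric(thresholdMethod)
    }
    fg <- norm < th  # grains are dark on a bright background
    if (!any(fg)) return(list())
    if (fillHoles) {
        filled <- EBImage::fillHull(EBImage::Image(matrix(as.numeric(fg),
                                                          nrow(fg), ncol(fg))))
        fg <- matrix(as.numeric(EBImage::imageData(filled)),
                     nrow(fg), ncol(fg)) > 0
    }
    lab <- labelComponents(fg)
    n <- max(lab)
    if (n == 0L) return(list())
    mpp2 <- micronsPerPixel(calibration)^2
    out <- list()
    for (id in seq_len(n)) {
        m <- cropComponent(lab, id, sourceDim = dim(image),
                           sourceId = sprintf("%s/obj%03d", sourceId, id))
        if (touchesBorder(m)) next
        area <- nForeground(m) * mpp2
        if (area < areaGateUm2[1] || area > areaGateUm2[2]) next
        out[[length(out) + 1L]] <- m
    }
    out
}

#' Import externally produced grain masks
#'
#' Ingests binary masks written by any upstream outline detector (for
#' example a semantic-segmentation network). Any nonzero pixel is
#' foreground; rasters containing several disjoint objects are split into
#' one [GrainMask-class] per 4-connected component.
#'
#' @param paths character vector of PNG or TIFF files.
#' @param calibration a [Calibration-class] (validated, carried by callers).
#' @return list of [GrainMask-class], in file order then component order.
#'
#' @examples
#' f <- tempfile(fileext = ".png")
#' m <- matrix(0, 20, 20); m[3:8, 3:8] <- 1; m[12:17, 12:17] <- 1
#' png::writePNG(m, f)
#' length(importMasks(f, Calibration(0.25)))
#' @export
importMasks <- function(paths, calibration) {
    validObject(calibration)
    out <- list()
    for (p in paths) {
        raster <- readRaster(p)
        fg <- collapseChannels(raster) != 0
        if (!any(fg)) next
        lab <- labelComponents(fg)
        base <- tools::file_path_sans_ext(basename(p))
        for (id in seq_len(max(lab))) {
            out[[length(out) + 1L]] <-
                cropComponent(lab, id, sourceDim = dim(fg),
                              sourceId = sprintf("%s/obj%03d", base, id))
        }
    }
    out
}

## Decode a single-image raster file by extension, with a fallback sniff.
readRaster <- function(path) {
    if (!file.exists(path)) stop("mask file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    res <- tryCatch({
        if (ext %in% c("png")) png::readPNG(path)
        else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
        else stop("unsupported raster format")
    }, error = function(e) {
        stop("cannot decode raster file '", path, "': ",
             conditionMessage(e), call. = FALSE)
    })
    res
}

#' Read a TIFF focus stack
#'
#' Reads a (possibly multi-page, possibly jpeg-compressed) TIFF as a
#' [FocusStack-class]; single-page files become one-layer stacks.
#'
#' @param path TIFF file path.
#' @param positionId label; defaults to the file name.
#' @return a [FocusStack-class].
#' @export
readFocusStack <- function(path, positionId = NULL) {
    if (is.null(positionId))
        positionId <- tools::file_path_sans_ext(basename(path))
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e)
                          stop("cannot decode TIFF '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    FocusStack(lapply(pages, collapseChannels), positionId)
}

#' Write a grain mask to a PNG file
#'
#' Writes the crop as an 8-bit binary PNG (foreground = 1). Re-importing
#' the file recovers the identical foreground pixel set.
#'
#' @param mask a [GrainMask-class].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
    png::writePNG(matrix(as.numeric(mask@pixels), nrow(mask@pixels),
                         ncol(mask@pixels)), path)
    invisible(path)
}
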
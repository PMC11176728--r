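#' @import methods
#' @importFrom stats dnorm pnorm rnorm runif sd var density cor quantile
#' @importFrom utils read.csv write.csv packageVersion head tail
NULL

#' Microscope calibration
#'
#' Holds the spatial calibration of the imaging system as microns per pixel.
#' All geometric quantities in the package are reported in microns (widths)
#' or square microns (areas) through this factor; a pixel covers
#' `micronsPerPixel()^2` square microns.
#'
#' @slot micronsPerPixel Numeric scalar, strictly positive and finite.
#'
#' @examples
#' cal <- Calibration(0.25)
#' micronsPerPixel(cal)
#' @export
setClass("Calibration", representation(micronsPerPixel = "numeric"))

setValidity("Calibration", function(object) {
    mpp <- object@micronsPerPixel
    if (length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
        return("micronsPerPixel must be a single finite value > 0")
    TRUE
})

#' @param micronsPerPixel microns per pixel, a single finite positive number.
#' @rdname Calibration-class
#' @export
Calibration <- function(micronsPerPixel) {
    new("Calibration", micronsPerPixel = as.numeric(micronsPerPixel))
}

#' @describeIn Calibration-class accessor for the scale factor.
#' @param object,x a `Calibration` object.
#' @export
micronsPerPixel <- function(object) object@micronsPerPixel

setMethod("show", "Calibration", function(object) {
    cat(sprintf("Calibration: %.6g um/px (pixel area %.6g um^2)\n",
                object@micronsPerPixel, object@micronsPerPixel^2))
})

#' Focus stack of one microscope position
#'
#' An ordered set of grayscale layers imaged at the same XY position but
#' different focus levels. Layers are numeric matrices (rows = image rows)
#' and must all share the same dimensions.
#'
#' @slot layers list of numeric matrices, all of identical dimension.
#' @slot positionId character label of the stage position.
#'
#' @examples
#' fs <- FocusStack(list(matrix(0, 4, 4), matrix(1, 4, 4)), "pos1")
#' nLayers(fs)
#' @export
setClass("FocusStack",
         representation(layers = "list", positionId = "character"))

setValidity("FocusStack", function(object) {
    if (length(object@layers) < 1L)
        return("a FocusStack needs at least one layer")
    dims <- lapply(object@layers, dim)
    if (any(vapply(object@layers, function(l) !is.matrix(l) || !is.numeric(l),
                   logical(1))))
        return("layers must be numeric matrices")
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
        return("all layers must share identical dimensions")
    TRUE
})

#' @param layers list of numeric matrices.
#' @param positionId text label.
#' @rdname FocusStack-class
#' @export
FocusStack <- function(layers, positionId = "stack") {
    new("FocusStack", layers = layers, positionId = as.character(positionId))
}

#' @describeIn FocusStack-class number of layers in the stack.
#' @param object,x a `FocusStack`.
#' @export
nLayers <- function(object) length(object@layers)

#' @describeIn FocusStack-class extract one layer as a matrix.
#' @param i layer index.
#' @export
getLayer <- function(object, i) object@layers[[i]]

setMethod("show", "FocusStack", function(object) {
    d <- dim(object@layers[[1]])
    cat(sprintf("FocusStack '%s': %d layer(s) of %d x %d px\n",
                object@positionId, length(object@layers), d[1], d[2]))
})

#' Binary mask of a single pollen grain
#'
#' The geometric substrate of all measurements: a binary raster whose
#' nonzero pixels form exactly one 4-connected foreground component.
#' Pixel (0,0) is the top-left pixel of the crop; pixel centers sit at
#' integer coordinates. `originOffset` records where the crop sits inside
#' its source raster (0-based row, col) and `sourceDim` the source raster's
#' dimensions, so border contact can be judged against the original field
#' of view rather than the tight crop.
#'
#' @slot pixels logical matrix, `TRUE` = grain.
#' @slot originOffset integer (row, col) offset of the crop, 0-based.
#' @slot sourceDim integer (nrow, ncol) of the source raster.
#' @slot sourceId character identifier of the source image/file.
#'
#' @examples
#' m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
#' gm <- GrainMask(m)
#' nForeground(gm)
#' @export
setClass("GrainMask",
         representation(pixels = "matrix", originOffset = "integer",
                        sourceDim = "integer", sourceId = "character"))

setValidity("GrainMask", function(object) {
    px <- object@pixels
    if (!is.logical(px)) return("pixels must be a logical matrix")
    n <- sum(px)
    if (n < 1L) return("mask must contain at least one foreground pixel")
    if (countComponents(px) != 1L)
        return("mask must contain exactly one 4-connected foreground component")
    if (length(object@originOffset) != 2L || any(object@originOffset < 0L))
        return("originOffset must be two non-negative integers")
    if (length(object@sourceDim) != 2L ||
        any(object@sourceDim < dim(px) + object@originOffset))
        return("sourceDim must contain the crop at its offset")
    TRUE
})

#' @param pixels logical or numeric matrix (nonzero = foreground).
#' @param originOffset 0-based (row, col) of the crop within the source.
#' @param sourceDim dimensions of the source raster; defaults to the crop
#'   placed at its offset.
#' @param sourceId text label.
#' @rdname GrainMask-class
#' @export
GrainMask <- function(pixels, originOffset = c(0L, 0L), sourceDim = NULL,
                      sourceId = "mask") {
    px <- if (is.logical(pixels)) pixels else pixels != 0
    storage.mode(px) <- "logical"
    off <- as.integer(originOffset)
    if (is.null(sourceDim)) sourceDim <- dim(px) + off
    new("GrainMask", pixels = px, originOffset = off,
        sourceDim = as.integer(sourceDim), sourceId = as.character(sourceId))
}

#' @describeIn GrainMask-class the logical pixel matrix of the crop.
#' @param object,x a `GrainMask`.
#' @export
maskPixels <- function(object) object@pixels

#' @describeIn GrainMask-class number of foreground pixels.
#' @export
nForeground <- function(object) sum(object@pixels)

#' @describeIn GrainMask-class TRUE if the grain touches the border of its
#'   source raster.
#' @export
touchesBorder <- function(object) {
    px <- object@pixels
    off <- object@originOffset
    sdim <- object@sourceDim
    rows <- which(rowSums(px) > 0)
    cols <- which(colSums(px) > 0)
    (off[1] + min(rows) - 1L) == 0L ||
    (off[2] + min(cols) - 1L) == 0L ||
    (off[1] + max(rows)) == sdim[1] ||
    (off[2] + max(cols)) == sdim[2]
}

setMethod("show", "GrainMask", function(object) {
    cat(sprintf("GrainMask '%s': %d x %d crop at (%d,%d), %d fg px%s\n",
                object@sourceId, nrow(object@pixels), ncol(object@pixels),
                object@originOffset[1], object@originOffset[2],
                sum(object@pixels),
                if (touchesBorder(object)) ", touches border" else ""))
})

#' Per-grain measurement record
#'
#' Bundles the two size parameters of one grain — calibrated area and the
#' rotational mean width — with the full width profile (one Feret width per
#' 1 degree rotation step) and quality-control flags.
#'
#' @slot grainId,sampleId character identifiers.
#' @slot areaUm2 area in square microns.
#' @slot meanWidthUm arithmetic mean of the width profile, microns.
#' @slot widthProfile numeric vector of per-angle widths, microns.
#' @slot suitable logical screening verdict.
#' @slot qcFlags character vector of QC reason codes.
#' @export
setClass("GrainMeasurement",
         representation(grainId = "character", sampleId = "character",
                        areaUm2 = "numeric", meanWidthUm = "numeric",
                        widthProfile = "numeric", suitable = "logical",
                        qcFlags = "character"))

setValidity("GrainMeasurement", function(object) {
    if (object@areaUm2 <= 0) return("areaUm2 must be > 0")
    wp <- object@widthProfile
    if (length(wp) < 1L || any(wp <= 0)) return("widthProfile must be positive")
    if (abs(object@meanWidthUm - mean(wp)) > 1e-8 * max(1, mean(wp)))
        return("meanWidthUm must equal the mean of the width profile")
    if (object@meanWidthUm > max(wp) + 1e-12)
        return("meanWidthUm cannot exceed the profile maximum")
    TRUE
})

setMethod("show", "GrainMeasurement", function(object) {
    cat(sprintf(
        "GrainMeasurement %s (sample %s): area %.1f um^2, mean width %.2f um, %s%s\n",
        object@grainId, object@sampleId, object@areaUm2, object@meanWidthUm,
        if (object@suitable) "suitable" else "unsuitable",
        if (length(object@qcFlags))
            paste0(" [", paste(object@qcFlags, collapse = ","), "]") else ""))
})

#' @describeIn GrainMeasurement-class coerce one measurement to a one-row
#'   data.frame (profile omitted).
#' @param x a `GrainMeasurement`.
#' @param row.names,optional,... ignored, present for generic consistency.
#' @export
setMethod("as.data.frame", "GrainMeasurement",
    function(x, row.names = NULL, optional = FALSE, ...) {
        data.frame(grain_id = x@grainId, sample_id = x@sampleId,
                   area_um2 = x@areaUm2, mean_width_um = x@meanWidthUm,
                   suitable = x@suitable,
                   qc_flags = paste(x@qcFlags, collapse = ";"),
                   stringsAsFactors = FALSE)
    })

#' Mixture of per-species size distributions
#'
#' A compound (mixture-of-normals) model of a pollen size distribution:
#' up to four species components, each a normal distribution with fixed
#' mean and SD (one reference-table row), weighted by a proportion vector
#' on the simplex.
#'
#' @slot components data.frame with columns `species`, `mean`, `sd`.
#' @slot proportions numeric simplex vector, one weight per component.
#'
#' @examples
#' ref <- betulaReference("mean_width")
#' spec <- MixtureSpec(ref[ref$species %in% c("B. nana", "B. pubescens"), ],
#'                     c(0.5, 0.5))
#' mixturePdf(21, spec)
#' @export
setClass("MixtureSpec",
         representation(components = "data.frame", proportions = "numeric"))

setValidity("MixtureSpec", function(object) {
    cmp <- object@components
    k <- nrow(cmp)
    if (k < 1L || k > 4L) return("between 1 and 4 components are supported")
    if (!all(c("species", "mean", "sd") %in% names(cmp)))
        return("components needs columns species, mean, sd")
    if (any(cmp$sd <= 0)) return("component sd must be > 0")
    p <- object@proportions
    if (length(p) != k) return("one proportion per component required")
    if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9)
        return("proportions must be non-negative and sum to 1 (within 1e-9)")
    TRUE
})

#' @param components data.frame with columns `species`, `mean`, `sd`.
#' @param proportions simplex weight vector (default uniform).
#' @rdname MixtureSpec-class
#' @export
MixtureSpec <- function(components, proportions = NULL) {
    components <- as.data.frame(components)
    if (is.null(proportions))
        proportions <- rep(1 / nrow(components), nrow(components))
    new("MixtureSpec", components = components,
        proportions = as.numeric(proportions))
}

#' @describeIn MixtureSpec-class the component table.
#' @param object,x a `MixtureSpec`.
#' @export
mixtureComponents <- function(object) object@components

#' @describeIn MixtureSpec-class the proportion vector, named by species.
#' @export
mixtureProportions <- function(object) {
    stats::setNames(object@proportions, object@components$species)
}

setMethod("show", "MixtureSpec", function(object) {
    cat(sprintf("MixtureSpec with %d component(s):\n", nrow(object@components)))
    df <- object@components
    df$proportion <- object@proportions
    print(df, row.names = FALSE)
})

#' Result of a proportion-unmixing fit
#'
#' Holds the estimated species proportions for one sample, the final
#' objective value, and optimizer diagnostics (generations, population
#' size, seed) so a fit is reproducible from its record alone.
#'
#' @slot proportions named numeric simplex vector.
#' @slot objective final objective value (lower is better).
#' @slot nObs number of observations used.
#' @slot converged logical.
#' @slot seed integer RNG seed of the fit.
#' @slot diagnostics list (generations, popSize, objectiveMethod).
#' @export
setClass("UnmixResult",
         representation(proportions = "numeric", objective = "numeric",
                        nObs = "integer", converged = "logical",
                        seed = "integer", diagnostics = "list"))

setValidity("UnmixResult", function(object) {
    p <- object@proportions
    if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6)
        return("proportions must lie on the simplex")
    if (!is.finite(object@objective)) return("objective must be finite")
    TRUE
})

#' @describeIn UnmixResult-class the estimated proportions (named).
#' @param object,x an `UnmixResult`.
#' @export
proportions <- function(object) object@proportions

setMethod("show", "UnmixResult", function(object) {
    cat(sprintf("UnmixResult (n = %d, %s, objective %.5g, seed %d):\n",
                object@nObs,
                if (object@converged) "converged" else "not converged",
                object@objective, object@seed))
    print(round(object@proportions, 4))
})
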
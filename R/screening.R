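#' Suitability screening of a grain mask
#'
#' Decides whether a grain can be measured, playing the role of the
#' suitable/unsuitable selection step that precedes measurement: only
#' intact single grains in polar view yield valid widths. The verdict is
#' rule-based and each rule contributes a reason code when violated:
#'
#' * `touches_border` — the grain touches the border of its source field
#'   of view (truncated outline, width undefined);
#' * `low_solidity` — area divided by convex-hull area below
#'   `solidityMin` (overlapping, folded or fragmented grains);
#' * `area_out_of_range` — calibrated area outside `areaGateUm2`;
#' * `multiple_components` — the raster holds more than one 4-connected
#'   object (only reachable for plain-matrix input; a valid
#'   [GrainMask-class] has exactly one).
#'
#' A verdict is suitable exactly when no reason fires. An external
#' suitability call (e.g. from a trained classifier, read from a CSV
#' column) overrides the heuristic when supplied.
#'
#' @param mask a [GrainMask-class], or a logical/numeric matrix.
#' @param calibration a [Calibration-class].
#' @param solidityMin minimum solidity (default 0.90).
#' @param areaGateUm2 accepted calibrated area range in um^2
#'   (default `c(150, 1500)`).
#' @param allowBorder if `TRUE`, border contact is not penalised.
#' @param external optional logical: an externally supplied verdict that
#'   replaces the heuristic (reasons then `"external_unsuitable"` or none).
#' @return list with elements `suitable` (logical) and `reasons`
#'   (character vector of codes, empty iff suitable).
#'
#' @examples
#' m <- matrix(FALSE, 101, 101)
#' m[(row(m) - 51)^2 + (col(m) - 51)^2 <= 40^2] <- TRUE
#' screenGrain(GrainMask(m), Calibration(0.25))
#' @export
screenGrain <- function(mask, calibration, solidityMin = 0.90,
                        areaGateUm2 = c(150, 1500), allowBorder = FALSE,
                        external = NULL) {
    validObject(calibration)
    if (!is.null(external)) {
        suitable <- isTRUE(external)
        return(list(suitable = suitable,
                    reasons = if (suitable) character()
                              else "external_unsuitable"))
    }
    if (is.matrix(mask)) {
        px <- if (is.logical(mask)) mask else mask != 0
        if (!any(px)) stop("mask has no foreground pixels")
        ncomp <- countComponents(px)
        touches <- any(px[1, ]) || any(px[nrow(px), ]) ||
            any(px[, 1]) || any(px[, ncol(px)])
    } else {
        stopIfEmptyMask(mask)
        px <- mask@pixels
        ncomp <- 1L
        touches <- touchesBorder(mask)
    }
    reasons <- character()
    if (!allowBorder && touches) reasons <- c(reasons, "touches_border")
    if (ncomp > 1L) reasons <- c(reasons, "multiple_components")
    area <- sum(px) * micronsPerPixel(calibration)^2
    if (area < areaGateUm2[1] || area > areaGateUm2[2])
        reasons <- c(reasons, "area_out_of_range")
    sol <- min(1, sum(px) / convexHullArea(px))
    if (sol < solidityMin) reasons <- c(reasons, "low_solidity")
    list(suitable = length(reasons) == 0L, reasons = reasons)
}

#' Solidity of a mask
#'
#' Foreground area divided by the area of its convex hull (computed over
#' pixel corners so both areas use the same pixel footprint); a proxy for
#' "intact single grain". Capped at 1.
#'
#' @param mask a [GrainMask-class] or logical matrix.
#' @return solidity in (0, 1].
#' @export
solidity <- function(mask) {
    px <- if (is.matrix(mask)) (if (is.logical(mask)) mask else mask != 0)
          else mask@pixels
    if (!any(px)) stop("mask has no foreground pixels")
    min(1, sum(px) / convexHullArea(px))
}
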
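#' @importFrom EBImage bwlabel fillHull otsu rotate Image imageData
NULL

## Connected-component labelling on a logical matrix (4-connectivity).
labelComponents <- function(px) {
    lab <- EBImage::bwlabel(matrix(as.numeric(px), nrow(px), ncol(px)))
    matrix(as.integer(EBImage::imageData(lab)), nrow(px), ncol(px))
}

countComponents <- function(px) {
    if (!any(px)) return(0L)
    max(labelComponents(px))
}

## 0-based (x = col, y = row) centers of foreground boundary pixels:
## pixels with at least one 4-neighbour outside the foreground (matrix
## edges count as outside). The Feret extent of the full pixel set is
## attained on this subset.
boundaryCoords <- function(px) {
    nr <- nrow(px); nc <- ncol(px)
    pad <- matrix(FALSE, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- px
    core <- pad[2:(nr + 1L), 2:(nc + 1L)]
    inner <- core &
        pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
        pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
    bnd <- core & !inner
    idx <- which(bnd, arr.ind = TRUE)
    cbind(x = idx[, 2L] - 1, y = idx[, 1L] - 1)
}

## Area of the convex hull of the foreground, computed over pixel *corners*
## (centers +/- 0.5) so it is on the same footing as the pixel-count area.
convexHullArea <- function(px) {
    bc <- boundaryCoords(px)
    if (nrow(bc) == 1L) return(1)
    corners <- rbind(
        cbind(bc[, 1] - 0.5, bc[, 2] - 0.5),
        cbind(bc[, 1] + 0.5, bc[, 2] - 0.5),
        cbind(bc[, 1] - 0.5, bc[, 2] + 0.5),
        cbind(bc[, 1] + 0.5, bc[, 2] + 0.5))
    h <- grDevices::chull(corners)
    xy <- corners[h, , drop = FALSE]
    polygonArea(xy[, 1], xy[, 2])
}

## Shoelace formula; vertices in hull order.
polygonArea <- function(x, y) {
    n <- length(x)
    j <- c(n, seq_len(n - 1L))
    abs(sum(x[j] * y - x * y[j])) / 2
}

## Tight bounding box of a logical matrix -> list(rows, cols) of index ranges.
bboxOf <- function(px) {
    rows <- which(rowSums(px) > 0)
    cols <- which(colSums(px) > 0)
    list(rows = range(rows), cols = range(cols))
}

## Crop a labelled object into a GrainMask carrying its provenance.
cropComponent <- function(lab, id, sourceDim, sourceId,
                          baseOffset = c(0L, 0L)) {
    px <- lab == id
    bb <- bboxOf(px)
    crop <- px[bb$rows[1]:bb$rows[2], bb$cols[1]:bb$cols[2], drop = FALSE]
    GrainMask(crop,
              originOffset = baseOffset + c(bb$rows[1] - 1L, bb$cols[1] - 1L),
              sourceDim = sourceDim, sourceId = sourceId)
}

## Rescale a numeric raster to [0, 1]; constant rasters map to 0.
normalize01 <- function(img) {
    rng <- range(img)
    if (rng[2] <= rng[1]) return(matrix(0, nrow(img), ncol(img)))
    (img - rng[1]) / (rng[2] - rng[1])
}

## Collapse an RGB(A) array read from PNG/TIFF to one grayscale channel.
collapseChannels <- function(a) {
    if (is.matrix(a)) return(a)
    if (length(dim(a)) == 3L) return(apply(a[, , seq_len(min(3, dim(a)[3])),
                                             drop = FALSE], c(1, 2), max))
    stop("cannot interpret raster with dimensions ",
         paste(dim(a), collapse = "x"))
}

stopIfEmptyMask <- function(mask) {
    if (sum(mask@pixels) < 1L) stop("mask has no foreground pixels")
    invisible(TRUE)
}
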
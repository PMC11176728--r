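## Shared shape builders and independent oracles for the test suite.

diskMask <- function(radius, margin = 4L) {
    size <- 2L * (ceiling(radius) + margin) + 1L
    c0 <- (size + 1) / 2
    m <- (row(matrix(0, size, size)) - c0)^2 +
         (col(matrix(0, size, size)) - c0)^2 <= radius^2
    m
}

squareMask <- function(side, margin = 4L) {
    size <- side + 2L * margin
    m <- matrix(FALSE, size, size)
    m[(margin + 1):(margin + side), (margin + 1):(margin + side)] <- TRUE
    m
}

rectMask <- function(h, w, margin = 4L) {
    m <- matrix(FALSE, h + 2L * margin, w + 2L * margin)
    m[(margin + 1):(margin + h), (margin + 1):(margin + w)] <- TRUE
    m
}

## Axis-aligned ellipse (optionally rotated by `deg`), semi-axes a (x), b (y).
ellipseMask <- function(a, b, deg = 0, margin = 4L) {
    rmax <- ceiling(max(a, b))
    size <- 2L * (rmax + margin) + 1L
    c0 <- (size + 1) / 2
    x <- col(matrix(0, size, size)) - c0
    y <- row(matrix(0, size, size)) - c0
    th <- deg * pi / 180
    xr <- x * cos(th) + y * sin(th)
    yr <- -x * sin(th) + y * cos(th)
    (xr / a)^2 + (yr / b)^2 <= 1
}

## Continuous perimeter of an ellipse by numerical quadrature.
ellipsePerimeter <- function(a, b) {
    f <- function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
    stats::integrate(f, 0, 2 * pi, rel.tol = 1e-10)$value
}

## Brute-force raster-rotation width oracle: rotate the binary raster and
## measure the extent of the rotated object along the first matrix axis.
rasterRotationWidth <- function(px, thetaDeg, k = 4L) {
    # upsample k-fold so each pixel becomes a k x k block, center-pad into
    # a square so nothing leaves the frame, rotate the raster, and measure
    # the horizontal extent of the rotated object at fine resolution
    up <- kronecker(matrix(as.numeric(px), nrow(px), ncol(px)),
                    matrix(1, k, k))
    D <- ceiling(sqrt(sum(dim(up)^2))) + 8L
    pad <- matrix(0, D, D)
    r0 <- floor((D - nrow(up)) / 2); c0 <- floor((D - ncol(up)) / 2)
    pad[(r0 + 1):(r0 + nrow(up)), (c0 + 1):(c0 + ncol(up))] <- up
    r <- EBImage::rotate(EBImage::Image(pad), thetaDeg, bg.col = 0)
    M <- EBImage::imageData(r) > 0.5
    cols <- which(colSums(M) > 0)
    if (!length(cols)) return(NA_real_)
    (max(cols) - min(cols) + 1) / k
}

## Straight-line z-score filter oracle, written as a direct transcription
## of the rule: per pass, drop |x - mean| / sd > threshold, re-estimating
## on survivors; skip a pass when sd = 0 or fewer than 3 values remain.
zscoreOracle <- function(x, threshold = 2.5, passes = 2L) {
    for (p in seq_len(passes)) {
        if (length(x) < 3) return(x)
        mu <- mean(x); s <- sd(x)
        if (s == 0) return(x)
        x <- x[abs((x - mu) / s) <= threshold]
    }
    x
}

## EM for mixture weights with fixed normal components: the independent
## maximum-likelihood oracle for the NLL-objective proportion fit.
emWeights <- function(x, means, sds, maxIter = 2000L, tol = 1e-12) {
    K <- length(means)
    dens <- sapply(seq_len(K), function(k) dnorm(x, means[k], sds[k]))
    dens <- matrix(dens, ncol = K)
    p <- rep(1 / K, K)
    for (it in seq_len(maxIter)) {
        num <- sweep(dens, 2, p, "*")
        resp <- num / pmax(rowSums(num), 1e-300)
        pNew <- colMeans(resp)
        if (max(abs(pNew - p)) < tol) { p <- pNew; break }
        p <- pNew
    }
    p
}

## Paste a crop-with-offset mask back onto its source canvas.
fullCanvasMask <- function(gm) {
    M <- matrix(FALSE, gm@sourceDim[1], gm@sourceDim[2])
    px <- maskPixels(gm)
    off <- gm@originOffset
    M[(off[1] + 1):(off[1] + nrow(px)), (off[2] + 1):(off[2] + ncol(px))] <- px
    M
}

maskIoU <- function(a, b) {
    A <- fullCanvasMask(a); B <- fullCanvasMask(b)
    sum(A & B) / sum(A | B)
}

referenceComponents <- function(species = c("B. nana", "B. pubescens"),
                                metric = "mean_width") {
    ref <- betulaReference(metric)
    ref[match(species, ref$species), , drop = FALSE]
}
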
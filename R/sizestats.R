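#' Per-sample series of grain sizes
#'
#' One stratigraphic sample's measurements of a single size metric
#' (either `"area"` in um^2 or `"mean_width"` in um).
#'
#' @slot sampleId character label.
#' @slot depth numeric depth in cm (`NA` if unknown).
#' @slot values positive numeric measurements.
#' @slot metric `"area"` or `"mean_width"`.
#' @export
setClass("SampleSeries",
         representation(sampleId = "character", depth = "numeric",
                        values = "numeric", metric = "character"))

setValidity("SampleSeries", function(object) {
    if (!object@metric %in% c("area", "mean_width"))
        return("metric must be 'area' or 'mean_width'")
    if (length(object@values) && any(object@values <= 0))
        return("values must be positive")
    TRUE
})

#' @param sampleId text label.
#' @param values numeric measurements (> 0).
#' @param depth depth in cm, `NA` allowed.
#' @param metric `"area"` or `"mean_width"`.
#' @rdname SampleSeries-class
#' @export
SampleSeries <- function(sampleId, values, depth = NA_real_,
                         metric = "mean_width") {
    new("SampleSeries", sampleId = as.character(sampleId),
        depth = as.numeric(depth), values = as.numeric(values),
        metric = metric)
}

setMethod("show", "SampleSeries", function(object) {
    cat(sprintf("SampleSeries '%s' (depth %s cm): %d %s value(s)\n",
                object@sampleId,
                if (is.na(object@depth)) "?" else format(object@depth),
                length(object@values), object@metric))
})

#' Pooled run of consecutive samples
#'
#' Concatenation of `binSize` consecutive stratigraphic samples, carrying
#' the member order, the pooled count for downstream minimum-count gating,
#' and a flag marking a trailing partial bin.
#'
#' @slot memberSampleIds character, in stratigraphic order.
#' @slot depths numeric depths of the members.
#' @slot values concatenated member values.
#' @slot metric size metric of the members.
#' @slot complete `FALSE` for a trailing bin with fewer members.
#' @export
setClass("PooledSeries",
         representation(memberSampleIds = "character", depths = "numeric",
                        values = "numeric", metric = "character",
                        complete = "logical"))

setMethod("show", "PooledSeries", function(object) {
    cat(sprintf("PooledSeries [%s]: n = %d%s\n",
                paste(object@memberSampleIds, collapse = ","),
                length(object@values),
                if (object@complete) "" else " (partial bin)"))
})

#' @describeIn PooledSeries-class pooled number of grains.
#' @param object a `PooledSeries`.
#' @export
pooledN <- function(object) length(object@values)

#' Iterative z-score outlier removal
#'
#' Removes exceptionally small and large measurements — typically
#' segmentation failures on detritus or fused grains — by discarding
#' values whose z-score exceeds `threshold` in absolute value. The filter
#' runs for `passes` rounds, re-estimating the mean and sample SD on the
#' survivors between rounds (otherwise a second pass would never remove
#' anything). A pass removes nothing when the SD is zero or fewer than
#' three values remain, so degenerate inputs pass through unchanged. The
#' output is always a subsequence of the input.
#'
#' @param values non-empty numeric vector.
#' @param threshold absolute z-score cut (default 2.5).
#' @param passes number of filtering rounds (default 2).
#' @return the surviving values, in input order.
#'
#' @examples
#' zscoreFilter(c(rep(20, 49), 60))  # the 60 is removed in pass 1
#' @export
zscoreFilter <- function(values, threshold = 2.5, passes = 2L) {
    if (length(values) == 0L) stop("values must be non-empty")
    stopifnot(threshold > 0, passes >= 0)
    out <- values
    for (p in seq_len(passes)) {
        if (length(out) < 3L) break
        s <- stats::sd(out)
        if (!is.finite(s) || s == 0) break
        z <- abs(out - mean(out)) / s
        out <- out[z <= threshold]
    }
    out
}

#' Pool consecutive stratigraphic samples
#'
#' Groups a depth-ordered list of [SampleSeries-class] into consecutive,
#' non-overlapping bins of `binSize` samples and concatenates their
#' values, so sparse 1-cm samples reach a workable grain count. A trailing
#' bin with fewer members is kept and flagged `complete = FALSE`. The
#' pooled count is carried for downstream gating (the minimum-count rule,
#' by default 25 grains, is applied by consumers such as
#' [unmixRecord()], not here).
#'
#' @param seriesList list of [SampleSeries-class], sorted by depth.
#' @param binSize number of consecutive samples per bin (default 5).
#' @return list of [PooledSeries-class].
#'
#' @examples
#' sl <- lapply(1:12, function(i)
#'     SampleSeries(paste0("s", i), rnorm(10, 22, 1), depth = i))
#' length(poolSeries(sl, 5))  # 3 bins, the last one partial
#' @export
poolSeries <- function(seriesList, binSize = 5L) {
    stopifnot(binSize >= 1L)
    if (length(seriesList) == 0L) return(list())
    metrics <- unique(vapply(seriesList, function(s) s@metric, character(1)))
    if (length(metrics) != 1L)
        stop("all series must share one metric; got: ",
             paste(metrics, collapse = ", "))
    depths <- vapply(seriesList, function(s) s@depth, numeric(1))
    if (!any(is.na(depths)) && is.unsorted(depths))
        stop("series must be sorted by depth")
    idx <- split(seq_along(seriesList),
                 ceiling(seq_along(seriesList) / binSize))
    lapply(idx, function(i) {
        members <- seriesList[i]
        new("PooledSeries",
            memberSampleIds = vapply(members, function(s) s@sampleId,
                                     character(1)),
            depths = vapply(members, function(s) s@depth, numeric(1)),
            values = unlist(lapply(members, function(s) s@values)),
            metric = metrics,
            complete = length(members) == binSize)
    })
}

#' Gaussian kernel density estimate of a size distribution
#'
#' Density curve of a per-sample (or pooled) size distribution, as used
#' for stratigraphic ridgeline diagrams. Gaussian kernel with Silverman's
#' rule-of-thumb bandwidth by default (the `nrd0` rule, matching standard
#' plotting defaults), evaluated on a grid wide enough that the curve
#' integrates to 1 within 1%.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param grid optional numeric grid to evaluate on; by default 512 points
#'   spanning the data plus three bandwidths.
#' @param bandwidth kernel bandwidth in data units, or `"auto"`.
#' @return data.frame with columns `x` and `density`.
#'
#' @examples
#' d <- sizeDensity(rnorm(500, 23, 1.2))
#' sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2)
#' @export
sizeDensity <- function(values, grid = NULL, bandwidth = "auto") {
    if (length(unique(values)) < 2L)
        stop("density needs at least 2 distinct values")
    bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(values)
          else as.numeric(bandwidth)
    if (is.null(grid)) {
        d <- stats::density(values, bw = bw, kernel = "gaussian", n = 512,
                            cut = 4)
        data.frame(x = d$x, density = d$y)
    } else {
        d <- stats::density(values, bw = bw, kernel = "gaussian",
                            n = length(grid), from = min(grid),
                            to = max(grid))
        data.frame(x = d$x, density = d$y)
    }
}

#' Mean, SD and count of a size series
#'
#' The summary format of the reference tables: arithmetic mean, sample SD
#' (n - 1 denominator) and grain count. A single-value series reports
#' SD = 0 with a QC note instead of `NA`.
#'
#' @param values non-empty numeric vector.
#' @return list with `mean`, `sd`, `n` and `qc` (character, possibly empty).
#'
#' @examples
#' summarizeSizes(c(1, 2, 3))  # mean 2, sd 1, n 3
#' @export
summarizeSizes <- function(values) {
    if (length(values) == 0L) stop("values must be non-empty")
    n <- length(values)
    if (n == 1L)
        return(list(mean = values, sd = 0, n = 1L, qc = "single_value_sd_undefined"))
    list(mean = mean(values), sd = stats::sd(values), n = n, qc = character())
}

#' Density curves for a pooled record
#'
#' Convenience wrapper producing one long data.frame of density curves for
#' a list of [PooledSeries-class], suitable for writing as the package's
#' density-curve CSV (columns `sample_id`, `x`, `density`).
#'
#' @param pooledList list of [PooledSeries-class].
#' @param gridN points per curve (default 256).
#' @return data.frame with columns `sample_id`, `x`, `density`.
#' @export
recordDensities <- function(pooledList, gridN = 256L) {
    rows <- lapply(pooledList, function(ps) {
        if (length(unique(ps@values)) < 2L) return(NULL)
        d <- stats::density(ps@values, bw = stats::bw.nrd0(ps@values),
                            n = gridN, cut = 4)
        data.frame(sample_id = paste(ps@memberSampleIds, collapse = "+"),
                   x = d$x, density = d$y, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(sample_id = character(), x = numeric(),
                          density = numeric()))
    do.call(rbind, rows)
}
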
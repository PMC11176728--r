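#' Reference size parameters of modern birch species
#'
#' Returns the packaged reference table of per-species size parameters
#' (mean and SD of the rotational mean width in um, or of the grain area
#' in um^2) measured on modern pollen of four birch species mounted in
#' silicone oil: *Betula nana* (dwarf birch), *B. humilis*, *B. pendula*
#' and *B. pubescens* (tree birches). These are the fixed component
#' parameters of the unmixing model; reference and fossil material must
#' share the mounting medium, because mounting systematically alters
#' grain size.
#'
#' @param metric `"mean_width"` (um) or `"area"` (um^2).
#' @return data.frame with columns `species`, `metric`, `mean`, `sd`, `n`,
#'   `mounting_medium`.
#'
#' @examples
#' betulaReference("mean_width")
#' @export
betulaReference <- function(metric = c("mean_width", "area")) {
    metric <- match.arg(metric)
    path <- system.file("extdata", "betula_reference_silicone.csv",
                        package = "betulaSize", mustWork = TRUE)
    ref <- read.csv(path, stringsAsFactors = FALSE)
    ref[ref$metric == metric, , drop = FALSE]
}

#' Compound (mixture-of-normals) size density
#'
#' The model density of a mixed sample: each birch species contributes a
#' normal component with fixed mean and SD, weighted by its pollen
#' proportion; the sample density is the proportion-weighted sum. The
#' density is non-negative and integrates to 1.
#'
#' @param x numeric vector of sizes.
#' @param spec a [MixtureSpec-class].
#' @return density values at `x`.
#'
#' @examples
#' spec <- MixtureSpec(data.frame(species = "a", mean = 20, sd = 1), 1)
#' mixturePdf(20, spec)  # 1 / sqrt(2 * pi)
#' @export
mixturePdf <- function(x, spec) {
    validObject(spec)
    as.numeric(componentDensities(x, spec@components) %*% spec@proportions)
}

## n x K matrix of per-component normal densities.
componentDensities <- function(x, components) {
    K <- nrow(components)
    matrix(vapply(seq_len(K), function(i)
        stats::dnorm(x, components$mean[i], components$sd[i]),
        numeric(length(x))), ncol = K)
}

#' Similarity objective between observed sizes and a mixture model
#'
#' Scores how well a compound distribution explains the observed size
#' values; lower is better. Two deterministic metrics are available:
#'
#' * `"nll"` (default): the mean negative log of the mixture density over
#'   the observations — the per-observation negative log-likelihood.
#'   Densities are floored at `1e-300` so far-outlying observations clamp
#'   rather than error.
#' * `"histL2"`: squared L2 distance between the empirical histogram
#'   probabilities and the model bin probabilities, on a fixed grid of 50
#'   bins spanning the observations and every component's mean +/- 5 SD —
#'   a more literal "distribution similarity".
#'
#' Both are invariant under relabeling of components and under
#' duplication of the observation vector.
#'
#' @param observations non-empty numeric vector.
#' @param spec a [MixtureSpec-class].
#' @param method `"nll"` or `"histL2"`.
#' @return scalar objective value.
#' @export
mixtureObjective <- function(observations, spec, method = c("nll", "histL2")) {
    method <- match.arg(method)
    if (length(observations) == 0L) stop("observations must be non-empty")
    validObject(spec)
    if (method == "nll") {
        D <- componentDensities(observations, spec@components)
        nllObjective(spec@proportions, D)
    } else {
        bp <- binProbabilities(observations, spec@components)
        histL2Objective(spec@proportions, bp$empirical, bp$model)
    }
}

nllObjective <- function(p, D) {
    mean(-log(pmax(as.numeric(D %*% p), 1e-300)))
}

histL2Objective <- function(p, empirical, modelBinMatrix) {
    sum((empirical - as.numeric(modelBinMatrix %*% p))^2)
}

## Fixed deterministic binning shared by data and model.
binProbabilities <- function(observations, components, nBins = 50L) {
    lo <- min(min(observations), min(components$mean - 5 * components$sd))
    hi <- max(max(observations), max(components$mean + 5 * components$sd))
    breaks <- seq(lo, hi, length.out = nBins + 1L)
    counts <- tabulate(findInterval(observations, breaks,
                                    rightmost.closed = TRUE,
                                    all.inside = TRUE), nBins)
    model <- vapply(seq_len(nrow(components)), function(i) {
        diff(stats::pnorm(breaks, components$mean[i], components$sd[i]))
    }, numeric(nBins))
    list(empirical = counts / length(observations), model = model,
         breaks = breaks)
}

#' Estimate species proportions by differential evolution
#'
#' Fits the proportion vector of a compound size distribution with the
#' component means and SDs held fixed at their reference values: only the
#' mixing proportions are free. The optimiser is classic differential
#' evolution (DE/rand/1/bin) over K non-negative raw weights in
#' `[0, 1]^K`, normalised by their sum onto the simplex before
#' evaluation; all-zero candidates are re-sampled. Defaults: population
#' `10 * K`, mutation factor F = 0.8, crossover CR = 0.9, 200
#' generations, all driven by `seed`, so a fit is exactly reproducible.
#'
#' A minimum observation count (default 25 grains) gates the fit, since
#' proportion estimates from sparser samples are unstable. With a single
#' component the proportion is 1 by construction and no optimisation
#' runs. A degenerate sample (zero variance) is fitted but flagged
#' `converged = FALSE`.
#'
#' @param observations numeric size values (one metric).
#' @param components data.frame with columns `species`, `mean`, `sd`
#'   (1 to 4 rows), e.g. from [betulaReference()].
#' @param seed integer RNG seed (default 1).
#' @param nGenerations,popSize,F,CR differential-evolution settings;
#'   `popSize` defaults to `10 * K`.
#' @param minObs minimum observation count (default 25).
#' @param objective `"nll"` or `"histL2"` (see [mixtureObjective()]).
#' @param locationShift optional shared location shift (um or um^2) added
#'   to every component mean before fitting, to absorb a known
#'   preparation-related size offset (default 0 = off).
#' @return an [UnmixResult-class].
#'
#' @examples
#' ref <- betulaReference("mean_width")
#' cmp <- ref[ref$species %in% c("B. nana", "B. pubescens"), ]
#' x <- sampleSizes(cmp, c(0.3, 0.7), n = 400, seed = 7)$values
#' fitProportions(x, cmp, seed = 7)
#' @export
fitProportions <- function(observations, components, seed = 1L,
                           nGenerations = 200L, popSize = NULL, F = 0.8,
                           CR = 0.9, minObs = 25L,
                           objective = c("nll", "histL2"),
                           locationShift = 0) {
    objective <- match.arg(objective)
    components <- as.data.frame(components)
    K <- nrow(components)
    if (K < 1L || K > 4L)
        stop("between 1 and 4 components are supported, got ", K)
    if (any(components$sd <= 0)) stop("component sd must be > 0")
    n <- length(observations)
    if (n < minObs)
        stop("need at least ", minObs, " observations, got ", n)
    if (locationShift != 0) components$mean <- components$mean + locationShift
    seed <- as.integer(seed)
    degenerate <- stats::sd(observations) == 0

    if (K == 1L) {
        spec <- MixtureSpec(components, 1)
        return(new("UnmixResult",
                   proportions = stats::setNames(1, components$species),
                   objective = mixtureObjective(observations, spec, objective),
                   nObs = n, converged = !degenerate, seed = seed,
                   diagnostics = list(generations = 0L, popSize = 0L,
                                      objectiveMethod = objective)))
    }

    ## Precompute the data-dependent pieces once; DE then only does
    ## K-vector algebra per candidate.
    if (objective == "nll") {
        D <- componentDensities(observations, components)
        evalFn <- function(p) nllObjective(p, D)
    } else {
        bp <- binProbabilities(observations, components)
        evalFn <- function(p) histL2Objective(p, bp$empirical, bp$model)
    }
    if (is.null(popSize)) popSize <- 10L * K

    de <- withr::with_seed(seed, deOptimizeSimplex(evalFn, K, popSize,
                                                   nGenerations, F, CR))
    converged <- !degenerate && de$spread < 1e-6 * (1 + abs(de$best))
    new("UnmixResult",
        proportions = stats::setNames(de$proportions, components$species),
        objective = de$best, nObs = n, converged = converged, seed = seed,
        diagnostics = list(generations = nGenerations, popSize = popSize,
                           objectiveMethod = objective))
}

## DE/rand/1/bin on K raw weights in [0,1]^K, evaluated after simplex
## normalisation. Returns the best normalised proportions.
deOptimizeSimplex <- function(evalFn, K, popSize, nGenerations, F, CR) {
    drawWeights <- function() {
        w <- stats::runif(K)
        while (sum(w) == 0) w <- stats::runif(K)
        w
    }
    pop <- t(vapply(seq_len(popSize), function(i) drawWeights(), numeric(K)))
    fitness <- apply(pop, 1L, function(w) evalFn(w / sum(w)))
    for (g in seq_len(nGenerations)) {
        for (i in seq_len(popSize)) {
            others <- sample(setdiff(seq_len(popSize), i), 3L)
            mutant <- pop[others[1], ] +
                F * (pop[others[2], ] - pop[others[3], ])
            mutant <- pmin(pmax(mutant, 0), 1)
            cross <- stats::runif(K) < CR
            cross[sample.int(K, 1L)] <- TRUE  # at least one mutant gene
            trial <- ifelse(cross, mutant, pop[i, ])
            if (sum(trial) == 0) trial <- drawWeights()
            f <- evalFn(trial / sum(trial))
            if (f <= fitness[i]) {
                pop[i, ] <- trial
                fitness[i] <- f
            }
        }
    }
    bestIdx <- which.min(fitness)
    w <- pop[bestIdx, ]
    list(proportions = w / sum(w), best = fitness[bestIdx],
         spread = max(fitness) - min(fitness))
}

#' Unmix a stratigraphic record
#'
#' Runs the per-sample unmixing over a pooled record: each
#' [PooledSeries-class] is z-score filtered, gated on the minimum grain
#' count, and fitted with [fitProportions()]. Samples failing the gate
#' appear in the output with missing proportions and a reason code, so
#' the stratigraphic table stays complete.
#'
#' @param pooledList list of [PooledSeries-class] (see [poolSeries()]).
#' @param components reference component table (1 to 4 rows).
#' @param seed base seed; sample `i` is fitted with `seed + i - 1`.
#' @param zscoreThreshold,zscorePasses outlier-filter settings
#'   (see [zscoreFilter()]).
#' @param minGrains minimum pooled grain count after filtering
#'   (default 25).
#' @param objective objective method passed to [fitProportions()].
#' @return data.frame with one row per pooled sample: `sample_id`,
#'   `depth` (mean member depth), `n`, one `p_<species>` column per
#'   component, `objective`, `converged`, `seed`, `reason`.
#'
#' @examples
#' ref <- betulaReference("mean_width")
#' cmp <- ref[ref$species %in% c("B. nana", "B. pubescens"), ]
#' rec <- makeStratigraphicRecord(depths = 1:5,
#'     proportionProfile = cbind(seq(0.1, 0.9, length.out = 5),
#'                               seq(0.9, 0.1, length.out = 5)),
#'     components = cmp, nPerSample = 60, seed = 3)
#' unmixRecord(poolSeries(rec, 1), cmp, seed = 3)
#' @export
unmixRecord <- function(pooledList, components, seed = 1L,
                        zscoreThreshold = 2.5, zscorePasses = 2L,
                        minGrains = 25L, objective = "nll") {
    components <- as.data.frame(components)
    if (length(pooledList) == 0L)
        return(emptyUnmixTable(components))
    rows <- lapply(seq_along(pooledList), function(i) {
        ps <- pooledList[[i]]
        id <- paste(ps@memberSampleIds, collapse = "+")
        depth <- mean(ps@depths)
        vals <- zscoreFilter(ps@values, threshold = zscoreThreshold,
                             passes = zscorePasses)
        base <- data.frame(sample_id = id, depth = depth,
                           n = length(vals), stringsAsFactors = FALSE)
        pcols <- paste0("p_", gsub("[^A-Za-z0-9]+", "_", components$species))
        if (length(vals) < minGrains) {
            base[pcols] <- NA_real_
            base$objective <- NA_real_
            base$converged <- NA
            base$seed <- NA_integer_
            base$reason <- sprintf("below_min_count_%d", minGrains)
            return(base)
        }
        fit <- fitProportions(vals, components, seed = seed + i - 1L,
                              minObs = minGrains, objective = objective)
        base[pcols] <- as.list(unname(fit@proportions))
        base$objective <- fit@objective
        base$converged <- fit@converged
        base$seed <- fit@seed
        base$reason <- ""
        base
    })
    do.call(rbind, rows)
}

emptyUnmixTable <- function(components) {
    pcols <- paste0("p_", gsub("[^A-Za-z0-9]+", "_", components$species))
    df <- data.frame(sample_id = character(), depth = numeric(),
                     n = integer(), stringsAsFactors = FALSE)
    for (pc in pcols) df[[pc]] <- numeric()
    df$objective <- numeric()
    df$converged <- logical()
    df$seed <- integer()
    df$reason <- character()
    df
}
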
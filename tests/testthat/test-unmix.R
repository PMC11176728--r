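cmp2 <- referenceComponents(c("B. nana", "B. pubescens"))
cmp3 <- referenceComponents(c("B. nana", "B. pendula", "B. pubescens"))

test_that("mixture density is a weighted sum of normals and normalizes", {
    s1 <- MixtureSpec(data.frame(species = "a", mean = 20, sd = 1), 1)
    expect_equal(mixturePdf(20, s1), 1 / sqrt(2 * pi))

    # symmetric two-component mixture at the midpoint: average of either
    s2 <- MixtureSpec(data.frame(species = c("a", "b"), mean = c(19, 21),
                                 sd = c(1, 1)), c(0.5, 0.5))
    expect_equal(mixturePdf(20, s2),
                 0.5 * dnorm(20, 19, 1) + 0.5 * dnorm(20, 21, 1))

    spec <- MixtureSpec(cmp2, c(0.3, 0.7))
    grid <- seq(min(cmp2$mean) - 8 * max(cmp2$sd),
                max(cmp2$mean) + 8 * max(cmp2$sd), length.out = 4001)
    y <- mixturePdf(grid, spec)
    expect_true(all(y >= 0))
    integral <- sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2)
    expect_equal(integral, 1, tolerance = 1e-3)
})

test_that("the objective has its closed form and mean invariances", {
    s1 <- MixtureSpec(data.frame(species = "a", mean = 20, sd = 2), 1)
    obs <- rep(20, 10)
    expect_equal(mixtureObjective(obs, s1), -log(1 / (2 * sqrt(2 * pi))))

    x <- withr::with_seed(1, rnorm(200, 21, 1.5))
    spec <- MixtureSpec(cmp2, c(0.4, 0.6))
    expect_equal(mixtureObjective(c(x, x), spec), mixtureObjective(x, spec))
    expect_equal(mixtureObjective(c(x, x), spec, "histL2"),
                 mixtureObjective(x, spec, "histL2"))

    # relabeling invariance
    specR <- MixtureSpec(cmp2[2:1, ], c(0.6, 0.4))
    expect_equal(mixtureObjective(x, specR), mixtureObjective(x, spec))

    # an observation far outside all components clamps, no error
    expect_true(is.finite(mixtureObjective(c(x, 1e6), spec)))

    # at large n the truth beats a degenerate corner
    x2 <- sampleSizes(cmp2, c(0.5, 0.5), 2000, seed = 8)$values
    expect_lt(mixtureObjective(x2, MixtureSpec(cmp2, c(0.5, 0.5))),
              mixtureObjective(x2, MixtureSpec(cmp2, c(1, 0))))
})

test_that("single-component fits are exact and gates enforce their bounds", {
    x <- withr::with_seed(2, rnorm(100, 20.5, 0.9))
    fit <- fitProportions(x, cmp2[1, , drop = FALSE], seed = 1)
    expect_identical(unname(proportions(fit)), 1)
    expect_true(fit@converged)

    expect_error(fitProportions(x[1:10], cmp2, seed = 1), "25")
    big <- do.call(rbind, rep(list(cmp2), 3))[1:5, ]
    expect_error(fitProportions(x, big, seed = 1), "1 and 4")

    # all-identical observations: degenerate, flagged non-converged
    degen <- fitProportions(rep(21, 40), cmp2, seed = 1)
    expect_false(degen@converged)
})

test_that("differential evolution matches the EM-for-weights oracle", {
    for (s in c(3, 14, 27)) {
        x <- sampleSizes(cmp2, c(0.35, 0.65), 500, seed = s)$values
        fit <- fitProportions(x, cmp2, seed = s)
        em <- emWeights(x, cmp2$mean, cmp2$sd)
        expect_lt(max(abs(proportions(fit) - em)), 0.01)
    }
    # three components, single-species truth: dominant component found
    x3 <- sampleSizes(cmp3[3, , drop = FALSE], 1, 1000, seed = 5)$values
    fit3 <- fitProportions(x3, cmp3, seed = 5)
    expect_gte(proportions(fit3)[["B. pubescens"]], 0.9)
    em3 <- emWeights(x3, cmp3$mean, cmp3$sd)
    expect_lt(max(abs(proportions(fit3) - em3)), 0.01)
})

test_that("fits are deterministic per seed and permutation equivariant", {
    x <- sampleSizes(cmp2, c(0.5, 0.5), 400, seed = 21)$values
    f1 <- fitProportions(x, cmp2, seed = 21)
    f2 <- fitProportions(x, cmp2, seed = 21)
    expect_identical(proportions(f1), proportions(f2))
    expect_identical(f1@objective, f2@objective)

    fPerm <- fitProportions(x, cmp2[2:1, ], seed = 21)
    expect_equal(proportions(fPerm)[names(proportions(f1))],
                 proportions(f1), tolerance = 0.01)
})

test_that("the histogram-L2 objective also recovers mixing proportions", {
    x <- sampleSizes(cmp2, c(0.3, 0.7), 1000, seed = 17)$values
    fit <- fitProportions(x, cmp2, seed = 17, objective = "histL2")
    expect_lt(abs(proportions(fit)[[1]] - 0.3), 0.07)
})

test_that("unmixRecord filters, gates and tabulates per pooled sample", {
    rec <- makeStratigraphicRecord(
        depths = 1:3,
        proportionProfile = rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.1, 0.9)),
        components = cmp2, nPerSample = 500, seed = 31)
    tab <- unmixRecord(poolSeries(rec, 1), cmp2, seed = 31)
    expect_identical(nrow(tab), 3L)
    # recovered dwarf-birch share is monotone in the generating gradient
    expect_true(all(diff(tab$p_B_nana) < 0))
    expect_lt(max(abs(tab$p_B_nana - c(0.9, 0.5, 0.1))), 0.1)

    # a sparse sample is flagged, not fitted
    sparse <- list(SampleSeries("tiny", rnorm(10, 21, 1), depth = 1),
                   SampleSeries("ok", sampleSizes(cmp2, c(0.5, 0.5), 200,
                                                  seed = 2)$values, depth = 2))
    tab2 <- unmixRecord(poolSeries(sparse, 1), cmp2, seed = 1)
    expect_true(is.na(tab2$p_B_nana[1]))
    expect_match(tab2$reason[1], "below_min_count")
    expect_false(is.na(tab2$p_B_nana[2]))

    expect_identical(nrow(unmixRecord(list(), cmp2)), 0L)
})
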
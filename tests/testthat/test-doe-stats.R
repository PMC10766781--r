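# Fast record generator: per-replicate selectivity laid out over the design
# without simulating spectra, for tests that target the ANOVA machinery.
directRecords <- function(design, mu, noiseSD = 0, replicates = 2,
                          seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    runs <- designRuns(design)
    do.call(rbind, lapply(seq_len(replicates), function(r)
        data.frame(species = "OOO", ox_degree = 3,
                   condition_set = runs$run_id,
                   selectivity = exp(log(mu(runs)) +
                                         rnorm(nrow(runs), 0, noiseSD)),
                   replicate = r)))
}

test_that("the ANOVA decomposition is complete and balanced", {
    des <- generateDesign()
    recs <- directRecords(des, function(r) 2 * 1.5^(r$A == 1),
                          noiseSD = 0.2, seed = 1)
    fit <- fitSelectivityAnova(recs, des, transform = "log")
    tab <- anovaTable(fit)
    expect_identical(tab$term[1:5], LETTERS[1:5])
    expect_equal(tab$df[1:5], rep(2, 5))
    expect_equal(sum(tab$df[grepl(":", tab$term)]), 40)  # 10 x 4 df
    # partition of total SS
    y <- log(recs$selectivity)
    expect_equal(sum(tab$sum_sq), sum((y - mean(y))^2), tolerance = 1e-8)

    # main-effect SS equals the closed-form between-level SS (54 obs/level)
    lvl <- designRuns(des)$A[match(recs$condition_set,
                                   designRuns(des)$run_id)]
    means <- tapply(y, lvl, mean)
    ssA <- 54 * sum((means - mean(y))^2)
    expect_equal(tab$sum_sq[tab$term == "A"], ssA, tolerance = 1e-8)
})

test_that("ANOVA results are invariant to run reordering", {
    des <- generateDesign()
    recs <- directRecords(des, function(r) 1.5 + 0.3 * r$C, noiseSD = 0.1,
                          seed = 2)
    fit1 <- fitSelectivityAnova(recs, des, transform = "log")
    fit2 <- fitSelectivityAnova(recs[sample(nrow(recs)), ], des,
                                transform = "log")
    expect_equal(anovaTable(fit1)$sum_sq, anovaTable(fit2)$sum_sq,
                 tolerance = 1e-10)
})

test_that("a planted additive effect is detected and inert factors are not", {
    des <- generateDesign()
    hits <- vapply(1:50, function(seed) {
        recs <- directRecords(des, function(r) c(1, 3, 2)[r$A + 1],
                              noiseSD = 0.3, seed = seed)
        tab <- anovaTable(fitSelectivityAnova(recs, des, transform = "log"))
        c(A = tab$p[tab$term == "A"] < 0.05,
          E = tab$p[tab$term == "E"] < 0.05)
    }, logical(2))
    expect_gte(sum(hits["A", ]), 48)
    # E is inert: its rejections are type-I errors, bounded by the
    # 99.9 % binomial quantile at the nominal 5 % level
    expect_lte(sum(hits["E", ]), qbinom(0.999, 50, 0.05))
})

test_that("a constant response yields zero sums of squares", {
    des <- generateDesign()
    recs <- directRecords(des, function(r) rep(2, nrow(r)))
    fit <- fitSelectivityAnova(recs, des)
    tab <- anovaTable(fit)
    expect_true(all(tab$sum_sq < 1e-20))
})

test_that("saturated fits and bad inputs fail loudly", {
    des <- generateDesign()
    recs <- directRecords(des, function(r) 1 + r$B, noiseSD = 0.1,
                          replicates = 1, seed = 3)
    # 81 single replicates with the full two-way model: 30 residual df, fits
    expect_s4_class(fitSelectivityAnova(recs, des), "SelectivityAnova")
    # two responses mixed
    recs2 <- rbind(recs, transform(recs, ox_degree = 1))
    expect_error(fitSelectivityAnova(recs2, des), "2 responses")
    recs3 <- transform(recs, condition_set = condition_set + 100)
    expect_error(fitSelectivityAnova(recs3, des), "absent from the design")
    # non-finite records are excluded with a message
    recs$selectivity[1] <- Inf
    expect_message(fitSelectivityAnova(recs, des), "excluded")
})

test_that("Tukey comparisons separate and equate level means correctly", {
    des <- generateDesign()
    # NaOAc (level 1) planted far above NH4Fo (level 0)
    recs <- directRecords(des, function(r) c(1, 6, 4)[r$A + 1],
                          noiseSD = 0.2, seed = 4)
    fit <- fitSelectivityAnova(recs, des, transform = "log")
    tk <- tukeyComparisons(fit, "A")
    cmp10 <- tk[tk$comparison == "1-0", ]
    expect_true(cmp10$significant)
    expect_gt(cmp10$lwr, 0)

    # response untouched by E: its level means are identical by balance
    tkE <- tukeyComparisons(fit, "E", alpha = 0.05)
    expect_true(all(tkE$p_adj > 0.5))

    # two levels tied, one apart: exactly two significant comparisons
    recs2 <- directRecords(des, function(r) c(1, 1, 5)[r$B + 1],
                           noiseSD = 0.15, seed = 5)
    tkB <- tukeyComparisons(fitSelectivityAnova(recs2, des,
                                                transform = "log"), "B")
    expect_identical(sum(tkB$significant), 2L)
    expect_false(tkB$significant[tkB$comparison == "1-0"])

    expect_error(tukeyComparisons(fit, "F"), "%in%")
})

test_that("condition recommendation recovers a planted optimum profile", {
    des <- generateDesign()
    d <- oilDist()
    camp <- simulateCampaign(campaignSpec(des, seed = 8),
                             cleanModel(scenario = "planted"))
    tgt <- data.frame(species = c("OOO", "OOL"), adduct = "[M+Na]+",
                      n_ox = 3)
    perRep <- batchSelectivity(camp$spectra, des, d, targets = tgt,
                               perReplicate = TRUE)
    agg <- batchSelectivity(camp$spectra, des, d, targets = tgt)
    rec <- recommendConditions(agg, des, transform = "log",
                               perReplicateRecords = perRep)
    expect_true(rec$discriminates)
    top <- rec$ranking[1, ]
    expect_identical(top$condition_set, 42L)
    expect_identical(top$additive, "NaOAc")
    fr <- rec$factorRecommendations
    expect_identical(fr$value[fr$factor == "A"], "NaOAc")
    expect_identical(fr$value[fr$factor == "D"], "5000")
    expect_false("E" %in% fr$factor)  # nozzle voltage is inert
})

test_that("flat responses are flagged as non-discriminating", {
    des <- generateDesign()
    d <- oilDist()
    camp <- simulateCampaign(campaignSpec(des, seed = 9), cleanModel())
    tgt <- data.frame(species = "OOO", adduct = "[M+Na]+", n_ox = 2)
    agg <- batchSelectivity(camp$spectra, des, d, targets = tgt)
    rec <- recommendConditions(agg, des)
    expect_false(rec$discriminates)
    expect_identical(nrow(rec$factorRecommendations), 0L)
})

test_that("a single response ranks by its own mean selectivity", {
    des <- generateDesign()
    recs <- directRecords(des, function(r) 1 + 0.5 * (r$run_id == 33),
                          noiseSD = 0, replicates = 2)
    agg <- stats::aggregate(selectivity ~ species + ox_degree +
                                condition_set, data = recs, FUN = mean)
    agg$sd <- 0
    rec <- recommendConditions(agg, des)
    expect_identical(rec$ranking$condition_set[1], 33L)
})
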
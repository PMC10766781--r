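test_that("the selectivity factor is the ratio of normalized areas", {
    expect_equal(selectivityFactor(5, 5, 0.3, 0.3), 1)
    expect_equal(selectivityFactor(10, 5, 0.4, 0.4), 2)
    expect_equal(selectivityFactor(10, 5, 0.3312, 0.6676),
                 (10 / 0.3312) / (5 / 0.6676), tolerance = 1e-12)
    expect_error(selectivityFactor(-1, 5, 0.3, 0.7), ">= 0")
    expect_error(selectivityFactor(1, 5, 0, 0.7), "normalization undefined")
    expect_warning(sInf <- selectivityFactor(1, 0, 0.3, 0.7), "infinite")
    expect_identical(sInf, Inf)
})

test_that("swapping oxidized and non-oxidized roles inverts the factor", {
    set.seed(3)
    for (i in 1:20) {
        a <- runif(2, 1, 100); f <- runif(2, 0.05, 0.9)
        expect_equal(selectivityFactor(a[1], a[2], f[1], f[2]),
                     1 / selectivityFactor(a[2], a[1], f[2], f[1]),
                     tolerance = 1e-12)
    }
})

test_that("selectivity is invariant under global intensity rescaling", {
    des <- generateDesign()
    d <- oilDist()
    s <- simulateSpectrum(run42(des), ionizationModel(noiseCV = 0.1),
                          d, seed = 11)
    sc <- Spectrum(mzValues(s), intensities(s) * 137.5,
                   conditionSetId = conditionSetId(s), replicate = 1L,
                   sample = "oil")
    w <- defaultWindows("oil")
    expect_equal(stage1Selectivity(sc, w, d)$selectivity,
                 stage1Selectivity(s, w, d)$selectivity, tolerance = 1e-12)
    ionOx <- targetIon(tagSpecies("OOO"), 3, "[M+Na]+")
    ionNon <- targetIon(tagSpecies("OOO"), 0, "[M+Na]+")
    expect_equal(stage2Selectivity(sc, ionOx, ionNon, d)$selectivity,
                 stage2Selectivity(s, ionOx, ionNon, d)$selectivity,
                 tolerance = 1e-12)
})

test_that("unit efficiencies give unit selectivity at matched composition", {
    des <- generateDesign()
    d <- oilDist()
    s <- simulateSpectrum(run42(des), cleanModel(), d)
    rec <- stage1Selectivity(s, defaultWindows("oil"), d, oxDegrees = 1:3)
    expect_equal(rec$selectivity, 1, tolerance = 1e-9)
})

test_that("stage-2 selectivity recovers planted efficiency ratios exactly", {
    des <- generateDesign()
    d <- oilDist()
    # oxidized species ionize 6.6x better than non-oxidized
    m66 <- ionizationModel(adducts = c("[M+NH4]+", "[M+Na]+"), maxOx = 3,
                           scenario = "null", noiseCV = 0,
                           baseline = data.frame(
                               species = rep(c("OOO", "OOL"), each = 6),
                               n_ox = rep(1:3, 4),
                               adduct = rep(rep(c("[M+NH4]+", "[M+Na]+"),
                                                each = 3), 2),
                               eff = 6.6))
    s <- simulateSpectrum(run42(des), m66, d)
    rec <- stage2Selectivity(s, targetIon(tagSpecies("OOO"), 2, "[M+Na]+"),
                             targetIon(tagSpecies("OOO"), 0, "[M+Na]+"), d)
    expect_equal(rec$selectivity, 6.6, tolerance = 1e-9)
    # window-level selectivity agrees when all ox degrees share the boost
    s1 <- stage1Selectivity(s, defaultWindows("oil"), d, oxDegrees = 1:3)
    expect_equal(s1$selectivity, 6.6, tolerance = 1e-9)

    # planted 120x efficiency for 3ox-OOO
    m120 <- ionizationModel(adducts = "[M+Na]+", maxOx = 3,
                            scenario = "null", noiseCV = 0,
                            baseline = data.frame(species = "OOO", n_ox = 3,
                                                  adduct = "[M+Na]+",
                                                  eff = 120))
    s120 <- simulateSpectrum(run42(des), m120, d)
    rec120 <- stage2Selectivity(
        s120, targetIon(tagSpecies("OOO"), 3, "[M+Na]+"),
        targetIon(tagSpecies("OOO"), 0, "[M+Na]+"), d)
    expect_equal(rec120$selectivity, 120, tolerance = 1e-9)
})

test_that("missing oxidized peaks give zero, missing non-oxidized infinite", {
    des <- generateDesign()
    d <- oilDist()
    m2 <- ionizationModel(adducts = "[M+Na]+", maxOx = 2, scenario = "null",
                          noiseCV = 0)
    s <- simulateSpectrum(run42(des), m2, d)
    rec <- stage2Selectivity(s, targetIon(tagSpecies("OOO"), 3, "[M+Na]+"),
                             targetIon(tagSpecies("OOO"), 0, "[M+Na]+"), d)
    expect_equal(rec$selectivity, 0)
    sOx <- Spectrum(950, 100, conditionSetId = 1L)
    recInf <- stage1Selectivity(sOx, defaultWindows("oil"), d)
    expect_identical(recInf$selectivity, Inf)
    expect_identical(recInf$flag, "infinite")
})

test_that("stage-2 ion pairs must be consistent", {
    d <- oilDist()
    s <- Spectrum(c(900, 950), c(1, 1))
    ox <- targetIon(tagSpecies("OOO"), 2, "[M+Na]+")
    expect_error(stage2Selectivity(s, ox,
                                   targetIon(tagSpecies("OOO"), 1, "[M+Na]+"),
                                   d), "nOx = 0")
    expect_error(stage2Selectivity(s, ox,
                                   targetIon(tagSpecies("OOL"), 0, "[M+Na]+"),
                                   d), "share species and adduct")
})

test_that("fragmentation leakage lowers window selectivity monotonically", {
    des <- generateDesign()
    d <- oilDist()
    sel <- vapply(c(0, 0.1, 0.3, 0.5), function(f) {
        m <- ionizationModel(adducts = c("[M+NH4]+", "[M+Na]+"), maxOx = 3,
                             scenario = "null", noiseCV = 0, leakage = f)
        s <- simulateSpectrum(run42(des), m, d)
        stage1Selectivity(s, defaultWindows("oil"), d,
                          oxDegrees = 1:3)$selectivity
    }, 0)
    expect_true(all(diff(sel) < 0))
    # one-directional ox->nonox leakage biases stage 1 below the stage-2
    # per-ion selectivity, which is unaffected in its oxidized numerator
    # only through the leaked fraction
    expect_lt(sel[3], 1)
})

test_that("batched selectivity aggregates replicates per condition", {
    des <- generateDesign()
    d <- oilDist()
    camp <- simulateCampaign(campaignSpec(des, seed = 5),
                             cleanModel(scenario = "planted"))
    tgt <- data.frame(species = "OOO", adduct = "[M+Na]+", n_ox = 3)
    agg <- batchSelectivity(camp$spectra, des, d, targets = tgt)
    expect_identical(nrow(agg), 81L)
    expect_true(all(agg$n_replicates == 2L))
    expect_true(all(agg$sd == 0))  # deterministic generator
    # per-replicate form has one row per spectrum x target
    rep <- batchSelectivity(camp$spectra, des, d, targets = tgt,
                            perReplicate = TRUE)
    expect_identical(nrow(rep), 162L)
    # argmax recovers the planted optimum condition profile
    best <- agg$condition_set[which.max(agg$selectivity)]
    expect_identical(best, 42L)

    # stage-1 batch over the same campaign
    s1 <- batchSelectivity(camp$spectra, des, d, stage = "stage1",
                           oxDegrees = 1:3)
    expect_identical(nrow(s1), 81L)
    expect_true(all(s1$species == "window-level"))

    # unknown condition ids are rejected
    s <- Spectrum(900, 1, conditionSetId = 99L)
    expect_error(batchSelectivity(list(s), des, d, targets = tgt),
                 "absent from the design")
})
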
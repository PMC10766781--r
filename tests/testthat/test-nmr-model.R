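test_that("per-FA profile follows from the NMR group concentrations", {
    prof <- faProfileFromNmr(oilQuant())
    p <- faFractions(prof)
    # 1000/885 * 3 = 3.39 mol FA per kg; published rounded fractions
    expect_lt(abs(p[["p1"]] - 0.056), 0.005)
    expect_lt(abs(p[["p2"]] - 0.07), 0.005)
    expect_lt(abs(p[["p0"]] - 0.874), 0.005)
    expect_equal(sum(p), 1, tolerance = 1e-12)

    # fresh, fully non-oxidized oil
    p0 <- faFractions(faProfileFromNmr(NmrGroupQuant(0, 0, 0, 885)))
    expect_equal(unname(p0), c(1, 0, 0))

    # hand-arithmetic oracle: molFA = 3 * 1000/900 = 10/3
    ph <- faFractions(faProfileFromNmr(NmrGroupQuant(0.1, 0.1, 0.3, 900)))
    expect_equal(unname(ph["p1"]), 0.2 / (10 / 3), tolerance = 1e-12)
    expect_equal(unname(ph["p2"]), 0.3 / (10 / 3), tolerance = 1e-12)
    expect_equal(unname(ph["p0"]), 1 - 0.5 / (10 / 3), tolerance = 1e-12)
})

test_that("invalid NMR inputs are rejected", {
    expect_error(faProfileFromNmr(NmrGroupQuant(-0.1, 0, 0)), ">= 0")
    expect_error(NmrGroupQuant(0.1, 0.1, 0.1, meanTagMass = -1), "> 0")
    # more oxidized groups than chains available
    expect_error(faProfileFromNmr(NmrGroupQuant(10, 0, 0, 885)),
                 "infeasible composition")
})

test_that("reported-precision intermediates reproduce the published worked example", {
    prof <- faProfileFromNmr(oilQuant(), digits = 3)
    expect_equal(unname(faFractions(prof)), c(0.874, 0.056, 0.070),
                 tolerance = 1e-12)
    pct <- 100 * oxProbabilities(tagOxDistribution(prof))
    expect_true(all(abs(pct[1:5] - c(66.76, 12.83, 16.86, 2.07, 1.35))
                    <= 0.01))
})

test_that("full-precision distribution is close to the published one", {
    pct <- 100 * oxProbabilities(oilDist())
    expect_true(all(abs(pct[1:5] - c(66.76, 12.83, 16.86, 2.07, 1.35))
                    <= 0.2))
})

test_that("degenerate profile puts all mass at zero oxidation", {
    d <- tagOxDistribution(FaOxidationProfile(1, 0, 0))
    expect_equal(unname(oxProbabilities(d)), c(1, rep(0, 6)))
})

test_that("distribution matches brute-force enumeration on random profiles", {
    set.seed(101)
    for (i in 1:100) {
        prof <- randomProfile()
        p <- faFractions(prof)
        got <- oxProbabilities(tagOxDistribution(prof))
        want <- enumOracle(p["p0"], p["p1"], p["p2"])
        expect_equal(unname(got), as.numeric(want), tolerance = 1e-12)
        expect_equal(sum(got), 1, tolerance = 1e-9)
        # closed-form corners
        expect_equal(unname(got["ox0"]), unname(p["p0"])^3, tolerance = 1e-12)
        expect_equal(unname(got["ox6"]), unname(p["p2"])^3, tolerance = 1e-12)
    }
})

test_that("more hydroperoxide strictly lowers the non-oxidized fraction", {
    probs0 <- vapply(seq(0.05, 0.5, by = 0.05), function(h) {
        d <- tagOxDistribution(faProfileFromNmr(NmrGroupQuant(0.02, 0.1, h)))
        oxProbabilities(d)[["ox0"]]
    }, 0)
    expect_true(all(diff(probs0) < 0))
})

test_that("normalization fractions cover the requested degrees", {
    d <- oilDist()
    pr <- oxProbabilities(d)
    fr <- normalizationFractions(d, 1:4)
    expect_equal(fr$fracOx, 1 - pr[["ox0"]] - pr[["ox5"]] - pr[["ox6"]],
                 tolerance = 1e-12)
    expect_equal(fr$fracNonox, pr[["ox0"]], tolerance = 1e-12)
    # 5ox + 6ox together stay below the 0.5 % cut
    expect_lt(pr[["ox5"]] + pr[["ox6"]], 0.005)
    expect_equal(negligibleOx(d)[c("ox5", "ox6")],
                 c(ox5 = TRUE, ox6 = TRUE))

    fr3 <- normalizationFractions(d, 3)
    expect_equal(fr3$fracOx, pr[["ox3"]], tolerance = 1e-12)

    # fresh oil: no oxidized fraction to normalize by
    fresh <- tagOxDistribution(FaOxidationProfile(1, 0, 0))
    expect_error(normalizationFractions(fresh, 1:4),
                 "normalization undefined")
    expect_error(normalizationFractions(d, 0:4), "subset of 1..6")
})

test_that("triple enumeration lists all 27 ordered combinations", {
    tr <- enumerateOxTriples(faProfileFromNmr(oilQuant()))
    expect_identical(nrow(tr), 27L)
    expect_false(anyDuplicated(tr[c("sn1", "sn2", "sn3")]) > 0)
    expect_equal(sum(tr$prob), 1, tolerance = 1e-12)
    agg <- tapply(tr$prob, tr$n_ox, sum)
    expect_equal(as.numeric(agg),
                 unname(oxProbabilities(oilDist()))[1:7][as.integer(names(agg)) + 1],
                 tolerance = 1e-12)
})

test_that("NMR tables round-trip through the distribution table", {
    path <- system.file("extdata", "nmr_quant.csv", package = "oxSelMS")
    nmr <- readNmrQuant(path)
    expect_identical(nrow(nmr), 2L)
    tab <- tagDistributionTable(nmr, digits = 3)
    expect_identical(tab$sample_id, nmr$sample_id)
    expect_equal(100 * tab$ox0[1], 66.76, tolerance = 0.01)
    expect_equal(rowSums(tab[paste0("ox", 0:6)]), c(1, 1),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_error(suppressWarnings(readNmrQuant(tempfile())),
                 "cannot open|does not exist")
})
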
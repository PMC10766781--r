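# Shared fixtures and independent oracles used across the suite.

# Oxidized rapeseed oil NMR inputs and derived distributions.
oilQuant <- function() oxidizedRapeseedOilNmr()
oilDist <- function(digits = NULL)
    tagOxDistribution(faProfileFromNmr(oilQuant(), digits = digits))

# Brute-force oracle: TAG oxidation-degree probabilities by exhaustive
# enumeration of all 27 ordered chain-state triples. Kept independent of
# the package's multinomial implementation.
enumOracle <- function(p0, p1, p2) {
    pv <- c(p0, p1, p2)
    prob <- numeric(7)
    n <- 0L
    for (a in 0:2) for (b in 0:2) for (cc in 0:2) {
        n <- n + 1L
        k <- a + b + cc
        prob[k + 1L] <- prob[k + 1L] + pv[a + 1L] * pv[b + 1L] * pv[cc + 1L]
    }
    attr(prob, "n_triples") <- n
    prob
}

randomProfile <- function() {
    x <- stats::runif(3)
    x <- x / sum(x)
    FaOxidationProfile(x[1], x[2], x[3])
}

# Small deterministic synthetic setup whose every target ion falls inside
# the oil windows (NH4/Na adducts only, up to 3 added oxygens).
cleanModel <- function(scenario = "null", noiseCV = 0, ...)
    ionizationModel(adducts = c("[M+NH4]+", "[M+Na]+"), maxOx = 3,
                    scenario = scenario, noiseCV = noiseCV, ...)

run42 <- function(design = generateDesign()) resolveConditions(design)[42, ]
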
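#' Construct a ground-truth ionization model
#'
#' The generator emulates centroided positive-mode FIA-ESI spectra of an
#' oxidized oil: one stick per (species, oxidation degree, adduct), with
#' intensity
#' `amount * P(k) * eff * adductWeight(additive, adduct) * oxBoost(condition)`
#' where `oxBoost` multiplies oxidized species (k >= 1) by per-factor level
#' curves and optional two-way interaction terms. A fraction `leakage` of
#' each oxidized stick is relocated to the species' non-oxidized m/z
#' (in-source fragmentation with loss of the oxygen-bearing moiety), and
#' multiplicative log-normal noise with coefficient of variation `noiseCV`
#' (unit mean) is applied per stick.
#'
#' The default "planted" scenario mirrors the qualitative structure of real
#' campaigns: sodiated adducts dominate with Na additives and ammoniated ones
#' with NH4Fo; the additive has the strongest effect on oxidized-species
#' efficiency (NaOAc best, NaI intermediate, NH4Fo weakest), concentration
#' and sheath gas temperature peak at their middle level, high capillary
#' voltage roughly doubles oxidized-species response, and nozzle voltage is
#' inert. The planted optimum profile is therefore
#' (NaOAc, 0.1 mM, 250 degC, 5000 V, any nozzle). The "null" scenario sets
#' every effect curve to 1 (no condition influences selectivity).
#'
#' @param species character vector of species names (default OOO and OOL).
#' @param adducts adduct labels generated (default all three).
#' @param maxOx highest oxidation degree generated (default 4).
#' @param scenario "planted" or "null".
#' @param baseline optional data.frame (species, n_ox, adduct, eff) of
#'   baseline efficiencies; rows missing from it default to 1. Use this to
#'   plant per-ion efficiency ratios.
#' @param leakage fraction of oxidized intensity leaking to the non-oxidized
#'   m/z (default 0).
#' @param noiseCV multiplicative noise CV (default 0.1).
#' @param interactionEffects named list of 3x3 matrices ("AD", "BC", ...)
#'   multiplying oxidized intensity by `m[level1+1, level2+1]`.
#' @return An [IonizationModel-class].
#' @examples
#' ionizationModel(scenario = "null", noiseCV = 0)
#' @export
ionizationModel <- function(species = c("OOO", "OOL"),
                            adducts = c("[M+H]+", "[M+NH4]+", "[M+Na]+"),
                            maxOx = 4, scenario = c("planted", "null"),
                            baseline = NULL, leakage = 0, noiseCV = 0.1,
                            interactionEffects = list()) {
    scenario <- match.arg(scenario)
    spObjs <- lapply(species, tagSpecies)
    targets <- buildTargetTable(spObjs, adducts, maxOx = maxOx)
    targets$eff <- 1
    if (!is.null(baseline)) {
        key <- paste(targets$species, targets$n_ox, targets$adduct)
        bkey <- paste(baseline$species, baseline$n_ox, baseline$adduct)
        hit <- match(key, bkey)
        targets$eff[!is.na(hit)] <- baseline$eff[hit[!is.na(hit)]]
    }
    targets$nonox_idx <- match(paste(targets$species, 0, targets$adduct),
                               paste(targets$species, targets$n_ox,
                                     targets$adduct))
    adductWeights <- rbind(
        NH4Fo = c("[M+H]+" = 0.10, "[M+NH4]+" = 0.85, "[M+Na]+" = 0.05),
        NaOAc = c("[M+H]+" = 0.02, "[M+NH4]+" = 0.03, "[M+Na]+" = 0.95),
        NaI = c("[M+H]+" = 0.02, "[M+NH4]+" = 0.03, "[M+Na]+" = 0.95))
    adductWeights <- adductWeights[, adducts, drop = FALSE]
    factorEffects <- if (scenario == "planted")
        list(A = c(1.0, 6.0, 4.0),   # NH4Fo / NaOAc / NaI
             B = c(0.8, 1.5, 1.0),   # optimum at 0.1 mM
             C = c(0.8, 1.4, 1.1),   # optimum at 250 degC
             D = c(1.0, 1.2, 2.0),   # high capillary voltage ~2x
             E = c(1.0, 1.0, 1.0))   # nozzle voltage inert
    else
        list(A = c(1, 1, 1), B = c(1, 1, 1), C = c(1, 1, 1),
             D = c(1, 1, 1), E = c(1, 1, 1))
    new("IonizationModel", targets = targets, adductWeights = adductWeights,
        factorEffects = factorEffects,
        interactionEffects = interactionEffects,
        leakage = as.numeric(leakage), noiseCV = as.numeric(noiseCV))
}

#' Simulate one FIA-MS spectrum under a condition set
#'
#' @param cond one row of [resolveConditions()] (a list or one-row
#'   data.frame with level indices `A`..`E` and the resolved `additive`).
#' @param model an [IonizationModel-class].
#' @param composition a [TagOxDistribution-class] shared by all species.
#' @param amounts named numeric, relative amounts per species.
#' @param replicate replicate index stored in the spectrum.
#' @param sample sample label.
#' @param scale global intensity scale (counts; default 1e6).
#' @param seed optional seed for this spectrum's noise draw.
#' @return A [Spectrum-class].
#' @examples
#' d <- resolveConditions(generateDesign())
#' m <- ionizationModel(scenario = "null", noiseCV = 0)
#' comp <- tagOxDistribution(FaOxidationProfile(0.874, 0.056, 0.07))
#' simulateSpectrum(d[42, ], m, comp)
#' @export
simulateSpectrum <- function(cond, model, composition,
                             amounts = c(OOO = 0.5, OOL = 0.5),
                             replicate = 1L, sample = "oil", scale = 1e6,
                             seed = NULL) {
    if (!is.null(seed))
        set.seed(seed)
    t <- model@targets
    pr <- oxProbabilities(composition)
    additive <- as.character(cond[["additive"]])
    if (!additive %in% rownames(model@adductWeights))
        stop("no adduct weights defined for additive '", additive, "'")
    w <- model@adductWeights[additive, t$adduct]
    oxBoost <- 1
    for (code in LETTERS[1:5])
        oxBoost <- oxBoost *
            model@factorEffects[[code]][cond[[code]] + 1L]
    for (nm in names(model@interactionEffects)) {
        f1 <- substr(nm, 1, 1); f2 <- substr(nm, 2, 2)
        oxBoost <- oxBoost *
            model@interactionEffects[[nm]][cond[[f1]] + 1L,
                                           cond[[f2]] + 1L]
    }
    intensity <- scale * unname(amounts[t$species]) * pr[t$n_ox + 1L] *
        t$eff * w * ifelse(t$n_ox > 0L, oxBoost, 1)
    if (model@noiseCV > 0) {
        sdlog <- sqrt(log(1 + model@noiseCV^2))
        intensity <- intensity *
            stats::rlnorm(length(intensity), meanlog = -sdlog^2 / 2,
                          sdlog = sdlog)
    }
    intensity <- unname(intensity)
    if (model@leakage > 0) {
        isOx <- t$n_ox > 0L
        moved <- model@leakage * intensity[isOx]
        intensity[isOx] <- intensity[isOx] - moved
        add <- vapply(split(moved, t$nonox_idx[isOx]), sum, 0)
        dest <- as.integer(names(add))
        intensity[dest] <- intensity[dest] + unname(add)
    }
    Spectrum(t$mz, intensity,
             conditionSetId = as.integer(cond[["run_id"]]),
             replicate = replicate, sample = sample)
}

#' Create a campaign specification
#'
#' @param design an [FrfDesign-class].
#' @param replicates replicate injections per condition set (default 2,
#'   duplicate measurements).
#' @param composition a [TagOxDistribution-class]; default: the distribution
#'   of the oxidized rapeseed oil computed from its NMR concentrations.
#' @param amounts named relative amounts per species.
#' @param seed campaign RNG seed.
#' @return A [CampaignSpec-class].
#' @examples
#' campaignSpec(generateDesign(), seed = 1)
#' @export
campaignSpec <- function(design, replicates = 2,
                         composition = tagOxDistribution(
                             faProfileFromNmr(oxidizedRapeseedOilNmr())),
                         amounts = c(OOO = 0.5, OOL = 0.5), seed = 1) {
    new("CampaignSpec", design = design, replicates = as.integer(replicates),
        composition = composition, amounts = amounts, seed = as.integer(seed))
}

#' Simulate a full measurement campaign
#'
#' Generates `replicates` spectra for each of the design's condition sets,
#' deterministically under the campaign seed. With `dir = NULL` the spectra
#' are returned in memory; otherwise each spectrum is written as a CSV file
#' and a manifest CSV maps files to (condition_set, replicate, sample).
#'
#' @param spec a [CampaignSpec-class].
#' @param model an [IonizationModel-class].
#' @param dir optional output directory for spectrum files + manifest.
#' @param sample sample label recorded in the spectra.
#' @param format spectrum file format when writing ("csv" or "mzml").
#' @return list with `spectra` (list of [Spectrum-class]; NULL when written
#'   to disk) and `manifest` (data.frame path, condition_set, replicate,
#'   sample; `path` is NA for in-memory campaigns).
#' @examples
#' camp <- simulateCampaign(campaignSpec(generateDesign(), seed = 1),
#'                          ionizationModel(noiseCV = 0))
#' length(camp$spectra)
#' @export
simulateCampaign <- function(spec, model, dir = NULL, sample = "oil",
                             format = c("csv", "mzml")) {
    format <- match.arg(format)
    validObject(spec); validObject(model)
    runs <- resolveConditions(spec@design)
    set.seed(spec@seed)
    spectra <- vector("list", nrow(runs) * spec@replicates)
    manifest <- vector("list", length(spectra))
    if (!is.null(dir) && !dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    i <- 0L
    for (r in seq_len(nrow(runs))) {
        cond <- runs[r, ]
        for (rep in seq_len(spec@replicates)) {
            i <- i + 1L
            s <- simulateSpectrum(cond, model, spec@composition,
                                  amounts = spec@amounts, replicate = rep,
                                  sample = sample)
            path <- NA_character_
            if (!is.null(dir)) {
                path <- sprintf("spectrum_c%02d_r%d.%s", runs$run_id[r], rep,
                                if (format == "csv") "csv" else "mzML")
                writeSpectrum(s, file.path(dir, path), format)
            } else {
                spectra[[i]] <- s
            }
            manifest[[i]] <- data.frame(
                path = path, condition_set = runs$run_id[r], replicate = rep,
                sample = sample)
        }
    }
    manifest <- do.call(rbind, manifest)
    if (!is.null(dir)) {
        utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                         row.names = FALSE, quote = FALSE)
        return(list(spectra = NULL, manifest = manifest))
    }
    list(spectra = spectra, manifest = manifest)
}
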
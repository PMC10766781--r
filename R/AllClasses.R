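#' @import methods
NULL

## ---------------------------------------------------------------------------
## NMR-side classes
## ---------------------------------------------------------------------------

#' NMR oxidation-group concentrations for a TAG sample
#'
#' Holds the concentrations of the three oxidation groups quantified by NMR in
#' an oxidized triacylglycerol (TAG) sample, in mol per kg TAG, together with
#' the mean molecular mass assumed for the TAG molecules (default 885 g/mol,
#' the mass of triolein).
#'
#' @slot aldehyde numeric(1), mol aldehyde groups per kg TAG.
#' @slot epoxide numeric(1), mol epoxide groups per kg TAG.
#' @slot hydroperoxide numeric(1), mol hydroperoxide groups per kg TAG.
#' @slot meanTagMass numeric(1), mean TAG molecular mass in g/mol.
#'
#' @seealso [NmrGroupQuant()], [faProfileFromNmr()]
#' @export
setClass("NmrGroupQuant",
    representation(
        aldehyde = "numeric",
        epoxide = "numeric",
        hydroperoxide = "numeric",
        meanTagMass = "numeric"
    )
)

setValidity("NmrGroupQuant", function(object) {
    msg <- character()
    for (sl in c("aldehyde", "epoxide", "hydroperoxide", "meanTagMass")) {
        v <- slot(object, sl)
        if (length(v) != 1L || !is.finite(v))
            msg <- c(msg, sprintf("'%s' must be a single finite number", sl))
    }
    if (length(msg))
        return(msg)
    if (object@aldehyde < 0 || object@epoxide < 0 || object@hydroperoxide < 0)
        msg <- c(msg, "group concentrations must be >= 0")
    if (object@meanTagMass <= 0)
        msg <- c(msg, "'meanTagMass' must be > 0")
    if (length(msg)) msg else TRUE
})

#' Create an NmrGroupQuant object
#'
#' @param aldehyde mol aldehyde groups per kg TAG.
#' @param epoxide mol epoxide groups per kg TAG.
#' @param hydroperoxide mol hydroperoxide groups per kg TAG.
#' @param meanTagMass mean TAG molecular mass (g/mol); defaults to 885,
#'   the monoisotopic-rounded mass of triolein.
#'
#' @return An [NmrGroupQuant-class] object.
#' @examples
#' oxidizedRapeseedOilNmr()
#' NmrGroupQuant(0.022, 0.167, 0.236)
#' @export
NmrGroupQuant <- function(aldehyde, epoxide, hydroperoxide, meanTagMass = 885) {
    new("NmrGroupQuant",
        aldehyde = as.numeric(aldehyde),
        epoxide = as.numeric(epoxide),
        hydroperoxide = as.numeric(hydroperoxide),
        meanTagMass = as.numeric(meanTagMass))
}

#' Per-fatty-acid oxidation profile
#'
#' Fractions of fatty-acid (FA) chains carrying 0, 1 or 2 added oxygen atoms.
#' One added oxygen corresponds to an epoxide or aldehyde group, two to a
#' hydroperoxide; chains with more than one oxidized group are not modeled.
#'
#' @slot p numeric(3), named `p0`, `p1`, `p2`; sums to 1.
#' @seealso [FaOxidationProfile()], [tagOxDistribution()]
#' @export
setClass("FaOxidationProfile", representation(p = "numeric"))

setValidity("FaOxidationProfile", function(object) {
    p <- object@p
    if (length(p) != 3L || !identical(names(p), c("p0", "p1", "p2")))
        return("'p' must be numeric(3) named p0, p1, p2")
    if (any(!is.finite(p)))
        return("fractions must be finite")
    if (any(p < -1e-12) || any(p > 1 + 1e-12))
        return("fractions must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9)
        return("fractions must sum to 1 (within 1e-9)")
    TRUE
})

#' Create a per-FA oxidation profile
#'
#' @param p0,p1,p2 fractions of FA chains with 0, 1 and 2 added oxygens.
#' @return A [FaOxidationProfile-class] object.
#' @examples
#' FaOxidationProfile(0.874, 0.056, 0.07)
#' @export
FaOxidationProfile <- function(p0, p1, p2) {
    new("FaOxidationProfile",
        p = c(p0 = as.numeric(p0), p1 = as.numeric(p1), p2 = as.numeric(p2)))
}

#' TAG oxidation-degree distribution
#'
#' Probability that a TAG molecule carries k = 0..6 added oxygen atoms in
#' total over its three acyl chains, under the assumption that the three
#' sn positions oxidize independently with the per-FA profile.
#'
#' @slot prob numeric(7), named `ox0` .. `ox6`; sums to 1.
#' @seealso [tagOxDistribution()], [normalizationFractions()]
#' @export
setClass("TagOxDistribution", representation(prob = "numeric"))

setValidity("TagOxDistribution", function(object) {
    pr <- object@prob
    if (length(pr) != 7L || !identical(names(pr), paste0("ox", 0:6)))
        return("'prob' must be numeric(7) named ox0..ox6")
    if (any(!is.finite(pr)) || any(pr < -1e-12) || any(pr > 1 + 1e-12))
        return("probabilities must lie in [0, 1]")
    if (abs(sum(pr) - 1) > 1e-9)
        return("probabilities must sum to 1 (within 1e-9)")
    TRUE
})

## ---------------------------------------------------------------------------
## Species / adducts / windows
## ---------------------------------------------------------------------------

#' A triacylglycerol species
#'
#' @slot name species short name, e.g. "OOO" (triolein) or "OOL"
#'   (dioleoyl-linoleoyl-glycerol).
#' @slot formula elemental formula of the neutral, non-oxidized molecule,
#'   e.g. "C57H104O6".
#' @slot acyls character(3), acyl chain labels for the three sn positions.
#' @seealso [tagSpecies()]
#' @export
setClass("TagSpecies",
    representation(name = "character", formula = "character",
                   acyls = "character"))

setValidity("TagSpecies", function(object) {
    if (length(object@acyls) != 3L)
        return("a TAG has exactly three acyl chains")
    m <- tryCatch(formulaMass(object@formula), error = function(e) NA_real_)
    if (!is.finite(m) || m <= 0)
        return(sprintf("formula '%s' does not parse to a positive mass",
                       object@formula))
    TRUE
})

#' An ESI adduct specification
#'
#' @slot label adduct label, one of "[M+H]+", "[M+NH4]+", "[M+Na]+".
#' @slot massShift mass added to the neutral molecule (Da), charge-carrier
#'   mass minus the electron mass.
#' @slot nominalShift integer nominal-mass shift.
#' @slot charge charge state (+1 for all supported adducts).
#' @seealso [adductSpec()]
#' @export
setClass("AdductSpec",
    representation(label = "character", massShift = "numeric",
                   nominalShift = "numeric", charge = "numeric"))

setValidity("AdductSpec", function(object) {
    if (object@massShift <= 0 || object@nominalShift <= 0)
        return("adduct mass shift must be > 0")
    if (object@charge != 1)
        return("only singly charged adducts are supported")
    TRUE
})

#' A target ion: species + oxidation degree + adduct
#'
#' @slot species a [TagSpecies-class].
#' @slot nOx integer, number of added oxygens (0..6).
#' @slot adduct an [AdductSpec-class].
#' @slot mz computed m/z of the ion.
#' @slot massMode "monoisotopic" or "nominal".
#' @seealso [targetIon()], [eicArea()], [stage2Selectivity()]
#' @export
setClass("TargetIon",
    representation(species = "TagSpecies", nOx = "integer",
                   adduct = "AdductSpec", mz = "numeric",
                   massMode = "character"))

setValidity("TargetIon", function(object) {
    if (object@nOx < 0L || object@nOx > 6L)
        return("'nOx' must be in 0..6")
    expect <- adductMz(object@species, object@nOx, object@adduct,
                       object@massMode)
    if (abs(object@mz - expect) > 1e-4)
        return("stored mz inconsistent with species/adduct arithmetic")
    TRUE
})

#' A mass window for stage-1 selectivity
#'
#' Windows are half-open intervals `[lo, hi)` so that a centroid falls in at
#' most one window of a non-overlapping set.
#'
#' @slot label window label, e.g. "nonox" or "ox1".
#' @slot lo,hi window bounds in Da.
#' @slot role one of "nonox", "ox", "ox-subclass".
#' @seealso [defaultWindows()], [windowArea()]
#' @export
setClass("MassWindow",
    representation(label = "character", lo = "numeric", hi = "numeric",
                   role = "character"))

setValidity("MassWindow", function(object) {
    if (object@lo >= object@hi)
        return("'lo' must be < 'hi'")
    if (!object@role %in% c("nonox", "ox", "ox-subclass"))
        return("role must be one of nonox/ox/ox-subclass")
    TRUE
})

#' Create a mass window
#'
#' @param label window label.
#' @param lo,hi bounds in Da (half-open, `[lo, hi)`).
#' @param role "nonox", "ox" or "ox-subclass".
#' @return A [MassWindow-class].
#' @examples
#' massWindow("nonox", 880, 910, "nonox")
#' @export
massWindow <- function(label, lo, hi, role = "ox") {
    new("MassWindow", label = label, lo = as.numeric(lo), hi = as.numeric(hi),
        role = role)
}

## ---------------------------------------------------------------------------
## Spectra
## ---------------------------------------------------------------------------

#' A centroided FIA-MS spectrum
#'
#' A composite (scan-summed) centroided spectrum from one flow-injection run,
#' carrying the design condition-set id and replicate index as metadata.
#'
#' @slot mz numeric, m/z values in strictly ascending order.
#' @slot intensity numeric, non-negative intensities, parallel to `mz`.
#' @slot conditionSetId integer, design run id (1..81), NA if unknown.
#' @slot replicate integer replicate index, NA if unknown.
#' @slot sample character sample label (e.g. "oil", "OOO_std").
#' @seealso [Spectrum()], [readSpectrum()], [windowArea()], [eicArea()]
#' @export
setClass("Spectrum",
    representation(mz = "numeric", intensity = "numeric",
                   conditionSetId = "integer", replicate = "integer",
                   sample = "character"))

setValidity("Spectrum", function(object) {
    if (length(object@mz) != length(object@intensity))
        return("'mz' and 'intensity' must have equal length")
    if (length(object@mz) && any(diff(object@mz) <= 0))
        return("'mz' must be strictly ascending")
    if (any(!is.finite(object@mz)) || any(!is.finite(object@intensity)))
        return("'mz' and 'intensity' must be finite")
    if (any(object@intensity < 0))
        return("intensities must be non-negative")
    TRUE
})

## ---------------------------------------------------------------------------
## Design
## ---------------------------------------------------------------------------

#' A three-level design factor
#'
#' @slot code single letter code A..E.
#' @slot name human-readable factor name.
#' @slot levels vector of exactly three distinct level values (character for
#'   categorical factors, numeric otherwise).
#' @slot unit unit string ("" for categorical).
#' @seealso [designFactor()], [defaultIonizationFactors()]
#' @export
setClass("DesignFactor",
    representation(code = "character", name = "character", levels = "ANY",
                   unit = "character"))

setValidity("DesignFactor", function(object) {
    if (length(object@levels) != 3L || anyDuplicated(object@levels))
        return("a factor must have exactly 3 distinct levels")
    TRUE
})

#' Create a design factor
#'
#' @param code single letter code (A..E).
#' @param name factor name.
#' @param levels three distinct level values, ordered low/mid/high (ordering
#'   is ignored for categorical factors).
#' @param unit unit string.
#' @return A [DesignFactor-class].
#' @examples
#' designFactor("C", "sheath gas temperature", c(150, 250, 350), "degC")
#' @export
designFactor <- function(code, name, levels, unit = "") {
    new("DesignFactor", code = code, name = name, levels = levels, unit = unit)
}

#' A regular 3^(5-1) fractional factorial design
#'
#' 81 runs over five three-level factors: the full 3^4 factorial on A..D with
#' E determined by a single GF(3) defining relation.
#'
#' @slot runs data.frame with columns `run_id`, level indices `A`..`E`
#'   (integers 0..2) and resolved physical values.
#' @slot factors list of five [DesignFactor-class] objects.
#' @slot generator integer(4), GF(3) coefficients of A..D in the defining
#'   relation for E.
#' @seealso [generateDesign()], [validateDesign()], [resolveConditions()]
#' @export
setClass("FrfDesign",
    representation(runs = "data.frame", factors = "list",
                   generator = "integer"))

setValidity("FrfDesign", function(object) {
    need <- c("run_id", LETTERS[1:5])
    if (!all(need %in% names(object@runs)))
        return("runs must contain run_id and level columns A..E")
    if (length(object@factors) != 5L)
        return("exactly five factors are required")
    if (length(object@generator) != 4L)
        return("generator must have 4 coefficients (A..D)")
    TRUE
})

## ---------------------------------------------------------------------------
## Synthetic data
## ---------------------------------------------------------------------------

#' Ground-truth ionization model for the synthetic-spectrum generator
#'
#' Encodes per-ion baseline ionization efficiencies, adduct formation
#' propensities per solvent additive, multiplicative per-factor effect curves
#' acting on oxidized species, optional two-way interaction multipliers,
#' in-source fragmentation leakage and multiplicative noise.
#'
#' @slot targets data.frame of generated ions: species, n_ox, adduct, mz,
#'   baseline efficiency `eff`, and `nonox_idx` (row of the corresponding
#'   non-oxidized ion, for leakage routing).
#' @slot adductWeights matrix additive x adduct of adduct formation weights.
#' @slot factorEffects named list (A..E), each a numeric(3) multiplier applied
#'   to oxidized-species intensity at the corresponding factor level.
#' @slot interactionEffects named list of 3x3 matrices, names like "AD";
#'   multiplier indexed by the two factors' level indices, applied to oxidized
#'   species.
#' @slot leakage numeric(1) in [0, 1): fraction of each oxidized ion's
#'   intensity relocated to the species' non-oxidized m/z (in-source
#'   fragmentation with oxygen loss).
#' @slot noiseCV numeric(1) >= 0: coefficient of variation of the
#'   multiplicative log-normal intensity noise.
#' @seealso [ionizationModel()], [simulateSpectrum()]
#' @export
setClass("IonizationModel",
    representation(targets = "data.frame", adductWeights = "matrix",
                   factorEffects = "list", interactionEffects = "list",
                   leakage = "numeric", noiseCV = "numeric"))

setValidity("IonizationModel", function(object) {
    if (any(object@targets$eff <= 0))
        return("baseline efficiencies must be > 0")
    if (object@leakage < 0 || object@leakage >= 1)
        return("'leakage' must be in [0, 1)")
    if (object@noiseCV < 0)
        return("'noiseCV' must be >= 0")
    if (!identical(sort(names(object@factorEffects)), LETTERS[1:5]))
        return("factorEffects must be named A..E")
    if (!all(vapply(object@factorEffects, length, 1L) == 3L))
        return("each factor effect curve must have 3 levels")
    TRUE
})

#' Specification of a simulated measurement campaign
#'
#' @slot design an [FrfDesign-class].
#' @slot replicates integer, replicate injections per condition set
#'   (default 2, duplicate measurements).
#' @slot composition a [TagOxDistribution-class] shared by the simulated
#'   species.
#' @slot amounts named numeric, relative molar amounts of the simulated TAG
#'   species.
#' @slot seed integer RNG seed for the campaign.
#' @seealso [campaignSpec()], [simulateCampaign()]
#' @export
setClass("CampaignSpec",
    representation(design = "FrfDesign", replicates = "integer",
                   composition = "TagOxDistribution", amounts = "numeric",
                   seed = "integer"))

setValidity("CampaignSpec", function(object) {
    if (object@replicates < 1L)
        return("'replicates' must be >= 1")
    if (is.null(names(object@amounts)) || any(object@amounts <= 0))
        return("'amounts' must be a named vector of positive values")
    TRUE
})

## ---------------------------------------------------------------------------
## ANOVA container
## ---------------------------------------------------------------------------

#' Fitted selectivity ANOVA for one response
#'
#' Fixed-effects decomposition of the selectivity factor over the design into
#' five main effects (2 df each) and ten two-way interactions (4 df each),
#' with F tests against the residual mean square.
#'
#' @slot fit the underlying [stats::aov] fit.
#' @slot table data.frame: term, df, sum_sq, mean_sq, F, p.
#' @slot response label of the response fitted (species/ox degree).
#' @slot transform "identity" or "log".
#' @slot nExcluded number of non-finite / flagged records excluded.
#' @seealso [fitSelectivityAnova()], [tukeyComparisons()]
#' @export
setClass("SelectivityAnova",
    representation(fit = "ANY", table = "data.frame", response = "character",
                   transform = "character", nExcluded = "integer"))
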
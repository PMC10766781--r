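#' Extract oxidation-degree probabilities
#'
#' @param object a [TagOxDistribution-class].
#' @return named numeric(7), probabilities for 0..6 added oxygens.
#' @examples
#' oxProbabilities(tagOxDistribution(FaOxidationProfile(0.874, 0.056, 0.07)))
#' @export
setGeneric("oxProbabilities", function(object)
    standardGeneric("oxProbabilities"))

#' Extract per-FA oxidation fractions
#'
#' @param object a [FaOxidationProfile-class].
#' @return named numeric(3) (`p0`, `p1`, `p2`).
#' @export
setGeneric("faFractions", function(object) standardGeneric("faFractions"))

#' @rdname spectrumAccessors
#' @export
setGeneric("mzValues", function(object) standardGeneric("mzValues"))

#' @rdname spectrumAccessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname spectrumAccessors
#' @export
setGeneric("totalIntensity", function(object)
    standardGeneric("totalIntensity"))

#' @rdname spectrumAccessors
#' @export
setGeneric("conditionSetId", function(object)
    standardGeneric("conditionSetId"))

#' Extract the run table of a design
#'
#' @param object an [FrfDesign-class].
#' @return data.frame of runs (level indices and resolved values).
#' @export
setGeneric("designRuns", function(object) standardGeneric("designRuns"))

#' Extract the m/z of a target ion
#'
#' @param object a [TargetIon-class].
#' @return numeric(1).
#' @export
setGeneric("ionMz", function(object) standardGeneric("ionMz"))

#' Extract the ANOVA term table
#'
#' @param object a [SelectivityAnova-class].
#' @return data.frame with columns term, df, sum_sq, mean_sq, F, p.
#' @export
setGeneric("anovaTable", function(object) standardGeneric("anovaTable"))

setMethod("oxProbabilities", "TagOxDistribution", function(object) object@prob)

setMethod("faFractions", "FaOxidationProfile", function(object) object@p)

#' Spectrum accessors
#'
#' `mzValues()` and `intensities()` return the centroid arrays,
#' `totalIntensity()` their sum, `conditionSetId()` the design run the
#' spectrum was acquired under.
#'
#' @param object a [Spectrum-class].
#' @name spectrumAccessors
#' @return numeric vectors (or a scalar for `totalIntensity` /
#'   `conditionSetId`).
NULL

setMethod("mzValues", "Spectrum", function(object) object@mz)
setMethod("intensities", "Spectrum", function(object) object@intensity)
setMethod("totalIntensity", "Spectrum", function(object)
    sum(object@intensity))
setMethod("conditionSetId", "Spectrum", function(object)
    object@conditionSetId)

#' @describeIn Spectrum-class number of centroids
#' @param x a Spectrum
#' @export
setMethod("length", "Spectrum", function(x) length(x@mz))

setMethod("designRuns", "FrfDesign", function(object) object@runs)

setMethod("ionMz", "TargetIon", function(object) object@mz)

setMethod("anovaTable", "SelectivityAnova", function(object) object@table)

## show methods -------------------------------------------------------------

setMethod("show", "NmrGroupQuant", function(object) {
    cat("NmrGroupQuant (mol per kg TAG)\n")
    cat(sprintf("  aldehyde: %.3f  epoxide: %.3f  hydroperoxide: %.3f\n",
                object@aldehyde, object@epoxide, object@hydroperoxide))
    cat(sprintf("  mean TAG mass: %.1f g/mol\n", object@meanTagMass))
})

setMethod("show", "FaOxidationProfile", function(object) {
    p <- object@p
    cat(sprintf(
        "FaOxidationProfile: p0 = %.4f, p1 = %.4f, p2 = %.4f (per mol FA)\n",
        p["p0"], p["p1"], p["p2"]))
})

setMethod("show", "TagOxDistribution", function(object) {
    cat("TagOxDistribution (% of TAG molecules):\n")
    pct <- sprintf("%5.2f", 100 * object@prob)
    cat(paste0("  ", paste(paste0(0:6, "ox: ", pct), collapse = "  "), "\n"))
})

setMethod("show", "TagSpecies", function(object) {
    cat(sprintf("TagSpecies %s (%s; acyls %s), monoisotopic M = %.4f Da\n",
                object@name, object@formula,
                paste(object@acyls, collapse = "/"),
                formulaMass(object@formula)))
})

setMethod("show", "TargetIon", function(object) {
    cat(sprintf("TargetIon %dox-%s %s, m/z %.4f (%s)\n",
                object@nOx, object@species@name, object@adduct@label,
                object@mz, object@massMode))
})

setMethod("show", "MassWindow", function(object) {
    cat(sprintf("MassWindow '%s' [%.1f, %.1f) Da, role %s\n",
                object@label, object@lo, object@hi, object@role))
})

setMethod("show", "Spectrum", function(object) {
    cat(sprintf(
        "Spectrum: %d centroids, TIC %.4g, condition %s, replicate %s, sample '%s'\n",
        length(object@mz), sum(object@intensity),
        ifelse(is.na(object@conditionSetId), "NA", object@conditionSetId),
        ifelse(is.na(object@replicate), "NA", object@replicate),
        object@sample))
})

setMethod("show", "FrfDesign", function(object) {
    cat(sprintf(
        "FrfDesign: 3^(5-1) regular fraction, %d runs\n  defining relation: E = %s (mod 3)\n",
        nrow(object@runs),
        paste(sprintf("%d*%s", object@generator, LETTERS[1:4]),
              collapse = " + ")))
    cat("  factors:",
        paste(vapply(object@factors, function(f)
            sprintf("%s=%s", f@code, f@name), ""), collapse = ", "), "\n")
})

setMethod("show", "IonizationModel", function(object) {
    cat(sprintf(
        "IonizationModel: %d target ions, leakage %.2f, noise CV %.2f\n",
        nrow(object@targets), object@leakage, object@noiseCV))
})

setMethod("show", "CampaignSpec", function(object) {
    cat(sprintf(
        "CampaignSpec: %d runs x %d replicates, species %s, seed %d\n",
        nrow(object@design@runs), object@replicates,
        paste(names(object@amounts), collapse = "/"), object@seed))
})

setMethod("show", "SelectivityAnova", function(object) {
    cat(sprintf("SelectivityAnova for response '%s' (%s scale), %d excluded\n",
                object@response, object@transform, object@nExcluded))
    print(object@table, row.names = FALSE, digits = 4)
})
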
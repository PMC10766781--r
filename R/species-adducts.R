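## Monoisotopic atomic masses (CODATA/IUPAC), electron mass in Da.
.ATOMIC_MONO <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, Na = 22.98976928)
.ATOMIC_NOMINAL <- c(C = 12, H = 1, N = 14, O = 16, Na = 23)
.ELECTRON_MASS <- 0.00054857990946

## Mass added per oxidation degree (one oxygen atom).
.DELTA_O_MONO <- 15.9949146221
.DELTA_O_NOMINAL <- 16

#' Mass of an elemental formula
#'
#' Parses simple Hill-style formulas such as "C57H104O6" (elements C, H, N,
#' O, Na; implicit count 1).
#'
#' @param formula formula string.
#' @param mode "monoisotopic" (default) or "nominal".
#' @return numeric(1), the neutral mass in Da.
#' @examples
#' formulaMass("C57H104O6")
#' @export
formulaMass <- function(formula, mode = c("monoisotopic", "nominal")) {
    mode <- match.arg(mode)
    tab <- if (mode == "monoisotopic") .ATOMIC_MONO else .ATOMIC_NOMINAL
    m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula)[[1]]
    parts <- regmatches(formula, list(m))[[1]]
    parts <- parts[nzchar(parts)]
    if (!length(parts) || paste(parts, collapse = "") != formula)
        stop("cannot parse formula '", formula, "'")
    total <- 0
    for (p in parts) {
        el <- sub("\\d+$", "", p)
        n <- sub("^[A-Za-z]+", "", p)
        n <- if (nzchar(n)) as.integer(n) else 1L
        if (!el %in% names(tab))
            stop("unknown element '", el, "' in formula '", formula, "'")
        total <- total + tab[[el]] * n
    }
    total
}

#' Built-in TAG species definitions
#'
#' "OOO" is triolein (C57H104O6) and "OOL" dioleoyl-linoleoyl-glycerol
#' (C57H102O6), the two major TAGs of rapeseed oil.
#'
#' @param name species name ("OOO" or "OOL"), or pass `formula` and `acyls`
#'   for a custom species.
#' @param formula elemental formula of the neutral non-oxidized molecule.
#' @param acyls character(3) acyl labels.
#' @return A [TagSpecies-class].
#' @examples
#' tagSpecies("OOO")
#' tagSpecies("PPP", formula = "C51H98O6", acyls = c("P", "P", "P"))
#' @export
tagSpecies <- function(name, formula = NULL, acyls = NULL) {
    builtin <- list(
        OOO = list(formula = "C57H104O6", acyls = c("O", "O", "O")),
        OOL = list(formula = "C57H102O6", acyls = c("O", "O", "L")))
    if (is.null(formula)) {
        if (!name %in% names(builtin))
            stop("unknown species '", name,
                 "'; supply 'formula' and 'acyls' for custom species")
        formula <- builtin[[name]]$formula
        acyls <- builtin[[name]]$acyls
    }
    new("TagSpecies", name = name, formula = formula, acyls = acyls)
}

#' ESI adduct specifications
#'
#' Positive-mode singly charged adducts. The mass shift is the charge-carrier
#' mass minus one electron mass.
#'
#' @param label one of "[M+H]+", "[M+NH4]+", "[M+Na]+".
#' @return An [AdductSpec-class].
#' @examples
#' adductSpec("[M+NH4]+")
#' @export
adductSpec <- function(label) {
    shifts <- list(
        "[M+H]+" = c(mono = .ATOMIC_MONO[["H"]] - .ELECTRON_MASS,
                     nominal = 1),
        "[M+NH4]+" = c(mono = .ATOMIC_MONO[["N"]] + 4 * .ATOMIC_MONO[["H"]] -
                           .ELECTRON_MASS, nominal = 18),
        "[M+Na]+" = c(mono = .ATOMIC_MONO[["Na"]] - .ELECTRON_MASS,
                      nominal = 23))
    if (!label %in% names(shifts))
        stop("unknown adduct label '", label, "'; supported: ",
             paste(names(shifts), collapse = ", "))
    s <- shifts[[label]]
    new("AdductSpec", label = label, massShift = unname(s["mono"]),
        nominalShift = unname(s["nominal"]), charge = 1)
}

#' m/z of a TAG adduct ion at a given oxidation degree
#'
#' Each added oxygen shifts the neutral mass by 15.9949 Da (monoisotopic) or
#' 16 Da (nominal); the adduct shift and +1 charge then give the m/z.
#'
#' @param species a [TagSpecies-class].
#' @param nOx number of added oxygens (0..6).
#' @param adduct an [AdductSpec-class] or adduct label string.
#' @param mode "monoisotopic" (default) or "nominal".
#' @return numeric(1) m/z.
#' @examples
#' adductMz(tagSpecies("OOO"), 0, "[M+NH4]+")
#' @export
adductMz <- function(species, nOx, adduct, mode = c("monoisotopic", "nominal")) {
    mode <- match.arg(mode)
    if (is.character(adduct))
        adduct <- adductSpec(adduct)
    nOx <- as.integer(nOx)
    if (nOx < 0L || nOx > 6L)
        stop("'nOx' must be in 0..6")
    if (mode == "monoisotopic") {
        (formulaMass(species@formula, "monoisotopic") + nOx * .DELTA_O_MONO +
             adduct@massShift) / adduct@charge
    } else {
        (formulaMass(species@formula, "nominal") + nOx * .DELTA_O_NOMINAL +
             adduct@nominalShift) / adduct@charge
    }
}

#' Create a target ion
#'
#' @inheritParams adductMz
#' @return A [TargetIon-class] with its m/z precomputed.
#' @examples
#' targetIon(tagSpecies("OOO"), 3, "[M+Na]+")
#' @export
targetIon <- function(species, nOx, adduct, mode = c("monoisotopic", "nominal")) {
    mode <- match.arg(mode)
    if (is.character(adduct))
        adduct <- adductSpec(adduct)
    new("TargetIon", species = species, nOx = as.integer(nOx),
        adduct = adduct, mz = adductMz(species, nOx, adduct, mode),
        massMode = mode)
}

#' Target-ion table for a monitoring campaign
#'
#' Cartesian product of species x oxidation degrees 0..`maxOx` x adducts,
#' sorted by m/z.
#'
#' @param species list of [TagSpecies-class] objects.
#' @param adducts character vector of adduct labels (or list of
#'   [AdductSpec-class]).
#' @param maxOx highest oxidation degree (<= 6).
#' @param mode mass mode.
#' @return data.frame: species, n_ox, adduct, mz.
#' @examples
#' buildTargetTable(list(tagSpecies("OOO"), tagSpecies("OOL")),
#'                  c("[M+NH4]+", "[M+Na]+"), maxOx = 3)
#' @export
buildTargetTable <- function(species, adducts, maxOx = 3,
                             mode = c("monoisotopic", "nominal")) {
    mode <- match.arg(mode)
    maxOx <- as.integer(maxOx)
    if (maxOx > 6L)
        stop("'maxOx' must be <= 6")
    if (is.character(adducts))
        adducts <- lapply(adducts, adductSpec)
    rows <- list()
    for (sp in species)
        for (ad in adducts)
            for (k in 0:maxOx)
                rows[[length(rows) + 1L]] <- data.frame(
                    species = sp@name, n_ox = k, adduct = ad@label,
                    mz = adductMz(sp, k, ad, mode))
    if (!length(rows))
        return(data.frame(species = character(), n_ox = integer(),
                          adduct = character(), mz = numeric()))
    out <- do.call(rbind, rows)
    out <- out[order(out$mz), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Default stage-1 mass windows
#'
#' The window sets used for window-level selectivity: a non-oxidized and an
#' oxidized region per sample kind, plus per-degree oxidized subclass windows
#' for the oil. All windows are half-open `[lo, hi)`.
#'
#' @param sampleKind "oil", "OOO_std" or "OOL_std".
#' @param subclasses logical; for "oil", also return the 1ox..4ox subclass
#'   windows.
#' @return list of [MassWindow-class] objects.
#' @examples
#' defaultWindows("oil")
#' @export
defaultWindows <- function(sampleKind = c("oil", "OOO_std", "OOL_std"),
                           subclasses = FALSE) {
    sampleKind <- match.arg(sampleKind)
    w <- switch(sampleKind,
        oil = list(massWindow("nonox", 880.0, 910.0, "nonox"),
                   massWindow("ox", 912.0, 970.0, "ox")),
        OOO_std = list(massWindow("nonox", 884.0, 908.0, "nonox"),
                       massWindow("ox", 915.0, 970.0, "ox")),
        OOL_std = list(massWindow("nonox", 883.0, 906.0, "nonox"),
                       massWindow("ox", 913.0, 968.0, "ox")))
    if (subclasses && sampleKind == "oil")
        w <- c(w, list(massWindow("ox1", 914.0, 926.0, "ox-subclass"),
                       massWindow("ox2", 928.0, 942.0, "ox-subclass"),
                       massWindow("ox3", 944.0, 957.0, "ox-subclass"),
                       massWindow("ox4", 959.0, 970.0, "ox-subclass")))
    w
}
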
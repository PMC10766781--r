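#' Composition-normalized selectivity factor
#'
#' The selectivity of ionization of oxidized versus non-oxidized TAG is the
#' ratio of composition-normalized peak areas,
#' \deqn{S = \frac{A_{ox} / f_{ox}}{A_{nonox} / f_{nonox}}}{
#'       S = (A_ox / f_ox) / (A_nonox / f_nonox)}
#' where the f are the model fractions of oxidized and non-oxidized TAG in
#' the sample (see [normalizationFractions()]). S > 1 means ionization
#' favors the oxidized species.
#'
#' @param areaOx,areaNonox integrated MS areas of the oxidized and
#'   non-oxidized signal.
#' @param fracOx,fracNonox composition fractions (must be > 0).
#' @return numeric(1); `Inf` (with a warning) when the non-oxidized species
#'   yields no signal.
#' @examples
#' selectivityFactor(10, 5, 0.33, 0.67)
#' @export
selectivityFactor <- function(areaOx, areaNonox, fracOx, fracNonox) {
    if (any(c(areaOx, areaNonox) < 0))
        stop("areas must be >= 0")
    if (fracOx <= 0 || fracNonox <= 0)
        stop("normalization undefined: composition fractions must be > 0")
    if (areaNonox == 0) {
        warning("non-oxidized species yields no signal: ",
                "infinite selectivity sentinel returned")
        return(Inf)
    }
    (areaOx / fracOx) / (areaNonox / fracNonox)
}

#' Stage-1 (mass-window) selectivity of one spectrum
#'
#' Integrates the non-oxidized and oxidized mass windows and normalizes by
#' the composition fractions: `fracOx` is the summed probability of the
#' requested oxidation degrees, `fracNonox` the zero-degree probability.
#'
#' @param s a [Spectrum-class].
#' @param windows list of [MassWindow-class] containing exactly one window
#'   with role "nonox" and one with role "ox" (e.g. [defaultWindows()]).
#' @param dist a [TagOxDistribution-class] for the sample.
#' @param oxDegrees oxidation degrees represented by the ox window
#'   (default 1:4).
#' @return one-row data.frame: sample, species, ox_degree, condition_set,
#'   replicate, selectivity, flag.
#' @export
stage1Selectivity <- function(s, windows, dist, oxDegrees = 1:4) {
    roles <- vapply(windows, function(w) w@role, "")
    if (sum(roles == "nonox") != 1L || sum(roles == "ox") != 1L)
        stop("'windows' must contain exactly one nonox and one ox window")
    wNon <- windows[[which(roles == "nonox")]]
    wOx <- windows[[which(roles == "ox")]]
    fr <- normalizationFractions(dist, oxDegrees)
    aOx <- windowArea(s, wOx)$area
    aNon <- windowArea(s, wNon)$area
    sel <- withCallingHandlers(
        selectivityFactor(aOx, aNon, fr$fracOx, fr$fracNonox),
        warning = function(w) invokeRestart("muffleWarning"))
    data.frame(sample = s@sample, species = "window-level",
               ox_degree = paste(range(oxDegrees), collapse = "-"),
               condition_set = s@conditionSetId, replicate = s@replicate,
               selectivity = sel,
               flag = if (is.infinite(sel)) "infinite" else "")
}

#' Stage-2 (selected-ion) selectivity of one spectrum
#'
#' Extracted-ion areas of a specific oxidized target ion and the matching
#' non-oxidized ion of the same species and adduct, normalized by the
#' per-degree composition fractions.
#'
#' @param s a [Spectrum-class].
#' @param ionOx oxidized [TargetIon-class] (nOx >= 1).
#' @param ionNonox non-oxidized [TargetIon-class] (same species and adduct,
#'   nOx = 0).
#' @param dist a [TagOxDistribution-class].
#' @param tol EIC half-width in Da.
#' @return one-row data.frame as in [stage1Selectivity()], with the ion's
#'   species, adduct and oxidation degree.
#' @export
stage2Selectivity <- function(s, ionOx, ionNonox, dist, tol = 0.35) {
    if (ionNonox@nOx != 0L)
        stop("'ionNonox' must have nOx = 0")
    if (ionOx@species@name != ionNonox@species@name ||
        ionOx@adduct@label != ionNonox@adduct@label)
        stop("the two ions must share species and adduct")
    k <- ionOx@nOx
    pr <- oxProbabilities(dist)
    fr <- list(fracOx = unname(pr[k + 1L]), fracNonox = unname(pr[1L]))
    if (fr$fracOx <= 0 || fr$fracNonox <= 0)
        stop("normalization undefined: zero composition fraction")
    aOx <- eicArea(s, ionOx, tol)$area
    aNon <- eicArea(s, ionNonox, tol)$area
    sel <- withCallingHandlers(
        selectivityFactor(aOx, aNon, fr$fracOx, fr$fracNonox),
        warning = function(w) invokeRestart("muffleWarning"))
    data.frame(sample = s@sample, species = ionOx@species@name,
               ox_degree = k, adduct = ionOx@adduct@label,
               condition_set = s@conditionSetId, replicate = s@replicate,
               selectivity = sel,
               flag = if (is.infinite(sel)) "infinite" else "")
}

#' Batched selectivity over a measurement campaign
#'
#' Computes per-replicate selectivity for every spectrum and target and
#' averages over replicates within each condition set. Selectivity is
#' computed per replicate and then averaged, preserving the SD semantics of
#' replicate error bars.
#'
#' @param spectra list of [Spectrum-class] objects (each carrying condition
#'   and replicate metadata), or a manifest data.frame from [readManifest()]
#'   whose files are then read with [readSpectrum()].
#' @param design an [FrfDesign-class]; every spectrum's condition id must be
#'   a design run.
#' @param dist a [TagOxDistribution-class] for the sample.
#' @param stage "stage2" (selected ions) or "stage1" (mass windows).
#' @param targets for stage 2: data.frame with columns species, adduct, n_ox
#'   (one row per oxidized target), e.g. from [buildTargetTable()] filtered
#'   to n_ox >= 1; default: 1..3 ox of OOO and OOL for both NH4 and Na
#'   adducts.
#' @param windows for stage 1: list of mass windows (default
#'   [defaultWindows()] for the oil).
#' @param tol EIC half-width (Da).
#' @param oxDegrees stage-1 oxidized degrees.
#' @param perReplicate if TRUE, return per-replicate records instead of
#'   replicate-averaged ones.
#' @return data.frame; replicate-averaged form has columns sample, species,
#'   ox_degree, (adduct,) condition_set, selectivity, sd, n_replicates,
#'   flags. Infinite-selectivity replicates are excluded from the average
#'   and counted in `flags`.
#' @export
batchSelectivity <- function(spectra, design, dist,
                             stage = c("stage2", "stage1"), targets = NULL,
                             windows = NULL, tol = 0.35, oxDegrees = 1:4,
                             perReplicate = FALSE) {
    stage <- match.arg(stage)
    if (is.data.frame(spectra)) {
        man <- spectra
        spectra <- lapply(seq_len(nrow(man)), function(i)
            readSpectrum(man$path[i], conditionSetId = man$condition_set[i],
                         replicate = man$replicate[i], sample = man$sample[i]))
    }
    ids <- vapply(spectra, conditionSetId, 1L)
    if (any(!ids %in% design@runs$run_id))
        stop("spectra reference condition sets absent from the design: ",
             paste(unique(ids[!ids %in% design@runs$run_id]), collapse = ", "))

    if (stage == "stage2") {
        if (is.null(targets))
            targets <- expand.grid(species = c("OOO", "OOL"),
                                   adduct = c("[M+NH4]+", "[M+Na]+"),
                                   n_ox = 1:3, stringsAsFactors = FALSE)
        targets <- targets[targets$n_ox >= 1L, , drop = FALSE]
        spCache <- lapply(stats::setNames(nm = unique(targets$species)),
                          tagSpecies)
        ions <- lapply(seq_len(nrow(targets)), function(i) {
            sp <- spCache[[targets$species[i]]]
            list(ox = targetIon(sp, targets$n_ox[i], targets$adduct[i]),
                 nonox = targetIon(sp, 0L, targets$adduct[i]))
        })
        recs <- list()
        for (s in spectra) {
            for (pair in ions) {
                recs[[length(recs) + 1L]] <-
                    stage2Selectivity(s, pair$ox, pair$nonox, dist, tol)
            }
        }
        out <- do.call(rbind, recs)
        keys <- c("sample", "species", "ox_degree", "adduct", "condition_set")
    } else {
        if (is.null(windows))
            windows <- defaultWindows("oil")
        out <- do.call(rbind, lapply(spectra, stage1Selectivity,
                                     windows = windows, dist = dist,
                                     oxDegrees = oxDegrees))
        keys <- c("sample", "species", "ox_degree", "condition_set")
    }
    if (perReplicate)
        return(out)
    .aggregateReplicates(out, keys)
}

.aggregateReplicates <- function(records, keys) {
    grp <- interaction(records[keys], drop = TRUE, lex.order = TRUE)
    rows <- lapply(split(records, grp), function(g) {
        finite <- is.finite(g$selectivity)
        nInf <- sum(!finite)
        base <- g[1L, keys, drop = FALSE]
        if (!any(finite)) {
            cbind(base, data.frame(selectivity = NA_real_, sd = NA_real_,
                                   n_replicates = 0L,
                                   flags = "all_replicates_infinite"))
        } else {
            av <- averageReplicates(g$selectivity[finite])
            flags <- c(if (nzchar(av$flag)) av$flag,
                       if (nInf > 0L) sprintf("%d_infinite_excluded", nInf))
            cbind(base, data.frame(selectivity = av$mean, sd = av$sd,
                                   n_replicates = av$n,
                                   flags = paste(flags, collapse = ";")))
        }
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$condition_set), , drop = FALSE]
}

#' Write a tidy selectivity table
#'
#' @param records data.frame from [batchSelectivity()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSelectivity <- function(records, path) {
    utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
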
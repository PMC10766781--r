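#' Reference NMR concentrations of the oxidized rapeseed oil
#'
#' Convenience constructor for the oxidized rapeseed oil used throughout the
#' examples: 0.022 mol aldehyde, 0.167 mol epoxide and 0.236 mol
#' hydroperoxide groups per kg TAG, with a mean TAG mass of 885 g/mol.
#'
#' @return An [NmrGroupQuant-class].
#' @examples
#' faProfileFromNmr(oxidizedRapeseedOilNmr())
#' @export
oxidizedRapeseedOilNmr <- function() {
    NmrGroupQuant(aldehyde = 0.022, epoxide = 0.167, hydroperoxide = 0.236,
                  meanTagMass = 885)
}

#' Convert NMR group concentrations into a per-FA oxidation profile
#'
#' With a mean TAG mass of M g/mol, 1 kg of oil contains 1000/M mol TAG and
#' three times as many mol of fatty-acid (FA) chains. Aldehyde and epoxide
#' groups each add one oxygen to a chain, hydroperoxides add two, and chains
#' carrying more than one oxidized group are neglected, so
#' `p1 = (aldehyde + epoxide) / molFA`, `p2 = hydroperoxide / molFA` and
#' `p0 = 1 - p1 - p2`.
#'
#' @param q an [NmrGroupQuant-class].
#' @param digits optional number of decimals to which `p1` and `p2` are
#'   rounded before `p0` is recomputed as their complement. Use this to
#'   reproduce worked examples computed from reported-precision intermediate
#'   fractions (e.g. `digits = 3` turns the oxidized rapeseed oil input into
#'   the published 0.056 / 0.070 / 0.874). Default `NULL`: full precision.
#' @return A [FaOxidationProfile-class].
#' @examples
#' faProfileFromNmr(oxidizedRapeseedOilNmr())
#' faProfileFromNmr(oxidizedRapeseedOilNmr(), digits = 3)
#' @export
faProfileFromNmr <- function(q, digits = NULL) {
    stopifnot(is(q, "NmrGroupQuant"))
    validObject(q)
    molFA <- 3 * (1000 / q@meanTagMass)
    p1 <- (q@aldehyde + q@epoxide) / molFA
    p2 <- q@hydroperoxide / molFA
    if (!is.null(digits)) {
        p1 <- round(p1, digits)
        p2 <- round(p2, digits)
    }
    p0 <- 1 - p1 - p2
    if (p0 < 0)
        stop("infeasible composition: oxidized groups exceed ",
             sprintf("%.2f mol FA per kg (p0 = %.4f < 0)", molFA, p0))
    FaOxidationProfile(p0, p1, p2)
}

#' TAG oxidation-degree distribution from a per-FA profile
#'
#' The three sn positions of the glycerol backbone are assumed to oxidize
#' independently, each chain carrying 0, 1 or 2 added oxygens with the
#' profile's fractions. The total number of added oxygens per TAG, k = 0..6,
#' then follows the trinomial expansion
#' \deqn{P(k) = \sum_{i+j+l=3,\; j+2l=k} \frac{3!}{i!\,j!\,l!}
#'       p_0^i p_1^j p_2^l}{P(k) = sum 3!/(i!j!l!) p0^i p1^j p2^l}
#' equivalent to enumerating the 27 ordered chain-state triples.
#'
#' @param p a [FaOxidationProfile-class].
#' @return A [TagOxDistribution-class].
#' @examples
#' tagOxDistribution(FaOxidationProfile(0.874, 0.056, 0.07))
#' @export
tagOxDistribution <- function(p) {
    stopifnot(is(p, "FaOxidationProfile"))
    validObject(p)
    pv <- p@p
    prob <- numeric(7)
    for (j in 0:3) {          # chains with one added oxygen
        for (l in 0:(3 - j)) { # chains with two added oxygens
            i <- 3L - j - l    # unoxidized chains
            k <- j + 2L * l
            coef <- factorial(3) / (factorial(i) * factorial(j) * factorial(l))
            prob[k + 1L] <- prob[k + 1L] +
                coef * pv["p0"]^i * pv["p1"]^j * pv["p2"]^l
        }
    }
    names(prob) <- paste0("ox", 0:6)
    new("TagOxDistribution", prob = prob)
}

#' Composition fractions used to normalize the selectivity factor
#'
#' Returns the model fraction of TAG molecules in the oxidized class (the
#' requested oxidation degrees) and the non-oxidized class (k = 0). These are
#' the "NMR %" denominators of the selectivity factor.
#'
#' @param d a [TagOxDistribution-class].
#' @param oxDegrees integer vector of oxidation degrees counted as oxidized
#'   (subset of 1..6; default 1:4, the degrees observed above trace level in
#'   oxidized rapeseed oil).
#' @return list with elements `fracOx` and `fracNonox`.
#' @examples
#' d <- tagOxDistribution(FaOxidationProfile(0.874, 0.056, 0.07))
#' normalizationFractions(d)
#' @export
normalizationFractions <- function(d, oxDegrees = 1:4) {
    stopifnot(is(d, "TagOxDistribution"))
    oxDegrees <- as.integer(oxDegrees)
    if (length(oxDegrees) == 0L || any(oxDegrees < 1L) || any(oxDegrees > 6L))
        stop("'oxDegrees' must be a non-empty subset of 1..6")
    fracOx <- sum(d@prob[oxDegrees + 1L])
    fracNonox <- unname(d@prob[1L])
    if (fracOx <= 0 || fracNonox <= 0)
        stop("normalization undefined: composition fraction is zero ",
             sprintf("(fracOx = %.3g, fracNonox = %.3g); ", fracOx, fracNonox),
             "selectivity cannot be computed for this sample")
    list(fracOx = fracOx, fracNonox = fracNonox)
}

#' Flag negligible high oxidation degrees
#'
#' @param d a [TagOxDistribution-class].
#' @param threshold probability below which a degree is flagged negligible
#'   (default 0.005, i.e. 0.5 %).
#' @return logical(7), named ox0..ox6, TRUE where the degree is negligible.
#' @export
negligibleOx <- function(d, threshold = 0.005) {
    stopifnot(is(d, "TagOxDistribution"))
    d@prob < threshold
}

#' Read a table of NMR group quantifications
#'
#' CSV with columns `sample_id`, `aldehyde_mol_per_kg`, `epoxide_mol_per_kg`,
#' `hydroperoxide_mol_per_kg` and optional `mean_tag_mass` (default 885).
#'
#' @param path CSV file path.
#' @return data.frame, one row per sample.
#' @export
readNmrQuant <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "aldehyde_mol_per_kg", "epoxide_mol_per_kg",
              "hydroperoxide_mol_per_kg")
    if (!all(need %in% names(df)))
        stop("NMR table must contain columns: ", paste(need, collapse = ", "))
    if (nrow(df) == 0L)
        stop("NMR table '", path, "' contains no samples")
    if (is.null(df$mean_tag_mass))
        df$mean_tag_mass <- 885
    df
}

#' Per-sample TAG oxidation-degree distributions
#'
#' Applies [faProfileFromNmr()] and [tagOxDistribution()] to each row of an
#' NMR quantification table.
#'
#' @param nmr data.frame as returned by [readNmrQuant()].
#' @param digits passed to [faProfileFromNmr()].
#' @return data.frame: sample_id, p0, p1, p2, ox0..ox6.
#' @export
tagDistributionTable <- function(nmr, digits = NULL) {
    res <- lapply(seq_len(nrow(nmr)), function(i) {
        q <- NmrGroupQuant(nmr$aldehyde_mol_per_kg[i],
                           nmr$epoxide_mol_per_kg[i],
                           nmr$hydroperoxide_mol_per_kg[i],
                           nmr$mean_tag_mass[i])
        prof <- tryCatch(faProfileFromNmr(q, digits = digits),
                         error = function(e)
                             stop("sample '", nmr$sample_id[i], "': ",
                                  conditionMessage(e), call. = FALSE))
        d <- tagOxDistribution(prof)
        c(faFractions(prof), oxProbabilities(d))
    })
    out <- cbind(data.frame(sample_id = nmr$sample_id),
                 as.data.frame(do.call(rbind, res)))
    out
}

#' Enumerate the ordered oxidation-state triples of a TAG
#'
#' Explicitly lists all ordered assignments of chain oxidation states
#' (0, 1 or 2 added oxygens) to the three sn positions — 27 combinations —
#' with their occurrence probabilities under a per-FA profile. Aggregating
#' the probabilities by total added oxygens reproduces [tagOxDistribution()].
#'
#' @param p a [FaOxidationProfile-class].
#' @return data.frame with 27 rows: sn1, sn2, sn3 (added oxygens per chain),
#'   n_ox (total), prob.
#' @examples
#' nrow(enumerateOxTriples(FaOxidationProfile(0.874, 0.056, 0.07)))
#' @export
enumerateOxTriples <- function(p) {
    stopifnot(is(p, "FaOxidationProfile"))
    pv <- p@p
    g <- expand.grid(sn3 = 0:2, sn2 = 0:2, sn1 = 0:2)[, 3:1]
    g$n_ox <- g$sn1 + g$sn2 + g$sn3
    g$prob <- pv[g$sn1 + 1L] * pv[g$sn2 + 1L] * pv[g$sn3 + 1L]
    rownames(g) <- NULL
    g
}
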
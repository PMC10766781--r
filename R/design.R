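#' The five ionization factors at their default levels
#'
#' A: solvent additive (NH4Fo, NaOAc, NaI; categorical), B: additive
#' concentration (0.05 / 0.1 / 0.2 mM), C: sheath gas temperature
#' (150 / 250 / 350 degC), D: capillary voltage (2000 / 3500 / 5000 V),
#' E: nozzle voltage (500 / 1000 / 1500 V).
#'
#' @return list of five [DesignFactor-class] objects, named A..E.
#' @examples
#' defaultIonizationFactors()
#' @export
defaultIonizationFactors <- function() {
    list(
        A = designFactor("A", "additive", c("NH4Fo", "NaOAc", "NaI")),
        B = designFactor("B", "conc_mM", c(0.05, 0.1, 0.2), "mM"),
        C = designFactor("C", "sheath_C", c(150, 250, 350), "degC"),
        D = designFactor("D", "capillary_V", c(2000, 3500, 5000), "V"),
        E = designFactor("E", "nozzle_V", c(500, 1000, 1500), "V"))
}

#' Generate the regular 3^(5-1) fractional factorial design
#'
#' The 81 runs are the full three-level factorial on factors A..D, ordered
#' lexicographically (A slowest), with factor E determined by the GF(3)
#' defining relation `E = g1*A + g2*B + g3*C + g4*D (mod 3)` on the level
#' indices 0..2. This regular fraction keeps main effects and two-way
#' interactions unconfounded with each other (resolution V), so both are
#' estimable from the 81 runs.
#'
#' @param factors list of five [DesignFactor-class] objects (default
#'   [defaultIonizationFactors()]).
#' @param generator integer(4) GF(3) coefficients of A..D; all must be
#'   nonzero mod 3, otherwise a main effect would be confounded with another
#'   main effect.
#' @return An [FrfDesign-class] with resolved physical values per run.
#' @examples
#' d <- generateDesign()
#' head(designRuns(d))
#' @export
generateDesign <- function(factors = defaultIonizationFactors(),
                           generator = c(1L, 1L, 1L, 1L)) {
    if (length(factors) != 5L)
        stop("exactly five factors are required")
    for (f in factors) validObject(f)
    generator <- as.integer(generator) %% 3L
    if (length(generator) != 4L || any(generator == 0L))
        stop("design-resolution error: all generator coefficients must be ",
             "nonzero mod 3 (a zero confounds E with a subset of A..D)")
    grid <- expand.grid(D = 0:2, C = 0:2, B = 0:2, A = 0:2)[, 4:1]
    E <- as.integer(as.matrix(grid) %*% generator %% 3L)
    runs <- data.frame(run_id = seq_len(nrow(grid)), grid, E = E)
    names(factors) <- LETTERS[1:5]
    for (code in LETTERS[1:5]) {
        f <- factors[[code]]
        runs[[f@name]] <- f@levels[runs[[code]] + 1L]
    }
    rownames(runs) <- NULL
    new("FrfDesign", runs = runs, factors = factors, generator = generator)
}

#' Validate a design table
#'
#' Checks run count (81), row uniqueness, one-factor balance (each level 27
#' times), two-factor balance (each ordered level pair 9 times), and reports
#' the confounding structure implied by a single-generator regular fraction.
#'
#' @param design an [FrfDesign-class] or a run data.frame with level columns
#'   A..E.
#' @return list: `checks` (data.frame check/pass/detail), `pass` (logical
#'   all-pass), `confounding` (character description).
#' @examples
#' validateDesign(generateDesign())$pass
#' @export
validateDesign <- function(design) {
    runs <- if (is(design, "FrfDesign")) design@runs else design
    lev <- as.matrix(runs[, LETTERS[1:5]])
    checks <- list()
    add <- function(check, pass, detail)
        checks[[length(checks) + 1L]] <<- data.frame(
            check = check, pass = pass, detail = detail)
    add("n_runs", nrow(lev) == 81L,
        sprintf("%d runs (expected 81)", nrow(lev)))
    add("unique_runs", anyDuplicated(as.data.frame(lev)) == 0L,
        "no duplicated level combinations")
    oneOk <- TRUE
    for (j in 1:5) {
        tab <- tabulate(lev[, j] + 1L, 3L)
        if (!all(tab == nrow(lev) / 3)) oneOk <- FALSE
    }
    add("one_factor_balance", oneOk && nrow(lev) == 81L,
        "each level of each factor occurs 27 times")
    pairOk <- TRUE
    for (j in 1:4) for (k in (j + 1):5) {
        tab <- table(lev[, j], lev[, k])
        if (!(all(dim(tab) == c(3, 3)) && all(tab == nrow(lev) / 9)))
            pairOk <- FALSE
    }
    add("two_factor_balance", pairOk && nrow(lev) == 81L,
        "each ordered level pair of any two factors occurs 9 times")
    checks <- do.call(rbind, checks)
    conf <- if (is(design, "FrfDesign"))
        sprintf(paste0(
            "defining relation E = %s (mod 3); word length 5 (resolution V):",
            " main effects and two-way interactions are aliased only with",
            " three-way or higher interactions"),
            paste(sprintf("%d*%s", design@generator, LETTERS[1:4]),
                  collapse = " + "))
    else "unknown (no generator supplied)"
    list(checks = checks, pass = all(checks$pass), confounding = conf)
}

#' Materialize runs as physical condition sets
#'
#' @param design an [FrfDesign-class].
#' @return data.frame with run_id, level indices A..E and the resolved
#'   additive, conc_mM, sheath_C, capillary_V, nozzle_V values; all 81
#'   conditions are distinct.
#' @examples
#' resolveConditions(generateDesign())[42, ]
#' @export
resolveConditions <- function(design) {
    stopifnot(is(design, "FrfDesign"))
    design@runs
}

#' Export / import a design as CSV
#'
#' @param design an [FrfDesign-class].
#' @param path CSV path.
#' @return `writeDesign`: `path`, invisibly. `readDesign`: the run
#'   data.frame (level indices plus resolved values).
#' @export
writeDesign <- function(design, path) {
    utils::write.csv(resolveConditions(design), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' @rdname writeDesign
#' @export
readDesign <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("run_id", LETTERS[1:5])
    if (!all(need %in% names(df)))
        stop("design CSV must contain columns: ",
             paste(need, collapse = ", "))
    df
}

#' Rebuild an FrfDesign from a run table
#'
#' @param runs run data.frame as produced by [readDesign()].
#' @param factors factor list (default [defaultIonizationFactors()]).
#' @param generator defining-relation coefficients used to produce the table.
#' @return An [FrfDesign-class].
#' @export
designFromRuns <- function(runs, factors = defaultIonizationFactors(),
                           generator = c(1L, 1L, 1L, 1L)) {
    names(factors) <- LETTERS[1:5]
    new("FrfDesign", runs = runs, factors = factors,
        generator = as.integer(generator))
}
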
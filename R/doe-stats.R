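#' Fit the selectivity ANOVA for one response
#'
#' Fixed-effects ANOVA of the selectivity factor over the design: five main
#' effects (2 df each) and all ten two-way interactions (4 df each), tested
#' against the residual mean square. On the balanced, orthogonal regular
#' fraction the sequential sums of squares coincide with types II/III. All
#' factors — including the numeric ones — enter as unordered 3-level factors.
#'
#' @param records per-replicate selectivity records (columns `condition_set`,
#'   `selectivity`, and optionally `species`/`ox_degree`/`adduct` used to
#'   subset a single response). Replicate-averaged records also work but
#'   leave fewer residual degrees of freedom.
#' @param design the [FrfDesign-class] the records were acquired under.
#' @param species,oxDegree,adduct optional filters selecting one response.
#' @param transform "identity" (default) or "log" (natural log of the
#'   selectivity, appropriate for multiplicative noise).
#' @param interactions include the ten two-way interactions (default TRUE).
#' @return A [SelectivityAnova-class].
#' @examples
#' \dontrun{
#' fit <- fitSelectivityAnova(records, generateDesign(), species = "OOO",
#'                            oxDegree = 3)
#' anovaTable(fit)
#' }
#' @export
fitSelectivityAnova <- function(records, design, species = NULL,
                                oxDegree = NULL, adduct = NULL,
                                transform = c("identity", "log"),
                                interactions = TRUE) {
    transform <- match.arg(transform)
    if (!is.null(species))
        records <- records[records$species %in% species, , drop = FALSE]
    if (!is.null(oxDegree))
        records <- records[records$ox_degree %in% oxDegree, , drop = FALSE]
    if (!is.null(adduct) && "adduct" %in% names(records))
        records <- records[records$adduct %in% adduct, , drop = FALSE]
    respCols <- intersect(c("species", "ox_degree", "adduct"), names(records))
    if (length(respCols)) {
        combos <- unique(records[respCols])
        if (nrow(combos) > 1L)
            stop("records contain ", nrow(combos), " responses; subset to a ",
                 "single species/ox degree/adduct before fitting")
    }
    runs <- design@runs
    if (any(!records$condition_set %in% runs$run_id))
        stop("records reference condition sets absent from the design")
    nAll <- nrow(records)
    records <- records[is.finite(records$selectivity), , drop = FALSE]
    nExcluded <- nAll - nrow(records)
    if (nExcluded > 0L)
        message(nExcluded,
                " non-finite selectivity record(s) excluded from the ANOVA")
    idx <- match(records$condition_set, runs$run_id)
    dat <- data.frame(
        y = if (transform == "log") log(records$selectivity)
            else records$selectivity)
    for (code in LETTERS[1:5])
        dat[[code]] <- factor(runs[[code]][idx], levels = 0:2)
    form <- if (interactions) y ~ (A + B + C + D + E)^2
            else y ~ A + B + C + D + E
    fit <- stats::aov(form, data = dat)
    if (stats::df.residual(fit) == 0L)
        stop("saturated model: zero residual degrees of freedom; supply ",
             "replicate records or drop interactions (interactions = FALSE)")
    sm <- summary(fit)[[1]]
    tab <- data.frame(term = trimws(rownames(sm)), df = sm$Df,
                      sum_sq = sm$`Sum Sq`, mean_sq = sm$`Mean Sq`,
                      F = sm$`F value`, p = sm$`Pr(>F)`)
    resp <- if (length(respCols))
        paste(vapply(respCols, function(cc)
            as.character(records[[cc]][1L]), ""), collapse = "/")
    else "selectivity"
    new("SelectivityAnova", fit = fit, table = tab, response = resp,
        transform = transform, nExcluded = as.integer(nExcluded))
}

#' Tukey comparisons of a factor's level means
#'
#' Studentized-range based simultaneous pairwise comparisons of the three
#' level means, at family-wise level `alpha`.
#'
#' @param fit a [SelectivityAnova-class].
#' @param factor factor code "A".."E".
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame: comparison, diff, lwr, upr, p_adj, significant.
#' @export
tukeyComparisons <- function(fit, factor = "A", alpha = 0.05) {
    stopifnot(is(fit, "SelectivityAnova"), factor %in% LETTERS[1:5])
    if (stats::df.residual(fit@fit) <= 0L)
        stop("Tukey comparisons require residual degrees of freedom")
    tk <- stats::TukeyHSD(fit@fit, which = factor, conf.level = 1 - alpha)
    m <- tk[[factor]]
    data.frame(comparison = rownames(m), diff = m[, "diff"],
               lwr = m[, "lwr"], upr = m[, "upr"], p_adj = m[, "p adj"],
               significant = m[, "p adj"] < alpha, row.names = NULL)
}

#' Rank condition sets and recommend factor levels
#'
#' Condition sets are ranked by their mean standardized selectivity across
#' responses (each response z-scored over its 81 condition means, so strong
#' and weak responders weigh equally); ties are broken by lower mean
#' replicate SD. Per-factor recommendations come from Tukey comparisons: for
#' each response the best level of each factor is taken where it is
#' distinguishable from the worst level at `alpha`, and the modal winner
#' across responses is reported.
#'
#' @param records replicate-averaged selectivity records from
#'   [batchSelectivity()] (one or more responses).
#' @param design the [FrfDesign-class].
#' @param alpha significance level for the Tukey comparisons.
#' @param transform response transform for the per-response ANOVA fits.
#' @param perReplicateRecords optional per-replicate records used for the
#'   ANOVA fits (more residual df); defaults to `records`.
#' @return list with `ranking` (data.frame condition_set, mean_z, mean_sd,
#'   rank, plus resolved factor levels), `factorRecommendations` (data.frame
#'   factor, level, value, n_responses_significant), `discriminates`
#'   (logical: FALSE when no term is significant for any response, i.e. the
#'   data show no discrimination between conditions).
#' @export
recommendConditions <- function(records, design, alpha = 0.05,
                                transform = c("identity", "log"),
                                perReplicateRecords = NULL) {
    transform <- match.arg(transform)
    runs <- design@runs
    respCols <- intersect(c("sample", "species", "ox_degree", "adduct"),
                          names(records))
    respKey <- interaction(records[respCols], drop = TRUE)
    fin <- is.finite(records$selectivity)

    ## ranking by mean standardized selectivity
    zrec <- records[fin, , drop = FALSE]
    zkey <- droplevels(respKey[fin])
    if (is.null(zrec$sd))
        zrec$sd <- 0
    zrec$z <- unsplit(lapply(split(zrec$selectivity, zkey), function(v) {
        s <- stats::sd(v)
        if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }), zkey)
    agg <- stats::aggregate(cbind(mean_z = z) ~ condition_set, data = zrec,
                            FUN = mean)
    sdagg <- stats::aggregate(cbind(mean_sd = sd) ~ condition_set,
                              data = zrec, FUN = mean)
    agg <- merge(agg, sdagg, by = "condition_set", all.x = TRUE)
    agg <- agg[order(-agg$mean_z, agg$mean_sd), , drop = FALSE]
    agg$rank <- seq_len(nrow(agg))
    valueCols <- setdiff(names(runs), c("run_id", LETTERS[1:5]))
    agg <- cbind(agg, runs[match(agg$condition_set, runs$run_id), valueCols,
                           drop = FALSE])
    rownames(agg) <- NULL

    ## per-factor Tukey winners across responses
    fitRecords <- if (is.null(perReplicateRecords)) records
                  else perReplicateRecords
    fitKey <- interaction(fitRecords[intersect(respCols, names(fitRecords))],
                          drop = TRUE)
    anySignif <- FALSE
    winners <- list()
    for (rk in levels(fitKey)) {
        sub <- fitRecords[fitKey == rk, , drop = FALSE]
        yv <- sub$selectivity[is.finite(sub$selectivity)]
        # an (almost) constant response carries no information about the
        # factors; F ratios would be numerical noise
        if (length(yv) < 2L || stats::sd(yv) <= 1e-10 * max(abs(yv), 1e-300))
            next
        fit <- tryCatch(
            fitSelectivityAnova(sub, design, transform = transform),
            error = function(e) NULL)
        if (is.null(fit))
            next
        if (any(fit@table$p[fit@table$term != "Residuals"] < alpha,
                na.rm = TRUE))
            anySignif <- TRUE
        means <- tryCatch(stats::model.tables(fit@fit, type = "means"),
                          error = function(e) NULL)
        for (code in LETTERS[1:5]) {
            tk <- tukeyComparisons(fit, code, alpha)
            if (!any(tk$significant))
                next
            lv <- means$tables[[code]]
            best <- as.integer(names(which.max(lv)))
            winners[[length(winners) + 1L]] <-
                data.frame(factor = code, level = best, response = rk)
        }
    }
    factorRec <- if (length(winners)) {
        wdf <- do.call(rbind, winners)
        do.call(rbind, lapply(split(wdf, wdf$factor), function(g) {
            tab <- sort(table(g$level), decreasing = TRUE)
            lvl <- as.integer(names(tab)[1L])
            f <- design@factors[[g$factor[1L]]]
            data.frame(factor = g$factor[1L], level = lvl,
                       value = as.character(f@levels[lvl + 1L]),
                       n_responses_significant = nrow(g))
        }))
    } else {
        data.frame(factor = character(), level = integer(),
                   value = character(), n_responses_significant = integer())
    }
    rownames(factorRec) <- NULL
    list(ranking = agg, factorRecommendations = factorRec,
         discriminates = anySignif)
}
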
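#' Read a pipeline configuration
#'
#' A single YAML file with per-subcommand sections (`nmr`, `design`,
#' `simulate`, `selectivity`, `optimize`) and a top-level `seed`. Missing
#' sections fall back to defaults matching the standard settings
#' (alpha = 0.05, duplicate replicates, default factor levels and windows,
#' EIC tolerance 0.35 Da).
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path))
        stop("config file '", path, "' does not exist")
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$seed))
        cfg$seed <- 1L
    alpha <- cfg$optimize$alpha
    if (!is.null(alpha) && (alpha <= 0 || alpha >= 1))
        stop("'alpha' must be in (0, 1)")
    cfg
}

.cfgDesign <- function(cfg) {
    gen <- cfg$design$generator
    if (is.null(gen))
        gen <- c(1L, 1L, 1L, 1L)
    generateDesign(generator = gen)
}

#' Pipeline subcommands
#'
#' Thin orchestration wrappers used by the `oxsel` command-line script; each
#' takes the parsed configuration list and writes its output files.
#' `cmdNmr` converts an NMR quantification CSV into per-sample TAG
#' oxidation-degree distributions; `cmdDesign` writes the design table;
#' `cmdSimulate` generates a synthetic campaign; `cmdSelectivity` computes
#' the selectivity table from a manifest of spectra; `cmdOptimize` runs the
#' ANOVA/Tukey analysis and writes reports.
#'
#' @param cfg configuration list from [readPipelineConfig()].
#' @param seed integer seed overriding the config seed.
#' @name pipelineCommands
#' @return the primary output object of the step, invisibly.
NULL

#' @rdname pipelineCommands
#' @export
cmdNmr <- function(cfg, seed = NULL) {
    sec <- cfg$nmr
    nmr <- readNmrQuant(sec$input)
    out <- tagDistributionTable(nmr, digits = sec$digits)
    utils::write.csv(out, sec$out, row.names = FALSE, quote = FALSE)
    message("wrote distributions for ", nrow(out), " sample(s) to ", sec$out)
    invisible(out)
}

#' @rdname pipelineCommands
#' @export
cmdDesign <- function(cfg, seed = NULL) {
    design <- .cfgDesign(cfg)
    rep <- validateDesign(design)
    if (!rep$pass)
        stop("generated design failed validation")
    writeDesign(design, cfg$design$out)
    message("wrote ", nrow(designRuns(design)), " runs to ", cfg$design$out)
    invisible(design)
}

#' @rdname pipelineCommands
#' @export
cmdSimulate <- function(cfg, seed = NULL) {
    sec <- cfg$simulate
    design <- .cfgDesign(cfg)
    model <- ionizationModel(
        scenario = if (is.null(sec$scenario)) "planted" else sec$scenario,
        leakage = if (is.null(sec$leakage)) 0 else sec$leakage,
        noiseCV = if (is.null(sec$noise_cv)) 0.1 else sec$noise_cv)
    spec <- campaignSpec(
        design,
        replicates = if (is.null(sec$replicates)) 2L else sec$replicates,
        seed = if (is.null(seed)) cfg$seed else seed)
    camp <- simulateCampaign(spec, model, dir = sec$out_dir,
                             sample = if (is.null(sec$sample)) "oil"
                                      else sec$sample)
    message("simulated ", nrow(camp$manifest), " spectra into ", sec$out_dir)
    invisible(camp)
}

#' @rdname pipelineCommands
#' @export
cmdSelectivity <- function(cfg, seed = NULL) {
    sec <- cfg$selectivity
    design <- .cfgDesign(cfg)
    nmr <- readNmrQuant(sec$nmr)
    row <- if (is.null(sec$sample_id)) 1L
           else which(nmr$sample_id == sec$sample_id)[1L]
    q <- NmrGroupQuant(nmr$aldehyde_mol_per_kg[row],
                       nmr$epoxide_mol_per_kg[row],
                       nmr$hydroperoxide_mol_per_kg[row],
                       nmr$mean_tag_mass[row])
    dist <- tagOxDistribution(faProfileFromNmr(q, digits = sec$digits))
    manifest <- readManifest(sec$manifest, dir = dirname(sec$manifest))
    missing <- !file.exists(manifest$path)
    if (any(missing)) {
        message(sum(missing), " spectrum file(s) missing; flagged and skipped")
        manifest <- manifest[!missing, , drop = FALSE]
    }
    stage <- if (is.null(sec$stage)) "stage2" else sec$stage
    tol <- if (is.null(sec$tol)) 0.35 else sec$tol
    recs <- batchSelectivity(manifest, design, dist, stage = stage, tol = tol,
                             perReplicate = isTRUE(sec$per_replicate))
    writeSelectivity(recs, sec$out)
    nInf <- sum(grepl("infinite", recs$flags %||% recs$flag))
    message("wrote ", nrow(recs), " selectivity records to ", sec$out,
            " (", nInf, " infinite-flagged)")
    invisible(recs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname pipelineCommands
#' @export
cmdOptimize <- function(cfg, seed = NULL) {
    sec <- cfg$optimize
    design <- .cfgDesign(cfg)
    records <- utils::read.csv(sec$records, stringsAsFactors = FALSE)
    alpha <- sec$alpha %||% 0.05
    transform <- sec$transform %||% "identity"
    rec <- recommendConditions(records, design, alpha = alpha,
                               transform = transform)
    outDir <- sec$out_dir %||% "."
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    utils::write.csv(rec$ranking, file.path(outDir, "ranking.csv"),
                     row.names = FALSE, quote = FALSE)

    ## per-response ANOVA and Tukey reports
    respCols <- intersect(c("sample", "species", "ox_degree", "adduct"),
                          names(records))
    key <- interaction(records[respCols], drop = TRUE)
    anovaRows <- list(); tukeyRows <- list()
    for (rk in levels(key)) {
        sub <- records[key == rk, , drop = FALSE]
        fit <- tryCatch(fitSelectivityAnova(sub, design,
                                            transform = transform),
                        error = function(e) NULL)
        if (is.null(fit)) next
        at <- anovaTable(fit); at$response <- rk
        anovaRows[[rk]] <- at
        for (code in LETTERS[1:5]) {
            tk <- tukeyComparisons(fit, code, alpha)
            tk$factor <- code; tk$response <- rk
            tukeyRows[[paste(rk, code)]] <- tk
        }
    }
    if (length(anovaRows))
        utils::write.csv(do.call(rbind, anovaRows),
                         file.path(outDir, "anova_report.csv"),
                         row.names = FALSE)
    if (length(tukeyRows))
        utils::write.csv(do.call(rbind, tukeyRows),
                         file.path(outDir, "tukey_report.csv"),
                         row.names = FALSE)
    lines <- c("Recommended ionization conditions",
               "=================================",
               if (!rec$discriminates)
                   "NO DISCRIMINATION: no factor significantly affects selectivity"
               else
                   apply(rec$factorRecommendations, 1, function(r)
                       sprintf("factor %s: level %s (%s), significant in %s response(s)",
                               r[["factor"]], r[["level"]], r[["value"]],
                               r[["n_responses_significant"]])),
               "",
               "Top 5 condition sets by mean standardized selectivity:",
               utils::capture.output(print(utils::head(rec$ranking, 5),
                                           row.names = FALSE)))
    writeLines(lines, file.path(outDir, "recommendation.txt"))
    message("wrote reports to ", outDir,
            if (!rec$discriminates) " (no discrimination)" else "")
    invisible(rec)
}

#' Command-line entry point
#'
#' Dispatches `oxsel <subcommand> --config <yaml> [--seed <int>]` where the
#' subcommand is one of nmr, design, simulate, selectivity, optimize. Used by
#' the `inst/scripts/oxsel.R` wrapper; returns an exit status instead of
#' calling `quit()` so it is testable.
#'
#' @param args character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status (0 on success), invisibly.
#' @export
oxselMain <- function(args = commandArgs(trailingOnly = TRUE)) {
    usage <- paste(
        "usage: oxsel <nmr|design|simulate|selectivity|optimize>",
        "--config <file.yaml> [--seed <int>]")
    status <- tryCatch({
        if (length(args) < 1L)
            stop(usage, call. = FALSE)
        sub <- args[[1L]]
        getOpt <- function(flag) {
            i <- which(args == flag)
            if (length(i) == 1L && i < length(args)) args[[i + 1L]] else NULL
        }
        cfgPath <- getOpt("--config")
        if (is.null(cfgPath))
            stop(usage, call. = FALSE)
        cfg <- readPipelineConfig(cfgPath)
        seed <- getOpt("--seed")
        if (!is.null(seed)) {
            cfg$seed <- as.integer(seed)
            seed <- as.integer(seed)
        }
        fn <- switch(sub, nmr = cmdNmr, design = cmdDesign,
                     simulate = cmdSimulate, selectivity = cmdSelectivity,
                     optimize = cmdOptimize,
                     stop("unknown subcommand '", sub, "'\n", usage,
                          call. = FALSE))
        fn(cfg, seed = seed)
        0L
    }, error = function(e) {
        message("error: ", conditionMessage(e))
        1L
    })
    invisible(status)
}
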
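#' @include AllClasses.R simulate.R qpcr.R cnv.R mito.R viability.R
#' @include cohortStats.R io.R
NULL

.configAsList <- function(config) {
    slots <- slotNames(config)
    out <- lapply(slots, function(s) {
        v <- slot(config, s)
        if (!is.null(names(v))) as.list(v) else v
    })
    names(out) <- slots
    out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the stages in dependency order - cohort simulation, qPCR
#' quantification, copy-number calling, NGS mitochondrial
#' quantification, viability-threshold derivation and evaluation, and
#' cohort statistics - writing each stage's outputs plus a run manifest
#' (seed, configuration snapshot, file digests, timestamps) to
#' `outDir`. Any stage failure halts the run with the failing stage
#' named.
#'
#' @param config a [SimulationConfig-class]; its seed drives every
#'   stage.
#' @param outDir output directory (created if absent).
#' @param referenceDeltaCt reference-sample delta-Ct used by the qPCR
#'   stage, cycles.
#' @param stages subset of
#'   `c("simulate", "qpcr", "cnv", "mtdna", "viability", "stats")`;
#'   stages a later stage depends on are run regardless.
#' @param nCnvSamples number of embryos run through the read-depth
#'   copy-number caller (kept small; the caller is per-sample).
#' @param grid optional [BinGrid-class] for the copy-number stage; a
#'   synthetic 22-autosome grid is built when omitted.
#' @param totalBases simulated aligned bases per sample for the NGS
#'   mitochondrial fraction stage.
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @examples
#' \donttest{
#' out <- tempfile("run")
#' m <- runPipeline(simulationConfig(nEmbryos = 40, seed = 1),
#'                  outDir = out, nCnvSamples = 1)
#' list.files(out)
#' }
#' @export
runPipeline <- function(config, outDir,
                        referenceDeltaCt = 8,
                        stages = c("simulate", "qpcr", "cnv", "mtdna",
                                   "viability", "stats"),
                        nCnvSamples = 2L, grid = NULL,
                        totalBases = 2e6, quiet = FALSE) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    stages <- match.arg(stages, several.ok = TRUE)
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    say <- function(stage, fmt, ...) {
        if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
    }
    runStage <- function(stage, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)), call. = FALSE))
    }
    outputs <- character(0)
    emit <- function(path) outputs <<- c(outputs, path)
    started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

    cohort <- runStage("simulate", {
        say("simulate", "cohort of %d embryos", config@nEmbryos)
        cohort <- simulateCohort(config)
        emit(writeSampleSheet(cohort, file.path(outDir,
                                                "sample_sheet.csv")))
        cohort
    })

    rqTable <- NULL
    if (any(c("qpcr", "viability", "stats") %in% stages)) {
        rqTable <- runStage("qpcr", {
            say("qpcr", "quantifying %d samples", nrow(cohort))
            ct <- simulateQpcrTable(cohort, config, referenceDeltaCt)
            emit(writeCtTable(ct, file.path(outDir, "ct_table.csv")))
            rq <- quantifyCtTable(ct, referenceDeltaCt,
                                  threshold = config@viabilityCutoff)
            path <- file.path(outDir, "rq_table.csv")
            write.csv(rq, path, row.names = FALSE, quote = FALSE)
            emit(path)
            rq
        })
    }

    if ("cnv" %in% stages) {
        runStage("cnv", {
            if (is.null(grid))
                grid <- syntheticBinGrid(seed = .substreamSeed(
                    if (is.finite(config@seed)) config@seed else 0,
                    "pipelinegrid"))
            emit(writeBinGrid(grid, file.path(outDir, "bin_grid.tsv")))
            take <- utils::head(order(cohort$ploidy == "euploid"),
                                nCnvSamples)
            say("cnv", "calling %d sample(s) over %d bins",
                length(take), length(grid))
            countsList <- list()
            callList <- list()
            for (i in take) {
                id <- cohort$embryo_id[i]
                counts <- simulateBinCounts(
                    grid, config, cohort$aneuploid_chromosomes[i],
                    index = i)
                prof <- callCopyNumber(counts, grid, embryoId = id)
                countsList[[id]] <- counts
                calls <- chromosomeCalls(prof)
                callList[[id]] <- list(
                    verdict = if (isAneuploid(prof)) "aneuploid"
                              else "euploid",
                    calls = as.data.frame(calls))
            }
            emit(writeBinCounts(countsList,
                                file.path(outDir, "bin_counts.tsv")))
            path <- file.path(outDir, "cnv_calls.json")
            jsonlite::write_json(callList, path, auto_unbox = TRUE,
                                 digits = NA)
            emit(path)
        })
    }

    if ("mtdna" %in% stages) {
        runStage("mtdna", {
            say("mtdna", "NGS mito fraction for %d samples", nrow(cohort))
            .maybeSeed(config@seed, "mitobases")
            mito <- rbinom(nrow(cohort), size = as.integer(totalBases),
                           prob = cohort$true_mt_fraction)
            mq <- mitoFraction(mito, as.integer(totalBases) - mito,
                               embryoId = cohort$embryo_id)
            path <- file.path(outDir, "mito_quant.csv")
            write.csv(mq, path, row.names = FALSE, quote = FALSE)
            emit(path)
            pile <- simulateMitoPileup(
                config, nSites = 2000L, depthMean = 150,
                plantedHeteroplasmies = data.frame(position = c(324, 1243),
                                                   fraction = c(0.3, 0.5)))
            emit(writePileup(pile, file.path(outDir, "mito_pileup.tsv")))
            calls <- heteroplasmyCalls(pile)
            path <- file.path(outDir, "heteroplasmy_calls.tsv")
            write.table(calls, path, sep = "\t", row.names = FALSE,
                        quote = FALSE)
            emit(path)
        })
    }

    if ("viability" %in% stages) {
        runStage("viability", {
            known <- merge(
                cohort[cohort$ploidy == "euploid" &
                       cohort$stage == "blastocyst" &
                       cohort$outcome != "unknown",
                       c("embryo_id", "outcome")],
                rqTable[, c("embryo_id", "rq")], by = "embryo_id")
            names(known)[names(known) == "rq"] <- "value"
            say("viability", "deriving threshold from %d outcomes",
                nrow(known))
            model <- deriveThreshold(known, roundingGrid = 0.0005)
            emit(writeThresholdModel(model, file.path(outDir,
                                                      "threshold.json")))
            metrics <- evaluateCohort(known, model)
            path <- file.path(outDir, "viability_metrics.json")
            jsonlite::write_json(metricsAsList(metrics), path,
                                 auto_unbox = TRUE, digits = NA,
                                 na = "null")
            emit(path)
            pred <- data.frame(
                embryo_id = known$embryo_id,
                value = known$value,
                prediction = classifyViability(known$value, model))
            path <- file.path(outDir, "predictions.csv")
            write.csv(pred, path, row.names = FALSE, quote = FALSE)
            emit(path)
        })
    }

    if ("stats" %in% stages) {
        runStage("stats", {
            say("stats", "group comparisons and per-age summary")
            merged <- merge(cohort, rqTable[, c("embryo_id", "rq")],
                            by = "embryo_id")
            cmp <- compareCohortGroups(merged, valueColumn = "rq")
            cmp <- lapply(cmp, function(x)
                if (is.null(x)) "skipped: group too small" else x)
            path <- file.path(outDir, "comparisons.json")
            jsonlite::write_json(cmp, path, auto_unbox = TRUE,
                                 digits = NA, na = "null")
            emit(path)
            summ <- summarizeByAge(
                merged[merged$stage == "blastocyst", , drop = FALSE],
                valueColumn = "rq")
            path <- file.path(outDir, "age_summary.csv")
            write.csv(summ, path, row.names = FALSE, quote = FALSE)
            emit(path)
        })
    }

    manifest <- list(
        package_version = as.character(packageVersion("mitoEmbryo")),
        seed = config@seed,
        config = .configAsList(config),
        stages = stages,
        started = started,
        finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        outputs = lapply(stats::setNames(outputs, basename(outputs)),
                         function(f)
                             list(path = basename(f),
                                  md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    invisible(manifest)
}
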
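#' @include AllClasses.R utils.R
NULL

.checkOutcomeTable <- function(records) {
    need <- c("value", "outcome")
    missing <- setdiff(need, names(records))
    if (length(missing))
        stop("records lack column(s): ", paste(missing, collapse = ", "))
    bad <- setdiff(unique(records$outcome),
                   c("implanted", "not_implanted", "unknown"))
    if (length(bad))
        stop("unrecognized outcome value(s): ", paste(bad, collapse = ", "))
    invisible(records)
}

#' Derive a viability threshold from a training cohort
#'
#' Formalizes the retrospective threshold rule: the cutoff is the
#' smallest multiple of `roundingGrid` strictly greater than the
#' largest assay value observed among implanting embryos, so that by
#' construction no training implanter exceeds it. At a rounding grid of
#' 0.003 a training cohort whose implanters all sit below 0.003 yields
#' exactly the published qPCR cutoff.
#'
#' @param records `data.frame` with columns `value` (assay units,
#'   positive) and `outcome` (`"implanted"` / `"not_implanted"`;
#'   `"unknown"` rows are ignored).
#' @param roundingGrid grid the cutoff is rounded up to (default
#'   0.0005 in qPCR relative-quantity units).
#' @param assay `"qpcr"` or `"ngs"` (label carried by the model).
#' @return a [ThresholdModel-class] with `derivation = "derived"`.
#' @examples
#' train <- data.frame(value = c(0.0004, 0.00217, 0.0164),
#'                     outcome = c("implanted", "implanted",
#'                                 "not_implanted"))
#' cutoff(deriveThreshold(train))                        # 0.0025
#' cutoff(deriveThreshold(train, roundingGrid = 0.003))  # 0.003
#' @export
deriveThreshold <- function(records, roundingGrid = 0.0005,
                            assay = c("qpcr", "ngs")) {
    assay <- match.arg(assay)
    .assertScalarNumber(roundingGrid, "roundingGrid", positive = TRUE)
    .checkOutcomeTable(records)
    records <- records[records$outcome != "unknown", , drop = FALSE]
    nImpl <- sum(records$outcome == "implanted")
    if (nImpl == 0L)
        stop("no implanted records: a threshold cannot be derived; ",
             "use fixedThreshold() instead")
    if (sum(records$outcome == "not_implanted") == 0L)
        stop("no non-implanted records: derivation needs both outcomes")
    maxImpl <- max(records$value[records$outcome == "implanted"])
    k <- floor(maxImpl / roundingGrid + 1e-9) + 1
    new("ThresholdModel", assay = assay, cutoff = k * roundingGrid,
        derivation = "derived", trainingMaxImplanter = maxImpl)
}

#' Fixed viability threshold
#'
#' Wraps a known cutoff (e.g. the published 0.003 for qPCR relative
#' quantity or 0.07 for the NGS percent) in a [ThresholdModel-class].
#'
#' @param cutoff positive threshold in assay units.
#' @param assay `"qpcr"` or `"ngs"`.
#' @return a [ThresholdModel-class] with `derivation = "fixed"`.
#' @examples
#' fixedThreshold(0.003, "qpcr")
#' @export
fixedThreshold <- function(cutoff = 0.003, assay = c("qpcr", "ngs")) {
    assay <- match.arg(assay)
    new("ThresholdModel", assay = assay, cutoff = cutoff,
        derivation = "fixed", trainingMaxImplanter = NA_real_)
}

#' Classify assay values against a viability threshold
#'
#' `"predicted_nonviable"` when the value strictly exceeds the model's
#' cutoff, else `"potentially_viable"`; a value exactly at the cutoff
#' is potentially viable.
#'
#' @param values positive assay values.
#' @param model a [ThresholdModel-class].
#' @return character vector in
#'   `{"potentially_viable", "predicted_nonviable"}`.
#' @examples
#' m <- fixedThreshold(0.003, "qpcr")
#' classifyViability(c(0.00426, 0.000131, 0.003), m)
#' @export
classifyViability <- function(values, model) {
    stopifnot(is(model, "ThresholdModel"))
    if (any(!is.finite(values) | values <= 0))
        stop("assay values must be positive")
    ifelse(values > model@cutoff, "predicted_nonviable",
           "potentially_viable")
}

#' Evaluate a viability threshold on a cohort with known outcomes
#'
#' Computes the predictive-performance metrics of a threshold on
#' embryos with known transfer outcome: the negative predictive value
#' (share of above-cutoff embryos that failed to implant; `NA` when no
#' embryo is above), the implantation rates below the cutoff and
#' overall, and the share of non-implanters sitting above the cutoff.
#' Rows with outcome `"unknown"` are excluded with a message tally.
#'
#' @param records `data.frame` with columns `value` and `outcome`.
#' @param model a [ThresholdModel-class].
#' @return a [CohortMetrics-class].
#' @examples
#' cohort <- data.frame(
#'     value = c(rep(0.001, 42), rep(0.001, 33), rep(0.005, 14)),
#'     outcome = c(rep("implanted", 42), rep("not_implanted", 47)))
#' evaluateCohort(cohort, fixedThreshold(0.003, "qpcr"))
#' @export
evaluateCohort <- function(records, model) {
    stopifnot(is(model, "ThresholdModel"))
    .checkOutcomeTable(records)
    unknown <- records$outcome == "unknown"
    if (any(unknown)) {
        message(sprintf("evaluateCohort: excluding %d record(s) with ",
                        sum(unknown)), "unknown outcome")
        records <- records[!unknown, , drop = FALSE]
    }
    if (nrow(records) == 0L)
        stop("no records with known outcome")
    above <- records$value > model@cutoff
    implanted <- records$outcome == "implanted"
    n <- nrow(records)
    nAbove <- sum(above)
    nBelow <- n - nAbove
    nAboveImpl <- sum(above & implanted)
    nNonimpl <- sum(!implanted)
    new("CohortMetrics",
        nTransferred = n,
        nImplanted = sum(implanted),
        nAbove = nAbove,
        nAboveImplanted = nAboveImpl,
        npv = if (nAbove > 0L) 100 * (nAbove - nAboveImpl) / nAbove
              else NA_real_,
        rateBelow = if (nBelow > 0L)
            100 * sum(!above & implanted) / nBelow else NA_real_,
        rateOverall = 100 * sum(implanted) / n,
        flaggedNonimplanterFraction = if (nNonimpl > 0L)
            100 * sum(above & !implanted) / nNonimpl else 0)
}

#' Blinded prospective validation of a viability threshold
#'
#' Derives (or fixes) the threshold on a training cohort and evaluates
#' it on a disjoint test cohort, touching test outcomes only inside the
#' evaluation step. Any embryo-id overlap between the two cohorts
#' violates blinding and is an error.
#'
#' @param training,test `data.frame`s with columns `embryo_id`,
#'   `value`, `outcome`.
#' @param roundingGrid passed to [deriveThreshold()] when no fixed
#'   model is supplied.
#' @param model optional [ThresholdModel-class]; when supplied it is
#'   used as-is (fixed-threshold mode) and the training cohort is only
#'   checked for id disjointness.
#' @param assay assay label for a derived model.
#' @return a list with `model` (the [ThresholdModel-class] used) and
#'   `metrics` (the test-set [CohortMetrics-class]).
#' @examples
#' train <- data.frame(embryo_id = paste0("T", 1:4),
#'                     value = c(0.001, 0.002, 0.004, 0.005),
#'                     outcome = c("implanted", "implanted",
#'                                 "not_implanted", "not_implanted"))
#' test <- data.frame(embryo_id = paste0("P", 1:3),
#'                    value = c(0.001, 0.004, 0.002),
#'                    outcome = c("implanted", "not_implanted",
#'                                "not_implanted"))
#' blindedValidate(train, test, roundingGrid = 0.003)
#' @export
blindedValidate <- function(training, test, roundingGrid = 0.0005,
                            model = NULL, assay = c("qpcr", "ngs")) {
    assay <- match.arg(assay)
    if (!all(c("embryo_id") %in% names(training)) ||
        !all(c("embryo_id") %in% names(test)))
        stop("training and test cohorts need an 'embryo_id' column")
    overlap <- intersect(training$embryo_id, test$embryo_id)
    if (length(overlap))
        stop("blinding violated: embryo id(s) in both cohorts: ",
             paste(utils::head(overlap, 5L), collapse = ", "))
    if (is.null(model))
        model <- deriveThreshold(training, roundingGrid, assay)
    stopifnot(is(model, "ThresholdModel"))
    list(model = model, metrics = evaluateCohort(test, model))
}
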
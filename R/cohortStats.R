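#' @include utils.R
NULL

#' Split a cohort into reproductively younger and older groups
#'
#' The published grouping contrasts women aged up to 37 with women aged
#' 38 and over; the boundary is configurable.
#'
#' @param records `data.frame` with a `maternal_age` column.
#' @param boundary first age counted as "older" (default 38; younger
#'   means `age <= boundary - 1`).
#' @return a list with `younger` and `older` subsets of `records`.
#' @examples
#' cohort <- data.frame(maternal_age = c(37, 38), rq = c(1, 2))
#' lengths(splitByAge(cohort))
#' @export
splitByAge <- function(records, boundary = 38) {
    if (!"maternal_age" %in% names(records))
        stop("records lack a 'maternal_age' column")
    list(younger = records[records$maternal_age <= boundary - 1, ,
                           drop = FALSE],
         older = records[records$maternal_age >= boundary, ,
                         drop = FALSE])
}

#' Unpaired two-tailed t-test between two groups
#'
#' Thin, total wrapper around the unpaired two-sample t-test used for
#' all cohort comparisons. Welch's variant (unequal variances,
#' Welch-Satterthwaite degrees of freedom) is the default; the pooled
#' variant is available for strict classical replication. When both
#' groups have zero variance the test degenerates: equal means give
#' `t = 0, p = 1` by convention, unequal means `t = +/-Inf, p = 0`.
#'
#' @param valuesA,valuesB numeric vectors, each with at least 2 finite
#'   values.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param labelA,labelB optional group labels carried in the result.
#' @return a list: `groupALabel`, `groupBLabel`, `nA`, `nB`, `meanA`,
#'   `meanB`, `tStatistic`, `degreesOfFreedom`, `pTwoTailed`,
#'   `variant`.
#' @examples
#' tTestUnpaired(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6),
#'               variant = "pooled")$pTwoTailed
#' @export
tTestUnpaired <- function(valuesA, valuesB,
                          variant = c("welch", "pooled"),
                          labelA = "A", labelB = "B") {
    variant <- match.arg(variant)
    valuesA <- valuesA[is.finite(valuesA)]
    valuesB <- valuesB[is.finite(valuesB)]
    if (length(valuesA) < 2L || length(valuesB) < 2L)
        stop("each group needs at least 2 finite values")
    degenerate <- var(valuesA) == 0 && var(valuesB) == 0
    if (degenerate) {
        equal <- mean(valuesA) == mean(valuesB)
        t <- if (equal) 0 else sign(mean(valuesA) - mean(valuesB)) * Inf
        p <- if (equal) 1 else 0
        df <- length(valuesA) + length(valuesB) - 2
    } else {
        fit <- t.test(valuesA, valuesB,
                      var.equal = identical(variant, "pooled"))
        t <- unname(fit$statistic)
        df <- unname(fit$parameter)
        p <- fit$p.value
    }
    list(groupALabel = labelA, groupBLabel = labelB,
         nA = length(valuesA), nB = length(valuesB),
         meanA = mean(valuesA), meanB = mean(valuesB),
         tStatistic = t, degreesOfFreedom = df, pTwoTailed = p,
         variant = variant)
}

#' Per-age cohort summary in the shape of the published summary tables
#'
#' One row per observed maternal age with the count, range and mean of
#' the chosen value per ploidy group. Groups with a single embryo
#' report the value as the range and mark the mean not applicable
#' (`NA`), as the published tables do.
#'
#' @param records `data.frame` with `maternal_age`, `ploidy` and the
#'   value column.
#' @param valueColumn name of the value column (default `"rq"`).
#' @return a `data.frame`: `age`, then per ploidy group (`euploid`,
#'   `aneuploid`) the columns `n_*`, `min_*`, `max_*`, `mean_*`.
#' @examples
#' cohort <- data.frame(maternal_age = c(26, 30, 30),
#'                      ploidy = c("euploid", "euploid", "aneuploid"),
#'                      rq = c(0.002273, 0.001, 0.003))
#' summarizeByAge(cohort)
#' @export
summarizeByAge <- function(records, valueColumn = "rq") {
    need <- c("maternal_age", "ploidy", valueColumn)
    missing <- setdiff(need, names(records))
    if (length(missing))
        stop("records lack column(s): ", paste(missing, collapse = ", "))
    if (nrow(records) == 0L) {
        out <- data.frame(age = numeric(0))
        for (g in c("euploid", "aneuploid"))
            for (s in c("n", "min", "max", "mean"))
                out[[paste(s, g, sep = "_")]] <- numeric(0)
        return(out)
    }
    ages <- sort(unique(records$maternal_age))
    rows <- lapply(ages, function(a) {
        row <- list(age = a)
        for (g in c("euploid", "aneuploid")) {
            v <- records[[valueColumn]][records$maternal_age == a &
                                        records$ploidy == g]
            row[[paste0("n_", g)]] <- length(v)
            row[[paste0("min_", g)]] <- if (length(v)) min(v) else NA_real_
            row[[paste0("max_", g)]] <- if (length(v)) max(v) else NA_real_
            row[[paste0("mean_", g)]] <- if (length(v) > 1L) mean(v)
                                         else NA_real_
        }
        as.data.frame(row)
    })
    do.call(rbind, rows)
}

#' Standard cohort group comparisons
#'
#' Runs the three comparisons the analysis reports on a cohort table:
#' reproductively younger vs older (blastocysts), euploid vs aneuploid
#' (blastocysts), and implanted vs not-implanted (euploid blastocysts
#' with known outcome). No multiple-testing correction is applied -
#' raw two-tailed p-values are reported, one per comparison.
#'
#' @param records cohort `data.frame` with `maternal_age`, `stage`,
#'   `ploidy`, `outcome` and the value column.
#' @param valueColumn name of the value column (default
#'   `"true_mt_rq"`; use `"rq"` for measured quantities).
#' @param ageBoundary passed to [splitByAge()].
#' @param variant passed to [tTestUnpaired()].
#' @return a named list of [tTestUnpaired()] results (`age`,
#'   `ploidy`, `outcome`); comparisons with an undersized group are
#'   `NULL`.
#' @export
compareCohortGroups <- function(records, valueColumn = "true_mt_rq",
                                ageBoundary = 38,
                                variant = c("welch", "pooled")) {
    variant <- match.arg(variant)
    v <- records[[valueColumn]]
    blast <- records$stage == "blastocyst"
    safe <- function(a, b, la, lb)
        if (sum(is.finite(a)) >= 2L && sum(is.finite(b)) >= 2L)
            tTestUnpaired(a, b, variant, la, lb) else NULL
    groups <- splitByAge(records[blast, , drop = FALSE], ageBoundary)
    list(
        age = safe(groups$older[[valueColumn]],
                   groups$younger[[valueColumn]],
                   "older", "younger"),
        ploidy = safe(v[blast & records$ploidy == "aneuploid"],
                      v[blast & records$ploidy == "euploid"],
                      "aneuploid", "euploid"),
        outcome = safe(
            v[blast & records$ploidy == "euploid" &
              records$outcome == "not_implanted"],
            v[blast & records$ploidy == "euploid" &
              records$outcome == "implanted"],
            "not_implanted", "implanted"))
}
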
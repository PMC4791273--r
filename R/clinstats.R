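#' Load the 28-patient tissue-microarray cohort
#'
#' The published immunohistochemistry cohort: 10 normal mucosa, 9 diploid
#' and 9 aneuploid colorectal carcinoma records with sex, age, TNM/UICC
#' staging, overall survival, vital status and thymosin beta-4
#' immunopositivity (IP, fraction of positively stained pixels, averaged
#' over duplicate cores). Shipped as a plain-text fixture.
#'
#' @param path CSV path; defaults to the bundled fixture.
#' @return data.frame of 28 cohort records, validated on load.
#' @export
load_tma_cohort <- function(path = system.file("extdata", "tma_table1b.csv",
                                               package = "imsmarker")) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age", "group", "ploidy", "T", "N", "M", "G",
            "UICC", "survival_months", "status", "ip")
  if (!identical(names(rec), need)) {
    stopf("cohort fixture corrupt: unexpected column set")
  }
  counts <- table(ifelse(rec$group == "normal", "normal", rec$ploidy))
  if (!identical(as.integer(counts[c("normal", "diploid", "aneuploid")]),
                 c(10L, 9L, 9L)) || nrow(rec) != 28L) {
    stopf("cohort fixture corrupt: expected 10 normal / 9 diploid / 9 aneuploid records")
  }
  if (any(rec$ip < 0 | rec$ip > 1)) stopf("cohort fixture corrupt: IP outside [0, 1]")
  tum <- rec$group == "tumor"
  if (any(is.na(rec$survival_months[tum])) || any(!rec$status[tum] %in% c("dead", "alive"))) {
    stopf("cohort fixture corrupt: tumors need survival and vital status")
  }
  rec
}

#' Load the published classifier peak tables
#'
#' Per-comparison peak masses with the model's printed weights and, where
#' printed, the ROC AUC. Shipped fixture data, not reproduced quantities.
#'
#' @param comparison `"normal_vs_carcinoma"`, `"diploid_vs_aneuploid"` or
#'   `"all"`.
#' @return data.frame with `comparison`, `peak_mz`, `weight`, `auc`.
#' @export
load_snn_peak_table <- function(comparison = c("all", "normal_vs_carcinoma",
                                               "diploid_vs_aneuploid")) {
  comparison <- match.arg(comparison)
  tab <- utils::read.delim(system.file("extdata", "snn_peak_weights.tsv",
                                       package = "imsmarker"))
  if (comparison != "all") tab <- tab[tab$comparison == comparison, ]
  tab
}

#' Load the peak-to-protein mass lookup fixture
#'
#' Protein assignments for the published marker peaks. Single identified
#' masses carry `mass_lo_da == mass_hi_da`; multi-protein entries carry the
#' printed mass range.
#'
#' @return data.frame with `peak_mz`, `name`, `accession`, `mass_lo_da`,
#'   `mass_hi_da`.
#' @export
load_protein_table <- function() {
  utils::read.delim(system.file("extdata", "protein_masses.tsv",
                                package = "imsmarker"))
}

#' Median immunopositivity of a patient subset
#'
#' Standard sample median (even n: mean of the two central order
#' statistics), reported rounded half-up to 4 decimals as in clinical
#' tables.
#'
#' @param records cohort data.frame.
#' @param subset logical vector or an expression-free selector function of
#'   the records; `NULL` selects everything.
#' @param var column to summarize (default `"ip"`).
#' @return the rounded median.
#' @export
group_median <- function(records, subset = NULL, var = "ip") {
  keep <- if (is.null(subset)) rep(TRUE, nrow(records))
          else if (is.function(subset)) subset(records)
          else subset
  v <- records[[var]][keep]
  if (!length(v)) stopf("empty selection")
  round_half_up(stats::median(v), 4)
}

#' Mann-Whitney U test
#'
#' U from rank sums with midranks for ties; the p-value is exact (by
#' enumeration) for small tie-free samples (total n <= 12) and otherwise a
#' normal approximation with tie and continuity correction.
#'
#' @param a,b numeric samples.
#' @param exact_max total sample size up to which the exact p is used.
#' @return list with `u`, `p`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 12L) {
  if (!length(a) || !length(b)) stopf("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && (length(a) + length(b)) <= exact_max
  wt <- stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  list(u = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal-approximation-with-tie-correction")
}

#' Optimal dichotomization cutoff (Youden)
#'
#' Candidate cutoffs are the midpoints between adjacent distinct sorted
#' values; the winner maximizes Youden's index (sensitivity + specificity
#' - 1) with a case counted marker-positive iff `value > cutoff`. Ties on
#' Youden break toward higher specificity. The cutoff is reported rounded
#' half-up to 4 decimals, sensitivity and specificity to whole percent.
#'
#' @param values numeric marker values (e.g. immunopositivity).
#' @param labels class label per value.
#' @param positive the positive class.
#' @return list with `cutoff`, `sensitivity`, `specificity` (fractions),
#'   `sensitivity_pct`, `specificity_pct` (rounded whole percents) and
#'   `youden`.
#' @export
optimal_cutoff <- function(values, labels, positive) {
  labels <- as.character(labels)
  if (!any(labels == positive) || all(labels == positive)) {
    stopf("both classes must be present")
  }
  sv <- sort(unique(values))
  if (length(sv) < 2L) stopf("all values identical; no cutoff exists")
  # midpoints between adjacent distinct values, plus the two boundary
  # cutoffs (everything positive / everything negative)
  cands <- c(sv[1] - (sv[2] - sv[1]) / 2,
             (sv[-1] + sv[-length(sv)]) / 2,
             sv[length(sv)] + (sv[length(sv)] - sv[length(sv) - 1]) / 2)
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  sens <- vapply(cands, function(ct) mean(pos > ct), numeric(1))
  spec <- vapply(cands, function(ct) mean(neg <= ct), numeric(1))
  youden <- sens + spec - 1
  best <- order(-youden, -spec)[1]
  list(cutoff = round_half_up(cands[best], 4),
       sensitivity = sens[best], specificity = spec[best],
       sensitivity_pct = round_half_up(100 * sens[best]),
       specificity_pct = round_half_up(100 * spec[best]),
       youden = youden[best])
}

#' Dichotomize marker values at a cutoff
#'
#' Marker-positive iff `ip > cutoff`, strictly; values exactly at the
#' cutoff are assigned negative (the published rule uses two strict
#' inequalities that leave equality undefined; this is the declared
#' resolution) and flagged via the `at_cutoff` attribute.
#'
#' @param ip numeric marker values, or a cohort data.frame with an `ip`
#'   column.
#' @param cutoff finite cutoff value.
#' @return logical vector of marker positivity.
#' @export
dichotomize <- function(ip, cutoff) {
  if (is.data.frame(ip)) ip <- ip$ip
  if (!is.finite(cutoff)) stopf("cutoff must be finite")
  out <- ip > cutoff
  attr(out, "at_cutoff") <- which(ip == cutoff)
  out
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator via [survival::survfit()]; censored times do
#' not drop the curve.
#'
#' @param times follow-up times (months, >= 0).
#' @param events event indicator: logical/0-1, or `"dead"`/`"alive"`.
#' @return a `survfit` object.
#' @export
kaplan_meier <- function(times, events) {
  if (!length(times)) stopf("empty input")
  if (any(times < 0)) stopf("times must be >= 0")
  ev <- as_event(events)
  survival::survfit(survival::Surv(times, ev) ~ 1)
}

as_event <- function(events) {
  if (is.character(events) || is.factor(events)) {
    as.integer(as.character(events) == "dead")
  } else {
    as.integer(events)
  }
}

#' Log-rank test between survival groups
#'
#' @param times follow-up times.
#' @param events event indicators (see [kaplan_meier()]).
#' @param group group label per subject (>= 2 groups).
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  ev <- as_event(events)
  if (sum(ev) < 1L) stopf("log-rank requires at least one event")
  group <- factor(group)
  if (nlevels(group) < 2L) stopf("log-rank requires >= 2 groups")
  sd <- survival::survdiff(survival::Surv(times, ev) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson fit via [survival::coxph()] with
#' Breslow tie handling by default; hazard ratio `exp(beta)` with the 95%
#' Wald interval `exp(beta +/- z * SE)` from the observed information
#' (`z = qnorm(0.975)`).
#'
#' @param times follow-up times.
#' @param events event indicators.
#' @param x covariate (binary marker or numeric); must be non-constant.
#' @param ties_method `"breslow"` (default) or `"efron"`.
#' @return an object of class `cox_result`: `hr`, `ci_low`, `ci_high`,
#'   `p` (Wald), `beta`, `se`, `n_events`, `ties_method`, `converged`.
#' @export
cox_univariate <- function(times, events, x, ties_method = c("breslow", "efron")) {
  ties_method <- match.arg(ties_method)
  ev <- as_event(events)
  if (length(unique(x)) < 2L) stopf("covariate is constant")
  if (sum(ev) < 1L) stopf("no events: cannot fit a Cox model")
  x <- if (is.logical(x)) as.integer(x) else x
  fit <- survival::coxph(survival::Surv(times, ev) ~ x, ties = ties_method,
                         control = survival::coxph.control(eps = 1e-10, iter.max = 50))
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  z <- stats::qnorm(0.975)
  converged <- is.finite(beta) && is.finite(se) && se < 1e3
  structure(list(hr = exp(beta), ci_low = exp(beta - z * se),
                 ci_high = exp(beta + z * se),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 beta = beta, se = se, n_events = sum(ev),
                 ties_method = ties_method, converged = converged),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> HR %.3f (95%% CI %.3f-%.3f), p = %.4g, %d events, %s ties%s\n",
              x$hr, x$ci_low, x$ci_high, x$p, x$n_events, x$ties_method,
              if (!x$converged) " [non-convergent: monotone likelihood?]" else ""))
  invisible(x)
}

#' Binary (logistic) regression of one binary outcome on another
#'
#' Logistic fit by [stats::glm()] with the Wald p-value for the slope;
#' Fisher's exact p is reported alongside for small tables. A zero cell
#' triggers Haldane continuity handling (0.5 added to every cell) for the
#' reported odds ratio, flagged in the result.
#'
#' @param x binary predictor (e.g. aneuploid ploidy status).
#' @param y binary outcome (e.g. marker positivity).
#' @return list with `odds_ratio`, `p` (Wald), `fisher_p`, `table`,
#'   `continuity` flag.
#' @export
binary_regression <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("a margin of the 2x2 table is structurally empty")
  }
  continuity <- any(tab == 0)
  fit <- stats::glm(y ~ x, family = stats::binomial())
  coefs <- summary(fit)$coefficients
  or <- if (continuity) {
    t2 <- tab + 0.5
    unname((t2[2, 2] * t2[1, 1]) / (t2[1, 2] * t2[2, 1]))
  } else {
    unname(exp(stats::coef(fit)["x"]))
  }
  list(odds_ratio = or, p = unname(coefs["x", "Pr(>|z|)"]),
       fisher_p = stats::fisher.test(tab)$p.value,
       table = tab, continuity = continuity)
}

#' Run the full clinical-statistics stage on a cohort
#'
#' Group medians, the Mann-Whitney comparisons, the Youden cutoff between
#' diploid and aneuploid carcinomas, dichotomization, Kaplan-Meier /
#' log-rank, the univariate Cox model, and the ploidy-marker binary
#' regression — the statistics computable from the published cohort table.
#'
#' @param cohort cohort data.frame as from [load_tma_cohort()].
#' @param ties_method Cox tie handling (default `"breslow"`).
#' @return list with all stage results.
#' @export
tma_stats <- function(cohort, ties_method = "breslow") {
  tum <- cohort[cohort$group == "tumor", ]
  dip <- tum[tum$ploidy == "diploid", ]
  ane <- tum[tum$ploidy == "aneuploid", ]
  nor <- cohort[cohort$group == "normal", ]
  cut <- optimal_cutoff(tum$ip, tum$ploidy, positive = "aneuploid")
  marker <- dichotomize(tum, cut$cutoff)
  cox <- cox_univariate(tum$survival_months, tum$status, marker,
                        ties_method = ties_method)
  list(
    medians = c(diploid = group_median(dip), aneuploid = group_median(ane),
                normal = group_median(nor), carcinoma = group_median(tum)),
    mwu_diploid_vs_aneuploid = mann_whitney_u(dip$ip, ane$ip),
    mwu_normal_vs_carcinoma = mann_whitney_u(nor$ip, tum$ip),
    cutoff = cut,
    marker_positive = sum(marker),
    km_positive = kaplan_meier(tum$survival_months[marker], tum$status[marker]),
    km_negative = kaplan_meier(tum$survival_months[!marker], tum$status[!marker]),
    logrank = logrank_test(tum$survival_months, tum$status, marker),
    cox = cox,
    binary_regression = binary_regression(tum$ploidy == "aneuploid", marker)
  )
}
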
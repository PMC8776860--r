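#' Apply the cohort exclusion filters
#'
#' Removes patients with overall survival below 0, missing OS months or OS
#' status, or stage group `excluded` (stage 0 and "I/II NOS" map there, see
#' [map_stage()]). Per-criterion removal counts are logged. The filter is
#' idempotent.
#'
#' @param table Cohort data.frame with `os_months`, `os_event`,
#'   `stage_group` columns.
#' @return The filtered cohort.
#' @export
filter_tcga_cohort <- function(table) {
  stopifnot(all(c("os_months", "os_event", "stage_group") %in% names(table)))
  bad_os <- !is.na(table$os_months) & table$os_months < 0
  miss_os <- is.na(table$os_months)
  miss_status <- is.na(table$os_event)
  bad_stage <- table$stage_group == "excluded"
  drop <- bad_os | miss_os | miss_status | bad_stage
  mx_log(paste0("exclusion filter: %d OS<0, %d missing OS, %d missing status,",
                " %d excluded stage; %d of %d removed"),
         sum(bad_os), sum(miss_os), sum(miss_status), sum(bad_stage),
         sum(drop), nrow(table))
  out <- table[!drop, , drop = FALSE]
  if (nrow(out) == 0L) stop("no patients remain after exclusion filters",
                            call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Median split of a continuous variable
#'
#' Values less than or equal to the sample median are labelled `low`, the
#' rest `high` (tie convention: `<= median` is low, logged once per call).
#'
#' @param values Numeric vector, n >= 2, non-constant.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) stop("median split needs n >= 2", call. = FALSE)
  if (stats::sd(v) == 0) stop("constant vector; median split undefined",
                              call. = FALSE)
  med <- stats::median(v)
  mx_log("median split at %g (ties to 'low')", med)
  factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator (censored subjects remain at risk through their
#' censoring time). Thin wrapper over [survival::survfit()] returning the
#' curve as plain vectors.
#'
#' @param times Non-negative follow-up times.
#' @param events Logical/0-1 event indicators.
#' @return A list of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`,
#'   `median` (NA when the curve never reaches 0.5).
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(all(times >= 0))
  events <- as.integer(events)
  if (sum(events) == 0L) {
    warning("no events: Kaplan-Meier curve is flat at 1", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param curve A [kaplan_meier()] result.
#' @param t Times at which to evaluate S(t).
#' @return Survival probabilities (right-continuous step function, S(0)=1).
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(ti) {
    idx <- which(curve$time <= ti)
    if (length(idx) == 0L) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

#' Log-rank test between survival groups
#'
#' @param times,events Follow-up times and event indicators.
#' @param group_labels Grouping with >= 2 non-empty groups.
#' @return List: `chisq`, `df`, `p_value`, `n_per_group`.
#' @export
log_rank <- function(times, events, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) < 2L) stop("log-rank needs >= 2 groups", call. = FALSE)
  if (any(table(g) == 0L)) stop("empty group in log-rank test", call. = FALSE)
  fit <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ g)
  df <- nlevels(g) - 1L
  list(chisq = fit$chisq, df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
       n_per_group = as.vector(table(g)))
}

new_survival_fit <- function(fit, data, iqr_terms = NULL, strata = NULL,
                             conf = 0.95) {
  s <- summary(fit)
  co <- s$coefficients
  terms <- rownames(co)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  hr_iqr <- NULL
  if (!is.null(iqr_terms)) {
    hr_iqr <- lapply(iqr_terms, function(tm) {
      iqr <- iqr_type7(data[[tm]])
      beta <- co[tm, "coef"]; se <- co[tm, "se(coef)"]
      c(hr = exp(beta * iqr),
        lo = exp((beta - z * se) * iqr),
        hi = exp((beta + z * se) * iqr),
        iqr = iqr)
    })
    names(hr_iqr) <- iqr_terms
  }
  structure(list(
    coefficients = stats::setNames(
      lapply(terms, function(tm) c(beta = co[tm, "coef"],
                                   se = co[tm, "se(coef)"])), terms),
    hr_per_iqr = hr_iqr,
    wald_p = stats::setNames(co[, "Pr(>|z|)"], terms),
    loglik = fit$loglik[length(fit$loglik)],
    n = fit$n, n_events = fit$nevent,
    strata = strata, df = length(stats::coef(fit)),
    model = fit
  ), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> n = %d, events = %d, loglik = %.3f%s\n",
              x$n, x$n_events, x$loglik,
              if (!is.null(x$strata)) paste0(", strata: ", x$strata) else ""))
  for (tm in names(x$coefficients)) {
    co <- x$coefficients[[tm]]
    cat(sprintf("  %-24s beta = %7.3f (se %.3f), p = %.3g\n",
                tm, co["beta"], co["se"], x$wald_p[tm]))
    if (!is.null(x$hr_per_iqr[[tm]])) {
      h <- x$hr_per_iqr[[tm]]
      cat(sprintf("  %-24s HR/IQR = %.3f (95%% CI %.3f-%.3f, IQR %.3g)\n",
                  "", h["hr"], h["lo"], h["hi"], h["iqr"]))
    }
  }
  invisible(x)
}

#' Univariable Cox regression reported per interquartile range
#'
#' Partial-likelihood fit (Efron tie handling) of a single continuous
#' predictor; the hazard ratio is reported per IQR change:
#' `HR = exp(beta * IQR)` with the confidence limits transformed the same
#' way. The IQR is computed on the analysis sample with linear-interpolation
#' (type 7) quantiles. Per-IQR reporting makes the HR invariant to affine
#' rescaling of the covariate.
#'
#' @param times,events Follow-up times and event indicators.
#' @param covariate Non-constant continuous covariate.
#' @param conf Confidence level (default 0.95).
#' @return A `survival_fit` with the `hr_per_iqr` slot populated.
#' @export
cox_per_iqr <- function(times, events, covariate, conf = 0.95) {
  if (stats::sd(covariate) == 0) stop("constant covariate", call. = FALSE)
  if (sum(events) == 0) stop("zero events; Cox model undefined",
                             call. = FALSE)
  df <- data.frame(time = times, event = as.integer(events), x = covariate)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = df,
                         ties = "efron")
  if (!is.null(fit$info) && any(!is.finite(stats::coef(fit)))) {
    stop("Cox fit did not converge", call. = FALSE)
  }
  new_survival_fit(fit, df, iqr_terms = "x", conf = conf)
}

#' Stage-stratified Cox models with a score-by-marker interaction
#'
#' Fits the reduced model (main effects of immune score and marker, baseline
#' hazard stratified by stage group) and the full model adding the
#' score-by-marker product term. Stratification gives each stage group its
#' own baseline hazard rather than modelling stage as a covariate, which
#' accommodates non-proportional stage effects. Also reports the marker
#' hazard ratio per IQR adjusted for the score (from the reduced model).
#'
#' @param table Filtered cohort data.frame.
#' @param score_term,marker_term Column names (e.g. `"immune_score"`,
#'   `"sox10_z"`).
#' @param strata_term Column defining the stratified baseline hazards
#'   (default `"stage_group"`).
#' @return List: `full`, `reduced` (both `survival_fit`),
#'   `marker_hr_adjusted` (per-IQR HR of the marker given the score).
#' @export
stratified_cox_interaction <- function(table, score_term, marker_term,
                                       strata_term = "stage_group") {
  need <- c("os_months", "os_event", score_term, marker_term, strata_term)
  stopifnot(all(need %in% names(table)))
  by_stratum <- tapply(as.integer(table$os_event), table[[strata_term]], sum)
  if (any(by_stratum == 0) || any(table(table[[strata_term]]) == 0)) {
    stop("every stratum must contain events", call. = FALSE)
  }
  d <- table
  d$.time <- d$os_months; d$.event <- as.integer(d$os_event)
  f_red <- stats::as.formula(sprintf(
    "survival::Surv(.time, .event) ~ %s + %s + survival::strata(%s)",
    score_term, marker_term, strata_term))
  f_full <- stats::as.formula(sprintf(
    "survival::Surv(.time, .event) ~ %s * %s + survival::strata(%s)",
    score_term, marker_term, strata_term))
  reduced <- survival::coxph(f_red, data = d, ties = "efron")
  full <- survival::coxph(f_full, data = d, ties = "efron")
  list(
    full = new_survival_fit(full, d, strata = strata_term),
    reduced = new_survival_fit(reduced, d,
                               iqr_terms = c(score_term, marker_term),
                               strata = strata_term),
    marker_hr_adjusted =
      new_survival_fit(reduced, d, iqr_terms = marker_term,
                       strata = strata_term)$hr_per_iqr[[marker_term]]
  )
}

#' Likelihood-ratio test between nested Cox models
#'
#' Statistic `2 * (loglik_full - loglik_reduced)` on a chi-square with df
#' equal to the difference in parameter counts.
#'
#' @param full,reduced `survival_fit` objects, reduced nested in full.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "survival_fit"), inherits(reduced, "survival_fit"))
  df <- full$df - reduced$df
  if (df < 0L) stop("models not nested: full has fewer parameters",
                    call. = FALSE)
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6) {
    stop("full model log-likelihood below reduced beyond tolerance; ",
         "check nesting/convergence", call. = FALSE)
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = if (df == 0L) 1 else
         stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Harrell's concordance index for a risk score
#'
#' Probability of concordance between predicted risk and observed survival
#' over usable (comparable) pairs; ties in the risk score count as 0.5
#' concordance. Higher risk is expected to go with shorter survival.
#'
#' @param times,events Follow-up times and event indicators.
#' @param risk Numeric risk scores (higher = higher hazard).
#' @return Concordance in [0, 1].
#' @export
harrell_c <- function(times, events, risk) {
  ev <- as.integer(events)
  if (sum(ev) == 0L) stop("no comparable pairs (zero events)", call. = FALSE)
  cc <- survival::concordance(survival::Surv(times, ev) ~ risk,
                              reverse = TRUE)
  unname(cc$concordance)
}

#' Harrell's c-index with bootstrap optimism correction
#'
#' Apparent concordance of a Cox model (ties in risk score count 0.5),
#' corrected for overfitting by the bootstrap: for each of `B` resamples the
#' model is refit, and the optimism is the mean of (c on the bootstrap
#' sample) minus (c of that bootstrap model evaluated on the original data).
#' Corrected c = apparent c - mean optimism. Deterministic given `seed`.
#'
#' @param table Cohort data.frame with `os_months`, `os_event`.
#' @param model_terms Character vector of covariate column names.
#' @param B Bootstrap replicates (>= 50).
#' @param seed Integer seed.
#' @return List: `apparent`, `optimism`, `corrected`, `B`.
#' @export
c_index_optimism <- function(table, model_terms, B = 200, seed = 1L) {
  if (B < 50) stop("B must be >= 50", call. = FALSE)
  need <- c("os_months", "os_event", model_terms)
  stopifnot(all(need %in% names(table)))
  d <- table[, need]
  d$os_event <- as.integer(d$os_event)
  if (sum(d$os_event) == 0) stop("no comparable pairs (zero events)",
                                 call. = FALSE)
  f <- stats::as.formula(paste("survival::Surv(os_months, os_event) ~",
                               paste(model_terms, collapse = " + ")))
  cindex <- function(fit, newdata) {
    lp <- stats::predict(fit, newdata = newdata, type = "lp")
    cc <- survival::concordance(
      survival::Surv(newdata$os_months, newdata$os_event) ~ lp,
      reverse = TRUE)
    unname(cc$concordance)
  }
  fit0 <- survival::coxph(f, data = d, ties = "efron")
  apparent <- cindex(fit0, d)
  opt <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(nrow(d), replace = TRUE)
      db <- d[idx, , drop = FALSE]
      fb <- tryCatch(survival::coxph(f, data = db, ties = "efron"),
                     error = function(e) NULL)
      if (is.null(fb)) return(NA_real_)
      cindex(fb, db) - cindex(fb, d)
    }, numeric(1))
  })
  if (anyNA(opt)) {
    mx_log("c-index bootstrap: %d of %d resamples failed to fit and were skipped",
           sum(is.na(opt)), B)
  }
  optimism <- mean(opt, na.rm = TRUE)
  list(apparent = apparent, optimism = optimism,
       corrected = apparent - optimism, B = B)
}

#' Pairwise expression tests across median-split subgroups
#'
#' Median-splits two genes into four subgroups (e.g. SOX10^hi CD8^low) and,
#' per response gene, runs all six pairwise Wilcoxon rank-sum tests with
#' Bonferroni adjustment (p multiplied by 6, capped at 1). Comparisons
#' involving a subgroup with fewer than 2 members are flagged, not computed.
#'
#' @param table Cohort data.frame.
#' @param split_gene_a,split_gene_b Column names of the two split variables.
#' @param response_genes Column names of the response expressions.
#' @return Data.frame: `response, group1, group2, n1, n2, statistic, p_raw,
#'   p_bonferroni, flagged`.
#' @export
subgroup_expression_tests <- function(table, split_gene_a, split_gene_b,
                                      response_genes) {
  a <- median_split(table[[split_gene_a]])
  b <- median_split(table[[split_gene_b]])
  grp <- interaction(ifelse(a == "high", "hi", "low"),
                     ifelse(b == "high", "hi", "low"), sep = "_")
  levels_grp <- levels(grp)
  combos <- utils::combn(levels_grp, 2L)
  out <- list()
  for (resp in response_genes) {
    y <- table[[resp]]
    for (j in seq_len(ncol(combos))) {
      g1 <- combos[1, j]; g2 <- combos[2, j]
      y1 <- y[grp == g1]; y2 <- y[grp == g2]
      flagged <- length(y1) < 2L || length(y2) < 2L
      if (flagged) {
        stat <- NA_real_; p <- NA_real_
      } else {
        wt <- suppressWarnings(stats::wilcox.test(y1, y2, exact = FALSE))
        stat <- unname(wt$statistic); p <- wt$p.value
        # a fully tied comparison has no evidence of a shift
        if (is.na(p)) p <- 1
      }
      out[[length(out) + 1L]] <- data.frame(
        response = resp, group1 = g1, group2 = g2,
        n1 = length(y1), n2 = length(y2),
        statistic = stat, p_raw = p,
        p_bonferroni = if (flagged) NA_real_ else min(1, 6 * p),
        flagged = flagged, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Linear marker-by-CD8 interaction on log2 expression
#'
#' Least-squares fit of `log2(response) ~ sox10_z + log2(cd8a_expr) +
#' sox10_z:log2(cd8a_expr)`; rows with non-positive expression where a log2
#' is required are excluded with the count logged.
#'
#' @param table Cohort data.frame.
#' @param response_gene Column name of the response expression
#'   (e.g. `"expr_IFNG"`).
#' @param marker_col Marker z-score column (default `"sox10_z"`).
#' @param cd8_col CD8 expression column (default `"cd8a_expr"`).
#' @return Data.frame: `term, estimate, se, t, p`.
#' @export
linear_interaction <- function(table, response_gene, marker_col = "sox10_z",
                               cd8_col = "cd8a_expr") {
  stopifnot(all(c(response_gene, marker_col, cd8_col) %in% names(table)))
  y <- table[[response_gene]]
  cd8 <- table[[cd8_col]]
  ok <- is.finite(y) & y > 0 & is.finite(cd8) & cd8 > 0 &
    is.finite(table[[marker_col]])
  if (sum(!ok) > 0L) {
    mx_log("linear interaction: %d row(s) excluded (non-positive expression or missing)",
           sum(!ok))
  }
  d <- data.frame(ly = log2(y[ok]), m = table[[marker_col]][ok],
                  lcd8 = log2(cd8[ok]))
  fit <- stats::lm(ly ~ m + lcd8 + m:lcd8, data = d)
  s <- summary(fit)$coefficients
  data.frame(
    term = c("intercept", marker_col, paste0("log2_", cd8_col),
             paste0(marker_col, ":log2_", cd8_col)),
    estimate = s[, 1], se = s[, 2], t = s[, 3], p = s[, 4],
    row.names = NULL, stringsAsFactors = FALSE)
}
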
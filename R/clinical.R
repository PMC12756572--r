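# Clinical outcome definitions and the statistical comparisons used in the
# descriptive and adjusted-model tables: VFD-30, proportion summaries,
# non-parametric group tests, the adjusted linear model for VFD-30, and the
# Cox proportional-hazards models.

#' Ventilator-free days at day 30
#'
#' VFD-30 = 30 - days of invasive ventilation, with death by day 30 and
#' ventilation >= 30 days both scored as 0.
#'
#' @param ventilation_days Non-negative integer days of invasive ventilation.
#' @param died_by_day30 Logical 30-day vital status.
#' @return Integer VFD-30 in [0, 30].
#' @export
compute_vfd30 <- function(ventilation_days, died_by_day30) {
  stopifnot(length(ventilation_days) == length(died_by_day30))
  if (any(ventilation_days < 0)) stop("ventilation_days must be non-negative")
  as.integer(ifelse(died_by_day30 | ventilation_days >= 30, 0L,
                    30L - ventilation_days))
}

#' Derive the outcome record table
#'
#' Adds VFD-30, the composite event (death or ventilation >= 30 days) and
#' the extubation endpoint (time to extubation, death censored at day 30)
#' to a clinical table.
#'
#' @param clinical A `clinical_table`.
#' @return Data frame: `sample_id`, `vfd30`, `event_composite`,
#'   `time_to_extubation`, `extubated` (event flag for the extubation
#'   endpoint).
#' @export
outcome_records <- function(clinical) {
  vfd <- compute_vfd30(clinical$ventilation_days, clinical$died_by_day30)
  composite <- clinical$died_by_day30 | clinical$ventilation_days >= 30
  time_ext <- pmin(clinical$ventilation_days, 30L)
  extubated <- !clinical$died_by_day30 & clinical$ventilation_days < 30
  data.frame(sample_id = clinical$sample_id, vfd30 = vfd,
             event_composite = composite,
             time_to_extubation = as.integer(time_ext),
             extubated = extubated, stringsAsFactors = FALSE)
}

# half-up rounding to one decimal (descriptive-table convention)
round_half_up1 <- function(p) floor(p * 10 + 0.5 + 1e-9) / 10

#' Percent summary of a category-by-group contingency table
#'
#' Percentages are 100 * cell / column total, rounded half-up to one
#' decimal, formatted as "n (pct%)".
#'
#' @param counts Matrix of counts, categories x groups.
#' @return List with `percent` (numeric matrix) and `formatted` (character
#'   matrix "n (x.y%)").
#' @export
proportion_summary <- function(counts) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  pct <- round_half_up1(100 * sweep(counts, 2, totals, "/"))
  fmt <- matrix(sprintf("%d (%.1f%%)", counts, pct), nrow = nrow(counts),
                dimnames = dimnames(counts))
  list(percent = pct, formatted = fmt)
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with continuity and tie
#' correction. Two-sided.
#'
#' @param x,y Numeric samples.
#' @return A `group_comparison` list: `statistic`, `p`, `test_name`.
#' @export
rank_sum_test <- function(x, y) {
  n <- length(x) + length(y)
  exact <- n <= 20 && !anyDuplicated(c(x, y))
  ht <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  structure(list(statistic = unname(ht$statistic), p = ht$p.value,
                 test_name = "rank_sum"), class = "group_comparison")
}

#' Kruskal-Wallis comparison across groups
#'
#' @param values Numeric vector.
#' @param groups Grouping factor.
#' @return A `group_comparison` list: `statistic`, `p`, `test_name`.
#' @export
kruskal_test <- function(values, groups) {
  if (length(unique(values)) == 1)
    return(structure(list(statistic = 0, p = 1,
                          test_name = "kruskal_wallis"),
                     class = "group_comparison"))
  ht <- stats::kruskal.test(values, as.factor(groups))
  structure(list(statistic = unname(ht$statistic), p = ht$p.value,
                 test_name = "kruskal_wallis"), class = "group_comparison")
}

# Design frame with the reference levels of the adjusted models: female,
# 0 to <1 month, infection/sepsis, no comorbidity, non-infectious. PIM2
# enters on the logit scale.
model_frame <- function(clinical, endotype = NULL, basicq = NULL,
                        include_sex = TRUE) {
  df <- data.frame(
    age_group = clinical$age_group,
    admission_reason = clinical$admission_reason,
    comorbidity = clinical$comorbidity,
    infection_status = clinical$infection_status,
    pim2_logit = stats::qlogis(clinical$pim2))
  if (include_sex) df$sex <- clinical$sex
  if (!is.null(endotype)) df$endotype1 <- as.integer(endotype == 1)
  if (!is.null(basicq)) df$basicq <- as.numeric(basicq)
  droplevels(df)
}

#' Adjusted linear regression for VFD-30
#'
#' Ordinary least squares of VFD-30 on endotype membership (or the BASICq
#' score) adjusted for sex, age group, reason for admission, comorbidity,
#' infection status and logit(PIM2); confidence intervals from t quantiles.
#'
#' @param clinical A `clinical_table`.
#' @param endotype Optional endotype labels (1/2) per sample.
#' @param basicq Optional BASICq score per sample (used if `endotype` NULL).
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame: `term`, `estimate`, `ci_lo`, `ci_hi`, `p`.
#' @export
fit_vfd_regression <- function(clinical, endotype = NULL, basicq = NULL,
                               conf_level = 0.95) {
  if (is.null(endotype) && is.null(basicq))
    stop("provide endotype labels or a BASICq score")
  df <- model_frame(clinical, endotype, basicq)
  df$vfd30 <- compute_vfd30(clinical$ventilation_days, clinical$died_by_day30)
  fit <- stats::lm(vfd30 ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  data.frame(term = rownames(sm), estimate = sm[, 1], ci_lo = ci[, 1],
             ci_hi = ci[, 2], p = sm[, 4], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Adjusted Cox proportional-hazards model
#'
#' Partial likelihood with Breslow tie handling (survival::coxph); hazard
#' ratios with Wald confidence intervals. Covariates follow the adjusted
#' models: endotype (or BASICq), age group, admission reason, comorbidity,
#' infection status, logit(PIM2).
#'
#' @param time Follow-up times.
#' @param event Event indicator (1 = event).
#' @param clinical A `clinical_table` (covariate source); NULL for an
#'   unadjusted model with `endotype`/`basicq` only.
#' @param endotype Optional endotype labels (1/2).
#' @param basicq Optional BASICq score.
#' @param conf_level Confidence level.
#' @return Data frame: `term`, `hr`, `ci_lo`, `ci_hi`, `p`.
#' @export
fit_cox_model <- function(time, event, clinical = NULL, endotype = NULL,
                          basicq = NULL, conf_level = 0.95) {
  event <- as.integer(event)
  if (sum(event) == 0) stop("no events in the data")
  df <- if (!is.null(clinical)) model_frame(clinical, endotype, basicq,
                                            include_sex = FALSE)
        else {
          d <- data.frame(row.names = seq_along(time))
          if (!is.null(endotype)) d$endotype1 <- as.integer(endotype == 1)
          if (!is.null(basicq)) d$basicq <- as.numeric(basicq)
          d
        }
  covars <- names(df)
  df$.time <- as.numeric(time)
  df$.event <- event
  form <- stats::reformulate(sprintf("`%s`", covars),
                             response = "survival::Surv(.time, .event)")
  fit <- survival::coxph(form, data = df, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  sm <- summary(fit, conf.int = conf_level)
  data.frame(term = rownames(sm$coefficients),
             hr = sm$conf.int[, "exp(coef)"],
             ci_lo = sm$conf.int[, 3], ci_hi = sm$conf.int[, 4],
             p = sm$coefficients[, "Pr(>|z|)"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Descriptive comparison table by endotype
#'
#' Builds the category-by-endotype proportion summaries and non-parametric
#' comparisons of the continuous variables (PIM2, ventilation days, VFD-30)
#' between endotypes.
#'
#' @param clinical A `clinical_table`.
#' @param endotype Endotype labels (1/2) per sample.
#' @return List with `proportions` (per categorical variable, formatted
#'   n (pct) by endotype) and `continuous` (data frame of medians, IQRs and
#'   rank-sum p per continuous variable).
#' @export
endotype_table1 <- function(clinical, endotype) {
  endotype <- factor(endotype, levels = c(1, 2))
  cats <- c("sex", "age_group", "admission_reason", "comorbidity",
            "infection_status")
  props <- lapply(stats::setNames(cats, cats), function(v) {
    tab <- table(clinical[[v]], endotype)
    proportion_summary(unclass(tab))$formatted
  })
  vfd <- compute_vfd30(clinical$ventilation_days, clinical$died_by_day30)
  cont <- lapply(list(pim2 = clinical$pim2,
                      ventilation_days = clinical$ventilation_days,
                      vfd30 = vfd), function(v) {
    x1 <- v[endotype == 1]; x2 <- v[endotype == 2]
    data.frame(median_e1 = stats::median(x1), median_e2 = stats::median(x2),
               p = rank_sum_test(x1, x2)$p)
  })
  cont <- cbind(variable = names(cont), do.call(rbind, cont))
  rownames(cont) <- NULL
  list(proportions = props, continuous = cont)
}
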
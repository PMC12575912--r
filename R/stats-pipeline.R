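# The cohort-level statistics layer: inter-reader agreement, normality-
# routed group comparison, logistic modeling, and the study-report driver.

#' Inter-reader intraclass correlation
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC (the
#' Shrout–Fleiss ICC(2,1)), computed from the two-way ANOVA mean squares,
#' with the conventional qualitative bands: >= 0.75 excellent,
#' 0.60–0.75 good, 0.40–0.60 fair, < 0.40 poor.
#'
#' @param reader1,reader2 Paired measurements of the same subjects by the
#'   two readers (length >= 3).
#' @return An `icc_result` list: `icc`, `band`, mean squares.
#' @examples
#' set.seed(1)
#' truth <- rlnorm(40, 2, 0.5)
#' compute_icc(truth * exp(rnorm(40, 0, 0.1)), truth * exp(rnorm(40, 0, 0.1)))
#' @export
compute_icc <- function(reader1, reader2) {
  stopifnot(is.numeric(reader1), is.numeric(reader2),
            length(reader1) == length(reader2))
  n <- length(reader1)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  x <- cbind(reader1, reader2)
  if (var(as.vector(x)) == 0) {
    stop("zero total variance: ICC undefined", call. = FALSE)
  }
  k <- 2
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = icc, band = icc_band(icc),
                 msr = msr, msc = msc, mse = mse, n = n),
            class = "icc_result")
}

#' Qualitative ICC band
#'
#' @param icc ICC value.
#' @return `"excellent"` (>= 0.75), `"good"` (0.60–0.75), `"fair"`
#'   (0.40–0.60) or `"poor"` (< 0.40).
#' @export
icc_band <- function(icc) {
  stopifnot(is.finite(icc))
  if (icc >= 0.75) "excellent"
  else if (icc >= 0.60) "good"
  else if (icc >= 0.40) "fair"
  else "poor"
}

#' Normality-routed two-group comparison
#'
#' Routes the comparison of a biomarker between LVI-positive and
#' LVI-negative groups the way clinical studies do: both groups are first
#' checked with the Shapiro–Wilk test; if both pass at `alpha_normal` the
#' groups are compared with the independent-samples t-test and summarized
#' as mean +/- sd, otherwise with the Mann–Whitney U test and summarized as
#' median (Q1, Q3). Constant data make the normality test inapplicable and
#' route to Mann–Whitney with a note.
#'
#' @param pos,neg Biomarker values in the two groups (each length >= 3).
#' @param alpha_normal Significance level of the normality screen.
#' @return A `group_comparison` list: `route` (`"t-test"` or
#'   `"mann-whitney"`), `statistic`, `p_value`, `shapiro_p`, per-group
#'   `summary_pos` / `summary_neg`, and `note`.
#' @export
compare_groups <- function(pos, neg, alpha_normal = 0.05) {
  stopifnot(is.numeric(pos), is.numeric(neg))
  if (length(pos) < 3 || length(neg) < 3) {
    stop("both groups need at least 3 values", call. = FALSE)
  }
  note <- NULL
  sw <- vapply(list(pos, neg), function(v) {
    if (var(v) == 0 || length(v) > 5000) return(NA_real_)
    shapiro.test(v)$p.value
  }, numeric(1))
  names(sw) <- c("pos", "neg")
  if (any(is.na(sw))) note <- "normality test inapplicable (constant data)"
  normal_both <- !any(is.na(sw)) && all(sw >= alpha_normal)
  if (normal_both) {
    ht <- t.test(pos, neg, var.equal = TRUE)
    route <- "t-test"
    summarize <- function(v) list(mean = mean(v), sd = sd(v))
  } else {
    ht <- suppressWarnings(wilcox.test(pos, neg, exact = FALSE))
    route <- "mann-whitney"
    summarize <- function(v) {
      q <- unname(quantile(v, c(0.25, 0.5, 0.75)))
      list(median = q[2], q1 = q[1], q3 = q[3])
    }
  }
  structure(list(route = route, statistic = unname(ht$statistic),
                 p_value = ht$p.value, shapiro_p = sw,
                 summary_pos = summarize(pos), summary_neg = summarize(neg),
                 note = note),
            class = "group_comparison")
}

#' Univariate logistic regression of LVI on one biomarker
#'
#' Maximum-likelihood logistic fit; the odds ratio is `exp(coefficient)`
#' with a Wald 95% confidence interval. Complete or quasi-complete
#' separation is flagged (monotone likelihood: the OR diverges) rather
#' than reported silently.
#'
#' @param x Biomarker values.
#' @param labels LVI labels.
#' @param conf_level Confidence level for the Wald interval.
#' @return One-row tibble: `estimate`, `se`, `or`, `or_lo`, `or_hi`,
#'   `p_value`, `separation`.
#' @export
univariate_logistic <- function(x, labels, conf_level = 0.95) {
  y <- lvi_indicator(labels)
  stopifnot(length(x) == length(y))
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  wald_table(fit, conf_level)[2, ]
}

wald_table <- function(fit, conf_level = 0.95) {
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  eta <- fit$fitted.values
  separation <- any(eta > 1 - 1e-8) || any(eta < 1e-8) || any(abs(beta) > 15)
  tibble::tibble(
    term = names(beta), estimate = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    or_lo = exp(unname(beta - zq * se)), or_hi = exp(unname(beta + zq * se)),
    p_value = unname(p), separation = separation
  )
}

#' Univariate screen and multivariate logistic model
#'
#' Fits a univariate logistic model per biomarker, enters every biomarker
#' with univariate p < `p_enter` (default 0.1) into one joint logistic fit,
#' and reports the joint Wald table; biomarkers significant at `p_report`
#' in the joint model are the independent predictors. Rank-deficient joint
#' designs (e.g. a biomarker entered twice) are flagged as collinear.
#'
#' @param data Subject-level data frame (one row per subject) with the
#'   biomarker columns and an LVI label column.
#' @param biomarkers Character vector of biomarker columns to screen.
#' @param label_col Name of the LVI label column.
#' @param p_enter Univariate screening threshold.
#' @param p_report Significance level declaring an independent predictor.
#' @return A `logistic_selection` list: `univariate` tibble, `selected`,
#'   `multivariate` tibble (or NULL), `independent`, `linear_predictor`,
#'   `collinear`, and the joint `fit`.
#' @export
multivariate_selection <- function(data, biomarkers = BIOMARKERS,
                                   label_col = "lvi", p_enter = 0.1,
                                   p_report = 0.05) {
  y <- lvi_indicator(data[[label_col]])
  uni <- do.call(rbind, lapply(biomarkers, function(bm) {
    row <- univariate_logistic(data[[bm]], y)
    row$term <- bm
    row
  }))
  selected <- uni$term[uni$p_value < p_enter]
  if (length(selected) == 0) {
    return(structure(list(univariate = uni, selected = character(),
                          multivariate = NULL, independent = character(),
                          linear_predictor = NULL, collinear = FALSE,
                          fit = NULL),
                     class = "logistic_selection"))
  }
  X <- data[, selected, drop = FALSE]
  df <- cbind(data.frame(.y = y), X)
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  collinear <- any(is.na(coef(fit)))
  if (collinear) {
    kept <- names(coef(fit))[!is.na(coef(fit))]
    warning("collinear predictors dropped from the joint model", call. = FALSE)
    df <- df[, c(".y", intersect(selected, kept)), drop = FALSE]
    fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  }
  multi <- wald_table(fit)
  multi <- multi[multi$term != "(Intercept)", , drop = FALSE]
  structure(list(
    univariate = uni, selected = selected, multivariate = multi,
    independent = multi$term[multi$p_value < p_report],
    linear_predictor = unname(predict(fit, type = "link")),
    collinear = collinear, fit = fit
  ), class = "logistic_selection")
}

#' Preset biomarker combinations
#'
#' The modality subsets used in the combined-ROC rows of the study report:
#' PET = SUVmax, MTV, TLG; IVIM = ADCstand, D, D*, f; DKI = MK, MD;
#' `MTV+D`; and `ALL`, the union of the nine biomarkers.
#'
#' @return Named list of biomarker column subsets.
#' @export
preset_combinations <- function() {
  list(
    "DKI" = c("mk", "md"),
    "IVIM" = c("adc", "d", "dstar", "f_pct"),
    "PET" = c("suvmax", "mtv", "tlg"),
    "MTV+D" = c("mtv", "d"),
    "DKI+IVIM+PET" = BIOMARKERS
  )
}

#' Combine biomarkers into one logistic score and its ROC
#'
#' Fits a joint logistic model on the member biomarkers; the per-subject
#' predicted probability is the combined score, whose ROC (direction
#' `"higher"`) summarizes the combination. The reported cutoff therefore
#' lives on the predicted-probability scale in (0, 1). A single-member
#' combination reproduces the raw biomarker's ROC exactly, because the
#' logistic link is monotone.
#'
#' @inheritParams multivariate_selection
#' @param members Non-empty character vector of biomarker columns.
#' @return A `combined_model` list: `members`, `scores`, `roc`
#'   (a [`roc_analysis()`] result), `coefficients` tibble, `fit`.
#' @export
combine_predictors <- function(data, members, label_col = "lvi") {
  if (length(members) == 0) stop("members must be non-empty", call. = FALSE)
  missing <- setdiff(members, names(data))
  if (length(missing) > 0) {
    stop("biomarker column(s) not in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- lvi_indicator(data[[label_col]])
  df <- cbind(data.frame(.y = y), data[, members, drop = FALSE])
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  scores <- unname(fitted(fit))
  structure(list(
    members = members, scores = scores,
    roc = roc_analysis(scores, y, direction = "higher"),
    coefficients = wald_table(fit), fit = fit
  ), class = "combined_model")
}

#' Run the full biomarker study pipeline on a cohort
#'
#' Reproduces the statistics layer of a two-group imaging-biomarker study
#' on a two-reader cohort table: per-biomarker inter-reader ICC; group
#' comparison routed by normality (on the reader-averaged values); the
#' univariate-to-multivariate logistic screen; per-biomarker ROC with
#' Youden cutoffs; and combined logistic models for the preset modality
#' subsets, each compared against the reference combination
#' (the independent-predictor model `MTV+D` for single parameters, the
#' all-modality model for modality subsets) with the DeLong test.
#'
#' @param cohort Cohort tibble in the dialect of [generate_cohort()] (one
#'   row per subject x reader).
#' @param alpha_normal,p_enter,p_report Thresholds passed to
#'   [compare_groups()] and [multivariate_selection()].
#' @return An `lvi_study_report` list of tibbles: `icc`, `comparison`,
#'   `univariate`, `multivariate`, `roc_parameters`, `roc_combinations`,
#'   plus `selection` (the [`multivariate_selection()`] object) and
#'   `subjects` (the reader-averaged subject-level table).
#' @export
run_pipeline <- function(cohort, alpha_normal = 0.05, p_enter = 0.1,
                         p_report = 0.05) {
  cohort <- validate_cohort(cohort)
  wide <- reshape_readers(cohort)
  subj <- wide$mean
  y <- lvi_indicator(subj$lvi)
  if (!any(y) || all(y)) {
    stop("cohort contains a single LVI class; group comparison and ROC stages need both",
         call. = FALSE)
  }

  icc_tbl <- do.call(rbind, lapply(BIOMARKERS, function(bm) {
    r <- compute_icc(wide$r1[[bm]], wide$r2[[bm]])
    tibble::tibble(biomarker = bm, icc = r$icc, band = r$band)
  }))

  comparison <- do.call(rbind, lapply(BIOMARKERS, function(bm) {
    g <- compare_groups(subj[[bm]][y], subj[[bm]][!y], alpha_normal)
    tibble::tibble(
      biomarker = bm, route = g$route, statistic = g$statistic,
      p_value = g$p_value,
      summary_pos = format_group_summary(g$summary_pos),
      summary_neg = format_group_summary(g$summary_neg)
    )
  }))

  sel <- multivariate_selection(subj, BIOMARKERS, "lvi", p_enter, p_report)

  roc_list <- lapply(BIOMARKERS, function(bm) roc_analysis(subj[[bm]], y))
  names(roc_list) <- BIOMARKERS

  combos <- lapply(preset_combinations(), function(m) {
    combine_predictors(subj, m, "lvi")
  })

  ref_param <- combos[["MTV+D"]]$scores
  roc_parameters <- do.call(rbind, lapply(BIOMARKERS, function(bm) {
    r <- roc_list[[bm]]
    dl <- delong_compare(subj[[bm]], ref_param, y)
    roc_row(bm, r, dl)
  }))

  ref_method <- combos[["DKI+IVIM+PET"]]$scores
  roc_combinations <- do.call(rbind, lapply(names(combos), function(nm) {
    cm <- combos[[nm]]
    dl <- if (nm == "DKI+IVIM+PET") NULL else {
      delong_compare(cm$scores, ref_method, y, direction_a = "higher",
                     direction_b = "higher")
    }
    roc_row(nm, cm$roc, dl)
  }))

  structure(list(
    icc = icc_tbl, comparison = comparison,
    univariate = sel$univariate, multivariate = sel$multivariate,
    roc_parameters = roc_parameters, roc_combinations = roc_combinations,
    selection = sel, combinations = combos, subjects = subj
  ), class = "lvi_study_report")
}

roc_row <- function(name, r, dl = NULL) {
  tibble::tibble(
    name = name, auc = r$auc, ci_lo = r$ci[1], ci_hi = r$ci[2],
    cutoff = r$cutoff, direction = r$direction,
    specificity = r$specificity, sensitivity = r$sensitivity,
    fpr = r$fpr, fnr = r$fnr,
    z_vs_combined = if (is.null(dl)) NA_real_ else dl$z,
    p_vs_combined = if (is.null(dl)) NA_real_ else dl$p_value
  )
}

format_group_summary <- function(s) {
  if (!is.null(s$mean)) {
    sprintf("%.3g +/- %.3g", s$mean, s$sd)
  } else {
    sprintf("%.3g (%.3g, %.3g)", s$median, s$q1, s$q3)
  }
}

validate_cohort <- function(cohort) {
  needed <- c("subject_id", "lvi", "reader", BIOMARKERS)
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(unique(cohort$reader), 1:2)) {
    stop("cohort must contain readers 1 and 2", call. = FALSE)
  }
  for (bm in BIOMARKERS) {
    if (any(!is.finite(cohort[[bm]])) || any(cohort[[bm]] <= 0)) {
      stop("biomarker ", bm, " has non-positive or missing values", call. = FALSE)
    }
  }
  if (any(cohort$f_pct >= 100)) {
    stop("f_pct must lie in (0, 100)", call. = FALSE)
  }
  tibble::as_tibble(cohort)
}

# split the two readers and build the reader-averaged subject table
reshape_readers <- function(cohort) {
  r1 <- cohort[cohort$reader == 1, ]
  r2 <- cohort[cohort$reader == 2, ]
  r1 <- r1[order(r1$subject_id), ]
  r2 <- r2[order(r2$subject_id), ]
  if (!identical(r1$subject_id, r2$subject_id)) {
    stop("readers 1 and 2 must cover the same subjects", call. = FALSE)
  }
  m <- r1
  for (bm in BIOMARKERS) m[[bm]] <- (r1[[bm]] + r2[[bm]]) / 2
  m$reader <- NULL
  list(r1 = r1, r2 = r2, mean = m)
}

#' @export
print.lvi_study_report <- function(x, ...) {
  cat("Two-group imaging-biomarker study report\n")
  cat(sprintf("  subjects: %d LVI+ / %d LVI-\n",
              sum(lvi_indicator(x$subjects$lvi)),
              sum(!lvi_indicator(x$subjects$lvi))))
  cat(sprintf("  selected into multivariate model: %s\n",
              paste(x$selection$selected, collapse = ", ")))
  cat(sprintf("  independent predictors (p < 0.05): %s\n",
              paste(x$selection$independent, collapse = ", ")))
  best <- x$roc_combinations[which.max(x$roc_combinations$auc), ]
  cat(sprintf("  best combination: %s (AUC %.3f)\n", best$name, best$auc))
  invisible(x)
}
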
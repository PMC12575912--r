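# ROC analysis with DeLong variance, and the DeLong test for paired AUCs.
# The AUC is the all-pairs concordance estimator (ties count 1/2), the
# operating point maximizes Youden's J with ties broken toward higher
# specificity, and variances come from the placement-value (structural
# component) decomposition of DeLong, DeLong & Clarke-Pearson.

# psi matrix: psi[i, j] = 1 if pos_i > neg_j, 0.5 if equal, else 0.
delong_psi <- function(pos, neg) {
  s <- sign(outer(pos, neg, "-"))
  (s + 1) / 2
}

delong_components <- function(pos, neg) {
  psi <- delong_psi(pos, neg)
  v10 <- rowMeans(psi)  # per-case placements
  v01 <- colMeans(psi)  # per-control placements
  list(auc = mean(psi), v10 = v10, v01 = v01,
       var_auc = var(v10) / length(pos) + var(v01) / length(neg))
}

#' ROC analysis of one biomarker
#'
#' Computes the empirical ROC of `scores` against the binary LVI labels:
#' AUC by all-pairs concordance (tied pairs count 1/2), a DeLong 95%
#' confidence interval (normal approximation on the placement-value
#' variance, truncated to \[0, 1\]), and the Youden-optimal operating point
#' with sensitivity, specificity, and the complementary false-positive and
#' false-negative rates in percent.
#'
#' Direction: with `"auto"` (default) the orientation is chosen so that
#' AUC >= 0.5 and recorded in the result — diffusion biomarkers, which are
#' lower in LVI-positive disease, come out `"lower"`; a positive call then
#' means score <= cutoff.
#'
#' @param scores Numeric biomarker values or model scores.
#' @param labels LVI labels (see [lvi_indicator()] for accepted codings).
#' @param direction `"auto"`, `"higher"` (higher score indicates LVI+), or
#'   `"lower"`.
#' @param conf_level Confidence level of the AUC interval.
#' @return A `roc_result` list: `auc`, `ci`, `var_auc`, `direction`,
#'   `cutoff`, `sensitivity`, `specificity`, `fpr`, `fnr` (all rates in
#'   percent), `youden`, `n_pos`, `n_neg`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(30, 1), rnorm(40))
#' y <- rep(c(TRUE, FALSE), c(30, 40))
#' roc_analysis(x, y)
#' @export
roc_analysis <- function(scores, labels, direction = c("auto", "higher", "lower"),
                         conf_level = 0.95) {
  direction <- match.arg(direction)
  y <- lvi_indicator(labels)
  stopifnot(length(scores) == length(y), is.numeric(scores), all(is.finite(scores)))
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  pos <- scores[y]
  neg <- scores[!y]
  if (direction == "auto") {
    auc_hi <- mean(delong_psi(pos, neg))
    direction <- if (auc_hi >= 0.5) "higher" else "lower"
  }
  sgn <- if (direction == "higher") 1 else -1
  comp <- delong_components(sgn * pos, sgn * neg)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- comp$auc + c(-1, 1) * z * sqrt(comp$var_auc)
  ci <- pmin(pmax(ci, 0), 1)

  # candidate cutoffs: midpoints between consecutive unique oriented scores,
  # plus sentinels classifying everything / nothing as positive
  s_or <- sgn * scores
  u <- sort(unique(s_or))
  cand <- c(min(u) - 1, (u[-1] + u[-length(u)]) / 2, max(u) + 1)
  op <- vapply(cand, function(cc) {
    pred <- s_or >= cc
    c(sens = mean(pred[y]), spec = mean(!pred[!y]))
  }, numeric(2))
  j <- op["sens", ] + op["spec", ] - 1
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1) best <- best[which.max(op["spec", best])]
  cutoff <- sgn * cand[best]

  structure(list(
    auc = comp$auc, ci = ci, var_auc = comp$var_auc,
    conf_level = conf_level, direction = direction,
    cutoff = cutoff,
    sensitivity = unname(100 * op["sens", best]),
    specificity = unname(100 * op["spec", best]),
    fpr = unname(100 - 100 * op["spec", best]),
    fnr = unname(100 - 100 * op["sens", best]),
    youden = unname(j[best]),
    n_pos = length(pos), n_neg = length(neg)
  ), class = "roc_result")
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two biomarkers measured on the same subjects using
#' the DeLong placement-value covariance: `Z = dAUC / se(dAUC)` with a
#' two-sided normal p-value. Each marker is oriented independently (by
#' default so its own AUC >= 0.5), matching how oriented per-parameter ROC
#' curves are compared in practice. Identical or rank-identical score
#' vectors give `Z = 0`, `p = 1`; zero variance with a nonzero AUC
#' difference is degenerate and raises an error.
#'
#' @param scores_a,scores_b Paired score vectors on the same subjects.
#' @param labels Shared LVI labels.
#' @param direction_a,direction_b Orientation per marker, as in
#'   [roc_analysis()].
#' @return A `delong_result` list: `auc_a`, `auc_b`, `delta`, `se`,
#'   `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           direction_a = "auto", direction_b = "auto") {
  y <- lvi_indicator(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  orient <- function(scores, direction) {
    pos <- scores[y]; neg <- scores[!y]
    if (direction == "auto") {
      direction <- if (mean(delong_psi(pos, neg)) >= 0.5) "higher" else "lower"
    }
    if (direction == "higher") scores else -scores
  }
  sa <- orient(scores_a, match.arg(direction_a, c("auto", "higher", "lower")))
  sb <- orient(scores_b, match.arg(direction_b, c("auto", "higher", "lower")))
  ca <- delong_components(sa[y], sa[!y])
  cb <- delong_components(sb[y], sb[!y])
  m <- sum(y); n <- sum(!y)
  var_delta <- (var(ca$v10) + var(cb$v10) - 2 * cov(ca$v10, cb$v10)) / m +
               (var(ca$v01) + var(cb$v01) - 2 * cov(ca$v01, cb$v01)) / n
  delta <- ca$auc - cb$auc
  if (var_delta <= .Machine$double.eps) {
    if (abs(delta) < 1e-12) {
      return(structure(list(auc_a = ca$auc, auc_b = cb$auc, delta = 0,
                            se = 0, z = 0, p_value = 1),
                       class = "delong_result"))
    }
    stop("zero variance of the AUC difference with unequal AUCs: degenerate",
         call. = FALSE)
  }
  z <- delta / sqrt(var_delta)
  structure(list(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
                 se = sqrt(var_delta), z = z,
                 p_value = 2 * pnorm(-abs(z))),
            class = "delong_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f), direction %s\n",
              x$auc, 100 * x$conf_level, x$ci[1], x$ci[2], x$direction))
  cat(sprintf("cutoff %.4g: sensitivity %.2f%%, specificity %.2f%% (FPR %.2f, FNR %.2f)\n",
              x$cutoff, x$sensitivity, x$specificity, x$fpr, x$fnr))
  invisible(x)
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong test: AUC %.3f vs %.3f, Z = %.4f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p_value))
  invisible(x)
}
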
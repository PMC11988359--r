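#' Unpaired two-group t test
#'
#' Welch's unequal-variance t test by default (robust to the unequal group
#' spreads seen in the breast cohort); Student's pooled-variance test is
#' available for parity with software that defaults to it.
#'
#' @param group_a,group_b numeric samples, n >= 2 each.
#' @param method `"welch"` or `"student"`.
#' @return A one-row data.frame: group means and sds, `t`, `df`, `p`,
#'   `method`.
#' @export
unpaired_t <- function(group_a, group_b, method = c("welch", "student")) {
  method <- match.arg(method)
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  ht <- stats::t.test(group_a, group_b, var.equal = method == "student")
  data.frame(mean_a = mean(group_a), sd_a = stats::sd(group_a),
             mean_b = mean(group_b), sd_b = stats::sd(group_b),
             t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, method = method, stringsAsFactors = FALSE)
}

#' ROC analysis of a continuous score
#'
#' Empirical (Mann-Whitney) AUC oriented so that AUC >= 0.5, DeLong 95%
#' confidence interval, and the Youden-optimal cutoff with its sensitivity
#' and specificity. The class treated as "positive" is reported.
#'
#' @param scores numeric predictor.
#' @param labels two-level factor/character/logical; both classes present.
#' @param positive which label is the case class; defaults to the class with
#'   the higher mean score after orientation.
#' @param conf_level confidence level of the AUC interval.
#' @return List of class `roc_result`: `auc`, `ci_low`, `ci_high`, `cutoff`,
#'   `sensitivity`, `specificity`, `direction`, `positive`, and the
#'   underlying `pROC::roc` object in `roc`.
#' @export
roc_analysis <- function(scores, labels, positive = NULL,
                         conf_level = 0.95) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("labels must contain exactly two classes")
  labels <- droplevels(labels)
  if (is.null(positive)) positive <- levels(labels)[2]
  lv <- c(setdiff(levels(labels), positive), positive)
  ## orient so that AUC >= 0.5 (not pROC's median-based "auto")
  r <- pROC::roc(response = labels, predictor = scores, levels = lv,
                 direction = "<", quiet = TRUE)
  if (as.numeric(pROC::auc(r)) < 0.5)
    r <- pROC::roc(response = labels, predictor = scores, levels = lv,
                   direction = ">", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, conf.level = conf_level,
                                                 method = "delong")))
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]        # first optimum if tied
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[3],
                 cutoff = best$threshold, sensitivity = best$sensitivity,
                 specificity = best$specificity, direction = r$direction,
                 positive = positive, roc = r),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "AUC = %.3f (95%% CI %.3f-%.3f), cutoff = %.4g, sens = %.3f, spec = %.3f (positive: %s)\n",
    x$auc, x$ci_low, x$ci_high, x$cutoff, x$sensitivity, x$specificity,
    x$positive))
  invisible(x)
}

#' Paired DeLong comparison of two AUCs
#'
#' Two-sided DeLong test for the difference between the AUCs of two scores
#' measured on the same lesions.
#'
#' @param scores1,scores2 two scores over the same cases.
#' @param labels two-level class labels.
#' @return Two-sided p-value.
#' @export
delong_compare <- function(scores1, scores2, labels) {
  stopifnot(length(scores1) == length(scores2),
            length(scores1) == length(labels))
  if (isTRUE(all.equal(as.numeric(scores1), as.numeric(scores2))))
    return(1)
  labels <- droplevels(as.factor(labels))
  ## orient each score so its AUC >= 0.5, then compare on a common direction
  orient <- function(s) {
    r <- pROC::roc(labels, s, direction = "<", quiet = TRUE)
    if (as.numeric(pROC::auc(r)) < 0.5) -s else s
  }
  r1 <- pROC::roc(labels, orient(scores1), direction = "<", quiet = TRUE)
  r2 <- pROC::roc(labels, orient(scores2), direction = "<", quiet = TRUE)
  as.numeric(pROC::roc.test(r1, r2, method = "delong",
                            paired = TRUE)$p.value)
}

#' Combined logistic model over several predictors
#'
#' In-sample logistic regression (maximum likelihood) on standardised
#' predictors, with ROC analysis of the fitted probabilities — the
#' "combined model" construction used to merge microstructural parameters
#' and ADC values into one discriminator.
#'
#' @param records data.frame of lesion records including a `group` column.
#' @param predictors character vector of predictor column names.
#' @param positive the `group` level modelled as the event (default
#'   `"malignant"` when present).
#' @return List of class `combined_model`: `predictors`, `coefficients`,
#'   `probabilities`, `roc` (a `roc_result`).
#' @export
combined_model <- function(records, predictors,
                           positive = if ("malignant" %in% records$group)
                             "malignant" else NULL) {
  stopifnot(all(predictors %in% names(records)), "group" %in% names(records))
  X <- records[, predictors, drop = FALSE]
  if (anyNA(X)) stop("missing predictor values")
  Xs <- as.data.frame(scale(X))
  labels <- droplevels(as.factor(records$group))
  if (is.null(positive)) positive <- levels(labels)[2]
  y <- as.integer(labels == positive)
  fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = cbind(y = y, Xs)))
  prob <- stats::fitted(fit)
  structure(list(predictors = predictors,
                 coefficients = stats::coef(fit),
                 probabilities = prob,
                 roc = roc_analysis(prob, labels, positive = positive)),
            class = "combined_model")
}

#' Immunohistochemical subgroup comparisons
#'
#' Compares each quantitative parameter between the positive and negative
#' levels of each marker among malignant lesions, with an unpaired t test.
#' Ki67 is dichotomised at 14% (>= 14% is "positive").
#'
#' @param records lesion records including `group`, marker columns (`er`,
#'   `pr`, `her2`, numeric `ki67`) and the quantitative columns.
#' @param markers markers to test.
#' @param parameters quantitative columns to compare.
#' @param method t-test flavour, see [unpaired_t()].
#' @param p_adjust optional multiplicity correction passed to
#'   [stats::p.adjust()] (e.g. `"holm"`); default `"none"`.
#' @return data.frame with one row per (marker, parameter) pair.
#' @export
ihc_subgroup_compare <- function(records,
                                 markers = c("er", "pr", "her2", "ki67"),
                                 parameters = c("d", "v_in", "d_ex",
                                                "cellularity"),
                                 method = "welch", p_adjust = "none") {
  mal <- records[records$group == "malignant", , drop = FALSE]
  rows <- list()
  for (m in markers) {
    lev <- if (m == "ki67") {
      factor(ifelse(mal[[m]] >= 14, "positive", "negative"),
             levels = c("negative", "positive"))
    } else factor(mal[[m]], levels = c("negative", "positive"))
    if (nlevels(droplevels(lev)) < 2L)
      stop("marker ", m, " has only one level among malignant lesions")
    for (p in parameters) {
      tt <- unpaired_t(mal[[p]][lev == "positive"],
                       mal[[p]][lev == "negative"], method = method)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(marker = m, parameter = p, n_positive = sum(lev == "positive"),
                   n_negative = sum(lev == "negative"),
                   stringsAsFactors = FALSE),
        tt)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- "mean_positive"
  names(out)[names(out) == "sd_a"] <- "sd_positive"
  names(out)[names(out) == "mean_b"] <- "mean_negative"
  names(out)[names(out) == "sd_b"] <- "sd_negative"
  out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  out
}
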
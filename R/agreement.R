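#' Cross-tabulate two raters' categorical calls
#'
#' @param ref,pred equal-length vectors (reference on rows, prediction on
#'   columns).
#' @param labels category order; defaults to the union of observed values.
#' @param exclude character vector of labels; pairs where either rater used
#'   one of them are dropped (e.g. `"fundal"`, whose implantation straddles
#'   the anterior and posterior walls and confounds agreement).
#' @return k x k integer matrix of counts.
#' @export
confusion_table <- function(ref, pred, labels = NULL, exclude = NULL) {
  if (length(ref) != length(pred)) stop("paired vectors required", call. = FALSE)
  if (!is.null(exclude)) {
    keep <- !(ref %in% exclude) & !(pred %in% exclude)
    ref <- ref[keep]; pred <- pred[keep]
  }
  labels <- labels %||% sort(unique(c(ref, pred)))
  tab <- table(factor(ref, levels = labels), factor(pred, levels = labels))
  unclass(as.matrix(tab))
}

check_table <- function(table) {
  if (!is.matrix(table) || nrow(table) != ncol(table) || nrow(table) < 2)
    stop("square k x k table with k >= 2 required", call. = FALSE)
  if (any(table < 0)) stop("negative counts", call. = FALSE)
  if (sum(table) == 0) stop("empty table", call. = FALSE)
  table
}

#' Overall percent agreement
#' @param table square confusion matrix (reference rows, prediction cols).
#' @return Agreement in percent: 100 x trace / total.
#' @export
percent_agreement <- function(table) {
  table <- check_table(table)
  100 * sum(diag(table)) / sum(table)
}

#' Cohen's kappa with interpretation band and significance
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' expected agreement from the marginal products. Exactly 1 for any
#' perfect-diagonal table. The p-value tests \eqn{\kappa = 0} with the
#' large-sample normal approximation; for a collection of per-fold kappas
#' use [kappa_ttest()]. Bands: 0-0.2 slight, 0.21-0.4 fair, 0.41-0.6
#' moderate, 0.61-0.8 substantial, 0.81-1 almost perfect.
#'
#' @param table square confusion matrix.
#' @return list(kappa, p_o, p_e, band, p_value); kappa is NA (flagged by a
#'   warning) when both raters used a single category (p_e = 1).
#' @export
cohens_kappa <- function(table) {
  table <- check_table(table)
  n <- sum(table)
  po <- sum(diag(table)) / n
  pr <- rowSums(table) / n
  pc <- colSums(table) / n
  pe <- sum(pr * pc)
  if (1 - pe < .Machine$double.eps^0.5) {
    warning("both raters used a single category; kappa undefined")
    return(list(kappa = NA_real_, p_o = po, p_e = pe, band = NA_character_,
                p_value = NA_real_))
  }
  kappa <- (po - pe) / (1 - pe)
  var0 <- (pe + pe^2 - sum(pr * pc * (pr + pc))) / (n * (1 - pe)^2)
  z <- if (var0 > 0) kappa / sqrt(var0) else Inf * sign(kappa)
  p <- 2 * stats::pnorm(-abs(z))
  list(kappa = kappa, p_o = po, p_e = pe, band = kappa_band(kappa), p_value = p)
}

#' Interpretation band for kappa or ICC
#' @param x agreement coefficient in `[-1, 1]`.
#' @return One of "poor" (below 0), "slight", "fair", "moderate",
#'   "substantial", "almost perfect".
#' @export
kappa_band <- function(x) {
  if (is.na(x)) return(NA_character_)
  if (x < 0) "poor"
  else if (x <= 0.2) "slight"
  else if (x <= 0.4) "fair"
  else if (x <= 0.6) "moderate"
  else if (x <= 0.8) "substantial"
  else "almost perfect"
}

#' One-sample t-test of agreement coefficients against zero
#'
#' Used for a collection of per-fold kappa or ICC values compared to a
#' theoretical mean of 0.
#'
#' @param values numeric vector of coefficients.
#' @return list(mean, p_value, t, df).
#' @export
kappa_ttest <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  if (sd(values) == 0) {
    return(list(mean = mean(values),
                p_value = if (mean(values) == 0) NA_real_ else 0,
                t = Inf, df = length(values) - 1))
  }
  tt <- t.test(values, mu = 0)
  list(mean = mean(values), p_value = tt$p.value,
       t = unname(tt$statistic), df = unname(tt$parameter))
}

#' Sensitivity, specificity, PPV and NPV against one positive class
#'
#' Collapses the table to 2x2 (positive class vs the rest) and applies the
#' standard confusion-matrix definitions, reported in percent.
#'
#' @param table square confusion matrix with dimnames, reference on rows.
#' @param positive_label the positive class (must be among the labels).
#' @return list(sensitivity, specificity, ppv, npv) in percent; a rate with
#'   an empty denominator is NA with a warning.
#' @export
binary_rates <- function(table, positive_label) {
  table <- check_table(table)
  labs <- rownames(table) %||% as.character(seq_len(nrow(table)))
  if (!positive_label %in% labs)
    stop(sprintf("positive label '%s' not among table labels", positive_label),
         call. = FALSE)
  i <- match(positive_label, labs)
  TP <- table[i, i]
  FN <- sum(table[i, -i])
  FP <- sum(table[-i, i])
  TN <- sum(table[-i, -i])
  rate <- function(num, den, what) {
    if (den == 0) { warning(sprintf("%s undefined (empty denominator)", what)); NA_real_ }
    else 100 * num / den
  }
  list(sensitivity = rate(TP, TP + FN, "sensitivity"),
       specificity = rate(TN, TN + FP, "specificity"),
       ppv = rate(TP, TP + FP, "PPV"),
       npv = rate(TN, TN + FN, "NPV"))
}

#' Intraclass correlation, two-way model, absolute agreement
#'
#' Single-measurement absolute-agreement ICC from the two-way ANOVA mean
#' squares (rows = subjects, columns = raters), which penalizes systematic
#' offsets between raters; the average-measures variant is available via
#' `type = "average"`. Banded on the same scale as kappa.
#'
#' @param x,y paired continuous measurements (>= 3 pairs).
#' @param type `"single"` (default) or `"average"`.
#' @return list(icc, band, ms (mean squares)); NA with a warning when the
#'   between-subject variance is zero.
#' @export
icc_absolute <- function(x, y, type = c("single", "average")) {
  type <- match.arg(type)
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 paired measurements", call. = FALSE)
  n <- length(x); k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  sub_means <- rowMeans(dat)
  rat_means <- colMeans(dat)
  ssr <- k * sum((sub_means - grand)^2)        # between subjects
  ssc <- n * sum((rat_means - grand)^2)        # between raters
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < .Machine$double.eps) {
    warning("zero between-subject variance; ICC undefined")
    return(list(icc = NA_real_, band = NA_character_,
                ms = c(msr = msr, msc = msc, mse = mse)))
  }
  icc <- if (type == "single") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
  list(icc = icc, band = kappa_band(icc), ms = c(msr = msr, msc = msc, mse = mse))
}

#' Bland-Altman analysis of paired measurements
#'
#' Bias is the mean of prediction minus reference (here: model-assigned
#' minus specialist-assigned); the limits of agreement are bias +/- 1.96
#' standard deviations of the differences, and the p-value is the
#' one-sample t-test of the differences against zero.
#'
#' @param pred,ref equal-length numeric vectors, n >= 2.
#' @return list(bias, loa_low, loa_high, sd, p_bias).
#' @export
bland_altman <- function(pred, ref) {
  if (length(pred) != length(ref) || length(pred) < 2)
    stop("need at least 2 paired values", call. = FALSE)
  d <- pred - ref
  bias <- mean(d)
  s <- sd(d)
  p <- if (s == 0) {
    if (bias == 0) NA_real_ else 0
  } else t.test(d, mu = 0)$p.value
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, p_bias = p)
}

#' Mean per-pair absolute relative error, in percent
#'
#' The per-pair definition (|pred - ref| / ref, then averaged), not the
#' relative difference of the means.
#'
#' @param pred,ref equal-length numeric vectors; all `ref` nonzero.
#' @return Percent error.
#' @export
relative_error <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("paired vectors required", call. = FALSE)
  if (any(ref == 0)) stop("reference values must be nonzero", call. = FALSE)
  mean(abs(pred - ref) / ref) * 100
}

#' Full two-rater agreement report
#'
#' Bundles the categorical statistics (percent agreement, kappa with band,
#' per-class rates) and, when measurements are supplied, the continuous
#' ones (ICC, Bland-Altman, relative error).
#'
#' @param ref_labels,pred_labels categorical calls (reference, prediction).
#' @param positive_label class for sensitivity/specificity (default: first
#'   level).
#' @param ref_meas,pred_meas optional paired measurements.
#' @param exclude labels to drop from the categorical comparison (pairs
#'   where either rater used one).
#' @return An `agreement_report` list.
#' @export
agreement_report <- function(ref_labels, pred_labels, positive_label = NULL,
                             ref_meas = NULL, pred_meas = NULL, exclude = NULL) {
  tab <- confusion_table(ref_labels, pred_labels, exclude = exclude)
  positive_label <- positive_label %||% rownames(tab)[1]
  kap <- cohens_kappa(tab)
  out <- list(table = tab,
              percent_agreement = percent_agreement(tab),
              kappa = kap$kappa, kappa_band = kap$band,
              kappa_p = kap$p_value,
              rates = binary_rates(tab, positive_label),
              positive_label = positive_label)
  if (!is.null(ref_meas) && !is.null(pred_meas)) {
    out$icc <- icc_absolute(pred_meas, ref_meas)
    out$bland_altman <- bland_altman(pred_meas, ref_meas)
    out$relative_error_pct <- relative_error(pred_meas, ref_meas)
  }
  structure(out, class = "agreement_report")
}
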
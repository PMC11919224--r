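#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom, the standard comparison for wPRS distributions between two
#' groups of unrelated individuals. Thin, structured wrapper around
#' [stats::t.test()].
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return List of class `famprs_welch`: `t`, `df`, `p_two_sided`,
#'   `mean_a`, `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`. The sign of `t`
#'   follows `mean_a - mean_b`.
#' @export
welch_t <- function(sample_a, sample_b) {
  sample_a <- as.numeric(sample_a); sample_b <- as.numeric(sample_b)
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_two_sided = tt$p.value,
                 mean_a = mean(sample_a), mean_b = mean(sample_b),
                 sd_a = stats::sd(sample_a), sd_b = stats::sd(sample_b),
                 n_a = length(sample_a), n_b = length(sample_b)),
            class = "famprs_welch")
}

#' @exportS3Method base::print
print.famprs_welch <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, p = %s\n", x$t, x$df,
              format_pvalue(x$p_two_sided)))
  cat(sprintf("  A: mean %.4f (sd %.4f, n %d); B: mean %.4f (sd %.4f, n %d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}

#' Display-floor a p-value
#'
#' p-values are stored at machine precision everywhere; only human-readable
#' output applies the conventional floor `< 2.2e-16`.
#'
#' @param p Numeric p-value.
#' @return Character rendering.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", formatC(p, format = "g", digits = 3))
}

#' ROC curve and AUC for score-based case discrimination
#'
#' Computes the receiver operating characteristic curve of a continuous
#' score against binary class labels and its area (AUC), the probability
#' that a random case scores above a random control (Mann-Whitney
#' interpretation; ties count 1/2). The 95% confidence interval uses
#' DeLong's closed-form variance by default, or a stratified bootstrap.
#' Computation is delegated to \pkg{pROC}.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (1/TRUE = case, 0/FALSE = control); both
#'   classes must be present.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_n Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return List of class `famprs_roc`: `auc`, `ci_low`, `ci_high`, and
#'   `curve`, a data.frame of `(fpr, tpr)` points from (0,0) to (1,1).
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- if (ci_method == "delong") {
    pROC::ci.auc(r, method = "delong")
  } else {
    pROC::ci.auc(r, method = "bootstrap", boot.n = boot_n, progress = "none")
  }
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), , drop = FALSE]
  rownames(curve) <- NULL
  structure(list(auc = as.numeric(r$auc),
                 ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[3]),
                 curve = curve),
            class = "famprs_roc")
}

#' @exportS3Method base::print
print.famprs_roc <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), %d curve points\n",
              x$auc, x$ci_low, x$ci_high, nrow(x$curve)))
  invisible(x)
}
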
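#' Iterative subsampling comparison of a small familial group against a
#' large population cohort
#'
#' The familial groups (roughly 10 individuals) are far smaller than the
#' population cohort (thousands), so a single Welch test is dominated by
#' the cohort's n. Following the published design, the cohort is
#' subsampled `iterations` times to random sets of `k` individuals (without
#' replacement within an iteration, independently across iterations), each
#' subsample is compared to the full familial vector with a Welch test,
#' and the spread of p-values (minimum, maximum) summarises the evidence.
#'
#' One master `seed` spawns per-iteration substreams so that the first
#' iterations are unchanged when `iterations` is increased.
#'
#' @param population_scores Numeric vector, length >= `k`.
#' @param family_scores Numeric vector, length >= 2.
#' @param k Subsample size (default 500).
#' @param iterations Number of subsamples (default 100).
#' @param seed Integer master seed (default 1).
#' @return List of class `famprs_subsample`: `n_iterations`,
#'   `subsample_size`, `seed`, `p_values`, `p_min`, `p_max`, `direction`
#'   (sign of family mean minus subsample mean, per iteration),
#'   `subsample_means`, `subsample_sds`, `family_mean`, `family_sd`,
#'   `n_significant_05`.
#' @export
subsample_compare <- function(population_scores, family_scores, k = 500,
                              iterations = 100, seed = 1) {
  population_scores <- as.numeric(population_scores)
  family_scores <- as.numeric(family_scores)
  if (k > length(population_scores)) {
    stop("subsample size k = ", k, " exceeds population size ",
         length(population_scores), call. = FALSE)
  }
  if (length(family_scores) < 2) stop("family group needs n >= 2",
                                      call. = FALSE)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, iterations)
  p <- means <- sds <- direction <- numeric(iterations)
  for (i in seq_len(iterations)) {
    set.seed(iter_seeds[i])
    sub <- population_scores[sample.int(length(population_scores), k)]
    w <- welch_t(family_scores, sub)
    p[i] <- w$p_two_sided
    means[i] <- mean(sub)
    sds[i] <- stats::sd(sub)
    direction[i] <- sign(w$mean_a - w$mean_b)
  }
  structure(list(n_iterations = iterations, subsample_size = k, seed = seed,
                 p_values = p, p_min = min(p), p_max = max(p),
                 direction = direction,
                 subsample_means = means, subsample_sds = sds,
                 family_mean = mean(family_scores),
                 family_sd = stats::sd(family_scores),
                 n_significant_05 = sum(p < 0.05)),
            class = "famprs_subsample")
}

#' @exportS3Method base::print
print.famprs_subsample <- function(x, ...) {
  cat(sprintf(
    "Subsampling comparison: %d iterations of k = %d (seed %d)\n",
    x$n_iterations, x$subsample_size, x$seed))
  cat(sprintf("  family mean %.4f (sd %.4f) vs subsample mean %.4f (sd %.4f)\n",
              x$family_mean, x$family_sd,
              mean(x$subsample_means), mean(x$subsample_sds)))
  cat(sprintf("  p range [%s, %s]; %d/%d iterations significant at 0.05\n",
              format_pvalue(x$p_min), format_pvalue(x$p_max),
              x$n_significant_05, x$n_iterations))
  invisible(x)
}

#' Family-wise wPRS report
#'
#' Builds the familial summary table: per-family affected and unaffected
#' mean (SD) plus a "Combined" row pooling all affected and all unaffected
#' individuals across families, together with the per-individual listing
#' (including HLA risk-allele status when the score table carries it).
#'
#' @param scores A score table whose `group` column distinguishes
#'   `familial_case` (or `case`/`affected`) from `unaffected_relative` (or
#'   `control`/`unaffected`) and whose `family_id` is populated.
#' @return List of class `famprs_family_report`: `summary` (data.frame
#'   `family_id` x `group` with `n`, `mean`, `sd`, `display`; `family_id`
#'   `"Combined"` pools across families) and `individuals` (the input
#'   rows).
#' @export
family_report <- function(scores) {
  stopifnot(all(c("family_id", "group", "wprs") %in% names(scores)))
  empty_fam <- is.na(scores$family_id) | scores$family_id == ""
  if (any(empty_fam)) {
    warning("dropping ", sum(empty_fam), " row(s) without a family_id")
    scores <- scores[!empty_fam, , drop = FALSE]
  }
  if (nrow(scores) == 0) stop("no family rows to report", call. = FALSE)
  per_family <- group_summary(scores, by = c("family_id", "group"))
  combined <- group_summary(scores, by = "group")
  combined <- cbind(family_id = "Combined", combined)
  summary <- format_group_summary(rbind(per_family, combined))
  structure(list(summary = summary, individuals = scores),
            class = "famprs_family_report")
}

#' @exportS3Method base::print
print.famprs_family_report <- function(x, ...) {
  cat("Familial wPRS summary (mean (SD)):\n")
  print(x$summary[, c("family_id", "group", "n", "display")],
        row.names = FALSE)
  invisible(x)
}
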
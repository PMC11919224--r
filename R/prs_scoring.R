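#' Score one individual's weighted polygenic risk
#'
#' Computes the weighted polygenic risk score wPRS = sum_i G_i * W_i, where
#' G_i is the individual's risk-allele dosage (0..2, fractional for imputed
#' data) at panel variant i and W_i = ln(OR_i) is the variant's weight.
#'
#' @param dosages Numeric vector of risk-allele dosages aligned to
#'   `panel$variant_id` order; `NA` marks missing genotypes.
#' @param panel A `famprs_panel` (or data.frame with a `weight` column).
#' @param missing_policy `"complete"` (default): sum over observed variants
#'   only. `"mean_impute"`: substitute `2 * freq` (the Hardy-Weinberg
#'   expected dosage) for missing variants; requires `freqs`.
#' @param freqs Panel risk-allele frequencies, needed for
#'   `"mean_impute"`.
#' @return List with `wprs` (numeric) and `n_used` (count of non-missing
#'   variants entering the sum).
#' @examples
#' panel <- data.frame(variant_id = "v1", weight = log(2.9))
#' score_individual(c(v1 = 2), panel)   # 2 * ln(2.9)
#' @export
score_individual <- function(dosages, panel,
                             missing_policy = c("complete", "mean_impute"),
                             freqs = NULL) {
  missing_policy <- match.arg(missing_policy)
  w <- panel$weight
  stopifnot(length(dosages) == length(w))
  miss <- is.na(dosages)
  if (all(miss)) stop("all panel variants missing; score undefined",
                      call. = FALSE)
  g <- dosages
  if (missing_policy == "mean_impute" && any(miss)) {
    if (is.null(freqs)) stop("mean_impute requires allele frequencies",
                             call. = FALSE)
    stopifnot(length(freqs) == length(w))
    g[miss] <- 2 * freqs[miss]
    miss <- rep(FALSE, length(g))
  }
  list(wprs = sum(g[!miss] * w[!miss]), n_used = sum(!is.na(dosages)))
}

#' Extract panel-aligned risk-allele dosages from genotypes
#'
#' Aligns a genotype container to a risk panel: looks up each panel variant
#' (by ID), orients the dataset's counted allele against the panel's risk
#' allele via [harmonize_variant()], and returns a samples x panel-variants
#' matrix of risk-allele dosages (`2 - dosage` where the counted allele is
#' the non-risk allele; `NA` where the variant is absent, unorientable, or
#' the genotype missing).
#'
#' @param geno A `famprs_genotypes` object.
#' @param panel A `famprs_panel`.
#' @return Numeric matrix, rows = samples, columns = panel variants.
#' @export
risk_dosages <- function(geno, panel) {
  stopifnot(inherits(geno, "famprs_genotypes"))
  idx <- match(panel$variant_id, geno$variants$variant_id)
  out <- matrix(NA_real_, nrow = length(geno$sample_ids),
                ncol = nrow(panel),
                dimnames = list(geno$sample_ids, panel$variant_id))
  for (j in seq_len(nrow(panel))) {
    i <- idx[j]
    if (is.na(i)) next
    orient <- harmonize_variant(panel$risk_allele[j], panel$other_allele[j],
                                c(geno$variants$a1[i], geno$variants$a2[i]))
    d <- geno$dosage[, i]
    out[, j] <- switch(orient,
                       match = d, strand_flip = d,
                       swap = 2 - d, strand_flip_swap = 2 - d,
                       fail = NA_real_)
  }
  out
}

#' Score a cohort against a risk panel
#'
#' Applies [score_individual()] to every sample of a dosage matrix and
#' attaches group labels, producing the score table consumed by all
#' downstream comparisons.
#'
#' @param dosages Either a `famprs_genotypes` object (harmonized internally
#'   via [risk_dosages()]) or a numeric samples x panel-variants matrix of
#'   risk-allele dosages already aligned to `panel`.
#' @param panel A `famprs_panel`.
#' @param labels Named character vector or data.frame assigning each sample
#'   a `group` (one of `"case"`, `"control"`, `"familial_case"`,
#'   `"unaffected_relative"`) and optionally a `family_id`. Names (or an
#'   `individual_id` column) must cover every sample.
#' @inheritParams score_individual
#' @return A score table data.frame: `family_id`, `individual_id`, `group`,
#'   `wprs`, `n_variants_used`.
#' @export
score_cohort <- function(dosages, panel, labels,
                         missing_policy = c("complete", "mean_impute"),
                         freqs = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (inherits(dosages, "famprs_genotypes")) {
    dosages <- risk_dosages(dosages, panel)
  }
  stopifnot(is.matrix(dosages), ncol(dosages) == nrow(panel))
  ids <- rownames(dosages)
  if (is.data.frame(labels)) {
    stopifnot(all(c("individual_id", "group") %in% names(labels)))
    m <- match(ids, labels$individual_id)
    if (anyNA(m)) stop("no group label for sample(s): ",
                       paste(utils::head(ids[is.na(m)], 3), collapse = ", "),
                       call. = FALSE)
    group <- labels$group[m]
    family_id <- if ("family_id" %in% names(labels))
      labels$family_id[m] else NA_character_
  } else {
    if (is.null(names(labels))) {
      if (length(labels) != length(ids))
        stop("unnamed labels must match sample count", call. = FALSE)
      group <- as.character(labels)
    } else {
      m <- match(ids, names(labels))
      if (anyNA(m)) stop("no group label for sample(s): ",
                         paste(utils::head(ids[is.na(m)], 3), collapse = ", "),
                         call. = FALSE)
      group <- as.character(labels[m])
    }
    family_id <- NA_character_
  }
  res <- lapply(seq_along(ids), function(i) {
    score_individual(dosages[i, ], panel, missing_policy, freqs)
  })
  data.frame(family_id = family_id, individual_id = ids, group = group,
             wprs = vapply(res, `[[`, 0, "wprs"),
             n_variants_used = vapply(res, `[[`, 0L, "n_used"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Group means and standard deviations of wPRS
#'
#' Summarises a score table by grouping keys: per-group n, arithmetic mean
#' and sample standard deviation (n - 1 denominator; `NA` for singleton
#' groups). Values are returned at full precision; use
#' [format_group_summary()] for the conventional 2-decimal rendering.
#'
#' @param scores A score table (see [score_cohort()]).
#' @param by Character vector of grouping columns, default
#'   `c("family_id", "group")`.
#' @return Data.frame with the grouping columns plus `n`, `mean`, `sd`.
#' @export
group_summary <- function(scores, by = c("family_id", "group")) {
  stopifnot(is.data.frame(scores), "wprs" %in% names(scores))
  if (nrow(scores) == 0) stop("empty score table", call. = FALSE)
  stopifnot(all(by %in% names(scores)))
  key <- interaction(scores[, by, drop = FALSE], drop = TRUE, sep = "\r")
  agg <- lapply(split(scores$wprs, key), function(x) {
    c(n = length(x), mean = mean(x),
      sd = if (length(x) >= 2) stats::sd(x) else NA_real_)
  })
  keys <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- by
  stats <- do.call(rbind, agg)
  out$n <- as.integer(stats[, "n"])
  out$mean <- stats[, "mean"]
  out$sd <- stats[, "sd"]
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Render a group summary at display precision
#'
#' @param summ Output of [group_summary()].
#' @param digits Decimal places (default 2, the conventional display).
#' @return The summary with an added `display` column `"mean (sd)"`.
#' @export
format_group_summary <- function(summ, digits = 2) {
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, format = "f",
                                                  digits = digits))
  summ$display <- ifelse(is.na(summ$sd), fmt(summ$mean),
                         paste0(fmt(summ$mean), " (", fmt(summ$sd), ")"))
  summ
}
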
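#' Run the full familial-vs-population wPRS analysis
#'
#' Orchestrates the whole pipeline on a simulated study: build a risk
#' panel, simulate and score a case-control cohort, ascertain multicase
#' families, then run every comparison the analysis defines —
#' case-vs-control Welch test and ROC/AUC, the three subsampling contrasts
#' (familial cases vs population cases, familial cases vs controls,
#' unaffected relatives vs controls), the family report, and the
#' kinship-aware mixed-model contrasts. Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed controlling every random draw.
#' @param k,iterations Subsampling parameters (defaults 500 and 100).
#' @param n_families Number of multicase families to ascertain (default
#'   3).
#' @param out_dir Optional directory; when given, writes `report.json`
#'   (full-precision numbers), `scores.csv`, `panel.tsv`, `family.ped`,
#'   `roc_points.csv` and a simulated-cohort `cohort.vcf`.
#' @return List of class `famprs_report` with elements `seed`, `config`,
#'   `panel_provenance`, `cohort` (welch, roc), `family_report`,
#'   `subsampling` (one `famprs_subsample` per contrast), `mixed_model`
#'   (one fit per contrast), `ascertainment`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1, k = 500,
                         iterations = 100, n_families = 3,
                         out_dir = NULL) {
  set.seed(seed)
  sim <- simulate_cohort(config)
  cohort <- sim$scores
  case_scores <- cohort$wprs[cohort$group == "case"]
  control_scores <- cohort$wprs[cohort$group == "control"]
  welch <- welch_t(case_scores, control_scores)
  roc <- roc_auc(cohort$wprs, cohort$group == "case")

  fams <- ascertain_multicase_families(sim$panel, sim$freqs, config,
                                       n_families = n_families)
  fam_scores <- do.call(rbind, lapply(fams$families, function(f) {
    data.frame(family_id = f$pedigree$family_id,
               individual_id = f$pedigree$individual_id,
               group = ifelse(f$affected, "familial_case",
                              "unaffected_relative"),
               wprs = f$wprs, stringsAsFactors = FALSE)
  }))
  fam_ped <- do.call(rbind, lapply(fams$families, `[[`, "pedigree"))
  report <- family_report(fam_scores)

  famcase <- fam_scores$wprs[fam_scores$group == "familial_case"]
  names(famcase) <- fam_scores$individual_id[fam_scores$group ==
                                               "familial_case"]
  unaff <- fam_scores$wprs[fam_scores$group == "unaffected_relative"]
  names(unaff) <- fam_scores$individual_id[fam_scores$group ==
                                             "unaffected_relative"]
  sub_k <- min(k, length(case_scores), length(control_scores))
  subsampling <- list(
    famcase_vs_cases = subsample_compare(case_scores, famcase, k = sub_k,
                                         iterations = iterations,
                                         seed = seed + 1),
    famcase_vs_controls = subsample_compare(control_scores, famcase,
                                            k = sub_k,
                                            iterations = iterations,
                                            seed = seed + 2),
    unaffected_vs_controls = subsample_compare(control_scores, unaff,
                                               k = sub_k,
                                               iterations = iterations,
                                               seed = seed + 3))

  sex_of <- function(ids) fam_ped$sex[match(ids, fam_ped$individual_id)]
  pop_sex <- function(n) rep(c("male", "female"), length.out = n)
  mm <- list(
    famcase_vs_controls = test_group_difference(
      famcase, control_scores, pedigree_a = fam_ped,
      sex = c(sex_of(names(famcase)), pop_sex(length(control_scores)))),
    famcase_vs_cases = test_group_difference(
      famcase, case_scores, pedigree_a = fam_ped,
      sex = c(sex_of(names(famcase)), pop_sex(length(case_scores)))),
    unaffected_vs_controls = test_group_difference(
      unaff, control_scores, pedigree_a = fam_ped,
      sex = c(sex_of(names(unaff)), pop_sex(length(control_scores)))))

  out <- structure(list(
    seed = seed, config = config,
    panel_provenance = attr(sim$panel, "provenance"),
    cohort = list(welch = welch, roc = roc,
                  n_cases = length(case_scores),
                  n_controls = length(control_scores)),
    family_report = report,
    family_scores = fam_scores,
    subsampling = subsampling,
    mixed_model = mm,
    ascertainment = list(attempts = fams$attempts,
                         rate = fams$ascertainment_rate)),
    class = "famprs_report")
  if (!is.null(out_dir)) write_report(out, sim, fams, out_dir)
  out
}

write_report <- function(report, sim, fams, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(sim$panel, file.path(out_dir, "panel.tsv"))
  write_score_table(rbind(
    sim$scores[, c("family_id", "individual_id", "group", "wprs")],
    report$family_scores), file.path(out_dir, "scores.csv"))
  fam_ped <- do.call(rbind, lapply(fams$families, `[[`, "pedigree"))
  utils::write.table(fam_ped, file.path(out_dir, "family.ped"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(report$cohort$roc$curve,
                   file.path(out_dir, "roc_points.csv"), row.names = FALSE)
  write_vcf(fams$families[[1]]$genotypes, file.path(out_dir, "family1.vcf"))
  jsonlite::write_json(report_as_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# plain-list rendering of the report for JSON serialisation
report_as_list <- function(report) {
  sub_as_list <- function(s) {
    s[c("n_iterations", "subsample_size", "seed", "p_min", "p_max",
        "n_significant_05", "family_mean", "family_sd")]
  }
  mm_as_list <- function(f) {
    list(beta_group = unname(f$beta["group"]), se_group = unname(f$se["group"]),
         h2 = f$h2, lrt_p = f$lrt_p, wald_p = f$wald_p,
         n_a = f$n_a, n_b = f$n_b)
  }
  list(seed = report$seed,
       panel_provenance = as.list(report$panel_provenance),
       cohort = list(
         n_cases = report$cohort$n_cases,
         n_controls = report$cohort$n_controls,
         welch = report$cohort$welch[c("t", "df", "p_two_sided", "mean_a",
                                       "mean_b", "sd_a", "sd_b")],
         auc = report$cohort$roc$auc,
         auc_ci = c(report$cohort$roc$ci_low, report$cohort$roc$ci_high)),
       family_summary = report$family_report$summary,
       subsampling = lapply(report$subsampling, sub_as_list),
       mixed_model = lapply(report$mixed_model, mm_as_list),
       ascertainment = report$ascertainment)
}

#' @exportS3Method base::print
print.famprs_report <- function(x, ...) {
  cat("== famprs pipeline report (seed ", x$seed, ") ==\n", sep = "")
  cat(sprintf("Cohort: %d cases vs %d controls\n",
              x$cohort$n_cases, x$cohort$n_controls))
  print(x$cohort$welch)
  print(x$cohort$roc)
  print(x$family_report)
  for (nm in names(x$subsampling)) {
    cat("--", nm, "--\n")
    print(x$subsampling[[nm]])
  }
  for (nm in names(x$mixed_model)) {
    f <- x$mixed_model[[nm]]
    cat(sprintf("Mixed model %s: beta = %.3f SD, LRT p = %s, Wald p = %s, h2 = %.2f\n",
                nm, f$beta["group"], format_pvalue(f$lrt_p),
                format_pvalue(f$wald_p), f$h2))
  }
  cat(sprintf("Family ascertainment: %d attempts (rate %.3f)\n",
              x$ascertainment$attempts, x$ascertainment$rate))
  invisible(x)
}
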
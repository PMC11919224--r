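#' Is an allele pair strand-ambiguous?
#'
#' A/T and C/G SNPs cannot be oriented across genotyping platforms from
#' their alleles alone (each allele is its own partner's reverse
#' complement), so they are excluded from cross-platform risk scoring.
#'
#' @param allele_a,allele_b Single nucleotides (`A`, `C`, `G`, `T`). HLA
#'   presence/absence pseudo-markers (alleles `P`/`A` by convention) are
#'   never ambiguous and should bypass this check via `build_panel`.
#' @return `TRUE` iff the unordered pair is \{A,T\} or \{C,G\}.
#' @examples
#' is_ambiguous("A", "T")  # TRUE
#' is_ambiguous("A", "G")  # FALSE
#' @export
is_ambiguous <- function(allele_a, allele_b) {
  a <- toupper(allele_a); b <- toupper(allele_b)
  if (!all(c(a, b) %in% c("A", "C", "G", "T"))) {
    stop("non-nucleotide allele for SNP ambiguity check: ",
         allele_a, "/", allele_b, call. = FALSE)
  }
  (a == revcomp(b))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", toupper(x))
}

is_hla_pseudo <- function(allele_a, allele_b) {
  !all(c(toupper(allele_a), toupper(allele_b)) %in% c("A", "C", "G", "T"))
}

#' Orient a summary-statistic variant against observed alleles
#'
#' Determines how the risk/other allele pair reported by a GWAS maps onto
#' the allele pair observed in a genotype dataset, so that risk-allele
#' dosage can be counted consistently. The observed pair is ordered
#' `(counted, other)`: `counted` is the allele the dataset's dosage counts
#' (ALT for VCF input).
#'
#' Orientations: `"match"` — the counted allele is the risk allele, dosage
#' used directly; `"swap"` — the counted allele is the other allele, risk
#' dosage is `2 - dosage`; `"strand_flip"` / `"strand_flip_swap"` — same
#' after reverse-complementing the observed pair (attempted only for
#' non-ambiguous SNPs); `"fail"` — alleles irreconcilable, variant dropped.
#'
#' @param risk_allele,other_allele Alleles as reported by the GWAS.
#' @param observed Character vector of length 2: `(counted, other)` alleles
#'   observed in the genotype data.
#' @return One of `"match"`, `"swap"`, `"strand_flip"`,
#'   `"strand_flip_swap"`, `"fail"`.
#' @export
harmonize_variant <- function(risk_allele, other_allele, observed) {
  stopifnot(length(observed) == 2)
  r <- toupper(risk_allele); o <- toupper(other_allele)
  obs <- toupper(observed)
  if (identical(c(r, o), obs)) return("match")
  if (identical(c(o, r), obs)) return("swap")
  hla <- is_hla_pseudo(r, o) || is_hla_pseudo(obs[1], obs[2])
  if (!hla && !is_ambiguous(r, o)) {
    flipped <- revcomp(obs)
    if (identical(c(r, o), flipped)) return("strand_flip")
    if (identical(c(o, r), flipped)) return("strand_flip_swap")
  }
  "fail"
}

#' Build a harmonized risk panel from GWAS summary records
#'
#' Intersects a GWAS risk-variant summary table with the variants available
#' in two genotyped datasets (a panel is only useful for variants observed
#' in *both* the cohort and the family data), drops strand-ambiguous SNPs,
#' checks that risk alleles can be oriented against each dataset, and
#' attaches log-odds-ratio weights. Variants with OR < 1 are re-oriented to
#' the opposite allele (OR inverted) so every panel weight is
#' `ln(OR) >= 0`.
#'
#' @param summary_tab Data.frame from [read_gwas_panel()].
#' @param variants_a,variants_b Variant tables of the two datasets:
#'   data.frames with columns `variant_id`, `a1` (counted allele), `a2`, as
#'   found in `famprs_genotypes$variants`. `variants_b` may be `NULL` to
#'   build a single-dataset panel.
#' @return An object of class `famprs_panel`: a data.frame with columns
#'   `variant_id`, `risk_allele`, `other_allele`, `or`, `weight`
#'   (`= ln(or)`), plus a `provenance` attribute counting variants removed
#'   by each exclusion rule (`n_summary`, `n_not_in_both`, `n_ambiguous`,
#'   `n_orientation_fail`, `n_or_inverted`, `n_final`).
#' @export
build_panel <- function(summary_tab, variants_a, variants_b = NULL) {
  stopifnot(is.data.frame(summary_tab))
  if (!"odds_ratio" %in% names(summary_tab) && "or" %in% names(summary_tab)) {
    summary_tab$odds_ratio <- summary_tab$or   # accept a panel as input
  }
  norm_vars <- function(v) {
    if (inherits(v, "famprs_genotypes")) v <- v$variants
    stopifnot(all(c("variant_id", "a1", "a2") %in% names(v)))
    v
  }
  variants_a <- norm_vars(variants_a)
  n_summary <- nrow(summary_tab)
  in_a <- summary_tab$variant_id %in% variants_a$variant_id
  if (!is.null(variants_b)) {
    variants_b <- norm_vars(variants_b)
    in_both <- in_a & summary_tab$variant_id %in% variants_b$variant_id
  } else {
    in_both <- in_a
  }
  n_not_in_both <- sum(!in_both)
  tab <- summary_tab[in_both, , drop = FALSE]
  if (nrow(tab) == 0) {
    stop("no summary variants found in both datasets; check that the ",
         "variant ID schemes (e.g. rsIDs vs chrom:pos) agree", call. = FALSE)
  }
  hla <- mapply(is_hla_pseudo, tab$risk_allele, tab$other_allele)
  ambiguous <- !hla & mapply(is_ambiguous, tab$risk_allele, tab$other_allele)
  n_ambiguous <- sum(ambiguous)
  tab <- tab[!ambiguous, , drop = FALSE]
  orient_ok <- function(v) {
    idx_a <- match(tab$variant_id, v$variant_id)
    mapply(function(r, o, a1, a2) {
      harmonize_variant(r, o, c(a1, a2)) != "fail"
    }, tab$risk_allele, tab$other_allele, v$a1[idx_a], v$a2[idx_a])
  }
  ok <- orient_ok(variants_a)
  if (!is.null(variants_b)) ok <- ok & orient_ok(variants_b)
  n_orientation_fail <- sum(!ok)
  tab <- tab[ok, , drop = FALSE]
  # orient so OR >= 1: flip risk/other and invert OR
  flip <- tab$odds_ratio < 1
  n_or_inverted <- sum(flip)
  risk <- ifelse(flip, tab$other_allele, tab$risk_allele)
  other <- ifelse(flip, tab$risk_allele, tab$other_allele)
  or <- ifelse(flip, 1 / tab$odds_ratio, tab$odds_ratio)
  panel <- data.frame(variant_id = tab$variant_id,
                      risk_allele = risk, other_allele = other,
                      or = or, weight = log(or),
                      stringsAsFactors = FALSE)
  rownames(panel) <- NULL
  attr(panel, "provenance") <- c(
    n_summary = n_summary, n_not_in_both = n_not_in_both,
    n_ambiguous = n_ambiguous, n_orientation_fail = n_orientation_fail,
    n_or_inverted = n_or_inverted, n_final = nrow(panel))
  class(panel) <- c("famprs_panel", "data.frame")
  panel
}

#' @exportS3Method base::print
print.famprs_panel <- function(x, ...) {
  p <- attr(x, "provenance")
  cat("famprs_panel:", nrow(x), "variants (max OR ",
      format(max(x$or), digits = 3), ")\n", sep = "")
  if (!is.null(p)) {
    cat("  provenance:", paste(names(p), p, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize / read a risk panel as TSV
#'
#' @param panel A `famprs_panel`.
#' @param path TSV path with columns `variant_id`, `risk_allele`,
#'   `other_allele`, `or`, `weight`.
#' @return `write_panel`: `path` invisibly; `read_panel`: a `famprs_panel`
#'   (provenance is not round-tripped).
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "risk_allele", "other_allele", "weight")
                %in% names(tab)))
  if (!"or" %in% names(tab)) tab$or <- exp(tab$weight)
  class(tab) <- c("famprs_panel", "data.frame")
  tab
}
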
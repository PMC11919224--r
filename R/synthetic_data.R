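#' Simulation configuration
#'
#' Parameters of the synthetic study: a risk panel shaped like the
#' published MS panel (167 variants of which 26 are HLA-like, one
#' large-effect allele at OR 2.9, remaining ORs in \[1.05, 1.6\] — the
#' scale of the non-HLA effects), a liability-threshold disease, and
#' case-control/family sample sizes. The default polygenic share of
#' liability variance (0.21) is calibrated so the simulated case-control
#' wPRS discrimination matches the published AUC of about 0.75; disease
#' prevalence defaults to 0.1 so that case sampling and multicase-family
#' ascertainment are tractable by direct rejection sampling.
#'
#' @param n_variants Panel size (default 167).
#' @param n_hla Number of HLA-like variants, coded as presence/absence
#'   pseudo-markers on chromosome 6 (default 26).
#' @param large_effect_or Odds ratio of the single large-effect HLA-like
#'   allele (default 2.9).
#' @param or_range Range of the remaining odds ratios (default
#'   `c(1.05, 1.6)`).
#' @param hla_freq Risk-allele frequency of the large-effect variant
#'   (default 0.15).
#' @param freq_range Range from which other risk-allele frequencies are
#'   drawn uniformly (default `c(0.05, 0.5)`).
#' @param disease_prevalence Population disease prevalence K (default
#'   0.1).
#' @param liability_h2_polygenic Share of liability variance explained by
#'   the panel score (default 0.21).
#' @param n_cases,n_controls Cohort sizes after case-control ascertainment
#'   (defaults 500 and 900).
#' @param min_affected_per_family Multicase ascertainment criterion
#'   (default 3).
#' @return A list of class `famprs_sim_config`.
#' @export
sim_config <- function(n_variants = 167, n_hla = 26, large_effect_or = 2.9,
                       or_range = c(1.05, 1.6), hla_freq = 0.15,
                       freq_range = c(0.05, 0.5),
                       disease_prevalence = 0.1,
                       liability_h2_polygenic = 0.21,
                       n_cases = 500, n_controls = 900,
                       min_affected_per_family = 3) {
  stopifnot(n_variants >= 1, n_hla >= 0, n_hla <= n_variants,
            large_effect_or > 0, all(or_range > 0),
            disease_prevalence > 0, disease_prevalence < 1,
            liability_h2_polygenic >= 0, liability_h2_polygenic <= 1,
            all(freq_range > 0), all(freq_range < 1))
  structure(as.list(environment()), class = "famprs_sim_config")
}

#' Simulate a risk panel
#'
#' Draws a synthetic risk panel per a [sim_config()]: one HLA-like
#' presence/absence pseudo-marker with the large effect, further HLA-like
#' pseudo-markers on chromosome 6, and non-HLA SNPs with non-ambiguous
#' allele pairs on the autosomes; odds ratios from `or_range`; risk-allele
#' frequencies from `freq_range`.
#'
#' @param config A `famprs_sim_config`.
#' @param seed Optional integer seed.
#' @return List with `panel` (a `famprs_panel`) and `freqs` (risk-allele
#'   frequencies aligned to the panel).
#' @export
simulate_panel <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- config$n_variants
  n_hla <- config$n_hla
  is_hla <- seq_len(m) <= n_hla
  ids <- ifelse(is_hla, sprintf("HLA%03d", seq_len(m)),
                sprintf("rs%06d", 100000 + seq_len(m)))
  or <- stats::runif(m, config$or_range[1], config$or_range[2])
  freqs <- stats::runif(m, config$freq_range[1], config$freq_range[2])
  if (n_hla >= 1 || m >= 1) {
    or[1] <- config$large_effect_or          # the DRB1*15:01-like allele
    freqs[1] <- config$hla_freq
  }
  # non-ambiguous SNP allele pairs for non-HLA variants
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pick <- sample.int(nrow(pairs), m, replace = TRUE)
  risk <- ifelse(is_hla, "P", pairs[pick, 1])
  other <- ifelse(is_hla, "A", pairs[pick, 2])
  panel <- data.frame(variant_id = ids, risk_allele = risk,
                      other_allele = other, or = or, weight = log(or),
                      chrom = ifelse(is_hla, "6",
                                     as.character(sample(1:22, m, TRUE))),
                      pos = sample.int(1e8, m),
                      stringsAsFactors = FALSE)
  class(panel) <- c("famprs_panel", "data.frame")
  list(panel = panel, freqs = freqs)
}

# Theoretical moments of the panel score under HWE and linkage
# equilibrium, and the liability threshold implied by the config.
liability_parameters <- function(panel, freqs, config) {
  w <- panel$weight
  mean_g <- sum(2 * freqs * w)
  var_g <- sum(2 * freqs * (1 - freqs) * w^2)
  h2 <- config$liability_h2_polygenic
  sigma2_e <- if (h2 > 0) var_g * (1 - h2) / h2 else {
    # null model: disease independent of the score; unit environment
    1
  }
  var_l <- if (h2 > 0) var_g + sigma2_e else sigma2_e
  mean_l <- if (h2 > 0) mean_g else 0   # no genetic part in the null model
  threshold <- mean_l + stats::qnorm(1 - config$disease_prevalence) *
    sqrt(var_l)
  list(mean_g = mean_g, var_g = var_g, sigma2_e = sigma2_e,
       threshold = threshold)
}

#' Simulate an unascertained population
#'
#' Draws `n` unrelated individuals: genotypes Binomial(2, freq) per variant
#' (Hardy-Weinberg, linkage equilibrium), liability = panel score +
#' N(0, sigma2_e) with sigma2_e set so the score explains
#' `liability_h2_polygenic` of liability variance, affection = liability
#' above the threshold implied by `disease_prevalence`. When the polygenic
#' share is 0, liability is pure noise and affection is independent of the
#' score.
#'
#' @param panel,freqs Output of [simulate_panel()].
#' @param n Number of individuals.
#' @param config The `famprs_sim_config` (sets prevalence and polygenic
#'   share).
#' @param seed Optional integer seed.
#' @param id_prefix Prefix for sample IDs.
#' @return List with `genotypes` (a `famprs_genotypes` whose counted allele
#'   is the risk allele), `wprs`, `liability`, `affected` (logical).
#' @export
simulate_population <- function(panel, freqs, n, config = sim_config(),
                                seed = NULL, id_prefix = "ind") {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(panel)
  stopifnot(length(freqs) == m)
  dos <- matrix(stats::rbinom(n * m, 2, rep(freqs, each = n)), nrow = n)
  ids <- sprintf("%s%05d", id_prefix, seq_len(n))
  dimnames(dos) <- list(ids, panel$variant_id)
  lp <- liability_parameters(panel, freqs, config)
  wprs <- as.numeric(dos %*% panel$weight)
  gen_part <- if (config$liability_h2_polygenic > 0) wprs else 0
  liability <- gen_part + stats::rnorm(n, 0, sqrt(lp$sigma2_e))
  geno <- new_genotypes(ids,
                        data.frame(variant_id = panel$variant_id,
                                   chrom = panel$chrom %||% "1",
                                   pos = panel$pos %||% seq_len(m),
                                   a1 = panel$risk_allele,
                                   a2 = panel$other_allele,
                                   stringsAsFactors = FALSE),
                        dos)
  list(genotypes = geno, wprs = wprs, liability = liability,
       affected = liability > lp$threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ascertain a case-control cohort from a simulated population
#'
#' Randomly samples the requested numbers of affected and unaffected
#' individuals without replacement.
#'
#' @param population Output of [simulate_population()].
#' @param n_cases,n_controls Requested class sizes.
#' @param seed Optional integer seed.
#' @return A score table (`individual_id`, `group` = `"case"`/`"control"`,
#'   `wprs`, plus `family_id = NA`) with attribute `index` giving row
#'   positions into the population.
#' @export
ascertain_case_control <- function(population, n_cases, n_controls,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  case_idx <- which(population$affected)
  control_idx <- which(!population$affected)
  if (length(case_idx) < n_cases) {
    stop("population has only ", length(case_idx), " cases; ",
         n_cases, " requested", call. = FALSE)
  }
  if (length(control_idx) < n_controls) {
    stop("population has only ", length(control_idx), " controls; ",
         n_controls, " requested", call. = FALSE)
  }
  pick <- c(sample(case_idx, n_cases), sample(control_idx, n_controls))
  out <- data.frame(
    family_id = NA_character_,
    individual_id = population$genotypes$sample_ids[pick],
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    wprs = population$wprs[pick],
    stringsAsFactors = FALSE)
  attr(out, "index") <- pick
  out
}

#' Simulate a case-control cohort in one call
#'
#' Generates population batches until the configured numbers of cases and
#' controls are available, then ascertains them. Errors if the case count
#' is still unreachable after `max_batches` batches (e.g. a prevalence too
#' low for the batch size).
#'
#' @param config A `famprs_sim_config`.
#' @param seed Optional integer seed.
#' @param max_batches Safety cap on the number of sampling batches.
#' @return List with `panel`, `freqs`, `scores` (score table of the
#'   ascertained cohort), `population` (the final pooled simulation).
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL,
                            max_batches = 10) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_panel(config)
  batch_n <- ceiling(1.3 * config$n_cases / config$disease_prevalence)
  pop <- simulate_population(sim$panel, sim$freqs, batch_n, config)
  batches <- 1
  while ((sum(pop$affected) < config$n_cases ||
          sum(!pop$affected) < config$n_controls) &&
         batches < max_batches) {
    extra <- simulate_population(sim$panel, sim$freqs, batch_n, config,
                                 id_prefix = sprintf("b%dind", batches + 1))
    pop <- list(genotypes = new_genotypes(
                  c(pop$genotypes$sample_ids, extra$genotypes$sample_ids),
                  pop$genotypes$variants,
                  rbind(pop$genotypes$dosage, extra$genotypes$dosage)),
                wprs = c(pop$wprs, extra$wprs),
                liability = c(pop$liability, extra$liability),
                affected = c(pop$affected, extra$affected))
    batches <- batches + 1
  }
  if (sum(pop$affected) < config$n_cases) {
    stop("could not reach ", config$n_cases, " cases after ", batches,
         " batches (prevalence ", config$disease_prevalence, ")",
         call. = FALSE)
  }
  scores <- ascertain_case_control(pop, config$n_cases, config$n_controls)
  list(panel = sim$panel, freqs = sim$freqs, scores = scores,
       population = pop)
}

#' Default three-generation family template
#'
#' A pedigree scaffold shaped after the study families: two founders, six
#' offspring (optionally including a monozygotic twin pair), one offspring
#' married to an unrelated founder with two children.
#'
#' @param mz Include an MZ twin pair among the offspring (default `TRUE`).
#' @return A template data.frame: `individual_id`, `father_id`,
#'   `mother_id`, `sex`, `mz_group`.
#' @export
default_family_template <- function(mz = TRUE) {
  tpl <- data.frame(
    individual_id = c("f1", "f2", "o1", "o2", "o3", "o4", "o5", "o6",
                      "s1", "g1", "g2"),
    father_id = c(NA, NA, "f1", "f1", "f1", "f1", "f1", "f1",
                  NA, "o1", "o1"),
    mother_id = c(NA, NA, "f2", "f2", "f2", "f2", "f2", "f2",
                  NA, "s1", "s1"),
    sex = c("male", "female", "male", "female", "male", "female",
            "male", "male", "female", "male", "female"),
    mz_group = NA_character_,
    stringsAsFactors = FALSE)
  if (mz) tpl$mz_group[tpl$individual_id %in% c("o5", "o6")] <- "mz1"
  tpl
}

#' Gene-drop a family's genotypes
#'
#' Simulates genotypes down a pedigree template: founders draw each
#' haplotype Bernoulli(freq) per variant, each non-founder receives one
#' uniformly chosen haplotype from each parent per variant (Mendelian
#' transmission, free recombination across the panel), and MZ co-twins
#' copy genotypes exactly. Liability and affection are generated as in
#' [simulate_population()], so family and population are comparable.
#'
#' @param panel,freqs Output of [simulate_panel()].
#' @param template A template as from [default_family_template()].
#' @param config The `famprs_sim_config`.
#' @param seed Optional integer seed.
#' @param family_id Family label for the pedigree records.
#' @return List with `genotypes` (`famprs_genotypes`, counted allele =
#'   risk allele), `wprs`, `liability`, `affected`, and `pedigree` (a
#'   validated pedigree data.frame with affection filled in).
#' @export
simulate_family <- function(panel, freqs, template = default_family_template(),
                            config = sim_config(), seed = NULL,
                            family_id = "fam1") {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(panel)
  ids <- template$individual_id
  n <- length(ids)
  miss_parent <- is.na(template$father_id) != is.na(template$mother_id)
  if (any(miss_parent)) stop("template parents must be both present or both ",
                             "missing", call. = FALSE)
  bad_parent <- (!is.na(template$father_id) &
                   !template$father_id %in% ids) |
    (!is.na(template$mother_id) & !template$mother_id %in% ids)
  if (any(bad_parent)) {
    stop("template references missing parent for ",
         ids[bad_parent][1], call. = FALSE)
  }
  ord <- pedigree_order(data.frame(individual_id = ids,
                                   father_id = template$father_id,
                                   mother_id = template$mother_id))
  H1 <- H2 <- matrix(0L, n, m, dimnames = list(ids, panel$variant_id))
  for (i in ord) {
    fa <- template$father_id[i]
    if (is.na(fa)) {
      H1[i, ] <- stats::rbinom(m, 1, freqs)
      H2[i, ] <- stats::rbinom(m, 1, freqs)
    } else {
      mo <- template$mother_id[i]
      tw <- NULL
      if (!is.na(template$mz_group[i])) {
        co <- which(!is.na(template$mz_group) &
                      template$mz_group == template$mz_group[i] &
                      seq_len(n) != i)
        done <- co[co %in% ord[seq_len(match(i, ord) - 1)]]
        if (length(done) > 0) tw <- done[1]
      }
      if (!is.null(tw)) {        # MZ co-twin: copy genotypes exactly
        H1[i, ] <- H1[tw, ]
        H2[i, ] <- H2[tw, ]
      } else {
        from_fa <- stats::rbinom(m, 1, 0.5)
        from_mo <- stats::rbinom(m, 1, 0.5)
        H1[i, ] <- ifelse(from_fa == 1, H1[fa, ], H2[fa, ])
        H2[i, ] <- ifelse(from_mo == 1, H1[mo, ], H2[mo, ])
      }
    }
  }
  dos <- H1 + H2
  mode(dos) <- "numeric"
  lp <- liability_parameters(panel, freqs, config)
  wprs <- as.numeric(dos %*% panel$weight)
  gen_part <- if (config$liability_h2_polygenic > 0) wprs else 0
  liability <- gen_part + stats::rnorm(n, 0, sqrt(lp$sigma2_e))
  affected <- liability > lp$threshold
  ped <- data.frame(family_id = family_id,
                    individual_id = ids,
                    father_id = template$father_id,
                    mother_id = template$mother_id,
                    sex = template$sex,
                    affection = ifelse(affected, "affected", "unaffected"),
                    mz_group = template$mz_group,
                    stringsAsFactors = FALSE)
  geno <- new_genotypes(ids,
                        data.frame(variant_id = panel$variant_id,
                                   chrom = panel$chrom %||% "1",
                                   pos = panel$pos %||% seq_len(m),
                                   a1 = panel$risk_allele,
                                   a2 = panel$other_allele,
                                   stringsAsFactors = FALSE),
                        dos)
  list(genotypes = geno, wprs = wprs, liability = liability,
       affected = affected, pedigree = validate_pedigree(ped))
}

#' Ascertain multicase families by rejection sampling
#'
#' Repeatedly simulates families from the template and keeps those with at
#' least `min_affected` affected members, mirroring how multicase families
#' enter real studies. The empirical ascertainment rate (families accepted
#' over attempts) is recorded.
#'
#' @param panel,freqs Output of [simulate_panel()].
#' @param config The `famprs_sim_config` (supplies
#'   `min_affected_per_family` unless `min_affected` is given).
#' @param n_families Number of families to collect (default 3).
#' @param min_affected Override of the ascertainment criterion.
#' @param template Family template (default
#'   [default_family_template()]).
#' @param max_attempts Cap on simulated families before giving up.
#' @param seed Optional integer seed.
#' @return List with `families` (list of [simulate_family()] results,
#'   relabelled `fam1..famN` with prefixed individual IDs), `attempts`,
#'   and `ascertainment_rate`.
#' @export
ascertain_multicase_families <- function(panel, freqs,
                                         config = sim_config(),
                                         n_families = 3,
                                         min_affected = NULL,
                                         template = default_family_template(),
                                         max_attempts = 10000,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  min_affected <- min_affected %||% config$min_affected_per_family
  stopifnot(min_affected >= 0)
  families <- list()
  attempts <- 0
  while (length(families) < n_families && attempts < max_attempts) {
    attempts <- attempts + 1
    fam <- simulate_family(panel, freqs, template, config,
                           family_id = sprintf("fam%d", length(families) + 1))
    if (sum(fam$affected) >= min_affected) {
      k <- length(families) + 1
      prefix <- sprintf("fam%d_", k)
      relabel <- function(x) ifelse(is.na(x), x, paste0(prefix, x))
      fam$pedigree$individual_id <- relabel(fam$pedigree$individual_id)
      fam$pedigree$father_id <- relabel(fam$pedigree$father_id)
      fam$pedigree$mother_id <- relabel(fam$pedigree$mother_id)
      fam$pedigree$mz_group <- relabel(fam$pedigree$mz_group)
      fam$genotypes$sample_ids <- relabel(fam$genotypes$sample_ids)
      rownames(fam$genotypes$dosage) <- fam$genotypes$sample_ids
      families[[k]] <- fam
    }
  }
  if (length(families) < n_families) {
    stop("only ", length(families), "/", n_families,
         " families with >= ", min_affected, " affected after ",
         attempts, " attempts; consider raising prevalence or the ",
         "polygenic share", call. = FALSE)
  }
  list(families = families, attempts = attempts,
       ascertainment_rate = n_families / attempts)
}
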
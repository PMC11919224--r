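test_that("simulated panels carry the configured shape", {
  sim <- simulate_panel(sim_config(), seed = 1)
  expect_equal(nrow(sim$panel), 167)
  expect_equal(sum(sim$panel$or == 2.9), 1)
  expect_equal(sum(grepl("^HLA", sim$panel$variant_id)), 26)
  expect_true(all(sim$panel$weight >= log(1.05) - 1e-9 |
                    sim$panel$or == 2.9))
  expect_true(all(sim$freqs > 0 & sim$freqs < 1))
  # SNP allele pairs are never strand-ambiguous
  snp <- sim$panel[sim$panel$risk_allele %in% c("A", "C", "G", "T"), ]
  expect_false(any(mapply(is_ambiguous, snp$risk_allele,
                          snp$other_allele)))
  # determinism under a seed; single-variant edge case
  sim2 <- simulate_panel(sim_config(), seed = 1)
  expect_identical(sim$panel, sim2$panel)
  expect_equal(nrow(simulate_panel(sim_config(n_variants = 1, n_hla = 0),
                                   seed = 2)$panel), 1)
})

test_that("population genotypes match Hardy-Weinberg inputs and the liability model", {
  cfg <- sim_config(n_variants = 30, n_hla = 2)
  sim <- simulate_panel(cfg, seed = 3)
  pop <- simulate_population(sim$panel, sim$freqs, 4000, cfg, seed = 4)
  # moment check: observed allele frequencies near the inputs
  obs <- colMeans(pop$genotypes$dosage) / 2
  expect_lt(max(abs(obs - sim$freqs)), 4 * sqrt(0.25 / (2 * 4000)) + 0.02)
  # prevalence near the configured value
  expect_lt(abs(mean(pop$affected) - cfg$disease_prevalence), 0.02)
  # wprs is the weighted dosage sum
  expect_equal(pop$wprs[1],
               sum(pop$genotypes$dosage[1, ] * sim$panel$weight),
               tolerance = 1e-12)
})

test_that("a zero polygenic share makes affection independent of the score", {
  cfg <- sim_config(n_variants = 30, n_hla = 2,
                    liability_h2_polygenic = 0)
  sim <- simulate_panel(cfg, seed = 5)
  pop <- simulate_population(sim$panel, sim$freqs, 6000, cfg, seed = 6)
  auc <- roc_auc(pop$wprs, pop$affected)$auc
  expect_lt(abs(auc - 0.5), 0.03)
})

test_that("case-control ascertainment returns exact counts, errors when short", {
  cfg <- sim_config(n_variants = 20, n_hla = 1)
  sim <- simulate_panel(cfg, seed = 7)
  pop <- simulate_population(sim$panel, sim$freqs, 2000, cfg, seed = 8)
  cc <- ascertain_case_control(pop, 50, 100, seed = 9)
  expect_equal(sum(cc$group == "case"), 50)
  expect_equal(sum(cc$group == "control"), 100)
  expect_false(any(duplicated(cc$individual_id)))
  cc2 <- ascertain_case_control(pop, 50, 100, seed = 9)
  expect_identical(cc, cc2)
  expect_error(ascertain_case_control(pop, 1e6, 10), "only")
})

test_that("gene dropping respects Mendelian transmission and MZ identity", {
  cfg <- sim_config(n_variants = 40, n_hla = 2)
  sim <- simulate_panel(cfg, seed = 10)
  fam <- simulate_family(sim$panel, sim$freqs, config = cfg, seed = 11)
  dos <- fam$genotypes$dosage
  ped <- fam$pedigree
  expect_true(all(dos %in% 0:2))
  # offspring dosage consistent with parents: homozygous parents pin the
  # transmitted allele
  for (i in which(!is.na(ped$father_id))) {
    if (!is.na(ped$mz_group[i])) next
    f <- dos[ped$father_id[i], ]; m <- dos[ped$mother_id[i], ]
    k <- dos[ped$individual_id[i], ]
    lo <- (f == 2) / 1 + (m == 2) / 1      # guaranteed copies
    hi <- 2 - (f == 0) - (m == 0)          # maximum possible copies
    expect_true(all(k >= lo & k <= hi))
  }
  # MZ pair identical genotype vectors
  mz_ids <- ped$individual_id[!is.na(ped$mz_group)]
  expect_equal(dos[mz_ids[1], ], dos[mz_ids[2], ])
  # heterozygous-parent transmission is a fair coin
  set.seed(12)
  tpl <- data.frame(individual_id = c("p", "m", "k"),
                    father_id = c(NA, NA, "p"), mother_id = c(NA, NA, "m"),
                    sex = c("male", "female", "male"),
                    mz_group = NA_character_)
  one <- sim_config(n_variants = 1, n_hla = 0, freq_range = c(0.5, 0.5001))
  pan1 <- simulate_panel(one, seed = 13)
  trans <- replicate(4000, {
    f <- simulate_family(pan1$panel, pan1$freqs, tpl, one)
    d <- f$genotypes$dosage
    if (d["p", 1] == 1 && d["m", 1] == 0) d["k", 1] else NA
  })
  trans <- trans[!is.na(trans)]
  expect_gt(length(trans), 100)
  expect_lt(abs(mean(trans) - 0.5), 3 * sqrt(0.25 / length(trans)))
})

test_that("multicase ascertainment enforces the criterion and biases scores up", {
  cfg <- sim_config()
  sim <- simulate_panel(cfg, seed = 14)
  res <- ascertain_multicase_families(sim$panel, sim$freqs, cfg,
                                      n_families = 3, seed = 15)
  expect_equal(length(res$families), 3)
  for (f in res$families) expect_gte(sum(f$affected), 3)
  expect_gte(res$attempts, 3)
  # min_affected = 0 accepts the first families drawn
  res0 <- ascertain_multicase_families(sim$panel, sim$freqs, cfg,
                                       n_families = 2, min_affected = 0,
                                       seed = 16)
  expect_equal(res0$attempts, 2)
  # ascertained family means exceed the population control mean
  pop <- simulate_population(sim$panel, sim$freqs, 4000, cfg, seed = 17)
  ctrl_mean <- mean(pop$wprs[!pop$affected])
  fam_mean <- mean(unlist(lapply(res$families, `[[`, "wprs")))
  expect_gt(fam_mean, ctrl_mean)
  expect_error(
    ascertain_multicase_families(sim$panel, sim$freqs, cfg,
                                 n_families = 2, min_affected = 11,
                                 max_attempts = 25, seed = 18),
    "attempts")
})

test_that("unascertained family scores are unbiased for the population mean", {
  cfg <- sim_config(n_variants = 30, n_hla = 2)
  sim <- simulate_panel(cfg, seed = 19)
  lp <- famprs:::liability_parameters(sim$panel, sim$freqs, cfg)
  set.seed(20)
  means <- replicate(300, mean(simulate_family(sim$panel, sim$freqs,
                                               config = cfg)$wprs))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - lp$mean_g), 4 * se)
})

test_that("simulated data exercise the real readers end to end", {
  cfg <- sim_config(n_variants = 12, n_hla = 2)
  sim <- simulate_panel(cfg, seed = 21)
  fam <- simulate_family(sim$panel, sim$freqs, config = cfg, seed = 22)
  td <- withr::local_tempdir()
  vcf <- file.path(td, "fam.vcf")
  pedf <- file.path(td, "fam.ped")
  panf <- file.path(td, "panel.tsv")
  write_vcf(fam$genotypes, vcf)
  write_panel(sim$panel, panf)
  utils::write.table(fam$pedigree, pedf, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  geno <- read_genotypes(vcf)
  panel <- read_panel(panf)
  ped <- read_pedigree(pedf)
  expect_equal(dim(geno$dosage), dim(fam$genotypes$dosage))
  scores <- score_cohort(geno, panel,
                         labels = data.frame(
                           individual_id = ped$individual_id,
                           group = ifelse(ped$affection == "affected",
                                          "familial_case",
                                          "unaffected_relative")))
  direct <- as.numeric(fam$genotypes$dosage %*% sim$panel$weight)
  expect_equal(scores$wprs[match(fam$genotypes$sample_ids,
                                 scores$individual_id)],
               direct, tolerance = 1e-9)
})
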
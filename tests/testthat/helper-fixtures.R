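# Shared fixture builders and independent oracles used across test files.

# tiny panel: data.frame is enough everywhere a famprs_panel is consumed
tiny_panel <- function(ors = c(2.9, 1.3, 1.1),
                       risk = c("T", "A", "G"), other = c("C", "G", "T")) {
  structure(data.frame(variant_id = paste0("v", seq_along(ors)),
                       risk_allele = risk, other_allele = other,
                       or = ors, weight = log(ors),
                       stringsAsFactors = FALSE),
            class = c("famprs_panel", "data.frame"))
}

# nuclear family: two founders, `n_kids` full siblings
nuclear_ped <- function(n_kids = 2, fam = "f1") {
  kids <- paste0("k", seq_len(n_kids))
  data.frame(family_id = fam,
             individual_id = c("dad", "mum", kids),
             father_id = c(NA, NA, rep("dad", n_kids)),
             mother_id = c(NA, NA, rep("mum", n_kids)),
             sex = c("male", "female",
                     rep(c("male", "female"), length.out = n_kids)),
             affection = "unknown", mz_group = NA_character_,
             stringsAsFactors = FALSE)
}

# three-generation pedigree with first cousins: k1 and k2 are sibs, each
# married to an unrelated founder, each with one child (c1, c2 are cousins)
cousin_ped <- function() {
  data.frame(family_id = "f1",
             individual_id = c("gp1", "gp2", "k1", "k2", "s1", "s2",
                               "c1", "c2"),
             father_id = c(NA, NA, "gp1", "gp1", NA, NA, "k1", "k2"),
             mother_id = c(NA, NA, "gp2", "gp2", NA, NA, "s1", "s2"),
             sex = c("male", "female", "male", "male", "female", "female",
                     "male", "female"),
             affection = "unknown", mz_group = NA_character_,
             stringsAsFactors = FALSE)
}

# random multi-generation pedigree for property tests: founders plus
# `n_extra` individuals whose parents are drawn from earlier members or
# new founder spouses
random_ped <- function(n_extra = 6, seed = 1) {
  set.seed(seed)
  ped <- data.frame(family_id = "r", individual_id = c("f1", "f2"),
                    father_id = NA_character_, mother_id = NA_character_,
                    sex = c("male", "female"), affection = "unknown",
                    mz_group = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n_extra)) {
    males <- ped$individual_id[ped$sex == "male"]
    females <- ped$individual_id[ped$sex == "female"]
    if (stats::runif(1) < 0.3 || length(males) == 0 ||
        length(females) == 0) {
      fa <- mo <- NA_character_         # new founder
    } else {
      fa <- sample(males, 1)
      mo <- sample(females, 1)
    }
    ped <- rbind(ped, data.frame(
      family_id = "r", individual_id = paste0("x", i),
      father_id = fa, mother_id = mo,
      sex = sample(c("male", "female"), 1), affection = "unknown",
      mz_group = NA_character_, stringsAsFactors = FALSE))
  }
  ped
}

# Independent gene-dropping Monte-Carlo estimate of the kinship
# coefficient: founder haplotypes get unique allele labels, transmission is
# Mendelian, phi is the average probability that one allele drawn from each
# individual is identical by descent. Chunked over drops to bound memory.
gene_drop_kinship <- function(ped, id_a, id_b, n_drops = 1e5,
                              chunk = 250000L) {
  ped <- famprs::validate_pedigree(ped)
  ids <- ped$individual_id
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  ia <- match(id_a, ids); ib <- match(id_b, ids)
  total_match <- 0
  sq_sum <- 0
  done <- 0
  while (done < n_drops) {
    nd <- min(chunk, n_drops - done)
    a1 <- a2 <- matrix(0L, nrow(ped), nd)
    for (i in seq_len(nrow(ped))) {
      if (is.na(fa[i])) {
        a1[i, ] <- 2L * i - 1L
        a2[i, ] <- 2L * i
      } else if (!is.na(ped$mz_group[i]) &&
                 any(!is.na(ped$mz_group[seq_len(i - 1)]) &
                     ped$mz_group[seq_len(i - 1)] == ped$mz_group[i])) {
        tw <- which(!is.na(ped$mz_group[seq_len(i - 1)]) &
                      ped$mz_group[seq_len(i - 1)] == ped$mz_group[i])[1]
        a1[i, ] <- a1[tw, ]
        a2[i, ] <- a2[tw, ]
      } else {
        pick_f <- stats::runif(nd) < 0.5
        pick_m <- stats::runif(nd) < 0.5
        a1[i, ] <- ifelse(pick_f, a1[fa[i], ], a2[fa[i], ])
        a2[i, ] <- ifelse(pick_m, a1[mo[i], ], a2[mo[i], ])
      }
    }
    per_drop <- 0.25 * ((a1[ia, ] == a1[ib, ]) + (a1[ia, ] == a2[ib, ]) +
                          (a2[ia, ] == a1[ib, ]) + (a2[ia, ] == a2[ib, ]))
    total_match <- total_match + sum(per_drop)
    sq_sum <- sq_sum + sum(per_drop^2)
    done <- done + nd
  }
  est <- total_match / n_drops
  se <- sqrt(max(sq_sum / n_drops - est^2, 0) / n_drops)
  list(phi = est, se = se)
}

# dosage-table text fixture on disk; returns the path
write_dosage_fixture <- function(path, dosages, variants) {
  tab <- cbind(variants, t(dosages))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  path
}
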
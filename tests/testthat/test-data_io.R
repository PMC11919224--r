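test_that("GWAS summary tables parse with validation of columns and ORs", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("variant_id,chrom,pos,risk_allele,other_allele,odds_ratio",
               "rsHLA,6,32600000,T,C,2.9",
               "rs1,1,1000,A,G,1.2"), f)
  tab <- read_gwas_panel(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$odds_ratio[1], 2.9)
  expect_equal(tab$variant_id, c("rsHLA", "rs1"))  # row order preserved

  # header only -> empty
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("variant_id,chrom,pos,risk_allele,other_allele,odds_ratio", f2)
  expect_equal(nrow(read_gwas_panel(f2)), 0)

  # OR = 0 -> validation error naming the row
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("variant_id,chrom,pos,risk_allele,other_allele,odds_ratio",
               "rs1,1,1000,A,G,0"), f3)
  expect_error(read_gwas_panel(f3), "positive.*row")

  # missing column -> format error naming it
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("variant_id,chrom,pos,risk_allele,odds_ratio",
               "rs1,1,1000,A,1.2"), f4)
  expect_error(read_gwas_panel(f4), "other_allele")
})

test_that("VCF genotypes load via GT and DS with explicit missingness", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"D\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rs1", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "0/1", "./.", sep = "\t"),
    paste("1", "200", "rs2", "A", "G", ".", "PASS", ".", "DS",
          "1.37", "0", ".", sep = "\t")), f)
  g <- read_genotypes(f)
  expect_s3_class(g, "famprs_genotypes")
  expect_equal(g$dosage["s1", "rs1"], 2)        # 1/1 = two ALT copies
  expect_equal(g$dosage["s2", "rs1"], 1)
  expect_true(is.na(g$dosage["s3", "rs1"]))     # ./. is missing, not 0
  expect_equal(g$dosage["s1", "rs2"], 1.37)     # DS stored unrounded
  expect_true(is.na(g$dosage["s3", "rs2"]))
  expect_equal(g$variants$a1, c("T", "G"))      # counted allele is ALT
})

test_that("VCF round-trip through write_vcf preserves dosages", {
  set.seed(42)
  panel <- tiny_panel()
  dos <- matrix(c(0, 1, 2, 1.37, 0.5, 2, NA, 0, 1), nrow = 3,
                dimnames = list(c("a", "b", "c"), panel$variant_id))
  geno <- famprs:::new_genotypes(
    c("a", "b", "c"),
    data.frame(variant_id = panel$variant_id, chrom = "1",
               pos = c(10L, 20L, 30L), a1 = panel$risk_allele,
               a2 = panel$other_allele, stringsAsFactors = FALSE),
    dos)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(geno, f)
  back <- read_genotypes(f)
  expect_equal(back$dosage, geno$dosage, tolerance = 1e-6)
  expect_equal(back$variants$variant_id, panel$variant_id)
})

test_that("dosage tables reject out-of-range and duplicate entries", {
  vars <- data.frame(variant_id = c("v1", "v2"), chrom = "1",
                     pos = c(1L, 2L), a1 = c("T", "A"), a2 = c("C", "G"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_fixture(f, matrix(c(0, 2.5, 1, 1), 2,
                                 dimnames = list(c("s1", "s2"), NULL)),
                       vars)
  expect_error(read_genotypes(f), "outside \\[0, 2\\]")
})

test_that("pedigrees parse, validate and reject structural errors", {
  ped <- load_family_pedigree()
  expect_equal(nrow(ped), 27)
  expect_equal(sum(ped$affection == "affected"), 9)
  # family 1: two founders, seven genotyped offspring
  f1 <- ped[ped$family_id == "1", ]
  expect_equal(sum(is.na(f1$father_id)), 2)
  expect_equal(nrow(f1), 9)

  # self-parenting is a cycle
  f <- withr::local_tempfile(fileext = ".ped")
  writeLines("f1 a a 0 1 1", f)
  expect_error(read_pedigree(f), "one parent|cycle")
  f2 <- withr::local_tempfile(fileext = ".ped")
  writeLines("f1 a a b 1 1\nf1 b a a 2 1", f2)
  expect_error(read_pedigree(f2), "cycle")

  # unknown parent
  f3 <- withr::local_tempfile(fileext = ".ped")
  writeLines("f1 a ghost mum 1 1\nf1 mum 0 0 2 1", f3)
  expect_error(read_pedigree(f3), "unknown parent")

  # MZ pair with different sexes violates the invariant
  f4 <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("f1 p 0 0 1 1 0", "f1 m 0 0 2 1 0",
               "f1 t1 p m 1 2 mz1", "f1 t2 p m 2 1 mz1"), f4)
  expect_error(read_pedigree(f4), "mixes sexes")
})

test_that("published family score fixture matches the study design counts", {
  tab <- load_table2_fixture()
  expect_equal(nrow(tab), 19)
  expect_equal(sum(tab$group == "familial_case"), 9)
  expect_equal(sum(tab$group == "unaffected_relative"), 10)
  expect_equal(as.vector(table(tab$family_id)), c(7, 6, 6))
  expect_equal(tab$wprs[tab$individual_id == "1-5"], 25.74)
  expect_equal(tab$hla_drb1_1501[tab$individual_id == "1-5"], "+/+")
  expect_equal(tab$wprs[tab$individual_id == "2-1"], 21.35)
  expect_equal(tab$hla_drb1_1501[tab$individual_id == "2-1"], "-/-")
  expect_true(all(tab$group[tab$individual_id %in%
                              c("1-3", "1-4", "1-5")] == "familial_case"))
})

test_that("score tables round-trip exactly through CSV", {
  tab <- load_table2_fixture()
  f <- withr::local_tempfile(fileext = ".csv")
  write_score_table(tab, f)
  back <- read_score_table(f)
  expect_equal(back$wprs, tab$wprs, tolerance = 1e-9)
  expect_equal(back$individual_id, tab$individual_id)
  expect_equal(back$group, tab$group)
})
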
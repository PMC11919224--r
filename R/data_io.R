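#' Read a GWAS risk-variant summary table
#'
#' Reads a delimited table of disease risk variants as published by a GWAS
#' (one row per variant), the raw material for a weighted polygenic risk
#' score panel. The file must have a header naming at least the six fields
#' below; extra columns are ignored.
#'
#' @param path Path to a CSV or TSV file with columns `variant_id`, `chrom`,
#'   `pos`, `risk_allele`, `other_allele`, `odds_ratio` (an `or` column is
#'   accepted as a synonym).
#' @return A data.frame with one row per variant, row order preserved,
#'   columns as above. `pos` is integer, `odds_ratio` numeric.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("variant_id,chrom,pos,risk_allele,other_allele,odds_ratio",
#'              "rsHLA,6,32600000,T,C,2.9"), f)
#' read_gwas_panel(f)
#' @export
read_gwas_panel <- function(path) {
  tab <- read_delim_auto(path)
  names(tab) <- tolower(names(tab))
  if ("or" %in% names(tab) && !"odds_ratio" %in% names(tab)) {
    names(tab)[names(tab) == "or"] <- "odds_ratio"
  }
  required <- c("variant_id", "chrom", "pos", "risk_allele",
                "other_allele", "odds_ratio")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("GWAS summary table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, required]
  tab$variant_id <- as.character(tab$variant_id)
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  tab$risk_allele <- toupper(as.character(tab$risk_allele))
  tab$other_allele <- toupper(as.character(tab$other_allele))
  or <- suppressWarnings(as.numeric(tab$odds_ratio))
  bad <- which(is.na(or) | or <= 0)
  if (length(bad) > 0) {
    stop("odds_ratio must be a positive real; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  same <- which(tab$risk_allele == tab$other_allele)
  if (length(same) > 0) {
    stop("risk_allele equals other_allele in row(s): ",
         paste(same, collapse = ", "), call. = FALSE)
  }
  tab$odds_ratio <- or
  rownames(tab) <- NULL
  tab
}

# Sniff comma vs whitespace delimiter from the header line.
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl(",", header, fixed = TRUE)) "," else ""
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, comment.char = "#",
                    blank.lines.skip = TRUE, check.names = TRUE)
}

#' Read a genotype matrix from VCF or dosage-table text
#'
#' Reads genotypes for a set of individuals at a set of variants into a
#' `famprs_genotypes` container: a dosage matrix (individuals x variants,
#' values in \[0, 2\], `NA` for missing) plus the allele pair each dosage
#' counts. Dosages count the *counted allele* (`a1`); `a2` is the other
#' observed allele. For VCF input the counted allele is ALT, so `a1 = ALT`,
#' `a2 = REF`; hard genotypes come from GT (`./.` becomes `NA`) and
#' fractional dosages from DS when GT is absent.
#'
#' Missing genotypes are carried as `NA`, never silently as 0; the scoring
#' step decides the missingness policy.
#'
#' @param path Path to a `.vcf` file, or to a whitespace/comma-delimited
#'   dosage table with columns `variant_id`, `chrom`, `pos`, `a1`, `a2`
#'   followed by one column per sample (dosage of `a1`; `NA` or `.` for
#'   missing).
#' @param format `"auto"` (default, by file extension), `"vcf"` or
#'   `"dosage"`.
#' @return An object of class `famprs_genotypes`: a list with `sample_ids`,
#'   `variants` (data.frame: `variant_id`, `chrom`, `pos`, `a1`, `a2`) and
#'   `dosage` (numeric matrix, samples x variants).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "dosage"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path)
}

read_genotypes_dosage <- function(path) {
  tab <- read_delim_auto(path)
  meta_cols <- c("variant_id", "chrom", "pos", "a1", "a2")
  if (!all(meta_cols %in% names(tab))) {
    stop("dosage table must have columns ", paste(meta_cols, collapse = ", "),
         call. = FALSE)
  }
  sample_ids <- setdiff(names(tab), meta_cols)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs", call. = FALSE)
  if (anyDuplicated(tab$variant_id)) stop("duplicate variant IDs", call. = FALSE)
  dos <- t(as.matrix(tab[, sample_ids, drop = FALSE]))
  mode(dos) <- "numeric"
  colnames(dos) <- tab$variant_id
  rownames(dos) <- sample_ids
  check_dosage_range(dos)
  new_genotypes(sample_ids,
                data.frame(variant_id = as.character(tab$variant_id),
                           chrom = as.character(tab$chrom),
                           pos = as.integer(tab$pos),
                           a1 = toupper(as.character(tab$a1)),
                           a2 = toupper(as.character(tab$a2)),
                           stringsAsFactors = FALSE),
                dos)
}

# VCF reading goes through vcfR; GT gives hard ALT counts, DS (when
# present) refines them to fractional dosages.
read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ids <- as.character(fix[, "ID"])
  if (anyDuplicated(ids)) stop("duplicate variant IDs", call. = FALSE)
  sample_ids <- colnames(vcf@gt)[-1]
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs", call. = FALSE)
  fmt_keys <- strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)
  has_gt <- any(vapply(fmt_keys, function(k) "GT" %in% k, TRUE))
  has_ds <- any(vapply(fmt_keys, function(k) "DS" %in% k, TRUE))
  if (!has_gt && !has_ds) stop("VCF has neither GT nor DS", call. = FALSE)
  dos <- matrix(NA_real_, nrow = length(sample_ids), ncol = length(ids),
                dimnames = list(sample_ids, ids))
  if (has_gt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    alt_count <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
    called <- !is.na(gt) & !grepl("\\.", gt)
    alt_count[called] <- vapply(strsplit(gt[called], "[/|]"),
                                function(a) sum(a == "1"), 0L)
    dos <- t(alt_count)
    dimnames(dos) <- list(sample_ids, ids)
  }
  if (has_ds) {
    ds <- t(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE))
    dos[!is.na(ds)] <- ds[!is.na(ds)]
  }
  check_dosage_range(dos)
  new_genotypes(sample_ids,
                data.frame(variant_id = ids,
                           chrom = as.character(fix[, "CHROM"]),
                           pos = as.integer(fix[, "POS"]),
                           a1 = toupper(as.character(fix[, "ALT"])),
                           a2 = toupper(as.character(fix[, "REF"])),
                           stringsAsFactors = FALSE),
                dos)
}

new_genotypes <- function(sample_ids, variants, dosage) {
  structure(list(sample_ids = sample_ids, variants = variants,
                 dosage = dosage),
            class = "famprs_genotypes")
}

check_dosage_range <- function(dos) {
  ok <- is.na(dos) | (dos >= 0 & dos <= 2)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("dosage outside [0, 2] at sample ", rownames(dos)[bad[1]],
         ", variant ", colnames(dos)[bad[2]], call. = FALSE)
  }
  invisible(TRUE)
}

#' @exportS3Method base::print
print.famprs_genotypes <- function(x, ...) {
  cat("famprs_genotypes:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants;",
      sum(is.na(x$dosage)), "missing entries\n")
  invisible(x)
}

#' Write genotypes as a sites+samples VCF
#'
#' Writes a `famprs_genotypes` container to a minimal VCF 4.2 text file.
#' Integral dosages are written as GT (`0/0`, `0/1`, `1/1`, missing `./.`),
#' fractional dosages as DS, with `a1` as ALT.
#'
#' @param geno A `famprs_genotypes` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "famprs_genotypes"))
  v <- geno$variants
  dos <- geno$dosage
  integral <- all(is.na(dos) | dos == round(dos))
  fmt <- if (integral) "GT" else "DS"
  enc <- function(col) {
    if (integral) {
      out <- c("0/0", "0/1", "1/1")[col + 1L]
      out[is.na(col)] <- "./."
    } else {
      out <- formatC(col, format = "g", digits = 8)
      out[is.na(col)] <- "."
    }
    out
  }
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$a2[i], v$a1[i],
            ".", "PASS", ".", fmt, enc(dos[, i])), collapse = "\t")
  }, "")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$sample_ids), collapse = "\t")),
             path)
  cat(paste(rows, collapse = "\n"), "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' Read a pedigree file
#'
#' Reads a PED-style whitespace (or comma) delimited file describing family
#' structure. Columns: `family_id`, `individual_id`, `father_id`,
#' `mother_id`, `sex`, `affection` and optionally `mz_group`. Founders have
#' father and mother coded `0` (or `.`/empty). Sex codes: `1`/`M` male,
#' `2`/`F` female, `0`/`U` unknown. Affection codes: `2`/`affected`,
#' `1`/`unaffected`, `0`/`unknown`. Individuals sharing a non-missing
#' `mz_group` label are monozygotic co-twins.
#'
#' Validation enforced: parents are either both present or both missing;
#' every named parent exists as a row; the pedigree is acyclic; MZ co-twins
#' share both parents and sex.
#'
#' @param path Path to the pedigree file. A header row is detected
#'   automatically (by a non-numeric token in the sex column position).
#' @return A data.frame of validated pedigree records with columns
#'   `family_id`, `individual_id`, `father_id`, `mother_id` (`NA` for
#'   founders), `sex` (`"male"`, `"female"`, `"unknown"`), `affection`
#'   (`"affected"`, `"unaffected"`, `"unknown"`), `mz_group` (`NA` if none).
#' @export
read_pedigree <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw)) & !grepl("^#", raw)]
  if (length(raw) == 0) stop("empty pedigree file", call. = FALSE)
  split1 <- strsplit(trimws(raw[1]), "[,[:space:]]+")[[1]]
  has_header <- any(tolower(split1) %in%
                      c("family_id", "individual_id", "fid", "iid"))
  rows <- strsplit(trimws(raw), "[,[:space:]]+")
  if (has_header) rows <- rows[-1]
  n_col <- lengths(rows)
  if (any(n_col < 6)) stop("pedigree rows need >= 6 columns", call. = FALSE)
  get <- function(i) vapply(rows, function(r) r[i], "")
  ped <- data.frame(
    family_id = get(1), individual_id = get(2),
    father_id = get(3), mother_id = get(4),
    sex = decode_sex(get(5)), affection = decode_affection(get(6)),
    mz_group = if (max(n_col) >= 7)
      vapply(rows, function(r) if (length(r) >= 7) r[7] else "0", "")
      else "0",
    stringsAsFactors = FALSE)
  miss_codes <- c("0", ".", "", "NA")
  ped$father_id[ped$father_id %in% miss_codes] <- NA
  ped$mother_id[ped$mother_id %in% miss_codes] <- NA
  ped$mz_group[ped$mz_group %in% miss_codes] <- NA
  validate_pedigree(ped)
}

decode_sex <- function(x) {
  x <- tolower(x)
  out <- rep("unknown", length(x))
  out[x %in% c("1", "m", "male")] <- "male"
  out[x %in% c("2", "f", "female")] <- "female"
  out
}

decode_affection <- function(x) {
  x <- tolower(x)
  out <- rep("unknown", length(x))
  out[x %in% c("2", "affected", "case", "+")] <- "affected"
  out[x %in% c("1", "unaffected", "control", "-")] <- "unaffected"
  out
}

#' Validate pedigree records
#'
#' Applies the structural checks documented in [read_pedigree()] to an
#' in-memory pedigree data.frame (as built by the simulator or by hand).
#'
#' @param ped A data.frame with the columns of [read_pedigree()]'s result.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_pedigree <- function(ped) {
  needed <- c("family_id", "individual_id", "father_id", "mother_id",
              "sex", "affection")
  stopifnot(all(needed %in% names(ped)))
  if (!"mz_group" %in% names(ped)) ped$mz_group <- NA_character_
  if (anyDuplicated(ped$individual_id)) {
    stop("duplicate individual_id: ",
         ped$individual_id[duplicated(ped$individual_id)][1], call. = FALSE)
  }
  one_parent <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(one_parent)) {
    stop("individual ", ped$individual_id[one_parent][1],
         " has exactly one parent; parents must be both present or both absent",
         call. = FALSE)
  }
  known <- ped$individual_id
  for (col in c("father_id", "mother_id")) {
    bad <- !is.na(ped[[col]]) & !(ped[[col]] %in% known)
    if (any(bad)) {
      stop("unknown parent ID '", ped[[col]][bad][1], "' for individual ",
           ped$individual_id[bad][1], call. = FALSE)
    }
  }
  # cycle check via iterative ancestor-peeling (topological sort)
  ord <- pedigree_order(ped, error_on_cycle = TRUE)
  # MZ group checks: same parents, same sex
  mzg <- ped$mz_group[!is.na(ped$mz_group)]
  for (g in unique(mzg)) {
    idx <- which(!is.na(ped$mz_group) & ped$mz_group == g)
    if (length(idx) < 2) next
    if (length(unique(ped$sex[idx])) > 1) {
      stop("MZ group '", g, "' mixes sexes", call. = FALSE)
    }
    same_parents <- length(unique(paste(ped$father_id[idx],
                                        ped$mother_id[idx]))) == 1
    if (!same_parents) {
      stop("MZ group '", g, "' members do not share both parents",
           call. = FALSE)
    }
  }
  ped[ord, , drop = FALSE]
}

# Topological order (founders first). Errors on cycles, naming a member.
pedigree_order <- function(ped, error_on_cycle = TRUE) {
  ids <- ped$individual_id
  placed <- rep(FALSE, nrow(ped))
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(ped$father_id) | ped$father_id %in% ids[placed]) &
      (is.na(ped$mother_id) | ped$mother_id %in% ids[placed])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    if (error_on_cycle) {
      stop("pedigree cycle involving individual ", ids[!placed][1],
           call. = FALSE)
    }
  }
  ord
}

#' Write / read a score table as CSV
#'
#' A score table holds one row per individual with the weighted polygenic
#' risk score and group label; it is the exchange format between scoring and
#' every downstream comparison.
#'
#' @param scores A data.frame with columns `family_id`, `individual_id`,
#'   `group`, `wprs` and optionally `n_variants_used`.
#' @param path Output (input) CSV path.
#' @return `write_score_table`: `path` invisibly. `read_score_table`: the
#'   data.frame, with `wprs` numeric at full precision.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(all(c("individual_id", "group", "wprs") %in% names(scores)))
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual_id", "group", "wprs") %in% names(tab)))
  tab$wprs <- as.numeric(tab$wprs)
  tab
}

#' Bundled per-individual familial wPRS fixture
#'
#' Returns the published per-individual weighted polygenic risk scores for
#' the three multicase multiple-sclerosis families (9 affected, 10
#' unaffected relatives), together with each individual's HLA-DRB1*15:01
#' risk-allele carrier status. This small table is bundled so the family
#' reporting and summary machinery can be exercised against published
#' numbers without any genotype data.
#'
#' @return A data.frame (score table) with columns `family_id`,
#'   `individual_id`, `group` (`"familial_case"` or
#'   `"unaffected_relative"`), `wprs`, `hla_drb1_1501` (`"+/+"`, `"+/-"`,
#'   `"-/-"`).
#' @examples
#' tab <- load_table2_fixture()
#' table(tab$group)
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "family_wprs_published.csv",
                      package = "famprs", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(family_id = "character"))
  tab$group <- ifelse(tab$affected == 1, "familial_case",
                      "unaffected_relative")
  tab[, c("family_id", "individual_id", "group", "wprs", "hla_drb1_1501")]
}

#' Bundled three-family pedigree
#'
#' Loads the bundled pedigree for the three multicase families scored in
#' [load_table2_fixture()]. The first family's structure (two ungenotyped
#' parents with seven genotyped offspring) follows the published pedigree
#' diagram; the internal structure of the other two families and all sexes
#' are a synthetic reconstruction consistent with the published member
#' counts, affection statuses and the monozygotic twin pair, suitable for
#' demonstrating kinship-aware analyses on the fixture scores.
#'
#' @return A validated pedigree data.frame (see [read_pedigree()]).
#' @export
load_family_pedigree <- function() {
  read_pedigree(system.file("extdata", "family_pedigree_synthetic.ped",
                            package = "famprs", mustWork = TRUE))
}
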
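#' Pedigree kinship matrix
#'
#' Computes the kinship coefficient phi(i, j) — the probability that one
#' allele sampled from i and one from j are identical by descent — for all
#' pairs in a pedigree, by the standard recursion processed in
#' founders-first order: phi(i, i) = (1 + phi(father_i, mother_i)) / 2,
#' phi(i, j) = (phi(father_i, j) + phi(mother_i, j)) / 2 for j already
#' processed, founders mutually unrelated. Monozygotic co-twins are
#' genetically identical: phi(twin_a, twin_b) = phi(a, a), applied before
#' any descendant of the twins is processed so it propagates correctly.
#'
#' @param ped A validated pedigree data.frame (see [read_pedigree()]).
#' @return Symmetric numeric matrix of kinship coefficients with
#'   individual IDs as dimnames. Diagonal is 0.5 for non-inbred
#'   individuals.
#' @export
kinship_matrix <- function(ped) {
  ped <- validate_pedigree(ped)   # also topologically sorts
  n <- nrow(ped)
  ids <- ped$individual_id
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      K[i, i] <- 0.5
    } else {
      K[i, i] <- 0.5 * (1 + K[fa[i], mo[i]])
      if (i > 1) {
        j <- seq_len(i - 1)
        K[i, j] <- K[j, i] <- 0.5 * (K[fa[i], j] + K[mo[i], j])
      }
    }
    # MZ adjustment: if an earlier-processed co-twin exists, identity
    if (!is.na(ped$mz_group[i])) {
      tw <- which(!is.na(ped$mz_group[seq_len(i - 1)]) &
                    ped$mz_group[seq_len(i - 1)] == ped$mz_group[i])
      for (t in tw) K[i, t] <- K[t, i] <- K[i, i]
    }
  }
  K
}

#' Kinship coefficient between two pedigree members
#'
#' @param ped A pedigree data.frame.
#' @param id_a,id_b Individual IDs (may be equal).
#' @return The kinship coefficient phi(id_a, id_b).
#' @examples
#' ped <- data.frame(family_id = "f", individual_id = c("p", "m", "c"),
#'                   father_id = c(NA, NA, "p"), mother_id = c(NA, NA, "m"),
#'                   sex = c("male", "female", "male"),
#'                   affection = "unknown", mz_group = NA)
#' kinship_coefficient(ped, "p", "c")  # 0.25
#' @export
kinship_coefficient <- function(ped, id_a, id_b) {
  K <- kinship_matrix(ped)
  if (!id_a %in% rownames(K)) stop("unknown id: ", id_a, call. = FALSE)
  if (!id_b %in% rownames(K)) stop("unknown id: ", id_b, call. = FALSE)
  K[id_a, id_b]
}

#' Relationship (expected genetic covariance) matrix
#'
#' Twice the kinship matrix: diagonal 1 for non-inbred individuals,
#' parent-offspring and full siblings 0.5, MZ co-twins 1. This is the
#' correlation structure of the additive genetic random effect in the
#' polygenic mixed model.
#'
#' @param ped A pedigree data.frame, or `NULL` with `ids` to build an
#'   identity block (unrelated individuals).
#' @param ids Optional individual IDs to select/order (defaults to all
#'   pedigree members).
#' @return Symmetric PSD matrix with IDs as dimnames.
#' @export
relationship_matrix <- function(ped = NULL, ids = NULL) {
  if (is.null(ped)) {
    stopifnot(!is.null(ids))
    return(diag(1, length(ids)) |> `dimnames<-`(list(ids, ids)))
  }
  phi2 <- 2 * kinship_matrix(ped)
  if (!is.null(ids)) {
    missing <- setdiff(ids, rownames(phi2))
    if (length(missing) > 0) stop("ids not in pedigree: ",
                                  paste(missing, collapse = ", "),
                                  call. = FALSE)
    phi2 <- phi2[ids, ids, drop = FALSE]
  }
  phi2
}

#' Rank-based inverse normal transform
#'
#' Maps values to standard normal quantiles by rank, the usual device to
#' enforce normality of a quantitative trait before variance-component
#' modelling: value at rank r maps to qnorm((r - c) / (n - 2c + 1)) with
#' the Blom offset c = 3/8; ties share their average rank.
#'
#' @param values Numeric vector, n >= 2, not all equal.
#' @param offset Rank offset c (default Blom, 3/8).
#' @return Numeric vector of transformed values.
#' @export
inverse_normalise <- function(values, offset = 3 / 8) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need n >= 2", call. = FALSE)
  if (length(unique(values)) == 1) {
    stop("constant vector: ranks degenerate", call. = FALSE)
  }
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (length(values) - 2 * offset + 1))
}

#' Fit the polygenic linear mixed model
#'
#' Fits y = X beta + g + e with cov(g) = sigma2_g * Phi2 (Phi2 the
#' relationship matrix) and cov(e) = sigma2_e * I, by maximum likelihood.
#' The relationship matrix is eigendecomposed once; on the rotated data the
#' covariance is diagonal in the heritability ratio h2 =
#' sigma2_g / (sigma2_g + sigma2_e), so the likelihood is profiled over
#' h2 in \[0, 1) by one-dimensional optimisation with generalised
#' least-squares fits inside.
#'
#' When `test` names a column of the design, the model is refitted without
#' it and the fixed effect is tested by likelihood ratio against chi-square
#' with 1 df (a Wald test from the profiled information is also reported).
#'
#' @param y Numeric response vector.
#' @param covariates Design matrix X (an intercept column is added if no
#'   constant column is present). A data.frame is converted via
#'   [stats::model.matrix()].
#' @param phi2 Relationship matrix (see [relationship_matrix()]), PSD,
#'   dimension matching `y`.
#' @param test Optional column name of the design to test (e.g.
#'   `"group"`).
#' @return List of class `famprs_polygenic_fit`: `beta`, `se`, `sigma2_g`,
#'   `sigma2_e`, `h2`, `loglik`, and when `test` is given `lrt_chisq`,
#'   `lrt_p`, `wald_z`, `wald_p`.
#' @export
fit_polygenic_model <- function(y, covariates, phi2, test = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  X <- build_design(covariates, n)
  stopifnot(nrow(phi2) == n, ncol(phi2) == n)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix", call. = FALSE)
  eig <- eigen(phi2, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    stop("relationship matrix is not positive semidefinite (min eigenvalue ",
         format(min(eig$values)), ")", call. = FALSE)
  }
  d <- pmax(eig$values, 0)
  ty <- crossprod(eig$vectors, y)
  tX <- crossprod(eig$vectors, X)
  full <- profile_ml(ty, tX, d)
  fit <- structure(
    list(beta = full$beta, se = full$se, sigma2_g = full$h2 * full$s2,
         sigma2_e = (1 - full$h2) * full$s2, h2 = full$h2,
         loglik = full$loglik),
    class = "famprs_polygenic_fit")
  if (!is.null(test)) {
    if (!test %in% colnames(X)) stop("test column '", test,
                                     "' not in design", call. = FALSE)
    null_fit <- profile_ml(ty, tX[, colnames(X) != test, drop = FALSE], d)
    fit$lrt_chisq <- max(0, 2 * (full$loglik - null_fit$loglik))
    fit$lrt_p <- stats::pchisq(fit$lrt_chisq, df = 1, lower.tail = FALSE)
    fit$wald_z <- full$beta[test] / full$se[test]
    fit$wald_p <- 2 * stats::pnorm(-abs(fit$wald_z))
    fit$tested <- test
  }
  fit
}

build_design <- function(covariates, n) {
  if (is.null(covariates)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  if (is.data.frame(covariates)) {
    X <- stats::model.matrix(~ ., data = covariates)
  } else {
    X <- as.matrix(covariates)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    has_const <- any(apply(X, 2, function(c) all(c == c[1])))
    if (!has_const) X <- cbind(`(Intercept)` = 1, X)
  }
  stopifnot(nrow(X) == n)
  X
}

# ML of the rotated model: var(ty_i) = s2 * (h2 * d_i + 1 - h2).
# Profile over h2 with closed-form GLS beta and s2 at each h2.
profile_ml <- function(ty, tX, d) {
  n <- length(ty)
  eval_h2 <- function(h2) {
    w <- h2 * d + (1 - h2)          # relative variances, > 0 for h2 < 1
    sw <- sqrt(w)
    Xw <- tX / sw
    yw <- ty / sw
    qrw <- qr(Xw)
    beta <- qr.coef(qrw, yw)
    rss <- sum(qr.resid(qrw, yw)^2)
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
    list(ll = ll, beta = beta, s2 = s2, w = w, qrw = qrw)
  }
  opt <- stats::optimize(function(h2) -eval_h2(h2)$ll,
                         interval = c(0, 1 - 1e-6), tol = 1e-8)
  # compare against the h2 = 0 boundary explicitly
  at0 <- eval_h2(0)
  h2 <- if (at0$ll >= -opt$objective) 0 else opt$minimum
  best <- eval_h2(h2)
  XtVX <- crossprod(qr.R(best$qrw))
  se <- sqrt(diag(chol2inv(chol(XtVX))) * best$s2)
  names(se) <- colnames(tX)
  beta <- best$beta
  names(beta) <- colnames(tX)
  list(beta = beta, se = se, s2 = best$s2, h2 = h2, loglik = best$ll)
}

#' @exportS3Method base::print
print.famprs_polygenic_fit <- function(x, ...) {
  cat("Polygenic mixed model (ML):\n")
  coefs <- data.frame(beta = x$beta, se = x$se)
  print(round(coefs, 4))
  cat(sprintf("  sigma2_g = %.4f, sigma2_e = %.4f, h2 = %.3f, loglik = %.3f\n",
              x$sigma2_g, x$sigma2_e, x$h2, x$loglik))
  if (!is.null(x$lrt_p)) {
    cat(sprintf("  %s: LRT chisq = %.3f, p = %s; Wald z = %.3f, p = %s\n",
                x$tested, x$lrt_chisq, format_pvalue(x$lrt_p),
                x$wald_z, format_pvalue(x$wald_p)))
  }
  invisible(x)
}

#' Kinship-aware test of a wPRS difference between a familial group and a
#' population group
#'
#' Pools the two groups, applies the rank-based inverse normal transform to
#' the combined wPRS (so the group effect is expressed in SD units of the
#' transformed trait), builds a block-diagonal relationship matrix — the
#' familial block from the pedigree, the population block an identity
#' (unrelated) — and fits the polygenic mixed model with the group
#' indicator (1 = group A) and optionally sex as fixed effects. The group
#' effect is tested by likelihood ratio (Wald also reported).
#'
#' @param scores_a Named numeric vector of group-A (familial) wPRS; names
#'   are pedigree individual IDs.
#' @param scores_b Numeric vector of group-B (population) wPRS; if named,
#'   names must not overlap group A.
#' @param pedigree_a Pedigree data.frame covering the group-A individuals
#'   (extra members are allowed and ignored), or `NULL` to treat group A as
#'   unrelated.
#' @param sex Optional character/factor vector of sexes aligned to
#'   `c(scores_a, scores_b)`, used as a covariate.
#' @return A `famprs_polygenic_fit` (see [fit_polygenic_model()]) whose
#'   `beta["group"]` is the group-A minus group-B difference in SD units.
#' @export
test_group_difference <- function(scores_a, scores_b, pedigree_a = NULL,
                                  sex = NULL) {
  ids_a <- names(scores_a)
  ids_b <- names(scores_b)
  if (!is.null(ids_a) && !is.null(ids_b) &&
      length(intersect(ids_a, ids_b)) > 0) {
    stop("individual IDs overlap between groups: ",
         paste(utils::head(intersect(ids_a, ids_b), 3), collapse = ", "),
         call. = FALSE)
  }
  n_a <- length(scores_a); n_b <- length(scores_b)
  y <- inverse_normalise(c(scores_a, scores_b))
  if (!is.null(pedigree_a)) {
    if (is.null(ids_a)) stop("scores_a must be named with pedigree IDs",
                             call. = FALSE)
    block_a <- relationship_matrix(pedigree_a, ids = ids_a)
  } else {
    block_a <- diag(1, n_a)
  }
  phi2 <- diag(1, n_a + n_b)
  phi2[seq_len(n_a), seq_len(n_a)] <- block_a
  covs <- data.frame(group = rep(c(1, 0), c(n_a, n_b)))
  if (!is.null(sex)) {
    stopifnot(length(sex) == n_a + n_b)
    if (length(unique(sex)) > 1) covs$sex <- factor(sex)
  }
  fit <- fit_polygenic_model(y, covs, phi2, test = "group")
  fit$n_a <- n_a
  fit$n_b <- n_b
  fit
}
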
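#' Rank-based inverse normal transformation
#'
#' Orders the values and maps them to expected normal quantiles:
#' qnorm((rank - c) / (n - 2c + 1)) with the Blom offset c = 3/8 by default.
#' Ties receive average ranks, so the transform is deterministic and
#' invariant to any monotone transformation of the input.
#'
#' @param values numeric vector (n >= 3, finite).
#' @param offset rank offset c (default 3/8).
#' @return transformed vector with mean approximately 0 and sd approximately 1.
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  if (length(values) < 3) tl_stop("need at least 3 values", "transloci_config")
  if (any(!is.finite(values))) tl_stop("values must be finite", "transloci_validation")
  if (length(unique(values)) == 1L) {
    tl_stop("all values identical: ranks are undefined", "transloci_degenerate")
  }
  n <- length(values)
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Friedewald derivation of LDL cholesterol
#'
#' LDL = TC - HDL - TG/5 in mg/dL, or TC - HDL - TG/2.2 in mmol/L. The
#' formula is invalid at high triglycerides (>= 400 mg/dL or 4.52 mmol/L);
#' such values are returned as NA.
#'
#' @param total_chol,hdl,tg biomarker vectors (same units, >= 0).
#' @param units "mg_dl" or "mmol_l"; never guessed from magnitudes.
#' @return LDL vector, NA where the formula is invalid.
#' @export
friedewald_ldl <- function(total_chol, hdl, tg, units = c("mg_dl", "mmol_l")) {
  units <- match.arg(units)
  if (any(c(total_chol, hdl, tg) < 0, na.rm = TRUE)) {
    tl_stop("lipid measurements must be non-negative", "transloci_validation")
  }
  divisor <- if (units == "mg_dl") 5 else 2.2
  limit <- if (units == "mg_dl") 400 else 4.52
  ldl <- total_chol - hdl - tg / divisor
  ldl[!is.na(tg) & tg >= limit] <- NA_real_
  ldl
}

#' Residualize a trait on covariates
#'
#' Regresses y on the covariate matrix (an intercept is always added) and
#' returns the residuals, which are orthogonal to every covariate column.
#'
#' @param y numeric outcome vector.
#' @param covariates numeric matrix or data.frame (may be NULL for
#'   intercept-only centering).
#' @return residual vector.
#' @export
residualize <- function(y, covariates = NULL) {
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("V", seq_len(ncol(covariates)))
    }
    X <- cbind(X, covariates)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    tl_stop(sprintf("covariates are rank deficient (collinear: %s)",
                    paste(drop, collapse = ", ")), "transloci_validation")
  }
  as.vector(qr.resid(qr_x, y))
}

#' Prepare a phenotype for association scanning
#'
#' Residualizes on covariates, applies the rank-based inverse normal
#' transformation (optional) and standardizes to mean 0, sd 1.
#'
#' @param y raw trait vector.
#' @param covariates optional covariate matrix.
#' @param transform "int_blom" (default) or "none".
#' @return numeric vector of class `prepared_phenotype` with attributes
#'   `transform` and `covariates_removed`.
#' @export
prepare_phenotype <- function(y, covariates = NULL,
                              transform = c("int_blom", "none")) {
  transform <- match.arg(transform)
  res <- residualize(y, covariates)
  out <- if (transform == "int_blom") inverse_normal_transform(res) else res
  out <- (out - mean(out)) / stats::sd(out)
  structure(out, transform = transform,
            covariates_removed = colnames(covariates),
            class = c("prepared_phenotype", class(out)))
}

#' Per-variant score-test association scan
#'
#' For each variant, the score statistic is z = r * sqrt(n) where r is the
#' sample correlation between dosage and the (standardized) trait; the
#' two-sided p-value comes from the normal tail. beta and se are the
#' univariate OLS slope of the standardized trait on dosage and its standard
#' error. The scan is a single matrix product over variants, which is what
#' makes permutation re-scans cheap.
#'
#' @param panel a `genotype_panel` with samples aligned to `y`.
#' @param y standardized phenotype vector (see [prepare_phenotype()]).
#' @return a `summary_stats` data.frame (zero-variance variants are excluded
#'   with a warning).
#' @export
score_test_scan <- function(panel, y) {
  X <- panel$dosages
  n <- nrow(X)
  if (length(y) != n) tl_stop("phenotype length does not match panel", "transloci_validation")
  v <- matrixVar(X)
  if (any(v == 0)) {
    warning(sprintf("excluding %d zero-variance variant(s) from the scan", sum(v == 0)))
    X <- X[, v > 0, drop = FALSE]
  }
  keep <- v > 0
  ys <- (y - mean(y)) / stats::sd(y)
  xs <- standardize_columns(X)
  r <- as.vector(crossprod(xs, ys)) / (n - 1)
  z <- r * sqrt(n)
  p <- 2 * stats::pnorm(-abs(z))
  sx <- sqrt(v[keep])
  beta <- r / sx            # slope of standardized y on raw dosage
  se <- sqrt(pmax(1 - r^2, 1e-12) / (n - 2)) / sx
  out <- cbind(panel$variants[keep, , drop = FALSE],
               data.frame(effect_allele = panel$variants$alt[keep],
                          beta = beta, se = se, z = z, p = p,
                          eaf = colMeans(X) / 2, n = n,
                          info = NA_real_, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Pairwise LD matrix (Pearson correlation of dosages)
#'
#' @param panel a `genotype_panel`.
#' @param variant_ids optional subset of variant ids.
#' @return object of class `ld_matrix`: list with `r` (correlation matrix,
#'   dimnames = variant ids) and `ids`.
#' @export
ld_matrix <- function(panel, variant_ids = NULL) {
  if (!is.null(variant_ids)) panel <- subset_panel(panel, variant_ids)
  X <- panel$dosages
  if (nrow(X) < 2) tl_stop("need at least 2 samples for LD", "transloci_validation")
  if (any(matrixVar(X) == 0)) {
    tl_stop("monomorphic variant in LD subset; filter before calling ld_matrix",
            "transloci_degenerate")
  }
  r <- stats::cor(X)
  dimnames(r) <- list(panel$variants$id, panel$variants$id)
  structure(list(r = r, ids = panel$variants$id), class = "ld_matrix")
}

#' Ridge-regularized LD correlation matrix
#'
#' Adds `epsilon` to the diagonal and rescales back to unit diagonal, which
#' guarantees positive semi-definiteness before inversion-based uses.
#'
#' @param ld an `ld_matrix`.
#' @param epsilon ridge size (default 1e-6).
#' @return an `ld_matrix` with the regularized correlation matrix.
#' @export
regularize_ld <- function(ld, epsilon = 1e-6) {
  r <- (ld$r + diag(epsilon, nrow(ld$r))) / (1 + epsilon)
  structure(list(r = r, ids = ld$ids), class = "ld_matrix")
}
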
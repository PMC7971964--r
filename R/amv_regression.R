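#' Adjusted regression of one metabolite on one exposure in one cohort
#'
#' Ordinary least squares of the (pre-standardized, log-scale) metabolite
#' on the exposure adjusted for age, sex, and BMI — the observational arm
#' of the triangulation. Binary exposures are coded 1 for the index
#' category (usually-insomnia / evening preference / short or long
#' duration) and 0 for the reference; continuous sleep duration is in
#' hours, so the coefficient is per one hour. Rows with missing values in
#' any model variable are dropped (listwise deletion).
#'
#' @param table cohort data frame containing `exposure_col`,
#'   `metabolite_col`, and the adjustment columns.
#' @param metabolite_col name of the metabolite column.
#' @param exposure_col name of the exposure column.
#' @param cohort cohort label carried into the result.
#' @param covariates adjustment set; defaults to age, sex, BMI. Use
#'   `character(0)` for the unadjusted (crude) variant.
#' @return an object of class `cohort_assoc`: list with `cohort`,
#'   `exposure`, `metabolite`, `beta`, `se`, `n`.
#' @export
fit_cohort <- function(table, metabolite_col, exposure_col = "exposure",
                       cohort = "cohort",
                       covariates = c("age", "sex", "bmi")) {
  needed <- c(exposure_col, metabolite_col, covariates)
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0L) {
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dat <- table[, needed, drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  n_par <- length(needed) + 1L  # + intercept
  if (n < n_par + 1L) {
    stop("too few complete rows (", n, ") for ", n_par, " parameters",
         call. = FALSE)
  }
  if (var(dat[[exposure_col]]) == 0) {
    stop("no contrast: exposure '", exposure_col,
         "' is constant in cohort '", cohort, "'", call. = FALSE)
  }
  rhs <- paste(c(sprintf("`%s`", exposure_col),
                 sprintf("`%s`", covariates)), collapse = " + ")
  fml <- stats::as.formula(sprintf("`%s` ~ %s", metabolite_col, rhs))
  fit <- lm(fml, data = dat)
  cf <- summary(fit)$coefficients
  row <- sprintf("`%s`", exposure_col)
  if (!row %in% rownames(cf)) row <- exposure_col
  structure(list(cohort = cohort, exposure = exposure_col,
                 metabolite = metabolite_col,
                 beta = unname(cf[row, "Estimate"]),
                 se = unname(cf[row, "Std. Error"]),
                 n = n),
            class = "cohort_assoc")
}

#' @export
print.cohort_assoc <- function(x, ...) {
  cat(sprintf("<cohort_assoc> %s: %s ~ %s, beta = %.4g (SE %.4g), n = %d\n",
              x$cohort, x$metabolite, x$exposure, x$beta, x$se, x$n))
  invisible(x)
}

#' Meta-analyse one exposure-metabolite association across cohorts
#'
#' Pools per-cohort adjusted regression coefficients by fixed-effect
#' (headline) and, when at least two cohorts contribute, DerSimonian-Laird
#' random-effects meta-analysis.
#'
#' @param assocs list of `cohort_assoc` for the same exposure-metabolite
#'   pair.
#' @return list with elements `fixed` and `random` (`meta_estimate`s;
#'   `random` is `NULL` for a single cohort).
#' @export
meta_cohorts <- function(assocs) {
  stopifnot(length(assocs) >= 1L,
            all(vapply(assocs, inherits, TRUE, "cohort_assoc")))
  expo <- unique(vapply(assocs, `[[`, "", "exposure"))
  met <- unique(vapply(assocs, `[[`, "", "metabolite"))
  if (length(expo) != 1L || length(met) != 1L) {
    stop("all cohort associations must share one exposure and one metabolite",
         call. = FALSE)
  }
  theta <- vapply(assocs, `[[`, 0, "beta")
  se <- vapply(assocs, `[[`, 0, "se")
  list(fixed = fixed_effect_meta(theta, se),
       random = if (length(assocs) >= 2L) random_effect_meta(theta, se)
                else NULL)
}

#' Run the full observational arm over a metabolite panel
#'
#' Fits the adjusted per-cohort regression for every metabolite column and
#' pools across cohorts.
#'
#' @param cohorts list of cohort data frames (as from
#'   [simulate_amv_cohorts()] or read from disk).
#' @param metabolite_cols metabolite column names; defaults to every
#'   column starting with `"metabolite"`.
#' @param exposure_col exposure column name.
#' @param covariates adjustment set, see [fit_cohort()].
#' @return a data frame with one row per metabolite: pooled fixed- and
#'   random-effects estimates, standard errors, p-values, and
#'   heterogeneity; the per-cohort fits are attached as attribute
#'   `"cohort_assocs"`.
#' @export
run_amv <- function(cohorts, metabolite_cols = NULL,
                    exposure_col = "exposure",
                    covariates = c("age", "sex", "bmi")) {
  stopifnot(length(cohorts) >= 1L)
  if (is.null(names(cohorts))) {
    names(cohorts) <- sprintf("cohort_%02d", seq_along(cohorts))
  }
  if (is.null(metabolite_cols)) {
    metabolite_cols <- grep("^metabolite", names(cohorts[[1L]]),
                            value = TRUE)
  }
  all_assocs <- list()
  rows <- lapply(metabolite_cols, function(m) {
    assocs <- lapply(names(cohorts), function(k) {
      fit_cohort(cohorts[[k]], m, exposure_col = exposure_col, cohort = k,
                 covariates = covariates)
    })
    all_assocs[[m]] <<- assocs
    pooled <- meta_cohorts(assocs)
    f <- pooled$fixed
    r <- pooled$random
    data.frame(metabolite = m, k = f$k,
               theta_fixed = f$pooled_theta, se_fixed = f$se,
               pval_fixed = f$pval, het_q = f$het_q,
               het_q_pval = f$het_q_pval,
               theta_random = if (is.null(r)) f$pooled_theta else r$pooled_theta,
               se_random = if (is.null(r)) f$se else r$se,
               pval_random = if (is.null(r)) f$pval else r$pval,
               tau2 = if (is.null(r)) 0 else r$tau2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cohort_assocs") <- all_assocs
  out
}
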
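.meta_estimate <- function(model, pooled, se, k, q, tau2 = NA_real_) {
  p <- 2 * pnorm(-abs(pooled / se))
  structure(list(pooled_theta = pooled, se = se,
                 ci_low = pooled - .Z95 * se, ci_high = pooled + .Z95 * se,
                 pval = p, model = model, het_q = q,
                 het_q_pval = if (k >= 2L)
                   pchisq(q, df = k - 1, lower.tail = FALSE) else NA_real_,
                 tau2 = tau2, k = as.integer(k)),
            class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("<meta_estimate> %s: theta = %.4g (SE %.4g, 95%% CI %.4g to %.4g), p = %.3g, k = %d\n",
              x$model, x$pooled_theta, x$se, x$ci_low, x$ci_high, x$pval,
              x$k))
  cat(sprintf("  Q = %.4g (p = %.3g)%s\n", x$het_q, x$het_q_pval,
              if (!is.na(x$tau2)) sprintf(", tau2 = %.4g", x$tau2) else ""))
  invisible(x)
}

.meta_check <- function(theta, se, min_k) {
  stopifnot(length(theta) == length(se))
  if (length(theta) < min_k) {
    stop("meta-analysis requires at least ", min_k, " estimate(s)",
         call. = FALSE)
  }
  if (any(is.na(theta)) || any(is.na(se)) || any(se <= 0)) {
    stop("estimates must be non-missing with positive standard errors",
         call. = FALSE)
  }
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools estimates with weights `1/se^2`: the pooled effect is the
#' weighted mean, its standard error `1/sqrt(sum(w))`, and heterogeneity is
#' summarized by Cochran's Q with a chi-square (k-1) p-value. Used to pool
#' per-dataset MR estimates across metabolite GWAS sources, and as the
#' headline pooling of per-cohort regression estimates.
#'
#' @param theta,se numeric vectors of per-unit estimates and standard
#'   errors (alternatively pass a 2-column data frame as `theta`).
#' @return a `meta_estimate` with model `"fixed"`.
#' @export
fixed_effect_meta <- function(theta, se = NULL) {
  if (is.null(se)) { se <- theta[[2L]]; theta <- theta[[1L]] }
  .meta_check(theta, se, 1L)
  w <- 1 / se^2
  pooled <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - pooled)^2)
  .meta_estimate("fixed", pooled, 1 / sqrt(sum(w)), length(theta), q)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Estimates the between-unit variance by the method of moments:
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights, then re-pools with weights `1/(se^2 + tau2)`.
#' When the inputs are homogeneous (Q at or below its expectation) the
#' result collapses to the fixed-effect answer.
#'
#' @param theta,se as in [fixed_effect_meta()]; at least two estimates.
#' @return a `meta_estimate` with model `"random_dl"` carrying `tau2`.
#' @export
random_effect_meta <- function(theta, se = NULL) {
  if (is.null(se)) { se <- theta[[2L]]; theta <- theta[[1L]] }
  .meta_check(theta, se, 2L)
  k <- length(theta)
  w <- 1 / se^2
  pooled_f <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - pooled_f)^2)
  c_denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (k - 1)) / c_denom)
  w_star <- 1 / (se^2 + tau2)
  pooled <- sum(w_star * theta) / sum(w_star)
  .meta_estimate("random_dl", pooled, 1 / sqrt(sum(w_star)), k, q,
                 tau2 = tau2)
}

#' Pool per-dataset MR estimates of one method across outcome datasets
#'
#' Extracts `theta`/`se` from a list of `mr_estimate`s and pools them by
#' fixed-effect meta-analysis (per-dataset heterogeneity Q statistics are
#' reported on the individual estimates, not pooled).
#'
#' @param estimates list of `mr_estimate`s for the same
#'   exposure-outcome-method triple, one per dataset.
#' @return a `meta_estimate` with model `"fixed"`.
#' @export
meta_mr_datasets <- function(estimates) {
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, TRUE, "mr_estimate")))
  methods <- unique(vapply(estimates, `[[`, "", "method"))
  if (length(methods) != 1L) {
    stop("cannot pool across different MR methods: ",
         paste(methods, collapse = ", "), call. = FALSE)
  }
  fixed_effect_meta(vapply(estimates, `[[`, 0, "theta"),
                    vapply(estimates, `[[`, 0, "se"))
}
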
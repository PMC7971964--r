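.Z95 <- qnorm(0.975)

.mr_estimate <- function(method, theta, se, pval, n_snps,
                         ci_low = theta - .Z95 * se,
                         ci_high = theta + .Z95 * se,
                         q_stat = NA_real_, q_pval = NA_real_,
                         egger_intercept = NA_real_,
                         egger_intercept_se = NA_real_,
                         egger_intercept_pval = NA_real_) {
  structure(list(method = method, theta = theta, se = se,
                 ci_low = ci_low, ci_high = ci_high, pval = pval,
                 n_snps = as.integer(n_snps),
                 q_stat = q_stat, q_pval = q_pval,
                 egger_intercept = egger_intercept,
                 egger_intercept_se = egger_intercept_se,
                 egger_intercept_pval = egger_intercept_pval),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: theta = %.4g (SE %.4g, 95%% CI %.4g to %.4g), p = %.3g, %d SNP(s)\n",
              x$method, x$theta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  heterogeneity Q = %.4g (p = %.3g)\n", x$q_stat, x$q_pval))
  }
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  intercept = %.4g (SE %.4g, p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_pval))
  }
  invisible(x)
}

#' Convert MR estimates to a long-format data frame
#' @param estimates an `mr_estimate` or list of them.
#' @param ... further label columns prepended to the result (e.g.
#'   `exposure`, `outcome`, `dataset`).
#' @return a data frame, one row per estimate.
#' @export
mr_estimates_table <- function(estimates, ...) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  labels <- list(...)
  do.call(rbind, lapply(estimates, function(e) {
    row <- data.frame(method = e$method, theta = e$theta, se = e$se,
                      ci_low = e$ci_low, ci_high = e$ci_high,
                      pval = e$pval, n_snps = e$n_snps,
                      q_stat = e$q_stat, q_pval = e$q_pval,
                      egger_intercept = e$egger_intercept,
                      egger_intercept_se = e$egger_intercept_se,
                      egger_intercept_pval = e$egger_intercept_pval,
                      stringsAsFactors = FALSE)
    if (length(labels) > 0L) row <- cbind(as.data.frame(labels), row)
    row
  }))
}

.hset_rows <- function(hset) {
  if (inherits(hset, "harmonized_set")) hset$rows else as.data.frame(hset)
}

#' Single-SNP Wald ratio estimate
#'
#' The causal effect from one instrument: the SNP-outcome beta divided by
#' the SNP-exposure beta, with the first-order (delta-method) standard
#' error `se_out / |beta_exp|` and a normal confidence interval and
#' p-value.
#'
#' @param hset a `harmonized_set` with exactly one row, or any object
#'   coercible to a one-row data frame with `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`.
#' @return an `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(hset) {
  r <- .hset_rows(hset)
  if (nrow(r) != 1L) stop("wald_ratio expects exactly one SNP", call. = FALSE)
  if (r$beta_exp == 0) stop("beta_exp is zero; Wald ratio undefined",
                            call. = FALSE)
  theta <- r$beta_out / r$beta_exp
  se <- r$se_out / abs(r$beta_exp)
  p <- 2 * pnorm(-abs(theta / se))
  .mr_estimate("wald_ratio", theta, se, p, 1L)
}

#' Inverse-variance-weighted MR with multiplicative random effects
#'
#' The primary causal estimate: the weighted least-squares slope of the
#' SNP-outcome betas on the SNP-exposure betas through the origin with
#' weights `1/se_out^2` (equivalently, the inverse-variance-weighted mean
#' of the per-SNP Wald ratios under first-order weights). Between-SNP
#' heterogeneity is measured by Cochran's Q over the per-SNP ratios; the
#' fixed-effect standard error is inflated by `max(1, sqrt(Q/(J-1)))` —
#' the multiplicative random-effects correction, which never deflates.
#' The p-value uses a normal reference.
#'
#' @param hset a `harmonized_set` with at least two SNPs.
#' @return an `mr_estimate` with method `"ivw_mre"` carrying `q_stat` and
#'   `q_pval`.
#' @export
mr_ivw <- function(hset) {
  r <- .hset_rows(hset)
  J <- nrow(r)
  if (J < 2L) {
    stop("IVW requires at least 2 SNPs; use wald_ratio() for a single SNP",
         call. = FALSE)
  }
  w <- 1 / r$se_out^2
  sxx <- sum(w * r$beta_exp^2)
  theta <- sum(w * r$beta_exp * r$beta_out) / sxx
  se_fixed <- 1 / sqrt(sxx)
  q <- sum(w * (r$beta_out - theta * r$beta_exp)^2)
  phi <- max(1, sqrt(q / (J - 1)))
  se <- se_fixed * phi
  p <- 2 * pnorm(-abs(theta / se))
  .mr_estimate("ivw_mre", theta, se, p, J,
               q_stat = q, q_pval = pchisq(q, df = J - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' The same weighted regression as IVW but with a free intercept; a
#' non-zero intercept indicates directional horizontal pleiotropy and the
#' slope is a pleiotropy-corrected causal estimate. Rows are first
#' reoriented so every SNP-exposure beta is non-negative (the estimator's
#' orientation convention). Standard errors are inflated by
#' `max(1, sqrt(Q_egger/(J-2)))`; p-values for slope and intercept use the
#' t distribution with J-2 degrees of freedom.
#'
#' @param hset a `harmonized_set` with at least three SNPs.
#' @return an `mr_estimate` with method `"egger"` carrying the intercept
#'   diagnostics.
#' @export
mr_egger <- function(hset) {
  r <- .hset_rows(hset)
  J <- nrow(r)
  if (J < 3L) stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  flip <- r$beta_exp < 0
  r$beta_out[flip] <- -r$beta_out[flip]
  r$beta_exp[flip] <- -r$beta_exp[flip]
  if (var(r$beta_exp) == 0) {
    stop("all SNP-exposure betas identical; Egger slope unidentifiable",
         call. = FALSE)
  }
  w <- 1 / r$se_out^2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * r$beta_exp); swy <- sum(w * r$beta_out)
  swxx <- sum(w * r$beta_exp^2); swxy <- sum(w * r$beta_exp * r$beta_out)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- r$beta_out - intercept - slope * r$beta_exp
  q <- sum(w * resid^2)
  phi <- max(1, sqrt(q / (J - 2)))
  se_slope <- sqrt(sw / det) * phi
  se_int <- sqrt(swxx / det) * phi
  p_slope <- 2 * pt(-abs(slope / se_slope), df = J - 2)
  p_int <- 2 * pt(-abs(intercept / se_int), df = J - 2)
  tq <- qt(0.975, df = J - 2)
  .mr_estimate("egger", slope, se_slope, p_slope, J,
               ci_low = slope - tq * se_slope,
               ci_high = slope + tq * se_slope,
               q_stat = q,
               q_pval = pchisq(q, df = J - 2, lower.tail = FALSE),
               egger_intercept = intercept, egger_intercept_se = se_int,
               egger_intercept_pval = p_int)
}

# Weighted median of per-SNP ratios: sort ratios, form standardized
# cumulative-weight midpoints, interpolate at probability one half.
.weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  ratio <- ratio[o]; weight <- weight[o]
  csum <- cumsum(weight)
  pmid <- (csum - weight / 2) / csum[length(csum)]
  if (0.5 <= pmid[1L]) return(ratio[1L])
  if (0.5 >= pmid[length(pmid)]) return(ratio[length(ratio)])
  approx(pmid, ratio, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' The weighted median of the per-SNP Wald ratios under first-order
#' inverse-variance weights `beta_exp^2 / se_out^2`; consistent when more
#' than half of the instrument weight comes from valid variants. The
#' standard error is the standard deviation of the estimate over seeded
#' parametric-bootstrap draws (exposure and outcome betas resampled from
#' normal laws at their reported standard errors); the confidence interval
#' and p-value use a normal reference.
#'
#' @param hset a `harmonized_set` with at least two SNPs.
#' @param n_boot parametric bootstrap draws for the standard error; `0`
#'   skips the bootstrap (SE, CI and p are then `NA`; useful in
#'   simulation loops that only need the point estimate).
#' @param seed integer seed for the bootstrap.
#' @return an `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000L, seed = 1L) {
  r <- .hset_rows(hset)
  J <- nrow(r)
  if (J < 2L) stop("weighted median requires at least 2 SNPs", call. = FALSE)
  w <- r$beta_exp^2 / r$se_out^2
  theta <- .weighted_median_point(r$beta_out / r$beta_exp, w)
  if (n_boot > 0L) {
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(J, r$beta_exp, r$se_exp)
      by <- rnorm(J, r$beta_out, r$se_out)
      wb <- bx^2 / r$se_out^2
      ok <- bx != 0
      .weighted_median_point(by[ok] / bx[ok], wb[ok])
    }, 0)
    se <- sd(boot)
    p <- 2 * pnorm(-abs(theta / se))
    .mr_estimate("weighted_median", theta, se, p, J)
  } else {
    .mr_estimate("weighted_median", theta, NA_real_, NA_real_, J,
                 ci_low = NA_real_, ci_high = NA_real_)
  }
}

#' Run every applicable MR method on a harmonized set
#'
#' Applies each estimator whose minimum SNP count is met: the Wald ratio
#' for a single SNP; IVW (flagged as the primary method) and the weighted
#' median from two SNPs; MR-Egger from three. Egger and the weighted
#' median serve as pleiotropy sensitivity analyses alongside IVW.
#'
#' @param hset a `harmonized_set`.
#' @param seed seed for the weighted-median bootstrap.
#' @param n_boot bootstrap draws, see [mr_weighted_median()].
#' @return a named list of `mr_estimate`s; the attribute `"primary"` names
#'   the primary method.
#' @export
run_all_methods <- function(hset, seed = 1L, n_boot = 1000L) {
  r <- .hset_rows(hset)
  J <- nrow(r)
  if (J < 1L) stop("empty harmonized set", call. = FALSE)
  out <- list()
  if (J == 1L) {
    out$wald_ratio <- wald_ratio(hset)
  } else {
    out$ivw_mre <- mr_ivw(hset)
    if (J >= 3L) out$egger <- mr_egger(hset)
    out$weighted_median <- mr_weighted_median(hset, n_boot = n_boot,
                                              seed = seed)
  }
  attr(out, "primary") <- if (J == 1L) "wald_ratio" else "ivw_mre"
  out
}
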
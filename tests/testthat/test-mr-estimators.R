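test_that("the Wald ratio matches its delta-method closed form", {
  h <- harmonized_set(0.5, 0.01, 0.1, 0.05)
  e <- wald_ratio(h)
  expect_equal(e$theta, 0.2)
  expect_equal(e$se, 0.1)

  h0 <- harmonized_set(0.5, 0.01, 0, 0.05)
  expect_equal(wald_ratio(h0)$theta, 0)

  expect_error(wald_ratio(harmonized_set(1e-300 * 0, 0.01, 0.1, 0.05)),
               "zero")

  for (seed in 1:20) {
    set.seed(seed)
    bx <- rnorm(1, 0.2, 0.05); by <- rnorm(1, 0.1, 0.05)
    sy <- runif(1, 0.01, 0.1)
    e <- wald_ratio(harmonized_set(bx, 0.01, by, sy))
    expect_equal(e$theta, by / bx, tolerance = 1e-12)
    expect_equal(e$se, sy / abs(bx), tolerance = 1e-12)
  }
})

test_that("IVW returns the common ratio exactly when ratios are collinear", {
  h <- harmonized_set(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.10),
                      c(0.02, 0.03))
  e <- mr_ivw(h)
  expect_equal(e$theta, 0.5, tolerance = 1e-12)
  expect_equal(e$q_stat, 0, tolerance = 1e-20)

  expect_error(mr_ivw(harmonized_set(0.1, 0.01, 0.05, 0.02)), "wald_ratio")
})

# Independent WLS-through-origin oracle via explicit normal equations.
ivw_oracle <- function(bx, by, sy) {
  w <- 1 / sy^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  q <- sum((bx^2 / sy^2) * (by / bx - theta)^2)
  se <- sqrt(1 / sum(w * bx^2)) * max(1, sqrt(q / (length(bx) - 1)))
  list(theta = theta, q = q, se = se)
}

test_that("IVW equals a weighted-least-squares oracle with MRE inflation", {
  h <- harmonized_set(c(0.10, 0.20, 0.15, 0.12), rep(0.01, 4),
                      c(0.05, 0.09, 0.08, 0.05), rep(0.02, 4))
  e <- mr_ivw(h)
  o <- ivw_oracle(h$rows$beta_exp, h$rows$beta_out, h$rows$se_out)
  expect_equal(e$theta, o$theta, tolerance = 1e-12)
  expect_equal(e$q_stat, o$q, tolerance = 1e-12)
  expect_equal(e$se, o$se, tolerance = 1e-12)
  # and against lm as a second, library-based route for the point estimate
  fit <- lm(beta_out ~ 0 + beta_exp, data = h$rows,
            weights = 1 / h$rows$se_out^2)
  expect_equal(e$theta, unname(coef(fit)), tolerance = 1e-12)

  for (seed in 1:25) {
    h <- random_hset(sample(3:20, 1), seed = seed)
    e <- mr_ivw(h)
    o <- ivw_oracle(h$rows$beta_exp, h$rows$beta_out, h$rows$se_out)
    expect_equal(e$theta, o$theta, tolerance = 1e-12)
    expect_equal(e$se, o$se, tolerance = 1e-12)
  }
})

test_that("Egger recovers a noiseless affine relation exactly", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  by <- 0.1 + 0.3 * bx
  e <- mr_egger(harmonized_set(bx, rep(0.01, 4), by, rep(0.02, 4)))
  expect_equal(e$theta, 0.3, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$q_stat, 0, tolerance = 1e-18)

  expect_error(mr_egger(harmonized_set(c(0.1, 0.2), rep(0.01, 2),
                                       c(0.1, 0.2), rep(0.02, 2))),
               "at least 3")
  expect_error(mr_egger(harmonized_set(rep(0.1, 4), rep(0.01, 4),
                                       rnorm(4), rep(0.02, 4))),
               "unidentifiable")
})

test_that("Egger matches a weighted lm oracle with MRE-scaled t inference", {
  for (seed in 1:25) {
    h <- random_hset(sample(4:20, 1), seed = seed + 100)
    r <- h$rows
    flip <- r$beta_exp < 0
    r$beta_out[flip] <- -r$beta_out[flip]
    r$beta_exp[flip] <- -r$beta_exp[flip]
    w <- 1 / r$se_out^2
    fit <- lm(beta_out ~ beta_exp, data = r, weights = w)
    sm <- summary(fit)
    J <- nrow(r)
    # lm's sigma-based SEs equal fixed-effect SEs times sqrt(Q/(J-2));
    # the estimator never deflates, so divide out sigma and apply the floor
    q <- sum(w * residuals(fit)^2)
    scale_back <- sm$sigma / max(1, sqrt(q / (J - 2)))
    e <- mr_egger(h)
    expect_equal(e$theta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(e$egger_intercept, unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(e$se, unname(sm$coefficients[2, 2]) / scale_back,
                 tolerance = 1e-10)
    expect_equal(e$egger_intercept_se,
                 unname(sm$coefficients[1, 2]) / scale_back,
                 tolerance = 1e-10)
    expect_equal(e$pval, 2 * pt(-abs(e$theta / e$se), J - 2),
                 tolerance = 1e-12)
  }
})

test_that("the weighted median interpolates cumulative weight midpoints", {
  h <- harmonized_set(c(0.1, 0.2, 0.4), rep(0.01, 3),
                      0.4 * c(0.1, 0.2, 0.4), c(0.01, 0.02, 0.04))
  e <- mr_weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(e$theta, 0.4, tolerance = 1e-12)  # constant ratios

  # three equally weighted ratios 0.1/0.2/0.3: midpoint lands on 0.2
  bx <- rep(0.1, 3)
  by <- c(0.01, 0.02, 0.03)
  e <- mr_weighted_median(harmonized_set(bx, rep(0.01, 3), by,
                                         rep(0.02, 3)),
                          n_boot = 100, seed = 1)
  expect_equal(e$theta, 0.2, tolerance = 1e-12)

  expect_error(mr_weighted_median(harmonized_set(0.1, 0.01, 0.1, 0.02)),
               "at least 2")
})

test_that("the weighted-median bootstrap is seeded and reproducible", {
  h <- random_hset(12, seed = 9)
  e1 <- mr_weighted_median(h, n_boot = 200, seed = 42)
  e2 <- mr_weighted_median(h, n_boot = 200, seed = 42)
  e3 <- mr_weighted_median(h, n_boot = 200, seed = 43)
  expect_identical(e1, e2)
  expect_false(identical(e1$se, e3$se))
  expect_true(e1$se > 0)
})

test_that("method gating follows the per-method SNP minima", {
  h1 <- random_hset(1, seed = 1)
  expect_named(run_all_methods(h1), "wald_ratio")
  h2 <- random_hset(2, seed = 2)
  expect_named(run_all_methods(h2, n_boot = 50),
               c("ivw_mre", "weighted_median"))
  h10 <- random_hset(10, seed = 3)
  res <- run_all_methods(h10, n_boot = 50)
  expect_named(res, c("ivw_mre", "egger", "weighted_median"))
  expect_identical(attr(res, "primary"), "ivw_mre")
})

test_that("estimates are scale-equivariant in the outcome units", {
  for (seed in 1:5) {
    h <- random_hset(8, seed = seed)
    c_scale <- 2.7
    hs <- h
    hs$rows$beta_out <- c_scale * hs$rows$beta_out
    hs$rows$se_out <- c_scale * hs$rows$se_out
    for (f in list(mr_ivw, mr_egger)) {
      e <- f(h); es <- f(hs)
      expect_equal(es$theta, c_scale * e$theta, tolerance = 1e-10)
      expect_equal(es$se, c_scale * e$se, tolerance = 1e-10)
      expect_equal(es$pval, e$pval, tolerance = 1e-10)
    }
    e <- mr_weighted_median(h, n_boot = 0)
    es <- mr_weighted_median(hs, n_boot = 0)
    expect_equal(es$theta, c_scale * e$theta, tolerance = 1e-10)
  }
})

test_that("estimates are invariant to per-SNP allele orientation", {
  for (seed in 1:5) {
    h <- random_hset(9, seed = seed + 50)
    hf <- h
    flip <- seq_len(9) %% 2 == 0
    hf$rows$beta_exp[flip] <- -hf$rows$beta_exp[flip]
    hf$rows$beta_out[flip] <- -hf$rows$beta_out[flip]
    expect_equal(mr_ivw(hf)$theta, mr_ivw(h)$theta, tolerance = 1e-12)
    expect_equal(mr_ivw(hf)$se, mr_ivw(h)$se, tolerance = 1e-12)
    expect_equal(mr_egger(hf)$theta, mr_egger(h)$theta, tolerance = 1e-12)
    expect_equal(mr_egger(hf)$egger_intercept, mr_egger(h)$egger_intercept,
                 tolerance = 1e-12)
    expect_equal(mr_weighted_median(hf, n_boot = 0)$theta,
                 mr_weighted_median(h, n_boot = 0)$theta,
                 tolerance = 1e-12)
  }
})
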
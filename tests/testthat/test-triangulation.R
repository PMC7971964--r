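test_that("the corrected threshold divides alpha by the effective tests", {
  expect_equal(signif(corrected_threshold(0.05, 17), 2), 0.0029)
  expect_equal(corrected_threshold(0.05, 1), 0.05)
  expect_equal(corrected_threshold(0.01, 4), 0.0025)
  expect_error(corrected_threshold(1.2, 17), "alpha")
  expect_error(corrected_threshold(0.05, 0), "effective_tests")
})

test_that("effective tests counts principal components to the target", {
  set.seed(10)
  indep <- matrix(rnorm(4000 * 10), 4000)
  k <- effective_tests_from_panel(indep, 0.95)
  expect_true(abs(k - 10) <= 1)

  copies <- matrix(rnorm(200), 200, 5)
  expect_equal(effective_tests_from_panel(copies, 0.95), 1L)

  degen <- cbind(rnorm(100), rep(1, 100))
  colnames(degen) <- c("a", "b")
  expect_error(effective_tests_from_panel(degen, 0.95), "zero-variance")
})

test_that("consistency verdicts follow the selection/replication rule", {
  thr <- corrected_threshold(0.05, 17)
  row <- function(ap, at, mp, mt) {
    classify_consistency("m", at, 0.02, ap, mt, 0.02, mp, threshold = thr)
  }
  # the citrate pattern: AMV passes the corrected threshold, MR has the
  # same (negative) sign with p < 0.05
  citrate <- row(1e-4, -0.08, 0.03, -0.03)
  expect_true(citrate$amv_passes); expect_false(citrate$mr_passes)
  expect_identical(citrate$verdict, "consistent")

  # direction disagreement despite a strong second arm
  expect_identical(row(1e-4, 0.2, 0.01, -0.1)$verdict, "not_consistent")
  # neither passes
  expect_identical(row(0.5, 0.1, 0.4, 0.1)$verdict, "not_selected")
  # MR selects, AMV replicates
  expect_identical(row(0.04, 0.05, 1e-4, 0.06)$verdict, "consistent")
  # MR selects, AMV same sign but p >= 0.05
  expect_identical(row(0.07, 0.05, 1e-4, 0.06)$verdict, "not_consistent")
  # both pass: symmetric rule, sign decides
  expect_identical(row(1e-4, 0.06, 1e-3, 0.08)$verdict, "consistent")
  expect_identical(row(1e-4, 0.06, 1e-3, -0.08)$verdict, "not_consistent")
  # zero estimates never count as sign agreement
  expect_identical(row(1e-4, 0, 0.01, 0.1)$verdict, "not_consistent")
})

test_that("verdicts agree with an exhaustive truth-table oracle", {
  thr <- 0.0029
  ps <- c(1e-4, 0.002, 0.0029, 0.01, 0.049, 0.05, 0.4)
  grid <- expand.grid(ap = ps, mp = ps, sa = c(1, -1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- classify_consistency("m", 0.1, 0.02, g$ap, g$sa * 0.05, 0.02,
                                g$mp, threshold = thr)$verdict
    want <- if (g$ap >= thr && g$mp >= thr) {
      "not_selected"
    } else if (g$ap < thr && g$mp < thr) {
      if (g$sa > 0) "consistent" else "not_consistent"
    } else if (g$ap < thr) {
      if (g$sa > 0 && g$mp < 0.05) "consistent" else "not_consistent"
    } else {
      if (g$sa > 0 && g$ap < 0.05) "consistent" else "not_consistent"
    }
    expect_identical(got, want,
                     label = sprintf("ap=%g mp=%g sign=%d", g$ap, g$mp,
                                     g$sa))
  }
})

test_that("each arm's pass flags depend only on that arm's p-values", {
  thr <- 0.0029
  a <- classify_consistency("m", 0.1, 0.02, 1e-4, 0.05, 0.02, 0.2,
                            threshold = thr)
  b <- classify_consistency("m", 0.1, 0.02, 1e-4, 0.05, 0.02, 1e-5,
                            threshold = thr)
  expect_identical(a$amv_passes, b$amv_passes)
  expect_false(a$mr_passes); expect_true(b$mr_passes)
})

test_that("concordance matches the simple-regression closed form", {
  x <- c(-0.1, 0.05, 0.2, 0.12, -0.07)
  expect_equal(concordance(x, x), list(slope = 1, intercept = 0, r2 = 1))
  cr <- concordance(x, -x)
  expect_equal(cr$slope, -1)
  expect_equal(cr$r2, 1)

  for (seed in 1:10) {
    set.seed(seed)
    a <- rnorm(20, 0, 0.1); m <- 0.6 * a + rnorm(20, 0, 0.05)
    got <- concordance(a, m)
    fit <- lm(m ~ a)
    expect_equal(got$slope, unname(coef(fit)[2]), tolerance = 1e-12)
    expect_equal(got$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
    expect_equal(got$r2, summary(fit)$r.squared, tolerance = 1e-12)
  }
  expect_error(concordance(rep(0.1, 5), rnorm(5)), "zero variance")
  expect_error(concordance(1:2, 1:2), "at least 3")
})

test_that("rendered outputs apply the selection filter deterministically", {
  set.seed(33)
  n <- 20
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    classify_consistency(sprintf("met_%02d", i), rnorm(1, 0, 0.1), 0.02,
                         runif(1), rnorm(1, 0, 0.1), 0.02, runif(1)^3,
                         threshold = 0.0029)
  }))
  d1 <- withr::local_tempdir()
  files <- render_outputs(rows, outdir = d1)
  tri <- read.delim(files[["triangulation"]])
  expect_equal(nrow(tri), n)
  sel <- read.delim(files[["selected"]])
  expect_equal(nrow(sel), sum(rows$amv_passes | rows$mr_passes))
  expect_true(file.exists(files[["plot_exposure"]]))

  d2 <- withr::local_tempdir()
  render_outputs(rows, outdir = d2)
  expect_identical(readLines(file.path(d1, "triangulation.tsv")),
                   readLines(file.path(d2, "triangulation.tsv")))
  expect_identical(readLines(file.path(d1, "selected_associations.tsv")),
                   readLines(file.path(d2, "selected_associations.tsv")))

  none <- rows
  none$amv_passes <- FALSE; none$mr_passes <- FALSE
  d3 <- withr::local_tempdir()
  f3 <- render_outputs(none, outdir = d3)
  expect_equal(length(readLines(f3[["selected"]])), 1L)  # header only
})
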
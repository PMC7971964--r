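test_that("significance filtering is a strict-threshold subset, order kept", {
  rec <- random_records(3, seed = 1)
  rec$pval <- c(1e-9, 1e-7, 4.9e-8)
  ds <- summary_dataset(rec, "t", "binary_exposure")
  kept <- filter_significant(ds)
  expect_identical(kept$records$snp_id, rec$snp_id[c(1, 3)])

  empty <- filter_significant(summary_dataset(rec[0, ], "t", "binary_exposure"))
  expect_equal(n_records(empty), 0L)

  big <- random_dataset(1000, seed = 2)
  big$records$pval <- 10^runif(1000, -10, 0)
  big <- summary_dataset(big$records, "t", "metabolite")
  thr <- 1e-4
  # brute-force oracle: one-line strict filter
  expect_identical(filter_significant(big, thr)$records,
                   { r <- big$records[big$records$pval < thr, ]
                     rownames(r) <- NULL; r })
})

test_that("palindromic SNPs are exactly the A/T and C/G pairs", {
  rec <- random_records(4, seed = 1)
  rec$effect_allele <- c("A", "A", "C", "G")
  rec$other_allele <- c("T", "G", "G", "A")
  ds <- summary_dataset(rec, "t", "binary_exposure")
  expect_identical(drop_palindromic(ds)$records$snp_id, rec$snp_id[c(2, 4)])

  clean <- random_dataset(50, seed = 3, palindromic_frac = 0)
  expect_identical(drop_palindromic(clean)$records, clean$records)

  mixed <- random_dataset(300, seed = 4, palindromic_frac = 0.4)
  pal_oracle <- paste(mixed$records$effect_allele,
                      mixed$records$other_allele) %in%
    c("A T", "T A", "C G", "G C")
  expect_identical(drop_palindromic(mixed)$records$snp_id,
                   mixed$records$snp_id[!pal_oracle])
})

# Independent re-implementation of greedy clumping for the oracle check.
clump_oracle <- function(rec, r2, thr) {
  avail <- rec$snp_id
  kept <- character(0)
  while (length(avail) > 0) {
    sub <- rec[rec$snp_id %in% avail, ]
    sub <- sub[order(sub$pval, sub$snp_id), ]
    top <- sub$snp_id[1]
    kept <- c(kept, top)
    avail <- setdiff(avail, c(top, avail[r2[avail, top] > thr]))
  }
  kept
}

test_that("greedy LD clumping keeps the most significant SNP per region", {
  rec <- random_records(2, seed = 5)
  rec$pval <- c(1e-10, 1e-9)
  ds <- summary_dataset(rec, "t", "binary_exposure")
  ld <- ld_matrix(matrix(c(1, 1, 1, 1), 2), rec$snp_id)
  expect_identical(ld_clump(ds, ld)$records$snp_id, rec$snp_id[1])

  ld0 <- ld_matrix(diag(2), rec$snp_id)
  expect_setequal(ld_clump(ds, ld0)$records$snp_id, rec$snp_id)

  for (seed in 1:20) {
    ds <- random_dataset(10, seed = seed)
    ld <- random_ld(ds$records$snp_id, block_size = 4, r2 = 0.5,
                    seed = seed)
    got <- ld_clump(ds, ld, 0.001)$records$snp_id
    expect_identical(got, clump_oracle(ds$records, unclass(ld), 0.001))
  }
})

test_that("clumping errors on SNPs absent from the LD matrix", {
  ds <- random_dataset(5, seed = 6)
  ld <- random_ld(ds$records$snp_id[1:4], block_size = 2, seed = 1)
  expect_error(ld_clump(ds, ld), ds$records$snp_id[5], fixed = TRUE)
})

test_that("reorientation flips negative-beta records and is idempotent", {
  rec <- random_records(1, seed = 7)
  rec$effect_allele <- "A"; rec$other_allele <- "G"
  rec$beta <- -0.02; rec$eaf <- 0.3
  ds <- summary_dataset(rec, "t", "binary_exposure")
  out <- reorient_to_risk_allele(ds)$records
  expect_identical(out$effect_allele, "G")
  expect_identical(out$other_allele, "A")
  expect_equal(out$beta, 0.02)
  expect_equal(out$eaf, 0.7)

  mixed <- random_dataset(100, seed = 8)
  once <- reorient_to_risk_allele(mixed)
  expect_true(all(once$records$beta >= 0))
  expect_identical(reorient_to_risk_allele(once)$records, once$records)

  pos <- mixed
  pos$records$beta <- abs(pos$records$beta)
  expect_identical(reorient_to_risk_allele(pos)$records, pos$records)
})

test_that("instrument strength is the sum of squared z-scores", {
  rec <- random_records(1, seed = 9)
  rec$beta <- 2; rec$se <- 1
  s <- instrument_strength(summary_dataset(rec, "t", "binary_exposure"))
  expect_equal(unname(s$per_snp_f), 4)
  expect_equal(s$total_f, 4)

  rec2 <- random_records(2, seed = 10)
  rec2$beta <- c(3, 4); rec2$se <- c(1, 1)
  expect_equal(
    instrument_strength(summary_dataset(rec2, "t", "binary_exposure"))$total_f,
    25)

  ds <- random_dataset(200, seed = 11)
  s <- instrument_strength(ds)
  expect_equal(s$total_f, sum((ds$records$beta / ds$records$se)^2))

  expect_error(instrument_strength(summary_dataset(rec[0, ], "t",
                                                   "binary_exposure")),
               "empty")
})

test_that("selection runs filter, palindrome drop, clump in fixed order", {
  # a palindromic SNP with the best p-value: if clumping ran first it would
  # evict its LD partner; dropping palindromes first must rescue the partner
  rec <- random_records(3, seed = 12)
  rec$effect_allele <- c("A", "A", "C")
  rec$other_allele <- c("T", "G", "T")
  rec$pval <- c(1e-12, 1e-9, 1e-8)
  ds <- summary_dataset(rec, "t", "binary_exposure")
  m <- diag(3); m[1, 2] <- m[2, 1] <- 0.9
  ld <- ld_matrix(m, rec$snp_id)
  iset <- select_instruments(ds, ld, threshold = 5e-8)
  expect_setequal(iset$dataset$records$snp_id, rec$snp_id[2:3])
  expect_named(iset$counts,
               c("input", "significant", "non_palindromic", "clumped"))
})
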